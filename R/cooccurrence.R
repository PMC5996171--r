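#' Equal-frequency binning of an abundance profile
#'
#' Discretizes one taxon's per-sample values into \code{B} equal-frequency
#' bins of the ranked values; tied values share the bin of their average rank.
#' The bin count defaults to Sturges' rule, \code{ceiling(log2(n) + 1)}.
#' Binning depends on ranks only, so it is invariant under monotone
#' transformations of the input. A constant vector collapses into bin 0 and is
#' flagged degenerate.
#'
#' @param x numeric per-sample values (n >= 4).
#' @param B number of bins (>= 2); default Sturges.
#' @return an object of class \code{binned_profile}: list with integer
#'   \code{bins} in [0, B-1], \code{B}, and \code{degenerate} flag.
#' @export
bin_profile <- function(x, B = NULL) {
  n <- length(x)
  stopifnot(n >= 4)
  B <- as.integer(B %||% ceiling(log2(n) + 1))
  stopifnot(B >= 2)
  bins <- .bin_profile_cpp(as.numeric(x), B)
  structure(list(bins = bins, B = B,
                 degenerate = length(unique(x)) == 1),
            class = "binned_profile")
}

#' N-dimensional checkerboard score (NC-score)
#'
#' Concordance statistic over binned profiles: across all sample pairs
#' \eqn{(i, j)}, pairs where both taxa's bins are strictly ordered the same
#' way count as concordant (C) and opposite strict orders (checkerboard
#' pattern) as discordant (D); the score is \eqn{(C - D) / (n(n-1)/2)}, in
#' [-1, 1]. Pairs tied in either profile count in neither C nor D. Degenerate
#' (constant) profiles score 0 and are flagged via attribute
#' \code{"degenerate"}.
#'
#' @param a,b \code{binned_profile}s over the same samples with the same
#'   \code{B} (raw integer bin vectors are also accepted).
#' @return the score, a single number in [-1, 1].
#' @export
nc_score <- function(a, b) {
  if (inherits(a, "binned_profile") && inherits(b, "binned_profile")) {
    stopifnot(a$B == b$B, length(a$bins) == length(b$bins))
    if (a$degenerate || b$degenerate)
      return(structure(0, degenerate = TRUE))
    a <- a$bins; b <- b$bins
  }
  stopifnot(length(a) == length(b))
  .nc_score_cpp(as.integer(a), as.integer(b))
}

# Core ReBoot computation for one taxon pair. x, y: relative abundances,
# rest: per-sample abundance of all other taxa (so columns renormalize to 1).
reboot_pair <- function(x, y, rest, B, n_iter) {
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(nc_obs = 0, z = 0, p_raw = 1, degenerate = TRUE))
  }
  st <- .reboot_stats_cpp(as.numeric(x), as.numeric(y), as.numeric(rest),
                          B, as.integer(n_iter))
  vb <- stats::var(st$boot); vn <- stats::var(st$null)
  denom <- sqrt(vb + vn)
  z <- if (denom > 0) (mean(st$boot) - mean(st$null)) / denom else 0
  list(nc_obs = st$nc_obs, z = z,
       p_raw = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' ReBoot significance of one taxon pair
#'
#' Compositionality-corrected significance for the NC-score of two taxa
#' inside a relative-abundance table. The null distribution permutes the two
#' taxa's rows independently across samples and renormalizes every sample
#' column to sum one (so the compositional coupling with the remaining taxa is
#' preserved); the alternative distribution bootstraps samples with
#' replacement. The two-sided p-value is the normal tail of
#' \deqn{z = (\bar{s}_{boot} - \bar{s}_{null}) /
#'       \sqrt{Var(s_{boot}) + Var(s_{null})}.}
#' This pooled-variance comparison is conservative under independence (its
#' null type-I error runs below nominal); see the package vignette.
#'
#' @param r a \code{relative_abundance} (columns summing to 1), or a plain
#'   proportions matrix.
#' @param taxon_a,taxon_b taxon row names (or indices).
#' @param n_iter permutation/bootstrap iterations (>= 100; default 1000).
#' @param seed integer seed (bit-reproducible results for a fixed seed).
#' @param B bin count; default Sturges on the sample count.
#' @return list with \code{nc_obs}, \code{z}, \code{p_raw},
#'   \code{degenerate}.
#' @export
reboot_pvalue <- function(r, taxon_a, taxon_b, n_iter = 1000, seed = NULL,
                          B = NULL) {
  m <- if (inherits(r, "relative_abundance")) r$props else as.matrix(r)
  stopifnot(n_iter >= 100, ncol(m) >= 4)
  x <- m[taxon_a, ]; y <- m[taxon_b, ]
  rest <- pmax(1 - colSums(m), 0) + colSums(m) - x - y
  B <- as.integer(B %||% ceiling(log2(ncol(m)) + 1))
  with_seed(seed, reboot_pair(x, y, rest, B, n_iter))
}

kingdom_pair_class <- function(ka, kb) {
  ifelse(ka == kb,
         ifelse(ka == "bacteria", "bacteria-bacteria", "eukaryote-eukaryote"),
         "inter-kingdom")
}

#' Test all taxon pairs and filter at several significance cutoffs
#'
#' Runs the ReBoot test once per unordered taxon pair (shared across cutoffs;
#' the cutoffs only filter) and returns one edge set per cutoff: raw p < 0.01,
#' 0.001, 0.0001, and the Bonferroni family-wise cutoff
#' \code{alpha / m_tested} with m_tested = T(T-1)/2 pairs at this taxonomic
#' level.
#'
#' @param r a \code{relative_abundance}, typically after
#'   \code{\link{network_prefilter}}. For two-kingdom analyses, concatenate
#'   the per-kingdom tables with \code{\link{bind_kingdoms}} first so each
#'   marker keeps its own composition.
#' @param kingdoms named character vector mapping every taxon to
#'   \code{"bacteria"} or \code{"eukaryote"}.
#' @param cutoffs raw p-value cutoffs (strict <).
#' @param bonferroni_alpha family-wise alpha for the Bonferroni cutoff.
#' @param n_iter ReBoot iterations per pair.
#' @param seed integer seed for the whole sweep.
#' @param B bin count; default Sturges.
#' @param level taxonomic level label recorded on each edge set.
#' @return named list of \code{edge_set} objects (\code{p0.01}, \code{p0.001},
#'   \code{p0.0001}, \code{bonferroni}), each a data.frame of edges
#'   (taxon_a < taxon_b, nc, p_raw, sign, kingdom_pair) with attributes
#'   \code{cutoff_label}, \code{cutoff_value}, \code{level}, \code{m_tested}.
#'   The full untruncated pair table is attached as attribute \code{pairs} of
#'   the returned list.
#' @export
edge_sweep <- function(r, kingdoms, cutoffs = c(0.01, 0.001, 1e-4),
                       bonferroni_alpha = 0.05, n_iter = 1000, seed = 1L,
                       B = NULL, level = "genus") {
  m <- if (inherits(r, "relative_abundance")) r$props else as.matrix(r)
  taxa <- rownames(m)
  stopifnot(length(taxa) >= 2)
  if (!all(taxa %in% names(kingdoms)))
    stop("kingdom mapping missing for: ",
         paste(setdiff(taxa, names(kingdoms)), collapse = ", "))
  B <- as.integer(B %||% ceiling(log2(ncol(m)) + 1))
  pr <- t(combn(taxa, 2))
  # canonical lexicographic order within each pair
  swap <- pr[, 1] > pr[, 2]
  pr[swap, ] <- pr[swap, c(2, 1)]
  n_pairs <- nrow(pr)

  colsum <- colSums(m)
  res <- with_seed(seed, {
    out <- matrix(0, n_pairs, 3,
                  dimnames = list(NULL, c("nc", "z", "p_raw")))
    for (k in seq_len(n_pairs)) {
      x <- m[pr[k, 1], ]; y <- m[pr[k, 2], ]
      rp <- reboot_pair(x, y, colsum - x - y, B, n_iter)
      out[k, ] <- c(rp$nc_obs, rp$z, rp$p_raw)
    }
    out
  })
  pairs <- data.frame(taxon_a = pr[, 1], taxon_b = pr[, 2],
                      nc = res[, "nc"], z = res[, "z"],
                      p_raw = res[, "p_raw"],
                      sign = ifelse(res[, "nc"] > 0, "positive", "negative"),
                      kingdom_pair = kingdom_pair_class(
                        unname(kingdoms[pr[, 1]]), unname(kingdoms[pr[, 2]])),
                      stringsAsFactors = FALSE)

  cutoffs <- sort(cutoffs, decreasing = TRUE)
  labels <- paste0("p", formatC(cutoffs, format = "fg"))
  thr <- c(stats::setNames(cutoffs, labels),
           bonferroni = bonferroni_alpha / n_pairs)
  sets <- lapply(seq_along(thr), function(i) {
    e <- pairs[pairs$p_raw < thr[i], , drop = FALSE]
    rownames(e) <- NULL
    structure(e, cutoff_label = names(thr)[i],
              cutoff_value = unname(thr[i]),
              level = level, m_tested = n_pairs, class = c("edge_set", "data.frame"))
  })
  names(sets) <- names(thr)
  attr(sets, "pairs") <- pairs
  attr(sets, "level") <- level
  sets
}

#' Concatenate per-kingdom relative-abundance tables for pair testing
#'
#' The two markers are separate sequencing compositions, so each kingdom is
#' converted to relative abundance on its own and the rows are then stacked;
#' sample columns are matched by name (intersection).
#'
#' @param a,b \code{relative_abundance} objects (e.g. 16S and 18S).
#' @return a \code{relative_abundance} over the shared samples. Columns sum
#'   to 2 (one composition per kingdom); ReBoot renormalization still operates
#'   within the stacked table.
#' @export
bind_kingdoms <- function(a, b) {
  shared <- intersect(colnames(a$props), colnames(b$props))
  if (!length(shared)) stop("no shared samples between the kingdom tables")
  if (length(intersect(rownames(a$props), rownames(b$props))))
    stop("taxon identifiers collide across kingdoms")
  structure(list(props = rbind(a$props[, shared, drop = FALSE],
                               b$props[, shared, drop = FALSE]),
                 taxon_totals = c(a$taxon_totals, b$taxon_totals),
                 taxonomy = c(a$taxonomy, b$taxonomy),
                 metadata = a$metadata[shared, , drop = FALSE],
                 zero_samples = union(a$zero_samples, b$zero_samples)),
            class = "relative_abundance")
}

#' Summarize an edge set by kingdom-pair class and sign
#'
#' @param e an \code{edge_set}.
#' @param kingdoms optional; unused when the edge set already carries
#'   kingdom-pair classes.
#' @return an object of class \code{edge_class_summary}: list with
#'   \code{counts} (class x sign table), \code{class_pct} (percent of all
#'   edges per class, rounded to nearest integer), \code{sign_pct_within}
#'   (percent positive/negative within each class, rounded), and
#'   \code{n_edges}.
#' @export
classify_edges <- function(e, kingdoms = NULL) {
  stopifnot(inherits(e, "edge_set"))
  classes <- c("bacteria-bacteria", "eukaryote-eukaryote", "inter-kingdom")
  if (nrow(e) && !all(e$kingdom_pair %in% classes))
    stop("unmapped kingdom-pair class present")
  cls <- factor(e$kingdom_pair, levels = classes)
  sgn <- factor(e$sign, levels = c("positive", "negative"))
  counts <- table(class = cls, sign = sgn)
  n <- nrow(e)
  class_tot <- rowSums(counts)
  class_pct <- if (n > 0) round(100 * class_tot / n) else class_tot * NA
  sign_pct <- if (n > 0) {
    t(apply(counts, 1, function(r) {
      if (sum(r) == 0) c(positive = NA_real_, negative = NA_real_)
      else round(100 * r / sum(r))
    }))
  } else counts * NA
  structure(list(counts = counts, class_pct = class_pct,
                 sign_pct_within = sign_pct, n_edges = n),
            class = "edge_class_summary")
}

#' @export
print.edge_class_summary <- function(x, ...) {
  cat(sprintf("%d edges\n", x$n_edges))
  for (cl in rownames(x$counts)) {
    cat(sprintf("  %-22s %4d (%s%%)  +%s%% / -%s%%\n", cl,
                sum(x$counts[cl, ]), x$class_pct[[cl]],
                x$sign_pct_within[cl, "positive"],
                x$sign_pct_within[cl, "negative"]))
  }
  invisible(x)
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set [%s, %s]: %d edges of %d tested pairs (cutoff %g)\n",
              attr(x, "level"), attr(x, "cutoff_label"), nrow(x),
              attr(x, "m_tested"), attr(x, "cutoff_value")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Write an edge set as TSV
#'
#' @param e an \code{edge_set}.
#' @param path output file.
#' @return invisibly, the written data.frame.
#' @export
write_edge_set <- function(e, path) {
  stopifnot(inherits(e, "edge_set"))
  df <- as.data.frame(e)
  df$cutoff_label <- rep(attr(e, "cutoff_label"), nrow(df))
  df$level <- rep(attr(e, "level"), nrow(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
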