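#' Alpha diversity estimators
#'
#' \code{chao1} is the bias-corrected Chao1 richness estimate
#' \eqn{S_{obs} + F_1(F_1 - 1) / (2 (F_2 + 1))} where \eqn{F_1} and \eqn{F_2}
#' are singleton and doubleton counts; it is defined even when no doubletons
#' are observed and reduces to \eqn{S_{obs}} without singletons.
#' \code{shannon} is \eqn{H = -\sum p_i \log_b p_i} (base 2 by default).
#' \code{simpson_evenness} is the inverse Simpson index divided by observed
#' richness, \eqn{(1 / \sum p_i^2) / S_{obs}}.
#' \code{richness} is the observed taxon count.
#'
#' @param counts non-negative integer counts for one sample.
#' @param base logarithm base for \code{shannon}.
#' @return a single number.
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) return(0)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname chao1
#' @export
richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' @rdname chao1
#' @export
shannon <- function(counts, base = 2) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) stop("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p) / log(base))
}

#' @rdname chao1
#' @export
simpson_evenness <- function(counts) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) stop("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  (1 / sum(p^2)) / sum(counts > 0)
}

#' Per-sample alpha diversity table
#'
#' @param t a \code{feature_table}.
#' @param base logarithm base for the Shannon index.
#' @return data.frame with one row per sample: richness, chao1, shannon,
#'   simpson_evenness, plus the sample metadata.
#' @export
alpha_diversity <- function(t, base = 2) {
  stopifnot(inherits(t, "feature_table"))
  res <- data.frame(
    sample = colnames(t$counts),
    richness = apply(t$counts, 2, richness),
    chao1 = apply(t$counts, 2, chao1),
    shannon = apply(t$counts, 2, function(x)
      if (all(x == 0)) NA_real_ else shannon(x, base)),
    simpson_evenness = apply(t$counts, 2, function(x)
      if (all(x == 0)) NA_real_ else simpson_evenness(x)),
    stringsAsFactors = FALSE
  )
  cbind(res, t$metadata[res$sample, , drop = FALSE])
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(i, j) = \sum_t |x_{ti} - x_{tj}| / \sum_t (x_{ti} + x_{tj})} on
#' relative abundances; values lie in [0, 1].
#'
#' @param r a \code{relative_abundance} (or a taxa-by-samples matrix of
#'   proportions).
#' @return a \code{dist} object over samples.
#' @export
bray_curtis <- function(r) {
  m <- if (inherits(r, "relative_abundance")) r$props else as.matrix(r)
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling via double centering. Negative eigenvalues are
#' clipped to zero for the explained-variance fractions and reported.
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param k number of axes requested.
#' @return list with \code{points} (samples x axes), \code{eig} (all
#'   eigenvalues), \code{explained} (fractions over clipped-positive
#'   eigenvalues) and \code{negative_eig} (count of negative eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  k_eff <- min(k, n - 1)
  fit <- suppressWarnings(stats::cmdscale(d, k = k_eff, eig = TRUE))
  pos <- pmax(fit$eig, 0)
  keep <- min(k_eff, sum(fit$eig > sqrt(.Machine$double.eps)))
  if (keep < k) warning(sprintf("only %d positive axes available", keep))
  pts <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts,
       eig = fit$eig,
       explained = pos / sum(pos),
       negative_eig = sum(fit$eig < 0))
}

#' Two-group differential abundance with BH correction
#'
#' Per-taxon Welch's two-sided t-test on relative abundances between two
#' sample groups, after dropping taxa whose total source reads are not
#' strictly greater than \code{min_reads}. P-values are Benjamini-Hochberg
#' adjusted. Taxa with zero variance in both groups get p = 1 and are flagged
#' rather than raising an error.
#'
#' @param r a \code{relative_abundance}.
#' @param group_a,group_b character vectors of sample IDs (each >= 2 samples).
#' @param min_reads absolute read floor (strictly-greater rule), e.g. 250 for
#'   16S and 50 for 18S tables.
#' @return data.frame with taxon, effect (mean proportion difference A - B),
#'   p_value, q_value, and a \code{degenerate} flag.
#' @export
diff_abundance <- function(r, group_a, group_b, min_reads = 0L) {
  stopifnot(inherits(r, "relative_abundance"),
            length(group_a) >= 2, length(group_b) >= 2)
  keep <- r$taxon_totals > min_reads
  m <- r$props[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(taxon = character(), effect = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      degenerate = logical()))
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      c(mean(xa) - mean(xb), 1, 1)
    } else {
      p <- tryCatch(stats::t.test(xa, xb)$p.value, error = function(e) 1)
      c(mean(xa) - mean(xb), p, 0)
    }
  }, numeric(3)))
  out <- data.frame(taxon = rownames(m),
                    effect = res[, 1],
                    p_value = res[, 2],
                    degenerate = res[, 3] == 1,
                    stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("taxon", "effect", "p_value", "q_value", "degenerate")]
}
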