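#' Remove taxa whose lineage matches any of a set of patterns
#'
#' Matching is case-insensitive fixed-substring matching against the full
#' joined lineage string. The special pattern \code{"Unassigned"} additionally
#' matches taxa whose lineage is empty or whitespace-only. Typical use is the
#' removal of host-derived signal: chloroplast reads from a 16S table and
#' Archaeplastida/Plantae or unassigned reads from an 18S table.
#'
#' @param t a \code{feature_table}.
#' @param patterns non-empty character vector of lineage substrings.
#' @return the filtered \code{feature_table}, with attributes
#'   \code{removed_taxa} (count), \code{removed_reads} (count) and
#'   \code{removed_ids}.
#' @export
exclude_lineages <- function(t, patterns) {
  stopifnot(inherits(t, "feature_table"))
  if (!length(patterns)) stop("`patterns` must be non-empty")
  lin <- t$taxonomy
  hit <- rep(FALSE, length(lin))
  for (p in patterns) {
    hit <- hit | grepl(tolower(p), tolower(lin), fixed = TRUE)
    if (tolower(p) == "unassigned")
      hit <- hit | !nzchar(trimws(lin))
  }
  removed <- rownames(t$counts)[hit]
  out <- subset_taxa_ft(t, !hit)
  attr(out, "removed_taxa") <- sum(hit)
  attr(out, "removed_reads") <- sum(t$counts[hit, , drop = FALSE])
  attr(out, "removed_ids") <- removed
  out
}

#' Remove rare taxa below a fraction of the grand total
#'
#' Drops taxa whose total count is strictly less than
#' \code{min_fraction} of the table's grand total (computed before any
#' removal). The default 0.1\% compensates for between-run bleed-through on
#' multiplexed sequencing runs.
#'
#' @param t a \code{feature_table}.
#' @param min_fraction fraction in [0, 1).
#' @return the filtered \code{feature_table} with a \code{removed_taxa}
#'   attribute.
#' @export
filter_min_total_fraction <- function(t, min_fraction = 0.001) {
  stopifnot(inherits(t, "feature_table"),
            min_fraction >= 0, min_fraction < 1)
  grand <- sum(t$counts)
  keep <- rowSums(t$counts) >= min_fraction * grand
  if (!any(keep)) warning("all taxa fell below the total-fraction threshold")
  out <- subset_taxa_ft(t, keep)
  attr(out, "removed_taxa") <- sum(!keep)
  out
}

#' Rarefy samples to a common depth
#'
#' Each sample with at least \code{depth} reads is subsampled without
#' replacement to exactly \code{depth}; samples with fewer reads are dropped
#' and reported, mirroring the practice of removing the lowest-depth samples
#' before normalizing to the smallest remaining library.
#'
#' @param t a \code{feature_table}.
#' @param depth target depth (>= 1).
#' @param seed integer seed; the operation is bit-reproducible given
#'   (input, seed).
#' @return the rarefied \code{feature_table}; dropped sample IDs in attribute
#'   \code{dropped_samples}.
#' @export
rarefy <- function(t, depth, seed = 1L) {
  stopifnot(inherits(t, "feature_table"))
  if (depth <= 0) stop("`depth` must be >= 1")
  totals <- colSums(t$counts)
  drop <- names(totals)[totals < depth]
  keep <- setdiff(colnames(t$counts), drop)
  if (!length(keep)) stop("no sample reaches the rarefaction depth")
  t2 <- subset_samples(t, keep)
  # feasibility is checked above, so vegan's "observed counts" heuristic
  # warning (triggered by tables without singletons) is noise here
  sub <- with_seed(seed, suppressWarnings(vegan::rrarefy(t(t2$counts), depth)))
  t2$counts <- t(sub)
  stopifnot(all(colSums(t2$counts) == depth))
  attr(t2, "dropped_samples") <- drop
  t2
}

.rank_names <- c("domain", "phylum", "class", "order", "family", "genus")

split_lineage <- function(lin, n = length(.rank_names)) {
  parts <- strsplit(lin, ";", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- n
    p[is.na(p)] <- ""
    p
  })
}

#' Collapse a feature table at a taxonomic rank
#'
#' Taxa sharing the lineage prefix down to \code{level} are summed. Taxa whose
#' lineage is unresolved at \code{level} are kept, grouped under their deepest
#' resolved name suffixed \code{"_unresolved"} (so informal groups survive the
#' collapse instead of being discarded). The grand total is conserved.
#'
#' @param t a \code{feature_table}.
#' @param level one of \code{"order"}, \code{"family"}, \code{"genus"}.
#' @return a collapsed \code{feature_table}; group labels are the name at
#'   \code{level} (or \code{"<deepest>_unresolved"}), disambiguated with the
#'   parent rank on label collisions.
#' @export
collapse_taxonomy <- function(t, level = c("genus", "family", "order")) {
  stopifnot(inherits(t, "feature_table"))
  level <- match.arg(level)
  li <- match(level, .rank_names)
  parts <- split_lineage(t$taxonomy)
  key <- character(length(parts))
  label <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    resolved <- which(nzchar(p)[seq_len(li)])
    if (length(resolved) && max(resolved) == li) {
      key[i] <- paste(p[seq_len(li)], collapse = ";")
      label[i] <- p[li]
    } else if (length(resolved)) {
      d <- max(resolved)
      key[i] <- paste(c(p[seq_len(d)], "_unresolved"), collapse = ";")
      label[i] <- paste0(p[d], "_unresolved")
    } else {
      key[i] <- "Unassigned"
      label[i] <- "Unassigned"
    }
  }
  uk <- unique(key)
  counts <- rowsum(t$counts, group = factor(key, levels = uk), reorder = FALSE)
  lab <- label[match(uk, key)]
  # disambiguate label collisions (same genus name under different parents)
  dup <- duplicated(lab) | duplicated(lab, fromLast = TRUE)
  if (any(dup)) {
    parent <- vapply(strsplit(uk, ";", fixed = TRUE), function(p) {
      if (length(p) >= 2) p[length(p) - 1] else ""
    }, "")
    lab[dup] <- ifelse(nzchar(parent[dup]),
                       paste(parent[dup], lab[dup], sep = "."), lab[dup])
    lab <- make.unique(lab)
  }
  rownames(counts) <- lab
  stopifnot(sum(counts) == sum(t$counts))
  feature_table(counts, stats::setNames(uk, lab), t$metadata)
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its sum; all-zero samples stay zero and
#' are flagged. The per-taxon source read totals are retained so downstream
#' prevalence/read-floor filters can reach back to the counts.
#'
#' @param t a \code{feature_table}.
#' @return an object of class \code{relative_abundance}: list with
#'   \code{props} (taxa x samples fractions), \code{taxon_totals},
#'   \code{metadata}, \code{taxonomy} and \code{zero_samples}.
#' @export
to_relative <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  cs <- colSums(t$counts)
  zero <- names(cs)[cs == 0]
  div <- ifelse(cs == 0, 1, cs)
  props <- sweep(t$counts, 2, div, "/")
  structure(list(props = props,
                 taxon_totals = rowSums(t$counts),
                 taxonomy = t$taxonomy,
                 metadata = t$metadata,
                 zero_samples = zero),
            class = "relative_abundance")
}

#' @export
print.relative_abundance <- function(x, ...) {
  cat(sprintf("relative_abundance: %d taxa x %d samples\n",
              nrow(x$props), ncol(x$props)))
  invisible(x)
}

#' Prevalence / abundance / read-floor prefilter for network inference
#'
#' Removes taxa present (count > 0) in fewer than \code{min_prevalence} of
#' samples, taxa whose relative abundance never reaches
#' \code{min_max_abundance} in any sample, and (optionally) taxa whose total
#' source read count is not strictly greater than \code{min_reads}.
#'
#' @param r a \code{relative_abundance}.
#' @param min_prevalence fraction of samples a taxon must occur in (default 5\%).
#' @param min_max_abundance per-sample relative abundance the taxon must reach
#'   at least once (default 1\%).
#' @param min_reads absolute source-read floor, applied as strictly-greater
#'   (default 0 = off).
#' @return the filtered \code{relative_abundance}.
#' @export
network_prefilter <- function(r, min_prevalence = 0.05,
                              min_max_abundance = 0.01, min_reads = 0L) {
  stopifnot(inherits(r, "relative_abundance"))
  n <- ncol(r$props)
  prev <- rowSums(r$props > 0) / n
  mx <- apply(r$props, 1, max)
  keep <- prev >= min_prevalence & mx >= min_max_abundance &
    r$taxon_totals > min_reads
  r$props <- r$props[keep, , drop = FALSE]
  r$taxon_totals <- r$taxon_totals[keep]
  r$taxonomy <- r$taxonomy[rownames(r$props)]
  r
}

#' Shared and niche-specific taxa
#'
#' A taxon is present in a niche when it has count > 0 in at least one sample
#' of that niche. Returns the count of taxa present in exactly each non-empty
#' niche subset, per-niche totals, and each region's percentage of the union
#' (both exact and rounded to the nearest integer).
#'
#' @param t a \code{feature_table}.
#' @param niches niche labels to consider; defaults to those present.
#' @return an object of class \code{niche_sharing} with fields
#'   \code{region_counts}, \code{totals}, \code{percentages},
#'   \code{percentages_rounded} and \code{union_size}. Region names join niche
#'   labels with \code{"+"}.
#' @export
niche_sharing <- function(t, niches = NULL) {
  stopifnot(inherits(t, "feature_table"))
  niche <- as.character(t$metadata$niche)
  niches <- niches %||% sort(unique(niche))
  if (length(niches) < 2) stop("need at least two niches")
  pres <- sapply(niches, function(g) {
    rowSums(t$counts[, niche == g, drop = FALSE]) > 0
  })
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  pattern <- apply(pres, 1, function(z) paste(niches[z], collapse = "+"))
  region_counts <- table(pattern)
  # order regions: singletons, pairs, ..., full set
  regions <- unlist(lapply(seq_along(niches), function(k) {
    apply(combn(niches, k), 2, paste, collapse = "+")
  }))
  rc <- stats::setNames(as.integer(region_counts[regions]), regions)
  rc[is.na(rc)] <- 0L
  union_size <- nrow(pres)
  pct <- 100 * rc / union_size
  structure(list(region_counts = rc,
                 totals = colSums(pres),
                 percentages = pct,
                 percentages_rounded = round(pct),
                 union_size = union_size),
            class = "niche_sharing")
}

#' @export
print.niche_sharing <- function(x, ...) {
  cat(sprintf("niche sharing over %d taxa:\n", x$union_size))
  for (r in names(x$region_counts)) {
    cat(sprintf("  %-30s %6d  (%d%%)\n", r, x$region_counts[[r]],
                x$percentages_rounded[[r]]))
  }
  invisible(x)
}
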