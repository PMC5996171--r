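#' Construct a feature table
#'
#' A feature table bundles a taxa-by-samples matrix of non-negative integer
#' counts, one semicolon-delimited taxonomic lineage per taxon, and per-sample
#' metadata. Every sample must carry a niche label from
#' \code{c("bulk", "rhizosphere", "root")}.
#'
#' @param counts integer matrix, taxa in rows, samples in columns, with
#'   dimnames.
#' @param taxonomy character vector of lineages (ranks separated by ";"),
#'   named by, or parallel to, the rows of \code{counts}. Empty strings are
#'   allowed and treated as unassigned.
#' @param metadata data.frame with one row per sample (rownames = sample IDs)
#'   and at least a \code{niche} column; \code{habitat}, \code{yield} and
#'   \code{marker} are carried along when present.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-integer count at taxon '%s', sample '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, 1], bad[1, 2]]))
  }
  if (is.null(names(taxonomy))) {
    if (length(taxonomy) != nrow(counts))
      stop("`taxonomy` length does not match the number of taxa")
    names(taxonomy) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(taxonomy)))
    stop("taxonomy missing for some taxa")
  taxonomy <- taxonomy[rownames(counts)]
  metadata <- as.data.frame(metadata)
  missing <- setdiff(colnames(counts), rownames(metadata))
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  metadata <- metadata[colnames(counts), , drop = FALSE]
  if (!"niche" %in% colnames(metadata))
    stop("metadata must contain a `niche` column")
  ok <- metadata$niche %in% c("bulk", "rhizosphere", "root")
  if (!all(ok))
    stop("invalid niche label(s): ",
         paste(unique(metadata$niche[!ok]), collapse = ", "))
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "feature_table")
}

#' Read a feature table from classic OTU-table TSV files
#'
#' The counts file has taxon IDs in the first column, one column per sample,
#' and a \code{taxonomy} column (by default the last column, or any column
#' named "taxonomy", case-insensitively) holding semicolon-delimited lineages.
#' The metadata file is keyed by sample ID in its first column.
#'
#' @param counts_path path to the tab-separated counts + taxonomy table.
#' @param metadata_path path to the tab-separated sample metadata table.
#' @return A validated \code{\link{feature_table}}.
#' @export
read_feature_table <- function(counts_path, metadata_path) {
  raw <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
  if (ncol(raw) < 3)
    stop("counts table needs at least one sample column and a taxonomy column")
  tax_col <- which(tolower(colnames(raw)) == "taxonomy")
  if (!length(tax_col)) tax_col <- ncol(raw)
  tax_col <- tax_col[1]
  ids <- as.character(raw[[1]])
  taxonomy <- as.character(raw[[tax_col]])
  taxonomy[is.na(taxonomy)] <- ""
  num <- raw[, -c(1, tax_col), drop = FALSE]
  counts <- as.matrix(num)
  suppressWarnings(storage.mode(counts) <- "double")
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                 ids[bad[1]], colnames(num)[bad[2]]))
  }
  rownames(counts) <- ids
  meta <- read.delim(metadata_path, check.names = FALSE,
                     stringsAsFactors = FALSE, row.names = 1)
  feature_table(counts, stats::setNames(taxonomy, ids), meta)
}

#' Write a feature table (and its metadata) to TSV
#'
#' Taxa are written in lexicographic order and samples in their current order,
#' so repeated writes of the same table are byte-identical.
#'
#' @param t a \code{feature_table}.
#' @param counts_path,metadata_path output paths; \code{metadata_path = NULL}
#'   skips the metadata file.
#' @return Invisibly, \code{t}.
#' @export
write_feature_table <- function(t, counts_path, metadata_path = NULL) {
  stopifnot(inherits(t, "feature_table"))
  ord <- order(rownames(t$counts), method = "radix")
  df <- data.frame(`#OTU ID` = rownames(t$counts)[ord],
                   t$counts[ord, , drop = FALSE],
                   taxonomy = unname(t$taxonomy[ord]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    md <- data.frame(`#SampleID` = rownames(t$metadata), t$metadata,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(t)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d taxa x %d samples (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat("niches:", paste(sprintf("%s=%d", names(table(x$metadata$niche)),
                               table(x$metadata$niche)), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.feature_table <- function(object, ...) {
  depths <- colSums(object$counts)
  cat(sprintf("feature_table: %d taxa, %d samples\n",
              nrow(object$counts), ncol(object$counts)))
  cat(sprintf("sample depth: min %d, median %d, max %d\n",
              min(depths), round(stats::median(depths)), max(depths)))
  cat(sprintf("taxa present per sample: median %d\n",
              round(stats::median(colSums(object$counts > 0)))))
  invisible(object)
}

n_taxa <- function(t) nrow(t$counts)
n_samples <- function(t) ncol(t$counts)

subset_taxa_ft <- function(t, keep) {
  t$counts <- t$counts[keep, , drop = FALSE]
  t$taxonomy <- t$taxonomy[rownames(t$counts)]
  t
}

#' Subset a feature table to a set of samples
#'
#' @param t a \code{feature_table}.
#' @param samples sample IDs to keep.
#' @return a \code{feature_table} restricted to \code{samples}.
#' @export
subset_samples <- function(t, samples) {
  stopifnot(inherits(t, "feature_table"))
  missing <- setdiff(samples, colnames(t$counts))
  if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
  t$counts <- t$counts[, samples, drop = FALSE]
  t$metadata <- t$metadata[samples, , drop = FALSE]
  t
}
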