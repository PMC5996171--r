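test_that("reading round-trips a written table and validates inputs", {
  t <- toy_table(matrix(c(5, 0, 2, 1, 3, 4), 3, 2))
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "counts.tsv"); mp <- file.path(dir, "meta.tsv")
  write_feature_table(t, cp, mp)
  t2 <- read_feature_table(cp, mp)
  expect_equal(dim(t2$counts), dim(t$counts))
  expect_equal(t2$counts[rownames(t$counts), colnames(t$counts)], t$counts)
  expect_equal(unname(t2$taxonomy[rownames(t$counts)]), unname(t$taxonomy))

  # negative count names the offending cell
  bad <- read.delim(cp, check.names = FALSE)
  bad[1, 2] <- -1
  bp <- file.path(dir, "bad.tsv")
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(bp, mp), "negative or non-integer")

  # sample missing from metadata is an error naming the sample
  md <- read.delim(mp, check.names = FALSE)
  mp2 <- file.path(dir, "meta2.tsv")
  write.table(md[-1, ], mp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(cp, mp2), md[1, 1])
})

test_that("constructor rejects duplicates and bad niche labels", {
  m <- matrix(1, 2, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  md <- data.frame(niche = c("bulk", "root"), row.names = c("s1", "s2"))
  expect_error(feature_table(m, c(A = "x", A = "y"), md), "duplicate taxon")
  m2 <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  md_bad <- data.frame(niche = c("bulk", "leaf"), row.names = c("s1", "s2"))
  expect_error(feature_table(m2, c(A = "x", B = "y"), md_bad), "invalid niche")
})

test_that("lineage exclusion removes matching taxa and reports reads", {
  counts <- matrix(c(10, 5, 7, 3, 2, 10, 5, 7, 3, 2), 5, 2,
                   dimnames = list(paste0("T", 1:5), c("s1", "s2")))
  tax <- setNames(c("d__E;p__Archaeplastida;c__X;o__;f__;g__",
                    "d__B;p__P;c__C;o__Chloroplast;f__;g__",
                    "d__E;p__archaeplastida;c__Y;o__;f__;g__",
                    "d__E;p__Fungi;c__C;o__O;f__F;g__G",
                    ""),
                  paste0("T", 1:5))
  t <- toy_table(counts, taxonomy = tax)

  r1 <- exclude_lineages(t, "Chloroplast")
  expect_false("T2" %in% rownames(r1$counts))
  expect_equal(nrow(r1$counts), 4)

  # case-insensitive substring hits both spellings; reads accounted exactly
  r2 <- exclude_lineages(t, "Archaeplastida")
  expect_setequal(rownames(r2$counts), c("T2", "T4", "T5"))
  expect_equal(attr(r2, "removed_reads"), sum(counts[c(1, 3), ]))

  # "Unassigned" also catches the empty lineage
  r3 <- exclude_lineages(t, "Unassigned")
  expect_false("T5" %in% rownames(r3$counts))

  # no matches is a no-op
  r4 <- exclude_lineages(t, "Metazoa")
  expect_equal(rownames(r4$counts), rownames(t$counts))
  expect_error(exclude_lineages(t, character()), "non-empty")
})

test_that("total-fraction filter applies a strict less-than rule", {
  # grand total exactly 10,000; 0.1% threshold = 10 reads
  counts <- cbind(c(9, 10, 11, 9970))
  rownames(counts) <- paste0("T", 1:4); colnames(counts) <- "s1"
  t <- toy_table(counts, niches = "bulk")
  f <- filter_min_total_fraction(t, 0.001)
  expect_setequal(rownames(f$counts), c("T2", "T3", "T4"))
  expect_equal(attr(f, "removed_taxa"), 1)

  expect_equal(rownames(filter_min_total_fraction(t, 0)$counts),
               rownames(t$counts))
  expect_warning(filter_min_total_fraction(t, 0.999), "all taxa")
})

test_that("rarefaction conserves depth, drops shallow samples, is seeded", {
  counts <- matrix(c(60, 40, 0, 40, 50, 30, 4, 3, 2), 3, 3,
                   dimnames = list(paste0("T", 1:3), c("s1", "s2", "s3")))
  t <- toy_table(counts)
  r <- rarefy(t, 100, seed = 7)
  expect_equal(attr(r, "dropped_samples"), "s3")
  expect_equal(unname(colSums(r$counts)), c(100, 100))
  # sample at exactly the target depth is unchanged
  expect_equal(r$counts[, "s1"], counts[, "s1"])
  expect_true(all(r$counts <= counts[, c("s1", "s2")]))

  r2 <- rarefy(t, 100, seed = 7)
  expect_identical(r$counts, r2$counts)
  r3 <- rarefy(t, 50, seed = 1)
  r4 <- rarefy(t, 50, seed = 2)
  expect_equal(unname(colSums(r3$counts)), unname(colSums(r4$counts)))
  expect_error(rarefy(t, 0), "depth")
})

test_that("taxonomic collapse sums groups, keeps unresolved taxa, conserves totals", {
  counts <- matrix(c(3, 4, 5, 6), 4, 1,
                   dimnames = list(paste0("T", 1:4), "s1"))
  tax <- setNames(c("d__B;p__P;c__C;o__O1;f__F1;g__G1",
                    "d__B;p__P;c__C;o__O1;f__F1;g__G1",
                    "d__B;p__P;c__C;o__O1;f__F1;g__G2",
                    "d__B;p__P;c__C;o__O1;f__F1;"),
                  paste0("T", 1:4))
  t <- toy_table(counts, niches = "bulk", taxonomy = tax)
  g <- collapse_taxonomy(t, "genus")
  expect_equal(sum(g$counts), sum(counts))
  expect_equal(unname(g$counts["g__G1", 1]), 7)
  expect_true("f__F1_unresolved" %in% rownames(g$counts))
  expect_equal(unname(g$counts["f__F1_unresolved", 1]), 6)
  f <- collapse_taxonomy(t, "family")
  expect_equal(nrow(f$counts), 1)
})

test_that("collapsing commutes with relative-abundance conversion", {
  set.seed(42)
  counts <- matrix(rpois(60, 20), 10, 6,
                   dimnames = list(paste0("T", 1:10), paste0("s", 1:6)))
  tax <- setNames(sprintf("d__B;p__P;c__C;o__O%d;f__F%d;g__G%d",
                          rep(1:5, each = 2), rep(1:5, each = 2), 1:10),
                  paste0("T", 1:10))
  t <- toy_table(counts, taxonomy = tax)
  a <- to_relative(collapse_taxonomy(t, "family"))$props
  r <- to_relative(t)$props
  grp <- sub(".*(f__F[0-9]+).*", "\\1", t$taxonomy)
  b <- rowsum(r, grp)[rownames(a), , drop = FALSE]
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("relative abundance columns sum to one and flag empty samples", {
  counts <- matrix(c(2, 3, 5, 0, 0, 0), 3, 2,
                   dimnames = list(paste0("T", 1:3), c("s1", "s2")))
  r <- to_relative(toy_table(counts))
  expect_equal(unname(r$props[, "s1"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(r$props[, "s2"]), c(0, 0, 0))
  expect_equal(r$zero_samples, "s2")
})

test_that("network prefilter enforces prevalence, abundance and read floors", {
  n <- 40
  props <- matrix(0.001, 4, n,
                  dimnames = list(paste0("T", 1:4), paste0("s", 1:n)))
  props[1, 1] <- 0.012       # rare but exceeds 1% once -> kept
  props[2, ] <- 0            # absent everywhere
  props[2, 1] <- 0.5         # present in 1/40 samples (2.5%) -> dropped
  props[3, ] <- 0.02         # ubiquitous and abundant -> kept
  props[4, ] <- 0.009        # never reaches 1% -> dropped
  r <- structure(list(props = props,
                      taxon_totals = setNames(c(100, 100, 100, 100),
                                              rownames(props)),
                      taxonomy = setNames(rep("x", 4), rownames(props)),
                      metadata = data.frame(niche = rep("bulk", n),
                                            row.names = colnames(props)),
                      zero_samples = character()),
                 class = "relative_abundance")
  out <- network_prefilter(r)
  expect_setequal(rownames(out$props), c("T1", "T3"))
  # no-op configuration
  out2 <- network_prefilter(r, min_prevalence = 0, min_max_abundance = 0)
  expect_equal(rownames(out2$props), rownames(props))
  # read floor is strictly greater-than
  out3 <- network_prefilter(r, min_prevalence = 0, min_max_abundance = 0,
                            min_reads = 100)
  expect_equal(nrow(out3$props), 0)
})

test_that("niche sharing matches brute-force set enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    counts <- matrix(rbinom(20 * 9, 1, 0.4) * rpois(180, 5), 20, 9,
                     dimnames = list(paste0("T", 1:20), paste0("s", 1:9)))
    t <- toy_table(counts)
    ns <- niche_sharing(t)
    # brute force: presence sets per niche
    niche <- t$metadata$niche
    pres <- lapply(c("bulk", "rhizosphere", "root"), function(g)
      rownames(counts)[rowSums(counts[, niche == g, drop = FALSE]) > 0])
    names(pres) <- c("bulk", "rhizosphere", "root")
    uni <- unique(unlist(pres))
    expect_equal(ns$union_size, length(uni))
    expect_equal(sum(ns$region_counts), length(uni))
    only_bulk <- setdiff(pres$bulk, union(pres$rhizosphere, pres$root))
    expect_equal(unname(ns$region_counts[["bulk"]]), length(only_bulk))
    all3 <- Reduce(intersect, pres)
    expect_equal(unname(ns$region_counts[["bulk+rhizosphere+root"]]),
                 length(all3))
  }
})

test_that("filters never increase counts", {
  set.seed(3)
  counts <- matrix(rpois(80, 6), 10, 8,
                   dimnames = list(paste0("T", 1:10), paste0("s", 1:8)))
  t <- toy_table(counts)
  for (op in list(function(x) exclude_lineages(x, "g__G1"),
                  function(x) filter_min_total_fraction(x, 0.01),
                  function(x) rarefy(x, 30, seed = 1))) {
    out <- op(t)
    shared_t <- intersect(rownames(out$counts), rownames(counts))
    shared_s <- intersect(colnames(out$counts), colnames(counts))
    expect_true(all(out$counts[shared_t, shared_s] <=
                      counts[shared_t, shared_s]))
  }
})
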