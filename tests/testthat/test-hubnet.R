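ab_for <- function(nodes, value = 0.02) setNames(rep(value, length(nodes)), nodes)

test_that("network construction records nodes, edges, weights and abundances", {
  e <- make_edge_set(data.frame(
    taxon_a = c("A", "B", "C"), taxon_b = c("B", "C", "D"),
    sign = c("positive", "negative", "positive"),
    nc = c(0.8, -0.6, 0.7), p_raw = 1e-6,
    kingdom_pair = "bacteria-bacteria"))
  g <- build_network(e, ab_for(LETTERS[1:4]))
  expect_equal(igraph::vcount(g$graph), 4)
  expect_equal(igraph::ecount(g$graph), 3)
  expect_equal(sort(igraph::E(g$graph)$weight), sort(abs(e$nc)))

  # node abundance equals the mean of that taxon's relative abundances
  counts <- matrix(c(2, 2, 6, 4, 0, 6), 3, 2,
                   dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  r <- to_relative(toy_table(counts))
  e2 <- make_edge_set(data.frame(taxon_a = "A", taxon_b = "B",
                                 sign = "positive",
                                 kingdom_pair = "bacteria-bacteria"))
  g2 <- build_network(e2, r)
  expect_equal(igraph::V(g2$graph)$abundance[igraph::V(g2$graph)$name == "A"],
               mean(c(0.2, 0.4)))

  dup <- e
  dup[2, c("taxon_a", "taxon_b")] <- dup[1, c("taxon_a", "taxon_b")]
  expect_error(build_network(dup, ab_for(LETTERS[1:4])), "duplicate")

  empty <- make_edge_set(data.frame(taxon_a = character(),
                                    taxon_b = character(),
                                    sign = character(),
                                    kingdom_pair = character()))
  g3 <- build_network(empty, ab_for("A"))
  expect_equal(igraph::vcount(g3$graph), 0)
})

test_that("centralities match hand values and a BFS oracle", {
  path <- make_edge_set(data.frame(taxon_a = c("a", "b"), taxon_b = c("b", "c"),
                                   sign = "positive",
                                   kingdom_pair = "bacteria-bacteria"))
  ce <- centralities(build_network(path, ab_for(letters[1:3])))
  expect_equal(ce$betweenness[ce$node == "b"], 1)
  expect_equal(ce$betweenness[ce$node == "a"], 0)

  star <- make_edge_set(data.frame(taxon_a = "hub",
                                   taxon_b = paste0("leaf", 1:5),
                                   sign = "positive",
                                   kingdom_pair = "bacteria-bacteria"))
  cs <- centralities(build_network(star, ab_for(c("hub", paste0("leaf", 1:5)))))
  expect_equal(cs$degree[cs$node == "hub"], 5)
  expect_equal(cs$closeness[cs$node == "leaf1"], (1 + 4 * 0.5) / 5)
  expect_equal(cs$closeness[cs$node == "hub"], 1)

  cmb <- t(combn(letters[1:5], 2))
  complete <- make_edge_set(data.frame(taxon_a = cmb[, 1], taxon_b = cmb[, 2],
                                       sign = "positive",
                                       kingdom_pair = "bacteria-bacteria"))
  cc <- centralities(build_network(complete, ab_for(letters[1:5])))
  expect_true(all(cc$betweenness == 0))
  expect_true(all(cc$closeness == 1))

  # random graphs vs the BFS/path-counting oracle (disconnected allowed)
  set.seed(17)
  for (i in 1:8) {
    nn <- sample(5:12, 1)
    nodes <- paste0("n", seq_len(nn))
    pairs <- t(combn(nodes, 2))
    take <- runif(nrow(pairs)) < 0.25
    if (!any(take)) take[1] <- TRUE
    e <- make_edge_set(data.frame(taxon_a = pairs[take, 1],
                                  taxon_b = pairs[take, 2],
                                  sign = "positive",
                                  kingdom_pair = "bacteria-bacteria"))
    g <- build_network(e, ab_for(nodes), include_isolated = nodes)
    ours <- centralities(g)
    oracle <- centralities_brute(
      data.frame(from = e$taxon_a, to = e$taxon_b), nodes)
    ours <- ours[match(oracle$node, ours$node), ]
    expect_equal(ours$degree, oracle$degree, ignore_attr = TRUE)
    expect_equal(ours$betweenness, oracle$betweenness, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(ours$closeness, oracle$closeness, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("normal-fit outlier threshold and its calibration", {
  vals <- c(10, 12, 8)  # mean 10; sd 2
  expect_equal(normal_outlier_threshold(vals, 0.1),
               10 + qnorm(0.9) * 2, tolerance = 1e-12)
  expect_equal(round(10 + qnorm(0.9) * 2, 3), 12.563)

  thr <- normal_outlier_threshold(rep(5, 10))
  expect_true(is.infinite(thr))
  expect_true(attr(thr, "degenerate"))

  set.seed(12)
  x <- rnorm(20000, 3, 1.5)
  frac <- mean(x > normal_outlier_threshold(x, 0.1))
  expect_lt(abs(frac - 0.10), 0.02)
})

test_that("hub calling applies the two-tier consensus rule", {
  # build a star (hub outlier on all three metrics) plus background chain
  star_net <- function(k = 6) {
    e <- make_edge_set(data.frame(
      taxon_a = c(rep("hub", k), "x1", "x2", "x3"),
      taxon_b = c(paste0("leaf", 1:k), "x2", "x3", "x4"),
      sign = "positive", kingdom_pair = "bacteria-bacteria"))
    build_network(e, ab_for(c("hub", paste0("leaf", 1:k), paste0("x", 1:4))))
  }
  chain_net <- function() {
    e <- make_edge_set(data.frame(taxon_a = paste0("x", 1:5),
                                  taxon_b = paste0("x", 2:6),
                                  sign = "positive",
                                  kingdom_pair = "bacteria-bacteria"))
    build_network(e, ab_for(paste0("x", 1:6)))
  }
  nets <- list(
    genus = list(p0.01 = star_net(), p0.001 = star_net(),
                 p0.0001 = chain_net(), bonferroni = chain_net()),
    family = list(p0.01 = star_net(), p0.001 = star_net(),
                  p0.0001 = chain_net(), bonferroni = chain_net()),
    order = list(p0.01 = chain_net(), p0.001 = chain_net(),
                 p0.0001 = chain_net(), bonferroni = chain_net()))
  hr <- call_hubs(nets)
  expect_true(hr$consensus$consensus_hub[hr$consensus$node == "hub"])
  lc <- hr$level_calls
  expect_true(lc$hub_at_level[lc$level == "genus" & lc$node == "hub"])
  expect_false(any(lc$hub_at_level[lc$level == "order"]))

  # outlier in only 1 of 4 networks is not a level hub
  nets1 <- nets
  nets1$genus$p0.001 <- chain_net()
  nets1$family <- nets1$order
  hr1 <- call_hubs(nets1)
  lc1 <- hr1$level_calls
  expect_false(lc1$hub_at_level[lc1$level == "genus" & lc1$node == "hub"])
  expect_false(any(hr1$consensus$consensus_hub))

  # consensus respects a cross-level identity key
  nets2 <- nets
  # rename the hub at the family level, then link it back via the key
  e <- make_edge_set(data.frame(
    taxon_a = c(rep("fhub", 6), "x1", "x2", "x3"),
    taxon_b = c(paste0("leaf", 1:6), "x2", "x3", "x4"),
    sign = "positive", kingdom_pair = "bacteria-bacteria"))
  fam_star <- build_network(e, ab_for(c("fhub", paste0("leaf", 1:6),
                                        paste0("x", 1:4))))
  nets2$family <- list(p0.01 = fam_star, p0.001 = fam_star,
                       p0.0001 = chain_net(), bonferroni = chain_net())
  hr2a <- call_hubs(nets2)
  expect_false(any(hr2a$consensus$consensus_hub))
  hr2b <- call_hubs(nets2, consensus_key = c(hub = "O1", fhub = "O1"))
  expect_true(hr2b$consensus$consensus_hub[hr2b$consensus$node == "O1"])

  # node relabeling does not change who is called
  perm_nets <- lapply(nets, function(levnets) lapply(levnets, function(nw) {
    g2 <- nw
    igraph::V(g2$graph)$name <- paste0("z_", igraph::V(g2$graph)$name)
    g2
  }))
  hrp <- call_hubs(perm_nets)
  expect_equal(sort(paste0("z_", hr$consensus$node[hr$consensus$consensus_hub])),
               sort(hrp$consensus$node[hrp$consensus$consensus_hub]))
})

test_that("level with too few non-empty networks yields no hubs", {
  e <- make_edge_set(data.frame(
    taxon_a = rep("hub", 6), taxon_b = paste0("leaf", 1:6),
    sign = "positive", kingdom_pair = "bacteria-bacteria"))
  empty <- make_edge_set(data.frame(taxon_a = character(),
                                    taxon_b = character(), sign = character(),
                                    kingdom_pair = character()))
  star <- build_network(e, ab_for(c("hub", paste0("leaf", 1:6))))
  nets <- list(genus = list(p0.01 = star,
                            p0.001 = build_network(empty, ab_for("hub")),
                            p0.0001 = build_network(empty, ab_for("hub")),
                            bonferroni = build_network(empty, ab_for("hub"))))
  expect_warning(hr <- call_hubs(nets), "non-empty")
  expect_false(any(hr$level_calls$hub_at_level))
})

test_that("degree never increases across nested cutoff networks", {
  com <- generate_community(canonical_config(seed = 19))
  r <- network_prefilter(to_relative(com$tables[["16S"]]))
  kd <- setNames(rep("bacteria", nrow(r$props)), rownames(r$props))
  sets <- edge_sweep(r, kd, n_iter = 150, seed = 2, level = "genus")
  degs <- lapply(sets, function(e) {
    g <- build_network(e, rowMeans(r$props))
    ce <- centralities(g)
    setNames(ce$degree, ce$node)
  })
  for (i in 1:3) {
    loose <- degs[[i]]; strict <- degs[[i + 1]]
    shared <- intersect(names(loose), names(strict))
    expect_true(all(strict[shared] <= loose[shared]))
  }
})

test_that("cluster abundance aggregates node sets per niche", {
  counts <- matrix(c(2, 2, 6, 4, 0, 6, 1, 1, 8), 3, 3,
                   dimnames = list(c("A", "B", "C"), paste0("s", 1:3)))
  r <- to_relative(toy_table(counts,
                             niches = c("bulk", "bulk", "root")))
  # full set sums to one in every niche
  expect_equal(unname(cluster_abundance(r, c("A", "B", "C"))),
               c(1, 1), tolerance = 1e-12)
  # single taxon: its per-niche mean
  expect_equal(unname(cluster_abundance(r, "A")),
               c(mean(c(0.2, 0.4)), 0.1))
  # two-taxon set vs hand summation
  expect_equal(unname(cluster_abundance(r, c("A", "B"))),
               c(mean(c(0.4, 0.4)), 0.2))
  expect_equal(unname(cluster_abundance(r, character())), c(0, 0))
  expect_error(cluster_abundance(r, "Z"), "Z")
})

test_that("GraphML export round-trips structure and attributes", {
  e <- make_edge_set(data.frame(
    taxon_a = c("A", "B"), taxon_b = c("B", "C"),
    sign = c("positive", "negative"), nc = c(0.9, -0.5), p_raw = 1e-5,
    kingdom_pair = "inter-kingdom"))
  g <- build_network(e, ab_for(c("A", "B", "C")),
                     kingdoms = c(A = "bacteria", B = "eukaryote",
                                  C = "bacteria"))
  f <- withr::local_tempfile(fileext = ".graphml")
  written <- export_graphml(g, f)
  expect_equal(sort(igraph::vertex_attr_names(written)),
               sort(c("name", "abundance", "kingdom", "degree",
                      "betweenness", "closeness")))
  back <- read_graphml(f)
  expect_true(igraph::isomorphic(back, g$graph))
  expect_setequal(igraph::V(back)$name, c("A", "B", "C"))
  expect_equal(sort(igraph::E(back)$nc), sort(e$nc))
  expect_setequal(igraph::E(back)$sign, unique(e$sign))

  empty <- make_edge_set(data.frame(taxon_a = character(),
                                    taxon_b = character(), sign = character(),
                                    kingdom_pair = character()))
  g0 <- build_network(empty, ab_for("A"))
  f0 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g0, f0)
  expect_equal(igraph::vcount(read_graphml(f0)), 0)
})
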