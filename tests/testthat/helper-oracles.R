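# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately written from first principles, separate from
# the package's implementation paths.

toy_table <- function(counts, niches = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("T", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(niches))
    niches <- rep_len(c("bulk", "rhizosphere", "root"), ncol(counts))
  if (is.null(taxonomy))
    taxonomy <- setNames(
      sprintf("d__D;p__P;c__C;o__O%d;f__F%d;g__G%d",
              seq_len(nrow(counts)), seq_len(nrow(counts)), seq_len(nrow(counts))),
      rownames(counts))
  md <- data.frame(niche = niches, habitat = "managed", yield = "none",
                   row.names = colnames(counts))
  feature_table(counts, taxonomy, md)
}

# NC-score by exhaustive enumeration of all sample pairs.
nc_brute <- function(a, b) {
  n <- length(a)
  cd <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (a[i] != a[j] && b[i] != b[j]) {
        same <- (a[i] < a[j]) == (b[i] < b[j])
        cd <- cd + if (same) 1 else -1
      }
    }
  }
  cd / (n * (n - 1) / 2)
}

# Equal-frequency binning oracle via average ranks.
bins_brute <- function(x, B) {
  r <- rank(x, ties.method = "average")
  pmin(B - 1, ceiling(r * B / length(x)) - 1)
}

# Weighted UniFrac by explicit per-branch descendant enumeration.
# Descendant tips are found by walking the edge list recursively.
unifrac_brute <- function(counts, tree) {
  props <- sweep(counts, 2, colSums(counts), "/")
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  n <- ncol(props)
  d <- matrix(0, n, n, dimnames = list(colnames(props), colnames(props)))
  branch_ab <- lapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- desc_tips(tree$edge[e, 2])
    tips <- intersect(tips, rownames(props))
    if (length(tips)) colSums(props[tips, , drop = FALSE]) else rep(0, n)
  })
  len <- tree$edge.length
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      num <- den <- 0
      for (e in seq_along(branch_ab)) {
        ab <- branch_ab[[e]]
        num <- num + len[e] * abs(ab[i] - ab[j])
        den <- den + len[e] * (ab[i] + ab[j])
      }
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  as.dist(d)
}

# Single-factor PERMANOVA F and R2 straight from the definitions.
permanova_stats_brute <- function(dm, groups) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  ss <- function(idx) {
    s <- 0
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (i < j) s <- s + dm[idx[i], idx[j]]^2
      }
    }
    s
  }
  ss_t <- ss(seq_len(n)) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + ss(idx) / length(idx)
  }
  a <- length(unique(groups))
  f <- ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  list(r2 = (ss_t - ss_w) / ss_t, f = f)
}

# Recursive permutation generator (independent of the package's).
perms_brute <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_brute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

permanova_p_brute <- function(dm, groups) {
  obs <- permanova_stats_brute(dm, groups)$f
  fs <- vapply(perms_brute(groups), function(g)
    permanova_stats_brute(dm, g)$f, numeric(1))
  mean(fs >= obs - 1e-12)
}

# Benjamini-Hochberg step-up from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- prev
  }
  pmin(q, 1)
}

# All-pairs shortest paths by BFS; betweenness by path counting.
centralities_brute <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(x) character()), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  n <- length(nodes)
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  npaths <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist[s, s] <- 0; npaths[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- dist[s, u] + 1
            npaths[s, v] <- npaths[s, u]
            nxt <- union(nxt, v)
          } else if (dist[s, v] == dist[s, u] + 1) {
            npaths[s, v] <- npaths[s, v] + npaths[s, u]
          }
        }
      }
      frontier <- nxt
    }
  }
  btw <- setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t || is.infinite(dist[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + npaths[s, v] * npaths[v, t] / npaths[s, t]
        }
      }
    }
  }
  deg <- vapply(nodes, function(x) length(adj[[x]]), numeric(1))
  harm <- vapply(seq_len(n), function(s) {
    d <- dist[s, -s]
    sum(1 / d[is.finite(d) & d > 0]) / (n - 1)
  }, numeric(1))
  data.frame(node = nodes, degree = deg,
             betweenness = if (n >= 3) btw / ((n - 1) * (n - 2) / 2) else 0,
             closeness = harm, row.names = NULL)
}

# Build an edge_set object directly (for tests that plant edges by hand).
make_edge_set <- function(df, cutoff_label = "bonferroni", level = "genus",
                          m_tested = nrow(df)) {
  df$taxon_a <- as.character(df$taxon_a)
  df$taxon_b <- as.character(df$taxon_b)
  swap <- df$taxon_a > df$taxon_b
  tmp <- df$taxon_a[swap]; df$taxon_a[swap] <- df$taxon_b[swap]; df$taxon_b[swap] <- tmp
  if (is.null(df$nc)) df$nc <- ifelse(df$sign == "positive", 0.7, -0.7)
  if (is.null(df$p_raw)) df$p_raw <- rep(1e-6, nrow(df))
  structure(df, cutoff_label = cutoff_label, cutoff_value = 0.05 / m_tested,
            level = level, m_tested = m_tested,
            class = c("edge_set", "data.frame"))
}
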