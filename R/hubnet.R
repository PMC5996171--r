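#' Build a signed co-occurrence network from an edge set
#'
#' Nodes are the taxa incident to at least one retained edge (optionally plus
#' isolated prefiltered-in taxa); edges carry the NC-score magnitude as
#' weight, with the sign and raw p-value kept as attributes. Node size
#' metadata is the taxon's mean relative abundance across samples.
#'
#' @param e an \code{edge_set}.
#' @param abundances a \code{relative_abundance}, or a named vector of mean
#'   relative abundances per taxon.
#' @param kingdoms optional named vector mapping taxa to kingdoms (stored as a
#'   node attribute).
#' @param include_isolated optional character vector of additional (edge-less)
#'   taxa to include as isolated nodes.
#' @return an object of class \code{cooccurrence_network}: list with
#'   \code{graph} (an \pkg{igraph} object), \code{cutoff_label}, \code{level}.
#' @export
build_network <- function(e, abundances, kingdoms = NULL,
                          include_isolated = NULL) {
  stopifnot(inherits(e, "edge_set"))
  if (nrow(e)) {
    key <- paste(e$taxon_a, e$taxon_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate taxon pair in edge set")
    if (any(e$taxon_a == e$taxon_b)) stop("self-loop in edge set")
  }
  ab <- if (inherits(abundances, "relative_abundance")) {
    rowMeans(abundances$props)
  } else abundances
  nodes <- union(unique(c(e$taxon_a, e$taxon_b)), include_isolated)
  if (length(setdiff(nodes, names(ab))))
    stop("abundance missing for: ",
         paste(setdiff(nodes, names(ab)), collapse = ", "))
  vdf <- data.frame(name = nodes,
                    abundance = unname(ab[nodes]),
                    stringsAsFactors = FALSE)
  if (!is.null(kingdoms)) vdf$kingdom <- unname(kingdoms[nodes])
  edf <- if (nrow(e)) {
    data.frame(from = e$taxon_a, to = e$taxon_b,
               weight = abs(e$nc), nc = e$nc, sign = e$sign,
               p_raw = e$p_raw, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), weight = numeric(),
               nc = numeric(), sign = character(), p_raw = numeric())
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  structure(list(graph = g,
                 cutoff_label = attr(e, "cutoff_label"),
                 level = attr(e, "level")),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network [%s, %s]: %d nodes, %d edges\n",
              x$level %||% "?", x$cutoff_label %||% "?",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node centralities of a co-occurrence network
#'
#' Degree is the incident edge count (signs ignored). Betweenness is
#' shortest-path betweenness on the unweighted topology, normalized by
#' \eqn{(N-1)(N-2)/2}. Closeness is harmonic closeness normalized by
#' \eqn{N-1}, which stays well-defined on disconnected graphs (unreachable
#' nodes contribute zero).
#'
#' @param g a \code{cooccurrence_network} (or igraph object).
#' @return data.frame with columns node, degree, betweenness, closeness.
#' @export
centralities <- function(g) {
  gr <- if (inherits(g, "cooccurrence_network")) g$graph else g
  n <- igraph::vcount(gr)
  if (n == 0) {
    return(data.frame(node = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric()))
  }
  deg <- igraph::degree(gr)
  btw <- if (n >= 3) {
    igraph::betweenness(gr, directed = FALSE, weights = NA,
                        normalized = TRUE)
  } else rep(0, n)
  clo <- if (n >= 2) {
    igraph::harmonic_centrality(gr, weights = NA, normalized = TRUE)
  } else rep(0, n)
  data.frame(node = igraph::V(gr)$name, degree = as.integer(deg),
             betweenness = as.numeric(btw), closeness = as.numeric(clo),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Outlier threshold from a normal fit
#'
#' Fits a normal distribution (sample mean and standard deviation) to a
#' centrality population and returns the value above which observations sit
#' in the upper \code{p} tail: \eqn{\bar{x} + z_{1-p} \, s}. A node is an
#' outlier iff its value is strictly greater than the threshold. With zero
#' variance the threshold is \code{Inf} (no outliers) and flagged degenerate.
#'
#' @param values numeric vector (>= 3 values).
#' @param p upper tail probability (default 0.1).
#' @return the threshold, with attribute \code{degenerate} when the fit was
#'   impossible.
#' @export
normal_outlier_threshold <- function(values, p = 0.1) {
  stopifnot(length(values) >= 3, p > 0, p < 1)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    return(structure(Inf, degenerate = TRUE))
  mean(values) + stats::qnorm(1 - p) * s
}

#' Call hub taxa across cutoff networks and taxonomic levels
#'
#' Implements the two-tier consensus rule: within one network a node is an
#' outlier on a metric when its value strictly exceeds the normal-fit
#' threshold computed on that network's own node population; a node is a hub
#' at a taxonomic level when it is an outlier on all three metrics (degree,
#' betweenness, closeness) in at least \code{min_cutoffs} of that level's
#' cutoff networks; a node is a consensus hub when it is a hub at
#' \code{min_levels} or more levels. Taxa absent from a network count as
#' non-outliers there. Thresholds are never pooled across networks.
#'
#' Because collapsing renames taxa per level (a genus node and its family's
#' node carry different labels), the cross-level consensus can match nodes
#' through an optional \code{consensus_key}: a named vector mapping node
#' labels to a shared identity (typically the order-level ancestor, see
#' \code{\link{order_ancestor_key}}); nodes without a key represent
#' themselves.
#'
#' @param networks nested named list: level -> cutoff label ->
#'   \code{cooccurrence_network} (empty networks allowed).
#' @param p upper tail probability of the normal fit (default 0.1).
#' @param min_cutoffs networks (out of the cutoffs supplied) required per
#'   level (default 2).
#' @param min_levels levels required for consensus (default 2).
#' @param consensus_key named character vector: node label -> cross-level
#'   identity.
#' @return an object of class \code{hub_report}: list of data.frames
#'   \code{flags} (per level/cutoff/node: centralities and outlier flags),
#'   \code{level_calls} (per level/node: networks with all-three outlier
#'   status, hub_at_level), and \code{consensus} (per node: levels hubbed,
#'   consensus_hub).
#' @export
call_hubs <- function(networks, p = 0.1, min_cutoffs = 2, min_levels = 2,
                      consensus_key = NULL) {
  flags <- list()
  for (lev in names(networks)) {
    nets <- networks[[lev]]
    nonempty <- sum(vapply(nets, function(nw)
      !is.null(nw) && igraph::vcount(nw$graph) > 0, logical(1)))
    if (nonempty < min_cutoffs)
      warning(sprintf("level '%s': only %d non-empty networks (< %d); no hubs callable",
                      lev, nonempty, min_cutoffs))
    for (cut in names(nets)) {
      nw <- nets[[cut]]
      if (is.null(nw) || igraph::vcount(nw$graph) == 0) next
      ce <- centralities(nw)
      if (nrow(ce) >= 3) {
        thr_d <- normal_outlier_threshold(ce$degree, p)
        thr_b <- normal_outlier_threshold(ce$betweenness, p)
        thr_c <- normal_outlier_threshold(ce$closeness, p)
      } else {
        thr_d <- thr_b <- thr_c <- Inf
      }
      ce$out_degree <- ce$degree > thr_d
      ce$out_betweenness <- ce$betweenness > thr_b
      ce$out_closeness <- ce$closeness > thr_c
      ce$out_all <- ce$out_degree & ce$out_betweenness & ce$out_closeness
      ce$level <- lev
      ce$cutoff <- cut
      flags[[paste(lev, cut)]] <- ce
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(node = character(), degree = integer(),
               betweenness = numeric(), closeness = numeric(),
               out_degree = logical(), out_betweenness = logical(),
               out_closeness = logical(), out_all = logical(),
               level = character(), cutoff = character())
  rownames(flags) <- NULL

  level_calls <- if (nrow(flags)) {
    agg <- stats::aggregate(out_all ~ level + node, data = flags, FUN = sum)
    names(agg)[3] <- "n_networks_all3"
    # levels with too few non-empty networks yield no hubs
    ok_level <- vapply(names(networks), function(lev) {
      sum(vapply(networks[[lev]], function(nw)
        !is.null(nw) && igraph::vcount(nw$graph) > 0, logical(1))) >= min_cutoffs
    }, logical(1))
    agg$hub_at_level <- agg$n_networks_all3 >= min_cutoffs &
      ok_level[agg$level]
    agg
  } else {
    data.frame(level = character(), node = character(),
               n_networks_all3 = integer(), hub_at_level = logical())
  }

  key_of <- function(nodes) {
    if (is.null(consensus_key)) return(nodes)
    k <- unname(consensus_key[nodes])
    ifelse(is.na(k), nodes, k)
  }
  consensus <- if (nrow(level_calls)) {
    lc <- level_calls
    lc$key <- key_of(lc$node)
    hub_lv <- unique(lc[lc$hub_at_level, c("key", "level")])
    nl <- if (nrow(hub_lv)) table(hub_lv$key) else table(character())
    keys <- sort(unique(lc$key))
    agg2 <- data.frame(node = keys,
                       n_levels = as.integer(nl[keys]),
                       stringsAsFactors = FALSE)
    agg2$n_levels[is.na(agg2$n_levels)] <- 0L
    agg2$consensus_hub <- agg2$n_levels >= min_levels
    agg2$members <- vapply(keys, function(k)
      paste(sort(unique(lc$node[lc$key == k])), collapse = ","), "")
    agg2[order(-agg2$n_levels, agg2$node), ]
  } else {
    data.frame(node = character(), n_levels = integer(),
               consensus_hub = logical(), members = character())
  }
  rownames(consensus) <- NULL
  structure(list(flags = flags, level_calls = level_calls,
                 consensus = consensus,
                 consensus_key = consensus_key,
                 params = list(p = p, min_cutoffs = min_cutoffs,
                               min_levels = min_levels)),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  hubs <- x$consensus$node[x$consensus$consensus_hub]
  cat(sprintf("hub_report: %d consensus hub(s)%s\n", length(hubs),
              if (length(hubs)) paste0(": ", paste(hubs, collapse = ", ")) else ""))
  lv <- x$level_calls[x$level_calls$hub_at_level, , drop = FALSE]
  if (nrow(lv)) {
    for (lev in unique(lv$level))
      cat(sprintf("  %s-level hubs: %s\n", lev,
                  paste(lv$node[lv$level == lev], collapse = ", ")))
  }
  invisible(x)
}

#' Write a hub report as a flat TSV (one row per level/cutoff/node)
#'
#' @param h a \code{hub_report}.
#' @param path output file.
#' @return invisibly, the flags table.
#' @export
write_hub_report <- function(h, path) {
  stopifnot(inherits(h, "hub_report"))
  df <- merge(h$flags,
              h$level_calls[, c("level", "node", "hub_at_level")],
              by = c("level", "node"), all.x = TRUE)
  key <- if (is.null(h$consensus_key)) df$node else {
    k <- unname(h$consensus_key[df$node])
    ifelse(is.na(k), df$node, k)
  }
  df$consensus_hub <- h$consensus$consensus_hub[match(key, h$consensus$node)]
  df <- df[order(df$level, df$cutoff, df$node), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Cross-level node identity from collapsed lineages
#'
#' Maps each collapsed node label to its order-level ancestor name, so hub
#' calls on a genus, its family and its order can be recognized as the same
#' taxon when forming the cross-level consensus. Nodes not resolved at the
#' order rank keep their full collapse key (which is identical at every
#' level by construction).
#'
#' @param taxonomy named character vector as carried by a collapsed table
#'   (\code{t$taxonomy} or \code{r$taxonomy}): node label -> lineage prefix.
#' @return named character vector: node label -> consensus identity.
#' @export
order_ancestor_key <- function(taxonomy) {
  out <- vapply(taxonomy, function(k) {
    parts <- trimws(strsplit(k, ";", fixed = TRUE)[[1]])
    if (length(parts) >= 4 && nzchar(parts[4]) && parts[4] != "_unresolved")
      parts[4]
    else k
  }, "")
  names(out) <- names(taxonomy)
  out
}

#' Combined relative abundance of a node set per niche
#'
#' For each niche, the mean over that niche's samples of the summed relative
#' abundances of the given taxa.
#'
#' @param r a \code{relative_abundance}.
#' @param node_set taxa (must be rows of \code{r}); an empty set gives zeros.
#' @param niches niche labels to report; defaults to those present.
#' @return named numeric vector, one entry per niche.
#' @export
cluster_abundance <- function(r, node_set, niches = NULL) {
  stopifnot(inherits(r, "relative_abundance"))
  if (length(setdiff(node_set, rownames(r$props))))
    stop("node_set taxa not in table: ",
         paste(setdiff(node_set, rownames(r$props)), collapse = ", "))
  niche <- as.character(r$metadata$niche)
  niches <- niches %||% sort(unique(niche))
  tot <- if (length(node_set)) {
    colSums(r$props[node_set, , drop = FALSE])
  } else rep(0, ncol(r$props))
  vapply(niches, function(g) mean(tot[niche == g]), numeric(1))
}

#' Export a network as GraphML (and read it back)
#'
#' Writes GraphML with node attributes (abundance, kingdom when present,
#' degree, betweenness, closeness, and hub flags when supplied) and edge
#' attributes (nc, sign, p_raw). The export round-trips through
#' \code{read_graphml}.
#'
#' @param g a \code{cooccurrence_network}.
#' @param path output path.
#' @param hub_flags optional named logical vector (consensus-hub status per
#'   node).
#' @return invisibly, the annotated igraph object that was written.
#' @export
export_graphml <- function(g, path, hub_flags = NULL) {
  stopifnot(inherits(g, "cooccurrence_network"))
  gr <- g$graph
  ce <- centralities(g)
  if (nrow(ce)) {
    idx <- match(igraph::V(gr)$name, ce$node)
    gr <- igraph::set_vertex_attr(gr, "degree", value = ce$degree[idx])
    gr <- igraph::set_vertex_attr(gr, "betweenness", value = ce$betweenness[idx])
    gr <- igraph::set_vertex_attr(gr, "closeness", value = ce$closeness[idx])
    if (!is.null(hub_flags)) {
      hf <- unname(hub_flags[igraph::V(gr)$name])
      hf[is.na(hf)] <- FALSE
      gr <- igraph::set_vertex_attr(gr, "hub", value = as.integer(hf))
    }
  }
  igraph::write_graph(gr, path, format = "graphml")
  invisible(gr)
}

#' @rdname export_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
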