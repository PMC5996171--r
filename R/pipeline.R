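#' Declarative configuration for the full analysis pipeline
#'
#' Defaults reproduce the study's stated settings: 0.1\% bleed-through
#' filter, rarefaction to the smallest retained library per kingdom, 5\%
#' prevalence and 1\% max-abundance network prefilters, cutoffs
#' \{0.01, 0.001, 0.0001, Bonferroni(0.05)\}, genus/family/order levels,
#' normal-fit outlier p = 0.1 with the 2-of-4-cutoffs / 2-of-3-levels hub
#' consensus, and 999 PERMANOVA permutations.
#'
#' @param table_16s,table_18s,metadata input TSV paths.
#' @param tree_16s,tree_18s optional newick paths (enable weighted UniFrac).
#' @param output_dir run directory (all outputs under fixed names).
#' @param exclude_16s,exclude_18s lineage exclusion patterns per kingdom.
#' @param min_total_fraction bleed-through filter fraction.
#' @param rarefy_depth integer depth, or \code{"auto-min"} (smallest sample
#'   per kingdom after the preceding filters).
#' @param min_prevalence,min_max_abundance,min_reads network prefilter
#'   parameters.
#' @param levels taxonomic collapse levels.
#' @param cutoffs raw p-value cutoffs; \code{bonferroni_alpha} the
#'   family-wise alpha.
#' @param n_iter ReBoot iterations per pair.
#' @param B NC-score bin count (NULL = Sturges).
#' @param outlier_p,min_cutoffs,min_levels hub-calling parameters.
#' @param n_perm PERMANOVA permutations.
#' @param scenarios named list of niche subsets analyzed as separate network
#'   scopes.
#' @param seed master seed for every stochastic stage.
#' @return a \code{run_config} list.
#' @export
run_config <- function(table_16s, table_18s, metadata,
                       tree_16s = NULL, tree_18s = NULL,
                       output_dir = "ncnet_run",
                       exclude_16s = c("Chloroplast"),
                       exclude_18s = c("Archaeplastida", "Plantae", "Unassigned"),
                       min_total_fraction = 0.001,
                       rarefy_depth = "auto-min",
                       min_prevalence = 0.05, min_max_abundance = 0.01,
                       min_reads = 0L,
                       levels = c("genus", "family", "order"),
                       cutoffs = c(0.01, 0.001, 1e-4),
                       bonferroni_alpha = 0.05,
                       n_iter = 1000, B = NULL,
                       outlier_p = 0.1, min_cutoffs = 2, min_levels = 2,
                       n_perm = 999,
                       scenarios = list(
                         all = c("bulk", "rhizosphere", "root"),
                         soil = c("bulk", "rhizosphere"),
                         root_assoc = c("rhizosphere", "root")),
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param cfg a \code{run_config}.
#' @export
write_run_config <- function(cfg, path) {
  y <- unclass(cfg)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

write_dist <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

num <- function(x) formatC(x, format = "g", digits = 15)

#' Run the full curation / diversity / network / hub pipeline
#'
#' Stages, per kingdom: lineage exclusion, bleed-through filter, rarefaction;
#' alpha diversity, Bray-Curtis (and weighted UniFrac when trees are given),
#' PCoA, single-factor PERMANOVA on niche. Then, for each niche-subset
#' scenario and each taxonomic level: collapse, relative abundance, network
#' prefilter, two-kingdom ReBoot edge sweep over all cutoffs, edge-class
#' summaries, GraphML export, and hub consensus calling across levels.
#' All outputs live under \code{cfg$output_dir} with fixed names, plus a
#' \code{manifest.yml} with the full configuration, seed, package version and
#' input/output checksums: two runs with identical inputs, configuration and
#' seed are byte-identical.
#'
#' @param cfg a \code{run_config}.
#' @return invisibly, a list with the curated tables, diversity results,
#'   per-scenario edge sets and networks, hub reports and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$table_16s, cfg$table_18s, cfg$metadata,
              cfg$tree_16s, cfg$tree_18s)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  markers <- c("16S", "18S")
  paths <- c("16S" = cfg$table_16s, "18S" = cfg$table_18s)
  exclude <- list("16S" = cfg$exclude_16s, "18S" = cfg$exclude_18s)
  trees <- list("16S" = cfg$tree_16s, "18S" = cfg$tree_18s)

  curated <- list()
  for (m in markers) {
    t <- stage(paste("read", m), read_feature_table(paths[[m]], cfg$metadata))
    t <- stage(paste("exclude", m), exclude_lineages(t, exclude[[m]]))
    t <- stage(paste("bleed-filter", m),
               filter_min_total_fraction(t, cfg$min_total_fraction))
    depth <- if (identical(cfg$rarefy_depth, "auto-min")) {
      min(colSums(t$counts))
    } else cfg$rarefy_depth
    t <- stage(paste("rarefy", m), rarefy(t, depth, seed = cfg$seed))
    curated[[m]] <- t
    write_feature_table(t, out(sprintf("curated_%s.tsv", tolower(m))))
  }

  diversity <- list()
  perm_rows <- list()
  for (m in markers) {
    t <- curated[[m]]
    al <- alpha_diversity(t)
    write_tsv(al, out(sprintf("alpha_%s.tsv", tolower(m))))
    r <- to_relative(t)
    bc <- bray_curtis(r)
    write_dist(bc, out(sprintf("beta_bray_%s.tsv", tolower(m))))
    beta <- bc
    if (!is.null(trees[[m]])) {
      tr <- read_newick(trees[[m]])
      wu <- stage(paste("unifrac", m), weighted_unifrac(t, tr))
      write_dist(wu, out(sprintf("beta_wunifrac_%s.tsv", tolower(m))))
      beta <- wu
    }
    pc <- pcoa(beta, k = 2)
    write_tsv(data.frame(sample = rownames(pc$points), pc$points,
                         check.names = FALSE),
              out(sprintf("pcoa_%s.tsv", tolower(m))))
    pm <- permanova(beta, t$metadata$niche, n_perm = cfg$n_perm,
                    seed = cfg$seed)
    perm_rows[[m]] <- data.frame(marker = m, factor = "niche",
                                 r_squared = pm$r_squared,
                                 p_value = pm$p_value,
                                 n_permutations = pm$n_permutations)
    diversity[[m]] <- list(alpha = al, beta = beta, pcoa = pc, permanova = pm)
  }
  write_tsv(do.call(rbind, perm_rows), out("permanova.tsv"))

  scen_results <- list()
  si <- 0
  for (sc in names(cfg$scenarios)) {
    si <- si + 1
    niches <- cfg$scenarios[[sc]]
    sdir <- out(paste0("scenario_", sc))
    dir.create(sdir, showWarnings = FALSE)
    li <- 0
    lev_networks <- list()
    lev_sets <- list()
    kingdoms_all <- character()
    abund_all <- list()
    consensus_key <- character()
    for (lev in cfg$levels) {
      li <- li + 1
      rel <- list()
      kingdoms <- character()
      for (m in markers) {
        t <- curated[[m]]
        keep <- colnames(t$counts)[t$metadata$niche %in% niches]
        t <- subset_samples(t, keep)
        tc <- collapse_taxonomy(t, lev)
        r <- network_prefilter(to_relative(tc),
                               min_prevalence = cfg$min_prevalence,
                               min_max_abundance = cfg$min_max_abundance,
                               min_reads = cfg$min_reads)
        rel[[m]] <- r
        kingdoms <- c(kingdoms, stats::setNames(
          rep(if (m == "16S") "bacteria" else "eukaryote", nrow(r$props)),
          rownames(r$props)))
      }
      comb <- stage(paste("bind", sc, lev), bind_kingdoms(rel[["16S"]], rel[["18S"]]))
      ck <- order_ancestor_key(comb$taxonomy)
      consensus_key <- c(consensus_key, ck[setdiff(names(ck), names(consensus_key))])
      sets <- stage(paste("edge_sweep", sc, lev),
                    edge_sweep(comb, kingdoms, cutoffs = cfg$cutoffs,
                               bonferroni_alpha = cfg$bonferroni_alpha,
                               n_iter = cfg$n_iter,
                               seed = cfg$seed + 100L * si + li,
                               B = cfg$B, level = lev))
      ab <- rowMeans(comb$props)
      nets <- list()
      for (cut in names(sets)) {
        write_edge_set(sets[[cut]], file.path(sdir,
          sprintf("edges_%s_%s.tsv", lev, cut)))
        nets[[cut]] <- build_network(sets[[cut]], ab, kingdoms = kingdoms)
      }
      cls <- classify_edges(sets[["bonferroni"]])
      cls_df <- data.frame(class = rownames(cls$counts),
                           positive = cls$counts[, "positive"],
                           negative = cls$counts[, "negative"],
                           pct_of_edges = cls$class_pct,
                           pct_positive_within = cls$sign_pct_within[, "positive"],
                           pct_negative_within = cls$sign_pct_within[, "negative"])
      write_tsv(cls_df, file.path(sdir, sprintf("edge_classes_%s.tsv", lev)))
      lev_networks[[lev]] <- nets
      lev_sets[[lev]] <- sets
      kingdoms_all <- c(kingdoms_all, kingdoms[setdiff(names(kingdoms),
                                                       names(kingdoms_all))])
      abund_all[[lev]] <- ab
    }
    hubs <- call_hubs(lev_networks, p = cfg$outlier_p,
                      min_cutoffs = cfg$min_cutoffs,
                      min_levels = cfg$min_levels,
                      consensus_key = consensus_key)
    write_hub_report(hubs, file.path(sdir, "hub_report.tsv"))
    node_key <- ifelse(is.na(consensus_key[names(consensus_key)]),
                       names(consensus_key), consensus_key)
    hub_flags <- stats::setNames(
      hubs$consensus$consensus_hub[match(node_key, hubs$consensus$node)],
      names(consensus_key))
    hub_flags[is.na(hub_flags)] <- FALSE
    for (lev in names(lev_networks)) {
      for (cut in names(lev_networks[[lev]])) {
        export_graphml(lev_networks[[lev]][[cut]],
                       file.path(sdir, sprintf("network_%s_%s.graphml", lev, cut)),
                       hub_flags = hub_flags)
      }
    }
    scen_results[[sc]] <- list(edge_sets = lev_sets, networks = lev_networks,
                               hub_report = hubs)
  }

  inputs <- c(cfg$table_16s, cfg$table_18s, cfg$metadata,
              cfg$tree_16s, cfg$tree_18s)
  outputs <- sort(list.files(cfg$output_dir, recursive = TRUE,
                             full.names = TRUE))
  outputs <- setdiff(outputs, out("manifest.yml"))
  manifest <- list(
    package = "ncnet",
    version = as.character(utils::packageVersion("ncnet")),
    seed = cfg$seed,
    config = {
      y <- unclass(cfg); y[!vapply(y, is.null, logical(1))]
    },
    input_checksums = as.list(tools::md5sum(inputs)),
    output_checksums = as.list(tools::md5sum(outputs)))
  yaml::write_yaml(manifest, out("manifest.yml"))

  invisible(list(curated = curated, diversity = diversity,
                 scenarios = scen_results, manifest = manifest,
                 output_dir = cfg$output_dir))
}
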