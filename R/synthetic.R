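#' Configuration for the synthetic two-kingdom community generator
#'
#' The generator emulates two separately sequenced marker tables (16S
#' bacteria, 18S eukaryotes) over a bulk/rhizosphere/root x managed/forest
#' sample design, with species-sorting niche gradients, planted signed
#' pairwise dependencies, and planted hub taxa. Per-taxon log-abundances
#' follow a latent Gaussian factor model,
#' \deqn{z_i(s) = base_i + niche_i(niche(s)) + \sum_f \lambda_{if} g_f(s) +
#'       \sigma_i \epsilon_i(s),}
#' with \eqn{\sigma_i^2 = 1 - \sum_f \lambda_{if}^2} so each taxon has unit
#' signal variance on top of its base; counts are drawn by multinomial
#' sampling at a log-normal per-sample depth, making the tables compositional
#' by construction. A planted pair with loading \eqn{\lambda} shares one
#' factor with loadings \eqn{\pm\lambda} (latent correlation
#' \eqn{\lambda^2}); a planted hub shares one factor with its k neighbors:
#' hub loading 0.99 and neighbor loadings in a moderate band
#' (\eqn{0.93\lambda} down to \eqn{0.8\lambda}, alternating signs), so
#' hub-neighbor dependencies are detectable while neighbor-neighbor ones fall
#' below the significance cutoffs -- the recovered module is a star centred
#' on the hub. Planted
#' taxa get elevated base abundance and dedicated family/order lineages so
#' the planted structure remains identifiable after taxonomic collapse.
#'
#' @param n_per_group samples per (niche, habitat) cell.
#' @param n_taxa taxa per kingdom (named vector, markers "16S" and "18S").
#' @param depth_meanlog,depth_sdlog log-normal sequencing depth parameters.
#' @param base_sd standard deviation of background base log-abundances.
#' @param noise_sd idiosyncratic log-scale sd of background (factor-free)
#'   taxa; planted taxa keep unit signal variance split between factor and
#'   residual.
#' @param planted_base mean base log-abundance of planted-pair taxa.
#' @param hub_base mean base log-abundance of hub-module taxa; kept moderate
#'   so the module's combined compositional mass stays small enough not to
#'   inject shared denominator noise into every other taxon's proportions.
#' @param n_niche_responsive niche-responsive taxa per kingdom.
#' @param niche_effect_sd sd of the per-taxon log-scale niche shifts
#'   (rhizosphere and root vs bulk).
#' @param planted_edges data.frame(taxon_a, taxon_b, sign, loading); taxa are
#'   OTU ids (B### for 16S, E### for 18S). Loadings in (0, 1].
#' @param planted_hubs data.frame(taxon, k, loading); neighbors are chosen
#'   deterministically from unplanted taxa (split across kingdoms for a hub
#'   with inter-kingdom reach).
#' @param seed integer seed; generation is bit-reproducible.
#' @return a \code{community_config} list.
#' @export
community_config <- function(n_per_group = 5,
                             n_taxa = c("16S" = 40, "18S" = 40),
                             depth_meanlog = log(4000), depth_sdlog = 0.3,
                             base_sd = 0.6, noise_sd = 0.5, planted_base = 0.8, hub_base = 0.5,
                             n_niche_responsive = 16, niche_effect_sd = 0.5,
                             planted_edges = NULL, planted_hubs = NULL,
                             seed = 1L) {
  stopifnot(n_per_group >= 1, all(n_taxa >= 4))
  if (!is.null(planted_edges))
    stopifnot(all(planted_edges$loading > 0), all(planted_edges$loading <= 1),
              all(planted_edges$sign %in% c("positive", "negative")))
  if (!is.null(planted_hubs))
    stopifnot(all(planted_hubs$loading > 0), all(planted_hubs$loading <= 1),
              all(planted_hubs$k < sum(n_taxa)))
  structure(list(n_per_group = n_per_group, n_taxa = n_taxa,
                 niches = c("bulk", "rhizosphere", "root"),
                 habitats = c("managed", "forest"),
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 base_sd = base_sd, noise_sd = noise_sd,
                 planted_base = planted_base, hub_base = hub_base,
                 n_niche_responsive = n_niche_responsive,
                 niche_effect_sd = niche_effect_sd,
                 planted_edges = planted_edges, planted_hubs = planted_hubs,
                 seed = as.integer(seed)),
            class = "community_config")
}

#' The canonical fixture configuration
#'
#' 3 niches x 2 habitats x 5 samples, 40 + 40 taxa, three planted positive
#' and two planted negative pairwise dependencies (loading 1, i.e. a shared
#' latent driver with only a residual idiosyncratic floor; one positive
#' pair per kingdom, one inter-kingdom, and both negative pairs inter-kingdom
#' -- within-composition co-exclusion is carried by the hub module's negative
#' spokes), and one planted hub (a bacterial
#' taxon with 12 neighbors, 8 bacterial + 4 eukaryotic, loading 0.95).
#'
#' @param seed integer seed.
#' @return a \code{community_config}.
#' @export
canonical_config <- function(seed = 101L) {
  edges <- data.frame(
    taxon_a = c("B005", "E005", "B007", "B009", "B012"),
    taxon_b = c("B006", "E006", "E007", "E010", "E009"),
    sign = c("positive", "positive", "positive", "negative", "negative"),
    loading = 1, stringsAsFactors = FALSE)
  hubs <- data.frame(taxon = "B001", k = 12L, loading = 0.95,
                     stringsAsFactors = FALSE)
  community_config(planted_edges = edges, planted_hubs = hubs, seed = seed)
}

otu_ids <- function(marker, n) {
  prefix <- if (marker == "16S") "B" else "E"
  sprintf("%s%03d", prefix, seq_len(n))
}

# Deterministic lineages: planted taxa get dedicated family/order; background
# taxa share families (4 genera) and orders (12 genera); the last two
# background taxa are left unresolved at genus rank.
synth_taxonomy <- function(marker, ids, planted) {
  n <- length(ids)
  dom <- if (marker == "16S") "d__Bacteria" else "d__Eukaryota"
  lin <- character(n)
  unresolved <- utils::tail(setdiff(ids, planted), 2)
  for (i in seq_len(n)) {
    id <- ids[i]
    pre <- substr(ids[1], 1, 1)  # kingdom-specific so labels never collide
    if (id %in% planted) {
      ordn <- paste0("o__O_", id)
      fam <- paste0("f__F_", id)
    } else {
      ordn <- sprintf("o__%sO%d", pre, (i - 1) %/% 12 + 1)
      fam <- sprintf("f__%sF%d", pre, (i - 1) %/% 4 + 1)
    }
    phy <- if (marker == "16S") {
      sprintf("p__Phy%d", (i - 1) %/% 20 + 1)
    } else if (i %% 2 == 1) "p__Fungi" else "p__Cercozoa"
    cls <- sprintf("c__Cls%d", (i - 1) %/% 12 + 1)
    gen <- if (id %in% unresolved) "" else paste0("g__G_", id)
    lin[i] <- paste(dom, phy, cls, ordn, fam, gen, sep = ";")
  }
  stats::setNames(lin, ids)
}

label_at <- function(lineage, level) {
  li <- match(level, .rank_names)
  p <- split_lineage(lineage)[[1]]
  resolved <- which(nzchar(p)[seq_len(li)])
  if (length(resolved) && max(resolved) == li) p[li]
  else if (length(resolved)) paste0(p[max(resolved)], "_unresolved")
  else "Unassigned"
}

#' Generate a synthetic two-kingdom community
#'
#' @param cfg a \code{community_config}.
#' @return list with \code{tables} (named list of \code{feature_table}s for
#'   16S and 18S), \code{trees} (random rooted trees per kingdom),
#'   \code{truth} (planted edges, hubs with their neighbor sets, niche
#'   effects, all factor-sharing pairs with expected signs, and per-level
#'   labels of the planted taxa) and \code{config}.
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "community_config"))
  with_seed(cfg$seed, {
    markers <- names(cfg$n_taxa)
    ids <- lapply(markers, function(m) otu_ids(m, cfg$n_taxa[[m]]))
    names(ids) <- markers
    all_ids <- unlist(ids, use.names = FALSE)
    kingdom_of <- stats::setNames(
      rep(c("bacteria", "eukaryote")[match(markers, c("16S", "18S"))],
          cfg$n_taxa), all_ids)

    # --- samples ---
    design <- expand.grid(rep = seq_len(cfg$n_per_group),
                          habitat = cfg$habitats, niche = cfg$niches,
                          stringsAsFactors = FALSE)
    sample_ids <- sprintf("%s_%s_%d", design$niche, design$habitat, design$rep)
    ns <- nrow(design)
    metadata <- data.frame(
      niche = design$niche, habitat = design$habitat,
      yield = ifelse(design$habitat == "forest", "none",
                     ifelse(design$rep %% 2 == 0, "high", "low")),
      row.names = sample_ids, stringsAsFactors = FALSE)

    # --- factor loadings ---
    edges <- cfg$planted_edges
    hubs <- cfg$planted_hubs
    planted <- unique(c(edges$taxon_a, edges$taxon_b, hubs$taxon))
    lambda <- list()  # factor name -> named loading vector
    hub_neighbors <- list()
    if (!is.null(edges) && nrow(edges)) {
      for (i in seq_len(nrow(edges))) {
        s <- if (edges$sign[i] == "positive") 1 else -1
        lambda[[paste0("edge", i)]] <-
          stats::setNames(c(edges$loading[i], s * edges$loading[i]),
                          c(edges$taxon_a[i], edges$taxon_b[i]))
      }
    }
    if (!is.null(hubs) && nrow(hubs)) {
      for (i in seq_len(nrow(hubs))) {
        h <- hubs$taxon[i]; k <- hubs$k[i]; lam <- hubs$loading[i]
        pool <- setdiff(all_ids, c(planted, unlist(hub_neighbors)))
        own <- pool[substr(pool, 1, 1) == substr(h, 1, 1)]
        oth <- setdiff(pool, own)
        n_own <- min(length(own), ceiling(k * 0.6))
        nb <- c(own[seq_len(n_own)], oth[seq_len(k - n_own)])
        hub_neighbors[[h]] <- nb
        # One shared factor; hub loading 0.99, neighbor loadings in a
        # moderate narrow band (0.93 down to 0.80 of `loading`) with
        # alternating signs (co-occurrence and co-exclusion around the hub,
        # and a stable combined module mass under renormalization). The
        # geometry is deliberate: hub-neighbor correlations (~0.99*0.7L)
        # sit above the loose significance cutoffs while neighbor-neighbor
        # correlations (~0.49L^2) sit below them, so the recovered module is
        # a star in which only the hub is central on degree, betweenness and
        # closeness.
        taper <- if (k > 1) lam * (0.93 - 0.13 * (seq_len(k) - 1) / (k - 1)) else lam
        taper <- taper * (-1)^(seq_len(k) - 1)
        lambda[[paste0("hub", i)]] <- stats::setNames(c(0.99, taper), c(h, nb))
      }
    }
    planted_all <- unique(c(planted, unlist(hub_neighbors)))

    # --- niche effects on taxa not carrying planted structure ---
    niche_eff <- list()
    for (m in markers) {
      free <- setdiff(ids[[m]], planted_all)
      resp <- utils::tail(free, min(cfg$n_niche_responsive, length(free)))
      eff <- data.frame(taxon = resp,
                        rhizosphere = rnorm(length(resp), 0, cfg$niche_effect_sd),
                        root = rnorm(length(resp), 0, cfg$niche_effect_sd),
                        stringsAsFactors = FALSE)
      niche_eff[[m]] <- eff
    }
    niche_eff_all <- do.call(rbind, niche_eff)

    # --- per-taxon base abundance ---
    base <- stats::setNames(rnorm(length(all_ids), 0, cfg$base_sd), all_ids)
    base[planted_all] <- rnorm(length(planted_all), cfg$planted_base, 0.3)
    hub_module <- unique(c(hubs$taxon, unlist(hub_neighbors)))
    if (length(hub_module))
      base[hub_module] <- rnorm(length(hub_module), cfg$hub_base, 0.3)

    # --- latent abundances and counts ---
    factors <- matrix(rnorm(length(lambda) * ns), length(lambda), ns,
                      dimnames = list(names(lambda), sample_ids))
    load_sq <- stats::setNames(numeric(length(all_ids)), all_ids)
    for (f in names(lambda)) {
      lam <- lambda[[f]]
      load_sq[names(lam)] <- load_sq[names(lam)] + lam^2
    }
    # loadings of 1 (and the hub's 0.99) exhaust the unit budget; keep a
    # small idiosyncratic floor so profiles are never exactly deterministic
    idio <- ifelse(load_sq > 0, sqrt(pmax(1 - load_sq, 0.005)), cfg$noise_sd)
    names(idio) <- all_ids

    tables <- list()
    for (m in markers) {
      tax <- ids[[m]]
      z <- matrix(base[tax], length(tax), ns,
                  dimnames = list(tax, sample_ids))
      for (f in names(lambda)) {
        lam <- lambda[[f]]
        sel <- intersect(names(lam), tax)
        if (length(sel))
          z[sel, ] <- z[sel, ] + outer(lam[sel], factors[f, ])
      }
      eff <- niche_eff[[m]]
      for (i in seq_len(nrow(eff))) {
        tx <- eff$taxon[i]
        z[tx, ] <- z[tx, ] +
          ifelse(design$niche == "rhizosphere", eff$rhizosphere[i],
                 ifelse(design$niche == "root", eff$root[i], 0))
      }
      z <- z + matrix(rnorm(length(tax) * ns), length(tax), ns) * idio[tax]
      depth <- pmax(50, round(rlnorm(ns, cfg$depth_meanlog, cfg$depth_sdlog)))
      counts <- sapply(seq_len(ns), function(s) {
        w <- exp(z[, s])
        rmultinom(1, depth[s], w / sum(w))
      })
      dimnames(counts) <- list(tax, sample_ids)
      md <- metadata
      md$marker <- m
      tables[[m]] <- feature_table(counts, synth_taxonomy(m, tax, planted_all), md)
    }

    trees <- lapply(markers, function(m) generate_tree(ids[[m]], seed = NULL))
    names(trees) <- markers

    # all factor-sharing pairs with expected correlation sign
    fp <- list()
    for (f in names(lambda)) {
      lam <- lambda[[f]]
      if (length(lam) >= 2) {
        cmb <- combn(names(lam), 2)
        fp[[f]] <- data.frame(
          taxon_a = pmin(cmb[1, ], cmb[2, ]),
          taxon_b = pmax(cmb[1, ], cmb[2, ]),
          sign = ifelse(lam[cmb[1, ]] * lam[cmb[2, ]] > 0,
                        "positive", "negative"),
          stringsAsFactors = FALSE)
      }
    }
    factor_pairs <- if (length(fp)) unique(do.call(rbind, fp)) else
      data.frame(taxon_a = character(), taxon_b = character(),
                 sign = character(), stringsAsFactors = FALSE)
    rownames(factor_pairs) <- NULL

    tax_all <- do.call(c, lapply(tables, function(t) t$taxonomy))
    names(tax_all) <- unlist(lapply(tables, function(t) rownames(t$counts)))
    labels <- data.frame(taxon = planted_all, stringsAsFactors = FALSE)
    for (lev in c("genus", "family", "order"))
      labels[[lev]] <- vapply(tax_all[planted_all], label_at, "", level = lev)

    truth <- list(planted_edges = edges, planted_hubs = hubs,
                  hub_neighbors = hub_neighbors,
                  niche_effects = niche_eff_all,
                  factor_pairs = factor_pairs,
                  planted_labels = labels,
                  kingdoms = kingdom_of)
    list(tables = tables, trees = trees, truth = truth, config = cfg)
  })
}

#' Random rooted tree over a taxon set
#'
#' Random binary topology with exponential branch lengths; every taxon is a
#' leaf.
#'
#' @param taxa character vector (>= 2).
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return an \code{ape::phylo}.
#' @export
generate_tree <- function(taxa, seed = 1L) {
  stopifnot(length(taxa) >= 2)
  with_seed(seed, {
    tr <- ape::rtree(length(taxa), tip.label = taxa, br = stats::rexp)
    tr
  })
}

#' Write the canonical fixture set to a directory
#'
#' Emits the canonical synthetic community (see \code{\link{canonical_config}})
#' as plain-text files: per-kingdom OTU tables + shared metadata TSV, newick
#' trees, the planted-truth tables, and a YAML echo of the configuration.
#' Regeneration with the same seed is byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed (default the canonical 101).
#' @return invisibly, the generated community object, with file paths in
#'   attribute \code{paths}.
#' @export
write_fixtures <- function(outdir, seed = 101L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  com <- generate_community(canonical_config(seed = seed))
  p <- function(f) file.path(outdir, f)
  write_feature_table(com$tables[["16S"]], p("table_16s.tsv"))
  write_feature_table(com$tables[["18S"]], p("table_18s.tsv"))
  md <- com$tables[["16S"]]$metadata
  md$marker <- NULL  # shared across both marker tables
  write.table(data.frame(`#SampleID` = rownames(md), md, check.names = FALSE),
              p("metadata.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(com$trees[["16S"]], p("tree_16s.nwk"))
  ape::write.tree(com$trees[["18S"]], p("tree_18s.nwk"))
  tw <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tw(com$truth$planted_edges, "truth_edges.tsv")
  hubs <- com$truth$planted_hubs
  hubs$neighbors <- vapply(hubs$taxon, function(h)
    paste(com$truth$hub_neighbors[[h]], collapse = ","), "")
  tw(hubs, "truth_hubs.tsv")
  tw(com$truth$niche_effects, "truth_niche_effects.tsv")
  tw(com$truth$factor_pairs, "truth_factor_pairs.tsv")
  tw(com$truth$planted_labels, "truth_planted_labels.tsv")
  cfg <- com$config
  class(cfg) <- NULL
  cfg$planted_edges <- NULL; cfg$planted_hubs <- NULL
  yaml::write_yaml(c(cfg, list(generator = "canonical_config")), p("config.yml"))
  files <- c("table_16s.tsv", "table_18s.tsv", "metadata.tsv", "tree_16s.nwk",
             "tree_18s.nwk", "truth_edges.tsv", "truth_hubs.tsv",
             "truth_niche_effects.tsv", "truth_factor_pairs.tsv",
             "truth_planted_labels.tsv", "config.yml")
  attr(com, "paths") <- stats::setNames(file.path(outdir, files), files)
  invisible(com)
}
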