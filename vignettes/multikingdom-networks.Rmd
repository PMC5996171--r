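---
title: "Multi-kingdom co-occurrence networks and hub taxa: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kingdom co-occurrence networks and hub taxa: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ncnet` re-implements, as a tested pipeline, a multi-kingdom microbiome
network analysis: paired 16S (bacterial) and 18S (eukaryotic) amplicon
feature tables from bulk soil, rhizosphere and root samples are curated,
summarized with standard alpha/beta diversity statistics, and mined for
signed co-occurrence networks using a checkerboard-type rank statistic with
a compositionality-corrected permutation test; the most central nodes are
then called as hub taxa under a two-tier consensus rule. A synthetic
two-kingdom community generator with planted ground truth serves as the
validation substrate for every stage.

# Curation model

Each kingdom's table is a taxa-by-samples matrix of read counts with a
semicolon-ranked lineage per taxon. Curation follows fixed, order-dependent
rules:

1. **Lineage exclusion** removes host-derived or unusable signal
   (chloroplast reads from 16S; Archaeplastida/Plantae and unassigned
   lineages from 18S). Matching is case-insensitive substring matching on
   the joined lineage, which tolerates Greengenes/SILVA prefix dialects.
   Exclusion runs *before* the bleed-through filter, so plant-derived reads
   do not inflate the grand total used by that filter; the order is
   configurable.
2. **Bleed-through filter**: taxa with fewer than 0.1% (strict `<`) of the
   grand total (computed before removal) are removed; this compensates for
   between-run carry-over on multiplexed sequencers.
3. **Rarefaction** subsamples each sample without replacement to a common
   depth; samples below the depth are dropped and reported rather than
   raising an error, mirroring the practice of removing the shallowest
   libraries and normalizing to the smallest remaining one ("auto-min").
   Rarefaction depths are chosen per kingdom because the two markers are
   independent sequencing experiments.
4. **Network prefilter** (on relative abundances): taxa present in fewer
   than 5% of samples are removed, as are taxa that never reach 1% relative
   abundance in any sample (a taxon is removed only if it is below 1%
   *everywhere* — the only reading under which a typical sparse table keeps
   any taxa), plus an optional absolute read floor (strictly-greater rule,
   e.g. >250 reads for 16S, >50 for 18S in group comparisons).

Taxonomic collapse (`order`, `family`, `genus`) sums taxa sharing the
lineage prefix down to the requested rank. Taxa unresolved at that rank are
kept, grouped under their deepest resolved name suffixed `_unresolved`,
because informal groups (placeholder clade names that are not formal
genera) are legitimate network nodes in this literature. The grand total is
conserved exactly.

# Diversity statistics

* Richness is the observed taxon count; Chao1 uses the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even with no doubletons.
* Shannon diversity uses log base 2 by default (the convention of the
  QIIME-1 lineage of tools this analysis style descends from); the base is
  an argument.
* Simpson evenness is inverse Simpson over observed richness.
* Beta diversity: Bray-Curtis on relative abundances, and *normalized*
  weighted UniFrac
  $d = \sum_b l_b\,|A_b - B_b| \,/\, \sum_b l_b\,(A_b + B_b)$
  over tree branches $b$ with length $l_b$ and descendant abundance
  fractions $A_b, B_b$ — the variant a QIIME-1-style workflow produces for
  beta-diversity matrices; it is bounded in $[0, 1]$.
* PCoA is classical metric scaling; negative eigenvalues are clipped to
  zero for explained-variance fractions and their count is reported.
* PERMANOVA is single-factor: $SS_{total} = \sum_{i<j} d_{ij}^2 / n$,
  within-group sums analogously, $R^2 = SS_{between}/SS_{total}$, and the
  permutation p-value uses the $(1+b)/(1+n_{perm})$ estimator so 999
  permutations give the conventional floor $p \ge 0.001$. An exact mode
  enumerates all label permutations for small designs. Multi-factor and
  stratified designs are out of scope.
* Two-group differential abundance uses Welch's t-test on proportions
  (the default two-group test of the STAMP-style comparison this stands in
  for) with Benjamini-Hochberg correction via `p.adjust`. Taxa with zero
  variance in both groups get $p = 1$ and a flag, not an error.

# The NC-score and its significance

The similarity is a checkerboard-type concordance score on discretized
profiles. Each taxon's per-sample relative abundances are binned into $B$
equal-frequency bins of the ranked values (ties share the bin of their
average rank); $B$ defaults to Sturges' rule $\lceil \log_2 n + 1 \rceil$.
For two binned profiles the score is

$$\mathrm{NC}(a, b) = \frac{C - D}{n(n-1)/2},$$

where, over all sample pairs, $C$ counts pairs in which both taxa's bins
are strictly ordered the same way and $D$ counts checkerboard patterns
(opposite strict orders). The score lies in $[-1, 1]$, is symmetric, and is
invariant under monotone transformations of either profile. The published
description of the score does not pin down its internal normalization;
the definition above, checked against an exhaustive pair-enumeration
oracle, is normative for this package.

Significance is assessed in the ReBoot style, which corrects for the
spurious associations induced by compositionality (within-sample closure):

* **Null distribution**: the two tested rows are permuted independently
  across samples and *every sample column of the table is renormalized to
  sum one* before re-binning and re-scoring. Renormalization is what makes
  the null compositional: a permuted abundant taxon still distorts all
  other proportions in its sample.
* **Bootstrap distribution**: samples are resampled with replacement and
  the score recomputed (columns keep their sums, so no renormalization is
  needed).
* The two-sided p-value is the standard normal tail of
  $z = (\bar s_{boot} - \bar s_{null}) / \sqrt{\widehat{Var}(s_{boot}) +
  \widehat{Var}(s_{null})}$.

**Conservatism.** This pooled-variance comparison is intrinsically
conservative under independence: the numerator varies with roughly the
null variance while the denominator pools about twice that, so the null
$z$ is approximately $N(0, 1/\sqrt2)$ and the realized type-I error at
$\alpha = 0.05$ is near 0.006 rather than 0.05 (we measured 0.006 over
1,200 independent null pairs). The same behaviour is documented for the
reference implementation of this procedure. We keep the estimator as
specified because conservatism is the safe direction for edge calling; the
practical consequence is reduced power, which matters at small sample
sizes (see *Power* below). The inner permutation/bootstrap loops are
implemented in C++ and driven by R's RNG, so all results are
bit-reproducible for a fixed seed.

The sweep tests all unordered pairs once and filters the shared p-values
at raw cutoffs 0.01, 0.001, 0.0001 and the Bonferroni family-wise cutoff
$0.05/m$ with $m = T(T-1)/2$ pairs at the current taxonomic level
(per-level families; whether the published analysis pooled levels is not
stated). Edge sets are nested across decreasing cutoffs by construction.
The two kingdom tables are converted to relative abundance *separately*
(each marker is its own composition) and then stacked for pair testing, so
inter-kingdom pairs are tested across compositions.

# Networks and hub calling

Each edge set becomes an undirected signed graph; edge weight is
$|\mathrm{NC}|$ with the sign kept as an attribute. Centralities are
computed on the unweighted topology (no weighted-path scheme is published
for this analysis): degree; shortest-path betweenness normalized by
$(N-1)(N-2)/2$; and *harmonic* closeness normalized by $N-1$. Harmonic
closeness deviates deliberately from the classical per-component
convention of network viewers because these networks are routinely
disconnected, where classical closeness is undefined; the choice is
switchable in the sense that the centrality table is exposed and any
column can be replaced upstream of threshold fitting.

Outliers are called by a normal fit: per network and per metric, the
threshold is $\bar x + z_{0.9}\, s$ (sample mean and SD, $p = 0.1$), and a
node is an outlier only with a strictly greater value. Thresholds are
fitted on each network's own edge-incident node population, never pooled
across networks; isolated prefiltered-in taxa are excluded by default
because the node population of an imported edge list is edge-incident.

The two-tier hub rule: a taxon is a **level hub** when it is an outlier on
all three metrics in at least 2 of that level's 4 cutoff networks, and a
**consensus hub** when it is a level hub at 2 of the 3 taxonomic levels.
Because collapsing renames nodes per level, consensus needs a cross-level
identity; `order_ancestor_key()` maps every node to its order-rank
ancestor (nodes unresolved at order keep their collapse key, which is
identical at every level by construction). This mirrors how hub identities
are matched across levels by name in practice.

# The synthetic community generator

The generator is the package's validation substrate. Per kingdom and
sample, latent log-abundances follow a Gaussian factor model

$$z_i(s) = \mathrm{base}_i + \mathrm{niche}_i(s) +
  \textstyle\sum_f \lambda_{if}\, g_f(s) + \sigma_i\,\epsilon_i(s),$$

and counts are drawn multinomially at a log-normal library depth, so the
tables are compositional by construction. Defaults (chosen once, as the
canonical study conditions):

* design: 3 niches x 2 habitats x 5 samples = 30 samples per kingdom;
  40 + 40 taxa;
* depth $\sim$ lognormal($\log 4000$, $0.3$), floored at 50 — between the
  two rarefaction depths typical of paired 16S/18S runs;
* background base log-abundance $\sim N(0, 0.6)$ with idiosyncratic SD
  0.5: a moderately even community. Strong dominance is deliberately
  avoided because a heavy-tailed community injects common "denominator
  noise" into every proportion, which inflates positive and masks negative
  associations — the very artefact the ReBoot null corrects for, but which
  also erodes the *point estimate* of planted correlations;
* niche effects: 16 taxa per kingdom get $N(0, 0.5)$ log-shifts in
  rhizosphere and root relative to bulk (species sorting; this is what
  PERMANOVA and the ordination detect);
* planted pairs share one factor with loadings $\pm\lambda$ (latent
  correlation $\lambda^2$); the canonical fixture plants 3 positive and
  2 negative pairs at $\lambda = 1$ (a shared latent driver with only a
  small residual floor, $\sigma_i^2 = 0.005$). Both negative pairs are
  inter-kingdom: within one composition, closure noise attenuates negative
  associations roughly twice as strongly as across compositions, and
  within-kingdom co-exclusion is already represented by the hub module;
* the planted hub shares one factor with $k = 12$ neighbors (8 bacterial,
  4 eukaryotic): hub loading 0.99, neighbor loadings in a narrow moderate
  band (0.93 down to 0.80 of the configured 0.95) with alternating signs.
  The geometry is deliberate: hub-neighbor correlations sit above the
  loose significance cutoffs while neighbor-neighbor correlations
  ($\approx \lambda_i \lambda_j$) sit mostly below them, so the recovered
  module is a star in which only the hub is central on degree, betweenness
  and closeness simultaneously. A positive-semidefiniteness constraint
  makes a "pure" star with uniformly strong spokes impossible
  ($k\rho^2 \le 1$ for mutually independent neighbors), so some
  neighbor-neighbor dependence is unavoidable; alternating signs also keep
  the module's combined mass stable under closure;
* planted taxa get elevated base abundance (pairs 0.8, hub module 0.5 on
  the log scale) and dedicated family/order lineages, so collapsing does
  not merge planted with background taxa and recovery is well-defined at
  every level.

**Power.** At $n = 30$ samples with Sturges binning ($B = 6$) the
conservative ReBoot z-test clears a Bonferroni threshold of
$\sim 2\times10^{-5}$ only for observed rank correlations around 0.93 or
higher. That is why the canonical fixture plants near-deterministic
dependencies: with the sample sizes of a real multi-niche study (about a
hundred or more samples), substantially weaker dependencies become
recoverable. Validation of the frozen defaults on held-out seeds gave
Bonferroni edge sensitivity 0.92 with perfect sign agreement, zero false
edges outside the planted/induced set, hub consensus recovery 0.90 and 0.3
false hubs per replicate.

**What the generator does not emulate**: sequencing error, chimeras and
OTU-picking artefacts (generation starts at the count table); phylogenetic
signal in abundances (trees are random, so UniFrac on synthetic data is
exercised numerically, not ecologically); spatial or temporal
autocorrelation between samples; and taxon-specific amplification bias.
Passing recovery tests therefore demonstrates correctness of the
statistical machinery under a known dependence structure, not performance
on real soil communities.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes curation, diversity, the 12-network sweep
(4 cutoffs x 3 levels) and hub calling for three sample scopes — all
niches, bulk+rhizosphere, rhizosphere+root — as scenarios over sample
subsets, not separate code paths. All stochastic stages derive from one
master seed; outputs (TSV, GraphML, YAML manifest) are byte-identical
across repeated runs with the same inputs, configuration and seed. The
manifest echoes the full configuration plus input/output checksums and is
sufficient to re-run the pipeline.

The test and acceptance runs use deliberately scaled problem sizes chosen
as a compromise between statistical resolution and turnaround: ReBoot
iterations of 150-500 per pair (point estimates of the null mean/variance
stabilize well before 500; p-values come from the normal tail, not from
empirical quantiles, so granularity is not iteration-limited), 200 null
pairs for calibration, 20 generator seeds for recovery, and 99-999
PERMANOVA permutations. The pipeline defaults remain 1,000 iterations and
999 permutations.

# Known limitations

* Only the checkerboard similarity family is implemented (no Spearman,
  SparCC or proportionality alternatives) — by design.
* The ReBoot z-test's conservatism costs power at small $n$; users with
  few samples should prefer the looser raw cutoffs and treat Bonferroni
  networks as high-confidence cores.
* Single-factor PERMANOVA only; no strata.
* Cross-level hub consensus keys on the order-rank ancestor, which can
  pool two strong genera of the same order into one consensus identity;
  with the dedicated lineages of the synthetic fixture this cannot happen,
  but on real tables the per-level hub calls should be inspected alongside
  the consensus.
* Visual cluster delineation and force-directed layout are not
  reproduced; networks are exported as GraphML for external viewers.
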