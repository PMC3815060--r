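---
title: "lipidnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lipidnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnet)
```

`lipidnet` integrates transcriptome, metabolome and lipidome profiles
measured under a balanced 2×2×2 chemostat design and asks where
transcript levels and metabolite/lipid levels move together — globally,
within metabolic-network neighborhoods, within pathways, and within
transcription-factor modules. This vignette explains each statistical
stage, the assumptions behind it, the tunable parameters, and the design
choices made where more than one defensible option existed.

## The factorial model

The design crosses carbon limitation (C = carbon-limited, N =
nitrogen-limited), oxygen availability (O = aerobic, A = anaerobic) and
temperature (T = 30°C, t = 15°C), each cell cultivated in replicate
chemostats at a fixed dilution rate so growth rate is not a confounder.
`fit_factorial()` codes each factor ±1 (first-listed level = +1) and
fits, per feature,

$$y = \beta_0 + \beta_C x_C + \beta_O x_O + \beta_T x_T +
      \beta_{CO} x_C x_O + \beta_{CT} x_C x_T + \beta_{OT} x_O x_T +
      \beta_{COT} x_C x_O x_T + \varepsilon$$

by ordinary least squares. Under balance the coded columns are
orthogonal (X′X = nI), so every term has one degree of freedom, each
term's F statistic is the squared t statistic of its coefficient, and
estimates equal half the difference of the corresponding level means. A
coefficient β therefore corresponds to a level difference of 2β — the
convention used consistently by the model matrix, the generator's
planted effects and `condition_ratio_attributes()`. The three-way term
is included by default because all interactions are of scientific
interest in this design; with a single replicate it saturates the model
and is rejected with an explicit error (`include_three_way = FALSE`
restores 1 residual df there). Multiple testing is controlled by
Bonferroni within each molecular layer (genes over genes, lipids over
lipids), because layers differ by orders of magnitude in family size;
the default α = 0.001 on the adjusted p follows the analysis convention
for calling condition-dependent features.

Assumptions: homoscedastic Gaussian noise per feature, replicates
exchangeable within a condition, no replicate-level random effect. No
empirical-Bayes variance moderation is applied — with n = 24 and 8
(or 7) model terms the residual has 16 df and per-feature variances are
stable.

## Correlation analysis

`all_pairs()` computes the Pearson product-moment correlation of every
gene with every target across all samples — replicates are treated as
independent samples (n = 24 in the full design), which mirrors how the
measurements were taken but does mean within-condition covariance
contributes to r; this is documented as a caveat rather than "fixed",
because condition means with n = 8 would be too short a vector for
stable inference. Significance uses the exact t transform
t = r√(n−2)/√(1−r²) on n−2 df (identical to `cor.test`'s two-sided
test), and Bonferroni adjustment with family = the number of pairs in
the layer tested. The three pair classes (gene–metabolite, gene–lipid,
gene–lipid-by-acyl-chain) are adjusted separately since they are
reported separately. Expression enters on its measured log2 scale and
targets on their linear biomass-normalised scale; pairs containing a
constant or NA-containing feature are dropped and logged, never imputed.
|r| = 1 yields p = 0 by convention and is flagged.

The split-half screen (`split_half_opposing()`) divides the samples by
one factor, runs the full Bonferroni-controlled analysis in each half
(n = 12 per half), and reports pairs significant in both halves as
*opposing* (sign flip) or *agreeing*. The within-half α is a free
parameter (`alpha_half`) because no established default exists for this
screen; results should be read qualitatively — the interesting outcome
is whether any opposing pair exists at all.

## The neighborhood correlation-bias test

A reconstruction (reaction table with stoichiometry and flattened
gene associations) is projected to a bipartite metabolite–gene map:
edge (m, g) exists iff some reaction touching m is catalysed by g.
Direction is ignored throughout — production and consumption are equally
informative about co-regulation. GPR boolean structure ("and"/"or") is
flattened to the set of mentioned genes, since the map links genes to
reactions without complex-formation logic.

For each species m, `neighborhood_test()` compares the correlation
coefficients {r(m, g) : g a neighbor} against {r(m, g) : g not a
neighbor} with a two-sided Mann–Whitney U test, at order 1
(genes of reactions touching m) or order 2 (genes within two reaction
steps; always a superset). BH adjustment runs across all species tested
in one run; order-1 and order-2 runs are adjusted separately. The
reported direction is the sign of the median shift between the groups —
an intentionally informal summary, since the U test itself is not
directional about magnitude. The companion report
(`table1_report()`) lists, per significant species, the linked-gene
count at the order tested, the count of genes significantly correlated
to it (Bonferroni p ≤ 0.01), and their overlap.

Currency metabolites: by default nothing is excluded — cofactor hubs
(ATP, NAD(P)H) remain testable nodes, which matches an analysis in which
such species appear among the tested metabolites. An exclusion list is
accepted everywhere (`build_bipartite(currency_ids=)`) because hub
shortcuts can make order-2 neighborhoods engulf the network; the choice
is the analyst's.

The Mann–Whitney p-value is exact (full enumeration, via the
tie-corrected rank-sum machinery) when the combined group size is ≤ 20
and tie-free, and otherwise uses the normal approximation with midrank
ties and continuity correction — the regime the real application lives
in, with hundreds of genes per group. Identical-valued groups return
p = 1 directly.

## Pathway and TF module stages

`pathway_test()` applies the same rank-sum logic to pathway-grouped
correlations: group A is every r(m, g) with *both* the metabolite and
the gene in the pathway (the stricter of the two possible membership
readings, chosen because the test is about in-pathway co-regulation),
group B is everything else. Pathways with no in-pathway pair, or
spanning the whole matrix, are skipped rather than producing NaN.
Membership arrives as two parallel GMT files (gene members, metabolite
members) matched by set name, keeping curated pathway databases out of
the package.

`tf_enrichment()` scores overlap between labeled query gene sets (the
per-factor ANOVA sets, and the per-species positively/negatively
correlated sets from `signed_query_sets()`, tested separately by sign)
and TF target sets, with the one-sided hypergeometric tail
P(X ≥ k) — equal to the one-sided Fisher exact test. Only
over-representation is tested. No multiple-testing correction is applied
by default because the conventional report threshold here is the raw
hypergeometric p ≤ 0.01; `bh = TRUE` adds BH control for users who want
it. The universe is an explicit required argument — measured genes, not
all genome annotations — because the choice changes every count.

## Flux balance analysis

`build_flux_model()` turns a reconstruction into max c·v subject to
S·v = 0 and lb ≤ v ≤ ub, synthesising a biomass reaction from a
composition mapping (component drains per unit growth) and applying
measured exchange rates as equality constraints by default (they were
imposed rates, not capacities); an inequality mode exists. Default
bounds are ±1000 (the usual genome-scale convention), reversible
reactions getting the negative lower bound.

The LP is solved by a package-authored dense two-phase tableau simplex
with Bland's anti-cycling rule (`R/lp.R`): variables are shifted by
their lower bounds, fixed (zero-width) variables are eliminated, rows
with negative right-hand sides flipped, lingering zero-valued
artificials driven out of the basis after phase 1, and the returned
point is re-validated against every constraint before being reported
optimal. A hand-rolled solver is a deliberate choice: the desk-scale
models here have tens of variables, an auditable tableau beats an
opaque dependency at that size, and the test suite cross-checks optima
against brute-force polytope-vertex enumeration. Alternate optima are
not resolved (no flux-variability analysis); the solution is one optimal
vertex, documented as non-unique. Steady-state residuals are reported
(‖S·v‖∞, tolerance 10⁻⁶ relative to the flux scale).

## The synthetic-data generator

`simulate_reconstruction()` builds a connected toy network (a spanning
chain of reactions plus random extras, 0–2 genes per reaction, every
gene used) and records the metabolite–gene edges it creates as an
independent ground-truth edge list. `simulate_omics()` generates
log2-scale expression as design effects + noise, and strictly positive
abundances as log-normal around their design effects — mirroring the
measured quantities' scales (log2-normalised arrays; biomass-normalised
linear abundances). Planted correlation links share a per-condition
latent response z ~ N(0, latent_sd²): the metabolite receives z, each
linked gene receives ±z, so the realised Pearson correlation carries the
planted sign with probability → 1 as noise shrinks. Drawing z at the
condition level (8 values) rather than per sample reflects that
replicates share an environment. `simulate_lipid_subspecies()` splits
designated lipids into per-acyl-chain rows (fixed random proportions ×
parent abundance × log-normal noise), giving the third pair class.

Default conditions are the study design itself: 8 conditions × 3
replicates. Default sizes — 200 genes, 30 metabolites, 40 reactions —
keep a full pipeline run under a second while preserving the geometry
that matters for the neighborhood test: neighborhoods must be a minority
of the gene universe, as in the real map where a median of two genes
attach to each metabolite in a universe of thousands. Default noise
(log2 sd 0.25 for both layers) and planted effect size (β = 2, a 4-fold
level difference) are conventional strong-effect settings for
well-replicated chemostat data; the calibration and recovery analyses
use the same sizes with noise 0.25 (null) and 0.1 (recovery,
"effects ≫ noise"). These were chosen once, from the design reasoning
above, not fitted to any result.

What the generator does *not* emulate: chemostat physiology, growth
rates and analytical-chemistry error structure; mean–variance
relationships and heavy tails of real arrays; correlated measurement
batches; acyl-chain biochemistry beyond labelled sub-species columns.
Passing tests therefore demonstrate statistical correctness and
calibration of the machinery, not robustness to every real-data
pathology.

## Numerical and convention notes

* Medians over even counts are the mean of the central pair.
* Bonferroni is `min(1, p·m)`; BH is the monotone step-up. Both are
  checked against hand-rolled oracles.
* Hypergeometric p-values are discrete; the null-calibration check uses
  large sets (hundreds of members in a universe of thousands) so the
  support is fine enough for a KS comparison against the uniform, and a
  small conservative bias at the atoms remains visible by construction.
* `merge_linear_pathways()` collapses chains through intermediates
  occurring in exactly two reactions, as product of one and substrate of
  the other; the intermediate is cancelled exactly (coefficient-scaled),
  gene sets are unioned, and merging is iterated to a fixed point.
  Degenerate cancellations (a side vanishing) abort that merge.
* PCA (`pca_variance_fractions()`) centres and unit-scales features by
  default, since layers mix scales; `scale. = FALSE` is available
  because the right choice for a single homogeneous layer is arguable.
* Pipeline runs derive every stage seed from the single config seed, so
  identical configs give byte-identical outputs (hashed in the
  manifest).

## Problem sizes used in verification

The statistical-oracle checks enumerate all rank-sum group sizes with
total ≤ 12, hypergeometric universes up to 30, and permutation tests at
n = 5–8 with 10⁴ shuffles. Null calibration uses one 200 × 30 run for
the omnibus KS checks and 200 repetitions at 50 × 10 for
Bonferroni-count calibration; planted recovery uses the default
200-gene/30-metabolite geometry at noise 0.1. FBA correctness uses three
toy models small enough for exhaustive vertex enumeration. These sizes
make the whole suite run in seconds while leaving each check adequately
powered.

## Known limitations

* Replicates as independent samples inflates effective n for the
  correlation tests; interpret borderline Bonferroni calls accordingly.
* The rank-sum neighborhood test compares dependent correlation values
  (all share the metabolite's sample vector); the permutation-based
  calibration checks show the null behaves well in practice, but the
  test is not exact in the strict iid sense.
* The relationship between the raw reconstruction statistics and the
  bipartite-map statistics (which reactions/species drop out) is left to
  the data: both summaries are reported, no filtering is guessed.
* FBA solutions are single vertices of a possibly degenerate optimal
  face; fluxes of individual reactions should not be over-interpreted
  without variability analysis.
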