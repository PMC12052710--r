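---
title: "Linking ruminal fiber degradation to feed efficiency and microbiota: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking ruminal fiber degradation to feed efficiency and microbiota: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenMWAS)
```

## The analysis problem

In fattening lambs, the rate at which ruminal microbes degrade dietary fiber
(neutral detergent fiber, NDF; acid detergent fiber, ADF) varies between
animals and plausibly drives differences in feed conversion efficiency. The
analysis this package implements asks two questions on a cohort of ~190
animals with genus-level 16S abundance profiles (~292 genera):

1. Is the ruminal fiber degradation rate associated with growth and feed
   efficiency traits, in particular the feed conversion ratio (FCR)?
2. Which bacterial genera are robustly associated with the degradation rate?

Robustness in the second question comes from demanding agreement between
three different screens — rank correlation, a covariate-adjusted two-part
association model, and a high-vs-low extreme-group contrast — and keeping
only the genera flagged by all three ("key genera").

## Degradation rates from an internal marker

Directly measuring fiber disappearance per animal is impractical at cohort
scale. Instead, acid-insoluble ash (AIA) — an indigestible mineral fraction
of the diet — serves as an internal marker. As digestible matter disappears
from the rumen, the marker concentrates; comparing fiber-to-marker ratios
between feed and rumen contents yields the degradation rate

$$D = \left(1 - \frac{A}{B}\cdot\frac{FB}{FA}\right)\times 100,$$

where $A$ and $B$ are AIA concentrations in feed and rumen contents and
$FA$, $FB$ the corresponding fiber concentrations (all g/kg dry matter).
`degradation_rate()` implements this; `generate_marker_panel()` inverts it
(solving $FB = FA\,(1-D)\,B/A$), which gives the simulator an exact
round-trip and the tests a machine-precision oracle.

Sampling noise can push $D$ below zero. We report negative rates with a
warning rather than clamping: truncation would bias the subsequent ranking
and extreme-group assignment.

Growth metrics follow the standard definitions: average daily gain
$ADG = (BW_{end}-BW_{start})/\text{days}$ over an interval, and
$FCR = FI/ADG$ (daily feed intake per unit gain; lower is better). A
non-gaining animal has undefined FCR, reported as missing — never infinity.

## Preprocessing the abundance table

- **Depth normalization** (`normalize_to_min_depth()`) rescales each sample
  to the smallest library size by a deterministic factor. We chose scaling
  over random subsampling to keep the pipeline reproducible end to end;
  randomized rarefaction is available as `rarefy_to_min_depth()` with a
  seed. Prevalence (share of samples with a nonzero count) is invariant to
  the scaling.
- **CLR transform** (`clr_transform()`): counts are compositional, so all
  quantitative analysis uses centered log-ratios,
  $\mathrm{clr}(x)_j = \log(p_j/g(p))$. Zeros are handled by a single
  pseudocount added to every cell before closure; the default 0.5 (on the
  depth-normalized count scale) is the conventional half-count. The
  pseudocount is the only zero-replacement device in the package.
- **Principal components** (`principal_components()`): the first three PCs
  of the full CLR matrix serve as covariates in the association model,
  absorbing broad community-structure gradients. PCA is computed on all
  genera; sign is fixed by making each component's largest-magnitude
  loading positive, so results do not depend on LAPACK sign conventions.

## The three screens

**Spearman screen.** `spearman_cor()` computes rho as Pearson correlation on
mid-ranks (ties receive average ranks). Two-sided p-values use the t
approximation for $n > 9$ and the exact permutation distribution (all $n!$
arrangements) for smaller vectors, where the approximation is poor and
enumeration is cheap. Correlations are labeled *moderate* ($p<0.01$,
$|\rho|>0.40$) or *weak* ($p<0.01$, $0.20<|\rho|\le 0.40$); either label
puts a genus in the Spearman hit set. The boundary $|\rho| = 0.40$ is
assigned to the weak class so that no significant correlation above 0.20 is
silently unclassified; `strict_bounds = TRUE` restores literal strict
inequalities.

**Two-part MWAS.** Genus prevalence routes each genus to one of two model
parts at the 60% boundary (`route_genera()`): genera present in fewer than
60% of samples are tested through a presence/absence indicator (binary
part), the rest through their CLR abundance (quantitative part). Both parts
fit least squares $y \sim 1 + \mathrm{PC}_{1..3} + g$ and take the absolute
partial t of the genus term. Inference is by permutation of $g$ against the
fixed $(y, \mathrm{PCs})$:

- exhaustive enumeration of all distinct arrangements when their number
  fits the permutation budget (all $\binom{n}{n_1}$ presence patterns, or
  all $n!$ orders), with $p$ = the proportion of arrangements at or above
  the observed statistic;
- otherwise Monte-Carlo sampling with the add-one estimate
  $p = (1+\#\{|t^*|\ge|t|\})/(1+N)$, which can never return zero.

Ties count as exceedances. Constant or covariate-collinear predictors are
unestimable and carry missing statistics. The Bonferroni family is the full
genus table (the conservative choice — the alternative of correcting within
each part would be less strict), with the significance threshold at
adjusted $p < 0.01$.

Two implementation notes. First, `mwas_screen()` batches all genera through
one shared permutation stream: shuffling $g$ against fixed $(y,
\mathrm{PCs})$ is distributionally identical to applying the inverse
shuffle to $(y, \mathrm{PCs})$, so a single permuted covariate block serves
every genus and the screen reduces to a handful of matrix products per
permutation block. Results are independent of genus ordering. The
single-genus reference path, `permutation_association()`, retains its own
seed and is what the tests cross-check against. Second, the budget
matters: with $N$ permutations the smallest attainable p-value is
$1/(N+1)$, so Bonferroni significance at $0.01$ across 292 genera requires
$N \ge 29{,}240$. `mwas_spec(adaptive = TRUE)` makes such budgets cheap by
early-stopping any genus once 10 permuted statistics have reached the
observed one (at that point the estimate is already confidently
non-significant) — the scheme used by large permutation-based association
tools; the full budget is spent only on the handful of genera that need it.

**Extreme-group contrast.** Animals are ranked on the degradation rate
after a single outlier-trimming pass at mean ± 2 SD (one pass, not
iterated); the top and bottom 10 form the high and low groups
(`extreme_groups()`, deterministic ID-order tie-breaks). Traits and genus
abundances are compared by Student's pooled t-test by default (the typical
default in commercial statistics software; Welch available via
`variant = "welch"`), with two thresholds: $p<0.05$ for traits, $p<0.01$
for genus-level differential abundance. Differential abundance is tested on
CLR values by default — the scale on which a location shift is
compositionally meaningful (the approach popularized by ALDEx2-style
analyses); `pipeline_params(diff_scale = "normalized")` tests
depth-normalized abundances instead. Group outputs report per-group and
pooled SEMs, since published tables are ambiguous about which is shown.

**Consensus.** `consensus_report()` intersects the three hit sets; the
result is order-invariant (pure set intersection), so it does not matter
whether the correlation/MWAS overlap is formed before or after the
differential filter. Consensus genera are tallied by phylum, with missing
taxonomy counted as "Unclassified" rather than dropped.

## The synthetic cohort generator

No per-animal dataset is published with the study, so the package carries a
generator (`sim_config()` / `generate_cohort()`) that reproduces the
statistical structure the analysis assumes, with known ground truth for
power and calibration studies. Defaults mirror the study scale: 190
animals, 292 genera.

- **Abundance**: per-genus log-normal base abundances (sdlog 1.5), per-genus
  structural prevalence uniform on 0.2–1.0 (so genera fall on both sides of
  the 60% routing boundary), per-cell log-normal overdispersion (sdlog 0.8)
  on top of a per-sample multinomial draw at a depth uniform on
  20,000–60,000. Zero-inflation is applied *before* counting: genera below
  the boundary are genuinely absent from those animals, which is what the
  binary model part assumes; sampling zeros alone could not guarantee it.
- **Causal structure**: by default 4 causal genera act through CLR
  abundance and 1 through presence/absence (structural prevalence 0.4).
  Quantitative effect sizes are calibrated by a fixed-point iteration so
  that each causal genus's marginal phenotype $R^2$ equals `quant_r2`
  (default 0.15) in expectation over the residual draw — a direct variance
  formula misses the target because causal CLR columns are mutually
  correlated. The binary genus shifts the phenotype by
  `binary_shift` × `noise_sd` (default 2 residual SDs) when present.
  Realized prevalence classes are re-checked after generation and the
  cohort is regenerated from a derived seed on violation.
- **Phenotypes**: NDFD has mean 55% and residual SD 4; ADFD tracks NDFD
  (0.8 × its deviation, own residual SD 2), making the two rates strongly
  concordant so their extreme groups overlap heavily, as observed in
  practice. FCR is linear in NDFD with negative slope (−0.05) and residual
  SD 0.7, yielding a moderate negative correlation (≈ −0.5) and FCR values
  near 6 — the realistic range for fattening lambs. The linear link is the
  simplest mechanism that reproduces the monotone negative association; it
  claims no mechanistic realism. Marker panels for both fiber fractions are
  constructed per animal by inverting the degradation formula, and body
  weights grow linearly at $ADG = ADFI/FCR$, so the digestibility module
  recovers all planted quantities exactly.

What the generator does **not** emulate: phylogenetic correlation between
genera, read-level sequencing error, batch structure, nonlinear
genus–phenotype links, and any real taxonomy (phylum labels are synthetic).
Passing tests therefore demonstrate the pipeline's statistical behavior
under its own assumptions, not performance on any particular real dataset.

## Numerical choices and degenerate inputs

- Permutation tie comparisons use a relative tolerance of $10^{-12}$ on the
  observed statistic, so bit-level noise cannot flip a tie.
- A constant phenotype makes every permuted statistic tie at zero, giving
  $p = 1$; a perfectly separating predictor (zero residual) is reported as
  $|t| = \infty$ and is matched only by other perfect separations.
- Zero-variance group comparisons: equal constants give $t=0, p=1$; two
  different constants give $t=\pm\infty$ with the smallest representable p.
- Per-genus permutation sub-seeds in `permutation_association()` derive
  deterministically from (seed, genus index); the batched screen draws one
  stream from the screen seed. Both make results independent of genus
  processing order, and the package never mutates the caller's RNG state.
- All tables are TSV (genus names such as `Family_XIII_UCG-002` are unsafe
  in CSV), UTF-8, missing values as empty cells.

## Problem sizes used by the test suite

The packaged checks run the generator at the study's native scale where the
property demands it: the null-calibration study uses 200 cohorts of
190 × 292 at 999 permutations each (feasible because of the batched
screen); the recovery study uses 20 cohorts with the default planted
structure at a 50,000-permutation adaptive budget; the group-direction
study uses 100 cohorts. Unit tests use smaller cohorts (40–100 animals,
8–60 genera) chosen to exercise the same code paths quickly.

## Known limitations

- The recovery rate of the three-method consensus is bounded by its least
  powerful arm. Under the default planted effects (per-genus $R^2 = 0.15$,
  $n = 190$), the 10-vs-10 extreme-group t-test at $p<0.01$ has per-genus
  power of roughly 0.6, so the consensus typically recovers about 3 of 5
  planted genera even though the Spearman and MWAS arms each run near or
  above 90% power. The intersection buys precision (empirically at or
  above every single arm), not sensitivity — worth keeping in mind when
  interpreting "key genera" counts.
- The two-part model tests presence/absence *or* abundance per genus, never
  both; a classical hurdle model is out of scope.
- Bonferroni across all genera is conservative under correlated CLR
  columns; no FDR alternative is exposed because the consensus design
  already trades recall for precision.
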