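# rumenMWAS

Tools for linking ruminal fiber degradation rates to feed efficiency and
rumen microbiota composition in fattening lambs — for animal scientists and
microbiome analysts working with genus-level 16S abundance tables and
per-animal phenotype records.

## What it computes

**Degradation rates from an internal marker.** Acid-insoluble ash (AIA) is
indigestible, so it concentrates in digesta as digestible matter disappears.
With AIA concentrations *A* (feed) and *B* (rumen contents) and fiber
concentrations *FA* (feed) and *FB* (rumen contents), the NDF or ADF
degradation rate is

    D = (1 − (A/B) · (FB/FA)) × 100   [%]

plus the standard growth metrics ADG = ΔBW/days and FCR = FI/ADG.

**Genus screening, three ways, and their consensus.**

1. *Spearman screen* — rank correlation of each genus with the phenotype;
   hits are correlations with p < 0.01 and |rho| > 0.20 (moderate > 0.40,
   weak 0.20–0.40).
2. *Two-part MWAS* — genera with prevalence < 60% are tested through a
   presence/absence indicator (y = β₁b + e), the rest through their centered
   log-ratio abundance (y = β₂q + e); both parts adjust for the first three
   CLR principal components, take the partial |t| of the genus term, obtain
   p by permutation (exhaustive enumeration when feasible, add-one
   Monte-Carlo otherwise), and apply Bonferroni at 0.01 across all genera.
3. *Differential abundance* — animals are trimmed at mean ± 2 SD, the top
   and bottom 10 by degradation rate form high/low groups, and each genus is
   compared by Student's t-test at p < 0.01.

The **consensus** ("key genera") is the three-way intersection, tallied by
phylum. A synthetic cohort generator (`sim_config()`, `generate_cohort()`)
reproduces the assumed data structure — compositional counts with
heterogeneous prevalence, a degradation phenotype driven by planted causal
genera, a negatively linked FCR, and marker panels that invert exactly —
with full ground truth for power and calibration studies.

## Worked example

```r
library(rumenMWAS)

# marker panel: AIA 2 g/kg in feed, 4 in digesta; NDF 400 in feed, 300 in digesta
degradation_rate(marker_measurement(A = 2, B = 4, FA = 400, FB = 300))
#> [1] 62.5

cohort <- generate_cohort(sim_config(seed = 42))   # 190 animals x 292 genera
res <- run_pipeline(cohort$abundance, cohort$phenotype, cohort$taxonomy,
                    targets = c("NDFD", "ADFD"),
                    spec = mwas_spec(n_permutations = 50000,
                                     adaptive = TRUE, seed = 42))

res$NDFD$consensus
#> consensus_report [NDFD]: 8 spearman, 5 mwas, 6 differential -> 2 consensus genera
#>    Genus_0109, Genus_0211
#>   phyla: Bacteroidetes: 1, Proteobacteria: 1

spearman_cor(res$phenotype$NDFD, res$phenotype$FCR)$rho
#> [1] -0.434
```

Reading the output: of 292 genera, 8 passed the Spearman screen, 5 were
Bonferroni-significant in the MWAS and 6 differed between the extreme
groups; 2 genera (both among the 5 planted causal genera for this seed)
survived all three filters. The degradation rate correlates moderately and
negatively with FCR (rho = −0.43): animals that degrade fiber faster convert
feed more efficiently — the high-NDFD group averaged FCR 5.50 against 6.37
in the low group, and the NDFD/ADFD extreme groups shared 6 of 10 high and
7 of 10 low animals. The consensus trades recall for precision: under the
default planted effect sizes its differential arm is the power bottleneck
(see the methods vignette), so expect it to recover a subset of the real
signals with few false positives, not all of them.

`run_pipeline(..., out_dir = "out")` additionally writes every intermediate
table (groups, trait comparisons, per-method results, consensus, phylum
tally, membership matrix, manifest) as TSV. A thin command-line front end
lives at `inst/scripts/rumenmwas.R` (`simulate` and `run-all` subcommands).

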