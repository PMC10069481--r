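# hostpref

Mosquito host-preference assays and skin-odor metabolomics consensus, as a
tidyverse-style R package.

## The problem

Female *Aedes aegypti* bite some people far more than others, and a person's
attractiveness is stable over months. Quantifying that requires two very
different pipelines, and `hostpref` implements both:

- **Behavior.** In a two-choice olfactometer, 30–40 mosquitoes fly upwind
  toward one of two odor stimuli (typically forearm-worn nylon swatches from
  two human subjects). Each mosquito is *not activated*, *activated but not
  attracted*, or *attracted* to one of the two traps. Trials with fewer than
  30 survivors or fewer than 10 attracted mosquitoes are excluded
  ("jackpotting" makes them uninterpretable). Per-trial percent-attracted
  vectors are compared by a two-sided Wilcoxon rank-sum test (exact by full
  enumeration for combined n ≤ 12, tie-corrected normal approximation with
  continuity correction above), with Bonferroni correction over an explicit
  comparison family and the nonparametric effect size `ES = Z / √N`.
- **Tournament scoring.** A round-robin of *n* subjects has *n(n−1)/2*
  pairwise competitions. Per pair, the winner's *margin of victory* is
  `round((total_winner − total_loser) / n_trials)` (half away from zero;
  losers get 0), and a subject's **attraction score** is the sum of its
  awarded margins — e.g. margins of 15, 18, 20, 21, 23, 23 and 24 against
  seven opponents give a score of 144.
- **Metabolomics.** Aligned GC/QTOF-MS peak-area tables (features =
  accurate mass @ retention time, detected as deprotonated \[M−H\]⁻ ions) are
  pushed through a consensus workflow: fuzzy duplicate merging (±100 ppm,
  ±0.05 min), rare-feature and prevalence filters, per-feature half-minimum
  imputation, log2 transform, group-level prevalence/CV quality filter,
  a ≥2-fold FDR < 0.05 "human-derived" filter against pooled unworn-nylon and
  solvent controls, per-experiment Welch volcano tests of high- versus
  low-attractor samples (≥2-fold, FDR < 0.05), and intersection across all
  replicate experiments with consistent direction. Hits are annotated with
  CHNO formula candidates enumerated within a ppm window under RDBE and
  hydrogen-bound constraints. Targeted re-analyses (rank-based mixed model
  for the small repeated-measures cohort; rank-sum tests on per-subject
  medians for the validation cohort; BH at q ≤ 0.10) are included.

Synthetic-data generators (`simulate_trials()`,
`simulate_feature_tables()`) produce both kinds of data with known ground
truth — planted fold changes, fuzzy twins, detection-limit censoring,
constant internal standards, nylon-derived features — so the whole pipeline
is testable without the original instrument data.

## Worked example

```r
library(hostpref)

cfg <- behavior_sim_config(c(S33 = 8, S25 = 2, S28 = 1),
                           n_trials_per_pair = 18, seed = 1)
run <- run_behavior(simulate_trials(cfg))
run$preferences[, c("stimulus_a", "stimulus_b", "median_pct_a",
                    "median_pct_b", "p_adj", "effect_size")]
#>   stimulus_a stimulus_b median_pct_a median_pct_b    p_adj effect_size
#> 1        S33        S28         58.9         8.89 4.56e-06       0.850
#> 2        S33        S25         55.6        13.89 1.00e-05       0.849
#> 3        S25        S28         48.1        20.00 6.69e-06       0.836
tidy(run$tournament)
#>   subject score total_attracted rank
#> 1     S33    31             682    1
#> 2     S25    10             382    2
#> 3     S28     0             173    3
```

All three pairs separate cleanly (Bonferroni-adjusted p ≪ 0.05, effect sizes
≈ 0.85), and the attraction scores rank the subjects by their latent weights,
with the subject that lost every competition scoring 0.

```r
mcfg <- metabo_sim_config(planted_hits = planted_hits(1:10, log2_effect = 2),
                          seed = 1)
sim <- simulate_feature_tables(mcfg)
mrun <- run_metabolomics(sim$tables)
mrun$manifest$stages
#>           stage records_in records_out removed
#> 1         input        220         220       0
#> 2   dedup_merge        220         200      20
#> 3     min_files        200         200       0
#> 4    prevalence        200         200       0
#> 5       quality        200         200       0
#> 6 human_derived        200         153      47
#> 7     consensus        153          10     143
head(mrun$hits[, c("feature_id", "direction", "mean_log2_fc", "top_formula")], 3)
#>      feature_id     direction mean_log2_fc top_formula
#> 1 138.6560@4.04 high_enriched        2.033        <NA>
#> 2 163.5484@5.25 high_enriched        2.038        <NA>
#> 3 205.1283@4.56 high_enriched        2.008   C7H18N4O3
```

The 20 fuzzy twin features are merged back into their parents, 153 of 200
features pass the human-derived filter, and the consensus intersection
returns exactly the 10 planted features, each with a mean log2 fold change
near the planted value of 2 (recall 1.0, no false hits at this seed).

Plot helpers: `autoplot()` on preference tests and tournament results,
`plot_volcano()` on per-experiment differential records, and
`plot_dilution_series()` on dose-response analyses.

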