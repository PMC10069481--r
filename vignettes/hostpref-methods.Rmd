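---
title: "Models and methods behind hostpref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hostpref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostpref)
```

## What the package models

Some people attract far more mosquitoes than others, and the differences are
stable over time. Two measurement pipelines quantify this. First, a two-choice
olfactometer assay: 30–40 female *Aedes aegypti* are released downwind of two
odor stimuli (typically forearm-worn nylon swatches from two human subjects);
each mosquito either never activates, activates but reaches no trap, or is
attracted into one of the two stimulus traps. Second, untargeted GC/QTOF-MS
profiling of the worn nylons, focused on carboxylic acids detected as
deprotonated \[M-H\]⁻ ions, asks which skin-derived compounds separate highly
from weakly attractive subjects. `hostpref` implements the statistics of both
pipelines plus synthetic-data generators with known ground truth, so every
stage can be validated end to end without access to the original instrument
data.

## Behavioral statistics

### Inclusion criteria

Preference estimates from low-participation trials are dominated by
"jackpotting" (2 vs 1 mosquitoes is not a preference). A two-choice trial
enters analysis only if at least 30 mosquitoes are alive at the end of the
assay *and* at least 10 entered either trap; single-stimulus trials require
more than 14 live mosquitoes. `include_trials()` applies these rules and
reports the first rule each excluded trial failed. The thresholds are
arguments of `inclusion_criteria()`, so stricter or looser screens are one
call away. Raising any threshold can only remove trials, never admit one — a
property the test suite checks.

### Percent attracted and the preference test

For each included trial the response is the percent of mosquitoes attracted to
each stimulus. The denominator is the number of mosquitoes alive at the end of
the assay by default: trials are already screened on that count, and using
survivors avoids penalising a trial for deaths unrelated to choice. The loaded
count is available via `denominator = "loaded"` for sensitivity analyses.

`compare_pair()` contrasts the two per-trial percent vectors with a two-sided
Wilcoxon rank-sum test. For combined sample sizes up to 12 the p-value is
exact — full enumeration of all `choose(n, n_x)` labelings of the observed
midranks, so ties are handled without approximation. Above that, a
tie-corrected normal approximation with continuity correction is used; the
crossover is where exact enumeration is cheap and the approximation already
accurate. Bonferroni correction uses an explicit family size, because the
appropriate family depends on how many pairs an analysis compares at once; the
default is the number of pairs in the invocation. The nonparametric effect
size is `ES = Z / sqrt(N)`, with `N` the total number of per-trial percent
observations entering the comparison (two per trial) — the most literal
reading of "number of observations". When every trial of a pair is excluded,
`compare_pair()` returns a sentinel result with `n_trials_included = 0` rather
than failing, so batch analyses keep running.

### Attraction scores

A round-robin tournament of `n` subjects has `n(n-1)/2` pairs. For each pair,
the total mosquitoes attracted to each subject are summed over all the pair's
trials; the winner's *margin of victory* is the count difference divided by
the number of trials, rounded to the nearest integer (half away from zero),
and the loser receives 0. A subject's attraction score is the sum of its
awarded margins. Rounding before summation reproduces the published integer
arithmetic (margins 15, 18, 20, 21, 23, 23, 24 summing to 144); whether the
original calculation rounded each margin or the final sum is not stated, so
`attraction_scores(round = FALSE)` provides the unrounded alternative.
Incomplete round-robins score the available pairs and warn rather than error,
since real tournaments have unequal trial counts.

### Dilution series

`dilution_series_analysis()` handles dose-response designs in which shrinking
swatch fractions of one subject's nylon compete against a fixed reference. One
`compare_pair()` runs per fraction, the family size defaults to the number of
fractions, and the output flags the largest fraction at which significance is
lost. Note that a two-sided test regains significance once the diluted
stimulus becomes significantly *weaker* than the reference, so the lost-at
fraction is most interpretable near the crossing point.

## The metabolomics consensus pipeline

`run_metabolomics()` chains the stages below and writes a manifest
reconciling the feature count into and out of every stage.

1. **Fuzzy deduplication** (`dedup_features`). Instrument peak detection
   splits one compound into near-identical "features". Features within
   ±100 ppm in mass *and* ±0.05 min in retention time are merged. Clustering
   is greedy in descending detection count (ties: total area, then label):
   the best-supported member becomes the representative and absorbs all
   unassigned neighbours, which makes the merge deterministic and idempotent.
   The merged row takes, per sample, the maximum of the members' areas — a
   duplicate is a split detection, not additional quantity. The ±100 ppm /
   ±0.05 min defaults are the targeted re-extraction windows; the original
   fuzzy thresholds were not published. Features detected in fewer than 10
   samples are then removed.
2. **Prevalence filter**: features observed in under 10% of samples are
   dropped (exactly 10% is kept — the published rule is strict "<").
3. **Half-minimum imputation**: each missing value becomes half the smallest
   observed area of that feature. Missing entries are explicit `NA`s
   throughout — zero is a legal peak area, and a loader flag
   (`zero_as_missing`) covers exports that encode missingness as 0.
4. **log2 transform**, only after full imputation.
5. **Quality filter**: keep features observed in ≥50% of samples of at least
   one subject group *and* showing a coefficient of variation below 40% in at
   least one subject group. The CV is computed on raw (not log) areas, the
   vendor-software convention, and both clauses use the pre-imputation
   missingness mask carried by the `feature_table` — imputed values never
   influence prevalence or quality decisions.
6. **Human-derived filter**: per subject, worn-nylon samples are compared
   against the pooled controls (unworn nylons plus solvent blanks) with a
   Welch test on log2 areas per feature and Benjamini–Hochberg correction
   across features; a feature is human-derived if any subject shows ≥2-fold
   enrichment at q < 0.05. Pooling the two control types is a choice — the
   published description names both without specifying pooling versus two
   separate tests.
7. **Per-experiment differential testing**: Welch test of high- versus
   low-attractor samples on log2 areas within each experiment,
   `log2FC = mean(high) − mean(low)`, BH across features, pass when
   `|log2FC| ≥ 1` and q < 0.05. The vendor software's exact test is unnamed
   in the original description; Welch on log2 areas is the conventional
   volcano-plot test, and moderated alternatives are deliberately out of
   scope.
8. **Consensus calling**: a feature is a hit only if it passes in *every*
   experiment with a consistent fold-change sign. A post-hoc redundancy sweep
   using the dedup tolerances collapses residual duplicate hits (keeping the
   smallest-q member per cluster) — the in-code analogue of a manual
   inspection step.

Thresholds are strict or non-strict exactly as printed: "<10 files", "<10%",
"<40%", "FDR<0.05" strict; "at least 50%", "at least 2-fold" non-strict; the
targeted analyses use q ≤ 0.10.

### Targeted re-analyses

`targeted_cohort1()` models a small repeated-measures design (2 high and 2
low attractor subjects × 4 experiments): per compound, subject-by-experiment
medians are rank-transformed globally and fit with
`rank ~ group + (1 | subject)` (lme4), with a Wald normal test on the group
coefficient and BH across compounds at q ≤ 0.10. The rank-based
repeated-measures analysis it mirrors was not fully specified; ranks-then-LMM
is the documented choice here. With only four subjects the Wald z is
anti-conservative — interpret borderline q-values cautiously at this design
size; the power of the test comes from consistency across experiments.
`targeted_cohort2()` is simpler and more robust: one median per subject
(11 high vs 7 low in the validation design), compared by the exact rank-sum
test, BH across compounds at q ≤ 0.10.

## Formula inference

`predict_formulas()` recovers the neutral mass of a deprotonated ion as
`ion_mz + 1.007276` Da. The bookkeeping: deprotonation removes a proton
(nucleus only), so the anion keeps the hydrogen's electron, and the neutral
mass is the ion mass plus one proton mass — the electron cancels exactly.
Setting `electron_correction = FALSE` adds a full hydrogen-atom mass instead
for comparison with software that ignores the electron. Enumeration is
exhaustive over C, H, N, O within configurable bounds (defaults C ≤ 40,
H ≤ 80, N ≤ 6, O ≤ 10, covering C3–C20 acids with margin), filtered to
|error| within the ppm window, rings-plus-double-bond equivalents
`RDBE = C − H/2 + N/2 + 1 ≥ 0`, and the hydrogen bound `H ≤ 2C + N + 2`, and
ranked by absolute ppm error. No isotope-pattern or MS/MS scoring — masses
alone decide, matching the original identification workflow.

## What the synthetic generators emulate — and what they do not

`simulate_trials()` draws, per trial, a loading of 30–40 mosquitoes; each
independently dies with the mortality rate (default 0.05), otherwise
activates with probability 0.85, is attracted with probability 0.8 given
activation, and chooses stimulus A with probability `w_A / (w_A + w_B)` given
attraction. Weights are latent subject attractiveness; the default 18 trials
per pair matches the worked scoring example. Independent Bernoulli outcomes
are the simplest generative model matching the reported count structure: no
spatial or social interaction between mosquitoes, no side bias, no
day-to-day environmental variation. Trial-to-trial variance beyond binomial
noise is therefore absent — the real assay's variance components were never
published, so these defaults are free parameters of the benchmark, not claims
about the assay. Dead mosquitoes occupy no behavioral category: categories
sum to the live count, and live plus dead equals loaded.

`simulate_feature_tables()` emulates the statistical structure of the
replicated untargeted experiments: 7 subjects (2 high, 2 low, 3 unclassified
attractors) plus unworn-nylon and solvent-blank control groups, 6 replicate
pieces per group per experiment, 4 experiments, 200 parent features with
log-normal areas (log2 baselines uniform over 14–22, within-group CV 0.25),
human-derived features 8-fold enriched on worn nylons over controls,
nylon-derived features absent from solvent blanks, exactly constant
internal-standard features, detection-limit censoring at 4096 counts (values
below it become explicit missing entries), and a configurable fraction of
fuzzy twin features jittered strictly within the dedup tolerances and
carrying a weaker copy of the parent's abundance pattern. Planted
differential effects (e.g. log2FC = 2 in high attractors) are applied
identically in every experiment. One master seed drives everything;
per-experiment streams are derived deterministically, so partial reruns
reproduce.

Deliberately not emulated: chromatographic peak shapes, retention-time drift
between batches, isotope envelopes, correlated compound families, and
subject-level random effects (between-subject abundance variation beyond the
planted effects is zero by default, so consensus false positives arise only
from sampling noise). Passing tests on these tables therefore demonstrate
that the pipeline's *logic* — filtering, imputation, testing, intersection —
recovers planted truth and controls false discoveries under the assumed noise
model; they do not certify performance against instrument artefacts the
generator omits.

## Numerical and design choices worth knowing

- Margins round half away from zero (`floor(x + 0.5)`), not banker's
  rounding; an unrounded mode exists.
- Rank-sum: exact enumeration at combined n ≤ 12, midranks for ties,
  tie-corrected variance; degenerate all-equal input returns Z = 0, p = 1.
- Greedy dedup order (detections, then area, then label) makes the merge
  independent of input row order; a second pass changes nothing.
- Stage filters never see imputed values; the missingness mask travels with
  the table.
- Welch tests across features are computed vectorised (row means and
  variances); they agree with `stats::t.test` per feature to numerical
  precision, which the test suite asserts.
- Problem sizes in the test suite (200 features × 54 samples per experiment,
  4 experiments; 18 trials per subject pair) were chosen to match the study's
  design scale while keeping the full suite fast.

## Worked example

```{r example, eval = FALSE}
library(hostpref)

# behavioral round-robin with known attractiveness weights
cfg <- behavior_sim_config(c(S33 = 8, S25 = 2, S28 = 1),
                           n_trials_per_pair = 18, seed = 1)
trials <- simulate_trials(cfg)
run <- run_behavior(trials)
run$preferences
tidy(run$tournament)

# metabolomics: plant ten 4-fold effects and recover them
mcfg <- metabo_sim_config(planted_hits = planted_hits(1:10, log2_effect = 2),
                          seed = 1)
sim <- simulate_feature_tables(mcfg)
mrun <- run_metabolomics(sim$tables)
mrun$manifest$stages
mrun$hits
```

## Known limitations

- The cohort-1 Wald test is anti-conservative at the 2-vs-2-subject design
  size; the cohort-2 rank-sum route is preferred when subject numbers allow.
- Cross-batch retention-time calibration is out of scope; the rt tolerance is
  the only defence against drift.
- Formula inference is mass-only and limited to CHNO; sulfur- or
  halogen-containing compounds will be mis- or un-annotated.
- The generators produce the *assumed* statistical structure; conclusions
  about real instrument data require the real data.
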