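---
title: "Attentive brain states in infant ERPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentive brain states in infant ERPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpstates)
library(dplyr)
```

## The scientific problem

Infants orient to faces, and the depth of that attentional engagement is
visible in the event-related potential (ERP): the *Nc* ("negative
central"), a frontal negativity roughly 300–800 ms after stimulus onset,
is larger (more negative) for stimuli that recruit more attention.
Beyond single components, the whole scalp field moves through a sequence
of quasi-stable topographies — *microstates* — whose durations and field
strengths characterise the underlying processing stages. This package
implements a complete analysis chain for asking whether such attentive
brain states, measured at an age before behavioural symptoms emerge,
carry information about a later categorical outcome (an ASD diagnosis at
three years) and a dimensional one (a socialization standard score):

1. classic Nc feature extraction (mean amplitude, peak latency) from
   frontal-region averages, with face-minus-control difference scores;
2. data-driven microstate discovery with a cross-validated choice of the
   number of maps, template fitting by spatial correlation, and per-map
   duration / mean-GFP features in the Nc window;
3. prediction of the categorical outcome by genetic-algorithm feature
   selection with a cross-validated SVM fitness, evaluated on a held-out
   sample with permutation inference; and
4. prediction of the dimensional outcome by elastic-net regression under
   leave-one-out cross-validation with nested hyperparameter tuning.

Because the human recordings behind this design are not publicly
deposited, the package ships a synthetic-cohort generator that plants
known microstate structure and outcome links, so every stage can be
validated by parameter recovery rather than by re-analysis of
unavailable data.

## Key quantities

For a scalp vector $v$ over $C$ channels, the global field power is the
population standard deviation across channels,
$\mathrm{GFP}(v) = \sqrt{\tfrac1C \sum_c (v_c - \bar v)^2}$, a
reference-free measure of field strength. The spatial correlation of two
topographies is the Pearson correlation across channels, equal to the
cosine of the angle between the average-referenced vectors. Microstate
analysis here is **polarity-sensitive** (signed correlations): the data
are time-locked evoked responses, where a sign flip is a different
component, unlike resting-state practice which discards polarity. A
configuration switch (`ignore_polarity`) provides the resting-state
convention for sensitivity analyses.

Given templates $m_1,\dots,m_k$ (zero-mean, unit-GFP rows), each sample
is labelled with the template of highest spatial correlation (ties to
the lowest index; flat samples carry the previous label forward so that
durations conserve the window). The global explained variance is
$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \, c_t\big)^2}{\sum_t \mathrm{GFP}_t^2},$$
with $c_t$ the winning correlation at sample $t$.

Per map and condition, the *duration* is the total occupancy of the
300–794 ms feature window (counting non-contiguous runs — this makes
durations sum exactly to the window length, a conservation law the test
suite checks on every simulated subject), and the *mean GFP* is the mean
raw field strength over the samples assigned to the map; a map with zero
duration is recorded absent rather than as a zero GFP.

## Microstate discovery and the number of maps

`aahc_cluster()` implements atomize-and-agglomerate hierarchical
clustering: every topography starts as its own cluster; at each step the
cluster contributing least to GEV is dissolved and its members
reassigned to the remaining centroid of highest correlation; centroids
are the polarity-aligned mean of members, renormalized to zero mean and
unit GFP. Tie-breaks (dissolution order and reassignment) always go to
the lowest index, making the procedure fully deterministic.

`select_n_maps()` chooses the number of maps by subject-level
cross-validation in the 0–794 ms window, in two stages:

* **Stage 1 — subject-level maps.** Each subject's GFP-peak topographies
  are clustered by AAHC into `max(k_range)` subject maps. Individual
  ERPs switch between states sharply, so subject-level peak topographies
  are essentially pure states. We deliberately do *not* learn from the
  grand average: when subjects' segment boundaries differ, grand-average
  samples near transitions are mixtures of two states (with a GFP dip
  from cancellation), and clustering them yields contaminated or
  spurious maps. GFP peaks are used for the same reason — they carry the
  most stable fields.
* **Stage 2 — group-level maps.** The pooled subject maps of the
  training subjects are agglomerated by weighted closest-pair merging
  (weights reflect each subject map's GFP-weighted fit), recording the
  centroid set at every candidate $k$. Closest-pair merging collapses
  near-duplicate maps (the same state estimated in many subjects) before
  anything else, so weak but genuinely distinct states survive to small
  $k$; an atomize-worst rule at this stage would instead dissolve them
  first.

Each candidate $k$ is scored by the mean GEV it achieves on held-out
subjects' full ERPs. The step from $k-1$ to $k$ is accepted when the
*marginal* held-out GEV gain of the $k$-set's most novel map (the one
least explained by the $k-1$ accepted maps) exceeds, at level
$\alpha = 0.05$, a randomization null in which that candidate's
component orthogonal to the span of the accepted maps is
channel-permuted. This null preserves everything the candidate could
gain from already-modelled structure and from generic
degrees-of-freedom inflation, while destroying any new topography.
Additionally, a candidate whose |correlation| with an accepted map
reaches 0.9 in most splits is treated as a refined duplicate of an
existing state, not a new one — the field's usual judgement about
near-collinear maps. The selected $k$ is the largest accepted step; if
no step is accepted the floor of `k_range` is returned with a warning.
Defaults: 10 random 50/50 splits, 200 randomizations.

## The synthetic cohort

`simulate_cohort()` emulates the study design end to end: three outcome
groups (default 40/72/19 subjects), three stimulus conditions
(face-direct, face-averted, and a non-social noise control), 64 channels
at 500 Hz over a −200…794 ms epoch, and four planted unit-GFP
topographies with pairwise |correlation| ≤ 0.5. Each group × condition
has a planned segment sequence (M1–M2–M3–M4–M1; the early state recurs
late so that every retained map occupies part of the 300–794 ms feature
window); subjects jitter the planned durations by a truncated Gaussian
(SD 30 ms, renormalized to the window) and the planned segment GFPs by a
Gaussian (SD 0.25 µV, floored). Map 3 is entirely absent in 15% of
subjects, reproducing the situation of a map found only in a subset of a
cohort, which the feature-table builder handles by dropping maps absent
in more than 5% of subjects — with the default generator this yields
exactly the 21-column design (sex, age, developmental level, plus
duration and GFP of M1/M2/M4 in each condition). Sensor noise is
spatially white by default (0.5 µV on the average); the group contrasts
plant shorter M1/M4 and longer M2 (face-direct) and weaker face-direct /
stronger control-condition M4 fields in the outcome group. The
continuous outcome is a linear function of planted features (defaults:
positive weights on face-direct M4 duration and GFP, a negative weight
on control-condition M4 GFP) plus a negative male sex effect and
Gaussian residual noise, so that recovery of both the coefficients'
signs and the feature ranking can be tested.

What the generator does **not** emulate: temporally and spatially
correlated EEG noise, volume-conduction geometry (planted maps are
random vectors, so topographic plots are caricatures), gradual state
transitions, trial-level variability behind the averages, and any true
biological link between brain states and diagnosis. Passing recovery
tests therefore demonstrates correctness of the estimation machinery
under the stated model, not clinical validity on real infants.

## Outcome prediction

The classifier stage works on the family-history subsample, split 70/30
with outcome stratification (largest-remainder apportionment, so 91
subjects split 64/27). `ga_select()` evolves binary feature masks with
fitness equal to the 10-fold cross-validated AUC of a class-weighted
linear SVM (weights inversely proportional to class frequency;
standardization strictly inside training folds), minus a tiny parsimony
term (1e-4 per feature) that only breaks ties toward sparser masks. GA
defaults — population 20, up to 25 generations with early stopping after
8 stale generations, uniform crossover 0.8, per-bit mutation 1/p,
elitism 2, 20 independent evolutions, memoized fitness — are sized so a
full selection completes in minutes on one core; the published protocol
named no GA settings, so these are package defaults, configurable in
`ga_params()`. Feature *incidence* is the fraction of evolutions whose
best set exceeded AUC 0.75 that contain the feature; the high-incidence
set collects features above 0.80.

`evaluate_classifier()` refits the SVM on stratified bootstrap resamples
of the training sample (1000 repetitions by default), scores the fixed
holdout, thresholds decision values at 0 for the confusion matrix, and
reports each metric as mean ± SD over repetitions with averaged
per-repetition 95% intervals (Wilson for proportions, Hanley–McNeil for
the AUC; the published analysis did not state its interval construction,
so this choice is ours and is recorded here). Metrics with zero
denominators in a repetition are excluded from that metric's mean with a
reported exclusion count. Significance against chance uses
`shuffle_test()`: outcome labels are permuted, the entire refit
procedure is repeated, and the one-sided add-one-corrected p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$ is returned.

`elasticnet_nested()` predicts the continuous outcome with leave-one-out
outer cross-validation; inside every outer fold, the mixing parameter
(α ∈ 0.1…1.0) and penalty are tuned by 10-fold × 10-repeat inner CV
minimizing RMSE, with exact ties resolved toward the sparser model. The
penalty grid is data-driven: ten log-spaced values from $\lambda_{max}$
down to $10^{-3}\lambda_{max}$ *plus an exact zero*. The zero endpoint
matters: a purely log-spaced grid floors the attainable bias at the
smallest grid value, so a noiseless linear outcome could never be
recovered to machine precision; with $n > p$ the $\lambda = 0$ limit is
ordinary least squares and is solved exactly by `lm.fit` rather than by
coordinate descent, which loses precision on near-saturated designs.
Pooled outer predictions give the RMSE and the relative error
(RMSE/outcome range, in percent); the RMSE interval is a subject-level
bootstrap over pooled (observed, predicted) pairs — refitting the full
nested loop inside the bootstrap would be computationally indefensible
and the pairs are exactly the exchangeable units of the pooled
statistic. Coefficients are recorded per outer fold in standard units;
"always selected" marks features nonzero in every fold.

## Numerical and design choices

* All windows are inclusive at both ends and expressed in ms relative to
  stimulus onset; a window extending beyond the epoch (the conventional
  300–800 ms Nc window against a 794 ms epoch end) is clipped with a
  message rather than failing or silently truncating.
* The frontal region memberships of real sensor nets are configuration,
  not code: `default_montage()` ships synthetic placeholder regions for
  the simulated 64- and 128-channel layouts and must be overridden for
  real recordings.
* Region averages are computed on average-referenced data, consistent
  with the topographic analyses.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; two runs of `run_pipeline()` under one
  configuration produce byte-identical tables and reports, which the
  test suite asserts.
* Degenerate inputs have defined behaviour: flat (zero-GFP) samples
  cannot be normalized and carry the previous label; a zero-duration map
  reports a missing (not zero) mean GFP; confusion-matrix ratios with
  zero denominators are missing, not zero; a cohort with no structure
  beyond the floor of `k_range` returns the floor with a warning.
* Problem sizes in the test suite (e.g. 40 reference subjects for map
  recovery, 20 GA evolutions at n = 120, LOO over 123 subjects for the
  elastic net) were chosen as the smallest sizes representative of the
  emulated study design.

## Known limitations

* The map-count procedure assumes the reference condition's states are
  expressed across most reference subjects; a state present in only a
  small minority would be merged or dropped at the pooled stage.
* The duplicate rule (|corr| ≥ 0.9) is a hard threshold; genuinely
  distinct states with very high mutual correlation would be missed by
  construction, at any method's peril.
* The GA explores $2^{21}$ masks heuristically; incidence is a
  stability summary across restarts, not a posterior probability.
* With $n < p$ the exact OLS limit is unavailable and the elastic net's
  smallest penalty is the smallest positive grid value.
* Shuffle p-values are limited below by $1/(n_{\text{shuffles}}+1)$.

## A small worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(group_sizes = c("noFH-noASD" = 12, "FH-noASD" = 14,
                                   "FH-ASD" = 7), seed = 3),
  k_range = 2:5, n_splits = 5, n_rand = 100,
  ga = ga_params(population_size = 10, n_generations = 6, n_evolutions = 2),
  n_repetitions = 25, n_shuffles = 99, inner_reps = 2, n_boot = 100,
  seed = 42)
res <- run_pipeline(cfg, out_dir = "run")
res$model$k_opt          # number of microstate maps
tidy(res$reports$high_incidence)
glance(res$regression)
autoplot(res$regression)
```
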