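---
title: "Methods: functional connectome group comparison and behavior prediction"
author: "fcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectome group comparison and behavior prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

# Overview

`fcnet` implements the statistical core of a whole-brain functional
connectivity study of cognitive impairment and recovery: building
Fisher-z connectivity matrices from region-of-interest (ROI) BOLD time
series, localizing group differences with the network-based statistic
(NBS), predicting psychomotor test scores from connectivity with
connectome predictive mapping (CPM), combining consensus networks into a
single psychomotor predictor network, and testing whether clinical group
membership moderates the brain–behavior slope. A synthetic cohort
generator with planted effects provides ground truth for every stage, so
the whole pipeline can be validated end to end without access to patient
data.

The motivating design is a three-group cohort — healthy controls (HC)
and cirrhotic patients with and without a history of overt hepatic
encephalopathy (OHE) — where patients are scanned before and after liver
transplantation and complete two psychomotor tests: the Number
Connection Test (NCT, completion time in seconds, higher = worse) and
the Digit Symbol Test (DST, correct symbols in 90 s, higher = better).

# Connectivity construction

ROI time series (T timepoints × N regions, default repetition time
2.5 s) are linearly detrended per region and band-pass filtered to
0.01–0.08 Hz, the conventional resting-state fluctuation band. The
filter is a forward–backward (zero-phase) Butterworth, order 2 per pass.
The filter family is a design choice — it is the common default in
resting-state pipelines — and the package's frequency-response tests are
stated against it: a 0.05 Hz sinusoid retains ≥ 90% of its amplitude, a
0.19 Hz sinusoid ≤ 10%. Before filtering, each series is padded to full
length by odd reflection at both ends, which keeps filter transients out
of the retained segment and makes the operation exactly symmetric under
time reversal (verified to 1e-8 in the tests). Nuisance signals (mean
white-matter and CSF signals, six head-motion parameters) are removed by
least-squares projection onto the confounds and their
backward-difference temporal derivatives. Band-pass before nuisance
regression is the default ordering; `preprocessTimeSeries(order =
"regress_first")` exposes the reverse, since pipelines differ on this
point.

Connectivity is the Pearson correlation between every pair of region
series, Fisher z-transformed (`atanh`) with correlations clipped to
±(1 − 1e-10) so z stays finite; clipping is reported when it triggers.
The N×N symmetric zero-diagonal matrix is equivalently carried as an
edge vector over the N(N−1)/2 region pairs in a fixed row-major
upper-triangle order; for the default 116-region AAL parcellation (78
cortical, 12 subcortical, 26 cerebellar regions) that is 6670 edges. The
vectorize/matricize pair is exact (bit-identical round trip).

First-volume discard (e.g. the first 10 volumes of an acquisition) is
deliberately the caller's responsibility — a `--discard-volumes` flag on
the `fc` stage — rather than hidden inside the operations.

# Network-based statistic

NBS controls the familywise error of edge-level group comparisons at
the level of connected components. The implementation follows the
standard recipe:

1. **Edge inclusion.** An edge enters the analysis if its z values are
   significantly nonzero (two-tailed one-sample t test, Bonferroni
   corrected over all E edges at level 0.05) in at least one group. The
   mask is computed once on the observed grouping and reused across
   permutations. The inclusion rule is stated in the source literature
   per participant, which cannot be a test (one number per edge per
   participant); the per-group reading implemented here is the nearest
   well-defined interpretation, and masking can be disabled
   (`alphaMask = NULL`).
2. **Edge-wise tests.** Two-sample one-tailed t tests at every included
   edge. Pooled-variance (Student) t is the default — the convention of
   the component-based testing literature — with Welch available by
   flag. Direction is explicit per contrast: HC > patient-pre for
   disrupted networks, post > pre for recovery/hyperconnectivity.
3. **Components.** Edges with p below the primary threshold (default
   1e-4) form a graph; connected components are found with igraph, and
   component size is its **edge count**. A hand-written depth-first
   search reference implementation (`bruteForceComponents`) provides an
   independent cross-check and agrees on 1000 random graphs.
4. **Permutation null.** Subjects are randomly reallocated to groups
   (default 10,000 permutations), the same mask and threshold applied,
   and the maximal component size recorded. A paired mode (within-pair
   swaps) exists for pre/post contrasts; by default pre-vs-post
   contrasts are unpaired two-sample comparisons because post cohorts
   are typically incomplete subsets.
5. **Corrected p.** Default estimator is `(1 + #{max >= M}) / (nPerm +
   1)`, which counts ties and cannot return 0. The common literal recipe
   — the strict-inequality proportion `#{max > M} / nPerm` — is retained
   behind `paperLiteral = TRUE` for exact replication of analyses that
   use it, with a warning when it returns an invalid 0.

Calibration (reproduced by `scripts/acceptance.R` and the test suite):
over 200 null cohorts (50 regions, 20 + 20 subjects, primary threshold
relaxed to 1e-2 so that the null actually produces suprathreshold edges
at this group size, 200 permutations) the familywise rejection rate at
corrected α = 0.05 stays within the 99% binomial band [0.01, 0.09]; and
with a planted 17-edge connected deficit of 0.8 z units (edge noise SD
0.1, 30 + 30 subjects, 500 permutations) the largest detected component
recovers ≥ 90% of planted edges with ≤ 10% extras at corrected
p ≤ 0.01 in at least 45 of 50 seeds.

# Connectome predictive mapping

CPM summarizes each subject by the mean Fisher-z strength over a
behavior-correlated edge set and predicts scores by simple linear
regression, assessed with k-fold cross-validation (default k = 5):

- Per fold, every edge is correlated with the score **on training
  subjects only**; edges with p < 0.01 are split into a positive tail
  (r > 0) and a negative tail (r < 0). The per-edge Pearson correlation
  p value equals the per-edge simple-regression slope p value, so one
  implementation satisfies both descriptions.
- Training strengths are regressed on scores (OLS), and held-out
  subjects are predicted. The convention is the positive-tail model for
  DST-like scores (higher = better) and the negative-tail model for
  NCT-like times (stronger connectivity, faster completion).
- Out-of-fold predictions are pooled and correlated with the observed
  scores (`rPredObs`); its significance uses the standard t transform by
  default, though the score-shuffle route used in the calibration study
  is the robust alternative since cross-validated correlations violate
  the independence assumptions of the parametric test.
- Consensus edges per tail are those selected in **every** fold; the
  union of the DST-positive and NCT-negative consensus networks — with
  per-edge provenance — forms the combined psychomotor network, which
  can then be applied as a fixed network to new cohorts
  (`applyNetwork`), returning r, F(1, n−2), p and the unstandardized
  slope.
- A fold whose chosen tail is empty predicts the training mean score
  rather than aborting, keeping the cross-validation total; this is
  logged loudly.

**A note on null calibration.** The pooled cross-validated correlation
is a *negatively biased* null statistic: each fold's intercept tracks
its training mean, which anticorrelates with the held-out fold's mean
by construction. With scores shuffled relative to connectomes (100
shuffles, n = 32, k = 5) the mean out-of-fold r in this implementation
is ≈ −0.10, not 0 — the pure train-mean predictor would give ≈ −0.34,
and overfitted slope noise dilutes it. This bias is inherent to the
pooled CV correlation and is precisely why permutation (not parametric)
reference distributions are recommended for CPM significance. The
acceptance suite states the idealized ±0.05 band for the mean null r
and therefore flags this property honestly rather than masking it; the
signal-recovery calibration (generator R² = 0.5, n = 32: mean r ≥ 0.4;
noiseless coupling: r ≥ 0.99) is unaffected.

# Group statistics and moderation

Behavior scores and network strengths are compared with standard
two-sample t tests (raw data or summary statistics, pooled or Welch).
The brain–behavior moderation model is

  score ~ 1 + strength + group + strength × group

fit by OLS with strength and the group indicator mean-centered before
forming the interaction (centering shifts only lower-order
coefficients, never the interaction term; a flag disables it).
Confidence intervals for all unstandardized coefficients come from
bias-corrected (BC, not accelerated — matching the stated analysis)
percentile bootstrap over nonparametric case resamples (default
10,000); resamples missing one moderator level are redrawn and counted.
The interaction's p value is additionally reported from the OLS t test.
The cited macro convention ("model 3") denotes a two-moderator design,
but the described analysis is a single moderator; the single-moderator
two-way interaction is implemented.

Calibration: with a true null interaction, the 95% BC interval covers 0
in 93–97% of 200 simulated cohorts (1000 resamples each; long-run
coverage measured at ≈ 0.95, so individual 200-replicate batches can
graze the band edges); with a true interaction of 12 at n = 36 the mean
point estimate is within 5% of the truth (OLS is exactly unbiased here,
so this checks the generator/fit plumbing).

# Synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions the package targets: groups HC = 32, non-OHE = 36,
OHE = 28 with paired pre/post sessions for patients (23 and 13
post-session completers); a 17-edge connected disrupted subnetwork
lowered by `deltaZ` in patient pre scans; a 19-edge hyperconnectivity
subnetwork raised in OHE post scans; and an 18-edge behavior-coupled
subnetwork. Planted sets are grown from a random spanning tree over a
sampled node subset (so the component logic is genuinely exercised) and
are mutually disjoint by default — mirroring the empirical finding that
post-surgical hyperconnectivity was not part of the initially disrupted
network.

Two generation modes exist. **Direct-z** (default) draws each
subject-session edge vector as shared base connectome (edges ~
N(0.25, 0.15), a realistic scale for Fisher-z resting-state
connectivity) + group/session offsets + subject factor + i.i.d. edge
noise; it is fast and gives exact control of effect sizes in z units.
**Time-series** mode draws T×N multivariate normal series whose
correlation is `tanh` of the subject's target z matrix, shrunk toward
identity by the smallest convex factor achieving a minimum eigenvalue
of 1e-3 (factor recorded per subject); empirical connectivity converges
to the target as T grows, exercising the Pearson/Fisher path.

Behavior is generated from each subject's **realized** strength `s` on
the coupled edge set (centered at the cohort mean): DST = 47.8 + β·s +
γ·g·s + noise and NCT = 40.4 − β·s − γ·g·s + noise, where g indicates
the moderator group. The negative NCT coupling encodes the convention
that stronger connectivity means faster completion. Intercepts sit at
healthy-control-scale values; score *variances* are smaller than
clinical tables because they reflect only the planted coupling plus
noise.

Two generator parameters deserve justification:

- **Subject strength factor** (`subjectStrengthSd`, default 0.15 z
  units, applied uniformly on the coupled edge set). Individual
  differences in network strength are what CPM assumes; with purely
  independent edge noise, each edge carries only 1/|edges| of the
  behavioral signal (per-edge correlation ≈ √(R²/|edges|) ≈ 0.17 at 18
  edges), and p < 0.01 edge selection can never fire regardless of the
  true strength-score coupling. A shared per-subject factor makes every
  coupled edge correlate with behavior at a realistic ≈ 0.6, the regime
  the method is designed for.
- **Effect sizes.** No z-unit effect sizes are reported for the
  empirical disrupted networks, so `deltaZ = 0.8` with edge noise 0.1
  (the calibration conditions above) was chosen once for testability —
  a clearly detectable but not degenerate planted effect — and is not
  revisited.

One root seed drives everything; per-subject streams are derived by a
counter so growing a cohort never reshuffles existing subjects, and all
outputs are bit-identical under a fixed seed.

What the generator does **not** emulate: hemodynamic response shapes,
scanner noise spectra, motion artifacts, spatial autocorrelation of the
parcellation, or heavy-tailed clinical score distributions. Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under the stated model, not that the pipeline is robust to
every artifact of real fMRI.

# Numerical choices and degenerate inputs

- Correlations clipped at ±(1 − 1e-10) before `atanh`; clipping logged.
- Zero-variance regions are an error naming the region; constant edges
  are skipped in CPM selection (logged); zero pooled variance at an
  edge yields one-tailed p = 0.5 / 0 / 1 by the sign of the mean
  difference (logged).
- Rank-deficient nuisance designs drop dependent columns with a
  warning.
- Fold assignment is one random partition from the run seed, written to
  the result for audit; `k = n` (leave-one-out) is accepted.
- Component ties: components are sorted by edge count descending;
  corrected p is monotone in size against the fixed null sample.
- Bootstrap quantiles use type-6 empirical quantiles; the BC interval
  reduces exactly to the percentile interval when the bootstrap
  distribution is median-unbiased.
- R is 1-indexed and all internal node indices are 1-based; external
  JSON truth files use 0-based node pairs, and all reports name edges
  by region label.

# Problem sizes used in validation

The shipped calibration studies run at desk scale, chosen to keep the
full suite in the minutes range while leaving each check statistically
meaningful: 200 null NBS cohorts at 50 regions / 200 permutations; 50
recovery cohorts at 116 regions / 500 permutations; 1000 random graphs
for the component oracle; 100 CPM score shuffles and 50 recovery
cohorts at n = 32; 200 moderation cohorts at 1000 bootstrap resamples.
The defaults of the user-facing functions remain the full-scale values
(10,000 permutations, 10,000 resamples).

# Known limitations

- The NBS permutation reallocates subjects freely; whether the original
  analysis preserved pre/post pairing in its permutations is unstated,
  so both unpaired (default) and sign-flip paired modes are provided.
- The published cross-validated correlations on the original cohort
  (r ≈ 0.5 for DST, r ≈ 0.45 for NCT) depend on unreleased patient data
  and are not reproduction targets; the package validates against
  planted ground truth instead.
- A "moderated mediation" trend mentioned in the source results names
  no mediator and is therefore not implementable; no mediation model is
  attempted.
- Published group-comparison p values from rounded summary tables
  cannot be regenerated exactly (the rounded inputs shift the third
  decimal); `summaryT()` reproduces them to the printed precision range
  only.
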