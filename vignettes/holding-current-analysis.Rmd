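---
title: "Window-based classification of drug responses in voltage-clamp recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based classification of drug responses in voltage-clamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampresp)
```

## The measurement problem

In whole-cell voltage clamp at a fixed potential (here V_clamp = −60 mV),
the amplifier injects whatever current is needed to hold the membrane at
that potential. A drug that opens or augments an inhibitory conductance
shows up as a slow *outward* (positive) shift of a few pA to a few tens of
pA in this holding current, I_holding; an excitatory action shows up as an
*inward* (negative) shift. The analytical problem is to decide, cell by
cell, whether a minutes-long bath or pressure application of an agonist
(here the NOP agonist nociceptin/orphanin FQ, N/OFQ, tested from 1 nM to
10 µM) changed I_holding, in which direction, and by how much — against
pA-scale noise and the ever-present possibility of slow drift.

`clampresp` implements that decision procedure, the sliding-window
analysis used to validate it, downstream population statistics
(permutation tests on group means and SDs, Hill concentration–response
fitting, Scott-bandwidth kernel densities for violin plots), a
desensitization metric for repeated agonist applications, and a small
quantification module for stimulated dopamine transients recorded with
fast-scan cyclic voltammetry (FSCV). Because the original per-cell
recordings are not publicly deposited, the package ships a synthetic
trace generator with known ground truth; every stage of the pipeline is
calibrated against that generator.

## The classifier

The trace is reduced to 30-s bin means (`bin_trace()`; a trailing
partial bin is discarded). For each drug epoch, `classify_response()`
compares the last eight pre-drug bins (a 4-min baseline window) with the
last eight bins whose start time falls within the application (the last
4 min of drug), using Student's *unpaired* two-sample t test with pooled
variance. The effect size is the difference of the two window means
(drug − baseline, pA). Direction is `none` when p ≥ α (default 0.05) or
when |effect| falls below an optional magnitude screen (`min_effect_pA`,
default 0; 1.5 pA is a useful secondary criterion when counting
clear-cut responders). Short pressure-ejection epochs (2 min = 4 bins)
use all available drug bins and are flagged `truncated` rather than
rejected — bath and pressure responses at matched concentrations are
statistically indistinguishable and are pooled downstream.

Two deliberate conventions: the baseline window ends immediately before
drug onset with no guard gap, and washout data are never used for
classification — washout only enters the sliding-window validation
below. A `welch = TRUE` switch substitutes the unequal-variance test for
users who prefer it; the default is the pooled form.

Because bin means of independent noise samples are themselves
independent and Gaussian, the nominal test level is exact under the
generator's null, and the suite verifies the realized type-I rate on
1000 null traces sits inside the binomial band around α.

## Sliding-window validation

A significant baseline-versus-drug comparison could in principle be
produced by slow drift rather than a drug response. `sliding_window()`
quantifies this: every 4-min (8-bin) window from the first bin to the
last full window, advancing one bin per step, is tested against the
fixed baseline window, and the per-window p values are Bonferroni
corrected with family size equal to the number of windows evaluated in
that cell. A genuine response produces a single contiguous run of
significant windows time-locked to the application (`max_consecutive`
summarizes the longest run); drift produces significance that persists
or grows during washout. `window_histogram()` aggregates results across
cells into the proportion significant per onset-aligned window start.
Bonferroni correction makes the family-wise error rate on null traces at
most α by construction; simulation shows it is conservative (observed
≈ 0.01–0.02) because overlapping windows are strongly correlated.

## Desensitization

For two applications in the same cell, `desensitization_ratio()` is the
signed ratio of the second effect to the first. A ratio near 1 means
full repeated responding; values near 0 mean the first application
functionally silenced the receptor. In the generator, a first
application at ≥ `desens_threshold_nM` (default 100 nM) multiplies
subsequent response amplitudes by `desens_frac` (default 0.14,
emulating strong VTA-style desensitization; setting it to 0.9 emulates
the much weaker SNc-style behavior).

## Population statistics

* `permutation_test()` compares two groups on the difference of means or
  of sample SDs (n − 1 denominator). The null distribution reassigns the
  pooled values to groups of the original sizes: exhaustively over all
  `choose(nx+ny, nx)` assignments when that count is ≤ 200,000,
  otherwise by Monte Carlo with the add-one correction
  p = (1 + #extreme)/(1 + n_perm), so p is never reported as 0.
  Two-tailed tests use |stat| ≥ |observed|; the one-tailed variant takes
  the tail in the direction of the observed statistic (the use case is
  testing whether a blocker *reduced* the spread of responses).
* `fit_hill()` fits R(c) = Emax·cⁿ/(EC50ⁿ + cⁿ) by least squares with
  the zero-concentration response fixed at 0 (effects are
  baseline-subtracted by construction). The Hill coefficient is fitted
  freely but bounded to [0.2, 5]; `fix_hill_n = 1` gives the classical
  fixed-slope fit. The optimizer is multi-started over log-spaced EC50
  initial values spanning the tested concentrations, and the converged
  start with the lowest residual sum of squares wins. The fit is pooled
  across cells (all per-cell points enter one fit) rather than
  fit-per-cell-then-averaged; with ~5 concentrations per cell and high
  amplitude heterogeneity, per-cell fits are poorly constrained.
* `kde_violin()` builds the Gaussian kernel density with bandwidth =
  Scott factor (n^(−1/5)) × sample SD on a grid spanning the data range
  ± 3 bandwidths, then renormalizes by the trapezoid rule so each curve
  integrates to exactly 1 — the equal-area convention for violins.

## The synthetic generator

`simulate_trace()` produces
current(t) = baseline + drift·t + Σ amp·g(t) + ε(t), where g rises as
1 − exp(−(t−t_on)/τ_on) during application and relaxes toward
(1 − recovery_frac)·g(t_off) with time constant τ_off afterwards
(recovery_frac < 1 models partial washout). Defaults: baseline 40 pA,
sampling 10 Hz, τ_on 30 s, τ_off 60 s, full recovery, iid Gaussian
noise with SD 2 pA. The recordings being emulated do not come with a
published noise figure; 2 pA at 10 Hz was chosen so that the 10–20 pA
effects reported for this receptor system are comfortably detectable,
and it is an explicit assumption of all calibration results. Drug
arrival is treated as instantaneous at t_on — perfusion dead-time is
unknowable after the fact and τ_on absorbs it; only window means matter
downstream. An optional AR(1) coefficient generates temporally
correlated noise for stress-testing the classifier against slow wander
(the stationary marginal SD is preserved).

`simulate_cohort()` adds population structure: each cell draws a class
from (p_outward, p_inward, p_none) — defaults 44/86, 15/86, 27/86 — and
a saturating amplitude (truncated normal of the correct sign; defaults
20 ± 10 pA outward, −16 ± 8 pA inward). The realized amplitude at each
epoch is the cell amplitude times the Hill factor cⁿ/(cⁿ + EC50ⁿ)
(defaults EC50 8 nM, n 1), with inward responses suppressed to zero
above `inward_max_conc_nM` (default 100 nM, reflecting that excitatory
responses are a low-concentration phenomenon) and desensitization
applied as above. Ground truth (class and realized amplitude per epoch)
is returned alongside the traces. Amplitude sign/class is drawn
independently of TH and projection labels by default; correlated label
generation is left to the user's own cohort specs.

What the generator does **not** emulate: synaptic events, series
resistance changes, seal degradation, biophysical channel models of the
GABA_A versus GIRK mechanisms, and non-stationary noise. Passing
calibration on this generator therefore demonstrates that the decision
procedure is correct and well-calibrated under its stated noise model —
not that any particular biological recording satisfies that model.

## FSCV quantification

`simulate_transients()` emulates the oxidation-potential current around
repeated stimulations: a double-exponential transient (normalized so
the programmed peak is exact), geometric per-stimulation rundown
(peak_k = peak·(1 − rundown)^(k−1)), a multiplicative drug effect from a
chosen stimulation onward, and Gaussian amplitude noise per stimulation
(between-stimulation release variability — the variance component that
matters for phase means; sample-level sensor noise is not modeled).
`background_subtract()` removes the mean of the 1 s preceding each
stimulation; `peak_amplitude()` takes the windowed maximum;
`percent_of_baseline()` is 100 × mean(drug peaks)/mean(baseline peaks).
The whole chain is invariant to constant background offsets. Rundown
alone drives percent-of-baseline below 100 monotonically — the confound
that motivates longer stimulation intervals for optical experiments,
and the reason drug effects estimated this way are upper bounds on
specificity. No chemometric calibration (nA to µM) is attempted, and
group-level mixed-effects inference is out of scope; summaries are
descriptive.

## Numerical and procedural choices

* Bin k covers [t0 + (k−1)·w, t0 + k·w); "bins during drug" are bins
  whose *start* lies in [t_on, t_off).
* Zero variance in both windows with equal means returns t = 0, p = 1;
  zero variance with unequal means returns p = 0 flagged `degenerate`.
* Traces round-trip through text exactly: numeric columns are written
  with 17 significant digits.
* Exhaustive permutation comparisons use a 1e-12 slack when comparing
  statistics to the observed value, so ties under floating point count
  as extreme (the conservative choice).
* Per-cell simulation seeds are derived deterministically from the
  cohort seed, so cohorts are reproducible element-by-element.

## Calibration problem sizes

The shipped suite calibrates type-I error on 1000 null traces, power on
500 responder traces (15 pA in 2 pA noise), sliding-window family-wise
error on 1000 null traces, EC50 recovery on 200 replicate cohorts of 48
cells (20% amplitude noise, truth 10 nM, median required within 25%),
desensitization recovery on 50-cell cohorts, and FSCV effect recovery
on 20-stimulation series; these sizes give binomial/SEM bands tight
enough to detect miscalibration of a few percentage points while
keeping the default run fast.

## Known limitations

* Partial washout is simulated and visible to the sliding-window
  analysis, but no categorical full-versus-partial recovery score is
  produced; recovery is reported descriptively.
* The pooled Hill fit assumes exchangeable cells across concentrations;
  systematic per-animal effects are not modeled.
* The classifier's exactness argument relies on independent bins;
  strongly autocorrelated noise (large AR(1) coefficients) inflates the
  realized type-I rate, which is precisely what the sliding-window
  validation is designed to expose.
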