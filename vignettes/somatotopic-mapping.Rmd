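---
title: "Mapping finger somatotopy: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping finger somatotopy: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

somatomap analyses fine-grained topographic finger maps in primary
somatosensory cortex (area 3b) from surface-sampled fMRI together with
matched psychophysics. This vignette explains the models the package
implements, the assumptions and numerical choices behind them, and what
the synthetic-data generator does and does not emulate — and hence what
a passing test suite does and does not establish about real data.

## The stimulus space and the travelling-wave protocol

All map analyses share a one-dimensional stimulus space of 25 units
spanning [-12.5, +12.5], divided into five equal 5-unit intervals, one
per finger, D1 (thumb) lowest. The interval *boundaries* are a package
convention: the space's extent and the five-finger equivalence are
standard, but nothing forces a particular partition, so we fix digit k
to occupy [-12.5 + 5(k-1), -12.5 + 5k) with centre -15 + 5k
(`digit_centers()`).

The travelling-wave (phase-encoded) protocol stimulates the five
fingertips in sequence, 5.12 s each, over 20 cycles of 25.6 s; at a TR
of 2 s a run is 256 volumes (`make_phase_design()`). A reverse-order
run mirrors the digit sequence. The blocked protocol
(`make_block_design()`) stimulates each finger 10 times for 5.12 s in a
pseudo-random order with at most two consecutive repeats, with a 2-s
pause after 70% of trials and a 6-s pause after 30%, giving a
208-volume run. How the 70/30 pause mix is counterbalanced across
fingers is underdetermined by the protocol description; we impose
*exact* per-finger proportions (7 short and 3 long pauses per finger at
the defaults), the strictest reading, so the pause structure cannot
differ between fingers even by chance.

## Haemodynamics

The neural drive of a vertex with preferred position $x$ and tuning
width $\sigma$ under stimulus position $s(t)$ is

$$r(t) = g \, \exp\!\left(-\frac{(s(t) - x)^2}{2\sigma^2}\right),$$

in % signal, convolved with a canonical double-gamma HRF (response
peak 6 s, undershoot 16 s, peak:undershoot 6:1) sampled at the TR and
normalised to peak 1 (`hrf_kernel()`). The double-gamma is the
community default consistent with the few-second haemodynamic delay
that surface-based travelling-wave pipelines assume; nothing downstream
depends on its fine shape except through the phase conventions below.

### The residual phase lag of mirror-averaged runs

`average_mirror_runs()` reverses the reverse-order run in time
scan-by-scan, shifts it forward by 2 TRs (4 s), and averages with the
forward run. A point often glossed over: time reversal *flips the
sign* of the haemodynamic delay. If the true delay at the cycle
frequency is $\tau$ (about 5.6 s for the canonical HRF at 1/25.6 Hz,
`hrf_phase_delay(25.6)`), the forward run carries $+\tau$ and the
time-reversed reverse run carries $-\tau + \text{shift}$. Their
average therefore carries a residual lag of exactly shift/2 = 2 s —
*independent of* $\tau$. `assign_digits_from_phase()` consequently
subtracts a 2-s lag by default before binning phase into five equal
fifths of the cycle (forward: increasing phase is D1 to D5; reverse:
D5 to D1; the boundary convention follows the digit intervals above).
For a single, non-averaged run the correct lag is the HRF's own phase
delay, and `hrf_phase_delay()` should be passed explicitly. Had we
subtracted the full 4-s shift instead, every phase would be biased by
2 s — about 40% of a digit bin — and vertices tuned near interval
boundaries would be systematically misassigned.

The averaging also attenuates the fundamental by
$\cos(\omega(\tau - \text{shift}/2))$ (about 0.64 here); this costs
amplitude, not phase, so digit assignment is unaffected.

## Stimulus-frequency Fourier statistics

`fourier_analyze()` computes, per vertex, the DFT of the demeaned
series; the signal is the power at the stimulus bin (bin = number of
cycles) and the noise is the mean power over all admissible bins:
frequencies at or above 0.005 Hz (the drift and slow-motion band below
is ignored) up to the Nyquist limit, excluding the stimulus bin and its
2nd and 3rd harmonics. Excluding harmonics is a package choice — the
response of a narrowly tuned vertex is non-sinusoidal, and counting its
harmonic power as noise would deflate the F-ratio of exactly the
vertices the analysis is meant to find. Response amplitude in %
signal is the DFT magnitude times 2 (negative frequencies) times 2
(peak-to-peak), divided by the series length and the vertex's mean
intensity, times 100.

For white Gaussian noise the statistic is exactly
$F(2, 2K)$-distributed ($K$ = number of noise bins), because distinct
DFT bins of white noise are independent complex Gaussians; p-values use
that reference. With 256 volumes at TR 2 s, $K = 123$. A
zero-variance series is flagged `NA`; a noiseless periodic series
(noise power at the float roundoff of the signal) is flagged `Inf`
rather than reported as a huge finite value.

Group-level helpers follow the same vector language: the cross-subject
F-ratio of per-subject complex coefficients is
$(\bar x^2 + \bar y^2) / \{[\sum(x-\bar x)^2/n + \sum(y-\bar y)^2/n] /
(2n-2)\}$ — the printed form of this formula in the literature is
typographically ambiguous about grouping, and we implement the reading
above literally and test it against hand evaluation. The dispersion
index $d = |\text{mean vector}| / \text{mean}|\text{vectors}|$ is
scale-free and lies in [0, 1], distinguishing consistent small signals
from inconsistent large ones.

Cluster filtering (`cluster_filter()`) keeps edge-connected components
of supra-threshold vertices (default p < 0.01) whose summed vertex
area reaches 14 mm²; vertex area assigns each vertex one third of
every incident triangle (`vertex_areas()`), so areas are conserved
exactly. The GLM-side extent rule (`extent_filter()`) keeps components
of more than 3 vertices — a voxel-count rule transplanted to the mesh
with edge adjacency, since a synthetic patch has no voxel grid.

## pRF modelling

`fit_prf()` estimates the 1D Gaussian pRF (centre $x \in [-12.5,
12.5]$, width $\sigma \in [0.5, 25]$) by a coarse grid (21 centres by
12 log-spaced widths) with gain and baseline solved linearly at each
candidate, then bounded L-BFGS-B refinement. The lower width bound 0.5
is one tenth of a fingertip's 5-unit interval; the upper bound is the
full five-finger space. We deliberately use least squares rather than
a variational-Bayes scheme: the package's validation surface is
parameter recovery on synthetic data, not posterior calibration, and a
variance-explained retention threshold (default 0.2 in
`summarize_prf()`) plays the role a posterior-probability cutoff plays
elsewhere. Vertices are pre-screened (`screen_vertices()`) by an
omnibus F-test on five HRF-convolved digit regressors at p < 0.05
uncorrected, which calibrates to a 5% type-I rate on pure noise.

**Identifiability caveat.** With only five discrete stimulus positions
and a free gain, the per-digit drive profile
$(g\,e^{-(c_d - x)^2/2\sigma^2})_{d=1..5}$ has at most five informative
values. A narrow pRF centred in an edge digit produces essentially one
nonzero value plus one small neighbour, and $(x, \sigma, g)$ then trade
off along a ridge: fits reach variance explained ≈ 1 at parameter
values far from the generator's. This is a property of the
design-model pair, not of the optimizer. Recovery statements in the
tests therefore use interior centres with $\sigma \ge 1.5$; users
should treat fitted widths of edge-digit vertices with narrow profiles
with caution. Continuous or denser stimulus spaces would remove the
degeneracy.

`summarize_prf()` reports per-digit mean/SD of retained widths and
marks digits with no retained fit as *missing* (`NA`), never as zero —
silent zeros would bias group averages downward.

## Representational similarity and resting-state coupling

`finger_betas()` fits the five-regressor GLM and forms the
`[4 -1 -1 -1 -1]`-type contrast per digit; the weights sum to zero, so
intensity offsets cancel. `between_run_similarity()` correlates digit
maps across two runs (Pearson over masked vertices), optionally Fisher
z-transformed for averaging. `neighbor_summary()` averages entries at
digit distance k; by default both off-diagonal wings are used (8, 6,
4, 2 ordered entries for k = 1..4). Whether one should average
ordered or unordered pairs is genuinely open for a non-symmetrized
between-run matrix; the `ordered` flag exposes both, and for a
symmetric matrix they coincide. `resting_xcorr()` computes the
Pearson correlation of overlapping segments at every lag up to ±130
TRs — the Pearson-per-lag form handles edges explicitly, since series
ends drop out of the overlap rather than being zero-padded.

## Mislocalization and acuity

`confusion_from_trials()` tabulates 5×5 stimulated-by-reported counts
(20 trials per digit in the standard session).  Mislocalizations group
by neighbour distance; across the five stimulated digits there are 8,
6, 4 and 2 ordered pairs at distance 1–4, so a total of T errors
splits under position-blind guessing as T·(8, 6, 4, 2)/20
(`chance_expected()`; e.g. T = 942 gives 376.8, rounding to 377 first
neighbours). Fractional expectations are used in tests; rounding is
display-only. The G-test uses $G = 2\sum O\ln(O/E)$ with zero cells
contributing 0 (the limit convention) and no Williams correction —
the small-sample correction is omitted deliberately to keep the
statistic exactly the log-likelihood ratio the chance model implies —
with Holm–Bonferroni across digit families (`g_test_family()`).
Percentages of mislocalizations are emitted normalized per total; the
per-stimulated-digit normalization can be formed from the returned
counts, since either reading of "relative distribution" appears in
practice.

Signal-detection measures pool false alarms for a digit over all
trials where any *other* digit was stimulated. The log-linear
correction adds 0.5 to hit and false-alarm counts and 1 to each
denominator — the standard constants for the cited transformation —
which keeps rates strictly inside (0, 1) so $d' = z(H) - z(FA)$ and
$\beta = \exp[(z(FA)^2 - z(H)^2)/2]$ are always finite. Because hit
and false-alarm denominators differ (20 vs 80 at the default design),
equal *raw* rates leave a small nonzero corrected $d'$; tests assert
the formulas exactly and the equal-rate property approximately.

Two-point discrimination thresholds come from a maximum-likelihood
binary logistic fit in pin distance; the threshold is the 50% crossing
$-\beta_0/\beta_1$. Step-like (separated) data are handled by
bracketing between the highest sub-50% and lowest supra-50% distance
rather than reporting the unstable glm estimate; all-same responses
are flagged non-estimable. Per-run thresholds are averaged across
runs (`two_pd_threshold_runs()`).

The detection staircase simulator (`simulate_staircase()`) runs two
interleaved 3-down/1-up staircases on the discrete 12-step
monofilament ladder (0.008–6 g, analysed as log10 of force in 0.1 mg
units). The convergence rule — stop when the SD of recent levels is
at most one step — needs a window to be computable; we use the last
10 presented levels, and the threshold estimate is their mean,
averaged over the two staircases. 3-down/1-up targets the
$0.5^{1/3} \approx 79.4\%$-correct point of the observer; the
simulator's mean estimate lands near that point for steep observers,
with the discrete ladder contributing quantization error of up to
about half a step.

## Group statistics

`hedges_g_boot()` computes the pooled-SD standardized mean difference
with the small-sample factor $J = 1 - 3/(4\,\mathrm{df} - 1)$ and a
seeded bootstrap CI over 10,000 resamples by default; the interval is
percentile unless `type = "bca"` is requested (percentile is the
simplest interval whose coverage the tests can reason about; BCa is
provided for skewed samples). `tost_equivalence()` runs two one-sided
pooled-variance t-tests against the band edges and reports the less
significant side. `power33_bounds()` sets the band to the effect size
detectable with 33% power, solved from the noncentral t distribution;
our convention is a *two-sided* test at level alpha with the pooled-df
noncentral-t power function, exposed via arguments, since the bound's
one- vs two-sidedness is not standardized. Note the composition is
conservative: with 33%-power bounds at typical group sizes, null data
rarely achieve equivalence at p < 0.05 — the declared-equivalence
rate is a reported quantity, not a calibration target.

`iterative_factor_model()` wraps maximum-likelihood factor analysis
with promax rotation in the exclusion procedure: while any variable's
maximal absolute loading is below the cutoff (default |0.4|, about 16%
shared variance), drop the worst such variable and refit; then drop
cross-loading variables (two or more loadings at the cutoff) the same
way; stop when every retained variable loads on exactly one factor.
Ties break by variable order. Each step removes one variable, so the
procedure terminates. The full trace is returned, and uniquenesses
(psi) near zero are reported as Heywood cases rather than silently
accepted.

## What the generator emulates — and what it does not

The synthetic patch is a flat 1-mm rectangular grid with a perfectly
linear somatotopic gradient, Gaussian tuning, stationary AR(1) Gaussian
noise, and a spatially constant HRF. Real cortex is folded, its
gradient is curved and interrupted, its noise is non-stationary with
physiological structure, and its HRF varies across vessels and depth;
none of that is modelled, and preprocessing (distortion, motion,
physiological denoising, segmentation) is out of scope entirely. The
AR(1) choice is the minimal temporally correlated noise model — enough
to verify that the statistics do not silently assume white noise, not a
claim about fMRI noise spectra. Passing tests therefore establish that
the *computations* are correct and calibrated under their stated
assumptions, and that parameters are recoverable when the model is
true; they do not establish robustness to the ways real data violate
the model.

## Problem sizes and tolerances

The validation suite uses a 20×10-vertex patch for end-to-end recovery
(256-volume runs, noise SD 0.3% at gain 2%, AR(1) 0.2), 3000 noise
vertices for calibration rates, 400 trials per distance for
two-point recovery, 40 staircase replicates, and n = 500 for the
planted two-factor recovery — sizes chosen so Monte-Carlo error is
well inside each assertion's tolerance while the whole suite runs in
well under a minute. Calibration assertions use three-sigma
Monte-Carlo bands; oracle equivalences use float tolerances (1e-9 to
1e-12); recovery assertions use the tolerances stated alongside each
test.
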