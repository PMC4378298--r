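---
title: "Directed low-frequency connectivity of the motor network: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed low-frequency connectivity of the motor network: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cortical motor areas — left and right primary motor cortex (LM1, RM1), left
and right premotor cortex (LPMC, RPMC), and the supplementary motor area
(SMA) — interact coherently at rest in the low-frequency band of the BOLD
signal (0.04–0.1 Hz). After stroke these interactions weaken, and
rehabilitation (mental practice, alone or combined with physical therapy)
may partially restore them. `lfogcnet` implements the quantitative pipeline
for asking those questions with *directed* functional connectivity:
parametric spectral Granger causality on ROI time series, band-integrated
causal flow, permutation significance, percent change statistics across
groups, and brain–behavior correlation, together with a ground-truth
simulator that makes every stage testable without scan data.

## Model and estimator

Each subject's analysis-ready data are a T×R matrix of region signals at
sampling interval `tr_s` (TR, seconds). For a region pair, a bivariate
vector-autoregressive (VAR) model of order *p* is fitted by least squares
(no intercept; inputs are detrended), with residual covariance
$\Sigma$ estimated with the unbiased denominator $T - p - Rp$. The
spectral machinery is the classical frequency-domain decomposition of
interdependence: with $A(f) = I - \sum_k A_k e^{-i 2\pi f k \,\mathrm{tr}}$,
transfer function $H = A^{-1}$ and spectral matrix
$S = H \Sigma H^* \cdot \mathrm{tr}$ (one-sided convention; any fixed
convention cancels in the log-ratios below), the total interdependence
between regions 1 and 2 splits as

$$M_{1,2}(f) = M_{1\to2}(f) + M_{2\to1}(f) + M_{1\cdot2}(f)$$

with

$$M_{2\to1}(f) = \ln \frac{S_{11}(f)}{\tilde H_{11}(f)\,\Sigma_{11}\,\tilde H_{11}^*(f)\,\mathrm{tr}},
\qquad \tilde H_{11} = H_{11} + \frac{\Sigma_{12}}{\Sigma_{11}} H_{12},$$

symmetrically for $M_{1\to2}$, $M_{1,2} = \ln(S_{11}S_{22}/\det S)$, and the
instantaneous term computed independently as
$\ln(\tilde H_{11}\Sigma_{11}\tilde H_{11}^* \cdot \tilde H_{22}\Sigma_{22}\tilde H_{22}^*\,\mathrm{tr}^2/\det S)$,
so the identity above is a genuine numerical check (asserted to $10^{-6}$
per frequency in the tests). The normalisation follows from
orthogonalising the second innovation against the first, which is why
$\tilde H_{11}$ carries $\Sigma_{12}/\Sigma_{11}$; the directed measures are
then nonnegative by construction. The instantaneous term has no pointwise
sign guarantee for *estimated* models and is left unclamped.

Band-integrated causal flow (iGC) is the normalised trapezoidal integral of
a directed spectrum over the analysis band (default 0.04–0.1 Hz), with the
band edges linearly interpolated on the 512-point frequency grid over
(0, Nyquist]; a constant spectrum integrates to itself exactly.

## Model order

Order selection by AIC/BIC (`select_order()`, default AIC with `p_max = 10`)
works well on broadband data and recovers planted orders in simulation. On
0.04–0.1 Hz band-passed series of 130–237 volumes, however, both criteria
saturate at `p_max`: the filtered process is nearly deterministic, each
added lag keeps reducing the one-step error, and the resulting fits are
wildly overparameterised (null causal flows of 0.5–1.0, occasional singular
regressors). The study pipeline therefore defaults to a *fixed* order of 3
— two poles for the single band resonance plus one lag for the coupling —
and exposes it in `study_config(order = )`. Results at these session
lengths are genuinely order-sensitive; any cross-group comparison must hold
the order fixed across groups, which the pipeline does.

## Permutation null and significance

Significance thresholds are built by destroying the cross-lag structure of
one member of a pair in every pooled subject (able-bodied plus stroke,
n = 26), recomputing both directed flows per subject, pooling all draws,
and taking the empirical $1-\alpha$ quantile ($\alpha = 0.01$).

The permutation scheme matters enormously on band-limited data. An
unrestricted shuffle of time indices whitens the permuted member; because
the flow estimator's finite-sample bias grows with the autocorrelation of
its inputs, the shuffled null sits far below the sampling distribution of
the flow on real (band-limited) null data — we measure a type-I error of
roughly 0.66 at a nominal 0.01. The package therefore defaults to a
*cyclic* permutation: a random rotation of the time axis by 10 to T−10
samples. This is still a permutation of time indices — amplitudes are
preserved exactly — but it also preserves the member's autocorrelation, and
the resulting threshold is calibrated (measured type-I error ≈ 0.005–0.01
at $\alpha = 0.01$ across hundreds of replicate null cohorts). The
unrestricted variant remains available (`scheme = "full"`) for comparison.

A consequence of calibration is honesty about power: at 130–237 volumes of
band-passed data, the subject-level null flow has a 99th percentile of
roughly 0.3–0.5, which exceeds the group-mean flow that any stationary
coupling of this network can produce (the strongest coupling compatible
with stationarity, 0.35 on seven edges with 0.35 self-terms, leaves the
companion spectral radius at 0.92 and yields asymptotic in-band pair flows
below 0.25). Single-connection detection against a calibrated
subject-level threshold is therefore essentially impossible at these
session lengths; only group-level contrasts carry usable signal. The
anti-conservative shuffle scheme *would* flag connections — at the price of
a meaningless false-positive rate. We consider the calibrated default the
defensible choice and report both behaviours in the test suite.

## Group contrasts and session-length bias

The able-bodied sessions have 237 volumes and the stroke sessions 130. The
flow estimator's bias depends on session length, so raw network sums are
confounded: the shorter stroke sessions carry *more* bias, enough to mask
or invert true group differences. For the network-level t tests the
pipeline therefore subtracts a per-subject, per-connection surrogate bias —
the mean flow over cyclic rotations of the same data
(`igc_surrogate_bias()`, 20 draws by default) — yielding an
`igc_corrected` column whose null expectation is near zero at any session
length. Raw iGC is retained everywhere else (thresholds, reports, ΔGC),
and pre/post ΔGC differences are computed between equal-length sessions
where the bias cancels by itself.

## The synthetic generator

`motor_network_spec()` encodes the five-node network with the seven
directed couplings reported significant in able-bodied participants
(LM1↔SMA, RPMC↔SMA, RPMC→LM1, SMA→RM1, SMA→LPMC), all at lag 1 with
coefficient 0.35, self-regression 0.35, identity innovation covariance, and
TR 2 s. Group scenarios scale the couplings: able-bodied 1.0 (13 subjects,
237 volumes), stroke 0.2 (13 subjects, 130 volumes), mental practice 0.3
(6 subjects), combined therapy 0.8 (7 subjects). Innovations are
band-shaped by the same zero-phase Butterworth design used in
preprocessing, with corners at `band_center_hz` ± 0.025 Hz
([0.045, 0.095] at the 0.07 Hz default) and rescaled to their pre-filter
standard deviation. The half-width is the widest for which the group-mean
SMA power peak lands inside 0.06–0.08 Hz in every replicate cohort we
simulated (the AR self-terms tilt power toward lower frequencies, so
shaping with the full analysis band pushes peaks below 0.06 Hz); narrower
shaping wastes effective sample and degrades flow estimation.

Synthetic behavior scores are
$\Delta\mathrm{FMA}_i = 2 + 25\,\Delta\mathrm{iGC}_i + \varepsilon_i$,
$\varepsilon \sim N(0, 3^2)$, rounded half-away-from-zero to integers;
slope and noise were chosen once to put synthetic scores on the integer
scale of the printed clinical table. Motion traces are smooth drifts
bounded strictly below 60% of the exclusion limits, with designated
violators spiking one axis beyond 2 mm / 1.5° on one volume.

What the generator does *not* emulate: hemodynamic convolution and its
regional variability, measurement noise outside the analysis band,
inter-subject coupling heterogeneity, and lesion geometry. Passing tests
on this generator show the estimator chain is correct for data that obey
the VAR model class it assumes — not that the scientific conclusions would
replicate on scanner data.

## Preprocessing

Sphere ROIs are closed balls in millimetre world space around published
MNI centers (6 mm radius), voxels included by center distance through the
image affine (0-based indices); extraction is the unweighted voxel mean.
Filtering is a least-squares linear detrend followed by a 4th-order
Butterworth band-pass applied forward and backward (zero phase — a causal
filter would add a frequency-dependent delay and corrupt directed-lag
structure), with odd-reflection padding of three filter lengths. Motion
exclusion reads "more than 2 mm / more than 1.5°" strictly: boundary
values are kept, displacements are taken relative to the first volume, and
rotations are assumed to arrive in degrees.

## Numerical choices and degenerate inputs

Tiny negative directed measures (within $10^{-8}$ of zero) are rounding
artefacts and are clamped to zero, counted per fit. Fitted models with
companion radius ≥ 1 warn rather than fail — mildly explosive fits are
routine at these session lengths and their spectra remain computable.
Near-singular spectral matrices (coherence → 1) and singular lag
regressors raise errors naming the frequency or suggesting a lower order.
Degenerate statistics (zero-variance inputs) either warn and return the
conventional $t = 0, p = 1$ (all-zero difference scores) or error (zero
variance with unequal means; constant correlation inputs). Peak frequency
breaks ties toward the lower frequency.

## Problem sizes used in the checks

The test-suite and acceptance-script Monte-Carlo blocks run at the study's
subject counts and session lengths (26-subject pools, 13 + 13 group
comparisons, 130/237 volumes), with 100–200 replicate cohorts for
calibration and ordering rates, 1000–2000 permutation draws per threshold,
and long runs (T = 10 000–50 000) for asymptotic oracles.

## Known limitations

Bivariate (not conditional) causality: indirect paths and common drivers
produce real bivariate flow between unconnected regions, which is visible
in the simulated network. Band-passed short sessions fundamentally limit
subject-level inference, as quantified above. The clinical tables ship as
printed; their analyses are reproductions, not new inference.
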