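---
title: "Models and methods behind choicekernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind choicekernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and what the package computes

`choicekernels` analyzes a two-alternative contrast-discrimination task: on
each trial an observer watches a drifting circular grating whose contrast is
refreshed every 100 ms for ten "samples", and reports whether the mean
contrast was stronger or weaker than a fixed 50% reference, together with a
binary confidence judgment. The decision-relevant quantity is the running
mean of the contrast samples, so the task probes temporal evidence
accumulation. The analyses quantify (i) how strongly each sample sways the
choice (psychophysical kernels), (ii) where and in which frequency bands
cortical population signals carry the stimulus, the accumulated evidence,
and the upcoming choice (spectral decoding and encoding models), (iii) how
much choice-predictive activity remains after the stimulus fluctuations are
regressed out (residual neural kernels), and (iv) whether choice signals in
motor cortex temporally lead the endogenous low-frequency choice signal in
visual cortex (lagged cross-correlation with a leakage reference).

Because the real magnetoencephalographic source data are large and
external, every stage is exercised against a synthetic-data generator that
reproduces the statistical structure the analyses assume. The generator is
first-class, tested code: its parameters define the study conditions for
all acceptance checks.

## Stimulus model

A pixel at eccentricity $d$ (degrees) has blending value
$a = \tfrac12 + \tfrac12 \sin\!\big(\pi (d - s) / (2r)\big)$ with
$r = 0.75^\circ$, and intensity $l = a(0.5 - c/2) + (1-a)(0.5 + c/2)$ for
Michelson contrast $c$; the spatial period is $4r = 3^\circ$. Advancing the
phase $s$ at $4/3\,^\circ\!/\mathrm{s}$ drifts the rings outward or inward.
An inner annulus of 1.5° is uniform mid-gray and the grating is truncated
at 11.3°. With this form the intensity extremes $0.5 \pm c/2$ are attained
in the grating region, so the rendered Michelson contrast equals the
requested one (to better than $10^{-9}$ on grids of $512^2$ pixels or
finer, limited only by how closely a pixel eccentricity approaches the
sine extrema). Frames are rendered only for verification; the analysis
itself never consumes pixels.

## Staircase and observer

A QUEST staircase holds accuracy at 75%: a posterior over the log10
contrast-offset threshold of an assumed Weibull psychometric function
(slope 3.5, guess rate 0.5, lapse 0.02, grid $[-3, -0.3]$ with a Gaussian
prior) is updated by Bayes rule after every trial, and the next trial is
placed at the posterior-mean threshold shifted to the 75%-correct point of
the assumed function (mean placement rule). The grid range, slope and
prior are package choices; only the target accuracy and the use of QUEST
are fixed by the task design.

The synthetic observer is a noisy weighted accumulator:
$\mathrm{DV} = \sum_{i=1}^{10} w_i (c_i - 0.5) + \eta$,
$\eta \sim \mathcal N(0, \sigma)$, choosing "stronger" iff
$\mathrm{DV} > 0$ (flipped with a 2% lapse), reporting high confidence iff
$|\mathrm{DV}|$ exceeds a criterion. The default weights decay as
$w_i \propto e^{-0.15 (i-1)}$, which reproduces the primacy signature:
kernel amplitudes fall over sample position and the group-mean kernel
slope is negative (about $-0.008$ AUC per position under the defaults,
matching the scale of the reported behavioral effect). Reaction times are
drawn from a shifted lognormal (shift 0.8 s, meanlog $-0.28$, sdlog 0.35)
placing ~5% of the mass below the 1.225 s exclusion threshold so the
fast-RT filter is exercised. Sample contrasts are drawn
$\mathcal N(0.5 \pm \delta, \mathrm{sd})$ with the noise level drawn per
trial from $\{0.05, 0.1, 0.15\}$ and per-sample rejection resampling into
$[0,1]$ (resampling preserves the nominal mean better than clipping).

## Synthetic ROI power

The generator emits trial × ROI × hemisphere × frequency × time power on
the epoch $[-0.25, 1.35]$ s at 1/60 s steps, with frequency bins 1–9 Hz
(step 1) and 10–150 Hz (step 5) or any requested subset. Its structure:

* **Visual gamma (40–75 Hz)**: power is baseline × (1 + offset +
  gain · $c_i e^{-\alpha_{\mathrm{sd}}(i-1)}$) convolved with a
  gamma-shaped impulse response peaking 190 ms after sample onset. The
  adaptation constant $\alpha_{\mathrm{sd}}$ grows with the within-trial
  contrast SD. The impulse response uses shape 20 (FWHM ≈ 130 ms): a
  temporally focal response keeps each sample's 190 ms extraction bin
  dominated by its own contrast, which is what makes residualizing on the
  same sample's contrast null the stimulus-driven kernel — a broad
  response would smear neighboring samples into the bin and leave
  choice-predictive stimulus information the per-sample regression cannot
  remove.
* **Visual low frequency (≤ 20 Hz)**: adds an endogenous choice signal
  $g_\alpha \cdot \mathrm{DV}/\mathrm{sd}(\mathrm{DV}) \cdot
  b(t - \Delta)$, with $\Delta = 150$ ms by default.
* **Motor ROIs (M1, IPS/PostCeS)**: hemisphere-lateralized build-up
  $g_m \cdot \mathrm{DV}/\mathrm{sd}(\mathrm{DV}) \cdot b(t)$, positive in
  the hemisphere contralateral to the hand reporting "stronger".
* $b(t)$ is a normalized piecewise-linear build-up: 0 before 0.4 s, to
  0.8 at 0.6 s, to 1 at 1.15 s. Noise is multiplicative lognormal
  (sdlog 0.15) and the pre-stimulus interval carries baseline plus noise
  only.

Two generator decisions deserve emphasis. First, the visual feedback
signal is *graded* (proportional to the decision variable) rather than a
binary function of the reported choice. Both downstream claims survive
either way, but lag identifiability does not: the cross-correlation
procedure compares a motor decoding-AUC time course with a visual kernel
time course, and each is a saturating monotone transform of the underlying
build-up. If the two channels carry different per-trial signals the two
transforms differ, and the Pearson-correlation peak is systematically
displaced from the injected lag (we measured 2–3 time bins of bias).
Sharing the graded signal — with gains calibrated so both curves span a
similar AUC range (~0.5–0.8, the magnitude range reported for real
data) — makes both curves the same function of $b$, and the peak sits at
the true lag. Second, the two-segment build-up gives the curves an
interior knee; a single linear ramp is nearly featureless under
correlation and leaves the peak poorly identified.

What the generator does **not** emulate: oscillatory phase, 1/f spectral
slopes beyond a static baseline profile, cross-frequency coupling, trial
history effects, head-movement or sensor artifacts, and source-leakage
mixing between ROIs (leakage handling is exercised on constructed
fixtures instead). Passing tests therefore validate the estimators'
logic and calibration, not their robustness to those real-data features.

## Behavioral statistics

Kernels use the ROC-AUC with ties counted half, computed separately
within each stimulus category — AUC(hit vs miss) and AUC(false alarm vs
correct reject) — and averaged, so stimulus-category differences cannot
masquerade as choice information. Missing cells propagate as missing.
Choice and confidence models are logistic regressions on the ten sample
contrasts with stratified 5-fold cross-validation (stratified on the
predicted variable); perfect separation falls back to a tiny L2 penalty
($10^{-6}$ on standardized predictors), deterministic and negligibly
biased. Because accuracy is titrated to 75%, the cross-validated accuracy
of the choice model is itself bounded near 75%. A reaction time exactly at
1.225 s is kept ("faster than" read strictly).

## Spectral estimation

Multitaper spectrograms use DPSS tapers computed from the tridiagonal
concentration eigenproblem, with 0.25 s windows and ±4 Hz smoothing below
10 Hz and 0.1 s windows with ±10 Hz smoothing above, at arbitrary center
frequencies via direct DFT; the taper count is $\max(1, 2TW - 1)$ from the
window × half-bandwidth product. Baselines are condition-independent:
mean raw power over all trials in $[-0.25, 0)$ s, per frequency and
ROI/hemisphere, converted to percent change. Lateralization is
contra-minus-ipsilateral relative to the hand reporting "stronger" and is
exactly antisymmetric under hemisphere swap. Band summaries use the
nearest time bin (ties toward the earlier bin); gamma collapses center
frequencies 50–65 Hz, the low-frequency band is the 10 Hz center (0–20 Hz
effective). The TFR path is optional in the pipeline — the generator can
emit band power directly — and is validated on synthetic narrow-band
series against an explicit tapered-DFT oracle.

## Decoding and encoding

Choice decoding per time bin uses linear SVMs (C = 1) on the 1–145 Hz
power pattern from both hemispheres, separate decoders per stimulus
category, features z-scored on training folds only, minority-choice
upsampling by random repetition in the training folds, 10-fold
cross-validation stratified on choice, and AUC computed from decision
values (class predictions would discard the ranking the AUC needs). The
fine-grained variant z-scores, retains principal components to 95%
cumulative variance, selects features with an L1-penalized linear
classifier at the C = 10/p scale, prunes weights below $10^{-5}$, and
refits an L2 SVM (C = 1/2); every reduction is fitted on training data
only. Contrast and accumulated-contrast (running-mean) decoding use ridge
regression with the penalty chosen from $\{0.1, 1, 10\}$ by nested 3-fold
cross-validation, scored as the Pearson correlation between held-out
predictions and targets. The ridge solve is the closed normal-equation
form so the stated penalty grid applies to the standard
$\alpha\lVert\beta\rVert^2$ objective exactly. The "convex hull" summary
of per-sample decoding curves is implemented as their pointwise upper
envelope. Encoding regressions standardize power and contrast, so the
slope equals the Pearson correlation. Leakage removal regresses the
target region's power on the source region's per frequency and keeps the
residuals (exactly orthogonal to the source in-sample).

## Kernels and lagged coupling

Neural-activity kernels substitute band power at 190 ms after each sample
onset for the sample contrast in the kernel computation; the residual
variant first regresses power on the same sample's contrast (per sample
position — a pooled variant is available but off by default). The
interaction choice model averages low-frequency and gamma power over
sample halves 1–5 and 6–10, z-scores, and fits
choice ~ α₁ + α₂ + γ₁ + γ₂ + α₁γ₁ + α₂γ₂; temporal asymmetries are
second-half minus first-half coefficients. The cross-correlation evaluates
the Pearson correlation between the M1 choice-decoding AUC on
$[0, 0.8]$ s and the visual low-frequency kernel shifted by lags in
$[-0.215, 0.215]$ s (positive = M1 leads), truncating — never padding —
lags that exceed the kernel support; the group peak lag is the argmax of
the subject-averaged correlation (not the mean of per-subject argmaxes,
which is noisier and biased toward the grid edges). The zero-lag
correlation between the M1 decoder and the M1 low-frequency kernel bounds
what source leakage alone could produce and is the reference for paired
comparisons.

## Group statistics

Subject AUCs at each time bin are modeled as
$\mathrm{auc}_{s,t} \sim \mathrm{StudentT}(\mu_t, \sigma_t, \gamma)$ with
$\mu_t \sim \mathcal N(0.5, 1)$, $\sigma_t \sim \mathrm U(0, 5)$,
$\gamma \sim \mathrm{Exp}(\text{mean } 29) + 1$, sampled with two MCMC
chains of 3000 iterations and gated on split-$\hat R < 1.05$ for every
parameter. Cluster inference uses threshold-free cluster enhancement
($H = 2$, $E = 0.5$, integration step $\max|t|/100$; 2-neighborhood on
time series, 4-neighborhood on time × frequency maps) with sign-flip
permutations of subject maps and the map-wise maximum statistic, two
sided. FDR control is Benjamini–Hochberg. One-sample/paired t-tests and
one-way ANOVA are thin wrappers around the standard routines.

## Problem sizes, tolerances and reproducibility

All randomness flows through one master seed with named substreams per
module, so identical configurations reproduce byte-identical tables. The
test suite sizes its simulations for a desktop run: staircase convergence
uses 3,000 trials; the null-kernel check 15 × 2,000 trials; the
feedback-lag recovery 20 cohorts of 15 subjects × 200 trials with the M1
decoding grid at 1/15 s (the lag grid keeps 1/60 s resolution from the
kernel axis); the family-wise-error simulation 400 null datasets × 250
permutations; Bayesian recovery 30 replicated cohorts. Monte-Carlo
tolerances are set from binomial or AUC standard errors at those sizes
(e.g. ±0.02 on staircase accuracy, ±0.01 on null-kernel group means,
±0.003 on the within-trial contrast SD, one 1/60 s bin on the recovered
feedback lag).

Known limitations: the generator's band-power shortcut bypasses phase;
the fine-grained decoder is exercised on synthetic feature matrices
rather than vertex grids; the cross-correlation's identifiability
analysis above shows the procedure is only unbiased when the motor and
visual choice signals share their temporal transform — with real data
this is an empirical assumption, not a guarantee; and the hierarchical
model ignores the boundedness of AUC values (adequate while values stay
far from 0 and 1, as here).
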