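---
title: "Noise modeling, artifact removal and FGLS inference for fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise modeling, artifact removal and FGLS inference for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsgls)
```

## The statistical problem

A functional near-infrared spectroscopy (fNIRS) channel records
concentration changes of oxy- and deoxyhemoglobin at ~10 Hz. Three noise
structures dominate and each, untreated, invalidates GLM inference:

1. **Power-law background.** The resting spectrum follows
   $S(f) \propto f^{\lambda}$ with $\lambda \approx -2$, i.e. strong
   positive serial correlation at low frequencies. Ordinary least squares
   remains unbiased in $\hat\beta$ but badly underestimates its variance,
   inflating $t$ and $F$ statistics.
2. **Quasi-periodic systemic physiology.** Cardiac pulsation (0.6–2 Hz in
   adults), respiration (0.15–0.4 Hz) and blood-pressure (Mayer) waves
   (0.05–0.2 Hz) put narrow-band excess power on top of the power law,
   which both masks responses and corrupts the spectral-slope estimate
   the noise model needs.
3. **Motion artifacts.** Optode decoupling produces *ripples* (smooth
   excursions lasting seconds) and *spikes* (3–4 samples), one to two
   orders of magnitude above the hemodynamic signal. They are local
   events; global filtering would both fail to remove them and destroy
   the temporal structure that makes fNIRS attractive.

The package addresses them in pipeline order — systemic cardiac removal,
motion correction, slower systemic bands, then feasible generalized least
squares (FGLS) inference — and ships Monte Carlo experiments verifying
that null p-values come out uniform.

## Systemic artifact removal by time-warped templates

For each band, high to low frequency:

1. Channels are averaged after discarding high-variance channels
   (variance z-score ≥ 1). Systemic artifacts are globally synchronous,
   so averaging enhances them while spontaneous hemodynamics average
   out. For the slow bands the band-passed channels are averaged instead
   of the raw ones, because slow task-locked modulations would otherwise
   dominate the average.
2. The average is band-passed (zero-phase 4th-order Butterworth) and
   local minima/maxima are marked by derivative sign changes. Alternation
   is enforced by keeping the larger-magnitude of two same-type extrema.
3. Per channel, the segments between events are split into rising
   (minimum→maximum) and falling phases, each linearly resampled to the
   rounded mean phase length (endpoints map to endpoints) and averaged:
   the time-warped signature waveform. The falling mean gets a linear
   ramp so the cycle closes, and the cycle is centered so that the
   estimate is DC-neutral — averaged raw segments otherwise inherit a
   spurious baseline from the slow $1/f$ wander of the channel, and
   subtracting it would shift the channel's level.
4. The template is stretched/contracted to each inter-event interval and
   subtracted; outside the first/last event nothing is subtracted.
5. A residual pass subtracts the event-triggered average around detected
   maxima (window = minimal event spacing, the unbiased choice). The
   warped template is slightly biased inside the event window but not
   outside it; event-triggered averaging is unbiased inside the window;
   their combination avoids both biases.

Detection happens once (on the average); template building and
subtraction are per channel, since artifact amplitude is channel
specific. For deoxyhemoglobin, whose cardiac trace is weak, events can be
detected on the corresponding oxy recording (`detection_source`).

Two properties of this design deserve flagging. Template amplitude is
*not* rescaled per event; the residual pass absorbs systematic amplitude
error, but incoherent cycle-to-cycle waveform variability (a cardiac
cycle is only ~10 samples at 10 Hz, with ~5% period jitter) cannot be
represented by any fixed template. One pass removes roughly 95% of
in-band artifact power; a second pass changes the series by about 15% of
the first pass's change — that contraction factor, not something
smaller, is the method's intrinsic convergence rate. Second, applied to a
*single* channel of pure noise the procedure is mildly destructive: with
no cross-channel averaging the detection series is the channel's own
band-passed noise, and the template coherently strips in-band noise
power (measured type-I error 0.55 downstream). With realistic channel
counts (the method's operating regime; validation here uses 6–8
channels) detection decorrelates from any single channel and inference
stays calibrated (KS p ≈ 0.98, type-I 0.053).

## Motion correction

Detection runs on a standardized copy (zero-phase Butterworth high-pass
at 0.01 Hz, then z-scoring) so thresholds are in SD units; corrections
are applied to the *original* series over detected supports only. Every
untouched sample is bitwise unchanged.

**Ripples.** Runs of ≥ 10 samples beyond ±4 SD mark an excursion; its
apex is the absolute maximum within the run. On each side of the apex a
~10 s window is searched for the global opposite extremum, extended 10
samples past it, and segmented into three pieces by piecewise-linear
segmentation; the onset is the end of the first left segment, the offset
the end of the second right segment. A 3rd-degree polynomial is fitted
separately to the rising and falling phase of the original series and
subtracted (the apex sample is handled once). Subtracting a smooth cubic
removes the excursion while preserving high-frequency content and hence
the power-law spectral structure. Overlapping supports are merged before
correction.

The segmentation runs two greedy passes — top-down recursive splitting at
the SSE-minimizing point, and bottom-up merging from atomic segments —
and polishes both (plus a few systematic restarts, including
adjacent-pair starts at the largest jumps) with exhaustive
per-breakpoint coordinate descent, keeping the best local optimum. On
windows up to ~60 samples this lands within a few percent of the
exhaustive optimum (verified against a brute-force oracle in the tests).

**Spikes.** Inflection magnitudes between successive local extrema are
z-scored; consecutive opposite inflections both above 2.5 SD mark a
spike, and consecutive hits are merged into a single implicated stretch
bounded by clean flanking extrema, which is linearly interpolated.
Stretches wider than 8 samples are by definition not spikes (3–4 points
at 10 Hz) and are left to the ripple path. The ordering
cardiac → motion → slower bands is deliberate: pulsations clutter the
piecewise-linear simplification the ripple detector relies on.

## FGLS inference

Designs are built for block paradigms under two bases: the canonical
double-gamma HRF (response peaking at 6 s, undershoot at 16 s,
peak:undershoot 6:1, 32 s span, unit peak) convolved with the stimulus,
or a finite-impulse-response basis spanning 20 s — 200 lag regressors at
10 Hz, 67 after temporal binning by 3 (binning block-averages
consecutive samples; the trailing partial bin is averaged as-is).

Four schemes are available in `fgls_fit()`:

* **ols** — reference only; badly miscalibrated under power-law noise.
* **precolor** — zero-phase 4th-order Butterworth high-pass (default
  cutoff 0.017 Hz) applied identically to the response and all design
  columns except the intercept. On its own this is *not* sufficient:
  measured type-I error at nominal 0.05 is ≈ 0.86 on $\lambda = -2$
  noise.
* **whiten** — OLS residuals → raw periodogram (no taper) → OLS
  regression of $\log S(f)$ on $\log f$ over positive frequencies
  (DC and Nyquist excluded) → both sides multiplied in the frequency
  domain by $S_{\text{model}}(f)^{-1/2}$ → re-fit.
* **combined** — precolor first; the exponent is fitted only above the
  cutoff; the model spectrum is multiplied by the squared amplitude
  response of the precoloring operator; whitening proceeds with the
  modified spectrum. This is the default inferential scheme.

Numerical choices: all filters are implemented spectrally from the
analytic Butterworth zero-phase magnitude response
$(1+(f/f_c)^{2\cdot4})^{-1}$ — exact, stable at very low cutoffs, and it
makes the combined scheme self-consistent. Precoloring is applied
circularly on the n-point grid so the whitener can invert the filter
response exactly bin-by-bin (with reflection-padded filtering the
stop-band re-amplification of the tiny response mismatch destroys
calibration); detection filters use even-reflection padding instead,
where edge wrap matters and exact invertibility does not. The model
spectrum's DC bin is set to the first positive-frequency value and the
spectrum floored at $10^{-8}$ of its maximum, so the implied circulant
covariance is positive definite. Because that covariance (the Toeplitz
matrix of the ACF obtained by inverse-transforming the model spectrum)
is exactly diagonalized by the DFT, spectral whitening and dense textbook
GLS $(X'V^{-1}X)^{-1}X'V^{-1}y$ agree to machine precision; the dense
path is kept as a validation oracle for moderate $n$. Degrees of freedom
are the naive $n - p$ after whitening (whitening treated as exact; no
Satterthwaite correction) — a known limitation, adequate at these $n$.
Inference is a two-sided $t$ on the task contrast (HRF basis) or an $F$
on all lag columns jointly (FIR basis).

## Synthetic data

`simulate_colored_noise()` draws independent complex-Gaussian Fourier
coefficients with standard deviation $\propto f^{\lambda/2}$ on the
half-spectrum (phases uniform by construction), symmetrizes and
inverse-transforms: stationary Gaussian noise whose expected spectrum
follows the requested power law, standardized to zero mean and unit
variance. We deliberately draw the coefficient *amplitudes* randomly
rather than fixing them at $f^{\lambda/2}$: with deterministic
amplitudes every realization has the same total power in every band, the
residual sum of squares loses its $\chi^2$ fluctuation, and null $F$
statistics concentrate — measured type-I error drops to ≈ 0.02 and the
p-value histogram visibly bows. Gaussian amplitudes restore the
textbook null (type-I 0.047–0.060, KS p > 0.8), which is the regime the
calibration claims are about.

Block designs default to the 15 s on / 30 s off paradigm (10 repetitions
→ 4500 samples at 10 Hz); task series are HRF convolutions scaled to a
target squared-RMS signal-to-noise ratio. The systemic-artifact
simulacrum concatenates stereotyped cycles (sinusoidal, or a fast-rise/
slow-decay pulse) with uniform cycle-period jitter (default ±10%,
spanning physiological heart-rate variability); the motion simulacra are
a smooth asymmetric ripple (default peak 30 noise SDs, 5 s — between one
and two orders of magnitude above the noise) and an alternating-sign
spike over a few samples. What the generator does *not* emulate:
heteroscedasticity, non-stationary artifact statistics, channel-to-channel
correlated hemodynamics, or low-frequency deviations from the power law
seen in real recordings. Tests passing on this synthetic family
demonstrate internal validity of the algorithms under their assumed noise
model, not performance on arbitrary real data. One consequence is
documented in the package's validation: on *exactly* power-law noise,
whitening alone is already optimal, so the real-data advantage of the
combined scheme over whiten-only (which arises from low-frequency model
misspecification that precoloring suppresses) does not reproduce —
whiten-only and combined tie statistically there, while both clearly beat
precoloring alone and match the white-noise OLS baseline within 1.5x on
residual-ACF outliers.

## Problem sizes and reproducibility

All validation experiments are pure functions of their settings and
seed. The test suite uses desk-scale versions of the experiments:
1000-replicate null calibrations at $n = 2048$ (the original experiments
used 10000 at $n = 4500$), 200-replicate motion recovery at $n = 4500$,
150 8-channel denoising simulations, and 100-window segmentation oracle
comparisons. `scripts/acceptance.R` recomputes the two headline numbers
(mean recovered spectral exponent; mean post-correction correlation)
from scratch at full length.

```{r example, eval = FALSE}
# a typical end-to-end run on synthetic data
art <- simulate_periodic_artifact(4500, 10, base_freq = 1.1,
                                  waveform_shape = "pulse", amplitude = 2,
                                  seed = 2)
rec <- synthetic_recording(4500, n_chan = 8, fs = 10, exponent = -2,
                           artifact = art, seed = 1)
den <- remove_systemic(rec)                       # cardiac, resp., BP
den2 <- remove_motion(den$recording)              # ripples + spikes
stim <- block_stimulus(15, 30, 10, fs = 10)
fit_recording(den2$recording, stim, basis = "hrf", scheme = "combined")
```

## Known limitations

* On strictly power-law noise the exponent fit is extremely sensitive to
  high-frequency artifact residue: the $f^{-2}$ floor at 2–5 Hz is
  orders of magnitude below any leftover harmonic of an imperfectly
  removed artifact, so the fitted slope flattens and whitening
  under-models low-frequency variance. Real recordings carry a white
  measurement-noise floor that buries such residues. When fitting
  artifact-cleaned data in a regime without such a floor, restrict the
  fit with `fit_range`/`exclude_bands`.
* Naive residual degrees of freedom after whitening.
* The spike pass assumes ≥ ~5 Hz sampling; at 1 Hz a "spike" is not
  resolvable.
* Systemic removal needs several channels to be harmless on pure noise;
  single-channel recordings pay an in-band noise penalty.
* Group inference uses a one-step method-of-moments between-subject
  variance with a non-negativity floor, not full ML; with equal
  first-level variances it reduces to the summary-statistic t-test.
* The age presets for children/toddlers shift the cardiac and
  respiratory bands to physiologically typical rates; they are
  configuration defaults, not fitted values.
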