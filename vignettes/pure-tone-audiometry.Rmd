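---
title: "Pure-tone audiometry by adaptive staircase: model, calibration and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pure-tone audiometry by adaptive staircase: model, calibration and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puretone)
```

## The measurement problem

Air-conduction pure-tone audiometry estimates, for each ear and each octave
frequency from 250 Hz to 8 kHz, the lowest hearing level (dB HL) at which a
listener reliably detects a tone. A smartphone-earphone combination can run
this test outside the clinic, but only if two things hold: the adaptive
threshold search behaves like the clinical procedure, and the device's output
is calibrated — i.e. the app knows what physical sound pressure level (dB SPL)
its digital amplitudes produce. `puretone` implements both halves and a
virtual-listener simulator that closes the loop, so the entire
test → calibrate → evaluate cycle runs on the desk with no subjects or
hardware.

## Units and the calibration identity

Hearing level is sound pressure level re-referenced to the normal-hearing
threshold of a specific transducer at each frequency:

$$\mathrm{dB\,SPL} = \mathrm{dB\,HL} + \mathrm{RETSPL}(f).$$

The RETSPL (reference equivalent threshold sound pressure level) table *is*
the calibration of a transducer. Three profiles ship with the package: the
ANSI S3.6-2010 values for the ER-3A insert earphone used by the reference
audiometer, the initial estimate used by the uncalibrated app build
(`"HearTest v1"`, borrowed from Apple EarPods measurements) and the
subjectively calibrated build (`"HearTest v2"`). `hl_to_spl()` and
`spl_to_hl()` apply the identity and are exact inverses; levels are carried as
reals throughout because calibration produces values like 7.3 dB SPL —
quantization to the clinical 5 dB grid happens only inside the staircase.

```{r}
retspl_at(packaged_retspl("ER-3A"), 250)
as.numeric(hl_to_spl(30, 2000, packaged_retspl("HearTest v2")))
```

## The staircase

The threshold search is the modified Hughson-Westlake procedure: start at
30 dB HL; while the listener does not respond, ascend in 10 dB steps; after
each response descend 10 dB; after each miss in the main phase ascend 5 dB.
Every change of direction is a *reversal*, and the first level heard on an
ascending run once three reversals have accrued is taken as the threshold.

Two conventions in this rule are genuinely open and we fixed them as follows:

* **What counts as a reversal.** The turn from the initial ascent into the
  first descent is reversal 1; thereafter each heard-while-ascending and each
  missed-while-descending adds one. The completion check uses the count
  *before* the final heard response — "heard first *after* three reversals".
  Under this convention a deterministic listener with threshold 40 produces
  the eight-presentation track 30, 40, 30, 35, 40, 30, 35, 40, and every
  deterministic threshold on the 5 dB grid is recovered exactly (a
  brute-force property test enumerates all of them at all six frequencies).
* **Boundary behaviour.** The testable range is −10 to 80 dB HL, except
  75 dB HL at 250 Hz where the device output maximum is lower. A miss at the
  ceiling terminates with a `NO_RESPONSE` sentinel rather than a fabricated
  number. At the floor, a response during a descending run counts as the
  turnaround, so a listener who hears everything completes at −10 dB HL after
  the usual ascending confirmations.

A hard cap of 50 presentations per track (a safety net, not part of the
clinical rule) guarantees termination for adversarial responders.

## The virtual listener

Simulated subjects carry per-ear, per-frequency true thresholds and respond
through a psychometric function
$$P(\text{heard}\mid L) = \gamma + (1-\gamma-\lambda)\,
F\!\left(\frac{L - \theta}{s}\right),$$
with $F$ the standard logistic, $\theta$ the true threshold, $s$ the logistic
scale in dB, $\gamma$ the guess rate and $\lambda$ the lapse rate (the
"unsure → I can't hear it" instruction makes lapses, not guesses, the
dominant human error). A deterministic step model ($P = \mathbf{1}[L \ge
\theta]$) is used wherever exactness matters.

Defaults: $s = 0.5$ dB (a steepness of 2 per dB), $\gamma = \lambda = 0.01$.
The scale value deserves a note. Written as a spread, 0.5 dB is steep — an
attentive listener in a booth — and it is the regime in which a 5 dB-grid
staircase is informative: with it, ≥ 95 % of recovered thresholds land within
±5 dB of truth while the guess/lapse channels still exercise every stochastic
code path. A listener with a 2 dB scale (shallower than most published
normal-hearing slopes at these frequencies) pushes single-response staircase
estimates beyond the ±5 dB band in roughly a fifth of tracks; that regime is
available via the `slope` argument but is not the reference condition.

Cohorts draw thresholds independently per ear and frequency from per-frequency
normal distributions (default mean 10, SD 5 dB HL — self-identified normal
hearing), quantized to 1 dB and clamped to [−10, 120]. Real audiograms are
correlated across frequencies and ears; nothing in the procedure under test
depends on that correlation, so independence is the simpler honest choice.
That is also the main caveat on what passing simulations show: they validate
the *procedure and arithmetic*, not human factors (attention drift, earphone
placement, ambient masking of low frequencies), which only subject testing
can.

## Calibration by median difference

A device whose assumed RETSPL is wrong by $\Delta(f)$ plays every tone
$\Delta(f)$ dB off its label and therefore mis-measures every threshold by the
same amount. Given paired thresholds from a reference audiometer and the
device over a cohort of ears, the per-frequency median of
(audiometer − device) estimates $-\Delta(f)$; the corrected table is

$$\mathrm{RETSPL}_{new}(f) = \mathrm{RETSPL}_{old}(f) -
\operatorname{median}_f(\mathrm{HL}_{aud} - \mathrm{HL}_{dev}).$$

The median is used instead of the mean because threshold differences are
non-normal and outlier-prone; with an even ear count it is the midpoint of
the central pair, which is how corrected tables acquire non-grid entries.
`calibrate_retspl()` packages the estimator as a model fit: `coef()` returns
the per-frequency medians, `predict()` applies the correction to
device-measured thresholds, `residuals()` gives the post-correction
disagreement, and `summary()` reports Spearman's rank correlation (with
average-rank ties; exact permutation p below 10 pairs, the large-sample t
approximation otherwise) and per-frequency mean absolute error before and
after.

```{r}
cohort <- sample_cohort(cohort_spec(20, mean_dbhl = 10, sd_dbhl = 8, seed = 42))
delta <- setNames(c(-15, -10, -4, 0, 7, 15), test_frequencies())
pm <- simulate_paired_measurements(cohort, delta)
fit <- calibrate_retspl(pm, packaged_retspl("HearTest v1"))
round(coef(fit), 1)
```

Because staircase output is quantized to 5 dB, the median difference can sit
up to 2.5 dB from $-\Delta$; the recovery property tested is therefore
"within 2.5 dB at every frequency, with post-correction MAE never above
pre-correction MAE". The simulated problem size mirrors the calibration
study design: 20 listeners, 40 ears.

## Masking and level limits

Air-conducted sound crosses to the opposite cochlea, mainly by bone
conduction, losing at least the interaural attenuation (IA); the conservative
clinical IA for air conduction is 40 dB. A presentation at $L$ dB SPL
therefore needs narrow-band noise of at least $L - \mathrm{IA}$ dB SPL in the
non-test ear; `masking_level()` implements exactly this, returning `NULL`
when the margin is non-positive. Masking noise is one-third-octave
band-limited Gaussian noise (the clinical convention; the band edges are
$f_c \cdot 2^{\pm 1/6}$), realized by FFT brick-wall filtering and scaled so
its RMS matches the requested SPL. Masking is computed and reported by the
session engine but applied only when enabled, matching a normal-hearing
testing scope.

## Signal synthesis and metering

Tones are continuous sinusoids with 20 ms raised-cosine onset/offset ramps
(long enough to avoid spectral splatter, short enough not to disturb the
"continuous tone" presentation). Amplitude comes from the device profile:
the packaged table gives, per device and channel, the SPL of a full-scale
sine measured with a 2-cc coupler, so a target of $T$ dB SPL needs fraction
$10^{(T - \max)/20}$ of full scale. Requests above the maximum raise an
error — this is precisely what caps the testable range at 80 dB HL
(75 at 250 Hz).

Two meters are provided because two references are in use: `measure_spl()`
is a plain RMS meter against a stated full-scale-RMS reference (a full-scale
sine reads −3.01 dB re that reference), while `measure_spl_profile()` meters
against a device profile, treating the coupler maxima as full-scale *sine*
SPLs; rendering a tone at a target and metering it back with the profile
meter round-trips within 0.1 dB on the steady-state segment. The ambient
meter is unweighted RMS (optionally block-wise, 250 ms default) — no
A-weighting, since the pause rule is a coarse 40 dB SPL gate, strict
inequality as specified.

## Severity categories

Measured thresholds are labelled with the six ASHA bands (normal 0–25 dB HL,
mild 26–40, moderate 41–55, moderately severe 56–70, severe 71–90, profound
above 90). The printed bands assign 90 dB HL to both severe and profound;
we keep 90 in severe so the bands partition the axis, and thresholds below
0 dB HL (the floor is −10) are normal.

## Numerical and testing choices

* All level arithmetic is exact real arithmetic; the only quantization is the
  staircase's own 5 dB grid relative to the 30 dB HL start.
* Simulation sizes: 40 ears for deterministic calibration recovery, 200 ears
  (100 listeners) for stochastic accuracy, chosen as the smallest sizes at
  which the binomial noise on a 95 % coverage check is well below the margin
  being asserted.
* Seeds are explicit everywhere randomness exists (cohort draw, logistic
  responses, noise synthesis); deterministic paths are seed-free and
  byte-reproducible, and serialized artifacts deliberately omit timestamps.
* The injected calibration errors used in recovery tests span the
  ±15 dB range with a fixed representative vector (−15, −10, −4, 0, 7, 15).

## Limitations

* Bone conduction, speech audiometry and conductive-loss simulation are out
  of scope; the masking arithmetic is the air-conduction formula only.
* Device profiles are defined at the six test frequencies; no interpolation
  of the frequency response between them is attempted.
* The simulator models stationary listeners; fatigue, learning and
  attention drift across a session are not represented.
* A passing simulation validates procedure and calibration arithmetic.
  Agreement of a physical device with a clinical audiometer additionally
  depends on transducer tolerances and fit, which require coupler and
  subject measurements.
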