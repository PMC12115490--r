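---
title: "FFT-based gait parameter estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FFT-based gait parameter estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fftgait)
library(dplyr)
```

## The problem

Children with Duchenne muscular dystrophy (DMD) lose ambulation gradually, and
daily step counts alone are a blunt progression marker: high-frequency,
high-velocity steps disappear before total counts do. Ankle-worn research IMUs
can measure community stride velocity precisely but are costly and scarce. A
single waist-worn consumer accelerometer (a phone at the lumbosacral junction,
near the body's center of mass) records a stable, periodic anteroposterior
signal during walking — enough to recover cadence, and from cadence plus
standing height, step length, velocity, and travel distance.

`fftgait` implements that estimation chain:

1. **Preprocess** — detrend and bandpass the anteroposterior axis to
   0.3–4.6 Hz.
2. **Window** — cut the bout into fixed, non-overlapping 5 s windows.
3. **Gate activity** — classify each 1 s slice as active when its peak
   acceleration reaches a threshold calibrated from a very-slow-walk
   recording (SC-L1).
4. **Detect cadence** — per window, the dominant in-band FFT peak, with a
   harmonic-disambiguation rule.
5. **Predict step length** — an eight-term regression on transformed cadence
   and height with a DMD adjustment.
6. **Aggregate** — steps, distance, and velocity per window, then bout
   totals, averages, and the 95th-percentile window velocity.

The package also contains the agreement statistics used to validate such
estimates against reference measurements (percentage Bland–Altman,
Passing–Bablok regression, Lin's concordance, MdAE/MdAPE), and a synthetic
signal generator with exact ground truth, so the whole chain is testable
without access to clinical recordings.

## The cadence detector

Each 5 s window is mean-removed and zero-padded before the FFT so that bin
spacing is at most 0.05 Hz (a raw 5 s window gives 0.2 Hz bins, too coarse
for cadence differences that matter clinically). Candidate peaks are local
maxima of the magnitude spectrum inside 0.3–4.6 Hz. The band's lower edge
excludes postural adjustments; the upper edge is the fastest cadence observed
in running children. If no candidate exists the window's step frequency is 0
and it contributes no steps.

**The 60%/60% harmonic rule.** Running and Trendelenburg-style gaits with a
pronounced lateral component often place the *largest* spectral peak near
twice the true step frequency. Let P be the highest-magnitude candidate and Q
the highest-magnitude candidate at a lower frequency. If Q's frequency is
below 60% of P's frequency *and* Q's magnitude is at least 60% of P's
magnitude, Q is selected. Two readings of this rule are possible (frequency
ratio vs an absolute threshold); the frequency-ratio reading is implemented
because it matches the approximately-2x harmonic phenomenon the rule exists
for. The rule is applied once, not recursively; with three or more comparable
peaks only the top-two construction above is used. Equal-magnitude ties go to
the lower frequency, favoring the fundamental.

A magnitude floor (default 5% of the spectrum maximum) keeps noise bins in
near-silent windows from producing spurious cadence; some floor is implied by
the "no peak, set to 0" behavior, and 5% was chosen once as a value well
below any genuine gait peak yet above broadband noise wiggle.

## Activity gating

The threshold is `mu + sigma` of the per-step peak accelerations in the
slowest calibration walk, with `sigma` in population form (divisor `m`,
following the defining formula literally). Peak detection uses positive local
maxima separated by at least the minimum physiologic step period (1/4.6 s)
with topographic prominence of at least 10% of the trace maximum; the
separation/prominence constants are implementation choices (the original
peaks may have been marked manually), exposed as arguments. A second is
active when the *absolute* preprocessed signal reaches the threshold —
absolute, because after detrending a step impact can present as a negative
excursion depending on device orientation. The boundary comparison is `>=`,
following the displayed classification rule over the looser prose. The
threshold is applied to the preprocessed signal for consistency with every
other stage. When no SC-L1 recording exists a threshold can be supplied
directly; a documented fallback (0.05 G) exists for exploratory runs and
warns loudly.

## The step-length model

With $u = \sqrt{\mathrm{sf}}$ (cadence in steps/s) and $v = 1/\sqrt{h}$
(height in m):

$$\mathrm{SL} = 3.33758\,u + 2.442582\,v - 3.072612\,uv - 2.505019
 + \mathrm{DMD}\,(1.87948 - 1.689478\,u - 1.865428\,v + 1.664073\,uv)$$

The transform reading matters: the untransformed variables give a predicted
step length of about 1.32 m for a 1.3 m child at 2 steps/s — physiologically
impossible — while the transformed reading gives 0.546 m, i.e. 35–40% of
standing height, which is typical of self-selected to fast walking. An
inactive window (sf = 0) predicts 0 m by convention, and the rare negative
prediction (very low cadence with the DMD adjustment) is clamped to 0 with a
warning.

`fit_step_length_model()` refits the same eight-term design by ordinary least
squares. The original coefficients come from mixed-model regression with
within-participant random effects; without participant identifiers that
structure cannot be reproduced, so the fit here is fixed-effects only and its
print method says so. Model selection across alternative covariate sets is
out of scope — only the final published form is fittable.

## Aggregation conventions

Per window: steps = cadence x active seconds; distance = steps x step
length; velocity = distance / *active* seconds. Bout averages divide by
*total* duration (active plus inactive), reflecting mobility density in
community settings — a child who walks 30 s and rests 30 s should not average
like a continuous walker. Both conventions are available
(`velocity_denominator = "total"` or `"active"`) and never mixed within one
summary. Fractional steps are kept per window; the bout total is also
reported rounded for comparison with observed counts. The 95th-percentile
step velocity is computed over per-window velocities of active windows
(type-7 quantile) — a window-weighted approximation of the stride-velocity-95
endpoint, since this method has no per-step timing.

Trailing partial windows of at least 1 s are kept, with their true duration
carried through every formula; discarding up to 5 s of a short clinical test
would bias totals low.

## Numerical choices

- **Filter**: 4th-order Butterworth bandpass applied forward-backward
  (`signal::filtfilt`), chosen because zero-phase filtering keeps step peaks
  aligned with the 1 s activity slices. Only the band is prescribed by the
  method; family and order are this package's defaults, exposed as
  arguments. Attenuation one octave outside the band exceeds 20 dB.
- **Filtering is whole-bout**, before windowing, so filtering and
  segmentation commute.
- **Resampling**: irregular timestamps are linearly interpolated onto a
  uniform grid at the median observed rate (simplest defensible choice; the
  applied rate is recorded in the result).
- **No taper** is applied before the FFT by default (zero-padding only); a
  Hann taper is available in `spectral_config()`. Rectangular-window
  sidelobes sit about 13 dB down and more than an octave of cadence away
  from the main peak, so they cannot trip the 60%/60% rule.
- **Quantiles** are type-7 (linear interpolation) everywhere, so MdAPE and
  IQR values reproduce bit-for-bit.
- **Passing–Bablok**: ties at slope −1 are excluded, the median index is
  offset by the count of slopes below −1, and the even-count median is the
  arithmetic mean of the two central shifted slopes; CIs use the
  large-sample rank-based normal approximation (exact small-sample tables
  are out of scope).
- **Bland–Altman percentages** use the pair mean as denominator (the
  standard percentage-BA form) with sign convention estimate − reference.

## The synthetic-data generator

`simulate_bout()` builds walk segments as
$A_1 \sin(2\pi f t) + A_2 \sin(4\pi f t + \varphi_2)$ plus slow sinusoidal
drift and Gaussian noise; rest segments carry drift and noise only. Step
events sit at the phase crossings of the fundamental — one step per cycle,
since the dominant spectral peak is steps per second. Ground-truth step
lengths come from the step-length equation at the segment's cadence, which
makes the step-length comparison a pipeline-consistency check rather than an
independent biomechanical validation. The generator emulates the spectral
phenomena the detector must handle (harmonics, drift, noise, rest) but *not*
flight-phase running dynamics, stride-to-stride variability, or 3-axis
biomechanics — so passing tests demonstrate correctness of the estimation
chain, not field accuracy on real children.

`simulate_validation_batch()` fixes the study conditions used by the
end-to-end checks: 50 bouts of 20–180 s alternating walk (8–30 s) and rest
(3–10 s) segments, per-segment cadences uniform on 1.2–3.0 Hz, fundamental
amplitude 0.5 G with harmonics at 0.1–0.3 G (fundamental-dominant), noise sd
0.1 G (20% of the fundamental), 0.05 G drift with a 60 s period, subject
heights uniform on 1.0–1.7 m and DMD status Bernoulli(0.4). The matching
SC-L1 trace is a 20 s, 1 Hz walk at 0.3 G. Per-bout seeds derive
deterministically from the master seed (`(1009 seed + i) mod 2^31 − 1`), and
all randomness flows through R's Mersenne–Twister via `withr::with_seed`, so
batches are bit-reproducible.

Problem sizes in the test-suite and acceptance script (50 bouts at 100 Hz,
20 replicates of 260 regression observations, 1000 brute-force agreement
instances at n ≤ 12) were chosen as the smallest sets that exercise every
rule while keeping a full run comfortably interactive.

## A worked example

```{r example}
subject <- subject_profile(height = 1.30, dmd = 0)
spec <- gait_sim_spec(
  rbind(walk_segment(60, 2.0), rest_segment(10), walk_segment(30, 2.6)),
  noise_sd = 0.1, drift_amplitude = 0.05, seed = 42)
sim <- simulate_bout(spec, subject)
scl1 <- simulate_scl1(seed = 43)

res <- run_pipeline(sim$recording, subject, scl1 = scl1, truth = sim$truth)
res$summary |> glimpse()
res$errors
```

```{r plot, fig.width = 7, fig.height = 5}
autoplot(res$timeline)
```

## Known limitations

- Cadence is quantized to the FFT bin width (≤ 0.05 Hz); windows mixing two
  cadences report a single dominant one.
- Step length inherits any bias of the published equation outside its
  calibration range (children 3–16; cadences of functional gait).
- Running with a true flight phase is out of the model's validated range.
- The activity gate is a single global threshold; postural changes that
  alter signal amplitude mid-bout are not re-thresholded.
- Bout averages depend on the chosen duration convention; comparisons across
  studies must match conventions.
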