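# fftgait

Estimation of step frequency, step count, step length, step velocity, and
travel distance from a single waist-worn accelerometer, for gait monitoring
in children with Duchenne muscular dystrophy (DMD) and typically developing
peers. The intended users are movement-science and digital-biomarker analysts
who have raw phone-IMU recordings and need temporospatial gait parameters
without laboratory-grade, individually calibrated equipment.

## Method

The anteroposterior axis of a waist-worn phone is detrended, bandpassed to
0.3–4.6 Hz, and cut into fixed 5 s windows. Per window:

- **Cadence** is the dominant peak of the FFT magnitude spectrum within the
  band, with a harmonic-disambiguation rule: if a lower-frequency peak sits
  below 60% of the dominant peak's frequency and carries at least 60% of its
  magnitude, the lower peak is the step frequency (gaits with a pronounced
  lateral component often put the largest peak at twice the true cadence).
  Windows with no in-band peak get cadence 0.
- **Active time** is gated per second: a 1 s slice is active when its peak
  absolute acceleration reaches a threshold μ + σ of per-step peaks from a
  very-slow-walk calibration recording (SC-L1).
- **Step length** comes from an eight-term regression with u = √sf,
  v = 1/√h:

  SL = 3.33758 u + 2.442582 v − 3.072612 uv − 2.505019
     + DMD · (1.87948 − 1.689478 u − 1.865428 v + 1.664073 uv)

  (sf = cadence in steps/s, h = standing height in m, DMD ∈ {0, 1}).
- Steps = cadence × active seconds; distance = steps × SL; bout averages
  divide by total duration (active + inactive), the community-mobility
  convention.

The package also provides the method-agreement statistics used to validate
such estimates (percentage Bland–Altman, Passing–Bablok regression, Lin's
concordance correlation, MdAE/MdAPE with IQRs), a refitting routine for the
step-length model, and a synthetic gait-signal simulator with exact ground
truth. See the vignette `vignettes/fft-gait-estimation.Rmd` for the full
methods account.

## Worked example

```r
library(fftgait)

subject <- subject_profile(height = 1.30, dmd = 0)
spec <- gait_sim_spec(
  rbind(walk_segment(60, 2.0), rest_segment(10), walk_segment(30, 2.6)),
  noise_sd = 0.1, drift_amplitude = 0.05, seed = 42)
sim  <- simulate_bout(spec, subject)      # recording + ground truth
scl1 <- simulate_scl1(seed = 43)          # slow-walk calibration trace

res <- run_pipeline(sim$recording, subject, scl1 = scl1, truth = sim$truth)
res
#> Gait pipeline result: 20 windows over 100.0 s (90 s active)
#>   steps 198.0, distance 118.1 m, avg cadence 1.98 Hz, avg velocity 1.18 m/s
```

The simulated bout walks 60 s at 2.0 Hz, rests 10 s, then walks 30 s at
2.6 Hz; ground truth is 198 steps. The pipeline calibrates a 0.318 G activity
threshold from the SC-L1 trace, finds 90 active seconds out of 100, and
recovers the step count, average cadence (1.98 Hz), average step length
(0.596 m), average velocity (1.18 m/s over total duration), and distance
(118.1 m) — here to within fractions of a percent of truth:

```r
res$errors
#>   metric         reference estimate pct_error
#> 1 step_count       198      198.     ~0
#> 2 step_frequency     1.98     1.98   ~0
#> 3 step_length        0.596    0.596  ~0
#> 4 step_velocity      1.18     1.18   ~0
#> 5 distance         118.     118.     ~0

autoplot(res$timeline)   # cadence / velocity / cumulative-distance panels
```

Validating estimates against reference measurements:

```r
d <- data.frame(reference = ref_counts, estimate = est_counts)
agreement_report(d, metric = "step_count")  # BA%, PB, CCC, MdAE/MdAPE + flags
```

A thin command-line front end over the same functions lives at
`inst/cli/fftgait.R` (subcommands `simulate`, `calibrate`, `estimate`,
`compare`).

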