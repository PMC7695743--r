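# pursuitkin

Kinematic analysis and modelling of aerial pursuit trajectories.

When a male blowfly chases a moving dummy female, high-speed stereo
videography reduces the chase to two synchronized 3D position tracks —
pursuer and target — sampled at 190 Hz with millimetre-scale
reconstruction noise. `pursuitkin` is for behavioural scientists and
control-minded biologists who want to go from such tracks to an explicit
steering control law: which visual signal drove the turns, with what gain,
and after what sensorimotor delay.

The geometry is described by three angles, each with an azimuth (H) and an
elevation (V) component: the **heading** θ<sub>P</sub> (direction of the
line of flight, i.e. the velocity), the **bearing** θ<sub>A</sub>
(direction of the line of sight to the target, external frame), and the
**error angle** θ<sub>E</sub> = θ<sub>A</sub> − θ<sub>P</sub> (egocentric
target direction). The candidate steering laws command the turn rate
Ω<sub>P</sub> from delayed visual input:

| strategy | law |
|---|---|
| pure pursuit (PP) | Ω<sub>P</sub>(t) = k<sub>p</sub> · θ<sub>E</sub>(t − Δt) |
| biased pursuit (BP) | Ω<sub>P</sub>(t) = k<sub>p</sub> · [θ<sub>E</sub>(t − Δt) + β] |
| proportional navigation (PN) | Ω<sub>P</sub>(t) = N · Ω<sub>A</sub>(t − Δt) |
| mixed pursuit (MP) | BP + PN terms with independent delays |

The package covers the full workflow:

* **trajectory I/O** — delimited-text tracks with a configurable dialect
  (`read_track()`, `write_track()`, `resample_uniform()`);
* **kinematics** — heading/bearing/error angles, range, speed, cumulative
  horizontal displacement x′, target angular size, angular rates, and
  body-saccade detection (`compute_angles()`, `compute_rates()`,
  `extract_saccades()`);
* **circular statistics** — mean-vector summaries and rose-plot bins of
  the six pursuit angles (`mean_vector()`, `summarize_pursuit_angles()`);
* **closed-loop simulation** — planar and 3D virtual flies under any of
  the laws, with interpolated delays and replayed, constant, or
  angular-size-driven forward speed (`simulate_planar()`,
  `simulate_3d()`);
* **system identification** — lag-scanned OLS fits of Ω<sub>P</sub>
  against θ<sub>E</sub>, θ<sub>A</sub>, Ω<sub>E</sub>, Ω<sub>A</sub>, plus
  speed-coupling relations (`lag_scan_fit()`, `identify_controllers()`,
  `speed_relations()`);
* **model evaluation** — replay-based trajectory error
  ε (mean point-to-point distance per plane), gain/bias grid search, and
  ANOVA strategy comparison (`trajectory_error()`, `grid_search()`,
  `compare_strategies()`);
* **synthetic data** — seeded chase generation with known ground-truth
  controllers and realistic measurement noise, driving end-to-end
  parameter-recovery experiments (`synthetic_spec()`, `gen_chase()`,
  `recovery_experiment()`).

The methods vignette (`vignettes/pursuit-kinematics.Rmd`) documents the
model assumptions, the measurement pipeline's filter choices, the
frame-validity masks behind the identification, and known limitations.

## Worked example

Generate twenty noisy chases driven by a known biased-pursuit controller
(k<sub>p</sub> = 26 s⁻¹, Δt = 2 frames ≈ 10.5 ms, 5 mm tracking noise),
then recover the controller two independent ways — lagged linear fits and
trajectory-error grid search:

```r
library(pursuitkin)

spec <- synthetic_spec("circle", seed = 1)   # 190 Hz, 5 mm noise, 1 m/s dummy
rec <- recovery_experiment(20, spec, noise_levels = 0.005,
                           do_grid = TRUE, grid = list(kp = seq(0, 60, 1)))
rec[, c("gain_true", "gain_hat", "delay_hat_ms", "R_own", "grid_kp")]
#>  gain_true gain_hat delay_hat_ms     R_own grid_kp
#>         26 26.43603     10.52632 0.9390854      26
```

The lag fit recovers the gain within 2% and the delay to the exact frame
(R = 0.94), and the replay grid search lands on the generating gain. The
four-input identification table shows *why* the error angle wins:

```r
chs <- gen_chases(6, spec)
angles <- lapply(chs, function(ch) compute_angles(ch$track))
rates <- lapply(angles, compute_rates)
identify_controllers(angles, rates, "horizontal")
#> Steering-input identification (horizontal plane):
#>   Omega_P ~ theta_E  gain     28.7  delay  10.5 ms  R  0.945 *
#>   Omega_P ~ theta_A  gain     1.14  delay  26.3 ms  R  0.441
#>   Omega_P ~ omega_E  gain   -0.701  delay   0.0 ms  R -0.686
#>   Omega_P ~ omega_A  gain    0.717  delay  31.6 ms  R  0.883 *
#>   (velocity window 31, position window 31, rate window 5 frames)
```

θ<sub>E</sub> carries the strongest correlation at the generating delay;
the bearing-rate fit is the expected closed-loop echo at a longer lag. The
vertical error angle of the same chases concentrates near the generating
23° bias (the sign follows the pursuer-below-target geometry):

```r
summarize_pursuit_angles(angles)$theta_EV
#> <circular_summary: n = 843, mu = -25.3 deg, r = 0.9478, sigma = 18.8 deg>
```

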