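---
title: "Identifying steering control laws from pursuit trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying steering control laws from pursuit trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A male blowfly chasing a moving dummy female solves a sensorimotor control
task: it must keep turning so that some visual quantity — the egocentric
direction of the target, or the drift of the target against the visual
background — stays where its nervous system wants it. High-speed stereo
videography turns each chase into two synchronized 3D position tracks
(pursuer and target, 190 Hz, millimetre-scale reconstruction noise). This
package reconstructs the angular quantities of the pursuit from those
tracks, identifies which candidate control law drove the steering, and
evaluates candidate controllers by replaying them against the recorded
chases.

Three angles describe the planar geometry (each has a horizontal/azimuth
and a vertical/elevation component):

* **heading** `theta_P` — direction of the line of flight (LOF), the line
  through consecutive pursuer positions, i.e. the velocity direction;
* **bearing** `theta_A` — direction of the line of sight (LOS) from
  pursuer to target, in the external frame;
* **error angle** `theta_E = theta_A - theta_P` — where the target sits in
  the pursuer's egocentric frame.

Azimuths live in (−180°, 180°], counter-clockwise positive from +x;
elevations in [−90°, 90°]. `Omega_P`, `Omega_A`, `Omega_E` are their time
derivatives.

## Candidate steering laws

All candidates command a turn rate from delayed visual input
(`controller_spec()`):

| strategy | law | behaviour |
|---|---|---|
| PP, pure pursuit | `Omega_P = kp * theta_E(t - dt1)` | tracking: converge into the target's wake |
| BP, biased pursuit | `Omega_P = kp * (theta_E(t - dt1) + beta)` | interception: hold the target at `-beta` |
| PN, proportional navigation | `Omega_P = N * Omega_A(t - dt2)` | null the LOS rotation (constant bearing) |
| MP, mixed pursuit | BP + PN terms, each with its own delay | hybrid |

An optional derivative gain `kd` adds `kd * Omega_E(t - dt1)` (the
proportional–derivative variant described for several other chasing
insects); it defaults to 0. Units: `kp` in s⁻¹ acting on degrees, `N` and
`kd` dimensionless, `beta` in degrees, delays in seconds.

Two closed-loop equilibria anchor intuition and tests: with a
non-manoeuvring target and no delay, BP settles where the command
vanishes, `theta_E = -beta` (a constant-bearing collision course), and PP
is the `beta = 0` special case that settles at `theta_E = 0`. On an exact
collision triangle the LOS does not rotate, so a PN pursuer of any `N`
flies silently straight into the target.

## From positions to angles: the measurement pipeline

`compute_angles()` estimates the pursuer's velocity with a zero-phase
Savitzky–Golay derivative filter and smooths the positions entering the
LOS with the matching zero-phase smoother; `compute_rates()` unwraps
azimuths, optionally smooths, and differentiates with central differences
(one-sided at the ends). Defaults: window 31 frames (~163 ms) and order 2
for positions/velocity, window 5 for rates. Degrees everywhere outside the
trigonometric kernels.

Why 31 frames: the recordings this package targets carry ~5 mm i.i.d.
reconstruction noise per coordinate at 190 Hz, while the pursuer moves
only ~6 mm per frame — raw frame-to-frame headings are useless. The
windows were calibrated once on the package's own synthetic ground-truth
chases (`recovery_experiment()`): order-2/window-31 filtering brings the
noise-free bias of the recovered proportional gain to about −1% and keeps
the 5 mm-noise bias within a few percent at the packaged conditions, while
delay recovery stays exact to the frame. Narrower windows leave too much
heading noise (attenuation bias pulls gains down); much wider windows
distort the signal band itself. For noise-free (simulated) tracks set the
windows to 0: any filtering only hurts there, and the fast bearing-rate
signal needed for PN identification does not survive heavy smoothing.

Degenerate frames: a stationary pursuer has no heading — such frames carry
the last valid heading and are flagged (`held`); a purely vertical
displacement leaves only the azimuth held. The apparent target size is
`rho = 2 atan(r / R_A)` for a sphere of radius `r` (8 mm dummy by
default).

One convention matters for unbiased identification: the simulator advances
the heading first and then steps the position along the *new* heading, so
the displacement arriving at frame *i* carries the heading commanded at
*i* − 1. Raw-difference heading extraction therefore assigns displacement
(*i*−1)→*i* to frame *i*. With the mismatched (forward) convention the
recovered gain is biased upward by roughly `1/(1 - kp*dt)` — a 15% error
at `kp = 26 s⁻¹` — an easy trap when validating controllers against their
own simulator.

## Identification by lagged linear fits

`lag_scan_fit()` shifts the input by each candidate delay (linear
interpolation between frames), fits OLS on the pooled overlap, and keeps
the delay with maximal |R| (ties to the smallest delay; optional parabolic
sub-frame refinement). `identify_controllers()` applies this to the four
candidate inputs — `theta_E`, `theta_A`, `Omega_E`, `Omega_A` — against
`Omega_P`, pooling frames across chases, and flags fits with |R| ≥ 0.7.

Pooled OLS is only as good as the frames that enter it. Four validity
filters are applied by default, each a statement about what 190 Hz
sampling and finite-window filters can resolve, not a tuning knob:

* **end trim** — half a filter window at each chase end, where zero-phase
  filters become one-sided and their noise gain rises several-fold;
* **rate ceiling** — frames whose measured |`Omega_P`| reaches 95% of a
  7000 °/s physiological ceiling (the fastest yaw rotations measured in
  blowflies); beyond it the output is not proportional to anything;
* **heading folds** — frames around any heading step above 90°/frame
  (±2 frames for the differentiation support): a sampled direction that
  moves more than a quarter turn between frames is within folding
  ambiguity of the half-turn-per-frame limit, and an unwrap error there
  poisons the rate with ±360°/frame outliers;
* **range floor** — frames where the *horizontal* pursuer–target distance
  (horizontal-plane fits) or the 3D range (vertical-plane fits) falls
  below 2 cm. The horizontal case is the important one: when the target
  passes nearly overhead the azimuthal bearing becomes singular and can
  legitimately sweep hundreds of degrees per frame with millimetres of
  physical motion.

The recovery experiment also analyses only chases that ended in capture by
default — the same inclusion rule the behavioural experiments used —
because abandoned chases accumulate close passes where all of the above
failure modes concentrate.

A fundamental caveat worth stating: OLS with a noisy regressor is
attenuated by `var(signal) / (var(signal) + var(noise))`. Angle-input fits
(`theta_E`) tolerate the residual ~1–2° of filtered heading noise well;
rate-input fits (`Omega_A`) do not, because differentiation amplifies the
noise past the signal. Recovering a navigation constant without bias
therefore requires clean rates; on noisy data the fitted `N` is biased
toward zero. The same mechanism would operate on real tracking data — a
point to keep in mind when comparing behavioural lag-fit gains with
replay-optimised gains.

`speed_relations()` applies the same machinery to the forward speed
(against |`Omega_PH`|, with negative delays for lead analysis, against
`theta_EH`, `Omega_EH`, and the angular size `rho`), and
`fit_boeddeker()` refits the angular-size speed law
`s = rho * S_v * exp(-rho / rho_star) + S_g` (with `s = S_g` below 0.5°)
by Levenberg–Marquardt. The law's published uses do not print its
coefficients; the package defaults (`S_g` 0.2 m/s, `S_v` 0.5 m/s per
degree, `rho_star` 6°) are placeholders giving a plausible 0.2–1.5 m/s
envelope and should be set explicitly for quantitative work.

## Replay evaluation and grid search

`trajectory_error()` scores a simulated chase against the measured one:
`eps_H` is the mean planar distance in (x, y); `eps_V` the mean distance
in (x′, z), where x′ is each trajectory's own cumulative horizontal path
length. `grid_search()` replays a strategy against every chase over a
parameter grid (speed replayed from the measured fly, initial conditions
from the measured first frames, delays defaulting to the identified
per-plane values: 10/26 ms horizontal, 21/32 ms vertical) and returns the
mean-ε surface and its argmin. `compare_strategies()` runs a one-way
ANOVA across per-chase ε with Tukey pairwise follow-up (`n.s.` / `*` /
`***` at 0.05 and 0.001).

Numerical choices that keep replay honest:

* **Integration** is explicit Euler at the track's frame interval (the
  native 190 Hz cadence); a convergence property test checks that halving
  the step changes final positions at first order. Delayed inputs are
  linearly interpolated in the simulation's own history and held at their
  initial value for `t < delay`.
* **Self-consistency**: replaying the generating controller against a
  clean synthetic chase reproduces it to ~0.1 mm, and the grid argmin
  lands exactly on the generating gain. This required forward-difference
  initial conditions and replay speeds (matching the integrator's
  convention); centered estimates shifted the argmin by several grid
  steps.
* **Smoothing before replay**: for noisy recordings, pass
  `smooth_window = 31` so measured tracks are denoised before serving as
  replay input and error reference. Raw cumulative x′ double-counts 5 mm
  jitter (~8 mm of spurious path length per frame), which otherwise
  dominates `eps_V`.
* **Vertical plane**: the vertical simulation runs in (x′, z) with the
  target placed at the measured pursuer's x′ plus the current horizontal
  range — this preserves the bearing elevation of the 3D geometry while
  keeping the vertical replay independent of the horizontal controller. A
  coupled full-3D mode exists as well; on near-planar chases the two agree
  to centimetre level (tested). Which construction the original analysis
  used is not documented; the decoupled form is the default because the
  replay evaluation treats the planes independently.
* The coupled simulator clamps elevation at ±85°: at the zenith the
  azimuth heading is undefined and the horizontal displacement underflows
  double precision. An optional turn-rate saturation (`omega_max`) is
  available but off by default — the steering laws are pure linear laws.

## The synthetic-data generator

`synthetic_spec()` + `gen_chase()` emulate the study conditions: a
0.50 × 0.50 × 0.70 m arena at 190 Hz; a circular dummy path at 1 m/s
(radius 0.15 m) or a "spring" path (y-translation with rotation about the
vertical axis, constrained to the recorded envelope of 0–1.5 m/s and
360–1300 °/s; defaults 0.4 m/s, 720 °/s, 0.07 m radius keep the speed
inside the envelope, with the translation reflecting at the walls since
the synthetic arena is shorter than the real 3 m course); i.i.d. isotropic
Gaussian position noise of 5 mm SD on both protagonists (the reported
reconstruction accuracy; its correlation structure is unreported, so
independence is assumed); an optional 24 Hz sinusoidal speed modulation
(relative amplitude 0.2 — the real amplitude is unreported; this free
parameter only feeds the low-pass property check). The virtual fly starts
uniformly in the arena, initially headed at the target with ±10° azimuth
(±5° elevation) jitter, flies at constant 1.2 m/s by default, and runs
its ground-truth controllers — horizontal BP `kp = 26 s⁻¹`/10.5 ms by
default, vertical BP `kp = 10 s⁻¹`, `beta = 23°`, 21 ms — for a 2 s
horizon; non-captures are returned flagged. Chase *i* of a family uses
seed `seed + i − 1`, making every experiment reproducible bit-for-bit.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: body-axis/head orientation (the heading
here is strictly the velocity direction; real flies side-slip and saccade
with head–body offsets), banked-turn roll coupling between the planes,
tracking dropouts, non-Gaussian or temporally correlated reconstruction
error, motor noise in the fly itself, and chase initiation/abandonment
behaviour. Recovery results therefore validate the estimation pipeline,
not the biological interpretation.

`recovery_experiment()` ties the loop together: generate chases at given
noise levels, run the measurement pipeline (windows adapt: unfiltered at
zero noise, standard windows otherwise), identify the controller, and
optionally locate the gain by grid search, reporting recovered versus
generating parameters.

## Problem sizes and known limitations

The packaged experiments use 12–20 chases of ≤2 s per condition and grid
scans of ≤91 × 20 replays; all tests and the acceptance script run in a
few minutes on one core.

* Noisy-data gain recovery scatters with the generator seed: across seeds
  the BP gain ranges roughly −14%…+2% around truth (attenuation by
  residual heading noise depends on each family's error-angle excursion).
  Delay recovery is exact to the frame in every configuration tested.
* The vertical bias-angle scan lands within one 1° grid step of the truth
  but with a consistent −1° lean — the footprint of the decoupled (x′, z)
  approximation to the coupled 3D generation.
* Rate-input (PN) identification requires clean rates (see the
  attenuation caveat above).
* The circular-statistics angular SD is the circular standard deviation
  `sqrt(-2 ln r)`; an arc-based SD would differ for wide distributions.
  Pooling across chases is frame-weighted.
* Mirroring chases onto a common target rotation direction is exposed as
  `compute_angles(mirror = TRUE)` and off by default; whether to mirror
  per chase is a dataset-level decision.

## A worked miniature

```{r, eval = FALSE}
library(pursuitkin)

spec <- synthetic_spec("circle", seed = 1)      # study conditions, 5 mm noise
rec <- recovery_experiment(20, spec, noise_levels = 0.005,
                           do_grid = TRUE, grid = list(kp = seq(0, 60, 1)))
rec[, c("gain_true", "gain_hat", "delay_hat_ms", "R_own", "grid_kp")]

chs <- gen_chases(6, spec)
angles <- lapply(chs, function(ch) compute_angles(ch$track))
summarize_pursuit_angles(angles)$theta_EV
```
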