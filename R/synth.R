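#' Specification of a synthetic chase experiment
#'
#' Bundles everything needed to generate a target trajectory and a
#' closed-loop virtual-fly chase with known ground truth. The defaults
#' reproduce the recorded study conditions: a 0.50 x 0.50 x 0.70 m flight
#' arena sampled at 190 Hz, a circular dummy path at 1 m/s, i.i.d. Gaussian
#' position noise with 5 mm standard deviation on both protagonists (the
#' stereo-reconstruction accuracy), and the identified horizontal
#' (kp = 26/s, 10 ms delay, no bias) and vertical (kp = 10/s, 21 ms delay,
#' 23 degree bias) biased-pursuit controllers. The "spring" target combines
#' a y-translation with a rotation about the vertical axis; its speed must
#' stay within 0-1.5 m/s and its angular velocity within 360-1300 deg/s,
#' the envelope of the recorded dummy trajectories.
#'
#' @param kind target path: `"circle"`, `"spring"` or `"line"`.
#' @param speed target translation speed, m/s (tangential speed for
#'   `"circle"`, y-translation speed for `"spring"`).
#' @param rotation_rate rotation rate of the `"spring"` path about the
#'   vertical axis, degrees/s.
#' @param radius path radius, m (circle radius, or spring rotation radius).
#' @param arena arena extents (x, y, z), meters.
#' @param h_controller,v_controller [controller_spec()] ground truth for
#'   the two planes.
#' @param policy [speed_policy()] of the virtual fly.
#' @param noise_sd measurement-noise standard deviation, meters.
#' @param frame_rate sampling rate, Hz.
#' @param duration chase horizon, seconds.
#' @param seed base random seed.
#' @param modulation_24hz add a 24 Hz sinusoidal modulation to the target
#'   speed (an artefact of the recorded circular trajectories).
#' @param modulation_amplitude relative amplitude of that modulation.
#' @param target_diameter dummy diameter, meters.
#' @param capture_radius capture distance, meters.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("circle", "spring", "line"),
                           speed = 1, rotation_rate = 720, radius = NULL,
                           arena = c(0.50, 0.50, 0.70),
                           h_controller = controller_spec("BP", kp = 26,
                                                          dt1 = 2 / 190),
                           v_controller = controller_spec("BP", kp = 10,
                                                          beta = 23,
                                                          dt1 = 0.021,
                                                          plane = "vertical"),
                           policy = speed_policy("constant", s_const = 1.2),
                           noise_sd = 0.005, frame_rate = 190,
                           duration = 2, seed = 1L,
                           modulation_24hz = FALSE,
                           modulation_amplitude = 0.2,
                           target_diameter = 0.008,
                           capture_radius = 0.010) {
  kind <- match.arg(kind)
  if (is.null(radius)) radius <- if (kind == "spring") 0.07 else 0.15
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (speed < 0) stop("speed must be non-negative")
  if (kind == "spring") {
    if (rotation_rate < 360 || rotation_rate > 1300)
      stop("spring rotation rate must lie in [360, 1300] deg/s")
    vmax <- speed + radius * rotation_rate * pi / 180
    if (vmax > 1.5)
      stop(sprintf("spring target speed envelope reaches %.2f m/s; must stay within [0, 1.5]",
                   vmax))
  }
  structure(list(kind = kind, speed = speed, rotation_rate = rotation_rate,
                 radius = radius, arena = arena,
                 h_controller = h_controller, v_controller = v_controller,
                 policy = policy, noise_sd = noise_sd,
                 frame_rate = frame_rate, duration = duration,
                 seed = as.integer(seed),
                 modulation_24hz = isTRUE(modulation_24hz),
                 modulation_amplitude = modulation_amplitude,
                 target_diameter = target_diameter,
                 capture_radius = capture_radius),
            class = "synthetic_spec")
}

# triangle wave bouncing between lo and hi, starting at lo moving up,
# parameterised by arc length s
bounce <- function(s, lo, hi) {
  span <- hi - lo
  ph <- (s / span) %% 2
  lo + span * ifelse(ph <= 1, ph, 2 - ph)
}

#' Generate a noise-free target trajectory
#'
#' Ideal dummy paths sampled at the spec's frame rate: a circle at constant
#' tangential speed, a "spring" (y-translation plus rotation about the
#' vertical axis, the translation reflecting at the arena walls), or a
#' straight line. An optional 24 Hz sinusoidal speed modulation can be
#' applied to the translation.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `time` (seconds), `xyz` (n x 3 positions, meters) and
#'   `speed` (the speed profile applied, m/s).
#' @export
gen_target <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("not a synthetic_spec")
  dt <- 1 / spec$frame_rate
  time <- seq(0, spec$duration, by = dt)
  n <- length(time)
  ctr <- spec$arena / 2
  sp <- rep_len(spec$speed, n)
  if (spec$modulation_24hz)
    sp <- sp * (1 + spec$modulation_amplitude * sin(2 * pi * 24 * time))
  # cumulative arc length under the (possibly modulated) speed profile
  arc <- c(0, cumsum((sp[-n] + sp[-1L]) / 2 * dt))
  xyz <- switch(spec$kind,
    circle = {
      ph <- arc / spec$radius
      cbind(ctr[1L] + spec$radius * cos(ph),
            ctr[2L] + spec$radius * sin(ph),
            ctr[3L])
    },
    spring = {
      ph <- spec$rotation_rate * pi / 180 * time
      y <- bounce(arc, 0.08, spec$arena[2L] - 0.08)
      cbind(ctr[1L] + spec$radius * cos(ph), y, ctr[3L])
    },
    line = {
      cbind(0.05 + arc, ctr[2L], ctr[3L])
    })
  list(time = time, xyz = xyz, speed = sp)
}

#' Generate a closed-loop synthetic chase with known ground truth
#'
#' Generates the spec's target path, places the virtual fly at a seeded
#' random start position inside the arena with its initial heading pointing
#' at the target (plus seeded jitter), simulates the chase under the spec's
#' ground-truth controllers, and finally adds independent Gaussian position
#' noise to both pursuer and target -- emulating stereo-reconstruction
#' error. The exact generating controllers are returned for
#' parameter-recovery experiments.
#'
#' @param spec a [synthetic_spec()].
#' @param seed random seed for this chase; defaults to the spec's seed.
#' @param chase_id chase label.
#' @return a list of class `synthetic_chase`: `track` (the noisy
#'   [pursuit_track()]), `clean` (the noise-free track), `controller`
#'   (list `h`, `v` of the generating [controller_spec()]s), `sim` (the
#'   full `sim_result`), `captured`, `capture_time`, `seed`.
#' @export
gen_chase <- function(spec, seed = spec$seed, chase_id = "synth") {
  if (!inherits(spec, "synthetic_spec")) stop("not a synthetic_spec")
  set.seed(seed)
  tgt <- gen_target(spec)
  a <- spec$arena
  margin <- 0.05
  for (try in 1:20) {
    start <- c(stats::runif(1, margin, a[1L] - margin),
               stats::runif(1, margin, a[2L] - margin),
               stats::runif(1, margin, a[3L] - margin))
    if (sqrt(sum((start - tgt$xyz[1L, ])^2)) > 0.15) break
  }
  L <- tgt$xyz[1L, ] - start
  az <- atan2d(L[2L], L[1L]) + stats::rnorm(1, 0, 10)
  el <- atan2d(L[3L], sqrt(L[1L]^2 + L[2L]^2)) + stats::rnorm(1, 0, 5)
  sim <- sim3d_core(tgt$xyz, tgt$time, spec$h_controller, spec$v_controller,
                    spec$policy, replay_speed = NULL,
                    init_pos = start, init_h = az, init_v = el,
                    capture_radius = spec$capture_radius,
                    stop_at_capture = TRUE,
                    target_diameter = spec$target_diameter)
  n <- length(sim$time)
  if (n < 10L) stop("chase captured almost immediately; adjust start or seed")
  clean <- pursuit_track(sim$time, sim$pursuer, sim$target,
                         chase_id = chase_id, frame_rate = spec$frame_rate)
  noisy <- clean
  if (spec$noise_sd > 0) {
    noisy$pursuer <- clean$pursuer + matrix(stats::rnorm(3 * n, 0, spec$noise_sd), n, 3L)
    noisy$target <- clean$target + matrix(stats::rnorm(3 * n, 0, spec$noise_sd), n, 3L)
  }
  structure(list(track = noisy, clean = clean,
                 controller = list(h = spec$h_controller,
                                   v = spec$v_controller),
                 sim = sim, captured = sim$captured,
                 capture_time = sim$capture_time, seed = seed),
            class = "synthetic_chase")
}

#' Generate a family of synthetic chases
#'
#' @param n number of chases.
#' @param spec a [synthetic_spec()]; chase `i` uses seed `spec$seed + i - 1`.
#' @return list of `synthetic_chase` objects with ids `synth_01`, ...
#' @export
gen_chases <- function(n, spec) {
  lapply(seq_len(n), function(i)
    gen_chase(spec, seed = spec$seed + i - 1L,
              chase_id = sprintf("synth_%02d", i)))
}

#' Parameter-recovery experiment on synthetic chases
#'
#' The end-to-end validation loop: generate chases with known controllers
#' at each noise level, push them through the measurement pipeline
#' ([compute_angles()], [compute_rates()]), identify the steering law by
#' lagged fits ([identify_controllers()]), and (optionally) locate the gain
#' by trajectory-error grid search ([grid_search()]). Reports recovered
#' versus generating parameters.
#'
#' @param n_chases chases per noise level.
#' @param spec a [synthetic_spec()]; its controller for `plane` is the
#'   ground truth.
#' @param noise_levels measurement-noise SDs (meters) to sweep.
#' @param plane which plane to analyse.
#' @param do_grid also run the grid search (slower).
#' @param grid grid-search axes; defaults to the strategy's default grid.
#' @param captured_only analyse only chases that ended in capture, the
#'   same inclusion rule applied to the recorded data (close passes in
#'   abandoned chases sweep the line of sight faster than the sampling can
#'   resolve); falls back to all chases when fewer than two captured.
#' @param windows filter windows used by the measurement pipeline, a vector
#'   `c(deriv, smooth, rate)` in frames. `NULL` adapts to the noise level:
#'   noise-free tracks are analysed unfiltered (filtering distorts the
#'   fast bearing-rate signal for no benefit), noisy tracks with the
#'   package's standard windows (31, 31, 5).
#' @param ... passed to [identify_controllers()] (e.g. `refine = TRUE`).
#' @return a data.frame of class `recovery_report`, one row per noise
#'   level: generating and recovered gain, relative gain error, generating
#'   and recovered delay (ms), best-fit R for the strategy's own input and
#'   for the competing input, and the grid-search argmin when requested.
#' @export
recovery_experiment <- function(n_chases, spec, noise_levels = c(0, 0.005),
                                plane = c("horizontal", "vertical"),
                                do_grid = FALSE, grid = NULL,
                                captured_only = TRUE, windows = NULL, ...) {
  plane <- match.arg(plane)
  if (n_chases < 1L) stop("need at least one chase")
  ctrl <- if (plane == "horizontal") spec$h_controller else spec$v_controller
  own_input <- if (ctrl$strategy == "PN") "omega_A" else "theta_E"
  alt_input <- if (ctrl$strategy == "PN") "theta_E" else "omega_A"
  gain_true <- if (ctrl$strategy == "PN") ctrl$N else ctrl$kp
  delay_true <- if (ctrl$strategy == "PN") ctrl$dt2 else ctrl$dt1

  rows <- lapply(noise_levels, function(nl) {
    sp <- spec
    sp$noise_sd <- nl
    w <- windows %||% if (nl == 0) c(0L, 0L, 0L) else c(31L, 31L, 5L)
    chases <- gen_chases(n_chases, sp)
    if (captured_only) {
      cap <- Filter(function(ch) isTRUE(ch$captured), chases)
      if (length(cap) >= 2L) chases <- cap
    }
    tracks <- lapply(chases, `[[`, "track")
    angles <- lapply(tracks, compute_angles,
                     target_diameter = spec$target_diameter,
                     deriv_window = w[1L], smooth_window = w[2L])
    rates <- lapply(angles, compute_rates, smooth_window = w[3L])
    id <- identify_controllers(angles, rates, plane,
                               trim = max(2L, ceiling(max(w) / 2)), ...)
    own <- id[[own_input]]
    alt <- id[[alt_input]]
    row <- data.frame(noise_sd = nl, strategy = ctrl$strategy,
                      n_chases = length(chases),
                      gain_true = gain_true, gain_hat = own$gain,
                      gain_relerr = own$gain / gain_true - 1,
                      delay_true_ms = 1000 * delay_true,
                      delay_hat_ms = 1000 * own$delay,
                      R_own = own$R, R_alt = alt$R)
    if (do_grid) {
      gs <- grid_search(tracks, ctrl$strategy, plane, grid = grid,
                        fixed = list(beta = ctrl$beta, kd = ctrl$kd),
                        delays = list(dt1 = ctrl$dt1, dt2 = ctrl$dt2),
                        smooth_window = w[2L])
      par <- setdiff(names(gs$surface), "eps")[1L]
      row[[paste0("grid_", par)]] <- gs$argmin[[par]]
      row$grid_eps <- gs$argmin$eps
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}
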