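#' Steering-controller specification
#'
#' Describes one of the four candidate steering laws for pursuit, all of the
#' form "turn rate commanded from delayed visual input":
#' \describe{
#'   \item{PP (pure pursuit)}{`Omega_P(t) = kp * theta_E(t - dt1)`; drives
#'     the egocentric target direction to zero (tracking).}
#'   \item{BP (biased pursuit)}{`Omega_P(t) = kp * (theta_E(t - dt1) + beta)`
#'     with a constant bias `beta`; holds the target at `-beta`
#'     (interception geometry).}
#'   \item{PN (proportional navigation)}{`Omega_P(t) = N * Omega_A(t - dt2)`;
#'     nulls the rotation of the line of sight.}
#'   \item{MP (mixed pursuit)}{the sum of the BP and PN commands, each with
#'     its own delay.}
#' }
#' An optional derivative gain `kd` adds `kd * Omega_E(t - dt1)` to the
#' theta_E path (the proportional-derivative variant used by several other
#' chasing insects); `kd = 0` disables it.
#'
#' @param strategy one of `"PP"`, `"BP"`, `"PN"`, `"MP"`.
#' @param kp proportional gain on the error angle, 1/s.
#' @param kd derivative gain on the error-angle rate, dimensionless.
#' @param beta bias angle in degrees (must be 0 for PP).
#' @param N navigation constant (dimensionless).
#' @param dt1 sensorimotor delay on the theta_E path, seconds.
#' @param dt2 sensorimotor delay on the Omega_A path, seconds.
#' @param plane which plane the controller acts in (bookkeeping only).
#' @return an object of class `controller_spec`.
#' @export
#' @examples
#' controller_spec("BP", kp = 26, dt1 = 0.010)
#' controller_spec("PN", N = 1.8, dt2 = 0.026)
controller_spec <- function(strategy = c("PP", "BP", "PN", "MP"),
                            kp = 0, kd = 0, beta = 0, N = 0,
                            dt1 = 0, dt2 = 0,
                            plane = c("horizontal", "vertical")) {
  strategy <- match.arg(strategy)
  plane <- match.arg(plane)
  if (kp < 0) stop("kp must be non-negative")
  if (dt1 < 0 || dt2 < 0) stop("delays must be non-negative")
  if (strategy == "PP" && beta != 0)
    stop("pure pursuit has beta = 0 by definition; use BP for a bias angle")
  if (strategy == "PN" && kp != 0)
    stop("proportional navigation has no proportional error-angle term (kp = 0)")
  if (strategy %in% c("PP", "BP") && N != 0)
    stop(strategy, " uses no bearing-rate term (N = 0); use MP to combine them")
  structure(list(strategy = strategy, kp = kp, kd = kd, beta = beta, N = N,
                 dt1 = dt1, dt2 = dt2, plane = plane),
            class = "controller_spec")
}

#' @export
print.controller_spec <- function(x, ...) {
  cat(sprintf("<controller_spec %s (%s): kp=%.3g/s kd=%.3g beta=%.3g deg N=%.3g dt1=%.1f ms dt2=%.1f ms>\n",
              x$strategy, x$plane, x$kp, x$kd, x$beta, x$N,
              1000 * x$dt1, 1000 * x$dt2))
  invisible(x)
}

#' Forward-speed policy for simulated pursuers
#'
#' How the virtual fly sets its forward speed: `"replay"` copies the
#' measured pursuer's instantaneous speed frame by frame (the evaluation
#' mode used for controller comparison), `"constant"` holds `s_const`, and
#' `"boeddeker"` applies the angular-size speed law
#' `s = S_g` when the apparent target size `rho <= 0.5` degrees, otherwise
#' `s = rho(t - dt) * S_v * exp(-rho(t - dt) / rho_star) + S_g`,
#' which decelerates on target-image expansion (close range) and has its
#' maximum `S_v * rho_star / e + S_g` at `rho = rho_star`.
#'
#' @param mode `"replay"`, `"constant"` or `"boeddeker"`.
#' @param s_const constant speed, m/s.
#' @param S_g ground-speed offset of the angular-size law, m/s. The original
#'   law's coefficients were not published with it; the defaults here are
#'   placeholders giving a plausible 0.2-1.5 m/s speed range and should be
#'   set explicitly for quantitative use.
#' @param S_v slope coefficient of the angular-size law, m/s per degree.
#' @param rho_star angular size of peak speed, degrees.
#' @param dt delay on the angular-size input, seconds.
#' @return an object of class `speed_policy`.
#' @export
speed_policy <- function(mode = c("replay", "constant", "boeddeker"),
                         s_const = 1.2, S_g = 0.2, S_v = 0.5,
                         rho_star = 6, dt = 0) {
  mode <- match.arg(mode)
  if (mode == "boeddeker") {
    if (is.null(S_g) || is.null(S_v) || is.null(rho_star) ||
        S_g <= 0 || S_v <= 0 || rho_star <= 0)
      stop("boeddeker mode needs positive S_g, S_v and rho_star")
  }
  if (dt < 0) stop("speed delay must be non-negative")
  structure(list(mode = mode, s_const = s_const, S_g = S_g, S_v = S_v,
                 rho_star = rho_star, dt = dt),
            class = "speed_policy")
}

#' Steering command of a controller
#'
#' Pure evaluation of the steering law on (already delayed) inputs;
#' vectorised over the inputs.
#'
#' @param spec a [controller_spec()].
#' @param theta_E error angle input, degrees (delayed by `dt1` upstream).
#' @param omega_A bearing-rate input, degrees/s (delayed by `dt2` upstream).
#' @param omega_E error-angle rate input, degrees/s (used when `kd > 0`).
#' @return commanded turn rate `Omega_P`, degrees/s.
#' @export
#' @examples
#' bp <- controller_spec("BP", kp = 1, beta = -30)
#' steering_command(bp, theta_E = 30, omega_A = 0)  # equilibrium: 0
steering_command <- function(spec, theta_E, omega_A = 0, omega_E = 0) {
  if (!inherits(spec, "controller_spec")) stop("not a controller_spec")
  switch(spec$strategy,
         PP = ,
         BP = spec$kp * (theta_E + spec$beta) + spec$kd * omega_E,
         PN = spec$N * omega_A,
         MP = spec$kp * (theta_E + spec$beta) + spec$kd * omega_E +
              spec$N * omega_A)
}

#' Forward-speed command of a speed policy
#'
#' @param policy a [speed_policy()].
#' @param rho apparent target angular size in degrees (delayed upstream);
#'   required for `"boeddeker"` mode.
#' @param replay_speed measured speed to pass through in `"replay"` mode.
#' @return forward speed in m/s (vectorised over `rho`/`replay_speed`).
#' @export
speed_command <- function(policy, rho = NULL, replay_speed = NULL) {
  if (!inherits(policy, "speed_policy")) stop("not a speed_policy")
  switch(policy$mode,
         replay = {
           if (is.null(replay_speed)) stop("replay mode needs replay_speed")
           replay_speed
         },
         constant = rep_len(policy$s_const, max(1L, length(rho))),
         boeddeker = {
           if (is.null(rho)) stop("boeddeker mode needs rho")
           if (any(rho <= 0)) stop("rho must be positive")
           ifelse(rho <= 0.5, policy$S_g,
                  rho * policy$S_v * exp(-rho / policy$rho_star) + policy$S_g)
         })
}

check_delays <- function(horizon, ...) {
  d <- c(...)
  if (any(d > horizon))
    stop("controller delay (", max(d), " s) exceeds the simulation horizon (",
         signif(horizon, 4), " s)")
}

#' Closed-loop planar pursuit simulation
#'
#' Simulates a pursuer chasing a moving target in a plane under a steering
#' law, with explicit Euler integration at the target track's frame
#' interval: each frame the controller reads its (delay-interpolated) inputs
#' from the simulation's own history, the heading is advanced by
#' `Omega_P * dt`, and the position by `speed * dt` along the new heading.
#' Delayed inputs are linearly interpolated in the input history and held at
#' their initial value for `t < delay`.
#'
#' @param target n x 2 matrix of target positions in the plane (meters).
#' @param time time stamps (seconds, uniform) for the target track.
#' @param spec a [controller_spec()].
#' @param policy a [speed_policy()].
#' @param init list with `position` (length-2) and `heading` (degrees).
#' @param capture_radius pursuer-target distance below which the chase
#'   counts as a capture (default 10 mm: the 8 mm dummy plus tracking
#'   spread).
#' @param replay_speed measured speed series for `"replay"` policies.
#' @param target_diameter target diameter in meters, for the angular-size
#'   input of the speed law.
#' @param stop_at_capture stop integrating at capture (default) or run the
#'   full horizon (used when comparing trajectories frame by frame).
#' @param omega_max optional saturation of the commanded turn rate,
#'   degrees/s (`Inf` leaves the steering laws pure). Real pursuers cannot
#'   turn arbitrarily fast -- blowfly yaw peaks reach about 7000 deg/s --
#'   so a cap is available for realism studies.
#' @return an object of class `sim_result`: list with `time`, `pursuer`
#'   (n x 2), `target`, `heading` (degrees, unwrapped), `diagnostics` (a
#'   data.frame of per-frame controller inputs and outputs: `theta_A`,
#'   `theta_E`, `omega_A`, `omega_P`, `speed`, `R_A`), `captured`,
#'   `capture_time`, `spec`, `policy`.
#' @export
simulate_planar <- function(target, time, spec,
                            policy = speed_policy("constant"),
                            init, capture_radius = 0.010,
                            replay_speed = NULL, target_diameter = 0.008,
                            stop_at_capture = TRUE, omega_max = Inf) {
  target <- as.matrix(target)
  n <- nrow(target)
  if (length(time) != n) stop("time and target lengths differ")
  if (n < 3L) stop("need at least 3 frames")
  dt <- diff(time[1:2])
  if (dt <= 0) stop("zero or negative frame interval")
  check_delays(time[n] - time[1L], spec$dt1, spec$dt2, policy$dt)
  if (policy$mode == "replay") {
    if (is.null(replay_speed) || length(replay_speed) != n)
      stop("replay policy needs a replay_speed series matching the track")
  }

  pos <- matrix(NA_real_, n, 2)
  heading <- thetaA_raw <- thetaA_u <- thetaE_w <- thetaE_u <-
    omegaA <- omegaE <- omegaP <- rho <- dist <- speed <- numeric(n)

  pos[1L, ] <- init$position
  heading[1L] <- init$heading
  sense <- function(i) {
    L <- target[i, ] - pos[i, ]
    d <- sqrt(sum(L^2))
    dist[i] <<- d
    thetaA_raw[i] <<- atan2d(L[2L], L[1L])
    rho[i] <<- 2 * atan2d(target_diameter / 2, d)
    e <- wrap180(thetaA_raw[i] - heading[i])
    if (i == 1L) {
      thetaA_u[i] <<- thetaA_raw[i]
      thetaE_w[i] <<- e
      thetaE_u[i] <<- e
      omegaA[i] <<- 0
      omegaE[i] <<- 0
    } else {
      dA <- wrap180(thetaA_raw[i] - thetaA_raw[i - 1L])
      thetaA_u[i] <<- thetaA_u[i - 1L] + dA
      omegaA[i] <<- dA / dt
      dE <- wrap180(e - thetaE_w[i - 1L])
      thetaE_w[i] <<- e
      thetaE_u[i] <<- thetaE_u[i - 1L] + dE
      omegaE[i] <<- dE / dt
    }
  }
  sense(1L)

  d1 <- spec$dt1 / dt
  d2 <- spec$dt2 / dt
  ds <- policy$dt / dt
  captured <- FALSE
  capture_time <- NA_real_
  last <- n
  for (i in seq_len(n - 1L)) {
    thE <- wrap180(delayed_value(thetaE_u, i, d1))
    omA <- delayed_value(omegaA, i, d2)
    omE <- delayed_value(omegaE, i, d1)
    omegaP[i] <- clamp_rate(steering_command(spec, thE, omA, omE), omega_max)
    speed[i] <- switch(policy$mode,
                       replay = replay_speed[i],
                       constant = policy$s_const,
                       boeddeker = speed_command(policy,
                                                 rho = delayed_value(rho, i, ds)))
    heading[i + 1L] <- heading[i] + omegaP[i] * dt
    pos[i + 1L, ] <- pos[i, ] +
      speed[i] * dt * c(cosd(heading[i + 1L]), sind(heading[i + 1L]))
    sense(i + 1L)
    if (dist[i + 1L] < capture_radius && !captured) {
      captured <- TRUE
      capture_time <- time[i + 1L]
      if (stop_at_capture) {
        last <- i + 1L
        break
      }
    }
  }
  omegaP[last] <- steering_command(spec,
                                   wrap180(delayed_value(thetaE_u, last, d1)),
                                   delayed_value(omegaA, last, d2),
                                   delayed_value(omegaE, last, d1))
  speed[last] <- speed[max(1L, last - 1L)]
  idx <- seq_len(last)
  structure(list(time = time[idx], pursuer = pos[idx, , drop = FALSE],
                 target = target[idx, , drop = FALSE],
                 heading = heading[idx],
                 diagnostics = data.frame(time = time[idx],
                                          theta_A = thetaA_raw[idx],
                                          theta_E = thetaE_w[idx],
                                          omega_A = omegaA[idx],
                                          omega_P = omegaP[idx],
                                          speed = speed[idx],
                                          R_A = dist[idx]),
                 captured = captured, capture_time = capture_time,
                 spec = spec, policy = policy),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result %s: %d frames, %s>\n",
              x$spec$strategy %||% "", length(x$time),
              if (isTRUE(x$captured))
                sprintf("capture at %.3f s", x$capture_time)
              else "no capture"))
  invisible(x)
}

# Initial position and heading of the measured pursuer. Heading comes from
# the first displacement (forward difference), matching the integrator
# convention that the step away from frame i carries the heading commanded
# at frame i. Smooth noisy tracks with smooth_track() before relying on
# these estimates.
track_init <- function(track) {
  d <- track$pursuer[2L, ] - track$pursuer[1L, ]
  vh <- sqrt(d[1L]^2 + d[2L]^2)
  list(position = track$pursuer[1L, ],
       heading_h = atan2d(d[2L], d[1L]),
       heading_v = atan2d(d[3L], vh))
}

# Measured pursuer speed series (m/s) for replay policies: speed over the
# step i -> i+1 assigned to frame i (the frame whose command drives that
# step), last frame repeated. Horizontal: |d(x, y)|/dt; vertical-plane
# (x', z) speed equals the full 3D speed because dx'/dt is the horizontal
# speed.
replay_speeds <- function(track) {
  dt <- 1 / track$frame_rate
  D <- diff(track$pursuer) / dt
  pad <- function(v) c(v, v[length(v)])
  vh <- sqrt(D[, 1L]^2 + D[, 2L]^2)
  v3 <- sqrt(vh^2 + D[, 3L]^2)
  list(horizontal = pad(vh), vertical = pad(v3), full = pad(v3))
}

# The vertical-plane pursuit problem extracted from a measured track: the
# pursuer lives in (x', z) where x' is its cumulative horizontal path
# length, and the target sits at abscissa x'_P(t) + horizontal range so that
# the planar bearing elevation reproduces theta_AV of the 3D geometry.
vertical_plane_problem <- function(track) {
  xp <- compute_x_prime(track)
  L <- track$target - track$pursuer
  rangeH <- sqrt(L[, 1L]^2 + L[, 2L]^2)
  list(target = cbind(xp + rangeH, track$target[, 3L]),
       pursuer = cbind(xp, track$pursuer[, 3L]))
}

#' Closed-loop 3D pursuit simulation against a recorded chase
#'
#' Simulates a virtual fly chasing the target of a recorded
#' [pursuit_track()], with independent steering controllers for the
#' horizontal and the vertical plane. Initial position and heading are taken
#' from the start of the measured pursuer track, and `"replay"` speed
#' policies copy the measured pursuer's instantaneous speed.
#'
#' Two modes:
#' \describe{
#'   \item{decoupled}{the horizontal controller runs in the (x, y) plane
#'     against the recorded target; the vertical controller runs in the
#'     (x', z) plane, where x' is cumulative horizontal path length and the
#'     target's abscissa is the measured pursuer's x' plus the current
#'     horizontal range (this preserves the bearing elevation of the 3D
#'     geometry). The two planar solutions are combined into one 3D
#'     trajectory.}
#'   \item{coupled}{a single 3D state (azimuth and elevation heading) is
#'     driven by both commanded turn rates and one 3D speed.}
#' }
#'
#' @param track a [pursuit_track()] providing the target and the measured
#'   pursuer (for initial conditions and replay speed).
#' @param h_spec,v_spec [controller_spec()] for the horizontal and vertical
#'   plane.
#' @param policy a [speed_policy()].
#' @param mode `"decoupled"` or `"coupled"`.
#' @param capture_radius capture distance, meters (3D).
#' @param stop_at_capture stop integrating at capture.
#' @param init optional list with `position` (xyz), `heading_h`,
#'   `heading_v`; defaults to the start of the measured track.
#' @return a `sim_result` whose `pursuer` is n x 3 and which carries the
#'   simulated chase as `$track` (a [pursuit_track()]) when it is at least
#'   3 frames long; `diagnostics` holds per-frame inputs/outputs for both
#'   planes (columns suffixed `_H` and `_V`).
#' @export
simulate_3d <- function(track, h_spec, v_spec,
                        policy = speed_policy("replay"),
                        mode = c("decoupled", "coupled"),
                        capture_radius = 0.010, stop_at_capture = TRUE,
                        init = NULL) {
  if (!inherits(track, "pursuit_track")) stop("not a pursuit_track")
  mode <- match.arg(mode)
  n <- length(track$time)
  ini <- track_init(track)
  if (!is.null(init)) ini[names(init)] <- init
  sp <- replay_speeds(track)

  if (mode == "coupled") {
    res <- sim3d_core(track$target, track$time, h_spec, v_spec, policy,
                      replay_speed = sp$full,
                      init_pos = ini$position, init_h = ini$heading_h,
                      init_v = ini$heading_v,
                      capture_radius = capture_radius,
                      stop_at_capture = stop_at_capture)
  } else {
    hsim <- simulate_planar(track$target[, 1:2], track$time, h_spec, policy,
                            init = list(position = ini$position[1:2],
                                        heading = ini$heading_h),
                            capture_radius = capture_radius,
                            replay_speed = sp$horizontal,
                            stop_at_capture = FALSE)
    vp <- vertical_plane_problem(track)
    vsim <- simulate_planar(vp$target, track$time, v_spec, policy,
                            init = list(position = vp$pursuer[1L, ],
                                        heading = ini$heading_v),
                            capture_radius = capture_radius,
                            replay_speed = sp$vertical,
                            stop_at_capture = FALSE)
    m <- min(nrow(hsim$pursuer), nrow(vsim$pursuer))
    pursuer <- cbind(hsim$pursuer[1:m, ], vsim$pursuer[1:m, 2L])
    dist3 <- sqrt(rowSums((pursuer - track$target[1:m, ])^2))
    hit <- which(dist3 < capture_radius)
    captured <- length(hit) > 0L
    last <- if (captured && stop_at_capture) hit[1L] else m
    idx <- seq_len(last)
    diag_h <- hsim$diagnostics[idx, ]
    diag_v <- vsim$diagnostics[idx, ]
    names(diag_h)[-1L] <- paste0(names(diag_h)[-1L], "_H")
    names(diag_v)[-1L] <- paste0(names(diag_v)[-1L], "_V")
    res <- structure(list(time = track$time[idx],
                          pursuer = pursuer[idx, , drop = FALSE],
                          target = track$target[idx, , drop = FALSE],
                          heading = cbind(h = hsim$heading[idx],
                                          v = vsim$heading[idx]),
                          diagnostics = cbind(diag_h, diag_v[-1L]),
                          captured = captured,
                          capture_time = if (captured) track$time[hit[1L]] else NA_real_,
                          spec = list(h = h_spec, v = v_spec),
                          policy = policy),
                     class = "sim_result")
  }
  if (nrow(res$pursuer) >= 3L) {
    res$track <- pursuit_track(res$time, res$pursuer,
                               track$target[seq_len(nrow(res$pursuer)), ],
                               chase_id = paste0(track$chase_id, "_sim"),
                               frame_rate = track$frame_rate)
  }
  res
}

# Shared coupled-3D integrator (also drives the synthetic-chase generator).
sim3d_core <- function(target, time, h_spec, v_spec, policy, replay_speed,
                       init_pos, init_h, init_v, capture_radius = 0.010,
                       stop_at_capture = TRUE, target_diameter = 0.008,
                       omega_max = Inf) {
  target <- as.matrix(target)
  n <- nrow(target)
  dt <- diff(time[1:2])
  if (dt <= 0) stop("zero or negative frame interval")
  check_delays(time[n] - time[1L], h_spec$dt1, h_spec$dt2,
               v_spec$dt1, v_spec$dt2, policy$dt)
  if (policy$mode == "replay" &&
      (is.null(replay_speed) || length(replay_speed) != n))
    stop("replay policy needs a replay_speed series matching the track")

  pos <- matrix(NA_real_, n, 3L)
  hh <- vv <- thAH_raw <- thAH_u <- thAV <- thEH_w <- thEH_u <- thEV <-
    omAH <- omAV <- omEH <- omEV <- omPH <- omPV <- rho <- dist <-
    speed <- numeric(n)
  pos[1L, ] <- init_pos
  hh[1L] <- init_h
  vv[1L] <- init_v

  sense <- function(i) {
    L <- target[i, ] - pos[i, ]
    lh <- sqrt(L[1L]^2 + L[2L]^2)
    d <- sqrt(lh^2 + L[3L]^2)
    dist[i] <<- d
    thAH_raw[i] <<- atan2d(L[2L], L[1L])
    thAV[i] <<- atan2d(L[3L], lh)
    rho[i] <<- 2 * atan2d(target_diameter / 2, d)
    eh <- wrap180(thAH_raw[i] - hh[i])
    thEV[i] <<- thAV[i] - vv[i]
    if (i == 1L) {
      thAH_u[i] <<- thAH_raw[i]
      thEH_w[i] <<- eh
      thEH_u[i] <<- eh
    } else {
      dA <- wrap180(thAH_raw[i] - thAH_raw[i - 1L])
      thAH_u[i] <<- thAH_u[i - 1L] + dA
      omAH[i] <<- dA / dt
      omAV[i] <<- (thAV[i] - thAV[i - 1L]) / dt
      dE <- wrap180(eh - thEH_w[i - 1L])
      thEH_w[i] <<- eh
      thEH_u[i] <<- thEH_u[i - 1L] + dE
      omEH[i] <<- dE / dt
      omEV[i] <<- (thEV[i] - thEV[i - 1L]) / dt
    }
  }
  sense(1L)

  d1h <- h_spec$dt1 / dt; d2h <- h_spec$dt2 / dt
  d1v <- v_spec$dt1 / dt; d2v <- v_spec$dt2 / dt
  ds <- policy$dt / dt
  captured <- FALSE
  capture_time <- NA_real_
  last <- n
  for (i in seq_len(n - 1L)) {
    omPH[i] <- clamp_rate(steering_command(h_spec,
                                           wrap180(delayed_value(thEH_u, i, d1h)),
                                           delayed_value(omAH, i, d2h),
                                           delayed_value(omEH, i, d1h)), omega_max)
    omPV[i] <- clamp_rate(steering_command(v_spec,
                                           delayed_value(thEV, i, d1v),
                                           delayed_value(omAV, i, d2v),
                                           delayed_value(omEV, i, d1v)), omega_max)
    speed[i] <- switch(policy$mode,
                       replay = replay_speed[i],
                       constant = policy$s_const,
                       boeddeker = speed_command(policy,
                                                 rho = delayed_value(rho, i, ds)))
    hh[i + 1L] <- hh[i] + omPH[i] * dt
    # keep the elevation off the zenith singularity, where azimuth heading
    # degenerates; no real pursuer flies perfectly vertically
    vv[i + 1L] <- max(-85, min(85, vv[i] + omPV[i] * dt))
    step <- speed[i] * dt
    pos[i + 1L, ] <- pos[i, ] + step * c(cosd(vv[i + 1L]) * cosd(hh[i + 1L]),
                                         cosd(vv[i + 1L]) * sind(hh[i + 1L]),
                                         sind(vv[i + 1L]))
    sense(i + 1L)
    if (dist[i + 1L] < capture_radius && !captured) {
      captured <- TRUE
      capture_time <- time[i + 1L]
      if (stop_at_capture) {
        last <- i + 1L
        break
      }
    }
  }
  idx <- seq_len(last)
  structure(list(time = time[idx], pursuer = pos[idx, , drop = FALSE],
                 target = target[idx, , drop = FALSE],
                 heading = cbind(h = hh[idx], v = vv[idx]),
                 diagnostics = data.frame(time = time[idx],
                                          theta_E_H = thEH_w[idx],
                                          theta_E_V = thEV[idx],
                                          omega_A_H = omAH[idx],
                                          omega_A_V = omAV[idx],
                                          omega_P_H = omPH[idx],
                                          omega_P_V = omPV[idx],
                                          speed = speed[idx],
                                          R_A = dist[idx]),
                 captured = captured, capture_time = capture_time,
                 spec = list(h = h_spec, v = v_spec), policy = policy),
            class = "sim_result")
}
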