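#' Angular observables of a pursuit
#'
#' Converts a [pursuit_track()] into the angular description of the chase.
#' The line of flight (LOF) connects consecutive pursuer positions and is
#' equivalent to the pursuer's velocity direction; its spherical angles are
#' the heading angles `theta_PH` (azimuth) and `theta_PV` (elevation). The
#' line of sight (LOS) connects pursuer to target; its angles are the
#' bearing angles `theta_AH`, `theta_AV`. The error angles (egocentric
#' target direction) are their difference,
#' `theta_E = theta_A - theta_P`, with the azimuth component wrapped into
#' (-180, 180].
#'
#' Azimuths are measured counter-clockwise from the +x axis; elevations are
#' `atan2(dz, horizontal displacement)` in \[-90, 90\] degrees. With 5 mm
#' reconstruction noise at 190 Hz, raw frame-to-frame displacements are
#' useless for heading, so the pursuer velocity is estimated with a
#' zero-phase Savitzky-Golay derivative filter and positions entering the
#' LOS are smoothed with the matching zero-phase filter; both are
#' configurable and can be disabled (`deriv_window = 0`) for clean data.
#'
#' @param track a [pursuit_track()].
#' @param target_diameter physical target diameter in meters (an 8 mm dummy
#'   sphere by default); only used for the apparent angular size `rho`.
#' @param deriv_window Savitzky-Golay window (frames, odd) for the velocity
#'   estimate; `0` or `1` falls back to raw finite differences.
#' @param smooth_window Savitzky-Golay window for smoothing positions before
#'   the LOS computation; `0` disables.
#' @param smooth_order polynomial order of both filters.
#' @param mirror if `TRUE`, the scene is mirrored (y negated) before
#'   analysis, the conventional normalisation that maps all chases onto a
#'   target rotating anticlockwise.
#' @return a data.frame of class `angle_series` with one row per frame:
#'   `time`, `theta_PH`, `theta_PV`, `theta_AH`, `theta_AV`, `theta_EH`,
#'   `theta_EV` (degrees), `R_A` (pursuer-target distance, m), `R_P`
#'   (pursuer speed, m/s), `x_prime` (cumulative horizontal path length, m),
#'   `rho` (target angular size, degrees), `held` (logical: heading carried
#'   over from the last moving frame). Attributes record `frame_rate`,
#'   `chase_id` and the filter settings.
#' @export
compute_angles <- function(track, target_diameter = 0.008,
                           deriv_window = 31L, smooth_window = 31L,
                           smooth_order = 2L, mirror = FALSE) {
  if (!inherits(track, "pursuit_track")) stop("not a pursuit_track")
  if (target_diameter <= 0) stop("target_diameter must be positive")
  n <- length(track$time)
  dt <- 1 / track$frame_rate
  P <- track$pursuer
  G <- track$target
  if (mirror) {
    P[, 2] <- -P[, 2]
    G[, 2] <- -G[, 2]
  }

  Ps <- apply(P, 2, sg_smooth, window = smooth_window, order = smooth_order)
  Gs <- apply(G, 2, sg_smooth, window = smooth_window, order = smooth_order)

  # LOF: velocity estimate per coordinate
  if (deriv_window > 1L) {
    V <- apply(P, 2, sg_deriv, window = deriv_window, order = smooth_order, dt = dt)
  } else {
    # displacement (i-1) -> i assigned to frame i: the heading at frame i is
    # the direction the pursuer arrived along
    V <- apply(P, 2, function(col) {
      d <- diff(col) / dt
      c(d[1L], d)
    })
  }
  vh <- sqrt(V[, 1]^2 + V[, 2]^2)
  speed <- sqrt(vh^2 + V[, 3]^2)
  # azimuth is undefined without horizontal displacement (stationary or
  # purely vertical flight); elevation only for a fully stationary pursuer
  az_ok <- vh > 1e-12
  el_ok <- speed > 1e-12
  theta_PH <- atan2d(V[, 2], V[, 1])
  theta_PV <- atan2d(V[, 3], vh)
  held <- !az_ok
  if (!any(az_ok)) stop("pursuer has no horizontal displacement; azimuth heading undefined throughout")
  hold_last <- function(x, ok) {
    first_ok <- which(ok)[1L]
    if (first_ok > 1L) x[seq_len(first_ok - 1L)] <- x[first_ok]
    for (i in seq_len(length(x))[-seq_len(first_ok)])
      if (!ok[i]) x[i] <- x[i - 1L]
    x
  }
  theta_PH <- hold_last(theta_PH, az_ok)
  theta_PV <- hold_last(theta_PV, el_ok)

  # LOS
  L <- Gs - Ps
  lh <- sqrt(L[, 1]^2 + L[, 2]^2)
  R_A <- sqrt(lh^2 + L[, 3]^2)
  theta_AH <- atan2d(L[, 2], L[, 1])
  theta_AV <- atan2d(L[, 3], lh)

  theta_EH <- wrap180(theta_AH - theta_PH)
  theta_EV <- theta_AV - theta_PV

  x_prime <- c(0, cumsum(sqrt(diff(Ps[, 1])^2 + diff(Ps[, 2])^2)))
  rho <- 2 * atan2d(target_diameter / 2, R_A)

  out <- data.frame(time = track$time,
                    theta_PH = theta_PH, theta_PV = theta_PV,
                    theta_AH = theta_AH, theta_AV = theta_AV,
                    theta_EH = theta_EH, theta_EV = theta_EV,
                    R_A = R_A, R_P = speed, x_prime = x_prime,
                    rho = rho, held = held)
  attr(out, "frame_rate") <- track$frame_rate
  attr(out, "chase_id") <- track$chase_id
  attr(out, "deriv_window") <- deriv_window
  attr(out, "smooth_window") <- smooth_window
  attr(out, "smooth_order") <- smooth_order
  class(out) <- c("angle_series", "data.frame")
  out
}

#' Cumulative horizontal displacement of the pursuer
#'
#' The abscissa of the vertical-plane representation: the horizontal path
#' length accumulated along the pursuer's (x, y) trajectory,
#' `x'(n) = sum over k <= n of hypot(dx_k, dy_k)`, with `x'(1) = 0`.
#' Computed on the raw coordinates; it is non-decreasing by construction.
#'
#' @param track a [pursuit_track()], or an n x >=2 matrix of positions.
#' @return numeric vector of cumulative horizontal path length, meters.
#' @export
compute_x_prime <- function(track) {
  P <- if (inherits(track, "pursuit_track")) track$pursuer else as.matrix(track)
  c(0, cumsum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)))
}

#' Angular rates of a pursuit
#'
#' First temporal derivatives of the six pursuit angles. Azimuth series are
#' unwrapped before differentiation; all series may be Savitzky-Golay
#' smoothed first; derivatives are central differences with one-sided ends.
#'
#' @param angles an `angle_series` from [compute_angles()].
#' @param smooth_window smoothing window in frames (odd); `0` disables.
#' @param smooth_order polynomial order of the smoother.
#' @return a data.frame of class `rate_series` with columns `time`,
#'   `omega_PH`, `omega_PV`, `omega_AH`, `omega_AV`, `omega_EH`, `omega_EV`
#'   in degrees per second, carrying the same attributes as the input.
#' @export
compute_rates <- function(angles, smooth_window = 5L, smooth_order = 2L) {
  if (!inherits(angles, "angle_series")) stop("not an angle_series")
  n <- nrow(angles)
  if (smooth_window > 1L && n < smooth_window)
    stop("series shorter than the smoothing window")
  dtv <- diff(angles$time)
  if (max(abs(dtv / stats::median(dtv) - 1)) > 0.01)
    stop("compute_rates needs a uniform time base; resample first")
  dt <- stats::median(dtv)

  rate_of <- function(x, azimuth) {
    if (azimuth) x <- unwrap_deg(x)
    x <- sg_smooth(x, smooth_window, smooth_order)
    gradient_uniform(x, dt)
  }
  out <- data.frame(time = angles$time,
                    omega_PH = rate_of(angles$theta_PH, TRUE),
                    omega_PV = rate_of(angles$theta_PV, FALSE),
                    omega_AH = rate_of(angles$theta_AH, TRUE),
                    omega_AV = rate_of(angles$theta_AV, FALSE),
                    omega_EH = rate_of(angles$theta_EH, TRUE),
                    omega_EV = rate_of(angles$theta_EV, FALSE))
  for (a in c("frame_rate", "chase_id")) attr(out, a) <- attr(angles, a)
  attr(out, "rate_smooth_window") <- smooth_window
  attr(out, "rate_smooth_order") <- smooth_order
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Detect body saccades in the yaw-rate trace
#'
#' Body saccades are brief, very fast yaw rotations; in blowfly pursuit they
#' reach several thousand degrees per second and are accompanied by a dip in
#' forward speed (a coordinated turn). Contiguous runs of
#' `|omega_PH| > threshold` are reported as events, each with its peak rate,
#' peak time, and the time of the forward-speed minimum in a window around
#' the event; `speed_lead` is positive when the deceleration precedes the
#' yaw peak.
#'
#' @param rates a `rate_series` from [compute_rates()].
#' @param speed forward-speed series (m/s) aligned with `rates` (e.g. the
#'   `R_P` column of the matching `angle_series`).
#' @param threshold yaw-rate threshold in degrees/s (default 1500).
#' @param search_window half-width, in seconds, of the speed-minimum search
#'   window around each event.
#' @return a data.frame with one row per saccade: `onset_time`,
#'   `offset_time`, `peak_time`, `peak_rate`, `speed_min_time`,
#'   `speed_lead`. Zero rows when no event crosses the threshold.
#' @export
extract_saccades <- function(rates, speed, threshold = 1500,
                             search_window = 0.05) {
  if (!inherits(rates, "rate_series")) stop("not a rate_series")
  if (length(speed) != nrow(rates))
    stop("speed series must align with the rate series")
  w <- abs(rates$omega_PH) > threshold
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  time <- rates$time
  rows <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- i0:i1
    pk <- seg[which.max(abs(rates$omega_PH[seg]))]
    win <- which(time >= time[i0] - search_window &
                 time <= time[i1] + search_window)
    sm <- win[which.min(speed[win])]
    data.frame(onset_time = time[i0], offset_time = time[i1],
               peak_time = time[pk], peak_rate = rates$omega_PH[pk],
               speed_min_time = time[sm],
               speed_lead = time[pk] - time[sm])
  })
  if (!length(rows))
    return(data.frame(onset_time = numeric(0), offset_time = numeric(0),
                      peak_time = numeric(0), peak_rate = numeric(0),
                      speed_min_time = numeric(0), speed_lead = numeric(0)))
  do.call(rbind, rows)
}
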