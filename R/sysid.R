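#' Lag-scanned linear fit between two signals
#'
#' For each candidate delay, shifts the input back in time by that delay
#' (linear interpolation between frames), fits ordinary least squares
#' `y = gain * x(t - delay) + intercept` over the valid overlap, and records
#' the Pearson correlation R. The fit with maximum `|R|` is returned; ties
#' are broken toward the smallest delay. Negative delays (the output leading
#' the input) are allowed for lead analysis.
#'
#' Multiple chases are supported by passing lists of per-chase vectors: the
#' shift is applied within each chase and the shifted pairs are pooled into
#' one fit per delay, so frames never leak across chase boundaries.
#'
#' @param x input signal: numeric vector, or list of per-chase vectors.
#' @param y output signal, matching `x` in shape.
#' @param frame_rate sampling rate, Hz.
#' @param delays candidate delays in seconds; default 0-50 ms in one-frame
#'   steps.
#' @param min_overlap smallest number of pooled pairs for a delay to be
#'   fitted; delays with fewer are skipped.
#' @param trim number of frames dropped at both ends of every chase before
#'   fitting. Series differentiated with finite-window filters carry much
#'   larger noise near their ends, where the filters become one-sided;
#'   trimming half a filter window removes those frames.
#' @param mask optional logical vector (or list of per-chase vectors)
#'   marking frames eligible for fitting; pairs whose output frame or
#'   shifted input frame is masked out are dropped.
#' @param refine if `TRUE`, the delay is refined below frame resolution by a
#'   parabolic interpolation of R around the grid peak, and the fit is
#'   recomputed at the refined delay.
#' @return an object of class `lag_fit`: list with `gain`, `intercept`,
#'   `delay` (seconds), `R`, `n`, `delays` (the scanned grid), `R_profile`
#'   (R at each scanned delay, `NA` where skipped).
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 190)
#' x <- sin(2 * pi * t)
#' f <- lag_scan_fit(x, 5 * x, frame_rate = 190)
#' c(f$gain, f$delay, f$R)
lag_scan_fit <- function(x, y, frame_rate, delays = NULL,
                         min_overlap = 10L, refine = FALSE, trim = 0L,
                         mask = NULL) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  if (length(x) != length(y) ||
      any(lengths(x) != lengths(y)))
    stop("x and y must have matching chases and lengths")
  if (is.null(mask)) {
    mask <- lapply(x, function(v) rep(TRUE, length(v)))
  } else {
    if (!is.list(mask)) mask <- list(mask)
    if (any(lengths(mask) != lengths(x)))
      stop("mask must match x in chases and lengths")
  }
  if (trim > 0L) {
    for (k in seq_along(mask)) {
      n <- length(mask[[k]])
      if (n > 2L * trim + 4L)
        mask[[k]][c(seq_len(trim), (n - trim + 1L):n)] <- FALSE
    }
  }
  dt <- 1 / frame_rate
  if (is.null(delays)) delays <- seq(0, 0.050, by = dt)

  fit_at <- function(d) {
    shift <- d / dt
    xs <- ys <- vector("list", length(x))
    for (k in seq_along(x)) {
      nk <- length(x[[k]])
      idx <- seq_len(nk) - shift
      xv <- stats::approx(seq_len(nk), x[[k]], xout = idx, rule = 1)$y
      src <- pmin(pmax(round(idx), 1L), nk)
      ok <- !is.na(xv) & mask[[k]] & mask[[k]][src]
      xs[[k]] <- xv[ok]
      ys[[k]] <- y[[k]][ok]
    }
    xs <- unlist(xs); ys <- unlist(ys)
    if (length(xs) < min_overlap || stats::sd(xs) == 0) return(NULL)
    g <- stats::cov(xs, ys) / stats::var(xs)
    list(gain = g, intercept = mean(ys) - g * mean(xs),
         R = stats::cor(xs, ys), n = length(xs))
  }

  ord <- order(delays)
  R_profile <- rep(NA_real_, length(delays))
  best <- NULL
  best_d <- NA_real_
  for (j in ord) {
    f <- fit_at(delays[j])
    if (is.null(f)) next
    R_profile[j] <- f$R
    if (is.null(best) || abs(f$R) > abs(best$R)) {
      best <- f
      best_d <- delays[j]
    }
  }
  if (is.null(best)) stop("no delay had enough overlap to fit")

  if (refine) {
    j <- which(delays == best_d)
    jo <- match(j, ord)
    if (jo > 1L && jo < length(ord)) {
      jm <- ord[jo - 1L]; jp <- ord[jo + 1L]
      if (!is.na(R_profile[jm]) && !is.na(R_profile[jp])) {
        r0 <- abs(R_profile[jm]); r1 <- abs(R_profile[j]); r2 <- abs(R_profile[jp])
        den <- r0 - 2 * r1 + r2
        if (den < 0) {
          off <- 0.5 * (r0 - r2) / den
          d_ref <- best_d + off * (delays[jp] - delays[jm]) / 2
          f <- fit_at(d_ref)
          if (!is.null(f) && abs(f$R) >= abs(best$R)) {
            best <- f
            best_d <- d_ref
          }
        }
      }
    }
  }
  structure(c(best, list(delay = best_d, delays = delays,
                         R_profile = R_profile)),
            class = "lag_fit")
}

#' @export
print.lag_fit <- function(x, ...) {
  cat(sprintf("<lag_fit: gain = %.4g, delay = %.1f ms, R = %.3f, n = %d>\n",
              x$gain, 1000 * x$delay, x$R, x$n))
  invisible(x)
}

#' Identify candidate steering controllers from chase data
#'
#' Runs [lag_scan_fit()] of the steering output `Omega_P` against each of
#' the four candidate inputs -- the error angle `theta_E`, the bearing angle
#' `theta_A`, and their rates `Omega_E` and `Omega_A` -- pooling frames
#' across chases. A fit whose input actually drives the steering shows a
#' strong linear correlation at its sensorimotor delay; fits are flagged
#' `accepted` at `|R| >= 0.7`, the conventional cut used for these data.
#'
#' @param angles an `angle_series` or list of them (one per chase).
#' @param rates the matching `rate_series` or list.
#' @param plane `"horizontal"` or `"vertical"`.
#' @param delays candidate delays in seconds (default 0-50 ms by frame).
#' @param accept_R acceptance threshold on `|R|`.
#' @param trim frames dropped at both ends of every chase before fitting;
#'   defaults to half the velocity-filter window of the angle series, where
#'   the zero-phase filters become one-sided and noisy.
#' @param min_range frames where the relevant range falls below this
#'   (meters) are excluded from the fits (0 disables). For the horizontal
#'   plane the relevant range is the *horizontal* pursuer-target distance:
#'   when the target sits nearly overhead the azimuthal bearing becomes
#'   singular and can sweep hundreds of degrees per frame without any
#'   physical motion to match; for the vertical plane it is the full 3D
#'   range. The 2 cm default is where a ~2.5 m/s relative speed at 190 Hz
#'   can still rotate the line of sight by tens of degrees per frame.
#' @param rate_limit physiological yaw-rate ceiling, degrees/s (`NULL`
#'   disables). Frames where the measured `|Omega_P|` reaches 95% of this
#'   ceiling are excluded: there the steering output is saturated, not
#'   proportional to any input, and regressing through censored output
#'   biases every gain toward zero. Independently, frames around any
#'   heading step larger than a quarter turn per frame are excluded (with
#'   a two-frame margin for the differentiation support): a sampled
#'   heading that moves more than 90 degrees between frames is within
#'   folding ambiguity of the half-turn-per-frame limit, so its rate
#'   cannot be trusted.
#' @param ... passed to [lag_scan_fit()] (e.g. `refine = TRUE`).
#' @return an object of class `controller_id`: a named list of `lag_fit`
#'   objects (`theta_E`, `theta_A`, `omega_E`, `omega_A`), each with an
#'   `accepted` flag, plus attributes recording the plane and the smoothing
#'   settings the series were computed with.
#' @export
identify_controllers <- function(angles, rates,
                                 plane = c("horizontal", "vertical"),
                                 delays = NULL, accept_R = 0.7,
                                 trim = NULL, min_range = 0.02,
                                 rate_limit = 7000, ...) {
  plane <- match.arg(plane)
  if (inherits(angles, "angle_series")) angles <- list(angles)
  if (inherits(rates, "rate_series")) rates <- list(rates)
  if (length(angles) != length(rates)) stop("angles and rates must pair up")
  sfx <- if (plane == "horizontal") "H" else "V"
  frame_rate <- attr(angles[[1L]], "frame_rate")
  if (is.null(trim)) {
    w <- max(attr(angles[[1L]], "deriv_window") %||% 0,
             attr(angles[[1L]], "smooth_window") %||% 0)
    trim <- ceiling(w / 2)
  }
  omP <- lapply(rates, `[[`, paste0("omega_P", sfx))
  thP <- lapply(angles, `[[`, paste0("theta_P", sfx))
  mask <- lapply(seq_along(angles), function(k) {
    rng <- if (plane == "horizontal") {
      angles[[k]]$R_A * cosd(angles[[k]]$theta_AV)
    } else {
      angles[[k]]$R_A
    }
    m <- rng > min_range
    if (!is.null(rate_limit)) m <- m & abs(omP[[k]]) < 0.95 * rate_limit
    jump <- which(abs(wrap180(diff(thP[[k]]))) > 90)
    if (length(jump)) {
      drop <- unique(pmin(pmax(rep(jump, each = 5) + (-2):2 + 1, 1),
                          length(m)))
      m[drop] <- FALSE
    }
    m
  })
  get_a <- function(v) lapply(angles, `[[`, paste0(v, sfx))
  get_r <- function(v) lapply(rates, `[[`, paste0(v, sfx))
  yy <- get_r("omega_P")
  fits <- list(
    theta_E = lag_scan_fit(get_a("theta_E"), yy, frame_rate, delays,
                           trim = trim, mask = mask, ...),
    theta_A = lag_scan_fit(get_a("theta_A"), yy, frame_rate, delays,
                           trim = trim, mask = mask, ...),
    omega_E = lag_scan_fit(get_r("omega_E"), yy, frame_rate, delays,
                           trim = trim, mask = mask, ...),
    omega_A = lag_scan_fit(get_r("omega_A"), yy, frame_rate, delays,
                           trim = trim, mask = mask, ...))
  for (nm in names(fits)) fits[[nm]]$accepted <- abs(fits[[nm]]$R) >= accept_R
  attr(fits, "plane") <- plane
  attr(fits, "accept_R") <- accept_R
  attr(fits, "smoothing") <- list(
    deriv_window = attr(angles[[1L]], "deriv_window"),
    smooth_window = attr(angles[[1L]], "smooth_window"),
    rate_smooth_window = attr(rates[[1L]], "rate_smooth_window"))
  class(fits) <- "controller_id"
  fits
}

#' @export
print.controller_id <- function(x, ...) {
  cat(sprintf("Steering-input identification (%s plane):\n", attr(x, "plane")))
  for (nm in names(x)) {
    f <- x[[nm]]
    cat(sprintf("  Omega_P ~ %-8s gain %8.3g  delay %5.1f ms  R %6.3f %s\n",
                nm, f$gain, 1000 * f$delay, f$R,
                if (isTRUE(f$accepted)) "*" else ""))
  }
  sm <- attr(x, "smoothing")
  cat(sprintf("  (velocity window %s, position window %s, rate window %s frames)\n",
              sm$deriv_window, sm$smooth_window, sm$rate_smooth_window))
  invisible(x)
}

#' Speed-coupling relations
#'
#' Lag-scanned fits of the pursuer's horizontal forward speed against the
#' yaw-rate magnitude `|Omega_PH|` (saccade/speed coupling; negative delays
#' allowed, a negative best delay meaning the deceleration leads the turn),
#' the error angle `theta_EH`, its rate `Omega_EH`, and the target angular
#' size `rho` (the input of the angular-size speed law).
#'
#' @param angles an `angle_series` or list of them.
#' @param rates the matching `rate_series` or list.
#' @param delays candidate delays in seconds; default -50 to 50 ms by frame.
#' @param ... passed to [lag_scan_fit()].
#' @return a named list of `lag_fit` objects (`abs_omega_PH`, `theta_EH`,
#'   `omega_EH`, `rho`) plus `scatter`, a data.frame of pooled
#'   (rho, speed) pairs for overlaying the angular-size law.
#' @export
speed_relations <- function(angles, rates, delays = NULL, ...) {
  if (inherits(angles, "angle_series")) angles <- list(angles)
  if (inherits(rates, "rate_series")) rates <- list(rates)
  frame_rate <- attr(angles[[1L]], "frame_rate")
  dt <- 1 / frame_rate
  if (is.null(delays)) delays <- seq(-0.050, 0.050, by = dt)
  hspeed <- lapply(angles, function(a) {
    c(diff(a$x_prime), NA)[seq_len(nrow(a))] / dt
  })
  hspeed <- lapply(hspeed, function(s) { s[length(s)] <- s[length(s) - 1L]; s })
  fits <- list(
    abs_omega_PH = lag_scan_fit(lapply(rates, function(r) abs(r$omega_PH)),
                                hspeed, frame_rate, delays, ...),
    theta_EH = lag_scan_fit(lapply(angles, `[[`, "theta_EH"), hspeed,
                            frame_rate, delays, ...),
    omega_EH = lag_scan_fit(lapply(rates, `[[`, "omega_EH"), hspeed,
                            frame_rate, delays, ...),
    rho = lag_scan_fit(lapply(angles, `[[`, "rho"), hspeed,
                       frame_rate, delays, ...))
  fits$scatter <- data.frame(rho = unlist(lapply(angles, `[[`, "rho")),
                             speed = unlist(hspeed))
  fits
}

#' Fit the angular-size speed law to (rho, speed) data
#'
#' Nonlinear least-squares refit of the piecewise speed law
#' `s = S_g` for `rho <= 0.5` degrees and
#' `s = rho * S_v * exp(-rho / rho_star) + S_g` above, using
#' Levenberg-Marquardt.
#'
#' @param rho target angular size, degrees.
#' @param speed forward speed, m/s.
#' @param start optional named list of starting values
#'   (`S_g`, `S_v`, `rho_star`); data-driven defaults otherwise.
#' @return the fitted model object (class `nls`); coefficients are
#'   `S_g`, `S_v`, `rho_star`.
#' @export
fit_boeddeker <- function(rho, speed, start = NULL) {
  ok <- is.finite(rho) & is.finite(speed)
  rho <- rho[ok]; speed <- speed[ok]
  if (is.null(start)) {
    pk <- rho[which.max(speed)]
    start <- list(S_g = max(min(speed), 1e-3),
                  S_v = max((max(speed) - min(speed)) * exp(1) / max(pk, 1), 0.01),
                  rho_star = max(pk, 1))
  }
  minpack.lm::nlsLM(
    speed ~ ifelse(rho <= 0.5, S_g, rho * S_v * exp(-rho / rho_star) + S_g),
    start = start,
    lower = c(S_g = 0, S_v = 0, rho_star = 0.1),
    data = data.frame(rho = rho, speed = speed))
}
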