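#' Wrap angles into (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
#' @examples
#' wrap180(c(190, -190, 180, -180, 720))
wrap180 <- function(x) {
  w <- ((x %% 360) + 360) %% 360
  ifelse(w > 180, w - 360, w)
}

#' Unwrap an azimuth series (degrees)
#'
#' Removes +-360 degree jumps so the series can be differentiated.
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped series; first element unchanged.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  adj <- cumsum(round(d / 360)) * 360
  c(x[1L], x[-1L] - adj)
}

cosd <- function(x) cos(x * pi / 180)
sind <- function(x) sin(x * pi / 180)
atan2d <- function(y, x) atan2(y, x) * 180 / pi

#' @keywords internal
#' Numerical derivative on a uniform grid: central differences inside,
#' one-sided at the ends.
gradient_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  g <- numeric(n)
  g[1L] <- (y[2L] - y[1L]) / dt
  g[n] <- (y[n] - y[n - 1L]) / dt
  if (n > 2L) g[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)
  g
}

# Savitzky-Golay smoothing; window <= 1 disables. Window is clipped to an odd
# value not exceeding the series length so short tracks stay usable.
sg_smooth <- function(x, window, order = 2L) {
  if (is.null(window) || window <= 1L) return(x)
  n <- length(x)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window %% 2L == 0L) window <- window - 1L
  if (window <= order + 1L) return(x)
  signal::sgolayfilt(x, p = order, n = window)
}

# Savitzky-Golay first-derivative filter (zero phase); returns dx/dt in
# units of x per second.
sg_deriv <- function(x, window, order = 2L, dt) {
  n <- length(x)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window %% 2L == 0L) window <- window - 1L
  if (window <= order + 1L || window < 3L) return(gradient_uniform(x, dt))
  signal::sgolayfilt(x, p = order, n = window, m = 1L, ts = dt)
}

# Linear interpolation into a sample history: value of the series at
# (current index - delay_frames), holding the first value before the record
# starts. `hist` has valid entries 1..i.
delayed_value <- function(hist, i, delay_frames) {
  idx <- i - delay_frames
  if (idx <= 1) return(hist[1L])
  lo <- floor(idx)
  hi <- ceiling(idx)
  if (lo == hi) return(hist[lo])
  w <- idx - lo
  (1 - w) * hist[lo] + w * hist[hi]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# saturate a commanded rate at +-limit
clamp_rate <- function(x, limit) {
  if (is.null(limit) || !is.finite(limit)) return(x)
  pmax(-limit, pmin(limit, x))
}
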