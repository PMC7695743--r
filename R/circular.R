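#' Circular summary of an angular sample
#'
#' Mean-vector statistics of a sample of angles: the direction `mu` of the
#' vector average of unit vectors, the mean resultant length `r_len`
#' (0 for a uniform distribution, 1 when all angles coincide), and the
#' circular standard deviation `sigma = sqrt(-2 log r_len)` expressed in
#' degrees. Counts are also binned (5 degree bins by default) for rose-plot
#' style displays.
#'
#' @param angles numeric vector of angles in degrees; wrapped internally.
#' @param bin_width bin width in degrees for the binned counts.
#' @return an object of class `circular_summary`: list with `mu` (degrees,
#'   `NA` when `r_len` is numerically zero), `r_len`, `sigma` (degrees),
#'   `n`, `bins` (named count vector over \[-180, 180)), and `undefined`
#'   (TRUE when the mean direction is undefined).
#' @export
#' @examples
#' mean_vector(c(0, 90))          # mu 45, r_len cos(45 deg)
#' mean_vector(c(0, 90, 180, 270))  # uniform: r_len 0, mu undefined
mean_vector <- function(angles, bin_width = 5) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 1L) stop("empty angle sample")
  C <- mean(cosd(angles))
  S <- mean(sind(angles))
  r_len <- sqrt(C^2 + S^2)
  undefined <- r_len < 1e-12
  mu <- if (undefined) NA_real_ else wrap180(atan2d(S, C))
  sigma <- if (undefined) Inf else sqrt(-2 * log(max(r_len, .Machine$double.xmin))) * 180 / pi
  w <- wrap180(angles)
  w[w == 180] <- -180
  breaks <- seq(-180, 180, by = bin_width)
  counts <- table(cut(w, breaks = breaks, right = FALSE, include.lowest = TRUE))
  bins <- as.integer(counts)
  names(bins) <- sprintf("%g", breaks[-length(breaks)] + bin_width / 2)
  structure(list(mu = mu, r_len = r_len, sigma = sigma, n = n,
                 bins = bins, undefined = undefined),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<circular_summary: n = %d, r = %.4f, mean direction undefined>\n",
                x$n, x$r_len))
  } else {
    cat(sprintf("<circular_summary: n = %d, mu = %.1f deg, r = %.4f, sigma = %.1f deg>\n",
                x$n, x$mu, x$r_len, x$sigma))
  }
  invisible(x)
}

#' Circular summaries of the six pursuit angles
#'
#' Pools frames across one or more chases (every frame counts once) and
#' returns one [mean_vector()] summary per angle: heading, bearing and error
#' angles in the horizontal and vertical plane.
#'
#' @param angles an `angle_series`, or a list of them.
#' @param bin_width bin width in degrees passed to [mean_vector()].
#' @return named list of six `circular_summary` objects:
#'   `theta_PH`, `theta_AH`, `theta_EH`, `theta_PV`, `theta_AV`, `theta_EV`.
#' @export
summarize_pursuit_angles <- function(angles, bin_width = 5) {
  if (inherits(angles, "angle_series")) angles <- list(angles)
  if (!length(angles)) stop("no angle series supplied")
  vars <- c("theta_PH", "theta_AH", "theta_EH",
            "theta_PV", "theta_AV", "theta_EV")
  out <- lapply(vars, function(v)
    mean_vector(unlist(lapply(angles, `[[`, v)), bin_width = bin_width))
  names(out) <- vars
  out
}
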