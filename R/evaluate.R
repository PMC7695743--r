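#' Identified sensorimotor delays per plane
#'
#' The default delays used when replaying controllers against recorded
#' chases: the error-angle path delay (`dt1`) and the bearing-rate path
#' delay (`dt2`) identified for each plane from the lagged fits
#' (horizontal: 10 and 26 ms; vertical: 21 and 32 ms).
#'
#' @param plane `"horizontal"` or `"vertical"`.
#' @return list with `dt1` and `dt2` in seconds.
#' @export
default_delays <- function(plane = c("horizontal", "vertical")) {
  plane <- match.arg(plane)
  if (plane == "horizontal") list(dt1 = 0.010, dt2 = 0.026)
  else list(dt1 = 0.021, dt2 = 0.032)
}

#' Trajectory error between a measured and a simulated chase
#'
#' The mean point-to-point distance between measured and simulated pursuer
#' positions, per plane of representation: `eps_H` is the mean planar
#' distance in (x, y); `eps_V` is the mean distance in the (x', z) plane,
#' where each trajectory contributes its own cumulative horizontal path
#' length x'.
#'
#' @param measured,simulated [pursuit_track()] objects on the same time
#'   base (the simulation must have run on the measured target track).
#' @return an object of class `error_score`: list with `eps_H`, `eps_V`
#'   (meters), the per-frame distance series `per_frame_H`, `per_frame_V`,
#'   and `chase_id`.
#' @export
trajectory_error <- function(measured, simulated) {
  if (!inherits(measured, "pursuit_track") ||
      !inherits(simulated, "pursuit_track"))
    stop("both arguments must be pursuit_track objects")
  n <- length(measured$time)
  if (length(simulated$time) != n)
    stop("track lengths differ (", n, " vs ", length(simulated$time),
         "); simulate with stop_at_capture = FALSE for frame-by-frame comparison")
  if (max(abs(measured$time - simulated$time)) > 1e-9)
    stop("tracks are not on the same time base")
  dH <- sqrt((measured$pursuer[, 1] - simulated$pursuer[, 1])^2 +
             (measured$pursuer[, 2] - simulated$pursuer[, 2])^2)
  xm <- compute_x_prime(measured)
  xs <- compute_x_prime(simulated)
  dV <- sqrt((xm - xs)^2 +
             (measured$pursuer[, 3] - simulated$pursuer[, 3])^2)
  structure(list(eps_H = mean(dH), eps_V = mean(dV),
                 per_frame_H = dH, per_frame_V = dV,
                 chase_id = measured$chase_id),
            class = "error_score")
}

#' @export
print.error_score <- function(x, ...) {
  cat(sprintf("<error_score '%s': eps_H = %.4f m, eps_V = %.4f m over %d frames>\n",
              x$chase_id, x$eps_H, x$eps_V, length(x$per_frame_H)))
  invisible(x)
}

# Replay one controller against one chase in one plane and return the
# plane's epsilon. Speed is replayed from the measured pursuer; initial
# conditions come from the start of the measured track.
replay_epsilon <- function(track, spec, plane, capture_radius = 0.010) {
  ini <- track_init(track)
  sp <- replay_speeds(track)
  if (plane == "horizontal") {
    sim <- simulate_planar(track$target[, 1:2], track$time, spec,
                           speed_policy("replay"),
                           init = list(position = ini$position[1:2],
                                       heading = ini$heading_h),
                           capture_radius = capture_radius,
                           replay_speed = sp$horizontal,
                           stop_at_capture = FALSE)
    mean(sqrt((track$pursuer[, 1] - sim$pursuer[, 1])^2 +
              (track$pursuer[, 2] - sim$pursuer[, 2])^2))
  } else {
    vp <- vertical_plane_problem(track)
    sim <- simulate_planar(vp$target, track$time, spec,
                           speed_policy("replay"),
                           init = list(position = c(vp$pursuer[1L, 1L],
                                                    vp$pursuer[1L, 2L]),
                                       heading = ini$heading_v),
                           capture_radius = capture_radius,
                           replay_speed = sp$vertical,
                           stop_at_capture = FALSE)
    # epsilon compares each trajectory's own cumulative horizontal path
    xs <- c(0, cumsum(abs(diff(sim$pursuer[, 1L]))))
    mean(sqrt((vp$pursuer[, 1L] - xs)^2 +
              (vp$pursuer[, 2L] - sim$pursuer[, 2L])^2))
  }
}

default_grid <- function(strategy) {
  switch(strategy,
         PP = list(kp = seq(0, 60, by = 1)),
         BP = list(kp = seq(0, 60, by = 1)),
         PN = list(N = seq(0, 8, by = 0.1)),
         MP = list(kp = seq(0, 60, by = 4), N = seq(0, 2, by = 0.1)))
}

#' Grid search of controller gains against recorded chases
#'
#' Replays a steering strategy against every chase for every point of a
#' parameter grid and scores each point by the mean trajectory error
#' across chases. The simulated fly flies at the measured fly's speed
#' (replay policy) and starts from the measured initial conditions; delays
#' default to the identified values for the plane ([default_delays()]).
#'
#' @param chases a list of [pursuit_track()] objects.
#' @param strategy `"PP"`, `"BP"`, `"PN"` or `"MP"`.
#' @param plane `"horizontal"` or `"vertical"`.
#' @param grid named list of parameter vectors to scan (any of `kp`, `N`,
#'   `beta`); the full factorial of the axes is evaluated. Defaults cover
#'   the plausible gain range for the strategy.
#' @param fixed named list of parameters held fixed (e.g. `beta = 23`
#'   while scanning `kp`).
#' @param delays list with `dt1`, `dt2` in seconds; default per plane.
#' @param capture_radius capture distance in meters (simulations run the
#'   full horizon regardless; this only fills the spec).
#' @param smooth_window if `> 1`, measured tracks are smoothed with
#'   [smooth_track()] before serving as replay input and error reference;
#'   use the angle pipeline's window (31) for noisy recordings and 0 for
#'   clean simulated data.
#' @return an object of class `grid_search_result`: list with `surface`
#'   (data.frame of grid coordinates plus mean `eps`), `per_chase` (matrix
#'   grid points x chases), `argmin` (row of `surface` at the minimum),
#'   `strategy`, `plane`, `delays`.
#' @export
grid_search <- function(chases, strategy, plane = c("horizontal", "vertical"),
                        grid = NULL, fixed = list(), delays = NULL,
                        capture_radius = 0.010, smooth_window = 0L) {
  plane <- match.arg(plane)
  if (inherits(chases, "pursuit_track")) chases <- list(chases)
  if (!length(chases)) stop("no chases supplied")
  if (smooth_window > 1L)
    chases <- lapply(chases, smooth_track, window = smooth_window)
  if (is.null(grid)) grid <- default_grid(strategy)
  if (!length(grid) || is.null(names(grid))) stop("grid must be a named list")
  if (is.null(delays)) delays <- default_delays(plane)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)

  per_chase <- matrix(NA_real_, nrow(pts), length(chases))
  colnames(per_chase) <- vapply(chases, `[[`, character(1), "chase_id")
  for (g in seq_len(nrow(pts))) {
    par <- c(as.list(pts[g, , drop = FALSE]), fixed)
    spec <- controller_spec(strategy,
                            kp = par$kp %||% 0,
                            kd = par$kd %||% 0,
                            beta = par$beta %||% 0,
                            N = par$N %||% 0,
                            dt1 = delays$dt1, dt2 = delays$dt2,
                            plane = plane)
    for (k in seq_along(chases)) {
      eps <- tryCatch(replay_epsilon(chases[[k]], spec, plane, capture_radius),
                      error = function(e) {
                        warning("simulation failed at grid point ", g,
                                ", chase ", k, ": ", conditionMessage(e))
                        NA_real_
                      })
      per_chase[g, k] <- eps
    }
  }
  surface <- cbind(pts, eps = rowMeans(per_chase, na.rm = TRUE))
  best <- which.min(surface$eps)
  structure(list(surface = surface, per_chase = per_chase,
                 argmin = surface[best, , drop = FALSE],
                 strategy = strategy, plane = plane, delays = delays),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search %s (%s): %d grid points x %d chases>\n",
              x$strategy, x$plane, nrow(x$surface), ncol(x$per_chase)))
  cat("  argmin: ")
  print(x$argmin, row.names = FALSE)
  invisible(x)
}

#' @export
plot.grid_search_result <- function(x, ...) {
  pars <- setdiff(names(x$surface), "eps")
  if (length(pars) == 1L) {
    graphics::plot(x$surface[[pars]], x$surface$eps, type = "l",
                   xlab = pars, ylab = "epsilon (m)",
                   main = sprintf("%s, %s plane", x$strategy, x$plane), ...)
    graphics::abline(v = x$argmin[[pars]], lty = 2)
  } else {
    z <- matrix(x$surface$eps, nrow = length(unique(x$surface[[pars[1L]]])))
    graphics::image(sort(unique(x$surface[[pars[1L]]])),
                    sort(unique(x$surface[[pars[2L]]])), z,
                    xlab = pars[1L], ylab = pars[2L],
                    main = sprintf("%s, %s plane", x$strategy, x$plane), ...)
  }
  invisible(x)
}

#' Compare pursuit strategies by their per-chase errors
#'
#' One-way ANOVA of the per-chase trajectory errors across strategies,
#' followed by Tukey honest-significant-difference pairwise comparisons.
#' Pairwise outcomes are labelled `"n.s."` (p > 0.05), `"*"` (p < 0.05) or
#' `"***"` (p < 0.001).
#'
#' @param scores either a data.frame with columns `strategy` and `eps`
#'   (optionally `chase_id`), or a named list of per-chase error vectors,
#'   one element per strategy.
#' @return an object of class `strategy_comparison`: list with `anova_F`,
#'   `anova_p`, `pairwise` (data.frame: comparison, difference, p_adj,
#'   label), and `groups` (per-strategy n, mean, median, quartiles for
#'   box-plot export).
#' @export
compare_strategies <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    if (is.null(names(scores))) stop("strategy list must be named")
    scores <- data.frame(
      strategy = rep(names(scores), lengths(scores)),
      eps = unlist(scores, use.names = FALSE))
  }
  if (!all(c("strategy", "eps") %in% names(scores)))
    stop("scores needs columns 'strategy' and 'eps'")
  scores$strategy <- factor(scores$strategy)
  if (nlevels(scores$strategy) < 2L) stop("need at least two strategies")
  cnt <- table(scores$strategy)
  if (any(cnt < 3L))
    stop("need at least 3 observations per strategy; got ",
         paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
  fit <- stats::aov(eps ~ strategy, data = scores)
  tab <- summary(fit)[[1L]]
  Fv <- tab[["F value"]][1L]
  pv <- tab[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$strategy
  pairwise <- data.frame(comparison = rownames(tk),
                         difference = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL)
  pairwise$label <- ifelse(pairwise$p_adj < 0.001, "***",
                           ifelse(pairwise$p_adj < 0.05, "*", "n.s."))
  groups <- do.call(rbind, lapply(split(scores$eps, scores$strategy),
                                  function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    data.frame(n = length(v), mean = mean(v),
               q25 = q[1L], median = q[2L], q75 = q[3L])
  }))
  groups <- cbind(strategy = rownames(groups), groups)
  rownames(groups) <- NULL
  structure(list(anova_F = Fv, anova_p = pv, pairwise = pairwise,
                 groups = groups),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g\n", x$anova_F, x$anova_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
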