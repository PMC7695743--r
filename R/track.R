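#' Pursuit track: synchronised 3D pursuer and target position series
#'
#' The central data container: time-stamped 3D positions of a pursuer and a
#' target sharing one time base, as produced by stereo-videography
#' reconstruction (or by the simulators in this package). Positions are in
#' meters, time in seconds; the nominal sampling rate of the recordings this
#' package targets is 190 Hz.
#'
#' @param time numeric vector of time stamps in seconds, strictly increasing.
#' @param pursuer n x 3 matrix (or data.frame) of pursuer x, y, z in meters.
#' @param target n x 3 matrix of target positions, same length as `pursuer`.
#' @param chase_id character label for the chase.
#' @param frame_rate sampling rate in Hz; estimated from `time` when `NULL`.
#' @param dt_tol maximum tolerated relative deviation of any time step from
#'   `1/frame_rate`; records that jitter more than this are rejected.
#' @return an object of class `pursuit_track`: a list with elements `time`,
#'   `pursuer`, `target`, `chase_id`, `frame_rate`.
#' @export
#' @examples
#' t <- seq(0, 0.1, by = 1 / 190)
#' p <- cbind(t, 0, 0); g <- cbind(1, 0, 0)[rep(1, length(t)), ]
#' pursuit_track(t, p, g, chase_id = "demo")
pursuit_track <- function(time, pursuer, target, chase_id = "chase",
                          frame_rate = NULL, dt_tol = 0.25) {
  pursuer <- as.matrix(pursuer)
  target <- as.matrix(target)
  storage.mode(pursuer) <- "double"
  storage.mode(target) <- "double"
  n <- length(time)
  if (n < 3L) stop("a pursuit track needs at least 3 frames, got ", n)
  if (nrow(pursuer) != n || nrow(target) != n)
    stop("pursuer and target series must match the time base length")
  if (ncol(pursuer) != 3L || ncol(target) != 3L)
    stop("pursuer and target must have 3 coordinate columns")
  if (!all(is.finite(time)) || !all(is.finite(pursuer)) || !all(is.finite(target)))
    stop("all times and coordinates must be finite")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(dt)
  if (frame_rate <= 0) stop("frame_rate must be positive")
  rel_dev <- abs(dt * frame_rate - 1)
  if (max(rel_dev) > dt_tol)
    stop(sprintf("time base deviates from 1/%.4g s by up to %.0f%% (tolerance %.0f%%)",
                 frame_rate, 100 * max(rel_dev), 100 * dt_tol))
  colnames(pursuer) <- colnames(target) <- c("x", "y", "z")
  structure(list(time = as.numeric(time), pursuer = pursuer, target = target,
                 chase_id = as.character(chase_id)[1L],
                 frame_rate = frame_rate),
            class = "pursuit_track")
}

#' @export
print.pursuit_track <- function(x, ...) {
  dur <- diff(range(x$time))
  cat(sprintf("<pursuit_track '%s': %d frames, %.3f s @ %.1f Hz>\n",
              x$chase_id, length(x$time), dur, x$frame_rate))
  rng <- apply(x$pursuer, 2, range)
  cat(sprintf("  pursuer x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' @export
as.data.frame.pursuit_track <- function(x, ...) {
  data.frame(t = x$time,
             xp = x$pursuer[, 1], yp = x$pursuer[, 2], zp = x$pursuer[, 3],
             xt = x$target[, 1], yt = x$target[, 2], zt = x$target[, 3])
}

#' Trajectory file dialect
#'
#' Declares how a delimited trajectory file is laid out: separator, units,
#' and the mapping from the canonical columns to the file's header names.
#' The canonical layout is `t,xp,yp,zp,xt,yt,zt` (time, pursuer xyz,
#' target xyz).
#'
#' @param sep field separator.
#' @param time_unit `"s"` or `"ms"`.
#' @param length_unit `"m"`, `"cm"` or `"mm"`.
#' @param columns named character vector mapping canonical names
#'   (`t`, `xp`, `yp`, `zp`, `xt`, `yt`, `zt`) to header names in the file.
#' @return a list of class `track_dialect`.
#' @export
track_dialect <- function(sep = ",", time_unit = c("s", "ms"),
                          length_unit = c("m", "cm", "mm"),
                          columns = NULL) {
  time_unit <- match.arg(time_unit)
  length_unit <- match.arg(length_unit)
  canonical <- c("t", "xp", "yp", "zp", "xt", "yt", "zt")
  if (is.null(columns)) columns <- stats::setNames(canonical, canonical)
  if (!all(canonical %in% names(columns)))
    stop("columns mapping must cover: ", paste(canonical, collapse = ", "))
  structure(list(sep = sep, time_unit = time_unit, length_unit = length_unit,
                 columns = columns),
            class = "track_dialect")
}

#' Read a trajectory dialect from a YAML sidecar file
#'
#' The sidecar holds keys `sep`, `time_unit`, `length_unit` and an optional
#' `columns` mapping, e.g. `columns: {t: time_ms, xp: fly_x, ...}`.
#'
#' @param path path to the YAML file.
#' @return a `track_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  cols <- if (!is.null(cfg$columns)) unlist(cfg$columns) else NULL
  track_dialect(sep = cfg$sep %||% ",",
                time_unit = cfg$time_unit %||% "s",
                length_unit = cfg$length_unit %||% "m",
                columns = cols)
}

#' Read a pursuit track from a delimited text file
#'
#' @param path path to a delimited text file with a header line.
#' @param dialect a [track_dialect()] describing separator, units and column
#'   names.
#' @param na_policy what to do with frames containing missing coordinates:
#'   `"drop"` removes them (with a message), `"interpolate"` fills them by
#'   linear interpolation in time, `"reject"` refuses the file.
#' @param chase_id chase label; defaults to the file name without extension.
#' @param dt_tol time-base tolerance passed to [pursuit_track()]. The
#'   default accepts any strictly increasing time base, because dropping
#'   frames under the `"drop"` policy leaves holes; [resample_uniform()]
#'   restores uniformity afterwards.
#' @param ... further arguments passed to [pursuit_track()].
#' @return a validated [pursuit_track()], in meters and seconds.
#' @export
#' @examples
#' f <- system.file("extdata", "example_chase.csv", package = "pursuitkin")
#' d <- system.file("extdata", "example_chase.yaml", package = "pursuitkin")
#' tr <- read_track(f, dialect = read_dialect(d))
#' tr
read_track <- function(path, dialect = track_dialect(),
                       na_policy = c("drop", "interpolate", "reject"),
                       chase_id = NULL, dt_tol = Inf, ...) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE)
  need <- dialect$columns
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols))
    stop("format error: missing columns ", paste(missing_cols, collapse = ", "),
         " in ", path)
  df <- df[, unname(need[c("t", "xp", "yp", "zp", "xt", "yt", "zt")])]
  names(df) <- c("t", "xp", "yp", "zp", "xt", "yt", "zt")

  bad <- rowSums(!is.finite(as.matrix(df))) > 0
  if (any(bad)) {
    if (na_policy == "reject")
      stop("validation error: ", sum(bad), " frames with missing values in ", path)
    if (na_policy == "drop") {
      message(sum(bad), " frame(s) with missing values dropped from ", basename(path))
      df <- df[!bad, , drop = FALSE]
    } else {
      ok <- which(!bad)
      for (j in 2:7) {
        df[[j]] <- stats::approx(df$t[ok], df[[j]][ok], xout = df$t, rule = 2)$y
      }
      message(sum(bad), " frame(s) interpolated in ", basename(path))
    }
  }
  tscale <- if (dialect$time_unit == "ms") 1e-3 else 1
  lscale <- switch(dialect$length_unit, m = 1, cm = 1e-2, mm = 1e-3)
  if (is.unsorted(df$t, strictly = TRUE))
    stop("validation error: non-monotone time in ", path)
  if (is.null(chase_id)) chase_id <- sub("\\.[^.]*$", "", basename(path))
  pursuit_track(df$t * tscale,
                as.matrix(df[, c("xp", "yp", "zp")]) * lscale,
                as.matrix(df[, c("xt", "yt", "zt")]) * lscale,
                chase_id = chase_id, dt_tol = dt_tol, ...)
}

#' Write a pursuit track to a delimited text file
#'
#' Writes the canonical `t,xp,yp,zp,xt,yt,zt` layout in seconds and meters at
#' full double precision, so that [read_track()] reproduces the track.
#'
#' @param track a [pursuit_track()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, sep = ",") {
  if (!inherits(track, "pursuit_track")) stop("not a pursuit_track")
  df <- as.data.frame(track)
  df[] <- lapply(df, function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of chases as one file per chase
#'
#' @param tracks a list of [pursuit_track()] objects.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return character vector of the written paths, one per chase, named by
#'   `chase_id`.
#' @export
write_tracks <- function(tracks, dir, sep = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(tracks, function(tr) {
    p <- file.path(dir, paste0(tr$chase_id, ".csv"))
    write_track(tr, p, sep = sep)
    p
  }, character(1))
  names(paths) <- vapply(tracks, `[[`, character(1), "chase_id")
  paths
}

#' Resample a track onto a uniform time grid
#'
#' Linear interpolation of all six coordinates onto a uniform grid spanning
#' the original time range. Resampling an already-uniform track at its own
#' rate is the identity.
#'
#' @param track a [pursuit_track()].
#' @param rate target sampling rate in Hz.
#' @return a [pursuit_track()] at the requested rate.
#' @export
resample_uniform <- function(track, rate) {
  if (!inherits(track, "pursuit_track")) stop("not a pursuit_track")
  if (rate <= 0) stop("rate must be positive")
  tt <- seq(track$time[1L], track$time[length(track$time)], by = 1 / rate)
  interp <- function(m) apply(m, 2, function(col)
    stats::approx(track$time, col, xout = tt)$y)
  pursuit_track(tt, interp(track$pursuer), interp(track$target),
                chase_id = track$chase_id, frame_rate = rate)
}

#' Smooth a track's coordinates with a zero-phase filter
#'
#' Savitzky-Golay smoothing of all six coordinate series. Measured tracks
#' carry reconstruction noise that inflates any path-length or velocity
#' quantity computed from raw frame-to-frame displacements (cumulative
#' horizontal displacement in particular double-counts jitter); smoothing
#' with the same zero-phase filter used by the angle pipeline removes that
#' bias without shifting the trajectory in time.
#'
#' @param track a [pursuit_track()].
#' @param window filter window in frames (odd); `<= 1` returns the track
#'   unchanged.
#' @param order polynomial order.
#' @return a [pursuit_track()] with smoothed coordinates.
#' @export
smooth_track <- function(track, window = 31L, order = 2L) {
  if (!inherits(track, "pursuit_track")) stop("not a pursuit_track")
  if (window <= 1L) return(track)
  track$pursuer <- apply(track$pursuer, 2, sg_smooth, window = window, order = order)
  track$target <- apply(track$target, 2, sg_smooth, window = window, order = order)
  colnames(track$pursuer) <- colnames(track$target) <- c("x", "y", "z")
  track
}
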