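# Shared fixture builders. Chase sets are memoised per (n, noise, strategy)
# so multiple test files can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

# straight-line track: pursuer marches along +x, target fixed ahead
line_track <- function(n = 10, step = 0.1, target = c(1, 0, 0),
                       frame_rate = 190) {
  tt <- seq(0, by = 1 / frame_rate, length.out = n)
  p <- cbind(step * (seq_len(n) - 1), 0, 0)
  g <- matrix(target, n, 3, byrow = TRUE)
  pursuit_track(tt, p, g, chase_id = "line", frame_rate = frame_rate)
}

# analytic circular pursuer path (for arc-length / derivative oracles)
circle_track <- function(n = 1000, radius = 1, quarter = TRUE,
                         frame_rate = 1000) {
  tt <- seq(0, by = 1 / frame_rate, length.out = n)
  ang <- seq(0, if (quarter) pi / 2 else 2 * pi, length.out = n)
  p <- cbind(radius * cos(ang), radius * sin(ang), 0)
  g <- matrix(c(0, 0, 0), n, 3, byrow = TRUE)
  pursuit_track(tt, p, g, chase_id = "circle", frame_rate = frame_rate)
}

bp_chases <- function(n = 6, noise = 0, seed = 1) {
  key <- sprintf("bp_%d_%g_%d", n, noise, seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- synthetic_spec("circle", noise_sd = noise, seed = seed)
    .fixture_cache[[key]] <- gen_chases(n, spec)
  }
  .fixture_cache[[key]]
}

pn_chases <- function(n = 6, noise = 0, seed = 1) {
  key <- sprintf("pn_%d_%g_%d", n, noise, seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- synthetic_spec("circle", noise_sd = noise, seed = seed,
                           h_controller = controller_spec("PN", N = 1.8,
                                                          dt2 = 0.026))
    .fixture_cache[[key]] <- gen_chases(n, spec)
  }
  .fixture_cache[[key]]
}

# measurement pipeline with explicit windows
pipeline <- function(tracks, dw = 0, sw = 0, rw = 0) {
  ang <- lapply(tracks, compute_angles, deriv_window = dw, smooth_window = sw)
  rat <- lapply(ang, compute_rates, smooth_window = rw)
  list(angles = ang, rates = rat)
}
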