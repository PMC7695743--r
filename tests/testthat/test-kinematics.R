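# Hand-trigonometry oracles use raw finite differences (deriv_window = 0)
# so the expected values are exact geometry, not filter output.

test_that("angles match hand trigonometry on constructed geometries", {
  # collinear: pursuer marching at the target dead ahead
  a <- compute_angles(line_track(4), deriv_window = 0, smooth_window = 0)
  expect_equal(a$theta_PH, rep(0, 4), tolerance = 1e-12)
  expect_equal(a$theta_AH, rep(0, 4), tolerance = 1e-12)
  expect_equal(a$theta_EH, rep(0, 4), tolerance = 1e-12)
  expect_equal(a$theta_AV, rep(0, 4), tolerance = 1e-12)

  # zenith: target directly above the moving pursuer's first position
  tr <- line_track(3, target = c(0, 0, 1))
  a <- compute_angles(tr, deriv_window = 0, smooth_window = 0)
  expect_equal(a$theta_AV[1], 90, tolerance = 1e-9)

  # 45-degree offsets, horizontal and vertical
  a <- compute_angles(line_track(3, target = c(1, 1, 0)),
                      deriv_window = 0, smooth_window = 0)
  expect_equal(a$theta_AH[1], 45, tolerance = 1e-9)
  expect_equal(a$theta_EH[1], 45, tolerance = 1e-9)
  a <- compute_angles(line_track(3, target = c(1, 0, 1)),
                      deriv_window = 0, smooth_window = 0)
  expect_equal(a$theta_AV[1], 45, tolerance = 1e-9)
})

test_that("error angles are the wrapped difference of bearing and heading", {
  ch <- bp_chases(2)[[2]]
  a <- compute_angles(ch$track, deriv_window = 0, smooth_window = 0)
  expect_equal(a$theta_EH, wrap180(a$theta_AH - a$theta_PH), tolerance = 1e-12)
  expect_equal(a$theta_EV, a$theta_AV - a$theta_PV, tolerance = 1e-12)
  expect_true(all(a$theta_PH > -180 & a$theta_PH <= 180))
  expect_true(all(abs(a$theta_PV) <= 90))
  expect_true(all(a$R_A >= 0))
  expect_true(all(diff(a$x_prime) >= 0))
  expect_true(all(a$rho > 0 & a$rho < 180))
})

test_that("error angles are invariant under rigid horizontal rotation", {
  ch <- bp_chases(2)[[1]]
  tr <- ch$clean
  phi <- 73 * pi / 180
  Rm <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  rot <- tr
  rot$pursuer[, 1:2] <- tr$pursuer[, 1:2] %*% Rm
  rot$target[, 1:2] <- tr$target[, 1:2] %*% Rm
  a0 <- compute_angles(tr, deriv_window = 0, smooth_window = 0)
  a1 <- compute_angles(rot, deriv_window = 0, smooth_window = 0)
  expect_equal(a1$theta_EH, a0$theta_EH, tolerance = 1e-9)
  expect_equal(a1$theta_EV, a0$theta_EV, tolerance = 1e-9)
  expect_equal(wrap180(a1$theta_PH - a0$theta_PH - 73),
               rep(0, nrow(a0)), tolerance = 1e-9)
  expect_equal(wrap180(a1$theta_AH - a0$theta_AH - 73),
               rep(0, nrow(a0)), tolerance = 1e-9)
})

test_that("stationary frames carry the previous heading and are flagged", {
  tt <- seq(0, by = 1 / 190, length.out = 6)
  p <- rbind(c(0, 0, 0), c(0.1, 0.1, 0), c(0.1, 0.1, 0),
             c(0.1, 0.1, 0), c(0.2, 0.2, 0), c(0.3, 0.3, 0))
  g <- matrix(c(1, 0, 0), 6, 3, byrow = TRUE)
  tr <- pursuit_track(tt, p, g, frame_rate = 190)
  a <- compute_angles(tr, deriv_window = 0, smooth_window = 0)
  expect_true(any(a$held))
  expect_equal(a$theta_PH[3], 45, tolerance = 1e-9)  # held from frame 2
  expect_equal(a$theta_PH[4], 45, tolerance = 1e-9)
})

test_that("cumulative horizontal displacement follows path-length oracles", {
  xp <- compute_x_prime(line_track(5))
  expect_equal(xp, c(0, 0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)

  vert <- pursuit_track(seq(0, by = 1 / 190, length.out = 5),
                        cbind(0, 0, (0:4) * 0.1),
                        matrix(c(1, 0, 0), 5, 3, byrow = TRUE),
                        frame_rate = 190)
  expect_equal(compute_x_prime(vert), rep(0, 5), tolerance = 1e-15)

  # quarter circle of radius 1 approaches arc length pi/2
  expect_equal(compute_x_prime(circle_track(1000))[1000], pi / 2,
               tolerance = 1e-4)
})

test_that("rates recover analytic derivatives", {
  tt <- seq(0, 1, by = 1 / 190)
  mk <- function(theta_deg) {
    n <- length(tt)
    # planar track whose heading is theta(t): integrate the direction
    dx <- cos(theta_deg * pi / 180) / 190
    dy <- sin(theta_deg * pi / 180) / 190
    p <- cbind(cumsum(c(0, dx[-n])), cumsum(c(0, dy[-n])), 0)
    pursuit_track(tt, p, matrix(c(10, 0, 0), n, 3, byrow = TRUE),
                  frame_rate = 190)
  }
  # linear ramp: constant rate
  a <- compute_angles(mk(10 * tt), deriv_window = 0, smooth_window = 0)
  r <- compute_rates(a, smooth_window = 0)
  expect_equal(r$omega_PH[3:180], rep(10, 178), tolerance = 1e-6)
  # constant angle: zero rate
  a <- compute_angles(mk(rep(25, length(tt))), deriv_window = 0,
                      smooth_window = 0)
  r <- compute_rates(a, smooth_window = 0)
  expect_equal(r$omega_PH, rep(0, nrow(r)), tolerance = 1e-9)
  # sinusoid: matches the analytic derivative within 1%
  theta <- 30 * sin(2 * pi * tt)
  a <- compute_angles(mk(theta), deriv_window = 0, smooth_window = 0)
  r <- compute_rates(a, smooth_window = 0)
  expected <- 30 * 2 * pi * cos(2 * pi * tt)
  mid <- 10:180
  expect_lt(max(abs(r$omega_PH[mid] - expected[mid - 1])) /
              max(abs(expected)), 0.01)
})

test_that("rate linearity: error rate equals bearing rate minus heading rate", {
  ch <- bp_chases(2)[[1]]
  a <- compute_angles(ch$clean, deriv_window = 0, smooth_window = 0)
  r <- compute_rates(a, smooth_window = 0)
  # identical except where the wrap of theta_E lands differently
  diffs <- r$omega_EH - (r$omega_AH - r$omega_PH)
  expect_lt(stats::median(abs(diffs)), 1e-6)
})

test_that("integrating rates reproduces the angle series up to a constant", {
  tt <- seq(0, 1, by = 1 / 190)
  theta <- 40 * sin(2 * pi * 0.8 * tt) + 15
  n <- length(tt)
  p <- cbind(cumsum(c(0, cos(theta * pi / 180)[-n] / 190)),
             cumsum(c(0, sin(theta * pi / 180)[-n] / 190)), 0)
  tr <- pursuit_track(tt, p, matrix(c(10, 0, 0), n, 3, byrow = TRUE),
                      frame_rate = 190)
  a <- compute_angles(tr, deriv_window = 0, smooth_window = 0)
  r <- compute_rates(a, smooth_window = 0)
  rebuilt <- a$theta_PH[2] + cumsum(r$omega_PH[-c(1, n)]) / 190
  resid <- rebuilt[-(n - 2)] - a$theta_PH[3:(n - 1)]
  expect_lt(max(abs(resid - mean(resid))), 1)   # shape matches up to a constant
})

test_that("short series are rejected by the smoother", {
  a <- compute_angles(line_track(4), deriv_window = 0, smooth_window = 0)
  expect_error(compute_rates(a, smooth_window = 5), "shorter than")
})

test_that("saccade extraction finds constructed events and their speed dip", {
  fr <- 190
  tt <- seq(0, 2, by = 1 / fr)
  n <- length(tt)
  om <- rep(0, n)
  bump <- function(center, width = 0.02) {
    3000 * exp(-((tt - center) / width)^2)
  }
  om <- bump(0.4) + bump(1.0) + bump(1.6)
  rates <- data.frame(time = tt, omega_PH = om, omega_PV = 0,
                      omega_AH = 0, omega_AV = 0, omega_EH = 0, omega_EV = 0)
  attr(rates, "frame_rate") <- fr
  class(rates) <- c("rate_series", "data.frame")
  speed <- rep(1.2, n)
  # dip the speed 10 ms before each yaw peak
  for (pk in c(0.4, 1.0, 1.6)) speed <- speed - 0.5 * exp(-((tt - pk + 0.010) / 0.02)^2)

  ev <- extract_saccades(rates, speed, threshold = 1500)
  expect_equal(nrow(ev), 3)
  expect_lt(max(abs(ev$peak_time - c(0.4, 1.0, 1.6))), 1 / fr)
  expect_lt(max(abs(ev$speed_lead - 0.010)), 1 / fr + 1e-9)

  none <- extract_saccades(rates, speed, threshold = 4000)
  expect_equal(nrow(none), 0)
})
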