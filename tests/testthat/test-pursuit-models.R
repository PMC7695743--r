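test_that("steering commands evaluate the control laws exactly", {
  bp <- controller_spec("BP", kp = 1, beta = -30)
  expect_equal(steering_command(bp, theta_E = 30), 0)        # equilibrium
  pn <- controller_spec("PN", N = 3)
  expect_equal(steering_command(pn, theta_E = 99, omega_A = 10), 30)
  mp <- controller_spec("MP", kp = 24, beta = 0, N = 0.15)
  expect_equal(steering_command(mp, theta_E = 2, omega_A = 20), 51)
  pd <- controller_spec("BP", kp = 2, beta = 5, kd = 0.5)
  expect_equal(steering_command(pd, theta_E = 10, omega_E = 4), 32)
})

test_that("controller invariants are enforced", {
  expect_error(controller_spec("PP", kp = 1, beta = 10), "beta = 0")
  expect_error(controller_spec("PN", kp = 3, N = 2), "kp = 0")
  expect_error(controller_spec("BP", kp = -1), "non-negative")
  expect_error(controller_spec("BP", kp = 1, dt1 = -0.01), "non-negative")
})

test_that("speed commands follow the angular-size law", {
  bd <- speed_policy("boeddeker", S_g = 0.2, S_v = 0.5, rho_star = 6)
  expect_equal(speed_command(bd, rho = 0.4), 0.2)            # small-target branch
  expect_equal(speed_command(speed_policy("replay"), replay_speed = 1.23), 1.23)
  expect_equal(speed_command(speed_policy("constant", s_const = 0.7)), 0.7)
  # the law peaks at rho_star with value S_v * rho_star / e + S_g
  rho <- seq(0.6, 40, by = 0.01)
  s <- speed_command(bd, rho = rho)
  expect_equal(rho[which.max(s)], 6, tolerance = 0.02)
  expect_equal(max(s), 0.5 * 6 * exp(-1) + 0.2, tolerance = 1e-5)
  expect_error(speed_policy("boeddeker", S_g = -1), "positive")
})

test_that("a pure pursuer launched at a stationary target flies straight", {
  tt <- seq(0, 2, by = 1 / 190)
  tgt <- cbind(rep(1, length(tt)), 0)
  sim <- simulate_planar(tgt, tt, controller_spec("PP", kp = 1),
                         speed_policy("constant", s_const = 1),
                         init = list(position = c(0, 0), heading = 0))
  expect_true(sim$captured)
  expect_equal(max(abs(sim$diagnostics$omega_P)), 0, tolerance = 1e-9)
  expect_equal(max(abs(sim$pursuer[, 2])), 0, tolerance = 1e-12)
})

test_that("pure pursuit of a faster pursuer converges into the wake", {
  # straight target at 1 m/s, pursuer at 1.5 m/s: tracking topology
  tt <- seq(0, 12, by = 1 / 190)
  tgt <- cbind(1.5 + tt, 0 * tt)
  sim <- simulate_planar(tgt, tt, controller_spec("PP", kp = 8),
                         speed_policy("constant", s_const = 1.5),
                         init = list(position = c(0, 0.4), heading = 0))
  expect_true(sim$captured)
  w <- which(sim$time >= sim$capture_time - 1.5 &
             sim$time <= sim$capture_time - 0.4)
  expect_lt(abs(median(sim$diagnostics$theta_E[w])), 2)
})

test_that("a constant-bearing collision triangle leaves PN silent", {
  # geometry chosen so the closing velocity lies along the line of sight:
  # target at (1, 0) moving +y at 1 m/s, pursuer speed 1.5 m/s heading
  # asin(1/1.5) above the x-axis
  tt <- seq(0, 2, by = 1 / 190)
  tgt <- cbind(rep(1, length(tt)), tt)
  h0 <- asin(1 / 1.5) * 180 / pi
  sim <- simulate_planar(tgt, tt, controller_spec("PN", N = 3),
                         speed_policy("constant", s_const = 1.5),
                         init = list(position = c(0, 0), heading = h0))
  expect_true(sim$captured)
  expect_lt(max(abs(sim$heading - h0)), 1)     # flew essentially straight
})

test_that("biased pursuit holds the target at minus the bias angle", {
  tt <- seq(0, 12, by = 1 / 190)
  tgt <- cbind(3 + tt, 0 * tt)
  sim <- simulate_planar(tgt, tt, controller_spec("BP", kp = 8, beta = -30),
                         speed_policy("constant", s_const = 1.5),
                         init = list(position = c(0, 0), heading = -30))
  expect_true(sim$captured)
  w <- which(sim$time >= sim$capture_time - 1.5 &
             sim$time <= sim$capture_time - 0.4)
  expect_equal(median(sim$diagnostics$theta_E[w]), 30, tolerance = 1)
})

test_that("pursuit capture holds over a seeded family of straight targets", {
  # the gain must let the pursuer out-turn its own orbit: a pure pursuer
  # circling at full error angle turns at kp * 90 deg/s, so its tightest
  # orbit has radius v / (kp * pi / 2); kp = 120 /s brings that under the
  # 10 mm capture radius at 1.5 m/s
  set.seed(42)
  for (k in 1:5) {
    dir <- runif(1, 0, 360)
    v <- runif(1, 0.4, 1)
    tt <- seq(0, 10, by = 1 / 190)
    tgt <- cbind(0.8 * cosd(dir) + v * tt * cosd(dir + 90),
                 0.8 * sind(dir) + v * tt * sind(dir + 90))
    sim <- simulate_planar(tgt, tt, controller_spec("PP", kp = 120),
                           speed_policy("constant", s_const = 1.5),
                           init = list(position = c(0, 0),
                                       heading = runif(1, 0, 360)))
    expect_true(sim$captured)
  }
})

test_that("delays are realised by interpolation and bounded by the horizon", {
  tt <- seq(0, 1, by = 1 / 190)
  tgt <- cbind(rep(1, length(tt)), 0)
  expect_error(simulate_planar(tgt, tt, controller_spec("BP", kp = 1, dt1 = 2),
                               speed_policy("constant"),
                               init = list(position = c(0, 0), heading = 0)),
               "exceeds the simulation horizon")
  # a 1.5-frame delay on a held initial input behaves like the held value
  sim <- simulate_planar(tgt, tt, controller_spec("BP", kp = 1, dt1 = 1.5 / 190),
                         speed_policy("constant", s_const = 1),
                         init = list(position = c(0, 0), heading = 10))
  expect_false(any(!is.finite(sim$diagnostics$omega_P)))
})

test_that("halving the integration step changes the path by O(dt)", {
  spec <- synthetic_spec("circle", noise_sd = 0, duration = 1.5)
  tg <- gen_target(spec)
  bp <- controller_spec("BP", kp = 8)
  run_at <- function(rate) {
    tt <- seq(0, spec$duration, by = 1 / rate)
    xy <- apply(tg$xyz[, 1:2], 2, function(col)
      stats::approx(tg$time, col, xout = tt)$y)
    sim <- simulate_planar(xy, tt, bp, speed_policy("constant", s_const = 0.8),
                           init = list(position = c(0.05, 0.05), heading = 45),
                           stop_at_capture = FALSE)
    sim$pursuer[nrow(sim$pursuer), ]
  }
  p190 <- run_at(190); p380 <- run_at(380); p760 <- run_at(760)
  e1 <- sqrt(sum((p190 - p380)^2))
  e2 <- sqrt(sum((p380 - p760)^2))
  expect_lt(e2, e1)                     # refinement shrinks the change
  expect_gt(e1 / e2, 1.4)               # at roughly first order
  expect_lt(e1 / e2, 4)
})

test_that("3D simulation: zero-gain controllers fly straight", {
  ch <- bp_chases(1)[[1]]
  z0 <- controller_spec("BP", kp = 0)
  zv <- controller_spec("BP", kp = 0, plane = "vertical")
  sim <- simulate_3d(ch$clean, z0, zv, speed_policy("constant", s_const = 1),
                     mode = "coupled", stop_at_capture = FALSE)
  expect_equal(diff(range(sim$heading[, "h"])), 0, tolerance = 1e-9)
  expect_equal(diff(range(sim$heading[, "v"])), 0, tolerance = 1e-9)
})

test_that("decoupled replay of the generating controllers reproduces the chase", {
  ch <- bp_chases(2)[[2]]
  spec <- synthetic_spec("circle", noise_sd = 0)
  sim <- simulate_3d(ch$clean, spec$h_controller, spec$v_controller,
                     speed_policy("replay"), mode = "decoupled",
                     stop_at_capture = FALSE)
  err <- trajectory_error(ch$clean, sim$track)
  expect_lt(err$eps_H, 0.002)
  expect_lt(err$eps_V, 0.005)
  # vertical equilibrium: the bias angle reappears as the held error angle
  d <- sim$diagnostics
  n <- nrow(d)
  expect_equal(median(d$theta_E_V[floor(n / 2):n]), 23, tolerance = 4)
})

test_that("coupled and decoupled modes agree on near-planar chases", {
  ch <- bp_chases(2)[[1]]
  spec <- synthetic_spec("circle", noise_sd = 0)
  dec <- simulate_3d(ch$clean, spec$h_controller, spec$v_controller,
                     speed_policy("replay"), mode = "decoupled",
                     stop_at_capture = FALSE)
  cou <- simulate_3d(ch$clean, spec$h_controller, spec$v_controller,
                     speed_policy("replay"), mode = "coupled",
                     stop_at_capture = FALSE)
  m <- min(nrow(dec$pursuer), nrow(cou$pursuer))
  dxy <- sqrt(rowSums((dec$pursuer[1:m, 1:2] - cou$pursuer[1:m, 1:2])^2))
  expect_lt(mean(dxy), 0.01)
})
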