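test_that("an exact linear relation is recovered with zero delay", {
  t <- seq(0, 2, by = 1 / 190)
  x <- sin(2 * pi * 1.3 * t) + 0.3 * sin(2 * pi * 3.7 * t)
  f <- lag_scan_fit(x, 5 * x, frame_rate = 190)
  expect_equal(f$gain, 5, tolerance = 1e-9)
  expect_equal(f$delay, 0)
  expect_equal(f$R, 1, tolerance = 1e-12)
})

test_that("a constructed shift is located on the delay grid", {
  set.seed(7)
  # band-limited signal: smoothed white noise
  x <- as.numeric(stats::filter(rnorm(800), rep(1, 15) / 15, sides = 2))
  x[is.na(x)] <- 0
  y <- 2 * c(rep(0, 3), x[1:(800 - 3)])     # y(t) = 2 x(t - 3 frames)
  f <- lag_scan_fit(x, y, frame_rate = 190)
  expect_equal(f$delay, 3 / 190, tolerance = 1e-9)
  expect_equal(f$gain, 2, tolerance = 0.02)
  # sub-frame refinement stays within half a frame of the true shift
  fr <- lag_scan_fit(x, y, frame_rate = 190, refine = TRUE)
  expect_lt(abs(fr$delay - 3 / 190), 0.5 / 190)
})

test_that("lag fits are equivariant under affine rescaling", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(600), rep(1, 9) / 9, sides = 2))
  x[is.na(x)] <- 0
  y <- 3 * c(rep(0, 2), x[1:598]) + rnorm(600, 0, 0.05)
  f0 <- lag_scan_fit(x, y, frame_rate = 190)
  f1 <- lag_scan_fit(2 * x + 5, -0.5 * y + 1, frame_rate = 190)
  expect_equal(f1$delay, f0$delay)
  expect_equal(abs(f1$R), abs(f0$R), tolerance = 1e-9)
  expect_equal(f1$gain, -0.5 * f0$gain / 2, tolerance = 1e-9)
})

test_that("delays with too little overlap are skipped, all skipped errors", {
  x <- rnorm(12)
  expect_error(lag_scan_fit(x, x, frame_rate = 190,
                            delays = c(0.3), min_overlap = 10),
               "no delay")
})

test_that("generative recovery: BP gains and delays from clean chases", {
  chs <- Filter(function(c) c$captured, bp_chases(8))
  pl <- pipeline(lapply(chs, `[[`, "track"))
  id <- identify_controllers(pl$angles, pl$rates, "horizontal", trim = 2)
  expect_lt(abs(id$theta_E$gain / 26 - 1), 0.03)
  expect_lt(abs(id$theta_E$delay - 2 / 190), 1.01 / 190)
  expect_true(id$theta_E$accepted)
  expect_lt(abs(id$omega_E$R), 0.7)      # the derivative path is not used
})

test_that("generative recovery: PN gain, delay and model discrimination", {
  chs <- Filter(function(c) c$captured, pn_chases(10))
  pl <- pipeline(lapply(chs, `[[`, "track"))
  id <- identify_controllers(pl$angles, pl$rates, "horizontal", trim = 2)
  expect_lt(abs(id$omega_A$gain / 1.8 - 1), 0.05)
  expect_lt(abs(id$omega_A$delay - 0.026), 1.6 / 190)
  expect_gt(abs(id$omega_A$R), abs(id$theta_E$R))   # discrimination
})

test_that("pure-noise steering correlates with no candidate input", {
  chs <- bp_chases(2)
  pl <- pipeline(lapply(chs, `[[`, "track"))
  set.seed(99)
  rates <- lapply(pl$rates, function(r) {
    r$omega_PH <- rnorm(nrow(r), 0, 300)
    r
  })
  id <- identify_controllers(pl$angles, rates, "horizontal", trim = 2)
  for (nm in names(id)) expect_lt(abs(id[[nm]]$R), 0.7)
})

test_that("recovered parameters approach truth as noise shrinks", {
  noises <- c(0.004, 0.002, 0)
  errs <- vapply(noises, function(nl) {
    chs <- bp_chases(8, noise = nl, seed = 5)
    w <- if (nl == 0) c(0, 0, 0) else c(31, 31, 5)
    pl <- pipeline(lapply(Filter(function(c) c$captured, chs), `[[`, "track"),
                   dw = w[1], sw = w[2], rw = w[3])
    id <- identify_controllers(pl$angles, pl$rates, "horizontal",
                               trim = max(2, ceiling(max(w) / 2)))
    abs(id$theta_E$gain - 26) / 26
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1] + 0.02)     # monotone within tolerance
})

test_that("speed relations recover a constructed lead and reject nulls", {
  chs <- bp_chases(3)
  pl <- pipeline(lapply(chs, `[[`, "track"))
  dt <- 1 / 190
  doctored <- lapply(seq_along(pl$angles), function(i) {
    a <- pl$angles[[i]]
    n <- nrow(a)
    om <- abs(pl$rates[[i]]$omega_PH)
    lead <- 2                                 # speed dips 2 frames early
    sp <- 1.4 - 5e-4 * c(om[(1 + lead):n], rep(om[n], lead))
    a$x_prime <- cumsum(c(0, sp[-n] * dt))    # so hspeed reproduces sp
    a
  })
  fits <- speed_relations(doctored, pl$rates)
  expect_lt(abs(fits$abs_omega_PH$delay + 2 / 190), 1.01 / 190)
  expect_lt(fits$abs_omega_PH$gain, 0)

  set.seed(12)
  nullsp <- lapply(pl$angles, function(a) {
    n <- nrow(a)
    a$x_prime <- cumsum(c(0, (1.2 + rnorm(n - 1, 0, 0.02)) * dt))
    a
  })
  nf <- speed_relations(nullsp, pl$rates)
  expect_lt(abs(nf$abs_omega_PH$R), 0.2)
  expect_lt(abs(nf$theta_EH$R), 0.2)
  expect_lt(abs(nf$omega_EH$R), 0.2)
})

test_that("the angular-size speed law refits its own parameters", {
  set.seed(13)
  rho <- runif(800, 0.2, 30)
  truth <- c(S_g = 0.25, S_v = 0.4, rho_star = 7)
  sp <- ifelse(rho <= 0.5, truth["S_g"],
               rho * truth["S_v"] * exp(-rho / truth["rho_star"]) + truth["S_g"])
  fit <- fit_boeddeker(rho, sp + rnorm(800, 0, 0.01))
  est <- coef(fit)
  expect_lt(abs(est[["S_g"]] / 0.25 - 1), 0.05)
  expect_lt(abs(est[["S_v"]] / 0.4 - 1), 0.05)
  expect_lt(abs(est[["rho_star"]] / 7 - 1), 0.05)
})
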