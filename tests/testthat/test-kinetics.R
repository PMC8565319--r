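# Mass-action schemes: integration, conservation, oracles, derived constants,
# intensity observable.

test_that("mass conservation holds for both schemes at every output time", {
  set.seed(3)
  tt <- 10^seq(-2, 1.5, length.out = 40)
  for (i in 1:5) {
    k <- 10^runif(5, -2, 1)
    p2 <- kinetic_params(10^runif(1, 3, 6), k[2], k[3])
    p3 <- kinetic_params(10^runif(1, 3, 6), k[2], k[3], k2 = k[4], k_m2 = k[5],
                         scheme = "three_step")
    ic <- initial_conditions(runif(1, 1, 5), runif(1, 5, 30))
    for (tr in list(simulate_scheme(p2, ic, tt), simulate_scheme(p3, ic, tt))) {
      ics <- tr$IC1 + if ("IC2" %in% names(tr)) tr$IC2 else 0
      expect_lt(max(abs(tr$SL + ics + tr$ED - ic$SL0)), 1e-8)
      expect_lt(max(abs(tr$P + ics + tr$ED - ic$P0)), 1e-8)
      expect_true(all(as.matrix(tr[, -1]) > -1e-10))
    }
  }
})

test_that("irreversible equal-concentration annealing matches the closed form", {
  p <- kinetic_params(1e5, 0, 0)
  a0 <- 5
  tt <- c(0.01, 0.1, 1, 5, 20)
  tr <- simulate_scheme(p, initial_conditions(a0, a0), tt)
  expect_rel(tr$SL, a0 / (1 + 1e5 * 1e-6 * a0 * tt), 1e-7)
})

test_that("pseudo-first-order trajectories match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  # complement in vast excess: the scheme linearizes with kon = k1 [P]
  k1 <- 10; k_m1 <- 0.05; k2 <- 0.3; k_m2 <- 0.01; kf <- 0.02
  SL0 <- 1e-4; P0 <- 1e4              # ratio 1e8 -> linearization error < 1e-8
  kon <- k1 * 1e-6 * P0
  A <- rbind(c(-kon, k_m1, 0, 0),
             c(kon, -(k_m1 + k2), k_m2, 0),
             c(0, k2, -(k_m2 + kf), 0),
             c(0, 0, kf, 0))
  p <- kinetic_params(k1, k_m1, kf, k2 = k2, k_m2 = k_m2, scheme = "three_step")
  tt <- c(0.5, 2, 10, 50)
  tr <- simulate_scheme(p, initial_conditions(SL0, P0), tt)
  for (i in seq_along(tt)) {
    y <- as.numeric(Matrix::expm(A * tt[i]) %*% c(SL0, 0, 0, 0))
    got <- unlist(tr[i, c("SL", "IC1", "IC2", "ED")], use.names = FALSE)
    expect_lt(max(abs(got - y)) / SL0, 1e-8)
  }
})

test_that("compiled and R integration engines agree", {
  p <- kinetic_params(2.8e5, 6.2, 0.067, k2 = 3.8, k_m2 = 1e-3,
                      scheme = "three_step")
  tt <- 10^seq(-2, 1, length.out = 25)
  a <- simulate_scheme(p, initial_conditions(0.05, 3), tt)
  b <- simulate_scheme(p, initial_conditions(0.05, 3), tt, engine = "r")
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-9)
})

test_that("two-step is the fast-conversion limit of three-step", {
  ic <- initial_conditions(3.6, 12)
  tt <- 10^seq(-1, 1, length.out = 15)
  two <- simulate_scheme(kinetic_params(1e5, 3, 1.75), ic, tt)
  # collapse IC2: conversion IC1 -> IC2 at the two-step kf, instant drain to
  # ED (kf' huge), so IC2 stays negligible and coarse species must agree
  three_b <- simulate_scheme(kinetic_params(1e5, 3, 1e4, k2 = 1.75, k_m2 = 0,
                                            scheme = "three_step"), ic, tt)
  expect_lt(max(abs(three_b$SL - two$SL)) / ic$SL0, 0.01)
  expect_lt(max(abs(three_b$IC1 - two$IC1)) / ic$SL0, 0.01)
  expect_lt(max(abs(three_b$ED - two$ED)) / ic$SL0, 0.01)
})

test_that("duplex formation is monotone when back-conversion is off", {
  p <- kinetic_params(2.8e5, 6.2, 0.067, k2 = 3.8, k_m2 = 0,
                      scheme = "three_step")
  tr <- simulate_scheme(p, initial_conditions(0.05, 2),
                        10^seq(-2, 2.5, length.out = 60))
  expect_true(all(diff(tr$ED) >= -1e-12))
})

test_that("derived constants follow the pre-equilibrium algebra", {
  p3 <- kinetic_params(28e4, 6.2, 0.067, k2 = 3.8, scheme = "three_step")
  d <- derived_constants(p3)
  expect_equal(signif(d$k_eff, 2), 1.7e5)
  expect_equal(derived_constants(kinetic_params(1e5, 4, 1))$K, 2.5e4)
  # k2 = k_m1 cancels
  pc <- kinetic_params(7e4, 2.2, 1, k2 = 2.2, scheme = "three_step")
  expect_equal(derived_constants(pc)$k_eff, 7e4)
  expect_error(derived_constants(kinetic_params(1e5, 0, 1)), "undefined")
})

test_that("predict_intensity is the brightness-weighted concentration sum", {
  p <- kinetic_params(1e5, 2, 0.5)
  tr <- simulate_scheme(p, initial_conditions(2, 8),
                        10^seq(-2, 1, length.out = 20))
  # equal brightness: conservation makes the signal constant
  flat <- predict_intensity(tr, brightness_vector(1, 1))
  expect_lt(diff(range(flat$intensity)), 1e-7 * 2)
  # duplex-only brightness: proportional to [ED], nondecreasing
  ed_only <- predict_intensity(tr, brightness_vector(0, 0))
  expect_equal(ed_only$intensity, tr$ED, tolerance = 1e-12)
  expect_true(all(diff(ed_only$intensity) >= 0))
  # hand-computed weighted sum on three points
  br <- brightness_vector(0.1, 0.95, scale = 2)
  sub3 <- predict_intensity(tr, br)
  expect_equal(sub3$intensity[1:3],
               2 * (0.1 * tr$SL[1:3] + 0.95 * tr$IC1[1:3] + tr$ED[1:3]))
})

test_that("parameter constructors validate their domain", {
  expect_error(kinetic_params(-1, 1, 1), "rates")
  expect_error(kinetic_params(1e5, 1, 1, scheme = "three_step"), "k2")
  expect_error(initial_conditions(0, 5), "SL0")
  expect_error(simulate_scheme(kinetic_params(1e5, 1, 1),
                               initial_conditions(1, 1), c(-1, 2)), ">= 0")
  expect_error(brightness_vector(-0.1, 1), ">= 0")
  expect_error(intensity_trace(1:3, c(1, 2, Inf), initial_conditions(1, 1)),
               "finite")
})
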