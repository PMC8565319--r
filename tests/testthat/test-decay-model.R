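# Analytic IRF-reconvolution model, chi-square, average lifetime.

test_that("model_decay reproduces the sigma -> 0 step-exponential limit", {
  m <- multiexp(1, 0.5)
  expect_equal(model_decay(m, irf(1e-6, 0), 0.5), exp(-1), tolerance = 1e-6)
  # before the pulse the signal is the offset alone
  m2 <- multiexp(c(0.5, 0.5), c(1, 3), offset = 7)
  v <- model_decay(m2, irf(0.1, 5), 5 - 10 * 0.1)
  expect_equal(v, 7, tolerance = 1e-10)
  # step position: half the amplitude at t = t0
  expect_equal(model_decay(multiexp(1, 1e3), irf(1e-3, 2), 2), 0.5,
               tolerance = 1e-3)
})

test_that("model_decay agrees with the numerical convolution oracle", {
  v <- model_decay(multiexp(1, 0.1), irf(0.01, 0.3), 0.3)
  expect_equal(v, conv_oracle(0.3, 0.1, 0.01, 0.3), tolerance = 1e-6)

  # property: randomized parameters over [t0 - 3 sigma, t0 + 10 tau]
  set.seed(101)
  for (i in 1:12) {
    tau <- 10^runif(1, -1.5, 0.8)
    sigma <- 10^runif(1, -2.3, -0.5)
    t0 <- runif(1, 0, 0.5)
    t <- seq(t0 - 3 * sigma, t0 + 10 * tau, length.out = 7)
    a <- model_decay(multiexp(1, tau), irf(sigma, t0), t)
    o <- conv_oracle(t, tau, sigma, t0)
    expect_lt(max(abs(a - o) / pmax(abs(o), 1e-12)), 1e-6)
  }
})

test_that("model_decay is monotone nonincreasing beyond the pulse", {
  set.seed(7)
  for (i in 1:6) {
    m <- multiexp(runif(3), sort(10^runif(3, -1.5, 0.7)))
    resp <- irf(10^runif(1, -2, -0.8), 0.2)
    t <- seq(0.2 + 5 * resp$sigma, 15, length.out = 200)
    expect_true(all(diff(model_decay(m, resp, t)) <= 1e-12))
  }
})

test_that("model_decay validates parameters", {
  expect_error(irf(-0.1), "sigma")
  expect_error(irf(0.1, NaN), "t0")
  expect_error(model_decay(multiexp(1, 1), irf(0.1, 0), c(1, NA)), "times")
  expect_error(multiexp(1, -2), "lifetimes")
  expect_error(multiexp(-1, 2), "amplitudes")
  expect_error(multiexp(numeric(0), numeric(0)), "component")
})

test_that("multiexp stores components in canonical lifetime order", {
  m <- multiexp(c(0.1, 0.46, 0.44), c(2.66, 0.11, 0.71))
  expect_equal(m$lifetimes, c(0.11, 0.71, 2.66))
  expect_equal(m$amplitudes, c(0.46, 0.44, 0.1))
})

test_that("average_lifetime matches the reference values and bounds", {
  expect_equal(round(average_lifetime(
    multiexp(c(0.46, 0.44, 0.10), c(0.11, 0.71, 2.66))), 2), 0.63)
  expect_equal(average_lifetime(multiexp(1, 4.19)), 4.19)
  expect_equal(average_lifetime(multiexp(c(0.5, 0.5), c(1, 3))), 2)
  expect_error(average_lifetime(multiexp(c(0, 0), c(1, 2))), "amplitudes")
  set.seed(11)
  for (i in 1:10) {
    m <- multiexp(runif(4), 10^runif(4, -2, 1))
    av <- average_lifetime(m)
    expect_gte(av, min(m$lifetimes))
    expect_lte(av, max(m$lifetimes))
  }
})

test_that("reduced_chi2 computes the Poisson-weighted statistic", {
  y <- c(10, 20, 30)
  expect_equal(reduced_chi2(y, y, 0)$chi2_reduced, 0)
  # single-bin arithmetic: (4 - 2)^2 / 4 = 1
  expect_equal(reduced_chi2(4, 2, 0)$chi2, 1)
  expect_error(reduced_chi2(y, y[1:2], 0), "shape")
  expect_error(reduced_chi2(y, y, 3), "n_free")
  # permutation invariance
  set.seed(5)
  yy <- rpois(50, 40); ff <- yy + rnorm(50)
  p <- sample(50)
  expect_equal(reduced_chi2(yy, ff, 2)$chi2, reduced_chi2(yy[p], ff[p], 2)$chi2)
})

test_that("reduced chi2 of the true model over Poisson draws is ~1", {
  # expectation of the Poisson-weighted statistic under the true model
  lam <- model_decay(multiexp(2000, 3, 50), irf(0.2, 1),
                     (1:2000 - 0.5) * 20 / 2000)
  set.seed(99)
  y <- rpois(2000, lam)
  expect_equal(reduced_chi2(y, lam, 0)$chi2_reduced, 1, tolerance = 0.05)
})
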