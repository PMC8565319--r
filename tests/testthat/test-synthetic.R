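# Synthetic-data generator: instrument realism, determinism, round trips.

test_that("propagation times map channel positions to seconds", {
  expect_equal(propagation_times(10, 20), 0.5)
  expect_equal(propagation_times(0, 7), 0)
  # the instrument's span of positions and speeds reaches ~0.1-10 s
  tt <- propagation_times(c(0.7, 70), 7)
  expect_equal(tt, c(0.1, 10))
  expect_error(propagation_times(10, 0), "speed")
  expect_error(experiment_design(1, 10, speed = 100), "speed")
})

test_that("pure-species zero-noise curves are proportional to the signature", {
  sig <- ref_sig()
  des <- experiment_design(3.6, 12, seed = 1)
  g <- generate_decay_curves(data.frame(T_s = 0.5, f_SL = 1, f_IC = 0,
                                        f_ED = 0),
                             sig, des, noise = "none", stitch = FALSE)
  cv <- g$curves[[1]][[2]]   # 5 ns window
  shape <- model_decay(multiexp(sig$sl_amplitudes, sig$sl_lifetimes),
                       cv$sigma, cv$times, t0 = sig$t0)
  resid <- stats::lm(cv$counts ~ shape)$residuals
  expect_lt(max(abs(resid)), 1e-6 * max(cv$counts))
  expect_error(generate_decay_curves(data.frame(T_s = 1, f_SL = 0.6,
                                                f_IC = 0.6, f_ED = -0.2),
                                     sig, des), "simplex")
})

test_that("photon totals match the configured budget", {
  des <- experiment_design(3.6, 12, counts_per_curve = 2e5, seed = 9)
  g <- generate_decay_curves(data.frame(T_s = 1, f_SL = 0.4, f_IC = 0.2,
                                        f_ED = 0.4),
                             ref_sig(), des, stitch = FALSE)
  for (cv in g$curves[[1]])
    expect_lt(abs(sum(cv$counts) - 2e5), 4 * sqrt(2e5))
})

test_that("generation is bit-reproducible under a fixed seed", {
  fr <- data.frame(T_s = 1, f_SL = 0.4, f_IC = 0.2, f_ED = 0.4)
  a <- quick_mixtures(fr, seed = 5, counts = 1e5)
  b <- quick_mixtures(fr, seed = 5, counts = 1e5)
  c <- quick_mixtures(fr, seed = 6, counts = 1e5)
  expect_identical(a$curves[[1]][[1]]$counts, b$curves[[1]][[1]]$counts)
  expect_identical(a$stitched[[1]]$counts, b$stitched[[1]]$counts)
  expect_false(identical(a$curves[[1]][[1]]$counts, c$curves[[1]][[1]]$counts))
})

test_that("reduced chi2 of the generating model against its draws is ~1", {
  sig <- ref_sig()
  des <- experiment_design(3.6, 12, seed = 2)
  fr <- data.frame(T_s = 1, f_SL = 0.4, f_IC = 0.2, f_ED = 0.4)
  for (sd in c(2, 3)) {
    des$seed <- sd
    noisy <- generate_decay_curves(fr, sig, des, stitch = FALSE)$curves[[1]][[3]]
    des2 <- des; clean <- generate_decay_curves(fr, sig, des2, noise = "none",
                                                stitch = FALSE)$curves[[1]][[3]]
    expect_equal(reduced_chi2(noisy, clean$counts, 0)$chi2_reduced, 1,
                 tolerance = 0.05)
  }
})

test_that("decay-domain round trip recovers the generating fractions", {
  sig <- ref_sig()
  fr <- data.frame(T_s = c(0.4, 1.5, 4), f_SL = c(0.65, 0.45, 0.25),
                   f_IC = c(0.15, 0.25, 0.3), f_ED = c(0.2, 0.3, 0.45))
  g <- quick_mixtures(fr, seed = 17)
  dec <- decompose_two_step_global(g$stitched, sig)
  expect_lt(max(abs(dec$table$frac_IC - fr$f_IC)), 0.05)
  expect_lt(max(abs(dec$table$frac_ED - fr$f_ED)), 0.05)
})

test_that("trf experiment composes kinetics, timing and decay generation", {
  des <- experiment_design(3.6, 12, counts_per_curve = 1e5, seed = 3)
  # no duplex formation: ED fraction identically zero
  p0 <- kinetic_params(1e5, 2.857, 0)
  e0 <- generate_trf_experiment(des, p0, noise = "none",
                                times = c(0.2, 1, 5))
  expect_equal(e0$truth$fractions$f_ED, rep(0, 3))
  # under the droplet-experiment truth the intermediate rises within the
  # first second and then decays
  p1 <- kinetic_params(1e5, 2.857, 1.75)
  e1 <- generate_trf_experiment(des, p1, noise = "none",
                                times = 10^seq(-1, 1, length.out = 10))
  icf <- e1$truth$fractions$f_IC
  peak <- which.max(icf)
  expect_lt(e1$truth$fractions$T_s[peak], 1.5)
  expect_gt(icf[peak], utils::tail(icf, 1))
  # generated fractions satisfy the conservation invariant
  expect_equal(e1$truth$fractions$f_SL + icf + e1$truth$fractions$f_ED,
               rep(1, 10), tolerance = 1e-8)
})

test_that("stopped-flow traces are exact at zero noise and rank with P0", {
  truth <- kinetic_params(0.91e5, 0.0012, 0.045)
  br <- brightness_vector(I_SL = 0.18, I_IC1 = 0.95)
  designs <- lapply(1:5, function(p) initial_conditions(0.05, p))
  tt <- 10^seq(log10(0.05), log10(400), length.out = 120)
  clean <- generate_trfi_traces(designs, truth, br, times = tt, noise = 0,
                                seed = 1)
  direct <- predict_intensity(simulate_scheme(truth, designs[[3]], tt), br)
  expect_equal(clean[[3]]$intensity, direct$intensity, tolerance = 1e-12)
  # intensity rises faster at higher complement concentration
  half_rise <- vapply(clean, function(tr) {
    y <- tr$intensity - tr$intensity[1]
    tr$times[which(y >= 0.5 * max(y))[1]]
  }, numeric(1))
  expect_true(all(diff(half_rise) < 0))
  expect_error(generate_trfi_traces(designs, truth, br, noise = -0.1), "noise")
})
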