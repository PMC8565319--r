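# Global kinetic fitting: trajectories (droplet mode) and intensity traces
# (stopped-flow mode).

test_that("noiseless trajectory fit recovers the generating rates", {
  truth <- kinetic_params(1e5, 2.857, 1.75)
  designs <- list(initial_conditions(3.6, 12), initial_conditions(3.6, 24))
  exps <- generate_trajectory_data(designs, truth, noise = 0, seed = 1)
  fit <- fit_concentration_trajectories(exps, n_starts = 2, seed = 1)
  expect_rel(fit$params$k1, 1e5, 1e-5)
  expect_rel(fit$params$k_m1, 2.857, 1e-5)
  expect_rel(fit$params$kf, 1.75, 1e-5)
  expect_rel(fit$K, 1e5 / 2.857, 1e-5)
})

test_that("trajectory fit flags a flat k1 direction as a lower bound", {
  # association much faster than the sampled grid resolves: only K and kf are
  # constrained, so the profile along k1 at fixed K is flat
  truth <- kinetic_params(2e7, 2e7 / 3.5e4, 1.75)
  designs <- list(initial_conditions(3.6, 12), initial_conditions(4.3, 14.4))
  exps <- generate_trajectory_data(designs, truth, noise = 0.05, seed = 4)
  fit <- fit_concentration_trajectories(exps, n_starts = 3, seed = 2)
  expect_true(fit$k1_lower_bound)
  expect_rel(fit$params$kf, 1.75, 0.25)
})

test_that("trajectory fit validates input size", {
  truth <- kinetic_params(1e5, 2.9, 1.75)
  short <- generate_trajectory_data(list(initial_conditions(3.6, 12)), truth,
                                    times = c(0.5, 5), noise = 0, seed = 1)
  expect_error(fit_concentration_trajectories(short), "3 informative")
})

test_that("noiseless intensity-trace fit recovers rates and brightnesses", {
  truth <- kinetic_params(0.91e5, 0.0012, 0.045)
  br <- brightness_vector(I_SL = 0.18, I_IC1 = 0.95)
  designs <- list(initial_conditions(0.05, 1), initial_conditions(0.05, 5))
  traces <- generate_trfi_traces(designs, truth, br, noise = 0,
                                 times = 10^seq(log10(0.05), log10(500),
                                                length.out = 300),
                                 seed = 1)
  fit <- fit_intensity_traces(traces, "two_step", n_starts = 2, seed = 1)
  expect_rel(fit$params$k1, 0.91e5, 1e-4)
  expect_rel(fit$params$kf, 0.045, 1e-3)
  expect_equal(fit$brightness$I_IC1, 0.95, tolerance = 1e-3)
  expect_equal(fit$brightness$I_SL, 0.18, tolerance = 1e-3)
})

test_that("fixed parameters are honoured and misnamed ones rejected", {
  truth <- kinetic_params(0.91e5, 0.0012, 0.045)
  br <- brightness_vector(I_SL = 0.18, I_IC1 = 0.95)
  designs <- list(initial_conditions(0.05, 2), initial_conditions(0.05, 4))
  traces <- generate_trfi_traces(designs, truth, br, noise = 0,
                                 times = 10^seq(log10(0.05), log10(500),
                                                length.out = 200),
                                 seed = 2)
  fit <- fit_intensity_traces(traces, "two_step",
                              fixed = list(I_SL = 0.18, k_m1 = 0.0012),
                              n_starts = 2, seed = 1)
  expect_equal(fit$brightness$I_SL, 0.18)
  expect_equal(fit$params$k_m1, 0.0012)
  expect_rel(fit$params$k1, 0.91e5, 1e-3)
  expect_error(fit_intensity_traces(traces, "two_step",
                                    fixed = list(I_bogus = 1)), "unknown fixed")
  expect_warning(fit_intensity_traces(traces[1], "two_step", n_starts = 1,
                                      seed = 1),
                 "weakly identifiable")
})

test_that("kinetic fit serializes to JSON", {
  truth <- kinetic_params(1e5, 2.857, 1.75)
  exps <- generate_trajectory_data(list(initial_conditions(3.6, 12),
                                        initial_conditions(3.6, 24)),
                                   truth, noise = 0, seed = 1)
  fit <- fit_concentration_trajectories(exps, n_starts = 1, seed = 1)
  path <- tempfile(fileext = ".json")
  write_kinetic_fit_json(fit, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$scheme, "two_step")
  expect_equal(j$rates$k1, fit$params$k1, tolerance = 1e-12)
  expect_equal(j$K, fit$K, tolerance = 1e-12)
})
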