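# Species signatures and global three-species decomposition.

noiseless_refs <- function(seed = 3) {
  des <- experiment_design(3.6, 12, seed = seed)
  generate_decay_curves(
    data.frame(T_s = c("SL_ref", "ED_ref"), f_SL = c(1, 0), f_IC = 0,
               f_ED = c(0, 1), stringsAsFactors = FALSE),
    ref_sig(), des, noise = "none", stitch = FALSE)
}

test_that("signature fit reproduces noiseless reference curves exactly", {
  refs <- noiseless_refs()
  fs <- suppressWarnings(fit_signatures(refs$curves[[1]], refs$curves[[2]],
                                        irf_init = irf(0.01, 0.05),
                                        n_starts = 2))
  expect_equal(fs$sl_amplitudes, c(0.46, 0.44, 0.10), tolerance = 1e-6)
  expect_rel(fs$sl_lifetimes, c(0.11, 0.71, 2.66), 1e-6)
  expect_rel(fs$ed_lifetime, 4.19, 1e-6)
  expect_rel(fs$t0, 0.1, 1e-3)
})

test_that("signature fit recovers the lifetimes from Poisson references", {
  des <- experiment_design(3.6, 12, seed = 6)
  refs <- generate_decay_curves(
    data.frame(T_s = c("SL_ref", "ED_ref"), f_SL = c(1, 0), f_IC = 0,
               f_ED = c(0, 1), stringsAsFactors = FALSE),
    ref_sig(), des, stitch = FALSE)
  fs <- suppressWarnings(fit_signatures(refs$curves[[1]], refs$curves[[2]],
                                        irf_init = irf(0.01, 0.05),
                                        n_starts = 3, seed = 2))
  expect_lt(max(abs(fs$sl_lifetimes / c(0.11, 0.71, 2.66) - 1)), 0.10)
  expect_rel(fs$ed_lifetime, 4.19, 0.10)
  expect_lt(max(abs(fs$sl_amplitudes - c(0.46, 0.44, 0.10))), 0.05)
  expect_lt(attr(fs, "fit_sl")$chi2_reduced, 1.3)
})

test_that("one-step decomposition solves constructed mixtures", {
  sig <- ref_sig()
  g <- quick_mixtures(data.frame(T_s = c(0.5, 1), f_SL = c(0.5, 1),
                                 f_IC = 0, f_ED = c(0.5, 0)),
                      noise = "none")
  # single-window curves
  d <- decompose_one_step(lapply(g$curves, `[[`, 3), sig)
  expect_equal(d$alpha[1], 0.5, tolerance = 1e-6)
  expect_equal(d$alpha[2], 0, tolerance = 1e-6)    # pure hairpin boundary
})

test_that("one-step fit misses a short-lived component that Eq.-6 captures", {
  sig <- ref_sig()
  g <- quick_mixtures(data.frame(T_s = 1, f_SL = 0.5, f_IC = 0.3, f_ED = 0.2),
                      seed = 13)
  one <- decompose_one_step(g$stitched, sig)
  two <- decompose_two_step_global(g$stitched, sig, tau_ic = 0.045)
  expect_gt(attr(one, "chi2_reduced_global"), 2 * two$chi2_reduced)
  expect_gt(attr(one, "chi2_reduced_global"), 1.5)
  expect_lt(two$chi2_reduced, 1.2)
})

test_that("three-species decomposition recovers noiseless mixtures exactly", {
  sig <- ref_sig()
  fr <- data.frame(T_s = c(0.3, 1, 3), f_SL = c(0.7, 0.5, 0.2),
                   f_IC = c(0.1, 0.2, 0.35), f_ED = c(0.2, 0.3, 0.45))
  g <- quick_mixtures(fr, noise = "none")
  dec <- decompose_two_step_global(g$stitched, sig)
  expect_equal(dec$table$frac_IC, fr$f_IC, tolerance = 1e-6)
  expect_equal(dec$table$frac_ED, fr$f_ED, tolerance = 1e-6)
  expect_rel(dec$tau_ic, 0.045, 1e-3)
  # fractions sum to one exactly by construction
  expect_equal(dec$table$frac_SL + dec$table$frac_IC + dec$table$frac_ED,
               rep(1, 3))
})

test_that("decomposition is scale-invariant and consistent with one-step", {
  sig <- ref_sig()
  fr <- data.frame(T_s = c(0.5, 2), f_SL = c(0.6, 0.3), f_IC = 0,
                   f_ED = c(0.4, 0.7))
  g <- quick_mixtures(fr, noise = "none")
  curves <- lapply(g$curves, `[[`, 3)
  dec <- decompose_two_step_global(curves, sig, beta_zero = TRUE)
  one <- decompose_one_step(curves, sig)
  expect_equal(dec$table$frac_ED, one$alpha, tolerance = 1e-9)

  scaled <- curves
  scaled[[1]]$counts <- scaled[[1]]$counts * 3
  dec2 <- decompose_two_step_global(scaled, sig, beta_zero = TRUE)
  expect_equal(dec2$table$frac_ED, dec$table$frac_ED, tolerance = 1e-8)
  expect_equal(dec2$table$scale[1] / dec$table$scale[1], 3, tolerance = 1e-6)
})

test_that("shared tau_IC is stable across data seeds", {
  sig <- ref_sig()
  fr <- data.frame(T_s = c(0.3, 1, 3), f_SL = c(0.6, 0.5, 0.4),
                   f_IC = c(0.15, 0.25, 0.3), f_ED = c(0.25, 0.25, 0.3))
  taus <- vapply(c(4, 5), function(sd) {
    g <- quick_mixtures(fr, seed = sd)
    decompose_two_step_global(g$stitched, sig)$tau_ic
  }, numeric(1))
  expect_lt(max(abs(taus / 0.045 - 1)), 0.2)
})

test_that("to_concentrations rescales fractions and propagates errors", {
  tab <- data.frame(T_s = 1, frac_SL = 0.5, frac_IC = 0.25, frac_ED = 0.25,
                    se_SL = 0.02, se_IC = 0.01, se_ED = 0.01)
  conc <- to_concentrations(tab, 3.6)
  expect_equal(unlist(conc[1, c("conc_SL", "conc_IC", "conc_ED")],
                      use.names = FALSE), c(1.8, 0.9, 0.9))
  expect_equal(conc$se_IC, 0.036)
  # completed reaction
  done <- to_concentrations(data.frame(T_s = 1, frac_SL = 0, frac_IC = 0,
                                       frac_ED = 1, se_SL = 0, se_IC = 0,
                                       se_ED = 0), 2)
  expect_equal(unlist(done[1, c("conc_SL", "conc_IC", "conc_ED")],
                      use.names = FALSE), c(0, 0, 2))
  expect_error(to_concentrations(tab, -1), "invalid parameter")
})
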