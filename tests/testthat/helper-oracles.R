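# Shared fixtures and independent oracles used across the suite.

# Reference signature values (equilibrated hairpin / duplex) used as
# generating truth throughout.
ref_sig <- function() default_signatures()

# Independent numerical-convolution oracle for the analytic reconvolution
# model: Simpson integration of
#   integral_{-inf}^{t - t0} exp(-(t - t0 - x)/tau) phi_sigma(x) dx.
# The integrand is proportional to a Gaussian of width sigma centred at
# x* = sigma^2/tau (the exponential tilts the IRF), so the quadrature domain
# is centred there; outside +/- 9 sigma the integrand is negligible.
conv_oracle <- function(t, tau, sigma, t0, A = 1, C = 0) {
  vapply(t, function(ti) {
    upper <- ti - t0
    centre <- sigma^2 / tau
    lo <- centre - 9 * sigma
    hi <- min(upper, centre + 9 * sigma)
    if (hi <= lo) return(C)
    n <- 4000L                      # even number of intervals
    x <- seq(lo, hi, length.out = n + 1L)
    fx <- exp(-(ti - t0 - x) / tau) * stats::dnorm(x, 0, sigma)
    h <- (hi - lo) / n
    w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
    C + A * sum(w * fx) * h / 3
  }, numeric(1))
}

# Quick synthetic mixture set for decomposition tests (smaller than the
# acceptance-scale run to keep the suite fast).
quick_mixtures <- function(fracs, seed = 42, counts = 1e6, noise = "poisson") {
  des <- experiment_design(3.6, 12, counts_per_curve = counts, seed = seed)
  generate_decay_curves(fracs, ref_sig(), des, noise = noise)
}

# One noiseless single-window curve from an arbitrary model.
model_curve <- function(model, response, window = 20, n_bins = 1000) {
  times <- (seq_len(n_bins) - 0.5) * window / n_bins
  decay_curve(times, model_decay(model, response, times), window,
              sigma = response$sigma)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
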