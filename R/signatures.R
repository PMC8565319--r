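#' Reference decay signatures of the annealing species
#'
#' Container for the fixed fluorescence-lifetime signatures used throughout
#' the three-species decomposition: the FRET-quenched stem-loop hairpin is a
#' triexponential with amplitudes summing to one,
#' \eqn{F_{SL}(t) = \sum_{i=1}^{3} A_i e^{-t/\tau_i}}, the extended duplex a
#' unit-amplitude monoexponential \eqn{F_{ED}(t) = e^{-t/\tau_{ED}}}, and the
#' transient intermediate complex a monoexponential
#' \eqn{F_{IC}(t) = e^{-t/\tau_{IC}}} whose single shared lifetime is
#' determined by the global decomposition (left `NA` until then).
#'
#' @param sl_amplitudes Stem-loop amplitudes (length 3 typical), sum to 1.
#' @param sl_lifetimes Stem-loop lifetimes (ns).
#' @param ed_lifetime Extended-duplex lifetime (ns).
#' @param tau_ic Intermediate-complex lifetime (ns) or `NA` if not yet fitted.
#' @param t0 Time origin of the reference fits (ns), default 0.
#' @return An object of class `species_signatures`.
#' @export
species_signatures <- function(sl_amplitudes, sl_lifetimes, ed_lifetime,
                               tau_ic = NA_real_, t0 = 0) {
  sl_amplitudes <- as.numeric(sl_amplitudes)
  if (any(sl_amplitudes < 0)) stop("SL amplitudes must be >= 0", call. = FALSE)
  if (abs(sum(sl_amplitudes) - 1) > 1e-9)
    stop("SL amplitudes must sum to 1", call. = FALSE)
  if (length(sl_amplitudes) != length(sl_lifetimes))
    stop("SL amplitudes/lifetimes length mismatch", call. = FALSE)
  if (any(sl_lifetimes <= 0) || ed_lifetime <= 0)
    stop("lifetimes must be > 0", call. = FALSE)
  if (!is.na(tau_ic) && tau_ic <= 0) stop("tau_ic must be > 0", call. = FALSE)
  ord <- order(sl_lifetimes)
  structure(list(sl_amplitudes = sl_amplitudes[ord],
                 sl_lifetimes = sl_lifetimes[ord],
                 ed_lifetime = ed_lifetime, tau_ic = tau_ic, t0 = t0),
            class = "species_signatures")
}

#' @export
print.species_signatures <- function(x, ...) {
  cat("Species decay signatures\n  SL (stem-loop):")
  cat(sprintf(" A=%.3g tau=%.3g ns;", x$sl_amplitudes, x$sl_lifetimes), "\n")
  cat(sprintf("  ED (duplex): tau = %.4g ns\n", x$ed_lifetime))
  cat(sprintf("  IC lifetime: %s\n",
              if (is.na(x$tau_ic)) "not fitted" else sprintf("%.4g ns", x$tau_ic)))
  invisible(x)
}

# IRF-convolved signature shapes on a curve's grid (unit total amplitude)
signature_basis <- function(sig, curve, which = c("SL", "IC", "ED"),
                            tau_ic = sig$tau_ic) {
  cols <- lapply(which, function(sp) switch(sp,
    SL = model_decay(multiexp(sig$sl_amplitudes, sig$sl_lifetimes),
                     curve$sigma, curve$times, t0 = sig$t0),
    IC = model_decay(multiexp(1, tau_ic), curve$sigma, curve$times, t0 = sig$t0),
    ED = model_decay(multiexp(1, sig$ed_lifetime), curve$sigma, curve$times,
                     t0 = sig$t0)))
  do.call(cbind, cols)
}

# Global fit of reference curves sharing component lifetimes/amplitudes, with
# free per-curve scale and dark-count offset (profiled linearly).
fit_shared_multiexp <- function(curves, n_comp, irf_init,
                                n_starts = 5, seed = 1) {
  ws <- lapply(curves, decay_weights)
  n_amp_free <- n_comp - 1   # softmax logits; amplitudes sum to 1

  unpack <- function(par) {
    taus <- exp(par[seq_len(n_comp)])
    t0 <- par[n_comp + 1]
    z <- c(par[n_comp + 1 + seq_len(n_amp_free)], 0)
    list(taus = taus, t0 = t0, amps = exp(z - max(z)) / sum(exp(z - max(z))))
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    if (any(p$taus > 500) || any(p$taus < 1e-4)) stop("tau out of bounds")
    unlist(lapply(seq_along(curves), function(i) {
      cv <- curves[[i]]
      shape <- model_decay(multiexp(p$amps, p$taus), cv$sigma, cv$times, t0 = p$t0)
      wnnls(segment_design(shape, cv$segment), cv$counts, ws[[i]])$resid
    }))
  }

  mean_tau <- mean(vapply(curves, function(cv)
    sum(cv$times * cv$counts) / sum(cv$counts), numeric(1)))
  par0 <- c(log(mean_tau * 3^(seq_len(n_comp) - (n_comp + 1) / 2)),
            irf_init$t0, rep(0, n_amp_free))
  best <- NULL
  for (start in multistart_inits(par0, n_starts, seed)) {
    f <- tryCatch(lm_fit(resid_fn, start), error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$ssr < best$ssr)) best <- f
  }
  if (is.null(best)) stop("fit failure: shared multiexponential fit", call. = FALSE)
  p <- unpack(best$par)

  # recover per-curve (per-segment) scale/offset
  scales <- offsets <- numeric(length(curves))
  nbins <- 0; n_lin <- 0
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    shape <- model_decay(multiexp(p$amps, p$taus), cv$sigma, cv$times, t0 = p$t0)
    cf <- wnnls(segment_design(shape, cv$segment), cv$counts, ws[[i]])$coef
    scales[i] <- cf[1]; offsets[i] <- cf[2]
    nbins <- nbins + length(cv$times)
    n_lin <- n_lin + 2 * length(unique(cv$segment))
  }
  n_free <- n_comp + 1 + n_amp_free + n_lin
  list(amplitudes = p$amps / sum(p$amps), lifetimes = p$taus, t0 = p$t0,
       scales = scales, offsets = offsets,
       chi2_reduced = best$ssr / (nbins - n_free), converged = best$converged)
}

#' Fit the reference species signatures
#'
#' Globally fits all pre-mix stem-loop reference curves to one shared
#' triexponential decay (amplitudes constrained to sum to one) and all
#' equilibrated-duplex reference curves to one shared monoexponential, each
#' with free per-curve scale and dark-count offset. The fitted signatures are
#' subsequently held fixed during mixture decomposition: residual free
#' stem-loop interconverts between its conformers much faster than the
#' annealing reaction progresses, so its decay law does not change along the
#' reaction coordinate.
#'
#' @param sl_curves List of [decay_curve()]s tagged `"SL_ref"` (or any curves
#'   to treat as stem-loop references).
#' @param ed_curves List of duplex reference curves (`"ED_ref"`).
#' @param irf_init Initial [irf()] guess for the shared time origin; per-bin
#'   IRF widths are taken from each curve's metadata.
#' @param n_sl_components Number of stem-loop components (default 3, as
#'   established for this hairpin; a warning is issued if 3 components do not
#'   improve on 2 by more than `delta_chi2`, but 3 are still returned).
#' @param delta_chi2 Improvement threshold for that warning (default 0.02).
#' @param n_starts,seed Multi-start control.
#' @return A [species_signatures()] object with attributes `fit_sl` and
#'   `fit_ed` carrying scales, offsets and reduced chi-squares.
#' @export
fit_signatures <- function(sl_curves, ed_curves, irf_init = irf(0.01, 0),
                           n_sl_components = 3, delta_chi2 = 0.02,
                           n_starts = 5, seed = 1) {
  stopifnot(length(sl_curves) >= 1, length(ed_curves) >= 1)
  fit_sl <- fit_shared_multiexp(sl_curves, n_sl_components, irf_init,
                                n_starts, seed)
  if (n_sl_components >= 3) {
    fit_sl2 <- tryCatch(
      fit_shared_multiexp(sl_curves, n_sl_components - 1, irf_init,
                          n_starts, seed),
      error = function(e) NULL)
    if (!is.null(fit_sl2) &&
        (fit_sl2$chi2_reduced - fit_sl$chi2_reduced) < delta_chi2)
      warning(sprintf(
        "%d SL components improve reduced chi2 by only %.3g over %d; keeping %d",
        n_sl_components, fit_sl2$chi2_reduced - fit_sl$chi2_reduced,
        n_sl_components - 1, n_sl_components), call. = FALSE)
  }
  fit_ed <- fit_shared_multiexp(ed_curves, 1, irf_init, n_starts, seed)
  sig <- species_signatures(fit_sl$amplitudes, fit_sl$lifetimes,
                            fit_ed$lifetimes, t0 = fit_sl$t0)
  attr(sig, "fit_sl") <- fit_sl
  attr(sig, "fit_ed") <- fit_ed
  sig
}
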