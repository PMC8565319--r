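# Global fitting of the annealing schemes to species-concentration
# trajectories (droplet TRF mode) and stopped-flow intensity traces
# (transient-intensity mode). Rate constants are shared across all
# experiments of one fit; per-experiment knowns (SL0, P0) stay fixed.
# Positivity is enforced by a log transform; Levenberg-Marquardt runs in the
# transformed space with seeded multi-starts.

rate_names <- function(scheme) {
  if (scheme == "two_step") c("k1", "k_m1", "kf") else c("k1", "k_m1", "k2", "k_m2", "kf")
}

params_from_vec <- function(k, scheme) {
  if (scheme == "two_step") kinetic_params(k[["k1"]], k[["k_m1"]], k[["kf"]])
  else kinetic_params(k[["k1"]], k[["k_m1"]], k[["kf"]], k2 = k[["k2"]],
                      k_m2 = k[["k_m2"]], scheme = "three_step")
}

# crude, data-driven initial rates: half-rise of the observable sets the
# pseudo-first-order scale, the late tail sets kf
guess_rise_times <- function(times, y) {
  y <- y - min(y)
  if (max(y) <= 0) return(c(t50 = stats::median(times), t90 = max(times)))
  c(t50 = times[which(y >= 0.5 * max(y))[1]],
    t90 = times[which(y >= 0.9 * max(y))[1]])
}

#' Global fit of the two-step scheme to species-concentration trajectories
#'
#' Fits shared rate constants (k1, k-1, kf) to the observed SL/IC/ED
#' concentrations of one or more mixing experiments by Levenberg-Marquardt
#' least squares, with the known total strand concentrations of each
#' experiment held fixed. Residuals are absolute (uM) by default, matching
#' the roughly constant dispersion of decomposition-derived concentrations;
#' set `weights = "relative"` for relative weighting. Because the association
#' step can be effectively instantaneous on the sampled time grid, the fit
#' profiles the objective along k1 (at fixed K = k1/k-1, refitting kf) and
#' flags k1 as a lower bound when the profile is flat.
#'
#' @param experiments List of experiments; each a list with `init`
#'   ([initial_conditions()]) and `data` (data frame `T_s`, `conc_SL`,
#'   `conc_IC`, `conc_ED` in uM, e.g. from [to_concentrations()]).
#' @param scheme Kinetic scheme; only `"two_step"` trajectories are observed
#'   in the droplet experiment (the bright second intermediate is
#'   indistinguishable from duplex in the decay domain).
#' @param init Optional [kinetic_params()] initial guess.
#' @param weights `"absolute"` (default) or `"relative"`.
#' @param n_starts,seed Multi-start control.
#' @param flat_threshold Flatness criterion in sigma units: k1 is flagged as
#'   a lower bound when increasing it 3-10x at fixed K raises the objective
#'   by less than `flat_threshold^2` residual variances (default 2, i.e. the
#'   profile stays within ~2 sigma of the minimum).
#' @return Object of class `kinetic_fit`: `params`, `K`, standard errors,
#'   `chi2_reduced` (residual mean square), `k1_lower_bound` flag,
#'   `covariance` (log-rate space).
#' @export
fit_concentration_trajectories <- function(experiments, scheme = "two_step",
                                           init = NULL, weights = "absolute",
                                           n_starts = 5, seed = 1,
                                           flat_threshold = 2) {
  stopifnot(scheme == "two_step")
  for (ex in experiments)
    if (nrow(ex$data) < 3)
      stop("data error: fewer than 3 informative time points", call. = FALSE)

  obs_cols <- c("conc_SL", "conc_IC", "conc_ED")
  resid_exp <- function(params, ex) {
    tr <- simulate_scheme(params, ex$init, ex$data$T_s, rtol = 1e-8)
    pred <- cbind(tr$SL, tr$IC1, tr$ED)
    obs <- as.matrix(ex$data[, obs_cols])
    r <- obs - pred
    if (weights == "relative") r <- r / pmax(abs(obs), 0.05 * ex$init$SL0)
    as.numeric(r)
  }
  resid_fn <- function(lpar) {
    k <- stats::setNames(exp(lpar), rate_names(scheme))
    if (k[["k1"]] > 1e10 || k[["k1"]] < 1 ||
        any(k[-1] > 1e3) || any(k[-1] < 1e-9))
      stop("rate out of bounds")
    unlist(lapply(experiments, function(ex) resid_exp(params_from_vec(k, scheme), ex)))
  }

  if (is.null(init)) {
    # first-point formation speed bounds k1; mid time scale sets kf
    k1g <- max(vapply(experiments, function(ex) {
      i <- which.min(ex$data$T_s)
      (ex$data$conc_IC[i] + ex$data$conc_ED[i]) /
        (ex$data$T_s[i] * ex$init$SL0 * ex$init$P0 * K1_UM)
    }, numeric(1)), 1e2)
    P0m <- mean(vapply(experiments, function(ex) ex$init$P0, numeric(1)))
    init <- kinetic_params(k1g, k1g * P0m * K1_UM, 1 / stats::median(
      unlist(lapply(experiments, function(ex) ex$data$T_s))))
  }
  par0 <- log(c(init$k1, init$k_m1, init$kf))

  best <- NULL
  for (start in multistart_inits(par0, n_starts, seed, spread = 1)) {
    f <- tryCatch(lm_fit(resid_fn, start), error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$ssr < best$ssr)) best <- f
  }
  if (is.null(best)) stop("fit failure: no start converged", call. = FALSE)

  k <- stats::setNames(exp(best$par), rate_names(scheme))
  params <- params_from_vec(k, scheme)
  dof <- best$n_resid - length(best$par)
  se_log <- sqrt(pmax(diag(best$cov), 0))
  se <- k * se_log
  Kconst <- k[["k1"]] / k[["k_m1"]]
  # se of K = k1/k_m1 in log space: var(logK) = var(lk1)+var(lkm1)-2cov
  vK <- best$cov[1, 1] + best$cov[2, 2] - 2 * best$cov[1, 2]
  K_se <- Kconst * sqrt(max(vK, 0))

  # profile along k1 at fixed K: flat objective means k1 is only bounded below
  prof <- vapply(c(3, 10), function(m) {
    pf <- function(lkf) {
      kk <- c(k1 = k[["k1"]] * m, k_m1 = k[["k_m1"]] * m, kf = exp(lkf))
      sum(unlist(lapply(experiments, function(ex)
        resid_exp(params_from_vec(kk, scheme), ex)))^2)
    }
    stats::optimize(pf, log(k[["kf"]]) + c(-1, 1))$objective
  }, numeric(1))
  k1_lower_bound <- all(prof - best$ssr <
                          flat_threshold^2 * best$ssr / dof)

  structure(list(params = params, K = Kconst, K_se = K_se,
                 rate_se = stats::setNames(se, rate_names(scheme)),
                 chi2_reduced = best$ssr / dof, ssr = best$ssr,
                 covariance = best$cov, k1_lower_bound = k1_lower_bound,
                 converged = best$converged, seed = seed),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  K = k1/k-1 = %.4g M^-1 (+/- %.2g)\n", x$K, x$K_se))
  if (isTRUE(x$k1_lower_bound))
    cat("  note: objective flat in k1 at fixed K -> k1 is a lower bound\n")
  if (!is.null(x$brightness)) {
    b <- x$brightness
    cat(sprintf("  brightness: I_SL = %.3g, I_IC1 = %.3g%s (I_ED = 1)\n",
                b$I_SL, b$I_IC1,
                if (!is.na(b$I_IC2)) sprintf(", I_IC2 = %.3g", b$I_IC2) else ""))
  }
  cat(sprintf("  residual mean square = %.4g\n", x$chi2_reduced))
  invisible(x)
}

#' Global fit of stopped-flow intensity traces
#'
#' Fits shared rate constants and shared relative species brightnesses
#' (duplex brightness fixed at 1, per-trace overall scale profiled out
#' analytically) to a set of stopped-flow traces recorded at different
#' complement concentrations. Any rate or brightness can be held fixed via
#' `fixed` (e.g. `fixed = list(I_IC1 = 0.01)` for the nearly dark kissing
#' complex whose lifetime is a hundredth of the duplex lifetime, or
#' `fixed = list(k_m2 = 0)` for irreversible intermediate conversion).
#'
#' @param traces List of [intensity_trace()]s (>= 2 different `P0` for k1 to
#'   be identifiable; a single trace with free brightnesses draws a warning).
#' @param scheme `"two_step"` or `"three_step"`.
#' @param fixed Named list of fixed parameters among k1, k_m1, k2, k_m2, kf,
#'   I_SL, I_IC1, I_IC2.
#' @param init Optional named vector of initial values for the free
#'   parameters (same names).
#' @param noise Relative noise level used to weight residuals (default
#'   `"auto"`: unweighted).
#' @param n_starts,seed Multi-start control.
#' @return A `kinetic_fit` with additional elements `brightness`
#'   ([brightness_vector()]), `trace_scales`, and `k_m2_upper_bound` when the
#'   back-conversion rate collapses to the boundary.
#' @export
fit_intensity_traces <- function(traces, scheme = c("two_step", "three_step"),
                                 fixed = list(), init = NULL, noise = "auto",
                                 n_starts = 5, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(length(traces) >= 1)
  bright_names <- if (scheme == "two_step") c("I_SL", "I_IC1")
                  else c("I_SL", "I_IC1", "I_IC2")
  all_names <- c(rate_names(scheme), bright_names)
  if (length(traces) < 2 && !all(bright_names %in% names(fixed)))
    warning("single trace with free brightnesses: parameters weakly identifiable",
            call. = FALSE)
  bad <- setdiff(names(fixed), all_names)
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  free_names <- setdiff(all_names, names(fixed))

  assemble <- function(lpar) {
    v <- stats::setNames(numeric(length(all_names)), all_names)
    v[free_names] <- exp(lpar)
    for (nm in names(fixed)) v[nm] <- fixed[[nm]]
    v
  }
  model_traces <- function(v) {
    params <- params_from_vec(v[rate_names(scheme)], scheme)
    br <- if (scheme == "two_step")
      brightness_vector(v[["I_SL"]], v[["I_IC1"]])
    else brightness_vector(v[["I_SL"]], v[["I_IC1"]], v[["I_IC2"]])
    lapply(traces, function(tr)
      predict_intensity(simulate_scheme(params, tr$design, tr$times,
                                        rtol = 1e-8), br)$intensity)
  }
  # physically sensible search bounds: first-order rates cannot exceed the
  # mixing-time resolution, k1 stays below diffusion control, and no species
  # outshines the fully unquenched duplex (I_ED = 1) by more than 50%
  lo <- log(ifelse(free_names == "k1", 1e0,
                   ifelse(free_names %in% bright_names, 1e-6, 1e-9)))
  hi <- log(ifelse(free_names == "k1", 1e10,
                   ifelse(free_names %in% bright_names, 1.5, 1e2)))
  resid_fn <- function(lpar) {
    if (any(lpar > hi) || any(lpar < lo)) stop("parameter out of bounds")
    preds <- model_traces(assemble(lpar))
    unlist(lapply(seq_along(traces), function(j) {
      pred <- preds[[j]]
      obs <- traces[[j]]$intensity
      s <- sum(pred * obs) / max(sum(pred^2), 1e-300)  # profiled scale
      obs - s * pred
    }))
  }

  starts <- NULL
  if (is.null(init)) {
    # pseudo-first-order half-rise of the fastest trace bounds k1; the slow
    # tail of the slowest trace sets kf
    rises <- t(vapply(traces, function(tr)
      guess_rise_times(tr$times, tr$intensity), numeric(2)))
    P0s <- vapply(traces, function(tr) tr$design$P0, numeric(1))
    k1g <- log(2) / (min(rises[, "t50"]) * max(P0s) * K1_UM)
    kfg <- log(10) / max(rises[, "t90"])
    init <- c(k1 = k1g, k_m1 = 0.3 * kfg, kf = kfg,
              k2 = 3 * kfg, k_m2 = 0.01 * kfg,
              I_SL = 0.2, I_IC1 = if (scheme == "two_step") 0.8 else 0.05,
              I_IC2 = 0.8)
    if (scheme == "three_step") {
      # structured starts from the robust two-step fit: under a fast IC1
      # pre-equilibrium the two-step description has k1_eff = k1 k2/(k_m1+k2)
      # and its intermediate is IC2, so invert that reduction over a small
      # grid of (k_m1 magnitude, k2/k_m1 ratio)
      pre <- fit_intensity_traces(traces, "two_step",
                                  fixed = fixed[names(fixed) %in%
                                                  c("k1", "k_m1", "kf", "I_SL")],
                                  n_starts = 3, seed = seed)
      starts <- list()
      for (m in c(0.5, 5, 50)) for (r in c(0.3, 1, 3)) {
        v0 <- c(k1 = pre$params$k1 * (1 + 1 / r), k_m1 = m, k2 = m * r,
                k_m2 = 0.02 * pre$params$kf, kf = pre$params$kf,
                I_SL = max(pre$brightness$I_SL, 1e-3),
                I_IC1 = 0.05, I_IC2 = min(pre$brightness$I_IC1, 1.4))
        starts <- c(starts, list(log(pmax(v0[free_names], 1e-8))))
      }
    }
  }
  par0 <- pmin(pmax(log(pmax(init[free_names], 1e-12)), lo + 0.1), hi - 0.1)
  starts <- c(list(par0), starts,
              multistart_inits(par0, n_starts, seed, spread = 0.7)[-1])

  best <- NULL
  for (start in starts) {
    start <- pmin(pmax(start, lo + 1e-3), hi - 1e-3)
    f <- tryCatch(lm_fit(resid_fn, start), error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$ssr < best$ssr)) best <- f
  }
  if (is.null(best)) stop("fit failure: no start converged", call. = FALSE)

  v <- assemble(best$par)
  params <- params_from_vec(v[rate_names(scheme)], scheme)
  br <- if (scheme == "two_step") brightness_vector(v[["I_SL"]], v[["I_IC1"]])
        else brightness_vector(v[["I_SL"]], v[["I_IC1"]], v[["I_IC2"]])
  preds <- model_traces(v)
  scales <- vapply(seq_along(traces), function(j)
    sum(preds[[j]] * traces[[j]]$intensity) / max(sum(preds[[j]]^2), 1e-300),
    numeric(1))
  se_log <- stats::setNames(sqrt(pmax(diag(best$cov), 0)), free_names)
  se <- v[free_names] * se_log
  dof <- best$n_resid - length(best$par)
  k_m2_ub <- scheme == "three_step" && !("k_m2" %in% names(fixed)) &&
    v[["k_m2"]] < 1e-4 * v[["kf"]]

  structure(list(params = params, brightness = br, trace_scales = scales,
                 K = v[["k1"]] / v[["k_m1"]],
                 K_se = NA_real_,
                 rate_se = se[intersect(free_names, rate_names(scheme))],
                 brightness_se = se[intersect(free_names, bright_names)],
                 chi2_reduced = best$ssr / dof, ssr = best$ssr,
                 covariance = best$cov, free_names = free_names,
                 k_m2_upper_bound = k_m2_ub, k1_lower_bound = FALSE,
                 converged = best$converged, seed = seed),
            class = "kinetic_fit")
}

#' Serialize a kinetic fit to JSON
#'
#' @param fit A `kinetic_fit`.
#' @param path Output path.
#' @export
write_kinetic_fit_json <- function(fit, path) {
  p <- fit$params
  out <- list(scheme = p$scheme,
              rates = list(k1 = p$k1, k_m1 = p$k_m1, k2 = p$k2, k_m2 = p$k_m2,
                           kf = p$kf),
              rate_se = as.list(fit$rate_se),
              K = fit$K, K_se = fit$K_se,
              chi2_reduced = fit$chi2_reduced,
              k1_lower_bound = fit$k1_lower_bound, seed = fit$seed)
  if (!is.null(fit$brightness))
    out$brightness <- list(I_SL = fit$brightness$I_SL,
                           I_IC1 = fit$brightness$I_IC1,
                           I_IC2 = fit$brightness$I_IC2)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
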