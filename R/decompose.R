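# Global decomposition of mixture decay curves into species fractions.
#
# For fixed signatures and intermediate lifetime tau_IC the mixture model is
#   counts ~ s * [(1-a-b) F_SL + b F_IC + a F_ED] + C
# per curve. Single-window curves are linear in the nonnegative species
# contributions, solved by weighted NNLS (fractions are ratios of nonnegative
# coefficients, so a, b >= 0 and a + b <= 1 hold by construction). Stitched
# curves carry one segment per source window whose IRF widths differ, so each
# segment gets its own free scale and dark-count offset while the fractions
# are shared across segments — the exact analogue of fitting the windowed
# acquisitions jointly. The only global nonlinear parameter, the shared
# tau_IC, is profiled on a deterministic log grid refined by golden-section
# search, so no multi-start is needed.

mixture_not_reference <- function(curves) {
  keep <- !vapply(curves, is_reference, logical(1))
  curves[keep]
}

# block design: per segment a scaled-shape column and an offset column
segment_design <- function(shape, segment) {
  segs <- unique(segment)
  do.call(cbind, lapply(segs, function(s) {
    ind <- as.numeric(segment == s)
    cbind(shape * ind, ind)
  }))
}

softmax_frac <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}

# fit one curve's fractions for a fixed species basis B (n x m)
decompose_curve <- function(cv, B, w) {
  m <- ncol(B)
  segs <- unique(cv$segment)
  if (length(segs) == 1L) {
    nn <- wnnls(cbind(B, 1), cv$counts, w)
    cs <- nn$coef[seq_len(m)]
    tot <- sum(cs)
    n_free <- m + 1
    s2 <- sum(nn$resid^2) / max(length(cv$counts) - n_free, 1)
    cov_c <- if (!is.null(nn$cov_unscaled) && all(seq_len(m) %in% nn$active))
      nn$cov_unscaled[match(seq_len(m), sort(nn$active)),
                      match(seq_len(m), sort(nn$active)), drop = FALSE] * s2
    else NULL
    cov_fr <- NULL
    if (!is.null(cov_c)) {
      Jf <- diag(1 / tot, m) - matrix(cs / tot^2, m, m, byrow = FALSE)
      cov_fr <- Jf %*% cov_c %*% t(Jf)
    }
    list(fractions = cs / tot, cov = cov_fr, scale = tot,
         offset = nn$coef[m + 1], resid = nn$resid,
         n = length(cv$counts), n_free = n_free)
  } else {
    resid_z <- function(z) {
      shape <- drop(B %*% softmax_frac(z))
      wnnls(segment_design(shape, cv$segment), cv$counts, w)$resid
    }
    fit <- lm_fit(resid_z, numeric(m - 1))
    fr <- softmax_frac(fit$par)
    shape <- drop(B %*% fr)
    nn <- wnnls(segment_design(shape, cv$segment), cv$counts, w)
    n_free <- (m - 1) + 2 * length(segs)
    # delta method through the softmax: d fr_i / d z_j = fr_i (1[i==j] - fr_j)
    Js <- matrix(0, m, m - 1)
    for (i in seq_len(m)) for (j in seq_len(m - 1))
      Js[i, j] <- fr[i] * ((i == j) - fr[j])
    cov_fr <- if (all(is.finite(fit$cov))) Js %*% fit$cov %*% t(Js) else NULL
    list(fractions = fr, cov = cov_fr, scale = nn$coef[1],
         offset = nn$coef[2], resid = nn$resid,
         n = length(cv$counts), n_free = n_free)
  }
}

species_basis_fixed <- function(cv, sig, species) {
  signature_basis(sig, cv, setdiff(species, "IC"))
}

decompose_all <- function(curves, sig, tau_ic, species, variance_floor = 1,
                          Bfix = NULL, w = NULL) {
  if (is.null(Bfix)) Bfix <- lapply(curves, species_basis_fixed, sig, species)
  if (is.null(w)) w <- lapply(curves, decay_weights, variance_floor)
  per_curve <- lapply(seq_along(curves), function(i) {
    B <- Bfix[[i]]
    if ("IC" %in% species) {
      ic_col <- signature_basis(sig, curves[[i]], "IC", tau_ic = tau_ic)
      B <- cbind(B[, 1, drop = FALSE], ic_col, B[, -1, drop = FALSE])
    }
    decompose_curve(curves[[i]], B, w[[i]])
  })
  ssr <- sum(vapply(per_curve, function(z) sum(z$resid^2), numeric(1)))
  list(per_curve = per_curve, ssr = ssr)
}

frac_row <- function(cv, z, species) {
  fr <- stats::setNames(z$fractions, species)
  se <- stats::setNames(if (!is.null(z$cov)) sqrt(pmax(diag(z$cov), 0))
                        else rep(NA_real_, length(species)), species)
  gv <- function(x, sp) if (sp %in% species) unname(x[sp]) else 0
  data.frame(id = if (is.null(cv$id)) NA_character_ else cv$id,
             T_s = cv$propagation_time,
             frac_SL = gv(fr, "SL"), frac_IC = gv(fr, "IC"),
             frac_ED = gv(fr, "ED"),
             se_SL = gv(se, "SL"), se_IC = gv(se, "IC"), se_ED = gv(se, "ED"),
             scale = z$scale, offset = z$offset,
             chi2_reduced = sum(z$resid^2) / (z$n - z$n_free))
}

#' One-step (two-species) decomposition
#'
#' Fits each mixture curve to the reaction-progress model
#' \eqn{F_1(t, T) = (1-\alpha) F_{SL}(t) + \alpha F_{ED}(t)} (plus free scale
#' and dark-count offset), the description appropriate if free hairpin
#' converted directly into duplex. Systematic early-time residuals of this
#' fit are what reveal the short-lived intermediate complex.
#'
#' @param curves List of mixture [decay_curve()]s carrying propagation times
#'   (reference-tagged curves are dropped).
#' @param signatures A fitted [species_signatures()].
#' @param variance_floor Poisson variance floor (default 1).
#' @return A data frame with one row per curve: `T_s`, `alpha` (duplex
#'   fraction), `alpha_se`, `scale`, `offset`, `chi2_reduced`; attribute
#'   `chi2_reduced_global`.
#' @export
decompose_one_step <- function(curves, signatures, variance_floor = 1) {
  curves <- mixture_not_reference(curves)
  stopifnot(length(curves) >= 1)
  species <- c("SL", "ED")
  res <- decompose_all(curves, signatures, NA, species, variance_floor)
  rows <- lapply(seq_along(curves), function(i) {
    r <- frac_row(curves[[i]], res$per_curve[[i]], species)
    data.frame(T_s = r$T_s, alpha = r$frac_ED, alpha_se = r$se_ED,
               scale = r$scale, offset = r$offset,
               chi2_reduced = r$chi2_reduced)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_tot <- sum(vapply(res$per_curve, function(z) z$n, numeric(1)))
  n_free <- sum(vapply(res$per_curve, function(z) z$n_free, numeric(1)))
  attr(out, "chi2_reduced_global") <- res$ssr / (n_tot - n_free)
  out
}

#' Global three-species decomposition with a shared intermediate lifetime
#'
#' Simultaneously fits all mixture curves (possibly from several mixing
#' experiments) to
#' \eqn{F_2(t,T) = (1-\alpha-\beta) F_{SL}(t) + \beta e^{-t/\tau_{IC}} +
#' \alpha F_{ED}(t)}, with per-curve fractions \eqn{\alpha(T), \beta(T)},
#' free scale and dark-count offset per stitched segment, and one
#' intermediate lifetime \eqn{\tau_{IC}} shared by every curve of every
#' experiment. The signatures are frozen; only \eqn{\tau_{IC}} is a global
#' nonlinear parameter.
#'
#' @param curves List of mixture [decay_curve()]s (or a list of lists, one
#'   per experiment; flattened, tracked by curve `id`).
#' @param signatures A fitted [species_signatures()]; not refitted.
#' @param tau_ic_range Search interval for the intermediate lifetime (ns),
#'   default `c(0.005, 1)`.
#' @param tau_ic Optional fixed intermediate lifetime: skip the profile and
#'   decompose at this value.
#' @param n_grid Profile grid size (default 25, log-spaced).
#' @param variance_floor Poisson variance floor (default 1).
#' @param beta_zero If `TRUE`, constrain the intermediate fraction to zero
#'   (the fit then coincides with [decompose_one_step()]).
#' @return An object of class `decomposition` with `table` (per-curve rows:
#'   `id`, `T_s`, `frac_SL`, `frac_IC`, `frac_ED`, standard errors, `scale`,
#'   `offset`), `tau_ic`, `tau_ic_se`, `chi2_reduced`, `at_boundary`, and
#'   `signatures` completed with the fitted `tau_ic`.
#' @export
decompose_two_step_global <- function(curves, signatures,
                                      tau_ic_range = c(0.005, 1),
                                      tau_ic = NULL, n_grid = 25,
                                      variance_floor = 1, beta_zero = FALSE) {
  if (length(curves) && is.list(curves[[1]]) && !inherits(curves[[1]], "decay_curve"))
    curves <- unlist(curves, recursive = FALSE)
  curves <- mixture_not_reference(curves)
  stopifnot(length(curves) >= 1)
  species <- if (beta_zero) c("SL", "ED") else c("SL", "IC", "ED")
  if (beta_zero && is.null(tau_ic)) tau_ic <- NA_real_

  Bfix <- lapply(curves, species_basis_fixed, signatures, species)
  w <- lapply(curves, decay_weights, variance_floor)
  obj <- function(tau) decompose_all(curves, signatures, tau, species,
                                     variance_floor, Bfix, w)$ssr
  at_boundary <- FALSE
  tau_se <- NA_real_
  if (is.null(tau_ic)) {
    grid <- exp(seq(log(tau_ic_range[1]), log(tau_ic_range[2]),
                    length.out = n_grid))
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(k - 1, 1)]; hi <- grid[min(k + 1, n_grid)]
    opt <- stats::optimize(function(lt) obj(exp(lt)), c(log(lo), log(hi)),
                           tol = 1e-7)
    tau_ic <- exp(opt$minimum)
    at_boundary <- (k == 1 || k == n_grid) &&
      min(tau_ic / tau_ic_range[1], tau_ic_range[2] / tau_ic) < 1.05
    if (at_boundary)
      warning("tau_IC is at the search boundary; value unreliable", call. = FALSE)
    h <- 0.05 * tau_ic   # chi2-profile curvature -> standard error
    d2 <- (obj(tau_ic + h) - 2 * opt$objective + obj(tau_ic - h)) / h^2
    if (is.finite(d2) && d2 > 0) tau_se <- sqrt(2 / d2)
  }

  fin <- decompose_all(curves, signatures, tau_ic, species, variance_floor,
                       Bfix, w)
  rows <- lapply(seq_along(curves), function(i)
    frac_row(curves[[i]], fin$per_curve[[i]], species))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  n_tot <- sum(vapply(fin$per_curve, function(z) z$n, numeric(1)))
  n_free <- sum(vapply(fin$per_curve, function(z) z$n_free, numeric(1))) +
    if (beta_zero) 0 else 1
  chi2_red <- fin$ssr / (n_tot - n_free)
  if (is.finite(tau_se)) tau_se <- tau_se * sqrt(max(chi2_red, 1))
  sig_out <- signatures
  sig_out$tau_ic <- tau_ic
  structure(list(table = tab, tau_ic = tau_ic, tau_ic_se = tau_se,
                 chi2_reduced = chi2_red, at_boundary = at_boundary,
                 signatures = sig_out),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "Three-species decomposition: %d curves, tau_IC = %.4g ns%s, reduced chi2 = %.4f\n",
    nrow(x$table), x$tau_ic,
    if (is.finite(x$tau_ic_se)) sprintf(" (+/- %.2g)", x$tau_ic_se) else "",
    x$chi2_reduced))
  print(utils::head(x$table[, c("T_s", "frac_SL", "frac_IC", "frac_ED")], 12))
  invisible(x)
}

#' Convert fitted fractions to species concentrations
#'
#' Rescales the decomposition fractions by the total labelled-strand
#' concentration of the experiment: `[SL] = (1-a-b) c_tot`, `[IC] = b c_tot`,
#' `[ED] = a c_tot` at each propagation time; standard errors propagate
#' linearly.
#'
#' @param result A `decomposition` (or its `table`).
#' @param total_labeled Total labelled-strand concentration (uM).
#' @return A data frame: `T_s`, `conc_SL`, `conc_IC`, `conc_ED` (uM) and
#'   standard errors.
#' @export
to_concentrations <- function(result, total_labeled) {
  if (!is.numeric(total_labeled) || total_labeled < 0)
    stop("invalid parameter: total_labeled must be >= 0", call. = FALSE)
  tab <- if (inherits(result, "decomposition")) result$table else result
  data.frame(T_s = tab$T_s,
             conc_SL = tab$frac_SL * total_labeled,
             conc_IC = tab$frac_IC * total_labeled,
             conc_ED = tab$frac_ED * total_labeled,
             se_SL = tab$se_SL * total_labeled,
             se_IC = tab$se_IC * total_labeled,
             se_ED = tab$se_ED * total_labeled)
}

#' Write a decomposition to CSV / JSON
#'
#' @param result A `decomposition`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @param total_labeled Optional total labelled concentration (uM) to add
#'   concentration columns.
#' @export
write_decomposition <- function(result, csv_path = NULL, json_path = NULL,
                                total_labeled = NULL) {
  tab <- result$table
  if (!is.null(total_labeled)) {
    conc <- to_concentrations(result, total_labeled)
    tab <- cbind(tab, conc[, -1])
  }
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(tau_ic_ns = result$tau_ic,
                              tau_ic_se_ns = result$tau_ic_se,
                              chi2_reduced = result$chi2_reduced,
                              at_boundary = result$at_boundary),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
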