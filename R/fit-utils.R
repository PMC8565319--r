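# Internal fitting machinery shared by all modules: a compact
# Levenberg-Marquardt least-squares routine (numerical Jacobian), a weighted
# nonnegative linear least-squares solver used to profile out the amplitudes
# that enter every decay model linearly, and seeded multi-start helpers.

# Evaluate with a temporary RNG state so generators are reproducible and do
# not disturb the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Forward-difference Jacobian of a residual vector.
num_jacobian <- function(fn, par, r0 = fn(par), eps = 1e-6) {
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

# Levenberg-Marquardt minimization of sum(resid_fn(par)^2).
# resid_fn must return a finite numeric vector (weights pre-applied).
# Returns par, ssr, covariance (sigma^2 (J'J)^-1), convergence info.
lm_fit <- function(resid_fn, par, maxit = 200, ftol = 1e-10, ptol = 1e-10,
                   lambda0 = 1e-3) {
  safe_resid <- function(p) {
    r <- tryCatch(resid_fn(p), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(NULL)
    r
  }
  r <- safe_resid(par)
  if (is.null(r)) stop("fit failure: residuals not finite at the start", call. = FALSE)
  ssr <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    J <- num_jacobian(safe_resid, par, r0 = r)
    if (any(!is.finite(J))) break
    g <- crossprod(J, r)           # gradient/2
    A <- crossprod(J)
    dscale <- pmax(sqrt(diag(A)), 1e-12)
    improved <- FALSE
    for (k in 1:30) {
      M <- A + lambda * diag(dscale^2, length(par))
      step <- tryCatch(solve(M, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- par - drop(step)
        rc <- safe_resid(cand)
        if (!is.null(rc) && sum(rc^2) < ssr) {
          rel <- (ssr - sum(rc^2)) / max(ssr, 1e-300)
          prel <- max(abs(cand - par) / pmax(abs(par), 1e-8))
          par <- cand; r <- rc; ssr <- sum(rc^2)
          lambda <- max(lambda / 4, 1e-12)
          improved <- TRUE
          if (rel < ftol || prel < ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved || converged) { converged <- converged || !improved; break }
  }
  J <- num_jacobian(safe_resid, par, r0 = r)
  dof <- max(length(r) - length(par), 1)
  A <- crossprod(J)
  cov <- tryCatch(solve(A) * ssr / dof, error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  list(par = par, ssr = ssr, cov = cov, n_resid = length(r),
       converged = converged, iterations = it)
}

# Weighted nonnegative least squares: min ||W^(1/2)(y - X b)|| with b >= 0 on
# the coordinates listed in `nonneg` (default all). Lawson-Hanson active set.
wnnls <- function(X, y, w = rep(1, length(y)), nonneg = seq_len(ncol(X))) {
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  p <- ncol(X)
  inset <- logical(p)
  inset[setdiff(seq_len(p), nonneg)] <- TRUE   # unconstrained: always active
  b <- numeric(p)
  solve_sub <- function(idx) {
    bt <- qr.coef(qr(Xw[, idx, drop = FALSE]), yw)
    bt[is.na(bt)] <- 0
    bt
  }
  restore <- function(idx) {
    repeat {
      bt <- solve_sub(idx)
      neg <- idx %in% nonneg & bt < -1e-14
      if (!any(neg)) { b <<- numeric(p); b[idx] <<- pmax(bt, 0); return(idx) }
      ratio <- b[idx][neg] / (b[idx][neg] - bt[neg])
      alpha <- min(ratio)
      b[idx] <<- b[idx] + alpha * (bt - b[idx])
      drop_i <- idx[neg][which.min(ratio)]
      b[drop_i] <<- 0
      idx <- setdiff(idx, drop_i)
      if (!length(idx)) return(idx)
    }
  }
  if (any(inset)) inset[seq_len(p)] <- seq_len(p) %in% restore(which(inset))
  for (outer in 1:(10 * p + 10)) {
    grad <- drop(crossprod(Xw, yw - Xw %*% b))
    cand <- which(!inset & grad > 1e-10 * max(abs(grad), 1))
    if (!length(cand)) break
    inset[cand[which.max(grad[cand])]] <- TRUE
    inset[seq_len(p)] <- seq_len(p) %in% restore(which(inset))
  }
  cov_unscaled <- tryCatch(solve(crossprod(Xw[, inset, drop = FALSE])),
                           error = function(e) NULL)
  list(coef = b, resid = drop(yw - Xw %*% b), active = which(inset),
       cov_unscaled = cov_unscaled)
}

# Deterministic per-start jitter for multi-start optimization: start 1 is the
# unperturbed initialization, later starts perturb log-scale parameters.
multistart_inits <- function(par, n_starts, seed, spread = 0.5) {
  if (n_starts <= 1) return(list(par))
  jit <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
    par + stats::rnorm(length(par), 0, spread)))
  c(list(par), jit)
}
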