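#' Mass-action parameters of the annealing schemes
#'
#' The two-step scheme is
#' \deqn{SL + P \rightleftharpoons IC \rightarrow ED}
#' with association rate \eqn{k_1} (M\eqn{^{-1}}s\eqn{^{-1}}), dissociation
#' rate \eqn{k_{-1}} (s\eqn{^{-1}}) and duplex-formation rate \eqn{k_f}
#' (s\eqn{^{-1}}). The three-step scheme inserts a second intermediate:
#' \deqn{SL + P \rightleftharpoons IC_1 \rightleftharpoons IC_2 \rightarrow ED}
#' with forward/backward interconversion rates \eqn{k_2, k_{-2}}
#' (s\eqn{^{-1}}). The chaperone peptide is not an explicit species; its
#' effect is absorbed into the rate constants.
#'
#' @param k1 Association rate constant (M^-1 s^-1).
#' @param k_m1 IC(1) dissociation rate (s^-1).
#' @param kf Duplex formation rate (s^-1), acting on the last intermediate.
#' @param k2,k_m2 IC1 <-> IC2 interconversion rates (s^-1); three-step only.
#' @param scheme `"two_step"` or `"three_step"`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1, k_m1, kf, k2 = NA_real_, k_m2 = NA_real_,
                           scheme = c("two_step", "three_step")) {
  scheme <- match.arg(scheme)
  rates <- c(k1 = k1, k_m1 = k_m1, kf = kf)
  if (scheme == "three_step") {
    if (is.na(k2)) stop("three_step requires k2", call. = FALSE)
    if (is.na(k_m2)) k_m2 <- 0
    rates <- c(rates, k2 = k2, k_m2 = k_m2)
  }
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("invalid parameter: rates must be finite and >= 0", call. = FALSE)
  structure(list(k1 = k1, k_m1 = k_m1, kf = kf,
                 k2 = if (scheme == "three_step") k2 else NA_real_,
                 k_m2 = if (scheme == "three_step") k_m2 else NA_real_,
                 scheme = scheme), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters (%s)\n", x$scheme))
  cat(sprintf("  k1 = %.4g M^-1 s^-1, k-1 = %.4g s^-1", x$k1, x$k_m1))
  if (x$scheme == "three_step")
    cat(sprintf(", k2 = %.4g s^-1, k-2 = %.4g s^-1", x$k2, x$k_m2))
  cat(sprintf(", kf = %.4g s^-1\n", x$kf))
  invisible(x)
}

#' Initial conditions of a mixing experiment
#'
#' At the mixing event (T = 0) all labelled strand is free stem-loop and no
#' intermediate or duplex exists; the mixing dead time (a few ms) is
#' neglected.
#'
#' @param SL0 Total labelled-strand concentration (uM).
#' @param P0 Total complementary-strand concentration (uM).
#' @return An object of class `initial_conditions`.
#' @export
initial_conditions <- function(SL0, P0) {
  if (!is.finite(SL0) || !is.finite(P0) || SL0 <= 0 || P0 <= 0)
    stop("invalid parameter: SL0 and P0 must be > 0", call. = FALSE)
  structure(list(SL0 = SL0, P0 = P0), class = "initial_conditions")
}

# per-uM rate: k1 is accepted in M^-1 s^-1, concentrations are uM internally
K1_UM <- 1e-6

scheme_deriv <- function(params) {
  k1u <- params$k1 * K1_UM
  if (params$scheme == "two_step") {
    function(t, y) {
      # y = (SL, IC1, ED, P)
      v_on <- k1u * y[1] * y[4]
      v_off <- params$k_m1 * y[2]
      v_f <- params$kf * y[2]
      c(-v_on + v_off, v_on - v_off - v_f, v_f, -v_on + v_off)
    }
  } else {
    function(t, y) {
      # y = (SL, IC1, IC2, ED, P)
      v_on <- k1u * y[1] * y[5]
      v_off <- params$k_m1 * y[2]
      v_12 <- params$k2 * y[2]
      v_21 <- params$k_m2 * y[3]
      v_f <- params$kf * y[3]
      c(-v_on + v_off,
        v_on - v_off - v_12 + v_21,
        v_12 - v_21 - v_f,
        v_f,
        -v_on + v_off)
    }
  }
}

#' Simulate an annealing scheme
#'
#' Integrates the mass-action rate equations of the selected scheme from
#' pre-steady-state initial conditions (all labelled strand free at T = 0)
#' with an adaptive RK45 solver.
#'
#' @param params A [kinetic_params()].
#' @param init An [initial_conditions()].
#' @param times Output times (s), all >= 0.
#' @param rtol,atol Solver tolerances (defaults 1e-8 and 1e-12 uM).
#' @param engine `"cpp"` (compiled stepper, default) or `"r"` (reference R
#'   implementation of the same method); both are adaptive Dormand-Prince
#'   RK45 and agree to solver tolerance.
#' @return A `concentration_trajectory`: data frame with columns `time_s`,
#'   `SL`, `IC1`, (`IC2` for three-step), `ED`, `P` in uM; attributes `params`
#'   and `init`.
#' @export
simulate_scheme <- function(params, init, times, rtol = 1e-8, atol = 1e-12,
                            engine = c("cpp", "r")) {
  stopifnot(inherits(params, "kinetic_params"), inherits(init, "initial_conditions"))
  engine <- match.arg(engine)
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  ord <- order(times)
  tt <- times[ord]
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  y0 <- if (params$scheme == "two_step") c(init$SL0, 0, 0, init$P0)
        else c(init$SL0, 0, 0, 0, init$P0)
  sol <- if (engine == "cpp") {
    rates <- c(params$k1 * K1_UM, params$k_m1,
               if (is.na(params$k2)) 0 else params$k2,
               if (is.na(params$k_m2)) 0 else params$k_m2, params$kf)
    rk45_scheme_cpp(rates, if (params$scheme == "two_step") 2L else 3L,
                    y0, tt, rtol, atol)
  } else {
    ode_rk45(scheme_deriv(params), y0, tt, rtol = rtol, atol = atol)
  }
  if (prepend) sol <- sol[-1, , drop = FALSE]
  sol <- sol[order(ord), , drop = FALSE]
  cols <- if (params$scheme == "two_step") c("SL", "IC1", "ED", "P")
          else c("SL", "IC1", "IC2", "ED", "P")
  out <- data.frame(time_s = times, sol)
  names(out) <- c("time_s", cols)
  structure(out, params = params, init = init,
            class = c("concentration_trajectory", "data.frame"))
}

#' Derived equilibrium and effective rate constants
#'
#' \eqn{K = k_1 / k_{-1}} is the intermediate-complex equilibrium constant.
#' For the three-step scheme the effective second-order annealing rate under
#' a fast IC1 pre-equilibrium is \eqn{k_{eff} = k_1 k_2 / k_{-1}}, comparable
#' to the apparent \eqn{k_1} of a two-step description.
#'
#' @param params A [kinetic_params()].
#' @return List with `K` (M^-1) and, for the three-step scheme, `k_eff`
#'   (M^-1 s^-1).
#' @export
derived_constants <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k_m1 <= 0)
    stop("undefined constant: k_m1 must be > 0", call. = FALSE)
  out <- list(K = params$k1 / params$k_m1)
  if (!is.na(params$k2)) out$k_eff <- params$k1 * params$k2 / params$k_m1
  out
}

#' Relative species brightnesses
#'
#' Observable map of the stopped-flow intensity experiment: the measured
#' signal is a brightness-weighted sum of species concentrations. The
#' extended duplex defines the brightness unit (`I_ED = 1`). For the two-step
#' scheme `I_IC1` is the (single) intermediate brightness; the three-step
#' scheme distinguishes the nearly dark kissing complex IC1 from the bright,
#' nearly duplex-like IC2.
#'
#' @param I_SL Stem-loop relative brightness.
#' @param I_IC1 First-intermediate relative brightness.
#' @param I_IC2 Second-intermediate relative brightness (three-step).
#' @param I_ED Duplex brightness, fixed at 1 by convention.
#' @param scale Per-trace multiplicative factor (arbitrary units).
#' @return An object of class `brightness_vector`.
#' @export
brightness_vector <- function(I_SL, I_IC1, I_IC2 = NA_real_, I_ED = 1,
                              scale = 1) {
  v <- c(I_SL, I_IC1, I_IC2, I_ED, scale)
  if (any(!is.na(v) & v < 0)) stop("brightnesses must be >= 0", call. = FALSE)
  structure(list(I_SL = I_SL, I_IC1 = I_IC1, I_IC2 = I_IC2, I_ED = I_ED,
                 scale = scale), class = "brightness_vector")
}

#' Stopped-flow intensity trace
#'
#' @param times Times since mixing (s), increasing.
#' @param intensity Measured intensity (arbitrary units).
#' @param design An [initial_conditions()] for the trace.
#' @param id Optional identifier.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, intensity, design, id = NULL) {
  if (length(times) != length(intensity))
    stop("shape error: times and intensity differ in length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be increasing", call. = FALSE)
  if (any(!is.finite(intensity))) stop("intensity must be finite", call. = FALSE)
  structure(list(times = times, intensity = intensity, design = design, id = id),
            class = "intensity_trace")
}

#' Predict a stopped-flow intensity trace from a trajectory
#'
#' `intensity(t) = scale * sum_species I_species [species](t)`.
#'
#' @param trajectory A `concentration_trajectory` from [simulate_scheme()].
#' @param brightness A [brightness_vector()].
#' @return An [intensity_trace()].
#' @export
predict_intensity <- function(trajectory, brightness) {
  stopifnot(inherits(trajectory, "concentration_trajectory"),
            inherits(brightness, "brightness_vector"))
  params <- attr(trajectory, "params")
  int <- brightness$I_SL * trajectory$SL +
    brightness$I_IC1 * trajectory$IC1 +
    brightness$I_ED * trajectory$ED
  if (params$scheme == "three_step") {
    if (is.na(brightness$I_IC2))
      stop("three-step trajectory needs I_IC2", call. = FALSE)
    int <- int + brightness$I_IC2 * trajectory$IC2
  }
  intensity_trace(trajectory$time_s, brightness$scale * int,
                  attr(trajectory, "init"))
}
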