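# Synthetic-data generator emulating the droplet-microfluidic TRF instrument
# and the stopped-flow intensity experiment. Every stochastic output takes an
# explicit seed and is bit-reproducible given (design, seed).

#' Table-derived default species signatures
#'
#' The equilibrated reference signatures of the doubly labelled hairpin
#' (triexponential, amplitudes 0.46/0.44/0.10, lifetimes 0.11/0.71/2.66 ns)
#' and of the annealed duplex (monoexponential, 4.19 ns), with the
#' intermediate-complex lifetime 0.045 ns determined by the global
#' decomposition. Used as generating truth by the synthetic module.
#'
#' @return A [species_signatures()].
#' @export
default_signatures <- function() {
  species_signatures(c(0.46, 0.44, 0.10), c(0.11, 0.71, 2.66), 4.19,
                     tau_ic = 0.045, t0 = 0.1)
}

#' Map droplet positions to reaction times
#'
#' In the droplet experiment the reaction time of a decay acquisition is the
#' propagation time of the droplet from the mixing T-junction to the
#' detection spot: `T = position / speed`.
#'
#' @param positions Channel positions downstream of the T-junction (mm).
#' @param speed Droplet propagation speed (mm/s); the instrument operates
#'   between 7 and 80 mm/s.
#' @return Propagation times (s).
#' @export
propagation_times <- function(positions, speed) {
  if (!is.numeric(speed) || length(speed) != 1L || !is.finite(speed) || speed <= 0)
    stop("invalid parameter: speed must be > 0", call. = FALSE)
  if (any(positions < 0)) stop("invalid parameter: positions must be >= 0", call. = FALSE)
  positions / speed
}

#' Experiment design for the synthetic instrument
#'
#' @param SL0,P0 Labelled / complementary strand concentrations (uM).
#' @param windows Acquisition window spans (ns), default `c(1, 5, 20)`.
#' @param n_bins Bins per window. The defaults (1000, 1000, 800 for the
#'   standard windows) put the bin centres of longer windows on a subgrid of
#'   shorter ones so that stitching can compare coincident samples.
#' @param counts_per_curve Photon budget per window acquisition (default 1e6).
#' @param dark_fraction Fraction of the budget contributed by the uniform
#'   dark-count background (default 0.02).
#' @param sigma1 IRF standard deviation in the reference 1 ns window (ns).
#' @param t0 Excitation time origin (ns).
#' @param speed Droplet speed (mm/s); must lie in the instrument range 7-80.
#' @param nc_ratio Chaperone:oligonucleotide molar ratio (metadata only).
#' @param seed Seed for all stochastic output of this design.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(SL0, P0, windows = c(1, 5, 20),
                              n_bins = NULL, counts_per_curve = 1e6,
                              dark_fraction = 0.02, sigma1 = 0.010, t0 = 0.1,
                              speed = 20, nc_ratio = 1, seed = 1) {
  if (speed < 7 || speed > 80)
    stop("invalid parameter: droplet speed outside the 7-80 mm/s range", call. = FALSE)
  windows <- sort(windows)
  if (is.null(n_bins)) {
    n_bins <- if (identical(windows, c(1, 5, 20))) c(1000, 1000, 800)
              else rep(1000, length(windows))
  }
  stopifnot(length(n_bins) == length(windows), counts_per_curve > 0,
            dark_fraction >= 0, dark_fraction < 1)
  structure(list(SL0 = SL0, P0 = P0, windows = windows, n_bins = n_bins,
                 counts_per_curve = counts_per_curve,
                 dark_fraction = dark_fraction, sigma1 = sigma1, t0 = t0,
                 speed = speed, nc_ratio = nc_ratio, seed = seed),
            class = "experiment_design")
}

window_grid <- function(window, n_bins) (seq_len(n_bins) - 0.5) * window / n_bins

# one window acquisition of a fraction mixture; lambda scaled to the photon
# budget, uniform dark counts added, then Poisson sampled (noise = "poisson")
synthesize_window <- function(fractions, sig, design, wi, propagation_time,
                              noise = "poisson", seed = 0, id = NULL) {
  sig$t0 <- design$t0
  w <- design$windows[wi]
  times <- window_grid(w, design$n_bins[wi])
  sigma <- window_sigma(w, design$sigma1)
  shape <- drop(signature_basis(sig, list(times = times, sigma = sigma),
                                c("SL", "IC", "ED")) %*% fractions)
  lam <- shape / sum(shape) * design$counts_per_curve * (1 - design$dark_fraction) +
    design$counts_per_curve * design$dark_fraction / length(times)
  counts <- if (noise == "poisson") with_seed(seed, stats::rpois(length(lam), lam))
            else lam
  decay_curve(times, counts, window = w, propagation_time = propagation_time,
              sigma = sigma, id = id)
}

#' Generate mixture decay curves for given species fractions
#'
#' Forward model of the droplet TRF observable: for each propagation time and
#' each acquisition window, the three-species mixture decay (stem-loop /
#' intermediate / duplex signatures convolved with the window-scaled Gaussian
#' IRF) is scaled to the photon budget, a uniform dark-count background is
#' added, and the curve is Poisson-sampled.
#'
#' @param fractions Data frame with columns `T_s`, `f_SL`, `f_IC`, `f_ED`
#'   (each row on the simplex). Reference rows can be encoded with
#'   `T_s = "SL_ref"` / `"ED_ref"`.
#' @param signatures A [species_signatures()] with `tau_ic` set.
#' @param design An [experiment_design()].
#' @param noise `"poisson"` (default) or `"none"`.
#' @param stitch Also return the stitched trace per propagation time
#'   (default `TRUE`).
#' @return A list with `curves` (list of lists, one per row of `fractions`,
#'   one [decay_curve()] per window) and, if `stitch`, `stitched`.
#' @export
generate_decay_curves <- function(fractions, signatures, design,
                                  noise = "poisson", stitch = TRUE) {
  stopifnot(inherits(signatures, "species_signatures"),
            inherits(design, "experiment_design"))
  if (is.na(signatures$tau_ic)) stop("signatures must carry tau_ic", call. = FALSE)
  fmat <- as.matrix(fractions[, c("f_SL", "f_IC", "f_ED")])
  if (any(fmat < -1e-9) || any(abs(rowSums(fmat) - 1) > 1e-6))
    stop("invalid parameter: fractions must lie on the simplex", call. = FALSE)
  fmat <- pmax(fmat, 0)
  curves <- lapply(seq_len(nrow(fmat)), function(r) {
    pt <- fractions$T_s[r]
    if (is.factor(pt)) pt <- as.character(pt)
    ptn <- suppressWarnings(as.numeric(pt))
    if (!is.na(ptn)) pt <- ptn
    lapply(seq_along(design$windows), function(wi)
      synthesize_window(fmat[r, ], signatures, design, wi, pt,
                        noise = noise,
                        seed = design$seed + 1000L * r + wi,
                        id = sprintf("sim_%g_%g", design$SL0, design$P0)))
  })
  out <- list(curves = curves)
  if (stitch) out$stitched <- lapply(curves, stitch_windows)
  out
}

scheme_fractions <- function(trajectory, SL0) {
  three <- "IC2" %in% names(trajectory)
  data.frame(T_s = trajectory$time_s,
             f_SL = trajectory$SL / SL0,
             f_IC = trajectory$IC1 / SL0,
             # the bright second intermediate shares the duplex lifetime, so
             # in the decay domain it counts as duplex
             f_ED = (trajectory$ED + if (three) trajectory$IC2 else 0) / SL0)
}

#' Generate a complete droplet TRF mixing experiment
#'
#' Composes [simulate_scheme()], [propagation_times()] and
#' [generate_decay_curves()]: species concentrations at each sampled
#' propagation time are mapped to decay-domain fractions (for the three-step
#' scheme, IC2 emits with the duplex lifetime and is counted as duplex) and
#' turned into windowed, Poisson-sampled decay curves, together with pre-mix
#' stem-loop and equilibrated-duplex reference acquisitions.
#'
#' @param design An [experiment_design()].
#' @param params A [kinetic_params()].
#' @param signatures A [species_signatures()] with `tau_ic`; default
#'   [default_signatures()].
#' @param times Propagation times (s); default 10 log-spaced in 0.1-10 s (the
#'   span reachable at the instrument's droplet speeds and channel lengths).
#' @param n_ref Reference acquisitions per species (default 2).
#' @param noise `"poisson"` or `"none"`.
#' @return List with `stitched` mixture curves, per-window `curves`,
#'   `reference` (list with `sl`, `ed` per-window curve lists), and `truth`
#'   (generating trajectory and fractions).
#' @export
generate_trf_experiment <- function(design, params,
                                    signatures = default_signatures(),
                                    times = 10^seq(-1, 1, length.out = 10),
                                    n_ref = 2, noise = "poisson") {
  traj <- simulate_scheme(params, initial_conditions(design$SL0, design$P0), times)
  frac <- scheme_fractions(traj, design$SL0)
  mix <- generate_decay_curves(frac, signatures, design, noise = noise)

  ref_design <- design
  ref_design$seed <- design$seed + 500000L
  ref_rows <- data.frame(
    T_s = rep(c("SL_ref", "ED_ref"), each = n_ref),
    f_SL = rep(c(1, 0), each = n_ref),
    f_IC = 0,
    f_ED = rep(c(0, 1), each = n_ref), stringsAsFactors = FALSE)
  refs <- generate_decay_curves(ref_rows, signatures, ref_design,
                                noise = noise, stitch = TRUE)
  list(stitched = mix$stitched, curves = mix$curves,
       reference = list(sl = refs$stitched[seq_len(n_ref)],
                        ed = refs$stitched[n_ref + seq_len(n_ref)],
                        windows = refs$curves),
       truth = list(trajectory = traj, fractions = frac, params = params,
                    signatures = signatures))
}

#' Generate noisy species-concentration trajectories
#'
#' Emulates the output of the decomposition stage directly: simulates the
#' scheme at each design and adds relative Gaussian noise to the SL, IC and
#' ED concentrations (IC2, when present, is folded into ED as in the decay
#' domain).
#'
#' @param designs List of [initial_conditions()] (or [experiment_design()]s).
#' @param params A [kinetic_params()].
#' @param times Sampled propagation times (s).
#' @param noise Relative Gaussian noise level (default 0.07).
#' @param seed Seed.
#' @return List of experiments in the format of
#'   [fit_concentration_trajectories()], with a `truth` attribute.
#' @export
generate_trajectory_data <- function(designs, params,
                                     times = 10^seq(-1, 1, length.out = 10),
                                     noise = 0.07, seed = 1) {
  if (noise < 0) stop("invalid parameter: negative noise", call. = FALSE)
  out <- lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    init <- if (inherits(d, "initial_conditions")) d
            else initial_conditions(d$SL0, d$P0)
    traj <- simulate_scheme(params, init, times)
    frac <- scheme_fractions(traj, init$SL0)
    conc <- cbind(frac$f_SL, frac$f_IC, frac$f_ED) * init$SL0
    eps <- with_seed(seed + 37L * i,
                     matrix(stats::rnorm(length(conc), 0, noise), nrow(conc)))
    obs <- conc * (1 + eps)
    list(init = init,
         data = data.frame(T_s = times, conc_SL = obs[, 1], conc_IC = obs[, 2],
                           conc_ED = obs[, 3]))
  })
  attr(out, "truth") <- params
  out
}

#' Generate stopped-flow intensity traces
#'
#' Simulates the selected scheme at each design, maps concentrations to
#' intensity with the species brightnesses, and multiplies each point by
#' `(1 + eps)`, `eps ~ N(0, noise)`.
#'
#' @param designs List of [initial_conditions()].
#' @param params A [kinetic_params()].
#' @param brightness A [brightness_vector()].
#' @param times Trace time grid (s); default 1000 log-spaced points between
#'   0.05 s (a typical stopped-flow dead time) and 500 s, emulating the point
#'   count of a stopped-flow digitizer.
#' @param noise Relative Gaussian noise sd (default 0.01).
#' @param seed Seed.
#' @return List of [intensity_trace()]s with a `truth` attribute.
#' @export
generate_trfi_traces <- function(designs, params, brightness,
                                 times = 10^seq(log10(0.05), log10(500),
                                                length.out = 1000),
                                 noise = 0.01, seed = 1) {
  if (noise < 0) stop("invalid parameter: negative noise", call. = FALSE)
  traces <- lapply(seq_along(designs), function(i) {
    tr <- predict_intensity(simulate_scheme(params, designs[[i]], times),
                            brightness)
    eps <- with_seed(seed + 101L * i, stats::rnorm(length(times), 0, noise))
    intensity_trace(times, tr$intensity * (1 + eps), designs[[i]],
                    id = sprintf("trace_P0_%g", designs[[i]]$P0))
  })
  attr(traces, "truth") <- list(params = params, brightness = brightness)
  traces
}
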