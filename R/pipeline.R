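# Configuration-driven pipelines tying the stages into the two workflows:
# TRF-DmF (decay curves -> signatures -> decomposition -> concentrations ->
# two-step kinetic fit) and Tr-FI (intensity traces -> global kinetic fit).

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or JSON) with a `mode` (`"trf"` or `"trfi"`), a
#' `seed`, an `output_dir`, and either a `simulate` block (designs, kinetic
#' parameters, noise; the pipeline generates its own inputs) or file inputs
#' (`curves`: decay TSV paths with reference tags; `traces`: trace CSV paths
#' plus designs). Validation reports every missing/invalid field by name.
#'
#' @param path Path to a YAML or JSON configuration file, or a list.
#' @return The validated configuration (class `pipeline_config`) with
#'   defaults filled in and a `config_hash` attribute.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  hash <- if (is.character(path) && file.exists(path))
    unname(tools::md5sum(path))
  else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tmp)
    on.exit(unlink(tmp))
    unname(tools::md5sum(tmp))
  }
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  need(!is.null(cfg$mode) && cfg$mode %in% c("trf", "trfi"),
       "mode: must be 'trf' or 'trfi'")
  if (is.null(cfg$seed)) cfg$seed <- 1
  need(is.numeric(cfg$seed), "seed: must be numeric")
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  if (is.null(cfg$scheme)) cfg$scheme <- "two_step"
  need(all(cfg$scheme %in% c("two_step", "three_step")),
       "scheme: must be 'two_step' and/or 'three_step'")

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    need(!is.null(sim$designs) && length(sim$designs) >= 1,
         "simulate.designs: at least one design with SL0 and P0 required")
    for (i in seq_along(sim$designs)) {
      d <- sim$designs[[i]]
      need(!is.null(d$SL0) && !is.null(d$P0),
           sprintf("simulate.designs[%d]: needs SL0 and P0 (uM)", i))
    }
    need(!is.null(sim$params$k1) && !is.null(sim$params$k_m1) &&
           !is.null(sim$params$kf),
         "simulate.params: needs k1, k_m1, kf")
  } else if (identical(cfg$mode, "trf")) {
    need(!is.null(cfg$curves$sl_ref) && length(cfg$curves$sl_ref) >= 1,
         "curves.sl_ref: stem-loop reference decay TSV path(s) required")
    need(!is.null(cfg$curves$ed_ref) && length(cfg$curves$ed_ref) >= 1,
         "curves.ed_ref: equilibrated-duplex reference decay TSV path(s) required")
    need(!is.null(cfg$curves$mixtures) && length(cfg$curves$mixtures) >= 1,
         "curves.mixtures: mixture decay TSV path(s) required")
    need(!is.null(cfg$total_labeled),
         "total_labeled: labelled-strand concentration(s) (uM) required")
    need(!is.null(cfg$P0),
         "P0: complementary-strand concentration(s) (uM) required")
  } else {
    need(!is.null(cfg$traces) && length(cfg$traces) >= 1,
         "traces: intensity trace CSV path(s) required")
  }
  if (length(problems))
    stop("schema validation error:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  attr(cfg, "config_hash") <- hash
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

cfg_design <- function(d, seed, i) {
  experiment_design(SL0 = d$SL0, P0 = d$P0,
                    counts_per_curve = d$counts_per_curve %||% 1e6,
                    seed = seed + 1000L * i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_params <- function(p, scheme = "two_step") {
  kinetic_params(p$k1, p$k_m1, p$kf, k2 = p$k2 %||% NA_real_,
                 k_m2 = p$k_m2 %||% NA_real_, scheme = scheme)
}

stamp <- function(cfg) {
  list(config_hash = attr(cfg, "config_hash"), seed = cfg$seed,
       package_version = as.character(utils::packageVersion("trfkin")))
}

#' Run the droplet-TRF analysis pipeline
#'
#' Executes the full decay-domain workflow: reference-signature fitting,
#' global three-species decomposition with shared intermediate lifetime,
#' conversion to concentrations, and the global two-step kinetic fit across
#' all experiments. With a `simulate` block the inputs are generated by the
#' synthetic instrument at the configured designs and seed; otherwise decay
#' TSV files are read. Writes `decomposition.csv`, `decomposition.json`,
#' `kinetics_trf.json` and `summary_trf.txt` into `output_dir`, each carrying
#' the config hash and seed.
#'
#' @param config Path to a config file or a config list
#'   (see [read_pipeline_config()]).
#' @return A report list: `signatures`, `decomposition`, `concentrations`,
#'   `kinetic_fit`, `truth` (when simulated), `files`.
#' @export
run_trf_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  if (!identical(cfg$mode, "trf"))
    stop("schema validation error: mode must be 'trf'", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    params <- cfg_params(sim$params)
    sig_gen <- default_signatures()
    times <- sim$times %||% 10^seq(-1, 1, length.out = 10)
    exps <- lapply(seq_along(sim$designs), function(i) {
      des <- cfg_design(sim$designs[[i]], cfg$seed, i)
      generate_trf_experiment(des, params, sig_gen, times = times,
                              noise = sim$noise %||% "poisson")
    })
    sl_ref <- unlist(lapply(exps, function(e)
      unlist(e$reference$windows[seq_along(e$reference$sl)],
             recursive = FALSE)), recursive = FALSE)
    ed_ref <- unlist(lapply(exps, function(e) {
      n_ref <- length(e$reference$sl)
      unlist(e$reference$windows[n_ref + seq_along(e$reference$ed)],
             recursive = FALSE)
    }), recursive = FALSE)
    mixtures <- lapply(exps, function(e) e$stitched)
    totals <- vapply(sim$designs, function(d) d$SL0, numeric(1))
    truth <- list(params = params,
                  trajectories = lapply(exps, function(e) e$truth$trajectory))
  } else {
    sl_ref <- lapply(cfg$curves$sl_ref, read_decay_tsv)
    ed_ref <- lapply(cfg$curves$ed_ref, read_decay_tsv)
    mixtures <- list(lapply(cfg$curves$mixtures, read_decay_tsv))
    totals <- as.numeric(cfg$total_labeled)
  }

  sig <- fit_signatures(sl_ref, ed_ref, seed = cfg$seed)
  dec <- decompose_two_step_global(mixtures, sig,
                                   tau_ic_range = cfg$fit$tau_ic_range %||% c(0.005, 1))

  ids <- unique(dec$table$id)
  if (length(totals) == 1L) totals <- rep(totals, length(ids))
  conc <- lapply(seq_along(ids), function(i) {
    tab <- dec$table[dec$table$id %in% ids[i] | is.na(dec$table$id), ]
    to_concentrations(structure(list(table = tab), class = "decomposition"),
                      totals[i])
  })
  experiments <- lapply(seq_along(ids), function(i) {
    d <- if (!is.null(cfg$simulate)) cfg$simulate$designs[[i]]
         else list(SL0 = totals[i], P0 = as.numeric(cfg$P0)[i])
    list(init = initial_conditions(d$SL0, d$P0),
         data = data.frame(T_s = conc[[i]]$T_s, conc_SL = conc[[i]]$conc_SL,
                           conc_IC = conc[[i]]$conc_IC,
                           conc_ED = conc[[i]]$conc_ED))
  })
  kin <- fit_concentration_trajectories(experiments, seed = cfg$seed)

  files <- file.path(cfg$output_dir,
                     c("decomposition.csv", "decomposition.json",
                       "kinetics_trf.json", "summary_trf.txt"))
  write_decomposition(dec, files[1], files[2])
  write_kinetic_fit_json(kin, files[3])
  derived <- derived_constants(kin$params)
  summary_lines <- c(
    "TRF-DmF pipeline summary",
    sprintf("config_hash: %s  seed: %d", attr(cfg, "config_hash"),
            as.integer(cfg$seed)),
    sprintf("tau_IC = %.4g ns (+/- %.2g), global reduced chi2 = %.4f",
            dec$tau_ic, dec$tau_ic_se, dec$chi2_reduced),
    sprintf("k1 = %.4g M^-1 s^-1%s, k-1 = %.4g s^-1, kf = %.4g s^-1",
            kin$params$k1,
            if (kin$k1_lower_bound) " (lower bound)" else "",
            kin$params$k_m1, kin$params$kf),
    sprintf("K = k1/k-1 = %.4g M^-1 (+/- %.2g)", derived$K, kin$K_se))
  writeLines(summary_lines, files[4])
  jsonlite::write_json(c(stamp(cfg), list(tau_ic_ns = dec$tau_ic)),
                       file.path(cfg$output_dir, "run_trf_meta.json"),
                       auto_unbox = TRUE, digits = NA)

  list(signatures = sig, decomposition = dec, concentrations = conc,
       kinetic_fit = kin, truth = truth, files = files,
       summary = summary_lines)
}

#' Run the stopped-flow intensity analysis pipeline
#'
#' Generates (or reads) stopped-flow intensity traces and fits the requested
#' kinetic scheme(s) globally. When both schemes are requested the report
#' contains both parameter sets side by side. Writes
#' `kinetics_trfi_<scheme>.json` and `summary_trfi.txt`.
#'
#' @param config Path to a config file or a config list.
#' @return A report list: `traces`, `fits` (one per scheme), `truth` (when
#'   simulated), `files`.
#' @export
run_trfi_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  if (!identical(cfg$mode, "trfi"))
    stop("schema validation error: mode must be 'trfi'", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    gen_scheme <- sim$params$scheme %||%
      (if (!is.null(sim$params$k2)) "three_step" else "two_step")
    params <- cfg_params(sim$params, gen_scheme)
    br <- brightness_vector(sim$brightness$I_SL %||% 0.18,
                            sim$brightness$I_IC1 %||% 0.95,
                            sim$brightness$I_IC2 %||% NA_real_)
    designs <- lapply(sim$designs, function(d) initial_conditions(d$SL0, d$P0))
    traces <- generate_trfi_traces(designs, params, br,
                                   noise = sim$noise %||% 0.01,
                                   seed = cfg$seed)
    truth <- list(params = params, brightness = br)
  } else {
    traces <- lapply(seq_along(cfg$traces), function(i) {
      dat <- utils::read.csv(cfg$traces[[i]])
      d <- cfg$designs[[i]]
      intensity_trace(dat$time_s, dat$intensity,
                      initial_conditions(d$SL0, d$P0))
    })
  }

  fits <- list()
  files <- character()
  for (sch in cfg$scheme) {
    fixed <- cfg$fit$fixed %||%
      (if (sch == "three_step") list(I_IC1 = 0.01) else list())
    fits[[sch]] <- fit_intensity_traces(traces, sch, fixed = fixed,
                                        seed = cfg$seed)
    fp <- file.path(cfg$output_dir, sprintf("kinetics_trfi_%s.json", sch))
    write_kinetic_fit_json(fits[[sch]], fp)
    files <- c(files, fp)
  }
  summary_lines <- c(
    "Tr-FI pipeline summary",
    sprintf("config_hash: %s  seed: %d", attr(cfg, "config_hash"),
            as.integer(cfg$seed)),
    unlist(lapply(names(fits), function(sch) {
      f <- fits[[sch]]
      sprintf("%s: k1 = %.4g M^-1 s^-1, k-1 = %.4g, %skf = %.4g s^-1, I_IC = %.3g",
              sch, f$params$k1, f$params$k_m1,
              if (sch == "three_step")
                sprintf("k2 = %.4g, k-2 = %.3g, ", f$params$k2, f$params$k_m2)
              else "",
              f$params$kf,
              if (sch == "three_step") f$brightness$I_IC2 else f$brightness$I_IC1)
    })))
  sf <- file.path(cfg$output_dir, "summary_trfi.txt")
  writeLines(summary_lines, sf)
  list(traces = traces, fits = fits, truth = truth,
       files = c(files, sf), summary = summary_lines)
}
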