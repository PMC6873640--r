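# Study drivers: per-configuration metric runs, the cohort sweep
# (sizes x variants x electrode configurations), the Laplace-vs-bidomain
# comparison, torso-height convergence in both truncation modes, and the
# metric correlation report. All results are tibbles; a full run is
# deterministic given its configuration.

#' Experiment configuration
#'
#' @param sizes torso size presets.
#' @param variants heart variants.
#' @param configs electrode configurations.
#' @param spacing voxel spacing, mm.
#' @param reference_voltage applied shock voltage for the DFT solve, V.
#' @param capacitance device capacitance, uF.
#' @param injected_current current for the impedance solve, A.
#' @param tol linear-solve relative residual tolerance.
#' @param half_heights torso-height sweep values, mm (increasing).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @param seed random seed recorded with the run (the pipeline itself is
#'   deterministic; the seed covers optional jitter extensions).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(sizes = c("small", "medium", "large"),
                              variants = "healthy",
                              configs = c("sicd", "tvicd1", "tvicd2"),
                              spacing = 2,
                              reference_voltage = 50,
                              capacitance = 100,
                              injected_current = 1,
                              tol = 1e-8,
                              half_heights = seq(80, 160, by = 20),
                              output_dir = NULL,
                              seed = 1L) {
  stopifnot(all(sizes %in% names(.torso_presets)),
            all(variants %in% c("healthy", "hcm", "dcm")),
            all(configs %in% c("sicd", "tvicd1", "tvicd2")),
            spacing > 0, reference_voltage > 0,
            !is.unsorted(half_heights, strictly = TRUE))
  structure(list(sizes = sizes, variants = variants, configs = configs,
                 spacing = spacing, reference_voltage = reference_voltage,
                 capacitance = capacitance,
                 injected_current = injected_current, tol = tol,
                 half_heights = half_heights, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load an experiment configuration from a YAML file
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

# build phantom + fibres + electrodes for one cell of the study grid;
# phantoms/fibres are reused across electrode configurations by callers
.prepare_case <- function(size, variant, spacing, tol = 1e-8) {
  ph <- build_torso_phantom(torso_params(size), heart_params(size, variant),
                            spacing = spacing)
  fb <- build_fibres(ph, tol = tol)
  list(phantom = ph, fibres = fb)
}

#' Run one (size, variant, configuration) case
#'
#' Builds the phantom and fibres, solves the Laplace problem at the
#' reference voltage for DFT and eta, and a current-injection solve for
#' the pathway impedance.
#'
#' @param config an [experiment_config()].
#' @param size,variant,electrode_config the case.
#' @param case optional pre-built `list(phantom, fibres)` to reuse across
#'   electrode configurations.
#' @param model a [conductivity_model()].
#' @return one-row [tibble::tibble()] with the shock metrics.
#' @export
run_configuration <- function(config, size, variant, electrode_config,
                              case = NULL, model = conductivity_model()) {
  if (!electrode_config %in% c("sicd", "tvicd1", "tvicd2")) {
    stop("unknown electrode configuration: ", electrode_config)
  }
  if (is.null(case)) case <- .prepare_case(size, variant, config$spacing,
                                           config$tol)
  ph <- case$phantom; fb <- case$fibres
  el <- place_electrodes(ph, electrode_config)
  op <- assemble_operator(ph, fb, model, "bulk")
  fld <- solve_laplace(ph, fb, model, el, config$reference_voltage,
                       tol = config$tol, op = op)
  myo <- ph$labels == ph$label_names["myocardium"]
  dft <- compute_dft(fld, myo)
  eta <- compute_eta(fld, ph, fb, model)
  inj <- inject_current(ph, fb, model, el, config$injected_current,
                        tol = config$tol, op = op)
  imp <- compute_impedance(inj)
  e_dft <- dft_energy(dft$dft_voltage, config$capacitance)
  v_ref <- config$reference_voltage
  cap <- config$capacitance
  sp <- config$spacing
  tibble::tibble(
    size = size, variant = variant, config = electrode_config,
    dft_voltage_V = dft$dft_voltage,
    dft_energy_J = e_dft,
    impedance_ohm = imp,
    eta = eta,
    g5_Vpcm = dft$g5,
    reference_voltage_V = v_ref,
    capacitance_uF = cap,
    spacing_mm = sp,
    n_myocardial_voxels = sum(myo))
}

#' Run the full cohort sweep
#'
#' All (size, variant, configuration) combinations of the experiment
#' configuration; phantoms and fibre fields are built once per
#' (size, variant) and shared across electrode configurations. Writes
#' `cohort_metrics.csv` and a JSON mirror when `config$output_dir` is set.
#'
#' @param config an [experiment_config()].
#' @param model a [conductivity_model()].
#' @param verbose print progress lines.
#' @return tibble of class `shock_cohort` with one row per case.
#' @export
run_cohort <- function(config, model = conductivity_model(),
                       verbose = FALSE) {
  rows <- list()
  for (size in config$sizes) {
    for (variant in config$variants) {
      case <- .prepare_case(size, variant, config$spacing, config$tol)
      for (ec in config$configs) {
        if (verbose) {
          message(sprintf("[shockvec] %s / %s / %s", size, variant, ec))
        }
        rows[[length(rows) + 1L]] <-
          run_configuration(config, size, variant, ec, case = case,
                            model = model)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("shock_cohort", class(out))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(config$output_dir, "cohort_metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(out, file.path(config$output_dir,
                                        "cohort_metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Pairwise Pearson correlations of the efficacy metrics
#'
#' Correlation coefficients between DFT energy, impedance and eta over the
#' rows of a cohort table.
#'
#' @param results a `shock_cohort` tibble (>= 3 rows).
#' @return tibble with `pair` and `r`.
#' @export
correlation_report <- function(results) {
  if (nrow(results) < 3) {
    stop("correlation report needs at least 3 complete rows")
  }
  tibble::tibble(
    pair = c("dft_energy~impedance", "dft_energy~eta", "impedance~eta"),
    r = c(cor(results$dft_energy_J, results$impedance_ohm),
          cor(results$dft_energy_J, results$eta),
          cor(results$impedance_ohm, results$eta)))
}

#' Compare Laplace and passive-bidomain DFTs on one case
#'
#' Solves both formulations at the reference voltage on the identical
#' phantom and returns the relative DFT difference
#' `|DFT_laplace - DFT_bidomain| / DFT_laplace`.
#'
#' @inheritParams run_configuration
#' @param params a [bidomain_params()].
#' @return list with `dft_laplace`, `dft_bidomain`, `rel_diff`,
#'   `steady_rel_change`.
#' @export
compare_laplace_bidomain <- function(config, size, variant, electrode_config,
                                     case = NULL,
                                     model = conductivity_model(),
                                     params = bidomain_params()) {
  if (is.null(case)) case <- .prepare_case(size, variant, config$spacing,
                                           config$tol)
  ph <- case$phantom; fb <- case$fibres
  el <- place_electrodes(ph, electrode_config)
  myo <- ph$labels == ph$label_names["myocardium"]
  fld_l <- solve_laplace(ph, fb, model, el, config$reference_voltage,
                         tol = config$tol)
  dft_l <- compute_dft(fld_l, myo)$dft_voltage
  fld_b <- solve_passive_bidomain(ph, fb, model, params, el,
                                  config$reference_voltage, tol = config$tol)
  dft_b <- compute_dft(fld_b, myo, v_ref = config$reference_voltage)$dft_voltage
  list(dft_laplace = dft_l, dft_bidomain = dft_b,
       rel_diff = abs(dft_l - dft_b) / dft_l,
       steady_rel_change = fld_b$steady_rel_change)
}

#' Torso-height convergence sweep
#'
#' Two modes: `"truncate_domain"` clips the phantom before solving (all
#' quantities recomputed per height); `"truncate_analysis"` performs one
#' full-domain solve and restricts only the analysis region of the eta
#' denominator (DFT and myocardial dissipation constant across rows).
#'
#' @inheritParams run_configuration
#' @param mode truncation mode.
#' @return tibble with columns `half_height_mm`, `eta`, `dft_voltage_V`,
#'   `power_heart_W`, `power_torso_W`.
#' @export
torso_height_sweep <- function(config, size = "tavi2", variant = "healthy",
                               electrode_config = "sicd",
                               mode = c("truncate_analysis",
                                        "truncate_domain"),
                               model = conductivity_model()) {
  mode <- match.arg(mode)
  rows <- list()
  if (mode == "truncate_analysis") {
    case <- .prepare_case(size, variant, config$spacing, config$tol)
    ph <- case$phantom; fb <- case$fibres
    el <- place_electrodes(ph, electrode_config)
    fld <- solve_laplace(ph, fb, model, el, config$reference_voltage,
                         tol = config$tol)
    myo <- ph$labels == ph$label_names["myocardium"]
    dft <- compute_dft(fld, myo)$dft_voltage
    for (hh in config$half_heights) {
      tr <- eta_truncated_analysis(fld, ph, fb, model, hh)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        half_height_mm = hh, eta = tr$eta, dft_voltage_V = dft,
        power_heart_W = tr$power_myo, power_torso_W = tr$power_region)
    }
  } else {
    full <- .prepare_case(size, variant, config$spacing, config$tol)
    for (hh in config$half_heights) {
      ph <- truncate_torso(full$phantom, hh)
      fb <- build_fibres(ph, tol = config$tol)
      el <- place_electrodes(ph, electrode_config)
      fld <- solve_laplace(ph, fb, model, el, config$reference_voltage,
                           tol = config$tol)
      myo <- ph$labels == ph$label_names["myocardium"]
      dft <- compute_dft(fld, myo)$dft_voltage
      ed <- compute_eta(fld, ph, fb, model, details = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        half_height_mm = hh, eta = ed$eta, dft_voltage_V = dft,
        power_heart_W = ed$power_myo, power_torso_W = ed$power_total)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  out
}
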