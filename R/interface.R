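#' Study run configuration
#'
#' Assembles every tunable of the end-to-end synthetic study into one
#' serializable list: device, modulation targets, pupil and BOLD session
#' parameters, pipeline thresholds and seeds. All thresholds default to
#' the protocol values used throughout the package (spike MAD 6/25,
#' motion-PCA variance 0.95, QC fraction 0.5, silencing tolerance 1e-3).
#'
#' @param seed master seed.
#' @param presets disease presets to simulate.
#' @param device list: `n_primaries`, `fwhm_nm`.
#' @param modulations named list of modulation specs (targeted/silenced).
#' @param pupil list: `n_per_condition`, `noise_sd_pct`, `duration_s`.
#' @param bold list: `dim`, `n_tr`, `n_acq`, `noise_sd_pct`, `ar_rho`.
#' @param thresholds list: `spike_voxel_k`, `spike_tr_k`, `pca_variance`,
#'   `qc_fraction`, `silencing_tolerance`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       presets = c("WT", "RCD1", "XLPRA2", "CRD2"),
                       device = list(n_primaries = 56, fwhm_nm = 16),
                       modulations = list(
                         LS = list(targeted = c("L", "S"),
                                   silenced = c("rod", "mel")),
                         LightFlux = list(targeted = c("L", "S", "rod",
                                                       "mel"),
                                          silenced = character(0)),
                         RodMel = list(targeted = c("rod", "mel"),
                                       silenced = c("L", "S"))),
                       pupil = list(n_per_condition = 4, noise_sd_pct = 2,
                                    duration_s = 360),
                       bold = list(dim = c(24, 24, 16), n_tr = 144,
                                   n_acq = 6, noise_sd_pct = 0.25,
                                   ar_rho = 0.3),
                       thresholds = list(spike_voxel_k = 6,
                                         spike_tr_k = 25,
                                         pca_variance = 0.95,
                                         qc_fraction = 0.5,
                                         silencing_tolerance = 1e-3)) {
  cfg <- list(seed = seed, presets = presets, device = device,
              modulations = modulations, pupil = pupil, bold = bold,
              thresholds = thresholds)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$pca_variance <= 0 || th$pca_variance > 1) {
    stop("pca_variance must be in (0, 1]", call. = FALSE)
  }
  if (th$qc_fraction < 0 || th$qc_fraction > 1) {
    stop("qc_fraction must be in [0, 1]", call. = FALSE)
  }
  if (th$silencing_tolerance <= 0) {
    stop("silencing_tolerance must be positive", call. = FALSE)
  }
  if (th$spike_voxel_k <= 0 || th$spike_tr_k <= 0) {
    stop("spike MAD multipliers must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return A `run_config` (read) or the path, invisibly (write).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$bold$dim <- as.numeric(cfg$bold$dim)
  cfg$modulations <- lapply(cfg$modulations, function(m) {
    m$silenced <- as.character(unlist(m$silenced))
    m$targeted <- if (is.list(m$targeted)) unlist(m$targeted) else m$targeted
    m
  })
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic study
#'
#' End-to-end orchestration: designs the spectral modulations on the
#' synthetic device, simulates pupillometry and BOLD sessions for each
#' disease preset, runs both analysis pipelines, and collects per-preset,
#' per-condition response tables. When `out_dir` is given, all tables are
#' written (CSV/JSON) and a manifest with md5 hashes is produced;
#' identical config and seed give identical hashes.
#'
#' @param config a `run_config`.
#' @param out_dir optional output directory.
#' @param verbose print stage progress (default FALSE).
#' @return List of class `study_result`: `modulations`, `pupil` (data
#'   frame), `bold` (data frame), `manifest` (or NULL).
#' @export
run_study <- function(config = run_config(), out_dir = NULL,
                      verbose = FALSE) {
  validate_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("designing modulations on the synthetic device")
  S <- receptor_sensitivities()
  dev <- stage("device", synth_device(config$device$n_primaries,
                                      config$device$fwhm_nm,
                                      seed = config$seed))
  mods <- stage("design", lapply(config$modulations, function(m) {
    design_modulation(dev, m$targeted, m$silenced, S,
                      tolerance = config$thresholds$silencing_tolerance,
                      seed = config$seed)
  }))
  contrasts <- lapply(mods, function(m) m$contrast_report$bipolar)

  say("simulating and analyzing pupillometry sessions")
  pupil_rows <- list()
  for (p in config$presets) {
    ses <- stage("synth_pupil",
                 synth_pupil_session(p, seed = config$seed,
                                     n_per_condition =
                                       config$pupil$n_per_condition,
                                     duration_s = config$pupil$duration_s,
                                     noise_sd_pct =
                                       config$pupil$noise_sd_pct,
                                     contrasts = contrasts[
                                       intersect(names(contrasts),
                                                 c("LS", "RodMel",
                                                   "LightFlux"))]))
    for (cond in unique(vapply(ses$acquisitions, `[[`, "", "condition"))) {
      fit <- stage("pupil_fit", analyze_pupil_condition(ses, cond))
      pupil_rows[[length(pupil_rows) + 1]] <- data.frame(
        preset = p, condition = cond,
        amplitude_pct = fit$amplitude, phase_rad = fit$phase,
        sem_amplitude = fit$sem_amplitude, sem_phase = fit$sem_phase,
        n_acq = fit$n_acq)
    }
  }
  pupil_tab <- do.call(rbind, pupil_rows)

  say("simulating and analyzing BOLD sessions")
  bold_rows <- list()
  for (p in config$presets) {
    ses <- stage("synth_bold",
                 synth_bold_session(p, seed = config$seed,
                                    dim = config$bold$dim,
                                    n_tr = config$bold$n_tr,
                                    n_acq = config$bold$n_acq,
                                    noise_sd_pct =
                                      config$bold$noise_sd_pct,
                                    ar_rho = config$bold$ar_rho))
    res <- stage("bold_analysis",
                 analyze_bold_session(
                   ses, spike_k = config$thresholds$spike_voxel_k,
                   tr_k = config$thresholds$spike_tr_k,
                   pca_variance = config$thresholds$pca_variance))
    for (roi in c("cortex", "lgn")) {
      mask <- if (roi == "cortex") ses$cortex_mask else ses$lgn_mask
      for (eye in unique(ses$eyes)) {
        rr <- roi_response(res$fit, mask,
                           acquisitions = which(ses$eyes == eye))
        bold_rows[[length(bold_rows) + 1]] <- data.frame(
          preset = p, roi = roi, eye = eye, mean_pct = rr$mean,
          sem = rr$sem, n_acq = rr$n_acq, n_voxels = rr$n_voxels)
      }
    }
  }
  bold_tab <- do.call(rbind, bold_rows)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fmt <- function(x) signif(x, 9)
    num <- vapply(pupil_tab, is.numeric, TRUE)
    pupil_out <- pupil_tab
    pupil_out[num] <- lapply(pupil_out[num], fmt)
    num <- vapply(bold_tab, is.numeric, TRUE)
    bold_out <- bold_tab
    bold_out[num] <- lapply(bold_out[num], fmt)
    files <- c(pupil = file.path(out_dir, "pupil_responses.csv"),
               bold = file.path(out_dir, "bold_roi_responses.csv"),
               modulations = file.path(out_dir, "modulations.json"))
    utils::write.csv(pupil_out, files["pupil"], row.names = FALSE)
    utils::write.csv(bold_out, files["bold"], row.names = FALSE)
    jsonlite::write_json(lapply(mods, function(m) list(
      background = fmt(m$background_settings),
      pos = fmt(m$pos_settings), neg = fmt(m$neg_settings),
      bipolar_contrast = fmt(m$contrast_report$bipolar),
      silenced = m$silenced)), files["modulations"], digits = NA)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }

  structure(list(modulations = mods, pupil = pupil_tab, bold = bold_tab,
                 manifest = manifest, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Synthetic study run (seed", x$config$seed, ")\n\n")
  cat("Pupil responses:\n")
  print(x$pupil, digits = 3, row.names = FALSE)
  cat("\nBOLD ROI responses:\n")
  print(x$bold, digits = 3, row.names = FALSE)
  invisible(x)
}
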