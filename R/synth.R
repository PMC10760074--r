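#' Retinal disease-model presets
#'
#' Multiplicative response gains per photoreceptor mechanism for the
#' studied genotypes. The gains are nominal (the disease literature is
#' qualitative): WT has full function; RCD1 severe rod loss with preserved
#' cones; XLPRA2 diminished rod and cone function; CRD2 nearly complete
#' cone loss; CRD2_treated restores the treated (left) eye while the
#' fellow eye stays at the CRD2 baseline.
#'
#' @param name one of "WT", "RCD1", "XLPRA2", "CRD2", "CRD2_treated".
#' @return Object of class `disease_preset`: `gains` (named L/S/rod/mel
#'   vector) and, for per-eye differences, `eye_gains` (list with `left`
#'   and `right` vectors).
#' @export
disease_preset <- function(name = c("WT", "RCD1", "XLPRA2", "CRD2",
                                    "CRD2_treated")) {
  name <- match.arg(name)
  g <- switch(name,
    WT = c(L = 1, S = 1, rod = 1, mel = 1),
    RCD1 = c(L = 1, S = 1, rod = 0.05, mel = 1),
    XLPRA2 = c(L = 0.4, S = 0.4, rod = 0.3, mel = 1),
    CRD2 = c(L = 0, S = 0, rod = 0.05, mel = 1),
    CRD2_treated = c(L = 0, S = 0, rod = 0.05, mel = 1))
  eye_gains <- if (name == "CRD2_treated") {
    list(left = c(L = 1, S = 1, rod = 0.5, mel = 1),
         right = c(L = 0, S = 0, rod = 0.05, mel = 1))
  } else {
    list(left = g, right = g)
  }
  structure(list(name = name, gains = g, eye_gains = eye_gains),
            class = "disease_preset")
}

#' @export
print.disease_preset <- function(x, ...) {
  cat("Disease preset", x$name, "- mechanism gains:\n")
  print(x$gains)
  invisible(x)
}

#' 1/f (pink) temporal noise
#'
#' Spectrally shaped Gaussian noise with amplitude proportional to
#' 1/sqrt(f), scaled to a target standard deviation. Fully seeded via the
#' caller's RNG state.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @return Numeric vector of length n.
#' @export
pink_noise <- function(n, sd = 1) {
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1)           # symmetric spectrum
  shaped <- Re(stats::fft(f / sqrt(freq), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  shaped * sd / stats::sd(shaped)
}

# nominal bipolar contrasts per condition when no designed modulation
# set is supplied (light flux ~0.95 on all; L+S 0.35 on cones; Rod+Mel
# 0.5 on rods/melanopsin)
nominal_condition_contrasts <- function() {
  list(
    LS = c(L = 0.35, S = 0.35, rod = 0, mel = 0),
    RodMel = c(L = 0, S = 0, rod = 0.5, mel = 0.5),
    LightFlux = c(L = 0.95, S = 0.95, rod = 0.95, mel = 0.95))
}

# relative pupil-drive efficacy per mechanism under a photopic background:
# cones dominate; rods largely saturated; melanopsin too slow at 1/6 Hz
mechanism_efficacy <- function() {
  c(L = 1, S = 1, rod = 0.05, mel = 0.02)
}

#' Simulate a pupillometry measurement session
#'
#' Generates consensual pupil area time series for the session protocol:
#' three conditions (L+S, Rod+Mel, light flux) at 1/6 Hz over 360 s,
#' `n_per_condition` acquisitions each per eye-order repeat (default 4,
#' i.e. 12 acquisitions). The response amplitude of each condition is the
#' light-flux amplitude scaled by the preset's mechanism gains and the
#' condition contrasts; pink noise and Poisson blink dropouts are added.
#'
#' @param preset a `disease_preset` or its name.
#' @param seed integer seed; the session is fully deterministic given it.
#' @param n_per_condition acquisitions per condition (default 4).
#' @param duration_s,sample_rate_hz,frequency_hz acquisition timing
#'   (defaults 360 s, 60 Hz, 1/6 Hz).
#' @param lightflux_amplitude_pct peak % area change of the light-flux
#'   response in WT (default 8).
#' @param amplitude_ratio optional override of the L+S : light-flux
#'   amplitude ratio (e.g. 0.34); when NULL the ratio follows from the
#'   contrasts and gains.
#' @param phase_rad response phase (default -2.6 rad: constriction lags
#'   the photic drive).
#' @param noise_sd_pct SD of the pink noise in % area change (default 2).
#' @param blink_rate_hz Poisson blink rate (default 0.1/s); each blink
#'   masks a 0.3 s window.
#' @param contrasts per-condition contrast list, default
#'   nominal values; supply values from designed modulations to couple the
#'   generator to [design_modulation()].
#' @param mean_area_px2 mean pupil area in px^2 (default 10000).
#' @return List of class `pupil_session`: `acquisitions` (each with
#'   `condition`, `eye`, and a `pupil_timeseries`), `preset`,
#'   `true_amplitudes`.
#' @export
synth_pupil_session <- function(preset = "WT", seed = 1,
                                n_per_condition = 4, duration_s = 360,
                                sample_rate_hz = 60, frequency_hz = 1 / 6,
                                lightflux_amplitude_pct = 8,
                                amplitude_ratio = NULL,
                                phase_rad = -2.6, noise_sd_pct = 2,
                                blink_rate_hz = 0.1,
                                contrasts = nominal_condition_contrasts(),
                                mean_area_px2 = 10000) {
  if (is.character(preset)) preset <- disease_preset(preset)
  if (!inherits(preset, "disease_preset")) {
    stop("unknown preset", call. = FALSE)
  }
  set.seed(seed)
  eff <- mechanism_efficacy()
  drive <- vapply(contrasts, function(cc) {
    sum(eff * preset$gains[names(eff)] * abs(cc[names(eff)]))
  }, 0)
  drive_wt_lf <- sum(eff * abs(contrasts$LightFlux[names(eff)]))
  amp <- lightflux_amplitude_pct * drive / drive_wt_lf
  if (!is.null(amplitude_ratio)) {
    amp["LS"] <- amp["LightFlux"] * amplitude_ratio
  }

  dt <- 1 / sample_rate_hz
  tm <- seq(0, duration_s - dt, by = dt)
  n <- length(tm)
  conds <- rep(names(contrasts), 2)           # one set per stimulated eye
  eyes <- rep(c("right", "left"), each = length(contrasts))
  acqs <- list()
  for (r in seq_len(n_per_condition / 2)) {
    for (i in seq_along(conds)) {
      signal <- amp[conds[i]] * sin(2 * pi * frequency_hz * tm + phase_rad)
      noise <- if (noise_sd_pct > 0) pink_noise(n, noise_sd_pct) else 0
      pct <- signal + noise
      valid <- rep(TRUE, n)
      n_blinks <- stats::rpois(1, blink_rate_hz * duration_s)
      if (n_blinks > 0) {
        starts <- stats::runif(n_blinks, 0, duration_s - 0.3)
        for (s in starts) valid[tm >= s & tm < s + 0.3] <- FALSE
      }
      area <- mean_area_px2 * (1 + pct / 100)
      acqs[[length(acqs) + 1]] <- list(
        condition = conds[i], eye = eyes[i],
        series = pupil_timeseries(tm, area, valid))
    }
  }
  structure(list(acquisitions = acqs, preset = preset,
                 true_amplitudes = amp, frequency_hz = frequency_hz,
                 phase_rad = phase_rad, seed = seed),
            class = "pupil_session")
}

#' Analyze one condition of a pupil session
#'
#' Applies acquisition QC, frame-wise averages the retained acquisitions
#' of the condition and fits the sinusoid with exhaustive-bootstrap SEMs.
#'
#' @param session a `pupil_session`.
#' @param condition condition label ("LS", "RodMel", "LightFlux").
#' @return A `pupil_fit` (see [bootstrap_sem()]).
#' @export
analyze_pupil_condition <- function(session, condition) {
  sel <- Filter(function(a) a$condition == condition, session$acquisitions)
  if (!length(sel)) stop("no acquisitions for condition", call. = FALSE)
  series <- lapply(sel, `[[`, "series")
  bootstrap_sem(series, session$frequency_hz)
}

#' Simulate a blocked-flicker BOLD session
#'
#' Generates per-acquisition 4-D volumes with HRF-convolved block
#' responses in mirror-symmetric cortical (positive) and LGN (negative)
#' regions, plus linear drift, AR(1) noise, scheduled global spikes, and
#' motion-correlated nuisance, with accompanying motion-parameter tables.
#' Acquisitions alternate stimulated eye (first half one eye, second half
#' the other), with per-eye amplitudes from the preset.
#'
#' @param preset a `disease_preset` or name.
#' @param seed integer seed; byte-identical outputs for identical inputs.
#' @param dim spatial dimensions (default c(24, 24, 16)).
#' @param n_tr TRs per acquisition (default 144, i.e. 432 s at TR 3 s).
#' @param tr repetition time (default 3).
#' @param n_acq acquisitions (default 6: 3 per eye).
#' @param stimulus_label stimulus type label (default "lightflux").
#' @param stimulus_contrast scalar in [0, 1] scaling the cone drive of the
#'   stimulus (default 0.95, light flux).
#' @param base_amplitude_pct cortical % signal change at full drive
#'   (default 0.25).
#' @param amplitude_left_pct,amplitude_right_pct optional explicit cortical
#'   amplitudes per stimulated eye, overriding the preset-derived values.
#' @param lgn_gain LGN amplitude relative to cortex, negative sign
#'   (default -0.6).
#' @param noise_sd_pct temporal noise SD in % of baseline (default 0.25).
#' @param ar_rho AR(1) coefficient of the noise (default 0.3).
#' @param drift_pct_per_acq max linear drift over an acquisition in %
#'   (default 0.5).
#' @param spikes_per_acq expected scheduled global spikes per acquisition
#'   (default 1); `spike_trs` fixes the schedule explicitly (list per
#'   acquisition).
#' @param spike_amplitude_pct global offset of a spike in % (default 5).
#' @param motion_coupling_pct amplitude of motion-correlated nuisance
#'   (default 0.1).
#' @param baseline mean signal level (default 1000).
#' @return List of class `bold_session`: `acquisitions` (list of
#'   `bold_series`), `motion` (list of t x 6 tables), `protocol`,
#'   `cortex_mask`, `lgn_mask`, `true_amplitudes` (per acquisition),
#'   `spike_trs`.
#' @export
synth_bold_session <- function(preset = "WT", seed = 1,
                               dim = c(24, 24, 16), n_tr = 144, tr = 3,
                               n_acq = 6, stimulus_label = "lightflux",
                               stimulus_contrast = 0.95,
                               base_amplitude_pct = 0.25,
                               amplitude_left_pct = NULL,
                               amplitude_right_pct = NULL,
                               lgn_gain = -0.6, noise_sd_pct = 0.25,
                               ar_rho = 0.3, drift_pct_per_acq = 0.5,
                               spikes_per_acq = 1,
                               spike_trs = NULL,
                               spike_amplitude_pct = 5,
                               motion_coupling_pct = 0.1,
                               baseline = 1000) {
  if (is.character(preset)) preset <- disease_preset(preset)
  set.seed(seed)
  protocol <- bold_protocol(tr = tr, duration = n_tr * tr, n_acq = n_acq)
  basis <- hrf_basis(tr)
  # a beta of 1 means 1% signal change against the same peak-normalized
  # canonical kernel the fitting stage uses
  kcan <- hrf_kernel(basis, c(1, 0, 0))
  conv <- stats::convolve(build_design(protocol, basis)$boxcar_over,
                          rev(kcan), type = "open")
  conv <- conv[seq_len(n_tr * basis$oversample)] * basis$dt
  response <- as.numeric(tapply(conv, rep(seq_len(n_tr),
                                          each = basis$oversample), mean))
  # bipolar modulation around the acquisition mean: the stated amplitude
  # is % signal change as measured (relative to the acquisition mean)
  response <- response - mean(response)

  # mirror-symmetric region geometry, proportional to the volume size
  cortex_mask <- array(FALSE, dim)
  lgn_mask <- array(FALSE, dim)
  rng <- function(n, lo, hi) max(1, round(n * lo)):min(n, round(n * hi))
  cx_l <- rng(dim[1], 0.167, 0.333)
  cx_r <- rev(dim[1] + 1 - cx_l)
  cortex_mask[c(cx_l, cx_r), rng(dim[2], 0.25, 0.5),
              rng(dim[3], 0.5625, 0.8125)] <- TRUE
  lg_l <- rng(dim[1], 0.417, 0.458)
  lg_r <- rev(dim[1] + 1 - lg_l)
  lgn_mask[c(lg_l, lg_r), rng(dim[2], 0.583, 0.667),
           rng(dim[3], 0.375, 0.5)] <- TRUE

  cone_drive <- function(eye) {
    g <- preset$eye_gains[[eye]]
    unname(stimulus_contrast * (g["L"] + g["S"]) / 2)
  }
  amp_eye <- c(
    left = if (is.null(amplitude_left_pct))
      base_amplitude_pct * cone_drive("left") else amplitude_left_pct,
    right = if (is.null(amplitude_right_pct))
      base_amplitude_pct * cone_drive("right") else amplitude_right_pct)

  eyes <- rep(c("left", "right"), each = ceiling(n_acq / 2))[seq_len(n_acq)]
  nv <- prod(dim)
  acqs <- vector("list", n_acq)
  motion <- vector("list", n_acq)
  spikes_out <- vector("list", n_acq)
  true_amp <- numeric(n_acq)
  mot_pattern <- array(stats::rnorm(nv, 0, 1), dim)
  for (a in seq_len(n_acq)) {
    amp <- unname(amp_eye[eyes[a]])
    true_amp[a] <- amp
    sig <- matrix(0, nv, n_tr)
    sig[which(cortex_mask), ] <- matrix(rep(amp * response, each = sum(cortex_mask)),
                                        sum(cortex_mask))
    sig[which(lgn_mask), ] <- matrix(rep(amp * lgn_gain * response,
                                         each = sum(lgn_mask)), sum(lgn_mask))
    # AR(1) noise, % units
    eps <- matrix(stats::rnorm(nv * n_tr), nv, n_tr)
    if (ar_rho != 0) {
      eps <- t(stats::filter(t(eps), ar_rho, method = "recursive"))
      eps <- unclass(eps) * sqrt(1 - ar_rho^2)
    }
    noise <- noise_sd_pct * eps
    # per-voxel random linear drift
    slope <- stats::runif(nv, -drift_pct_per_acq, drift_pct_per_acq)
    drift <- outer(slope, (seq_len(n_tr) - 1) / (n_tr - 1))
    # motion parameters: quasi-periodic cardiopulmonary oscillations
    # (sampled at TR, hence aliased) plus measurement jitter
    tt_tr <- (seq_len(n_tr) - 1) * tr
    f_task <- 1 / (protocol$block_on + protocol$block_off)
    draw_resp_freq <- function() {
      # ventilation rates whose TR-aliased frequency lands on the stimulus
      # fundamental or its second harmonic are avoided, as in the protocol
      repeat {
        f <- stats::runif(1, 0.15, 0.4)
        alias <- abs(f - round(f * tr) / tr)
        if (min(abs(alias - c(f_task, 2 * f_task))) > 2 / (n_tr * tr)) {
          return(f)
        }
      }
    }
    mp <- vapply(c(rep(0.05, 3), rep(0.002, 3)), function(s) {
      s * sin(2 * pi * draw_resp_freq() * tt_tr +
                stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n_tr, 0, 0.2 * s)
    }, numeric(n_tr))
    colnames(mp) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad",
                      "rz_rad")
    mot_nuis <- motion_coupling_pct *
      outer(as.vector(mot_pattern), scale(mp[, 1])[, 1])
    # scheduled global spikes
    st <- if (!is.null(spike_trs)) spike_trs[[a]]
          else if (spikes_per_acq > 0)
            sort(sample(seq(10, n_tr - 10), stats::rpois(1, spikes_per_acq)))
          else integer(0)
    spike_sig <- matrix(0, nv, n_tr)
    if (length(st)) spike_sig[, st] <- spike_amplitude_pct
    pct <- sig + noise + drift + mot_nuis + spike_sig
    raw <- baseline * (1 + pct / 100)
    acqs[[a]] <- bold_series(array(raw, c(dim, n_tr)), tr = tr,
                             acquisition_id = a, eye = eyes[a],
                             stimulus_label = stimulus_label)
    motion[[a]] <- mp
    spikes_out[[a]] <- st
  }
  structure(list(acquisitions = acqs, motion = motion, protocol = protocol,
                 basis = basis, cortex_mask = cortex_mask,
                 lgn_mask = lgn_mask, true_amplitudes = true_amp,
                 eyes = eyes, spike_trs = spikes_out, preset = preset,
                 seed = seed),
            class = "bold_session")
}

#' Preprocess and fit a synthetic (or loaded) BOLD session
#'
#' Runs the full time-series hygiene and model-fitting chain on a
#' `bold_session`: per-acquisition linear detrend, MAD spike detection,
#' motion-PCA + spike confound regression, optional hemispheric mirror
#' averaging, then the nonlinear forward-model fit of the concatenated
#' acquisitions.
#'
#' @param session a `bold_session`.
#' @param mirror apply [mirror_average()] to each cleaned acquisition
#'   (default TRUE).
#' @param spike_k,tr_k MAD thresholds passed to [detect_spikes()].
#' @param pca_variance variance fraction for [motion_confounds()].
#' @return List: `fit` (a `bold_fit`), `cleaned` acquisitions,
#'   `spike_events` per acquisition.
#' @export
analyze_bold_session <- function(session, mirror = TRUE, spike_k = 6,
                                 tr_k = 25, pca_variance = 0.95) {
  n_tr <- session$protocol$n_tr
  trend <- seq_len(n_tr) - (n_tr + 1) / 2
  cleaned <- vector("list", length(session$acquisitions))
  spikes <- vector("list", length(session$acquisitions))
  confs <- vector("list", length(session$acquisitions))
  for (a in seq_along(session$acquisitions)) {
    s <- linear_detrend(session$acquisitions[[a]])
    sp <- detect_spikes(s, voxel_k = spike_k, tr_k = tr_k)
    mc <- motion_confounds(session$motion[[a]],
                           variance_target = pca_variance)
    s <- regress_confounds(s, list(mc, sp))
    if (mirror) s <- mirror_average(s)
    cleaned[[a]] <- s
    spikes[[a]] <- sp
    # full set regressed from the data (detrend included), for the
    # Frisch-Waugh correction of the task design in the fit
    confs[[a]] <- cbind(trend, mc$regressors, sp$confounds)
  }
  fit <- fit_forward_model(cleaned, session$protocol, session$basis,
                           confounds = confs)
  list(fit = fit, cleaned = cleaned, spike_events = spikes)
}

#' Write a BOLD session to disk
#'
#' Emits NIfTI-1 volumes, 6-column motion CSVs and a protocol JSON in the
#' formats the analysis stages consume.
#'
#' @param session a `bold_session`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest of written files.
#' @export
write_bold_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (a in seq_along(session$acquisitions)) {
    nif <- file.path(dir, sprintf("acq%02d_bold.nii.gz", a))
    RNifti::writeNifti(RNifti::asNifti(session$acquisitions[[a]]$data,
                                       pixdim = c(2, 2, 3,
                                                  session$protocol$tr)),
                       nif)
    mot <- file.path(dir, sprintf("acq%02d_motion.csv", a))
    utils::write.csv(as.data.frame(session$motion[[a]]), mot,
                     row.names = FALSE)
    files <- c(files, nif, mot)
  }
  pj <- file.path(dir, "protocol.json")
  jsonlite::write_json(list(tr = session$protocol$tr,
                            duration = session$protocol$duration,
                            block_on = session$protocol$block_on,
                            block_off = session$protocol$block_off,
                            n_acq = session$protocol$n_acq,
                            onsets = session$protocol$onsets,
                            eyes = session$eyes,
                            preset = session$preset$name,
                            seed = session$seed),
                       pj, auto_unbox = TRUE, digits = NA)
  files <- c(files, pj)
  invisible(files)
}

#' Read a BOLD session from disk
#'
#' Counterpart of [write_bold_session()].
#'
#' @param dir directory written by [write_bold_session()].
#' @return A `bold_session` (without generator ground truth).
#' @export
read_bold_session <- function(dir) {
  pj <- jsonlite::read_json(file.path(dir, "protocol.json"),
                            simplifyVector = TRUE)
  protocol <- bold_protocol(tr = pj$tr, duration = pj$duration,
                            block_on = pj$block_on,
                            block_off = pj$block_off, n_acq = pj$n_acq)
  acqs <- vector("list", pj$n_acq)
  motion <- vector("list", pj$n_acq)
  for (a in seq_len(pj$n_acq)) {
    img <- RNifti::readNifti(file.path(dir,
                                       sprintf("acq%02d_bold.nii.gz", a)))
    acqs[[a]] <- bold_series(array(as.numeric(img), dim(img)), tr = pj$tr,
                             acquisition_id = a, eye = pj$eyes[a])
    motion[[a]] <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("acq%02d_motion.csv", a))))
  }
  structure(list(acquisitions = acqs, motion = motion, protocol = protocol,
                 basis = hrf_basis(pj$tr), eyes = pj$eyes,
                 preset = disease_preset(pj$preset), seed = pj$seed),
            class = "bold_session")
}
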