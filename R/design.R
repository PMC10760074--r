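#' Design a silent-substitution spectral modulation
#'
#' Searches device settings for a symmetric bipolar modulation around the
#' half-on background that silences one set of photoreceptors while
#' maximizing the minimum contrast on the targeted set (max-min criterion).
#'
#' With a fixed background the bipolar Weber contrast is linear in the
#' symmetric settings perturbation \eqn{d} (\eqn{w^\pm = w_0 \pm d}), so the
#' search is a seeded multi-start projected-gradient ascent of a smooth
#' min-contrast surrogate inside the silencing null space, followed by
#' alternating projections onto the gamut box and the null space. Silenced
#' contrasts come out at numerical precision, far below `tolerance`.
#'
#' @param device a `device_model`.
#' @param targeted pigment labels to drive; either a character vector (all
#'   positive sign) or a named sign vector such as `c(L = 1, S = -1)` for an
#'   opponent (chromatic) modulation.
#' @param silenced pigment labels whose contrast must vanish.
#' @param sensitivities receptor matrix from [receptor_sensitivities()].
#' @param tolerance admissible absolute contrast on silenced pigments
#'   (default 1e-3).
#' @param n_starts multi-start count (default 20).
#' @param seed integer seed controlling the starts.
#' @param background_settings background settings scalar or vector
#'   (default half-on, 0.5).
#' @return Object of class `spectral_modulation` with background/pos/neg
#'   settings and spectra, the achieved `contrast_report`, and the minimum
#'   targeted contrast.
#' @export
design_modulation <- function(device, targeted, silenced, sensitivities,
                              tolerance = 1e-3, n_starts = 20, seed = 1,
                              background_settings = 0.5) {
  if (is.character(targeted)) {
    signs <- rep(1, length(targeted))
    names(signs) <- targeted
  } else {
    signs <- sign(targeted)
    if (any(signs == 0)) stop("targeted signs must be non-zero", call. = FALSE)
  }
  t_lab <- names(signs)
  pig <- colnames(sensitivities)
  if (!all(c(t_lab, silenced) %in% pig)) {
    stop("unknown pigment label", call. = FALSE)
  }
  if (length(intersect(t_lab, silenced))) {
    stop("targeted and silenced sets must be disjoint", call. = FALSE)
  }

  n <- device$n_primaries
  w0 <- rep(background_settings, length.out = n)
  grid <- device$wavelengths
  dl <- mean(diff(grid))
  # excitation per unit settings: E[p, j] = nd * sum_l S_p P_j dl
  E <- device$nd_factor * crossprod(sensitivities, device$primaries) * dl
  e_bg <- excitation(device_spectrum(device, w0), sensitivities)
  if (any(e_bg <= 0)) {
    stop("background excitation must be strictly positive", call. = FALSE)
  }
  M <- E / e_bg                      # contrast per unit d, rows = pigments
  Mt <- M[t_lab, , drop = FALSE] * signs
  A <- M[silenced, , drop = FALSE]

  # null-space basis of the silencing constraints
  if (nrow(A) > 0) {
    sv <- svd(A, nu = 0, nv = n)
    rankA <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-10)
    if (rankA >= n) {
      stop("infeasible: silencing constraints leave no degrees of freedom",
           call. = FALSE)
    }
    N <- sv$v[, seq(rankA + 1, n), drop = FALSE]
    AtAinv <- solve(tcrossprod(A) + diag(1e-14, nrow(A)))
    proj_null <- function(d) d - drop(crossprod(A, AtAinv %*% (A %*% d)))
  } else {
    N <- diag(n)
    proj_null <- identity
  }
  dmax <- pmin(1 - w0, w0)           # symmetric-arm box half-width

  obj <- function(z, k_soft) {
    d <- drop(N %*% z)
    cc <- drop(Mt %*% d)
    m <- min(cc)
    sm <- m - log(sum(exp(-k_soft * (cc - m)))) / k_soft
    pen <- sum(pmax(0, abs(d) - dmax)^2)
    -sm + 1e4 * pen
  }
  grad <- function(z, k_soft) {
    d <- drop(N %*% z)
    cc <- drop(Mt %*% d)
    m <- min(cc)
    w <- exp(-k_soft * (cc - m)); w <- w / sum(w)
    g_d <- -drop(crossprod(Mt, w)) +
      1e4 * 2 * pmax(0, abs(d) - dmax) * sign(d)
    drop(crossprod(N, g_d))
  }

  polish <- function(d) {
    for (i in 1:400) {
      d_new <- proj_null(pmin(pmax(d, -dmax), dmax))
      if (max(abs(d_new - d)) < 1e-14) { d <- d_new; break }
      d <- d_new
    }
    # scale out to the gamut boundary (improves every targeted contrast)
    s <- max(abs(d / dmax))
    if (s > 0) d <- d * min(1 / s, 1e6)
    proj_null_clip <- d
    for (i in 1:200) {
      proj_null_clip <- proj_null(pmin(pmax(proj_null_clip, -dmax), dmax))
    }
    proj_null_clip
  }

  set.seed(seed)
  # deterministic warm starts plus seeded random restarts
  starts <- list(dmax * sign(colSums(Mt)),
                 dmax * sign(colMeans(M[t_lab, , drop = FALSE] * signs)))
  for (s in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <- stats::runif(n, -1, 1) * dmax
  }
  best <- NULL
  best_val <- -Inf
  for (d0 in starts) {
    z0 <- drop(crossprod(N, d0))
    fit <- try(stats::optim(z0, obj, grad, method = "L-BFGS-B",
                            control = list(maxit = 500), k_soft = 100),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    fit2 <- try(stats::optim(fit$par, obj, grad, method = "L-BFGS-B",
                             control = list(maxit = 500), k_soft = 3000),
                silent = TRUE)
    if (!inherits(fit2, "try-error")) fit <- fit2
    d <- polish(drop(N %*% fit$par))
    cc <- drop(Mt %*% d)
    sil <- if (nrow(A)) max(abs(drop(A %*% d))) else 0
    if (sil <= tolerance && min(cc) > best_val) {
      best_val <- min(cc)
      best <- d
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0("infeasible: no settings met the silencing ",
                        "tolerance %.2g"), tolerance), call. = FALSE)
  }

  pos <- w0 + best
  neg <- w0 - best
  rep_ <- contrast(device_spectrum(device, pos), device_spectrum(device, neg),
                   device_spectrum(device, w0), sensitivities,
                   targeted = t_lab, silenced = silenced)
  structure(list(
    background_settings = w0, pos_settings = pos, neg_settings = neg,
    targeted = signs, silenced = silenced,
    contrast_report = rep_, min_targeted_contrast = best_val,
    tolerance = tolerance, seed = seed, device_n_primaries = n
  ), class = "spectral_modulation")
}

#' @export
print.spectral_modulation <- function(x, ...) {
  cat("Silent-substitution modulation\n")
  cat("  targeted:", paste0(names(x$targeted),
                            ifelse(x$targeted > 0, "(+)", "(-)"),
                            collapse = " "), "\n")
  cat("  silenced:", paste(x$silenced, collapse = " "), "\n")
  cat(sprintf("  min targeted contrast: %.4f\n", x$min_targeted_contrast))
  sil <- x$contrast_report$bipolar[x$silenced]
  if (length(sil)) {
    cat(sprintf("  max |silenced contrast|: %.2e\n", max(abs(sil))))
  }
  invisible(x)
}

#' Temporal stimulus profile
#'
#' Describes the temporal course of a modulation: a slow sinusoid (default
#' 1/6 Hz, 360 s, for pupillometry) or blocked flicker (12 s on / 12 s off
#' with 1.5 s half-cosine ramps over 432 s, for fMRI; flicker rate 32, 4 or
#' 16 Hz depending on the modulation).
#'
#' @param kind "sinusoid" or "blocked_flicker".
#' @param frequency sinusoid frequency in Hz (default 1/6).
#' @param duration total duration in s.
#' @param block_on,block_off block durations in s.
#' @param ramp half-cosine ramp duration in s.
#' @param flicker_hz square-wave alternation rate within a block.
#' @param sample_rate output sampling rate in Hz.
#' @return Object of class `temporal_profile`.
#' @export
temporal_profile <- function(kind = c("sinusoid", "blocked_flicker"),
                             frequency = 1 / 6,
                             duration = if (kind == "sinusoid") 360 else 432,
                             block_on = 12, block_off = 12, ramp = 1.5,
                             flicker_hz = 16,
                             sample_rate = if (kind == "sinusoid") 60
                                           else max(60, 4 * flicker_hz)) {
  kind <- match.arg(kind)
  if (kind == "blocked_flicker" && ramp > block_on / 2) {
    stop("ramp longer than half the on-block", call. = FALSE)
  }
  f_chk <- if (kind == "sinusoid") frequency else flicker_hz
  if (sample_rate < 2 * f_chk) {
    stop("sample_rate must be at least twice the modulation frequency",
         call. = FALSE)
  }
  structure(list(kind = kind, frequency = frequency, duration = duration,
                 block_on = block_on, block_off = block_off, ramp = ramp,
                 flicker_hz = flicker_hz, sample_rate = sample_rate),
            class = "temporal_profile")
}

#' Block envelope of a blocked-flicker profile
#'
#' Gating envelope in [0,1]: 1 inside an on-block, 0 during off periods,
#' half-cosine transitions of length `ramp` at block onset and offset.
#'
#' @param profile a blocked-flicker `temporal_profile`.
#' @param time times in s.
#' @return Envelope values.
#' @export
block_envelope <- function(profile, time) {
  cyc <- profile$block_on + profile$block_off
  tau <- time %% cyc
  env <- numeric(length(time))
  on <- tau < profile$block_on
  env[on] <- 1
  r <- profile$ramp
  rise <- on & tau < r
  env[rise] <- 0.5 * (1 - cos(pi * tau[rise] / r))
  fall <- on & tau > profile$block_on - r
  env[fall] <- 0.5 * (1 - cos(pi * (profile$block_on - tau[fall]) / r))
  env
}

#' Settings trajectory of a modulation over time
#'
#' Sinusoid: \eqn{w(t) = w_0 + \sin(2\pi f t)\,(w^+ - w_0)}. Blocked
#' flicker: square-wave alternation between the two arms at the flicker
#' rate, gated by the 12 s on/off block envelope, with the static background
#' shown between blocks.
#'
#' @param profile a `temporal_profile`.
#' @param modulation a `spectral_modulation`.
#' @return List with `time`, `settings` (time x n_primaries), `envelope`
#'   and `n_blocks`.
#' @export
make_waveform <- function(profile, modulation) {
  dt <- 1 / profile$sample_rate
  time <- seq(0, profile$duration - dt, by = dt)
  w0 <- modulation$background_settings
  dp <- modulation$pos_settings - w0
  if (profile$kind == "sinusoid") {
    amp <- sin(2 * pi * profile$frequency * time)
    env <- rep(1, length(time))
    n_blocks <- NA_integer_
  } else {
    env <- block_envelope(profile, time)
    sq <- ifelse(floor(2 * profile$flicker_hz * time) %% 2 == 0, 1, -1)
    amp <- env * sq
    n_blocks <- floor(profile$duration /
                        (profile$block_on + profile$block_off))
  }
  settings <- outer(amp, dp) + matrix(w0, nrow = length(time),
                                      ncol = length(w0), byrow = TRUE)
  list(time = time, settings = settings, envelope = env, n_blocks = n_blocks)
}

#' Monte-Carlo validation of a modulation under device imprecision
#'
#' Re-evaluates the realized photoreceptor contrasts of a designed
#' modulation under multiplicative perturbation of the primary outputs,
#' emulating measured imprecision in the spectral output of the device.
#'
#' @param modulation a `spectral_modulation`.
#' @param device the `device_model` it was designed on.
#' @param sensitivities receptor matrix.
#' @param primary_noise_sd SD of the per-primary multiplicative gain error
#'   (0 collapses the ensemble onto the nominal report).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @return List with `draws` (n_draws x pigments bipolar contrasts),
#'   `nominal` report, and `silenced_quantiles` of max |silenced contrast|.
#' @export
validate_modulation <- function(modulation, device, sensitivities,
                                primary_noise_sd = 0.01, n_draws = 200,
                                seed = 1) {
  if (primary_noise_sd < 0) stop("perturbation must be >= 0", call. = FALSE)
  set.seed(seed)
  npig <- ncol(sensitivities)
  draws <- matrix(NA_real_, n_draws, npig,
                  dimnames = list(NULL, colnames(sensitivities)))
  for (i in seq_len(n_draws)) {
    g <- 1 + stats::rnorm(device$n_primaries, 0, primary_noise_sd)
    dev_i <- device
    dev_i$primaries <- sweep(device$primaries, 2, g, `*`)
    rep_i <- contrast(device_spectrum(dev_i, modulation$pos_settings),
                      device_spectrum(dev_i, modulation$neg_settings),
                      device_spectrum(dev_i, modulation$background_settings),
                      sensitivities)
    draws[i, ] <- rep_i$bipolar
  }
  sil <- modulation$silenced
  q <- if (length(sil)) {
    stats::quantile(apply(abs(draws[, sil, drop = FALSE]), 1, max),
                    c(0.5, 0.75, 0.95, 1))
  } else {
    NULL
  }
  list(draws = draws, nominal = modulation$contrast_report,
       silenced_quantiles = q)
}
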