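#' Visual pigment template constants
#'
#' Constants of the A1 visual-pigment nomogram: a log-exponential-sum
#' alpha band plus a Gaussian beta band. The alpha band is
#' \deqn{S_\alpha(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda} and
#' \eqn{a = a_0 + a_1 \exp(-(\lambda_{max}-300)^2/11940)}; the beta band is
#' \eqn{S_\beta(\lambda) = A_\beta \exp(-((\lambda-\lambda_{m\beta})/b_\beta)^2)}
#' with \eqn{\lambda_{m\beta} = 189 + 0.315\,\lambda_{max}} and
#' \eqn{b_\beta = -40.5 + 0.195\,\lambda_{max}}.
#'
#' @return Named list of template constants. Pass a modified copy to
#'   [pigment_template()] to override individual constants.
#' @export
pigment_template_constants <- function() {
  list(
    A = 69.7, B = 28, C = -14.9, D = 0.674,
    b = 0.922, c = 1.104,
    a0 = 0.8795, a1 = 0.0459, a_center = 300, a_denom = 11940,
    beta_A = 0.26, beta_lm0 = 189, beta_lm1 = 0.315,
    beta_b0 = -40.5, beta_b1 = 0.195
  )
}

#' Canine photopigment set
#'
#' The four canine photopigments with their peak sensitivities: the L/M
#' ("L") cone at 555 nm, the S cone at 429 nm, rhodopsin at 506 nm and
#' melanopsin at 480 nm. Dogs are dichromats; melanopsin is treated as an
#' ordinary pigment (no intrinsic-response kinetics).
#'
#' @return Named numeric vector of lambda-max values in nm.
#' @export
canine_pigments <- function() {
  c(L = 555, S = 429, rod = 506, mel = 480)
}

#' Default wavelength grid
#'
#' 380-780 nm at 2 nm steps, the spectroradiometer convention used
#' throughout the package.
#'
#' @param from,to,by grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
wavelength_grid <- function(from = 380, to = 780, by = 2) {
  seq(from, to, by = by)
}

check_grid <- function(grid) {
  if (length(grid) < 2 || any(!is.finite(grid)) || any(diff(grid) <= 0)) {
    stop("wavelength grid must be finite and strictly increasing", call. = FALSE)
  }
  invisible(grid)
}

#' Evaluate a visual pigment spectral sensitivity template
#'
#' Evaluates the A1 nomogram (alpha plus beta band) for a pigment with the
#' given peak wavelength, peak-normalized to 1 on the grid.
#'
#' @param lambda_max peak wavelength in nm; must lie in (300, 700).
#' @param grid wavelengths (nm) at which to evaluate; strictly increasing.
#' @param constants template constants, see [pigment_template_constants()].
#' @return List with `wavelengths` and `values` (peak 1), class
#'   `spectral_sensitivity`.
#' @examples
#' s <- pigment_template(555)
#' s$values[s$wavelengths == 555]
#' @export
pigment_template <- function(lambda_max, grid = wavelength_grid(),
                             constants = pigment_template_constants()) {
  check_grid(grid)
  if (!is.finite(lambda_max) || lambda_max <= 300 || lambda_max >= 700) {
    stop("lambda_max outside template validity (300, 700) nm", call. = FALSE)
  }
  k <- constants
  x <- lambda_max / grid
  a <- k$a0 + k$a1 * exp(-(lambda_max - k$a_center)^2 / k$a_denom)
  alpha <- 1 / (exp(k$A * (a - x)) + exp(k$B * (k$b - x)) +
                  exp(k$C * (k$c - x)) + k$D)
  lm_beta <- k$beta_lm0 + k$beta_lm1 * lambda_max
  b_beta <- k$beta_b0 + k$beta_b1 * lambda_max
  beta <- k$beta_A * exp(-((grid - lm_beta) / b_beta)^2)
  v <- alpha + beta
  v <- v / max(v)
  structure(list(wavelengths = grid, values = v, lambda_max = lambda_max),
            class = "spectral_sensitivity")
}

#' Canine crystalline lens transmittance
#'
#' Parametric default lens model: unit transmittance in the long-wave
#' visible, with a sigmoidal short-wavelength cutoff
#' \eqn{T(\lambda) = 1/(1 + e^{-(\lambda - \lambda_{1/2})/s})}. A measured
#' curve can be supplied instead as a two-column table (see
#' [read_spectrum_csv()]).
#'
#' @param grid wavelengths in nm.
#' @param half_height_nm wavelength of 50% transmittance (default 400 nm).
#' @param slope_nm sigmoid slope scale (default 10 nm).
#' @return List with `wavelengths` and `transmittance` in [0, 1].
#' @export
lens_transmittance <- function(grid = wavelength_grid(), half_height_nm = 400,
                               slope_nm = 10) {
  check_grid(grid)
  t <- 1 / (1 + exp(-(grid - half_height_nm) / slope_nm))
  list(wavelengths = grid, transmittance = t)
}

resample_to <- function(x_from, y_from, x_to) {
  if (max(x_from) < min(x_to) || min(x_from) > max(x_to)) {
    stop("wavelength ranges do not overlap", call. = FALSE)
  }
  stats::approx(x_from, y_from, xout = x_to, rule = 2)$y
}

#' Apply pre-receptoral filtering to a spectral sensitivity
#'
#' Pointwise product of a pigment sensitivity with a transmittance curve
#' (e.g. the crystalline lens). The result is deliberately not
#' re-normalized: filtering changes the effective peak.
#'
#' @param sens a `spectral_sensitivity` (or list with `wavelengths`,
#'   `values`).
#' @param lens list with `wavelengths` and `transmittance`; resampled onto
#'   the sensitivity grid if needed.
#' @return Filtered `spectral_sensitivity` on the sensitivity grid.
#' @export
apply_prereceptoral_filter <- function(sens, lens) {
  tr <- if (identical(lens$wavelengths, sens$wavelengths)) {
    lens$transmittance
  } else {
    resample_to(lens$wavelengths, lens$transmittance, sens$wavelengths)
  }
  if (any(tr < -1e-12) || any(tr > 1 + 1e-12)) {
    stop("transmittance must lie in [0, 1]", call. = FALSE)
  }
  out <- sens
  out$values <- sens$values * tr
  out
}

#' Filtered canine receptor sensitivities
#'
#' Convenience constructor: evaluates the pigment template for each canine
#' pigment and applies the lens model, returning a wavelength-by-pigment
#' matrix used by the excitation and stimulus-design machinery.
#'
#' @param grid wavelength grid (nm).
#' @param pigments named lambda-max vector, default [canine_pigments()].
#' @param lens lens model, default [lens_transmittance()]; `NULL` skips
#'   pre-receptoral filtering.
#' @param constants template constants.
#' @return Matrix (length(grid) x n pigments) with pigment names as columns
#'   and a `wavelengths` attribute.
#' @export
receptor_sensitivities <- function(grid = wavelength_grid(),
                                   pigments = canine_pigments(),
                                   lens = lens_transmittance(grid),
                                   constants = pigment_template_constants()) {
  S <- vapply(pigments, function(lm) {
    s <- pigment_template(lm, grid, constants)
    if (!is.null(lens)) s <- apply_prereceptoral_filter(s, lens)
    s$values
  }, numeric(length(grid)))
  attr(S, "wavelengths") <- grid
  S
}

#' Photoreceptor excitations from a spectrum
#'
#' Inner-product receptor model: \eqn{e_p = \sum_\lambda S_p(\lambda)
#' \Phi(\lambda) \Delta\lambda} for each pigment, using the (filtered)
#' sensitivities.
#'
#' @param spectrum radiance values on the sensitivity grid (non-negative),
#'   or a list with `wavelengths` and `values`.
#' @param sensitivities matrix from [receptor_sensitivities()].
#' @return Named numeric vector of excitations (arbitrary linear units).
#' @export
excitation <- function(spectrum, sensitivities) {
  grid <- attr(sensitivities, "wavelengths")
  phi <- if (is.list(spectrum)) {
    resample_to(spectrum$wavelengths, spectrum$values, grid)
  } else {
    spectrum
  }
  if (length(phi) != nrow(sensitivities)) {
    stop("spectrum and sensitivities are on different grids", call. = FALSE)
  }
  if (any(phi < -1e-12)) stop("negative spectral power", call. = FALSE)
  dl <- mean(diff(grid))
  drop(crossprod(sensitivities, phi)) * dl
}

#' Photoreceptor contrasts of a bipolar modulation
#'
#' Bipolar Weber contrast per pigment,
#' \eqn{C_p = (e_p^{+} - e_p^{-}) / (2 e_p^{bg})}, for a modulation between
#' a stimulating and a suppressing spectrum around a common background. The
#' report also carries the unipolar contrasts of each arm against the
#' background, since either convention may be wanted.
#'
#' @param arm_pos,arm_neg,background spectra on the sensitivity grid.
#' @param sensitivities matrix from [receptor_sensitivities()].
#' @param targeted,silenced optional pigment label sets recorded in the
#'   report.
#' @return Object of class `contrast_report`: named `bipolar`,
#'   `unipolar_pos`, `unipolar_neg` contrast vectors plus label sets.
#' @export
contrast <- function(arm_pos, arm_neg, background, sensitivities,
                     targeted = character(), silenced = character()) {
  e_pos <- excitation(arm_pos, sensitivities)
  e_neg <- excitation(arm_neg, sensitivities)
  e_bg <- excitation(background, sensitivities)
  if (any(e_bg <= 0)) {
    stop("background excitation must be strictly positive for every pigment",
         call. = FALSE)
  }
  structure(list(
    bipolar = (e_pos - e_neg) / (2 * e_bg),
    unipolar_pos = (e_pos - e_bg) / e_bg,
    unipolar_neg = (e_neg - e_bg) / e_bg,
    targeted = targeted, silenced = silenced
  ), class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Photoreceptor contrast report\n")
  m <- rbind(bipolar = x$bipolar, `unipolar +arm` = x$unipolar_pos,
             `unipolar -arm` = x$unipolar_neg)
  print(round(m, 5))
  if (length(x$targeted)) cat("targeted:", paste(x$targeted, collapse = ", "), "\n")
  if (length(x$silenced)) cat("silenced:", paste(x$silenced, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a wavelength-indexed spectrum CSV
#'
#' Files carry a `wavelength_nm,value` header, one row per grid point.
#'
#' @param path file path.
#' @return List with `wavelengths` and `values`.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("expected columns wavelength_nm,value", call. = FALSE)
  }
  list(wavelengths = d$wavelength_nm, values = d$value)
}

#' @rdname read_spectrum_csv
#' @param spectrum list with `wavelengths` and `values`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelengths, value = spectrum$values),
    path, row.names = FALSE)
  invisible(path)
}
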