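#' Multiprimary device model
#'
#' A light-engine model mapping a settings vector \eqn{w \in [0,1]^n} to a
#' spectrum \eqn{\Phi(w) = \nu (P w + \Phi_0)}, where \eqn{P} holds the
#' primary spectral power distributions column-wise, \eqn{\Phi_0} is the
#' residual (dark) spectrum and \eqn{\nu} a scalar neutral-density factor.
#'
#' @param primaries wavelength x n_primaries matrix of non-negative SPDs.
#' @param wavelengths grid in nm (rows of `primaries`).
#' @param nd_factor scalar transmittance of neutral-density filtering.
#' @param dark_light residual spectrum at all-zero settings (default 0).
#' @return Object of class `device_model`.
#' @export
device_model <- function(primaries, wavelengths, nd_factor = 1,
                         dark_light = NULL) {
  primaries <- as.matrix(primaries)
  check_grid(wavelengths)
  if (nrow(primaries) != length(wavelengths)) {
    stop("primaries rows must match wavelength grid", call. = FALSE)
  }
  if (any(primaries < 0)) stop("primaries must be non-negative", call. = FALSE)
  if (is.null(dark_light)) dark_light <- numeric(length(wavelengths))
  structure(list(primaries = primaries, wavelengths = wavelengths,
                 nd_factor = nd_factor, dark_light = dark_light,
                 n_primaries = ncol(primaries)),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf("Multiprimary device: %d primaries on %g-%g nm, ND factor %g\n",
              x$n_primaries, min(x$wavelengths), max(x$wavelengths),
              x$nd_factor))
  invisible(x)
}

#' Spectrum produced by a settings vector
#'
#' @param device a `device_model`.
#' @param settings numeric vector in [0,1] per primary.
#' @return Radiance vector on the device wavelength grid.
#' @export
device_spectrum <- function(device, settings) {
  if (length(settings) != device$n_primaries) {
    stop("settings length must equal number of primaries", call. = FALSE)
  }
  if (any(settings < -1e-9) || any(settings > 1 + 1e-9)) {
    stop("settings outside device gamut [0, 1]", call. = FALSE)
  }
  device$nd_factor * (drop(device$primaries %*% settings) + device$dark_light)
}

#' Synthesize a Gaussian-primary light engine
#'
#' Default synthetic stand-in for a digital light synthesis engine: Gaussian
#' primaries with equally spaced centers spanning 400-700 nm, equal peak
#' power and a common full width at half maximum. Deterministic; the seed is
#' recorded for provenance of any downstream stochastic use.
#'
#' @param n_primaries number of primaries (>= 3; default 56).
#' @param fwhm_nm full width at half maximum of each primary (default 16).
#' @param grid wavelength grid in nm.
#' @param seed integer recorded on the device.
#' @param nd_factor scalar neutral-density transmittance.
#' @return A `device_model`.
#' @export
synth_device <- function(n_primaries = 56, fwhm_nm = 16,
                         grid = wavelength_grid(), seed = 1, nd_factor = 1) {
  if (n_primaries < 3) stop("need at least 3 primaries", call. = FALSE)
  centers <- seq(400, 700, length.out = n_primaries)
  sd_nm <- fwhm_nm / (2 * sqrt(2 * log(2)))
  P <- vapply(centers, function(mu) exp(-(grid - mu)^2 / (2 * sd_nm^2)),
              numeric(length(grid)))
  dev <- device_model(P, grid, nd_factor = nd_factor)
  dev$seed <- seed
  dev$centers <- centers
  dev
}

#' Read a device primary matrix from CSV
#'
#' Expects a `wavelength_nm` column followed by one column per primary.
#'
#' @param path CSV path.
#' @param nd_factor,dark_light see [device_model()].
#' @return A `device_model`.
#' @export
read_device_csv <- function(path, nd_factor = 1, dark_light = NULL) {
  d <- utils::read.csv(path)
  if (names(d)[1] != "wavelength_nm") {
    stop("first column must be wavelength_nm", call. = FALSE)
  }
  device_model(as.matrix(d[, -1, drop = FALSE]), d$wavelength_nm,
               nd_factor = nd_factor, dark_light = dark_light)
}

#' Luminance of a spectrum under a supplied luminosity function
#'
#' Metadata helper: integrates a spectrum against a photopic luminosity
#' table. Reported for bookkeeping only; contrast calculations are
#' luminance-free.
#'
#' @param spectrum list with `wavelengths` and `values`, or a radiance
#'   vector on `grid`.
#' @param luminosity list with `wavelengths` and `values` (e.g. V(lambda)).
#' @param grid grid for a bare-vector spectrum.
#' @param km luminous efficacy scaling (default 683 lm/W).
#' @return Scalar luminance in the units implied by the inputs.
#' @export
spectrum_luminance <- function(spectrum, luminosity, grid = wavelength_grid(),
                               km = 683) {
  if (is.list(spectrum)) {
    grid <- spectrum$wavelengths
    spectrum <- spectrum$values
  }
  v <- resample_to(luminosity$wavelengths, luminosity$values, grid)
  km * sum(spectrum * v) * mean(diff(grid))
}
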