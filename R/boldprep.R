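#' BOLD acquisition container
#'
#' Wraps a 4-D (x, y, z, t) signal array with its repetition time and
#' protocol metadata. RAS+ orientation is assumed; the sagittal midline is
#' taken at the x-dimension midpoint unless overridden.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param tr repetition time in s (default 3).
#' @param acquisition_id,eye,stimulus_label optional metadata (`eye` is
#'   "left"/"right"; `stimulus_label` e.g. "lightflux", "LS", "LminusS").
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(data, tr = 3, acquisition_id = NULL, eye = NULL,
                        stimulus_label = NULL) {
  d <- dim(data)
  if (length(d) != 4 || d[4] < 2) stop("need a 4-D array with t >= 2",
                                       call. = FALSE)
  if (!all(is.finite(data))) stop("non-finite voxel values", call. = FALSE)
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  structure(list(data = data, tr = tr, dim = d,
                 acquisition_id = acquisition_id, eye = eye,
                 stimulus_label = stimulus_label),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series %dx%dx%d, %d TRs at TR = %gs", x$dim[1],
              x$dim[2], x$dim[3], x$dim[4], x$tr))
  if (!is.null(x$stimulus_label)) cat(", stimulus", x$stimulus_label)
  if (!is.null(x$eye)) cat(",", x$eye, "eye")
  cat("\n")
  invisible(x)
}

as_voxel_matrix <- function(series) {
  d <- series$dim
  matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
}

from_voxel_matrix <- function(series, m) {
  series$data <- array(m, dim = series$dim)
  series
}

#' Remove the per-voxel linear trend
#'
#' Least-squares line removed from each voxel time series; the voxel mean
#' is preserved (only the centered-time slope component is subtracted).
#'
#' @param series a `bold_series`.
#' @return Detrended `bold_series`.
#' @export
linear_detrend <- function(series) {
  nt <- series$dim[4]
  if (nt < 3) stop("need at least 3 time points", call. = FALSE)
  Y <- as_voxel_matrix(series)
  tc <- seq_len(nt) - (nt + 1) / 2
  slope <- (Y %*% tc) / sum(tc^2)
  from_voxel_matrix(series, Y - tcrossprod(slope, tc))
}

raw_mad <- function(x, center = stats::median(x)) {
  stats::median(abs(x - center))
}

#' Detect transient signal spikes with a two-stage MAD rule
#'
#' Stage 1: a voxel sample is an outlier when it lies at least
#' `voxel_k` median absolute deviations above that voxel's temporal median
#' (raw MAD, no normality scaling; one-sided by default, matching the
#' upward-going artifact this targets). Stage 2: the per-TR count of
#' outlier voxels is itself screened, and a TR is flagged when its count is
#' at least `tr_k` MAD above the median count. One indicator confound
#' column is produced per flagged TR. The count MAD is floored at one
#' count (the counter's resolution), so a constant count vector yields no
#' flags and near-null data is not over-flagged.
#'
#' @param series a detrended `bold_series`.
#' @param voxel_k voxel-level MAD multiplier (default 6).
#' @param tr_k TR-level MAD multiplier (default 25).
#' @param two_sided flag downward deviations as well (default FALSE).
#' @param mask logical/index vector of voxels to consider (default: voxels
#'   with non-zero temporal variance).
#' @return List of class `spike_events`: `flagged` (TR indices),
#'   `counts` (outlier voxels per TR), `confounds` (t x n_flagged 0/1
#'   matrix), `voxel_k`, `tr_k`.
#' @export
detect_spikes <- function(series, voxel_k = 6, tr_k = 25, two_sided = FALSE,
                          mask = NULL) {
  Y <- as_voxel_matrix(series)
  if (is.null(mask)) {
    v <- apply(Y, 1, stats::var)
    mask <- v > 0
  }
  Ym <- Y[mask, , drop = FALSE]
  med <- apply(Ym, 1, stats::median)
  dev <- Ym - med
  madv <- apply(abs(dev), 1, stats::median)
  out <- dev >= voxel_k * madv
  if (two_sided) out <- out | (dev <= -voxel_k * madv)
  counts <- colSums(out)
  med_c <- stats::median(counts)
  mad_c <- raw_mad(counts, med_c)
  # dispersion floor of one count (the counter's resolution) so that a
  # mostly-quiet count vector (MAD = 0) neither flags everything nor an
  # all-equal vector anything
  flagged <- which(counts >= med_c + tr_k * max(mad_c, 1) &
                     counts > med_c)
  nt <- series$dim[4]
  conf <- matrix(0, nt, length(flagged))
  if (length(flagged)) {
    conf[cbind(flagged, seq_along(flagged))] <- 1
    colnames(conf) <- paste0("spike_", flagged)
  }
  structure(list(flagged = flagged, counts = counts, confounds = conf,
                 voxel_k = voxel_k, tr_k = tr_k),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("Spike detection (voxel %g MAD, TR %g MAD): %d TR(s) flagged",
              x$voxel_k, x$tr_k, length(x$flagged)))
  if (length(x$flagged)) cat(":", paste(x$flagged, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Build motion confound regressors
#'
#' Expands 6 rigid-body motion parameters into 24 regressors (originals,
#' backward-difference temporal derivatives with a zero first row, and the
#' squares of both), centers them, and reduces them by principal components
#' analysis to the smallest leading set explaining at least
#' `variance_target` of the variance.
#'
#' @param motion t x 6 matrix or data frame (3 translations, 3 rotations).
#' @param variance_target cumulative variance fraction to retain
#'   (default 0.95).
#' @return List of class `confound_matrix`: `regressors` (t x k principal
#'   component columns `pc1..pck`), `variance_explained`, `raw24`.
#' @export
motion_confounds <- function(motion, variance_target = 0.95) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6) stop("need 6 motion parameter columns",
                             call. = FALSE)
  motion <- motion[, 1:6, drop = FALSE]
  deriv <- rbind(0, diff(motion))
  X24 <- cbind(motion, deriv, motion^2, deriv^2)
  colnames(X24) <- c(paste0("p", 1:6), paste0("d", 1:6),
                     paste0("p", 1:6, "sq"), paste0("d", 1:6, "sq"))
  Xc <- scale(X24, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2, function(x) any(x != 0))
  if (!any(keep)) {
    warning("zero motion: no confound components retained")
    return(structure(list(regressors = matrix(0, nrow(X24), 0),
                          variance_explained = NA_real_, raw24 = X24),
                     class = "confound_matrix"))
  }
  pc <- stats::prcomp(Xc[, keep, drop = FALSE], center = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= variance_target)[1]
  reg <- pc$x[, seq_len(k), drop = FALSE]
  colnames(reg) <- paste0("pc", seq_len(k))
  structure(list(regressors = reg, variance_explained = cum[k],
                 raw24 = X24),
            class = "confound_matrix")
}

#' Regress confounds from every voxel
#'
#' Per-voxel ordinary least squares on the confound matrix (plus an
#' intercept); residuals are returned with the voxel mean restored.
#' Rank-deficient confound columns are dropped with a warning.
#'
#' Note for downstream model fitting: after this sequential removal the
#' task regressors must be residualized against the same confound set
#' (Frisch-Waugh), which [fit_forward_model()] does via its `confounds`
#' argument; otherwise chance task-confound overlap biases amplitudes
#' downward.
#'
#' @param series a `bold_series`.
#' @param confounds a `confound_matrix`, numeric matrix, or a list of
#'   either/`spike_events` whose columns are bound together.
#' @return Cleaned `bold_series`.
#' @export
regress_confounds <- function(series, confounds) {
  X <- confound_columns(confounds)
  nt <- series$dim[4]
  if (nrow(X) != nt) stop("confound rows must match time points",
                          call. = FALSE)
  if (ncol(X) == 0) return(series)
  Xf <- cbind(1, X)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    warning(sprintf("dropping %d rank-deficient confound column(s)",
                    ncol(Xf) - qrX$rank))
  }
  Y <- as_voxel_matrix(series)
  mu <- rowMeans(Y)
  res <- t(qr.resid(qrX, t(Y)))
  from_voxel_matrix(series, res + mu)
}

confound_columns <- function(confounds) {
  one <- function(x) {
    if (inherits(x, "confound_matrix")) x$regressors
    else if (inherits(x, "spike_events")) x$confounds
    else as.matrix(x)
  }
  if (is.list(confounds) && !inherits(confounds, c("confound_matrix",
                                                   "spike_events"))) {
    do.call(cbind, lapply(confounds, one))
  } else {
    one(confounds)
  }
}

#' Write a confound matrix to CSV
#'
#' One column per regressor, header `pc1..pcK,spike_<tr>`.
#'
#' @param confounds anything accepted by [regress_confounds()].
#' @param path output path.
#' @export
write_confounds_csv <- function(confounds, path) {
  X <- confound_columns(confounds)
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}

#' Average a volume with its sagittal mirror image
#'
#' Voxel-wise \eqn{(v + \mathrm{flip}_x(v))/2}, symmetrizing left and right
#' hemispheres about the x midpoint of the (template-space) volume. Exactly
#' mirror-symmetric output; idempotent.
#'
#' @param x a `bold_series`, 4-D array, or 3-D array/map.
#' @param axis mirrored axis (default 1, the x dimension).
#' @return Same type as the input, symmetrized.
#' @export
mirror_average <- function(x, axis = 1) {
  if (inherits(x, "bold_series")) {
    x$data <- mirror_average(x$data, axis)
    return(x)
  }
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- rev(seq_len(d[axis]))
  flipped <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  array((x + flipped) / 2, dim = d)
}
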