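#' Fit an ellipse to pupil border points with iterative trimming
#'
#' Direct least-squares conic fit (numerically stabilised scatter-matrix
#' decomposition) to candidate pupil-boundary points, followed by iterative
#' removal of poorly-fit points: fit, drop points whose approximate
#' geometric residual exceeds `residual_threshold_px`, refit, until the
#' surviving set is stable or `max_iter` is reached. This rejects border
#' imperfections such as eyelash occlusions or the first Purkinje reflex.
#'
#' @param x,y border point coordinates in pixels (or `x` a two-column
#'   matrix).
#' @param max_iter maximum trimming iterations (default 10).
#' @param residual_threshold_px residual beyond which a point is dropped
#'   (default 2 px); also the rmse bound of the quality flag.
#' @return Object of class `ellipse_fit`: center (`cx`,`cy`), semi-axes
#'   (`a` >= `b`), `orientation` (rad), `area` (px^2, pi*a*b), `rmse`,
#'   `n_used`, `quality` ("good"/"poor").
#' @export
fit_ellipse <- function(x, y = NULL, max_iter = 10,
                        residual_threshold_px = 2) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  # robust prefilter: gross outliers (eyelash clusters, glints) lie at
  # radial distances far from the bulk of the border
  r <- sqrt((x - stats::median(x))^2 + (y - stats::median(y))^2)
  mad_r <- stats::median(abs(r - stats::median(r)))
  keep <- abs(r - stats::median(r)) <=
    max(4 * mad_r, 2 * residual_threshold_px)
  if (sum(keep) < 5) keep <- rep(TRUE, length(x))
  fit <- NULL
  for (it in seq_len(max_iter)) {
    if (sum(keep) < 5) break
    fit <- ellipse_direct_fit(x[keep], y[keep])
    res <- ellipse_residuals(fit, x[keep], y[keep])
    bad <- res > residual_threshold_px
    if (!any(bad)) break
    # progressive trimming: shed at most the worst 10% per refit, so a
    # fit distorted by gross outliers cannot discard the inliers
    ndrop <- min(sum(bad), max(1, ceiling(0.1 * sum(keep))))
    worst <- order(res, decreasing = TRUE)[seq_len(ndrop)]
    if (sum(keep) - ndrop < 5) break
    keep[which(keep)[worst]] <- FALSE
  }
  if (is.null(fit)) stop("fewer than 5 usable border points", call. = FALSE)
  rmse <- sqrt(mean(ellipse_residuals(fit, x[keep], y[keep])^2))
  quality <- if (sum(keep) < 5 || rmse > residual_threshold_px) "poor"
             else "good"
  structure(c(fit, list(rmse = rmse, n_used = sum(keep), used = keep,
                        quality = quality)),
            class = "ellipse_fit")
}

# Stabilised direct least-squares conic ellipse fit.
ellipse_direct_fit <- function(x, y) {
  if (length(x) < 5) stop("fewer than 5 usable border points", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-9)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("degenerate border point configuration",
                              call. = FALSE)
  T_ <- -solve(S3, t(S2))
  Mmat <- S1 + S2 %*% T_
  Mmat <- rbind(Mmat[3, ] / 2, -Mmat[2, ], Mmat[1, ] / 2)
  ev <- eigen(Mmat)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("points do not determine an ellipse", call. = FALSE)
  a1 <- evec[, ok[1]]
  coef <- c(a1, drop(T_ %*% a1))      # A B C D E F in scaled frame
  # un-scale: conic in original coordinates
  A <- coef[1] / sc^2
  B <- coef[2] / sc^2
  C <- coef[3] / sc^2
  D <- coef[4] / sc - 2 * A * mx - B * my
  E <- coef[5] / sc - 2 * C * my - B * mx
  F_ <- coef[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef[4] * mx / sc - coef[5] * my / sc
  conic_to_ellipse(c(A, B, C, D, E, F_))
}

conic_to_ellipse <- function(k) {
  k <- unname(k)
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F_ <- k[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("conic is not an ellipse", call. = FALSE)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # conic value at the center; centered form is A u^2 + B uv + C v^2 = -q0
  q0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F_
  mu <- -q0
  Q <- matrix(c(A, B / 2, B / 2, C), 2) / mu
  e <- eigen(Q, symmetric = TRUE)
  if (any(e$values <= 0)) stop("conic is not an ellipse", call. = FALSE)
  ax <- 1 / sqrt(e$values)            # decreasing eigenvalues -> ax[1] <= ax[2]
  a <- max(ax); b <- min(ax)
  v <- e$vectors[, which.min(e$values)]
  list(cx = cx, cy = cy, a = a, b = b,
       orientation = atan2(v[2], v[1]) %% pi,
       area = pi * a * b, conic = k)
}

# Approximate geometric distance of points to a fitted ellipse (radial).
ellipse_residuals <- function(fit, x, y) {
  dx <- x - fit$cx; dy <- y - fit$cy
  th <- atan2(dy, dx) - fit$orientation
  r_pt <- sqrt(dx^2 + dy^2)
  r_el <- fit$a * fit$b /
    sqrt((fit$b * cos(th))^2 + (fit$a * sin(th))^2)
  abs(r_pt - r_el)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(paste0("Ellipse fit: center (%.2f, %.2f), semi-axes ",
                     "%.2f x %.2f px, area %.1f px^2\n"),
              x$cx, x$cy, x$a, x$b, x$area))
  cat(sprintf("  rmse %.3f px on %d points [%s]\n", x$rmse, x$n_used,
              x$quality))
  invisible(x)
}

#' Acquisition-level quality control
#'
#' An acquisition is excluded when more than 50% of its video frames carry
#' a poor pupil fit (strict inequality: exactly half poor is retained).
#'
#' @param quality per-frame quality flags ("good"/"poor"), or a list of
#'   `ellipse_fit` objects.
#' @return List with `include` (logical) and `fraction_poor`.
#' @export
qc_acquisition <- function(quality) {
  if (is.list(quality) && inherits(quality[[1]], "ellipse_fit")) {
    quality <- vapply(quality, `[[`, "", "quality")
  }
  if (!length(quality)) stop("empty acquisition", call. = FALSE)
  frac <- mean(quality == "poor")
  list(include = frac <= 0.5, fraction_poor = frac)
}

#' Percent-change pupil area time series
#'
#' Expresses ellipse area over time as percentage change relative to the
#' acquisition mean over valid frames; the result re-means to zero on the
#' valid frames.
#'
#' @param time frame timestamps in s.
#' @param area pupil area in px^2.
#' @param valid per-frame validity mask (default all valid).
#' @return Object of class `pupil_timeseries` with `time`,
#'   `area_pct_change`, `valid`.
#' @export
pupil_timeseries <- function(time, area, valid = rep(TRUE, length(area))) {
  stopifnot(length(time) == length(area), length(valid) == length(area))
  m <- mean(area[valid])
  pct <- 100 * (area - m) / m
  structure(list(time = time, area_pct_change = pct, valid = valid),
            class = "pupil_timeseries")
}

#' Fit a sinusoidal pupil response at the stimulation frequency
#'
#' Linear regression of the percent-change area series on an intercept and
#' a sine and cosine at the stimulation frequency (default 1/6 Hz),
#' restricted to valid frames. Amplitude is
#' \eqn{\sqrt{\beta_{sin}^2 + \beta_{cos}^2}} (peak % area change) and
#' phase is \eqn{\mathrm{atan2}(\beta_{cos}, \beta_{sin})} in (-pi, pi].
#'
#' @param series a `pupil_timeseries`, or anything accepted by
#'   [pupil_timeseries()] wrapped in a list.
#' @param frequency stimulation frequency in Hz (default 1/6).
#' @return Object of class `pupil_fit` with `amplitude`, `phase`,
#'   `beta_sin`, `beta_cos`, `frequency`, `n_valid`, residual `sigma`.
#' @export
fit_sinusoid <- function(series, frequency = 1 / 6) {
  t <- series$time[series$valid]
  yv <- series$area_pct_change[series$valid]
  if (length(t) < 8 || diff(range(t)) < 2 / frequency) {
    stop("need at least two full cycles of valid data", call. = FALSE)
  }
  X <- cbind(1, sin(2 * pi * frequency * t), cos(2 * pi * frequency * t))
  b <- stats::lm.fit(X, yv)
  co <- unname(b$coefficients)
  structure(list(amplitude = sqrt(co[2]^2 + co[3]^2),
                 phase = atan2(co[3], co[2]),
                 beta_sin = co[2], beta_cos = co[3],
                 intercept = co[1],
                 frequency = frequency, n_valid = length(t),
                 sigma = sqrt(sum(b$residuals^2) /
                                max(1, length(t) - 3))),
            class = "pupil_fit")
}

#' @export
print.pupil_fit <- function(x, ...) {
  cat(sprintf(paste0("Pupil response at %.4f Hz: amplitude %.3f%% area ",
                     "change, phase %.3f rad"), x$frequency, x$amplitude,
              x$phase))
  if (!is.null(x$sem_amplitude)) {
    cat(sprintf(" (SEM %.3f%%, %.3f rad; n = %d acquisitions)",
                x$sem_amplitude, x$sem_phase, x$n_acq))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.pupil_fit <- function(object, ...) {
  c(amplitude = unname(object$amplitude), phase = unname(object$phase))
}

# All multisets of size n drawn from 1..n (combinations with replacement);
# count is choose(2n-1, n).
multiset_resamples <- function(n) {
  cmb <- utils::combn(2 * n - 1, n)
  cmb - (seq_len(n) - 1L)
}

circular_sd <- function(theta) {
  mu <- atan2(mean(sin(theta)), mean(cos(theta)))
  d <- atan2(sin(theta - mu), cos(theta - mu))
  stats::sd(d)
}

#' Exhaustive bootstrap SEM of the pupil response
#'
#' Enumerates every multiset of the condition's acquisitions sampled with
#' replacement (35 for four acquisitions), frame-wise averages each
#' resampled set, refits the sinusoid, and reports the standard deviation
#' of the resulting amplitudes (and, circularly, phases) as the SEM. The
#' point estimate comes from the unresampled average.
#'
#' @param series_list list of `pupil_timeseries`, one per acquisition,
#'   on a common time base.
#' @param frequency stimulation frequency in Hz.
#' @return A `pupil_fit` augmented with `sem_amplitude`, `sem_phase`,
#'   `n_acq`, `n_resamples`.
#' @export
bootstrap_sem <- function(series_list, frequency = 1 / 6) {
  n <- length(series_list)
  if (n < 2) stop("need at least two acquisitions", call. = FALSE)
  len <- vapply(series_list, function(s) length(s$area_pct_change), 0L)
  if (length(unique(len)) != 1) {
    stop("acquisition series lengths differ", call. = FALSE)
  }
  tm <- series_list[[1]]$time
  Y <- vapply(series_list, function(s) {
    y <- s$area_pct_change
    y[!s$valid] <- NA_real_
    y
  }, numeric(len[1]))

  avg_series <- function(idx) {
    y <- rowMeans(Y[, idx, drop = FALSE], na.rm = TRUE)
    valid <- is.finite(y)
    y <- y - mean(y[valid])           # re-mean to zero after masking
    structure(list(time = tm, area_pct_change = y, valid = valid),
              class = "pupil_timeseries")
  }

  point <- fit_sinusoid(avg_series(seq_len(n)), frequency)
  idx <- multiset_resamples(n)
  amps <- numeric(ncol(idx)); phis <- numeric(ncol(idx))
  for (j in seq_len(ncol(idx))) {
    f <- fit_sinusoid(avg_series(idx[, j]), frequency)
    amps[j] <- f$amplitude
    phis[j] <- f$phase
  }
  point$sem_amplitude <- stats::sd(amps)
  point$sem_phase <- circular_sd(phis)
  point$n_acq <- n
  point$n_resamples <- ncol(idx)
  point$resample_amplitudes <- amps
  point
}
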