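# Batch solve of symmetric k x k systems A_v w_v = b_v, columns of A9
# holding vec(A_v). Closed-form adjugate for k = 3 (the hot path).
solve_sym_batch <- function(A9, B, k) {
  if (k == 3) {
    a11 <- A9[1, ]; a21 <- A9[2, ]; a31 <- A9[3, ]
    a22 <- A9[5, ]; a32 <- A9[6, ]; a33 <- A9[9, ]
    c11 <- a22 * a33 - a32 * a32
    c12 <- a32 * a31 - a21 * a33
    c13 <- a21 * a32 - a22 * a31
    det <- a11 * c11 + a21 * c12 + a31 * c13
    det[abs(det) < 1e-300] <- NA_real_
    b1 <- B[1, ]; b2 <- B[2, ]; b3 <- B[3, ]
    c22 <- a11 * a33 - a31 * a31
    c23 <- a21 * a31 - a11 * a32
    c33 <- a11 * a22 - a21 * a21
    rbind((c11 * b1 + c12 * b2 + c13 * b3) / det,
          (c12 * b1 + c22 * b2 + c23 * b3) / det,
          (c13 * b1 + c23 * b2 + c33 * b3) / det)
  } else {
    out <- matrix(NA_real_, k, ncol(A9))
    for (v in seq_len(ncol(A9))) {
      A <- matrix(A9[, v], k, k)
      w <- try(solve(A, B[, v]), silent = TRUE)
      if (!inherits(w, "try-error")) out[, v] <- w
    }
    out
  }
}

#' Blocked stimulus protocol
#'
#' The blocked-flicker fMRI protocol: 12 s stimulation alternating with
#' 12 s of steady background over a 432 s acquisition at TR 3 s, with 6
#' acquisitions per stimulus concatenated for fitting.
#'
#' @param tr repetition time in s.
#' @param duration acquisition duration in s.
#' @param block_on,block_off block durations in s.
#' @param n_acq acquisitions concatenated per stimulus.
#' @param onset time of the first block onset in s.
#' @return Object of class `bold_protocol` (includes `n_tr` and the block
#'   onset times).
#' @export
bold_protocol <- function(tr = 3, duration = 432, block_on = 12,
                          block_off = 12, n_acq = 6, onset = 0) {
  n_tr <- duration / tr
  if (abs(n_tr - round(n_tr)) > 1e-9) {
    stop("duration must be a multiple of TR", call. = FALSE)
  }
  cyc <- block_on + block_off
  onsets <- onset + cyc * seq_len(max(0, floor((duration - onset) / cyc))) -
    cyc
  structure(list(tr = tr, duration = duration, block_on = block_on,
                 block_off = block_off, n_acq = n_acq,
                 n_tr = as.integer(round(n_tr)),
                 onsets = onsets, n_blocks = length(onsets)),
            class = "bold_protocol")
}

#' Hemodynamic response basis set
#'
#' Three-component basis sampled at TR-subdivided resolution: a canonical
#' double-gamma kernel, its temporal derivative, and its dispersion
#' derivative, each unit-norm. The fitted kernel is the weighted
#' combination, peak-normalized so that per-acquisition response
#' amplitudes are identifiable. A custom basis can be supplied as a CSV
#' (one column per component) via [read_hrf_basis_csv()].
#'
#' @param tr repetition time in s.
#' @param oversample temporal subdivisions per TR (default 10).
#' @param duration kernel support in s (default 30).
#' @return Object of class `hrf_basis`: `basis` (L x 3 matrix), `dt`,
#'   `time`, `oversample`.
#' @export
hrf_basis <- function(tr = 3, oversample = 10, duration = 30) {
  dt <- tr / oversample
  t <- seq(0, duration - dt, by = dt)
  gam <- function(disp) {
    stats::dgamma(t, shape = 6, scale = disp) -
      stats::dgamma(t, shape = 16, scale = 1) / 6
  }
  h1 <- gam(1)
  h2 <- c(0, diff(h1)) / dt
  h3 <- (h1 - gam(1.01)) / 0.01
  B <- cbind(h1 / sqrt(sum(h1^2)), h2 / sqrt(sum(h2^2)),
             h3 / sqrt(sum(h3^2)))
  colnames(B) <- c("canonical", "temporal_deriv", "dispersion_deriv")
  structure(list(basis = B, dt = dt, time = t, oversample = oversample,
                 tr = tr),
            class = "hrf_basis")
}

#' @rdname hrf_basis
#' @param path CSV with one column per basis component.
#' @export
read_hrf_basis_csv <- function(path, tr = 3, oversample = 10) {
  B <- as.matrix(utils::read.csv(path))
  B <- sweep(B, 2, sqrt(colSums(B^2)), `/`)
  dt <- tr / oversample
  structure(list(basis = B, dt = dt,
                 time = seq(0, by = dt, length.out = nrow(B)),
                 oversample = oversample, tr = tr),
            class = "hrf_basis")
}

#' Kernel implied by a weight vector
#'
#' @param basis an `hrf_basis`.
#' @param weights numeric weights, one per basis component.
#' @param normalize peak-normalize so the dominant extremum is +1/-1.
#' @return Kernel sampled on the basis time grid.
#' @export
hrf_kernel <- function(basis, weights, normalize = TRUE) {
  k <- drop(basis$basis %*% weights)
  if (normalize) {
    s <- k[which.max(abs(k))]
    if (abs(s) > 0) k <- k / abs(s)
  }
  k
}

#' Square-wave block regressor
#'
#' Unit-height boxcar representation of the stimulation blocks for one
#' acquisition, built on the TR-subdivided grid (for convolution with the
#' hemodynamic kernel) and sampled back at TR resolution. Block timing not
#' aligned to the TR grid is handled by area-weighted sampling of the
#' oversampled regressor, with a warning.
#'
#' @param protocol a `bold_protocol`.
#' @param basis an `hrf_basis` (supplies the oversampled grid); when
#'   `NULL` the raw boxcar is returned without convolution.
#' @param center subtract the mean from each regressor column
#'   (default TRUE, matching per-acquisition mean removal of the data).
#' @return List: `regressors` (n_tr x 3 convolved basis regressors, or
#'   n_tr x 1 boxcar when `basis` is NULL), `boxcar_tr` (TR-resolution
#'   boxcar), `boxcar_over`.
#' @export
build_design <- function(protocol, basis = NULL, center = TRUE) {
  os <- if (is.null(basis)) 10L else basis$oversample
  dt <- protocol$tr / os
  tt <- seq(0, protocol$duration - dt, by = dt)
  cyc <- protocol$block_on + protocol$block_off
  box <- as.numeric(((tt - protocol$onsets[1]) %% cyc) < protocol$block_on &
                      tt >= protocol$onsets[1])
  if (abs(protocol$block_on / protocol$tr -
            round(protocol$block_on / protocol$tr)) > 1e-9) {
    warning("block duration is not TR-aligned; using area-weighted sampling")
  }
  # TR-resolution sample = mean over each TR bin (area-weighted)
  bin <- rep(seq_len(protocol$n_tr), each = os)
  box_tr <- as.numeric(tapply(box, bin, mean))
  if (is.null(basis)) {
    return(list(regressors = matrix(box_tr, ncol = 1), boxcar_tr = box_tr,
                boxcar_over = box))
  }
  G <- vapply(seq_len(ncol(basis$basis)), function(i) {
    conv <- stats::convolve(box, rev(basis$basis[, i]),
                            type = "open")[seq_along(box)] * basis$dt
    as.numeric(tapply(conv, bin, mean))
  }, numeric(protocol$n_tr))
  colnames(G) <- colnames(basis$basis)
  if (center) G <- scale(G, center = TRUE, scale = FALSE)
  list(regressors = G, boxcar_tr = box_tr, boxcar_over = box)
}

percent_signal_change <- function(Y) {
  mu <- rowMeans(Y)
  mu[mu == 0] <- 1
  100 * (Y - mu) / mu
}

#' Fit the nonlinear BOLD forward model
#'
#' Jointly estimates, per voxel, three hemodynamic kernel weights shared
#' across acquisitions and one response amplitude (beta, in % signal
#' change) per acquisition, minimizing the L2 norm of a square-wave block
#' regressor convolved with the weighted kernel against the concatenated
#' data. Convolution is performed per acquisition, so no response bleeds
#' across acquisition boundaries.
#'
#' Because the model is bilinear in (weights, betas), the search alternates
#' exact least-squares updates of each given the other, with the kernel
#' peak renormalized to 1 every iteration to resolve the beta-kernel scale
#' degeneracy; this is deterministic and converges to the stationary point
#' of the L2 objective.
#'
#' @param acquisitions list of `bold_series` (one per acquisition, common
#'   dimensions), or a single vox x time matrix already in % signal change.
#' @param protocol a `bold_protocol` (its `n_acq` must match).
#' @param basis an `hrf_basis`.
#' @param percent convert each acquisition to % signal change about the
#'   voxel's acquisition mean (default TRUE; set FALSE if already done).
#' @param confounds optional per-acquisition confound columns (list, one
#'   element per acquisition; matrices, `confound_matrix` or
#'   `spike_events`). The task regressors are residualized against these
#'   (Frisch-Waugh), so amplitude estimates are unbiased when the same
#'   columns were regressed from the data by [regress_confounds()].
#' @param mask logical vector/array of voxels to fit (default: non-zero
#'   temporal variance).
#' @param tol relative SSE convergence tolerance (default 1e-8).
#' @param max_iter maximum alternations (default 200).
#' @return Object of class `bold_fit`: `betas` (n_acq x n_voxel),
#'   `mean_beta`, `weights` (3 x n_voxel), `r2` (raw, can be negative for
#'   unmodellable voxels), `dim`, `mask`, `converged`, `protocol`, `basis`.
#' @export
fit_forward_model <- function(acquisitions, protocol, basis = hrf_basis(protocol$tr),
                              percent = TRUE, confounds = NULL, mask = NULL,
                              tol = 1e-8, max_iter = 200) {
  if (is.list(acquisitions) && inherits(acquisitions[[1]], "bold_series")) {
    dims <- acquisitions[[1]]$dim
    Ys <- lapply(acquisitions, function(a) {
      Y <- as_voxel_matrix(a)
      if (percent) Y <- percent_signal_change(Y)
      Y
    })
  } else {
    Y <- as.matrix(acquisitions)
    n_tr <- protocol$n_tr
    if (ncol(Y) != n_tr * protocol$n_acq) {
      stop("matrix columns must equal n_tr * n_acq", call. = FALSE)
    }
    dims <- c(nrow(Y), 1, 1, ncol(Y))
    Ys <- lapply(seq_len(protocol$n_acq), function(a) {
      Y[, (a - 1) * n_tr + seq_len(n_tr), drop = FALSE]
    })
  }
  n_acq <- length(Ys)
  if (n_acq != protocol$n_acq) {
    stop("number of acquisitions does not match protocol n_acq",
         call. = FALSE)
  }
  nv <- nrow(Ys[[1]])

  # center each acquisition (per-acquisition intercept absorbed)
  Ys <- lapply(Ys, function(Y) Y - rowMeans(Y))
  if (is.null(mask)) {
    v <- Reduce(`+`, lapply(Ys, function(Y) rowSums(Y^2)))
    mask_vec <- v > 0
  } else {
    mask_vec <- as.logical(mask)
  }
  Ysm <- lapply(Ys, function(Y) t(Y[mask_vec, , drop = FALSE]))  # T_a x nvm
  nvm <- sum(mask_vec)
  nb <- ncol(basis$basis)

  G0 <- build_design(protocol, basis, center = FALSE)$regressors
  Glist <- if (is.null(confounds)) {
    rep(list(scale(G0, center = TRUE, scale = FALSE)), n_acq)
  } else {
    lapply(seq_len(n_acq), function(a) {
      C <- confound_columns(confounds[[a]])
      qr.resid(qr(cbind(1, C)), G0)
    })
  }
  Gram <- lapply(Glist, crossprod)                        # nb x nb each
  U <- lapply(seq_len(n_acq),
              function(a) crossprod(Glist[[a]], Ysm[[a]]))  # nb x nvm
  SST <- Reduce(`+`, lapply(Ysm, function(Ya) colSums(Ya^2)))
  Gram9 <- t(matrix(vapply(Gram, as.numeric, numeric(nb * nb)),
                    nrow = nb * nb))                      # n_acq x nb^2

  W <- matrix(rep(c(1, rep(0, nb - 1)), nvm), nrow = nb)  # canonical start
  beta <- matrix(0, n_acq, nvm)
  sse_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (a in seq_len(n_acq)) {
      den_a <- colSums(W * (Gram[[a]] %*% W))
      beta[a, ] <- colSums(W * U[[a]]) / den_a
    }
    beta[!is.finite(beta)] <- 0
    Bsum <- Reduce(`+`, lapply(seq_len(n_acq),
                               function(a) U[[a]] *
                                 rep(beta[a, ], each = nb)))
    A9 <- crossprod(Gram9, beta^2)                        # nb^2 x nvm
    Wnew <- solve_sym_batch(A9, Bsum, nb)
    ok <- is.finite(colSums(Wnew)) & colSums(abs(Wnew)) > 0
    W[, ok] <- Wnew[, ok]
    # resolve scale: kernel dominant extremum to +/-1
    K <- basis$basis %*% W                                # L x nvm
    pk_idx <- max.col(t(abs(K)), ties.method = "first")
    s <- abs(K[cbind(pk_idx, seq_len(nvm))])
    s[s == 0] <- 1
    W <- W / rep(s, each = nb)
    beta <- beta * rep(s, each = n_acq)
    # SSE via identities: ||y||^2 - 2 b r'y + b^2 r'r per acquisition
    sse <- SST
    for (a in seq_len(n_acq)) {
      ry <- colSums(W * U[[a]])
      den_a <- colSums(W * (Gram[[a]] %*% W))
      sse <- sse - 2 * beta[a, ] * ry + beta[a, ]^2 * den_a
    }
    tot <- sum(sse)
    if (is.finite(tot) &&
        abs(sse_prev - tot) <= tol * max(sum(SST), 1e-12)) {
      converged <- TRUE
      break
    }
    sse_prev <- tot
  }
  r2m <- ifelse(SST > 0, 1 - sse / SST, 0)

  expand <- function(m, fill = NA_real_) {
    out <- matrix(fill, nrow(m), nv)
    out[, mask_vec] <- m
    out
  }
  betas <- expand(beta)
  weights <- expand(W)
  r2 <- rep(NA_real_, nv); r2[mask_vec] <- r2m
  structure(list(betas = betas, mean_beta = colMeans(betas),
                 weights = weights, r2 = r2, dim = dims[1:3],
                 mask = mask_vec, converged = converged, n_acq = n_acq,
                 protocol = protocol, basis = basis, n_iter = it),
            class = "bold_fit")
}

#' @export
print.bold_fit <- function(x, ...) {
  cat(sprintf(paste0("BOLD forward-model fit: %d voxels (%d in mask), ",
                     "%d acquisitions\n"),
              length(x$r2), sum(x$mask), x$n_acq))
  cat(sprintf("  converged: %s after %d alternations\n", x$converged,
              x$n_iter))
  cat(sprintf("  median in-mask R^2: %.3f; max %.3f\n",
              stats::median(x$r2[x$mask]), max(x$r2[x$mask])))
  invisible(x)
}

#' @export
coef.bold_fit <- function(object, ...) {
  object$betas
}

#' R-squared map of the across-acquisition average time series
#'
#' Averages the acquisitions voxel-wise, fits the forward model to the
#' averaged series (a single amplitude per voxel), and returns the map of
#' the coefficient of determination. Zero-variance voxels get R^2 = 0.
#'
#' @param acquisitions as in [fit_forward_model()].
#' @param protocol a `bold_protocol`.
#' @param basis an `hrf_basis`.
#' @param percent convert to % signal change first (default TRUE).
#' @return 3-D array of R^2 values.
#' @export
r2_map <- function(acquisitions, protocol, basis = hrf_basis(protocol$tr),
                   percent = TRUE) {
  if (is.list(acquisitions) && inherits(acquisitions[[1]], "bold_series")) {
    dims <- acquisitions[[1]]$dim
    Ys <- lapply(acquisitions, function(a) {
      Y <- as_voxel_matrix(a)
      if (percent) Y <- percent_signal_change(Y)
      Y
    })
    Yavg <- Reduce(`+`, Ys) / length(Ys)
  } else {
    Y <- as.matrix(acquisitions)
    n_tr <- protocol$n_tr
    if (ncol(Y) != n_tr * protocol$n_acq) {
      stop("matrix columns must equal n_tr * n_acq", call. = FALSE)
    }
    Yavg <- Reduce(`+`, lapply(seq_len(protocol$n_acq), function(a) {
      Y[, (a - 1) * n_tr + seq_len(n_tr), drop = FALSE]
    })) / protocol$n_acq
    dims <- c(nrow(Y), 1, 1)
  }
  p1 <- protocol
  p1$n_acq <- 1
  fit <- fit_forward_model(Yavg, p1, basis, percent = FALSE)
  r2 <- fit$r2
  r2[!fit$mask] <- 0
  r2[!is.finite(r2)] <- 0
  array(r2, dim = dims[1:3])
}

#' Define regions of interest from an R-squared map
#'
#' Thresholds and binarizes the map, labels 26-connected components, drops
#' components smaller than `min_size`, and names the surviving components
#' by decreasing size (the visual cortex region is expected to be the
#' largest, the LGN the smaller).
#'
#' @param map 3-D array (e.g. from [r2_map()]).
#' @param threshold binarization threshold; alternatively
#'   `top_fraction` selects the top fraction of in-mask values.
#' @param min_size minimum component size in voxels (default 10).
#' @param top_fraction if not NULL, threshold at this upper quantile of
#'   positive map values (default NULL; spec default 0.005 when used).
#' @param labels names for the components in decreasing size order.
#' @return List of class `roi_set`: per-ROI integer voxel indices.
#' @export
define_rois <- function(map, threshold = NULL, min_size = 10,
                        top_fraction = NULL,
                        labels = c("cortex", "lgn")) {
  if (is.null(threshold)) {
    if (is.null(top_fraction)) top_fraction <- 0.005
    threshold <- stats::quantile(map[map > 0], 1 - top_fraction,
                                 names = FALSE)
  }
  bin <- map >= threshold
  if (!any(bin)) {
    warning("no voxels above threshold")
    return(structure(list(), class = "roi_set"))
  }
  comp <- label_components_26(bin)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_size)
  if (!length(keep)) {
    warning("no components of at least min_size voxels")
    return(structure(list(), class = "roi_set"))
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  rois <- lapply(keep, function(k) which(comp == k))
  nm <- labels[seq_along(rois)]
  nm[is.na(nm)] <- paste0("roi", seq_along(rois))[is.na(nm)]
  names(rois) <- nm
  structure(rois, class = "roi_set")
}

# 26-connectivity component labelling of a 3-D logical array.
label_components_26 <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  idx_all <- which(bin)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(i, d)
      for (j in seq_len(nrow(nb))) {
        p <- ai + nb[j, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (bin[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

#' ROI response summary
#'
#' Averages the per-acquisition response amplitudes over the voxels of a
#' region, then summarizes across acquisitions: mean % signal change and
#' SEM (SD / sqrt(n acquisitions)).
#'
#' @param fit a `bold_fit`.
#' @param roi integer voxel indices (e.g. one element of a `roi_set`) or a
#'   logical array.
#' @param acquisitions optional subset of acquisition indices (e.g. the
#'   three acquisitions of one eye).
#' @return List: `mean`, `sem`, `n_acq`, `per_acquisition` (ROI-mean beta
#'   per acquisition), `n_voxels`.
#' @export
roi_response <- function(fit, roi, acquisitions = NULL) {
  if (is.logical(roi) || is.array(roi)) roi <- which(as.logical(roi))
  if (!length(roi)) stop("empty ROI", call. = FALSE)
  if (max(roi) > ncol(fit$betas)) stop("ROI outside volume", call. = FALSE)
  if (is.null(acquisitions)) acquisitions <- seq_len(fit$n_acq)
  b <- fit$betas[acquisitions, roi, drop = FALSE]
  per_acq <- rowMeans(b, na.rm = TRUE)
  n <- length(per_acq)
  list(mean = mean(per_acq), sem = stats::sd(per_acq) / sqrt(n),
       n_acq = n, per_acquisition = per_acq, n_voxels = length(roi))
}
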