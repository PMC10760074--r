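# regressor built through the same oversampled path the fitter uses,
# with the canonical peak-1 kernel
canonical_regressor <- function(protocol, basis) {
  box <- build_design(protocol, basis)$boxcar_over
  k <- hrf_kernel(basis, c(1, 0, 0))
  conv <- stats::convolve(box, rev(k), type = "open")
  conv <- conv[seq_along(box)] * basis$dt
  as.numeric(tapply(conv, rep(seq_len(protocol$n_tr),
                              each = basis$oversample), mean))
}

test_that("protocol arithmetic matches the printed block structure", {
  p <- bold_protocol()
  expect_identical(p$n_tr, 144L)
  expect_identical(p$n_blocks, 18L)
  des <- build_design(p, center = FALSE)
  expect_equal(mean(des$boxcar_tr[1:8]), 0.5)     # one on/off cycle
  expect_equal(which(des$boxcar_tr[1:8] == 1), 1:4)
  expect_error(bold_protocol(tr = 3, duration = 433), "multiple")
})

test_that("the hemodynamic basis is unit-norm and independent", {
  b <- hrf_basis()
  expect_equal(unname(colSums(b$basis^2)), rep(1, 3), tolerance = 1e-12)
  expect_identical(qr(b$basis)$rank, 3L)
  k <- hrf_kernel(b, c(1, 0, 0))
  expect_equal(max(abs(k)), 1, tolerance = 1e-12)
})

test_that("noiseless betas are recovered to 1e-3 with R^2 ~ 1", {
  p <- bold_protocol()
  b <- hrf_basis()
  reg <- canonical_regressor(p, b)
  betas_true <- c(0.5, 0.4, 0.6, 0.5, 0.45, 0.55)
  nv <- 10
  Y <- matrix(0, nv, p$n_tr * 6)
  for (a in 1:6) {
    Y[, (a - 1) * p$n_tr + seq_len(p$n_tr)] <-
      matrix(rep(betas_true[a] * reg, each = nv), nv)
  }
  fit <- fit_forward_model(Y, p, b, percent = FALSE)
  expect_true(fit$converged)
  for (a in 1:6) {
    expect_lt(max(abs(fit$betas[a, ] - betas_true[a])), 1e-3)
  }
  expect_gt(min(fit$r2), 0.999)
  expect_equal(fit$mean_beta[1], mean(betas_true), tolerance = 1e-3)
})

test_that("negative responses are recovered with their sign", {
  p <- bold_protocol(duration = 216, n_acq = 2)
  b <- hrf_basis()
  reg <- canonical_regressor(p, b)
  Y <- rbind(c(-0.4 * reg, -0.5 * reg))
  fit <- fit_forward_model(Y, p, b, percent = FALSE)
  expect_equal(unname(fit$betas[, 1]), c(-0.4, -0.5), tolerance = 1e-3)
})

test_that("pure-noise voxels give null-centered mean betas", {
  p <- bold_protocol(duration = 216, n_acq = 2)
  b <- hrf_basis()
  set.seed(31)
  nv <- 100
  Y <- matrix(rnorm(nv * p$n_tr * 2), nv)
  fit <- fit_forward_model(Y, p, b, percent = FALSE)
  mb <- fit$mean_beta
  expect_lt(abs(mean(mb)), 2 * sd(mb) / sqrt(nv))
})

test_that("joint concatenated fit equals separate fits for a fixed kernel", {
  # one-component basis freezes the kernel shape; only amplitudes are fit
  b <- hrf_basis()
  b1 <- b
  b1$basis <- b$basis[, 1, drop = FALSE]
  p6 <- bold_protocol()
  p1 <- bold_protocol(n_acq = 1)
  set.seed(17)
  reg <- canonical_regressor(p1, b1)
  nv <- 8
  Ys <- lapply(1:6, function(a) {
    matrix(rnorm(nv * p1$n_tr, 0, 0.5), nv) +
      matrix(rep(0.1 * a * reg, each = nv), nv)
  })
  joint <- fit_forward_model(do.call(cbind, Ys), p6, b1, percent = FALSE)
  for (a in 1:6) {
    sep <- fit_forward_model(Ys[[a]], p1, b1, percent = FALSE)
    expect_equal(joint$betas[a, ], sep$betas[1, ], tolerance = 1e-9)
  }
})

test_that("R^2 equals 1 - SSE/SST against brute-force sums", {
  p <- bold_protocol(duration = 216, n_acq = 2)
  b <- hrf_basis()
  set.seed(41)
  reg <- canonical_regressor(p, b)
  y <- 0.8 * c(reg, reg) + rnorm(2 * p$n_tr, 0, 0.4)
  fit <- fit_forward_model(rbind(y), p, b, percent = FALSE)
  # reconstruct the fitted series from the returned parameters
  box <- build_design(p, b)$boxcar_over
  k <- hrf_kernel(b, fit$weights[, 1])
  conv <- stats::convolve(box, rev(k), type = "open")[seq_along(box)] *
    b$dt
  r <- as.numeric(tapply(conv, rep(seq_len(p$n_tr), each = b$oversample),
                         mean))
  yc <- c(y[1:p$n_tr] - mean(y[1:p$n_tr]),
          y[p$n_tr + 1:p$n_tr] - mean(y[p$n_tr + 1:p$n_tr]))
  pred <- c(fit$betas[1, 1] * (r - mean(r)), fit$betas[2, 1] * (r - mean(r)))
  sse <- sum((yc - pred)^2)
  sst <- sum(yc^2)
  expect_equal(fit$r2[1], 1 - sse / sst, tolerance = 1e-6)
})

test_that("r2_map is 1 for perfect voxels and 0 for flat ones", {
  p <- bold_protocol(duration = 216, n_acq = 2)
  b <- hrf_basis()
  reg <- canonical_regressor(p, b)
  Y <- rbind(c(0.5 * reg, 0.5 * reg),
             rep(3, 2 * p$n_tr))
  r2 <- r2_map(Y, p, b, percent = FALSE)
  expect_equal(r2[1], 1, tolerance = 1e-6)
  expect_identical(r2[2], 0)
})

test_that("ROI definition labels blobs by size and respects min_size", {
  map <- array(0, c(12, 12, 8))
  map[2:5, 2:5, 2:4] <- 0.9            # 48 voxels
  map[8:9, 8:9, 6:7] <- 0.8            # 8 voxels
  rois <- define_rois(map, threshold = 0.5, min_size = 5)
  expect_named(rois, c("cortex", "lgn"))
  expect_length(rois$cortex, 48)
  expect_length(rois$lgn, 8)
  expect_length(intersect(rois$cortex, rois$lgn), 0)

  rois2 <- define_rois(map, threshold = 0.5, min_size = 10)
  expect_named(rois2, "cortex")
  expect_warning(define_rois(map, threshold = 2), "no voxels")
})

test_that("26-connectivity joins diagonal neighbours", {
  bin <- array(FALSE, c(4, 4, 4))
  bin[1, 1, 1] <- TRUE
  bin[2, 2, 2] <- TRUE                 # corner-diagonal neighbour
  lab <- conedrive:::label_components_26(bin)
  expect_identical(lab[1, 1, 1], lab[2, 2, 2])
})

test_that("ROI response averages voxels then acquisitions", {
  p <- bold_protocol(duration = 216, n_acq = 2)
  fit <- structure(list(
    betas = rbind(c(0.5, 0.5, 0.1), c(0.7, 0.7, 0.1)),
    mean_beta = c(0.6, 0.6, 0.1), n_acq = 2,
    r2 = c(1, 1, 1), mask = rep(TRUE, 3)), class = "bold_fit")
  rr <- roi_response(fit, 1:2)
  expect_equal(rr$mean, 0.6)
  expect_equal(rr$sem, sd(c(0.5, 0.7)) / sqrt(2))
  expect_equal(rr$per_acquisition, c(0.5, 0.7))
  expect_error(roi_response(fit, 10), "outside")
  expect_error(roi_response(fit, integer(0)), "empty")
})
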