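test_that("linear detrend removes lines, keeps means, is idempotent", {
  nt <- 50
  tt <- seq_len(nt)
  a <- 7; b <- 0.3
  arr <- array(rep(a + b * tt, each = 8), c(2, 2, 2, nt))
  s <- bold_series(arr, tr = 3)
  d <- linear_detrend(s)
  expect_equal(as.numeric(d$data),
               rep(a + b * mean(tt), length(d$data)), tolerance = 1e-9)
  expect_equal(linear_detrend(d)$data, d$data, tolerance = 1e-9)

  # superposed trend-orthogonal oscillation survives to high accuracy
  sig <- qr.resid(qr(cbind(1, tt)), 2 * sin(2 * pi * tt / 8))
  arr2 <- array(rep(a + b * tt + sig, each = 8), c(2, 2, 2, nt))
  d2 <- linear_detrend(bold_series(arr2, tr = 3))
  got <- d2$data[1, 1, 1, ] - mean(d2$data[1, 1, 1, ])
  expect_equal(got, sig - mean(sig), tolerance = 1e-6)
})

test_that("constructed global spikes are flagged exactly", {
  set.seed(21)
  s <- null_bold()
  target <- c(17L, 40L)
  s$data[, , , target] <- s$data[, , , target] + 10  # 10 SD offset, global
  sp <- detect_spikes(linear_detrend(s))
  expect_identical(sp$flagged, target)
  expect_identical(dim(sp$confounds), c(60L, 2L))
  expect_equal(colSums(sp$confounds), c(spike_17 = 1, spike_40 = 1))
})

test_that("constant series and null noise produce no flags", {
  s <- bold_series(array(5, c(4, 4, 2, 30)), tr = 3)
  sp <- detect_spikes(s)
  expect_length(sp$flagged, 0)

  # specificity over seeds: well under 1% of TRs falsely flagged
  total <- 0; flagged <- 0
  for (sd in 1:25) {
    set.seed(sd)
    sp <- detect_spikes(linear_detrend(null_bold()))
    flagged <- flagged + length(sp$flagged)
    total <- total + 60
  }
  expect_lt(flagged / total, 0.01)
})

test_that("spikes of 8 voxel-MADs on 2% of voxels are always caught", {
  hits <- vapply(1:25, function(sd) {
    set.seed(sd)
    s <- null_bold(dim = c(16, 16, 8))
    nv <- prod(dim(s$data)[1:3])
    vox <- sample(nv, ceiling(0.02 * nv))
    idx <- cbind(arrayInd(vox, dim(s$data)[1:3]), 33L)
    # raw MAD of N(0,1) is ~0.674; 8 MADs above the median
    s$data[idx] <- s$data[idx] + 8 * 0.674
    33L %in% detect_spikes(linear_detrend(s))$flagged
  }, TRUE)
  expect_true(all(hits))
})

test_that("motion expansion yields 24 regressors reduced by PCA", {
  set.seed(5)
  mp <- matrix(rnorm(60 * 6), 60, 6)
  mc <- motion_confounds(mp)
  expect_identical(ncol(mc$raw24), 24L)
  expect_gte(mc$variance_explained, 0.95)
  expect_lt(ncol(mc$regressors), 24)

  # rank-1 motion: few components suffice
  base <- cumsum(rnorm(60, 0, 0.1))
  mp1 <- outer(base, c(1, 2, 0.5, -1, 0.2, 3))
  mc1 <- motion_confounds(mp1)
  expect_lte(ncol(mc1$regressors), 4)
  expect_gte(mc1$variance_explained, 0.95)

  expect_warning(mc0 <- motion_confounds(matrix(0, 60, 6)), "zero motion")
  expect_identical(ncol(mc0$regressors), 0L)
  expect_error(motion_confounds(matrix(0, 60, 5)), "6 motion")
})

test_that("confound regression equals the closed-form projection", {
  set.seed(9)
  nt <- 48
  X <- matrix(rnorm(nt * 3), nt, 3)
  arr <- array(rnorm(8 * nt, 100, 1), c(2, 2, 2, nt))
  s <- bold_series(arr, tr = 3)
  out <- regress_confounds(s, X)
  Xf <- cbind(1, X)
  P <- diag(nt) - Xf %*% solve(crossprod(Xf)) %*% t(Xf)
  for (v in 1:2) {
    y <- arr[v, 1, 1, ]
    expect_equal(out$data[v, 1, 1, ], drop(P %*% y) + mean(y),
                 tolerance = 1e-9)
  }

  # confound orthogonal to the signal leaves it untouched
  sig <- sin(2 * pi * seq_len(nt) / 12)
  Xo <- qr.resid(qr(cbind(1, sig)), matrix(rnorm(nt * 2), nt, 2))
  arr2 <- array(rep(100 + sig, each = 8), c(2, 2, 2, nt))
  out2 <- regress_confounds(bold_series(arr2, tr = 3), Xo)
  expect_equal(out2$data, arr2, tolerance = 1e-9)

  # signal equal to a confound column is annihilated
  arr3 <- array(rep(100 + X[, 1], each = 8), c(2, 2, 2, nt))
  out3 <- regress_confounds(bold_series(arr3, tr = 3), X)
  expect_lt(sd(out3$data[1, 1, 1, ]), 1e-9)

  expect_warning(regress_confounds(s, cbind(X, X[, 1])), "rank-deficient")
})

test_that("mirror averaging is symmetric, idempotent and halves unilateral signal", {
  set.seed(13)
  arr <- array(rnorm(6 * 4 * 2 * 5), c(6, 4, 2, 5))
  m <- mirror_average(arr)
  expect_equal(m, m[6:1, , , , drop = FALSE], tolerance = 1e-12)
  expect_equal(mirror_average(m), m, tolerance = 1e-12)

  sym <- (arr + arr[6:1, , , , drop = FALSE]) / 2
  expect_equal(mirror_average(sym), sym, tolerance = 1e-12)

  uni <- array(0, c(6, 4, 2, 5))
  uni[1, 1, 1, ] <- 1
  mu <- mirror_average(uni)
  expect_equal(mu[1, 1, 1, ], rep(0.5, 5))
  expect_equal(mu[6, 1, 1, ], rep(0.5, 5))

  # odd x-extent: the midline plane maps onto itself
  odd <- array(rnorm(5 * 3 * 2 * 2), c(5, 3, 2, 2))
  mo <- mirror_average(odd)
  expect_equal(mo[3, , , ], odd[3, , , ], tolerance = 1e-12)
})
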