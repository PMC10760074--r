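test_that("noiseless circles and ellipses are recovered exactly", {
  cp <- circle_points()
  f <- fit_ellipse(cp$x, cp$y)
  expect_equal(f$a, 50, tolerance = 1e-6)
  expect_equal(f$b, 50, tolerance = 1e-6)
  expect_equal(f$area, pi * 2500, tolerance = 1e-4)
  expect_identical(f$quality, "good")

  ep <- ellipse_points()
  f2 <- fit_ellipse(ep$x, ep$y)
  expect_equal(f2$a, 40, tolerance = 1e-6)
  expect_equal(f2$b, 20, tolerance = 1e-6)
  expect_equal(f2$cx, 10, tolerance = 1e-6)
  expect_equal(f2$cy, -5, tolerance = 1e-6)
  expect_equal(f2$orientation, 0.7, tolerance = 1e-6)
})

test_that("gross outliers are trimmed away by the iterative fit", {
  cp <- circle_points()
  set.seed(3)
  x <- c(cp$x, runif(10, 0, 40))       # simulated eyelash points
  y <- c(cp$y, runif(10, 150, 200))
  f <- fit_ellipse(x, y)
  expect_lt(abs(f$a - 50), 0.5)
  expect_lt(abs(f$b - 50), 0.5)
  expect_true(all(!f$used[61:70]))
})

test_that("degenerate border point sets are rejected", {
  cp <- circle_points()
  expect_error(fit_ellipse(cp$x[1:4], cp$y[1:4]), "5 usable")
  expect_error(fit_ellipse(1:20, 2 * (1:20) + 1), "degenerate|ellipse")
})

test_that("acquisition QC excludes only above 50% poor frames", {
  expect_true(qc_acquisition(rep("good", 100))$include)
  expect_true(qc_acquisition(rep(c("good", "poor"), 50))$include)
  q <- c(rep("poor", 51), rep("good", 49))
  expect_false(qc_acquisition(q)$include)
  expect_error(qc_acquisition(character(0)), "empty")

  # a 96-acquisition session with exactly 4 constructed bad acquisitions
  set.seed(8)
  frac <- c(rep(0.2, 92), rep(0.6, 4))[sample(96)]
  dec <- vapply(frac, function(fr) {
    q <- c(rep("poor", round(100 * fr)), rep("good", 100 - round(100 * fr)))
    qc_acquisition(q)$include
  }, TRUE)
  expect_identical(sum(!dec), 4L)
})

test_that("percent-change series re-means to zero on valid frames", {
  set.seed(1)
  area <- runif(600, 9000, 11000)
  valid <- runif(600) > 0.2
  s <- pupil_timeseries(seq(0, by = 1 / 60, length.out = 600), area, valid)
  expect_lt(abs(mean(s$area_pct_change[valid])), 1e-9)
})

test_that("sinusoid regression recovers amplitude and phase exactly", {
  s <- sine_series(amp = 10, phase = pi / 3)
  f <- fit_sinusoid(s)
  expect_equal(unname(f$amplitude), 10, tolerance = 1e-9)
  expect_equal(unname(f$phase), pi / 3, tolerance = 1e-9)

  # time-shift rotates the phase and leaves amplitude unchanged
  dt <- 1.25
  s2 <- s
  s2$time <- s$time + dt
  f2 <- fit_sinusoid(s2)
  expect_equal(f2$amplitude, f$amplitude, tolerance = 1e-9)
  dphi <- (f$phase - f2$phase + pi) %% (2 * pi) - pi
  target <- (2 * pi * dt / 6 + pi) %% (2 * pi) - pi
  expect_equal(dphi, target, tolerance = 1e-9)
})

test_that("masked frames (blinks) barely move the estimate", {
  s <- sine_series(amp = 6, phase = -2.6)
  set.seed(12)
  s$valid <- runif(length(s$time)) > 0.4
  f <- fit_sinusoid(s)
  expect_lt(abs(f$amplitude - 6) / 6, 0.01)
})

test_that("under-sampled series are refused", {
  s <- sine_series(duration = 10)      # < 2 cycles at 1/6 Hz
  expect_error(fit_sinusoid(s), "two full cycles")
})

test_that("pure-noise amplitude stays under the null bound", {
  n <- 21600
  tm <- seq(0, by = 1 / 60, length.out = n)
  amps <- vapply(1:20, function(sd) {
    set.seed(sd)
    s <- pupil_timeseries(tm, 10000 * (1 + rnorm(n, 0, 0.02)))
    fit_sinusoid(s)$amplitude
  }, 0)
  # amplitude ~ Rayleigh(sigma*sqrt(2/n)) in % units; 3/sqrt(n/2) bound
  expect_lt(max(amps), 3 * 2 / sqrt(n / 2))
})

test_that("exhaustive bootstrap enumerates multisets and degenerates to 0", {
  s <- sine_series()
  expect_error(bootstrap_sem(list(s)), "at least two")

  b4 <- bootstrap_sem(replicate(4, s, simplify = FALSE))
  expect_identical(b4$n_resamples, 35L)
  expect_equal(b4$sem_amplitude, 0)
  expect_equal(b4$sem_phase, 0)

  b2 <- bootstrap_sem(replicate(2, s, simplify = FALSE))
  expect_identical(b2$n_resamples, 3L)

  # n = 2 multisets are exactly {11, 12, 22}
  ms <- conedrive:::multiset_resamples(2)
  expect_identical(ms, cbind(c(1L, 1L), c(1L, 2L), c(2L, 2L)))

  # point estimate equals the fit of the plain average
  set.seed(4)
  mk <- function() {
    s <- sine_series(amp = 5, phase = 1)
    s$area_pct_change <- s$area_pct_change + rnorm(length(s$time), 0, 1)
    s
  }
  lst <- replicate(4, mk(), simplify = FALSE)
  b <- bootstrap_sem(lst)
  Y <- rowMeans(vapply(lst, `[[`, numeric(21600), "area_pct_change"))
  direct <- fit_sinusoid(structure(
    list(time = lst[[1]]$time, area_pct_change = Y - mean(Y),
         valid = rep(TRUE, length(Y))), class = "pupil_timeseries"))
  expect_equal(b$amplitude, direct$amplitude, tolerance = 1e-9)
  expect_gt(b$sem_amplitude, 0)
})

test_that("amplitude recovery is accurate under pink noise", {
  # 200 seeded synthetic acquisitions, amplitude 5%, pink noise SD 2%
  errs <- vapply(1:200, function(sd) {
    set.seed(sd)
    tm <- seq(0, 360 - 1 / 60, by = 1 / 60)
    pct <- 5 * sin(2 * pi * tm / 6 - 2.6) + conedrive::pink_noise(21600, 2)
    s <- pupil_timeseries(tm, 10000 * (1 + pct / 100))
    abs(fit_sinusoid(s)$amplitude - 5)
  }, 0)
  expect_lt(median(errs), 0.3)
})
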