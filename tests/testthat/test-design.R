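S_full <- receptor_sensitivities()

test_that("light-flux design gives equal contrast on all pigments", {
  dev <- synth_device(n_primaries = 16)
  m <- design_modulation(dev, c("L", "S", "rod", "mel"), character(0),
                         S_full, n_starts = 5, seed = 1)
  cc <- m$contrast_report$bipolar
  expect_lt(diff(range(cc)), 1e-3)
  expect_gt(min(cc), 0.9)
})

test_that("silencing and arm symmetry hold on a mid-size device", {
  dev <- synth_device(n_primaries = 16)
  m <- design_modulation(dev, c("L", "S"), c("rod", "mel"), S_full,
                         n_starts = 8, seed = 3)
  cc <- m$contrast_report$bipolar
  expect_lt(max(abs(cc[c("rod", "mel")])), 1e-3)
  expect_gt(min(cc[c("L", "S")]), 0.1)
  # symmetric arms, exactly, and within gamut
  expect_equal(m$pos_settings + m$neg_settings,
               2 * m$background_settings)
  expect_true(all(m$pos_settings >= 0 & m$pos_settings <= 1))
  expect_true(all(m$neg_settings >= 0 & m$neg_settings <= 1))
})

test_that("opponent targeting yields opposite-sign cone contrasts", {
  dev <- synth_device(n_primaries = 16)
  m <- design_modulation(dev, c(L = 1, S = -1), c("rod", "mel"), S_full,
                         n_starts = 8, seed = 2)
  cc <- m$contrast_report$bipolar
  expect_gt(cc[["L"]], 0.02)
  expect_lt(cc[["S"]], -0.02)
  expect_lt(max(abs(cc[c("rod", "mel")])), 1e-3)
})

test_that("identical config and seed give bit-identical designs", {
  dev <- synth_device(n_primaries = 12)
  m1 <- design_modulation(dev, c("L", "S"), c("rod", "mel"), S_full,
                          n_starts = 4, seed = 11)
  m2 <- design_modulation(dev, c("L", "S"), c("rod", "mel"), S_full,
                          n_starts = 4, seed = 11)
  expect_identical(m1$pos_settings, m2$pos_settings)
  expect_identical(m1$contrast_report$bipolar,
                   m2$contrast_report$bipolar)
})

test_that("optimizer dominates random feasible modulations (toy device)", {
  dev <- toy_device()
  m <- design_modulation(dev, c("L", "S"), c("rod"), S_full,
                         n_starts = 10, seed = 5)
  best <- m$min_targeted_contrast
  expect_gt(best, 0)

  # random symmetric modulations constrained to the silencing null space
  grid <- dev$wavelengths
  dl <- mean(diff(grid))
  E <- crossprod(S_full, dev$primaries) * dl
  e_bg <- excitation(device_spectrum(dev, rep(0.5, 3)), S_full)
  M <- E / e_bg
  A <- M["rod", , drop = FALSE]
  N <- svd(A, nv = 3)$v[, 2:3]
  set.seed(99)
  worst_margin <- Inf
  for (i in 1:10000) {
    z <- rnorm(2)
    d <- drop(N %*% z)
    sc <- 0.5 / max(abs(d))
    d <- d * sc * runif(1)             # random feasible magnitude
    cand <- min(drop(M[c("L", "S"), ] %*% d))
    worst_margin <- min(worst_margin, best - cand)
  }
  expect_gte(worst_margin + 1e-9, 0)
})

test_that("infeasible silencing demands raise an error", {
  dev <- toy_device()
  # 3 primaries cannot silence 3 mechanisms and still drive the fourth
  expect_error(design_modulation(dev, "S", c("L", "rod", "mel"), S_full,
                                 n_starts = 2, seed = 1, tolerance = 1e-9),
               "infeasible")
})

test_that("sinusoidal waveform starts at background and blocks sum right", {
  dev <- synth_device(n_primaries = 8)
  m <- design_modulation(dev, c("L", "S", "rod", "mel"), character(0),
                         S_full, n_starts = 3, seed = 1)
  prof <- temporal_profile("sinusoid", sample_rate = 20)
  wf <- make_waveform(prof, m)
  expect_equal(wf$settings[1, ], m$background_settings)
  expect_equal(nrow(wf$settings), 360 * 20)

  prof_b <- temporal_profile("blocked_flicker", flicker_hz = 16,
                             sample_rate = 80)
  wf_b <- make_waveform(prof_b, m)
  expect_equal(wf_b$n_blocks, 18)
  # total on-time: block membership times dt equals 18 x 12 s
  tau <- wf_b$time %% 24
  expect_equal(sum(tau < 12) / 80, 216)
  # half-cosine envelope midpoint at half the ramp
  expect_equal(block_envelope(prof_b, 0.75), 0.5)
  expect_equal(block_envelope(prof_b, 6), 1)
  expect_equal(block_envelope(prof_b, 18), 0)
})

test_that("invalid temporal profiles are rejected", {
  expect_error(temporal_profile("blocked_flicker", ramp = 7), "ramp")
  expect_error(temporal_profile("blocked_flicker", flicker_hz = 32,
                                sample_rate = 40), "twice")
})

test_that("perturbation ensemble collapses to nominal at zero noise", {
  dev <- synth_device(n_primaries = 12)
  m <- design_modulation(dev, c("L", "S"), c("rod", "mel"), S_full,
                         n_starts = 4, seed = 1)
  v0 <- validate_modulation(m, dev, S_full, primary_noise_sd = 0,
                            n_draws = 5)
  for (i in 1:5) {
    expect_equal(v0$draws[i, ], m$contrast_report$bipolar,
                 tolerance = 1e-12)
  }

  v1 <- validate_modulation(m, dev, S_full, primary_noise_sd = 0.01,
                            n_draws = 100, seed = 2)
  # brute-force re-evaluation of one draw with the same RNG stream
  set.seed(2)
  g <- 1 + rnorm(dev$n_primaries, 0, 0.01)
  dev_p <- dev
  dev_p$primaries <- sweep(dev$primaries, 2, g, `*`)
  rep1 <- contrast(device_spectrum(dev_p, m$pos_settings),
                   device_spectrum(dev_p, m$neg_settings),
                   device_spectrum(dev_p, m$background_settings), S_full)
  expect_equal(v1$draws[1, ], rep1$bipolar, tolerance = 1e-12)
  expect_true(all(diff(v1$silenced_quantiles) >= 0))
  expect_gt(v1$silenced_quantiles[["95%"]], 0)
})
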