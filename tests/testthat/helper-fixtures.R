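# shared fixtures, all generated in code

circle_points <- function(n = 60, cx = 100, cy = 80, r = 50) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_points <- function(n = 80, cx = 10, cy = -5, a = 40, b = 20,
                           ang = 0.7) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + a * cos(th) * cos(ang) - b * sin(th) * sin(ang),
       y = cy + a * cos(th) * sin(ang) + b * sin(th) * cos(ang))
}

# noiseless sinusoidal pupil series on the standard 60 Hz / 360 s grid
sine_series <- function(amp = 10, phase = pi / 3, f = 1 / 6,
                        duration = 360, fs = 60, mean_area = 10000) {
  tm <- seq(0, duration - 1 / fs, by = 1 / fs)
  area <- mean_area * (1 + amp / 100 * sin(2 * pi * f * tm + phase))
  pupil_timeseries(tm, area)
}

# tiny 3-primary device for oracle-scale optimizer checks
toy_device <- function() {
  synth_device(n_primaries = 3, fwhm_nm = 60)
}

# small null BOLD volume: iid Gaussian about a baseline
null_bold <- function(dim = c(10, 10, 6), n_tr = 60, sd = 1,
                      baseline = 100, tr = 3) {
  bold_series(array(stats::rnorm(prod(dim) * n_tr, baseline, sd),
                    c(dim, n_tr)), tr = tr)
}
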