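test_that("resultant magnitude is the per-sample Euclidean norm", {
  tr <- accel_trace(ax = 3, ay = 4, az = 0)
  expect_equal(resultant_magnitude(tr), 5)

  n <- 100
  tr <- accel_trace(ax = rep(0, n), ay = rep(0, n), az = rep(9.81, n))
  expect_equal(resultant_magnitude(tr), rep(9.81, n))

  set.seed(7)
  ax <- rnorm(n); ay <- rnorm(n); az <- rnorm(n)
  tr <- accel_trace(ax, ay, az)
  byhand <- vapply(seq_len(n), function(i) sqrt(ax[i]^2 + ay[i]^2 + az[i]^2),
                   numeric(1))
  expect_equal(resultant_magnitude(tr), byhand)

  expect_error(accel_trace(numeric(0), numeric(0), numeric(0)), "empty trace")
  expect_error(accel_trace(200, 0, 0), "exceeds device range")
})

test_that("segmentation uses consecutive windows, drops partial tails, demeans", {
  fs <- 100
  segs <- segment_and_demean(rnorm(1800 * fs), fs, window_s = 6,
                             analysis_start_s = 0, analysis_duration_s = 1800)
  expect_length(segs, 300)

  segs <- segment_and_demean(rnorm(75 * fs), fs, window_s = 6,
                             analysis_start_s = 0, analysis_duration_s = 75)
  expect_length(segs, 12) # 72 s used, 3 s dropped
  expect_equal(segs[[12]]$t_start, 66)

  segs <- segment_and_demean(rep(9.81, 30 * fs), fs, window_s = 6,
                             analysis_start_s = 0, analysis_duration_s = 30)
  for (s in segs) expect_equal(s$values, rep(0, 6 * fs))

  segs <- segment_and_demean(rnorm(60 * fs), fs, analysis_start_s = 12,
                             analysis_duration_s = 24)
  expect_equal(vapply(segs, `[[`, numeric(1), "t_start"), c(12, 18, 24, 30))
  for (s in segs) expect_lt(abs(mean(s$values)), 1e-12)

  expect_error(segment_and_demean(rnorm(100), fs, window_s = 6,
                                  analysis_start_s = 0),
               "insufficient data")
})

test_that("amplitude spectrum is calibrated for exact-bin sinusoids", {
  fs <- 1600
  t <- (0:(6 * fs - 1)) / fs
  seg <- segment_and_demean(2 * sin(2 * pi * 18 * t), fs, 6, 0, 6)[[1]]
  sp <- amplitude_spectrum(seg, fs)
  expect_equal(sp$freqs[2] - sp$freqs[1], 1 / 6)
  i <- which.max(sp$amplitudes)
  expect_equal(sp$freqs[i], 18)
  expect_equal(sp$amplitudes[i], 2, tolerance = 1e-6)
  expect_true(all(sp$amplitudes >= 0))

  seg$values <- rep(0, length(seg$values))
  expect_true(all(amplitude_spectrum(seg, fs)$amplitudes == 0))
})

test_that("spectral energy matches time-domain energy (Parseval)", {
  fs <- 200
  set.seed(11)
  seg <- segment_and_demean(rnorm(6 * fs), fs, 6, 0, 6)[[1]]
  sp <- amplitude_spectrum(seg, fs)
  n <- length(seg$values)
  # one-sided amplitudes 2|X|/n make the energy factor n/2 for interior bins
  expect_equal(sum(sp$amplitudes^2) * n / 2, sum(seg$values^2),
               tolerance = 0.01)
})

test_that("half-bin scalloping attenuates but never below the rectangular-window floor", {
  fs <- 1600
  t <- (0:(6 * fs - 1)) / fs
  seg <- segment_and_demean(2 * sin(2 * pi * (18 + 1 / 12) * t), fs, 6, 0, 6)[[1]]
  pk <- band_peak(amplitude_spectrum(seg, fs), shiver_band())
  expect_gt(pk$max_amplitude, 2 * 0.6) # worst-case scalloping loss < 40%
  expect_lt(pk$max_amplitude, 2)
  expect_lt(abs(pk$freq_at_max - (18 + 1 / 12)), 1 / 12 + 1e-9)
})

test_that("allometric shivering frequency follows the log-log mass law", {
  expect_equal(predict_shiver_frequency(1700), 10^(1.85 - 0.18 * log10(1700)))
  expect_equal(round(predict_shiver_frequency(1700), 1), 18.6)
  expect_equal(predict_shiver_frequency(1), 10^1.85, tolerance = 1e-12)
  expect_equal(predict_shiver_frequency(1000), 10^1.31, tolerance = 1e-12)
  # strictly decreasing in mass
  m <- seq(100, 5000, by = 50)
  expect_true(all(diff(predict_shiver_frequency(m)) < 0))
  expect_error(predict_shiver_frequency(0), "positive")
  expect_error(predict_shiver_frequency(-5), "positive")
})

test_that("band peak restricts to the closed band and breaks ties low", {
  fs <- 1600
  t <- (0:(6 * fs - 1)) / fs
  x <- 2 * sin(2 * pi * 18 * t) + 5 * sin(2 * pi * 40 * t)
  seg <- segment_and_demean(x, fs, 6, 0, 6)[[1]]
  pk <- band_peak(amplitude_spectrum(seg, fs), shiver_band(10, 30))
  expect_equal(pk$freq_at_max, 18)
  expect_equal(pk$max_amplitude, 2, tolerance = 1e-6)

  seg$values <- rep(0, length(seg$values))
  pk <- band_peak(amplitude_spectrum(seg, fs), shiver_band(10, 30))
  expect_equal(pk$max_amplitude, 0)
  expect_equal(pk$freq_at_max, 10) # low-frequency tie-break

  seg <- segment_and_demean(3 * sin(2 * pi * 25 * t), fs, 6, 0, 6)[[1]]
  pk <- band_peak(amplitude_spectrum(seg, fs), shiver_band(10, 30))
  expect_equal(pk$freq_at_max, 25)
  expect_equal(pk$max_amplitude, 3, tolerance = 1e-6)

  sp <- amplitude_spectrum(seg, fs)
  expect_error(band_peak(sp, shiver_band(0.001, 0.002)), "band outside resolution")
})

test_that("shivering summary averages window peaks", {
  pk <- data.frame(max_amplitude = c(1, 2, 3), freq_at_max = c(18, 18, 18))
  s <- shivering_summary(pk, animal_id = "A01", day = 1)
  expect_equal(s$intensity, 2)
  expect_equal(s$mean_freq, 18)
  expect_equal(s$n_windows, 3)
  expect_error(shivering_summary(pk[0, ]), "no window peaks")
})

test_that("simulated tremor frequency is recovered to within half a bin across the band", {
  for (f in c(10.7, 16.04, 23.3, 29.5)) {
    sim <- gen_accel_trace(calibration_spec(f, duration_s = 30, seed = 3))
    r <- analyze_shivering(sim$trace, analysis_start_s = 0,
                           analysis_duration_s = 30)
    expect_lt(abs(r$summary$mean_freq - f), 1 / 12 + 1e-9)
  }
})

test_that("constant orientation offsets do not move the detected tremor peak", {
  base <- gen_accel_trace(calibration_spec(18, duration_s = 12, seed = 5))
  ref <- analyze_shivering(base$trace, analysis_start_s = 0,
                           analysis_duration_s = 12)$summary
  # offsets along the tremor axis (orientation drift in the sensing
  # direction) and a small oblique offset; a large oblique offset would
  # rotate the static vector away from the tremor axis and attenuate the
  # peak by the projection factor, which is a physical effect, not noise
  for (off in list(c(0, 0, 5), c(0, 0, -30), c(0.5, 0.5, 0))) {
    tr <- accel_trace(base$trace$ax + off[1], base$trace$ay + off[2],
                      base$trace$az + off[3], fs = base$trace$fs)
    r <- analyze_shivering(tr, analysis_start_s = 0,
                           analysis_duration_s = 12)$summary
    expect_equal(r$mean_freq, ref$mean_freq)
    expect_lt(abs(r$intensity / ref$intensity - 1), 0.05)
  }
})
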