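# shared fixtures, built in code

# a clean continuous-tremor recording for calibration checks:
# no noise, no suspension phases, tremor axis aligned with gravity so the
# resultant magnitude carries the full tremor amplitude
calibration_spec <- function(freq, amp = 2, duration_s = 126, seed = 42,
                             ideal_sensor = FALSE, ...) {
  tremor_spec(tremor_freq = freq, tremor_amp = amp, noise_sd = 0,
              suspension_s = 0, tremor_axis = "gravity",
              duration_s = duration_s, seed = seed,
              device_resolution_g = if (ideal_sensor) 1e-12 else 0.004,
              ...)
}

# brute-force oracle for the minimum-mean consecutive run
brute_lowest_mean <- function(v, k) {
  v <- v[!is.na(v)]
  means <- vapply(seq_len(length(v) - k + 1),
                  function(i) mean(v[i:(i + k - 1)]), numeric(1))
  i <- which.min(means)
  list(mean = means[i], start_index = i)
}

# cohort defaults with the day-5 SERCA activity mean forced to the day-1
# value (null day effect, everything else unchanged)
null_activity_defaults <- function() {
  r <- cohort_defaults()
  r$mean_d5[r$variable == "serca_activity"] <- r$mean_d1[r$variable == "serca_activity"]
  r
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max rel err %.4g vs tol %.4g",
                              max(abs(actual / expected - 1)), tol))
}
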