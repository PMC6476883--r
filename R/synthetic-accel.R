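#' Specification of a synthetic shivering accelerometer recording
#'
#' Describes the forward model used by [gen_accel_trace()]: a constant gravity
#' vector, a burst/suspension tremor process (sinusoid along a fixed axis,
#' gated by alternating exponentially distributed shivering and pause phases)
#' and white sensor noise, quantized and clipped to the device physics.
#'
#' @param mass_g Body mass in grams; sets the default tremor frequency via
#'   [predict_shiver_frequency()].
#' @param tremor_freq Tremor frequency in Hz (default: allometric prediction).
#' @param tremor_amp Tremor amplitude in m/s^2 along the tremor axis.
#' @param burst_s,suspension_s Mean durations (s) of shivering bursts and
#'   suspension pauses; both exponentially distributed.
#' @param noise_sd Per-axis Gaussian sensor/motion noise, m/s^2.
#' @param gravity_vector 3-vector with magnitude 9.80665 m/s^2.
#' @param tremor_axis Unit 3-vector of the tremor direction, or `"random"`
#'   (drawn uniformly on the sphere), or `"gravity"` (aligned with
#'   `gravity_vector`; the resultant-magnitude method then sees the full
#'   tremor amplitude, which is the configuration used for amplitude
#'   calibration checks).
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param device_range_g,device_resolution_g Sensor full scale and
#'   quantization step in g.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `tremor_spec`.
#' @export
tremor_spec <- function(mass_g = 1700,
                        tremor_freq = predict_shiver_frequency(mass_g),
                        tremor_amp = 2,
                        burst_s = 20, suspension_s = 5,
                        noise_sd = 0.1,
                        gravity_vector = c(0, 0, STANDARD_GRAVITY),
                        tremor_axis = "random",
                        fs = 1600, duration_s = 2400,
                        device_range_g = 16, device_resolution_g = 0.004,
                        seed = 1L) {
  stopifnot(tremor_freq > 0, tremor_freq < fs / 2,
            tremor_amp >= 0, burst_s > 0, suspension_s >= 0,
            noise_sd >= 0, fs > 0, duration_s > 0)
  if (abs(sqrt(sum(gravity_vector^2)) - STANDARD_GRAVITY) > 1e-6) {
    stop("gravity_vector must have magnitude 9.80665 m/s^2", call. = FALSE)
  }
  structure(list(mass_g = mass_g, tremor_freq = tremor_freq,
                 tremor_amp = tremor_amp, burst_s = burst_s,
                 suspension_s = suspension_s, noise_sd = noise_sd,
                 gravity_vector = gravity_vector, tremor_axis = tremor_axis,
                 fs = fs, duration_s = duration_s,
                 device_range_g = device_range_g,
                 device_resolution_g = device_resolution_g,
                 seed = as.integer(seed)),
            class = "tremor_spec")
}

# alternating burst/suspension activity mask, exponential phase durations
tremor_activity_intervals <- function(duration_s, burst_s, suspension_s) {
  t <- 0
  on <- list()
  repeat {
    b <- stats::rexp(1, 1 / burst_s)
    on[[length(on) + 1L]] <- c(t, min(t + b, duration_s))
    t <- t + b
    if (t >= duration_s) break
    if (suspension_s > 0) t <- t + stats::rexp(1, 1 / suspension_s)
    if (t >= duration_s) break
  }
  do.call(rbind, on)
}

#' Generate a synthetic tri-axial shivering recording
#'
#' Forward model: `a(t) = g + s(t) m(t) u + noise`, where `s(t)` is a
#' sinusoid of amplitude `tremor_amp` at `tremor_freq`, `m(t)` an on/off
#' burst mask, and `u` the tremor axis. Samples are quantized to the device
#' resolution (4 mg steps by default) and clipped to the +/-16 g range.
#'
#' @param spec A [tremor_spec()].
#' @return A list with `trace` (an [accel_trace()]) and `truth`: the
#'   generating parameters, the realised tremor axis, phase offset, burst
#'   intervals and active fraction. Pass `truth` to
#'   [expected_shiver_intensity()] for the analytic pipeline expectation.
#' @export
gen_accel_trace <- function(spec) {
  stopifnot(inherits(spec, "tremor_spec"))
  withr::with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    tt <- (seq_len(n) - 1L) / spec$fs
    u <- spec$tremor_axis
    if (identical(u, "random")) {
      v <- rnorm(3)
      u <- v / sqrt(sum(v^2))
    } else if (identical(u, "gravity")) {
      u <- spec$gravity_vector / sqrt(sum(spec$gravity_vector^2))
    } else {
      u <- u / sqrt(sum(u^2))
    }
    phase <- runif(1, 0, 2 * pi)
    iv <- tremor_activity_intervals(spec$duration_s, spec$burst_s,
                                    spec$suspension_s)
    active <- logical(n)
    for (r in seq_len(nrow(iv))) {
      i0 <- floor(iv[r, 1] * spec$fs) + 1L
      i1 <- min(ceiling(iv[r, 2] * spec$fs), n)
      if (i1 >= i0) active[i0:i1] <- TRUE
    }
    s <- spec$tremor_amp * sin(2 * pi * spec$tremor_freq * tt + phase) * active
    q <- spec$device_resolution_g * STANDARD_GRAVITY
    lim <- spec$device_range_g * STANDARD_GRAVITY
    mk_axis <- function(gcomp, ucomp) {
      x <- gcomp + s * ucomp + rnorm(n, 0, spec$noise_sd)
      pmin(pmax(round(x / q) * q, -lim), lim)
    }
    trace <- accel_trace(
      ax = mk_axis(spec$gravity_vector[1], u[1]),
      ay = mk_axis(spec$gravity_vector[2], u[2]),
      az = mk_axis(spec$gravity_vector[3], u[3]),
      fs = spec$fs,
      device_range_g = spec$device_range_g,
      device_resolution_g = spec$device_resolution_g)
    truth <- list(tremor_freq = spec$tremor_freq,
                  tremor_amp = spec$tremor_amp,
                  tremor_axis = u, phase = phase,
                  burst_intervals = iv,
                  active_fraction = mean(active),
                  gravity_vector = spec$gravity_vector,
                  fs = spec$fs, duration_s = spec$duration_s,
                  spec = spec)
    list(trace = trace, truth = truth)
  })
}

#' Analytic expectation of shivering intensity for a synthetic recording
#'
#' Direct spectral oracle: reconstructs the noiseless, unquantized resultant
#' magnitude of the generated signal window by window and evaluates the
#' discrete Fourier sum by explicit summation (no FFT) at the band bins
#' around the tremor frequency, returning the mean in-band peak amplitude the
#' analysis pipeline should report. Independent of the FFT analysis path.
#'
#' @param truth The `truth` record from [gen_accel_trace()].
#' @param window_s,analysis_start_s,analysis_duration_s Analysis interval,
#'   matching the arguments given to [analyze_shivering()].
#' @param band A [shiver_band()].
#' @param bin_halo Number of bins to each side of the tremor bin searched for
#'   the peak (the gated sinusoid's energy is concentrated there).
#' @return Expected shivering intensity in m/s^2.
#' @export
expected_shiver_intensity <- function(truth, window_s = 6,
                                      analysis_start_s = 600,
                                      analysis_duration_s = 1800,
                                      band = shiver_band(), bin_halo = 3) {
  fs <- truth$fs
  nper <- round(window_s * fs)
  nwin <- floor(min(analysis_duration_s,
                    truth$duration_s - analysis_start_s) / window_s + 1e-9)
  stopifnot(nwin >= 1)
  kc <- round(truth$tremor_freq * window_s)
  ks <- (kc - bin_halo):(kc + bin_halo)
  ks <- ks[ks * (1 / window_s) >= band$lo - 1e-9 &
             ks * (1 / window_s) <= band$hi + 1e-9 & ks >= 1]
  gmag <- sqrt(sum(truth$gravity_vector^2))
  g <- truth$gravity_vector
  u <- truth$tremor_axis
  peaks <- numeric(nwin)
  for (w in seq_len(nwin)) {
    i0 <- round(analysis_start_s * fs) + (w - 1L) * nper
    tt <- (i0 + seq_len(nper) - 1L) / fs
    active <- rep(FALSE, nper)
    iv <- truth$burst_intervals
    for (r in seq_len(nrow(iv))) {
      active <- active | (tt >= iv[r, 1] & tt <= iv[r, 2])
    }
    s <- truth$tremor_amp * sin(2 * pi * truth$tremor_freq * tt + truth$phase) * active
    mag <- sqrt((g[1] + s * u[1])^2 + (g[2] + s * u[2])^2 + (g[3] + s * u[3])^2)
    j <- seq_len(nper) - 1L
    peaks[w] <- if (length(ks)) {
      max(vapply(ks, function(k) {
        2 * Mod(sum(mag * exp(-2i * pi * k * j / nper))) / nper
      }, numeric(1)))
    } else 0
  }
  mean(peaks)
}
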