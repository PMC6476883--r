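#' Split a magnitude series into consecutive demeaned windows
#'
#' Cuts the resultant-acceleration series into non-overlapping consecutive
#' windows of `window_s` seconds inside the analysis interval
#' `[analysis_start_s, analysis_start_s + analysis_duration_s)` and subtracts
#' each window's mean. Demeaning removes the static gravity component (and any
#' slow orientation drift) so that every window's spectrum has zero DC.
#' A trailing partial window is dropped, never zero-padded.
#'
#' @param magnitude Numeric vector, resultant acceleration in m/s^2.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 6).
#' @param analysis_start_s Offset of the analysis interval from the first
#'   sample, in seconds (default 0).
#' @param analysis_duration_s Length of the analysis interval in seconds;
#'   defaults to everything from `analysis_start_s` to the end of the data.
#' @param signal_start_s Time of `magnitude[1]` in seconds (default 0).
#' @return A list of segments; each segment is a list with `window_index`
#'   (1-based), `t_start` (seconds), `values` (mean-removed) and `n`.
#' @export
segment_and_demean <- function(magnitude, fs, window_s = 6,
                               analysis_start_s = 0,
                               analysis_duration_s = NULL,
                               signal_start_s = 0) {
  stopifnot(is.numeric(magnitude), fs > 0, window_s > 0)
  i0 <- round((analysis_start_s - signal_start_s) * fs) + 1L
  if (i0 < 1L) stop("insufficient data: analysis starts before the recording",
                    call. = FALSE)
  avail_s <- (length(magnitude) - i0 + 1L) / fs
  if (is.null(analysis_duration_s)) analysis_duration_s <- avail_s
  use_s <- min(analysis_duration_s, avail_s)
  nper <- round(window_s * fs)
  nwin <- floor(use_s / window_s + 1e-9)
  if (nwin < 1L) stop("insufficient data", call. = FALSE)
  lapply(seq_len(nwin), function(w) {
    idx <- i0 + (w - 1L) * nper + seq_len(nper) - 1L
    v <- magnitude[idx]
    list(window_index = w,
         t_start = analysis_start_s + (w - 1L) * window_s,
         values = v - mean(v),
         n = nper)
  })
}

#' One-sided amplitude spectrum of a demeaned window
#'
#' Discrete Fourier transform of one window with rectangular weighting,
#' scaled so that a pure sinusoid of amplitude A at an exact bin frequency
#' yields a peak of approximately A. The frequency grid runs from 0 to fs/2
#' with spacing 1/window_s (1/6 Hz for 6-s windows).
#'
#' @param segment One element of the list returned by [segment_and_demean()].
#' @param fs Sampling rate in Hz.
#' @return A list of class `spectral_window` with `window_index`, `freqs`
#'   (Hz) and `amplitudes` (m/s^2).
#' @export
amplitude_spectrum <- function(segment, fs) {
  v <- segment$values
  n <- length(v)
  if (n < 2L) stop("segment too short", call. = FALSE)
  X <- fft(v)
  half <- floor(n / 2)
  amps <- Mod(X[seq_len(half + 1L)]) / n
  # double interior bins to fold negative frequencies (one-sided convention);
  # DC and (for even n) the Nyquist bin are not doubled
  interior <- 2:(half + if (n %% 2 == 0) 0L else 1L)
  amps[interior] <- 2 * amps[interior]
  structure(
    list(window_index = segment$window_index,
         t_start = segment$t_start,
         freqs = (0:half) * fs / n,
         amplitudes = amps),
    class = "spectral_window"
  )
}

#' Allometric prediction of shivering frequency
#'
#' Mammalian shivering frequency scales with body mass as
#' log10(f) = 1.85 - 0.18 log10(m), with f in Hz and m in grams.
#' For a 1700 g piglet this predicts about 18.55 Hz.
#'
#' @param mass_g Body mass in grams (vectorized, must be > 0).
#' @return Predicted shivering frequency in Hz.
#' @export
#' @examples
#' predict_shiver_frequency(1700)
predict_shiver_frequency <- function(mass_g) {
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be positive", call. = FALSE)
  }
  10^(1.85 - 0.18 * log10(mass_g))
}

#' Shivering frequency band
#'
#' The closed frequency band `[lo, hi]` within which spectral peaks are
#' sought. The defaults (10-30 Hz) bracket the allometric prediction for
#' neonatal piglets; pass `mass_g` to record the predicted centre frequency.
#'
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @param mass_g Optional body mass in grams used to compute
#'   `predicted_center` via [predict_shiver_frequency()].
#' @return A list of class `shiver_band`.
#' @export
shiver_band <- function(lo = 10, hi = 30, mass_g = NULL) {
  stopifnot(lo > 0, hi > lo)
  center <- if (!is.null(mass_g)) predict_shiver_frequency(mass_g) else NA_real_
  if (is.finite(center) && (center < lo || center > hi)) {
    warning("allometric prediction ", signif(center, 4),
            " Hz lies outside the band [", lo, ", ", hi, "] Hz")
  }
  structure(list(lo = lo, hi = hi, predicted_center = center),
            class = "shiver_band")
}

#' In-band spectral peak of one window
#'
#' Finds the maximum amplitude among frequency bins with
#' `lo <= freq <= hi` (closed interval) and its frequency. Ties are broken
#' toward the lowest frequency, so the result is deterministic.
#'
#' @param spectrum A `spectral_window` from [amplitude_spectrum()].
#' @param band A [shiver_band()].
#' @return A list with `window_index`, `max_amplitude` (m/s^2) and
#'   `freq_at_max` (Hz).
#' @export
band_peak <- function(spectrum, band) {
  eps <- 1e-9
  sel <- which(spectrum$freqs >= band$lo - eps & spectrum$freqs <= band$hi + eps)
  if (length(sel) == 0L) stop("band outside resolution", call. = FALSE)
  a <- spectrum$amplitudes[sel]
  i <- which.max(a) # first maximum = lowest frequency on ties
  list(window_index = spectrum$window_index,
       t_start = spectrum$t_start,
       max_amplitude = a[i],
       freq_at_max = spectrum$freqs[sel[i]])
}

#' Summarise window peaks into per-animal shivering measures
#'
#' Shivering intensity is the arithmetic mean over windows of the in-band
#' maximum amplitude; the mean peak frequency is averaged the same way.
#'
#' @param peaks A data frame with columns `max_amplitude` and `freq_at_max`
#'   (one row per window), as produced by [analyze_shivering()], or a list of
#'   peaks from [band_peak()].
#' @param animal_id,day Identifiers copied into the summary row.
#' @return A one-row [tibble::tibble()] with `animal_id`, `day`, `intensity`
#'   (m/s^2), `mean_freq` (Hz) and `n_windows`.
#' @export
shivering_summary <- function(peaks, animal_id = NA, day = NA) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, lapply(peaks, function(p) {
      data.frame(max_amplitude = p$max_amplitude, freq_at_max = p$freq_at_max)
    }))
  }
  if (is.null(peaks) || nrow(peaks) == 0L) stop("no window peaks", call. = FALSE)
  tibble::tibble(
    animal_id = animal_id,
    day = day,
    intensity = mean(peaks$max_amplitude),
    mean_freq = mean(peaks$freq_at_max),
    n_windows = nrow(peaks)
  )
}

#' Full shivering analysis of one accelerometer trace
#'
#' Runs the complete spectral pipeline: resultant magnitude, consecutive
#' demeaned windows, one-sided amplitude spectra, in-band peak extraction and
#' the per-recording summary. The default analysis interval starts after a
#' 10-min acclimation period and covers the following 30 min, matching the
#' interval used for metabolic rate.
#'
#' @param trace An [accel_trace()].
#' @param band A [shiver_band()]; if `mass_g` is given instead, the default
#'   10-30 Hz band is annotated with the allometric prediction.
#' @param mass_g Optional body mass in grams (used only to annotate the band).
#' @param window_s FFT window length in seconds.
#' @param analysis_start_s,analysis_duration_s Analysis interval (seconds
#'   relative to the first sample); defaults 600 s and 1800 s.
#' @param animal_id,day Identifiers carried through to the outputs.
#' @return A list with `peaks` (tibble: one row per window with `t_start_s`,
#'   `max_amplitude`, `freq_at_max`) and `summary` (one-row tibble from
#'   [shivering_summary()]).
#' @export
analyze_shivering <- function(trace, band = shiver_band(), mass_g = NULL,
                              window_s = 6,
                              analysis_start_s = 600,
                              analysis_duration_s = 1800,
                              animal_id = NA, day = NA) {
  stopifnot(inherits(trace, "accel_trace"))
  if (!is.null(mass_g)) band <- shiver_band(band$lo, band$hi, mass_g = mass_g)
  mag <- resultant_magnitude(trace)
  segs <- segment_and_demean(mag, trace$fs, window_s = window_s,
                             analysis_start_s = analysis_start_s,
                             analysis_duration_s = analysis_duration_s,
                             signal_start_s = trace$start_time)
  pk <- lapply(segs, function(s) band_peak(amplitude_spectrum(s, trace$fs), band))
  peaks <- tibble::tibble(
    animal_id = animal_id,
    day = day,
    window_index = vapply(pk, `[[`, integer(1), "window_index"),
    t_start_s = vapply(pk, `[[`, numeric(1), "t_start"),
    max_amplitude = vapply(pk, `[[`, numeric(1), "max_amplitude"),
    freq_at_max = vapply(pk, `[[`, numeric(1), "freq_at_max")
  )
  list(peaks = peaks, summary = shivering_summary(peaks, animal_id, day))
}
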