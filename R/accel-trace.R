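#' @importFrom stats approx fft lm coef median rnorm runif sd shapiro.test var
#' @importFrom utils head tail
NULL

STANDARD_GRAVITY <- 9.80665 # m/s^2 per g

#' Tri-axial accelerometer trace
#'
#' Container for a raw tri-axial acceleration recording together with the
#' device metadata needed for validity checks. The default metadata match a
#' logger built around the ADXL345 sensor sampled at 1600 Hz with a +/-16 g
#' range and 4 mg per-axis resolution.
#'
#' @param ax,ay,az Numeric vectors of acceleration in m/s^2, one per axis.
#'   Must have equal, positive length.
#' @param fs Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds.
#' @param device_range_g Full-scale range of the sensor in g (+/-).
#' @param device_resolution_g Quantization step of the sensor in g.
#' @return An object of class `accel_trace`.
#' @export
#' @examples
#' tr <- accel_trace(ax = c(3, 0), ay = c(4, 0), az = c(0, 9.81))
#' resultant_magnitude(tr)
accel_trace <- function(ax, ay, az, fs = 1600, start_time = 0,
                        device_range_g = 16, device_resolution_g = 0.004) {
  if (length(ax) == 0L) stop("empty trace", call. = FALSE)
  if (length(ax) != length(ay) || length(ax) != length(az)) {
    stop("axis vectors must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  lim <- device_range_g * STANDARD_GRAVITY
  mx <- max(abs(ax), abs(ay), abs(az))
  if (mx > lim + 1e-9) {
    stop(sprintf("sample magnitude %.3f m/s^2 exceeds device range +/-%.3f m/s^2",
                 mx, lim), call. = FALSE)
  }
  structure(
    list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         fs = fs, start_time = start_time,
         device_range_g = device_range_g,
         device_resolution_g = device_resolution_g),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  n <- length(x$ax)
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s), range +/-%g g, resolution %g g\n",
              n, x$fs, n / x$fs, x$device_range_g, x$device_resolution_g))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$ax)

#' Resultant acceleration magnitude
#'
#' Collapses the three axes into the resultant acceleration
#' a(t) = sqrt(ax^2 + ay^2 + az^2), the scalar series on which all
#' spectral shivering analysis operates.
#'
#' @param trace An [accel_trace()].
#' @return Numeric vector of the same length as the trace, in m/s^2.
#' @export
resultant_magnitude <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}
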