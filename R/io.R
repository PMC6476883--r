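read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  d
}

#' Read an accelerometer CSV
#'
#' Expects a header `time_s,ax,ay,az` with acceleration in m/s^2 and strictly
#' increasing time; gzip-compressed files are accepted transparently. The
#' sampling rate is inferred from the median time step unless given.
#'
#' @param path CSV (optionally `.gz`) file path.
#' @param fs Sampling rate in Hz; inferred from the time column if `NULL`.
#' @param ... Passed to [accel_trace()] (device metadata).
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path, fs = NULL, ...) {
  d <- read_checked_csv(path, c("time_s", "ax", "ay", "az"), "accelerometer CSV")
  if (any(diff(d$time_s) <= 0)) stop("time_s must be strictly increasing",
                                     call. = FALSE)
  if (is.null(fs)) fs <- 1 / median(diff(d$time_s))
  accel_trace(d$ax, d$ay, d$az, fs = fs, start_time = d$time_s[1], ...)
}

#' Write an accelerometer trace as CSV
#'
#' @param trace An [accel_trace()].
#' @param path Output path (use `.gz` for compression).
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- length(trace$ax)
  d <- tibble::tibble(time_s = trace$start_time + (seq_len(n) - 1L) / trace$fs,
                      ax = trace$ax, ay = trace$ay, az = trace$az)
  readr::write_csv(d, path, progress = FALSE)
  invisible(path)
}

#' Read a multiplexed gas-analyzer CSV
#'
#' Expects a header `time_s,o2_frac,co2_frac`; the channel schedule is
#' supplied separately (see [read_schedule_yaml()]).
#'
#' @param path CSV (optionally `.gz`) file path.
#' @param schedule A [gas_schedule()].
#' @return A [gas_trace()].
#' @export
read_gas_csv <- function(path, schedule = gas_schedule()) {
  d <- read_checked_csv(path, c("time_s", "o2_frac", "co2_frac"), "gas CSV")
  gas_trace(d$time_s, d$o2_frac, d$co2_frac, schedule = schedule)
}

#' Write a gas trace as CSV
#' @param trace A [gas_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_csv <- function(trace, path) {
  stopifnot(inherits(trace, "gas_trace"))
  readr::write_csv(tibble::tibble(time_s = trace$time, o2_frac = trace$o2_frac,
                                  co2_frac = trace$co2_frac),
                   path, progress = FALSE)
  invisible(path)
}

#' Read a cohort table CSV
#'
#' @param path CSV file with at least `animal_id`, `mother_id`, `day`.
#' @return A tibble.
#' @export
read_cohort_csv <- function(path) {
  read_checked_csv(path, c("animal_id", "mother_id", "day"), "cohort CSV")
}

#' Read a session schedule / configuration YAML
#'
#' The YAML may contain `channels`, `slot_s`, `fr_l_per_h` and a
#' `chamber_map` list of `{chamber, animal_id, day}` entries.
#'
#' @param path YAML file path.
#' @return A list with `schedule` (a [gas_schedule()]), `fr_l_per_h` and
#'   `chamber_map` (tibble or `NULL`).
#' @export
read_schedule_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  sch <- gas_schedule(
    channels = if (!is.null(y$channels)) y$channels else c(1:6, 0L),
    slot_s = if (!is.null(y$slot_s)) y$slot_s else 60)
  cm <- NULL
  if (!is.null(y$chamber_map)) {
    cm <- do.call(rbind, lapply(y$chamber_map, function(e) {
      tibble::tibble(chamber = e$chamber, animal_id = e$animal_id,
                     day = if (!is.null(e$day)) e$day else NA)
    }))
  }
  list(schedule = sch, fr_l_per_h = y$fr_l_per_h, chamber_map = cm)
}
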