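JOULES_PER_ML_O2 <- 20.1

#' Multiplexing schedule of the gas analyzer
#'
#' One shared analyzer cycles through several chambers plus one reference
#' (incurrent air) channel. The default mirrors a six-chamber setup with one
#' reference channel, one minute per channel, repeating. Channel `0` denotes
#' the reference.
#'
#' @param channels Integer vector giving the channel visited in each slot of
#'   one cycle; `0` is the reference channel.
#' @param slot_s Duration of one slot in seconds.
#' @return A list of class `gas_schedule`.
#' @export
gas_schedule <- function(channels = c(1:6, 0L), slot_s = 60) {
  stopifnot(length(channels) >= 1L, slot_s > 0)
  structure(list(channels = as.integer(channels), slot_s = slot_s),
            class = "gas_schedule")
}

#' Multiplexed gas-analyzer trace
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param o2_frac Fractional O2 concentration (e.g. 0.2095), in (0, 1).
#' @param co2_frac Fractional CO2 concentration, in `[0, 1)`.
#' @param schedule A [gas_schedule()] describing the channel rotation.
#' @return A list of class `gas_trace`.
#' @export
gas_trace <- function(time, o2_frac, co2_frac, schedule = gas_schedule()) {
  stopifnot(length(time) == length(o2_frac), length(time) == length(co2_frac))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(o2_frac <= 0 | o2_frac >= 1)) stop("o2_frac must lie in (0,1)", call. = FALSE)
  if (any(co2_frac < 0 | co2_frac >= 1)) stop("co2_frac must lie in [0,1)", call. = FALSE)
  stopifnot(inherits(schedule, "gas_schedule"))
  structure(list(time = time, o2_frac = o2_frac, co2_frac = co2_frac,
                 schedule = schedule),
            class = "gas_trace")
}

#' @export
print.gas_trace <- function(x, ...) {
  cat(sprintf("<gas_trace> %d samples over %.0f s, %d-channel schedule x %g s slots\n",
              length(x$time), diff(range(x$time)),
              length(x$schedule$channels), x$schedule$slot_s))
  invisible(x)
}

#' Demultiplex a shared analyzer trace into per-slot channel means
#'
#' The channel measured at time t is `schedule$channels[floor(t / slot_s) mod
#' n_channels + 1]`. The first `washout_s` seconds of every slot are discarded
#' to let the analyzer and tubing equilibrate after the gas switch; the
#' remaining samples are averaged per slot. Slots in which no sample survives
#' the washout are marked missing with a warning.
#'
#' @param trace A [gas_trace()].
#' @param washout_s Seconds discarded at the start of each slot (default 15).
#' @return A tibble with one row per slot: `slot` (0-based), `channel`,
#'   `slot_start_s`, `o2_mean`, `co2_mean`, `n_samples`, `missing`.
#' @export
demux <- function(trace, washout_s = 15) {
  stopifnot(inherits(trace, "gas_trace"), washout_s >= 0)
  sch <- trace$schedule
  nchan <- length(sch$channels)
  slot <- floor(trace$time / sch$slot_s)
  keep <- (trace$time - slot * sch$slot_s) >= washout_s
  slots <- seq.int(min(slot), max(slot))
  out <- lapply(slots, function(s) {
    sel <- keep & slot == s
    n <- sum(sel)
    tibble::tibble(
      slot = s,
      channel = sch$channels[(s %% nchan) + 1L],
      slot_start_s = s * sch$slot_s,
      o2_mean = if (n) mean(trace$o2_frac[sel]) else NA_real_,
      co2_mean = if (n) mean(trace$co2_frac[sel]) else NA_real_,
      n_samples = n,
      missing = n == 0L
    )
  })
  out <- do.call(rbind, out)
  if (any(out$missing)) {
    warning(sum(out$missing), " slot(s) had no samples after washout; marked missing")
  }
  out
}

#' Incurrent-air baseline from reference-channel slots
#'
#' Builds linear interpolators for the incurrent (reference) O2 and CO2
#' fractions from the reference-channel slot means, so slow analyzer or
#' supply-air drift is corrected at each chamber reading's time. Beyond the
#' first/last reference slot the baseline is extrapolated as a constant.
#'
#' @param ref_slots Tibble of reference-channel rows from [demux()] (rows with
#'   `channel == 0` and `missing == FALSE`).
#' @return A list with functions `fio2(t)` and `fico2(t)`.
#' @export
reference_baseline <- function(ref_slots) {
  ref_slots <- ref_slots[!ref_slots$missing, , drop = FALSE]
  if (nrow(ref_slots) == 0L) stop("no reference slots", call. = FALSE)
  mk <- function(y) {
    if (nrow(ref_slots) == 1L) {
      v <- y[1]
      function(t) rep(v, length(t))
    } else {
      x <- ref_slots$slot_start_s
      yy <- y
      function(t) approx(x, yy, xout = t, rule = 2)$y
    }
  }
  list(fio2 = mk(ref_slots$o2_mean), fico2 = mk(ref_slots$co2_mean))
}

#' Oxygen consumption from incurrent/excurrent gas fractions
#'
#' Open-flow pull-mode calculation with water vapour scrubbed and CO2 left in
#' the air stream, flow metered excurrent:
#' \deqn{VO2 = FR \frac{(FiO2 - FeO2) - FeO2 (FeCO2 - FiCO2)}{1 - FeO2}}
#' with FR converted from l/h to ml/h. A negative result (possible with noisy
#' near-zero exchange) is returned with a warning rather than clipped so that
#' downstream selection rules see the measured value.
#'
#' @param fio2,feo2 Incurrent and excurrent fractional O2 (vectorized).
#' @param fico2,feco2 Incurrent and excurrent fractional CO2.
#' @param fr_l_per_h Flow rate through the chamber in l/h.
#' @return VO2 in ml O2 per hour.
#' @export
compute_vo2 <- function(fio2, feo2, fico2, feco2, fr_l_per_h) {
  if (any(feo2 >= 1)) stop("FeO2 must be < 1", call. = FALSE)
  stopifnot(all(fr_l_per_h > 0))
  vo2 <- fr_l_per_h * 1000 * ((fio2 - feo2) - feo2 * (feco2 - fico2)) / (1 - feo2)
  if (any(vo2 < 0, na.rm = TRUE)) {
    warning("negative VO2 value(s) computed; check baseline and fractions")
  }
  vo2
}

#' Minimum-mean run of k consecutive values
#'
#' Finds the contiguous run of `k` values whose mean is smallest; the
#' earliest start wins on ties. Used to select the three lowest consecutive
#' per-slot VO2 readings per measurement, a standard guard against activity
#' artefacts inflating resting metabolic rate.
#'
#' @param values Numeric vector; `NA`s (missing slots) are excluded before
#'   windowing, so runs are contiguous in the surviving sequence.
#' @param k Run length (default 3).
#' @return A list with `mean`, `start_index` (1-based position in the
#'   NA-stripped sequence) and `indices` (positions in the original vector).
#' @export
lowest_consecutive_mean <- function(values, k = 3) {
  pos <- which(!is.na(values))
  v <- values[pos]
  n <- length(v)
  if (n < k) stop("too few readings", call. = FALSE)
  cs <- c(0, cumsum(v))
  means <- (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
  i <- which.min(means) # first minimum = earliest start on ties
  list(mean = means[i], start_index = i, indices = pos[i:(i + k - 1)])
}

#' Convert oxygen consumption to heat production
#'
#' Uses the oxycaloric equivalent 20.1 J per ml O2:
#' W = VO2 (ml/h) x 20.1 / 3600.
#'
#' @param vo2_ml_per_h Oxygen consumption in ml/h (must be >= 0).
#' @return Heat production in watts.
#' @export
heat_production <- function(vo2_ml_per_h) {
  if (any(vo2_ml_per_h < 0)) stop("negative VO2", call. = FALSE)
  vo2_ml_per_h * JOULES_PER_ML_O2 / 3600
}

#' Per-chamber metabolic summary of one multiplexed session
#'
#' Chains the full respirometry pipeline: demultiplex, reference baseline,
#' per-slot VO2, selection of the k lowest consecutive readings, conversion
#' to watts. Only slots starting inside the analysis interval (default
#' 600-2400 s: 10 min acclimation, then 30 min) are used. Chambers with fewer
#' than `k` usable in-window slots are flagged.
#'
#' @param trace A [gas_trace()].
#' @param chamber_map Data frame mapping `chamber` to `animal_id` and `day`;
#'   chambers absent from the map are summarised with `animal_id = NA`.
#' @param fr_l_per_h Flow rate in l/h (single value, or named per chamber).
#' @param washout_s Per-slot washout discarded by [demux()].
#' @param k Number of lowest consecutive slot readings averaged.
#' @param analysis_start_s,analysis_duration_s Analysis interval in seconds.
#' @param mass_g Optional named vector (by animal id) of body mass in grams;
#'   adds a mass-specific `heat_W_per_kg` column for graphical use.
#' @return A list with `slots` (per-slot tibble incl. per-slot VO2) and
#'   `summary` (tibble: one row per chamber with `vo2_ml_per_h`, `heat_W`,
#'   `selected_start_slot`, `n_slots`, `status`).
#' @export
session_metabolic_summary <- function(trace, chamber_map = NULL,
                                      fr_l_per_h, washout_s = 15, k = 3,
                                      analysis_start_s = 600,
                                      analysis_duration_s = 1800,
                                      mass_g = NULL) {
  slots <- demux(trace, washout_s = washout_s)
  base <- reference_baseline(slots[slots$channel == 0L, , drop = FALSE])
  ch_slots <- slots[slots$channel != 0L, , drop = FALSE]
  ch_slots$fio2 <- base$fio2(ch_slots$slot_start_s)
  ch_slots$fico2 <- base$fico2(ch_slots$slot_start_s)
  chambers <- sort(unique(ch_slots$channel))
  fr_of <- function(ch) {
    if (length(fr_l_per_h) == 1L && is.null(names(fr_l_per_h))) return(fr_l_per_h)
    unname(fr_l_per_h[as.character(ch)])
  }
  ch_slots$vo2_ml_per_h <- NA_real_
  ok <- !ch_slots$missing
  if (any(ok)) {
    ch_slots$vo2_ml_per_h[ok] <- compute_vo2(
      ch_slots$fio2[ok], ch_slots$o2_mean[ok],
      ch_slots$fico2[ok], ch_slots$co2_mean[ok],
      vapply(ch_slots$channel[ok], fr_of, numeric(1)))
  }
  in_win <- ch_slots$slot_start_s >= analysis_start_s &
    ch_slots$slot_start_s < analysis_start_s + analysis_duration_s
  summ <- lapply(chambers, function(ch) {
    sel <- ch_slots[in_win & ch_slots$channel == ch & !ch_slots$missing, ,
                    drop = FALSE]
    row <- tibble::tibble(chamber = ch, animal_id = NA, day = NA,
                          flow_l_per_h = fr_of(ch), n_slots = nrow(sel),
                          vo2_ml_per_h = NA_real_, heat_W = NA_real_,
                          selected_start_slot = NA_integer_, status = "ok")
    if (!is.null(chamber_map)) {
      m <- chamber_map[chamber_map$chamber == ch, , drop = FALSE]
      if (nrow(m) == 1L) {
        row$animal_id <- m$animal_id
        if ("day" %in% names(m)) row$day <- m$day
      }
    }
    if (nrow(sel) < k) {
      row$status <- "too_few_slots"
      return(row)
    }
    low <- lowest_consecutive_mean(sel$vo2_ml_per_h, k = k)
    row$vo2_ml_per_h <- low$mean
    row$selected_start_slot <- sel$slot[low$start_index]
    if (low$mean >= 0) {
      row$heat_W <- heat_production(low$mean)
    } else {
      row$status <- "negative_vo2"
    }
    row
  })
  summ <- do.call(rbind, summ)
  if (!is.null(mass_g)) {
    m <- unname(mass_g[as.character(summ$animal_id)])
    summ$mass_g <- m
    summ$heat_W_per_kg <- summ$heat_W / (m / 1000)
  }
  list(slots = ch_slots, summary = summ)
}
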