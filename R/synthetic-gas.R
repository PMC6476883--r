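#' Specification of a synthetic multiplexed respirometry session
#'
#' Forward model for [gen_gas_trace()]: each chamber's excurrent fractions
#' are the steady-state solution of the same open-flow mass balance that
#' [compute_vo2()] inverts, approached from incurrent air with a first-order
#' chamber washout; the shared analyzer switches channels per the schedule
#' with a fast first-order switching transient, and Gaussian analyzer noise
#' is added.
#'
#' @param true_vo2_ml_h Numeric vector of true VO2 per chamber, ml/h.
#' @param rq Respiratory quotient; `true_vco2_ml_h` defaults to
#'   `rq * true_vo2_ml_h`.
#' @param true_vco2_ml_h True VCO2 per chamber, ml/h.
#' @param fr_l_per_h Flow rate through each chamber, l/h.
#' @param fio2,fico2 Incurrent fractions at t = 0.
#' @param drift_o2_per_h,drift_co2_per_h Linear drift of the incurrent
#'   fractions, per hour (analyzer/supply drift seen by all channels).
#' @param noise_sd Analyzer noise SD on the reported fractions.
#' @param chamber_volume_l Chamber volume in litres (default 20).
#' @param chamber_tau_s First-order chamber washout time constant in seconds;
#'   defaults to 60 s.
#' @param switch_tau_s Analyzer/tubing equilibration time constant after a
#'   channel switch, seconds.
#' @param schedule A [gas_schedule()]; channel i draws from
#'   `true_vo2_ml_h[i]`, channel 0 from incurrent air.
#' @param duration_s Session length in seconds.
#' @param sample_dt_s Analyzer sampling interval in seconds.
#' @param seed Integer seed.
#' @return A list of class `chamber_spec`.
#' @export
chamber_spec <- function(true_vo2_ml_h = seq(800, 1800, by = 200),
                         rq = 0.8,
                         true_vco2_ml_h = rq * true_vo2_ml_h,
                         fr_l_per_h = 250,
                         fio2 = 0.2095, fico2 = 0.0004,
                         drift_o2_per_h = 0, drift_co2_per_h = 0,
                         noise_sd = 2e-5,
                         chamber_volume_l = 20,
                         chamber_tau_s = 60,
                         switch_tau_s = 3,
                         schedule = gas_schedule(c(seq_along(true_vo2_ml_h), 0L)),
                         duration_s = 2400, sample_dt_s = 1,
                         seed = 1L) {
  stopifnot(all(true_vo2_ml_h >= 0), fr_l_per_h > 0,
            fio2 > 0, fio2 < 1, fico2 >= 0, fico2 < 1,
            chamber_volume_l > 0, chamber_tau_s > 0, switch_tau_s > 0,
            duration_s > 0, sample_dt_s > 0, noise_sd >= 0)
  structure(list(true_vo2_ml_h = true_vo2_ml_h,
                 true_vco2_ml_h = true_vco2_ml_h,
                 fr_l_per_h = fr_l_per_h, fio2 = fio2, fico2 = fico2,
                 drift_o2_per_h = drift_o2_per_h,
                 drift_co2_per_h = drift_co2_per_h,
                 noise_sd = noise_sd,
                 chamber_volume_l = chamber_volume_l,
                 chamber_tau_s = chamber_tau_s,
                 switch_tau_s = switch_tau_s,
                 schedule = schedule, duration_s = duration_s,
                 sample_dt_s = sample_dt_s, seed = as.integer(seed)),
            class = "chamber_spec")
}

#' Steady-state excurrent fractions for a given true gas exchange
#'
#' Solves the open-flow mass balance used by [compute_vo2()] exactly for
#' FeO2 and FeCO2 given true VO2/VCO2, so generator and analysis share one
#' mass balance and are exact inverses at noiseless steady state.
#'
#' @param vo2_ml_h,vco2_ml_h True gas exchange rates, ml/h.
#' @param fr_l_per_h Flow rate, l/h.
#' @param fio2,fico2 Incurrent fractions.
#' @return A list with `feo2` and `feco2`.
#' @export
steady_state_fractions <- function(vo2_ml_h, vco2_ml_h, fr_l_per_h,
                                   fio2 = 0.2095, fico2 = 0.0004) {
  fr <- fr_l_per_h * 1000
  feco2 <- fico2 + vco2_ml_h / fr
  d <- feco2 - fico2
  feo2 <- (fr * fio2 - vo2_ml_h) / (fr * (1 + d) - vo2_ml_h)
  if (any(feo2 <= 0 | feo2 >= 1) || any(feco2 < 0 | feco2 >= 1)) {
    stop("infeasible steady state: excurrent fraction outside (0,1)",
         call. = FALSE)
  }
  list(feo2 = feo2, feco2 = feco2)
}

#' Generate a synthetic multiplexed gas-analyzer trace
#'
#' @param spec A [chamber_spec()].
#' @return A list with `trace` (a [gas_trace()]) and `truth` (per-chamber
#'   true VO2/VCO2, steady-state fractions, drift lines, and the spec).
#' @export
gen_gas_trace <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  withr::with_seed(spec$seed, {
    tt <- seq(0, spec$duration_s - spec$sample_dt_s, by = spec$sample_dt_s)
    n <- length(tt)
    fio2_t <- spec$fio2 + spec$drift_o2_per_h * tt / 3600
    fico2_t <- spec$fico2 + spec$drift_co2_per_h * tt / 3600
    ss <- steady_state_fractions(spec$true_vo2_ml_h, spec$true_vco2_ml_h,
                                 spec$fr_l_per_h, spec$fio2, spec$fico2)
    # deficits relative to incurrent air are flow-determined, so under supply
    # drift the excurrent level tracks the drift line at constant offset
    def_o2 <- spec$fio2 - ss$feo2
    def_co2 <- ss$feco2 - spec$fico2
    washin <- 1 - exp(-tt / spec$chamber_tau_s) # animal enters at t = 0
    sch <- spec$schedule
    nchan <- length(sch$channels)
    slot <- floor(tt / sch$slot_s)
    chan <- sch$channels[(slot %% nchan) + 1L]
    target_o2 <- fio2_t
    target_co2 <- fico2_t
    for (i in seq_along(spec$true_vo2_ml_h)) {
      sel <- chan == i
      target_o2[sel] <- fio2_t[sel] - def_o2[i] * washin[sel]
      target_co2[sel] <- fico2_t[sel] + def_co2[i] * washin[sel]
    }
    # analyzer relaxes toward the selected channel with the switch transient
    o2 <- target_o2
    co2 <- target_co2
    decay <- exp(-(tt - slot * sch$slot_s) / spec$switch_tau_s)
    for (s in unique(slot)) {
      sel <- which(slot == s)
      first <- sel[1]
      if (first == 1L) next
      o2[sel] <- target_o2[sel] + (o2[first - 1L] - target_o2[first]) * decay[sel]
      co2[sel] <- target_co2[sel] + (co2[first - 1L] - target_co2[first]) * decay[sel]
    }
    o2 <- o2 + rnorm(n, 0, spec$noise_sd)
    co2 <- pmax(co2 + rnorm(n, 0, spec$noise_sd), 0)
    trace <- gas_trace(tt, o2, co2, schedule = sch)
    truth <- list(true_vo2_ml_h = spec$true_vo2_ml_h,
                  true_vco2_ml_h = spec$true_vco2_ml_h,
                  feo2_ss = ss$feo2, feco2_ss = ss$feco2,
                  fio2_at = function(t) spec$fio2 + spec$drift_o2_per_h * t / 3600,
                  fico2_at = function(t) spec$fico2 + spec$drift_co2_per_h * t / 3600,
                  spec = spec)
    list(trace = trace, truth = truth)
  })
}
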