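#' Configuration for an end-to-end synthetic run
#'
#' Bundles every stage parameter and the single seed from which all
#' randomness flows. The default sizes are deliberately small (short
#' accelerometer recordings, a handful of instrumented animals) so a full
#' run finishes in seconds; the study-scale values are the generator
#' defaults and can be requested explicitly.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_accel_animals Animals per day given a simulated accelerometer
#'   recording.
#' @param accel_duration_s,accel_start_s,accel_analysis_s Accelerometer
#'   recording length and analysis interval (seconds).
#' @param window_s FFT window length (seconds).
#' @param band_lo,band_hi Shivering band edges in Hz.
#' @param gas_duration_s Gas session length (seconds).
#' @param gas_analysis_start_s,gas_analysis_s Respirometry analysis interval.
#' @param washout_s Demultiplexer washout (seconds).
#' @param fr_l_per_h Named-by-day flow rates in l/h (defaults: 250 on day 1,
#'   330 on day 5).
#' @param cohort A [cohort_spec()]; its seed is overridden by `seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       n_accel_animals = 2L,
                       accel_duration_s = 180, accel_start_s = 30,
                       accel_analysis_s = 120, window_s = 6,
                       band_lo = 10, band_hi = 30,
                       gas_duration_s = 2400,
                       gas_analysis_start_s = 600, gas_analysis_s = 1800,
                       washout_s = 15,
                       fr_l_per_h = c("1" = 250, "5" = 330),
                       cohort = cohort_spec()) {
  if (band_hi <= band_lo || band_lo <= 0) {
    stop("invalid band: need 0 < band_lo < band_hi", call. = FALSE)
  }
  if (band_hi > 1600 / 2) stop("band_hi exceeds the Nyquist frequency",
                               call. = FALSE)
  if (accel_start_s + window_s > accel_duration_s) {
    stop("accelerometer analysis window does not fit the recording",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, accelerometer recordings and one multiplexed gas
#' session per day; runs the shivering and respirometry analyses; fits the
#' age-effect and expression models on the cohort table; and writes every
#' artifact plus a manifest with content hashes. A rerun with the same
#' configuration and seed reproduces identical hashes.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- config$cohort
  cohort$seed <- config$seed
  gc <- gen_cohort(cohort)
  tab <- gc$table
  out <- list()
  p <- function(f) file.path(config$out_dir, f)

  readr::write_csv(tab, p("cohort.csv"), progress = FALSE)
  out$cohort <- p("cohort.csv")
  jsonlite::write_json(
    list(day_difference = as.list(gc$truth$day_difference),
         mother_of = gc$truth$mother_of,
         seed = config$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  out$truth <- p("truth.json")

  # accelerometry: one synthetic recording per instrumented animal-day,
  # tremor amplitude taken from the cohort's shivering column
  ids <- unique(tab$animal_id)[seq_len(min(config$n_accel_animals,
                                           length(unique(tab$animal_id))))]
  peaks <- list(); summaries <- list()
  for (id in ids) {
    for (dy in c(1L, 5L)) {
      row <- tab[tab$animal_id == id & tab$day == dy, ]
      sp <- tremor_spec(mass_g = row$mass_g,
                        tremor_amp = max(row$shiver_intensity, 0.1),
                        tremor_axis = "gravity",
                        duration_s = config$accel_duration_s,
                        seed = config$seed + 7L * match(id, ids) + dy)
      sim <- gen_accel_trace(sp)
      res <- analyze_shivering(sim$trace,
                               band = shiver_band(config$band_lo, config$band_hi),
                               mass_g = row$mass_g,
                               window_s = config$window_s,
                               analysis_start_s = config$accel_start_s,
                               analysis_duration_s = config$accel_analysis_s,
                               animal_id = id, day = dy)
      peaks[[length(peaks) + 1L]] <- res$peaks
      summaries[[length(summaries) + 1L]] <- res$summary
    }
  }
  readr::write_csv(do.call(rbind, peaks), p("accel_peaks.csv"), progress = FALSE)
  readr::write_csv(do.call(rbind, summaries), p("shivering_summary.csv"),
                   progress = FALSE)
  out$accel_peaks <- p("accel_peaks.csv")
  out$shivering_summary <- p("shivering_summary.csv")

  # respirometry: one 6-chamber session per day; chamber true VO2 derived
  # from the cohort's heat production via the 20.1 J/ml oxycaloric equivalent
  vo2 <- list()
  for (dy in c(1L, 5L)) {
    rows <- tab[tab$day == dy, ][seq_len(min(6L, sum(tab$day == dy))), ]
    true_vo2 <- rows$heat_W * 3600 / JOULES_PER_ML_O2
    fr <- unname(config$fr_l_per_h[as.character(dy)])
    gs <- gen_gas_trace(chamber_spec(true_vo2_ml_h = true_vo2,
                                     fr_l_per_h = fr,
                                     duration_s = config$gas_duration_s,
                                     seed = config$seed + 100L + dy))
    cm <- tibble::tibble(chamber = seq_len(nrow(rows)),
                         animal_id = rows$animal_id, day = dy)
    sm <- session_metabolic_summary(
      gs$trace, chamber_map = cm, fr_l_per_h = fr,
      washout_s = config$washout_s,
      analysis_start_s = config$gas_analysis_start_s,
      analysis_duration_s = config$gas_analysis_s,
      mass_g = stats::setNames(rows$mass_g, rows$animal_id))
    vo2[[length(vo2) + 1L]] <- sm$summary
  }
  readr::write_csv(do.call(rbind, vo2), p("vo2_summary.csv"), progress = FALSE)
  out$vo2_summary <- p("vo2_summary.csv")

  # inference on the cohort table
  models <- list(
    serca_activity_by_day = fit_mixed(tab, model_spec("serca_activity", "day",
                                                      weights_by_day = TRUE)),
    activity_by_expression = fit_mixed(tab, model_spec(
      "serca_activity", c("serca1a_expr", "sln_expr"))),
    heat_by_day_mass = fit_mixed(tab, model_spec("heat_W", c("day", "mass_g")))
  )
  model_json <- lapply(models, function(m) {
    if (!m$converged) return(list(converged = FALSE))
    list(converged = TRUE,
         fixed = as.list(stats::setNames(m$fixed$estimate, m$fixed$term)),
         anova = lapply(seq_len(nrow(m$anova)), function(i) {
           list(term = m$anova$term[i], chisq = m$anova$chisq[i],
                df = m$anova$df[i], p = m$anova$p[i])
         }),
         varcomp = m$varcomp[c("mother", "animal", "residual")],
         r2_marginal = m$r2_marginal)
  })
  jsonlite::write_json(model_json, p("models.json"), auto_unbox = TRUE,
                       digits = NA)
  out$models <- p("models.json")

  cfg <- config
  cfg$cohort <- unclass(cfg$cohort)
  cfg$cohort$responses <- as.list(cfg$cohort$responses)
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
    config_hash = digest_string(as.character(cfg_json))
  )
  manifest$artifacts <- lapply(names(out), function(k) {
    list(name = k, path = basename(out[[k]]),
         md5 = unname(tools::md5sum(out[[k]])))
  })
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
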