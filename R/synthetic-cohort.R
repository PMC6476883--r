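#' Default per-day response distributions for the synthetic cohort
#'
#' Means and per-day residual SDs for each response, on the scales used in
#' neonatal piglet cold-exposure work: body mass (g), rectal body temperature
#' before/after cold exposure (deg C), SERCA activity (ATP hydrolysed per min
#' and mg total protein), SERCA1a and sarcolipin expression (target/reference
#' copy ratios), shivering intensity (m/s^2), mean shivering frequency (Hz)
#' and heat production (W). Day-5 expression and activity are more variable
#' than day-1 (heteroscedasticity), and shivering intensity halves from day 1
#' to day 5 while total heat rises roughly in proportion to body mass.
#'
#' @return A data frame with columns `variable`, `mean_d1`, `sd_d1`,
#'   `mean_d5`, `sd_d5`.
#' @export
cohort_defaults <- function() {
  tibble::tibble(
    variable = c("mass_g", "tb_before", "tb_after", "serca_activity",
                 "serca1a_expr", "sln_expr", "shiver_intensity",
                 "shiver_freq_hz", "heat_W"),
    mean_d1 = c(1411.9, 38.6, 38.6, 0.36, 1.0, 1.0, 2.0, 17.97, 8.5),
    sd_d1   = c(16.5,   0.09, 0.09, 0.07, 0.30, 0.30, 0.40, 1.66, 1.2),
    mean_d5 = c(1987.6, 39.2, 39.0, 0.96, 2.0, 2.5, 1.0, 17.97, 11.9),
    sd_d5   = c(29.0,   0.07, 0.07, 0.12, 0.80, 1.00, 0.25, 1.66, 1.6)
  )
}

#' Specification of a synthetic animal cohort
#'
#' Each response is generated as
#' `day mean + mother effect + animal effect + residual`, with animals nested
#' in mothers and measured on both days (the repeated-measures unit). The
#' animal-level random SD defaults to half the variable's pooled residual SD
#' and the mother-level SD to half of that. The two expression responses
#' (and their animal effects) are correlated with coefficient `expr_cor`, and
#' SERCA activity can optionally be driven by the expression values through
#' stated slopes instead of being drawn independently.
#'
#' @param n_mothers Number of mothers (default 5).
#' @param litter_sizes Integer vector of animals per mother (default 3 each,
#'   giving the 15-animal scale of a biopsy-limited cohort).
#' @param responses Data frame in the format of [cohort_defaults()].
#' @param animal_sd_scale Animal random-effect SD as a fraction of the
#'   variable's pooled residual SD.
#' @param mother_sd_scale Mother random-effect SD as a fraction of the
#'   animal-level SD.
#' @param expr_cor Correlation between SERCA1a and SLN expression (residuals
#'   and animal effects), default 0.7.
#' @param activity_model `NULL` to draw SERCA activity from its own day
#'   distribution, or a list with `intercept`, `slope_sln`, `slope_serca1a`
#'   and `resid_sd` to generate it from the expression columns.
#' @param exposure_min_range Range (min) of cold-exposure duration.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mothers = 5,
                        litter_sizes = rep(3L, n_mothers),
                        responses = cohort_defaults(),
                        animal_sd_scale = 0.5,
                        mother_sd_scale = 0.5,
                        expr_cor = 0.7,
                        activity_model = NULL,
                        exposure_min_range = c(60, 90),
                        seed = 1L) {
  if (length(litter_sizes) != n_mothers) {
    stop("litter_sizes must have one entry per mother", call. = FALSE)
  }
  stopifnot(all(litter_sizes >= 1), all(responses$sd_d1 >= 0),
            all(responses$sd_d5 >= 0), abs(expr_cor) < 1,
            animal_sd_scale >= 0, mother_sd_scale >= 0)
  structure(list(n_mothers = n_mothers, litter_sizes = as.integer(litter_sizes),
                 responses = responses, animal_sd_scale = animal_sd_scale,
                 mother_sd_scale = mother_sd_scale, expr_cor = expr_cor,
                 activity_model = activity_model,
                 exposure_min_range = exposure_min_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table with known ground truth
#'
#' @param spec A [cohort_spec()].
#' @return A list with `table` (tibble: one row per animal x day with columns
#'   `animal_id`, `mother_id`, `day`, the responses of
#'   [cohort_defaults()] and `exposure_min`) and `truth` (all generating
#'   parameters plus the realised mother/animal effects).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n_animals <- sum(spec$litter_sizes)
    mother_of <- rep(seq_len(spec$n_mothers), times = spec$litter_sizes)
    days <- c(1L, 5L)
    resp <- spec$responses
    tab <- tibble::tibble(
      animal_id = sprintf("A%02d", rep(seq_len(n_animals), each = 2L)),
      mother_id = sprintf("M%d", rep(mother_of, each = 2L)),
      day = rep(days, n_animals)
    )
    d5 <- tab$day == 5L
    # correlated standard normals for the two expression responses
    z1 <- rnorm(nrow(tab))
    z2 <- spec$expr_cor * z1 + sqrt(1 - spec$expr_cor^2) * rnorm(nrow(tab))
    za1 <- rnorm(n_animals)
    za2 <- spec$expr_cor * za1 + sqrt(1 - spec$expr_cor^2) * rnorm(n_animals)
    mother_eff <- list()
    animal_eff <- list()
    for (i in seq_len(nrow(resp))) {
      v <- resp$variable[i]
      pooled_sd <- mean(c(resp$sd_d1[i], resp$sd_d5[i]))
      a_sd <- spec$animal_sd_scale * pooled_sd
      m_sd <- spec$mother_sd_scale * a_sd
      m_eff <- rnorm(spec$n_mothers, 0, m_sd)
      a_eff <- switch(v,
        serca1a_expr = a_sd * za1,
        sln_expr = a_sd * za2,
        rnorm(n_animals, 0, a_sd))
      z <- switch(v, serca1a_expr = z1, sln_expr = z2, rnorm(nrow(tab)))
      day_mean <- ifelse(d5, resp$mean_d5[i], resp$mean_d1[i])
      day_sd <- ifelse(d5, resp$sd_d5[i], resp$sd_d1[i])
      tab[[v]] <- day_mean + m_eff[mother_of][rep(seq_len(n_animals), each = 2L)] +
        rep(a_eff, each = 2L) + day_sd * z
      mother_eff[[v]] <- m_eff
      animal_eff[[v]] <- a_eff
    }
    if (!is.null(spec$activity_model)) {
      am <- spec$activity_model
      tab$serca_activity <- am$intercept +
        am$slope_sln * tab$sln_expr +
        am$slope_serca1a * tab$serca1a_expr +
        rnorm(nrow(tab), 0, am$resid_sd)
    }
    tab$exposure_min <- rep(runif(n_animals, spec$exposure_min_range[1],
                                  spec$exposure_min_range[2]), each = 2L)
    truth <- list(spec = spec, mother_of = mother_of,
                  mother_effects = mother_eff, animal_effects = animal_eff,
                  day_difference = stats::setNames(
                    resp$mean_d5 - resp$mean_d1, resp$variable))
    list(table = tab, truth = truth)
  })
}
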