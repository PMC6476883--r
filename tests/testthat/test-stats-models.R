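test_that("mixed fit reduces to ordinary least squares at zero random variance", {
  sp <- cohort_spec(animal_sd_scale = 0, mother_sd_scale = 0, seed = 13)
  tab <- gen_cohort(sp)$table
  f <- fit_mixed(tab, model_spec("serca_activity", "day"))
  ols <- lm(serca_activity ~ factor(day), data = tab)
  expect_true(f$converged)
  expect_equal(unname(f$fixed$estimate), unname(coef(ols)), tolerance = 1e-6)
})

test_that("type-II chi-square of a single two-level term equals the squared Wald z", {
  tab <- gen_cohort(cohort_spec(seed = 14))$table
  f <- fit_mixed(tab, model_spec("serca_activity", "day"))
  z <- f$fixed$estimate[f$fixed$term == "day5"] /
    f$fixed$se[f$fixed$term == "day5"]
  expect_equal(f$anova$chisq[f$anova$term == "day"], z^2, tolerance = 1e-6)
})

test_that("a constant response yields a null day effect", {
  tab <- gen_cohort(cohort_spec(seed = 15))$table
  tab$serca_activity <- 0.5 + 1e-9 * seq_len(nrow(tab)) # avoid exact singularity
  f <- fit_mixed(tab, model_spec("serca_activity", "day"))
  expect_lt(abs(f$fixed$estimate[f$fixed$term == "day5"]), 1e-8)
})

test_that("unknown model terms and missing values are rejected", {
  tab <- gen_cohort(cohort_spec(seed = 16))$table
  expect_error(fit_mixed(tab, model_spec("serca_activity", "no_such_column")),
               "no_such_column")
  tab$serca_activity[1] <- NA
  expect_error(fit_mixed(tab, model_spec("serca_activity", "day")), "missing values")
})

test_that("variance components are non-negative and per-day weights track the injected SD ratio", {
  ratios <- sapply(1:30, function(s) {
    tab <- gen_cohort(cohort_spec(seed = 300 + s))$table
    f <- fit_mixed(tab, model_spec("serca_activity", "day", weights_by_day = TRUE))
    expect_true(all(unlist(f$varcomp[c("mother", "animal", "residual")]) >= 0))
    unname(f$varcomp$day_sd_ratio["5"] / f$varcomp$day_sd_ratio["1"])
  })
  expect_lt(abs(median(ratios) / (0.12 / 0.07) - 1), 0.25)
})

test_that("Box-Cox matches its defining transforms and recovers log-normality", {
  y <- c(1, 2, 5, 9)
  d <- data.frame(y = y)
  # lambda = 1: shape-preserving shift y - 1
  expect_equal((y^1 - 1) / 1, y - 1)
  bc <- box_cox(y, lambda_grid = 0) # forced lambda = 0 -> natural log
  expect_equal(bc$transformed, log(y))

  set.seed(17)
  bc <- box_cox(exp(rnorm(500)))
  expect_lt(abs(bc$lambda_hat), 0.25)

  expect_error(box_cox(c(1, -2, 3)), "positive")
})

test_that("Shapiro-Wilk diagnostics are calibrated under normality and powerful under skew", {
  set.seed(18)
  p_null <- replicate(200, shapiro.test(rnorm(100))$p.value)
  expect_lt(abs(median(p_null) - 0.5), 0.12)
  p_skew <- replicate(100, shapiro.test(exp(rnorm(100)))$p.value)
  expect_gt(mean(p_skew < 0.05), 0.95)

  tab <- gen_cohort(cohort_spec(seed = 19))$table
  f <- fit_mixed(tab, model_spec("serca_activity", "day"))
  r <- residual_normality(f)
  expect_true(r$p >= 0 && r$p <= 1 && r$W <= 1)
  expect_error(shapiro.test(rep(1, 10)))
})

test_that("auto transform engages only when residuals reject normality", {
  tab <- gen_cohort(cohort_spec(seed = 20))$table
  f <- fit_mixed(tab, model_spec("serca_activity", "day", transform = "auto"))
  if (is.na(f$lambda)) {
    expect_gte(f$shapiro$p, 0.05)
  } else {
    expect_true(is.finite(f$lambda))
  }
  tab$heat_W <- exp(tab$heat_W / 4) # force a right-skewed response
  f2 <- fit_mixed(tab, model_spec("heat_W", "day", transform = "boxcox"))
  expect_true(is.finite(f2$lambda))
})

test_that("marginal pseudo-r2 spans its limits and recovers a known partition", {
  tab <- gen_cohort(cohort_spec(seed = 21))$table
  tab$flat <- rnorm(nrow(tab), 10, 0.5)
  f0 <- fit_mixed(tab, model_spec("flat", "day"))
  expect_lt(f0$r2_marginal, 0.15) # no fixed-effect variance injected

  f1 <- fit_mixed(tab, model_spec("serca_activity", "day"))
  expect_gt(f1$r2_marginal, 0.5) # day difference dominates this response
  expect_true(f1$r2_marginal <= 1)

  # 50/50 fixed/random+residual partition at larger n
  set.seed(22)
  n <- 250
  d <- tibble::tibble(
    animal_id = sprintf("A%03d", rep(1:n, each = 2)),
    mother_id = sprintf("M%02d", rep(rep(1:50, length.out = n), each = 2)),
    day = rep(c(1, 5), n))
  delta <- 2 # var of +/-1 split = 1
  d$y <- ifelse(d$day == 5, delta / 2, -delta / 2) + rnorm(2 * n, 0, 1)
  f <- fit_mixed(d, model_spec("y", "day"))
  expect_lt(abs(f$r2_marginal - 0.5), 0.1)
})

test_that("partial regression slopes equal the full-model coefficients", {
  set.seed(23)
  for (s in 1:20) {
    tab <- gen_cohort(cohort_spec(seed = 400 + s))$table
    pr <- partial_regression(tab, model_spec("serca_activity",
                                             c("serca1a_expr", "sln_expr")))
    # the internal Frisch-Waugh assertion ran; check the pairs reproduce it
    fit <- lm(y_resid ~ 0 + x_resid, data = pr$sln_expr$residual_pairs)
    expect_equal(unname(coef(fit)), pr$sln_expr$slope, tolerance = 1e-8)
  }
})

test_that("orthogonal predictors give partial slopes equal to single-predictor slopes", {
  set.seed(24)
  n <- 60
  d <- tibble::tibble(
    animal_id = sprintf("A%03d", rep(1:n, each = 2)),
    mother_id = sprintf("M%02d", rep(rep(1:12, length.out = n), each = 2)),
    day = rep(c(1, 5), n))
  x1 <- rnorm(2 * n)
  x2 <- residuals(lm(rnorm(2 * n) ~ x1)) # exactly orthogonal to x1
  d$x1 <- x1; d$x2 <- as.numeric(x2)
  d$y <- 0.8 * d$x1 + 0.3 * d$x2 + rnorm(2 * n, 0, 0.5)
  pr <- partial_regression(d, model_spec("y", c("x1", "x2")))
  f1 <- fit_mixed(d, model_spec("y", "x1"))
  expect_equal(pr$x1$slope, f1$fixed$estimate[f1$fixed$term == "x1"],
               tolerance = 0.05)
  expect_error(
    partial_regression(within(d, x2 <- x1 + 1e-9 * rnorm(2 * n)),
                       model_spec("y", c("x1", "x2"))),
    "collinear")
})
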