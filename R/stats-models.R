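#' Mixed-model specification
#'
#' Describes one linear mixed-effects model on the cohort table: a response,
#' fixed-effect terms, the nested random structure (animal ID within mother,
#' the repeated-measures unit across days), an optional per-day residual
#' variance (heteroscedasticity correction) and an optional Box-Cox
#' transform of the response.
#'
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect column names (e.g.
#'   `"day"`, or `c("day", "mass_g")`). `day` is modelled as a two-level
#'   factor.
#' @param weights_by_day If `TRUE`, estimate a distinct residual variance per
#'   day level (`nlme::varIdent`).
#' @param transform `"none"`, `"boxcox"` (always transform) or `"auto"`
#'   (transform only when a Shapiro-Wilk test on the untransformed fit's
#'   residuals rejects normality at p < 0.05).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, fixed = "day", weights_by_day = FALSE,
                       transform = c("none", "boxcox", "auto")) {
  transform <- match.arg(transform)
  stopifnot(is.character(response), length(response) == 1L,
            is.character(fixed), length(fixed) >= 1L)
  structure(list(response = response, fixed = fixed,
                 weights_by_day = weights_by_day, transform = transform),
            class = "model_spec")
}

#' Box-Cox transformation with grid profile-likelihood
#'
#' Transforms positive data with `y(lambda) = (y^lambda - 1)/lambda`
#' (`log y` at `lambda = 0`), choosing `lambda` to maximise the Box-Cox
#' profile log-likelihood over a grid.
#'
#' @param values Positive numeric vector.
#' @param lambda_grid Candidate `lambda` values (default -2 to 2 by 0.01).
#' @return A list with `transformed`, `lambda_hat` and the profile
#'   (`lambda`, `loglik`).
#' @export
box_cox <- function(values, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox requires positive values", call. = FALSE)
  }
  d <- data.frame(y = values)
  prof <- MASS::boxcox(y ~ 1, data = d, lambda = lambda_grid, plotit = FALSE)
  lambda_hat <- prof$x[which.max(prof$y)]
  transformed <- if (abs(lambda_hat) < 1e-12) log(values) else
    (values^lambda_hat - 1) / lambda_hat
  list(transformed = transformed, lambda_hat = lambda_hat,
       lambda = prof$x, loglik = prof$y)
}

fit_lme_quietly <- function(formula, data, weights) {
  ctrl <- nlme::lmeControl(returnObject = TRUE, maxIter = 200, msMaxIter = 200)
  args <- list(fixed = formula, random = ~ 1 | mother_id / animal_id,
               data = data, method = "REML", control = ctrl)
  if (!is.null(weights)) args$weights <- weights
  fit <- try(suppressWarnings(do.call(nlme::lme, args)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    ctrl$opt <- "optim"
    args$control <- ctrl
    fit <- try(suppressWarnings(do.call(nlme::lme, args)), silent = TRUE)
  }
  fit
}

#' Fit a linear mixed model with nested random effects
#'
#' REML fit of `response ~ fixed terms` with random intercepts for mother and
#' for animal nested within mother, followed by type-II Wald chi-square tests
#' per fixed term (the mixed-model analogue of a type-II ANOVA), variance
#' components, a marginal pseudo-r-squared and residual diagnostics.
#' A singular or non-converged fit is returned flagged
#' (`converged = FALSE`), never raised as an error.
#'
#' @param table Cohort data frame with columns `mother_id`, `animal_id`,
#'   `day` and the modelled variables; no missing values in modelled columns.
#' @param spec A [model_spec()].
#' @return A list of class `shiver_fit` with elements `model` (the `lme`
#'   fit), `fixed` (tibble: term, estimate, se), `anova` (tibble: term,
#'   chisq, df, p), `varcomp` (mother, animal, residual variances and any
#'   per-day SD ratios), `r2_marginal`, `shapiro` (W, p), `lambda`
#'   (Box-Cox, `NA` if untransformed), `converged` and `spec`.
#' @export
fit_mixed <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("mother_id", "animal_id", "day", spec$response,
            setdiff(spec$fixed, "day"))
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("unknown term/column: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- as.data.frame(table[, need])
  if (anyNA(d)) stop("missing values in modelled columns", call. = FALSE)
  d$mother_id <- factor(d$mother_id)
  d$animal_id <- factor(d$animal_id)
  d$day <- factor(d$day)
  if (length(unique(d$mother_id)) < 2L) stop("need >= 2 mothers", call. = FALSE)
  lambda <- NA_real_
  y <- d[[spec$response]]
  d$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(spec$fixed, collapse = " + ")))
  wts <- if (spec$weights_by_day) nlme::varIdent(form = ~ 1 | day) else NULL
  fit <- fit_lme_quietly(fml, d, wts)
  shap <- NULL
  if (!inherits(fit, "try-error")) {
    shap <- try(residual_normality(fit), silent = TRUE)
    need_bc <- spec$transform == "boxcox" ||
      (spec$transform == "auto" && !inherits(shap, "try-error") &&
         shap$p < 0.05)
    if (need_bc) {
      bc <- box_cox(y)
      lambda <- bc$lambda_hat
      d$.y <- bc$transformed
      fit <- fit_lme_quietly(fml, d, wts)
      if (!inherits(fit, "try-error")) {
        shap <- try(residual_normality(fit), silent = TRUE)
      }
    }
  }
  if (inherits(fit, "try-error")) {
    return(structure(list(model = NULL, fixed = NULL, anova = NULL,
                          varcomp = NULL, r2_marginal = NA_real_,
                          shapiro = NULL, lambda = lambda,
                          converged = FALSE, spec = spec, data = d),
                     class = "shiver_fit"))
  }
  sm <- summary(fit)$tTable
  fixed <- tibble::tibble(term = rownames(sm),
                          estimate = unname(sm[, "Value"]),
                          se = unname(sm[, "Std.Error"]))
  an <- suppressWarnings(car::Anova(fit, type = "II"))
  anova_tab <- tibble::tibble(term = rownames(an), chisq = an[, "Chisq"],
                              df = an[, "Df"],
                              p = round(an[, "Pr(>Chisq)"], 4))
  vc <- extract_varcomp(fit)
  res <- structure(list(model = fit, fixed = fixed, anova = anova_tab,
                        varcomp = vc, r2_marginal = NA_real_,
                        shapiro = if (inherits(shap, "try-error")) NULL else shap,
                        lambda = lambda, converged = TRUE, spec = spec,
                        data = d),
                   class = "shiver_fit")
  res$r2_marginal <- marginal_pseudo_r2(res)
  res
}

#' @export
print.shiver_fit <- function(x, ...) {
  cat("<shiver_fit>", x$spec$response, "~",
      paste(x$spec$fixed, collapse = " + "), "\n")
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$anova))) {
    cat(sprintf("  %s: chi^2 = %.3f, df = %d, p = %.4f\n",
                x$anova$term[i], x$anova$chisq[i], x$anova$df[i], x$anova$p[i]))
  }
  cat(sprintf("  marginal pseudo-r^2 = %.3f\n", x$r2_marginal))
  invisible(x)
}

# mother/animal/residual variances (+ per-day residual SD ratios if weighted)
extract_varcomp <- function(fit) {
  vc <- suppressWarnings(nlme::VarCorr(fit))
  v <- suppressWarnings(as.numeric(vc[, "Variance"]))
  rows <- rownames(vc)
  iint <- which(rows == "(Intercept)")
  mother_var <- v[iint[1]]
  animal_var <- if (length(iint) > 1) v[iint[2]] else NA_real_
  resid_var <- v[which(rows == "Residual")]
  out <- list(mother = mother_var, animal = animal_var, residual = resid_var)
  vs <- fit$modelStruct$varStruct
  if (!is.null(vs)) {
    out$day_sd_ratio <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
  }
  out
}

# per-observation residual variances in data order
# (sigma^2 scaled by the squared per-day varIdent SD ratios)
residual_variances <- function(fit, data) {
  s2 <- fit$sigma^2
  vs <- fit$modelStruct$varStruct
  if (is.null(vs)) return(rep(s2, nrow(data)))
  cf <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
  s2 * unname(cf[as.character(data$day)])^2
}

#' Shapiro-Wilk test on conditional model residuals
#'
#' @param fit A [fit_mixed()] result or an `nlme::lme` object.
#' @return A list with `W` and `p`.
#' @export
residual_normality <- function(fit) {
  r <- if (inherits(fit, "shiver_fit")) {
    if (!fit$converged) stop("fit did not converge", call. = FALSE)
    stats::residuals(fit$model, type = "pearson")
  } else {
    stats::residuals(fit, type = "pearson")
  }
  if (length(r) < 3L) stop("need >= 3 residuals", call. = FALSE)
  if (diff(range(r)) < 1e-12) stop("residuals are degenerate (all identical)",
                                   call. = FALSE)
  sw <- shapiro.test(r)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

#' Marginal pseudo-r-squared of a mixed fit
#'
#' Fraction of total variance attributable to the fixed effects:
#' `var(X beta) / (var(X beta) + var_mother + var_animal + var_residual)`,
#' with the residual variance averaged over observations when per-day
#' weights are in force.
#'
#' @param fit A converged [fit_mixed()] result.
#' @return A value in `[0, 1]`.
#' @export
marginal_pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "shiver_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  mu <- stats::predict(fit$model, level = 0)
  vf <- stats::var(mu)
  vr <- mean(residual_variances(fit$model, fit$data))
  va <- fit$varcomp$animal
  if (!is.finite(va)) va <- 0
  out <- vf / (vf + fit$varcomp$mother + va + vr)
  max(0, min(1, out))
}

# marginal covariance matrix V implied by the fitted lme object,
# block-diagonal over mothers: Zm sm2 Zm' + Za sa2 Za' + diag(resid var)
marginal_covariance <- function(fit, data) {
  vc <- extract_varcomp(fit)
  sm2 <- vc$mother
  sa2 <- vc$animal
  rv <- residual_variances(fit, data)
  n <- nrow(data)
  V <- diag(rv, n)
  mo <- as.character(data$mother_id)
  an <- as.character(data$animal_id)
  same_m <- outer(mo, mo, "==")
  same_a <- outer(an, an, "==")
  V <- V + sm2 * same_m + sa2 * same_a
  V
}

#' Partial (added-variable) regressions for a two-predictor mixed model
#'
#' For the model `response ~ x1 + x2` under the nested random structure,
#' computes per-predictor partial residual pairs: residuals of the response
#' against the other predictor versus residuals of the predictor against the
#' other predictor, both computed by generalised least squares under the full
#' model's estimated marginal covariance. By the Frisch-Waugh-Lovell
#' identity the slope of each partial fit equals the corresponding
#' coefficient of the full mixed model, which is asserted.
#'
#' @param table Cohort data frame.
#' @param spec A [model_spec()] with exactly two fixed-effect predictors
#'   (e.g. SERCA1a and SLN expression explaining SERCA activity).
#' @return A list with one element per predictor, each containing
#'   `residual_pairs` (tibble `x_resid`, `y_resid` on the whitened scale),
#'   `slope` and `se` (from the full fit), plus the full `fit`.
#' @export
partial_regression <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"), length(spec$fixed) == 2L)
  x1 <- spec$fixed[1]; x2 <- spec$fixed[2]
  r <- stats::cor(table[[x1]], table[[x2]])
  if (abs(r) > 0.999) stop("collinear predictors", call. = FALSE)
  fit <- fit_mixed(table, spec)
  if (!fit$converged) stop("full model did not converge", call. = FALSE)
  d <- fit$data
  V <- marginal_covariance(fit$model, d)
  L <- chol(V) # V = L'L
  wh <- function(v) backsolve(L, v, transpose = TRUE)
  y <- wh(d$.y)
  ones <- wh(rep(1, nrow(d)))
  Xw <- list(wh(d[[x1]]), wh(d[[x2]]))
  names(Xw) <- c(x1, x2)
  out <- list(fit = fit)
  for (j in 1:2) {
    xj <- spec$fixed[j]; xo <- spec$fixed[3 - j]
    Zo <- cbind(ones, Xw[[xo]])
    proj <- function(v) v - Zo %*% qr.coef(qr(Zo), v)
    ex <- proj(Xw[[xj]])
    ey <- proj(y)
    slope <- sum(ex * ey) / sum(ex^2)
    est <- fit$fixed$estimate[fit$fixed$term == xj]
    if (abs(slope - est) > 1e-6 * max(1, abs(est))) {
      stop("partial slope does not match the full-model coefficient",
           call. = FALSE)
    }
    out[[xj]] <- list(
      residual_pairs = tibble::tibble(x_resid = as.numeric(ex),
                                      y_resid = as.numeric(ey)),
      slope = slope,
      se = fit$fixed$se[fit$fixed$term == xj])
  }
  out
}
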