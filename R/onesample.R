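#' PANSS percentage reduction
#'
#' Total scale: `100 * (baseline - endpoint) / (baseline - 30)` — the 30
#' floor of the total score is subtracted from the baseline so the
#' denominator is the improvable range. Subscales carry no floor:
#' `100 * (baseline - endpoint) / baseline`. Positive values mean
#' improvement.
#'
#' @param baseline,endpoint numeric score vectors.
#' @param scale "total" or "subscale".
#' @return percentage reduction vector.
#' @export
panss_reduction <- function(baseline, endpoint, scale = c("total",
                                                          "subscale")) {
  scale <- match.arg(scale)
  if (scale == "total") {
    if (any(baseline <= 30, na.rm = TRUE))
      stop_dtmr("total-scale reduction undefined for baseline <= 30")
    100 * (baseline - endpoint) / (baseline - 30)
  } else {
    if (any(baseline <= 0, na.rm = TRUE))
      stop_dtmr("subscale reduction undefined for baseline <= 0")
    100 * (baseline - endpoint) / baseline
  }
}

#' Covariate specification
#'
#' The standard adjustment set: sex, age and age-squared, study center,
#' the top five genetic principal components, illness course, and previous
#' medication; the assigned antipsychotic class is added if and only if the
#' outcome is a treatment-efficacy measure.
#'
#' @param efficacy is the outcome a PANSS reduction / responder flag?
#' @return character vector of model terms.
#' @export
covariate_spec <- function(efficacy = TRUE) {
  base <- c("sex", "age", "I(age^2)", "center", paste0("PC", 1:5),
            "course", "prior_med")
  if (efficacy) c(base, "drug_class") else base
}

#' Covariate-adjusted association between an exposure and an outcome
#'
#' OLS for continuous outcomes, maximum-likelihood logistic regression for
#' binary ones; both conventional and HC3-robust inference are attached.
#' Logistic fits additionally report the odds ratio. Complete-case analysis.
#'
#' @param data cohort data.frame.
#' @param outcome,exposure column names (exposure typically a standardized
#'   score or a measured trait).
#' @param covariates character vector of adjustment terms (see
#'   [covariate_spec()]).
#' @param family "linear" or "logistic".
#' @return an `effect_estimate`: estimate (beta or log-OR), se/se_hc3,
#'   ci95/ci95_hc3, p/p_hc3, `or` and its CI for logistic, n, model
#'   descriptor, and the underlying fit (for diagnostics).
#' @export
fit_adjusted <- function(data, outcome, exposure,
                         covariates = character(0),
                         family = c("linear", "logistic")) {
  family <- match.arg(family)
  rhs <- c(exposure, covariates)
  fml <- stats::reformulate(rhs, response = outcome)
  use <- stats::complete.cases(
    data[, intersect(all.vars(fml), names(data)), drop = FALSE])
  d <- droplevels(data[use, , drop = FALSE])
  fit <- if (family == "linear") stats::lm(fml, data = d)
         else stats::glm(fml, data = d, family = stats::binomial())
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_dtmr("rank-deficient model: collinear term(s) %s",
              paste(names(cf)[is.na(cf)], collapse = ", "))
  if (family == "logistic") {
    eta <- stats::predict(fit, type = "link")
    if (!fit$converged || max(abs(eta)) > 15) {
      warning("possible separation in logistic model; estimate withheld",
              call. = FALSE)
      return(effect_estimate(NA, NA, NA, NA, NA, NA, nrow(d),
                             model = list(outcome = outcome,
                                          exposure = exposure,
                                          family = family,
                                          flag = "separation")))
    }
  }
  sm <- summary(fit)$coefficients
  term <- rownames(sm)[2]   # exposure is the first RHS term
  est <- sm[term, 1]; se <- sm[term, 2]; p <- sm[term, 4]
  hc3 <- hc3_se(fit)
  se3 <- hc3[term]
  z3 <- est / se3
  p3 <- 2 * stats::pnorm(abs(z3), lower.tail = FALSE)
  ee <- effect_estimate(est, se, se3, p, p3, fdr = NA_real_, n = nrow(d),
                        model = list(outcome = outcome, exposure = exposure,
                                     covariates = covariates,
                                     family = family))
  if (family == "logistic") {
    ee$or <- exp(est)
    ee$or_ci95 <- exp(ee$ci95)
  }
  ee$fit <- fit
  ee
}

effect_estimate <- function(est, se, se_hc3, p, p_hc3, fdr, n, model) {
  out <- list(estimate = est, se = se, se_hc3 = se_hc3,
              ci95 = est + c(-1, 1) * 1.96 * se,
              ci95_hc3 = est + c(-1, 1) * 1.96 * se_hc3,
              p = p, p_hc3 = p_hc3, p_fdr = fdr, n = n, model = model)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s]: beta = %.4g (95%% CI %.4g, %.4g), p = %.3g",
              x$model$outcome %||% "?", x$model$exposure %||% "?",
              x$model$family %||% "linear",
              x$estimate, x$ci95[1], x$ci95[2], x$p))
  if (!is.null(x$or)) cat(sprintf(", OR = %.3f", x$or))
  cat(sprintf(" [n = %d]\n", x$n))
  invisible(x)
}

#' Trend test of a baseline characteristic against a continuous score
#'
#' Continuous characteristics: p-value of the score coefficient in a linear
#' regression. Binary: logistic regression. Categorical (> 2 levels): the
#' overall F-test of the score across categories.
#'
#' @param data data.frame.
#' @param characteristic,score column names.
#' @return p-for-trend.
#' @export
trend_test <- function(data, characteristic, score) {
  x <- data[[characteristic]]
  s <- data[[score]]
  if (length(unique(stats::na.omit(x))) < 2)
    stop_dtmr("trend_test: characteristic '%s' has zero variance",
              characteristic)
  if (is.factor(x) || is.character(x)) {
    x <- factor(x)
    if (nlevels(x) == 2) {
      fit <- stats::glm(x ~ s, family = stats::binomial())
      return(summary(fit)$coefficients["s", 4])
    }
    fit <- stats::lm(s ~ x)
    fs <- summary(fit)$fstatistic
    return(unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
  }
  if (length(unique(stats::na.omit(x))) == 2) {
    fit <- stats::glm(factor(x) ~ s, family = stats::binomial())
    return(summary(fit)$coefficients["s", 4])
  }
  fit <- stats::lm(x ~ s)
  summary(fit)$coefficients["s", 4]
}

#' One-sample two-stage least-squares (instrumental-variable) estimate
#'
#' Stage 1 regresses the trait on the score (plus covariates); stage 2
#' regresses the outcome on the predicted trait (plus the same covariates).
#' The standard error is the proper 2SLS variance — residuals are computed
#' with the observed trait, not the stage-2 fitted values. The first-stage
#' partial F of the score is reported and a weak-instrument warning is
#' issued below 10.
#'
#' @param data cohort data.frame.
#' @param outcome,trait,score column names.
#' @param covariates adjustment terms entering both stages.
#' @return an `effect_estimate` (per trait unit) with `first_stage_f`.
#' @export
two_stage_ls <- function(data, outcome, trait, score,
                         covariates = character(0)) {
  vars <- unique(c(outcome, trait, score,
                   intersect(all.vars(stats::reformulate(
                     c(covariates, "1"))), names(data))))
  use <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[use, , drop = FALSE]
  n <- nrow(d)
  Xc <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data = d)
  else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- d[[outcome]]
  tr <- d[[trait]]
  s <- d[[score]]

  s1 <- stats::lm(tr ~ s + Xc - 1)
  tval <- summary(s1)$coefficients["s", 3]
  fs_f <- tval^2
  if (fs_f < 10)
    warning(sprintf("weak instrument: first-stage F = %.2f < 10", fs_f),
            call. = FALSE)
  fitted_tr <- stats::fitted(s1)

  W <- cbind(trait = fitted_tr, Xc)
  X <- cbind(trait = tr, Xc)
  WtWi <- solve(crossprod(W))
  bhat <- WtWi %*% crossprod(W, y)
  resid <- y - X %*% bhat            # IV residuals use the observed trait
  sigma2 <- sum(resid^2) / (n - ncol(W))
  V <- sigma2 * WtWi
  est <- unname(bhat["trait", 1])
  se <- unname(sqrt(V["trait", "trait"]))
  p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
  ee <- effect_estimate(est, se, se, p, p, NA_real_, n,
                        model = list(outcome = outcome, exposure = trait,
                                     instrument = score,
                                     covariates = covariates,
                                     family = "2sls"))
  ee$first_stage_f <- fs_f
  ee
}

#' Convert a per-SD score effect to per-unit-of-trait
#'
#' The per-SD effect of a lowering score divided by the trait change per SD
#' of that score; the printed multiplier is `unit_step / |score_to_trait|`
#' rounded to two decimals.
#'
#' @param beta_per_sd_score outcome units per SD of score.
#' @param score_to_trait_beta trait mg/dL per SD of score (nonzero).
#' @param unit_step trait step for reporting (default 10 mg/dL).
#' @return list(multiplier, rescaled_effect).
#' @export
rescale_per_trait_units <- function(beta_per_sd_score, score_to_trait_beta,
                                    unit_step = 10) {
  if (score_to_trait_beta == 0)
    stop_dtmr("score_to_trait_beta must be nonzero")
  mult <- round(unit_step / abs(score_to_trait_beta), 2)
  list(multiplier = mult, rescaled_effect = beta_per_sd_score * mult)
}

#' Stratum labels for the standard subgroup rules
#'
#' `hyperlipemia`: baseline TG >= 151 mg/dL or HDL <= 40 mg/dL (columns
#' `TG`, `HDL`); `prediabetes`: baseline glucose >= 100.8 mg/dL (column
#' `glucose`); `drug_metabolic_class`: column `drug_class`; `sex`: column
#' `sex`; `clinical_stage`: column `first_episode`. All cutpoints inclusive
#' on the quoted side.
#'
#' @param data cohort data.frame with the rule's columns.
#' @param rule rule name, or the name of an existing binary/factor column.
#' @return a factor of stratum labels.
#' @export
stratum_labels <- function(data, rule) {
  lab <- switch(rule,
    hyperlipemia = factor(ifelse(data$TG >= 151 | data$HDL <= 40,
                                 "hyperlipemia", "normal"),
                          levels = c("normal", "hyperlipemia")),
    prediabetes = factor(ifelse(data$glucose >= 100.8,
                                "prediabetes_diabetes", "normoglycemic"),
                         levels = c("normoglycemic", "prediabetes_diabetes")),
    drug_metabolic_class = factor(ifelse(data$drug_class == 1,
                                         "stronger", "milder"),
                                  levels = c("milder", "stronger")),
    sex = factor(ifelse(data$sex == 1, "male", "female")),
    clinical_stage = factor(ifelse(data$first_episode == 1,
                                   "first_episode", "recurrent")),
    {
      if (!rule %in% names(data))
        stop_dtmr("unknown stratum rule or column '%s'", rule)
      factor(data[[rule]])
    })
  lab
}

#' Stratified association with an interaction test
#'
#' Refits the adjusted model within each stratum (flagging strata with
#' n < 30) and fits a pooled model with a score-by-stratum product term;
#' the product term's p-value is reported as `p_interaction`. The score is
#' kept in whole-sample SD units across strata.
#'
#' @param data cohort data.frame.
#' @param outcome,score column names.
#' @param stratum a rule name for [stratum_labels()] or a column name.
#' @param covariates adjustment terms.
#' @param family "linear" or "logistic".
#' @return list(by_stratum = named list of `effect_estimate`,
#'   p_interaction, strata = the label factor).
#' @export
stratified_with_interaction <- function(data, outcome, score, stratum,
                                        covariates = character(0),
                                        family = "linear") {
  lab <- stratum_labels(data, stratum)
  d <- data
  d$.stratum <- lab
  # drop covariate terms fully determined by the stratum (e.g. sex when
  # stratifying on sex): they are collinear within and across strata
  determined <- vapply(covariates, function(term) {
    vars <- intersect(all.vars(stats::reformulate(term)), names(d))
    length(vars) > 0 && all(vapply(vars, function(v)
      all(tapply(d[[v]], lab, function(z)
        length(unique(z[!is.na(z)])) <= 1)), TRUE))
  }, TRUE)
  covariates <- covariates[!determined]
  res <- list()
  for (lv in levels(lab)) {
    ds <- d[!is.na(lab) & lab == lv, , drop = FALSE]
    ee <- fit_adjusted(ds, outcome, score, covariates, family)
    ee$low_n <- ee$n < 30
    if (ee$low_n)
      warning(sprintf("stratum '%s' has n = %d < 30", lv, ee$n),
              call. = FALSE)
    res[[lv]] <- ee
  }
  fml <- stats::reformulate(
    c(sprintf("%s * .stratum", score), covariates), response = outcome)
  pooled <- if (family == "linear") stats::lm(fml, data = d)
            else stats::glm(fml, data = d, family = stats::binomial())
  sm <- summary(pooled)$coefficients
  int_rows <- grep(sprintf("^%s:\\.stratum", score), rownames(sm))
  p_int <- if (length(int_rows) == 1) sm[int_rows, 4] else {
    # multi-level stratum: joint Wald test on all product terms
    b <- stats::coef(pooled)[int_rows]
    V <- stats::vcov(pooled)[int_rows, int_rows, drop = FALSE]
    stat <- as.numeric(t(b) %*% solve(V) %*% b)
    stats::pchisq(stat, df = length(b), lower.tail = FALSE)
  }
  list(by_stratum = res, p_interaction = unname(p_int), strata = lab)
}

#' Mediation by conditioning two scores on the same variants
#'
#' Fits the joint model `outcome ~ pqtl_score + trait_score + covariates`,
#' where both scores are built on the identical variant set and differ only
#' in weights (protein effects vs trait effects). Attenuation of the pQTL
#' score's coefficient once the trait score is in the model indicates
#' mediation through the measured trait.
#'
#' @param data cohort data.frame.
#' @param outcome outcome column.
#' @param pqtl_score,trait_score `score_vector` objects (see
#'   [compute_grs()]) aligned with `data` rows.
#' @param covariates adjustment terms.
#' @return list of conditioned `effect_estimate`s (`pqtl`, `trait`) plus a
#'   `collinear` flag when |r| > 0.99.
#' @export
mediation_condition <- function(data, outcome, pqtl_score, trait_score,
                                covariates = character(0)) {
  stopifnot(inherits(pqtl_score, "score_vector"),
            inherits(trait_score, "score_vector"))
  if (!setequal(pqtl_score$variant_ids, trait_score$variant_ids))
    stop_dtmr("mediation_condition: the two scores must use identical variants")
  d <- data
  d$.pqtl <- pqtl_score$standardized
  d$.trait_grs <- trait_score$standardized
  r <- stats::cor(d$.pqtl, d$.trait_grs)
  collinear <- is.finite(r) && abs(r) > 0.99
  if (collinear) {
    warning(sprintf("scores nearly collinear (r = %.3f): conditioned %s",
                    r, "estimates are not identified"), call. = FALSE)
    return(list(pqtl = NULL, trait = NULL, collinear = TRUE,
                correlation = r))
  }
  fml <- stats::reformulate(c(".pqtl", ".trait_grs", covariates),
                            response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  hc3 <- hc3_se(fit)
  mk <- function(term, label) {
    est <- sm[term, 1]; se <- sm[term, 2]
    ee <- effect_estimate(est, se, hc3[term], sm[term, 4],
                          2 * stats::pnorm(abs(est / hc3[term]),
                                           lower.tail = FALSE),
                          NA_real_, length(stats::resid(fit)),
                          model = list(outcome = outcome, exposure = label,
                                       conditioned_on = setdiff(
                                         c("pqtl", "trait"), label),
                                       family = "linear"))
    ee
  }
  list(pqtl = mk(".pqtl", "pqtl"), trait = mk(".trait_grs", "trait"),
       collinear = collinear, correlation = r)
}

#' 2x2 factorial group allocation by median-dichotomized scores
#'
#' Each score is dichotomized at its in-sample median; values exactly at the
#' median go to the "high" group. The both-low group is the reference level
#' (for lowering scores it corresponds to genetically higher levels of both
#' traits).
#'
#' @param score_a,score_b numeric score vectors.
#' @return factor with levels `low_low` (reference), `high_low`,
#'   `low_high`, `high_high` ("high"/"low" refer to score_a then score_b).
#' @export
factorial_groups <- function(score_a, score_b) {
  ha <- score_a >= stats::median(score_a)
  hb <- score_b >= stats::median(score_b)
  factor(paste(ifelse(ha, "high", "low"), ifelse(hb, "high", "low"),
               sep = "_"),
         levels = c("low_low", "high_low", "low_high", "high_high"))
}

#' Factorial effects and the non-additive interaction test
#'
#' Regression of the outcome on three group indicators against the both-low
#' reference (plus covariates); non-additivity is assessed in a separate
#' model carrying the product of the two continuous scores. The factorial
#' significance threshold is Bonferroni-corrected for the four PANSS
#' outcomes: 0.05/4 = 0.0125.
#'
#' @param data cohort data.frame containing the score columns.
#' @param outcome outcome column.
#' @param groups factor from [factorial_groups()].
#' @param score_a,score_b continuous score column names.
#' @param covariates adjustment terms.
#' @return list(group_effects = named `effect_estimate`s,
#'   p_product_interaction, alpha_factorial = 0.0125).
#' @export
factorial_effects <- function(data, outcome, groups, score_a, score_b,
                              covariates = character(0)) {
  if (any(table(groups) == 0))
    stop_dtmr("factorial_effects: empty factorial group")
  d <- data
  d$.group <- groups
  fml <- stats::reformulate(c(".group", covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  hc3 <- hc3_se(fit)
  lv <- levels(groups)[-1]
  ge <- lapply(lv, function(g) {
    term <- paste0(".group", g)
    est <- sm[term, 1]; se <- sm[term, 2]
    effect_estimate(est, se, hc3[term], sm[term, 4],
                    2 * stats::pnorm(abs(est / hc3[term]),
                                     lower.tail = FALSE),
                    NA_real_, length(stats::resid(fit)),
                    model = list(outcome = outcome, exposure = g,
                                 reference = levels(groups)[1],
                                 family = "linear"))
  })
  names(ge) <- lv
  fml2 <- stats::reformulate(c(sprintf("%s * %s", score_a, score_b),
                               covariates), response = outcome)
  fit2 <- stats::lm(fml2, data = d)
  sm2 <- summary(fit2)$coefficients
  prod_term <- paste0(score_a, ":", score_b)
  list(group_effects = ge,
       p_product_interaction = unname(sm2[prod_term, 4]),
       alpha_factorial = 0.05 / 4)
}

#' Multiplicity adjustment (Benjamini-Hochberg or Bonferroni)
#'
#' BH: step-up with the running-minimum monotonicity enforcement;
#' Bonferroni: `min(1, m * p)`.
#'
#' @param pvalues numeric vector of p-values.
#' @param method "bh" or "bonferroni".
#' @param m number of tests (defaults to `length(pvalues)`).
#' @return adjusted p-values, same order as input.
#' @export
adjust_multiplicity <- function(pvalues, method = c("bh", "bonferroni"),
                                m = length(pvalues)) {
  method <- match.arg(method)
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
            m >= length(pvalues))
  if (method == "bonferroni") return(pmin(1, m * pvalues))
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  i <- n:1                         # ranks, largest p first
  pmin(1, cummin(m / i * pvalues[o]))[ro]
}
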