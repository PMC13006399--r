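#' Breusch-Pagan and White heteroskedasticity tests
#'
#' Both are Lagrange-multiplier tests: the squared OLS residuals are
#' regressed on the model's regressors (Breusch-Pagan) or on the
#' regressors plus their squares and pairwise products (White); the
#' statistic is n times the auxiliary R-squared, referred to chi-square
#' with (auxiliary regressors) degrees of freedom.
#'
#' @param model a fitted `lm`.
#' @return the test p-value; the statistic and df are attached as
#'   attributes `"statistic"` and `"df"`.
#' @export
breusch_pagan <- function(model) {
  X <- stats::model.matrix(model)
  lm_aux_test(stats::resid(model)^2, X[, -1, drop = FALSE])
}

#' @rdname breusch_pagan
#' @export
white_test <- function(model) {
  X <- stats::model.matrix(model)[, -1, drop = FALSE]
  k <- ncol(X)
  aug <- X
  for (i in seq_len(k)) for (j in i:k)
    aug <- cbind(aug, X[, i] * X[, j])
  # drop constant and duplicated columns (e.g. squares of dummies)
  keep <- apply(aug, 2, stats::sd) > 0
  aug <- aug[, keep, drop = FALSE]
  aug <- aug[, !duplicated(t(aug)), drop = FALSE]
  lm_aux_test(stats::resid(model)^2, aug)
}

# n * R^2 auxiliary LM test of e2 on Z (with intercept)
lm_aux_test <- function(e2, Z) {
  n <- length(e2)
  fit <- stats::lm(e2 ~ Z)
  ok <- !is.na(stats::coef(fit))[-1]
  r2 <- summary(fit)$r.squared
  df <- sum(ok)
  stat <- n * r2
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  attr(p, "statistic") <- stat
  attr(p, "df") <- df
  p
}

#' HC3 heteroskedasticity-consistent standard errors
#'
#' Sandwich covariance with per-observation weights `e_i^2 / (1 - h_ii)^2`.
#' For linear models, `(X'X)^{-1} X' diag(w) X (X'X)^{-1}`; for GLMs
#' (logistic log-odds) the score residuals `x_i (y_i - mu_i)` replace
#' `x_i e_i` and the inverse information is the bread.
#'
#' @param model a fitted `lm` or `glm`.
#' @return named vector of robust standard errors, one per coefficient.
#' @export
hc3_se <- function(model) {
  X <- stats::model.matrix(model)
  h <- stats::hatvalues(model)
  if (inherits(model, "glm")) {
    u <- X * (model$y - stats::fitted(model))    # score residuals
    bread <- stats::summary.glm(model)$cov.unscaled
    meat <- crossprod(u / (1 - h))
    V <- bread %*% meat %*% bread
  } else {
    e <- stats::resid(model)
    XtXi <- solve(crossprod(X))
    meat <- crossprod(X * (e / (1 - h)))
    V <- XtXi %*% meat %*% XtXi
  }
  out <- sqrt(diag(V))
  names(out) <- colnames(X)
  out
}

#' Influence measures: Cook's distance and studentized deleted residuals
#'
#' Closed forms from the hat matrix for linear models; the standard
#' one-step approximations ([stats::cooks.distance()] /
#' [stats::rstudent()]) for GLMs. Observations with Cook's D above
#' `cooks_max` or |studentized deleted residual| above `rstudent_max` are
#' flagged, and the model is refitted without them.
#'
#' @param model a fitted `lm` or `glm`.
#' @param cooks_max flag threshold for Cook's distance (default 0.5).
#' @param rstudent_max flag threshold for |studentized residual|
#'   (default 4).
#' @return list(measures = data.frame(cooks_d, rstudent, flagged),
#'   influential (row indices), refit (model without flagged rows, or the
#'   original model if nothing was flagged)).
#' @export
influence_measures <- function(model, cooks_max = 0.5, rstudent_max = 4) {
  if (inherits(model, "glm")) {
    cd <- stats::cooks.distance(model)
    rs <- stats::rstudent(model)
  } else {
    X <- stats::model.matrix(model)
    h <- stats::hatvalues(model)
    e <- stats::resid(model)
    n <- length(e)
    pdim <- ncol(X)
    s2 <- sum(e^2) / (n - pdim)
    if (sum(e^2) < 1e-16 * max(1, sum(stats::fitted(model)^2))) {
      # numerically exact fit: no influence, avoid 0/0
      cd <- rs <- rep(0, n)
    } else {
      cd <- e^2 * h / (pdim * s2 * (1 - h)^2)
      # deleted residual variance
      s2i <- (sum(e^2) - e^2 / (1 - h)) / (n - pdim - 1)
      rs <- e / sqrt(s2i * (1 - h))
    }
  }
  flagged <- (is.finite(cd) & cd > cooks_max) |
    (is.finite(rs) & abs(rs) > rstudent_max)
  refit <- model
  if (any(flagged)) {
    # refit from the design matrix: robust to transformed formula terms
    Xa <- stats::model.matrix(model)
    ya <- stats::model.response(stats::model.frame(model))
    keep <- !flagged
    Xk <- Xa[keep, , drop = FALSE]
    yk <- ya[keep]
    refit <- if (inherits(model, "glm"))
      stats::glm(yk ~ Xk - 1, family = stats::family(model))
    else stats::lm(yk ~ Xk - 1)
    names(refit$coefficients) <- colnames(Xa)
  }
  list(measures = data.frame(cooks_d = as.numeric(cd),
                             rstudent = as.numeric(rs),
                             flagged = flagged),
       influential = which(flagged),
       refit = refit)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing covariate
#' j on the remaining covariates. An exactly collinear covariate reports
#' `Inf`.
#'
#' @param x a numeric covariate matrix (columns named), or a fitted `lm`
#'   whose non-intercept design columns are used.
#' @return named vector of VIFs.
#' @export
vif <- function(x) {
  if (inherits(x, "lm")) x <- stats::model.matrix(x)[, -1, drop = FALSE]
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2) return(stats::setNames(rep(1, k), colnames(x)))
  out <- vapply(seq_len(k), function(j) {
    fit <- stats::lm(x[, j] ~ x[, -j, drop = FALSE])
    # exact collinearity triggers a harmless perfect-fit warning here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(x)
  out
}

#' Stable/sensitive classification of a primary vs sensitivity estimate
#'
#' "Stable" requires all of: (i) unchanged direction of association,
#' (ii) overlapping conventional 95% CIs, (iii) concordant statistical
#' significance at alpha; otherwise "sensitive".
#'
#' @param primary,sensitivity `effect_estimate` objects (or lists with
#'   `estimate`, `ci95`, `p`).
#' @param alpha significance level (default 0.05).
#' @return "stable" or "sensitive", with the three condition results
#'   attached as attribute `"conditions"`.
#' @export
stability_classify <- function(primary, sensitivity, alpha = 0.05) {
  same_dir <- sign(primary$estimate) == sign(sensitivity$estimate)
  overlap <- primary$ci95[1] <= sensitivity$ci95[2] &&
    sensitivity$ci95[1] <= primary$ci95[2]
  concordant <- (primary$p < alpha) == (sensitivity$p < alpha)
  out <- if (same_dir && overlap && concordant) "stable" else "sensitive"
  attr(out, "conditions") <- c(direction = same_dir, ci_overlap = overlap,
                               significance = concordant)
  out
}

#' Full diagnostics report for a fitted linear model
#'
#' Bundles the heteroskedasticity tests, HC3 SEs, influence screen with
#' refit, VIFs, and the stable/sensitive label comparing the exposure
#' coefficient before and after excluding influential observations.
#'
#' @param model a fitted `lm`.
#' @param term coefficient of interest (default: second coefficient, the
#'   exposure in [fit_adjusted()] models).
#' @return a `diagnostics_report` list.
#' @export
model_diagnostics <- function(model, term = NULL) {
  term <- term %||% names(stats::coef(model))[2]
  idx <- match(term, names(stats::coef(model)))
  bp <- breusch_pagan(model)
  wt <- white_test(model)
  hc3 <- hc3_se(model)
  infl <- influence_measures(model)
  vifs <- vif(model)
  grab <- function(fit) {
    sm <- summary(fit)$coefficients
    est <- sm[idx, 1]; se <- sm[idx, 2]
    list(estimate = est, se = se, ci95 = est + c(-1, 1) * 1.96 * se,
         p = sm[idx, 4])
  }
  primary <- grab(model)
  refit <- grab(infl$refit)
  out <- list(bp_p = as.numeric(bp), white_p = as.numeric(wt),
              hc3_se = hc3,
              influential = infl$influential,
              vif = vifs,
              primary_estimate = primary$estimate,
              refit_estimate = refit$estimate,
              stability = stability_classify(primary, refit))
  class(out) <- "diagnostics_report"
  out
}
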