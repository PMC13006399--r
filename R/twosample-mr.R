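#' Harmonized two-sample MR input
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome per-variant
#'   association statistics, harmonized to a common effect allele.
#' @param variant_ids optional ids (defaults to snp1..snpK).
#' @return an `mr_input` data.frame.
#' @export
mr_input <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                     variant_ids = NULL) {
  k <- length(beta_exposure)
  stopifnot(length(se_exposure) == k, length(beta_outcome) == k,
            length(se_outcome) == k, k >= 1)
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop_dtmr("mr_input: all standard errors must be positive")
  out <- data.frame(
    variant_id = variant_ids %||% paste0("snp", seq_len(k)),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    stringsAsFactors = FALSE)
  class(out) <- c("mr_input", "data.frame")
  out
}

mr_result <- function(method, estimate, se, p, k, ...) {
  out <- c(list(method = method, estimate = estimate, se = se,
                ci95 = estimate + c(-1, 1) * 1.96 * se, p = p, k = k),
           list(...))
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4g (95%% CI %.4g, %.4g), p = %.3g, k = %d\n",
              x$method, x$estimate, x$ci95[1], x$ci95[2], x$p, x$k))
  invisible(x)
}

wald_ratios <- function(input) {
  ratio <- input$beta_outcome / input$beta_exposure
  # second-order-free inverse-variance weights
  w <- (input$beta_exposure / input$se_outcome)^2
  list(ratio = ratio, w = w)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted average of per-variant Wald ratios with weights
#' `(beta_exposure/se_outcome)^2`; algebraically the slope of
#' zero-intercept weighted least squares of outcome betas on exposure
#' betas. The fixed-effects SE is `(sum w)^{-1/2}`; the random-effects SE
#' multiplies it by `max(1, sqrt(Q/(k-1)))`. With `model = "auto"` the
#' random-effects model is used when Cochran's Q has p < 0.05.
#'
#' @param input an [mr_input()].
#' @param model "auto", "fixed", or "random".
#' @return an `mr_result` carrying q_statistic, q_p and both SEs.
#' @export
mr_ivw <- function(input, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  k <- nrow(input)
  wr <- wald_ratios(input)
  est <- sum(wr$w * wr$ratio) / sum(wr$w)
  se_fixed <- 1 / sqrt(sum(wr$w))
  q <- cochran_q(input, est)
  se_random <- se_fixed * max(1, sqrt(q$Q / max(1, k - 1)))
  use_random <- switch(model,
                       fixed = FALSE,
                       random = TRUE,
                       auto = is.finite(q$p) && q$p < 0.05)
  se <- if (use_random) se_random else se_fixed
  p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
  mr_result(if (use_random) "ivw_random" else "ivw_fixed",
            est, se, p, k,
            se_fixed = se_fixed, se_random = se_random,
            q_statistic = q$Q, q_df = q$df, q_p = q$p)
}

#' Cochran's Q heterogeneity test across Wald ratios
#'
#' `Q = sum_j w_j (ratio_j - estimate)^2`, referred to chi-square with
#' k - 1 degrees of freedom.
#'
#' @param input an [mr_input()].
#' @param estimate pooled estimate (defaults to the fixed-effects IVW).
#' @return list(Q, df, p).
#' @export
cochran_q <- function(input, estimate = NULL) {
  wr <- wald_ratios(input)
  if (is.null(estimate)) estimate <- sum(wr$w * wr$ratio) / sum(wr$w)
  Q <- sum(wr$w * (wr$ratio - estimate)^2)
  df <- nrow(input) - 1
  p <- if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  list(Q = Q, df = df, p = p)
}

#' Weighted-median MR estimate
#'
#' Orders the Wald ratios and reports the value at which the normalized
#' cumulative inverse-variance weight crosses 0.5, linearly interpolating
#' between the flanking ratios. The SE comes from a seeded parametric
#' bootstrap (exposure and outcome betas resampled from their normal
#' sampling distributions).
#'
#' @param input an [mr_input()] with k >= 3.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(input, n_boot = 1000, seed = 1L) {
  if (nrow(input) < 3)
    stop_dtmr("weighted median requires k >= 3 instruments")
  wm <- function(ratio, w) {
    o <- order(ratio)
    ratio <- ratio[o]; w <- w[o]
    cw <- (cumsum(w) - w / 2) / sum(w)
    if (cw[1] >= 0.5) return(ratio[1])
    if (cw[length(cw)] <= 0.5) return(ratio[length(cw)])
    stats::approx(cw, ratio, xout = 0.5, ties = "ordered")$y
  }
  wr <- wald_ratios(input)
  est <- wm(wr$ratio, wr$w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(input), input$beta_exposure,
                         input$se_exposure)
      by <- stats::rnorm(nrow(input), input$beta_outcome, input$se_outcome)
      wm(by / bx, (bx / input$se_outcome)^2)
    }, 0)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
  mr_result("wm", est, se, p, nrow(input), n_boot = n_boot)
}

#' MR-Egger regression and intercept (pleiotropy) test
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept, weights `1/se_outcome^2`, after re-orienting each variant so
#' its exposure beta is positive. The intercept estimate, SE and p form the
#' directional-pleiotropy test; the slope is the Egger causal estimate.
#' SEs use the multiplicative random-effects scaling `max(1, sigma)`.
#'
#' @param input an [mr_input()] with k >= 3.
#' @return an `mr_result` with egger_intercept, egger_intercept_se,
#'   egger_intercept_p.
#' @export
mr_egger <- function(input) {
  k <- nrow(input)
  if (k < 3) stop_dtmr("MR-Egger requires k >= 3 instruments")
  flip <- sign(input$beta_exposure)
  flip[flip == 0] <- 1
  bx <- input$beta_exposure * flip
  by <- input$beta_outcome * flip
  w <- 1 / input$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  # multiplicative random-effects scaling; exact fits (sigma = 0) keep SE 0
  adj <- if (is.finite(sigma) && sigma > 0) max(1, sigma) / sigma else 1
  slope <- sm["bx", 1]
  slope_se <- sm["bx", 2] * adj
  int <- sm["(Intercept)", 1]
  int_se <- sm["(Intercept)", 2] * adj
  df <- k - 2
  p_slope <- 2 * stats::pt(abs(slope / slope_se), df, lower.tail = FALSE)
  p_int <- 2 * stats::pt(abs(int / int_se), df, lower.tail = FALSE)
  mr_result("egger", slope, slope_se, p_slope, k,
            egger_intercept = int, egger_intercept_se = int_se,
            egger_intercept_p = p_int)
}

#' PRESSO-style global pleiotropy test and outlier removal
#'
#' The observed residual sum of squares of outcome betas about their
#' leave-one-out IVW predictions is compared against its distribution under
#' `n_sim` parametric simulations from the no-pleiotropy model. Per-variant
#' outlier p-values are the analogous single-variant tail probabilities,
#' Bonferroni-corrected; variants with adjusted outlier p < 0.05 are removed
#' from the returned input.
#'
#' @param input an [mr_input()] with k >= 4.
#' @param n_sim number of simulations (default 1000).
#' @param seed RNG seed.
#' @return list(global_p, outlier_p (named, Bonferroni-adjusted),
#'   outliers (ids), filtered (the cleaned `mr_input`)).
#' @export
mr_presso <- function(input, n_sim = 1000, seed = 1L) {
  k <- nrow(input)
  if (k < 4) stop_dtmr("mr_presso requires k >= 4 instruments")
  # leave-one-out IVW estimates from weighted totals (vectorized)
  loo_ivw <- function(bx, by, sy) {
    w <- (bx / sy)^2
    r <- by / bx
    (sum(w * r) - w * r) / (sum(w) - w)
  }
  loo_est <- loo_ivw(input$beta_exposure, input$beta_outcome,
                     input$se_outcome)
  obs_res2 <- (input$beta_outcome - loo_est * input$beta_exposure)^2
  obs_rss <- sum(obs_res2)
  sims <- with_seed(seed, {
    BX <- matrix(stats::rnorm(k * n_sim, input$beta_exposure,
                              input$se_exposure), k, n_sim)
    BY <- matrix(stats::rnorm(k * n_sim, loo_est * input$beta_exposure,
                              input$se_outcome), k, n_sim)
    W <- (BX / input$se_outcome)^2
    R <- BY / BX
    WR <- W * R
    LOO <- (rep(colSums(WR), each = k) - WR) /
      (rep(colSums(W), each = k) - W)
    t((BY - LOO * BX)^2)               # n_sim x k
  })
  sim_rss <- rowSums(sims)
  global_p <- (sum(sim_rss >= obs_rss) + 1) / (n_sim + 1)
  outlier_p <- vapply(seq_len(k), function(j)
    (sum(sims[, j] >= obs_res2[j]) + 1) / (n_sim + 1), 0)
  outlier_p_adj <- pmin(1, outlier_p * k)
  names(outlier_p_adj) <- input$variant_id
  out_ids <- input$variant_id[outlier_p_adj < 0.05]
  filtered <- input[!input$variant_id %in% out_ids, , drop = FALSE]
  class(filtered) <- class(input)
  list(global_p = global_p, outlier_p = outlier_p_adj,
       outliers = out_ids, filtered = filtered)
}
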