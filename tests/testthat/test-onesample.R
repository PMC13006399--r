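test_that("PANSS reduction formulas and domain errors", {
  expect_equal(panss_reduction(90, 60, "total"), 50)
  expect_equal(panss_reduction(90, 90, "total"), 0)
  expect_equal(panss_reduction(20, 10, "subscale"), 50)
  expect_error(panss_reduction(30, 20, "total"), "baseline")
  expect_error(panss_reduction(0, 0, "subscale"), "baseline")
  # improvement is positive, worsening negative
  expect_lt(panss_reduction(90, 100, "total"), 0)
})

test_that("covariate_spec carries age^2 with age and drug class only for
           efficacy outcomes", {
  ce <- covariate_spec(efficacy = TRUE)
  ct <- covariate_spec(efficacy = FALSE)
  expect_true(all(c("age", "I(age^2)") %in% ce))
  expect_true("drug_class" %in% ce)
  expect_false("drug_class" %in% ct)
})

test_that("fit_adjusted reduces to the covariance ratio without covariates
           and recovers a known OR", {
  set.seed(3)
  d <- data.frame(y = rnorm(100), x = rnorm(100))
  ee <- fit_adjusted(d, "y", "x", character(0), "linear")
  expect_equal(ee$estimate, cov(d$y, d$x) / var(d$x), tolerance = 1e-10)
  expect_equal(ee$ci95, ee$estimate + c(-1, 1) * 1.96 * ee$se)
  expect_identical(ee$n, 100L)

  # logistic parameter recovery: OR 1.2 per SD
  ors <- vapply(1:40, function(s) {
    set.seed(s)
    x <- rnorm(2000)
    pr <- plogis(log(1.2) * x)
    dd <- data.frame(y = rbinom(2000, 1, pr), x = x)
    fit_adjusted(dd, "y", "x", character(0), "logistic")$or
  }, 0)
  expect_gt(mean(ors), 1.15)
  expect_lt(mean(ors), 1.25)

  # rank deficiency errors with the collinear term named
  d$z <- d$x
  expect_error(fit_adjusted(d, "y", "x", "z", "linear"), "collinear.*z")

  # complete separation is flagged and the estimate withheld
  ds <- data.frame(y = rep(0:1, each = 20), x = c(rnorm(20), rnorm(20) + 50))
  expect_warning(sep <- fit_adjusted(ds, "y", "x", character(0), "logistic"),
                 "separation")
  expect_true(is.na(sep$estimate))
})

test_that("trend_test handles continuous, binary, categorical, degenerate", {
  set.seed(5)
  n <- 2000
  s <- rnorm(n)
  strong <- 0.5 * s + rnorm(n)
  d <- data.frame(s = s, strong = strong,
                  bin = rbinom(n, 1, plogis(s)),
                  cat = factor(sample(letters[1:4], n, TRUE)),
                  const = 1)
  expect_lt(trend_test(d, "strong", "s"), 1e-4)
  expect_lt(trend_test(d, "bin", "s"), 1e-4)
  expect_gt(trend_test(d, "cat", "s"), 0.001)   # independent by construction
  expect_error(trend_test(d, "const", "s"), "zero variance")
})

test_that("two_stage_ls: exact identification without noise, IV recovery
           under confounding where OLS is biased", {
  # noiseless, unconfounded: 2SLS = OLS = truth
  set.seed(7)
  g <- rnorm(400)
  trait <- 2 * g
  y <- 0.5 * trait
  d0 <- data.frame(y = y, trait = trait, g = g)
  ts0 <- suppressWarnings(two_stage_ls(d0, "y", "trait", "g"))
  expect_equal(ts0$estimate, 0.5, tolerance = 1e-10)
  expect_gt(ts0$first_stage_f, 10)

  # confounded: single large-sample check (full Monte Carlo in acceptance)
  set.seed(8)
  n <- 20000
  g <- rnorm(n)
  u <- rnorm(n)
  trait <- 2 * g + 3 * u + rnorm(n)
  y <- 0.5 * trait + 2 * u + rnorm(n)
  d <- data.frame(y = y, trait = trait, g = g)
  ols <- coef(lm(y ~ trait, d))[2]
  tsls <- two_stage_ls(d, "y", "trait", "g")
  expect_gt(ols, 0.55)                       # biased upward by confounding
  expect_lt(abs(tsls$estimate - 0.5), 3 * tsls$se)

  # weak instrument warns but still returns an estimate
  dweak <- data.frame(y = rnorm(200), trait = rnorm(200), g = rnorm(200))
  expect_warning(tw <- two_stage_ls(dweak, "y", "trait", "g"),
                 "weak instrument")
  expect_true(is.finite(tw$estimate))
})

test_that("unit conversion multipliers match the printed values", {
  expect_equal(rescale_per_trait_units(1.23, -6.34)$multiplier, 1.58)
  expect_equal(rescale_per_trait_units(0.96, -2.02)$multiplier, 4.95)
  expect_equal(rescale_per_trait_units(-1.70, -0.68)$multiplier, 14.71)
  r <- rescale_per_trait_units(1.23, -6.34)
  expect_equal(r$rescaled_effect, 1.23 * 1.58)
  expect_error(rescale_per_trait_units(1, 0), "nonzero")
})

test_that("stratum labels honour the quoted inclusive cutoffs", {
  d <- data.frame(TG = c(151, 150.9, 100), HDL = c(50, 50, 40),
                  glucose = c(100.8, 100.7, 90))
  hl <- stratum_labels(d, "hyperlipemia")
  expect_identical(as.character(hl), c("hyperlipemia", "normal",
                                       "hyperlipemia"))
  gl <- stratum_labels(d, "prediabetes")
  expect_identical(as.character(gl),
                   c("prediabetes_diabetes", "normoglycemic",
                     "normoglycemic"))
  expect_error(stratum_labels(d, "unknown_rule"), "unknown stratum")
})

test_that("stratified analysis drops stratum-determined covariates and
           reports an interaction p", {
  set.seed(11)
  n <- 600
  d <- data.frame(sex = rbinom(n, 1, 0.5), s = rnorm(n), age = runif(n, 20, 40))
  d$y <- 1 + 0.5 * d$s + 0.3 * d$sex + rnorm(n)
  res <- stratified_with_interaction(d, "y", "s", "sex",
                                     covariates = c("sex", "age"))
  expect_named(res$by_stratum, c("female", "male"))
  expect_true(all(vapply(res$by_stratum, function(e) is.finite(e$estimate),
                         TRUE)))
  expect_true(res$p_interaction > 0 && res$p_interaction <= 1)
  # equal true effects: interaction should usually be non-significant
  expect_gt(res$p_interaction, 0.001)
  # low-n strata are flagged
  dd <- d[1:40, ]
  w <- capture_warnings(stratified_with_interaction(dd, "y", "s", "sex"))
  expect_true(any(grepl("n = \\d+ < 30", w)))
})

test_that("mediation conditioning attenuates the pQTL score under full
           mediation but not under a direct effect", {
  one_rep <- function(s, direct) {
    set.seed(s)
    n <- 3000; m <- 6
    G <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(paste0("s", 1:n), paste0("v", 1:m)))
    w_p <- runif(m, 0.3, 0.6)            # variant -> protein
    w_d <- runif(m, -0.4, 0.4)           # extra direct variant -> trait
    protein <- G %*% w_p + rnorm(n)
    trait <- protein + G %*% w_d + rnorm(n)
    y <- if (direct) as.numeric(G %*% w_p) + rnorm(n)
         else as.numeric(0.8 * trait) + rnorm(n)
    mk_score <- function(w) {
      raw <- as.numeric(G %*% w)
      structure(list(raw = raw,
                     standardized = (raw - mean(raw)) / sd(raw),
                     variant_ids = colnames(G)), class = "score_vector")
    }
    d <- data.frame(y = y)
    r <- mediation_condition(d, "y", mk_score(w_p), mk_score(w_p + w_d))
    c(pqtl = r$pqtl$estimate, trait = r$trait$estimate)
  }
  med <- t(vapply(1:30, one_rep, numeric(2), direct = FALSE))
  dir <- t(vapply(31:60, one_rep, numeric(2), direct = TRUE))
  # full mediation: trait-score coefficient carries the signal
  expect_gt(mean(abs(med[, "trait"])), 3 * mean(abs(med[, "pqtl"])))
  # direct effect: the pqtl coefficient survives conditioning
  expect_gt(mean(abs(dir[, "pqtl"])), 3 * mean(abs(dir[, "trait"])))

  # identical weights -> collinearity flag
  set.seed(99)
  G <- matrix(rbinom(300, 2, 0.3), 100, 3,
              dimnames = list(NULL, paste0("v", 1:3)))
  raw <- as.numeric(G %*% c(1, 2, 3))
  sv <- structure(list(raw = raw,
                       standardized = (raw - mean(raw)) / sd(raw),
                       variant_ids = colnames(G)), class = "score_vector")
  expect_warning(
    mediation_condition(data.frame(y = rnorm(100)), "y", sv, sv),
    "collinear")
  # different variant sets error out
  sv2 <- sv; sv2$variant_ids <- c("v1", "v2", "zz")
  expect_error(
    mediation_condition(data.frame(y = rnorm(100)), "y", sv, sv2),
    "identical variants")
})

test_that("factorial groups: median dichotomy with exact-median to high,
           balanced sizes, reference both-low", {
  g <- factorial_groups(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  expect_identical(as.character(g),
                   c("low_low", "low_high", "high_low", "high_high"))
  expect_identical(levels(g)[1], "low_low")

  # value exactly at the median goes to 'high'
  g2 <- factorial_groups(c(1, 2, 3), c(3, 2, 1))
  expect_identical(as.character(g2)[2], "high_high")

  set.seed(17)
  a <- rnorm(2000); b <- rnorm(2000)
  tab <- table(factorial_groups(a, b))
  expect_true(all(abs(tab - 500) < 4 * sqrt(2000 * 0.25 * 0.75)))
})

test_that("factorial effects are additive under additive truth and the
           threshold is 0.05/4", {
  set.seed(19)
  n <- 20000
  a <- rnorm(n); b <- rnorm(n)
  y <- 2 + 1 * (a >= median(a)) + 1.5 * (b >= median(b)) + rnorm(n)
  d <- data.frame(y = y, a = a, b = b)
  gr <- factorial_groups(a, b)
  fe <- factorial_effects(d, "y", gr, "a", "b")
  expect_equal(fe$alpha_factorial, 0.0125)
  hh <- fe$group_effects$high_high$estimate
  hl <- fe$group_effects$high_low$estimate
  lh <- fe$group_effects$low_high$estimate
  se_sum <- sqrt(fe$group_effects$high_high$se^2 +
                 fe$group_effects$high_low$se^2 +
                 fe$group_effects$low_high$se^2)
  expect_lt(abs(hh - (hl + lh)), 4 * se_sum)
  # additive truth: product term not significant at the factorial threshold
  expect_gt(fe$p_product_interaction, 0.0125)
  expect_error(factorial_effects(d[1, ], "y", gr[1], "a", "b"),
               "empty factorial group")
})

test_that("multiplicity adjustment matches its defining step-up rule", {
  expect_equal(adjust_multiplicity(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_multiplicity(rep(0.007, 5), "bh"), rep(0.007, 5))
  expect_equal(adjust_multiplicity(0.02, "bonferroni", m = 4), 0.08)
  expect_equal(adjust_multiplicity(0.4, "bonferroni", m = 4), 1)

  # brute-force BH oracle: q* such that adjusted p_(i) = min over j >= i of
  # m p_(j) / j, capped at 1
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(3:12, 1))
    got <- adjust_multiplicity(p, "bh")
    o <- order(p)
    ps <- p[o]
    mlen <- length(p)
    adj <- vapply(seq_len(mlen), function(i2)
      min(1, min(mlen * ps[i2:mlen] / (i2:mlen))), 0)
    want <- numeric(mlen)
    want[o] <- adj
    expect_equal(got, want, tolerance = 1e-12)
  }
})
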