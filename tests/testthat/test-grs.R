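cand_df <- function(p, chrom = "1", pos = seq_along(p), ids = NULL) {
  data.frame(variant_id = ids %||% paste0("v", seq_along(p)),
             chrom = chrom, pos = pos, p = p, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

block_ld <- function(ids, block, r2_in = 0.9) {
  m <- outer(block, block, function(a, b) ifelse(a == b, r2_in, 0))
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

test_that("ld_clump keeps the lowest-p index per LD cluster", {
  cand <- cand_df(c(1e-9, 1e-8))
  ld <- block_ld(cand$variant_id, c(1, 1), r2_in = 1)
  expect_identical(ld_clump(cand, ld, 0.1), "v1")

  # mutually independent candidates all survive
  cand5 <- cand_df(runif(5))
  ld5 <- block_ld(cand5$variant_id, 1:5)
  expect_setequal(ld_clump(cand5, ld5, 0.1), cand5$variant_id)

  # 20 variants in 4 blocks vs an independently coded greedy oracle
  set.seed(5)
  blocks <- rep(1:4, each = 5)
  cand20 <- cand_df(runif(20), pos = sample(1:1000, 20))
  ld20 <- block_ld(cand20$variant_id, blocks, r2_in = 0.5)
  got <- ld_clump(cand20, ld20, r2_max = 0.1)
  oracle <- local({
    left <- cand20[order(cand20$p, cand20$chrom, cand20$pos), ]
    kept <- character(0)
    while (nrow(left)) {
      idx <- left$variant_id[1]
      kept <- c(kept, idx)
      left <- left[ld20[idx, left$variant_id] < 0.1, , drop = FALSE]
    }
    kept
  })
  expect_identical(got, oracle)

  # missing LD entries are treated as independent, with a warning
  expect_warning(
    kept <- ld_clump(cand_df(c(0.1, 0.2), ids = c("v1", "zz")),
                     ld5[1:1, 1:1, drop = FALSE]),
    "no LD entry")
  expect_setequal(kept, c("v1", "zz"))
})

grs_stats <- function() {
  # 50 variants, of which exactly 6 pass p, MAF and window jointly before
  # clumping (all mutually independent here)
  set.seed(7)
  n <- 50
  df <- data.frame(
    variant_id = sprintf("q%02d", 1:n), chrom = "5",
    pos = seq(1e6, 1e6 + 490000, by = 10000),
    ea = "A", oa = "G",
    eaf = rep(0.2, n), beta = rnorm(n, 0, 0.05), se = 0.01,
    p = rep(0.5, n), n = 50000, stringsAsFactors = FALSE)
  df$p[1:6] <- 1e-9
  df$p[7] <- 1e-9; df$eaf[7] <- 0.005        # fails strict MAF
  df$p[8] <- 1e-9; df$pos[8] <- 2e6          # outside window
  df
}

test_that("select_instruments applies region, p, MAF filters then clumps", {
  df <- grs_stats()
  region <- list(gene = "T", chrom = "5", start = 1e6, end = 1.1e6)
  ld <- block_ld(df$variant_id, seq_len(nrow(df)))
  rule <- selection_rule("drug_target")
  inst <- select_instruments(df, region, ld, rule)
  expect_s3_class(inst, "instrument_set")
  expect_identical(inst$k, 6L)
  expect_setequal(inst$variants$variant_id, sprintf("q%02d", 1:6))

  # MAF exactly 0.005 is excluded (strict >)
  expect_false("q07" %in% inst$variants$variant_id)

  # no instrument survives an unreachable p threshold
  df2 <- df; df2$p <- 1e-7
  expect_error(select_instruments(df2, region, ld, rule),
               "no valid instruments.*p_max")
})

test_that("orientation to trait-lowering flips, is idempotent, drops zeros", {
  df <- grs_stats()[1:4, ]
  df$beta <- c(0.3, -0.2, 0.1, 0)
  df$weight <- df$beta
  inst <- structure(list(target = NULL, variants = df,
                         selection_rule = selection_rule("drug_target"),
                         orientation = "raw", k = 4L),
                    class = "instrument_set")
  expect_warning(orient_to_lowering(inst), "zero-beta")
  low <- suppressWarnings(orient_to_lowering(inst))
  expect_identical(low$k, 3L)
  expect_true(all(low$variants$beta < 0))
  expect_identical(low$variants$ea, c("G", "A", "G"))  # flipped where b > 0
  expect_equal(low$variants$eaf[1], 0.8)
  # idempotent
  again <- orient_to_lowering(low)
  expect_identical(again$variants, low$variants)
})

test_that("pQTL action sign rule: inhibitor negates, activator keeps,
           involution", {
  df <- grs_stats()[1:2, ]
  df$weight <- c(0.2, -0.1)
  inst <- structure(list(target = NULL, variants = df,
                         selection_rule = selection_rule("pqtl"),
                         orientation = "raw", k = 2L),
                    class = "instrument_set")
  inh <- apply_action_sign(inst, "inhibitor")
  expect_equal(inh$variants$weight, c(-0.2, 0.1))
  expect_equal(apply_action_sign(inst, "activator")$variants$weight,
               c(0.2, -0.1))
  expect_equal(apply_action_sign(inh, "inhibitor")$variants$weight,
               inst$variants$weight)
  expect_error(apply_action_sign(inst, "agonist"), "unknown action")
})

mini_panel <- function(dosage, ea = "A", oa = "G") {
  vid <- colnames(dosage)
  p <- list(dosage = dosage,
            variants = data.frame(variant_id = vid, chrom = "1",
                                  pos = seq_along(vid), ea = ea, oa = oa,
                                  eaf = colMeans(dosage, na.rm = TRUE) / 2,
                                  block = 1L, stringsAsFactors = FALSE))
  class(p) <- "genotype_panel"
  p
}

mini_inst <- function(ids, weights, ea = "A", oa = "G", eaf = 0.3) {
  structure(list(target = NULL,
                 variants = data.frame(variant_id = ids, ea = ea, oa = oa,
                                       eaf = eaf, beta = weights,
                                       se = 0.01, weight = weights,
                                       stringsAsFactors = FALSE),
                 selection_rule = selection_rule("drug_target"),
                 orientation = "raw", k = length(ids)),
            class = "instrument_set")
}

test_that("compute_grs is a dosage-weight product with allele matching and
           mean imputation", {
  dos <- matrix(c(0, 1, 2, 1,
                  2, 0, 1, 1,
                  1, 1, 0, 2), 4, 3,
                dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  panel <- mini_panel(dos)
  w <- c(0.5, -1, 2)
  sv <- compute_grs(panel, mini_inst(c("a", "b", "c"), w))
  expect_equal(unname(sv$raw), as.numeric(dos %*% w))
  expect_lt(abs(mean(sv$standardized)), 1e-8)
  expect_lt(abs(sd(sv$standardized) - 1), 1e-8)

  # single variant, unit weight: score equals dosage
  one <- compute_grs(panel, mini_inst("a", 1))
  expect_equal(unname(one$raw), unname(dos[, "a"]))
  # all weights zero: all scores zero
  zero <- compute_grs(panel, mini_inst(c("a", "b"), c(0, 0)))
  expect_true(all(zero$raw == 0))
  # missing dosage mean-imputed per variant
  dos_na <- dos; dos_na[1, "a"] <- NA
  svna <- compute_grs(mini_panel(dos_na), mini_inst(c("a", "b", "c"), w))
  imput <- mean(dos_na[-1, "a"])
  expect_equal(unname(svna$raw[1]),
               imput * w[1] + dos[1, "b"] * w[2] + dos[1, "c"] * w[3])
  # absent variant errors with the id in the message
  expect_error(compute_grs(panel, mini_inst("zz", 1)), "zz")
})

test_that("score is invariant under allele-swap plus weight negation", {
  set.seed(11)
  dos <- matrix(rbinom(200, 2, 0.4), 50, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
  rownames(dos) <- paste0("s", 1:50)
  panel <- mini_panel(dos)
  w <- rnorm(4)
  base <- compute_grs(panel, mini_inst(paste0("m", 1:4), w))
  # swap allele labels of variant 2 in the instrument and negate its weight;
  # the panel still counts the original allele, so compute_grs must flip
  w2 <- w; w2[2] <- -w2[2]
  ea <- rep("A", 4); oa <- rep("G", 4)
  ea[2] <- "G"; oa[2] <- "A"
  swapped <- compute_grs(panel, mini_inst(paste0("m", 1:4), w2, ea, oa))
  expect_equal(swapped$standardized, base$standardized, tolerance = 1e-12)
})

test_that("instrument strength follows the quoted R2 and F formulas", {
  # single variant beta 0.1, MAF 0.5 -> R2 = 0.01 * 2 * 0.25 = 0.005
  i1 <- mini_inst("a", 0.1, eaf = 0.5)
  s1 <- instrument_strength(i1, 2111)
  expect_equal(s1$r_squared, 0.005)
  # F = [(N-K-1)/K] R2/(1-R2) = 2109 * 0.005/0.995
  expect_equal(s1$f_statistic, 2109 * 0.005 / 0.995, tolerance = 1e-12)
  expect_true(s1$strong)

  # all-zero weights: R2 = 0, F = 0
  s0 <- instrument_strength(mini_inst(c("a", "b"), c(0, 0)), 1000)
  expect_equal(s0$r_squared, 0)
  expect_equal(s0$f_statistic, 0)

  # adding a nonzero variant increases R2
  s2 <- instrument_strength(mini_inst(c("a", "b"), c(0.1, 0.05),
                                      eaf = c(0.5, 0.2)), 2111)
  expect_gt(s2$r_squared, s1$r_squared)

  # missing MAF falls back to the squared Wald statistic
  im <- mini_inst("a", 0.1, eaf = NA_real_)
  sm <- instrument_strength(im, 2111)
  expect_equal(sm$f_statistic, (0.1 / 0.01)^2)

  expect_error(instrument_strength(i1, 2), "n_samples")
})

test_that("per-SD regression effects are invariant to positive affine
           rescaling of raw weights", {
  set.seed(13)
  dos <- matrix(rbinom(600, 2, 0.3), 150, 4,
                dimnames = list(paste0("s", 1:150), paste0("m", 1:4)))
  panel <- mini_panel(dos)
  w <- rnorm(4)
  y <- rnorm(150) + as.numeric(dos %*% w)
  s_a <- compute_grs(panel, mini_inst(paste0("m", 1:4), w))
  s_b <- compute_grs(panel, mini_inst(paste0("m", 1:4), 3.7 * w))
  b_a <- coef(lm(y ~ s_a$standardized))[2]
  b_b <- coef(lm(y ~ s_b$standardized))[2]
  expect_equal(unname(b_a), unname(b_b), tolerance = 1e-10)
})
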