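# independent exact-HWE oracle: direct log-factorial evaluation of the
# conditional distribution of heterozygote counts given the allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  lp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

test_that("exact HWE test: anchor values, symmetry, enumeration oracle", {
  # most probable heterozygote configuration -> p = 1
  expect_equal(hwe_test(25, 50, 25), 1)
  # all-heterozygote extreme fails the 1e-6 filter
  expect_lt(hwe_test(0, 100, 0), 1e-6)
  expect_error(hwe_test(0, 0, 0), "zero")

  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:66, 1)                    # totals up to ~200 alleles
    cnt <- as.vector(rmultinom(1, n, c(0.3, 0.45, 0.25)))
    p1 <- hwe_test(cnt[1], cnt[2], cnt[3])
    expect_equal(p1, hwe_test(cnt[3], cnt[2], cnt[1]), tolerance = 1e-12)
    expect_equal(p1, hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  # larger totals against the oracle
  for (cnt in list(c(120, 60, 20), c(50, 100, 50), c(198, 2, 0))) {
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  # chi-square route approximates the exact test at large balanced counts
  expect_equal(hwe_test(2500, 5000, 2500, method = "chisq"), 1)
})

make_panel <- function(dosage, ids = NULL) {
  vid <- colnames(dosage) %||% sprintf("v%03d", seq_len(ncol(dosage)))
  colnames(dosage) <- vid
  rownames(dosage) <- ids %||% sprintf("S%03d", seq_len(nrow(dosage)))
  p <- list(dosage = dosage,
            variants = data.frame(variant_id = vid, chrom = "1",
                                  pos = seq_len(ncol(dosage)),
                                  ea = "A", oa = "G",
                                  eaf = colMeans(dosage, na.rm = TRUE) / 2,
                                  block = 1L, stringsAsFactors = FALSE))
  class(p) <- "genotype_panel"
  p
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("variant_qc applies the three filters in order and matches brute
           force", {
  set.seed(2)
  n <- 400
  g_ok <- rbinom(n, 2, 0.3)
  g_miss <- g_ok; g_miss[1:12] <- NA             # 3% missing
  g_rare <- rbinom(n, 2, 0.001)                  # MAF < 0.01
  g_edge <- c(rep(1L, 8), rep(0L, n - 8))        # MAF exactly 0.01
  g_hwe <- rep(1L, n)                            # all hets
  panel <- make_panel(cbind(ok = g_ok, miss = g_miss, rare = g_rare,
                            edge = g_edge, hwe = g_hwe))
  res <- variant_qc(panel)
  expect_true("ok" %in% res$keep)
  expect_true("edge" %in% res$keep)   # strict "<": MAF exactly 0.01 retained
  expect_identical(res$removed$reason[res$removed$variant_id == "miss"],
                   "missingness")
  expect_identical(res$removed$reason[res$removed$variant_id == "rare"],
                   "maf")
  expect_identical(res$removed$reason[res$removed$variant_id == "hwe"],
                   "hwe")

  # 100 random variants vs an independent rule application
  set.seed(3)
  G <- sapply(1:100, function(j) {
    g <- rbinom(120, 2, runif(1, 0.002, 0.5))
    if (runif(1) < 0.2) g[sample(120, sample(0:8, 1))] <- NA
    g
  })
  pan <- make_panel(G)
  got <- variant_qc(pan)$keep
  th <- qc_thresholds()
  want <- colnames(pan$dosage)[apply(pan$dosage, 2, function(g) {
    gg <- g[!is.na(g)]
    maf <- min(mean(gg) / 2, 1 - mean(gg) / 2)
    mean(is.na(g)) <= th$variant_missing_max &&
      maf >= th$variant_maf_min &&
      hwe_oracle(sum(gg == 0), sum(gg == 1), sum(gg == 2)) >= th$hwe_p_min
  })]
  expect_identical(got, want)
})

test_that("sample_qc removes missing, duplicated, and outlying samples", {
  cfg <- sim_config(n_samples = 150, n_variants = 300, ld_block_size = 1,
                    ld_rho = 0, seed = 8)
  panel <- simulate_genotype_panel(cfg)
  G <- panel$dosage
  G["S0002", ] <- G["S0001", ]                   # duplicate pair, PI-hat ~ 1
  G["S0003", seq_len(30)] <- NA                  # 10% missing
  panel$dosage <- G
  res <- sample_qc(panel)
  expect_identical(
    res$removed$reason[res$removed$sample_id == "S0003"], "missingness")
  dup_removed <- intersect(res$removed$sample_id, c("S0001", "S0002"))
  expect_identical(dup_removed, "S0002")   # equal missingness -> later id
  # unrelated simulated samples produce no relatedness removals
  cfg2 <- sim_config(n_samples = 200, n_variants = 500, ld_block_size = 1,
                     ld_rho = 0, seed = 9)
  res2 <- sample_qc(simulate_genotype_panel(cfg2))
  expect_false("relatedness" %in% res2$removed$reason)

  # QC is idempotent: a second pass removes nothing
  kept <- res2$keep
  pan3 <- simulate_genotype_panel(cfg2)
  pan3$dosage <- pan3$dosage[kept, , drop = FALSE]
  res3 <- sample_qc(pan3)
  expect_identical(res3$keep, kept)
})

test_that("relatedness is skipped with too few markers", {
  cfg <- sim_config(n_samples = 50, n_variants = 40, seed = 1)
  expect_warning(sample_qc(simulate_genotype_panel(cfg)),
                 "relatedness step skipped")
})

test_that("exclusion cascade bookkeeping balances and handles overlap", {
  led <- exclusion_cascade(3030, list(no_genotype = 474, outlier = 442,
                                      cvd_drug = 3))
  expect_identical(led$n_remaining[nrow(led)], 2111L)
  expect_true(all(diff(led$n_remaining) <= 0))
  expect_identical(led$n_remaining,
                   cumsum(c(3030L, -led$n_removed[-1])))

  expect_identical(exclusion_cascade(100, list())$n_remaining, 100L)

  # overlapping steps: each id counted once, at its first removing step
  ids <- paste0("P", 1:10)
  expect_warning(exclusion_cascade(ids, list(c = "nope")), "unknown id")
  led2 <- suppressWarnings(
    exclusion_cascade(ids, list(a = c("P1", "P2", "P3"),
                                b = c("P3", "P4"),
                                c = c("P1", "P9", "nope"))))
  expect_identical(led2$n_removed, c(0L, 3L, 1L, 1L))
  expect_identical(led2$n_remaining[4], 5L)
  expect_setequal(attr(led2, "remaining_ids"),
                  c("P5", "P6", "P7", "P8", "P10"))
})
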