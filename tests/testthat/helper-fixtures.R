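# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# small cohort with a known causal chain, no confounding unless asked
tiny_config <- function(seed = 1, n = 500, confounded = FALSE, ...) {
  sim_config(n_samples = n, n_variants = 10, ld_block_size = 1, ld_rho = 0,
             n_causal = 5,
             confounder_trait_beta = if (confounded) 10 else 0,
             confounder_outcome_beta = if (confounded) 5 else 0,
             seed = seed, ...)
}

# deterministic small regression fixture (n rows, k covariates)
lm_fixture <- function(n = 20, k = 2, seed = 42, hetero = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
  sd <- if (hetero) abs(X[, 1]) + 0.2 else 1
  y <- 1 + X %*% rep(0.5, k) + rnorm(n, 0, sd)
  d <- data.frame(y = as.numeric(y), X)
  list(data = d, fit = lm(y ~ ., data = d), X = cbind(1, X), y = d$y)
}

# one-row summary-stat record
rec <- function(ea, oa, beta = 0.1, eaf = 0.3, se = 0.02, p = 1e-9) {
  list(ea = ea, oa = oa, beta = beta, eaf = eaf, se = se, p = p)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

sumstats_df <- function(n = 3) {
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = "1",
             pos = 1000 * seq_len(n), ea = "A", oa = "G",
             eaf = 0.3, beta = 0.1, se = 0.02, p = 5e-09, n = 10000,
             stringsAsFactors = FALSE)
}
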