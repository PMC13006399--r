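#' Simulation configuration for the synthetic cohort generator
#'
#' Describes a complete synthetic study: a genotype panel (biallelic variants
#' in Hardy-Weinberg equilibrium with block LD), a quantitative metabolic
#' trait (mg/dL) driven by a sparse set of causal variants, and a treatment
#' outcome (percentage symptom reduction on the PANSS) causally downstream of
#' the trait. A latent confounder feeds both the trait and the outcome so
#' that naive observational regression is biased while genetic instruments
#' remain valid.
#'
#' @param n_samples number of individuals (>= 2).
#' @param n_variants number of biallelic variants.
#' @param maf_range length-2 vector of minor-allele frequencies in (0, 0.5];
#'   per-variant MAFs are drawn uniformly from this interval.
#' @param ld_block_size variants per LD block (equicorrelated latent draw).
#' @param ld_rho target latent correlation within a block, in [0, 1).
#' @param n_causal number of causal variants (spread across blocks).
#' @param variance_explained fraction of trait variance the causal score
#'   should explain; when non-`NULL` it overrides `grs_trait_beta`.
#' @param grs_trait_beta trait units (mg/dL) per SD of the standardized
#'   causal score; derived from `variance_explained` when that is given.
#' @param trait_outcome_beta percent PANSS reduction per trait unit (mg/dL);
#'   the true causal effect every estimator should recover.
#' @param pqtl_chain optional `list(variant_protein =, protein_trait =)`
#'   betas; when given, the genetic effect on the trait is routed through a
#'   simulated protein level (a pQTL mediation chain).
#' @param covariate_effects named numeric vector of additive covariate
#'   effects on the trait (names among `sex`, `age`).
#' @param noise_sd_trait,noise_sd_outcome residual SDs of trait (mg/dL) and
#'   outcome (percent reduction).
#' @param confounder_trait_beta,confounder_outcome_beta effects of the
#'   latent standard-normal confounder on trait and outcome.
#' @param trait_mean,outcome_mean marginal means (mg/dL; percent reduction).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_samples = 2000,
                       n_variants = 40,
                       maf_range = c(0.05, 0.45),
                       ld_block_size = 5,
                       ld_rho = 0.5,
                       n_causal = 5,
                       variance_explained = 0.05,
                       grs_trait_beta = NULL,
                       trait_outcome_beta = 0.5,
                       pqtl_chain = NULL,
                       covariate_effects = c(sex = -3, age = 0.3),
                       noise_sd_trait = 25,
                       noise_sd_outcome = 20,
                       confounder_trait_beta = 10,
                       confounder_outcome_beta = 5,
                       trait_mean = 100,
                       outcome_mean = 50,
                       seed = 1L) {
  assert_that(is.numeric(n_samples) && n_samples >= 2,
              "n_samples must be >= 2 (got %s)", format(n_samples))
  assert_that(is.numeric(n_variants) && n_variants >= 1,
              "n_variants must be positive")
  assert_that(length(maf_range) == 2 && all(maf_range > 0) &&
              all(maf_range <= 0.5) && maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  assert_that(ld_rho >= 0 && ld_rho < 1, "ld_rho must be in [0, 1)")
  assert_that(ld_block_size >= 1, "ld_block_size must be >= 1")
  assert_that(n_causal >= 1 && n_causal <= n_variants,
              "n_causal must be in [1, n_variants]")
  if (!is.null(variance_explained))
    assert_that(variance_explained >= 0 && variance_explained < 1,
                "variance_explained must be in [0, 1)")
  if (!is.null(pqtl_chain))
    assert_that(all(c("variant_protein", "protein_trait") %in%
                    names(pqtl_chain)),
                "pqtl_chain needs variant_protein and protein_trait betas")
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = as.numeric(ld_rho),
              n_causal = as.integer(n_causal),
              variance_explained = variance_explained,
              grs_trait_beta = grs_trait_beta,
              trait_outcome_beta = trait_outcome_beta,
              pqtl_chain = pqtl_chain,
              covariate_effects = covariate_effects,
              noise_sd_trait = noise_sd_trait,
              noise_sd_outcome = noise_sd_outcome,
              confounder_trait_beta = confounder_trait_beta,
              confounder_outcome_beta = confounder_outcome_beta,
              trait_mean = trait_mean,
              outcome_mean = outcome_mean,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genotype panel in HWE with block LD
#'
#' Draws per-variant MAFs from `maf_range`, then hard-call dosages in
#' \{0, 1, 2\} by thresholding an equicorrelated Gaussian latent variable per
#' LD block at the HWE genotype-probability quantiles. Each variant is
#' therefore marginally in exact Hardy-Weinberg proportions; within a block,
#' latent correlation `ld_rho` induces genotype LD of roughly that magnitude.
#'
#' @param config a [sim_config()].
#' @return a `genotype_panel`: list with `dosage` (n x m integer matrix,
#'   dimnames = sample/variant ids) and `variants` (data.frame: variant_id,
#'   chrom, pos, ea, oa, eaf, block). `eaf` is the frequency of the effect
#'   (alternate) allele whose count the dosage records.
#' @export
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m <- config$n_variants
  with_seed(config$seed, {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(m)]
    rho <- config$ld_rho
    dos <- matrix(0L, n, m)
    for (b in unique(block)) {
      idx <- which(block == b)
      shared <- stats::rnorm(n)
      for (j in idx) {
        z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
        p <- maf[j]
        # cumulative HWE probabilities for dosage 0 / 1 / 2
        c0 <- (1 - p)^2
        c1 <- c0 + 2 * p * (1 - p)
        dos[, j] <- ifelse(z < stats::qnorm(c0), 0L,
                    ifelse(z < stats::qnorm(c1), 1L, 2L))
      }
    }
    ids <- sprintf("S%04d", seq_len(n))
    vid <- sprintf("rs%05d", seq_len(m))
    dimnames(dos) <- list(ids, vid)
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
    panel <- list(
      dosage = dos,
      variants = data.frame(variant_id = vid,
                            chrom = "11",
                            pos = 116700000L + 10000L * (seq_len(m) - 1L),
                            ea = ea, oa = unname(oa),
                            eaf = maf, block = block,
                            stringsAsFactors = FALSE))
    class(panel) <- "genotype_panel"
    panel
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (%d LD blocks)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$block))))
  invisible(x)
}

#' Ground-truth record for a simulated study
#'
#' Chooses `n_causal` causal variants spread over distinct LD blocks and
#' draws their per-allele effects. The stored betas are on the raw trait
#' scale actually used by [simulate_phenotypes()], so parameter-recovery
#' tests can compare estimates against them directly.
#'
#' @param panel a `genotype_panel`.
#' @param config the matching [sim_config()].
#' @return a `truth_record`: causal_variant_ids, per-layer true betas
#'   (variant_trait, and variant_protein / protein_trait when a pQTL chain is
#'   configured, trait_outcome), and variance_explained_target.
#' @export
make_truth <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    v <- panel$variants
    blocks <- unique(v$block)
    # one causal variant per block until n_causal is reached
    pick <- integer(0)
    bi <- rep_len(blocks, config$n_causal)
    for (b in seq_len(config$n_causal)) {
      cand <- setdiff(which(v$block == bi[b]), pick)
      if (length(cand) == 0) cand <- setdiff(seq_len(nrow(v)), pick)
      pick <- c(pick, cand[1L + (b - 1L) %% length(cand)])
    }
    raw <- stats::rnorm(config$n_causal, mean = 0, sd = 1)
    raw[raw == 0] <- 0.1
    # scale so the standardized causal score has the requested trait effect
    G <- panel$dosage[, pick, drop = FALSE]
    g <- as.numeric(G %*% raw)
    sdg <- stats::sd(g)
    if (sdg == 0) sdg <- 1
    b_sd <- config$grs_trait_beta
    if (!is.null(config$variance_explained)) {
      v_rest <- resid_variance(config)
      h <- config$variance_explained
      b_sd <- sqrt(h * v_rest / (1 - h))
    }
    if (is.null(b_sd)) b_sd <- 5
    beta_trait <- raw * b_sd / sdg
    truth <- list(causal_variant_ids = v$variant_id[pick],
                  beta_variant_trait = beta_trait,
                  beta_trait_outcome = config$trait_outcome_beta,
                  beta_variant_protein = NULL,
                  beta_protein_trait = NULL,
                  variance_explained_target = config$variance_explained,
                  grs_trait_beta = b_sd)
    if (!is.null(config$pqtl_chain)) {
      truth$beta_variant_protein <-
        raw * config$pqtl_chain$variant_protein / sdg
      truth$beta_protein_trait <- config$pqtl_chain$protein_trait
    }
    class(truth) <- "truth_record"
    truth
  })
}

# non-genetic trait variance implied by a config (covariates + confounder +
# residual noise); used to convert variance_explained into a per-SD beta
resid_variance <- function(config) {
  ce <- config$covariate_effects
  v_cov <- 0
  if ("sex" %in% names(ce)) v_cov <- v_cov + ce[["sex"]]^2 * 0.25
  if ("age" %in% names(ce)) v_cov <- v_cov + ce[["age"]]^2 * (45 - 18)^2 / 12
  v_cov + config$confounder_trait_beta^2 + config$noise_sd_trait^2
}

#' Simulate phenotypes, covariates, and PANSS outcomes for a panel
#'
#' Builds the cohort table: covariates (sex, age, 5 study centers, five
#' genetic PCs, illness course, previous medication, assigned drug class),
#' the metabolic trait, and PANSS totals/subscales at baseline and endpoint.
#' The trait is `trait_mean + beta_sd * standardized causal score +
#' covariate effects + confounder + noise`; the percentage reduction is
#' generated on the reduction scale (`outcome_mean + trait_outcome_beta *
#' (trait - trait_mean) + confounder + noise`) and back-transformed into
#' endpoint scores, so baseline total minus 30 is always positive.
#'
#' @param panel a `genotype_panel`.
#' @param truth a `truth_record` referring to variants of `panel`.
#' @param config the matching [sim_config()].
#' @return a data.frame cohort table with one row per sample.
#' @export
simulate_phenotypes <- function(panel, truth, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(truth, "truth_record"))
  miss <- setdiff(truth$causal_variant_ids, panel$variants$variant_id)
  if (length(miss))
    stop_dtmr("truth references variants absent from panel: %s",
              paste(miss, collapse = ", "))
  n <- nrow(panel$dosage)
  with_seed(config$seed + 2L, {
    sex <- stats::rbinom(n, 1, 0.5)
    age <- stats::runif(n, 18, 45)
    center <- factor(sample(paste0("C", 1:5), n, replace = TRUE))
    pcs <- matrix(stats::rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("PC", 1:5)))
    course <- stats::rlnorm(n, log(4.5), 0.9)
    prior_med <- stats::rbinom(n, 1, 0.52)
    drug_class <- stats::rbinom(n, 1, 0.5)
    U <- stats::rnorm(n)

    G <- panel$dosage[, truth$causal_variant_ids, drop = FALSE]
    ce <- config$covariate_effects
    cov_part <- 0
    if ("sex" %in% names(ce)) cov_part <- cov_part + ce[["sex"]] * sex
    if ("age" %in% names(ce)) cov_part <- cov_part + ce[["age"]] * (age - 31.5)

    if (!is.null(truth$beta_variant_protein)) {
      protein <- as.numeric(G %*% truth$beta_variant_protein) +
        stats::rnorm(n, 0, 1)
      genetic_part <- truth$beta_protein_trait * protein
    } else {
      protein <- NULL
      genetic_part <- as.numeric(G %*% truth$beta_variant_trait)
    }
    trait <- config$trait_mean + genetic_part + cov_part +
      config$confounder_trait_beta * U +
      stats::rnorm(n, 0, config$noise_sd_trait)

    reduction <- config$outcome_mean +
      config$trait_outcome_beta * (trait - config$trait_mean) +
      config$confounder_outcome_beta * U +
      stats::rnorm(n, 0, config$noise_sd_outcome)

    baseline_total <- pmax(41, round(stats::rnorm(n, 90, 15)))
    endpoint_total <- baseline_total - reduction / 100 * (baseline_total - 30)
    sub_base <- list(p = pmax(8, round(stats::rnorm(n, 22, 5))),
                     n = pmax(8, round(stats::rnorm(n, 23, 5))),
                     g = pmax(17, round(stats::rnorm(n, 45, 9))))
    sub_red <- lapply(c(p = 1, n = 2, g = 3), function(k)
      reduction + stats::rnorm(n, 0, 8))

    out <- data.frame(
      sample_id = rownames(panel$dosage),
      sex = sex, age = age, center = center,
      pcs, course = course, prior_med = prior_med, drug_class = drug_class,
      trait = trait,
      baseline_total = baseline_total, endpoint_total = endpoint_total,
      baseline_p = sub_base$p, endpoint_p = sub_base$p * (1 - sub_red$p / 100),
      baseline_n = sub_base$n, endpoint_n = sub_base$n * (1 - sub_red$n / 100),
      baseline_g = sub_base$g, endpoint_g = sub_base$g * (1 - sub_red$g / 100),
      stringsAsFactors = FALSE)
    if (!is.null(protein)) out$protein <- protein
    out$reduction_total <- panss_reduction(out$baseline_total,
                                           out$endpoint_total, "total")
    out$reduction_p <- panss_reduction(out$baseline_p, out$endpoint_p,
                                       "subscale")
    out$reduction_n <- panss_reduction(out$baseline_n, out$endpoint_n,
                                       "subscale")
    out$reduction_g <- panss_reduction(out$baseline_g, out$endpoint_g,
                                       "subscale")
    out$responder <- as.integer(out$reduction_total >
                                stats::median(out$reduction_total))
    out
  })
}

#' Simulate external GWAS summary statistics matched to a panel
#'
#' Draws an independent genotype panel with the same variant metadata and a
#' trait with the same genetic architecture, then runs the per-variant
#' marginal regression of trait on dosage, recording beta, SE, p, effect
#' allele, frequency, and N. Optionally simulates a second trait whose causal
#' variant is shared with the first (colocalization H4 scenario) or lies in a
#' different LD block (H3 scenario).
#'
#' @param panel a `genotype_panel` (its variants define the universe).
#' @param truth a `truth_record` for the first trait.
#' @param config the matching [sim_config()].
#' @param n_gwas GWAS sample size (default 10000).
#' @param second_trait one of "none", "shared", "distinct".
#' @param seed seed for the GWAS panel (default `config$seed + 3`).
#' @return a data.frame of summary statistics (columns variant_id, chrom,
#'   pos, ea, oa, eaf, beta, se, p, n); with `second_trait != "none"` an
#'   attribute `"trait2"` holds the second trait's table and
#'   `"causal2"` its causal variant id.
#' @export
simulate_summary_stats <- function(panel, truth, config, n_gwas = 10000,
                                   second_trait = c("none", "shared",
                                                    "distinct"),
                                   seed = NULL) {
  second_trait <- match.arg(second_trait)
  stopifnot(inherits(panel, "genotype_panel"), inherits(truth, "truth_record"))
  seed <- seed %||% (config$seed + 3L)
  cfg2 <- config
  cfg2$n_samples <- as.integer(n_gwas)
  cfg2$seed <- as.integer(seed)
  gpanel <- simulate_genotype_panel(cfg2)
  # keep the original variant universe (ids, positions, alleles)
  gpanel$variants <- panel$variants
  colnames(gpanel$dosage) <- panel$variants$variant_id

  with_seed(seed + 7L, {
    G <- gpanel$dosage[, truth$causal_variant_ids, drop = FALSE]
    y <- as.numeric(G %*% truth$beta_variant_trait) +
      stats::rnorm(n_gwas, 0, sqrt(resid_variance(config)))
    ss <- marginal_gwas(gpanel, y)
    if (second_trait != "none") {
      v <- gpanel$variants
      c1 <- truth$causal_variant_ids[1]
      if (second_trait == "shared") {
        c2 <- c1
      } else {
        b1 <- v$block[v$variant_id == c1]
        cand <- v$variant_id[v$block != b1]
        c2 <- cand[ceiling(length(cand) / 2)]
      }
      # second-trait causal effect sized to explain 2% of its variance:
      # a clearly detectable single-variant signal at GWAS sample sizes
      p2 <- v$eaf[v$variant_id == c2]
      vres <- resid_variance(config)
      b2 <- sqrt(0.02 / 0.98 * vres / (2 * p2 * (1 - p2)))
      y2 <- b2 * gpanel$dosage[, c2] +
        stats::rnorm(n_gwas, 0, sqrt(vres))
      ss2 <- marginal_gwas(gpanel, y2)
      attr(ss, "trait2") <- ss2
      attr(ss, "causal2") <- c2
    }
    ss
  })
}

# vectorized per-variant simple linear regression of y on each dosage column
marginal_gwas <- function(panel, y) {
  G <- panel$dosage
  n <- nrow(G)
  gm <- colMeans(G)
  vg <- apply(G, 2, stats::var)
  vg[vg == 0] <- NA_real_
  cv <- as.numeric(crossprod(scale(G, center = gm, scale = FALSE),
                             y - mean(y))) / (n - 1)
  beta <- cv / vg
  s2 <- pmax(0, (stats::var(y) - beta^2 * vg)) * (n - 1) / (n - 2)
  se <- sqrt(s2 / ((n - 1) * vg))
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  v <- panel$variants
  data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
             ea = v$ea, oa = v$oa, eaf = gm / 2,
             beta = beta, se = se, p = p, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a complete miniature study to disk
#'
#' Materializes genotypes (TSV), the cohort table, first- and second-trait
#' summary statistics, a target-gene definition table, and a JSON truth
#' ledger in the formats the readers in this package consume, so an
#' end-to-end run needs no external data.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param second_trait passed to [simulate_summary_stats()].
#' @return invisibly, a named list of the file paths written.
#' @export
make_fixture_suite <- function(config = sim_config(), dir,
                               second_trait = "shared") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_genotype_panel(config)
  truth <- make_truth(panel, config)
  cohort <- simulate_phenotypes(panel, truth, config)
  ss <- simulate_summary_stats(panel, truth, config,
                               second_trait = second_trait)
  v <- panel$variants
  targets <- data.frame(
    gene = "TARGET1", chrom = v$chrom[1],
    start = min(v$pos) + 50000L, end = max(v$pos) - 50000L,
    drug = "drugA", action = "inhibitor", modality = "lipid",
    stringsAsFactors = FALSE)
  paths <- list(
    dosage = file.path(dir, "dosages.tsv"),
    variants = file.path(dir, "variants.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    sumstats = file.path(dir, "sumstats_trait1.tsv"),
    sumstats2 = file.path(dir, "sumstats_trait2.tsv"),
    targets = file.path(dir, "targets.tsv"),
    truth = file.path(dir, "truth.json"))
  write_dosage_tsv(panel, paths$dosage)
  utils::write.table(v, paths$variants, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort, paths$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ss, paths$sumstats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss2 <- attr(ss, "trait2")
  if (!is.null(ss2))
    utils::write.table(ss2, paths$sumstats2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else paths$sumstats2 <- NULL
  utils::write.table(targets, paths$targets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(causal_variant_ids = truth$causal_variant_ids,
         beta_variant_trait = truth$beta_variant_trait,
         beta_trait_outcome = truth$beta_trait_outcome,
         variance_explained_target = truth$variance_explained_target,
         causal2 = attr(ss, "causal2")),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write / read a dosage matrix as TSV (samples x variants)
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @export
write_dosage_tsv <- function(panel, path) {
  df <- data.frame(sample_id = rownames(panel$dosage), panel$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param variants_path optional variants metadata TSV written by
#'   [make_fixture_suite()]; when given, the returned panel carries full
#'   variant metadata.
#' @export
read_dosage_tsv <- function(path, variants_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df[[1]]
  if (!is.null(variants_path)) {
    variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
    variants$chrom <- as.character(variants$chrom)
  } else {
    variants <- data.frame(variant_id = colnames(dos), chrom = NA_character_,
                           pos = NA_integer_, ea = NA_character_,
                           oa = NA_character_,
                           eaf = colMeans(dos, na.rm = TRUE) / 2,
                           block = NA_integer_, stringsAsFactors = FALSE)
  }
  panel <- list(dosage = dos, variants = variants)
  class(panel) <- "genotype_panel"
  panel
}
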