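#' Pipeline configuration
#'
#' Validates the full-run configuration before any stage executes; unknown
#' keys are rejected so typos fail fast. Either a simulation block (the
#' synthetic-study generator) or explicit input paths must be supplied.
#'
#' @param out_dir directory for stage artifacts and the report.
#' @param seed master seed; every stage derives its randomness from it.
#' @param sim named list of [sim_config()] overrides, or `NULL` to read
#'   inputs from `paths`.
#' @param paths named list (dosage, variants, cohort, sumstats, sumstats2,
#'   targets) when running on files instead of the generator.
#' @param qc named list of [qc_thresholds()] overrides.
#' @param coloc_priors list(p1, p2, p12).
#' @param second_trait coloc scenario for the generator: "shared" or
#'   "distinct".
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("dtmr_run_"),
                            seed = 1L,
                            sim = list(),
                            paths = NULL,
                            qc = list(),
                            coloc_priors = list(p1 = 1e-4, p2 = 1e-4,
                                                p12 = 1e-5),
                            second_trait = "shared") {
  if (!is.null(paths)) {
    need <- c("dosage", "cohort", "sumstats", "targets")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stop_dtmr("pipeline_config: paths lacks %s",
                paste(missing, collapse = ", "))
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone))
      stop_dtmr("pipeline_config: missing input file(s): %s",
                paste(gone, collapse = ", "))
  }
  if (length(sim)) {
    unknown <- setdiff(names(sim), names(formals(sim_config)))
    if (length(unknown))
      stop_dtmr("pipeline_config: unknown sim key(s): %s",
                paste(unknown, collapse = ", "))
  }
  if (length(qc)) {
    unknown <- setdiff(names(qc), names(formals(qc_thresholds)))
    if (length(unknown))
      stop_dtmr("pipeline_config: unknown qc key(s): %s",
                paste(unknown, collapse = ", "))
  }
  stopifnot(all(c("p1", "p2", "p12") %in% names(coloc_priors)))
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              paths = paths, qc = qc, coloc_priors = coloc_priors,
              second_trait = second_trait)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) -> genotype/sample QC with exclusion
#' ledger -> instrument selection and GRS construction -> one-sample
#' associations (trait, efficacy, trend, 2SLS, FDR) -> stratified and
#' factorial analyses -> two-sample MR (PRESSO screen, IVW, weighted
#' median, Egger) -> colocalization -> diagnostics -> report. Artifacts are
#' written under `config$out_dir`; identical config + seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(name) message(sprintf("[dtmr] stage: %s", name))
  res <- list()

  log_stage("simulate/load")
  if (is.null(config$paths)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    panel <- simulate_genotype_panel(scfg)
    truth <- make_truth(panel, scfg)
    cohort <- simulate_phenotypes(panel, truth, scfg)
    ss <- simulate_summary_stats(panel, truth, scfg,
                                 second_trait = config$second_trait)
    v <- panel$variants
    targets <- data.frame(gene = "TARGET1", chrom = v$chrom[1],
                          start = min(v$pos), end = max(v$pos),
                          drug = "drugA", action = "inhibitor",
                          modality = "lipid", stringsAsFactors = FALSE)
    res$truth <- truth
  } else {
    panel <- read_dosage_tsv(config$paths$dosage,
                             config$paths$variants %||% NULL)
    cohort <- utils::read.delim(config$paths$cohort,
                                stringsAsFactors = FALSE)
    cohort$center <- factor(cohort$center)
    ss <- read_summary_stats(config$paths$sumstats)
    if (!is.null(config$paths$sumstats2))
      attr(ss, "trait2") <- read_summary_stats(config$paths$sumstats2)
    targets <- read_target_genes(config$paths$targets)
  }

  log_stage("qc")
  th <- do.call(qc_thresholds, config$qc)
  vqc <- variant_qc(panel, th)
  sqc <- sample_qc(panel, th)
  ledger <- exclusion_cascade(
    rownames(panel$dosage),
    split(sqc$removed$sample_id, sqc$removed$reason))
  panel$dosage <- panel$dosage[sqc$keep, vqc$keep, drop = FALSE]
  panel$variants <- panel$variants[panel$variants$variant_id %in% vqc$keep, ,
                                   drop = FALSE]
  cohort <- cohort[match(sqc$keep, cohort$sample_id), , drop = FALSE]
  utils::write.table(as.data.frame(ledger),
                     file.path(config$out_dir, "exclusion_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$qc <- list(variant = vqc, sample = sqc, ledger = ledger)

  log_stage("scores")
  ss_kept <- ss[ss$variant_id %in% vqc$keep, , drop = FALSE]
  ld <- ld_matrix(panel)
  inst <- select_instruments(ss_kept, targets[1, ], ld,
                             selection_rule("drug_target"))
  inst_low <- orient_to_lowering(inst)
  grs <- compute_grs(panel, inst_low)
  # strength on the standardized-trait scale
  inst_std <- inst_low
  trait_sd <- stats::sd(cohort$trait)
  inst_std$variants$weight <- inst_std$variants$weight / trait_sd
  strength <- instrument_strength(inst_std, max(ss_kept$n))
  cohort$grs <- grs$standardized
  res$instruments <- inst_low
  res$strength <- strength

  log_stage("assoc")
  covs_t <- covariate_spec(efficacy = FALSE)
  covs_e <- covariate_spec(efficacy = TRUE)
  trait_assoc <- fit_adjusted(cohort, "trait", "grs", covs_t, "linear")
  outcomes <- c("reduction_total", "reduction_p", "reduction_n",
                "reduction_g")
  eff <- lapply(outcomes, function(o)
    fit_adjusted(cohort, o, "grs", covs_e, "linear"))
  names(eff) <- outcomes
  fdr <- adjust_multiplicity(vapply(eff, `[[`, 0, "p"), "bh")
  for (i in seq_along(eff)) eff[[i]]$p_fdr <- fdr[i]
  responder <- fit_adjusted(cohort, "responder", "grs", covs_e, "logistic")
  trends <- c(age = trend_test(cohort, "age", "grs"),
              sex = trend_test(cohort, "sex", "grs"))
  tsls <- two_stage_ls(cohort, "reduction_total", "trait", "grs", covs_e)
  conv <- rescale_per_trait_units(eff$reduction_total$estimate,
                                  trait_assoc$estimate)
  res$assoc <- list(trait = trait_assoc, efficacy = eff,
                    responder = responder, trend = trends, tsls = tsls,
                    conversion = conv)

  log_stage("strata/factorial")
  strat <- stratified_with_interaction(cohort, "reduction_total", "grs",
                                       "sex", covs_e)
  # stand-in second target: the trailing LD block, weighted by its
  # marginal trait betas (synthetic-only construct)
  vb <- panel$variants
  last_block <- vb$variant_id[vb$block == max(vb$block)]
  ss2 <- ss_kept[ss_kept$variant_id %in% last_block, , drop = FALSE]
  ss2$weight <- ss2$beta
  inst_b <- list(target = NULL, variants = ss2,
                 selection_rule = selection_rule("drug_target"),
                 orientation = "raw", k = nrow(ss2))
  class(inst_b) <- "instrument_set"
  grs_b <- compute_grs(panel, inst_b)
  cohort$grs_b <- grs_b$standardized
  groups <- factorial_groups(cohort$grs, cohort$grs_b)
  fact <- factorial_effects(cohort, "reduction_total", groups,
                            "grs", "grs_b", covs_e)
  res$strata <- strat
  res$factorial <- fact

  log_stage("two-sample MR")
  out_gwas <- marginal_gwas(panel, cohort$reduction_total)
  iv <- inst_low$variants$variant_id
  mx <- ss_kept[match(iv, ss_kept$variant_id), ]
  my <- out_gwas[match(iv, out_gwas$variant_id), ]
  mri <- mr_input(mx$beta, mx$se, my$beta, my$se, iv)
  presso <- if (nrow(mri) >= 4) mr_presso(mri, seed = config$seed) else NULL
  mri_use <- if (!is.null(presso)) presso$filtered else mri
  mr <- list(ivw = mr_ivw(mri_use),
             wm = if (nrow(mri_use) >= 3)
               mr_weighted_median(mri_use, seed = config$seed) else NULL,
             egger = if (nrow(mri_use) >= 3) mr_egger(mri_use) else NULL,
             presso = presso)
  res$mr2 <- mr

  log_stage("coloc")
  ss2t <- attr(ss, "trait2")
  if (!is.null(ss2t)) {
    ss2t <- ss2t[ss2t$variant_id %in% vqc$keep, , drop = FALSE]
    reg <- data.frame(variant_id = ss_kept$variant_id, pos = ss_kept$pos,
                      p = ss_kept$p)
    pruned <- ld_prune_region(reg, ld)
    i1 <- match(pruned, ss_kept$variant_id)
    i2 <- match(pruned, ss2t$variant_id)
    ci <- data.frame(variant_id = pruned,
                     beta1 = ss_kept$beta[i1], se1 = ss_kept$se[i1],
                     beta2 = ss2t$beta[i2], se2 = ss2t$se[i2],
                     maf = pmin(ss_kept$eaf[i1], 1 - ss_kept$eaf[i1]),
                     n1 = ss_kept$n[i1], n2 = ss2t$n[i2])
    res$coloc <- coloc_posteriors(ci, config$coloc_priors)
  }

  log_stage("diagnostics")
  res$diagnostics <- model_diagnostics(eff$reduction_total$fit, "grs")

  log_stage("report")
  write_report(res, config)
  invisible(res)
}

write_report <- function(res, config) {
  eff <- res$assoc$efficacy
  tab <- data.frame(
    outcome = names(eff),
    estimate = vapply(eff, `[[`, 0, "estimate"),
    se = vapply(eff, `[[`, 0, "se"),
    se_hc3 = vapply(eff, `[[`, 0, "se_hc3"),
    ci_lo = vapply(eff, function(e) e$ci95[1], 0),
    ci_hi = vapply(eff, function(e) e$ci95[2], 0),
    p = vapply(eff, `[[`, 0, "p"),
    p_fdr = vapply(eff, `[[`, 0, "p_fdr"),
    n = vapply(eff, `[[`, 0L, "n"))
  utils::write.table(tab, file.path(config$out_dir, "efficacy_assoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(
    "dtmr pipeline report",
    sprintf("seed: %d", config$seed),
    sprintf("instruments: k = %d, R2 = %.4f, F = %.1f (%s)",
            res$strength$k, res$strength$r_squared,
            res$strength$f_statistic,
            if (res$strength$strong) "strong" else "weak"),
    sprintf("score -> trait: beta = %.3f mg/dL per SD (p = %.3g)",
            res$assoc$trait$estimate, res$assoc$trait$p),
    sprintf("per-10-mg/dL conversion multiplier: %.2f",
            res$assoc$conversion$multiplier),
    sprintf("2SLS trait -> reduction: %.4f %%/mg/dL (first-stage F %.1f)",
            res$assoc$tsls$estimate, res$assoc$tsls$first_stage_f),
    sprintf("IVW: %.4f (p = %.3g); factorial product-term p = %.3g",
            res$mr2$ivw$estimate, res$mr2$ivw$p,
            res$factorial$p_product_interaction),
    if (!is.null(res$coloc))
      sprintf("coloc: PP.H4 = %.3f, lead = %s",
              res$coloc$pp["H4"], res$coloc$lead_variant),
    sprintf("diagnostics: BP p = %.3g, White p = %.3g, stability = %s",
            res$diagnostics$bp_p, res$diagnostics$white_p,
            res$diagnostics$stability))
  writeLines(lines, file.path(config$out_dir, "report.txt"))
  invisible(NULL)
}
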