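#' Pairwise LD (r-squared) from a reference genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param variant_ids subset of variants (default all).
#' @return symmetric matrix of squared Pearson correlations between dosages.
#' @export
ld_matrix <- function(panel, variant_ids = NULL) {
  G <- panel$dosage
  if (!is.null(variant_ids)) G <- G[, variant_ids, drop = FALSE]
  r <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Greedy LD clumping
#'
#' Takes the lowest-p unprocessed variant as index, discards all others with
#' r-squared >= `r2_max` against it, and repeats. Ties in p are broken by
#' (chrom, pos). Pairs without an LD entry are treated as independent with a
#' warning.
#'
#' @param candidates data.frame with variant_id, p, chrom, pos.
#' @param ld square r-squared matrix with variant ids as dimnames.
#' @param r2_max clumping threshold (default 0.1).
#' @return character vector of retained variant ids (in index order).
#' @export
ld_clump <- function(candidates, ld, r2_max = 0.1) {
  stopifnot(nrow(candidates) >= 1)
  ord <- order(candidates$p, candidates$chrom, candidates$pos)
  cand <- candidates[ord, , drop = FALSE]
  missing_ld <- setdiff(cand$variant_id, rownames(ld))
  if (length(missing_ld)) {
    warning(sprintf("no LD entry for %d variant(s); treated as r2 = 0",
                    length(missing_ld)), call. = FALSE)
    pad <- matrix(0, length(missing_ld), length(missing_ld),
                  dimnames = list(missing_ld, missing_ld))
    full <- matrix(0, nrow(ld) + length(missing_ld),
                   ncol(ld) + length(missing_ld))
    rownames(full) <- colnames(full) <- c(rownames(ld), missing_ld)
    full[rownames(ld), colnames(ld)] <- ld
    full[missing_ld, missing_ld] <- pad
    diag(full) <- 1
    ld <- full
  }
  keep <- character(0)
  todo <- cand$variant_id
  while (length(todo)) {
    idx <- todo[1]
    keep <- c(keep, idx)
    r2 <- ld[idx, todo]
    todo <- todo[r2 < r2_max & todo != idx]
  }
  keep
}

#' Select instruments for a drug-target (or genome-wide) score
#'
#' Applies, in order: the target-region window (when a region is given),
#' the association threshold `p <= p_max`, the common-variant filter
#' `MAF > maf_min` (strict), then greedy LD clumping at `r2_max`. Drug-target
#' scores use p < 5e-8, r2 < 0.1 and a 100 kb window; genome-wide
#' ("traditional") scores use p < 5e-8, r2 < 0.001 and no region filter;
#' pQTL scores use p < 0.005 within the window.
#'
#' @param stats harmonized summary-stats data.frame.
#' @param region one row of a target-gene table, or `NULL` for genome-wide.
#' @param ld r-squared matrix covering the candidates.
#' @param rule list with p_max, r2_max, maf_min, window_bp, source; see
#'   [selection_rule()].
#' @return an `instrument_set` (orientation "raw", weights = trait betas).
#' @export
select_instruments <- function(stats, region = NULL, ld,
                               rule = selection_rule()) {
  df <- stats
  fail_at <- function(stage) {
    stop_dtmr("no valid instruments: all candidates removed at filter '%s'",
              stage)
  }
  if (!is.null(region)) {
    df <- filter_target_region(df, region, rule$window_bp)
    if (nrow(df) == 0) fail_at("region")
  }
  df <- df[df$p <= rule$p_max, , drop = FALSE]
  if (nrow(df) == 0) fail_at("p_max")
  maf <- pmin(df$eaf, 1 - df$eaf)
  df <- df[maf > rule$maf_min, , drop = FALSE]
  if (nrow(df) == 0) fail_at("maf")
  kept <- ld_clump(df, ld, rule$r2_max)
  df <- df[match(kept, df$variant_id), , drop = FALSE]
  df$weight <- df$beta
  rownames(df) <- NULL
  inst <- list(target = region, variants = df, selection_rule = rule,
               orientation = "raw", k = nrow(df))
  class(inst) <- "instrument_set"
  inst
}

#' Selection rules for the three score flavours
#'
#' @param type "drug_target" (p < 5e-8, r2 < 0.1, 100 kb window),
#'   "traditional" (p < 5e-8, r2 < 0.001, genome-wide), or
#'   "pqtl" (p < 0.005, r2 < 0.1, 100 kb window).
#' @return a rule list (p_max, r2_max, maf_min, window_bp, source).
#' @export
selection_rule <- function(type = c("drug_target", "traditional", "pqtl")) {
  type <- match.arg(type)
  switch(type,
    drug_target = list(p_max = 5e-8, r2_max = 0.1, maf_min = 0.005,
                       window_bp = 100000, source = "gwas"),
    traditional = list(p_max = 5e-8, r2_max = 0.001, maf_min = 0.005,
                       window_bp = NA, source = "gwas"),
    pqtl        = list(p_max = 0.005, r2_max = 0.1, maf_min = 0.005,
                       window_bp = 100000, source = "pqtl"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: k = %d, orientation = %s, source = %s\n",
              x$k, x$orientation, x$selection_rule$source))
  invisible(x)
}

#' Orient all instrument weights to trait-lowering
#'
#' For each variant with a positive trait beta, swaps effect/other alleles,
#' negates the beta, and mirrors the frequency, so that every weight is <= 0
#' on the trait scale and a higher score means a genetically lower trait.
#' Variants with beta exactly 0 are dropped with a warning. Idempotent.
#'
#' @param inst an `instrument_set`.
#' @return the oriented `instrument_set` (orientation "lowering").
#' @export
orient_to_lowering <- function(inst) {
  v <- inst$variants
  zero <- v$beta == 0
  if (any(zero)) {
    warning(sprintf("dropped %d zero-beta variant(s) during orientation",
                    sum(zero)), call. = FALSE)
    v <- v[!zero, , drop = FALSE]
  }
  flip <- v$beta > 0
  if (any(flip)) {
    tmp <- v$ea[flip]
    v$ea[flip] <- v$oa[flip]
    v$oa[flip] <- tmp
    v$eaf[flip] <- 1 - v$eaf[flip]
    v$beta[flip] <- -v$beta[flip]
  }
  v$weight <- v$beta
  inst$variants <- v
  inst$k <- nrow(v)
  inst$orientation <- "lowering"
  inst
}

#' Apply the drug-action sign rule to a pQTL score
#'
#' Mimics pharmacological modulation of the target protein: for a target
#' inhibited by its drug, all weights are multiplied by -1 (simulated
#' suppression); for an activator target the weights are kept. An involution
#' for inhibitors.
#'
#' @param inst an `instrument_set` built from pQTL statistics.
#' @param action "inhibitor" or "activator".
#' @return the adjusted `instrument_set`.
#' @export
apply_action_sign <- function(inst, action) {
  if (!action %in% c("inhibitor", "activator"))
    stop_dtmr("unknown action '%s'", action)
  if (action == "inhibitor") inst$variants$weight <- -inst$variants$weight
  inst
}

#' Compute a weighted genetic risk score
#'
#' Raw score per sample is the sum of effect-allele dosages weighted by the
#' instrument weights; missing dosages are mean-imputed per variant (2 x
#' eaf in the panel). The standardized score (mean 0, SD 1 in-sample) is
#' attached alongside.
#'
#' @param panel a `genotype_panel` whose dosages count the instrument's
#'   effect alleles.
#' @param inst an `instrument_set`.
#' @return a `score_vector`: list(raw, standardized, variant_ids), both
#'   numeric vectors named by sample id.
#' @export
compute_grs <- function(panel, inst) {
  v <- inst$variants
  missing <- setdiff(v$variant_id, colnames(panel$dosage))
  if (length(missing))
    stop_dtmr("instrument variants absent from panel: %s",
              paste(missing, collapse = ", "))
  G <- panel$dosage[, v$variant_id, drop = FALSE]
  # align panel dosages to the instrument's effect alleles
  pv <- panel$variants[match(v$variant_id, panel$variants$variant_id), ]
  if (!all(is.na(pv$ea))) {
    same <- pv$ea == v$ea & pv$oa == v$oa
    swapped <- pv$ea == v$oa & pv$oa == v$ea
    if (any(!same & !swapped, na.rm = TRUE))
      stop_dtmr("allele mismatch between panel and instruments: %s",
                paste(v$variant_id[!same & !swapped], collapse = ", "))
    if (any(swapped))
      G[, swapped] <- 2 - G[, swapped]
  }
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      na <- is.na(G[, j])
      if (any(na)) G[na, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  raw <- as.numeric(G %*% v$weight)
  names(raw) <- rownames(G)
  s <- stats::sd(raw)
  std <- if (is.finite(s) && s > 0) (raw - mean(raw)) / s else raw * 0
  out <- list(raw = raw, standardized = std, variant_ids = v$variant_id)
  class(out) <- "score_vector"
  out
}

#' Instrument strength: variance explained and F statistic
#'
#' R-squared is the sum over instruments of beta^2 x 2 x MAF x (1 - MAF)
#' (per-allele betas on a variance-1 trait scale), and
#' F = [(N - K - 1)/K] x R^2/(1 - R^2). For variants without allele
#' frequency the conventional fallback F = (beta/SE)^2 is used, and the
#' overall F is the average of the per-route F contributions. F > 10 is
#' flagged as a strong instrument.
#'
#' @param inst an `instrument_set`; weights must be on a standardized-trait
#'   scale for R-squared to be a variance fraction.
#' @param n_samples GWAS sample size N.
#' @return list(r_squared, f_statistic, k, strong).
#' @export
instrument_strength <- function(inst, n_samples) {
  v <- inst$variants
  k <- nrow(v)
  if (n_samples <= k + 1)
    stop_dtmr("instrument_strength: need n_samples > k + 1 (n = %d, k = %d)",
              n_samples, k)
  maf <- pmin(v$eaf, 1 - v$eaf)
  has_maf <- is.finite(maf)
  r2 <- sum(v$weight[has_maf]^2 * 2 * maf[has_maf] * (1 - maf[has_maf]))
  if (all(has_maf)) {
    f <- if (r2 == 0) 0 else (n_samples - k - 1) / k * r2 / (1 - r2)
  } else {
    # mixed route: formula-F for frequency-backed variants, Wald-F fallback
    # for the rest, averaged
    f_parts <- numeric(0)
    if (any(has_maf) && r2 > 0) {
      k1 <- sum(has_maf)
      f_parts <- rep((n_samples - k1 - 1) / k1 * r2 / (1 - r2), k1)
    }
    f_parts <- c(f_parts, (v$weight[!has_maf] / v$se[!has_maf])^2)
    f <- mean(f_parts)
  }
  list(r_squared = r2, f_statistic = f, k = k, strong = f > 10)
}
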