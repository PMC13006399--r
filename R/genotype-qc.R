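#' Quality-control thresholds
#'
#' Defaults reproduce the study-standard filters: variant missingness > 0.02,
#' MAF < 0.01, exact HWE p < 1e-6; sample missingness > 0.05, heterozygosity
#' beyond 3 SD, relatedness PI-hat >= 0.2, PC outliers beyond 6 SD on any of
#' the top five components.
#'
#' @param variant_missing_max,variant_maf_min,hwe_p_min variant-level limits.
#' @param sample_missing_max,het_sd,ibd_max,pc_outlier_sd sample-level limits.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(variant_missing_max = 0.02,
                          variant_maf_min = 0.01,
                          hwe_p_min = 1e-6,
                          sample_missing_max = 0.05,
                          het_sd = 3,
                          ibd_max = 0.2,
                          pc_outlier_sd = 6) {
  th <- list(variant_missing_max = variant_missing_max,
             variant_maf_min = variant_maf_min,
             hwe_p_min = hwe_p_min,
             sample_missing_max = sample_missing_max,
             het_sd = het_sd,
             ibd_max = ibd_max,
             pc_outlier_sd = pc_outlier_sd)
  stopifnot(all(vapply(th, function(x) is.numeric(x) && x >= 0, TRUE)))
  class(th) <- "qc_thresholds"
  th
}

#' Exact (or chi-square) Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test conditional on the observed allele counts: the
#' p-value is the total probability of all heterozygote configurations no
#' more probable than the observed one. The exact distribution is evaluated
#' with the numerically stable ratio recurrence over heterozygote counts.
#' Symmetric under allele relabeling (swapping `n_AA` and `n_aa`).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @param method "exact" (default) or "chisq" (1-df Pearson test, no
#'   continuity correction).
#' @return the p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_dtmr("hwe_test: all genotype counts are zero")
  if (method == "chisq") {
    p <- (2 * n_AA + n_Aa) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    o <- c(n_AA, n_Aa, n_aa)
    if (any(e == 0)) return(1)
    x2 <- sum((o - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  nA <- 2 * n_AA + n_Aa       # count of the A allele
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)         # test is symmetric in the allele labels
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities by the ratio recurrence
  # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    nAA_h <- (rare - h) / 2
    naa_h <- (2 * n - rare - h) / 2
    logp[i] <- logp[i - 1] +
      log(4 * nAA_h * naa_h) - log((h + 2) * (h + 1))
  }
  prob <- exp(logp - logsum(logp))
  obs <- match(n_Aa, hets)
  if (is.na(obs))
    stop_dtmr("hwe_test: inconsistent genotype counts (parity)")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

dosage_maf <- function(g) {
  p <- mean(g, na.rm = TRUE) / 2
  min(p, 1 - p)
}

#' Variant-level QC
#'
#' Removes a variant if missingness exceeds `variant_missing_max`, OR its
#' MAF is strictly below `variant_maf_min`, OR its exact HWE p-value is
#' strictly below `hwe_p_min`. The first failing rule (in that order) is
#' recorded as the reason.
#'
#' @param panel a `genotype_panel` (hard-call dosages, NAs allowed).
#' @param thresholds a [qc_thresholds()].
#' @return list with `keep` (variant ids retained) and `removed`
#'   (data.frame variant_id, reason).
#' @export
variant_qc <- function(panel, thresholds = qc_thresholds()) {
  G <- panel$dosage
  reasons <- character(0)
  removed <- character(0)
  keep <- character(0)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    vid <- colnames(G)[j]
    miss <- mean(is.na(g))
    if (miss > thresholds$variant_missing_max) {
      removed <- c(removed, vid); reasons <- c(reasons, "missingness")
      next
    }
    if (dosage_maf(g) < thresholds$variant_maf_min) {
      removed <- c(removed, vid); reasons <- c(reasons, "maf")
      next
    }
    gg <- g[!is.na(g)]
    pv <- hwe_test(sum(gg == 0), sum(gg == 1), sum(gg == 2))
    if (pv < thresholds$hwe_p_min) {
      removed <- c(removed, vid); reasons <- c(reasons, "hwe")
      next
    }
    keep <- c(keep, vid)
  }
  list(keep = keep,
       removed = data.frame(variant_id = removed, reason = reasons,
                            stringsAsFactors = FALSE))
}

#' Method-of-moments relatedness (PI-hat) from dosages
#'
#' Standardized genetic-relationship estimate between every pair of samples:
#' the average over variants of the products of allele-frequency-centred,
#' variance-scaled dosages. Expectation is ~1 for duplicates/monozygotic
#' pairs, ~0.5 for first-degree relatives, ~0 for unrelated pairs.
#'
#' @param panel a `genotype_panel`.
#' @return symmetric n x n matrix of PI-hat estimates.
#' @export
pihat_matrix <- function(panel) {
  G <- panel$dosage
  p <- colMeans(G, na.rm = TRUE) / 2
  ok <- p > 0 & p < 1
  G <- G[, ok, drop = FALSE]
  p <- p[ok]
  Z <- sweep(G, 2, 2 * p, `-`)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  Z[is.na(Z)] <- 0
  A <- tcrossprod(Z) / ncol(Z)
  dimnames(A) <- list(rownames(G), rownames(G))
  A
}

#' Sample-level QC
#'
#' Removes samples for (in order): missingness above `sample_missing_max`;
#' heterozygosity rate beyond `het_sd` SDs of the cohort mean; relatedness
#' (within each pair with PI-hat >= `ibd_max`, the member with the higher
#' missingness is dropped, ties broken by dropping the lexicographically
#' later id); PC outliers beyond `pc_outlier_sd` SDs on any of the top five
#' components. PCA is skipped with a warning when fewer than 3 samples
#' survive the earlier steps.
#'
#' @param panel a `genotype_panel`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `keep` (sample ids) and `removed`
#'   (data.frame sample_id, reason).
#' @export
sample_qc <- function(panel, thresholds = qc_thresholds()) {
  G <- panel$dosage
  ids <- rownames(G)
  removed <- character(0); reasons <- character(0)
  drop_sample <- function(id, why) {
    removed <<- c(removed, id); reasons <<- c(reasons, why)
  }
  miss <- rowMeans(is.na(G))
  names(miss) <- ids
  for (id in ids[miss > thresholds$sample_missing_max])
    drop_sample(id, "missingness")
  alive <- setdiff(ids, removed)

  het <- rowMeans(G[alive, , drop = FALSE] == 1, na.rm = TRUE)
  mu <- mean(het); s <- stats::sd(het)
  if (is.finite(s) && s > 0)
    for (id in alive[abs(het - mu) > thresholds$het_sd * s])
      drop_sample(id, "heterozygosity")
  alive <- setdiff(ids, removed)

  if (ncol(G) < 100) {
    warning(sprintf(paste0("relatedness step skipped: %d variants are too ",
                           "few for a stable PI-hat estimate"), ncol(G)),
            call. = FALSE)
  } else if (length(alive) >= 2) {
    sub <- panel; sub$dosage <- G[alive, , drop = FALSE]
    A <- pihat_matrix(sub)
    ut <- which(upper.tri(A) & A >= thresholds$ibd_max, arr.ind = TRUE)
    in_play <- stats::setNames(rep(TRUE, length(alive)), alive)
    for (r in seq_len(nrow(ut))) {
      pair <- rownames(A)[ut[r, ]]
      if (!all(in_play[pair])) next   # a member already dropped
      mi <- miss[pair]
      victim <- if (mi[1] > mi[2]) pair[1]
        else if (mi[2] > mi[1]) pair[2]
        else max(pair)          # tie -> lexicographically later id
      drop_sample(victim, "relatedness")
      in_play[victim] <- FALSE
    }
  }
  alive <- setdiff(ids, removed)

  if (length(alive) < 3) {
    warning("fewer than 3 samples: PCA outlier step skipped", call. = FALSE)
  } else {
    X <- G[alive, , drop = FALSE]
    X[is.na(X)] <- 0
    sds <- apply(X, 2, stats::sd)
    X <- X[, sds > 0, drop = FALSE]
    npc <- min(5, ncol(X), length(alive) - 1)
    pcs <- stats::prcomp(X, center = TRUE, scale. = TRUE)$x[, seq_len(npc),
                                                            drop = FALSE]
    out <- rep(FALSE, length(alive))
    for (k in seq_len(npc)) {
      z <- pcs[, k]
      s <- stats::sd(z)
      if (s > 0) out <- out | abs(z - mean(z)) > thresholds$pc_outlier_sd * s
    }
    for (id in alive[out]) drop_sample(id, "pc_outlier")
  }
  list(keep = setdiff(ids, removed),
       removed = data.frame(sample_id = removed, reason = reasons,
                            stringsAsFactors = FALSE))
}

#' Sequential exclusion cascade with an auditable ledger
#'
#' Applies removal steps in order to a starting id set; ids already removed
#' by an earlier step are not double-counted, and unknown ids are ignored
#' with a warning. The returned ledger satisfies
#' `n_remaining = previous n_remaining - n_removed` at every step.
#'
#' @param ids starting ids (character), or a single count `n` (ids are then
#'   generated as `P1..Pn`).
#' @param steps named list of id vectors to remove, in order. For
#'   count-style bookkeeping a step may instead be a single integer, read as
#'   "remove this many of the currently remaining" (taken from the head).
#' @return an `exclusion_ledger` data.frame: step, n_removed, n_remaining.
#' @export
exclusion_cascade <- function(ids, steps) {
  if (is.numeric(ids) && length(ids) == 1) ids <- paste0("P", seq_len(ids))
  remaining <- ids
  led <- data.frame(step = "start", n_removed = 0L,
                    n_remaining = length(remaining),
                    stringsAsFactors = FALSE)
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    label <- names(steps)[k] %||% paste0("step", k)
    if (label == "") label <- paste0("step", k)
    if (is.numeric(st) && length(st) == 1) {
      st <- utils::head(remaining, st)
    } else {
      unknown <- setdiff(st, ids)
      if (length(unknown))
        warning(sprintf("step '%s': %d unknown id(s) ignored", label,
                        length(unknown)), call. = FALSE)
    }
    gone <- intersect(remaining, st)
    remaining <- setdiff(remaining, gone)
    led <- rbind(led, data.frame(step = label, n_removed = length(gone),
                                 n_remaining = length(remaining),
                                 stringsAsFactors = FALSE))
  }
  attr(led, "remaining_ids") <- remaining
  class(led) <- c("exclusion_ledger", "data.frame")
  led
}
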