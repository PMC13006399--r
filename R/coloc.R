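#' Sliding-window LD pruning before colocalization
#'
#' Within each window (positions closer than `window_bp`), any pair with
#' r-squared >= `r2_max` loses one member: the variant with the larger p
#' (tie broken by dropping the later position). Defaults match the standard
#' pre-colocalization pruning (500 kb window, r-squared 0.8).
#'
#' @param variants data.frame with variant_id, pos, p.
#' @param ld r-squared matrix with variant ids as dimnames.
#' @param window_bp window size in bp (default 500000).
#' @param r2_max pruning threshold (default 0.8).
#' @return retained variant ids.
#' @export
ld_prune_region <- function(variants, ld, window_bp = 500000, r2_max = 0.8) {
  # greedy in ascending (p, pos) order: a variant is kept unless it is in
  # high LD, within the window, with an already-kept (better-p) variant --
  # so of any conflicting pair the larger-p (tie: later-position) member
  # is the one dropped
  v <- variants[order(variants$p, variants$pos), , drop = FALSE]
  keep <- character(0)
  keep_pos <- numeric(0)
  for (i in seq_len(nrow(v))) {
    near <- abs(keep_pos - v$pos[i]) <= window_bp
    if (!any(near) ||
        all(ld[v$variant_id[i], keep[near]] < r2_max)) {
      keep <- c(keep, v$variant_id[i])
      keep_pos <- c(keep_pos, v$pos[i])
    }
  }
  keep[order(match(keep, variants$variant_id))]
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect with standard error `se` and a N(0, prior_sd^2)
#' effect prior: with `z = beta/se` and `r = prior_sd^2/(prior_sd^2 + se^2)`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se effect estimate and standard error (vectors allowed).
#' @param prior_sd prior SD of the true effect (default 0.15 for a
#'   quantitative trait on the SD scale).
#' @return log approximate Bayes factor(s) favouring association.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop_dtmr("wakefield_log_abf: se must be positive")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

# reconstruct beta/se from p, MAF and N for a variance-1 quantitative trait
zmaf_to_beta_se <- function(p, maf, n) {
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  se <- 1 / sqrt(2 * n * maf * (1 - maf))
  list(beta = z * se, se = se)
}

# estimate the outcome SD from the relationship var(beta_j) ~ sdY^2 /
# (2 N maf_j (1 - maf_j)); regression of 1/se^2 on 2 N maf (1-maf) through
# the origin. Used to put arbitrary-scale betas on the SD scale so the
# effect prior applies and results are invariant to common rescaling.
estimate_sdy <- function(se, maf, n) {
  oneover <- 1 / se^2
  nvx <- 2 * n * maf * (1 - maf)
  m <- sum(nvx * oneover) / sum(nvx^2)
  if (!is.finite(m) || m <= 0) return(1)
  sqrt(1 / m)
}

#' Bayesian colocalization of two traits in one locus
#'
#' Enumerates the five hypotheses — H0: no association; H1/H2: only trait
#' 1/2 associated; H3: two distinct causal variants; H4: one shared causal
#' variant — from per-variant Wakefield ABFs and the prior probabilities
#' that a variant is causal for trait 1 (`p1`), trait 2 (`p2`), or both
#' (`p12`). Reports the five posteriors, the per-variant posterior of being
#' the shared variant given H4, and the lead shared variant (the argmax).
#'
#' @param input data.frame with `variant_id` and either `beta1, se1,
#'   beta2, se2` or `p1, p2` plus `maf` and `n1, n2`.
#' @param priors list(p1, p2, p12); defaults 1e-4, 1e-4, 1e-5.
#' @param prior_sd effect-prior SD passed to [wakefield_log_abf()].
#' @return a `coloc_result`: pp (named H0..H4, sums to 1), priors,
#'   snp_pp_h4 (named; sums to 1), lead_variant, lead_pp_h4.
#' @export
coloc_posteriors <- function(input,
                             priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                             prior_sd = 0.15) {
  if (nrow(input) < 2)
    stop_dtmr("coloc_posteriors: need at least 2 variants")
  if (all(c("beta1", "se1", "beta2", "se2") %in% names(input))) {
    b1 <- input$beta1; s1 <- input$se1
    b2 <- input$beta2; s2 <- input$se2
    if (all(c("maf", "n1", "n2") %in% names(input))) {
      # put both traits on the SD scale before applying the effect prior
      sdy1 <- estimate_sdy(s1, input$maf, input$n1)
      sdy2 <- estimate_sdy(s2, input$maf, input$n2)
      b1 <- b1 / sdy1; s1 <- s1 / sdy1
      b2 <- b2 / sdy2; s2 <- s2 / sdy2
    }
    l1 <- wakefield_log_abf(b1, s1, prior_sd)
    l2 <- wakefield_log_abf(b2, s2, prior_sd)
  } else if (all(c("p1", "p2", "maf") %in% names(input))) {
    r1 <- zmaf_to_beta_se(input$p1, input$maf, input$n1)
    r2 <- zmaf_to_beta_se(input$p2, input$maf, input$n2)
    l1 <- wakefield_log_abf(r1$beta, r1$se, prior_sd)
    l2 <- wakefield_log_abf(r2$beta, r2$se, prior_sd)
  } else {
    stop_dtmr("coloc input needs beta/se pairs or p + maf + n columns")
  }
  ls1 <- logsum(l1)
  ls2 <- logsum(l2)
  ls12 <- logsum(l1 + l2)
  # log unnormalized hypothesis weights
  lh0 <- 0
  lh1 <- log(priors$p1) + ls1
  lh2 <- log(priors$p2) + ls2
  # H3: sum over ordered distinct pairs = S1*S2 - S12
  cross <- logdiff(ls1 + ls2, ls12)
  lh3 <- log(priors$p1) + log(priors$p2) + cross
  lh4 <- if (priors$p12 > 0) log(priors$p12) + ls12 else -Inf
  lall <- c(H0 = lh0, H1 = lh1, H2 = lh2, H3 = lh3, H4 = lh4)
  fin <- is.finite(lall)
  denom <- logsum(lall[fin])
  pp <- ifelse(fin, exp(lall - denom), 0)
  names(pp) <- names(lall)
  snp_pp <- exp(l1 + l2 - ls12)
  names(snp_pp) <- input$variant_id
  lead <- which.max(snp_pp)
  out <- list(pp = pp, priors = priors,
              snp_pp_h4 = snp_pp,
              lead_variant = input$variant_id[lead],
              lead_pp_h4 = unname(snp_pp[lead]))
  class(out) <- "coloc_result"
  out
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalization posteriors:\n")
  print(round(x$pp, 4))
  cat(sprintf("lead shared variant: %s (SNP.PP.H4 = %.3f)\n",
              x$lead_variant, x$lead_pp_h4))
  invisible(x)
}
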