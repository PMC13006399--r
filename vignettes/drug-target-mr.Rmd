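---
title: "Drug-target Mendelian randomization for treatment response: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target MR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dtmr)
```

## The question and the causal model

Antipsychotic-treated patients are frequently dyslipidemic or
hyperglycemic, and many receive metabolic-modifying co-medication. Whether
pharmacological lowering of a lipid or glucose trait helps or harms the
antipsychotic response cannot be read off observational regressions:
symptom severity, adherence, diet and co-medication confound the
trait–outcome relationship. `dtmr` operationalizes the genetic workaround.
Variants in and around a gene encoding a drug's pharmacological target that
associate with the drug's biomarker (e.g. triglycerides for an APOC3
inhibitor, glucose for a GCK activator) proxy lifelong modulation of that
target. Aggregated into a weighted score, they form an instrument that is
(by Mendel's laws) independent of the confounders above.

The estimand chain is:

1. **score → trait**: the drug-target GRS must move the measured trait
   (trend tests, adjusted linear regression, instrument strength R²/F);
2. **score → efficacy**: the same score against the PANSS percentage
   reduction (total and positive/negative/general subscales), adjusted for
   the covariate set;
3. **trait → efficacy**: two-stage least squares with a genome-wide
   ("traditional") score instrumenting the trait;
4. corroboration: two-sample MR estimators on summary statistics,
   protein-level (pQTL) scores with the drug-action sign rule, mediation by
   conditioning, colocalization at the locus, and a 2×2 factorial contrast
   of two targets.

## Outcome construction

The total PANSS has a floor of 30 (each of 30 items scores at least 1), so
the improvable range at baseline is `baseline − 30` and the percentage
reduction is `100 (baseline − endpoint) / (baseline − 30)`. Subscale floors
are not subtracted. We orient the formula so that **positive values mean
improvement**: the source material prints the numerator as
endpoint − baseline yet reports positive medians throughout, so the printed
sign cannot be the operational one; we follow the reported convention and
document the flip rather than reproduce the typo. The binary "responder"
outcome is a reduction strictly greater than the in-sample median; ties at
the median are non-responders.

## Covariates

`covariate_spec()` encodes the standard adjustment set: sex, age and age²
(the source lists "age, age," which we read as a quadratic age term),
study center, the top five genetic principal components, illness course,
and previous medication; the assigned antipsychotic class is added exactly
when the outcome is an efficacy measure. The invariants (age² travels with
age; drug class iff efficacy outcome) are enforced structurally.

## Instrument construction

- Drug-target scores: p ≤ 5×10⁻⁸, MAF > 0.005 (strict), ±100 kb window
  around the gene, greedy LD clumping at r² < 0.1 (ties in p broken by
  chromosome/position — the tie rule is ours, the source is silent).
- Genome-wide scores: same thresholds but r² < 0.001 and no window.
- pQTL scores: p ≤ 0.005 within the window; for targets *inhibited* by
  their drug all weights are multiplied by −1 to mimic suppression, for
  activator targets weights are kept.

Weights are harmonized to trait-lowering orientation (`orient_to_lowering`),
and `compute_grs` aligns panel dosages to the instrument's effect alleles
before scoring, so the standardized score is invariant to allele-label
bookkeeping. Missing dosages are mean-imputed per variant — scoring
practice the source does not discuss.

The variance-explained formula R² = Σβ²·2·MAF·(1−MAF) is only a variance
fraction when the per-allele betas are on a variance-1 trait scale;
`instrument_strength` documents and expects that convention. When a
variant lacks allele-frequency information the fallback is the squared
Wald statistic (β/SE)² — the source prints the fallback without the
square, which we read as shorthand for the conventional statistic.

## Two-stage least squares

Stage 1 regresses the trait on the score, stage 2 the outcome on the
predicted trait; covariates enter **both** stages (the source words stage 1
as trait ~ GRS alone, but conditioning both stages is the consistent
estimator under its adjusted models; the choice is configurable). Standard
errors come from the proper IV variance — residuals are formed with the
*observed* trait — not the naive stage-2 OLS SE, which is anticonservative.
First-stage partial F below 10 triggers a weak-instrument warning but the
estimate is still returned.

## Two-sample estimators

Wald ratios use second-order-free weights `(β_exposure/se_outcome)²` — the
simplest standard choice; the source names methods but not weighting
variants. IVW fixed-effects SE is `(Σw)^{-1/2}`; the random-effects model
scales it by `max(1, √(Q/(k−1)))` and is selected automatically when
Cochran's Q has p < 0.05. The weighted median interpolates the ratio at the
0.5 crossing of normalized cumulative weight and bootstraps its SE
parametrically under a fixed seed. MR-Egger re-orients inputs to positive
exposure betas and reports the weighted intercept as the directional
pleiotropy test. The PRESSO-style test is re-specified from its published
logic — observed residual sum of squares about leave-one-out IVW fits,
compared to parametric simulations under the no-pleiotropy model, with
Bonferroni-corrected per-variant outlier tails — because the original is a
package citation, not a formula, in the source. With `n_sim` simulations
the smallest achievable outlier p is `k/(n_sim+1)`; the default
`n_sim = 1000` keeps that below the 0.05 flag threshold for k ≤ 50.

## Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor
`log ABF = ½[log(1−r) + r·z²]`, `r = W/(W+V)`. The five-hypothesis
enumeration uses priors p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ (the cited method's
defaults; the source states none) and the decision threshold PP.H4 > 0.6
as quoted (the field often uses 0.8; we honour the quoted value). Effects
are put on the SD scale before the prior applies: when MAF and N accompany
beta/se, the trait SD is estimated from the se–MAF–N relationship (as the
reference implementation does), which also makes the posteriors invariant
to rescaling both traits by a common constant. Both input routes — beta/se
and p+MAF+N — are implemented because the source does not say which was
used. Pre-pruning follows the quoted 500 kb window and r² 0.8, greedy in
ascending (p, position) order.

The enumeration assumes at most one causal variant per trait in the locus.
The test suite shows both sides of that assumption: single-causal
simulations give decisive PP.H4 (shared) or PP.H3 (distinct), while the
pipeline's default five-causal-variant trait yields H3-leaning posteriors —
a faithful property of the method, not a defect.

## Diagnostics and the stability rule

Breusch-Pagan and White are LM (n·R²) tests on the squared residuals; HC3
uses leverage-squared residual weights (score residuals and the inverse
information for logistic models); influence combines Cook's D > 0.5 with
|studentized deleted residual| > 4 and refits without flagged points
(refitting from the design matrix, so transformed terms like age² are
safe); VIF > 10 flags collinearity. An effect is "stable" iff direction,
conventional-95%-CI overlap, and α = 0.05 significance all agree between
the primary and the refit model — CI overlap is tested on conventional
intervals because the source reports both flavours without saying which
feeds the rule (configurable).

## The synthetic cohort: what it emulates and what it does not

The motivating studies' individual-level data are access-restricted, so the
generator is the package's test bed. It emulates: ~2,000-sample cohorts;
biallelic variants in exact marginal HWE (dosages are thresholded
equicorrelated Gaussians, so each variant's genotype frequencies are exact
HWE at its sampled MAF) with block LD of tunable strength; a trait in
mg/dL whose causal score explains a target variance fraction (defaults in
the 0.3–5.5% range reported for real drug-target scores); a PANSS endpoint
generated on the reduction scale and back-transformed so baseline totals
stay above the 30 floor; covariates (sex ~ Bernoulli(0.5), age ~
Uniform(18, 45) matching the cohorts' age range, five centers, five PCs,
course, prior medication, drug class); and matched external summary
statistics from an independent panel, with a second trait whose causal
variant is shared (H4) or in a different LD block (H3).

Fixed choices, made once:

- **Confounding**: the criteria require "confounded trait–outcome noise"
  but no magnitude. We give the latent confounder 10 mg/dL per SD on the
  trait and 5 percentage points on the reduction — strong enough that naive
  OLS of reduction on trait is biased by ≈ +0.07 (visibly outside the
  acceptance band) while 2SLS stays centred on the truth.
- **Noise scales**: trait residual SD 25 mg/dL and outcome residual SD 20
  points give trait and reduction spreads comparable to the reported
  cohort IQRs (reduction median ≈ 50).
- **Second-trait effect**: the shared/distinct causal variant explains 2%
  of the second trait's variance — a clearly detectable single-variant
  GWAS signal at n = 10,000.

Not emulated: haplotype structure beyond constant-correlation blocks,
population stratification beyond PC covariates, genotyping error, integer
PANSS items (endpoints are continuous so reductions round-trip exactly),
and ceiling effects — reductions can exceed 100%, preserving the linearity
that the estimator contracts assume. A green suite therefore establishes
correctness of the statistical machinery under its stated model, not
robustness to those real-data features.

## Numerical choices and degenerate inputs

Exact HWE uses the stable ratio recurrence over heterozygote counts (the
two-sided "sum of no-more-probable configurations" definition, with a
1 + 10⁻¹² slack on the comparison); the χ² version is available but tail
probabilities at the 10⁻⁶ filter are exactly why the exact test is the
default. Relatedness screening is skipped with a warning below 100
markers — the PI-hat sampling SD at locus scale would otherwise flag
nearly everyone. Within a flagged pair the higher-missingness member is
dropped, ties by lexicographically later id. Exact-fit regressions report
zero influence rather than 0/0. Median dichotomization sends exact-median
values to the "high" group; the both-low group is the factorial reference.
Stratified models keep the score in whole-sample SD units for
comparability across strata, and covariates fully determined by the
stratum are dropped from both the stratum and pooled fits.

## Known limitations

The pQTL mediation model identifies attenuation only when protein and
trait weights are not proportional (the conditional fit is otherwise
collinear, which the code flags rather than reports). The CLI is a thin
wrapper over `run_pipeline()`. One bookkeeping discrepancy in the source
material is documented rather than resolved: the validation cohort's
printed exclusion arithmetic (568 − 265 − 11 − 3) yields 289, not the 292
participants reported; the ledger invariant in this package always follows
the arithmetic.
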