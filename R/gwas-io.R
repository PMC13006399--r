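#' Read GWAS / pQTL summary statistics from a tab-delimited file
#'
#' Expects columns `variant_id, chrom, pos, ea, oa, eaf, beta, se, p, n`.
#' Rows violating the record invariants (se > 0, 0 < p <= 1, eaf in (0,1),
#' ea != oa, parseable numerics) are dropped with a warning that lists the
#' offending line numbers.
#'
#' @param path file path.
#' @return data.frame of validated records, one row per variant.
#' @export
read_summary_stats <- function(path) {
  required <- c("variant_id", "chrom", "pos", "ea", "oa", "eaf",
                "beta", "se", "p", "n")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_dtmr("summary-stats file %s lacks column(s): %s", path,
              paste(missing, collapse = ", "))
  for (col in c("pos", "eaf", "beta", "se", "p", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
    !is.finite(df$p) | df$p <= 0 | df$p > 1 |
    !is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1 |
    is.na(df$ea) | is.na(df$oa) | df$ea == df$oa
  if (any(bad)) {
    warning(sprintf("dropped %d invalid summary-stat row(s) (file lines: %s)",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a target-gene definition table
#'
#' Columns: `gene, chrom, start, end, drug, action, modality`, with `action`
#' one of `inhibitor`/`activator` — the action drives the sign rule for
#' pQTL-based scores.
#'
#' @param path file path.
#' @return data.frame of target regions.
#' @export
read_target_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  required <- c("gene", "chrom", "start", "end", "drug", "action")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_dtmr("target-gene file lacks column(s): %s",
              paste(missing, collapse = ", "))
  assert_that(all(df$start <= df$end), "target regions must have start <= end")
  assert_that(all(df$action %in% c("inhibitor", "activator")),
              "action must be inhibitor or activator")
  df
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize one summary-stat record against a reference record
#'
#' Aligns record `b` to the allele orientation of reference record `a` for
#' the same variant: if `b`'s effect allele equals `a`'s other allele the
#' record is flipped (beta negated, eaf mirrored, alleles swapped). When the
#' allele pairs only match after strand complementation, `b` is first
#' complemented. Palindromic variants (A/T, C/G) are resolved by allele
#' frequency provided both records are clearly away from 0.5
#' (`|eaf - 0.5| > margin`); otherwise they are rejected.
#'
#' @param a,b one-row data.frames (or lists) with fields `ea, oa, eaf, beta`.
#' @param margin palindromic ambiguity margin on eaf (default 0.08).
#' @return list with `status` ("ok", "flipped", "rejected"), the (possibly
#'   modified) record `b`, and a `reason` code when rejected.
#' @export
harmonize_pair <- function(a, b, margin = 0.08) {
  rej <- function(reason) list(status = "rejected", b = NULL, reason = reason)
  al <- c(a$ea, a$oa)
  if (is_palindromic(a$ea, a$oa)) {
    if (!setequal(c(b$ea, b$oa), al)) return(rej("incompatible_alleles"))
    if (abs(a$eaf - 0.5) <= margin || abs(b$eaf - 0.5) <= margin)
      return(rej("palindromic_ambiguous"))
    # allele labels carry no strand information for palindromes; the
    # frequencies alone identify the shared allele: flip iff the two effect
    # alleles sit on opposite sides of 0.5
    flip <- (a$eaf - 0.5) * (b$eaf - 0.5) < 0
    if (flip) b <- flip_record(b)
    return(list(status = if (flip) "flipped" else "ok", b = b))
  }
  if (setequal(c(b$ea, b$oa), al)) {
    if (b$ea == a$ea) return(list(status = "ok", b = b))
    return(list(status = "flipped", b = flip_record(b)))
  }
  # try strand complement before rejecting
  bc <- b
  bc$ea <- unname(COMPLEMENT[b$ea])
  bc$oa <- unname(COMPLEMENT[b$oa])
  if (!any(is.na(c(bc$ea, bc$oa))) && setequal(c(bc$ea, bc$oa), al)) {
    if (bc$ea == a$ea) return(list(status = "ok", b = bc))
    return(list(status = "flipped", b = flip_record(bc)))
  }
  rej("incompatible_alleles")
}

flip_record <- function(b) {
  tmp <- b$ea
  b$ea <- b$oa
  b$oa <- tmp
  b$beta <- -b$beta
  b$eaf <- 1 - b$eaf
  b
}

#' Restrict summary statistics to a window around a target gene
#'
#' Keeps records on the region's chromosome with position in
#' `[start - window, end + window]`, both ends inclusive (1-based
#' coordinates).
#'
#' @param stats summary-stats data.frame.
#' @param region one row of a target-gene table.
#' @param window flank size in bp (default 100000, the drug-target window).
#' @return the subset data.frame.
#' @export
filter_target_region <- function(stats, region, window = 100000) {
  assert_that(window >= 0, "window must be non-negative")
  keep <- stats$chrom == as.character(region$chrom) &
    stats$pos >= region$start - window &
    stats$pos <= region$end + window
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
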