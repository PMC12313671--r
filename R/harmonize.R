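# Allele harmonization: aligning exposure and outcome summary statistics so
# that both effect sizes refer to the same effect allele, the precondition of
# every two-sample MR estimator.

PALINDROMIC_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Construct an instrument table
#'
#' The harmonized unit consumed by every estimator: one row per SNP with
#' exposure and outcome effects on a shared effect allele.  Normally produced
#' by [harmonize()] or the simulator; this constructor is exported for
#' pre-harmonized data (provenance is recorded as `"manual"`).
#'
#' @param variant_id,beta_exp,se_exp,beta_out,se_out Per-SNP identifiers and
#'   effect/standard-error pairs; all SEs must be strictly positive.
#' @param eaf_exp,eaf_out Effect-allele frequencies in each GWAS.
#' @param n_exp,n_out GWAS sample sizes.
#' @param chrom,pos Optional genomic annotation (used by LD clumping).
#' @param exposure_name,outcome_name Trait labels.
#' @param provenance How the table was built (`"harmonization"`,
#'   `"simulation"` or `"manual"`).
#' @return A data frame of class `instrument_table`.
#' @export
instrument_table <- function(variant_id, beta_exp, se_exp, beta_out, se_out,
                             eaf_exp = NA_real_, eaf_out = NA_real_,
                             n_exp = NA_integer_, n_out = NA_integer_,
                             chrom = NA_character_, pos = NA_integer_,
                             exposure_name = "exposure", outcome_name = "outcome",
                             provenance = "manual") {
  df <- data.frame(variant_id = as.character(variant_id),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
                   eaf_exp = as.numeric(eaf_exp), n_exp = as.numeric(n_exp),
                   beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
                   eaf_out = as.numeric(eaf_out), n_out = as.numeric(n_out),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$variant_id)) {
    mr_error("mr_domain_error", "instrument_table variant_ids must be unique")
  }
  if (any(!is.finite(df$se_exp)) || any(df$se_exp <= 0) ||
      any(!is.finite(df$se_out)) || any(df$se_out <= 0)) {
    mr_error("mr_domain_error", "all instrument SEs must be strictly positive")
  }
  structure(df, class = c("instrument_table", "data.frame"),
            exposure_name = exposure_name, outcome_name = outcome_name,
            provenance = provenance)
}

# Subsetting keeps the class and labels.
#' @export
`[.instrument_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("beta_exp", "beta_out") %in% names(out))) {
    attr(out, "exposure_name") <- attr(x, "exposure_name")
    attr(out, "outcome_name") <- attr(x, "outcome_name")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("instrument_table", "data.frame")
  }
  out
}

#' @export
print.instrument_table <- function(x, ...) {
  cat(sprintf("Instrument table: %s -> %s (%d SNPs, provenance: %s)\n",
              attr(x, "exposure_name") %||% "exposure",
              attr(x, "outcome_name") %||% "outcome",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Harmonization report\n")
  cat(sprintf("  input exposure SNPs : %d\n", x$n_input))
  cat(sprintf("  matched             : %d (of which %d allele-flipped)\n",
              x$n_matched, x$n_flipped))
  cat(sprintf("  palindromic dropped : %d\n", x$n_palindromic_dropped))
  cat(sprintf("  allele mismatches   : %d\n", x$n_allele_mismatch_dropped))
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins two summary-statistics tables on `variant_id` and aligns the outcome
#' effects to the exposure's effect allele.  When the outcome's alleles are
#' swapped relative to the exposure, the outcome beta sign is flipped and its
#' effect-allele frequency replaced by `1 - eaf`.  Palindromic SNPs (A/T or
#' C/G) are strand-ambiguous: they are retained only when both frequencies lie
#' outside `0.5 +/- palindrome_eaf_tol` and, after allele alignment, fall on
#' the same side of 0.5; otherwise they are dropped and counted.  Allele pairs
#' matching neither directly nor after swapping are dropped as mismatches.
#'
#' @param exposure,outcome Data frames in the canonical schema of
#'   [read_sumstats()].
#' @param palindrome_eaf_tol Half-width of the ambiguity band around 0.5
#'   within which a palindromic SNP's strand cannot be inferred from its
#'   frequency (default 0.08).
#' @param exposure_name,outcome_name Trait labels; default to the tables'
#'   `trait` attributes.
#' @return A list with `instruments` (an [instrument_table()]) and `report`
#'   (counts of matched/flipped/dropped SNPs).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_tol = 0.08,
                      exposure_name = NULL, outcome_name = NULL) {
  if (!is.numeric(palindrome_eaf_tol) || palindrome_eaf_tol < 0 || palindrome_eaf_tol >= 0.5) {
    mr_error("mr_domain_error", "`palindrome_eaf_tol` must be in [0, 0.5)")
  }
  exposure_name <- exposure_name %||% attr(exposure, "trait") %||% "exposure"
  outcome_name <- outcome_name %||% attr(outcome, "trait") %||% "outcome"
  n_input <- nrow(exposure)

  exposure$.ord <- seq_len(nrow(exposure))
  m <- merge(exposure, outcome, by = "variant_id", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0L) {
    mr_error("mr_no_overlap",
             sprintf("no overlapping instruments between %s and %s",
                     exposure_name, outcome_name))
  }
  m <- m[order(m$.ord), , drop = FALSE]

  direct <- m$effect_allele_exp == m$effect_allele_out &
    m$other_allele_exp == m$other_allele_out
  swapped <- !direct & m$effect_allele_exp == m$other_allele_out &
    m$other_allele_exp == m$effect_allele_out
  mismatch <- !direct & !swapped

  # Align swapped outcome records to the exposure's effect allele.
  m$beta_out[swapped] <- -m$beta_out[swapped]
  m$eaf_out[swapped] <- 1 - m$eaf_out[swapped]

  pal <- paste(m$effect_allele_exp, m$other_allele_exp, sep = "/") %in% PALINDROMIC_PAIRS
  lo <- 0.5 - palindrome_eaf_tol
  hi <- 0.5 + palindrome_eaf_tol
  ambiguous <- m$eaf_exp >= lo & m$eaf_exp <= hi | m$eaf_out >= lo & m$eaf_out <= hi
  disagree <- (m$eaf_exp - 0.5) * (m$eaf_out - 0.5) <= 0
  pal_drop <- !mismatch & pal & (ambiguous | disagree)

  keep <- !mismatch & !pal_drop
  report <- structure(list(n_input = n_input,
                           n_matched = sum(keep),
                           n_flipped = sum(swapped & keep),
                           n_palindromic_dropped = sum(pal_drop),
                           n_allele_mismatch_dropped = sum(mismatch)),
                      class = "harmonization_report")

  kept <- m[keep, , drop = FALSE]
  instruments <- instrument_table(variant_id = kept$variant_id,
                                  chrom = kept$chrom_exp, pos = kept$pos_exp,
                                  beta_exp = kept$beta_exp, se_exp = kept$se_exp,
                                  eaf_exp = kept$eaf_exp, n_exp = kept$n_exp,
                                  beta_out = kept$beta_out, se_out = kept$se_out,
                                  eaf_out = kept$eaf_out, n_out = kept$n_out,
                                  exposure_name = exposure_name,
                                  outcome_name = outcome_name,
                                  provenance = "harmonization")
  list(instruments = instruments, report = report)
}
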