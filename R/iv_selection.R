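# Instrument selection: genome-wide p-value threshold with a relaxed
# fallback, greedy LD clumping, MAF and instrument-strength (F) filters, and
# Steiger directionality filtering.

#' Instrument-selection configuration
#'
#' Bundles the thresholds used across the selection pipeline: genome-wide
#' significance `p_primary` (5e-8) with relaxed fallback `p_fallback` (1e-5)
#' when fewer than `min_snps_for_primary` SNPs reach the primary threshold;
#' clumping at `clump_r2` within `clump_window_kb`; minor-allele-frequency
#' floor `maf_min`; per-SNP F-statistic floor `f_min`; and the reporting
#' alpha for the Steiger directionality z-test.
#'
#' @param p_primary,p_fallback Primary and fallback p-value thresholds.
#' @param min_snps_for_primary Minimum count of primary-threshold SNPs below
#'   which the fallback threshold is used.
#' @param clump_r2 LD r-squared above which a SNP is clumped away.
#' @param clump_window_kb Window (kb) within which clumping applies.
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param f_min Minimum per-SNP F statistic (exclusive).
#' @param steiger_alpha Significance level recorded by [steiger_filter()].
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_primary = 5e-8, p_fallback = 1e-5,
                             min_snps_for_primary = 3L, clump_r2 = 0.001,
                             clump_window_kb = 10000, maf_min = 0.01,
                             f_min = 10, steiger_alpha = 0.05) {
  ok <- p_primary > 0 && p_primary <= p_fallback && p_fallback < 1 &&
    clump_r2 > 0 && clump_r2 < 1 && clump_window_kb > 0 &&
    maf_min > 0 && maf_min < 0.5 && f_min > 0 &&
    steiger_alpha > 0 && steiger_alpha < 1 && min_snps_for_primary >= 1
  if (!isTRUE(ok)) mr_error("mr_domain_error", "invalid selection_config")
  structure(list(p_primary = p_primary, p_fallback = p_fallback,
                 min_snps_for_primary = as.integer(min_snps_for_primary),
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 maf_min = maf_min, f_min = f_min,
                 steiger_alpha = steiger_alpha),
            class = "selection_config")
}

#' Select instruments by p-value with a relaxed fallback
#'
#' Returns all records below the genome-wide threshold; when fewer than
#' `min_snps_for_primary` qualify, the relaxed fallback threshold is used
#' instead and reported.
#'
#' @param records Summary-statistics data frame.
#' @param config A [selection_config()].
#' @return List with `records` (the subset) and `threshold_used`.
#' @export
select_by_pvalue <- function(records, config = selection_config()) {
  primary <- records[records$pval < config$p_primary, , drop = FALSE]
  if (nrow(primary) >= config$min_snps_for_primary) {
    return(list(records = primary, threshold_used = config$p_primary))
  }
  list(records = records[records$pval < config$p_fallback, , drop = FALSE],
       threshold_used = config$p_fallback)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the most significant remaining SNP as an index SNP and
#' removes every remaining SNP on the same chromosome within
#' `clump_window_kb` of it whose r-squared with the index exceeds `clump_r2`.
#' Ties in p-value are broken by lexicographic `variant_id`.  The retained
#' index SNPs are returned in their input row order.
#'
#' @param records Summary-statistics data frame (needs `chrom`, `pos`, `pval`).
#' @param ld An [ld_matrix()] covering every record.
#' @param config A [selection_config()].
#' @return The clumped subset of `records`.
#' @export
ld_clump <- function(records, ld, config = selection_config()) {
  if (nrow(records) == 0L) return(records)
  missing <- setdiff(records$variant_id, ld$ids)
  if (length(missing)) {
    mr_error("mr_missing_ld",
             sprintf("variant(s) absent from LD matrix: %s",
                     paste(missing, collapse = ", ")))
  }
  ord <- order(records$pval, records$variant_id)
  window_bp <- config$clump_window_kb * 1000
  alive <- rep(TRUE, nrow(records))
  index <- logical(nrow(records))
  for (i in ord) {
    if (!alive[i]) next
    index[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & records$chrom == records$chrom[i] &
                    abs(records$pos - records$pos[i]) <= window_bp)
    if (length(cand)) {
      r2 <- ld$r2[records$variant_id[i], records$variant_id[cand]]
      alive[cand[r2 > config$clump_r2]] <- FALSE
    }
  }
  records[index, , drop = FALSE]
}

#' Minor-allele-frequency filter
#'
#' Retains records with `min(eaf, 1 - eaf) > maf_min`.
#'
#' @inheritParams ld_clump
#' @export
filter_maf <- function(records, config = selection_config()) {
  records[pmin(records$eaf, 1 - records$eaf) > config$maf_min, , drop = FALSE]
}

#' Per-SNP instrument-strength F statistic
#'
#' The squared Wald z, `(beta / se)^2`, the standard large-sample
#' approximation to the first-stage F for one SNP.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`); vectorized.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    mr_error("mr_domain_error", "se must be strictly positive")
  }
  (beta / se)^2
}

#' Instrument-strength filter
#'
#' Removes records whose F statistic does not exceed `f_min` (weak
#' instruments).
#'
#' @inheritParams ld_clump
#' @export
filter_f <- function(records, config = selection_config()) {
  records[f_statistic(records$beta, records$se) > config$f_min, , drop = FALSE]
}

#' Variance in a trait explained by one SNP
#'
#' On the standardized-genotype scale,
#' `r2 = b^2 v / (b^2 v + se^2 v n)` with `v = 2 eaf (1 - eaf)`, clamped to
#' `[0, 1)`.  For binary traits this applies the same formula to log-odds
#' effects with the reported case-control sample size (a conservative
#' approximation).
#'
#' @param beta,se Per-allele effect and standard error.
#' @param eaf Effect-allele frequency in (0, 1).
#' @param n GWAS sample size (> 3).
#' @return Numeric vector of r-squared values.
#' @export
variance_explained <- function(beta, eaf, se, n) {
  if (any(!(eaf > 0 & eaf < 1))) mr_error("mr_domain_error", "eaf must be in (0,1)")
  if (any(n <= 3)) mr_error("mr_domain_error", "n must exceed 3")
  if (any(se <= 0)) mr_error("mr_domain_error", "se must be positive")
  v <- 2 * eaf * (1 - eaf)
  num <- beta^2 * v
  r2 <- num / (num + se^2 * v * n)
  pmin(pmax(r2, 0), 1 - 1e-15)
}

#' Steiger directionality filter
#'
#' For each instrument, compares the variance it explains in the exposure and
#' in the outcome ([variance_explained()]).  SNPs explaining at least as much
#' outcome as exposure variance are removed: such instruments are more likely
#' to act on the outcome first (reverse causation).  A z statistic from the
#' difference of Fisher-transformed correlations is reported for
#' transparency; removal is keyed on the direction alone.
#'
#' @param table An [instrument_table()] with frequencies and sample sizes on
#'   both sides.
#' @param config A [selection_config()] (supplies the reporting alpha).
#' @return List with `table` (the retained subset) and `steiger` (per-SNP
#'   data frame: r2_exp, r2_out, z, p, direction_ok).
#' @export
steiger_filter <- function(table, config = selection_config()) {
  assert_instrument_table(table, 1L, "steiger_filter")
  if (any(table$n_exp <= 3) || any(table$n_out <= 3)) {
    mr_error("mr_domain_error", "Steiger filtering needs n > 3 on both sides")
  }
  r2_exp <- variance_explained(table$beta_exp, table$eaf_exp, table$se_exp, table$n_exp)
  r2_out <- variance_explained(table$beta_out, table$eaf_out, table$se_out, table$n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (table$n_exp - 3) + 1 / (table$n_out - 3))
  p <- two_sided_p(z)
  direction_ok <- r2_exp > r2_out
  steiger <- data.frame(variant_id = table$variant_id,
                        r2_exp = r2_exp, r2_out = r2_out, z = z, p = p,
                        significant = p < config$steiger_alpha,
                        direction_ok = direction_ok,
                        stringsAsFactors = FALSE)
  list(table = table[direction_ok, , drop = FALSE], steiger = steiger,
       n_removed = sum(!direction_ok))
}
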