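# Two-step MR mediation: the exposure->mediator effect beta(A) and the
# mediator->outcome effect beta(B) combine into the mediated (indirect)
# effect beta(A) x beta(B); the direct effect is total - indirect and the
# proportion mediated is indirect / total x 100%.  Inference uses the
# first-order delta method.

#' Delta-method (Sobel) standard error of a product of coefficients
#'
#' First-order: `sqrt(beta_b^2 se_a^2 + beta_a^2 se_b^2)`, assuming the two
#' coefficients are estimated independently (they come from separate MR
#' fits).  `exact = TRUE` adds the second-order `se_a^2 se_b^2` term.
#'
#' @param beta_a,se_a Exposure-to-mediator coefficient and SE.
#' @param beta_b,se_b Mediator-to-outcome coefficient and SE.
#' @param exact Include the second-order term (default `FALSE`).
#' @return The standard error of `beta_a * beta_b`.
#' @export
sobel_se <- function(beta_a, se_a, beta_b, se_b, exact = FALSE) {
  if (any(se_a <= 0) || any(se_b <= 0)) {
    mr_error("mr_domain_error", "sobel_se: standard errors must be positive")
  }
  v <- beta_b^2 * se_a^2 + beta_a^2 * se_b^2
  if (exact) v <- v + se_a^2 * se_b^2
  if (!exact && all(beta_a == 0) && all(beta_b == 0)) {
    warning("sobel_se: both coefficients are zero; first-order SE degenerates to 0",
            call. = FALSE)
  }
  sqrt(v)
}

coef_of <- function(est, what) {
  if (inherits(est, "mr_result")) return(est[[what]])
  if (is.list(est) && all(c("beta", "se") %in% names(est))) return(est[[what]])
  mr_error("mr_domain_error",
           "estimates must be mr_result objects or lists with beta and se")
}

#' Combine two-step MR estimates into a mediation decomposition
#'
#' Given the exposure-to-mediator estimate (beta A), the mediator-to-outcome
#' estimate (beta B) and the total exposure-to-outcome estimate, computes the
#' indirect (mediated) effect `A x B`, the direct effect `total - indirect`,
#' the proportion mediated `100 x indirect / total`, and delta-method 95%
#' confidence intervals.  The proportion's SE treats indirect and total as
#' independent (their covariance is unobtainable from summary data) and is
#' undefined when the indirect effect is zero; proportions outside
#' `[0, 100]%` (inconsistent mediation) are reported unchanged with a flag.
#'
#' @param est_a,est_b,est_total `mr_result` objects (or lists with `beta`
#'   and `se`) for the two legs and the total effect.
#' @param exact Use the exact product variance in [sobel_se()].
#' @return A list of class `mediation_result`.
#' @export
mediate <- function(est_a, est_b, est_total, exact = FALSE) {
  beta_a <- coef_of(est_a, "beta"); se_a <- coef_of(est_a, "se")
  beta_b <- coef_of(est_b, "beta"); se_b <- coef_of(est_b, "se")
  total <- coef_of(est_total, "beta"); se_total <- coef_of(est_total, "se")
  crit <- crit95()

  indirect <- beta_a * beta_b
  se_indirect <- sobel_se(beta_a, se_a, beta_b, se_b, exact = exact)
  ci_indirect <- indirect + c(-1, 1) * crit * se_indirect
  pval_indirect <- if (se_indirect > 0) two_sided_p(indirect / se_indirect) else NA_real_
  direct <- total - indirect

  proportion <- se_proportion <- NA_real_
  ci_proportion <- c(NA_real_, NA_real_)
  inconsistent <- FALSE
  if (total != 0) {
    proportion <- 100 * indirect / total
    inconsistent <- proportion < 0 || proportion > 100
    if (indirect != 0) {
      se_proportion <- abs(proportion) *
        sqrt(se_indirect^2 / indirect^2 + se_total^2 / total^2)
      ci_proportion <- proportion + c(-1, 1) * crit * se_proportion
    }
  }
  structure(list(beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
                 total = total, se_total = se_total,
                 indirect = indirect, se_indirect = se_indirect,
                 ci_indirect = ci_indirect, pval_indirect = pval_indirect,
                 direct = direct,
                 proportion = proportion, se_proportion = se_proportion,
                 ci_proportion = ci_proportion, inconsistent = inconsistent),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta(A) = %.6g (se %.6g); beta(B) = %.6g (se %.6g)\n",
              x$beta_a, x$se_a, x$beta_b, x$se_b))
  cat(sprintf("  indirect = %.6g (se %.6g), 95%% CI [%.6g, %.6g], p = %.3g\n",
              x$indirect, x$se_indirect, x$ci_indirect[1], x$ci_indirect[2],
              x$pval_indirect))
  cat(sprintf("  total = %.6g, direct = %.6g\n", x$total, x$direct))
  if (is.na(x$proportion)) {
    cat("  proportion mediated: undefined (total effect is zero)\n")
  } else {
    cat(sprintf("  proportion mediated = %.4g%%", x$proportion))
    if (!is.na(x$se_proportion)) {
      cat(sprintf(", 95%% CI [%.4g%%, %.4g%%]",
                  x$ci_proportion[1], x$ci_proportion[2]))
    }
    cat(if (x$inconsistent) "  [outside 0-100%: inconsistent mediation]\n" else "\n")
  }
  invisible(x)
}

#' Batch mediation over candidate exposure-mediator-outcome triples
#'
#' Applies [mediate()] to every candidate, returning one row per triple
#' sorted by the indirect-effect p-value, with a significance column at
#' `alpha` on the indirect effect.
#'
#' @param candidates List of lists, each with labels `exposure`, `mediator`,
#'   `outcome` and estimates `est_a`, `est_b`, `est_total`.
#' @param alpha Significance level on `pval_indirect` (default 0.05).
#' @param exact Passed to [mediate()].
#' @return Data frame of mediation decompositions.
#' @export
mediation_screen <- function(candidates, alpha = 0.05, exact = FALSE) {
  cols <- c("exposure", "mediator", "outcome", "beta_a", "se_a", "beta_b",
            "se_b", "indirect", "se_indirect", "ci_low", "ci_high",
            "pval_indirect", "total", "direct", "proportion_pct",
            "prop_ci_low", "prop_ci_high", "significant")
  if (length(candidates) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$exposure <- out$mediator <- out$outcome <- character(0)
    out$significant <- logical(0)
    return(out[cols])
  }
  labels <- vapply(candidates, function(cd) {
    paste(cd$exposure, cd$mediator, cd$outcome, sep = " | ")
  }, character(1))
  if (anyDuplicated(labels)) {
    mr_error("mr_domain_error", "candidate (exposure, mediator, outcome) triples must be unique")
  }
  rows <- lapply(candidates, function(cd) {
    m <- mediate(cd$est_a, cd$est_b, cd$est_total, exact = exact)
    data.frame(exposure = cd$exposure, mediator = cd$mediator,
               outcome = cd$outcome,
               beta_a = m$beta_a, se_a = m$se_a,
               beta_b = m$beta_b, se_b = m$se_b,
               indirect = m$indirect, se_indirect = m$se_indirect,
               ci_low = m$ci_indirect[1], ci_high = m$ci_indirect[2],
               pval_indirect = m$pval_indirect,
               total = m$total, direct = m$direct,
               proportion_pct = m$proportion,
               prop_ci_low = m$ci_proportion[1],
               prop_ci_high = m$ci_proportion[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$pval_indirect) & out$pval_indirect < alpha
  out <- out[order(out$pval_indirect), , drop = FALSE]
  rownames(out) <- NULL
  out[cols]
}

primary_mr <- function(table, ivw_model = "random") {
  if (nrow(table) == 1L) mr_wald_ratio(table) else mr_ivw(table, model = ivw_model)
}

select_instruments <- function(records, config, ld = NULL) {
  sel <- select_by_pvalue(records, config)
  recs <- filter_f(filter_maf(sel$records, config), config)
  if (!is.null(ld) && nrow(recs) > 1L) recs <- ld_clump(recs, ld, config)
  list(records = recs, threshold_used = sel$threshold_used)
}

mr_leg <- function(iv_records, target_records, config, exposure_name, outcome_name,
                   leg_method = "max_likelihood", ivw_model = "random") {
  h <- harmonize(iv_records, target_records,
                 exposure_name = exposure_name, outcome_name = outcome_name)
  st <- steiger_filter(h$instruments, config)
  if (nrow(st$table) == 0L) {
    mr_error("mr_no_instruments",
             sprintf("no instruments survive Steiger filtering for %s -> %s",
                     exposure_name, outcome_name))
  }
  estimate <- if (nrow(st$table) == 1L) {
    mr_wald_ratio(st$table)
  } else if (leg_method == "max_likelihood") {
    mr_max_likelihood(st$table)
  } else {
    mr_ivw(st$table, model = ivw_model)
  }
  list(estimate = estimate, table = st$table,
       steiger_removed = st$n_removed, report = h$report)
}

#' Two-step MR mediation from raw summary statistics
#'
#' Runs the full mediation pipeline on three summary-statistics tables:
#' leg A instruments the exposure (p-value selection, MAF and F filters,
#' optional clumping) against the mediator; the total effect reuses the same
#' instruments against the outcome; leg B instruments the mediator against
#' the outcome.  Mediator instruments that are genome-wide significant for
#' the exposure (`pval < exclude_exposure_p` in the exposure GWAS) are
#' excluded from leg B: such SNPs reach the outcome through the exposure's
#' direct path as well, violating leg B's exclusion restriction.  Every leg
#' is Steiger-filtered.
#'
#' Each leg's effect defaults to the maximum-likelihood estimate rather than
#' IVW: a ratio-based leg is attenuated toward the null by roughly `1/F`
#' (exposure-side sampling error in the denominator), and the product of two
#' legs compounds the attenuation, whereas the profile-likelihood estimator
#' models that error and is mean-unbiased in calibration runs.  Set
#' `leg_method = "ivw"` to reproduce an IVW-based decomposition; a single
#' surviving instrument always uses the Wald ratio.
#'
#' @param exposure,mediator,outcome Summary-statistics data frames
#'   ([read_sumstats()] schema).
#' @param ld Optional [ld_matrix()] for clumping.
#' @param config A [selection_config()].
#' @param exclude_exposure_p Exposure p-value below which a SNP is barred
#'   from instrumenting the mediator (default 5e-8).
#' @param leg_method `"max_likelihood"` (default) or `"ivw"`.
#' @param ivw_model IVW model when `leg_method = "ivw"`.
#' @param exact Passed to [mediate()].
#' @return A `mediation_result` with an extra `legs` element (per-leg
#'   estimates and instrument counts).
#' @export
two_step_mediation <- function(exposure, mediator, outcome, ld = NULL,
                               config = selection_config(),
                               exclude_exposure_p = 5e-8,
                               leg_method = c("max_likelihood", "ivw"),
                               ivw_model = "random", exact = FALSE) {
  leg_method <- match.arg(leg_method)
  exp_name <- attr(exposure, "trait") %||% "exposure"
  med_name <- attr(mediator, "trait") %||% "mediator"
  out_name <- attr(outcome, "trait") %||% "outcome"

  exp_iv <- select_instruments(exposure, config, ld)
  if (nrow(exp_iv$records) == 0L) {
    mr_error("mr_no_instruments", "no exposure instruments pass selection")
  }
  leg_a <- mr_leg(exp_iv$records, mediator, config, exp_name, med_name,
                  leg_method, ivw_model)
  leg_total <- mr_leg(exp_iv$records, outcome, config, exp_name, out_name,
                      leg_method, ivw_model)

  med_iv <- select_instruments(mediator, config, ld)
  exposure_hits <- exposure$variant_id[exposure$pval < exclude_exposure_p]
  med_records <- med_iv$records[!med_iv$records$variant_id %in% exposure_hits, ,
                                drop = FALSE]
  if (nrow(med_records) == 0L) {
    mr_error("mr_no_instruments",
             "no mediator instruments remain after excluding exposure-associated SNPs")
  }
  leg_b <- mr_leg(med_records, outcome, config, med_name, out_name,
                  leg_method, ivw_model)

  result <- mediate(leg_a$estimate, leg_b$estimate, leg_total$estimate,
                    exact = exact)
  result$legs <- list(a = leg_a, b = leg_b, total = leg_total)
  result
}
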