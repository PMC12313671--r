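# Heterogeneity and pleiotropy diagnostics: Cochran's Q / I^2, the MR-PRESSO
# global, outlier and distortion tests, and leave-one-out analysis.  The
# Egger intercept test lives with mr_egger() in mr_core.R.

#' Cochran's Q heterogeneity test
#'
#' Heterogeneity of the per-SNP Wald ratios around the IVW estimate:
#' `Q = sum w_i (ratio_i - beta_IVW)^2` with `w_i = beta_exp_i^2 / se_out_i^2`,
#' referred to a chi-square with `k - 1` degrees of freedom.  `I^2 = max(0,
#' (Q - df) / Q)` summarises the proportional excess heterogeneity.
#'
#' @param table An [instrument_table()] with at least two SNPs.
#' @return A list of class `heterogeneity_result`: Q, df, pval, i2.
#' @export
cochran_q <- function(table) {
  assert_instrument_table(table, 2L, "cochran_q")
  rc <- ratio_components(table, "cochran_q")
  beta_ivw <- sum(rc$weight * rc$ratio) / sum(rc$weight)
  Q <- sum(rc$weight * (rc$ratio - beta_ivw)^2)
  df <- nrow(table) - 1L
  structure(list(Q = Q, df = df,
                 pval = stats::pchisq(Q, df, lower.tail = FALSE),
                 i2 = if (Q > 0) max(0, (Q - df) / Q) else 0),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g, I2 = %.1f%%\n",
              x$Q, x$df, x$pval, 100 * x$i2))
  invisible(x)
}

# Leave-one-out fixed-effect IVW slopes for every SNP at once, from running
# sums.  `w` are the regression weights 1/se_out^2.
loo_ivw_beta <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' (a) Global test: the observed weighted residual sum of squares, with each
#' SNP's expected outcome effect taken from the leave-one-out IVW fit, is
#' compared against a null distribution built by parametric simulation
#' (`beta_out* ~ N(loo_fit * beta_exp, se_out^2)`,
#' `beta_exp* ~ N(beta_exp, se_exp^2)`).  (b) Outlier test: each SNP's
#' observed squared residual is compared against its simulated distribution;
#' p-values are Bonferroni-adjusted by the SNP count and flagged below
#' `alpha`.  (c) Distortion test: when outliers are flagged, the IVW estimate
#' without them is compared against the raw estimate, referred to the
#' distribution of the same difference under random removal of equally many
#' SNPs.  Empirical p-values use the `(1 + r) / (n + 1)` estimator.
#'
#' @param table An [instrument_table()] with at least four SNPs.
#' @param n_sim Parametric simulations for the null distribution (default
#'   1000; a warning is raised below 100).
#' @param alpha Outlier significance level after Bonferroni adjustment.
#' @param seed Integer seed; identical seeds give identical results.
#' @return A list of class `presso_result`.
#' @export
mr_presso <- function(table, n_sim = 1000L, alpha = 0.05, seed) {
  assert_instrument_table(table, 4L, "mr_presso")
  if (n_sim < 100L) warning("mr_presso: n_sim < 100 gives coarse p-values", call. = FALSE)
  k <- nrow(table)
  bx <- table$beta_exp; by <- table$beta_out
  sx <- table$se_exp; sy <- table$se_out
  w <- 1 / sy^2

  loo <- loo_ivw_beta(bx, by, w)
  res_obs <- w * (by - loo * bx)^2
  rss_obs <- sum(res_obs)

  withr::with_seed(as.integer(seed), {
    bx_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                                  sd = rep(sx, each = n_sim)), n_sim, k)
    by_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(loo * bx, each = n_sim),
                                  sd = rep(sy, each = n_sim)), n_sim, k)
    wm <- matrix(w, n_sim, k, byrow = TRUE)
    sxy <- rowSums(wm * bx_sim * by_sim)
    sxx <- rowSums(wm * bx_sim^2)
    loo_sim <- (sxy - wm * bx_sim * by_sim) / (sxx - wm * bx_sim^2)
    res_sim <- wm * (by_sim - loo_sim * bx_sim)^2
    rss_sim <- rowSums(res_sim)

    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    outlier_raw <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (n_sim + 1)
    outlier_p <- pmin(1, outlier_raw * k)
    outlier_idx <- which(outlier_p < alpha)

    beta_raw <- sum(w * bx * by) / sum(w * bx^2)
    beta_corrected <- NA_real_
    distortion_p <- NA_real_
    if (length(outlier_idx)) {
      kept <- setdiff(seq_len(k), outlier_idx)
      beta_corrected <- sum(w[kept] * bx[kept] * by[kept]) /
        sum(w[kept] * bx[kept]^2)
      obs_diff <- beta_raw - beta_corrected
      sim_diff <- vapply(seq_len(n_sim), function(s) {
        drop <- sample.int(k, length(outlier_idx))
        kd <- setdiff(seq_len(k), drop)
        beta_raw - sum(w[kd] * bx[kd] * by[kd]) / sum(w[kd] * bx[kd]^2)
      }, numeric(1))
      distortion_p <- (1 + sum(abs(sim_diff) >= abs(obs_diff))) / (n_sim + 1)
    }
  })

  structure(list(rss_obs = rss_obs, global_p = global_p,
                 outlier_indices = outlier_idx,
                 outlier_p = outlier_p, outlier_p_raw = outlier_raw,
                 distortion_p = distortion_p,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 n_sim = as.integer(n_sim), alpha = alpha,
                 seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outlier_indices)) {
    cat(sprintf("  outliers (Bonferroni p < %.3g): %s\n", x$alpha,
                paste(x$outlier_indices, collapse = ", ")))
    cat(sprintf("  beta raw = %.4g, corrected = %.4g, distortion p = %.4g\n",
                x$beta_raw, x$beta_corrected, x$distortion_p))
  } else {
    cat("  no outliers flagged; distortion test not applicable\n")
  }
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator with each SNP removed in turn and flags rows
#' whose confidence interval excludes the full-table estimate (instruments
#' that single-handedly drive the pooled effect).
#'
#' @param table An [instrument_table()] with at least three SNPs.
#' @param model IVW model passed through to [mr_ivw()].
#' @return Data frame with one row per left-out SNP: left_out_variant, beta,
#'   se, ci_low, ci_high, pval, flagged.
#' @export
leave_one_out <- function(table, model = "random") {
  assert_instrument_table(table, 3L, "leave_one_out")
  full <- mr_ivw(table, model = model)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    fit <- mr_ivw(table[-i, , drop = FALSE], model = model)
    data.frame(left_out_variant = table$variant_id[i], beta = fit$beta,
               se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- full$beta < out$ci_low | full$beta > out$ci_high
  out
}
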