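# The causal-effect estimators.  All operate on a harmonized
# instrument_table; for k >= 2 instruments the inverse-variance weighted
# (IVW) estimator is the primary method, with maximum likelihood, MR-Egger,
# weighted median and the two mode-based estimators as pleiotropy-robust
# companions.  A single instrument is handled by the Wald ratio.

new_mr_result <- function(method, beta, se, pval, n_snps, df = NULL, extra = list()) {
  crit <- if (is.null(df)) crit95() else stats::qt(0.975, df)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval, n_snps = as.integer(n_snps), extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate [%s] (%d SNPs)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.6g (se %.6g), 95%% CI [%.6g, %.6g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.6g, 95%% CI [%.6g, %.6g]\n",
              exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

ratio_components <- function(table, fun = "ratio-based estimator") {
  if (any(table$beta_exp == 0)) {
    mr_error("mr_degenerate_instrument",
             sprintf("%s: beta_exp = 0 for %s", fun,
                     paste(table$variant_id[table$beta_exp == 0], collapse = ", ")))
  }
  list(ratio = table$beta_out / table$beta_exp,
       weight = table$beta_exp^2 / table$se_out^2)
}

#' Wald ratio estimator for a single instrument
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se_out / |beta_exp|` (exposure-side noise ignored at first order).
#'
#' @param table An [instrument_table()] with exactly one SNP.
#' @return An `mr_result`.
#' @export
mr_wald_ratio <- function(table) {
  assert_instrument_table(table, 1L, "mr_wald_ratio")
  if (nrow(table) != 1L) {
    mr_error("mr_domain_error", "mr_wald_ratio is defined for exactly one SNP")
  }
  if (table$beta_exp == 0) {
    mr_error("mr_degenerate_instrument", "beta_exp = 0: degenerate instrument")
  }
  beta <- table$beta_out / table$beta_exp
  se <- table$se_out / abs(table$beta_exp)
  new_mr_result("wald_ratio", beta, se, two_sided_p(beta / se), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome on exposure effects through the origin with
#' weights `1/se_out^2` (equivalently, an inverse-variance meta-analysis of
#' the per-SNP Wald ratios).  The default multiplicative random-effects model
#' inflates the fixed-effect SE by `max(1, sqrt(Q/(k-1)))` where Q is
#' Cochran's heterogeneity statistic; `model = "fixed"` skips the inflation.
#'
#' @param table An [instrument_table()] with at least two SNPs.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_result`; `extra` carries Q and the model label.
#' @export
mr_ivw <- function(table, model = c("random", "fixed")) {
  model <- match.arg(model)
  assert_instrument_table(table, 2L, "mr_ivw")
  w <- 1 / table$se_out^2
  sxx <- sum(w * table$beta_exp^2)
  beta <- sum(w * table$beta_exp * table$beta_out) / sxx
  se <- sqrt(1 / sxx)
  Q <- NA_real_
  if (all(table$beta_exp != 0)) {
    rc <- ratio_components(table)
    Q <- sum(rc$weight * (rc$ratio - beta)^2)
  }
  if (model == "random" && is.finite(Q)) {
    se <- se * max(1, sqrt(Q / (nrow(table) - 1)))
  }
  new_mr_result("ivw", beta, se, two_sided_p(beta / se), nrow(table),
                extra = list(model = model, Q = Q))
}

# Profile negative log-likelihood core: with the per-SNP true exposure
# effects profiled out, -2 log L(b) = sum (by - b bx)^2 / (sy^2 + b^2 sx^2)
# up to a constant.
ml_profile_rss <- function(b, bx, by, sx2, sy2) {
  sum((by - b * bx)^2 / (sy2 + b^2 * sx2))
}

#' Maximum-likelihood estimator
#'
#' Fits the bivariate measurement model `beta_exp_i ~ N(xi_i, se_exp_i^2)`,
#' `beta_out_i ~ N(b xi_i, se_out_i^2)` jointly over the nuisance effects
#' `xi` and the causal slope `b`, by minimizing the profile objective
#' `sum (by - b bx)^2 / (sy^2 + b^2 sx^2)`.  The search starts at the IVW
#' estimate and expands its bracket until the optimum is interior; the SE
#' comes from the curvature of the profile log-likelihood at the optimum.
#'
#' @param table An [instrument_table()] with at least two SNPs.
#' @param tol Convergence tolerance on `b` (default 1e-10).
#' @param max_expand Maximum bracket expansions before a convergence error.
#' @return An `mr_result`.
#' @export
mr_max_likelihood <- function(table, tol = 1e-10, max_expand = 200L) {
  assert_instrument_table(table, 2L, "mr_max_likelihood")
  bx <- table$beta_exp; by <- table$beta_out
  sx2 <- table$se_exp^2; sy2 <- table$se_out^2
  init <- mr_ivw(table, model = "fixed")
  width <- max(abs(init$beta), 1) + 100 * init$se
  lo <- init$beta - width
  hi <- init$beta + width
  for (i in seq_len(max_expand)) {
    opt <- stats::optimize(ml_profile_rss, c(lo, hi),
                           bx = bx, by = by, sx2 = sx2, sy2 = sy2, tol = tol)
    margin <- 1e-6 * (hi - lo)
    if (opt$minimum > lo + margin && opt$minimum < hi - margin) {
      b <- opt$minimum
      # Observed information = 0.5 * d2/db2 of the profile objective.
      h <- max(1e-6, 1e-6 * abs(b))
      f0 <- ml_profile_rss(b, bx, by, sx2, sy2)
      fp <- ml_profile_rss(b + h, bx, by, sx2, sy2)
      fm <- ml_profile_rss(b - h, bx, by, sx2, sy2)
      info <- 0.5 * (fp - 2 * f0 + fm) / h^2
      if (!is.finite(info) || info <= 0) {
        mr_error("mr_convergence_error",
                 "non-positive profile curvature at the ML optimum")
      }
      se <- sqrt(1 / info)
      return(new_mr_result("max_likelihood", b, se, two_sided_p(b / se),
                           nrow(table)))
    }
    span <- hi - lo
    lo <- lo - span
    hi <- hi + span
  }
  mr_error("mr_convergence_error",
           sprintf("maximum-likelihood search did not converge after %d bracket expansions (last bracket [%.3g, %.3g])",
                   max_expand, lo, hi))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept,
#' after orienting every SNP so its exposure effect is non-negative (required
#' for the intercept to be identifiable).  The intercept absorbs directional
#' pleiotropy; the slope is the causal estimate.  SEs are inflated by
#' `max(1, sqrt(RSS_w / (k - 2)))` (multiplicative random effects) and
#' p-values/CIs use the t distribution with `k - 2` degrees of freedom.
#'
#' @param table An [instrument_table()] with at least three SNPs.
#' @return A list of class `mr_egger_result`: `slope` (an `mr_result`),
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(table) {
  assert_instrument_table(table, 3L, "mr_egger")
  flip <- table$beta_exp < 0
  bx <- ifelse(flip, -table$beta_exp, table$beta_exp)
  by <- ifelse(flip, -table$beta_out, table$beta_out)
  w <- 1 / table$se_out^2
  k <- nrow(table)
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  fitted <- X %*% coefs
  rss_w <- sum(w * (by - fitted)^2)
  scale <- max(1, sqrt(rss_w / (k - 2)))
  ses <- sqrt(diag(solve(XtWX))) * scale
  tval <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tval), df = k - 2)
  slope <- new_mr_result("egger", coefs[2], ses[2], pvals[2], k, df = k - 2,
                         extra = list(intercept = coefs[1],
                                      intercept_se = ses[1],
                                      intercept_p = pvals[1],
                                      rss_w = rss_w))
  structure(list(slope = slope, intercept = unname(coefs[1]),
                 intercept_se = unname(ses[1]), intercept_p = unname(pvals[1])),
            class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.6g (se %.6g), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

# Interpolated weighted median of `x` with weights `w`: cumulative
# standardized weight p_j = (S_j - w_j/2) / S_total, linear interpolation to
# p = 0.5.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(table, n_boot, seed, point_fun) {
  if (n_boot == 0L) return(NA_real_)
  if (is.null(seed)) {
    mr_error("mr_domain_error", "an explicit `seed` is required when n_boot > 0")
  }
  k <- nrow(table)
  withr::with_seed(as.integer(seed), {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, table$beta_exp, table$se_exp)
      by <- stats::rnorm(k, table$beta_out, table$se_out)
      point_fun(bx, by)
    }, numeric(1))
  })
  stats::sd(est)
}

#' Weighted median estimator
#'
#' Interpolated weighted median of the per-SNP Wald ratios with
#' inverse-variance weights `beta_exp^2 / se_out^2`; consistent when valid
#' instruments carry more than half of the total weight.  The SE comes from a
#' parametric bootstrap (resampling the exposure and outcome effects from
#' their sampling distributions) with an explicit seed.
#'
#' @param table An [instrument_table()] with at least three SNPs.
#' @param n_boot Bootstrap replicates for the SE (default 5000; 0 skips the
#'   bootstrap and returns `NA` SE/p).
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(table, n_boot = 5000L, seed = NULL) {
  assert_instrument_table(table, 3L, "mr_weighted_median")
  rc <- ratio_components(table, "mr_weighted_median")
  beta <- weighted_median_point(rc$ratio, rc$weight)
  se <- boot_se(table, n_boot, seed, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / table$se_out^2)
  })
  pval <- if (is.na(se)) NA_real_ else two_sided_p(beta / se)
  new_mr_result("weighted_median", beta, se, pval, nrow(table))
}

mode_point <- function(ratio, w, bandwidth_factor) {
  if (diff(range(ratio)) < 1e-12) return(ratio[1])
  k <- length(ratio)
  spread <- min(stats::sd(ratio), stats::mad(ratio))
  if (spread <= 0) spread <- stats::sd(ratio)
  h <- bandwidth_factor * 0.9 * spread * k^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512L)
  wn <- w / sum(w)
  dens <- colSums(wn * stats::dnorm(outer(ratio, grid, "-") / h))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The mode of a Gaussian kernel density over the per-SNP Wald ratios,
#' evaluated on a 512-point grid spanning the ratio range plus three
#' bandwidths.  Bandwidth: `bandwidth_factor * 0.9 * min(SD, MAD) * k^(-1/5)`
#' (MAD on the consistent normal scale).  The simple mode weights every ratio
#' equally; the weighted mode uses inverse-variance weights.  Consistent when
#' the largest cluster of ratios (by count or weight) comes from valid
#' instruments.  SE by parametric bootstrap with an explicit seed.
#'
#' @param table An [instrument_table()] with at least three SNPs.
#' @param weighted Use inverse-variance weights (`TRUE`, the weighted mode)
#'   or equal weights (`FALSE`, the simple mode).
#' @param bandwidth_factor Multiplier on the default kernel bandwidth.
#' @param n_boot Bootstrap replicates for the SE (default 1000; 0 skips).
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`).
#' @return An `mr_result` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mr_mode <- function(table, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000L, seed = NULL) {
  assert_instrument_table(table, 3L, "mr_mode")
  rc <- ratio_components(table, "mr_mode")
  w <- if (weighted) rc$weight else rep(1, nrow(table))
  beta <- mode_point(rc$ratio, w, bandwidth_factor)
  se <- boot_se(table, n_boot, seed, function(bx, by) {
    wb <- if (weighted) bx^2 / table$se_out^2 else w
    mode_point(by / bx, wb, bandwidth_factor)
  })
  pval <- if (is.na(se)) NA_real_ else two_sided_p(beta / se)
  new_mr_result(if (weighted) "weighted_mode" else "simple_mode",
                beta, se, pval, nrow(table))
}

#' Run every applicable estimator on an instrument table
#'
#' Dispatch: one SNP gives the Wald ratio alone; two SNPs give IVW and
#' maximum likelihood; three or more give all six multi-instrument methods
#' (IVW, maximum likelihood, MR-Egger slope, weighted median, simple mode,
#' weighted mode).  IVW (or the Wald ratio for one SNP) is flagged as the
#' primary method.
#'
#' @param table An [instrument_table()].
#' @param seed Integer seed for the bootstrap SEs of the median/mode methods.
#' @param methods `"all"` or a character subset of the method labels.
#' @param ivw_model Passed to [mr_ivw()].
#' @param n_boot_median,n_boot_mode Bootstrap sizes (0 skips the bootstrap).
#' @param bandwidth_factor Passed to [mr_mode()].
#' @return A data frame with one row per method: method, n_snps, beta, se,
#'   ci_low, ci_high, pval, primary.
#' @export
mr_estimate_all <- function(table, seed, methods = "all",
                            ivw_model = "random",
                            n_boot_median = 5000L, n_boot_mode = 1000L,
                            bandwidth_factor = 1) {
  assert_instrument_table(table, 1L, "mr_estimate_all")
  k <- nrow(table)
  applicable <- if (k == 1L) "wald_ratio" else if (k == 2L) {
    c("ivw", "max_likelihood")
  } else {
    c("ivw", "max_likelihood", "egger", "weighted_median",
      "simple_mode", "weighted_mode")
  }
  wanted <- if (identical(methods, "all")) applicable else {
    unknown <- setdiff(methods, c("wald_ratio", "ivw", "max_likelihood", "egger",
                                  "weighted_median", "simple_mode", "weighted_mode"))
    if (length(unknown)) {
      mr_error("mr_domain_error",
               sprintf("unknown method(s): %s", paste(unknown, collapse = ", ")))
    }
    bad <- setdiff(methods, applicable)
    if (length(bad)) {
      mr_error("mr_domain_error",
               sprintf("method(s) not applicable to a %d-SNP table: %s",
                       k, paste(bad, collapse = ", ")))
    }
    applicable[applicable %in% methods]
  }
  fit_one <- function(m) {
    switch(m,
           wald_ratio = mr_wald_ratio(table),
           ivw = mr_ivw(table, model = ivw_model),
           max_likelihood = mr_max_likelihood(table),
           egger = mr_egger(table)$slope,
           weighted_median = mr_weighted_median(
             table, n_boot = n_boot_median,
             seed = if (n_boot_median > 0) sub_seed(seed, 1L)),
           simple_mode = mr_mode(
             table, weighted = FALSE, bandwidth_factor = bandwidth_factor,
             n_boot = n_boot_mode, seed = if (n_boot_mode > 0) sub_seed(seed, 2L)),
           weighted_mode = mr_mode(
             table, weighted = TRUE, bandwidth_factor = bandwidth_factor,
             n_boot = n_boot_mode, seed = if (n_boot_mode > 0) sub_seed(seed, 3L)))
  }
  out <- do.call(rbind, lapply(lapply(wanted, fit_one), as.data.frame))
  out$primary <- out$method %in% c("ivw", "wald_ratio")
  rownames(out) <- NULL
  out
}
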