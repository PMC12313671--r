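# Simulation-study layer: the repeated-simulation experiments that the
# analysis scripts, the test suite and scripts/acceptance.R all share.  Each
# study is a pure function of its seed and configuration.

#' Estimator calibration study
#'
#' Repeatedly simulates an exposure/outcome GWAS pair, harmonizes it, and
#' records every requested estimator's point estimate plus whether the IVW
#' 95% confidence interval covers the true causal effect.
#'
#' @param n_reps Number of simulation replicates.
#' @param seed Integer seed (replicate seeds are derived from it).
#' @param config A [sim_config()]; its `theta` is the recovery target.
#' @param methods Estimators to record (labels as in [mr_estimate_all()]).
#' @return List with `estimates` (replicates x methods matrix), `mean`,
#'   `mcse` (Monte-Carlo standard errors of the means), `theta`,
#'   `ivw_coverage`, `n_reps`.
#' @export
study_estimator_calibration <- function(n_reps = 500L, seed = 101L,
                                        config = sim_config(),
                                        methods = c("ivw", "max_likelihood",
                                                    "egger", "weighted_median",
                                                    "weighted_mode")) {
  est <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  cover <- logical(n_reps)
  sel_config <- selection_config()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_pair(cfg)
    # estimators see what the pipeline gives them: selected instruments
    iv <- select_instruments(bundle$exposure, sel_config)
    tab <- harmonize(iv$records, bundle$outcome)$instruments
    ivw <- mr_ivw(tab)
    cover[r] <- ivw$ci_low <= config$theta && config$theta <= ivw$ci_high
    for (m in methods) {
      est[r, m] <- switch(m,
                          ivw = ivw$beta,
                          max_likelihood = mr_max_likelihood(tab)$beta,
                          egger = mr_egger(tab)$slope$beta,
                          weighted_median = mr_weighted_median(tab, n_boot = 0L)$beta,
                          simple_mode = mr_mode(tab, weighted = FALSE, n_boot = 0L)$beta,
                          weighted_mode = mr_mode(tab, weighted = TRUE, n_boot = 0L)$beta)
    }
  }
  list(estimates = est, mean = colMeans(est),
       mcse = apply(est, 2, stats::sd) / sqrt(n_reps),
       theta = config$theta, ivw_coverage = mean(cover), n_reps = n_reps)
}

#' Cochran's Q type-I error study
#'
#' Rejection rate of the heterogeneity test at `alpha` over homogeneous
#' (no-pleiotropy) replicates.
#'
#' @inheritParams study_estimator_calibration
#' @param alpha Test level.
#' @return List with `pvals`, `rejection_rate`, `n_reps`.
#' @export
study_q_calibration <- function(n_reps = 2000L, seed = 104L,
                                config = sim_config(), alpha = 0.05) {
  pvals <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_pair(cfg)
    cochran_q(harmonize(bundle$exposure, bundle$outcome)$instruments)$pval
  }, numeric(1))
  list(pvals = pvals, rejection_rate = mean(pvals < alpha), n_reps = n_reps)
}

#' MR-Egger intercept test study
#'
#' Per-replicate Egger intercept estimates and test p-values under the
#' configured pleiotropy scenario.  With balanced pleiotropy
#' (`pleiotropy_mean = 0`) the rejection rate estimates the intercept test's
#' type-I error; with directional pleiotropy the intercept estimates recover
#' the weight-implied per-allele pleiotropy mean.
#'
#' @inheritParams study_q_calibration
#' @return List with `intercepts`, `pvals`, `rejection_rate`,
#'   `intercept_target` (mean weight-implied per-allele target across
#'   replicates), `n_reps`.
#' @export
study_egger_intercept <- function(n_reps = 2000L, seed = 105L,
                                  config = sim_config(pleiotropy_frac = 1,
                                                      pleiotropy_sd = 0.03),
                                  alpha = 0.05) {
  intercepts <- pvals <- targets <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_pair(cfg)
    tab <- harmonize(bundle$exposure, bundle$outcome)$instruments
    fit <- mr_egger(tab)
    intercepts[r] <- fit$intercept
    pvals[r] <- fit$intercept_p
    # weight-implied intercept target: the Egger intercept estimates the
    # weighted mean of the per-allele pleiotropy effects after the
    # exposure-positive orientation flip
    alpha_pa <- bundle$truth$pleiotropy /
      sqrt(2 * bundle$exposure$eaf * (1 - bundle$exposure$eaf))
    w <- 1 / tab$se_out^2
    targets[r] <- sum(w * alpha_pa * sign(tab$beta_exp)) / sum(w)
  }
  list(intercepts = intercepts, pvals = pvals,
       rejection_rate = mean(pvals < alpha),
       intercept_target = mean(targets), n_reps = n_reps)
}

#' MR-PRESSO null calibration study
#'
#' Global-test p-values over clean (no-pleiotropy) replicates; under the
#' null they should be approximately Uniform(0, 1).
#'
#' @inheritParams study_q_calibration
#' @param n_sim Simulations inside each MR-PRESSO call.
#' @return List with `global_p`, `n_reps`.
#' @export
study_presso_null <- function(n_reps = 200L, seed = 1040L,
                              config = sim_config(n_snps = 20L),
                              n_sim = 1000L) {
  global_p <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_pair(cfg)
    tab <- harmonize(bundle$exposure, bundle$outcome)$instruments
    mr_presso(tab, n_sim = n_sim, seed = sub_seed(seed, r + n_reps))$global_p
  }, numeric(1))
  list(global_p = global_p, n_reps = n_reps)
}

#' MR-PRESSO planted-outlier detection study
#'
#' Shifts one SNP's outcome effect by `shift` outcome SEs (cycling the
#' planted index across replicates) and records how often the outlier test
#' flags exactly that SNP.
#'
#' @inheritParams study_presso_null
#' @param shift Outcome-SE multiples added to the planted SNP.
#' @return List with `detected` (logical per replicate), `detection_rate`,
#'   `n_reps`.
#' @export
study_presso_outlier <- function(n_reps = 200L, seed = 1041L,
                                 config = sim_config(n_snps = 20L),
                                 shift = 10, n_sim = 1000L) {
  detected <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_pair(cfg)
    tab <- harmonize(bundle$exposure, bundle$outcome)$instruments
    idx <- ((r - 1L) %% nrow(tab)) + 1L
    tab$beta_out[idx] <- tab$beta_out[idx] + shift * tab$se_out[idx]
    fit <- mr_presso(tab, n_sim = n_sim, seed = sub_seed(seed, r + n_reps))
    idx %in% fit$outlier_indices
  }, logical(1))
  list(detected = detected, detection_rate = mean(detected), n_reps = n_reps)
}

#' Steiger reverse-instrument removal study
#'
#' Simulates pairs containing reverse-causal SNPs (outcome-first) and records
#' the fraction of reverse SNPs removed and forward SNPs retained by
#' [steiger_filter()].
#'
#' @inheritParams study_q_calibration
#' @return List with `reverse_removed`, `forward_retained` (per-replicate
#'   fractions), `reverse_removal_rate`, `forward_retention_rate`, `n_reps`.
#' @export
study_steiger_reverse <- function(n_reps = 500L, seed = 1050L,
                                  config = sim_config(reverse_frac = 0.2,
                                                      outcome_type = "quantitative")) {
  reverse_removed <- forward_retained <- numeric(n_reps)
  sel_config <- selection_config()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_pair(cfg)
    # mirror the pipeline order: Steiger sees only selected instruments
    iv <- select_instruments(bundle$exposure, sel_config)
    tab <- harmonize(iv$records, bundle$outcome)$instruments
    st <- steiger_filter(tab, sel_config)
    rev_ids <- bundle$exposure$variant_id[bundle$truth$reverse_idx]
    is_rev <- st$steiger$variant_id %in% rev_ids
    reverse_removed[r] <- if (any(is_rev)) mean(!st$steiger$direction_ok[is_rev]) else NA
    forward_retained[r] <- if (any(!is_rev)) mean(st$steiger$direction_ok[!is_rev]) else NA
  }
  list(reverse_removed = reverse_removed, forward_retained = forward_retained,
       reverse_removal_rate = mean(reverse_removed, na.rm = TRUE),
       forward_retention_rate = mean(forward_retained, na.rm = TRUE),
       n_reps = n_reps)
}

#' Mediation recovery study
#'
#' Repeatedly simulates an exposure/mediator/outcome chain and runs the full
#' two-step mediation pipeline, recording the indirect-effect estimates,
#' delta-method CI coverage of the true indirect effect, the proportion
#' mediated, and the exact conservation of the effect decomposition.
#'
#' @inheritParams study_estimator_calibration
#' @return List with `results` (per-replicate data frame), `mean_indirect`,
#'   `mcse_indirect`, `ci_coverage`, `mean_proportion`, `true_indirect`,
#'   `true_total`, `n_reps`.
#' @export
study_mediation_recovery <- function(n_reps = 300L, seed = 106L,
                                     config = sim_config()) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- sub_seed(seed, r)
    bundle <- simulate_chain(cfg)
    med <- two_step_mediation(bundle$exposure, bundle$mediator, bundle$outcome)
    rows[[r]] <- data.frame(indirect = med$indirect,
                            se_indirect = med$se_indirect,
                            covered = med$ci_indirect[1] <= bundle$truth$indirect &
                              bundle$truth$indirect <= med$ci_indirect[2],
                            total = med$total, direct = med$direct,
                            proportion = med$proportion,
                            conserved = identical(med$direct, med$total - med$indirect))
  }
  results <- do.call(rbind, rows)
  truth <- simulate_chain(config)$truth
  list(results = results,
       mean_indirect = mean(results$indirect),
       mcse_indirect = stats::sd(results$indirect) / sqrt(n_reps),
       ci_coverage = mean(results$covered),
       mean_proportion = mean(results$proportion),
       true_indirect = truth$indirect, true_total = truth$total,
       n_reps = n_reps)
}

# Build a batch of independent exposure GWAS (own instrument panels) plus
# the matching combined outcome GWAS over all panels.
simulate_screen_batch <- function(n_exposures, config, seed, thetas = NULL) {
  exposures <- list()
  outcome_parts <- vector("list", n_exposures)
  for (i in seq_len(n_exposures)) {
    cfg <- config
    if (!is.null(thetas)) cfg$theta <- thetas[i]
    cfg$seed <- sub_seed(seed, i)
    b <- simulate_pair(cfg)
    prefix <- sprintf("e%03d_", i)
    b$exposure$variant_id <- paste0(prefix, b$exposure$variant_id)
    b$outcome$variant_id <- paste0(prefix, b$outcome$variant_id)
    label <- sprintf("exposure_%03d", i)
    attr(b$exposure, "trait") <- label
    exposures[[label]] <- b$exposure
    outcome_parts[[i]] <- b$outcome
  }
  outcome <- do.call(rbind, outcome_parts)
  attr(outcome, "trait") <- "outcome"
  list(exposures = exposures, outcome = outcome)
}

#' All-null screen FDR study
#'
#' Screens batches of exposures with no causal effect on the outcome and
#' records, per replicate, the fraction of exposures called significant at
#' FDR < 0.05; under Benjamini-Hochberg control the mean fraction stays at
#' or below 0.05.
#'
#' @param n_reps Number of screen replicates.
#' @param n_exposures Exposures per screen.
#' @param seed Integer seed.
#' @param config Per-exposure [sim_config()]; `theta` is forced to 0.
#' @return List with `fdr_positive_fraction` (per replicate), `mean_fraction`,
#'   `n_reps`, `n_exposures`.
#' @export
study_null_screen <- function(n_reps = 200L, n_exposures = 100L, seed = 107L,
                              config = sim_config(theta = 0)) {
  config$theta <- 0
  frac <- vapply(seq_len(n_reps), function(r) {
    batch <- simulate_screen_batch(n_exposures, config, sub_seed(seed, r * 1000L))
    res <- run_screen(batch$exposures, batch$outcome, seed = sub_seed(seed, r),
                      methods = "ivw", n_boot_median = 0L, n_boot_mode = 0L)
    prim <- res[res$primary, , drop = FALSE]
    sum(prim$fdr_significant) / n_exposures
  }, numeric(1))
  list(fdr_positive_fraction = frac, mean_fraction = mean(frac),
       n_reps = n_reps, n_exposures = n_exposures)
}

#' Screen ranking-recovery study
#'
#' Batches mixing a few causal exposures among nulls; records how often the
#' causal exposures occupy exactly the smallest primary-method p-values.
#'
#' @param n_reps Number of screen replicates.
#' @param n_null,n_causal Batch composition.
#' @param theta Causal effect of the non-null exposures.
#' @param seed Integer seed.
#' @param config Per-exposure [sim_config()] template.
#' @return List with `top_ranked` (logical per replicate), `success_rate`.
#' @export
study_screen_ranking <- function(n_reps = 100L, n_null = 17L, n_causal = 3L,
                                 theta = 0.2, seed = 108L,
                                 config = sim_config(n_out = 500000L)) {
  thetas <- c(rep(theta, n_causal), rep(0, n_null))
  top <- vapply(seq_len(n_reps), function(r) {
    batch <- simulate_screen_batch(n_null + n_causal, config,
                                   sub_seed(seed, r * 1000L), thetas = thetas)
    res <- run_screen(batch$exposures, batch$outcome, seed = sub_seed(seed, r),
                      methods = "ivw", n_boot_median = 0L, n_boot_mode = 0L)
    prim <- res[res$primary, , drop = FALSE]
    causal_labels <- names(batch$exposures)[seq_len(n_causal)]
    ranked <- prim$exposure[order(prim$pval)]
    setequal(ranked[seq_len(n_causal)], causal_labels)
  }, logical(1))
  list(top_ranked = top, success_rate = mean(top), n_reps = n_reps)
}
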