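# Summary-statistic simulator with known ground truth.  Works on the
# standardized-genotype scale: per-SNP joint effects are drawn there, marginal
# effects are propagated through block LD, sampling noise is added with the
# LD-implied correlation, and everything is rescaled to per-allele units via
# 1/sqrt(2 maf (1 - maf)).  Binary outcomes are generated directly on the
# log-odds scale with effective-sample-size standard errors.

#' Simulation configuration
#'
#' Defines a synthetic GWAS study: `n_snps` exposure instruments with total
#' standardized heritability `exposure_h2` split evenly across SNPs, MAFs
#' uniform on `maf_range`, block LD (`ld_block_size` SNPs per block with
#' within-block correlation `ld_rho^|i-j|`), and a causal structure given by
#' `theta` (exposure to outcome) or the chain coefficients `a` (exposure to
#' mediator), `b` (mediator to outcome) and `c_prime` (direct).  A
#' `pleiotropy_frac` fraction of instruments receives an extra direct outcome
#' effect drawn as `N(pleiotropy_mean, pleiotropy_sd^2)` on the standardized
#' scale, oriented by the sign of the SNP's exposure effect (so
#' `pleiotropy_mean != 0` is directional pleiotropy as MR-Egger sees it); a
#' `reverse_frac` fraction acts on the outcome first, with the exposure
#' association induced through `theta_rev`.  Binary outcomes use
#' `case_fraction` and the effective sample size `4/(1/cases + 1/controls)`.
#'
#' Defaults describe the package's reference calibration study: 50 strong
#' instruments (mean F about 200, pQTL-like), 50,000 samples per GWAS, a
#' binary outcome with FinnGen-like prevalence, causal effect 0.2, chain
#' 0.3 x 0.5 with direct effect 0.1, no pleiotropy, no LD.
#'
#' @param n_snps Exposure instrument count.
#' @param n_exp,n_med,n_out GWAS sample sizes (> 10).
#' @param maf_range Range for the uniform MAF draw, within (0, 0.5].
#' @param exposure_h2 Total variance in the exposure explained by its
#'   instruments, in (0, 1); also used for the mediator's own instruments.
#' @param theta True causal effect (pair simulation).
#' @param a,b,c_prime Chain coefficients (chain simulation); the true total
#'   effect is `a b + c_prime`.
#' @param pleiotropy_frac,pleiotropy_mean,pleiotropy_sd Invalid-instrument
#'   fraction and the oriented mean/sd of their direct outcome effects.
#' @param reverse_frac Fraction of SNPs acting through the outcome first.
#' @param theta_rev Outcome-to-exposure effect inducing the reverse SNPs'
#'   exposure associations.
#' @param ld_block_size,ld_rho LD block size and within-block correlation
#'   parameter (`ld_rho = 0` or block size 1 gives independent SNPs).
#' @param outcome_type `"binary"` (log-odds effects, effective-n SEs) or
#'   `"quantitative"`.
#' @param case_fraction Case fraction for a binary outcome, in (0, 1).
#' @param n_snps_med Mediator-specific instrument count (defaults to
#'   `n_snps`).
#' @param seed Integer seed; the simulator is a pure function of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50L, n_exp = 50000L, n_med = 50000L,
                       n_out = 50000L, maf_range = c(0.05, 0.5),
                       exposure_h2 = 0.2, theta = 0.2,
                       a = 0.3, b = 0.5, c_prime = 0.1,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0, reverse_frac = 0, theta_rev = 0.3,
                       ld_block_size = 1L, ld_rho = 0,
                       outcome_type = c("binary", "quantitative"),
                       case_fraction = 0.007, n_snps_med = NULL, seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  n_snps_med <- as.integer(n_snps_med %||% n_snps)
  ok <- n_snps >= 1 && n_snps_med >= 1 &&
    n_exp > 10 && n_med > 10 && n_out > 10 &&
    length(maf_range) == 2L && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
    maf_range[1] <= maf_range[2] &&
    exposure_h2 > 0 && exposure_h2 < 1 &&
    pleiotropy_frac >= 0 && pleiotropy_frac <= 1 && pleiotropy_sd >= 0 &&
    reverse_frac >= 0 && reverse_frac <= 1 &&
    ld_block_size >= 1 && ld_rho >= 0 && ld_rho < 1 &&
    case_fraction > 0 && case_fraction < 1 &&
    is.finite(theta) && is.finite(a) && is.finite(b) && is.finite(c_prime) &&
    theta_rev != 0
  if (!isTRUE(ok)) mr_error("mr_domain_error", "invalid sim_config")
  structure(list(n_snps = as.integer(n_snps), n_exp = as.numeric(n_exp),
                 n_med = as.numeric(n_med), n_out = as.numeric(n_out),
                 maf_range = as.numeric(maf_range), exposure_h2 = exposure_h2,
                 theta = theta, a = a, b = b, c_prime = c_prime,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 reverse_frac = reverse_frac, theta_rev = theta_rev,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 n_snps_med = n_snps_med, seed = as.integer(seed)),
            class = "sim_config")
}

# Block-diagonal genotype correlation structure; returns the correlation
# matrix R, its r^2, and per-SNP positions placing each block on its own
# locus (blocks on one chromosome sit 50 Mb apart; within a block SNPs are
# 10 kb apart, well inside the default 10,000 kb clumping window).
make_ld_structure <- function(n, block_size, rho) {
  n_blocks <- ceiling(n / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(n)]
  chrom <- as.character(((block_of - 1L) %% 22L) + 1L)
  within <- stats::ave(seq_len(n), block_of, FUN = seq_along)
  pos <- 1000000L + ((block_of - 1L) %/% 22L) * 50000000L + (within - 1L) * 10000L
  R <- diag(1, n)
  if (rho > 0 && block_size > 1L) {
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      R[idx, idx] <- rho^abs(outer(within[idx], within[idx], "-"))
    }
  }
  list(R = R, chrom = chrom, pos = pos, block_of = block_of)
}

# Correlated noise draw: eps ~ N(0, se^2 R), block by block.
correlated_noise <- function(struct, se, rho, block_size) {
  n <- length(struct$chrom)
  z <- stats::rnorm(n)
  if (rho > 0 && block_size > 1L) {
    for (b in unique(struct$block_of)) {
      idx <- which(struct$block_of == b)
      if (length(idx) > 1L) {
        L <- chol(struct$R[idx, idx])
        z[idx] <- as.numeric(crossprod(L, z[idx]))
      }
    }
  }
  se * z
}

effective_n <- function(n, case_fraction) 4 * n * case_fraction * (1 - case_fraction)

sumstats_from_std <- function(ids, struct, beta_hat_std, se_std, maf, n) {
  fac <- 1 / sqrt(2 * maf * (1 - maf))
  beta <- beta_hat_std * fac
  se <- se_std * fac
  data.frame(variant_id = ids, chrom = struct$chrom, pos = struct$pos,
             effect_allele = "A", other_allele = "G",
             eaf = maf, beta = beta, se = se,
             pval = two_sided_p(beta / se), n = as.numeric(n),
             stringsAsFactors = FALSE)
}

#' Simulate an exposure/outcome GWAS pair with known truth
#'
#' Draws per-SNP standardized exposure effects `N(0, h2/n_snps)`, propagates
#' them through the LD structure to marginal effects, adds correlated
#' sampling noise at the GWAS sample sizes, and builds the outcome GWAS from
#' `theta` times the exposure effects plus any pleiotropic direct effects and
#' reverse-causal SNPs.  All randomness comes from the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` summary-statistics data frames,
#'   `ld` (an [ld_matrix()]), and `truth` (a `sim_truth` list holding the
#'   generating parameters, per-SNP true marginal effects, and the
#'   pleiotropic/reverse index sets).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  withr::with_seed(config$seed, {
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    struct <- make_ld_structure(n, config$ld_block_size, config$ld_rho)
    g_std <- stats::rnorm(n, 0, sqrt(config$exposure_h2 / n))

    n_rev <- floor(config$reverse_frac * n)
    reverse_idx <- if (n_rev > 0) sort(sample.int(n, n_rev)) else integer(0)
    eta <- numeric(n)
    if (n_rev > 0) {
      # outcome-origin effects scaled so the induced exposure association has
      # the same magnitude distribution as a forward instrument
      eta[reverse_idx] <- stats::rnorm(n_rev, 0,
                                       sqrt(config$exposure_h2 / n) / abs(config$theta_rev))
      g_std[reverse_idx] <- config$theta_rev * eta[reverse_idx]
    }

    n_pl <- round(config$pleiotropy_frac * n)
    forward <- setdiff(seq_len(n), reverse_idx)
    pleio_idx <- if (n_pl > 0) sort(sample(forward, min(n_pl, length(forward)))) else integer(0)
    alpha <- numeric(n)
    if (length(pleio_idx)) {
      alpha[pleio_idx] <- sign(g_std[pleio_idx]) *
        stats::rnorm(length(pleio_idx), config$pleiotropy_mean, config$pleiotropy_sd)
    }

    out_direct <- config$theta * g_std + alpha
    out_direct[reverse_idx] <- eta[reverse_idx]

    use_ld <- config$ld_rho > 0 && config$ld_block_size > 1L
    m_exp <- if (use_ld) as.numeric(struct$R %*% g_std) else g_std
    m_out <- if (use_ld) as.numeric(struct$R %*% out_direct) else out_direct

    se_exp_std <- 1 / sqrt(config$n_exp)
    n_eff_out <- if (config$outcome_type == "binary") {
      effective_n(config$n_out, config$case_fraction)
    } else config$n_out
    se_out_std <- 1 / sqrt(n_eff_out)

    bhat_exp <- m_exp + correlated_noise(struct, se_exp_std, config$ld_rho,
                                         config$ld_block_size)
    bhat_out <- m_out + correlated_noise(struct, se_out_std, config$ld_rho,
                                         config$ld_block_size)

    ids <- sprintf("rs%05d", seq_len(n))
    exposure <- sumstats_from_std(ids, struct, bhat_exp, se_exp_std, maf, config$n_exp)
    outcome <- sumstats_from_std(ids, struct, bhat_out, se_out_std, maf, config$n_out)
  })
  attr(exposure, "trait") <- "exposure"
  attr(outcome, "trait") <- "outcome"
  fac <- 1 / sqrt(2 * maf * (1 - maf))
  truth <- structure(list(theta = config$theta, total = config$theta,
                          exposure_marginal = m_exp * fac,
                          outcome_marginal = m_out * fac,
                          exposure_marginal_std = m_exp,
                          outcome_marginal_std = m_out,
                          pleiotropy = alpha, pleiotropy_idx = pleio_idx,
                          reverse_idx = reverse_idx,
                          config = config),
                     class = "sim_truth")
  list(exposure = exposure, outcome = outcome,
       ld = ld_matrix(exposure$variant_id, struct$R^2), truth = truth)
}

#' Simulate an exposure/mediator/outcome GWAS triple with known truth
#'
#' Builds a causal chain: `n_snps` exposure instruments (standardized effects
#' `gamma`), `n_snps_med` mediator-specific instruments (`delta`), mediator
#' true effects `a gamma + delta`, outcome true effects
#' `b (a gamma + delta) + c_prime gamma`, so the true total exposure effect
#' is `a b + c_prime` and the true indirect effect `a b`.  Three independent
#' GWAS noise draws honour the two-sample design of each leg.
#'
#' @param config A [sim_config()] with `a`, `b`, `c_prime` set.
#' @return List with `exposure`, `mediator`, `outcome` summary-statistics
#'   data frames, `ld`, and `truth`.
#' @export
simulate_chain <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_e <- config$n_snps
  n_m <- config$n_snps_med
  n <- n_e + n_m
  exposure_idx <- seq_len(n_e)
  mediator_idx <- n_e + seq_len(n_m)
  withr::with_seed(sub_seed(config$seed, 7L), {
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    struct <- make_ld_structure(n, config$ld_block_size, config$ld_rho)
    gamma <- c(stats::rnorm(n_e, 0, sqrt(config$exposure_h2 / n_e)), numeric(n_m))
    delta <- c(numeric(n_e), stats::rnorm(n_m, 0, sqrt(config$exposure_h2 / n_m)))
    med_true <- config$a * gamma + delta
    out_true <- config$b * med_true + config$c_prime * gamma

    use_ld <- config$ld_rho > 0 && config$ld_block_size > 1L
    m_exp <- if (use_ld) as.numeric(struct$R %*% gamma) else gamma
    m_med <- if (use_ld) as.numeric(struct$R %*% med_true) else med_true
    m_out <- if (use_ld) as.numeric(struct$R %*% out_true) else out_true

    se_exp_std <- 1 / sqrt(config$n_exp)
    se_med_std <- 1 / sqrt(config$n_med)
    n_eff_out <- if (config$outcome_type == "binary") {
      effective_n(config$n_out, config$case_fraction)
    } else config$n_out
    se_out_std <- 1 / sqrt(n_eff_out)

    bhat_exp <- m_exp + correlated_noise(struct, se_exp_std, config$ld_rho,
                                         config$ld_block_size)
    bhat_med <- m_med + correlated_noise(struct, se_med_std, config$ld_rho,
                                         config$ld_block_size)
    bhat_out <- m_out + correlated_noise(struct, se_out_std, config$ld_rho,
                                         config$ld_block_size)

    ids <- sprintf("rs%05d", seq_len(n))
    exposure <- sumstats_from_std(ids, struct, bhat_exp, se_exp_std, maf, config$n_exp)
    mediator <- sumstats_from_std(ids, struct, bhat_med, se_med_std, maf, config$n_med)
    outcome <- sumstats_from_std(ids, struct, bhat_out, se_out_std, maf, config$n_out)
  })
  attr(exposure, "trait") <- "exposure"
  attr(mediator, "trait") <- "mediator"
  attr(outcome, "trait") <- "outcome"
  truth <- structure(list(a = config$a, b = config$b, c_prime = config$c_prime,
                          indirect = config$a * config$b,
                          total = config$a * config$b + config$c_prime,
                          exposure_idx = exposure_idx,
                          mediator_idx = mediator_idx,
                          exposure_marginal_std = m_exp,
                          mediator_marginal_std = m_med,
                          outcome_marginal_std = m_out,
                          config = config),
                     class = "sim_truth")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = ld_matrix(exposure$variant_id, struct$R^2), truth = truth)
}

#' Write a simulated bundle to disk as plain-text fixtures
#'
#' Writes the summary-statistics TSVs, the LD pair list and a `truth.txt`
#' key = value file so that file-level integration tests exercise the
#' pipeline exactly as a user would.  Bytes are deterministic for a given
#' config.
#'
#' @param bundle Output of [simulate_pair()] or [simulate_chain()].
#' @param out_dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (tab in intersect(c("exposure", "mediator", "outcome"), names(bundle))) {
    p <- file.path(out_dir, paste0(tab, ".tsv"))
    write_sumstats(bundle[[tab]], p)
    paths[tab] <- p
  }
  paths["ld"] <- file.path(out_dir, "ld.tsv")
  write_ld_matrix(bundle$ld, paths[["ld"]])

  tr <- bundle$truth
  scalars <- Filter(function(x) is.numeric(x) && length(x) == 1L,
                    tr[setdiff(names(tr), "config")])
  lines <- sprintf("%s = %.17g", names(scalars), unlist(scalars))
  cfg <- tr$config
  lines <- c(lines, sprintf("seed = %d", cfg$seed),
             sprintf("outcome_type = %s", cfg$outcome_type))
  paths["truth"] <- file.path(out_dir, "truth.txt")
  writeLines(lines, paths[["truth"]])
  invisible(paths)
}
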