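# The causal-effect estimators.

test_that("Wald ratio arithmetic, null boundary and joint sign flip", {
  tab <- make_table(0.1, 0.005, 0.05, 0.01)
  fit <- mr_wald_ratio(tab)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, 0.1)

  null_tab <- make_table(0.1, 0.005, 0, 0.01)
  expect_equal(mr_wald_ratio(null_tab)$beta, 0)
  expect_equal(mr_wald_ratio(null_tab)$pval, 1)

  flip <- make_table(-0.1, 0.005, -0.05, 0.01)
  expect_equal(mr_wald_ratio(flip)$beta, fit$beta)
  expect_equal(mr_wald_ratio(flip)$se, fit$se)

  expect_error(mr_wald_ratio(make_table(0, 0.005, 0.05, 0.01)),
               class = "mr_degenerate_instrument")
})

test_that("IVW reproduces the hand-computed weighted mean of Wald ratios", {
  tab <- make_table(beta_exp = c(0.1, 0.2), se_exp = 0.005,
                    beta_out = c(0.05, 0.06), se_out = c(0.01, 0.02))
  fit <- mr_ivw(tab, model = "fixed")
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)
  expect_equal(fit$se, 1 / sqrt(200), tolerance = 1e-12)
  expect_error(mr_ivw(tab[1, ]), "wald", class = "mr_insufficient_instruments")
})

test_that("exact-line data give Q = 0 and random-effects = fixed-effects", {
  tab <- make_table(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.005,
                    beta_out = c(0.03, 0.06, 0.09), se_out = 0.01)
  fixed <- mr_ivw(tab, model = "fixed")
  random <- mr_ivw(tab, model = "random")
  expect_equal(fixed$beta, 0.3, tolerance = 1e-12)
  expect_equal(random$se, fixed$se)
  expect_equal(fixed$extra$Q, 0, tolerance = 1e-20)
})

test_that("duplicating every SNP shrinks the fixed-effect SE by sqrt(2)", {
  tab <- random_table(6, PROP_SEED)
  dup <- instrument_table(variant_id = sprintf("d%02d", 1:12),
                          beta_exp = rep(tab$beta_exp, 2),
                          se_exp = rep(tab$se_exp, 2),
                          beta_out = rep(tab$beta_out, 2),
                          se_out = rep(tab$se_out, 2))
  f1 <- mr_ivw(tab, model = "fixed")
  f2 <- mr_ivw(dup, model = "fixed")
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$se, f1$se / sqrt(2), tolerance = 1e-12)
})

test_that("IVW equals independent weighted-least-squares and meta-analysis oracles", {
  skip_if_not_installed("metafor")
  for (s in 1:10) {
    tab <- random_table(sample(3:12, 1), PROP_SEED + s)
    fit <- mr_ivw(tab, model = "fixed")
    expect_lt(abs(fit$beta - ivw_oracle_beta(tab)), 1e-10)
    # fixed-effect meta-analysis of the Wald ratios is the same estimator
    ratio <- tab$beta_out / tab$beta_exp
    rse <- tab$se_out / abs(tab$beta_exp)
    meta <- metafor::rma(yi = ratio, sei = rse, method = "FE")
    expect_equal(fit$beta, as.numeric(meta$beta), tolerance = 1e-10)
    expect_equal(fit$se, meta$se, tolerance = 1e-10)
  }
})

test_that("maximum likelihood reduces to IVW when exposure noise vanishes", {
  tab <- make_table(beta_exp = c(0.1, 0.2), se_exp = 1e-8,
                    beta_out = c(0.05, 0.06), se_out = c(0.01, 0.02))
  ml <- mr_max_likelihood(tab)
  expect_equal(ml$beta, 0.4, tolerance = 1e-6)
  expect_equal(ml$se, 1 / sqrt(200), tolerance = 1e-4)

  line <- make_table(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
                     beta_out = c(0.03, 0.06, 0.09), se_out = 0.01)
  expect_equal(mr_max_likelihood(line)$beta, 0.3, tolerance = 1e-8)
})

test_that("Egger recovers an exact affine relationship", {
  tab <- make_table(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.005,
                    beta_out = 0.1 + 0.3 * c(0.1, 0.2, 0.3), se_out = 0.01)
  fit <- mr_egger(tab)
  expect_equal(fit$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope$extra$rss_w, 0, tolerance = 1e-16)
  expect_error(mr_egger(tab[1:2, ]), class = "mr_insufficient_instruments")
})

test_that("Egger is invariant to each SNP's reported allele orientation", {
  tab <- random_table(8, PROP_SEED + 20L)
  flipped <- tab
  flipped$beta_exp[c(2, 5)] <- -flipped$beta_exp[c(2, 5)]
  flipped$beta_out[c(2, 5)] <- -flipped$beta_out[c(2, 5)]
  f0 <- mr_egger(tab)
  f1 <- mr_egger(flipped)
  expect_equal(f1$slope$beta, f0$slope$beta, tolerance = 1e-12)
  expect_equal(f1$intercept, f0$intercept, tolerance = 1e-12)
})

test_that("weighted median: middle order statistic, dominance, and oracle", {
  eq <- make_table(beta_exp = c(1, 1, 1), se_exp = 0.005,
                   beta_out = c(0.2, 0.5, 0.9), se_out = 1)
  expect_equal(mr_weighted_median(eq, n_boot = 0L)$beta, 0.5)

  # one SNP holds 90% of the weight, the rest split evenly around it
  dom <- instrument_table(variant_id = c("a", "b", "c"),
                          beta_exp = c(1, 3, 1), se_exp = 0.005,
                          beta_out = c(0.2, 3 * 0.5, 0.9),
                          se_out = c(1, 1, 1))
  # weights 1, 9, 1 -> cumulative standardized weights 1/22, 1/2, 21/22
  expect_equal(mr_weighted_median(dom, n_boot = 0L)$beta, 0.5)

  for (s in 1:25) {
    k <- sample(3:7, 1)
    tab <- random_table(k, PROP_SEED + 100L + s)
    rc <- list(ratio = tab$beta_out / tab$beta_exp,
               weight = tab$beta_exp^2 / tab$se_out^2)
    expect_equal(mr_weighted_median(tab, n_boot = 0L)$beta,
                 weighted_median_oracle(rc$ratio, rc$weight),
                 tolerance = 1e-12)
  }
})

test_that("mode estimators find the majority cluster and honor weights", {
  same <- make_table(beta_exp = c(1, 1, 1), se_exp = 0.005,
                     beta_out = c(0.3, 0.3, 0.3), se_out = 0.01)
  expect_equal(mr_mode(same, n_boot = 0L)$beta, 0.3)

  clust <- make_table(beta_exp = rep(1, 4), se_exp = 0.005,
                      beta_out = c(0.2, 0.21, 0.19, 0.9), se_out = 1)
  est <- mr_mode(clust, weighted = FALSE, n_boot = 0L)$beta
  expect_gte(est, 0.19)
  expect_lte(est, 0.21)

  # the minority cluster carries ~80% of the weight
  two <- instrument_table(variant_id = sprintf("t%d", 1:7),
                          beta_exp = rep(1, 7), se_exp = 0.005,
                          beta_out = c(0.20, 0.21, 0.19, 0.20, 0.22, 0.80, 0.81),
                          se_out = c(rep(1, 5), rep(0.35, 2)))
  simple <- mr_mode(two, weighted = FALSE, n_boot = 0L)$beta
  weighted <- mr_mode(two, weighted = TRUE, n_boot = 0L)$beta
  expect_lt(abs(simple - 0.2), 0.05)
  expect_lt(abs(weighted - 0.8), 0.05)
})

test_that("bootstrap SEs are seed-reproducible and seeds are mandatory", {
  tab <- random_table(6, PROP_SEED + 3L)
  a <- mr_weighted_median(tab, n_boot = 200L, seed = 7L)
  b <- mr_weighted_median(tab, n_boot = 200L, seed = 7L)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(tab, n_boot = 200L), class = "mr_domain_error")
})

test_that("estimate_all dispatches on instrument count", {
  one <- random_table(1, PROP_SEED + 4L)
  est1 <- mr_estimate_all(one, seed = 1L)
  expect_equal(est1$method, "wald_ratio")
  expect_true(est1$primary)

  two <- random_table(2, PROP_SEED + 5L)
  expect_setequal(mr_estimate_all(two, seed = 1L)$method,
                  c("ivw", "max_likelihood"))

  ten <- random_table(10, PROP_SEED + 6L)
  est10 <- mr_estimate_all(ten, seed = 1L, n_boot_median = 0L, n_boot_mode = 0L)
  expect_setequal(est10$method,
                  c("ivw", "max_likelihood", "egger", "weighted_median",
                    "simple_mode", "weighted_mode"))
  expect_equal(est10$method[est10$primary], "ivw")
  expect_error(mr_estimate_all(ten[0, ], seed = 1L),
               class = "mr_insufficient_instruments")
})

test_that("deterministic estimates are invariant to SNP row order", {
  tab <- random_table(12, PROP_SEED + 7L)
  perm <- tab[withr::with_seed(1, sample(12)), ]
  e0 <- mr_estimate_all(tab, seed = 1L, n_boot_median = 0L, n_boot_mode = 0L)
  e1 <- mr_estimate_all(perm, seed = 1L, n_boot_median = 0L, n_boot_mode = 0L)
  closed_form <- e0$method != "max_likelihood"
  expect_equal(e1$beta[closed_form], e0$beta[closed_form], tolerance = 1e-12)
  # the ML optimizer is iterative; hold it to its own convergence tolerance
  expect_equal(e1$beta[!closed_form], e0$beta[!closed_form], tolerance = 1e-8)
})

test_that("estimates obey scale equivariance and outcome-sign antisymmetry", {
  for (s in 1:5) {
    tab <- random_table(9, PROP_SEED + 200L + s)
    e0 <- mr_estimate_all(tab, seed = 1L, n_boot_median = 0L, n_boot_mode = 0L)

    c_ <- -2.5
    scaled <- instrument_table(variant_id = tab$variant_id,
                               beta_exp = c_ * tab$beta_exp,
                               se_exp = abs(c_) * tab$se_exp,
                               beta_out = tab$beta_out, se_out = tab$se_out)
    e1 <- mr_estimate_all(scaled, seed = 1L, n_boot_median = 0L, n_boot_mode = 0L)
    expect_equal(e1$beta, e0$beta / c_, tolerance = 1e-6)

    negated <- instrument_table(variant_id = tab$variant_id,
                                beta_exp = tab$beta_exp, se_exp = tab$se_exp,
                                beta_out = -tab$beta_out, se_out = tab$se_out)
    e2 <- mr_estimate_all(negated, seed = 1L, n_boot_median = 0L, n_boot_mode = 0L)
    expect_equal(e2$beta, -e0$beta, tolerance = 1e-6)
  }
})

test_that("nominal 95% CIs cover the null at their advertised rate", {
  # analytic methods at 400 replicates (band 0.95 +/- 3 binomial SEs);
  # bootstrap methods at 150 replicates with 200 bootstrap draws (wider band
  # for the extra bootstrap noise)
  n1 <- 400L
  cover <- matrix(NA, n1, 3, dimnames = list(NULL, c("ivw", "ml", "egger")))
  cfg <- sim_config(theta = 0)
  sel <- selection_config()
  for (r in seq_len(n1)) {
    cfg$seed <- mrmediate:::sub_seed(PROP_SEED, 300L + r)
    b <- simulate_pair(cfg)
    iv <- mrmediate:::select_instruments(b$exposure, sel)
    tab <- harmonize(iv$records, b$outcome)$instruments
    fits <- list(ivw = mr_ivw(tab), ml = mr_max_likelihood(tab),
                 egger = mr_egger(tab)$slope)
    cover[r, ] <- vapply(fits, function(f) f$ci_low <= 0 && 0 <= f$ci_high,
                         logical(1))
  }
  band1 <- 3 * sqrt(0.95 * 0.05 / n1)
  for (m in colnames(cover)) {
    expect_gte(mean(cover[, m]), 0.95 - band1)
    expect_lte(mean(cover[, m]), min(1, 0.95 + band1))
  }

  n2 <- 150L
  cover2 <- matrix(NA, n2, 2, dimnames = list(NULL, c("wm", "wmode")))
  for (r in seq_len(n2)) {
    cfg$seed <- mrmediate:::sub_seed(PROP_SEED, 900L + r)
    b <- simulate_pair(cfg)
    iv <- mrmediate:::select_instruments(b$exposure, sel)
    tab <- harmonize(iv$records, b$outcome)$instruments
    sd_ <- mrmediate:::sub_seed(PROP_SEED, 1500L + r)
    fits <- list(wm = mr_weighted_median(tab, n_boot = 200L, seed = sd_),
                 wmode = mr_mode(tab, n_boot = 200L, seed = sd_ + 1L))
    cover2[r, ] <- vapply(fits, function(f) f$ci_low <= 0 && 0 <= f$ci_high,
                          logical(1))
  }
  for (m in colnames(cover2)) {
    expect_gte(mean(cover2[, m]), 0.88)
    expect_lte(mean(cover2[, m]), 1)
  }
})
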