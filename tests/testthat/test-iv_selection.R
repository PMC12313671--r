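# Instrument selection: p-value thresholding with fallback, LD clumping,
# MAF and F filters, variance explained, Steiger directionality.

test_that("p-value selection uses the genome-wide threshold when enough SNPs pass", {
  recs <- make_sumstats(sprintf("rs%d", 1:4), pval = c(1e-9, 1e-9, 1e-9, 0.5))
  sel <- select_by_pvalue(recs, selection_config())
  expect_equal(nrow(sel$records), 3L)
  expect_equal(sel$threshold_used, 5e-8)
})

test_that("too few genome-wide hits trigger the relaxed fallback", {
  recs <- make_sumstats(sprintf("rs%d", 1:3), pval = c(1e-6, 1e-7, 0.5))
  sel <- select_by_pvalue(recs, selection_config())
  expect_equal(nrow(sel$records), 2L)
  expect_equal(sel$threshold_used, 1e-5)

  none <- make_sumstats(sprintf("rs%d", 1:3), pval = 0.9)
  sel0 <- select_by_pvalue(none, selection_config())
  expect_equal(nrow(sel0$records), 0L)
  expect_equal(sel0$threshold_used, 1e-5)
})

test_that("greedy clumping keeps index SNPs and drops their LD partners", {
  recs <- make_sumstats(c("s1", "s2", "s3"), pval = c(1e-10, 1e-9, 1e-8),
                        pos = 1)
  recs$pos <- c(1e6, 1e6 + 5e4, 1e6 + 1e5)
  r2 <- diag(1, 3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- r2[2, 3] <- r2[3, 2] <- 5e-4
  ld <- ld_matrix(c("s1", "s2", "s3"), r2)
  got <- ld_clump(recs, ld, selection_config())
  expect_equal(got$variant_id, c("s1", "s3"))
})

test_that("high LD outside the window does not clump", {
  recs <- make_sumstats(c("s1", "s2"), pval = c(1e-10, 1e-9), pos = 1)
  recs$pos <- c(1e6, 1e6 + 2e10 / 1000)  # 20,000 kb apart
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  ld <- ld_matrix(c("s1", "s2"), r2)
  expect_equal(nrow(ld_clump(recs, ld, selection_config())), 2L)
  # and zero LD everywhere is the identity
  ld0 <- ld_matrix(c("s1", "s2"), diag(1, 2))
  recs$pos <- c(1e6, 1.1e6)
  expect_equal(ld_clump(recs, ld0, selection_config()), recs)
})

test_that("clumping matches a brute-force greedy oracle on block-LD panels", {
  for (s in 1:5) {
    bundle <- simulate_pair(sim_config(n_snps = 40L, ld_block_size = 5L,
                                       ld_rho = 0.9, seed = PROP_SEED + s))
    cfg <- selection_config(clump_r2 = 0.1)
    got <- ld_clump(bundle$exposure, bundle$ld, cfg)
    oracle <- clump_oracle_ids(bundle$exposure, bundle$ld, 0.1, cfg$clump_window_kb)
    expect_setequal(got$variant_id, oracle)
    # input row order is preserved
    expect_identical(got$variant_id,
                     bundle$exposure$variant_id[bundle$exposure$variant_id %in% oracle])
    # independence: no retained same-chromosome pair in the window exceeds r2
    for (i in seq_len(nrow(got))) {
      near <- got$chrom == got$chrom[i] &
        abs(got$pos - got$pos[i]) <= cfg$clump_window_kb * 1000 &
        got$variant_id != got$variant_id[i]
      if (any(near)) {
        expect_lte(max(bundle$ld$r2[got$variant_id[i], got$variant_id[near]]), 0.1)
      }
    }
  }
})

test_that("clumping a variant missing from the LD matrix is fatal", {
  recs <- make_sumstats(c("s1", "s2"))
  ld <- ld_matrix("s1", matrix(1))
  expect_error(ld_clump(recs, ld, selection_config()), "s2",
               class = "mr_missing_ld")
})

test_that("the MAF filter is symmetric around 0.5", {
  recs <- make_sumstats(sprintf("rs%d", 1:3), eaf = c(0.005, 0.995, 0.30))
  got <- filter_maf(recs, selection_config())
  expect_equal(got$variant_id, "rs3")
})

test_that("the F statistic is the squared Wald ratio and filters at f_min", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0.02, 0.01), 4)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_error(f_statistic(0.1, 0), class = "mr_domain_error")
  recs <- make_sumstats(c("a", "b"), beta = c(0.1, 0.02), se = c(0.02, 0.01))
  expect_equal(filter_f(recs, selection_config())$variant_id, "a")
})

test_that("variance explained matches the closed form and is monotone in beta", {
  expect_equal(variance_explained(0, 0.4, 0.01, 1000), 0)
  expect_equal(variance_explained(0.1, 0.5, 0.01, 10000), 0.005 / 0.505,
               tolerance = 1e-12)
  r2 <- variance_explained(c(0.05, 0.1, 0.2, 0.4), 0.3, 0.01, 20000)
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 < 1))
  expect_error(variance_explained(0.1, 1.2, 0.01, 1000), class = "mr_domain_error")
  expect_error(variance_explained(0.1, 0.3, 0.01, 3), class = "mr_domain_error")
})

test_that("Steiger filtering removes outcome-first SNPs and keeps forward ones", {
  # forward SNP: much larger exposure than outcome effect
  tab <- make_table(beta_exp = c(0.2, 0.1), se_exp = 0.01,
                    beta_out = c(0.02, 0.1), se_out = 0.01)
  st <- steiger_filter(tab, selection_config())
  expect_true(st$steiger$direction_ok[1])
  expect_false(st$steiger$direction_ok[2])  # equal r2 on both sides: removed
  expect_equal(st$steiger$z[2], 0)
  expect_equal(st$table$variant_id, "s01")
  expect_equal(st$n_removed, 1L)
  # the filter never removes a SNP with r2_exp > r2_out
  expect_true(all(st$steiger$direction_ok == (st$steiger$r2_exp > st$steiger$r2_out)))
})

test_that("Steiger retains essentially all instruments under forward-only simulation", {
  # exposure-only SNPs (theta = 0), selected as the pipeline would
  kept <- total <- 0
  for (s in 1:40) {
    bundle <- simulate_pair(sim_config(theta = 0, outcome_type = "quantitative",
                                       seed = PROP_SEED + s))
    iv <- mrmediate:::select_instruments(bundle$exposure, selection_config())
    tab <- harmonize(iv$records, bundle$outcome)$instruments
    st <- steiger_filter(tab, selection_config())
    kept <- kept + sum(st$steiger$direction_ok)
    total <- total + nrow(tab)
  }
  expect_gte(kept / total, 0.99)
})
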