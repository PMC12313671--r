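# Fixture builders shared across the test files.  Everything is generated in
# code; property-test seeds are fixed at 42 (and small offsets of it).

PROP_SEED <- 42L

make_sumstats <- function(variant_id, effect_allele = "A", other_allele = "G",
                          eaf = 0.3, beta = 0.1, se = 0.01, pval = NULL,
                          n = 50000L, chrom = "1", pos = NULL) {
  k <- length(variant_id)
  rec <- function(x) rep_len(x, k)
  beta <- rec(beta); se <- rec(se)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = variant_id, chrom = rec(chrom),
             pos = if (is.null(pos)) seq(1e6, by = 1e4, length.out = k) else rec(pos),
             effect_allele = rec(effect_allele), other_allele = rec(other_allele),
             eaf = rec(eaf), beta = beta, se = se, pval = rec(pval),
             n = rec(n), stringsAsFactors = FALSE)
}

make_table <- function(beta_exp, se_exp, beta_out, se_out,
                       eaf = 0.3, n_exp = 50000L, n_out = 50000L) {
  k <- length(beta_exp)
  instrument_table(variant_id = sprintf("s%02d", seq_len(k)),
                   beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
                   beta_out = beta_out, se_out = rep_len(se_out, k),
                   eaf_exp = rep_len(eaf, k), eaf_out = rep_len(eaf, k),
                   n_exp = rep_len(n_exp, k), n_out = rep_len(n_out, k))
}

random_table <- function(k, seed) {
  withr::with_seed(seed, {
    make_table(beta_exp = rnorm(k, 0, 0.1) + 0.2 * sign(rnorm(k)),
               se_exp = runif(k, 0.005, 0.02),
               beta_out = rnorm(k, 0, 0.05),
               se_out = runif(k, 0.01, 0.05))
  })
}

# Independent reference implementations ("oracles") -------------------------

# IVW slope via weighted least squares through the origin with lm().
ivw_oracle_beta <- function(tab) {
  w <- 1 / tab$se_out^2
  unname(coef(lm(tab$beta_out ~ 0 + tab$beta_exp, weights = w))[1])
}

# Interpolated weighted percentile at 0.5 by explicit stepwise construction.
weighted_median_oracle <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  p <- numeric(length(r))
  run <- 0
  for (j in seq_along(r)) {
    p[j] <- run + w[j] / 2
    run <- run + w[j]
  }
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  j <- max(which(p < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# Greedy clumping by explicit set manipulation.
clump_oracle_ids <- function(records, ld, r2_max, window_kb) {
  remaining <- records[order(records$pval, records$variant_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$variant_id)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0L) break
    drop <- remaining$chrom == idx$chrom &
      abs(remaining$pos - idx$pos) <= window_kb * 1000 &
      ld$r2[idx$variant_id, remaining$variant_id] > r2_max
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}
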