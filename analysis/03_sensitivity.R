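#!/usr/bin/env Rscript
# Step 3: sensitivity analysis of the top screening hit.
#
# For the exposure with the smallest primary-method FDR: Cochran's Q / I^2,
# the MR-Egger intercept test, MR-PRESSO (global, outlier, distortion) and
# leave-one-out IVW.

suppressPackageStartupMessages({
  library(optparse)
  library(mrmediate)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260926L),
  make_option("--in-dir", type = "character", default = "results/synthetic",
              dest = "in_dir"),
  make_option("--out-dir", type = "character", default = "results/sensitivity",
              dest = "out_dir")
)))

screen <- utils::read.delim("results/screen/screen_full.tsv")
prim <- screen[screen$primary, ]
top <- prim$exposure[which.min(prim$fdr)]
message("top screening hit: ", top)

exposure <- read_sumstats(file.path(opts$in_dir, paste0(top, ".tsv")), trait = top)
outcome <- read_sumstats(file.path(opts$in_dir, "outcome.tsv"), trait = "outcome")
cfg <- selection_config()
iv <- select_by_pvalue(exposure, cfg)
tab <- harmonize(filter_f(filter_maf(iv$records, cfg), cfg), outcome)$instruments
tab <- steiger_filter(tab, cfg)$table

het <- cochran_q(tab)
egger <- mr_egger(tab)
presso <- mr_presso(tab, n_sim = 2000L, seed = opts$seed)
loo <- leave_one_out(tab)

dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
diag <- data.frame(exposure = top, n_snps = nrow(tab),
                   Q = het$Q, Q_df = het$df, Q_p = het$pval, I2 = het$i2,
                   egger_intercept = egger$intercept,
                   egger_intercept_p = egger$intercept_p,
                   presso_rss = presso$rss_obs, presso_global_p = presso$global_p,
                   presso_n_outliers = length(presso$outlier_indices))
utils::write.table(diag, file.path(opts$out_dir, "diagnostics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(loo, file.path(opts$out_dir, "leave_one_out.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("Cochran's Q = %.2f (df %d, p = %.3f), I2 = %.1f%%",
                het$Q, het$df, het$pval, 100 * het$i2))
message(sprintf("Egger intercept = %.4f (p = %.3f)", egger$intercept,
                egger$intercept_p))
message(sprintf("MR-PRESSO global p = %.3f, %d outlier(s) flagged",
                presso$global_p, length(presso$outlier_indices)))
message(sprintf("leave-one-out: %d/%d rows flagged as influential",
                sum(loo$flagged), nrow(loo)))
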