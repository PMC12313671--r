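#!/usr/bin/env Rscript
# Step 1: generate the synthetic study data.
#
# Builds (a) a screening batch of 20 microbial-taxon-like exposures against
# one binary liver-disease-like outcome (FinnGen-shaped: 500,000 samples,
# 0.7% cases), three of them truly causal (theta = 0.2), and (b) one
# exposure -> protein-ratio mediator -> outcome causal chain
# (a = 0.3, b = 0.5, direct c' = 0.1).  Everything is written as plain-text
# fixtures under results/synthetic/ for the downstream steps.

suppressPackageStartupMessages({
  library(optparse)
  library(mrmediate)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260926L),
  make_option("--out-dir", type = "character", default = "results/synthetic",
              dest = "out_dir")
)))

n_taxa <- 20L
n_causal <- 3L
screen_cfg <- sim_config(n_out = 500000L)   # binary outcome, case fraction 0.007
thetas <- c(rep(0.2, n_causal), rep(0, n_taxa - n_causal))

batch <- mrmediate:::simulate_screen_batch(n_taxa, screen_cfg, opts$seed,
                                           thetas = thetas)
dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
for (label in names(batch$exposures)) {
  write_sumstats(batch$exposures[[label]],
                 file.path(opts$out_dir, paste0(label, ".tsv")))
}
write_sumstats(batch$outcome, file.path(opts$out_dir, "outcome.tsv"))
writeLines(sprintf("causal = %s",
                   paste(names(batch$exposures)[seq_len(n_causal)], collapse = ",")),
           file.path(opts$out_dir, "screen_truth.txt"))

chain <- simulate_chain(sim_config(seed = opts$seed + 1L))
write_fixture(chain, file.path(opts$out_dir, "chain"))

message(sprintf("wrote %d exposure GWAS (%d causal), 1 outcome GWAS and 1 mediation chain to %s",
                n_taxa, n_causal, opts$out_dir))
message(sprintf("chain truth: indirect = %.3f, total = %.3f",
                chain$truth$indirect, chain$truth$total))
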