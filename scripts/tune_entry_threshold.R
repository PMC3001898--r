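#!/usr/bin/env Rscript
# Calibration of the forward-selection entry threshold.
#
# Runs null genome scans (a pure-noise phenotype, no genetic effect) at
# the package's reference null scale and reports, for a grid of entry
# thresholds, the mean number of QTLs called per scan at an RMIP
# threshold of 0.25.  The packaged default entry threshold is the grid
# value whose null call rate is closest to 0.25 QTLs per scan (about one
# false positive every four genome scans).
#
# Usage: Rscript scripts/tune_entry_threshold.R [n_scans] [seed]

suppressMessages(library(hsqtl))

args <- commandArgs(trailingOnly = TRUE)
n_scans <- if (length(args) >= 1) as.integer(args[1]) else 60L
seed <- if (length(args) >= 2) as.integer(args[2]) else 20260929L

thresholds <- c(2.0, 2.5, 3.0, 3.5)
B <- 50L

calls <- matrix(0, n_scans, length(thresholds),
                dimnames = list(NULL, thresholds))
for (i in seq_len(n_scans)) {
  # reference null scale: one 100 Mb chromosome, markers every 2 Mb, n=400
  cfg <- hs_config(n_individuals = 400, chromosomes = c(`1` = 100),
                   marker_spacing = 2, qtl_spec = list(),
                   null_phenotypes = "null_trait", polygenic_h2 = 0,
                   seed = seed + i)
  st <- simulate_hs_study(cfg)
  for (j in seq_along(thresholds)) {
    pr <- rmip(st$phenotypes, st$dosage, "null_trait", B = B,
               entry_logp = thresholds[j], seed = seed + 100000 + i)
    calls[i, j] <- nrow(call_qtls(pr, rmip_threshold = 0.25))
  }
}

cat("null scans:", n_scans, " B:", B, "\n")
cat("mean called QTLs per null scan at RMIP >= 0.25:\n")
print(colMeans(calls))
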