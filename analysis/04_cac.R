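#!/usr/bin/env Rscript
# Stage 4: estimate the critical aggregation concentration from the
# simulated pyrene titration as the intersection of the two linear regimes
# of I1/I3 vs log10(concentration), with a bootstrap confidence interval.

suppressPackageStartupMessages(library(lipoaggr))

titr <- read_titration_table("results/titration.tsv")
fit <- fit_cac_segmented(titr, n_bootstrap = 500, seed = 201L)

if (fit$flag == "ok") {
  cat(sprintf("cac = %.2f uM (95%% bootstrap CI %.2f-%.2f uM)\n",
              fit$cac_uM, fit$bootstrap_ci_uM[1], fit$bootstrap_ci_uM[2]))
  cat("segment slopes (ratio per log10 uM):\n")
  print(fit$segments, row.names = FALSE)
} else {
  cat("no breakpoint detected in the titration\n")
}

write_cac_fit(fit, "results/cac_fit.json", "results/cac_segments.tsv", titr)
cat("fit written to results/cac_fit.json\n")
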