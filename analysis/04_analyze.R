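#!/usr/bin/env Rscript
# Full behavioural analysis of the simulated trial tables: responder tables
# with Wilson intervals, Fisher's exact tests against control with Bonferroni
# correction, the threshold rule, Spearman correlations and the repeat check.
# Expects the tables written by 03_simulate.R.

library(conchvision)
library(jsonlite)

dir.create("results", showWarnings = FALSE)

for (exp in c("contrast", "resolution")) {
  trials <- read_trials(sprintf("results/trials_%s.csv", exp))
  manifest <- read.csv(sprintf("results/manifest_%s.csv", exp))
  an <- run_analysis(trials, manifest, exp)
  print(an)

  write.csv(an$response_table,
            sprintf("results/response_table_%s.csv", exp), row.names = FALSE)
  write.csv(an$threshold$levels,
            sprintf("results/fet_levels_%s.csv", exp), row.names = FALSE)
  report <- list(
    experiment = exp,
    threshold_level = an$threshold$threshold_level,
    alpha_min_deg = an$threshold$alpha_min_deg,
    alpha = an$alpha, bonferroni_m = an$m,
    spearman_response = an$spearman_response[c("rho", "p_value", "n")],
    spearman_reemergence = if (!is.null(an$spearman_reemergence))
      an$spearman_reemergence[c("rho", "p_value", "n")],
    repeat_check = if (!is.null(an$repeat_check))
      an$repeat_check[c("V", "p_value", "n_nonzero")])
  write_json(report, sprintf("results/threshold_%s.json", exp),
             auto_unbox = TRUE, digits = NA, null = "null")
  cat("\n")
}
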