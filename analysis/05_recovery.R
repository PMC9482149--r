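#!/usr/bin/env Rscript
# Threshold-recovery study: how often does the full analysis pipeline recover
# the identifiable acuity target (the smallest designed check width above the
# generating threshold, 0.53 deg -> alpha_min 1.06 deg) from finite simulated
# data? 200 replicate experiments at the study's sample size.

library(conchvision)

seed <- 20220826
design <- simulation_design("resolution")
pars <- resolution_observer()

rec <- do.call(rbind, lapply(1:200, function(r) {
  sim <- simulate_trials(design, pars, seed = seed + r)
  out <- recover_threshold(sim, design, pars)
  data.frame(replicate = r, threshold_level = out$threshold_level,
             alpha_min_deg = out$alpha_min_deg, recovered = out$recovered)
}))
dir.create("results", showWarnings = FALSE)
write.csv(rec, "results/threshold_recovery.csv", row.names = FALSE)

tab <- table(rec$threshold_level, useNA = "ifany")
cat("Recovered thresholds over 200 replicates:\n"); print(tab)
cat(sprintf("Modal threshold: %s deg; alpha_min = %s deg; recovery rate %.1f%%.\n",
            names(which.max(tab)), 2 * as.numeric(names(which.max(tab))),
            100 * mean(rec$recovered)))
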