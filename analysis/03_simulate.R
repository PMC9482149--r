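#!/usr/bin/env Rscript
# Generate synthetic behavioural trial tables for both experiments under the
# study design (20 individuals x 2 repeats for contrast; 19 x 2 for
# resolution) with the default psychometric observers.

library(conchvision)

seed <- 20220826
dir.create("results", showWarnings = FALSE)

for (exp in c("contrast", "resolution")) {
  design <- simulation_design(exp)
  params <- if (exp == "contrast") contrast_observer() else resolution_observer()
  sim <- simulate_trials(design, params, seed = seed)
  write_trials(sim$trials, sprintf("results/trials_%s.csv", exp))
  write.csv(sim$manifest, sprintf("results/manifest_%s.csv", exp),
            row.names = FALSE)
  resp <- trial_responses(sim$trials)
  cat(sprintf("%s experiment: %d trials (%d individuals x %d repeats x %d stimuli), %d responses.\n",
              exp, nrow(resp), design$n_individuals, design$repeats,
              nrow(design$manifest), sum(resp$response)))
}
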