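#!/usr/bin/env Rscript
# Anatomical estimates for the sectioned eye: inter-receptor angle, angular
# resolution, Land's optical sensitivity, and the retinal cell census
# extrapolated from the sampled patch to the whole retina.

library(conchvision)

eye <- eye_anatomy(s_um = 6.5, f_um = 720, A_um = 630, d_um = 6.6,
                   x_um = 70.9, k_per_um = 0.0067)
census <- retina_sample(189, sampled_area_um2 = 204.8 * 10,
                        total_area_mm2 = 1.7)
est <- run_optics(eye, census)
dir.create("results", showWarnings = FALSE)
write.csv(est, "results/optical_estimates.csv", row.names = FALSE)
print(est)

cat(sprintf("\nThe eye resolves ~%.2f deg (2 x %.2f deg inter-receptor angle);",
            est$value[est$quantity == "angular_resolution"],
            est$value[est$quantity == "inter_receptor_angle"]))
cat(sprintf(" optical sensitivity %.2f um^2 sr.\n",
            est$value[est$quantity == "optical_sensitivity"]))
cat(sprintf("Census: %d sampled cells -> %.3g cells/eye; main photoreceptors at 23,400/mm^2 -> %.3g per eye.\n",
            189, est$value[est$quantity == "total_cells_per_eye"],
            total_from_density(23400, 1.7)))
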