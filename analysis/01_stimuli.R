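#!/usr/bin/env Rscript
# Build the stimulus set of both behavioural experiments: nine loom contrasts
# plus a control on the 10-s exponential expansion, and eight isoluminant
# checkerboard looms plus a control on the 5-s linear expansion. Writes the
# labelled manifest and verifies the isoluminance calibration of the
# checkerboard grey.

library(conchvision)

seed <- 20220826
man <- stimulus_manifest(display = display_model(1), seed = seed)
dir.create("results", showWarnings = FALSE)
write.csv(man, "results/stimulus_manifest.csv", row.names = FALSE)

cat("Stimulus manifest:", nrow(man), "stimuli (",
    sum(man$experiment == "contrast"), "contrast /",
    sum(man$experiment == "resolution"), "resolution ).\n")
cat("Contrast labels:",
    paste(sort(man$contrast_label[man$experiment == "contrast" &
                                    !man$is_control]), collapse = ", "), "\n")
cat("Checkerboard grey byte (linear display):",
    man$grey_byte[man$experiment == "resolution"][1],
    "| on a gamma-1.357 display:",
    isoluminant_grey(0, 255, display_model(1.357)), "\n")

# isoluminance contract: mean frame luminance stays flat while the grey disc
# expands over a balanced checkerboard
cfg <- viewing_config(frame_width_px = 132, frame_height_px = 132)
spec <- checker_loom_spec(3.2, profile = expansion_profile(
  "linear", duration_s = 5, alpha_max_deg = 30, frame_rate = 6))
lum <- vapply(render_sequence(spec, cfg), frame_mean_luminance, numeric(1))
cat(sprintf("Isoluminance drift over the loom: %.3f%% (max dev. from onset)\n",
            100 * max(abs(lum - lum[1])) / lum[1]))

# a short rendered sequence, written as greyscale PNGs for inspection
write_frame_sequence(render_sequence(spec, cfg), "scratch/frames_checker")
cat("Wrote example frames under scratch/frames_checker/.\n")
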