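# shared fixtures: small geometry, canonical profiles, a hand-built trial table

test_cfg <- function(...) {
  viewing_config(viewing_distance_mm = 50, pixel_pitch_mm = 0.25,
                 frame_width_px = 120, frame_height_px = 120, ...)
}

slow_loom <- function() expansion_profile("exponential", duration_s = 10,
                                          alpha_max_deg = 83,
                                          alpha_start_deg = 0.1)
fast_loom <- function() expansion_profile("linear", duration_s = 5,
                                          alpha_max_deg = 83)

# two individuals x two stimuli x one repeat, covering the scoring rules:
# responder, stop-feeding-only pause, eventless trial
tiny_trials <- function() {
  rbind(
    data.frame(individual_id = "a", experiment = "resolution",
               stimulus_id = "R01", repeat_index = 1L,
               event_category = c("stop_feeding", "partial_eyestalk_withdrawal",
                                  "full_eyestalk_withdrawal"),
               event_time_s = c(1, 3, 4.5), reemergence_s = 60),
    data.frame(individual_id = "a", experiment = "resolution",
               stimulus_id = "R00", repeat_index = 1L,
               event_category = "stop_feeding", event_time_s = 2,
               reemergence_s = NA_real_),
    data.frame(individual_id = "b", experiment = "resolution",
               stimulus_id = "R01", repeat_index = 1L,
               event_category = NA_character_, event_time_s = NA_real_,
               reemergence_s = NA_real_),
    data.frame(individual_id = "b", experiment = "resolution",
               stimulus_id = "R00", repeat_index = 1L,
               event_category = NA_character_, event_time_s = NA_real_,
               reemergence_s = NA_real_))
}

tiny_manifest <- function() {
  data.frame(stimulus_id = c("R00", "R01"), experiment = "resolution",
             level = c(0, 0.53), is_control = c(TRUE, FALSE),
             stringsAsFactors = FALSE)
}

# independent two-sided Fisher oracle: enumerate all 2x2 tables with the
# observed margins and sum hypergeometric probabilities <= observed
fisher_oracle_p <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  support <- max(0, K - n2):min(n1, K)
  probs <- stats::dhyper(support, n1, n2, K)
  obs <- stats::dhyper(k1, n1, n2, K)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
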