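#' Parameters of a synthetic psychometric observer
#'
#' Describes a population of observers whose probability of responding to a
#' stimulus of magnitude `level` follows a high-threshold psychometric
#' function on the log-level scale:
#' `P(level) = guess + (1 - guess - lapse) * Phi((log(level) - log(theta)) / slope)`,
#' with a control (zero-magnitude) stimulus answered at the guess rate.
#' Individuals draw their own log-threshold from
#' `Normal(log(theta), individual_sd)`. Responding trials also receive a
#' re-emergence time `max(0, base + gain * log(level / theta) + noise)`, so
#' stronger stimuli keep the animal withdrawn longer.
#'
#' @param threshold Population threshold theta in level units (contrast, or
#'   check width in degrees); the level at which the core function is at 50%.
#' @param slope Spread sigma of the psychometric function on the log-level
#'   scale (> 0; smaller is steeper).
#' @param guess_rate Floor response probability (default 0.02; the study
#'   reports no spontaneous control rate, so this is a synthetic convention).
#' @param lapse_rate Ceiling shortfall (default 0.02).
#' @param reemergence_base_s,reemergence_gain_s,reemergence_noise_sd_s
#'   Re-emergence model: seconds at threshold, seconds per log-unit of
#'   relative level, and noise SD.
#' @param individual_sd Between-individual SD of log-threshold (default 0.05).
#' @return An object of class `observer_params`.
#' @seealso [contrast_observer()], [resolution_observer()] for the two
#'   experiments' default observers.
#' @export
observer_params <- function(threshold, slope, guess_rate = 0.02,
                            lapse_rate = 0.02, reemergence_base_s = 90,
                            reemergence_gain_s = 25,
                            reemergence_noise_sd_s = 15,
                            individual_sd = 0.05) {
  if (threshold <= 0 || slope <= 0) stop("need threshold, slope > 0", call. = FALSE)
  if (guess_rate < 0 || guess_rate > 0.1 || lapse_rate < 0 || lapse_rate > 0.1)
    stop("guess and lapse rates must lie in [0, 0.1]", call. = FALSE)
  if (guess_rate + lapse_rate >= 1) stop("guess + lapse must be < 1", call. = FALSE)
  if (individual_sd < 0 || reemergence_noise_sd_s < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 reemergence_base_s = reemergence_base_s,
                 reemergence_gain_s = reemergence_gain_s,
                 reemergence_noise_sd_s = reemergence_noise_sd_s,
                 individual_sd = individual_sd),
            class = "observer_params")
}

#' Default observer for the contrast-sensitivity experiment
#'
#' Threshold 0.09 and slope 0.29 on log-contrast, back-solved once from the
#' study's printed response rates (20% at contrast 0.07, 62.5% at 0.10) with
#' 2% guess and lapse rates.
#'
#' @param ... Overrides passed to [observer_params()].
#' @return An `observer_params` object.
#' @export
contrast_observer <- function(...) {
  args <- utils::modifyList(list(threshold = 0.09, slope = 0.29), list(...))
  do.call(observer_params, args)
}

#' Default observer for the spatial-resolution experiment
#'
#' Threshold 0.45 deg (between the 0.4 and 0.53 deg check widths, so the
#' smallest supra-threshold designed level is 0.53 deg) with a steep slope
#' of 0.08 log-units, giving near-step behaviour around threshold.
#'
#' @param ... Overrides passed to [observer_params()].
#' @return An `observer_params` object.
#' @export
resolution_observer <- function(...) {
  args <- utils::modifyList(list(threshold = 0.45, slope = 0.08), list(...))
  do.call(observer_params, args)
}

#' Design of a simulated behavioural experiment
#'
#' The study conditions: the contrast experiment presents the nine loom
#' contrasts derived from object bytes 0..230 against 255 plus a contrast-0
#' control to 20 individuals, twice each (n = 40 trials per level); the
#' resolution experiment presents the eight check widths 0.3-3.2 deg plus a
#' control to 19 individuals, twice each (n = 38).
#'
#' @param experiment `"contrast"` or `"resolution"`.
#' @param levels Stimulus levels (defaults per experiment as above).
#' @param n_individuals Number of animals (default 20 contrast / 19
#'   resolution).
#' @param repeats Presentations per animal per stimulus (default 2).
#' @param control Include a control stimulus (default TRUE).
#' @return An object of class `simulation_design` carrying a stimulus
#'   manifest (`$manifest`).
#' @export
simulation_design <- function(experiment = c("contrast", "resolution"),
                              levels = NULL, n_individuals = NULL,
                              repeats = 2, control = TRUE) {
  experiment <- match.arg(experiment)
  if (is.null(levels))
    levels <- if (experiment == "contrast")
      michelson_contrast(contrast_series_bytes(), 255) else check_width_series()
  if (is.unsorted(levels, strictly = TRUE) &&
      is.unsorted(rev(levels), strictly = TRUE))
    stop("levels must be strictly ordered", call. = FALSE)
  levels <- sort(levels)
  if (is.null(n_individuals))
    n_individuals <- if (experiment == "contrast") 20L else 19L
  if (n_individuals < 1) stop("need at least one individual", call. = FALSE)
  prefix <- if (experiment == "contrast") "C" else "R"
  man <- data.frame(
    stimulus_id = c(if (control) paste0(prefix, "00"),
                    sprintf("%s%02d", prefix, seq_along(levels))),
    experiment = experiment,
    level = c(if (control) 0, levels),
    is_control = c(if (control) TRUE, rep(FALSE, length(levels))),
    stringsAsFactors = FALSE)
  structure(list(experiment = experiment, levels = levels,
                 n_individuals = as.integer(n_individuals),
                 repeats = as.integer(repeats), control = control,
                 manifest = man),
            class = "simulation_design")
}

#' Psychometric response probability
#'
#' `P = guess + (1 - guess - lapse) * Phi((log(level) - log(theta)) / slope)`.
#' A non-positive level (the control) maps to the guess rate. At
#' `level = theta` the probability is the midpoint
#' `guess + (1 - guess - lapse)/2`; as level grows it approaches
#' `1 - lapse`.
#'
#' @param level Stimulus magnitude(s); 0 denotes the control.
#' @param params An [observer_params()].
#' @param theta Threshold to use (default the population value; pass an
#'   individual's draw when simulating).
#' @return Response probability in `[guess, 1 - lapse]`.
#' @export
psychometric_p <- function(level, params, theta = params$threshold) {
  stopifnot(inherits(params, "observer_params"))
  core <- ifelse(level > 0,
                 stats::pnorm((log(pmax(level, .Machine$double.xmin)) -
                                 log(theta)) / params$slope),
                 0)
  params$guess_rate + (1 - params$guess_rate - params$lapse_rate) * core
}

# marginal response probability across the individual-threshold distribution
marginal_psychometric_p <- function(level, params) {
  s <- sqrt(params$slope^2 + params$individual_sd^2)
  core <- ifelse(level > 0,
                 stats::pnorm((log(pmax(level, .Machine$double.xmin)) -
                                 log(params$threshold)) / s),
                 0)
  params$guess_rate + (1 - params$guess_rate - params$lapse_rate) * core
}

# deterministic per-individual RNG substream seed (kept below 2^31)
individual_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i) %% (.Machine$integer.max - 1)) + 1L
}

#' Simulate a behavioural trial table
#'
#' Draws, for each individual, a log-normal threshold around the population
#' value, then Bernoulli responses per trial from [psychometric_p()].
#' Responding trials receive an ordered event sequence along the expansion:
#' between two and five events taken in severity order from the ethogram
#' (stop feeding first; full withdrawals only in responding trials), placed
#' at increasing angular sizes mapped to times through [time_to_reach()],
#' plus a re-emergence time increasing with log relative level.
#' Non-responding trials occasionally (30%) show a stop-feeding-only pause -
#' the event pattern the exclusion rule is there to discount - and otherwise
#' carry the eventless sentinel row. Fully reproducible from `seed`:
#' each individual consumes its own substream derived from the global seed.
#'
#' @param design A [simulation_design()].
#' @param params An [observer_params()].
#' @param profile Expansion profile under which event times are placed;
#'   default the experiment's paradigm (10-s exponential loom for contrast,
#'   5-s linear loom for resolution).
#' @param seed Integer seed governing all draws.
#' @return List with `trials` (long-format table, see [validate_trials()])
#'   and `manifest`.
#' @export
simulate_trials <- function(design, params, profile = NULL, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(params, "observer_params"))
  if (is.null(profile))
    profile <- if (design$experiment == "contrast")
      expansion_profile("exponential") else expansion_profile("linear")
  man <- design$manifest
  rows <- vector("list", design$n_individuals)
  cats <- transition_categories()
  angle_lo <- max(2, profile$alpha_start_deg * 1.01)
  angle_hi <- 0.95 * profile$alpha_max_deg
  for (i in seq_len(design$n_individuals)) {
    set.seed(individual_seed(seed, i))
    theta_i <- exp(log(params$threshold) +
                     stats::rnorm(1, 0, params$individual_sd))
    out <- list()
    for (s in seq_len(nrow(man))) {
      for (rep_idx in seq_len(design$repeats)) {
        level <- man$level[s]
        p <- psychometric_p(level, params, theta_i)
        responded <- stats::runif(1) < p
        if (responded) {
          n_ev <- sample(2:5, 1)
          ev_cats <- cats[seq_len(n_ev)]
          ev_angles <- sort(stats::runif(n_ev, angle_lo, angle_hi))
          ev_times <- time_to_reach(profile, ev_angles)
          rel <- if (level > 0) log(level / params$threshold) else 0
          reem <- max(0, params$reemergence_base_s +
                        params$reemergence_gain_s * rel +
                        stats::rnorm(1, 0, params$reemergence_noise_sd_s))
          out[[length(out) + 1]] <- data.frame(
            individual_id = sprintf("ind%02d", i),
            experiment = design$experiment,
            stimulus_id = man$stimulus_id[s],
            repeat_index = rep_idx,
            event_category = ev_cats,
            event_time_s = ev_times,
            reemergence_s = reem,
            stringsAsFactors = FALSE)
        } else {
          pause <- stats::runif(1) < 0.3
          out[[length(out) + 1]] <- data.frame(
            individual_id = sprintf("ind%02d", i),
            experiment = design$experiment,
            stimulus_id = man$stimulus_id[s],
            repeat_index = rep_idx,
            event_category = if (pause) "stop_feeding" else NA_character_,
            event_time_s = if (pause)
              time_to_reach(profile, stats::runif(1, angle_lo, 20)) else NA_real_,
            reemergence_s = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
    rows[[i]] <- do.call(rbind, out)
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  validate_trials(trials)
  list(trials = trials, manifest = man)
}

#' Expected responder table of a design under an observer
#'
#' The deterministic counterpart of [simulate_trials()]: responders at each
#' level are the rounded expected count `n * P(level)` under the marginal
#' (individual-averaged) psychometric function, with the control at the
#' guess rate. Useful for exercising the threshold logic without sampling
#' noise.
#'
#' @param design A [simulation_design()].
#' @param params An [observer_params()].
#' @return A `response_table` data frame (see [build_response_table()]).
#' @export
expected_response_table <- function(design, params) {
  man <- design$manifest
  n <- design$n_individuals * design$repeats
  p <- marginal_psychometric_p(man$level, params)
  out <- data.frame(level = man$level, k = as.integer(round(n * p)),
                    n = as.integer(n), p_hat = round(n * p) / n,
                    is_control = man$is_control)
  class(out) <- c("response_table", "data.frame")
  out
}

#' Threshold recovery check on simulated data
#'
#' Runs the full analysis path (trial scoring, responder table, exact tests
#' against control, Bonferroni, threshold rule) on simulated trials and
#' compares the recovered threshold with the identifiable target: the
#' smallest designed level above the generating theta (a discrete level
#' series cannot localise theta more finely).
#'
#' @param sim Output of [simulate_trials()].
#' @param design The [simulation_design()] used.
#' @param params The generating [observer_params()].
#' @param alpha,m Passed to [determine_threshold()].
#' @return List with `threshold_level`, `alpha_min_deg`, `generating_theta`,
#'   `expected_level` and logical `recovered`.
#' @export
recover_threshold <- function(sim, design, params, alpha = 0.05, m = NULL) {
  tab <- build_response_table(sim$trials, sim$manifest, design$experiment)
  th <- determine_threshold(tab, alpha = alpha, m = m,
                            experiment = design$experiment)
  above <- design$levels[design$levels > params$threshold]
  expected <- if (length(above)) min(above) else NA_real_
  list(threshold_level = th$threshold_level,
       alpha_min_deg = th$alpha_min_deg,
       generating_theta = params$threshold,
       expected_level = expected,
       recovered = isTRUE(all.equal(th$threshold_level, expected)) ||
         (is.na(th$threshold_level) && is.na(expected)))
}
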