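#' The five-category withdrawal ethogram
#'
#' Behavioural transition categories in increasing order of severity:
#' stop feeding, partial then full proboscis withdrawal, partial then full
#' eyestalk withdrawal. The order is used for severity comparisons and for
#' placing simulated events along the stimulus expansion.
#'
#' @return Character vector of the five category names, severity-ordered.
#' @export
transition_categories <- function() {
  c("stop_feeding",
    "partial_proboscis_withdrawal",
    "full_proboscis_withdrawal",
    "partial_eyestalk_withdrawal",
    "full_eyestalk_withdrawal")
}

trial_key_cols <- c("individual_id", "experiment", "stimulus_id", "repeat_index")

#' Validate a long-format trials table
#'
#' A trials table has one row per behavioural transition event, with columns
#' `individual_id`, `experiment` ("contrast" or "resolution"), `stimulus_id`,
#' `repeat_index` (1 or 2), `event_category`, `event_time_s` and
#' `reemergence_s`. A trial with no events carries a single sentinel row with
#' `event_category = NA`. Checks the schema, category names, repeat indices,
#' non-decreasing event times within each trial, and that each trial carries
#' a single re-emergence value.
#'
#' @param trials Data frame in the schema above.
#' @return The validated data frame, invisibly.
#' @export
validate_trials <- function(trials) {
  needed <- c(trial_key_cols, "event_category", "event_time_s", "reemergence_s")
  missing <- setdiff(needed, names(trials))
  if (length(missing))
    stop("trials table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !is.na(trials$event_category) &
    !trials$event_category %in% transition_categories()
  if (any(bad))
    stop("unknown event categories: ",
         paste(unique(trials$event_category[bad]), collapse = ", "),
         " (rows ", paste(utils::head(which(bad), 5), collapse = ", "), ")",
         call. = FALSE)
  if (!all(trials$repeat_index %in% c(1L, 2L)))
    stop("repeat_index must be 1 or 2", call. = FALSE)
  key <- interaction(trials[trial_key_cols], drop = TRUE)
  for (k in split(seq_len(nrow(trials)), key)) {
    tt <- trials$event_time_s[k]
    if (is.unsorted(tt[!is.na(tt)]))
      stop("event times decrease within trial (rows ",
           paste(k, collapse = ", "), ")", call. = FALSE)
    if (length(unique(trials$reemergence_s[k])) > 1)
      stop("conflicting reemergence values within a trial (rows ",
           paste(k, collapse = ", "), ")", call. = FALSE)
  }
  invisible(trials)
}

#' Response scoring rule for a single trial
#'
#' A trial counts as a response if and only if it contains at least one
#' transition other than "stop feeding": stop-feeding-only trials are
#' excluded to reduce false positives, since feeding pauses occur
#' spontaneously.
#'
#' @param event_categories Character vector of a trial's event categories
#'   (possibly containing the `NA` sentinel of an eventless trial).
#' @return Logical scalar.
#' @examples
#' is_response(c("stop_feeding"))                               # FALSE
#' is_response(c("stop_feeding", "partial_eyestalk_withdrawal")) # TRUE
#' @export
is_response <- function(event_categories) {
  any(!is.na(event_categories) & event_categories != "stop_feeding")
}

#' One row per trial with its response score
#'
#' Collapses the long event table to unique trials, scoring each with
#' [is_response()] and carrying the re-emergence time through.
#'
#' @param trials Long-format trials table (see [validate_trials()]).
#' @return Data frame with the trial key columns, `response` (logical) and
#'   `reemergence_s`.
#' @export
trial_responses <- function(trials) {
  validate_trials(trials)
  if (nrow(trials) == 0)
    return(data.frame(individual_id = character(0), experiment = character(0),
                      stimulus_id = character(0), repeat_index = integer(0),
                      response = logical(0), reemergence_s = numeric(0)))
  key <- interaction(trials[trial_key_cols], drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  out <- do.call(rbind, lapply(idx, function(k) {
    cbind(trials[k[1], trial_key_cols, drop = FALSE],
          data.frame(response = is_response(trials$event_category[k]),
                     reemergence_s = trials$reemergence_s[k[1]]))
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate trials into a per-level responder table
#'
#' Joins each trial to its stimulus level through the manifest and counts
#' responders k out of n trials at each level (the response unit is the
#' trial, individual x repeat, so 20 individuals tested twice give n = 40;
#' `by = "individual"` instead scores an individual as responding if it
#' responded in at least one repeat). Exactly one control level must be
#' present in the manifest rows used.
#'
#' @param trials Long-format trials table.
#' @param manifest Data frame with columns `stimulus_id`, `experiment`,
#'   `level` (Michelson contrast or check width in degrees; 0 for the
#'   control) and `is_control`.
#' @param experiment `"contrast"` or `"resolution"`.
#' @param by `"trial"` (default) or `"individual"`.
#' @return Data frame of class `response_table` with columns `level`, `k`,
#'   `n`, `p_hat`, `is_control`, sorted by level with the control first.
#' @export
build_response_table <- function(trials, manifest,
                                 experiment = c("contrast", "resolution"),
                                 by = c("trial", "individual")) {
  experiment <- match.arg(experiment)
  by <- match.arg(by)
  tr <- trial_responses(trials)
  tr <- tr[tr$experiment == experiment, , drop = FALSE]
  man <- manifest[manifest$experiment == experiment, , drop = FALSE]
  if (sum(man$is_control) != 1)
    stop("manifest must contain exactly one control stimulus for ",
         experiment, call. = FALSE)
  if (nrow(tr) == 0) {
    out <- data.frame(level = numeric(0), k = integer(0), n = integer(0),
                      p_hat = numeric(0), is_control = logical(0))
    class(out) <- c("response_table", "data.frame")
    return(out)
  }
  if (anyDuplicated(tr[trial_key_cols]))
    stop("duplicate (individual, stimulus, repeat) trials", call. = FALSE)
  m <- match(tr$stimulus_id, man$stimulus_id)
  if (anyNA(m))
    stop("trials reference stimuli absent from the manifest: ",
         paste(unique(tr$stimulus_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  tr$level <- man$level[m]
  tr$is_control <- man$is_control[m]
  if (by == "individual") {
    agg <- stats::aggregate(response ~ individual_id + level + is_control,
                            data = tr, FUN = any)
    tr <- agg
  }
  k <- stats::aggregate(response ~ level + is_control, data = tr, FUN = sum)
  n <- stats::aggregate(response ~ level + is_control, data = tr, FUN = length)
  out <- data.frame(level = k$level, k = as.integer(k$response),
                    n = as.integer(n$response), is_control = k$is_control)
  out$p_hat <- out$k / out$n
  out <- out[order(!out$is_control, out$level),
             c("level", "k", "n", "p_hat", "is_control")]
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

#' Fraction of transitions occurring beyond an angular size
#'
#' Maps each event time to the stimulus angular size through the expansion
#' profile and reports the fraction of events (optionally of one category)
#' falling after the stimulus subtended the given angle - the statistic
#' behind "most transitions occur late in the expansion".
#'
#' @param trials Long-format trials table.
#' @param profile The [expansion_profile()] under which the trials ran.
#' @param angle_threshold_deg Angular size cut in degrees.
#' @param category Optional single category to restrict to.
#' @return Fraction in `[0, 1]`; 0 with a warning when no events exist.
#' @export
transitions_by_angle <- function(trials, profile, angle_threshold_deg,
                                 category = NULL) {
  validate_trials(trials)
  ev <- trials[!is.na(trials$event_category), , drop = FALSE]
  if (!is.null(category))
    ev <- ev[ev$event_category == category, , drop = FALSE]
  if (nrow(ev) == 0) {
    warning("no transition events; fraction defined as 0", call. = FALSE)
    return(0)
  }
  angles <- alpha_at(profile, ev$event_time_s)
  mean(angles > angle_threshold_deg)
}

#' Per-level central tendency of re-emergence times
#'
#' Summarises, for responding trials only (non-responders have no withdrawal
#' to re-emerge from and carry a missing value), the time to resume grazing
#' at each stimulus level. The median is the default aggregator.
#'
#' @param trials Long-format trials table.
#' @param manifest Stimulus manifest (see [build_response_table()]).
#' @param experiment `"contrast"` or `"resolution"`.
#' @param fun Aggregator (default [stats::median]).
#' @return Data frame with `level`, `reemergence_s` and `n_obs`; empty when
#'   no re-emergence times were recorded.
#' @export
reemergence_summary <- function(trials, manifest,
                                experiment = c("contrast", "resolution"),
                                fun = stats::median) {
  experiment <- match.arg(experiment)
  tr <- trial_responses(trials)
  tr <- tr[tr$experiment == experiment & !is.na(tr$reemergence_s), , drop = FALSE]
  man <- manifest[manifest$experiment == experiment, , drop = FALSE]
  if (nrow(tr) == 0)
    return(data.frame(level = numeric(0), reemergence_s = numeric(0),
                      n_obs = integer(0)))
  tr$level <- man$level[match(tr$stimulus_id, man$stimulus_id)]
  agg <- stats::aggregate(reemergence_s ~ level, data = tr, FUN = fun)
  cnt <- stats::aggregate(reemergence_s ~ level, data = tr, FUN = length)
  data.frame(level = agg$level, reemergence_s = agg$reemergence_s,
             n_obs = as.integer(cnt$reemergence_s))
}

#' Read / write trials tables as CSV
#'
#' Plain UTF-8 CSV in the long one-row-per-event schema; the written file
#' round-trips through [read_trials()] unchanged.
#'
#' @param trials Trials data frame.
#' @param path CSV file path.
#' @return `read_trials` returns the validated data frame; `write_trials`
#'   returns the path invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(tr)
  tr
}
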