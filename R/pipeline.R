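#' Stimulus manifest for both behavioural experiments
#'
#' Builds the full stimulus set of the study: the contrast series (nine
#' looms from object bytes 0..230 on a 255 background, 10-s exponential
#' expansion, plus a contrast-0 control) and the resolution series (eight
#' isoluminant checkerboard looms with check widths 0.3-3.2 deg, 5-s linear
#' expansion, plus a control), each labelled with its computed Michelson
#' contrast or check width. A seed yields a reproducible randomised
#' presentation order within each experiment, as stimuli were presented in
#' randomised order in the study.
#'
#' @param display A [display_model()] for contrast labels and the
#'   checkerboard grey calibration.
#' @param seed Optional integer; when given, adds a `presentation_order`
#'   column randomised within experiment.
#' @return Data frame with columns `stimulus_id`, `experiment`, `level`,
#'   `is_control`, `object_byte`, `background_byte`, `grey_byte`,
#'   `check_width_deg`, `contrast_label`, `duration_s`, `shape` (and
#'   `presentation_order` when seeded).
#' @export
stimulus_manifest <- function(display = display_model(), seed = NULL) {
  bytes <- contrast_series_bytes()
  contrast <- data.frame(
    stimulus_id = c("C00", sprintf("C%02d", seq_along(bytes))),
    experiment = "contrast",
    level = c(0, michelson_contrast(bytes, 255, display)),
    is_control = c(TRUE, rep(FALSE, length(bytes))),
    object_byte = c(255L, bytes),
    background_byte = 255L,
    grey_byte = NA_integer_,
    check_width_deg = NA_real_,
    contrast_label = c(0, contrast_label(bytes, 255, display)),
    duration_s = 10,
    shape = "exponential",
    stringsAsFactors = FALSE)
  widths <- check_width_series()
  grey <- isoluminant_grey(0, 255, display)
  resolution <- data.frame(
    stimulus_id = c("R00", sprintf("R%02d", seq_along(widths))),
    experiment = "resolution",
    level = c(0, widths),
    is_control = c(TRUE, rep(FALSE, length(widths))),
    object_byte = grey,
    background_byte = NA_integer_,
    grey_byte = grey,
    check_width_deg = c(NA_real_, widths),
    contrast_label = 0,
    duration_s = 5,
    shape = "linear",
    stringsAsFactors = FALSE)
  man <- rbind(contrast, resolution)
  if (!is.null(seed)) {
    set.seed(seed)
    man$presentation_order <- stats::ave(
      seq_len(nrow(man)), man$experiment,
      FUN = function(i) sample(length(i)))
  }
  rownames(man) <- NULL
  man
}

#' Anatomical estimate table: optics plus retinal census
#'
#' Combines the optical estimates (inter-receptor angle, angular resolution,
#' sensitivity) with the cell-census extrapolations in one tidy table, using
#' the study's reporting conventions (angles 2 d.p. with resolution twice
#' the rounded inter-receptor angle; per-eye totals to the nearest 100
#' cells; densities to 3 significant figures).
#'
#' @param anatomy An [eye_anatomy()].
#' @param census Optional [retina_sample()]; adds per-eye totals and
#'   densities (overall and per class).
#' @return Data frame with columns `quantity`, `value`, `units`.
#' @export
run_optics <- function(anatomy = eye_anatomy(), census = NULL) {
  out <- report_optical_estimates(anatomy)
  if (!is.null(census)) {
    stopifnot(inherits(census, "retina_sample"))
    out <- rbind(out, data.frame(
      quantity = "total_cells_per_eye",
      value = extrapolate_total(census),
      units = "cells"))
    out <- rbind(out, data.frame(
      quantity = "cell_density",
      value = signif(cell_density(census), 3),
      units = "cells/mm^2"))
    if (length(census$counts) > 1 && !is.null(names(census$counts))) {
      for (cls in names(census$counts)) {
        out <- rbind(out, data.frame(
          quantity = paste0("total_", cls, "_per_eye"),
          value = extrapolate_total(census, cls),
          units = "cells"))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Full behavioural analysis of one experiment
#'
#' The complete statistical battery applied to a trials table: responder
#' aggregation with Wilson score intervals per level, Fisher's exact test of
#' each level against the control with Bonferroni correction and the
#' threshold rule, Spearman rank correlations of response probability and of
#' median re-emergence time with stimulus level, and a paired Wilcoxon
#' signed-rank check for a difference between the two repeats (on per-level
#' response proportions).
#'
#' @param trials Long-format trials table.
#' @param manifest Stimulus manifest (see [build_response_table()]).
#' @param experiment `"contrast"` or `"resolution"`.
#' @param alpha Significance level for the threshold rule (default 0.05).
#' @param m Bonferroni family size (default: number of non-control levels).
#' @param confidence Wilson interval confidence (default 0.95).
#' @return List of class `conch_analysis` with elements `response_table`
#'   (with `wilson_lower`/`wilson_upper`), `threshold`
#'   (a `threshold_result`), `spearman_response`, `spearman_reemergence`,
#'   `reemergence`, `repeat_check`, and the call parameters.
#' @export
run_analysis <- function(trials, manifest,
                         experiment = c("contrast", "resolution"),
                         alpha = 0.05, m = NULL, confidence = 0.95) {
  experiment <- match.arg(experiment)
  tab <- build_response_table(trials, manifest, experiment)
  if (nrow(tab) == 0) stop("no trials for experiment ", experiment, call. = FALSE)
  ci <- lapply(seq_len(nrow(tab)),
               function(i) wilson_interval(tab$k[i], tab$n[i], confidence))
  tab$wilson_lower <- vapply(ci, `[[`, numeric(1), "lower")
  tab$wilson_upper <- vapply(ci, `[[`, numeric(1), "upper")

  th <- determine_threshold(tab, alpha = alpha, m = m, experiment = experiment)

  lev <- tab[!tab$is_control, ]
  sp_resp <- spearman_cor(lev$level, lev$p_hat)

  reem <- reemergence_summary(trials, manifest, experiment)
  reem_lev <- reem[reem$level > 0, , drop = FALSE]
  sp_reem <- if (nrow(reem_lev) >= 3)
    spearman_cor(reem_lev$level, reem_lev$reemergence_s) else NULL

  tr <- trial_responses(trials)
  tr <- tr[tr$experiment == experiment, , drop = FALSE]
  man <- manifest[manifest$experiment == experiment, , drop = FALSE]
  tr$level <- man$level[match(tr$stimulus_id, man$stimulus_id)]
  prop_by_rep <- function(r) {
    sub <- tr[tr$repeat_index == r & tr$level > 0, ]
    agg <- stats::aggregate(response ~ level, data = sub, FUN = mean)
    agg$response[order(agg$level)]
  }
  p1 <- prop_by_rep(1); p2 <- prop_by_rep(2)
  repeat_check <- if (length(p1) == length(p2) && length(p1) > 0)
    wilcoxon_signed_rank_paired(p1, p2) else NULL

  structure(list(experiment = experiment, response_table = tab,
                 threshold = th, spearman_response = sp_resp,
                 spearman_reemergence = sp_reem, reemergence = reem,
                 repeat_check = repeat_check,
                 alpha = alpha, m = th$m, confidence = confidence),
            class = "conch_analysis")
}

#' @export
print.conch_analysis <- function(x, ...) {
  cat("== Behavioural analysis:", x$experiment, "experiment ==\n")
  print(x$response_table, digits = 3)
  print(x$threshold)
  cat(sprintf("  Response ~ level: Spearman rho = %.3f, p = %.3g (%s)\n",
              x$spearman_response$rho, x$spearman_response$p_value,
              x$spearman_response$method))
  if (!is.null(x$spearman_reemergence))
    cat(sprintf("  Re-emergence ~ level: rho = %.3f, p = %.3g\n",
                x$spearman_reemergence$rho, x$spearman_reemergence$p_value))
  if (!is.null(x$repeat_check))
    cat(sprintf("  Repeat 1 vs 2 (paired Wilcoxon): V = %g, p = %.3g\n",
                x$repeat_check$V, x$repeat_check$p_value))
  invisible(x)
}

#' Simulate and analyse one experiment end to end
#'
#' Convenience wrapper: builds the study design, simulates a trial table
#' with the experiment's default observer, and runs the full analysis.
#'
#' @param experiment `"contrast"` or `"resolution"`.
#' @param seed Integer seed for the simulation.
#' @param params Observer (defaults per experiment).
#' @param ... Passed to [run_analysis()].
#' @return List with `sim` (trials + manifest), `design`, `params` and
#'   `analysis`.
#' @export
simulate_experiment <- function(experiment = c("contrast", "resolution"),
                                seed = 1L, params = NULL, ...) {
  experiment <- match.arg(experiment)
  design <- simulation_design(experiment)
  if (is.null(params))
    params <- if (experiment == "contrast") contrast_observer()
              else resolution_observer()
  sim <- simulate_trials(design, params, seed = seed)
  analysis <- run_analysis(sim$trials, sim$manifest, experiment, ...)
  list(sim = sim, design = design, params = params, analysis = analysis)
}
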