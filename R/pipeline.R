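#' Compare firing rates of two groups of spike trains
#'
#' Reports group means and SDs and an appropriate two-sample test: each group
#' is checked for normality (Kolmogorov-Smirnov against a normal with the
#' sample moments); when both pass, Welch's approximate t test compares the
#' means, otherwise the Wilcoxon-Mann-Whitney rank test is used.
#'
#' @param group_a,group_b Lists of \code{spike_train}s (size >= 2 each).
#' @param normality_alpha KS significance level below which a group is treated
#'   as non-normal (default 0.05).
#' @return List with per-group \code{mean_hz}, \code{sd_hz}, \code{n}, plus
#'   \code{test} ("welch_t" or "wilcoxon_rank_sum") and \code{p_value}.
#' @export
compare_rates <- function(group_a, group_b, normality_alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 trains")
  ra <- vapply(group_a, firing_rate, numeric(1))
  rb <- vapply(group_b, firing_rate, numeric(1))
  ks_normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value) >
      normality_alpha
  }
  normal <- ks_normal(ra) && ks_normal(rb)
  p <- if (normal) {
    stats::t.test(ra, rb, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(ra, rb)$p.value)
  }
  list(mean_hz = c(a = mean(ra), b = mean(rb)),
       sd_hz = c(a = stats::sd(ra), b = stats::sd(rb)),
       n = c(a = length(ra), b = length(rb)),
       test = if (normal) "welch_t" else "wilcoxon_rank_sum",
       p_value = p)
}

#' Run the full synchrony-inhibition pipeline on one session
#'
#' Sequences connectivity identification, pairwise and event synchrony,
#' inhibition-versus-level quantification, the baseline check, the per-PC
#' comparison, single-PC extrapolation, long-latency analysis, the
#' precision window sweep, and the spatial permutation tests, collecting the
#' results into one report. Group analyses are skipped (with a warning in the
#' report) when fewer than \code{min_presyn} presynaptic PCs are identified;
#' \code{use_ground_truth_group = TRUE} instead analyses the generator's
#' injected presynaptic group, which is the mode used for parameter-recovery
#' studies.
#'
#' @param session A \code{recording_session}, or a \code{\link{synth_config}}
#'   to simulate one.
#' @param alpha Slope-test significance level.
#' @param baseline_window_ms Baseline window for modulation analyses.
#' @param min_events Collapse threshold (events per PC in the high level).
#' @param min_presyn Minimum identified group size for group analyses
#'   (default 4).
#' @param use_ground_truth_group Analyse the injected presynaptic group
#'   instead of the identified one (synthetic sessions only).
#' @param perm_seed Seed for the spatial permutation draws.
#' @param sweep_max_ms Largest half-window of the precision sweep.
#' @return Object of class \code{pipeline_report} (a nested list); see the
#'   individual stage functions for the block contents.
#' @export
run_pipeline <- function(session, alpha = 0.05,
                         baseline_window_ms = c(-55, -5),
                         min_events = 10, min_presyn = 4,
                         use_ground_truth_group = FALSE,
                         perm_seed = 1L, sweep_max_ms = 250) {
  if (inherits(session, "synth_config")) session <- simulate_session(session)
  stopifnot(inherits(session, "recording_session"))
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  report <- list(schema_version = "1.0",
                 n_pcs = length(session$pcs),
                 duration_s = session$duration,
                 dcn_rate_hz = firing_rate(session$dcn))

  conn <- identify_presynaptic(session, alpha = alpha,
                               baseline_window_ms = baseline_window_ms)
  report$connectivity <- list(
    presyn_ids = conn$presyn_ids,
    n_presyn = length(conn$presyn_ids),
    per_pc = lapply(conn$results, function(r) if (is.null(r)) NULL else
      r[c("pre_slope", "post_slope", "t_stat", "p_value",
          "onset_latency_ms", "excitation_at_cs", "broad_trough",
          "is_presynaptic")]))

  group_ids <- conn$presyn_ids
  if (use_ground_truth_group) {
    if (is.null(session$ground_truth))
      stop("use_ground_truth_group requires a synthetic session")
    group_ids <- session$ground_truth$presyn_ids
  }

  if (length(group_ids) >= 2) {
    non_ids <- setdiff(names(session$pcs), group_ids)
    if (length(group_ids) >= 2 && length(non_ids) >= 2)
      report$rates <- compare_rates(session$pcs[group_ids],
                                    session$pcs[non_ids])
  }

  if (length(group_ids) < min_presyn) {
    note(sprintf("only %d presynaptic PCs (< %d): group analyses skipped",
                 length(group_ids), min_presyn))
  } else {
    report$spatial <- list(
      ML = unclass(spatial_permutation_test(group_ids, session$layout, "ML",
                                            seed = perm_seed))[
        c("observed_mean_sep_um", "percentile", "n_perm")],
      RC = unclass(spatial_permutation_test(group_ids, session$layout, "RC",
                                            seed = perm_seed + 1L))[
        c("observed_mean_sep_um", "percentile", "n_perm")])

    sync <- synchrony_vs_separation(session, group_ids)
    report$synchrony <- list(presyn = sync$presyn, other = sync$other,
                             ratio = sync$ratio)

    events <- sync_events(session$pcs[group_ids])
    dist <- withCallingHandlers(
      level_distribution(events),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    report$levels <- list(levels = dist$levels, average_pct = dist$average)

    mod <- inhibition_by_level(session, group_ids, events,
                               baseline_window_ms = baseline_window_ms,
                               min_events = min_events)
    report$modulation <- list(
      levels = mod$levels, percent_change = mod$percent_change,
      duration_ms = mod$duration_ms, n_events = mod$n_events,
      all_cs_percent_change = mod$all_cs$percent_change,
      response_window_ms = c(mod$all_cs$window$start_ms,
                             mod$all_cs$window$end_ms),
      normalized_curve = mod$normalized_curve,
      fit = mod$fit[c("slope", "intercept", "r", "p", "n")],
      high_threshold_k = mod$collapse$threshold_k,
      high_level_value = mod$collapse$merged_value)
    report$baseline_check <- baseline_vs_level(mod)
    report$per_pc <- per_pc_comparison(session, group_ids, events,
                                       baseline_window_ms = baseline_window_ms,
                                       min_events = min_events)
    if (!is.null(mod$fit)) {
      report$single_pc <- list(
        f0.01 = extrapolate_single_pc(mod, 0.01),
        f0.02 = extrapolate_single_pc(mod, 0.02))
    }
    ll <- long_latency_analysis(session, group_ids, events,
                                min_events = min_events)
    report$long_latency <- list(
      pre = if (is.null(ll$pre)) "no long-latency modulation" else ll$pre,
      post = if (is.null(ll$post)) "no long-latency modulation" else ll$post)

    sw <- sweep_sync_windows(session, group_ids,
                             high_level_threshold = mod$collapse$threshold_k,
                             windows_ms = seq(5, sweep_max_ms, by = 5),
                             response_window = mod$all_cs$window,
                             baseline_window_ms = baseline_window_ms)
    single_eff <- mod$percent_change[1]
    report$sweep <- list(
      windows_ms = sw$windows_ms, annulus_counts = sw$annulus_counts,
      cusum = sw$cusum, effect_pct = sw$effect_pct,
      cusum_double_window_ms = sw$cusum_double_window_ms,
      donut = donut_comparison(sw, single_eff))
  }

  report$warnings <- warnings_log
  class(report) <- c("pipeline_report", "list")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d PCs, %.0f s; %d identified presynaptic\n",
              x$n_pcs, x$duration_s, x$connectivity$n_presyn))
  if (!is.null(x$modulation))
    cat(sprintf("  all-CS inhibition %.1f%% in [%.1f, %.1f] ms; fit r=%.3f\n",
                x$modulation$all_cs_percent_change,
                x$modulation$response_window_ms[1],
                x$modulation$response_window_ms[2],
                x$modulation$fit$r))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Identical reports (same config and seed) serialize to byte-identical JSON.
#'
#' @param report A \code{pipeline_report}.
#' @param path Optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null",
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
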