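#' Smallest window at which the cusum doubles the precise-event count
#'
#' Given annulus counts over ascending windows (each the number of high-sync
#' events qualifying at that window but at no smaller one), returns the first
#' window whose cumulative sum reaches twice the count of the first (most
#' precise) window.
#'
#' @param annulus_counts Integer vector of annulus counts.
#' @param windows_ms Ascending window half-widths (ms), same length.
#' @return The window (ms), or \code{NA} if the cusum never doubles.
#' @export
cusum_doubling_window <- function(annulus_counts, windows_ms) {
  stopifnot(length(annulus_counts) == length(windows_ms))
  cs <- cumsum(annulus_counts)
  hit <- which(cs >= 2 * annulus_counts[1])
  if (length(hit) == 0) NA_real_ else windows_ms[hit[1]]
}

#' Window sweep of high-synchrony events and their inhibitory effect
#'
#' Measures how the inhibition of DCN activity depends on the temporal
#' precision of CS synchrony. For each half-window W (ascending 5 ms steps), a
#' reference CS qualifies as a high-synchrony event when at least
#' \code{high_level_threshold} group PCs (including the reference) fire a CS
#' within +/-W of it. Annulus counts are events qualifying at W but at no
#' smaller window; their cumulative sum is the cusum. The inhibitory effect at
#' W is the percent change of the DCN correlogram triggered by all events
#' qualifying at a window of at most W (events pooled across reference PCs).
#' The cusum-doubling window is the first whose cusum reaches twice the +/-5 ms
#' count, and the donut effect uses the events qualifying at the doubling
#' window but not at +/-5 ms.
#'
#' @param session A \code{recording_session}.
#' @param presyn_ids The presynaptic group.
#' @param high_level_threshold Minimum count k of a high-synchrony event
#'   (typically the collapse threshold of
#'   \code{\link{collapse_high_levels}}).
#' @param windows_ms Ascending half-windows in 5 ms steps (default 5..250).
#' @param response_window Response window for the percent change, usually the
#'   all-CS window of \code{\link{inhibition_by_level}}.
#' @param baseline_window_ms Baseline window.
#' @param lag_range_ms Correlogram half-range.
#' @return Object of class \code{window_sweep_result}: list with
#'   \code{windows_ms}, \code{annulus_counts}, \code{cusum},
#'   \code{effect_pct}, \code{cusum_double_window_ms}, \code{donut_effect_pct}
#'   (NA and flagged when the donut set is empty), \code{donut_n},
#'   \code{all_cs_effect_pct}.
#' @export
sweep_sync_windows <- function(session, presyn_ids, high_level_threshold,
                               windows_ms = seq(5, 250, by = 5),
                               response_window,
                               baseline_window_ms = c(-55, -5),
                               lag_range_ms = 110) {
  stopifnot(inherits(session, "recording_session"),
            length(presyn_ids) >= 2, high_level_threshold >= 1)
  if (any(diff(windows_ms) != 5) || windows_ms[1] != 5)
    stop("windows must ascend from 5 in 5 ms steps")
  group <- session$pcs[presyn_ids]
  x <- length(group)
  k_star <- high_level_threshold
  if (k_star > x) stop("high_level_threshold exceeds the group size")

  # per reference CS: the smallest half-window (ms) at which it qualifies,
  # i.e. the (k*-1)-th smallest nearest-CS distance among the other PCs
  ref_times <- numeric(0)
  w_min <- numeric(0)
  for (i in seq_len(x)) {
    ref <- group[[i]]$times
    if (length(ref) == 0) next
    if (k_star == 1) {
      d_need <- rep(0, length(ref))
    } else {
      dmat <- matrix(Inf, nrow = length(ref), ncol = x - 1)
      col <- 0
      for (j in seq_len(x)) {
        if (j == i) next
        col <- col + 1
        dmat[, col] <- nearest_event_distance(ref, group[[j]]$times)
      }
      d_need <- apply(dmat, 1, function(d) sort(d)[k_star - 1]) * 1000
    }
    ref_times <- c(ref_times, ref)
    w_min <- c(w_min, d_need)
  }
  if (length(ref_times) == 0) stop("group has no CSs")
  # snap to the window grid: the first window >= the needed distance
  step <- 5
  w_grid <- ceiling(pmax(w_min, step) / step - 1e-9) * step
  w_grid[w_min > max(windows_ms)] <- Inf

  annulus <- vapply(windows_ms, function(w) sum(w_grid == w), numeric(1))
  cusum <- cumsum(annulus)

  eff <- rep(NA_real_, length(windows_ms))
  for (wi in seq_along(windows_ms)) {
    trig <- ref_times[w_grid <= windows_ms[wi]]
    if (length(trig) == 0) next
    cg <- cs_triggered_histogram(trig, session$dcn, lag_range_ms, 1)
    eff[wi] <- tryCatch(
      percent_change(cg, baseline_window_ms, response_window),
      error = function(e) NA_real_)
  }

  w_double <- cusum_doubling_window(annulus, windows_ms)
  donut_eff <- NA_real_
  donut_n <- 0L
  if (!is.na(w_double)) {
    donut <- ref_times[w_grid > windows_ms[1] & w_grid <= w_double]
    donut_n <- length(donut)
    if (donut_n > 0) {
      cg <- cs_triggered_histogram(donut, session$dcn, lag_range_ms, 1)
      donut_eff <- tryCatch(
        percent_change(cg, baseline_window_ms, response_window),
        error = function(e) NA_real_)
    }
  }
  all_cg <- cs_triggered_histogram(sort(unlist(lapply(group, `[[`, "times"))),
                                   session$dcn, lag_range_ms, 1)
  all_eff <- percent_change(all_cg, baseline_window_ms, response_window)

  structure(list(windows_ms = windows_ms,
                 annulus_counts = annulus,
                 cusum = cusum,
                 effect_pct = eff,
                 cusum_double_window_ms = w_double,
                 donut_effect_pct = donut_eff,
                 donut_n = donut_n,
                 all_cs_effect_pct = all_eff,
                 high_level_threshold = k_star),
            class = "window_sweep_result")
}

#' @export
print.window_sweep_result <- function(x, ...) {
  cat(sprintf("<window_sweep_result> k*=%d; %d windows; +/-5 ms events %d; cusum doubles at %s ms\n",
              x$high_level_threshold, length(x$windows_ms),
              x$annulus_counts[1],
              ifelse(is.na(x$cusum_double_window_ms), "NA",
                     format(x$cusum_double_window_ms))))
  invisible(x)
}

#' Compare the effect of precise, dispersed and single-CS events
#'
#' Labels the inhibitory effect of four event classes: events in which a
#' single PC fired (level 1/x), high-synchrony events in the precise +/-5 ms
#' window, high-synchrony events at the cusum-doubling window, and the donut
#' set (doubling window minus the precise events). Also returns each value
#' with the single-CS effect subtracted, which isolates the contribution of
#' synchrony beyond one cell's own CS.
#'
#' @param sweep A \code{\link{sweep_sync_windows}} result.
#' @param single_pc_effect Percent change of level-1/x events (e.g. the first
#'   point of \code{\link{inhibition_by_level}}).
#' @return List with \code{effects} (named: single_cs, precise_5ms,
#'   cusum_window, donut) and \code{subtracted} (same minus single_cs).
#'   The donut entry is NA with \code{donut_defined = FALSE} when the set is
#'   empty or the cusum never doubles.
#' @export
donut_comparison <- function(sweep, single_pc_effect) {
  stopifnot(inherits(sweep, "window_sweep_result"))
  precise <- sweep$effect_pct[1]
  cus <- if (is.na(sweep$cusum_double_window_ms)) NA_real_ else
    sweep$effect_pct[match(sweep$cusum_double_window_ms, sweep$windows_ms)]
  eff <- c(single_cs = single_pc_effect,
           precise_5ms = precise,
           cusum_window = cus,
           donut = sweep$donut_effect_pct)
  list(effects = eff,
       subtracted = eff - single_pc_effect,
       donut_defined = sweep$donut_n > 0 && !is.na(sweep$donut_effect_pct))
}
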