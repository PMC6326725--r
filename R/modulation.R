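# centered moving average; NA where the window is incomplete
centered_moving_average <- function(x, k) {
  n <- length(x)
  lo <- floor((k - 1) / 2)
  hi <- ceiling((k - 1) / 2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - lo >= 1 && i + hi <= n)
      out[i] <- mean(x[(i - lo):(i + hi)])
  }
  out
}

#' Detect the post-CS response window of a correlogram
#'
#' Baseline is the mean bin rate in \code{baseline_window_ms}. The response
#' start is the center of the first post-0 bin whose centered moving average
#' (3 bins by default) falls below baseline; the end is the center of the
#' first later bin whose moving average returns to or above baseline. With
#' k-bin smoothing the detected end lags the true edge by up to half the
#' smoothing window.
#'
#' @param cg A \code{cs_correlogram} with 1 ms bins.
#' @param baseline_window_ms Baseline window (default c(-55, -5)).
#' @param smoothing_bins Moving-average width (3 by default; 6 helps on
#'   sparse histograms where 3-bin smoothing oscillates).
#' @return Object of class \code{response_window}: list with \code{start_ms},
#'   \code{end_ms}, \code{duration_ms}, \code{baseline_hz},
#'   \code{smoothing_bins}.
#' @export
define_response_window <- function(cg, baseline_window_ms = c(-55, -5),
                                   smoothing_bins = 3) {
  stopifnot(inherits(cg, "cs_correlogram"), smoothing_bins >= 1)
  ctr <- cg$lag_centers_ms
  rate <- cg$rate_hz
  base_idx <- ctr > baseline_window_ms[1] & ctr < baseline_window_ms[2]
  if (!any(base_idx)) stop("correlogram does not cover the baseline window")
  baseline <- mean(rate[base_idx])
  if (baseline <= 0) stop("zero baseline activity")
  ma <- centered_moving_average(rate, smoothing_bins)
  post <- which(ctr > 0 & !is.na(ma))
  below <- post[ma[post] < baseline]
  if (length(below) == 0)
    stop("response start not found: moving average never falls below baseline")
  i_start <- below[1]
  after <- post[post > i_start]
  back <- after[ma[after] >= baseline]
  if (length(back) == 0)
    stop("response end not found: moving average never returns to baseline")
  i_end <- back[1]
  structure(list(start_ms = ctr[i_start], end_ms = ctr[i_end],
                 duration_ms = ctr[i_end] - ctr[i_start],
                 baseline_hz = baseline, smoothing_bins = smoothing_bins),
            class = "response_window")
}

#' @export
print.response_window <- function(x, ...) {
  cat(sprintf("<response_window> %.1f to %.1f ms (duration %.1f ms), baseline %.2f Hz\n",
              x$start_ms, x$end_ms, x$duration_ms, x$baseline_hz))
  invisible(x)
}

#' Percent change of correlogram rate in a response window
#'
#' \code{100 * (mean rate in [start_ms, end_ms) - baseline) / baseline}, the
#' inhibition (negative) or excitation (positive) relative to pre-CS activity.
#'
#' @param cg A \code{cs_correlogram}.
#' @param baseline_window_ms Baseline window.
#' @param response_window A \code{\link{response_window}} or a numeric
#'   \code{c(start_ms, end_ms)}.
#' @return Percent change (scalar).
#' @export
percent_change <- function(cg, baseline_window_ms = c(-55, -5),
                           response_window) {
  stopifnot(inherits(cg, "cs_correlogram"))
  if (inherits(response_window, "response_window"))
    response_window <- c(response_window$start_ms, response_window$end_ms)
  ctr <- cg$lag_centers_ms
  base_idx <- ctr > baseline_window_ms[1] & ctr < baseline_window_ms[2]
  resp_idx <- ctr >= response_window[1] - 1e-9 & ctr < response_window[2]
  if (!any(base_idx) || !any(resp_idx))
    stop("windows outside the correlogram lag range")
  baseline <- mean(cg$rate_hz[base_idx])
  if (baseline <= 0) stop("zero baseline")
  100 * (mean(cg$rate_hz[resp_idx]) - baseline) / baseline
}

#' Collapse sparse high synchrony levels into one weighted level
#'
#' Merges the topmost synchrony levels downward until every PC in the group
#' has at least \code{min_events} events in the merged bin. The merged bin's
#' level value is the weighted average of the merged levels, weighted by the
#' total number of CSs at each level summed across all PCs. PCs whose total
#' event count is below \code{min_events} even after a full merge are flagged
#' and excluded from per-PC analyses.
#'
#' @param events A \code{\link{sync_events}} table.
#' @param min_events Minimum per-PC events in the merged high level.
#' @return List with \code{threshold_k} (lowest count k in the merged bin; an
#'   event is "high synchrony" when its k is at least this), \code{merged_k}
#'   (the merged counts), \code{merged_value} (weighted level value),
#'   \code{value_by_k} (length-x map from count k to analysis level value) and
#'   \code{excluded_pcs}.
#' @export
collapse_high_levels <- function(events, min_events = 10) {
  stopifnot(inherits(events, "data.frame"), nrow(events) > 0, min_events >= 1)
  x <- events$x[1]
  pcs <- unique(events$ref_cell)
  cnt <- matrix(0L, nrow = length(pcs), ncol = x,
                dimnames = list(pcs, NULL))
  for (i in seq_along(pcs))
    cnt[i, ] <- tabulate(events$k[events$ref_cell == pcs[i]], nbins = x)
  excluded <- pcs[rowSums(cnt) < min_events]
  ok <- !(pcs %in% excluded)
  if (!any(ok))
    stop("no PC reaches min_events even after a full merge")
  j <- NA_integer_
  for (cand in x:1) {
    if (all(rowSums(cnt[ok, cand:x, drop = FALSE]) >= min_events)) {
      j <- cand
      break
    }
  }
  n_by_k <- colSums(cnt)  # totals across all PCs
  merged_k <- j:x
  merged_value <- sum((merged_k / x) * n_by_k[merged_k]) /
    sum(n_by_k[merged_k])
  value_by_k <- seq_len(x) / x
  value_by_k[merged_k] <- merged_value
  list(threshold_k = j, merged_k = merged_k, merged_value = merged_value,
       value_by_k = value_by_k, excluded_pcs = excluded,
       counts = cnt, min_events = min_events)
}

# per-PC correlograms for a subset of each PC's CSs; unweighted group average.
# `pick` maps a PC id to the trigger times to use (possibly empty).
group_level_histogram <- function(session, presyn_ids, pick, lag_range_ms) {
  cgs <- list()
  for (id in presyn_ids) {
    tt <- pick(id)
    if (length(tt) == 0) next
    cgs[[id]] <- cs_triggered_histogram(tt, session$dcn,
                                        lag_range_ms = lag_range_ms,
                                        bin_width_ms = 1)
  }
  if (length(cgs) == 0) return(NULL)
  average_correlograms(cgs)
}

#' Post-CS inhibition of DCN activity by synchrony level
#'
#' For each (possibly collapsed) synchrony level, builds a CS-triggered
#' histogram per presynaptic PC from that PC's CSs at that level, averages the
#' per-PC histograms (unweighted), and measures the percent change of DCN
#' activity in the response window relative to baseline. With
#' \code{method = "ALL_CS"} the response window is fixed from the all-CS group
#' histogram; with \code{"PER_LEVEL"} it is re-detected per level (falling
#' back from 3- to 6-bin smoothing, NA when no window can be found). Per-level
#' response durations are returned for the duration-versus-level analysis in
#' either case.
#'
#' @param session A \code{recording_session}.
#' @param presyn_ids The presynaptic PC group (>= 2 cells).
#' @param events Optional precomputed \code{\link{sync_events}} for the group.
#' @param method \code{"ALL_CS"} or \code{"PER_LEVEL"}.
#' @param baseline_window_ms Baseline window (default c(-55, -5); c(-30, -5)
#'   suits sessions with a shorter flat pre-CS stretch).
#' @param lag_range_ms Correlogram half-range (default 110 ms).
#' @param min_events Collapse rule threshold (default 10).
#' @param window_half_ms Synchrony window half-width (default 5 ms).
#' @param smoothing_bins Moving-average width for window detection.
#' @return Object of class \code{modulation_result}: list with \code{levels},
#'   \code{percent_change}, \code{duration_ms}, \code{baseline_hz},
#'   \code{n_events} (all per level), \code{all_cs} (window + percent change
#'   of the all-CS histogram), \code{normalized_curve}, \code{fit}
#'   (slope/intercept/r/p of percent change vs level), \code{collapse},
#'   \code{events}.
#' @export
inhibition_by_level <- function(session, presyn_ids, events = NULL,
                                method = c("ALL_CS", "PER_LEVEL"),
                                baseline_window_ms = c(-55, -5),
                                lag_range_ms = 110, min_events = 10,
                                window_half_ms = 5, smoothing_bins = 3) {
  method <- match.arg(method)
  stopifnot(inherits(session, "recording_session"), length(presyn_ids) >= 2)
  group <- session$pcs[presyn_ids]
  if (is.null(events)) events <- sync_events(group, window_half_ms)
  collapse <- collapse_high_levels(events, min_events)
  x <- events$x[1]
  events$analysis_level <- collapse$value_by_k[events$k]

  all_cg <- group_level_histogram(session, presyn_ids,
                                  function(id) group[[id]]$times,
                                  lag_range_ms)
  all_win <- define_response_window(all_cg, baseline_window_ms, smoothing_bins)
  all_pct <- percent_change(all_cg, baseline_window_ms, all_win)

  level_values <- sort(unique(events$analysis_level))
  n_lv <- length(level_values)
  pct <- dur <- base <- rep(NA_real_, n_lv)
  n_ev <- integer(n_lv)
  for (li in seq_len(n_lv)) {
    lv <- level_values[li]
    sub <- events[abs(events$analysis_level - lv) < 1e-12, , drop = FALSE]
    n_ev[li] <- nrow(sub)
    cg <- group_level_histogram(session, presyn_ids, function(id)
      sub$time_s[sub$ref_cell == id], lag_range_ms)
    if (is.null(cg)) next
    ctr <- cg$lag_centers_ms
    base[li] <- mean(cg$rate_hz[ctr > baseline_window_ms[1] &
                                  ctr < baseline_window_ms[2]])
    win_lv <- tryCatch(
      define_response_window(cg, baseline_window_ms, smoothing_bins),
      error = function(e) tryCatch(
        define_response_window(cg, baseline_window_ms, 6),
        error = function(e2) NULL))
    if (!is.null(win_lv)) dur[li] <- win_lv$duration_ms
    win_use <- if (method == "ALL_CS") all_win else win_lv
    if (!is.null(win_use))
      pct[li] <- tryCatch(
        percent_change(cg, baseline_window_ms, win_use),
        error = function(e) NA_real_)
  }
  keep <- n_ev > 0
  level_values <- level_values[keep]
  pct <- pct[keep]; dur <- dur[keep]; base <- base[keep]; n_ev <- n_ev[keep]

  fit <- NULL
  usable <- !is.na(pct)
  if (sum(usable) >= 3) {
    lmfit <- stats::lm(pct[usable] ~ level_values[usable])
    sm <- summary(lmfit)
    fit <- list(slope = unname(stats::coef(lmfit)[2]),
                intercept = unname(stats::coef(lmfit)[1]),
                r = unname(stats::cor(level_values[usable], pct[usable])),
                p = unname(sm$coefficients[2, 4]),
                n = sum(usable),
                levels = level_values[usable],
                percent_change = pct[usable])
  }
  structure(list(levels = level_values,
                 percent_change = pct,
                 duration_ms = dur,
                 baseline_hz = base,
                 n_events = n_ev,
                 method = method,
                 all_cs = list(window = all_win, percent_change = all_pct,
                               histogram = all_cg),
                 normalized_curve = if (all_pct != 0) pct / all_pct else
                   rep(NA_real_, length(pct)),
                 fit = fit,
                 collapse = collapse,
                 baseline_window_ms = baseline_window_ms,
                 events = events),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> %d levels, all-CS change %.1f%% in [%.1f, %.1f] ms\n",
              length(x$levels), x$all_cs$percent_change,
              x$all_cs$window$start_ms, x$all_cs$window$end_ms))
  print(data.frame(level = round(x$levels, 4), n = x$n_events,
                   percent_change = round(x$percent_change, 2),
                   duration_ms = x$duration_ms))
  invisible(x)
}

#' Baseline activity versus synchrony level
#'
#' Checks that the synchrony dependence of the inhibition is not an artifact
#' of the pre-CS baseline varying with level: per-level baselines (rates are
#' already normalized per trigger CS) are expressed as percent difference from
#' the all-CS baseline and regressed on level.
#'
#' @param mod A \code{\link{modulation_result}}.
#' @return List with \code{levels}, \code{percent_diff}, \code{slope},
#'   \code{p}, \code{n}.
#' @export
baseline_vs_level <- function(mod) {
  stopifnot(inherits(mod, "modulation_result"))
  ok <- !is.na(mod$baseline_hz)
  if (sum(ok) < 3) stop("fewer than 3 levels with a baseline estimate")
  base_all <- mod$all_cs$window$baseline_hz
  pd <- 100 * (mod$baseline_hz[ok] - base_all) / base_all
  lv <- mod$levels[ok]
  fit <- stats::lm(pd ~ lv)
  sm <- summary(fit)
  list(levels = lv, percent_diff = pd,
       slope = unname(stats::coef(fit)[2]),
       p = unname(sm$coefficients[2, 4]),
       n = sum(ok))
}

#' Per-PC comparison of all-CS versus high-synchrony inhibition
#'
#' For each presynaptic PC, the percent change of DCN activity is measured
#' from all of its CSs and from only its high-synchrony CSs (count at or above
#' the collapse threshold), both in the response window fixed from the all-CS
#' group histogram. The pairs are compared with a Wilcoxon signed-rank test.
#'
#' @inheritParams inhibition_by_level
#' @return List with \code{pc_id}, \code{all_pct}, \code{high_pct},
#'   \code{n_stronger_high} (PCs where the high-synchrony inhibition is the
#'   stronger, i.e. more negative), \code{p_value} (signed-rank) and
#'   \code{threshold_k}.
#' @export
per_pc_comparison <- function(session, presyn_ids, events = NULL,
                              baseline_window_ms = c(-55, -5),
                              lag_range_ms = 110, min_events = 10,
                              window_half_ms = 5) {
  stopifnot(length(presyn_ids) >= 2)
  group <- session$pcs[presyn_ids]
  if (is.null(events)) events <- sync_events(group, window_half_ms)
  collapse <- collapse_high_levels(events, min_events)
  use <- setdiff(presyn_ids, collapse$excluded_pcs)
  all_cg <- group_level_histogram(session, presyn_ids,
                                  function(id) group[[id]]$times,
                                  lag_range_ms)
  win <- define_response_window(all_cg, baseline_window_ms)
  all_pct <- high_pct <- rep(NA_real_, length(use))
  for (i in seq_along(use)) {
    id <- use[i]
    cg_all <- cs_triggered_histogram(group[[id]], session$dcn,
                                     lag_range_ms, 1)
    hi_times <- events$time_s[events$ref_cell == id &
                                events$k >= collapse$threshold_k]
    cg_hi <- cs_triggered_histogram(hi_times, session$dcn, lag_range_ms, 1)
    all_pct[i] <- percent_change(cg_all, baseline_window_ms, win)
    high_pct[i] <- percent_change(cg_hi, baseline_window_ms, win)
  }
  p <- if (length(use) >= 2)
    stats::wilcox.test(all_pct, high_pct, paired = TRUE,
                       exact = length(use) < 50)$p.value
  else NA_real_
  list(pc_id = use, all_pct = all_pct, high_pct = high_pct,
       n_stronger_high = sum(high_pct < all_pct),
       p_value = p, threshold_k = collapse$threshold_k,
       excluded_pcs = collapse$excluded_pcs)
}

#' Extrapolate the inhibitory effect of a single PC
#'
#' Uses the fitted percent-change-versus-level regression to predict the
#' effect at the population fraction represented by one PC (0.01-0.02 when
#' 50-100 PCs converge on a DCN cell), with the regression prediction standard
#' error and a two-sided t test of the prediction against zero.
#'
#' @param mod A \code{\link{modulation_result}} with a regression fit over at
#'   least 3 levels.
#' @param fraction Population fraction of a single PC, in (0, 1].
#' @return List with \code{fraction}, \code{predicted_pct}, \code{se},
#'   \code{t}, \code{df}, \code{p_value}.
#' @export
extrapolate_single_pc <- function(mod, fraction) {
  stopifnot(inherits(mod, "modulation_result"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  fit <- mod$fit
  if (is.null(fit) || fit$n < 3)
    stop("regression fit over at least 3 levels required")
  lv <- fit$levels; y <- fit$percent_change
  lmfit <- stats::lm(y ~ lv)
  pr <- stats::predict(lmfit, newdata = data.frame(lv = fraction),
                       se.fit = TRUE)
  tval <- pr$fit / pr$se.fit
  df <- fit$n - 2
  list(fraction = fraction,
       predicted_pct = unname(pr$fit),
       se = unname(pr$se.fit),
       t = unname(tval), df = df,
       p_value = unname(2 * stats::pt(-abs(tval), df)))
}

#' Long-latency modulation of DCN activity around CSs
#'
#' On the all-CS group correlogram over +/-1000 ms, the baseline is the mean
#' over the whole lag range; the correlogram is smoothed with a centered
#' moving average (50 ms wide by default) and the contiguous supra-baseline
#' period containing the smoothed maximum is located in each of the lag ranges
#' (-1000, -50) ms (pre-CS) and (+100, +1000) ms (long-latency post-CS). When
#' no smoothed excursion rises above baseline in a range, that side reports no
#' long-latency modulation. Percent change within the fixed periods is then
#' computed per synchrony level and correlated with level (Pearson).
#'
#' @inheritParams inhibition_by_level
#' @param smooth_ms Smoothing width in ms (default 50).
#' @return List with elements \code{pre} and \code{post}; each is either
#'   \code{NULL} (no modulation) or a list with \code{window_ms},
#'   \code{levels}, \code{percent_change}, \code{r}, \code{p}.
#' @export
long_latency_analysis <- function(session, presyn_ids, events = NULL,
                                  min_events = 10, window_half_ms = 5,
                                  smooth_ms = 50) {
  stopifnot(length(presyn_ids) >= 2)
  group <- session$pcs[presyn_ids]
  if (is.null(events)) events <- sync_events(group, window_half_ms)
  collapse <- collapse_high_levels(events, min_events)
  events$analysis_level <- collapse$value_by_k[events$k]
  L <- 1000
  all_cg <- group_level_histogram(session, presyn_ids,
                                  function(id) group[[id]]$times, L)
  ctr <- all_cg$lag_centers_ms
  baseline <- mean(all_cg$rate_hz)
  k <- round(smooth_ms)
  if (k %% 2 == 0) k <- k + 1
  sm <- centered_moving_average(all_cg$rate_hz, k)

  find_period <- function(range_ms) {
    idx <- which(ctr > range_ms[1] & ctr < range_ms[2] & !is.na(sm))
    if (length(idx) == 0) return(NULL)
    if (max(sm[idx]) <= baseline) return(NULL)
    peak <- idx[which.max(sm[idx])]
    lo <- peak
    while (lo > min(idx) && !is.na(sm[lo - 1]) && sm[lo - 1] > baseline)
      lo <- lo - 1
    hi <- peak
    while (hi < max(idx) && !is.na(sm[hi + 1]) && sm[hi + 1] > baseline)
      hi <- hi + 1
    c(ctr[lo], ctr[hi])
  }
  pre_w <- find_period(c(-1000, -50))
  post_w <- find_period(c(100, 1000))

  level_values <- sort(unique(events$analysis_level))
  lvl_cgs <- lapply(level_values, function(lv) {
    sub <- events[abs(events$analysis_level - lv) < 1e-12, , drop = FALSE]
    group_level_histogram(session, presyn_ids, function(id)
      sub$time_s[sub$ref_cell == id], L)
  })
  per_side <- function(w) {
    if (is.null(w)) return(NULL)
    pc <- vapply(lvl_cgs, function(cg) {
      if (is.null(cg)) return(NA_real_)
      b <- mean(cg$rate_hz)
      inw <- cg$lag_centers_ms >= w[1] & cg$lag_centers_ms <= w[2]
      100 * (mean(cg$rate_hz[inw]) - b) / b
    }, numeric(1))
    ok <- !is.na(pc)
    ct <- if (sum(ok) >= 3)
      stats::cor.test(level_values[ok], pc[ok]) else NULL
    list(window_ms = w, levels = level_values, percent_change = pc,
         r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
         p = if (is.null(ct)) NA_real_ else ct$p.value)
  }
  list(pre = per_side(pre_w), post = per_side(post_w),
       baseline_hz = baseline)
}
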