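#' Two-regression slope test for a monosynaptic PC-DCN connection
#'
#' A connected PC produces a short-latency negative deflection in its
#' CS-triggered correlogram of DCN activity. The test fits least-squares lines
#' to the 1 ms bin rates in a window just before the CS (default -10..0 ms,
#' switched to -15..-5 ms when an excitatory response is visible at the CS)
#' and just after it (3..13 ms), and compares the two slopes with a pooled-
#' variance t statistic on \code{n1 + n2 - 4} degrees of freedom. A PC is
#' called presynaptic when the slope difference is significant, the post-CS
#' slope is the more negative, the onset latency of the inhibition falls in
#' (0, 5] ms, and the trough does not already begin before the CS (broad
#' troughs centered on 0 reflect shared synchrony rather than a direct
#' connection and are excluded).
#'
#' Onset latency is the center of the first post-0 bin whose 3-bin moving
#' average falls below the baseline mean; the broad-trough veto fires when the
#' mean rate in the 5 ms immediately preceding the CS is more than
#' \code{excitation_sd} baseline standard deviations below baseline, in which
#' case the reported onset is the start of the contiguous sub-baseline run
#' (possibly negative). Excitation at the CS is flagged when any bin in
#' [-5, +3) ms exceeds baseline by more than \code{excitation_sd} baseline
#' standard deviations.
#'
#' @param cg A \code{cs_correlogram} with 1 ms bins covering at least
#'   [-60, +100] ms.
#' @param alpha Two-sided significance level (default 0.05).
#' @param baseline_window_ms Baseline window (default c(-55, -5)).
#' @param pre_window_ms,pre_window_excited_ms,post_window_ms Slope windows.
#' @param excitation_sd SD multiple for the excitation / broad-trough checks.
#' @return Object of class \code{connection_result}: list with \code{pc_id},
#'   \code{pre_window_ms}, \code{post_window_ms}, \code{pre_slope},
#'   \code{post_slope} (Hz/ms), \code{t_stat}, \code{df}, \code{p_value},
#'   \code{onset_latency_ms}, \code{excitation_at_cs}, \code{broad_trough},
#'   \code{is_presynaptic}.
#' @export
slope_test <- function(cg, alpha = 0.05,
                       baseline_window_ms = c(-55, -5),
                       pre_window_ms = c(-10, 0),
                       pre_window_excited_ms = c(-15, -5),
                       post_window_ms = c(3, 13),
                       excitation_sd = 2) {
  stopifnot(inherits(cg, "cs_correlogram"))
  if (cg$bin_width_ms != 1)
    stop("slope_test requires 1 ms bins")
  ctr <- cg$lag_centers_ms
  if (min(ctr) > -60 || max(ctr) < 100)
    stop("correlogram must cover at least [-60, +100] ms")
  rate <- cg$rate_hz

  base_idx <- ctr > baseline_window_ms[1] & ctr < baseline_window_ms[2]
  base_rate <- rate[base_idx]
  baseline <- mean(base_rate)
  if (baseline <= 0) stop("zero baseline activity")
  base_sd <- stats::sd(base_rate)

  # excitation visible at the time of the CS?
  exc_idx <- ctr > -5 & ctr < 3
  excitation <- any(rate[exc_idx] > baseline + excitation_sd * base_sd)
  pre_w <- if (excitation) pre_window_excited_ms else pre_window_ms

  fit_window <- function(w) {
    idx <- ctr > w[1] & ctr < w[2]
    if (sum(idx) < 3) stop("fewer than 3 bins in window [",
                           w[1], ", ", w[2], "] ms")
    x <- ctr[idx]; y <- rate[idx]
    fit <- stats::lm.fit(cbind(1, x), y)
    list(slope = fit$coefficients[2], rss = sum(fit$residuals^2),
         sxx = sum((x - mean(x))^2), n = length(x))
  }
  f1 <- fit_window(pre_w)
  f2 <- fit_window(post_window_ms)
  df <- f1$n + f2$n - 4
  sp2 <- (f1$rss + f2$rss) / df
  se <- sqrt(sp2 * (1 / f1$sxx + 1 / f2$sxx))
  d_slope <- f1$slope - f2$slope
  if (se > 0) {
    t_stat <- d_slope / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    # noiseless bins: slopes either coincide or differ exactly
    t_stat <- if (abs(d_slope) < 1e-12) 0 else sign(d_slope) * Inf
    p <- if (abs(d_slope) < 1e-12) 1 else 0
  }

  # onset latency from the 3-bin moving-average baseline crossing
  ma <- centered_moving_average(rate, 3)
  post <- which(ctr > 0 & ma < baseline)
  onset <- if (length(post) > 0) ctr[post[1]] else NA_real_

  # broad trough beginning before the CS
  pre_idx <- ctr > -5 & ctr < 0
  broad <- !excitation &&
    mean(rate[pre_idx]) < baseline -
      excitation_sd * base_sd / sqrt(sum(pre_idx))
  if (broad && length(post) > 0) {
    i <- post[1]
    while (i > 1 && !is.na(ma[i - 1]) && ma[i - 1] < baseline) i <- i - 1
    onset <- ctr[i]
  }

  is_pre <- isTRUE(p < alpha) && f2$slope < f1$slope && !broad &&
    !is.na(onset) && onset > 0 && onset <= 5
  structure(list(pc_id = NA_character_,
                 pre_window_ms = pre_w, post_window_ms = post_window_ms,
                 pre_slope = unname(f1$slope), post_slope = unname(f2$slope),
                 t_stat = unname(t_stat), df = df, p_value = unname(p),
                 onset_latency_ms = onset,
                 excitation_at_cs = excitation,
                 broad_trough = broad,
                 baseline_hz = baseline,
                 is_presynaptic = is_pre),
            class = "connection_result")
}

#' @export
print.connection_result <- function(x, ...) {
  cat(sprintf(
    "<connection_result> %s: pre %.3f, post %.3f Hz/ms; t=%.2f (df=%d, p=%.3g); onset %.1f ms; %spresynaptic\n",
    ifelse(is.na(x$pc_id), "?", x$pc_id), x$pre_slope, x$post_slope,
    x$t_stat, x$df, x$p_value, x$onset_latency_ms,
    if (x$is_presynaptic) "" else "not "))
  invisible(x)
}

#' Identify the presynaptic PC group of a session
#'
#' Applies \code{\link{slope_test}} to the CS-triggered correlogram of every
#' PC against the session's DCN train and partitions the PCs into presynaptic
#' and non-synaptic groups.
#'
#' @param session A \code{recording_session}.
#' @param alpha Significance level for the slope test.
#' @param lag_range_ms Correlogram half-range (must cover the baseline and
#'   slope windows; default 110 ms).
#' @param ... Passed to \code{\link{slope_test}}.
#' @return List with \code{presyn_ids} (character vector) and \code{results}
#'   (named list of \code{connection_result}s). PCs with no CSs are reported
#'   as non-synaptic with a NULL result.
#' @export
identify_presynaptic <- function(session, alpha = 0.05, lag_range_ms = 110,
                                 ...) {
  stopifnot(inherits(session, "recording_session"), length(session$pcs) >= 1)
  results <- vector("list", length(session$pcs))
  names(results) <- names(session$pcs)
  for (id in names(session$pcs)) {
    pc <- session$pcs[[id]]
    if (length(pc$times) == 0) next
    cg <- cs_triggered_histogram(pc, session$dcn, lag_range_ms = lag_range_ms,
                                 bin_width_ms = 1)
    r <- slope_test(cg, alpha = alpha, ...)
    r$pc_id <- id
    results[[id]] <- r
  }
  pre <- names(results)[vapply(results, function(r)
    !is.null(r) && isTRUE(r$is_presynaptic), logical(1))]
  list(presyn_ids = pre, results = results)
}

#' Spatial permutation test of a PC group's restriction along an array axis
#'
#' Compares the observed mean pairwise separation of the group along the
#' mediolateral (ML) or rostrocaudal (RC) axis to the distribution of the same
#' statistic for randomly drawn groups of the same size on the occupied
#' electrode positions (one cell per location, sampled without replacement).
#' The percentile is the fraction of null values below the observed statistic,
#' with ties counted toward the higher (conservative) percentile.
#'
#' @param group Character vector of cell ids (size >= 2).
#' @param layout An \code{\link{array_layout}} covering the group.
#' @param axis \code{"ML"} or \code{"RC"}.
#' @param n_perm Number of random groups (default 1000).
#' @param seed Optional integer seed for the permutation draws.
#' @return Object of class \code{spatial_test_result}: list with
#'   \code{observed_mean_sep_um}, \code{null_distribution},
#'   \code{percentile}, \code{axis}, \code{n_perm}.
#' @export
spatial_permutation_test <- function(group, layout, axis = c("ML", "RC"),
                                     n_perm = 1000, seed = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(layout, "array_layout"), length(group) >= 2)
  if (!all(group %in% layout$cell_id))
    stop("group contains cells absent from layout")
  if (length(group) > nrow(layout))
    stop("group larger than the number of occupied positions")
  pitch <- attr(layout, "pitch_um")
  idx <- if (axis == "ML") layout$ml_index else layout$rc_index
  names(idx) <- layout$cell_id
  mean_sep <- function(v) mean(stats::dist(v)) * pitch
  observed <- mean_sep(idx[group])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  g <- length(group)
  null <- vapply(seq_len(n_perm), function(i)
    mean_sep(idx[sample.int(length(idx), g)]), numeric(1))
  # mid-p convention: the separation statistic is discrete (multiples of
  # pitch / number of pairs), so counting ties fully would bias percentiles
  # upward and break the uniform null calibration; half the tie mass keeps
  # the percentile unbiased
  percentile <- 100 * (sum(null < observed - 1e-12) +
                         0.5 * sum(abs(null - observed) <= 1e-12)) / n_perm
  structure(list(observed_mean_sep_um = observed,
                 null_distribution = null,
                 percentile = percentile,
                 axis = axis, n_perm = n_perm),
            class = "spatial_test_result")
}

#' @export
print.spatial_test_result <- function(x, ...) {
  cat(sprintf("<spatial_test_result> %s: observed %.1f um, percentile %.1f (n_perm=%d)\n",
              x$axis, x$observed_mean_sep_um, x$percentile, x$n_perm))
  invisible(x)
}
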