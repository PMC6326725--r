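#' CS-triggered histogram (crosscorrelogram)
#'
#' Bins the lags of target (DCN) spikes relative to each trigger CS onset.
#' Lag bins are half-open \code{[k, k+1)} ms and labeled by their centers
#' (..., -0.5, +0.5, ... ms for 1 ms bins). Rate is
#' \code{counts / n_triggers / bin_width}, i.e. the conditional firing rate of
#' the target around a trigger. Triggers near the recording edges still
#' contribute (no edge correction).
#'
#' @param triggers A \code{spike_train} or a numeric vector of trigger times
#'   in seconds (e.g. the pooled CSs of a group).
#' @param target A \code{spike_train} (typically the DCN cell).
#' @param lag_range_ms Half-width of the lag range in ms (default 1000;
#'   short-latency views use 100).
#' @param bin_width_ms Bin width in ms (default 1).
#' @return Object of class \code{cs_correlogram}: list with
#'   \code{lag_centers_ms}, \code{counts}, \code{rate_hz}, \code{n_triggers},
#'   \code{bin_width_ms}, \code{lag_range_ms}.
#' @export
cs_triggered_histogram <- function(triggers, target, lag_range_ms = 1000,
                                   bin_width_ms = 1) {
  trig <- if (inherits(triggers, "spike_train")) triggers$times else
    as.numeric(triggers)
  stopifnot(inherits(target, "spike_train"), bin_width_ms > 0,
            lag_range_ms > 0)
  if (length(trig) == 0) stop("zero triggers")
  L <- lag_range_ms / 1000
  bw <- bin_width_ms / 1000
  n_bins <- round(2 * lag_range_ms / bin_width_ms)
  tt <- target$times
  counts <- integer(n_bins)
  if (length(tt) > 0) {
    i1 <- findInterval(trig - L, tt) + 1L       # first spike >= t - L
    i2 <- findInterval(trig + L - 1e-12, tt)    # last spike < t + L
    m <- pmax(i2 - i1 + 1L, 0L)
    if (sum(m) > 0) {
      sel <- sequence(m) - 1L + rep(i1, m)
      lags <- tt[sel] - rep(trig, m)
      bin <- floor((lags + L) / bw) + 1L
      bin <- bin[bin >= 1 & bin <= n_bins]
      counts <- tabulate(bin, nbins = n_bins)
    }
  }
  centers <- seq(-lag_range_ms + bin_width_ms / 2, lag_range_ms,
                 by = bin_width_ms)
  structure(list(lag_centers_ms = centers,
                 counts = counts,
                 rate_hz = counts / (length(trig) * bw),
                 n_triggers = length(trig),
                 bin_width_ms = bin_width_ms,
                 lag_range_ms = lag_range_ms),
            class = "cs_correlogram")
}

#' @export
print.cs_correlogram <- function(x, ...) {
  cat(sprintf("<cs_correlogram> %d triggers, +/-%g ms at %g ms bins, mean rate %.2f Hz\n",
              x$n_triggers, x$lag_range_ms, x$bin_width_ms, mean(x$rate_hz)))
  invisible(x)
}

#' @export
as.data.frame.cs_correlogram <- function(x, ...) {
  data.frame(lag_ms_center = x$lag_centers_ms, count = x$counts,
             rate_hz = x$rate_hz)
}

#' Plot a correlogram
#' @param x A \code{cs_correlogram}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.cs_correlogram <- function(x, ...) {
  plot(x$lag_centers_ms, x$rate_hz, type = "h",
       xlab = "Lag (ms)", ylab = "Rate (Hz)", ...)
  invisible(x)
}

#' Average correlograms across cells
#'
#' Unweighted mean of the per-cell rate profiles (each cell's histogram counts
#' equally regardless of its CS count); counts are summed and
#' \code{n_triggers} accumulated for reference.
#'
#' @param cgs List of \code{cs_correlogram}s on identical bins.
#' @return A \code{cs_correlogram} whose \code{rate_hz} is the unweighted mean.
#' @export
average_correlograms <- function(cgs) {
  stopifnot(length(cgs) >= 1)
  ref <- cgs[[1]]
  for (cg in cgs)
    if (!isTRUE(all.equal(cg$lag_centers_ms, ref$lag_centers_ms)))
      stop("correlograms must share identical bins")
  rate <- Reduce(`+`, lapply(cgs, `[[`, "rate_hz")) / length(cgs)
  structure(list(lag_centers_ms = ref$lag_centers_ms,
                 counts = Reduce(`+`, lapply(cgs, `[[`, "counts")),
                 rate_hz = rate,
                 n_triggers = sum(vapply(cgs, `[[`, numeric(1), "n_triggers")),
                 bin_width_ms = ref$bin_width_ms,
                 lag_range_ms = ref$lag_range_ms),
            class = "cs_correlogram")
}

#' CS-triggered raster
#'
#' One row of target spike lags per trigger. With
#' \code{order = "by_sync_level"} rows are grouped by each trigger's synchrony
#' level (ascending) and chronological within a level, as in synchrony-sorted
#' raster displays.
#'
#' @param triggers \code{spike_train} or numeric trigger times (seconds).
#' @param target Target \code{spike_train}.
#' @param lag_range_ms Half-width of the displayed lag range (ms).
#' @param order \code{"chronological"} or \code{"by_sync_level"}.
#' @param levels Numeric synchrony level per trigger; required for
#'   \code{"by_sync_level"}.
#' @return Object of class \code{cs_raster}: list with \code{trigger_time_s},
#'   \code{level} (or NA), and \code{lags_ms} (list of per-trigger lag
#'   vectors), ordered as requested.
#' @export
cs_triggered_raster <- function(triggers, target, lag_range_ms = 1000,
                                order = c("chronological", "by_sync_level"),
                                levels = NULL) {
  order <- match.arg(order)
  trig <- if (inherits(triggers, "spike_train")) triggers$times else
    as.numeric(triggers)
  if (length(trig) == 0) stop("zero triggers")
  if (order == "by_sync_level") {
    if (is.null(levels) || length(levels) != length(trig) || anyNA(levels))
      stop("order = 'by_sync_level' requires a synchrony level per trigger")
  }
  L <- lag_range_ms / 1000
  tt <- target$times
  rows <- lapply(trig, function(t) {
    i1 <- findInterval(t - L, tt) + 1L
    i2 <- findInterval(t + L - 1e-12, tt)
    if (i2 < i1) numeric(0) else (tt[i1:i2] - t) * 1000
  })
  ord <- if (order == "by_sync_level")
    order(levels, trig) else order(trig)
  structure(list(trigger_time_s = trig[ord],
                 level = if (is.null(levels)) rep(NA_real_, length(trig)) else
                   levels[ord],
                 lags_ms = rows[ord],
                 lag_range_ms = lag_range_ms),
            class = "cs_raster")
}

#' Rebuild a histogram from a raster
#'
#' Flattens the raster's per-trigger lags into binned counts; by construction
#' this equals \code{\link{cs_triggered_histogram}} on the same inputs.
#'
#' @param raster A \code{cs_raster}.
#' @param bin_width_ms Bin width (ms).
#' @return A \code{cs_correlogram}.
#' @export
raster_to_histogram <- function(raster, bin_width_ms = 1) {
  L <- raster$lag_range_ms
  n_bins <- round(2 * L / bin_width_ms)
  lags <- unlist(raster$lags_ms)
  bin <- floor((lags + L) / bin_width_ms) + 1L
  bin <- bin[bin >= 1 & bin <= n_bins]
  counts <- tabulate(bin, nbins = n_bins)
  n_trig <- length(raster$trigger_time_s)
  structure(list(lag_centers_ms = seq(-L + bin_width_ms / 2, L,
                                      by = bin_width_ms),
                 counts = counts,
                 rate_hz = counts / (n_trig * bin_width_ms / 1000),
                 n_triggers = n_trig,
                 bin_width_ms = bin_width_ms,
                 lag_range_ms = L),
            class = "cs_correlogram")
}
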