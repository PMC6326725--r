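#' Zero-lag cross-correlation coefficient C(0)
#'
#' Pairwise synchrony of two spike trains over the whole recording: the trains
#' are binned into zero-one sequences X(i), Y(i) (1 ms bins by default),
#' mean-centered into V(i) = X(i) - mean(X) and W(i) = Y(i) - mean(Y), and
#' \deqn{C(0) = \sum_i V(i) W(i) / \sqrt{\sum_i V(i)^2 \sum_i W(i)^2}.}
#' C(0) ranges between -1 and 1; it is 1 for perfectly synchronized trains and
#' 0 in expectation for independent trains.
#'
#' @param train_a,train_b \code{spike_train}s of equal duration.
#' @param bin_ms Bin width in ms (default 1).
#' @return The coefficient (dimensionless scalar).
#' @examples
#' a <- spike_train("a", "PC_CS", c(0.01, 0.5), 1)
#' c0(a, a)  # 1
#' @export
c0 <- function(train_a, train_b, bin_ms = 1) {
  stopifnot(inherits(train_a, "spike_train"), inherits(train_b, "spike_train"))
  if (abs(train_a$duration - train_b$duration) > 1e-9)
    stop("trains must have equal durations")
  if (length(train_a$times) == 0 || length(train_b$times) == 0)
    stop("C(0) is undefined for an empty train (zero variance)")
  x <- binarize(train_a, bin_ms)
  y <- binarize(train_b, bin_ms)
  v <- x - mean(x)
  w <- y - mean(y)
  den <- sqrt(sum(v^2) * sum(w^2))
  if (den == 0)
    stop("C(0) is undefined: a train has zero variance after binning")
  sum(v * w) / den
}

#' Per-CS synchrony events of a presynaptic group
#'
#' Every CS of every PC in the group serves in turn as the reference of one
#' synchrony event: the event's count \code{k} is the number of group PCs
#' (including the reference) with at least one CS onset within
#' \code{+/- window_half_ms} of the reference onset, and its level is
#' \code{k / x} where \code{x} is the group size. A non-reference PC counts at
#' most once per event however many of its CSs fall in the window, so levels
#' range over \code{1/x, 2/x, ..., 1}.
#'
#' @param group List of \code{spike_train}s (the presynaptic group, size >= 2).
#' @param window_half_ms Half-width of the synchrony window in ms (default 5).
#' @return Object of class \code{sync_events}: data frame with columns
#'   \code{ref_cell}, \code{time_s}, \code{k}, \code{x}, \code{level}.
#' @export
sync_events <- function(group, window_half_ms = 5) {
  stopifnot(is.list(group), length(group) >= 2)
  if (window_half_ms <= 0) stop("window_half_ms must be positive")
  x <- length(group)
  w <- window_half_ms / 1000
  ids <- unname(vapply(group, function(g) g$cell_id, character(1)))
  out <- vector("list", x)
  for (i in seq_len(x)) {
    ref <- group[[i]]$times
    if (length(ref) == 0) next
    k <- rep(1L, length(ref))
    for (j in seq_len(x)) {
      if (j == i) next
      d <- nearest_event_distance(ref, group[[j]]$times)
      k <- k + as.integer(d <= w + 1e-12)
    }
    out[[i]] <- data.frame(ref_cell = ids[i], time_s = ref, k = k, x = x,
                           level = k / x, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(ref_cell = character(0), time_s = numeric(0),
                     k = integer(0), x = integer(0), level = numeric(0))
  class(ev) <- c("sync_events", "data.frame")
  ev
}

#' Distribution of synchrony levels per PC and group average
#'
#' For each reference PC, the percentage of its CSs at each synchrony level
#' \code{k/x}; each per-PC curve sums to 100. The group average is the
#' unweighted mean of the per-PC curves. PCs with zero CSs are excluded with a
#' warning.
#'
#' @param events A \code{\link{sync_events}} table from one group.
#' @return List with \code{levels} (the x/x grid), \code{per_pc} (matrix,
#'   PCs x levels, percent) and \code{average} (vector, percent).
#' @export
level_distribution <- function(events) {
  stopifnot(inherits(events, "data.frame"), nrow(events) > 0)
  x <- events$x[1]
  lv <- seq_len(x) / x
  pcs <- sort(unique(events$ref_cell))
  mat <- matrix(0, nrow = length(pcs), ncol = x,
                dimnames = list(pcs, sprintf("%d/%d", seq_len(x), x)))
  for (i in seq_along(pcs)) {
    ki <- events$k[events$ref_cell == pcs[i]]
    if (length(ki) == 0) next
    mat[i, ] <- 100 * tabulate(ki, nbins = x) / length(ki)
  }
  empty <- rowSums(mat) == 0
  if (any(empty)) {
    warning("PC(s) with zero CSs excluded: ",
            paste(pcs[empty], collapse = ", "))
    mat <- mat[!empty, , drop = FALSE]
  }
  list(levels = lv, per_pc = mat, average = colMeans(mat))
}

#' Pairwise synchrony as a function of mediolateral separation
#'
#' Computes C(0) for every PC pair in the session, splits the pairs into the
#' presynaptic population (both PCs presynaptic) and the remaining pairs, and
#' summarizes each population per ML distance bucket (multiples of the array
#' pitch): mean, median, SEM and n. The ratio curve (presynaptic over other)
#' is defined only at distances where both populations have pairs.
#'
#' @param session A \code{recording_session}.
#' @param presyn_ids Character vector of presynaptic PC ids.
#' @param bin_ms C(0) bin width in ms.
#' @return List with \code{pairs} (per-pair table: cell_a, cell_b, ml_um, c0,
#'   presyn_pair), \code{presyn}, \code{other} (per-distance summaries) and
#'   \code{ratio} (data frame ml_um, ratio).
#' @export
synchrony_vs_separation <- function(session, presyn_ids, bin_ms = 1) {
  stopifnot(inherits(session, "recording_session"))
  pcs <- session$pcs
  ids <- names(pcs)
  lay <- session$layout
  pitch <- attr(lay, "pitch_um")
  ml <- stats::setNames(lay$ml_index, lay$cell_id)
  cmb <- utils::combn(ids, 2)
  n_pair <- ncol(cmb)
  rows <- data.frame(cell_a = cmb[1, ], cell_b = cmb[2, ],
                     ml_um = abs(ml[cmb[1, ]] - ml[cmb[2, ]]) * pitch,
                     c0 = NA_real_,
                     presyn_pair = cmb[1, ] %in% presyn_ids &
                       cmb[2, ] %in% presyn_ids,
                     stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(n_pair)) {
    a <- pcs[[rows$cell_a[i]]]; b <- pcs[[rows$cell_b[i]]]
    rows$c0[i] <- if (length(a$times) > 0 && length(b$times) > 0)
      c0(a, b, bin_ms) else NA_real_
  }
  summarize <- function(df) {
    if (nrow(df) == 0) return(NULL)
    sp <- split(df$c0, df$ml_um)
    data.frame(ml_um = as.numeric(names(sp)),
               mean = vapply(sp, mean, numeric(1), na.rm = TRUE),
               median = vapply(sp, stats::median, numeric(1), na.rm = TRUE),
               sem = vapply(sp, function(v)
                 stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), numeric(1)),
               n = vapply(sp, function(v) sum(!is.na(v)), numeric(1)),
               row.names = NULL)
  }
  pre <- summarize(rows[rows$presyn_pair, , drop = FALSE])
  oth <- summarize(rows[!rows$presyn_pair, , drop = FALSE])
  if (is.null(pre) || is.null(oth))
    stop("both pair populations must be non-empty")
  common <- intersect(pre$ml_um, oth$ml_um)
  ratio <- data.frame(ml_um = common,
                      ratio = pre$mean[match(common, pre$ml_um)] /
                        oth$mean[match(common, oth$ml_um)])
  list(pairs = rows, presyn = pre, other = oth, ratio = ratio)
}
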