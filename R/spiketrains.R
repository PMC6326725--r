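#' Construct a spike train
#'
#' A spike train holds the sorted event onset times of one cell over a known
#' recording duration. For Purkinje cells the events are complex-spike (CS)
#' onsets; for a deep-cerebellar-nuclear (DCN) cell they are ordinary spike
#' times.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param kind Either \code{"PC_CS"} (complex spikes of a Purkinje cell) or
#'   \code{"DCN"} (spikes of a nuclear neuron).
#' @param times Numeric vector of event onset times in seconds, strictly
#'   increasing, all within \code{[0, duration]}.
#' @param duration Recording duration in seconds.
#' @return An object of class \code{spike_train} with fields \code{cell_id},
#'   \code{kind}, \code{times} and \code{duration}.
#' @examples
#' st <- spike_train("pc1", "PC_CS", c(0.5, 1.2, 3.7), duration = 10)
#' @export
spike_train <- function(cell_id, kind = c("PC_CS", "DCN"), times, duration) {
  kind <- match.arg(kind)
  stopifnot(is.character(cell_id), length(cell_id) == 1L)
  times <- unname(as.numeric(times))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a positive scalar (seconds)")
  if (length(times) > 0) {
    if (anyNA(times))
      stop("spike train '", cell_id, "' contains NA times")
    if (any(times < 0) || any(times > duration))
      stop("spike train '", cell_id, "' has times outside [0, duration]")
    if (is.unsorted(times, strictly = TRUE))
      stop("spike train '", cell_id, "' has unsorted or duplicate times")
    if (kind == "DCN" && length(times) > 1L && min(diff(times)) < 0.001)
      stop("DCN train '", cell_id, "' violates the 1 ms minimum inter-spike interval")
  }
  structure(list(cell_id = cell_id, kind = kind, times = times,
                 duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s]: %d events over %.1f s (%.3f Hz)\n",
              x$cell_id, x$kind, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Mean firing rate of a spike train
#' @param train A \code{spike_train}.
#' @return Rate in Hz.
#' @export
firing_rate <- function(train) length(train$times) / train$duration

#' Construct an electrode-array layout
#'
#' Maps each cell to a grid position on the recording array. The mediolateral
#' (ML) separation of a pair is \code{|delta ml_index| * pitch_um}; likewise
#' rostrocaudal (RC) separation uses \code{rc_index}.
#'
#' @param cell_id Character vector of cell ids.
#' @param ml_index Integer mediolateral column index per cell.
#' @param rc_index Integer rostrocaudal row index per cell.
#' @param pitch_um Electrode pitch in micrometers (default 250).
#' @return Object of class \code{array_layout}: a data frame with attribute
#'   \code{pitch_um}.
#' @export
array_layout <- function(cell_id, ml_index, rc_index, pitch_um = 250) {
  stopifnot(length(cell_id) == length(ml_index),
            length(cell_id) == length(rc_index), pitch_um > 0)
  if (anyDuplicated(cell_id))
    stop("duplicate cell_id in layout")
  pos <- paste(ml_index, rc_index, sep = ",")
  if (anyDuplicated(pos))
    stop("layout places more than one cell at a single (ml, rc) position")
  out <- data.frame(cell_id = as.character(cell_id),
                    ml_index = as.integer(ml_index),
                    rc_index = as.integer(rc_index),
                    stringsAsFactors = FALSE)
  attr(out, "pitch_um") <- pitch_um
  class(out) <- c("array_layout", "data.frame")
  out
}

#' Construct a recording session
#'
#' One session bundles the CS trains of all recorded PCs, the spike train of
#' one DCN neuron, and the array layout; synthetic sessions additionally carry
#' ground truth (see \code{\link{simulate_session}}).
#'
#' @param pcs List of \code{spike_train} objects of kind \code{PC_CS}.
#' @param dcn A \code{spike_train} of kind \code{DCN}.
#' @param layout An \code{array_layout} covering every PC.
#' @param ground_truth Optional list of generator ground truth.
#' @return Object of class \code{recording_session}.
#' @export
recording_session <- function(pcs, dcn, layout, ground_truth = NULL) {
  stopifnot(is.list(pcs), length(pcs) >= 1L,
            inherits(dcn, "spike_train"), inherits(layout, "array_layout"))
  for (p in pcs) {
    if (!inherits(p, "spike_train") || p$kind != "PC_CS")
      stop("pcs must be spike_train objects of kind PC_CS")
    if (abs(p$duration - dcn$duration) > 1e-9)
      stop("all trains in a session must share one duration (cell '",
           p$cell_id, "')")
    if (!p$cell_id %in% layout$cell_id)
      stop("PC '", p$cell_id, "' present in spikes but absent from layout")
  }
  if (dcn$kind != "DCN") stop("dcn must be a spike_train of kind DCN")
  names(pcs) <- vapply(pcs, function(p) p$cell_id, character(1))
  structure(list(pcs = pcs, dcn = dcn, layout = layout,
                 duration = dcn$duration, ground_truth = ground_truth),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %d PCs + 1 DCN ('%s'), %.1f s\n",
              length(x$pcs), x$dcn$cell_id, x$duration))
  if (!is.null(x$ground_truth))
    cat(sprintf("  synthetic; %d ground-truth presynaptic PCs\n",
                length(x$ground_truth$presyn_ids)))
  invisible(x)
}

#' Binarize a spike train
#'
#' Turns a spike train into the zero-one sequence X(i) used by the zero-lag
#' correlation: X(i) = 1 iff at least one event onset falls in the i-th bin
#' \code{[(i-1)*bin, i*bin)}. Two events in one bin still yield a single 1.
#' The trailing partial bin is kept, so the length is
#' \code{ceiling(duration / bin)}.
#'
#' @param train A \code{spike_train}.
#' @param bin_ms Bin width in milliseconds (default 1).
#' @return Integer vector of 0/1 of length \code{ceiling(duration/bin)}.
#' @export
binarize <- function(train, bin_ms = 1) {
  stopifnot(inherits(train, "spike_train"), bin_ms > 0)
  bin_s <- bin_ms / 1000
  n <- ceiling(train$duration / bin_s - 1e-9)
  out <- integer(n)
  if (length(train$times) > 0) {
    idx <- pmin(floor(train$times / bin_s) + 1L, n)
    out[idx] <- 1L
  }
  out
}

#' Read a recording session from CSV files
#'
#' The spike table must have columns \code{cell_id,kind,time_s} and the layout
#' table columns \code{cell_id,ml_index,rc_index}. Exactly one cell of kind
#' \code{DCN} is expected.
#'
#' @param spike_table_path Path to the spike CSV.
#' @param layout_path Path to the layout CSV.
#' @param duration Recording duration in seconds; when \code{NULL} the maximum
#'   observed time is rounded up to the next whole second.
#' @param pitch_um Electrode pitch in micrometers.
#' @return A \code{recording_session}.
#' @seealso \code{\link{write_session}}
#' @export
read_session <- function(spike_table_path, layout_path, duration = NULL,
                         pitch_um = 250) {
  sp <- utils::read.csv(spike_table_path, stringsAsFactors = FALSE)
  ly <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "kind", "time_s")
  if (!all(need %in% names(sp)))
    stop("spike table must have columns ", paste(need, collapse = ","))
  if (!all(c("cell_id", "ml_index", "rc_index") %in% names(ly)))
    stop("layout table must have columns cell_id,ml_index,rc_index")
  if (is.null(duration)) duration <- ceiling(max(sp$time_s))
  layout <- array_layout(ly$cell_id, ly$ml_index, ly$rc_index,
                         pitch_um = pitch_um)
  kinds <- tapply(sp$kind, sp$cell_id, function(k) unique(k))
  if (any(lengths(kinds) > 1))
    stop("cell with inconsistent kind in spike table")
  ids <- names(kinds)
  trains <- lapply(ids, function(id) {
    tt <- sort(sp$time_s[sp$cell_id == id])
    if (anyDuplicated(sp$time_s[sp$cell_id == id]))
      stop("duplicate times for cell '", id, "'")
    spike_train(id, kinds[[id]], tt, duration)
  })
  is_dcn <- vapply(trains, function(t) t$kind == "DCN", logical(1))
  if (sum(is_dcn) != 1L)
    stop("expected exactly one DCN cell, found ", sum(is_dcn))
  recording_session(trains[!is_dcn], trains[is_dcn][[1]], layout)
}

#' Write a recording session to CSV files
#'
#' Times are serialized at microsecond precision, so a read/write round trip
#' is lossless at 1 microsecond.
#'
#' @param session A \code{recording_session}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (\code{spikes}, \code{layout}, and
#'   \code{ground_truth} when present).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trains <- c(session$pcs, list(session$dcn))
  sp <- do.call(rbind, lapply(trains, function(t) {
    if (length(t$times) == 0) return(NULL)
    data.frame(cell_id = t$cell_id, kind = t$kind,
               time_s = sprintf("%.6f", t$times), stringsAsFactors = FALSE)
  }))
  spike_path <- file.path(dir, "spikes.csv")
  layout_path <- file.path(dir, "layout.csv")
  utils::write.csv(sp, spike_path, row.names = FALSE, quote = FALSE)
  ly <- as.data.frame(session$layout)
  utils::write.csv(ly, layout_path, row.names = FALSE, quote = FALSE)
  paths <- list(spikes = spike_path, layout = layout_path)
  if (!is.null(session$ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(session$ground_truth, gt_path, auto_unbox = TRUE,
                         digits = NA)
    paths$ground_truth <- gt_path
  }
  invisible(paths)
}

# nearest-event distance from each query time to a sorted reference vector
nearest_event_distance <- function(query, ref) {
  if (length(ref) == 0) return(rep(Inf, length(query)))
  i <- findInterval(query, ref)
  d_lo <- ifelse(i >= 1, query - ref[pmax(i, 1L)], Inf)
  d_hi <- ifelse(i < length(ref), ref[pmin(i + 1L, length(ref))] - query, Inf)
  pmin(d_lo, d_hi)
}
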