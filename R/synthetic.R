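#' Configuration for the synthetic olivocerebellar generator
#'
#' Defaults emulate the recording conditions the analysis expects: ~20 min
#' sessions, a presynaptic group of PCs confined to one mediolateral column of
#' a 250 um grid, complex-spike (CS) synchrony produced by shared network
#' events (the inferior-olive analog) with per-cell recruitment and a few ms
#' of jitter, and a DCN neuron whose rate is multiplicatively inhibited after
#' presynaptic CSs with depth proportional to the event's synchrony fraction.
#'
#' @param seed Integer RNG seed; all randomness flows from it.
#' @param duration_s Session duration in seconds.
#' @param n_pcs Number of recorded PCs.
#' @param n_presyn Number of PCs that are truly presynaptic to the DCN cell.
#' @param grid_ml,grid_rc Array grid shape (columns x rows).
#' @param pitch_um Electrode pitch in micrometers.
#' @param network_event_rate_hz Rate of shared synchrony events (Hz).
#' @param recruit_prob_presyn Per-event recruitment probability of a
#'   presynaptic PC.
#' @param recruit_prob_other Same for non-presynaptic PCs.
#' @param jitter_ms Gaussian SD of the per-cell CS jitter around the event
#'   time, truncated at \code{jitter_trunc_ms}.
#' @param jitter_trunc_ms Truncation bound of the jitter (ms).
#' @param background_cs_rate_hz Independent Poisson CS rate per PC (Hz).
#' @param cs_refractory_ms Per-cell CS refractory period; the later of two
#'   closer events is dropped.
#' @param dcn_base_rate_hz Baseline DCN rate (Hz).
#' @param inhibition List with \code{delay_ms}, \code{duration_ms},
#'   \code{rise_ms}, \code{max_fraction} (depth scale; the multiplicative
#'   factor of an event with synchrony fraction s is
#'   \code{1 - max_fraction * s}). The kernel drops immediately to half its
#'   depth at \code{delay_ms} after the CS onset (the sharp monosynaptic
#'   IPSP, which makes correlograms fall below baseline right at the delay)
#'   and deepens linearly to full depth over \code{rise_ms} (IPSP summation,
#'   which makes them keep declining through the post-CS slope-test window).
#' @param long_latency List with \code{enabled}, \code{gain},
#'   \code{pre_ms = c(-414, -136)} and \code{post_ms = c(146, 456)}: rate is
#'   multiplied by \code{1 + gain * s} inside these windows around each
#'   synchrony event.
#' @param pre_cs_excitation List with \code{enabled}, \code{gain} and
#'   \code{window_ms}: brief rate increase around each presynaptic CS, used
#'   to exercise the excitation-aware branch of the slope test.
#' @return Object of class \code{synth_config} (a named list).
#' @export
synth_config <- function(seed = 1L,
                         duration_s = 1200,
                         n_pcs = 20L,
                         n_presyn = 6L,
                         grid_ml = 4L,
                         grid_rc = 8L,
                         pitch_um = 250,
                         network_event_rate_hz = 0.8,
                         recruit_prob_presyn = 0.35,
                         recruit_prob_other = 0.05,
                         jitter_ms = 2,
                         jitter_trunc_ms = 5,
                         background_cs_rate_hz = 0.2,
                         cs_refractory_ms = 10,
                         dcn_base_rate_hz = 35,
                         inhibition = list(),
                         long_latency = list(),
                         pre_cs_excitation = list()) {
  inh <- utils::modifyList(
    list(delay_ms = 1.5, duration_ms = 67, rise_ms = 10, max_fraction = 1.0),
    inhibition)
  ll <- utils::modifyList(
    list(enabled = FALSE, gain = 0.2, pre_ms = c(-414, -136),
         post_ms = c(146, 456)),
    long_latency)
  exc <- utils::modifyList(
    list(enabled = FALSE, gain = 1.0, window_ms = c(-4, 2)),
    pre_cs_excitation)
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              n_pcs = as.integer(n_pcs), n_presyn = as.integer(n_presyn),
              grid_ml = as.integer(grid_ml), grid_rc = as.integer(grid_rc),
              pitch_um = pitch_um,
              network_event_rate_hz = network_event_rate_hz,
              recruit_prob_presyn = recruit_prob_presyn,
              recruit_prob_other = recruit_prob_other,
              jitter_ms = jitter_ms, jitter_trunc_ms = jitter_trunc_ms,
              background_cs_rate_hz = background_cs_rate_hz,
              cs_refractory_ms = cs_refractory_ms,
              dcn_base_rate_hz = dcn_base_rate_hz,
              inhibition = inh, long_latency = ll,
              pre_cs_excitation = exc)
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    stopifnot(duration_s > 0, n_pcs >= 1, n_presyn >= 0, n_presyn <= n_pcs,
              n_presyn <= grid_rc, n_pcs <= grid_ml * grid_rc,
              recruit_prob_presyn >= 0, recruit_prob_presyn <= 1,
              recruit_prob_other >= 0, recruit_prob_other <= 1,
              network_event_rate_hz >= 0, background_cs_rate_hz >= 0,
              dcn_base_rate_hz >= 0, jitter_ms >= 0,
              inhibition$delay_ms > 0, inhibition$duration_ms > 0,
              inhibition$rise_ms >= 0)
  })
  invisible(cfg)
}

#' Read a generator configuration from JSON or YAML
#'
#' @param path Path to a \code{.json} or \code{.yaml}/\code{.yml} file whose
#'   fields override the \code{\link{synth_config}} defaults.
#' @return A \code{synth_config}.
#' @export
read_synth_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(synth_config, vals)
}

# one truncated-normal draw per element of `n` (vectorized rejection)
rtruncnorm0 <- function(n, sd, bound) {
  if (sd == 0 || bound == 0) return(numeric(n))
  out <- stats::rnorm(n, 0, sd)
  bad <- which(abs(out) > bound)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(out[bad]) > bound]
  }
  out
}

#' Generate the CS population of a synthetic session
#'
#' Shared network events occur as a Poisson process; each PC is independently
#' recruited into each event with its class probability (presynaptic vs
#' other), firing one CS at the event time plus truncated Gaussian jitter.
#' Independent background CSs are superimposed, and a per-cell CS refractory
#' period is enforced by dropping the later event. Ground truth records, per
#' event, the surviving recruited cells and the presynaptic synchrony fraction
#' \code{s = |recruited presyn| / n_presyn}.
#'
#' Uses the current RNG state; \code{\link{simulate_session}} seeds it from
#' \code{cfg$seed}.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List with \code{trains} (list of PC \code{spike_train}s),
#'   \code{layout} (an \code{\link{array_layout}}) and \code{truth}.
#' @export
generate_cs_population <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_pcs
  ids <- sprintf("pc%02d", seq_len(n))
  presyn_ids <- if (cfg$n_presyn > 0) ids[seq_len(cfg$n_presyn)] else character(0)

  # layout: presynaptic PCs occupy one mediolateral column
  presyn_col <- ceiling(cfg$grid_ml / 2)
  ml <- integer(n); rc <- integer(n)
  ml[seq_len(cfg$n_presyn)] <- presyn_col
  rc[seq_len(cfg$n_presyn)] <- seq_len(cfg$n_presyn)
  all_pos <- expand.grid(ml = seq_len(cfg$grid_ml), rc = seq_len(cfg$grid_rc))
  taken <- paste(ml[seq_len(cfg$n_presyn)], rc[seq_len(cfg$n_presyn)])
  free <- all_pos[!paste(all_pos$ml, all_pos$rc) %in% taken, , drop = FALSE]
  n_other <- n - cfg$n_presyn
  if (n_other > 0) {
    pick <- free[sample.int(nrow(free), n_other), , drop = FALSE]
    ml[(cfg$n_presyn + 1):n] <- pick$ml
    rc[(cfg$n_presyn + 1):n] <- pick$rc
  }
  layout <- array_layout(ids, ml, rc, pitch_um = cfg$pitch_um)

  # shared network events
  n_ev <- stats::rpois(1, cfg$network_event_rate_hz * cfg$duration_s)
  ev_times <- sort(stats::runif(n_ev, 0, cfg$duration_s))
  p_recruit <- ifelse(ids %in% presyn_ids,
                      cfg$recruit_prob_presyn, cfg$recruit_prob_other)

  cand <- vector("list", n)   # per PC: data.frame(time, event)
  for (j in seq_len(n)) {
    rec <- if (n_ev > 0) which(stats::runif(n_ev) < p_recruit[j]) else integer(0)
    t_rec <- ev_times[rec] +
      rtruncnorm0(length(rec), cfg$jitter_ms, cfg$jitter_trunc_ms) / 1000
    n_bg <- stats::rpois(1, cfg$background_cs_rate_hz * cfg$duration_s)
    t_bg <- stats::runif(n_bg, 0, cfg$duration_s)
    df <- data.frame(time = c(t_rec, t_bg),
                     event = c(rec, rep(0L, n_bg)))
    df <- df[df$time >= 0 & df$time <= cfg$duration_s, , drop = FALSE]
    df <- df[order(df$time), , drop = FALSE]
    # CS refractory: drop the later of any two events closer than the period
    if (nrow(df) > 1) {
      keep <- rep(TRUE, nrow(df))
      last <- df$time[1]
      for (i in 2:nrow(df)) {
        if (df$time[i] - last < cfg$cs_refractory_ms / 1000) {
          keep[i] <- FALSE
        } else last <- df$time[i]
      }
      df <- df[keep, , drop = FALSE]
    }
    cand[[j]] <- df
  }

  trains <- lapply(seq_len(n), function(j)
    spike_train(ids[j], "PC_CS", cand[[j]]$time, cfg$duration_s))
  names(trains) <- ids

  # per-event surviving recruited sets and presynaptic synchrony fraction
  recruited <- vector("list", n_ev)
  for (e in seq_len(n_ev)) recruited[[e]] <- character(0)
  for (j in seq_len(n)) {
    evs <- cand[[j]]$event
    for (e in evs[evs > 0]) recruited[[e]] <- c(recruited[[e]], ids[j])
  }
  s <- if (cfg$n_presyn > 0 && n_ev > 0)
    vapply(recruited, function(r) sum(r %in% presyn_ids), numeric(1)) /
      cfg$n_presyn
  else numeric(n_ev)

  # per-CS provenance table used by the DCN generator
  cs_tab <- do.call(rbind, lapply(seq_len(n), function(j) {
    df <- cand[[j]]
    if (nrow(df) == 0) return(NULL)
    data.frame(cell_id = ids[j], time = df$time, event = df$event,
               stringsAsFactors = FALSE)
  }))

  mean_rate <- mean(vapply(trains, firing_rate, numeric(1)))
  if (mean_rate > 5)
    warning("mean CS rate ", round(mean_rate, 2),
            " Hz exceeds 5 Hz (biologically implausible)")

  truth <- list(presyn_ids = presyn_ids,
                network_event_times = ev_times,
                recruited = recruited,
                sync_fraction = s,
                cs_table = cs_tab,
                inhibition = cfg$inhibition,
                long_latency = cfg$long_latency)
  list(trains = trains, layout = layout, truth = truth)
}

# multiplicative inhibition kernel: an immediate drop to half depth at onset
# (the sharp monosynaptic IPSP), deepening linearly to full depth over
# rise_ms, holding until duration_ms, then switching off
kernel_multiplier_at <- function(t_rel, factor, rise_s, dur_s) {
  m <- rep(1, length(t_rel))
  inside <- t_rel >= 0 & t_rel < dur_s
  if (rise_s > 0) {
    frac <- 0.5 + 0.5 * pmin(1, t_rel[inside] / rise_s)
  } else frac <- rep(1, sum(inside))
  m[inside] <- 1 - (1 - factor) * frac
  m
}

#' Generate the DCN train of a synthetic session
#'
#' Inhomogeneous Poisson spiking (exact thinning over a piecewise rate) with a
#' 1 ms absolute refractory period. Every surviving presynaptic CS belonging
#' to a synchrony event with fraction \code{s} and \code{k} recruited
#' presynaptic cells contributes a multiplicative kernel whose combined
#' event factor is \code{1 - max_fraction * s} (each CS carries
#' \code{(1 - max_fraction*s)^(1/k)}), starting \code{delay_ms} after the CS
#' onset, ramping to full depth over \code{rise_ms} and lasting
#' \code{duration_ms}. Background presynaptic CSs count as single-cell events
#' (\code{s = 1/n_presyn}). Optional long-latency excitation windows multiply
#' the rate by \code{1 + gain * s} around each synchrony event.
#'
#' @param cs List returned by \code{\link{generate_cs_population}} (or at
#'   least its \code{truth} element).
#' @param cfg A \code{\link{synth_config}}.
#' @return A \code{spike_train} of kind \code{DCN}. The attribute
#'   \code{clipped} counts rate evaluations clipped at zero.
#' @export
generate_dcn_train <- function(cs, cfg) {
  truth <- cs$truth
  x <- max(length(truth$presyn_ids), 1L)
  inh <- cfg$inhibition
  mf <- inh$max_fraction
  delay_s <- inh$delay_ms / 1000
  dur_s <- inh$duration_ms / 1000
  rise_s <- inh$rise_ms / 1000

  # kernel list from presynaptic CSs
  tab <- truth$cs_table
  k_start <- numeric(0); k_factor <- numeric(0)
  if (!is.null(tab) && length(truth$presyn_ids) > 0) {
    tab <- tab[tab$cell_id %in% truth$presyn_ids, , drop = FALSE]
    if (nrow(tab) > 0) {
      n_pre_in_event <- vapply(truth$recruited, function(r)
        sum(r %in% truth$presyn_ids), numeric(1))
      s_cs <- ifelse(tab$event > 0, truth$sync_fraction[tab$event], 1 / x)
      k_cs <- ifelse(tab$event > 0, pmax(n_pre_in_event[tab$event], 1), 1)
      k_start <- tab$time + delay_s
      k_factor <- pmax(0, 1 - mf * s_cs)^(1 / k_cs)
    }
  }

  # long-latency excitation windows around synchrony events
  ll <- cfg$long_latency
  ll_start <- numeric(0); ll_end <- numeric(0); ll_gain <- numeric(0)
  if (isTRUE(ll$enabled) && length(truth$sync_fraction) > 0) {
    act <- which(truth$sync_fraction > 0)
    ev <- truth$network_event_times[act]
    sv <- truth$sync_fraction[act]
    ll_start <- c(ev + ll$pre_ms[1] / 1000, ev + ll$post_ms[1] / 1000)
    ll_end <- c(ev + ll$pre_ms[2] / 1000, ev + ll$post_ms[2] / 1000)
    ll_gain <- rep(1 + ll$gain * sv, 2)
  }

  # brief excitation around each presynaptic CS (optional)
  exc <- cfg$pre_cs_excitation
  ex_start <- numeric(0); ex_end <- numeric(0); ex_gain <- numeric(0)
  if (isTRUE(exc$enabled) && length(k_start) > 0) {
    cs_t <- k_start - delay_s
    ex_start <- cs_t + exc$window_ms[1] / 1000
    ex_end <- cs_t + exc$window_ms[2] / 1000
    ex_gain <- rep(1 + exc$gain, length(cs_t))
  }

  max_gain <- 1
  if (length(ll_gain) > 0) max_gain <- max_gain * max(ll_gain)^2
  if (length(ex_gain) > 0) max_gain <- max_gain * max(ex_gain)^min(3, length(ex_gain))
  r_max <- cfg$dcn_base_rate_hz * max_gain
  if (r_max <= 0)
    return(spike_train("dcn1", "DCN", numeric(0), cfg$duration_s))

  n_cand <- stats::rpois(1, r_max * cfg$duration_s)
  cand <- sort(stats::runif(n_cand, 0, cfg$duration_s))
  mult <- rep(1, n_cand)

  apply_window <- function(start, end, f, shaped) {
    i1 <- findInterval(start, cand) + 1L
    i2 <- findInterval(end, cand)
    if (i2 >= i1) {
      idx <- i1:i2
      if (shaped) {
        mult[idx] <<- mult[idx] *
          kernel_multiplier_at(cand[idx] - start, f, rise_s, end - start)
      } else {
        mult[idx] <<- mult[idx] * f
      }
    }
  }
  for (i in seq_along(k_start))
    apply_window(k_start[i], k_start[i] + dur_s, k_factor[i], shaped = TRUE)
  for (i in seq_along(ll_start))
    apply_window(ll_start[i], ll_end[i], ll_gain[i], shaped = FALSE)
  for (i in seq_along(ex_start))
    apply_window(ex_start[i], ex_end[i], ex_gain[i], shaped = FALSE)

  clipped <- sum(mult < 0)
  if (clipped > 0) {
    warning(clipped, " rate evaluations clipped at zero")
    mult <- pmax(mult, 0)
  }
  rate <- cfg$dcn_base_rate_hz * mult
  keep <- stats::runif(n_cand) < rate / r_max
  times <- cand[keep]

  # 1 ms absolute refractory
  if (length(times) > 1) {
    keep2 <- logical(length(times))
    keep2[1] <- TRUE
    last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last >= 0.001) {
        keep2[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep2]
  }
  out <- spike_train("dcn1", "DCN", times, cfg$duration_s)
  attr(out, "clipped") <- clipped
  out
}

#' Simulate a complete synthetic recording session
#'
#' Seeds the RNG from \code{cfg$seed}, generates the CS population and the
#' DCN train, and bundles them with the layout and ground truth. The same
#' config and seed always reproduce the identical session.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return A \code{recording_session} whose \code{ground_truth} holds the
#'   generator's event times, recruited sets, per-event synchrony fractions
#'   and injected kernel parameters.
#' @examples
#' s <- simulate_session(synth_config(seed = 1, duration_s = 60))
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  cs <- generate_cs_population(cfg)
  dcn <- generate_dcn_train(cs, cfg)
  recording_session(cs$trains, dcn, cs$layout, ground_truth = cs$truth)
}
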