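# shared test fixtures, all generated in code

# homogeneous Poisson spike train; DCN trains get the 1 ms refractory enforced
poisson_train <- function(rate_hz, duration_s, cell_id = "p",
                          kind = "PC_CS") {
  n <- stats::rpois(1, rate_hz * duration_s)
  # runif's ~2^32 granularity can produce exact ties among many draws
  tt <- unique(sort(stats::runif(n, 0, duration_s)))
  if (kind == "DCN" && length(tt) > 1) {
    keep <- c(TRUE, diff(tt) >= 0.001)
    while (!all(keep)) {
      tt <- tt[keep]
      keep <- c(TRUE, diff(tt) >= 0.001)
    }
  }
  spike_train(cell_id, kind, tt, duration_s)
}

# fabricate a correlogram directly from a rate profile (Hz) given as a
# function of bin center (ms); 1 ms bins over +/-lag_range_ms
make_cg <- function(rate_at, lag_range_ms = 110, n_triggers = 1000) {
  centers <- seq(-lag_range_ms + 0.5, lag_range_ms, by = 1)
  rate <- vapply(centers, rate_at, numeric(1))
  structure(list(lag_centers_ms = centers,
                 counts = round(rate * n_triggers / 1000),
                 rate_hz = rate,
                 n_triggers = n_triggers,
                 bin_width_ms = 1,
                 lag_range_ms = lag_range_ms),
            class = "cs_correlogram")
}

# small fast synthetic config for module tests
quick_config <- function(seed = 1, ...) {
  synth_config(seed = seed, duration_s = 200, ...)
}
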