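test_that("slope test recovers hand-constructed slopes and calls the connection", {
  # flat 30 Hz before the CS, falling 30 -> 5 Hz linearly over 3-13 ms,
  # trough until 70 ms, then recovery
  rate_at <- function(t) {
    if (t < 3) 30
    else if (t <= 13) 30 - 2.5 * (t - 3)
    else if (t < 70) 5
    else 30
  }
  r <- slope_test(make_cg(rate_at))
  expect_equal(r$pre_slope, 0, tolerance = 1e-9)
  expect_equal(r$post_slope, -2.5, tolerance = 1e-9)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$onset_latency_ms, 0)
  expect_lte(r$onset_latency_ms, 5)
  expect_true(r$is_presynaptic)
})

test_that("a flat correlogram is not called presynaptic", {
  r <- slope_test(make_cg(function(t) 30))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$is_presynaptic)
})

test_that("a broad trough beginning before the CS is excluded", {
  # inhibition starting at -10 ms: trough centered on 0, not monosynaptic
  rate_at <- function(t) if (t >= -10 && t < 40) 2 else 30
  r <- slope_test(make_cg(rate_at))
  expect_true(r$broad_trough)
  expect_lte(r$onset_latency_ms, 0)
  expect_false(r$is_presynaptic)
})

test_that("visible excitation at the CS switches the pre window", {
  rate_at <- function(t) {
    if (t >= -4 && t < 2) 80          # excitation at the CS
    else if (t >= 3 && t <= 13) 30 - 2.5 * (t - 3)
    else if (t > 13 && t < 70) 5
    else 30
  }
  r <- slope_test(make_cg(rate_at))
  expect_true(r$excitation_at_cs)
  expect_equal(r$pre_window_ms, c(-15, -5))
})

test_that("slope test rejects degenerate inputs", {
  expect_error(slope_test(make_cg(function(t) 30, lag_range_ms = 30)),
               "cover")
  expect_error(slope_test(make_cg(function(t) 0)), "baseline")
})

test_that("identification on a kernel-free session is calibrated near alpha", {
  set.seed(99)
  fp <- c()
  for (seed in 1:3) {
    s <- simulate_session(synth_config(seed = seed, duration_s = 600,
                                       inhibition = list(max_fraction = 0)))
    id <- identify_presynaptic(s)
    fp <- c(fp, vapply(id$results, function(r) r$p_value, numeric(1)))
  }
  # 60 pairs: binomial 95% band around 0.05 is wide but bounded
  expect_lt(mean(fp < 0.05), 0.14)
  # and an empty presynaptic group when none is injected
  s0 <- simulate_session(quick_config(seed = 4, n_presyn = 0))
  expect_length(identify_presynaptic(s0)$presyn_ids, 0)
})

test_that("column-confined groups score below the 5th ML percentile", {
  lay <- array_layout(sprintf("c%02d", 1:20),
                      ml_index = rep(1:4, each = 5),
                      rc_index = rep(1:5, times = 4))
  grp <- sprintf("c%02d", 1:5)  # all in ml column 1
  r <- spatial_permutation_test(grp, lay, "ML", n_perm = 1000, seed = 1)
  expect_equal(r$observed_mean_sep_um, 0)
  expect_lt(r$percentile, 5)
  # the same group spans all rows: RC separation is not extreme
  r_rc <- spatial_permutation_test(grp, lay, "RC", n_perm = 1000, seed = 1)
  expect_gt(r_rc$percentile, 5)
})

test_that("random groups give approximately uniform percentiles", {
  lay <- array_layout(sprintf("c%02d", 1:24),
                      ml_index = rep(1:4, each = 6),
                      rc_index = rep(1:6, times = 4))
  set.seed(7)
  pct <- vapply(1:150, function(i) {
    grp <- sample(lay$cell_id, 6)
    spatial_permutation_test(grp, lay, "ML", n_perm = 200)$percentile
  }, numeric(1))
  # K-S against uniform; discreteness of the statistic leaves ties, so test
  # coarse uniformity of the quartile shares instead of exact continuity
  expect_gt(mean(pct < 50), 0.35)
  expect_lt(mean(pct < 50), 0.65)
  expect_gt(mean(pct < 25), 0.12)
  expect_lt(mean(pct < 25), 0.40)
})

test_that("permutation percentile is invariant to relabeling and translation", {
  lay <- array_layout(sprintf("c%02d", 1:12),
                      ml_index = rep(1:3, each = 4),
                      rc_index = rep(1:4, times = 3))
  grp <- c("c01", "c02", "c05", "c09")
  r1 <- spatial_permutation_test(grp, lay, "ML", n_perm = 500, seed = 3)
  # relabel cells (same geometry)
  lay2 <- lay
  lay2$cell_id <- rev(lay$cell_id)
  grp2 <- rev(lay$cell_id)[match(grp, lay$cell_id)]
  r2 <- spatial_permutation_test(grp2, lay2, "ML", n_perm = 500, seed = 3)
  expect_equal(r1$percentile, r2$percentile)
  # translate the grid
  lay3 <- lay
  lay3$ml_index <- lay$ml_index + 10L
  r3 <- spatial_permutation_test(grp, lay3, "ML", n_perm = 500, seed = 3)
  expect_equal(r1$percentile, r3$percentile)
  expect_error(spatial_permutation_test(lay$cell_id[1], lay, "ML"), "2")
})
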