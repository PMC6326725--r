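test_that("C(0) reproduces hand-computed values", {
  a <- spike_train("a", "PC_CS", c(0.0005, 0.0015), 0.004)  # X = 1,1,0,0
  b <- spike_train("b", "PC_CS", c(0.0005), 0.004)          # Y = 1,0,0,0
  expect_equal(c0(a, b), 0.57735, tolerance = 1e-5)
  # X = 1,0,1,0 vs Y = 1,0,0,1 -> exactly 0
  x <- spike_train("x", "PC_CS", c(0.0005, 0.0025), 0.004)
  y <- spike_train("y", "PC_CS", c(0.0005, 0.0035), 0.004)
  expect_equal(c0(x, y), 0)
  # identical trains -> exactly 1
  expect_equal(c0(a, a), 1)
  expect_error(c0(a, spike_train("e", "PC_CS", numeric(0), 0.004)), "empty")
})

test_that("C(0) equals the brute-force Pearson correlation of the binary vectors", {
  set.seed(10)
  for (i in 1:200) {
    n_bins <- sample(10:100, 1)
    dur <- n_bins / 1000
    ta <- sort(sample(n_bins, sample(2:min(9, n_bins - 1), 1))) / 1000 - 5e-4
    tb <- sort(sample(n_bins, sample(2:min(9, n_bins - 1), 1))) / 1000 - 5e-4
    a <- spike_train("a", "PC_CS", ta, dur)
    b <- spike_train("b", "PC_CS", tb, dur)
    oracle <- suppressWarnings(cor(binarize(a), binarize(b)))
    if (is.na(oracle)) next  # zero variance (all bins occupied)
    expect_equal(c0(a, b), oracle, tolerance = 1e-12)
    expect_equal(c0(a, b), c0(b, a))  # symmetry
    expect_lte(abs(c0(a, b)), 1)
  }
})

test_that("sync events count cells (not spikes) within the +/-5 ms window", {
  dur <- 1
  ref <- spike_train("r", "PC_CS", 0.5, dur)
  mk <- function(id, off_ms) spike_train(id, "PC_CS", 0.5 + off_ms / 1000, dur)
  # x = 4, others at +3, +4.9, +6 ms -> k = 3, level 0.75
  ev <- sync_events(list(ref, mk("b", 3), mk("c", 4.9), mk("d", 6)))
  ev_r <- ev[ev$ref_cell == "r", ]
  expect_equal(ev_r$k, 3L)
  expect_equal(ev_r$level, 0.75)
  # a non-reference PC with two CSs in the window counts once
  twice <- spike_train("t", "PC_CS", c(0.497, 0.503), dur)
  ev2 <- sync_events(list(ref, twice))
  expect_equal(ev2$k[ev2$ref_cell == "r"], 2L)
  # reference alone in a group of 7 -> level 1/7
  g7 <- c(list(ref), lapply(1:6, function(i) mk(paste0("z", i), 100 + i)))
  ev7 <- sync_events(g7)
  expect_equal(ev7$level[ev7$ref_cell == "r"], 1 / 7)
  expect_error(sync_events(list(ref, twice), window_half_ms = 0), "positive")
})

test_that("every CS of the group yields exactly one sync event", {
  s <- simulate_session(quick_config(seed = 12))
  gt <- s$ground_truth$presyn_ids
  ev <- sync_events(s$pcs[gt])
  got <- split(ev$time_s, ev$ref_cell)
  for (id in gt)
    expect_equal(sort(got[[id]]), s$pcs[[id]]$times)
})

test_that("per-PC level distributions sum to 100 percent", {
  s <- simulate_session(quick_config(seed = 13))
  gt <- s$ground_truth$presyn_ids
  ev <- sync_events(s$pcs[gt])
  ld <- level_distribution(ev)
  expect_true(all(abs(rowSums(ld$per_pc) - 100) < 1e-9))
  expect_equal(length(ld$average), length(gt))
  # defaults: low levels are the most common, yet mass exists beyond level 1/x
  expect_equal(unname(which.max(ld$average)), 1L)
  expect_gt(sum(ld$average[-1]), 0)
})

test_that("synchrony vs ML separation separates presyn and other pairs", {
  s <- simulate_session(synth_config(seed = 14, duration_s = 600))
  gt <- s$ground_truth$presyn_ids
  sv <- synchrony_vs_separation(s, gt)
  # ratio above one wherever defined (recruit_prob_other << presyn)
  expect_true(all(sv$ratio$ratio > 1))
  # presyn mean at 0 um exceeds non-syn mean at 0 um
  p0 <- sv$presyn$mean[sv$presyn$ml_um == 0]
  o0 <- sv$other$mean[sv$other$ml_um == 0]
  expect_gt(p0, o0)
  expect_equal(nrow(sv$pairs), choose(length(s$pcs), 2))
})

test_that("equal recruitment for all PCs gives a ratio near one", {
  s <- simulate_session(synth_config(seed = 15, duration_s = 600,
                                     recruit_prob_other = 0.35))
  gt <- s$ground_truth$presyn_ids
  sv <- synchrony_vs_separation(s, gt)
  expect_true(all(abs(sv$ratio$ratio - 1) < 0.35))
})
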