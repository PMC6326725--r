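test_that("same seed reproduces the session bit-identically, different seeds differ", {
  a <- simulate_session(quick_config(seed = 7))
  b <- simulate_session(quick_config(seed = 7))
  expect_identical(a$dcn$times, b$dcn$times)
  for (id in names(a$pcs)) expect_identical(a$pcs[[id]]$times, b$pcs[[id]]$times)
  c <- simulate_session(quick_config(seed = 8))
  expect_false(identical(a$dcn$times, c$dcn$times))
})

test_that("forced full recruitment with zero jitter gives synchrony level 1", {
  s <- simulate_session(quick_config(seed = 2, recruit_prob_presyn = 1,
                                     jitter_ms = 0,
                                     background_cs_rate_hz = 0))
  gt <- s$ground_truth
  # events colliding inside the CS refractory period lose their CSs entirely
  # (fraction 0); every surviving event recruits the full group
  expect_true(all(gt$sync_fraction %in% c(0, 1)))
  expect_gt(mean(gt$sync_fraction == 1), 0.95)
  ev <- sync_events(s$pcs[gt$presyn_ids])
  expect_true(all(ev$level == 1))
})

test_that("per-PC CS rates match the analytic expectation within 3 SE", {
  cfg <- synth_config(seed = 3, duration_s = 1200)
  s <- simulate_session(cfg)
  gt <- s$ground_truth$presyn_ids
  for (grp in list(gt, setdiff(names(s$pcs), gt))) {
    p <- if (identical(grp, gt)) cfg$recruit_prob_presyn else
      cfg$recruit_prob_other
    mu <- cfg$network_event_rate_hz * p + cfg$background_cs_rate_hz
    n_tot <- sum(vapply(s$pcs[grp], function(t) length(t$times), numeric(1)))
    expected <- mu * cfg$duration_s * length(grp)
    # refractory dropping removes a small fraction, so allow the 3 SE band
    # around the (slightly conservative) Poisson expectation
    expect_lt(abs(n_tot - expected), 3 * sqrt(expected) + 0.02 * expected)
  }
})

test_that("presynaptic PCs are column-confined and C(0)-coupled above others", {
  s <- simulate_session(synth_config(seed = 4, duration_s = 600,
                                     recruit_prob_other = 0))
  gt <- s$ground_truth$presyn_ids
  lay <- s$layout
  ml <- lay$ml_index[match(gt, lay$cell_id)]
  expect_equal(length(unique(ml)), 1L)
  # with recruit_prob_other = 0, presyn/other C(0) is ~0, presyn/presyn high
  others <- setdiff(names(s$pcs), gt)
  # at 1 ms bins and +/-2 ms jitter, coupled pairs reach C(0) of a few
  # percent while independent pairs sit at the 1/sqrt(N) noise floor;
  # average over pairs to tame single-pair noise
  cross <- mean(vapply(others, function(o)
    c0(s$pcs[[gt[1]]], s$pcs[[o]]), numeric(1)))
  pairs <- utils::combn(gt, 2)
  within <- mean(vapply(seq_len(ncol(pairs)), function(i)
    c0(s$pcs[[pairs[1, i]]], s$pcs[[pairs[2, i]]]), numeric(1)))
  expect_lt(abs(cross), 0.01)
  expect_gt(within, 0.015)
  expect_gt(within, 5 * abs(cross))
})

test_that("DCN train is homogeneous at base rate without presynaptic kernels", {
  cfg <- quick_config(seed = 5, n_presyn = 0)
  s <- simulate_session(cfg)
  n <- length(s$dcn$times)
  expected <- cfg$dcn_base_rate_hz * cfg$duration_s
  expect_lt(abs(n - expected), 3 * sqrt(expected) + 0.01 * expected)
  expect_gte(min(diff(s$dcn$times)), 0.001)
})

test_that("full-synchrony events with max_fraction 1 silence the DCN cell", {
  s <- simulate_session(synth_config(seed = 6, duration_s = 300,
                                     recruit_prob_presyn = 1, jitter_ms = 0,
                                     background_cs_rate_hz = 0))
  ev <- s$ground_truth$network_event_times
  ev <- ev[s$ground_truth$sync_fraction == 1]
  inh <- s$ground_truth$inhibition
  in_window <- 0
  for (t in ev) {
    lo <- t + inh$delay_ms / 1000
    hi <- t + (inh$delay_ms + inh$duration_ms) / 1000
    in_window <- in_window + sum(s$dcn$times >= lo & s$dcn$times < hi)
  }
  # kernels of later overlapping events are the only way spikes could appear
  expect_equal(in_window, 0)
})

test_that("deeper injected kernels produce monotonically deeper measured inhibition", {
  effects <- vapply(c(0.4, 0.8), function(mf) {
    s <- simulate_session(synth_config(
      seed = 11, duration_s = 600, inhibition = list(max_fraction = mf)))
    gt <- s$ground_truth$presyn_ids
    cgs <- lapply(gt, function(id)
      cs_triggered_histogram(s$pcs[[id]], s$dcn, 110, 1))
    cg <- average_correlograms(cgs)
    w <- define_response_window(cg)
    percent_change(cg, response_window = w)
  }, numeric(1))
  expect_lt(effects[2], effects[1])  # more negative at 0.8
  expect_lt(effects[1], 0)
})

test_that("implausible CS-rate configurations raise a warning", {
  cfg <- synth_config(seed = 1, duration_s = 50,
                      background_cs_rate_hz = 6)
  expect_warning(simulate_session(cfg), "implausible")
})
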