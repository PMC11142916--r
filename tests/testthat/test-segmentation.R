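# Two-level HMM segmentation, shift estimation, sawtooth detection,
# classification and dwell extraction.

test_that("noiseless alternating trace segments exactly", {
  fs <- 100
  lab_true <- rep(rep(c("free", "bound"), 8), each = 3 * fs)
  x <- ifelse(lab_true == "bound", 0.60, 0)
  tr <- angular_trace(x, fs)
  tr$angle_filt_rad <- x   # already noiseless
  seg <- segment_two_level(tr, bin = 1)
  expect_identical(seg$K, 2L)
  expect_equal(unname(seg$levels), c(0, 0.60), tolerance = 1e-9)
  expect_identical(as.character(seg$labels), lab_true)
})

test_that("constant trace plus noise selects K = 1 with no transitions", {
  set.seed(8)
  tr <- angular_trace(rnorm(40000, 0.3, 0.2), 4000)
  tr <- sliding_average(tr, 100)
  seg <- segment_two_level(tr)
  expect_identical(seg$K, 1L)
  expect_identical(nrow(seg$segments), 1L)
  expect_error(estimate_bound_shift(seg), "both free and bound")
})

test_that("segmentation recovers labels and shift on noisy simulation", {
  cfg <- rotor_sim_config(duration = 400, event_prob_per_bound = 0, seed = 31)
  sim <- simulate_rotor_trace(cfg)
  tr <- sliding_average(sim$trace)
  seg <- segment_two_level(tr)
  expect_identical(seg$K, 2L)

  gt <- sim$ground_truth$intervals
  true_lab <- gt$state[findInterval(tr$time_s, gt$start_s)]
  acc <- mean(as.character(seg$labels) == true_lab)
  expect_gte(acc, 0.95)

  sh <- estimate_bound_shift(seg)
  expect_equal(sh$shift_rad, 0.60, tolerance = 3 * sh$se_rad + 0.02)
  expect_lt(sh$se_rad, 0.05)
})

test_that("a synthetic ramp is detected with correct size, rate and post state", {
  # at a gentle noise level every event is quantified within the
  # headline tolerances
  cfg <- single_event_config(size_bp = 5, rate_bp_s = 11.4, noise_sd = 0.15,
                             duration = 60, seed = 13)
  sim <- simulate_rotor_trace(cfg)
  tr <- sliding_average(sim$trace)
  seg <- segment_two_level(tr)
  ev <- detect_sawtooth_events(tr, seg)
  gt <- sim$ground_truth$events
  gt <- gt[!gt$censored, ]
  expect_equal(nrow(ev), nrow(gt))
  for (i in seq_len(nrow(gt))) {
    j <- which.min(abs(ev$start_s - gt$start_s[i]))
    expect_lt(abs(ev$max_loop_size_bp[j] - 5), 0.5)
    expect_lt(abs(ev$rate_bp_s[j] - 11.4) / 11.4, 0.10)
    expect_identical(ev$post_state[j], "bound")
  }

  # at the full measured noise the per-event rate scatter is ~10%
  # (1 sigma), so the tolerances hold for the event means
  cfgN <- single_event_config(size_bp = 5, rate_bp_s = 11.4, noise_sd = 0.49,
                              duration = 120, seed = 13)
  simN <- simulate_rotor_trace(cfgN)
  trN <- sliding_average(simN$trace)
  segN <- segment_two_level(trN)
  evN <- detect_sawtooth_events(trN, segN)
  expect_gte(nrow(evN), 5)
  expect_lt(abs(mean(evN$max_loop_size_bp) - 5), 0.5)
  expect_lt(abs(mean(evN$rate_bp_s) - 11.4) / 11.4, 0.10)
  expect_true(all(abs(evN$rate_bp_s - 11.4) / 11.4 < 0.35))
  expect_true(all(evN$post_state == "bound"))
})

test_that("a ramp ending at the free level reports post_state free", {
  cfg <- single_event_config(size_bp = 8, rate_bp_s = 15, noise_sd = 0.49,
                             duration = 60, seed = 14)
  cfg$p_post_bound <- 0
  sim <- simulate_rotor_trace(cfg)
  tr <- sliding_average(sim$trace)
  seg <- segment_two_level(tr)
  ev <- detect_sawtooth_events(tr, seg)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$post_state == "free"))
})

test_that("event-free noise yields no detections over 600 s", {
  cfg <- rotor_sim_config(duration = 600, event_prob_per_bound = 0, seed = 17)
  sim <- simulate_rotor_trace(cfg)
  tr <- sliding_average(sim$trace)
  seg <- segment_two_level(tr)
  ev <- detect_sawtooth_events(tr, seg)
  expect_identical(nrow(ev), 0L)
})

test_that("detection is invariant to a constant angle offset", {
  cfg <- single_event_config(size_bp = 6, rate_bp_s = 20, noise_sd = 0.49,
                             duration = 40, seed = 19)
  sim <- simulate_rotor_trace(cfg)
  tr1 <- sliding_average(sim$trace)
  tr2 <- tr1
  tr2$angle_rad <- tr2$angle_rad + 3.7
  tr2$angle_filt_rad <- tr2$angle_filt_rad + 3.7
  seg1 <- segment_two_level(tr1)
  seg2 <- segment_two_level(tr2)
  expect_equal(unname(diff(seg2$levels)), unname(diff(seg1$levels)),
               tolerance = 1e-6)
  ev1 <- detect_sawtooth_events(tr1, seg1)
  ev2 <- detect_sawtooth_events(tr2, seg2)
  expect_equal(ev2$start_s, ev1$start_s, tolerance = 1e-6)
  expect_equal(ev2$max_loop_size_bp, ev1$max_loop_size_bp, tolerance = 1e-6)
  expect_equal(ev2$rate_bp_s, ev1$rate_bp_s, tolerance = 1e-6)
})

test_that("time rescaling rescales durations and rates, not sizes", {
  cfg <- single_event_config(size_bp = 6, rate_bp_s = 15, noise_sd = 0.3,
                             duration = 40, seed = 23)
  sim <- simulate_rotor_trace(cfg)
  tr1 <- sliding_average(sim$trace)
  seg1 <- segment_two_level(tr1)
  ev1 <- detect_sawtooth_events(tr1, seg1)
  # same samples played at half speed
  tr2 <- angular_trace(sim$trace$angle_rad, 2000)
  tr2 <- sliding_average(tr2)
  seg2 <- segment_two_level(tr2)
  ev2 <- detect_sawtooth_events(tr2, seg2)
  expect_equal(nrow(ev2), nrow(ev1))
  if (nrow(ev1) && nrow(ev2)) {
    expect_equal(ev2$duration_s, 2 * ev1$duration_s, tolerance = 0.05)
    expect_equal(ev2$rate_bp_s, ev1$rate_bp_s / 2, tolerance = 0.05)
    expect_equal(ev2$max_loop_size_bp, ev1$max_loop_size_bp, tolerance = 0.05)
  }
})

test_that("classification follows the cluster-gap and size rules", {
  ev <- tibble::tibble(
    start_s = c(10, 11.5, 40, 80, 120),
    end_s = c(10.5, 12, 40.4, 80.3, 120.5),
    duration_s = c(0.5, 0.5, 0.4, 0.3, 0.5),
    max_loop_size_bp = c(5, 6, 25, 5, 4),
    rate_bp_s = c(11, 12, 33, 11, 12),
    pre_state = "bound",
    post_state = c("bound", "free", "bound", "bound", "free")
  )
  cl <- classify_events(ev)
  # events 0.5 s apart share a cluster (closed interval at the gap)
  expect_identical(cl$cluster_id[1], cl$cluster_id[2])
  expect_identical(cl$class[1:2], c("clustered", "clustered"))
  expect_identical(cl$class[3], "long_range")   # isolated 25 bp
  expect_identical(cl$class[4], "single_to_bound")
  expect_identical(cl$class[5], "single_to_free")

  # a gap of exactly cluster_gap still clusters
  ev2 <- ev[1:2, ]
  ev2$start_s <- c(0, 2.5); ev2$end_s <- c(0.5, 3.0)
  cl2 <- classify_events(ev2, cluster_gap = 2)
  expect_identical(cl2$cluster_id[1], cl2$cluster_id[2])
})

test_that("dwell extraction censors boundaries and tags post-event dwells", {
  fs <- 100
  lab <- c(rep("bound", 250), rep("free", 300), rep("bound", 200),
           rep("free", 250))
  x <- ifelse(lab == "bound", 0.6, 0)
  tr <- angular_trace(x, fs)
  tr$angle_filt_rad <- x
  seg <- segment_two_level(tr, bin = 1)
  dw <- extract_dwells(seg)
  expect_identical(nrow(dw), 4L)
  expect_true(dw$censored[1])          # trace starts mid-bound
  expect_true(dw$censored[4])
  expect_false(any(dw$censored[2:3]))
  expect_equal(dw$duration_s[2], 3, tolerance = 1e-9)
  expect_false(any(dw$state == "translocating"))

  # with events: relabelled dwells + post-event tag
  cfg <- single_event_config(size_bp = 6, rate_bp_s = 12, noise_sd = 0.49,
                             duration = 60, seed = 37)
  sim <- simulate_rotor_trace(cfg)
  trs <- sliding_average(sim$trace)
  segs <- segment_two_level(trs)
  evs <- detect_sawtooth_events(trs, segs)
  dws <- extract_dwells(segs, evs)
  expect_true(any(dws$state == "translocating"))
  expect_true(any(dws$post_event))
  # uncensored bound dwells match ground truth within one filter window
  gt <- sim$ground_truth$dwells
  gt_b <- gt[gt$state == "bound" & !gt$censored & gt$duration_s > 0.5, ]
  got_b <- dws[dws$state == "bound" & !dws$censored & dws$duration_s > 0.5, ]
  expect_equal(nrow(got_b), nrow(gt_b))
  m <- vapply(gt_b$start_s, function(s) which.min(abs(got_b$start_s - s)),
              integer(1))
  expect_true(all(abs(got_b$start_s[m] - gt_b$start_s) < 0.2))
  expect_true(all(abs(got_b$duration_s[m] - gt_b$duration_s) < 0.4))
})

test_that("resolvable pre-bound fraction matches the configured probability", {
  cfg <- rotor_sim_config(duration = 1500, seed = 41)
  sim <- simulate_rotor_trace(cfg)
  tr <- sliding_average(sim$trace)
  seg <- segment_two_level(tr)
  ev <- classify_events(detect_sawtooth_events(tr, seg))
  expect_gte(nrow(ev), 60)
  p_hat <- mean(ev$pre_state == "bound")
  se <- sqrt(0.95 * 0.05 / nrow(ev))
  expect_lt(abs(p_hat - 0.95), 3 * se + 0.02)
})
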