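# Synthetic-data generator: rotor traces with ground truth, dwell
# sampling, kinetic traces, spot frames, kymographs.

test_that("noiseless two-level trace is piecewise constant at the shift", {
  cfg <- rotor_sim_config(duration = 30, noise_sd = 0,
                          event_prob_per_bound = 0, seed = 3)
  sim <- simulate_rotor_trace(cfg)
  lv <- sort(unique(round(sim$trace$angle_rad, 12)))
  expect_length(lv, 2L)
  expect_equal(diff(lv), 0.60, tolerance = 1e-12)
})

test_that("a forced single event has the exact size/rate geometry", {
  cfg <- single_event_config(size_bp = 5, rate_bp_s = 11.4)
  sim <- simulate_rotor_trace(cfg)
  ev <- sim$ground_truth$events
  ev <- ev[!ev$censored, ]
  expect_gt(nrow(ev), 0)
  # duration = size / rate; ramp height = size * 2 pi / pitch
  expect_equal(ev$duration_s, rep(5 / 11.4, nrow(ev)), tolerance = 1e-3)
  i0 <- round(ev$start_s[1] * cfg$sample_rate) + 1L
  i1 <- floor(ev$end_s[1] * cfg$sample_rate)
  ramp <- sim$trace$angle_rad[i0:i1]
  expect_equal(max(ramp) - 0.60, 5 * 2 * pi / 10.5,
               tolerance = 5 * 11.4 / 4000)  # within one sample of ramp
})

test_that("ground truth tiles the trace and is seed-deterministic", {
  cfg <- rotor_sim_config(duration = 120, seed = 99)
  sim1 <- simulate_rotor_trace(cfg)
  sim2 <- simulate_rotor_trace(cfg)
  expect_identical(sim1$trace$angle_rad, sim2$trace$angle_rad)
  expect_identical(sim1$ground_truth$events, sim2$ground_truth$events)

  iv <- sim1$ground_truth$intervals
  expect_equal(iv$start_s[1], 0)
  expect_equal(iv$end_s[nrow(iv)], 120)
  expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)], tolerance = 1e-12)

  ev <- sim1$ground_truth$events
  ev <- ev[!ev$censored, ]
  expect_true(all(abs(ev$duration_s * ev$rate_bp_s - ev$size_bp) <=
                    max(ev$rate_bp_s) / cfg$sample_rate + 1e-9))
})

test_that("OU noise has the configured stationary sd and correlation time", {
  cfg <- rotor_sim_config(duration = 200, shift_bound = 0, noise_sd = 0.49,
                          noise_tau = 0.010, event_prob_per_bound = 0,
                          seed = 5)
  sim <- simulate_rotor_trace(cfg)
  x <- sim$trace$angle_rad
  expect_equal(sd(x), 0.49, tolerance = 0.05 * 0.49)
  lag <- round(0.010 * cfg$sample_rate)
  rho <- cor(x[-(1:lag)], x[1:(length(x) - lag)])
  expect_equal(rho, exp(-1), tolerance = 0.04)

  # the 100-point filtered fluctuation matches the measured 0.35 rad
  f <- sliding_average(x, 100)
  expect_equal(sd(f[101:(length(f) - 100)]), 0.35, tolerance = 0.04)
})

test_that("simulate_dwells draws the requested exponential mixture", {
  d1 <- simulate_dwells(list(c(1, 4)), 1e5, seed = 1)
  expect_equal(mean(d1$dwell_s), 4, tolerance = 3 * 4 / sqrt(1e5))

  d2 <- simulate_dwells(list(c(0.41, 1.6), c(0.59, 35.4)), 1e5, seed = 2)
  mix_mean <- 0.41 * 1.6 + 0.59 * 35.4
  expect_equal(mix_mean, 21.5, tolerance = 0.05)
  se <- sd(d2$dwell_s) / sqrt(1e5)
  expect_equal(mean(d2$dwell_s), mix_mean, tolerance = 3 * se)
  # component fractions within binomial 3 se of the weights
  p1 <- mean(d2$component == 1L)
  expect_lt(abs(p1 - 0.41), 3 * sqrt(0.41 * 0.59 / 1e5))

  expect_error(simulate_dwells(list(c(0.5, 1), c(0.6, 2)), 10), "sum to 1")
  expect_error(simulate_dwells(list(c(1, -2)), 10), "> 0")
  expect_error(simulate_dwells(list(c(1, 2)), 0), "n")
})

test_that("mixture config invariants are enforced", {
  expect_error(rotor_sim_config(duration = 1e-4), "samples")
  expect_error(rotor_sim_config(size_modes = list(c(0.7, 5, 1),
                                                  c(0.2, 20, 2))), "sum to 1")
  expect_error(rotor_sim_config(rate_modes = list(c(0.5, -3, 1),
                                                  c(0.5, 30, 2))), "> 0")
})

test_that("spot frames obey the rotor geometry", {
  # noiseless frame: maximum at (cx + R, cy) for theta = 0
  fr <- simulate_spot_frames(0, center = c(21, 21), radius = 8,
                             photons = Inf)[[1]]
  idx <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(21, 29))  # (row = cy, col = cx + R)

  # periodicity
  two <- simulate_spot_frames(c(1.1, 1.1 + 2 * pi), center = c(21, 21),
                              radius = 8, photons = Inf)
  expect_equal(two[[1]], two[[2]], tolerance = 1e-12)

  expect_error(simulate_spot_frames(0, center = c(5, 5), radius = 8,
                                    photons = 1e3), "outside")

  # localization error shrinks ~ 1/sqrt(photons)
  centroid_err <- function(photons, seed) {
    fr <- simulate_spot_frames(pi / 4, center = c(21, 21), radius = 8,
                               photons = photons, seed = seed)[[1]]
    f <- fit_spot(fr)
    sqrt((f$x - (21 + 8 * cos(pi / 4)))^2 + (f$y - (21 + 8 * sin(pi / 4)))^2)
  }
  e_lo <- vapply(1:25, function(s) centroid_err(500, s), numeric(1))
  e_hi <- vapply(1:25, function(s) centroid_err(5e4, s), numeric(1))
  ratio <- mean(e_lo) / mean(e_hi)
  expect_gt(ratio, 10 / 2.5)   # expected sqrt(100) = 10, allow MC slack
  expect_lt(ratio, 10 * 2.5)
})

test_that("kinetic traces follow their closed-form models", {
  flat <- simulate_kinetic_trace(kinetic_sim_config("exp1", amplitudes = 0,
                                                    rates = 1, offset = 0.7))
  expect_true(all(abs(flat$signal - 0.7) < 1e-12))

  e1 <- simulate_kinetic_trace(kinetic_sim_config("exp1", amplitudes = 2,
                                                  rates = 1, offset = 0.5,
                                                  duration = 5,
                                                  sample_rate = 100))
  i <- which.min(abs(e1$time_s - 1))
  expect_equal(e1$signal[i], 0.5 + 2 * (1 - exp(-1)), tolerance = 1e-9)

  # biphasic: initial slope = E/1000 * (Af kf + As ks) per second
  bi <- simulate_kinetic_trace(kinetic_sim_config(
    "phosphate_biphasic", rates = c(2, 0.2), enzyme_nM = 75,
    cal_slope = 1, cal_intercept = 0, duration = 20, sample_rate = 1000))
  slope0 <- (bi$signal[2] - bi$signal[1]) / (bi$time_s[2] - bi$time_s[1])
  expect_equal(slope0, 0.075 * (15 * 2 + 10 * 0.2), tolerance = 0.01)

  expect_error(kinetic_sim_config("sigmoid"), "unknown model")
  expect_error(kinetic_sim_config("phosphate_biphasic", rates = c(0.1, 1)),
               "fast rate")

  # anisotropy pair reproduces its relaxing r(t)
  an <- simulate_kinetic_trace(kinetic_sim_config(
    "anisotropy_pair", amplitudes = c(0.25, 0.05), rates = 3,
    duration = 3, sample_rate = 200))
  r <- anisotropy(an$ivv, an$ivh)
  expect_equal(r[1], 0.25, tolerance = 1e-9)
  expect_equal(r[length(r)], 0.05, tolerance = 1e-3)
})

test_that("kymograph simulation is static until initiation, then diffuses", {
  cfg0 <- kymo_sim_config(n_lines = 200, localization_sd = 0,
                          diffusion_coefficient = 0,
                          initiation_time_mean = 0.5, seed = 2)
  sim0 <- simulate_kymograph(cfg0)
  expect_true(all(sim0$track$true_pos_px == 51))
  expect_true(all(sim0$track$render_pos_px == 51))

  cfgD <- kymo_sim_config(n_lines = 400, diffusion_coefficient = 3,
                          initiation_time_mean = 1, seed = 4)
  simD <- simulate_kymograph(cfgD)
  pre <- simD$track$time_s < simD$initiation_time_s
  expect_true(all(simD$track$true_pos_px[pre] == 51))
  expect_gt(sd(simD$track$true_pos_px[!pre]), 0)

  # initiation-time mean recovered over many seeds (Monte Carlo)
  ts <- vapply(1:200, function(s) {
    simulate_kymograph(kymo_sim_config(n_lines = 2, initiation_time_mean = 5,
                                       seed = s))$initiation_time_s
  }, numeric(1))
  expect_equal(mean(ts), 5, tolerance = 3 * 5 / sqrt(200))
})
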