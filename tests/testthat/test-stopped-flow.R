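# Anisotropy, exponential phase fits, phosphate calibration, ATPase
# bursts, cumulative steps and half-times.

test_that("anisotropy follows the polarized-channel formula", {
  expect_equal(anisotropy(2, 2), 0)
  expect_equal(anisotropy(2, 1), 0.25)          # IVV/IVH = 2
  expect_equal(anisotropy(2, 1, G = 2), 0)      # G rescales IVH
  expect_error(anisotropy(c(1, 2), c(1, 0)), "sample: 2")
  df <- tibble::tibble(time_s = 0:2, ivv = c(2, 2, 2), ivh = c(1, 2, 4))
  out <- anisotropy(df)
  expect_equal(out$r, c(0.25, 0, -0.2))
})

test_that("anisotropy is bounded and scale-invariant (property)", {
  set.seed(2)
  for (i in 1:50) {
    ivv <- rexp(20) + 1e-3
    ivh <- rexp(20) + 1e-3
    r <- anisotropy(ivv, ivh)
    expect_true(all(r >= -0.5 & r < 1))
    c_ <- runif(1, 0.1, 10)
    expect_equal(anisotropy(c_ * ivv, c_ * ivh), r, tolerance = 1e-12)
  }
})

test_that("single-exponential rate recovery within 5%", {
  cfg <- kinetic_sim_config("exp1", amplitudes = 1, rates = 0.7,
                            offset = 0.2, noise_sd = 0.01, duration = 10,
                            sample_rate = 200, seed = 4)
  tr <- simulate_kinetic_trace(cfg)
  f <- fit_exponential_phases(tr, n_phases = 1)
  expect_identical(f$direction, "rise")
  expect_lt(abs(f$rates[1] - 0.7) / 0.7, 0.05)
  expect_lt(abs(f$amplitudes[1] - 1), 0.05)
})

test_that("double-exponential with 10x separated rates recovers both", {
  cfg <- kinetic_sim_config("exp2", amplitudes = c(1, 0.6),
                            rates = c(5, 0.5), offset = 0.1,
                            noise_sd = 0.005, duration = 12,
                            sample_rate = 400, seed = 6)
  tr <- simulate_kinetic_trace(cfg)
  f <- fit_exponential_phases(tr, n_phases = 2)
  expect_lt(abs(f$rates[1] - 5) / 5, 0.10)
  expect_lt(abs(f$rates[2] - 0.5) / 0.5, 0.10)
  expect_gt(f$rates[1], f$rates[2])   # fastest first
})

test_that("falling traces are auto-detected and fitted", {
  cfg <- kinetic_sim_config("exp1", amplitudes = 2, rates = 1.2,
                            offset = 0.5, direction = "fall",
                            noise_sd = 0.01, duration = 8,
                            sample_rate = 250, seed = 8)
  tr <- simulate_kinetic_trace(cfg)
  f <- fit_exponential_phases(tr, n_phases = 1)
  expect_identical(f$direction, "fall")
  expect_lt(abs(f$rates[1] - 1.2) / 1.2, 0.05)
})

test_that("constant trace is flagged as no kinetics", {
  tr <- tibble::tibble(time_s = seq(0, 5, by = 0.01),
                       signal = 1.3 + rnorm(501, 0, 1e-4))
  f <- fit_exponential_phases(tr, n_phases = 1)
  expect_true(f$no_kinetics)
  expect_equal(f$amplitudes, 0)
})

test_that("parametric single-exponential recovery across seeds (property)", {
  for (s in 1:6) {
    cfg <- kinetic_sim_config("exp1", amplitudes = 1.5, rates = 2,
                              offset = 0, noise_sd = 0.02, duration = 5,
                              sample_rate = 200, seed = s)
    f <- fit_exponential_phases(simulate_kinetic_trace(cfg), n_phases = 1)
    expect_lt(abs(f$rates[1] - 2), 4 * f$se_rates[1] + 0.05)
    expect_lt(abs(f$amplitudes[1] - 1.5), 4 * f$se_amplitudes[1] + 0.02)
  }
})

test_that("phosphate calibration finds the line and its linear range", {
  exact <- tibble::tibble(pi_uM = 0:6, fluorescence = 1 + 2 * (0:6))
  cal <- pbp_calibrate(exact)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 1, tolerance = 1e-12)

  # saturation above 6 uM (reporter concentration): range ends there
  sat <- tibble::tibble(
    pi_uM = 0:8,
    fluorescence = c(1 + 2 * (0:6), 13.4, 13.6) + c(rnorm(7, 0, 0.01), 0, 0)
  )
  cal2 <- pbp_calibrate(sat)
  expect_lte(cal2$linear_range_uM, 6)
  expect_equal(cal2$slope, 2, tolerance = 0.05)

  expect_error(pbp_calibrate(exact[1:2, ]), "3 usable")
  expect_error(pbp_calibrate(tibble::tibble(pi_uM = 0:5, fluorescence = 2)),
               "variation")
})

test_that("biphasic burst amplitudes are recovered per enzyme", {
  cfg <- kinetic_sim_config("phosphate_biphasic", rates = c(2, 0.2),
                            enzyme_nM = 75, burst_atps_per_enzyme = 15,
                            slow_atps_per_enzyme = 10, cal_slope = 0.8,
                            cal_intercept = 0.05, noise_sd = 0.002,
                            duration = 30, sample_rate = 100, seed = 10)
  tr <- simulate_kinetic_trace(cfg)
  cal <- list(slope = 0.8, intercept = 0.05)
  b <- atpase_burst(tr, enzyme_nM = 75, calibration = cal)
  expect_lt(abs(b$fast_atps_per_enzyme - 15) / 15, 0.10)
  expect_lt(abs(b$slow_atps_per_enzyme - 10) / 10, 0.15)
  expect_gt(b$k_fast, b$k_slow)
  expect_true(b$slow_constrained)

  # calibration-slope rescaling cancels when trace and fit share it
  cfg2 <- cfg; cfg2$cal_slope <- 1.6
  tr2 <- simulate_kinetic_trace(cfg2)
  b2 <- atpase_burst(tr2, enzyme_nM = 75,
                     calibration = list(slope = 1.6, intercept = 0.05))
  expect_equal(b2$fast_atps_per_enzyme, b$fast_atps_per_enzyme,
               tolerance = 0.05)

  # single-phase, zero-noise trace: slow amplitude collapses to ~0
  cfg1 <- kinetic_sim_config("phosphate_biphasic", rates = c(2, 0.002),
                             enzyme_nM = 75, burst_atps_per_enzyme = 15,
                             slow_atps_per_enzyme = 1e-9, cal_slope = 0.8,
                             cal_intercept = 0.05, noise_sd = 0,
                             duration = 10, sample_rate = 100)
  b1 <- atpase_burst(simulate_kinetic_trace(cfg1), 75,
                     list(slope = 0.8, intercept = 0.05))
  expect_lt(b1$slow_atps_per_enzyme *
              (1 - exp(-b1$k_slow * 10)), 0.5)

  # trace shorter than 1/k_slow: slow phase flagged poorly constrained
  cfgS <- kinetic_sim_config("phosphate_biphasic", rates = c(5, 0.05),
                             enzyme_nM = 75, noise_sd = 0.001,
                             duration = 3, sample_rate = 200, seed = 12)
  bS <- atpase_burst(simulate_kinetic_trace(cfgS), 75,
                     list(slope = 0.8, intercept = 0.05))
  expect_false(bS$slow_constrained)

  expect_error(atpase_burst(tr, enzyme_nM = 0, calibration = cal), "enzyme")
})

test_that("cumulative step times are i / rate", {
  s1 <- cumulative_steps(11.4, 25)
  expect_equal(s1$time_s[1], 1 / 11.4, tolerance = 1e-12)
  s2 <- cumulative_steps(32.7, 21)
  expect_equal(s2$time_s[21], 21 / 32.7, tolerance = 1e-12)
  expect_equal(round(s2$time_s[21], 3), 0.642)
  expect_identical(nrow(cumulative_steps(10, 0)), 0L)
})

test_that("half_time interpolates the midpoint crossing", {
  t <- seq(0, 10, by = 0.001)
  tr <- tibble::tibble(time_s = t, signal = exp(-log(2) * t))
  expect_equal(half_time(tr, smooth_frac = 0), 1.0, tolerance = 0.01)

  set.seed(14)
  trn <- tibble::tibble(time_s = t,
                        signal = exp(-log(2) * t) + rnorm(length(t), 0, 0.01))
  expect_equal(half_time(trn), 1.0, tolerance = 0.05)

  # rising biphasic: the monotone trend still has a unique midpoint
  rise <- tibble::tibble(time_s = t,
                         signal = 1 - 0.7 * exp(-2 * t) - 0.3 * exp(-0.3 * t))
  ht <- half_time(rise, smooth_frac = 0)
  mid_val <- 1 - 0.7 * exp(-2 * ht) - 0.3 * exp(-0.3 * ht)
  lvl0 <- 0; lvl1 <- 1 - 0.7 * exp(-20) - 0.3 * exp(-3)
  expect_equal(mid_val, (lvl0 + lvl1) / 2, tolerance = 0.02)

  expect_error(half_time(tibble::tibble(time_s = t, signal = rep(1, length(t)))),
               "no transition")
})
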