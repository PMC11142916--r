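# Angle extraction: spot fitting, circle fit, polar angles, filtering,
# and the twist unit conversion.

test_that("rad/bp conversion matches the helical pitch and roundtrips", {
  expect_equal(rad_to_bp(0.598), 1.00, tolerance = 0.005)
  expect_equal(rad_to_bp(2 * pi), 10.5, tolerance = 1e-12)
  expect_identical(rad_to_bp(0), 0)
  # conversion constant is computed from the pitch, not hard-coded
  expect_equal(bp_to_rad(1), 2 * pi / 10.5, tolerance = 1e-15)
  for (pitch in c(10.5, 10, 12.3)) {
    x <- c(-3.2, 0, 0.598, 7 * pi)
    expect_equal(bp_to_rad(rad_to_bp(x, pitch), pitch), x, tolerance = 1e-12)
  }
  expect_error(rad_to_bp(1, pitch = 0), "pitch")
})

test_that("fit_spot recovers sub-pixel centres and flags flat frames", {
  # integer-centre self-consistency
  f1 <- fit_spot(render_gauss_frame(20, 20))
  expect_true(f1$converged)
  expect_lt(abs(f1$x - 20), 1e-4)
  expect_lt(abs(f1$y - 20), 1e-4)

  # sub-pixel centre, oracle = dense brute-force grid search
  fr <- render_gauss_frame(20.3, 19.6)
  grid <- expand.grid(x = seq(19.8, 20.8, by = 0.002),
                      y = seq(19.1, 20.1, by = 0.002))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((fr - render_gauss_frame(grid$x[i], grid$y[i]))^2)
  }, numeric(1))
  oracle <- unlist(grid[which.min(sse), ])
  expect_equal(oracle[["x"]], 20.3, tolerance = 0.003)
  expect_equal(oracle[["y"]], 19.6, tolerance = 0.003)
  f2 <- fit_spot(fr)
  expect_lt(abs(f2$x - oracle[["x"]]), 1e-3)
  expect_lt(abs(f2$y - oracle[["y"]]), 1e-3)

  expect_error(fit_spot(matrix(5, 41, 41)), "no spot")
})

test_that("circle fit is exact on circles and errors on collinear points", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  pts <- data.frame(x = 5 + 2 * cos(th), y = 5 + 2 * sin(th))
  fit <- estimate_rotation_center(pts)
  expect_equal(unname(fit$center), c(5, 5), tolerance = 1e-9)
  expect_equal(fit$radius, 2, tolerance = 1e-9)

  # three points: the algebraic fit must return their circumcircle
  p1 <- c(1, 0); p2 <- c(3.5, 2); p3 <- c(0.5, 4)
  cc <- circumcenter(p1, p2, p3)
  fit3 <- estimate_rotation_center(data.frame(x = c(p1[1], p2[1], p3[1]),
                                              y = c(p1[2], p2[2], p3[2])))
  expect_equal(unname(fit3$center), cc, tolerance = 1e-9)
  expect_equal(fit3$radius, sqrt(sum((p1 - cc)^2)), tolerance = 1e-9)

  expect_error(estimate_rotation_center(data.frame(x = 1:5, y = 2 * (1:5))),
               "collinear")
  expect_error(estimate_rotation_center(data.frame(x = 1:2, y = c(0, 1))),
               "3 points")
})

test_that("to_angles unwraps across the boundary and accumulates turns", {
  expect_equal(to_angles(data.frame(x = 3, y = 0), c(0, 0))$angle_rad, 0)

  # crossing the +/-pi boundary stays continuous
  th_true <- seq(pi - 0.3, pi + 0.7, length.out = 50)
  pts <- data.frame(x = cos(th_true), y = sin(th_true))
  tr <- to_angles(pts, c(0, 0))
  expect_lt(max(abs(diff(tr$angle_rad))), pi)
  expect_equal(diff(range(tr$angle_rad)), 1.0, tolerance = 1e-9)

  # three full turns; oracle = cumulative sum of the true increments
  inc <- runif(600, 0, 2 * pi / 100)
  inc <- inc * (6 * pi / sum(inc))
  th3 <- cumsum(inc)
  tr3 <- to_angles(data.frame(x = 2 * cos(th3), y = 2 * sin(th3)), c(0, 0))
  expect_equal(tr3$angle_rad[600] - tr3$angle_rad[1], th3[600] - th3[1],
               tolerance = 1e-9)
  expect_equal(tr3$angle_rad[600] - tr3$angle_rad[1], 6 * pi, tolerance = 0.2)

  expect_error(to_angles(data.frame(x = c(1, 0), y = c(1, 0)), c(0, 0)),
               "frame")
})

test_that("to_angles is rotation-invariant up to a global offset", {
  set.seed(4)
  th <- cumsum(rnorm(200, 0.02, 0.05))
  pts <- data.frame(x = 3 + 1.5 * cos(th), y = -1 + 1.5 * sin(th))
  base <- to_angles(pts, c(3, -1))$angle_rad
  for (phi in c(0.7, 2.9)) {
    rot <- data.frame(
      x = 3 + cos(phi) * (pts$x - 3) - sin(phi) * (pts$y + 1),
      y = -1 + sin(phi) * (pts$x - 3) + cos(phi) * (pts$y + 1)
    )
    shifted <- to_angles(rot, c(3, -1))$angle_rad
    d <- shifted - base
    expect_lt(diff(range(d)), 1e-9)                  # constant offset
    m <- (d[1] - phi) %% (2 * pi)
    expect_lt(min(m, 2 * pi - m), 1e-9)              # offset = phi mod 2pi
  }
})

test_that("sliding_average filters as expected at the edges and interior", {
  expect_equal(sliding_average(rep(2.5, 50), 10), rep(2.5, 50))
  x <- rnorm(40)
  expect_equal(sliding_average(x, 1), x)

  # white noise sd shrinks by ~1/sqrt(window)
  set.seed(11)
  z <- rnorm(2e5)
  f <- sliding_average(z, 100)
  interior <- f[101:(2e5 - 100)]
  expect_equal(sd(interior), 0.1, tolerance = 0.03)

  # mean preservation: exact for constant and linear traces under the
  # shrunken-edge policy, O(window/n) in general
  lin <- 0.3 + 0.01 * seq_len(500)
  expect_equal(mean(sliding_average(lin, 25)), mean(lin), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(400)
    err <- abs(mean(sliding_average(y, 50)) - mean(y))
    expect_lt(err, 50 / 400 * sd(y))
  }

  # valid mode marks incomplete windows
  v <- sliding_average(angular_trace(rnorm(30), 100), window = 11,
                       edge = "valid")
  expect_true(all(is.na(v$angle_filt_rad[1:5])))
  expect_false(anyNA(v$angle_filt_rad[6:25]))
  expect_error(sliding_average(numeric(0), 1), "empty")
})

test_that("full chain from frames to angles recovers the truth", {
  set.seed(21)
  th_true <- cumsum(rnorm(150, 0.05, 0.1))
  frames <- simulate_spot_frames(th_true, center = c(21, 21), radius = 8,
                                 psf_sd = 1.5, photons = 1e4, seed = 5)
  spots <- purrr::map_dfr(frames, function(fr) {
    f <- fit_spot(fr)
    tibble::tibble(x = f$x, y = f$y)
  })
  ctr <- estimate_rotation_center(spots)
  expect_equal(unname(ctr$center), c(21, 21), tolerance = 0.1)
  expect_equal(ctr$radius, 8, tolerance = 0.1)
  tr <- to_angles(spots, ctr$center)
  err <- (tr$angle_rad - th_true) - mean(tr$angle_rad - th_true)
  expect_lt(sqrt(mean(err^2)), 0.05)
})
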