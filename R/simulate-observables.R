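#' Render camera frames of the tracked nanoparticle
#'
#' For each angle in the trace the backscattering spot is placed at
#' `(cx + R cos(theta), cy + R sin(theta))` and rendered as a symmetric 2D
#' Gaussian whose total intensity is `photons`; per-pixel Poisson shot
#' noise is added. With `photons = Inf` the noiseless expected image
#' (unit total intensity) is returned, which is useful for geometry
#' checks and tracking-precision calibrations.
#'
#' @param trace An [angular_trace()] tibble (or numeric vector of angles,
#'   rad).
#' @param center Length-2 numeric `(cx, cy)`, pixels.
#' @param radius Rotor-arm projection radius, pixels (> 0).
#' @param psf_sd Gaussian point-spread sd, pixels.
#' @param photons Expected total photons per frame; `Inf` for noiseless.
#' @param frame_size Length-2 integer `(nrow, ncol)` of each frame.
#' @param seed Optional seed for the shot noise.
#' @return List of numeric matrices, one frame per angle.
#' @export
simulate_spot_frames <- function(trace, center, radius, psf_sd = 1.5,
                                 photons = 1e4, frame_size = c(41, 41),
                                 seed = NULL) {
  angles <- if (is.data.frame(trace)) trace$angle_rad else as.numeric(trace)
  check_number(radius, "radius", 0, strict_lower = TRUE)
  check_number(psf_sd, "psf_sd", 0, strict_lower = TRUE)
  nr <- frame_size[1L]; nc <- frame_size[2L]
  cx <- center[[1L]]; cy <- center[[2L]]
  margin <- 3 * psf_sd
  if (cx - radius - margin < 1 || cx + radius + margin > nc ||
      cy - radius - margin < 1 || cy + radius + margin > nr) {
    abort("spot orbit (centre +/- radius + 3 psf_sd) extends outside the frame.")
  }
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  render <- function(theta) {
    sx <- cx + radius * cos(theta)
    sy <- cy + radius * sin(theta)
    g <- exp(-((xs - sx)^2 + (ys - sy)^2) / (2 * psf_sd^2))
    g / (2 * pi * psf_sd^2)  # unit total intensity
  }
  with_seed(seed, {
    lapply(angles, function(theta) {
      g <- render(theta)
      if (is.infinite(photons)) return(g)
      matrix(rpois(nr * nc, photons * g), nr, nc)
    })
  })
}

#' Configuration for stopped-flow kinetic trace simulation
#'
#' Supported models: `exp1` / `exp2` (one or two saturating or decaying
#' exponential phases), `anisotropy_pair` (a pair of polarized intensity
#' channels consistent with an exponentially relaxing anisotropy at
#' constant total intensity), and `phosphate_biphasic` (two rising phases
#' in ATPs hydrolysed per enzyme, scaled by enzyme concentration and a
#' linear fluorescence calibration; the fast phase models the initial
#' ATPase burst of ~15 ATPs per enzyme followed by a slower phase of
#' ~10).
#'
#' @param model One of `"exp1"`, `"exp2"`, `"anisotropy_pair"`,
#'   `"phosphate_biphasic"`.
#' @param amplitudes Phase amplitudes. For `anisotropy_pair`,
#'   `c(r0, r_inf)` (initial and final anisotropy).
#' @param rates Rate constants, 1/s (one per phase).
#' @param offset Signal offset (baseline).
#' @param direction `"rise"` or `"fall"` for the exponential models.
#' @param enzyme_nM Enzyme concentration (phosphate model), nM.
#' @param burst_atps_per_enzyme,slow_atps_per_enzyme Phase amplitudes of
#'   the phosphate model, ATPs per enzyme.
#' @param cal_slope,cal_intercept Linear fluorescence calibration
#'   (fluorescence = intercept + slope * [Pi in uM]).
#' @param intensity Total intensity of the anisotropy channel pair.
#' @param noise_sd Gaussian noise sd added to each channel.
#' @param duration Trace length, s.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional seed.
#' @return A validated `kinetic_sim_config` list.
#' @export
kinetic_sim_config <- function(model = c("exp1", "exp2", "anisotropy_pair",
                                         "phosphate_biphasic"),
                               amplitudes = 1, rates = 1, offset = 0,
                               direction = c("rise", "fall"),
                               enzyme_nM = 75,
                               burst_atps_per_enzyme = 15,
                               slow_atps_per_enzyme = 10,
                               cal_slope = 0.8, cal_intercept = 0.05,
                               intensity = 1,
                               noise_sd = 0, duration = 10,
                               sample_rate = 500, seed = NULL) {
  model <- tryCatch(match.arg(model),
                    error = function(e) abort(sprintf("unknown model `%s`.",
                                                      model[1L])))
  direction <- match.arg(direction)
  if (any(!is.finite(amplitudes))) abort("amplitudes must be finite.")
  if (any(rates <= 0)) abort("rates must be > 0.")
  check_number(noise_sd, "noise_sd", 0)
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  check_number(enzyme_nM, "enzyme_nM", 0, strict_lower = TRUE)
  n_phase <- switch(model, exp1 = 1L, exp2 = 2L, anisotropy_pair = 1L,
                    phosphate_biphasic = 2L)
  if (model %in% c("exp1", "exp2") && length(amplitudes) != n_phase) {
    abort(sprintf("model `%s` needs %d amplitude(s).", model, n_phase))
  }
  if (model == "phosphate_biphasic") {
    if (length(rates) != 2L) abort("phosphate_biphasic needs 2 rates.")
    if (rates[1L] <= rates[2L]) {
      abort("phosphate_biphasic requires fast rate > slow rate.")
    }
  } else if (length(rates) != n_phase) {
    abort(sprintf("model `%s` needs %d rate(s).", model, n_phase))
  }
  if (model == "anisotropy_pair" && length(amplitudes) != 2L) {
    abort("anisotropy_pair needs amplitudes = c(r0, r_inf).")
  }
  structure(
    list(model = model, amplitudes = amplitudes, rates = rates,
         offset = offset, direction = direction, enzyme_nM = enzyme_nM,
         burst_atps_per_enzyme = burst_atps_per_enzyme,
         slow_atps_per_enzyme = slow_atps_per_enzyme,
         cal_slope = cal_slope, cal_intercept = cal_intercept,
         intensity = intensity, noise_sd = noise_sd, duration = duration,
         sample_rate = sample_rate, seed = seed),
    class = "kinetic_sim_config"
  )
}

#' Simulate a stopped-flow kinetic trace
#'
#' Evaluates the noiseless model curve of a [kinetic_sim_config()] and
#' adds Gaussian noise. `anisotropy_pair` returns a three-column tibble
#' `(time_s, ivv, ivh)`; all other models return `(time_s, signal)`.
#' The phosphate model produces fluorescence
#' `cal_intercept + cal_slope * [Pi]` with
#' `[Pi] = E * (A_fast (1 - exp(-k_fast t)) + A_slow (1 - exp(-k_slow t)))`
#' in uM.
#'
#' @param config A [kinetic_sim_config()].
#' @return Tibble of class `kinetic_trace`, with attributes `channel` and
#'   `truth` (the noiseless parameters).
#' @export
simulate_kinetic_trace <- function(config) {
  if (!inherits(config, "kinetic_sim_config")) {
    config <- do.call(kinetic_sim_config, config)
  }
  cf <- config
  n <- max(2L, round(cf$duration * cf$sample_rate))
  t <- (seq_len(n) - 1) / cf$sample_rate

  phase <- function(A, k) {
    if (cf$direction == "rise") A * (1 - exp(-k * t)) else A * exp(-k * t)
  }
  out <- switch(
    cf$model,
    exp1 = tibble(time_s = t,
                  signal = cf$offset + phase(cf$amplitudes[1L], cf$rates[1L])),
    exp2 = tibble(time_s = t,
                  signal = cf$offset + phase(cf$amplitudes[1L], cf$rates[1L]) +
                    phase(cf$amplitudes[2L], cf$rates[2L])),
    anisotropy_pair = {
      r <- cf$amplitudes[2L] +
        (cf$amplitudes[1L] - cf$amplitudes[2L]) * exp(-cf$rates[1L] * t)
      tibble(time_s = t,
             ivv = cf$intensity * (1 + 2 * r) / 3,
             ivh = cf$intensity * (1 - r) / 3)
    },
    phosphate_biphasic = {
      e_uM <- cf$enzyme_nM / 1000
      pi_uM <- e_uM * (cf$burst_atps_per_enzyme * (1 - exp(-cf$rates[1L] * t)) +
                         cf$slow_atps_per_enzyme * (1 - exp(-cf$rates[2L] * t)))
      tibble(time_s = t,
             signal = cf$cal_intercept + cf$cal_slope * pi_uM)
    }
  )
  if (cf$noise_sd > 0) {
    out <- with_seed(cf$seed, {
      for (col in setdiff(names(out), "time_s")) {
        out[[col]] <- out[[col]] + rnorm(n, 0, cf$noise_sd)
      }
      out
    })
  }
  attr(out, "channel") <- switch(cf$model,
                                 phosphate_biphasic = "phosphate",
                                 anisotropy_pair = "anisotropy",
                                 "fluorescence")
  attr(out, "truth") <- cf
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Configuration for kymograph simulation
#'
#' Emulates a confocal line-scan kymograph of a DNA-bound enzyme: the
#' spot sits at the recognition site (with per-line localization jitter)
#' until an exponentially distributed sliding-initiation time, then
#' performs an unbiased 1D random walk. Defaults follow the acquisition
#' settings of the measurements (28 ms line time, 100 nm pixels).
#'
#' @param n_lines Number of scan lines.
#' @param line_time Line-scan time, s.
#' @param pixel_size Pixel size, nm.
#' @param n_pixels Pixels per scan line.
#' @param site_position Recognition-site position, pixel (0-based allowed,
#'   must lie in `[1, n_pixels)` after rounding for rendering).
#' @param localization_sd Per-line localization jitter, pixels (>= 0).
#' @param initiation_time_mean Mean of the exponential sliding-initiation
#'   time, s.
#' @param diffusion_coefficient 1D diffusion coefficient, pixel^2/s.
#' @param spot_amplitude Peak expected photon count of the spot.
#' @param background Expected background photon count per pixel.
#' @param spot_sd Rendered spot Gaussian sd, pixels.
#' @param seed Optional seed.
#' @return A validated `kymo_sim_config` list.
#' @export
kymo_sim_config <- function(n_lines = 500, line_time = 0.028,
                            pixel_size = 100, n_pixels = 101,
                            site_position = 51, localization_sd = 0.3,
                            initiation_time_mean = 5,
                            diffusion_coefficient = 2,
                            spot_amplitude = 100, background = 2,
                            spot_sd = 1.5, seed = NULL) {
  check_number(n_lines, "n_lines", 1)
  check_number(line_time, "line_time", 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  check_number(n_pixels, "n_pixels", 3)
  if (site_position < 0 || site_position >= n_pixels) {
    abort("site_position must lie within [0, n_pixels).")
  }
  check_number(localization_sd, "localization_sd", 0)
  check_number(initiation_time_mean, "initiation_time_mean", 0,
               strict_lower = TRUE)
  check_number(diffusion_coefficient, "diffusion_coefficient", 0)
  check_number(spot_sd, "spot_sd", 0, strict_lower = TRUE)
  structure(
    list(n_lines = as.integer(n_lines), line_time = line_time,
         pixel_size = pixel_size, n_pixels = as.integer(n_pixels),
         site_position = site_position, localization_sd = localization_sd,
         initiation_time_mean = initiation_time_mean,
         diffusion_coefficient = diffusion_coefficient,
         spot_amplitude = spot_amplitude, background = background,
         spot_sd = spot_sd, seed = seed),
    class = "kymo_sim_config"
  )
}

#' Simulate a kymograph with a static-then-diffusing spot
#'
#' @param config A [kymo_sim_config()].
#' @return List with `kymo` (integer matrix, one scan line per row),
#'   `track` (tibble: `line`, `time_s`, `true_pos_px`, `render_pos_px`),
#'   `initiation_time_s` (the true sliding start), and `config`.
#' @export
simulate_kymograph <- function(config) {
  if (!inherits(config, "kymo_sim_config")) {
    config <- do.call(kymo_sim_config, config)
  }
  cf <- config
  with_seed(cf$seed, {
    t_init <- rexp(1L, 1 / cf$initiation_time_mean)
    times <- (seq_len(cf$n_lines) - 1) * cf$line_time
    step_sd <- sqrt(2 * cf$diffusion_coefficient * cf$line_time)
    pos <- rep(cf$site_position, cf$n_lines)
    moving <- times >= t_init
    if (any(moving) && step_sd > 0) {
      steps <- rnorm(sum(moving), 0, step_sd)
      pos[moving] <- cf$site_position + cumsum(steps)
      # reflect at the scan boundaries
      pos <- abs(pos)
      pos <- (cf$n_pixels - 1) - abs((cf$n_pixels - 1) - pos)
    }
    render_pos <- pos + if (cf$localization_sd > 0) {
      rnorm(cf$n_lines, 0, cf$localization_sd)
    } else 0
    px <- seq_len(cf$n_pixels) - 1
    expected <- outer(render_pos, px,
                      function(p, x) cf$background +
                        cf$spot_amplitude * exp(-(x - p)^2 / (2 * cf$spot_sd^2)))
    kymo <- matrix(rpois(length(expected), expected),
                   nrow = cf$n_lines, ncol = cf$n_pixels)
    list(kymo = kymo,
         track = tibble(line = seq_len(cf$n_lines), time_s = times,
                        true_pos_px = pos, render_pos_px = render_pos),
         initiation_time_s = t_init,
         config = cf)
  })
}
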