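# Stopped-flow kinetics: anisotropy, exponential phase fits, phosphate
# calibration, biphasic ATPase bursts, cumulative-step overlays.

#' Fluorescence anisotropy from polarized emission channels
#'
#' `r = (IVV / (G * IVH) - 1) / (IVV / (G * IVH) + 2)`, elementwise.
#' For positive intensities r is bounded in [-0.5, 1) and is invariant
#' under common scaling of both channels. The G factor corrects the
#' detection-path sensitivity ratio (set to ~1 in a T-configuration
#' instrument).
#'
#' @param ivv,ivh Parallel / perpendicular emission intensities, or a
#'   data frame with `ivv` and `ivh` columns as the first argument.
#' @param G G-factor ratio (default 1).
#' @return Numeric vector of anisotropies, or the input tibble with an
#'   `r` column appended when a data frame was given.
#' @export
anisotropy <- function(ivv, ivh = NULL, G = 1) {
  if (is.data.frame(ivv)) {
    df <- ivv
    if (!all(c("ivv", "ivh") %in% names(df))) {
      abort("data-frame input must have `ivv` and `ivh` columns.")
    }
    df$r <- anisotropy(df$ivv, df$ivh, G = G)
    return(df)
  }
  if (length(ivv) != length(ivh)) abort("`ivv` and `ivh` must match in length.")
  check_number(G, "G", 0, strict_lower = TRUE)
  corr <- G * ivh
  bad <- which(!is.finite(corr) | corr <= 0)
  if (length(bad)) {
    abort(sprintf("IVH (after G correction) must be > 0; first offending sample: %d.",
                  bad[1L]))
  }
  ratio <- ivv / corr
  (ratio - 1) / (ratio + 2)
}

#' Fit one or two exponential phases to a kinetic trace
#'
#' Least-squares fit of `offset + sum_i A_i (1 - exp(-k_i t))` (rising)
#' or `offset + sum_i A_i exp(-k_i t)` (falling); the direction is
#' auto-detected from the endpoint means unless given. The first
#' `dead_time` seconds are excluded (stopped-flow mixing artifact).
#' Rates are reported fastest first. If the fitted total amplitude is
#' indistinguishable from the residual noise the fit is flagged
#' `no_kinetics`.
#'
#' @param trace Tibble with `time_s` and `signal` columns.
#' @param n_phases 1 or 2.
#' @param direction `"rise"`, `"fall"`, or `NULL` to auto-detect.
#' @param dead_time Seconds excluded at the start (default 2 ms).
#' @return An `exp_phase_fit`: `offset`, `amplitudes`, `rates` (1/s,
#'   descending), `se_amplitudes`, `se_rates`, `se_offset`, `sigma`,
#'   `direction`, `no_kinetics`, `n`, plus the fitted model frame for
#'   plotting.
#' @export
fit_exponential_phases <- function(trace, n_phases = 1, direction = NULL,
                                   dead_time = 0.002) {
  stopifnot(n_phases %in% c(1L, 2L))
  d <- tibble(time_s = trace$time_s, signal = trace$signal)
  d <- d[d$time_s >= dead_time & is.finite(d$signal), ]
  if (nrow(d) < 10L) abort("need at least 10 points after the dead time.")
  t0 <- d$time_s[1L]
  tt <- d$time_s - t0   # fit from the first usable point
  y <- d$signal

  n_head <- max(3L, ceiling(nrow(d) * 0.05))
  n_tail <- max(3L, ceiling(nrow(d) * 0.1))
  y0 <- mean(head(y, n_head)); y1 <- mean(tail(y, n_tail))
  if (is.null(direction)) direction <- if (y1 >= y0) "rise" else "fall"
  amp_tot <- y1 - y0
  if (direction == "fall") amp_tot <- y0 - y1

  # crude half-time for rate initialisation
  mid <- (y0 + y1) / 2
  cross <- if (direction == "rise") which(y >= mid) else which(y <= mid)
  t_half <- if (length(cross)) max(tt[cross[1L]], diff(range(tt)) / 200) else
    diff(range(tt)) / 4
  k_half <- log(2) / t_half

  noise <- sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (abs(amp_tot) < 3 * noise / sqrt(n_head) + .Machine$double.eps * 100) {
    out <- list(offset = mean(y), amplitudes = rep(0, n_phases),
                rates = rep(NA_real_, n_phases),
                se_amplitudes = rep(NA_real_, n_phases),
                se_rates = rep(NA_real_, n_phases), se_offset = sd(y) / sqrt(length(y)),
                sigma = sd(y), direction = direction, no_kinetics = TRUE,
                n = nrow(d), model = NULL,
                data = tibble(time_s = d$time_s, signal = y, fitted = mean(y)))
    return(structure(out, class = "exp_phase_fit"))
  }

  form <- if (n_phases == 1L) {
    if (direction == "rise") y ~ off + A1 * (1 - exp(-k1 * tt))
    else y ~ off + A1 * exp(-k1 * tt)
  } else {
    if (direction == "rise") {
      y ~ off + A1 * (1 - exp(-k1 * tt)) + A2 * (1 - exp(-k2 * tt))
    } else {
      y ~ off + A1 * exp(-k1 * tt) + A2 * exp(-k2 * tt)
    }
  }
  start <- if (n_phases == 1L) {
    list(off = if (direction == "rise") y0 else y1, A1 = abs(amp_tot),
         k1 = k_half)
  } else {
    list(off = if (direction == "rise") y0 else y1,
         A1 = abs(amp_tot) / 2, k1 = 4 * k_half,
         A2 = abs(amp_tot) / 2, k2 = k_half / 4)
  }
  if (direction == "fall") {
    # for a fall, A e^{-kt} starts at A above the offset
    if (n_phases == 1L) start$A1 <- abs(amp_tot)
  }
  lower <- c(off = -Inf,
             if (n_phases == 1L) c(A1 = 0, k1 = 1e-8)
             else c(A1 = 0, k1 = 1e-8, A2 = 0, k2 = 1e-8))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(sprintf(
      "exponential fit did not converge (starts: %s): %s",
      paste(sprintf("%s=%.3g", names(start), unlist(start)), collapse = ", "),
      conditionMessage(e)))
  )
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  amp <- cf[grep("^A", names(cf))]
  rate <- cf[grep("^k", names(cf))]
  se_amp <- sm[grep("^A", rownames(sm)), 2L]
  se_rate <- sm[grep("^k", rownames(sm)), 2L]
  o <- order(rate, decreasing = TRUE)   # fastest first, always
  structure(
    list(offset = unname(cf["off"]), amplitudes = unname(amp[o]),
         rates = unname(rate[o]), se_amplitudes = unname(se_amp[o]),
         se_rates = unname(se_rate[o]),
         se_offset = unname(sm["off", 2L]),
         sigma = summary(fit)$sigma, direction = direction,
         no_kinetics = FALSE, n = nrow(d), model = fit,
         data = tibble(time_s = d$time_s, signal = y,
                       fitted = as.numeric(stats::fitted(fit)))),
    class = "exp_phase_fit"
  )
}

#' @export
print.exp_phase_fit <- function(x, ...) {
  cat(sprintf("<exp_phase_fit> %s, %d phase(s)%s\n", x$direction,
              length(x$amplitudes), if (x$no_kinetics) " [no kinetics]" else ""))
  for (i in seq_along(x$amplitudes)) {
    cat(sprintf("  phase %d: A = %.4g +/- %.2g, k = %.4g +/- %.2g 1/s\n", i,
                x$amplitudes[i], x$se_amplitudes[i], x$rates[i], x$se_rates[i]))
  }
  cat(sprintf("  offset %.4g, residual sd %.3g, n = %d\n", x$offset, x$sigma, x$n))
  invisible(x)
}

#' Calibrate a phosphate-release fluorescence signal
#'
#' Ordinary least-squares line through phosphate standards, with the
#' linear range determined by forward selection: starting from the three
#' lowest concentrations, standards are added while their prediction
#' residual stays within `tol_sd` residual standard deviations of the
#' current line (fluorescence saturates as free phosphate approaches the
#' reporter-protein concentration).
#'
#' @param standards Data frame with columns `pi_uM` (added phosphate,
#'   uM) and `fluorescence`.
#' @param tol_sd Outlier threshold in residual sds (default 4).
#' @return A `pbp_calibration`: `slope` (fluorescence per uM),
#'   `intercept`, `linear_range_uM`, `sigma`, `n_used`, `model`.
#' @export
pbp_calibrate <- function(standards, tol_sd = 4) {
  d <- as.data.frame(standards)[, c("pi_uM", "fluorescence")]
  d <- d[complete.cases(d), ]
  d <- d[order(d$pi_uM), ]
  if (nrow(d) < 3L) abort("need at least 3 usable standards.")
  if (sd(d$fluorescence) < .Machine$double.eps) {
    abort("standards carry no fluorescence variation; cannot calibrate.")
  }
  n_in <- 3L
  while (n_in < nrow(d)) {
    m <- lm(fluorescence ~ pi_uM, data = d[seq_len(n_in), ])
    sig <- max(suppressWarnings(summary(m)$sigma), 1e-6 * sd(d$fluorescence))
    pred <- predict(m, newdata = d[n_in + 1L, , drop = FALSE])
    if (abs(d$fluorescence[n_in + 1L] - pred) > tol_sd * sig) break
    n_in <- n_in + 1L
  }
  m <- lm(fluorescence ~ pi_uM, data = d[seq_len(n_in), ])
  structure(
    list(slope = unname(coef(m)[2L]), intercept = unname(coef(m)[1L]),
         linear_range_uM = d$pi_uM[n_in],
         sigma = suppressWarnings(summary(m)$sigma),
         n_used = n_in, model = m),
    class = "pbp_calibration"
  )
}

#' @export
print.pbp_calibration <- function(x, ...) {
  cat(sprintf("<pbp_calibration> slope %.4g /uM, intercept %.4g, linear to %.3g uM (n = %d)\n",
              x$slope, x$intercept, x$linear_range_uM, x$n_used))
  invisible(x)
}

#' Quantify a biphasic ATPase burst from a phosphate-release trace
#'
#' Converts fluorescence to uM phosphate with the supplied calibration,
#' then to ATPs hydrolysed per enzyme (dividing by the enzyme
#' concentration), and fits two rising exponential phases. The fast
#' phase is the initial burst; its amplitude is the ATPs per enzyme
#' consumed before the slow phase takes over. If the trace is shorter
#' than `2 / k_slow` the slow amplitude is flagged poorly constrained.
#' A `burst_linear` variant fits a fast phase plus a linear steady-state
#' tail instead.
#'
#' @param trace Tibble with `time_s` and `signal` (fluorescence).
#' @param enzyme_nM Enzyme concentration, nM (> 0).
#' @param calibration A [pbp_calibrate()] result (or list with `slope`
#'   and `intercept`).
#' @param model `"double_exp"` (default) or `"burst_linear"`.
#' @param dead_time Seconds excluded at the start.
#' @return A `burst_fit`: `fast_atps_per_enzyme`, `k_fast`,
#'   `slow_atps_per_enzyme`, `k_slow` (or `steady_rate`), standard
#'   errors, `slow_constrained`, `enzyme_nM`, `calibration`.
#' @export
atpase_burst <- function(trace, enzyme_nM, calibration,
                         model = c("double_exp", "burst_linear"),
                         dead_time = 0.002) {
  model <- match.arg(model)
  check_number(enzyme_nM, "enzyme_nM", 0, strict_lower = TRUE)
  pi_uM <- (trace$signal - calibration$intercept) / calibration$slope
  atp <- pi_uM / (enzyme_nM / 1000)
  d <- tibble(time_s = trace$time_s, signal = atp)

  if (model == "double_exp") {
    f <- fit_exponential_phases(d, n_phases = 2, direction = "rise",
                                dead_time = dead_time)
    k_fast <- f$rates[1L]; k_slow <- f$rates[2L]
    out <- list(fast_atps_per_enzyme = f$amplitudes[1L], k_fast = k_fast,
                slow_atps_per_enzyme = f$amplitudes[2L], k_slow = k_slow,
                se_fast = f$se_amplitudes[1L], se_slow = f$se_amplitudes[2L],
                se_k_fast = f$se_rates[1L], se_k_slow = f$se_rates[2L],
                steady_rate = NA_real_,
                slow_constrained = is.finite(k_slow) &&
                  max(d$time_s) >= 2 / k_slow,
                enzyme_nM = enzyme_nM, calibration = calibration,
                model = model, fit = f)
  } else {
    dd <- d[d$time_s >= dead_time, ]
    tt <- dd$time_s; y <- dd$signal
    start <- list(A1 = max(y) / 2, k1 = log(2) / (max(tt) / 20),
                  v = (tail(y, 1) - max(y) / 2) / max(tt), off = 0)
    fit <- minpack.lm::nlsLM(y ~ off + A1 * (1 - exp(-k1 * tt)) + v * tt,
                             start = start,
                             lower = c(A1 = 0, k1 = 1e-8, v = -Inf, off = -Inf))
    cf <- coef(fit); sm <- summary(fit)$coefficients
    out <- list(fast_atps_per_enzyme = unname(cf["A1"]),
                k_fast = unname(cf["k1"]),
                slow_atps_per_enzyme = NA_real_, k_slow = NA_real_,
                se_fast = sm["A1", 2L], se_slow = NA_real_,
                se_k_fast = sm["k1", 2L], se_k_slow = NA_real_,
                steady_rate = unname(cf["v"]),
                slow_constrained = TRUE,
                enzyme_nM = enzyme_nM, calibration = calibration,
                model = model, fit = fit)
  }
  structure(out, class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("<burst_fit> fast: %.2f ATPs/enzyme at %.3g 1/s",
              x$fast_atps_per_enzyme, x$k_fast))
  if (is.finite(x$slow_atps_per_enzyme)) {
    cat(sprintf("; slow: %.2f ATPs/enzyme at %.3g 1/s%s",
                x$slow_atps_per_enzyme, x$k_slow,
                if (!x$slow_constrained) " [poorly constrained]" else ""))
  }
  cat(sprintf(" (enzyme %.3g nM)\n", x$enzyme_nM))
  invisible(x)
}

#' Cumulative stepping times at a fixed translocation rate
#'
#' Step `i` of a motor advancing 1 bp per step at `rate_bp_s` occurs at
#' `i / rate_bp_s`; useful as a staircase overlay on ensemble kinetics.
#'
#' @param rate_bp_s Translocation rate, bp/s (> 0).
#' @param n_steps Number of steps (>= 0).
#' @return Tibble: `step`, `time_s`.
#' @export
cumulative_steps <- function(rate_bp_s, n_steps) {
  check_number(rate_bp_s, "rate_bp_s", 0, strict_lower = TRUE)
  check_number(n_steps, "n_steps", 0)
  n_steps <- as.integer(n_steps)
  tibble(step = seq_len(n_steps), time_s = seq_len(n_steps) / rate_bp_s)
}

#' Time to reach 50% of a kinetic transition
#'
#' Linear interpolation of the first crossing of the midpoint between
#' the initial and final signal levels (medians of the leading/trailing
#' stretches of a lightly smoothed trace). Errors if the trace never
#' crosses its midpoint.
#'
#' @param trace Tibble with `time_s` and `signal`.
#' @param smooth_frac Fraction of the trace length used as the smoothing
#'   window (0 disables smoothing).
#' @return Half-time, s.
#' @export
half_time <- function(trace, smooth_frac = 0.02) {
  t <- trace$time_s; y <- trace$signal
  n <- length(y)
  if (n < 5L) abort("trace too short.")
  if (smooth_frac > 0) {
    w <- max(1L, round(n * smooth_frac))
    y <- sliding_average(y, window = min(w, n))
  }
  # initial level from the first sample (the edge of the smoothed
  # series is unshrunk), final level from the trailing plateau
  n_tail <- max(3L, ceiling(n * 0.1))
  y0 <- y[1L]; y1 <- median(tail(y, n_tail))
  if (abs(y1 - y0) < .Machine$double.eps * 100) {
    abort("no transition: initial and final levels coincide.")
  }
  mid <- (y0 + y1) / 2
  crossed <- if (y1 > y0) y >= mid else y <= mid
  i <- which(crossed)[1L]
  if (is.na(i)) abort("signal never crosses the midpoint.")
  if (i == 1L) return(t[1L])
  # linear interpolation between the bracketing samples
  t[i - 1L] + (mid - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}
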