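#' Configuration for the nano-rotor trace simulator
#'
#' Defaults reproduce the statistical structure of the measured twist
#' traces: a 4 kHz angular series with a reversible +0.60 rad bound-state
#' shift (1.0 bp at 10.5 bp/turn), Ornstein-Uhlenbeck angular noise whose
#' 100-point-filtered standard deviation is ~0.35 rad, exponential-mixture
#' bound dwells (41% at 1.6 s, 59% at 35.4 s with ATP), and sawtooth
#' loop-translocation events with bimodal maximum loop sizes (4.9 / 21.5
#' bp) and ramp rates (11.4 / 32.7 bp/s). Events larger than
#' `long_size_threshold` are coupled to the fast rate mode
#' (`couple_large_fast`), and the mode weights make the mean true event
#' duration ~370 ms.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration Trace length in seconds.
#' @param shift_bound Bound-minus-free angular shift, rad.
#' @param helical_pitch DNA helical pitch, bp per turn.
#' @param noise_sd Stationary sd of the OU angular noise, rad. The default
#'   0.49 rad filters to ~0.35 rad through a 100-point (25 ms) window.
#' @param noise_tau OU correlation time, s.
#' @param dwell_free Mean free-state dwell, s.
#' @param dwell_bound_components Exponential mixture for pre-event bound
#'   dwells: list of `c(weight, lifetime_s)`.
#' @param post_bound_components Exponential mixture for the short bound
#'   dwells that follow loop collapse.
#' @param event_prob_per_bound Probability a bound dwell ends in a
#'   translocation event.
#' @param size_modes Gaussian mixture of maximum loop sizes: list of
#'   `c(weight, mean_bp, sd_bp)`. Draws are truncated at `min_size`.
#' @param rate_modes Gaussian mixture of ramp rates: list of
#'   `c(weight, mean_bp_s, sd_bp_s)`; weights are the marginal rate-mode
#'   fractions.
#' @param couple_large_fast If `TRUE`, events larger than
#'   `long_size_threshold` always take the fast rate mode; small events
#'   draw the slow mode with the conditional probability that preserves
#'   the marginal rate weights.
#' @param long_size_threshold Size (bp) above which events are "long
#'   range" and rate-coupled.
#' @param min_size Lower truncation of size draws, bp.
#' @param p_post_bound Probability an event collapses into a bound state.
#' @param p_pre_bound Probability the bound dwell preceding an event is
#'   long enough to be resolvable; with probability `1 - p_pre_bound` it
#'   is truncated below the filter resolution.
#' @param p_cluster Probability that an event ending bound is followed by
#'   another event within `cluster_gap`.
#' @param cluster_gap Maximum gap (s) between clustered events.
#' @param level_free Absolute angle of the free state, rad.
#' @param seed Master seed; spawns independent per-stream seeds.
#' @return A validated `rotor_sim_config` list.
#' @export
rotor_sim_config <- function(sample_rate = 4000,
                             duration = 60,
                             shift_bound = 0.60,
                             helical_pitch = 10.5,
                             noise_sd = 0.49,
                             noise_tau = 0.010,
                             dwell_free = 1.5,
                             dwell_bound_components = list(c(0.41, 1.6),
                                                           c(0.59, 35.4)),
                             post_bound_components = list(c(0.37, 0.17),
                                                          c(0.63, 3.5)),
                             event_prob_per_bound = 0.95,
                             size_modes = list(c(0.75, 4.9, 1.2),
                                               c(0.25, 21.5, 3.0)),
                             rate_modes = list(c(0.34, 11.4, 1.5),
                                               c(0.66, 32.7, 3.5)),
                             couple_large_fast = TRUE,
                             long_size_threshold = 12,
                             min_size = 2.5,
                             p_post_bound = 0.77,
                             p_pre_bound = 0.95,
                             p_cluster = 0.35,
                             cluster_gap = 2,
                             level_free = 0,
                             seed = 1L) {
  check_number(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  check_number(duration, "duration", 0, strict_lower = TRUE)
  if (round(sample_rate * duration) < 2) {
    abort("sample_rate * duration must be >= 2 samples.")
  }
  check_number(shift_bound, "shift_bound")
  check_number(helical_pitch, "helical_pitch", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(noise_tau, "noise_tau", 0, strict_lower = TRUE)
  check_number(dwell_free, "dwell_free", 0, strict_lower = TRUE)
  bnd <- check_mixture(dwell_bound_components, "dwell_bound_components", 2L)
  pbnd <- check_mixture(post_bound_components, "post_bound_components", 2L)
  szm <- check_mixture(size_modes, "size_modes", 3L)
  rtm <- check_mixture(rate_modes, "rate_modes", 3L)
  if (any(szm[, 3L] <= 0) || any(rtm[, 3L] <= 0)) {
    abort("mode sds must be > 0.")
  }
  for (p in c("event_prob_per_bound", "p_post_bound", "p_pre_bound",
              "p_cluster")) {
    check_number(get(p), p, 0, 1)
  }
  check_number(cluster_gap, "cluster_gap", 0, strict_lower = TRUE)
  check_number(min_size, "min_size", 0, strict_lower = TRUE)
  if (couple_large_fast && nrow(rtm) == 2L && nrow(szm) == 2L) {
    p_small <- szm[1L, 1L]
    if (rtm[1L, 1L] > p_small + 1e-8) {
      abort(paste0("with couple_large_fast the slow-rate weight cannot ",
                   "exceed the small-size weight."))
    }
  }
  structure(
    list(sample_rate = sample_rate, duration = duration,
         shift_bound = shift_bound, helical_pitch = helical_pitch,
         noise_sd = noise_sd, noise_tau = noise_tau,
         dwell_free = dwell_free,
         dwell_bound_components = bnd, post_bound_components = pbnd,
         event_prob_per_bound = event_prob_per_bound,
         size_modes = szm, rate_modes = rtm,
         couple_large_fast = couple_large_fast,
         long_size_threshold = long_size_threshold, min_size = min_size,
         p_post_bound = p_post_bound, p_pre_bound = p_pre_bound,
         p_cluster = p_cluster, cluster_gap = cluster_gap,
         level_free = level_free, seed = as.integer(seed)),
    class = "rotor_sim_config"
  )
}

#' Draw i.i.d. dwell times from an exponential mixture
#'
#' @param components List of `c(weight, lifetime_s)`; weights must sum
#'   to 1 and lifetimes must be positive.
#' @param n Number of draws (>= 1).
#' @param seed Optional seed.
#' @return Tibble with `dwell_s` and the generating `component`.
#' @export
simulate_dwells <- function(components, n, seed = NULL) {
  m <- check_mixture(components, "components", 2L)
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  with_seed(seed, {
    comp <- sample.int(nrow(m), n, replace = TRUE, prob = m[, 1L])
    tibble(dwell_s = rexp(n, rate = 1 / m[comp, 2L]), component = comp)
  })
}

# Stationary Ornstein-Uhlenbeck sample on a uniform grid, via its exact
# AR(1) discretisation.
sim_ou <- function(n, sd, tau, dt) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- rnorm(n) * sd * sqrt(1 - a^2)
  innov[1L] <- rnorm(1) * sd  # stationary start
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# One exponential-mixture draw (scalar).
draw_mix_exp <- function(m) {
  k <- sample.int(nrow(m), 1L, prob = m[, 1L])
  rexp(1L, rate = 1 / m[k, 2L])
}

# Exponential-mixture draw conditioned on (lower, upper); rejection with
# a deterministic fallback so pathological bounds cannot hang.
draw_mix_exp_cond <- function(m, lower = 0, upper = Inf) {
  for (i in seq_len(1000L)) {
    x <- draw_mix_exp(m)
    if (x > lower && x < upper) return(x)
  }
  min(lower + m[1L, 2L] / 10, upper * 0.99)
}

# Truncated Gaussian-mixture draw for sizes/rates (> lower).
draw_mix_gauss <- function(m, lower = 0, comp = NULL) {
  k <- if (is.null(comp)) sample.int(nrow(m), 1L, prob = m[, 1L]) else comp
  repeat {
    x <- rnorm(1L, m[k, 2L], m[k, 3L])
    if (x > lower) return(list(value = x, component = k))
  }
}

#' Simulate a nano-rotor angular trace with ground truth
#'
#' Builds a continuous-time state sequence (free dwells, bound dwells,
#' sawtooth loop-translocation events with linear ramps and single-sample
#' collapse), samples it at `config$sample_rate`, and adds stationary
#' Ornstein-Uhlenbeck angular noise. Every dwell and event is recorded in
#' the returned ground truth, so parameter-recovery tests can compare the
#' analysis chain against the exact simulation truth.
#'
#' @param config A [rotor_sim_config()].
#' @return List with `trace` (an [angular_trace()] tibble) and
#'   `ground_truth` (list: `intervals`, `events`, `dwells`, `config`,
#'   `flags`).
#' @export
simulate_rotor_trace <- function(config) {
  if (!inherits(config, "rotor_sim_config")) {
    config <- do.call(rotor_sim_config, config)
  }
  cf <- config
  seeds <- spawn_seeds(cf$seed, 2L)
  rad_per_bp <- 2 * pi / cf$helical_pitch
  lvl <- c(free = cf$level_free, bound = cf$level_free + cf$shift_bound)

  # conditional slow-rate probability for small events (preserves the
  # marginal rate weights under the large->fast coupling)
  q_slow_small <- if (cf$couple_large_fast && nrow(cf$rate_modes) == 2L &&
                        nrow(cf$size_modes) == 2L) {
    min(1, cf$rate_modes[1L, 1L] / cf$size_modes[1L, 1L])
  } else NA_real_

  draw_rate <- function(size) {
    if (!is.na(q_slow_small)) {
      if (size > cf$long_size_threshold) {
        draw_mix_gauss(cf$rate_modes, lower = 0.1, comp = 2L)$value
      } else {
        k <- if (runif(1L) < q_slow_small) 1L else 2L
        draw_mix_gauss(cf$rate_modes, lower = 0.1, comp = k)$value
      }
    } else {
      draw_mix_gauss(cf$rate_modes, lower = 0.1)$value
    }
  }

  segs <- list()   # rows: start, end, state, level0, slope
  evs <- list()    # rows: start, end, size, rate, pre_resolvable, post_state, cluster
  t <- 0
  cluster_id <- 0L
  n_seg <- 0L
  n_ev <- 0L
  add_seg <- function(dur, state, level0, slope = 0, tag = "") {
    n_seg <<- n_seg + 1L
    segs[[n_seg]] <<- c(t, t + dur, match(state, c("free", "bound", "translocating")),
                        level0, slope, match(tag, c("", "pre", "post")) - 1L)
    t <<- t + dur
  }

  with_seed(seeds[1L], {
    while (t < cf$duration) {
      add_seg(rexp(1L, 1 / cf$dwell_free), "free", lvl["free"])
      if (t >= cf$duration) break
      will_event <- runif(1L) < cf$event_prob_per_bound
      if (will_event) {
        # enforce the configured resolvable-pre-bound fraction exactly:
        # resolvable pre-dwells are drawn conditioned above the filter
        # resolution, the rest are truncated below it (binding and
        # initiation closely spaced)
        resolvable <- runif(1L) < cf$p_pre_bound
        d_bound <- if (resolvable) {
          draw_mix_exp_cond(cf$dwell_bound_components, lower = 0.1)
        } else {
          runif(1L, 0.005, 0.045)
        }
      } else {
        resolvable <- TRUE
        d_bound <- draw_mix_exp(cf$dwell_bound_components)
      }
      add_seg(d_bound, "bound", lvl["bound"], tag = "pre")
      if (!will_event || t >= cf$duration) next
      cluster_id <- cluster_id + 1L
      repeat {
        sz <- draw_mix_gauss(cf$size_modes, lower = cf$min_size)$value
        rt <- draw_rate(sz)
        dur_ev <- sz / rt
        ends_bound <- runif(1L) < cf$p_post_bound
        ev_start <- t
        add_seg(dur_ev, "translocating", lvl["bound"], slope = rt * rad_per_bp)
        n_ev <- n_ev + 1L
        evs[[n_ev]] <- c(ev_start, ev_start + dur_ev, sz, rt,
                         as.numeric(resolvable),
                         if (ends_bound) 2 else 1, cluster_id)
        if (t >= cf$duration || !ends_bound) break
        again <- runif(1L) < cf$p_cluster
        if (again) {
          # the follow-up event's pre-dwell is this post-collapse bound
          # dwell; honour p_pre_bound here too
          resolvable <- runif(1L) < cf$p_pre_bound
          d_pb <- if (resolvable) {
            draw_mix_exp_cond(cf$post_bound_components, lower = 0.1,
                              upper = cf$cluster_gap)
          } else {
            runif(1L, 0.005, 0.045)
          }
        } else {
          d_pb <- draw_mix_exp(cf$post_bound_components)
        }
        add_seg(d_pb, "bound", lvl["bound"], tag = "post")
        if (!again || t >= cf$duration) break
      }
    }
  })

  seg_m <- do.call(rbind, segs)
  colnames(seg_m) <- c("start", "end", "state", "level0", "slope", "tag")
  # truncate at the requested duration
  keep <- seg_m[, "start"] < cf$duration
  seg_m <- seg_m[keep, , drop = FALSE]
  truncated <- seg_m[, "end"] > cf$duration
  seg_m[truncated, "end"] <- cf$duration

  state_names <- c("free", "bound", "translocating")
  intervals <- tibble(
    start_s = seg_m[, "start"], end_s = seg_m[, "end"],
    state = state_names[seg_m[, "state"]],
    censored = seg_m[, "start"] == 0 | truncated,
    post_event = seg_m[, "tag"] == 2
  )

  ev_m <- if (n_ev > 0L) do.call(rbind, evs) else
    matrix(numeric(0), ncol = 7L)
  events <- tibble(
    start_s = ev_m[, 1L], end_s = pmin(ev_m[, 2L], cf$duration),
    duration_s = pmin(ev_m[, 2L], cf$duration) - ev_m[, 1L],
    size_bp = ev_m[, 3L], rate_bp_s = ev_m[, 4L],
    pre_resolvable = ev_m[, 5L] == 1,
    post_state = c("free", "bound")[ev_m[, 6L]],
    cluster_id = as.integer(ev_m[, 7L]),
    censored = ev_m[, 2L] > cf$duration
  )
  events$pre_state <- rep("bound", nrow(events))
  tb <- table(events$cluster_id)
  events$clustered <- events$cluster_id %in% as.integer(names(tb[tb > 1L]))

  # sample the deterministic part, then add OU noise
  n <- round(cf$sample_rate * cf$duration)
  tt <- (seq_len(n) - 1) / cf$sample_rate
  idx <- findInterval(tt, seg_m[, "start"])
  angle <- seg_m[idx, "level0"] + seg_m[idx, "slope"] * (tt - seg_m[idx, "start"])
  noise <- with_seed(seeds[2L], sim_ou(n, cf$noise_sd, cf$noise_tau,
                                       1 / cf$sample_rate))
  trace <- angular_trace(angle + noise, cf$sample_rate, time_s = tt,
                         metadata = list(simulated = TRUE, seed = cf$seed,
                                         shift_bound = cf$shift_bound,
                                         helical_pitch = cf$helical_pitch))

  dwells <- dplyr::filter(intervals, .data$state != "translocating")
  dwells <- dplyr::mutate(dwells, duration_s = .data$end_s - .data$start_s)

  flags <- list(
    too_short = nrow(intervals) < 2L,
    n_events = sum(!events$censored)
  )
  list(trace = trace,
       ground_truth = list(intervals = intervals, events = events,
                           dwells = dwells, config = cf, flags = flags))
}
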