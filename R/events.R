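# Sawtooth loop-translocation event detection.
#
# Events are linear positive twist ramps on top of the two-level
# (free/bound) trace, terminated by an abrupt collapse on loop release.
# They are detected by ramp analysis on top of the HMM segmentation
# rather than by adding ramp states to the HMM: ramps are non-stationary
# and poorly modelled by constant-emission states.

#' Default detection parameters for sawtooth events
#'
#' @param rise_threshold Candidate threshold above the bound level, rad;
#'   `NULL` means 2x the filtered noise sd.
#' @param collapse_fraction Fraction of the accrued rise that must be
#'   lost for the event to count as collapsed.
#' @param collapse_window Window after the peak within which the collapse
#'   must complete, s.
#' @param min_duration Minimum event duration, s.
#' @param min_size Minimum reportable maximum loop size, bp (sizing below
#'   ~2 bp is unreliable at the ~1 bp / 80 ms resolution of the traces).
#' @param slope_tmin Minimum t-statistic of the ramp slope.
#' @param state_window Window used to classify pre/post states, s.
#' @param max_lookback Maximum distance to search for the ramp foot, s.
#' @return Named list of parameters.
#' @export
sawtooth_params <- function(rise_threshold = NULL, collapse_fraction = 0.8,
                            collapse_window = 0.05, min_duration = 0.1,
                            min_size = 2, slope_tmin = 3,
                            state_window = 0.15, max_lookback = 5) {
  list(rise_threshold = rise_threshold, collapse_fraction = collapse_fraction,
       collapse_window = collapse_window, min_duration = min_duration,
       min_size = min_size, slope_tmin = slope_tmin,
       state_window = state_window, max_lookback = max_lookback)
}

# Robust ramp fit (rlm, OLS fallback). The slope standard error is
# corrected for residual autocorrelation with an AR(1) effective sample
# size: angular noise is strongly correlated between raw samples, so the
# naive OLS t-statistic is inflated by almost an order of magnitude.
ramp_fit <- function(tt, yy) {
  ols <- lm(yy ~ tt)
  slope <- coef(ols)[[2L]]
  icpt <- coef(ols)[[1L]]
  rob <- tryCatch(MASS::rlm(yy ~ tt, maxit = 50), error = function(e) NULL)
  if (!is.null(rob) && isTRUE(rob$converged)) {
    slope <- coef(rob)[[2L]]
    icpt <- coef(rob)[[1L]]
  }
  se <- tryCatch(summary(ols)$coefficients[2L, 2L], error = function(e) NA_real_)
  if (!is.na(se)) {
    res <- residuals(ols)
    n <- length(res)
    infl <- sqrt(n / ar1_neff(res))
    se <- se * infl
  }
  r2 <- suppressWarnings(stats::cor(yy, icpt + slope * tt)^2)
  list(slope = slope, intercept = icpt, se = se,
       tstat = if (is.na(se) || se == 0) Inf else slope / se,
       r_squared = if (is.finite(r2)) r2 else NA_real_)
}

#' Detect sawtooth loop-translocation events
#'
#' Candidate intervals are maximal runs where the filtered angle exceeds
#' the bound level by at least `rise_threshold` (default 2x the filtered
#' noise sd). A candidate becomes an event if (i) the angle collapses by
#' at least `collapse_fraction` of the accrued rise within
#' `collapse_window` of the peak, (ii) the ramp's robust linear-fit slope
#' is significantly positive, and (iii) duration and size pass the
#' minima. The ramp foot is traced back to the last crossing of the
#' pre-event baseline.
#'
#' Sizing corrects for the boxcar filter delay: with a `w`-sample window
#' the filtered peak lags and underestimates the true pre-collapse peak
#' by ~`slope * w / (2 * fs)`, so the maximum loop size is read from the
#' ramp fit evaluated at the smear-corrected collapse time. Rates are the
#' ramp slope over the trimmed ramp interior, converted with
#' [rad_to_bp()].
#'
#' @param trace A filtered [angular_trace()].
#' @param seg The [segment_two_level()] result for `trace`.
#' @param params A [sawtooth_params()] list.
#' @param pitch Helical pitch for the rad-to-bp conversion.
#' @return Tibble of class `translocation_events`: one row per event with
#'   `start_s`, `end_s`, `duration_s`, `max_loop_size_bp`, `rate_bp_s`,
#'   ramp-fit columns, `pre_state`, `post_state` (`cluster_id` and
#'   `class` are added by [classify_events()]). Detection parameters are
#'   attached as the `params` attribute. An empty tibble is a valid
#'   result.
#' @export
detect_sawtooth_events <- function(trace, seg, params = sawtooth_params(),
                                   pitch = 10.5) {
  params <- modifyList(sawtooth_params(), params[!vapply(params, is.null, TRUE)])
  fs <- trace_sample_rate(trace)
  filt <- trace$angle_filt_rad
  if (is.null(filt)) abort("`trace` must carry an `angle_filt_rad` column.")
  n <- length(filt)
  win <- attr(trace, "metadata")$filter_window
  if (is.null(win)) win <- seg$bin
  sigma <- seg$noise_sd_filtered
  thr <- if (is.null(params$rise_threshold)) 2 * sigma else params$rise_threshold
  lev <- seg$levels
  base_bound <- if ("bound" %in% names(lev)) lev[["bound"]] else lev[[1L]]
  base_free <- lev[["free"]]
  shift <- base_bound - base_free

  empty <- tibble(start_s = numeric(0), end_s = numeric(0),
                  duration_s = numeric(0), max_loop_size_bp = numeric(0),
                  rate_bp_s = numeric(0), slope_rad_s = numeric(0),
                  intercept_rad = numeric(0), r_squared = numeric(0),
                  pre_state = character(0), post_state = character(0))

  dev <- filt - base_bound
  above <- dev > thr
  if (!any(above)) {
    return(structure(empty, params = params,
                     class = c("translocation_events", class(empty))))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  regions <- cbind(starts[r$values], ends[r$values])

  w_col <- max(1L, round(params$collapse_window * fs))
  look <- round(params$max_lookback * fs)
  swin <- max(1L, round(params$state_window * fs))
  half_w <- win / (2 * fs)
  state_of_mean <- function(m) {
    if (!is.finite(m)) return("unresolved")
    mid <- (base_bound + base_free) / 2
    if (abs(m - mid) < 0.1 * abs(shift)) return("unresolved")
    if (abs(m - base_bound) <= abs(m - base_free)) "bound" else "free"
  }

  out <- list()
  last_end_idx <- 0L
  for (g in seq_len(nrow(regions))) {
    a <- regions[g, 1L]; b <- regions[g, 2L]
    if (a <= last_end_idx) next
    peak <- max(filt[a:b])
    rise <- peak - base_bound
    # a higher region right behind this one means this is a leading
    # bump of the same ramp; let its walk-back absorb this region
    if (g < nrow(regions)) {
      a2 <- regions[g + 1L, 1L]; b2 <- regions[g + 1L, 2L]
      if (a2 - b <= w_col && max(filt[a2:b2]) > peak) next
    }
    # the ramp ends where the trace leaves the candidate region, so the
    # collapse is checked after the region end (the in-region argmax can
    # be a mid-ramp noise bump); the near-collapse peak anchors sizing
    jmax <- min(n, b + w_col)
    post_min <- min(filt[b:jmax])
    if (post_min > peak - params$collapse_fraction * rise) next
    tail_lo <- max(a, b - 2L * win)
    ipk <- tail_lo - 1L + which.max(filt[tail_lo:b])
    # ramp foot: last crossing of the baseline before the peak
    j0 <- max(1L, ipk - look)
    below <- which(filt[j0:ipk] <= base_bound + 0.5 * sigma)
    jstart <- if (length(below)) j0 - 1L + max(below) else j0
    len <- ipk - jstart + 1L
    if (len < 4L) next
    # ramp slope is fitted on the *raw* trace (the boxcar filter smears
    # the ramp ends); the fit window is made self-consistent by
    # iterating the baseline-crossing start point
    raw <- trace$angle_rad
    i0 <- jstart
    fit <- ramp_fit(trace$time_s[i0:ipk], raw[i0:ipk])
    for (iter in 1:2) {
      if (!is.finite(fit$slope) || fit$slope <= 0) break
      t_cross <- (base_bound - fit$intercept) / fit$slope
      idx_cross <- (t_cross - trace$time_s[1L]) * fs
      if (!is.finite(idx_cross)) break
      i_new <- as.integer(max(j0, min(ipk - 3L, floor(idx_cross) + 1L)))
      if (abs(i_new - i0) <= 2L) break
      i0 <- i_new
      fit <- ramp_fit(trace$time_s[i0:ipk], raw[i0:ipk])
    }
    if (!is.finite(fit$slope) || fit$slope <= 0 ||
        (is.finite(fit$tstat) && fit$tstat < params$slope_tmin)) next
    # smear-corrected collapse time and size
    t_end <- trace$time_s[ipk] + half_w
    size_rad <- max(fit$intercept + fit$slope * t_end, peak) - base_bound
    t_start <- (base_bound - fit$intercept) / fit$slope
    t_start <- min(max(t_start, trace$time_s[jstart] - half_w), trace$time_s[ipk])
    duration <- t_end - t_start
    size_bp <- rad_to_bp(size_rad, pitch)
    if (duration < params$min_duration || size_bp < params$min_size) next
    out[[length(out) + 1L]] <- tibble(
      start_s = t_start, end_s = t_end, duration_s = duration,
      max_loop_size_bp = size_bp,
      rate_bp_s = rad_to_bp(fit$slope, pitch),
      slope_rad_s = fit$slope, intercept_rad = fit$intercept,
      r_squared = fit$r_squared,
      foot_idx = i0, end_idx = b
    )
    last_end_idx <- b
  }
  if (!length(out)) {
    return(structure(empty, params = params,
                     class = c("translocation_events", class(empty))))
  }
  res <- dplyr::bind_rows(out)

  # pre/post states in a second pass, once all events are known.
  # The pre state is read from the Viterbi labels one filter window
  # before the ramp foot: pre-event dwells are long, so the HMM's
  # persistence makes its label far more reliable than a local window
  # mean. Post-collapse dwells can be much shorter than an HMM bin, so
  # the post state is classified by level proximity of a short window
  # after the collapse has settled, truncated at the next event.
  n_ev <- nrow(res)
  smear <- round(half_w * fs)
  min_len <- max(3L, round(0.04 * fs))
  pre_state <- post_state <- character(n_ev)
  lab_chr <- as.character(seg$labels)
  for (i in seq_len(n_ev)) {
    idx_pre <- res$foot_idx[i] - 2L * smear
    pre_state[i] <- if (idx_pre < 1L ||
                          (i > 1L && idx_pre <= res$end_idx[i - 1L] + smear)) {
      "unresolved"
    } else {
      st <- lab_chr[idx_pre]
      if (st == "translocating") "unresolved" else st
    }
    post_lo <- min(n, res$end_idx[i] + 2L * smear)
    post_hi <- min(n, post_lo + swin)
    if (i < n_ev) post_hi <- min(post_hi, res$foot_idx[i + 1L] - smear)
    post_state[i] <- if (post_hi - post_lo >= min_len) {
      state_of_mean(mean(filt[post_lo:post_hi]))
    } else "unresolved"
  }
  res$pre_state <- pre_state
  res$post_state <- post_state
  res$foot_idx <- NULL
  res$end_idx <- NULL
  structure(res, params = params,
            class = c("translocation_events", setdiff(class(res),
                                                      "translocation_events")))
}

#' Assign cluster ids and classes to detected events
#'
#' Events whose gap to a neighbour is at most `cluster_gap` (closed
#' interval: a gap of exactly `cluster_gap` counts) share a cluster id
#' and are classed `clustered`. Isolated events larger than
#' `long_threshold` are `long_range`; remaining events are
#' `single_to_bound` or `single_to_free` by their post-collapse state
#' (`NA` class when the post state is unresolved).
#'
#' @param events Event table from [detect_sawtooth_events()] (time
#'   ordered; it is re-sorted defensively).
#' @param cluster_gap Maximum inter-event gap within a cluster, s.
#' @param long_threshold Size above which events are long range, bp.
#' @return The events with `cluster_id` and `class` columns.
#' @export
classify_events <- function(events, cluster_gap = 2, long_threshold = 12) {
  if (nrow(events) == 0L) {
    events$cluster_id <- integer(0)
    events$class <- character(0)
    return(events)
  }
  atts <- attr(events, "params")
  events <- dplyr::arrange(events, .data$start_s)
  gap <- c(Inf, events$start_s[-1L] - events$end_s[-nrow(events)])
  events$cluster_id <- cumsum(gap > cluster_gap)
  sizes <- table(events$cluster_id)
  in_cluster <- events$cluster_id %in% as.integer(names(sizes[sizes > 1L]))
  cls <- dplyr::case_when(
    in_cluster ~ "clustered",
    events$max_loop_size_bp > long_threshold ~ "long_range",
    events$post_state == "bound" ~ "single_to_bound",
    events$post_state == "free" ~ "single_to_free",
    TRUE ~ NA_character_
  )
  events$class <- cls
  attr(events, "params") <- c(atts, list(cluster_gap = cluster_gap,
                                         long_threshold = long_threshold))
  events
}
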