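# Kymograph single-particle tracking and sliding-event detection.

#' Extract a single-particle track from a kymograph
#'
#' Per scan line, the spot position is the background-subtracted
#' intensity-weighted centroid in a window around the brightest pixel.
#' The search is restricted to `max_jump_px` around the last linked
#' position (greedy linking); lines without a qualifying pixel are left
#' as gaps (`NA`).
#'
#' @param kymo Integer/numeric matrix, one scan line per row.
#' @param max_jump_px Maximum line-to-line jump, pixels.
#' @param window_px Centroid half-window, pixels.
#' @param snr_min Minimum peak height above the line median, in units of
#'   the line MAD, for a line to contain a spot.
#' @param line_time Line-scan time, s (recorded on the track).
#' @param pixel_size Pixel size, nm (recorded on the track).
#' @return Tibble of class `kymo_track`: `line`, `time_s`,
#'   `position_px` (NA at gaps). Errors if more than half the lines have
#'   no spot.
#' @export
build_track <- function(kymo, max_jump_px = 5, window_px = 3, snr_min = 3,
                        line_time = 0.028, pixel_size = 100) {
  if (!is.matrix(kymo) || nrow(kymo) == 0L || ncol(kymo) < 3L) {
    abort("`kymo` must be a non-empty matrix (one scan line per row).")
  }
  n_lines <- nrow(kymo); n_px <- ncol(kymo)
  pos <- rep(NA_real_, n_lines)
  last <- NA_real_
  for (i in seq_len(n_lines)) {
    line <- as.numeric(kymo[i, ])
    bg <- median(line)
    noise <- max(mad(line), .Machine$double.eps)
    search <- if (is.na(last)) seq_len(n_px) else {
      lo <- max(1L, floor(last + 1 - max_jump_px))
      hi <- min(n_px, ceiling(last + 1 + max_jump_px))
      lo:hi
    }
    pk <- search[which.max(line[search])]
    if (line[pk] <= bg + snr_min * noise) next  # gap
    lo <- max(1L, pk - window_px); hi <- min(n_px, pk + window_px)
    wts <- pmax(line[lo:hi] - bg, 0)
    if (sum(wts) <= 0) next
    # centroid in 0-based pixel coordinates
    pos[i] <- sum((lo:hi - 1) * wts) / sum(wts)
    last <- pos[i]
  }
  if (mean(is.na(pos)) > 0.5) {
    abort(sprintf("more than half of the lines (%d/%d) have no detectable spot.",
                  sum(is.na(pos)), n_lines))
  }
  out <- tibble(line = seq_len(n_lines),
                time_s = (seq_len(n_lines) - 1) * line_time,
                position_px = pos)
  attr(out, "line_time_s") <- line_time
  attr(out, "pixel_size_nm") <- pixel_size
  class(out) <- c("kymo_track", class(out))
  out
}

#' Baseline position statistics of a non-sliding enzyme
#'
#' Mean and standard deviation of the track position over a baseline
#' window (gaps excluded). The sd is floored at `sd_floor` pixels to
#' avoid zero-sd degeneracy on noiseless synthetic tracks.
#'
#' @param track A [build_track()] tibble.
#' @param baseline_lines Line indices of the baseline window (default:
#'   all lines).
#' @param sd_floor Lower bound on the reported sd, pixels.
#' @return List: `mean`, `sd`, `n` (non-gap baseline lines).
#' @export
baseline_stats <- function(track, baseline_lines = NULL, sd_floor = 0.05) {
  if (is.null(baseline_lines)) baseline_lines <- track$line
  p <- track$position_px[track$line %in% baseline_lines]
  p <- p[!is.na(p)]
  if (length(p) < 10L) abort("need at least 10 non-gap baseline lines.")
  list(mean = mean(p), sd = max(sd(p), sd_floor), n = length(p))
}

#' Detect sliding events by sustained displacement
#'
#' A sliding event is a maximal run of at least `m` consecutive non-gap
#' lines whose position deviates from the baseline mean by strictly more
#' than `k` baseline standard deviations (a displacement of exactly
#' `k` sd does not qualify; gaps reset the run). The initiation time of
#' the first event is `(start_line - t0_line) * line_time`, with
#' `t0_line` the frame before ATP delivery.
#'
#' @param track A [build_track()] tibble.
#' @param mean,sd Baseline statistics ([baseline_stats()]).
#' @param k Displacement threshold, sd units (default 4).
#' @param m Minimum run length, lines (default 5).
#' @param t0_line Time-zero line index.
#' @param line_time Line time, s; defaults to the track attribute.
#' @return List with `events` (tibble: `start_line`, `end_line`,
#'   `duration_lines`, `max_displacement_sd`, `initiation_time_s`) and
#'   `initiation_time_s` of the first event (`NA` if none).
#' @export
detect_sliding <- function(track, mean, sd, k = 4, m = 5, t0_line = 1,
                           line_time = NULL) {
  if (sd <= 0) abort("`sd` must be > 0.")
  if (t0_line < min(track$line) || t0_line > max(track$line)) {
    abort("`t0_line` must lie within the track.")
  }
  if (is.null(line_time)) line_time <- attr(track, "line_time_s")
  if (is.null(line_time)) line_time <- 0.028
  disp <- abs(track$position_px - mean) / sd
  hit <- !is.na(disp) & disp > k       # strict inequality; gaps break runs
  runs <- label_runs(hit)
  runs <- runs[runs$value == "TRUE" & (runs$end_idx - runs$start_idx + 1L) >= m, ]
  events <- tibble(
    start_line = track$line[runs$start_idx],
    end_line = track$line[runs$end_idx],
    duration_lines = runs$end_idx - runs$start_idx + 1L,
    max_displacement_sd = vapply(seq_len(nrow(runs)), function(i) {
      max(disp[runs$start_idx[i]:runs$end_idx[i]], na.rm = TRUE)
    }, numeric(1)),
    initiation_time_s = (track$line[runs$start_idx] - t0_line) * line_time
  )
  list(events = events,
       initiation_time_s = if (nrow(events)) events$initiation_time_s[1L]
       else NA_real_)
}
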