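#' Convert twist between radians and base pairs
#'
#' B-form DNA makes one full turn (2*pi rad) every `pitch` base pairs, so a
#' twist change of `2*pi/pitch` rad corresponds to 1 bp. At the default
#' pitch of 10.5 bp/turn the conversion constant is 0.598 rad per bp
#' (computed, not hard-coded). The two functions are exact inverses.
#'
#' @param delta_rad,delta_bp Twist change in radians / base pairs.
#' @param pitch Helical pitch in bp per turn (> 0). Default 10.5.
#' @return Numeric vector of the converted twist.
#' @examples
#' rad_to_bp(2 * pi)      # one full turn = 10.5 bp
#' bp_to_rad(1)           # 0.598 rad
#' @export
rad_to_bp <- function(delta_rad, pitch = 10.5) {
  check_number(pitch, "pitch", lower = 0, strict_lower = TRUE)
  delta_rad / (2 * pi / pitch)
}

#' @rdname rad_to_bp
#' @export
bp_to_rad <- function(delta_bp, pitch = 10.5) {
  check_number(pitch, "pitch", lower = 0, strict_lower = TRUE)
  delta_bp * (2 * pi / pitch)
}

#' Build an angular-trace tibble
#'
#' The standard container for a rotor-angle time series: a tibble with
#' columns `time_s` and `angle_rad` (plus `angle_filt_rad` once filtered),
#' uniformly sampled at `sample_rate_hz`. Provenance (rotation centre,
#' radius, filter window, sign convention) travels in attributes. The sign
#' convention is increasing angle = downstream translocation (positive
#' twist).
#'
#' @param angle_rad Unwrapped rotor angle in radians.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param time_s Optional explicit time stamps; defaults to
#'   `(seq_along(angle_rad) - 1) / sample_rate_hz`.
#' @param metadata Named list of provenance entries.
#' @return A tibble of class `angular_trace`.
#' @export
angular_trace <- function(angle_rad, sample_rate_hz, time_s = NULL,
                          metadata = list()) {
  if (!is.numeric(angle_rad) || anyNA(angle_rad) || any(!is.finite(angle_rad))) {
    abort("`angle_rad` must be finite and non-missing.")
  }
  check_number(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  if (is.null(time_s)) time_s <- (seq_along(angle_rad) - 1) / sample_rate_hz
  out <- tibble(time_s = time_s, angle_rad = as.numeric(angle_rad))
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "metadata") <- metadata
  class(out) <- c("angular_trace", class(out))
  out
}

trace_sample_rate <- function(trace) {
  sr <- attr(trace, "sample_rate_hz")
  if (!is.null(sr)) return(sr)
  dt <- stats::median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) abort("cannot infer sample rate from trace.")
  1 / dt
}

#' Fit a symmetric 2D Gaussian to the brightest spot in a frame
#'
#' Locates the brightest pixel and refines its position to sub-pixel
#' precision by nonlinear least squares of
#' `b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * w^2))`
#' within a `window` x `window` region around it. Coordinates are
#' (x = column, y = row), in pixels, 1-based.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param window Side of the square fit region in pixels (default 13).
#' @param snr_min Minimum peak height above the median background, in units
#'   of the frame's robust noise (MAD), below which "no spot" is raised.
#' @return A `spot_fit` list: `x`, `y`, `amplitude`, `width`, `background`,
#'   `residual` (RMS), `converged`.
#' @export
fit_spot <- function(frame, window = 13, snr_min = 3) {
  if (!is.matrix(frame) || any(dim(frame) < 3L)) {
    abort("`frame` must be a matrix with at least 3 rows and columns.")
  }
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  peak <- max(frame)
  if (peak <= bg + snr_min * max(noise, .Machine$double.eps)) {
    abort("no spot: no pixel rises above the background threshold.")
  }
  idx <- which(frame == peak, arr.ind = TRUE)[1L, ]
  h <- (window - 1L) %/% 2L
  rows <- max(1L, idx[1L] - h):min(nrow(frame), idx[1L] + h)
  cols <- max(1L, idx[2L] - h):min(ncol(frame), idx[2L] + h)
  sub <- frame[rows, cols, drop = FALSE]
  d <- expand.grid(y = rows, x = cols)
  d$z <- as.vector(sub)

  # moment-based starting values
  w0 <- max(1, window / 5)
  start <- list(x0 = as.numeric(idx[2L]), y0 = as.numeric(idx[1L]),
                A = peak - bg, w = w0, b = bg)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * w^2)),
      data = d, start = start,
      lower = c(x0 = min(cols) - 1, y0 = min(rows) - 1, A = 0, w = 0.2,
                b = -Inf),
      upper = c(x0 = max(cols) + 1, y0 = max(rows) + 1, A = Inf,
                w = window, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(x = as.numeric(idx[2L]), y = as.numeric(idx[1L]),
                amplitude = peak - bg, width = w0, background = bg,
                residual = NA_real_, converged = FALSE)
  } else {
    cf <- coef(fit)
    out <- list(x = unname(cf["x0"]), y = unname(cf["y0"]),
                amplitude = unname(cf["A"]), width = unname(cf["w"]),
                background = unname(cf["b"]),
                residual = sqrt(mean(residuals(fit)^2)),
                converged = fit$convInfo$isConv)
  }
  structure(out, class = "spot_fit")
}

#' Estimate the rotation centre and radius of a circular point cloud
#'
#' Algebraic (Kasa) least-squares circle fit: solves the linear system
#' `2x*cx + 2y*cy + c = x^2 + y^2`. No iterative refinement is applied;
#' for rotor tracks, where points cover the full circle or a substantial
#' arc, the algebraic and geometric fits agree to well below the tracking
#' noise.
#'
#' @param points Data frame or matrix with columns `x`, `y` (pixels).
#' @return List with `center` (length-2 numeric) and `radius`.
#' @export
estimate_rotation_center <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3L) abort("need at least 3 points to fit a circle.")
  x <- pts[, 1L]; y <- pts[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  qr_A <- qr(A)
  if (qr_A$rank < 3L) abort("points are collinear; no circle is defined.")
  sol <- qr.coef(qr_A, x^2 + y^2)
  cx <- sol[1L]; cy <- sol[2L]
  r2 <- sol[3L] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) abort("degenerate circle fit (radius <= 0).")
  list(center = c(x = unname(cx), y = unname(cy)), radius = sqrt(r2))
}

#' Convert tracked positions to an unwrapped polar-angle trace
#'
#' Each point's polar angle about `center` is taken with `atan2` and the
#' series is unwrapped so that successive differences lie in (-pi, pi],
#' i.e. the trace is continuous across the +/-pi boundary and accumulates
#' full turns.
#'
#' @param points Data frame with columns `x`, `y` (and optionally `frame`).
#' @param center Length-2 numeric, the rotation centre.
#' @param sample_rate_hz Sampling rate of the position series.
#' @return An [angular_trace()] tibble.
#' @export
to_angles <- function(points, center, sample_rate_hz = 4000) {
  pts <- as.data.frame(points)
  dx <- pts$x - center[[1L]]
  dy <- pts$y - center[[2L]]
  r <- sqrt(dx^2 + dy^2)
  if (any(r < .Machine$double.eps^0.5)) {
    abort(sprintf("point at the rotation centre (first offending frame: %d).",
                  which(r < .Machine$double.eps^0.5)[1L]))
  }
  theta <- atan2(dy, dx)
  d <- diff(theta)
  d <- d - 2 * pi * floor((d + pi) / (2 * pi))  # wrap increments into (-pi, pi]
  unwrapped <- c(theta[1L], theta[1L] + cumsum(d))
  angular_trace(unwrapped, sample_rate_hz,
                metadata = list(center = unname(center),
                                radius = mean(r),
                                sign_convention = "increasing = downstream (positive twist)"))
}

#' Centred sliding average of an angular trace
#'
#' A 100-point sliding average of a 4 kHz trace gives the 40 Hz filtered
#' series used for state calling. Edges use symmetrically shrunken windows
#' by default (the window radius shrinks near the boundaries so the output
#' has the same length as the input); `edge = "valid"` instead marks
#' samples whose full window does not fit as `NA`. Odd windows are truly
#' centred and preserve the mean of constant and linear traces exactly;
#' even windows take one extra trailing sample (a half-sample lag, the
#' usual boxcar convention). The global mean is preserved to
#' O(window / length) in general.
#'
#' @param trace An [angular_trace()] tibble, or a bare numeric vector.
#' @param window Window length in samples (>= 1). Default 100.
#' @param edge `"shrink"` (default) or `"valid"`.
#' @return The trace with an `angle_filt_rad` column added (or a numeric
#'   vector if the input was one). Filter settings are recorded in the
#'   trace metadata.
#' @export
sliding_average <- function(trace, window = 100, edge = c("shrink", "valid")) {
  edge <- match.arg(edge)
  is_trace <- is.data.frame(trace)
  x <- if (is_trace) trace$angle_rad else as.numeric(trace)
  n <- length(x)
  if (n == 0L) abort("empty trace.")
  window <- as.integer(window)
  if (window < 1L || window > n) abort("`window` must be in [1, length(trace)].")

  h <- (window - 1L) %/% 2L  # nominal radius; even windows use h and h+1
  h2 <- window - 1L - h
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  if (edge == "shrink") {
    # radius shrinks symmetrically near the edges
    rad <- pmin(h, i - 1L, n - i)
    lo <- i - rad
    hi <- i + rad
    # for even windows extend one extra trailing sample where it fits
    if (h2 > h) {
      ext <- (rad == h) & (i + h2 <= n)
      hi[ext] <- i[ext] + h2
    }
    filt <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    lo <- i - h; hi <- i + h2
    filt <- rep(NA_real_, n)
    ok <- lo >= 1L & hi <= n
    filt[ok] <- (cs[hi[ok] + 1L] - cs[lo[ok]]) / window
  }

  if (!is_trace) return(filt)
  trace$angle_filt_rad <- filt
  md <- attr(trace, "metadata")
  md$filter_window <- window
  md$filter_edge <- edge
  attr(trace, "metadata") <- md
  trace
}
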