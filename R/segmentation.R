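# Two-level hidden-Markov segmentation of filtered angular traces.
#
# The HMM runs on means of non-overlapping bins (default: one bin per
# filter window) so that Gaussian emissions are approximately independent
# despite the correlated angular noise; the Viterbi path is then expanded
# back to full sampling rate. Boundary resolution is therefore one bin.

# Baum-Welch for Gaussian emissions. States flagged in `fixed` keep
# their emission parameters (used for the broad ramp/outlier state that
# absorbs translocation excursions so the level states stay clean).
em_hmm_gauss <- function(y, mu0, sd0, fixed = rep(FALSE, length(mu0)),
                         max_iter = 100, tol = 1e-7) {
  K <- length(mu0)
  mu <- mu0
  sdv <- pmax(sd0, 1e-12)
  trans <- matrix(0.02 / (K - 1), K, K); diag(trans) <- 0.98
  init <- rep(1 / K, K)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    fb <- hmm_forward_backward(y, mu, sdv, trans, init)
    ll_trace <- c(ll_trace, fb$loglik)
    g <- fb$gamma
    ns <- pmax(colSums(g), 1e-12)
    mu_new <- colSums(g * y) / ns
    sd_new <- sqrt(pmax(colSums(g * (outer(y, mu_new, "-"))^2) / ns, 1e-24))
    mu[!fixed] <- mu_new[!fixed]
    sdv[!fixed] <- sd_new[!fixed]
    xi <- fb$xi
    trans <- xi / pmax(rowSums(xi), 1e-300)
    trans <- pmax(trans, 1e-10)
    trans <- trans / rowSums(trans)
    init <- pmax(g[1L, ], 1e-10); init <- init / sum(init)
    if (is.finite(ll_old) && abs(fb$loglik - ll_old) < tol * (1 + abs(ll_old))) break
    ll_old <- fb$loglik
  }
  list(mu = mu, sd = sdv, trans = trans, init = init,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = it)
}

#' Segment a filtered angular trace into free and bound levels
#'
#' Fits Gaussian-emission hidden Markov models with K = 1 and K = 2
#' states to bin means of the filtered trace, selects K by BIC, and
#' returns the Viterbi state path expanded to full sampling rate. The
#' lower level is labelled `free`, the higher `bound` (site engagement
#' adds a positive twist offset). K = 2 fitting uses several
#' deterministic quantile-based initialisations and keeps the best
#' likelihood.
#'
#' @param trace An [angular_trace()]; if no `angle_filt_rad` column is
#'   present, a 100-point sliding average is applied first.
#' @param bin Bin width in samples for the HMM emissions; defaults to 4
#'   filter windows. Emissions are means of *raw* angle bins, wide
#'   enough that the correlated angular noise is ~independent between
#'   bins (correlated emissions reward spurious mode-splitting of a
#'   single level). State boundaries are then refined to the filtered
#'   trace's midpoint crossing, restoring filter-window resolution.
#' @param max_states Maximum number of levels considered (1 or 2).
#' @param max_iter,tol EM controls.
#' @return A `state_segmentation` object: per-sample `labels`
#'   (`free`/`bound` factor), fitted `levels` (rad), per-state
#'   `emission_sd` (bin scale), `noise_sd_filtered` (robust sd of the
#'   filtered residuals, rad), `segments` tibble, `K`, `bic`, `loglik`,
#'   and the bin series used.
#' @export
segment_two_level <- function(trace, bin = NULL, max_states = 2,
                              max_iter = 100, tol = 1e-7) {
  fs <- trace_sample_rate(trace)
  if (nrow(trace) / fs < 2) abort("need at least 2 s of data to segment.")
  if (is.null(trace$angle_filt_rad)) {
    trace <- sliding_average(trace, window = min(100L, nrow(trace)))
  }
  filt <- trace$angle_filt_rad
  win <- attr(trace, "metadata")$filter_window
  if (is.null(win)) win <- 100L
  if (is.null(bin)) bin <- 4L * win
  bin <- max(1L, as.integer(bin))
  y <- bin_means(trace$angle_rad, bin)
  ny <- length(y)
  if (ny < 10L) abort("too few bins; lower `bin` or provide a longer trace.")

  # every model carries a fixed broad "ramp" state far above the levels:
  # translocation excursions are strongly positive and non-stationary,
  # so without it they drag the bound level upwards
  med_y <- median(y)
  mad_y <- max(mad(y), 0.05 * sd(y), 1e-12)  # mad can degenerate to 0
  out_mu <- med_y + 10 * mad_y
  out_sd <- 10 * mad_y

  fit_levels <- function(K) {
    sdy <- max(sd(y), 1e-12)
    inits <- if (K == 1L) {
      list(med_y)
    } else {
      list(quantile(y, c(0.10, 0.90)), quantile(y, c(0.25, 0.75)),
           quantile(y, c(0.35, 0.65)),
           c(mean(y) - sdy, mean(y) + sdy),
           quantile(y, c(0.05, 0.60)))
    }
    best <- NULL
    for (ini in inits) {
      mu0 <- sort(as.numeric(ini))
      if (K == 2L && diff(mu0) < 1e-12) {
        mu0 <- mu0 + c(-1, 1) * max(sdy, 1e-9) / 2
      }
      fit <- tryCatch(
        em_hmm_gauss(y, c(mu0, out_mu),
                     c(rep(max(sdy / 2, 1e-9), K), out_sd),
                     fixed = c(rep(FALSE, K), TRUE), max_iter = max_iter,
                     tol = tol),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (is.null(best)) return(NULL)
    # order the level states ascending; the ramp state stays last
    o <- c(order(best$mu[seq_len(K)]), K + 1L)
    mu <- best$mu[o]; sdv <- best$sd[o]
    trans <- best$trans[o, o, drop = FALSE]
    init <- best$init[o]
    path <- hmm_viterbi(y, mu, sdv, trans, init)
    # free parameters: K means + K sds + (K+1) K transition probabilities
    p_free <- 2 * K + (K + 1L) * K
    list(K = K, mu = mu[seq_len(K)], sd = sdv[seq_len(K)],
         loglik = best$loglik, bic = -2 * best$loglik + p_free * log(ny),
         path = path, trans = trans, loglik_trace = best$loglik_trace)
  }

  fits <- list(fit_levels(1L))
  if (max_states >= 2) fits[[2L]] <- fit_levels(2L)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    abort("HMM did not converge in any of the restarts tried (6).")
  }

  pick <- which.min(vapply(fits, `[[`, numeric(1), "bic"))
  f <- fits[[pick]]
  state_names <- if (f$K == 1L) "free" else c("free", "bound")
  # ramp-state bins take the nearest level's label
  path_lab <- pmin(f$path, f$K)
  lab_bin <- factor(state_names[path_lab],
                    levels = c("free", "bound", "translocating"))

  # expand bin labels to full rate
  idx <- ceiling(seq_along(filt) / bin)
  labels <- lab_bin[idx]
  levels_rad <- setNames(vapply(seq_len(f$K), function(k) {
    yk <- y[f$path == k]
    if (length(yk)) median(yk) else f$mu[k]
  }, numeric(1)), state_names)

  # refine state boundaries to the filtered midpoint crossing nearest
  # the coarse boundary (the HMM bin grid is coarser than the filter)
  if (f$K == 2L && bin > 1L) {
    n_s <- length(labels)
    mid <- mean(levels_rad)
    bnd <- which(labels[-1L] != labels[-n_s])
    lab_chr <- as.character(labels)
    for (b in bnd) {
      lo <- max(1L, b - bin + 1L); hi <- min(n_s, b + bin)
      seg_f <- filt[lo:hi]
      cr <- which(diff(sign(seg_f - mid)) != 0)
      if (!length(cr)) next
      cut <- lo - 1L + cr[which.min(abs(lo - 1L + cr - b))]
      if (cut != b) {
        if (cut > b) {
          lab_chr[(b + 1L):cut] <- lab_chr[b]
        } else {
          lab_chr[(cut + 1L):b] <- lab_chr[b + 1L]
        }
      }
    }
    labels <- factor(lab_chr, levels = levels(labels))
  }

  # robust full-rate filtered residual sd (events appear as outliers)
  resid <- filt - levels_rad[as.character(labels)]
  noise_sd_filtered <- stats::mad(resid, center = 0)

  runs <- label_runs(labels)
  segments <- tibble(
    start_s = trace$time_s[runs$start_idx],
    end_s = trace$time_s[runs$end_idx] + 1 / fs,
    state = runs$value
  )

  structure(
    list(labels = labels, levels = levels_rad,
         emission_sd = setNames(f$sd, state_names),
         noise_sd_filtered = noise_sd_filtered,
         segments = segments, K = f$K, bic = f$bic, loglik = f$loglik,
         loglik_trace = f$loglik_trace, trans = f$trans,
         bin = bin, sample_rate_hz = fs,
         y_bin = y, labels_bin = lab_bin,
         time_bin_s = (seq_len(ny) - 0.5) * bin / fs),
    class = "state_segmentation"
  )
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("<state_segmentation> K = %d, %d segments\n", x$K,
              nrow(x$segments)))
  cat("levels (rad):", paste(sprintf("%s = %.3f", names(x$levels), x$levels),
                             collapse = ", "), "\n")
  cat(sprintf("filtered noise sd: %.3f rad; BIC: %.1f\n",
              x$noise_sd_filtered, x$bic))
  invisible(x)
}

#' Estimate the bound-state twist shift
#'
#' The shift is the bound level minus the free level. Levels are
#' re-estimated as medians of the per-bin means of each state (robust to
#' residual ramp contamination of the bound state); bins adjacent to a
#' state transition are excluded. The uncertainty combines the two
#' median standard errors, each corrected for residual bin-to-bin
#' autocorrelation via an AR(1) effective sample size.
#'
#' @param seg A `state_segmentation` with both states present (run
#'   [relabel_events()] first if events were detected, so translocating
#'   samples are excluded).
#' @return List with `shift_rad`, `se_rad`, per-state `levels_rad` and
#'   effective sample sizes.
#' @export
estimate_bound_shift <- function(seg) {
  if (seg$K < 2L || !all(c("free", "bound") %in% levels(droplevels(seg$labels_bin)))) {
    abort("both free and bound states must be present to estimate a shift.")
  }
  lb <- as.character(seg$labels_bin)
  nb <- length(lb)
  interior <- c(TRUE, lb[-1L] == lb[-nb]) & c(lb[-nb] == lb[-1L], TRUE)
  est <- lapply(c("free", "bound"), function(st) {
    y <- seg$y_bin[lb == st & interior]
    if (length(y) < 3L) abort(sprintf("too few %s bins for a level estimate.", st))
    neff <- ar1_neff(y)
    list(level = median(y), se = 1.2533 * sd(y) / sqrt(neff), neff = neff)
  })
  names(est) <- c("free", "bound")
  shift <- est$bound$level - est$free$level
  list(shift_rad = shift,
       se_rad = sqrt(est$free$se^2 + est$bound$se^2),
       levels_rad = c(free = est$free$level, bound = est$bound$level),
       n_eff = c(free = est$free$neff, bound = est$bound$neff))
}

#' Relabel samples inside detected events as translocating
#'
#' @param seg A `state_segmentation`.
#' @param events Event table from [detect_sawtooth_events()].
#' @return The segmentation with `labels`, `labels_bin` and `segments`
#'   updated.
#' @export
relabel_events <- function(seg, events) {
  if (nrow(events) == 0L) return(seg)
  fs <- seg$sample_rate_hz
  n <- length(seg$labels)
  lab <- seg$labels
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$start_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(events$end_s[i] * fs))
    lab[i0:i1] <- "translocating"
  }
  seg$labels <- lab
  # a bin is translocating if any of its samples is
  g <- ceiling(seq_len(n) / seg$bin)
  tr <- tapply(lab == "translocating", g, any)
  lb <- as.character(seg$labels_bin)
  lb[tr] <- "translocating"
  seg$labels_bin <- factor(lb, levels = levels(seg$labels))
  runs <- label_runs(lab)
  seg$segments <- tibble(
    start_s = (runs$start_idx - 1L) / fs,
    end_s = runs$end_idx / fs,
    state = runs$value
  )
  seg
}

#' Extract per-state dwell times from a segmentation
#'
#' Contiguous same-state intervals become dwells. Samples inside detected
#' events are relabelled `translocating` first, so bound dwells are split
#' at events. Dwells touching the trace boundaries are flagged censored;
#' bound dwells that begin within `post_tol_s` of an event end are tagged
#' `post_event`.
#'
#' @param seg A `state_segmentation`.
#' @param events Optional event table; when supplied, [relabel_events()]
#'   is applied first.
#' @param post_tol_s Tolerance for the post-event tag, s.
#' @return Tibble: `state`, `start_s`, `end_s`, `duration_s`, `censored`,
#'   `post_event`.
#' @export
extract_dwells <- function(seg, events = NULL, post_tol_s = 0.1) {
  if (!is.null(events)) seg <- relabel_events(seg, events)
  segs <- seg$segments
  total <- max(segs$end_s)
  out <- dplyr::mutate(
    segs,
    duration_s = .data$end_s - .data$start_s,
    censored = .data$start_s <= 0 | .data$end_s >= total - 1e-9
  )
  ends <- if (!is.null(events) && nrow(events)) events$end_s else numeric(0)
  out$post_event <- out$state == "bound" &
    vapply(out$start_s, function(s) any(abs(s - ends) <= post_tol_s), logical(1))
  out[, c("state", "start_s", "end_s", "duration_s", "censored", "post_event")]
}
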