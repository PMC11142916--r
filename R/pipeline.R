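# End-to-end orchestration: extract -> filter -> segment -> events ->
# statistics, with a manifest tying results to one configuration.

#' Run the full twist-trace analysis pipeline
#'
#' Stages, in order: load (or simulate) the angular trace; apply the
#' sliding-average filter; segment free/bound levels; detect, classify
#' and relabel sawtooth events; extract dwells; fit the population
#' statistics (Gaussian mixtures of event sizes and rates, exponential
#' mixture of bound dwells, summary fractions). Any stage error aborts
#' with the stage name. All effective parameters and seeds are echoed
#' into the manifest; identical configurations reproduce results
#' bit for bit.
#'
#' @param trace An [angular_trace()], a path to one, or `NULL` to
#'   simulate from `sim_config`.
#' @param sim_config A [rotor_sim_config()] used when `trace` is `NULL`.
#' @param filter_window Sliding-average window, samples.
#' @param event_params [sawtooth_params()] overrides.
#' @param cluster_gap,long_threshold Classification parameters
#'   ([classify_events()]).
#' @param size_K,rate_K Components of the size/rate Gaussian mixtures.
#' @param min_events Minimum classified events required before mixture
#'   fitting is attempted.
#' @param seed Seed for the mixture-fit restarts.
#' @param out_dir Optional directory; when given, the trace, event table,
#'   fits and manifest are written there.
#' @return A `nanorotor_results` list: `trace`, `seg`, `shift`, `events`,
#'   `dwells`, `fits` (list), `ground_truth` (when simulated),
#'   `manifest`.
#' @export
run_pipeline <- function(trace = NULL, sim_config = NULL,
                         filter_window = 100, event_params = sawtooth_params(),
                         cluster_gap = 2, long_threshold = 12,
                         size_K = 2, rate_K = 2, min_events = 10,
                         seed = 1, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  ground_truth <- NULL
  input_path <- NULL
  trace <- stage("load", {
    if (is.character(trace)) {
      input_path <- trace
      read_trace(trace)
    } else if (is.null(trace)) {
      if (is.null(sim_config)) abort("either `trace` or `sim_config` is required.")
      sim <- simulate_rotor_trace(sim_config)
      ground_truth <- sim$ground_truth
      sim$trace
    } else trace
  })
  if (nrow(trace) == 0L) abort("pipeline stage `load` failed: empty trace.")

  trace <- stage("filter", sliding_average(trace, window = filter_window))
  seg <- stage("segment", segment_two_level(trace))
  events <- stage("events", {
    ev <- detect_sawtooth_events(trace, seg, params = event_params)
    classify_events(ev, cluster_gap = cluster_gap,
                    long_threshold = long_threshold)
  })
  seg <- stage("events", relabel_events(seg, events))
  shift <- stage("segment", {
    if (seg$K >= 2L) estimate_bound_shift(seg) else NULL
  })
  dwells <- stage("events", extract_dwells(seg))

  fits <- stage("statistics", {
    out <- list()
    if (nrow(events) >= min_events) {
      out$size_mix <- fit_gaussian_mixture(events$max_loop_size_bp, K = size_K,
                                           seed = seed)
      out$rate_mix <- fit_gaussian_mixture(events$rate_bp_s, K = rate_K,
                                           seed = seed)
      out$fractions <- summarize_fractions(events)
    }
    bd <- dwells[dwells$state == "bound" & !dwells$censored, ]
    if (nrow(bd) >= 5L) {
      out$bound_dwell_fit <- fit_exp_mixture(bd$duration_s, Kmax = 2,
                                             seed = seed)
    }
    out
  })

  manifest <- run_manifest(
    inputs = input_path,
    params = list(filter_window = filter_window,
                  event_params = attr(events, "params"),
                  size_K = size_K, rate_K = rate_K,
                  sim_config = if (!is.null(ground_truth)) {
                    unclass(ground_truth$config)
                  }),
    seed = seed
  )

  res <- structure(
    list(trace = trace, seg = seg, shift = shift, events = events,
         dwells = dwells, fits = fits, ground_truth = ground_truth,
         manifest = manifest),
    class = "nanorotor_results"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tr_out <- trace
    tr_out$label <- as.character(seg$labels)
    write_trace(tr_out, file.path(out_dir, "trace.tsv"))
    write_events(events, file.path(out_dir, "events.tsv"))
    for (nm in names(fits)) {
      if (inherits(fits[[nm]], c("gauss_mix_fit", "exp_mix_fit"))) {
        write_json_result(fits[[nm]], file.path(out_dir, paste0(nm, ".json")))
      }
    }
    write_json_result(manifest, file.path(out_dir, "manifest.json"))
  }
  res
}

#' @export
print.nanorotor_results <- function(x, ...) {
  cat("<nanorotor_results>\n")
  cat(sprintf("  trace: %d samples at %.0f Hz (%.1f s)\n", nrow(x$trace),
              trace_sample_rate(x$trace), nrow(x$trace) / trace_sample_rate(x$trace)))
  cat(sprintf("  segmentation: K = %d", x$seg$K))
  if (!is.null(x$shift)) {
    cat(sprintf(", bound shift %.3f +/- %.3f rad", x$shift$shift_rad,
                x$shift$se_rad))
  }
  cat("\n")
  cat(sprintf("  events: %d detected\n", nrow(x$events)))
  for (nm in names(x$fits)) {
    if (inherits(x$fits[[nm]], c("gauss_mix_fit", "exp_mix_fit"))) {
      cat(sprintf("  -- %s --\n", nm)); print(x$fits[[nm]])
    }
  }
  invisible(x)
}
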