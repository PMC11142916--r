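# broom-style tidiers for the fitted objects.

#' @export
tidy.gauss_mix_fit <- function(x, ...) {
  tibble(component = seq_len(x$K), weight = x$weights, mean = x$means,
         sd = x$sds, se_mean = x$se_means)
}

#' @export
glance.gauss_mix_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, bic = x$bic, n = x$n,
         converged = x$converged)
}

#' @export
tidy.exp_mix_fit <- function(x, ...) {
  tibble(component = seq_len(x$K), weight = x$weights,
         lifetime_s = x$lifetimes, se_lifetime_s = x$se_lifetimes,
         se_weight = x$se_weights)
}

#' @export
glance.exp_mix_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, bic = x$bic,
         mean_lifetime_s = mixture_mean(x), n = x$n_used,
         n_censored = x$n_censored, censoring = x$censoring)
}

#' @export
tidy.exp_phase_fit <- function(x, ...) {
  np <- length(x$amplitudes)
  tibble(
    term = c("offset", paste0(rep(c("A", "k"), np),
                              rep(seq_len(np), each = 2))),
    estimate = c(x$offset, as.numeric(rbind(x$amplitudes, x$rates))),
    std.error = c(x$se_offset,
                  as.numeric(rbind(x$se_amplitudes, x$se_rates)))
  )
}

#' @export
glance.exp_phase_fit <- function(x, ...) {
  tibble(direction = x$direction, n_phases = length(x$amplitudes),
         sigma = x$sigma, no_kinetics = x$no_kinetics, n = x$n)
}

#' @export
tidy.burst_fit <- function(x, ...) {
  tibble(
    phase = c("fast", "slow"),
    atps_per_enzyme = c(x$fast_atps_per_enzyme, x$slow_atps_per_enzyme),
    rate_s = c(x$k_fast, x$k_slow),
    se_atps = c(x$se_fast, x$se_slow),
    se_rate_s = c(x$se_k_fast, x$se_k_slow)
  )
}

#' @export
glance.burst_fit <- function(x, ...) {
  tibble(enzyme_nM = x$enzyme_nM, model = x$model,
         slow_constrained = x$slow_constrained,
         calibration_slope = x$calibration$slope,
         calibration_intercept = x$calibration$intercept)
}

#' @export
tidy.state_segmentation <- function(x, ...) {
  as_tibble(x$segments)
}

#' @export
glance.state_segmentation <- function(x, ...) {
  tibble(K = x$K,
         level_free_rad = x$levels[["free"]],
         level_bound_rad = if (x$K >= 2L) x$levels[["bound"]] else NA_real_,
         noise_sd_filtered_rad = x$noise_sd_filtered,
         bic = x$bic, loglik = x$loglik, n_segments = nrow(x$segments))
}

#' @export
tidy.pbp_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}
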