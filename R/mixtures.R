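# Population fits for event sizes/rates (Gaussian mixtures) and dwell
# times (exponential mixtures), both by EM with seeded restarts. The EM
# loops record their log-likelihood trajectory so monotonicity can be
# asserted.

#' Fit a K-component Gaussian mixture by EM
#'
#' With `K = 1` the fit is the closed form: the sample mean and sample
#' standard deviation (n - 1 denominator). For `K >= 2`, EM runs from
#' several seeded initialisations and the best likelihood is kept;
#' components are returned sorted by ascending mean. Standard errors of
#' the means are `sd_k / sqrt(n_k)` with `n_k` the effective
#' (responsibility-weighted) component size.
#'
#' @param values Numeric observations (n >= 5 K).
#' @param K Number of components.
#' @param restarts Number of seeded EM restarts (K >= 2).
#' @param seed Seed for the restart jitter.
#' @param max_iter,tol EM controls.
#' @return A `gauss_mix_fit`: `K`, `weights`, `means`, `sds`, `se_means`,
#'   `loglik`, `bic`, `n`, `loglik_trace`.
#' @export
fit_gaussian_mixture <- function(values, K, restarts = 10, seed = 1,
                                 max_iter = 500, tol = 1e-8) {
  K <- as.integer(K)
  x <- as.numeric(values[is.finite(values)])
  n <- length(x)
  if (n < 5 * K) abort(sprintf("need at least %d values for K = %d.", 5 * K, K))
  if (sd(x) < .Machine$double.eps) {
    abort("degenerate input: all values identical.")
  }
  if (K == 1L) {
    m <- mean(x); s <- sd(x)
    ll <- sum(dnorm(x, m, s, log = TRUE))
    return(structure(
      list(K = 1L, weights = 1, means = m, sds = s, se_means = s / sqrt(n),
           loglik = ll, bic = -2 * ll + 2 * log(n), n = n,
           loglik_trace = ll, converged = TRUE),
      class = "gauss_mix_fit"
    ))
  }

  em_once <- function(mu0, sd0, w0) {
    mu <- mu0; sdv <- pmax(sd0, 1e-12); w <- w0
    ll_trace <- numeric(0)
    ll_old <- -Inf
    floor_sd <- 1e-6 * sd(x)
    for (it in seq_len(max_iter)) {
      ld <- vapply(seq_len(K),
                   function(k) log(w[k]) + dnorm(x, mu[k], sdv[k], log = TRUE),
                   numeric(n))
      mx <- apply(ld, 1L, max)
      p <- exp(ld - mx)
      rs <- rowSums(p)
      ll <- sum(mx + log(rs))
      ll_trace <- c(ll_trace, ll)
      g <- p / rs
      nk <- colSums(g)
      if (any(nk < 1e-8)) return(NULL)   # empty component
      w <- nk / n
      mu <- colSums(g * x) / nk
      sdv <- sqrt(colSums(g * (outer(x, mu, "-"))^2) / nk)
      if (any(sdv < floor_sd)) return(NULL)  # collapsing component
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll_old))) break
      ll_old <- ll
    }
    list(mu = mu, sd = sdv, w = w, loglik = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, g = g, converged = it < max_iter)
  }

  jit <- with_seed(seed, matrix(rnorm(restarts * K), restarts, K))
  best <- NULL
  for (r in seq_len(restarts)) {
    qs <- quantile(x, (seq_len(K) - 0.5) / K)
    mu0 <- sort(as.numeric(qs) + jit[r, ] * sd(x) / 4)
    fit <- em_once(mu0, rep(sd(x) / K, K), rep(1 / K, K))
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) {
    abort(sprintf("all %d EM restarts hit a degenerate component.", restarts))
  }
  o <- order(best$mu)
  nk <- colSums(best$g)[o]
  p_free <- 3 * K - 1
  structure(
    list(K = K, weights = best$w[o], means = best$mu[o], sds = best$sd[o],
         se_means = best$sd[o] / sqrt(nk),
         loglik = best$loglik, bic = -2 * best$loglik + p_free * log(n),
         n = n, loglik_trace = best$ll_trace, converged = best$converged),
    class = "gauss_mix_fit"
  )
}

#' @export
print.gauss_mix_fit <- function(x, ...) {
  cat(sprintf("<gauss_mix_fit> K = %d, n = %d, BIC = %.1f\n", x$K, x$n, x$bic))
  for (k in seq_len(x$K)) {
    cat(sprintf("  %d: weight %.2f, mean %.3f +/- %.3f (sd %.3f)\n",
                k, x$weights[k], x$means[k], x$se_means[k], x$sds[k]))
  }
  invisible(x)
}

exp_mix_loglik <- function(par, t_obs, t_cens) {
  K <- (length(par) + 1L) %/% 2L
  w <- if (K == 1L) 1 else c(par[seq_len(K - 1L)], 1 - sum(par[seq_len(K - 1L)]))
  tau <- par[K:(2L * K - 1L)]
  if (any(w <= 0) || any(tau <= 0)) return(-Inf)
  dens <- function(t) {
    m <- vapply(seq_len(K), function(k) w[k] / tau[k] * exp(-t / tau[k]),
                numeric(length(t)))
    rowSums(matrix(m, nrow = length(t)))
  }
  surv <- function(t) {
    m <- vapply(seq_len(K), function(k) w[k] * exp(-t / tau[k]),
                numeric(length(t)))
    rowSums(matrix(m, nrow = length(t)))
  }
  ll <- 0
  if (length(t_obs)) ll <- ll + sum(log(dens(t_obs)))
  if (length(t_cens)) ll <- ll + sum(log(surv(t_cens)))
  ll
}

#' Fit an exponential mixture to dwell times by EM, selecting K by BIC
#'
#' Lifetimes of a K-component exponential mixture are estimated by
#' maximum likelihood (EM); K is chosen between 1 and `Kmax` by BIC
#' unless forced with `K`. Censored dwells (flagged via `censored`) are
#' dropped by default; `censoring = "mle"` instead keeps them with a
#' right-censored likelihood (the E-step uses the exponential
#' memorylessness: a censored dwell contributes `t + tau_k` to component
#' k's mean). With `K = 1` and dropped censoring the estimate is the
#' closed-form MLE, the sample mean. Standard errors come from the
#' observed Fisher information (numerical Hessian).
#'
#' @param dwells Numeric dwell times, s.
#' @param K Force the number of components (`NULL` = select by BIC).
#' @param Kmax Largest K considered.
#' @param censoring `"drop"` or `"mle"`.
#' @param censored Logical vector marking boundary-truncated dwells.
#' @param restarts,seed,max_iter,tol EM controls.
#' @return An `exp_mix_fit`: `K`, `weights`, `lifetimes` (ascending, s),
#'   `se_lifetimes`, `se_weights`, `loglik`, `bic`, `bic_all`, `n_used`,
#'   `n_censored`, `censoring`, `loglik_trace`.
#' @export
fit_exp_mixture <- function(dwells, K = NULL, Kmax = 2, censoring = c("drop", "mle"),
                            censored = NULL, restarts = 10, seed = 1,
                            max_iter = 1000, tol = 1e-10) {
  censoring <- match.arg(censoring)
  t_all <- as.numeric(dwells)
  if (is.null(censored)) censored <- rep(FALSE, length(t_all))
  ok <- is.finite(t_all) & t_all > 0
  t_all <- t_all[ok]; censored <- censored[ok]
  if (censoring == "drop") {
    t_obs <- t_all[!censored]; t_cens <- numeric(0)
  } else {
    t_obs <- t_all[!censored]; t_cens <- t_all[censored]
  }
  if (length(t_obs) < 5L) abort("need at least 5 uncensored dwells.")
  n <- length(t_obs) + length(t_cens)

  fit_K <- function(Kk) {
    if (Kk == 1L) {
      tau <- (sum(t_obs) + sum(t_cens)) / length(t_obs)
      ll <- exp_mix_loglik(tau, t_obs, t_cens)
      return(list(K = 1L, w = 1, tau = tau, loglik = ll,
                  bic = -2 * ll + 1 * log(n), ll_trace = ll, converged = TRUE))
    }
    em_once <- function(tau0, w0) {
      tau <- tau0; w <- w0
      ll_trace <- numeric(0); ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        par <- c(w[-Kk], tau)
        ll <- exp_mix_loglik(par, t_obs, t_cens)
        ll_trace <- c(ll_trace, ll)
        # responsibilities
        lo <- vapply(seq_len(Kk),
                     function(k) log(w[k]) - log(tau[k]) - t_obs / tau[k],
                     numeric(length(t_obs)))
        go <- exp(lo - apply(lo, 1L, max))
        go <- go / rowSums(go)
        if (length(t_cens)) {
          lc <- vapply(seq_len(Kk),
                       function(k) log(w[k]) - t_cens / tau[k],
                       numeric(length(t_cens)))
          gc_ <- exp(lc - apply(lc, 1L, max))
          gc_ <- gc_ / rowSums(gc_)
        } else gc_ <- matrix(0, 0L, Kk)
        nk <- colSums(go) + colSums(gc_)
        if (any(nk < 1e-8)) return(NULL)
        # censored dwells contribute t + tau (memorylessness)
        num <- colSums(go * t_obs) +
          (if (length(t_cens)) colSums(gc_ * t_cens) + colSums(gc_) * tau else 0)
        tau <- num / nk
        w <- nk / n
        if (any(tau < 1e-12)) return(NULL)
        if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll_old))) break
        ll_old <- ll
      }
      list(tau = tau, w = w, loglik = ll_trace[length(ll_trace)],
           ll_trace = ll_trace, converged = it < max_iter)
    }
    qs <- with_seed(seed, replicate(restarts, sort(runif(Kk, 0.05, 0.95))))
    best <- NULL
    for (r in seq_len(restarts)) {
      tau0 <- as.numeric(quantile(t_obs, qs[, r])) / log(2)
      tau0 <- pmax(tau0, 1e-6 * mean(t_obs))
      fit <- em_once(tau0, rep(1 / Kk, Kk))
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
    }
    if (is.null(best)) return(NULL)
    o <- order(best$tau)
    list(K = Kk, w = best$w[o], tau = best$tau[o], loglik = best$loglik,
         bic = -2 * best$loglik + (2 * Kk - 1) * log(n),
         ll_trace = best$ll_trace, converged = best$converged)
  }

  Ks <- if (is.null(K)) seq_len(Kmax) else as.integer(K)
  fits <- lapply(Ks, fit_K)
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) abort("exponential-mixture EM failed for every K.")
  fits <- fits[keep]; Ks <- Ks[keep]
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  f <- fits[[which.min(bics)]]

  # observed Fisher information at the MLE
  par_hat <- c(if (f$K > 1L) f$w[-f$K] else NULL, f$tau)
  se <- rep(NA_real_, length(par_hat))
  hess <- tryCatch(
    pracma::hessian(function(p) -exp_mix_loglik(p, t_obs, t_cens), par_hat),
    error = function(e) NULL
  )
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }
  se_w <- if (f$K > 1L) c(se[seq_len(f$K - 1L)], se[1L]) else 0
  se_tau <- se[f$K:(2L * f$K - 1L)]
  if (f$K == 1L) se_tau <- f$tau / sqrt(length(t_obs))  # closed form

  structure(
    list(K = f$K, weights = f$w, lifetimes = f$tau,
         se_lifetimes = se_tau, se_weights = se_w,
         loglik = f$loglik, bic = f$bic,
         bic_all = setNames(bics, paste0("K", Ks)),
         n_used = n, n_censored = sum(censored),
         censoring = censoring, loglik_trace = f$ll_trace,
         converged = f$converged),
    class = "exp_mix_fit"
  )
}

#' @export
print.exp_mix_fit <- function(x, ...) {
  cat(sprintf("<exp_mix_fit> K = %d (BIC-selected), n = %d, censoring = %s\n",
              x$K, x$n_used, x$censoring))
  for (k in seq_len(x$K)) {
    cat(sprintf("  %d: weight %.2f, lifetime %.3f +/- %.3f s\n",
                k, x$weights[k], x$lifetimes[k], x$se_lifetimes[k]))
  }
  cat(sprintf("  mixture mean %.2f s\n", mixture_mean(x)))
  invisible(x)
}

#' Mean of an exponential mixture
#'
#' `sum(w_i * tau_i)`: e.g. components (0.41, 1.6 s) and (0.59, 35.4 s)
#' give a 21.5 s average lifetime.
#'
#' @param weights Mixture weights (sum to 1), or an `exp_mix_fit`.
#' @param lifetimes Component lifetimes, s (ignored when a fit is given).
#' @return Mean dwell time, s.
#' @export
mixture_mean <- function(weights, lifetimes = NULL) {
  if (inherits(weights, "exp_mix_fit")) {
    lifetimes <- weights$lifetimes
    weights <- weights$weights
  }
  m <- check_mixture(as.list(as.data.frame(rbind(weights, lifetimes))),
                     "mixture", 2L)
  sum(m[, 1L] * m[, 2L])
}

#' Event-population summary fractions with Wilson intervals
#'
#' Computes the fraction of events preceded by a resolvable bound state,
#' followed by a bound state, classed long-range, and clustered. The
#' pre-bound fraction counts unresolved assignments in its denominator
#' (an event whose preceding state cannot be assigned is thereby *not*
#' pre-bound); the post-bound fraction excludes unresolved post states,
#' since sub-resolution post-collapse dwells are unclassifiable.
#'
#' @param events A classified event table ([classify_events()]).
#' @param level Confidence level of the Wilson intervals.
#' @return Tibble: `metric`, `k`, `n`, `fraction`, `ci_lower`, `ci_upper`.
#' @export
summarize_fractions <- function(events, level = 0.95) {
  if (nrow(events) == 0L) abort("empty event list.")
  if (!"class" %in% names(events)) events <- classify_events(events)
  rows <- list(
    pre_bound = c(sum(events$pre_state == "bound"), nrow(events)),
    post_bound = c(sum(events$post_state == "bound"),
                   sum(events$post_state %in% c("bound", "free"))),
    long_range = c(sum(events$class == "long_range", na.rm = TRUE), nrow(events)),
    clustered = c(sum(events$class == "clustered", na.rm = TRUE), nrow(events))
  )
  purrr::map_dfr(names(rows), function(nm) {
    k <- rows[[nm]][1L]; n <- rows[[nm]][2L]
    if (n == 0L) {
      return(tibble(metric = nm, k = k, n = n, fraction = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_))
    }
    ci <- wilson_ci(k, n, level)
    tibble(metric = nm, k = k, n = n, fraction = k / n,
           ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  })
}
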