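# Internal helpers shared across modules.

# Run code with a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched. All stochastic operations in the package go
# through this so that a single seed makes a run reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# One master seed deterministically spawns independent per-stream seeds
# (dwells, event sizes, noise, ...) so adding a stream never perturbs
# the draws of another.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g.", name, upper))
  }
  invisible(x)
}

# Mixture components supplied as list of c(weight, par1[, par2]) rows.
# Returns a matrix with one row per component.
check_mixture <- function(components, name, n_par = 2L, tol = 1e-8) {
  if (is.matrix(components)) components <- asplit(components, 1L)
  if (!is.list(components) || length(components) == 0L) {
    abort(sprintf("`%s` must be a non-empty list of numeric vectors.", name))
  }
  m <- do.call(rbind, lapply(components, as.numeric))
  if (ncol(m) != n_par) {
    abort(sprintf("each component of `%s` must have %d entries.", name, n_par))
  }
  if (any(!is.finite(m))) abort(sprintf("`%s` contains non-finite values.", name))
  if (abs(sum(m[, 1L]) - 1) > tol) {
    abort(sprintf("weights in `%s` must sum to 1 (got %.6f).", name, sum(m[, 1L])))
  }
  if (any(m[, 1L] < 0)) abort(sprintf("weights in `%s` must be >= 0.", name))
  if (any(m[, 2L] <= 0)) {
    abort(sprintf("scale parameters in `%s` must be > 0.", name))
  }
  m
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# Effective-sample-size inflation factor for an AR(1)-correlated series:
# var(mean) ~ (sigma^2/n) * (1+rho)/(1-rho).
ar1_neff <- function(x) {
  n <- length(x)
  if (n < 10L) return(n)
  rho <- suppressWarnings(stats::cor(x[-n], x[-1L]))
  if (!is.finite(rho)) return(n)
  rho <- min(max(rho, 0), 0.99)
  n * (1 - rho) / (1 + rho)
}

# Means of non-overlapping bins of `width` samples (trailing partial bin
# kept as its own mean).
bin_means <- function(x, width) {
  n <- length(x)
  g <- ceiling(seq_len(n) / width)
  as.numeric(tapply(x, g, mean))
}

# Run-length segments of a label vector: tibble(start_idx, end_idx, value).
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  end <- cumsum(r$lengths)
  tibble(
    start_idx = c(1L, head(end, -1L) + 1L),
    end_idx = end,
    value = r$values
  )
}
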