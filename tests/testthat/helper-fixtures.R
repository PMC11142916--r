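# Shared fixtures, all generated in code.

# noiseless symmetric 2D Gaussian frame, 1-based pixel coordinates
render_gauss_frame <- function(x0, y0, nr = 41, nc = 41, sd = 1.5,
                               amplitude = 1000, background = 10) {
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  background + amplitude * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sd^2))
}

# exact circumcentre of three points (oracle for the circle fit)
circumcenter <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy)
}

# deterministic single-event rotor config: one forced sawtooth of given
# size (bp) and rate (bp/s) inside an otherwise quiet bound trace
single_event_config <- function(size_bp = 5, rate_bp_s = 11.4,
                                noise_sd = 0, duration = 30, seed = 1) {
  rotor_sim_config(
    duration = duration, noise_sd = noise_sd,
    dwell_free = 2,
    dwell_bound_components = list(c(1, 8)),
    post_bound_components = list(c(1, 3)),
    event_prob_per_bound = 1, p_cluster = 0,
    p_pre_bound = 1, p_post_bound = 1,
    size_modes = list(c(1, size_bp, 1e-6)),
    rate_modes = list(c(1, rate_bp_s, 1e-6)),
    couple_large_fast = FALSE, min_size = 0.5,
    seed = seed
  )
}
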