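# Independent oracles used across the suite. These deliberately avoid the
# package's fast code paths: brute-force sums, dense quadrature from the
# model primitives, explicit sorts.

# Explicit O(n^2) non-uniform discrete Fourier transform:
# y(k) = sum_j x[j] exp(-2i pi k . (j - c)), c = floor(n/2).
oracle_nudft <- function(img, coords) {
  n <- dim(img)[1]
  cen <- n %/% 2
  j <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))) - cen
  ph <- exp(-2i * pi * (coords %*% t(j)))
  as.vector(ph %*% as.vector(img))
}

# Dense midpoint quadrature of the signal integral, assembled from the
# exported model primitives only (independent of the analytic integrator
# and of simulate_timecourse's internal quadrature path).
oracle_signal <- function(t, i, params, seq, nodes_per_tr = 400L) {
  upper <- t - params$delta_t
  if (upper <= 0) return(0)
  lower <- max(0, upper - seq$labeling_duration)
  angles <- quadratic_flip_schedule(seq)
  breaks <- (0:seq$n_readouts) * seq$tr
  edges <- sort(unique(c(lower, upper, breaks[breaks > lower & breaks < upper])))
  total <- 0
  integrand <- function(td) {
    gamma_dispersion_kernel(td, params) *
      t1_recovery_factor(params$delta_t, td, seq$t1_blood) *
      rf_attenuation_factor(td, angles, seq$tr)
  }
  for (k in seq_len(length(edges) - 1)) {
    u <- edges[k]; v <- edges[k + 1]
    if (u == 0) {
      # graded substitution td = v * w^3 smooths the td^(p*s) factor
      h <- 1 / nodes_per_tr
      w <- (seq_len(nodes_per_tr) - 0.5) * h
      td <- v * w^3
      total <- total + sum(integrand(td) * 3 * v * w^2) * h
    } else {
      h <- (v - u) / nodes_per_tr
      td <- u + (seq_len(nodes_per_tr) - 0.5) * h
      total <- total + sum(integrand(td)) * h
    }
  }
  params$amplitude * sin(angles[i] * pi / 180) * total
}

oracle_timecourse <- function(params, seq, nodes_per_tr = 400L) {
  t_ex <- excitation_times(seq)
  vapply(seq_along(t_ex), function(i) {
    oracle_signal(t_ex[i], i, params, seq, nodes_per_tr)
  }, numeric(1))
}

# Largest nearest-neighbour angular gap within a set of spoke directions,
# treating each spoke as a full diameter (antipodal symmetry).
oracle_max_nn_gap <- function(dirs) {
  m <- nrow(dirs)
  gaps <- vapply(seq_len(m), function(i) {
    cosang <- abs(dirs[-i, , drop = FALSE] %*% dirs[i, ])
    min(acos(pmin(pmax(cosang, -1), 1)))
  }, numeric(1))
  max(gaps)
}
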