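# Shared fixtures: small, deterministic, built in code at test time.

# short-horizon profile for tests that only need qualitative dynamics
short_profile <- function() hypoxia_profile(t_onset = 2, ramp_tau = 1,
                                            alpha_min = 0.6, horizon = 30)

# compact single-cell matrix with planted structure
small_sc <- function(seed = 11, n_genes = 400, cells_per_state = 40, ...) {
  synth_sc_counts(seed,
                  states = c("MPP", "EEP", "CEP-1", "ProE"),
                  n_genes = n_genes, cells_per_state = cells_per_state,
                  progenitor_states = c("EEP", "CEP-1"), ...)
}

# brute-force O(n^2) pairwise-domination oracle for the Pareto front
pareto_oracle <- function(points) {
  n <- nrow(points)
  keep <- vapply(seq_len(n), function(i) {
    dominated <- vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      points$cost[j] <= points$cost[i] &&
        points$speed[j] >= points$speed[i] &&
        (points$cost[j] < points$cost[i] ||
           points$speed[j] > points$speed[i])
    }, logical(1))
    !any(dominated)
  }, logical(1))
  out <- points[keep, , drop = FALSE]
  out[order(out$cost, -out$speed), , drop = FALSE]
}
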