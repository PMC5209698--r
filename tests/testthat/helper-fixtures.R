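# Shared fixtures: the study induction curve, noiseless kinetic series,
# and a lazily built (then cached) bias lookup table reused across files.

study_curve <- function() induction_curve(2.23, 22, 4)

noiseless_series <- function(t_half, curve = study_curve(),
                             times = default_time_grid(), k_a = 0.01) {
  list(times = times,
       values = simulate_occupancy(kinetic_model(k_a, log(2) / t_half),
                                   curve, times))
}

cached_bias_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_bias_table(study_curve())
    tab
  }
})

# From-definition BH step-up (independent oracle for bh_adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force two-sample KS statistic: sup |F_a - F_b| over all jump points.
ks_stat_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}
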