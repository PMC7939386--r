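# Independent oracles used across the suite.

# Brute-force maximiser of the censored-exponential log-likelihood;
# independent of the closed-form estimator it checks.
brute_force_theta <- function(runs) {
  # locate the stationary point of the likelihood by a central-difference
  # score root; sharper than golden-section maximisation
  score <- function(l) {
    h <- l * 1e-6
    (run_length_loglik(l + h, runs) - run_length_loglik(l - h, runs)) /
      (2 * h)
  }
  1 / uniroot(score, interval = c(1e-6, 1e3), tol = 1e-13)$root
}

# A small deterministic censored run table used in several places.
toy_runs <- function() run_table(y = c(1, 2, 3), w = c(1, 1, 0))

# Random censored run tables for property-style loops.
random_run_table <- function(seed, n = 50) {
  set.seed(seed)
  tracks <- runif(n, 2, 15)
  landing <- runif(n, 0, tracks)
  t_end <- tracks - landing
  x <- rexp(n, 1 / runif(1, 1, 8))
  w <- as.integer(x <= t_end)
  run_table(y = pmin(x, t_end), w = w, t = t_end)
}

# Chi-squared goodness of fit of completed step counts against the
# geometric law with known per-step detachment probability.
geometric_gof_p <- function(steps, p_detach) {
  qs <- unique(qgeom(seq(0.1, 0.9, by = 0.1), p_detach))
  edges <- c(-1, qs, Inf)
  obs <- table(cut(steps, edges))
  expected <- diff(pgeom(edges, p_detach))
  suppressWarnings(chisq.test(as.vector(obs), p = expected)$p.value)
}
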