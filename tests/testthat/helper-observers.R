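# Shared builders for simulated-observer tests.

# A response-noise-free (fp = fn = 0), behaviourally clean observer with a
# flat field at `db` on every test location (blind spots stay at 0).
flat_observer <- function(db = 20, grid = build_grid("right"), seed = 7, ...) {
  sample_observer(hill_model(peak_db = db, slope_db_per_deg = 0,
                             interobserver_sd = 0, pointwise_sd = 0),
                  grid, fp_rate = 0, fn_rate = 0, dropout_prob = 0,
                  landing_error_sd_deg = 0, distance_drift_sd_cm = 0,
                  seed = seed, ...)
}

# A synthetic gaze stream with explicit sample positions at 50 Hz.
stream_at <- function(xy, n = 6, t0 = 0.3, rate = 50, valid = TRUE) {
  t <- t0 + (seq_len(n) - 1) / rate
  data.frame(t_s = t, x_deg = rep(xy[1], n), y_deg = rep(xy[2], n),
             valid = rep(valid, length.out = n))
}

# Brute-force discrete posterior: prior times the product of likelihood terms.
brute_posterior <- function(prior, domain, stimuli, responses, sigma) {
  pmf <- prior
  for (k in seq_along(stimuli)) {
    ps <- pnorm((domain - stimuli[k]) / sigma)
    pmf <- pmf * if (responses[k]) ps else 1 - ps
  }
  pmf / sum(pmf)
}

# Reproduce the bootstrap replicate stream of bca_bootstrap_ci (sorted data,
# seeded index draws) so tests can compare its quantiles independently.
with_boot_stats <- function(data, statistic, n_boot, seed) {
  data <- sort(data)
  n <- length(data)
  set.seed(seed)
  vapply(seq_len(n_boot), function(b)
    statistic(data[sample.int(n, n, replace = TRUE)]), numeric(1))
}
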