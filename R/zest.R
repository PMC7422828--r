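#' ZEST configuration
#'
#' Parameters of the Bayesian (ZEST) threshold procedure: the discrete dB
#' domain over which the posterior is maintained (integers 0..34), the fixed
#' slope of the cumulative-Gaussian likelihood (1.25 dB), the dynamic
#' termination criterion (posterior SD <= 1.5 dB), a safety cap on
#' presentations per location, and the default bimodal prior.
#'
#' The optional guess/lapse rates `gamma` and `lambda` extend the likelihood
#' to `gamma + (1 - gamma - lambda) * Phi((t - s) / sigma)`; both default to 0
#' (a pure cumulative Gaussian).
#'
#' @param db_domain Integer dB grid over which the posterior lives.
#' @param likelihood_slope_sigma Slope (SD) of the cumulative-Gaussian
#'   likelihood, dB.
#' @param termination_sd Posterior SD at or below which a location
#'   terminates, dB.
#' @param min_presentations Floor below which the dynamic criterion is not
#'   consulted: a location never terminates with fewer presentations. Guards
#'   against spuriously confident posteriors after one or two trials.
#' @param max_presentations Per-location presentation cap.
#' @param gamma,lambda Guess and lapse rates of the likelihood.
#' @param prior A [prior_spec()].
#' @return An object of class `zest_config`.
#' @export
zest_config <- function(db_domain = 0:34,
                        likelihood_slope_sigma = 1.25,
                        termination_sd = 1.5,
                        min_presentations = 4,
                        max_presentations = 20,
                        gamma = 0, lambda = 0,
                        prior = prior_spec()) {
  stopifnot(likelihood_slope_sigma > 0, termination_sd > 0,
            min_presentations >= 1, max_presentations >= min_presentations,
            all(diff(db_domain) > 0),
            gamma >= 0, lambda >= 0, gamma + lambda < 1)
  structure(list(db_domain = as.numeric(db_domain),
                 likelihood_slope_sigma = likelihood_slope_sigma,
                 termination_sd = termination_sd,
                 min_presentations = as.integer(min_presentations),
                 max_presentations = as.integer(max_presentations),
                 gamma = gamma, lambda = lambda,
                 prior = prior),
            class = "zest_config")
}

#' Bimodal prior specification
#'
#' The starting prior combines a healthy component (centred on the normative
#' sensitivity for the location) with a broad abnormal component at low dB,
#' so that both normal and damaged locations are reached quickly. The exact
#' component constants are conventions, not measurements, and are fully
#' overridable.
#'
#' @param healthy_mean,healthy_sd Mean and SD of the healthy component, dB.
#' @param abnormal_mean,abnormal_sd Mean and SD of the abnormal component, dB.
#' @param abnormal_weight Mixture weight of the abnormal component, in
#'   `[0, 1]`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(healthy_mean = 23, healthy_sd = 2,
                       abnormal_mean = 5, abnormal_sd = 8,
                       abnormal_weight = 0.2) {
  stopifnot(healthy_sd > 0, abnormal_sd > 0,
            abnormal_weight >= 0, abnormal_weight <= 1)
  structure(list(healthy_mean = healthy_mean, healthy_sd = healthy_sd,
                 abnormal_mean = abnormal_mean, abnormal_sd = abnormal_sd,
                 abnormal_weight = abnormal_weight),
            class = "prior_spec")
}

#' Evaluate the bimodal prior on the dB domain
#'
#' @param spec A [prior_spec()].
#' @param config A [zest_config()].
#' @return Normalised probability mass vector over `config$db_domain`.
#' @export
make_prior <- function(spec = prior_spec(), config = zest_config()) {
  d <- config$db_domain
  w <- spec$abnormal_weight
  pmf <- (1 - w) * stats::dnorm(d, spec$healthy_mean, spec$healthy_sd) +
    w * stats::dnorm(d, spec$abnormal_mean, spec$abnormal_sd)
  s <- sum(pmf)
  if (!is.finite(s) || s <= 0) stop("prior has zero mass on the dB domain")
  pmf / s
}

#' Probability of seeing a stimulus given a threshold
#'
#' The frequency-of-seeing likelihood: a cumulative Gaussian in dB,
#' `Phi((threshold - stimulus) / slope)`. Probability is 0.5 when the
#' stimulus sits at threshold, rises towards 1 for brighter (lower-dB)
#' stimuli, and falls towards 0 for dimmer ones. Optional guess/lapse rates
#' compress the curve into `[gamma, 1 - lambda]`.
#'
#' @param stimulus_db Stimulus attenuation, dB.
#' @param threshold_db Threshold attenuation, dB (vectorised).
#' @param slope Likelihood slope, dB.
#' @param gamma,lambda Guess and lapse rates.
#' @return Detection probability.
#' @export
p_seen <- function(stimulus_db, threshold_db, slope = 1.25,
                   gamma = 0, lambda = 0) {
  stopifnot(slope > 0)
  gamma + (1 - gamma - lambda) *
    stats::pnorm((threshold_db - stimulus_db) / slope)
}

#' Initialise the ZEST state for one location
#'
#' @param config A [zest_config()].
#' @param prior Optional [prior_spec()] overriding `config$prior`.
#' @param location Optional `c(x_deg, y_deg)` tag carried for bookkeeping.
#' @return An object of class `zest_state`: posterior pmf over the domain,
#'   presentation count, termination flag.
#' @export
zest_state <- function(config = zest_config(), prior = NULL, location = NULL) {
  pmf <- make_prior(if (is.null(prior)) config$prior else prior, config)
  structure(list(pmf = pmf, n_presentations = 0L, terminated = FALSE,
                 location = location),
            class = "zest_state")
}

#' Bayesian update of a ZEST state
#'
#' Multiplies the current posterior by the likelihood of the observed
#' response (`p_seen` for a hit, its complement for a miss) at every candidate
#' threshold, renormalises, and increments the presentation count.
#'
#' @param state A [zest_state()].
#' @param stimulus_db Presented stimulus attenuation, dB.
#' @param seen Logical: was the response a hit?
#' @param config The [zest_config()].
#' @return The updated `zest_state` (with `terminated` refreshed).
#' @export
zest_update <- function(state, stimulus_db, seen, config = zest_config()) {
  if (state$terminated) stop("cannot update a terminated ZEST state")
  ps <- p_seen(stimulus_db, config$db_domain, config$likelihood_slope_sigma,
               config$gamma, config$lambda)
  lik <- if (seen) ps else 1 - ps
  post <- state$pmf * lik
  s <- sum(post)
  if (!is.finite(s) || s <= 0) stop("posterior mass vanished in ZEST update")
  state$pmf <- post / s
  state$n_presentations <- state$n_presentations + 1L
  state$terminated <- is_terminated(state, config)
  state
}

posterior_moments <- function(state, config) {
  m <- sum(state$pmf * config$db_domain)
  v <- sum(state$pmf * (config$db_domain - m)^2)
  c(mean = m, sd = sqrt(v))
}

#' Posterior standard deviation of a ZEST state
#'
#' @inheritParams zest_update
#' @return Posterior SD in dB.
#' @export
posterior_sd <- function(state, config = zest_config()) {
  unname(posterior_moments(state, config)["sd"])
}

#' Next stimulus level for a ZEST state
#'
#' Standard ZEST placement: the posterior mean, snapped to the nearest value
#' on the dB domain; exact ties round down (towards the brighter stimulus).
#'
#' @inheritParams zest_update
#' @return A stimulus level from `config$db_domain`.
#' @export
next_stimulus <- function(state, config = zest_config()) {
  if (state$terminated) stop("location already terminated")
  m <- posterior_moments(state, config)["mean"]
  d <- config$db_domain
  dist <- abs(d - m)
  cand <- which(dist <= min(dist) + 1e-12)
  d[cand[1]]  # domain is increasing, so the first candidate is the lower tie
}

#' Has a ZEST state reached its termination criterion?
#'
#' Dynamic termination: the location stops once the spread (SD) of the
#' posterior is at or below `termination_sd` — consulted only after
#' `min_presentations` trials — or unconditionally when the presentation cap
#' is reached.
#'
#' @inheritParams zest_update
#' @return Logical.
#' @export
is_terminated <- function(state, config = zest_config()) {
  if (state$n_presentations >= config$max_presentations) return(TRUE)
  state$n_presentations >= config$min_presentations &&
    posterior_sd(state, config) <= config$termination_sd
}

#' Threshold estimate from a ZEST state
#'
#' The posterior mean (continuous, not snapped to the grid), clamped to the
#' dB domain.
#'
#' @inheritParams zest_update
#' @return Estimated sensitivity, dB.
#' @export
zest_estimate <- function(state, config = zest_config()) {
  m <- posterior_moments(state, config)["mean"]
  unname(pmin(pmax(m, min(config$db_domain)), max(config$db_domain)))
}

#' Seed a location's prior from completed neighbours
#'
#' Growth-pattern seeding: the healthy component of the prior is shifted by
#' the mean deviation (estimate minus normative value) observed at completed
#' neighbouring locations within one lattice step (6 degrees Chebyshev). With
#' no completed neighbour the prior specification is returned untouched.
#'
#' @param location `c(x_deg, y_deg)` of the location about to start.
#' @param completed Data frame of completed test locations with columns
#'   `x_deg`, `y_deg`, `estimate_db`, `normative_db`. May be empty.
#' @param normative_db Normative sensitivity at `location`, dB; becomes the
#'   healthy-component mean before shifting.
#' @param spec Base [prior_spec()] supplying the remaining constants.
#' @return A `prior_spec` for the location.
#' @export
seed_from_neighbors <- function(location, completed,
                                normative_db, spec = prior_spec()) {
  spec$healthy_mean <- normative_db
  if (!is.null(completed) && nrow(completed) > 0) {
    nb <- pmax(abs(completed$x_deg - location[1]),
               abs(completed$y_deg - location[2])) <= 6
    if (any(nb)) {
      shift <- mean(completed$estimate_db[nb] - completed$normative_db[nb])
      spec$healthy_mean <- normative_db + shift
    }
  }
  spec
}
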