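# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parametric hill-of-vision model
#'
#' Normal visual sensitivity declines roughly linearly with eccentricity from
#' a foveal peak (the "hill of vision"). The generator draws a per-observer
#' height offset and adds independent pointwise noise on top of the radial
#' profile. Defaults (peak 23 dB, 0.25 dB/deg falloff, 1 dB between-observer
#' and 1 dB pointwise SD) are a calibration chosen to land cohort mean
#' sensitivity near the high-teens/low-twenties dB regime typical of young
#' normally sighted adults on a 0--34 dB scale.
#'
#' @param peak_db Sensitivity at fixation, dB.
#' @param slope_db_per_deg Radial falloff, dB per degree of eccentricity.
#' @param interobserver_sd Between-observer SD of the hill height, dB.
#' @param pointwise_sd Within-observer location-to-location SD, dB.
#' @return An object of class `hill_model`.
#' @export
hill_model <- function(peak_db = 23, slope_db_per_deg = 0.25,
                       interobserver_sd = 1, pointwise_sd = 1) {
  stopifnot(peak_db >= 0, slope_db_per_deg >= 0,
            interobserver_sd >= 0, pointwise_sd >= 0)
  structure(list(peak_db = peak_db, slope_db_per_deg = slope_db_per_deg,
                 interobserver_sd = interobserver_sd,
                 pointwise_sd = pointwise_sd),
            class = "hill_model")
}

#' Expected hill-of-vision sensitivity at given locations
#'
#' The noise-free generator mean: `peak - slope * eccentricity`, clamped to
#' `[0, 34]`. Used both by the generator and as the default normative surface
#' for prior seeding.
#'
#' @param hill A [hill_model()].
#' @param grid A [build_grid()] result (or data frame with `x_deg`, `y_deg`).
#' @return Numeric vector of sensitivities, dB.
#' @export
hill_expectation <- function(hill, grid) {
  ecc <- sqrt(grid$x_deg^2 + grid$y_deg^2)
  pmin(pmax(hill$peak_db - hill$slope_db_per_deg * ecc, 0), 34)
}

#' Draw one simulated observer
#'
#' An observer is a set of true per-location thresholds on the test grid plus
#' the behavioural parameters that shape their responses: the slope of their
#' frequency-of-seeing curve, false-positive and false-negative rates,
#' saccade latency and landing error, tracker sample rate and dropout, and
#' trial-to-trial viewing-distance drift. Thresholds are
#' `clamp(peak - slope * ecc + observer offset + pointwise noise, 0, 34)`;
#' blind-spot locations are truly blind (threshold 0 and a hard `blind`
#' flag: nothing displayable is ever detected there, so only false-positive
#' responses occur).
#'
#' Optional `defects` carve simulated field loss out of the hill: each is a
#' `list(polygon = <n x 2 matrix of x_deg, y_deg vertices>, depth_db = <dB>)`
#' subtracted at every grid point inside the polygon (e.g. arcuate,
#' nerve-fibre-bundle-shaped regions).
#'
#' @param hill A [hill_model()].
#' @param grid A [build_grid()] result.
#' @param fos_slope_db Frequency-of-seeing slope, dB. Defaults to 1.25 so a
#'   matched observer is exactly the ZEST likelihood; change it to create
#'   model mismatch.
#' @param fp_rate,fn_rate False-positive and false-negative response rates.
#' @param saccade_latency_mean_s,saccade_latency_sd_s Saccade latency
#'   distribution, seconds.
#' @param landing_error_sd_deg Per-saccade landing error SD, degrees.
#' @param sample_rate_hz Eye-tracker sample rate.
#' @param dropout_prob Per-sample probability of an invalid tracker sample.
#' @param distance_drift_sd_cm Per-trial random-walk SD of viewing distance.
#' @param defects Optional list of simulated field defects (see above).
#' @param seed RNG seed; the same seed reproduces the observer exactly.
#' @return An object of class `sim_observer`.
#' @export
sample_observer <- function(hill = hill_model(), grid = build_grid("right"),
                            fos_slope_db = 1.25,
                            fp_rate = 0.028, fn_rate = 0.073,
                            saccade_latency_mean_s = 0.3,
                            saccade_latency_sd_s = 0.05,
                            landing_error_sd_deg = 0.5,
                            sample_rate_hz = 50,
                            dropout_prob = 0.02,
                            distance_drift_sd_cm = 0.5,
                            defects = NULL,
                            seed = 1) {
  stopifnot(fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate < 1,
            fos_slope_db > 0, sample_rate_hz > 0)
  thr <- with_seed(seed, {
    base <- hill$peak_db - hill$slope_db_per_deg *
      sqrt(grid$x_deg^2 + grid$y_deg^2)
    base <- base + stats::rnorm(1, 0, hill$interobserver_sd) +
      stats::rnorm(nrow(grid), 0, hill$pointwise_sd)
    base
  })
  if (!is.null(defects)) {
    for (d in defects) {
      inside <- point_in_polygon(grid$x_deg, grid$y_deg, d$polygon)
      thr[inside] <- thr[inside] - d$depth_db
    }
  }
  thr <- pmin(pmax(thr, 0), 34)
  blind <- grid$role == "blind_spot"
  thr[blind] <- 0
  structure(list(true_thresholds = thr, blind = blind, grid = grid,
                 fos_slope_db = fos_slope_db,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 saccade_latency_mean_s = saccade_latency_mean_s,
                 saccade_latency_sd_s = saccade_latency_sd_s,
                 landing_error_sd_deg = landing_error_sd_deg,
                 sample_rate_hz = sample_rate_hz,
                 dropout_prob = dropout_prob,
                 distance_drift_sd_cm = distance_drift_sd_cm,
                 seed = seed),
            class = "sim_observer")
}

# Ray-casting point-in-polygon; polygon an n x 2 matrix, vertices in order.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Latent detection response of a simulated observer
#'
#' Draws whether the observer notices a stimulus, from the error-adjusted
#' frequency-of-seeing curve
#' `p = fp + (1 - fp - fn) * Phi((threshold - stimulus) / fos_slope)`.
#' Blind-spot locations detect nothing displayable, so their response is a
#' false positive with probability `fp` regardless of intensity. A blank
#' (invisible) stimulus may be passed as `stimulus_db = Inf`, for which the
#' curve collapses to `fp` at any location.
#'
#' @param observer A [sample_observer()].
#' @param location_index Row index of the location in `observer$grid`.
#' @param stimulus_db Stimulus attenuation, dB (`Inf` for a blank).
#' @return Logical: did the observer see (respond to) the stimulus? Uses the
#'   current global RNG stream.
#' @export
respond <- function(observer, location_index, stimulus_db) {
  p <- if (observer$blind[location_index] || is.infinite(stimulus_db)) {
    observer$fp_rate
  } else {
    t <- observer$true_thresholds[location_index]
    observer$fp_rate + (1 - observer$fp_rate - observer$fn_rate) *
      stats::pnorm((t - stimulus_db) / observer$fos_slope_db)
  }
  stats::runif(1) < p
}

#' Synthesise a gaze stream for one presentation
#'
#' Generates tracker samples (nominally 50 Hz) in visual-field degrees
#' relative to the pre-trial fixation point. A seen trial holds fixation
#' (with small jitter) until a saccade latency drawn from the observer's
#' latency distribution, then lands on the target with a per-saccade landing
#' error plus per-sample jitter. An unseen trial holds fixation throughout,
#' except that with probability `fp_rate` an erroneous saccade is made to a
#' random location in the trackable region. Samples drop out (become
#' invalid) with the observer's `dropout_prob`.
#'
#' @param observer A [sample_observer()].
#' @param seen Logical latent response (from [respond()]).
#' @param target_deg Target offset `c(x, y)` relative to fixation, degrees.
#' @param trial_duration_s Stream duration, seconds.
#' @param fixation_jitter_sd_deg SD of fixational gaze noise, degrees.
#' @param sample_jitter_sd_deg SD of post-saccade per-sample noise, degrees.
#' @return A gaze-stream data frame (`t_s`, `x_deg`, `y_deg`, `valid`) in
#'   the dialect accepted by [classify_response()].
#' @export
gaze_stream <- function(observer, seen, target_deg, trial_duration_s = 2,
                        fixation_jitter_sd_deg = 0.3,
                        sample_jitter_sd_deg = 0.2) {
  n <- round(trial_duration_s * observer$sample_rate_hz)
  t_s <- seq_len(n) / observer$sample_rate_hz
  x <- stats::rnorm(n, 0, fixation_jitter_sd_deg)
  y <- stats::rnorm(n, 0, fixation_jitter_sd_deg)
  goal <- NULL
  if (seen) {
    goal <- target_deg + stats::rnorm(2, 0, observer$landing_error_sd_deg)
  } else if (stats::runif(1) < observer$fp_rate) {
    goal <- c(stats::runif(1, -27, 27), stats::runif(1, -15, 15))
  }
  if (!is.null(goal)) {
    lat <- max(0.08, stats::rnorm(1, observer$saccade_latency_mean_s,
                                  observer$saccade_latency_sd_s))
    post <- t_s > lat
    x[post] <- goal[1] + stats::rnorm(sum(post), 0, sample_jitter_sd_deg)
    y[post] <- goal[2] + stats::rnorm(sum(post), 0, sample_jitter_sd_deg)
  }
  data.frame(t_s = t_s, x_deg = x, y_deg = y,
             valid = stats::runif(n) >= observer$dropout_prob)
}

#' Draw a cohort of independent simulated observers
#'
#' Per-observer seeds are derived deterministically from the master seed, so
#' the whole cohort reproduces exactly while observers stay independent.
#'
#' @param n Number of observers.
#' @param hill A [hill_model()].
#' @param grid A [build_grid()] result.
#' @param seed Master seed.
#' @param ... Behavioural parameters forwarded to [sample_observer()].
#' @return List of `sim_observer` objects.
#' @export
sample_cohort <- function(n, hill = hill_model(), grid = build_grid("right"),
                          seed = 1, ...) {
  if (n == 0) return(list())
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seeds, function(s)
    sample_observer(hill = hill, grid = grid, seed = s, ...))
}
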