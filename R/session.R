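#' Session configuration
#'
#' All knobs of a full perimetric test session in one object: display and
#' viewing geometry, ZEST parameters, the classifier's eccentricity model,
#' catch-trial rate, refixation behaviour, the normative surface used to
#' centre priors, and the prior for blind-spot locations (centred low, since
#' their expected sensitivity is ~0).
#'
#' @param screen A [screen_model()].
#' @param distance_cm Nominal starting viewing distance, cm.
#' @param trackbox_deg Tracker half-extents, degrees `c(h, v)`.
#' @param zest A [zest_config()].
#' @param classifier_model Coefficient list for [params_for_eccentricity()],
#'   or `NULL` for its default.
#' @param catch_rate Per-trial probability that a catch trial (blank or
#'   maximum-luminance, 50/50) is inserted instead of a test trial. The
#'   default 0.07 yields on the order of 20 catch trials in a typical
#'   session.
#' @param p_unstable_fixation Per-trial probability that fixation is unstable
#'   at trial onset, forcing a refixation trial.
#' @param max_placement_retries Refixation attempts before a placement is
#'   abandoned for this trial.
#' @param max_unplaceable Abandoned placements after which a location is
#'   flagged unmeasured.
#' @param max_total_trials Safety cap on the whole session.
#' @param trial_duration_s Gaze-stream duration recorded per presentation.
#' @param simulate_gaze If `TRUE` (default) every presentation synthesises a
#'   gaze stream that is scored by the saccadic classifier; if `FALSE` the
#'   observer's latent response is used directly (fast path that isolates
#'   the thresholding layer).
#' @param normative A [hill_model()] providing the normative surface that
#'   centres location priors, or a numeric vector of per-location dB values.
#' @param blind_prior [prior_spec()] used at blind-spot locations.
#' @param stimulus_diameter_deg Stimulus angular diameter (Goldmann III).
#' @param blur_sigma_deg Gaussian edge-blur sigma, degrees. Recorded in the
#'   configuration for completeness; this package does not render stimuli.
#' @return An object of class `session_config`.
#' @export
session_config <- function(screen = screen_model(),
                           distance_cm = 60,
                           trackbox_deg = c(27, 15),
                           zest = zest_config(),
                           classifier_model = NULL,
                           catch_rate = 0.07,
                           p_unstable_fixation = 0.03,
                           max_placement_retries = 3,
                           max_unplaceable = 10,
                           max_total_trials = 3000,
                           trial_duration_s = 2,
                           simulate_gaze = TRUE,
                           normative = hill_model(),
                           blind_prior = prior_spec(healthy_mean = 2,
                                                    healthy_sd = 3,
                                                    abnormal_mean = 0,
                                                    abnormal_sd = 2,
                                                    abnormal_weight = 0.5),
                           stimulus_diameter_deg = 0.43,
                           blur_sigma_deg = 0.1) {
  stopifnot(catch_rate >= 0, catch_rate <= 0.5,
            p_unstable_fixation >= 0, p_unstable_fixation < 1,
            max_placement_retries >= 1, max_total_trials > 0)
  structure(list(screen = screen, distance_cm = distance_cm,
                 trackbox_deg = trackbox_deg, zest = zest,
                 classifier_model = classifier_model,
                 catch_rate = catch_rate,
                 p_unstable_fixation = p_unstable_fixation,
                 max_placement_retries = max_placement_retries,
                 max_unplaceable = max_unplaceable,
                 max_total_trials = max_total_trials,
                 trial_duration_s = trial_duration_s,
                 simulate_gaze = simulate_gaze,
                 normative = normative,
                 blind_prior = blind_prior,
                 stimulus_diameter_deg = stimulus_diameter_deg,
                 blur_sigma_deg = blur_sigma_deg),
            class = "session_config")
}

classifier_for <- function(target_deg, model) {
  if (is.null(model)) params_for_eccentricity(target_deg)
  else params_for_eccentricity(target_deg, model)
}

#' Run a full simulated perimetric session
#'
#' Orchestrates one complete test on a simulated observer: locations are
#' scheduled uniformly at random from the currently active set (the current
#' growth-pattern stage plus the blind-spot points, which are tested
#' throughout); each trial waits for stable fixation, places the target
#' gaze-contingently on the tangent screen (triggering a refixation trial on
#' placement failure), presents it, scores the response — by synthesising a
#' gaze stream and running the saccadic classifier, unless
#' `simulate_gaze = FALSE` — and feeds the outcome to the location's ZEST
#' state. Catch trials (blank or maximum luminance) are randomly interleaved
#' and never touch the threshold estimates. A growth stage opens once every
#' location of the previous stage has terminated, with each new location's
#' prior seeded from its completed neighbours. The session ends when all 46
#' locations have terminated (or caps are hit) and is fully reproducible
#' under `seed`.
#'
#' @param observer A [sample_observer()].
#' @param config A [session_config()].
#' @param seed Integer seed for everything stochastic in the session.
#' @return An object of class `test_result`: `locations` (data frame with
#'   `x_deg`, `y_deg`, `role`, `group`, `dls_db`, `n_presentations`,
#'   `terminated`, `posterior_sd_db`, `unmeasured`), `trial_log`, trial
#'   counts by type (`n_trials`), estimated catch-trial error rates
#'   (`fp_rate_est`, `fn_rate_est`), refixation count, and `eye`.
#' @export
run_session <- function(observer, config = session_config(), seed = 1) {
  with_seed(seed, run_session_impl(observer, config))
}

run_session_impl <- function(observer, config) {
  grid <- observer$grid
  nloc <- nrow(grid)
  zc <- config$zest
  normative <- if (inherits(config$normative, "hill_model"))
    hill_expectation(config$normative, grid) else rep_len(config$normative, nloc)

  states <- vector("list", nloc)
  unplaceable <- integer(nloc)
  unmeasured <- logical(nloc)
  bs <- which(grid$role == "blind_spot")
  for (i in bs) states[[i]] <- zest_state(zc, prior = config$blind_prior,
                                          location = c(grid$x_deg[i], grid$y_deg[i]))

  open_stage <- function(k) {
    done <- which(grid$role == "test" & !vapply(states, is.null, TRUE) &
                    vapply(states, function(s) isTRUE(s$terminated), TRUE))
    completed <- if (length(done)) data.frame(
      x_deg = grid$x_deg[done], y_deg = grid$y_deg[done],
      estimate_db = vapply(states[done], zest_estimate, 0, config = zc),
      normative_db = normative[done]) else NULL
    for (i in which(grid$group == k)) {
      sp <- seed_from_neighbors(c(grid$x_deg[i], grid$y_deg[i]),
                                completed, normative[i], zc$prior)
      states[[i]] <<- zest_state(zc, prior = sp,
                                 location = c(grid$x_deg[i], grid$y_deg[i]))
    }
  }
  stage <- 1L
  n_stages <- max(grid$group)
  open_stage(stage)

  fixation_angle <- c(0, 0)           # gaze direction, deg from screen centre
  distance <- config$distance_cm
  log_rows <- vector("list", config$max_total_trials)
  nlog <- 0L
  n_refix <- 0L
  catch <- c(blank_n = 0L, blank_hit = 0L, supra_n = 0L, supra_miss = 0L)

  term <- function(i) !is.null(states[[i]]) &&
    (states[[i]]$terminated || unmeasured[i])
  push <- function(row) { nlog <<- nlog + 1L; log_rows[[nlog]] <<- row }

  while (nlog < config$max_total_trials) {
    # advance growth stages whose locations have all finished
    while (stage < n_stages &&
           all(vapply(which(grid$group == stage), term, TRUE))) {
      stage <- stage + 1L
      open_stage(stage)
    }
    active <- which((grid$group == stage | grid$role == "blind_spot") &
                      !vapply(seq_len(nloc), term, TRUE))
    if (!length(active)) {
      if (all(vapply(seq_len(nloc), term, TRUE))) break
      next
    }

    is_catch <- stats::runif(1) < config$catch_rate
    if (is_catch) {
      type <- if (stats::runif(1) < 0.5) "catch_blank" else "catch_supra"
      cand <- active[grid$role[active] == "test"]
      if (!length(cand)) cand <- which(grid$role == "test")
      i <- if (length(cand) > 1) sample(cand, 1) else cand
    } else {
      type <- "test"
      i <- if (length(active) > 1) sample(active, 1) else active
    }
    target <- c(grid$x_deg[i], grid$y_deg[i])

    # viewing-distance random walk, kept inside the tracker's focal range
    distance <- min(70, max(50, distance +
                              stats::rnorm(1, 0, observer$distance_drift_sd_cm)))

    # fixation-stability gate and gaze-contingent placement, with refixation
    placed <- FALSE
    for (attempt in seq_len(config$max_placement_retries)) {
      unstable <- stats::runif(1) < config$p_unstable_fixation
      viewer <- viewer_state(distance_cm = distance,
                             fixation_px = angle_to_px(fixation_angle,
                                                       list(distance_cm = distance),
                                                       config$screen),
                             trackbox_deg = config$trackbox_deg,
                             screen = config$screen)
      chk <- if (unstable) list(valid = FALSE, reason = "unstable_fixation")
      else placement_valid(target, viewer, config$screen,
                           config$stimulus_diameter_deg)
      if (chk$valid) { placed <- TRUE; break }
      n_refix <- n_refix + 1L
      push(list(type = "refixation", x_deg = NA_real_, y_deg = NA_real_,
                stimulus_db = NA_real_, outcome = chk$reason,
                viewing_distance_cm = distance))
      # attention-grabbing recentering: gaze returns near screen centre
      fixation_angle <- stats::rnorm(2, 0, 1)
      if (nlog >= config$max_total_trials) break
    }
    if (!placed) {
      unplaceable[i] <- unplaceable[i] + 1L
      if (unplaceable[i] >= config$max_unplaceable && type == "test")
        unmeasured[i] <- TRUE
      next
    }
    placement <- field_offset_to_px(target, viewer, config$screen)

    stimulus_db <- switch(type,
                          test = next_stimulus(states[[i]], zc),
                          catch_blank = Inf,
                          catch_supra = 0)
    seen <- respond(observer, i, stimulus_db)
    if (config$simulate_gaze) {
      stream <- gaze_stream(observer, seen, target, config$trial_duration_s)
      cls <- classify_response(stream, target,
                               classifier_for(target, config$classifier_model))
      hit <- cls$hit
    } else {
      hit <- seen
    }

    if (type == "test") {
      states[[i]] <- zest_update(states[[i]], stimulus_db, hit, zc)
    } else if (type == "catch_blank") {
      catch["blank_n"] <- catch["blank_n"] + 1L
      if (hit) catch["blank_hit"] <- catch["blank_hit"] + 1L
    } else {
      catch["supra_n"] <- catch["supra_n"] + 1L
      if (!hit) catch["supra_miss"] <- catch["supra_miss"] + 1L
    }
    push(list(type = type, x_deg = target[1], y_deg = target[2],
              stimulus_db = stimulus_db,
              outcome = if (hit) "hit" else "miss",
              viewing_distance_cm = distance))

    # a hit ends with gaze on the target; a miss leaves fixation in place
    if (hit) fixation_angle <- fixation_angle + target + stats::rnorm(2, 0, 0.3)
    # keep the notional fixation inside the trackable region
    fixation_angle <- pmin(pmax(fixation_angle, -config$trackbox_deg * 0.9),
                           config$trackbox_deg * 0.9)
  }

  trial_log <- do.call(rbind, lapply(log_rows[seq_len(nlog)], as.data.frame))
  if (is.null(trial_log))
    trial_log <- data.frame(type = character(), x_deg = numeric(),
                            y_deg = numeric(), stimulus_db = numeric(),
                            outcome = character(),
                            viewing_distance_cm = numeric())
  trial_log$index <- seq_len(nrow(trial_log)) - 1L   # 0-based
  trial_log <- trial_log[c("index", setdiff(names(trial_log), "index"))]

  locations <- data.frame(
    x_deg = grid$x_deg, y_deg = grid$y_deg, role = grid$role,
    group = grid$group,
    dls_db = vapply(seq_len(nloc), function(i)
      if (is.null(states[[i]])) NA_real_ else zest_estimate(states[[i]], zc), 0),
    n_presentations = vapply(seq_len(nloc), function(i)
      if (is.null(states[[i]])) 0L else states[[i]]$n_presentations, 0L),
    terminated = vapply(seq_len(nloc), function(i)
      !is.null(states[[i]]) && states[[i]]$terminated, TRUE),
    posterior_sd_db = vapply(seq_len(nloc), function(i)
      if (is.null(states[[i]])) NA_real_ else posterior_sd(states[[i]], zc), 0),
    unmeasured = unmeasured)

  er <- estimate_error_rates(trial_log)
  structure(list(locations = locations,
                 trial_log = trial_log,
                 n_trials = c(test = sum(trial_log$type == "test"),
                              catch_blank = unname(catch["blank_n"]),
                              catch_supra = unname(catch["supra_n"]),
                              refixation = n_refix),
                 fp_rate_est = unname(er["fp"]), fn_rate_est = unname(er["fn"]),
                 n_refixations = n_refix,
                 eye = attr(grid, "eye")),
            class = "test_result")
}

#' Estimate false-positive and false-negative rates from a trial log
#'
#' The false-positive rate is the fraction of blank catch trials answered
#' with a hit; the false-negative rate is the fraction of maximum-luminance
#' catch trials answered with a miss. With no catch trials of a kind, the
#' corresponding rate is `NA` (undefined) rather than 0.
#'
#' @param trial_log A `test_result$trial_log` data frame.
#' @return Named numeric vector `c(fp =, fn =)`.
#' @export
estimate_error_rates <- function(trial_log) {
  blank <- trial_log$type == "catch_blank"
  supra <- trial_log$type == "catch_supra"
  fp <- if (any(blank)) mean(trial_log$outcome[blank] == "hit") else NA_real_
  fn <- if (any(supra)) mean(trial_log$outcome[supra] == "miss") else NA_real_
  c(fp = fp, fn = fn)
}

#' @export
print.test_result <- function(x, ...) {
  tp <- x$locations$role == "test"
  cat("Simulated perimetric test (", x$eye, " eye)\n", sep = "")
  cat(sprintf("  mean sensitivity: %.2f dB over %d test locations\n",
              mean(x$locations$dls_db[tp]), sum(tp)))
  cat(sprintf("  trials: %d test, %d blank catch, %d supra catch, %d refixation\n",
              x$n_trials["test"], x$n_trials["catch_blank"],
              x$n_trials["catch_supra"], x$n_trials["refixation"]))
  cat(sprintf("  catch-trial error rates: fp = %s, fn = %s\n",
              format(x$fp_rate_est, digits = 3),
              format(x$fn_rate_est, digits = 3)))
  invisible(x)
}
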