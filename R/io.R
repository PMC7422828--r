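#' Default run configuration
#'
#' The full configuration tree of a simulation run as a plain nested list of
#' scalars, suitable for lossless JSON/YAML round-tripping. Every default in
#' the package is represented here and overridable from a config file.
#'
#' @return Nested list with sections `seed`, `eye`, `screen`, `viewer`,
#'   `luminance`, `zest`, `classifier`, `session`, `observer`, `cohort`,
#'   `stats`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    eye = "right",
    screen = list(width_cm = 59.7, height_cm = 33.6,
                  width_px = 2560, height_px = 1440,
                  prohibited_zones = NULL),
    viewer = list(distance_cm = 60, trackbox_deg = c(27, 15)),
    luminance = list(background_cd_m2 = 10, max_increment_cd_m2 = 225,
                     hfa_max_increment_cd_m2 = 3183.1, db_domain_max = 34),
    zest = list(db_domain_min = 0L, db_domain_max = 34L,
                likelihood_slope_sigma = 1.25, termination_sd = 1.5,
                min_presentations = 4L, max_presentations = 20L,
                gamma = 0, lambda = 0,
                prior = list(healthy_mean = 23, healthy_sd = 2,
                             abnormal_mean = 5, abnormal_sd = 8,
                             abnormal_weight = 0.2)),
    classifier = list(n_base = 6, d_base = 2.77, d_gain = 0.06,
                      r_base = 1.62, r_gain = 0.04,
                      anchor_ecc_deg = sqrt(162), d_min = 1, r_min = 0.5),
    session = list(catch_rate = 0.07, p_unstable_fixation = 0.03,
                   max_placement_retries = 3L, max_unplaceable = 10L,
                   max_total_trials = 3000L, trial_duration_s = 2,
                   simulate_gaze = TRUE, stimulus_diameter_deg = 0.43,
                   blur_sigma_deg = 0.1),
    observer = list(hill = list(peak_db = 23, slope_db_per_deg = 0.25,
                                interobserver_sd = 1, pointwise_sd = 1),
                    fos_slope_db = 1.25, fp_rate = 0.028, fn_rate = 0.073,
                    saccade_latency_mean_s = 0.3, saccade_latency_sd_s = 0.05,
                    landing_error_sd_deg = 0.5, sample_rate_hz = 50,
                    dropout_prob = 0.02, distance_drift_sd_cm = 0.5),
    cohort = list(n_observers = 4L, n_runs = 2L),
    stats = list(n_boot = 20000L, conf_level = 0.95, alpha_pointwise = 0.01)
  )
}

# Recursively merge user values onto defaults; unknown keys are errors.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user) || is.null(names(user)))
    return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user))   # [[<-]] with NULL would delete the key
    defaults[k] <- list(merge_config(defaults[[k]], user[[k]],
                                     paste0(path, ".", k)))
  defaults
}

#' Load a run configuration from JSON or YAML
#'
#' Reads the file (format chosen by extension: `.json`, `.yaml`/`.yml`),
#' validates every key against [default_run_config()] — unknown keys raise an
#' error naming the offending key — and fills unspecified values with the
#' defaults. An empty file yields the all-defaults configuration.
#'
#' @param path Path to a JSON or YAML configuration file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(user) == 0) user <- NULL
  merge_config(default_run_config(), user)
}

#' Save a run configuration
#'
#' @param config A configuration list.
#' @param path Output path; extension selects JSON or YAML.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path,
                                                  precision = 15)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null")
  invisible(path)
}

# Materialise the component objects of a configuration.
config_screen <- function(cfg) {
  s <- cfg$screen
  pz <- s$prohibited_zones
  if (!is.null(pz) && is.matrix(pz)) pz <- asplit(pz, 1)
  screen_model(s$width_cm, s$height_cm, s$width_px, s$height_px,
               prohibited_zones = pz)
}

config_zest <- function(cfg) {
  z <- cfg$zest
  p <- z$prior
  zest_config(db_domain = z$db_domain_min:z$db_domain_max,
              likelihood_slope_sigma = z$likelihood_slope_sigma,
              termination_sd = z$termination_sd,
              min_presentations = z$min_presentations,
              max_presentations = z$max_presentations,
              gamma = z$gamma, lambda = z$lambda,
              prior = prior_spec(p$healthy_mean, p$healthy_sd,
                                 p$abnormal_mean, p$abnormal_sd,
                                 p$abnormal_weight))
}

config_hill <- function(cfg) {
  h <- cfg$observer$hill
  hill_model(h$peak_db, h$slope_db_per_deg, h$interobserver_sd, h$pointwise_sd)
}

#' Build a session configuration from a run configuration
#'
#' @param cfg A configuration list from [load_config()] or
#'   [default_run_config()].
#' @return A [session_config()].
#' @export
config_session <- function(cfg = default_run_config()) {
  s <- cfg$session
  session_config(screen = config_screen(cfg),
                 distance_cm = cfg$viewer$distance_cm,
                 trackbox_deg = cfg$viewer$trackbox_deg,
                 zest = config_zest(cfg),
                 classifier_model = cfg$classifier,
                 catch_rate = s$catch_rate,
                 p_unstable_fixation = s$p_unstable_fixation,
                 max_placement_retries = s$max_placement_retries,
                 max_unplaceable = s$max_unplaceable,
                 max_total_trials = s$max_total_trials,
                 trial_duration_s = s$trial_duration_s,
                 simulate_gaze = s$simulate_gaze,
                 normative = config_hill(cfg),
                 stimulus_diameter_deg = s$stimulus_diameter_deg,
                 blur_sigma_deg = s$blur_sigma_deg)
}

#' Draw the configured cohort of simulated observers
#'
#' @inheritParams config_session
#' @param n Number of observers; defaults to `cfg$cohort$n_observers`.
#' @return List of `sim_observer` objects.
#' @export
config_cohort <- function(cfg = default_run_config(), n = NULL) {
  o <- cfg$observer
  sample_cohort(n = if (is.null(n)) cfg$cohort$n_observers else n,
                hill = config_hill(cfg), grid = build_grid(cfg$eye),
                seed = cfg$seed,
                fos_slope_db = o$fos_slope_db,
                fp_rate = o$fp_rate, fn_rate = o$fn_rate,
                saccade_latency_mean_s = o$saccade_latency_mean_s,
                saccade_latency_sd_s = o$saccade_latency_sd_s,
                landing_error_sd_deg = o$landing_error_sd_deg,
                sample_rate_hz = o$sample_rate_hz,
                dropout_prob = o$dropout_prob,
                distance_drift_sd_cm = o$distance_drift_sd_cm)
}

# 31-bit FNV-style hash of a string; cheap provenance fingerprint for
# summaries (kept below 2^31 so bitwXor stays in integer range).
fnv1a <- function(s) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write session results to disk
#'
#' Writes, per session, a pointwise results CSV (`x_deg`, `y_deg`, `role`,
#' `dls_db`, `n_presentations`, `terminated`; coordinates in right-eye-format
#' degrees, dB to 2 decimal places) and a trial-log CSV, plus one
#' `summary.json` covering all sessions with catch-trial error rates, trial
#' counts, and a provenance block (configuration hash, seed, package
#' version). Column order is stable.
#'
#' @param results A `test_result` or list of them.
#' @param dir Output directory (created if needed).
#' @param config The configuration used (stored for provenance).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, dir, config = default_run_config()) {
  if (inherits(results, "test_result")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  summaries <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    loc <- to_right_eye_format(r$locations, eye = r$eye)
    loc$dls_db <- round(loc$dls_db, 2)
    loc$posterior_sd_db <- round(loc$posterior_sd_db, 2)
    f1 <- file.path(dir, sprintf("session_%03d_results.csv", i))
    utils::write.csv(loc[c("x_deg", "y_deg", "role", "group", "dls_db",
                           "n_presentations", "terminated")],
                     f1, row.names = FALSE)
    f2 <- file.path(dir, sprintf("session_%03d_trials.csv", i))
    utils::write.csv(r$trial_log, f2, row.names = FALSE)
    files <- c(files, f1, f2)
    summaries[[i]] <- list(session = i,
                           mean_sensitivity_db = round(mean_sensitivity(r), 4),
                           n_trials = as.list(r$n_trials),
                           fp_rate_est = r$fp_rate_est,
                           fn_rate_est = r$fn_rate_est,
                           eye = r$eye)
  }
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA, null = "null"))
  summary <- list(
    provenance = list(
      package = "gazeperim",
      version = as.character(utils::packageVersion("gazeperim")),
      config_hash = fnv1a(cfg_json),
      seed = config$seed,
      units = "angles deg, times s, luminance cd/m2, 0-based trial indices"),
    sessions = summaries)
  f3 <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, f3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(files, f3))
}

#' Deterministic miniature fixture cohort
#'
#' A canned small dataset for tests and documentation: a cohort of observers
#' measured twice on each of two simulated devices. Device A is the full
#' gaze-contingent pipeline (gaze synthesis plus saccadic classification);
#' device B is a button-press-style comparator that scores the observer's
#' latent response directly. Byte-identical for a given seed.
#'
#' @param seed Master seed.
#' @param n_observers Cohort size.
#' @param cfg Base configuration.
#' @return List: `ms` (observers x 2 runs x 2 devices array of mean
#'   sensitivities), `pointwise` (list by device of runs x locations x
#'   observers arrays), `results` (nested list of `test_result`s), `grid`,
#'   `config`.
#' @export
make_fixtures <- function(seed = 1, n_observers = 4,
                          cfg = default_run_config()) {
  cfg$seed <- seed
  cfg$cohort$n_observers <- n_observers
  observers <- config_cohort(cfg)
  grid <- build_grid(cfg$eye)
  devices <- list(A = TRUE, B = FALSE)   # simulate_gaze per device
  ms <- array(NA_real_, c(n_observers, 2, 2),
              dimnames = list(NULL, c("run1", "run2"), c("A", "B")))
  pointwise <- list()
  results <- list()
  for (d in seq_along(devices)) {
    dev <- names(devices)[d]
    sc <- config_session(cfg)
    sc$simulate_gaze <- devices[[dev]]
    pw <- array(NA_real_, c(2, nrow(grid), n_observers))
    results[[dev]] <- vector("list", n_observers)
    for (o in seq_len(n_observers)) {
      results[[dev]][[o]] <- vector("list", 2)
      for (run in 1:2) {
        s <- (seed * 7 + o * 101 + run * 13 + d * 10007) %% .Machine$integer.max
        res <- run_session(observers[[o]], sc, seed = s)
        ms[o, run, d] <- mean_sensitivity(res)
        pw[run, , o] <- res$locations$dls_db
        results[[dev]][[o]][[run]] <- res
      }
    }
    pointwise[[dev]] <- pw
  }
  list(ms = ms, pointwise = pointwise, results = results, grid = grid,
       config = cfg)
}

#' Read and write gaze logs
#'
#' The gaze-log CSV dialect: columns `t_s` (seconds), `x_px`, `y_px`
#' (screen pixels), `valid` (0/1), `distance_cm`. [as_field_stream()]
#' converts such a log into the visual-field-degree stream (relative to a
#' fixation point) accepted by [classify_response()].
#'
#' @param path CSV file path.
#' @return `read_gaze_log`: a data frame in the gaze-log dialect.
#' @export
read_gaze_log <- function(path) {
  g <- utils::read.csv(path)
  need <- c("t_s", "x_px", "y_px", "valid", "distance_cm")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop("gaze log lacks column(s): ", paste(missing, collapse = ", "))
  g$valid <- as.logical(g$valid)
  g
}

#' @rdname read_gaze_log
#' @param log Data frame in the gaze-log dialect.
#' @export
write_gaze_log <- function(log, path) {
  log$valid <- as.integer(log$valid)
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_gaze_log
#' @param fixation_px Fixation point the offsets are measured from.
#' @param screen A [screen_model()].
#' @export
as_field_stream <- function(log, fixation_px, screen = screen_model()) {
  off <- t(vapply(seq_len(nrow(log)), function(i) {
    viewer <- viewer_state(distance_cm = log$distance_cm[i],
                           fixation_px = fixation_px, screen = screen)
    px_to_field_offset(c(log$x_px[i], log$y_px[i]), viewer, screen)
  }, numeric(2)))
  data.frame(t_s = log$t_s, x_deg = off[, 1], y_deg = off[, 2],
             valid = log$valid)
}
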