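#' Saccadic response classifier parameters
#'
#' A presentation is scored a hit when at least `n_samples` valid gaze
#' samples land inside a `box_halfwidth * 2` degree square box centred on the
#' target within `deadline_s` seconds of stimulus onset.
#'
#' @param n_samples Required number of in-box gaze samples (N >= 1).
#' @param box_width_deg Full width D of the square acceptance box, degrees.
#' @param deadline_s Response deadline R from stimulus onset, seconds.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(n_samples = 6, box_width_deg = 2.77,
                              deadline_s = 1.62) {
  stopifnot(n_samples >= 1, box_width_deg > 0, deadline_s > 0)
  structure(list(n_samples = as.integer(n_samples),
                 box_width_deg = box_width_deg,
                 deadline_s = deadline_s),
            class = "classifier_params")
}

#' Classifier parameters as a function of stimulus eccentricity
#'
#' N, D and R vary with eccentricity: saccades to peripheral targets are
#' slower and less accurate, so the box widens and the deadline lengthens
#' (and the sample criterion never grows) as eccentricity increases. The
#' default model is affine in eccentricity and anchored so that a target at
#' (+9, +9) degrees — eccentricity `sqrt(162) ~ 12.73` deg — yields exactly
#' N = 6, D = 2.77, R = 1.62. All coefficients are overridable; constant
#' overrides give constant parameters at every eccentricity.
#'
#' @param target_deg Target location `c(x, y)`, visual-field degrees.
#' @param model List of coefficients: `n_base`, `d_base`, `r_base` (values at
#'   the anchor eccentricity), `d_gain`, `r_gain` (fractional change per
#'   degree of eccentricity away from the anchor), `anchor_ecc_deg`, and
#'   clipping bounds `d_min`, `r_min`.
#' @return A [classifier_params()] for that eccentricity.
#' @examples
#' params_for_eccentricity(c(9, 9))  # N=6, D=2.77, R=1.62
#' @export
params_for_eccentricity <- function(target_deg,
                                    model = list(n_base = 6,
                                                 d_base = 2.77, d_gain = 0.06,
                                                 r_base = 1.62, r_gain = 0.04,
                                                 anchor_ecc_deg = sqrt(162),
                                                 d_min = 1, r_min = 0.5)) {
  ecc <- sqrt(sum(as.numeric(target_deg)^2))
  de <- ecc - model$anchor_ecc_deg
  classifier_params(
    n_samples = round(model$n_base),
    box_width_deg = max(model$d_min, model$d_base * (1 + model$d_gain * de)),
    deadline_s = max(model$r_min, model$r_base * (1 + model$r_gain * de)))
}

#' Classify a presentation as hit or miss from the gaze stream
#'
#' Counts valid gaze samples that fall, at or before the deadline, inside the
#' closed box `[target +/- D/2]` per axis. Counting is cumulative — the in-box
#' samples need not be consecutive — and samples on the box boundary count as
#' inside. Invalid samples are skipped, never interpolated.
#'
#' @param stream A gaze stream: data frame with columns `t_s` (seconds from
#'   stimulus onset, non-decreasing), `x_deg`, `y_deg` (gaze position,
#'   visual-field degrees) and `valid` (logical).
#' @param target_deg Target centre `c(x, y)`, degrees.
#' @param params A [classifier_params()].
#' @return List: `hit` (logical), `n_in_box` (in-box samples before the
#'   deadline), `time_to_criterion_s` (time of the Nth in-box sample, `NA` on
#'   a miss) and `reason` (`"criterion_met"`, `"insufficient_samples"` or
#'   `"no_data"`).
#' @export
classify_response <- function(stream, target_deg,
                              params = classifier_params()) {
  if (is.null(stream) || nrow(stream) == 0)
    return(list(hit = FALSE, n_in_box = 0L, time_to_criterion_s = NA_real_,
                reason = "no_data"))
  if (is.unsorted(stream$t_s)) stop("gaze stream must be time-ordered")
  half <- params$box_width_deg / 2
  ok <- stream$valid & stream$t_s <= params$deadline_s &
    abs(stream$x_deg - target_deg[1]) <= half &
    abs(stream$y_deg - target_deg[2]) <= half
  n <- sum(ok)
  if (n >= params$n_samples) {
    list(hit = TRUE, n_in_box = as.integer(n),
         time_to_criterion_s = stream$t_s[which(ok)[params$n_samples]],
         reason = "criterion_met")
  } else {
    list(hit = FALSE, n_in_box = as.integer(n),
         time_to_criterion_s = NA_real_,
         reason = "insufficient_samples")
  }
}

#' Is fixation currently stable?
#'
#' Gatekeeper for trial onset: gaze-contingent placement needs a trustworthy
#' fixation estimate, so a trial only starts once the dispersion (per-axis
#' range) of the last `window` valid samples is at or below a limit. Fewer
#' than `window` valid samples, or any invalid sample inside the window,
#' counts as unstable.
#'
#' @param stream Gaze stream (same dialect as [classify_response()]).
#' @param window Number of trailing samples considered.
#' @param dispersion_limit_deg Maximum allowed per-axis range, degrees.
#' @return Logical.
#' @export
fixation_stable <- function(stream, window = 10, dispersion_limit_deg = 1.5) {
  if (is.null(stream) || nrow(stream) < window) return(FALSE)
  tail_idx <- seq.int(nrow(stream) - window + 1L, nrow(stream))
  s <- stream[tail_idx, , drop = FALSE]
  if (!all(s$valid)) return(FALSE)
  max(diff(range(s$x_deg)), diff(range(s$y_deg))) <= dispersion_limit_deg
}
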