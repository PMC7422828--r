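#' Luminance and decibel scale configuration
#'
#' Perimetric differential light sensitivity (DLS) is expressed as attenuation
#' of the largest displayable luminance increment, in decibels:
#' \eqn{DLS = 10 \log_{10}(\Delta L_{max} / \Delta L_{jnd})}. Each device has
#' its own maximum increment, so dB values are device-relative and must be
#' rescaled before devices are compared. This object holds the constants of
#' both scales: the test display (background 10 cd/m2, maximum increment
#' 225 cd/m2, dB domain 0--34) and the reference HFA perimeter (maximum
#' increment 3183.1 cd/m2).
#'
#' @param background_cd_m2 Background luminance in cd/m2.
#' @param max_increment_cd_m2 Largest displayable luminance increment of the
#'   test display, cd/m2 (defines 0 dB on its scale).
#' @param hfa_max_increment_cd_m2 Largest displayable increment of the HFA,
#'   cd/m2 (defines 0 dB on the HFA scale).
#' @param db_domain_max Upper end of the test display's dB domain.
#' @return An object of class `luminance_config`.
#' @examples
#' cfg <- luminance_config()
#' dls_from_increment(225, cfg)   # 0 dB: no attenuation
#' dls_from_increment(22.5, cfg)  # 10 dB: one log unit
#' @export
luminance_config <- function(background_cd_m2 = 10,
                             max_increment_cd_m2 = 225,
                             hfa_max_increment_cd_m2 = 3183.1,
                             db_domain_max = 34) {
  stopifnot(background_cd_m2 > 0, max_increment_cd_m2 > 0,
            hfa_max_increment_cd_m2 > 0, db_domain_max >= 0)
  structure(list(background_cd_m2 = background_cd_m2,
                 max_increment_cd_m2 = max_increment_cd_m2,
                 hfa_max_increment_cd_m2 = hfa_max_increment_cd_m2,
                 db_domain_max = db_domain_max),
            class = "luminance_config")
}

#' Convert a luminance increment to attenuation dB
#'
#' Raw (unclamped) sensitivity in dB of attenuation relative to the display's
#' maximum increment. Higher dB means a smaller increment was detectable,
#' i.e. greater sensitivity.
#'
#' @param delta_L_cd_m2 Detected luminance increment(s), cd/m2; must be > 0.
#' @param config A [luminance_config()].
#' @return Sensitivity in dB (vectorised).
#' @export
dls_from_increment <- function(delta_L_cd_m2, config = luminance_config()) {
  if (any(!is.finite(delta_L_cd_m2)) || any(delta_L_cd_m2 <= 0))
    stop("luminance increment must be a positive finite value (cd/m2)")
  10 * log10(config$max_increment_cd_m2 / delta_L_cd_m2)
}

#' Convert test-display dB to a luminance increment
#'
#' Inverse of [dls_from_increment()]; needed by any stimulus renderer.
#'
#' @param dls_db Sensitivity in dB on the test display scale.
#' @param config A [luminance_config()].
#' @return Luminance increment in cd/m2.
#' @export
increment_from_db <- function(dls_db, config = luminance_config()) {
  if (any(!is.finite(dls_db))) stop("dB value must be finite")
  config$max_increment_cd_m2 * 10^(-dls_db / 10)
}

#' Convert HFA dB to a luminance increment
#'
#' The HFA reports attenuation relative to its own, much brighter, maximum
#' pedestal (3183.1 cd/m2 at 0 dB).
#'
#' @param dls_hfa_db Sensitivity in dB on the HFA scale; must be >= 0.
#' @param config A [luminance_config()].
#' @return Luminance increment in cd/m2.
#' @export
increment_from_hfa_db <- function(dls_hfa_db, config = luminance_config()) {
  if (any(!is.finite(dls_hfa_db)) || any(dls_hfa_db < 0))
    stop("HFA dB values must be finite and non-negative")
  config$hfa_max_increment_cd_m2 * 10^(-dls_hfa_db / 10)
}

#' Rescale HFA dB values onto the test display's dB scale
#'
#' Converts HFA attenuation values to linear cd/m2 and re-expresses them as
#' attenuation of the test display's maximum increment. Values that come out
#' negative (the detected increment was brighter than anything the display can
#' show) are rounded up to zero; values above the display's dB domain are
#' clamped to its maximum, so the image of the map is exactly
#' `[0, db_domain_max]`.
#'
#' @inheritParams increment_from_hfa_db
#' @return Sensitivity in dB on the test display scale, in `[0, db_domain_max]`.
#' @export
hfa_to_native_db <- function(dls_hfa_db, config = luminance_config()) {
  raw <- dls_from_increment(increment_from_hfa_db(dls_hfa_db, config), config)
  pmin(pmax(raw, 0), config$db_domain_max)
}

# apostilb -> cd/m2 (1 asb = 1/pi cd/m2); exposed for tests against HFA tables.
#' @keywords internal
asb_to_cd_m2 <- function(asb) asb / pi
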