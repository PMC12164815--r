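#' Analytical quality-control profile of the XRF measurement
#'
#' Repeatability (coefficient of variation), recovery (accuracy) and the
#' limit of detection of the field instrument. Defaults are the values of
#' the portable-XRF quality control of the Araro survey: CV 0.75%,
#' recovery 117%, LOD 4 mg/kg.
#'
#' @param cv Coefficient of variation of repeated measurements
#'   (proportion, >= 0).
#' @param accuracy Recovery factor (measured/true; > 0).
#' @param lod Limit of detection, mg/kg (> 0).
#' @return An object of class `aqc_profile`.
#' @export
aqc_profile <- function(cv = 0.0075, accuracy = 1.17, lod = 4) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (accuracy <= 0) stop("accuracy must be > 0", call. = FALSE)
  if (lod <= 0) stop("lod must be > 0", call. = FALSE)
  structure(list(cv = cv, accuracy = accuracy, lod = lod),
            class = "aqc_profile")
}

#' Generate a synthetic dust survey
#'
#' Emulates a sampling campaign over `area_ha` hectares: the number of
#' samples follows the NMX-AA-132 formula ([required_sample_count()]),
#' true concentrations are drawn from `true_spec`, and measured values are
#' truth x recovery x multiplicative lognormal noise with the instrument's
#' CV (mean-one noise). Measurements below the LOD are flagged. Set
#' `correct_recovery = TRUE` to divide the recovery factor back out, as a
#' recovery-corrected laboratory report would.
#'
#' @param area_ha Sampled area, hectares.
#' @param true_spec [lognormal_spec()] of the true concentration field.
#' @param aqc An [aqc_profile()].
#' @param seed Optional integer seed.
#' @param correct_recovery Divide measured values by the recovery factor.
#' @return A [dust_survey()] with `area_ha` attached.
#' @export
#' @examples
#' spec <- fit_lognormal_moments(15.21, 5.94)
#' sv <- generate_dust_survey(11400, spec, seed = 1)
#' nrow(sv$records)  # 40
generate_dust_survey <- function(area_ha, true_spec, aqc = aqc_profile(),
                                 seed = NULL, correct_recovery = FALSE) {
  stopifnot(inherits(true_spec, "lognormal_spec"), inherits(aqc, "aqc_profile"))
  n <- required_sample_count(area_ha)
  if (!is.null(seed)) set.seed(seed)
  truth <- sample_lognormal(true_spec, n)
  noise <- if (aqc$cv > 0) {
    s2 <- log(1 + aqc$cv^2)
    stats::rlnorm(n, -s2 / 2, sqrt(s2))
  } else {
    rep(1, n)
  }
  measured <- truth * aqc$accuracy * noise
  if (correct_recovery) measured <- measured / aqc$accuracy
  dust_survey(
    sample_id = sprintf("S%03d", seq_len(n)),
    concentration = measured,
    below_lod = measured < aqc$lod,
    lod = aqc$lod,
    area_ha = area_ha
  )
}

#' Generate a synthetic body-weight population for an age group
#'
#' Draws `n` body weights from the group's truncated lognormal
#' specification; all values fall inside the spec's truncation bounds.
#'
#' @param group One of [age_groups()] (label is validated and attached as
#'   an attribute).
#' @param spec [lognormal_spec()] of the body-weight distribution,
#'   e.g. from [fit_lognormal_range()] or [input_specs()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return Numeric vector of body weights in kg, with attribute
#'   `age_group`.
#' @export
generate_bw_population <- function(group, spec, n, seed = NULL) {
  group <- match_age_group(group)
  bw <- sample_lognormal(spec, n, seed = seed)
  attr(bw, "age_group") <- group
  bw
}
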