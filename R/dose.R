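#' Average daily dose by incidental dust ingestion
#'
#' ADDig = Cs * IR * EF * ED / (BW * AT) * CF, in mg/kg/day. Linear in the
#' dust concentration Cs. All rate and time parameters come from an
#' [exposure_factors()] bundle; `BW` and `AT` may be overridden to
#' evaluate the formula at a sampled body weight or a carcinogenic
#' averaging time.
#'
#' @param Cs Dust concentration, mg/kg (vectorized, >= 0).
#' @param f An [exposure_factors()] object.
#' @param BW Body weight, kg (default: the bundle's mean).
#' @param AT Averaging time, days (default: the bundle's non-carcinogenic
#'   value).
#' @return Average daily dose, mg/kg/day.
#' @export
#' @examples
#' cfg <- default_araro_config()
#' add_ingestion(15.6, cfg$age_groups$preschooler)  # 9.56e-5
add_ingestion <- function(Cs, f, BW = f$BW_mean, AT = f$AT) {
  check_conc(Cs)
  Cs * f$IR * f$EF * f$ED / (BW * AT) * f$CF
}

#' Average daily dose by inhalation of resuspended dust
#'
#' ADDih = C * InhR * EF * ED / (PEF * BW * AT), in mg/kg/day, with the
#' particle emission factor PEF converting the dust concentration to an
#' inhalable air concentration.
#'
#' @inheritParams add_ingestion
#' @param C Dust concentration, mg/kg (vectorized, >= 0).
#' @return Average daily dose, mg/kg/day.
#' @export
add_inhalation <- function(C, f, BW = f$BW_mean, AT = f$AT) {
  check_conc(C)
  C * f$InhR * f$EF * f$ED / (f$PEF * BW * AT)
}

#' Average daily dose by dermal contact with dust
#'
#' ADDd = C * AF * ABS * EV * EF * ED * CF * SA / (BW * AT), in mg/kg/day:
#' dust adhering to exposed skin (AF, SA), of which a fraction ABS is
#' absorbed, EV contact events per day.
#'
#' @inheritParams add_inhalation
#' @return Average daily dose, mg/kg/day.
#' @export
add_dermal <- function(C, f, BW = f$BW_mean, AT = f$AT) {
  check_conc(C)
  C * f$AF * f$ABS * f$EV * f$EF * f$ED * f$CF * f$SA / (BW * AT)
}

check_conc <- function(C) {
  if (any(C < 0, na.rm = TRUE)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  invisible(C)
}

#' Rescale an average daily dose to the carcinogenic averaging time
#'
#' Every pathway dose is proportional to 1/AT, so substituting the
#' lifetime averaging time cAT for AT is the rescaling
#' cADD = ADD * AT / cAT.
#'
#' @param add Average daily dose, mg/kg/day (vectorized).
#' @param AT Non-carcinogenic averaging time used to compute `add`, days.
#' @param cAT Carcinogenic (lifetime) averaging time, days.
#' @return Carcinogenic average daily dose, mg/kg/day.
#' @export
carcinogenic_add <- function(add, AT, cAT) {
  if (AT <= 0 || cAT <= 0) stop("AT and cAT must be positive", call. = FALSE)
  add * AT / cAT
}

#' Hazard quotient
#'
#' HQ = ADD / RfD; values above 1 flag potential non-carcinogenic risk.
#'
#' @param add Average daily dose, mg/kg/day (vectorized).
#' @param rfd Reference dose, mg/kg/day (> 0).
#' @return Dimensionless hazard quotient.
#' @export
hazard_quotient <- function(add, rfd) {
  if (!is.numeric(rfd) || length(rfd) != 1L || rfd <= 0) {
    stop("rfd must be a single positive number", call. = FALSE)
  }
  add / rfd
}

#' Carcinogenic risk from a carcinogenic average daily dose
#'
#' Two conventions are supported. `"printed"` computes CR = cADD / SF,
#' which is what the source study's formula table states and what its
#' tabulated cancer risks numerically reproduce. `"standard"` computes the
#' usual USEPA product CR = cADD x SF. The default configuration uses
#' `"printed"` so the study's tables are reproduced; switch to
#' `"standard"` for conventional assessments.
#'
#' @param cadd Carcinogenic average daily dose, mg/kg/day (vectorized).
#' @param sf Slope factor, (mg/kg/day)^-1 (> 0).
#' @param convention `"printed"` or `"standard"`.
#' @return Dimensionless lifetime excess cancer risk.
#' @export
cancer_risk <- function(cadd, sf, convention = c("printed", "standard")) {
  convention <- match.arg(convention)
  if (!is.numeric(sf) || length(sf) != 1L || sf <= 0) {
    stop("sf must be a single positive number", call. = FALSE)
  }
  if (convention == "printed") cadd / sf else cadd * sf
}

#' Hazard index: sum of pathway hazard quotients
#'
#' @param hqs Numeric vector (or list) of non-negative hazard quotients;
#'   an empty input sums to 0.
#' @return Dimensionless hazard index.
#' @export
hazard_index <- function(hqs) {
  hqs <- as.numeric(unlist(hqs))
  if (any(hqs < 0)) stop("hazard quotients must be >= 0", call. = FALSE)
  sum(hqs)
}

#' Accumulated cancer risk: sum of pathway cancer risks
#'
#' @param crs Numeric vector (or list) of non-negative pathway cancer
#'   risks; an empty input sums to 0.
#' @return Dimensionless accumulated cancer risk.
#' @export
accumulated_cancer_risk <- function(crs) {
  crs <- as.numeric(unlist(crs))
  if (any(crs < 0)) stop("cancer risks must be >= 0", call. = FALSE)
  sum(crs)
}

#' Screen an average daily dose against its pathway safety criterion
#'
#' Flags doses strictly above the pathway screening limit: the oral RfD
#' (3.0e-4 mg/kg/day) for the oral and inhalation pathways, and the dermal
#' screening value (1.23e-4 mg/kg/day) for the dermal pathway. This is the
#' dose-level screen of the summary tables, distinct from the hazard
#' quotient (which for inhalation divides by the inhalation RfD).
#'
#' @param add Average daily dose, mg/kg/day (vectorized).
#' @param pathway One of [pathways()].
#' @param criteria A [tox_criteria()] object.
#' @return Logical: `TRUE` where the dose exceeds the screening limit.
#' @export
screen_add <- function(add, pathway, criteria = tox_criteria()) {
  pathway <- match_pathway(pathway)
  add > screening_limit(pathway, criteria)
}

screening_limit <- function(pathway, criteria) {
  switch(pathway,
         oral = criteria$rfd_oral,
         inhalation = criteria$rfd_oral,
         dermal = criteria$rfd_dermal_screen)
}

hq_denominator <- function(pathway, criteria) {
  switch(pathway,
         oral = criteria$rfd_oral,
         inhalation = criteria$rfd_inhalation,
         dermal = criteria$rfd_hq_dermal)
}
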