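#' Valid age-group labels
#'
#' The population is stratified into four biological age groups; the label
#' set is closed because every exposure parameter table is keyed by it.
#'
#' @return Character vector of the four valid age-group labels.
#' @export
#' @examples
#' age_groups()
age_groups <- function() {
  c("preschooler", "elementary", "adolescent", "adult")
}

#' Valid exposure-pathway labels
#'
#' @return Character vector of the three dust exposure pathways.
#' @export
pathways <- function() {
  c("oral", "dermal", "inhalation")
}

match_age_group <- function(group) {
  match.arg(group, age_groups())
}

match_pathway <- function(pathway) {
  match.arg(pathway, pathways())
}

#' Exposure-factor bundle for one age group
#'
#' Collects every anthropometric and exposure parameter needed by the
#' pathway dose formulas for a single age group. Units follow USEPA
#' convention: dust concentration in mg/kg, intake in mg dust/day,
#' inhalation in m^3/day, skin area in cm^2, times in days or years.
#'
#' @param AsC_mean Mean dust arsenic concentration, mg/kg.
#' @param AsC_min,AsC_max Observed concentration range, mg/kg (also used as
#'   truncation bounds for the simulated concentration distribution).
#' @param AsC_sd Standard deviation of the dust concentration, mg/kg.
#' @param EF Exposure frequency, days/year.
#' @param ED Exposure duration, years.
#' @param BW_mean Mean body weight, kg.
#' @param BW_min,BW_max Body-weight range, kg (truncation bounds).
#' @param AT Non-carcinogenic averaging time, days.
#' @param cAT Carcinogenic (lifetime) averaging time, days.
#' @param IR Dust ingestion rate, mg/day.
#' @param InhR Inhalation rate, m^3/day.
#' @param PEF Particle emission factor, m^3/kg.
#' @param SA Exposed skin surface area, cm^2.
#' @param AF Dust-to-skin adherence factor, mg/cm^2.
#' @param ABS Dermal absorption fraction (dimensionless).
#' @param EV Event frequency, events/day.
#' @param CF Mass conversion factor, kg/mg (1e-6).
#'
#' @return An object of class `exposure_factors` (a validated named list).
#' @export
exposure_factors <- function(AsC_mean, AsC_min, AsC_max, AsC_sd,
                             EF, ED, BW_mean, BW_min, BW_max,
                             AT, cAT, IR, InhR, PEF, SA, AF, ABS,
                             EV = 1, CF = 1e-6) {
  f <- list(
    AsC_mean = AsC_mean, AsC_min = AsC_min, AsC_max = AsC_max,
    AsC_sd = AsC_sd, EF = EF, ED = ED,
    BW_mean = BW_mean, BW_min = BW_min, BW_max = BW_max,
    AT = AT, cAT = cAT, IR = IR, InhR = InhR, PEF = PEF,
    SA = SA, AF = AF, ABS = ABS, EV = EV, CF = CF
  )
  # config files may deliver whole numbers as integers
  f <- lapply(f, function(v) if (is.numeric(v)) as.numeric(v) else v)
  validate_exposure_factors(f)
  structure(f, class = "exposure_factors")
}

validate_exposure_factors <- function(f, group = NULL) {
  where <- if (is.null(group)) "" else sprintf(" (age group '%s')", group)
  num_fields <- names(f)
  for (nm in num_fields) {
    v <- f[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("exposure factor '%s'%s must be a finite number", nm, where),
           call. = FALSE)
    }
    # AsC_sd = 0 is legal: it collapses the concentration to a point mass
    lo_ok <- if (nm == "AsC_sd") v >= 0 else v > 0
    if (!lo_ok) {
      stop(sprintf("exposure factor '%s'%s must be positive (got %g)",
                   nm, where, v), call. = FALSE)
    }
  }
  if (f$AsC_min > f$AsC_mean || f$AsC_mean > f$AsC_max) {
    stop(sprintf("AsC_min <= AsC_mean <= AsC_max violated%s", where),
         call. = FALSE)
  }
  if (f$BW_min > f$BW_mean || f$BW_mean > f$BW_max) {
    stop(sprintf("BW_min <= BW_mean <= BW_max violated%s", where),
         call. = FALSE)
  }
  # AT should be the exposure duration expressed in days of actual exposure
  if (abs(f$AT - f$ED * f$EF) > 1) {
    warning(sprintf("AT (%g d) differs from ED x EF (%g d) by more than 1 day%s",
                    f$AT, f$ED * f$EF, where), call. = FALSE)
  }
  invisible(f)
}

#' Toxicity criteria for hazard and cancer-risk calculations
#'
#' Reference doses, slope factor and regulatory limits. Two denominators are
#' distinguished for the dermal pathway: the screening limit used to flag
#' individual average daily doses (`rfd_dermal_screen`) and the denominator
#' used for the dermal hazard quotient (`rfd_hq_dermal`). The inhalation
#' hazard quotient divides by the inhalation reference dose
#' (`rfd_inhalation`, default 1.5e-5 mg/kg/day for arsenic), while
#' inhalation dose screening keeps the ingestion value of 3.0e-4.
#'
#' @param rfd_oral Oral (ingestion) reference dose, mg/kg/day.
#' @param rfd_inhalation Inhalation reference dose used as the inhalation HQ
#'   denominator, mg/kg/day.
#' @param rfd_dermal_screen Dermal dose screening limit, mg/kg/day.
#' @param rfd_hq_dermal Denominator of the dermal hazard quotient, mg/kg/day.
#' @param sf Cancer slope factor, (mg/kg/day)^-1, applied to all pathways.
#' @param hq_limit Hazard-quotient safety criterion (1).
#' @param cr_limit Carcinogenic-risk safety criterion (1e-5).
#'
#' @return An object of class `tox_criteria`.
#' @export
tox_criteria <- function(rfd_oral = 3.0e-4,
                         rfd_inhalation = 1.5e-5,
                         rfd_dermal_screen = 1.23e-4,
                         rfd_hq_dermal = 3.0e-4,
                         sf = 1.5,
                         hq_limit = 1,
                         cr_limit = 1e-5) {
  tc <- list(
    rfd_oral = rfd_oral, rfd_inhalation = rfd_inhalation,
    rfd_dermal_screen = rfd_dermal_screen, rfd_hq_dermal = rfd_hq_dermal,
    sf = sf, hq_limit = hq_limit, cr_limit = cr_limit
  )
  for (nm in names(tc)) {
    v <- tc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("toxicity criterion '%s' must be a positive finite number", nm),
           call. = FALSE)
    }
    tc[[nm]] <- as.numeric(v)
  }
  structure(tc, class = "tox_criteria")
}

#' Study configuration
#'
#' Bundles the per-age-group exposure factors, toxicity criteria and
#' simulation settings that drive [run_simulation()].
#'
#' @param groups Named list with one [exposure_factors()] object per age
#'   group; all four labels from [age_groups()] must be present.
#' @param toxicity A [tox_criteria()] object.
#' @param n_iterations Number of Monte Carlo scenarios (default 10,000).
#' @param seed Integer seed controlling all random draws.
#' @param cr_convention Either `"printed"` (cancer risk = cADD / SF, the
#'   convention the source study tabulated) or `"standard"` (cADD x SF,
#'   the usual USEPA form). See [cancer_risk()].
#' @param bw_coverage Central coverage probability with which the reported
#'   body-weight ranges are interpreted when fitting the lognormal
#'   body-weight distribution (see [fit_lognormal_range()]).
#' @param metadata Optional named list of inert annotations carried along
#'   (e.g. the tabulated dermal contact factor DFS = 362.4 mg*year/kg/day,
#'   which no dose formula consumes).
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups, toxicity = tox_criteria(),
                         n_iterations = 10000, seed = 20180000,
                         cr_convention = c("printed", "standard"),
                         bw_coverage = 0.99,
                         metadata = list(DFS = 362.4)) {
  cr_convention <- match.arg(cr_convention)
  if (!is.list(groups)) stop("'groups' must be a named list", call. = FALSE)
  unknown <- setdiff(names(groups), age_groups())
  if (length(unknown)) {
    stop("unknown age-group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_groups <- setdiff(age_groups(), names(groups))
  if (length(missing_groups)) {
    stop("missing age group(s): ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  for (g in age_groups()) {
    if (!inherits(groups[[g]], "exposure_factors")) {
      groups[[g]] <- do.call(exposure_factors, as.list(groups[[g]]))
    }
    validate_exposure_factors(unclass(groups[[g]]), group = g)
  }
  if (!inherits(toxicity, "tox_criteria")) {
    toxicity <- do.call(tox_criteria, as.list(toxicity))
  }
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop("n_iterations must be >= 1", call. = FALSE)
  }
  if (bw_coverage <= 0 || bw_coverage >= 1) {
    stop("bw_coverage must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      age_groups = groups[age_groups()],
      toxicity = toxicity,
      n_iterations = as.integer(n_iterations),
      seed = as.integer(seed),
      cr_convention = cr_convention,
      bw_coverage = bw_coverage,
      metadata = metadata
    ),
    class = "study_config"
  )
}

#' Default configuration for the Araro dust-arsenic study conditions
#'
#' Returns the exposure, anthropometric and toxicity parameters of the
#' Araro (Michoacan, Mexico) geothermal-community dust survey: arsenic
#' concentration mean 15.6 mg/kg (SD 5.94, observed range 5.94-42.53),
#' exposure frequency 350 d/y, group-specific exposure durations, body
#' weights, averaging times, intake and inhalation rates, skin areas, and
#' arsenic toxicity criteria (oral RfD 3e-4, slope factor 1.5). The
#' carcinogenic averaging time is the 70-year lifetime (25,550 days) and
#' the dermal event frequency is 1/day.
#'
#' @return A [study_config()] object.
#' @export
#' @examples
#' cfg <- default_araro_config()
#' cfg$age_groups$preschooler$IR
default_araro_config <- function() {
  asc <- list(AsC_mean = 15.6, AsC_min = 5.94, AsC_max = 42.53, AsC_sd = 5.94)
  common <- c(asc, list(EF = 350, PEF = 1.36e9, AF = 0.5, ABS = 0.03,
                        EV = 1, CF = 1e-6, cAT = 25550))
  mk <- function(ED, BW_mean, BW_min, BW_max, AT, IR, InhR, SA) {
    do.call(exposure_factors,
            c(common, list(ED = ED, BW_mean = BW_mean, BW_min = BW_min,
                           BW_max = BW_max, AT = AT, IR = IR, InhR = InhR,
                           SA = SA)))
  }
  groups <- list(
    preschooler = mk(ED = 3.51,  BW_mean = 16.31, BW_min = 10,   BW_max = 39,
                     AT = 1229,  IR = 100, InhR = 9.5,   SA = 760),
    elementary  = mk(ED = 8.82,  BW_mean = 33.8,  BW_min = 14,   BW_max = 95.7,
                     AT = 3087,  IR = 100, InhR = 12,    SA = 1080),
    adolescent  = mk(ED = 15.88, BW_mean = 60.91, BW_min = 25.9, BW_max = 158.4,
                     AT = 5558,  IR = 30,  InhR = 15.75, SA = 1840),
    adult       = mk(ED = 42.94, BW_mean = 72.67, BW_min = 45,   BW_max = 194.2,
                     AT = 15029, IR = 30,  InhR = 14.67, SA = 1935)
  )
  study_config(groups, toxicity = tox_criteria(),
               n_iterations = 10000, seed = 20180000,
               cr_convention = "printed")
}

config_as_list <- function(config) {
  list(
    age_groups = lapply(config$age_groups, function(f) unclass(f)),
    toxicity = unclass(config$toxicity),
    simulation = list(
      n_iterations = config$n_iterations,
      seed = config$seed,
      cr_convention = config$cr_convention,
      bw_coverage = config$bw_coverage
    ),
    metadata = config$metadata
  )
}

#' Save a study configuration to YAML or JSON
#'
#' The format is chosen from the file extension (`.yml`/`.yaml` or `.json`).
#' [load_config()] reads the result back to an identical configuration.
#'
#' @param config A [study_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- config_as_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    writeLines(yaml::as.yaml(x, precision = 15), path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Load a study configuration from YAML or JSON
#'
#' Unspecified fields fall back to the Araro defaults of
#' [default_araro_config()]; the file only needs to list overrides. The
#' expected layout has top-level keys `age_groups` (named blocks of
#' exposure factors), `toxicity` and `simulation` (`n_iterations`, `seed`,
#' `cr_convention`, `bw_coverage`).
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A fully validated [study_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  defaults <- default_araro_config()
  def <- config_as_list(defaults)

  merge_block <- function(base, override, what) {
    if (is.null(override)) return(base)
    unknown <- setdiff(names(override), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown field(s) in %s: %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    base[names(override)] <- override
    base
  }

  if (!is.null(raw$age_groups)) {
    unknown <- setdiff(names(raw$age_groups), age_groups())
    if (length(unknown)) {
      stop("unknown age-group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (g in names(raw$age_groups)) {
      def$age_groups[[g]] <- merge_block(def$age_groups[[g]],
                                         raw$age_groups[[g]],
                                         sprintf("age group '%s'", g))
    }
  }
  def$toxicity <- merge_block(def$toxicity, raw$toxicity, "toxicity")
  def$simulation <- merge_block(def$simulation, raw$simulation, "simulation")
  if (!is.null(raw$metadata)) def$metadata <- raw$metadata

  study_config(
    groups = def$age_groups,
    toxicity = do.call(tox_criteria, def$toxicity),
    n_iterations = def$simulation$n_iterations,
    seed = def$simulation$seed,
    cr_convention = def$simulation$cr_convention,
    bw_coverage = def$simulation$bw_coverage,
    metadata = def$metadata
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration: dust arsenic multi-pathway risk\n")
  cat(sprintf("  age groups : %s\n", paste(names(x$age_groups), collapse = ", ")))
  cat(sprintf("  iterations : %d (seed %d, CR convention '%s')\n",
              x$n_iterations, x$seed, x$cr_convention))
  cat(sprintf("  AsC mean   : %g mg/kg (range %g-%g)\n",
              x$age_groups[[1]]$AsC_mean, x$age_groups[[1]]$AsC_min,
              x$age_groups[[1]]$AsC_max))
  cat(sprintf("  oral RfD %g, inhalation RfD %g, SF %g\n",
              x$toxicity$rfd_oral, x$toxicity$rfd_inhalation, x$toxicity$sf))
  invisible(x)
}
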