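#' Number of dust samples required for a sampling area
#'
#' Sample-count formula of the Mexican dust/soil sampling norm
#' NMX-AA-132-SCFI-2016: n = 2.26 * A^0.31, truncated to an integer
#' (minimum 1), with A the sampling area in hectares. For the 11,400 ha
#' Araro area this yields 40.90, i.e. 40 samples.
#'
#' @param area_ha Sampling area in hectares (> 0); vectorized.
#' @return Integer vector of required sample counts.
#' @export
#' @examples
#' required_sample_count(11400)  # 40
required_sample_count <- function(area_ha) {
  if (!is.numeric(area_ha) || any(!is.finite(area_ha)) || any(area_ha <= 0)) {
    stop("area_ha must be positive and finite", call. = FALSE)
  }
  pmax(1L, as.integer(floor(2.26 * area_ha^0.31)))
}

#' Construct a dust-concentration survey
#'
#' A `dust_survey` holds per-sample concentration records together with the
#' analytical limit of detection (LOD) and, optionally, the sampled area.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param concentration Numeric vector of measured concentrations, mg/kg.
#' @param below_lod Logical vector flagging records below the LOD.
#' @param lod Analytical limit of detection, mg/kg.
#' @param area_ha Optional sampled area, hectares.
#' @return An object of class `dust_survey` with a `records` data frame.
#' @export
dust_survey <- function(sample_id, concentration,
                        below_lod = rep(FALSE, length(concentration)),
                        lod = 4, area_ha = NULL) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) != length(concentration) ||
      length(below_lod) != length(concentration)) {
    stop("sample_id, concentration and below_lod must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration <= 0)) {
    stop("concentrations must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0) {
    stop("lod must be a single positive number", call. = FALSE)
  }
  below_lod <- as.logical(below_lod)
  if (any(below_lod & concentration > lod)) {
    stop("records flagged below_lod must have concentration <= lod",
         call. = FALSE)
  }
  structure(
    list(
      records = data.frame(sample_id = sample_id,
                           concentration = concentration,
                           below_lod = below_lod,
                           stringsAsFactors = FALSE),
      lod = lod,
      area_ha = area_ha
    ),
    class = "dust_survey"
  )
}

#' Substitute or drop below-LOD records
#'
#' Applies a censoring policy to records flagged as below the limit of
#' detection: `"half_lod"` replaces the value with LOD/2 (the default
#' convention), `"lod"` with the LOD itself, and `"drop"` removes the
#' records. Unflagged records are never touched.
#'
#' @param survey A [dust_survey()].
#' @param policy One of `"half_lod"`, `"lod"`, `"drop"`.
#' @return A new `dust_survey` with the policy applied (flags cleared for
#'   substituted records).
#' @export
censor_below_lod <- function(survey, policy = c("half_lod", "lod", "drop")) {
  stopifnot(inherits(survey, "dust_survey"))
  policy <- match.arg(policy)
  rec <- survey$records
  flagged <- rec$below_lod
  if (policy == "drop") {
    rec <- rec[!flagged, , drop = FALSE]
  } else {
    sub <- if (policy == "half_lod") survey$lod / 2 else survey$lod
    rec$concentration[flagged] <- sub
    rec$below_lod[flagged] <- FALSE
  }
  out <- survey
  out$records <- rec
  out
}

#' Descriptive statistics and threshold exceedance of a survey
#'
#' Computes n, mean, sample SD, median, min, max of the concentrations and
#' the fraction of records strictly above a regulatory threshold (default:
#' the Mexican NOM-147 soil arsenic limit of 22 mg/kg).
#'
#' @param survey A non-empty [dust_survey()].
#' @param threshold Regulatory threshold, mg/kg.
#' @return An object of class `survey_summary`: a list with fields `n`,
#'   `mean`, `sd`, `median`, `min`, `max`, `threshold`,
#'   `frac_above_threshold`.
#' @export
summarize_survey <- function(survey, threshold = 22) {
  stopifnot(inherits(survey, "dust_survey"))
  x <- survey$records$concentration
  if (length(x) == 0L) stop("survey is empty", call. = FALSE)
  structure(
    list(
      n = length(x),
      mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else 0,
      median = stats::median(x),
      min = min(x),
      max = max(x),
      threshold = threshold,
      frac_above_threshold = mean(x > threshold)
    ),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("Dust survey: n = %d\n", x$n))
  cat(sprintf("  mean %.2f  sd %.2f  median %.2f  range %.2f-%.2f mg/kg\n",
              x$mean, x$sd, x$median, x$min, x$max))
  cat(sprintf("  fraction above %g mg/kg: %.4f\n",
              x$threshold, x$frac_above_threshold))
  invisible(x)
}

#' @export
print.dust_survey <- function(x, ...) {
  cat(sprintf("dust_survey: %d records, LOD %g mg/kg", nrow(x$records), x$lod))
  if (!is.null(x$area_ha)) cat(sprintf(", area %g ha", x$area_ha))
  cat("\n")
  print(utils::head(x$records))
  invisible(x)
}

#' Read a dust survey from CSV
#'
#' Expects a header with columns `sample_id`, `concentration_mg_kg` and
#' optionally `below_lod` (0/1 or logical); any further columns (e.g.
#' `lat`, `lon`) are ignored by the computations.
#'
#' @param path CSV file path.
#' @param lod Limit of detection to attach, mg/kg.
#' @return A [dust_survey()].
#' @export
read_dust_survey <- function(path, lod = 4) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "concentration_mg_kg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("survey CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$concentration_mg_kg) | df$concentration_mg_kg <= 0)
  if (length(bad)) {
    stop(sprintf("invalid concentration at row %d of %s", bad[1], path),
         call. = FALSE)
  }
  below <- if ("below_lod" %in% names(df)) as.logical(df$below_lod) else
    rep(FALSE, nrow(df))
  dust_survey(df$sample_id, df$concentration_mg_kg, below, lod = lod)
}

#' Write a dust survey to CSV
#'
#' @param survey A [dust_survey()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dust_survey <- function(survey, path) {
  stopifnot(inherits(survey, "dust_survey"))
  df <- survey$records
  names(df) <- c("sample_id", "concentration_mg_kg", "below_lod")
  df$below_lod <- as.integer(df$below_lod)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
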