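#' Distribution specifications for a group's random inputs
#'
#' Builds the lognormal specifications actually sampled for one age group:
#' the dust concentration fitted by moments (mean, SD) and truncated to the
#' observed range, and the body weight fitted from its mean and reported
#' range (central-coverage reading, see [fit_lognormal_range()]).
#'
#' @param f An [exposure_factors()] object.
#' @param bw_coverage Coverage probability for the body-weight range fit.
#' @return List with elements `AsC` and `BW`, both [lognormal_spec()].
#' @export
input_specs <- function(f, bw_coverage = 0.99) {
  asc <- fit_lognormal_moments(f$AsC_mean, f$AsC_sd)
  asc$lower <- f$AsC_min
  asc$upper <- f$AsC_max
  bw <- if (f$BW_min < f$BW_mean && f$BW_mean < f$BW_max) {
    fit_lognormal_range(f$BW_mean, f$BW_min, f$BW_max, coverage = bw_coverage)
  } else {
    # degenerate range collapses body weight to its mean
    lognormal_spec(log(f$BW_mean), 0)
  }
  list(AsC = asc, BW = bw)
}

#' Monte Carlo propagation of concentration and body-weight uncertainty
#'
#' For every age group, draws `n_iterations` paired scenarios of dust
#' arsenic concentration and body weight (the two sensitive inputs; all
#' other factors are constants), evaluates the oral, dermal and inhalation
#' average daily doses, hazard quotients and carcinogenic risks per
#' scenario, and accumulates the within-scenario pathway sums (dose sum,
#' hazard index HI, accumulated cancer risk aCR). Draws are shared across
#' pathways within a scenario, so HI and aCR are sums of jointly simulated
#' quotients. Exceedance fractions are counted against the pathway dose
#' screening limits, the hazard-quotient limit (1) and the cancer-risk
#' limit (1e-5).
#'
#' @param config A [study_config()]; `config$seed` makes the run
#'   reproducible (identical config and seed give identical summaries).
#' @param keep_draws Keep the per-scenario draws and outputs (needed for
#'   plots or custom statistics; default `FALSE` to save memory).
#' @return An object of class `risk_simulation`: per group a list with,
#'   for each of `oral`, `dermal`, `inhalation` and `sum`, the
#'   [mc_summary()] of `add`, `hq` and `cr`; `hi` and `acr` alias the sum
#'   hazard-quotient and cancer-risk summaries.
#' @export
#' @examples
#' cfg <- default_araro_config()
#' cfg$n_iterations <- 200
#' sim <- run_simulation(cfg)
#' sim$groups$preschooler$oral$add$median
run_simulation <- function(config, keep_draws = FALSE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  tox <- config$toxicity
  n <- config$n_iterations

  groups <- lapply(age_groups(), function(g) {
    f <- config$age_groups[[g]]
    specs <- input_specs(f, config$bw_coverage)
    asc <- sample_lognormal(specs$AsC, n)
    bw <- sample_lognormal(specs$BW, n)

    adds <- list(
      oral = add_ingestion(asc, f, BW = bw),
      dermal = add_dermal(asc, f, BW = bw),
      inhalation = add_inhalation(asc, f, BW = bw)
    )
    hqs <- lapply(pathways(), function(p) {
      hazard_quotient(adds[[p]], hq_denominator(p, tox))
    })
    names(hqs) <- pathways()
    crs <- lapply(pathways(), function(p) {
      cadd <- carcinogenic_add(adds[[p]], f$AT, f$cAT)
      cancer_risk(cadd, tox$sf, config$cr_convention)
    })
    names(crs) <- pathways()

    per_pathway <- lapply(pathways(), function(p) {
      list(
        add = mc_summary(adds[[p]], limit = screening_limit(p, tox)),
        hq = mc_summary(hqs[[p]], limit = tox$hq_limit),
        cr = mc_summary(crs[[p]], limit = tox$cr_limit)
      )
    })
    names(per_pathway) <- pathways()

    add_sum <- Reduce(`+`, adds)
    hi <- Reduce(`+`, hqs)
    acr <- Reduce(`+`, crs)
    per_pathway$sum <- list(
      add = mc_summary(add_sum),
      hq = mc_summary(hi, limit = tox$hq_limit),
      cr = mc_summary(acr, limit = tox$cr_limit)
    )
    per_pathway$hi <- per_pathway$sum$hq
    per_pathway$acr <- per_pathway$sum$cr
    if (keep_draws) {
      per_pathway$draws <- list(AsC = asc, BW = bw, add = adds, hq = hqs,
                                cr = crs, hi = hi, acr = acr)
    }
    per_pathway
  })
  names(groups) <- age_groups()

  structure(
    list(groups = groups, config = config, seed = config$seed,
         n_iterations = n),
    class = "risk_simulation"
  )
}

#' Tabulate simulation summaries in the layout of the study's tables
#'
#' One row per age group x pathway (plus the pathway sum), with mean, SD,
#' median, min, max, P95 and the applicable safety limit -- mirroring the
#' dose, hazard-quotient and cancer-risk summary tables.
#'
#' @param sim A [run_simulation()] result.
#' @param metric `"add"`, `"hq"` or `"cr"`.
#' @return A data frame.
#' @export
summary_table <- function(sim, metric = c("add", "hq", "cr")) {
  stopifnot(inherits(sim, "risk_simulation"))
  metric <- match.arg(metric)
  rows <- lapply(age_groups(), function(g) {
    do.call(rbind, lapply(c(pathways(), "sum"), function(p) {
      s <- sim$groups[[g]][[p]][[metric]]
      data.frame(age_group = g, pathway = p, mean = s$mean, sd = s$sd,
                 median = s$median, min = s$min, max = s$max, p95 = s$p95,
                 limit = s$limit, exceed_frac = s$exceed_frac,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.risk_simulation <- function(x, ...) {
  cat(sprintf("risk_simulation: %d iterations, seed %d, CR convention '%s'\n",
              x$n_iterations, x$seed, x$config$cr_convention))
  for (g in age_groups()) {
    hi <- x$groups[[g]]$hi
    acr <- x$groups[[g]]$acr
    cat(sprintf("  %-11s HI mean %.4f (P95 %.4f)  aCR mean %.3e\n",
                g, hi$mean, hi$p95, acr$mean))
  }
  invisible(x)
}

#' Rank-correlation contribution of each random input to an output
#'
#' Re-draws the group's scenarios and attributes output variance to the
#' varying inputs via squared Spearman rank correlations, normalized to
#' sum to one. With a single varying input that input receives 1.0.
#'
#' @param config A [study_config()].
#' @param group One of [age_groups()].
#' @param pathway One of [pathways()]; the analyzed output is that
#'   pathway's average daily dose.
#' @return Named numeric vector of proportions over varying inputs
#'   (`AsC`, `BW`), summing to 1.
#' @export
sensitivity_contributions <- function(config, group, pathway) {
  stopifnot(inherits(config, "study_config"))
  group <- match_age_group(group)
  pathway <- match_pathway(pathway)
  f <- config$age_groups[[group]]
  specs <- input_specs(f, config$bw_coverage)
  set.seed(config$seed)
  n <- config$n_iterations
  asc <- sample_lognormal(specs$AsC, n)
  bw <- sample_lognormal(specs$BW, n)
  out <- switch(pathway,
                oral = add_ingestion(asc, f, BW = bw),
                dermal = add_dermal(asc, f, BW = bw),
                inhalation = add_inhalation(asc, f, BW = bw))
  inputs <- list(AsC = asc, BW = bw)
  varying <- vapply(inputs, function(x) stats::var(x) > 0, logical(1))
  if (!any(varying)) {
    stop("no varying inputs: both distributions are degenerate", call. = FALSE)
  }
  if (sum(varying) == 1L) {
    res <- 1
    names(res) <- names(inputs)[varying]
    return(res)
  }
  rho2 <- vapply(inputs[varying], function(x) {
    stats::cor(x, out, method = "spearman")^2
  }, numeric(1))
  rho2 / sum(rho2)
}
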