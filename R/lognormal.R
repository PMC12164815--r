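#' Lognormal distribution specification with optional truncation
#'
#' The two random inputs of the risk simulation -- dust arsenic
#' concentration and body weight -- are modelled as lognormal variables,
#' optionally truncated to an observed or plausible range in natural units.
#'
#' @param mu Log-scale location (mean of log values).
#' @param sigma Log-scale spread (SD of log values), >= 0.
#' @param lower,upper Truncation bounds in natural units
#'   (defaults: no truncation). `lower` must be positive and below `upper`.
#' @return An object of class `lognormal_spec`.
#' @export
lognormal_spec <- function(mu, sigma, lower = 0, upper = Inf) {
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (lower < 0 || lower >= upper) {
    stop("require 0 <= lower < upper", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, lower = lower, upper = upper),
            class = "lognormal_spec")
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf("lognormal_spec: mu = %.4f, sigma = %.4f (median %.4g)",
              x$mu, x$sigma, exp(x$mu)))
  if (x$lower > 0 || is.finite(x$upper)) {
    cat(sprintf(", truncated to [%g, %g]", x$lower, x$upper))
  }
  cat("\n")
  invisible(x)
}

#' Fit a lognormal distribution from its arithmetic mean and SD
#'
#' Method-of-moments inversion: sigma^2 = ln(1 + (sd/mean)^2),
#' mu = ln(mean) - sigma^2/2. With sd = 0 the fit degenerates to a point
#' mass at `mean`. No truncation bounds are set; attach them afterwards via
#' [lognormal_spec()] or by modifying the returned object.
#'
#' @param mean Arithmetic mean in natural units (> 0).
#' @param sd Arithmetic standard deviation (>= 0).
#' @return A [lognormal_spec()] without truncation.
#' @export
#' @examples
#' fit_lognormal_moments(15.21, 5.94)  # mu 2.651, sigma 0.3768
fit_lognormal_moments <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  lognormal_spec(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Fit a lognormal distribution from a mean and a reported range
#'
#' Body weights are tabulated as a mean plus a population range only. The
#' range [lo, hi] is read as the central `coverage` interval of the
#' untruncated lognormal, giving sigma = (ln hi - ln lo) / (2 z) with z the
#' standard-normal quantile of (1 + coverage)/2; mu is then chosen so the
#' arithmetic mean matches (mu = ln mean - sigma^2/2). Truncation bounds
#' are set to [lo, hi].
#'
#' @param mean Arithmetic mean, natural units.
#' @param lo,hi Reported range, natural units (0 < lo < mean < hi).
#' @param coverage Central coverage probability assigned to [lo, hi]
#'   (default 0.99: the range is read as near-extremes of the population).
#' @return A [lognormal_spec()] truncated to [lo, hi].
#' @export
#' @examples
#' fit_lognormal_range(16.31, 10, 39)  # preschooler body weight, kg
fit_lognormal_range <- function(mean, lo, hi, coverage = 0.99) {
  if (!(lo > 0 && lo < mean && mean < hi)) {
    stop("require 0 < lo < mean < hi", call. = FALSE)
  }
  if (coverage <= 0 || coverage >= 1) {
    stop("coverage must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + coverage) / 2)
  sigma <- (log(hi) - log(lo)) / (2 * z)
  lognormal_spec(mu = log(mean) - sigma^2 / 2, sigma = sigma,
                 lower = lo, upper = hi)
}

#' Draw truncated lognormal samples
#'
#' Rejection sampling: draws outside `[lower, upper]` are redrawn until the
#' sample is complete. A degenerate spec (sigma = 0) yields a constant
#' vector at exp(mu). Passing a seed makes the draw reproducible; with
#' `seed = NULL` the current RNG stream is used (so a caller that seeds
#' once can make several dependent draws).
#'
#' @param spec A [lognormal_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` in natural units.
#' @export
sample_lognormal <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "lognormal_spec"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (spec$sigma == 0) {
    v <- exp(spec$mu)
    if (v < spec$lower || v > spec$upper) {
      stop("degenerate spec lies outside truncation bounds", call. = FALSE)
    }
    return(rep(v, n))
  }
  mass <- stats::plnorm(spec$upper, spec$mu, spec$sigma) -
    stats::plnorm(spec$lower, spec$mu, spec$sigma)
  if (mass <= 1e-12) {
    stop("truncation interval carries (near-)zero probability mass",
         call. = FALSE)
  }
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("rejection sampling failed to fill the truncation interval",
           call. = FALSE)
    }
    need <- n - length(out)
    # oversample by the inverse acceptance rate to finish in few rounds
    m <- max(need, ceiling(need / mass * 1.1))
    x <- stats::rlnorm(m, spec$mu, spec$sigma)
    x <- x[x >= spec$lower & x <= spec$upper]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Quantile of a truncated lognormal distribution
#'
#' Closed-form quantile used as an independent check on the rejection
#' sampler: maps p to the untruncated quantile scale restricted to the
#' truncation interval.
#'
#' @param p Probability in [0, 1]; vectorized.
#' @param spec A [lognormal_spec()].
#' @return Quantiles in natural units.
#' @export
qlnorm_truncated <- function(p, spec) {
  stopifnot(inherits(spec, "lognormal_spec"))
  if (spec$sigma == 0) return(rep(exp(spec$mu), length(p)))
  plo <- stats::plnorm(spec$lower, spec$mu, spec$sigma)
  phi <- stats::plnorm(spec$upper, spec$mu, spec$sigma)
  stats::qlnorm(plo + p * (phi - plo), spec$mu, spec$sigma)
}

#' Summarize a vector of simulated values
#'
#' Standard Monte Carlo summary: mean, SD, median, min, max, 95th and 97th
#' percentiles (linear-interpolation convention, R type 7), and the
#' fraction of iterations strictly above a stated limit.
#'
#' @param x Numeric vector of simulated values.
#' @param limit Safety limit against which exceedance is counted
#'   (NA: no exceedance fraction reported).
#' @return An object of class `mc_summary`.
#' @export
mc_summary <- function(x, limit = NA_real_) {
  if (!length(x)) stop("cannot summarize an empty vector", call. = FALSE)
  q <- stats::quantile(x, c(0.95, 0.97), names = FALSE, type = 7)
  structure(
    list(
      mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else 0,
      median = stats::median(x),
      min = min(x),
      max = max(x),
      p95 = q[1],
      p97 = q[2],
      limit = limit,
      exceed_frac = if (is.na(limit)) NA_real_ else mean(x > limit),
      n_iter = length(x)
    ),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("mc_summary (n = %d): mean %.3e +/- %.3e, median %.3e\n",
              x$n_iter, x$mean, x$sd, x$median))
  cat(sprintf("  range %.3e-%.3e, P95 %.3e, P97 %.3e",
              x$min, x$max, x$p95, x$p97))
  if (!is.na(x$limit)) {
    cat(sprintf("; frac > %.3g: %.4f", x$limit, x$exceed_frac))
  }
  cat("\n")
  invisible(x)
}
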