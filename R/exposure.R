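# Exposure model: per-stratum distribution of the UPF share of total energy
# and counterfactual transformations of it.
#
# A stratum's intake is represented as a log-normal distribution moment-matched
# to the reported arithmetic mean and SD, truncated to [0, upper] (upper = 100%
# of energy at baseline; counterfactual transforms may tighten it).  A zero SD
# degenerates to a point mass.

.lnorm_dist <- function(meanlog, sdlog, upper) {
  structure(list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 upper = upper, norm = plnorm(upper, meanlog, sdlog)),
            class = "exposure_dist")
}

#' Degenerate (point-mass) exposure distribution
#'
#' @param x Location, % of total energy (>= 0).
#' @return An `exposure_dist` of family `point_mass`.
#' @export
point_mass <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 100)
    stop("point mass location must lie in [0, 100] % of energy", call. = FALSE)
  structure(list(family = "point_mass", location = x), class = "exposure_dist")
}

#' Fit a stratum exposure distribution from its mean and SD
#'
#' Moment-matches a log-normal distribution to the arithmetic mean and SD of
#' the UPF energy share: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`.  The density is truncated to
#' `[0, upper]` and renormalised (the mass above 100% of energy is negligible
#' for realistic intakes).  `sd_pct = 0` returns a point mass.
#'
#' @param mean_pct Mean UPF share of total energy, % in (0, 100).
#' @param sd_pct Standard deviation of the share, % (>= 0).
#' @param upper Upper support bound, % of energy (default 100).
#' @return An object of class `exposure_dist`.
#' @export
#' @examples
#' fit_exposure(19.4, 8.7)
fit_exposure <- function(mean_pct, sd_pct, upper = 100) {
  if (!is.numeric(mean_pct) || length(mean_pct) != 1L ||
      mean_pct <= 0 || mean_pct >= 100)
    stop("'mean_pct' must lie strictly between 0 and 100", call. = FALSE)
  if (!is.numeric(sd_pct) || length(sd_pct) != 1L || sd_pct < 0)
    stop("'sd_pct' must be non-negative", call. = FALSE)
  if (sd_pct == 0) return(point_mass(mean_pct))
  s2 <- log(1 + (sd_pct / mean_pct)^2)
  .lnorm_dist(meanlog = log(mean_pct) - s2 / 2, sdlog = sqrt(s2),
              upper = upper)
}

#' Exposure density, CDF, quantile and mean
#'
#' Evaluators for `exposure_dist` objects.  Densities and CDFs account for the
#' truncation of the log-normal support; the point-mass family has no density
#' (its integrals are handled in closed form by the PIF engine).
#'
#' @param dist An `exposure_dist`.
#' @param x Intake values, % of energy (vectorised).
#' @param p Probabilities in (0, 1).
#' @return Numeric vector (`exp_density`, `exp_cdf`), quantile in % energy
#'   (`exp_quantile`), or scalar mean (`exp_mean`).
#' @name exposure-evaluators
NULL

#' @rdname exposure-evaluators
#' @export
exp_density <- function(dist, x) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (dist$family == "point_mass")
    stop("a point mass has no density; use closed-form expectations",
         call. = FALSE)
  ifelse(x < 0 | x > dist$upper, 0,
         dlnorm(x, dist$meanlog, dist$sdlog) / dist$norm)
}

#' @rdname exposure-evaluators
#' @export
exp_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (dist$family == "point_mass")
    return(as.numeric(x >= dist$location))
  pmin(1, plnorm(pmin(x, dist$upper), dist$meanlog, dist$sdlog) / dist$norm)
}

#' @rdname exposure-evaluators
#' @export
exp_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly between 0 and 1", call. = FALSE)
  if (dist$family == "point_mass") return(rep(dist$location, length(p)))
  qlnorm(p * dist$norm, dist$meanlog, dist$sdlog)
}

#' @rdname exposure-evaluators
#' @export
exp_mean <- function(dist) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (dist$family == "point_mass") return(dist$location)
  # mean of a log-normal truncated to [0, upper]
  ml <- dist$meanlog; sl <- dist$sdlog
  exp(ml + sl^2 / 2) * pnorm((log(dist$upper) - ml - sl^2) / sl) / dist$norm
}

#' Quantile cut-point of an exposure distribution
#'
#' Intake below which a fraction `q` of the stratum lies; used to anchor the
#' first-quintile counterfactual (q = 0.2).
#'
#' @param dist An `exposure_dist`.
#' @param q Fraction in (0, 1).
#' @return Intake cut-point, % of total energy.
#' @export
quintile_cutpoint <- function(dist, q = 0.2) exp_quantile(dist, q)

# ---- counterfactual scenarios -------------------------------------------

#' Counterfactual intake scenarios
#'
#' Constructors for the scenario objects accepted by [apply_scenario()] and
#' the pipeline functions:
#' * `scenario_baseline()` leaves the exposure unchanged (PIF = 0);
#' * `scenario_reduction(r)` multiplies every individual intake by `1 - r`
#'   (for a log-normal this shifts `meanlog` by `log(1 - r)` and leaves the
#'   log-scale SD, hence the coefficient of variation, unchanged);
#' * `scenario_quintile(q)` moves the whole stratum to its own bottom
#'   quintile: either the baseline distribution truncated at its `q`-quantile
#'   and renormalised (`method = "truncate"`, default) or a point mass at the
#'   mean of that bottom segment (`method = "point_mass"`).
#'
#' @param r Proportional reduction fraction in \[0, 1\].
#' @param q Quantile defining the bottom segment (default 0.2).
#' @param method Interpretation of the quintile shift; see Details.
#' @return An object of class `scenario` with a `label` field.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_baseline <- function() {
  structure(list(type = "baseline", label = "baseline"), class = "scenario")
}

#' @rdname scenarios
#' @export
scenario_reduction <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1)
    stop("reduction fraction 'r' must lie in [0, 1]", call. = FALSE)
  structure(list(type = "proportional_reduction", r = r,
                 label = sprintf("reduce_%g", 100 * r)),
            class = "scenario")
}

#' @rdname scenarios
#' @export
scenario_quintile <- function(q = 0.2, method = c("truncate", "point_mass")) {
  method <- match.arg(method)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must lie strictly between 0 and 1", call. = FALSE)
  structure(list(type = "first_quintile", q = q, method = method,
                 label = "first_quintile"),
            class = "scenario")
}

#' Default counterfactual scenario set
#'
#' The four counterfactuals evaluated by the primary model: 10%, 20% and 50%
#' proportional reductions in UPF intake and the shift to the baseline first
#' quintile.
#'
#' @return Named list of `scenario` objects.
#' @export
default_scenarios <- function() {
  s <- list(scenario_reduction(0.1), scenario_reduction(0.2),
            scenario_reduction(0.5), scenario_quintile())
  names(s) <- vapply(s, `[[`, "", "label")
  s
}

#' Transform an exposure distribution under a counterfactual scenario
#'
#' @param dist Baseline `exposure_dist`.
#' @param scenario A [scenarios] object.
#' @return The counterfactual `exposure_dist`.
#' @export
#' @examples
#' d <- fit_exposure(19.4, 8.7)
#' apply_scenario(d, scenario_reduction(0.5))
apply_scenario <- function(dist, scenario) {
  stopifnot(inherits(dist, "exposure_dist"), inherits(scenario, "scenario"))
  switch(scenario$type,
    baseline = dist,
    proportional_reduction = {
      r <- scenario$r
      if (dist$family == "point_mass")
        return(point_mass(dist$location * (1 - r)))
      if (r == 1) return(point_mass(0))
      # law of (1-r)X: shift meanlog; the truncation bound scales with X
      .lnorm_dist(dist$meanlog + log1p(-r), dist$sdlog,
                  upper = dist$upper * (1 - r))
    },
    first_quintile = {
      if (dist$family == "point_mass") return(dist)
      cut <- exp_quantile(dist, scenario$q)
      trunc <- .lnorm_dist(dist$meanlog, dist$sdlog, upper = cut)
      if (scenario$method == "point_mass") point_mass(exp_mean(trunc))
      else trunc
    },
    stop("unknown scenario type: ", scenario$type, call. = FALSE))
}

#' @export
print.exposure_dist <- function(x, ...) {
  if (x$family == "point_mass") {
    cat(sprintf("exposure: point mass at %.2f%% energy\n", x$location))
  } else {
    cat(sprintf(
      "exposure: log-normal(meanlog %.4f, sdlog %.4f) truncated to [0, %.4g]%%, mean %.2f%%\n",
      x$meanlog, x$sdlog, x$upper, exp_mean(x)))
  }
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("counterfactual scenario:", x$label, "\n")
  invisible(x)
}
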