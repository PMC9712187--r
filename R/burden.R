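# Burden accounting: PIFs -> attributable/averted events, aggregation and
# reporting helpers.

#' Validate a stratified exposure table
#'
#' Required columns: `sex`, `age_group`, `mean_pct`, `sd_pct`, `population`;
#' optional `se_mean_pct` (standard error of the stratum mean, used by the
#' Monte Carlo intake perturbation).  Age bands outside 30-69 are rejected
#' with the offending rows named, since events outside that range are not
#' premature under this model.
#'
#' @param df A `data.frame`.
#' @return The validated `data.frame` (invisibly unchanged), with `sex` and
#'   `age_group` as character.
#' @export
validate_exposure_table <- function(df) {
  need <- c("sex", "age_group", "mean_pct", "sd_pct", "population")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("exposure table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sex <- as.character(df$sex)
  df$age_group <- as.character(df$age_group)
  .check_strata(df)
  if (any(df$mean_pct <= 0 | df$mean_pct >= 100))
    stop("exposure means must lie strictly between 0 and 100% of energy",
         call. = FALSE)
  if (any(df$sd_pct < 0))
    stop("exposure SDs must be non-negative", call. = FALSE)
  if (any(df$population < 0))
    stop("populations must be non-negative", call. = FALSE)
  key <- paste(df$sex, df$age_group)
  if (anyDuplicated(key))
    stop("duplicated stratum rows: ", paste(unique(key[duplicated(key)]),
         collapse = "; "), call. = FALSE)
  df
}

.check_strata <- function(df) {
  bad_sex <- !df$sex %in% .SEXES
  if (any(bad_sex))
    stop("invalid sex in row(s) ", paste(which(bad_sex), collapse = ", "),
         ": ", paste(unique(df$sex[bad_sex]), collapse = ", "), call. = FALSE)
  bad_age <- !df$age_group %in% .AGE_GROUPS
  if (any(bad_age))
    stop("age group outside the premature range 30-69 in row(s) ",
         paste(which(bad_age), collapse = ", "), ": ",
         paste(unique(df$age_group[bad_age]), collapse = ", "),
         "; only bands ", .AGE_GROUPS[1], " ... ",
         .AGE_GROUPS[length(.AGE_GROUPS)], " are modelled", call. = FALSE)
  invisible(df)
}

#' Validate a stratified event table
#'
#' Required columns: `sex`, `age_group`, `outcome` (`CHD`/`stroke`), `metric`
#' (`deaths`/`incident_cases`/`dalys`), `value`, and 95% uncertainty interval
#' columns `ui_low`, `ui_high` with `ui_low <= value <= ui_high`.  Ages
#' outside 30-69 are rejected with the offending rows named.
#'
#' @param df A `data.frame`.
#' @return The validated `data.frame`.
#' @export
validate_event_table <- function(df) {
  need <- c("sex", "age_group", "outcome", "metric", "value",
            "ui_low", "ui_high")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("sex", "age_group", "outcome", "metric"))
    df[[col]] <- as.character(df[[col]])
  .check_strata(df)
  bad <- !df$outcome %in% .OUTCOMES
  if (any(bad))
    stop("invalid outcome in row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  bad <- !df$metric %in% .METRICS
  if (any(bad))
    stop("invalid metric in row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  if (any(df$value < 0))
    stop("event counts must be non-negative", call. = FALSE)
  bad <- df$ui_low > df$value | df$value > df$ui_high
  if (any(bad, na.rm = TRUE))
    stop("uncertainty interval must bracket the value in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  df
}

#' Read stratified input tables
#'
#' Thin CSV readers that apply the corresponding validator.
#'
#' @param path Path to a comma-separated file with a header row.
#' @return Validated `data.frame`.
#' @name table-readers
NULL

#' @rdname table-readers
#' @export
read_exposure_table <- function(path)
  validate_exposure_table(read.csv(path, stringsAsFactors = FALSE))

#' @rdname table-readers
#' @export
read_event_table <- function(path)
  validate_event_table(read.csv(path, stringsAsFactors = FALSE))

#' Events attributable to an impact fraction
#'
#' @param pif Potential impact fraction in \[0, 1\].
#' @param baseline_events Baseline event count (>= 0).
#' @return `pif * baseline_events`, unrounded.
#' @export
attributable_events <- function(pif, baseline_events) {
  if (any(pif < 0 | pif > 1))
    stop("'pif' must lie in [0, 1]", call. = FALSE)
  if (any(baseline_events < 0))
    stop("'baseline_events' must be non-negative", call. = FALSE)
  pif * baseline_events
}

# PIFs for one stratum: named list (attributable + one entry per scenario)
.stratum_pifs <- function(curve, base, scenarios, grid_step, m) {
  ib <- .rr_integral(curve, base, grid_step, m)
  if (!is.finite(ib) || ib <= 0)
    stop("non-positive baseline integral; check inputs", call. = FALSE)
  paf <- 1 - rr_at(curve, curve$spec$x_tmrel) / ib
  out <- c(list(attributable = paf),
           lapply(scenarios, function(s) {
             cf <- apply_scenario(base, s)
             (ib - .rr_integral(curve, cf, grid_step, m)) / ib
           }))
  out
}

#' Deterministic stratum-level burden computation
#'
#' For every stratum and outcome, computes the population attributable
#' fraction (counterfactual at TMREL, reported under scenario label
#' `"attributable"`) and the PIF of each counterfactual scenario, then
#' multiplies by the stratum's baseline events for every metric.
#'
#' @param exposure Exposure table (see [validate_exposure_table()]).
#' @param events Event table (see [validate_event_table()]).
#' @param rr_specs Named list of [rr_spec()] objects keyed by outcome.
#' @param scenarios Named list of [scenarios] objects (default the 10/20/50%
#'   reductions and the first-quintile shift).
#' @param grid_step,m Integration controls passed to the PIF engine.
#' @return `data.frame` of cells with columns `scenario`, `sex`, `age_group`,
#'   `outcome`, `metric`, `pif`, `events` (baseline) and `averted`
#'   (`pif * events`; for scenario `"attributable"` this is the attributable
#'   burden).
#' @export
compute_burden <- function(exposure, events, rr_specs = default_rr_specs(),
                           scenarios = default_scenarios(),
                           grid_step = 0.1, m = 100) {
  exposure <- validate_exposure_table(exposure)
  events <- validate_event_table(events)
  if (length(scenarios) && is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "label")
  curves <- lapply(rr_specs, build_rr_curve)
  out <- vector("list", nrow(exposure) * length(curves))
  k <- 0L
  for (i in seq_len(nrow(exposure))) {
    base <- fit_exposure(exposure$mean_pct[i], exposure$sd_pct[i])
    ev_i <- events[events$sex == exposure$sex[i] &
                   events$age_group == exposure$age_group[i], , drop = FALSE]
    for (o in names(curves)) {
      pifs <- .stratum_pifs(curves[[o]], base, scenarios, grid_step, m)
      ev_o <- ev_i[ev_i$outcome == o, , drop = FALSE]
      if (!nrow(ev_o)) next
      k <- k + 1L
      out[[k]] <- do.call(rbind, lapply(names(pifs), function(sc)
        data.frame(scenario = sc, sex = exposure$sex[i],
                   age_group = exposure$age_group[i], outcome = o,
                   metric = ev_o$metric, pif = pifs[[sc]],
                   events = ev_o$value,
                   averted = pifs[[sc]] * ev_o$value,
                   stringsAsFactors = FALSE)))
    }
  }
  cells <- do.call(rbind, out[seq_len(k)])
  rownames(cells) <- NULL
  cells
}

#' Aggregate stratum-level burden cells
#'
#' Sums attributable/averted events over age strata within sex, adds
#' sex-combined (`"total"`) rows and outcome-combined (`"CVD"`) rows, per
#' scenario and metric.  Totals are exact sums of the unrounded cells;
#' rounding is applied only at the reporting layer ([report_rounding()]).
#'
#' @param cells Output of [compute_burden()].
#' @return `data.frame` with columns `scenario`, `metric`, `outcome`
#'   (including `"CVD"`), `sex` (including `"total"`), `events`, `averted`.
#' @export
aggregate_burden <- function(cells) {
  if (!nrow(cells)) stop("no cells to aggregate", call. = FALSE)
  by_sex <- aggregate(cbind(events, averted) ~ scenario + metric + outcome + sex,
                      data = cells, FUN = sum)
  sex_tot <- aggregate(cbind(events, averted) ~ scenario + metric + outcome,
                       data = by_sex, FUN = sum)
  sex_tot$sex <- "total"
  lev1 <- rbind(by_sex, sex_tot[names(by_sex)])
  cvd <- aggregate(cbind(events, averted) ~ scenario + metric + sex,
                   data = lev1, FUN = sum)
  cvd$outcome <- "CVD"
  agg <- rbind(lev1, cvd[names(lev1)])
  agg <- agg[order(agg$scenario, agg$metric, agg$outcome, agg$sex), ]
  rownames(agg) <- NULL
  agg
}

#' Nearest-hundred reporting rounding
#'
#' Event counts are reported rounded to the nearest hundred, halves away from
#' zero.  Applied only when reporting, never inside the computation.
#'
#' @param value Numeric vector (event counts).
#' @return Rounded counts.
#' @export
#' @examples
#' report_rounding(c(19237.4, 150, 0))
report_rounding <- function(value) {
  sign(value) * floor(abs(value) / 100 + 0.5) * 100
}

#' Percentage of total events that is attributable
#'
#' @param attributable Attributable event count.
#' @param total_events Total event count (> 0).
#' @return Integer percentage, rounded half away from zero.
#' @export
#' @examples
#' percent_attributable(19200, 88438)  # 22
percent_attributable <- function(attributable, total_events) {
  if (any(total_events <= 0))
    stop("'total_events' must be positive", call. = FALSE)
  if (any(attributable < 0))
    stop("'attributable' must be non-negative", call. = FALSE)
  .round_half_up(100 * attributable / total_events)
}

#' Outcome and sex shares of an aggregated burden
#'
#' For one scenario and metric, expresses each outcome's (and each sex's)
#' attributable/averted events as an integer percentage of the CVD total,
#' with the denominators carried alongside so shares stay auditable.
#'
#' @param agg Output of [aggregate_burden()].
#' @param scenario Scenario label (default `"attributable"`).
#' @param metric Metric (default `"deaths"`).
#' @return `data.frame` with columns `dimension` (`outcome`/`sex`), `level`,
#'   `averted`, `denominator`, `share_pct`.
#' @export
burden_shares <- function(agg, scenario = "attributable", metric = "deaths") {
  sub <- agg[agg$scenario == scenario & agg$metric == metric, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for that scenario/metric", call. = FALSE)
  denom <- sub$averted[sub$outcome == "CVD" & sub$sex == "total"]
  if (!length(denom) || denom <= 0)
    stop("CVD total is zero; shares undefined", call. = FALSE)
  oc <- sub[sub$outcome != "CVD" & sub$sex == "total", , drop = FALSE]
  sx <- sub[sub$outcome == "CVD" & sub$sex != "total", , drop = FALSE]
  data.frame(
    dimension = c(rep("outcome", nrow(oc)), rep("sex", nrow(sx))),
    level = c(oc$outcome, sx$sex),
    averted = c(oc$averted, sx$averted),
    denominator = denom,
    share_pct = .round_half_up(100 * c(oc$averted, sx$averted) / denom),
    stringsAsFactors = FALSE)
}

#' Bar chart of averted events by scenario
#'
#' Minimal graphical summary: total averted CVD events per counterfactual
#' scenario for one metric, as a base-graphics bar chart.
#'
#' @param agg Output of [aggregate_burden()].
#' @param metric Metric to plot (default `"deaths"`).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted named vector.
#' @export
plot_averted <- function(agg, metric = "deaths", ...) {
  sub <- agg[agg$metric == metric & agg$outcome == "CVD" &
             agg$sex == "total" & agg$scenario != "attributable", ,
             drop = FALSE]
  if (!nrow(sub)) stop("nothing to plot", call. = FALSE)
  v <- stats::setNames(sub$averted, sub$scenario)
  graphics::barplot(v, ylab = paste("averted", metric),
                    xlab = "scenario", ...)
  invisible(v)
}
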