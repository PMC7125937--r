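# Adaptation scenarios: which period's OT and SMT fields feed the relative-
# risk evaluation for a future projection.
#
# "Adapting to SMT" flattens the risk curve as summers warm (future SMT,
# reference OT). "Lagged adaptation to OT" assumes people adjust to half the
# century's shift in the daily temperature distribution, implemented as the
# average of the baseline-threshold run and the fully-shifted-threshold run.

#' Adaptation scenario names
#'
#' @return Character vector of the five recognized scenarios.
#' @export
adaptation_scenarios <- function() {
  c("none", "smt", "lagged_ot", "both_lagged", "both_nonlagged")
}

#' Plan the (OT, SMT, weight) runs for an adaptation scenario
#'
#' Each scenario is a weighted set of engine runs over the future
#' temperatures, differing only in which period's OT and SMT fields are used:
#' \describe{
#'   \item{none}{reference OT, reference SMT, weight 1.}
#'   \item{smt}{reference OT, future SMT, weight 1 ("adapting to SMT").}
#'   \item{lagged_ot}{(reference OT, reference SMT, 1/2) plus
#'     (future OT, reference SMT, 1/2) ("lagged adaptation to OT").}
#'   \item{both_lagged}{(reference OT, future SMT, 1/2) plus
#'     (future OT, future SMT, 1/2).}
#'   \item{both_nonlagged}{future OT, future SMT, weight 1.}
#' }
#'
#' @param scenario One of [adaptation_scenarios()].
#' @param exposure_ref,exposure_future [exposure_fields()] on the same grid.
#' @param lag_fraction Fraction of the OT shift adapted to in the lagged
#'   scenarios, default 0.5 (values other than 0.5 depart from the reference
#'   method and are labelled accordingly in run manifests).
#' @return List of runs, each `list(ot, smt, weight, label)`; weights sum
#'   to 1.
#' @export
plan_runs <- function(scenario = adaptation_scenarios(), exposure_ref,
                      exposure_future, lag_fraction = 0.5) {
  scenario <- match.arg(scenario)
  if (!all(dim(exposure_ref$ot) == dim(exposure_future$ot))) {
    stop("alignment error: exposure field sets on different grids", call. = FALSE)
  }
  if (lag_fraction < 0 || lag_fraction > 1) {
    stop("input error: `lag_fraction` must be in [0, 1]", call. = FALSE)
  }
  run <- function(ot, smt, weight, label) list(ot = ot, smt = smt,
                                               weight = weight, label = label)
  w <- lag_fraction
  switch(scenario,
    none = list(run(exposure_ref$ot, exposure_ref$smt, 1, "ot_ref/smt_ref")),
    smt = list(run(exposure_ref$ot, exposure_future$smt, 1, "ot_ref/smt_fut")),
    lagged_ot = list(
      run(exposure_ref$ot, exposure_ref$smt, 1 - w, "ot_ref/smt_ref"),
      run(exposure_future$ot, exposure_ref$smt, w, "ot_fut/smt_ref")),
    both_lagged = list(
      run(exposure_ref$ot, exposure_future$smt, 1 - w, "ot_ref/smt_fut"),
      run(exposure_future$ot, exposure_future$smt, w, "ot_fut/smt_fut")),
    both_nonlagged = list(run(exposure_future$ot, exposure_future$smt, 1,
                              "ot_fut/smt_fut"))
  )
}

#' Project a future decade under an adaptation scenario
#'
#' Runs [project_scenario()] once per planned (OT, SMT) pair and combines
#' the results with the plan weights (the lagged average is applied to death
#' totals, i.e. the response, not to the OT field itself; set
#' `average_fields = TRUE` to average the OT/SMT fields instead as a
#' sensitivity variant).
#'
#' @param tg_future Future-decade `temp_grid`.
#' @param pop Population matrix.
#' @param bm A [baseline_mortality()].
#' @param scenario One of [adaptation_scenarios()].
#' @param exposure_ref,exposure_future Exposure fields of the reference and
#'   future decades.
#' @param params A `gen_erf_params`.
#' @param pop_scale National population factor for the future decade.
#' @param lag_fraction See [plan_runs()].
#' @param average_fields If `TRUE`, run once on weight-averaged OT/SMT
#'   fields instead of averaging run totals.
#' @param af_convention See [attributable_deaths()].
#' @return A `mortality_result` whose components are the weighted
#'   combinations of the constituent runs; `runs` holds the per-run decadal
#'   means and labels.
#' @export
project_adaptation <- function(tg_future, pop, bm, scenario, exposure_ref,
                               exposure_future, params, pop_scale = 1,
                               lag_fraction = 0.5, average_fields = FALSE,
                               af_convention = c("rr_minus_1", "excess_over_rr")) {
  af_convention <- match.arg(af_convention)
  plan <- plan_runs(scenario, exposure_ref, exposure_future, lag_fraction)
  if (average_fields && length(plan) > 1L) {
    ot <- Reduce(`+`, lapply(plan, function(r) r$weight * r$ot))
    smt <- Reduce(`+`, lapply(plan, function(r) r$weight * r$smt))
    plan <- list(list(ot = ot, smt = smt, weight = 1, label = "field_average"))
  }
  runs <- lapply(plan, function(r) {
    project_scenario(tg_future, pop, bm, list(ot = r$ot, smt = r$smt),
                     params, pop_scale = pop_scale,
                     af_convention = af_convention)
  })
  wts <- vapply(plan, `[[`, numeric(1), "weight")
  combined <- runs[[1]]
  combined$deaths_by_cell_year <- Reduce(`+`, Map(function(r, w)
    w * r$deaths_by_cell_year, runs, wts))
  combined$annual_totals <- colSums(combined$deaths_by_cell_year)
  names(combined$annual_totals) <- combined$years
  combined$decadal_mean <- mean(combined$annual_totals)
  combined$warnings <- list(
    n_clamped = sum(vapply(runs, function(r) r$warnings$n_clamped, numeric(1))),
    n_smt_above_xint = sum(vapply(runs, function(r)
      r$warnings$n_smt_above_xint, numeric(1))))
  combined$runs <- data.frame(
    label = vapply(plan, `[[`, character(1), "label"),
    weight = wts,
    decadal_mean = vapply(runs, `[[`, numeric(1), "decadal_mean"))
  combined$scenario <- scenario
  combined
}

#' Fraction of the no-adaptation increase retained under adaptation
#'
#' Both arguments are increases (future minus baseline decadal-mean deaths).
#' Returned as a percent: 100 means adaptation changed nothing, 0 means it
#' eliminated the increase.
#'
#' @param increase_no_adapt Increase without adaptation (> 0).
#' @param increase_adapt Increase under the adaptation scenario.
#' @return Percent of the no-adaptation increase retained.
#' @export
adaptation_attenuation <- function(increase_no_adapt, increase_adapt) {
  if (!is.finite(increase_no_adapt) || increase_no_adapt <= 0) {
    stop("undefined ratio: no-adaptation increase must be > 0", call. = FALSE)
  }
  100 * increase_adapt / increase_no_adapt
}
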