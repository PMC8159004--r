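# Treasury-style unemployment scenarios: yearly aggregate rates
# 2020-2024 over a constant 4% pre-shock baseline, mapped onto model
# cycles (the life-table starts its population in 2011, so calendar
# 2020+k is modelled as cycle k).

new_scenario <- function(name, rates, years = 2020:2024,
                         baseline_rate = 0.04, duration = 5L) {
  stopifnot(length(rates) == length(years))
  if (any(rates < 0 | rates > 1) || baseline_rate < 0 ||
      baseline_rate > 1)
    stop("scenario rates must lie in [0, 1]", call. = FALSE)
  if (!duration %in% c(5L, 10L))
    stop("shock duration must be 5 or 10 years", call. = FALSE)
  structure(list(name = name, years = as.integer(years),
                 rates = as.numeric(rates),
                 baseline_rate = baseline_rate,
                 duration = as.integer(duration)),
            class = "cvd_scenario")
}

#' Built-in pandemic unemployment scenarios
#'
#' The four published Treasury projections of yearly unemployment rates
#' 2020-2024 plus the no-pandemic baseline (constant 4\%):
#' \describe{
#'   \item{baseline}{4\% every year.}
#'   \item{base_case}{5.3, 7.7, 7.6, 6.6, 5.3 (\%).}
#'   \item{early_recovery}{5.3, 7.7, 6.4, 5.5, 4.8 (\%): earlier
#'     recovery in services exports.}
#'   \item{extended_border}{5.3, 7.7, 8.1, 7.6, 6.6 (\%): border
#'     restrictions extended.}
#'   \item{resurgence}{5.3, 9.0, 8.5, 7.3, 5.8 (\%): resurgence in
#'     community transmission.}
#' }
#'
#' @return named list of `cvd_scenario` objects.
#' @export
#' @examples
#' builtin_scenarios()$base_case$rates
builtin_scenarios <- function() {
  list(
    baseline = new_scenario("baseline", rep(0.04, 5)),
    base_case = new_scenario("base_case",
                             c(0.053, 0.077, 0.076, 0.066, 0.053)),
    early_recovery = new_scenario("early_recovery",
                                  c(0.053, 0.077, 0.064, 0.055, 0.048)),
    extended_border = new_scenario("extended_border",
                                   c(0.053, 0.077, 0.081, 0.076, 0.066)),
    resurgence = new_scenario("resurgence",
                              c(0.053, 0.090, 0.085, 0.073, 0.058))
  )
}

#' Yearly aggregate unemployment increments of a scenario
#'
#' The absolute difference between the scenario's projected yearly
#' rates and the constant pre-shock baseline rate.
#'
#' @param scenario a `cvd_scenario`.
#' @param floor_zero floor negative increments at zero (all built-in
#'   scenarios are non-negative anyway).
#' @return data frame with columns `year`, `increment` (proportion).
#' @export
#' @examples
#' scenario_increments(builtin_scenarios()$base_case)
scenario_increments <- function(scenario, floor_zero = FALSE) {
  if (!inherits(scenario, "cvd_scenario"))
    stop("expected a 'cvd_scenario'", call. = FALSE)
  inc <- scenario$rates - scenario$baseline_rate
  if (floor_zero) inc <- pmax(inc, 0)
  data.frame(year = scenario$years, increment = inc)
}

#' Map calendar-year increments onto model cycles
#'
#' The life-table population starts in `model_start_year` (default
#' 2011), so the pandemic shock of calendar year `2020 + k` is applied
#' at model cycle `k`. A 10-year sensitivity either holds the final
#' increment for cycles 5-9 (`"hold_last"`, the default) or repeats the
#' whole 5-year profile (`"repeat"`). Cycles at or beyond the duration
#' carry zero shock.
#'
#' @param increments data frame from [scenario_increments()].
#' @param model_start_year first model calendar year.
#' @param duration 5 or 10 years.
#' @param extension `"hold_last"` or `"repeat"`.
#' @return data frame with columns `cycle` (0-based), `year` (pandemic
#'   calendar year), `model_year`, `increment`.
#' @export
map_to_model_years <- function(increments, model_start_year = 2011L,
                               duration = 5L,
                               extension = c("hold_last", "repeat")) {
  extension <- match.arg(extension)
  if (!duration %in% c(5L, 10L))
    stop("shock duration must be 5 or 10 years", call. = FALSE)
  inc <- increments[order(increments$year), ]
  base <- inc$increment
  n <- length(base)
  prof <- if (duration <= n) base[seq_len(duration)]
  else if (extension == "hold_last") c(base, rep(base[n], duration - n))
  else rep(base, length.out = duration)
  cyc <- seq_len(duration) - 1L
  data.frame(cycle = cyc,
             year = inc$year[1] + cyc,
             model_year = as.integer(model_start_year) + cyc,
             increment = prof)
}
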