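# Risk linkage: stratified unemployment increments -> relative risks on
# CVD incidence. The effect sizes originate from multi-country
# recession studies: the percent change in CVD incidence per 1% RELATIVE
# increase in the unemployment rate, by sex and age band, scaled
# linearly with the size of the relative increase. The risk acts on
# incidence of both CHD and stroke; case fatality is untouched.

#' Built-in unemployment-to-CVD effect sizes
#'
#' Percent change in annual CVD incidence per 1\% relative increase in
#' the unemployment rate, with 95\% confidence limits, by sex and the
#' published age bands (35-44, 45-59, 60-64). For men aged 35-44 the
#' central effect is +0.85\% (i.e. relative risk 1.0085 per 1\%
#' relative unemployment increase).
#'
#' @return data frame with columns `sex`, `age_band`, `beta`, `ci_low`,
#'   `ci_high` (all in percent per 1\% relative increase).
#' @export
#' @examples
#' builtin_effects()
builtin_effects <- function() {
  eff <- data.frame(
    sex = rep(c("female", "male"), each = 3),
    age_band = rep(CVD_EFFECT_BANDS, 2),
    beta = c(-0.14, 0.10, 0.23, 0.85, 0.48, 0.38),
    ci_low = c(-1.95, -1.09, -0.22, 0.06, -0.06, -0.16),
    ci_high = c(1.67, 1.30, 0.68, 1.64, 1.02, 0.91),
    stringsAsFactors = FALSE
  )
  stopifnot(all(eff$ci_low <= eff$beta & eff$beta <= eff$ci_high))
  eff
}

#' Relative unemployment increase of a stratum (percent)
#'
#' A stratum's absolute rate increment expressed relative to its own
#' pre-shock rate: `100 * dU / baseline_rate`. This is the quantity the
#' effect sizes are indexed on ("per 1\% relative increase").
#'
#' @param dU absolute increment(s), proportion scale.
#' @param baseline_rate pre-shock stratum rate(s), proportion scale,
#'   strictly positive.
#' @return percent relative increase (vectorised).
#' @export
#' @examples
#' relative_increase(0.0004, 0.04)  # 1 percent
relative_increase <- function(dU, baseline_rate) {
  if (any(baseline_rate <= 0))
    stop("baseline rate must be positive", call. = FALSE)
  100 * dU / baseline_rate
}

#' Relative risk on CVD incidence from a relative unemployment increase
#'
#' Linear scaling: `rr = 1 + (beta / 100) * rel_increase_pct`. A 1\%
#' relative increase with beta = 0.85 gives rr = 1.0085; a 2\% increase
#' gives a 1.7\% incidence increase (rr = 1.017). Negative betas give
#' rr below 1.
#'
#' @param beta percent incidence change per 1\% relative unemployment
#'   increase (an [builtin_effects()] row's `beta`, or a numeric
#'   vector).
#' @param rel_increase_pct relative unemployment increase in percent.
#' @return relative risk (vectorised); errors if any rr would be
#'   non-positive.
#' @export
#' @examples
#' incidence_rr(0.85, 1)  # 1.0085
#' incidence_rr(0.85, 2)  # 1.017
incidence_rr <- function(beta, rel_increase_pct) {
  if (any(!is.finite(rel_increase_pct)))
    stop("relative increase must be finite", call. = FALSE)
  rr <- 1 + (beta / 100) * rel_increase_pct
  if (any(rr <= 0))
    stop("pathological inputs: implied relative risk is non-positive",
         call. = FALSE)
  rr
}

#' Per-stratum, per-cycle incidence relative risks for a scenario
#'
#' Chains calibration and linkage: the scenario's aggregate yearly
#' increments are disaggregated into strata ([shock_series()]), each
#' cell increment is expressed relative to its own baseline rate, and
#' the sex- and age-matched effect size converts it into a relative
#' risk. Model age bands map to the closest published effect band
#' (45-54 to 45-59; 55-64 to 60-64). Only bands 35-64 receive risks;
#' other ages are implicitly rr = 1.
#'
#' @param bundle a `cvd_bundle` of model inputs.
#' @param scenario a `cvd_scenario` or the name of a built-in scenario.
#' @param reading `"relative"` (default: the increment is divided by
#'   the stratum's own baseline rate) or `"percentage_point"` (the
#'   increment in points is used directly as the percent scale), a
#'   sensitivity switch for the ambiguous source convention.
#' @param duration,extension,model_start_year,increment_scale passed to
#'   [shock_series()].
#' @param rr_floor `NULL` (default: a non-positive implied relative
#'   risk is an error) or a small positive value at which implied
#'   relative risks are truncated. The linear effect model can imply a
#'   negative incidence multiplier when a strongly negative sampled
#'   effect size meets a large relative unemployment increase; the
#'   Monte-Carlo engine truncates such draws since incidence cannot be
#'   negative.
#' @return data frame with columns `cycle`, `model_year`, `ethnicity`,
#'   `sex`, `age_band`, `dU`, `rel_pct`, `rr`.
#' @export
shock_rr_table <- function(bundle, scenario = "base_case",
                           reading = c("relative", "percentage_point"),
                           duration = 5L,
                           extension = c("hold_last", "repeat"),
                           model_start_year = 2011L,
                           increment_scale = 1, rr_floor = NULL) {
  reading <- match.arg(reading)
  extension <- match.arg(extension)
  if (is.character(scenario)) {
    scenario <- bundle$scenarios[[scenario]] %||%
      stop("unknown scenario '", scenario, "'", call. = FALSE)
  }
  ss <- shock_series(scenario, bundle$population,
                     bundle$baseline_unemployment,
                     model_start_year = model_start_year,
                     duration = duration, extension = extension,
                     increment_scale = increment_scale)
  ss <- ss[ss$model_use, ]
  bl <- bundle$baseline_unemployment
  key <- paste(ss$ethnicity, ss$sex, ss$age_band)
  base_rate <- bl$rate[match(key, paste(bl$ethnicity, bl$sex,
                                        bl$age_band))]
  ss$rel_pct <- if (reading == "relative")
    relative_increase(ss$dU, base_rate) else 100 * ss$dU
  eff <- bundle$effects
  ekey <- paste(ss$sex, effect_band_for(ss$age_band))
  beta <- eff$beta[match(ekey, paste(eff$sex, eff$age_band))]
  if (any(is.na(beta)))
    stop("missing effect size for some sex x band cell", call. = FALSE)
  ss$rr <- if (is.null(rr_floor)) incidence_rr(beta, ss$rel_pct)
  else pmax(1 + (beta / 100) * ss$rel_pct, rr_floor)
  ss[, c("cycle", "model_year", "ethnicity", "sex", "age_band",
         "dU", "rel_pct", "rr")]
}

#' Apply incidence relative risks to an epidemiology table
#'
#' Multiplies CHD and stroke incidence by the stratum's relative risk
#' for ages inside the affected bands; case fatality, prevalence and
#' background mortality are untouched, as are ages outside 35-64.
#'
#' @param epi a `cvd_epi` table.
#' @param rrs data frame with columns `ethnicity`, `sex`, `age_band`,
#'   `rr` (e.g. one cycle of [shock_rr_table()]).
#' @param year optional: if `rrs` has a `cycle` or `model_year` column,
#'   restrict to that cycle/year first.
#' @return the shocked `cvd_epi` table.
#' @export
apply_shock <- function(epi, rrs, year = NULL) {
  validate_epi(epi)
  if (!is.null(year)) {
    if ("model_year" %in% names(rrs) && year %in% rrs$model_year)
      rrs <- rrs[rrs$model_year == year, ]
    else if ("cycle" %in% names(rrs))
      rrs <- rrs[rrs$cycle == year, ]
  }
  band <- age_band_of(epi$age)
  key <- paste(epi$ethnicity, epi$sex, band)
  idx <- match(key, paste(rrs$ethnicity, rrs$sex, rrs$age_band))
  affected <- !is.na(band) & band %in% CVD_MODEL_BANDS
  if (any(affected & is.na(idx) & band %in% unique(rrs$age_band)))
    stop("missing stratum mapping in rr table", call. = FALSE)
  rr <- ifelse(affected & !is.na(idx), rrs$rr[idx], 1)
  epi$chd_i <- epi$chd_i * rr
  epi$str_i <- epi$str_i * rr
  epi
}
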