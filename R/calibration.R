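# Calibration: disaggregating an aggregate absolute unemployment-rate
# change into ethnicity-, sex- and age-specific absolute changes under
# the assumption that pre-shock relative rates are preserved.
#
# For groups g with baseline rates U_g and populations pop_g, the two
# constraints
#   (i)  dU_g / dU_h = U_g / U_h            (ratio preservation)
#   (ii) sum(pop_g dU_g) / sum(pop_g) = dU  (aggregate consistency)
# have the unique solution
#   dU_g = dU * U_g * N / sum(pop_h U_h),  N = sum(pop_h).

#' Relative unemployment-rate weights between population groups
#'
#' Computes the ethnic (Maori / non-Maori), sex (female / male) and age
#' band (relative to the 45-54 reference band) rate ratios from a
#' baseline unemployment table. Marginal rates are simple means over
#' the complementary cells by default; for multiplicatively built
#' tables (the synthetic generator) the configured ratios are recovered
#' exactly. Supply `population` for population-weighted marginals.
#'
#' @param baseline a baseline unemployment table
#'   (see [generate_unemployment_baseline()]).
#' @param population optional population table for weighted marginals.
#' @return list with elements `w_ethnicity` (scalar), `w_sex` (scalar),
#'   `w_age` (named vector over the five bands, reference 45-54 = 1).
#' @export
#' @examples
#' b <- generate_unemployment_baseline()
#' derive_weights(b)$w_ethnicity  # = configured ethnic ratio
derive_weights <- function(baseline, population = NULL) {
  validate_baseline(baseline)
  if (any(baseline$rate <= 0))
    stop("all baseline rates must be positive to form weights",
         call. = FALSE)
  w <- rep(1, nrow(baseline))
  if (!is.null(population)) {
    bp <- band_populations(population)
    key <- paste(baseline$ethnicity, baseline$sex, baseline$age_band)
    w <- bp$count[match(key, paste(bp$ethnicity, bp$sex, bp$age_band))]
  }
  marg <- function(sel) {
    sum(baseline$rate[sel] * w[sel]) / sum(w[sel])
  }
  u_e <- vapply(CVD_ETHNICITIES,
                function(e) marg(baseline$ethnicity == e), numeric(1))
  u_s <- vapply(CVD_SEXES,
                function(s) marg(baseline$sex == s), numeric(1))
  u_a <- vapply(CVD_AGE_BANDS,
                function(b) marg(baseline$age_band == b), numeric(1))
  list(w_ethnicity = unname(u_e["maori"] / u_e["non_maori"]),
       w_sex = unname(u_s["female"] / u_s["male"]),
       w_age = u_a / u_a["45-54"])
}

#' Disaggregate an aggregate rate change along one axis
#'
#' Splits an aggregate absolute unemployment-rate change `dU` across
#' groups so that group changes are proportional to group baseline
#' rates and their population-weighted mean equals `dU`.
#'
#' @param dU_overall aggregate absolute change (proportion, e.g. 0.037
#'   for +3.7 percentage points).
#' @param groups data frame with columns `population` (>= 0, at least
#'   one positive) and `rate` (> 0); optionally a `name` column.
#' @return `groups` with an added `dU` column.
#' @export
#' @examples
#' g <- data.frame(name = c("maori", "non_maori"),
#'                 population = c(100, 900), rate = c(0.08, 0.04))
#' disaggregate_one_axis(0.01, g)$dU  # 2:1 ratio, weighted mean 0.01
disaggregate_one_axis <- function(dU_overall, groups) {
  if (!all(c("population", "rate") %in% names(groups)))
    stop("groups need columns 'population' and 'rate'", call. = FALSE)
  if (any(groups$population < 0) || sum(groups$population) <= 0)
    stop("populations must be non-negative with a positive total",
         call. = FALSE)
  if (any(groups$rate <= 0))
    stop("every group baseline rate must be positive", call. = FALSE)
  n_total <- sum(groups$population)
  denom <- sum(groups$population * groups$rate)
  groups$dU <- dU_overall * groups$rate * n_total / denom
  groups
}

#' Disaggregate an aggregate rate change over the full stratification
#'
#' Produces an absolute unemployment-rate change for every ethnicity x
#' sex x 10-year-band cell. Cell changes are proportional to the
#' product of the marginal ethnic, sex and age rates (so sex and age
#' patterns follow the general population, not each ethnicity) and are
#' renormalised so the population-weighted mean over all working-age
#' cells equals `dU_overall` exactly.
#'
#' Cells whose shifted rate would leave `[0, 1]` are clipped with a
#' warning; this cannot occur at realistic shock sizes.
#'
#' @param dU_overall aggregate absolute change (proportion).
#' @param population population table (single-year ages).
#' @param baseline baseline unemployment table.
#' @param year calendar year attached to the output rows.
#' @return data frame with columns `ethnicity`, `sex`, `age_band`,
#'   `year`, `dU`, `model_use` (`TRUE` for bands 35-64, the bands the
#'   disease model consumes).
#' @export
disaggregate_full <- function(dU_overall, population, baseline,
                              year = NA_integer_) {
  validate_baseline(baseline)
  if (any(baseline$rate <= 0))
    stop("every baseline rate must be positive", call. = FALSE)
  bp <- band_populations(population)
  key_b <- paste(baseline$ethnicity, baseline$sex, baseline$age_band)
  pop_cell <- bp$count[match(key_b, paste(bp$ethnicity, bp$sex,
                                          bp$age_band))]
  if (any(is.na(pop_cell)) || sum(pop_cell) <= 0)
    stop("population table must cover every stratum", call. = FALSE)

  # marginal rates (general-population sex and age patterns)
  u_e <- vapply(CVD_ETHNICITIES, function(e)
    mean(baseline$rate[baseline$ethnicity == e]), numeric(1))
  u_s <- vapply(CVD_SEXES, function(s)
    mean(baseline$rate[baseline$sex == s]), numeric(1))
  u_a <- vapply(CVD_AGE_BANDS, function(b)
    mean(baseline$rate[baseline$age_band == b]), numeric(1))

  score <- u_e[baseline$ethnicity] * u_s[baseline$sex] *
    u_a[baseline$age_band]
  dU <- dU_overall * score * sum(pop_cell) / sum(pop_cell * score)

  shifted <- baseline$rate + dU
  clip_lo <- shifted < 0
  clip_hi <- shifted > 1
  if (any(clip_lo | clip_hi)) {
    warning("clipping ", sum(clip_lo | clip_hi),
            " cell delta(s) whose shifted rate leaves [0, 1]",
            call. = FALSE)
    dU[clip_lo] <- -baseline$rate[clip_lo]
    dU[clip_hi] <- 1 - baseline$rate[clip_hi]
  }
  out <- baseline[, c("ethnicity", "sex", "age_band")]
  out$year <- year
  out$dU <- unname(dU)
  out$model_use <- out$age_band %in% CVD_MODEL_BANDS
  rownames(out) <- NULL
  out
}

#' Build a per-stratum unemployment shock series for a scenario
#'
#' Combines [scenario_increments()], [map_to_model_years()] and
#' [disaggregate_full()] into the per-cell absolute rate increments the
#' risk linkage consumes, one row per model cycle and stratum.
#'
#' @param scenario a `cvd_scenario` (see [builtin_scenarios()]).
#' @param population,baseline model inputs (see [fixture_bundle()]).
#' @param model_start_year first model calendar year (default 2011).
#' @param duration shock duration in years (5 or 10).
#' @param extension how a 10-year shock extends the 5-year profile:
#'   `"hold_last"` or `"repeat"`.
#' @param increment_scale multiplicative factor on all aggregate
#'   increments (used by the uncertainty engine).
#' @return data frame with columns `cycle`, `year`, `model_year`,
#'   `ethnicity`, `sex`, `age_band`, `dU`, `model_use`.
#' @export
shock_series <- function(scenario, population, baseline,
                         model_start_year = 2011L, duration = 5L,
                         extension = c("hold_last", "repeat"),
                         increment_scale = 1) {
  extension <- match.arg(extension)
  inc <- scenario_increments(scenario)
  mapped <- map_to_model_years(inc, model_start_year = model_start_year,
                               duration = duration, extension = extension)
  out <- lapply(seq_len(nrow(mapped)), function(k) {
    cells <- disaggregate_full(mapped$increment[k] * increment_scale,
                               population, baseline,
                               year = mapped$year[k])
    cells$cycle <- mapped$cycle[k]
    cells$model_year <- mapped$model_year[k]
    cells
  })
  out <- do.call(rbind, out)
  out[, c("cycle", "year", "model_year", "ethnicity", "sex",
          "age_band", "dU", "model_use")]
}
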