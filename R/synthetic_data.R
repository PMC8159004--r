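# Seeded synthetic model inputs.
#
# The generators emulate the joint statistical structure of the
# administrative inputs a national CVD life-table model consumes (census
# population counts, labour-force unemployment averages, burden-of-disease
# epidemiology and cost schedules) without reproducing any real values:
# a younger indigenous age structure, roughly doubled indigenous
# unemployment, age-graded unemployment (young higher), Gompertz-like
# age-increasing disease rates, and an ethnic CVD burden gap.

#' Settings for the synthetic population generator
#'
#' @param total total population size (persons); default is of the order
#'   of a small high-income country.
#' @param maori_share proportion of the population that is Maori.
#' @param maori_age_scale,non_maori_age_scale scale (years) of the
#'   exponential age pyramid per ethnic group; smaller = younger. The
#'   defaults give median ages of roughly 24 and 38 years.
#' @param younger_maori logical; when `FALSE` both groups share the
#'   non-Maori age scale.
#' @param jitter_sd log-normal coefficient of variation of the per-cell
#'   count jitter (0 disables it).
#' @return a named list of settings for [generate_population()].
#' @export
population_config <- function(total = 4.4e6, maori_share = 0.15,
                              maori_age_scale = 35,
                              non_maori_age_scale = 55,
                              younger_maori = TRUE,
                              jitter_sd = 0.05) {
  list(total = total, maori_share = maori_share,
       maori_age_scale = maori_age_scale,
       non_maori_age_scale = non_maori_age_scale,
       younger_maori = younger_maori, jitter_sd = jitter_sd)
}

#' Generate a stratified synthetic population table
#'
#' Produces person counts for every ethnicity x sex x single-year-age
#' cell, ages 0 to 110. Age pyramids are exponential with an ethnicity-
#' specific scale, so the Maori distribution is younger by default.
#'
#' @param config settings from [population_config()].
#' @param seed integer RNG seed; a fixed seed gives a byte-identical
#'   table.
#' @return data frame with columns `ethnicity`, `sex`, `age`, `count`.
#' @export
#' @examples
#' pop <- generate_population(population_config(total = 1e5), seed = 1)
#' sum(pop$count)
generate_population <- function(config = population_config(), seed = 1L) {
  if (!is.numeric(config$total) || config$total <= 0)
    stop("population total must be positive", call. = FALSE)
  if (config$maori_share < 0 || config$maori_share > 1)
    stop("maori_share must lie in [0, 1]", call. = FALSE)
  ages <- 0:CVD_MAX_AGE
  grid <- expand.grid(age = ages, sex = CVD_SEXES,
                      ethnicity = CVD_ETHNICITIES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("ethnicity", "sex", "age")]
  scale_of <- function(e) {
    if (e == "maori" && config$younger_maori) config$maori_age_scale
    else config$non_maori_age_scale
  }
  share <- ifelse(grid$ethnicity == "maori", config$maori_share,
                  1 - config$maori_share)
  w_age <- vapply(seq_len(nrow(grid)), function(k) {
    sc <- scale_of(grid$ethnicity[k])
    exp(-grid$age[k] / sc)
  }, numeric(1))
  # normalise age weights within each ethnicity x sex cell
  for (e in CVD_ETHNICITIES) for (s in CVD_SEXES) {
    sel <- grid$ethnicity == e & grid$sex == s
    w_age[sel] <- w_age[sel] / sum(w_age[sel])
  }
  counts <- config$total * share * 0.5 * w_age
  if (config$jitter_sd > 0) {
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + config$jitter_sd^2))
    counts <- counts * rlnorm(length(counts), -sdlog^2 / 2, sdlog)
  }
  grid$count <- round(counts)
  validate_population(grid)
  grid
}

#' Weighted median age of a generated population
#'
#' @param population a population table.
#' @param ethnicity optional ethnicity filter.
#' @return median age in years (count-weighted).
#' @export
population_median_age <- function(population, ethnicity = NULL) {
  validate_population(population)
  if (!is.null(ethnicity))
    population <- population[population$ethnicity == ethnicity, ]
  tot <- aggregate(count ~ age, population, sum)
  tot <- tot[order(tot$age), ]
  cum <- cumsum(tot$count) / sum(tot$count)
  tot$age[which(cum >= 0.5)[1]]
}

#' Settings for the baseline unemployment generator
#'
#' Stratum rates are built multiplicatively from an overall rate:
#' `rate = base * f_ethnicity * f_sex * f_ageband`, with the base chosen
#' so the population-weighted mean equals `overall`. The configured
#' group ratios therefore hold exactly in the output.
#'
#' @param overall overall unemployment rate (proportion of the labour
#'   force, ages 15-64); default 4\%, the pre-shock level.
#' @param ethnic_ratio Maori / non-Maori rate ratio (default 2: the
#'   indigenous rate is about double).
#' @param sex_ratio female / male rate ratio.
#' @param age_factors named multipliers per 10-year band, expressed
#'   relative to the 45-54 reference band; the default declines with
#'   age (youth unemployment highest).
#' @param age_gradient logical; `FALSE` flattens the age profile.
#' @return a named list for [generate_unemployment_baseline()].
#' @export
unemployment_config <- function(overall = 0.04, ethnic_ratio = 2.0,
                                sex_ratio = 1.1,
                                age_factors = c("15-24" = 3.0,
                                                "25-34" = 1.4,
                                                "35-44" = 1.1,
                                                "45-54" = 1.0,
                                                "55-64" = 0.9),
                                age_gradient = TRUE) {
  list(overall = overall, ethnic_ratio = ethnic_ratio,
       sex_ratio = sex_ratio, age_factors = age_factors,
       age_gradient = age_gradient)
}

#' Generate baseline (pre-shock) unemployment rates by stratum
#'
#' Rates cover every ethnicity x sex x 10-year band (15-24 ... 55-64)
#' cell. Construction is multiplicative, so configured ethnic, sex and
#' age ratios are recovered exactly from the output (see
#' [derive_weights()]). When a population table is supplied the base
#' level is normalised so the population-weighted mean rate equals the
#' configured overall rate.
#'
#' @param config settings from [unemployment_config()].
#' @param seed accepted for interface symmetry; the table is
#'   deterministic in the configuration (ratio constraints must hold
#'   exactly, so no noise is added).
#' @param population optional population table used to weight the
#'   normalisation; without it, cells are weighted uniformly.
#' @return data frame with columns `ethnicity`, `sex`, `age_band`,
#'   `rate`.
#' @export
generate_unemployment_baseline <- function(config = unemployment_config(),
                                           seed = 1L,
                                           population = NULL) {
  stop_if_not_scalar_prob(config$overall, "overall")
  if (config$ethnic_ratio <= 0 || config$sex_ratio <= 0)
    stop("group rate ratios must be positive", call. = FALSE)
  af <- config$age_factors
  if (!all(CVD_AGE_BANDS %in% names(af)))
    stop("age_factors must name every band 15-24 ... 55-64", call. = FALSE)
  if (!config$age_gradient) af[] <- 1
  grid <- expand.grid(age_band = CVD_AGE_BANDS, sex = CVD_SEXES,
                      ethnicity = CVD_ETHNICITIES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("ethnicity", "sex", "age_band")]
  f <- ifelse(grid$ethnicity == "maori", config$ethnic_ratio, 1) *
    ifelse(grid$sex == "female", config$sex_ratio, 1) *
    unname(af[grid$age_band])
  w <- rep(1, nrow(grid))
  if (!is.null(population)) {
    bp <- band_populations(population)
    key <- paste(grid$ethnicity, grid$sex, grid$age_band)
    w <- bp$count[match(key, paste(bp$ethnicity, bp$sex, bp$age_band))]
  }
  base <- config$overall / (sum(w * f) / sum(w))
  grid$rate <- base * f
  if (any(grid$rate > 1))
    stop("configured ratios produce unemployment rates above 1",
         call. = FALSE)
  validate_baseline(grid)
  grid
}

#' Settings for the synthetic epidemiology generator
#'
#' Age curves are exponential in age (Gompertz-like), the simplest shape
#' consistent with rates that rise monotonically with age. Levels and
#' slopes are set so rates at working ages are of realistic magnitude
#' (for example, all-cause background mortality near 0.7\% per year and
#' CHD incidence near 0.8\% per year for men at age 64).
#'
#' @param ethnic_ratio Maori / non-Maori ratio applied to background
#'   mortality and disease incidence at every age.
#' @param ethnic_cf_ratio Maori / non-Maori case-fatality ratio.
#' @param male_incidence_ratio male / female disease incidence ratio.
#' @param mort0,mort_slope Gompertz intercept (rate at age 0) and slope
#'   (per year of age) for background (CVD-deleted) all-cause mortality.
#' @param chd_i0,str_i0,inc_slope intercepts and common slope for CHD
#'   and stroke incidence.
#' @param chd_f0,str_f0,cf_slope intercepts and slope for annual case
#'   fatality among prevalent cases.
#' @param prev_years steady-state multiplier converting incidence into
#'   initial prevalence (prevalence ~ incidence x mean duration).
#' @param chd_dw,str_dw disability weights of prevalent CHD and stroke
#'   (placeholder values: the source model's morbidity weights are not
#'   published; only HALY differences are reported downstream).
#' @param bg_cost0,cost_slope annual background health-system cost per
#'   person (currency units, 2011 base) and its exponential age slope.
#' @param chd_cost,str_cost annual cost per prevalent case.
#' @param mort_trend annual proportional mortality decline per ethnic
#'   group (defaults 2.25\% Maori, 1.75\% non-Maori).
#' @param mort_trend_horizon years after the model start over which the
#'   mortality trend applies (default 15, i.e. out to 2026 from a 2011
#'   start), frozen thereafter.
#' @param disease_trend annual proportional decline of disease incidence
#'   and case fatality (default 2\%).
#' @param jitter_sd coefficient of variation of a seeded log-normal
#'   jitter applied per sex and parameter (shared across ethnicities and
#'   ages so monotonicity and ethnic ratios are preserved exactly).
#' @return a named list for [generate_epi_params()].
#' @export
epi_config <- function(ethnic_ratio = 2.0, ethnic_cf_ratio = 1.5,
                       male_incidence_ratio = 1.6,
                       mort0 = 3e-5, mort_slope = 0.085,
                       chd_i0 = 2e-5, str_i0 = 1.2e-5, inc_slope = 0.08,
                       chd_f0 = 0.008, str_f0 = 0.012, cf_slope = 0.03,
                       prev_years = 12, chd_dw = 0.12, str_dw = 0.25,
                       bg_cost0 = 1500, cost_slope = 0.02,
                       chd_cost = 6500, str_cost = 9000,
                       mort_trend = c(maori = 0.0225, non_maori = 0.0175),
                       mort_trend_horizon = 15L,
                       disease_trend = 0.02,
                       jitter_sd = 0.03) {
  cfg <- as.list(environment())
  slopes <- c(cfg$mort_slope, cfg$inc_slope, cfg$cf_slope, cfg$cost_slope)
  if (any(slopes < 0)) stop("age slopes must be non-negative", call. = FALSE)
  ratios <- c(cfg$ethnic_ratio, cfg$ethnic_cf_ratio,
              cfg$male_incidence_ratio)
  if (any(ratios <= 0)) stop("rate ratios must be positive", call. = FALSE)
  cfg
}

#' Generate a synthetic epidemiology and cost table
#'
#' One row per ethnicity x sex x single-year age (0-110) with background
#' mortality, CHD and stroke incidence / case fatality / initial
#' prevalence, disability weights and annual costs, plus the secular
#' trend parameters carried as the `"trends"` attribute.
#'
#' The `bg_mort` column is background mortality with the two modelled
#' CVD causes removed; the engine adds disease-specific excess deaths on
#' top, so total mortality emerges from the state equations.
#'
#' @param config settings from [epi_config()].
#' @param seed integer RNG seed for the per-sex parameter jitter.
#' @return data frame of class `cvd_epi` with a `"trends"` attribute
#'   (list: `mort`, `mort_horizon`, `disease`).
#' @export
generate_epi_params <- function(config = epi_config(), seed = 1L) {
  ages <- 0:CVD_MAX_AGE
  grid <- expand.grid(age = ages, sex = CVD_SEXES,
                      ethnicity = CVD_ETHNICITIES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("ethnicity", "sex", "age")]

  # one jitter factor per sex x parameter, shared across ethnicity and
  # age: preserves monotone age curves and exact ethnic ratios
  set.seed(as.integer(seed))
  params <- c("bg_mort", "chd_i", "str_i", "chd_f", "str_f",
              "bg_cost", "chd_cost", "str_cost")
  sdlog <- sqrt(log(1 + config$jitter_sd^2))
  jit <- matrix(rlnorm(length(params) * 2, -sdlog^2 / 2, sdlog),
                nrow = 2, dimnames = list(CVD_SEXES, params))
  if (config$jitter_sd == 0) jit[] <- 1

  e_mult <- ifelse(grid$ethnicity == "maori", config$ethnic_ratio, 1)
  cf_mult <- ifelse(grid$ethnicity == "maori", config$ethnic_cf_ratio, 1)
  m_mult <- ifelse(grid$sex == "male", config$male_incidence_ratio, 1)
  jof <- function(p) jit[cbind(grid$sex, p)]

  gomp <- function(r0, slope) r0 * exp(slope * grid$age)
  cap <- function(x) pmin(x, 0.99)

  grid$bg_mort <- cap(gomp(config$mort0, config$mort_slope) *
                        e_mult * jof("bg_mort"))
  grid$chd_i <- cap(gomp(config$chd_i0, config$inc_slope) *
                      e_mult * m_mult * jof("chd_i"))
  grid$str_i <- cap(gomp(config$str_i0, config$inc_slope) *
                      e_mult * m_mult * jof("str_i"))
  grid$chd_f <- cap(gomp(config$chd_f0, config$cf_slope) *
                      cf_mult * jof("chd_f"))
  grid$str_f <- cap(gomp(config$str_f0, config$cf_slope) *
                      cf_mult * jof("str_f"))
  grid$chd_prev <- pmin(grid$chd_i * config$prev_years, 0.35)
  grid$str_prev <- pmin(grid$str_i * config$prev_years, 0.35)
  grid$chd_dw <- config$chd_dw
  grid$str_dw <- config$str_dw
  grid$bg_cost <- gomp(config$bg_cost0, config$cost_slope) * jof("bg_cost")
  grid$chd_cost <- config$chd_cost * jof("chd_cost")
  grid$str_cost <- config$str_cost * jof("str_cost")

  attr(grid, "trends") <- list(mort = config$mort_trend,
                               mort_horizon = config$mort_trend_horizon,
                               disease = config$disease_trend)
  class(grid) <- c("cvd_epi", class(grid))
  validate_epi(grid)
  grid
}

#' Secular trend parameters of an epidemiology table
#' @param epi a `cvd_epi` table.
#' @return list with elements `mort` (named per-ethnicity annual
#'   mortality decline), `mort_horizon` (years), `disease` (annual
#'   incidence / case-fatality decline).
#' @export
epi_trends <- function(epi) attr(epi, "trends")

#' Build a complete, mutually consistent model input set
#'
#' Bundles a seeded synthetic population, baseline unemployment table
#' and epidemiology table with the built-in scenario and effect-size
#' constants. All tables share stratum keys, so the bundle feeds the
#' whole pipeline directly.
#'
#' @param seed integer seed; sub-generators receive `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param population_config,unemployment_config,epi_config generator
#'   settings (defaults as documented in each constructor).
#' @return list of class `cvd_bundle` with elements `population`,
#'   `baseline_unemployment`, `epi`, `scenarios`, `effects`, `seed`.
#' @export
#' @examples
#' b <- fixture_bundle(seed = 7,
#'   population_config = population_config(total = 2e5))
#' names(b)
fixture_bundle <- function(seed = 1L,
                           population_config = cvdshock::population_config(),
                           unemployment_config = cvdshock::unemployment_config(),
                           epi_config = cvdshock::epi_config()) {
  seed <- as.integer(seed)
  pop <- generate_population(population_config, seed)
  baseline <- generate_unemployment_baseline(unemployment_config,
                                             seed + 1L, population = pop)
  epi <- generate_epi_params(epi_config, seed + 2L)
  bundle <- structure(list(population = pop,
                           baseline_unemployment = baseline,
                           epi = epi,
                           scenarios = builtin_scenarios(),
                           effects = builtin_effects(),
                           seed = seed),
                      class = "cvd_bundle")
  validate_bundle(bundle)
  bundle
}

# ---- validators ------------------------------------------------------

#' Validate a population table
#' @param population candidate table.
#' @return the table, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_population <- function(population) {
  need <- c("ethnicity", "sex", "age", "count")
  if (!all(need %in% names(population)))
    stop("population table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(population$count < 0))
    stop("population counts must be non-negative", call. = FALSE)
  if (sum(population$count) <= 0)
    stop("population total must be positive", call. = FALSE)
  combos <- unique(population[, c("ethnicity", "sex")])
  if (nrow(combos) != 4L)
    stop("all 4 ethnicity x sex combinations must be present",
         call. = FALSE)
  invisible(population)
}

#' Validate a baseline unemployment table
#' @param baseline candidate table.
#' @return the table, invisibly.
#' @export
validate_baseline <- function(baseline) {
  need <- c("ethnicity", "sex", "age_band", "rate")
  if (!all(need %in% names(baseline)))
    stop("baseline table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(baseline$rate < 0 | baseline$rate > 1))
    stop("unemployment rates must lie in [0, 1]", call. = FALSE)
  if (nrow(baseline) != length(CVD_AGE_BANDS) * 4L)
    stop("every ethnicity x sex x band cell must be present",
         call. = FALSE)
  invisible(baseline)
}

#' Validate an epidemiology table
#' @param epi candidate `cvd_epi` table.
#' @return the table, invisibly.
#' @export
validate_epi <- function(epi) {
  rate_cols <- c("bg_mort", "chd_i", "str_i", "chd_f", "str_f",
                 "chd_prev", "str_prev", "chd_dw", "str_dw")
  need <- c("ethnicity", "sex", "age", rate_cols,
            "bg_cost", "chd_cost", "str_cost")
  if (!all(need %in% names(epi)))
    stop("epi table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (cl in rate_cols)
    if (any(epi[[cl]] < 0 | epi[[cl]] > 1))
      stop("epi column '", cl, "' must lie in [0, 1]", call. = FALSE)
  if (any(epi$chd_f >= 1 | epi$str_f >= 1))
    stop("case fatality must be below 1", call. = FALSE)
  if (is.null(attr(epi, "trends")))
    stop("epi table must carry a 'trends' attribute", call. = FALSE)
  invisible(epi)
}

#' Validate a full input bundle
#' @param bundle candidate `cvd_bundle`.
#' @return the bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  need <- c("population", "baseline_unemployment", "epi",
            "scenarios", "effects")
  if (!all(need %in% names(bundle)))
    stop("bundle needs elements ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_population(bundle$population)
  validate_baseline(bundle$baseline_unemployment)
  validate_epi(bundle$epi)
  invisible(bundle)
}

# Aggregate a single-year-age population into working-age bands.
band_populations <- function(population) {
  validate_population(population)
  pop <- population[population$age >= 15 & population$age <= 64, ]
  pop$age_band <- age_band_of(pop$age)
  aggregate(count ~ ethnicity + sex + age_band, pop, sum)
}
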