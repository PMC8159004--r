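# Plain-text persistence. All tables are CSV; scalar settings travel as
# JSON. Column dictionary:
#   population.csv  ethnicity,sex,age,count
#   unemployment_baseline.csv  ethnicity,sex,age_band,rate
#   epi.csv  ethnicity,sex,age,bg_mort,chd_i,chd_f,chd_prev,str_i,
#            str_f,str_prev,chd_dw,str_dw,bg_cost,chd_cost,str_cost
#   trends.json  mort (per-ethnicity annual decline), mort_horizon,
#            disease
#   scenarios.csv  scenario,year,rate,baseline_rate,duration
#   effects.csv  sex,age_band,beta,ci_low,ci_high

#' Write a model input bundle to a directory of CSV/JSON files
#'
#' @param bundle a `cvd_bundle`.
#' @param dir target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write.csv(df, file.path(dir, f),
                                 row.names = FALSE)
  w(bundle$population, "population.csv")
  w(bundle$baseline_unemployment, "unemployment_baseline.csv")
  w(as.data.frame(bundle$epi), "epi.csv")
  tr <- epi_trends(bundle$epi)
  tr$mort <- as.list(tr$mort)  # keep ethnicity names through JSON
  jsonlite::write_json(tr, file.path(dir, "trends.json"),
                       auto_unbox = TRUE, digits = NA)
  sc <- do.call(rbind, lapply(bundle$scenarios, function(s)
    data.frame(scenario = s$name, year = s$years, rate = s$rates,
               baseline_rate = s$baseline_rate,
               duration = s$duration)))
  w(sc, "scenarios.csv")
  w(bundle$effects, "effects.csv")
  invisible(dir)
}

#' Read a model input bundle written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return a validated `cvd_bundle`.
#' @export
read_bundle <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f),
                             stringsAsFactors = FALSE)
  epi <- rd("epi.csv")
  tr <- jsonlite::read_json(file.path(dir, "trends.json"),
                            simplifyVector = TRUE)
  tr$mort <- unlist(tr$mort)
  attr(epi, "trends") <- tr
  class(epi) <- c("cvd_epi", class(epi))
  sc_df <- rd("scenarios.csv")
  scenarios <- lapply(split(sc_df, sc_df$scenario), function(d) {
    d <- d[order(d$year), ]
    new_scenario(d$scenario[1], d$rate, years = d$year,
                 baseline_rate = d$baseline_rate[1],
                 duration = d$duration[1])
  })
  scenarios <- scenarios[order(match(names(scenarios),
                                     names(builtin_scenarios())))]
  bundle <- structure(list(
    population = rd("population.csv"),
    baseline_unemployment = rd("unemployment_baseline.csv"),
    epi = epi, scenarios = scenarios, effects = rd("effects.csv"),
    seed = NA_integer_), class = "cvd_bundle")
  validate_bundle(bundle)
  bundle
}
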