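# Monte-Carlo propagation of parameter uncertainty. Multiplicative
# parameters (unemployment increments, disease incidence and case
# fatality, costs) are perturbed by log-normal factors with mean 1 and
# the stated coefficient of variation; effect sizes are sampled on
# their natural percent scale from the normal implied by their printed
# 95% CI (a log-normal is impossible for sign-crossing intervals).

#' Uncertainty settings
#'
#' @param n_draws number of Monte-Carlo draws (default 2000; tests and
#'   examples use far fewer).
#' @param seed integer RNG seed; the full draw table is a deterministic
#'   function of `(seed, n_draws)`.
#' @param unemployment_cv coefficient of variation of the log-normal
#'   factor on unemployment increments (default 20\%).
#' @param epi_cv CV on disease incidence and case fatality (default
#'   5\%).
#' @param cost_cv CV on all cost parameters (default 10\%).
#' @param sample_effects sample effect-size betas from their CIs.
#' @return list of class `cvd_uncertainty`.
#' @export
uncertainty_config <- function(n_draws = 2000L, seed = 1L,
                               unemployment_cv = 0.20, epi_cv = 0.05,
                               cost_cv = 0.10, sample_effects = TRUE) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (any(c(unemployment_cv, epi_cv, cost_cv) < 0))
    stop("coefficients of variation must be >= 0", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 unemployment_cv = unemployment_cv, epi_cv = epi_cv,
                 cost_cv = cost_cv, sample_effects = sample_effects),
            class = "cvd_uncertainty")
}

#' Mean-one log-normal multiplicative factors
#'
#' Draws factors with `E[X] = 1` and coefficient of variation `cv`
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2 / 2`). `cv = 0`
#' returns exact ones.
#'
#' @param n number of draws.
#' @param cv coefficient of variation.
#' @return numeric vector of length `n`.
#' @export
sample_lognormal_factor <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Full draw table: one row per draw, deterministic in (seed, n_draws).
draw_table <- function(cfg, effects) {
  set.seed(cfg$seed)
  n <- cfg$n_draws
  out <- data.frame(
    u = sample_lognormal_factor(n, cfg$unemployment_cv),
    chd_i = sample_lognormal_factor(n, cfg$epi_cv),
    chd_f = sample_lognormal_factor(n, cfg$epi_cv),
    str_i = sample_lognormal_factor(n, cfg$epi_cv),
    str_f = sample_lognormal_factor(n, cfg$epi_cv),
    cost = sample_lognormal_factor(n, cfg$cost_cv))
  for (k in seq_len(nrow(effects))) {
    sd_k <- (effects$ci_high[k] - effects$ci_low[k]) /
      (2 * qnorm(0.975))
    col <- paste0("beta_", effects$sex[k], "_", effects$age_band[k])
    out[[col]] <- if (cfg$sample_effects)
      rnorm(n, effects$beta[k], sd_k) else rep(effects$beta[k], n)
  }
  out
}

#' Perturb a model input bundle for one Monte-Carlo draw
#'
#' Deterministic given `(cfg$seed, draw_index)`: the complete draw
#' table is regenerated from the seed and row `draw_index` is applied.
#' Epi incidence / case-fatality columns and costs are multiplied by
#' their factors, effect betas are replaced by their sampled values,
#' and the unemployment factor is attached as `bundle$u_factor`
#' (consumed by [shock_rr_table()] via `increment_scale`).
#'
#' @param bundle a `cvd_bundle`.
#' @param cfg an [uncertainty_config()].
#' @param draw_index draw number in `1:n_draws`.
#' @return the perturbed bundle (still a `cvd_bundle`).
#' @export
sample_parameters <- function(bundle, cfg, draw_index) {
  stopifnot(inherits(cfg, "cvd_uncertainty"))
  if (draw_index < 1 || draw_index > cfg$n_draws)
    stop("draw_index out of range", call. = FALSE)
  d <- draw_table(cfg, bundle$effects)[draw_index, ]
  epi <- bundle$epi
  epi$chd_i <- pmin(epi$chd_i * d$chd_i, 0.999)
  epi$chd_f <- pmin(epi$chd_f * d$chd_f, 0.999)
  epi$str_i <- pmin(epi$str_i * d$str_i, 0.999)
  epi$str_f <- pmin(epi$str_f * d$str_f, 0.999)
  for (cl in c("bg_cost", "chd_cost", "str_cost"))
    epi[[cl]] <- epi[[cl]] * d$cost
  bundle$epi <- epi
  eff <- bundle$effects
  bcol <- paste0("beta_", eff$sex, "_", eff$age_band)
  eff$beta <- as.numeric(d[1, bcol])
  bundle$effects <- eff
  bundle$u_factor <- d$u
  bundle
}

#' Monte-Carlo model runs for a scenario
#'
#' Each draw perturbs the bundle ([sample_parameters()]), rebuilds the
#' shock relative risks with the drawn unemployment factor, runs the
#' life-table for the shocked and no-shock arms with the same drawn
#' epidemiology, and collects [diff_outputs()].
#'
#' @param bundle a `cvd_bundle`.
#' @param scenario scenario object or built-in name.
#' @param cfg an [uncertainty_config()].
#' @param econ an [economic_config()].
#' @param reading,duration,extension passed to [shock_rr_table()].
#' @param rr_floor truncation point for sampled relative risks
#'   (default 0.01): extreme negative effect-size draws combined with
#'   large relative increases would otherwise imply negative incidence.
#' @return data frame of class `cvd_mc`: stacked `cvd_output` rows with
#'   a leading `draw` column.
#' @export
run_monte_carlo <- function(bundle, scenario = "base_case",
                            cfg = uncertainty_config(),
                            econ = economic_config(),
                            reading = "relative", duration = 5L,
                            extension = "hold_last", rr_floor = 0.01) {
  draws <- vector("list", cfg$n_draws)
  for (k in seq_len(cfg$n_draws)) {
    pb <- sample_parameters(bundle, cfg, k)
    shock <- shock_rr_table(pb, scenario, reading = reading,
                            duration = duration, extension = extension,
                            increment_scale = pb$u_factor,
                            rr_floor = rr_floor)
    scen_run <- run_cohort(pb, shock = shock, econ = econ)
    base_run <- run_cohort(pb, shock = NULL, econ = econ)
    ob <- diff_outputs(scen_run, base_run)
    ob$draw <- k
    draws[[k]] <- ob
  }
  out <- do.call(rbind, draws)
  class(out) <- c("cvd_mc", "data.frame")
  out
}

#' Mean and percentile uncertainty interval per output cell
#'
#' @param draws a `cvd_mc` table (or any data frame with `draw`,
#'   grouping columns and `haly_change` / `cost_change`).
#' @param level interval coverage (default 0.95, i.e. 2.5th and 97.5th
#'   percentiles).
#' @return data frame per ethnicity x sex x age-band x horizon cell
#'   with `haly_mean`, `haly_lower`, `haly_upper`, `cost_mean`,
#'   `cost_lower`, `cost_upper`, `n_draws`. With a single draw the
#'   interval columns are `NA` (undefined).
#' @export
summarize_ui <- function(draws, level = 0.95) {
  if (is.null(draws) || nrow(draws) == 0)
    stop("no draws to summarise", call. = FALSE)
  a <- (1 - level) / 2
  by <- list(ethnicity = draws$ethnicity, sex = draws$sex,
             age_band = draws$age_band, horizon = draws$horizon)
  one <- function(x, f) aggregate(x, by = by, FUN = f)$x
  n_draws <- length(unique(draws$draw))
  out <- aggregate(draws$haly_change, by = by, FUN = mean)
  names(out)[names(out) == "x"] <- "haly_mean"
  qlo <- function(x) unname(quantile(x, a, type = 7))
  qhi <- function(x) unname(quantile(x, 1 - a, type = 7))
  if (n_draws >= 2) {
    out$haly_lower <- one(draws$haly_change, qlo)
    out$haly_upper <- one(draws$haly_change, qhi)
  } else {
    out$haly_lower <- NA_real_
    out$haly_upper <- NA_real_
  }
  out$cost_mean <- one(draws$cost_change, mean)
  if (n_draws >= 2) {
    out$cost_lower <- one(draws$cost_change, qlo)
    out$cost_upper <- one(draws$cost_change, qhi)
  } else {
    out$cost_lower <- NA_real_
    out$cost_upper <- NA_real_
  }
  out$n_draws <- n_draws
  out
}
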