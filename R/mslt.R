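# Proportional multi-state life-table engine.
#
# Every ethnicity x sex x starting-age cohort of the model-start
# population is advanced in annual cycles until age 110. Two disease
# processes (CHD, stroke) run in parallel as three-state difference
# equations (never-diseased / prevalent / dead-of-disease); prevalence
# feeds morbidity weights and per-case costs, and disease deaths
# combine with background (CVD-deleted) mortality under competing-risk
# independence:
#   survival(t) = (1 - bg) * (1 - p_chd f_chd) * (1 - p_str f_str)
# where p_d is start-of-cycle prevalence among the alive. This is the
# exact expectation of the individual-level transition kernel, so the
# engine can be validated against a microsimulation with identical
# rates.

#' Economic settings of a model run
#'
#' @param discount_rate annual discount rate for health and costs
#'   (default 3\%; sensitivity 0\% and 6\%).
#' @param horizons reporting horizons in years (`Inf` = lifetime).
#' @param nzd_2011_to_2019 multiplier from 2011 to 2019 currency units.
#' @param nzd_to_usd_2019 multiplier from 2019 local currency to 2019
#'   US dollars.
#' @return list of class `cvd_econ`.
#' @export
economic_config <- function(discount_rate = 0.03,
                            horizons = c(5, 10, 20, Inf),
                            nzd_2011_to_2019 = 1.098,
                            nzd_to_usd_2019 = 0.69) {
  if (discount_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (any(horizons <= 0)) stop("horizons must be positive", call. = FALSE)
  structure(list(discount_rate = discount_rate, horizons = horizons,
                 nzd_2011_to_2019 = nzd_2011_to_2019,
                 nzd_to_usd_2019 = nzd_to_usd_2019),
            class = "cvd_econ")
}

#' One annual step of a three-state disease process
#'
#' States are proportions of a closed cohort: `healthy` (never
#' diseased), `diseased` (prevalent), `dead` (died of the disease).
#' Incidence moves healthy to diseased; case fatality moves (existing)
#' diseased to dead; new cases do not face fatality within their
#' incident cycle. Remission is zero.
#'
#' @param state list or data frame with numeric `healthy`, `diseased`,
#'   `dead` (each cycle sums to its previous total).
#' @param i annual incidence in `[0, 1)`.
#' @param f annual case fatality in `[0, 1)`.
#' @return updated state (same shape, vectorised).
#' @export
#' @examples
#' disease_step(list(healthy = 1, diseased = 0, dead = 0),
#'              i = 0.01, f = 0)
disease_step <- function(state, i, f) {
  if (any(i < 0 | i >= 1) || any(f < 0 | f >= 1))
    stop("incidence and case fatality must lie in [0, 1)", call. = FALSE)
  list(healthy = state$healthy * (1 - i),
       diseased = state$diseased * (1 - f) + state$healthy * i,
       dead = state$dead + state$diseased * f)
}

#' Apply secular trends to an epidemiology table at a model cycle
#'
#' Background mortality declines by the ethnicity-specific annual trend
#' up to the trend horizon (default 15 cycles, i.e. out to 2026 from a
#' 2011 start) and is frozen thereafter. Disease incidence and case
#' fatality decline by the disease trend every cycle (no freeze), or
#' not at all when `freeze_disease = TRUE` (the trend level-off
#' sensitivity).
#'
#' @param epi a `cvd_epi` table.
#' @param cycle model cycle (0-based; 0 returns the table unchanged).
#' @param freeze_disease disable the disease incidence / case-fatality
#'   trend.
#' @return the trended `cvd_epi` table.
#' @export
apply_trends <- function(epi, cycle, freeze_disease = FALSE) {
  validate_epi(epi)
  if (cycle < 0) stop("cycle must be >= 0", call. = FALSE)
  tr <- epi_trends(epi)
  mt <- tr$mort[ifelse(epi$ethnicity == "maori", "maori", "non_maori")]
  epi$bg_mort <- epi$bg_mort * (1 - mt)^min(cycle, tr$mort_horizon)
  dfac <- if (freeze_disease) 1 else (1 - tr$disease)^cycle
  for (cl in c("chd_i", "str_i", "chd_f", "str_f"))
    epi[[cl]] <- epi[[cl]] * dfac
  epi
}

# rate lookup matrices: one row per ethnicity x sex stratum, one column
# per single-year age
.epi_matrices <- function(epi) {
  strata <- paste(rep(CVD_ETHNICITIES, each = 2), CVD_SEXES)
  cols <- c("bg_mort", "chd_i", "chd_f", "chd_prev", "str_i", "str_f",
            "str_prev", "chd_dw", "str_dw", "bg_cost", "chd_cost",
            "str_cost")
  key <- paste(epi$ethnicity, epi$sex)
  out <- lapply(cols, function(cl) {
    m <- matrix(NA_real_, nrow = length(strata), ncol = CVD_MAX_AGE + 1L,
                dimnames = list(strata, NULL))
    m[cbind(match(key, strata), epi$age + 1L)] <- epi[[cl]]
    if (anyNA(m)) stop("epi table must cover ages 0-110 for every stratum",
                       call. = FALSE)
    m
  })
  names(out) <- cols
  out
}

#' Run the multi-state life-table for every cohort
#'
#' Advances each ethnicity x sex x starting-age cohort of the bundle's
#' population from the model start until age 110, with trended rates
#' and (optionally) shocked CVD incidence. Per cycle the engine accrues
#' person-years (trapezoidal half-cycle correction), morbidity-adjusted
#' life years discounted at `(1 + r)^-t`, and health-system costs
#' (background per person-year plus per-prevalent-case disease costs,
#' discounted identically). Transitions are applied in the order
#' trends, shock relative risk, disease step, mortality.
#'
#' @param bundle a `cvd_bundle`.
#' @param shock `NULL` for the no-shock counterfactual, or a relative-
#'   risk table from [shock_rr_table()].
#' @param econ an [economic_config()].
#' @param freeze_disease_trend sensitivity switch: no secular decline
#'   in disease incidence / case fatality.
#' @return object of class `cvd_run`: list with `keys` (one row per
#'   cohort: `ethnicity`, `sex`, `age0`, `stratum`, `pop`) and
#'   cycle-indexed matrices `alive`, `deaths`, `prev_chd`, `prev_str`,
#'   `ly`, `haly`, `cost` (cohort x cycle; `haly` and `cost` are
#'   discounted accruals of that cycle), plus `econ`.
#' @export
run_cohort <- function(bundle, shock = NULL, econ = economic_config(),
                       freeze_disease_trend = FALSE) {
  validate_bundle(bundle)
  epi <- bundle$epi
  tr <- epi_trends(epi)
  M <- .epi_matrices(epi)
  strata <- rownames(M$bg_mort)

  pop <- bundle$population
  key <- paste(pop$ethnicity, pop$sex)
  keys <- data.frame(ethnicity = pop$ethnicity, sex = pop$sex,
                     age0 = pop$age, stratum = match(key, strata),
                     pop = pop$count, stringsAsFactors = FALSE)
  keys <- keys[order(keys$stratum, keys$age0), ]
  rownames(keys) <- NULL
  nc <- nrow(keys)
  n_cycles <- CVD_MAX_AGE + 1L

  # precompute shock rr per cohort x cycle (1 outside shocked cells)
  rr_mat <- NULL
  if (!is.null(shock) && nrow(shock) > 0) {
    shock_cycles <- sort(unique(shock$cycle))
    rr_mat <- matrix(1, nrow = nc, ncol = max(shock_cycles) + 1L)
    skey <- paste(shock$cycle, shock$ethnicity, shock$sex,
                  shock$age_band)
    for (t in shock_cycles) {
      band <- age_band_of(keys$age0 + t)
      ck <- paste(t, keys$ethnicity, keys$sex, band)
      idx <- match(ck, skey)
      rr_mat[!is.na(idx), t + 1L] <- shock$rr[idx[!is.na(idx)]]
    }
  }

  mort_trend <- tr$mort[ifelse(keys$ethnicity == "maori",
                               "maori", "non_maori")]
  r <- econ$discount_rate

  # state vectors
  l <- keys$pop
  a0 <- keys$age0
  s_idx <- keys$stratum
  at <- function(m, age) m[cbind(s_idx, age + 1L)]
  sc <- 1 - at(M$chd_prev, a0); cc <- at(M$chd_prev, a0)
  ss <- 1 - at(M$str_prev, a0); cs <- at(M$str_prev, a0)

  zero <- matrix(0, nrow = nc, ncol = n_cycles)
  alive <- zero; deaths <- zero; prev_chd <- zero; prev_str <- zero
  ly <- zero; haly <- zero; cost <- zero

  for (t in 0:(n_cycles - 1L)) {
    age <- a0 + t
    act <- age <= CVD_MAX_AGE & l > 0
    if (!any(act)) break
    ai <- pmin(age, CVD_MAX_AGE)

    dfac <- if (freeze_disease_trend) 1 else (1 - tr$disease)^t
    mfac <- (1 - mort_trend)^min(t, tr$mort_horizon)
    rr <- if (!is.null(rr_mat) && t < ncol(rr_mat)) rr_mat[, t + 1L]
    else rep(1, nc)

    bg <- at(M$bg_mort, ai) * mfac
    i_chd <- pmin(at(M$chd_i, ai) * dfac * rr, 0.999)
    i_str <- pmin(at(M$str_i, ai) * dfac * rr, 0.999)
    f_chd <- at(M$chd_f, ai) * dfac
    f_str <- at(M$str_f, ai) * dfac

    tot_chd <- sc + cc
    tot_str <- ss + cs
    p_chd <- ifelse(tot_chd > 0, cc / tot_chd, 0)
    p_str <- ifelse(tot_str > 0, cs / tot_str, 0)

    terminal <- age >= CVD_MAX_AGE
    surv <- (1 - bg) * (1 - p_chd * f_chd) * (1 - p_str * f_str)
    surv[terminal] <- 0
    l_next <- l * surv
    L <- (l + l_next) / 2
    L[terminal] <- 0

    sc_n <- sc * (1 - i_chd); cc_n <- cc * (1 - f_chd) + sc * i_chd
    ss_n <- ss * (1 - i_str); cs_n <- cs * (1 - f_str) + ss * i_str
    p_chd_n <- ifelse(sc_n + cc_n > 0, cc_n / (sc_n + cc_n), 0)
    p_str_n <- ifelse(ss_n + cs_n > 0, cs_n / (ss_n + cs_n), 0)
    pb_chd <- (p_chd + p_chd_n) / 2
    pb_str <- (p_str + p_str_n) / 2

    w <- pmax(0, 1 - pb_chd * at(M$chd_dw, ai) -
                pb_str * at(M$str_dw, ai))
    disc <- (1 + r)^(-t)

    k <- t + 1L
    alive[act, k] <- l[act]
    deaths[act, k] <- (l - l_next)[act]
    prev_chd[act, k] <- (l * p_chd)[act]
    prev_str[act, k] <- (l * p_str)[act]
    ly[act, k] <- L[act]
    haly[act, k] <- (L * w * disc)[act]
    cost[act, k] <- ((L * at(M$bg_cost, ai) +
                        L * (pb_chd * at(M$chd_cost, ai) +
                               pb_str * at(M$str_cost, ai))) * disc)[act]

    l <- l_next
    sc <- sc_n; cc <- cc_n; ss <- ss_n; cs <- cs_n
  }

  structure(list(keys = keys, alive = alive, deaths = deaths,
                 prev_chd = prev_chd, prev_str = prev_str, ly = ly,
                 haly = haly, cost = cost, econ = econ),
            class = "cvd_run")
}

#' Cohort trajectories as a long data frame
#'
#' @param run a `cvd_run`.
#' @return data frame with one row per cohort and cycle (cycles with
#'   any activity), columns `ethnicity`, `sex`, `age0`, `cycle`,
#'   `alive`, `deaths`, `prev_chd`, `prev_str`, `ly`, `haly_disc`,
#'   `cost_disc`.
#' @export
as_trajectory_df <- function(run) {
  stopifnot(inherits(run, "cvd_run"))
  nc <- nrow(run$keys); nt <- ncol(run$alive)
  out <- data.frame(
    ethnicity = rep(run$keys$ethnicity, nt),
    sex = rep(run$keys$sex, nt),
    age0 = rep(run$keys$age0, nt),
    cycle = rep(0:(nt - 1L), each = nc),
    alive = as.vector(run$alive), deaths = as.vector(run$deaths),
    prev_chd = as.vector(run$prev_chd),
    prev_str = as.vector(run$prev_str),
    ly = as.vector(run$ly), haly_disc = as.vector(run$haly),
    cost_disc = as.vector(run$cost), stringsAsFactors = FALSE)
  out[out$alive > 0 | out$cycle == 0, ]
}

#' Scenario-minus-baseline differences by stratum and horizon
#'
#' HALY change is scenario minus baseline (negative = loss); cost
#' change is scenario minus baseline (positive = additional cost).
#' Results are sliced at each reporting horizon (cycles `0 ... h - 1`)
#' and aggregated to ethnicity x sex x starting-age-band cells over the
#' model's affected starting ages (35-64).
#'
#' @param scenario_run,baseline_run `cvd_run` objects sharing cohorts
#'   and economic settings.
#' @return data frame of class `cvd_output` with columns `ethnicity`,
#'   `sex`, `age_band` (starting-age band), `horizon` (years; `Inf` =
#'   lifetime), `population` (model-start persons of the cell),
#'   `haly_change`, `cost_change`.
#' @export
diff_outputs <- function(scenario_run, baseline_run) {
  stopifnot(inherits(scenario_run, "cvd_run"),
            inherits(baseline_run, "cvd_run"))
  if (!identical(scenario_run$keys, baseline_run$keys))
    stop("runs must share identical cohorts", call. = FALSE)
  if (!identical(scenario_run$econ, baseline_run$econ))
    stop("runs must share identical economic settings", call. = FALSE)
  econ <- scenario_run$econ
  d_haly <- scenario_run$haly - baseline_run$haly
  d_cost <- scenario_run$cost - baseline_run$cost
  keys <- scenario_run$keys
  band0 <- age_band_of(keys$age0)
  keep <- !is.na(band0) & band0 %in% CVD_MODEL_BANDS

  nt <- ncol(d_haly)
  rows <- list()
  for (h in econ$horizons) {
    cyc <- seq_len(min(h, nt))
    hh <- rowSums(d_haly[, cyc, drop = FALSE])
    cc <- rowSums(d_cost[, cyc, drop = FALSE])
    agg <- aggregate(cbind(pop = keys$pop[keep], haly = hh[keep],
                           cost = cc[keep]),
                     by = list(ethnicity = keys$ethnicity[keep],
                               sex = keys$sex[keep],
                               age_band = band0[keep]), FUN = sum)
    agg$horizon <- h
    rows[[length(rows) + 1L]] <- agg
  }
  out <- do.call(rbind, rows)
  out <- data.frame(ethnicity = out$ethnicity, sex = out$sex,
                    age_band = out$age_band, horizon = out$horizon,
                    population = out$pop, haly_change = out$haly,
                    cost_change = out$cost, stringsAsFactors = FALSE)
  attr(out, "econ") <- econ
  class(out) <- c("cvd_output", class(out))
  out
}
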