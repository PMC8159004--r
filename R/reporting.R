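# Reporting: per-capita normalisation, ethnic equity ratios, horizon
# shares, currency conversion, and assembly of the headline tables.
# Sign convention: HALY losses are negative, additional costs positive;
# equity ratios are computed on magnitudes.

#' Change per 1000 persons
#'
#' @param change absolute change (HALYs or currency units).
#' @param population persons in the group (positive).
#' @return `1000 * change / population` (vectorised).
#' @export
#' @examples
#' per_capita(-100, 10000)  # -10 per 1000
per_capita <- function(change, population) {
  if (any(population <= 0))
    stop("population must be positive", call. = FALSE)
  1000 * change / population
}

#' Ethnic equity ratio of per-capita losses
#'
#' Ratio of the magnitudes of the Maori and non-Maori per-capita
#' changes. A ratio above 1 means the per-capita loss falls more
#' heavily on Maori.
#'
#' @param maori_pc,nonmaori_pc per-capita changes (any common unit).
#' @return `abs(maori_pc) / abs(nonmaori_pc)` (vectorised); headline
#'   tables round it to one decimal.
#' @export
#' @examples
#' round(equity_ratio(-49.9, -13.5), 1)  # 3.7
equity_ratio <- function(maori_pc, nonmaori_pc) {
  if (any(nonmaori_pc == 0))
    stop("non-Maori per-capita change must be non-zero", call. = FALSE)
  abs(maori_pc) / abs(nonmaori_pc)
}

#' Share of the lifetime change accrued by a horizon
#'
#' @param horizon_change cumulative change at the horizon.
#' @param lifetime_change lifetime change (non-zero).
#' @return percent of the lifetime change (`100 * horizon / lifetime`),
#'   unrounded; table presentation rounds to the nearest integer.
#' @export
#' @examples
#' round(horizon_share(-3010, -30300))  # 10
horizon_share <- function(horizon_change, lifetime_change) {
  if (any(lifetime_change == 0))
    stop("lifetime change must be non-zero", call. = FALSE)
  100 * horizon_change / lifetime_change
}

#' Convert 2011-value costs to 2019 local currency and US dollars
#'
#' Pure reporting multiplications; the factors live in
#' [economic_config()].
#'
#' @param values_2011 cost changes in 2011 currency units.
#' @param econ an [economic_config()] (or a list with the two factor
#'   elements).
#' @return data frame with columns `nzd_2011`, `nzd_2019`, `usd_2019`.
#' @export
currency_convert <- function(values_2011, econ = economic_config()) {
  if (econ$nzd_2011_to_2019 <= 0 || econ$nzd_to_usd_2019 <= 0)
    stop("conversion factors must be positive", call. = FALSE)
  nzd19 <- values_2011 * econ$nzd_2011_to_2019
  data.frame(nzd_2011 = values_2011, nzd_2019 = nzd19,
             usd_2019 = nzd19 * econ$nzd_to_usd_2019)
}

#' Summarise an output bundle with margins, per-capita rates and equity
#'
#' Expands the cell-level scenario-minus-baseline differences to all
#' marginal groups ("all" ethnicities / sexes / age bands, where "all
#' ages" means starting ages 35-64), attaches per-1000 rates and, for
#' Maori rows, the Maori / non-Maori per-capita equity ratio of the
#' matching non-Maori group.
#'
#' @param output a `cvd_output` from [diff_outputs()].
#' @return data frame with columns `ethnicity`, `sex`, `age_band`,
#'   `horizon`, `population`, `haly_change`, `cost_change`,
#'   `haly_per_1000`, `cost_per_1000`, `equity_ratio` (`NA` where not
#'   applicable).
#' @export
summarize_output <- function(output) {
  stopifnot(inherits(output, "cvd_output"))
  df <- as.data.frame(output)
  margin <- function(d, col) {
    d[[col]] <- "all"
    aggregate(cbind(population, haly_change, cost_change) ~
                ethnicity + sex + age_band + horizon, d, sum)
  }
  pieces <- list(df)
  for (cols in list("age_band", "sex", c("sex", "age_band"),
                    "ethnicity", c("ethnicity", "age_band"),
                    c("ethnicity", "sex"),
                    c("ethnicity", "sex", "age_band"))) {
    d <- df
    for (cl in cols) d[[cl]] <- "all"
    pieces[[length(pieces) + 1L]] <-
      aggregate(cbind(population, haly_change, cost_change) ~
                  ethnicity + sex + age_band + horizon, d, sum)
  }
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(out[, c("ethnicity", "sex", "age_band",
                                 "horizon")]), ]
  out$haly_per_1000 <- per_capita(out$haly_change, out$population)
  out$cost_per_1000 <- per_capita(out$cost_change, out$population)

  out$equity_ratio <- NA_real_
  is_m <- out$ethnicity == "maori"
  mk <- paste(out$sex, out$age_band, out$horizon)
  nm <- out[out$ethnicity == "non_maori", ]
  idx <- match(mk[is_m], paste(nm$sex, nm$age_band, nm$horizon))
  denom <- nm$haly_per_1000[idx]
  ok <- !is.na(denom) & denom != 0
  out$equity_ratio[which(is_m)[ok]] <-
    equity_ratio(out$haly_per_1000[is_m][ok], denom[ok])
  rownames(out) <- NULL
  out[order(out$horizon, out$ethnicity, out$sex, out$age_band), ]
}

#' Headline results table for one scenario run
#'
#' A compact analogue of the published results layout: one row per
#' group, HALY change, per-1000 rate, equity ratio and cost change in
#' 2011 and converted currencies at each horizon.
#'
#' @param output a `cvd_output`.
#' @param econ the [economic_config()] of the run (defaults to the one
#'   attached to the output).
#' @param digits rounding applied to the presentation columns
#'   (`NULL` = unrounded).
#' @return data frame (one row per group x horizon).
#' @export
report_table <- function(output, econ = NULL, digits = NULL) {
  econ <- econ %||% attr(output, "econ") %||% economic_config()
  s <- summarize_output(output)
  cc <- currency_convert(s$cost_change, econ)
  s$cost_nzd_2019 <- cc$nzd_2019
  s$cost_usd_2019 <- cc$usd_2019
  if (!is.null(digits)) {
    num <- vapply(s, is.numeric, logical(1)) &
      !(names(s) %in% c("horizon", "population"))
    s[num] <- lapply(s[num], round, digits = digits)
    s$equity_ratio <- round(s$equity_ratio, 1)
  }
  s
}
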