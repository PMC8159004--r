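# Shared fixtures and the independent individual-level oracle.

# Default bundle at a reduced population size: engine cost does not
# depend on counts, but generation and aggregation stay light.
tiny_bundle <- function(seed = 1L, total = 2e5) {
  fixture_bundle(seed = seed,
                 population_config = population_config(total = total))
}

# A bundle whose effect sizes are all strictly positive (absolute
# values of the built-ins), so every shocked stratum has rr > 1.
positive_effect_bundle <- function(seed = 1L) {
  b <- tiny_bundle(seed)
  b$effects$beta <- abs(b$effects$beta)
  b$effects$ci_low <- pmin(b$effects$ci_low, b$effects$beta)
  b$effects$ci_high <- pmax(b$effects$ci_high, b$effects$beta)
  b
}

# Epi table with all rates, disability and costs zeroed: the
# conservation limit of the life-table (nobody dies before 110,
# nothing is discounted away by morbidity).
zero_epi_bundle <- function(seed = 1L, total = 1e4) {
  b <- tiny_bundle(seed, total = total)
  for (cl in c("bg_mort", "chd_i", "chd_f", "chd_prev", "str_i",
               "str_f", "str_prev", "chd_dw", "str_dw", "bg_cost",
               "chd_cost", "str_cost"))
    b$epi[[cl]] <- 0
  attr(b$epi, "trends") <- list(mort = c(maori = 0, non_maori = 0),
                                mort_horizon = 15L, disease = 0)
  b
}

# Rate schedules for one cohort (ethnicity, sex, starting age) computed
# directly from the epi table and trend parameters, independently of
# the engine's internal lookup.
cohort_schedules <- function(bundle, ethnicity, sex, age0, n_cycles) {
  epi <- bundle$epi
  tr <- epi_trends(epi)
  sel <- epi$ethnicity == ethnicity & epi$sex == sex
  row_at <- function(age) epi[sel & epi$age == age, ]
  mt <- tr$mort[[ethnicity]]
  t <- 0:(n_cycles - 1)
  ages <- pmin(age0 + t, 110)
  sched <- data.frame(cycle = t, age = ages)
  base <- do.call(rbind, lapply(ages, row_at))
  sched$bg <- base$bg_mort * (1 - mt)^pmin(t, tr$mort_horizon)
  dfac <- (1 - tr$disease)^t
  sched$chd_i <- base$chd_i * dfac
  sched$chd_f <- base$chd_f * dfac
  sched$str_i <- base$str_i * dfac
  sched$str_f <- base$str_f * dfac
  sched$chd_prev0 <- row_at(age0)$chd_prev
  sched$str_prev0 <- row_at(age0)$str_prev
  sched
}

# Individual-level stochastic oracle for a single cohort. Kernel per
# cycle: (1) case fatality kills existing cases of each disease
# (independent draws); (2) incidence among never-diseased survivors;
# (3) background mortality among all survivors. Returns the alive
# proportion and disease prevalence among the alive at the START of
# each cycle.
microsim_cohort <- function(sched, n = 1e5, seed = 99L) {
  set.seed(seed)
  alive <- rep(TRUE, n)
  chd <- runif(n) < sched$chd_prev0[1]
  str <- runif(n) < sched$str_prev0[1]
  nt <- nrow(sched)
  out <- data.frame(cycle = sched$cycle, alive = NA_real_,
                    p_chd = NA_real_, p_str = NA_real_)
  for (k in seq_len(nt)) {
    na <- sum(alive)
    out$alive[k] <- na / n
    out$p_chd[k] <- if (na > 0) mean(chd[alive]) else 0
    out$p_str[k] <- if (na > 0) mean(str[alive]) else 0
    if (na == 0) next
    if (sched$age[k] >= 110) { alive[] <- FALSE; next }
    die_chd <- alive & chd & runif(n) < sched$chd_f[k]
    die_str <- alive & str & runif(n) < sched$str_f[k]
    new_chd <- alive & !chd & runif(n) < sched$chd_i[k]
    new_str <- alive & !str & runif(n) < sched$str_i[k]
    chd <- chd | new_chd
    str <- str | new_str
    alive <- alive & !die_chd & !die_str
    alive <- alive & !(runif(n) < sched$bg[k])
  }
  out
}

# Deterministic engine trajectory for the same single cohort, pulled
# out of a full run.
engine_cohort_trajectory <- function(run, ethnicity, sex, age0) {
  k <- which(run$keys$ethnicity == ethnicity & run$keys$sex == sex &
               run$keys$age0 == age0)
  stopifnot(length(k) == 1)
  pop <- run$keys$pop[k]
  data.frame(cycle = 0:(ncol(run$alive) - 1L),
             alive = run$alive[k, ] / pop,
             p_chd = ifelse(run$alive[k, ] > 0,
                            run$prev_chd[k, ] / run$alive[k, ], 0),
             p_str = ifelse(run$alive[k, ] > 0,
                            run$prev_str[k, ] / run$alive[k, ], 0))
}
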