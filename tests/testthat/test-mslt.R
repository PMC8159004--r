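test_that("disease_step bookkeeping and guards", {
  s0 <- list(healthy = 1, diseased = 0, dead = 0)
  s1 <- disease_step(s0, i = 0.01, f = 0)
  expect_equal(s1$diseased, 0.01)
  expect_equal(s1$healthy + s1$diseased + s1$dead, 1)

  # no inflow: prevalence decays only through case fatality
  st <- list(healthy = 0.7, diseased = 0.3, dead = 0)
  traj <- numeric(10)
  for (k in 1:10) { st <- disease_step(st, i = 0, f = 0.1)
    traj[k] <- st$diseased }
  expect_equal(traj, 0.3 * 0.9^(1:10))
  expect_equal(st$healthy, 0.7)

  expect_error(disease_step(s0, i = 1, f = 0), "\\[0, 1\\)")
  expect_error(disease_step(s0, i = 0.1, f = -0.1), "\\[0, 1\\)")
})

test_that("secular trends decay multiplicatively and freeze on time", {
  b <- tiny_bundle(1)
  epi <- b$epi
  expect_equal(apply_trends(epi, 0), epi)

  t2 <- apply_trends(epi, 2)
  m <- epi$ethnicity == "maori"
  expect_equal(t2$bg_mort[m], epi$bg_mort[m] * 0.9775^2,
               tolerance = 1e-12)
  expect_equal(t2$bg_mort[!m], epi$bg_mort[!m] * 0.9825^2,
               tolerance = 1e-12)
  expect_equal(t2$chd_i, epi$chd_i * 0.98^2, tolerance = 1e-12)

  # mortality trend frozen after the 15-cycle horizon
  t15 <- apply_trends(epi, 15)
  t20 <- apply_trends(epi, 20)
  expect_equal(t20$bg_mort, t15$bg_mort, tolerance = 1e-12)
  # disease trend keeps declining
  expect_lt(max(t20$chd_i / t15$chd_i), 1)

  # trend level-off sensitivity leaves disease rates untouched
  fz <- apply_trends(epi, 10, freeze_disease = TRUE)
  expect_identical(fz$chd_i, epi$chd_i)
  expect_identical(fz$chd_f, epi$chd_f)
})

test_that("conservation limit: no mortality, no disease, no discounting", {
  b <- zero_epi_bundle(1, total = 1e4)
  run <- run_cohort(b, NULL, economic_config(discount_rate = 0))
  expected <- sum(b$population$count * (110 - b$population$age))
  expect_equal(sum(run$haly), expected, tolerance = 1e-9)
  expect_equal(sum(run$ly), expected, tolerance = 1e-9)
  expect_equal(sum(run$cost), 0)
})

test_that("discounting follows (1+r)^-t", {
  b <- zero_epi_bundle(1, total = 1e6)
  run <- run_cohort(b, NULL, economic_config(discount_rate = 0.03))
  k <- which(run$keys$age0 == 99)[1]
  pop <- run$keys$pop[k]
  # ages 99..109 contribute one undiscounted year each at cycles 0..10
  expect_equal(run$haly[k, 1:11], pop * 1.03^-(0:10), tolerance = 1e-12)
  expect_equal(sum(run$haly[k, ]), pop * sum(1.03^-(0:10)),
               tolerance = 1e-12)
})

test_that("run_cohort is deterministic and conserves cohorts", {
  b <- tiny_bundle(1)
  r1 <- run_cohort(b, NULL)
  r2 <- run_cohort(b, NULL)
  expect_identical(r1, r2)

  # alive non-increasing; alive + cumulative dead = initial cohort
  expect_true(all(diff(t(r1$alive)) <= 1e-12))
  expect_equal(rowSums(r1$deaths), r1$keys$pop, tolerance = 1e-9)
  # prevalent cases never exceed the alive
  expect_true(all(r1$prev_chd <= r1$alive + 1e-9))
  expect_true(all(r1$prev_str <= r1$alive + 1e-9))
  # extinct by age 110
  last <- ncol(r1$alive)
  expect_true(all(r1$alive[r1$keys$age0 == 0, last] >= 0))
  expect_equal(sum(r1$alive[, last] *
                     (r1$keys$age0 + last - 1 > 110)), 0)
})

test_that("scenario-minus-baseline differences behave as expected", {
  b <- positive_effect_bundle(1)
  shock <- shock_rr_table(b, "base_case")
  expect_true(all(shock$rr > 1))
  scen <- run_cohort(b, shock)
  base <- run_cohort(b, NULL)

  same <- diff_outputs(base, base)
  expect_true(all(same$haly_change == 0))
  expect_true(all(same$cost_change == 0))

  out <- diff_outputs(scen, base)
  life <- out[is.infinite(out$horizon), ]
  expect_true(all(life$haly_change <= 0))

  # cumulative losses grow with the horizon in magnitude
  tot <- tapply(out$haly_change, out$horizon, sum)
  tot <- tot[order(as.numeric(names(tot)))]
  expect_true(all(diff(abs(tot)) >= 0))

  # economic-config mismatch is rejected
  other <- run_cohort(b, NULL, economic_config(discount_rate = 0.06))
  expect_error(diff_outputs(scen, other), "identical economic")
})

test_that("life-table agrees with a small microsimulation", {
  # quick check at reduced n; the full 1e5 oracle runs in acceptance
  b <- tiny_bundle(1)
  run <- run_cohort(b, NULL)
  eth <- "maori"; sx <- "male"; a0 <- 55
  n_cyc <- 30
  sched <- cohort_schedules(b, eth, sx, a0, n_cyc)
  n <- 5e4
  sim <- microsim_cohort(sched, n = n, seed = 7)
  eng <- engine_cohort_trajectory(run, eth, sx, a0)[1:n_cyc, ]
  se <- function(p) pmax(sqrt(p * (1 - p) / n), 1e-4)
  expect_true(all(abs(eng$alive - sim$alive) <=
                    3 * se(eng$alive) + 1e-6))
  expect_true(all(abs(eng$p_chd - sim$p_chd) <=
                    3 * se(eng$p_chd) / sqrt(pmax(eng$alive, 0.01)) +
                    1e-6))
})
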