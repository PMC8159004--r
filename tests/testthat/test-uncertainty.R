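test_that("mean-one log-normal factors have the requested CV", {
  expect_equal(sample_lognormal_factor(5, 0), rep(1, 5))
  set.seed(1)
  x <- sample_lognormal_factor(5e4, 0.10)
  expect_equal(mean(x), 1, tolerance = 0.005)
  expect_equal(sd(x) / mean(x), 0.10, tolerance = 0.01)
})

test_that("degenerate uncertainty returns the base bundle exactly", {
  b <- tiny_bundle(1)
  cfg <- uncertainty_config(n_draws = 3, seed = 9,
                            unemployment_cv = 0, epi_cv = 0,
                            cost_cv = 0, sample_effects = FALSE)
  pb <- sample_parameters(b, cfg, 2)
  expect_equal(as.data.frame(pb$epi), as.data.frame(b$epi))
  expect_equal(pb$effects, b$effects)
  expect_equal(pb$u_factor, 1)
})

test_that("draw tables are deterministic and betas match their CIs", {
  b <- tiny_bundle(1)
  cfg <- uncertainty_config(n_draws = 10000, seed = 3)
  d1 <- cvdshock:::draw_table(cfg, b$effects)
  d2 <- cvdshock:::draw_table(cfg, b$effects)
  expect_identical(d1, d2)

  # men 35-44: sampled beta SD ~ (1.64 - 0.06) / 3.92
  implied <- (1.64 - 0.06) / (2 * qnorm(0.975))
  expect_equal(sd(d1[["beta_male_35-44"]]), implied, tolerance = 0.05)
  expect_equal(mean(d1[["beta_male_35-44"]]), 0.85, tolerance = 0.02)

  # sample_parameters is deterministic in (seed, draw_index)
  expect_identical(sample_parameters(b, cfg, 7),
                   sample_parameters(b, cfg, 7))
  expect_error(sample_parameters(b, cfg, 10001), "out of range")
})

test_that("summarize_ui: means, collapsing intervals, single draws", {
  cells <- expand.grid(ethnicity = "maori", sex = "male",
                       age_band = "35-44", horizon = c(5, Inf),
                       stringsAsFactors = FALSE)
  draws <- do.call(rbind, lapply(1:50, function(d) {
    x <- cells; x$draw <- d
    x$haly_change <- -100 + (d - 25.5) * 2  # symmetric around -100
    x$cost_change <- 7
    x
  }))
  s <- summarize_ui(draws)
  expect_equal(s$haly_mean, rep(-100, 2))
  expect_equal(s$cost_mean, rep(7, 2))
  expect_equal(s$cost_lower, rep(7, 2))  # constant draws collapse
  expect_equal(s$cost_upper, rep(7, 2))
  expect_lt(max(abs(s$haly_mean -
                      apply(cbind(s$haly_lower, s$haly_upper), 1,
                            mean))), 1e-9)

  one <- draws[draws$draw == 1, ]
  s1 <- summarize_ui(one)
  expect_true(all(is.na(s1$haly_lower)))
  expect_equal(s1$n_draws, rep(1L, 2))
  expect_error(summarize_ui(draws[0, ]), "no draws")
})

test_that("monte carlo runs are reproducible and shrink with SDs", {
  b <- tiny_bundle(1, total = 5e4)
  cfg <- uncertainty_config(n_draws = 4, seed = 11)
  mc1 <- run_monte_carlo(b, "base_case", cfg)
  mc2 <- run_monte_carlo(b, "base_case", cfg)
  expect_identical(mc1, mc2)
  expect_equal(length(unique(mc1$draw)), 4)

  # zero parameter SDs collapse the interval onto the point estimate
  cfg0 <- uncertainty_config(n_draws = 4, seed = 11,
                             unemployment_cv = 0, epi_cv = 0,
                             cost_cv = 0, sample_effects = FALSE)
  mc0 <- run_monte_carlo(b, "base_case", cfg0)
  s0 <- summarize_ui(mc0)
  expect_equal(s0$haly_lower, s0$haly_upper, tolerance = 1e-12)
  s1 <- summarize_ui(mc1)
  expect_true(all(s1$haly_upper - s1$haly_lower >=
                    s0$haly_upper - s0$haly_lower - 1e-9))
  expect_gt(sum(s1$haly_upper - s1$haly_lower), 0)
})
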