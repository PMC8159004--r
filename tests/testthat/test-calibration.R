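# Oracle: solve the ratio + conservation constraints as an explicit
# linear system (n-1 pairwise ratio rows plus one population-weighted
# conservation row) and compare with the closed-form implementation.
solve_axis_oracle <- function(dU, pop, rate) {
  n <- length(pop)
  A <- matrix(0, n, n)
  for (g in seq_len(n - 1)) {           # dU_g * U_{g+1} - dU_{g+1} * U_g = 0
    A[g, g] <- rate[g + 1]
    A[g, g + 1] <- -rate[g]
  }
  A[n, ] <- pop / sum(pop)              # conservation row
  b <- c(rep(0, n - 1), dU)
  as.numeric(solve(A, b))
}

test_that("derive_weights returns the defining rate ratios", {
  bl <- generate_unemployment_baseline(
    unemployment_config(ethnic_ratio = 1, sex_ratio = 1,
                        age_gradient = FALSE))
  w <- derive_weights(bl)
  expect_equal(w$w_ethnicity, 1)
  expect_equal(w$w_sex, 1)
  expect_equal(unname(w$w_age), rep(1, 5))

  bl2 <- generate_unemployment_baseline(
    unemployment_config(ethnic_ratio = 2.0))
  expect_equal(derive_weights(bl2)$w_ethnicity, 2.0, tolerance = 1e-12)

  bl2$rate[1] <- 0
  expect_error(derive_weights(bl2), "positive")
})

test_that("one-axis disaggregation matches hand and linear-system oracles", {
  # equal rates: every group change equals the aggregate change
  g <- data.frame(population = c(10, 200, 3000), rate = rep(0.05, 3))
  expect_equal(disaggregate_one_axis(0.02, g)$dU, rep(0.02, 3))

  # frozen 2x2 example: dU_NM = 10/1100, dU_M = 20/1100
  g2 <- data.frame(population = c(100, 900), rate = c(0.08, 0.04))
  d2 <- disaggregate_one_axis(0.01, g2)$dU
  expect_equal(d2, c(20 / 1100, 10 / 1100), tolerance = 1e-12)

  # five age bands against the generic constrained-solve oracle
  set.seed(11)
  for (rep_i in 1:20) {
    n <- sample(2:5, 1)
    pop <- runif(n, 50, 5000)
    rate <- runif(n, 0.01, 0.15)
    dU <- runif(1, -0.01, 0.05)
    got <- disaggregate_one_axis(dU, data.frame(population = pop,
                                                rate = rate))$dU
    expect_equal(got, solve_axis_oracle(dU, pop, rate),
                 tolerance = 1e-10)
  }

  expect_error(disaggregate_one_axis(
    0.01, data.frame(population = c(0, 0), rate = c(0.1, 0.1))),
    "positive total")
  expect_error(disaggregate_one_axis(
    0.01, data.frame(population = c(1, 1), rate = c(0, 0.1))),
    "positive")
})

test_that("full disaggregation conserves, preserves ratios, is linear", {
  b <- tiny_bundle(2)
  pop <- b$population
  bl <- b$baseline_unemployment

  flat <- generate_unemployment_baseline(
    unemployment_config(ethnic_ratio = 1, sex_ratio = 1,
                        age_gradient = FALSE))
  expect_equal(disaggregate_full(0.03, pop, flat)$dU, rep(0.03, 20))

  cells <- disaggregate_full(0.037, pop, bl, year = 2021)
  bp <- cvdshock:::band_populations(pop)
  key <- paste(cells$ethnicity, cells$sex, cells$age_band)
  w <- bp$count[match(key, paste(bp$ethnicity, bp$sex, bp$age_band))]
  expect_equal(sum(cells$dU * w) / sum(w), 0.037, tolerance = 1e-10)

  # ethnic ratio within every sex x band cell equals w_e
  w_e <- derive_weights(bl)$w_ethnicity
  m <- cells[cells$ethnicity == "maori", ]
  nm <- cells[cells$ethnicity == "non_maori", ]
  nm <- nm[match(paste(m$sex, m$age_band), paste(nm$sex, nm$age_band)), ]
  expect_equal(m$dU / nm$dU, rep(w_e, nrow(m)), tolerance = 1e-12)

  # homogeneity: scaling the aggregate scales every cell exactly
  cells3 <- disaggregate_full(3 * 0.037, pop, bl)
  expect_equal(cells3$dU, 3 * cells$dU, tolerance = 1e-14)

  # only bands 35-64 are flagged for model use
  expect_identical(cells$model_use,
                   cells$age_band %in% c("35-44", "45-54", "55-64"))
})

test_that("post-shock rates reproduce pre-shock weights (round trip)", {
  b <- tiny_bundle(3)
  bl <- b$baseline_unemployment
  cells <- disaggregate_full(0.05, b$population, bl)
  post <- bl
  key <- paste(bl$ethnicity, bl$sex, bl$age_band)
  post$rate <- bl$rate +
    cells$dU[match(key, paste(cells$ethnicity, cells$sex,
                              cells$age_band))]
  w0 <- derive_weights(bl)
  w1 <- derive_weights(post)
  expect_equal(w1$w_ethnicity, w0$w_ethnicity, tolerance = 1e-10)
  expect_equal(w1$w_sex, w0$w_sex, tolerance = 1e-10)
  expect_equal(w1$w_age, w0$w_age, tolerance = 1e-10)
})

test_that("deltas that would push a rate outside [0,1] are clipped", {
  b <- tiny_bundle(1)
  expect_warning(
    cells <- disaggregate_full(0.6, b$population,
                               b$baseline_unemployment),
    "clipping")
  bl <- b$baseline_unemployment
  expect_true(all(bl$rate + cells$dU <= 1 + 1e-12))
})
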