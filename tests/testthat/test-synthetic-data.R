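test_that("population generation is deterministic and respects config", {
  cfg <- population_config(total = 1e5)
  p1 <- generate_population(cfg, seed = 1)
  p2 <- generate_population(cfg, seed = 1)
  expect_identical(p1, p2)
  p3 <- generate_population(cfg, seed = 2)
  expect_false(identical(p1$count, p3$count))

  none <- generate_population(population_config(total = 1e5,
                                                maori_share = 0), 1)
  expect_equal(sum(none$count[none$ethnicity == "maori"]), 0)
  expect_gt(sum(none$count), 0)

  expect_error(generate_population(population_config(total = 0)),
               "positive")
})

test_that("default Maori age structure is younger", {
  p <- generate_population(population_config(total = 5e5), seed = 3)
  expect_lt(population_median_age(p, "maori"),
            population_median_age(p, "non_maori"))
  flat <- generate_population(
    population_config(total = 5e5, younger_maori = FALSE,
                      jitter_sd = 0), seed = 3)
  expect_equal(population_median_age(flat, "maori"),
               population_median_age(flat, "non_maori"))
})

test_that("baseline unemployment recovers configured ratios exactly", {
  pop <- generate_population(population_config(total = 2e5), seed = 1)
  bl <- generate_unemployment_baseline(unemployment_config(),
                                       population = pop)
  w <- derive_weights(bl)
  expect_equal(w$w_ethnicity, 2.0, tolerance = 1e-12)
  expect_equal(w$w_sex, 1.1, tolerance = 1e-12)
  # age gradient: youth above the oldest working band
  y <- bl$rate[bl$age_band == "15-24"]
  o <- bl$rate[bl$age_band == "55-64"]
  expect_true(all(y > o))
  # population-weighted mean equals the configured overall rate
  bp <- cvdshock:::band_populations(pop)
  key <- paste(bl$ethnicity, bl$sex, bl$age_band)
  wts <- bp$count[match(key, paste(bp$ethnicity, bp$sex, bp$age_band))]
  expect_equal(sum(bl$rate * wts) / sum(wts), 0.04, tolerance = 1e-12)
})

test_that("impossible unemployment configurations are rejected", {
  expect_error(
    generate_unemployment_baseline(
      unemployment_config(overall = 0.5, ethnic_ratio = 4)),
    "above 1")
})

test_that("epi generation: determinism, ratios, age monotonicity", {
  e1 <- generate_epi_params(seed = 5)
  e2 <- generate_epi_params(seed = 5)
  expect_identical(e1, e2)
  expect_false(identical(generate_epi_params(seed = 6)$chd_i, e1$chd_i))

  # ethnic incidence ratio holds at every age
  for (s in c("female", "male")) {
    m <- e1[e1$ethnicity == "maori" & e1$sex == s, ]
    nm <- e1[e1$ethnicity == "non_maori" & e1$sex == s, ]
    expect_equal(m$chd_i / nm$chd_i, rep(2, nrow(m)), tolerance = 1e-12)
    expect_equal(m$bg_mort / nm$bg_mort, rep(2, nrow(m)),
                 tolerance = 1e-12)
  }

  # incidence and mortality rise with age within each stratum
  for (key in split(e1, paste(e1$ethnicity, e1$sex))) {
    key <- key[order(key$age), ]
    expect_true(all(diff(key$chd_i) >= 0))
    expect_true(all(diff(key$bg_mort) >= 0))
    expect_gt(key$chd_i[key$age == 64], key$chd_i[key$age == 35])
  }
  expect_true(all(e1$chd_f < 1 & e1$str_f < 1))
  expect_error(epi_config(inc_slope = -0.1), "non-negative")
  expect_error(epi_config(ethnic_ratio = -1), "positive")
})

test_that("fixture bundles validate and share constants across seeds", {
  b1 <- tiny_bundle(1)
  b2 <- tiny_bundle(2)
  expect_silent(validate_bundle(b1))
  expect_false(identical(b1$epi$chd_i, b2$epi$chd_i))
  expect_identical(b1$scenarios, b2$scenarios)
  expect_identical(b1$effects, b2$effects)
})

test_that("a bundle feeds an end-to-end run without key errors", {
  b <- tiny_bundle(4, total = 5e4)
  shock <- shock_rr_table(b, "base_case")
  out <- diff_outputs(run_cohort(b, shock), run_cohort(b, NULL))
  expect_s3_class(out, "cvd_output")
  expect_equal(sort(unique(out$age_band)),
               sort(c("35-44", "45-54", "55-64")))
  expect_true(all(is.finite(out$haly_change)))
})
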