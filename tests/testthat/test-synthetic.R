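test_that("BMI generator reproduces configured cell moments", {
  bp <- default_bmi_params()
  bp$mean <- 24.5
  bp$sd <- 5.0
  cfg <- synthetic_config(seed = 1, n_bmi_records = 50000, bmi_params = bp)
  rec <- generate_bmi_survey(cfg)
  expect_equal(nrow(rec), 50000)
  cell <- rec[rec$sex == "female" & rec$age >= 20 & rec$age <= 24, ]
  bmi <- cell$weight / cell$height^2
  expect_gt(nrow(cell), 1000)
  expect_lt(abs(mean(bmi) - 24.5), 0.1)
  expect_lt(abs(sd(bmi) - 5.0) / 5.0, 0.05)
  # heights and weights respect the record invariants
  expect_true(all(rec$height > 0.5 & rec$height < 2.5))
  expect_true(all(rec$weight > 20 & rec$weight < 350))
})

test_that("generators are pure functions of the configuration", {
  cfg <- synthetic_config(seed = 7, n_bmi_records = 500)
  expect_identical(generate_bmi_survey(cfg), generate_bmi_survey(cfg))
  expect_identical(generate_consumption_survey(cfg, 400),
                   generate_consumption_survey(cfg, 400))
  cfg2 <- synthetic_config(seed = 8, n_bmi_records = 500)
  expect_false(identical(generate_bmi_survey(cfg), generate_bmi_survey(cfg2)))
})

test_that("empty requests return empty frames without error", {
  cfg <- synthetic_config(seed = 1, n_bmi_records = 0)
  expect_equal(nrow(generate_bmi_survey(cfg)), 0)
  expect_equal(nrow(generate_consumption_survey(cfg, 0)), 0)
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(synthetic_config(n_bmi_records = -5), "non-negative")
  expect_error(synthetic_config(sex_ratio = 1.2), "sex_ratio")
  bad_probs <- list(`15-24` = list(
    milk = c(0.5, 0.2, 0.1, 0.1, 0.05, 0.01),  # sums to 0.96
    juice = cup_probs_for_mean(200),
    ssb = ssb_probs_for_mean(200)))
  expect_error(synthetic_config(consumption_probs = bad_probs), "sum to 1")
})

test_that("degenerate category probabilities yield a constant column", {
  probs <- lapply(consumption_bands(), function(b) list(
    milk = setNames(c(0, 0, 0, 0, 1, 0), names(cup_probs_for_mean(200))),
    juice = cup_probs_for_mean(200),
    ssb = ssb_probs_for_mean(150)))
  names(probs) <- consumption_bands()
  cfg <- synthetic_config(seed = 3, consumption_probs = probs)
  rec <- generate_consumption_survey(cfg, 500)
  expect_true(all(rec$milk_category == "none"))
  expect_true(all(rec$age >= 15))
})

test_that("population pyramid covers all bands and aggregates correctly", {
  cfg <- synthetic_config(seed = 1)
  pyr <- generate_population_pyramid(cfg)
  expect_setequal(unique(pyr$band), model_bands())
  flat <- pyr
  flat$count <- 1e5
  cfg2 <- synthetic_config(seed = 1, pyramid = flat)
  expect_equal(sum(generate_population_pyramid(cfg2)$count), 26e5)
  # default SA-like pyramid declines with age for both sexes
  for (s in c("male", "female")) {
    cnt <- pyr$count[pyr$sex == s][match(model_bands(),
                                         pyr$band[pyr$sex == s])]
    expect_true(all(diff(cnt) <= 0))
  }
  expect_error(
    generate_population_pyramid(
      synthetic_config(pyramid = pyr[pyr$band != "80+", ])),
    "missing bands")
})

test_that("generate-then-refit round trip recovers distribution parameters", {
  bp <- default_bmi_params()
  cfg <- synthetic_config(seed = 11, n_bmi_records = 50000, bmi_params = bp)
  rec <- generate_bmi_survey(cfg)
  cell <- bp[bp$band == "40-44" & bp$sex == "female", ]
  fit <- fit_bmi_distribution(rec, band = "40-44", sex = "female")
  expect_lt(abs(fit$mean - cell$mean) / cell$mean, 0.02)
  expect_lt(abs(fit$sd - cell$sd) / cell$sd, 0.02)
})

test_that("gamma survey weights average one and exercise weighted paths", {
  cfg <- synthetic_config(seed = 5, n_bmi_records = 5000,
                          weight_scheme = "gamma")
  rec <- generate_bmi_survey(cfg)
  expect_true(all(rec$survey_weight > 0))
  expect_lt(abs(mean(rec$survey_weight) - 1), 0.05)
})
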