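test_that("cup categories map to midpoint volumes with caps", {
  m <- category_volume_map()
  expect_equal(midpoint_volume(">2 cups", m), 500)
  expect_equal(midpoint_volume("1-2 cups", m), 375)
  expect_equal(midpoint_volume("0.5-1 cup", m), 187.5)
  expect_equal(midpoint_volume(c("<0.5 cup", "<1 cup"), m), c(125, 125))
  expect_equal(midpoint_volume("none", m), 0)
  expect_true(is.na(midpoint_volume("don't know", m)))
  expect_error(midpoint_volume("three cups", m), "unknown")
})

test_that("SSB weekly frequencies convert to daily volumes", {
  m <- category_volume_map()
  expect_equal(ssb_daily_volume("every day", m), 330)
  expect_equal(ssb_daily_volume("1-3 times last week", m), 2 / 7 * 330)
  expect_equal(ssb_daily_volume("4-6 times last week", m), 5 / 7 * 330)
  expect_equal(ssb_daily_volume("none", m), 0)
  m200 <- category_volume_map(serving_volume = 200)
  expect_equal(ssb_daily_volume("every day", m200), 200)
  expect_error(ssb_daily_volume("twice", m), "unknown")
})

test_that("band estimation averages imputed volumes and handles missing", {
  est <- estimate_consumption(tiny_consumption_records(),
                              bands = "15-24")
  expect_equal(est$mean[est$beverage == "ssb"], 0.165)
  expect_equal(est$mean[est$beverage == "milk"], 0)
  expect_equal(est$sd[est$beverage == "milk"], 0)
  # a "don't know" respondent drops out of the milk mean only
  rec <- tiny_consumption_records()
  rec$milk_category <- c("don't know", "1-2 cups")
  est2 <- estimate_consumption(rec, bands = "15-24")
  expect_equal(est2$mean[est2$beverage == "milk"], 0.375)
  expect_equal(est2$mean[est2$beverage == "ssb"], 0.165)
  rec$milk_category <- c("don't know", "don't know")
  expect_error(estimate_consumption(rec, bands = "15-24"), "15-24")
})

test_that("estimates are invariant to record order and weight rescaling", {
  cfg <- synthetic_config(seed = 2)
  rec <- generate_consumption_survey(cfg, 3000)
  est <- estimate_consumption(rec)
  perm <- rec[rev(seq_len(nrow(rec))), ]
  est_perm <- estimate_consumption(perm)
  expect_equal(est$mean, est_perm$mean, tolerance = 1e-12)
  rec$survey_weight <- rec$survey_weight * 17
  est_scaled <- estimate_consumption(rec)
  expect_equal(est$mean, est_scaled$mean, tolerance = 1e-12)
  expect_equal(est$sd, est_scaled$sd, tolerance = 1e-12)
})

test_that("derived volumes stay within the imputation caps", {
  cfg <- synthetic_config(seed = 4)
  rec <- generate_consumption_survey(cfg, 5000)
  m <- category_volume_map()
  milk <- midpoint_volume(rec$milk_category, m)
  ssb <- ssb_daily_volume(rec$ssb_frequency, m)
  expect_true(all(milk[!is.na(milk)] >= 0 & milk[!is.na(milk)] <= 500))
  expect_true(all(ssb >= 0 & ssb <= m$serving_volume))
})

test_that("calibrated synthetic survey recovers the baseline SSB mean", {
  cfg <- synthetic_config(seed = 6)
  rec <- generate_consumption_survey(cfg, 20000)
  est <- estimate_consumption(rec)
  ssb_1524 <- est$mean[est$band == "15-24" & est$beverage == "ssb"]
  expect_lt(abs(ssb_1524 - 0.209), 0.012)
  milk_1524 <- est$mean[est$band == "15-24" & est$beverage == "milk"]
  expect_lt(abs(milk_1524 - 0.205), 0.012)
})

test_that("diet consumption derives as a fixed share of SSB", {
  ssb <- data.frame(band = c("15-24", "65+"), beverage = "ssb",
                    mean = c(0.209, 0.120), sd = c(0.01, 0.02))
  diet <- derive_diet_consumption(ssb)
  expect_equal(diet$mean, c(0.00836, 0.0048))
  expect_equal(diet$sd, 0.04 * ssb$sd)
  expect_equal(unique(diet$beverage), "diet")
  expect_equal(derive_diet_consumption(ssb, 0)$mean, c(0, 0))
  expect_error(derive_diet_consumption(ssb, -0.1), "fraction")
})
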