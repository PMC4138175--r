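test_that("BMI cleaning trims the weighted 1st-99th percentile range", {
  rec <- data.frame(height = 1, weight = seq(20, 35, length.out = 1000))
  kept <- clean_bmi(rec)
  expect_true(abs(nrow(kept) - 980) <= 1)
  expect_true(all(kept$bmi >= quantile(rec$weight, 0.01) - 0.02))
  same <- data.frame(height = 1.6, weight = rep(70, 50))
  expect_equal(nrow(clean_bmi(same)), 50)
  expect_error(clean_bmi(data.frame()), "non-empty")
})

test_that("histogram least-squares fit recovers lognormal cell parameters", {
  bp <- default_bmi_params()
  bp$mean <- 27
  bp$sd <- 6
  cfg <- synthetic_config(seed = 21, n_bmi_records = 50000, bmi_params = bp)
  rec <- generate_bmi_survey(cfg)
  fit <- fit_bmi_distribution(rec, family = "lognormal")
  expect_lt(abs(fit$mean - 27) / 27, 0.01)
  expect_lt(abs(fit$sd - 6) / 6, 0.02)
  cmp <- compare_bmi_families(rec)
  expect_setequal(cmp$family, c("lognormal", "gamma"))
  expect_true(all(is.finite(cmp$residual)))
  expect_true(all(abs(cmp$mean_diff) < 1))
  expect_error(fit_bmi_distribution(rec[1:20, ]), "at least 30")
})

test_that("histogram fit agrees with an independent maximum-likelihood fit", {
  skip_if_not_installed("fitdistrplus")
  bp <- default_bmi_params()
  bp$mean <- 27
  bp$sd <- 6
  cfg <- synthetic_config(seed = 23, n_bmi_records = 30000, bmi_params = bp)
  rec <- generate_bmi_survey(cfg)
  ours <- fit_bmi_distribution(rec, family = "lognormal")
  mle <- fitdistrplus::fitdist(rec$weight / rec$height^2, "lnorm")
  mu <- unname(mle$estimate["meanlog"])
  s <- unname(mle$estimate["sdlog"])
  mle_mean <- exp(mu + s^2 / 2)
  mle_sd <- mle_mean * sqrt(exp(s^2) - 1)
  expect_lt(abs(ours$mean - mle_mean) / mle_mean, 0.01)
  expect_lt(abs(ours$sd - mle_sd) / mle_sd, 0.03)
})

test_that("lognormal and gamma fits imply nearly the same obesity prevalence", {
  cfg <- synthetic_config(seed = 22, n_bmi_records = 50000)
  rec <- generate_bmi_survey(cfg)
  ln <- fit_bmi_distribution(rec, band = "45-49", sex = "female",
                             family = "lognormal")
  ga <- fit_bmi_distribution(rec, band = "45-49", sex = "female",
                             family = "gamma")
  p_ln <- bmi_tail_prevalence(ln$mean, ln$sd, 30, "lognormal")
  p_ga <- bmi_tail_prevalence(ga$mean, ga$sd, 30, "gamma")
  expect_lt(abs(p_ln - p_ga), 0.01)
})

test_that("polynomial smoothing has interpolation and nesting properties", {
  bands <- model_bands()
  x <- band_midpoint(bands)
  quad <- 20 + 0.3 * x - 0.002 * x^2
  expect_equal(smooth_across_ages(quad, bands, degree = 2), quad,
               tolerance = 1e-9)
  expect_equal(smooth_across_ages(quad, bands, degree = 0),
               rep(mean(quad), length(quad)))
  set.seed(1)
  noisy <- quad + rnorm(length(quad), 0, 0.5)
  r2 <- sum((noisy - smooth_across_ages(noisy, bands, 2))^2)
  r3 <- sum((noisy - smooth_across_ages(noisy, bands, 3))^2)
  expect_lte(r3, r2)
  expect_error(smooth_across_ages(quad, bands, degree = 13), "degree")
})

test_that("energy converts to weight and BMI by the equilibrium factors", {
  expect_equal(delta_weight(-94, 94), -1)
  expect_equal(delta_weight(-45.78, 94), -0.487, tolerance = 1e-3)
  expect_equal(delta_weight(0, 94), 0)
  expect_equal(delta_weight(-94, list(mean = 94, sd = 2.96)), -1)
  expect_equal(delta_bmi(-0.487, 1.601), -0.19, tolerance = 5e-3)
  expect_equal(delta_bmi(-0.487, 1.693), -0.17, tolerance = 5e-3)
  expect_equal(delta_bmi(0, 1.6), 0)
})

test_that("prevalence shift matches the closed-form lognormal tail", {
  pr <- shift_and_prevalence(27, 6, -0.19, threshold = 30)
  expect_equal(pr$baseline, lognormal_tail_oracle(27, 6, 30),
               tolerance = 1e-9)
  expect_equal(pr$baseline, 0.2777, tolerance = 1e-4)
  expect_equal(pr$shifted, lognormal_tail_oracle(26.81, 6, 30),
               tolerance = 1e-9)
  expect_equal(pr$shifted, 0.2679, tolerance = 5e-4)
  expect_equal((pr$shifted - pr$baseline) / pr$baseline, -0.035,
               tolerance = 1e-2)
  none <- shift_and_prevalence(27, 6, 0)
  expect_identical(none$baseline, none$shifted)
  expect_error(shift_and_prevalence(27, 6, -30), "positive")
})

test_that("downward mean shifts reduce tail prevalence for both families", {
  for (fam in c("lognormal", "gamma")) {
    for (m in c(22, 26, 30)) {
      for (s in c(4, 6)) {
        for (d in c(-0.05, -0.2, -1)) {
          pr <- shift_and_prevalence(m, s, d, threshold = 30, family = fam)
          expect_lt(pr$shifted, pr$baseline)
        }
      }
    }
  }
  # fixed-sigma variant preserves the monotonicity
  pr <- shift_and_prevalence(27, 6, -0.19, hold = "sigma")
  expect_lt(pr$shifted, pr$baseline)
})

test_that("head counts scale prevalence changes by band populations", {
  prev <- data.frame(band = "20-24", sex = c("male", "female"),
                     baseline = 0.10, shifted = 0.095)
  pyr <- data.frame(band = "20-24", sex = c("male", "female"),
                    count = c(1e6, 1e6))
  res <- obesity_headcount(prev, pyr)
  expect_equal(res$by_band$count_change, c(-5000, -5000))
  expect_equal(res$by_sex$rel_change, c(-0.05, -0.05))
  pyr0 <- pyr
  pyr0$count <- 0
  expect_equal(obesity_headcount(prev, pyr0)$national$count_change, 0)
  expect_error(obesity_headcount(prev, pyr[1, ]), "missing bands")
})
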