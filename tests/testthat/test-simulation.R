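test_that("null intervention leaves every output unchanged", {
  for (sc in list(tax_scenario(0, 1), tax_scenario(0.2, 0))) {
    fit <- ssb_tax_model(scenario = sc)
    expect_true(all(fit$consumption_shift$delta == 0))
    expect_true(all(fit$energy$net == 0))
    expect_true(all(fit$bmi$bmi_delta == 0))
    expect_equal(fit$bmi$shifted, fit$bmi$baseline)
    expect_equal(fit$obesity$national$count_change, 0)
  }
})

test_that("doubling baseline consumption doubles every energy delta", {
  cons <- default_consumption()
  fit1 <- ssb_tax_model(consumption = cons)
  cons2 <- cons
  cons2$mean <- 2 * cons$mean
  fit2 <- ssb_tax_model(consumption = cons2)
  expect_equal(fit2$energy$net, 2 * fit1$energy$net, tolerance = 1e-12)
})

test_that("degenerate Monte Carlo equals the deterministic run", {
  els <- default_elasticities()
  els$sd <- 0
  cons <- default_consumption()
  cons$sd <- 0
  fit <- ssb_tax_model(consumption = cons, elasticities = els,
                       kj_per_kg = list(mean = 94, sd = 0))
  mc <- run_monte_carlo(fit, mc_config(n_draws = 50, seed = 1),
                        keep_draws = TRUE)
  expect_equal(max(abs(sweep(mc$draws$energy, 2, fit$energy$net))), 0,
               tolerance = 1e-12)
  expect_equal(mc$energy$lower, mc$energy$upper, tolerance = 1e-12)
})

test_that("Monte Carlo is reproducible and contains the point estimate", {
  fit <- ssb_tax_model()
  mc1 <- run_monte_carlo(fit, mc_config(n_draws = 2000, seed = 42))
  mc2 <- run_monte_carlo(fit, mc_config(n_draws = 2000, seed = 42))
  expect_identical(mc1$energy, mc2$energy)
  expect_identical(mc1$obesity, mc2$obesity)
  expect_true(all(mc1$energy$lower <= mc1$energy$point &
                  mc1$energy$point <= mc1$energy$upper))
  expect_true(all(mc1$bmi$lower <= mc1$bmi$point &
                  mc1$bmi$point <= mc1$bmi$upper))
  expect_true(all(mc1$obesity$lower <= mc1$obesity$point &
                  mc1$obesity$point <= mc1$obesity$upper))
  expect_error(mc_config(n_draws = 1), "n_draws")
})

test_that("interval width shrinks as uncertainty SDs shrink", {
  width_at <- function(scale) {
    els <- default_elasticities()
    els$sd <- els$sd * scale
    cons <- default_consumption()
    cons$sd <- cons$sd * scale
    fit <- ssb_tax_model(consumption = cons, elasticities = els,
                         kj_per_kg = list(mean = 94, sd = 2.96 * scale))
    mc <- run_monte_carlo(fit, mc_config(n_draws = 2000, seed = 5))
    e <- mc$energy[mc$energy$band == "20-24", ]
    e$upper - e$lower
  }
  w <- sapply(c(1, 0.1, 0.01), width_at)
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], w[1] / 50)
})

test_that("permuting the sampling order leaves draw distributions unchanged", {
  fit <- ssb_tax_model()
  pvals <- sapply(1:5, function(s) {
    a <- run_monte_carlo(fit, mc_config(n_draws = 2000, seed = s),
                         keep_draws = TRUE)
    nq <- ncol(a$draws$quantities)
    b <- run_monte_carlo(fit, mc_config(n_draws = 2000, seed = s + 100),
                         sample_order = rev(seq_len(nq)), keep_draws = TRUE)
    suppressWarnings(
      stats::ks.test(a$draws$energy[, "20-24"], b$draws$energy[, "20-24"])$p.value)
  })
  expect_true(all(pvals > 0.01))
})

test_that("obesity reduction grows along both sensitivity axes", {
  fit <- ssb_tax_model()
  grid <- two_way_sensitivity(fit)
  for (s in c("male", "female")) {
    g <- grid[grid$sex == s, ]
    for (pr in unique(g$pass_on_rate)) {
      col <- g$rel_change[g$pass_on_rate == pr][order(
        g$tax_rate[g$pass_on_rate == pr])]
      expect_true(all(diff(abs(col)) > 0))
    }
    for (tr in unique(g$tax_rate)) {
      row <- g$rel_change[g$tax_rate == tr][order(
        g$pass_on_rate[g$tax_rate == tr])]
      expect_true(all(diff(abs(row)) > 0))
    }
  }
  # the (20%, 100%) cell is the main analysis, bit for bit
  main <- fit$obesity$by_sex
  cell <- grid[grid$tax_rate == 0.20 & grid$pass_on_rate == 1.00, ]
  expect_identical(cell$rel_change[match(main$sex, cell$sex)],
                   main$rel_change)
  expect_error(two_way_sensitivity(fit, numeric(0)), "non-empty")
})

test_that("serving-size reruns scale the SSB arm of the chain", {
  fit <- ssb_tax_model()
  tor <- serving_size_tornado(fit)
  m <- tor[tor$sex == "male", ]
  m <- m[order(m$size), ]
  # identity at the reference size
  expect_equal(m$rel_change[m$size == 330],
               fit$obesity$by_sex$rel_change[fit$obesity$by_sex$sex == "male"],
               tolerance = 1e-12)
  # smaller servings give smaller absolute changes, monotonically
  expect_true(all(diff(abs(m$rel_change)) > 0))
  expect_true(all(diff(abs(m$abs_change)) > 0))
})

test_that("serving-size rerun from records matches the rescaling route", {
  cfg <- synthetic_config(seed = 31)
  rec <- generate_consumption_survey(cfg, 8000)
  est <- estimate_consumption(rec, category_volume_map(330))
  est <- rbind(est, derive_diet_consumption(est[est$beverage == "ssb", ]))
  fit <- ssb_tax_model(consumption = est)
  via_scale <- serving_size_tornado(fit, sizes = 500)
  via_records <- serving_size_tornado(fit, sizes = 500, records = rec)
  expect_equal(via_scale$rel_change, via_records$rel_change,
               tolerance = 1e-10)
})
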