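test_that("generators are deterministic under a fixed seed", {
  a <- simulate_cause_specific(500, 0.2, 0.1, beta1 = 0.5, seed = 42)
  b <- simulate_cause_specific(500, 0.2, 0.1, beta1 = 0.5, seed = 42)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(
    tibble::as_tibble(simulate_cause_specific(500, 0.2, 0.1, seed = 43)),
    tibble::as_tibble(a)))

  f1 <- simulate_fine_gray(500, p = 0.6, beta = 0.3, seed = 7)
  f2 <- simulate_fine_gray(500, p = 0.6, beta = 0.3, seed = 7)
  expect_identical(tibble::as_tibble(f1), tibble::as_tibble(f2))

  r1 <- emulate_registry(2000, seed = 5)
  r2 <- emulate_registry(2000, seed = 5)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
})

test_that("cause-specific generator honours its closed-form structure", {
  no2 <- simulate_cause_specific(2000, 0.3, 0, seed = 11)
  expect_false(any(no2$event == 2))

  big <- simulate_cause_specific(50000, 0.3, 0.2, seed = 12)
  frac1 <- mean(big$event == 1)
  p1 <- 0.3 / 0.5
  expect_lt(abs(frac1 - p1), 3 * sqrt(p1 * (1 - p1) / 50000))

  expect_error(simulate_cause_specific(0, 0.3, 0.2), ">= 1")
  expect_error(simulate_cause_specific(10, -1, 0.2), "lambda1")
})

test_that("the closed-form CIF behaves at its limits and matches the empirical curve", {
  expect_equal(true_cif_cause_specific(0, 0, 0.3, 0.2), 0)
  expect_equal(true_cif_cause_specific(1e9, 0, 0.3, 0.2), 0.6)
  expect_error(true_cif_cause_specific(-1, 0, 0.3, 0.2), ">= 0")

  coh <- simulate_cause_specific(50000, 0.25, 0.2, beta1 = 0.4, beta2 = 0.2,
                                 seed = 13)
  aj <- aalen_johansen(coh$time, coh$event)
  for (t0 in c(1, 2, 3.5, 5)) {
    truth <- mean(true_cif_cause_specific(t0, coh$x, 0.25, 0.2, 0.4, 0.2))
    expect_lt(abs(eval_step(aj$cif1, t0) - truth), 0.01)
  }
})

test_that("the Fine-Gray generator matches its subdistribution", {
  base <- simulate_fine_gray(50000, p = 0.6, beta = 0.5, x = rep(0, 50000),
                             seed = 14)
  frac1 <- mean(base$event == 1)
  expect_lt(abs(frac1 - 0.6), 3 * sqrt(0.6 * 0.4 / 50000))

  null <- simulate_fine_gray(20000, p = 0.5, beta = 0, seed = 15)
  tab <- table(null$x > 0, null$event == 1)
  expect_gt(chisq.test(tab)$p.value, 0.01)

  coh <- simulate_fine_gray(50000, p = 0.6, beta = 0.4, seed = 16)
  aj <- aalen_johansen(coh$time, coh$event)
  for (t0 in c(1, 2, 4)) {
    truth <- mean(true_cif_fine_gray(t0, coh$x, 0.6, 0.4))
    expect_lt(abs(eval_step(aj$cif1, t0) - truth), 0.01)
  }
  expect_error(simulate_fine_gray(10, p = 1.2), "p must lie")
})

test_that("risk-equation predictions follow the configured formula", {
  cfg <- risk_config(coefficients = c(age = -0.02, egfr = -0.1),
                     centers = c(age = 70, egfr = 20),
                     baseline_survival = c(`2` = 0.9, `5` = 0.7))
  base <- predict_risk(data.frame(age = 70, egfr = 20), cfg)
  expect_equal(base$lp, 0)
  expect_equal(base$risk_2y, 0.1)
  expect_equal(base$risk_5y, 0.3)

  worse <- predict_risk(data.frame(age = 70, egfr = 15), cfg)
  expect_gt(worse$risk_2y, base$risk_2y)   # negative coef, lower egfr
  grid <- predict_risk(data.frame(age = 70, egfr = seq(30, 8)), cfg)
  expect_true(all(diff(grid$risk_5y) > 0))

  expect_error(predict_risk(data.frame(age = 70), cfg), "missing covariate")
  expect_error(predict_risk(data.frame(age = NA, egfr = 1), cfg), "missing")
  expect_error(risk_config(c(0.1), baseline_survival = c(`2` = 0.9)),
               "named")
  expect_error(risk_config(c(a = 0.1), baseline_survival = c(`2` = 1.5)),
               "\\(0, 1\\]")
})

test_that("risk configs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"coefficients": {"age": -0.02, "egfr": -0.1},
               "centers": {"age": 70, "egfr": 20},
               "baseline_survival": {"2": 0.9, "5": 0.7}}', path)
  cfg <- read_risk_config(path)
  expect_equal(unname(cfg$coefficients), c(-0.02, -0.1))
  expect_equal(predict_risk(data.frame(age = 70, egfr = 20), cfg)$risk_5y, 0.3)
  expect_error(read_risk_config(tempfile()), "not found")
})

test_that("the registry emulation reproduces its incidence targets", {
  coh <- emulate_registry(seed = 2)
  expect_s3_class(coh, "cr_cohort")          # construction passes validation
  aj <- aalen_johansen(coh$time, coh$event)
  f1_2 <- eval_step(aj$cif1, 2)
  expect_gt(f1_2, 0.10); expect_lt(f1_2, 0.16)
  expect_lt(abs(eval_step(aj$cif1, 5) - 0.20), 0.03)
  expect_lt(abs(eval_step(aj$cif2, 2) - 0.16), 0.03)
  expect_lt(abs(eval_step(aj$cif2, 5) - 0.25), 0.03)

  # administrative censoring only: censored exactly at the cutoff
  cens <- coh$event == 0
  expect_true(all(coh$time[cens] == coh$admin_censor_time[cens]))
  expect_true(all(coh$time <= coh$admin_censor_time + 1e-12))

  old <- filter_subgroup(coh, "age", ">=", 70)
  expect_gt(nrow(old), 0.5 * nrow(coh))
  aj_old <- aalen_johansen(old$time, old$event)
  # heavier competing mortality, lower kidney-failure incidence than overall
  expect_gt(eval_step(aj_old$cif2, 5), eval_step(aj$cif2, 5))
  expect_lt(eval_step(aj_old$cif1, 5), eval_step(aj$cif1, 5))
})
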