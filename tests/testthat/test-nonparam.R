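test_that("Kaplan-Meier matches hand product-limit calculations", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(eval_step(km, c(0.5, 1, 2.9, 3, 10)),
               c(1, 2 / 3, 2 / 3, 0, 0))

  expect_equal(eval_step(kaplan_meier(c(1, 2, 3), c(0, 0, 0)), c(1, 3)),
               c(1, 1))
  expect_equal(eval_step(kaplan_meier(5, 1), c(4.9, 5)), c(1, 0))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Aalen-Johansen matches hand calculations and exposes KM overestimation", {
  aj <- aalen_johansen(c(1, 2, 3), c(1, 0, 2))
  expect_equal(eval_step(aj$cif1, c(0.5, 1, 3)), c(0, 1 / 3, 1 / 3))
  expect_equal(eval_step(aj$cif2, c(2.9, 3)), c(0, 2 / 3))
  expect_equal(eval_step(aj$cif1, 3) + eval_step(aj$cif2, 3) +
                 eval_step(aj$surv, 3), 1)

  # competing event first: CIF gives 1/2 while cause-1 KM jumps to 1
  aj2 <- aalen_johansen(c(1, 2), c(2, 1))
  expect_equal(eval_step(aj2$cif1, 2), 0.5)
  km1 <- kaplan_meier(c(1, 2), c(0, 1))
  expect_equal(1 - eval_step(km1, 2), 1)
})

test_that("with no competing events the CIF equals 1 - KM at every time", {
  set.seed(401)
  for (r in 1:20) {
    d <- random_cohort_raw(sample(3:40, 1), p_comp = 0)
    aj <- aalen_johansen(d$time, d$event)
    km <- kaplan_meier(d$time, as.integer(d$event == 1))
    expect_equal(aj$cif1$values, 1 - eval_step(km, aj$cif1$times),
                 tolerance = 1e-12)
  }
})

test_that("components always sum to one and KM dominates the CIF", {
  set.seed(402)
  for (r in 1:200) {
    d <- random_cohort_raw(sample(2:50, 1))
    aj <- aalen_johansen(d$time, d$event)
    total <- aj$cif1$values + aj$cif2$values + aj$surv$values
    expect_lt(max(abs(total - 1)), 1e-12)
    km1 <- 1 - eval_step(kaplan_meier(d$time, as.integer(d$event == 1)),
                         aj$cif1$times)
    expect_true(all(km1 - aj$cif1$values >= -1e-12))
    # monotone in the right directions, within [0, 1]
    expect_true(all(diff(aj$cif1$values) >= -1e-12))
    expect_true(all(diff(aj$surv$values) <= 1e-12))
    expect_true(all(aj$cif1$values >= 0 & aj$cif1$values <= 1 + 1e-12))
  }
})

test_that("small cohorts match loop-based oracles exactly", {
  set.seed(403)
  for (r in 1:100) {
    n <- sample(1:8, 1)
    tm <- sort(sample(seq(0.5, 10, by = 0.5), n))  # distinct times
    ev <- sample(0:2, n, replace = TRUE)
    t_eval <- runif(1, 0, 11)
    aj <- aalen_johansen(tm, ev)
    expect_equal(eval_step(aj$cif1, t_eval), oracle_aj(tm, ev, t_eval, 1),
                 tolerance = 1e-12)
    expect_equal(eval_step(aj$cif2, t_eval), oracle_aj(tm, ev, t_eval, 2),
                 tolerance = 1e-12)
    expect_equal(eval_step(kaplan_meier(tm, as.integer(ev == 1)), t_eval),
                 oracle_km(tm, as.integer(ev == 1), t_eval),
                 tolerance = 1e-12)
  }
})

test_that("estimates and variances agree with survival and cmprsk", {
  skip_if_not_installed("survival")
  skip_if_not_installed("cmprsk")
  set.seed(404)
  d <- random_cohort_raw(300)
  km <- kaplan_meier(d$time, as.integer(d$event == 1))
  sf <- survival::survfit(survival::Surv(d$time, d$event == 1) ~ 1)
  i <- match(sf$time, km$times)
  expect_equal(km$values[i], sf$surv, tolerance = 1e-12)
  se_sf <- sf$std.err * sf$surv          # NaN where the risk set is exhausted
  ok <- is.finite(se_sf)
  expect_equal(sqrt(pmax(km$variance[i], 0))[ok], se_sf[ok],
               tolerance = 1e-10)

  aj <- aalen_johansen(d$time, d$event)
  tp <- cmprsk::timepoints(cmprsk::cuminc(d$time, d$event, cencode = 0),
                           times = aj$cif1$times)
  expect_equal(unname(tp$est["1 1", ]), aj$cif1$values, tolerance = 1e-12)

  # delta-method variance equals survfit's multi-state std.err at a horizon
  sms <- survival::survfit(
    survival::Surv(d$time, factor(d$event, 0:2, c("c", "e1", "e2"))) ~ 1)
  sm <- summary(sms, times = 2)
  idx <- which(sms$states == "e1")
  expect_equal(sqrt(crvalidate:::step_variance_at(aj$cif1, 2)),
               unname(sm$std.err[, idx]), tolerance = 1e-8)
})

test_that("censoring survival reverses the roles of event and censoring", {
  expect_equal(eval_step(censoring_survival(c(1, 2), c(0, 1)), c(0.9, 1, 2)),
               c(1, 0.5, 0.5))
  expect_equal(eval_step(censoring_survival(c(1, 2), c(1, 2)), 2), 1)
  expect_equal(eval_step(censoring_survival(c(2, 2), c(0, 0)), 2), 0)
  # at a tied time the event leaves the censoring risk set first
  g <- censoring_survival(c(1, 1, 2), c(1, 0, 0))
  expect_equal(eval_step(g, 1), 1 - 1 / 2)
})

test_that("step evaluation honours sides and extrapolates constantly", {
  sf <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(eval_step(sf, 2, side = "right"), 1 / 3)
  expect_equal(eval_step(sf, 2, side = "left"), 2 / 3)
  expect_equal(eval_step(sf, 0.2), 1)
  expect_equal(eval_step(sf, 99), 0)
  expect_error(eval_step(sf, -1), "finite and >= 0")
})

test_that("confidence limits stay within [0, 1] and variances are nonnegative", {
  set.seed(405)
  d <- random_cohort_raw(80)
  for (comp in list(kaplan_meier(d$time, as.integer(d$event == 1)),
                    aalen_johansen(d$time, d$event)$cif1)) {
    td <- tidy(comp)
    expect_true(all(td$std_error >= 0))
    ok <- !is.na(td$conf_low)
    expect_true(all(td$conf_low[ok] >= 0 & td$conf_high[ok] <= 1))
    expect_true(all(td$conf_low[ok] <= td$estimate[ok] + 1e-12))
    expect_true(all(td$conf_high[ok] >= td$estimate[ok] - 1e-12))
  }
})
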