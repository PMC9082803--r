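test_that("the Cox fitter maximises the hand-written partial likelihood", {
  tm <- c(1, 2, 3, 4); st <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_fit(tm, st, x)
  # grid-search maximiser of the explicit Breslow partial likelihood
  pl <- function(b) {
    risk <- exp(b * x)
    sum(vapply(seq_along(tm), function(i)
      b * x[i] - log(sum(risk[tm >= tm[i]])), 0)[st == 1])
  }
  grid <- seq(-4, 4, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, pl, 0))]
  expect_equal(fit$beta, b_star, tolerance = 1e-4)
  expect_lt(abs(fit$score), 1e-8)
})

test_that("the Cox fitter agrees with coxph and recovers a known effect", {
  skip_if_not_installed("survival")
  coh <- simulate_cause_specific(5000, 0.2, 0.1, beta1 = 0.7,
                                 admin_censor = 5, seed = 801)
  fit <- cox_fit(coh$time, as.integer(coh$event == 1), coh$x)
  cp <- survival::coxph(survival::Surv(time, event == 1) ~ x,
                        data = coh, ties = "breslow")
  expect_equal(fit$beta, unname(coef(cp)), tolerance = 1e-7)
  expect_equal(fit$se, sqrt(unname(vcov(cp)[1, 1])), tolerance = 1e-7)
  expect_lt(abs(fit$beta - 0.7), 3 * fit$se)

  # null case: permuted covariate
  perm <- withr::with_seed(1, sample(coh$x))
  null_fit <- cox_fit(coh$time, as.integer(coh$event == 1), perm)
  expect_lt(abs(null_fit$beta), 3 * null_fit$se)
})

test_that("Cox fitter rejects degenerate inputs", {
  expect_error(cox_fit(c(1, 2), c(0, 0), c(1, 2)), "no events")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 1), c(2, 2, 2)), "no information")
})

test_that("Fine-Gray reduces to Cox when weights are all one", {
  set.seed(802)
  n <- 400
  d <- random_cohort_raw(n, p_cens = 0)      # no random censoring
  x <- rnorm(n)
  fg <- fine_gray_fit(d$time, d$event, x)
  # equivalent Cox data: competing-event subjects kept event-free forever
  t2 <- ifelse(d$event == 2, max(d$time) + 1, d$time)
  s2 <- as.integer(d$event == 1)
  cx <- cox_fit(t2, s2, x)
  expect_equal(fg$beta, cx$beta, tolerance = 1e-8)
  expect_equal(fg$se, cx$se, tolerance = 1e-8)
})

test_that("Fine-Gray agrees with cmprsk::crr and recovers the subdistribution effect", {
  skip_if_not_installed("cmprsk")
  coh <- simulate_fine_gray(5000, p = 0.6, beta = 0.5, seed = 803,
                            admin_censor = 4, random_censor_rate = 0.15)
  fit <- fine_gray_fit(coh$time, coh$event, coh$x)
  cr <- cmprsk::crr(coh$time, coh$event, cov1 = matrix(coh$x),
                    failcode = 1, cencode = 0)
  expect_equal(fit$beta, unname(cr$coef), tolerance = 1e-4)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)

  null_coh <- simulate_fine_gray(5000, p = 0.5, beta = 0, seed = 804)
  nf <- fine_gray_fit(null_coh$time, null_coh$event, null_coh$x)
  expect_lt(abs(nf$beta), 3 * nf$se)
  expect_error(fine_gray_fit(c(1, 2), c(2, 0), c(1, 2)), "no cause-1")
})

test_that("rankit scaling reproduces closed-form Blom scores", {
  z <- rankit_scale(c(0.1, 0.5, 0.2))
  expect_equal(round(z, 4), c(-0.5448, 0.5448, 0))
  expect_equal(rankit_scale(c(5, 1, 3)), -rankit_scale(c(1, 5, 3)))
  expect_equal(rankit_scale(log(c(0.1, 0.5, 0.2))),
               rankit_scale(c(0.1, 0.5, 0.2)))
  expect_error(rankit_scale(rep(2, 5)), "identical")
  expect_lt(abs(mean(rankit_scale(runif(100)))), 1e-10)
})

test_that("explained variation transforms D as published", {
  expect_equal(r2_d(0), 0)
  expect_equal(round(100 * r2_d(2.13)), 52)
  expect_equal(round(100 * r2_d(2.23), 1), 54.3)
  expect_equal(round(100 * r2_d(2.04), 1), 49.8)
  d <- seq(0, 6, by = 0.25)
  expect_true(all(diff(r2_d(d)) > 0))
  expect_true(all(r2_d(d) >= 0 & r2_d(d) < 1))
  expect_equal(r2_d(-1.5), r2_d(1.5))
  expect_error(r2_d(Inf), "finite")
})

test_that("the D statistic is null for uninformative predictors", {
  coh <- simulate_cause_specific(3000, 0.25, 0.1, beta1 = 0, beta2 = 0,
                                 admin_censor = 5, seed = 805)
  co2 <- tibble::as_tibble(coh)
  co2$lp <- withr::with_seed(2, rnorm(nrow(co2)))
  co2 <- as_cohort(co2, horizons = c(2, 5))
  d <- d_statistic(co2, engine = "cox")
  expect_lt(abs(d$d), 3 * d$se)
})

test_that("Fine-Gray D falls below Cox D when high risk also predicts early death", {
  set.seed(806)
  n <- 4000
  x <- rnorm(n)
  t1 <- rexp(n, 0.2 * exp(0.9 * x))
  t2 <- rexp(n, 0.25 * exp(0.9 * x))   # the same patients also die early
  tm <- pmin(t1, t2, 6)
  ev <- ifelse(t1 <= tm, 1L, ifelse(t2 <= tm, 2L, 0L))
  coh <- make_cohort(tm, ev, risk = plogis(x), lp = x)
  d_cox <- d_statistic(coh, engine = "cox")
  d_fg <- d_statistic(coh, engine = "fine_gray")
  expect_lt(d_fg$d, d_cox$d)
  expect_lt(d_fg$r2d, d_cox$r2d)
})

test_that("D and C rank effect sizes identically", {
  betas <- c(0.2, 0.5, 0.8, 1.2, 1.6)
  cs <- ds <- numeric(length(betas))
  for (i in seq_along(betas)) {
    coh <- simulate_cause_specific(1500, 0.2, 0.1, beta1 = betas[i],
                                   admin_censor = 5, seed = 810 + i)
    ds[i] <- d_statistic(coh, engine = "cox", use_lp = TRUE)$d
    cs[i] <- concordance_cr(coh, 2, variant = "harrell", use_lp = TRUE)$c
  }
  expect_equal(cor(ds, cs, method = "spearman"), 1)
})

test_that("ranks of predicted risk substitute for the linear predictor", {
  coh <- simulate_cause_specific(2000, 0.2, 0.1, beta1 = 0.8,
                                 admin_censor = 5, seed = 812)
  via_lp <- d_statistic(coh, engine = "cox", use_lp = TRUE)
  via_risk <- d_statistic(coh, horizon = 2, engine = "cox", use_lp = FALSE)
  expect_equal(via_lp$d, via_risk$d, tolerance = 1e-12)
})
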