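test_that("perfect and inverted rankings hit the extremes", {
  h <- harrell_c(c(1, 2, 3), c(1, 1, 1), c(0.9, 0.5, 0.1))
  expect_equal(h$c, 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(0.1, 0.5, 0.9))$c, 0)
  expect_error(harrell_c(c(1, 2), c(0, 0), c(0.2, 0.4)), "no examinable pairs")
})

test_that("competing events open pairs that Harrell's rule cannot examine", {
  # A fails from cause 1 at t=1; B has a competing event at t=0.5
  tm <- c(1, 0.5); ev <- c(1, 2); rk <- c(0.8, 0.9)
  expect_error(harrell_c(tm, as.integer(ev == 1), rk), "no examinable pairs")
  w <- wolbers_c(tm, ev, rk, "infinity")
  expect_equal(w$n_pairs, 1)
  expect_equal(w$c, 0)
})

test_that("all variants reduce to Harrell when competing events are absent", {
  set.seed(701)
  d <- random_cohort_raw(150, p_comp = 0)
  rk <- runif(150)
  h <- harrell_c(d$time, as.integer(d$event == 1), rk)
  expect_equal(wolbers_c(d$time, d$event, rk, "infinity")$c, h$c)
  expect_equal(wolbers_c(d$time, d$event, rk, "censoring_complete",
                         admin_censor_time = d$time)$c, h$c)
})

test_that("the IPCW estimate equals the unweighted competing-risk C without censoring", {
  set.seed(702)
  n <- 200
  tm <- rexp(n, 0.4) + 0.01
  ev <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  rk <- runif(n)
  tau <- 2
  expect_equal(ipcw_c(tm, ev, rk, tau = tau)$c,
               wolbers_c(tm, ev, rk, "infinity", tau = tau)$c)
})

test_that("every variant matches exhaustive pair enumeration on small cohorts", {
  set.seed(703)
  for (r in 1:300) {
    n <- sample(2:10, 1)
    d <- random_cohort_raw(n)
    rk <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force risk ties
    st <- as.integer(d$event == 1)
    o <- oracle_concordance(d$time, st, rk)
    if (!is.na(o)) expect_equal(harrell_c(d$time, st, rk)$c, o)

    o_inf <- oracle_concordance(d$time, st, rk, inf_flag = d$event == 2)
    if (!is.na(o_inf))
      expect_equal(wolbers_c(d$time, d$event, rk, "infinity")$c, o_inf)

    act <- d$time + rexp(n)
    t2 <- ifelse(d$event == 2, act, d$time)
    o_cc <- oracle_concordance(t2, ifelse(d$event == 2, 0L, st), rk)
    if (!is.na(o_cc))
      expect_equal(wolbers_c(d$time, d$event, rk, "censoring_complete",
                             admin_censor_time = act)$c, o_cc)

    tau <- runif(1, 0.5, 5)
    g <- censoring_survival(d$time, d$event)
    wts <- 1 / eval_step(g, pmin(d$time, tau), side = "left")^2
    o_ip <- oracle_concordance(d$time, st, rk, tau = tau, ipcw = TRUE,
                               competing = d$event == 2, weight = wts)
    if (!is.na(o_ip) && all(is.finite(wts[st == 1 & d$time <= tau])))
      expect_equal(ipcw_c(d$time, d$event, rk, tau = tau)$c, o_ip)
  }
})

test_that("C agrees with survival::concordance on tied, censored data", {
  skip_if_not_installed("survival")
  set.seed(704)
  n <- 400
  tm <- sample(1:25, n, replace = TRUE) / 5
  st <- rbinom(n, 1, 0.5)
  rk <- sample(1:10, n, replace = TRUE) / 10
  cc <- survival::concordance(survival::Surv(tm, st) ~ rk, reverse = TRUE)
  expect_equal(harrell_c(tm, st, rk)$c, unname(cc$concordance),
               tolerance = 1e-12)
})

test_that("negating risks flips C and monotone transforms leave it unchanged", {
  set.seed(705)
  d <- random_cohort_raw(100)
  rk <- runif(100)
  for (fn in list(
    function(r) harrell_c(d$time, as.integer(d$event == 1), r),
    function(r) wolbers_c(d$time, d$event, r, "infinity"),
    function(r) ipcw_c(d$time, d$event, r, tau = 2))) {
    base <- fn(rk)$c
    expect_equal(fn(-rk)$c, 1 - base, tolerance = 1e-12)
    expect_equal(fn(qlogis(rk))$c, base, tolerance = 1e-12)
  }
})

test_that("the competing-risk C drops below Harrell's C when high risk also predicts early death", {
  # high-risk subjects fail early from cause 1 but also die early from the
  # competing cause; Harrell's rule discards those deaths while Wolbers'
  # rule scores the added (mostly discordant) pairs, pulling C down
  set.seed(706)
  n <- 3000
  x <- rnorm(n)
  t1 <- rexp(n, 0.25 * exp(1.2 * x))
  t2 <- rexp(n, 0.25 * exp(1.2 * x))
  tm <- pmin(t1, t2, 6)
  ev <- ifelse(t1 <= tm, 1L, ifelse(t2 <= tm, 2L, 0L))
  rk <- plogis(x)
  h <- harrell_c(tm, as.integer(ev == 1), rk)
  w <- wolbers_c(tm, ev, rk, "infinity")
  expect_lt(w$c, h$c)
})

test_that("bootstrap intervals cover the large-sample concordance", {
  big <- simulate_cause_specific(30000, 0.25, 0.15, beta1 = 0.8, beta2 = 0.2,
                                 admin_censor = 4, seed = 707)
  target <- wolbers_c(big$time, big$event, big$risk_2y, "infinity")$c
  set.seed(708)
  hits <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(big), 600)
    co <- tibble::as_tibble(big)[idx, ]
    ci <- concordance_cr(as_cohort(co, horizons = c(2, 5)), 2,
                         variant = "wolbers_infinity", boot = 200,
                         seed = 1000 + r)
    hits <- hits + (ci$conf_low <= target && target <= ci$conf_high)
  }
  expect_gte(hits / reps, 0.88)
})
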