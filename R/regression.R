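#' Single-covariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the Cox partial likelihood for one
#' covariate, with Breslow handling of tied event times. Used internally by
#' the D statistic (the covariate there is the rankit-scaled linear
#' predictor, which is tie-free), but exported because the fit itself is a
#' useful building block.
#'
#' @param time Follow-up times.
#' @param status 1 = event, 0 = censored.
#' @param x Numeric covariate.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param tol Convergence tolerance on the step and the score.
#' @return A `cr_fit` object: list with `beta`, `se`, `loglik`, `n_iter`,
#'   `engine = "cox"`, `n`, `n_event`.
#' @export
cox_fit <- function(time, status, x, max_iter = 50, tol = 1e-10) {
  stopifnot(length(time) == length(status), length(time) == length(x))
  if (length(time) < 2) abort("need at least 2 subjects")
  if (!all(status %in% c(0, 1))) abort("status must be 0 or 1")
  if (sum(status) == 0) abort("no events; partial likelihood undefined")
  ord <- order(time)
  t_s <- time[ord]; s_s <- status[ord]; x_s <- x[ord]
  n <- length(t_s)
  # risk set of time t = suffix of subjects with T >= t; with ties all
  # subjects sharing the time enter the same suffix
  first_idx <- which(!duplicated(t_s))
  suffix_start <- rep(first_idx, diff(c(first_idx, n + 1L)))
  ev <- which(s_s == 1)

  deriv <- function(beta) {
    ebx <- exp(beta * x_s)
    s0 <- rev(cumsum(rev(ebx)))
    s1 <- rev(cumsum(rev(x_s * ebx)))
    s2 <- rev(cumsum(rev(x_s^2 * ebx)))
    k <- suffix_start[ev]
    xbar <- s1[k] / s0[k]
    list(loglik = sum(beta * x_s[ev] - log(s0[k])),
         score = sum(x_s[ev] - xbar),
         info = sum(s2[k] / s0[k] - xbar^2))
  }

  beta <- 0
  d <- deriv(beta)
  n_iter <- 0L
  repeat {
    if (n_iter >= max_iter) break
    if (d$info <= .Machine$double.eps * sum(x_s^2 + 1))
      abort("covariate carries no information in the event risk sets (constant or separated)")
    step <- d$score / d$info
    new_beta <- beta + step
    d_new <- deriv(new_beta)
    halvings <- 0L
    while (!is.finite(d_new$loglik) || d_new$loglik < d$loglik - 1e-12) {
      step <- step / 2
      new_beta <- beta + step
      d_new <- deriv(new_beta)
      halvings <- halvings + 1L
      if (halvings > 30)
        abort("Cox partial likelihood failed to increase; possible monotone likelihood (separation)")
    }
    beta <- new_beta
    d <- d_new
    n_iter <- n_iter + 1L
    if (abs(step) < tol || abs(d$score) < tol) break
  }
  if (abs(beta) > 30)
    abort("Cox fit diverged (|beta| > 30); monotone likelihood (separation) likely")
  structure(list(beta = beta, se = 1 / sqrt(d$info), loglik = d$loglik,
                 score = d$score, n_iter = n_iter, engine = "cox",
                 n = n, n_event = length(ev)), class = "cr_fit")
}

#' Single-covariate Fine-Gray subdistribution-hazard fit
#'
#' Weighted-partial-likelihood estimate of the subdistribution log hazard
#' ratio for the event of interest. Subjects with a competing event remain in
#' the risk set after their event, down-weighted at later times t by
#' `G(t-) / G(T_i-)` where `G` is the censoring-distribution survival; with
#' no random censoring all weights are 1 and the fit equals [cox_fit()] on
#' data where competing-event subjects are kept event-free for all time.
#' Breslow handling of ties; model-based standard error from the observed
#' information of the weighted pseudo-likelihood (a seeded bootstrap is
#' available through [d_statistic()] when that approximation matters).
#'
#' @param time Follow-up times.
#' @param event Event codes 0/1/2.
#' @param x Numeric covariate.
#' @param cens Optional censoring-survival [cr_stepfun]; estimated from the
#'   data when `NULL`.
#' @inheritParams cox_fit
#' @return A `cr_fit` object with `engine = "fine_gray"`.
#' @export
fine_gray_fit <- function(time, event, x, cens = NULL, max_iter = 50,
                          tol = 1e-10) {
  stopifnot(length(time) == length(event), length(time) == length(x))
  if (!all(event %in% c(0, 1, 2))) abort("event codes must be 0, 1 or 2")
  if (sum(event == 1) == 0) abort("no cause-1 events; nothing to fit")
  if (is.null(cens)) cens <- censoring_survival(time, event)

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
  n <- length(t_s)
  first_idx <- which(!duplicated(t_s))
  suffix_start <- rep(first_idx, diff(c(first_idx, n + 1L)))
  ev <- which(e_s == 1)
  ev_times <- unique(t_s[ev])
  k_nat <- suffix_start[match(ev_times, t_s)]       # natural risk-set suffix
  g_left_ev <- eval_step(cens, ev_times, side = "left")   # G(t_j-)
  if (any(g_left_ev <= 0))
    abort("censoring survival reaches 0 while subdistribution weights are still needed")

  # competing-event subjects, ordered by time, contribute to later risk sets
  cmp <- which(e_s == 2)
  g_cmp <- eval_step(cens, t_s[cmp], side = "left")       # G(T_i-)
  # index of last competing subject with T_i < t_j, per event time
  cmp_before <- findInterval(ev_times, t_s[cmp], left.open = FALSE)
  # strict inequality: competing events tied with t_j are already in the
  # natural suffix (T_i >= t_j), so drop them here
  cmp_before <- vapply(seq_along(ev_times), function(j) {
    k <- cmp_before[j]
    while (k > 0 && t_s[cmp[k]] >= ev_times[j]) k <- k - 1L
    k
  }, integer(1))

  d1 <- as.integer(table(factor(t_s[ev], levels = ev_times)))
  sum_x_ev <- as.numeric(tapply(x_s[ev], factor(t_s[ev], levels = ev_times),
                                sum, default = 0))

  deriv <- function(beta) {
    ebx <- exp(beta * x_s)
    f0 <- ebx; f1 <- x_s * ebx; f2 <- x_s^2 * ebx
    S0 <- rev(cumsum(rev(f0))); S1 <- rev(cumsum(rev(f1)))
    S2 <- rev(cumsum(rev(f2)))
    # weighted prefix sums over competing subjects: f_i / G(T_i-)
    if (length(cmp) > 0) {
      C0 <- cumsum(f0[cmp] / g_cmp); C1 <- cumsum(f1[cmp] / g_cmp)
      C2 <- cumsum(f2[cmp] / g_cmp)
      pre <- function(cs, k) ifelse(k > 0, cs[pmax(k, 1)], 0)
      b0 <- g_left_ev * pre(C0, cmp_before)
      b1 <- g_left_ev * pre(C1, cmp_before)
      b2 <- g_left_ev * pre(C2, cmp_before)
    } else b0 <- b1 <- b2 <- 0
    s0 <- S0[k_nat] + b0
    s1 <- S1[k_nat] + b1
    s2 <- S2[k_nat] + b2
    xbar <- s1 / s0
    list(loglik = beta * sum(sum_x_ev) - sum(d1 * log(s0)),
         score = sum(sum_x_ev - d1 * xbar),
         info = sum(d1 * (s2 / s0 - xbar^2)))
  }

  beta <- 0
  d <- deriv(beta)
  n_iter <- 0L
  repeat {
    if (n_iter >= max_iter) break
    if (d$info <= .Machine$double.eps * sum(x_s^2 + 1))
      abort("covariate carries no information in the subdistribution risk sets")
    step <- d$score / d$info
    new_beta <- beta + step
    d_new <- deriv(new_beta)
    halvings <- 0L
    while (!is.finite(d_new$loglik) || d_new$loglik < d$loglik - 1e-12) {
      step <- step / 2
      new_beta <- beta + step
      d_new <- deriv(new_beta)
      halvings <- halvings + 1L
      if (halvings > 30)
        abort("Fine-Gray pseudo-likelihood failed to increase; possible separation")
    }
    beta <- new_beta
    d <- d_new
    n_iter <- n_iter + 1L
    if (abs(step) < tol || abs(d$score) < tol) break
  }
  if (abs(beta) > 30) abort("Fine-Gray fit diverged (|beta| > 30)")
  structure(list(beta = beta, se = 1 / sqrt(d$info), loglik = d$loglik,
                 score = d$score, n_iter = n_iter, engine = "fine_gray",
                 n = n, n_event = sum(e_s == 1)), class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat("<", x$engine, " fit: beta = ", sprintf("%.4f", x$beta),
      " (se ", sprintf("%.4f", x$se), "), ", x$n_event, "/", x$n,
      " events, ", x$n_iter, " iterations>\n", sep = "")
  invisible(x)
}

#' Tidy a single-covariate survival regression fit
#' @param x A `cr_fit`.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @export
tidy.cr_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(engine = x$engine, estimate = x$beta, std_error = x$se,
         conf_low = x$beta - z * x$se, conf_high = x$beta + z * x$se)
}

#' @rdname tidy.cr_fit
#' @export
glance.cr_fit <- function(x, ...) {
  tibble(engine = x$engine, loglik = x$loglik, n = x$n, n_event = x$n_event,
         n_iter = x$n_iter)
}
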