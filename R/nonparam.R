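#' @include stepfun.R
NULL

# Counting-process summary at the distinct observed times. At tied times
# events are processed before censorings, so both contribute to the at-risk
# count of the event process at that time, and the censoring process at time
# t sees n_risk - d subjects at risk.
risk_table <- function(time, event) {
  if (length(time) == 0) abort("empty input: no subjects")
  if (any(!is.finite(time) | time <= 0)) abort("times must be finite and > 0")
  if (!all(event %in% c(0, 1, 2))) abort("event codes must be 0, 1 or 2")
  ut <- sort(unique(time))
  f <- factor(time, levels = ut)
  n <- length(time)
  # counts kept as doubles: products like n * (n - d) overflow integers
  d1 <- as.numeric(tapply(event == 1, f, sum, default = 0))
  d2 <- as.numeric(tapply(event == 2, f, sum, default = 0))
  cc <- as.numeric(tapply(event == 0, f, sum, default = 0))
  total_at_t <- d1 + d2 + cc
  n_risk <- n - c(0, cumsum(total_at_t)[-length(ut)])
  list(time = ut, n_risk = n_risk, d1 = d1, d2 = d2, d = d1 + d2, c = cc)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function from right-censored data,
#' with Greenwood pointwise variance. To "ignore competing events" in a
#' competing-risk cohort, map event code 2 to status 0 before calling (the
#' [observed_probability()] wrapper does this).
#'
#' @param time Positive follow-up times.
#' @param status 1 = event, 0 = censored.
#' @return A [cr_stepfun] of type `"survival"` (initial value 1).
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
#' eval_step(km, c(0.5, 1, 2.9, 3))
#' @export
kaplan_meier <- function(time, status) {
  if (!all(status %in% c(0, 1))) abort("status must be 0 or 1")
  rt <- risk_table(time, as.integer(status))
  frac <- ifelse(rt$n_risk > 0, rt$d1 / rt$n_risk, 0)
  surv <- cumprod(1 - frac)
  # Greenwood: Var = S(t)^2 * sum d / (n (n - d)); term dropped where n == d
  gw <- ifelse(rt$n_risk > rt$d1,
               rt$d1 / (rt$n_risk * (rt$n_risk - rt$d1)), 0)
  variance <- surv^2 * cumsum(gw)
  new_stepfun(rt$time, surv, variance = variance, n_risk = rt$n_risk,
              n_event = rt$d1, init = 1, type = "survival")
}

#' Censoring-distribution survival estimate
#'
#' Kaplan-Meier estimate of the censoring distribution G(t): the roles of
#' event and censoring are reversed, so any event (code 1 or 2) censors the
#' censoring process. At tied times events precede censorings, hence the
#' at-risk set of the censoring process at time t excludes subjects with an
#' event at t. Used to build inverse-probability-of-censoring weights.
#'
#' @param time Positive follow-up times.
#' @param event Event codes in \{0, 1, 2\} (0 = censored).
#' @return A [cr_stepfun] of type `"censoring"` (initial value 1).
#' @export
censoring_survival <- function(time, event) {
  rt <- risk_table(time, event)
  at_risk <- rt$n_risk - rt$d
  frac <- ifelse(at_risk > 0, rt$c / at_risk, 0)
  g <- cumprod(1 - frac)
  gw <- ifelse(at_risk > rt$c, rt$c / (at_risk * (at_risk - rt$c)), 0)
  variance <- g^2 * cumsum(gw)
  new_stepfun(rt$time, g, variance = variance, n_risk = at_risk,
              n_event = rt$c, init = 1, type = "censoring")
}

#' Aalen-Johansen cumulative incidence estimates
#'
#' Nonparametric estimate of the cause-specific cumulative incidence functions
#' under competing risks: `F_k(t) = sum over event times t_j <= t of
#' S(t_j-) d_kj / n_j`, where `S` is the all-cause Kaplan-Meier survival.
#' The three components satisfy `F1(t) + F2(t) + S(t) = 1` at every grid
#' point. No independence assumption between the competing processes is
#' required. Pointwise variances for the incidence curves use the
#' delta-method (Aalen-type) estimator.
#'
#' @param time Positive follow-up times.
#' @param event Event codes: 0 censored, 1 event of interest, 2 competing.
#' @return A `cr_aj` object: list with [cr_stepfun] components `cif1`,
#'   `cif2` (type `"incidence"`, initial value 0) and `surv` (all-cause
#'   survival), sharing one time grid.
#' @examples
#' aj <- aalen_johansen(c(1, 2, 3), c(1, 0, 2))
#' eval_step(aj$cif1, 2)
#' @export
aalen_johansen <- function(time, event) {
  rt <- risk_table(time, event)
  frac <- ifelse(rt$n_risk > 0, rt$d / rt$n_risk, 0)
  surv <- cumprod(1 - frac)
  s_minus <- c(1, surv[-length(surv)])
  inc1 <- ifelse(rt$n_risk > 0, s_minus * rt$d1 / rt$n_risk, 0)
  inc2 <- ifelse(rt$n_risk > 0, s_minus * rt$d2 / rt$n_risk, 0)
  f1 <- cumsum(inc1)
  f2 <- cumsum(inc2)
  gw <- ifelse(rt$n_risk > rt$d, rt$d / (rt$n_risk * (rt$n_risk - rt$d)), 0)
  var_s <- surv^2 * cumsum(gw)
  structure(list(
    cif1 = new_stepfun(rt$time, f1, variance = cif_variance(rt, surv, f1, rt$d1),
                       n_risk = rt$n_risk, n_event = rt$d1,
                       init = 0, type = "incidence"),
    cif2 = new_stepfun(rt$time, f2, variance = cif_variance(rt, surv, f2, rt$d2),
                       n_risk = rt$n_risk, n_event = rt$d2,
                       init = 0, type = "incidence"),
    surv = new_stepfun(rt$time, surv, variance = var_s, n_risk = rt$n_risk,
                       n_event = rt$d, init = 1, type = "survival"),
    n = length(time)), class = "cr_aj")
}

# Delta-method pointwise variance of the cause-k CIF (Aalen-type):
#   Var F_k(t) = sum_j [F_k(t) - F_k(t_j)]^2 d_j / (n_j (n_j - d_j))
#              + sum_j S(t_j-)^2 d_kj (n_j - d_kj) / n_j^3
#              - 2 sum_j [F_k(t) - F_k(t_j)] S(t_j-) d_kj / n_j^2
# computed in one pass by expanding the squares into cumulative sums.
cif_variance <- function(rt, surv, fk, dk) {
  n_j <- as.numeric(rt$n_risk)
  dk <- as.numeric(dk)
  s_minus <- c(1, surv[-length(surv)])
  q <- ifelse(n_j > rt$d, rt$d / (n_j * (n_j - rt$d)), 0)
  w <- s_minus^2 * dk * (n_j - dk) / n_j^3
  r <- s_minus * dk / n_j^2
  cq <- cumsum(q); cfq <- cumsum(fk * q); cf2q <- cumsum(fk^2 * q)
  cw <- cumsum(w); cr_ <- cumsum(r); cfr <- cumsum(fk * r)
  v <- fk^2 * cq - 2 * fk * cfq + cf2q + cw - 2 * (fk * cr_ - cfr)
  pmax(v, 0)
}

#' @export
print.cr_aj <- function(x, ...) {
  m <- length(x$cif1$times)
  cat("<Aalen-Johansen estimate: n = ", x$n, ", ", m, " distinct times>\n",
      sep = "")
  cat("  final: F1 = ", format(x$cif1$values[m]), ", F2 = ",
      format(x$cif2$values[m]), ", S = ", format(x$surv$values[m]), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn aalen_johansen Tidy into a long tibble with one row per time
#'   and state (`cif1`, `cif2`, `surv`).
#' @param x A `cr_aj` object.
#' @param ... Unused.
#' @export
tidy.cr_aj <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$cif1), state = "cif1"),
    dplyr::mutate(tidy(x$cif2), state = "cif2"),
    dplyr::mutate(tidy(x$surv), state = "surv")
  ) |>
    dplyr::relocate("state")
}

#' @describeIn aalen_johansen Plot the stacked components over time.
#' @param object A `cr_aj` object.
#' @export
autoplot.cr_aj <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$estimate,
                                    colour = .data$state)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (years)", y = "Probability",
                  colour = NULL) +
    ggplot2::scale_colour_manual(values = c(cif1 = "#1b7837", cif2 = "#762a83",
                                            surv = "grey40"),
                                 labels = c(cif1 = "Event of interest",
                                            cif2 = "Competing event",
                                            surv = "Event-free")) +
    ggplot2::theme_minimal()
}
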