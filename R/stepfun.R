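#' Right-continuous step-function estimates
#'
#' Nonparametric survival-type estimates are stored as right-continuous
#' piecewise-constant functions over the distinct observed event/censoring
#' times: a grid of strictly increasing `times`, the estimate `values` at each
#' grid point, an optional pointwise `variance`, and the at-risk / event
#' counts. Before the first grid time the function equals `init` (1 for a
#' survival curve, 0 for a cumulative incidence curve); beyond the last grid
#' time it is extrapolated as constant.
#'
#' @name cr_stepfun
NULL

new_stepfun <- function(times, values, variance = NULL, n_risk = NULL,
                        n_event = NULL, init, type) {
  stopifnot(length(times) == length(values),
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 variance = variance, n_risk = n_risk, n_event = n_event,
                 init = init, type = type),
            class = "cr_stepfun")
}

#' @export
print.cr_stepfun <- function(x, ...) {
  cat("<cr_stepfun: ", x$type, ", ", length(x$times), " steps, range [",
      format(min(c(x$init, x$values))), ", ",
      format(max(c(x$init, x$values))), "]>\n", sep = "")
  invisible(x)
}

#' Evaluate a step function
#'
#' @param step A [cr_stepfun] object.
#' @param t Vector of evaluation times, all `>= 0`.
#' @param side `"right"` (default) for the right-continuous value, `"left"`
#'   for the left limit (for example the survival just before a jump,
#'   needed by inverse-censoring weights).
#' @return Numeric vector of estimates; constant extrapolation beyond the
#'   last grid time.
#' @export
eval_step <- function(step, t, side = c("right", "left")) {
  side <- match.arg(side)
  if (any(!is.finite(t) | t < 0)) abort("evaluation times must be finite and >= 0")
  idx <- findInterval(t, step$times,
                      left.open = identical(side, "left"))
  c(step$init, step$values)[idx + 1L]
}

step_variance_at <- function(step, t) {
  if (is.null(step$variance)) return(rep(NA_real_, length(t)))
  idx <- findInterval(t, step$times)
  c(0, step$variance)[idx + 1L]
}

#' @describeIn cr_stepfun Tidy a step function into a tibble with one row per
#'   grid time (columns `time`, `estimate`, `std_error`, `n_risk`, `n_event`,
#'   and log(-log)-based `conf_low` / `conf_high` when a variance is
#'   available).
#' @param x A `cr_stepfun` object.
#' @param ... Unused.
#' @param conf_level Confidence level for the pointwise interval.
#' @export
tidy.cr_stepfun <- function(x, ..., conf_level = 0.95) {
  out <- tibble(time = x$times, estimate = x$values)
  if (!is.null(x$variance)) {
    out$std_error <- sqrt(pmax(x$variance, 0))
    ci <- loglog_ci(x$values, out$std_error, conf_level,
                    increasing = x$type != "survival")
    out$conf_low <- ci$lower
    out$conf_high <- ci$upper
  }
  if (!is.null(x$n_risk)) out$n_risk <- x$n_risk
  if (!is.null(x$n_event)) out$n_event <- x$n_event
  out
}

# Pointwise CI on the complementary log(-log) scale so bounds stay in [0, 1].
# For survival S: exp(-exp(log(-log S) -/+ z * se / (S log S))).
# For an incidence F the same transform is applied to F directly
# (log(-log F)), which also respects [0, 1].
loglog_ci <- function(est, se, conf_level = 0.95, increasing = FALSE) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(est))
  ok <- is.finite(est) & is.finite(se) & est > 0 & est < 1 & se > 0
  th <- log(-log(est[ok]))
  se_th <- se[ok] / abs(est[ok] * log(est[ok]))
  lo <- exp(-exp(th + z * se_th))
  hi <- exp(-exp(th - z * se_th))
  lower[ok] <- lo
  upper[ok] <- hi
  deg <- is.finite(est) & !ok
  lower[deg] <- est[deg]
  upper[deg] <- est[deg]
  list(lower = pmin(lower, upper), upper = pmax(lower, upper))
}
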