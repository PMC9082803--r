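#' Jackknife pseudo-values of the cumulative incidence
#'
#' One pseudo-observation per subject for the cause-specific cumulative
#' incidence at the horizon:
#' `PV_i = n * F(horizon) - (n - 1) * F^(-i)(horizon)`, where `F^(-i)` is the
#' Aalen-Johansen estimate with subject i removed. With no censoring the
#' pseudo-values equal the event indicators exactly; under censoring they
#' spread the estimator's mass over all subjects and may legitimately fall
#' outside \[0, 1\]. They are the working response of the smoothed
#' calibration curve.
#'
#' Two algorithms are available and agree exactly: a naive jackknife that
#' refits the estimator n times, and a one-pass algorithm that updates the
#' product-limit prefix sums in O(n + #times). The naive route is the
#' default up to n = 2000, the one-pass route above.
#'
#' @param cohort A `cr_cohort` (or data frame with `time` and `event`).
#' @param horizon Horizon in years.
#' @param cause Cause of interest, 1 (default) or 2.
#' @param method `"auto"` (default), `"fast"` or `"naive"`.
#' @return Numeric vector of pseudo-values, one per row of `cohort`, in row
#'   order.
#' @examples
#' coh <- data.frame(time = c(1, 2, 3), event = c(1, 2, 1))
#' pseudo_values(coh, horizon = 2.5)  # no censoring: indicators (1, 0, 0)
#' @export
pseudo_values <- function(cohort, horizon, cause = 1,
                          method = c("auto", "fast", "naive")) {
  method <- match.arg(method)
  check_nonempty(cohort)
  n <- nrow(cohort)
  if (n < 2) abort("pseudo-values need at least 2 subjects")
  if (method == "auto") method <- if (n <= 2000) "naive" else "fast"
  time <- cohort$time
  event <- cohort$event
  if (method == "naive") {
    pseudo_values_naive(time, event, horizon, cause)
  } else {
    pseudo_values_fast(time, event, horizon, cause)
  }
}

pseudo_values_naive <- function(time, event, horizon, cause = 1) {
  n <- length(time)
  comp <- if (cause == 1) "cif1" else "cif2"
  full <- eval_step(aalen_johansen(time, event)[[comp]], horizon)
  vapply(seq_len(n), function(i) {
    loo <- eval_step(aalen_johansen(time[-i], event[-i])[[comp]], horizon)
    n * full - (n - 1) * loo
  }, numeric(1))
}

# Exact leave-one-out CIF in one pass. Removing subject i lowers the at-risk
# count by one at every grid time <= T_i and removes its own event; because
# the estimator depends on the data only through the per-time counts, all n
# leave-one-out values follow from two families of prefix arrays:
#   P_j, F_j   : original all-cause survival and cause-k CIF prefixes
#   Q_j, A_j   : the same prefixes with every at-risk count reduced by one
# For a subject with grid index K (= number of grid times <= T_i):
#   contribution of times <= K uses the reduced-count prefixes,
#   contribution of times  > K scales the remaining original increments by
#   S'(t_K) / P_K, where S'(t_K) accounts for the subject's own event.
pseudo_values_fast <- function(time, event, horizon, cause = 1) {
  n <- length(time)
  rt <- risk_table(time, event)
  m <- length(rt$time)
  dk <- if (cause == 1) rt$d1 else rt$d2
  nj <- rt$n_risk
  dj <- rt$d

  frac <- ifelse(nj > 0, dj / nj, 0)
  P <- cumprod(1 - frac)                      # S(t_j)
  P_minus <- c(1, P[-m])                      # S(t_j-)
  Fk <- cumsum(ifelse(nj > 0, P_minus * dk / nj, 0))
  J <- findInterval(horizon, rt$time)         # grid times <= horizon
  F_tau <- if (J == 0) 0 else Fk[J]

  # reduced-count prefixes (subject at risk through t_l, no event decrement)
  m_l <- ifelse(nj > 1, 1 - dj / (nj - 1), 1)
  Q <- cumprod(m_l)
  Q_minus <- c(1, Q[-m])
  A <- cumsum(ifelse(nj > 1, Q_minus * dk / (nj - 1), 0))

  K_all <- match(time, rt$time)               # each subject's own grid index
  pv <- numeric(n)
  for (i in seq_len(n)) {
    K <- K_all[i]
    if (K > J) {
      # removal only thins risk sets over the whole window [0, horizon]
      loo <- if (J == 0) 0 else A[J]
    } else {
      head_part <- if (event[i] == 0) {
        if (K == 0) 0 else A[K]
      } else {
        own <- if (nj[K] > 1) Q_minus[K] * (dk[K] - (event[i] == cause)) / (nj[K] - 1) else 0
        (if (K > 1) A[K - 1] else 0) + own
      }
      s_after <- if (event[i] == 0) {
        Q[K]
      } else if (nj[K] > 1) {
        Q_minus[K] * (1 - (dj[K] - 1) / (nj[K] - 1))
      } else {
        Q_minus[K]
      }
      tail_part <- if (K < J && P[K] > 0) {
        (s_after / P[K]) * (F_tau - Fk[K])
      } else 0
      loo <- head_part + tail_part
    }
    pv[i] <- n * F_tau - (n - 1) * loo
  }
  pv
}

#' Pseudo-value smoothed calibration curve
#'
#' Local-linear regression of the pseudo-values on the predicted risks,
#' evaluated on an equally spaced grid spanning the observed predicted-risk
#' range. The bandwidth is chosen by the direct plug-in rule
#' ([KernSmooth::dpill()]); values are not clamped to \[0, 1\] since
#' pseudo-values legitimately exceed that range.
#'
#' @param pv Numeric vector of pseudo-values (see [pseudo_values()]).
#' @param predicted Predicted risks, same length as `pv`.
#' @param grid_size Number of grid points (default 100).
#' @param bandwidth Optional fixed bandwidth; default is plug-in.
#' @return Tibble with columns `predicted` (grid) and `observed` (smoothed
#'   pseudo-value).
#' @export
calibration_curve <- function(pv, predicted, grid_size = 100,
                              bandwidth = NULL) {
  if (length(pv) != length(predicted))
    abort("pv and predicted must have the same length")
  rng <- range(predicted)
  if (diff(rng) <= 0)
    abort("predicted risks are constant; no spread to smooth over")
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(KernSmooth::dpill(predicted, pv),
                          error = function(e) NA_real_)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      # normal-reference fallback when the plug-in pilot fails
      bandwidth <- 1.06 * sd(predicted) * length(predicted)^(-1 / 5)
    }
  }
  fit <- KernSmooth::locpoly(predicted, pv, degree = 1, bandwidth = bandwidth,
                             gridsize = grid_size, range.x = rng)
  tibble(predicted = fit$x, observed = fit$y)
}

#' Full calibration assessment at a horizon
#'
#' Bundles calibration-in-the-large (O/E with interval), the grouped
#' calibration points and the pseudo-value smoothed curve into one object
#' with `tidy()`, `glance()` and `autoplot()` methods.
#'
#' @inheritParams calibration_groups
#' @param grid_size Grid size for the smoothed curve.
#' @param curve Compute the pseudo-value smoothed curve? (Only meaningful
#'   for `method = "cif"`-style absolute risks; the curve always uses
#'   cause-1 cumulative-incidence pseudo-values.)
#' @return A `cr_calibration` object.
#' @export
calibrate <- function(cohort, horizon, method = c("cif", "km"),
                      n_groups = 10, conf_level = 0.95, grid_size = 100,
                      curve = TRUE) {
  method <- match.arg(method)
  rc <- risk_col(cohort, horizon)
  oe <- oe_ratio(cohort, horizon, method, conf_level)
  groups <- calibration_groups(cohort, horizon, n_groups, method, conf_level)
  crv <- NULL
  pv <- NULL
  if (curve) {
    pv <- pseudo_values(cohort, horizon)
    crv <- calibration_curve(pv, cohort[[rc]], grid_size)
  }
  structure(list(horizon = horizon, method = method, summary = oe,
                 groups = groups, curve = crv, pseudo_values = pv,
                 n = nrow(cohort)),
            class = "cr_calibration")
}

#' @export
print.cr_calibration <- function(x, ...) {
  s <- x$summary
  cat("Calibration at ", x$horizon, " years (", x$method, " arm, n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  E = %.3f  O = %.3f  O/E = %.2f (%.2f-%.2f)\n",
              s$expected, s$observed, s$oe, s$conf_low, s$conf_high))
  invisible(x)
}

#' @describeIn calibrate Grouped calibration points as a tibble.
#' @param x,object A `cr_calibration` object.
#' @param ... Unused.
#' @export
tidy.cr_calibration <- function(x, ...) x$groups

#' @describeIn calibrate One-row summary (E, O, O/E and interval).
#' @export
glance.cr_calibration <- function(x, ...) {
  dplyr::mutate(x$summary, n = x$n)
}

#' @describeIn calibrate Calibration plot: grouped points with intervals,
#'   smoothed curve, and the identity line.
#' @export
autoplot.cr_calibration <- function(object, ...) {
  p <- ggplot2::ggplot(object$groups,
                       ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted risk", y = "Observed probability",
                  title = paste0("Calibration at ", object$horizon,
                                 " years (", object$method, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(object$curve)) {
    p <- p + ggplot2::geom_line(data = object$curve, colour = "#1b7837")
  }
  p
}
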