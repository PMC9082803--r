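#' Rankit-scale a linear predictor
#'
#' Ranks the values (mid-ranks for ties), converts to Blom normal scores
#' `qnorm((r - 3/8) / (n + 1/4))` and divides by `kappa = sqrt(8 / pi)`.
#' Entering the result as the single covariate of a survival regression
#' yields the Royston-Sauerbrei D statistic as the fitted coefficient. The
#' output has mean approximately 0 and is antisymmetric under order reversal;
#' any monotone transform of the input leaves it unchanged.
#'
#' @param lp Numeric linear predictors (length >= 2, not all identical).
#' @return Numeric vector of scaled scores.
#' @examples
#' rankit_scale(c(0.1, 0.5, 0.2))
#' @export
rankit_scale <- function(lp) {
  n <- length(lp)
  if (n < 2) abort("need at least 2 values")
  if (length(unique(lp)) == 1)
    abort("all linear predictors identical; D statistic undefined")
  r <- rank(lp, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
}

#' Explained variation from a D statistic
#'
#' Royston-Sauerbrei transformation of the prognostic-separation D statistic
#' to the proportion of explained variation on the log-time scale:
#' `R2_D = (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)` with
#' `kappa^2 = 8 / pi`. Strictly increasing in `|D|`, bounded in \[0, 1).
#'
#' @param d D statistic (finite).
#' @return Explained variation in \[0, 1).
#' @examples
#' r2_d(2.13)  # ~0.52
#' @export
r2_d <- function(d) {
  if (any(!is.finite(d))) abort("d must be finite")
  kappa2 <- 8 / pi
  (d^2 / kappa2) / (pi^2 / 6 + d^2 / kappa2)
}

#' Royston-Sauerbrei D statistic for a validation cohort
#'
#' The linear predictors of the model under validation are ranked, scaled
#' ([rankit_scale()]) and entered as the single covariate of a new survival
#' regression on the validation data; the fitted coefficient is D. It can be
#' read as the log hazard ratio comparing two equally sized prognostic
#' groups. With `engine = "cox"` competing events are censored (the naive
#' treatment); with `engine = "fine_gray"` the regression targets the
#' subdistribution hazard so competing events are accounted for. If the
#' cohort has no `lp` column the predicted risks at `horizon` are used
#' instead — rank-equivalent to the linear predictor under any monotone
#' link, so D is unchanged.
#'
#' @param cohort A `cr_cohort`.
#' @param horizon Horizon whose risk column is the ranking fallback when no
#'   `lp` column exists.
#' @param engine `"cox"` or `"fine_gray"`.
#' @param use_lp Force use of the `lp` column (default: use it when present).
#' @param boot Bootstrap replicates for the D interval (0 = model-based
#'   Wald interval from the information matrix).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return A `cr_dstat` object with fields `d`, `se`, `conf_low`,
#'   `conf_high`, `kappa`, `r2d`, `engine`.
#' @export
d_statistic <- function(cohort, horizon = NULL,
                        engine = c("cox", "fine_gray"),
                        use_lp = "lp" %in% names(cohort), boot = 0,
                        seed = 1L, conf_level = 0.95) {
  engine <- match.arg(engine)
  check_nonempty(cohort)
  lp <- if (isTRUE(use_lp)) {
    if (!"lp" %in% names(cohort)) abort("cohort has no 'lp' column")
    cohort$lp
  } else {
    if (is.null(horizon)) abort("supply a horizon when the cohort has no 'lp' column")
    cohort[[risk_col(cohort, horizon)]]
  }
  fit_one <- function(time, event, lp) {
    z <- rankit_scale(lp)
    if (engine == "cox") cox_fit(time, as.integer(event == 1), z)
    else fine_gray_fit(time, event, z)
  }
  fit <- fit_one(cohort$time, cohort$event, lp)
  z_q <- qnorm(1 - (1 - conf_level) / 2)
  lo <- fit$beta - z_q * fit$se
  hi <- fit$beta + z_q * fit$se
  if (boot > 0) {
    n <- nrow(cohort)
    ds <- withr_seed(seed, vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_one(cohort$time[idx], cohort$event[idx], lp[idx])$beta,
               error = function(e) NA_real_)
    }, numeric(1)))
    alpha <- (1 - conf_level) / 2
    qs <- quantile(ds, c(alpha, 1 - alpha), na.rm = TRUE, type = 7)
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  structure(list(d = fit$beta, se = fit$se, conf_low = lo, conf_high = hi,
                 kappa = sqrt(8 / pi), r2d = r2_d(fit$beta),
                 engine = engine, fit = fit, n = nrow(cohort)),
            class = "cr_dstat")
}

#' @export
print.cr_dstat <- function(x, ...) {
  cat(sprintf("D statistic (%s): %.3f (%.3f-%.3f), R2_D = %.1f%%\n",
              x$engine, x$d, x$conf_low, x$conf_high, 100 * x$r2d))
  invisible(x)
}

#' Tidy a D-statistic result
#' @param x A `cr_dstat`.
#' @param ... Unused.
#' @export
tidy.cr_dstat <- function(x, ...) {
  tibble(engine = x$engine, d = x$d, std_error = x$se,
         conf_low = x$conf_low, conf_high = x$conf_high,
         kappa = x$kappa, r2d = x$r2d)
}

#' @rdname tidy.cr_dstat
#' @export
glance.cr_dstat <- function(x, ...) {
  tibble(engine = x$engine, d = x$d, r2d = x$r2d, n = x$n)
}
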