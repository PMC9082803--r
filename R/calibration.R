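#' Observed outcome probability at a prediction horizon
#'
#' The observed probability of the event of interest by the horizon, computed
#' either by `1 - KM` with competing events censored (`method = "km"`,
#' "ignoring competing events") or by the Aalen-Johansen cumulative incidence
#' (`method = "cif"`, "taking competing events into account"). With no
#' competing events the two coincide; otherwise the KM version estimates a
#' hypothetical risk in a world where the competing event cannot occur and is
#' never smaller than the CIF.
#'
#' @param cohort A `cr_cohort` (or any data frame with `time` and `event`).
#' @param horizon Horizon in years, `> 0`. Events occurring exactly at the
#'   horizon count as within the horizon. A horizon beyond the maximum
#'   follow-up triggers a warning and constant extrapolation.
#' @param method `"cif"` (default) or `"km"`.
#' @param conf_level Confidence level for the log(-log) interval.
#' @return One-row tibble: `horizon`, `method`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`.
#' @export
observed_probability <- function(cohort, horizon, method = c("cif", "km"),
                                 conf_level = 0.95) {
  method <- match.arg(method)
  check_nonempty(cohort)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0)
    abort("horizon must be a single positive number")
  time <- cohort$time
  event <- cohort$event
  if (horizon > max(time))
    warn(paste0("horizon ", horizon, " exceeds maximum follow-up ",
                format(max(time)), "; estimate extrapolated as constant"))
  if (method == "km") {
    km <- kaplan_meier(time, as.integer(event == 1))
    est <- 1 - eval_step(km, horizon)
    se <- sqrt(step_variance_at(km, horizon))
  } else {
    aj <- aalen_johansen(time, event)
    est <- eval_step(aj$cif1, horizon)
    se <- sqrt(step_variance_at(aj$cif1, horizon))
  }
  ci <- loglog_ci(est, se, conf_level)
  tibble(horizon = horizon, method = method, estimate = est, std_error = se,
         conf_low = ci$lower, conf_high = ci$upper)
}

#' Observed/expected ratio from summary inputs
#'
#' Calibration-in-the-large: the observed probability divided by the average
#' predicted risk. The confidence interval comes from a log-scale Wald
#' interval using the standard error of the observed probability, treating
#' the average predicted risk as fixed.
#'
#' @param observed Observed probability O.
#' @param expected Average predicted risk E, `> 0`.
#' @param se Standard error of O (optional; CI is `NA` without it).
#' @param conf_level Confidence level.
#' @return One-row tibble: `observed`, `expected`, `oe`, `conf_low`,
#'   `conf_high`.
#' @examples
#' oe_stat(0.31, 0.41, se = 0.005)
#' @export
oe_stat <- function(observed, expected, se = NULL, conf_level = 0.95) {
  if (!is.numeric(expected) || expected <= 0)
    abort("expected (average predicted risk) must be > 0")
  ratio <- observed / expected
  lo <- hi <- NA_real_
  if (!is.null(se) && is.finite(se) && observed > 0) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    # delta method on log O: se(log O) = se(O)/O
    lo <- ratio * exp(-z * se / observed)
    hi <- ratio * exp(z * se / observed)
  }
  tibble(observed = observed, expected = expected, oe = ratio,
         conf_low = lo, conf_high = hi)
}

#' Observed/expected ratio for a cohort
#'
#' @inheritParams observed_probability
#' @param boot Number of bootstrap replicates for the CI; `0` (default) uses
#'   the log-scale Wald interval from [oe_stat()].
#' @param seed Seed for the bootstrap resampling.
#' @return One-row tibble: `horizon`, `method`, `expected`, `observed`,
#'   `oe`, `conf_low`, `conf_high`.
#' @export
oe_ratio <- function(cohort, horizon, method = c("cif", "km"),
                     conf_level = 0.95, boot = 0, seed = 1L) {
  method <- match.arg(method)
  rc <- risk_col(cohort, horizon)
  expected <- mean(cohort[[rc]])
  obs <- observed_probability(cohort, horizon, method, conf_level)
  res <- oe_stat(obs$estimate, expected, obs$std_error, conf_level)
  if (boot > 0) {
    qs <- boot_quantiles(cohort, horizon, conf_level, boot, seed,
                         function(co) {
                           o <- suppressWarnings(
                             observed_probability(co, horizon, method)$estimate)
                           o / mean(co[[rc]])
                         })
    res$conf_low <- qs[1]
    res$conf_high <- qs[2]
  }
  tibble(horizon = horizon, method = method, expected = expected,
         observed = res$observed, oe = res$oe,
         conf_low = res$conf_low, conf_high = res$conf_high)
}

boot_quantiles <- function(cohort, horizon, conf_level, B, seed, stat_fun) {
  n <- nrow(cohort)
  stats_ <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stat_fun(as_tibble(cohort)[idx, , drop = FALSE])
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  unname(quantile(stats_, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Grouped calibration points
#'
#' Divides the cohort into groups by quantiles of predicted risk at the
#' horizon (rank-based with stable order, so group sizes differ by at most
#' one even with heavily tied risks) and computes, per group, the mean
#' predicted risk and the observed probability with its interval.
#'
#' @inheritParams observed_probability
#' @param n_groups Number of risk groups (default 10, i.e. deciles).
#' @return Tibble with one row per group: `group`, `n`, `predicted`,
#'   `observed`, `conf_low`, `conf_high`.
#' @export
calibration_groups <- function(cohort, horizon, n_groups = 10,
                               method = c("cif", "km"), conf_level = 0.95) {
  method <- match.arg(method)
  check_nonempty(cohort)
  n <- nrow(cohort)
  if (n < n_groups)
    abort(paste0("fewer subjects (", n, ") than groups (", n_groups, ")"))
  rc <- risk_col(cohort, horizon)
  ord <- order(cohort[[rc]])  # stable ties
  sizes <- rep(n %/% n_groups, n_groups)
  if (n %% n_groups > 0) sizes[seq_len(n %% n_groups)] <- sizes[seq_len(n %% n_groups)] + 1L
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), sizes)
  purrr::map_dfr(seq_len(n_groups), function(g) {
    sub <- as_tibble(cohort)[grp == g, , drop = FALSE]
    obs <- suppressWarnings(
      observed_probability(sub, horizon, method, conf_level))
    tibble(group = g, n = nrow(sub), predicted = mean(sub[[rc]]),
           observed = obs$estimate, conf_low = obs$conf_low,
           conf_high = obs$conf_high)
  })
}
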