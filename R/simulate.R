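#' Simulate a competing-risk cohort from cause-specific hazards
#'
#' Latent cause-1 and cause-2 times are drawn from exponential hazards
#' `lambda_k * exp(beta_k * x)`; the observed time is the minimum of the
#' latent times, a per-subject administrative censoring time and an optional
#' random censoring time. The true cause-1 cumulative incidence is available
#' in closed form ([true_cif_cause_specific()]), and by default each subject's
#' predicted risk at every horizon is set to that true value, so the
#' generated model is perfectly calibrated for the absolute risk by
#' construction.
#'
#' @param n Cohort size.
#' @param lambda1,lambda2 Baseline cause-specific hazards (per year);
#'   `lambda1 > 0`, `lambda2 >= 0`.
#' @param beta1,beta2 Log hazard ratios per unit of `x`.
#' @param x Covariate vector of length `n`, or `NULL` to draw standard
#'   normals.
#' @param horizons Prediction horizons (years) for the risk columns.
#' @param admin_censor Administrative censoring: a single cutoff (years), a
#'   vector of per-subject times, or `Inf` (default) for complete follow-up.
#' @param random_censor_rate Exponential rate of an independent random
#'   censoring time (0 = none).
#' @param risk `"true_cif"` (default) attaches the closed-form cause-1 CIF at
#'   each horizon as the predicted risk; `"net"` attaches the cause-1 net
#'   risk `1 - exp(-lambda1 e^{beta1 x} t)`, the miscalibrated-for-absolute-
#'   risk quantity a model developed with competing events censored targets.
#' @param risk_scale Multiplier applied to the predicted risks (truncated at
#'   1) to emulate an over- or under-predicting model.
#' @param seed Integer seed; the output is bit-identical across runs for a
#'   fixed seed.
#' @return A `cr_cohort` with columns `id`, `time`, `event`, `x`, `lp`,
#'   `admin_censor_time` (when finite) and one risk column per horizon. The
#'   generating parameters are stored in the `truth` attribute.
#' @export
simulate_cause_specific <- function(n, lambda1, lambda2, beta1 = 0,
                                    beta2 = 0, x = NULL, horizons = c(2, 5),
                                    admin_censor = Inf,
                                    random_censor_rate = 0,
                                    risk = c("true_cif", "net"),
                                    risk_scale = 1, seed = 1L) {
  risk <- match.arg(risk)
  if (n < 1) abort("n must be >= 1")
  if (lambda1 <= 0 || lambda2 < 0) abort("need lambda1 > 0 and lambda2 >= 0")
  if (random_censor_rate < 0) abort("random_censor_rate must be >= 0")
  withr_seed(seed, {
    if (is.null(x)) x <- rnorm(n)
    stopifnot(length(x) == n)
    h1 <- lambda1 * exp(beta1 * x)
    h2 <- lambda2 * exp(beta2 * x)
    t1 <- rexp(n) / h1
    t2 <- if (lambda2 > 0) rexp(n) / h2 else rep(Inf, n)
    ca <- if (length(admin_censor) == 1) rep(admin_censor, n) else admin_censor
    stopifnot(length(ca) == n, all(ca > 0))
    cr_ <- if (random_censor_rate > 0) rexp(n) / random_censor_rate else rep(Inf, n)
    tt <- pmin(t1, t2, ca, cr_)
    event <- ifelse(t1 <= tt, 1L, ifelse(t2 <= tt, 2L, 0L))
    dat <- tibble(id = seq_len(n), time = tt, event = event, x = x,
                  lp = beta1 * x)
    if (any(is.finite(ca))) dat$admin_censor_time <- ca
    for (h in horizons) {
      r <- switch(risk,
                  true_cif = true_cif_cause_specific(h, x, lambda1, lambda2,
                                                     beta1, beta2),
                  net = 1 - exp(-h1 * h))
      dat[[paste0("risk_", format_horizon(h), "y")]] <- pmin(r * risk_scale, 1)
    }
    out <- as_cohort(dat, horizons = horizons)
    attr(out, "truth") <- list(mechanism = "cause_specific",
                               lambda1 = lambda1, lambda2 = lambda2,
                               beta1 = beta1, beta2 = beta2, seed = seed,
                               risk = risk, risk_scale = risk_scale)
    out
  })
}

#' Closed-form cause-1 cumulative incidence under cause-specific hazards
#'
#' For exponential cause-specific hazards `h_k = lambda_k exp(beta_k x)`:
#' `F1(t; x) = h1 / (h1 + h2) * (1 - exp(-(h1 + h2) t))`.
#'
#' @param t Time(s), `>= 0`.
#' @param x Covariate value(s).
#' @inheritParams simulate_cause_specific
#' @return Cause-1 cumulative incidence, recycled over `t` and `x`.
#' @export
true_cif_cause_specific <- function(t, x, lambda1, lambda2, beta1 = 0,
                                    beta2 = 0) {
  if (any(t < 0)) abort("t must be >= 0")
  h1 <- lambda1 * exp(beta1 * x)
  h2 <- lambda2 * exp(beta2 * x)
  h <- h1 + h2
  ifelse(h > 0, h1 / h * (1 - exp(-h * t)), 0)
}

#' Simulate from the Fine-Gray subdistribution model
#'
#' Cause-1 times follow the subdistribution
#' `F1(t; x) = 1 - [1 - p (1 - exp(-t))]^exp(beta x)`, so `beta` is the
#' subdistribution log hazard ratio and is directly recoverable by
#' [fine_gray_fit()]. Cause 1 occurs with probability
#' `1 - (1 - p)^exp(beta x)`; the complementary mass is assigned to the
#' competing event, whose time is drawn from an independent exponential.
#'
#' @param n Cohort size.
#' @param p Baseline long-run cause-1 fraction, in (0, 1).
#' @param beta Subdistribution log hazard ratio per unit of `x`.
#' @param x Covariate vector, or `NULL` for standard normals.
#' @param cause2_rate Exponential rate of the competing-event times.
#' @inheritParams simulate_cause_specific
#' @return A `cr_cohort` (risk columns hold the true subdistribution CIF at
#'   each horizon); truth stored in the `truth` attribute.
#' @export
simulate_fine_gray <- function(n, p, beta = 0, x = NULL, cause2_rate = 1,
                               horizons = c(2, 5), admin_censor = Inf,
                               random_censor_rate = 0, seed = 1L) {
  if (p <= 0 || p >= 1) abort("p must lie in (0, 1)")
  if (n < 1) abort("n must be >= 1")
  withr_seed(seed, {
    if (is.null(x)) x <- rnorm(n)
    stopifnot(length(x) == n)
    ebx <- exp(beta * x)
    p1 <- 1 - (1 - p)^ebx
    is1 <- runif(n) < p1
    tt <- numeric(n)
    # invert F1(t; x) / P(cause 1 | x) at U ~ Unif(0, 1)
    u <- runif(sum(is1)) * p1[is1]
    tt[is1] <- -log(1 - (1 - (1 - u)^(1 / ebx[is1])) / p)
    tt[!is1] <- rexp(sum(!is1)) / cause2_rate
    cause <- ifelse(is1, 1L, 2L)
    ca <- if (length(admin_censor) == 1) rep(admin_censor, n) else admin_censor
    stopifnot(length(ca) == n, all(ca > 0))
    cr_ <- if (random_censor_rate > 0) rexp(n) / random_censor_rate else rep(Inf, n)
    cens <- pmin(ca, cr_)
    obs <- pmin(tt, cens)
    event <- ifelse(tt <= cens, cause, 0L)
    dat <- tibble(id = seq_len(n), time = obs, event = event, x = x,
                  lp = beta * x)
    if (any(is.finite(ca))) dat$admin_censor_time <- ca
    for (h in horizons) {
      dat[[paste0("risk_", format_horizon(h), "y")]] <-
        true_cif_fine_gray(h, x, p, beta)
    }
    out <- as_cohort(dat, horizons = horizons)
    attr(out, "truth") <- list(mechanism = "fine_gray", p = p, beta = beta,
                               cause2_rate = cause2_rate, seed = seed)
    out
  })
}

#' Closed-form cause-1 CIF under the Fine-Gray model
#' @inheritParams simulate_fine_gray
#' @param t Time(s), `>= 0`.
#' @param x Covariate value(s).
#' @export
true_cif_fine_gray <- function(t, x, p, beta = 0) {
  if (any(t < 0)) abort("t must be >= 0")
  1 - (1 - p * (1 - exp(-t)))^exp(beta * x)
}

#' Risk-equation configuration
#'
#' Holds the pieces of a published risk equation of the usual Cox form:
#' per-covariate coefficients, centering constants and a baseline survival
#' `S0(tau)` per horizon, with `risk = 1 - S0(tau)^exp(lp)` and
#' `lp = sum(coef * (covariate - center))`. No coefficients are shipped with
#' the package: values come from the model's publication via this
#' configuration (see [read_risk_config()]).
#'
#' @param coefficients Named numeric vector of coefficients.
#' @param centers Named numeric vector of centering constants (defaults to 0
#'   for every coefficient).
#' @param baseline_survival Named numeric vector: names are horizons (years),
#'   values `S0(tau)` in (0, 1\].
#' @return A `cr_risk_config` object.
#' @export
risk_config <- function(coefficients, centers = NULL, baseline_survival) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    abort("coefficients must be a fully named numeric vector")
  if (is.null(centers)) centers <- stats::setNames(rep(0, length(coefficients)),
                                                   names(coefficients))
  missing_c <- setdiff(names(coefficients), names(centers))
  centers[missing_c] <- 0
  if (is.null(names(baseline_survival)))
    abort("baseline_survival must be named by horizon")
  s0 <- as.numeric(baseline_survival)
  if (any(s0 <= 0 | s0 > 1)) abort("baseline survival must lie in (0, 1]")
  structure(list(coefficients = coefficients,
                 centers = centers[names(coefficients)],
                 baseline_survival = baseline_survival),
            class = "cr_risk_config")
}

#' Read a risk-equation configuration from JSON
#'
#' Expects top-level keys `coefficients`, optional `centers`, and
#' `baseline_survival` (an object keyed by horizon).
#'
#' @param path Path to a JSON file.
#' @return A `cr_risk_config`.
#' @export
read_risk_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$coefficients) || is.null(cfg$baseline_survival))
    abort("config must contain 'coefficients' and 'baseline_survival'")
  risk_config(unlist(cfg$coefficients),
              if (!is.null(cfg$centers)) unlist(cfg$centers) else NULL,
              unlist(cfg$baseline_survival))
}

#' Predicted risks from a risk-equation configuration
#'
#' @param covariates Data frame with one column per coefficient name.
#' @param config A [risk_config()].
#' @return Tibble with `lp` and one `risk_<h>y` column per configured
#'   horizon.
#' @export
predict_risk <- function(covariates, config) {
  if (!inherits(config, "cr_risk_config")) abort("config must be a cr_risk_config")
  nm <- names(config$coefficients)
  missing_cov <- setdiff(nm, names(covariates))
  if (length(missing_cov) > 0)
    abort(paste0("missing covariate(s): ", paste(missing_cov, collapse = ", ")))
  if (anyNA(covariates[nm]))
    abort("missing covariate values; imputation is out of scope, supply complete data")
  m <- as.matrix(covariates[nm])
  lp <- drop(sweep(m, 2, config$centers, "-") %*% config$coefficients)
  out <- tibble(lp = lp)
  for (h in names(config$baseline_survival)) {
    s0 <- config$baseline_survival[[h]]
    out[[paste0("risk_", format_horizon(as.numeric(h)), "y")]] <- 1 - s0^exp(lp)
  }
  out
}
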