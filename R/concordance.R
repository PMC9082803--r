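new_concordance <- function(counts, variant, n, tau = Inf,
                            conf_low = NA_real_, conf_high = NA_real_) {
  total <- counts$concordant + counts$discordant + counts$tied
  if (total <= 0) abort("no examinable pairs")
  structure(list(
    c = (counts$concordant + 0.5 * counts$tied) / total,
    conf_low = conf_low, conf_high = conf_high,
    n_concordant = counts$concordant, n_discordant = counts$discordant,
    n_tied = counts$tied, n_pairs = counts$n_pairs,
    variant = variant, n = n, tau = tau), class = "cr_concordance")
}

#' Harrell's C-index
#'
#' The proportion of examinable pairs in which the subject with the higher
#' predicted risk experiences the event sooner. A pair is examinable when the
#' smaller follow-up time belongs to an event; risk ties credit 0.5. Censored
#' subjects are treated as if they might still experience the outcome, which
#' is the naive treatment of competing events (map event code 2 to status 0
#' to reproduce it).
#'
#' @param time Follow-up times.
#' @param status 1 = event of interest, 0 = censored.
#' @param risk Predicted risks (any rank-equivalent score).
#' @param tau Optional truncation: only pairs whose anchor event time is
#'   `<= tau` are counted. Default `Inf`.
#' @return A `cr_concordance` object.
#' @export
harrell_c <- function(time, status, risk, tau = Inf) {
  stopifnot(length(time) == length(status), length(time) == length(risk))
  if (length(time) < 2) abort("need at least 2 subjects")
  if (!all(status %in% c(0, 1))) abort("status must be 0 or 1")
  counts <- concordance_pairs(as.numeric(time), as.integer(status),
                              logical(length(time)), as.numeric(risk),
                              tau, rep(1, length(time)), FALSE,
                              integer(length(time)))
  new_concordance(counts, "harrell", length(time), tau)
}

#' Wolbers' competing-risk adaptations of the C-index
#'
#' Subjects with a competing event are retained in the risk set instead of
#' being censored: either with follow-up set to infinity (they can never
#' experience the event of interest; requires follow-up complete apart from
#' administrative censoring), or — under purely administrative censoring
#' ("censoring complete") — censored at the administrative censoring date
#' they would have had.
#'
#' @param time Follow-up times.
#' @param event Event codes 0/1/2.
#' @param risk Predicted risks.
#' @param variant `"infinity"` or `"censoring_complete"`.
#' @param admin_censor_time Per-subject administrative censoring times;
#'   required (for competing-event subjects) under `"censoring_complete"`.
#' @param tau Optional truncation of anchor event times.
#' @return A `cr_concordance` object.
#' @export
wolbers_c <- function(time, event, risk,
                      variant = c("infinity", "censoring_complete"),
                      admin_censor_time = NULL, tau = Inf) {
  variant <- match.arg(variant)
  stopifnot(length(time) == length(event), length(time) == length(risk))
  if (!all(event %in% c(0, 1, 2))) abort("event codes must be 0, 1 or 2")
  n <- length(time)
  status <- as.integer(event == 1)
  if (variant == "infinity") {
    inf_flag <- event == 2
    t2 <- as.numeric(time)
  } else {
    comp <- event == 2
    if (any(comp) && (is.null(admin_censor_time) ||
                      anyNA(admin_censor_time[comp])))
      abort("censoring_complete variant needs admin_censor_time for every competing-event subject")
    inf_flag <- logical(n)
    t2 <- as.numeric(time)
    t2[comp] <- admin_censor_time[comp]
  }
  counts <- concordance_pairs(t2, status, inf_flag, as.numeric(risk), tau,
                              rep(1, n), FALSE, integer(n))
  new_concordance(counts, paste0("wolbers_", variant), n, tau)
}

#' Truncated IPCW C-index for the cause-1 cumulative incidence
#'
#' Concordance restricted to anchor events before the horizon `tau`, with
#' pairs reweighted by inverse censoring probabilities to recover the
#' pseudo-population that would have been observed without random censoring.
#' A pair is examinable when the anchor has a cause-1 event at `T_i <= tau`
#' and the partner either survives past `T_i` or has a competing event; the
#' pair weight is `1 / G(T_i-)^2`, the inverse censoring survival at the left
#' limit of the anchor's event time for both members (one published choice
#' among several). With no random censoring all weights are 1 and the
#' estimate equals [wolbers_c()] (infinity variant) truncated at `tau`.
#'
#' @param time Follow-up times.
#' @param event Event codes 0/1/2.
#' @param risk Predicted risks.
#' @param tau Truncation horizon (required).
#' @param cens Optional censoring-survival [cr_stepfun] (e.g. from
#'   [censoring_survival()]); estimated from `time`/`event` when `NULL`.
#' @return A `cr_concordance` object.
#' @export
ipcw_c <- function(time, event, risk, tau, cens = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  if (!all(event %in% c(0, 1, 2))) abort("event codes must be 0, 1 or 2")
  if (missing(tau) || !is.finite(tau)) abort("ipcw_c needs a finite truncation time tau")
  n <- length(time)
  if (is.null(cens)) cens <- censoring_survival(time, event)
  g_at <- eval_step(cens, pmin(time, tau), side = "left")
  anchor <- event == 1 & time <= tau
  if (any(anchor & g_at <= 0))
    abort("censoring survival reaches 0 before tau with weighted pairs remaining; truncate at an earlier tau")
  w <- ifelse(anchor, 1 / g_at^2, 0)
  counts <- concordance_pairs(as.numeric(time), as.integer(event == 1),
                              logical(n), as.numeric(risk), tau, w, TRUE,
                              as.integer(event == 2))
  new_concordance(counts, "ipcw", n, tau)
}

#' Concordance for a validation cohort
#'
#' Data-frame-first wrapper over the C-index variants, using the predicted
#' risks at a horizon (or the linear predictor) as the ranking score, with an
#' optional seeded nonparametric bootstrap interval.
#'
#' @param cohort A `cr_cohort`.
#' @param horizon Horizon whose risk column provides the ranking score
#'   (ignored when `use_lp = TRUE`); also the default `tau` for the IPCW
#'   variant.
#' @param variant One of `"harrell"`, `"wolbers_infinity"`,
#'   `"wolbers_censoring_complete"`, `"ipcw"`.
#' @param use_lp Rank by the `lp` column instead of the risk column.
#' @param tau Optional truncation of anchor event times.
#' @param boot Bootstrap replicates for the CI (0 = none).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return A `cr_concordance` object; see [tidy.cr_concordance()].
#' @export
concordance_cr <- function(cohort, horizon,
                           variant = c("harrell", "wolbers_infinity",
                                       "wolbers_censoring_complete", "ipcw"),
                           use_lp = FALSE, tau = NULL, boot = 0, seed = 1L,
                           conf_level = 0.95) {
  variant <- match.arg(variant)
  check_nonempty(cohort)
  risk <- if (use_lp) {
    if (!"lp" %in% names(cohort)) abort("cohort has no 'lp' column")
    cohort$lp
  } else {
    cohort[[risk_col(cohort, horizon)]]
  }
  one <- function(co, rk) {
    switch(variant,
      harrell = harrell_c(co$time, as.integer(co$event == 1), rk,
                          tau = tau %||% Inf),
      wolbers_infinity = wolbers_c(co$time, co$event, rk, "infinity",
                                   tau = tau %||% Inf),
      wolbers_censoring_complete = wolbers_c(co$time, co$event, rk,
                                             "censoring_complete",
                                             co$admin_censor_time,
                                             tau = tau %||% Inf),
      ipcw = ipcw_c(co$time, co$event, rk, tau = tau %||% horizon))
  }
  res <- one(cohort, risk)
  if (boot > 0) {
    n <- nrow(cohort)
    cs <- withr_seed(seed, vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(one(as_tibble(cohort)[idx, , drop = FALSE], risk[idx])$c,
               error = function(e) NA_real_)
    }, numeric(1)))
    alpha <- (1 - conf_level) / 2
    qs <- quantile(cs, c(alpha, 1 - alpha), na.rm = TRUE, type = 7)
    res$conf_low <- unname(qs[1])
    res$conf_high <- unname(qs[2])
  }
  res
}

#' @export
print.cr_concordance <- function(x, ...) {
  cat("C-index (", x$variant, "): ", sprintf("%.4f", x$c), sep = "")
  if (is.finite(x$conf_low))
    cat(sprintf(" (%.3f-%.3f)", x$conf_low, x$conf_high))
  cat("\n  pairs: ", format(x$n_pairs), " examinable; n = ", x$n, sep = "")
  if (is.finite(x$tau)) cat(", truncated at ", x$tau, sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy a concordance result
#' @param x A `cr_concordance`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, interval, variant and
#'   (weighted) pair counts.
#' @export
tidy.cr_concordance <- function(x, ...) {
  tibble(variant = x$variant, estimate = x$c, conf_low = x$conf_low,
         conf_high = x$conf_high, n_concordant = x$n_concordant,
         n_discordant = x$n_discordant, n_tied = x$n_tied,
         n_pairs = x$n_pairs, n = x$n)
}

#' @rdname tidy.cr_concordance
#' @export
glance.cr_concordance <- function(x, ...) tidy(x, ...)
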