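#' Construct a validation cohort
#'
#' A cohort is a tibble with one row per subject: a follow-up time in years,
#' an event code (0 = censored, 1 = event of interest, 2 = competing event)
#' and one predicted-risk column per prediction horizon. Optional columns hold
#' a linear predictor, an administrative censoring time and arbitrary
#' covariates used for subgroup analyses.
#'
#' Rows violating the field contracts (non-positive times, event codes outside
#' \{0, 1, 2\}, risks outside \[0, 1\]) are rejected with an error listing the
#' offending row numbers; nothing is silently dropped or imputed.
#'
#' @param data A data frame with one row per subject.
#' @param horizons Numeric vector of prediction horizons in years. If `NULL`,
#'   horizons are inferred from the names of the risk columns.
#' @param id,time,event Names of the identifier, follow-up time and event-code
#'   columns.
#' @param risk Named character vector mapping horizon (as character, e.g.
#'   `"2"`) to risk column name, or `NULL` to use columns named
#'   `paste0(risk_prefix, horizon, "y")`.
#' @param risk_prefix Prefix used to locate risk columns when `risk` is `NULL`.
#' @param lp Optional name of a linear-predictor column.
#' @param admin_censor_time Optional name of a column giving the follow-up a
#'   subject would have had if administratively censored.
#' @param event_codes Named vector mapping the input labels used for
#'   censored / event-of-interest / competing-event onto codes 0, 1, 2, e.g.
#'   `c(censored = 0, kidney_failure = 1, death = 2)` when `event` holds
#'   labels. Defaults to the identity coding 0/1/2.
#' @return A `cr_cohort` tibble with standardised columns `id`, `time`,
#'   `event`, one `risk_<h>y` column per horizon, and any extra columns from
#'   `data`; horizons are stored as an attribute.
#' @examples
#' df <- data.frame(id = 1:3, time = c(1, 2, 3), event = c(1, 0, 2),
#'                  risk_2y = c(0.2, 0.3, 0.4))
#' as_cohort(df, horizons = 2)
#' @export
as_cohort <- function(data, horizons = NULL, id = "id", time = "time",
                      event = "event", risk = NULL, risk_prefix = "risk_",
                      lp = NULL, admin_censor_time = NULL,
                      event_codes = NULL) {
  data <- as_tibble(data)
  need <- c(id, time, event, unname(risk), lp, admin_censor_time)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort schema error: column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }

  out <- data
  ren <- c(id = id, time = time, event = event)
  names(out)[match(ren, names(out))] <- names(ren)
  if (!is.null(lp) && lp != "lp") names(out)[names(out) == lp] <- "lp"
  if (!is.null(admin_censor_time) && admin_censor_time != "admin_censor_time")
    names(out)[names(out) == admin_censor_time] <- "admin_censor_time"

  if (!is.null(event_codes)) {
    lab <- as.character(out$event)
    if (!all(lab %in% names(event_codes))) {
      bad <- which(!lab %in% names(event_codes))
      abort(paste0("cohort validation error: unmapped event label(s) in row(s) ",
                   format_rows(bad)))
    }
    out$event <- unname(event_codes[lab])
  }
  out$event <- as.integer(out$event)

  # locate risk columns
  if (is.null(risk)) {
    if (is.null(horizons)) {
      rx <- paste0("^", risk_prefix, "([0-9.]+)y$")
      cand <- grep(rx, names(out), value = TRUE)
      if (length(cand) == 0) {
        abort("cohort schema error: no risk columns found and no horizons given")
      }
      horizons <- as.numeric(sub(rx, "\\1", cand))
      risk <- stats::setNames(cand, as.character(horizons))
    } else {
      risk <- stats::setNames(paste0(risk_prefix, horizons, "y"),
                              as.character(horizons))
      missing_cols <- setdiff(unname(risk), names(out))
      if (length(missing_cols) > 0) {
        abort(paste0("cohort schema error: risk column(s) not found: ",
                     paste(missing_cols, collapse = ", ")))
      }
    }
  } else {
    if (is.null(names(risk)) && !is.null(horizons) &&
        length(risk) == length(horizons)) {
      names(risk) <- as.character(horizons)
    }
    horizons <- as.numeric(names(risk))
  }
  horizons <- sort(horizons)
  risk <- risk[as.character(horizons)]
  std <- paste0("risk_", format_horizon(horizons), "y")
  names(out)[match(unname(risk), names(out))] <- std

  validate_cohort_fields(out, std)

  new_cohort(out, horizons = horizons)
}

format_horizon <- function(h) {
  vapply(h, function(x) format(x, trim = TRUE, scientific = FALSE), "")
}

risk_col <- function(cohort, horizon) {
  col <- paste0("risk_", format_horizon(horizon), "y")
  if (!col %in% names(cohort)) {
    abort(paste0("no predicted-risk column for horizon ", horizon,
                 " (expected column '", col, "')"))
  }
  col
}

format_rows <- function(idx, max_show = 10) {
  shown <- utils::head(idx, max_show)
  s <- paste(shown, collapse = ", ")
  if (length(idx) > max_show) s <- paste0(s, ", ... (", length(idx), " rows)")
  s
}

validate_cohort_fields <- function(out, risk_cols) {
  if (nrow(out) == 0) abort("cohort validation error: cohort is empty")
  problems <- character()
  bad <- which(!is.finite(out$time) | out$time <= 0)
  if (length(bad) > 0)
    problems <- c(problems, paste0("time must be > 0; offending row(s): ",
                                   format_rows(bad)))
  bad <- which(is.na(out$event) | !out$event %in% c(0L, 1L, 2L))
  if (length(bad) > 0)
    problems <- c(problems, paste0("event must be 0, 1 or 2; offending row(s): ",
                                   format_rows(bad)))
  for (rc in risk_cols) {
    r <- out[[rc]]
    bad <- which(!is.finite(r) | r < 0 | r > 1)
    if (length(bad) > 0)
      problems <- c(problems, paste0(rc, " must lie in [0, 1]; offending row(s): ",
                                     format_rows(bad)))
  }
  if ("admin_censor_time" %in% names(out)) {
    act <- out$admin_censor_time
    bad <- which(!is.na(act) & out$event %in% c(1L, 2L) & act < out$time)
    if (length(bad) > 0)
      problems <- c(problems, paste0(
        "admin_censor_time must be >= time for subjects with an event; ",
        "offending row(s): ", format_rows(bad)))
  }
  if (length(problems) > 0)
    abort(paste0("cohort validation error:\n  ",
                 paste(problems, collapse = "\n  ")))
  invisible(out)
}

new_cohort <- function(data, horizons) {
  structure(data,
            horizons = as.numeric(horizons),
            class = c("cr_cohort", class(as_tibble(data))))
}

#' @export
print.cr_cohort <- function(x, ...) {
  h <- attr(x, "horizons")
  cat("# A competing-risk validation cohort: ", nrow(x), " subjects, horizons ",
      paste(h, collapse = "/"), " years\n", sep = "")
  ev <- table(factor(x$event, levels = 0:2))
  cat("# events: ", ev[["1"]], " of interest, ", ev[["2"]], " competing, ",
      ev[["0"]], " censored\n", sep = "")
  NextMethod()
}

#' Horizons declared by a cohort
#' @param cohort A `cr_cohort`.
#' @return Numeric vector of prediction horizons (years).
#' @export
horizons <- function(cohort) attr(cohort, "horizons")

#' Read a cohort from a delimited text file
#'
#' Reads a header-ed delimited file (comma-separated by default) and validates
#' it into a [as_cohort()] cohort. Column names can be remapped through the
#' same arguments as `as_cohort()`.
#'
#' @param path Path to the file.
#' @param delim Field separator, default `","`.
#' @inheritParams as_cohort
#' @param ... Passed on to [as_cohort()].
#' @return A `cr_cohort` tibble.
#' @export
read_cohort <- function(path, horizons = NULL, delim = ",", ...) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  as_cohort(data, horizons = horizons, ...)
}

#' Write a cohort to a delimited text file
#'
#' @param cohort A `cr_cohort`.
#' @param path Output path.
#' @param delim Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  readr::write_delim(as_tibble(cohort), path, delim = delim)
  invisible(path)
}

#' Filter a cohort to a covariate-defined subgroup
#'
#' Keeps the rows whose covariate satisfies `op` against `value` (for example
#' the patients aged 70 or older), preserving row order and the cohort's
#' horizon metadata.
#'
#' @param cohort A `cr_cohort`.
#' @param covariate Name of a covariate column present on all records.
#' @param op Comparator: one of `">="`, `">"`, `"<="`, `"<"`, `"=="`, `"!="`.
#' @param value Threshold or level compared against.
#' @return The filtered `cr_cohort` (possibly empty).
#' @examples
#' coh <- as_cohort(data.frame(id = 1:3, time = 1:3, event = c(1, 0, 2),
#'                             risk_2y = c(.2, .3, .4), age = c(65, 70, 75)),
#'                  horizons = 2)
#' filter_subgroup(coh, "age", ">=", 70)
#' @export
filter_subgroup <- function(cohort, covariate, op = ">=", value) {
  if (!covariate %in% names(cohort)) {
    abort(paste0("unknown covariate: ", covariate))
  }
  op <- match.arg(op, c(">=", ">", "<=", "<", "==", "!="))
  x <- cohort[[covariate]]
  if (anyNA(x)) abort(paste0("covariate '", covariate, "' has missing values"))
  keep <- do.call(op, list(x, value))
  new_cohort(as_tibble(cohort)[keep, , drop = FALSE],
             horizons = attr(cohort, "horizons"))
}

check_nonempty <- function(cohort, what = "cohort") {
  if (nrow(cohort) == 0) abort(paste0(what, " is empty"))
  invisible(cohort)
}
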