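#' Two-way external validation report
#'
#' Runs every calibration and discrimination measure at every horizon in two
#' arms — "ignoring competing events by censoring" (KM observed
#' probabilities, Harrell's C, Cox-based D) and "taking competing events into
#' account" (Aalen-Johansen observed probabilities, a competing-risk C
#' variant, Fine-Gray-based D) — so the two columns can be contrasted
#' directly.
#'
#' @param cohort A `cr_cohort`.
#' @param horizons Horizons to validate (default: all declared by the
#'   cohort).
#' @param n_groups Risk groups for the grouped calibration.
#' @param c_variant Competing-risk C-index variant: default
#'   `"wolbers_censoring_complete"` when the cohort carries administrative
#'   censoring times (the right choice under purely administrative
#'   censoring), otherwise `"wolbers_infinity"`; `"ipcw"` truncates at the
#'   horizon and reweights by inverse censoring probabilities.
#' @param curve Compute pseudo-value smoothed calibration curves?
#' @param boot Bootstrap replicates for C and D intervals (0 = model-based /
#'   none).
#' @param seed Seed for any bootstrap resampling.
#' @param conf_level Confidence level throughout.
#' @return A `cr_validation` object: `metrics` (one row per horizon x metric
#'   x arm), `calibration` (per horizon x arm `cr_calibration` objects),
#'   `cif` (the Aalen-Johansen fit), and metadata. `tidy()` returns the
#'   metrics table; `autoplot()` draws the calibration plots.
#' @export
validate_model <- function(cohort, horizons = NULL, n_groups = 10,
                           c_variant = NULL, curve = TRUE, boot = 0,
                           seed = 1L, conf_level = 0.95) {
  check_nonempty(cohort)
  horizons <- horizons %||% attr(cohort, "horizons")
  if (is.null(horizons)) abort("no horizons declared or supplied")
  if (is.null(c_variant)) {
    c_variant <- if ("admin_censor_time" %in% names(cohort) &&
                     !anyNA(cohort$admin_censor_time))
      "wolbers_censoring_complete" else "wolbers_infinity"
  }
  c_variant <- match.arg(c_variant, c("wolbers_censoring_complete",
                                      "wolbers_infinity", "ipcw"))
  arms <- c(naive = "km", competing = "cif")
  metrics <- list()
  calib <- list()
  for (h in horizons) {
    rc <- risk_col(cohort, h)
    for (arm in names(arms)) {
      cal <- calibrate(cohort, h, method = arms[[arm]], n_groups = n_groups,
                       conf_level = conf_level,
                       curve = curve && arm == "competing")
      calib[[paste0(format_horizon(h), "y_", arm)]] <- cal
      cc <- concordance_cr(cohort, h,
                           variant = if (arm == "naive") "harrell" else c_variant,
                           use_lp = "lp" %in% names(cohort),
                           boot = boot, seed = seed, conf_level = conf_level)
      dd <- d_statistic(cohort, h,
                        engine = if (arm == "naive") "cox" else "fine_gray",
                        boot = boot, seed = seed, conf_level = conf_level)
      s <- cal$summary
      metrics[[length(metrics) + 1L]] <- tibble(
        horizon = h, arm = arm,
        metric = c("expected", "observed", "oe", "c", "d", "r2d"),
        estimate = c(s$expected, s$observed, s$oe, cc$c, dd$d, dd$r2d),
        conf_low = c(NA, attr(cal, "obs_low") %||% NA, s$conf_low,
                     cc$conf_low, dd$conf_low, NA),
        conf_high = c(NA, NA, s$conf_high, cc$conf_high, dd$conf_high, NA))
      # fill observed CI from the group-free observed probability
      op <- suppressWarnings(observed_probability(cohort, h, arms[[arm]],
                                                  conf_level))
      k <- length(metrics)
      metrics[[k]]$conf_low[2] <- op$conf_low
      metrics[[k]]$conf_high[2] <- op$conf_high
    }
  }
  ev2 <- vapply(horizons, function(h)
    sum(cohort$event == 1 & cohort$time <= h), numeric(1))
  dth <- vapply(horizons, function(h)
    sum(cohort$event == 2 & cohort$time <= h), numeric(1))
  structure(list(
    metrics = dplyr::bind_rows(metrics),
    calibration = calib,
    cif = aalen_johansen(cohort$time, cohort$event),
    meta = list(n = nrow(cohort), horizons = horizons,
                events_by_horizon = stats::setNames(ev2, horizons),
                competing_by_horizon = stats::setNames(dth, horizons),
                censored = sum(cohort$event == 0),
                c_variant_competing = c_variant, n_groups = n_groups,
                boot = boot, seed = seed, conf_level = conf_level)),
    class = "cr_validation")
}

#' @export
print.cr_validation <- function(x, ...) {
  m <- x$meta
  cat("External validation, n = ", m$n, " (", m$censored, " censored)\n",
      sep = "")
  for (i in seq_along(m$horizons)) {
    cat("  by ", m$horizons[i], "y: ", m$events_by_horizon[i],
        " events of interest, ", m$competing_by_horizon[i],
        " competing events\n", sep = "")
  }
  cat("  competing-risk C variant: ", m$c_variant_competing, "\n\n", sep = "")
  wide <- tidyr::pivot_wider(x$metrics[, c("horizon", "arm", "metric", "estimate")],
                             names_from = "arm", values_from = "estimate")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @describeIn validate_model Metrics table: one row per horizon x arm x
#'   metric with estimate and interval.
#' @param x,object A `cr_validation`.
#' @param ... Unused.
#' @export
tidy.cr_validation <- function(x, ...) x$metrics

#' @describeIn validate_model One-row cohort summary.
#' @export
glance.cr_validation <- function(x, ...) {
  m <- x$meta
  tibble(n = m$n, censored = m$censored,
         horizons = paste(m$horizons, collapse = "/"),
         c_variant = m$c_variant_competing)
}

#' @describeIn validate_model Calibration plots for every horizon and arm.
#' @export
autoplot.cr_validation <- function(object, ...) {
  groups <- purrr::imap_dfr(object$calibration, function(cal, nm) {
    dplyr::mutate(cal$groups, horizon = cal$horizon, arm = cal$method)
  })
  curves <- purrr::compact(purrr::map(object$calibration, function(cal) {
    if (is.null(cal$curve)) return(NULL)
    dplyr::mutate(cal$curve, horizon = cal$horizon, arm = cal$method)
  }))
  p <- ggplot2::ggplot(groups, ggplot2::aes(x = .data$predicted,
                                            y = .data$observed,
                                            colour = .data$arm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::facet_wrap(~horizon, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c(km = "#d95f02", cif = "#1b7837"),
                                 labels = c(km = "Ignoring competing events",
                                            cif = "Accounting for competing events")) +
    ggplot2::labs(x = "Predicted risk", y = "Observed probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (length(curves) > 0) {
    p <- p + ggplot2::geom_line(data = dplyr::bind_rows(curves))
  }
  p
}

#' Write a validation report to disk
#'
#' Writes `metrics.csv` (one row per horizon x arm x metric, mirroring the
#' two-column naive / competing-risk layout), `calibration_groups.csv`,
#' `calibration_curve.csv`, `cif_curves.csv` and a `report.json` run summary.
#' Numeric values round-trip exactly through the CSVs.
#'
#' @param report A `cr_validation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(report, dir) {
  if (!inherits(report, "cr_validation")) abort("report must be a cr_validation")
  if (nrow(report$metrics) == 0) abort("empty metric set; nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  groups <- purrr::map_dfr(report$calibration, function(cal)
    dplyr::mutate(cal$groups, horizon = cal$horizon, arm = cal$method,
                  .before = 1))
  readr::write_csv(groups, file.path(dir, "calibration_groups.csv"))
  curves <- purrr::map_dfr(report$calibration, function(cal) {
    if (is.null(cal$curve)) return(NULL)
    dplyr::mutate(cal$curve, horizon = cal$horizon, arm = cal$method,
                  .before = 1)
  })
  readr::write_csv(curves, file.path(dir, "calibration_curve.csv"))
  readr::write_csv(tidy(report$cif), file.path(dir, "cif_curves.csv"))
  meta <- report$meta
  meta$events_by_horizon <- as.list(meta$events_by_horizon)
  meta$competing_by_horizon <- as.list(meta$competing_by_horizon)
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
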