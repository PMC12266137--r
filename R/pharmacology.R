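## Screen analytics: 2^-ddCt expression quantification, serial dilution
## design, threshold hit calling, and absolute EC50/IC50 estimation by
## constrained four-parameter logistic least squares.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per sample before calibration.
#' dCt = Ct(target) - Ct(housekeeping) per sample; ddCt subtracts the
#' mean dCt of the calibrator condition; fold change = 2^-ddCt, also
#' reported as percent of calibrator.
#'
#' @param measurements data frame with columns `sample_id`, `condition`,
#'   `ct_target`, `ct_housekeeping` (and optionally `replicate`). Ct
#'   values must be positive and below the 40-cycle assay ceiling.
#' @param calibrator_condition condition used as the calibrator (e.g.
#'   mock treatment); must be present.
#' @return data frame per sample: `sample_id`, `condition`, `delta_ct`,
#'   `ddct`, `fold_change`, `percent_of_calibrator`.
#' @export
ddct_fold_change <- function(measurements, calibrator_condition) {
  need <- c("sample_id", "condition", "ct_target", "ct_housekeeping")
  stopifnot(all(need %in% names(measurements)))
  ct <- c(measurements$ct_target, measurements$ct_housekeeping)
  if (any(is.na(ct)) || any(ct <= 0) || any(ct >= 40)) {
    stop("Ct values must be positive and below the 40-cycle ceiling")
  }
  if (!calibrator_condition %in% measurements$condition) {
    stop("calibrator condition '", calibrator_condition,
         "' not present in the measurements")
  }
  ## average technical replicates per sample
  agg <- stats::aggregate(
    cbind(ct_target, ct_housekeeping) ~ sample_id + condition,
    data = measurements, FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_housekeeping
  cal <- mean(agg$delta_ct[agg$condition == calibrator_condition])
  agg$ddct <- agg$delta_ct - cal
  agg$fold_change <- 2^(-agg$ddct)
  agg$percent_of_calibrator <- 100 * agg$fold_change
  agg[order(agg$condition, agg$sample_id),
      c("sample_id", "condition", "delta_ct", "ddct", "fold_change",
        "percent_of_calibrator")]
}

#' Geometric serial dilution series
#'
#' @param start highest dose (> 0).
#' @param factor dilution factor (> 1).
#' @param points number of doses (>= 1).
#' @return numeric vector `start / factor^(0:(points-1))`, descending
#'   (e.g. a five-point four-fold series from 20 gives a 0.078--20
#'   range).
#' @export
serial_dilution <- function(start, factor, points) {
  stopifnot(start > 0, factor > 1, points >= 1)
  start / factor^(seq_len(points) - 1L)
}

#' Call screen hits above an expression threshold
#'
#' Hits are candidates whose percent-of-mock expression strictly exceeds
#' `threshold_percent` (e.g. > 125 for the single-dose screen, > 140 at
#' the top dose of a dose-response screen). Negative controls are
#' excluded from the hit set by id; a control exceeding the threshold
#' triggers a warning since it indicates an assay problem.
#'
#' @param fold_changes named numeric vector of percent-of-mock values,
#'   or a data frame with `aso_id`, `dose`, `response` (in which case
#'   `at_dose` selects the dose level and replicates are averaged).
#' @param threshold_percent strict threshold.
#' @param at_dose dose level for data-frame input; an error is raised if
#'   absent from the table.
#' @param controls ids of negative controls (never hits).
#' @return character vector of hit ids.
#' @export
call_hits <- function(fold_changes, threshold_percent, at_dose = NULL,
                      controls = character(0)) {
  if (is.data.frame(fold_changes)) {
    stopifnot(all(c("aso_id", "dose", "response") %in%
                    names(fold_changes)))
    if (is.null(at_dose)) {
      stop("at_dose must be given for dose-response input")
    }
    sel <- abs(fold_changes$dose - at_dose) < 1e-9
    if (!any(sel)) {
      stop("dose level ", at_dose, " not present in the table")
    }
    agg <- stats::aggregate(response ~ aso_id,
                            data = fold_changes[sel, , drop = FALSE],
                            FUN = mean)
    values <- stats::setNames(agg$response, agg$aso_id)
  } else {
    values <- fold_changes
  }
  over <- names(values)[values > threshold_percent]
  bad_controls <- intersect(over, controls)
  if (length(bad_controls) > 0L) {
    warning("negative control(s) above threshold: ",
            paste(bad_controls, collapse = ", "), call. = FALSE)
  }
  setdiff(over, controls)
}

## four-parameter logistic in log-dose space; increasing for
## stimulation, decreasing for inhibition
.fpl <- function(logx, logec50, hill, bottom, top, increasing) {
  f <- 1 / (1 + exp(hill * (logec50 - logx)))
  if (!increasing) f <- 1 - f
  bottom + (top - bottom) * f
}

#' Fit a dose-response curve and report the absolute EC50/IC50
#'
#' Stimulation curves arrive on the raw percent-of-mock scale; the
#' baseline (100, the mock level) is subtracted before fitting, so the
#' adjusted response spans roughly 0--100 (values below mock appear as
#' negative and are retained). Inhibition curves are fitted on the raw
#' percent-of-mock scale directly. The normalized variable-slope
#' logistic `y = 100 / (1 + (EC50/x)^h)` (decreasing form for
#' inhibition) is fitted by Levenberg-Marquardt least squares with a
#' multi-start grid of log-spaced EC50 initial values; the reported
#' absolute EC50/IC50 is the dose at which the fitted curve crosses 50
#' on the 0--100 normalized span, which for this symmetric model equals
#' the EC50 parameter itself. With `span = "free"` the bottom and top
#' asymptotes are fitted as well (a full four-parameter logistic).
#'
#' @param table a `dose_table` data frame (`dose`, `response`, optional
#'   `aso_id`, `replicate`).
#' @param mode `"stimulation"` (EC50) or `"inhibition"` (IC50); defaults
#'   to the table's `mode` attribute when present.
#' @param baseline percent-of-mock baseline subtracted in stimulation
#'   mode.
#' @param span `"normalized"` (default) fixes the response span at
#'   0--100, the normalized-response model with two free parameters
#'   (EC50, Hill); `"free"` additionally fits the bottom and top
#'   asymptotes for data whose plateau is not known a priori.
#' @param replicate_means fit dose-level replicate means instead of the
#'   pooled individual points.
#' @return a `dose_response_fit`: `aso_id`, `mode`, `ec50_or_ic50`,
#'   `hill`, `bottom`, `top`, `r_squared`, `converged`, `extrapolated`
#'   (EC50 outside the fitted dose span), `baseline_adjusted`, `rss`.
#'   Non-convergence is reported via `converged = FALSE`, never
#'   silently.
#' @export
fit_dose_response <- function(table, mode = NULL, baseline = 100,
                              span = c("normalized", "free"),
                              replicate_means = FALSE) {
  if (is.null(mode)) mode <- attr(table, "mode")
  mode <- match.arg(mode, c("stimulation", "inhibition"))
  span <- match.arg(span)
  stopifnot(all(c("dose", "response") %in% names(table)))
  if (length(unique(table$dose)) < 2L) {
    stop("at least 2 distinct doses are required for fitting")
  }
  if (length(unique(table$dose)) < 4L) {
    warning("fewer than 4 dose levels: the fit may be poorly constrained",
            call. = FALSE)
  }
  x <- table$dose
  y <- table$response
  if (mode == "stimulation") y <- y - baseline
  if (replicate_means) {
    agg <- stats::aggregate(y, by = list(dose = x), FUN = mean)
    x <- agg$dose
    y <- agg$x
  }
  logx <- log(x)
  increasing <- mode == "stimulation"

  ## multi-start over log-spaced EC50 initials; hill kept positive by a
  ## box constraint (direction is carried by the model form, not the
  ## slope sign)
  starts_ec <- seq(min(logx), max(logx), length.out = 7L)
  starts_h <- c(0.5, 1, 2)
  amp <- max(abs(y), 1)
  b0 <- min(y)
  t0 <- max(y)
  best <- NULL
  dat <- data.frame(logx = logx, y = y)
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  for (le in starts_ec) {
    for (h in starts_h) {
      fit <- tryCatch(suppressWarnings(
        if (span == "normalized") {
          minpack.lm::nlsLM(
            y ~ .fpl(logx, logec50, hill, 0, 100, increasing),
            data = dat, start = list(logec50 = le, hill = h),
            lower = c(logec50 = min(logx) - log(1e4), hill = 1e-3),
            upper = c(logec50 = max(logx) + log(1e4), hill = 100),
            control = ctl)
        } else {
          minpack.lm::nlsLM(
            y ~ .fpl(logx, logec50, hill, bottom, top, increasing),
            data = dat,
            start = list(logec50 = le, hill = h, bottom = b0, top = t0),
            lower = c(logec50 = min(logx) - log(1e4), hill = 1e-3,
                      bottom = -1e4 * amp, top = -1e4 * amp),
            upper = c(logec50 = max(logx) + log(1e4), hill = 100,
                      bottom = 1e4 * amp, top = 1e4 * amp),
            control = ctl)
        }),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  aso_id <- if ("aso_id" %in% names(table)) table$aso_id[1] else NA_character_
  if (is.null(best)) {
    return(structure(
      list(aso_id = aso_id, mode = mode, ec50_or_ic50 = NA_real_,
           hill = NA_real_, bottom = NA_real_, top = NA_real_,
           span = span, r_squared = NA_real_, converged = FALSE,
           extrapolated = NA, baseline_adjusted = mode == "stimulation",
           rss = NA_real_,
           diagnostics = "no start converged"),
      class = "dose_response_fit"))
  }
  cf <- stats::coef(best$fit)
  ec50 <- exp(cf[["logec50"]])
  tss <- sum((y - mean(y))^2)
  bottom <- if (span == "normalized") 0 else cf[["bottom"]]
  top <- if (span == "normalized") 100 else cf[["top"]]
  structure(
    list(aso_id = aso_id, mode = mode, ec50_or_ic50 = ec50,
         hill = cf[["hill"]], bottom = bottom, top = top,
         span = span,
         r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
         converged = TRUE,
         extrapolated = ec50 < min(x) || ec50 > max(x),
         baseline_adjusted = mode == "stimulation",
         rss = best$rss, diagnostics = NULL),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lab <- if (x$mode == "stimulation") "EC50" else "IC50"
  if (x$converged) {
    cat(sprintf(
      "%s fit (%s): %s = %.4g, hill = %.3g, span [%.3g, %.3g], R^2 = %.4f%s\n",
      x$mode, ifelse(is.na(x$aso_id), "?", x$aso_id), lab, x$ec50_or_ic50,
      x$hill, x$bottom, x$top, x$r_squared,
      if (isTRUE(x$extrapolated)) " (extrapolated)" else ""))
  } else {
    cat(sprintf("%s fit did not converge: %s\n", x$mode, x$diagnostics))
  }
  invisible(x)
}

#' Predicted response of a fitted dose-response curve
#'
#' @param fit a `dose_response_fit`.
#' @param dose dose vector.
#' @param normalized return the response on the 0--100 normalized span
#'   instead of the fitted scale (50 at the absolute EC50 by
#'   definition).
#' @return numeric vector of predicted responses.
#' @export
predict_dose_response <- function(fit, dose, normalized = FALSE) {
  stopifnot(inherits(fit, "dose_response_fit"), fit$converged)
  y <- .fpl(log(dose), log(fit$ec50_or_ic50), fit$hill, fit$bottom,
            fit$top, fit$mode == "stimulation")
  if (normalized) {
    y <- 100 * (y - fit$bottom) / (fit$top - fit$bottom)
  }
  y
}
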