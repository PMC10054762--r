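# Calibration fitting, back-calculation, per-level linearity summaries and
# LOD/LOQ from the dispersion of intercepts across replicate curves.
# The unweighted least-squares kernel here is shared with the depletion
# fit in the stability module.

#' Unweighted least-squares line fit
#'
#' The single regression kernel used for both the calibration line
#' (response ratio vs nominal concentration) and the ln-linear depletion fit
#' (ln % remaining vs time). Ordinary least squares with no weighting; r2 is
#' the regression sum of squares over the total sum of squares.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A list with `slope`, `intercept`, `r2`, `n`, `residual_sd`,
#'   `intercept_se` (standard error of the intercept from the single fit).
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("at least 2 points are required", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("singular design: all x values identical", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  # numerical guard: exact fits can land a hair above 1 in floating point
  r2 <- min(max(r2, 0), 1)
  residual_sd <- if (n > 2) sqrt(sum(stats::resid(fit)^2) / (n - 2)) else 0
  intercept_se <- if (n > 2)
    suppressWarnings(
      summary(fit)$coefficients["(Intercept)", "Std. Error"]) else NA_real_
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r2 = r2, n = n,
       residual_sd = residual_sd, intercept_se = intercept_se)
}

#' Fit a calibration line to standard measurements
#'
#' Ordinary (unweighted) least squares of the analyte/IS peak-area ratio on
#' nominal concentration. By default replicate ratios are averaged to one
#' ratio per level before fitting, mirroring the practice of fitting one
#' line per injected curve; set `average_replicates = FALSE` to fit all
#' individual points.
#'
#' @param standards A `measurement_table` of `standard` rows (other roles are
#'   ignored) covering at least two distinct nominal levels.
#' @param average_replicates Average replicate ratios per level first?
#' @return An object of class `calibration_fit`: `slope`, `intercept`, `r2`,
#'   `n_points`, `residual_sd`, `intercept_se`.
#' @examples
#' std <- simulate_calibration(calibration_sim_params())
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, average_replicates = TRUE) {
  standards <- as_measurement_table(as.data.frame(standards))
  std <- standards[standards$role == "standard", , drop = FALSE]
  if (nrow(std) == 0) stop("no standard rows present", call. = FALSE)
  if (length(unique(std$nominal_conc)) < 2)
    stop("insufficient data: need >= 2 distinct nominal levels",
         call. = FALSE)
  ratio <- area_ratio(std)
  if (average_replicates) {
    agg <- stats::aggregate(ratio, by = list(nominal = std$nominal_conc),
                            FUN = mean)
    x <- agg$nominal; y <- agg$x
  } else {
    x <- std$nominal_conc; y <- ratio
  }
  k <- ols_fit(x, y)
  structure(list(slope = k$slope, intercept = k$intercept, r2 = k$r2,
                 n_points = k$n, residual_sd = k$residual_sd,
                 intercept_se = k$intercept_se),
            class = "calibration_fit")
}

#' Fit one calibration line per batch
#'
#' Splits the standards by `batch_id` (one injected curve per batch) and fits
#' each curve separately, for use with [lod_loq()].
#'
#' @inheritParams fit_calibration
#' @return A list of `calibration_fit` objects, one per batch.
#' @export
fit_calibration_curves <- function(standards, average_replicates = TRUE) {
  standards <- as_measurement_table(as.data.frame(standards))
  std <- standards[standards$role == "standard", , drop = FALSE]
  if (nrow(std) == 0) stop("no standard rows present", call. = FALSE)
  batches <- unique(std$batch_id)
  lapply(batches, function(b)
    fit_calibration(std[std$batch_id == b, , drop = FALSE],
                    average_replicates = average_replicates))
}

#' Back-calculate a concentration from a response ratio
#'
#' Inverts the calibration line: `(ratio - intercept) / slope`. Values may be
#' negative for responses below the fitted intercept; callers decide how to
#' flag results below the limit of detection.
#'
#' @param fit A `calibration_fit`.
#' @param ratio Numeric vector of analyte/IS response ratios.
#' @return Back-calculated concentrations (ng/mL).
#' @export
back_calculate <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.finite(fit$slope) || fit$slope == 0)
    stop("degenerate fit: zero slope", call. = FALSE)
  (ratio - fit$intercept) / fit$slope
}

#' Per-level back-calculation summary
#'
#' Accuracy, precision and recovery of back-calculated concentrations at one
#' nominal level: mean, sample SD (n-1 denominator), %RSD = 100 SD/mean,
#' accuracy (% error) = 100 (mean - nominal)/nominal and recovery =
#' 100 mean/nominal. Recovery and accuracy differ by exactly 100 by
#' construction.
#'
#' @param back_calcs Numeric vector (>= 2) of back-calculated concentrations.
#' @param nominal Nominal concentration (ng/mL), > 0.
#' @return An object of class `level_summary` (also a one-row data frame)
#'   with columns `nominal`, `mean_back_calc`, `sd`, `rsd_pct`,
#'   `accuracy_pct`, `recovery_pct`.
#' @export
summarize_level <- function(back_calcs, nominal) {
  if (length(back_calcs) < 2)
    stop("insufficient replicates: need >= 2 values", call. = FALSE)
  stopifnot(nominal > 0)
  m <- mean(back_calcs)
  s <- stats::sd(back_calcs)
  out <- data.frame(nominal = nominal,
                    mean_back_calc = m,
                    sd = s,
                    rsd_pct = 100 * s / m,
                    accuracy_pct = 100 * (m - nominal) / nominal,
                    recovery_pct = 100 * m / nominal)
  class(out) <- c("level_summary", "data.frame")
  out
}

#' Linearity table across all calibration levels
#'
#' Back-calculates every standard through the fitted line and summarises each
#' nominal level with [summarize_level()], pooling replicates across curves.
#'
#' @param standards A `measurement_table` of standard rows.
#' @param fit A `calibration_fit`; fitted from `standards` if omitted.
#' @return A data frame with one row per level.
#' @export
summarize_levels <- function(standards, fit = NULL) {
  standards <- as_measurement_table(as.data.frame(standards))
  std <- standards[standards$role == "standard", , drop = FALSE]
  if (is.null(fit)) fit <- fit_calibration(std)
  bc <- back_calculate(fit, area_ratio(std))
  levels <- sort(unique(std$nominal_conc))
  out <- do.call(rbind, lapply(levels, function(lv)
    summarize_level(bc[std$nominal_conc == lv], lv)))
  rownames(out) <- NULL
  out
}

#' Limits of detection and quantification
#'
#' Computed from the dispersion of intercepts across replicate calibration
#' curves: LOD = 3.3 SD(intercept)/slope and LOQ = 10 SD(intercept)/slope,
#' with the slope taken as the mean of the per-curve slopes. The LOQ/LOD
#' ratio is 10/3.3 by construction.
#'
#' @param fits A list of at least two `calibration_fit` objects (one per
#'   curve). With a single fit the intercept standard error of that fit can
#'   be substituted via `use_intercept_se = TRUE` (non-default fallback).
#' @param use_intercept_se Use the single-fit intercept SE instead of the
#'   across-curve SD (requires exactly one fit).
#' @return A list with `lod`, `loq` (ng/mL), `sd_intercept`, `slope`,
#'   `n_curves`.
#' @export
lod_loq <- function(fits, use_intercept_se = FALSE) {
  if (inherits(fits, "calibration_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "calibration_fit")))
  if (use_intercept_se) {
    if (length(fits) != 1)
      stop("use_intercept_se applies to a single fit", call. = FALSE)
    sd_int <- fits[[1]]$intercept_se
    if (!is.finite(sd_int))
      stop("intercept SE unavailable for this fit", call. = FALSE)
    slope <- fits[[1]]$slope
    n_curves <- 1L
  } else {
    if (length(fits) < 2)
      stop("insufficient curves: need >= 2 calibration fits", call. = FALSE)
    sd_int <- stats::sd(vapply(fits, `[[`, numeric(1), "intercept"))
    slope <- mean(vapply(fits, `[[`, numeric(1), "slope"))
    n_curves <- length(fits)
  }
  list(lod = 3.3 * sd_int / slope, loq = 10 * sd_int / slope,
       sd_intercept = sd_int, slope = slope, n_curves = n_curves)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit: ratio = %.6g x + %.6g (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_points))
  invisible(x)
}
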