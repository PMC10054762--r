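# Metabolic-stability kinetics: percent-remaining normalization, log-linear
# phase selection, first-order rate fit, in vitro half-life, intrinsic
# clearance (whole-body and per-mg units) and clearance classification.

#' Normalize a depletion time course to percent remaining
#'
#' Averages replicate concentrations per stop time, normalizes each mean to
#' the time-zero mean (percent remaining; 100 at t = 0 by construction) and
#' takes natural logs.
#'
#' @param timecourse Data frame with columns `time_min`, `conc` and
#'   optionally `replicate_id` (see [read_timecourse_table()]).
#' @return An object of class `depletion_timecourse`: a data frame with
#'   `time_min`, `mean_conc`, `pct_remaining`, `ln_pct_remaining`, times
#'   strictly increasing.
#' @examples
#' tc <- simulate_depletion(depletion_sim_params())
#' percent_remaining(tc)
#' @export
percent_remaining <- function(timecourse) {
  tc <- as_timecourse_table(as.data.frame(timecourse))
  agg <- stats::aggregate(conc ~ time_min, data = tc, FUN = mean)
  agg <- agg[order(agg$time_min), , drop = FALSE]
  if (agg$time_min[1] != 0)
    stop("normalization error: time course must contain t = 0",
         call. = FALSE)
  c0 <- agg$conc[1]
  if (c0 <= 0)
    stop("degenerate baseline: mean concentration at t = 0 must be > 0",
         call. = FALSE)
  out <- data.frame(time_min = agg$time_min,
                    mean_conc = agg$conc,
                    pct_remaining = 100 * agg$conc / c0)
  out$ln_pct_remaining <- log(out$pct_remaining)
  rownames(out) <- NULL
  class(out) <- c("depletion_timecourse", "data.frame")
  out
}

#' Select the log-linear depletion phase
#'
#' Manual mode keeps every point inside the given time window. Auto mode
#' keeps the longest prefix of time points anchored at t = 0 whose ln-linear
#' fit reaches `r2_floor` (ties broken toward more points); prefixes shorter
#' than `min_points` are not considered. Anchoring at the baseline prevents
#' cherry-picked interior windows.
#'
#' @param tc A `depletion_timecourse` from [percent_remaining()].
#' @param mode `"manual"` (requires `window`) or `"auto"`.
#' @param window Length-2 numeric `(t_start, t_end)` in minutes, manual mode.
#' @param min_points Minimum number of points in the selected phase.
#' @param r2_floor Minimum r2 a qualifying prefix must reach (auto mode).
#' @return The subset of `tc` rows forming the selected phase, with
#'   attribute `window` recording the time span used.
#' @export
select_linear_phase <- function(tc, mode = c("manual", "auto"),
                                window = NULL, min_points = 4,
                                r2_floor = 0.99) {
  stopifnot(inherits(tc, "depletion_timecourse"))
  mode <- match.arg(mode)
  tc <- tc[order(tc$time_min), , drop = FALSE]
  if (mode == "manual") {
    if (is.null(window) || length(window) != 2)
      stop("manual mode requires window = c(t_start, t_end)", call. = FALSE)
    keep <- tc$time_min >= window[1] & tc$time_min <= window[2]
    out <- tc[keep, , drop = FALSE]
    if (nrow(out) < 2)
      stop("selected window contains fewer than 2 points", call. = FALSE)
    attr(out, "window") <- c(window[1], window[2])
    return(out)
  }
  n <- nrow(tc)
  if (n < min_points)
    stop("auto mode requires at least min_points time points", call. = FALSE)
  best <- 0L
  for (k in seq(min_points, n)) {
    f <- ols_fit(tc$time_min[1:k], tc$ln_pct_remaining[1:k])
    if (f$r2 >= r2_floor) best <- k
  }
  if (best == 0L)
    stop("no linear phase found: no prefix of >= ", min_points,
         " points reaches r2 = ", r2_floor,
         "; consider manual window selection", call. = FALSE)
  out <- tc[1:best, , drop = FALSE]
  attr(out, "window") <- c(tc$time_min[1], tc$time_min[best])
  out
}

#' Fit the first-order depletion line
#'
#' Unweighted least squares of ln(% remaining) on time over the selected
#' phase, through the same regression kernel as the calibration fit. Two
#' points are accepted with a warning (r2 is 1 by construction).
#'
#' @param subset A `depletion_timecourse` subset (>= 3 points recommended).
#' @return A list with `slope` (per minute, negative for depletion),
#'   `intercept` (ln % scale), `r2`, `n`.
#' @export
fit_depletion <- function(subset) {
  stopifnot(is.data.frame(subset))
  if (nrow(subset) < 2)
    stop("need at least 2 points to fit", call. = FALSE)
  if (nrow(subset) == 2)
    warning("degenerate fit through 2 points; r2 forced to 1",
            call. = FALSE)
  f <- ols_fit(subset$time_min, subset$ln_pct_remaining)
  list(slope = f$slope, intercept = f$intercept, r2 = f$r2, n = f$n)
}

#' In vitro half-life from the depletion slope
#'
#' `t1/2 = ln 2 / |slope|` for a negative (depleting) slope. Setting
#' `slope_digits` rounds the slope first, reproducing hand calculations done
#' from a slope printed at fixed precision.
#'
#' @param slope Fitted ln-linear slope (per minute), < 0.
#' @param slope_digits Optional number of decimals to round the slope to
#'   before inverting (default: full precision).
#' @return Half-life in minutes.
#' @export
half_life <- function(slope, slope_digits = NULL) {
  if (!is.finite(slope) || slope >= 0)
    stop("no depletion: slope must be negative (substrate stable, ",
         "half-life undefined)", call. = FALSE)
  if (!is.null(slope_digits)) slope <- round(slope, slope_digits)
  log(2) / abs(slope)
}

#' Intrinsic clearance from the in vitro half-life
#'
#' Scales the depletion rate to whole-body intrinsic clearance
#' (`0.693 / t1/2` times incubation volume per mg microsomal protein, mg
#' protein per g liver, and g liver per kg body weight) and also reports the
#' per-mg-protein value in uL/min/mg. Under the default constants the two
#' differ by the fixed factor 45 x 26 / 1000 = 1.17.
#'
#' @param t_half In vitro half-life (minutes), > 0.
#' @param design A [study_design()] supplying the scaling constants.
#' @return A list with `clint_ml_min_kg` and `clint_ul_min_mg`.
#' @export
intrinsic_clearance <- function(t_half, design = study_design()) {
  if (!is.finite(t_half) || t_half <= 0)
    stop("t_half must be > 0", call. = FALSE)
  per_mg <- 0.693 / t_half *
    design$incubation_volume_mL / design$microsomal_protein_mg
  list(clint_ml_min_kg = per_mg * design$mg_protein_per_g_liver *
         design$g_liver_per_kg_bw,
       clint_ul_min_mg = 1000 * per_mg)
}

#' Clearance bands
#'
#' Cut-points for the low/intermediate/high classification of whole-body
#' intrinsic clearance, in mL/min/kg. Defaults: low below 15, high above 45,
#' intermediate between. Fully overridable; published scoring schemes vary.
#'
#' @param low_max Upper bound of the low class (exclusive).
#' @param high_min Lower bound of the high class (exclusive).
#' @return A list with `low_max`, `high_min`.
#' @export
clearance_bands <- function(low_max = 15, high_min = 45) {
  if (!is.finite(low_max) || !is.finite(high_min) || low_max >= high_min)
    stop("malformed bands: need low_max < high_min", call. = FALSE)
  list(low_max = low_max, high_min = high_min)
}

#' Classify intrinsic clearance
#'
#' @param clint_ml_min_kg Whole-body intrinsic clearance (mL/min/kg).
#' @param bands A [clearance_bands()] object.
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
classify_clearance <- function(clint_ml_min_kg, bands = clearance_bands()) {
  stopifnot(is.finite(clint_ml_min_kg))
  if (clint_ml_min_kg < bands$low_max) "low"
  else if (clint_ml_min_kg > bands$high_min) "high"
  else "intermediate"
}

#' End-to-end metabolic-stability assessment
#'
#' Normalizes a raw time course, selects the log-linear phase, fits the
#' first-order rate, and derives half-life, intrinsic clearance and the
#' clearance class.
#'
#' @param timecourse Data frame with `time_min`, `conc`, `replicate_id`.
#' @param design A [study_design()].
#' @param mode Phase selection mode, `"manual"` or `"auto"`.
#' @param window Manual window, default `c(0, 30)` minutes.
#' @param min_points,r2_floor Auto-mode controls (see
#'   [select_linear_phase()]).
#' @param rounding `"full"` carries full precision through the chain;
#'   `"printed"` rounds the slope to 4 decimals before the half-life and the
#'   half-life to 2 decimals before the clearance, matching hand arithmetic
#'   on values printed at those precisions.
#' @param bands A [clearance_bands()] object.
#' @return An object of class `stability_result`: window, slope, intercept,
#'   r2, `k_dep` (= |slope|), `t_half_min`, `clint_ml_min_kg`,
#'   `clint_ul_min_mg`, `clearance_class`, plus the normalized time course.
#' @examples
#' tc <- simulate_depletion(depletion_sim_params(plateau_fraction = 0))
#' assess_stability(tc)
#' @export
assess_stability <- function(timecourse, design = study_design(),
                             mode = c("manual", "auto"), window = c(0, 30),
                             min_points = 4, r2_floor = 0.99,
                             rounding = c("full", "printed"),
                             bands = clearance_bands()) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  tc <- percent_remaining(timecourse)
  phase <- select_linear_phase(tc, mode = mode, window = window,
                               min_points = min_points, r2_floor = r2_floor)
  fit <- fit_depletion(phase)
  slope_digits <- if (rounding == "printed") 4 else NULL
  th <- half_life(fit$slope, slope_digits = slope_digits)
  th_for_cl <- if (rounding == "printed") round(th, 2) else th
  cl <- intrinsic_clearance(th_for_cl, design)
  structure(list(window = attr(phase, "window"),
                 slope = fit$slope, intercept_ln = fit$intercept,
                 r2 = fit$r2, n_points = fit$n,
                 k_dep = abs(fit$slope),
                 t_half_min = th,
                 clint_ml_min_kg = cl$clint_ml_min_kg,
                 clint_ul_min_mg = cl$clint_ul_min_mg,
                 clearance_class = classify_clearance(cl$clint_ml_min_kg,
                                                      bands),
                 rounding = rounding,
                 timecourse = tc),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Metabolic stability assessment\n")
  cat(sprintf("  phase: %g-%g min (%d points)\n",
              x$window[1], x$window[2], x$n_points))
  cat(sprintf("  ln(%% remaining) = %.4f t + %.4f   (r2 = %.4f)\n",
              x$slope, x$intercept_ln, x$r2))
  cat(sprintf("  k = %.4f /min,  in vitro t1/2 = %.2f min\n",
              x$k_dep, x$t_half_min))
  cat(sprintf("  CLint = %.1f mL/min/kg  (%.1f uL/min/mg)\n",
              x$clint_ml_min_kg, x$clint_ul_min_mg))
  cat(sprintf("  clearance class: %s\n", x$clearance_class))
  invisible(x)
}

#' Plot a depletion time course
#'
#' Percent remaining against time with the fitted first-order line over the
#' selected phase.
#'
#' @param x A `stability_result`.
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.stability_result <- function(x, ...) {
  tc <- x$timecourse
  graphics::plot(tc$time_min, tc$pct_remaining, pch = 16,
                 xlab = "time (min)", ylab = "% remaining",
                 ylim = c(0, max(100, tc$pct_remaining)), ...)
  tt <- seq(x$window[1], x$window[2], length.out = 50)
  graphics::lines(tt, exp(x$intercept_ln + x$slope * tt), col = "steelblue")
  invisible(x)
}
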