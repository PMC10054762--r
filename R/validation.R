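# Method-validation assessment: QC precision/accuracy (intra/inter-batch),
# extraction recovery, matrix effect and IS-normalized matrix effect,
# carryover, and the threshold-based pass/fail report.

#' Quality-control statistics at one level
#'
#' Precision (%RSD), accuracy (% error) and recovery of back-calculated QC
#' concentrations, tagged with the batch scope. Intra-batch statistics come
#' from replicates within one day; inter-batch statistics pool all
#' replicates across days.
#'
#' @param back_calcs Numeric vector (>= 2) of back-calculated concentrations.
#' @param nominal Nominal QC concentration (ng/mL).
#' @param scope `"intra_batch"` or `"inter_batch"`.
#' @param level_name QC level label (e.g. `"MQC"`).
#' @return An object of class `qc_statistics` (one-row data frame) with
#'   `level_name`, `scope`, `n`, `mean`, `sd`, `precision_rsd_pct`,
#'   `accuracy_pct`, `recovery_pct`.
#' @export
qc_statistics <- function(back_calcs, nominal,
                          scope = c("intra_batch", "inter_batch"),
                          level_name = NA_character_) {
  scope <- match.arg(scope)
  if (length(back_calcs) < 2)
    stop("insufficient replicates: need >= 2 values", call. = FALSE)
  stopifnot(nominal > 0)
  m <- mean(back_calcs)
  s <- stats::sd(back_calcs)
  out <- data.frame(level_name = level_name, scope = scope,
                    n = length(back_calcs), mean = m, sd = s,
                    precision_rsd_pct = 100 * s / m,
                    accuracy_pct = 100 * (m - nominal) / nominal,
                    recovery_pct = 100 * m / nominal)
  class(out) <- c("qc_statistics", "data.frame")
  out
}

#' QC summary table across levels and scopes
#'
#' Back-calculates QC measurements through a calibration fit and computes
#' [qc_statistics()] per level. With more than one batch present, intra-batch
#' statistics use the first batch and inter-batch statistics pool all
#' batches.
#'
#' @param qcs A `measurement_table` of `qc` rows.
#' @param fit A `calibration_fit` used for back-calculation.
#' @param design A [study_design()] naming the QC levels.
#' @return A data frame with one row per level and scope.
#' @export
summarize_qcs <- function(qcs, fit, design = study_design()) {
  qcs <- as_measurement_table(as.data.frame(qcs))
  qc <- qcs[qcs$role == "qc", , drop = FALSE]
  if (nrow(qc) == 0) stop("no qc rows present", call. = FALSE)
  bc <- back_calculate(fit, area_ratio(qc))
  lev <- design$qc_levels
  scopes <- if (length(unique(qc$batch_id)) > 1)
    c("intra_batch", "inter_batch") else "intra_batch"
  out <- list()
  for (nm in names(lev)) {
    sel <- qc$nominal_conc == lev[[nm]]
    if (!any(sel)) next
    for (sc in scopes) {
      keep <- if (sc == "intra_batch")
        sel & qc$batch_id == min(qc$batch_id) else sel
      out[[length(out) + 1L]] <-
        qc_statistics(bc[keep], lev[[nm]], scope = sc, level_name = nm)
    }
  }
  if (!length(out)) stop("no qc rows match the designed levels",
                         call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extraction recovery
#'
#' Ratio of the mean response of extracted matrix QCs to the mean response of
#' neat-solvent QCs, times 100. Invariant under common rescaling of both
#' groups.
#'
#' @param matrix_qcs,neat_qcs Numeric response vectors (areas or ratios, the
#'   same type for both groups), non-empty.
#' @return Recovery in percent.
#' @export
extraction_recovery <- function(matrix_qcs, neat_qcs) {
  if (!length(matrix_qcs) || !length(neat_qcs))
    stop("both response groups must be non-empty", call. = FALSE)
  if (mean(neat_qcs) <= 0)
    stop("degenerate reference: neat mean must be > 0", call. = FALSE)
  100 * mean(matrix_qcs) / mean(neat_qcs)
}

#' Matrix effect
#'
#' Ratio-of-means matrix effect: mean response in matrix-spiked samples
#' (set 1) over mean response in neat solvent (set 2), times 100. 100% means
#' no ionization suppression or enhancement.
#'
#' @param set1_matrix,set2_neat Numeric response vectors, non-empty, same
#'   response type.
#' @return Matrix effect in percent.
#' @export
matrix_effect <- function(set1_matrix, set2_neat) {
  if (!length(set1_matrix) || !length(set2_neat))
    stop("both response groups must be non-empty", call. = FALSE)
  if (mean(set2_neat) <= 0)
    stop("degenerate reference: neat mean must be > 0", call. = FALSE)
  100 * mean(set1_matrix) / mean(set2_neat)
}

#' Internal-standard normalized matrix effect
#'
#' Analyte matrix effect divided by internal-standard matrix effect, as a
#' unitless ratio (not x100). Values near 1 indicate that matrix effects
#' cancel in the peak-area ratio.
#'
#' @param me_analyte Analyte matrix effect (%).
#' @param me_is Internal-standard matrix effect (%), > 0.
#' @return Dimensionless normalized matrix effect.
#' @export
is_normalized_me <- function(me_analyte, me_is) {
  if (!is.finite(me_is) || me_is <= 0)
    stop("internal-standard matrix effect must be > 0", call. = FALSE)
  me_analyte / me_is
}

#' Quantitative carryover check
#'
#' Residual analyte signal in a blank injected after a high-concentration
#' sample, expressed as a fraction of the response at the lower limit of
#' quantification. Passes when the fraction does not exceed the configured
#' limit (default 20% of LLOQ).
#'
#' @param blank_response Analyte response in the post-high blank, >= 0.
#' @param lloq_response Analyte response at the LLOQ, > 0.
#' @param thresholds An [acceptance_thresholds()] object.
#' @return A list with `fraction`, `limit` and logical `pass`.
#' @export
carryover_check <- function(blank_response, lloq_response,
                            thresholds = acceptance_thresholds()) {
  stopifnot(lloq_response > 0, blank_response >= 0)
  fraction <- blank_response / lloq_response
  list(fraction = fraction,
       limit = thresholds$carryover_max_fraction_of_lloq,
       pass = fraction <= thresholds$carryover_max_fraction_of_lloq)
}

#' Threshold-based validation verdict
#'
#' Evaluates every available statistic against the configured limits and
#' reports each criterion as (value, limit, verdict). The overall verdict is
#' the conjunction of all criteria; failures are listed, never hidden.
#' QC accuracy and precision at the LLOQ-level QC use the wider LLOQ limits.
#'
#' @param qc_stats A data frame of [qc_statistics()] rows (any number of
#'   levels and scopes). Required.
#' @param fit Optional `calibration_fit`; adds the r2 criterion.
#' @param me_normalized Optional IS-normalized matrix effect; adds the
#'   interval criterion.
#' @param carryover Optional result of [carryover_check()]; adds the
#'   carryover criterion.
#' @param thresholds An [acceptance_thresholds()] object.
#' @param lloq_level Name of the QC level evaluated with LLOQ limits.
#' @param required_levels QC level names that must be present; a missing one
#'   raises an incomplete-run error naming the level. Default: none enforced.
#' @return An object of class `acceptance_report`: a data frame of criteria
#'   (`criterion`, `value`, `limit`, `pass`) with attribute `overall_pass`.
#' @export
evaluate_acceptance <- function(qc_stats, fit = NULL, me_normalized = NULL,
                                carryover = NULL,
                                thresholds = acceptance_thresholds(),
                                lloq_level = "LLQC",
                                required_levels = NULL) {
  stopifnot(is.data.frame(qc_stats))
  if (!is.null(required_levels)) {
    missing_lv <- setdiff(required_levels, qc_stats$level_name)
    if (length(missing_lv))
      stop("incomplete run: missing QC level ",
           paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  add <- function(criterion, value, limit, pass)
    rows[[length(rows) + 1L]] <<- data.frame(
      criterion = criterion, value = value, limit = limit, pass = pass)
  for (i in seq_len(nrow(qc_stats))) {
    st <- qc_stats[i, ]
    is_lloq <- identical(st$level_name, lloq_level)
    bias_lim <- if (is_lloq) thresholds$max_bias_pct_lloq else
      thresholds$max_bias_pct
    rsd_lim <- if (is_lloq) thresholds$max_rsd_pct_lloq else
      thresholds$max_rsd_pct
    tag <- paste0(st$level_name, "/", st$scope)
    add(paste0("accuracy|", tag), abs(st$accuracy_pct), bias_lim,
        abs(st$accuracy_pct) <= bias_lim)
    add(paste0("precision|", tag), st$precision_rsd_pct, rsd_lim,
        st$precision_rsd_pct <= rsd_lim)
  }
  if (!is.null(fit))
    add("calibration_r2", fit$r2, thresholds$min_r2,
        fit$r2 >= thresholds$min_r2)
  if (!is.null(me_normalized)) {
    rng <- thresholds$me_normalized_range
    add("is_normalized_me", me_normalized, rng[2],
        me_normalized >= rng[1] && me_normalized <= rng[2])
  }
  if (!is.null(carryover))
    add("carryover_fraction", carryover$fraction, carryover$limit,
        isTRUE(carryover$pass))
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "overall_pass") <- all(report$pass)
  class(report) <- c("acceptance_report", "data.frame")
  report
}

#' @export
print.acceptance_report <- function(x, ...) {
  cat("Validation acceptance report\n")
  df <- as.data.frame(x)
  df$value <- signif(df$value, 5)
  df$verdict <- ifelse(df$pass, "PASS", "FAIL")
  print(df[c("criterion", "value", "limit", "verdict")], row.names = FALSE)
  cat("Overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}
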