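# Sample roles recognised throughout the pipeline. `standard` rows carry the
# calibration curve, `qc` rows the quality controls, `matrix_set1`/`neat_set2`
# the paired matrix-effect design, `timepoint` the depletion incubations.
MEASUREMENT_ROLES <- c("standard", "qc", "blank", "blank_with_is",
                       "matrix_set1", "neat_set2", "timepoint")

MEASUREMENT_COLUMNS <- c("sample_id", "role", "nominal_conc", "analyte_area",
                         "is_area", "replicate_id", "batch_id", "time_min")

#' Study design: concentration levels and physiological scaling constants
#'
#' Bundles the calibration levels, quality-control levels and the constants
#' used to scale the in vitro depletion rate to whole-body intrinsic
#' clearance. Defaults describe a human-liver-microsome incubation of 1 mg
#' microsomal protein in 1 mL, scaled with 45 mg microsomal protein per gram
#' of liver and 26 g liver per kg body weight, with an 11-point calibration
#' from 1 to 3000 ng/mL.
#'
#' @param calibration_levels Numeric vector of nominal standard
#'   concentrations (ng/mL), strictly increasing, at least two.
#' @param qc_levels Named numeric vector of QC concentrations (ng/mL). Names
#'   are the level labels; the lowest level is treated as the LLOQ-level QC
#'   when thresholds distinguish it.
#' @param incubation_volume_mL Incubation volume (mL).
#' @param microsomal_protein_mg Microsomal protein per incubation (mg).
#' @param mg_protein_per_g_liver Microsomal protein yield (mg/g liver).
#' @param g_liver_per_kg_bw Liver mass per kg body weight (g/kg).
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$qc_levels
#' @export
study_design <- function(calibration_levels = c(1, 3, 15, 50, 100, 300, 500,
                                                900, 1500, 2400, 3000),
                         qc_levels = c(LLQC = 1, LQC = 3, MQC = 900,
                                       HQC = 2400),
                         incubation_volume_mL = 1,
                         microsomal_protein_mg = 1,
                         mg_protein_per_g_liver = 45,
                         g_liver_per_kg_bw = 26) {
  stopifnot(is.numeric(calibration_levels), length(calibration_levels) >= 2)
  if (any(diff(calibration_levels) <= 0))
    stop("calibration_levels must be strictly increasing", call. = FALSE)
  if (is.null(names(qc_levels)) || any(!nzchar(names(qc_levels))))
    stop("qc_levels must be a named numeric vector", call. = FALSE)
  scal <- c(incubation_volume_mL, microsomal_protein_mg,
            mg_protein_per_g_liver, g_liver_per_kg_bw)
  if (any(!is.finite(scal)) || any(scal <= 0))
    stop("all scaling constants must be strictly positive", call. = FALSE)
  structure(list(calibration_levels = as.numeric(calibration_levels),
                 qc_levels = qc_levels,
                 incubation_volume_mL = incubation_volume_mL,
                 microsomal_protein_mg = microsomal_protein_mg,
                 mg_protein_per_g_liver = mg_protein_per_g_liver,
                 g_liver_per_kg_bw = g_liver_per_kg_bw),
            class = "study_design")
}

#' Acceptance thresholds for method validation
#'
#' Numeric limits applied by [evaluate_acceptance()]. Regulatory guidance is
#' commonly summarised as bias and precision within +/-15% (20% at the lower
#' limit of quantification); those figures are defaults here, not constants,
#' and every limit can be overridden.
#'
#' @param max_bias_pct Maximum absolute accuracy bias (%) at non-LLOQ levels.
#' @param max_bias_pct_lloq Maximum absolute bias (%) at the LLOQ level.
#' @param max_rsd_pct Maximum precision %RSD at non-LLOQ levels.
#' @param max_rsd_pct_lloq Maximum %RSD at the LLOQ level.
#' @param min_r2 Minimum calibration coefficient of determination.
#' @param carryover_max_fraction_of_lloq Maximum blank response expressed as
#'   a fraction of the LLOQ response.
#' @param me_normalized_range Length-2 numeric, acceptable interval for the
#'   IS-normalized matrix effect (dimensionless).
#' @return An object of class `acceptance_thresholds`.
#' @export
acceptance_thresholds <- function(max_bias_pct = 15, max_bias_pct_lloq = 20,
                                  max_rsd_pct = 15, max_rsd_pct_lloq = 20,
                                  min_r2 = 0.98,
                                  carryover_max_fraction_of_lloq = 0.20,
                                  me_normalized_range = c(0.85, 1.15)) {
  vals <- c(max_bias_pct, max_bias_pct_lloq, max_rsd_pct, max_rsd_pct_lloq,
            min_r2, carryover_max_fraction_of_lloq, me_normalized_range)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be strictly positive", call. = FALSE)
  if (max_bias_pct_lloq < max_bias_pct || max_rsd_pct_lloq < max_rsd_pct)
    stop("LLOQ thresholds must be >= non-LLOQ thresholds", call. = FALSE)
  if (length(me_normalized_range) != 2 ||
      me_normalized_range[1] >= me_normalized_range[2])
    stop("me_normalized_range must be an increasing length-2 interval",
         call. = FALSE)
  structure(list(max_bias_pct = max_bias_pct,
                 max_bias_pct_lloq = max_bias_pct_lloq,
                 max_rsd_pct = max_rsd_pct,
                 max_rsd_pct_lloq = max_rsd_pct_lloq,
                 min_r2 = min_r2,
                 carryover_max_fraction_of_lloq = carryover_max_fraction_of_lloq,
                 me_normalized_range = as.numeric(me_normalized_range)),
            class = "acceptance_thresholds")
}

#' Validate a measurement table
#'
#' Checks a data frame of analyte measurements against the role-specific
#' invariants: recognised roles, non-negative peak areas, positive nominal
#' concentrations where present, `time_min` present if and only if the row is
#' a depletion time point, and positive replicate/batch ids.
#'
#' @param df Data frame with columns `sample_id`, `role`, `nominal_conc`,
#'   `analyte_area`, `is_area`, `replicate_id`, `batch_id`, `time_min`
#'   (missing optional columns are added as `NA`).
#' @return The validated data frame, with class `measurement_table` prepended,
#'   row order preserved.
#' @export
as_measurement_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("sample_id", "role", "analyte_area")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(MEASUREMENT_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[MEASUREMENT_COLUMNS]
  df$role <- as.character(df$role)
  bad_role <- which(!df$role %in% MEASUREMENT_ROLES)
  if (length(bad_role))
    stop("unknown role '", df$role[bad_role[1]], "' at row ", bad_role[1],
         call. = FALSE)
  num_cols <- c("nominal_conc", "analyte_area", "is_area", "replicate_id",
                "batch_id", "time_min")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])

  bad <- which(!is.na(df$analyte_area) & df$analyte_area < 0)
  if (length(bad))
    stop("negative analyte_area at row ", bad[1], call. = FALSE)
  bad <- which(!is.na(df$is_area) & df$is_area < 0)
  if (length(bad))
    stop("negative is_area at row ", bad[1], call. = FALSE)
  bad <- which(!is.na(df$nominal_conc) & df$nominal_conc <= 0)
  if (length(bad))
    stop("nominal_conc must be > 0 when present (row ", bad[1], ")",
         call. = FALSE)

  # role-conditional requirements
  needs_nominal <- df$role %in% c("standard", "qc")
  bad <- which(needs_nominal & is.na(df$nominal_conc))
  if (length(bad))
    stop("nominal_conc required for role '", df$role[bad[1]], "' (row ",
         bad[1], ")", call. = FALSE)
  bad <- which(df$role == "timepoint" & is.na(df$time_min))
  if (length(bad))
    stop("time_min required for timepoint rows (row ", bad[1], ")",
         call. = FALSE)
  bad <- which(df$role != "timepoint" & !is.na(df$time_min))
  if (length(bad))
    stop("time_min only allowed on timepoint rows (row ", bad[1], ")",
         call. = FALSE)
  bad <- which(!is.na(df$time_min) & df$time_min < 0)
  if (length(bad))
    stop("time_min must be >= 0 (row ", bad[1], ")", call. = FALSE)
  for (col in c("replicate_id", "batch_id")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 1)
    if (length(bad))
      stop(col, " must be >= 1 (row ", bad[1], ")", call. = FALSE)
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read a measurement table from delimited text
#'
#' Tables are comma-separated UTF-8 with a header row and period decimal
#' separator. Every row is validated against the role-specific invariants;
#' row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A validated `measurement_table`.
#' @seealso [write_measurement_table()]
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  as_measurement_table(df)
}

#' Write a measurement table to delimited text
#'
#' Numeric fields are written with enough significant digits (17) that a
#' write/read round trip reproduces every value bit-for-bit.
#'
#' @param df A `measurement_table` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(df, path) {
  df <- as_measurement_table(df)
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- vapply(out[[col]], function(x)
        if (is.na(x)) NA_character_ else sprintf("%.17g", x), character(1))
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Analyte / internal-standard peak-area ratio
#'
#' The quantification response: analyte peak area divided by the
#' internal-standard peak area of the same injection. Scale-invariant under
#' common rescaling of both areas.
#'
#' @param measurements A `measurement_table` or data frame with
#'   `analyte_area` and `is_area` columns.
#' @return Numeric vector of ratios, one per row.
#' @export
area_ratio <- function(measurements) {
  a <- measurements$analyte_area
  i <- measurements$is_area
  if (is.null(a) || is.null(i))
    stop("analyte_area and is_area columns are required", call. = FALSE)
  bad <- which(is.na(i) | i == 0)
  if (length(bad))
    stop("internal-standard area missing or zero at row ", bad[1],
         call. = FALSE)
  as.numeric(a) / as.numeric(i)
}

#' Read a depletion time-course table
#'
#' Time courses are CSV files with columns `time_min`, `conc` (measured
#' concentration, ng/mL, or any response proportional to it) and
#' `replicate_id`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with validated columns, ordered as stored.
#' @export
read_timecourse_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_timecourse_table(df)
}

#' @rdname read_timecourse_table
#' @param df Data frame to validate in place of a file.
#' @export
as_timecourse_table <- function(df) {
  required <- c("time_min", "conc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(df$replicate_id)) df$replicate_id <- 1L
  df$time_min <- as.numeric(df$time_min)
  df$conc <- as.numeric(df$conc)
  if (any(!is.finite(df$time_min)) || any(df$time_min < 0))
    stop("time_min must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(df$conc)))
    stop("conc must be finite", call. = FALSE)
  df
}
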