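# End-to-end orchestration: read a run configuration, execute
# simulate -> calibrate -> validate -> stability, and write a merged
# machine-readable report plus a text summary. Identical config and seed
# give identical reports.

#' Read a run configuration
#'
#' Configurations are YAML or JSON (by file extension) with optional blocks
#' `design`, `thresholds`, `bands`, `simulate` (sub-blocks `calibration`,
#' `qc`, `matrix`, `depletion`), `inputs` (paths to `standards`, `qcs`,
#' `timecourse` CSVs) and `stability` (mode/window/rounding), plus a
#' top-level `seed` (required whenever any `simulate` block is present).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list, validated for the seed requirement.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (!is.null(cfg$simulate) && is.null(cfg$seed))
    stop("seed required whenever a simulate block is present",
         call. = FALSE)
  if (!is.null(cfg$inputs)) {
    for (p in unlist(cfg$inputs))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  cfg
}

config_design <- function(cfg) {
  args <- cfg$design
  if (is.null(args)) return(study_design())
  if (!is.null(args$qc_levels)) args$qc_levels <- unlist(args$qc_levels)
  do.call(study_design, args)
}

config_thresholds <- function(cfg) {
  if (is.null(cfg$thresholds)) return(acceptance_thresholds())
  do.call(acceptance_thresholds, cfg$thresholds)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order: simulate (or load) input tables,
#' fit the calibration and linearity summaries, compute the validation
#' statistics and acceptance verdict, and assess metabolic stability. Each
#' stage's outputs are written before the next starts when `out_dir` is
#' given; a failing stage leaves prior outputs in place alongside a `FAILED`
#' marker naming the stage.
#'
#' @param config A list from [read_run_config()] (or built in code).
#' @param out_dir Optional output directory; created if missing.
#' @param verbose Print one log line per stage.
#' @return A list (class `pipeline_report`) with elements `calibration`,
#'   `levels`, `lod_loq`, `validation`, `matrix_effect`, `stability`,
#'   `overall`, mirroring everything the text summary prints.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = TRUE) {
  design <- config_design(config)
  thresholds <- config_thresholds(config)
  bands <- if (!is.null(config$bands)) do.call(clearance_bands, config$bands)
  else clearance_bands()
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  say <- function(...) if (verbose) message(...)
  out <- list()
  stage <- "setup"
  write_stage <- function(name, df) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  run <- function() {
    # --- standards ---------------------------------------------------------
    stage <<- "calibration"
    standards <- if (!is.null(config$inputs$standards))
      read_measurement_table(config$inputs$standards)
    else {
      sim <- config$simulate$calibration
      sim$seed <- seed
      simulate_calibration(do.call(calibration_sim_params, sim), design)
    }
    say("calibration: ", nrow(standards), " standard rows")
    fit <- fit_calibration(standards)
    out$calibration <<- list(slope = fit$slope, intercept = fit$intercept,
                             r2 = fit$r2, n_points = fit$n_points)
    levels_tab <- summarize_levels(standards, fit)
    out$levels <<- levels_tab
    write_stage("calibration_levels", levels_tab)
    curves <- fit_calibration_curves(standards)
    if (length(curves) >= 2) {
      ll <- lod_loq(curves)
      out$lod_loq <<- list(lod = ll$lod, loq = ll$loq,
                           n_curves = ll$n_curves)
      say(sprintf("calibration: LOD %.4g / LOQ %.4g ng/mL over %d curves",
                  ll$lod, ll$loq, ll$n_curves))
    }

    # --- validation --------------------------------------------------------
    stage <<- "validation"
    qc_stats <- NULL
    if (!is.null(config$inputs$qcs)) {
      qcs <- read_measurement_table(config$inputs$qcs)
      qc_stats <- summarize_qcs(qcs, fit, design)
    } else if (!is.null(config$simulate$qc)) {
      simc <- config$simulate$calibration
      simc$seed <- seed
      params <- do.call(calibration_sim_params, simc)
      qargs <- config$simulate$qc
      qargs$params <- params
      qargs$design <- design
      qcs <- do.call(simulate_qc, qargs)
      qc_stats <- summarize_qcs(qcs, fit, design)
    }
    me <- NULL
    if (!is.null(config$simulate$matrix)) {
      margs <- config$simulate$matrix
      margs$seed <- seed + 2L
      sets <- do.call(simulate_matrix_effect_sets, margs)
      me_a <- matrix_effect(sets$set1_matrix$analyte_response,
                            sets$set2_neat$analyte_response)
      me_i <- matrix_effect(sets$set1_matrix$is_response,
                            sets$set2_neat$is_response)
      me <- list(me_analyte_pct = me_a, me_is_pct = me_i,
                 is_normalized_me = is_normalized_me(me_a, me_i))
      out$matrix_effect <<- me
      say(sprintf("validation: ME %.2f%% / %.2f%%, normalized %.3f",
                  me_a, me_i, me$is_normalized_me))
    }
    if (!is.null(qc_stats)) {
      report <- evaluate_acceptance(
        qc_stats, fit = fit,
        me_normalized = if (!is.null(me)) me$is_normalized_me,
        thresholds = thresholds)
      out$validation <<- list(qc = qc_stats, report = as.data.frame(report),
                              overall_pass = attr(report, "overall_pass"))
      write_stage("qc_statistics", qc_stats)
      write_stage("acceptance_report", as.data.frame(report))
      say("validation: overall ",
          if (attr(report, "overall_pass")) "PASS" else "FAIL")
    }

    # --- stability ---------------------------------------------------------
    stage <<- "stability"
    tc <- if (!is.null(config$inputs$timecourse))
      read_timecourse_table(config$inputs$timecourse)
    else if (!is.null(config$simulate$depletion)) {
      dargs <- config$simulate$depletion
      dargs$seed <- seed + 3L
      simulate_depletion(do.call(depletion_sim_params, dargs))
    }
    if (!is.null(tc)) {
      sargs <- config$stability
      mode <- if (!is.null(sargs$mode)) sargs$mode else "manual"
      window <- if (!is.null(sargs$window)) as.numeric(sargs$window)
      else c(0, 30)
      rounding <- if (!is.null(sargs$rounding)) sargs$rounding else "full"
      min_points <- if (!is.null(sargs$min_points)) sargs$min_points else 4
      r2_floor <- if (!is.null(sargs$r2_floor)) sargs$r2_floor else 0.99
      st <- assess_stability(tc, design, mode = mode, window = window,
                             min_points = min_points, r2_floor = r2_floor,
                             rounding = rounding, bands = bands)
      out$stability <<- st
      write_stage("depletion_timecourse", st$timecourse)
      write_stage("stability_result", data.frame(
        slope = st$slope, intercept_ln = st$intercept_ln, r2 = st$r2,
        t_half_min = st$t_half_min,
        clint_ml_min_kg = st$clint_ml_min_kg,
        clint_ul_min_mg = st$clint_ul_min_mg,
        clearance_class = st$clearance_class))
      say(sprintf(
        "stability: t1/2 %.2f min, CLint %.1f mL/min/kg (%s clearance)",
        st$t_half_min, st$clint_ml_min_kg, st$clearance_class))
    }
    out$overall <<- list(
      validation_pass = if (!is.null(out$validation))
        out$validation$overall_pass else NA)
  }

  ok <- tryCatch({ run(); TRUE }, error = function(e) {
    if (!is.null(out_dir))
      writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  class(out) <- "pipeline_report"
  if (!is.null(out_dir)) {
    writeLines(render_report_json(out), file.path(out_dir, "report.json"))
    writeLines(render_summary(out), file.path(out_dir, "summary.txt"))
  }
  invisible(out)
}

# Machine-readable report: every number the text summary echoes.
render_report_json <- function(report) {
  x <- list(calibration = report$calibration,
            lod_loq = report$lod_loq,
            levels = report$levels,
            matrix_effect = report$matrix_effect)
  if (!is.null(report$validation))
    x$validation <- list(qc = report$validation$qc,
                         report = report$validation$report,
                         overall_pass = report$validation$overall_pass)
  if (!is.null(report$stability)) {
    st <- report$stability
    x$stability <- list(window = st$window, slope = st$slope,
                        intercept_ln = st$intercept_ln, r2 = st$r2,
                        k_dep = st$k_dep, t_half_min = st$t_half_min,
                        clint_ml_min_kg = st$clint_ml_min_kg,
                        clint_ul_min_mg = st$clint_ul_min_mg,
                        clearance_class = st$clearance_class)
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows")
}

render_summary <- function(report) {
  lines <- character()
  push <- function(...) lines <<- c(lines, sprintf(...))
  push("Run summary")
  if (!is.null(report$calibration)) {
    cb <- report$calibration
    push("calibration: ratio = %.6g x + %.6g, r2 = %.4f (%d levels)",
         cb$slope, cb$intercept, cb$r2, cb$n_points)
  }
  if (!is.null(report$lod_loq))
    push("LOD = %.4g ng/mL, LOQ = %.4g ng/mL (%d curves)",
         report$lod_loq$lod, report$lod_loq$loq, report$lod_loq$n_curves)
  if (!is.null(report$matrix_effect)) {
    me <- report$matrix_effect
    push("matrix effect: analyte %.2f%%, IS %.2f%%, normalized %.3f",
         me$me_analyte_pct, me$me_is_pct, me$is_normalized_me)
  }
  if (!is.null(report$validation))
    push("validation verdict: %s",
         if (report$validation$overall_pass) "PASS" else "FAIL")
  if (!is.null(report$stability)) {
    st <- report$stability
    push("stability: slope %.4f /min, intercept %.4f, r2 %.4f", st$slope,
         st$intercept_ln, st$r2)
    push("in vitro t1/2 = %.2f min, CLint = %.2f mL/min/kg (%.2f uL/min/mg)",
         st$t_half_min, st$clint_ml_min_kg, st$clint_ul_min_mg)
    push("clearance class: %s", st$clearance_class)
  }
  lines
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(render_summary(x))
  invisible(x)
}

#' Path to a packaged example dataset
#'
#' Small CSV datasets from a published selpercatinib metabolic-stability
#' study in human liver microsomes ship with the package:
#' `"slp_depletion_timecourse.csv"` (mean depletion time course, ng/mL, ten
#' stop times), `"slp_backcalc_summary.csv"` (per-level back-calculation
#' summary of an 11-point calibration) and `"slp_qc_summary.csv"`
#' (intra/inter-batch QC summary at four levels).
#'
#' @param file Dataset file name; with no argument, lists available files.
#' @return Full path to the installed file.
#' @examples
#' microstab_example()
#' tc <- read_timecourse_table(microstab_example("slp_depletion_timecourse.csv"))
#' @export
microstab_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "microstab")))
  path <- system.file("extdata", file, package = "microstab")
  if (!nzchar(path)) stop("no packaged dataset named '", file, "'",
                          call. = FALSE)
  path
}
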