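# Generators for every input table the pipeline consumes. Each generator is
# deterministic under its seed and collapses to an exact, noise-free oracle
# when all dispersion parameters are zero.

#' Calibration simulation parameters
#'
#' Parameters of the simulated detector response. The default slope and
#' intercept reproduce a selpercatinib/filgotinib peak-area-ratio calibration
#' in human liver microsomes (response = 1.7298 x + 3.62941 over
#' 1-3000 ng/mL). Noise has an additive component (constant SD in ratio
#' units) and a proportional component (CV of the signal term).
#'
#' @param slope_true True response slope (ratio per ng/mL), > 0.
#' @param intercept_true True response intercept (ratio units).
#' @param additive_sd Additive noise SD (ratio units), >= 0.
#' @param proportional_cv Proportional noise CV (fraction in [0, 1)).
#' @param n_replicates Replicate curves per simulated batch.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return An object of class `calibration_sim_params`.
#' @export
calibration_sim_params <- function(slope_true = 1.7298,
                                   intercept_true = 3.62941,
                                   additive_sd = 0,
                                   proportional_cv = 0,
                                   n_replicates = 6,
                                   seed = 1L) {
  stopifnot(slope_true > 0, additive_sd >= 0,
            proportional_cv >= 0, proportional_cv < 1,
            n_replicates >= 1)
  structure(list(slope_true = slope_true, intercept_true = intercept_true,
                 additive_sd = additive_sd, proportional_cv = proportional_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "calibration_sim_params")
}

#' Depletion simulation parameters
#'
#' Parameters of the simulated substrate-depletion time course. The mean
#' curve is biphasic: a first-order phase decaying at `k_dep` towards a
#' non-depleting plateau, C(t) = c0 * ((1 - plateau) * exp(-k_dep * t) +
#' plateau). Defaults emulate a microsomal incubation starting at 626 ng/mL
#' that decays at 0.0291 /min towards roughly 30% remaining by 70 min,
#' sampled at the standard stop times with three replicates. Replicate noise
#' is multiplicative lognormal (concentrations stay positive, CV roughly
#' constant across the curve).
#'
#' @param c0 Concentration at time zero (ng/mL), > 0.
#' @param k_dep First-order depletion rate constant (per minute), > 0.
#' @param plateau_fraction Non-depleting fraction in [0, 1).
#' @param replicate_cv Replicate coefficient of variation (fraction), >= 0.
#' @param times_min Stop times (minutes); must include 0.
#' @param n_replicates Replicates per time point.
#' @param seed Integer seed.
#' @return An object of class `depletion_sim_params`.
#' @export
depletion_sim_params <- function(c0 = 626,
                                 k_dep = 0.0291,
                                 plateau_fraction = 0.30,
                                 replicate_cv = 0,
                                 times_min = c(0, 2.5, 7.5, 15, 20, 30, 40,
                                               50, 60, 70),
                                 n_replicates = 3,
                                 seed = 1L) {
  stopifnot(c0 > 0, k_dep > 0,
            plateau_fraction >= 0, plateau_fraction < 1,
            replicate_cv >= 0, n_replicates >= 1)
  if (!any(times_min == 0))
    stop("times_min must include 0 (the normalization baseline)",
         call. = FALSE)
  structure(list(c0 = c0, k_dep = k_dep,
                 plateau_fraction = plateau_fraction,
                 replicate_cv = replicate_cv,
                 times_min = sort(as.numeric(times_min)),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "depletion_sim_params")
}

#' Simulate calibration-standard measurements
#'
#' For each calibration level x and replicate curve, the peak-area ratio is
#' drawn as `slope_true * x + intercept_true + eps` with
#' `eps ~ Normal(0, additive_sd + proportional_cv * slope_true * x)`. The
#' internal-standard area is held fixed and the analyte area back-derived
#' from the ratio, so [area_ratio()] recovers the simulated response exactly.
#' Negative draws are resampled (with a warning) to respect area
#' non-negativity.
#'
#' @param params A [calibration_sim_params()] object.
#' @param design A [study_design()] object supplying the levels.
#' @param is_area Fixed internal-standard peak area (detector counts).
#' @return A `measurement_table` of `standard` rows; `batch_id` identifies
#'   the replicate curve.
#' @export
simulate_calibration <- function(params, design = study_design(),
                                 is_area = 1e5) {
  stopifnot(inherits(params, "calibration_sim_params"),
            inherits(design, "study_design"))
  set.seed(params$seed)
  levels <- design$calibration_levels
  rows <- expand.grid(nominal_conc = levels,
                      replicate_id = seq_len(params$n_replicates))
  mu <- params$slope_true * rows$nominal_conc + params$intercept_true
  sigma <- params$additive_sd +
    params$proportional_cv * params$slope_true * rows$nominal_conc
  ratio <- stats::rnorm(nrow(rows), mu, sigma)
  n_resampled <- 0L
  while (any(ratio < 0)) {
    neg <- ratio < 0
    n_resampled <- n_resampled + sum(neg)
    ratio[neg] <- stats::rnorm(sum(neg), mu[neg], sigma[neg])
  }
  if (n_resampled > 0)
    warning(n_resampled, " negative simulated ratio(s) resampled",
            call. = FALSE)
  as_measurement_table(data.frame(
    sample_id = sprintf("STD_%g_r%d", rows$nominal_conc, rows$replicate_id),
    role = "standard",
    nominal_conc = rows$nominal_conc,
    analyte_area = ratio * is_area,
    is_area = is_area,
    replicate_id = rows$replicate_id,
    batch_id = rows$replicate_id,
    time_min = NA_real_))
}

#' Simulate quality-control measurements
#'
#' QC replicates at the designed levels, generated through the same response
#' model as [simulate_calibration()] with a per-level relative dispersion, so
#' back-calculation through a fitted curve recovers the nominal
#' concentrations in expectation.
#'
#' @param params A [calibration_sim_params()] object (response model).
#' @param design A [study_design()] object supplying `qc_levels`.
#' @param qc_cv Relative SD of the back-calculated concentration (fraction).
#' @param n_replicates Replicates per level per batch.
#' @param n_batches Number of batches (days); 1 for an intra-batch set.
#' @param is_area Fixed internal-standard peak area.
#' @return A `measurement_table` of `qc` rows.
#' @export
simulate_qc <- function(params, design = study_design(), qc_cv = 0.02,
                        n_replicates = 6, n_batches = 1, is_area = 1e5) {
  stopifnot(inherits(params, "calibration_sim_params"), qc_cv >= 0,
            n_replicates >= 2, n_batches >= 1)
  set.seed(params$seed + 1L)
  rows <- expand.grid(level_name = names(design$qc_levels),
                      replicate_id = seq_len(n_replicates),
                      batch_id = seq_len(n_batches),
                      stringsAsFactors = FALSE)
  nominal <- design$qc_levels[rows$level_name]
  conc <- nominal * (1 + stats::rnorm(nrow(rows), 0, qc_cv))
  conc[conc <= 0] <- nominal[conc <= 0] * 1e-3  # floor; qc_cv << 1 in practice
  ratio <- params$slope_true * conc + params$intercept_true
  as_measurement_table(data.frame(
    sample_id = sprintf("%s_b%d_r%d", rows$level_name, rows$batch_id,
                        rows$replicate_id),
    role = "qc",
    nominal_conc = as.numeric(nominal),
    analyte_area = ratio * is_area,
    is_area = is_area,
    replicate_id = rows$replicate_id,
    batch_id = rows$batch_id,
    time_min = NA_real_))
}

#' Simulate a substrate-depletion time course
#'
#' Mean curve `C(t) = c0 * ((1 - plateau_fraction) * exp(-k_dep * t) +
#' plateau_fraction)`; each replicate observation is the mean multiplied by
#' lognormal noise with unit mean and coefficient of variation
#' `replicate_cv`.
#'
#' @param params A [depletion_sim_params()] object.
#' @return A time-course data frame with columns `time_min`, `conc`,
#'   `replicate_id`.
#' @export
simulate_depletion <- function(params) {
  stopifnot(inherits(params, "depletion_sim_params"))
  set.seed(params$seed)
  rows <- expand.grid(time_min = params$times_min,
                      replicate_id = seq_len(params$n_replicates))
  mean_conc <- params$c0 *
    ((1 - params$plateau_fraction) * exp(-params$k_dep * rows$time_min) +
       params$plateau_fraction)
  if (params$replicate_cv > 0) {
    sdlog <- sqrt(log(1 + params$replicate_cv^2))
    noise <- stats::rlnorm(nrow(rows), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise <- rep(1, nrow(rows))
  }
  out <- data.frame(time_min = rows$time_min,
                    conc = mean_conc * noise,
                    replicate_id = rows$replicate_id)
  out[order(out$time_min, out$replicate_id), , drop = FALSE]
}

#' Simulate paired matrix-effect sample sets
#'
#' Two groups of responses for the matrix-effect design: set 2 measured in
#' neat solvent at the nominal response, set 1 in biological matrix with the
#' response scaled by the true matrix effect. The downstream ratio-of-means
#' estimator recovers `true_me_*` in expectation.
#'
#' @param true_me_analyte True analyte matrix effect (%; 100 = none).
#' @param true_me_is True internal-standard matrix effect (%).
#' @param cv Replicate coefficient of variation (fraction).
#' @param n Replicates per set, >= 2.
#' @param seed Integer seed.
#' @param neat_analyte,neat_is Nominal neat responses (detector counts).
#' @return A list with data frames `set1_matrix` and `set2_neat`, each with
#'   columns `analyte_response`, `is_response`, `replicate_id`.
#' @export
simulate_matrix_effect_sets <- function(true_me_analyte = 100,
                                        true_me_is = 100,
                                        cv = 0, n = 6, seed = 1L,
                                        neat_analyte = 1e4, neat_is = 1e5) {
  stopifnot(n >= 2, cv >= 0, true_me_analyte > 0, true_me_is > 0)
  set.seed(as.integer(seed))
  noise <- function(k) if (cv > 0) 1 + stats::rnorm(k, 0, cv) else rep(1, k)
  set2 <- data.frame(analyte_response = neat_analyte * noise(n),
                     is_response = neat_is * noise(n),
                     replicate_id = seq_len(n))
  set1 <- data.frame(
    analyte_response = neat_analyte * true_me_analyte / 100 * noise(n),
    is_response = neat_is * true_me_is / 100 * noise(n),
    replicate_id = seq_len(n))
  list(set1_matrix = set1, set2_neat = set2)
}
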