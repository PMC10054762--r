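# Shared fixtures built in code.

# Published selpercatinib depletion time course: mean concentrations (ng/mL)
# at the ten incubation stop times (average of three repeats).
slp_depletion_means <- function() {
  data.frame(time_min = c(0, 2.5, 7.5, 15, 20, 30, 40, 50, 60, 70),
             conc = c(626, 586, 527, 418, 353, 264, 238, 227, 218, 197),
             replicate_id = 1L)
}

# Minimal noise-free standards table on a known line (ratio = slope*x + int).
make_standards <- function(levels = c(1, 3, 15, 50, 100, 300, 500, 900,
                                      1500, 2400, 3000),
                           slope = 1.7298, intercept = 3.62941,
                           n_replicates = 1, is_area = 1e5,
                           batch_offset = 0) {
  rows <- expand.grid(nominal_conc = levels,
                      replicate_id = seq_len(n_replicates))
  ratio <- slope * rows$nominal_conc + intercept
  as_measurement_table(data.frame(
    sample_id = sprintf("S%g_%d", rows$nominal_conc, rows$replicate_id),
    role = "standard",
    nominal_conc = rows$nominal_conc,
    analyte_area = ratio * is_area,
    is_area = is_area,
    replicate_id = rows$replicate_id,
    batch_id = rows$replicate_id + batch_offset,
    time_min = NA_real_))
}

# Independent OLS oracle: brute-force normal equations (X'X)^-1 X'y.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
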