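test_that("percent remaining and ln columns reproduce the published table", {
  tc <- percent_remaining(slp_depletion_means())
  expect_equal(round(tc$pct_remaining, 2),
               c(100.00, 93.61, 84.19, 66.77, 56.39, 42.17, 38.02, 36.26,
                 34.82, 31.47))
  expect_equal(round(tc$ln_pct_remaining, 2),
               c(4.61, 4.54, 4.43, 4.20, 4.03, 3.74, 3.64, 3.59, 3.55, 3.45))
  expect_equal(tc$pct_remaining[1], 100)
})

test_that("percent_remaining validates the baseline", {
  bad <- data.frame(time_min = c(5, 10), conc = c(1, 2), replicate_id = 1)
  expect_error(percent_remaining(bad), "t = 0")
  zero <- data.frame(time_min = c(0, 10), conc = c(0, 2), replicate_id = 1)
  expect_error(percent_remaining(zero), "degenerate baseline")
  flat <- percent_remaining(data.frame(time_min = c(0, 10, 20),
                                       conc = 5, replicate_id = 1))
  expect_equal(flat$pct_remaining, rep(100, 3))
  expect_equal(flat$ln_pct_remaining, rep(log(100), 3))
})

test_that("manual phase selection keeps the windowed points, idempotently", {
  tc <- percent_remaining(slp_depletion_means())
  ph <- select_linear_phase(tc, "manual", window = c(0, 30))
  expect_equal(ph$time_min, c(0, 2.5, 7.5, 15, 20, 30))
  # idempotent and order-independent
  shuffled <- tc[sample(nrow(tc)), ]
  class(shuffled) <- class(tc)
  ph2 <- select_linear_phase(shuffled, "manual", window = c(0, 30))
  expect_equal(ph2$time_min, ph$time_min)
  ph3 <- select_linear_phase(ph, "manual", window = c(0, 30))
  expect_equal(as.data.frame(ph3), as.data.frame(ph))
  expect_error(select_linear_phase(tc, "manual"), "requires window")
})

test_that("auto phase selection matches prefix enumeration", {
  tc <- percent_remaining(slp_depletion_means())
  # independent oracle: enumerate prefixes, keep the longest with r2 >= floor
  enumerate <- function(floor_, min_pts) {
    best <- 0
    for (k in min_pts:nrow(tc)) {
      fit <- lm(tc$ln_pct_remaining[1:k] ~ tc$time_min[1:k])
      r2 <- summary(fit)$r.squared
      if (r2 >= floor_) best <- k
    }
    best
  }
  for (floor_ in c(0.95, 0.99, 0.995)) {
    expected_n <- enumerate(floor_, 4)
    ph <- select_linear_phase(tc, "auto", r2_floor = floor_, min_points = 4)
    expect_equal(nrow(ph), expected_n)
  }
  # on these data with floor 0.995 the phase ends at 30 min
  ph <- select_linear_phase(tc, "auto", r2_floor = 0.995, min_points = 4)
  expect_equal(max(ph$time_min), 30)
  # globally log-linear data select every point
  mono <- percent_remaining(
    simulate_depletion(depletion_sim_params(plateau_fraction = 0)))
  expect_equal(nrow(select_linear_phase(mono, "auto", r2_floor = 0.99)),
               nrow(mono))
  # impossible floor advises manual selection
  expect_error(select_linear_phase(tc, "auto", r2_floor = 0.99999),
               "manual")
})

test_that("depletion fit reproduces the published regression", {
  tc <- percent_remaining(slp_depletion_means())
  f <- fit_depletion(select_linear_phase(tc, "manual", window = c(0, 30)))
  expect_equal(round(f$slope, 4), -0.0291)
  expect_equal(round(f$intercept, 4), 4.6221)
  expect_equal(round(f$r2, 4), 0.9971)
})

test_that("noise-free monoexponential fit is exact", {
  d <- depletion_sim_params(k_dep = 0.05, plateau_fraction = 0,
                            replicate_cv = 0)
  tc <- percent_remaining(simulate_depletion(d))
  f <- fit_depletion(tc)
  expect_equal(f$slope, -0.05, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_warning(fit_depletion(tc[1:2, ]), "2 points")
})

test_that("half-life inverts the slope, with optional printed rounding", {
  expect_equal(round(half_life(-0.0291), 2), 23.82)
  expect_equal(half_life(-0.029149, slope_digits = 4),
               log(2) / 0.0291)
  expect_equal(half_life(-log(2)), 1)
  expect_error(half_life(0), "no depletion")
  expect_error(half_life(0.01), "no depletion")
})

test_that("intrinsic clearance scales by the physiological constants", {
  cl <- intrinsic_clearance(23.82)
  expect_equal(round(cl$clint_ml_min_kg), 34)
  expect_equal(cl$clint_ul_min_mg, 1000 * 0.693 / 23.82)
  # algebraic inversion: t_half = 0.693*45*26 gives 1 mL/min/kg
  expect_equal(intrinsic_clearance(0.693 * 45 * 26)$clint_ml_min_kg, 1)
  # linearity in the liver-mass constant
  d2 <- study_design(g_liver_per_kg_bw = 52)
  expect_equal(intrinsic_clearance(23.82, d2)$clint_ml_min_kg,
               2 * cl$clint_ml_min_kg)
  expect_error(intrinsic_clearance(0), "> 0")
})

test_that("clearance classification respects the configured bands", {
  expect_equal(classify_clearance(34), "intermediate")
  expect_equal(classify_clearance(10), "low")
  expect_equal(classify_clearance(50), "high")
  b <- clearance_bands(low_max = 40, high_min = 60)
  expect_equal(classify_clearance(34, b), "low")
  expect_error(clearance_bands(50, 40), "malformed")
})

test_that("full pipeline identity on noise-free monoexponential data", {
  for (k in c(0.01, 0.0291, 0.1)) {
    d <- depletion_sim_params(k_dep = k, plateau_fraction = 0,
                              replicate_cv = 0)
    st <- assess_stability(simulate_depletion(d), window = c(0, 30))
    expect_equal(st$k_dep, k, tolerance = 1e-10)
    expect_equal(st$t_half_min, log(2) / k, tolerance = 1e-10)
    expect_equal(st$clint_ml_min_kg,
                 0.693 / (log(2) / k) * 45 * 26, tolerance = 1e-10)
  }
})

test_that("result invariants: t1/2 * k = ln 2 and unit ratio 1.17", {
  set.seed(21)
  for (i in 1:10) {
    d <- depletion_sim_params(k_dep = runif(1, 0.005, 0.1),
                              plateau_fraction = 0,
                              replicate_cv = 0.03, seed = i)
    st <- assess_stability(simulate_depletion(d), window = c(0, 30))
    expect_equal(st$t_half_min * st$k_dep, log(2), tolerance = 1e-12)
    expect_equal(st$clint_ml_min_kg / st$clint_ul_min_mg, 45 * 26 / 1000)
  }
})

test_that("printed-rounding mode reproduces the published arithmetic chain", {
  st <- assess_stability(slp_depletion_means(), window = c(0, 30),
                         rounding = "printed")
  expect_equal(round(st$t_half_min, 2), 23.82)
  expect_equal(round(st$clint_ml_min_kg), 34)
  expect_equal(st$clearance_class, "intermediate")
  # full precision differs by about 0.1%
  st_full <- assess_stability(slp_depletion_means(), window = c(0, 30))
  expect_lt(abs(st_full$t_half_min - st$t_half_min) / st$t_half_min, 0.005)
})
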