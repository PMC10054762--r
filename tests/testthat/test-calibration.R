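test_that("OLS kernel matches brute-force normal equations", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- runif(n, 0, 100)
    y <- runif(1, -2, 2) * x + runif(1, -5, 5) + rnorm(n)
    f <- ols_fit(x, y)
    oracle <- ols_normal_equations(x, y)
    expect_equal(f$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-10)
  }
})

test_that("calibration fit recovers exact lines and rejects bad designs", {
  # two-point exact line
  std <- make_standards(levels = c(1, 3), slope = 2, intercept = 3)
  fit <- fit_calibration(std)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 3, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  # noise-free 11-level curve on the reference response line
  fit2 <- fit_calibration(make_standards())
  expect_equal(fit2$slope, 1.7298, tolerance = 1e-12)
  expect_equal(fit2$intercept, 3.62941, tolerance = 1e-12)
  expect_equal(fit2$r2, 1)
  # degenerate designs
  expect_error(fit_calibration(make_standards(levels = 5)),
               "insufficient data")
  expect_error(fit_calibration(std[0, ]), "no standard rows")
})

test_that("r2 = 1 for noise-free calibration at any >= 2 distinct levels", {
  set.seed(9)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    lv <- sort(sample(seq(1, 3000, by = 7), k))
    fit <- fit_calibration(make_standards(levels = lv, slope = runif(1, .1, 3),
                                          intercept = runif(1, 0, 5)))
    expect_equal(fit$r2, 1)
  }
})

test_that("the shared kernel reproduces the depletion regression", {
  # the published time/ln(%) pairs fed through the same OLS core
  tc <- slp_depletion_means()
  ln <- log(100 * tc$conc / 626)
  keep <- tc$time_min <= 30
  f <- ols_fit(tc$time_min[keep], ln[keep])
  expect_equal(round(f$slope, 4), -0.0291)
})

test_that("back-calculation inverts the line and round-trips", {
  fit <- fit_calibration(make_standards(levels = c(1, 3), slope = 2,
                                        intercept = 3))
  expect_equal(back_calculate(fit, 9), 3)
  refit <- fit_calibration(make_standards())
  expect_equal(back_calculate(refit, 3.62941), 0, tolerance = 1e-9)
  expect_equal(back_calculate(refit, 1.7298 * 900 + 3.62941), 900)
  set.seed(5)
  x <- runif(50, 0, 3000)
  expect_equal(back_calculate(refit, refit$slope * x + refit$intercept), x,
               tolerance = 1e-12)
  fit0 <- refit; fit0$slope <- 0
  expect_error(back_calculate(fit0, 1), "zero slope")
})

test_that("level summaries reproduce published accuracy/recovery figures", {
  # mid-level QC: mean 898.67 at nominal 900
  vals <- 898.67 + c(-0.5, 0.5)
  s <- summarize_level(vals, 900)
  expect_equal(round(s$accuracy_pct, 2), -0.15)
  expect_equal(round(s$accuracy_pct, 3), -0.148)
  expect_equal(round(s$recovery_pct, 2), 99.85)
  # high QC: mean 2387.68 at nominal 2400
  s2 <- summarize_level(2387.68 + c(-1, 1), 2400)
  expect_equal(round(s2$recovery_pct, 2), 99.49)
  expect_equal(round(s2$accuracy_pct, 2), -0.51)
  # constant replicates equal to nominal
  s3 <- summarize_level(c(50, 50, 50), 50)
  expect_equal(s3$sd, 0)
  expect_equal(s3$rsd_pct, 0)
  expect_equal(s3$accuracy_pct, 0)
  expect_equal(s3$recovery_pct, 100)
  expect_error(summarize_level(1, 1), "insufficient replicates")
})

test_that("recovery - accuracy = 100 for every level summary", {
  set.seed(31)
  for (i in 1:25) {
    nominal <- runif(1, 1, 3000)
    vals <- nominal * (1 + rnorm(6, 0, 0.05))
    s <- summarize_level(vals, nominal)
    expect_equal(s$recovery_pct - s$accuracy_pct, 100)
  }
})

test_that("sample SD uses the n-1 denominator", {
  s <- summarize_level(c(1, 2, 3), 2)
  expect_equal(s$sd, 1)  # sqrt(((1)^2+0+(1)^2)/2)
})

test_that("LOD/LOQ follow the intercept-dispersion formulas", {
  f <- function(slope, intercept) {
    structure(list(slope = slope, intercept = intercept, r2 = 1,
                   n_points = 11, residual_sd = 0, intercept_se = NA_real_),
              class = "calibration_fit")
  }
  fits <- list(f(2, 3.5), f(2, 3.7))
  ll <- lod_loq(fits)
  # independent hand arithmetic from the stated formulas
  sd_int <- sqrt(((3.5 - 3.6)^2 + (3.7 - 3.6)^2) / 1)
  expect_equal(ll$lod, 3.3 * sd_int / 2, tolerance = 1e-10)
  expect_equal(ll$loq, 10 * sd_int / 2, tolerance = 1e-10)
  # identical intercepts -> zero limits
  ll0 <- lod_loq(list(f(2, 3.5), f(2, 3.5)))
  expect_equal(ll0$lod, 0)
  expect_equal(ll0$loq, 0)
  expect_error(lod_loq(list(f(2, 3.5))), "insufficient curves")
})

test_that("loq/lod = 10/3.3 for any pooled curves", {
  set.seed(77)
  for (i in 1:20) {
    fits <- lapply(1:sample(2:6, 1), function(j)
      fit_calibration(make_standards(levels = c(1, 50, 3000),
                                     slope = runif(1, .5, 3),
                                     intercept = runif(1, 0, 5))))
    ll <- lod_loq(fits)
    if (ll$lod > 0) expect_equal(ll$loq / ll$lod, 10 / 3.3)
  }
})

test_that("per-batch curve fitting feeds multi-curve LOD/LOQ", {
  std <- rbind(make_standards(slope = 1.73, intercept = 3.6),
               make_standards(slope = 1.73, intercept = 3.7,
                              batch_offset = 1))
  curves <- fit_calibration_curves(std)
  expect_length(curves, 2)
  ll <- lod_loq(curves)
  expect_equal(ll$sd_intercept, sd(c(3.6, 3.7)), tolerance = 1e-9)
})
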