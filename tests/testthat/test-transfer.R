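cal_simple <- function(a1 = 1, b1 = 0, a2 = 2, b2 = 20, ...) {
  transfer_calibration(
    pw_slope = a1, pw_intercept = b1,
    pw_direction = "phosphate_to_water",
    wt_slope = a2, wt_intercept = b2,
    wt_direction = "water_to_temperature", ...
  )
}

test_that("enamel_to_water applies or inverts the published map exactly", {
  expect_equal(enamel_to_water(18, cal_simple()), 18)
  inv <- transfer_calibration(
    pw_slope = 1.1, pw_intercept = 24.0,
    pw_direction = "water_to_phosphate",
    wt_slope = 1, wt_intercept = 0,
    wt_direction = "water_to_temperature"
  )
  expect_equal(enamel_to_water(13.0, inv), -10.0)
})

test_that("water -> enamel -> water round-trips to machine precision", {
  set.seed(9)
  for (dir in c("phosphate_to_water", "water_to_phosphate")) {
    a <- runif(1, 0.7, 1.3)
    b <- runif(1, 15, 30)
    cal <- transfer_calibration(
      pw_slope = a, pw_intercept = b, pw_direction = dir,
      wt_slope = 1, wt_intercept = 0,
      wt_direction = "water_to_temperature"
    )
    dw <- runif(100, -15, 0)
    # construct the enamel values from the published map and invert
    dp <- if (dir == "water_to_phosphate") a * dw + b else (dw - b) / a
    expect_lt(max(abs(enamel_to_water(dp, cal) - dw)), 1e-10)
  }
})

test_that("water_to_temperature arithmetic and MAT commutation", {
  cal <- cal_simple(a2 = 2, b2 = 20)
  expect_equal(water_to_temperature(-5, cal), 10)
  warm <- water_to_temperature(-3, cal, "warm_extreme")
  cold <- water_to_temperature(-8, cal, "cold_extreme")
  expect_equal(warm, 14)
  expect_equal(cold, 4)
  # affine maps commute with averaging: MAT equals map of mean delta
  expect_equal((warm + cold) / 2, water_to_temperature(-5.5, cal))
  # equal delta spacing maps to equal temperature spacing
  temps <- water_to_temperature(c(-8, -6, -4, -2), cal)
  expect_equal(diff(temps), rep(diff(temps)[1], 3))
})

test_that("seasonal water-temperature maps are used when defined", {
  cal <- transfer_calibration(
    pw_slope = 1, pw_intercept = 0, pw_direction = "phosphate_to_water",
    wt_slope = 2, wt_intercept = 20, wt_direction = "water_to_temperature",
    wt_seasonal = list(warm = list(slope = 3, intercept = 25))
  )
  expect_equal(water_to_temperature(-5, cal, "warm_extreme"), 10)
  expect_equal(water_to_temperature(-5, cal, "cold_extreme"), 10)  # falls back
  expect_equal(water_to_temperature(-5, cal, "annual"), 10)
})

test_that("compound error is zero without uncertainty and seeded", {
  cal <- cal_simple()
  expect_equal(compound_error_mc(18, 0, cal, n_mc = 1000, seed = 1), 0)
  cal_u <- cal_simple(pw_resid_se = 0.3)
  e1 <- compound_error_mc(18, 0.2, cal_u, n_mc = 2000, seed = 5)
  e2 <- compound_error_mc(18, 0.2, cal_u, n_mc = 2000, seed = 5)
  e3 <- compound_error_mc(18, 0.2, cal_u, n_mc = 2000, seed = 6)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
  expect_equal(e1, e3, tolerance = 0.1)
  expect_error(compound_error_mc(18, -0.1, cal_u, n_mc = 2000),
               class = "paleoseas_config_error")
})

test_that("MC propagation matches the analytic affine oracle", {
  # only input noise sigma through slopes a1 * a2: sd(T) = |a1*a2| * sigma
  a1 <- 1.1; a2 <- 2.3; sigma <- 0.25
  cal <- cal_simple(a1 = a1, b1 = 3, a2 = a2, b2 = 20)
  n <- 10000
  mc <- compound_error_mc(18, sigma, cal, n_mc = n, seed = 11)
  analytic <- abs(a1 * a2) * sigma
  mc_se <- analytic / sqrt(2 * (n - 1))
  expect_lt(abs(mc - analytic), 3 * mc_se)
})

test_that("compound error is monotone in every component sd", {
  base <- list(d18O_sd = 0.1, pw_slope_se = 0.01, pw_resid_se = 0.2,
               wt_intercept_se = 0.1, wt_resid_se = 0.2)
  err_with <- function(mod) {
    p <- utils::modifyList(base, mod)
    cal <- cal_simple(pw_slope_se = p$pw_slope_se,
                      pw_resid_se = p$pw_resid_se,
                      wt_intercept_se = p$wt_intercept_se,
                      wt_resid_se = p$wt_resid_se)
    compound_error_mc(18, p$d18O_sd, cal, n_mc = 20000, seed = 2)
  }
  e0 <- err_with(list())
  for (comp in names(base)) {
    bigger <- as.list(setNames(base[[comp]] * 3, comp))
    expect_gt(err_with(bigger), e0)
  }
})

test_that("reconstruct_temperatures orders quantities and handles partials", {
  est <- tibble::tibble(
    tooth_id = c("T1", "T2"), layer_id = "2", method = "fitted",
    summer_peak = c(19, 18.5), winter_trough = c(15, NA),
    mean_annual = c(17, NA), seasonality = c(4, NA),
    completeness = c("both_extremes", "peak_only")
  )
  cal <- example_calibration()
  tt <- reconstruct_temperatures(est, cal, n_mc = 1000, seed = 4)
  expect_gt(tt$T_warmest_month[1], tt$MAT[1])
  expect_gt(tt$MAT[1], tt$T_coldest_month[1])
  expect_true(is.na(tt$MAT[2]) && is.na(tt$T_coldest_month[2]))
  expect_true(all(tt$err_T_warmest > 0))
  lt <- layer_temperatures(tt, cal,
                           reference = c(T_warmest_month = 20.5,
                                         T_coldest_month = 4.9))
  # tooth-mean and layer-delta routes agree for a single annual affine map
  tm <- lt[lt$route == "tooth_mean", ]
  ld <- lt[lt$route == "layer_delta", ]
  expect_equal(tm$T_warmest_month_mean, ld$T_warmest_month_mean)
  expect_true("delta_modern_warmest" %in% names(lt))
})

test_that("calibration YAML round-trips through read_calibration", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "phosphate_water:",
    "  direction: water_to_phosphate",
    "  slope: 0.94", "  intercept: 23.3", "  resid_se: 0.3",
    "water_temperature:",
    "  direction: temperature_to_water",
    "  slope: 0.58", "  intercept: -13.6"
  ), tmp)
  cal <- read_calibration(tmp)
  ref <- example_calibration(with_uncertainty = FALSE)
  expect_equal(enamel_to_water(17, cal), enamel_to_water(17, ref))
  expect_equal(water_to_temperature(-7, cal), water_to_temperature(-7, ref))
  template <- system.file("extdata", "calibration_template.yml",
                          package = "paleoseas")
  expect_s3_class(read_calibration(template), "transfer_calibration")
})
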