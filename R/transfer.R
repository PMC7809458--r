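#' Define the two-stage isotope-temperature calibration
#'
#' Temperature reconstruction chains two affine relationships: enamel
#' phosphate d18O to drinking-water d18O, and drinking-water
#' (approximately precipitation) d18O to air temperature. Published
#' calibrations come in either direction; each stage records its published
#' slope/intercept and direction and is inverted exactly when needed, so no
#' precision is lost transcribing a regression stated the other way round.
#'
#' Coefficient uncertainties (standard errors, optional slope-intercept
#' covariance, and the regression residual standard error) feed the
#' Monte-Carlo compound-error propagation in [compound_error_mc()].
#'
#' @param pw_slope,pw_intercept Phosphate/water stage coefficients as
#'   published.
#' @param pw_direction `"phosphate_to_water"` (water = slope*phosphate +
#'   intercept) or `"water_to_phosphate"` (the published regression
#'   predicts phosphate from water and is inverted).
#' @param wt_slope,wt_intercept Water/temperature stage coefficients as
#'   published.
#' @param wt_direction `"water_to_temperature"` or
#'   `"temperature_to_water"`.
#' @param pw_slope_se,pw_intercept_se,pw_resid_se,pw_cov Uncertainties of
#'   the phosphate/water stage (standard errors, residual se in permil,
#'   slope-intercept covariance), all in the published direction.
#' @param wt_slope_se,wt_intercept_se,wt_resid_se,wt_cov Likewise for the
#'   water/temperature stage (residual se in the published response units).
#' @param wt_seasonal Optional list with elements `warm` and/or `cold`,
#'   each a list like the annual water/temperature stage
#'   (`slope`, `intercept`, `direction`, and `*_se`/`cov` fields), used for
#'   season-specific regressions; by default the annual map is applied to
#'   seasonal extremes.
#' @return An object of class `"transfer_calibration"`.
#' @seealso [example_calibration()], [read_calibration()]
#' @export
transfer_calibration <- function(pw_slope, pw_intercept,
                                 pw_direction = c("phosphate_to_water",
                                                  "water_to_phosphate"),
                                 wt_slope, wt_intercept,
                                 wt_direction = c("water_to_temperature",
                                                  "temperature_to_water"),
                                 pw_slope_se = 0, pw_intercept_se = 0,
                                 pw_resid_se = 0, pw_cov = 0,
                                 wt_slope_se = 0, wt_intercept_se = 0,
                                 wt_resid_se = 0, wt_cov = 0,
                                 wt_seasonal = NULL) {
  pw_direction <- match.arg(pw_direction)
  wt_direction <- match.arg(wt_direction)
  for (v in c(pw_slope, wt_slope)) {
    if (!is.finite(v) || v == 0) {
      stop_paleoseas("calibration slopes must be finite and non-zero",
                     "paleoseas_config_error")
    }
  }
  for (v in c(pw_slope_se, pw_intercept_se, pw_resid_se,
              wt_slope_se, wt_intercept_se, wt_resid_se)) {
    assert_number(v, "standard error", lower = 0)
  }
  stage <- function(slope, intercept, direction, slope_se, intercept_se,
                    resid_se, cov) {
    list(slope = slope, intercept = intercept, direction = direction,
         slope_se = slope_se, intercept_se = intercept_se,
         resid_se = resid_se, cov = cov)
  }
  seasonal <- NULL
  if (!is.null(wt_seasonal)) {
    seasonal <- purrr::map(wt_seasonal, function(s) {
      stage(s$slope, s$intercept,
            s$direction %||% "water_to_temperature",
            s$slope_se %||% 0, s$intercept_se %||% 0,
            s$resid_se %||% 0, s$cov %||% 0)
    })
  }
  structure(
    list(
      pw = stage(pw_slope, pw_intercept, pw_direction,
                 pw_slope_se, pw_intercept_se, pw_resid_se, pw_cov),
      wt = stage(wt_slope, wt_intercept, wt_direction,
                 wt_slope_se, wt_intercept_se, wt_resid_se, wt_cov),
      wt_seasonal = seasonal
    ),
    class = "transfer_calibration"
  )
}

# effective forward (a, b) of a stage given its published direction:
# forward means "input of this pipeline stage -> output of this stage"
stage_forward <- function(stage, forward_direction) {
  if (stage$direction == forward_direction) {
    c(a = stage$slope, b = stage$intercept)
  } else {
    c(a = 1 / stage$slope, b = -stage$intercept / stage$slope)
  }
}

wt_stage <- function(cal, season) {
  if (season %in% c("warm_extreme", "cold_extreme") &&
      !is.null(cal$wt_seasonal)) {
    key <- if (season == "warm_extreme") "warm" else "cold"
    if (!is.null(cal$wt_seasonal[[key]])) return(cal$wt_seasonal[[key]])
  }
  cal$wt
}

#' @export
print.transfer_calibration <- function(x, ...) {
  pw <- stage_forward(x$pw, "phosphate_to_water")
  wt <- stage_forward(x$wt, "water_to_temperature")
  cat("Transfer calibration\n")
  cat(sprintf("  enamel -> water: d18Ow = %.4f * d18Op + %.4f  (published %s)\n",
              pw["a"], pw["b"], x$pw$direction))
  cat(sprintf("  water -> temperature: T = %.4f * d18Ow + %.4f  (published %s)\n",
              wt["a"], wt["b"], x$wt$direction))
  if (!is.null(x$wt_seasonal)) {
    cat("  seasonal water -> temperature maps:",
        paste(names(x$wt_seasonal), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Illustrative calibration coefficients
#'
#' A synthetic, field-plausible coefficient set for examples, tests, and the
#' synthetic-data generator: a large-bovid phosphate-water relationship
#' published in the water-to-phosphate direction
#' (`d18Op = 0.94 d18Ow + 23.3`) and a mid-latitude
#' precipitation-temperature relationship published in the
#' temperature-to-water direction (`d18Ow = 0.58 T - 13.6`). These are NOT
#' a published ground truth for any particular site or species; real
#' analyses must transcribe the calibration appropriate to their taxon and
#' region (see [read_calibration()] and the shipped
#' `calibration_template.yml`).
#'
#' @param with_uncertainty If `TRUE` (default), attach plausible coefficient
#'   standard errors and residual standard errors so compound errors are
#'   non-zero; `FALSE` gives an exact deterministic calibration.
#' @return A [transfer_calibration()].
#' @export
example_calibration <- function(with_uncertainty = TRUE) {
  transfer_calibration(
    pw_slope = 0.94, pw_intercept = 23.3,
    pw_direction = "water_to_phosphate",
    wt_slope = 0.58, wt_intercept = -13.6,
    wt_direction = "temperature_to_water",
    pw_slope_se = if (with_uncertainty) 0.02 else 0,
    pw_intercept_se = if (with_uncertainty) 0.25 else 0,
    pw_resid_se = if (with_uncertainty) 0.3 else 0,
    wt_slope_se = if (with_uncertainty) 0.015 else 0,
    wt_intercept_se = if (with_uncertainty) 0.2 else 0,
    wt_resid_se = if (with_uncertainty) 0.35 else 0
  )
}

#' Read a calibration from a YAML file
#'
#' Reads the key-value calibration format documented in the shipped
#' template (`system.file("extdata", "calibration_template.yml",
#' package = "paleoseas")`).
#'
#' @param path Path to a YAML calibration file.
#' @return A [transfer_calibration()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop_paleoseas(sprintf("calibration file not found: %s", path),
                   "paleoseas_config_error")
  }
  y <- yaml::read_yaml(path)
  pw <- y$phosphate_water
  wt <- y$water_temperature
  if (is.null(pw) || is.null(wt)) {
    stop_paleoseas(
      "calibration file must define `phosphate_water` and `water_temperature` blocks",
      "paleoseas_config_error"
    )
  }
  transfer_calibration(
    pw_slope = pw$slope, pw_intercept = pw$intercept,
    pw_direction = pw$direction %||% "phosphate_to_water",
    wt_slope = wt$slope, wt_intercept = wt$intercept,
    wt_direction = wt$direction %||% "water_to_temperature",
    pw_slope_se = pw$slope_se %||% 0,
    pw_intercept_se = pw$intercept_se %||% 0,
    pw_resid_se = pw$resid_se %||% 0, pw_cov = pw$cov %||% 0,
    wt_slope_se = wt$slope_se %||% 0,
    wt_intercept_se = wt$intercept_se %||% 0,
    wt_resid_se = wt$resid_se %||% 0, wt_cov = wt$cov %||% 0,
    wt_seasonal = y$water_temperature_seasonal
  )
}

#' Convert enamel phosphate d18O to drinking-water d18O
#'
#' @param d18Op Numeric vector, permil VSMOW.
#' @param cal A [transfer_calibration()].
#' @return Drinking-water d18O, permil VSMOW.
#' @export
enamel_to_water <- function(d18Op, cal) {
  stopifnot(inherits(cal, "transfer_calibration"))
  ab <- stage_forward(cal$pw, "phosphate_to_water")
  unname(ab["a"] * d18Op + ab["b"])
}

#' Convert drinking-water d18O to air temperature
#'
#' @param d18Odw Numeric vector, permil VSMOW.
#' @param cal A [transfer_calibration()].
#' @param season Which water-temperature map to apply: `"annual"` (default;
#'   the annual-scale regression applied to any value, including seasonal
#'   extremes), `"warm_extreme"` or `"cold_extreme"` (use the seasonal maps
#'   when the calibration defines them, otherwise fall back to annual).
#' @return Air temperature, degrees C.
#' @export
water_to_temperature <- function(d18Odw, cal,
                                 season = c("annual", "warm_extreme",
                                            "cold_extreme")) {
  stopifnot(inherits(cal, "transfer_calibration"))
  season <- match.arg(season)
  ab <- stage_forward(wt_stage(cal, season), "water_to_temperature")
  unname(ab["a"] * d18Odw + ab["b"])
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

draw_stage <- function(stage, n) {
  # joint normal draw of (slope, intercept) with optional covariance
  s2 <- stage$slope_se^2
  i2 <- stage$intercept_se^2
  cv <- stage$cov
  if (s2 == 0 && i2 == 0) {
    slope <- rep(stage$slope, n)
    intercept <- rep(stage$intercept, n)
  } else {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    slope <- stage$slope + sqrt(s2) * z1
    if (s2 > 0) {
      rho <- cv / sqrt(s2 * i2 + (s2 * i2 == 0))
      rho <- max(-1, min(1, if (is.finite(rho)) rho else 0))
    } else rho <- 0
    intercept <- stage$intercept +
      sqrt(i2) * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  list(slope = slope, intercept = intercept)
}

apply_stage_draw <- function(x, draw, stage, forward_direction, resid) {
  fwd <- stage$direction == forward_direction
  out <- if (fwd) draw$slope * x + draw$intercept
         else (x - draw$intercept) / draw$slope
  # residual scatter of the regression, in its response units; when the
  # published response is the stage input, the scatter maps through 1/slope
  if (stage$resid_se > 0) {
    out <- out + if (fwd) stage$resid_se * resid
                 else stage$resid_se * resid / draw$slope
  }
  out
}

#' Monte-Carlo compound error of a reconstructed temperature
#'
#' Propagates all uncertainty sources through the two-stage transfer by
#' simulation: the input d18O (measurement plus fit uncertainty, as one
#' standard deviation), the published coefficients of both calibration
#' stages (standard errors, with covariance when provided), and the
#' residual scatter of each regression. Returns the half-width of the MC
#' temperature distribution: by default its standard deviation; with
#' `coverage` set, half the width of the central interval at that coverage.
#'
#' @param d18O Central enamel d18O value, permil.
#' @param d18O_sd One standard deviation of the input value, permil
#'   (>= 0).
#' @param cal A [transfer_calibration()].
#' @param n_mc Number of draws (>= 1000; default 10000).
#' @param seed Integer seed; same seed gives identical output, and the
#'   caller's RNG state is untouched.
#' @param season Passed to [water_to_temperature()].
#' @param coverage `NULL` (default: report the MC standard deviation) or a
#'   coverage probability in (0, 1), e.g. `0.95` for half the central 95%
#'   interval.
#' @return Error half-width in degrees C.
#' @export
compound_error_mc <- function(d18O, d18O_sd, cal, n_mc = 10000, seed = 1L,
                              season = "annual", coverage = NULL) {
  stopifnot(inherits(cal, "transfer_calibration"))
  assert_number(d18O, "d18O")
  if (!is.numeric(d18O_sd) || d18O_sd < 0) {
    stop_paleoseas("`d18O_sd` must be a non-negative number",
                   "paleoseas_config_error")
  }
  assert_number(n_mc, "n_mc", lower = 1000)
  draws <- mc_temperature_draws(d18O, d18O_sd, cal, n_mc, seed, season)
  if (is.null(coverage)) {
    sd(draws)
  } else {
    assert_number(coverage, "coverage", lower = 1e-6, upper = 1 - 1e-6)
    q <- quantile(draws, c((1 - coverage) / 2, (1 + coverage) / 2),
                  names = FALSE)
    diff(q) / 2
  }
}

mc_temperature_draws <- function(d18O, d18O_sd, cal, n_mc, seed, season) {
  wt <- wt_stage(cal, season)
  with_local_seed(seed, {
    dp <- d18O + d18O_sd * rnorm(n_mc)
    pw_draw <- draw_stage(cal$pw, n_mc)
    dw <- apply_stage_draw(dp, pw_draw, cal$pw, "phosphate_to_water",
                           rnorm(n_mc))
    wt_draw <- draw_stage(wt, n_mc)
    apply_stage_draw(dw, wt_draw, wt, "water_to_temperature", rnorm(n_mc))
  })
}

#' Reconstruct seasonal temperatures per tooth
#'
#' Maps damping-corrected summer-peak, winter-trough and mean-annual enamel
#' d18O values through [enamel_to_water()] and [water_to_temperature()] to
#' the mean temperature of the warmest month, the coldest month, and the
#' mean annual temperature, each with a Monte-Carlo compound error.
#'
#' @param estimates A corrected seasonal-estimate tibble
#'   ([correct_extremes()]; raw [extract_seasonal()] output also works, the
#'   temperatures are then uncorrected for damping).
#' @param cal A [transfer_calibration()].
#' @param d18O_sd One-sd uncertainty of each extreme d18O value, permil
#'   (measurement plus fit; default 0.2, the typical replicate
#'   reproducibility of enamel phosphate measurements).
#' @param n_mc,seed Monte-Carlo settings (see [compound_error_mc()]). Each
#'   tooth/quantity uses a sub-seed derived from `seed` so rows are
#'   independent but the whole table is reproducible.
#' @param coverage Passed to [compound_error_mc()].
#' @return A tibble per tooth: `T_warmest_month`, `T_coldest_month`, `MAT`
#'   (degrees C), their compound errors `err_*`, `n_mc` and `seed`.
#' @export
reconstruct_temperatures <- function(estimates, cal, d18O_sd = 0.2,
                                     n_mc = 10000, seed = 1L,
                                     coverage = NULL) {
  stopifnot(inherits(cal, "transfer_calibration"))
  map_temp <- function(d18O, season) {
    out <- rep(NA_real_, length(d18O))
    ok <- is.finite(d18O)
    out[ok] <- water_to_temperature(enamel_to_water(d18O[ok], cal), cal,
                                    season = season)
    out
  }
  err_for <- function(d18O, season, idx) {
    purrr::map2_dbl(d18O, idx, function(v, i) {
      if (!is.finite(v)) return(NA_real_)
      compound_error_mc(v, d18O_sd, cal, n_mc = n_mc,
                        seed = (seed + 7919L * i) %% .Machine$integer.max,
                        season = season, coverage = coverage)
    })
  }
  idx <- seq_len(nrow(estimates))
  out <- estimates %>%
    mutate(
      T_warmest_month = map_temp(.data$summer_peak, "warm_extreme"),
      T_coldest_month = map_temp(.data$winter_trough, "cold_extreme"),
      MAT = map_temp(.data$mean_annual, "annual"),
      err_T_warmest = err_for(.data$summer_peak, "warm_extreme", idx),
      err_T_coldest = err_for(.data$winter_trough, "cold_extreme",
                              idx + nrow(estimates)),
      err_MAT = err_for(.data$mean_annual, "annual",
                        idx + 2L * nrow(estimates)),
      n_mc = n_mc, seed = seed
    )
  out
}

#' Aggregate tooth temperatures to layer level
#'
#' Reports both aggregation routes: averaging per-tooth reconstructed
#' temperatures (`route = "tooth_mean"`, the default interpretation) and
#' mapping the layer-mean d18O values through the calibration
#' (`route = "layer_delta"`). For a single annual affine map the two agree
#' exactly on teeth with both extremes; with seasonal maps or partial teeth
#' they can differ, which is why both are shown.
#'
#' @param tooth_temps Output of [reconstruct_temperatures()].
#' @param cal The same [transfer_calibration()].
#' @param reference Optional named numeric vector of modern reference
#'   temperatures, e.g. `c(T_warmest_month = 20.5, T_coldest_month = 4.9)`;
#'   matching `delta_modern_*` columns are added to the `tooth_mean` route.
#' @return A tibble with one row per layer and route: layer n, mean, sd of
#'   each temperature quantity and the mean per-tooth compound error.
#' @export
layer_temperatures <- function(tooth_temps, cal, reference = NULL) {
  mean_or_na <- function(x) if (any(is.finite(x))) mean(x, na.rm = TRUE) else NA_real_
  sd_or_na <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) >= 2) sd(x) else NA_real_
  }
  tooth_route <- tooth_temps %>%
    group_by(.data$layer_id) %>%
    summarise(
      route = "tooth_mean",
      n_teeth = dplyr::n(),
      across(all_of(c("T_warmest_month", "T_coldest_month", "MAT")),
             list(mean = mean_or_na, sd = sd_or_na)),
      err_T_warmest = mean_or_na(.data$err_T_warmest),
      err_T_coldest = mean_or_na(.data$err_T_coldest),
      err_MAT = mean_or_na(.data$err_MAT),
      .groups = "drop"
    )
  delta_route <- tooth_temps %>%
    group_by(.data$layer_id) %>%
    summarise(
      n_teeth = dplyr::n(),
      peak = mean_or_na(.data$summer_peak),
      trough = mean_or_na(.data$winter_trough),
      annual = mean_or_na(.data$mean_annual),
      .groups = "drop"
    ) %>%
    mutate(
      route = "layer_delta",
      T_warmest_month_mean = as.numeric(water_to_temperature(
        enamel_to_water(.data$peak, cal), cal, "warm_extreme")),
      T_coldest_month_mean = as.numeric(water_to_temperature(
        enamel_to_water(.data$trough, cal), cal, "cold_extreme")),
      MAT_mean = as.numeric(water_to_temperature(
        enamel_to_water(.data$annual, cal), cal, "annual"))
    ) %>%
    select("layer_id", "route", "n_teeth", "T_warmest_month_mean",
           "T_coldest_month_mean", "MAT_mean")
  out <- bind_rows(tooth_route, delta_route) %>%
    mutate(layer_id = layer_factor(.data$layer_id)) %>%
    arrange(.data$layer_id, .data$route) %>%
    mutate(layer_id = as.character(.data$layer_id))
  if (!is.null(reference)) {
    if ("T_warmest_month" %in% names(reference)) {
      out$delta_modern_warmest <-
        out$T_warmest_month_mean - reference[["T_warmest_month"]]
    }
    if ("T_coldest_month" %in% names(reference)) {
      out$delta_modern_coldest <-
        out$T_coldest_month_mean - reference[["T_coldest_month"]]
    }
    if ("MAT" %in% names(reference)) {
      out$delta_modern_MAT <- out$MAT_mean - reference[["MAT"]]
    }
  }
  out
}
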