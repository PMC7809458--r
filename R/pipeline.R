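#' Run the full paleoseasonality pipeline
#'
#' Orchestrates the stages end to end: per-tooth sinusoid fitting and
#' classification, extremum extraction, damping correction, temperature
#' reconstruction with compound errors, inter-layer statistics, strontium
#' locality screening and collagen QC/trends. Every stage's table is kept
#' in the returned object so any number in the stats report is traceable
#' to an intermediate, and stages are individually re-runnable through
#' their exported functions.
#'
#' @param enamel Validated enamel tibble ([read_samples()]).
#' @param cal A [transfer_calibration()].
#' @param maturation_length,sample_length Damping-window widths, mm
#'   (required unless `damping = FALSE`).
#' @param sr,collagen Optional validated Sr / collagen tibbles.
#' @param baseline Optional [sr_baseline()] for locality screening
#'   (required when `sr` is given).
#' @param method Extremum extraction method (see [extract_extremes()]).
#' @param k Sinusoidality classification threshold ([classify_series()]).
#' @param damping Apply the damping correction? When `FALSE` raw extremes
#'   feed the transfer directly.
#' @param f_floor Damping reliability floor ([correct_extremes()]).
#' @param d18O_sd,n_mc,coverage Compound-error settings
#'   ([reconstruct_temperatures()]).
#' @param seed Integer seed for all Monte-Carlo stages; recorded in the
#'   report.
#' @param reference Optional modern reference temperatures
#'   ([layer_temperatures()]).
#' @param contrasts Layer pairs (earlier first) for Cohen's d, as a list of
#'   length-2 character vectors; defaults to consecutive stratigraphic
#'   pairs present in the data.
#' @return An object of class `"seasonality_run"`: a list with `fits`,
#'   `estimates_raw`, `estimates`, `tooth_temperatures`,
#'   `layer_temperatures`, `stats` (summaries, ANOVA, Levene, Tukey,
#'   normality, effect sizes, correlation), `sr_screen`, `sr_homogeneity`,
#'   `collagen_qc`, `collagen_trends`, and a `report` recording settings,
#'   seed and exclusions.
#' @export
run_seasonality_pipeline <- function(enamel, cal,
                                     maturation_length = NULL,
                                     sample_length = NULL,
                                     sr = NULL, collagen = NULL,
                                     baseline = NULL,
                                     method = c("observed", "fitted"),
                                     k = 2, damping = TRUE, f_floor = 0.3,
                                     d18O_sd = 0.2, n_mc = 10000,
                                     coverage = NULL, seed = 1L,
                                     reference = NULL, contrasts = NULL) {
  method <- match.arg(method)
  if (damping) {
    assert_number(maturation_length, "maturation_length", lower = 0)
    assert_number(sample_length, "sample_length", lower = 0)
  }

  fits <- fit_seasonal(enamel, k = k)
  estimates_raw <- extract_seasonal(fits, method = method)
  excluded <- attr(estimates_raw, "excluded")

  estimates <- if (damping) {
    correct_extremes(estimates_raw, fits, maturation_length, sample_length,
                     f_floor = f_floor)
  } else {
    estimates_raw
  }

  tooth_temps <- reconstruct_temperatures(estimates, cal,
                                          d18O_sd = d18O_sd, n_mc = n_mc,
                                          seed = seed, coverage = coverage)
  layer_temps <- layer_temperatures(tooth_temps, cal, reference = reference)

  seasons <- c("summer", "winter", "mean_annual")
  summaries <- purrr::map(setNames(seasons, seasons),
                          ~ layer_summary(estimates, season = .x))

  winter <- season_values(estimates, "winter")
  enough <- length(unique(winter$layer_id)) >= 2 &&
    all(table(winter$layer_id) >= 2)
  stats <- list(
    summaries = summaries,
    anova_winter = if (enough) anova_oneway(winter) else NULL,
    levene_winter = if (enough) levene_test(winter) else NULL,
    tukey_winter = if (enough) tukey_hsd(winter) else NULL,
    normality_winter = normality_check(winter$value)
  )

  if (is.null(contrasts)) {
    present <- levels(droplevels(layer_factor(unique(winter$layer_id))))
    contrasts <- if (length(present) >= 2) {
      purrr::map(seq_len(length(present) - 1),
                 ~ present[c(.x, .x + 1)])
    } else list()
  }
  stats$effect_sizes <- purrr::map(contrasts, function(pr) {
    purrr::map(setNames(seasons, seasons), function(s) {
      tryCatch(layer_cohens_d(estimates, pr[1], pr[2], season = s),
               paleoseas_error = function(e) NULL)
    }) %>% bind_rows()
  }) %>% bind_rows()

  if (!is.null(collagen)) {
    stats$winter_collagen_correlation <- tryCatch(
      season_collagen_correlation(estimates, collagen, season = "winter"),
      paleoseas_error = function(e) NULL
    )
  }

  sr_screen_tbl <- NULL
  sr_homog <- NULL
  if (!is.null(sr)) {
    if (is.null(baseline)) {
      stop_paleoseas("`baseline` is required when `sr` is supplied",
                     "paleoseas_config_error")
    }
    sr_screen_tbl <- sr_screen(sr, baseline)
    sr_homog <- sr_seasonal_homogeneity(sr)
  }

  collagen_passed <- NULL
  collagen_trends <- NULL
  if (!is.null(collagen)) {
    collagen_passed <- collagen_qc(collagen)
    collagen_trends <- collagen_layer_trends(collagen_passed)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("paleoseas")),
    seed = seed, method = method, damping = damping,
    maturation_length = maturation_length, sample_length = sample_length,
    k = k, f_floor = f_floor, d18O_sd = d18O_sd, n_mc = n_mc,
    n_teeth = nrow(fits),
    n_layers = length(unique(fits$layer_id)),
    excluded_non_sinusoidal = excluded,
    n_excluded = length(excluded)
  )

  structure(
    list(fits = fits, estimates_raw = estimates_raw,
         estimates = estimates, tooth_temperatures = tooth_temps,
         layer_temperatures = layer_temps, stats = stats,
         sr_screen = sr_screen_tbl, sr_homogeneity = sr_homog,
         collagen_qc = collagen_passed, collagen_trends = collagen_trends,
         report = report),
    class = "seasonality_run"
  )
}

#' @export
print.seasonality_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "Seasonality run: %d teeth in %d layers (%d excluded as non-sinusoidal), method = %s, damping %s\n",
    r$n_teeth, r$n_layers, r$n_excluded, r$method,
    if (r$damping) "on" else "off"))
  if (r$n_excluded > 0) {
    cat("  excluded:", paste(r$excluded_non_sinusoidal, collapse = ", "),
        "\n")
  }
  cat("Layer temperatures (tooth-mean route):\n")
  print(dplyr::filter(x$layer_temperatures, .data$route == "tooth_mean"))
  invisible(x)
}

#' @rdname run_seasonality_pipeline
#' @param x A `seasonality_run`.
#' @param ... Unused.
#' @export
glance.seasonality_run <- function(x, ...) {
  winter <- x$stats$summaries$winter
  tibble(
    n_teeth = x$report$n_teeth,
    n_layers = x$report$n_layers,
    n_excluded = x$report$n_excluded,
    anova_winter_p = if (!is.null(x$stats$anova_winter))
      x$stats$anova_winter$p else NA_real_,
    levene_winter_p = if (!is.null(x$stats$levene_winter))
      x$stats$levene_winter$p else NA_real_,
    winter_range = max(winter$max) - min(winter$min),
    seed = x$report$seed
  )
}

#' Write a pipeline run to disk
#'
#' Writes every stage table as CSV plus a machine-readable
#' `run_summary.json` (settings, seed, exclusions, scalar statistics and
#' the path of every table) into `dir`.
#'
#' @param run A [run_seasonality_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "seasonality_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  put <- function(tbl, name) {
    if (is.null(tbl)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(dplyr::select(tbl, -dplyr::any_of("fit")), p)
    paths[[name]] <<- p
  }
  put(run$fits, "fits")
  put(run$estimates_raw, "estimates_raw")
  put(run$estimates, "estimates_corrected")
  put(run$tooth_temperatures, "tooth_temperatures")
  put(run$layer_temperatures, "layer_temperatures")
  for (s in names(run$stats$summaries)) {
    put(run$stats$summaries[[s]], paste0("summary_", s))
  }
  put(run$stats$tukey_winter, "tukey_winter")
  put(run$stats$effect_sizes, "effect_sizes")
  put(run$sr_screen, "sr_screen")
  put(run$sr_homogeneity, "sr_homogeneity")
  put(run$collagen_trends, "collagen_trends")

  summary <- c(
    run$report,
    list(
      tables = paths,
      anova_winter = run$stats$anova_winter,
      levene_winter = run$stats$levene_winter,
      winter_collagen_correlation = run$stats$winter_collagen_correlation,
      shapiro_winter_p = run$stats$normality_winter$shapiro_p
    )
  )
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration names the input tables, calibration file, damping
#' geometry, extraction and Monte-Carlo settings, and the output
#' directory; see `system.file("extdata", "run_config_template.yml",
#' package = "paleoseas")`.
#'
#' @param path Path to the YAML run configuration.
#' @return The [run_seasonality_pipeline()] result, after writing outputs
#'   to the configured directory.
#' @export
run_from_config <- function(path) {
  if (!file.exists(path)) {
    stop_paleoseas(sprintf("config file not found: %s", path),
                   "paleoseas_config_error")
  }
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  enamel <- read_samples(resolve(cfg$enamel), "enamel")
  sr <- if (!is.null(cfg$sr)) read_samples(resolve(cfg$sr), "sr")
  collagen <- if (!is.null(cfg$collagen))
    read_samples(resolve(cfg$collagen), "collagen")
  cal <- read_calibration(resolve(cfg$calibration))
  baseline <- if (!is.null(cfg$sr_baseline)) {
    sr_baseline(cfg$sr_baseline$mean, cfg$sr_baseline$sd,
                cfg$sr_baseline$source %||% "config")
  }
  run <- run_seasonality_pipeline(
    enamel, cal,
    maturation_length = cfg$maturation_length,
    sample_length = cfg$sample_length,
    sr = sr, collagen = collagen, baseline = baseline,
    method = cfg$method %||% "observed",
    k = cfg$k %||% 2,
    damping = cfg$damping %||% TRUE,
    f_floor = cfg$f_floor %||% 0.3,
    d18O_sd = cfg$d18O_sd %||% 0.2,
    n_mc = cfg$n_mc %||% 10000,
    seed = cfg$seed %||% 1L
  )
  if (!is.null(cfg$output_dir)) write_run(run, resolve(cfg$output_dir))
  run
}
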