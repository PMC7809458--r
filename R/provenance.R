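#' Define a bioavailable strontium baseline
#'
#' The local 87Sr/86Sr range against which enamel values are screened,
#' typically measured on modern plants sampled near the site.
#'
#' @param mean,sd Baseline mean and standard deviation (87Sr/86Sr).
#' @param source Label describing where the baseline comes from.
#' @return An object of class `"sr_baseline"`.
#' @export
sr_baseline <- function(mean, sd, source = "local plants") {
  assert_number(mean, "mean", lower = 0.70, upper = 0.74)
  assert_number(sd, "sd", lower = 0)
  structure(list(mean = mean, sd = sd, source = source),
            class = "sr_baseline")
}

#' @export
print.sr_baseline <- function(x, ...) {
  cat(sprintf("Sr baseline (%s): %.4f +/- %.4f (1 sd)\n",
              x$source, x$mean, x$sd))
  invisible(x)
}

#' Strontium locality screening
#'
#' Classifies each tooth as `local` when all of its 87Sr/86Sr measurements
#' fall within `mean +/- k_sd * sd` of the bioavailable baseline, i.e. the
#' animal's enamel matches the local bedrock signal and its d18O can be
#' read as a local climate proxy. Teeth with any measurement outside the
#' window are flagged `nonlocal` (candidate long-distance migrants).
#'
#' @param measurements A validated Sr tibble ([read_samples()]).
#' @param baseline An [sr_baseline()].
#' @param k_sd Half-width of the acceptance window in baseline sds
#'   (default 3).
#' @return A tibble per tooth: `n`, `sr_mean`, `sr_min`, `sr_max`,
#'   `status`; the overall summary (mean, sd, min, max across all
#'   measurements) is in `attr(x, "summary")`.
#' @export
sr_screen <- function(measurements, baseline, k_sd = 3) {
  stopifnot(inherits(baseline, "sr_baseline"))
  assert_number(k_sd, "k_sd", lower = 0)
  if (nrow(measurements) == 0) {
    stop_paleoseas("no Sr measurements supplied", "paleoseas_io_error")
  }
  dev <- abs(measurements$sr_ratio - baseline$mean)
  if (baseline$sd == 0 && any(dev > 0)) {
    stop_paleoseas(
      "degenerate baseline: sd = 0 but measurements deviate from the mean",
      "paleoseas_degenerate_error"
    )
  }
  lo <- baseline$mean - k_sd * baseline$sd
  hi <- baseline$mean + k_sd * baseline$sd
  out <- measurements %>%
    group_by(.data$tooth_id) %>%
    summarise(
      n = dplyr::n(),
      sr_mean = mean(.data$sr_ratio),
      sr_min = min(.data$sr_ratio),
      sr_max = max(.data$sr_ratio),
      status = if (all(.data$sr_ratio >= lo & .data$sr_ratio <= hi))
        "local" else "nonlocal",
      .groups = "drop"
    )
  attr(out, "summary") <- tibble(
    n = nrow(measurements),
    mean = mean(measurements$sr_ratio),
    sd = if (nrow(measurements) >= 2) sd(measurements$sr_ratio) else NA_real_,
    min = min(measurements$sr_ratio),
    max = max(measurements$sr_ratio)
  )
  out
}

#' Intra-tooth seasonal homogeneity of strontium
#'
#' A tooth whose sequential Sr measurements vary beyond analytical noise
#' sampled different geologies over the year (seasonal movement). Reports
#' each tooth's intra-tooth range and flags ranges exceeding
#' `k * analytical_sd`.
#'
#' @param measurements A validated Sr tibble with >= 2 positions for the
#'   teeth to assess.
#' @param analytical_sd Analytical 1-sd of a single Sr measurement.
#' @param k Range threshold in analytical sds (default 4: two measurements
#'   2 sd apart each).
#' @return A tibble per tooth: `n`, `sr_range`, `status` in
#'   `{"homogeneous", "variable", "not_assessable"}` (single-measurement
#'   teeth are not assessable).
#' @export
sr_seasonal_homogeneity <- function(measurements, analytical_sd = 0.0001,
                                    k = 4) {
  assert_number(analytical_sd, "analytical_sd", lower = 0)
  assert_number(k, "k", lower = 0)
  measurements %>%
    group_by(.data$tooth_id) %>%
    summarise(
      n = dplyr::n(),
      sr_range = if (dplyr::n() >= 2) diff(range(.data$sr_ratio)) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(status = dplyr::case_when(
      n < 2 ~ "not_assessable",
      sr_range > k * analytical_sd ~ "variable",
      TRUE ~ "homogeneous"
    ))
}

#' Collagen quality control
#'
#' Screens bone-collagen samples on the atomic C:N ratio, the standard
#' collagen-integrity criterion: well-preserved collagen falls in roughly
#' 2.9--3.6; values outside indicate degradation or contamination. Samples
#' without a C:N value pass with a warning.
#'
#' @param samples A validated collagen tibble ([read_samples()]).
#' @param cn_low,cn_high Acceptance window (defaults 2.9 and 3.6).
#' @return The passing rows; rejected rows with a `reason` column are in
#'   `attr(x, "rejected")`.
#' @export
collagen_qc <- function(samples, cn_low = 2.9, cn_high = 3.6) {
  assert_number(cn_low, "cn_low", lower = 0)
  assert_number(cn_high, "cn_high", lower = cn_low)
  if (!"CN_ratio" %in% names(samples)) {
    warn("no CN_ratio column: all collagen samples pass unchecked")
    attr(samples, "rejected") <- samples[0, , drop = FALSE]
    return(samples)
  }
  missing_cn <- is.na(samples$CN_ratio)
  if (any(missing_cn)) {
    warn(sprintf("%d collagen sample(s) lack C:N and pass unchecked: %s",
                 sum(missing_cn),
                 paste(samples$specimen_id[missing_cn], collapse = ", ")))
  }
  bad <- !missing_cn &
    (samples$CN_ratio < cn_low | samples$CN_ratio > cn_high)
  rejected <- samples[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- sprintf("C:N %.2f outside [%.2f, %.2f]",
                               rejected$CN_ratio, cn_low, cn_high)
  }
  out <- samples[!bad, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Per-layer collagen isotope trends
#'
#' Diachronic table of bone-collagen d13C and d15N by layer, ordered
#' stratigraphically. Single-specimen layers report `sd` as `NA`, not zero.
#'
#' @param samples A (QC-passed) collagen tibble.
#' @return A tibble per layer: `n`, `d13C_mean`, `d13C_sd`, `d15N_mean`,
#'   `d15N_sd`.
#' @export
collagen_layer_trends <- function(samples) {
  if (nrow(samples) == 0) {
    stop_paleoseas("no collagen samples", "paleoseas_empty_result_error")
  }
  sd_or_na <- function(x) if (length(x) >= 2) sd(x) else NA_real_
  samples %>%
    mutate(layer_id = layer_factor(.data$layer_id)) %>%
    group_by(.data$layer_id) %>%
    summarise(
      n = dplyr::n(),
      d13C_mean = mean(.data$d13C), d13C_sd = sd_or_na(.data$d13C),
      d15N_mean = mean(.data$d15N), d15N_sd = sd_or_na(.data$d15N),
      .groups = "drop"
    ) %>%
    arrange(.data$layer_id) %>%
    mutate(layer_id = as.character(.data$layer_id))
}
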