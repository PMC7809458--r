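#' Read sample tables
#'
#' Readers for the three CSV table kinds used across the pipeline. Each
#' validates its rows against the field invariants, drops violating rows with
#' row-level diagnostics (attached as the `"rejected"` attribute and reported
#' in a warning), and returns a tibble. Unknown extra columns are preserved.
#'
#' Expected columns (header row, comma-separated, UTF-8):
#' \describe{
#'   \item{enamel}{`tooth_id`, `layer_id`, `position_mm`, `d18O`; optional
#'     `replicate_sd`, `taxon`, `tooth_position`. `position_mm` is the
#'     distance along the growth axis from the enamel--root junction (ERJ),
#'     increasing toward the occlusal surface, i.e. larger position =
#'     earlier-formed enamel; set `positions_from = "occlusal"` if your table
#'     measured from the occlusal surface instead.}
#'   \item{sr}{`tooth_id`, `sr_ratio` (87Sr/86Sr); optional `position_mm`.}
#'   \item{collagen}{`specimen_id`, `layer_id`, `d13C`, `d15N`; optional
#'     `pct_C`, `pct_N`, `CN_ratio`, `collagen_yield_pct`.}
#' }
#'
#' Row-level invariants: positions and replicate sds non-negative, delta
#' values finite, `0.70 < sr_ratio < 0.74` (plausibility guard), `CN_ratio > 0`
#' when present. Enamel rows duplicated on `(tooth_id, position_mm)` are
#' averaged with a warning (replicate drilling of the same strip). Enamel
#' tables are returned sorted by tooth and ascending `position_mm`.
#'
#' @param path Path to a CSV file.
#' @param kind One of `"enamel"`, `"sr"`, `"collagen"`.
#' @param positions_from For enamel tables: the landmark positions were
#'   measured from, `"erj"` (default) or `"occlusal"`. In the latter case
#'   positions are flipped per tooth (`max - position`) so downstream code
#'   always sees the ERJ convention.
#' @return A validated tibble; rejected rows (with a `reason` column) are in
#'   `attr(x, "rejected")`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("tooth_id,layer_id,position_mm,d18O",
#'              "T1,2,2,-6.1", "T1,2,1,-6.5", "T1,2,3,-5.9"), path)
#' read_samples(path, "enamel")
#' @export
read_samples <- function(path, kind = c("enamel", "sr", "collagen"),
                         positions_from = c("erj", "occlusal")) {
  kind <- match.arg(kind)
  positions_from <- match.arg(positions_from)
  if (!file.exists(path)) {
    stop_paleoseas(sprintf("File not found: %s", path),
                   "paleoseas_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  switch(kind,
    enamel   = validate_enamel(raw, positions_from = positions_from),
    sr       = validate_sr(raw),
    collagen = validate_collagen(raw)
  )
}

required_cols <- function(data, cols, kind) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_paleoseas(
      sprintf("%s table is missing required column(s): %s",
              kind, paste(missing, collapse = ", ")),
      "paleoseas_format_error"
    )
  }
}

coerce_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

reject_rows <- function(data, bad, reason) {
  rej <- data[bad, , drop = FALSE]
  if (nrow(rej) > 0) {
    rej$row <- which(bad)
    rej$reason <- reason
  }
  rej
}

finish_validated <- function(kept, rejected, kind) {
  if (nrow(rejected) > 0) {
    warn(sprintf(
      "%s table: rejected %d row(s): %s", kind, nrow(rejected),
      paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
            collapse = "; ")
    ))
  }
  attr(kept, "rejected") <- as_tibble(rejected)
  kept
}

validate_enamel <- function(data, positions_from = "erj") {
  required_cols(data, c("tooth_id", "layer_id", "position_mm", "d18O"),
                "enamel")
  data <- as_tibble(data)
  data$tooth_id <- as.character(data$tooth_id)
  data$layer_id <- as.character(data$layer_id)
  data$position_mm <- coerce_num(data$position_mm)
  data$d18O <- coerce_num(data$d18O)
  if ("replicate_sd" %in% names(data)) {
    data$replicate_sd <- coerce_num(data$replicate_sd)
  }

  bad <- !is.finite(data$position_mm) | data$position_mm < 0 |
    !is.finite(data$d18O)
  if ("replicate_sd" %in% names(data)) {
    bad <- bad | (!is.na(data$replicate_sd) & data$replicate_sd < 0)
  }
  bad[is.na(bad)] <- TRUE
  rejected <- reject_rows(data, bad, "non-finite or negative required field")
  kept <- data[!bad, , drop = FALSE]

  dup <- kept %>%
    group_by(.data$tooth_id, .data$position_mm) %>%
    filter(dplyr::n() > 1) %>%
    ungroup()
  if (nrow(dup) > 0) {
    warn(sprintf(
      "enamel table: averaged %d duplicate (tooth_id, position_mm) row group(s)",
      nrow(distinct(dup, .data$tooth_id, .data$position_mm))
    ))
    num_cols <- intersect(c("d18O", "replicate_sd"), names(kept))
    kept <- kept %>%
      group_by(across(all_of(setdiff(names(kept), num_cols)))) %>%
      summarise(across(all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
                .groups = "drop")
  }

  if (positions_from == "occlusal") {
    kept <- kept %>%
      group_by(.data$tooth_id) %>%
      mutate(position_mm = max(.data$position_mm) - .data$position_mm) %>%
      ungroup()
  }
  kept <- arrange(kept, .data$tooth_id, .data$position_mm)
  finish_validated(kept, rejected, "enamel")
}

validate_sr <- function(data) {
  required_cols(data, c("tooth_id", "sr_ratio"), "sr")
  data <- as_tibble(data)
  data$tooth_id <- as.character(data$tooth_id)
  data$sr_ratio <- coerce_num(data$sr_ratio)
  if ("position_mm" %in% names(data)) {
    data$position_mm <- coerce_num(data$position_mm)
  }
  bad <- !is.finite(data$sr_ratio) |
    data$sr_ratio <= 0.70 | data$sr_ratio >= 0.74
  bad[is.na(bad)] <- TRUE
  rejected <- reject_rows(data, bad,
                          "sr_ratio missing or outside (0.70, 0.74)")
  finish_validated(data[!bad, , drop = FALSE], rejected, "sr")
}

validate_collagen <- function(data) {
  required_cols(data, c("specimen_id", "layer_id", "d13C", "d15N"),
                "collagen")
  data <- as_tibble(data)
  data$specimen_id <- as.character(data$specimen_id)
  data$layer_id <- as.character(data$layer_id)
  for (col in intersect(c("d13C", "d15N", "pct_C", "pct_N", "CN_ratio",
                          "collagen_yield_pct"), names(data))) {
    data[[col]] <- coerce_num(data[[col]])
  }
  bad <- !is.finite(data$d13C) | !is.finite(data$d15N)
  if ("CN_ratio" %in% names(data)) {
    bad <- bad | (!is.na(data$CN_ratio) & data$CN_ratio <= 0)
  }
  bad[is.na(bad)] <- TRUE
  rejected <- reject_rows(data, bad, "non-finite delta value or C:N <= 0")
  finish_validated(data[!bad, , drop = FALSE], rejected, "collagen")
}

#' Split an enamel table into per-tooth series
#'
#' Checks the per-tooth series invariants (at least 3 samples, strictly
#' monotonic positions after duplicate averaging) and returns the table
#' nested by tooth.
#'
#' @param enamel A validated enamel tibble from [read_samples()].
#' @param min_samples Minimum samples per tooth (default 3).
#' @return A tibble with one row per tooth: `tooth_id`, `layer_id`,
#'   `n_samples`, `span_mm`, and a `samples` list-column of per-sample
#'   tibbles ordered by `position_mm`.
#' @export
tooth_series <- function(enamel, min_samples = 3) {
  required_cols(enamel, c("tooth_id", "layer_id", "position_mm", "d18O"),
                "enamel")
  nested <- enamel %>%
    arrange(.data$tooth_id, .data$position_mm) %>%
    tidyr::nest(samples = -c("tooth_id", "layer_id"))
  nested <- nested %>%
    mutate(
      n_samples = purrr::map_int(.data$samples, nrow),
      span_mm = purrr::map_dbl(.data$samples,
                               ~ diff(range(.x$position_mm)))
    )
  small <- nested$n_samples < min_samples
  if (any(small)) {
    warn(sprintf("dropping %d tooth/teeth with fewer than %d samples: %s",
                 sum(small), min_samples,
                 paste(nested$tooth_id[small], collapse = ", ")))
    nested <- nested[!small, , drop = FALSE]
  }
  non_mono <- purrr::map_lgl(nested$samples,
                             ~ any(diff(.x$position_mm) <= 0))
  if (any(non_mono)) {
    stop_paleoseas(
      sprintf("non-monotonic position_mm within tooth/teeth: %s",
              paste(nested$tooth_id[non_mono], collapse = ", ")),
      "paleoseas_format_error"
    )
  }
  nested
}

#' Two-point scale normalization
#'
#' Maps raw instrument delta values onto a reference scale (e.g. VSMOW) with
#' the unique affine map sending the measured values of two standards to
#' their accepted values.
#'
#' @param raw Numeric vector of raw delta values (permil).
#' @param standards A [normalization_standards()] object.
#' @return Numeric vector on the target scale.
#' @examples
#' std <- normalization_standards(measured = c(0, 10), accepted = c(2, 22))
#' two_point_normalize(5, std)  # 12
#' @export
two_point_normalize <- function(raw, standards) {
  stopifnot(inherits(standards, "normalization_standards"))
  a <- standards$slope
  b <- standards$intercept
  a * raw + b
}

#' Define two normalization standards
#'
#' @param measured Length-2 numeric: measured values of the two standards.
#' @param accepted Length-2 numeric: their accepted values on the target
#'   scale (permil).
#' @return An object of class `"normalization_standards"` holding the
#'   affine map coefficients.
#' @export
normalization_standards <- function(measured, accepted) {
  if (length(measured) != 2 || length(accepted) != 2 ||
      !all(is.finite(measured)) || !all(is.finite(accepted))) {
    stop_paleoseas("`measured` and `accepted` must be two finite values each.",
                   "paleoseas_config_error")
  }
  if (measured[1] == measured[2] || accepted[1] == accepted[2]) {
    stop_paleoseas(
      "degenerate calibration: the two standards must differ in both measured and accepted values.",
      "paleoseas_degenerate_error"
    )
  }
  a <- diff(accepted) / diff(measured)
  b <- accepted[1] - a * measured[1]
  structure(
    list(measured = measured, accepted = accepted, slope = a, intercept = b),
    class = "normalization_standards"
  )
}

#' @export
print.normalization_standards <- function(x, ...) {
  cat("Two-point normalization: scale = ",
      format(x$slope), " * raw + ", format(x$intercept), "\n", sep = "")
  invisible(x)
}
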