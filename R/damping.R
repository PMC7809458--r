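#' Amplitude damping factor from time-averaging
#'
#' Enamel does not mineralize instantaneously: a length of crown matures
#' simultaneously, and each drilled strip averages a further length of
#' enamel along the growth axis. Both act as uniform moving-average windows
#' on the seasonal input signal, attenuating its recorded amplitude. For a
#' sinusoid of wavelength `lam`, a uniform window of width `L` multiplies
#' the amplitude by `|sinc(L/lam)|`, so the combined damping factor is
#' \deqn{f = |\mathrm{sinc}(L_{mat}/\lambda)| \cdot
#'       |\mathrm{sinc}(L_{samp}/\lambda)|}
#' with `sinc(x) = sin(pi x)/(pi x)`. The recorded amplitude is `f` times
#' the true amplitude; dividing by `f` undoes the damping.
#'
#' No default window lengths are shipped: maturation geometry is
#' taxon-specific and must be supplied explicitly (see the package
#' vignette).
#'
#' @param maturation_length Length of enamel maturing simultaneously, mm
#'   (>= 0).
#' @param sample_length Height of the drilled strip along the growth axis,
#'   mm (>= 0).
#' @param lam Annual-cycle wavelength along the growth axis, mm (> 0),
#'   typically from [fit_sinusoid()].
#' @return The damping factor `f` in (0, 1].
#' @examples
#' damping_factor(0, 0, 30)              # 1: no averaging
#' damping_factor(0, 15, 30)             # 2/pi: window of half a cycle
#' @export
damping_factor <- function(maturation_length, sample_length, lam) {
  assert_number(maturation_length, "maturation_length", lower = 0)
  assert_number(sample_length, "sample_length", lower = 0)
  assert_number(lam, "lam", lower = 1e-12)
  if (maturation_length + sample_length >= lam) {
    stop_paleoseas(
      sprintf(
        "unreliable correction: total averaging window (%.2f mm) is not smaller than the wavelength (%.2f mm); the damping factor is near or past its first zero.",
        maturation_length + sample_length, lam),
      "paleoseas_unreliable_error"
    )
  }
  abs(sinc(maturation_length / lam)) * abs(sinc(sample_length / lam))
}

#' Attenuate a dense signal with the averaging windows (forward model)
#'
#' Applies the two uniform moving averages (maturation, then drill strip)
#' to a densely, regularly sampled signal. This is the forward counterpart
#' of [damping_factor()]: on a sinusoid the output/input amplitude ratio
#' equals `f` up to discretization error. Used by the synthetic-data
#' generator and as an independent numerical check of the closed form.
#'
#' Edges where the windows extend past the signal are dropped, so the
#' output is shorter than the input by about the total window width.
#'
#' @param signal Tibble with `position_mm` and `value`, regularly spaced.
#' @param maturation_length,sample_length Window widths, mm (>= 0).
#' @param lam Optional wavelength, mm; when given, sampling coarser than 50
#'   points per cycle is refused.
#' @return Tibble with `position_mm` and `value`, trimmed at the edges.
#' @export
forward_convolve <- function(signal, maturation_length, sample_length,
                             lam = NULL) {
  stopifnot(all(c("position_mm", "value") %in% names(signal)))
  assert_number(maturation_length, "maturation_length", lower = 0)
  assert_number(sample_length, "sample_length", lower = 0)
  x <- signal$position_mm
  dx <- diff(x)
  if (length(dx) < 2 || diff(range(dx)) > 1e-8 * mean(dx)) {
    stop_paleoseas("forward_convolve needs a regularly spaced signal",
                   "paleoseas_resolution_error")
  }
  dx <- mean(dx)
  if (!is.null(lam)) {
    assert_number(lam, "lam", lower = 1e-12)
    if (lam / dx < 50) {
      stop_paleoseas(
        sprintf("sampling too coarse: %.1f points per cycle, need >= 50",
                lam / dx),
        "paleoseas_resolution_error"
      )
    }
  }
  v <- signal$value
  v <- moving_average(v, maturation_length / dx)
  v <- moving_average(v, sample_length / dx)
  keep <- !is.na(v)
  tibble(position_mm = x[keep], value = v[keep])
}

# uniform moving average of continuous width m (in sample spacings):
# edge samples get fractional weight from their partial overlap with the
# window, so non-integer widths carry no rounding bias
moving_average <- function(v, m) {
  if (m <= 1) return(v)
  h <- m / 2
  j_max <- ceiling(h - 0.5)
  offs <- -j_max:j_max
  wts <- pmax(0, pmin(offs + 0.5, h) - pmax(offs - 0.5, -h)) / m
  as.numeric(stats::filter(v, wts, sides = 2))
}

#' Correct seasonal extremes for amplitude damping
#'
#' Undoes the amplitude attenuation of [damping_factor()] on extracted
#' seasonal estimates: the recorded half-seasonality `A = (peak - trough)/2`
#' is inflated to `A' = A / f` and the extremes re-centered on the (damping
#' invariant) mean annual value: corrected peak `= mean_annual + A'`,
#' corrected trough `= mean_annual - A'`. Only rows with both extremes can
#' be corrected; partial rows pass through unchanged with `f = NA`.
#'
#' Correction is refused when `f` falls below `f_floor`, since dividing by
#' a small factor amplifies noise unboundedly.
#'
#' @param estimates A seasonal-estimate tibble from [extract_seasonal()].
#' @param fits The matching [fit_seasonal()] table (supplies each tooth's
#'   wavelength).
#' @param maturation_length,sample_length Averaging-window widths, mm.
#' @param f_floor Reliability floor on `f` (default 0.3).
#' @return The estimate tibble with raw values preserved in
#'   `summer_peak_raw`, `winter_trough_raw`, `seasonality_raw`, the damping
#'   factor in `f`, and `summer_peak`, `winter_trough`, `seasonality`
#'   replaced by corrected values; `mean_annual` is unchanged.
#' @export
correct_extremes <- function(estimates, fits, maturation_length,
                             sample_length, f_floor = 0.3) {
  assert_number(f_floor, "f_floor", lower = 0, upper = 1)
  lam_tbl <- fits %>% select("tooth_id", "lam")
  out <- estimates %>%
    left_join(lam_tbl, by = "tooth_id") %>%
    mutate(
      summer_peak_raw = .data$summer_peak,
      winter_trough_raw = .data$winter_trough,
      seasonality_raw = .data$seasonality,
      f = purrr::map_dbl(.data$lam, function(l) {
        if (!is.finite(l)) return(NA_real_)
        damping_factor(maturation_length, sample_length, l)
      })
    )
  low <- out$completeness == "both_extremes" &
    is.finite(out$f) & out$f < f_floor
  if (any(low)) {
    stop_paleoseas(
      sprintf(
        "damping factor below reliability floor %.2f for tooth/teeth: %s",
        f_floor,
        paste(sprintf("%s (f = %.2f)", out$tooth_id[low], out$f[low]),
              collapse = ", ")),
      "paleoseas_unreliable_error"
    )
  }
  both <- out$completeness == "both_extremes"
  A_corr <- (out$summer_peak_raw - out$winter_trough_raw) / 2 / out$f
  out$summer_peak[both] <- out$mean_annual[both] + A_corr[both]
  out$winter_trough[both] <- out$mean_annual[both] - A_corr[both]
  out$seasonality[both] <- 2 * A_corr[both]
  out$f[!both] <- NA_real_
  select(out, -"lam")
}
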