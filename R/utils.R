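#' Normalized sinc function
#'
#' `sinc(x) = sin(pi*x) / (pi*x)` with `sinc(0) = 1`. This is the amplitude
#' response of a uniform moving-average window of width `x` cycles applied to
#' a sinusoid, and underlies the damping model.
#'
#' @param x Numeric vector, window width in units of the wavelength.
#' @return Numeric vector of the same length.
#' @examples
#' sinc(0)      # 1
#' sinc(0.5)    # 2/pi
#' sinc(1)      # 0 (window spans a full cycle)
#' @export
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

# wrap an angle into [0, 2*pi)
wrap_phase <- function(phi) {
  phi %% (2 * pi)
}

# Stop with a classed condition so callers/tests can match on class.
stop_paleoseas <- function(msg, class, ...) {
  abort(msg, class = c(class, "paleoseas_error"), ...)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_paleoseas(sprintf("`%s` must be supplied.", name),
                   "paleoseas_config_error")
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < lower || x > upper) {
    stop_paleoseas(
      sprintf("`%s` must be a single finite number in [%s, %s].",
              name, format(lower), format(upper)),
      "paleoseas_config_error"
    )
  }
  invisible(x)
}

# stratigraphic ordering used throughout: older (lower) layers first
layer_factor <- function(layer_id, levels = NULL) {
  layer_id <- as.character(layer_id)
  if (is.null(levels)) {
    known <- c("1", "2", "3", "4", "5A", "5B")
    seen <- unique(layer_id)
    levels <- c(intersect(known, seen), sort(setdiff(seen, known)))
  }
  factor(layer_id, levels = levels)
}
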