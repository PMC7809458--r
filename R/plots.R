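#' Plot all intra-tooth seasonal profiles
#'
#' Faceted points-plus-fitted-curve panels, one per tooth, the standard way
#' intra-tooth series are inspected for seasonal structure.
#'
#' @param fits A [fit_seasonal()] table.
#' @return A ggplot object.
#' @export
plot_seasonal_profiles <- function(fits) {
  pts <- purrr::map(fits$fit, augment) %>% bind_rows()
  curves <- purrr::map(fits$fit, function(f) {
    d <- tibble(position_mm = seq(min(f$data$position_mm),
                                  max(f$data$position_mm),
                                  length.out = 200))
    d$d18O <- predict(f, d)
    d$tooth_id <- f$tooth_id
    d
  }) %>% bind_rows()
  labs <- fits %>%
    mutate(label = sprintf("%s (%s)", .data$tooth_id,
                           .data$classification))
  pts <- left_join(pts, select(labs, "tooth_id", "label"), by = "tooth_id")
  curves <- left_join(curves, select(labs, "tooth_id", "label"),
                      by = "tooth_id")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$position_mm,
                                    y = .data$d18O)) +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "Distance from enamel-root junction (mm)",
                  y = expression(delta^18 * O ~ "(permil VSMOW)"))
}

#' Plot seasonal d18O by layer
#'
#' Summer, mean-annual and winter values as points per tooth with a line
#' through the layer means, layers in stratigraphic order.
#'
#' @param estimates A seasonal-estimate tibble.
#' @return A ggplot object.
#' @export
plot_layer_seasons <- function(estimates) {
  long <- estimates %>%
    select("tooth_id", "layer_id", summer = "summer_peak",
           winter = "winter_trough", mean_annual = "mean_annual") %>%
    tidyr::pivot_longer(c("summer", "mean_annual", "winter"),
                        names_to = "season", values_to = "d18O") %>%
    filter(is.finite(.data$d18O)) %>%
    mutate(layer_id = layer_factor(.data$layer_id),
           season = factor(.data$season,
                           levels = c("summer", "mean_annual", "winter")))
  means <- long %>%
    group_by(.data$layer_id, .data$season) %>%
    summarise(d18O = mean(.data$d18O), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$layer_id, y = .data$d18O,
                                     colour = .data$season)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$season)) +
    ggplot2::scale_colour_manual(values = c(summer = "#E6A817",
                                            mean_annual = "#4C9A52",
                                            winter = "#3B6FB6")) +
    ggplot2::labs(x = "Layer", y = expression(delta^18 * O ~
                                                "(permil VSMOW)"),
                  colour = NULL)
}

#' Plot reconstructed layer temperatures
#'
#' Per-tooth reconstructed temperatures with compound-error bars by layer,
#' one panel per quantity, with optional modern reference lines.
#'
#' @param tooth_temps A [reconstruct_temperatures()] table.
#' @param reference Optional named vector, e.g.
#'   `c(T_warmest_month = 20.5, T_coldest_month = 4.9)`.
#' @return A ggplot object.
#' @export
plot_temperatures <- function(tooth_temps, reference = NULL) {
  vals <- tooth_temps %>%
    select("tooth_id", "layer_id", "T_warmest_month", "MAT",
           "T_coldest_month") %>%
    tidyr::pivot_longer(-c("tooth_id", "layer_id"),
                        names_to = "quantity", values_to = "value")
  errs <- tooth_temps %>%
    select("tooth_id", "layer_id",
           T_warmest_month = "err_T_warmest", MAT = "err_MAT",
           T_coldest_month = "err_T_coldest") %>%
    tidyr::pivot_longer(-c("tooth_id", "layer_id"),
                        names_to = "quantity", values_to = "err_")
  long <- left_join(vals, errs,
                    by = c("tooth_id", "layer_id", "quantity")) %>%
    filter(is.finite(.data$value)) %>%
    mutate(layer_id = layer_factor(.data$layer_id),
           quantity = factor(.data$quantity,
                             levels = c("T_warmest_month", "MAT",
                                        "T_coldest_month")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$layer_id,
                                          y = .data$value)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$value - .data$err_,
                   ymax = .data$value + .data$err_),
      position = ggplot2::position_jitter(width = 0.1, seed = 1),
      size = 0.3) +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = "Layer", y = "Temperature (°C)")
  if (!is.null(reference)) {
    ref <- tibble(quantity = factor(names(reference),
                                    levels = levels(long$quantity)),
                  value = unname(reference))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value),
                                 colour = "grey50", linetype = 2)
  }
  p
}
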