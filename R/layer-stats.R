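#' Pull one season's values out of a seasonal-estimate table
#'
#' @param estimates A seasonal-estimate tibble ([extract_seasonal()] or
#'   [correct_extremes()] output).
#' @param season `"winter"` (winter troughs), `"summer"` (summer peaks) or
#'   `"mean_annual"`.
#' @return A tibble with `tooth_id`, `layer_id`, `value` (permil); teeth
#'   lacking that season (partial series) are dropped.
#' @export
season_values <- function(estimates,
                          season = c("winter", "summer", "mean_annual")) {
  season <- match.arg(season)
  col <- switch(season, winter = "winter_trough", summer = "summer_peak",
                mean_annual = "mean_annual")
  out <- estimates %>%
    select("tooth_id", "layer_id", value = all_of(col)) %>%
    filter(is.finite(.data$value))
  if (nrow(out) == 0) {
    stop_paleoseas(sprintf("no estimates carry the %s season", season),
                   "paleoseas_empty_result_error")
  }
  out
}

#' Per-layer group summaries of seasonal values
#'
#' @inheritParams season_values
#' @return A tibble per layer, ordered stratigraphically (older layers
#'   first): `n`, `mean`, `sd`, `min`, `max` in permil. `sd` is `NA` for
#'   single-specimen layers (not zero).
#' @export
layer_summary <- function(estimates,
                          season = c("winter", "summer", "mean_annual")) {
  season <- match.arg(season)
  season_values(estimates, season) %>%
    mutate(layer_id = layer_factor(.data$layer_id)) %>%
    group_by(.data$layer_id) %>%
    summarise(
      season = season,
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2) sd(.data$value) else NA_real_,
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) %>%
    arrange(.data$layer_id) %>%
    mutate(layer_id = as.character(.data$layer_id))
}

check_groups <- function(data, min_groups = 2, min_per_group = 2) {
  counts <- table(data$layer_id)
  if (length(counts) < min_groups || any(counts < min_per_group)) {
    stop_paleoseas(
      sprintf(
        "need at least %d groups with >= %d values each (got sizes: %s)",
        min_groups, min_per_group,
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")),
      "paleoseas_insufficient_data_error"
    )
  }
  invisible(data)
}

#' One-way fixed-effects ANOVA across layers
#'
#' Classical one-way ANOVA of `value` by `layer_id` (via [stats::aov()]).
#'
#' @param data A tibble with `layer_id` and `value` columns, e.g. from
#'   [season_values()].
#' @return One-row tibble: `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(data) {
  check_groups(data)
  fit <- aov(value ~ factor(layer_id), data = data)
  s <- summary(fit)[[1]]
  tibble(F = s$`F value`[1], p = s$`Pr(>F)`[1],
         df_between = s$Df[1], df_within = s$Df[2])
}

#' Levene's test for equality of variances across layers
#'
#' @inheritParams anova_oneway
#' @param center Deviations taken about the group `"mean"` (default) or
#'   `"median"` (Brown-Forsythe variant).
#' @return One-row tibble: `F`, `p`.
#' @export
levene_test <- function(data, center = c("mean", "median")) {
  center <- match.arg(center)
  check_groups(data)
  res <- car::leveneTest(value ~ factor(layer_id), data = data,
                         center = get(center))
  tibble(F = res$`F value`[1], p = res$`Pr(>F)`[1])
}

#' Tukey HSD pairwise layer comparisons
#'
#' Tukey's range test on the one-way layer model, with the Tukey-Kramer
#' adjustment for unbalanced groups (via [stats::TukeyHSD()]).
#'
#' @inheritParams anova_oneway
#' @return A tibble per layer pair: `contrast`, `diff`, `conf_low`,
#'   `conf_high`, `p_adj`.
#' @export
tukey_hsd <- function(data) {
  check_groups(data)
  fit <- aov(value ~ factor(layer_id), data = data)
  tk <- TukeyHSD(fit)[[1]]
  tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]), conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"])
  )
}

#' Cohen's d effect size between two groups
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' using `(n - 1)` weights and no small-sample (Hedges) correction. The
#' sign convention follows stratigraphic reading order: list the earlier
#' (lower, older) group first, so a rise from group a to group b gives a
#' negative `d`.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A single number.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_paleoseas("each group needs at least 2 finite values",
                   "paleoseas_insufficient_data_error")
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    stop_paleoseas("pooled sd is zero: effect size undefined",
                   "paleoseas_degenerate_error")
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Cohen's d for a layer contrast of one season
#'
#' Convenience wrapper computing [cohens_d()] between two layers' seasonal
#' values, earlier layer first.
#'
#' @inheritParams season_values
#' @param layer_a,layer_b Layer ids; `layer_a` should be the
#'   stratigraphically earlier (lower) layer.
#' @return One-row tibble: `season`, `contrast`, `d`, `n_a`, `n_b`.
#' @export
layer_cohens_d <- function(estimates, layer_a, layer_b,
                           season = c("winter", "summer", "mean_annual")) {
  season <- match.arg(season)
  vals <- season_values(estimates, season)
  a <- vals$value[vals$layer_id == layer_a]
  b <- vals$value[vals$layer_id == layer_b]
  tibble(season = season,
         contrast = paste(layer_a, "vs", layer_b),
         d = cohens_d(a, b),
         n_a = length(a), n_b = length(b))
}

#' Correlation between seasonal enamel d18O and collagen d13C across layers
#'
#' Tests whether diachronic shifts in (by default winter) enamel d18O track
#' shifts in the plant/feeding baseline recorded by bone-collagen d13C.
#' Each collagen specimen (or each layer, see `pairing`) is paired with its
#' layer's mean seasonal d18O value and a Pearson correlation is computed.
#'
#' @inheritParams season_values
#' @param collagen A validated collagen tibble ([read_samples()]).
#' @param pairing `"per_specimen"` (default): every collagen specimen in a
#'   layer with seasonal data contributes a pair (layer mean d18O, specimen
#'   d13C); `"per_layer"`: one pair of layer means per layer.
#' @return One-row tibble: `r`, `r_squared`, `p` (two-sided), `n`,
#'   `pairing`.
#' @export
season_collagen_correlation <- function(estimates, collagen,
                                        season = c("winter", "summer",
                                                   "mean_annual"),
                                        pairing = c("per_specimen",
                                                    "per_layer")) {
  season <- match.arg(season)
  pairing <- match.arg(pairing)
  layer_means <- season_values(estimates, season) %>%
    group_by(.data$layer_id) %>%
    summarise(d18O_mean = mean(.data$value), .groups = "drop")
  paired <- collagen %>%
    select("specimen_id", "layer_id", "d13C") %>%
    dplyr::inner_join(layer_means, by = "layer_id")
  if (pairing == "per_layer") {
    paired <- paired %>%
      group_by(.data$layer_id, .data$d18O_mean) %>%
      summarise(d13C = mean(.data$d13C), .groups = "drop")
  }
  if (nrow(paired) < 3) {
    stop_paleoseas("need at least 3 pairs for a correlation",
                   "paleoseas_insufficient_data_error")
  }
  ct <- cor.test(paired$d18O_mean, paired$d13C, method = "pearson")
  tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p = ct$p.value, n = nrow(paired), pairing = pairing)
}

#' Normality diagnostics for a sample
#'
#' Theoretical-vs-sample normal quantiles (the table behind a qqnorm plot)
#' plus a Shapiro-Wilk p value as a numeric companion. Advisory only; no
#' pipeline stage gates on it.
#'
#' @param values Numeric vector (>= 3 finite values).
#' @return An object of class `"normality_check"`: `$qq`, a tibble with
#'   `theoretical` and `sample` columns (one row per input value), and
#'   `$shapiro_p`. Has `print()` and [autoplot()] methods.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop_paleoseas("need at least 3 finite values",
                   "paleoseas_insufficient_data_error")
  }
  qq <- tibble(
    theoretical = qnorm(ppoints(length(values)))[order(order(values))],
    sample = values
  )
  structure(
    list(qq = qq, shapiro_p = shapiro.test(values)$p.value),
    class = "normality_check"
  )
}

#' @export
print.normality_check <- function(x, ...) {
  cat(sprintf("Normality check: n = %d, Shapiro-Wilk p = %.3g\n",
              nrow(x$qq), x$shapiro_p))
  invisible(x)
}

#' @rdname normality_check
#' @param object A `normality_check`.
#' @param ... Unused.
#' @export
autoplot.normality_check <- function(object, ...) {
  ggplot2::ggplot(object$qq,
                  ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_qq_line(ggplot2::aes(sample = .data$sample),
                          inherit.aes = FALSE, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Theoretical quantiles", y = "Sample quantiles",
                  subtitle = sprintf("Shapiro-Wilk p = %.3g",
                                     object$shapiro_p))
}
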