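make_estimates <- function(layers, winters, summers = winters + 4) {
  tibble::tibble(
    tooth_id = paste0("T", seq_along(layers)), layer_id = layers,
    method = "observed", summer_peak = summers, winter_trough = winters,
    mean_annual = (summers + winters) / 2, seasonality = summers - winters,
    completeness = "both_extremes"
  )
}

test_that("layer_summary computes group statistics in stratigraphic order", {
  est <- make_estimates(c("5A", "5A", "2", "2", "2"),
                        c(-8, -6, -9, -10, -11))
  s <- layer_summary(est, "winter")
  expect_equal(s$layer_id, c("2", "5A"))  # older layer first
  expect_equal(s$mean[s$layer_id == "5A"], -7)
  expect_equal(s$sd[s$layer_id == "5A"], sqrt(2))
  expect_equal(s$n, c(3L, 2L))
})

test_that("partial-series teeth contribute only their available season", {
  est <- make_estimates(c("2", "2", "2"), c(-9, -10, -11))
  est$summer_peak[2] <- NA
  est$completeness[2] <- "trough_only"
  expect_equal(layer_summary(est, "summer")$n, 2L)
  expect_equal(layer_summary(est, "winter")$n, 3L)
  est$winter_trough <- NA
  expect_error(season_values(est, "winter"),
               class = "paleoseas_empty_result_error")
})

test_that("one-way ANOVA matches a from-scratch sums-of-squares oracle", {
  d <- tibble::tibble(
    layer_id = rep(c("a", "b", "c"), times = c(5, 4, 6)),
    value = c(6.1, 5.8, 6.4, 5.9, 6.2, 7.0, 7.3, 6.8, 7.1,
              5.2, 5.5, 5.1, 5.4, 4.9, 5.3)
  )
  res <- anova_oneway(d)
  # independent oracle: explicit between/within sums of squares
  gm <- mean(d$value)
  groups <- split(d$value, d$layer_id)
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  dfb <- length(groups) - 1
  dfw <- nrow(d) - length(groups)
  F_oracle <- (ssb / dfb) / (ssw / dfw)
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(F_oracle, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("identical groups give F = 0, p = 1 and two groups give F = t^2", {
  same <- tibble::tibble(layer_id = rep(c("a", "b"), each = 3),
                         value = rep(c(1, 2, 3), 2))
  res <- anova_oneway(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  set.seed(2)
  two <- tibble::tibble(layer_id = rep(c("a", "b"), each = 8),
                        value = rnorm(16))
  res2 <- anova_oneway(two)
  tt <- t.test(value ~ layer_id, data = two, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  short <- tibble::tibble(layer_id = c("a", "a", "b"), value = 1:3)
  expect_error(anova_oneway(short),
               class = "paleoseas_insufficient_data_error")
})

test_that("Levene detects gross variance differences and is calibrated", {
  gross <- tibble::tibble(
    layer_id = rep(c("a", "b"), each = 6),
    value = c(0, 0.001, -0.001, 0.002, -0.002, 0.001,
              0, 10, -10, 8, -8, 9))
  expect_lt(levene_test(gross)$p, 0.05)
  # null calibration: equal variances -> p approximately uniform
  set.seed(31)
  ps <- replicate(400, {
    d <- tibble::tibble(layer_id = rep(c("a", "b", "c"), each = 10),
                        value = rnorm(30))
    levene_test(d)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Tukey HSD matches a studentized-range hand computation", {
  d <- tibble::tibble(
    layer_id = rep(c("a", "b", "c"), times = c(5, 4, 6)),
    value = c(6.1, 5.8, 6.4, 5.9, 6.2, 7.0, 7.3, 6.8, 7.1,
              5.2, 5.5, 5.1, 5.4, 4.9, 5.3)
  )
  res <- tukey_hsd(d)
  groups <- split(d$value, d$layer_id)
  mse <- sum(sapply(groups, function(g) sum((g - mean(g))^2))) /
    (nrow(d) - 3)
  # Tukey-Kramer p for the a-b pair, from first principles
  q_ab <- abs(mean(groups$a) - mean(groups$b)) /
    sqrt(mse / 2 * (1 / 5 + 1 / 4))
  p_ab <- ptukey(q_ab, nmeans = 3, df = nrow(d) - 3, lower.tail = FALSE)
  expect_equal(res$p_adj[res$contrast == "b-a"], p_ab, tolerance = 0.005)
})

test_that("identical groups give Tukey p = 1 and p_adj dominates raw p", {
  same <- tibble::tibble(layer_id = rep(c("a", "b", "c"), each = 3),
                         value = rep(c(1, 2, 3), 3))
  expect_true(all(tukey_hsd(same)$p_adj > 0.999))
  set.seed(4)
  d <- tibble::tibble(layer_id = rep(c("a", "b", "c"), each = 6),
                      value = rnorm(18) + rep(c(0, 0.5, 1), each = 6))
  tk <- tukey_hsd(d)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    raw <- t.test(d$value[d$layer_id == pair[1]],
                  d$value[d$layer_id == pair[2]], var.equal = TRUE)$p.value
    p_adj <- tk$p_adj[tk$contrast == paste(pair[2], pair[1], sep = "-")]
    expect_gte(p_adj, raw - 1e-10)
  }
})

test_that("Cohen's d is the pooled-sd mean difference with sign convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)  # pooled sd = 1
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)),
               class = "paleoseas_degenerate_error")
  expect_error(cohens_d(1, c(1, 2)),
               class = "paleoseas_insufficient_data_error")
})

test_that("Cohen's d invariances: antisymmetry, shift, scale", {
  set.seed(6)
  a <- rnorm(8, 0, 1)
  b <- rnorm(10, 1, 1.2)
  d0 <- cohens_d(a, b)
  expect_equal(cohens_d(b, a), -d0)
  expect_equal(cohens_d(a + 5, b + 5), d0)
  expect_equal(cohens_d(3 * a, 3 * b), d0)  # scale cancels in d
  est <- make_estimates(rep(c("2", "5A"), each = 3), c(-9, -10, -11, -7, -8, -7.5))
  ld <- layer_cohens_d(est, "2", "5A", season = "winter")
  expect_equal(ld$d, cohens_d(c(-9, -10, -11), c(-7, -8, -7.5)))
  expect_lt(ld$d, 0)  # winter rise from older to younger layer
})

test_that("correlation matches the covariance-formula hand computation", {
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  est <- make_estimates(paste0("L", 1:5), x)
  collagen <- tibble::tibble(specimen_id = paste0("C", 1:5),
                             layer_id = paste0("L", 1:5), d13C = y,
                             d15N = 5)
  res <- season_collagen_correlation(est, collagen, season = "winter")
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$r_squared, r_hand^2, tolerance = 1e-12)
  # perfectly collinear pairs
  collagen2 <- dplyr::mutate(collagen, d13C = 2 * x + 1)
  res2 <- season_collagen_correlation(est, collagen2, season = "winter")
  expect_equal(res2$r, 1, tolerance = 1e-12)
})

test_that("correlation pairing modes give the expected sample sizes", {
  est <- make_estimates(rep(c("2", "5A"), each = 2), c(-9, -10, -7, -8))
  collagen <- tibble::tibble(
    specimen_id = paste0("C", 1:7),
    layer_id = c("2", "2", "2", "5A", "5A", "1", "1"),
    d13C = c(-19, -19.2, -19.1, -20.3, -20.2, -19.5, -19.6), d15N = 5
  )
  # layer 1 has no winter data: pairs come only from layers 2 and 5A
  per_spec <- season_collagen_correlation(est, collagen)
  expect_equal(per_spec$n, 5L)
  expect_error(
    season_collagen_correlation(est, collagen, pairing = "per_layer"),
    class = "paleoseas_insufficient_data_error"
  )
})

test_that("normality diagnostics behave on null and gross cases", {
  set.seed(8)
  hits <- mean(replicate(200, {
    normality_check(rnorm(50))$shapiro_p > 0.05
  }))
  expect_gte(hits, 0.9)
  bad <- normality_check(c(1, 1, 1, 100))
  expect_lt(bad$shapiro_p, 0.01)
  nc <- normality_check(rnorm(23))
  expect_equal(nrow(nc$qq), 23)  # quantile table length = input length
  expect_s3_class(autoplot(nc), "ggplot")
})
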