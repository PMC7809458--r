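test_that("damping factor closed forms", {
  expect_equal(damping_factor(0, 0, 30), 1)
  expect_equal(damping_factor(0, 15, 30), 2 / pi)
  expect_equal(damping_factor(15, 0, 30), 2 / pi)
})

test_that("closed form matches an independent numerical convolution", {
  lam <- 30
  mat <- lam / 4
  samp <- lam / 10
  f <- damping_factor(mat, samp, lam)
  dx <- lam / 2000
  x <- seq(0, 6 * lam, by = dx)
  v <- sin(2 * pi * x / lam)
  v <- oracle_moving_average(v, round(mat / dx))
  keep <- !is.na(v)
  x <- x[keep]; v <- v[keep]
  v <- oracle_moving_average(v, round(samp / dx))
  keep <- !is.na(v)
  x <- x[keep]; v <- v[keep]
  mid <- v[x > 2 * lam & x < 4 * lam]
  amp <- (max(mid) - min(mid)) / 2
  expect_equal(f, amp, tolerance = 1e-4)
})

test_that("forward_convolve attenuates amplitude by f", {
  lam <- 30
  x <- seq(0, 8 * lam, by = lam / 200)
  sig <- tibble::tibble(position_mm = x, value = sin(2 * pi * x / lam))
  # zero windows: identity
  out0 <- forward_convolve(sig, 0, 0, lam = lam)
  expect_equal(out0$value, sig$value)
  # half-wavelength window: 2/pi
  out2 <- forward_convolve(sig, lam / 2, 0, lam = lam)
  expect_equal((max(out2$value) - min(out2$value)) / 2, 2 / pi,
               tolerance = 1e-3)
  # full-wavelength window: first sinc zero annihilates the cycle
  out1 <- forward_convolve(sig, lam, 0, lam = lam)
  expect_lt(max(abs(out1$value)), 0.01)
  # coarse sampling refused
  coarse <- tibble::tibble(position_mm = seq(0, 8 * lam, by = lam / 10),
                           value = 0)
  expect_error(forward_convolve(coarse, 5, 0, lam = lam),
               class = "paleoseas_resolution_error")
})

test_that("damping factor is monotone non-increasing in window widths", {
  lam <- 35
  widths <- seq(0, 15, by = 1)
  f_mat <- sapply(widths, function(w) damping_factor(w, 1.5, lam))
  f_samp <- sapply(widths, function(w) damping_factor(12, w, lam))
  expect_true(all(diff(f_mat) <= 1e-12))
  expect_true(all(diff(f_samp) <= 1e-12))
  expect_error(damping_factor(20, 16, 35),
               class = "paleoseas_unreliable_error")
})

test_that("correct_extremes undoes damping and preserves the mean", {
  est <- tibble::tibble(
    tooth_id = "T1", layer_id = "2", method = "fitted",
    summer_peak = -5, winter_trough = -7, mean_annual = -6,
    seasonality = 2, completeness = "both_extremes"
  )
  fits <- tibble::tibble(tooth_id = "T1", lam = 30)
  # f = 1 leaves the estimate unchanged
  c1 <- correct_extremes(est, fits, 0, 0)
  expect_equal(c1$summer_peak, -5)
  expect_equal(c1$winter_trough, -7)
  # hand arithmetic at f = 0.8: A 1 -> 1.25; window solved so that
  # sinc(w/lam) = 0.8 exactly
  w <- uniroot(function(w) sinc(w / 30) - 0.8, c(0, 29), tol = 1e-12)$root
  c2 <- correct_extremes(est, fits, w, 0)
  expect_equal(c2$f, 0.8, tolerance = 1e-9)
  expect_equal(c2$summer_peak, -6 + 1 / 0.8, tolerance = 1e-8)
  expect_equal(c2$winter_trough, -6 - 1 / 0.8, tolerance = 1e-8)
  expect_equal(c2$mean_annual, -6)  # invariant under correction
  expect_equal(c2$summer_peak_raw, -5)
  # reliability floor
  w_low <- uniroot(function(w) sinc(w / 30) - 0.25, c(0, 29))$root
  expect_error(correct_extremes(est, fits, w_low, 0),
               class = "paleoseas_unreliable_error")
})

test_that("damp-then-correct recovers the true amplitude", {
  # generate with known true A = 2, damp to f ~ 0.7, refit, correct
  lam <- 30
  w <- uniroot(function(w) sinc(w / lam) - 0.7, c(0, lam - 1))$root
  errs <- sapply(1:20, function(seed) {
    set.seed(200 + seed)
    x <- seq(-w, 45 + w, by = lam / 200)
    dense <- tibble::tibble(position_mm = x,
                            value = -6 + 2 * sin(2 * pi * x / lam + seed))
    damped <- forward_convolve(dense, w, 0, lam = lam)
    pos <- seq(0, 45, length.out = 14)
    d <- tibble::tibble(
      tooth_id = "T1", layer_id = "2", position_mm = pos,
      d18O = approx(damped$position_mm, damped$value, pos)$y +
        rnorm(14, 0, 0.2)
    )
    fits <- fit_seasonal(d)
    est <- extract_seasonal(fits, method = "fitted")
    corr <- correct_extremes(est, fits, w, 0)
    abs(corr$seasonality / 2 - 2)
  })
  expect_lt(median(errs), 0.2)
})
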