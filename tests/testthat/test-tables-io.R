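test_that("enamel reader sorts by position within tooth and keeps extras", {
  path <- write_temp_csv(c(
    "tooth_id,layer_id,position_mm,d18O,note",
    "T1,2,2,-6.1,a", "T1,2,1,-6.5,b", "T1,2,3,-5.9,c"
  ))
  tbl <- read_samples(path, "enamel")
  expect_equal(tbl$position_mm, c(1, 2, 3))
  expect_equal(tbl$d18O, c(-6.5, -6.1, -5.9))
  expect_true("note" %in% names(tbl))  # unknown columns preserved
})

test_that("rows violating invariants are rejected with diagnostics", {
  path <- write_temp_csv(c(
    "tooth_id,layer_id,position_mm,d18O",
    "T1,2,1,-6.5", "T1,2,2,", "T1,2,3,-5.9", "T1,2,-1,-6.0"
  ))
  expect_warning(tbl <- read_samples(path, "enamel"), "rejected 2 row")
  expect_equal(nrow(tbl), 2)
  rej <- attr(tbl, "rejected")
  expect_equal(sort(rej$row), c(2, 4))
  expect_true(all(nzchar(rej$reason)))
})

test_that("missing required columns raise a format error", {
  path <- write_temp_csv(c("tooth_id,layer_id,d18O", "T1,2,-6.1"))
  expect_error(read_samples(path, "enamel"),
               class = "paleoseas_format_error")
  path2 <- write_temp_csv(c("tooth_id,position_mm", "T1,1"))
  expect_error(read_samples(path2, "sr"),
               class = "paleoseas_format_error")
})

test_that("duplicate (tooth, position) enamel rows are averaged with warning", {
  path <- write_temp_csv(c(
    "tooth_id,layer_id,position_mm,d18O",
    "T1,2,1,-6.0", "T1,2,1,-7.0", "T1,2,2,-5.0"
  ))
  expect_warning(tbl <- read_samples(path, "enamel"), "duplicate")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$d18O[tbl$position_mm == 1], -6.5)
})

test_that("occlusal position convention is flipped to the ERJ convention", {
  path <- write_temp_csv(c(
    "tooth_id,layer_id,position_mm,d18O",
    "T1,2,0,-6.0", "T1,2,10,-5.0", "T1,2,20,-4.0"
  ))
  tbl <- read_samples(path, "enamel", positions_from = "occlusal")
  expect_equal(tbl$position_mm, c(0, 10, 20))
  expect_equal(tbl$d18O, c(-4.0, -5.0, -6.0))
})

test_that("sr reader enforces the plausibility window", {
  path <- write_temp_csv(c(
    "tooth_id,sr_ratio", "T1,0.7104", "T1,0.75", "T2,0.7108"
  ))
  expect_warning(tbl <- read_samples(path, "sr"), "rejected 1 row")
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$sr_ratio > 0.70 & tbl$sr_ratio < 0.74))
})

test_that("collagen reader validates deltas and C:N", {
  path <- write_temp_csv(c(
    "specimen_id,layer_id,d13C,d15N,CN_ratio",
    "C1,2,-20.1,5.2,3.2", "C2,2,,4.8,3.1", "C3,5A,-19.8,4.4,-1"
  ))
  expect_warning(tbl <- read_samples(path, "collagen"), "rejected 2 row")
  expect_equal(tbl$specimen_id, "C1")
})

test_that("write then re-read is lossless for all typed fields", {
  sim <- simulate_isotopes(paper_like_scenario(seed = 3L))
  for (kind in c("enamel", "sr", "collagen")) {
    tbl <- sim[[kind]]
    path <- withr::local_tempfile(fileext = ".csv")
    readr::write_csv(tbl, path)
    back <- read_samples(path, kind)
    expect_equal(as.data.frame(back), as.data.frame(tbl),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("tooth_series enforces per-series invariants", {
  enamel <- tibble::tibble(
    tooth_id = c(rep("A", 4), "B"), layer_id = "2",
    position_mm = c(1, 2, 3, 4, 1), d18O = -6
  )
  expect_warning(nested <- tooth_series(enamel), "fewer than 3")
  expect_equal(nested$tooth_id, "A")
  expect_equal(nested$n_samples, 4L)
  dup <- tibble::tibble(tooth_id = "A", layer_id = "2",
                        position_mm = c(1, 1, 2), d18O = -6)
  expect_error(tooth_series(dup), class = "paleoseas_format_error")
})

test_that("two-point normalization is the exact affine standard map", {
  ident <- normalization_standards(c(10, 20), c(10, 20))
  expect_equal(two_point_normalize(15, ident), 15)
  std <- normalization_standards(measured = c(0, 10), accepted = c(2, 22))
  expect_equal(two_point_normalize(5, std), 12)
  expect_error(normalization_standards(c(5, 5), c(1, 2)),
               class = "paleoseas_degenerate_error")
})

test_that("normalization round-trips through the inverse map exactly", {
  set.seed(42)
  for (i in 1:5) {
    m <- sort(runif(2, -5, 30))
    a <- runif(2, 15, 40)
    std <- normalization_standards(m, a)
    inv <- normalization_standards(a, m)  # constructed inverse
    raw <- runif(100, -10, 40)
    back <- two_point_normalize(two_point_normalize(raw, std), inv)
    expect_lt(max(abs(back - raw)), 1e-12)
  }
})

test_that("normalization is exactly affine in its argument", {
  std <- normalization_standards(c(1, 9), c(3, 25))
  x <- 1.7
  shifts <- two_point_normalize(x + c(0, 2, -4, 10), std) -
    two_point_normalize(c(0, 2, -4, 10), std)
  expect_equal(shifts, rep(shifts[1], 4))
})
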