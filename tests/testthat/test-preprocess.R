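test_that("a 1355-column B-scan averaged by 10 and trimmed by 15 leaves 106 columns", {
  bscan <- matrix(rnorm(8 * 1355), 8, 1355)
  avg <- average_columns(bscan, 10)
  expect_equal(ncol(avg$intensity), 136)
  trimmed <- trim_edges(avg, 15)
  expect_equal(ncol(trimmed$intensity), 106)
  expect_equal(trimmed$trimmed, 15L)
  # trailing partial block is the mean of the 5 remaining raw columns
  expect_equal(avg$intensity[, 136], rowMeans(bscan[, 1351:1355]))
  expect_equal(avg$intensity[, 1], rowMeans(bscan[, 1:10]))
})

test_that("column counts match brute-force block enumeration across sizes", {
  set.seed(42)
  for (rep in 1:25) {
    n_raw <- sample(20:300, 1)
    window <- sample(1:15, 1)
    bscan <- matrix(rnorm(3 * n_raw), 3, n_raw)
    avg <- average_columns(bscan, window)
    # brute force: enumerate blocks, including the trailing partial one
    starts <- seq(1, n_raw, by = window)
    expect_equal(ncol(avg$intensity), length(starts))
    expect_equal(ncol(avg$intensity), ceiling(n_raw / window))
    for (j in seq_along(starts)) {
      cols <- starts[j]:min(starts[j] + window - 1, n_raw)
      expect_equal(avg$intensity[, j], rowMeans(bscan[, cols, drop = FALSE]))
    }
    n_trim <- sample(0:3, 1)
    if (2 * n_trim < length(starts))
      expect_equal(ncol(trim_edges(avg, n_trim)$intensity),
                   length(starts) - 2 * n_trim)
  }
})

test_that("degenerate averaging and trimming cases behave as documented", {
  m <- matrix(5, 4, 10)
  one <- average_columns(m, 10)
  expect_equal(dim(one$intensity), c(4, 1))
  expect_true(all(one$intensity == 5))
  # window wider than the B-scan: single column, not an error
  expect_equal(ncol(average_columns(m, 50)$intensity), 1)
  r <- matrix(rnorm(40), 4, 10)
  expect_equal(average_columns(r, 1)$intensity, r)
  avg <- average_columns(r, 2)
  expect_identical(trim_edges(avg, 0)$intensity, avg$intensity)
  expect_error(trim_edges(avg, 3), "leave nothing")
  expect_error(average_columns(r, 0))
})

test_that("averaging then trimming commutes with trimming raw columns by window multiples", {
  set.seed(7)
  bscan <- matrix(rnorm(5 * 120), 5, 120)
  window <- 10
  for (n_trim in 1:3) {
    a <- trim_edges(average_columns(bscan, window), n_trim)$intensity
    raw_trim <- bscan[, (n_trim * window + 1):(120 - n_trim * window)]
    b <- average_columns(raw_trim, window)$intensity
    expect_equal(a, b)
  }
})

test_that("calibration recovers the phantom noise floor and validates regions", {
  px <- phantom_with_cal(small_spec(n_ascans = 200, n_bscans = 10, seed = 31))
  cal <- px$cal
  # air mean approximates the log noise-floor amplitude; speckle shifts the
  # mean of log by digamma(k) - log(k)
  expected_air <- log(1e-9) + digamma(16) - log(16)
  voxels <- octskin:::annotation_voxels(
    px$volume, octskin:::truth_annotations(px$truth, px$volume, "v")[[1]])
  se <- sd(voxels) / sqrt(length(voxels))
  expect_lt(abs(cal$air_mean - expected_air), 4 * se)
  expect_lt(cal$air_mean, cal$muscle_mean)
  expect_gt(cal$prominence_threshold, 0)

  # pooling a reference with itself changes nothing
  ref <- list(volume = px$volume,
              annotations = octskin:::truth_annotations(px$truth, px$volume, "v"))
  expect_equal(calibrate(list(ref, ref))[c("air_mean", "muscle_mean",
                                           "prominence_threshold")],
               calibrate(list(ref))[c("air_mean", "muscle_mean",
                                      "prominence_threshold")])

  # air annotated deeper than muscle is rejected
  swapped <- list(volume = px$volume, annotations = rev(ref$annotations))
  swapped$annotations[[1]]$region <- "air"
  swapped$annotations[[2]]$region <- "muscle"
  expect_error(calibrate(list(swapped)), "shallower")

  # uniform volume: air mean cannot sit below muscle mean
  flat <- oct_volume(array(1, c(60, 10, 2)), 4, 4.4)
  uni <- list(volume = flat,
              annotations = list(
                region_annotation("f", "air", c(0, 10), c(0, 10), c(0, 2)),
                region_annotation("f", "muscle", c(40, 50), c(0, 10), c(0, 2))))
  expect_error(calibrate(list(uni)), "calibration failure")
})
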