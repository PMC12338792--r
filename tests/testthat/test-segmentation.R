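test_that("peak detection matches the brute-force prominence oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(20:80, 1)
    x <- rnorm(n)
    if (rep %% 3 == 0) x <- round(x, 1)          # induce plateaus
    floor_ <- quantile(x, runif(1, 0.1, 0.6))
    prom <- runif(1, 0.1, 1.5)
    expect_identical(detect_peaks(x, floor_, prom),
                     as.integer(oracle_peaks(x, floor_, prom)),
                     info = sprintf("rep %d", rep))
  }
})

test_that("peak detection honours floor, prominence and plateau conventions", {
  prof <- rep(0, 30)
  prof[12] <- 5; prof[18] <- 4
  expect_equal(detect_peaks(prof, noise_floor = 1, prominence = 2), c(12, 18))
  expect_equal(detect_peaks(rep(3, 25), 0, 0.5), integer(0))
  low <- rep(0, 20); low[7] <- 0.8
  expect_equal(detect_peaks(low, noise_floor = 1, prominence = 0.5), integer(0))
  shallow <- c(0, 1, 3, 3, 3, 1, 0)
  expect_equal(detect_peaks(shallow, -1, 1), 3L)   # plateau -> shallowest index
  expect_equal(detect_peaks(prof, 1, 4.5), 12L)    # second peak under-prominent
})

test_that("muscle boundary search skips the surface flank and applies the threshold", {
  px <- phantom_with_cal(noiseless_spec(mu = 30))
  avg <- preprocess_volume(px$volume, window = 10, n_trim = 1)
  col <- avg[, 2, 1]
  truth_px <- octskin:::interface_pixel(px$truth$muscle_depth[1, 1], 4)
  surface <- detect_peaks(col, px$cal$air_mean, px$cal$prominence_threshold)[1]
  found <- detect_muscle_boundary(col, surface, px$cal$muscle_mean,
                                  descent = px$cal$prominence_threshold)
  expect_lte(abs(found - truth_px), 1)
  expect_true(is.na(detect_muscle_boundary(col, surface, min(col) - 1)))
  expect_true(is.na(detect_muscle_boundary(rep(5, 40), 3, 4, descent = 10)))
})

test_that("noiseless phantom columns segment to ground truth within one pixel", {
  px <- phantom_with_cal(noiseless_spec(mu = 40, n_ascans = 60, n_bscans = 3))
  avg <- preprocess_volume(px$volume, window = 10, n_trim = 1)
  seg <- segment_volume(avg, px$cal)
  expect_true(all(seg$valid))
  surf_px <- octskin:::interface_pixel(100, 4)
  dej_px <- octskin:::interface_pixel(120, 4)
  musc_px <- octskin:::interface_pixel(520, 4)
  expect_true(all(abs(seg$surface_idx - surf_px) <= 1))
  expect_true(all(abs(seg$dej_idx - dej_px) <= 1))
  expect_true(all(abs(seg$muscle_idx - musc_px) <= 1))
})

test_that("columns with missing or disordered boundaries are invalid, not errors", {
  cal <- structure(list(air_mean = -1, muscle_mean = 2,
                        prominence_threshold = 1),
                   class = "calibration_reference")
  single <- rep(0, 40); single[10] <- 5
  s <- segment_column(single, cal)
  expect_false(s$valid)
  expect_true(is.na(s$dej_idx))
  # boundary (first drop below muscle mean) lands before the second peak
  tangled <- rep(0, 40); tangled[10] <- 5; tangled[30] <- 5
  tangled[12:28] <- 1.5
  cal$muscle_mean <- 1.6
  s2 <- segment_column(tangled, cal)
  expect_false(s2$valid)
})

test_that("thickness follows (muscle - surface) * pitch over valid columns only", {
  seg <- data.frame(bscan = 1, column = 1:3,
                    surface_idx = c(10L, 10L, NA), dej_idx = c(15L, 15L, NA),
                    muscle_idx = c(110L, 120L, NA),
                    valid = c(TRUE, TRUE, FALSE))
  th <- measure_thickness(seg, 4.0)
  expect_equal(th$per_ascan, c(400, 440))
  expect_equal(th$volume_mean, 420)
  expect_equal(th$n_valid, 2)
  expect_equal(th$n_total, 3)
  expect_equal(measure_thickness(seg, 4.0, refractive_index = 1.4)$volume_mean,
               300)
  seg$valid <- FALSE
  expect_error(measure_thickness(seg, 4.0), "failed")
})

test_that("segmentation is equivariant to a constant log-intensity shift", {
  px <- phantom_with_cal(small_spec(n_ascans = 60, n_bscans = 2, seed = 8))
  avg <- preprocess_volume(px$volume, window = 10, n_trim = 1)
  seg1 <- segment_volume(avg, px$cal)
  cal2 <- px$cal
  cal2$air_mean <- cal2$air_mean + 7.5
  cal2$muscle_mean <- cal2$muscle_mean + 7.5
  seg2 <- segment_volume(avg + 7.5, cal2)
  expect_identical(seg1, seg2)
})

test_that("thicker phantoms measure correspondingly thicker, pixel for pixel", {
  base <- NULL
  for (extra_px in c(0, 5, 12)) {
    spec <- noiseless_spec(mu = 30, n_ascans = 40, n_bscans = 2)
    spec$layers[[3]]$thickness <- 400 + extra_px * 4
    spec <- phantom_spec(spec$layers, n_ascans_per_bscan = 40, n_bscans = 2,
                         speckle_shape = Inf, thickness_jitter = 0)
    m <- phantom_metrics(spec, n_trim = 1)
    if (extra_px == 0) base <- m$thickness$volume_mean
    expect_lte(abs(m$thickness$volume_mean - (base + extra_px * 4)), 4)
  }
})
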