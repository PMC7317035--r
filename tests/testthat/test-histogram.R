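# The high-signal threshold chain: histogram construction, first peak,
# sharpest decline, tangent intercept, volumes.

test_that("histograms conserve voxels and span the ROI intensities", {
  set.seed(10)
  dims <- c(10, 10, 10)
  v <- volume3d(array(rexp(1000, 1 / 50), dim = dims), 0.4, "MRI")
  m <- lung_mask(array(runif(1000) < 0.9, dim = dims), 0.4)
  h <- build_histogram(v, m)
  expect_equal(sum(h$counts), sum(m))
  expect_equal(h$n_voxels, sum(m))
  # hot voxels above the robust range are clipped, not dropped
  hmax <- build_histogram(v, m, range_policy = "max")
  expect_equal(sum(hmax$counts), sum(m))
  expect_error(build_histogram(v, lung_mask(array(FALSE, dims), 0.4)), "empty mask")
  expect_error(build_histogram(v, m, n_bins = 8), "n_bins")
})

test_that("a constant ROI lands in a single bin", {
  v <- make_uniform_volume(5)
  m <- make_full_mask()
  h <- build_histogram(v, m, range = c(0, 10))
  expect_equal(max(h$counts), sum(m))
  expect_equal(sum(h$counts > 0), 1)
})

test_that("first peak is the lowest-intensity prominent mode", {
  ph <- make_lung_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L),
                                       lesion_fraction = 0.2))
  h <- build_histogram(ph$long, ph$mask)
  p <- find_first_peak(h)
  expect_lt(abs(h$bin_centers[p] - 100), 5 * h$bin_width[1])
  # never the high-signal mode, even though it is also prominent
  expect_lt(h$bin_centers[p], 200)
  # agreement with the exhaustive local-maxima oracle
  y <- h$smoothed_counts
  prominent <- Filter(function(i) oracle_prominence(y, i) >= 0.05 * max(y),
                      oracle_local_maxima(y))
  expect_equal(p, min(prominent))
})

test_that("boundary and degenerate histograms follow the stated conventions", {
  # strictly decreasing: bin 1 is admitted as the peak
  h <- intensity_histogram(0:5, c(10, 8, 5, 3, 1), smooth_window = 1)
  expect_equal(find_first_peak(h), 1L)
  # flat: no peak
  expect_error(find_first_peak(intensity_histogram(0:5, rep(3, 5), smooth_window = 1)),
               "degenerate")
  # monotone increasing after the peak claim: no declining slope
  h2 <- intensity_histogram(0:5, c(1, 2, 3, 4, 5), smooth_window = 1)
  expect_error(find_sharpest_decline(h2, find_first_peak(h2)), "declining")
})

test_that("sharpest decline matches the worked example and brute force", {
  h <- intensity_histogram(0:6, c(1, 8, 4, 2, 1, 1), smooth_window = 1)
  p <- find_first_peak(h)
  expect_equal(p, 2L)
  d <- find_sharpest_decline(h, p)
  expect_equal(d, 3L)  # central difference (2 - 8)/2 = -3 is the minimum
  o <- oracle_threshold_chain(h$bin_centers, h$bin_width, h$smoothed_counts)
  expect_equal(o$peak, p)
  expect_equal(o$decline, d)
  expect_equal(tangent_threshold(h, d), o$threshold)
})

test_that("decline sits near the inflection of a Gaussian mode", {
  m <- 100; s <- 20; bw <- 2
  edges <- seq(0, 300, by = bw)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- round(1e6 * dnorm(centers, m, s) * bw)
  h <- intensity_histogram(edges, counts)
  d <- find_sharpest_decline(h, find_first_peak(h))
  expect_lt(abs(h$bin_centers[d] - (m + s)), 2 * bw)
})

test_that("tangent intercept follows the line geometry", {
  # line through (10, 6) with slope -3 per unit crosses zero at 12
  h <- intensity_histogram(seq(6.5, 13.5, by = 1), c(14, 12, 9, 6, 3, 2, 1),
                           smooth_window = 1)
  expect_equal(h$bin_centers[4], 10)
  expect_equal(tangent_threshold(h, 4L), 12)
  # zero count at the decline point: threshold is the bin centre itself
  h0 <- intensity_histogram(seq(0.5, 7.5, by = 1), c(9, 6, 3, 0, 0, 0, 0),
                            smooth_window = 1)
  expect_equal(tangent_threshold(h0, 4L), h0$bin_centers[4])
  # non-negative slope errors
  rising <- intensity_histogram(0:5, c(1, 2, 3, 4, 5), smooth_window = 1)
  expect_error(tangent_threshold(rising, 3L), "negative")
})

test_that("single-Gaussian threshold approximates the mode plus two sigmas", {
  m <- 100; s <- 20; bw <- s / 10
  edges <- seq(0, 300, by = bw)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- round(1e6 * dnorm(centers, m, s) * bw)
  h <- intensity_histogram(edges, counts)
  thr <- tangent_threshold(h, find_sharpest_decline(h, find_first_peak(h)))
  expect_lt(abs(thr - (m + 2 * s)), 1.5 * bw)
})

test_that("high-signal counting is strict, conservative and monotone", {
  set.seed(11)
  dims <- c(12, 12, 12)
  v <- volume3d(array(rnorm(prod(dims), 100, 20), dim = dims), 0.4, "MRI")
  m <- lung_mask(array(runif(prod(dims)) < 0.7, dim = dims), 0.4)
  vv <- voxel_volume_mm3(v)
  roi_n <- sum(m)
  prev <- Inf
  for (thr in c(-Inf, 60, 90, 100, 110, 140, Inf)) {
    r <- high_signal_volume(v, m, min(max(thr, -1e12), 1e12))
    low_n <- sum(unclass(v)[unclass(m)] <= r$threshold)
    expect_identical(r$high_signal_voxels + low_n, roi_n)   # exact conservation
    expect_equal(r$total_roi_volume_mm3, roi_n * vv)
    expect_lte(r$high_signal_volume_mm3, prev)              # monotone in threshold
    prev <- r$high_signal_volume_mm3
  }
  # extremes
  expect_equal(high_signal_volume(v, m, max(unclass(v)))$high_signal_volume_mm3, 0)
  expect_equal(high_signal_volume(v, m, min(unclass(v)) - 1)$high_signal_volume_mm3,
               roi_n * vv)
})

test_that("threshold chain is shift- and scale-equivariant", {
  ph <- make_lung_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L)))
  rng <- c(0, quantile(unclass(ph$long)[unclass(ph$mask)], 0.995, names = FALSE))
  base <- threshold_scan(ph$long, ph$mask, range = rng)
  shift <- 37.5
  vs <- volume3d(unclass(ph$long) + shift, attr(ph$long, "voxel_mm"), "MRI")
  rs <- threshold_scan(vs, ph$mask, range = rng + shift)
  expect_equal(rs$threshold, base$threshold + shift, tolerance = 1e-9)
  expect_equal(rs$peak_bin_center, base$peak_bin_center + shift, tolerance = 1e-9)
  expect_identical(rs$high_signal_voxels, base$high_signal_voxels)
  k <- 2.5
  vk <- volume3d(unclass(ph$long) * k, attr(ph$long, "voxel_mm"), "MRI")
  rk <- threshold_scan(vk, ph$mask, range = rng * k)
  expect_equal(rk$threshold, base$threshold * k, tolerance = 1e-9)
  expect_identical(rk$high_signal_voxels, base$high_signal_voxels)
})

test_that("quantify_scan reports per-echo results and total lung volume", {
  dims <- c(24, 24, 24)
  mask_arr <- array(FALSE, dim = dims)
  mask_arr[seq_len(12500)] <- TRUE
  m <- lung_mask(mask_arr, 0.4)
  expect_equal(mask_volume_mm3(m), 800)   # 12500 x 0.064 mm^3

  ph <- make_lung_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L)))
  q <- quantify_scan(ph$long, ph$long, ph$mask)
  expect_equal(q$short$threshold, q$long$threshold)
  expect_equal(q$short$high_signal_volume_mm3, q$long$high_signal_volume_mm3)
  expect_equal(q$total_lung_volume_mm3, mask_volume_mm3(ph$mask))

  # no-lesion phantom: only the parenchyma tail exceeds the threshold
  # (run at the full 64^3 geometry: 256 bins need a big ROI for stable counts)
  ph0 <- make_lung_phantom(phantom_spec(lesion_fraction = 0))
  q0 <- quantify_scan(ph0$short, ph0$long, ph0$mask)
  expect_lt(q0$long$high_signal_volume_mm3 / q0$total_lung_volume_mm3, 0.05)
  expect_lt(q0$short$high_signal_volume_mm3 / q0$total_lung_volume_mm3, 0.05)
})

test_that("high-signal mask can be exported and matches the count", {
  ph <- make_lung_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L)))
  r <- threshold_scan(ph$long, ph$mask, return_mask = TRUE)
  expect_equal(sum(r$high_signal_mask), r$high_signal_voxels)
  expect_true(all(unclass(ph$mask)[unclass(r$high_signal_mask)]))
})
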