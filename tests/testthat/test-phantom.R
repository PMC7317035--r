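# Phantom and cohort generators: ground truth, determinism, trajectories.

small_spec <- function(...) phantom_spec(grid_shape = c(32L, 32L, 32L), ...)

test_that("phantom geometry matches its specification exactly", {
  ph <- make_lung_phantom(small_spec(lesion_fraction = 0.1))
  lung <- unclass(ph$mask); lesion <- unclass(ph$truth$lesion_mask)
  # lesion nested inside lung
  expect_true(all(lung[lesion]))
  # lesion voxel count hits the target within one voxel
  expect_lte(abs(sum(lesion) - 0.1 * sum(lung)), 1)
  expect_equal(ph$truth$true_lesion_volume_mm3,
               sum(lesion) * voxel_volume_mm3(ph$mask))
  expect_equal(ph$truth$true_lung_volume_mm3,
               sum(lung) * voxel_volume_mm3(ph$mask))
  # lung occupies roughly the requested fraction of the grid
  expect_lt(abs(mean(lung) - 0.3), 0.02)
})

test_that("no-lesion phantom has empty lesion mask and zero lesion volume", {
  ph <- make_lung_phantom(small_spec(lesion_fraction = 0))
  expect_equal(sum(ph$truth$lesion_mask), 0)
  expect_equal(ph$truth$true_lesion_volume_mm3, 0)
})

test_that("phantom generation is deterministic under a seed", {
  a <- make_lung_phantom(small_spec(seed = 11L))
  b <- make_lung_phantom(small_spec(seed = 11L))
  expect_identical(unclass(a$long), unclass(b$long))
  expect_identical(unclass(a$short), unclass(b$short))
  expect_identical(unclass(a$pet), unclass(b$pet))
  c <- make_lung_phantom(small_spec(seed = 12L))
  expect_false(identical(unclass(a$long), unclass(c$long)))
})

test_that("unachievable lesion fractions error with the achievable maximum", {
  expect_error(make_lung_phantom(small_spec(lesion_fraction = 0.85)),
               "achievable maximum")
  expect_error(phantom_spec(mu_low = 300, mu_high = 100), "mu_high")
  expect_error(phantom_spec(lung_fraction = 1.2), "lung_fraction")
})

test_that("well-separated modes give a bimodal in-ROI histogram", {
  # separation 8 x max(sigma): two local maxima must survive smoothing
  ph <- make_lung_phantom(small_spec(mu_low = 100, sigma_low = 20,
                                     mu_high = 300, sigma_high = 25,
                                     lesion_fraction = 0.15))
  h <- build_histogram(ph$long, ph$mask)
  maxima <- oracle_local_maxima(h$smoothed_counts)
  prominent <- maxima[vapply(maxima, function(i)
    oracle_prominence(h$smoothed_counts, i) >= 0.05 * max(h$smoothed_counts),
    logical(1))]
  expect_gte(length(prominent), 2)
  # modes located near the generating means (within one smoothing window)
  locs <- h$bin_centers[prominent]
  expect_lt(min(abs(locs - 100)), 5 * h$bin_width[1])
  expect_lt(min(abs(locs - 300)), 5 * h$bin_width[1])
})

test_that("PET channel is elevated inside the lesion", {
  ph <- make_lung_phantom(small_spec(lesion_fraction = 0.15))
  les <- unclass(ph$truth$lesion_mask)
  paren <- unclass(ph$mask) & !les
  expect_gt(mean(unclass(ph$pet)[les]), mean(unclass(ph$pet)[paren]) + 2)
})

test_that("cohort trajectories implement the designed arm structure", {
  tc <- make_cohort(cohort_spec(seed = 1L), small_spec())
  final <- max(tc$day)
  m <- tapply(tc$lung_volume_mm3[tc$day == final], tc$arm[tc$day == final], mean)
  expect_gt(m[["high"]], m[["low"]])
  # low arm returns toward control by the final day; high arm stays elevated
  expect_lt((m[["low"]] - m[["control"]]) / m[["control"]], 0.05)
  expect_gt((m[["high"]] - m[["control"]]) / m[["control"]], 0.15)
  # inflammation bump: lesion burden peaks at the peak day in the low arm
  low <- tc[tc$arm == "low", ]
  peak_day <- unique(low$day)[which.max(tapply(low$lesion_volume_mm3, low$day, mean))]
  expect_equal(peak_day, 7)
  # controls carry no lesion at any day
  expect_true(all(tc$lesion_volume_mm3[tc$arm == "control"] == 0))
  # baseline present for every animal
  expect_true(all(tapply(tc$day, tc$animal_id, function(d) 0 %in% d)))
})

test_that("noiseless cohorts are identical within arm and seeded runs reproduce", {
  cs <- cohort_spec(noise_cv = 0, seed = 3L)
  tc <- make_cohort(cs, small_spec())
  for (a in c("control", "low", "high")) {
    arm <- tc[tc$arm == a, ]
    traj <- split(arm$lung_volume_mm3, arm$animal_id)
    for (t2 in traj[-1]) expect_equal(unname(t2), unname(traj[[1]]))
  }
  expect_identical(make_cohort(cs, small_spec())$lung_volume_mm3,
                   tc$lung_volume_mm3)
})

test_that("controls-only cohorts are allowed but empty arms of controls are not", {
  tc <- make_cohort(cohort_spec(n_low = 0L, n_high = 0L), small_spec())
  expect_true(all(tc$arm == "control"))
  expect_true(all(tc$lesion_volume_mm3 == 0))
  expect_error(cohort_spec(n_control = 0L), "control")
  expect_error(cohort_spec(n_low = -1L), "nonnegative")
})

test_that("cohort rows materialise into phantoms matching the design", {
  tc <- make_cohort(cohort_spec(noise_cv = 0), small_spec())
  row <- tc[tc$arm == "high" & tc$day == 7, ][1, ]
  ph <- cohort_phantom(row, small_spec())
  expect_equal(ph$truth$true_lesion_volume_mm3 / ph$truth$true_lung_volume_mm3,
               row$lesion_fraction, tolerance = 0.02)
})

test_that("qPCR table generator injects effects as Ct shifts and is seeded", {
  genes <- c("grem1", "actb", "b2m", "hprt1", "ldha", "rplp1")
  refs <- genes[-1]
  eff <- data.frame(gene = "grem1", group = "bleomycin", day = NA, log2fc = 2)
  ct <- make_qpcr_table(genes, refs, effects = eff, noise_sd = 0,
                        sample_shift_sd = 0, seed = 5L)
  # +2 log2 effect lowers the target Ct by exactly 2 cycles
  d7 <- ct[ct$day == 7, ]
  expect_equal(mean(d7$grem1[d7$group == "bleomycin"]),
               mean(d7$grem1[d7$group == "control"]) - 2)
  # reference genes unaffected by group
  expect_equal(mean(d7$actb[d7$group == "bleomycin"]),
               mean(d7$actb[d7$group == "control"]))
  expect_identical(ct, make_qpcr_table(genes, refs, effects = eff, noise_sd = 0,
                                       sample_shift_sd = 0, seed = 5L))
  expect_error(make_qpcr_table(genes, character(0)), "reference")
  expect_error(make_qpcr_table(genes, refs,
                               effects = data.frame(gene = "actb", group = "x",
                                                    log2fc = 1)),
               "reference genes")
})
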