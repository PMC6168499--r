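test_that("layouts carry the documented well counts", {
  lay <- generate_layout()
  expect_equal(lay$n_rows * lay$n_cols, 240)
  expect_equal(nrow(well_centers(lay)), 240)
  alt <- generate_layout(n_rows = 5, well_size = 250, well_pitch = 255)
  expect_equal(alt$n_rows, 5L)
  expect_equal(alt$well_size, 250)
  single <- generate_layout(1, 1)
  expect_equal(nrow(well_centers(single)), 1)
  expect_error(generate_layout(0, 10), "n_rows")
})

test_that("seeding sizes are reproducible, in-band, and larger at the channel ends", {
  lay <- generate_layout()
  d1 <- sample_seeding_sizes(lay, seed = 11)
  d2 <- sample_seeding_sizes(lay, seed = 11)
  expect_identical(d1, d2)
  for (seed in c(1, 7, 123)) {
    d <- sample_seeding_sizes(lay, seed = seed)
    expect_gte(mean(d$diameter_um >= 50 & d$diameter_um <= 100), 0.90)
  }
  # Monte-Carlo estimate of the generator's own mean profile
  ends <- mids <- numeric(200)
  for (i in 1:200) {
    d <- sample_seeding_sizes(lay, seed = i)
    ends[i] <- mean(d$diameter_um[d$col %in% c(1, lay$n_cols)])
    mids[i] <- mean(d$diameter_um[d$col %in% c(15, 16)])
  }
  expect_gt(mean(ends), mean(mids))
  expect_error(
    sample_seeding_sizes(lay, 1, size_params = list(end_mean = 200)),
    "larger than the wells")
})

test_that("ground-truth contours have exact circle limits and monotone roughening", {
  circ <- spheroid_contour(50, 0, n_vertices = 720)
  expect_equal(polygon_area(circ), pi * 50^2, tolerance = 0.005)
  expect_lt(abs(shape_factor(circ) - 1), 0.005)
  sf <- vapply(c(0.05, 0.1, 0.2, 0.3), function(a) {
    shape_factor(spheroid_contour(50, a, seed = 5))
  }, numeric(1))
  expect_true(all(diff(sf) > 0))
  expect_error(spheroid_contour(-1, 0), "radius")
  expect_error(spheroid_contour(50, 1.2), "amplitude")
})

test_that("hill effect spans 0 to 1 with EC50 at half effect", {
  expect_equal(hill_effect(0, 100, 3), 0)
  expect_equal(hill_effect(100, 100, 3), 0.5)
  expect_gt(hill_effect(1e5, 100, 3), 0.999)
  e <- hill_effect(seq(1, 500, by = 1), 100, 2)
  expect_true(all(diff(e) > 0))
})

test_that("rendered wells round-trip through the analyzer", {
  lay <- generate_layout(n_rows = 2, n_cols = 4)
  # dose 0 everywhere: fully viable control
  gt0 <- ground_truth(lay, seed = 3, row_doses = c(0, 0))
  imgs <- render_experiment(lay, gt0, days = c(4, 8), seed = 3)
  meas <- measure_timecourse(imgs)
  vf <- meas$viable_fraction[meas$day == 8]
  expect_true(all(abs(vf - 1) < 0.10))   # grown slightly, stained fully

  # known half-viability, unchanged size
  crop <- gradspheroid:::render_crop(50, 0.03, viable = 0.5, contour_seed = 2,
                                     crop_px = 150, pixel_scale = 1,
                                     noise_sd = 0.03, endpoint = TRUE,
                                     rng_seed = 9)
  seg_bf <- segment_spheroid(crop$brightfield)
  seg_fda <- segment_spheroid(crop$fda, segmentation_params(polarity = "bright"))
  expect_equal(seg_fda$area_um2 / seg_bf$area_um2, 0.5, tolerance = 0.10)

  # saturating dose in disaggregation mode: final-day S_F above baseline
  gt_hi <- ground_truth(lay, seed = 4, ec50 = 10, hill = 3,
                        row_doses = c(500, 500), ec50_cv = 0)
  imgs_hi <- render_experiment(lay, gt_hi, days = c(4, 8), seed = 4)
  m <- measure_timecourse(imgs_hi)
  expect_gt(mean(m$shape_factor[m$day == 8]),
            mean(m$shape_factor[m$day == 4]))
})

test_that("rendering is deterministic under fixed seeds", {
  lay <- generate_layout(n_rows = 2, n_cols = 3)
  gt <- ground_truth(lay, seed = 5)
  a <- render_experiment(lay, gt, days = c(4, 8), seed = 9)
  b <- render_experiment(lay, gt, days = c(4, 8), seed = 9)
  expect_identical(a$images, b$images)
  c <- render_experiment(lay, gt, days = c(4, 8), seed = 10)
  expect_false(identical(a$images, c$images))
})

test_that("measured shape factors track the polygon oracle on rendered spheroids", {
  amps <- c(0, 0.05, 0.1, 0.18, 0.25, 0.32)
  oracle <- measured <- numeric(length(amps))
  for (i in seq_along(amps)) {
    xy <- spheroid_contour(45, amps[i], seed = 20 + i)
    oracle[i] <- shape_factor(xy)
    crop <- rendered_disk(45, amps[i], seed = 30 + i, contour_seed = 20 + i)
    measured[i] <- shape_factor(segment_spheroid(crop$brightfield))
  }
  expect_lt(mean(abs(measured - oracle)), 0.05)
  expect_gt(stats::cor(measured, oracle), 0.95)
})

test_that("image sets survive a disk round trip", {
  lay <- generate_layout(n_rows = 2, n_cols = 2)
  gt <- ground_truth(lay, seed = 6)
  imgs <- render_experiment(lay, gt, days = c(4, 8), seed = 6)
  dir <- withr::local_tempdir()
  write_image_set(imgs, dir)
  back <- read_image_set(dir)
  expect_equal(back$drug_day, 5)
  m1 <- measure_timecourse(imgs)
  m2 <- measure_timecourse(back)
  expect_equal(m1$area_um2, m2$area_um2, tolerance = 0.01)
})
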