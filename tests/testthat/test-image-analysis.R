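test_that("segmentation recovers clean synthetic disks with high overlap", {
  xy <- spheroid_contour(55, 0.1, seed = 8)
  crop <- rendered_disk(55, 0.1, seed = 2, noise_sd = 0.02, contour_seed = 8)
  seg <- segment_spheroid(crop$brightfield)
  truth <- contour_mask(xy, ncol(crop$brightfield))
  iou <- sum(seg$mask & truth) / sum(seg$mask | truth)
  expect_gte(iou, 0.95)
  expect_length(seg$flags, 0)
})

test_that("segmentation flags blanks and multiple objects", {
  set.seed(1)
  blank <- matrix(0.85 + rnorm(150^2, 0, 0.03), 150)
  seg <- segment_spheroid(blank)
  expect_true("no_detection" %in% seg$flags)
  expect_true(is.na(seg$area_um2))

  two <- matrix(0.85, 160, 160)
  xg <- matrix(seq_len(160), 160, 160, byrow = TRUE)
  yg <- matrix(seq_len(160), 160, 160)
  two[(xg - 45)^2 + (yg - 45)^2 < 30^2] <- 0.4
  two[(xg - 115)^2 + (yg - 115)^2 < 20^2] <- 0.4
  seg2 <- segment_spheroid(two + rnorm(160^2, 0, 0.01))
  expect_true("multi_object" %in% seg2$flags)
  expect_equal(seg2$area_um2, pi * 30^2, tolerance = 0.05)  # largest kept
})

test_that("shape factor hits the closed forms and the isoperimetric bound", {
  # ideal circle: exactly 1 in the continuum (polygonal truncation only)
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(cos(theta), sin(theta)) * 40
  expect_equal(shape_factor(circle), 1, tolerance = 1e-4)

  # rendered circle at radius >= 32 px: within 2%
  crop <- rendered_disk(32, 0, seed = 5)
  expect_lt(abs(shape_factor(segment_spheroid(crop$brightfield)) - 1), 0.02)

  # axis-aligned square: 4/pi
  s <- 50
  square <- cbind(c(0, s / 2, s, s, s, s / 2, 0, 0),
                  c(0, 0, 0, s / 2, s, s, s, s / 2))
  expect_equal(shape_factor(square), 4 / pi, tolerance = 0.01)

  # scale invariance to <= 0.1%
  xy <- spheroid_contour(50, 0.2, seed = 3)
  expect_equal(shape_factor(xy * 17.3), shape_factor(xy), tolerance = 1e-3)

  # isoperimetric bound on every detection across seeds and amplitudes
  for (i in 1:8) {
    a <- c(0, 0.05, 0.15, 0.25)[(i %% 4) + 1]
    crop <- rendered_disk(30 + 7 * i, a, seed = 40 + i, contour_seed = i)
    sf <- shape_factor(segment_spheroid(crop$brightfield))
    expect_gte(sf, 1 - 0.02)
  }
  expect_error(shape_factor(cbind(1:3, 1:3)), "8 vertices")
  degenerate <- cbind(rep(1, 10), rep(2, 10))
  expect_error(shape_factor(degenerate), "area")
})

test_that("viable fraction is the FDA/baseline area ratio with status annotation", {
  vf <- viable_fraction(c(5000 * pi, 0, 2500 * pi), rep(5000 * pi, 3))
  expect_equal(as.numeric(vf), c(1, 0, 0.5))
  expect_identical(attr(vf, "status"),
                   c("grown/unaffected", "detrimental/unhealthy",
                     "detrimental/unhealthy"))
  expect_error(viable_fraction(100, 0), "baseline")
  expect_error(viable_fraction(100, NA_real_), "baseline")
})

test_that("timecourse measurement fixes the baseline before the drug day", {
  lay <- generate_layout(n_rows = 2, n_cols = 4)
  gt <- ground_truth(lay, seed = 12, row_doses = c(0, 0))
  imgs <- render_experiment(lay, gt, days = c(3, 4, 8), seed = 12)
  meas <- measure_timecourse(imgs)   # drug day 5 -> baseline = day 4
  d4 <- meas[meas$day == 4, ]
  expect_equal(meas$baseline_area_um2[meas$day == 8],
               d4$area_um2[match(paste(meas$well_row[meas$day == 8],
                                       meas$well_col[meas$day == 8]),
                                 paste(d4$well_row, d4$well_col))])
  # vehicle control: mean S_F change from baseline to final day <= 5%
  expect_lt(abs(mean(meas$shape_factor[meas$day == 8]) /
                  mean(meas$shape_factor[meas$day == 4]) - 1), 0.05)
  # V_F exists only where FDA frames exist (final day)
  expect_true(all(is.na(meas$viable_fraction[meas$day < 8])))
  expect_true(all(!is.na(meas$viable_fraction[meas$day == 8])))
  expect_true(all(!is.na(meas$shape_factor)))
})

test_that("edge-column exclusion retains the documented well count", {
  lay <- generate_layout()
  tab <- tibble::tibble(well_row = rep(1:8, each = 30),
                        well_col = rep(1:30, 8))
  kept <- exclude_edge_columns(tab, lay, k = 3)
  expect_equal(sort(unique(kept$well_col)), 4:27)   # 24 columns retained
  expect_equal(nrow(kept), 8 * 24)
  expect_identical(exclude_edge_columns(tab, lay, k = 0), tab)
  expect_error(exclude_edge_columns(tab, lay, k = 15), "every column")
})
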