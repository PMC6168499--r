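test_that("MW-based diffusivity estimate covers the compound panel and is monotone", {
  panel <- c(cisplatin = 300, enzalutamide = 464, calcein = 623,
             docetaxel = 808)
  D <- vapply(panel, estimate_diffusion_coefficient, numeric(1))
  expect_true(all(D >= 0.2e-10 & D <= 0.8e-10))
  expect_true(all(diff(D) < 0))       # heavier -> slower
  expect_identical(estimate_diffusion_coefficient(500, override = 3e-10),
                   3e-10)
  expect_error(estimate_diffusion_coefficient(50), "supported range")
  expect_error(estimate_diffusion_coefficient(5000), "supported range")
})

test_that("transport solver conserves mass and relaxes to the mean on a closed domain", {
  set.seed(42)
  c0 <- matrix(runif(30 * 20), 30, 20)
  sol <- advection_diffusion_2d(c0, dx = 1e-5, dy = 1e-5, D = 1e-9,
                                duration = 3)
  last <- sol$frames[[length(sol$frames)]]
  expect_lt(abs(sum(last) - sum(c0)) / sum(c0), 0.001)
  expect_lt(max(abs(last - mean(c0))), max(abs(c0 - mean(c0))) * 0.1)
})

test_that("1D steady advection-diffusion matches the exponential closed form", {
  L <- 1e-4; nx <- 150; dx <- L / nx; D <- 1e-9
  for (Pe in c(0.1, 1, 10)) {
    u <- Pe * D / L
    uf <- matrix(u, 1, nx + 1)
    sol <- advection_diffusion_2d(
      matrix(0, 1, nx), dx = dx, dy = dx, D = D, u_face = uf,
      duration = 30 * L^2 / D,
      bc = list(x0 = list(type = "dirichlet", value = 0),
                x1 = list(type = "dirichlet", value = 1),
                y0 = list(type = "closed"), y1 = list(type = "closed")),
      steady_tol = 1e-10)
    x <- sol$x
    analytic <- (exp(Pe * x / L) - 1) / (exp(Pe) - 1)
    num <- as.vector(sol$frames[[length(sol$frames)]])
    expect_lt(max(abs(num - analytic)) / max(analytic), 0.01,
              label = sprintf("profile error at Pe = %g", Pe))
  }
})

test_that("matched side concentrations give a uniform steady field", {
  lay <- generate_layout()
  calc <- compound("calcein", 623, diffusion_coefficient = 4.0e-10,
                   source_concentration = 100)
  fld <- solve_gradient(lay, 1.4e-13, calc, duration = 2 * 3600,
                        grid_spacing = 40, c_medium = 100)
  last <- fld$frames[[length(fld$frames)]]
  expect_lt(max(abs(last - 100)) / 100, 0.005)
})

test_that("row summaries behave on uniform, linear and simulated fields", {
  fld <- quick_calcein_field()
  lay <- fld$layout

  uniform <- fld
  uniform$frames <- lapply(fld$frames, function(f) matrix(55, nrow(f), ncol(f)))
  rc <- row_concentrations(uniform, max(fld$times))
  expect_equal(rc$mean_uM, rep(55, lay$n_rows))
  expect_lt(max(rc$spread_frac), 1e-12)
  expect_equal(rc$n_wells, rep(lay$n_cols - 6L, lay$n_rows))

  linear <- fld
  W <- lay$channel_width
  linear$frames <- lapply(fld$frames, function(f) {
    matrix(rep(100 * (1 - fld$y / W), ncol(f)), nrow(f), ncol(f))
  })
  rcl <- row_concentrations(linear, max(fld$times))
  # linear in row index up to the sub-cell quadrature error of the
  # footprint averaging (step ~12 uM between rows)
  expect_lt(max(abs(diff(diff(rcl$mean_uM)))), 0.1)

  # established default gradient: strictly decreasing from the drug side
  rcg <- row_concentrations(fld, max(fld$times))
  expect_true(all(diff(rcg$mean_uM) < 0))
  expect_error(row_concentrations(fld, max(fld$times) + 1e6), "time range")
  expect_error(row_concentrations(fld, 0, exclude_edge_columns = 15),
               "no wells")
})

test_that("the simulated field respects the maximum principle and is deterministic", {
  fld <- quick_calcein_field()
  for (f in fld$frames) {
    expect_gte(min(f), -1e-9)
    expect_lte(max(f), 100 * (1 + 1e-9))
  }
  fld2 <- quick_calcein_field()
  expect_identical(fld$frames[[length(fld$frames)]],
                   fld2$frames[[length(fld2$frames)]])
})

test_that("gradient steepness increases as diffusivity drops", {
  lay <- generate_layout()
  ratio <- vapply(c(0.3e-10, 1e-10), function(D) {
    cmp <- compound("x", 500, diffusion_coefficient = D,
                    source_concentration = 100)
    fld <- solve_gradient(lay, 1.4e-13, cmp, duration = 4 * 3600,
                          grid_spacing = 40, save_every = 3600)
    rc <- row_concentrations(fld, 4 * 3600)
    rc$mean_uM[1] / rc$mean_uM[lay$n_rows]
  }, numeric(1))
  expect_gt(ratio[1], ratio[2])
})

test_that("row means are grid-converged to within 1%", {
  calc <- compound("calcein", 623, diffusion_coefficient = 4.0e-10,
                   source_concentration = 100)
  lay <- generate_layout()
  coarse <- solve_gradient(lay, 1.4e-13, calc, 2 * 3600,
                           grid_spacing = 40, grid_spacing_x = 50)
  fine <- solve_gradient(lay, 1.4e-13, calc, 2 * 3600,
                         grid_spacing = 20, grid_spacing_x = 25)
  rc_c <- row_concentrations(coarse, 2 * 3600)
  rc_f <- row_concentrations(fine, 2 * 3600)
  expect_lt(max(abs(rc_c$mean_uM - rc_f$mean_uM) / rc_f$mean_uM), 0.01)
})

test_that("stability metrics detect drift and respect the establishment window", {
  rows <- 1:8
  mk <- function(times, means_fun) {
    do.call(rbind, lapply(times, function(t) {
      tibble::tibble(time_s = t, row = rows, mean_uM = means_fun(t),
                     spread_frac = 0, n_wells = 24)
    }))
  }
  times <- seq(0, 20 * 3600, by = 1800)
  base <- 100 - 10 * (rows - 1)
  const <- mk(times, function(t) base)
  sm <- stability_metrics(const)
  expect_equal(sm$t_stable, max(times) - 3600)
  expect_true(is.na(sm$drift_24h))   # series shorter than 24 h post-window

  # row 5 jumps 15% at hour 6 -> stability ends 5 h after the 1 h window
  jump <- mk(times, function(t) {
    v <- base; if (t >= 6 * 3600) v[5] <- v[5] * 1.15; v
  })
  expect_equal(stability_metrics(jump)$t_stable, 5 * 3600)

  long <- mk(seq(0, 26 * 3600, by = 1800), function(t) base * (1 + t * 1e-7))
  expect_equal(stability_metrics(long)$drift_24h,
               (1 + 25 * 3600 * 1e-7) / (1 + 3600 * 1e-7) - 1,
               tolerance = 1e-6)
  expect_error(stability_metrics(mk(c(0, 600), function(t) base)),
               "establishment")
})
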