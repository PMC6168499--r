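test_that("channel resistance is linear in length and dominated by depth", {
  seg <- channel_segment(100, 7, 1000)
  seg2 <- channel_segment(100, 7, 2000)
  expect_equal(channel_resistance(seg2), 2 * channel_resistance(seg))

  deep <- channel_segment(500, 35, 5000)
  shallow <- channel_segment(500, 7, 5000)
  expect_gt(channel_resistance(shallow), channel_resistance(deep))

  # height/width orientation convention: swapped on construction
  expect_equal(channel_resistance(channel_segment(7, 100, 1000)),
               channel_resistance(channel_segment(100, 7, 1000)))
  expect_error(channel_segment(100, -7, 1000), "invalid channel geometry")
})

test_that("square-duct resistance agrees with the series-solution oracle", {
  for (s in c(10, 35, 150)) {
    R <- channel_resistance(channel_segment(s, s, 1000))
    R_oracle <- duct_resistance_series_oracle(s, s, 1000, terms = 20)
    expect_lt(abs(R - R_oracle) / R_oracle, 0.01)
  }
  # and at a shallow aspect ratio typical of the device
  R <- channel_resistance(channel_segment(500, 35, 10000))
  R_oracle <- duct_resistance_series_oracle(500, 35, 10000, terms = 25)
  expect_lt(abs(R - R_oracle) / R_oracle, 0.01)
})

test_that("reservoir capacitance is the cross-section over rho g", {
  r8 <- reservoir(8, 1, role = "side_source")
  r4 <- reservoir(4, 1, role = "central")
  expect_equal(reservoir_capacitance(r8) / reservoir_capacitance(r4), 4)
  # C * rho * g returns the area
  expect_equal(reservoir_capacitance(r4) * 1000 * 9.81, pi * 0.002^2)
  # direct arithmetic: pi (0.002)^2 / (1000 * 9.81)
  expect_equal(reservoir_capacitance(r4), 1.281e-9, tolerance = 1e-3)
})

test_that("overflow closed form pins the central pressure", {
  rho_g <- 1000 * 9.81
  hS <- 1.2e-3; hC <- 0.4e-3; R_T <- 1e13; C_S <- 5e-9
  p0 <- pressure_overflow(0, hS, hC, R_T, C_S)
  expect_equal(p0$P_CS, rho_g * hS)
  expect_equal(p0$P_CS - p0$P_CC, rho_g * (hS - hC))
  pinf <- pressure_overflow(1e12, hS, hC, R_T, C_S)
  expect_equal(pinf$P_CS, rho_g * hC, tolerance = 1e-12)
  t <- seq(0, 16 * 3600, by = 600)
  pt <- pressure_overflow(t, hS, hC, R_T, C_S)
  expect_true(all(pt$P_CC == rho_g * hC))       # constant in time
  expect_true(all(diff(pt$P_CS - pt$P_CC) <= 0))  # dP non-increasing
  expect_true(all(pt$P_CS - pt$P_CC >= 0))
  expect_error(pressure_overflow(-1, hS, hC, R_T, C_S), "time")
})

test_that("no-overflow closed form equilibrates at the volume-weighted mean height", {
  rho_g <- 1000 * 9.81
  hS <- 1.2e-3; hC <- 0.4e-3; R_T <- 1e13; C_S <- 5e-9
  A_S <- pi * 0.004^2; A_C <- pi * 0.002^2
  # symmetric initial condition: dP identically zero
  sym <- pressure_no_overflow(c(0, 100, 1e5), hC, hC, R_T, C_S, A_S, A_C)
  expect_equal(sym$P_CS, rep(rho_g * hC, 3))
  expect_equal(sym$P_CC, rep(rho_g * hC, 3))
  # algebraic limit of both branches (derived independently from the volume
  # balance: 4 side + 2 central reservoirs share the total volume)
  h_eq <- (2 * A_S * hS + A_C * hC) / (2 * A_S + A_C)
  pinf <- pressure_no_overflow(1e12, hS, hC, R_T, C_S, A_S, A_C)
  expect_equal(pinf$P_CS, rho_g * h_eq, tolerance = 1e-12)
  expect_equal(pinf$P_CC, rho_g * h_eq, tolerance = 1e-12)
  # dP decays faster without the overflow ports
  t <- seq(0, 16 * 3600, by = 600)
  ovf <- pressure_overflow(t, hS, hC, R_T, C_S)
  no <- pressure_no_overflow(t, hS, hC, R_T, C_S, A_S, A_C)
  expect_true(all(no$P_CS - no$P_CC <= ovf$P_CS - ovf$P_CC + 1e-12))
  # monotone approach from both sides
  expect_true(all(diff(no$P_CC) >= 0))
  expect_true(all(diff(no$P_CS) <= 0))
})

test_that("network integration matches the closed forms on the reducible topology", {
  net <- fast_network(overflow = TRUE)
  C_S <- reservoir_capacitance(net$reservoirs$W1)
  hS <- net$reservoirs$W1$initial_height * 1e-3
  hC <- net$reservoirs$W3$initial_height * 1e-3
  sim <- simulate_network(net, 16 * 3600, step = 10, save_every = 600)
  ref <- pressure_overflow(sim$pressure$times, hS, hC, net$R_T, C_S)
  expect_lt(max(abs(sim$pressure$P_CS - ref$P_CS) / ref$P_CS), 0.01)
  expect_true(all(diff(sim$pressure$dP) <= 1e-9))
  expect_true(all(sim$pressure$dP >= -1e-9))
  # flow law dP = R_T * Q at every sample
  expect_equal(sim$pressure$Q_central, sim$pressure$dP / net$R_T)

  net0 <- fast_network(overflow = FALSE)
  sim0 <- simulate_network(net0, 16 * 3600, step = 10, save_every = 600)
  A_S <- pi * 0.004^2; A_C <- pi * 0.002^2
  ref0 <- pressure_no_overflow(sim0$pressure$times, hS, hC, net0$R_T, C_S,
                               A_S, A_C)
  expect_lt(max(abs(sim0$pressure$P_CS - ref0$P_CS) / ref0$P_CS), 0.01)
  expect_lt(max(abs(sim0$pressure$P_CC - ref0$P_CC) / ref0$P_CC), 0.01)

  # without overflow ports, total volume is conserved to within tolerance
  tot <- rowSums(sim0$state$volumes_uL)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 0.001)

  # overflow ports prolong the pressure difference: dP halving takes longer
  half_time <- function(p) p$times[which(p$dP <= p$dP[1] / 2)[1]]
  expect_gt(half_time(sim$pressure), half_time(sim0$pressure))
})

test_that("volume QC discards only when a reservoir deviates beyond tolerance", {
  expected <- c(W1 = 60, W2 = 60, W3 = 5, W4 = 5)
  ok <- qc_volume_check(expected, expected)
  expect_identical(ok$verdict, "accept")
  expect_true(all(ok$deviations == 0))

  dev12 <- expected; dev12["W2"] <- 60 * 1.12
  expect_identical(qc_volume_check(dev12, expected)$verdict, "discard")

  dev10 <- expected; dev10["W2"] <- 60 * 1.10   # exactly at tolerance
  expect_identical(qc_volume_check(dev10, expected)$verdict, "accept")

  # permutation invariance over reservoir order
  perm <- sample(names(expected))
  expect_identical(qc_volume_check(dev12[perm], expected)$verdict, "discard")
  expect_identical(qc_volume_check(dev10[perm], expected)$verdict, "accept")

  # indeterminate: expected zero, nonzero measurement
  exp0 <- c(A = 0, B = 10); meas0 <- c(A = 1, B = 10)
  res <- qc_volume_check(meas0, exp0)
  expect_identical(res$verdict, "discard")
  expect_true(is.na(res$deviations["A"]))
})
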