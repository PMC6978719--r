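# Flow solver: inlet arithmetic, Poiseuille analytic limit (axisymmetric
# and planar), null flow, conservation, physical ordering, regime refusal.

test_that("inlet condition implements the duplex flow-rate formula", {
  ic <- inlet_condition(0.9, 0.3, 2e-3, 130, 80)
  expect_equal(ic$mean_velocity, 0.5)
  expect_equal(ic$flow_rate, 0.5 * pi * 4e-6)

  ic2 <- inlet_condition(0.4, 0.4, 2e-3, 120, 70)
  expect_equal(ic2$mean_velocity, 0.4)       # psv = edv limit
  expect_equal(ic2$flow_rate, 0.4 * pi * (2e-3)^2, tolerance = 1e-12)
  expect_equal(ic2$flow_rate, 5.027e-6, tolerance = 1e-3)

  # MAP = dbp + pulse pressure / 3, in Pa
  expect_equal(ic$mean_arterial_pressure, (80 + 50 / 3) * 133.322,
               tolerance = 1e-12)

  expect_error(inlet_condition(0.2, 0.3, 2e-3, 130, 80),
               class = "icasflow_input_error")
  expect_error(inlet_condition(0.9, 0.3, 2e-3, 80, 80),
               class = "icasflow_input_error")
  expect_error(inlet_condition(0.9, 0.3, -1, 130, 80),
               class = "icasflow_input_error")
})

test_that("poiseuille reference matches the closed form and scaling laws", {
  ref <- poiseuille_reference(5.027e-6, 0.002, 0.01, 3.5e-3)
  expect_equal(ref$pressure_drop, 28.0, tolerance = 1e-3)
  expect_equal(ref$wall_wss, 2.80, tolerance = 1e-3)

  ref2 <- poiseuille_reference(5.027e-6, 0.004, 0.01, 3.5e-3)
  expect_equal(ref2$pressure_drop / ref$pressure_drop, 1 / 16)
  expect_equal(ref2$wall_wss / ref$wall_wss, 1 / 8)

  expect_equal(poiseuille_reference(0, 0.002, 0.01, 3.5e-3),
               list(pressure_drop = 0, wall_wss = 0))
  expect_error(poiseuille_reference(1e-6, -1, 0.01, 3.5e-3),
               class = "icasflow_input_error")
})

test_that("straight-tube solve reproduces Poiseuille flow", {
  u <- 5.027e-6 / (pi * 4e-6)
  ic <- inlet_condition(u, u, 2e-3, 130, 80)
  geom <- make_stenosis_profile(stenosis_spec(2e-3, 0, 5e-3, 10e-3), 20e-3,
                                128L)
  f <- solve_steady_flow(geom, ic, numerics = coarse_numerics())
  ref <- poiseuille_reference(ic$flow_rate, 2e-3, 20e-3, 3.5e-3)

  n <- length(f$wall_pressure)
  dp <- f$wall_pressure[1] - f$wall_pressure[n]
  expect_lt(abs(dp - ref$pressure_drop) / ref$pressure_drop, 0.02)

  # WSS flat and at the analytic value away from the end buffers
  mid <- seq(round(n * 0.2), round(n * 0.8))
  expect_lt(max(abs(f$wall_wss[mid] - ref$wall_wss)) / ref$wall_wss, 0.02)

  # wall pressure anchored at MAP at the inlet
  expect_equal(f$wall_pressure[1], ic$mean_arterial_pressure)
  # arc length strictly increasing, spanning the tube
  expect_true(all(diff(f$wall_s) > 0))
  expect_equal(max(f$wall_s), 20e-3, tolerance = 1e-6)
  expect_lt(f$mass_error, 0.005)
})

test_that("planar straight channel reproduces plane Poiseuille flow", {
  spec <- stenosis_spec(1.5e-3, 0, 5e-3, 10e-3, side = "upper")
  geom <- make_stenosis_profile(spec, 20e-3, 128L)
  geom$mode <- "planar"  # zero lesion keeps both walls at R0
  geom$wall_upper <- rep(1.5e-3, length(geom$z))
  geom$wall_lower <- rep(1.5e-3, length(geom$z))
  ic <- inlet_condition(0.45, 0.225, 1.5e-3, 130, 80)
  f <- solve_steady_flow(geom, ic, numerics = coarse_numerics())
  R0 <- 1.5e-3
  ubar <- ic$mean_velocity
  # plane Poiseuille: dp/dz = 3 mu ubar / R0^2, tau_w = 3 mu ubar / R0
  n <- length(f$wall_pressure)
  dp <- f$wall_pressure[1] - f$wall_pressure[n]
  expect_lt(abs(dp - 3 * 3.5e-3 * ubar * 20e-3 / R0^2) /
              (3 * 3.5e-3 * ubar * 20e-3 / R0^2), 0.02)
  mid <- seq(round(n * 0.2), round(n * 0.8))
  expect_lt(max(abs(f$wall_wss[mid] - 3 * 3.5e-3 * ubar / R0)) /
              (3 * 3.5e-3 * ubar / R0), 0.02)
  expect_lt(f$mass_error, 0.005)
})

test_that("zero inflow yields the quiescent anchored field", {
  geom <- make_stenosis_profile(stenosis_spec(1.5e-3, 50, 8e-3, 19e-3), 38e-3)
  ic <- inlet_condition(0, 0, 1.5e-3, 130, 80)
  f <- solve_steady_flow(geom, ic, numerics = coarse_numerics())
  expect_true(f$converged)
  expect_true(all(f$u == 0) && all(f$v == 0))
  expect_true(all(f$wall_wss == 0))
  expect_true(all(f$wall_pressure == ic$mean_arterial_pressure))
})

test_that("stenosed solve obeys conservation and physical ordering", {
  f <- fixture_field_50()
  expect_true(f$converged)
  expect_lte(f$final_residual, f$numerics$convergence_tolerance)
  # half-resolution test grid: the station-flux measurement itself carries
  # ~4x the quadrature error of the default grid, where <= 0.5% holds
  expect_lt(f$mass_error, 0.01)

  ref <- poiseuille_reference(f$inlet$flow_rate, 1.5e-3, 38e-3, 3.5e-3)
  n <- length(f$wall_pressure)
  dp <- f$wall_pressure[1] - f$wall_pressure[n]
  # dissipation exceeds the straight-tube drop; WSS_max exceeds Poiseuille
  expect_gt(dp, ref$pressure_drop)
  expect_gt(max(f$wall_wss), ref$wall_wss)
  # net pressure loss from origin to terminal reference stations
  expect_lt(f$wall_pressure[n], f$wall_pressure[1])
  expect_true(all(f$wall_wss >= 0))
})

test_that("throat Reynolds cap refuses out-of-regime cases", {
  geom <- make_stenosis_profile(stenosis_spec(1.5e-3, 80, 8e-3, 19e-3), 38e-3)
  ic <- inlet_condition(1.5, 0.9, 1.5e-3, 130, 80)
  expect_gt(throat_reynolds(geom, ic), 2000)
  err <- tryCatch(solve_steady_flow(geom, ic, numerics = coarse_numerics()),
                  icasflow_regime_error = function(e) e)
  expect_s3_class(err, "icasflow_regime_error")
  expect_gt(err$reynolds, 2000)
})

test_that("wall profile extraction refuses unconverged fields", {
  f <- fixture_field_50()
  g <- f
  g$converged <- FALSE
  expect_error(wall_profile(g), class = "icasflow_convergence_error")
  prof <- wall_profile(f)
  expect_true(all(diff(prof$s) > 0))
  expect_true(all(prof$wss >= 0))
  expect_true(all(is.finite(prof$pressure)))
})

test_that("resistance outlet anchors the outlet pressure", {
  geom <- make_stenosis_profile(stenosis_spec(1.5e-3, 30, 8e-3, 19e-3), 38e-3)
  ic <- inlet_condition(0.45, 0.225, 1.5e-3, 130, 80)
  Rd <- 1e9
  out <- outlet_model("resistance", distal_pressure = 9000,
                      distal_resistance = Rd)
  f <- solve_steady_flow(geom, ic, outlet = out,
                         numerics = coarse_numerics())
  n <- length(f$wall_pressure)
  expect_equal(f$wall_pressure[n], 9000 + Rd * ic$flow_rate,
               tolerance = 1e-9)
})

test_that("flow field exports are well-formed", {
  f <- fixture_field_50()
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_flowfield_vtk(f, vtk)
  head <- readLines(vtk, n = 6)
  expect_identical(head[4], "DATASET STRUCTURED_GRID")
  expect_match(head[5], "^DIMENSIONS 129 25 1$")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_wall_profile_csv(wall_profile(f), csv)
  df <- utils::read.csv(csv)
  expect_identical(names(df), c("s_m", "wss_pa", "pressure_pa"))
  expect_equal(nrow(df), 129)
})
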