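# Steady incompressible Newtonian flow through a stenosed lumen:
# configuration objects, the solver wrapper around the compiled
# streamfunction-vorticity core, wall shear stress / wall pressure
# extraction, and field exports.

#' Blood fluid properties
#'
#' Constant-property Newtonian blood. Density defaults to 1060 kg/m^3
#' (1.06 g/cm^3, standard whole blood) and dynamic viscosity to
#' 3.5e-3 Pa s.
#'
#' @param density fluid density (kg/m^3).
#' @param dynamic_viscosity dynamic viscosity (Pa s).
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 3.5e-3) {
  check_scalar(density, "density", positive = TRUE)
  check_scalar(dynamic_viscosity, "dynamic_viscosity", positive = TRUE)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Inlet boundary condition from duplex ultrasonography and blood pressure
#'
#' Time-averaged inflow for the steady problem. The mean velocity is
#' `psv/3 + 2*edv/3` (the standard duplex estimate of the time-averaged
#' velocity, analogous to the mean-arterial-pressure formula), the flow rate
#' is `mean velocity x cross-sectional area`, and the mean arterial pressure
#' `MAP = diastolic + (systolic - diastolic)/3` (converted to Pa) anchors the
#' absolute pressure level.
#'
#' @param psv peak-systolic velocity (m/s).
#' @param edv end-diastolic velocity (m/s); must satisfy `psv >= edv > 0`
#'   (or both zero for the null-flow case).
#' @param inlet_radius inlet lumen radius (m).
#' @param systolic_bp,diastolic_bp brachial blood pressure (mmHg).
#' @return object of class `inlet_condition` with fields `psv`, `edv`,
#'   `mean_velocity` (m/s), `flow_rate` (m^3/s), `inlet_radius` (m) and
#'   `mean_arterial_pressure` (Pa).
#' @examples
#' ic <- inlet_condition(0.9, 0.3, 1.5e-3, 130, 80)
#' ic$mean_velocity  # 0.5 m/s
#' @export
inlet_condition <- function(psv, edv, inlet_radius, systolic_bp,
                            diastolic_bp) {
  check_scalar(psv, "psv", nonneg = TRUE)
  check_scalar(edv, "edv", nonneg = TRUE)
  if (psv < edv) icas_stop("icasflow_input_error", "psv must be >= edv")
  if (psv > 0 && edv <= 0) {
    icas_stop("icasflow_input_error", "edv must be > 0 for nonzero inflow")
  }
  check_scalar(inlet_radius, "inlet_radius", positive = TRUE)
  check_scalar(systolic_bp, "systolic_bp", positive = TRUE)
  check_scalar(diastolic_bp, "diastolic_bp", positive = TRUE)
  if (systolic_bp <= diastolic_bp) {
    icas_stop("icasflow_input_error", "systolic_bp must exceed diastolic_bp")
  }
  mean_velocity <- psv / 3 + 2 * edv / 3
  flow_rate <- mean_velocity * pi * inlet_radius^2
  map_pa <- mmhg_to_pa(diastolic_bp + (systolic_bp - diastolic_bp) / 3)
  structure(list(psv = psv, edv = edv, inlet_radius = inlet_radius,
                 systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
                 mean_velocity = mean_velocity, flow_rate = flow_rate,
                 mean_arterial_pressure = map_pa),
            class = "inlet_condition")
}

#' Outlet boundary model
#'
#' Reduced-order stand-in for the distal vasculature. The default
#' `reference_pressure` kind leaves the pressure field anchored at the inlet
#' mean arterial pressure, so the terminal/origin pressure ratio is an
#' FFR-like absolute ratio. The `resistance` kind instead pins the outlet
#' pressure to `distal_pressure + distal_resistance * Q` (a linear lumped
#' resistance) and anchors the field there.
#'
#' @param kind `"reference_pressure"` (default) or `"resistance"`.
#' @param distal_pressure distal reference pressure (Pa, `resistance` kind).
#' @param distal_resistance linear resistance (Pa s/m^3, `resistance` kind).
#' @return object of class `outlet_model`.
#' @export
outlet_model <- function(kind = c("reference_pressure", "resistance"),
                         distal_pressure = 0, distal_resistance = 0) {
  kind <- match.arg(kind)
  check_scalar(distal_pressure, "distal_pressure", nonneg = TRUE)
  check_scalar(distal_resistance, "distal_resistance", nonneg = TRUE)
  structure(list(kind = kind, distal_pressure = distal_pressure,
                 distal_resistance = distal_resistance),
            class = "outlet_model")
}

#' Numerical configuration of the steady solver
#'
#' @param axial_cells,radial_cells structured-grid cells (>= 16 each;
#'   defaults 256 x 48).
#' @param convergence_tolerance normalised steady-state residual below which
#'   the solve is declared converged (default 1e-6).
#' @param max_iterations relaxation-sweep cap (default 40000).
#' @param under_relaxation named factors in (0, 1]: `vorticity` for the
#'   interior Gauss-Seidel update, `wall` for the wall-vorticity condition.
#' @param psi_sor SOR acceleration factor for the streamfunction Poisson
#'   sweeps (in (0, 2)).
#' @param psi_sweeps streamfunction sweeps per outer iteration.
#' @param reynolds_cap laminar cap on the throat-jet Reynolds number; cases
#'   above it are refused as out of regime (default 2000).
#' @param check_every residual-evaluation interval (iterations).
#' @return object of class `numerics_config`.
#' @export
numerics_config <- function(axial_cells = 256L, radial_cells = 48L,
                            convergence_tolerance = 1e-6,
                            max_iterations = 40000L,
                            under_relaxation = c(vorticity = 1.0, wall = 0.6),
                            psi_sor = 1.8, psi_sweeps = 8L,
                            reynolds_cap = 2000, check_every = 50L) {
  check_scalar(axial_cells, "axial_cells", positive = TRUE)
  check_scalar(radial_cells, "radial_cells", positive = TRUE)
  if (axial_cells < 16 || radial_cells < 16) {
    icas_stop("icasflow_config_error", "grid must have >= 16 cells per axis")
  }
  check_scalar(convergence_tolerance, "convergence_tolerance", positive = TRUE)
  check_scalar(max_iterations, "max_iterations", positive = TRUE)
  ur <- under_relaxation
  if (!is.numeric(ur) || is.null(names(ur)) ||
      !all(c("vorticity", "wall") %in% names(ur)) ||
      any(ur <= 0) || any(ur > 1)) {
    icas_stop("icasflow_config_error",
              "under_relaxation must name `vorticity` and `wall`, in (0, 1]")
  }
  check_scalar(psi_sor, "psi_sor", positive = TRUE)
  if (psi_sor >= 2) {
    icas_stop("icasflow_config_error", "psi_sor must be below 2")
  }
  check_scalar(reynolds_cap, "reynolds_cap", positive = TRUE)
  structure(list(axial_cells = as.integer(axial_cells),
                 radial_cells = as.integer(radial_cells),
                 convergence_tolerance = convergence_tolerance,
                 max_iterations = as.integer(max_iterations),
                 under_relaxation = ur[c("vorticity", "wall")],
                 psi_sor = psi_sor, psi_sweeps = as.integer(psi_sweeps),
                 reynolds_cap = reynolds_cap,
                 check_every = as.integer(check_every)),
            class = "numerics_config")
}

#' Closed-form Poiseuille reference for a straight tube
#'
#' Analytic validation oracle: `dP = 8 mu L Q / (pi R^4)` and wall shear
#' stress `tau_w = 4 mu Q / (pi R^3)` for fully developed laminar flow.
#'
#' @param Q volumetric flow rate (m^3/s).
#' @param R tube radius (m).
#' @param L tube length (m).
#' @param mu dynamic viscosity (Pa s).
#' @return list with `pressure_drop` (Pa) and `wall_wss` (Pa).
#' @export
poiseuille_reference <- function(Q, R, L, mu) {
  check_scalar(Q, "Q", nonneg = TRUE)
  check_scalar(R, "R", positive = TRUE)
  check_scalar(L, "L", positive = TRUE)
  check_scalar(mu, "mu", positive = TRUE)
  list(pressure_drop = 8 * mu * L * Q / (pi * R^4),
       wall_wss = 4 * mu * Q / (pi * R^3))
}

# central first/second derivatives of a 1-d profile on a uniform grid
profile_derivs <- function(y, dx) {
  n <- length(y)
  d1 <- c(y[2] - y[1],
          (y[3:n] - y[1:(n - 2)]) / 2,
          y[n] - y[n - 1]) / dx
  d2 <- c(0, y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)], 0) / dx^2
  list(d1 = d1, d2 = d2)
}

#' Throat-jet Reynolds number of a case
#'
#' `Re_jet = rho * U_jet * D_throat / mu`, with the jet velocity taken as the
#' mean velocity through the narrowest cross-section. Used to refuse cases
#' outside the steady laminar regime.
#'
#' @param geometry a `vessel_geometry`.
#' @param inlet an [inlet_condition()].
#' @param fluid a [fluid_properties()].
#' @return the Reynolds number (dimensionless).
#' @export
throat_reynolds <- function(geometry, inlet, fluid = fluid_properties()) {
  if (geometry$mode == "axisymmetric") {
    r_throat <- min(geometry$wall)
    u_jet <- inlet$flow_rate / (pi * r_throat^2)
    fluid$density * u_jet * 2 * r_throat / fluid$dynamic_viscosity
  } else {
    h_min <- min(geometry$wall_upper + geometry$wall_lower)
    q <- inlet$mean_velocity * 2 * geometry$reference_radius
    u_jet <- q / h_min
    fluid$density * u_jet * h_min / fluid$dynamic_viscosity
  }
}

#' Solve steady flow through a stenosed lumen
#'
#' Solves the steady incompressible Navier-Stokes equations in the reduced
#' geometry (axisymmetric `(r, z)` by default; planar two-wall channel for
#' eccentric lesions) with a fully developed parabolic inflow carrying the
#' inlet flow rate, no-slip rigid walls and a zero-gradient outflow. The
#' compiled core relaxes the streamfunction-vorticity form of the equations;
#' mass conservation is exact by construction of the streamfunction. The
#' pressure level is anchored so the inlet-plane pressure equals the mean
#' arterial pressure (reference-pressure outlet) or so the outlet pressure
#' equals `distal_pressure + distal_resistance * Q` (resistance outlet).
#'
#' @param geometry a [make_stenosis_profile()] result.
#' @param inlet an [inlet_condition()].
#' @param outlet an [outlet_model()].
#' @param fluid a [fluid_properties()].
#' @param numerics a [numerics_config()].
#' @return object of class `flow_field`: grid (`z`, `eta`, `r`), velocity
#'   components (`u` axial, `v` cross-stream; m/s), streamfunction `psi`,
#'   vorticity `omega`, wall arrays (`wall_s` arc length, `wall_wss`,
#'   `wall_pressure`), convergence diagnostics and the input objects.
#' @export
solve_steady_flow <- function(geometry, inlet,
                              outlet = outlet_model(),
                              fluid = fluid_properties(),
                              numerics = numerics_config()) {
  if (!inherits(geometry, "vessel_geometry")) {
    icas_stop("icasflow_input_error", "`geometry` must be a vessel_geometry")
  }
  if (!inherits(inlet, "inlet_condition")) {
    icas_stop("icasflow_input_error", "`inlet` must be an inlet_condition")
  }
  stopifnot(inherits(outlet, "outlet_model"),
            inherits(fluid, "fluid_properties"),
            inherits(numerics, "numerics_config"))

  # resample the boundary onto the solver's axial resolution
  nz <- numerics$axial_cells
  nr <- numerics$radial_cells
  z <- seq(0, geometry$total_length, length.out = nz + 1L)
  dxi <- z[2] - z[1]
  axisym <- geometry$mode == "axisymmetric"

  mu <- fluid$dynamic_viscosity
  nu <- mu / fluid$density
  Q <- inlet$flow_rate
  MAP <- inlet$mean_arterial_pressure

  if (Q == 0) {
    return(null_flow_field(geometry, z, nr, inlet, outlet, fluid, numerics))
  }

  re_jet <- throat_reynolds(geometry, inlet, fluid)
  if (re_jet > numerics$reynolds_cap) {
    icas_stop("icasflow_regime_error",
              sprintf("throat-jet Reynolds number %.0f exceeds laminar cap %.0f",
                      re_jet, numerics$reynolds_cap),
              reynolds = re_jet)
  }

  ur <- numerics$under_relaxation

  # flow-rate continuation for convectively stiff cases: ramp the flow rate
  # through intermediate solves that warm-start the next stage (scaled with
  # the flow-rate ratio); intermediate stages run at half grid resolution
  # and a relaxed tolerance, and are bilinearly interpolated up
  fracs <- if (re_jet <= 700) 1 else if (re_jet <= 1200) c(0.5, 1) else
    c(0.25, 0.5, 0.75, 1)

  # grid-resolution-parameterised solver closure
  make_runner <- function(nzc, nrc) {
    zc <- seq(0, geometry$total_length, length.out = nzc + 1L)
    dxic <- zc[2] - zc[1]
    etac <- seq(0, 1, length.out = nrc + 1L)
    if (axisym) {
      a <- stats::approx(geometry$z, geometry$wall, zc)$y
      d <- profile_derivs(a, dxic)
      attr(a, "dxi") <- dxic
      function(Qs, tol, init, relax_scale) {
        psi_in <- (Qs / (2 * pi)) * (2 * etac^2 - etac^4)
        w_in <- rep(4 * Qs / (pi * a[1]^4), nrc + 1L)
        .solve_axisym_core(a, d$d1, d$d2, psi_in, w_in, Qs, nu, nrc,
                           tol, numerics$max_iterations,
                           ur[["vorticity"]] * relax_scale,
                           ur[["wall"]] * relax_scale,
                           numerics$psi_sor, numerics$psi_sweeps,
                           numerics$check_every, init$psi, init$w)
      }
    } else {
      yu <- stats::approx(geometry$z, geometry$wall_upper, zc)$y
      yl <- stats::approx(geometry$z, geometry$wall_lower, zc)$y
      du <- profile_derivs(yu, dxic)
      dl <- profile_derivs(yl, dxic)
      attr(yl, "dxi") <- dxic
      R0 <- (yu[1] + yl[1]) / 2
      y_in <- -yl[1] + etac * (yu[1] + yl[1])
      function(Qs, tol, init, relax_scale) {
        umax <- 1.5 * Qs / (2 * R0)
        psi_in <- umax * ((y_in + R0) - (y_in^3 + R0^3) / (3 * R0^2))
        w_in <- 2 * umax * y_in / R0^2
        .solve_planar_core(yl, dl$d1, dl$d2, yu, du$d1, du$d2,
                           psi_in, w_in, Qs, nu, nrc,
                           tol, numerics$max_iterations,
                           ur[["vorticity"]] * relax_scale,
                           ur[["wall"]] * relax_scale,
                           numerics$psi_sor, numerics$psi_sweeps,
                           numerics$check_every, init$psi, init$w)
      }
    }
  }
  Q_target <- if (axisym) Q else
    inlet$mean_velocity * 2 * geometry$reference_radius

  # bilinear interpolation between uniform (xi, eta) grids
  regrid <- function(M, nz_to, nr_to) {
    nz_from <- nrow(M) - 1L; nr_from <- ncol(M) - 1L
    if (nz_from == nz_to && nr_from == nr_to) return(M)
    x_from <- seq(0, 1, length.out = nz_from + 1L)
    x_to <- seq(0, 1, length.out = nz_to + 1L)
    M1 <- apply(M, 2, function(col) stats::approx(x_from, col, x_to)$y)
    y_from <- seq(0, 1, length.out = nr_from + 1L)
    y_to <- seq(0, 1, length.out = nr_to + 1L)
    t(apply(M1, 1, function(row) stats::approx(y_from, row, y_to)$y))
  }

  stage_runner <- make_runner(max(64L, nz %/% 2L), max(16L, nr %/% 2L))
  final_runner <- make_runner(nz, nr)

  solve_stage <- function(runner, Qs, tol, init) {
    core <- runner(Qs, tol, init, 1)
    if (!core$converged) {
      # retry the stage with halved, then quartered, relaxation factors
      for (relax_scale in c(0.5, 0.25)) {
        core <- runner(Qs, tol, init, relax_scale)
        if (core$converged) break
      }
    }
    core
  }

  init <- list(psi = NULL, w = NULL)
  core <- NULL
  nk <- length(fracs)
  for (k in seq_len(nk)) {
    Qs <- Q_target * fracs[k]
    last <- k == nk
    tol_k <- if (last) numerics$convergence_tolerance else
      max(numerics$convergence_tolerance, 1e-4)
    core <- solve_stage(if (last) final_runner else stage_runner,
                        Qs, tol_k, init)
    if (!core$converged) break
    scale_next <- if (k < nk) fracs[k + 1] / fracs[k] else 1
    if (k == nk - 1) {
      init <- list(psi = regrid(core$psi * scale_next, nz, nr),
                   w = regrid(core$w * scale_next, nz, nr))
    } else {
      init <- list(psi = core$psi * scale_next, w = core$w * scale_next)
    }
  }

  if (axisym) {
    a <- stats::approx(geometry$z, geometry$wall, z)$y
    r_mat <- outer(a, seq(0, 1, length.out = nr + 1L))
    omega <- core$w * r_mat           # core unknown is omega / r
  } else {
    yu <- stats::approx(geometry$z, geometry$wall_upper, z)$y
    yl <- stats::approx(geometry$z, geometry$wall_lower, z)$y
    eta_f <- seq(0, 1, length.out = nr + 1L)
    r_mat <- outer(-yl, 1 - eta_f) + outer(yu, eta_f)  # y(i, j)
    omega <- core$w
  }
  eta <- seq(0, 1, length.out = nr + 1L)

  if (!core$converged) {
    icas_stop("icasflow_convergence_error",
              sprintf("solver did not converge in %d iterations (residual %.3g)",
                      numerics$max_iterations, core$residual),
              residual = core$residual, iterations = core$iterations)
  }

  field <- list(z = z, eta = eta, r = r_mat, u = core$u, v = core$v,
                psi = core$psi, omega = omega,
                mode = geometry$mode,
                converged = core$converged, final_residual = core$residual,
                iterations = core$iterations,
                geometry = geometry, inlet = inlet, outlet = outlet,
                fluid = fluid, numerics = numerics)
  class(field) <- "flow_field"

  wp <- wall_quantities(field)
  field$wall_s <- wp$s
  field$wall_wss <- wp$wss
  # anchor the pressure level per the outlet model
  p <- wp$p_rel + MAP
  if (outlet$kind == "resistance") {
    p_out_target <- outlet$distal_pressure + outlet$distal_resistance * Q
    p <- wp$p_rel - wp$p_rel[length(wp$p_rel)] + p_out_target
  }
  field$wall_pressure <- p
  field$mass_error <- mass_conservation_error(field)
  field
}

# quiescent field for Q = 0: uniform MAP, zero velocity and WSS
null_flow_field <- function(geometry, z, nr, inlet, outlet, fluid, numerics) {
  nz1 <- length(z)
  eta <- seq(0, 1, length.out = nr + 1L)
  zero <- matrix(0, nz1, nr + 1L)
  r_mat <- if (geometry$mode == "axisymmetric") {
    outer(stats::approx(geometry$z, geometry$wall, z)$y, eta)
  } else {
    outer(-stats::approx(geometry$z, geometry$wall_lower, z)$y, 1 - eta) +
      outer(stats::approx(geometry$z, geometry$wall_upper, z)$y, eta)
  }
  wall <- wall_curve(geometry, z)
  s <- cumtrapz(sqrt(1 + wall$slope^2), z)
  field <- list(z = z, eta = eta, r = r_mat, u = zero, v = zero,
                psi = zero, omega = zero, mode = geometry$mode,
                converged = TRUE, final_residual = 0, iterations = 0L,
                geometry = geometry, inlet = inlet, outlet = outlet,
                fluid = fluid, numerics = numerics,
                wall_s = s, wall_wss = rep(0, nz1),
                wall_pressure = rep(inlet$mean_arterial_pressure, nz1),
                mass_error = 0)
  class(field) <- "flow_field"
  field
}

cumtrapz <- function(y, x) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# prominent-side wall curve resampled on the solver grid
wall_curve <- function(geometry, z) {
  if (geometry$mode == "axisymmetric") {
    w <- stats::approx(geometry$z, geometry$wall, z)$y
  } else {
    w <- stats::approx(geometry$z, prominent_wall(geometry), z)$y
  }
  list(offset = w, slope = profile_derivs(w, z[2] - z[1])$d1)
}

# WSS magnitude and relative wall pressure along the prominent side,
# from the converged vorticity field: tau_w = mu * |omega_wall|, and
# dp/dz along the wall from the tangential wall momentum balance
# (grad p = -mu curl omega at a stationary no-slip wall).
wall_quantities <- function(field) {
  mu <- field$fluid$dynamic_viscosity
  z <- field$z
  dxi <- z[2] - z[1]
  deta <- field$eta[2] - field$eta[1]
  nj <- length(field$eta)
  axisym <- field$mode == "axisymmetric"

  if (axisym) {
    a <- field$r[, nj]
    ap <- profile_derivs(a, dxi)$d1
    om <- field$omega
    om_wall <- om[, nj]
    wss <- mu * abs(om_wall)
    # phi = r * omega; (1/r) dphi/dr at the wall
    phi <- field$r * om
    phi_eta <- (3 * phi[, nj] - 4 * phi[, nj - 1] + phi[, nj - 2]) / (2 * deta)
    term1 <- phi_eta / a^2
    om_xi <- profile_derivs(om_wall, dxi)$d1
    om_eta <- (3 * om[, nj] - 4 * om[, nj - 1] + om[, nj - 2]) / (2 * deta)
    om_z <- om_xi + (-ap / a) * om_eta
    dpdz <- -mu * (term1 - ap * om_z)
    s <- cumtrapz(sqrt(1 + ap^2), z)
  } else {
    geom <- field$geometry
    upper_prominent <- min(geom$wall_upper) <= min(geom$wall_lower)
    jw <- if (upper_prominent) nj else 1L
    jn1 <- if (upper_prominent) nj - 1L else 2L
    jn2 <- if (upper_prominent) nj - 2L else 3L
    h <- field$r[, nj] - field$r[, 1]
    yw <- if (upper_prominent) field$r[, nj] else -field$r[, 1]
    ywp <- profile_derivs(yw, dxi)$d1
    om <- field$omega
    om_wall <- om[, jw]
    wss <- mu * abs(om_wall)
    sgn <- if (upper_prominent) 1 else -1
    om_eta <- sgn * (3 * om[, jw] - 4 * om[, jn1] + om[, jn2]) / (2 * deta)
    om_y <- om_eta / h
    hp <- profile_derivs(h, dxi)$d1
    ylp <- profile_derivs(-field$r[, 1], dxi)$d1
    eta_w <- if (upper_prominent) 1 else 0
    B <- (ylp - eta_w * hp) / h
    om_z <- profile_derivs(om_wall, dxi)$d1 + B * om_eta
    # dp/dz along the wall: p_z = -mu om_y, p_y = mu om_z; wall slope dy/dz
    slope <- if (upper_prominent) ywp else -ywp
    dpdz <- -mu * om_y + slope * mu * om_z
    s <- cumtrapz(sqrt(1 + ywp^2), z)
  }
  list(s = s, wss = wss, p_rel = cumtrapz(dpdz, z), dpdz = dpdz)
}
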