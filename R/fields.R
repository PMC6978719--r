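# Derived quantities and exports for solved flow fields.

#' Longitudinal wall profile on the prominent side
#'
#' Extracts the wall shear stress magnitude and wall pressure against arc
#' length along the prominent-side wall (the wall contributing more to the
#' luminal narrowing; in axisymmetric mode the single wall, whose azimuthal
#' label is arbitrary). WSS is `mu` times the wall-normal gradient of the
#' wall-tangential velocity at the wall; wall pressure is anchored per the
#' outlet model of the solve.
#'
#' @param field a converged [solve_steady_flow()] result.
#' @param geometry the `vessel_geometry` of the solve (defaults to the one
#'   stored in `field`).
#' @param side side label recorded on the profile (cosmetic in axisymmetric
#'   mode; the plaqued wall is always used in planar mode).
#' @return object of class `wall_profile`: data frame with columns `s` (m),
#'   `wss` (Pa), `pressure` (Pa) plus a `side_label` attribute.
#' @export
wall_profile <- function(field, geometry = field$geometry,
                         side = "prominent") {
  if (!inherits(field, "flow_field")) {
    icas_stop("icasflow_input_error", "`field` must be a flow_field")
  }
  if (!isTRUE(field$converged)) {
    icas_stop("icasflow_convergence_error",
              "refusing to extract a wall profile from an unconverged field",
              residual = field$final_residual)
  }
  out <- data.frame(s = field$wall_s, wss = field$wall_wss,
                    pressure = field$wall_pressure)
  attr(out, "side_label") <- side
  attr(out, "mode") <- field$mode
  class(out) <- c("wall_profile", "data.frame")
  out
}

#' Discrete mass-conservation error of a solved field
#'
#' Integrates the axial velocity over each cross-section (composite Simpson
#' quadrature over the grid nodes, so the measurement itself does not
#' dominate the discretisation error) and reports the largest relative
#' deviation of the station flow rate from the inlet flow rate.
#'
#' @param field a `flow_field`.
#' @return maximum relative flow-rate deviation (dimensionless fraction).
#' @export
mass_conservation_error <- function(field) {
  if (!inherits(field, "flow_field")) {
    icas_stop("icasflow_input_error", "`field` must be a flow_field")
  }
  nz1 <- length(field$z)
  if (field$mode == "axisymmetric") {
    Qref <- field$inlet$flow_rate
    if (Qref == 0) return(0)
    Qs <- vapply(seq_len(nz1), function(i) {
      r <- field$r[i, ]
      2 * pi * simpson(field$u[i, ] * r, r)
    }, numeric(1))
  } else {
    Qref <- field$inlet$mean_velocity * 2 * field$geometry$reference_radius
    if (Qref == 0) return(0)
    Qs <- vapply(seq_len(nz1), function(i) {
      simpson(field$u[i, ], field$r[i, ])
    }, numeric(1))
  }
  max(abs(Qs - Qref) / abs(Qref))
}

trapz <- function(y, x) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# composite Simpson on a uniform grid; trapezoid on a trailing odd cell
simpson <- function(y, x) {
  n <- length(x)
  if (n < 3) return(trapz(y, x))
  h <- x[2] - x[1]
  m <- if ((n - 1) %% 2 == 0) n else n - 1
  idx <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1; w[m] <- 1
  out <- sum(w * y[idx]) * h / 3
  if (m < n) out <- out + (y[n - 1] + y[n]) / 2 * h
  out
}

# mapped first derivatives of a node matrix M(i, j): returns d/dz and d/dr
# at fixed physical coordinates, using the body-fitted metric terms
mapped_gradient <- function(M, field) {
  z <- field$z; eta <- field$eta
  dxi <- z[2] - z[1]; deta <- eta[2] - eta[1]
  nz1 <- nrow(M); nj1 <- ncol(M)
  Mx <- (rbind(M[2, , drop = FALSE], M[3:nz1, , drop = FALSE], M[nz1, , drop = FALSE]) -
         rbind(M[1, , drop = FALSE], M[1:(nz1 - 2), , drop = FALSE], M[nz1 - 1, , drop = FALSE]))
  Mx <- Mx / c(dxi, rep(2 * dxi, nz1 - 2), dxi)
  Me <- (cbind(M[, 2, drop = FALSE], M[, 3:nj1, drop = FALSE], M[, nj1, drop = FALSE]) -
         cbind(M[, 1, drop = FALSE], M[, 1:(nj1 - 2), drop = FALSE], M[, nj1 - 1, drop = FALSE]))
  Me <- sweep(Me, 2, c(deta, rep(2 * deta, nj1 - 2), deta), "/")
  # physical metric: y(i, j) stored in field$r; dy/deta and dy/dxi
  y_e <- (cbind(field$r[, 2, drop = FALSE], field$r[, 3:nj1, drop = FALSE],
                field$r[, nj1, drop = FALSE]) -
          cbind(field$r[, 1, drop = FALSE], field$r[, 1:(nj1 - 2), drop = FALSE],
                field$r[, nj1 - 1, drop = FALSE]))
  y_e <- sweep(y_e, 2, c(deta, rep(2 * deta, nj1 - 2), deta), "/")
  y_x <- (rbind(field$r[2, , drop = FALSE], field$r[3:nz1, , drop = FALSE],
                field$r[nz1, , drop = FALSE]) -
          rbind(field$r[1, , drop = FALSE], field$r[1:(nz1 - 2), , drop = FALSE],
                field$r[nz1 - 1, , drop = FALSE]))
  y_x <- y_x / c(dxi, rep(2 * dxi, nz1 - 2), dxi)
  Mr <- Me / y_e
  Mz <- Mx - (y_x / y_e) * Me
  list(dz = Mz, dr = Mr)
}

#' Reconstruct the full-field pressure of a solved flow
#'
#' Diagnostic volumetric pressure for visualisation/export: the axial
#' momentum balance is integrated along each body-fitted grid line from the
#' inlet plane (anchored at the solve's inlet pressure level). The wall
#' metrics of the package use the more accurate wall-line integration stored
#' in the field (`wall_pressure`); this reconstruction is for contour output.
#'
#' @param field a converged `flow_field`.
#' @return matrix of pressure (Pa) at the grid nodes.
#' @export
pressure_field <- function(field) {
  if (!isTRUE(field$converged)) {
    icas_stop("icasflow_convergence_error",
              "refusing to reconstruct pressure from an unconverged field")
  }
  rho <- field$fluid$density; mu <- field$fluid$dynamic_viscosity
  z <- field$z
  nz1 <- length(z); nj1 <- length(field$eta)
  gu <- mapped_gradient(field$u, field)
  gv <- mapped_gradient(field$v, field)
  # z-component of the viscous term: mu * (lap u) with axisymmetric metric
  guz <- mapped_gradient(gu$dz, field)
  gur <- mapped_gradient(gu$dr, field)
  lap_u <- guz$dz + gur$dr
  if (field$mode == "axisymmetric") {
    rr <- field$r
    rr[, 1] <- 1  # axis column handled by symmetry below
    extra <- gu$dr / rr
    extra[, 1] <- gur$dr[, 1]  # lim (u_r / r) = u_rr on the axis
    lap_u <- lap_u + extra
  }
  dpdz <- -rho * (field$u * gu$dz + field$v * gu$dr) + mu * lap_u
  # integrate along each grid line following the line's physical slope
  dpdr <- -rho * (field$u * gv$dz + field$v * gv$dr)  # inviscid radial balance
  # slope of the eta = const line: dy/dz
  yx <- (rbind(field$r[2, , drop = FALSE], field$r[3:nz1, , drop = FALSE],
               field$r[nz1, , drop = FALSE]) -
         rbind(field$r[1, , drop = FALSE], field$r[1:(nz1 - 2), , drop = FALSE],
               field$r[nz1 - 1, , drop = FALSE]))
  yx <- yx / c(z[2] - z[1], rep(2 * (z[2] - z[1]), nz1 - 2), z[2] - z[1])
  dline <- dpdz + yx * dpdr
  p0 <- field$wall_pressure[1]
  p <- apply(dline, 2, function(col) cumtrapz(col, z))
  p + p0
}

#' Write a solved field as a legacy VTK structured grid
#'
#' ASCII `STRUCTURED_GRID` file with the velocity vector and pressure scalar
#' at the grid nodes, readable by ParaView/VisIt.
#'
#' @param field a converged `flow_field`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_flowfield_vtk <- function(field, path) {
  p <- pressure_field(field)
  nz1 <- length(field$z); nj1 <- length(field$eta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "icasflow steady flow field", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz1, nj1),
               sprintf("POINTS %d double", nz1 * nj1)), con)
  zz <- matrix(rep(field$z, nj1), nz1, nj1)
  writeLines(sprintf("%.9g %.9g 0", as.vector(zz), as.vector(field$r)), con)
  writeLines(c(sprintf("POINT_DATA %d", nz1 * nj1),
               "VECTORS velocity double"), con)
  writeLines(sprintf("%.9g %.9g 0", as.vector(field$u), as.vector(field$v)),
             con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", as.vector(p)), con)
  invisible(path)
}

#' Write a vessel geometry as a legacy VTK structured grid
#'
#' @param geometry a `vessel_geometry`.
#' @param path output `.vtk` path.
#' @param radial_cells cross-stream resolution of the exported grid.
#' @return `path`, invisibly.
#' @export
write_geometry_vtk <- function(geometry, path, radial_cells = 16L) {
  z <- geometry$z
  eta <- seq(0, 1, length.out = radial_cells + 1L)
  r <- if (geometry$mode == "axisymmetric") {
    outer(geometry$wall, eta)
  } else {
    outer(-geometry$wall_lower, 1 - eta) + outer(geometry$wall_upper, eta)
  }
  nz1 <- length(z); nj1 <- length(eta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "icasflow vessel lumen", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz1, nj1),
               sprintf("POINTS %d double", nz1 * nj1)), con)
  zz <- matrix(rep(z, nj1), nz1, nj1)
  writeLines(sprintf("%.9g %.9g 0", as.vector(zz), as.vector(r)), con)
  invisible(path)
}

#' Write a wall profile as CSV
#'
#' Columns `s_m`, `wss_pa`, `pressure_pa`.
#'
#' @param profile a [wall_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wall_profile_csv <- function(profile, path) {
  df <- data.frame(s_m = profile$s, wss_pa = profile$wss,
                   pressure_pa = profile$pressure)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %s, %d x %d nodes, %s (residual %.2e, %d sweeps)\n",
              x$mode, length(x$z), length(x$eta),
              if (x$converged) "converged" else "NOT converged",
              x$final_residual, x$iterations))
  cat(sprintf("  Q = %.3g mL/s, WSS range on wall [%.3g, %.3g] Pa, dP(wall) = %.3g Pa\n",
              x$inlet$flow_rate * 1e6, min(x$wall_wss), max(x$wall_wss),
              x$wall_pressure[1] - x$wall_pressure[length(x$wall_pressure)]))
  invisible(x)
}

#' @export
summary.flow_field <- function(object, ...) {
  structure(list(mode = object$mode, converged = object$converged,
                 residual = object$final_residual,
                 iterations = object$iterations,
                 mass_error = object$mass_error,
                 flow_rate = object$inlet$flow_rate,
                 wss_max = max(object$wall_wss),
                 pressure_drop = object$wall_pressure[1] -
                   object$wall_pressure[length(object$wall_pressure)]),
            class = "summary.flow_field")
}

#' @export
print.summary.flow_field <- function(x, ...) {
  cat("Steady stenosed-lumen flow solution\n")
  cat(sprintf("  mode: %s   converged: %s (residual %.2e, %d sweeps)\n",
              x$mode, x$converged, x$residual, x$iterations))
  cat(sprintf("  flow rate: %.4g mL/s   mass-conservation error: %.3g%%\n",
              x$flow_rate * 1e6, 100 * x$mass_error))
  cat(sprintf("  wall WSS max: %.4g Pa   wall pressure drop: %.4g Pa\n",
              x$wss_max, x$pressure_drop))
  invisible(x)
}

#' @export
plot.flow_field <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$wall_s * 1e3, x$wall_wss, type = "l",
                 xlab = "arc length [mm]", ylab = "WSS [Pa]",
                 main = "Prominent-side wall shear stress", ...)
  graphics::plot(x$wall_s * 1e3, x$wall_pressure / MMHG_TO_PA, type = "l",
                 xlab = "arc length [mm]", ylab = "pressure [mmHg]",
                 main = "Prominent-side wall pressure", ...)
  invisible(x)
}
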