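// Steady incompressible Newtonian flow in a stenosed lumen.
//
// Streamfunction-vorticity relaxation on a body-fitted structured grid
// (xi = axial coordinate, eta = scaled cross-stream coordinate in [0,1]).
// Axisymmetric mode solves for the reduced vorticity W = omega/r (regular on
// the axis); planar mode solves for omega itself between two walls.
// Convection is discretised with second-order upwind-biased differences,
// diffusion with central differences; the nonlinear system is relaxed by
// under-relaxed pointwise Gauss-Seidel with a first-order-upwind diagonal,
// interleaved with SOR sweeps of the streamfunction Poisson equation and a
// Thom-type wall-vorticity update. Mass conservation is exact by
// construction of the streamfunction.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sou(const NumericMatrix& W, int i, int j, int di, int dj,
                         int imax, int jmax, double d) {
  // upwind-biased derivative of W at (i,j) taking points at -(di,dj) steps;
  // second order where two upstream points exist, first order otherwise
  int i1 = i - di, j1 = j - dj, i2 = i - 2 * di, j2 = j - 2 * dj;
  bool have2 = i2 >= 0 && i2 <= imax && j2 >= 0 && j2 <= jmax;
  double sgn = (di + dj) >= 0 ? 1.0 : -1.0;  // derivative sign along +xi/+eta
  if (have2) {
    return sgn * (3.0 * W(i, j) - 4.0 * W(i1, j1) + W(i2, j2)) / (2.0 * d);
  }
  return sgn * (W(i, j) - W(i1, j1)) / d;
}

// [[Rcpp::export(name = ".solve_axisym_core")]]
List solve_axisym_core(NumericVector a, NumericVector ap, NumericVector app,
                       NumericVector psi_in, NumericVector w_in,
                       double Q, double nu, int nr,
                       double tol, int max_iter,
                       double relax_w, double relax_wall, double sor_psi,
                       int psi_sweeps, int check_every,
                       Nullable<NumericMatrix> psi0 = R_NilValue,
                       Nullable<NumericMatrix> w0 = R_NilValue) {
  const int nz = a.size() - 1;      // axial cells; nodes 0..nz
  const int nj = nr;                // radial cells; nodes 0..nr
  const double deta = 1.0 / nj;
  // axial spacing: uniform grid assumed; caller passes coordinates via a only
  // (dxi supplied through ap/app scaling); reconstruct from total extent:
  // caller guarantees uniform spacing dxi passed as attribute
  const double dxi = as<double>(a.attr("dxi"));
  const double dxi2 = dxi * dxi, deta2 = deta * deta;

  NumericMatrix psi(nz + 1, nj + 1), W(nz + 1, nj + 1);
  NumericMatrix u(nz + 1, nj + 1), v(nz + 1, nj + 1);

  const double a0 = a[0];
  const double psi_wall = Q / (2.0 * M_PI);
  const double Uin = Q / (M_PI * a0 * a0);
  const double Win = 4.0 * Q / (M_PI * a0 * a0 * a0 * a0);
  const double res_w_scale = std::max(Win * Uin / a0, 1e-300);
  const double res_p_scale = std::max(4.0 * Q / (M_PI * a0 * a0), 1e-300);

  // initial guess: locally fully developed (Poiseuille in the local radius)
  if (psi0.isNotNull() && w0.isNotNull()) {
    NumericMatrix p0(psi0), q0(w0);
    for (int i = 0; i <= nz; ++i)
      for (int j = 0; j <= nj; ++j) { psi(i, j) = p0(i, j); W(i, j) = q0(i, j); }
  } else {
    for (int i = 0; i <= nz; ++i) {
      for (int j = 0; j <= nj; ++j) {
        double eta = j * deta;
        psi(i, j) = psi_wall * (2.0 * eta * eta - eta * eta * eta * eta);
        W(i, j) = 4.0 * Q / (M_PI * std::pow(a[i], 4));
      }
    }
  }
  for (int j = 0; j <= nj; ++j) { psi(0, j) = psi_in[j]; W(0, j) = w_in[j]; }

  auto update_velocity = [&](void) {
    for (int i = 0; i <= nz; ++i) {
      double A = a[i];
      for (int j = 1; j < nj; ++j) {
        double eta = j * deta;
        double ps_e = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
        double ps_x;
        if (i == 0) ps_x = (psi(1, j) - psi(0, j)) / dxi;
        else if (i == nz) ps_x = (psi(nz, j) - psi(nz - 1, j)) / dxi;
        else ps_x = (psi(i + 1, j) - psi(i - 1, j)) / (2.0 * dxi);
        double b = -eta * ap[i] / A;
        double r = eta * A;
        u(i, j) = ps_e / (eta * A * A);
        v(i, j) = -(ps_x + b * ps_e) / r;
      }
      double r1 = deta * A;
      u(i, 0) = 2.0 * psi(i, 1) / (r1 * r1);
      v(i, 0) = 0.0;
      u(i, nj) = 0.0; v(i, nj) = 0.0;
    }
  };

  double res = NA_REAL, res0 = NA_REAL;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // outlet: zero-gradient
    for (int j = 0; j <= nj; ++j) {
      psi(nz, j) = psi(nz - 1, j);
      W(nz, j) = W(nz - 1, j);
    }
    // streamfunction SOR
    for (int sweep = 0; sweep < psi_sweeps; ++sweep) {
      for (int i = 1; i < nz; ++i) {
        double A = a[i];
        for (int j = 1; j < nj; ++j) {
          double eta = j * deta;
          double b = -eta * ap[i] / A;
          double g = -eta * app[i] / A + 2.0 * eta * ap[i] * ap[i] / (A * A);
          double ce2 = b * b + 1.0 / (A * A);
          double ce1 = g - 1.0 / (eta * A * A);
          double r = eta * A;
          double pxx = (psi(i + 1, j) - 2.0 * psi(i, j) + psi(i - 1, j)) / dxi2;
          double pee = (psi(i, j + 1) - 2.0 * psi(i, j) + psi(i, j - 1)) / deta2;
          double pxe = (psi(i + 1, j + 1) - psi(i + 1, j - 1)
                        - psi(i - 1, j + 1) + psi(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double pe = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
          double R = pxx + 2.0 * b * pxe + ce2 * pee + ce1 * pe
                     + r * r * W(i, j);
          double diag = 2.0 / dxi2 + 2.0 * ce2 / deta2;
          psi(i, j) += sor_psi * R / diag;
        }
        psi(i, 0) = 0.0;
        psi(i, nj) = psi_wall;
      }
      for (int j = 0; j <= nj; ++j) psi(nz, j) = psi(nz - 1, j);
    }

    update_velocity();

    // Thom wall vorticity (under-relaxed)
    for (int i = 1; i <= nz; ++i) {
      double A = a[i];
      double fac = (1.0 + ap[i] * ap[i]) / (A * A * A);
      double om_w = -fac * 2.0 * (psi(i, nj - 1) - psi_wall) / deta2;
      double Wtarget = om_w / A;  // W = omega/r at r = a
      W(i, nj) = (1.0 - relax_wall) * W(i, nj) + relax_wall * Wtarget;
    }

    // vorticity Gauss-Seidel sweep; direction alternates so information
    // propagates both with the bulk flow and against it (recirculation)
    bool fwd = (iter % 2) == 1;
    for (int ii = 1; ii < nz; ++ii) {
      int i = fwd ? ii : nz - ii;
      double A = a[i];
      // axis node j = 0: symmetric, diffusion W_zz + 4 W_rr
      {
        double conv = u(i, 0) * ((u(i, 0) >= 0.0)
                        ? sou(W, i, 0, 1, 0, nz, nj, dxi)
                        : sou(W, i, 0, -1, 0, nz, nj, dxi));
        double Wxx = (W(i + 1, 0) - 2.0 * W(i, 0) + W(i - 1, 0)) / dxi2;
        double Wee = 2.0 * (W(i, 1) - W(i, 0)) / deta2;  // mirror node
        double R = nu * (Wxx + 4.0 * Wee / (A * A)) - conv;
        double diag = std::fabs(u(i, 0)) * 1.5 / dxi
                      + nu * (2.0 / dxi2 + 8.0 / (deta2 * A * A));
        W(i, 0) += relax_w * R / diag;
      }
      for (int j = 1; j < nj; ++j) {
        double eta = j * deta;
        double b = -eta * ap[i] / A;
        double g = -eta * app[i] / A + 2.0 * eta * ap[i] * ap[i] / (A * A);
        double ce2 = b * b + 1.0 / (A * A);
        double ce1 = g + 3.0 / (eta * A * A);
        double Cxi = u(i, j);
        double Ceta = u(i, j) * b + v(i, j) / A;
        double convX = (Cxi >= 0.0) ? sou(W, i, j, 1, 0, nz, nj, dxi)
                                    : sou(W, i, j, -1, 0, nz, nj, dxi);
        double convE = (Ceta >= 0.0) ? sou(W, i, j, 0, 1, nz, nj, deta)
                                     : sou(W, i, j, 0, -1, nz, nj, deta);
        double conv = Cxi * convX + Ceta * convE;
        double Wxx = (W(i + 1, j) - 2.0 * W(i, j) + W(i - 1, j)) / dxi2;
        double Wee = (W(i, j + 1) - 2.0 * W(i, j) + W(i, j - 1)) / deta2;
        double Wxe = (W(i + 1, j + 1) - W(i + 1, j - 1)
                      - W(i - 1, j + 1) + W(i - 1, j - 1))
                     / (4.0 * dxi * deta);
        double We = (W(i, j + 1) - W(i, j - 1)) / (2.0 * deta);
        double R = nu * (Wxx + 2.0 * b * Wxe + ce2 * Wee + ce1 * We) - conv;
        double diag = std::fabs(Cxi) * 1.5 / dxi + std::fabs(Ceta) * 1.5 / deta
                      + nu * (2.0 / dxi2 + 2.0 * ce2 / deta2);
        W(i, j) += relax_w * R / diag;
      }
    }

    if (iter % check_every == 0 || iter == max_iter) {
      // steady-state residuals of the full second-order discretisation
      double sw = 0.0, sp = 0.0; long nnode = 0;
      for (int i = 1; i < nz; ++i) {
        double A = a[i];
        for (int j = 1; j < nj; ++j) {
          double eta = j * deta;
          double b = -eta * ap[i] / A;
          double g = -eta * app[i] / A + 2.0 * eta * ap[i] * ap[i] / (A * A);
          double ce2 = b * b + 1.0 / (A * A);
          double Cxi = u(i, j);
          double Ceta = u(i, j) * b + v(i, j) / A;
          double convX = (Cxi >= 0.0) ? sou(W, i, j, 1, 0, nz, nj, dxi)
                                      : sou(W, i, j, -1, 0, nz, nj, dxi);
          double convE = (Ceta >= 0.0) ? sou(W, i, j, 0, 1, nz, nj, deta)
                                       : sou(W, i, j, 0, -1, nz, nj, deta);
          double Wxx = (W(i + 1, j) - 2.0 * W(i, j) + W(i - 1, j)) / dxi2;
          double Wee = (W(i, j + 1) - 2.0 * W(i, j) + W(i, j - 1)) / deta2;
          double Wxe = (W(i + 1, j + 1) - W(i + 1, j - 1)
                        - W(i - 1, j + 1) + W(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double We = (W(i, j + 1) - W(i, j - 1)) / (2.0 * deta);
          double ce1 = g + 3.0 / (eta * A * A);
          double Rw = nu * (Wxx + 2.0 * b * Wxe + ce2 * Wee + ce1 * We)
                      - (Cxi * convX + Ceta * convE);
          double pxx = (psi(i + 1, j) - 2.0 * psi(i, j) + psi(i - 1, j)) / dxi2;
          double pee = (psi(i, j + 1) - 2.0 * psi(i, j) + psi(i, j - 1)) / deta2;
          double pxe = (psi(i + 1, j + 1) - psi(i + 1, j - 1)
                        - psi(i - 1, j + 1) + psi(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double pe = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
          double r = eta * A;
          double Rp = pxx + 2.0 * b * pxe + ce2 * pee
                      + (g - 1.0 / (eta * A * A)) * pe + r * r * W(i, j);
          sw += Rw * Rw; sp += Rp * Rp; ++nnode;
        }
      }
      // normalise by the current solution magnitude (throat scales dominate
      // severe stenoses), floored at the inlet reference scale
      double w2 = 0.0, umax = 0.0, src2 = 0.0, amin = a[0];
      for (int i = 1; i < nz; ++i) {
        if (a[i] < amin) amin = a[i];
        for (int j = 1; j < nj; ++j) {
          w2 += W(i, j) * W(i, j);
          double r = j * deta * a[i];
          src2 += r * r * W(i, j) * r * r * W(i, j);
          if (std::fabs(u(i, j)) > umax) umax = std::fabs(u(i, j));
        }
      }
      double w_scale = std::max(res_w_scale,
                                std::sqrt(w2 / nnode) * umax / amin);
      double p_scale = std::max(res_p_scale, std::sqrt(src2 / nnode));
      double res_w = std::sqrt(sw / nnode) / w_scale;
      double res_p = std::sqrt(sp / nnode) / p_scale;
      res = std::max(res_w, res_p);
      if (res <= tol) { converged = true; break; }
      if (!std::isfinite(res)) break;
      if (iter == check_every) res0 = res;
      else if (res > 1e3 * res0 && res > 1.0) break;   // diverging: bail early
    }
  }
  update_velocity();

  return List::create(_["psi"] = psi, _["w"] = W, _["u"] = u, _["v"] = v,
                      _["converged"] = converged, _["residual"] = res,
                      _["iterations"] = std::min(iter, max_iter));
}

// [[Rcpp::export(name = ".solve_planar_core")]]
List solve_planar_core(NumericVector yl, NumericVector ylp, NumericVector ylpp,
                       NumericVector yu, NumericVector yup, NumericVector yupp,
                       NumericVector psi_in, NumericVector w_in,
                       double q, double nu, int nr,
                       double tol, int max_iter,
                       double relax_w, double relax_wall, double sor_psi,
                       int psi_sweeps, int check_every,
                       Nullable<NumericMatrix> psi0 = R_NilValue,
                       Nullable<NumericMatrix> w0 = R_NilValue) {
  const int nz = yl.size() - 1;
  const int nj = nr;
  const double deta = 1.0 / nj;
  const double dxi = as<double>(yl.attr("dxi"));
  const double dxi2 = dxi * dxi, deta2 = deta * deta;

  NumericMatrix psi(nz + 1, nj + 1), W(nz + 1, nj + 1);
  NumericMatrix u(nz + 1, nj + 1), v(nz + 1, nj + 1);

  const double h0 = yl[0] + yu[0];
  const double Uin = q / h0;
  const double Win = 6.0 * q / (h0 * h0);  // wall vorticity scale
  const double res_w_scale = std::max(Win * Uin / h0, 1e-300);
  const double res_p_scale = std::max(Win, 1e-300);

  // initial guess: locally fully developed plane Poiseuille
  if (psi0.isNotNull() && w0.isNotNull()) {
    NumericMatrix p0(psi0), q0(w0);
    for (int i = 0; i <= nz; ++i)
      for (int j = 0; j <= nj; ++j) { psi(i, j) = p0(i, j); W(i, j) = q0(i, j); }
  } else {
    for (int i = 0; i <= nz; ++i) {
      double h = yl[i] + yu[i];
      for (int j = 0; j <= nj; ++j) {
        double eta = j * deta;
        psi(i, j) = q * eta * eta * (3.0 - 2.0 * eta);
        W(i, j) = -6.0 * q / (h * h) * (1.0 - 2.0 * eta);
      }
    }
  }
  for (int j = 0; j <= nj; ++j) { psi(0, j) = psi_in[j]; W(0, j) = w_in[j]; }

  auto metrics = [&](int i, double eta, double& h, double& B, double& G) {
    h = yl[i] + yu[i];
    double hp = ylp[i] + yup[i], hpp = ylpp[i] + yupp[i];
    B = (ylp[i] - eta * hp) / h;
    G = (ylpp[i] - eta * hpp) / h - 2.0 * B * hp / h;
  };

  auto update_velocity = [&](void) {
    for (int i = 0; i <= nz; ++i) {
      double h, B, G;
      for (int j = 1; j < nj; ++j) {
        double eta = j * deta;
        metrics(i, eta, h, B, G);
        double ps_e = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
        double ps_x;
        if (i == 0) ps_x = (psi(1, j) - psi(0, j)) / dxi;
        else if (i == nz) ps_x = (psi(nz, j) - psi(nz - 1, j)) / dxi;
        else ps_x = (psi(i + 1, j) - psi(i - 1, j)) / (2.0 * dxi);
        u(i, j) = ps_e / h;
        v(i, j) = -(ps_x + B * ps_e);
      }
      u(i, 0) = 0.0; v(i, 0) = 0.0; u(i, nj) = 0.0; v(i, nj) = 0.0;
    }
  };

  double res = NA_REAL, res0 = NA_REAL;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int j = 0; j <= nj; ++j) {
      psi(nz, j) = psi(nz - 1, j);
      W(nz, j) = W(nz - 1, j);
    }
    for (int sweep = 0; sweep < psi_sweeps; ++sweep) {
      for (int i = 1; i < nz; ++i) {
        double h, B, G;
        for (int j = 1; j < nj; ++j) {
          double eta = j * deta;
          metrics(i, eta, h, B, G);
          double ce2 = B * B + 1.0 / (h * h);
          double pxx = (psi(i + 1, j) - 2.0 * psi(i, j) + psi(i - 1, j)) / dxi2;
          double pee = (psi(i, j + 1) - 2.0 * psi(i, j) + psi(i, j - 1)) / deta2;
          double pxe = (psi(i + 1, j + 1) - psi(i + 1, j - 1)
                        - psi(i - 1, j + 1) + psi(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double pe = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
          double R = pxx + 2.0 * B * pxe + ce2 * pee + G * pe + W(i, j);
          double diag = 2.0 / dxi2 + 2.0 * ce2 / deta2;
          psi(i, j) += sor_psi * R / diag;
        }
        psi(i, 0) = 0.0;
        psi(i, nj) = q;
      }
      for (int j = 0; j <= nj; ++j) psi(nz, j) = psi(nz - 1, j);
    }

    update_velocity();

    for (int i = 1; i <= nz; ++i) {
      double h = yl[i] + yu[i];
      double Bu = (ylp[i] - (yup[i] + ylp[i])) / h;   // B at eta = 1
      double Bl = ylp[i] / h;                          // B at eta = 0
      double om_up = -(Bu * Bu + 1.0 / (h * h))
                     * 2.0 * (psi(i, nj - 1) - q) / deta2;
      double om_lo = -(Bl * Bl + 1.0 / (h * h))
                     * 2.0 * (psi(i, 1) - 0.0) / deta2;
      W(i, nj) = (1.0 - relax_wall) * W(i, nj) + relax_wall * om_up;
      W(i, 0) = (1.0 - relax_wall) * W(i, 0) + relax_wall * om_lo;
    }

    bool fwd = (iter % 2) == 1;
    for (int ii = 1; ii < nz; ++ii) {
      int i = fwd ? ii : nz - ii;
      double h, B, G;
      for (int j = 1; j < nj; ++j) {
        double eta = j * deta;
        metrics(i, eta, h, B, G);
        double ce2 = B * B + 1.0 / (h * h);
        double Cxi = u(i, j);
        double Ceta = u(i, j) * B + v(i, j) / h;
        double convX = (Cxi >= 0.0) ? sou(W, i, j, 1, 0, nz, nj, dxi)
                                    : sou(W, i, j, -1, 0, nz, nj, dxi);
        double convE = (Ceta >= 0.0) ? sou(W, i, j, 0, 1, nz, nj, deta)
                                     : sou(W, i, j, 0, -1, nz, nj, deta);
        double conv = Cxi * convX + Ceta * convE;
        double Wxx = (W(i + 1, j) - 2.0 * W(i, j) + W(i - 1, j)) / dxi2;
        double Wee = (W(i, j + 1) - 2.0 * W(i, j) + W(i, j - 1)) / deta2;
        double Wxe = (W(i + 1, j + 1) - W(i + 1, j - 1)
                      - W(i - 1, j + 1) + W(i - 1, j - 1))
                     / (4.0 * dxi * deta);
        double We = (W(i, j + 1) - W(i, j - 1)) / (2.0 * deta);
        double R = nu * (Wxx + 2.0 * B * Wxe + ce2 * Wee + G * We) - conv;
        double diag = std::fabs(Cxi) * 1.5 / dxi + std::fabs(Ceta) * 1.5 / deta
                      + nu * (2.0 / dxi2 + 2.0 * ce2 / deta2);
        W(i, j) += relax_w * R / diag;
      }
    }

    if (iter % check_every == 0 || iter == max_iter) {
      double sw = 0.0, sp = 0.0; long nnode = 0;
      for (int i = 1; i < nz; ++i) {
        double h, B, G;
        for (int j = 1; j < nj; ++j) {
          double eta = j * deta;
          metrics(i, eta, h, B, G);
          double ce2 = B * B + 1.0 / (h * h);
          double Cxi = u(i, j);
          double Ceta = u(i, j) * B + v(i, j) / h;
          double convX = (Cxi >= 0.0) ? sou(W, i, j, 1, 0, nz, nj, dxi)
                                      : sou(W, i, j, -1, 0, nz, nj, dxi);
          double convE = (Ceta >= 0.0) ? sou(W, i, j, 0, 1, nz, nj, deta)
                                       : sou(W, i, j, 0, -1, nz, nj, deta);
          double Wxx = (W(i + 1, j) - 2.0 * W(i, j) + W(i - 1, j)) / dxi2;
          double Wee = (W(i, j + 1) - 2.0 * W(i, j) + W(i, j - 1)) / deta2;
          double Wxe = (W(i + 1, j + 1) - W(i + 1, j - 1)
                        - W(i - 1, j + 1) + W(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double We = (W(i, j + 1) - W(i, j - 1)) / (2.0 * deta);
          double Rw = nu * (Wxx + 2.0 * B * Wxe + ce2 * Wee + G * We)
                      - (Cxi * convX + Ceta * convE);
          double pxx = (psi(i + 1, j) - 2.0 * psi(i, j) + psi(i - 1, j)) / dxi2;
          double pee = (psi(i, j + 1) - 2.0 * psi(i, j) + psi(i, j - 1)) / deta2;
          double pxe = (psi(i + 1, j + 1) - psi(i + 1, j - 1)
                        - psi(i - 1, j + 1) + psi(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double pe = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
          double Rp = pxx + 2.0 * B * pxe + ce2 * pee + G * pe + W(i, j);
          sw += Rw * Rw; sp += Rp * Rp; ++nnode;
        }
      }
      double w2 = 0.0, umax = 0.0, hmin = yl[0] + yu[0];
      for (int i = 1; i < nz; ++i) {
        double h = yl[i] + yu[i];
        if (h < hmin) hmin = h;
        for (int j = 1; j < nj; ++j) {
          w2 += W(i, j) * W(i, j);
          if (std::fabs(u(i, j)) > umax) umax = std::fabs(u(i, j));
        }
      }
      double w_norm = std::sqrt(w2 / nnode);
      double w_scale = std::max(res_w_scale, w_norm * umax / hmin);
      double p_scale = std::max(res_p_scale, w_norm);
      double res_w = std::sqrt(sw / nnode) / w_scale;
      double res_p = std::sqrt(sp / nnode) / p_scale;
      res = std::max(res_w, res_p);
      if (res <= tol) { converged = true; break; }
      if (!std::isfinite(res)) break;
      if (iter == check_every) res0 = res;
      else if (res > 1e3 * res0 && res > 1.0) break;   // diverging: bail early
    }
  }
  update_velocity();

  return List::create(_["psi"] = psi, _["w"] = W, _["u"] = u, _["v"] = v,
                      _["converged"] = converged, _["residual"] = res,
                      _["iterations"] = std::min(iter, max_iter));
}
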