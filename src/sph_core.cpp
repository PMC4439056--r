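// Core particle loops: cubic-spline kernel, uniform-grid neighbor search,
// SPH density/pressure/viscosity, cross-phase coupling, and the MLS elastic
// pipeline (displacement gradient -> Green-Saint-Venant strain -> Hooke stress
// -> elastic + volume-conservation forces with energy-consistent reactions).
#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline double sigma_norm(double h, int dim) {
  if (dim == 2) return 10.0 / (7.0 * M_PI * h * h);
  return 1.0 / (M_PI * h * h * h);
}

// W(q) with q = r/h, support q < 2
static inline double w_of_q(double q, double sig) {
  if (q < 1.0) return sig * (1.0 - 1.5 * q * q + 0.75 * q * q * q);
  if (q < 2.0) { double t = 2.0 - q; return sig * 0.25 * t * t * t; }
  return 0.0;
}
static inline double dw_dq(double q, double sig) {
  if (q < 1.0) return sig * (-3.0 * q + 2.25 * q * q);
  if (q < 2.0) { double t = 2.0 - q; return -0.75 * sig * t * t; }
  return 0.0;
}
static inline double d2w_dq2(double q, double sig) {
  if (q < 1.0) return sig * (-3.0 + 4.5 * q);
  if (q < 2.0) return 1.5 * sig * (2.0 - q);
  return 0.0;
}

// [[Rcpp::export]]
List kernel_cubic_cpp(NumericMatrix rvec, double h, int dim) {
  int n = rvec.nrow(), d = rvec.ncol();
  double sig = sigma_norm(h, dim);
  NumericVector W(n), lapW(n);
  NumericMatrix gradW(n, d);
  for (int i = 0; i < n; ++i) {
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) r2 += rvec(i, k) * rvec(i, k);
    double r = std::sqrt(r2), q = r / h;
    W[i] = w_of_q(q, sig);
    double wr = dw_dq(q, sig) / h;           // dW/dr
    double wrr = d2w_dq2(q, sig) / (h * h);  // d2W/dr2
    if (r > 1e-12) {
      for (int k = 0; k < d; ++k) gradW(i, k) = wr * rvec(i, k) / r;
      lapW[i] = wrr + (dim - 1) * wr / r;
    } else {
      for (int k = 0; k < d; ++k) gradW(i, k) = 0.0;
      lapW[i] = -3.0 * dim * sig / (h * h);  // radial limit at r -> 0
    }
  }
  return List::create(_["W"] = W, _["gradW"] = gradW, _["lapW"] = lapW);
}

struct CellKey {
  long long v;
  bool operator==(const CellKey& o) const { return v == o.v; }
};
struct CellHash {
  std::size_t operator()(const CellKey& k) const {
    return std::hash<long long>()(k.v);
  }
};
static inline long long pack_cell(int cx, int cy, int cz) {
  return ((long long)(cx + 1048576)) |
         (((long long)(cy + 1048576)) << 21) |
         (((long long)(cz + 1048576)) << 42);
}

// All unordered pairs with distance < radius (strict), uniform grid, exact.
// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, double radius) {
  int n = pos.nrow(), d = pos.ncol();
  double r2 = radius * radius;
  std::unordered_map<CellKey, std::vector<int>, CellHash> grid;
  grid.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pos(i, 0) / radius);
    int cy = (int)std::floor(pos(i, 1) / radius);
    int cz = (d > 2) ? (int)std::floor(pos(i, 2) / radius) : 0;
    grid[{pack_cell(cx, cy, cz)}].push_back(i);
  }
  std::vector<int> ai, bj;
  int zlo = (d > 2) ? -1 : 0, zhi = (d > 2) ? 1 : 0;
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pos(i, 0) / radius);
    int cy = (int)std::floor(pos(i, 1) / radius);
    int cz = (d > 2) ? (int)std::floor(pos(i, 2) / radius) : 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = zlo; dz <= zhi; ++dz) {
          auto it = grid.find({pack_cell(cx + dx, cy + dy, cz + dz)});
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double s = 0.0;
            for (int k = 0; k < d; ++k) {
              double t = pos(i, k) - pos(j, k);
              s += t * t;
            }
            if (s < r2) { ai.push_back(i + 1); bj.push_back(j + 1); }
          }
        }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = bj[k]; }
  return out;
}

// rho_i = sum_j m_j W(r_ij) including the self term.
// [[Rcpp::export]]
NumericVector densities_cpp(NumericMatrix pos, NumericVector mass,
                            IntegerMatrix pairs, double h, int dim) {
  int n = pos.nrow(), d = pos.ncol();
  double sig = sigma_norm(h, dim);
  NumericVector rho(n);
  double w0 = w_of_q(0.0, sig);
  for (int i = 0; i < n; ++i) rho[i] = mass[i] * w0;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) {
      double t = pos(i, k) - pos(j, k);
      r2 += t * t;
    }
    double w = w_of_q(std::sqrt(r2) / h, sig);
    rho[i] += mass[j] * w;
    rho[j] += mass[i] * w;
  }
  return rho;
}

// Pairwise pressure force, mean-pressure form with the particle-volume factor
// symmetrized per pair: f_pair = -(p_i+p_j)/2 * (m_i/rho_i + m_j/rho_j)/2 *
// gradW(r_i - r_j), applied +f to i and -f to j (exactly antisymmetric;
// compressed regions repel). Equals the per-particle sum with m_j/rho_j for
// uniform particle volumes.
// [[Rcpp::export]]
NumericMatrix pressure_forces_cpp(NumericMatrix pos, NumericVector mass,
                                  NumericVector rho, NumericVector pres,
                                  IntegerMatrix pairs, double h, int dim) {
  int n = pos.nrow(), d = pos.ncol();
  double sig = sigma_norm(h, dim);
  NumericMatrix f(n, d);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double r2 = 0.0;
    double rv[3];
    for (int k = 0; k < d; ++k) { rv[k] = pos(i, k) - pos(j, k); r2 += rv[k] * rv[k]; }
    double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    double wr = dw_dq(r / h, sig) / h;
    double vbar = 0.5 * (mass[i] / rho[i] + mass[j] / rho[j]);
    double c = -0.5 * (pres[i] + pres[j]) * vbar * wr / r;
    for (int k = 0; k < d; ++k) {
      f(i, k) += c * rv[k];
      f(j, k) -= c * rv[k];
    }
  }
  return f;
}

// f_i += sum_j mu_ij (v_j - v_i) (m_j / rho_j) lapW(r_ij)
// [[Rcpp::export]]
NumericMatrix viscosity_forces_cpp(NumericMatrix pos, NumericMatrix vel,
                                   NumericVector mass, NumericVector rho,
                                   IntegerMatrix pairs, NumericVector mu_pair,
                                   double h, int dim) {
  int n = pos.nrow(), d = pos.ncol();
  double sig = sigma_norm(h, dim);
  NumericMatrix f(n, d);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) {
      double t = pos(i, k) - pos(j, k);
      r2 += t * t;
    }
    double r = std::sqrt(r2), q = r / h;
    double lap;
    if (r > 1e-12)
      lap = d2w_dq2(q, sig) / (h * h) + (dim - 1) * (dw_dq(q, sig) / h) / r;
    else
      lap = -3.0 * dim * sig / (h * h);
    double mu = mu_pair[p];
    for (int k = 0; k < d; ++k) {
      double dv = vel(j, k) - vel(i, k);
      f(i, k) += mu * dv * (mass[j] / rho[j]) * lap;
      f(j, k) += mu * (-dv) * (mass[i] / rho[i]) * lap;
    }
  }
  return f;
}

// Rheological viscosity coefficient per pair:
// mu = beta1 * (1 - cos^2(theta) * |dv| / |dr|)^beta2, base clamped to [0,1].
// [[Rcpp::export]]
NumericVector rheo_mu_cpp(NumericMatrix pos, NumericMatrix vel,
                          IntegerMatrix pairs, double beta1, double beta2) {
  int d = pos.ncol(), m = pairs.nrow();
  NumericVector mu(m);
  for (int p = 0; p < m; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double dv2 = 0.0, dr2 = 0.0, dot = 0.0;
    for (int k = 0; k < d; ++k) {
      double a = vel(i, k) - vel(j, k), b = pos(i, k) - pos(j, k);
      dv2 += a * a; dr2 += b * b; dot += a * b;
    }
    double dv = std::sqrt(dv2), dr = std::sqrt(dr2);
    if (dv < 1e-12) { mu[p] = beta1; continue; }
    double c2 = (dot * dot) / (dv2 * dr2);  // cos^2 theta
    double base = 1.0 - c2 * dv / dr;
    if (base < 0.0) base = 0.0;
    if (base > 1.0) base = 1.0;
    mu[p] = beta1 * std::pow(base, beta2);
  }
  return mu;
}

// Cross-phase coupling f = -Kc m_a m_b gradW, applied +f to a / -f to b.
// [[Rcpp::export]]
List coupling_forces_cpp(NumericMatrix pos, NumericVector mass,
                         IntegerMatrix pairs, double Kc, double h, int dim) {
  int n = pos.nrow(), d = pos.ncol(), m = pairs.nrow();
  double sig = sigma_norm(h, dim);
  NumericMatrix f(n, d), pf(m, d);
  for (int p = 0; p < m; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double r2 = 0.0;
    double rv[3];
    for (int k = 0; k < d; ++k) { rv[k] = pos(i, k) - pos(j, k); r2 += rv[k] * rv[k]; }
    double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    double wr = dw_dq(r / h, sig) / h;
    double c = -Kc * mass[i] * mass[j] * wr / r;
    for (int k = 0; k < d; ++k) {
      pf(p, k) = c * rv[k];
      f(i, k) += c * rv[k];
      f(j, k) -= c * rv[k];
    }
  }
  return List::create(_["forces"] = f, _["pair_force"] = pf);
}

static inline bool inv_small(const double* A, double* Ainv, int d) {
  if (d == 2) {
    double det = A[0] * A[3] - A[1] * A[2];
    double tr = (A[0] + A[3]) / 2.0;
    if (std::fabs(det) < 1e-10 * tr * tr) return false;
    Ainv[0] = A[3] / det; Ainv[1] = -A[1] / det;
    Ainv[2] = -A[2] / det; Ainv[3] = A[0] / det;
    return true;
  }
  // 3x3 adjugate
  double c00 = A[4] * A[8] - A[5] * A[7];
  double c01 = A[5] * A[6] - A[3] * A[8];
  double c02 = A[3] * A[7] - A[4] * A[6];
  double det = A[0] * c00 + A[1] * c01 + A[2] * c02;
  double tr = (A[0] + A[4] + A[8]) / 3.0;
  if (std::fabs(det) < 1e-10 * tr * tr * tr) return false;
  Ainv[0] = c00 / det;
  Ainv[1] = (A[2] * A[7] - A[1] * A[8]) / det;
  Ainv[2] = (A[1] * A[5] - A[2] * A[4]) / det;
  Ainv[3] = c01 / det;
  Ainv[4] = (A[0] * A[8] - A[2] * A[6]) / det;
  Ainv[5] = (A[2] * A[3] - A[0] * A[5]) / det;
  Ainv[6] = c02 / det;
  Ainv[7] = (A[1] * A[6] - A[0] * A[7]) / det;
  Ainv[8] = (A[0] * A[4] - A[1] * A[3]) / det;
  return true;
}

// Full elastic pass. Reference-configuration neighborhoods (pairs computed on
// `ref` within 2 h_e). Returns per-particle tensors, forces and energies.
// Reactions use the exact per-neighbor MLS weight g_ij = A^-1 x_ij w_ij, the
// gradient of the per-particle energy, so momentum balances exactly.
// [[Rcpp::export]]
List elastic_compute_cpp(NumericMatrix ref, NumericMatrix disp,
                         IntegerMatrix pairs, double h_e, double lambda,
                         double mu, double kv, NumericVector vol, int dim,
                         bool reaction) {
  int n = ref.nrow(), d = ref.ncol();
  double sig = sigma_norm(h_e, dim);
  // adjacency lists from pairs
  std::vector<std::vector<int>> nbr(n);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    nbr[i].push_back(j);
    nbr[j].push_back(i);
  }
  NumericMatrix grad_u(n, d * d), strain(n, d * d), stress(n, d * d);
  NumericMatrix f_el(n, d), f_vol(n, d), dvec(n, d);
  LogicalVector degen(n);
  double U_el = 0.0, U_vol = 0.0;
  NumericVector detJv(n);
  std::vector<double> A(d * d), Ainv(d * d), B(d * d), b(d), di(d);
  std::vector<double> J(d * d), eps(d * d), sg(d * d), Js(d * d), C(d * d);
  for (int i = 0; i < n; ++i) {
    int nn = (int)nbr[i].size();
    if (nn < d + 1) { degen[i] = true; detJv[i] = 1.0; continue; }
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(B.begin(), B.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    for (int j : nbr[i]) {
      double x[3], du[3], r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        x[k] = ref(j, k) - ref(i, k);
        du[k] = disp(j, k) - disp(i, k);
        r2 += x[k] * x[k];
      }
      double w = w_of_q(std::sqrt(r2) / h_e, sig);
      for (int a = 0; a < d; ++a) {
        b[a] -= x[a] * w;
        for (int c = 0; c < d; ++c) {
          A[a * d + c] += x[a] * x[c] * w;   // A = sum x x^T w
          B[a * d + c] += du[a] * x[c] * w;  // B = sum du x^T w
        }
      }
    }
    if (!inv_small(A.data(), Ainv.data(), d)) {
      // Tikhonov: A + 1e-6 tr(A)/d I, retry
      double tr = 0.0;
      for (int k = 0; k < d; ++k) tr += A[k * d + k];
      for (int k = 0; k < d; ++k) A[k * d + k] += 1e-6 * tr / d;
      if (!inv_small(A.data(), Ainv.data(), d)) {
        degen[i] = true; detJv[i] = 1.0;
        continue;
      }
    }
    // Ju = B A^-1 (Jacobian du/dx); J = I + Ju
    for (int a = 0; a < d; ++a)
      for (int c = 0; c < d; ++c) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) s += B[a * d + k] * Ainv[k * d + c];
        J[a * d + c] = s + (a == c ? 1.0 : 0.0);
        grad_u(i, a * d + c) = s;
      }
    // d_i = A^-1 b
    for (int a = 0; a < d; ++a) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += Ainv[a * d + k] * b[k];
      di[a] = s;
      dvec(i, a) = s;
    }
    // strain = J^T J - I (unhalved Green-Saint-Venant, as modeled)
    double treps = 0.0;
    for (int a = 0; a < d; ++a)
      for (int c = 0; c < d; ++c) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) s += J[k * d + a] * J[k * d + c];
        eps[a * d + c] = s - (a == c ? 1.0 : 0.0);
        strain(i, a * d + c) = eps[a * d + c];
      }
    for (int k = 0; k < d; ++k) treps += eps[k * d + k];
    // Hooke: sigma = lambda tr(eps) I + 2 mu eps
    double e_dc = 0.0;  // eps : sigma
    for (int a = 0; a < d; ++a)
      for (int c = 0; c < d; ++c) {
        sg[a * d + c] = lambda * treps * (a == c ? 1.0 : 0.0) + 2.0 * mu * eps[a * d + c];
        stress(i, a * d + c) = sg[a * d + c];
        e_dc += eps[a * d + c] * sg[a * d + c];
      }
    U_el += vol[i] * e_dc / 2.0;
    // det J and cofactor matrix C (C_ab = d det / d J_ab)
    double detJ;
    if (d == 2) {
      detJ = J[0] * J[3] - J[1] * J[2];
      C[0] = J[3]; C[1] = -J[2]; C[2] = -J[1]; C[3] = J[0];
    } else {
      detJ = J[0] * (J[4] * J[8] - J[5] * J[7]) - J[1] * (J[3] * J[8] - J[5] * J[6]) +
             J[2] * (J[3] * J[7] - J[4] * J[6]);
      C[0] = J[4] * J[8] - J[5] * J[7];
      C[1] = J[5] * J[6] - J[3] * J[8];
      C[2] = J[3] * J[7] - J[4] * J[6];
      C[3] = J[2] * J[7] - J[1] * J[8];
      C[4] = J[0] * J[8] - J[2] * J[6];
      C[5] = J[1] * J[6] - J[0] * J[7];
      C[6] = J[1] * J[5] - J[2] * J[4];
      C[7] = J[2] * J[3] - J[0] * J[5];
      C[8] = J[0] * J[4] - J[1] * J[3];
    }
    detJv[i] = detJ;
    U_vol += vol[i] * kv * (detJ - 1.0) * (detJ - 1.0) / 2.0;
    // Js = J sigma ; elastic force on i: -2 v Js d_i
    for (int a = 0; a < d; ++a)
      for (int c = 0; c < d; ++c) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) s += J[a * d + k] * sg[k * d + c];
        Js[a * d + c] = s;
      }
    double cvol = vol[i] * kv * (detJ - 1.0);
    for (int a = 0; a < d; ++a) {
      double s_el = 0.0, s_vl = 0.0;
      for (int k = 0; k < d; ++k) {
        s_el += Js[a * d + k] * di[k];
        s_vl += C[a * d + k] * di[k];
      }
      f_el(i, a) += -2.0 * vol[i] * s_el;
      f_vol(i, a) += -cvol * s_vl;
    }
    if (reaction) {
      for (int j : nbr[i]) {
        double x[3], r2 = 0.0;
        for (int k = 0; k < d; ++k) {
          x[k] = ref(j, k) - ref(i, k);
          r2 += x[k] * x[k];
        }
        double w = w_of_q(std::sqrt(r2) / h_e, sig);
        double g[3];
        for (int a = 0; a < d; ++a) {
          double s = 0.0;
          for (int k = 0; k < d; ++k) s += Ainv[a * d + k] * x[k];
          g[a] = s * w;
        }
        for (int a = 0; a < d; ++a) {
          double s_el = 0.0, s_vl = 0.0;
          for (int k = 0; k < d; ++k) {
            s_el += Js[a * d + k] * g[k];
            s_vl += C[a * d + k] * g[k];
          }
          f_el(j, a) += -2.0 * vol[i] * s_el;
          f_vol(j, a) += -cvol * s_vl;
        }
      }
    }
  }
  return List::create(_["grad_u"] = grad_u, _["strain"] = strain,
                      _["stress"] = stress, _["force_elastic"] = f_el,
                      _["force_volume"] = f_vol, _["d"] = dvec,
                      _["det_J"] = detJv, _["degenerate"] = degen,
                      _["energy_elastic"] = U_el, _["energy_volume"] = U_vol);
}

// Kernel splat of particle volumes onto a raster: S(x) = sum_j v_j W(x - x_j).
// [[Rcpp::export]]
NumericMatrix splat_field_cpp(NumericMatrix pos, NumericVector vol, double h,
                              double x0, double y0, double spacing, int nx,
                              int ny, int dim) {
  double sig = sigma_norm(h, dim);
  NumericMatrix out(ny, nx);  // row = y index, col = x index
  int reach = (int)std::ceil(2.0 * h / spacing) + 1;
  for (int p = 0; p < pos.nrow(); ++p) {
    int cx = (int)std::floor((pos(p, 0) - x0) / spacing);
    int cy = (int)std::floor((pos(p, 1) - y0) / spacing);
    for (int iy = std::max(0, cy - reach); iy <= std::min(ny - 1, cy + reach); ++iy)
      for (int ix = std::max(0, cx - reach); ix <= std::min(nx - 1, cx + reach); ++ix) {
        double dx = x0 + ix * spacing - pos(p, 0);
        double dy = y0 + iy * spacing - pos(p, 1);
        double r = std::sqrt(dx * dx + dy * dy);
        out(iy, ix) += vol[p] * w_of_q(r / h, sig);
      }
  }
  return out;
}

// Fused per-step force assembly for the multiphase scene. Phases: 1 = fluid,
// 2 = elastic, 3 = rigid. Fluid-fluid: EOS pressure + constant-viscosity
// forces (Mueller force densities, integrate with a = f/rho). Elastic pairs:
// rheological viscosity (same density form). Cross-phase: coupling forces
// (true forces). Returns updated fluid densities/pressures and the two
// accumulators.
// [[Rcpp::export]]
List scene_forces_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                      IntegerVector phase, NumericVector dens0, double h,
                      double rho0, double K, bool clamp_p, double mu_f,
                      double beta1, double beta2, double h_e, double Kc,
                      double ch, int dim) {
  int n = pos.nrow(), d = pos.ncol();
  double rmax = 2.0 * std::max(h, std::max(h_e, ch));
  double sig_h = sigma_norm(h, dim);
  double sig_e = sigma_norm(h_e, dim);
  double sig_c = sigma_norm(ch, dim);
  // grid
  std::unordered_map<CellKey, std::vector<int>, CellHash> grid;
  grid.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pos(i, 0) / rmax);
    int cy = (int)std::floor(pos(i, 1) / rmax);
    int cz = (d > 2) ? (int)std::floor(pos(i, 2) / rmax) : 0;
    grid[{pack_cell(cx, cy, cz)}].push_back(i);
  }
  std::vector<int> pa, pb;
  std::vector<double> pr2;
  pa.reserve(12 * n); pb.reserve(12 * n); pr2.reserve(12 * n);
  int zlo = (d > 2) ? -1 : 0, zhi = (d > 2) ? 1 : 0;
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pos(i, 0) / rmax);
    int cy = (int)std::floor(pos(i, 1) / rmax);
    int cz = (d > 2) ? (int)std::floor(pos(i, 2) / rmax) : 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = zlo; dz <= zhi; ++dz) {
          auto it = grid.find({pack_cell(cx + dx, cy + dy, cz + dz)});
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double s = 0.0;
            for (int k = 0; k < d; ++k) {
              double t = pos(i, k) - pos(j, k);
              s += t * t;
            }
            if (s < rmax2) { pa.push_back(i); pb.push_back(j); pr2.push_back(s); }
          }
        }
  }
  // fluid densities (fluid-fluid pairs + self term)
  NumericVector dens = clone(dens0);
  double w0h = w_of_q(0.0, sig_h);
  for (int i = 0; i < n; ++i) if (phase[i] == 1) dens[i] = mass[i] * w0h;
  for (size_t p = 0; p < pa.size(); ++p) {
    int i = pa[p], j = pb[p];
    if (phase[i] == 1 && phase[j] == 1) {
      double w = w_of_q(std::sqrt(pr2[p]) / h, sig_h);
      dens[i] += mass[j] * w;
      dens[j] += mass[i] * w;
    }
  }
  NumericVector pres(n);
  for (int i = 0; i < n; ++i) {
    if (phase[i] == 1) {
      double pv = K * (dens[i] - rho0);
      pres[i] = (clamp_p && pv < 0) ? 0.0 : pv;
    }
  }
  NumericMatrix F_sph(n, d), F_coup(n, d), F_press(n, d);
  for (size_t p = 0; p < pa.size(); ++p) {
    int i = pa[p], j = pb[p];
    int pi = phase[i], pj = phase[j];
    double r = std::sqrt(pr2[p]);
    if (r < 1e-12) continue;
    double rv[3];
    for (int k = 0; k < d; ++k) rv[k] = pos(i, k) - pos(j, k);
    if (pi == 1 && pj == 1) {
      if (r < 2.0 * h) {
        double q = r / h;
        double wr = dw_dq(q, sig_h) / h;
        double vbar = 0.5 * (mass[i] / dens[i] + mass[j] / dens[j]);
        double c = -0.5 * (pres[i] + pres[j]) * vbar * wr / r;
        double lap = d2w_dq2(q, sig_h) / (h * h) + (dim - 1) * (wr) / r;
        for (int k = 0; k < d; ++k) {
          double fp = c * rv[k];
          F_sph(i, k) += fp;
          F_sph(j, k) -= fp;
          F_press(i, k) += fp;
          F_press(j, k) -= fp;
          double dv = vel(j, k) - vel(i, k);
          F_sph(i, k) += mu_f * dv * (mass[j] / dens[j]) * lap;
          F_sph(j, k) += mu_f * (-dv) * (mass[i] / dens[i]) * lap;
        }
      }
    } else if (pi == 2 && pj == 2) {
      if (r < 2.0 * h_e && beta1 > 0) {
        double q = r / h_e;
        double wr = dw_dq(q, sig_e) / h_e;
        double lap = d2w_dq2(q, sig_e) / (h_e * h_e) + (dim - 1) * wr / r;
        double dv2 = 0.0, dot = 0.0;
        for (int k = 0; k < d; ++k) {
          double a = vel(i, k) - vel(j, k);
          dv2 += a * a; dot += a * rv[k];
        }
        double mu;
        double dvn = std::sqrt(dv2);
        if (dvn < 1e-12) mu = beta1;
        else {
          double c2 = (dot * dot) / (dv2 * pr2[p]);
          double base = 1.0 - c2 * dvn / r;
          if (base < 0.0) base = 0.0;
          if (base > 1.0) base = 1.0;
          mu = beta1 * std::pow(base, beta2);
        }
        for (int k = 0; k < d; ++k) {
          double dv = vel(j, k) - vel(i, k);
          F_sph(i, k) += mu * dv * (mass[j] / dens[j]) * lap;
          F_sph(j, k) += mu * (-dv) * (mass[i] / dens[i]) * lap;
        }
      }
    } else if (pi != pj) {
      if (r < 2.0 * ch && Kc > 0) {
        double wr = dw_dq(r / ch, sig_c) / ch;
        double c = -Kc * mass[i] * mass[j] * wr / r;
        for (int k = 0; k < d; ++k) {
          F_coup(i, k) += c * rv[k];
          F_coup(j, k) -= c * rv[k];
        }
      }
    }
  }
  return List::create(_["dens"] = dens, _["pres"] = pres,
                      _["F_sph"] = F_sph, _["F_coup"] = F_coup,
                      _["F_press"] = F_press);
}
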