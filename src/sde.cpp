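#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout shared with R/as_param_vector():
//  0 b, 1 p1, 2 p2, 3 P1, 4 P2, 5 hp, 6 X1, 7 X2, 8 hx,
//  9 s1, 10 s2, 11 S1, 12 S2, 13 hs, 14 Z1, 15 Z2, 16 hz,
// 17 A1, 18 A2, 19 ha, 20 R1, 21 R2, 22 hr, 23 U1, 24 U2, 25 hu,
// 26 dTF1, 27 dTF2

static inline double hact(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double xh = std::pow(x, h);
  return xh / (std::pow(K, h) + xh);
}

static inline double hinh(double x, double K, double h) {
  double Kh = std::pow(K, h);
  if (x <= 0.0) return 1.0;
  return Kh / (Kh + std::pow(x, h));
}

static inline void rhs(const double *x, const double *p,
                       double a1, double a2, double d1, double d2,
                       double apc1, double apc2, double sscale,
                       double *out) {
  double TF1 = x[0] > 0.0 ? x[0] : 0.0;
  double TF2 = x[1] > 0.0 ? x[1] : 0.0;
  double CY1 = x[2] > 0.0 ? x[2] : 0.0;
  double CY2 = x[3] > 0.0 ? x[3] : 0.0;
  double c1 = CY1 + apc1, c2 = CY2 + apc2;
  out[0] = (p[0] + p[1] * hact(TF1, p[3], p[5])) * hinh(TF2, p[7], p[8])
         + p[9] * hact(c1, p[11], p[13]) * hinh(c2, p[15], p[16])
         - p[26] * TF1;
  out[1] = (p[0] + p[2] * hact(TF2, p[4], p[5])) * hinh(TF1, p[6], p[8])
         + p[10] * hact(c2, p[12], p[13]) * hinh(c1, p[14], p[16])
         - p[27] * TF2;
  out[2] = sscale * a1 * hact(TF1, p[17], p[19]) * hinh(TF2, p[21], p[22])
         * hinh(c2, p[24], p[25]) - d1 * CY1;
  out[3] = sscale * a2 * hact(TF2, p[18], p[19]) * hinh(TF1, p[20], p[22])
         * hinh(c1, p[23], p[25]) - d2 * CY2;
}

// [[Rcpp::export]]
NumericVector drift_cpp(NumericVector state, NumericVector par,
                        double a1, double a2, double d1, double d2,
                        double apc1, double apc2, double secretion_scale) {
  NumericVector out(4);
  rhs(state.begin(), par.begin(), a1, a2, d1, d2, apc1, apc2,
      secretion_scale, out.begin());
  return out;
}

// Solve the 4x4 linear system J * step = -f in place (Gaussian elimination
// with partial pivoting).  Returns false when J is numerically singular.
static bool solve4(double J[4][4], const double f[4], double step[4]) {
  double A[4][5];
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) A[i][j] = J[i][j];
    A[i][4] = -f[i];
  }
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    for (int r = c + 1; r < 4; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
    if (std::fabs(A[piv][c]) < 1e-300) return false;
    if (piv != c) for (int j = c; j < 5; ++j) std::swap(A[piv][j], A[c][j]);
    for (int r = c + 1; r < 4; ++r) {
      double m = A[r][c] / A[c][c];
      for (int j = c; j < 5; ++j) A[r][j] -= m * A[c][j];
    }
  }
  for (int i = 3; i >= 0; --i) {
    double s = A[i][4];
    for (int j = i + 1; j < 4; ++j) s -= A[i][j] * step[j];
    step[i] = s / A[i][i];
  }
  return true;
}

// Damped Newton iteration (central-difference Jacobian, projection onto the
// non-negative orthant) from each row of `starts`.  Returns the terminal
// point, its normalized residual and a convergence flag per start.
// [[Rcpp::export]]
List newton_roots_cpp(NumericMatrix starts, NumericVector par,
                      double a1, double a2, double d1, double d2,
                      double apc1, double apc2, double secretion_scale,
                      double tol, int max_iter) {
  int n = starts.nrow();
  NumericMatrix roots(n, 4);
  NumericVector residual(n);
  LogicalVector converged(n);
  const double *p = par.begin();
  double x[4], f[4], fn[4], xn[4], J[4][4], step[4], up[4], dn[4],
         fu[4], fd[4];
  for (int s = 0; s < n; ++s) {
    for (int k = 0; k < 4; ++k) x[k] = starts(s, k) > 0 ? starts(s, k) : 0;
    rhs(x, p, a1, a2, d1, d2, apc1, apc2, secretion_scale, f);
    bool ok = false;
    double res = 0;
    for (int it = 0; it < max_iter; ++it) {
      double xmax = 0, fmax = 0;
      for (int k = 0; k < 4; ++k) {
        if (std::fabs(x[k]) > xmax) xmax = std::fabs(x[k]);
        if (std::fabs(f[k]) > fmax) fmax = std::fabs(f[k]);
      }
      res = fmax / (1 + xmax);
      if (res < tol) { ok = true; break; }
      for (int j = 0; j < 4; ++j) {
        double h = 1e-7 * (std::fabs(x[j]) > 1e-3 ? std::fabs(x[j]) : 1e-3);
        for (int k = 0; k < 4; ++k) { up[k] = x[k]; dn[k] = x[k]; }
        up[j] = x[j] + h;
        dn[j] = x[j] - h > 0 ? x[j] - h : 0;
        rhs(up, p, a1, a2, d1, d2, apc1, apc2, secretion_scale, fu);
        rhs(dn, p, a1, a2, d1, d2, apc1, apc2, secretion_scale, fd);
        for (int k = 0; k < 4; ++k) J[k][j] = (fu[k] - fd[k]) / (up[j] - dn[j]);
      }
      if (!solve4(J, f, step)) break;
      double fnorm = 0;
      for (int k = 0; k < 4; ++k)
        if (std::fabs(f[k]) > fnorm) fnorm = std::fabs(f[k]);
      double lam = 1.0;
      for (int ls = 0; ls < 9; ++ls) {
        for (int k = 0; k < 4; ++k) {
          xn[k] = x[k] + lam * step[k];
          if (xn[k] < 0) xn[k] = 0;
        }
        rhs(xn, p, a1, a2, d1, d2, apc1, apc2, secretion_scale, fn);
        double fnew = 0;
        for (int k = 0; k < 4; ++k)
          if (std::fabs(fn[k]) > fnew) fnew = std::fabs(fn[k]);
        if (fnew < fnorm || lam < 1.0 / 256) break;
        lam /= 2;
      }
      bool moved = false;
      for (int k = 0; k < 4; ++k) {
        if (xn[k] != x[k]) moved = true;
        x[k] = xn[k]; f[k] = fn[k];
      }
      if (!moved) break;
    }
    for (int k = 0; k < 4; ++k) roots(s, k) = x[k];
    residual[s] = res;
    converged[s] = ok;
  }
  return List::create(_["roots"] = roots, _["residual"] = residual,
                      _["converged"] = converged);
}

// Euler-Maruyama path with piecewise-constant APC instruction.
// sched: rows (t_start, apc1, apc2), t_start ascending, first row at 0.
// noise: n_steps x 4 standard normal draws (drawn in R for reproducibility).
// States are clamped at zero after each step (multiplicative noise vanishes
// at zero, so zero is the natural reflecting/absorbing boundary).
// [[Rcpp::export]]
List em_path_cpp(NumericVector init, NumericVector par,
                 double a1, double a2, double d1, double d2,
                 NumericMatrix sched, double secretion_scale,
                 double dt, int n_steps, int record_every,
                 NumericMatrix noise, NumericVector nvol) {
  int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 4);
  double x[4], f[4];
  for (int k = 0; k < 4; ++k) { x[k] = init[k]; out(0, k) = x[k]; }
  double sqdt = std::sqrt(dt);
  int seg = 0, n_seg = sched.nrow(), rec = 1;
  bool noisy = noise.nrow() > 0;
  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    while (seg + 1 < n_seg && t >= sched(seg + 1, 0) - 1e-12) ++seg;
    rhs(x, par.begin(), a1, a2, d1, d2, sched(seg, 1), sched(seg, 2),
        secretion_scale, f);
    for (int k = 0; k < 4; ++k) {
      double xn = x[k] + f[k] * dt;
      if (noisy) xn += nvol[k] * x[k] * sqdt * noise(i, k);
      x[k] = xn > 0.0 ? xn : 0.0;
    }
    double nrm = x[0] + x[1] + x[2] + x[3];
    if (!std::isfinite(nrm) || nrm > 1e12) {
      return List::create(_["states"] = out, _["exploded"] = true,
                          _["step"] = i + 1);
    }
    if ((i + 1) % record_every == 0) {
      for (int k = 0; k < 4; ++k) out(rec, k) = x[k];
      ++rec;
    }
  }
  return List::create(_["states"] = out, _["exploded"] = false,
                      _["step"] = n_steps);
}
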