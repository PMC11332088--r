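// Joint log-density (with analytic gradient) and a No-U-Turn sampler for the
// multiplex social relations model.
//
// Unconstrained parameter layout (has_re == 1):
//   eta      [M]            per-layer intercepts
//   lambda   [P*M]          covariate coefficients, column-major P x M
//   ls       [K]  K = 2M    log generalized-effect scales sigma
//   lv       [M]            log free dyadic scales varsigma (tied: full
//                           scale vector is rep(varsigma, 2))
//   yL       [T]  T=K(K-1)/2 unconstrained Cholesky corr factor (generalized)
//   yG       [T]            unconstrained Cholesky corr factor (dyadic)
//   zg       [J*K]          raw generalized effects, column-major J x K
//   zd       [D*K]          raw dyadic effects, column-major D x K
// With has_re == 0 only eta and lambda are present (intercept-only model).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double HALF_LOG_2PI = 0.9189385332046727;

struct Ctx {
  int J, M, K, D, P, N, T, has_re, dim;
  const int *s, *r, *l, *y, *d, *slot;
  const double *X; // N x P column-major (may be null when P == 0)
  double scale_rate, lkj_eta, eps_pen, eta_sd;
};

static Ctx make_ctx(List data) {
  Ctx c;
  c.J = as<int>(data["J"]);
  c.M = as<int>(data["M"]);
  c.D = as<int>(data["D"]);
  c.P = as<int>(data["P"]);
  c.has_re = as<int>(data["has_re"]);
  c.K = 2 * c.M;
  c.T = c.K * (c.K - 1) / 2;
  IntegerVector s = data["obs_s"], r = data["obs_r"], l = data["obs_l"],
                y = data["obs_y"], d = data["obs_d"], sl = data["obs_slot"];
  c.N = s.size();
  c.s = INTEGER(s); c.r = INTEGER(r); c.l = INTEGER(l);
  c.y = INTEGER(y); c.d = INTEGER(d); c.slot = INTEGER(sl);
  NumericMatrix X = data["X"];
  c.X = (c.P > 0) ? REAL(X) : nullptr;
  c.scale_rate = as<double>(data["scale_rate"]);
  c.lkj_eta = as<double>(data["lkj_eta"]);
  c.eps_pen = as<double>(data["epsilon"]);
  c.eta_sd = as<double>(data["eta_sd"]);
  c.dim = c.has_re
    ? c.M + c.P * c.M + c.K + c.M + 2 * c.T + (c.J + c.D) * c.K
    : c.M + c.P * c.M;
  return c;
}

// Forward construction of a Cholesky correlation factor from unconstrained y
// via tanh canonical partial correlations. Returns the log-density
// contribution: unnormalized LKJ(eta) on L, plus (optionally) the
// log-Jacobian of the y -> L transform. L is K x K column-major.
static double chol_forward(const double *yv, int K, double lkj_eta,
                           bool jacobian, std::vector<double> &L,
                           std::vector<double> &z) {
  std::fill(L.begin(), L.end(), 0.0);
  L[0] = 1.0;
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double s = 1.0;
    for (int j = 0; j < i; ++j, ++idx) {
      double zz = std::tanh(yv[idx]);
      z[idx] = zz;
      double w = std::sqrt(s);
      double Lij = zz * w;
      L[i + j * K] = Lij;
      if (jacobian) lp += std::log1p(-zz * zz) + 0.5 * std::log(s);
      s -= Lij * Lij;
      if (s < 1e-14) s = 1e-14;
    }
    double Lii = std::sqrt(s);
    L[i + i * K] = Lii;
    lp += (K - (i + 1) + 2.0 * lkj_eta - 2.0) * std::log(Lii);
  }
  return lp;
}

// Reverse-mode through chol_forward. dL holds adjoints of L on entry
// (the LKJ diagonal term is added here); writes adjoints of y into dy.
static void chol_backward(const std::vector<double> &L,
                          const std::vector<double> &z, int K,
                          double lkj_eta, bool jacobian,
                          std::vector<double> &dL, const double *yv,
                          double *dy) {
  int idx_row_start = 0;
  for (int i = 1; i < K; ++i) {
    // recompute the s sequence for this row
    std::vector<double> sseq(i + 1);
    sseq[0] = 1.0;
    for (int j = 0; j < i; ++j) {
      double Lij = L[i + j * K];
      sseq[j + 1] = sseq[j] - Lij * Lij;
      if (sseq[j + 1] < 1e-14) sseq[j + 1] = 1e-14;
    }
    double Lii = L[i + i * K];
    double aLii = dL[i + i * K] + (K - (i + 1) + 2.0 * lkj_eta - 2.0) / Lii;
    double ds = aLii * 0.5 / Lii; // adjoint of s_i  (Lii = sqrt(s_i))
    for (int j = i - 1; j >= 0; --j) {
      int idx = idx_row_start + j;
      double zz = z[idx];
      double sj = sseq[j];
      double w = std::sqrt(sj);
      double Lij = L[i + j * K];
      double dLij = dL[i + j * K] - 2.0 * Lij * ds; // ext + via s_{j+1}
      double dsj = ds;                              // pass-through
      if (jacobian) dsj += 0.5 / sj;
      double dz = dLij * w;
      if (jacobian) dz += -2.0 * zz / (1.0 - zz * zz);
      dsj += dLij * zz * 0.5 / w;
      dy[idx] = dz * (1.0 - zz * zz); // tanh chain rule
      ds = dsj;
    }
    idx_row_start += i;
  }
}

// Joint log-density and gradient on the unconstrained scale.
static double lp_grad(const Ctx &c, const double *q, double *grad,
                      bool jacobian) {
  const int M = c.M, K = c.K, J = c.J, D = c.D, P = c.P, T = c.T;
  std::fill(grad, grad + c.dim, 0.0);
  double lp = 0.0;

  const double *eta = q;
  const double *lam = q + M; // P x M
  double *deta = grad;
  double *dlam = grad + M;

  // --- intercept / coefficient priors: Normal(0, eta_sd)
  double inv_eta_var = 1.0 / (c.eta_sd * c.eta_sd);
  for (int m = 0; m < M; ++m) {
    lp += -0.5 * eta[m] * eta[m] * inv_eta_var - std::log(c.eta_sd)
          - HALF_LOG_2PI;
    deta[m] += -eta[m] * inv_eta_var;
  }
  for (int p = 0; p < P * M; ++p) {
    lp += -0.5 * lam[p] * lam[p] * inv_eta_var - std::log(c.eta_sd)
          - HALF_LOG_2PI;
    dlam[p] += -lam[p] * inv_eta_var;
  }

  if (!c.has_re) {
    // intercept-only likelihood
    for (int n = 0; n < c.N; ++n) {
      int m = c.l[n];
      double th = eta[m];
      for (int p = 0; p < P; ++p) th += lam[p + m * P] * c.X[n + p * c.N];
      double lse = (th > 0) ? th + std::log1p(std::exp(-th))
                            : std::log1p(std::exp(th));
      lp += c.y[n] * th - lse;
      double g = c.y[n] - 1.0 / (1.0 + std::exp(-th));
      deta[m] += g;
      for (int p = 0; p < P; ++p) dlam[p + m * P] += g * c.X[n + p * c.N];
    }
    return lp;
  }

  const double *ls = q + M + P * M;
  const double *lv = ls + K;
  const double *yL = lv + M;
  const double *yG = yL + T;
  const double *zg = yG + T; // J x K
  const double *zd = zg + J * K; // D x K
  double *dls = grad + M + P * M;
  double *dlv = dls + K;
  double *dyL = dlv + M;
  double *dyG = dyL + T;
  double *dzg = dyG + T;
  double *dzd = dzg + J * K;

  std::vector<double> sigma(K), vsfull(K);
  for (int k = 0; k < K; ++k) sigma[k] = std::exp(ls[k]);
  for (int k = 0; k < K; ++k) vsfull[k] = std::exp(lv[k % M]);

  // --- correlation Cholesky factors
  std::vector<double> Lg(K * K), zLg(T), Gd(K * K), zGd(T);
  lp += chol_forward(yL, K, c.lkj_eta, jacobian, Lg, zLg);
  lp += chol_forward(yG, K, c.lkj_eta, jacobian, Gd, zGd);

  // --- non-centered transforms: U = Z L', V = U * sigma (columnwise)
  std::vector<double> Ug(J * K), Uw(D * K);
  for (int cK = 0; cK < K; ++cK) {
    for (int j = 0; j < J; ++j) {
      double acc = 0.0;
      for (int k = 0; k <= cK; ++k) acc += zg[j + k * J] * Lg[cK + k * K];
      Ug[j + cK * J] = acc;
    }
    for (int dd = 0; dd < D; ++dd) {
      double acc = 0.0;
      for (int k = 0; k <= cK; ++k) acc += zd[dd + k * D] * Gd[cK + k * K];
      Uw[dd + cK * D] = acc;
    }
  }

  // --- likelihood
  std::vector<double> GV(J * K, 0.0), GW(D * K, 0.0);
  for (int n = 0; n < c.N; ++n) {
    int sj = c.s[n], rk = c.r[n], m = c.l[n], dd = c.d[n], sl = c.slot[n];
    double th = eta[m] + sigma[m] * Ug[sj + m * J]
              + sigma[M + m] * Ug[rk + (M + m) * J]
              + vsfull[sl] * Uw[dd + sl * D];
    for (int p = 0; p < P; ++p) th += lam[p + m * P] * c.X[n + p * c.N];
    double lse = (th > 0) ? th + std::log1p(std::exp(-th))
                          : std::log1p(std::exp(th));
    lp += c.y[n] * th - lse;
    double g = c.y[n] - 1.0 / (1.0 + std::exp(-th));
    deta[m] += g;
    for (int p = 0; p < P; ++p) dlam[p + m * P] += g * c.X[n + p * c.N];
    GV[sj + m * J] += g;            // adjoint of V(s, m)
    GV[rk + (M + m) * J] += g;      // adjoint of V(r, M+m)
    GW[dd + sl * D] += g;           // adjoint of W(d, slot)
  }

  // --- raw-effect priors: Normal(0, 1)
  for (int i = 0; i < J * K; ++i) {
    lp += -0.5 * zg[i] * zg[i] - HALF_LOG_2PI;
    dzg[i] += -zg[i];
  }
  for (int i = 0; i < D * K; ++i) {
    lp += -0.5 * zd[i] * zd[i] - HALF_LOG_2PI;
    dzd[i] += -zd[i];
  }

  // --- backprop generalized block: V(.,k) = sigma[k] * U(.,k)
  std::vector<double> dLg(K * K, 0.0), dGd(K * K, 0.0);
  for (int cK = 0; cK < K; ++cK) {
    double dsig = 0.0;
    for (int j = 0; j < J; ++j) {
      double gv = GV[j + cK * J];
      dsig += gv * Ug[j + cK * J];
      double dU = gv * sigma[cK];
      for (int k = 0; k <= cK; ++k) {
        dzg[j + k * J] += dU * Lg[cK + k * K];
        dLg[cK + k * K] += dU * zg[j + k * J];
      }
    }
    // Exponential(rate) prior on sigma, plus log-Jacobian of exp
    lp += std::log(c.scale_rate) - c.scale_rate * sigma[cK];
    if (jacobian) lp += ls[cK];
    dls[cK] = (dsig - c.scale_rate) * sigma[cK] + (jacobian ? 1.0 : 0.0);
  }

  // --- backprop dyadic block (tied scales)
  std::vector<double> dvs(K, 0.0);
  for (int cK = 0; cK < K; ++cK) {
    double dv = 0.0;
    for (int dd = 0; dd < D; ++dd) {
      double gw = GW[dd + cK * D];
      dv += gw * Uw[dd + cK * D];
      double dU = gw * vsfull[cK];
      for (int k = 0; k <= cK; ++k) {
        dzd[dd + k * D] += dU * Gd[cK + k * K];
        dGd[cK + k * K] += dU * zd[dd + k * D];
      }
    }
    dvs[cK] = dv;
  }
  for (int m = 0; m < M; ++m) {
    double vs = vsfull[m];
    lp += std::log(c.scale_rate) - c.scale_rate * vs; // M free scales only
    if (jacobian) lp += lv[m];
    dlv[m] = (dvs[m] + dvs[M + m] - c.scale_rate) * vs
             + (jacobian ? 1.0 : 0.0);
  }

  // --- block-symmetry penalty on rho = Gd Gd'
  if (M >= 2) {
    std::vector<double> rho(K * K, 0.0), Arho(K * K, 0.0);
    for (int a = 0; a < K; ++a)
      for (int b = 0; b <= a; ++b) {
        double acc = 0.0;
        for (int k = 0; k <= b; ++k) acc += Gd[a + k * K] * Gd[b + k * K];
        rho[a + b * K] = acc;
        rho[b + a * K] = acc;
      }
    double inv_e2 = 1.0 / (c.eps_pen * c.eps_pen);
    for (int m = 0; m < M - 1; ++m)
      for (int n = m + 1; n < M; ++n) {
        double d1 = rho[(m + M) + (n + M) * K] - rho[m + n * K];
        double d2 = rho[m + (n + M) * K] - rho[n + (m + M) * K];
        lp += -0.5 * d1 * d1 * inv_e2 - std::log(c.eps_pen) - HALF_LOG_2PI;
        lp += -0.5 * d2 * d2 * inv_e2 - std::log(c.eps_pen) - HALF_LOG_2PI;
        Arho[(m + M) + (n + M) * K] += -d1 * inv_e2;
        Arho[m + n * K] += d1 * inv_e2;
        Arho[m + (n + M) * K] += -d2 * inv_e2;
        Arho[n + (m + M) * K] += d2 * inv_e2;
      }
    // dGd += (Arho + Arho') Gd
    for (int a = 0; a < K; ++a)
      for (int k = 0; k <= a; ++k) {
        double acc = 0.0;
        for (int b = 0; b < K; ++b)
          acc += (Arho[a + b * K] + Arho[b + a * K]) * Gd[b + k * K];
        dGd[a + k * K] += acc;
      }
  }

  // --- backprop the Cholesky constructions
  chol_backward(Lg, zLg, K, c.lkj_eta, jacobian, dLg, yL, dyL);
  chol_backward(Gd, zGd, K, c.lkj_eta, jacobian, dGd, yG, dyG);

  return lp;
}

//' @noRd
// [[Rcpp::export(name = ".srm_lp_grad")]]
List srm_lp_grad_cpp(NumericVector par, List data, bool jacobian = true) {
  Ctx c = make_ctx(data);
  if ((int)par.size() != c.dim)
    stop("parameter vector has length %d, expected %d", (int)par.size(), c.dim);
  NumericVector grad(c.dim);
  double lp = lp_grad(c, REAL(par), REAL(grad), jacobian);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

//' @noRd
// [[Rcpp::export(name = ".srm_chol_from_y")]]
NumericMatrix srm_chol_from_y(NumericVector y, int K) {
  if ((int)y.size() != K * (K - 1) / 2) stop("wrong length for 'y'");
  std::vector<double> L(K * K), z(y.size());
  chol_forward(REAL(y), K, 1.0, false, L, z);
  NumericMatrix out(K, K);
  std::copy(L.begin(), L.end(), out.begin());
  return out;
}


// ---------------- No-U-Turn sampler ----------------
//
// Multinomial-weighted variant is not used; this is the classic
// slice-sampling NUTS with dual-averaging step-size adaptation and a
// diagonal mass matrix estimated from a single warmup window.

struct TreeState {
  std::vector<double> qm, pm, gm; double lpm; // backward end
  std::vector<double> qp, pp, gp; double lpp; // forward end
  std::vector<double> qprop;                  // proposal drawn from subtree
  double n;       // slice-accepted states in subtree
  bool s;         // subtree still valid
  bool diverged;
  double alpha;   // accept-statistic accumulator
  int nalpha;
};

struct Sampler {
  const Ctx &c;
  std::vector<double> minv; // diagonal inverse mass (posterior variances)
  double eps;
  int max_depth;
  long n_grad;

  Sampler(const Ctx &ctx) : c(ctx), minv(ctx.dim, 1.0), eps(0.1),
                            max_depth(10), n_grad(0) {}

  double logdens(const std::vector<double> &q, std::vector<double> &g) {
    ++n_grad;
    return lp_grad(c, q.data(), g.data(), true);
  }

  // one leapfrog step, in place; returns new log-density
  double leapfrog(std::vector<double> &q, std::vector<double> &p,
                  std::vector<double> &g, double direction) {
    double e = direction * eps;
    for (int i = 0; i < c.dim; ++i) p[i] += 0.5 * e * g[i];
    for (int i = 0; i < c.dim; ++i) q[i] += e * minv[i] * p[i];
    double lp = logdens(q, g);
    for (int i = 0; i < c.dim; ++i) p[i] += 0.5 * e * g[i];
    return lp;
  }

  double kinetic(const std::vector<double> &p) {
    double k = 0.0;
    for (int i = 0; i < c.dim; ++i) k += p[i] * p[i] * minv[i];
    return 0.5 * k;
  }

  void sample_momentum(std::vector<double> &p) {
    for (int i = 0; i < c.dim; ++i) p[i] = norm_rand() / std::sqrt(minv[i]);
  }

  bool no_uturn(const std::vector<double> &qm, const std::vector<double> &qp,
                const std::vector<double> &pm, const std::vector<double> &pp) {
    double a = 0.0, b = 0.0;
    for (int i = 0; i < c.dim; ++i) {
      double dq = qp[i] - qm[i];
      a += dq * minv[i] * pm[i];
      b += dq * minv[i] * pp[i];
    }
    return a >= 0.0 && b >= 0.0;
  }

  void build_tree(const std::vector<double> &q, const std::vector<double> &p,
                  const std::vector<double> &g, double lp, double logu,
                  int dir, int depth, double H0, TreeState &out) {
    if (depth == 0) {
      std::vector<double> q1 = q, p1 = p, g1 = g;
      double lp1 = leapfrog(q1, p1, g1, (double)dir);
      double H = lp1 - kinetic(p1);
      bool div = !std::isfinite(H) || (H0 - H) > 1000.0;
      out.qm = q1; out.pm = p1; out.gm = g1; out.lpm = lp1;
      out.qp = q1; out.pp = p1; out.gp = g1; out.lpp = lp1;
      out.qprop = q1;
      out.n = (!div && logu <= H) ? 1.0 : 0.0;
      out.s = !div;
      out.diverged = div;
      double a = std::exp(std::min(0.0, H - H0));
      out.alpha = std::isfinite(a) ? a : 0.0;
      out.nalpha = 1;
      return;
    }
    TreeState first;
    build_tree(q, p, g, lp, logu, dir, depth - 1, H0, first);
    out = first;
    if (!first.s) return;
    TreeState second;
    if (dir == -1)
      build_tree(first.qm, first.pm, first.gm, first.lpm, logu, dir,
                 depth - 1, H0, second);
    else
      build_tree(first.qp, first.pp, first.gp, first.lpp, logu, dir,
                 depth - 1, H0, second);
    if (dir == -1) {
      out.qm = second.qm; out.pm = second.pm; out.gm = second.gm;
      out.lpm = second.lpm;
    } else {
      out.qp = second.qp; out.pp = second.pp; out.gp = second.gp;
      out.lpp = second.lpp;
    }
    double ntot = first.n + second.n;
    if (second.n > 0.0 && unif_rand() * ntot < second.n)
      out.qprop = second.qprop;
    out.n = ntot;
    out.diverged = first.diverged || second.diverged;
    out.s = second.s && no_uturn(out.qm, out.qp, out.pm, out.pp);
    out.alpha = first.alpha + second.alpha;
    out.nalpha = first.nalpha + second.nalpha;
  }

  // one NUTS transition; returns accept statistic, updates q/g/lp in place
  double transition(std::vector<double> &q, std::vector<double> &g,
                    double &lp, int &depth_used, bool &diverged) {
    std::vector<double> p(c.dim);
    sample_momentum(p);
    double H0 = lp - kinetic(p);
    double logu = H0 - exp_rand(); // log of u ~ U(0, exp(H0))
    TreeState state;
    state.qm = q; state.pm = p; state.gm = g; state.lpm = lp;
    state.qp = q; state.pp = p; state.gp = g; state.lpp = lp;
    state.qprop = q;
    state.n = 1.0; state.s = true; state.diverged = false;
    double alpha = 0.0; int nalpha = 0;
    int depth = 0;
    while (state.s && depth < max_depth) {
      int dir = (unif_rand() < 0.5) ? -1 : 1;
      TreeState sub;
      if (dir == -1)
        build_tree(state.qm, state.pm, state.gm, state.lpm, logu, dir, depth,
                   H0, sub);
      else
        build_tree(state.qp, state.pp, state.gp, state.lpp, logu, dir, depth,
                   H0, sub);
      alpha = sub.alpha; nalpha = sub.nalpha;
      if (sub.s && sub.n > 0.0 && unif_rand() * state.n < sub.n)
        state.qprop = sub.qprop;
      if (dir == -1) {
        state.qm = sub.qm; state.pm = sub.pm; state.gm = sub.gm;
        state.lpm = sub.lpm;
      } else {
        state.qp = sub.qp; state.pp = sub.pp; state.gp = sub.gp;
        state.lpp = sub.lpp;
      }
      state.n += sub.n;
      state.diverged = state.diverged || sub.diverged;
      if (!sub.s || !no_uturn(state.qm, state.qp, state.pm, state.pp)) break;
      ++depth;
    }
    depth_used = depth;
    diverged = state.diverged;
    if (state.qprop != q) {
      q = state.qprop;
      lp = logdens(q, g);
    }
    return (nalpha > 0) ? alpha / nalpha : 0.0;
  }

  double find_initial_eps(const std::vector<double> &q0,
                          const std::vector<double> &g0, double lp0) {
    eps = 1.0;
    std::vector<double> p(c.dim);
    sample_momentum(p);
    double H0 = lp0 - kinetic(p);
    std::vector<double> q = q0, pp = p, g = g0;
    double lp1 = leapfrog(q, pp, g, 1.0);
    double H1 = lp1 - kinetic(pp);
    double a = (std::isfinite(H1 - H0) && (H1 - H0) > std::log(0.5)) ? 1.0
                                                                     : -1.0;
    for (int it = 0; it < 50; ++it) {
      q = q0; pp = p; g = g0;
      lp1 = leapfrog(q, pp, g, 1.0);
      H1 = lp1 - kinetic(pp);
      double dH = std::isfinite(H1 - H0) ? H1 - H0 : -1e10;
      if (a * dH <= a * std::log(0.5)) break;
      eps *= std::pow(2.0, a);
      if (eps < 1e-10 || eps > 1e7) break;
    }
    return eps;
  }
};

//' @noRd
// [[Rcpp::export(name = ".srm_nuts")]]
List srm_nuts_cpp(List data, NumericVector init, int warmup, int iter,
                  double adapt_delta, int max_depth, int refresh,
                  int chain_id) {
  Ctx c = make_ctx(data);
  if ((int)init.size() != c.dim)
    stop("init has length %d, expected %d", (int)init.size(), c.dim);
  Sampler smp(c);
  smp.max_depth = max_depth;

  std::vector<double> q(init.begin(), init.end()), g(c.dim);
  double lp = smp.logdens(q, g);
  if (!std::isfinite(lp))
    stop("log-density is not finite at the initial values (lp = %f)", lp);

  // dual-averaging state
  smp.find_initial_eps(q, g, lp);
  double mu = std::log(10.0 * smp.eps);
  double logeps = std::log(smp.eps), logeps_bar = 0.0, hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // single variance-estimation window for the diagonal mass matrix
  int win_lo = (int)(0.25 * warmup), win_hi = (int)(0.70 * warmup);
  std::vector<double> wmean(c.dim, 0.0), wm2(c.dim, 0.0);
  long wn = 0;

  int total = warmup + iter;
  NumericMatrix draws(iter, c.dim);
  NumericVector lp_out(iter), accept_out(iter);
  IntegerVector depth_out(iter), div_out(iter);
  int n_div_warmup = 0;

  for (int it = 0; it < total; ++it) {
    if (it % 20 == 0) Rcpp::checkUserInterrupt();
    if (refresh > 0 && (it % refresh == 0 || it == total - 1))
      Rcout << "chain " << chain_id << "  iter " << (it + 1) << " / " << total
            << (it < warmup ? "  (warmup)" : "  (sampling)")
            << "  step size " << smp.eps << std::endl;
    int depth_used = 0; bool diverged = false;
    double alpha = smp.transition(q, g, lp, depth_used, diverged);

    if (it < warmup) {
      if (diverged) ++n_div_warmup;
      // dual averaging towards the target acceptance statistic
      ++da_count;
      double eta_t = 1.0 / (da_count + t0);
      hbar = (1.0 - eta_t) * hbar + eta_t * (adapt_delta - alpha);
      logeps = mu - std::sqrt((double)da_count) / gamma * hbar;
      double xi = std::pow((double)da_count, -kappa);
      logeps_bar = xi * logeps + (1.0 - xi) * logeps_bar;
      smp.eps = std::exp(logeps);

      if (it >= win_lo && it < win_hi) {
        ++wn;
        for (int i = 0; i < c.dim; ++i) {
          double d = q[i] - wmean[i];
          wmean[i] += d / wn;
          wm2[i] += d * (q[i] - wmean[i]);
        }
      }
      if (it == win_hi - 1 && wn > 10) {
        double shrink = (double)wn / (wn + 5.0);
        for (int i = 0; i < c.dim; ++i)
          smp.minv[i] = shrink * (wm2[i] / (wn - 1)) +
                        (1.0 - shrink) * 1e-3;
        // restart step-size adaptation under the new metric
        smp.find_initial_eps(q, g, lp);
        mu = std::log(10.0 * smp.eps);
        logeps = std::log(smp.eps); logeps_bar = 0.0; hbar = 0.0;
        da_count = 0;
      }
      if (it == warmup - 1) smp.eps = std::exp(logeps_bar);
    } else {
      int k = it - warmup;
      for (int i = 0; i < c.dim; ++i) draws(k, i) = q[i];
      lp_out[k] = lp;
      accept_out[k] = alpha;
      depth_out[k] = depth_used;
      div_out[k] = diverged ? 1 : 0;
    }
  }

  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["accept_stat"] = accept_out,
                      _["treedepth"] = depth_out,
                      _["divergent"] = div_out,
                      _["step_size"] = smp.eps,
                      _["inv_mass"] = NumericVector(smp.minv.begin(),
                                                    smp.minv.end()),
                      _["n_grad"] = (double)smp.n_grad,
                      _["warmup_divergences"] = n_div_warmup);
}
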