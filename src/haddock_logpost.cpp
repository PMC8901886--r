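// Joint log-posterior of the haddock life-cycle state-space model in the
// non-centred parameterization: theta = [mapped parameters, recruitment
// innovations u_rec (Y), effort increments u_eff (Y-1)].  The forward
// recursion mirrors simulate_haddock() in R/haddock.R exactly; an R
// implementation of the same density is kept in the test suite as a
// cross-check.  The adaptive Metropolis-within-Gibbs chain runner lives
// here too: the density is evaluated hundreds of thousands of times per
// fit, so the model list is parsed once per chain and the sweep loop
// stays in compiled code, drawing from R's RNG so a set.seed() in R
// makes runs reproducible.
#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// parameter ids of the estimation map (keep in step with R/inference.R)
enum ParamId {
  P_PHI = 1, P_TPHI, P_ME, P_SIGPHI, P_MA, P_M4, P_G, P_D, P_F,
  P_SIGF, P_Q, P_SIGL, P_SIGI, P_SIGXI, P_E0
};

struct HadModel {
  int A, Y, fished_min;
  bool catchM_age, plus_group, est_u_rec, est_u_eff;
  std::vector<double> W, P, T, G, logI, logL, n_init; // matrices A x Y, col-major
  std::vector<int> ages;
  double phi, T_phi, m_e, sigma_phi, M4, sigma_F, sigma_xi, e0;
  std::vector<double> m_a, g, D, f, q, sigL, sigI;
  std::vector<int> has_m, has_g, has_D, surveyed, landed;
  std::vector<int> map_ti, map_id, map_row;          // estimation map rows
  std::vector<double> pr_fam, pr_p1, pr_p2, pr_tr;   // priors per theta entry
  std::vector<double> u_rec0, u_eff0;
  int n_theta, n_dim;
};

static std::vector<double> as_vec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}
static std::vector<int> as_ivec_logical(SEXP x) {
  LogicalVector v(x);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] == TRUE;
  return out;
}

static HadModel parse_model(List m) {
  HadModel M;
  M.A = as<int>(m["A"]);
  M.Y = as<int>(m["Y"]);
  M.fished_min = as<int>(m["fished_min_age"]);
  M.catchM_age = as<bool>(m["catch_M_age_specific"]);
  M.plus_group = as<bool>(m["plus_group"]);
  M.est_u_rec = as<bool>(m["est_u_rec"]);
  M.est_u_eff = as<bool>(m["est_u_eff"]);
  M.W = as_vec(m["W"]);
  M.P = as_vec(m["P"]);
  M.T = as_vec(m["T"]);
  M.G = as_vec(m["G"]);
  M.logI = as_vec(m["logI"]);
  M.logL = as_vec(m["logL"]);
  M.n_init = as_vec(m["n_init"]);
  IntegerVector a = m["ages"];
  M.ages.assign(a.begin(), a.end());
  M.phi = as<double>(m["phi"]);
  M.T_phi = as<double>(m["T_phi"]);
  M.m_e = as<double>(m["m_e"]);
  M.sigma_phi = as<double>(m["sigma_phi"]);
  M.M4 = as<double>(m["M4plus"]);
  M.sigma_F = as<double>(m["sigma_F"]);
  M.sigma_xi = as<double>(m["sigma_xi"]);
  M.e0 = as<double>(m["e0"]);
  M.m_a = as_vec(m["m_a"]);
  M.g = as_vec(m["g"]);
  M.D = as_vec(m["D"]);
  M.f = as_vec(m["f"]);
  M.q = as_vec(m["q"]);
  M.sigL = as_vec(m["sigma_L"]);
  M.sigI = as_vec(m["sigma_I"]);
  M.has_m = as_ivec_logical(m["has_m"]);
  M.has_g = as_ivec_logical(m["has_g"]);
  M.has_D = as_ivec_logical(m["has_D"]);
  M.surveyed = as_ivec_logical(m["surveyed"]);
  M.landed = as_ivec_logical(m["landed"]);
  IntegerMatrix map = m["map"];
  for (int k = 0; k < map.nrow(); ++k) {
    M.map_ti.push_back(map(k, 0));
    M.map_id.push_back(map(k, 1));
    M.map_row.push_back(map(k, 2));
  }
  NumericMatrix prior = m["prior"];
  M.n_theta = prior.nrow();
  for (int k = 0; k < M.n_theta; ++k) {
    M.pr_fam.push_back(prior(k, 0));
    M.pr_p1.push_back(prior(k, 1));
    M.pr_p2.push_back(prior(k, 2));
    M.pr_tr.push_back(prior(k, 3));
  }
  M.u_rec0 = as_vec(m["u_rec0"]);
  M.u_eff0 = as_vec(m["u_eff0"]);
  M.n_dim = M.n_theta + (M.est_u_rec ? M.Y : 0) + (M.est_u_eff ? M.Y - 1 : 0);
  return M;
}

// the joint density; scratch buffers are passed in to avoid per-call allocation
struct Scratch {
  std::vector<double> phi_y, e, delta, N, Mm, Fm, u_rec, u_eff;
  void size(const HadModel &M) {
    phi_y.resize(M.Y);
    e.resize(M.Y);
    delta.resize(M.A);
    N.assign(M.A * M.Y, 0.0);
    Mm.resize(M.A * M.Y);
    Fm.resize(M.A * M.Y);
    u_rec.resize(M.Y);
    u_eff.resize(M.Y > 0 ? M.Y - 1 : 0);
  }
};

static double logpost(const HadModel &Mo, const double *theta, Scratch &S) {
  const int A = Mo.A, Y = Mo.Y;
  double phi = Mo.phi, T_phi = Mo.T_phi, m_e = Mo.m_e, sigma_phi = Mo.sigma_phi;
  double M4 = Mo.M4, sigma_F = Mo.sigma_F, sigma_xi = Mo.sigma_xi, e0 = Mo.e0;
  // local copies of the age vectors that the map can touch
  std::vector<double> m_a(Mo.m_a), g(Mo.g), D(Mo.D), f(Mo.f), q(Mo.q),
      sigL(Mo.sigL), sigI(Mo.sigI);

  double lp = 0.0;
  for (size_t k = 0; k < Mo.map_ti.size(); ++k) {
    const int ti = Mo.map_ti[k], id = Mo.map_id[k], row = Mo.map_row[k];
    const double th = theta[ti];
    if (!R_finite(th)) return R_NegInf;
    const double val = (Mo.pr_tr[ti] == 1.0) ? std::exp(th) : th;
    switch (id) {
    case P_PHI: phi = val; break;
    case P_TPHI: T_phi = val; break;
    case P_ME: m_e = val; break;
    case P_SIGPHI: sigma_phi = val; break;
    case P_MA: m_a[row] = val; break;
    case P_M4: M4 = val; break;
    case P_G: g[row] = val; break;
    case P_D: D[row] = val; break;
    case P_F: f[row] = val; break;
    case P_SIGF: sigma_F = val; break;
    case P_Q: q[row] = val; break;
    case P_SIGL: sigL[row] = val; break;
    case P_SIGI: sigI[row] = val; break;
    case P_SIGXI: sigma_xi = val; break;
    case P_E0: e0 = val; break;
    default: return R_NegInf;
    }
  }
  for (int k = 0; k < Mo.n_theta; ++k) {
    const double th = theta[k];
    const int fam = (int)Mo.pr_fam[k], tr = (int)Mo.pr_tr[k];
    const double p1 = Mo.pr_p1[k], p2 = Mo.pr_p2[k];
    if (fam == 0) {
      lp += R::dnorm(th, p1, p2, 1);
    } else if (fam == 1) {
      if (th < p1 || th > p2) return R_NegInf;
      lp += -std::log(p2 - p1);
    } else { // half-normal on the natural value
      const double val = (tr == 1) ? std::exp(th) : th;
      if (val < 0) return R_NegInf;
      lp += M_LN2 + R::dnorm(val, 0.0, p1, 1);
      if (tr == 1) lp += th; // Jacobian
    }
  }

  int off = Mo.n_theta;
  for (int y = 0; y < Y; ++y)
    S.u_rec[y] = Mo.est_u_rec ? theta[off + y] : Mo.u_rec0[y];
  if (Mo.est_u_rec) off += Y;
  for (int y = 0; y < Y - 1; ++y)
    S.u_eff[y] = Mo.est_u_eff ? theta[off + y] : Mo.u_eff0[y];
  if (Mo.est_u_rec)
    for (int y = 0; y < Y; ++y) lp += R::dnorm(S.u_rec[y], 0.0, 1.0, 1);
  if (Mo.est_u_eff)
    for (int y = 0; y < Y - 1; ++y) lp += R::dnorm(S.u_eff[y], 0.0, 1.0, 1);

  // fecundity with exact-unbiasedness correction
  double Tbar = 0.0;
  for (int y = 0; y < Y; ++y) Tbar += Mo.T[y];
  Tbar /= Y;
  double sum_ex = 0.0;
  for (int y = 0; y < Y; ++y) {
    S.phi_y[y] = std::exp(T_phi * (Mo.T[y] - Tbar));
    sum_ex += S.phi_y[y];
  }
  for (int y = 0; y < Y; ++y) S.phi_y[y] *= phi * Y / sum_ex;

  S.e[0] = e0;
  for (int y = 1; y < Y; ++y) S.e[y] = S.e[y - 1] + sigma_F * S.u_eff[y - 1];

  for (int a = 0; a < A; ++a) {
    S.delta[a] = 1.0;
    if (!Mo.has_g[a]) continue;
    double s = 0.0;
    for (int y = 0; y < Y; ++y) s += std::exp(g[a] * Mo.G[y]);
    if (!R_finite(s) || s <= 0.0) return R_NegInf; // exp overflow at extreme g
    S.delta[a] = Y / s;
  }

  std::fill(S.N.begin(), S.N.end(), 0.0);
  for (int a = 1; a < A; ++a) S.N[a] = Mo.n_init[a - 1]; // first year column
  const double sp2 = sigma_phi * sigma_phi;
  for (int y = 0; y < Y; ++y) {
    double *Ny = &S.N[(size_t)y * A];
    double *My = &S.Mm[(size_t)y * A];
    double *Fy = &S.Fm[(size_t)y * A];
    const double *Py = &Mo.P[(size_t)y * A];
    const double *Wy = &Mo.W[(size_t)y * A];
    const double ee = std::exp(S.e[y]);
    double ssb = 0.0;
    for (int a = 1; a < A; ++a) ssb += Ny[a] * Py[a] * Wy[a];
    Ny[0] = (ssb > 0.0 && S.phi_y[y] > 0.0)
      ? std::exp(std::log(1000.0 * ssb * S.phi_y[y]) - m_e - sp2 / 2 + sigma_phi * S.u_rec[y])
      : 0.0;
    for (int a = 0; a < A; ++a) {
      double Mv = Mo.has_m[a] ? m_a[a] : M4;
      if (Mo.has_g[a]) Mv *= S.delta[a] * std::exp(g[a] * Mo.G[y]);
      if (Mo.has_D[a]) Mv *= 1.0 + D[a] * Ny[a];
      My[a] = Mv;
      Fy[a] = (Mo.ages[a] >= Mo.fished_min) ? f[a] * ee : 0.0;
    }
    if (y < Y - 1) {
      double *Nn = &S.N[(size_t)(y + 1) * A];
      for (int a = 0; a < A - 1; ++a)
        Nn[a + 1] = Ny[a] * std::exp(-(My[a] + Fy[a]));
      if (Mo.plus_group)
        Nn[A - 1] += Ny[A - 1] * std::exp(-(My[A - 1] + Fy[A - 1]));
    }
  }

  // landings: independent lognormal with mean-one correction
  for (int a = 0; a < A; ++a) {
    if (!Mo.landed[a]) continue;
    for (int y = 0; y < Y; ++y) {
      const double obs = Mo.logL[(size_t)y * A + a];
      if (!R_finite(obs)) continue;
      const double Fv = S.Fm[(size_t)y * A + a];
      const double Mc = Mo.catchM_age ? S.Mm[(size_t)y * A + a] : M4;
      const double Z = Fv + Mc;
      const double C = (Z > 0.0)
        ? Fv / Z * S.N[(size_t)y * A + a] * (1.0 - std::exp(-Z)) : 0.0;
      if (C <= 0.0 || sigL[a] <= 0.0) return R_NegInf;
      lp += R::dnorm(obs, std::log(C) - 0.5 * sigL[a] * sigL[a], sigL[a], 1);
    }
  }
  // survey indices: year effect xi_y marginalized analytically
  // (compound-symmetry covariance, Sherman-Morrison)
  const double xi2 = sigma_xi * sigma_xi;
  for (int y = 0; y < Y; ++y) {
    double q1 = 0.0, q2 = 0.0, logdet = 0.0, sinv = 0.0;
    int k = 0;
    for (int a = 0; a < A; ++a) {
      if (!Mo.surveyed[a]) continue;
      const double obs = Mo.logI[(size_t)y * A + a];
      if (!R_finite(obs)) continue;
      const double Nv = S.N[(size_t)y * A + a];
      if (Nv <= 0.0 || sigI[a] <= 0.0) return R_NegInf;
      const double r = obs - std::log(q[a] * Nv);
      const double v = sigI[a] * sigI[a];
      q1 += r * r / v;
      q2 += r / v;
      sinv += 1.0 / v;
      logdet += std::log(v);
      ++k;
    }
    if (k == 0) continue;
    const double c = 1.0 + xi2 * sinv;
    const double quad = q1 - xi2 * q2 * q2 / c;
    lp += -0.5 * (k * LOG2PI + logdet + std::log(c) + quad);
  }
  return lp;
}

// [[Rcpp::export]]
double haddock_logpost_cpp(NumericVector theta, List m) {
  HadModel M = parse_model(m);
  if (theta.size() != M.n_dim)
    stop("theta has length %d, expected %d", theta.size(), M.n_dim);
  Scratch S;
  S.size(M);
  return logpost(M, REAL(theta), S);
}

// lower-triangular Cholesky factor of a (copied) symmetric matrix;
// returns false if not positive definite
static bool cholesky(std::vector<double> &A, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0.0) return false;
    const double Ljj = std::sqrt(s);
    A[j * d + j] = Ljj;
    for (int i = j + 1; i < d; ++i) {
      double t = A[i * d + j];
      for (int k = 0; k < j; ++k) t -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = t / Ljj;
    }
    for (int k = j + 1; k < d; ++k) A[j * d + k] = 0.0;
  }
  return true;
}

// One adaptive chain for the haddock model: componentwise Gaussian
// random-walk proposals (per-coordinate scales adapted during warmup
// toward 0.44 acceptance, Robbins-Monro on the log scale, step t^-0.6)
// interleaved with joint proposals from the running empirical
// covariance of the chain (classic adaptive-Metropolis moves, target
// acceptance 0.23) that carry the sampler across the posterior
// correlation between parameters and latent innovations.  Scales are
// frozen after warmup.  Uses R's RNG.
// [[Rcpp::export]]
List haddock_mcmc_chain_cpp(List m, NumericVector init, int warmup, int iter,
                            int thin, double scale0) {
  HadModel M = parse_model(m);
  const int d = M.n_dim;
  if (init.size() != d) stop("init has length %d, expected %d", init.size(), d);
  Scratch S;
  S.size(M);

  std::vector<double> theta(init.begin(), init.end());
  double lp = logpost(M, theta.data(), S);
  if (!R_finite(lp)) stop("initial point has zero posterior density");

  std::vector<double> ls(d, std::log(scale0));
  const int n_keep = iter / thin;
  NumericMatrix draws(n_keep, d);
  NumericVector lp_keep(n_keep);
  std::vector<double> acc_n(d, 0.0);

  // running mean / covariance (Welford) for the joint proposal
  std::vector<double> mu(theta), cov(d * d, 0.0), L(d * d, 0.0);
  std::vector<double> prop(d), z(d);
  double n_cov = 1.0, ls_joint = std::log(2.38 / std::sqrt((double)d));
  bool have_L = false;
  const int joint_start = 200, joint_per_sweep = 2, refresh = 100;

  // ridge move for the fecundity temperature coefficient: T_phi and the
  // recruitment innovations trade off along log phi_y = const; propose a
  // T_phi shift with exactly compensating u_rec so every latent state is
  // unchanged (a volume-preserving shear; only prior terms decide
  // acceptance).  Mixes the dominant slow direction of the posterior.
  int tphi_idx = -1, sigphi_idx = -1;
  for (size_t k = 0; k < M.map_ti.size(); ++k) {
    if (M.map_id[k] == P_TPHI) tphi_idx = M.map_ti[k];
    if (M.map_id[k] == P_SIGPHI) sigphi_idx = M.map_ti[k];
  }
  const bool do_ridge = tphi_idx >= 0 && M.est_u_rec;
  std::vector<double> Tc(M.Y); // centred temperature
  {
    double Tbar = 0.0;
    for (int y = 0; y < M.Y; ++y) Tbar += M.T[y];
    Tbar /= M.Y;
    for (int y = 0; y < M.Y; ++y) Tc[y] = M.T[y] - Tbar;
  }
  // log delta_T correction as a function of T_phi
  auto log_deltaT = [&](double tphi) {
    double s = 0.0;
    for (int y = 0; y < M.Y; ++y) s += std::exp(tphi * Tc[y]);
    return std::log((double)M.Y / s);
  };
  double ls_ridge = std::log(0.2);
  const int u_off = M.n_theta;

  // analogous ridge for the age-0 predation coefficient: a g_0 shift
  // changes age-0 mortality M_0y, compensated by raising the same
  // year's recruitment innovation so the age-1 cohort is unchanged
  // (exact when age 0 is unsurveyed and density-independent).
  int g0_idx = -1, m0_idx = -1;
  for (size_t k = 0; k < M.map_ti.size(); ++k) {
    if (M.map_id[k] == P_G && M.map_row[k] == 0) g0_idx = M.map_ti[k];
    if (M.map_id[k] == P_MA && M.map_row[k] == 0) m0_idx = M.map_ti[k];
  }
  const bool do_g0 = g0_idx >= 0 && M.est_u_rec && M.has_g[0];
  auto pred_factor = [&](double g0, int y) {
    double s = 0.0;
    for (int yy = 0; yy < M.Y; ++yy) s += std::exp(g0 * M.G[yy]);
    return (double)M.Y / s * std::exp(g0 * M.G[y]);
  };
  double ls_g0 = std::log(1e-4);
  int kept = 0;
  const int total = warmup + iter;
  for (int t = 1; t <= total; ++t) {
    const double step = std::pow((double)std::max(10, t), -0.6);
    for (int j = 0; j < d; ++j) {
      const double old = theta[j];
      theta[j] = old + std::exp(ls[j]) * norm_rand();
      const double lpp = logpost(M, theta.data(), S);
      const bool acc = R_finite(lpp) && (lpp - lp > std::log(unif_rand()));
      if (acc) {
        lp = lpp;
      } else {
        theta[j] = old;
      }
      if (t <= warmup) {
        ls[j] += step * ((acc ? 1.0 : 0.0) - 0.44);
      } else if (acc) {
        acc_n[j] += 1.0;
      }
    }
    if (t <= warmup) {
      // update running covariance with the post-sweep state
      n_cov += 1.0;
      for (int i = 0; i < d; ++i) {
        const double di = theta[i] - mu[i];
        mu[i] += di / n_cov;
        for (int j = 0; j <= i; ++j) {
          cov[i * d + j] += di * (theta[j] - mu[j]);
        }
      }
      if (t >= joint_start && t % refresh == 0) {
        std::vector<double> A(d * d);
        for (int i = 0; i < d; ++i) {
          for (int j = 0; j <= i; ++j) {
            A[i * d + j] = A[j * d + i] = cov[i * d + j] / (n_cov - 1.0);
          }
          A[i * d + i] += 1e-10;
        }
        have_L = cholesky(A, d);
        if (have_L) L = A;
      }
    }
    if (do_ridge) {
      for (int rep = 0; rep < 2; ++rep) {
        const double sigphi = sigphi_idx >= 0
          ? ((int)M.pr_tr[sigphi_idx] == 1 ? std::exp(theta[sigphi_idx]) : theta[sigphi_idx])
          : M.sigma_phi;
        if (sigphi <= 0.0) break;
        const double tphi_old = theta[tphi_idx];
        const double delta = std::exp(ls_ridge) * norm_rand();
        const double dc = log_deltaT(tphi_old + delta) - log_deltaT(tphi_old);
        prop = theta;
        prop[tphi_idx] = tphi_old + delta;
        for (int y = 0; y < M.Y; ++y) {
          prop[u_off + y] -= (delta * Tc[y] + dc) / sigphi;
        }
        const double lpp = logpost(M, prop.data(), S);
        const bool acc = R_finite(lpp) && (lpp - lp > std::log(unif_rand()));
        if (acc) {
          theta = prop;
          lp = lpp;
        }
        if (t <= warmup) ls_ridge += step * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }
    if (do_g0) {
      for (int rep = 0; rep < 2; ++rep) {
        const double sigphi = sigphi_idx >= 0
          ? ((int)M.pr_tr[sigphi_idx] == 1 ? std::exp(theta[sigphi_idx]) : theta[sigphi_idx])
          : M.sigma_phi;
        if (sigphi <= 0.0) break;
        const double m0 = m0_idx >= 0
          ? ((int)M.pr_tr[m0_idx] == 1 ? std::exp(theta[m0_idx]) : theta[m0_idx])
          : M.m_a[0];
        const double g_old = theta[g0_idx];
        const double delta = std::exp(ls_g0) * norm_rand();
        const double g_new = g_old + delta;
        double s_old = 0.0, s_new = 0.0;
        for (int y = 0; y < M.Y; ++y) {
          s_old += std::exp(g_old * M.G[y]);
          s_new += std::exp(g_new * M.G[y]);
        }
        prop = theta;
        prop[g0_idx] = g_new;
        for (int y = 0; y < M.Y; ++y) {
          const double dM = m0 * (M.Y / s_new * std::exp(g_new * M.G[y]) -
                                  M.Y / s_old * std::exp(g_old * M.G[y]));
          prop[u_off + y] += dM / sigphi;
        }
        const double lpp = logpost(M, prop.data(), S);
        const bool acc = R_finite(lpp) && (lpp - lp > std::log(unif_rand()));
        if (acc) {
          theta = prop;
          lp = lpp;
        }
        if (t <= warmup) ls_g0 += step * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }
    if (have_L && t >= joint_start) {
      for (int rep = 0; rep < joint_per_sweep; ++rep) {
        for (int j = 0; j < d; ++j) z[j] = norm_rand();
        const double sc = std::exp(ls_joint);
        for (int i = 0; i < d; ++i) {
          double s = 0.0;
          for (int j = 0; j <= i; ++j) s += L[i * d + j] * z[j];
          prop[i] = theta[i] + sc * s;
        }
        const double lpp = logpost(M, prop.data(), S);
        const bool acc = R_finite(lpp) && (lpp - lp > std::log(unif_rand()));
        if (acc) {
          theta = prop;
          lp = lpp;
        }
        if (t <= warmup) ls_joint += step * ((acc ? 1.0 : 0.0) - 0.23);
      }
    }
    if (t > warmup && (t - warmup) % thin == 0) {
      for (int j = 0; j < d; ++j) draws(kept, j) = theta[j];
      lp_keep[kept] = lp;
      ++kept;
    }
  }
  NumericVector accept(d), scales(d);
  for (int j = 0; j < d; ++j) {
    accept[j] = acc_n[j] / iter;
    scales[j] = std::exp(ls[j]);
  }
  return List::create(
    _["draws"] = draws, _["lp"] = lp_keep,
    _["accept"] = accept, _["scales"] = scales,
    _["joint_scale"] = std::exp(ls_joint)
  );
}
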