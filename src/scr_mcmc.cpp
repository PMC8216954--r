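#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for spatially explicit capture-recapture
// with data augmentation. Detection hazard at squared distance d2:
//   lambda = exp(alpha0 + beta*c + a_sex*male) * exp(-(d2/sigma^2)^theta)
//   p = 1 - exp(-lambda)   so   log(1 - p) = -lambda
// Activity centers live on a discrete grid; all-zero (augmented)
// histories therefore cost one kernel-sum S(g) = sum_j kern(d2(g,j)),
// which is cached per grid point and invalidated whenever sigma or theta
// moves. Kernel terms with (d2/sigma^2)^theta > 30 are dropped (kern <
// 1e-13); trap distances are pre-sorted per grid point so the inner sum
// breaks early.

static inline double scr_log1mexp(double lam) {
  // log(1 - exp(-lam)), lam > 0
  if (lam > M_LN2) return std::log1p(-std::exp(-lam));
  return std::log(-std::expm1(-lam));
}

struct Sampler {
  int n_obs, M, K, J, G;
  // capture cells (CSR over observed individuals)
  std::vector<int> cell_ptr, cell_j, cell_c; // c = behaviour covariate (0/1)
  std::vector<int> n_post; // per observed individual: #occasions with c=1
  // geometry
  const double *logd2;   // G x J, column-major (g + G*j)
  const double *slogd2;  // sorted ascending per grid point, G x J
  double cell_area;
  // neighbour lists
  std::vector<int> nbr, nbr_ptr;
  // model flags
  bool use_sex, use_behav, use_sexsig;
  // parameters
  double alpha0, beta, asex, sigma, ssex, theta, psi, psi_sex;
  // latent state
  std::vector<int> z, male, sidx, sex_known;
  std::vector<double> llcache;
  // S cache: one per sex class actually needed
  std::vector<double> Sc[2];
  std::vector<int> Sver[2];
  int ver;

  double l2s(int m) const {
    double ls = std::log(sigma) + (use_sexsig && m ? ssex : 0.0);
    return 2.0 * ls;
  }

  double computeS(int g, int m, double sig, double th, double ss) const {
    double l2 = 2.0 * (std::log(sig) + (use_sexsig && m ? ss : 0.0));
    double S = 0.0;
    const double *row = slogd2 + g; // stride G over j
    for (int j = 0; j < J; ++j) {
      double u = th * (row[(size_t)G * j] - l2);
      if (u > 3.4012) break; // exp(u) > 30 -> kern < 1e-13, sorted => done
      S += std::exp(-std::exp(u));
    }
    return S;
  }

  double getS(int g, int m) {
    int cls = (use_sexsig && m) ? 1 : 0;
    if (Sver[cls][g] != ver) {
      Sc[cls][g] = computeS(g, cls, sigma, theta, ssex);
      Sver[cls][g] = ver;
    }
    return Sc[cls][g];
  }

  // log-likelihood of observed individual i at grid point g under
  // (a0, b, as, sig, th, ss); S supplied by caller.
  double ll_obs(int i, int g, double S, double a0, double b, double as,
                double sig, double th, double ss) const {
    int m = male[i];
    double eta0 = a0 + (use_sex && m ? as : 0.0);
    double h0 = std::exp(eta0);
    double H;
    if (use_behav) {
      int n1 = n_post[i];
      H = h0 * ((K - n1) + n1 * std::exp(b));
    } else {
      H = h0 * K;
    }
    double l2 = 2.0 * (std::log(sig) + (use_sexsig && m ? ss : 0.0));
    double ll = -H * S;
    for (int c = cell_ptr[i]; c < cell_ptr[i + 1]; ++c) {
      int j = cell_j[c];
      double u = th * (logd2[g + (size_t)G * j] - l2);
      double kern = std::exp(-std::exp(u));
      double hk = h0 * (use_behav && cell_c[c] ? std::exp(b) : 1.0);
      double lam = hk * kern;
      if (lam <= 0.0) return R_NegInf;
      ll += scr_log1mexp(lam) + lam;
    }
    return ll;
  }

  // all-zero history (augmented individual), never captured so c = 0
  double ll_aug(int g, int m, double S, double a0, double as) const {
    double eta0 = a0 + (use_sex && m ? as : 0.0);
    return -K * std::exp(eta0) * S;
  }

  // cached-parameter likelihood for any individual with z = 1
  double ll_at(int i, int g) {
    double S = getS(g, male[i]);
    if (i < n_obs)
      return ll_obs(i, g, S, alpha0, beta, asex, sigma, theta, ssex);
    return ll_aug(g, male[i], S, alpha0, asex);
  }

  // likelihood under proposed parameters (no cache)
  double ll_prop(int i, int g, double a0, double b, double as,
                 double sig, double th, double ss) const {
    int m = male[i];
    double S = computeS(g, (use_sexsig && m) ? 1 : 0, sig, th, ss);
    if (i < n_obs) return ll_obs(i, g, S, a0, b, as, sig, th, ss);
    return ll_aug(g, m, S, a0, as);
  }
};

// [[Rcpp::export]]
List scr_mcmc_chain(int n_obs, int M, int K,
                    IntegerVector cell_ptr, IntegerVector cell_j,
                    IntegerVector cell_c, IntegerVector n_post,
                    IntegerVector sex_obs,
                    NumericMatrix logd2, NumericMatrix slogd2,
                    NumericMatrix grid, double cell_area,
                    bool use_sex, bool use_behav, bool use_sexsig,
                    List start, List ctrl) {
  Sampler s;
  s.n_obs = n_obs; s.M = M; s.K = K;
  s.J = logd2.ncol(); s.G = logd2.nrow();
  s.cell_ptr.assign(cell_ptr.begin(), cell_ptr.end());
  s.cell_j.assign(cell_j.begin(), cell_j.end());
  s.cell_c.assign(cell_c.begin(), cell_c.end());
  s.n_post.assign(n_post.begin(), n_post.end());
  s.logd2 = REAL(logd2); s.slogd2 = REAL(slogd2);
  s.cell_area = cell_area;
  s.use_sex = use_sex; s.use_behav = use_behav; s.use_sexsig = use_sexsig;

  s.alpha0 = as<double>(start["alpha0"]);
  s.beta = as<double>(start["beta"]);
  s.asex = as<double>(start["asex"]);
  s.sigma = as<double>(start["sigma"]);
  s.ssex = as<double>(start["ssex"]);
  s.theta = as<double>(start["theta"]);
  s.psi = as<double>(start["psi"]);
  s.psi_sex = as<double>(start["psi_sex"]);
  IntegerVector s0 = start["centers"]; // 0-based grid index, length M

  int n_iter = as<int>(ctrl["n_iterations"]);
  int n_burn = as<int>(ctrl["n_burnin"]);
  double jump = as<double>(ctrl["center_jump"]);
  double unif_prob = as<double>(ctrl["uniform_prob"]);
  NumericVector scales = ctrl["proposal_scales"]; // a0, beta, asex, sigma, ssex, theta
  bool adapt = as<bool>(ctrl["adapt"]);

  int G = s.G, J = s.J;
  // neighbour lists within `jump` km
  {
    double j2 = jump * jump;
    std::vector<std::vector<int> > nb(G);
    const double *gx = REAL(grid), *gy = REAL(grid) + G;
    for (int a = 0; a < G; ++a)
      for (int b = a + 1; b < G; ++b) {
        double dx = gx[a] - gx[b], dy = gy[a] - gy[b];
        if (dx * dx + dy * dy <= j2) { nb[a].push_back(b); nb[b].push_back(a); }
      }
    s.nbr_ptr.resize(G + 1, 0);
    for (int a = 0; a < G; ++a) s.nbr_ptr[a + 1] = s.nbr_ptr[a] + nb[a].size();
    s.nbr.reserve(s.nbr_ptr[G]);
    for (int a = 0; a < G; ++a)
      s.nbr.insert(s.nbr.end(), nb[a].begin(), nb[a].end());
  }

  RNGScope scope;
  s.z.assign(M, 0); s.male.assign(M, 0); s.sex_known.assign(M, 0);
  s.sidx.assign(M, 0); s.llcache.assign(M, 0.0);
  s.Sc[0].assign(G, 0.0); s.Sc[1].assign(G, 0.0);
  s.Sver[0].assign(G, -1); s.Sver[1].assign(G, -1);
  s.ver = 0;

  for (int i = 0; i < M; ++i) {
    s.sidx[i] = s0[i];
    if (i < n_obs) {
      s.z[i] = 1;
      if (sex_obs[i] >= 0) { s.male[i] = sex_obs[i]; s.sex_known[i] = 1; }
      else s.male[i] = (unif_rand() < s.psi_sex) ? 1 : 0;
    } else {
      s.z[i] = (unif_rand() < s.psi) ? 1 : 0;
      s.male[i] = (unif_rand() < s.psi_sex) ? 1 : 0;
    }
  }
  for (int i = 0; i < M; ++i)
    if (s.z[i]) s.llcache[i] = s.ll_at(i, s.sidx[i]);

  int n_keep = n_iter - n_burn;
  int n_par_rec = 11;
  NumericMatrix out(n_keep, n_par_rec);
  CharacterVector cn = CharacterVector::create(
      "alpha0", "g0", "beta", "asex", "sigma", "ssex", "theta",
      "psi", "psi_sex", "N", "D");
  double area_total = G * cell_area;

  // adaptation bookkeeping: params 0..5
  int acc[6] = {0, 0, 0, 0, 0, 0}, tries[6] = {0, 0, 0, 0, 0, 0};
  double sc[6];
  for (int p = 0; p < 6; ++p) sc[p] = scales[p];
  int acc_center = 0, try_center = 0;

  bool want[6] = {true, use_behav, use_sex, true, use_sexsig, true};

  for (int it = 0; it < n_iter; ++it) {
    // ---- scalar detection parameters ----
    for (int p = 0; p < 6; ++p) {
      if (!want[p]) continue;
      double a0 = s.alpha0, b = s.beta, as_ = s.asex,
             sig = s.sigma, th = s.theta, ss = s.ssex;
      double step = norm_rand() * sc[p];
      switch (p) {
        case 0: a0 += step; break;
        case 1: b += step; break;
        case 2: as_ += step; break;
        case 3: sig += step; break;
        case 4: ss += step; break;
        case 5: th += step; break;
      }
      ++tries[p];
      if (sig <= 0.0) continue;                 // flat prior on (0, inf)
      if (th < 0.5 || th > 1.0) continue;       // uniform(0.5, 1)
      bool geom = (p >= 3);                     // sigma/ssex/theta move S
      double dll = 0.0;
      std::vector<double> newll;
      newll.reserve(M);
      bool ok = true;
      for (int i = 0; i < M && ok; ++i) {
        if (!s.z[i]) continue;
        double nll;
        if (geom) {
          nll = s.ll_prop(i, s.sidx[i], a0, b, as_, sig, th, ss);
        } else {
          double S = s.getS(s.sidx[i], s.male[i]);
          nll = (i < n_obs)
            ? s.ll_obs(i, s.sidx[i], S, a0, b, as_, sig, th, ss)
            : s.ll_aug(s.sidx[i], s.male[i], S, a0, as_);
        }
        if (!R_finite(nll)) ok = false;
        newll.push_back(nll);
        dll += nll - s.llcache[i];
      }
      if (ok && std::log(unif_rand()) < dll) {
        s.alpha0 = a0; s.beta = b; s.asex = as_;
        s.sigma = sig; s.theta = th; s.ssex = ss;
        int q = 0;
        for (int i = 0; i < M; ++i)
          if (s.z[i]) s.llcache[i] = newll[q++];
        if (geom) ++s.ver;
        ++acc[p];
      }
    }

    // ---- activity centers ----
    for (int i = 0; i < M; ++i) {
      if (!s.z[i]) { // prior draw
        s.sidx[i] = (int)(unif_rand() * G) % G;
        continue;
      }
      int g = s.sidx[i], gp;
      double lqratio = 0.0;
      if (unif_rand() < unif_prob) {
        gp = (int)(unif_rand() * G) % G;
      } else {
        int deg = s.nbr_ptr[g + 1] - s.nbr_ptr[g];
        if (deg == 0) continue;
        gp = s.nbr[s.nbr_ptr[g] + ((int)(unif_rand() * deg) % deg)];
        int degp = s.nbr_ptr[gp + 1] - s.nbr_ptr[gp];
        lqratio = std::log((double)deg) - std::log((double)degp);
      }
      ++try_center;
      double nll = s.ll_at(i, gp);
      if (std::log(unif_rand()) < nll - s.llcache[i] + lqratio) {
        s.sidx[i] = gp; s.llcache[i] = nll; ++acc_center;
      }
    }

    // ---- inclusion indicators (augmented only) ----
    for (int i = n_obs; i < M; ++i) {
      double ll0 = s.z[i] ? s.llcache[i]
                          : s.ll_aug(s.sidx[i], s.male[i],
                                     s.getS(s.sidx[i], s.male[i]),
                                     s.alpha0, s.asex);
      double p1 = s.psi * std::exp(ll0);
      double pr = p1 / (p1 + (1.0 - s.psi));
      int znew = (unif_rand() < pr) ? 1 : 0;
      if (znew && !s.z[i]) s.llcache[i] = ll0;
      s.z[i] = znew;
    }

    // ---- sex ----
    bool sex_in_lik = use_sex || use_sexsig;
    for (int i = 0; i < M; ++i) {
      if (s.sex_known[i]) continue;
      if (!sex_in_lik || !s.z[i]) {
        s.male[i] = (unif_rand() < s.psi_sex) ? 1 : 0;
        continue;
      }
      int save = s.male[i];
      s.male[i] = 0; double ll_f = s.ll_at(i, s.sidx[i]);
      s.male[i] = 1; double ll_m = s.ll_at(i, s.sidx[i]);
      double wm = s.psi_sex * std::exp(ll_m - std::fmax(ll_f, ll_m));
      double wf = (1.0 - s.psi_sex) * std::exp(ll_f - std::fmax(ll_f, ll_m));
      int mnew = (unif_rand() < wm / (wm + wf)) ? 1 : 0;
      s.male[i] = mnew;
      s.llcache[i] = (mnew == 1) ? ll_m : ll_f;
      (void)save;
    }

    // ---- psi, psi_sex (conjugate beta) ----
    int Nz = 0, Nm = 0;
    for (int i = 0; i < M; ++i) {
      Nz += s.z[i];
      if (s.z[i]) Nm += s.male[i];
    }
    s.psi = R::rbeta(1.0 + Nz, 1.0 + (M - Nz));
    s.psi_sex = R::rbeta(1.0 + Nm, 1.0 + (Nz - Nm));

    // ---- adaptation (burn-in only) ----
    if (adapt && it < n_burn && (it + 1) % 100 == 0) {
      for (int p = 0; p < 6; ++p) {
        if (!want[p] || tries[p] == 0) continue;
        double r = (double)acc[p] / tries[p];
        if (r > 0.4) sc[p] *= 1.25;
        else if (r < 0.2) sc[p] /= 1.25;
        acc[p] = 0; tries[p] = 0;
      }
    }

    // ---- record ----
    if (it >= n_burn) {
      int row = it - n_burn;
      out(row, 0) = s.alpha0;
      out(row, 1) = 1.0 - std::exp(-std::exp(s.alpha0));
      out(row, 2) = s.beta;
      out(row, 3) = s.asex;
      out(row, 4) = s.sigma;
      out(row, 5) = s.ssex;
      out(row, 6) = s.theta;
      out(row, 7) = s.psi;
      out(row, 8) = s.psi_sex;
      out(row, 9) = Nz;
      out(row, 10) = Nz / area_total;
    }
  }
  colnames(out) = cn;
  NumericVector fs(6);
  for (int p = 0; p < 6; ++p) fs[p] = sc[p];
  return List::create(_["draws"] = out,
                      _["accept_center"] = try_center ? (double)acc_center / try_center : NA_REAL,
                      _["final_scales"] = fs);
}
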