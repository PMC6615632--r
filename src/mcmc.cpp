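// Metropolis-Hastings samplers for the multicategory and two-sided gamma
// DFE models. One scalar variable is proposed per iteration, cycling
// deterministically through the variable blocks. The observation term of
// the likelihood is maintained through per-line sums of residuals and
// squared residuals, refreshed from scratch periodically to bound
// floating-point drift. All proposal kernels are symmetric, so acceptance
// uses the plain Metropolis ratio. R's RNG is used throughout so chains
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// log gamma pdf parametrized by (mean, shape); rate = shape / mean
static inline double lgamma_pdf(double x, double mean, double shape) {
  if (x <= 0.0 || mean <= 0.0 || shape <= 0.0) return R_NegInf;
  double rate = shape / mean;
  return shape * std::log(rate) - std::lgamma(shape) +
         (shape - 1.0) * std::log(x) - rate * x;
}

static inline double tune_scale_cpp(double scale, double rate) {
  double s = scale * std::exp(rate - 0.25);
  if (s < 1e-8) s = 1e-8;
  if (s > 1e8) s = 1e8;
  return s;
}

// Shared (nuisance) part of both models: fixed effects, plate effects,
// per-line means, variances, and the residual bookkeeping.
struct SharedModel {
  int n_b, n_f, n_p, n_lines;
  std::vector<double> y;
  std::vector<int> plate;  // 0-based, empty if n_p == 0
  std::vector<int> line;   // 0-based
  std::vector<std::vector<int>> fix_carriers;
  std::vector<std::vector<int>> plate_obs;

  std::vector<double> f, p, ybar;
  double Vp, Ve;

  std::vector<double> d;        // y - g - F f - p[r]
  std::vector<double> S1, S2;   // per-line sums of d and d^2
  std::vector<double> nline;
  double Sp2;

  // scratch per-line buffers
  std::vector<double> tS1, tS2;

  void setup(const NumericVector& y_, const IntegerMatrix& F,
             const IntegerVector& plate_, int n_p_,
             const IntegerVector& line_, int n_lines_) {
    n_b = y_.size();
    n_f = F.ncol();
    n_p = n_p_;
    n_lines = n_lines_;
    y.assign(y_.begin(), y_.end());
    plate.assign(plate_.begin(), plate_.end());
    line.assign(line_.begin(), line_.end());
    fix_carriers.assign(n_f, {});
    for (int j = 0; j < n_f; ++j)
      for (int i = 0; i < n_b; ++i)
        if (F(i, j) == 1) fix_carriers[j].push_back(i);
    plate_obs.assign(n_p, {});
    if (n_p > 0)
      for (int i = 0; i < n_b; ++i) plate_obs[plate[i]].push_back(i);
    f.assign(n_f, 0.0);
    p.assign(n_p, 0.0);
    ybar.assign(std::max(n_lines, 1), 0.0);
    nline.assign(std::max(n_lines, 1), 0.0);
    std::vector<double> ysum(std::max(n_lines, 1), 0.0);
    for (int i = 0; i < n_b; ++i) {
      nline[line[i]] += 1.0;
      ysum[line[i]] += y[i];
    }
    for (int l = 0; l < n_lines; ++l)
      if (nline[l] > 0) ybar[l] = ysum[l] / nline[l];
    double m = 0, ss = 0;
    for (int i = 0; i < n_b; ++i) m += y[i];
    if (n_b > 0) m /= n_b;
    for (int i = 0; i < n_b; ++i) ss += (y[i] - m) * (y[i] - m);
    Ve = (n_b > 1) ? ss / (n_b - 1) : 1.0;
    if (Ve <= 0) Ve = 1.0;
    Vp = Ve / 10.0;
    d.assign(n_b, 0.0);
    S1.assign(std::max(n_lines, 1), 0.0);
    S2.assign(std::max(n_lines, 1), 0.0);
    tS1 = S1;
    tS2 = S2;
    Sp2 = 0.0;
  }

  // recompute d, S1, S2, Sp2 given genotypic values g
  void refresh(const std::vector<double>& g) {
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    for (int i = 0; i < n_b; ++i) {
      double di = y[i] - g[i];
      if (n_p > 0) di -= p[plate[i]];
      d[i] = di;
    }
    for (int j = 0; j < n_f; ++j) {
      double fj = f[j];
      if (fj != 0.0)
        for (int i : fix_carriers[j]) d[i] -= fj;
    }
    for (int i = 0; i < n_b; ++i) {
      S1[line[i]] += d[i];
      S2[line[i]] += d[i] * d[i];
    }
    Sp2 = 0.0;
    for (int k = 0; k < n_p; ++k) Sp2 += p[k] * p[k];
  }

  double obs_term() const { return obs_term_sums(S1, S2, ybar, Ve); }

  double obs_term_sums(const std::vector<double>& s1,
                       const std::vector<double>& s2,
                       const std::vector<double>& yb, double ve) const {
    if (n_b == 0) return 0.0;
    double ll = 0.0;
    for (int l = 0; l < n_lines; ++l) {
      if (nline[l] == 0) continue;
      ll += -0.5 * nline[l] * (LOG2PI + std::log(ve)) -
            (s2[l] - 2.0 * yb[l] * s1[l] + nline[l] * yb[l] * yb[l]) /
            (2.0 * ve);
    }
    return ll;
  }

  double plate_term() const {
    if (n_p == 0) return 0.0;
    return -0.5 * n_p * (LOG2PI + std::log(Vp)) - Sp2 / (2.0 * Vp);
  }

  // delta of the observation term if every observation in idx has its
  // residual shifted by dd (does not commit)
  double delta_obs_shift(const std::vector<int>& idx, double dd) {
    tS1 = S1;
    tS2 = S2;
    for (int i : idx) {
      int l = line[i];
      tS1[l] += dd;
      tS2[l] += dd * (2.0 * d[i] + dd);
    }
    return obs_term_sums(tS1, tS2, ybar, Ve) - obs_term();
  }

  void commit_shift(const std::vector<int>& idx, double dd) {
    for (int i : idx) {
      int l = line[i];
      S1[l] += dd;
      S2[l] += dd * (2.0 * d[i] + dd);
      d[i] += dd;
    }
  }
};

// Per-block bookkeeping for adaptive scales and acceptance reporting.
struct Block {
  int type;       // model-specific code
  int index;      // which element of the block's vector
  double scale;
  long long prop_win = 0, acc_win = 0;     // adaptation window
  long long prop_tot = 0, acc_tot = 0;     // sampling phase only
};

static void tune_block(Block& b, int tune_window) {
  if (b.prop_win >= tune_window) {
    double rate = (double)b.acc_win / (double)b.prop_win;
    b.scale = tune_scale_cpp(b.scale, rate);
    b.prop_win = 0;
    b.acc_win = 0;
  }
}

static List acceptance_summary(const std::vector<Block>& blocks,
                               const std::vector<std::string>& type_names) {
  std::vector<long long> prop(type_names.size(), 0), acc(type_names.size(), 0);
  std::vector<double> sc(type_names.size(), 0.0);
  std::vector<int> cnt(type_names.size(), 0);
  for (const Block& b : blocks) {
    prop[b.type] += b.prop_tot;
    acc[b.type] += b.acc_tot;
    sc[b.type] += b.scale;
    cnt[b.type] += 1;
  }
  CharacterVector nm;
  NumericVector pr, ac, msc;
  for (size_t t = 0; t < type_names.size(); ++t) {
    if (cnt[t] == 0) continue;
    nm.push_back(type_names[t]);
    pr.push_back((double)prop[t]);
    ac.push_back((double)acc[t]);
    msc.push_back(sc[t] / cnt[t]);
  }
  return List::create(_["block"] = nm, _["proposals"] = pr,
                      _["accepted"] = ac, _["mean_scale"] = msc);
}

// ---------------------------------------------------------------------------
// Multicategory sampler
// ---------------------------------------------------------------------------

// block type codes
enum { MC_M = 0, MC_E, MC_Q, MC_F, MC_P, MC_VP, MC_YBAR, MC_VE, MC_NTYPES };

// category-occupancy part of the likelihood:
// as printed, sum_i log q[m_i] + log multinomial(n_c, q, v)
//           = 2 * sum_k v_k log q_k + log(n_m! / prod v_k!)
static double cat_term(const std::vector<int>& v, const std::vector<double>& q,
                       int n_m, bool as_printed) {
  double lq = 0.0, lcoef = std::lgamma(n_m + 1.0);
  for (size_t k = 0; k < v.size(); ++k) {
    if (v[k] > 0) {
      if (q[k] <= 0.0) return R_NegInf;
      lq += v[k] * std::log(q[k]);
    }
    lcoef -= std::lgamma(v[k] + 1.0);
  }
  return (as_printed ? 2.0 * lq : lq) + lcoef;
}

// [[Rcpp::export]]
List mcmc_multicat_cpp(NumericVector y, IntegerMatrix M, IntegerMatrix F,
                       IntegerVector plate, int n_p, IntegerVector line,
                       int n_lines, int n_c, double e_max, double burnin,
                       double sampling, double thin, bool as_printed,
                       int tune_window, double refresh_every,
                       Nullable<List> init = R_NilValue) {
  SharedModel sh;
  sh.setup(y, F, plate, n_p, line, n_lines);
  int n_b = sh.n_b, n_m = M.ncol();

  std::vector<std::vector<int>> carriers(n_m);
  for (int j = 0; j < n_m; ++j)
    for (int i = 0; i < n_b; ++i)
      if (M(i, j) == 1) carriers[j].push_back(i);

  // state
  std::vector<int> m(n_m, 0);
  std::vector<double> e(n_c, 0.0);
  std::vector<double> q(n_c, 1.0 / n_c);
  std::vector<int> v(n_c, 0);
  v[0] = n_m;
  if (init.isNotNull()) {
    List in(init);
    if (in.containsElementNamed("m")) {
      IntegerVector m0 = in["m"];
      for (int j = 0; j < n_m; ++j) m[j] = m0[j];
    }
    if (in.containsElementNamed("e")) {
      NumericVector e0 = in["e"];
      for (int k = 0; k < n_c; ++k) e[k] = e0[k];
      e[0] = 0.0;
    }
    if (in.containsElementNamed("q")) {
      NumericVector q0v = in["q"];
      for (int k = 0; k < n_c; ++k) q[k] = q0v[k];
    }
    std::fill(v.begin(), v.end(), 0);
    for (int j = 0; j < n_m; ++j) v[m[j]] += 1;
  }
  std::vector<int> C((size_t)n_b * n_c, 0);  // carried count per category
  for (int j = 0; j < n_m; ++j)
    for (int i : carriers[j]) C[(size_t)i * n_c + m[j]] += 1;
  std::vector<double> g(n_b, 0.0);
  for (int j = 0; j < n_m; ++j) {
    double ej = e[m[j]];
    if (ej != 0.0)
      for (int i : carriers[j]) g[i] += ej;
  }
  sh.refresh(g);

  // blocks
  std::vector<Block> blocks;
  for (int j = 0; j < n_m && n_c >= 2; ++j)
    blocks.push_back({MC_M, j, 0.0});
  for (int k = 1; k < n_c; ++k) blocks.push_back({MC_E, k, 0.1});
  for (int k = 1; k < n_c; ++k) blocks.push_back({MC_Q, k, 0.1});
  for (int j = 0; j < sh.n_f; ++j) blocks.push_back({MC_F, j, 0.1});
  for (int k = 0; k < n_p; ++k) blocks.push_back({MC_P, k, 0.1});
  if (n_p > 0) blocks.push_back({MC_VP, 0, 0.5});
  if (n_b > 0) {
    for (int l = 0; l < n_lines; ++l) blocks.push_back({MC_YBAR, l, 0.1});
    blocks.push_back({MC_VE, 0, 0.5});
  }
  if (blocks.empty()) stop("model has no free variables");
  int nblocks = blocks.size();

  double ll_cat = cat_term(v, q, n_m, as_printed);
  double ll_obs = sh.obs_term();
  double ll_plate = sh.plate_term();

  long long n_burn = (long long)burnin;
  long long n_samp = (long long)sampling;
  long long thin_ll = (long long)thin;
  long long n_draws = (thin_ll > 0) ? n_samp / thin_ll : 0;
  long long refresh = (long long)refresh_every;

  int base_cols = (n_c - 1) * 2 + n_lines + 1 + (n_p > 0 ? 1 + n_p : 0) +
                  sh.n_f + n_m + 1;
  NumericMatrix draws(std::max((long long)0, n_draws), base_cols);
  long long drawn = 0;

  std::vector<int> vtmp(n_c);
  std::vector<double> qtmp(n_c);

  long long total_it = n_burn + n_samp;
  for (long long it = 0; it < total_it; ++it) {
    bool in_burn = it < n_burn;
    Block& b = blocks[it % nblocks];
    bool accept = false;
    double delta = 0.0, dcat = 0.0, dobs = 0.0, dplate = 0.0;

    switch (b.type) {
      case MC_M: {
        int j = b.index, a = m[j];
        int bcat = (int)(unif_rand() * (n_c - 1));
        if (bcat >= a) bcat += 1;
        vtmp = v;
        vtmp[a] -= 1;
        vtmp[bcat] += 1;
        double ct_new = cat_term(vtmp, q, n_m, as_printed);
        dcat = ct_new - ll_cat;
        double de = e[bcat] - e[a];
        dobs = (de != 0.0) ? sh.delta_obs_shift(carriers[j], -de) : 0.0;
        delta = dcat + dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          if (de != 0.0) sh.commit_shift(carriers[j], -de);
          for (int i : carriers[j]) {
            C[(size_t)i * n_c + a] -= 1;
            C[(size_t)i * n_c + bcat] += 1;
          }
          v = vtmp;
          m[j] = bcat;
          ll_cat += dcat;
          ll_obs += dobs;
        }
        break;
      }
      case MC_E: {
        int k = b.index;
        double prop = e[k] + norm_rand() * b.scale;
        if (std::fabs(prop) <= e_max) {
          double de = prop - e[k];
          sh.tS1 = sh.S1;
          sh.tS2 = sh.S2;
          for (int i = 0; i < n_b; ++i) {
            int c = C[(size_t)i * n_c + k];
            if (c) {
              double dd = -c * de;
              int l = sh.line[i];
              sh.tS1[l] += dd;
              sh.tS2[l] += dd * (2.0 * sh.d[i] + dd);
            }
          }
          dobs = sh.obs_term_sums(sh.tS1, sh.tS2, sh.ybar, sh.Ve) - ll_obs;
          delta = dobs;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            for (int i = 0; i < n_b; ++i) {
              int c = C[(size_t)i * n_c + k];
              if (c) sh.d[i] += -c * de;
            }
            sh.S1 = sh.tS1;
            sh.S2 = sh.tS2;
            e[k] = prop;
            ll_obs += dobs;
          }
        }
        break;
      }
      case MC_Q: {
        int k = b.index;
        double prop = q[k] + (2.0 * unif_rand() - 1.0) * b.scale;
        if (prop >= 0.0) {
          double rest = 0.0;
          for (int kk = 1; kk < n_c; ++kk) rest += (kk == k) ? prop : q[kk];
          if (rest < 1.0) {
            qtmp = q;
            qtmp[k] = prop;
            qtmp[0] = 1.0 - rest;
            double ct_new = cat_term(v, qtmp, n_m, as_printed);
            dcat = ct_new - ll_cat;
            delta = dcat;
            if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
              accept = true;
              q = qtmp;
              ll_cat += dcat;
            }
          }
        }
        break;
      }
      case MC_F: {
        int j = b.index;
        double df = norm_rand() * b.scale;
        dobs = sh.delta_obs_shift(sh.fix_carriers[j], -df);
        delta = dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.commit_shift(sh.fix_carriers[j], -df);
          sh.f[j] += df;
          ll_obs += dobs;
        }
        break;
      }
      case MC_P: {
        int k = b.index;
        double dp = norm_rand() * b.scale;
        double pnew = sh.p[k] + dp;
        dplate = -(pnew * pnew - sh.p[k] * sh.p[k]) / (2.0 * sh.Vp);
        dobs = sh.delta_obs_shift(sh.plate_obs[k], -dp);
        delta = dplate + dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.commit_shift(sh.plate_obs[k], -dp);
          sh.Sp2 += pnew * pnew - sh.p[k] * sh.p[k];
          sh.p[k] = pnew;
          ll_plate += dplate;
          ll_obs += dobs;
        }
        break;
      }
      case MC_VP: {
        double vnew = sh.Vp * std::exp(norm_rand() * b.scale);
        if (vnew > 0.0 && R_FINITE(vnew)) {
          double pt_new = -0.5 * n_p * (LOG2PI + std::log(vnew)) -
                          sh.Sp2 / (2.0 * vnew);
          dplate = pt_new - ll_plate;
          delta = dplate;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            sh.Vp = vnew;
            ll_plate = pt_new;
          }
        }
        break;
      }
      case MC_YBAR: {
        int l = b.index;
        double prop = sh.ybar[l] + norm_rand() * b.scale;
        std::vector<double> yb = sh.ybar;
        yb[l] = prop;
        double ot_new = sh.obs_term_sums(sh.S1, sh.S2, yb, sh.Ve);
        dobs = ot_new - ll_obs;
        delta = dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.ybar[l] = prop;
          ll_obs = ot_new;
        }
        break;
      }
      case MC_VE: {
        double vnew = sh.Ve * std::exp(norm_rand() * b.scale);
        if (vnew > 0.0 && R_FINITE(vnew)) {
          double ot_new = sh.obs_term_sums(sh.S1, sh.S2, sh.ybar, vnew);
          dobs = ot_new - ll_obs;
          delta = dobs;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            sh.Ve = vnew;
            ll_obs = ot_new;
          }
        }
        break;
      }
    }

    b.prop_win += 1;
    if (accept) b.acc_win += 1;
    if (!in_burn) {
      b.prop_tot += 1;
      if (accept) b.acc_tot += 1;
    }
    if (in_burn) tune_block(b, tune_window);

    if (refresh > 0 && (it + 1) % refresh == 0) {
      for (int i = 0; i < n_b; ++i) g[i] = 0.0;
      for (int j = 0; j < n_m; ++j) {
        double ej = e[m[j]];
        if (ej != 0.0)
          for (int i : carriers[j]) g[i] += ej;
      }
      sh.refresh(g);
      ll_cat = cat_term(v, q, n_m, as_printed);
      ll_obs = sh.obs_term();
      ll_plate = sh.plate_term();
    }

    if (!in_burn && thin_ll > 0 && ((it - n_burn + 1) % thin_ll == 0) &&
        drawn < n_draws) {
      int col = 0;
      for (int k = 1; k < n_c; ++k) draws(drawn, col++) = e[k];
      for (int k = 1; k < n_c; ++k) draws(drawn, col++) = q[k];
      for (int l = 0; l < n_lines; ++l) draws(drawn, col++) = sh.ybar[l];
      draws(drawn, col++) = sh.Ve;
      if (n_p > 0) {
        draws(drawn, col++) = sh.Vp;
        for (int k = 0; k < n_p; ++k) draws(drawn, col++) = sh.p[k];
      }
      for (int j = 0; j < sh.n_f; ++j) draws(drawn, col++) = sh.f[j];
      for (int j = 0; j < n_m; ++j) draws(drawn, col++) = (double)m[j];
      draws(drawn, col++) = ll_cat + ll_obs + ll_plate;
      drawn += 1;
    }
    if ((it & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<std::string> type_names = {"m", "e", "q", "f", "p",
                                         "V_p", "ybar", "V_e"};
  return List::create(_["draws"] = draws,
                      _["acceptance"] = acceptance_summary(blocks, type_names),
                      _["n_draws"] = (double)drawn);
}

// ---------------------------------------------------------------------------
// Two-sided gamma sampler
// ---------------------------------------------------------------------------

enum { GM_MU = 0, GM_ESEL, GM_Q0, GM_MEAN, GM_SHAPE, GM_F, GM_P, GM_VP,
       GM_YBAR, GM_VE, GM_NTYPES };

// side-count part: as printed, sum_j log q[mu_j] + log binomial(q0, v0)
static double side_term(int v0, int n_m, double q0, bool as_printed) {
  if (q0 <= 0.0 || q0 >= 1.0) return R_NegInf;
  int v1 = n_m - v0;
  double lq = v0 * std::log(q0) + v1 * std::log(1.0 - q0);
  double lcoef = std::lgamma(n_m + 1.0) - std::lgamma(v0 + 1.0) -
                 std::lgamma(v1 + 1.0);
  return (as_printed ? 2.0 * lq : lq) + lcoef;
}

// [[Rcpp::export]]
List mcmc_gamma_cpp(NumericVector y, IntegerMatrix M, IntegerMatrix F,
                    IntegerVector plate, int n_p, IntegerVector line,
                    int n_lines, bool same_mean, bool same_shape,
                    double mean_max, double shape_min, double shape_max,
                    double burnin, double sampling, double thin,
                    bool as_printed, int tune_window, double refresh_every,
                    Nullable<List> init = R_NilValue) {
  SharedModel sh;
  sh.setup(y, F, plate, n_p, line, n_lines);
  int n_b = sh.n_b, n_m = M.ncol();

  std::vector<std::vector<int>> carriers(n_m);
  for (int j = 0; j < n_m; ++j)
    for (int i = 0; i < n_b; ++i)
      if (M(i, j) == 1) carriers[j].push_back(i);

  // state: init means/shapes mid-prior-ish, magnitudes from the implied
  // gamma, sides at random
  double mean[2], shape[2];
  mean[0] = mean[1] = mean_max / 5.0;
  shape[0] = shape[1] = 1.0;
  double q0 = 0.5;
  std::vector<int> mu(n_m);
  std::vector<double> E0(n_m), E1(n_m);  // magnitudes per side
  for (int j = 0; j < n_m; ++j) {
    mu[j] = (unif_rand() < 0.5) ? 0 : 1;
    E0[j] = R::rgamma(shape[0], mean[0] / shape[0]);
    E1[j] = R::rgamma(shape[1], mean[1] / shape[1]);
    if (E0[j] <= 0) E0[j] = mean[0];
    if (E1[j] <= 0) E1[j] = mean[1];
  }
  if (init.isNotNull()) {
    List in(init);
    if (in.containsElementNamed("mu")) {
      IntegerVector mu0 = in["mu"];
      for (int j = 0; j < n_m; ++j) mu[j] = mu0[j];
    }
    if (in.containsElementNamed("E")) {
      NumericMatrix Ein = in["E"];
      for (int j = 0; j < n_m; ++j) {
        E0[j] = Ein(0, j);
        E1[j] = Ein(1, j);
      }
    }
    if (in.containsElementNamed("mean")) {
      NumericVector m0 = in["mean"];
      mean[0] = m0[0]; mean[1] = m0[1];
    }
    if (in.containsElementNamed("shape")) {
      NumericVector s0 = in["shape"];
      shape[0] = s0[0]; shape[1] = s0[1];
    }
    if (in.containsElementNamed("q_neg")) q0 = as<double>(in["q_neg"]);
  }
  int v0 = 0;
  for (int j = 0; j < n_m; ++j) v0 += (mu[j] == 0);

  std::vector<double> g(n_b, 0.0);
  for (int j = 0; j < n_m; ++j) {
    double s = (mu[j] == 0) ? -E0[j] : E1[j];
    for (int i : carriers[j]) g[i] += s;
  }
  sh.refresh(g);

  std::vector<double> pdf_j(n_m);
  double ll_pdf = 0.0;
  for (int j = 0; j < n_m; ++j) {
    double x = (mu[j] == 0) ? E0[j] : E1[j];
    pdf_j[j] = lgamma_pdf(x, mean[mu[j]], shape[mu[j]]);
    ll_pdf += pdf_j[j];
  }
  double ll_side = side_term(v0, n_m, q0, as_printed);
  double ll_obs = sh.obs_term();
  double ll_plate = sh.plate_term();

  std::vector<Block> blocks;
  for (int j = 0; j < n_m; ++j) blocks.push_back({GM_MU, j, 0.0});
  for (int j = 0; j < n_m; ++j) blocks.push_back({GM_ESEL, j, 0.05});
  blocks.push_back({GM_Q0, 0, 0.1});
  blocks.push_back({GM_MEAN, 0, 0.05});
  if (!same_mean) blocks.push_back({GM_MEAN, 1, 0.05});
  blocks.push_back({GM_SHAPE, 0, 0.5});
  if (!same_shape) blocks.push_back({GM_SHAPE, 1, 0.5});
  for (int j = 0; j < sh.n_f; ++j) blocks.push_back({GM_F, j, 0.1});
  for (int k = 0; k < n_p; ++k) blocks.push_back({GM_P, k, 0.1});
  if (n_p > 0) blocks.push_back({GM_VP, 0, 0.5});
  if (n_b > 0) {
    for (int l = 0; l < n_lines; ++l) blocks.push_back({GM_YBAR, l, 0.1});
    blocks.push_back({GM_VE, 0, 0.5});
  }
  if (blocks.empty()) stop("model has no free variables");
  int nblocks = blocks.size();

  long long n_burn = (long long)burnin;
  long long n_samp = (long long)sampling;
  long long thin_ll = (long long)thin;
  long long n_draws = (thin_ll > 0) ? n_samp / thin_ll : 0;
  long long refresh = (long long)refresh_every;

  int base_cols = 5 + n_lines + 1 + (n_p > 0 ? 1 + n_p : 0) + sh.n_f +
                  n_m + 1;
  NumericMatrix draws(std::max((long long)0, n_draws), base_cols);
  long long drawn = 0;

  long long total_it = n_burn + n_samp;
  for (long long it = 0; it < total_it; ++it) {
    bool in_burn = it < n_burn;
    Block& b = blocks[it % nblocks];
    bool accept = false;
    double delta = 0.0, dobs = 0.0;

    switch (b.type) {
      case GM_MU: {
        int j = b.index, a = mu[j], bn = 1 - a;
        double Ea = (a == 0) ? E0[j] : E1[j];
        double Eb = (bn == 0) ? E0[j] : E1[j];
        double sa = (a == 0) ? -Ea : Ea;
        double sb = (bn == 0) ? -Eb : Eb;
        double pdf_new = lgamma_pdf(Eb, mean[bn], shape[bn]);
        double dpdf = pdf_new - pdf_j[j];
        int v0_new = v0 + ((bn == 0) ? 1 : -1);
        double st_new = side_term(v0_new, n_m, q0, as_printed);
        double dside = st_new - ll_side;
        double dg = sb - sa;
        dobs = sh.delta_obs_shift(carriers[j], -dg);
        delta = dpdf + dside + dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.commit_shift(carriers[j], -dg);
          mu[j] = bn;
          v0 = v0_new;
          pdf_j[j] = pdf_new;
          ll_pdf += dpdf;
          ll_side = st_new;
          ll_obs += dobs;
        }
        break;
      }
      case GM_ESEL: {
        int j = b.index, a = mu[j];
        double Ea = (a == 0) ? E0[j] : E1[j];
        double prop = Ea + norm_rand() * b.scale;
        if (prop > 0.0) {
          double pdf_new = lgamma_pdf(prop, mean[a], shape[a]);
          double dpdf = pdf_new - pdf_j[j];
          double dg = ((a == 0) ? -prop : prop) - ((a == 0) ? -Ea : Ea);
          dobs = sh.delta_obs_shift(carriers[j], -dg);
          delta = dpdf + dobs;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            sh.commit_shift(carriers[j], -dg);
            if (a == 0) E0[j] = prop; else E1[j] = prop;
            pdf_j[j] = pdf_new;
            ll_pdf += dpdf;
            ll_obs += dobs;
          }
        }
        break;
      }
      case GM_Q0: {
        double prop = q0 + (2.0 * unif_rand() - 1.0) * b.scale;
        if (prop > 0.0 && prop < 1.0) {
          double st_new = side_term(v0, n_m, prop, as_printed);
          double dside = st_new - ll_side;
          delta = dside;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            q0 = prop;
            ll_side = st_new;
          }
        }
        break;
      }
      case GM_MEAN: {
        int s = b.index;
        double prop = mean[s] + norm_rand() * b.scale;
        if (prop > 0.0 && prop <= mean_max) {
          double m_new[2] = {mean[0], mean[1]};
          m_new[s] = prop;
          if (same_mean) m_new[1 - s] = prop;
          double dpdf = 0.0;
          std::vector<double> pdf_new(n_m);
          for (int j = 0; j < n_m; ++j) {
            int side = mu[j];
            if (m_new[side] != mean[side]) {
              double x = (side == 0) ? E0[j] : E1[j];
              pdf_new[j] = lgamma_pdf(x, m_new[side], shape[side]);
              dpdf += pdf_new[j] - pdf_j[j];
            } else pdf_new[j] = pdf_j[j];
          }
          delta = dpdf;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            mean[0] = m_new[0];
            mean[1] = m_new[1];
            pdf_j = pdf_new;
            ll_pdf += dpdf;
          }
        }
        break;
      }
      case GM_SHAPE: {
        int s = b.index;
        double prop = shape[s] + norm_rand() * b.scale;
        if (prop >= shape_min && prop <= shape_max) {
          double s_new[2] = {shape[0], shape[1]};
          s_new[s] = prop;
          if (same_shape) s_new[1 - s] = prop;
          double dpdf = 0.0;
          std::vector<double> pdf_new(n_m);
          for (int j = 0; j < n_m; ++j) {
            int side = mu[j];
            if (s_new[side] != shape[side]) {
              double x = (side == 0) ? E0[j] : E1[j];
              pdf_new[j] = lgamma_pdf(x, mean[side], s_new[side]);
              dpdf += pdf_new[j] - pdf_j[j];
            } else pdf_new[j] = pdf_j[j];
          }
          delta = dpdf;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            shape[0] = s_new[0];
            shape[1] = s_new[1];
            pdf_j = pdf_new;
            ll_pdf += dpdf;
          }
        }
        break;
      }
      case GM_F: {
        int j = b.index;
        double df = norm_rand() * b.scale;
        dobs = sh.delta_obs_shift(sh.fix_carriers[j], -df);
        delta = dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.commit_shift(sh.fix_carriers[j], -df);
          sh.f[j] += df;
          ll_obs += dobs;
        }
        break;
      }
      case GM_P: {
        int k = b.index;
        double dp = norm_rand() * b.scale;
        double pnew = sh.p[k] + dp;
        double dplate = -(pnew * pnew - sh.p[k] * sh.p[k]) / (2.0 * sh.Vp);
        dobs = sh.delta_obs_shift(sh.plate_obs[k], -dp);
        delta = dplate + dobs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.commit_shift(sh.plate_obs[k], -dp);
          sh.Sp2 += pnew * pnew - sh.p[k] * sh.p[k];
          sh.p[k] = pnew;
          ll_plate += dplate;
          ll_obs += dobs;
        }
        break;
      }
      case GM_VP: {
        double vnew = sh.Vp * std::exp(norm_rand() * b.scale);
        if (vnew > 0.0 && R_FINITE(vnew)) {
          double pt_new = -0.5 * n_p * (LOG2PI + std::log(vnew)) -
                          sh.Sp2 / (2.0 * vnew);
          delta = pt_new - ll_plate;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            sh.Vp = vnew;
            ll_plate = pt_new;
          }
        }
        break;
      }
      case GM_YBAR: {
        int l = b.index;
        double prop = sh.ybar[l] + norm_rand() * b.scale;
        std::vector<double> yb = sh.ybar;
        yb[l] = prop;
        double ot_new = sh.obs_term_sums(sh.S1, sh.S2, yb, sh.Ve);
        delta = ot_new - ll_obs;
        if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
          accept = true;
          sh.ybar[l] = prop;
          ll_obs = ot_new;
        }
        break;
      }
      case GM_VE: {
        double vnew = sh.Ve * std::exp(norm_rand() * b.scale);
        if (vnew > 0.0 && R_FINITE(vnew)) {
          double ot_new = sh.obs_term_sums(sh.S1, sh.S2, sh.ybar, vnew);
          delta = ot_new - ll_obs;
          if (R_FINITE(delta) && std::log(unif_rand()) < delta) {
            accept = true;
            sh.Ve = vnew;
            ll_obs = ot_new;
          }
        }
        break;
      }
    }

    b.prop_win += 1;
    if (accept) b.acc_win += 1;
    if (!in_burn) {
      b.prop_tot += 1;
      if (accept) b.acc_tot += 1;
    }
    if (in_burn) tune_block(b, tune_window);

    if (refresh > 0 && (it + 1) % refresh == 0) {
      for (int i = 0; i < n_b; ++i) g[i] = 0.0;
      for (int j = 0; j < n_m; ++j) {
        double s = (mu[j] == 0) ? -E0[j] : E1[j];
        for (int i : carriers[j]) g[i] += s;
      }
      sh.refresh(g);
      ll_pdf = 0.0;
      for (int j = 0; j < n_m; ++j) {
        double x = (mu[j] == 0) ? E0[j] : E1[j];
        pdf_j[j] = lgamma_pdf(x, mean[mu[j]], shape[mu[j]]);
        ll_pdf += pdf_j[j];
      }
      ll_side = side_term(v0, n_m, q0, as_printed);
      ll_obs = sh.obs_term();
      ll_plate = sh.plate_term();
    }

    if (!in_burn && thin_ll > 0 && ((it - n_burn + 1) % thin_ll == 0) &&
        drawn < n_draws) {
      int col = 0;
      draws(drawn, col++) = mean[0];
      draws(drawn, col++) = mean[1];
      draws(drawn, col++) = shape[0];
      draws(drawn, col++) = shape[1];
      draws(drawn, col++) = 1.0 - q0;
      for (int l = 0; l < n_lines; ++l) draws(drawn, col++) = sh.ybar[l];
      draws(drawn, col++) = sh.Ve;
      if (n_p > 0) {
        draws(drawn, col++) = sh.Vp;
        for (int k = 0; k < n_p; ++k) draws(drawn, col++) = sh.p[k];
      }
      for (int j = 0; j < sh.n_f; ++j) draws(drawn, col++) = sh.f[j];
      for (int j = 0; j < n_m; ++j)
        draws(drawn, col++) = (mu[j] == 0) ? -E0[j] : E1[j];
      draws(drawn, col++) = ll_pdf + ll_side + ll_obs + ll_plate;
      drawn += 1;
    }
    if ((it & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<std::string> type_names = {"mu", "E", "q", "mean", "shape",
                                         "f", "p", "V_p", "ybar", "V_e"};
  return List::create(_["draws"] = draws,
                      _["acceptance"] = acceptance_summary(blocks, type_names),
                      _["n_draws"] = (double)drawn);
}
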