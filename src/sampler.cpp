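// Adaptive random-walk Metropolis-within-Gibbs sampler for the package's
// hierarchical GLMMs: binomial (logit), Gaussian, multinomial logit
// (reference category 0) and zero-inflated negative binomial, each with up
// to three crossed Gaussian random-effect factors.
//
// Scalar parameters are updated one at a time with per-parameter proposal
// scales adapted toward a 44% acceptance rate during burn-in only. Linear
// predictors, per-category exponentials (multinomial) and per-row
// log-likelihood terms are cached and updated incrementally over only the
// rows a proposal touches; sparse design columns (state dummies,
// interactions) visit just their non-zero rows. Random-effect SDs get both
// a centred conditional update and a non-centred interweaving (rescale)
// move, which keeps the hyper-SD chains mixing when per-level information
// is weak. Caches are refreshed periodically to stop numerical drift.
//
// Priors: fixed effects N(m_beta, s_beta^2); random-effect SDs
// half-N(0, s_re^2); Gaussian residual SD half-N(0, s_sigma^2); ZINB
// log-dispersion N(0, s_logphi^2). Hyper-SDs are sampled on the log scale
// (Jacobian included). Constants independent of the parameters are dropped.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Family { BINOM = 1, GAUSS = 2, MULTINOM = 3, ZINB = 4 };

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -18.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct Chain {
  int family, n, p, pz, K, F;
  std::vector<double> Xc, Xzc;          // column-major copies of X, Xz
  std::vector<double> y, trials;
  std::vector<std::vector<int> > nz;    // per design column: non-zero rows
  std::vector<bool> is_binary;          // design column is 0/1
  std::vector<int> reidx;               // F * n level indices (f-major)
  std::vector<int> nlev;
  std::vector<std::vector<std::vector<int> > > rows; // rows[f][level]

  std::vector<double> beta, zbeta;      // p*K (k-major), pz
  double aux;                           // log sigma / log phi
  bool has_aux;
  std::vector<double> log_sd;
  std::vector<std::vector<double> > u;  // u[f]: nlev[f]*K (k-major)

  std::vector<double> eta;              // K*n
  std::vector<double> etaz;             // n
  std::vector<double> E;                // K*n: exp(eta) (multinomial only)
  std::vector<double> S;                // n: sum_k E (multinomial only)
  std::vector<double> rowll;            // n
  double ll;

  double m_beta, s_beta, s_re, s_sigma, s_logphi;

  // scratch for staged single-column proposals
  std::vector<double> tE, tS, tll, teta;

  double row_ll_general(int i, double eta_i, double etaz_i, double aux_) const {
    switch (family) {
    case BINOM:
      return y[i] * eta_i - trials[i] * log1p_exp(eta_i);
    case GAUSS: {
      double sig = std::exp(aux_);
      double r = y[i] - eta_i;
      return -aux_ - 0.5 * r * r / (sig * sig);
    }
    case ZINB: {
      double phi = std::exp(aux_);
      double mu = std::exp(eta_i);
      double pi = 1.0 / (1.0 + std::exp(-etaz_i));
      double k = y[i];
      double lnb = std::lgamma(k + phi) - std::lgamma(phi) - std::lgamma(k + 1.0)
        + phi * std::log(phi / (phi + mu)) + k * std::log(mu / (phi + mu));
      if (k == 0.0) {
        double v = pi + (1.0 - pi) * std::exp(lnb);
        return std::log(v > 1e-300 ? v : 1e-300);
      }
      return std::log1p(-pi) + lnb;
    }
    }
    return NA_REAL;
  }

  void refresh() {
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < p; ++j) e += Xc[j * n + i] * beta[k * p + j];
        for (int f = 0; f < F; ++f) e += u[f][k * nlev[f] + reidx[f * n + i]];
        eta[k * n + i] = e;
      }
    if (family == ZINB)
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < pz; ++j) e += Xzc[j * n + i] * zbeta[j];
        etaz[i] = e;
      }
    ll = 0.0;
    if (family == MULTINOM) {
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < n; ++i) E[k * n + i] = std::exp(eta[k * n + i]);
      for (int i = 0; i < n; ++i) {
        double sum = 0.0;
        for (int k = 0; k < K; ++k) sum += E[k * n + i];
        S[i] = sum;
        int yi = (int) y[i];
        double v = -std::log1p(sum);
        if (yi > 0) v += eta[(yi - 1) * n + i];
        rowll[i] = v;
        ll += v;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        rowll[i] = row_ll_general(i, eta[i], etaz[i], aux);
        ll += rowll[i];
      }
    }
  }

  // stage a proposal adding delta(t, i) to eta column k over rows rr;
  // returns the log-likelihood change, caching new values in scratch
  template <class DeltaFun>
  double stage(int k, const std::vector<int>& rr, DeltaFun delta) {
    double dll = 0.0;
    if (family == MULTINOM) {
      for (size_t t = 0; t < rr.size(); ++t) {
        int i = rr[t];
        double d = delta(t, i);
        double e_new = E[k * n + i] * std::exp(d);
        double s_new = S[i] - E[k * n + i] + e_new;
        teta[t] = eta[k * n + i] + d;
        tE[t] = e_new; tS[t] = s_new;
        int yi = (int) y[i];
        double v = -std::log1p(s_new);
        if (yi > 0) v += (yi - 1 == k) ? teta[t] : eta[(yi - 1) * n + i];
        tll[t] = v;
        dll += v - rowll[i];
      }
    } else {
      for (size_t t = 0; t < rr.size(); ++t) {
        int i = rr[t];
        teta[t] = eta[i] + delta(t, i);
        tll[t] = row_ll_general(i, teta[t], etaz[i], aux);
        dll += tll[t] - rowll[i];
      }
    }
    return dll;
  }

  void commit(int k, const std::vector<int>& rr) {
    if (family == MULTINOM) {
      for (size_t t = 0; t < rr.size(); ++t) {
        int i = rr[t];
        eta[k * n + i] = teta[t];
        E[k * n + i] = tE[t];
        S[i] = tS[t];
        rowll[i] = tll[t];
      }
    } else {
      for (size_t t = 0; t < rr.size(); ++t) {
        int i = rr[t];
        eta[i] = teta[t];
        rowll[i] = tll[t];
      }
    }
  }
};

// [[Rcpp::export]]
List mwg_chain(List data, List prior, List ctrl) {
  Chain s;
  s.family = as<int>(data["family"]);
  NumericMatrix X = as<NumericMatrix>(data["X"]);
  NumericVector yv = as<NumericVector>(data["y"]);
  s.n = X.nrow(); s.p = X.ncol();
  s.K = as<int>(data["K"]);
  s.y.assign(yv.begin(), yv.end());
  if (data.containsElementNamed("trials") && !Rf_isNull(data["trials"])) {
    NumericVector tv = as<NumericVector>(data["trials"]);
    s.trials.assign(tv.begin(), tv.end());
  } else s.trials.assign(s.n, 1.0);
  s.Xc.assign((size_t) s.p * s.n, 0.0);
  for (int j = 0; j < s.p; ++j)
    for (int i = 0; i < s.n; ++i) s.Xc[j * s.n + i] = X(i, j);
  s.pz = 0;
  if (s.family == ZINB && data.containsElementNamed("Xz") && !Rf_isNull(data["Xz"])) {
    NumericMatrix Xz = as<NumericMatrix>(data["Xz"]);
    s.pz = Xz.ncol();
    s.Xzc.assign((size_t) s.pz * s.n, 0.0);
    for (int j = 0; j < s.pz; ++j)
      for (int i = 0; i < s.n; ++i) s.Xzc[j * s.n + i] = Xz(i, j);
  }
  IntegerMatrix re = as<IntegerMatrix>(data["re"]);
  s.F = re.ncol();
  IntegerVector nl = as<IntegerVector>(data["nlev"]);
  s.nlev.assign(nl.begin(), nl.end());
  s.reidx.assign((size_t) s.F * s.n, 0);
  for (int f = 0; f < s.F; ++f)
    for (int i = 0; i < s.n; ++i) s.reidx[f * s.n + i] = re(i, f);
  s.rows.resize(s.F);
  for (int f = 0; f < s.F; ++f) {
    s.rows[f].assign(s.nlev[f], std::vector<int>());
    for (int i = 0; i < s.n; ++i) s.rows[f][s.reidx[f * s.n + i]].push_back(i);
  }

  s.nz.resize(s.p);
  s.is_binary.assign(s.p, true);
  for (int j = 0; j < s.p; ++j) {
    for (int i = 0; i < s.n; ++i) {
      double x = s.Xc[j * s.n + i];
      if (x != 0.0) {
        s.nz[j].push_back(i);
        if (x != 1.0) s.is_binary[j] = false;
      }
    }
  }

  s.m_beta = as<double>(prior["beta_mean"]);
  s.s_beta = as<double>(prior["beta_sd"]);
  s.s_re = as<double>(prior["re_sd_scale"]);
  s.s_sigma = as<double>(prior["sigma_scale"]);
  s.s_logphi = as<double>(prior["logphi_sd"]);

  int iterations = as<int>(ctrl["iterations"]);
  int burn_in = as<int>(ctrl["burn_in"]);
  int thin = as<int>(ctrl["thin"]);

  s.beta.assign(s.p * s.K, 0.0);
  s.zbeta.assign(s.pz, 0.0);
  s.has_aux = (s.family == GAUSS || s.family == ZINB);
  if (s.family == GAUSS) {
    double m = 0.0, v = 0.0;
    for (int i = 0; i < s.n; ++i) m += s.y[i];
    m /= s.n;
    for (int i = 0; i < s.n; ++i) v += (s.y[i] - m) * (s.y[i] - m);
    s.aux = 0.5 * std::log(v / std::max(s.n - 1, 1) + 1e-8);
  } else s.aux = 0.0;
  s.log_sd.assign(s.F, std::log(0.5));
  s.u.resize(s.F);
  for (int f = 0; f < s.F; ++f) s.u[f].assign(s.nlev[f] * s.K, 0.0);
  s.eta.assign((size_t) s.n * s.K, 0.0);
  s.etaz.assign(s.n, 0.0);
  s.E.assign(s.family == MULTINOM ? (size_t) s.n * s.K : 0, 0.0);
  s.S.assign(s.family == MULTINOM ? s.n : 0, 0.0);
  s.rowll.assign(s.n, 0.0);
  s.tE.assign(s.n, 0.0); s.tS.assign(s.n, 0.0);
  s.tll.assign(s.n, 0.0); s.teta.assign(s.n, 0.0);
  s.refresh();
  if (!std::isfinite(s.ll)) stop("non-finite log-likelihood at initialization");

  std::vector<double> sc_beta(s.p * s.K, 0.3), sc_zbeta(s.pz, 0.3);
  std::vector<std::vector<double> > sc_u(s.F);
  for (int f = 0; f < s.F; ++f) sc_u[f].assign(s.nlev[f] * s.K, 0.5);
  std::vector<double> sc_logsd(s.F, 0.4), sc_asis(s.F, 0.3);
  double sc_aux = 0.2;
  const double astep = 0.08, target = 0.44;

  int n_keep = (iterations - burn_in + thin - 1) / thin;
  int n_par = s.p * s.K + s.pz + (s.has_aux ? 1 : 0) + s.F;
  NumericMatrix draws(n_keep, n_par);
  std::vector<double> prop(s.n);
  // interweaving-move scratch (whole-data staging across all K columns)
  std::vector<double> w_eta((size_t) s.n * s.K), w_E((size_t) s.n * s.K),
    w_S(s.n), w_ll(s.n);
  int stored = 0;

  // two fixed-effect sweeps per iteration: single-site updates of
  // correlated coefficients (state intercepts vs age terms) are the
  // slowest-mixing directions, and the extra sweep roughly halves their
  // autocorrelation for a modest share of total cost
  int beta_sweeps = 2;

  for (int it = 0; it < iterations; ++it) {
    bool adapting = it < burn_in;

    // ---- fixed effects ----
    for (int sweep = 0; sweep < beta_sweeps; ++sweep)
    for (int k = 0; k < s.K; ++k)
      for (int j = 0; j < s.p; ++j) {
        int idx = k * s.p + j;
        double delta = R::rnorm(0.0, sc_beta[idx]);
        double bnew = s.beta[idx] + delta;
        const std::vector<int>& rr = s.nz[j];
        const double* xj = &s.Xc[(size_t) j * s.n];
        double dll = s.is_binary[j]
          ? s.stage(k, rr, [&](size_t, int) { return delta; })
          : s.stage(k, rr, [&](size_t, int i) { return delta * xj[i]; });
        double dpr = (-0.5 * (bnew - s.m_beta) * (bnew - s.m_beta)
                      + 0.5 * (s.beta[idx] - s.m_beta) * (s.beta[idx] - s.m_beta))
                     / (s.s_beta * s.s_beta);
        bool acc = std::log(R::runif(0.0, 1.0)) < (dll + dpr);
        if (acc) { s.beta[idx] = bnew; s.commit(k, rr); s.ll += dll; }
        if (adapting) sc_beta[idx] *= std::exp(astep * ((acc ? 1.0 : 0.0) - target));
      }

    // ---- zero-part coefficients (zinb) ----
    for (int j = 0; j < s.pz; ++j) {
      double delta = R::rnorm(0.0, sc_zbeta[j]);
      double bnew = s.zbeta[j] + delta;
      double llnew = 0.0;
      for (int i = 0; i < s.n; ++i) {
        prop[i] = s.etaz[i] + s.Xzc[j * s.n + i] * delta;
        llnew += s.row_ll_general(i, s.eta[i], prop[i], s.aux);
      }
      double dpr = (-0.5 * bnew * bnew + 0.5 * s.zbeta[j] * s.zbeta[j])
                   / (s.s_beta * s.s_beta);
      bool acc = std::log(R::runif(0.0, 1.0)) < (llnew - s.ll + dpr);
      if (acc) {
        s.zbeta[j] = bnew;
        for (int i = 0; i < s.n; ++i) s.etaz[i] = prop[i];
        s.ll = llnew;
        for (int i = 0; i < s.n; ++i)
          s.rowll[i] = s.row_ll_general(i, s.eta[i], s.etaz[i], s.aux);
      }
      if (adapting) sc_zbeta[j] *= std::exp(astep * ((acc ? 1.0 : 0.0) - target));
    }

    // ---- auxiliary scale parameter ----
    if (s.has_aux) {
      double anew = s.aux + R::rnorm(0.0, sc_aux);
      double llnew = 0.0;
      for (int i = 0; i < s.n; ++i)
        llnew += s.row_ll_general(i, s.eta[i], s.etaz[i], anew);
      double dpr;
      if (s.family == GAUSS) {
        double s0 = std::exp(s.aux), s1 = std::exp(anew);
        dpr = (-0.5 * s1 * s1 + 0.5 * s0 * s0) / (s.s_sigma * s.s_sigma)
              + (anew - s.aux);
      } else {
        dpr = (-0.5 * anew * anew + 0.5 * s.aux * s.aux)
              / (s.s_logphi * s.s_logphi);
      }
      bool acc = std::log(R::runif(0.0, 1.0)) < (llnew - s.ll + dpr);
      if (acc) {
        s.aux = anew; s.ll = llnew;
        for (int i = 0; i < s.n; ++i)
          s.rowll[i] = s.row_ll_general(i, s.eta[i], s.etaz[i], s.aux);
      }
      if (adapting) sc_aux *= std::exp(astep * ((acc ? 1.0 : 0.0) - target));
    }

    // ---- random-effect latents (centred) ----
    for (int f = 0; f < s.F; ++f) {
      double sdf = std::exp(s.log_sd[f]);
      for (int k = 0; k < s.K; ++k)
        for (int l = 0; l < s.nlev[f]; ++l) {
          int idx = k * s.nlev[f] + l;
          const std::vector<int>& rr = s.rows[f][l];
          double delta = R::rnorm(0.0, sc_u[f][idx]);
          double uold = s.u[f][idx], unew = uold + delta;
          double dll = s.stage(k, rr, [&](size_t, int) { return delta; });
          double dpr = (-0.5 * unew * unew + 0.5 * uold * uold) / (sdf * sdf);
          bool acc = std::log(R::runif(0.0, 1.0)) < (dll + dpr);
          if (acc) { s.u[f][idx] = unew; s.commit(k, rr); s.ll += dll; }
          if (adapting) sc_u[f][idx] *= std::exp(astep * ((acc ? 1.0 : 0.0) - target));
        }
    }

    // ---- random-effect SDs: centred conditional update ----
    for (int f = 0; f < s.F; ++f) {
      double lnew = s.log_sd[f] + R::rnorm(0.0, sc_logsd[f]);
      double s0 = std::exp(s.log_sd[f]), s1 = std::exp(lnew);
      int m = s.nlev[f] * s.K;
      double ss = 0.0;
      for (int t = 0; t < m; ++t) ss += s.u[f][t] * s.u[f][t];
      double lp1 = -m * lnew - 0.5 * ss / (s1 * s1)
        - 0.5 * s1 * s1 / (s.s_re * s.s_re) + lnew;
      double lp0 = -m * s.log_sd[f] - 0.5 * ss / (s0 * s0)
        - 0.5 * s0 * s0 / (s.s_re * s.s_re) + s.log_sd[f];
      bool acc = std::log(R::runif(0.0, 1.0)) < (lp1 - lp0);
      if (acc) s.log_sd[f] = lnew;
      if (adapting) sc_logsd[f] *= std::exp(astep * ((acc ? 1.0 : 0.0) - target));
    }

    // ---- random-effect SDs: interweaving (non-centred rescale) move ----
    // in (log sd, u/sd) coordinates the target is L(sd * utilde) x
    // N(utilde; 0, 1) x p(sd) x sd; propose log sd' and rescale all latents
    for (int f = 0; f < s.F; ++f) {
      double lnew = s.log_sd[f] + R::rnorm(0.0, sc_asis[f]);
      double s0 = std::exp(s.log_sd[f]), s1 = std::exp(lnew);
      double c = s1 / s0;
      double dll = 0.0;
      if (s.family == MULTINOM) {
        for (int i = 0; i < s.n; ++i) {
          int l = s.reidx[f * s.n + i];
          double Snew = 0.0;
          for (int k = 0; k < s.K; ++k) {
            double d = (c - 1.0) * s.u[f][k * s.nlev[f] + l];
            double en = s.eta[k * s.n + i] + d;
            double En = std::exp(en);
            w_eta[k * s.n + i] = en;
            w_E[k * s.n + i] = En;
            Snew += En;
          }
          w_S[i] = Snew;
          int yi = (int) s.y[i];
          double v = -std::log1p(Snew);
          if (yi > 0) v += w_eta[(yi - 1) * s.n + i];
          w_ll[i] = v;
          dll += v - s.rowll[i];
        }
      } else {
        for (int i = 0; i < s.n; ++i) {
          int l = s.reidx[f * s.n + i];
          double en = s.eta[i] + (c - 1.0) * s.u[f][l];
          w_eta[i] = en;
          w_ll[i] = s.row_ll_general(i, en, s.etaz[i], s.aux);
          dll += w_ll[i] - s.rowll[i];
        }
      }
      double dpr = (-0.5 * s1 * s1 + 0.5 * s0 * s0) / (s.s_re * s.s_re)
                   + (lnew - s.log_sd[f]);
      bool acc = std::log(R::runif(0.0, 1.0)) < (dll + dpr);
      if (acc) {
        s.log_sd[f] = lnew;
        int m = s.nlev[f] * s.K;
        for (int t = 0; t < m; ++t) s.u[f][t] *= c;
        s.eta = w_eta;
        if (s.family == MULTINOM) { s.E = w_E; s.S = w_S; }
        s.rowll = w_ll;
        s.ll += dll;
      }
      if (adapting) sc_asis[f] *= std::exp(astep * ((acc ? 1.0 : 0.0) - target));
    }

    if ((it + 1) % 500 == 0) s.refresh();

    if (it >= burn_in && (it - burn_in) % thin == 0 && stored < n_keep) {
      int col = 0;
      for (int k = 0; k < s.K; ++k)
        for (int j = 0; j < s.p; ++j) draws(stored, col++) = s.beta[k * s.p + j];
      for (int j = 0; j < s.pz; ++j) draws(stored, col++) = s.zbeta[j];
      if (s.has_aux) draws(stored, col++) = std::exp(s.aux);
      for (int f = 0; f < s.F; ++f) draws(stored, col++) = std::exp(s.log_sd[f]);
      ++stored;
    }
  }

  return List::create(_["draws"] = draws, _["loglik"] = s.ll);
}
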