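// Marginal log-likelihood and analytic score for the naive one-factor and
// vignette-adjusted two-factor probit graded response models.
//
// Latents are integrated by tensor-product Gauss-Hermite quadrature on the
// standardized scale (theta = mu_country + z). Category probabilities are
// cached per (country, item, rating, node) because persons sharing a
// response pattern cell reuse them. Gradients are accumulated per record
// from posterior node weights; probabilities are floored at 1e-300 so
// extreme optimizer proposals survive the log.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PROB_FLOOR = 1e-300;

// P(a < Z <= b), stable in both tails; a may be -Inf, b +Inf.
static inline double cdf_interval(double a, double b) {
  double p;
  if (a > 0.0)
    p = R::pnorm(a, 0.0, 1.0, 0, 0) - R::pnorm(b, 0.0, 1.0, 0, 0);
  else
    p = R::pnorm(b, 0.0, 1.0, 1, 0) - R::pnorm(a, 0.0, 1.0, 1, 0);
  return p > 0.0 ? p : 0.0;
}

struct CellTabs {
  // per (c, j, y, node): log prob, d/dm, d/dtau_lower, d/dtau_upper
  std::vector<double> logp, dm, dlo, dhi;
  int strideY, strideJ, strideC;
  void alloc(int C, int J, int G) {
    strideY = G; strideJ = 4 * G; strideC = J * strideJ;
    size_t n = (size_t)C * strideC;
    logp.assign(n, 0.0); dm.assign(n, 0.0);
    dlo.assign(n, 0.0); dhi.assign(n, 0.0);
  }
  inline size_t at(int c, int j, int y, int g) const {
    return (size_t)c * strideC + (size_t)j * strideJ + (size_t)y * strideY + g;
  }
};

// fill one (c, j) block of tables for G propensity means m[g] against
// thresholds t1 < t2 < t3
static void fill_block(CellTabs& T, int c, int j, const std::vector<double>& m,
                       double t1, double t2, double t3, bool want_grad) {
  const int G = (int)m.size();
  for (int g = 0; g < G; ++g) {
    double a1 = t1 - m[g], a2 = t2 - m[g], a3 = t3 - m[g];
    double d1 = R::dnorm(a1, 0.0, 1.0, 0), d2 = R::dnorm(a2, 0.0, 1.0, 0),
           d3 = R::dnorm(a3, 0.0, 1.0, 0);
    double P[4], lo[4], hi[4];
    P[0] = cdf_interval(R_NegInf, a1); lo[0] = 0.0; hi[0] = d1;
    P[1] = cdf_interval(a1, a2);       lo[1] = d1;  hi[1] = d2;
    P[2] = cdf_interval(a2, a3);       lo[2] = d2;  hi[2] = d3;
    P[3] = cdf_interval(a3, R_PosInf); lo[3] = d3;  hi[3] = 0.0;
    for (int y = 0; y < 4; ++y) {
      double Pf = P[y] > PROB_FLOOR ? P[y] : PROB_FLOOR;
      size_t k = T.at(c, j, y, g);
      T.logp[k] = std::log(Pf);
      if (want_grad) {
        T.dlo[k] = -lo[y] / Pf;          // d logP / d tau_lower
        T.dhi[k] = hi[y] / Pf;           // d logP / d tau_upper
        T.dm[k] = (lo[y] - hi[y]) / Pf;  // d logP / d m
      }
    }
  }
}

// Row-wise log-sum-exp with weights; converts L rows to posterior weights
// in place when want_grad.
static double rows_to_loglik(std::vector<double>& L, int n, int G,
                             const std::vector<double>& w2,
                             NumericVector& pll, bool want_grad) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double* row = &L[(size_t)i * G];
    double M = row[0];
    for (int g = 1; g < G; ++g) if (row[g] > M) M = row[g];
    double s = 0.0;
    for (int g = 0; g < G; ++g) s += w2[g] * std::exp(row[g] - M);
    double ll = M + std::log(s);
    pll[i] = ll;
    total += ll;
    if (want_grad)
      for (int g = 0; g < G; ++g)
        row[g] = w2[g] * std::exp(row[g] - M) / s;
  }
  return total;
}

// [[Rcpp::export]]
List adjusted_loglik_cpp(IntegerVector p_country,
                         IntegerVector s_person, IntegerVector s_item,
                         IntegerVector s_rating,
                         IntegerVector v_person, IntegerVector v_item,
                         IntegerVector v_vig, IntegerVector v_rating,
                         NumericVector lambda, NumericVector gamma_,
                         NumericMatrix beta, NumericVector tau,
                         double mu_uk,
                         NumericVector z, NumericVector w,
                         bool want_grad) {
  const int n = p_country.size(), J = lambda.size(), V = beta.ncol(),
            Q = z.size(), G = Q * Q;
  const int nS = s_person.size(), nV = v_person.size();

  // tau layout: ((c * J) + j) * 3 + k
  auto tauat = [&](int c, int j, int k) { return tau[((c * J) + j) * 3 + k]; };

  std::vector<double> thIN(Q), thUK(Q);
  for (int q = 0; q < Q; ++q) { thIN[q] = z[q]; thUK[q] = mu_uk + z[q]; }

  // self tables on the (theta, eta) grid, node index g = q * Q + r
  CellTabs TS; TS.alloc(2, J, G);
  std::vector<double> m(G);
  for (int c = 0; c < 2; ++c) {
    const std::vector<double>& th = (c == 0) ? thIN : thUK;
    for (int j = 0; j < J; ++j) {
      for (int q = 0; q < Q; ++q)
        for (int r = 0; r < Q; ++r)
          m[q * Q + r] = lambda[j] * th[q] + gamma_[j] * z[r];
      fill_block(TS, c, j, m, tauat(c, j, 0), tauat(c, j, 1), tauat(c, j, 2),
                 want_grad);
    }
  }

  // vignette tables depend on eta only: one table row per (c, j * V + v)
  CellTabs TV; TV.alloc(2, J * V, Q);
  std::vector<double> mv(Q);
  for (int c = 0; c < 2; ++c)
    for (int j = 0; j < J; ++j)
      for (int v = 0; v < V; ++v) {
        for (int r = 0; r < Q; ++r)
          mv[r] = beta(j, v) + gamma_[j] * z[r];
        fill_block(TV, c, j * V + v, mv, tauat(c, j, 0), tauat(c, j, 1),
                   tauat(c, j, 2), want_grad);
      }

  // accumulate per-person conditional log-likelihood over the grid
  std::vector<double> L((size_t)n * G, 0.0);
  for (int s = 0; s < nS; ++s) {
    const int i = s_person[s], c = p_country[i];
    const double* tab = &TS.logp[TS.at(c, s_item[s], s_rating[s], 0)];
    double* row = &L[(size_t)i * G];
    for (int g = 0; g < G; ++g) row[g] += tab[g];
  }
  for (int s = 0; s < nV; ++s) {
    const int i = v_person[s], c = p_country[i];
    const double* tab = &TV.logp[TV.at(c, v_item[s] * V + v_vig[s],
                                       v_rating[s], 0)];
    double* row = &L[(size_t)i * G];
    for (int q = 0; q < Q; ++q) {
      double* rq = row + q * Q;
      for (int r = 0; r < Q; ++r) rq[r] += tab[r];
    }
  }

  std::vector<double> w2(G);
  for (int q = 0; q < Q; ++q)
    for (int r = 0; r < Q; ++r) w2[q * Q + r] = w[q] * w[r];

  NumericVector pll(n);
  double total = rows_to_loglik(L, n, G, w2, pll, want_grad);

  if (!want_grad)
    return List::create(_["loglik"] = total, _["person_loglik"] = pll);

  // gradient accumulation; L now holds posterior node weights
  NumericVector gl(J), gg(J), gt(2 * J * 3);
  NumericMatrix gb(J, V);
  double gmu = 0.0;
  for (int s = 0; s < nS; ++s) {
    const int i = s_person[s], c = p_country[i], j = s_item[s], y = s_rating[s];
    const std::vector<double>& th = (c == 0) ? thIN : thUK;
    const size_t base = TS.at(c, j, y, 0);
    const double* W = &L[(size_t)i * G];
    double sdm_th = 0.0, sdm_eta = 0.0, sdm = 0.0, slo = 0.0, shi = 0.0;
    for (int q = 0; q < Q; ++q) {
      const double* Wq = W + q * Q;
      const double* dmq = &TS.dm[base + q * Q];
      const double* loq = &TS.dlo[base + q * Q];
      const double* hiq = &TS.dhi[base + q * Q];
      double rowdm = 0.0;
      for (int r = 0; r < Q; ++r) {
        double ww = Wq[r];
        double gdm = ww * dmq[r];
        rowdm += gdm;
        sdm_eta += gdm * z[r];
        slo += ww * loq[r];
        shi += ww * hiq[r];
      }
      sdm += rowdm;
      sdm_th += rowdm * th[q];
    }
    gl[j] += sdm_th;
    gg[j] += sdm_eta;
    if (c == 1) gmu += sdm * lambda[j];
    if (y >= 1) gt[((c * J) + j) * 3 + (y - 1)] += slo;
    if (y <= 2) gt[((c * J) + j) * 3 + y] += shi;
  }
  std::vector<double> Wr(Q);
  for (int s = 0; s < nV; ++s) {
    const int i = v_person[s], c = p_country[i], j = v_item[s],
              v = v_vig[s], y = v_rating[s];
    const size_t base = TV.at(c, j * V + v, y, 0);
    const double* W = &L[(size_t)i * G];
    for (int r = 0; r < Q; ++r) Wr[r] = 0.0;
    for (int q = 0; q < Q; ++q) {
      const double* Wq = W + q * Q;
      for (int r = 0; r < Q; ++r) Wr[r] += Wq[r];
    }
    double sdm = 0.0, sdm_eta = 0.0, slo = 0.0, shi = 0.0;
    for (int r = 0; r < Q; ++r) {
      double gdm = Wr[r] * TV.dm[base + r];
      sdm += gdm;
      sdm_eta += gdm * z[r];
      slo += Wr[r] * TV.dlo[base + r];
      shi += Wr[r] * TV.dhi[base + r];
    }
    gb(j, v) += sdm;
    gg[j] += sdm_eta;
    if (y >= 1) gt[((c * J) + j) * 3 + (y - 1)] += slo;
    if (y <= 2) gt[((c * J) + j) * 3 + y] += shi;
  }

  return List::create(_["loglik"] = total, _["person_loglik"] = pll,
                      _["grad_lambda"] = gl, _["grad_gamma"] = gg,
                      _["grad_beta"] = gb, _["grad_tau"] = gt,
                      _["grad_mu"] = gmu);
}

// [[Rcpp::export]]
List naive_loglik_cpp(IntegerVector p_country,
                      IntegerVector s_person, IntegerVector s_item,
                      IntegerVector s_rating,
                      NumericVector lambda, NumericVector tau,
                      double mu_uk,
                      NumericVector z, NumericVector w,
                      bool want_grad) {
  const int n = p_country.size(), J = lambda.size(), Q = z.size();
  const int nS = s_person.size();
  auto tauat = [&](int j, int k) { return tau[j * 3 + k]; };

  std::vector<double> thIN(Q), thUK(Q);
  for (int q = 0; q < Q; ++q) { thIN[q] = z[q]; thUK[q] = mu_uk + z[q]; }

  CellTabs T; T.alloc(2, J, Q);
  std::vector<double> m(Q);
  for (int c = 0; c < 2; ++c) {
    const std::vector<double>& th = (c == 0) ? thIN : thUK;
    for (int j = 0; j < J; ++j) {
      for (int q = 0; q < Q; ++q) m[q] = lambda[j] * th[q];
      fill_block(T, c, j, m, tauat(j, 0), tauat(j, 1), tauat(j, 2), want_grad);
    }
  }

  std::vector<double> L((size_t)n * Q, 0.0);
  for (int s = 0; s < nS; ++s) {
    const int i = s_person[s], c = p_country[i];
    const double* tab = &T.logp[T.at(c, s_item[s], s_rating[s], 0)];
    double* row = &L[(size_t)i * Q];
    for (int q = 0; q < Q; ++q) row[q] += tab[q];
  }

  std::vector<double> w1(w.begin(), w.end());
  NumericVector pll(n);
  double total = rows_to_loglik(L, n, Q, w1, pll, want_grad);

  if (!want_grad)
    return List::create(_["loglik"] = total, _["person_loglik"] = pll);

  NumericVector gl(J), gt(J * 3);
  double gmu = 0.0;
  for (int s = 0; s < nS; ++s) {
    const int i = s_person[s], c = p_country[i], j = s_item[s], y = s_rating[s];
    const std::vector<double>& th = (c == 0) ? thIN : thUK;
    const size_t base = T.at(c, j, y, 0);
    const double* W = &L[(size_t)i * Q];
    double sdm_th = 0.0, sdm = 0.0, slo = 0.0, shi = 0.0;
    for (int q = 0; q < Q; ++q) {
      double gdm = W[q] * T.dm[base + q];
      sdm += gdm;
      sdm_th += gdm * th[q];
      slo += W[q] * T.dlo[base + q];
      shi += W[q] * T.dhi[base + q];
    }
    gl[j] += sdm_th;
    if (c == 1) gmu += sdm * lambda[j];
    if (y >= 1) gt[j * 3 + (y - 1)] += slo;
    if (y <= 2) gt[j * 3 + y] += shi;
  }
  return List::create(_["loglik"] = total, _["person_loglik"] = pll,
                      _["grad_lambda"] = gl, _["grad_tau"] = gt,
                      _["grad_mu"] = gmu);
}
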