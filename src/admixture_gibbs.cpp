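// Gibbs sampler for the Pritchard-Stephens-Donnelly admixture model with
// independent allele frequencies (biallelic loci, unphased diploids).
//
// State: P (L x K) population allele frequencies, Q (n x K) admixture
// proportions, z origin indicators per allele copy (sampled, not stored),
// alpha the shared Dirichlet concentration (Metropolis update, uniform
// prior on (0, alpha_max)).
//
// The complete-data log-likelihood recorded after burn-in is evaluated at
// the state entering each sweep, reusing the mixture totals computed while
// sampling the origin indicators.
//
// Uses R's RNG so runs are reproducible via set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// branchless cumulative-sum inversion (K is small)
static inline int sample_cat(const double *w, int K, double tot) {
  double u = unif_rand() * tot;
  double c = 0.0;
  int k = 0;
  for (int kk = 0; kk < K - 1; ++kk) {
    c += w[kk];
    k += (u > c);
  }
  return k;
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix dose, int K, int burn_in, int n_iter,
                     double lambda = 1.0, double alpha_init = 1.0,
                     double alpha_prop_sd = 0.025, double alpha_max = 10.0) {
  const int n = dose.nrow(), L = dose.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K cannot exceed the number of samples");

  RNGScope scope;
  const int *dose_ptr0 = INTEGER(dose);

  if (K == 1) {
    // degenerate case: Q is identically 1 and the origin indicators are
    // trivial, so only the allele frequencies are sampled
    std::vector<double> a1(L, 0.0), a0(L, 0.0);
    double n_het1 = 0.0;
    for (int j = 0; j < L; ++j) {
      const int *dj = dose_ptr0 + (std::size_t)j * n;
      for (int i = 0; i < n; ++i) {
        int d = dj[i];
        if (d == NA_INTEGER) continue;
        a1[j] += d;
        a0[j] += 2 - d;
        if (d == 1) n_het1 += 1.0;
      }
    }
    std::vector<double> logliks1;
    logliks1.reserve(n_iter);
    std::vector<double> Psum1(L, 0.0);
    const int total1 = burn_in + n_iter;
    for (int sweep = 0; sweep < total1; ++sweep) {
      double ll = n_het1 * std::log(2.0);
      for (int j = 0; j < L; ++j) {
        double a = R::rgamma(lambda + a1[j], 1.0);
        double b = R::rgamma(lambda + a0[j], 1.0);
        double p = a / (a + b);
        if (p < 1e-9) p = 1e-9;
        if (p > 1.0 - 1e-9) p = 1.0 - 1e-9;
        if (sweep >= burn_in) {
          ll += a1[j] * std::log(p) + a0[j] * std::log(1.0 - p);
          Psum1[j] += p;
        }
      }
      if (sweep >= burn_in) logliks1.push_back(ll);
    }
    NumericMatrix Qm1(n, 1), Pm1(L, 1);
    std::fill(Qm1.begin(), Qm1.end(), 1.0);
    for (int j = 0; j < L; ++j) Pm1(j, 0) = Psum1[j] / n_iter;
    return List::create(
      _["Q"] = Qm1, _["P"] = Pm1,
      _["loglik_trace"] = NumericVector(logliks1.begin(), logliks1.end()),
      _["alpha_trace"] =
        NumericVector(burn_in + n_iter, alpha_init),
      _["alpha_accept_rate"] = NA_REAL);
  }

  std::vector<double> P(L * K), Q(n * K, 1.0 / K);
  std::vector<double> n1(L * K), n0(L * K), nq(n * K);
  std::vector<double> Qsum(n * K, 0.0), Psum(L * K, 0.0);
  double alpha = alpha_init;
  const double LOG2 = std::log(2.0);

  for (int j = 0; j < L * K; ++j) P[j] = unif_rand();

  std::vector<double> w0(K), w1(K), logliks;
  logliks.reserve(n_iter);
  std::vector<double> alpha_trace;
  alpha_trace.reserve(burn_in + n_iter);
  int alpha_acc = 0, alpha_try = 0;
  const int *dose_ptr = INTEGER(dose);

  const int total = burn_in + n_iter;
  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    std::fill(nq.begin(), nq.end(), 0.0);
    double ll = 0.0;

    // sample origins z for every allele copy; locus-major for locality.
    // log-likelihood terms are accumulated as a running product, flushed
    // to log scale before underflow, which avoids a log() per genotype.
    double llprod = 1.0;
    long n_het = 0;
    for (int j = 0; j < L; ++j) {
      const double *pj = &P[j * K];
      double *cnt1 = &n1[j * K], *cnt0 = &n0[j * K];
      const int *dj = dose_ptr + (std::size_t)j * n;
      for (int i = 0; i < n; ++i) {
        int d = dj[i];
        if (d == NA_INTEGER) continue;
        const double *qi = &Q[i * K];
        double *nqi = &nq[i * K];
        if (d == 1) {
          double t0 = 0.0, t1 = 0.0;
          for (int k = 0; k < K; ++k) {
            double q = qi[k];
            w1[k] = q * pj[k];
            w0[k] = q - w1[k];
            t1 += w1[k];
            t0 += w0[k];
          }
          int k0 = sample_cat(w0.data(), K, t0);
          nqi[k0] += 1.0; cnt0[k0] += 1.0;
          int k1 = sample_cat(w1.data(), K, t1);
          nqi[k1] += 1.0; cnt1[k1] += 1.0;
          ++n_het;
          llprod *= (t1 > 1e-300 ? t1 : 1e-300) *
                    (t0 > 1e-300 ? t0 : 1e-300);
        } else {
          const bool b = (d == 2);
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w1[k] = qi[k] * (b ? pj[k] : (1.0 - pj[k]));
            tot += w1[k];
          }
          double *cnt = b ? cnt1 : cnt0;
          int k1 = sample_cat(w1.data(), K, tot);
          int k2 = sample_cat(w1.data(), K, tot);
          nqi[k1] += 1.0; cnt[k1] += 1.0;
          nqi[k2] += 1.0; cnt[k2] += 1.0;
          llprod *= tot * tot;
        }
        if (llprod < 1e-250) {
          ll += std::log(llprod);
          llprod = 1.0;
        }
      }
    }
    ll += std::log(llprod) + n_het * LOG2;

    if (sweep >= burn_in) logliks.push_back(ll);

    // update P ~ Beta(lambda + n1, lambda + n0)
    for (int j = 0; j < L; ++j)
      for (int k = 0; k < K; ++k) {
        double a = R::rgamma(lambda + n1[j * K + k], 1.0);
        double b = R::rgamma(lambda + n0[j * K + k], 1.0);
        double p = a / (a + b);
        if (p < 1e-9) p = 1e-9;
        if (p > 1.0 - 1e-9) p = 1.0 - 1e-9;
        P[j * K + k] = p;
      }

    // update Q_i ~ Dirichlet(alpha + counts)
    double sum_log_q = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + nq[i * K + k], 1.0);
        if (g < 1e-300) g = 1e-300;
        Q[i * K + k] = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) {
        Q[i * K + k] /= s;
        if (Q[i * K + k] < 1e-12) Q[i * K + k] = 1e-12;
        sum_log_q += std::log(Q[i * K + k]);
      }
    }

    // Metropolis update of alpha (only meaningful for K > 1)
    if (K > 1) {
      ++alpha_try;
      double prop = alpha + norm_rand() * alpha_prop_sd;
      if (prop > 0.0 && prop < alpha_max) {
        double lr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                         - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                    + (prop - alpha) * sum_log_q;
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
          alpha = prop;
          ++alpha_acc;
        }
      }
    }
    alpha_trace.push_back(alpha);

    if (sweep >= burn_in) {
      for (int t = 0; t < n * K; ++t) Qsum[t] += Q[t];
      for (int t = 0; t < L * K; ++t) Psum[t] += P[t];
    }
  }

  NumericMatrix Qm(n, K), Pm(L, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qm(i, k) = Qsum[i * K + k] / n_iter;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qm(i, k);
    for (int k = 0; k < K; ++k) Qm(i, k) /= s;
  }
  for (int j = 0; j < L; ++j)
    for (int k = 0; k < K; ++k) Pm(j, k) = Psum[j * K + k] / n_iter;

  return List::create(
    _["Q"] = Qm, _["P"] = Pm,
    _["loglik_trace"] = NumericVector(logliks.begin(), logliks.end()),
    _["alpha_trace"] = NumericVector(alpha_trace.begin(), alpha_trace.end()),
    _["alpha_accept_rate"] =
      alpha_try ? (double)alpha_acc / alpha_try : NA_REAL);
}
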