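// Four-level random-intercept logistic model:
//   logit P(y_i = 1) = beta0 + u_{j(i)} + v_{k(i)} + f_{l(i)}
// fitted by exact Gibbs sampling with Polya-Gamma data augmentation.
// All randomness goes through R's RNG so set.seed() in R controls the chain.

#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact PG(1, z) sampler (Devroye alternating-series rejection method).
// PG(1, z) = J*(1, z/2) / 4 where J* is the Jacobi-type distribution.
// ---------------------------------------------------------------------------

static const double TRUNC = 0.64;  // series crossover point

// n-th coefficient of the alternating series for the J*(1, z) density
static inline double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * 0.5 * x);
  } else {
    return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
           std::exp(-2.0 * np5 * np5 / x);
  }
}

// P(proposal falls in the exponential right tail), i.e. p / (p + q)
static double mass_texpon(double Z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * Z * Z;
  double b = std::sqrt(1.0 / t) * (t * Z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * Z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - Z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + Z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(mu = 1/Z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double Z) {
  double t = TRUNC;
  double X = t + 1.0;
  double mu = 1.0 / Z;
  if (mu > t) {
    // rejection from scaled inverse-chi-square proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double E1, E2;
      do {
        E1 = exp_rand();
        E2 = exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * Z * Z * X);
    }
  } else {
    // draw IG(mu, 1) until it lands below t
    while (X > t) {
      double Y = norm_rand();
      Y = Y * Y;
      double mu_Y = mu * Y;
      X = mu + 0.5 * mu * mu_Y -
          0.5 * mu * std::sqrt(4.0 * mu_Y + mu_Y * mu_Y);
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// one PG(1, z) draw
double rpg1(double z) {
  double Z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * Z * Z;
  double p_right = mass_texpon(Z);
  for (;;) {
    double X;
    if (unif_rand() < p_right) {
      X = TRUNC + exp_rand() / fz;
    } else {
      X = rtigauss(Z);
    }
    // squeeze accept/reject on the alternating series
    double S = a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

//' Draw from the Polya-Gamma PG(1, z) distribution
//'
//' Exact draws via the alternating-series rejection sampler.  Exposed
//' mainly so the augmentation scheme can be validated against the
//' closed-form moments E[PG(1,z)] = tanh(z/2)/(2z).
//'
//' @param z numeric vector of tilting parameters.
//' @return numeric vector of PG(1, z) draws, same length as \code{z}.
//' @keywords internal
// [[Rcpp::export]]
NumericVector rpolyagamma(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// sum of n iid PG(1, z) draws; proposal constants computed once
static double rpg_sum(int n, double z) {
  double Z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * Z * Z;
  double p_right = mass_texpon(Z);
  double total = 0.0;
  for (int r = 0; r < n; ++r) {
    for (;;) {
      double X;
      if (unif_rand() < p_right) {
        X = TRUNC + exp_rand() / fz;
      } else {
        X = rtigauss(Z);
      }
      double S = a_coef(0, X);
      double Y = unif_rand() * S;
      int m = 0;
      bool accept = false;
      for (;;) {
        ++m;
        if (m % 2 == 1) {
          S -= a_coef(m, X);
          if (Y <= S) { accept = true; break; }
        } else {
          S += a_coef(m, X);
          if (Y > S) break;
        }
      }
      if (accept) { total += 0.25 * X; break; }
    }
  }
  return total;
}

// ---------------------------------------------------------------------------
// Gibbs cycle.  Index vectors are 0-based and dense.  Update order is fixed
// (omega, beta0, u, v, f, variances) so seeded runs are reproducible.
// In this intercept-only model all persons of a cluster share one linear
// predictor, so the auxiliary draws enter only through per-cluster sums:
// the cycle runs on cluster aggregates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs4_cpp(IntegerVector y,
                IntegerVector cl,    // person -> cluster (0-based)
                IntegerVector di,    // person -> district
                IntegerVector st,    // person -> state
                int J, int K, int L,
                int burn_in, int n_iter, int thin,
                double prior_a, double prior_b,
                double beta0_init,
                NumericVector u_init,
                NumericVector v_init,
                NumericVector f_init,
                double s2u_init, double s2v_init, double s2f_init,
                bool keep_effects) {
  int n = y.size();
  int n_keep = n_iter / thin;

  double beta0 = beta0_init;
  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> f(f_init.begin(), f_init.end());
  double s2u = s2u_init, s2v = s2v_init, s2f = s2f_init;

  // per-cluster aggregates and maps (cluster -> district / state)
  std::vector<int> nj(J, 0), dj(J, -1), sj(J, -1);
  std::vector<double> Kj(J, 0.0), Sj(J, 0.0);
  for (int i = 0; i < n; ++i) {
    int j = cl[i];
    nj[j] += 1;
    Kj[j] += y[i] - 0.5;
    if (dj[j] < 0) dj[j] = di[i];
    else if (dj[j] != di[i]) stop("cluster %d maps to two districts", j + 1);
    if (sj[j] < 0) sj[j] = st[i];
    else if (sj[j] != st[i]) stop("cluster %d maps to two states", j + 1);
  }
  for (int j = 0; j < J; ++j)
    if (nj[j] == 0) stop("empty cluster index %d", j + 1);

  NumericVector d_beta0(n_keep), d_s2u(n_keep), d_s2v(n_keep), d_s2f(n_keep);
  NumericMatrix d_u(keep_effects ? n_keep : 0, keep_effects ? J : 0);
  NumericMatrix d_v(keep_effects ? n_keep : 0, keep_effects ? K : 0);
  NumericMatrix d_f(keep_effects ? n_keep : 0, keep_effects ? L : 0);
  NumericVector mean_u(J), mean_v(K), mean_f(L);

  std::vector<double> A(std::max(J, std::max(K, L))), B(A.size());

  int total = burn_in + n_iter;
  int kept = 0;
  for (int it = 0; it < total; ++it) {
    // (a) auxiliary omega | psi: per-cluster sums of PG(1, psi_j) draws
    for (int j = 0; j < J; ++j) {
      double psi = beta0 + u[j] + v[dj[j]] + f[sj[j]];
      double w = rpg_sum(nj[j], psi);
      if (!R_finite(w)) {
        w = rpg_sum(nj[j], psi);  // retry once
        if (!R_finite(w))
          stop("Polya-Gamma draw degenerate in cluster %d (psi = %g)",
               j + 1, psi);
      }
      Sj[j] = w;
    }

    // (b) beta0 | ... with a flat prior
    {
      double P = 0.0, m = 0.0;
      for (int j = 0; j < J; ++j) {
        P += Sj[j];
        m += Kj[j] - Sj[j] * (u[j] + v[dj[j]] + f[sj[j]]);
      }
      beta0 = m / P + norm_rand() / std::sqrt(P);
    }

    // cluster residuals u_j
    {
      double pu = 1.0 / s2u;
      for (int j = 0; j < J; ++j) {
        double prec = Sj[j] + pu;
        double m = Kj[j] - Sj[j] * (beta0 + v[dj[j]] + f[sj[j]]);
        u[j] = m / prec + norm_rand() / std::sqrt(prec);
      }
    }

    // district residuals v_k
    {
      std::fill(A.begin(), A.begin() + K, 0.0);
      std::fill(B.begin(), B.begin() + K, 0.0);
      for (int j = 0; j < J; ++j) {
        A[dj[j]] += Sj[j];
        B[dj[j]] += Kj[j] - Sj[j] * (beta0 + u[j] + f[sj[j]]);
      }
      double pv = 1.0 / s2v;
      for (int k = 0; k < K; ++k) {
        double prec = A[k] + pv;
        v[k] = B[k] / prec + norm_rand() / std::sqrt(prec);
      }
    }

    // state residuals f_l
    {
      std::fill(A.begin(), A.begin() + L, 0.0);
      std::fill(B.begin(), B.begin() + L, 0.0);
      for (int j = 0; j < J; ++j) {
        A[sj[j]] += Sj[j];
        B[sj[j]] += Kj[j] - Sj[j] * (beta0 + u[j] + v[dj[j]]);
      }
      double pf = 1.0 / s2f;
      for (int l = 0; l < L; ++l) {
        double prec = A[l] + pf;
        f[l] = B[l] / prec + norm_rand() / std::sqrt(prec);
      }
    }

    // (c) variance components | residuals  ~ Inv-Gamma
    {
      double ssu = 0.0, ssv = 0.0, ssf = 0.0;
      for (int j = 0; j < J; ++j) ssu += u[j] * u[j];
      for (int k = 0; k < K; ++k) ssv += v[k] * v[k];
      for (int l = 0; l < L; ++l) ssf += f[l] * f[l];
      s2u = (prior_b + 0.5 * ssu) / R::rgamma(prior_a + 0.5 * J, 1.0);
      s2v = (prior_b + 0.5 * ssv) / R::rgamma(prior_a + 0.5 * K, 1.0);
      s2f = (prior_b + 0.5 * ssf) / R::rgamma(prior_a + 0.5 * L, 1.0);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      d_beta0[kept] = beta0;
      d_s2u[kept] = s2u;
      d_s2v[kept] = s2v;
      d_s2f[kept] = s2f;
      if (keep_effects) {
        for (int j = 0; j < J; ++j) d_u(kept, j) = u[j];
        for (int k = 0; k < K; ++k) d_v(kept, k) = v[k];
        for (int l = 0; l < L; ++l) d_f(kept, l) = f[l];
      }
      for (int j = 0; j < J; ++j) mean_u[j] += u[j];
      for (int k = 0; k < K; ++k) mean_v[k] += v[k];
      for (int l = 0; l < L; ++l) mean_f[l] += f[l];
      ++kept;
    }
  }

  for (int j = 0; j < J; ++j) mean_u[j] /= kept;
  for (int k = 0; k < K; ++k) mean_v[k] /= kept;
  for (int l = 0; l < L; ++l) mean_f[l] /= kept;

  List out = List::create(
      _["beta0"] = d_beta0, _["sigma2_u"] = d_s2u, _["sigma2_v"] = d_s2v,
      _["sigma2_f"] = d_s2f, _["mean_u"] = mean_u, _["mean_v"] = mean_v,
      _["mean_f"] = mean_f);
  if (keep_effects) {
    out["u"] = d_u;
    out["v"] = d_v;
    out["f"] = d_f;
  }
  return out;
}
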