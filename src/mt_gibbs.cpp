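// Gibbs sampler core for the bivariate spike-and-slab regression
//   Y = 1 mu' + X beta + E,  rows of E ~ N2(0, R)
//   beta[j,k] = d[j,k] * b[j,k],  d[j,k] ~ Bern(pi_k),  b[j,.] ~ N2(0, Sigma)
//   R ~ IW(nu_R, S_R), Sigma ~ IW(nu_S, S_S), pi_k ~ Beta(a_k, b_k),
//   mu ~ N2(0, v_mu I).
// The latent b is kept for both traits of every SNP (components with d = 0
// are refreshed from their conditional prior) so the Sigma update stays a
// conjugate inverse-Wishart on all m latent rows.
// All randomness comes from R's RNG so set.seed() gives bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// symmetric pd inverse of a 2x2 with escalating jitter
mat inv2_safe(mat S) {
  S = symmatu(S);
  double jit = 0.0;
  for (int tries = 0; tries < 8; ++tries) {
    mat Sj = S + jit * eye(2, 2);
    double det = Sj(0, 0) * Sj(1, 1) - Sj(0, 1) * Sj(0, 1);
    if (det > 0 && Sj(0, 0) > 0) {
      mat out(2, 2);
      out(0, 0) = Sj(1, 1) / det;
      out(1, 1) = Sj(0, 0) / det;
      out(0, 1) = out(1, 0) = -Sj(0, 1) / det;
      return out;
    }
    jit = (jit == 0.0) ? 1e-10 : jit * 100.0;
  }
  Rcpp::stop("2x2 covariance matrix is numerically singular");
}

// one draw from IW(df, S) via Bartlett on the Wishart(df, S^{-1}) scale
mat riwish2(double df, const mat& S) {
  mat Sinv = inv2_safe(S);
  mat L = chol(symmatu(Sinv) + 1e-12 * eye(2, 2), "lower");
  mat A(2, 2, fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = R::norm_rand();
  mat LA = L * A;
  return inv2_safe(LA * LA.t());
}

struct Prior {
  double nu_R, nu_S;
  mat S_R, S_S;
  vec beta_a, beta_b;   // Beta prior counts for pi_1, pi_2
  double mu_var;
  bool upd_mu, upd_R, upd_Sigma, upd_pi;
};

Prior read_prior(const Rcpp::List& pr) {
  Prior p;
  p.nu_R = Rcpp::as<double>(pr["nu_R"]);
  p.nu_S = Rcpp::as<double>(pr["nu_Sigma"]);
  p.S_R = Rcpp::as<mat>(pr["S_R"]);
  p.S_S = Rcpp::as<mat>(pr["S_Sigma"]);
  p.beta_a = Rcpp::as<vec>(pr["pi_a"]);
  p.beta_b = Rcpp::as<vec>(pr["pi_b"]);
  p.mu_var = Rcpp::as<double>(pr["mu_var"]);
  p.upd_mu = Rcpp::as<bool>(pr["update_mu"]);
  p.upd_R = Rcpp::as<bool>(pr["update_R"]);
  p.upd_Sigma = Rcpp::as<bool>(pr["update_Sigma"]);
  p.upd_pi = Rcpp::as<bool>(pr["update_pi"]);
  return p;
}

struct State {
  vec mu;      // 2
  mat b;       // m x 2 latent slab effects
  imat d;      // m x 2 inclusion indicators
  mat beta;    // m x 2, beta = d .* b
  mat R, Sigma;
  vec pi;      // 2
};

// one full Gibbs sweep; U = Y - 1 mu' - X beta is maintained in place
void sweep(const mat& X, const mat& Y, const vec& xtx, State& st, mat& U,
           const Prior& pr) {
  const int n = X.n_rows, m = X.n_cols;

  // --- mu | rest ------------------------------------------------------
  if (pr.upd_mu) {
    mat Rinv = inv2_safe(st.R);
    vec ybar = trans(mean(U, 0)) + st.mu;  // colmeans(Y - X beta)
    mat P = double(n) * Rinv + (1.0 / pr.mu_var) * eye(2, 2);
    mat V = inv2_safe(P);
    vec mn = V * (double(n) * (Rinv * ybar));
    mat L = chol(symmatu(V) + 1e-14 * eye(2, 2), "lower");
    vec z(2);
    z(0) = R::norm_rand();
    z(1) = R::norm_rand();
    vec mu_new = mn + L * z;
    for (int k = 0; k < 2; ++k) U.col(k) += st.mu(k) - mu_new(k);
    st.mu = mu_new;
  }

  // --- per-SNP (d, b) sweep, trait within SNP -------------------------
  mat Rinv = inv2_safe(st.R);
  for (int j = 0; j < m; ++j) {
    double t[2];
    t[0] = dot(X.col(j), U.col(0));
    t[1] = dot(X.col(j), U.col(1));
    for (int k = 0; k < 2; ++k) {
      const int o = 1 - k;
      const double ck = t[k] + xtx(j) * st.beta(j, k);  // x'(resid excl. j,k)
      const double g = Rinv(k, k) * ck + Rinv(k, o) * t[o];
      const double lam = Rinv(k, k) * xtx(j);
      const double m0 = st.Sigma(k, o) / st.Sigma(o, o) * st.b(j, o);
      double v0 = st.Sigma(k, k) -
                  st.Sigma(k, o) * st.Sigma(k, o) / st.Sigma(o, o);
      if (v0 < 1e-12) v0 = 1e-12;
      const double v1 = 1.0 / (lam + 1.0 / v0);
      const double m1 = v1 * (g + m0 / v0);
      int dn;
      if (st.pi(k) >= 1.0) {
        dn = 1;
      } else if (st.pi(k) <= 0.0) {
        dn = 0;
      } else {
        const double logodds = std::log(st.pi(k)) - std::log1p(-st.pi(k)) +
                               0.5 * (std::log(v1) - std::log(v0)) +
                               0.5 * (m1 * m1 / v1 - m0 * m0 / v0);
        const double p1 =
            (logodds > 0) ? 1.0 / (1.0 + std::exp(-logodds))
                          : std::exp(logodds) / (1.0 + std::exp(logodds));
        dn = (unif_rand() < p1) ? 1 : 0;
      }
      const double bn = dn ? m1 + std::sqrt(v1) * norm_rand()
                           : m0 + std::sqrt(v0) * norm_rand();
      const double beta_new = dn ? bn : 0.0;
      const double delta = beta_new - st.beta(j, k);
      if (delta != 0.0) {
        U.col(k) -= delta * X.col(j);
        t[k] -= delta * xtx(j);
      }
      st.b(j, k) = bn;
      st.d(j, k) = dn;
      st.beta(j, k) = beta_new;
    }
  }

  // --- Sigma | latent effects -----------------------------------------
  if (pr.upd_Sigma) {
    mat SS = pr.S_S + st.b.t() * st.b;
    st.Sigma = riwish2(pr.nu_S + double(m), SS);
  }

  // --- R | residuals ---------------------------------------------------
  if (pr.upd_R) {
    mat SR = pr.S_R + U.t() * U;
    st.R = riwish2(pr.nu_R + double(n), SR);
  }

  // --- pi | indicators --------------------------------------------------
  if (pr.upd_pi) {
    for (int k = 0; k < 2; ++k) {
      double nd = accu(st.d.col(k));
      st.pi(k) = R::rbeta(pr.beta_a(k) + nd, pr.beta_b(k) + double(m) - nd);
    }
  }
}

State read_state(const Rcpp::List& s) {
  State st;
  st.mu = Rcpp::as<vec>(s["mu"]);
  st.b = Rcpp::as<mat>(s["b"]);
  st.d = Rcpp::as<imat>(s["d"]);
  st.beta = st.b % conv_to<mat>::from(st.d);
  st.R = Rcpp::as<mat>(s["R"]);
  st.Sigma = Rcpp::as<mat>(s["Sigma"]);
  st.pi = Rcpp::as<vec>(s["pi"]);
  return st;
}

Rcpp::List write_state(const State& st) {
  return Rcpp::List::create(
      Rcpp::Named("mu") = st.mu, Rcpp::Named("b") = st.b,
      Rcpp::Named("d") = st.d, Rcpp::Named("R") = st.R,
      Rcpp::Named("Sigma") = st.Sigma, Rcpp::Named("pi") = st.pi);
}

}  // namespace

// [[Rcpp::export(name = ".mt_gibbs_fit")]]
Rcpp::List mt_gibbs_fit(const arma::mat& X, const arma::mat& Y,
                        const Rcpp::List& init, const Rcpp::List& prior,
                        int n_iter, int burn_in, int thin) {
  const int n = X.n_rows, m = X.n_cols;
  if ((int)Y.n_rows != n || Y.n_cols != 2)
    Rcpp::stop("Y must be n x 2 and row-aligned with X");
  Prior pr = read_prior(prior);
  State st = read_state(init);
  vec xtx = trans(sum(square(X), 0));
  mat U = Y;
  U.each_row() -= st.mu.t();
  U -= X * st.beta;

  const int n_keep = (n_iter - burn_in) / thin;
  cube beta_draws(n_keep, m, 2);
  Rcpp::IntegerVector d1(n_keep * m), d2(n_keep * m);
  mat R_draws(n_keep, 3), Sigma_draws(n_keep, 3), pi_draws(n_keep, 2),
      mu_draws(n_keep, 2);

  Rcpp::RNGScope scope;
  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    sweep(X, Y, xtx, st, U, pr);
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        beta_draws(kept, j, 0) = st.beta(j, 0);
        beta_draws(kept, j, 1) = st.beta(j, 1);
        d1[kept + n_keep * j] = st.d(j, 0);
        d2[kept + n_keep * j] = st.d(j, 1);
      }
      R_draws(kept, 0) = st.R(0, 0);
      R_draws(kept, 1) = st.R(0, 1);
      R_draws(kept, 2) = st.R(1, 1);
      Sigma_draws(kept, 0) = st.Sigma(0, 0);
      Sigma_draws(kept, 1) = st.Sigma(0, 1);
      Sigma_draws(kept, 2) = st.Sigma(1, 1);
      pi_draws(kept, 0) = st.pi(0);
      pi_draws(kept, 1) = st.pi(1);
      mu_draws(kept, 0) = st.mu(0);
      mu_draws(kept, 1) = st.mu(1);
      ++kept;
    }
  }
  mat B1 = beta_draws.slice(0), B2 = beta_draws.slice(1);
  d1.attr("dim") = Rcpp::IntegerVector::create(n_keep, m);
  d2.attr("dim") = Rcpp::IntegerVector::create(n_keep, m);
  return Rcpp::List::create(
      Rcpp::Named("beta1") = B1, Rcpp::Named("beta2") = B2,
      Rcpp::Named("d1") = d1, Rcpp::Named("d2") = d2,
      Rcpp::Named("R") = R_draws, Rcpp::Named("Sigma") = Sigma_draws,
      Rcpp::Named("pi") = pi_draws, Rcpp::Named("mu") = mu_draws,
      Rcpp::Named("final_state") = write_state(st));
}

// single Gibbs transition, for successive-conditional sampler validation
// [[Rcpp::export(name = ".mt_gibbs_step")]]
Rcpp::List mt_gibbs_step(const arma::mat& X, const arma::mat& Y,
                         const Rcpp::List& state, const Rcpp::List& prior) {
  Prior pr = read_prior(prior);
  State st = read_state(state);
  vec xtx = trans(sum(square(X), 0));
  mat U = Y;
  U.each_row() -= st.mu.t();
  U -= X * st.beta;
  Rcpp::RNGScope scope;
  sweep(X, Y, xtx, st, U, pr);
  return write_state(st);
}
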