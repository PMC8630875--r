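#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Polya-Gamma PG(1, z) sampling, Devroye alternating-series method.
// PG(1, z) = J*(1, z/2) / 4 where J* is sampled on a mixture of a truncated
// inverse-Gaussian (left of t = 0.64) and a truncated exponential (right).
// All randomness goes through R's RNG so set.seed() governs reproducibility.
// ---------------------------------------------------------------------------

static const double PG_TRUNC = 0.64;

// n-th term of the alternating series for the J*(1, .) density at x
static double pg_a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > PG_TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  }
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
         std::exp(-2.0 * np5 * np5 / x);
}

// P(X <= t) weight for the two-piece proposal, z >= 0
static double pg_mass_texpon(double z) {
  double t = PG_TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, PG_TRUNC)
static double pg_rtigauss(double z) {
  double t = PG_TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) {  // mu > t: rejection from scaled chi-square proposal
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// [[Rcpp::export(name = ".rpg1")]]
double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  for (;;) {
    double x;
    if (R::unif_rand() < pg_mass_texpon(z)) {
      x = PG_TRUNC + R::exp_rand() / fz;
    } else {
      x = pg_rtigauss(z);
    }
    double s = pg_a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Blockwise Gibbs sampler for the geo-additive Bernoulli-logit model.
// Each design block j contributes f_j = X_j beta_j to the linear predictor;
// blocks flagged `grouped` carry a region-level design (G x d) plus a row ->
// region index, so region-indexed precision pieces cost O(G d^2), not O(n d^2).
// Full conditionals: beta_j ~ N with precision X'Omega X + K/tau^2 (+ridge),
// tau_j^2 ~ IG(a + rank/2, b + beta' K beta / 2).
// ---------------------------------------------------------------------------

struct Block {
  arma::mat X;        // n x d, or G x d when grouped
  arma::uvec group;   // length n, 0-based region index (empty if ungrouped)
  arma::mat K;        // d x d penalty (prior precision up to 1/tau^2)
  bool penalized;     // sample tau^2?
  bool center;        // project constant direction out of draws
  int rank;           // rank of K
  double a, b;        // inverse-gamma hyperparameters
  arma::vec beta;
  double tau2;
  arma::vec f;        // n-vector of current fitted values
  arma::mat Xw;       // workspace (ungrouped)
};

static double stable_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -10.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".gibbs_pg")]]
List gibbs_pg(const arma::vec& y, List blocks_in, int n_iter, int n_burnin,
              int thin, double lik_weight, double ridge) {
  const int n = y.n_elem;
  const int nb = blocks_in.size();
  std::vector<Block> blk(nb);

  for (int j = 0; j < nb; ++j) {
    List bj = blocks_in[j];
    Block& B = blk[j];
    B.X = as<arma::mat>(bj["X"]);
    if (!Rf_isNull(bj["group"])) {
      IntegerVector g = bj["group"];
      B.group.set_size(g.size());
      for (int i = 0; i < g.size(); ++i) B.group[i] = g[i] - 1;
    }
    B.K = as<arma::mat>(bj["K"]);
    B.penalized = as<bool>(bj["penalized"]);
    B.center = as<bool>(bj["center"]);
    B.rank = as<int>(bj["rank"]);
    B.a = as<double>(bj["a"]);
    B.b = as<double>(bj["b"]);
    B.beta = as<arma::vec>(bj["init"]);
    B.tau2 = as<double>(bj["tau2_init"]);
    if (B.group.is_empty()) {
      if ((int)B.X.n_rows != n) stop("block design row count != n");
      B.f = B.X * B.beta;
      B.Xw.set_size(B.X.n_rows, B.X.n_cols);
    } else {
      arma::vec fg = B.X * B.beta;
      B.f.set_size(n);
      for (int i = 0; i < n; ++i) B.f[i] = fg[B.group[i]];
    }
  }

  arma::vec eta(n, arma::fill::zeros);
  for (int j = 0; j < nb; ++j) eta += blk[j].f;

  const int n_keep = (n_iter - n_burnin) / thin;
  std::vector<arma::mat> draws(nb);
  for (int j = 0; j < nb; ++j) draws[j].set_size(n_keep, blk[j].beta.n_elem);
  int n_pen = 0;
  for (int j = 0; j < nb; ++j) if (blk[j].penalized) ++n_pen;
  arma::mat tau2_draws(n_keep, n_pen);
  arma::vec dev_draws(n_keep);

  arma::vec omega(n), kappa(n);
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 200 == 0) Rcpp::checkUserInterrupt();

    if (lik_weight > 0.0) {
      for (int i = 0; i < n; ++i) omega[i] = lik_weight * rpg1(eta[i]);
      kappa = lik_weight * (y - 0.5);
    } else {
      omega.zeros();
      kappa.zeros();
    }

    for (int j = 0; j < nb; ++j) {
      Block& B = blk[j];
      const int d = B.beta.n_elem;
      arma::mat P;
      arma::vec bvec;
      if (B.group.is_empty()) {
        B.Xw = B.X;
        B.Xw.each_col() %= omega;
        P = B.X.t() * B.Xw;
        // r_i = kappa_i - omega_i * (eta_i - f_ji)
        arma::vec r = kappa - omega % (eta - B.f);
        bvec = B.X.t() * r;
      } else {
        const int G = B.X.n_rows;
        arma::vec Wg(G, arma::fill::zeros), sg(G, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          unsigned int g = B.group[i];
          Wg[g] += omega[i];
          sg[g] += kappa[i] - omega[i] * (eta[i] - B.f[i]);
        }
        arma::mat Xg = B.X;
        Xg.each_col() %= Wg;
        P = B.X.t() * Xg;
        bvec = B.X.t() * sg;
      }
      P += B.K / B.tau2;
      P.diag() += ridge;

      arma::mat U = arma::chol(P);
      arma::vec m = arma::solve(arma::trimatu(U),
                                arma::solve(arma::trimatl(U.t()), bvec));
      arma::vec zdraw(d);
      for (int q = 0; q < d; ++q) zdraw[q] = R::norm_rand();
      arma::vec beta_new = m + arma::solve(arma::trimatu(U), zdraw);
      if (B.center) beta_new -= arma::mean(beta_new);

      arma::vec f_new;
      if (B.group.is_empty()) {
        f_new = B.X * beta_new;
      } else {
        arma::vec fg = B.X * beta_new;
        f_new.set_size(n);
        for (int i = 0; i < n; ++i) f_new[i] = fg[B.group[i]];
      }
      eta += f_new - B.f;
      B.f = f_new;
      B.beta = beta_new;

      if (B.penalized) {
        double quad = arma::as_scalar(B.beta.t() * B.K * B.beta);
        double shape = B.a + 0.5 * B.rank;
        double rate = B.b + 0.5 * quad;
        B.tau2 = 1.0 / R::rgamma(shape, 1.0 / rate);
      }
    }

    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      double dev = 0.0;
      for (int i = 0; i < n; ++i)
        dev += y[i] * eta[i] - stable_log1pexp(eta[i]);
      dev_draws[keep] = -2.0 * dev;
      int pj = 0;
      for (int j = 0; j < nb; ++j) {
        draws[j].row(keep) = blk[j].beta.t();
        if (blk[j].penalized) tau2_draws(keep, pj++) = blk[j].tau2;
      }
      ++keep;
    }
  }

  List beta_out(nb);
  for (int j = 0; j < nb; ++j) beta_out[j] = draws[j];
  return List::create(_["beta"] = beta_out,
                      _["tau2"] = tau2_draws,
                      _["deviance"] = dev_draws,
                      _["n_keep"] = n_keep);
}
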