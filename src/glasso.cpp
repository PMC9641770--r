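// Per-edge-penalty graphical lasso (block coordinate descent), support-
// constrained Gaussian MLE, and a Metropolis structure search over graphs
// with Bernoulli edge priors and a BIC marginal-likelihood surrogate.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <string>
#include <random>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// Block coordinate descent for
//   max  log det Theta - tr(S Theta) - sum_{i != j} Lambda_ij |Theta_ij|
// with the diagonal unpenalized (W_ii = S_ii throughout).
// Solves each column's lasso subproblem by coordinate descent on beta,
// W12 = W11 beta; at the optimum W = S + Lambda o sign(Theta) off-diagonal.
static void glasso_core(const mat& S, const mat& Lambda, double tol,
                        int max_iter, mat& W, mat& Beta, int& niter,
                        bool& converged) {
  const uword p = S.n_rows;
  W.diag() = S.diag();

  double sbar = 0.0;
  if (p > 1) {
    sbar = accu(abs(S)) - accu(abs(S.diag()));
    sbar /= (double)(p * (p - 1));
  }
  const double thr = tol * std::max(sbar, 1e-12);
  const double inner_thr = thr * 0.05;

  converged = false;
  niter = 0;
  if (p == 1) { converged = true; return; }

  for (int it = 0; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      // views without column/row j
      uvec idx(p - 1);
      for (uword k = 0, t = 0; k < p; ++k) if (k != j) idx(t++) = k;
      vec s12 = S.col(j); s12.shed_row(j);
      vec l12 = Lambda.col(j); l12.shed_row(j);
      mat W11 = W.submat(idx, idx);
      vec beta = Beta.col(j); beta.shed_row(j);

      vec c = W11 * beta; // running product
      for (int inner = 0; inner < 1000; ++inner) {
        double del = 0.0;
        for (uword i = 0; i < p - 1; ++i) {
          const double wii = W11(i, i);
          if (wii <= 0) continue;
          const double r = s12(i) - (c(i) - wii * beta(i));
          const double bnew = soft_threshold(r, l12(i)) / wii;
          const double diff = bnew - beta(i);
          if (diff != 0.0) {
            c += W11.col(i) * diff;
            beta(i) = bnew;
            del = std::max(del, std::fabs(diff));
          }
        }
        if (del < inner_thr) break;
      }

      vec w12 = W11 * beta;
      for (uword t = 0; t < p - 1; ++t) {
        max_delta = std::max(max_delta, std::fabs(W(idx(t), j) - w12(t)));
        W(idx(t), j) = w12(t);
        W(j, idx(t)) = w12(t);
        Beta(idx(t), j) = beta(t);
      }
    }
    niter = it + 1;
    if (max_delta < thr) { converged = true; break; }
  }
}

static mat theta_from_wb(const mat& W, const mat& Beta) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    vec beta = Beta.col(j); beta.shed_row(j);
    vec w12 = W.col(j); w12.shed_row(j);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (uword k = 0, t = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -beta(t++) * t22;
    }
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, const arma::mat& Lambda,
                      double tol = 1e-7, int max_iter = 200) {
  mat W = S;
  mat Beta(S.n_rows, S.n_cols, fill::zeros);
  int niter = 0; bool conv = false;
  glasso_core(S, Lambda, tol, max_iter, W, Beta, niter, conv);
  mat Theta = theta_from_wb(W, Beta);
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("niter") = niter,
                            Rcpp::Named("converged") = conv);
}

static double gauss_loglik(const mat& Theta, const mat& S, double n,
                           bool& ok);
static bool constrained_fit(const mat& S, const umat& adj, double tol,
                            int max_iter, mat& W, mat& Beta, mat& Theta);

// Warm-started fits along a penalty-weight path: Lambda = Lbase * omega for
// each omega in order. Each omega's support is rescored by the training-fold
// MLE restricted to that support (removing the lasso shrinkage bias) and the
// held-out BIC of the refit is returned.
// [[Rcpp::export]]
arma::vec glasso_bic_path_cpp(const arma::mat& S_tr, const arma::mat& S_te,
                              const arma::mat& Lbase,
                              const arma::vec& omegas, double n_te,
                              double tol = 1e-9, int max_iter = 500,
                              double zero_tol = 1e-8) {
  const uword p = S_tr.n_rows;
  mat W = S_tr, Wr = S_tr;
  mat Beta(p, p, fill::zeros), Br(p, p, fill::zeros);
  vec bic(omegas.n_elem);
  for (uword o = 0; o < omegas.n_elem; ++o) {
    mat Lambda = Lbase * omegas(o);
    Lambda.diag().zeros();
    int niter; bool conv;
    glasso_core(S_tr, Lambda, tol, max_iter, W, Beta, niter, conv);
    mat Theta = theta_from_wb(W, Beta);
    if (!conv) { bic(o) = datum::inf; continue; }
    umat adj(p, p, fill::zeros);
    double nedge = 0.0;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j)
        if (std::fabs(Theta(i, j)) > zero_tol) {
          adj(i, j) = 1; adj(j, i) = 1; nedge += 1.0;
        }
    mat Theta_r;
    bool ok = constrained_fit(S_tr, adj, tol, max_iter, Wr, Br, Theta_r);
    double ll = ok ? gauss_loglik(Theta_r, S_te, n_te, ok) : -datum::inf;
    if (!ok) { bic(o) = datum::inf; continue; }
    bic(o) = -2.0 * ll + nedge * std::log(n_te);
  }
  return bic;
}

static const double EXCLUDED_PENALTY = 1e10;

// MLE of a Gaussian precision matrix restricted to a support: zero penalty
// on allowed edges, an effectively infinite one elsewhere.
static bool constrained_fit(const mat& S, const umat& adj, double tol,
                            int max_iter, mat& W, mat& Beta, mat& Theta) {
  const uword p = S.n_rows;
  mat Lambda(p, p);
  Lambda.fill(EXCLUDED_PENALTY);
  for (uword i = 0; i < p; ++i) {
    Lambda(i, i) = 0.0;
    for (uword j = 0; j < p; ++j) if (adj(i, j)) Lambda(i, j) = 0.0;
  }
  int niter; bool conv;
  glasso_core(S, Lambda, tol, max_iter, W, Beta, niter, conv);
  Theta = theta_from_wb(W, Beta);
  return Theta.is_finite();
}

// [[Rcpp::export]]
Rcpp::List constrained_mle_cpp(const arma::mat& S, const arma::umat& adj,
                               double tol = 1e-7, int max_iter = 200) {
  mat W = S, Theta;
  mat Beta(S.n_rows, S.n_cols, fill::zeros);
  bool ok = constrained_fit(S, adj, tol, max_iter, W, Beta, Theta);
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("ok") = ok);
}

// Gaussian log-likelihood at Theta given sample covariance S and n samples.
static double gauss_loglik(const mat& Theta, const mat& S, double n,
                           bool& ok) {
  double ldet, sign;
  ok = log_det(ldet, sign, Theta);
  if (!ok || sign <= 0) { ok = false; return -datum::inf; }
  const double p = (double)S.n_rows;
  return 0.5 * n * (ldet - accu(S % Theta) - p * std::log(2.0 * datum::pi));
}

static double graph_bic(const mat& S, const umat& adj, double n, double tol,
                        int max_iter, bool& ok) {
  mat W = S, Theta;
  mat Beta(S.n_rows, S.n_cols, fill::zeros);
  ok = constrained_fit(S, adj, tol, max_iter, W, Beta, Theta);
  if (!ok) return datum::inf;
  double ll = gauss_loglik(Theta, S, n, ok);
  if (!ok) return datum::inf;
  double nedge = 0.0;
  for (uword i = 0; i < adj.n_rows; ++i)
    for (uword j = i + 1; j < adj.n_cols; ++j) if (adj(i, j)) nedge += 1.0;
  return -2.0 * ll + nedge * std::log(n);
}

// [[Rcpp::export]]
double graph_bic_cpp(const arma::mat& S, const arma::umat& adj, double n,
                     double tol = 1e-7, int max_iter = 200) {
  bool ok;
  double b = graph_bic(S, adj, n, tol, max_iter, ok);
  if (!ok) Rcpp::stop("support-constrained MLE failed (non-PD fit)");
  return b;
}

static std::string graph_key(const umat& adj) {
  const uword p = adj.n_rows;
  std::string key(p * (p - 1) / 2, '0');
  uword t = 0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) key[t++] = adj(i, j) ? '1' : '0';
  return key;
}

// Metropolis-Hastings over graph structures: single-edge toggle proposals,
// acceptance exp(-dBIC/2) * Bernoulli prior odds, posterior inclusion =
// post-burn-in visit frequency per edge.
// [[Rcpp::export]]
Rcpp::List mcmc_search_cpp(const arma::mat& S, double n,
                           const arma::mat& prior, arma::umat adj,
                           int iter, int burnin, int seed,
                           double tol = 1e-6, int max_iter = 200) {
  const uword p = S.n_rows;
  if (burnin >= iter) Rcpp::stop("burnin must be smaller than iter");

  mat logit(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j) {
      double pr = std::min(std::max(prior(i, j), 1e-12), 1.0 - 1e-12);
      logit(i, j) = std::log(pr / (1.0 - pr));
    }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const uword npairs = p * (p - 1) / 2;
  std::vector<std::pair<uword, uword>> pairs;
  pairs.reserve(npairs);
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) pairs.push_back({i, j});

  std::unordered_map<std::string, double> bic_cache;
  // warm-start state for the support-constrained fits: the chain moves by
  // single-edge toggles, so the current fit is an excellent start
  mat Wc = S, Bc(p, p, fill::zeros);

  auto eval_graph = [&](const umat& g, bool& ok) -> double {
    mat Wp = Wc, Bp = Bc, Theta;
    ok = constrained_fit(S, g, tol, max_iter, Wp, Bp, Theta);
    if (!ok) return datum::inf;
    double ll = gauss_loglik(Theta, S, n, ok);
    if (!ok) return datum::inf;
    double nedge = 0.0;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j) if (g(i, j)) nedge += 1.0;
    Wc = Wp; Bc = Bp; // keep the latest fit as next warm start
    return -2.0 * ll + nedge * std::log(n);
  };

  bool ok;
  double bic_cur = eval_graph(adj, ok);
  if (!ok) Rcpp::stop("start graph yields a non-PD restricted MLE");
  bic_cache[graph_key(adj)] = bic_cur;

  mat incl(p, p, fill::zeros);
  long accepted = 0, failed_pd = 0;

  for (int t = 0; t < iter; ++t) {
    uword k = (uword)std::min((double)npairs - 1.0,
                              std::floor(unif(rng) * npairs));
    uword i = pairs[k].first, j = pairs[k].second;
    bool adding = !adj(i, j);
    adj(i, j) = adding; adj(j, i) = adding;

    std::string key = graph_key(adj);
    double bic_new;
    auto hit = bic_cache.find(key);
    if (hit != bic_cache.end()) {
      bic_new = hit->second;
      ok = std::isfinite(bic_new);
    } else {
      bic_new = eval_graph(adj, ok);
      bic_cache[key] = ok ? bic_new : datum::inf;
    }

    bool accept = false;
    if (ok) {
      double log_alpha = -(bic_new - bic_cur) / 2.0 +
        (adding ? logit(i, j) : -logit(i, j));
      accept = std::log(unif(rng)) < log_alpha;
    } else {
      ++failed_pd;
    }

    if (accept) {
      bic_cur = bic_new;
      ++accepted;
    } else {
      adj(i, j) = !adding; adj(j, i) = !adding; // revert
    }
    if (t >= burnin) incl += conv_to<mat>::from(adj);
  }

  incl /= (double)(iter - burnin);
  incl.diag().zeros();
  return Rcpp::List::create(
    Rcpp::Named("probs") = incl,
    Rcpp::Named("acceptance_rate") = (double)accepted / (double)iter,
    Rcpp::Named("failed_pd") = failed_pd,
    Rcpp::Named("graphs_evaluated") = (double)bic_cache.size());
}
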