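// Coordinate descent for the per-target elastic-net regressions, working on
// precomputed Gram quantities (G = X'X, c = X'y, yty = y'y).  The Gram form
// lets one crossprod per phenotype serve every target gene and every
// permutation-refit cheaply, which is what makes the label-permutation null
// (two network re-estimations per permutation) tractable.
//
// Objective per target (no intercept; the R layer centers/standardizes):
//   f(b) = 1/2 ||y - X b||^2 + lambda * sum_j [ (1-delta)/2 b_j^2 + delta |b_j| ]
//
// Coordinate update: z_j = g_j + G_jj b_j with gradient g = c - G b, then
//   b_j <- soft(z_j, lambda*delta) / (G_jj + lambda*(1-delta)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One full pass over the coordinates in `idx`; returns the largest weighted
// squared coefficient change max_j G_jj * (delta beta_j)^2 (glmnet-style
// scale-free convergence measure).
static double cd_sweep(const arma::mat& G, const arma::vec& c, arma::vec& g,
                       arma::vec& beta, const arma::uvec& idx,
                       double lam_l1, double lam_l2) {
  double maxdel = 0.0;
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    arma::uword j = idx[k];
    double gjj = G(j, j);
    if (gjj <= 0.0) continue;  // degenerate column: never enters
    double z = g[j] + gjj * beta[j];
    double bnew = soft(z, lam_l1) / (gjj + lam_l2);
    double del = bnew - beta[j];
    if (del != 0.0) {
      beta[j] = bnew;
      g -= del * G.col(j);
      double a = gjj * del * del;
      if (a > maxdel) maxdel = a;
    }
  }
  return maxdel;
}

// Solve one lambda by active-set coordinate descent (warm-started beta/g).
// Convergence: max_j G_jj (delta beta_j)^2 < tol * scale, scale = y'y.
// Returns true on convergence; `iters` counts sweeps.
static bool cd_solve(const arma::mat& G, const arma::vec& c, arma::vec& g,
                     arma::vec& beta, const arma::uvec& free_idx,
                     double lam_l1, double lam_l2, double tol, double scale,
                     int maxit, int& iters) {
  iters = 0;
  const double thr = tol * (scale > 0.0 ? scale : 1.0);
  for (;;) {
    // full sweep
    double del = cd_sweep(G, c, g, beta, free_idx, lam_l1, lam_l2);
    ++iters;
    if (del < thr) return true;
    if (iters >= maxit) return false;
    // iterate on the current active set until stable
    arma::uvec act = arma::intersect(free_idx, arma::find(beta != 0.0));
    while (act.n_elem > 0) {
      double d2 = cd_sweep(G, c, g, beta, act, lam_l1, lam_l2);
      ++iters;
      if (d2 < thr) break;
      if (iters >= maxit) return false;
    }
  }
}

// [[Rcpp::export(name = ".cd_elnet_path")]]
List cd_elnet_path(const arma::mat& G, const arma::vec& c, double yty,
                   const arma::vec& lambdas, double delta,
                   const LogicalVector& exclude, double tol, int maxit) {
  const arma::uword p = G.n_rows;
  if (c.n_elem != p || (arma::uword)exclude.size() != p)
    stop("Gram matrix, correlation vector and exclusion mask sizes disagree");
  const arma::uword nlam = lambdas.n_elem;

  std::vector<arma::uword> freev;
  freev.reserve(p);
  for (arma::uword j = 0; j < p; ++j)
    if (!exclude[j] && G(j, j) > 0.0) freev.push_back(j);
  arma::uvec free_idx(freev);

  arma::mat betas(p, nlam, arma::fill::zeros);
  arma::vec rss(nlam), dfv(nlam);
  LogicalVector converged(nlam);
  IntegerVector iterations(nlam);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec g = c;  // gradient at beta = 0

  for (arma::uword s = 0; s < nlam; ++s) {
    double lam = lambdas[s];
    bool ok = true;
    int it = 0;
    if (lam == 0.0) {
      // unpenalized least squares on the free coordinates
      arma::vec bsub;
      arma::mat Gs = G.submat(free_idx, free_idx);
      arma::vec cs = c.elem(free_idx);
      bool solved = arma::solve(bsub, Gs, cs,
                                arma::solve_opts::likely_sympd +
                                arma::solve_opts::no_approx);
      if (!solved) bsub = arma::pinv(Gs) * cs;
      beta.zeros();
      beta.elem(free_idx) = bsub;
      g = c - G * beta;
    } else {
      double l1 = lam * delta, l2 = lam * (1.0 - delta);
      ok = cd_solve(G, c, g, beta, free_idx, l1, l2, tol, yty, maxit, it);
      if (!ok) {  // relax tolerance once, then give up with the zero solution
        ok = cd_solve(G, c, g, beta, free_idx, l1, l2, tol * 100.0, yty,
                      maxit, it);
        if (!ok) {
          beta.zeros();
          g = c;
        }
      }
    }
    betas.col(s) = beta;
    // ||y - Xb||^2 = yty - b'c - b'g   (g = c - G b)
    double r = yty - arma::dot(beta, c) - arma::dot(beta, g);
    rss[s] = r > 0.0 ? r : 0.0;
    dfv[s] = (double)arma::uvec(arma::find(beta != 0.0)).n_elem;
    converged[s] = ok;
    iterations[s] = it;
  }

  return List::create(_["beta"] = betas, _["rss"] = rss, _["df"] = dfv,
                      _["converged"] = converged, _["iterations"] = iterations);
}
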