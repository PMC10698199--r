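// Lloyd k-means with random-row initialization, best of `restarts` by
// total within-cluster sum of squares. Restarts that converge to an
// empty cluster are re-initialized (bounded retries). Uses R's RNG, so
// results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// squared Euclidean distances of every row of X to every row of C
static void sq_dist(const arma::mat& X, const arma::mat& C,
                    const arma::vec& x2, arma::mat& D) {
  D = -2.0 * (X * C.t());
  arma::vec c2 = arma::sum(arma::square(C), 1);
  D.each_col() += x2;
  D.each_row() += c2.t();
}

// [[Rcpp::export]]
List cpp_kmeans(const arma::mat& X, int k, int restarts, int max_iter) {
  const int n = X.n_rows;
  if (k > n) stop("k exceeds the number of rows");
  arma::vec x2 = arma::sum(arma::square(X), 1);

  arma::uvec best_assign;
  double best_wss = R_PosInf;
  int done = 0, guard = 0;
  const int guard_max = 4 * restarts + 20;
  arma::mat D(n, k), C(k, X.n_cols), Cn(k, X.n_cols);
  arma::uvec assign(n), newassign(n);
  arma::vec cnt(k), dmin(n);

  while (done < restarts && guard < guard_max) {
    ++guard;
    // sample k distinct rows as initial centers via R's RNG
    IntegerVector init = sample(n, k, false); // 1-based
    for (int j = 0; j < k; ++j) C.row(j) = X.row(init[j] - 1);

    bool empty = false, converged = false;
    double wss = 0.0;
    for (int it = 0; it < max_iter; ++it) {
      sq_dist(X, C, x2, D);
      for (int i = 0; i < n; ++i) {
        arma::uword j;
        dmin[i] = D.row(i).min(j);
        newassign[i] = j;
      }
      if (it > 0 && !arma::any(newassign != assign)) {
        // assignments (hence centers) are fixed points: done
        converged = true;
        wss = arma::accu(dmin);
        break;
      }
      assign = newassign;
      Cn.zeros(); cnt.zeros();
      for (int i = 0; i < n; ++i) {
        Cn.row(assign[i]) += X.row(i);
        cnt[assign[i]] += 1.0;
      }
      if (arma::any(cnt == 0)) { empty = true; break; }
      Cn.each_col() /= cnt;
      C = Cn;
    }
    if (empty) continue; // re-initialize this restart
    if (!converged) {    // iteration cap hit: score the last assignment
      sq_dist(X, C, x2, D);
      wss = 0.0;
      for (int i = 0; i < n; ++i) wss += D(i, assign[i]);
    }
    ++done;
    if (wss < best_wss) { best_wss = wss; best_assign = assign; }
  }
  if (!best_assign.n_elem)
    stop("k-means failed to produce a valid clustering");
  IntegerVector cl(n);
  for (int i = 0; i < n; ++i) cl[i] = best_assign[i] + 1;
  return List::create(_["cluster"] = cl, _["tot_withinss"] = best_wss);
}
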