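// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Pairwise fitted RMSD over a frame ensemble.
//
// fitc, measc: 3 x n_atoms x n_frames cubes (nm). For each frame pair
// (i, j) the optimal proper rotation superposing frame j's fit atoms on
// frame i's (Kabsch, SVD with determinant-sign correction) is applied to
// frame j's measure atoms, and the RMSD over the measure atoms returned.
//
// Uses the trace identity: with both frames' measure coordinates centred
// at their *fit-selection* centroids,
//   N * rmsd^2 = ||Mj||^2 + ||Mi||^2 - 2 tr(R * B),  B = Mj * Mi^T,
// so only two 3x3 covariances and one 3x3 SVD are needed per pair.
// [[Rcpp::export]]
arma::mat cpp_pairwise_rmsd(const arma::cube& fitc, const arma::cube& measc) {
  const arma::uword T = fitc.n_slices;
  const arma::uword nm = measc.n_cols;

  std::vector<arma::mat> F(T), M(T);
  arma::vec ssm(T);
  for (arma::uword f = 0; f < T; ++f) {
    arma::vec cf = arma::mean(fitc.slice(f), 1);
    F[f] = fitc.slice(f);
    F[f].each_col() -= cf;
    M[f] = measc.slice(f);
    M[f].each_col() -= cf;               // centred at the fit centroid
    ssm(f) = arma::accu(arma::square(M[f]));
  }

  arma::mat out(T, T, arma::fill::zeros);
  arma::mat U, V, A, B, R;
  arma::vec s;
  for (arma::uword i = 0; i < T; ++i) {
    for (arma::uword j = i + 1; j < T; ++j) {
      // rotate frame j onto frame i: maximize tr(R * A), A = Fj * Fi^T
      A = F[j] * F[i].t();
      arma::svd(U, s, V, A);
      double d = arma::det(V * U.t());
      if (d < 0) V.col(2) *= -1.0;
      R = V * U.t();
      B = M[j] * M[i].t();
      double tr = arma::trace(R * B);
      double ms = (ssm(i) + ssm(j) - 2.0 * tr) / double(nm);
      out(i, j) = out(j, i) = std::sqrt(std::max(ms, 0.0));
    }
  }
  return out;
}
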