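// Compiled training loop for the tied-weight linear autoencoder.
// The algorithm is identical to the reference R implementation
// (ae_batch_grad + Adam in train_ae); epoch-level permutations are drawn
// in R so that determinism is governed entirely by R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tabs, tpres: pixels x pairs (column-per-image); perm0, perm1:
// pairs x epochs permutation matrices (1-based); dg: task target or
// empty for the conventional loss.
// [[Rcpp::export(name = ".ae_train_loop")]]
Rcpp::List ae_train_loop(Rcpp::NumericMatrix tabs_, Rcpp::NumericMatrix tpres_,
                         Rcpp::NumericMatrix w0_, Rcpp::IntegerMatrix perm0_,
                         Rcpp::IntegerMatrix perm1_, Rcpp::NumericVector dg_,
                         int half, double lr, double beta1, double beta2,
                         double eps) {
  const mat tabs(tabs_.begin(), tabs_.nrow(), tabs_.ncol(), false, true);
  const mat tpres(tpres_.begin(), tpres_.nrow(), tpres_.ncol(), false, true);
  const uword N = tabs.n_rows;
  const uword P = 2 * (uword)half;
  const uword np = tabs.n_cols;
  const uword epochs = perm0_.ncol();
  const uword nb = np / (uword)half;
  const bool task = dg_.size() > 0;

  mat w(w0_.begin(), w0_.nrow(), w0_.ncol(), false, true);
  mat W = w;  // working copy
  const uword M = W.n_cols;
  vec dg;
  if (task) dg = vec(dg_.begin(), dg_.size());
  const double dg2 = task ? dot(dg, dg) : 0.0;

  mat m(N, M, fill::zeros), v(N, M, fill::zeros);
  mat G(N, P), V, GV, wtw, vtv, grad;
  vec loss_trace(epochs, fill::zeros);
  double step = 0.0;

  for (uword ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (uword b = 0; b < nb; ++b) {
      for (uword j = 0; j < (uword)half; ++j) {
        const uword i0 = (uword)perm0_(b * half + j, ep) - 1;
        const uword i1 = (uword)perm1_(b * half + j, ep) - 1;
        G.col(j) = tabs.col(i0);
        G.col(half + j) = tpres.col(i1);
      }
      V = G.t() * W;            // P x M
      GV = G * V;               // N x M
      wtw = W.t() * W;
      vtv = V.t() * V;
      double loss;
      if (task) {
        vec a = sum(G.cols(half, P - 1), 1);
        vec bw = W.t() * dg;
        rowvec yv = sum(V.rows(half, P - 1), 0);
        grad = (GV * wtw + W * vtv - a * bw.t() - dg * yv) * (2.0 / P);
        loss = (accu(wtw % vtv) - 2.0 * dot(bw, yv.t()) + half * dg2) / P;
      } else {
        grad = (GV * wtw + W * vtv - 2.0 * GV) * (2.0 / P);
        loss = (accu(wtw % vtv) - 2.0 * trace(vtv) + accu(G % G)) / P;
      }
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d",
                   (int)ep + 1);
      step += 1.0;
      m = beta1 * m + (1.0 - beta1) * grad;
      v = beta2 * v + (1.0 - beta2) * (grad % grad);
      const double c1 = 1.0 - std::pow(beta1, step);
      const double c2 = 1.0 - std::pow(beta2, step);
      W -= lr * (m / c1) / (sqrt(v / c2) + eps);
      ep_loss += loss;
    }
    loss_trace(ep) = ep_loss / nb;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("trace") = loss_trace);
}
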