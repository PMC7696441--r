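// Training engine for the 1D convolutional spike classifier.
//
// The network is described by an integer "meta" matrix compiled in R
// (one row per layer, columns documented below). Parameters live in one
// flat numeric vector; weight matrices are Armadillo views into it, so
// the Adam update mutates the R-side vector in place. Dropout masks are
// drawn from R's RNG, which keeps whole training runs reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// meta columns (0-based). kind: 1 conv1d, 2 maxpool1d, 3 flatten,
// 4 dropout, 5 dense.
enum MetaCol {
  M_KIND = 0, M_LIN, M_CIN, M_COUT, M_RELU, M_BN,
  M_PK, M_PS, M_WOFF, M_BOFF, M_GOFF, M_BEOFF, M_SOFF, M_LOUT, M_NCOL
};

static const double BN_EPS = 1e-5;

// im2col for kernel 3, stride 1, zero "same" padding.
// X: n x L x C  ->  M: (n*L) x (3*C); block k holds input position l+k-1.
static void im2col3(const cube& X, mat& M) {
  const uword n = X.n_rows, L = X.n_cols, C = X.n_slices;
  M.zeros(n * L, 3 * C);
  for (uword c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (uword k = 0; k < 3; ++k) {
      for (uword l = 0; l < L; ++l) {
        const sword li = static_cast<sword>(l) + static_cast<sword>(k) - 1;
        if (li < 0 || li >= static_cast<sword>(L)) continue;
        M.col(k * C + c).subvec(l * n, l * n + n - 1) =
          S.col(static_cast<uword>(li));
      }
    }
  }
}

// adjoint of im2col3: scatter-add columns of dM back onto input positions
static void col2im3(const mat& dM, cube& dX) {
  const uword n = dX.n_rows, L = dX.n_cols, C = dX.n_slices;
  dX.zeros();
  for (uword c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    for (uword k = 0; k < 3; ++k) {
      for (uword l = 0; l < L; ++l) {
        const sword li = static_cast<sword>(l) + static_cast<sword>(k) - 1;
        if (li < 0 || li >= static_cast<sword>(L)) continue;
        S.col(static_cast<uword>(li)) +=
          dM.col(k * C + c).subvec(l * n, l * n + n - 1);
      }
    }
  }
}

struct LayerCache {
  mat M;        // conv: im2col matrix
  mat xh;       // conv+bn: normalized activations ((n*L) x C)
  rowvec iv;    // conv+bn: 1/sqrt(var+eps) per channel
  cube pre;     // conv: pre-relu output (post-bn)
  ucube argmax; // pool: winning input position per output element
  mat in;       // dense: layer input
  mat preD;     // dense: pre-relu output
  mat dropmask; // dropout: inverted-dropout mask
};

struct NetState {
  const IntegerMatrix& meta;
  const NumericVector& drop;
  double* par;
  double* rmu;
  double* rv;
  bool train;        // batch-norm batch stats + dropout active
  bool update_stats; // update running batch-norm statistics
  double bn_mom;
  NetState(const IntegerMatrix& m, const NumericVector& d, double* p,
           double* mu, double* v, bool tr, bool up, double mom)
    : meta(m), drop(d), par(p), rmu(mu), rv(v), train(tr),
      update_stats(up), bn_mom(mom) {}
};

// forward pass; fills caches (only when caches != nullptr) and returns logits
static mat net_forward(NetState& st, const cube& X0,
                       std::vector<LayerCache>* caches) {
  const IntegerMatrix& meta = st.meta;
  const int nl = meta.nrow();
  cube A = X0;   // activation while 3-d
  mat Am;        // activation once flattened
  bool flat = false;

  for (int li = 0; li < nl; ++li) {
    const int kind = meta(li, M_KIND);
    LayerCache* cc = caches ? &((*caches)[li]) : nullptr;
    if (kind == 1) { // conv1d (+ optional batch norm, relu)
      const uword n = A.n_rows, L = A.n_cols, C = A.n_slices;
      const uword Cout = meta(li, M_COUT);
      mat Mtmp;
      mat& M = cc ? cc->M : Mtmp;
      im2col3(A, M);
      const mat W(st.par + meta(li, M_WOFF), 3 * C, Cout, false, true);
      const colvec b(st.par + meta(li, M_BOFF), Cout, false, true);
      mat Y = M * W;
      Y.each_row() += b.t();
      if (meta(li, M_BN)) {
        const colvec g(st.par + meta(li, M_GOFF), Cout, false, true);
        const colvec be(st.par + meta(li, M_BEOFF), Cout, false, true);
        const int soff = meta(li, M_SOFF);
        rowvec mu(Cout), var(Cout);
        if (st.train) {
          mu = mean(Y, 0);
          var = mean(square(Y), 0) - square(mu);
          if (st.update_stats) {
            for (uword c = 0; c < Cout; ++c) {
              st.rmu[soff + c] = st.bn_mom * st.rmu[soff + c] +
                (1.0 - st.bn_mom) * mu(c);
              st.rv[soff + c] = st.bn_mom * st.rv[soff + c] +
                (1.0 - st.bn_mom) * var(c);
            }
          }
        } else {
          for (uword c = 0; c < Cout; ++c) {
            mu(c) = st.rmu[soff + c];
            var(c) = st.rv[soff + c];
          }
        }
        rowvec iv = 1.0 / sqrt(var + BN_EPS);
        Y.each_row() -= mu;
        Y.each_row() %= iv;
        if (cc) { cc->xh = Y; cc->iv = iv; }
        Y.each_row() %= g.t();
        Y.each_row() += be.t();
      }
      cube Yc(Y.memptr(), n, L, Cout);
      if (cc) cc->pre = Yc;
      if (meta(li, M_RELU)) Yc.transform([](double x) { return x > 0 ? x : 0.0; });
      A = Yc;
    } else if (kind == 2) { // maxpool1d, valid
      const uword n = A.n_rows, L = A.n_cols, C = A.n_slices;
      const uword pk = meta(li, M_PK), ps = meta(li, M_PS);
      const uword Lout = meta(li, M_LOUT);
      cube Y(n, Lout, C);
      ucube am(n, Lout, C);
      for (uword c = 0; c < C; ++c) {
        const mat& S = A.slice(c);
        for (uword lo = 0; lo < Lout; ++lo) {
          const uword start = lo * ps;
          colvec best = S.col(start);
          ucolvec bidx(n, fill::value(start));
          for (uword k = 1; k < pk; ++k) {
            const colvec& cand = S.col(start + k);
            for (uword i = 0; i < n; ++i) {
              if (cand(i) > best(i)) { best(i) = cand(i); bidx(i) = start + k; }
            }
          }
          Y.slice(c).col(lo) = best;
          am.slice(c).col(lo) = bidx;
        }
      }
      if (cc) cc->argmax = am;
      A = Y;
    } else if (kind == 3) { // flatten
      Am = mat(A.memptr(), A.n_rows, A.n_cols * A.n_slices);
      flat = true;
    } else if (kind == 4) { // dropout
      const double rate = st.drop[li];
      if (st.train && rate > 0) {
        NumericVector r = Rcpp::runif(Am.n_elem);
        mat mk(Am.n_rows, Am.n_cols);
        const double keepinv = 1.0 / (1.0 - rate);
        for (uword i = 0; i < Am.n_elem; ++i)
          mk(i) = (r[i] >= rate) ? keepinv : 0.0;
        if (cc) cc->dropmask = mk;
        Am %= mk;
      }
    } else if (kind == 5) { // dense
      const uword Cout = meta(li, M_COUT), Cin = meta(li, M_CIN);
      if (cc) cc->in = Am;
      const mat W(st.par + meta(li, M_WOFF), Cin, Cout, false, true);
      const colvec b(st.par + meta(li, M_BOFF), Cout, false, true);
      mat Y = Am * W;
      Y.each_row() += b.t();
      if (cc) cc->preD = Y;
      if (meta(li, M_RELU)) Y.transform([](double x) { return x > 0 ? x : 0.0; });
      Am = Y;
    } else {
      stop("unknown layer kind");
    }
  }
  if (!flat) stop("network must contain a flatten layer");
  return Am; // logits; softmax applied by the loss / prediction code
}

// softmax + cross-entropy; y is 0-based class index
static double softmax_ce(const mat& Z, const ivec& y, mat& P, mat& dZ,
                         bool want_grad) {
  const uword n = Z.n_rows;
  P = Z;
  P.each_col() -= max(P, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);
  double loss = 0.0;
  for (uword i = 0; i < n; ++i)
    loss -= std::log(std::max(P(i, static_cast<uword>(y(i))), 1e-12));
  loss /= n;
  if (want_grad) {
    dZ = P;
    for (uword i = 0; i < n; ++i) dZ(i, static_cast<uword>(y(i))) -= 1.0;
    dZ /= static_cast<double>(n);
  }
  return loss;
}

// backward pass, accumulating into flat grad vector
static void net_backward(NetState& st, const cube& X0,
                         std::vector<LayerCache>& caches, const mat& dZ0,
                         double* grad) {
  const IntegerMatrix& meta = st.meta;
  const int nl = meta.nrow();
  mat dAm = dZ0;
  cube dA;
  bool flat = true; // we start at the top, below the flatten it becomes false

  for (int li = nl - 1; li >= 0; --li) {
    const int kind = meta(li, M_KIND);
    LayerCache& cc = caches[li];
    if (kind == 5) { // dense
      if (meta(li, M_RELU)) dAm %= conv_to<mat>::from(cc.preD > 0);
      const uword Cout = meta(li, M_COUT), Cin = meta(li, M_CIN);
      const mat W(st.par + meta(li, M_WOFF), Cin, Cout, false, true);
      mat dW(grad + meta(li, M_WOFF), Cin, Cout, false, true);
      colvec db(grad + meta(li, M_BOFF), Cout, false, true);
      dW = cc.in.t() * dAm;
      db = sum(dAm, 0).t();
      dAm = dAm * W.t();
    } else if (kind == 4) { // dropout
      if (st.train && st.drop[li] > 0 && cc.dropmask.n_elem > 0)
        dAm %= cc.dropmask;
    } else if (kind == 3) { // flatten -> reshape gradient to cube
      const uword n = dAm.n_rows;
      const uword L = meta(li, M_LIN), C = meta(li, M_CIN);
      dA = cube(dAm.memptr(), n, L, C);
      flat = false;
    } else if (kind == 2) { // maxpool
      const uword n = dA.n_rows, C = dA.n_slices;
      const uword Lin = meta(li, M_LIN), Lout = meta(li, M_LOUT);
      cube dX(n, Lin, C, fill::zeros);
      for (uword c = 0; c < C; ++c) {
        for (uword lo = 0; lo < Lout; ++lo) {
          for (uword i = 0; i < n; ++i) {
            dX(i, cc.argmax(i, lo, c), c) += dA(i, lo, c);
          }
        }
      }
      dA = dX;
    } else if (kind == 1) { // conv1d
      const uword n = dA.n_rows, L = dA.n_cols;
      const uword C = meta(li, M_CIN), Cout = meta(li, M_COUT);
      if (meta(li, M_RELU)) dA %= conv_to<cube>::from(cc.pre > 0);
      mat dY(dA.memptr(), n * L, Cout);
      if (meta(li, M_BN)) {
        const colvec g(st.par + meta(li, M_GOFF), Cout, false, true);
        colvec dg(grad + meta(li, M_GOFF), Cout, false, true);
        colvec dbe(grad + meta(li, M_BEOFF), Cout, false, true);
        dg = sum(dY % cc.xh, 0).t();
        dbe = sum(dY, 0).t();
        if (st.train) {
          // backprop through batch statistics
          mat dxh = dY;
          dxh.each_row() %= g.t();
          rowvec mdxh = mean(dxh, 0);
          rowvec mdxx = mean(dxh % cc.xh, 0);
          dY = dxh;
          dY.each_row() -= mdxh;
          dY -= cc.xh.each_row() % mdxx;
          dY.each_row() %= cc.iv;
        } else {
          dY.each_row() %= g.t();
          dY.each_row() %= cc.iv;
        }
      }
      const mat W(st.par + meta(li, M_WOFF), 3 * C, Cout, false, true);
      mat dW(grad + meta(li, M_WOFF), 3 * C, Cout, false, true);
      colvec db(grad + meta(li, M_BOFF), Cout, false, true);
      dW = cc.M.t() * dY;
      db = sum(dY, 0).t();
      mat dM = dY * W.t();
      cube dX(n, L, C);
      col2im3(dM, dX);
      dA = dX;
    }
  }
  (void)flat;
  (void)X0;
}

static cube as_input_cube(const NumericMatrix& X, int L, int C) {
  const uword n = X.nrow();
  if (static_cast<uword>(X.ncol()) != static_cast<uword>(L) * C)
    stop("input has %d columns; expected %d", X.ncol(), L * C);
  cube A(X.begin(), n, L, C); // copies
  return A;
}

//' @noRd
// [[Rcpp::export(name = ".cnn_epoch")]]
List cnn_epoch(NumericMatrix X, IntegerVector y, IntegerVector perm,
               int batch_size, IntegerMatrix meta, NumericVector drop_rates,
               NumericVector params, NumericVector adam_m, NumericVector adam_v,
               int adam_t, NumericVector bn_rmu, NumericVector bn_rv,
               double lr, double beta1, double beta2, double adam_eps,
               double bn_momentum, int n_classes) {
  const int n = X.nrow();
  const int L0 = meta(0, M_LIN), C0 = meta(0, M_CIN);
  const int nl = meta.nrow();
  cube Xall = as_input_cube(X, L0, C0);

  NetState st(meta, drop_rates, params.begin(), bn_rmu.begin(), bn_rv.begin(),
              true, true, bn_momentum);
  const uword npar = params.size();
  vec grad(npar, fill::zeros);
  vec pv(params.begin(), npar, false, true);
  vec mv(adam_m.begin(), npar, false, true);
  vec vv(adam_v.begin(), npar, false, true);

  double loss_sum = 0.0;
  int correct = 0;
  int t = adam_t;

  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(s + batch_size, n) - 1;
    const int nb = e - s + 1;
    cube Xb(nb, L0, C0);
    ivec yb(nb);
    for (int i = 0; i < nb; ++i) {
      const int src = perm[s + i] - 1;
      for (int c = 0; c < C0; ++c)
        for (int l = 0; l < L0; ++l)
          Xb(i, l, c) = Xall(src, l, c);
      yb(i) = y[src] - 1;
    }
    std::vector<LayerCache> caches(nl);
    mat Z = net_forward(st, Xb, &caches);
    mat P, dZ;
    const double loss = softmax_ce(Z, yb, P, dZ, true);
    loss_sum += loss * nb;
    for (int i = 0; i < nb; ++i)
      if (static_cast<int>(P.row(i).index_max()) == yb(i)) ++correct;
    grad.zeros();
    net_backward(st, Xb, caches, dZ, grad.memptr());
    // Adam, in place on the flat parameter vector
    ++t;
    mv = beta1 * mv + (1.0 - beta1) * grad;
    vv = beta2 * vv + (1.0 - beta2) * square(grad);
    const double c1 = 1.0 - std::pow(beta1, t);
    const double c2 = 1.0 - std::pow(beta2, t);
    pv -= lr * (mv / c1) / (sqrt(vv / c2) + adam_eps);
  }
  (void)n_classes;
  return List::create(_["loss"] = loss_sum / n,
                      _["accuracy"] = static_cast<double>(correct) / n,
                      _["adam_t"] = t);
}

//' @noRd
// [[Rcpp::export(name = ".cnn_forward_probs")]]
NumericMatrix cnn_forward_probs(NumericMatrix X, IntegerMatrix meta,
                                NumericVector drop_rates, NumericVector params,
                                NumericVector bn_rmu, NumericVector bn_rv,
                                int n_classes) {
  const int n = X.nrow();
  const int L0 = meta(0, M_LIN), C0 = meta(0, M_CIN);
  cube Xall = as_input_cube(X, L0, C0);
  NetState st(meta, drop_rates, params.begin(), bn_rmu.begin(), bn_rv.begin(),
              false, false, 0.9);
  NumericMatrix out(n, n_classes);
  const int chunk = 512;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(s + chunk, n) - 1;
    const int nb = e - s + 1;
    cube Xb(nb, L0, C0);
    for (int i = 0; i < nb; ++i)
      for (int c = 0; c < C0; ++c)
        for (int l = 0; l < L0; ++l)
          Xb(i, l, c) = Xall(s + i, l, c);
    mat Z = net_forward(st, Xb, nullptr);
    mat P, dZ;
    ivec dummy(nb, fill::zeros);
    softmax_ce(Z, dummy, P, dZ, false);
    for (int i = 0; i < nb; ++i)
      for (int k = 0; k < n_classes; ++k)
        out(s + i, k) = P(i, k);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cnn_loss_grad")]]
List cnn_loss_grad(NumericMatrix X, IntegerVector y, IntegerMatrix meta,
                   NumericVector drop_rates, NumericVector params,
                   NumericVector bn_rmu, NumericVector bn_rv, bool train_mode,
                   int n_classes) {
  const int n = X.nrow();
  const int L0 = meta(0, M_LIN), C0 = meta(0, M_CIN);
  const int nl = meta.nrow();
  cube Xb = as_input_cube(X, L0, C0);
  // copies of the running stats: this entry point never mutates state
  NumericVector rmu = clone(bn_rmu), rv = clone(bn_rv);
  NetState st(meta, drop_rates, params.begin(), rmu.begin(), rv.begin(),
              train_mode, false, 0.9);
  ivec yb(n);
  for (int i = 0; i < n; ++i) yb(i) = y[i] - 1;
  std::vector<LayerCache> caches(nl);
  mat Z = net_forward(st, Xb, &caches);
  mat P, dZ;
  const double loss = softmax_ce(Z, yb, P, dZ, true);
  NumericVector grad(params.size());
  net_backward(st, Xb, caches, dZ, grad.begin());
  (void)n_classes;
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
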