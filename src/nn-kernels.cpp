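// Compiled kernels for the sequence-network engine: same-padded dilated 1D
// convolution and the concurrent spatial/channel squeeze-and-excitation
// layer, forward and backward. Interfaces mirror the R reference
// implementations in R/nn-engine.R (which remain the documentation of the
// algebra); shapes are T x channels matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// stack the k dilated taps side by side: out(t, (j-1)*cin + c) = xpad(t + (j-1)*d, c)
static arma::mat im2col(const arma::mat& x, int k, int dilation) {
  const int Tn = x.n_rows, cin = x.n_cols;
  const int pad = (k - 1) / 2 * dilation;
  arma::mat xpad(Tn + 2 * pad, cin, arma::fill::zeros);
  xpad.rows(pad, pad + Tn - 1) = x;
  arma::mat xcat(Tn, k * cin);
  for (int j = 0; j < k; ++j) {
    xcat.cols(j * cin, (j + 1) * cin - 1) =
      xpad.rows(j * dilation, j * dilation + Tn - 1);
  }
  return xcat;
}

// [[Rcpp::export(name = "cpp_conv_fwd")]]
List cpp_conv_fwd(const arma::mat& x, const arma::mat& W,
                  const arma::vec& b, int k, int dilation) {
  arma::mat xcat = (k == 1) ? x : im2col(x, k, dilation);
  arma::mat y = xcat * W;
  y.each_row() += b.t();
  return List::create(_["y"] = y, _["xcat"] = xcat);
}

// [[Rcpp::export(name = "cpp_conv_bwd")]]
List cpp_conv_bwd(const arma::mat& dy, const arma::mat& W,
                  const arma::mat& xcat, int k, int cin, int dilation) {
  const int Tn = dy.n_rows;
  arma::mat dW = xcat.t() * dy;
  arma::vec db = arma::sum(dy, 0).t();
  arma::mat dxcat = dy * W.t();
  arma::mat dx;
  if (k == 1) {
    dx = dxcat;
  } else {
    const int pad = (k - 1) / 2 * dilation;
    arma::mat dxpad(Tn + 2 * pad, cin, arma::fill::zeros);
    for (int j = 0; j < k; ++j) {
      dxpad.rows(j * dilation, j * dilation + Tn - 1) +=
        dxcat.cols(j * cin, (j + 1) * cin - 1);
    }
    dx = dxpad.rows(pad, pad + Tn - 1);
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

static arma::vec sigmoid(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// [[Rcpp::export(name = "cpp_scse_fwd")]]
List cpp_scse_fwd(const arma::mat& x, const arma::mat& W1,
                  const arma::vec& b1, const arma::mat& W2,
                  const arma::vec& b2, const arma::vec& v, double bv) {
  const int Tn = x.n_rows;
  arma::rowvec z = arma::mean(x, 0);
  arma::vec a1pre = W1.t() * z.t() + b1;
  arma::vec a1 = arma::clamp(a1pre, 0.0, arma::datum::inf);
  arma::vec s = sigmoid(W2.t() * a1 + b2);
  arma::mat xc = x;
  xc.each_row() %= s.t();
  arma::vec q = sigmoid(x * v + bv);
  arma::mat xs = x;
  xs.each_col() %= q;
  arma::umat m = (xc >= xs);
  arma::mat y = arma::max(xc, xs);
  return List::create(_["y"] = y, _["z"] = z, _["a1pre"] = a1pre,
                      _["a1"] = a1, _["s"] = s, _["q"] = q, _["m"] = m,
                      _["Tn"] = Tn);
}

// [[Rcpp::export(name = "cpp_scse_bwd")]]
List cpp_scse_bwd(const arma::mat& dy, const arma::mat& x,
                  const arma::mat& W1, const arma::mat& W2,
                  const arma::vec& v, const arma::rowvec& z,
                  const arma::vec& a1pre, const arma::vec& a1,
                  const arma::vec& s, const arma::vec& q,
                  const arma::umat& m) {
  const int Tn = x.n_rows;
  arma::mat dxc = dy % arma::conv_to<arma::mat>::from(m);
  arma::mat dxs = dy - dxc;
  // spatial gate
  arma::mat dx = dxs;
  dx.each_col() %= q;
  arma::vec dq = arma::sum(dxs % x, 1);
  arma::vec dqpre = dq % q % (1.0 - q);
  arma::vec dv = x.t() * dqpre;
  double dbv = arma::accu(dqpre);
  dx += dqpre * v.t();
  // channel gate
  arma::mat t = dxc;
  t.each_row() %= s.t();
  dx += t;
  arma::vec ds = arma::sum(dxc % x, 0).t();
  arma::vec dspre = ds % s % (1.0 - s);
  arma::mat dW2 = a1 * dspre.t();
  arma::vec da1 = W2 * dspre;
  arma::vec da1pre = da1 % arma::conv_to<arma::vec>::from(a1pre > 0);
  arma::mat dW1 = z.t() * da1pre.t();
  arma::vec dz = W1 * da1pre;
  dx.each_row() += dz.t() / Tn;
  return List::create(_["dW1"] = dW1, _["db1"] = da1pre, _["dW2"] = dW2,
                      _["db2"] = dspre, _["dv"] = dv, _["dbv"] = dbv,
                      _["dx"] = dx);
}

// ---- full attention-residual block ----------------------------------------
// One call per block per sample: conv -> ReLU -> scSE -> conv (+ shortcut),
// ReLU after the addition, scSE on the sum. Mirrors the layer algebra above.

static List scse_fwd_l(const arma::mat& x, const List& p) {
  return cpp_scse_fwd(x, as<arma::mat>(p["W1"]), as<arma::vec>(p["b1"]),
                      as<arma::mat>(p["W2"]), as<arma::vec>(p["b2"]),
                      as<arma::vec>(p["v"]), as<double>(p["bv"]));
}

static List scse_bwd_l(const arma::mat& dy, const arma::mat& x,
                       const List& p, const List& cache) {
  return cpp_scse_bwd(dy, x, as<arma::mat>(p["W1"]), as<arma::mat>(p["W2"]),
                      as<arma::vec>(p["v"]), as<arma::rowvec>(cache["z"]),
                      as<arma::vec>(cache["a1pre"]), as<arma::vec>(cache["a1"]),
                      as<arma::vec>(cache["s"]), as<arma::vec>(cache["q"]),
                      as<arma::umat>(cache["m"]));
}

// [[Rcpp::export(name = "cpp_resblock_fwd")]]
List cpp_resblock_fwd(const arma::mat& x, const List& p, int dilation) {
  List conv1 = p["conv1"], conv2 = p["conv2"];
  int k1 = as<int>(conv1["k"]), k2 = as<int>(conv2["k"]);
  List c1 = cpp_conv_fwd(x, as<arma::mat>(conv1["W"]),
                         as<arma::vec>(conv1["b"]), k1, dilation);
  arma::mat c1y = c1["y"];
  arma::mat h1 = arma::clamp(c1y, 0.0, arma::datum::inf);
  List s1 = scse_fwd_l(h1, p["se1"]);
  arma::mat s1y = s1["y"];
  List c2 = cpp_conv_fwd(s1y, as<arma::mat>(conv2["W"]),
                         as<arma::vec>(conv2["b"]), k2, dilation);
  arma::mat add = as<arma::mat>(c2["y"]);
  List pc;
  bool has_proj = !Rf_isNull(p["proj"]);
  if (has_proj) {
    List proj = p["proj"];
    pc = cpp_conv_fwd(x, as<arma::mat>(proj["W"]),
                      as<arma::vec>(proj["b"]), as<int>(proj["k"]), 1);
    add += as<arma::mat>(pc["y"]);
  } else {
    add += x;
  }
  arma::mat h2 = arma::clamp(add, 0.0, arma::datum::inf);
  List s2 = scse_fwd_l(h2, p["se2"]);
  return List::create(_["y"] = s2["y"], _["c1"] = c1, _["c1y"] = c1y,
                      _["h1"] = h1, _["s1"] = s1, _["s1y"] = s1y,
                      _["c2"] = c2, _["pc"] = pc, _["add"] = add,
                      _["h2"] = h2, _["s2"] = s2);
}

// [[Rcpp::export(name = "cpp_resblock_bwd")]]
List cpp_resblock_bwd(const arma::mat& dy, const List& p, const List& cache,
                      int dilation) {
  List conv1 = p["conv1"], conv2 = p["conv2"];
  arma::mat h2 = cache["h2"];
  List b2 = scse_bwd_l(dy, h2, p["se2"], cache["s2"]);
  arma::mat dadd = as<arma::mat>(b2["dx"]) %
    arma::conv_to<arma::mat>::from(as<arma::mat>(cache["add"]) > 0);
  List c2cache = cache["c2"];
  List bc2 = cpp_conv_bwd(dadd, as<arma::mat>(conv2["W"]),
                          as<arma::mat>(c2cache["xcat"]),
                          as<int>(conv2["k"]), as<int>(conv2["cin"]),
                          dilation);
  arma::mat dx_sc;
  List gproj;
  bool has_proj = !Rf_isNull(p["proj"]);
  if (has_proj) {
    List proj = p["proj"];
    List pcache = cache["pc"];
    List bp = cpp_conv_bwd(dadd, as<arma::mat>(proj["W"]),
                           as<arma::mat>(pcache["xcat"]),
                           as<int>(proj["k"]), as<int>(proj["cin"]), 1);
    dx_sc = as<arma::mat>(bp["dx"]);
    gproj = List::create(_["W"] = bp["dW"], _["b"] = bp["db"]);
  } else {
    dx_sc = dadd;
  }
  arma::mat h1 = cache["h1"];
  List b1 = scse_bwd_l(as<arma::mat>(bc2["dx"]), h1, p["se1"], cache["s1"]);
  arma::mat dc1 = as<arma::mat>(b1["dx"]) %
    arma::conv_to<arma::mat>::from(as<arma::mat>(cache["c1y"]) > 0);
  List c1cache = cache["c1"];
  List bc1 = cpp_conv_bwd(dc1, as<arma::mat>(conv1["W"]),
                          as<arma::mat>(c1cache["xcat"]),
                          as<int>(conv1["k"]), as<int>(conv1["cin"]),
                          dilation);
  List grad = List::create(
    _["conv1"] = List::create(_["W"] = bc1["dW"], _["b"] = bc1["db"]),
    _["se1"] = List::create(_["W1"] = b1["dW1"], _["b1"] = b1["db1"],
                            _["W2"] = b1["dW2"], _["b2"] = b1["db2"],
                            _["v"] = b1["dv"], _["bv"] = b1["dbv"]),
    _["conv2"] = List::create(_["W"] = bc2["dW"], _["b"] = bc2["db"]),
    _["se2"] = List::create(_["W1"] = b2["dW1"], _["b1"] = b2["db1"],
                            _["W2"] = b2["dW2"], _["b2"] = b2["db2"],
                            _["v"] = b2["dv"], _["bv"] = b2["dbv"]),
    _["proj"] = has_proj ? wrap(gproj) : R_NilValue);
  return List::create(_["grad"] = grad,
                      _["dx"] = as<arma::mat>(bc1["dx"]) + dx_sc);
}
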