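// Transformer encoder for multichannel fNIRS window regression.
//
// Forward pass, analytic backward pass and the hybrid MSE + Pearson loss
// are implemented here; optimisation (AdamW) lives in R.  Input windows
// arrive flattened as an (B*T) x F matrix with each window's T time steps
// contiguous; all linear algebra runs through BLAS via Armadillo.
//
// Architecture (post-norm residual blocks):
//   affine input projection F_in -> D, (+ positional encoding)
//   n_blocks x [ multi-head self-attention -> dropout -> add -> layernorm;
//                feed-forward D -> Dff (GELU) -> D -> dropout -> add ->
//                layernorm ]
//   affine output projection D -> F_out
//
// The core is templated on the floating type: training uses the
// single-precision path (the standard precision for this model class,
// and about twice as fast on one CPU), while gradient-checking and any
// caller needing strict accuracy use the double path.  Dropout masks are
// drawn from Armadillo's RNG seeded from R's RNG, so everything is
// reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double LN_EPS = 1e-5;

struct Cfg {
  int T, Fin, Fout, D, H, nblocks, Dff;
  double dropout;
  std::string posenc;
  bool training;
};

static Cfg read_cfg(const List& cfg, bool training) {
  Cfg c;
  c.T = as<int>(cfg["window_len"]);
  c.Fin = as<int>(cfg["n_features_in"]);
  c.Fout = as<int>(cfg["n_features_out"]);
  c.D = as<int>(cfg["embed_dim"]);
  c.H = as<int>(cfg["n_heads"]);
  c.nblocks = as<int>(cfg["n_blocks"]);
  c.Dff = as<int>(cfg["ff_dim"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.posenc = as<std::string>(cfg["positional_encoding"]);
  c.training = training;
  return c;
}

static std::string bname(const char* stem, int i) {
  return std::string(stem) + std::to_string(i);
}

// named parameter store converted once per call from the R list
template <typename T>
struct Params {
  std::map<std::string, Mat<T>> m;
  const Mat<T>& mat(const std::string& n) const {
    auto it = m.find(n);
    if (it == m.end()) stop("missing parameter: " + n);
    return it->second;
  }
  Row<T> row(const std::string& n) const {
    const Mat<T>& x = mat(n);
    return conv_to<Row<T>>::from(vectorise(x));
  }
};

template <typename T>
static Params<T> read_params(const List& p) {
  Params<T> out;
  CharacterVector nms = p.names();
  for (int i = 0; i < p.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    RObject o = p[i];
    if (Rf_isMatrix(o)) {
      out.m[nm] = conv_to<Mat<T>>::from(as<mat>(o));
    } else {
      vec v = as<vec>(o);
      out.m[nm] = conv_to<Mat<T>>::from(mat(v.memptr(), 1, v.n_elem));
    }
  }
  return out;
}

// sinusoidal positional encoding, T x D
template <typename T>
static Mat<T> sinusoidal_pe(int Tlen, int D) {
  Mat<T> pe(Tlen, D, fill::zeros);
  for (int t = 0; t < Tlen; ++t) {
    for (int i = 0; i < D / 2; ++i) {
      double w = std::pow(10000.0, -2.0 * i / D);
      pe(t, 2 * i) = (T)std::sin(t * w);
      if (2 * i + 1 < D) pe(t, 2 * i + 1) = (T)std::cos(t * w);
    }
  }
  return pe;
}

template <typename T>
static Mat<T> gelu(const Mat<T>& x) {
  return (T)0.5 * x % ((T)1 + erf(x / (T)M_SQRT2));
}
template <typename T>
static Mat<T> gelu_grad(const Mat<T>& x) {
  return (T)0.5 * ((T)1 + erf(x / (T)M_SQRT2)) +
         x % exp((T)(-0.5) * square(x)) / (T)std::sqrt(2.0 * M_PI);
}

template <typename T>
static Mat<T> dropout_mask(uword n, uword m, double p) {
  Mat<T> mask(n, m, fill::randu);
  T keep = (T)(1.0 - p);
  mask.transform([keep](T u) { return u < keep ? (T)1 / keep : (T)0; });
  return mask;
}

// layer norm forward; stores xhat and inverse sd
template <typename T>
static Mat<T> layernorm_fwd(const Mat<T>& x, const Row<T>& g, const Row<T>& b,
                            Mat<T>& xhat, Col<T>& invstd) {
  Col<T> mu = mean(x, 1);
  Col<T> va = var(x, 1, 1);  // population variance per row
  invstd = (T)1 / sqrt(va + (T)LN_EPS);
  xhat = x.each_col() - mu;
  xhat.each_col() %= invstd;
  Mat<T> y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

template <typename T>
static Mat<T> layernorm_bwd(const Mat<T>& dy, const Mat<T>& xhat,
                            const Col<T>& invstd, const Row<T>& g,
                            Row<T>& gg, Row<T>& gb) {
  gg = sum(dy % xhat, 0);
  gb = sum(dy, 0);
  Mat<T> dxhat = dy.each_row() % g;
  Col<T> m1 = mean(dxhat, 1);
  Col<T> m2 = mean(dxhat % xhat, 1);
  Mat<T> dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invstd;
  return dx;
}

template <typename T>
struct BlockCache {
  Mat<T> Ain, Q, K, V, Ctx, M1, xhat1;
  Col<T> invstd1;
  Mat<T> Hmid, Z1, G, M2, xhat2;
  Col<T> invstd2;
  std::vector<Mat<T>> P;  // softmax attention, one T x T matrix per (b, h)
};

template <typename T>
struct FwdCache {
  Mat<T> Xf, Hfinal;
  std::vector<BlockCache<T>> blocks;
};

template <typename T>
static Mat<T> forward_core(const Params<T>& params, const Mat<T>& Xf,
                           const Cfg& c, FwdCache<T>* cache) {
  const int Tlen = c.T;
  const int B = Xf.n_rows / Tlen;
  const int dh = c.D / c.H;
  const T scal = (T)(1.0 / std::sqrt((double)dh));
  bool drop = c.training && c.dropout > 0.0;

  Mat<T> H = Xf * params.mat("W_in");
  H.each_row() += params.row("b_in");
  if (c.posenc == "sinusoidal" || c.posenc == "learned") {
    Mat<T> pe = (c.posenc == "learned") ? params.mat("P_pos")
                                        : sinusoidal_pe<T>(Tlen, c.D);
    for (int b = 0; b < B; ++b) H.rows(b * Tlen, b * Tlen + Tlen - 1) += pe;
  }
  if (cache) { cache->Xf = Xf; cache->blocks.resize(c.nblocks); }

  for (int l = 0; l < c.nblocks; ++l) {
    BlockCache<T> bc;
    bc.Ain = H;
    Mat<T> Q = H * params.mat(bname("Wq", l));
    Q.each_row() += params.row(bname("bq", l));
    Mat<T> K = H * params.mat(bname("Wk", l));
    K.each_row() += params.row(bname("bk", l));
    Mat<T> V = H * params.mat(bname("Wv", l));
    V.each_row() += params.row(bname("bv", l));
    Mat<T> Ctx(Q.n_rows, c.D);
    if (cache) bc.P.reserve((size_t)B * c.H);
    Mat<T> S(Tlen, Tlen);
    for (int b = 0; b < B; ++b) {
      int r0 = b * Tlen, r1 = b * Tlen + Tlen - 1;
      for (int h = 0; h < c.H; ++h) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scal;
        S.each_col() -= max(S, 1);
        S = exp(S);
        S.each_col() /= sum(S, 1);
        Ctx.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
        if (cache) bc.P.push_back(S);
      }
    }
    Mat<T> O = Ctx * params.mat(bname("Wo", l));
    O.each_row() += params.row(bname("bo", l));
    if (drop) {
      bc.M1 = dropout_mask<T>(O.n_rows, O.n_cols, c.dropout);
      O %= bc.M1;
    }
    Mat<T> R1 = bc.Ain + O;
    Mat<T> Hmid = layernorm_fwd(R1, params.row(bname("ln1g", l)),
                                params.row(bname("ln1b", l)),
                                bc.xhat1, bc.invstd1);
    Mat<T> Z1 = Hmid * params.mat(bname("W1", l));
    Z1.each_row() += params.row(bname("b1", l));
    Mat<T> G = gelu(Z1);
    Mat<T> Z2 = G * params.mat(bname("W2", l));
    Z2.each_row() += params.row(bname("b2", l));
    if (drop) {
      bc.M2 = dropout_mask<T>(Z2.n_rows, Z2.n_cols, c.dropout);
      Z2 %= bc.M2;
    }
    Mat<T> R2 = Hmid + Z2;
    H = layernorm_fwd(R2, params.row(bname("ln2g", l)),
                      params.row(bname("ln2b", l)),
                      bc.xhat2, bc.invstd2);
    if (cache) {
      bc.Q = std::move(Q); bc.K = std::move(K); bc.V = std::move(V);
      bc.Ctx = std::move(Ctx); bc.Hmid = std::move(Hmid);
      bc.Z1 = std::move(Z1); bc.G = std::move(G);
      cache->blocks[l] = std::move(bc);
    }
  }
  Mat<T> Yp = H * params.mat("W_out");
  Yp.each_row() += params.row("b_out");
  if (cache) cache->Hfinal = std::move(H);
  return Yp;
}

// Hybrid loss: MSE over all cells + alpha * mean over (window, feature)
// of (1 - Pearson r over time).  Zero-variance series contribute r = 0
// with zero gradient.
template <typename T>
static double hybrid_loss_grad(const Mat<T>& Yp, const Mat<T>& Yt, int Tlen,
                               double alpha, double eps, Mat<T>& dY) {
  const int B = Yp.n_rows / Tlen;
  const int F = Yp.n_cols;
  const double ntot = (double)Yp.n_elem;
  Mat<T> diff = Yp - Yt;
  double mse = accu(conv_to<mat>::from(square(diff))) / ntot;
  dY = (T)(2.0 / ntot) * diff;
  double rsum = 0.0;
  const T tol = (T)1e-12;
  for (int b = 0; b < B; ++b) {
    int r0 = b * Tlen, r1 = b * Tlen + Tlen - 1;
    for (int f = 0; f < F; ++f) {
      Col<T> p = Yp.submat(r0, f, r1, f);
      Col<T> y = Yt.submat(r0, f, r1, f);
      Col<T> pc = p - mean(p), yc = y - mean(y);
      T sp = std::sqrt(dot(pc, pc)), sy = std::sqrt(dot(yc, yc));
      if (sp < tol || sy < tol) continue;  // r = 0, no gradient
      T denom = sp * sy + (T)eps;
      T r = dot(pc, yc) / denom;
      rsum += (double)r;
      Col<T> dr = yc / denom - (r * sy / (sp * denom)) * pc;
      dr -= mean(dr);
      dY.submat(r0, f, r1, f) -= (T)(alpha / ((double)B * F)) * dr;
    }
  }
  return mse + alpha * (1.0 - rsum / ((double)B * F));
}

template <typename T>
static List loss_grad_core(const List& params_r, const mat& X, const mat& Y,
                           const Cfg& c, double alpha, double eps) {
  const int Tlen = c.T, dh = c.D / c.H;
  const T scal = (T)(1.0 / std::sqrt((double)dh));
  const int B = X.n_rows / Tlen;
  bool drop = c.training && c.dropout > 0.0;
  // dropout draws go through fill::randu, which RcppArmadillo routes to
  // R's RNG: reproducible under set.seed()
  Params<T> params = read_params<T>(params_r);
  Mat<T> Xf = conv_to<Mat<T>>::from(X);
  Mat<T> Yt = conv_to<Mat<T>>::from(Y);
  FwdCache<T> fc;
  Mat<T> Yp = forward_core<T>(params, Xf, c, &fc);
  Mat<T> dY;
  double loss = hybrid_loss_grad<T>(Yp, Yt, Tlen, alpha, eps, dY);

  List g;
  g["W_out"] = conv_to<mat>::from(fc.Hfinal.t() * dY);
  g["b_out"] = conv_to<rowvec>::from(sum(dY, 0));
  Mat<T> dH = dY * params.mat("W_out").t();

  for (int l = c.nblocks - 1; l >= 0; --l) {
    BlockCache<T>& bc = fc.blocks[l];
    Row<T> gg, gb;
    Mat<T> dR2 = layernorm_bwd<T>(dH, bc.xhat2, bc.invstd2,
                                  params.row(bname("ln2g", l)), gg, gb);
    g[bname("ln2g", l)] = conv_to<rowvec>::from(gg);
    g[bname("ln2b", l)] = conv_to<rowvec>::from(gb);
    Mat<T> dHmid = dR2;
    Mat<T> dZ2 = drop ? Mat<T>(dR2 % bc.M2) : dR2;
    g[bname("W2", l)] = conv_to<mat>::from(bc.G.t() * dZ2);
    g[bname("b2", l)] = conv_to<rowvec>::from(sum(dZ2, 0));
    Mat<T> dG = dZ2 * params.mat(bname("W2", l)).t();
    Mat<T> dZ1 = dG % gelu_grad(bc.Z1);
    g[bname("W1", l)] = conv_to<mat>::from(bc.Hmid.t() * dZ1);
    g[bname("b1", l)] = conv_to<rowvec>::from(sum(dZ1, 0));
    dHmid += dZ1 * params.mat(bname("W1", l)).t();

    Mat<T> dR1 = layernorm_bwd<T>(dHmid, bc.xhat1, bc.invstd1,
                                  params.row(bname("ln1g", l)), gg, gb);
    g[bname("ln1g", l)] = conv_to<rowvec>::from(gg);
    g[bname("ln1b", l)] = conv_to<rowvec>::from(gb);
    Mat<T> dAin = dR1;
    Mat<T> dO = drop ? Mat<T>(dR1 % bc.M1) : dR1;
    g[bname("Wo", l)] = conv_to<mat>::from(bc.Ctx.t() * dO);
    g[bname("bo", l)] = conv_to<rowvec>::from(sum(dO, 0));
    Mat<T> dCtx = dO * params.mat(bname("Wo", l)).t();

    Mat<T> dQ(dCtx.n_rows, c.D, fill::zeros), dK = dQ, dV = dQ;
    Mat<T> dP(Tlen, Tlen), dS(Tlen, Tlen);
    for (int b = 0; b < B; ++b) {
      int r0 = b * Tlen, r1 = b * Tlen + Tlen - 1;
      for (int h = 0; h < c.H; ++h) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        const Mat<T>& P = bc.P[(size_t)b * c.H + h];
        Mat<T> dCb = dCtx.submat(r0, c0, r1, c1);
        dP = dCb * bc.V.submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = P.t() * dCb;
        Col<T> rs = sum(dP % P, 1);
        dS = P % (dP.each_col() - rs);
        dQ.submat(r0, c0, r1, c1) =
            dS * bc.K.submat(r0, c0, r1, c1) * scal;
        dK.submat(r0, c0, r1, c1) =
            dS.t() * bc.Q.submat(r0, c0, r1, c1) * scal;
      }
    }
    g[bname("Wq", l)] = conv_to<mat>::from(bc.Ain.t() * dQ);
    g[bname("bq", l)] = conv_to<rowvec>::from(sum(dQ, 0));
    g[bname("Wk", l)] = conv_to<mat>::from(bc.Ain.t() * dK);
    g[bname("bk", l)] = conv_to<rowvec>::from(sum(dK, 0));
    g[bname("Wv", l)] = conv_to<mat>::from(bc.Ain.t() * dV);
    g[bname("bv", l)] = conv_to<rowvec>::from(sum(dV, 0));
    dAin += dQ * params.mat(bname("Wq", l)).t() +
            dK * params.mat(bname("Wk", l)).t() +
            dV * params.mat(bname("Wv", l)).t();
    dH = dAin;
  }

  g["W_in"] = conv_to<mat>::from(fc.Xf.t() * dH);
  g["b_in"] = conv_to<rowvec>::from(sum(dH, 0));
  if (c.posenc == "learned") {
    Mat<T> gP(Tlen, c.D, fill::zeros);
    for (int b = 0; b < B; ++b) gP += dH.rows(b * Tlen, b * Tlen + Tlen - 1);
    g["P_pos"] = conv_to<mat>::from(gP);
  }
  return List::create(_["loss"] = loss, _["grads"] = g,
                      _["pred"] = conv_to<mat>::from(Yp));
}

// [[Rcpp::export]]
arma::mat cpp_transformer_forward(List params, arma::mat X, List cfg,
                                  bool training = false,
                                  bool single = false) {
  Cfg c = read_cfg(cfg, training);
  if ((int)X.n_cols != c.Fin) stop("feature count does not match config");
  if (X.n_rows % c.T != 0) stop("rows must be a multiple of window_len");
  if (!X.is_finite()) stop("input contains non-finite values");
  if (single) {
    Params<float> p = read_params<float>(params);
    fmat Xf = conv_to<fmat>::from(X);
    return conv_to<mat>::from(forward_core<float>(p, Xf, c, nullptr));
  }
  Params<double> p = read_params<double>(params);
  return forward_core<double>(p, X, c, nullptr);
}

// [[Rcpp::export]]
List cpp_transformer_loss_grad(List params, arma::mat X, arma::mat Y,
                               List cfg, double alpha, double eps,
                               bool training = true, bool single = false) {
  Cfg c = read_cfg(cfg, training);
  if ((int)X.n_cols != c.Fin) stop("feature count does not match config");
  if (X.n_rows % c.T != 0) stop("rows must be a multiple of window_len");
  if (single) return loss_grad_core<float>(params, X, Y, c, alpha, eps);
  return loss_grad_core<double>(params, X, Y, c, alpha, eps);
}
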