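// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// CNN with a fixed topology: valid 2-D convolution (the 1-D one-hot variant
// is the special case kw == image width) -> ReLU -> max pooling -> dropout ->
// flatten -> dense(d1, ReLU) -> dense(d2, sigmoid) -> dense(1, sigmoid).
// Inputs arrive column-major: X is (H*W) x B, one vectorised image per column.
// All heavy arithmetic runs in single precision through BLAS GEMM.

struct Arch {
  int H, W, kh, kw, F, ph, pw, d1, d2;
  int oh, ow, poh, pow, flat;
};

static Arch read_arch(const Rcpp::List& arch) {
  Arch a;
  a.H = arch["H"]; a.W = arch["W"];
  a.kh = arch["kh"]; a.kw = arch["kw"]; a.F = arch["F"];
  a.ph = arch["ph"]; a.pw = arch["pw"];
  a.d1 = arch["d1"]; a.d2 = arch["d2"];
  a.oh = a.H - a.kh + 1;
  a.ow = a.W - a.kw + 1;
  a.poh = a.oh / a.ph;
  a.pow = a.ow / a.pw;
  a.flat = a.poh * a.pow * a.F;
  return a;
}

// im2col for one sample: rows are output positions (j*oh + i), cols kernel taps
static void im2col_one(const float* xb, const Arch& a, float* dst, int ldst) {
  for (int dj = 0; dj < a.kw; ++dj) {
    for (int di = 0; di < a.kh; ++di) {
      int k = dj * a.kh + di;
      float* col_k = dst + (size_t)k * ldst;
      for (int j = 0; j < a.ow; ++j) {
        const float* src = xb + (size_t)(j + dj) * a.H + di;
        memcpy(col_k + (size_t)j * a.oh, src, a.oh * sizeof(float));
      }
    }
  }
}

struct ForwardState {
  fmat col;    // (oh*ow*B) x (kh*kw)
  fmat A1;     // (oh*ow*B) x F, post-ReLU conv activations
  umat amax;   // flat x B, row index into A1 of each pooled maximum
  fmat D;      // flat x B, pooled (and possibly dropped-out) features
  fmat H1;     // d1 x B
  fmat H2;     // d2 x B
  frowvec yhat;  // 1 x B
};

static void forward_pass(const fmat& Xf, const fmat& Wc, const fvec& bc,
                         const fmat& W1, const fvec& b1,
                         const fmat& W2, const fvec& b2,
                         const fvec& W3, float b3,
                         const Arch& a, const fmat* dropmask,
                         ForwardState& st, bool keep_for_backward) {
  const int B = Xf.n_cols;
  const int opos = a.oh * a.ow;

  st.col.set_size((size_t)opos * B, a.kh * a.kw);
  for (int b = 0; b < B; ++b)
    im2col_one(Xf.colptr(b), a, st.col.memptr() + (size_t)b * opos, st.col.n_rows);

  st.A1 = st.col * Wc;
  st.A1.each_row() += bc.t();
  st.A1.transform([](float v) { return v > 0.0f ? v : 0.0f; });

  // max pooling with argmax bookkeeping
  st.D.set_size(a.flat, B);
  st.amax.set_size(a.flat, B);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < a.F; ++f) {
      const float* af = st.A1.colptr(f);
      for (int pj = 0; pj < a.pow; ++pj) {
        for (int pi = 0; pi < a.poh; ++pi) {
          float best = -1.0f;  // activations are >= 0 after ReLU
          size_t besti = 0;
          for (int dj = 0; dj < a.pw; ++dj) {
            for (int di = 0; di < a.ph; ++di) {
              size_t row = (size_t)b * opos +
                           (size_t)(pj * a.pw + dj) * a.oh + (pi * a.ph + di);
              float v = af[row];
              if (v > best) { best = v; besti = row; }
            }
          }
          int fi = f * a.poh * a.pow + pj * a.poh + pi;
          st.D(fi, b) = best;
          st.amax(fi, b) = besti;
        }
      }
    }
  }

  if (dropmask) st.D %= *dropmask;

  st.H1 = W1.t() * st.D;
  st.H1.each_col() += b1;
  st.H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });

  st.H2 = W2.t() * st.H1;
  st.H2.each_col() += b2;
  st.H2 = 1.0f / (1.0f + exp(-st.H2));

  st.yhat = W3.t() * st.H2 + b3;
  st.yhat = 1.0f / (1.0f + exp(-st.yhat));

  if (!keep_for_backward) { st.col.reset(); st.A1.reset(); }
}

static fmat as_fmat(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  const double* p = m.begin();
  float* q = out.memptr();
  for (size_t i = 0; i < out.n_elem; ++i) q[i] = (float)p[i];
  return out;
}

static fvec as_fvec(const Rcpp::NumericVector& v) {
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

struct Params {
  fmat Wc, W1, W2;
  fvec bc, b1, b2, W3;
  float b3;
};

static Params read_params(const Rcpp::List& params) {
  Params p;
  p.Wc = as_fmat(params["Wc"]);
  p.bc = as_fvec(params["bc"]);
  p.W1 = as_fmat(params["W1"]);
  p.b1 = as_fvec(params["b1"]);
  p.W2 = as_fmat(params["W2"]);
  p.b2 = as_fvec(params["b2"]);
  p.W3 = as_fvec(params["W3"]);
  p.b3 = (float)Rcpp::as<double>(params["b3"]);
  return p;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_predict_cpp(const Rcpp::NumericMatrix& X,
                                   const Rcpp::List& params,
                                   const Rcpp::List& arch) {
  Arch a = read_arch(arch);
  Params p = read_params(params);
  fmat Xf = as_fmat(X);
  ForwardState st;
  forward_pass(Xf, p.Wc, p.bc, p.W1, p.b1, p.W2, p.b2, p.W3, p.b3,
               a, nullptr, st, false);
  Rcpp::NumericVector out(st.yhat.n_elem);
  for (size_t i = 0; i < st.yhat.n_elem; ++i) out[i] = st.yhat[i];
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_fwdbwd_cpp(const Rcpp::NumericMatrix& X,
                         const Rcpp::NumericVector& y,
                         const Rcpp::List& params,
                         const Rcpp::List& arch,
                         const Rcpp::NumericMatrix& dropmask) {
  Arch a = read_arch(arch);
  Params p = read_params(params);
  fmat Xf = as_fmat(X);
  const int B = Xf.n_cols;
  fmat mask = as_fmat(dropmask);

  ForwardState st;
  forward_pass(Xf, p.Wc, p.bc, p.W1, p.b1, p.W2, p.b2, p.W3, p.b3,
               a, &mask, st, true);

  fvec yf = as_fvec(y);
  // binary cross-entropy, clipped for numeric safety
  double loss = 0.0;
  const float eps = 1e-7f;
  for (int b = 0; b < B; ++b) {
    float q = std::min(std::max(st.yhat[b], eps), 1.0f - eps);
    loss -= yf[b] * std::log(q) + (1.0f - yf[b]) * std::log(1.0f - q);
  }
  loss /= B;

  // output layer: d(loss)/d(preactivation) for sigmoid + BCE
  frowvec dZ3 = (st.yhat - yf.t()) / (float)B;        // 1 x B
  fvec dW3 = st.H2 * dZ3.t();                         // d2 x 1
  float db3 = accu(dZ3);

  fmat dH2 = p.W3 * dZ3;                              // d2 x B
  fmat dZ2 = dH2 % st.H2 % (1.0f - st.H2);
  fmat dW2 = st.H1 * dZ2.t();                         // d1 x d2
  fvec db2 = sum(dZ2, 1);

  fmat dH1 = p.W2 * dZ2;                              // d1 x B
  fmat dZ1 = dH1;
  dZ1.elem(find(st.H1 <= 0.0f)).zeros();
  fmat dW1 = st.D * dZ1.t();                          // flat x d1
  fvec db1 = sum(dZ1, 1);

  fmat dD = p.W1 * dZ1;                               // flat x B
  dD %= mask;

  // route pooled gradients back through the argmax scatter and the conv
  // ReLU mask; only pooled maxima carry gradient, so accumulate dWc over
  // those rows of the im2col matrix instead of a dense GEMM
  const int taps = a.kh * a.kw;
  fmat dWc(taps, a.F, fill::zeros);
  fvec dbc(a.F, fill::zeros);
  const size_t ldc = st.col.n_rows;
  for (int b = 0; b < B; ++b) {
    for (int fi = 0; fi < a.flat; ++fi) {
      float v = dD(fi, b);
      if (v == 0.0f) continue;
      int f = fi / (a.poh * a.pow);
      size_t row = st.amax(fi, b);
      if (st.A1(row, f) <= 0.0f) continue;
      dbc[f] += v;
      float* w = dWc.colptr(f);
      const float* c = st.col.memptr() + row;
      for (int k = 0; k < taps; ++k) w[k] += v * c[(size_t)k * ldc];
    }
  }

  auto num_mat = [](const fmat& m) {
    Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
    const float* q = m.memptr();
    double* d = out.begin();
    for (size_t i = 0; i < m.n_elem; ++i) d[i] = q[i];
    return out;
  };
  auto num_vec = [](const fvec& v) {
    Rcpp::NumericVector out(v.n_elem);
    for (size_t i = 0; i < v.n_elem; ++i) out[i] = v[i];
    return out;
  };

  Rcpp::NumericVector yhat(B);
  for (int b = 0; b < B; ++b) yhat[b] = st.yhat[b];

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("yhat") = yhat,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wc") = num_mat(dWc),
      Rcpp::Named("bc") = num_vec(dbc),
      Rcpp::Named("W1") = num_mat(dW1),
      Rcpp::Named("b1") = num_vec(db1),
      Rcpp::Named("W2") = num_mat(dW2),
      Rcpp::Named("b2") = num_vec(db2),
      Rcpp::Named("W3") = num_vec(dW3),
      Rcpp::Named("b3") = db3));
}

// In-place Adamax update over a list of parameter arrays. The caller owns
// params / m / u exclusively (snapshots are deep-copied on the R side).
// [[Rcpp::export]]
void adamax_update_cpp(Rcpp::List params, const Rcpp::List& grads,
                       Rcpp::List m, Rcpp::List u, double lr_t,
                       double beta1, double beta2, double eps) {
  for (int k = 0; k < params.size(); ++k) {
    Rcpp::NumericVector p = params[k];
    Rcpp::NumericVector g = grads[k];
    Rcpp::NumericVector mk = m[k];
    Rcpp::NumericVector uk = u[k];
    const R_xlen_t n = p.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      mk[i] = beta1 * mk[i] + (1.0 - beta1) * g[i];
      double au = std::abs(g[i]);
      uk[i] = beta2 * uk[i] > au ? beta2 * uk[i] : au;
      p[i] -= lr_t * mk[i] / (uk[i] + eps);
    }
  }
}
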