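// Minimal CNN engine: 3x3 same-padding convolutions (im2col + GEMM), batch
// normalization, ReLU, global average pooling, dense sigmoid head, binary
// cross-entropy with per-example weights. One call runs a full
// forward+backward pass over a batch and returns loss, predictions, and
// gradients; a second call does inference with running BN statistics.
//
// Layout: a batch is an arma::mat of size (C x H*W*B); column p + HW*b holds
// the C channel values of pixel p (row-major, p = y*W + x) of image b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// im2col for a 3x3 kernel, padding 1, stride s.
// in:  (C x H*W*B), out: (C*9 x Ho*Wo*B)
static arma::mat im2col3(const arma::mat& x, int H, int W, int B, int s,
                         int& Ho, int& Wo) {
  const int C = x.n_rows;
  Ho = (H - 1) / s + 1;
  Wo = (W - 1) / s + 1;
  arma::mat cols(C * 9, (size_t)Ho * Wo * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t xoff = (size_t)b * H * W;
    const size_t coff = (size_t)b * Ho * Wo;
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const size_t ccol = coff + (size_t)oy * Wo + ox;
        double* dst = cols.colptr(ccol);
        for (int ky = -1; ky <= 1; ++ky) {
          const int iy = oy * s + ky;
          for (int kx = -1; kx <= 1; ++kx) {
            const int ix = ox * s + kx;
            const int kidx = (ky + 1) * 3 + (kx + 1);
            if (iy < 0 || iy >= H || ix < 0 || ix >= W) continue;
            const double* src = x.colptr(xoff + (size_t)iy * W + ix);
            std::copy(src, src + C, dst + (size_t)kidx * C);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col3: scatter column gradients back onto the input grid.
static arma::mat col2im3(const arma::mat& dcols, int C, int H, int W, int B,
                         int s, int Ho, int Wo) {
  arma::mat dx(C, (size_t)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t xoff = (size_t)b * H * W;
    const size_t coff = (size_t)b * Ho * Wo;
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const size_t ccol = coff + (size_t)oy * Wo + ox;
        const double* src = dcols.colptr(ccol);
        for (int ky = -1; ky <= 1; ++ky) {
          const int iy = oy * s + ky;
          for (int kx = -1; kx <= 1; ++kx) {
            const int ix = ox * s + kx;
            const int kidx = (ky + 1) * 3 + (kx + 1);
            if (iy < 0 || iy >= H || ix < 0 || ix >= W) continue;
            double* dst = dx.colptr(xoff + (size_t)iy * W + ix);
            const double* s2 = src + (size_t)kidx * C;
            for (int c = 0; c < C; ++c) dst[c] += s2[c];
          }
        }
      }
    }
  }
  return dx;
}

struct LayerCache {
  arma::mat cols;      // im2col of layer input
  arma::mat z;         // conv output, pre-BN
  arma::mat xhat;      // BN-normalized
  arma::vec mu, var;   // batch statistics
  arma::umat relu_mask;
  int H, W, Ho, Wo;
};

// Full forward + backward over one batch.
// params: list of conv layers (W, gamma, beta, rmean, rvar) + head (hw, hb).
// x: (3 x H*W*B) input batch; y: labels; wt: per-example loss weights.
// [[Rcpp::export]]
List cnn_train_batch(List params, const arma::mat& x, int H, int W, int B,
                     const arma::vec& y, const arma::vec& wt,
                     const IntegerVector& strides, double dropout_rate,
                     int dropout_seed, bool update_running) {
  List convs = params["convs"];
  const int L = convs.size();
  std::vector<LayerCache> caches(L);
  std::vector<arma::mat> acts(L + 1);
  acts[0] = x;
  int curH = H, curW = W;

  List new_running(L);
  for (int l = 0; l < L; ++l) {
    List ly = convs[l];
    arma::mat Wm = ly["W"];
    arma::vec gamma = ly["gamma"], beta = ly["beta"];
    arma::vec rmean = ly["rmean"], rvar = ly["rvar"];
    LayerCache& ck = caches[l];
    ck.H = curH; ck.W = curW;
    ck.cols = im2col3(acts[l], curH, curW, B, strides[l], ck.Ho, ck.Wo);
    ck.z = Wm * ck.cols;
    const double m = (double)ck.z.n_cols;
    ck.mu = arma::mean(ck.z, 1);
    ck.var = arma::var(ck.z, 1, 1);  // population variance
    arma::vec inv_sd = 1.0 / arma::sqrt(ck.var + BN_EPS);
    ck.xhat = ck.z;
    ck.xhat.each_col() -= ck.mu;
    ck.xhat.each_col() %= inv_sd;
    arma::mat a = ck.xhat;
    a.each_col() %= gamma;
    a.each_col() += beta;
    ck.relu_mask = (a > 0);
    a.elem(arma::find(ck.relu_mask == 0)).zeros();
    acts[l + 1] = std::move(a);
    if (update_running) {
      arma::vec nm = BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * ck.mu;
      arma::vec nv = BN_MOMENTUM * rvar +
        (1 - BN_MOMENTUM) * ck.var * (m / std::max(m - 1.0, 1.0));
      new_running[l] = List::create(Named("rmean") = nm, Named("rvar") = nv);
    }
    curH = ck.Ho; curW = ck.Wo;
  }

  // global average pool over each image's spatial positions
  const int C = acts[L].n_rows;
  const size_t HW = (size_t)curH * curW;
  arma::mat pooled(C, B);
  for (int b = 0; b < B; ++b) {
    pooled.col(b) = arma::mean(acts[L].cols(b * HW, (b + 1) * HW - 1), 1);
  }

  // dropout on the pooled features (training only)
  arma::mat drop_mask(C, B, arma::fill::ones);
  if (dropout_rate > 0) {
    std::mt19937 rng(dropout_seed);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    for (arma::uword i = 0; i < drop_mask.n_elem; ++i) {
      drop_mask(i) = U(rng) < dropout_rate ? 0.0 : 1.0 / (1.0 - dropout_rate);
    }
    pooled %= drop_mask;
  }

  arma::vec hw = params["hw"];
  double hb = params["hb"];
  arma::vec score = pooled.t() * hw + hb;
  arma::vec p = 1.0 / (1.0 + arma::exp(-score));
  arma::vec pc = arma::clamp(p, 1e-12, 1 - 1e-12);
  double loss = -arma::mean(wt % (y % arma::log(pc) +
                                  (1 - y) % arma::log(1 - pc)));

  // ---- backward ----
  arma::vec dscore = wt % (p - y) / (double)B;
  arma::vec dhw = pooled * dscore;
  double dhb = arma::accu(dscore);
  arma::mat dpooled = hw * dscore.t();          // C x B
  if (dropout_rate > 0) dpooled %= drop_mask;

  arma::mat dact(C, acts[L].n_cols);
  for (int b = 0; b < B; ++b) {
    arma::vec g = dpooled.col(b) / (double)HW;
    dact.cols(b * HW, (b + 1) * HW - 1) = arma::repmat(g, 1, HW);
  }

  List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    List ly = convs[l];
    arma::mat Wm = ly["W"];
    arma::vec gamma = ly["gamma"];
    LayerCache& ck = caches[l];
    dact.elem(arma::find(ck.relu_mask == 0)).zeros();
    arma::vec dgamma = arma::sum(dact % ck.xhat, 1);
    arma::vec dbeta = arma::sum(dact, 1);
    // BN backward (batch statistics)
    const double m = (double)ck.z.n_cols;
    arma::vec inv_sd = 1.0 / arma::sqrt(ck.var + BN_EPS);
    arma::mat dxhat = dact;
    dxhat.each_col() %= gamma;
    arma::vec sum_dxhat = arma::sum(dxhat, 1);
    arma::vec sum_dxhat_xhat = arma::sum(dxhat % ck.xhat, 1);
    arma::mat dz = dxhat * m;
    dz.each_col() -= sum_dxhat;
    arma::mat xs = ck.xhat;
    xs.each_col() %= sum_dxhat_xhat;
    dz -= xs;
    arma::vec coef = inv_sd / m;
    dz.each_col() %= coef;
    arma::mat dW = dz * ck.cols.t();
    if (l > 0) {
      arma::mat dcols = Wm.t() * dz;
      dact = col2im3(dcols, acts[l].n_rows, ck.H, ck.W, B,
                     strides[l], ck.Ho, ck.Wo);
    }
    grads[l] = List::create(Named("W") = dW, Named("gamma") = dgamma,
                            Named("beta") = dbeta);
  }

  return List::create(Named("loss") = loss,
                      Named("pred") = p,
                      Named("grads") = grads,
                      Named("dhw") = dhw,
                      Named("dhb") = dhb,
                      Named("running") = new_running);
}

// Inference with running BN statistics.
// [[Rcpp::export]]
arma::vec cnn_predict_batch(List params, const arma::mat& x, int H, int W,
                            int B, const IntegerVector& strides) {
  List convs = params["convs"];
  const int L = convs.size();
  arma::mat act = x;
  int curH = H, curW = W;
  for (int l = 0; l < L; ++l) {
    List ly = convs[l];
    arma::mat Wm = ly["W"];
    arma::vec gamma = ly["gamma"], beta = ly["beta"];
    arma::vec rmean = ly["rmean"], rvar = ly["rvar"];
    int Ho, Wo;
    arma::mat cols = im2col3(act, curH, curW, B, strides[l], Ho, Wo);
    arma::mat z = Wm * cols;
    arma::vec inv_sd = 1.0 / arma::sqrt(rvar + BN_EPS);
    z.each_col() -= rmean;
    z.each_col() %= inv_sd % gamma;
    z.each_col() += beta;
    z.elem(arma::find(z < 0)).zeros();
    act = std::move(z);
    curH = Ho; curW = Wo;
  }
  const size_t HW = (size_t)curH * curW;
  arma::vec hw = params["hw"];
  double hb = params["hb"];
  arma::vec out(B);
  for (int b = 0; b < B; ++b) {
    arma::vec pooled = arma::mean(act.cols(b * HW, (b + 1) * HW - 1), 1);
    out(b) = 1.0 / (1.0 + std::exp(-(arma::dot(pooled, hw) + hb)));
  }
  return out;
}
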