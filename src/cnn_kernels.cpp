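// Compute kernels for the 1-D convolutional multi-label classifier.
//
// Parameters live in one flat vector theta with fixed layout (see
// .param_layout() on the R side, which must stay in sync):
//   for each of the 4 conv blocks: W (kernel*c_in x c_out, column-major), b
//   then the dense layer: W (flat_dim x 4), b (4).
// Activations are (batch * length) x channels matrices, sample index
// fastest, so position p occupies the contiguous row block
// [(p-1)*B, p*B - 1] and convolution reduces to block copies + one matmul.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Geometry {
  int kernel, pool, n_layers;
  std::vector<int> channels;  // per layer output channels
  std::vector<int> len;       // signal length entering each layer (+ final)
  int input_len, flat_dim;
};

Geometry make_geometry(const Rcpp::IntegerVector& channels, int kernel,
                       int pool, int input_len) {
  Geometry g;
  g.kernel = kernel;
  g.pool = pool;
  g.n_layers = channels.size();
  g.input_len = input_len;
  g.channels.assign(channels.begin(), channels.end());
  g.len.resize(g.n_layers + 1);
  g.len[0] = input_len;
  for (int l = 0; l < g.n_layers; ++l) g.len[l + 1] = g.len[l] / pool;
  g.flat_dim = g.len[g.n_layers] * g.channels[g.n_layers - 1];
  return g;
}

struct ParamView {
  std::vector<mat> convW;
  std::vector<rowvec> convb;
  mat denseW;
  rowvec denseb;
};

// Slice theta into parameter matrices (copies; sizes are tiny).
ParamView unpack(const vec& theta, const Geometry& g) {
  ParamView p;
  uword off = 0;
  int c_in = 1;
  for (int l = 0; l < g.n_layers; ++l) {
    int fan = g.kernel * c_in, c_out = g.channels[l];
    p.convW.push_back(mat(&theta[off], fan, c_out));
    off += (uword)fan * c_out;
    p.convb.push_back(rowvec(&theta[off], c_out));
    off += c_out;
    c_in = c_out;
  }
  p.denseW = mat(&theta[off], g.flat_dim, 4);
  off += (uword)g.flat_dim * 4;
  p.denseb = rowvec(&theta[off], 4);
  off += 4;
  if (off != theta.n_elem) Rcpp::stop("theta length does not match geometry");
  return p;
}

struct LayerCache {
  mat Xcol;    // (B*L) x (kernel*c_in)
  umat active; // ReLU mask
  umat argmax; // pool-window offset (0-based) of each max
};

// im2col for one layer: out-of-range positions contribute zeros.
mat im2col(const mat& A, int B, int L, int c_in, int kernel) {
  int hw = (kernel - 1) / 2;
  mat Xcol(A.n_rows, (uword)kernel * c_in, fill::zeros);
  for (int o = 0; o < kernel; ++o) {
    for (int p = 0; p < L; ++p) {
      int q = p + o - hw;
      if (q < 0 || q >= L) continue;
      Xcol.submat((uword)p * B, (uword)o * c_in, (uword)(p + 1) * B - 1,
                  (uword)(o + 1) * c_in - 1) =
          A.rows((uword)q * B, (uword)(q + 1) * B - 1);
    }
  }
  return Xcol;
}

mat forward(const ParamView& pv, const Geometry& g, const mat& X, int B,
            std::vector<LayerCache>* cache, mat* H_out) {
  mat A = reshape(X, (uword)B * g.input_len, 1);
  int c_in = 1;
  for (int l = 0; l < g.n_layers; ++l) {
    int L = g.len[l], Lp = g.len[l + 1], c_out = g.channels[l];
    mat Xcol = im2col(A, B, L, c_in, g.kernel);
    mat Z = Xcol * pv.convW[l];
    Z.each_row() += pv.convb[l];
    umat active = Z > 0;
    mat R = Z % conv_to<mat>::from(active);
    mat P((uword)B * Lp, c_out);
    umat amax((uword)B * Lp, c_out, fill::zeros);
    for (int q = 0; q < Lp; ++q) {
      uword o0 = (uword)q * B, o1 = (uword)(q + 1) * B - 1;
      mat best = R.rows((uword)(q * g.pool) * B,
                        (uword)(q * g.pool + 1) * B - 1);
      umat am_blk(best.n_rows, best.n_cols, fill::zeros);
      for (int o = 1; o < g.pool; ++o) {
        mat cand = R.rows((uword)(q * g.pool + o) * B,
                          (uword)(q * g.pool + o + 1) * B - 1);
        uvec idx = find(cand > best);
        best.elem(idx) = cand.elem(idx);
        am_blk.elem(idx).fill((uword)o);
      }
      P.rows(o0, o1) = best;
      amax.rows(o0, o1) = am_blk;
    }
    if (cache) {
      (*cache)[l].Xcol = std::move(Xcol);
      (*cache)[l].active = std::move(active);
      (*cache)[l].argmax = std::move(amax);
    }
    A = std::move(P);
    c_in = c_out;
  }
  mat H = reshape(A, B, g.flat_dim);
  if (H_out) *H_out = H;
  mat logits = H * pv.denseW;
  logits.each_row() += pv.denseb;
  return 1.0 / (1.0 + exp(-logits));
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(const arma::vec& theta, const arma::mat& X,
                          const Rcpp::IntegerVector& channels, int kernel,
                          int pool, int input_len) {
  Geometry g = make_geometry(channels, kernel, pool, input_len);
  ParamView pv = unpack(theta, g);
  return forward(pv, g, X, X.n_rows, nullptr, nullptr);
}

// One forward + backward pass; returns the (clamped) BCE loss and the
// gradient as a flat vector matching the theta layout.
// [[Rcpp::export(name = ".cnn_train_step_cpp")]]
Rcpp::List cnn_train_step_cpp(const arma::vec& theta, const arma::mat& X,
                              const arma::mat& Y,
                              const Rcpp::IntegerVector& channels, int kernel,
                              int pool, int input_len) {
  Geometry g = make_geometry(channels, kernel, pool, input_len);
  ParamView pv = unpack(theta, g);
  int B = X.n_rows;
  std::vector<LayerCache> cache(g.n_layers);
  mat H;
  mat prob = forward(pv, g, X, B, &cache, &H);

  const double eps = 1e-7;
  mat pc = clamp(prob, eps, 1.0 - eps);
  double loss = -accu(Y % log(pc) + (1.0 - Y) % log(1.0 - pc)) / pc.n_elem;

  vec grad(theta.n_elem, fill::zeros);
  // offsets mirror unpack()
  std::vector<uword> woff(g.n_layers), boff(g.n_layers);
  uword off = 0;
  int c_in = 1;
  for (int l = 0; l < g.n_layers; ++l) {
    woff[l] = off;
    off += (uword)(g.kernel * c_in) * g.channels[l];
    boff[l] = off;
    off += g.channels[l];
    c_in = g.channels[l];
  }
  uword dW_off = off, db_off = off + (uword)g.flat_dim * 4;

  mat dlogits = (prob - Y) / (double)(B * 4);
  mat dWd = H.t() * dlogits;
  grad.subvec(dW_off, dW_off + dWd.n_elem - 1) = vectorise(dWd);
  grad.subvec(db_off, db_off + 3) = sum(dlogits, 0).t();

  mat dA = dlogits * pv.denseW.t();
  dA.reshape((uword)B * g.len[g.n_layers], g.channels[g.n_layers - 1]);
  int hw = (g.kernel - 1) / 2;
  for (int l = g.n_layers - 1; l >= 0; --l) {
    int L = g.len[l], Lp = g.len[l + 1], c_out = g.channels[l];
    int ci = (l == 0) ? 1 : g.channels[l - 1];
    // un-pool: gradient flows to the argmax offset only
    mat dZ((uword)B * L, c_out, fill::zeros);
    for (int q = 0; q < Lp; ++q) {
      mat dP = dA.rows((uword)q * B, (uword)(q + 1) * B - 1);
      const umat& am = cache[l].argmax;
      for (int o = 0; o < g.pool; ++o) {
        umat sel = am.rows((uword)q * B, (uword)(q + 1) * B - 1) == (uword)o;
        dZ.rows((uword)(q * g.pool + o) * B,
                (uword)(q * g.pool + o + 1) * B - 1) =
            dP % conv_to<mat>::from(sel);
      }
    }
    dZ %= conv_to<mat>::from(cache[l].active);
    mat dW = cache[l].Xcol.t() * dZ;
    grad.subvec(woff[l], woff[l] + dW.n_elem - 1) = vectorise(dW);
    grad.subvec(boff[l], boff[l] + c_out - 1) = sum(dZ, 0).t();
    if (l > 0) {
      mat dXcol = dZ * pv.convW[l].t();
      mat dAprev((uword)B * L, ci, fill::zeros);
      for (int o = 0; o < g.kernel; ++o) {
        for (int p = 0; p < L; ++p) {
          int q = p + o - hw;
          if (q < 0 || q >= L) continue;
          dAprev.rows((uword)q * B, (uword)(q + 1) * B - 1) +=
              dXcol.submat((uword)p * B, (uword)o * ci,
                           (uword)(p + 1) * B - 1, (uword)(o + 1) * ci - 1);
        }
      }
      dA = std::move(dAprev);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
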