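// Compact convolutional network for single-channel index tiles:
//   conv 3x3 (same) -> ReLU -> maxpool 2x2 ->
//   conv 3x3 (same) -> ReLU -> maxpool 2x2 ->
//   dense -> ReLU -> dense(5) -> softmax,
// trained with momentum SGD under a step-halving learning-rate schedule
// and categorical cross-entropy. All randomness (weight init, shuffling)
// is injected from R, so the C++ side is fully deterministic.
//
// Images are stored one per row, pixels column-major (pixel p = i + j*s).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

struct Weights {
  mat W1; vec b1;  // 9 x c1
  mat W2; vec b2;  // 9*c1 x c2
  mat W3; vec b3;  // flat x h
  mat W4; vec b4;  // h x 5
};

static Weights weights_from_list(const List& w) {
  Weights out;
  out.W1 = as<mat>(w["W1"]); out.b1 = as<vec>(w["b1"]);
  out.W2 = as<mat>(w["W2"]); out.b2 = as<vec>(w["b2"]);
  out.W3 = as<mat>(w["W3"]); out.b3 = as<vec>(w["b3"]);
  out.W4 = as<mat>(w["W4"]); out.b4 = as<vec>(w["b4"]);
  return out;
}

static List weights_to_list(const Weights& w) {
  return List::create(_["W1"] = w.W1, _["b1"] = w.b1,
                      _["W2"] = w.W2, _["b2"] = w.b2,
                      _["W3"] = w.W3, _["b3"] = w.b3,
                      _["W4"] = w.W4, _["b4"] = w.b4);
}

static Weights weights_zeros_like(const Weights& w) {
  Weights z;
  z.W1 = arma::zeros<mat>(w.W1.n_rows, w.W1.n_cols); z.b1 = arma::zeros<vec>(w.b1.n_elem);
  z.W2 = arma::zeros<mat>(w.W2.n_rows, w.W2.n_cols); z.b2 = arma::zeros<vec>(w.b2.n_elem);
  z.W3 = arma::zeros<mat>(w.W3.n_rows, w.W3.n_cols); z.b3 = arma::zeros<vec>(w.b3.n_elem);
  z.W4 = arma::zeros<mat>(w.W4.n_rows, w.W4.n_cols); z.b4 = arma::zeros<vec>(w.b4.n_elem);
  return z;
}

// im2col for 3x3 "same" convolution with zero padding; input (s*s) x cin,
// output (s*s) x (9*cin), patch column = c*9 + (di+1) + (dj+1)*3.
static mat im2col3(const mat& in, int s) {
  const int cin = in.n_cols;
  mat out(s * s, 9 * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (di + 1) + (dj + 1) * 3;
        for (int j = 0; j < s; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= s) continue;
          for (int i = 0; i < s; ++i) {
            const int is = i + di;
            if (is < 0 || is >= s) continue;
            out(i + j * s, col) = in(is + js * s, c);
          }
        }
      }
  return out;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the image.
static mat col2im3(const mat& dP, int s, int cin) {
  mat out(s * s, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (di + 1) + (dj + 1) * 3;
        for (int j = 0; j < s; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= s) continue;
          for (int i = 0; i < s; ++i) {
            const int is = i + di;
            if (is < 0 || is >= s) continue;
            out(is + js * s, c) += dP(i + j * s, col);
          }
        }
      }
  return out;
}

// 2x2 max pooling with argmax bookkeeping for the backward pass.
static mat maxpool2(const mat& in, int s, arma::umat& idx) {
  const int s2 = s / 2, C = in.n_cols;
  mat out(s2 * s2, C);
  idx.set_size(s2 * s2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < s2; ++j)
      for (int i = 0; i < s2; ++i) {
        uword best = (2 * i) + (2 * j) * s;
        double bv = in(best, c);
        const uword cand[3] = {
          (uword)((2 * i + 1) + (2 * j) * s),
          (uword)((2 * i) + (2 * j + 1) * s),
          (uword)((2 * i + 1) + (2 * j + 1) * s)};
        for (int k = 0; k < 3; ++k)
          if (in(cand[k], c) > bv) { bv = in(cand[k], c); best = cand[k]; }
        out(i + j * s2, c) = bv;
        idx(i + j * s2, c) = best;
      }
  return out;
}

static mat maxpool2_back(const mat& dout, const arma::umat& idx, int s,
                         int C) {
  mat din(s * s, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword p = 0; p < dout.n_rows; ++p)
      din(idx(p, c), c) += dout(p, c);
  return din;
}

static vec softmax(const vec& z) {
  vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

// Forward + (optionally) backward for one image; returns loss, fills
// probabilities, accumulates gradients into g when backward.
static double image_pass(const Weights& w, const vec& x, int y, int side,
                         bool backward, Weights* g, vec* probs_out) {
  const int s1 = side, s2 = side / 2, s4 = side / 4;
  const int c1 = w.W1.n_cols, c2 = w.W2.n_cols;

  mat in(x);                     // (s1*s1) x 1
  mat P1 = im2col3(in, s1);      // (s1*s1) x 9
  mat Z1 = P1 * w.W1;            // (s1*s1) x c1
  Z1.each_row() += w.b1.t();
  mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
  arma::umat idx1;
  mat Pool1 = maxpool2(A1, s1, idx1);   // (s2*s2) x c1

  mat P2 = im2col3(Pool1, s2);   // (s2*s2) x 9*c1
  mat Z2 = P2 * w.W2;            // (s2*s2) x c2
  Z2.each_row() += w.b2.t();
  mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
  arma::umat idx2;
  mat Pool2 = maxpool2(A2, s2, idx2);   // (s4*s4) x c2

  vec flat = arma::vectorise(Pool2);    // s4*s4*c2
  vec z3 = w.W3.t() * flat + w.b3;
  vec a3 = arma::clamp(z3, 0.0, arma::datum::inf);
  vec z4 = w.W4.t() * a3 + w.b4;
  vec p = softmax(z4);
  if (probs_out) *probs_out = p;
  double loss = -std::log(std::max(p(y), 1e-12));
  if (!backward) return loss;

  vec dz4 = p;
  dz4(y) -= 1.0;
  g->W4 += a3 * dz4.t();
  g->b4 += dz4;
  vec da3 = w.W4 * dz4;
  vec dz3 = da3 % arma::conv_to<vec>::from(z3 > 0);
  g->W3 += flat * dz3.t();
  g->b3 += dz3;
  vec dflat = w.W3 * dz3;
  mat dPool2(dflat.memptr(), s4 * s4, c2);  // copies
  mat dA2 = maxpool2_back(dPool2, idx2, s2, c2);
  mat dZ2 = dA2 % arma::conv_to<mat>::from(Z2 > 0);
  g->W2 += P2.t() * dZ2;
  g->b2 += dZ2.t() * arma::ones<vec>(dZ2.n_rows);
  mat dP2 = dZ2 * w.W2.t();
  mat dPool1 = col2im3(dP2, s2, c1);
  mat dA1 = maxpool2_back(dPool1, idx1, s1, c1);
  mat dZ1 = dA1 % arma::conv_to<mat>::from(Z1 > 0);
  g->W1 += P1.t() * dZ1;
  g->b1 += dZ1.t() * arma::ones<vec>(dZ1.n_rows);
  return loss;
}

// [[Rcpp::export]]
List cnn_loss_grad_cpp(List w_list, const arma::mat& X,
                       const arma::ivec& y, int side) {
  Weights w = weights_from_list(w_list);
  Weights g = weights_zeros_like(w);
  double loss = 0.0;
  const int n = X.n_rows;
  for (int i = 0; i < n; ++i) {
    vec x = X.row(i).t();
    loss += image_pass(w, x, y(i), side, true, &g, nullptr);
  }
  loss /= n;
  g.W1 /= n; g.b1 /= n; g.W2 /= n; g.b2 /= n;
  g.W3 /= n; g.b3 /= n; g.W4 /= n; g.b4 /= n;
  return List::create(_["loss"] = loss, _["grad"] = weights_to_list(g));
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List w_list, const arma::mat& X, int side) {
  Weights w = weights_from_list(w_list);
  const int n = X.n_rows;
  mat out(n, 5);
  vec p;
  for (int i = 0; i < n; ++i) {
    vec x = X.row(i).t();
    image_pass(w, x, 0, side, false, nullptr, &p);
    out.row(i) = p.t();
  }
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List w_list, const arma::mat& X, const arma::ivec& y,
                   int side, const arma::imat& order, int batch_size,
                   double lr0, int halve_every, double momentum,
                   const arma::mat& Xval, const arma::ivec& yval) {
  Weights w = weights_from_list(w_list);
  Weights v = weights_zeros_like(w);  // momentum velocity
  const int n = X.n_rows;
  const int epochs = order.n_cols;
  std::vector<double> batch_loss;
  std::vector<double> val_loss;
  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n) - 1;
      const int bs = end - start + 1;
      Weights g = weights_zeros_like(w);
      double loss = 0.0;
      for (int k = start; k <= end; ++k) {
        const int i = order(k, e);
        vec x = X.row(i).t();
        loss += image_pass(w, x, y(i), side, true, &g, nullptr);
      }
      loss /= bs;
      const double lr = lr0 * std::pow(0.5, (double)(step / halve_every));
      auto sgd = [&](mat& wm, mat& vm, const mat& gm) {
        vm = momentum * vm - lr * (gm / bs);
        wm += vm;
      };
      auto sgdv = [&](vec& wv, vec& vv, const vec& gv) {
        vv = momentum * vv - lr * (gv / bs);
        wv += vv;
      };
      sgd(w.W1, v.W1, g.W1); sgdv(w.b1, v.b1, g.b1);
      sgd(w.W2, v.W2, g.W2); sgdv(w.b2, v.b2, g.b2);
      sgd(w.W3, v.W3, g.W3); sgdv(w.b3, v.b3, g.b3);
      sgd(w.W4, v.W4, g.W4); sgdv(w.b4, v.b4, g.b4);
      batch_loss.push_back(loss);
      ++step;
    }
    if (Xval.n_rows > 0) {
      double vl = 0.0;
      for (uword i = 0; i < Xval.n_rows; ++i) {
        vec x = Xval.row(i).t();
        vl += image_pass(w, x, yval(i), side, false, nullptr, nullptr);
      }
      val_loss.push_back(vl / Xval.n_rows);
    }
  }
  return List::create(_["weights"] = weights_to_list(w),
                      _["batch_loss"] = batch_loss,
                      _["val_loss"] = val_loss,
                      _["steps"] = (double)step);
}
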