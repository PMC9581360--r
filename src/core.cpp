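#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pairwise sup-norm (Chebyshev) distance between the rows of P.
// Row i of P is the sampled ILD signal of direction i over one period.
// [[Rcpp::export]]
arma::mat pairwise_sup_dist(const arma::mat& P) {
  const uword n = P.n_rows, m = P.n_cols;
  mat D(n, n, fill::zeros);
  for (uword t = 0; t < m; ++t) {
    const vec col = P.col(t);
    for (uword i = 0; i < n; ++i) {
      const double pi_ = col[i];
      for (uword j = i + 1; j < n; ++j) {
        const double d = std::fabs(pi_ - col[j]);
        if (d > D(i, j)) D(i, j) = d;
      }
    }
  }
  return symmatu(D);
}

namespace {

// The network trains in single precision: the ILD inputs are smooth
// signals of magnitude ~1 after scaling, and the median over the
// evaluation steps absorbs rounding jitter, while sgemm roughly halves
// the wall time of the training loop.

// Fill with standard normal draws from R's RNG in a fixed element order.
void fill_randn(fmat& M, double sd) {
  for (uword k = 0; k < M.n_elem; ++k)
    M[k] = static_cast<float>(R::norm_rand() * sd);
}

inline fmat relu(const fmat& Z) {
  return clamp(Z, 0.0f, std::numeric_limits<float>::max());
}

inline void relu_backprop(fmat& dZ, const fmat& Z) {
  dZ.elem(find(Z <= 0.0f)).zeros();
}

struct Adam {
  fmat m, v;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(fmat& W, const fmat& g, float lr, double t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * square(g);
    const float c1 = 1.0f - static_cast<float>(std::pow(0.9, t));
    const float c2 = 1.0f - static_cast<float>(std::pow(0.999, t));
    W -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

// ILD matrix (n_t x n_dir, dB) for direction vectors NV (3 x n_dir).
fmat ild_cols(const fmat& Yl, const fmat& Zl, const fmat& Yr,
              const fmat& Zr, float ky, float kz, const fmat& NV) {
  const fmat envl = cos(ky * (Yl * NV)) % cos(kz * (Zl * NV));
  const fmat envr = cos(ky * (Yr * NV)) % cos(kz * (Zr * NV));
  return 20.0f * log10(envl / envr);
}

inline void quantize(fmat& P, float step) {
  if (step > 0.0f) P = floor(P / step + 0.5f) * step;
}

} // namespace

// Train the 3-hidden-layer ReLU regressor mapping discretized ILD signals
// to (theta, phi), and evaluate the test grid after each of the final
// n_eval training steps.  Randomness (weight init, training directions)
// comes from R's RNG, so set.seed() in R makes the run reproducible.
//
// Yl, Zl, Yr, Zr: per-ear pitch/yaw axis histories (n_t x 3).
// grid_ild: raw ILD matrix of the test grid (n_grid x n_t, dB).
// Returns per-grid-direction median guesses (degrees) and the final loss.
// [[Rcpp::export]]
Rcpp::List mlp_train_ild(const arma::mat& Yl, const arma::mat& Zl,
                         const arma::mat& Yr, const arma::mat& Zr,
                         double ky, double kz,
                         const arma::mat& grid_ild,
                         double theta_max, double phi_max,
                         int n_steps, int n_eval, int batch,
                         double lr, double lr_end, int h1, int h2, int h3,
                         double quant_step, double ild_scale) {
  const uword d = Yl.n_rows;          // input dimension = samples per period
  if (grid_ild.n_cols != d) Rcpp::stop("grid_ild has wrong sample count");
  if (n_eval > n_steps) Rcpp::stop("n_eval must be <= n_steps");
  const uword ng = grid_ild.n_rows;

  const fmat fYl = conv_to<fmat>::from(Yl), fZl = conv_to<fmat>::from(Zl);
  const fmat fYr = conv_to<fmat>::from(Yr), fZr = conv_to<fmat>::from(Zr);
  const float fky = static_cast<float>(ky), fkz = static_cast<float>(kz);
  const float fquant = static_cast<float>(quant_step);

  // Test-grid inputs, quantized and scaled once (d x n_grid).
  fmat Xg = conv_to<fmat>::from(grid_ild.t());
  quantize(Xg, fquant);
  Xg /= static_cast<float>(ild_scale);

  // He-initialised weights, zero biases.
  fmat W1(h1, d), W2(h2, h1), W3(h3, h2), W4(2, h3);
  fill_randn(W1, std::sqrt(2.0 / d));
  fill_randn(W2, std::sqrt(2.0 / h1));
  fill_randn(W3, std::sqrt(2.0 / h2));
  fill_randn(W4, std::sqrt(2.0 / h3));
  fvec b1(h1, fill::zeros), b2(h2, fill::zeros), b3(h3, fill::zeros),
       b4(2, fill::zeros);

  Adam aW1(h1, d), aW2(h2, h1), aW3(h3, h2), aW4(2, h3);
  Adam ab1(h1, 1), ab2(h2, 1), ab3(h3, 1), ab4(2, 1);

  fmat Gth(n_eval, ng), Gph(n_eval, ng);
  double loss = NA_REAL;
  const float inv_b = 1.0f / static_cast<float>(batch);

  for (int s = 1; s <= n_steps; ++s) {
    // Fresh uniformly random directions in |theta| <= theta_max,
    // |phi| <= phi_max.
    fmat NV(3, batch);
    frowvec tgt_th(batch), tgt_ph(batch);
    for (int b = 0; b < batch; ++b) {
      const double th = R::runif(-theta_max, theta_max);
      const double ph = R::runif(-phi_max, phi_max);
      const double thr = th * datum::pi / 180.0;
      const double phr = ph * datum::pi / 180.0;
      NV(0, b) = static_cast<float>(std::cos(thr) * std::cos(phr));
      NV(1, b) = static_cast<float>(std::sin(thr) * std::cos(phr));
      NV(2, b) = static_cast<float>(std::sin(phr));
      tgt_th[b] = static_cast<float>(th / theta_max);
      tgt_ph[b] = static_cast<float>(ph / phi_max);
    }
    fmat X = ild_cols(fYl, fZl, fYr, fZr, fky, fkz, NV);
    quantize(X, fquant);
    X /= static_cast<float>(ild_scale);
    fmat Yt = join_cols(tgt_th, tgt_ph);   // 2 x batch, scaled to [-1, 1]

    // Forward.
    fmat Z1 = W1 * X;  Z1.each_col() += b1;  fmat A1 = relu(Z1);
    fmat Z2 = W2 * A1; Z2.each_col() += b2;  fmat A2 = relu(Z2);
    fmat Z3 = W3 * A2; Z3.each_col() += b3;  fmat A3 = relu(Z3);
    fmat Yhat = W4 * A3; Yhat.each_col() += b4;

    fmat dY = (Yhat - Yt) * inv_b;         // d(MSE)/dYhat up to a constant
    loss = accu(square(Yhat - Yt)) * inv_b * 0.5;
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged: non-finite loss at step %d", s);

    // Backward.
    fmat gW4 = dY * A3.t(); fvec gb4 = sum(dY, 1);
    fmat dZ3 = W4.t() * dY; relu_backprop(dZ3, Z3);
    fmat gW3 = dZ3 * A2.t(); fvec gb3 = sum(dZ3, 1);
    fmat dZ2 = W3.t() * dZ3; relu_backprop(dZ2, Z2);
    fmat gW2 = dZ2 * A1.t(); fvec gb2 = sum(dZ2, 1);
    fmat dZ1 = W2.t() * dZ2; relu_backprop(dZ1, Z1);
    fmat gW1 = dZ1 * X.t(); fvec gb1 = sum(dZ1, 1);

    // Exponential learning-rate decay from lr to lr_end over the run.
    const double t = static_cast<double>(s);
    const float lr_t = static_cast<float>(
        lr * std::pow(lr_end / lr, (t - 1.0) / std::max(1, n_steps - 1)));
    aW4.step(W4, gW4, lr_t, t); aW3.step(W3, gW3, lr_t, t);
    aW2.step(W2, gW2, lr_t, t); aW1.step(W1, gW1, lr_t, t);
    fmat b1m(b1.memptr(), h1, 1, false), b2m(b2.memptr(), h2, 1, false),
         b3m(b3.memptr(), h3, 1, false), b4m(b4.memptr(), 2, 1, false);
    ab4.step(b4m, fmat(gb4), lr_t, t); ab3.step(b3m, fmat(gb3), lr_t, t);
    ab2.step(b2m, fmat(gb2), lr_t, t); ab1.step(b1m, fmat(gb1), lr_t, t);

    // Test phase: evaluate the whole grid after each of the last
    // n_eval steps.
    const int k = s - (n_steps - n_eval);
    if (k >= 1) {
      fmat E1 = relu(W1 * Xg + repmat(b1, 1, ng));
      fmat E2 = relu(W2 * E1 + repmat(b2, 1, ng));
      fmat E3 = relu(W3 * E2 + repmat(b3, 1, ng));
      fmat Eo = W4 * E3 + repmat(b4, 1, ng);
      Gth.row(k - 1) = Eo.row(0) * static_cast<float>(theta_max);
      Gph.row(k - 1) = Eo.row(1) * static_cast<float>(phi_max);
    }
  }

  // Median over the evaluation steps, per grid direction and coordinate.
  mat guesses(ng, 2);
  for (uword i = 0; i < ng; ++i) {
    guesses(i, 0) = static_cast<double>(median(Gth.col(i)));
    guesses(i, 1) = static_cast<double>(median(Gph.col(i)));
  }
  return Rcpp::List::create(Rcpp::Named("guesses") = guesses,
                            Rcpp::Named("final_loss") = loss);
}
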