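// Feed-forward softmax classifier: ReLU hidden layers with inverted
// dropout, Adam, categorical cross-entropy. All randomness (init order,
// epoch shuffles, dropout masks) is drawn from R's RNG so training is
// deterministic given the R seed and independent of threading.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat rnorm_mat(int r, int c, double sd) {
  arma::mat m(r, c);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = R::norm_rand() * sd;
  return m;
}

static void shuffle_inplace(arma::uvec &v) {
  // Fisher-Yates using R's RNG
  for (arma::uword i = v.n_elem - 1; i > 0; --i) {
    arma::uword j = (arma::uword)(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

static arma::mat softmax_rows(arma::mat z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

// [[Rcpp::export(name = "cpp_train_mlp")]]
List cpp_train_mlp(const arma::mat &X, const arma::ivec &y, int k_out,
                   const arma::ivec &hidden, double dropout, int epochs,
                   int batch_size, double lr, int patience,
                   double min_delta) {
  const arma::uword n = X.n_rows;
  const int L = hidden.n_elem + 1;
  std::vector<int> sizes;
  sizes.push_back(X.n_cols);
  for (arma::uword l = 0; l < hidden.n_elem; ++l) sizes.push_back(hidden[l]);
  sizes.push_back(k_out);

  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = rnorm_mat(sizes[l], sizes[l + 1], std::sqrt(2.0 / sizes[l]));
    mW[l].zeros(sizes[l], sizes[l + 1]);
    vW[l].zeros(sizes[l], sizes[l + 1]);
    b[l].zeros(sizes[l + 1]);
    mb[l].zeros(sizes[l + 1]);
    vb[l].zeros(sizes[l + 1]);
  }

  arma::mat Y(n, k_out, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) Y(i, y[i] - 1) = 1.0;

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t_step = 0;
  double best = std::numeric_limits<double>::infinity();
  int stale = 0;
  arma::uvec ord = arma::regspace<arma::uvec>(0, n - 1);
  std::vector<arma::mat> acts(L), masks(L);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    shuffle_inplace(ord);
    double total_loss = 0.0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword stop = std::min<arma::uword>(start + batch_size - 1, n - 1);
      arma::uvec idx = ord.subvec(start, stop);
      arma::mat Xb = X.rows(idx);
      arma::mat Yb = Y.rows(idx);
      const double bn = (double)Xb.n_rows;

      // forward
      arma::mat A = Xb;
      for (int l = 0; l < L; ++l) {
        arma::mat Z = A * W[l];
        Z.each_row() += b[l];
        if (l < L - 1) {
          Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
          if (dropout > 0) {
            arma::mat m(Z.n_rows, Z.n_cols);
            for (arma::uword jj = 0; jj < m.n_cols; ++jj)
              for (arma::uword ii = 0; ii < m.n_rows; ++ii)
                m(ii, jj) = (R::unif_rand() >= dropout) ? 1.0 : 0.0;
            Z %= m / (1.0 - dropout);
            masks[l] = m;
          }
        } else {
          Z = softmax_rows(Z);
        }
        acts[l] = Z;
        A = Z;
      }
      total_loss -= arma::accu(Yb % arma::log(arma::clamp(acts[L - 1], 1e-12, 1.0)));

      // backward + Adam
      arma::mat delta = (acts[L - 1] - Yb) / bn;
      ++t_step;
      const double c1 = 1.0 - std::pow(beta1, (double)t_step);
      const double c2 = 1.0 - std::pow(beta2, (double)t_step);
      for (int l = L - 1; l >= 0; --l) {
        const arma::mat &A_prev = (l == 0) ? Xb : acts[l - 1];
        arma::mat gW = A_prev.t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<arma::mat>::from(acts[l - 1] > 0);
          if (dropout > 0 && masks[l - 1].n_elem > 0)
            delta %= masks[l - 1] / (1.0 - dropout);
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * (gW % gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * (gb % gb);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    double epoch_loss = total_loss / (double)n;
    if (!std::isfinite(best) || best - epoch_loss > min_delta) {
      best = epoch_loss;
      stale = 0;
    } else if (++stale >= patience) {
      break;
    }
  }

  List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) {
    Wl[l] = W[l];
    bl[l] = b[l];
  }
  return List::create(Named("W") = Wl, Named("b") = bl);
}

// [[Rcpp::export(name = "cpp_mlp_predict")]]
arma::mat cpp_mlp_predict(const arma::mat &X, const List &net) {
  List Wl = net["W"], bl = net["b"];
  const int L = Wl.size();
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(Wl[l]);
    arma::rowvec b = as<arma::rowvec>(bl[l]);
    arma::mat Z = A * W;
    Z.each_row() += b;
    if (l < L - 1)
      Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    else
      Z = softmax_rows(Z);
    A = Z;
  }
  return A;
}
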