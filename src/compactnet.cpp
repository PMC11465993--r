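// Compact convolutional network for emitter-count classification and
// coordinate regression on small (15x15) single-channel spot images.
//
// Layout conventions:
//  - a batch of images is an arma::mat X (H*H x B), one column per image,
//    pixels in column-major (row + H*col) order;
//  - an activation with C channels is an arma::mat (C x S*B) where column
//    b*S + s holds the channel vector at spatial index s of image b.
//
// Architecture ("compact" backbone): two residual conv blocks
//   conv3x3(1->C) -> ReLU -> conv3x3(C->C) + skip -> ReLU -> maxpool2
//   conv3x3(C->2C) -> ReLU -> conv3x3(2C->2C) + skip -> ReLU
// followed by flatten -> FC(hidden) -> ReLU -> FC(out).
// Classification adds softmax + cross-entropy; regression is linear with the
// MSE loss 1/(2I) sum[(dx)^2 + (dy)^2] (optionally minimized over emitter
// permutations).
//
// All randomness (init, shuffling) draws from R's RNG, so results are pure
// functions of set.seed() under single-threaded execution.

#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col(const mat& A, int H, int B, int ci, mat& P) {
  const int S = H * H;
  P.zeros(ci * 9, (uword)S * B);
  for (int n = 0; n < B; ++n) {
    for (int j = 0; j < H; ++j) {
      for (int i = 0; i < H; ++i) {
        const uword col = (uword)n * S + i + (uword)H * j;
        double* pc = P.colptr(col);
        for (int t = 0; t < 9; ++t) {
          const int di = t % 3 - 1, dj = t / 3 - 1;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= H || jj < 0 || jj >= H) continue;
          const uword src = (uword)n * S + ii + (uword)H * jj;
          std::memcpy(pc + (uword)t * ci, A.colptr(src), ci * sizeof(double));
        }
      }
    }
  }
}

static void col2im(const mat& P, int H, int B, int ci, mat& dA) {
  const int S = H * H;
  dA.zeros(ci, (uword)S * B);
  for (int n = 0; n < B; ++n) {
    for (int j = 0; j < H; ++j) {
      for (int i = 0; i < H; ++i) {
        const uword col = (uword)n * S + i + (uword)H * j;
        const double* pc = P.colptr(col);
        for (int t = 0; t < 9; ++t) {
          const int di = t % 3 - 1, dj = t / 3 - 1;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= H || jj < 0 || jj >= H) continue;
          const uword src = (uword)n * S + ii + (uword)H * jj;
          double* pd = dA.colptr(src);
          const double* ps = pc + (uword)t * ci;
          for (int c = 0; c < ci; ++c) pd[c] += ps[c];
        }
      }
    }
  }
}

struct ConvCache { mat P, Z; };

static mat conv_forward(const mat& A, const mat& W, const vec& b,
                        int H, int B, ConvCache& cache) {
  const int ci = A.n_rows;
  im2col(A, H, B, ci, cache.P);
  cache.Z = W * cache.P;
  cache.Z.each_col() += b;
  return cache.Z;
}

static mat conv_backward(const mat& dZ, const mat& W, const ConvCache& cache,
                         int H, int B, mat& dW, vec& db) {
  dW = dZ * cache.P.t();
  db = sum(dZ, 1);
  mat dP = W.t() * dZ;
  mat dA;
  col2im(dP, H, B, W.n_cols / 9, dA);
  return dA;
}

static mat maxpool_forward(const mat& A, int H, int B, umat& argsrc) {
  const int C = A.n_rows, Hp = H / 2, S = H * H, Sp = Hp * Hp;
  mat out(C, (uword)Sp * B);
  argsrc.set_size(C, (uword)Sp * B);
  for (int n = 0; n < B; ++n) {
    for (int jp = 0; jp < Hp; ++jp) {
      for (int ip = 0; ip < Hp; ++ip) {
        const uword oc = (uword)n * Sp + ip + (uword)Hp * jp;
        const uword cand[4] = {
          (uword)n * S + (2 * ip)     + (uword)H * (2 * jp),
          (uword)n * S + (2 * ip + 1) + (uword)H * (2 * jp),
          (uword)n * S + (2 * ip)     + (uword)H * (2 * jp + 1),
          (uword)n * S + (2 * ip + 1) + (uword)H * (2 * jp + 1) };
        for (int c = 0; c < C; ++c) {
          double best = A(c, cand[0]); uword bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            const double v = A(c, cand[q]);
            if (v > best) { best = v; bi = cand[q]; }
          }
          out(c, oc) = best; argsrc(c, oc) = bi;
        }
      }
    }
  }
  return out;
}

static mat maxpool_backward(const mat& dOut, const umat& argsrc,
                            int C, int H, int B) {
  mat dA(C, (uword)H * H * B, fill::zeros);
  for (uword oc = 0; oc < dOut.n_cols; ++oc) {
    for (int c = 0; c < C; ++c) dA(c, argsrc(c, oc)) += dOut(c, oc);
  }
  return dA;
}

static mat flatten_forward(const mat& A, int S, int B) {
  const int C = A.n_rows;
  mat F((uword)C * S, B);
  for (int n = 0; n < B; ++n) {
    double* fc = F.colptr(n);
    for (int s = 0; s < S; ++s) {
      std::memcpy(fc + (uword)C * s, A.colptr((uword)n * S + s),
                  C * sizeof(double));
    }
  }
  return F;
}

static mat flatten_backward(const mat& dF, int C, int S, int B) {
  mat dA(C, (uword)S * B);
  for (int n = 0; n < B; ++n) {
    const double* fc = dF.colptr(n);
    for (int s = 0; s < S; ++s) {
      std::memcpy(dA.colptr((uword)n * S + s), fc + (uword)C * s,
                  C * sizeof(double));
    }
  }
  return dA;
}

struct Net {
  mat Wc1, Wc2, Wc3, Wc4, Wf1, Wf2;
  vec bc1, bc2, bc3, bc4, bf1, bf2;
  int C, hidden, out_dim;
};

static Net net_from_list(Rcpp::List params) {
  Net net;
  net.Wc1 = Rcpp::as<mat>(params["Wc1"]); net.bc1 = Rcpp::as<vec>(params["bc1"]);
  net.Wc2 = Rcpp::as<mat>(params["Wc2"]); net.bc2 = Rcpp::as<vec>(params["bc2"]);
  net.Wc3 = Rcpp::as<mat>(params["Wc3"]); net.bc3 = Rcpp::as<vec>(params["bc3"]);
  net.Wc4 = Rcpp::as<mat>(params["Wc4"]); net.bc4 = Rcpp::as<vec>(params["bc4"]);
  net.Wf1 = Rcpp::as<mat>(params["Wf1"]); net.bf1 = Rcpp::as<vec>(params["bf1"]);
  net.Wf2 = Rcpp::as<mat>(params["Wf2"]); net.bf2 = Rcpp::as<vec>(params["bf2"]);
  net.C = net.Wc1.n_rows;
  net.hidden = net.Wf1.n_rows;
  net.out_dim = net.Wf2.n_rows;
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  return Rcpp::List::create(
    Rcpp::Named("Wc1") = net.Wc1, Rcpp::Named("bc1") = net.bc1,
    Rcpp::Named("Wc2") = net.Wc2, Rcpp::Named("bc2") = net.bc2,
    Rcpp::Named("Wc3") = net.Wc3, Rcpp::Named("bc3") = net.bc3,
    Rcpp::Named("Wc4") = net.Wc4, Rcpp::Named("bc4") = net.bc4,
    Rcpp::Named("Wf1") = net.Wf1, Rcpp::Named("bf1") = net.bf1,
    Rcpp::Named("Wf2") = net.Wf2, Rcpp::Named("bf2") = net.bf2);
}

struct FwdCache {
  ConvCache c1, c2, c3, c4;
  mat a1, a2, p, a3, a4, F, h1, out;
  umat poolarg;
  int H, Hp, B;
};

static mat net_forward(const Net& net, const mat& X, FwdCache& fc) {
  const int B = X.n_cols;
  const int H = (int)std::lround(std::sqrt((double)X.n_rows));
  const int Hp = H / 2;
  fc.H = H; fc.Hp = Hp; fc.B = B;
  // input as 1-channel activation: (1 x S*B)
  mat A0(1, X.n_rows * (uword)B);
  for (int n = 0; n < B; ++n) {
    std::memcpy(A0.memptr() + (uword)n * X.n_rows, X.colptr(n),
                X.n_rows * sizeof(double));
  }
  mat z1 = conv_forward(A0, net.Wc1, net.bc1, H, B, fc.c1);
  fc.a1 = clamp(z1, 0.0, datum::inf);
  mat z2 = conv_forward(fc.a1, net.Wc2, net.bc2, H, B, fc.c2);
  fc.a2 = clamp(z2 + fc.a1, 0.0, datum::inf);
  fc.p = maxpool_forward(fc.a2, H, B, fc.poolarg);
  mat z3 = conv_forward(fc.p, net.Wc3, net.bc3, Hp, B, fc.c3);
  fc.a3 = clamp(z3, 0.0, datum::inf);
  mat z4 = conv_forward(fc.a3, net.Wc4, net.bc4, Hp, B, fc.c4);
  fc.a4 = clamp(z4 + fc.a3, 0.0, datum::inf);
  fc.F = flatten_forward(fc.a4, Hp * Hp, B);
  mat zh = net.Wf1 * fc.F;
  zh.each_col() += net.bf1;
  fc.h1 = clamp(zh, 0.0, datum::inf);
  fc.out = net.Wf2 * fc.h1;
  fc.out.each_col() += net.bf2;
  return fc.out;
}

static void net_backward(const Net& net, const FwdCache& fc, const mat& dOut,
                         Net& g) {
  const int B = fc.B, H = fc.H, Hp = fc.Hp;
  g.Wf2 = dOut * fc.h1.t();
  g.bf2 = sum(dOut, 1);
  mat dh1 = net.Wf2.t() * dOut;
  dh1 %= conv_to<mat>::from(fc.h1 > 0);
  g.Wf1 = dh1 * fc.F.t();
  g.bf1 = sum(dh1, 1);
  mat dF = net.Wf1.t() * dh1;
  mat da4 = flatten_backward(dF, fc.a4.n_rows, Hp * Hp, B);
  mat dz4 = da4 % conv_to<mat>::from(fc.a4 > 0);
  mat da3 = conv_backward(dz4, net.Wc4, fc.c4, Hp, B, g.Wc4, g.bc4);
  da3 += dz4; // skip connection
  mat dz3 = da3 % conv_to<mat>::from(fc.a3 > 0);
  mat dp = conv_backward(dz3, net.Wc3, fc.c3, Hp, B, g.Wc3, g.bc3);
  mat da2 = maxpool_backward(dp, fc.poolarg, fc.a2.n_rows, H, B);
  mat dz2 = da2 % conv_to<mat>::from(fc.a2 > 0);
  mat da1 = conv_backward(dz2, net.Wc2, fc.c2, H, B, g.Wc2, g.bc2);
  da1 += dz2; // skip connection
  mat dz1 = da1 % conv_to<mat>::from(fc.a1 > 0);
  mat dA0 = conv_backward(dz1, net.Wc1, fc.c1, H, B, g.Wc1, g.bc1);
  (void)dA0;
}

static mat softmax_cols(const mat& Z) {
  mat P = Z;
  P.each_row() -= max(Z, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

// permutations of 0..(I-1) for permutation-min MSE
static std::vector<std::vector<int> > all_perms(int I) {
  std::vector<int> idx(I);
  for (int i = 0; i < I; ++i) idx[i] = i;
  std::vector<std::vector<int> > out;
  do { out.push_back(idx); } while (std::next_permutation(idx.begin(), idx.end()));
  return out;
}

// For each column, reorder the emitter blocks (x_i, y_i) of Y to minimize the
// MSE against the prediction; returns the reordered targets.
static mat best_perm_targets(const mat& out, const mat& Y) {
  const int I = out.n_rows / 2;
  if (I < 2) return Y;
  std::vector<std::vector<int> > perms = all_perms(I);
  mat Yb = Y;
  for (uword n = 0; n < out.n_cols; ++n) {
    double best = datum::inf;
    const std::vector<int>* bp = nullptr;
    for (size_t p = 0; p < perms.size(); ++p) {
      double cost = 0;
      for (int i = 0; i < I; ++i) {
        const int src = perms[p][i];
        const double dx = out(2 * i, n) - Y(2 * src, n);
        const double dy = out(2 * i + 1, n) - Y(2 * src + 1, n);
        cost += dx * dx + dy * dy;
      }
      if (cost < best) { best = cost; bp = &perms[p]; }
    }
    for (int i = 0; i < I; ++i) {
      Yb(2 * i, n) = Y(2 * (*bp)[i], n);
      Yb(2 * i + 1, n) = Y(2 * (*bp)[i] + 1, n);
    }
  }
  return Yb;
}

// task: 0 = classify (Y = 0-based class indices), 1 = localize canonical,
// 2 = localize permutation-min. Returns mean per-sample loss; fills dOut.
static double loss_and_grad(int task, const mat& out, const mat& Y,
                            mat& dOut) {
  const int B = out.n_cols;
  if (task == 0) {
    mat P = softmax_cols(out);
    double L = 0;
    dOut = P;
    for (int n = 0; n < B; ++n) {
      const int k = (int)Y(0, n);
      L -= std::log(std::max(P(k, n), 1e-300));
      dOut(k, n) -= 1.0;
    }
    dOut /= B;
    return L / B;
  }
  const int I = out.n_rows / 2;
  mat Yt = (task == 2) ? best_perm_targets(out, Y) : Y;
  mat D = out - Yt;
  dOut = D / ((double)I * B);
  return accu(square(D)) / (2.0 * I * B);
}

struct AdamState { std::vector<mat> mW, vW; std::vector<vec> mb, vb; long t = 0; };

static void adam_step(std::vector<mat*>& Ws, std::vector<vec*>& bs,
                      std::vector<mat*>& gWs, std::vector<vec*>& gbs,
                      AdamState& st, double lr, double wd) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.t += 1;
  const double c1 = 1.0 - std::pow(b1, (double)st.t);
  const double c2 = 1.0 - std::pow(b2, (double)st.t);
  for (size_t i = 0; i < Ws.size(); ++i) {
    mat g = *gWs[i] + wd * (*Ws[i]); // L2 penalty on weights only
    st.mW[i] = b1 * st.mW[i] + (1 - b1) * g;
    st.vW[i] = b2 * st.vW[i] + (1 - b2) * square(g);
    *Ws[i] -= lr * (st.mW[i] / c1) / (sqrt(st.vW[i] / c2) + eps);
    vec gb = *gbs[i];
    st.mb[i] = b1 * st.mb[i] + (1 - b1) * gb;
    st.vb[i] = b2 * st.vb[i] + (1 - b2) * square(gb);
    *bs[i] -= lr * (st.mb[i] / c1) / (sqrt(st.vb[i] / c2) + eps);
  }
}

static mat he_init(int rows, int cols, double fan_in) {
  mat W(rows, cols);
  const double sd = std::sqrt(2.0 / fan_in);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
  return W;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_init(int channels, int hidden, int out_dim, int input_hw) {
  const int Hp = input_hw / 2;
  Net net;
  net.Wc1 = he_init(channels, 9, 9);
  net.Wc2 = he_init(channels, channels * 9, channels * 9.0);
  net.Wc3 = he_init(2 * channels, channels * 9, channels * 9.0);
  net.Wc4 = he_init(2 * channels, 2 * channels * 9, 2 * channels * 9.0);
  net.Wf1 = he_init(hidden, 2 * channels * Hp * Hp, 2.0 * channels * Hp * Hp);
  net.Wf2 = he_init(out_dim, hidden, (double)hidden);
  net.bc1.zeros(channels); net.bc2.zeros(channels);
  net.bc3.zeros(2 * channels); net.bc4.zeros(2 * channels);
  net.bf1.zeros(hidden); net.bf2.zeros(out_dim);
  return net_to_list(net);
}

// [[Rcpp::export]]
arma::mat cpp_net_forward(Rcpp::List params, const arma::mat& X,
                          bool softmax) {
  Net net = net_from_list(params);
  mat out;
  const uword chunk = 512; // bound memory on large inputs
  FwdCache fc;
  out.set_size(net.out_dim, X.n_cols);
  for (uword start = 0; start < X.n_cols; start += chunk) {
    const uword end = std::min(start + chunk - 1, X.n_cols - 1);
    mat o = net_forward(net, X.cols(start, end), fc);
    out.cols(start, end) = softmax ? softmax_cols(o) : o;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_train(Rcpp::List params, const arma::mat& X,
                         const arma::mat& Y, int task, int epochs,
                         int batch_size, double lr0, double lr1,
                         double weight_decay,
                         Rcpp::Nullable<Rcpp::NumericMatrix> X_val_,
                         Rcpp::Nullable<Rcpp::NumericMatrix> Y_val_,
                         bool verbose) {
  Net net = net_from_list(params);
  const int n = X.n_cols;
  mat X_val, Y_val;
  const bool has_val = X_val_.isNotNull();
  if (has_val) {
    X_val = Rcpp::as<mat>(X_val_.get());
    Y_val = Rcpp::as<mat>(Y_val_.get());
  }

  AdamState st;
  std::vector<mat*> Ws = { &net.Wc1, &net.Wc2, &net.Wc3, &net.Wc4,
                           &net.Wf1, &net.Wf2 };
  std::vector<vec*> bs = { &net.bc1, &net.bc2, &net.bc3, &net.bc4,
                           &net.bf1, &net.bf2 };
  for (size_t i = 0; i < Ws.size(); ++i) {
    st.mW.push_back(zeros<mat>(size(*Ws[i])));
    st.vW.push_back(zeros<mat>(size(*Ws[i])));
    st.mb.push_back(zeros<vec>(bs[i]->n_elem));
    st.vb.push_back(zeros<vec>(bs[i]->n_elem));
  }

  std::vector<double> hist_train, hist_val, hist_metric;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  FwdCache fc;
  Net grads;

  for (int ep = 0; ep < epochs; ++ep) {
    // cosine annealing from lr0 to lr1 across epochs
    const double frac = epochs > 1 ? (double)ep / (epochs - 1) : 0.0;
    const double lr = lr1 + 0.5 * (lr0 - lr1) * (1.0 + std::cos(M_PI * frac));
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)(unif_rand() * (i + 1));
      std::swap(order[i], order[std::min(j, i)]);
    }
    double ep_loss = 0; int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int B = stop - start;
      mat Xb(X.n_rows, B), Yb(Y.n_rows, B);
      for (int k = 0; k < B; ++k) {
        Xb.col(k) = X.col(order[start + k]);
        Yb.col(k) = Y.col(order[start + k]);
      }
      mat out = net_forward(net, Xb, fc);
      mat dOut;
      const double L = loss_and_grad(task, out, Yb, dOut);
      if (!std::isfinite(L)) {
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      }
      net_backward(net, fc, dOut, grads);
      std::vector<mat*> gWs = { &grads.Wc1, &grads.Wc2, &grads.Wc3,
                                &grads.Wc4, &grads.Wf1, &grads.Wf2 };
      std::vector<vec*> gbs = { &grads.bc1, &grads.bc2, &grads.bc3,
                                &grads.bc4, &grads.bf1, &grads.bf2 };
      adam_step(Ws, bs, gWs, gbs, st, lr, weight_decay);
      ep_loss += L; ++n_batches;
    }
    ep_loss /= n_batches;
    hist_train.push_back(ep_loss);
    double vloss = NA_REAL, vmetric = NA_REAL;
    if (has_val) {
      mat vout;
      vloss = 0; double acc = 0; double se = 0;
      const uword chunk = 512;
      long ncorrect = 0;
      for (uword s0 = 0; s0 < X_val.n_cols; s0 += chunk) {
        const uword s1 = std::min(s0 + chunk - 1, X_val.n_cols - 1);
        mat o = net_forward(net, X_val.cols(s0, s1), fc);
        mat dOut_unused;
        vloss += loss_and_grad(task, o, Y_val.cols(s0, s1), dOut_unused) *
          (s1 - s0 + 1);
        if (task == 0) {
          for (uword k = 0; k < o.n_cols; ++k) {
            uword pred = index_max(o.col(k));
            if ((int)pred == (int)Y_val(0, s0 + k)) ++ncorrect;
          }
        } else {
          se += accu(square(o - Y_val.cols(s0, s1)));
        }
      }
      vloss /= X_val.n_cols;
      if (task == 0) vmetric = (double)ncorrect / X_val.n_cols;
      else vmetric = std::sqrt(se / ((double)Y_val.n_rows * X_val.n_cols));
      (void)acc;
    }
    hist_val.push_back(vloss);
    hist_metric.push_back(vmetric);
    if (verbose) {
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << " lr " << lr << " loss " << ep_loss;
      if (has_val) Rcpp::Rcout << " val " << vloss << " metric " << vmetric;
      Rcpp::Rcout << std::endl;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = net_to_list(net),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq(1, epochs),
      Rcpp::Named("train_loss") = hist_train,
      Rcpp::Named("val_loss") = hist_val,
      Rcpp::Named("val_metric") = hist_metric));
}
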