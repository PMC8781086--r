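// Multitask quantile sequence-to-sequence LSTM.
//
// Encoder LSTM consumes (glucose, insulin, carbs) windows; a decoder LSTM,
// initialised with the final encoder state, consumes the exogenous
// (insulin, carbs) inputs of the 4-step (20 min) forecast horizon; three
// per-step linear heads emit the lower / median / upper quantile of the
// glucose trajectory.  Training minimises the uniformly weighted sum of the
// per-quantile pinball losses with Adam, gradient-norm clipping and early
// stopping on a validation split.  All randomness (weight init, batch
// shuffling) flows through one std::mt19937 seed so runs are reproducible
// across machines with a single thread.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// parameter order inside the flat list
enum { ENC_W = 0, ENC_B, DEC_W, DEC_B, HEAD_W, HEAD_B, N_PAR };

struct Cache {
  std::vector<mat> xh;           // [B x (D+H)] input||h_prev at each step
  std::vector<mat> ig, fg, gg, og, cs, tc;  // gates, cell state, tanh(cell)
};

inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// One LSTM pass over `inputs` (each B x D); h, c updated in place.
void lstm_forward(const mat& W, const rowvec& b,
                  const std::vector<mat>& inputs,
                  mat& h, mat& c, Cache* cache) {
  const uword H = h.n_cols;
  for (const mat& x : inputs) {
    mat xh = join_rows(x, h);
    mat z = xh * W;
    z.each_row() += b;
    mat ig = sigm(z.cols(0, H - 1));
    mat fg = sigm(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat og = sigm(z.cols(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    mat tc = tanh(c);
    h = og % tc;
    if (cache) {
      cache->xh.push_back(xh);
      cache->ig.push_back(ig); cache->fg.push_back(fg);
      cache->gg.push_back(gg); cache->og.push_back(og);
      cache->cs.push_back(c);  cache->tc.push_back(tc);
    }
  }
}

// Backward pass through time.  dh_ext[t] is the gradient injected at h_t by
// downstream consumers (heads); dh_carry/dc_carry arrive from states consumed
// after the final step (the decoder's initial state, for the encoder).
void lstm_backward(const mat& W, const Cache& cache, const mat& c0,
                   const std::vector<mat>* dh_ext,
                   mat dh_carry, mat dc_carry,
                   mat& dW, rowvec& db, mat& dh0, mat& dc0) {
  const uword H = dh_carry.n_cols;
  const int T = static_cast<int>(cache.xh.size());
  const uword D = cache.xh[0].n_cols - H;
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dh_carry;
    if (dh_ext) dh += (*dh_ext)[t];
    const mat& og = cache.og[t];
    const mat& tc = cache.tc[t];
    mat dc = dc_carry + dh % og % (1.0 - tc % tc);
    const mat& c_prev = (t == 0) ? c0 : cache.cs[t - 1];
    mat di = dc % cache.gg[t];
    mat df = dc % c_prev;
    mat dg = dc % cache.ig[t];
    mat do_ = dh % tc;
    mat dz = join_rows(join_rows(di % cache.ig[t] % (1.0 - cache.ig[t]),
                                 df % cache.fg[t] % (1.0 - cache.fg[t])),
                       join_rows(dg % (1.0 - cache.gg[t] % cache.gg[t]),
                                 do_ % og % (1.0 - og)));
    dW += cache.xh[t].t() * dz;
    db += sum(dz, 0);
    mat dxh = dz * W.t();
    dh_carry = dxh.cols(D, D + H - 1);
    dc_carry = dc % cache.fg[t];
  }
  dh0 = dh_carry;
  dc0 = dc_carry;
}

// Slice rows `idx` of cube X (n x T x D) into per-step [B x D] matrices.
std::vector<mat> gather_steps(const cube& X, const uvec& idx) {
  const uword T = X.n_cols, D = X.n_slices, B = idx.n_elem;
  std::vector<mat> out(T);
  for (uword t = 0; t < T; ++t) {
    mat xt(B, D);
    for (uword d = 0; d < D; ++d) {
      const mat& sl = X.slice(d);
      for (uword b = 0; b < B; ++b) xt(b, d) = sl(idx(b), t);
    }
    out[t] = xt;
  }
  return out;
}

std::vector<mat> params_from_list(const Rcpp::List& lst) {
  std::vector<mat> p(N_PAR);
  for (int k = 0; k < N_PAR; ++k) p[k] = Rcpp::as<mat>(lst[k]);
  return p;
}

Rcpp::List params_to_list(const std::vector<mat>& p) {
  return Rcpp::List::create(
      Rcpp::Named("enc_W") = p[ENC_W], Rcpp::Named("enc_b") = p[ENC_B],
      Rcpp::Named("dec_W") = p[DEC_W], Rcpp::Named("dec_b") = p[DEC_B],
      Rcpp::Named("head_W") = p[HEAD_W], Rcpp::Named("head_b") = p[HEAD_B]);
}

// Forward through encoder + decoder + heads for rows idx.
// preds[q] is B x Tdec.  Returns caches when `train` so backward can run.
struct ForwardOut {
  std::vector<mat> preds;  // 3 quantiles, each B x Tdec
  Cache enc_cache, dec_cache;
  mat enc_c0, dec_c0;      // initial cell states (zeros / encoder final)
  std::vector<mat> dec_h;  // decoder hidden per step (B x H)
};

ForwardOut forward_all(const std::vector<mat>& p,
                       const cube& Xenc, const cube& Xdec,
                       const uvec& idx, bool train) {
  const uword H = p[HEAD_W].n_rows, B = idx.n_elem, Tdec = Xdec.n_cols;
  ForwardOut out;
  std::vector<mat> enc_in = gather_steps(Xenc, idx);
  std::vector<mat> dec_in = gather_steps(Xdec, idx);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  out.enc_c0 = c;
  lstm_forward(p[ENC_W], p[ENC_B].row(0), enc_in, h, c,
               train ? &out.enc_cache : nullptr);
  out.dec_c0 = c;
  // decoder needs per-step h for the heads even in inference
  Cache* dcache = &out.dec_cache;
  lstm_forward(p[DEC_W], p[DEC_B].row(0), dec_in, h, c, dcache);
  out.dec_h.resize(Tdec);
  out.preds.assign(3, mat(B, Tdec));
  for (uword t = 0; t < Tdec; ++t) {
    mat hdec = out.dec_cache.og[t] % out.dec_cache.tc[t];
    out.dec_h[t] = hdec;
    mat y = hdec * p[HEAD_W];
    y.each_row() += p[HEAD_B].row(0);
    for (uword q = 0; q < 3; ++q) out.preds[q].col(t) = y.col(q);
  }
  return out;
}

// total pinball loss (mean over quantiles of per-quantile batch means)
double pinball_total(const std::vector<mat>& preds, const mat& Y,
                     const vec& taus) {
  double total = 0.0;
  for (uword q = 0; q < 3; ++q) {
    mat d = Y - preds[q];
    mat l = taus(q) * clamp(d, 0.0, datum::inf) +
            (1.0 - taus(q)) * clamp(-d, 0.0, datum::inf);
    total += accu(l) / l.n_elem;
  }
  return total / 3.0;
}

}  // namespace

// [[Rcpp::export(name = ".ms_init_params")]]
Rcpp::List ms_init_params(int enc_in, int dec_in, int hidden, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  auto glorot = [&](uword r, uword c) {
    double lim = std::sqrt(6.0 / (double)(r + c));
    std::uniform_real_distribution<double> u(-lim, lim);
    mat m(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) m(i, j) = u(rng);
    return m;
  };
  const uword H = hidden;
  std::vector<mat> p(N_PAR);
  p[ENC_W] = glorot(enc_in + H, 4 * H);
  p[ENC_B] = mat(1, 4 * H, fill::zeros);
  p[ENC_B].cols(H, 2 * H - 1).fill(1.0);  // forget-gate bias
  p[DEC_W] = glorot(dec_in + H, 4 * H);
  p[DEC_B] = mat(1, 4 * H, fill::zeros);
  p[DEC_B].cols(H, 2 * H - 1).fill(1.0);
  p[HEAD_W] = glorot(H, 3);
  p[HEAD_B] = mat(1, 3, fill::zeros);
  return params_to_list(p);
}

// [[Rcpp::export(name = ".ms_predict")]]
arma::cube ms_predict(Rcpp::List params, arma::cube Xenc, arma::cube Xdec) {
  std::vector<mat> p = params_from_list(params);
  const uword n = Xenc.n_rows, Tdec = Xdec.n_cols;
  uvec idx = regspace<uvec>(0, n - 1);
  ForwardOut fo = forward_all(p, Xenc, Xdec, idx, false);
  cube out(n, Tdec, 3);
  for (uword q = 0; q < 3; ++q) out.slice(q) = fo.preds[q];
  return out;
}

// [[Rcpp::export(name = ".ms_loss")]]
double ms_loss(Rcpp::List params, arma::cube Xenc, arma::cube Xdec,
               arma::mat Y, arma::vec taus) {
  std::vector<mat> p = params_from_list(params);
  uvec idx = regspace<uvec>(0, Xenc.n_rows - 1);
  ForwardOut fo = forward_all(p, Xenc, Xdec, idx, false);
  return pinball_total(fo.preds, Y, taus);
}

// [[Rcpp::export(name = ".ms_train")]]
Rcpp::List ms_train(Rcpp::List params,
                    arma::cube Xenc, arma::cube Xdec, arma::mat Y,
                    arma::uvec train_idx, arma::uvec val_idx,
                    arma::vec taus, double lr, int batch_size,
                    int max_epochs, int patience, double min_delta,
                    double clip_norm, int seed) {
  std::vector<mat> p = params_from_list(params);
  const uword H = p[HEAD_W].n_rows;
  const uword Denc = p[ENC_W].n_rows - H, Ddec = p[DEC_W].n_rows - H;
  const uword Tdec = Xdec.n_cols;

  std::vector<mat> m(N_PAR), v(N_PAR);
  for (int k = 0; k < N_PAR; ++k) {
    m[k] = mat(size(p[k]), fill::zeros);
    v[k] = mat(size(p[k]), fill::zeros);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long adam_t = 0;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<uword> order(train_idx.begin(), train_idx.end());

  mat Yval = Y.rows(val_idx);
  auto val_loss_fn = [&]() {
    ForwardOut fo = forward_all(p, Xenc, Xdec, val_idx, false);
    return pinball_total(fo.preds, Yval, taus);
  };

  std::vector<mat> best = p;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0;
  std::vector<double> tr_hist, val_hist;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batch = 0;
    for (size_t start = 0; start < order.size();
         start += static_cast<size_t>(batch_size)) {
      size_t stop = std::min(order.size(), start + (size_t)batch_size);
      uvec idx(stop - start);
      for (size_t i = start; i < stop; ++i) idx(i - start) = order[i];
      const uword B = idx.n_elem;

      ForwardOut fo = forward_all(p, Xenc, Xdec, idx, true);
      mat Yb = Y.rows(idx);
      double L = pinball_total(fo.preds, Yb, taus);
      if (!std::isfinite(L))
        Rcpp::stop("non-finite training loss at epoch %d", epoch);
      ep_loss += L;
      ++n_batch;

      // gradients ---------------------------------------------------------
      std::vector<mat> g(N_PAR);
      for (int k = 0; k < N_PAR; ++k) g[k] = mat(size(p[k]), fill::zeros);
      rowvec gb_enc(4 * H, fill::zeros), gb_dec(4 * H, fill::zeros);

      const double scale = 1.0 / (3.0 * (double)B * (double)Tdec);
      std::vector<mat> dh_ext(Tdec, mat(B, H, fill::zeros));
      rowvec ghead_b(3, fill::zeros);
      for (uword t = 0; t < Tdec; ++t) {
        mat dy(B, 3);
        for (uword q = 0; q < 3; ++q) {
          vec d = Yb.col(t) - fo.preds[q].col(t);
          vec gq(B);
          for (uword b = 0; b < B; ++b)
            gq(b) = (d(b) > 0 ? -taus(q) : (1.0 - taus(q))) * scale;
          dy.col(q) = gq;
        }
        g[HEAD_W] += fo.dec_h[t].t() * dy;
        ghead_b += sum(dy, 0);
        dh_ext[t] = dy * p[HEAD_W].t();
      }
      g[HEAD_B].row(0) = ghead_b;

      mat dh0, dc0;
      mat zero_carry(B, H, fill::zeros);
      lstm_backward(p[DEC_W], fo.dec_cache, fo.dec_c0, &dh_ext,
                    zero_carry, zero_carry, g[DEC_W], gb_dec, dh0, dc0);
      g[DEC_B].row(0) = gb_dec;
      mat dh0e, dc0e;
      lstm_backward(p[ENC_W], fo.enc_cache, fo.enc_c0, nullptr,
                    dh0, dc0, g[ENC_W], gb_enc, dh0e, dc0e);
      g[ENC_B].row(0) = gb_enc;

      // clip global norm, Adam step --------------------------------------
      double sq = 0.0;
      for (int k = 0; k < N_PAR; ++k) sq += accu(g[k] % g[k]);
      double norm = std::sqrt(sq);
      if (norm > clip_norm && norm > 0)
        for (int k = 0; k < N_PAR; ++k) g[k] *= clip_norm / norm;

      ++adam_t;
      double corr1 = 1.0 - std::pow(b1, (double)adam_t);
      double corr2 = 1.0 - std::pow(b2, (double)adam_t);
      for (int k = 0; k < N_PAR; ++k) {
        m[k] = b1 * m[k] + (1.0 - b1) * g[k];
        v[k] = b2 * v[k] + (1.0 - b2) * (g[k] % g[k]);
        p[k] -= lr * (m[k] / corr1) / (sqrt(v[k] / corr2) + eps);
      }
      (void)Denc; (void)Ddec;
    }

    double vl = val_loss_fn();
    tr_hist.push_back(ep_loss / std::max(1, n_batch));
    val_hist.push_back(vl);
    if (vl < best_val - min_delta) {
      best_val = vl;
      best = p;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  if (best_val == datum::inf) {  // max_epochs == 0
    best = p;
    best_val = val_loss_fn();
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(best),
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}
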