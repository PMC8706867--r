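// Single-precision GRU language model: teacher-forced training with full
// backpropagation through time, Adam with a stepped-decay learning rate,
// and batched ancestral sampling.  All randomness is driven by an explicit
// std::mt19937 seed so runs are reproducible.
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

namespace {

// Parameter container.  Gate column layout within the 3H matrices:
// [0,H) = reset, [H,2H) = update, [2H,3H) = candidate.
struct GruParams {
  fmat E;                     // V x D embedding
  std::vector<fmat> Wx;       // per layer: in x 3H
  std::vector<fmat> Wh;       // per layer: H  x 3H
  std::vector<frowvec> b;     // per layer: 3H
  fmat Wy;                    // H x V
  frowvec by;                 // V
  int L, H, V, D;
};

fmat as_fmat(SEXP m) {
  NumericMatrix nm(m);
  fmat out(nm.nrow(), nm.ncol());
  for (int j = 0; j < nm.ncol(); ++j)
    for (int i = 0; i < nm.nrow(); ++i) out(i, j) = (float)nm(i, j);
  return out;
}

NumericMatrix as_rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

GruParams unpack(const List& par) {
  GruParams p;
  p.E = as_fmat(par["E"]);
  List wx = par["Wx"], wh = par["Wh"], bb = par["b"];
  p.L = wx.size();
  for (int l = 0; l < p.L; ++l) {
    p.Wx.push_back(as_fmat(wx[l]));
    p.Wh.push_back(as_fmat(wh[l]));
    fmat bm = as_fmat(bb[l]);
    p.b.push_back(bm.row(0));
  }
  p.Wy = as_fmat(par["Wy"]);
  fmat bym = as_fmat(par["by"]);
  p.by = bym.row(0);
  p.H = p.Wh[0].n_rows;
  p.V = p.Wy.n_cols;
  p.D = p.E.n_cols;
  return p;
}

List pack(const GruParams& p) {
  List wx(p.L), wh(p.L), bb(p.L);
  for (int l = 0; l < p.L; ++l) {
    wx[l] = as_rmat(p.Wx[l]);
    wh[l] = as_rmat(p.Wh[l]);
    bb[l] = as_rmat(fmat(p.b[l]));
  }
  return List::create(_["E"] = as_rmat(p.E), _["Wx"] = wx, _["Wh"] = wh,
                      _["b"] = bb, _["Wy"] = as_rmat(p.Wy),
                      _["by"] = as_rmat(fmat(p.by)));
}

inline fmat sigmoidf(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

// One GRU layer forward step.  Caches R, Z, N and the candidate part of
// h_prev * Wh (needed for the reset-gate gradient).
struct StepCache { fmat R, Z, N, Ghn; };

fmat gru_step(const fmat& X, const fmat& Hp, const fmat& Wx, const fmat& Wh,
              const frowvec& b, StepCache& c) {
  const int H = Hp.n_cols;
  fmat A = X * Wx;
  A.each_row() += b;
  fmat Gh = Hp * Wh;
  c.R = sigmoidf(A.cols(0, H - 1) + Gh.cols(0, H - 1));
  c.Z = sigmoidf(A.cols(H, 2 * H - 1) + Gh.cols(H, 2 * H - 1));
  c.Ghn = Gh.cols(2 * H, 3 * H - 1);
  c.N = arma::tanh(A.cols(2 * H, 3 * H - 1) + c.R % c.Ghn);
  return (1.0f - c.Z) % c.N + c.Z % Hp;
}

// Softmax over rows, in place, with max subtraction.
void softmax_rows(fmat& x) {
  fvec mx = arma::max(x, 1);
  x.each_col() -= mx;
  x = arma::exp(x);
  fvec s = arma::sum(x, 1);
  x.each_col() /= s;
}

struct Grads {
  fmat E;
  std::vector<fmat> Wx, Wh;
  std::vector<frowvec> b;
  fmat Wy;
  frowvec by;
  explicit Grads(const GruParams& p) {
    E.zeros(p.E.n_rows, p.E.n_cols);
    for (int l = 0; l < p.L; ++l) {
      Wx.push_back(arma::zeros<fmat>(p.Wx[l].n_rows, p.Wx[l].n_cols));
      Wh.push_back(arma::zeros<fmat>(p.Wh[l].n_rows, p.Wh[l].n_cols));
      b.push_back(arma::zeros<frowvec>(p.b[l].n_elem));
    }
    Wy.zeros(p.Wy.n_rows, p.Wy.n_cols);
    by.zeros(p.by.n_elem);
  }
};

// Forward + backward over one padded batch.  tokens is (B x T) of 0-based
// indices; positions where target == pad are excluded from the loss.
// Returns mean NLL per non-pad target; fills grads.
double batch_grad(const GruParams& p, const arma::imat& tokens, int pad,
                  Grads& g) {
  const int B = tokens.n_rows, T = tokens.n_cols;
  const int steps = T - 1;  // inputs 0..T-2 predict targets 1..T-1
  const int H = p.H, L = p.L, V = p.V;

  std::vector<fmat> Emb(steps);
  std::vector<std::vector<fmat> > Hs(L, std::vector<fmat>(steps));
  std::vector<std::vector<StepCache> > C(L, std::vector<StepCache>(steps));
  std::vector<fmat> dLogits(steps);

  double loss = 0.0;
  long n_tok = 0;
  const fmat h0 = arma::zeros<fmat>(B, H);

  for (int t = 0; t < steps; ++t) {
    fmat X(B, p.D);
    for (int i = 0; i < B; ++i) X.row(i) = p.E.row(tokens(i, t));
    Emb[t] = X;
    for (int l = 0; l < L; ++l) {
      const fmat& Hp = (t == 0) ? h0 : Hs[l][t - 1];
      X = gru_step(X, Hp, p.Wx[l], p.Wh[l], p.b[l], C[l][t]);
      Hs[l][t] = X;
    }
    fmat logits = X * p.Wy;
    logits.each_row() += p.by;
    softmax_rows(logits);
    fmat dl = logits;  // becomes (softmax - onehot) for counted rows
    for (int i = 0; i < B; ++i) {
      int y = tokens(i, t + 1);
      if (y == pad) {
        dl.row(i).zeros();
      } else {
        loss -= std::log(std::max(logits(i, y), 1e-12f));
        dl(i, y) -= 1.0f;
        ++n_tok;
      }
    }
    dLogits[t] = dl;
  }
  if (n_tok == 0) return 0.0;
  const float inv_n = 1.0f / (float)n_tok;

  // Backward through time.
  std::vector<fmat> dHnext(L, arma::zeros<fmat>(B, H));
  for (int t = steps - 1; t >= 0; --t) {
    fmat dl = dLogits[t] * inv_n;
    g.Wy += Hs[L - 1][t].t() * dl;
    g.by += arma::sum(dl, 0);
    fmat dX_above = dl * p.Wy.t();  // gradient w.r.t. top hidden state
    for (int l = L - 1; l >= 0; --l) {
      fmat dH = dX_above + dHnext[l];
      const StepCache& c = C[l][t];
      const fmat& Hp = (t == 0) ? h0 : Hs[l][t - 1];
      const fmat& Xin = (l == 0) ? Emb[t] : Hs[l - 1][t];
      fmat dZpre = dH % (Hp - c.N) % c.Z % (1.0f - c.Z);
      fmat dNpre = (dH % (1.0f - c.Z)) % (1.0f - c.N % c.N);
      fmat dRpre = (dNpre % c.Ghn) % c.R % (1.0f - c.R);
      fmat dA(B, 3 * H), dGh(B, 3 * H);
      dA.cols(0, H - 1) = dRpre;
      dA.cols(H, 2 * H - 1) = dZpre;
      dA.cols(2 * H, 3 * H - 1) = dNpre;
      dGh.cols(0, H - 1) = dRpre;
      dGh.cols(H, 2 * H - 1) = dZpre;
      dGh.cols(2 * H, 3 * H - 1) = dNpre % c.R;
      g.Wx[l] += Xin.t() * dA;
      g.Wh[l] += Hp.t() * dGh;
      g.b[l] += arma::sum(dA, 0);
      dX_above = dA * p.Wx[l].t();
      dHnext[l] = dGh * p.Wh[l].t() + dH % c.Z;
    }
    for (int i = 0; i < B; ++i) g.E.row(tokens(i, t)) += dX_above.row(i);
  }
  return loss / (double)n_tok;
}

struct AdamState {
  Grads m, v;
  long t;
  AdamState(const GruParams& p) : m(p), v(p), t(0) {}
};

void adam_one(fmat& w, fmat& gm, fmat& gv, const fmat& g, float lr,
              float bc1, float bc2) {
  gm = 0.9f * gm + 0.1f * g;
  gv = 0.999f * gv + 0.001f * (g % g);
  w -= lr * (gm / bc1) / (arma::sqrt(gv / bc2) + 1e-8f);
}

void adam_row(frowvec& w, frowvec& gm, frowvec& gv, const frowvec& g,
              float lr, float bc1, float bc2) {
  gm = 0.9f * gm + 0.1f * g;
  gv = 0.999f * gv + 0.001f * (g % g);
  w -= lr * (gm / bc1) / (arma::sqrt(gv / bc2) + 1e-8f);
}

double grad_sqnorm(const Grads& g) {
  double s = arma::accu(arma::conv_to<arma::mat>::from(g.E % g.E));
  for (size_t l = 0; l < g.Wx.size(); ++l) {
    s += arma::accu(arma::conv_to<arma::mat>::from(g.Wx[l] % g.Wx[l]));
    s += arma::accu(arma::conv_to<arma::mat>::from(g.Wh[l] % g.Wh[l]));
    s += arma::dot(g.b[l], g.b[l]);
  }
  s += arma::accu(arma::conv_to<arma::mat>::from(g.Wy % g.Wy));
  s += arma::dot(g.by, g.by);
  return s;
}

void scale_grads(Grads& g, float f) {
  g.E *= f;
  for (size_t l = 0; l < g.Wx.size(); ++l) {
    g.Wx[l] *= f; g.Wh[l] *= f; g.b[l] *= f;
  }
  g.Wy *= f; g.by *= f;
}

}  // namespace

// Learning rate under the stepped exponential decay: multiply by
// (1 - decay_rate) once every decay_every steps.
// [[Rcpp::export(name = ".cpp_lr_at_step")]]
double cpp_lr_at_step(double step, double initial_lr, double decay_rate,
                      double decay_every) {
  return initial_lr * std::pow(1.0 - decay_rate,
                               std::floor(step / decay_every));
}

// Run `steps` optimisation steps.  sequences: list of 1-based integer
// vectors (BOS ... EOS).  Returns updated params, Adam state and the
// per-step loss / lr history.  step0 is the global step count already
// taken (the schedule and loss history continue from there).
// [[Rcpp::export(name = ".cpp_gru_train")]]
List cpp_gru_train(List params, Nullable<List> opt_state, List sequences,
                   int steps, int batch_size, double initial_lr,
                   double decay_rate, int decay_every, int pad_index_1b,
                   int step0, int seed, double clip_norm,
                   bool bucket_by_length) {
  GruParams p = unpack(params);
  AdamState adam(p);
  if (opt_state.isNotNull()) {
    List os(opt_state);
    GruParams m = unpack(os["m"]), v = unpack(os["v"]);
    adam.m.E = m.E; adam.v.E = v.E;
    for (int l = 0; l < p.L; ++l) {
      adam.m.Wx[l] = m.Wx[l]; adam.m.Wh[l] = m.Wh[l]; adam.m.b[l] = m.b[l];
      adam.v.Wx[l] = v.Wx[l]; adam.v.Wh[l] = v.Wh[l]; adam.v.b[l] = v.b[l];
    }
    adam.m.Wy = m.Wy; adam.m.by = m.by;
    adam.v.Wy = v.Wy; adam.v.by = v.by;
    adam.t = (long)as<double>(os["t"]);
  }

  const int n_seq = sequences.size();
  std::vector<std::vector<int> > seqs(n_seq);
  for (int i = 0; i < n_seq; ++i) {
    IntegerVector s = sequences[i];
    seqs[i].assign(s.begin(), s.end());
  }
  const int pad = pad_index_1b - 1;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n_seq - 1);

  // length-bucketed sampling: draw each batch as a random contiguous
  // window of the length-sorted corpus, so batch padding stays small
  std::vector<int> order(n_seq);
  for (int i = 0; i < n_seq; ++i) order[i] = i;
  if (bucket_by_length) {
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) {
                       return seqs[a].size() < seqs[b].size();
                     });
  }
  const int max_start = std::max(0, n_seq - batch_size);
  std::uniform_int_distribution<int> pick_start(0, max_start);

  NumericVector loss_hist(steps), lr_hist(steps);
  for (int s = 0; s < steps; ++s) {
    const int B = batch_size;  // sampling with replacement across steps
    std::vector<int> idx(B);
    int maxlen = 2;
    if (bucket_by_length) {
      const int start = pick_start(rng);
      for (int i = 0; i < B; ++i) {
        idx[i] = order[(start + i) % n_seq];
        maxlen = std::max(maxlen, (int)seqs[idx[i]].size());
      }
    } else {
      for (int i = 0; i < B; ++i) {
        idx[i] = pick(rng);
        maxlen = std::max(maxlen, (int)seqs[idx[i]].size());
      }
    }
    arma::imat tokens(B, maxlen);
    tokens.fill(pad);
    for (int i = 0; i < B; ++i)
      for (size_t t = 0; t < seqs[idx[i]].size(); ++t)
        tokens(i, t) = seqs[idx[i]][t] - 1;

    Grads g(p);
    double loss = batch_grad(p, tokens, pad, g);
    double nrm = std::sqrt(grad_sqnorm(g));
    if (clip_norm > 0 && nrm > clip_norm) scale_grads(g, (float)(clip_norm / nrm));

    double lr = cpp_lr_at_step(step0 + s, initial_lr, decay_rate, decay_every);
    adam.t += 1;
    float bc1 = 1.0f - std::pow(0.9f, (float)adam.t);
    float bc2 = 1.0f - std::pow(0.999f, (float)adam.t);
    adam_one(p.E, adam.m.E, adam.v.E, g.E, (float)lr, bc1, bc2);
    for (int l = 0; l < p.L; ++l) {
      adam_one(p.Wx[l], adam.m.Wx[l], adam.v.Wx[l], g.Wx[l], (float)lr, bc1, bc2);
      adam_one(p.Wh[l], adam.m.Wh[l], adam.v.Wh[l], g.Wh[l], (float)lr, bc1, bc2);
      adam_row(p.b[l], adam.m.b[l], adam.v.b[l], g.b[l], (float)lr, bc1, bc2);
    }
    adam_one(p.Wy, adam.m.Wy, adam.v.Wy, g.Wy, (float)lr, bc1, bc2);
    adam_row(p.by, adam.m.by, adam.v.by, g.by, (float)lr, bc1, bc2);

    loss_hist[s] = loss;
    lr_hist[s] = lr;
    if (s % 20 == 0) Rcpp::checkUserInterrupt();
  }

  GruParams pm, pv;
  List mpk, vpk;
  {
    // pack Adam moments through the same GruParams layout
    GruParams tmpm = p, tmpv = p;
    tmpm.E = adam.m.E; tmpv.E = adam.v.E;
    for (int l = 0; l < p.L; ++l) {
      tmpm.Wx[l] = adam.m.Wx[l]; tmpm.Wh[l] = adam.m.Wh[l]; tmpm.b[l] = adam.m.b[l];
      tmpv.Wx[l] = adam.v.Wx[l]; tmpv.Wh[l] = adam.v.Wh[l]; tmpv.b[l] = adam.v.b[l];
    }
    tmpm.Wy = adam.m.Wy; tmpm.by = adam.m.by;
    tmpv.Wy = adam.v.Wy; tmpv.by = adam.v.by;
    mpk = pack(tmpm); vpk = pack(tmpv);
  }
  return List::create(
      _["params"] = pack(p),
      _["opt"] = List::create(_["m"] = mpk, _["v"] = vpk,
                              _["t"] = (double)adam.t),
      _["loss"] = loss_hist, _["lr"] = lr_hist);
}

// Loss and analytic gradients for one batch (finite-difference checks).
// [[Rcpp::export(name = ".cpp_gru_grad")]]
List cpp_gru_grad(List params, List sequences, int pad_index_1b) {
  GruParams p = unpack(params);
  const int n_seq = sequences.size();
  const int pad = pad_index_1b - 1;
  int maxlen = 2;
  for (int i = 0; i < n_seq; ++i)
    maxlen = std::max(maxlen, (int)((IntegerVector)sequences[i]).size());
  arma::imat tokens(n_seq, maxlen);
  tokens.fill(pad);
  for (int i = 0; i < n_seq; ++i) {
    IntegerVector s = sequences[i];
    for (int t = 0; t < s.size(); ++t) tokens(i, t) = s[t] - 1;
  }
  Grads g(p);
  double loss = batch_grad(p, tokens, pad, g);
  GruParams gp = p;
  gp.E = g.E;
  for (int l = 0; l < p.L; ++l) {
    gp.Wx[l] = g.Wx[l]; gp.Wh[l] = g.Wh[l]; gp.b[l] = g.b[l];
  }
  gp.Wy = g.Wy; gp.by = g.by;
  return List::create(_["loss"] = loss, _["grads"] = pack(gp));
}

// Mean NLL of the model on a list of encoded sequences (no update).
// [[Rcpp::export(name = ".cpp_gru_nll")]]
double cpp_gru_nll(List params, List sequences, int pad_index_1b) {
  GruParams p = unpack(params);
  const int n_seq = sequences.size();
  const int pad = pad_index_1b - 1;
  int maxlen = 2;
  for (int i = 0; i < n_seq; ++i)
    maxlen = std::max(maxlen, (int)((IntegerVector)sequences[i]).size());
  arma::imat tokens(n_seq, maxlen);
  tokens.fill(pad);
  for (int i = 0; i < n_seq; ++i) {
    IntegerVector s = sequences[i];
    for (int t = 0; t < s.size(); ++t) tokens(i, t) = s[t] - 1;
  }
  const int B = n_seq, T = maxlen, steps = T - 1;
  fmat h0 = arma::zeros<fmat>(B, p.H);
  std::vector<fmat> H(p.L, h0);
  double loss = 0.0;
  long n_tok = 0;
  for (int t = 0; t < steps; ++t) {
    fmat X(B, p.D);
    for (int i = 0; i < B; ++i) X.row(i) = p.E.row(tokens(i, t));
    for (int l = 0; l < p.L; ++l) {
      StepCache c;
      H[l] = gru_step(X, H[l], p.Wx[l], p.Wh[l], p.b[l], c);
      X = H[l];
    }
    fmat logits = X * p.Wy;
    logits.each_row() += p.by;
    softmax_rows(logits);
    for (int i = 0; i < B; ++i) {
      int y = tokens(i, t + 1);
      if (y != pad) {
        loss -= std::log(std::max(logits(i, y), 1e-12f));
        ++n_tok;
      }
    }
  }
  return n_tok ? loss / (double)n_tok : NA_REAL;
}

// Ancestral sampling: n sequences from BOS, stopping at EOS or max_len
// emitted tokens.  Returns a list of 1-based token index vectors
// (specials stripped).
// [[Rcpp::export(name = ".cpp_gru_sample")]]
List cpp_gru_sample(List params, int n, int max_len, double temperature,
                    int bos_1b, int eos_1b, int seed) {
  GruParams p = unpack(params);
  const int bos = bos_1b - 1, eos = eos_1b - 1;
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<fmat> H(p.L, arma::zeros<fmat>(n, p.H));
  std::vector<int> cur(n, bos);
  std::vector<bool> alive(n, true);
  std::vector<std::vector<int> > out(n);
  const float invT = (float)(1.0 / temperature);

  for (int t = 0; t < max_len; ++t) {
    fmat X(n, p.D);
    for (int i = 0; i < n; ++i) X.row(i) = p.E.row(cur[i]);
    for (int l = 0; l < p.L; ++l) {
      StepCache c;
      H[l] = gru_step(X, H[l], p.Wx[l], p.Wh[l], p.b[l], c);
      X = H[l];
    }
    fmat logits = X * p.Wy;
    logits.each_row() += p.by;
    logits *= invT;
    softmax_rows(logits);
    bool any_alive = false;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      double u = unif(rng), acc = 0.0;
      int tok = p.V - 1;
      for (int v = 0; v < p.V; ++v) {
        acc += logits(i, v);
        if (u <= acc) { tok = v; break; }
      }
      if (tok == eos) {
        alive[i] = false;
      } else {
        out[i].push_back(tok + 1);
        cur[i] = tok;
        any_alive = true;
      }
    }
    if (!any_alive) break;
    if (t % 16 == 0) Rcpp::checkUserInterrupt();
  }
  List res(n);
  for (int i = 0; i < n; ++i) res[i] = IntegerVector(out[i].begin(), out[i].end());
  return res;
}

// Next-token probability rows for one encoded prefix (softmax check).
// [[Rcpp::export(name = ".cpp_gru_probs")]]
NumericMatrix cpp_gru_probs(List params, IntegerVector prefix_1b) {
  GruParams p = unpack(params);
  const int T = prefix_1b.size();
  std::vector<fmat> H(p.L, arma::zeros<fmat>(1, p.H));
  NumericMatrix out(T, p.V);
  for (int t = 0; t < T; ++t) {
    fmat X = p.E.row(prefix_1b[t] - 1);
    for (int l = 0; l < p.L; ++l) {
      StepCache c;
      H[l] = gru_step(X, H[l], p.Wx[l], p.Wh[l], p.b[l], c);
      X = H[l];
    }
    fmat logits = X * p.Wy;
    logits.each_row() += p.by;
    softmax_rows(logits);
    for (int v = 0; v < p.V; ++v) out(t, v) = logits(0, v);
  }
  return out;
}
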