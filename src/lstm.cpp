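// Compiled core of the many-to-one LSTM round regressor: batched forward,
// backpropagation through time and Adam updates. The R level owns parameter
// initialization and all user-facing semantics; this file is performance
// machinery. Parameter vector layout must match flatten_lstm() in R/lstm.R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

struct Layer {
  mat Wxi, Whi, Wxg, Whg, Wxf, Whf, Wxo, Who;
  rowvec bi, bg, bf, bo;
};

struct Params {
  mat Wfx;          // d_in x H
  rowvec bfx;       // H
  std::vector<Layer> layers;
  vec Why;          // H
  double by;
};

static Params unpack(const Rcpp::NumericVector& v, int d_in, int H, int L) {
  Params p;
  const double* ptr = v.begin();
  size_t pos = 0;
  auto take_mat = [&](int nr, int nc) {
    mat m(ptr + pos, nr, nc);  // column-major, copies
    pos += (size_t)nr * nc;
    return m;
  };
  auto take_row = [&](int n) {
    rowvec r(ptr + pos, n);
    pos += n;
    return r;
  };
  p.Wfx = take_mat(d_in, H);
  p.bfx = take_row(H);
  p.layers.resize(L);
  for (int l = 0; l < L; ++l) {
    Layer& ly = p.layers[l];
    ly.Wxi = take_mat(H, H); ly.Whi = take_mat(H, H); ly.bi = take_row(H);
    ly.Wxg = take_mat(H, H); ly.Whg = take_mat(H, H); ly.bg = take_row(H);
    ly.Wxf = take_mat(H, H); ly.Whf = take_mat(H, H); ly.bf = take_row(H);
    ly.Wxo = take_mat(H, H); ly.Who = take_mat(H, H); ly.bo = take_row(H);
  }
  p.Why = vec(ptr + pos, H); pos += H;
  p.by = v[pos++];
  if (pos != (size_t)v.size()) Rcpp::stop("parameter vector length mismatch");
  return p;
}

static Rcpp::NumericVector pack(const Params& p) {
  std::vector<double> out;
  auto push_mat = [&](const mat& m) { out.insert(out.end(), m.begin(), m.end()); };
  auto push_row = [&](const rowvec& r) { out.insert(out.end(), r.begin(), r.end()); };
  push_mat(p.Wfx); push_row(p.bfx);
  for (const Layer& ly : p.layers) {
    push_mat(ly.Wxi); push_mat(ly.Whi); push_row(ly.bi);
    push_mat(ly.Wxg); push_mat(ly.Whg); push_row(ly.bg);
    push_mat(ly.Wxf); push_mat(ly.Whf); push_row(ly.bf);
    push_mat(ly.Wxo); push_mat(ly.Who); push_row(ly.bo);
  }
  push_mat(p.Why);
  out.push_back(p.by);
  return Rcpp::NumericVector(out.begin(), out.end());
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Forward pass over one full sequence (no dropout): returns the estimate.
static double forward_one(const Params& p, const mat& F) {
  const int T = F.n_rows, L = p.layers.size(), H = p.Wfx.n_cols;
  std::vector<rowvec> h(L, rowvec(H, fill::zeros)), c(L, rowvec(H, fill::zeros));
  for (int t = 0; t < T; ++t) {
    rowvec inp = F.row(t) * p.Wfx + p.bfx;
    for (int l = 0; l < L; ++l) {
      const Layer& ly = p.layers[l];
      rowvec i = sigm(inp * ly.Wxi + h[l] * ly.Whi + ly.bi);
      rowvec g = tanh(inp * ly.Wxg + h[l] * ly.Whg + ly.bg);
      rowvec f = sigm(inp * ly.Wxf + h[l] * ly.Whf + ly.bf);
      rowvec o = sigm(inp * ly.Wxo + h[l] * ly.Who + ly.bo);
      c[l] = f % c[l] + i % g;
      h[l] = o % tanh(c[l]);
      inp = h[l];
    }
  }
  return dot(h[L - 1], p.Why) + p.by;
}

// [[Rcpp::export]]
double lstm_forward_cpp(Rcpp::NumericVector params, Rcpp::NumericMatrix X,
                        int d_in, int H, int L) {
  Params p = unpack(params, d_in, H, L);
  mat F(X.begin(), X.nrow(), X.ncol());
  if (F.n_rows < 1) Rcpp::stop("empty sequence");
  return forward_one(p, F);
}

static double pearson(const vec& a, const vec& b) {
  double sa = stddev(a), sb = stddev(b);
  if (sa == 0.0 || sb == 0.0 || a.n_elem < 2) return -datum::inf;
  return as_scalar(cor(a, b));
}

struct Adam {
  std::vector<mat> m, v;
  long t = 0;
};

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::NumericVector params0,
                          Rcpp::IntegerVector seq_lens, Rcpp::NumericMatrix Xall,
                          Rcpp::NumericVector y,
                          Rcpp::IntegerVector vseq_lens, Rcpp::NumericMatrix Xvall,
                          Rcpp::NumericVector vy,
                          int d_in, int H, int L,
                          int epochs, double lr, double dropout, double l2,
                          int batch_size, int seed) {
  Params p = unpack(params0, d_in, H, L);
  const int R = seq_lens.size(), RV = vseq_lens.size();
  mat X(Xall.begin(), Xall.nrow(), Xall.ncol());
  mat XV(Xvall.begin(), Xvall.nrow(), Xvall.ncol());
  std::vector<int> start(R), vstart(RV);
  for (int i = 0, s = 0; i < R; ++i) { start[i] = s; s += seq_lens[i]; }
  for (int i = 0, s = 0; i < RV; ++i) { vstart[i] = s; s += vseq_lens[i]; }

  std::mt19937 rng(seed);
  auto runif01 = [&]() { return rng() * (1.0 / 4294967296.0); };
  auto rint = [&](int n) { return (int)(rng() % (unsigned)n); };

  // Gradient container mirroring Params
  Params g = p;  // shapes
  auto zero_grad = [&](Params& q) {
    q.Wfx.zeros(); q.bfx.zeros();
    for (Layer& ly : q.layers) {
      ly.Wxi.zeros(); ly.Whi.zeros(); ly.bi.zeros();
      ly.Wxg.zeros(); ly.Whg.zeros(); ly.bg.zeros();
      ly.Wxf.zeros(); ly.Whf.zeros(); ly.bf.zeros();
      ly.Wxo.zeros(); ly.Who.zeros(); ly.bo.zeros();
    }
    q.Why.zeros(); q.by = 0.0;
  };

  // Adam state over the packed vector
  Rcpp::NumericVector flat0 = pack(p);
  vec am(flat0.size(), fill::zeros), av(flat0.size(), fill::zeros);
  long adam_t = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  double best_r = -datum::inf;
  int best_epoch = 0;
  Rcpp::NumericVector best_params = Rcpp::clone(flat0);
  std::vector<double> history;

  std::vector<int> order(R);
  for (int i = 0; i < R; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int b0 = 0; b0 < R; b0 += batch_size) {
      const int B = std::min(batch_size, R - b0);
      // augmentation: random start clip, then tile to the batch max length
      std::vector<int> off(B), tc(B);
      int Tmax = 0;
      for (int b = 0; b < B; ++b) {
        int Td = seq_lens[order[b0 + b]];
        int omax = std::min(Td - 1, Td / 2);
        off[b] = (omax > 0) ? rint(omax + 1) : 0;
        tc[b] = Td - off[b];
        Tmax = std::max(Tmax, tc[b]);
      }
      const int T = Tmax;
      // forward with caches
      std::vector<mat> Fv(T);           // B x d_in
      std::vector<mat> Xt(T);           // B x H (input transform output)
      std::vector<std::vector<mat>> gi(L), gg(L), gf(L), go(L), cs(L), hs(L),
          hdrop(L), mask(L);
      for (int l = 0; l < L; ++l) {
        gi[l].resize(T); gg[l].resize(T); gf[l].resize(T); go[l].resize(T);
        cs[l].resize(T); hs[l].resize(T); hdrop[l].resize(T); mask[l].resize(T);
      }
      for (int t = 0; t < T; ++t) {
        mat F(B, d_in);
        for (int b = 0; b < B; ++b) {
          int idx = order[b0 + b];
          int row = start[idx] + off[b] + (t % tc[b]);
          F.row(b) = X.row(row);
        }
        Fv[t] = F;
        Xt[t] = F * p.Wfx;
        Xt[t].each_row() += p.bfx;
      }
      for (int l = 0; l < L; ++l) {
        const Layer& ly = p.layers[l];
        mat h(B, H, fill::zeros), c(B, H, fill::zeros);
        for (int t = 0; t < T; ++t) {
          const mat& inp = (l == 0) ? Xt[t] : hdrop[l - 1][t];
          mat ai = inp * ly.Wxi + h * ly.Whi; ai.each_row() += ly.bi;
          mat ag = inp * ly.Wxg + h * ly.Whg; ag.each_row() += ly.bg;
          mat af = inp * ly.Wxf + h * ly.Whf; af.each_row() += ly.bf;
          mat ao = inp * ly.Wxo + h * ly.Who; ao.each_row() += ly.bo;
          mat i = sigm(ai), gm = tanh(ag), f = sigm(af), o = sigm(ao);
          c = f % c + i % gm;
          h = o % tanh(c);
          mat mk(B, H);
          if (dropout > 0.0) {
            for (uword q = 0; q < mk.n_elem; ++q)
              mk(q) = (runif01() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
          } else mk.ones();
          gi[l][t] = i; gg[l][t] = gm; gf[l][t] = f; go[l][t] = o;
          cs[l][t] = c; hs[l][t] = h; mask[l][t] = mk;
          hdrop[l][t] = h % mk;
        }
      }
      vec yhat(B);
      for (int b = 0; b < B; ++b)
        yhat(b) = dot(hdrop[L - 1][T - 1].row(b), p.Why) + p.by;

      // backward
      zero_grad(g);
      vec dy(B);
      for (int b = 0; b < B; ++b)
        dy(b) = 2.0 * (yhat(b) - y[order[b0 + b]]) / B;
      g.Why += hdrop[L - 1][T - 1].t() * dy;
      g.by += accu(dy);
      // dh_ext[t]: gradient wrt the (dropped) output of the current layer
      std::vector<mat> dh_ext(T, mat(B, H, fill::zeros));
      dh_ext[T - 1] = dy * p.Why.t();  // B x H
      for (int l = L - 1; l >= 0; --l) {
        const Layer& ly = p.layers[l];
        std::vector<mat> dinp(T);
        mat dh_rec(B, H, fill::zeros), dc_next(B, H, fill::zeros);
        for (int t = T - 1; t >= 0; --t) {
          mat dh = dh_ext[t] % mask[l][t] + dh_rec;
          mat tc_ = tanh(cs[l][t]);
          mat do_ = dh % tc_;
          mat dc = dc_next + dh % go[l][t] % (1.0 - tc_ % tc_);
          mat di = dc % gg[l][t];
          mat dg = dc % gi[l][t];
          mat cprev = (t == 0) ? mat(B, H, fill::zeros) : cs[l][t - 1];
          mat df = dc % cprev;
          dc_next = dc % gf[l][t];
          mat dai = di % gi[l][t] % (1.0 - gi[l][t]);
          mat dag = dg % (1.0 - gg[l][t] % gg[l][t]);
          mat daf = df % gf[l][t] % (1.0 - gf[l][t]);
          mat dao = do_ % go[l][t] % (1.0 - go[l][t]);
          const mat& inp = (l == 0) ? Xt[t] : hdrop[l - 1][t];
          mat hprev = (t == 0) ? mat(B, H, fill::zeros) : hs[l][t - 1];
          g.layers[l].Wxi += inp.t() * dai;  g.layers[l].Whi += hprev.t() * dai;
          g.layers[l].Wxg += inp.t() * dag;  g.layers[l].Whg += hprev.t() * dag;
          g.layers[l].Wxf += inp.t() * daf;  g.layers[l].Whf += hprev.t() * daf;
          g.layers[l].Wxo += inp.t() * dao;  g.layers[l].Who += hprev.t() * dao;
          g.layers[l].bi += sum(dai, 0); g.layers[l].bg += sum(dag, 0);
          g.layers[l].bf += sum(daf, 0); g.layers[l].bo += sum(dao, 0);
          dinp[t] = dai * ly.Wxi.t() + dag * ly.Wxg.t() +
                    daf * ly.Wxf.t() + dao * ly.Wxo.t();
          dh_rec = dai * ly.Whi.t() + dag * ly.Whg.t() +
                   daf * ly.Whf.t() + dao * ly.Who.t();
        }
        dh_ext = dinp;  // feeds the layer below (through its dropout mask)
      }
      for (int t = 0; t < T; ++t) {
        g.Wfx += Fv[t].t() * dh_ext[t];
        g.bfx += sum(dh_ext[t], 0);
      }
      // L2 penalty on weight matrices (not biases)
      g.Wfx += 2.0 * l2 * p.Wfx;
      for (int l = 0; l < L; ++l) {
        g.layers[l].Wxi += 2.0 * l2 * p.layers[l].Wxi;
        g.layers[l].Whi += 2.0 * l2 * p.layers[l].Whi;
        g.layers[l].Wxg += 2.0 * l2 * p.layers[l].Wxg;
        g.layers[l].Whg += 2.0 * l2 * p.layers[l].Whg;
        g.layers[l].Wxf += 2.0 * l2 * p.layers[l].Wxf;
        g.layers[l].Whf += 2.0 * l2 * p.layers[l].Whf;
        g.layers[l].Wxo += 2.0 * l2 * p.layers[l].Wxo;
        g.layers[l].Who += 2.0 * l2 * p.layers[l].Who;
      }
      g.Why += 2.0 * l2 * p.Why;

      // Adam over the packed vectors
      Rcpp::NumericVector pf = pack(p), gf_ = pack(g);
      ++adam_t;
      double c1 = 1.0 - std::pow(b1, (double)adam_t);
      double c2 = 1.0 - std::pow(b2, (double)adam_t);
      for (int q = 0; q < pf.size(); ++q) {
        am(q) = b1 * am(q) + (1.0 - b1) * gf_[q];
        av(q) = b2 * av(q) + (1.0 - b2) * gf_[q] * gf_[q];
        pf[q] -= lr * (am(q) / c1) / (std::sqrt(av(q) / c2) + eps);
      }
      p = unpack(pf, d_in, H, L);
    }

    // epoch-end validation: round-level Pearson r, best checkpoint kept
    vec vp(RV);
    for (int i = 0; i < RV; ++i)
      vp(i) = forward_one(p, XV.rows(vstart[i], vstart[i] + vseq_lens[i] - 1));
    double r = pearson(vp, vec(vy.begin(), RV));
    history.push_back(std::isfinite(r) ? r : NA_REAL);
    if (std::isfinite(r) && r > best_r) {
      best_r = r;
      best_epoch = ep + 1;
      best_params = pack(p);
    }
  }

  bool have_best = std::isfinite(best_r);
  return Rcpp::List::create(
      Rcpp::Named("params") = have_best ? best_params : pack(p),
      Rcpp::Named("best_epoch") = have_best ? best_epoch : epochs,
      Rcpp::Named("best_val_r") = have_best ? best_r : NA_REAL,
      Rcpp::Named("history") = Rcpp::NumericVector(history.begin(), history.end()));
}
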