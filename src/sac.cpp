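// Self-attention + convolution classifier: forward pass, backpropagation and
// Adam training. Single-threaded; dropout, shuffling and any other randomness
// use R's RNG so training is reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct SacP {
  arma::mat wq1, wk1, wv1, wq2, wk2, wv2;
  std::vector<arma::mat> cW;
  std::vector<arma::vec> cb;
  std::vector<int> win;
  arma::mat fcw;
  arma::vec fcb;
};

SacP load_params(const List &p) {
  SacP s;
  s.wq1 = as<arma::mat>(p["wq1"]); s.wk1 = as<arma::mat>(p["wk1"]);
  s.wv1 = as<arma::mat>(p["wv1"]); s.wq2 = as<arma::mat>(p["wq2"]);
  s.wk2 = as<arma::mat>(p["wk2"]); s.wv2 = as<arma::mat>(p["wv2"]);
  List conv = p["conv"];
  for (int w = 0; w < conv.size(); ++w) {
    List cw = conv[w];
    s.cW.push_back(as<arma::mat>(cw["W"]));
    s.cb.push_back(as<arma::vec>(cw["b"]));
    s.win.push_back(as<int>(cw["h"]));
  }
  s.fcw = as<arma::mat>(p["fc_w"]);
  s.fcb = as<arma::vec>(p["fc_b"]);
  return s;
}

List dump_params(const SacP &s) {
  List conv(s.cW.size());
  for (size_t w = 0; w < s.cW.size(); ++w) {
    conv[w] = List::create(
        _["W"] = s.cW[w],
        _["b"] = NumericVector(s.cb[w].begin(), s.cb[w].end()),
        _["h"] = s.win[w]);
  }
  return List::create(_["wq1"] = s.wq1, _["wk1"] = s.wk1, _["wv1"] = s.wv1,
                      _["wq2"] = s.wq2, _["wk2"] = s.wk2, _["wv2"] = s.wv2,
                      _["conv"] = conv, _["fc_w"] = s.fcw,
                      _["fc_b"] = NumericVector(s.fcb.begin(), s.fcb.end()));
}

SacP zeros_like(const SacP &s) {
  SacP g;
  g.wq1 = arma::zeros(arma::size(s.wq1)); g.wk1 = arma::zeros(arma::size(s.wk1));
  g.wv1 = arma::zeros(arma::size(s.wv1)); g.wq2 = arma::zeros(arma::size(s.wq2));
  g.wk2 = arma::zeros(arma::size(s.wk2)); g.wv2 = arma::zeros(arma::size(s.wv2));
  for (size_t w = 0; w < s.cW.size(); ++w) {
    g.cW.push_back(arma::zeros(arma::size(s.cW[w])));
    g.cb.push_back(arma::zeros(s.cb[w].n_elem));
    g.win.push_back(s.win[w]);
  }
  g.fcw = arma::zeros(arma::size(s.fcw));
  g.fcb = arma::zeros(s.fcb.n_elem);
  return g;
}

void zero_grads(SacP &g) {
  g.wq1.zeros(); g.wk1.zeros(); g.wv1.zeros();
  g.wq2.zeros(); g.wk2.zeros(); g.wv2.zeros();
  for (size_t w = 0; w < g.cW.size(); ++w) { g.cW[w].zeros(); g.cb[w].zeros(); }
  g.fcw.zeros(); g.fcb.zeros();
}

arma::mat col_softmax(const arma::mat &S) {
  arma::mat A = S;
  A.each_row() -= arma::max(S, 0);
  A = arma::exp(A);
  arma::rowvec cs = arma::sum(A, 0);
  A.each_row() /= cs;
  return A;
}

struct Cache {
  arma::mat X, Q1, K1, V1, A1, H1, Q2, K2, V2, A2, H2;
  std::vector<arma::mat> Xw, C; // per window: flattened windows, pre-relu maps
  std::vector<arma::uvec> argmax;
  arma::vec Z, Zd, mask, probs;
};

void forward_sample(const arma::mat &X, const SacP &P, Cache &c,
                    double dropout, bool training) {
  double sc = 1.0 / std::sqrt((double)P.wq1.n_rows);
  c.X = X;
  c.Q1 = P.wq1 * X; c.K1 = P.wk1 * X; c.V1 = P.wv1 * X;
  c.A1 = col_softmax(c.K1.t() * c.Q1 * sc);
  c.H1 = c.V1 * c.A1;
  c.Q2 = P.wq2 * c.H1; c.K2 = P.wk2 * c.H1; c.V2 = P.wv2 * c.H1;
  c.A2 = col_softmax(c.K2.t() * c.Q2 * sc);
  c.H2 = c.V2 * c.A2;

  int m = X.n_cols, k = X.n_rows;
  int n_total = 0;
  for (size_t w = 0; w < P.cW.size(); ++w) n_total += P.cW[w].n_rows;
  c.Z.set_size(n_total);
  c.Xw.assign(P.cW.size(), arma::mat());
  c.C.assign(P.cW.size(), arma::mat());
  c.argmax.assign(P.cW.size(), arma::uvec());
  int off = 0;
  for (size_t w = 0; w < P.cW.size(); ++w) {
    int h = P.win[w], npos = m - h + 1;
    arma::mat Xw(h * k, npos);
    for (int p = 0; p < npos; ++p) {
      Xw.col(p) = arma::vectorise(c.H2.cols(p, p + h - 1));
    }
    arma::mat C = P.cW[w] * Xw;
    C.each_col() += P.cb[w];
    arma::mat Cr = arma::clamp(C, 0.0, arma::datum::inf);
    arma::uvec am(Cr.n_rows);
    for (arma::uword f = 0; f < Cr.n_rows; ++f) {
      am[f] = Cr.row(f).index_max();
      c.Z[off + f] = Cr(f, am[f]);
    }
    c.Xw[w] = std::move(Xw);
    c.C[w] = std::move(C);
    c.argmax[w] = std::move(am);
    off += Cr.n_rows;
  }
  if (training && dropout > 0) {
    double keep = 1.0 - dropout;
    c.mask.set_size(n_total);
    for (int i = 0; i < n_total; ++i) {
      c.mask[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    }
    c.Zd = c.Z % c.mask;
  } else {
    c.mask.reset();
    c.Zd = c.Z;
  }
  arma::vec s = P.fcw * c.Zd + P.fcb;
  s -= s.max();
  arma::vec e = arma::exp(s);
  c.probs = e / arma::accu(e);
}

// backward through one attention layer; accumulates weight grads, returns
// gradient w.r.t. the layer input.
arma::mat attn_backward(const arma::mat &Xin, const arma::mat &Q,
                        const arma::mat &K, const arma::mat &V,
                        const arma::mat &A, const arma::mat &dH,
                        const arma::mat &wq, const arma::mat &wk,
                        const arma::mat &wv, arma::mat &gwq, arma::mat &gwk,
                        arma::mat &gwv) {
  double sc = 1.0 / std::sqrt((double)Q.n_rows);
  arma::mat dV = dH * A.t();
  arma::mat dA = V.t() * dH;
  arma::mat dS(arma::size(A));
  for (arma::uword j = 0; j < A.n_cols; ++j) {
    arma::vec aj = A.col(j), dj = dA.col(j);
    dS.col(j) = aj % (dj - arma::dot(aj, dj));
  }
  arma::mat dK = Q * dS.t() * sc;
  arma::mat dQ = K * dS * sc;
  gwq += dQ * Xin.t();
  gwk += dK * Xin.t();
  gwv += dV * Xin.t();
  return wq.t() * dQ + wk.t() * dK + wv.t() * dV;
}

// backward for one sample; returns gradient w.r.t. the input matrix X
arma::mat backward_sample(const Cache &c, const SacP &P, int y, double scale,
                          SacP &G) {
  arma::vec ds = c.probs;
  ds[y] -= 1.0;
  ds *= scale;
  G.fcw += ds * c.Zd.t();
  G.fcb += ds;
  arma::vec dZ = P.fcw.t() * ds;
  if (c.mask.n_elem) dZ %= c.mask;

  arma::mat dH2(arma::size(c.H2), arma::fill::zeros);
  int off = 0, k = c.X.n_rows;
  for (size_t w = 0; w < P.cW.size(); ++w) {
    int h = P.win[w];
    for (arma::uword f = 0; f < P.cW[w].n_rows; ++f) {
      arma::uword pm = c.argmax[w][f];
      if (c.C[w](f, pm) > 0) {
        double d = dZ[off + f];
        if (d != 0) {
          G.cW[w].row(f) += d * c.Xw[w].col(pm).t();
          G.cb[w][f] += d;
          arma::vec dxw = d * P.cW[w].row(f).t();
          dH2.cols(pm, pm + h - 1) +=
              arma::reshape(dxw, k, h);
        }
      }
    }
    off += P.cW[w].n_rows;
  }
  arma::mat dH1 = attn_backward(c.H1, c.Q2, c.K2, c.V2, c.A2, dH2,
                                P.wq2, P.wk2, P.wv2, G.wq2, G.wk2, G.wv2);
  return attn_backward(c.X, c.Q1, c.K1, c.V1, c.A1, dH1,
                       P.wq1, P.wk1, P.wv1, G.wq1, G.wk1, G.wv1);
}

struct Adam {
  arma::mat m, v;
  void init(arma::uword r, arma::uword c) {
    m.zeros(r, c);
    v.zeros(r, c);
  }
  void step(arma::mat &w, const arma::mat &g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    w -= lr * (m / (1 - std::pow(b1, t))) /
         (arma::sqrt(v / (1 - std::pow(b2, t))) + eps);
  }
};

void shuffle_r(arma::uvec &v) {
  for (arma::uword i = v.n_elem; i > 1; --i) {
    arma::uword j = (arma::uword)(unif_rand() * i);
    if (j >= i) j = i - 1;
    std::swap(v[i - 1], v[j]);
  }
}

double clamp01(double p) {
  const double eps = 1e-7;
  return std::min(std::max(p, eps), 1.0 - eps);
}

arma::mat sample_slice(const arma::cube &E, const arma::umat &index,
                       const arma::mat &table, bool use_table, arma::uword s) {
  if (!use_table) return E.slice(s);
  arma::mat X(table.n_cols, index.n_rows);
  for (arma::uword j = 0; j < index.n_rows; ++j) {
    X.col(j) = table.row(index(j, s) - 1).t();
  }
  return X;
}

double dataset_loss(const arma::cube &E, const IntegerVector &y,
                    const arma::umat &index, const arma::mat &table,
                    bool use_table, const SacP &P) {
  arma::uword n = use_table ? index.n_cols : E.n_slices;
  Cache c;
  double loss = 0;
  for (arma::uword s = 0; s < n; ++s) {
    forward_sample(sample_slice(E, index, table, use_table, s), P, c, 0, false);
    loss += -std::log(clamp01(c.probs[y[s]]));
  }
  return loss / (double)n;
}

} // namespace

// [[Rcpp::export]]
List sac_forward_cpp(arma::cube E, List params) {
  SacP P = load_params(params);
  arma::uword n = E.n_slices;
  arma::mat probs(n, 2);
  arma::mat meanA(E.n_cols, E.n_cols, arma::fill::zeros);
  Cache c;
  for (arma::uword s = 0; s < n; ++s) {
    forward_sample(E.slice(s), P, c, 0, false);
    probs.row(s) = c.probs.t();
    meanA += c.A1;
  }
  if (n > 0) meanA /= (double)n;
  return List::create(_["probs"] = probs, _["mean_attention1"] = meanA);
}

// mean loss and analytic gradients over a dataset (no dropout); used by the
// numeric gradient checks and by the training loop's test-loss tracking.
// [[Rcpp::export]]
List sac_loss_grad_cpp(arma::cube E, IntegerVector y, List params) {
  SacP P = load_params(params);
  SacP G = zeros_like(P);
  arma::uword n = E.n_slices;
  double scale = 1.0 / (double)n;
  double loss = 0;
  Cache c;
  for (arma::uword s = 0; s < n; ++s) {
    forward_sample(E.slice(s), P, c, 0, false);
    loss += -std::log(clamp01(c.probs[y[s]])) * scale;
    backward_sample(c, P, y[s], scale, G);
  }
  return List::create(_["loss"] = loss, _["grads"] = dump_params(G));
}

// [[Rcpp::export]]
List sac_train_cpp(arma::cube E, IntegerVector y, List params, int epochs,
                   int batch_size, double lr, double dropout, arma::cube E_test,
                   IntegerVector y_test, bool use_table, arma::umat index,
                   arma::umat index_test, arma::mat table) {
  SacP P = load_params(params);
  SacP G = zeros_like(P);
  arma::uword n = use_table ? index.n_cols : E.n_slices;

  Adam a_q1, a_k1, a_v1, a_q2, a_k2, a_v2, a_fw, a_fb, a_tab;
  a_q1.init(P.wq1.n_rows, P.wq1.n_cols); a_k1.init(P.wk1.n_rows, P.wk1.n_cols);
  a_v1.init(P.wv1.n_rows, P.wv1.n_cols); a_q2.init(P.wq2.n_rows, P.wq2.n_cols);
  a_k2.init(P.wk2.n_rows, P.wk2.n_cols); a_v2.init(P.wv2.n_rows, P.wv2.n_cols);
  a_fw.init(P.fcw.n_rows, P.fcw.n_cols); a_fb.init(P.fcb.n_elem, 1);
  std::vector<Adam> a_cW(P.cW.size()), a_cb(P.cW.size());
  for (size_t w = 0; w < P.cW.size(); ++w) {
    a_cW[w].init(P.cW[w].n_rows, P.cW[w].n_cols);
    a_cb[w].init(P.cb[w].n_elem, 1);
  }
  arma::mat gtable;
  if (use_table) {
    a_tab.init(table.n_rows, table.n_cols);
    gtable.zeros(table.n_rows, table.n_cols);
  }

  arma::uvec order = arma::regspace<arma::uvec>(0, n - 1);
  arma::vec train_hist(epochs), test_hist(epochs, arma::fill::zeros);
  bool has_test = (use_table ? index_test.n_cols : E_test.n_slices) > 0;
  double t_adam = 0;
  Cache c;

  for (int ep = 0; ep < epochs; ++ep) {
    shuffle_r(order);
    double ep_loss = 0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword stop = std::min(n, start + (arma::uword)batch_size);
      double scale = 1.0 / (double)(stop - start);
      zero_grads(G);
      if (use_table) gtable.zeros();
      for (arma::uword ii = start; ii < stop; ++ii) {
        arma::uword s = order[ii];
        forward_sample(sample_slice(E, index, table, use_table, s), P, c,
                       dropout, true);
        ep_loss += -std::log(clamp01(c.probs[y[s]]));
        arma::mat dX = backward_sample(c, P, y[s], scale, G);
        if (use_table) {
          for (arma::uword j = 0; j < index.n_rows; ++j) {
            gtable.row(index(j, s) - 1) += dX.col(j).t();
          }
        }
      }
      t_adam += 1;
      a_q1.step(P.wq1, G.wq1, lr, t_adam); a_k1.step(P.wk1, G.wk1, lr, t_adam);
      a_v1.step(P.wv1, G.wv1, lr, t_adam); a_q2.step(P.wq2, G.wq2, lr, t_adam);
      a_k2.step(P.wk2, G.wk2, lr, t_adam); a_v2.step(P.wv2, G.wv2, lr, t_adam);
      for (size_t w = 0; w < P.cW.size(); ++w) {
        a_cW[w].step(P.cW[w], G.cW[w], lr, t_adam);
        arma::mat b = P.cb[w], gb = G.cb[w];
        a_cb[w].step(b, gb, lr, t_adam);
        P.cb[w] = b.col(0);
      }
      a_fw.step(P.fcw, G.fcw, lr, t_adam);
      arma::mat fb = P.fcb, gfb = G.fcb;
      a_fb.step(fb, gfb, lr, t_adam);
      P.fcb = fb.col(0);
      if (use_table) a_tab.step(table, gtable, lr, t_adam);
    }
    train_hist[ep] = ep_loss / (double)n;
    if (has_test) {
      test_hist[ep] = dataset_loss(E_test, y_test, index_test, table,
                                   use_table, P);
    }
  }
  return List::create(_["params"] = dump_params(P),
                      _["train_loss"] = train_hist,
                      _["test_loss"] = test_hist,
                      _["table"] = table);
}
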