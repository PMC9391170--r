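// Margin-ranking trainer for translational knowledge-graph embeddings
// (TransE / TransH / TransR). Single-threaded; all randomness comes from R's
// RNG so runs are reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Fisher-Yates shuffle driven by R's RNG
void shuffle_r(arma::uvec &v) {
  for (arma::uword i = v.n_elem; i > 1; --i) {
    arma::uword j = (arma::uword)(unif_rand() * i);
    if (j >= i) j = i - 1;
    std::swap(v[i - 1], v[j]);
  }
}

int draw_other(const IntegerVector &pool, int avoid) {
  if (pool.size() == 1) return pool[0];
  for (;;) {
    int j = (int)(unif_rand() * pool.size());
    if (j >= pool.size()) j = pool.size() - 1;
    if (pool[j] != avoid) return pool[j];
  }
}

struct Adam {
  arma::mat m, v;
  explicit Adam(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                                v(r, c, arma::fill::zeros) {}
  void step(arma::mat &w, const arma::mat &g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

} // namespace

// score of one triple and, if grads given, accumulate d(score)/d(params)
// scaled by `sgn` into the gradient tables.
static double trans_score_grad(const arma::mat &ent, const arma::mat &rel,
                               const arma::mat &normals, const arma::cube &proj,
                               int model, int norm_order,
                               int h, int r, int t, double sgn,
                               arma::mat *gent, arma::mat *grel,
                               arma::mat *gnorm, arma::cube *gproj) {
  arma::rowvec eh = ent.row(h), et = ent.row(t), lr = rel.row(r);
  arma::rowvec ph = eh, pt = et;
  if (model == 2) { // TransH
    arma::rowvec w = normals.row(r);
    ph = eh - arma::dot(w, eh) * w;
    pt = et - arma::dot(w, et) * w;
  } else if (model == 3) { // TransR
    const arma::mat &M = proj.slice(r);
    ph = eh * M.t();
    pt = et * M.t();
  }
  arma::rowvec a = ph + lr - pt;
  double s = (norm_order == 1) ? arma::accu(arma::abs(a))
                               : std::sqrt(arma::accu(a % a));
  if (gent == nullptr) return s;
  arma::rowvec g; // d s / d a
  if (norm_order == 1) {
    g = arma::sign(a);
  } else {
    g = a / std::max(s, 1e-12);
  }
  g *= sgn;
  grel->row(r) += g;
  if (model == 1) {
    gent->row(h) += g;
    gent->row(t) -= g;
  } else if (model == 2) {
    arma::rowvec w = normals.row(r);
    double wg = arma::dot(w, g);
    gent->row(h) += g - wg * w;
    gent->row(t) -= g - wg * w;
    // a depends on w through -(w.h)w + (w.t)w
    gnorm->row(r) += -(wg * eh + arma::dot(w, eh) * g)
                     + (wg * et + arma::dot(w, et) * g);
  } else {
    const arma::mat &M = proj.slice(r);
    gent->row(h) += g * M;
    gent->row(t) -= g * M;
    gproj->slice(r) += g.t() * (eh - et);
  }
  return s;
}

// [[Rcpp::export]]
List trans_train_cpp(IntegerVector head, IntegerVector rel, IntegerVector tail,
                     arma::mat ent, arma::mat relmat, arma::mat normals,
                     arma::cube proj, int model, int norm_order,
                     double margin, double lr, int epochs, int batch_size,
                     int neg_ratio, IntegerVector head_cand,
                     IntegerVector tail_cand) {
  const arma::uword n = head.size();
  arma::uvec order = arma::regspace<arma::uvec>(0, n - 1);
  bool has_h = model == 2, has_r = model == 3;

  Adam a_ent(ent.n_rows, ent.n_cols), a_rel(relmat.n_rows, relmat.n_cols);
  Adam a_norm(has_h ? normals.n_rows : 1, has_h ? normals.n_cols : 1);
  std::vector<Adam> a_proj;
  if (has_r) {
    for (arma::uword r = 0; r < proj.n_slices; ++r)
      a_proj.emplace_back(proj.n_rows, proj.n_cols);
  }
  arma::mat gent(ent.n_rows, ent.n_cols), grel(relmat.n_rows, relmat.n_cols);
  arma::mat gnorm(has_h ? normals.n_rows : 1, has_h ? normals.n_cols : 1);
  arma::cube gproj(has_r ? proj.n_rows : 1, has_r ? proj.n_cols : 1,
                   has_r ? proj.n_slices : 1);

  arma::vec loss_hist(epochs, arma::fill::zeros);
  double t_adam = 0;
  bool head_ok = head_cand.size() > 1, tail_ok = tail_cand.size() > 1;

  for (int ep = 0; ep < epochs; ++ep) {
    shuffle_r(order);
    double ep_loss = 0;
    arma::uword n_pairs_total = 0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword stop = std::min(n, start + batch_size);
      gent.zeros(); grel.zeros(); gnorm.zeros(); gproj.zeros();
      arma::uword n_pairs = (stop - start) * neg_ratio;
      double inv = 1.0 / (double)n_pairs;
      for (arma::uword ii = start; ii < stop; ++ii) {
        int i = order[ii];
        int h = head[i], r = rel[i], t = tail[i];
        for (int k = 0; k < neg_ratio; ++k) {
          int hn = h, tn = t;
          bool corrupt_head = head_ok && (!tail_ok || unif_rand() < 0.5);
          if (corrupt_head) hn = draw_other(head_cand, h);
          else tn = draw_other(tail_cand, t);
          double s_pos = trans_score_grad(ent, relmat, normals, proj, model,
                                          norm_order, h, r, t, 0, nullptr,
                                          nullptr, nullptr, nullptr);
          double s_neg = trans_score_grad(ent, relmat, normals, proj, model,
                                          norm_order, hn, r, tn, 0, nullptr,
                                          nullptr, nullptr, nullptr);
          double hinge = s_pos + margin - s_neg;
          if (hinge > 0) {
            ep_loss += hinge;
            trans_score_grad(ent, relmat, normals, proj, model, norm_order,
                             h, r, t, inv, &gent, &grel, &gnorm, &gproj);
            trans_score_grad(ent, relmat, normals, proj, model, norm_order,
                             hn, r, tn, -inv, &gent, &grel, &gnorm, &gproj);
          }
        }
      }
      n_pairs_total += n_pairs;
      t_adam += 1;
      a_ent.step(ent, gent, lr, t_adam);
      a_rel.step(relmat, grel, lr, t_adam);
      if (has_h) a_norm.step(normals, gnorm, lr, t_adam);
      if (has_r) {
        for (arma::uword r = 0; r < proj.n_slices; ++r) {
          arma::mat sl = proj.slice(r);
          a_proj[r].step(sl, gproj.slice(r), lr, t_adam);
          proj.slice(r) = sl;
        }
      }
      // constraints: entity norms <= 1; unit hyperplane normals
      for (arma::uword e = 0; e < ent.n_rows; ++e) {
        double nr = arma::norm(ent.row(e), 2);
        if (nr > 1.0) ent.row(e) /= nr;
      }
      if (has_h) {
        for (arma::uword r = 0; r < normals.n_rows; ++r) {
          double nr = arma::norm(normals.row(r), 2);
          if (nr > 1e-12) normals.row(r) /= nr;
        }
      }
    }
    loss_hist[ep] = ep_loss / (double)n_pairs_total;
  }
  return List::create(_["ent"] = ent, _["rel"] = relmat,
                      _["normals"] = normals, _["proj"] = proj,
                      _["loss"] = loss_hist);
}
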