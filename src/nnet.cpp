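// 1D-CNN adherence classifier with an optional domain-adversarial head.
//
// Architecture: conv(kernel m) -> relu -> maxpool(p) -> conv(m) -> relu ->
// maxpool(p) -> flatten -> [label head: dense -> relu -> 2-unit softmax]
//                          [domain head, via gradient reversal:
//                           dense -> relu -> 2-unit softmax].
// The layers before the flatten are the shared feature extractor. During
// backpropagation the domain head's gradient is multiplied by -lambda at
// the flatten boundary (gradient reversal), so the extractor is pushed
// toward features on which source and target windows are indistinguishable
// while the domain head itself is trained to separate them.
//
// All randomness (batch shuffling) draws from R's RNG so that a set.seed()
// on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Arch {
  int n_days, n_chan, kernel, pool, f1, f2, dense, dom_units;
  int L1, L1p, L2, L2p, D;
  bool has_domain;
};

struct Net {
  mat W1, W2, Wd, Wo, Wdm, Wdo;
  vec b1, b2, bd, bo, bdm, bdo;
};

Arch arch_from_list(const Rcpp::List& a) {
  Arch r;
  r.n_days = a["n_days"]; r.n_chan = a["n_features"];
  r.kernel = a["kernel_size"]; r.pool = a["pool_size"];
  Rcpp::IntegerVector filt = a["filters"];
  r.f1 = filt[0]; r.f2 = filt[1];
  r.dense = a["dense_units"];
  r.dom_units = a["domain_head_units"];
  r.has_domain = a["has_domain"];
  r.L1 = r.n_days - r.kernel + 1;
  r.L1p = r.L1 / r.pool;
  r.L2 = r.L1p - r.kernel + 1;
  r.L2p = r.L2 / r.pool;
  r.D = r.f2 * r.L2p;
  return r;
}

Net net_from_list(const Rcpp::List& w, const Arch& a) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<vec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<vec>(w["b2"]);
  n.Wd = Rcpp::as<mat>(w["Wd"]); n.bd = Rcpp::as<vec>(w["bd"]);
  n.Wo = Rcpp::as<mat>(w["Wo"]); n.bo = Rcpp::as<vec>(w["bo"]);
  if (a.has_domain) {
    n.Wdm = Rcpp::as<mat>(w["Wdm"]); n.bdm = Rcpp::as<vec>(w["bdm"]);
    n.Wdo = Rcpp::as<mat>(w["Wdo"]); n.bdo = Rcpp::as<vec>(w["bdo"]);
  }
  return n;
}

Rcpp::List net_to_list(const Net& n, const Arch& a) {
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
    Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
    Rcpp::Named("Wd") = n.Wd, Rcpp::Named("bd") = n.bd,
    Rcpp::Named("Wo") = n.Wo, Rcpp::Named("bo") = n.bo);
  if (a.has_domain) {
    out["Wdm"] = n.Wdm; out["bdm"] = n.bdm;
    out["Wdo"] = n.Wdo; out["bdo"] = n.bdo;
  }
  return out;
}

// column t of the result is the vectorized patch X[, t .. t+m-1]
mat im2col(const mat& X, int m) {
  int Lout = X.n_cols - m + 1;
  mat P(X.n_rows * m, Lout);
  for (int t = 0; t < Lout; ++t) P.col(t) = vectorise(X.cols(t, t + m - 1));
  return P;
}

void maxpool(const mat& A, int p, mat& out, imat& idx) {
  int Lp = A.n_cols / p;
  out.set_size(A.n_rows, Lp);
  idx.set_size(A.n_rows, Lp);
  for (int q = 0; q < Lp; ++q) {
    for (uword f = 0; f < A.n_rows; ++f) {
      uword best = q * p;
      for (int j = 1; j < p; ++j)
        if (A(f, q * p + j) > A(f, best)) best = q * p + j;
      out(f, q) = A(f, best);
      idx(f, q) = best;
    }
  }
}

struct Cache {
  mat X0, P1, Z1, A1p, P2, Z2, A2p;
  imat idx1, idx2;
  vec flat, h_pre, h, logits, prob;
  vec hd_pre, hd, dlogits, dprob;
};

vec softmax2(const vec& z) {
  double m = z.max();
  vec e = exp(z - m);
  return e / accu(e);
}

// forward one sample; xrow has layout [channel-major: N values of ch 1, ...]
void forward_sample(const Net& net, const Arch& a, const rowvec& xrow,
                    Cache& c, bool domain) {
  c.X0 = reshape(mat(xrow), a.n_days, a.n_chan).t();  // (C x N)
  c.P1 = im2col(c.X0, a.kernel);
  c.Z1 = net.W1.t() * c.P1;
  c.Z1.each_col() += net.b1;
  mat A1 = clamp(c.Z1, 0.0, datum::inf);
  maxpool(A1, a.pool, c.A1p, c.idx1);
  c.P2 = im2col(c.A1p, a.kernel);
  c.Z2 = net.W2.t() * c.P2;
  c.Z2.each_col() += net.b2;
  mat A2 = clamp(c.Z2, 0.0, datum::inf);
  maxpool(A2, a.pool, c.A2p, c.idx2);
  c.flat = vectorise(c.A2p);
  c.h_pre = net.Wd.t() * c.flat + net.bd;
  c.h = clamp(c.h_pre, 0.0, datum::inf);
  c.logits = net.Wo.t() * c.h + net.bo;
  c.prob = softmax2(c.logits);
  if (domain) {
    c.hd_pre = net.Wdm.t() * c.flat + net.bdm;
    c.hd = clamp(c.hd_pre, 0.0, datum::inf);
    c.dlogits = net.Wdo.t() * c.hd + net.bdo;
    c.dprob = softmax2(c.dlogits);
  }
}

// accumulate gradients for one sample.
// gl: d(label loss)/d(label logits); gd: d(domain loss)/d(domain logits);
// the domain contribution reaching the extractor is scaled by -lambda (GRL).
void backward_sample(const Net& net, const Arch& a, const Cache& c,
                     const vec& gl, const vec& gd, double lambda,
                     bool domain, Net& g) {
  vec dflat(a.D, fill::zeros);
  if (accu(abs(gl)) > 0) {
    g.Wo += c.h * gl.t();
    g.bo += gl;
    vec dh = net.Wo * gl;
    dh.elem(find(c.h_pre <= 0)).zeros();
    g.Wd += c.flat * dh.t();
    g.bd += dh;
    dflat += net.Wd * dh;
  }
  if (domain) {
    g.Wdo += c.hd * gd.t();
    g.bdo += gd;
    vec dhd = net.Wdo * gd;
    dhd.elem(find(c.hd_pre <= 0)).zeros();
    g.Wdm += c.flat * dhd.t();
    g.bdm += dhd;
    dflat += (-lambda) * (net.Wdm * dhd);  // gradient reversal
  }
  // back through pool2 / conv2
  mat dA2p = reshape(dflat, a.f2, a.L2p);
  mat dA2(a.f2, a.L2, fill::zeros);
  for (int q = 0; q < a.L2p; ++q)
    for (int f = 0; f < a.f2; ++f) dA2(f, c.idx2(f, q)) += dA2p(f, q);
  mat dZ2 = dA2;
  dZ2.elem(find(c.Z2 <= 0)).zeros();
  g.W2 += c.P2 * dZ2.t();
  g.b2 += sum(dZ2, 1);
  mat dP2 = net.W2 * dZ2;
  mat dA1p(a.f1, a.L1p, fill::zeros);
  for (int t = 0; t < a.L2; ++t)
    dA1p.cols(t, t + a.kernel - 1) += reshape(dP2.col(t), a.f1, a.kernel);
  // back through pool1 / conv1
  mat dA1(a.f1, a.L1, fill::zeros);
  for (int q = 0; q < a.L1p; ++q)
    for (int f = 0; f < a.f1; ++f) dA1(f, c.idx1(f, q)) += dA1p(f, q);
  mat dZ1 = dA1;
  dZ1.elem(find(c.Z1 <= 0)).zeros();
  g.W1 += c.P1 * dZ1.t();
  g.b1 += sum(dZ1, 1);
}

Net zeros_like(const Net& n, const Arch& a) {
  Net g;
  g.W1 = zeros<mat>(size(n.W1)); g.b1 = zeros<vec>(size(n.b1));
  g.W2 = zeros<mat>(size(n.W2)); g.b2 = zeros<vec>(size(n.b2));
  g.Wd = zeros<mat>(size(n.Wd)); g.bd = zeros<vec>(size(n.bd));
  g.Wo = zeros<mat>(size(n.Wo)); g.bo = zeros<vec>(size(n.bo));
  if (a.has_domain) {
    g.Wdm = zeros<mat>(size(n.Wdm)); g.bdm = zeros<vec>(size(n.bdm));
    g.Wdo = zeros<mat>(size(n.Wdo)); g.bdo = zeros<vec>(size(n.bdo));
  }
  return g;
}

double ce2(const vec& prob, int y) {
  return -std::log(std::max(prob(y), 1e-12));
}

// label + domain loss and gradients over a set of rows (one batch)
void batch_pass(const Net& net, const Arch& a, const mat& X,
                const Rcpp::IntegerVector& y, const Rcpp::IntegerVector& dom,
                const Rcpp::NumericVector& w, const Rcpp::NumericVector& dw,
                const uvec& rows, double lambda, bool domain, bool want_grad,
                Net* grad, double& label_loss, double& domain_loss) {
  double wsum = 0.0, dwsum = 0.0;
  for (uword k = 0; k < rows.n_elem; ++k) {
    wsum += w[rows(k)];
    dwsum += dw[rows(k)];
  }
  if (wsum <= 0) wsum = 1.0;
  if (dwsum <= 0) dwsum = 1.0;
  label_loss = 0.0;
  domain_loss = 0.0;
  Cache c;
  for (uword k = 0; k < rows.n_elem; ++k) {
    uword i = rows(k);
    forward_sample(net, a, X.row(i), c, domain);
    label_loss += w[i] * ce2(c.prob, y[i]) / wsum;
    vec gl(2, fill::zeros), gd(2, fill::zeros);
    gl = c.prob;
    gl(y[i]) -= 1.0;
    gl *= w[i] / wsum;
    if (domain) {
      domain_loss += dw[i] * ce2(c.dprob, dom[i]) / dwsum;
      gd = c.dprob;
      gd(dom[i]) -= 1.0;
      gd *= dw[i] / dwsum;
    }
    if (want_grad) backward_sample(net, a, c, gl, gd, lambda, domain, *grad);
  }
}

struct AdamState {
  std::vector<mat> m_w, v_w;
  std::vector<vec> m_b, v_b;
  long t = 0;
};

void adam_step(std::vector<mat*>& W, std::vector<mat*>& gW,
               std::vector<vec*>& b, std::vector<vec*>& gb,
               AdamState& s, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  if (s.t == 0) {
    for (auto* w : W) { s.m_w.push_back(zeros<mat>(size(*w)));
                        s.v_w.push_back(zeros<mat>(size(*w))); }
    for (auto* v : b) { s.m_b.push_back(zeros<vec>(size(*v)));
                        s.v_b.push_back(zeros<vec>(size(*v))); }
  }
  s.t += 1;
  double c1 = 1.0 - std::pow(b1, (double)s.t);
  double c2 = 1.0 - std::pow(b2, (double)s.t);
  for (size_t i = 0; i < W.size(); ++i) {
    s.m_w[i] = b1 * s.m_w[i] + (1 - b1) * (*gW[i]);
    s.v_w[i] = b2 * s.v_w[i] + (1 - b2) * square(*gW[i]);
    *W[i] -= lr * (s.m_w[i] / c1) / (sqrt(s.v_w[i] / c2) + eps);
  }
  for (size_t i = 0; i < b.size(); ++i) {
    s.m_b[i] = b1 * s.m_b[i] + (1 - b1) * (*gb[i]);
    s.v_b[i] = b2 * s.v_b[i] + (1 - b2) * square(*gb[i]);
    *b[i] -= lr * (s.m_b[i] / c1) / (sqrt(s.v_b[i] / c2) + eps);
  }
}

void collect_params(Net& n, const Arch& a, std::vector<mat*>& W,
                    std::vector<vec*>& b) {
  W = {&n.W1, &n.W2, &n.Wd, &n.Wo};
  b = {&n.b1, &n.b2, &n.bd, &n.bo};
  if (a.has_domain) {
    W.push_back(&n.Wdm); W.push_back(&n.Wdo);
    b.push_back(&n.bdm); b.push_back(&n.bdo);
  }
}

// Fisher-Yates permutation driven by R's RNG (deterministic under set.seed)
uvec r_permutation(int n) {
  uvec p(n);
  for (int i = 0; i < n; ++i) p(i) = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p(i), p(j));
  }
  return p;
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_forward_cpp(Rcpp::List weights, Rcpp::List arch,
                                   arma::mat X) {
  Arch a = arch_from_list(arch);
  Net net = net_from_list(weights, a);
  Rcpp::NumericMatrix out(X.n_rows, 2);
  Cache c;
  for (uword i = 0; i < X.n_rows; ++i) {
    forward_sample(net, a, X.row(i), c, false);
    out(i, 0) = c.prob(0);
    out(i, 1) = c.prob(1);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_features_cpp(Rcpp::List weights, Rcpp::List arch,
                                    arma::mat X) {
  Arch a = arch_from_list(arch);
  Net net = net_from_list(weights, a);
  Rcpp::NumericMatrix out(X.n_rows, a.D);
  Cache c;
  for (uword i = 0; i < X.n_rows; ++i) {
    forward_sample(net, a, X.row(i), c, false);
    for (int j = 0; j < a.D; ++j) out(i, j) = c.flat(j);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_loss_cpp(Rcpp::List weights, Rcpp::List arch, arma::mat X,
                       Rcpp::IntegerVector y, Rcpp::IntegerVector dom,
                       Rcpp::NumericVector w, Rcpp::NumericVector dw,
                       double lambda) {
  Arch a = arch_from_list(arch);
  Net net = net_from_list(weights, a);
  uvec rows = regspace<uvec>(0, X.n_rows - 1);
  double ll, dl;
  batch_pass(net, a, X, y, dom, w, dw, rows, lambda, a.has_domain, false,
             nullptr, ll, dl);
  return Rcpp::List::create(Rcpp::Named("label_loss") = ll,
                            Rcpp::Named("domain_loss") = dl);
}

// [[Rcpp::export]]
Rcpp::List nn_grad_cpp(Rcpp::List weights, Rcpp::List arch, arma::mat X,
                       Rcpp::IntegerVector y, Rcpp::IntegerVector dom,
                       Rcpp::NumericVector w, Rcpp::NumericVector dw,
                       double lambda) {
  Arch a = arch_from_list(arch);
  Net net = net_from_list(weights, a);
  Net grad = zeros_like(net, a);
  uvec rows = regspace<uvec>(0, X.n_rows - 1);
  double ll, dl;
  batch_pass(net, a, X, y, dom, w, dw, rows, lambda, a.has_domain, true,
             &grad, ll, dl);
  Rcpp::List g = net_to_list(grad, a);
  g.attr("label_loss") = ll;
  g.attr("domain_loss") = dl;
  return g;
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List weights, Rcpp::List arch,
                        arma::mat X, Rcpp::IntegerVector y,
                        Rcpp::IntegerVector dom, Rcpp::NumericVector w,
                        Rcpp::NumericVector dw,
                        arma::mat Xval, Rcpp::IntegerVector yval,
                        Rcpp::NumericVector lambda_per_epoch,
                        int batch_size, double lr, int patience) {
  Arch a = arch_from_list(arch);
  Net net = net_from_list(weights, a);
  int n = X.n_rows;
  int epochs = lambda_per_epoch.size();
  bool domain = a.has_domain;
  std::vector<mat*> Wp, gWp;
  std::vector<vec*> bp, gbp;
  collect_params(net, a, Wp, bp);
  AdamState adam;

  Net best = net;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0;
  std::vector<double> h_train, h_dom, h_val;

  Rcpp::IntegerVector dval(yval.size(), 0);
  Rcpp::NumericVector wval(yval.size(), 1.0);

  for (int e = 0; e < epochs; ++e) {
    double lambda = lambda_per_epoch[e];
    uvec perm = r_permutation(n);
    double ep_label = 0.0, ep_dom = 0.0;
    int n_batches = 0;
    for (int at = 0; at < n; at += batch_size) {
      int hi = std::min(at + batch_size, n) - 1;
      uvec rows = perm.subvec(at, hi);
      Net grad = zeros_like(net, a);
      std::vector<mat*> gW; std::vector<vec*> gb;
      collect_params(grad, a, gW, gb);
      double ll, dl;
      batch_pass(net, a, X, y, dom, w, dw, rows, lambda, domain, true,
                 &grad, ll, dl);
      adam_step(Wp, gW, bp, gb, adam, lr);
      ep_label += ll; ep_dom += dl; n_batches += 1;
    }
    ep_label /= n_batches; ep_dom /= n_batches;

    double vl = datum::nan;
    if (Xval.n_rows > 0) {
      uvec vr = regspace<uvec>(0, Xval.n_rows - 1);
      double vdl;
      batch_pass(net, a, Xval, yval, dval, wval, wval, vr, 0.0, false, false,
                 nullptr, vl, vdl);
    }
    h_train.push_back(ep_label);
    h_dom.push_back(domain ? ep_dom : NA_REAL);
    h_val.push_back(vl);

    if (Xval.n_rows > 0) {
      if (vl < best_val - 1e-12) {
        best_val = vl; best = net; best_epoch = e + 1; bad = 0;
      } else {
        bad += 1;
        if (patience > 0 && bad >= patience) break;
      }
    } else {
      best = net; best_epoch = e + 1;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(best, a),
    Rcpp::Named("final_weights") = net_to_list(net, a),
    Rcpp::Named("train_label_loss") = h_train,
    Rcpp::Named("train_domain_loss") = h_dom,
    Rcpp::Named("val_loss") = h_val,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val);
}
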