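// Compiled fast path for meta-training: one call runs the forward pass of a
// whole event (LSTM + decision + EM gate + competitive retrieval), samples
// actions and rewards, computes the phase-specific head gradients and
// backpropagates through the event. Semantics are defined by the pure-R
// reference implementation (forward_step / rollout_event / event_backward);
// the test suite checks the two paths against each other.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static inline vec sigmoid_v(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static inline vec softmax_v(const vec& z) {
  vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

// cosine evidence of cue against the first n_mem columns of M; zero-norm
// convention: evidence 0
static vec evidence_v(const mat& M, int n_mem, const vec& cue) {
  vec x(n_mem, arma::fill::zeros);
  double cn = arma::norm(cue);
  if (cn == 0.0) return x;
  for (int i = 0; i < n_mem; ++i) {
    double mn = arma::norm(M.col(i));
    if (mn > 0.0) x(i) = arma::dot(M.col(i), cue) / (mn * cn);
  }
  return x;
}

// synchronous no-leak no-noise competitive accumulation
static vec lca_forward(const vec& x, double gate, double beta, int n_cycles) {
  int n = x.n_elem;
  vec w(n, arma::fill::zeros);
  for (int tau = 0; tau < n_cycles; ++tau) {
    double tot = arma::accu(w);
    vec pre = gate * x - beta * (tot - w);
    w = arma::clamp(pre, 0.0, arma::datum::inf);
    w.elem(arma::find(pre <= 0.0)).zeros();
  }
  return w;
}

// reverse pass through the accumulation cycles; the rectifier masks are
// reconstructed by re-running the (deterministic) forward recursion
static void lca_backward_c(const vec& x, double gate, double beta,
                           int n_cycles, const vec& dw_final,
                           double& dgate, vec& dx) {
  int n = x.n_elem;
  arma::umat on(n, n_cycles);
  vec w(n, arma::fill::zeros);
  for (int tau = 0; tau < n_cycles; ++tau) {
    double tot = arma::accu(w);
    vec pre = gate * x - beta * (tot - w);
    for (int i = 0; i < n; ++i) {
      on(i, tau) = pre(i) > 0.0 ? 1 : 0;
      w(i) = pre(i) > 0.0 ? pre(i) : 0.0;
    }
  }
  vec dw = dw_final;
  dgate = 0.0;
  dx.zeros(n);
  for (int tau = n_cycles - 1; tau >= 0; --tau) {
    vec dpre(n, arma::fill::zeros);
    for (int i = 0; i < n; ++i) if (on(i, tau)) dpre(i) = dw(i);
    dgate += arma::dot(dpre, x);
    dx += gate * dpre;
    double s = arma::accu(dpre);
    dw = -beta * (s - dpre);
  }
}

// [[Rcpp::export(name = ".event_core")]]
List event_core(const List& par, const arma::mat& X,
                const IntegerVector& queried,
                const IntegerVector& target, const arma::vec& h0,
                const arma::vec& c0, const arma::mat& M0, int phase,
                const IntegerVector& encode_steps,
                double beta, int n_cycles, bool em_on, double gate_clamp,
                double penalty, double reward_correct, double eta,
                double value_coef, double gamma, bool value_detached,
                bool adv_norm) {
  const mat W_lstm = par["W_lstm"]; const vec b_lstm = par["b_lstm"];
  const mat W_d = par["W_d"];       const vec b_d = par["b_d"];
  const vec u_g = par["u_g"];       const double b_g = as<double>(par["b_g"]);
  const mat W_pi = par["W_pi"];     const vec b_pi = par["b_pi"];
  const vec w_v = par["w_v"];       const double b_v = as<double>(par["b_v"]);

  const int S = X.n_rows;
  const int H = h0.n_elem;
  const int Hd = W_d.n_rows;
  const int A = W_pi.n_rows;
  const int B = A - 1;
  const int Din = X.n_cols;
  const int D = Din + H;
  const bool clamped = gate_clamp >= 0.0;

  int n_encode = encode_steps.size();
  int n0 = M0.n_cols;
  mat M(H, n0 + (em_on ? n_encode : 0));
  if (n0 > 0) M.cols(0, n0 - 1) = M0;
  int n_mem = n0;

  // caches
  mat Zc(D, S), GI(H, S), GF(H, S), GO(H, S), GG(H, S);
  mat Cprev(H, S), Cprov(H, S), Hprov(H, S), Dprovpre(Hd, S), Dprov(Hd, S);
  mat Cnew(H, S), Dpre(Hd, S), Dmat(Hd, S);
  mat POL(A, S), LOG(A, S);
  vec alpha_s(S), val(S), gatev(S);
  IntegerVector n_mem_s(S);
  mat XE(std::max(n_mem + n_encode, 1), S, arma::fill::zeros);  // evidence
  mat WACT(std::max(n_mem + n_encode, 1), S, arma::fill::zeros);

  IntegerVector action(S), rewarded(S);
  NumericVector reward(S);
  vec h = h0, c = c0;
  double loss = 0.0;

  for (int s = 0; s < S; ++s) {
    vec z(D);
    z.subvec(0, Din - 1) = X.row(s).t();
    z.subvec(Din, D - 1) = h;
    vec pre = W_lstm * z + b_lstm;
    vec gi = sigmoid_v(pre.subvec(0, H - 1));
    vec gf = sigmoid_v(pre.subvec(H, 2 * H - 1));
    vec go = sigmoid_v(pre.subvec(2 * H, 3 * H - 1));
    vec gg = arma::tanh(pre.subvec(3 * H, 4 * H - 1));
    Cprev.col(s) = c;
    vec c_prov = gf % c + gi % gg;
    vec h_prov = go % arma::tanh(c_prov);
    vec d_prov_pre = W_d * h_prov + b_d;
    vec d_prov = arma::clamp(d_prov_pre, 0.0, arma::datum::inf);

    double gate_pre = arma::dot(u_g.subvec(0, H - 1), h_prov) +
      arma::dot(u_g.subvec(H, H + Hd - 1), d_prov) + b_g;
    double alpha = 1.0 / (1.0 + std::exp(-gate_pre));
    if (clamped) alpha = gate_clamp;

    vec mu(H, arma::fill::zeros);
    int nm = em_on ? n_mem : 0;
    if (nm > 0) {
      vec xe = evidence_v(M, nm, c_prov);
      vec w = lca_forward(xe, alpha, beta, n_cycles);
      mu = M.cols(0, nm - 1) * w;
      XE.submat(0, s, nm - 1, s) = xe;
      WACT.submat(0, s, nm - 1, s) = w;
    }
    vec c_new = c_prov + mu;
    vec h_new = go % arma::tanh(c_new);
    vec d_pre = W_d * h_new + b_d;
    vec d = arma::clamp(d_pre, 0.0, arma::datum::inf);
    vec logits = W_pi * d + b_pi;
    vec pol = softmax_v(logits);
    double v = arma::dot(w_v, d) + b_v;
    if (!pol.is_finite() || !std::isfinite(v)) {
      stop("non-finite activations in forward step (training divergence)");
    }

    Zc.col(s) = z; GI.col(s) = gi; GF.col(s) = gf; GO.col(s) = go;
    GG.col(s) = gg; Cprov.col(s) = c_prov; Hprov.col(s) = h_prov;
    Dprovpre.col(s) = d_prov_pre; Dprov.col(s) = d_prov;
    Cnew.col(s) = c_new; Dpre.col(s) = d_pre; Dmat.col(s) = d;
    POL.col(s) = pol; LOG.col(s) = logits;
    alpha_s(s) = alpha; val(s) = v; gatev(s) = alpha;
    n_mem_s[s] = nm;

    h = h_new; c = c_new;

    if (queried[s] > 0) {
      int a;
      if (phase == 2) {
        a = (int)pol.index_max() + 1;
      } else {
        double u = R::runif(0.0, 1.0), acc = 0.0;
        a = A;
        for (int k = 0; k < A; ++k) { acc += pol(k); if (u <= acc) { a = k + 1; break; } }
      }
      action[s] = a;
      double r = (a == A) ? 0.0 : (a == target[s] ? reward_correct : -penalty);
      reward[s] = r;
      rewarded[s] = 1;
    } else {
      action[s] = NA_INTEGER;
      reward[s] = NA_REAL;
      rewarded[s] = 0;
    }

    if (em_on) {
      for (int e = 0; e < n_encode; ++e) {
        if (encode_steps[e] == s + 1) { M.col(n_mem) = c; ++n_mem; }
      }
    }
  }

  List out = List::create(
    Named("h") = NumericVector(h.begin(), h.end()),
    Named("c") = NumericVector(c.begin(), c.end()),
    Named("gate") = NumericVector(gatev.begin(), gatev.end()),
    Named("value") = NumericVector(val.begin(), val.end()),
    Named("action") = action,
    Named("reward") = reward,
    Named("policies") = wrap(POL.t()),
    Named("cells") = wrap(Cnew),
    Named("act_mat") = wrap(WACT),
    Named("new_memories") = (n_mem > n0)
      ? wrap(mat(M.cols(n0, n_mem - 1)))
      : wrap(mat(H, 0))
  );
  if (phase == 2) { out["loss"] = NA_REAL; return out; }

  // ---- head gradients ----
  // gamma >= 0 replaces the immediate reward by the within-event
  // discounted return in the advantage and the critic target
  vec ret(S, arma::fill::zeros);
  {
    double acc = 0.0;
    for (int s = S - 1; s >= 0; --s) {
      double r = rewarded[s] ? reward[s] : 0.0;
      acc = r + (gamma >= 0.0 ? gamma : 0.0) * acc;
      ret(s) = gamma >= 0.0 ? acc : r;
    }
  }
  // optional per-event advantage standardisation for the policy term
  vec adv_all(S, arma::fill::zeros);
  if (phase == 1) {
    std::vector<double> raw;
    for (int s = 0; s < S; ++s) {
      if (rewarded[s]) { adv_all(s) = ret(s) - val(s); raw.push_back(adv_all(s)); }
    }
    if (adv_norm && raw.size() > 1) {
      double mu_ = 0.0, sd_ = 0.0;
      for (double r : raw) mu_ += r;
      mu_ /= raw.size();
      for (double r : raw) sd_ += (r - mu_) * (r - mu_);
      sd_ = std::sqrt(sd_ / (raw.size() - 1));
      if (sd_ < 1e-4) sd_ = 1e-4;
      for (int s = 0; s < S; ++s) {
        if (rewarded[s]) adv_all(s) = (adv_all(s) - mu_) / sd_;
      }
    }
  }
  mat dlogits(A, S, arma::fill::zeros);
  vec dval(S, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    if (!rewarded[s]) continue;
    if (phase == 0) {                     // supervised: CE on the B states
      vec lb = LOG.submat(0, s, B - 1, s);
      vec p = softmax_v(lb);
      int tgt = target[s] - 1;
      double pt = std::max(p(tgt), 1e-12);
      loss += -std::log(pt);
      for (int k = 0; k < B; ++k) dlogits(k, s) = p(k);
      dlogits(tgt, s) -= 1.0;
    } else {                              // actor-critic
      int a = action[s] - 1;
      vec pol = POL.col(s);
      vec logp = arma::log(arma::clamp(pol, 1e-12, arma::datum::inf));
      double ent = -arma::dot(pol, logp);
      double tgt_r = ret(s);
      double adv = adv_all(s);
      loss += -logp(a) * adv + value_coef * std::pow(val(s) - tgt_r, 2)
        - eta * ent;
      vec one(A, arma::fill::zeros); one(a) = 1.0;
      dlogits.col(s) = adv * (pol - one) + eta * (pol % (logp + ent));
      dval(s) = 2.0 * value_coef * (val(s) - tgt_r);
    }
  }
  if (!std::isfinite(loss)) stop("non-finite loss");

  // ---- backward ----
  mat gW_lstm(arma::size(W_lstm), arma::fill::zeros);
  vec gb_lstm(4 * H, arma::fill::zeros);
  mat gW_d(arma::size(W_d), arma::fill::zeros);
  vec gb_d(Hd, arma::fill::zeros);
  vec gu_g(H + Hd, arma::fill::zeros);
  double gb_g = 0.0;
  mat gW_pi(arma::size(W_pi), arma::fill::zeros);
  vec gb_pi(A, arma::fill::zeros);
  vec gw_v(Hd, arma::fill::zeros);
  double gb_v = 0.0;

  mat DA(4 * H, S, arma::fill::zeros);
  mat DDpre(Hd, S, arma::fill::zeros), DDprov(Hd, S, arma::fill::zeros);
  vec dh_carry(H, arma::fill::zeros), dc_carry(H, arma::fill::zeros);

  for (int s = S - 1; s >= 0; --s) {
    vec dlg = dlogits.col(s);
    double dvs = dval(s);
    // with a detached critic, the value-regression gradient trains only
    // the value head; the trunk (and hence the retrieval gate) is shaped
    // by the policy and entropy terms alone
    vec dd = W_pi.t() * dlg + (value_detached ? 0.0 : dvs) * w_v;
    gb_pi += dlg;
    gw_v += dvs * Dmat.col(s);
    gb_v += dvs;

    vec dd_pre = dd % arma::conv_to<vec>::from(Dpre.col(s) > 0);
    DDpre.col(s) = dd_pre;
    gb_d += dd_pre;
    vec dh_new = dh_carry + W_d.t() * dd_pre;

    vec tanh_c_new = arma::tanh(Cnew.col(s));
    vec do_ = dh_new % tanh_c_new;
    vec dc_new = dh_new % GO.col(s) % (1.0 - arma::square(tanh_c_new)) +
      dc_carry;
    vec dc_prov = dc_new;

    vec dh_prov(H, arma::fill::zeros), dd_prov(Hd, arma::fill::zeros);
    int nm = n_mem_s[s];
    if (nm > 0) {
      mat Mn = M.cols(0, nm - 1);
      vec dw_fin = Mn.t() * dc_new;
      double dalpha; vec dx;
      lca_backward_c(XE.submat(0, s, nm - 1, s), alpha_s(s), beta,
                     n_cycles, dw_fin, dalpha, dx);
      if (!clamped) {
        double a_ = alpha_s(s);
        double dgate_pre = dalpha * a_ * (1.0 - a_);
        gu_g.subvec(0, H - 1) += dgate_pre * Hprov.col(s);
        gu_g.subvec(H, H + Hd - 1) += dgate_pre * Dprov.col(s);
        gb_g += dgate_pre;
        dh_prov = u_g.subvec(0, H - 1) * dgate_pre;
        dd_prov = u_g.subvec(H, H + Hd - 1) * dgate_pre;
      }
      vec cue = Cprov.col(s);
      double cn2 = arma::dot(cue, cue);
      if (cn2 > 0.0) {
        double cn = std::sqrt(cn2);
        double xsum = 0.0;
        vec xe = XE.submat(0, s, nm - 1, s);
        for (int i = 0; i < nm; ++i) {
          if (dx(i) == 0.0) continue;
          double mn = arma::norm(Mn.col(i));
          if (mn == 0.0) continue;
          dc_prov += dx(i) / (mn * cn) * Mn.col(i);
          xsum += dx(i) * xe(i);
        }
        dc_prov -= cue * (xsum / cn2);
      }
    }
    vec dd_prov_pre = dd_prov % arma::conv_to<vec>::from(Dprovpre.col(s) > 0);
    if (arma::any(dd_prov_pre != 0.0)) {
      DDprov.col(s) = dd_prov_pre;
      gb_d += dd_prov_pre;
      dh_prov += W_d.t() * dd_prov_pre;
    }
    vec tanh_c_prov = arma::tanh(Cprov.col(s));
    do_ += dh_prov % tanh_c_prov;
    dc_prov += dh_prov % GO.col(s) % (1.0 - arma::square(tanh_c_prov));

    vec dgf = dc_prov % Cprev.col(s);
    vec dgi = dc_prov % GG.col(s);
    vec dgg = dc_prov % GI.col(s);
    dc_carry = dc_prov % GF.col(s);

    vec da(4 * H);
    da.subvec(0, H - 1) = dgi % GI.col(s) % (1.0 - GI.col(s));
    da.subvec(H, 2 * H - 1) = dgf % GF.col(s) % (1.0 - GF.col(s));
    da.subvec(2 * H, 3 * H - 1) = do_ % GO.col(s) % (1.0 - GO.col(s));
    da.subvec(3 * H, 4 * H - 1) = dgg % (1.0 - arma::square(GG.col(s)));
    DA.col(s) = da;
    gb_lstm += da;
    vec dz = W_lstm.t() * da;
    dh_carry = dz.subvec(Din, D - 1);
  }
  gW_lstm = DA * Zc.t();
  {
    // W_d multiplies h_new = go % tanh(c_new) (and h_prov pre-retrieval)
    mat Hnew(H, S);
    for (int s = 0; s < S; ++s) {
      Hnew.col(s) = GO.col(s) % arma::tanh(Cnew.col(s));
    }
    gW_d = DDpre * Hnew.t() + DDprov * Hprov.t();
  }
  gW_pi = dlogits * Dmat.t();

  out["loss"] = loss;
  out["grads"] = List::create(
    Named("W_lstm") = wrap(gW_lstm), Named("b_lstm") = wrap(gb_lstm),
    Named("W_d") = wrap(gW_d), Named("b_d") = wrap(gb_d),
    Named("u_g") = wrap(gu_g), Named("b_g") = gb_g,
    Named("W_pi") = wrap(gW_pi), Named("b_pi") = wrap(gb_pi),
    Named("w_v") = wrap(gw_v), Named("b_v") = gb_v);
  return out;
}

// One Adam step over the named parameter list; returns updated parameters
// and moment estimates.
// [[Rcpp::export(name = ".adam_core")]]
List adam_core(const List& par, const List& grads, const List& m,
               const List& v, int t, double lr, double beta1, double beta2,
               double eps) {
  CharacterVector nms = par.names();
  List par2(par.size()), m2(par.size()), v2(par.size());
  par2.names() = nms; m2.names() = nms; v2.names() = nms;
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (int i = 0; i < par.size(); ++i) {
    NumericVector p = par[i], g = grads[i], mm = m[i], vv = v[i];
    int n = p.size();
    NumericVector pn(n), mn(n), vn(n);
    for (int k = 0; k < n; ++k) {
      if (!std::isfinite(g[k])) stop("non-finite gradient");
      mn[k] = beta1 * mm[k] + (1.0 - beta1) * g[k];
      vn[k] = beta2 * vv[k] + (1.0 - beta2) * g[k] * g[k];
      pn[k] = p[k] - lr * (mn[k] / bc1) / (std::sqrt(vn[k] / bc2) + eps);
    }
    pn.attr("dim") = p.attr("dim");
    par2[i] = pn; m2[i] = mn; v2[i] = vn;
  }
  return List::create(Named("par") = par2, Named("m") = m2,
                      Named("v") = v2);
}
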