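// Recurrent encoder (LSTM or GRU) + concatenation attention + linear decoder,
// with hand-derived reverse-mode gradients. Batched over examples: the input
// is a cube with slice t = (input_size x batch) matrix of time point t.
// All randomness (init, dropout masks, shuffling) lives on the R side; these
// routines are deterministic functions of their arguments.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct NetConfig {
  unsigned int input_size, hidden, layers, att_hidden, dec_hidden;
  double dropout;
  bool use_attention;
  bool gru;
};

NetConfig parse_config(const Rcpp::List& cfg) {
  NetConfig c;
  c.input_size = Rcpp::as<unsigned int>(cfg["input_size"]);
  c.hidden = Rcpp::as<unsigned int>(cfg["hidden"]);
  c.layers = Rcpp::as<unsigned int>(cfg["layers"]);
  c.att_hidden = Rcpp::as<unsigned int>(cfg["att_hidden"]);
  c.dec_hidden = Rcpp::as<unsigned int>(cfg["dec_hidden"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.use_attention = Rcpp::as<bool>(cfg["use_attention"]);
  c.gru = Rcpp::as<std::string>(cfg["encoder"]) == "gru";
  return c;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  std::vector<cube> gates;  // per layer: activated gates (4H or 3H, B, T)
  std::vector<cube> cells;  // LSTM cell states (H, B, T)
  std::vector<cube> unh;    // GRU: U_n * h_{t-1} cache (H, B, T)
  std::vector<cube> hs;     // hidden outputs per layer (H, B, T)
  cube U;                   // attention tanh units (A, B, T)
  mat S, W;                 // scores / softmax weights (T, B)
  mat context;              // (H, B)
  mat z1, z1d;              // decoder pre/post dropout (D, B)
  rowvec zo;                // pre-sigmoid output (1, B)
  vec p;                    // probabilities (B)
};

// Forward pass filling the cache. drop_mask: (D x B) 0/1 matrix or empty for
// evaluation mode (inverted dropout, scale 1/(1-dropout) applied here).
void forward_pass(const Rcpp::List& par, const NetConfig& c, const cube& X,
                  const mat& drop_mask, Cache& K) {
  const unsigned int T = X.n_slices, B = X.n_cols, H = c.hidden;
  const unsigned int G = c.gru ? 3 * H : 4 * H;
  K.gates.assign(c.layers, cube(G, B, T));
  K.hs.assign(c.layers, cube(H, B, T));
  if (c.gru) K.unh.assign(c.layers, cube(H, B, T));
  else K.cells.assign(c.layers, cube(H, B, T));

  for (unsigned int l = 0; l < c.layers; ++l) {
    std::string sl = std::to_string(l + 1);
    const mat Wi = par["Wi" + sl], Wh = par["Wh" + sl];
    const vec b = par["b" + sl];
    mat h(H, B, fill::zeros), cst(H, B, fill::zeros);
    for (unsigned int t = 0; t < T; ++t) {
      const mat xt = (l == 0) ? X.slice(t) : K.hs[l - 1].slice(t);
      if (c.gru) {
        mat arz = Wi.rows(0, 2 * H - 1) * xt + Wh.rows(0, 2 * H - 1) * h;
        arz.each_col() += b.rows(0, 2 * H - 1);
        mat r = sigm(arz.rows(0, H - 1));
        mat z = sigm(arz.rows(H, 2 * H - 1));
        mat uh = Wh.rows(2 * H, 3 * H - 1) * h;
        mat an = Wi.rows(2 * H, 3 * H - 1) * xt + r % uh;
        an.each_col() += b.rows(2 * H, 3 * H - 1);
        mat n = tanh(an);
        K.unh[l].slice(t) = uh;
        K.gates[l].slice(t) = join_cols(r, join_cols(z, n));
        h = (1.0 - z) % n + z % h;
      } else {
        mat a = Wi * xt + Wh * h;
        a.each_col() += b;
        mat i = sigm(a.rows(0, H - 1));
        mat f = sigm(a.rows(H, 2 * H - 1));
        mat g = tanh(a.rows(2 * H, 3 * H - 1));
        mat o = sigm(a.rows(3 * H, 4 * H - 1));
        cst = f % cst + i % g;
        K.cells[l].slice(t) = cst;
        K.gates[l].slice(t) = join_cols(join_cols(i, f), join_cols(g, o));
        h = o % tanh(cst);
      }
      K.hs[l].slice(t) = h;
    }
  }

  const cube& Hs = K.hs[c.layers - 1];
  const mat hT = Hs.slice(T - 1);
  if (c.use_attention) {
    const mat Wa1 = par["Wa1"];
    const vec ba1 = par["ba1"], wa2 = par["wa2"];
    const double ba2 = Rcpp::as<double>(par["ba2"]);
    K.U.set_size(c.att_hidden, B, T);
    K.S.set_size(T, B);
    for (unsigned int t = 0; t < T; ++t) {
      mat pre = Wa1 * join_cols(Hs.slice(t), hT);
      pre.each_col() += ba1;
      K.U.slice(t) = tanh(pre);
      K.S.row(t) = wa2.t() * K.U.slice(t) + ba2;
    }
    mat E = exp(K.S.each_row() - max(K.S, 0));
    K.W = E.each_row() / sum(E, 0);
    K.context.zeros(H, B);
    for (unsigned int t = 0; t < T; ++t)
      K.context += Hs.slice(t).each_row() % K.W.row(t);
  } else {
    K.W.zeros(T, B);
    K.W.row(T - 1).ones();
    K.context = hT;
  }

  const mat Wd1 = par["Wd1"];
  const vec bd1 = par["bd1"], wd2 = par["wd2"];
  const double bd2 = Rcpp::as<double>(par["bd2"]);
  K.z1 = Wd1 * K.context;
  K.z1.each_col() += bd1;
  if (drop_mask.n_elem > 0 && c.dropout > 0)
    K.z1d = (K.z1 % drop_mask) / (1.0 - c.dropout);
  else
    K.z1d = K.z1;
  K.zo = wd2.t() * K.z1d + bd2;
  K.p = vectorise(sigm(K.zo));
}

// Reverse pass from an upstream gradient dzo on the pre-sigmoid output.
// Fills param gradients (if gpar non-null) and input gradients (if gx
// non-null). drop_mask as in forward_pass.
void backward_pass(const Rcpp::List& par, const NetConfig& c, const cube& X,
                   const Cache& K, const rowvec& dzo, const mat& drop_mask,
                   Rcpp::List* gpar, cube* gx) {
  const unsigned int T = X.n_slices, B = X.n_cols, H = c.hidden;
  const vec wd2 = par["wd2"];
  const mat Wd1 = par["Wd1"];

  // decoder
  mat dz1d = wd2 * dzo;  // (D, B)
  mat dz1 = (drop_mask.n_elem > 0 && c.dropout > 0)
                ? mat((dz1d % drop_mask) / (1.0 - c.dropout))
                : dz1d;
  if (gpar) {
    (*gpar)["wd2"] = vec(K.z1d * dzo.t());
    (*gpar)["bd2"] = accu(dzo);
    (*gpar)["Wd1"] = mat(dz1 * K.context.t());
    (*gpar)["bd1"] = vec(sum(dz1, 1));
  }
  mat dC = Wd1.t() * dz1;  // gradient on context (H, B)

  // attention
  const cube& Hs = K.hs[c.layers - 1];
  cube dHs(H, B, T, fill::zeros);
  if (c.use_attention) {
    const mat Wa1 = par["Wa1"];
    const vec wa2 = par["wa2"];
    mat dw(T, B);
    for (unsigned int t = 0; t < T; ++t) {
      dw.row(t) = sum(Hs.slice(t) % dC, 0);
      dHs.slice(t) += dC.each_row() % K.W.row(t);
    }
    rowvec wdot = sum(K.W % dw, 0);
    mat ds = K.W % (dw.each_row() - wdot);
    const mat hT = Hs.slice(T - 1);
    mat gWa1(size(Wa1), fill::zeros);
    vec gba1(Wa1.n_rows, fill::zeros), gwa2(wa2.n_elem, fill::zeros);
    double gba2 = 0.0;
    mat dhT(H, B, fill::zeros);
    for (unsigned int t = 0; t < T; ++t) {
      rowvec dst = ds.row(t);
      mat du = wa2 * dst;
      mat dpre = du % (1.0 - K.U.slice(t) % K.U.slice(t));
      if (gpar) {
        gWa1 += dpre * join_cols(Hs.slice(t), hT).t();
        gba1 += sum(dpre, 1);
        gwa2 += K.U.slice(t) * dst.t();
        gba2 += accu(dst);
      }
      mat dz2 = Wa1.t() * dpre;
      dHs.slice(t) += dz2.rows(0, H - 1);
      dhT += dz2.rows(H, 2 * H - 1);
    }
    dHs.slice(T - 1) += dhT;
    if (gpar) {
      (*gpar)["Wa1"] = gWa1;
      (*gpar)["ba1"] = gba1;
      (*gpar)["wa2"] = gwa2;
      (*gpar)["ba2"] = gba2;
    }
  } else {
    dHs.slice(T - 1) += dC;
  }

  // BPTT, top layer down
  cube dOut = dHs;
  for (int l = c.layers - 1; l >= 0; --l) {
    std::string sl = std::to_string(l + 1);
    const mat Wi = par["Wi" + sl], Wh = par["Wh" + sl];
    const unsigned int in_rows = (l == 0) ? c.input_size : H;
    const bool need_din = (l > 0) || (gx != nullptr);
    cube dIn;
    if (need_din) dIn.zeros(in_rows, B, T);
    mat gWi(size(Wi), fill::zeros), gWh(size(Wh), fill::zeros);
    vec gb(Wi.n_rows, fill::zeros);
    mat dh(H, B, fill::zeros), dc(H, B, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      dh += dOut.slice(t);
      const mat xt = (l == 0) ? X.slice(t) : K.hs[l - 1].slice(t);
      const mat hprev =
          (t > 0) ? mat(K.hs[l].slice(t - 1)) : mat(H, B, fill::zeros);
      if (c.gru) {
        const mat& gt = K.gates[l].slice(t);
        mat r = gt.rows(0, H - 1), z = gt.rows(H, 2 * H - 1),
            n = gt.rows(2 * H, 3 * H - 1);
        const mat& uh = K.unh[l].slice(t);
        mat dzg = dh % (hprev - n);
        mat dn = dh % (1.0 - z);
        mat dhprev = dh % z;
        mat dan = dn % (1.0 - n % n);
        mat dr = dan % uh;
        mat dunh = dan % r;
        dhprev += Wh.rows(2 * H, 3 * H - 1).t() * dunh;
        mat dar = dr % r % (1.0 - r);
        mat daz = dzg % z % (1.0 - z);
        mat darz = join_cols(dar, daz);
        if (gpar) {
          gWh.rows(2 * H, 3 * H - 1) += dunh * hprev.t();
          gWi.rows(0, 2 * H - 1) += darz * xt.t();
          gWi.rows(2 * H, 3 * H - 1) += dan * xt.t();
          gWh.rows(0, 2 * H - 1) += darz * hprev.t();
          gb.rows(0, 2 * H - 1) += sum(darz, 1);
          gb.rows(2 * H, 3 * H - 1) += sum(dan, 1);
        }
        if (need_din)
          dIn.slice(t) = Wi.rows(0, 2 * H - 1).t() * darz +
                         Wi.rows(2 * H, 3 * H - 1).t() * dan;
        dhprev += Wh.rows(0, 2 * H - 1).t() * darz;
        dh = dhprev;
      } else {
        const mat& gt = K.gates[l].slice(t);
        mat i = gt.rows(0, H - 1), f = gt.rows(H, 2 * H - 1),
            g = gt.rows(2 * H, 3 * H - 1), o = gt.rows(3 * H, 4 * H - 1);
        mat tc = tanh(K.cells[l].slice(t));
        mat do_ = dh % tc;
        dc += dh % o % (1.0 - tc % tc);
        const mat cprev =
            (t > 0) ? mat(K.cells[l].slice(t - 1)) : mat(H, B, fill::zeros);
        mat dai = (dc % g) % i % (1.0 - i);
        mat daf = (dc % cprev) % f % (1.0 - f);
        mat dag = (dc % i) % (1.0 - g % g);
        mat dao = do_ % o % (1.0 - o);
        mat da = join_cols(join_cols(dai, daf), join_cols(dag, dao));
        if (gpar) {
          gWi += da * xt.t();
          gWh += da * hprev.t();
          gb += sum(da, 1);
        }
        if (need_din) dIn.slice(t) = Wi.t() * da;
        dh = Wh.t() * da;
        dc = dc % f;
      }
    }
    if (gpar) {
      (*gpar)["Wi" + sl] = gWi;
      (*gpar)["Wh" + sl] = gWh;
      (*gpar)["b" + sl] = gb;
    }
    if (l > 0)
      dOut = dIn;
    else if (gx)
      *gx = dIn;
  }
}

}  // namespace

// Evaluation-mode forward: probabilities, attention weights, context.
// [[Rcpp::export]]
Rcpp::List ta_forward_cpp(Rcpp::List params, Rcpp::List config,
                          arma::cube X) {
  NetConfig c = parse_config(config);
  Cache K;
  forward_pass(params, c, X, mat(), K);
  return Rcpp::List::create(Rcpp::Named("prob") = K.p,
                            Rcpp::Named("attention") = K.W,
                            Rcpp::Named("context") = K.context);
}

// Mean binary cross-entropy over the batch and its parameter gradients.
// y: 0/1 vector of length B. drop_mask: (dec_hidden x B) 0/1 matrix or NULL.
// [[Rcpp::export]]
Rcpp::List ta_loss_grad_cpp(Rcpp::List params, Rcpp::List config,
                            arma::cube X, arma::vec y,
                            Rcpp::Nullable<Rcpp::NumericMatrix> drop_mask) {
  NetConfig c = parse_config(config);
  mat dm;
  if (drop_mask.isNotNull()) dm = Rcpp::as<mat>(drop_mask.get());
  Cache K;
  forward_pass(params, c, X, dm, K);
  const double eps = 1e-7;
  vec pc = clamp(K.p, eps, 1.0 - eps);
  double loss = -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));
  rowvec dzo = ((K.p - y) / static_cast<double>(y.n_elem)).t();
  Rcpp::List gpar;
  backward_pass(params, c, X, K, dzo, dm, &gpar, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("prob") = K.p,
                            Rcpp::Named("grads") = gpar);
}

// Gradient of the sigmoid output probability with respect to the inputs,
// per example (evaluation mode); used by integrated gradients.
// [[Rcpp::export]]
Rcpp::List ta_input_grad_cpp(Rcpp::List params, Rcpp::List config,
                             arma::cube X) {
  NetConfig c = parse_config(config);
  Cache K;
  forward_pass(params, c, X, mat(), K);
  rowvec dzo = (K.p % (1.0 - K.p)).t();
  cube gx;
  backward_pass(params, c, X, K, dzo, mat(), nullptr, &gx);
  return Rcpp::List::create(Rcpp::Named("prob") = K.p,
                            Rcpp::Named("grad") = gx);
}
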