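// Character-enhanced bi-LSTM token tagger: forward pass, cross-entropy loss
// and full backpropagation over one flattened parameter vector.
//
// The recurrent cell is the coupled-gate variant used throughout this
// package: the forget gate equals (1 - input gate) and a constant +1 is
// added inside the input-gate sigmoid:
//   i_t = sigma(W_i [z_t; h_{t-1}] + b_i + 1)
//   c_t = i_t . c_{t-1} + (1 - i_t) . tanh(W_c [z_t; h_{t-1}] + b_c)
//   o_t = sigma(W_o [z_t; h_{t-1}] + b_o)
//   h_t = o_t . tanh(c_t)
// h_0 = c_0 = 0.
//
// The character LSTMs see one-hot inputs, so their input-weight products
// reduce to column lookups (W z = W.col(code)); only the recurrent block is
// a real matrix-vector product. The label LSTMs take dense inputs.
//
// Parameter vector layout (must match param_layout() on the R side):
//   char_fwd:  W_i, W_c, W_o (hid x (inp+hid) each), b_i, b_c, b_o (hid)
//   char_bwd:  same
//   label_fwd: same (inp = word_dim + 2*char_hidden)
//   label_bwd: same
//   W_1 (ff x 2*label_hidden), b_1 (ff), W_2 (n_labels x ff), b_2 (n_labels)

#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::uvec;
using arma::uword;
using arma::vec;

namespace {

struct LstmW {
  mat Wi, Wc, Wo;
  vec bi, bc, bo;
  uword hid, inp;
};

// Aliasing views into a flat vector; writes propagate to the underlying
// memory (used both for reading parameters and accumulating gradients).
LstmW make_view(double* base, size_t& off, uword hid, uword inp) {
  LstmW L;
  L.hid = hid;
  L.inp = inp;
  const uword cols = inp + hid;
  L.Wi = mat(base + off, hid, cols, false, true); off += hid * cols;
  L.Wc = mat(base + off, hid, cols, false, true); off += hid * cols;
  L.Wo = mat(base + off, hid, cols, false, true); off += hid * cols;
  L.bi = vec(base + off, hid, false, true); off += hid;
  L.bc = vec(base + off, hid, false, true); off += hid;
  L.bo = vec(base + off, hid, false, true); off += hid;
  return L;
}

struct Cache {
  mat I, G, O, C, TC, H;  // gate/state activations, hid x m
  void resize(uword hid, uword m) {
    I.set_size(hid, m);
    G.set_size(hid, m);
    O.set_size(hid, m);
    C.set_size(hid, m);
    TC.set_size(hid, m);
    H.set_size(hid, m);
  }
};

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Shared gate math for one step given the three preactivations.
inline void cell_step(const vec& ui, const vec& uc, const vec& uo, vec& h,
                      vec& c, Cache* ca, uword t) {
  const vec ig = sigmoid(ui + 1.0);
  const vec g = arma::tanh(uc);
  const vec o = sigmoid(uo);
  c = ig % c + (1.0 - ig) % g;
  const vec tc = arma::tanh(c);
  h = o % tc;
  if (ca) {
    ca->I.col(t) = ig;
    ca->G.col(t) = g;
    ca->O.col(t) = o;
    ca->C.col(t) = c;
    ca->TC.col(t) = tc;
    ca->H.col(t) = h;
  }
}

// Backward gate math at step t; consumes dh/dc (gradients on h_t, c_t) and
// leaves dh/dc holding the step's preactivation grads via out-params.
inline void cell_back(const Cache& ca, uword t, const vec& cprev, vec& dh,
                      vec& dc, vec& dui, vec& duc, vec& duo) {
  const vec tc = ca.TC.col(t);
  const vec o = ca.O.col(t);
  const vec ig = ca.I.col(t);
  const vec g = ca.G.col(t);
  duo = (dh % tc) % o % (1.0 - o);
  dc += dh % o % (1.0 - tc % tc);
  dui = (dc % (cprev - g)) % ig % (1.0 - ig);
  duc = (dc % (1.0 - ig)) % (1.0 - g % g);
  dc %= ig;  // gradient to c_{t-1}
}

// ---- dense-input LSTM (label layer) ----------------------------------------

void lstm_fwd(const mat& Z, const LstmW& P, Cache* ca, vec& h_last,
              mat* H_all) {
  const uword m = Z.n_cols, hid = P.hid, inp = P.inp;
  vec h(hid, arma::fill::zeros), c(hid, arma::fill::zeros);
  if (ca) ca->resize(hid, m);
  const auto Wxi = P.Wi.cols(0, inp - 1), Whi = P.Wi.cols(inp, inp + hid - 1);
  const auto Wxc = P.Wc.cols(0, inp - 1), Whc = P.Wc.cols(inp, inp + hid - 1);
  const auto Wxo = P.Wo.cols(0, inp - 1), Who = P.Wo.cols(inp, inp + hid - 1);
  for (uword t = 0; t < m; ++t) {
    const vec z = Z.col(t);
    cell_step(Wxi * z + Whi * h + P.bi, Wxc * z + Whc * h + P.bc,
              Wxo * z + Who * h + P.bo, h, c, ca, t);
    if (H_all) H_all->col(t) = h;
  }
  h_last = h;
}

void lstm_bwd(const LstmW& P, const Cache& ca, const mat& Z,
              const mat& dH_ext, LstmW& Gw, mat* dZ) {
  const uword m = ca.I.n_cols, hid = P.hid, inp = P.inp;
  vec dh(hid, arma::fill::zeros), dc(hid, arma::fill::zeros);
  vec dui, duc, duo;
  vec zh(inp + hid);
  for (uword t = m; t-- > 0;) {
    dh += dH_ext.col(t);
    const vec cprev =
        (t == 0) ? vec(hid, arma::fill::zeros) : vec(ca.C.col(t - 1));
    const vec hprev =
        (t == 0) ? vec(hid, arma::fill::zeros) : vec(ca.H.col(t - 1));
    cell_back(ca, t, cprev, dh, dc, dui, duc, duo);
    zh.head(inp) = Z.col(t);
    zh.tail(hid) = hprev;
    Gw.Wi += dui * zh.t();
    Gw.Wc += duc * zh.t();
    Gw.Wo += duo * zh.t();
    Gw.bi += dui;
    Gw.bc += duc;
    Gw.bo += duo;
    const vec dzh = P.Wi.t() * dui + P.Wc.t() * duc + P.Wo.t() * duo;
    if (dZ) dZ->col(t) = dzh.head(inp);
    dh = dzh.tail(hid);
  }
}

// ---- one-hot-input LSTM (character layer, "last" output) -------------------

void lstm_fwd_oh(const uvec& codes, const LstmW& P, Cache* ca, vec& h_last) {
  const uword m = codes.n_elem, hid = P.hid, inp = P.inp;
  vec h(hid, arma::fill::zeros), c(hid, arma::fill::zeros);
  if (ca) ca->resize(hid, m);
  const auto Whi = P.Wi.cols(inp, inp + hid - 1);
  const auto Whc = P.Wc.cols(inp, inp + hid - 1);
  const auto Who = P.Wo.cols(inp, inp + hid - 1);
  for (uword t = 0; t < m; ++t) {
    const uword cd = codes[t];
    cell_step(P.Wi.col(cd) + Whi * h + P.bi, P.Wc.col(cd) + Whc * h + P.bc,
              P.Wo.col(cd) + Who * h + P.bo, h, c, ca, t);
  }
  h_last = h;
}

void lstm_bwd_oh(const uvec& codes, const LstmW& P, const Cache& ca,
                 const vec& dh_last, LstmW& Gw) {
  const uword m = ca.I.n_cols, hid = P.hid, inp = P.inp;
  vec dh = dh_last, dc(hid, arma::fill::zeros);
  vec dui, duc, duo;
  const auto Whi = P.Wi.cols(inp, inp + hid - 1);
  const auto Whc = P.Wc.cols(inp, inp + hid - 1);
  const auto Who = P.Wo.cols(inp, inp + hid - 1);
  for (uword t = m; t-- > 0;) {
    const uword cd = codes[t];
    const vec cprev =
        (t == 0) ? vec(hid, arma::fill::zeros) : vec(ca.C.col(t - 1));
    const vec hprev =
        (t == 0) ? vec(hid, arma::fill::zeros) : vec(ca.H.col(t - 1));
    cell_back(ca, t, cprev, dh, dc, dui, duc, duo);
    Gw.Wi.col(cd) += dui;
    Gw.Wc.col(cd) += duc;
    Gw.Wo.col(cd) += duo;
    Gw.Wi.cols(inp, inp + hid - 1) += dui * hprev.t();
    Gw.Wc.cols(inp, inp + hid - 1) += duc * hprev.t();
    Gw.Wo.cols(inp, inp + hid - 1) += duo * hprev.t();
    Gw.bi += dui;
    Gw.bc += duc;
    Gw.bo += duo;
    dh = Whi.t() * dui + Whc.t() * duc + Who.t() * duo;
  }
}

size_t lstm_size(uword hid, uword inp) {
  return 3 * hid * (inp + hid) + 3 * hid;
}

}  // namespace

// [[Rcpp::export]]
List cpp_tagger_run(const arma::mat& X, const List& char_codes,
                    NumericVector p, int word_dim, int char_dim,
                    int char_hidden, int label_hidden, int ff_hidden,
                    int n_labels, Nullable<NumericMatrix> dropout_mask_,
                    Nullable<IntegerVector> gold_, bool want_grad,
                    bool want_states) {
  const uword n = X.n_rows;
  const uword wd = word_dim, cd = char_dim, ch = char_hidden;
  const uword lh = label_hidden, fh = ff_hidden, nl = n_labels;
  const uword ed = wd + 2 * ch;
  if (static_cast<uword>(char_codes.size()) != n)
    stop("char_codes length does not match the number of tokens");
  if (n == 0) stop("empty token sequence");

  const size_t expected = 2 * lstm_size(ch, cd) + 2 * lstm_size(lh, ed) +
                          fh * 2 * lh + fh + nl * fh + nl;
  if (static_cast<size_t>(p.size()) != expected)
    stop("parameter vector has length %d, expected %d", (int)p.size(),
         (int)expected);

  double* base = REAL(p);
  size_t off = 0;
  LstmW cf = make_view(base, off, ch, cd);
  LstmW cb = make_view(base, off, ch, cd);
  LstmW lf = make_view(base, off, lh, ed);
  LstmW lb = make_view(base, off, lh, ed);
  mat W1(base + off, fh, 2 * lh, false, true); off += fh * 2 * lh;
  vec b1(base + off, fh, false, true); off += fh;
  mat W2(base + off, nl, fh, false, true); off += nl * fh;
  vec b2(base + off, nl, false, true); off += nl;

  // ---- character-enhanced token embeddings -------------------------------
  mat E(ed, n);
  std::vector<Cache> cfc(want_grad ? n : 0), cbc(want_grad ? n : 0);
  std::vector<uvec> fwd_codes(n), bwd_codes(n);
  for (uword i = 0; i < n; ++i) {
    IntegerVector codes = char_codes[i];
    const uword m = codes.size();
    if (m == 0) stop("token %d has no characters", (int)(i + 1));
    uvec cv(m);
    for (uword j = 0; j < m; ++j) {
      const int cj = codes[j];
      if (cj < 0 || cj >= (int)cd) stop("character code out of range");
      cv[j] = cj;
    }
    fwd_codes[i] = cv;
    bwd_codes[i] = arma::reverse(cv);
    vec hf, hb;
    lstm_fwd_oh(fwd_codes[i], cf, want_grad ? &cfc[i] : nullptr, hf);
    lstm_fwd_oh(bwd_codes[i], cb, want_grad ? &cbc[i] : nullptr, hb);
    E.col(i).subvec(0, wd - 1) = X.row(i).t();
    E.col(i).subvec(wd, wd + ch - 1) = hf;
    E.col(i).subvec(wd + ch, ed - 1) = hb;
  }

  // ---- dropout (inverted; mask already scaled by 1/keep) -----------------
  mat Ed;
  mat M;
  bool has_mask = dropout_mask_.isNotNull();
  if (has_mask) {
    M = as<mat>(dropout_mask_.get());
    if (M.n_rows != ed || M.n_cols != n)
      stop("dropout mask must be e_dim x n_tokens");
    Ed = E % M;
  } else {
    Ed = E;
  }

  // ---- label bi-LSTM (full sequence) -------------------------------------
  mat Hf(lh, n), Hb(lh, n);
  Cache lfc, lbc;
  vec dummy;
  lstm_fwd(Ed, lf, want_grad ? &lfc : nullptr, dummy, &Hf);
  const mat Edr = arma::fliplr(Ed);
  lstm_fwd(Edr, lb, want_grad ? &lbc : nullptr, dummy, &Hb);
  mat D(2 * lh, n);
  D.rows(0, lh - 1) = Hf;
  D.rows(lh, 2 * lh - 1) = arma::fliplr(Hb);

  // ---- feedforward label prediction --------------------------------------
  mat U1 = W1 * D;
  U1.each_col() += b1;
  const mat L = arma::tanh(U1);
  mat S = W2 * L;
  S.each_col() += b2;
  mat A(nl, n);
  for (uword i = 0; i < n; ++i) {
    vec s = S.col(i);
    s -= s.max();  // overflow-safe softmax
    s = arma::exp(s);
    A.col(i) = s / arma::accu(s);
  }

  List out;
  out["probabilities"] = wrap(mat(A.t()));
  if (want_states) {
    out["embeddings"] = wrap(mat(E.t()));
    out["label_states"] = wrap(mat(D.t()));
  }

  bool has_gold = gold_.isNotNull();
  IntegerVector gold;
  if (has_gold) {
    gold = gold_.get();
    if (static_cast<uword>(gold.size()) != n)
      stop("gold label vector length mismatch");
    double loss = 0.0;
    for (uword i = 0; i < n; ++i) {
      const int gi = gold[i];
      if (gi < 0 || gi >= (int)nl) stop("gold label index out of range");
      loss -= std::log(A(gi, i));
    }
    out["loss"] = loss;
  }

  if (want_grad) {
    if (!has_gold) stop("gradient requires gold labels");
    NumericVector gvec(p.size());
    double* gbase = REAL(gvec);
    size_t goff = 0;
    LstmW gcf = make_view(gbase, goff, ch, cd);
    LstmW gcb = make_view(gbase, goff, ch, cd);
    LstmW glf = make_view(gbase, goff, lh, ed);
    LstmW glb = make_view(gbase, goff, lh, ed);
    mat gW1(gbase + goff, fh, 2 * lh, false, true); goff += fh * 2 * lh;
    vec gb1(gbase + goff, fh, false, true); goff += fh;
    mat gW2(gbase + goff, nl, fh, false, true); goff += nl * fh;
    vec gb2(gbase + goff, nl, false, true); goff += nl;

    mat dS = A;
    for (uword i = 0; i < n; ++i) dS(gold[i], i) -= 1.0;
    gW2 += dS * L.t();
    gb2 += arma::sum(dS, 1);
    const mat dU1 = (W2.t() * dS) % (1.0 - L % L);
    gW1 += dU1 * D.t();
    gb1 += arma::sum(dU1, 1);
    const mat dD = W1.t() * dU1;

    mat dZf(ed, n), dZb(ed, n);
    lstm_bwd(lf, lfc, Ed, dD.rows(0, lh - 1), glf, &dZf);
    lstm_bwd(lb, lbc, Edr, arma::fliplr(dD.rows(lh, 2 * lh - 1)), glb, &dZb);
    mat dE = dZf + arma::fliplr(dZb);
    if (has_mask) dE %= M;

    for (uword i = 0; i < n; ++i) {
      lstm_bwd_oh(fwd_codes[i], cf, cfc[i],
                  dE.col(i).subvec(wd, wd + ch - 1), gcf);
      lstm_bwd_oh(bwd_codes[i], cb, cbc[i],
                  dE.col(i).subvec(wd + ch, ed - 1), gcb);
    }
    out["gradient"] = gvec;
  }

  return out;
}

// Single coupled-gate LSTM step on raw matrices (reference entry point used
// by lstm_step(); the training path goes through cpp_tagger_run).
// [[Rcpp::export]]
List cpp_lstm_step(const arma::vec& z, const arma::vec& h_prev,
                   const arma::vec& c_prev, const arma::mat& Wi,
                   const arma::mat& Wc, const arma::mat& Wo,
                   const arma::vec& bi, const arma::vec& bc,
                   const arma::vec& bo) {
  const vec zh = arma::join_cols(z, h_prev);
  const vec ig = sigmoid(Wi * zh + bi + 1.0);
  const vec g = arma::tanh(Wc * zh + bc);
  const vec o = sigmoid(Wo * zh + bo);
  const vec c = ig % c_prev + (1.0 - ig) % g;
  const vec h = o % arma::tanh(c);
  return List::create(_["h"] = h, _["c"] = c);
}
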