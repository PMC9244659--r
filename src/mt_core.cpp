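// Fast inner loops of the multitask attention-GRU: fused forward pass and
// backpropagation through time. Mirrors the reference R implementation
// (R/rnn_core.R) exactly; the R version remains the oracle in the tests.
//
// Input projections, attention maps and their gradients are computed as
// single time-stacked GEMMs ((T*B) x d matrices); only the recurrent
// h_{t-1} -> h_t products run sequentially.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;
using arma::span;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }
static inline mat prelu(const mat& x, double a) {
  return arma::max(x, arma::zeros<mat>(arma::size(x))) +
         a * arma::min(x, arma::zeros<mat>(arma::size(x)));
}
static inline mat prelu_grad(const mat& x, double a) {
  return arma::conv_to<mat>::from(x > 0) +
         a * arma::conv_to<mat>::from(x <= 0);
}

struct GruLayer {
  mat Wz, Wr, Wn, Uz, Ur, Un;
  rowvec bz, br, bn;
};

struct Params {
  rowvec a, b, mu, ls;
  std::vector<GruLayer> gru;
  mat Wb, Wa;
  vec K;
  double alpha_att;
  mat W1, W2;
  rowvec b1, b2;
  double alpha_fc;
};

static Params unpack(const List& p) {
  Params P;
  List norm = p["norm"];
  P.a = as<rowvec>(norm["a"]);
  P.b = as<rowvec>(norm["b"]);
  P.mu = as<rowvec>(norm["mu"]);
  P.ls = as<rowvec>(norm["ls"]);
  List gru = p["gru"];
  for (int l = 0; l < gru.size(); ++l) {
    List g = gru[l];
    GruLayer G;
    G.Wz = as<mat>(g["Wz"]); G.Wr = as<mat>(g["Wr"]); G.Wn = as<mat>(g["Wn"]);
    G.Uz = as<mat>(g["Uz"]); G.Ur = as<mat>(g["Ur"]); G.Un = as<mat>(g["Un"]);
    G.bz = as<rowvec>(g["bz"]); G.br = as<rowvec>(g["br"]);
    G.bn = as<rowvec>(g["bn"]);
    P.gru.push_back(G);
  }
  List at = p["attn"];
  P.Wb = as<mat>(at["Wb"]); P.Wa = as<mat>(at["Wa"]); P.K = as<vec>(at["K"]);
  P.alpha_att = as<double>(at["alpha"]);
  List fc = p["fc"];
  P.W1 = as<mat>(fc["W1"]); P.W2 = as<mat>(fc["W2"]);
  P.b1 = as<rowvec>(fc["b1"]); P.b2 = as<rowvec>(fc["b2"]);
  P.alpha_fc = as<double>(fc["alpha"]);
  return P;
}

// Time-stacked layout: a (T*B) x d matrix whose row block t covers rows
// [t*B, (t+1)*B).
struct Cache {
  int B, T, L, H;
  mat Xr, Xn;                 // (T*B) x D
  std::vector<mat> h, z, r, n, g;  // per layer, (T*B) x H stacked
  mat Uall, V, Pp, Tt;        // attention, (T*B) x *
  mat S, Wt, C, O, E1, E, logits;
};

static void forward_pass(const Params& P, const cube& X, Cache& c) {
  const int B = X.n_rows, D = X.n_cols, T = X.n_slices;
  const int L = P.gru.size();
  const int H = P.gru[0].Uz.n_rows;
  c.B = B; c.T = T; c.L = L; c.H = H;

  c.Xr.set_size(T * B, D);
  for (int t = 0; t < T; ++t) c.Xr.rows(t * B, t * B + B - 1) = X.slice(t);
  rowvec sig = arma::exp(P.ls);
  c.Xn = c.Xr;
  c.Xn.each_row() -= P.mu;
  c.Xn.each_row() %= (P.a / sig);
  c.Xn.each_row() += P.b;

  c.h.assign(L, mat()); c.z.assign(L, mat()); c.r.assign(L, mat());
  c.n.assign(L, mat()); c.g.assign(L, mat());
  const mat* inp = &c.Xn;
  for (int l = 0; l < L; ++l) {
    const GruLayer& G = P.gru[l];
    // one big GEMM per gate for the input projections
    mat Az = (*inp) * G.Wz.t(); Az.each_row() += G.bz;
    mat Ar = (*inp) * G.Wr.t(); Ar.each_row() += G.br;
    mat An = (*inp) * G.Wn.t(); An.each_row() += G.bn;
    mat hs(T * B, H), zs(T * B, H), rs(T * B, H), ns(T * B, H), gs(T * B, H);
    mat h_prev(B, H, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      span rows(t * B, t * B + B - 1);
      mat z = sigm(Az.rows(rows) + h_prev * G.Uz.t());
      mat r = sigm(Ar.rows(rows) + h_prev * G.Ur.t());
      mat gg = h_prev * G.Un.t();
      mat n = arma::tanh(An.rows(rows) + r % gg);
      mat h = (1.0 - z) % n + z % h_prev;
      zs.rows(rows) = z; rs.rows(rows) = r; ns.rows(rows) = n;
      gs.rows(rows) = gg; hs.rows(rows) = h;
      h_prev = std::move(h);
    }
    c.z[l] = std::move(zs); c.r[l] = std::move(rs); c.n[l] = std::move(ns);
    c.g[l] = std::move(gs); c.h[l] = std::move(hs);
    inp = &c.h[l];
  }

  const mat& Htop = c.h[L - 1];
  mat hN = Htop.rows((T - 1) * B, T * B - 1);
  c.Uall.set_size(T * B, 2 * H);
  c.Uall.cols(H, 2 * H - 1) = Htop;
  for (int t = 0; t < T; ++t)
    c.Uall.submat(t * B, 0, t * B + B - 1, H - 1) = hN;
  c.V = c.Uall * P.Wb.t();
  c.Pp = prelu(c.V, P.alpha_att);
  c.Tt = arma::tanh(c.Pp * P.Wa.t());
  vec s_all = c.Tt * P.K;                     // (T*B)
  c.S.set_size(B, T);
  for (int t = 0; t < T; ++t) c.S.col(t) = s_all.subvec(t * B, t * B + B - 1);
  mat Sm = c.S.each_col() - arma::max(c.S, 1);
  mat W = arma::exp(Sm);
  W.each_col() /= arma::sum(W, 1);
  c.Wt = W;
  mat C(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat Ht = Htop.rows(t * B, t * B + B - 1);
    C += Ht.each_col() % W.col(t);
  }
  c.C = C;
  c.O = arma::join_rows(C, hN);
  c.E1 = c.O * P.W1.t();
  c.E1.each_row() += P.b1;
  c.E = prelu(c.E1, P.alpha_fc);
  c.logits = c.E * P.W2.t();
  c.logits.each_row() += P.b2;
}

static List backward_pass(const Params& P, const Cache& c, const mat& dLg) {
  const int B = c.B, T = c.T, L = c.L, H = c.H;
  const mat& Htop = c.h[L - 1];
  mat hN = Htop.rows((T - 1) * B, T * B - 1);

  mat gW2 = dLg.t() * c.E;
  rowvec gb2 = arma::sum(dLg, 0);
  mat dE = dLg * P.W2;
  mat dE1 = dE % prelu_grad(c.E1, P.alpha_fc);
  double galpha_fc =
      arma::accu(dE % c.E1 % arma::conv_to<mat>::from(c.E1 <= 0));
  mat gW1 = dE1.t() * c.O;
  rowvec gb1 = arma::sum(dE1, 0);
  mat dO = dE1 * P.W1;
  mat dC = dO.cols(0, H - 1);
  mat dhN_acc = dO.cols(H, 2 * H - 1);

  mat dWt(B, T);
  for (int t = 0; t < T; ++t)
    dWt.col(t) = arma::sum(dC % Htop.rows(t * B, t * B + B - 1), 1);
  vec rowdot = arma::sum(dWt % c.Wt, 1);
  mat dS = c.Wt % (dWt.each_col() - rowdot);

  // attention backward, fully time-stacked
  vec ds_all(T * B);
  for (int t = 0; t < T; ++t) ds_all.subvec(t * B, t * B + B - 1) = dS.col(t);
  vec gK = c.Tt.t() * ds_all;
  mat dT = ds_all * P.K.t();
  mat dQ = dT % (1.0 - c.Tt % c.Tt);
  mat gWa = dQ.t() * c.Pp;
  mat dP = dQ * P.Wa;
  mat dV = dP % prelu_grad(c.V, P.alpha_att);
  double galpha_att =
      arma::accu(dP % c.V % arma::conv_to<mat>::from(c.V <= 0));
  mat gWb = dV.t() * c.Uall;
  mat dU = dV * P.Wb;
  mat dHtop(T * B, H);
  for (int t = 0; t < T; ++t) {
    span rows(t * B, t * B + B - 1);
    dhN_acc += dU.submat(t * B, 0, t * B + B - 1, H - 1);
    dHtop.rows(rows) =
        dC.each_col() % c.Wt.col(t) + dU.submat(t * B, H, t * B + B - 1,
                                                2 * H - 1);
  }
  dHtop.rows((T - 1) * B, T * B - 1) += dhN_acc;

  List g_gru(L);
  mat dOut = std::move(dHtop);
  for (int l = L - 1; l >= 0; --l) {
    const GruLayer& G = P.gru[l];
    const mat& inp = (l == 0) ? c.Xn : c.h[l - 1];
    mat Daz(T * B, H), Dar(T * B, H), Dan(T * B, H);
    mat gUz(H, H, arma::fill::zeros), gUr(H, H, arma::fill::zeros),
        gUn(H, H, arma::fill::zeros);
    mat dh_next(B, H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      span rows(t * B, t * B + B - 1);
      mat dh = dOut.rows(rows) + dh_next;
      mat z = c.z[l].rows(rows);
      mat r = c.r[l].rows(rows);
      mat n = c.n[l].rows(rows);
      mat gg = c.g[l].rows(rows);
      mat h_prev = (t > 0) ? c.h[l].rows((t - 1) * B, t * B - 1)
                           : mat(B, H, arma::fill::zeros);
      mat dz = dh % (h_prev - n);
      mat dn = dh % (1.0 - z);
      mat dh_prev = dh % z;
      mat dan = dn % (1.0 - n % n);
      mat dgg = dan % r;
      mat dr = dan % gg;
      dh_prev += dgg * G.Un;
      gUn += dgg.t() * h_prev;
      mat daz = dz % z % (1.0 - z);
      mat dar = dr % r % (1.0 - r);
      gUz += daz.t() * h_prev;
      gUr += dar.t() * h_prev;
      dh_prev += daz * G.Uz + dar * G.Ur;
      Daz.rows(rows) = std::move(daz);
      Dar.rows(rows) = std::move(dar);
      Dan.rows(rows) = std::move(dan);
      dh_next = std::move(dh_prev);
    }
    // input-side gradients as single stacked GEMMs
    mat gWz = Daz.t() * inp;
    mat gWr = Dar.t() * inp;
    mat gWn = Dan.t() * inp;
    rowvec gbz = arma::sum(Daz, 0);
    rowvec gbr = arma::sum(Dar, 0);
    rowvec gbn = arma::sum(Dan, 0);
    dOut = Daz * G.Wz + Dar * G.Wr + Dan * G.Wn;
    g_gru[l] = List::create(
        Named("Wz") = gWz, Named("Wr") = gWr, Named("Wn") = gWn,
        Named("Uz") = gUz, Named("Ur") = gUr, Named("Un") = gUn,
        Named("bz") = arma::conv_to<vec>::from(gbz),
        Named("br") = arma::conv_to<vec>::from(gbr),
        Named("bn") = arma::conv_to<vec>::from(gbn));
  }

  rowvec sig = arma::exp(P.ls);
  mat xc = c.Xr;
  xc.each_row() -= P.mu;
  rowvec s1 = arma::sum(dOut % xc, 0);
  rowvec s0 = arma::sum(dOut, 0);
  rowvec da = s1 / sig;
  rowvec db = s0;
  rowvec dmu = -(s0 % P.a / sig);
  rowvec dls = -(s1 % P.a / sig);

  List norm = List::create(Named("a") = arma::conv_to<vec>::from(da),
                           Named("b") = arma::conv_to<vec>::from(db),
                           Named("mu") = arma::conv_to<vec>::from(dmu),
                           Named("ls") = arma::conv_to<vec>::from(dls));
  List attn = List::create(Named("Wb") = gWb, Named("Wa") = gWa,
                           Named("K") = gK, Named("alpha") = galpha_att);
  List fc = List::create(Named("W1") = gW1,
                         Named("b1") = arma::conv_to<vec>::from(gb1),
                         Named("W2") = gW2,
                         Named("b2") = arma::conv_to<vec>::from(gb2),
                         Named("alpha") = galpha_fc);
  return List::create(Named("norm") = norm, Named("gru") = g_gru,
                      Named("attn") = attn, Named("fc") = fc);
}

// [[Rcpp::export(name = ".aw_forward_cpp")]]
List aw_forward_cpp(List params, arma::cube X) {
  Params P = unpack(params);
  Cache c;
  forward_pass(P, X, c);
  const int B = c.B, T = c.T, L = c.L;
  return List::create(
      Named("logits") = c.logits,
      Named("probabilities") = sigm(c.logits),
      Named("attention_weights") = c.Wt,
      Named("context_vector") = c.C,
      Named("penultimate_embedding") = c.E,
      Named("last_hidden") = mat(c.h[L - 1].rows((T - 1) * B, T * B - 1)));
}

// [[Rcpp::export(name = ".aw_batch_grad_cpp")]]
List aw_batch_grad_cpp(List params, arma::cube X, arma::mat Y) {
  Params P = unpack(params);
  Cache c;
  forward_pass(P, X, c);
  const mat& lg = c.logits;
  mat sp = arma::max(lg, arma::zeros<mat>(arma::size(lg))) - lg % Y +
           arma::log1p(arma::exp(-arma::abs(lg)));
  double loss = arma::accu(sp) / lg.n_elem;
  mat dLg = (sigm(lg) - Y) / double(lg.n_elem);
  List grads = backward_pass(P, c, dLg);
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
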