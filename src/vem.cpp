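#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential (Gauss-Seidel) sweeps of the mean-field fixed point for the
// membership probabilities tau of a directed WSBM. Each row i is set to
// the exact maximiser of the variational objective over tau_i with all
// other rows held fixed:
//
//   log tau_iq = log theta_q
//     + sum_{j != i} sum_l tau_jl [ X_ij C1(q,l) + (1-X_ij) C2(q,l)
//                                   + L_ij C3(q,l) + Y_ij C4(q,l) ]   (out)
//     + sum_{j != i} sum_l tau_jl [ X_ji C1(l,q) + (1-X_ji) C2(l,q)
//                                   + L_ji C3(l,q) + Y_ji C4(l,q) ]   (in)
//
// with C1 = log pi + alpha log beta - lgamma(alpha), C2 = log(1 - pi),
// C3 = alpha - 1, C4 = -beta, and L = X o log Y (zero off the support).
// Rows are normalised by max-shifted softmax, floored at tau_floor and
// renormalised. damping > 0 blends the proposal with the previous row.
//
// Layout notes: tau is kept vertex-major (Q x n) internally; the
// non-edge terms use running column sums of tau, and pairs without an
// edge in either direction contribute only through those sums, so the
// inner loop touches edges only.
// [[Rcpp::export]]
List tau_sweep_cpp(const NumericMatrix X, const NumericMatrix Y,
                   const NumericMatrix L, const NumericMatrix tau,
                   const NumericVector log_theta,
                   const NumericMatrix C1, const NumericMatrix C2,
                   const NumericMatrix C3, const NumericMatrix C4,
                   const double damping, const int max_sweeps,
                   const double tol, const double tau_floor)
{
  const int n = X.nrow();
  const int Q = tau.ncol();

  // vertex-major copy of tau and its column sums
  std::vector<double> tt((size_t) n * Q);
  std::vector<double> cs(Q, 0.0);
  for (int j = 0; j < n; ++j)
    for (int l = 0; l < Q; ++l) {
      const double v = tau(j, l);
      tt[(size_t) j * Q + l] = v;
      cs[l] += v;
    }

  // transposes so that both edge directions of vertex i are contiguous
  std::vector<double> Xt((size_t) n * n), Yt((size_t) n * n), Lt((size_t) n * n);
  const double *Xp = X.begin(), *Yp = Y.begin(), *Lp = L.begin();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      Xt[(size_t) i * n + j] = Xp[(size_t) j * n + i];
      Yt[(size_t) i * n + j] = Yp[(size_t) j * n + i];
      Lt[(size_t) i * n + j] = Lp[(size_t) j * n + i];
    }

  std::vector<double> sxo(Q), slo(Q), syo(Q), sxi(Q), sli(Q), syi(Q), s(Q);
  double delta = 0.0;
  int sweeps = 0;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    delta = 0.0;
    for (int i = 0; i < n; ++i) {
      std::fill(sxo.begin(), sxo.end(), 0.0);
      std::fill(slo.begin(), slo.end(), 0.0);
      std::fill(syo.begin(), syo.end(), 0.0);
      std::fill(sxi.begin(), sxi.end(), 0.0);
      std::fill(sli.begin(), sli.end(), 0.0);
      std::fill(syi.begin(), syi.end(), 0.0);
      // outgoing edges of i: X(i, .) is column i of Xt; incoming: column i of X
      const double *xo = &Xt[(size_t) i * n], *yo = &Yt[(size_t) i * n],
                   *lo = &Lt[(size_t) i * n];
      const double *xi = Xp + (size_t) i * n, *yi = Yp + (size_t) i * n,
                   *li = Lp + (size_t) i * n;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double *tj = &tt[(size_t) j * Q];
        if (xo[j] != 0.0) {
          const double yv = yo[j], lv = lo[j];
          for (int l = 0; l < Q; ++l) {
            sxo[l] += tj[l]; slo[l] += lv * tj[l]; syo[l] += yv * tj[l];
          }
        }
        if (xi[j] != 0.0) {
          const double yv = yi[j], lv = li[j];
          for (int l = 0; l < Q; ++l) {
            sxi[l] += tj[l]; sli[l] += lv * tj[l]; syi[l] += yv * tj[l];
          }
        }
      }
      double *ti = &tt[(size_t) i * Q];
      double smax = -HUGE_VAL;
      for (int q = 0; q < Q; ++q) {
        double v = log_theta[q];
        for (int l = 0; l < Q; ++l) {
          const double rest = cs[l] - ti[l];           // sum_{j != i} tau_jl
          const double sno = rest - sxo[l];            // non-edges, outgoing
          const double sni = rest - sxi[l];            // non-edges, incoming
          v += sxo[l] * C1(q, l) + sno * C2(q, l)
             + slo[l] * C3(q, l) + syo[l] * C4(q, l)
             + sxi[l] * C1(l, q) + sni * C2(l, q)
             + sli[l] * C3(l, q) + syi[l] * C4(l, q);
        }
        if (!R_finite(v))
          stop("non-finite log-weight in tau update at vertex %d, block %d",
               i + 1, q + 1);
        s[q] = v;
        if (v > smax) smax = v;
      }
      double tot = 0.0;
      for (int q = 0; q < Q; ++q) { s[q] = std::exp(s[q] - smax); tot += s[q]; }
      double tot2 = 0.0;
      for (int q = 0; q < Q; ++q) {
        double v = s[q] / tot;
        if (damping > 0.0) v = (1.0 - damping) * v + damping * ti[q];
        if (v < tau_floor) v = tau_floor;
        s[q] = v; tot2 += v;
      }
      for (int q = 0; q < Q; ++q) {
        const double v = s[q] / tot2;
        const double d = std::fabs(v - ti[q]);
        if (d > delta) delta = d;
        cs[q] += v - ti[q];
        ti[q] = v;
      }
    }
    ++sweeps;
    if (delta < tol) break;
  }

  NumericMatrix out(n, Q);
  for (int j = 0; j < n; ++j)
    for (int l = 0; l < Q; ++l) out(j, l) = tt[(size_t) j * Q + l];
  return List::create(_["tau"] = out, _["sweeps"] = sweeps, _["delta"] = delta);
}
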