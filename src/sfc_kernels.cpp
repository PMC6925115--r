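// Batched per-location complex tensor contractions for the SFC layer.
// Layouts (column-major): x [P, S, Fin], w [P, Fin, Fout], g [P, S, Fout]
// with P the product of the independent axes, S the shared/batch block and
// Fin/Fout the contracted blocks. These are the hot loops of training; the
// split-real gradient identities are
//   gx = conj(W)^T g   and   gw = g conj(x)^T (summed over S).

#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

typedef std::complex<double> cplx;

// [[Rcpp::export]]
ComplexVector sfc_contract_fwd(const ComplexVector& x,
                               const ComplexVector& w,
                               int P, int S, int Fin, int Fout) {
  ComplexVector out(static_cast<R_xlen_t>(P) * S * Fout);
  const cplx* xp = reinterpret_cast<const cplx*>(&x[0]);
  const cplx* wp = reinterpret_cast<const cplx*>(&w[0]);
  cplx* op = reinterpret_cast<cplx*>(&out[0]);
  for (int fo = 0; fo < Fout; ++fo)
    for (int fi = 0; fi < Fin; ++fi) {
      const cplx* wv = wp + (static_cast<R_xlen_t>(fo) * Fin + fi) * P;
      for (int s = 0; s < S; ++s) {
        const cplx* xv = xp + (static_cast<R_xlen_t>(fi) * S + s) * P;
        cplx* ov = op + (static_cast<R_xlen_t>(fo) * S + s) * P;
        for (int p = 0; p < P; ++p) ov[p] += xv[p] * wv[p];
      }
    }
  return out;
}

// [[Rcpp::export]]
ComplexVector sfc_contract_gx(const ComplexVector& g,
                              const ComplexVector& w,
                              int P, int S, int Fin, int Fout) {
  ComplexVector gx(static_cast<R_xlen_t>(P) * S * Fin);
  const cplx* gp = reinterpret_cast<const cplx*>(&g[0]);
  const cplx* wp = reinterpret_cast<const cplx*>(&w[0]);
  cplx* op = reinterpret_cast<cplx*>(&gx[0]);
  for (int fi = 0; fi < Fin; ++fi)
    for (int fo = 0; fo < Fout; ++fo) {
      const cplx* wv = wp + (static_cast<R_xlen_t>(fo) * Fin + fi) * P;
      for (int s = 0; s < S; ++s) {
        const cplx* gv = gp + (static_cast<R_xlen_t>(fo) * S + s) * P;
        cplx* ov = op + (static_cast<R_xlen_t>(fi) * S + s) * P;
        for (int p = 0; p < P; ++p) ov[p] += gv[p] * std::conj(wv[p]);
      }
    }
  return gx;
}

// [[Rcpp::export]]
ComplexVector sfc_contract_gw(const ComplexVector& x,
                              const ComplexVector& g,
                              int P, int S, int Fin, int Fout) {
  ComplexVector gw(static_cast<R_xlen_t>(P) * Fin * Fout);
  const cplx* xp = reinterpret_cast<const cplx*>(&x[0]);
  const cplx* gp = reinterpret_cast<const cplx*>(&g[0]);
  cplx* op = reinterpret_cast<cplx*>(&gw[0]);
  for (int fo = 0; fo < Fout; ++fo)
    for (int fi = 0; fi < Fin; ++fi) {
      cplx* ov = op + (static_cast<R_xlen_t>(fo) * Fin + fi) * P;
      for (int s = 0; s < S; ++s) {
        const cplx* xv = xp + (static_cast<R_xlen_t>(fi) * S + s) * P;
        const cplx* gv = gp + (static_cast<R_xlen_t>(fo) * S + s) * P;
        for (int p = 0; p < P; ++p) ov[p] += std::conj(xv[p]) * gv[p];
      }
    }
  return gw;
}

// Fused Adam update on split real/imaginary parts. Returns the updated
// weights; the moment buffers m and v are updated in place (they are
// owned exclusively by the optimizer state). v packs the two second
// moments as a complex pair.
// [[Rcpp::export]]
ComplexVector adam_update(const ComplexVector& w_in, ComplexVector m,
                          ComplexVector v, const ComplexVector& grad,
                          double lr, double b1, double b2,
                          double eps, double c1, double s2) {
  R_xlen_t nlen = w_in.size();
  ComplexVector w = clone(w_in);
  cplx* wp = reinterpret_cast<cplx*>(&w[0]);
  cplx* mp = reinterpret_cast<cplx*>(&m[0]);
  cplx* vp = reinterpret_cast<cplx*>(&v[0]);
  const cplx* gp = reinterpret_cast<const cplx*>(&grad[0]);
  const double k = lr / c1;
  for (R_xlen_t i = 0; i < nlen; ++i) {
    const double gr = gp[i].real(), gi = gp[i].imag();
    const double mr = b1 * mp[i].real() + (1 - b1) * gr;
    const double mi = b1 * mp[i].imag() + (1 - b1) * gi;
    const double vr = b2 * vp[i].real() + (1 - b2) * gr * gr;
    const double vi = b2 * vp[i].imag() + (1 - b2) * gi * gi;
    mp[i] = cplx(mr, mi);
    vp[i] = cplx(vr, vi);
    wp[i] -= cplx(k * mr / (std::sqrt(vr) / s2 + eps),
                  k * mi / (std::sqrt(vi) / s2 + eps));
  }
  return w;
}
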