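#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Axisymmetric total-Lagrangian assembly for 6-node (P2) triangles with
// affine geometry (straight edges, midside nodes at edge midpoints).
//
// Deformation-gradient components, in this fixed order:
//   0: F_rR = 1 + dur/dR   1: F_rZ = dur/dZ
//   2: F_zR = duz/dR       3: F_zZ = 1 + duz/dZ
//   4: F_tt = 1 + ur/R     (hoop)
// Symmetric material tensors (S, C, Sconst) use order {11, 22, 33, 12}.
//
// Material laws: 0 = compressible Neo-Hookean  S = mu (I - Cinv) + lam lnJ Cinv
//                1 = Saint Venant-Kirchhoff    S = lam tr(E) I + 2 mu E
// Quasi-linear viscoelasticity enters as S_tot = geff * S_law + Sconst with
// geff and Sconst supplied per element / quadrature point by the caller.

static const int IP[5] = {0, 0, 1, 1, 2}; // physical row index i of F-pair p
static const int JP[5] = {0, 1, 0, 1, 2}; // reference col index J of F-pair p

// [[Rcpp::export]]
List asm_core(IntegerMatrix conn, NumericVector u,
              NumericMatrix dNdR, NumericMatrix dNdZ, NumericMatrix Nmat,
              NumericVector Rq, NumericVector wq,
              IntegerVector law_e, NumericVector lam_e, NumericVector mu_e,
              NumericVector geff_e, NumericMatrix Sconst,
              bool want_K, bool want_qp) {
  const int nel = conn.nrow();
  const int nqp = dNdR.nrow();
  const int nq  = nqp / nel;
  const int ndof = u.size();

  NumericVector fint(ndof);
  double minJ = R_PosInf;

  // element tangents are returned as values only; the (constant) sparsity
  // pattern in element-major, row-major-block order is rebuilt by the caller
  NumericVector Kx;
  if (want_K) Kx = NumericVector(nel * 144);
  NumericMatrix Fq, Sq, Seq;
  if (want_qp) {
    Fq  = NumericMatrix(nqp, 5);
    Sq  = NumericMatrix(nqp, 4);
    Seq = NumericMatrix(nqp, 4);
  }

  double Ke[144], AG[60], G0[6], G1[6], G4[6];

  for (int e = 0; e < nel; ++e) {
    double ur[6], uz[6];
    int dofs[12];
    for (int a = 0; a < 6; ++a) {
      int n = conn(e, a);
      ur[a] = u[2 * n];
      uz[a] = u[2 * n + 1];
      dofs[2 * a]     = 2 * n;
      dofs[2 * a + 1] = 2 * n + 1;
    }
    if (want_K) std::fill(Ke, Ke + 144, 0.0);
    const int law = law_e[e];
    const double lam = lam_e[e], mu = mu_e[e], geff = geff_e[e];
    double felem[12] = {0};

    for (int q = 0; q < nq; ++q) {
      const int g = e * nq + q;
      double F11 = 1, F12 = 0, F21 = 0, F22 = 1, F33 = 1;
      const double R = Rq[g];
      for (int a = 0; a < 6; ++a) {
        const double dR = dNdR(g, a), dZ = dNdZ(g, a), Na = Nmat(g, a);
        F11 += dR * ur[a];  F12 += dZ * ur[a];
        F21 += dR * uz[a];  F22 += dZ * uz[a];
        F33 += Na * ur[a] / R;
        G0[a] = dR; G1[a] = dZ; G4[a] = Na / R;
      }
      const double J2 = F11 * F22 - F12 * F21;
      const double J  = J2 * F33;
      if (J < minJ) minJ = J;
      if (J <= 0.0) {
        return List::create(_["fint"] = fint, _["minJ"] = minJ,
                            _["ok"] = false);
      }
      // C = F^T F and its inverse (block 2x2 + hoop)
      const double C11 = F11 * F11 + F21 * F21;
      const double C22 = F12 * F12 + F22 * F22;
      const double C12 = F11 * F12 + F21 * F22;
      const double C33 = F33 * F33;
      const double dC2 = C11 * C22 - C12 * C12;
      const double Ci11 = C22 / dC2, Ci22 = C11 / dC2, Ci12 = -C12 / dC2;
      const double Ci33 = 1.0 / C33;

      // second Piola-Kirchhoff stress of the underlying elastic law
      double S11, S22, S33, S12, mufac = 0, lnJ = 0;
      if (law == 0) {
        lnJ = std::log(J);
        S11 = mu * (1 - Ci11) + lam * lnJ * Ci11;
        S22 = mu * (1 - Ci22) + lam * lnJ * Ci22;
        S33 = mu * (1 - Ci33) + lam * lnJ * Ci33;
        S12 = (lam * lnJ - mu) * Ci12;
        mufac = mu - lam * lnJ;
      } else {
        const double E11 = 0.5 * (C11 - 1), E22 = 0.5 * (C22 - 1);
        const double E33 = 0.5 * (C33 - 1), E12 = 0.5 * C12;
        const double trE = E11 + E22 + E33;
        S11 = lam * trE + 2 * mu * E11;
        S22 = lam * trE + 2 * mu * E22;
        S33 = lam * trE + 2 * mu * E33;
        S12 = 2 * mu * E12;
      }
      // total stress (viscoelastic convolution state folded in by caller)
      const double T11 = geff * S11 + Sconst(g, 0);
      const double T22 = geff * S22 + Sconst(g, 1);
      const double T33 = geff * S33 + Sconst(g, 2);
      const double T12 = geff * S12 + Sconst(g, 3);

      if (want_qp) {
        Fq(g, 0) = F11; Fq(g, 1) = F12; Fq(g, 2) = F21;
        Fq(g, 3) = F22; Fq(g, 4) = F33;
        Sq(g, 0) = T11; Sq(g, 1) = T22; Sq(g, 2) = T33; Sq(g, 3) = T12;
        Seq(g, 0) = S11; Seq(g, 1) = S22; Seq(g, 2) = S33; Seq(g, 3) = S12;
      }

      // first Piola-Kirchhoff components (active pairs)
      const double P11 = F11 * T11 + F12 * T12;
      const double P12 = F11 * T12 + F12 * T22;
      const double P21 = F21 * T11 + F22 * T12;
      const double P22 = F21 * T12 + F22 * T22;
      const double P33 = F33 * T33;

      const double w = wq[g];
      for (int a = 0; a < 6; ++a) {
        felem[2 * a]     += w * (P11 * G0[a] + P12 * G1[a] + P33 * G4[a]);
        felem[2 * a + 1] += w * (P21 * G0[a] + P22 * G1[a]);
      }

      if (want_K) {
        double Fm[3][3] = {{F11, F12, 0}, {F21, F22, 0}, {0, 0, F33}};
        double St[3][3] = {{T11, T12, 0}, {T12, T22, 0}, {0, 0, T33}};
        double Ci[3][3] = {{Ci11, Ci12, 0}, {Ci12, Ci22, 0}, {0, 0, Ci33}};

        // material tangent (material frame), scaled by geff
        auto CC = [&](int M, int Jx, int P, int Q) -> double {
          double v;
          if (law == 0)
            v = lam * Ci[M][Jx] * Ci[P][Q] +
                mufac * (Ci[M][P] * Ci[Jx][Q] + Ci[M][Q] * Ci[Jx][P]);
          else
            v = lam * (M == Jx) * (P == Q) +
                mu * ((M == P) * (Jx == Q) + (M == Q) * (Jx == P));
          return geff * v;
        };

        double A[5][5];
        for (int p = 0; p < 5; ++p) {
          const int i = IP[p], Jx = JP[p];
          for (int qc = 0; qc < 5; ++qc) {
            const int k = IP[qc], L = JP[qc];
            double v = (i == k) ? St[L][Jx] : 0.0;
            for (int M = 0; M < 3; ++M) {
              const double FiM = Fm[i][M];
              if (FiM == 0) continue;
              for (int Q = 0; Q < 3; ++Q) {
                const double FkQ = Fm[k][Q];
                if (FkQ == 0) continue;
                v += FiM * CC(M, Jx, L, Q) * FkQ;
              }
            }
            A[p][qc] = v;
          }
        }
        // AG = A * G (G is 5 x 12, sparse by construction)
        for (int p = 0; p < 5; ++p)
          for (int a = 0; a < 6; ++a) {
            AG[p * 12 + 2 * a] =
                A[p][0] * G0[a] + A[p][1] * G1[a] + A[p][4] * G4[a];
            AG[p * 12 + 2 * a + 1] = A[p][2] * G0[a] + A[p][3] * G1[a];
          }
        // Ke += w * G^T * AG
        for (int a = 0; a < 6; ++a) {
          for (int c = 0; c < 12; ++c) {
            Ke[(2 * a) * 12 + c] +=
                w * (G0[a] * AG[0 * 12 + c] + G1[a] * AG[1 * 12 + c] +
                     G4[a] * AG[4 * 12 + c]);
            Ke[(2 * a + 1) * 12 + c] +=
                w * (G0[a] * AG[2 * 12 + c] + G1[a] * AG[3 * 12 + c]);
          }
        }
      }
    }

    for (int a = 0; a < 12; ++a) fint[dofs[a]] += felem[a];
    if (want_K) std::copy(Ke, Ke + 144, Kx.begin() + e * 144);
  }

  List out = List::create(_["fint"] = fint, _["minJ"] = minJ, _["ok"] = true);
  if (want_K) out["Kx"] = Kx;
  if (want_qp) {
    out["Fq"] = Fq; out["Sq"] = Sq; out["Seq"] = Seq;
  }
  return out;
}
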