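// Compiled element-residual kernel for the stabilized equal-order solver.
// Mirrors the R reference implementation (element_residual in solver.R)
// entry for entry; the R path remains available as engine = "r" and the
// two are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cof3(const double F[9], double H[9]) {
  H[0] = F[4] * F[8] - F[5] * F[7];
  H[1] = F[5] * F[6] - F[3] * F[8];
  H[2] = F[3] * F[7] - F[4] * F[6];
  H[3] = F[7] * F[2] - F[8] * F[1];
  H[4] = F[8] * F[0] - F[6] * F[2];
  H[5] = F[6] * F[1] - F[7] * F[0];
  H[6] = F[1] * F[5] - F[2] * F[4];
  H[7] = F[2] * F[3] - F[0] * F[5];
  H[8] = F[0] * F[4] - F[1] * F[3];
}

static inline double det3(const double F[9]) {
  return F[0] * (F[4] * F[8] - F[7] * F[5])
       - F[3] * (F[1] * F[8] - F[7] * F[2])
       + F[6] * (F[1] * F[5] - F[4] * F[2]);
}

// out = A^T A
static inline void ata(const double A[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[k + 3 * i] * A[k + 3 * j];
      C[i + 3 * j] = s;
    }
}

// out = A B
static inline void mul3(const double A[9], const double B[9], double C[9]) {
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[i + 3 * k] * B[k + 3 * j];
      C[i + 3 * j] = s;
    }
}

static inline void mv3(const double A[9], const double v[3], double out[3]) {
  for (int i = 0; i < 3; ++i)
    out[i] = A[i] * v[0] + A[i + 3] * v[1] + A[i + 6] * v[2];
}

static inline double ddot3(const double A[9], const double B[9]) {
  double s = 0;
  for (int k = 0; k < 9; ++k) s += A[k] * B[k];
  return s;
}

// [[Rcpp::export(name = "cpp_element_residual")]]
List cpp_element_residual(
    NumericMatrix Zl,        
    NumericMatrix Ustar_l,   
    NumericMatrix Vstar_l,   
    NumericMatrix Mstar_l,   
    NumericMatrix Gmat,      
    NumericVector Vvol,      
    NumericMatrix qL,        
    NumericVector qw,        
    NumericMatrix Mab,       
    double gdt, double tau, double t_new,
    int problem,             
    int d,
    int variant,             
    NumericVector matpar,    
    NumericMatrix f0,        
    NumericMatrix s0,        
    double active_T0,        
    double active_q,         
    double rho0s, double rho0, double rho0f,
    NumericMatrix b_cen,     
    
    int upv,                 
    NumericVector porepar,   
    NumericMatrix Kperm,     
    int src_mode,            
    NumericVector srcpar,    
    
    IntegerVector fol_owner, 
    IntegerMatrix fol_loc,   
    NumericVector fol_area,
    NumericMatrix fol_normal,  
    NumericVector fol_pmag,    
    double crel)
{
  const int E = Zl.nrow();
  const int nl = d + 1;
  const int nld = Zl.ncol();
  const int nq = qw.size();
  NumericMatrix Res(E, nld);
  std::vector<int> bad;

  const double G_ = matpar[0];
  const double Gf_ = matpar.size() > 1 ? matpar[1] : 0.0;
  // HO: a b af bf as bs afs bfs in matpar[0..7]

  const double pc_c = porepar.size() ? porepar[4] : 0.0;
  const double pc_eps = porepar.size() ? porepar[5] : 1e-3;
  const double pc_crit = porepar.size() ? porepar[6] : 1e-3;
  const double phi0 = porepar.size() ? porepar[7] : 0.0;

  for (int e = 0; e < E; ++e) {
    double Gr[4][3];  // shape gradients, embedded
    for (int a = 0; a < nl; ++a) {
      for (int j = 0; j < 3; ++j) Gr[a][j] = 0.0;
      for (int j = 0; j < d; ++j) Gr[a][j] = Gmat(e, a * d + j);
    }
    // velocities, displacements, accelerations (local, embedded 3-vectors)
    double vl[4][3], ul[4][3], vd[4][3];
    for (int a = 0; a < nl; ++a)
      for (int i = 0; i < 3; ++i) { vl[a][i] = 0; ul[a][i] = 0; vd[a][i] = 0; }
    for (int a = 0; a < nl; ++a)
      for (int i = 0; i < d; ++i) {
        const double v = Zl(e, a * d + i);
        vl[a][i] = v;
        ul[a][i] = Ustar_l(e, a * d + i) + gdt * v;
        vd[a][i] = (v - Vstar_l(e, a * d + i)) / gdt;
      }
    // F = I + grad u, Gv = grad v (embedded)
    double F[9], Gv[9];
    for (int k = 0; k < 9; ++k) { F[k] = 0; Gv[k] = 0; }
    F[0] = F[4] = F[8] = 1.0;
    for (int a = 0; a < nl; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          F[i + 3 * j] += ul[a][i] * Gr[a][j];
          Gv[i + 3 * j] += vl[a][i] * Gr[a][j];
        }
    const double J = det3(F);
    if (J <= 1e-12) { bad.push_back(e + 1); continue; }
    double H[9], C[9];
    cof3(F, H);
    ata(F, C);
    const double Jm23 = std::pow(J, -2.0 / 3.0);
    double Cbar[9];
    for (int k = 0; k < 9; ++k) Cbar[k] = Jm23 * C[k];
    const double I1b = Cbar[0] + Cbar[4] + Cbar[8];

    // Stil = 2 dW/dCbar
    double Stil[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    double fvec[3] = {0, 0, 0}, svec[3] = {0, 0, 0};
    double I4fb = 0, I4f_tot = 0;
    if (f0.nrow() == E) {
      for (int i = 0; i < 3; ++i) fvec[i] = f0(e, i);
      double Cf[3];
      mv3(Cbar, fvec, Cf);
      I4fb = fvec[0] * Cf[0] + fvec[1] * Cf[1] + fvec[2] * Cf[2];
      double Ctf[3];
      mv3(C, fvec, Ctf);
      I4f_tot = fvec[0] * Ctf[0] + fvec[1] * Ctf[1] + fvec[2] * Ctf[2];
    }
    switch (variant) {
    case 0:  // neo-Hookean
      Stil[0] = Stil[4] = Stil[8] = G_;
      break;
    case 1: {  // Mooney-Rivlin: 2(C1 + C2 I1b) I - 2 C2 Cbar
      const double c1 = matpar[0], c2 = matpar[1];
      for (int k = 0; k < 9; ++k) Stil[k] = -2.0 * c2 * Cbar[k];
      Stil[0] += 2.0 * (c1 + c2 * I1b);
      Stil[4] += 2.0 * (c1 + c2 * I1b);
      Stil[8] += 2.0 * (c1 + c2 * I1b);
      break;
    }
    case 2: {  // standard reinforced
      Stil[0] = Stil[4] = Stil[8] = G_;
      const double g = I4fb > 1.0 ? I4fb - 1.0 : 0.0;
      const double cfac = 2.0 * Gf_ * g;
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          Stil[i + 3 * j] += cfac * fvec[i] * fvec[j];
      break;
    }
    case 3: {  // Holzapfel-Ogden
      const double a_ = matpar[0], b_ = matpar[1], af_ = matpar[2],
                   bf_ = matpar[3], as_ = matpar[4], bs_ = matpar[5],
                   afs_ = matpar[6], bfs_ = matpar[7];
      const double iso = a_ * std::exp(b_ * (I1b - 3.0));
      Stil[0] = Stil[4] = Stil[8] = iso;
      for (int i = 0; i < 3; ++i) svec[i] = s0(e, i);
      double Cs[3];
      mv3(Cbar, svec, Cs);
      const double I4sb = svec[0] * Cs[0] + svec[1] * Cs[1] + svec[2] * Cs[2];
      double Cfb[3];
      mv3(Cbar, fvec, Cfb);
      const double I8 = fvec[0] * Cs[0] + fvec[1] * Cs[1] + fvec[2] * Cs[2];
      const double g4f = I4fb > 1.0 ? I4fb - 1.0 : 0.0;
      const double g4s = I4sb > 1.0 ? I4sb - 1.0 : 0.0;
      const double cf = 2.0 * af_ * g4f * std::exp(bf_ * g4f * g4f);
      const double cs = 2.0 * as_ * g4s * std::exp(bs_ * g4s * g4s);
      const double c8 = afs_ * I8 * std::exp(bfs_ * I8 * I8);
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          Stil[i + 3 * j] += cf * fvec[i] * fvec[j] + cs * svec[i] * svec[j]
            + c8 * (fvec[i] * svec[j] + svec[i] * fvec[j]);
      break;
    }
    }
    // S_iso = Jm23 (Stil - (Stil:Cbar)/3 Cbar^{-1}); det(Cbar) = 1
    double cofCb[9], Sdev[9];
    cof3(Cbar, cofCb);  // symmetric: cof = adj
    const double trSC = ddot3(Stil, Cbar);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i)
        Sdev[i + 3 * j] = Jm23 * (Stil[i + 3 * j]
                                  - trSC / 3.0 * cofCb[j + 3 * i]);
    // active deviatoric stress
    if (active_T0 >= 0.0 && f0.nrow() == E) {
      const double T = active_T0 * (1.0 + active_q * (I4f_tot - 1.0));
      double Sa[9];
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i) Sa[i + 3 * j] = T * fvec[i] * fvec[j];
      double cofC[9];
      cof3(C, cofC);
      const double SaC = ddot3(Sa, C);
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
          Sdev[i + 3 * j] += Sa[i + 3 * j]
            - SaC / 3.0 * cofC[j + 3 * i] / (J * J);
    }
    double Pdev[9];
    mul3(F, Sdev, Pdev);

    // pressures
    double pbar = 0;
    for (int a = 0; a < nl; ++a) pbar += Zl(e, nl * d + a);
    pbar /= nl;
    double gradp[3] = {0, 0, 0};
    for (int a = 0; a < nl; ++a)
      for (int j = 0; j < 3; ++j) gradp[j] += Zl(e, nl * d + a) * Gr[a][j];

    const double Ve = Vvol[e];
    // momentum: stress + pressure; hyper inertia via mass weights
    for (int a = 0; a < nl; ++a) {
      double PG[3], HG[3];
      mv3(Pdev, Gr[a], PG);
      mv3(H, Gr[a], HG);
      for (int i = 0; i < d; ++i) {
        double acc = Ve * (PG[i] - pbar * HG[i]);
        if (problem == 0) {
          double mvd = 0;
          for (int b = 0; b < nl; ++b) mvd += Mab(a, b) * vd[b][i];
          acc += Ve * rho0s * mvd;
        }
        Res(e, a * d + i) += acc;
      }
    }
    // continuity with fine-scale term (enters with a minus sign)
    const double HdotGv = ddot3(H, Gv);
    // Baumgarte relaxation of the volumetric constraint
    double cviol = 0.0;
    if (crel > 0.0) {
      cviol = J - 1.0;
      if (problem == 1)
        for (int a = 0; a < nl; ++a) cviol -= Zl(e, nl * d + nl + a) / nl;
    }
    double vdot_el[3] = {0, 0, 0};
    for (int a = 0; a < nl; ++a)
      for (int i = 0; i < 3; ++i) vdot_el[i] += vd[a][i] / nl;
    double Hgp[3];
    mv3(H, gradp, Hgp);
    double vpr[3];
    for (int i = 0; i < 3; ++i)
      vpr[i] = -tau * (vdot_el[i] + Hgp[i] / rho0s - b_cen(e, i));
    for (int a = 0; a < nl; ++a) {
      double HGa[3];
      mv3(H, Gr[a], HGa);
      Res(e, nl * d + a) += Ve / nl * (HdotGv + crel / gdt * cviol)
        - Ve * (vpr[0] * HGa[0] + vpr[1] * HGa[1] + vpr[2] * HGa[2]);
    }

    if (problem == 1) {
      // K0 = H^T K H / J (using H = J F^{-T})
      double KH[9], K0[9];
      double Km[9];
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i) Km[i + 3 * j] = Kperm(i, j);
      mul3(Km, H, KH);
      double Ht[9];
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i) Ht[i + 3 * j] = H[j + 3 * i];
      mul3(Ht, KH, K0);
      for (int k = 0; k < 9; ++k) K0[k] /= J;
      double gradmu[3] = {0, 0, 0};
      for (int a = 0; a < nl; ++a)
        for (int j = 0; j < 3; ++j)
          gradmu[j] += Zl(e, nl * d + nl + a) * Gr[a][j];
      double K0gp[3], K0gm[3];
      mv3(K0, gradp, K0gp);
      mv3(K0, gradmu, K0gm);
      double dpi_avg = 0;
      for (int q = 0; q < nq; ++q) {
        double mu_q = 0, mdot_q = 0, p_q = 0;
        double vdq[3] = {0, 0, 0};
        for (int a = 0; a < nl; ++a) {
          const double L = qL(q, a);
          const double m_a = Zl(e, nl * d + nl + a);
          mu_q += L * m_a;
          mdot_q += L * (m_a - Mstar_l(e, a)) / gdt;
          p_q += L * Zl(e, nl * d + a);
          for (int i = 0; i < d; ++i) vdq[i] += L * vd[a][i];
        }
        // pore pressures and d(pPV+pc)/dm
        double p_pv, dpv;
        if (upv == 0) {
          p_pv = porepar[0] * mu_q;
          dpv = porepar[0];
        } else {
          const double q1 = porepar[0], q2 = porepar[1], q3 = porepar[2];
          const double x = mu_q + phi0;
          p_pv = q1 * (std::exp(q3 * x) - std::exp(q3 * phi0))
               + q2 * std::log(q3 * x / phi0);
          dpv = q1 * q3 * std::exp(q3 * x) + q2 / x;
        }
        const double dd = mu_q + phi0 - pc_crit;
        const double den = pc_eps * pc_eps + dd * dd;
        const double p_c = pc_c * pc_eps * pc_eps / den;
        const double dpc = -2.0 * pc_c * pc_eps * pc_eps * dd / (den * den);
        // clamped: a negative d(pPV+pc)/dm (past the porosity floor)
        // would turn K0m into an antidiffusion
        dpi_avg += qw[q] * std::max(dpv + dpc, 0.0);
        double Sq = 0;
        if (src_mode >= 0) {
          const double ppore = p_q + p_pv + p_c;
          if (src_mode == 0)
            Sq = srcpar[0] * (srcpar[2] - ppore) - srcpar[1] * (ppore - srcpar[3]);
          else if (src_mode == 1)
            Sq = srcpar[0] * ppore;
          else
            Sq = -srcpar[1] * (ppore - srcpar[3]);
        }
        const double rho_q = rho0 + rho0f * mu_q;
        for (int a = 0; a < nl; ++a) {
          const double cN = qw[q] * qL(q, a) * Ve;
          for (int i = 0; i < d; ++i)
            Res(e, a * d + i) += cN * rho_q * vdq[i];
          Res(e, nl * d + a) -= cN * mdot_q;
          Res(e, nl * d + nl + a) += cN * (mdot_q - Sq);
        }
      }
      for (int a = 0; a < nl; ++a) {
        double s = 0;
        for (int j = 0; j < 3; ++j)
          s += Gr[a][j] * (K0gp[j] + dpi_avg * K0gm[j]);
        Res(e, nl * d + nl + a) += Ve * s;
      }
    }
  }

  // follower pressure facets
  const int B = fol_owner.size();
  for (int f = 0; f < B; ++f) {
    const double pmag = fol_pmag[f];
    if (pmag == 0.0) continue;
    const int e = fol_owner[f] - 1;
    // recompute H of the owner element
    double Gr[4][3];
    for (int a = 0; a < nl; ++a) {
      for (int j = 0; j < 3; ++j) Gr[a][j] = 0.0;
      for (int j = 0; j < d; ++j) Gr[a][j] = Gmat(e, a * d + j);
    }
    double F[9];
    for (int k = 0; k < 9; ++k) F[k] = 0;
    F[0] = F[4] = F[8] = 1.0;
    for (int a = 0; a < nl; ++a)
      for (int i = 0; i < d; ++i) {
        const double u = Ustar_l(e, a * d + i) + gdt * Zl(e, a * d + i);
        for (int j = 0; j < 3; ++j) F[i + 3 * j] += u * Gr[a][j];
      }
    double H[9];
    cof3(F, H);
    double n0[3] = {0, 0, 0};
    for (int j = 0; j < d; ++j) n0[j] = fol_normal(f, j);
    double Hn[3];
    mv3(H, n0, Hn);
    const double cA = fol_area[f] / d;
    for (int a = 0; a < d; ++a) {
      const int la = fol_loc(f, a) - 1;
      for (int i = 0; i < d; ++i)
        Res(e, la * d + i) += cA * pmag * Hn[i];
    }
  }

  return List::create(_["Res"] = Res,
                      _["bad"] = IntegerVector(bad.begin(), bad.end()));
}
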