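// Core of the reduced brain PBPK model: 13-state right-hand side, analytic
// Jacobian, and a stiff RODAS3 Rosenbrock integrator with step clipping onto
// a requested output grid.
//
// State order (0-based):
//   0 plasma, 1 lymph, 2 tissue_vasc, 3 tissue_endo_free, 4 tissue_endo_complex,
//   5 tissue_endo_FcRn, 6 tissue_isf, 7 brain_vasc, 8 csf_LV, 9 csf_TFV,
//   10 csf_CM, 11 csf_SAS, 12 brain_isf
// All states are amounts in nmol (FcRn species in nmol of receptor).
//
// Only the FcRn association term k_on * C_free * C_FcRn * V_endo is nonlinear;
// everything else is assembled once per call into a constant coefficient
// matrix A acting on amounts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const int NS = 13;

struct Pars {
  // physiological
  double Vp, Vly, Vtv, Vte, Vti, Vbv, Vbi, VLV, VTFV, VCM, VSAS;
  double Qt, Qb, Lt, Lb, Qcsf, Qisf;
  double sTV, sTL, sBISF, sCSF;
  double FcRnSS, FR, kup, kon, koff;
  // drug
  double sBBB, sBCSFB, sCI, kdeg;
};

static Pars unpack(const arma::vec& phys, const arma::vec& drug) {
  Pars p;
  p.Vp = phys[0];  p.Vly = phys[1];  p.Vtv = phys[2];  p.Vte = phys[3];
  p.Vti = phys[4]; p.Vbv = phys[5];  p.Vbi = phys[6];  p.VLV = phys[7];
  p.VTFV = phys[8]; p.VCM = phys[9]; p.VSAS = phys[10];
  p.Qt = phys[11]; p.Qb = phys[12]; p.Lt = phys[13]; p.Lb = phys[14];
  p.Qcsf = phys[15]; p.Qisf = phys[16];
  p.sTV = phys[17]; p.sTL = phys[18]; p.sBISF = phys[19]; p.sCSF = phys[20];
  p.FcRnSS = phys[21]; p.FR = phys[22]; p.kup = phys[23];
  p.kon = phys[24]; p.koff = phys[25];
  p.sBBB = drug[0]; p.sBCSFB = drug[1]; p.sCI = drug[2]; p.kdeg = drug[3];
  return p;
}

// Linear flux coefficient matrix on amounts: dA/dt = M A + bilinear(A) + inf.
static arma::mat linear_matrix(const Pars& p) {
  arma::mat A(NS, NS, arma::fill::zeros);
  // plasma <-> vascular spaces
  A(0, 0) -= (p.Qt + p.Qb) / p.Vp;
  A(2, 0) += p.Qt / p.Vp;
  A(7, 0) += p.Qb / p.Vp;
  // lymph -> plasma
  A(1, 1) -= (p.Lt + p.Lb) / p.Vly;
  A(0, 1) += (p.Lt + p.Lb) / p.Vly;
  // tissue vascular: return to plasma, paracellular convection, endosomal uptake
  double tv_out = (p.Qt - p.Lt) + (1.0 - p.sTV) * p.Lt + p.kup * p.Vte;
  A(0, 2) += (p.Qt - p.Lt) / p.Vtv;
  A(6, 2) += (1.0 - p.sTV) * p.Lt / p.Vtv;
  A(3, 2) += p.kup * p.Vte / p.Vtv;
  A(2, 2) -= tv_out / p.Vtv;
  // endosomal free drug: degradation (association is bilinear)
  A(3, 3) -= p.kdeg;
  // FcRn complex: dissociation and exocytosis at k_CLupT; receptor returned
  A(3, 4) += p.koff;
  A(5, 4) += p.koff + p.kup;
  A(2, 4) += p.FR * p.kup;
  A(6, 4) += (1.0 - p.FR) * p.kup;
  A(4, 4) -= p.koff + p.kup;
  // tissue ISF -> lymph
  A(1, 6) += (1.0 - p.sTL) * p.Lt / p.Vti;
  A(6, 6) -= (1.0 - p.sTL) * p.Lt / p.Vti;
  // brain vascular: return to plasma, BCSFB (split LV/TFV), BBB
  double bcsfb = (1.0 - p.sBCSFB) * p.Qcsf;
  double bbb   = (1.0 - p.sBBB) * p.Qisf;
  A(0, 7)  += (p.Qb - p.Lb) / p.Vbv;
  A(8, 7)  += 0.5 * bcsfb / p.Vbv;
  A(9, 7)  += 0.5 * bcsfb / p.Vbv;
  A(12, 7) += bbb / p.Vbv;
  A(7, 7)  -= ((p.Qb - p.Lb) + bcsfb + bbb) / p.Vbv;
  // CSF chain LV -> TFV -> CM -> SAS at the cumulated fluid flow
  double qhalf = 0.5 * (p.Qcsf + p.Qisf), qfull = p.Qcsf + p.Qisf;
  A(9, 8)  += qhalf / p.VLV;  A(8, 8)   -= qhalf / p.VLV;
  A(10, 9) += qfull / p.VTFV; A(9, 9)   -= qfull / p.VTFV;
  A(11, 10) += qfull / p.VCM; A(10, 10) -= qfull / p.VCM;
  // SAS: glymphatic transfer to brain ISF, drainage to lymph
  double glymph = (1.0 - p.sCI) * p.Qisf;
  double sas_ly = (1.0 - p.sCSF) * p.Qcsf;
  A(12, 11) += glymph / p.VSAS;
  A(1, 11)  += sas_ly / p.VSAS;
  A(11, 11) -= (glymph + sas_ly) / p.VSAS;
  // brain ISF efflux: total (1 - sigma_BISF) * Q_ISF, split between
  // ventricular recycling (LV, TFV) and lymphatic drainage
  double isf_out = (1.0 - p.sBISF) * p.Qisf;
  A(8, 12) += 0.25 * isf_out / p.Vbi;
  A(9, 12) += 0.25 * isf_out / p.Vbi;
  A(1, 12) += 0.50 * isf_out / p.Vbi;
  A(12, 12) -= isf_out / p.Vbi;
  return A;
}

// Full rhs: linear part + FcRn association + infusion.
static arma::vec rhs_vec(const arma::mat& A, const Pars& p,
                         const arma::vec& y, const arma::vec& inf) {
  arma::vec d = A * y + inf;
  double bind = p.kon * y[3] * y[5] / p.Vte;  // k_on * C_free * C_FcRn * V_endo
  d[3] -= bind;
  d[4] += bind;
  d[5] -= bind;
  return d;
}

// Jacobian = A + bilinear block (rows 3,4,5; cols 3,5).
static void fill_jacobian(arma::mat& J, const arma::mat& A, const Pars& p,
                          const arma::vec& y) {
  J = A;
  double d3 = p.kon * y[5] / p.Vte;  // d bind / d y3
  double d5 = p.kon * y[3] / p.Vte;  // d bind / d y5
  J(3, 3) -= d3; J(3, 5) -= d5;
  J(4, 3) += d3; J(4, 5) += d5;
  J(5, 3) -= d3; J(5, 5) -= d5;
}

// RODAS3: 4-stage, order 3(2), L-stable, stiffly accurate Rosenbrock method
// (coefficients as tabulated by Sandu et al. for atmospheric-chemistry
// integrators). Autonomous form; infusions are constant within a segment.
struct Rodas3 {
  static const int S = 4;
  double gamma = 0.5;
  double a31 = 2.0, a41 = 2.0, a43 = 1.0;              // other a_ij zero
  double c21 = 4.0, c31 = 1.0, c32 = -1.0;
  double c41 = 1.0, c42 = -1.0, c43 = -8.0 / 3.0;
  double m1 = 2.0, m2 = 0.0, m3 = 1.0, m4 = 1.0;
  double e4 = 1.0;                                      // error = e4 * K4
};

//' @noRd
// [[Rcpp::export(name = ".integrate_segment")]]
Rcpp::List integrate_segment(arma::vec y0, double t0, double t1,
                             arma::vec tout, arma::vec phys, arma::vec drug,
                             arma::vec inf, double rtol, double atol,
                             double hmax = 0.0, double h0 = 0.0) {
  const Pars p = unpack(phys, drug);
  const arma::mat A = linear_matrix(p);
  const Rodas3 tab;

  if (t1 <= t0) Rcpp::stop("integrate_segment: t1 must exceed t0");
  for (arma::uword i = 0; i < tout.n_elem; ++i)
    if (tout[i] < t0 - 1e-12 || tout[i] > t1 + 1e-12)
      Rcpp::stop("integrate_segment: output time outside segment");
  if (!y0.is_finite()) Rcpp::stop("integrate_segment: non-finite initial state");

  const double span = t1 - t0;
  if (hmax <= 0.0) hmax = span;
  double h = (h0 > 0.0) ? h0 : std::min(1e-4 * span, hmax);
  const double hmin = 16.0 * std::numeric_limits<double>::epsilon() *
                      std::max(std::abs(t0), std::abs(t1));

  arma::mat out(tout.n_elem, NS);
  arma::uword iout = 0;
  // output times at (or numerically before) t0
  while (iout < tout.n_elem && tout[iout] <= t0 + 1e-12) {
    out.row(iout) = y0.t();
    ++iout;
  }

  arma::vec y = y0;
  double t = t0;
  arma::mat J(NS, NS), G(NS, NS);
  arma::vec K1(NS), K2(NS), K3(NS), K4(NS), F(NS), rhs(NS), ynew(NS), yerr(NS);
  long nsteps = 0, nreject = 0;
  const long max_steps = 5000000;

  while (t < t1 - 1e-12) {
    if (++nsteps > max_steps)
      Rcpp::stop("integrate_segment: step limit exceeded (t = %g)", t);
    h = std::min(h, hmax);
    if (t + h > t1) h = t1 - t;
    // clip to the next output time so grid values are exact solver states
    if (iout < tout.n_elem && t + h > tout[iout] && tout[iout] > t + hmin)
      h = tout[iout] - t;

    bool accepted = false;
    while (!accepted) {
      if (h < hmin)
        Rcpp::stop("integrate_segment: step size underflow at t = %g", t);
      fill_jacobian(J, A, p, y);
      G = -J;
      G.diag() += 1.0 / (h * tab.gamma);
      arma::mat Ginv;
      if (!arma::inv(Ginv, G))
        Rcpp::stop("integrate_segment: singular Rosenbrock matrix at t = %g", t);

      F = rhs_vec(A, p, y, inf);
      K1 = Ginv * F;
      // stage 2: Y2 = y (a2j = 0)
      rhs = F + (tab.c21 / h) * K1;
      K2 = Ginv * rhs;
      // stage 3: Y3 = y + 2 K1
      F = rhs_vec(A, p, y + tab.a31 * K1, inf);
      rhs = F + (tab.c31 * K1 + tab.c32 * K2) / h;
      K3 = Ginv * rhs;
      // stage 4: Y4 = y + 2 K1 + K3
      F = rhs_vec(A, p, y + tab.a41 * K1 + tab.a43 * K3, inf);
      rhs = F + (tab.c41 * K1 + tab.c42 * K2 + tab.c43 * K3) / h;
      K4 = Ginv * rhs;

      ynew = y + tab.m1 * K1 + tab.m3 * K3 + tab.m4 * K4;
      yerr = tab.e4 * K4;

      double err = 0.0;
      for (int i = 0; i < NS; ++i) {
        double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
        double e = yerr[i] / sc;
        err += e * e;
      }
      err = std::sqrt(err / NS);
      if (!std::isfinite(err)) err = 2.0;  // force rejection

      if (err <= 1.0) {
        t += h;
        y = ynew;
        // amounts may dip microscopically below zero; clamp within tolerance
        for (int i = 0; i < NS; ++i)
          if (y[i] < 0.0 && y[i] > -atol) y[i] = 0.0;
        while (iout < tout.n_elem && tout[iout] <= t + 1e-12) {
          out.row(iout) = y.t();
          ++iout;
        }
        accepted = true;
        double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -1.0 / 3.0)));
        h *= fac;
      } else {
        ++nreject;
        double fac = std::max(0.1, 0.9 * std::pow(err, -1.0 / 3.0));
        h *= fac;
      }
    }
  }
  while (iout < tout.n_elem) {  // numerical stragglers at t1
    out.row(iout) = y.t();
    ++iout;
  }

  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("yend") = y,
                            Rcpp::Named("nsteps") = (double)nsteps,
                            Rcpp::Named("nreject") = (double)nreject,
                            Rcpp::Named("hlast") = h);
}

//' @noRd
// [[Rcpp::export(name = ".rhs_cpp")]]
arma::vec rhs_cpp(arma::vec state, arma::vec phys, arma::vec drug,
                  arma::vec inf) {
  if (!state.is_finite()) Rcpp::stop("rhs: non-finite state");
  const Pars p = unpack(phys, drug);
  const arma::mat A = linear_matrix(p);
  return rhs_vec(A, p, state, inf);
}

//' @noRd
// [[Rcpp::export(name = ".jac_cpp")]]
arma::mat jac_cpp(arma::vec state, arma::vec phys, arma::vec drug) {
  const Pars p = unpack(phys, drug);
  const arma::mat A = linear_matrix(p);
  arma::mat J(NS, NS);
  fill_jacobian(J, A, p, state);
  return J;
}
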