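// O'Hara-Rudy (2011) human ventricular myocyte model with the Dutta et al.
// conductance rescaling of IKr, IKs, IK1, ICaL and INaL, under static
// multi-channel drug block (per-channel conductance scale factors).
// Fixed-step forward Euler with Rush-Larsen updates for Hodgkin-Huxley
// gates; this loop is the performance budget of the whole pipeline.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// state vector layout (must match ordStateNames() on the R side)
enum {
  iV = 0, iNai, iNass, iKi, iKss, iCai, iCass, iCansr, iCajsr,
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFf, iFs, iFcaf, iFcas, iJca, iNca, iFfp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1, iJrelnp, iJrelp, iCaMKt,
  NSTATE
};

// Rush-Larsen gate list: indices into the state for which (xss, tau) are
// produced; nca is handled in RL form too (linear ODE).
static const int RLGATES[] = {
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFf, iFs, iFcaf, iFcas, iJca, iNca, iFfp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1, iJrelnp, iJrelp
};
static const int NRL = sizeof(RLGATES) / sizeof(int);

struct OrdParams {
  // effective maximal conductances: base * dutta scaler * drug scale
  double GNa, GNaL, Gto, PCa, GKr, GKs, GK1, Gncx, Pnak, GKb, PNab, PCab, GpCa;
  int celltype; // 0 endo, 1 epi, 2 M
};

// physical constants and geometry
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Lcell = 0.01, rad = 0.0011;
static const double pi_ = 3.14;
static const double vcell = 1000.0 * pi_ * rad * rad * Lcell;
static const double Ageo = 2.0 * pi_ * rad * rad + 2.0 * pi_ * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
                    vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

// u / (exp(u) - 1), series-guarded near u = 0
static inline double exprel_inv(double u) {
  if (std::fabs(u) < 1e-7) return 1.0 / (1.0 + 0.5 * u + u * u / 6.0);
  return u / (std::exp(u) - 1.0);
}

// Evaluates the full right-hand side at state y.
// Outputs: xss/tauv for the NRL Rush-Larsen gates, dy for the remaining
// states (v, concentrations, CaMKt; gate entries of dy are filled with
// (xss - x)/tau for the derivative interface), currents (named order below).
static void ord_core(const double* y, const OrdParams& P, double Ist,
                     double* xss, double* tauv, double* dy, double* cur) {
  const double v = y[iV];
  const double nai = y[iNai], nass = y[iNass], ki = y[iKi], kss = y[iKss];
  const double cai = y[iCai], cass = y[iCass], cansr = y[iCansr], cajsr = y[iCajsr];

  // CaMK
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068,
               CaMKo = 0.05, KmCaM = 0.0015;
  const double CaMKb = CaMKo * (1.0 - y[iCaMKt]) / (1.0 + KmCaM / cass);
  const double CaMKa = CaMKb + y[iCaMKt];
  const double dCaMKt = aCaMK * CaMKb * (CaMKb + y[iCaMKt]) - bCaMK * y[iCaMKt];
  const double fp_frac = 1.0 / (1.0 + KmCaMK / CaMKa); // CaMK-phosphorylated fraction

  // reversal potentials
  const double ENa = (Rgas * Temp / Frdy) * std::log(nao / nai);
  const double EK = (Rgas * Temp / Frdy) * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs = (Rgas * Temp / Frdy) * std::log((ko + PKNa * nao) / (ki + PKNa * nai));
  const double vfrt = v * Frdy / (Rgas * Temp);
  const double vffrt = vfrt * Frdy;

  // ---- INa (fast) ----
  xss[0] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));                    // m
  tauv[0] = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                   8.552 * std::exp(-(v + 77.42) / 5.955));
  const double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  xss[1] = hss;                                                             // hf
  tauv[1] = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                   6.149 * std::exp((v + 0.5096) / 20.27));
  xss[2] = hss;                                                             // hs
  tauv[2] = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                   0.3343 * std::exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 1.0 - Ahf;
  const double h = Ahf * y[iHf] + Ahs * y[iHs];
  xss[3] = hss;                                                             // j
  const double tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                                   0.3052 * std::exp((v + 0.9941) / 38.45));
  tauv[3] = tj;
  xss[4] = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));                      // hsp
  tauv[4] = 3.0 * tauv[2];
  const double hp = Ahf * y[iHf] + Ahs * y[iHsp];
  xss[5] = hss;                                                             // jp
  tauv[5] = 1.46 * tj;
  const double m3 = y[iM] * y[iM] * y[iM];
  const double INa = P.GNa * (v - ENa) * m3 *
      ((1.0 - fp_frac) * h * y[iJ] + fp_frac * hp * y[iJp]);

  // ---- INaL ----
  xss[6] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));                    // mL
  tauv[6] = tauv[0];
  xss[7] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));                     // hL
  tauv[7] = 200.0;
  xss[8] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));                     // hLp
  tauv[8] = 600.0;
  double GNaL = P.GNaL;
  if (P.celltype == 1) GNaL *= 0.6;
  const double INaL = GNaL * (v - ENa) * y[iML] *
      ((1.0 - fp_frac) * y[iHL] + fp_frac * y[iHLp]);

  // ---- Ito ----
  xss[9] = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));                    // a
  tauv[9] = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                      3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  double delta_epi = 1.0;
  if (P.celltype == 1)
    delta_epi = 1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0));
  xss[10] = iss;                                                            // iF
  double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                              0.08004 * std::exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                              1.780e-8 * std::exp((v + 114.1) / 8.079));
  tiF *= delta_epi; tiS *= delta_epi;
  tauv[10] = tiF;
  xss[11] = iss;                                                            // iS
  tauv[11] = tiS;
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double ito_i = AiF * y[iIF] + AiS * y[iIS];
  xss[12] = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));                   // ap
  tauv[12] = tauv[9];
  const double dti_develop = 1.354 + 1e-4 / (std::exp((v - 167.4) / 15.89) +
                                             std::exp(-(v - 12.23) / 0.2154));
  const double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  xss[13] = iss;                                                            // iFp
  tauv[13] = dti_develop * dti_recover * tiF;
  xss[14] = iss;                                                            // iSp
  tauv[14] = dti_develop * dti_recover * tiS;
  const double ito_ip = AiF * y[iIFp] + AiS * y[iISp];
  double Gto = P.Gto;
  if (P.celltype == 1 || P.celltype == 2) Gto *= 4.0;
  const double Ito = Gto * (v - EK) *
      ((1.0 - fp_frac) * y[iA] * ito_i + fp_frac * y[iAp] * ito_ip);

  // ---- ICaL / ICaNa / ICaK ----
  xss[15] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));                   // d
  tauv[15] = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) + std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  xss[16] = fss;                                                            // ff
  tauv[16] = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                          0.0045 * std::exp((v + 20.0) / 10.0));
  xss[17] = fss;                                                            // fs
  tauv[17] = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                             0.000035 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 1.0 - Aff;
  const double f = Aff * y[iFf] + Afs * y[iFs];
  xss[18] = fss;                                                            // fcaf
  tauv[18] = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                          0.04 * std::exp((v - 4.0) / 7.0));
  xss[19] = fss;                                                            // fcas
  tauv[19] = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                            0.00012 * std::exp(v / 7.0));
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  const double fca = Afcaf * y[iFcaf] + Afcas * y[iFcas];
  xss[20] = fss;                                                            // jca
  tauv[20] = 75.0;
  xss[21] = 0.0;                                                            // nca (filled below)
  tauv[21] = 1.0;
  xss[22] = fss;                                                            // ffp
  tauv[22] = 2.5 * tauv[16];
  const double fpv = Aff * y[iFfp] + Afs * y[iFs];
  xss[23] = fss;                                                            // fcafp
  tauv[23] = 2.5 * tauv[18];
  const double fcap = Afcaf * y[iFcafp] + Afcas * y[iFcas];
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = y[iJca] * 1.0;
  const double tmp_nca = 1.0 + Kmn / cass;
  const double anca = 1.0 / (k2n / km2n + tmp_nca * tmp_nca * tmp_nca * tmp_nca);
  // dnca = anca*k2n - nca*km2n  ->  RL with xss = anca*k2n/km2n, tau = 1/km2n
  xss[21] = anca * k2n / km2n;
  tauv[21] = 1.0 / km2n;
  const double nca = y[iNca];
  // GHK driving terms (guarded at v ~ 0)
  const double PhiCaL = 4.0 * Frdy *
      ((cass * std::exp(2.0 * vfrt) - 0.341 * cao) * exprel_inv(2.0 * vfrt));
  const double PhiCaNa = Frdy *
      ((0.75 * nass * std::exp(vfrt) - 0.75 * nao) * exprel_inv(vfrt));
  const double PhiCaK = Frdy *
      ((0.75 * kss * std::exp(vfrt) - 0.75 * ko) * exprel_inv(vfrt));
  double PCa = P.PCa;
  if (P.celltype == 1) PCa *= 1.2; else if (P.celltype == 2) PCa *= 2.5;
  const double PCap = 1.1 * PCa;
  const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  const double dgate = y[iD];
  const double caGateNP = f * (1.0 - nca) + y[iJca] * fca * nca;
  const double caGateP = fpv * (1.0 - nca) + y[iJca] * fcap * nca;
  const double ICaL = (1.0 - fp_frac) * PCa * PhiCaL * dgate * caGateNP +
                      fp_frac * PCap * PhiCaL * dgate * caGateP;
  const double ICaNa = (1.0 - fp_frac) * PCaNa * PhiCaNa * dgate * caGateNP +
                       fp_frac * PCaNap * PhiCaNa * dgate * caGateP;
  const double ICaK = (1.0 - fp_frac) * PCaK * PhiCaK * dgate * caGateNP +
                      fp_frac * PCaKp * PhiCaK * dgate * caGateP;

  // ---- IKr ----
  const double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  xss[24] = xrss;                                                           // xrf
  tauv[24] = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                            4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  xss[25] = xrss;                                                           // xrs
  tauv[25] = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                            1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double Axrs = 1.0 - Axrf;
  const double xr = Axrf * y[iXrf] + Axrs * y[iXrs];
  const double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
                     1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  double GKr = P.GKr;
  if (P.celltype == 1) GKr *= 1.3; else if (P.celltype == 2) GKr *= 0.8;
  const double IKr = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // ---- IKs ----
  const double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  xss[26] = xs1ss;                                                          // xs1
  tauv[26] = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                            0.001292 * std::exp(-(v + 210.0) / 230.0));
  xss[27] = xs1ss;                                                          // xs2
  tauv[27] = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                    0.0193 * std::exp(-(v + 66.54) / 31.0));
  const double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  double GKs = P.GKs;
  if (P.celltype == 1) GKs *= 1.4;
  const double IKs = GKs * KsCa * y[iXs1] * y[iXs2] * (v - EKs);

  // ---- IK1 ----
  xss[28] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                  (1.5692 * ko + 3.8115)));                 // xk1
  tauv[28] = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                      std::exp((v + 236.8) / 69.33));
  const double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  double GK1 = P.GK1;
  if (P.celltype == 1) GK1 *= 1.2; else if (P.celltype == 2) GK1 *= 1.3;
  const double IK1 = GK1 * std::sqrt(ko) * rk1 * y[iXk1] * (v - EK);

  // ---- INaCa (myoplasmic and subspace components) ----
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5,
               wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3,
               kcaon = 1.5e6, kcaoff = 5.0e3, qna = 0.5224, qca = 0.1670;
  const double hca = std::exp(qca * vfrt), hna = std::exp(qna * vfrt);
  const double KmCaAct = 150.0e-6, zca = 2.0, zna = 1.0;
  double Gncx = P.Gncx;
  if (P.celltype == 1) Gncx *= 1.1; else if (P.celltype == 2) Gncx *= 1.4;
  double INaCa_i, INaCa_ss;
  {
    const double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    const double h2 = (nai * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    const double h5 = nai * nai / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon, k2 = kcaoff;
    const double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    const double k5 = kcaoff, k6 = h6 * cai * kcaon;
    const double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4),
                 E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    const double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  {
    const double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    const double h2 = (nass * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    const double h5 = nass * nass / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon, k2 = kcaoff;
    const double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    const double k5 = kcaoff, k6 = h6 * cass * kcaon;
    const double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4),
                 E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    const double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }

  // ---- INaK ----
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4,
                 k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    const double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
    const double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
    const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8,
                 Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2, Khp = 1.698e-7,
                 Knap = 224.0, Kxkur = 292.0;
    const double Pph = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    const double nk1 = nai / Knai, nk2 = nao / Knao, kk1 = ki / Kki, kk2 = ko / Kko;
    const double denom_i = (1.0 + nk1) * (1.0 + nk1) * (1.0 + nk1) +
                           (1.0 + kk1) * (1.0 + kk1) - 1.0;
    const double denom_o = (1.0 + nk2) * (1.0 + nk2) * (1.0 + nk2) +
                           (1.0 + kk2) * (1.0 + kk2) - 1.0;
    const double a1 = k1p * nk1 * nk1 * nk1 / denom_i;
    const double b1 = k1m * MgADP;
    const double a2 = k2p;
    const double b2 = k2m * nk2 * nk2 * nk2 / denom_o;
    const double a3 = k3p * kk2 * kk2 / denom_o;
    const double b3 = k3m * Pph * H / (1.0 + MgATP / Kmgatp);
    const double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
    const double b4 = k4m * kk1 * kk1 / denom_i;
    const double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    const double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    const double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    const double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    const double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4),
                 E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    const double zk = 1.0;
    const double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    const double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    double Pnak = P.Pnak;
    if (P.celltype == 1) Pnak *= 0.9; else if (P.celltype == 2) Pnak *= 0.7;
    INaK = Pnak * (zna * JnakNa + zk * JnakK);
  }

  // ---- background and pump currents ----
  const double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  double GKb = P.GKb;
  if (P.celltype == 1) GKb *= 0.6;
  const double IKb = GKb * xkb * (v - EK);
  const double INab = P.PNab * Frdy *
      ((nai * std::exp(vfrt) - nao) * exprel_inv(vfrt));
  const double ICab = P.PCab * 4.0 * Frdy *
      ((cai * std::exp(2.0 * vfrt) - 0.341 * cao) * exprel_inv(2.0 * vfrt));
  const double IpCa = P.GpCa * cai / (0.0005 + cai);

  // ---- diffusion and SR fluxes ----
  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  const double bt = 4.75, a_rel = 0.5 * bt;
  double Jrel_inf = a_rel * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  if (P.celltype == 2) Jrel_inf *= 1.7;
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  const double btp = 1.25 * bt, a_relp = 0.5 * btp;
  double Jrel_infp = a_relp * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  if (P.celltype == 2) Jrel_infp *= 1.7;
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  xss[29] = Jrel_inf;  tauv[29] = tau_rel;   // Jrelnp
  xss[30] = Jrel_infp; tauv[30] = tau_relp;  // Jrelp
  const double Jrel = (1.0 - fp_frac) * y[iJrelnp] + fp_frac * y[iJrelp];

  double Jupnp = 0.004375 * cai / (cai + 0.00092);
  double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  if (P.celltype == 1) { Jupnp *= 1.3; Jupp *= 1.3; }
  const double Jleak = 0.0039375 * cansr / 15.0;
  const double Jup = (1.0 - fp_frac) * Jupnp + fp_frac * Jupp - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  // ---- concentration and voltage derivatives ----
  const double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs +
                      IK1 + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa +
                      ICab + Ist;
  dy[iV] = -Itot;
  dy[iNai] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
                 (Frdy * vmyo) + JdiffNa * vss / vmyo;
  dy[iNass] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  dy[iKi] = -(Ito + IKr + IKs + IK1 + IKb + Ist - 2.0 * INaK) * Acap /
                (Frdy * vmyo) + JdiffK * vss / vmyo;
  dy[iKss] = -ICaK * Acap / (Frdy * vss) - JdiffK;
  double cmdnmax = 0.05;
  if (P.celltype == 1) cmdnmax *= 1.3;
  const double kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005,
               BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124, KmBSL = 0.0087,
               csqnmax = 10.0, kmcsqn = 0.8;
  const double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / ((kmcmdn + cai) * (kmcmdn + cai)) +
                             trpnmax * kmtrpn / ((kmtrpn + cai) * (kmtrpn + cai)));
  dy[iCai] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * Frdy * vmyo) -
                     Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  const double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / ((KmBSR + cass) * (KmBSR + cass)) +
                              BSLmax * KmBSL / ((KmBSL + cass) * (KmBSL + cass)));
  dy[iCass] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                       Jrel * vjsr / vss - Jdiff);
  dy[iCansr] = Jup - Jtr * vjsr / vnsr;
  const double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn /
                               ((kmcsqn + cajsr) * (kmcsqn + cajsr)));
  dy[iCajsr] = Bcajsr * (Jtr - Jrel);
  dy[iCaMKt] = dCaMKt;

  if (cur) {
    cur[0] = INa; cur[1] = INaL; cur[2] = Ito; cur[3] = ICaL; cur[4] = ICaNa;
    cur[5] = ICaK; cur[6] = IKr; cur[7] = IKs; cur[8] = IK1; cur[9] = INaCa_i;
    cur[10] = INaCa_ss; cur[11] = INaK; cur[12] = INab; cur[13] = ICab;
    cur[14] = IKb; cur[15] = IpCa; cur[16] = Jrel; cur[17] = Jup;
  }
}

static OrdParams make_params(NumericVector g, NumericVector scales, int celltype) {
  // g: named base*dutta effective conductances (13); scales: 7 drug scales in
  // order INa, INaL, Ito, ICaL, IKr, IKs, IK1 (already in [0,1])
  OrdParams P;
  P.GNa = g["GNa"] * scales[0];
  P.GNaL = g["GNaL"] * scales[1];
  P.Gto = g["Gto"] * scales[2];
  P.PCa = g["PCa"] * scales[3];
  P.GKr = g["GKr"] * scales[4];
  P.GKs = g["GKs"] * scales[5];
  P.GK1 = g["GK1"] * scales[6];
  P.Gncx = g["Gncx"]; P.Pnak = g["Pnak"]; P.GKb = g["GKb"];
  P.PNab = g["PNab"]; P.PCab = g["PCab"]; P.GpCa = g["GpCa"];
  P.celltype = celltype;
  return P;
}

// [[Rcpp::export(name = ".ord_derivs_cpp")]]
List ord_derivs_cpp(NumericVector state, NumericVector g, NumericVector scales,
                    int celltype, double stim) {
  if (state.size() != NSTATE) stop("state vector must have %d elements", NSTATE);
  double xss[NRL], tauv[NRL], dy[NSTATE], cur[18];
  std::memset(dy, 0, sizeof(dy));
  OrdParams P = make_params(g, scales, celltype);
  ord_core(state.begin(), P, stim, xss, tauv, dy, cur);
  for (int k = 0; k < NRL; ++k)
    dy[RLGATES[k]] = (xss[k] - state[RLGATES[k]]) / tauv[k];
  NumericVector dout(NSTATE);
  for (int k = 0; k < NSTATE; ++k) dout[k] = dy[k];
  NumericVector curv(18);
  for (int k = 0; k < 18; ++k) curv[k] = cur[k];
  curv.names() = CharacterVector::create(
      "INa", "INaL", "Ito", "ICaL", "ICaNa", "ICaK", "IKr", "IKs", "IK1",
      "INaCa_i", "INaCa_ss", "INaK", "INab", "ICab", "IKb", "IpCa",
      "Jrel", "Jup");
  return List::create(_["derivs"] = dout, _["currents"] = curv);
}

// Advance the model one step (forward Euler + Rush-Larsen); returns false on
// non-finite blowup, filling bad_name with the offending component.
static bool ord_step(double* y, const OrdParams& P, double Ist, double dt,
                     std::string& bad_name) {
  double xss[NRL], tauv[NRL], dy[NSTATE];
  std::memset(dy, 0, sizeof(dy));
  ord_core(y, P, Ist, xss, tauv, dy, NULL);
  // direct (Euler) states
  static const int EUL[] = {iV, iNai, iNass, iKi, iKss, iCai, iCass,
                            iCansr, iCajsr, iCaMKt};
  for (int k = 0; k < 10; ++k) {
    const int s = EUL[k];
    y[s] += dt * dy[s];
    if (!std::isfinite(y[s])) { bad_name = "state_" + std::to_string(s); return false; }
  }
  for (int k = 0; k < NRL; ++k) {
    const int s = RLGATES[k];
    y[s] = xss[k] + (y[s] - xss[k]) * std::exp(-dt / tauv[k]);
    if (!std::isfinite(y[s])) { bad_name = "gate_" + std::to_string(s); return false; }
  }
  return true;
}

// [[Rcpp::export(name = ".ord_pace_cpp")]]
List ord_pace_cpp(NumericVector state, NumericVector g, NumericVector scales,
                  int celltype, int n_beats, double cl_ms, double dt_ms,
                  double record_dt_ms, double stim_amp, double stim_dur,
                  bool record) {
  if (state.size() != NSTATE) stop("state vector must have %d elements", NSTATE);
  OrdParams P = make_params(g, scales, celltype);
  const long steps_per_beat = (long)std::lround(cl_ms / dt_ms);
  const long rec_every = (long)std::lround(record_dt_ms / dt_ms);
  const int samples = (int)std::lround(cl_ms / record_dt_ms);
  double y[NSTATE];
  for (int k = 0; k < NSTATE; ++k) y[k] = state[k];
  NumericMatrix vmat = record ? NumericMatrix(n_beats, samples) : NumericMatrix(0, 0);
  NumericVector beat_norms(n_beats);
  double prev[NSTATE];
  std::string bad;
  for (int b = 0; b < n_beats; ++b) {
    std::memcpy(prev, y, sizeof(y));
    for (long s = 0; s < steps_per_beat; ++s) {
      const double t = s * dt_ms;
      if (record && s % rec_every == 0) vmat(b, (int)(s / rec_every)) = y[iV];
      const double Ist = (t < stim_dur) ? stim_amp : 0.0;
      // accuracy refinement for the stiff fast phases (upstroke, rapid
      // phase-3): when one step moves V by more than 0.1 mV the step is
      // redone as ten substeps; everywhere else the base grid is used
      const double v_before = y[iV];
      double ytry[NSTATE]; std::memcpy(ytry, y, sizeof(ytry));
      if (!ord_step(y, P, Ist, dt_ms, bad))
        stop("numerical blowup in %s at beat %d, t = %.1f ms", bad.c_str(), b + 1, t);
      if (std::fabs(y[iV] - v_before) > 0.1) {
        std::memcpy(y, ytry, sizeof(ytry));
        for (int sub = 0; sub < 10; ++sub)
          if (!ord_step(y, P, Ist, dt_ms / 10.0, bad))
            stop("numerical blowup in %s at beat %d, t = %.1f ms",
                 bad.c_str(), b + 1, t);
      }
    }
    double nrm = 0.0;
    for (int k = 0; k < NSTATE; ++k) {
      const double d = y[k] - prev[k];
      nrm += d * d;
    }
    beat_norms[b] = std::sqrt(nrm);
    if (b % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = y[k];
  return List::create(_["v"] = vmat, _["final_state"] = fin,
                      _["beat_norms"] = beat_norms);
}
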