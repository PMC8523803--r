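#include "tt06.h"
#include <cmath>

namespace tt06 {

void initial_state(double* y, double* V) {
  *V = -85.23;
  y[0] = 0.00172;    // m
  y[1] = 0.7444;     // h
  y[2] = 0.7045;     // j
  y[3] = 3.373e-5;   // d
  y[4] = 0.7888;     // f
  y[5] = 0.9755;     // f2
  y[6] = 0.9953;     // fCass
  y[7] = 2.42e-8;    // r
  y[8] = 0.999998;   // s
  y[9] = 0.00621;    // xr1
  y[10] = 0.4712;    // xr2
  y[11] = 0.0095;    // xs
  y[12] = 0.9073;    // Rbar
  y[13] = 0.000126;  // Cai
  y[14] = 0.00036;   // CaSS
  y[15] = 3.64;      // CaSR
  y[16] = 8.604;     // Nai
  y[17] = 136.89;    // Ki
}

void gate_rates(double V, int cell_type, double* inf, double* tau) {
  // m
  inf[0] = 1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
                  (1.0 + std::exp((-56.86 - V) / 9.03)));
  {
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    tau[0] = am * bm;
  }
  // h
  inf[1] = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                  (1.0 + std::exp((V + 71.55) / 7.43)));
  {
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    tau[1] = 1.0 / (ah + bh);
  }
  // j
  inf[2] = inf[1];
  {
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    tau[2] = 1.0 / (aj + bj);
  }
  // d
  inf[3] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  {
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    tau[3] = ad * bd + gd;
  }
  // f
  inf[4] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  tau[4] = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
           200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
           180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  // f2
  inf[5] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  tau[5] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
           31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
           80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  // r
  inf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  // s (epicardial/M form; endocardial differs)
  if (cell_type == 1) {
    inf[7] = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    tau[7] = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {
    inf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau[7] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
             5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  // xr1
  inf[8] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  {
    double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    tau[8] = a * b;
  }
  // xr2
  inf[9] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  {
    double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    tau[9] = a * b;
  }
  // xs
  inf[10] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  {
    double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    tau[10] = a * b + 80.0;
  }
  inf[11] = 0.0;
  tau[11] = 1.0;
}

void currents(double V, const double* y, int cell_type, double* I) {
  const double ENa = RTONF * std::log(Nao / y[16]);
  const double EK = RTONF * std::log(Ko / y[17]);
  const double EKs = RTONF * std::log((Ko + pKNa * Nao) / (y[17] + pKNa * y[16]));
  const double ECa = 0.5 * RTONF * std::log(Cao / y[13]);

  I[0] = GNa * y[0] * y[0] * y[0] * y[1] * y[2] * (V - ENa);

  {
    double vshift = V - 15.0;
    double ical;
    if (std::fabs(vshift) < 1e-6) {
      ical = GCaL * y[3] * y[4] * y[5] * y[6] * 2.0 * Frdy *
             (0.25 * y[14] - Cao);
    } else {
      double e2 = std::exp(2.0 * vshift / RTONF);
      double coef = 4.0 * vshift * (Frdy / RTONF) / (e2 - 1.0);
      ical = GCaL * y[3] * y[4] * y[5] * y[6] * coef * (0.25 * y[14] * e2 - Cao);
    }
    I[1] = ical;
  }

  I[2] = Gto_of(cell_type) * y[7] * y[8] * (V - EK);
  I[3] = GKr * std::sqrt(Ko / 5.4) * y[9] * y[10] * (V - EK);
  I[4] = GKs_of(cell_type) * y[11] * y[11] * (V - EKs);

  {
    double u = V - EK;
    double a = 0.1 / (1.0 + std::exp(0.06 * (u - 200.0)));
    double b = (3.0 * std::exp(0.0002 * (u + 100.0)) + std::exp(0.1 * (u - 10.0))) /
               (1.0 + std::exp(-0.5 * u));
    I[5] = GK1 * std::sqrt(Ko / 5.4) * (a / (a + b)) * u;
  }

  {
    double ef = std::exp(gamma_ncx * V / RTONF);
    double er = std::exp((gamma_ncx - 1.0) * V / RTONF);
    double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
                 (1.0 + ksat * er);
    I[6] = knaca * (ef * y[16] * y[16] * y[16] * Cao -
                    er * Nao * Nao * Nao * y[13] * alpha_ncx) / den;
  }

  I[7] = PNaK * (Ko / (Ko + KmK)) * (y[16] / (y[16] + KmNa)) /
         (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
          0.0353 * std::exp(-V / RTONF));

  I[8] = GpCa * y[13] / (y[13] + KpCa);
  I[9] = GpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  I[10] = GbCa * (V - ECa);
  I[11] = GbNa * (V - ENa);
}

void conc_derivs(double V, const double* y, const double* I,
                 double Istim_K, double* dy) {
  (void)V;
  const double inverseVcF2 = 1.0 / (2.0 * Vc * Frdy);
  const double inverseVcF = 1.0 / (Vc * Frdy);
  const double inversevssF2 = 1.0 / (2.0 * Vss * Frdy);

  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (ECsr / y[15]) * (ECsr / y[15]));
  double k1 = k1p / kcasr;
  double k2 = k2p * kcasr;
  double O = k1 * y[14] * y[14] * y[12] / (k3r + k1 * y[14] * y[14]);
  double Irel = Vrel * O * (y[15] - y[14]);
  double Ileak = Vleak * (y[15] - y[13]);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (y[13] * y[13]));
  double Ixfer = Vxfer * (y[14] - y[13]);

  dy[12] = -k2 * y[14] * y[12] + k4r * (1.0 - y[12]);

  double bufc = 1.0 / (1.0 + Bufc * Kbufc / ((y[13] + Kbufc) * (y[13] + Kbufc)));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((y[15] + Kbufsr) * (y[15] + Kbufsr)));
  double bufss = 1.0 / (1.0 + Bufss * Kbufss / ((y[14] + Kbufss) * (y[14] + Kbufss)));

  dy[13] = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                   (I[10] + I[8] - 2.0 * I[6]) * CAP * inverseVcF2);
  dy[14] = bufss * (-I[1] * CAP * inversevssF2 + Irel * Vsr / Vss -
                    Ixfer * Vc / Vss);
  dy[15] = bufsr * (Iup - Irel - Ileak);
  dy[16] = -(I[0] + I[11] + 3.0 * I[7] + 3.0 * I[6]) * CAP * inverseVcF;
  dy[17] = -(Istim_K + I[5] + I[2] + I[3] + I[4] - 2.0 * I[7] + I[9]) * CAP * inverseVcF;

  double css50 = (y[14] / 0.05) * (y[14] / 0.05);
  double fCass_inf = 0.6 / (1.0 + css50) + 0.4;
  double tau_fCass = 80.0 / (1.0 + css50) + 2.0;
  dy[6] = (fCass_inf - y[6]) / tau_fCass;
}

}  // namespace tt06
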