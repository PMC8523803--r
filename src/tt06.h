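#ifndef CARDIOFIB_TT06_H
#define CARDIOFIB_TT06_H

// Human ventricular myocyte membrane model (ten Tusscher & Panfilov 2006
// formulation). State layout (18 entries, membrane voltage kept separately):
//   0:m 1:h 2:j 3:d 4:f 5:f2 6:fCass 7:r 8:s 9:xr1 10:xr2 11:xs
//   12:Rbar 13:Cai 14:CaSS 15:CaSR 16:Nai 17:Ki
// Voltage in mV, time in ms, currents in pA/pF, concentrations in mM.

namespace tt06 {

const int N_STATE = 18;
const int N_VGATE = 12;  // voltage-dependent gates: m h j d f f2 r s xr1 xr2 xs (+1 pad)

// physical constants
const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
const double RTONF = Rgas * Temp / Frdy;  // mV

// geometry / capacitance factors used in the concentration balance
const double CAP = 0.185, Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;

// external concentrations (mM)
const double Ko = 5.4, Nao = 140.0, Cao = 2.0;

// maximal conductances (nS/pF) and permeabilities
const double GNa = 14.838, GK1 = 5.405, GKr = 0.153;
const double GCaL = 0.0000398, GbNa = 0.00029, GbCa = 0.000592;
const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
const double knaca = 1000.0, gamma_ncx = 0.35, KmCa = 1.38, KmNai = 87.5;
const double ksat = 0.1, alpha_ncx = 2.5;
const double pKNa = 0.03;

// SR calcium handling
const double Vmaxup = 0.006375, Kup = 0.00025;
const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
const double k1p = 0.15, k2p = 0.045, k3r = 0.060, k4r = 0.005;
const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;
const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;
const double Bufss = 0.4, Kbufss = 0.00025;

// cell-type dependent conductances (0 = epi, 1 = endo, 2 = M)
inline double Gto_of(int ct) { return ct == 1 ? 0.073 : 0.294; }
inline double GKs_of(int ct) { return ct == 2 ? 0.098 : 0.392; }

// steady-state values and time constants of the voltage-dependent gates
void gate_rates(double V, int cell_type, double* inf, double* tau);

// all twelve membrane currents (pA/pF); order:
//   0:INa 1:ICaL 2:Ito 3:IKr 4:IKs 5:IK1 6:INaCa 7:INaK 8:IpCa 9:IpK 10:IbCa 11:IbNa
void currents(double V, const double* y, int cell_type, double* I);

// time derivatives of fCass, Rbar and the five concentrations, given the
// currents; writes dy[6], dy[12..17] (other entries untouched)
void conc_derivs(double V, const double* y, const double* I,
                 double Istim_K, double* dy);

// published epicardial resting state
void initial_state(double* y, double* V);

}  // namespace tt06

#endif
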