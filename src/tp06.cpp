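// ten Tusscher-Panfilov (2006) human ventricular myocyte model and a 1D
// monodomain cable driver.  Reaction step: forward Euler for V and
// concentrations, Rush-Larsen for the gating variables (all gates, fCass and
// the SR release gate have closed-form steady-state/time-constant form).
// Diffusion: explicit central differences with no-flux ends, operator split.
// Units: ms, mV, pA/pF, mM; conductances in nS/pF.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double Rgas = 8314.472, Frd = 96485.3415, Tmp = 310.0;
const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;
const double Bufss = 0.4, Kbufss = 0.00025;
const double Vmaxup = 0.006375, Kup = 0.00025;
const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
const double Vleak = 0.00036, Vxfer = 0.0038;
const double pKNa = 0.03;
const double GK1 = 5.405, GNa = 14.838, GbNa = 0.00029;
const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
const double GCaL = 0.00003980, GbCa = 0.000592;
const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1;
const double ncag = 0.35;
const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146, GKr = 0.153;
const double CAP = 0.185;
const double rtof = Rgas * Tmp / Frd;

struct Cell {
  double V, Cai, CaSR, CaSS, Nai, Ki;
  double m, h, j, xr1, xr2, xs, r, s, d, f, f2, fcass, rbar;
};

// published initial (resting) state
Cell init_cell() {
  Cell c;
  c.V = -86.2; c.Cai = 0.00007; c.CaSR = 1.3; c.CaSS = 0.00007;
  c.Nai = 7.67; c.Ki = 138.3;
  c.m = 0.0; c.h = 0.75; c.j = 0.75;
  c.xr1 = 0.0; c.xr2 = 1.0; c.xs = 0.0; c.r = 0.0; c.s = 1.0;
  c.d = 0.0; c.f = 1.0; c.f2 = 1.0; c.fcass = 1.0; c.rbar = 1.0;
  return c;
}

// cell_type: 0 = endo, 1 = M, 2 = epi
inline void step_cell(Cell &c, int cell_type, double dt, double istim,
                      double gkr_scale) {
  const double V = c.V;
  const double gks = (cell_type == 1) ? 0.098 : 0.392;
  const double gto = (cell_type == 0) ? 0.073 : 0.294;

  const double Ek = rtof * std::log(Ko / c.Ki);
  const double Ena = rtof * std::log(Nao / c.Nai);
  const double Eks = rtof * std::log((Ko + pKNa * Nao) / (c.Ki + pKNa * c.Nai));
  const double Eca = 0.5 * rtof * std::log(Cao / c.Cai);

  const double INa = GNa * c.m * c.m * c.m * c.h * c.j * (V - Ena);
  const double IbNa = GbNa * (V - Ena);

  double vmek = V - Ek;
  const double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (vmek - 200.0)));
  const double Bk1 = (3.0 * std::exp(0.0002 * (vmek + 100.0)) +
                      std::exp(0.1 * (vmek - 10.0))) /
                     (1.0 + std::exp(-0.5 * vmek));
  const double IK1 = GK1 * (Ak1 / (Ak1 + Bk1)) * vmek;

  const double IKr = gkr_scale * GKr * std::sqrt(Ko / 5.4) * c.xr1 * c.xr2 *
                     vmek;
  const double IKs = gks * c.xs * c.xs * (V - Eks);
  const double Ito = gto * c.r * c.s * vmek;

  double vm15 = V - 15.0;
  double expv = std::exp(2.0 * vm15 * Frd / (Rgas * Tmp));
  double ICaL;
  if (std::fabs(vm15) < 1e-6) {
    // L'Hopital limit of the GHK driving term at V = 15 mV
    ICaL = GCaL * c.d * c.f * c.f2 * c.fcass * 2.0 * Frd *
           (0.25 * c.CaSS - Cao);
  } else {
    ICaL = GCaL * c.d * c.f * c.f2 * c.fcass * 4.0 * vm15 *
           (Frd * Frd / (Rgas * Tmp)) *
           (0.25 * expv * c.CaSS - Cao) / (expv - 1.0);
  }
  const double IbCa = GbCa * (V - Eca);

  const double INaK = knak * (Ko / (Ko + KmK)) * (c.Nai / (c.Nai + KmNa)) /
                      (1.0 + 0.1245 * std::exp(-0.1 * V * Frd / (Rgas * Tmp)) +
                       0.0353 * std::exp(-V * Frd / (Rgas * Tmp)));
  const double INaCa =
      knaca * (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
      (1.0 / (KmCa + Cao)) *
      (1.0 / (1.0 + ksat * std::exp((ncag - 1.0) * V * Frd / (Rgas * Tmp)))) *
      (std::exp(ncag * V * Frd / (Rgas * Tmp)) * c.Nai * c.Nai * c.Nai * Cao -
       std::exp((ncag - 1.0) * V * Frd / (Rgas * Tmp)) * Nao * Nao * Nao *
           c.Cai * 2.5);
  const double IpCa = GpCa * c.Cai / (KpCa + c.Cai);
  const double IpK = GpK * vmek / (1.0 + std::exp((25.0 - V) / 5.98));

  const double Itot = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa +
                      INaK + INaCa + IpCa + IpK + istim;

  // calcium subsystem
  const double kCaSR = maxsr - (maxsr - minsr) /
                                   (1.0 + (EC / c.CaSR) * (EC / c.CaSR));
  const double k1 = k1p / kCaSR;
  const double k2 = k2p * kCaSR;
  // rbar: dR/dt = k4 (1-R) - k2 Css R  -> exact exponential update
  {
    const double a = k2 * c.CaSS + k4;
    const double rinf = k4 / a;
    c.rbar = rinf + (c.rbar - rinf) * std::exp(-dt * a);
  }
  const double sOO = k1 * c.CaSS * c.CaSS * c.rbar /
                     (k3 + k1 * c.CaSS * c.CaSS);
  const double Irel = Vrel * sOO * (c.CaSR - c.CaSS);
  const double Ileak = Vleak * (c.CaSR - c.Cai);
  const double Iup = Vmaxup / (1.0 + Kup * Kup / (c.Cai * c.Cai));
  const double Ixfer = Vxfer * (c.CaSS - c.Cai);

  {
    const double CaCSQN = Bufsr * c.CaSR / (c.CaSR + Kbufsr);
    const double dCaSR = dt * (Iup - Irel - Ileak);
    const double bjsr = Bufsr - CaCSQN - dCaSR - c.CaSR + Kbufsr;
    const double cjsr = Kbufsr * (CaCSQN + dCaSR + c.CaSR);
    c.CaSR = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;
  }
  {
    const double CaSSBuf = Bufss * c.CaSS / (c.CaSS + Kbufss);
    const double dCaSS = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
                               (-ICaL / (2.0 * Vss * Frd) * CAP));
    const double bcss = Bufss - CaSSBuf - dCaSS - c.CaSS + Kbufss;
    const double ccss = Kbufss * (CaSSBuf + dCaSS + c.CaSS);
    c.CaSS = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;
  }
  {
    const double CaBuf = Bufc * c.Cai / (c.Cai + Kbufc);
    const double dCai = dt * (-(IbCa + IpCa - 2.0 * INaCa) /
                                  (2.0 * Vc * Frd) * CAP -
                              (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    const double bc = Bufc - CaBuf - dCai - c.Cai + Kbufc;
    const double cc = Kbufc * (CaBuf + dCai + c.Cai);
    c.Cai = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;
  }
  c.Nai += -dt * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) / (Vc * Frd) * CAP;
  c.Ki += -dt * (istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) /
          (Vc * Frd) * CAP;

  // gating variables (Rush-Larsen)
  {
    const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                      0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    const double taum = am * bm;
    const double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
    c.m = minf - (minf - c.m) * std::exp(-dt / taum);
  }
  {
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    const double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    c.h = hinf - (hinf - c.h) * std::exp(-dt * (ah + bh));
    c.j = hinf - (hinf - c.j) * std::exp(-dt * (aj + bj));
  }
  {
    const double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    const double inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    c.xr1 = inf - (inf - c.xr1) * std::exp(-dt / (a * b));
  }
  {
    const double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    const double inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    c.xr2 = inf - (inf - c.xr2) * std::exp(-dt / (a * b));
  }
  {
    const double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    const double b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    const double inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    c.xs = inf - (inf - c.xs) * std::exp(-dt / (a * b + 80.0));
  }
  {
    const double tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    const double inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    c.r = inf - (inf - c.r) * std::exp(-dt / tau);
  }
  {
    double inf, tau;
    if (cell_type == 0) {  // endo
      inf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      tau = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    } else {
      inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
            5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    }
    c.s = inf - (inf - c.s) * std::exp(-dt / tau);
  }
  {
    const double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double g = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    const double inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    c.d = inf - (inf - c.d) * std::exp(-dt / (a * b + g));
  }
  {
    const double tau = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                       200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                       180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    const double inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    c.f = inf - (inf - c.f) * std::exp(-dt / tau);
  }
  {
    const double tau = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                       31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                       80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    const double inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    c.f2 = inf - (inf - c.f2) * std::exp(-dt / tau);
  }
  {
    const double q = 1.0 + (c.CaSS / 0.05) * (c.CaSS / 0.05);
    const double tau = 80.0 / q + 2.0;
    const double inf = 0.6 / q + 0.4;
    c.fcass = inf - (inf - c.fcass) * std::exp(-dt / tau);
  }

  c.V = V - dt * Itot;
}

}  // namespace

//' @name tp06_run
//' Run the ten Tusscher-Panfilov model on a strand (or a single cell)
//'
//' Internal engine behind the tissue-simulation wrappers.
//'
//' @keywords internal
// [[Rcpp::export(name = ".tp06_run")]]
List tp06_run(IntegerVector cell_type, double gkr_scale, double cl_ms,
              int n_beats, double dt, double dx_mm, double d_mm2_ms,
              int n_stim_nodes, double stim_amp, double stim_dur_ms,
              int n_record_beats, double record_dt_ms) {
  const int N = cell_type.size();
  if (N < 1) stop("empty cell_type map");
  if (dt > 0.05 + 1e-12) stop("dt must be <= 0.05 ms (Rush-Larsen limit)");
  if (n_record_beats > n_beats) n_record_beats = n_beats;
  std::vector<Cell> cells(N);
  for (int i = 0; i < N; ++i) cells[i] = init_cell();

  const double lam = (N > 1) ? d_mm2_ms * dt / (dx_mm * dx_mm) : 0.0;
  if (N > 1 && lam > 0.5) stop("explicit diffusion unstable: D*dt/dx^2 > 0.5");

  const long steps_per_beat = (long)std::llround(cl_ms / dt);
  const long rec_stride = (long)std::llround(record_dt_ms / dt);
  const long rec_start_beat = n_beats - n_record_beats;
  const long n_rec =
      (long)(n_record_beats * steps_per_beat / rec_stride) + 1;
  NumericMatrix Vrec(n_rec, N);
  NumericVector trec(n_rec);
  long irec = 0;

  std::vector<double> Vnew(N);
  bool blown = false;
  for (long beat = 0; beat < n_beats && !blown; ++beat) {
    for (long s = 0; s < steps_per_beat; ++s) {
      const double tbeat = s * dt;
      const double istim = (tbeat < stim_dur_ms) ? stim_amp : 0.0;
      if (beat >= rec_start_beat && (s % rec_stride) == 0 && irec < n_rec) {
        for (int i = 0; i < N; ++i) Vrec(irec, i) = cells[i].V;
        trec[irec] = (beat - rec_start_beat) * cl_ms + tbeat;
        ++irec;
      }
      for (int i = 0; i < N; ++i) {
        const double is = (i < n_stim_nodes || N == 1) ? istim : 0.0;
        step_cell(cells[i], cell_type[i], dt, is, gkr_scale);
      }
      if (N > 1 && lam > 0.0) {
        for (int i = 0; i < N; ++i) {
          const double vl = cells[i > 0 ? i - 1 : 1].V;
          const double vr = cells[i < N - 1 ? i + 1 : N - 2].V;
          Vnew[i] = cells[i].V + lam * (vl - 2.0 * cells[i].V + vr);
        }
        for (int i = 0; i < N; ++i) cells[i].V = Vnew[i];
      }
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(cells[i].V) || cells[i].V < -120.0 ||
            cells[i].V > 90.0) {
          blown = true;
          break;
        }
      }
      if (blown) break;
    }
  }
  if (blown)
    stop("integration failure: membrane potential left physiological bounds");

  if (irec < n_rec) {
    Vrec = Vrec(Range(0, std::max(0L, irec - 1)), _);
    trec = trec[Range(0, std::max(0L, irec - 1))];
  }
  NumericVector vfin(N);
  for (int i = 0; i < N; ++i) vfin[i] = cells[i].V;
  return List::create(_["time_ms"] = trec, _["V"] = Vrec,
                      _["V_final"] = vfin, _["cl_ms"] = cl_ms,
                      _["n_record_beats"] = n_record_beats);
}

// [[Rcpp::export(name = ".tp06_rest_drift")]]
double tp06_rest_drift(int cell_type, double duration_ms, double dt) {
  Cell c = init_cell();
  const double v0 = c.V;
  const long n = (long)std::llround(duration_ms / dt);
  double vmax_dev = 0.0;
  for (long s = 0; s < n; ++s) {
    step_cell(c, cell_type, dt, 0.0, 1.0);
    const double dev = std::fabs(c.V - v0);
    if (dev > vmax_dev) vmax_dev = dev;
  }
  return vmax_dev;
}
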