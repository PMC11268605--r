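// Implicit (backward-Euler) integrator for the compartmental double-cable
// equation under extracellular potential drive.
//
// Unknowns per compartment i: V_i (trans-axolemmal potential, mV) and W_i
// (periaxonal potential relative to the extracellular medium, mV). For
// unmyelinated fibers and nodes of Ranvier the periaxonal layer is shorted
// to the extracellular medium (W fixed at 0); internodal compartments carry
// a myelin sheath (Cmy, gmy) and a periaxonal axial pathway (Rp).
//
// Units: mV, ms, uA, uF, mS, kOhm (so C*dV/dt is uA and g*V is uA).
//
// Gating is advanced by exponential Euler on rates evaluated at the previous
// step's voltage; ionic currents are then linear in V so each time step is
// one banded direct solve (half-bandwidth 3 after interleaving V and W).

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y + x / 2.0;
  return x / (1.0 - std::exp(-x / y));
}

struct Rates { double inf[4]; double tau[4]; };

// mech 1: Hodgkin-Huxley (gates m, h, n, -)
static Rates hh_rates_c(double v) {
  Rates r;
  double am = 0.1 * vtrap(v + 40.0, 10.0);
  double bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  double ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  double an = 0.01 * vtrap(v + 55.0, 10.0);
  double bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  r.inf[0] = am / (am + bm); r.tau[0] = 1.0 / (am + bm);
  r.inf[1] = ah / (ah + bh); r.tau[1] = 1.0 / (ah + bh);
  r.inf[2] = an / (an + bn); r.tau[2] = 1.0 / (an + bn);
  r.inf[3] = 0.0; r.tau[3] = 1.0;
  return r;
}

// mech 2: myelinated nodal set (gates m, h, mp, s), 36 C
static Rates mrg_rates_c(double v) {
  Rates r;
  double am  = 6.57 * vtrap(v + 20.4, 10.3);
  double bm  = 0.304 * vtrap(-(v + 25.7), 9.16);
  double ah  = 0.34 * vtrap(-(v + 114.0), 11.0);
  double bh  = 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  double ap  = 0.0353 * vtrap(v + 27.0, 10.2);
  double bp  = 0.000883 * vtrap(-(v + 34.0), 10.0);
  double as_ = 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
  double bs_ = 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  r.inf[0] = am / (am + bm);   r.tau[0] = 1.0 / (am + bm);
  r.inf[1] = ah / (ah + bh);   r.tau[1] = 1.0 / (ah + bh);
  r.inf[2] = ap / (ap + bp);   r.tau[2] = 1.0 / (ap + bp);
  r.inf[3] = as_ / (as_ + bs_); r.tau[3] = 1.0 / (as_ + bs_);
  return r;
}

// Banded solve with partial pivoting (LAPACK dgbsv). The double-cable system
// is not diagonally dominant (the periaxonal row couples strongly to the
// axolemmal unknown), so pivoting is required for stability at strong drive.
// AB uses the LAPACK general-band layout with KL extra super-diagonals for
// fill-in: A(i,j) stored at AB[KL + KU + i - j + j*ldab], ldab = 2*KL+KU+1.
static void band_solve(std::vector<double>& AB, std::vector<double>& b,
                       std::vector<int>& ipiv, int N, int KB) {
  int kl = KB, ku = KB, nrhs = 1, ldab = 2 * KB + KB + 1, info = 0;
  F77_CALL(dgbsv)(&N, &kl, &ku, &nrhs, AB.data(), &ldab, ipiv.data(),
                  b.data(), &N, &info);
  if (info != 0)
    stop("banded solve failed (LAPACK dgbsv info = %d)", info);
}

// [[Rcpp::export(name = ".simulate_cable_cpp")]]
List simulate_cable_cpp(NumericVector Cm, IntegerVector mech,
                        NumericVector gpas, NumericVector epas,
                        NumericVector gna, NumericVector gk,
                        NumericVector gnap,
                        NumericVector ena, NumericVector ek,
                        NumericVector Cmy, NumericVector gmy,
                        LogicalVector wfree,
                        NumericVector Ra, NumericVector Rp,
                        NumericMatrix footprints, NumericMatrix Isrc,
                        NumericMatrix clampI, IntegerVector clampComp,
                        NumericMatrix vclampV, IntegerVector vclampComp,
                        double dt, int n_steps, int rec_every,
                        double v_init,
                        bool record_gates, bool record_imem) {
  const int n = Cm.size();
  const int N = 2 * n;
  const int KB = 3;
  const int n_src = footprints.ncol();
  const int n_clamp = clampComp.size();
  const int n_vclamp = vclampComp.size();
  const int n_rec = n_steps / rec_every + 1;

  // axial conductances (uA/mV); 0 where no connection
  std::vector<double> a(n - 1), p(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    a[i] = 1.0 / Ra[i];
    p[i] = std::isfinite(Rp[i]) ? 1.0 / Rp[i] : 0.0;
  }

  std::vector<double> V(n, v_init), W(n, 0.0), Ve(n, 0.0), VeNew(n, 0.0);
  std::vector<double> g1(n), g2(n), g3(n), g4(n);   // gates
  for (int i = 0; i < n; ++i) {
    if (mech[i] == 1) {
      Rates r = hh_rates_c(V[i]);
      g1[i] = r.inf[0]; g2[i] = r.inf[1]; g3[i] = r.inf[2]; g4[i] = 0.0;
    } else if (mech[i] == 2) {
      Rates r = mrg_rates_c(V[i]);
      g1[i] = r.inf[0]; g2[i] = r.inf[1]; g3[i] = r.inf[2]; g4[i] = r.inf[3];
    } else {
      g1[i] = g2[i] = g3[i] = g4[i] = 0.0;
    }
  }

  NumericMatrix recV(n, n_rec), recW(n, n_rec);
  NumericMatrix recI(record_imem ? n : 1, record_imem ? n_rec : 1);
  NumericMatrix recG1(record_gates ? n : 1, record_gates ? n_rec : 1);
  NumericMatrix recG2(record_gates ? n : 1, record_gates ? n_rec : 1);
  NumericMatrix recG3(record_gates ? n : 1, record_gates ? n_rec : 1);
  NumericMatrix recG4(record_gates ? n : 1, record_gates ? n_rec : 1);
  NumericVector recT(n_rec);

  std::vector<double> G(n), GE(n);

  // initial extracellular field (t = 0): sources sampled by caller at step
  // times 1..n_steps; field at t=0 taken as 0-current state unless the first
  // sample says otherwise -- use zero (stimuli evaluate to 0 before onset).
  auto record_state = [&](int ri, double t, const std::vector<double>& imem) {
    recT[ri] = t;
    for (int i = 0; i < n; ++i) {
      recV(i, ri) = V[i]; recW(i, ri) = W[i];
      if (record_imem) recI(i, ri) = imem[i];
      if (record_gates) {
        recG1(i, ri) = g1[i]; recG2(i, ri) = g2[i];
        recG3(i, ri) = g3[i]; recG4(i, ri) = g4[i];
      }
    }
  };

  // ionic linearization at current gates
  auto update_GE = [&]() {
    for (int i = 0; i < n; ++i) {
      double Gi = gpas[i], GEi = gpas[i] * epas[i];
      if (mech[i] == 1) {
        double gNa = gna[i] * g1[i] * g1[i] * g1[i] * g2[i];
        double gK = gk[i] * g3[i] * g3[i] * g3[i] * g3[i];
        Gi += gNa + gK; GEi += gNa * ena[i] + gK * ek[i];
      } else if (mech[i] == 2) {
        double gNa = gna[i] * g1[i] * g1[i] * g1[i] * g2[i];
        double gNap = gnap[i] * g3[i] * g3[i] * g3[i];
        double gK = gk[i] * g4[i];
        Gi += gNa + gNap + gK;
        GEi += (gNa + gNap) * ena[i] + gK * ek[i];
      }
      G[i] = Gi; GE[i] = GEi;
    }
  };

  update_GE();
  {
    std::vector<double> imem0(n, 0.0);
    for (int i = 0; i < n; ++i)
      imem0[i] = wfree[i] ? (gmy[i] * W[i]) : (G[i] * V[i] - GE[i]);
    record_state(0, 0.0, imem0);
  }

  const int LDAB = 3 * KB + 1;
  std::vector<double> A((size_t)LDAB * N), b(N), Vold(n), Wold(n);
  std::vector<int> ipiv(N);
  std::vector<double> imem(n, 0.0);

  for (int step = 1; step <= n_steps; ++step) {
    double t = step * dt;
    // field at compartments for this step
    for (int i = 0; i < n; ++i) VeNew[i] = 0.0;
    for (int s = 0; s < n_src; ++s) {
      double cur = Isrc(s, step - 1);
      if (cur != 0.0)
        for (int i = 0; i < n; ++i) VeNew[i] += footprints(i, s) * cur;
    }

    // gate update (exponential Euler at V^n)
    for (int i = 0; i < n; ++i) {
      if (mech[i] == 0) continue;
      Rates r = (mech[i] == 1) ? hh_rates_c(V[i]) : mrg_rates_c(V[i]);
      double e;
      e = std::exp(-dt / r.tau[0]); g1[i] = r.inf[0] + (g1[i] - r.inf[0]) * e;
      e = std::exp(-dt / r.tau[1]); g2[i] = r.inf[1] + (g2[i] - r.inf[1]) * e;
      e = std::exp(-dt / r.tau[2]); g3[i] = r.inf[2] + (g3[i] - r.inf[2]) * e;
      if (mech[i] == 2) {
        e = std::exp(-dt / r.tau[3]);
        g4[i] = r.inf[3] + (g4[i] - r.inf[3]) * e;
      }
    }
    update_GE();

    std::fill(A.begin(), A.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    auto at = [&](int row, int col) -> double& {
      return A[(size_t)col * LDAB + (2 * KB + row - col)];
    };

    for (int i = 0; i < n; ++i) {
      int rv = 2 * i, rw = 2 * i + 1;
      double aL = (i > 0) ? a[i - 1] : 0.0;
      double aR = (i < n - 1) ? a[i] : 0.0;
      double pL = (i > 0) ? p[i - 1] : 0.0;
      double pR = (i < n - 1) ? p[i] : 0.0;

      // axolemma row
      at(rv, rv) = Cm[i] / dt + G[i] + aL + aR;
      at(rv, rw) = aL + aR;
      if (i > 0)     { at(rv, rv - 2) -= aL; at(rv, rw - 2) -= aL; }
      if (i < n - 1) { at(rv, rv + 2) -= aR; at(rv, rw + 2) -= aR; }
      b[rv] = Cm[i] / dt * V[i] + GE[i];
      if (i > 0)     b[rv] += aL * (VeNew[i - 1] - VeNew[i]);
      if (i < n - 1) b[rv] += aR * (VeNew[i + 1] - VeNew[i]);

      // periaxonal row
      if (wfree[i]) {
        at(rw, rw) = Cmy[i] / dt + gmy[i] + pL + pR;
        if (i > 0)     at(rw, rw - 2) -= pL;
        if (i < n - 1) at(rw, rw + 2) -= pR;
        at(rw, rv) -= Cm[i] / dt + G[i];
        b[rw] = Cmy[i] / dt * W[i] - Cm[i] / dt * V[i] - GE[i];
        if (i > 0)     b[rw] += pL * (VeNew[i - 1] - VeNew[i]);
        if (i < n - 1) b[rw] += pR * (VeNew[i + 1] - VeNew[i]);
      } else {
        at(rw, rw) = 1.0; b[rw] = 0.0;
      }
    }

    // intracellular current clamps
    for (int c = 0; c < n_clamp; ++c)
      b[2 * clampComp[c]] += clampI(c, step - 1);

    // voltage clamps: overwrite the axolemma row
    for (int c = 0; c < n_vclamp; ++c) {
      int i = vclampComp[c], rv = 2 * i;
      for (int col = std::max(0, rv - KB); col <= std::min(N - 1, rv + KB);
           ++col)
        at(rv, col) = 0.0;
      at(rv, rv) = 1.0;
      b[rv] = vclampV(c, step - 1);
    }

    band_solve(A, b, ipiv, N, KB);

    for (int i = 0; i < n; ++i) { Vold[i] = V[i]; Wold[i] = W[i]; }
    for (int i = 0; i < n; ++i) { V[i] = b[2 * i]; W[i] = b[2 * i + 1]; }
    for (int i = 0; i < n; ++i) Ve[i] = VeNew[i];

    if (step % rec_every == 0) {
      // membrane current delivered to the extracellular medium (uA)
      for (int i = 0; i < n; ++i) {
        if (wfree[i]) {
          imem[i] = Cmy[i] * (W[i] - Wold[i]) / dt + gmy[i] * W[i];
        } else {
          double ax = Cm[i] * (V[i] - Vold[i]) / dt + G[i] * V[i] - GE[i];
          double per = 0.0;
          if (i > 0)
            per += ((i > 0 ? p[i - 1] : 0.0)) *
                   (W[i - 1] + Ve[i - 1] - Ve[i]);
          if (i < n - 1)
            per += p[i] * (W[i + 1] + Ve[i + 1] - Ve[i]);
          imem[i] = ax + per;
        }
        if (!std::isfinite(V[i]))
          stop("cable solver diverged at compartment %d, t = %.4f ms",
               i + 1, t);
      }
      record_state(step / rec_every, t, imem);
    }
  }

  List out = List::create(
    _["time"] = recT, _["V"] = recV, _["W"] = recW);
  if (record_imem) out["imem"] = recI;
  if (record_gates)
    out["gates"] = List::create(_["g1"] = recG1, _["g2"] = recG2,
                                _["g3"] = recG3, _["g4"] = recG4);
  return out;
}
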