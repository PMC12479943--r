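#include <Rcpp.h>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire neuron with an optional
// low-threshold Ca2+-like current for post-inhibitory rebound bursting.
//
// C dV/dt = -gL (V - EL) + gL * dT * exp((V - VT)/dT) - w + I_T + I_inj
// dw/dt   = (a (V - EL) - w) / tau_w
// I_T     = gT * m_inf(V) * h * (ECa - V)
// dh/dt   = (h_inf(V) - h) / tau_h          (de-inactivates when hyperpolarized)
//
// Spike emission: when the deterministic upstroke first satisfies
// dV/dt >= dvdt_crit (mV/ms) inside the exponential blow-up region
// (V > VT), a stylized waveform is painted into the trace: linear rise to
// +40 mV over 0.3 ms, then exponential decay toward the reset with time
// constant tau_spk; integration resumes from V_reset with w += b.
// The voltage at spike initiation is recorded as the ground-truth
// threshold.

// [[Rcpp::export]]
List adex_integrate_cpp(NumericVector I_inj, double dt_ms,
                        double C_pF, double gL_nS, double EL_mV,
                        double VT_mV, double dT_mV,
                        double Vreset_mV, double a_nS, double b_pA,
                        double tauw_ms,
                        double gT_nS, double ECa_mV, double tauh_ms,
                        double peak_mV, double rise_ms, double tauspk_ms,
                        double dvdt_crit) {
    int n = I_inj.size();
    NumericVector V(n);
    std::vector<double> spike_t;      // ms, time of spike initiation
    std::vector<double> spike_thr;    // mV, voltage at initiation

    double v = EL_mV, w = 0.0, h = 0.0;
    // start h at steady state for EL
    double hinf0 = 1.0 / (1.0 + std::exp((EL_mV + 72.0) / 5.0));
    h = hinf0;

    int i = 0;
    int rise_n = std::max(1, (int)std::round(rise_ms / dt_ms));
    while (i < n) {
        V[i] = v;
        // gating
        double minf = 1.0 / (1.0 + std::exp(-(v + 52.0) / 4.0));
        double hinf = 1.0 / (1.0 + std::exp((v + 72.0) / 5.0));
        double IT = gT_nS * minf * h * (ECa_mV - v);   // pA (nS * mV)
        double expo = gL_nS * dT_mV * std::exp((v - VT_mV) / dT_mV);
        // clip the exponential to keep the step finite
        if (expo > 1e4) expo = 1e4;
        double dv = (-gL_nS * (v - EL_mV) + expo - w + IT + I_inj[i]) / C_pF; // mV/ms
        double dwdt = (a_nS * (v - EL_mV) - w) / tauw_ms;
        double dh = (hinf - h) / tauh_ms;

        if (dv >= dvdt_crit && v > VT_mV) {
            // spike initiation: paint stylized waveform
            spike_t.push_back(i * dt_ms);
            spike_thr.push_back(v);
            double thr = v;
            int j = i;
            for (int k = 1; k <= rise_n && j + k < n; ++k) {
                V[j + k] = thr + (peak_mV - thr) * (double)k / rise_n;
            }
            // exponential decay from peak toward reset until within 0.5 mV
            int k = rise_n + 1;
            double vd = peak_mV;
            while (j + k < n) {
                vd = Vreset_mV + (peak_mV - Vreset_mV) *
                     std::exp(-(k - rise_n) * dt_ms / tauspk_ms);
                if (vd - Vreset_mV < 0.5) break;
                V[j + k] = vd;
                ++k;
            }
            i = j + k;            // resume after the waveform
            v = Vreset_mV;
            w += b_pA;
            // adaptation and h keep integrating implicitly; h inactivates
            // strongly during the spike:
            h = h * std::exp(-(k * dt_ms) / tauh_ms);
            continue;
        }

        v += dt_ms * dv;
        w += dt_ms * dwdt;
        h += dt_ms * dh;
        if (h < 0) h = 0;
        if (h > 1) h = 1;
        if (v < -120.0) v = -120.0;
        ++i;
    }

    return List::create(_["V"] = V,
                        _["spike_times_ms"] = wrap(spike_t),
                        _["spike_thresholds_mV"] = wrap(spike_thr));
}
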