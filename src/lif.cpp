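#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven simulation of a network of leaky integrate-and-fire neurons
// with exponential postsynaptic currents.
//
// Subthreshold dynamics between grid points are propagated exactly:
//   dV/dt = -V/tau_m + I/C_m,   dI/dt = -I/tau_s,
// current jumps (spike arrivals) are constrained to the grid. Spikes are
// detected by threshold crossing at the end of a step, the membrane is reset
// to V_r and clamped there for the absolute refractory period.
//
// Connectivity is passed in CSR layout ordered by source neuron; each
// recurrent spike is delivered to its targets `delay_steps` steps later via a
// ring buffer of pending current increments. External input is a sorted
// event list (arrival step per source spike, delay already folded in by the
// caller); each event deposits the external PSC amplitude onto the fixed
// target set of its source.
//
// `state` allows exact continuation across successive calls (used by the
// structural-plasticity loop): it carries V, I, refractory counters and the
// ring buffer of in-flight spikes. `step0` is the global index of the first
// step, so ring-buffer slots stay aligned across chunk boundaries.
//
// [[Rcpp::export]]
List simulate_lif_cpp(int n,
                      NumericVector v0,
                      IntegerVector syn_ptr,
                      IntegerVector syn_tgt,
                      NumericVector syn_amp,
                      IntegerVector ext_astep,
                      IntegerVector ext_src,
                      IntegerVector ext_ptr,
                      IntegerVector ext_tgt,
                      double ext_amp,
                      int steps,
                      double dt,
                      double tau_m,
                      double tau_s,
                      double c_m,
                      double v_r,
                      double theta,
                      int ref_steps,
                      int delay_steps,
                      double t0,
                      double step0,
                      Nullable<List> state,
                      IntegerVector record_v)
{
    if (tau_s >= tau_m)
        stop("degenerate PSC kernel: tau_s must be < tau_m");
    const double p11 = std::exp(-dt / tau_m);
    const double p22 = std::exp(-dt / tau_s);
    const double p21 = (p11 - p22) * tau_m * tau_s / ((tau_m - tau_s) * c_m);

    const int D = delay_steps + 1;
    std::vector<double> V(v0.begin(), v0.end());
    std::vector<double> I(n, 0.0);
    std::vector<int> refr(n, 0);
    std::vector<double> ring((size_t)D * n, 0.0);

    if (state.isNotNull()) {
        List st(state);
        NumericVector sV = st["V"], sI = st["I"];
        IntegerVector sR = st["refractory"];
        NumericMatrix sB = st["ring"];
        if (sV.size() != n || sB.nrow() != D)
            stop("simulation state does not match network/delay dimensions");
        for (int i = 0; i < n; ++i) {
            V[i] = sV[i]; I[i] = sI[i]; refr[i] = sR[i];
            for (int d = 0; d < D; ++d) ring[(size_t)d * n + i] = sB(d, i);
        }
    }

    std::vector<double> sp_t;
    std::vector<int> sp_id;
    sp_t.reserve(4096); sp_id.reserve(4096);

    const int nrec = record_v.size();
    NumericMatrix vtrace(nrec > 0 ? steps : 0, nrec);

    const int nev = ext_astep.size();
    int eptr = 0;
    while (eptr < nev && ext_astep[eptr] < 0) ++eptr;

    const long long g0 = (long long)step0;
    for (int s = 0; s < steps; ++s) {
        // pending recurrent arrivals scheduled for this step
        double *row = &ring[(size_t)((g0 + s) % D) * n];
        for (int i = 0; i < n; ++i) { I[i] += row[i]; row[i] = 0.0; }
        // external arrivals
        while (eptr < nev && ext_astep[eptr] == s) {
            const int src = ext_src[eptr];
            for (int k = ext_ptr[src]; k < ext_ptr[src + 1]; ++k)
                I[ext_tgt[k]] += ext_amp;
            ++eptr;
        }
        // propagate one step and detect threshold crossings
        const int slot = (int)((g0 + s + delay_steps) % D);
        double *out = &ring[(size_t)slot * n];
        for (int i = 0; i < n; ++i) {
            if (refr[i] > 0) {
                --refr[i];
                V[i] = v_r;
                I[i] *= p22;
                continue;
            }
            V[i] = p11 * V[i] + p21 * I[i];
            I[i] *= p22;
            if (V[i] >= theta) {
                sp_t.push_back(t0 + (s + 1) * dt);
                sp_id.push_back(i + 1);
                V[i] = v_r;
                refr[i] = ref_steps;
                for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k)
                    out[syn_tgt[k]] += syn_amp[k];
            }
        }
        for (int r = 0; r < nrec; ++r) vtrace(s, r) = V[record_v[r]];
        if ((s & 1023) == 0) {
            for (int i = 0; i < n; ++i)
                if (!std::isfinite(V[i]))
                    stop("membrane potential diverged at step %d (neuron %d)", s, i + 1);
        }
    }

    NumericVector fV(V.begin(), V.end()), fI(I.begin(), I.end());
    IntegerVector fR(refr.begin(), refr.end());
    NumericMatrix fB(D, n);
    for (int d = 0; d < D; ++d)
        for (int i = 0; i < n; ++i) fB(d, i) = ring[(size_t)d * n + i];

    return List::create(
        _["times"] = NumericVector(sp_t.begin(), sp_t.end()),
        _["ids"] = IntegerVector(sp_id.begin(), sp_id.end()),
        _["state"] = List::create(_["V"] = fV, _["I"] = fI,
                                  _["refractory"] = fR, _["ring"] = fB),
        _["v_trace"] = vtrace);
}

// Low-pass filtered spike signals x_i(t) = sum_k exp(-(t - t_ik)/tau_f),
// sampled on the grid t = dt_f, 2 dt_f, ..., K dt_f. Spikes must be sorted
// by time; ids are 1-based. Returns a K x n matrix (rows = sample times).
// [[Rcpp::export]]
NumericMatrix lowpass_filter_cpp(NumericVector times, IntegerVector ids,
                                 int n, double T, double tau_f, double dt_f)
{
    const int K = (int)std::floor(T / dt_f + 1e-9);
    NumericMatrix out(K, n);
    std::vector<double> x(n, 0.0);
    const double a = std::exp(-dt_f / tau_f);
    int p = 0, nsp = times.size();
    for (int k = 1; k <= K; ++k) {
        const double t = k * dt_f;
        for (int i = 0; i < n; ++i) x[i] *= a;
        while (p < nsp && times[p] <= t + 1e-12) {
            x[ids[p] - 1] += std::exp(-(t - times[p]) / tau_f);
            ++p;
        }
        for (int i = 0; i < n; ++i) out(k - 1, i) = x[i];
    }
    return out;
}

// Pearson correlation R(t) across neurons between the low-pass filtered
// responses of two runs, computed in streaming form (deviations taken from
// the instantaneous population mean of each run). Returns one value per
// sample time t = dt_f, ..., K dt_f; samples where either run has zero
// population variance are NA.
// [[Rcpp::export]]
NumericVector corr_filtered_cpp(NumericVector t1, IntegerVector id1,
                                NumericVector t2, IntegerVector id2,
                                int n, double T, double tau_f, double dt_f)
{
    const int K = (int)std::floor(T / dt_f + 1e-9);
    NumericVector R(K);
    std::vector<double> x(n, 0.0), y(n, 0.0);
    const double a = std::exp(-dt_f / tau_f);
    int p1 = 0, p2 = 0;
    const int n1 = t1.size(), n2 = t2.size();
    for (int k = 1; k <= K; ++k) {
        const double t = k * dt_f;
        for (int i = 0; i < n; ++i) { x[i] *= a; y[i] *= a; }
        while (p1 < n1 && t1[p1] <= t + 1e-12) {
            x[id1[p1] - 1] += std::exp(-(t - t1[p1]) / tau_f); ++p1;
        }
        while (p2 < n2 && t2[p2] <= t + 1e-12) {
            y[id2[p2] - 1] += std::exp(-(t - t2[p2]) / tau_f); ++p2;
        }
        double mx = 0.0, my = 0.0;
        for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
        mx /= n; my /= n;
        double sxx = 0.0, syy = 0.0, sxy = 0.0;
        for (int i = 0; i < n; ++i) {
            const double dx = x[i] - mx, dy = y[i] - my;
            sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
        }
        R[k - 1] = (sxx > 0.0 && syy > 0.0) ? sxy / std::sqrt(sxx * syy)
                                            : NA_REAL;
    }
    return R;
}
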