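#include <Rcpp.h>
using namespace Rcpp;

// Coupled backward-Euler integrator for the dendritic calcium field, the
// per-spine calcium pools, the two-threshold weight rule and (optionally) a
// passive voltage cable with a somatic integrator.
//
// Units: time s, space um, concentration uM, current pA, voltage mV.
//
// The spine ODEs are eliminated into the dendritic tridiagonal system each
// step (Schur complement), so one implicit step is a single Thomas solve of
// size n_seg. The system matrix is constant over the run; its forward
// elimination factors are computed once.
//
// Flux convention follows the printed model: the spine gains J_ds = k_d*C_d
// and loses J_sd = k_s*C_s in concentration units; the dendritic segment
// sees the same fluxes scaled by `flux_scale` (1 in paper mode, V_s/V_d in
// volume-corrected mode).

// [[Rcpp::export]]
List ca_core(int n_seg, double dx, double dt, int n_steps, double t0,
             double D, double tau_decay,
             IntegerVector spine_seg,   // 0-based, one spine per segment
             double k_d, double k_s, double flux_scale,
             NumericVector Cd0, NumericVector Cs0, NumericVector Isyn0,
             List spikes,               // per-spine sorted spike times (s)
             double I0, double tau_syn, double jsyn_coef,
             bool plasticity, NumericVector w0,
             double theta_p, double theta_d, double gamma_p, double gamma_d,
             bool voltage, double u_rest, double v_tau, double v_lambda,
             double v_csyn, double soma_tau, double R_ratio, int soma_seg,
             NumericVector ud0, double usoma0,
             int store_every, bool store_field) {
  const int n_sp = spine_seg.size();
  const double lam = D / (dx * dx);
  const double decay = (tau_decay > 0 && R_finite(tau_decay)) ? 1.0 / tau_decay : 0.0;
  const double beta = 1.0 + dt * (k_s + decay);

  // which spine (if any) sits at each segment
  std::vector<int> seg_spine(n_seg, -1);
  for (int j = 0; j < n_sp; ++j) {
    int s = spine_seg[j];
    if (s < 0 || s >= n_seg) stop("spine segment index out of range");
    if (seg_spine[s] >= 0) stop("more than one spine on a segment");
    seg_spine[s] = j;
  }

  // constant tridiagonal system (I - dt*A) for the dendrite, spine-eliminated
  const double off = -dt * lam;
  std::vector<double> diag(n_seg), cp(n_seg), m(n_seg);
  for (int i = 0; i < n_seg; ++i) {
    double nb = (i == 0 || i == n_seg - 1) ? 1.0 : 2.0; // no-flux ends
    diag[i] = 1.0 + dt * decay + dt * lam * nb;
    if (seg_spine[i] >= 0)
      diag[i] += dt * flux_scale * k_d * (1.0 - dt * k_s / beta);
  }
  if (n_seg < 2) stop("need at least 2 segments");
  m[0] = 1.0 / diag[0];
  cp[0] = off * m[0];
  for (int i = 1; i < n_seg; ++i) {
    double denom = diag[i] - off * cp[i - 1];
    if (denom == 0.0) stop("singular linear system");
    m[i] = 1.0 / denom;
    cp[i] = off * m[i];
  }

  // voltage cable factors (leak + axial coupling, backward Euler)
  std::vector<double> vcp, vm;
  const double voff = -dt * v_lambda;
  if (voltage) {
    vcp.resize(n_seg); vm.resize(n_seg);
    std::vector<double> vdiag(n_seg);
    for (int i = 0; i < n_seg; ++i) {
      double nb = (i == 0 || i == n_seg - 1) ? 1.0 : 2.0;
      vdiag[i] = 1.0 + dt / v_tau + dt * v_lambda * nb;
    }
    vm[0] = 1.0 / vdiag[0];
    vcp[0] = voff * vm[0];
    for (int i = 1; i < n_seg; ++i) {
      double denom = vdiag[i] - voff * vcp[i - 1];
      vm[i] = 1.0 / denom;
      vcp[i] = voff * vm[i];
    }
  }

  // state
  std::vector<double> Cd(Cd0.begin(), Cd0.end());
  std::vector<double> Cs(Cs0.begin(), Cs0.end());
  std::vector<double> I(Isyn0.begin(), Isyn0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> ud;
  double usoma = usoma0;
  if (voltage) ud.assign(ud0.begin(), ud0.end());
  if ((int)Cd.size() != n_seg) stop("Cd0 length mismatch");
  if ((int)Cs.size() != n_sp || (int)I.size() != n_sp || (int)w.size() != n_sp)
    stop("per-spine state length mismatch");

  // spike bookkeeping: fold spikes at or before t0 into the current state
  std::vector<const double*> sp_ptr(n_sp);
  std::vector<int> sp_n(n_sp), sp_i(n_sp, 0);
  std::vector<NumericVector> sp_keep(n_sp);
  for (int j = 0; j < n_sp; ++j) {
    sp_keep[j] = as<NumericVector>(spikes[j]);
    sp_ptr[j] = sp_keep[j].begin();
    sp_n[j] = sp_keep[j].size();
    while (sp_i[j] < sp_n[j] && sp_ptr[j][sp_i[j]] <= t0) {
      I[j] += I0 * std::exp(-(t0 - sp_ptr[j][sp_i[j]]) / tau_syn);
      ++sp_i[j];
    }
  }
  const double edt = std::exp(-dt / tau_syn);

  // storage
  int n_frames = n_steps / store_every + 1;
  NumericVector t_out(n_frames);
  NumericMatrix Cs_out(n_frames, n_sp), w_out(n_frames, n_sp);
  NumericMatrix Cd_out(store_field ? n_frames : 0, store_field ? n_seg : 0);
  NumericVector usoma_out(voltage ? n_frames : 0);
  NumericMatrix ud_out((voltage && store_field) ? n_frames : 0,
                       (voltage && store_field) ? n_seg : 0);
  int frame = 0;
  t_out[0] = t0;
  for (int j = 0; j < n_sp; ++j) { Cs_out(0, j) = Cs[j]; w_out(0, j) = w[j]; }
  if (store_field) for (int i = 0; i < n_seg; ++i) Cd_out(0, i) = Cd[i];
  if (voltage) {
    usoma_out[0] = usoma;
    if (store_field) for (int i = 0; i < n_seg; ++i) ud_out(0, i) = ud[i];
  }

  std::vector<double> d(n_seg);   // rhs / Thomas workspace
  std::vector<double> rhs_s(n_sp);

  for (int step = 0; step < n_steps; ++step) {
    const double t_next = t0 + (double)(step + 1) * dt;

    // weight update from step-start calcium (explicit Euler, then clamp)
    if (plasticity) {
      for (int j = 0; j < n_sp; ++j) {
        double dw = 0.0;
        if (Cs[j] > theta_p) dw += (1.0 - w[j]) * gamma_p;
        if (Cs[j] > theta_d) dw -= w[j] * gamma_d;
        w[j] += dt * dw;
        if (w[j] < 0.0) w[j] = 0.0;
        if (w[j] > 1.0) w[j] = 1.0;
      }
    }

    // implicit calcium step; J_syn held at its step-start value
    for (int i = 0; i < n_seg; ++i) d[i] = Cd[i];
    for (int j = 0; j < n_sp; ++j) {
      double Jsyn = jsyn_coef * I[j];
      rhs_s[j] = Cs[j] + dt * Jsyn;
      d[spine_seg[j]] += dt * flux_scale * k_s * rhs_s[j] / beta;
    }
    d[0] *= m[0];
    for (int i = 1; i < n_seg; ++i) d[i] = (d[i] - off * d[i - 1]) * m[i];
    for (int i = n_seg - 2; i >= 0; --i) d[i] -= cp[i] * d[i + 1];
    for (int j = 0; j < n_sp; ++j)
      Cs[j] = (rhs_s[j] + dt * k_d * d[spine_seg[j]]) / beta;
    std::swap(Cd, d);

    // passive cable + soma (one-way coupling, drive at step-start values)
    if (voltage) {
      for (int i = 0; i < n_seg; ++i)
        d[i] = ud[i] + dt * u_rest / v_tau;
      for (int j = 0; j < n_sp; ++j)
        d[spine_seg[j]] += dt * v_csyn * w[j] * I[j];
      d[0] *= vm[0];
      for (int i = 1; i < n_seg; ++i) d[i] = (d[i] - voff * d[i - 1]) * vm[i];
      for (int i = n_seg - 2; i >= 0; --i) d[i] -= vcp[i] * d[i + 1];
      std::swap(ud, d);
      double a = dt / soma_tau;
      usoma = (usoma + a * (u_rest + R_ratio * ud[soma_seg])) /
              (1.0 + a * (1.0 + R_ratio));
      if (!R_finite(usoma)) stop("divergent voltage: unstable cable parameters");
    }

    // synaptic current to end-of-step (exact for the exponential kernel)
    for (int j = 0; j < n_sp; ++j) {
      I[j] *= edt;
      while (sp_i[j] < sp_n[j] && sp_ptr[j][sp_i[j]] <= t_next) {
        I[j] += I0 * std::exp(-(t_next - sp_ptr[j][sp_i[j]]) / tau_syn);
        ++sp_i[j];
      }
    }

    if ((step + 1) % store_every == 0) {
      ++frame;
      t_out[frame] = t_next;
      for (int j = 0; j < n_sp; ++j) {
        Cs_out(frame, j) = Cs[j];
        w_out(frame, j) = w[j];
      }
      if (store_field) for (int i = 0; i < n_seg; ++i) Cd_out(frame, i) = Cd[i];
      if (voltage) {
        usoma_out[frame] = usoma;
        if (store_field) for (int i = 0; i < n_seg; ++i) ud_out(frame, i) = ud[i];
      }
    }
  }

  List final_state = List::create(
    _["C_d"] = NumericVector(Cd.begin(), Cd.end()),
    _["C_s"] = NumericVector(Cs.begin(), Cs.end()),
    _["I_syn"] = NumericVector(I.begin(), I.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["t"] = t0 + (double)n_steps * dt);
  if (voltage) {
    final_state["u_dend"] = NumericVector(ud.begin(), ud.end());
    final_state["u_soma"] = usoma;
  }
  List out = List::create(
    _["t"] = t_out, _["C_s"] = Cs_out, _["w"] = w_out,
    _["final"] = final_state);
  if (store_field) out["C_d"] = Cd_out;
  if (voltage) {
    out["u_soma"] = usoma_out;
    if (store_field) out["u_dend"] = ud_out;
  }
  return out;
}
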