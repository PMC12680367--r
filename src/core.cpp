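// Overdamped integrator for the coupled cell-ECM-adhesion system.
//
// State: ECM crosslink positions P (damping eta_ecm), cell organising
// centres C and vertices V (damping eta_cell), bound-integrin counts Nb
// per focal adhesion.  Positions advance by Heun's method with an adaptive
// step bounded by the stiffest spring incident to any node; Nb advances by
// an exact exponential update of the linear binding ODE with the force
// frozen over the step (unconditionally stable, preserves [0, N]).
//
// The Kelvin-Voigt dashpot of the cell segments makes the overdamped
// velocity implicit: (eta*I + D(x)) v = F_conservative, with D the sum of
// rank-one axial dashpot projectors.  Because each dashpot couples one
// vertex to its cell centre only, the system is solved exactly per cell
// via a 2x2 Schur complement at the centre (unconditionally stable).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double koff_c(double F, double kc, double Fc, double ks, double Fs) {
  double a = F / Fs;
  if (a > 500.0) a = 500.0;
  return kc * std::exp(-F / Fc) + ks * std::exp(a);
}

struct Forces {
  std::vector<double> FP, FC, FV;   // 2*k each, interleaved x,y
  std::vector<double> kP, kC, kV;   // stiffness accumulators for dt bound
  std::vector<double> ux, uy;       // segment unit axes (per vertex)
};

// [[Rcpp::export(name = ".core_run")]]
List core_run(NumericMatrix pos0, IntegerMatrix fib, NumericVector L0,
              NumericVector ref0, LogicalVector pinned,
              double EtA, double rho, double eta_ecm,
              NumericMatrix cent0, NumericMatrix vert0,
              IntegerVector vert_cell, NumericVector seg_L0,
              NumericVector cell_kseg, NumericVector cell_gseg,
              NumericVector cell_kang, NumericVector cell_Fco,
              double eta_cell,
              IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_cell,
              NumericVector ang_th0,
              NumericMatrix ext_force,
              IntegerVector fa_vert, IntegerVector fa_node,
              NumericVector fa_N, NumericVector fa_Nb0, LogicalVector fa_att0,
              double ki, double L0i,
              double Kon, double kc, double Fc, double ks, double Fs,
              double t0, double t_end, double safety, double sample_dt,
              double detach_thr, bool active, bool relax_mode, double tol,
              double fixed_dt, int max_steps, double ramp_time) {
  const int n = pos0.nrow(), m = fib.nrow();
  const int nc = cent0.nrow(), nv = vert0.nrow();
  const int na = ang_i.size(), nfa = fa_vert.size();
  const double TWOPI = 2.0 * M_PI;

  std::vector<double> P(2 * n), C(2 * nc), V(2 * nv);
  for (int i = 0; i < n; ++i) { P[2*i] = pos0(i,0); P[2*i+1] = pos0(i,1); }
  for (int i = 0; i < nc; ++i) { C[2*i] = cent0(i,0); C[2*i+1] = cent0(i,1); }
  for (int i = 0; i < nv; ++i) { V[2*i] = vert0(i,0); V[2*i+1] = vert0(i,1); }
  std::vector<double> Nb(nfa);
  std::vector<int> att(nfa);
  for (int i = 0; i < nfa; ++i) { Nb[i] = fa_Nb0[i]; att[i] = fa_att0[i] ? 1 : 0; }

  Forces f1, f2;
  f1.FP.assign(2*n,0); f1.FC.assign(2*nc,0); f1.FV.assign(2*nv,0);
  f1.kP.assign(n,0); f1.kC.assign(nc,0); f1.kV.assign(nv,0);
  f1.ux.assign(nv,0); f1.uy.assign(nv,0);
  f2 = f1;
  // velocity work arrays (filled by vel_solve)
  std::vector<double> vP1(2*n), vC1(2*nc), vV1(2*nv);
  std::vector<double> vP2(2*n), vC2(2*nc), vV2(2*nv);

  // conservative + active forces at positions (p, c, v); contraction is
  // scaled by the myosin activation ramp (pulling forces act abruptly)
  auto eval = [&](const std::vector<double>& p, const std::vector<double>& c,
                  const std::vector<double>& v, Forces& out, double tnow) {
    const double act = (ramp_time > 0.0)
      ? std::min((tnow - t0) / ramp_time, 1.0) : 1.0;
    std::fill(out.FP.begin(), out.FP.end(), 0.0);
    std::fill(out.FC.begin(), out.FC.end(), 0.0);
    std::fill(out.FV.begin(), out.FV.end(), 0.0);
    std::fill(out.kP.begin(), out.kP.end(), 0.0);
    std::fill(out.kC.begin(), out.kC.end(), 0.0);
    std::fill(out.kV.begin(), out.kV.end(), 0.0);
    // ECM fibres (bilinear springs)
    for (int e = 0; e < m; ++e) {
      const int a = fib(e,0), b = fib(e,1);
      const double dx = p[2*b] - p[2*a], dy = p[2*b+1] - p[2*a+1];
      const double len = std::sqrt(dx*dx + dy*dy);
      if (len <= 0.0)
        stop("zero-length fibre %d at t = %g", e + 1, tnow);
      const double s = (len - L0[e]) / L0[e];
      const double mod = (s >= 0.0) ? EtA : rho * EtA;
      const double T = mod * s;
      const double ux = dx / len, uy = dy / len;
      out.FP[2*a]   += T * ux; out.FP[2*a+1] += T * uy;
      out.FP[2*b]   -= T * ux; out.FP[2*b+1] -= T * uy;
      const double kf = mod / L0[e];
      out.kP[a] += kf; out.kP[b] += kf;
    }
    // cell segments: elastic spring along the axis (+ active contraction)
    for (int i = 0; i < nv; ++i) {
      const int cc = vert_cell[i];
      const double dx = v[2*i] - c[2*cc], dy = v[2*i+1] - c[2*cc+1];
      const double len = std::sqrt(dx*dx + dy*dy);
      if (len <= 0.0)
        stop("zero-length cell segment (vertex %d) at t = %g", i + 1, tnow);
      const double ux = dx / len, uy = dy / len;
      out.ux[i] = ux; out.uy[i] = uy;
      double mag = -cell_kseg[cc] * (len - seg_L0[i]);
      if (active && cell_Fco[cc] != 0.0) {
        // myosin stall: contraction tapers off below ~15% of rest length
        // so a segment can never be driven through the organising centre
        double fl = (len - 0.15 * seg_L0[i]) / (0.10 * seg_L0[i]);
        if (fl > 1.0) fl = 1.0;
        if (fl < 0.0) fl = 0.0;
        mag -= act * fl * cell_Fco[cc];
      }
      out.FV[2*i]   += mag * ux; out.FV[2*i+1] += mag * uy;
      out.FC[2*cc]   -= mag * ux; out.FC[2*cc+1] -= mag * uy;
      out.kV[i] += cell_kseg[cc]; out.kC[cc] += cell_kseg[cc];
      if (active) {
        out.FV[2*i]   += ext_force(i,0);
        out.FV[2*i+1] += ext_force(i,1);
      }
    }
    // angular restoring forces (harmonic in the signed centre angle)
    for (int a0 = 0; a0 < na; ++a0) {
      const int i = ang_i[a0], j = ang_j[a0], cc = ang_cell[a0];
      const double dix = v[2*i] - c[2*cc], diy = v[2*i+1] - c[2*cc+1];
      const double djx = v[2*j] - c[2*cc], djy = v[2*j+1] - c[2*cc+1];
      const double li2 = dix*dix + diy*diy, lj2 = djx*djx + djy*djy;
      double th = std::atan2(djy, djx) - std::atan2(diy, dix);
      while (th < 0.0) th += TWOPI;
      while (th >= TWOPI) th -= TWOPI;
      const double dev = th - ang_th0[a0];
      const double kang = cell_kang[cc];
      const double Fix =  kang * dev * (-diy) / li2;
      const double Fiy =  kang * dev * ( dix) / li2;
      const double Fjx = -kang * dev * (-djy) / lj2;
      const double Fjy = -kang * dev * ( djx) / lj2;
      out.FV[2*i]   += Fix; out.FV[2*i+1] += Fiy;
      out.FV[2*j]   += Fjx; out.FV[2*j+1] += Fjy;
      out.FC[2*cc]   -= Fix + Fjx; out.FC[2*cc+1] -= Fiy + Fjy;
      out.kV[i] += kang / li2; out.kV[j] += kang / lj2;
      out.kC[cc] += kang / li2 + kang / lj2;
    }
    // focal adhesions: parallel integrin springs, Newton pairs
    for (int q = 0; q < nfa; ++q) {
      if (!att[q]) continue;
      const int vi = fa_vert[q], l = fa_node[q];
      const double dx = v[2*vi] - p[2*l], dy = v[2*vi+1] - p[2*l+1];
      const double dist = std::sqrt(dx*dx + dy*dy);
      if (dist <= 0.0)
        stop("adhesion %d has coincident endpoints at t = %g", q + 1, tnow);
      const double eps = dist - L0i;
      const double Fmag = Nb[q] * ki * eps;
      const double ux = dx / dist, uy = dy / dist;
      out.FV[2*vi]   -= Fmag * ux; out.FV[2*vi+1] -= Fmag * uy;
      out.FP[2*l]    += Fmag * ux; out.FP[2*l+1]  += Fmag * uy;
      const double kfa = Nb[q] * ki;
      out.kV[vi] += kfa; out.kP[l] += kfa;
    }
  };

  // solve (eta*I + D) v = F for the overdamped velocities; D couples each
  // vertex to its centre through an axial dashpot projector P_i, so
  //   v_i = (1/eta)(I - c P_i) F_i + c P_i v_c,   c = gamma/(eta+gamma)
  //   (eta I + g sum P_i) v_c = F_c + (g/eta) sum P_i F_i,
  //   g = gamma*eta/(eta+gamma)
  auto vel_solve = [&](const Forces& f, std::vector<double>& vP,
                       std::vector<double>& vC, std::vector<double>& vV) {
    for (int i = 0; i < n; ++i) {
      if (pinned[i]) { vP[2*i] = 0.0; vP[2*i+1] = 0.0; continue; }
      vP[2*i] = f.FP[2*i] / eta_ecm;
      vP[2*i+1] = f.FP[2*i+1] / eta_ecm;
    }
    std::vector<double> M(4 * nc), rhs(2 * nc);
    for (int cc = 0; cc < nc; ++cc) {
      M[4*cc] = eta_cell; M[4*cc+1] = 0.0; M[4*cc+2] = 0.0; M[4*cc+3] = eta_cell;
      rhs[2*cc] = f.FC[2*cc]; rhs[2*cc+1] = f.FC[2*cc+1];
    }
    for (int i = 0; i < nv; ++i) {
      const int cc = vert_cell[i];
      const double gam = cell_gseg[cc];
      if (gam <= 0.0) continue;
      const double g = gam * eta_cell / (eta_cell + gam);
      const double ax = f.ux[i], ay = f.uy[i];
      M[4*cc]   += g * ax * ax; M[4*cc+1] += g * ax * ay;
      M[4*cc+2] += g * ay * ax; M[4*cc+3] += g * ay * ay;
      const double pf = (f.FV[2*i] * ax + f.FV[2*i+1] * ay);  // u.F_i
      rhs[2*cc]   += (g / eta_cell) * pf * ax;
      rhs[2*cc+1] += (g / eta_cell) * pf * ay;
    }
    for (int cc = 0; cc < nc; ++cc) {
      const double det = M[4*cc] * M[4*cc+3] - M[4*cc+1] * M[4*cc+2];
      vC[2*cc]   = ( M[4*cc+3] * rhs[2*cc] - M[4*cc+1] * rhs[2*cc+1]) / det;
      vC[2*cc+1] = (-M[4*cc+2] * rhs[2*cc] + M[4*cc]   * rhs[2*cc+1]) / det;
    }
    for (int i = 0; i < nv; ++i) {
      const int cc = vert_cell[i];
      const double gam = cell_gseg[cc];
      const double cfac = gam / (eta_cell + gam);
      const double ax = f.ux[i], ay = f.uy[i];
      const double pf = (f.FV[2*i] * ax + f.FV[2*i+1] * ay);
      const double pv = (vC[2*cc] * ax + vC[2*cc+1] * ay);
      vV[2*i]   = (f.FV[2*i]   - cfac * pf * ax) / eta_cell + cfac * pv * ax;
      vV[2*i+1] = (f.FV[2*i+1] - cfac * pf * ay) / eta_cell + cfac * pv * ay;
    }
  };

  // sampling setup
  const int S_max = (sample_dt > 0.0)
    ? (int)std::floor((t_end - t0) / sample_dt + 1e-9) + 2 : 2;
  NumericVector s_times(S_max);
  NumericMatrix s_P(S_max, 2*n), s_V(S_max, 2*nv), s_C(S_max, 2*nc);
  NumericMatrix s_Nb(S_max, nfa), s_F(S_max, nfa), s_eps(S_max, nfa),
                s_att(S_max, nfa);
  int S = 0;
  auto record = [&](double tnow) {
    if (S >= S_max) return;
    s_times[S] = tnow;
    for (int i = 0; i < 2*n; ++i) s_P(S,i) = P[i];
    for (int i = 0; i < 2*nv; ++i) s_V(S,i) = V[i];
    for (int i = 0; i < 2*nc; ++i) s_C(S,i) = C[i];
    for (int q = 0; q < nfa; ++q) {
      s_Nb(S,q) = Nb[q];
      s_att(S,q) = att[q];
      if (att[q]) {
        const double dx = V[2*fa_vert[q]] - P[2*fa_node[q]];
        const double dy = V[2*fa_vert[q]+1] - P[2*fa_node[q]+1];
        const double dist = std::sqrt(dx*dx + dy*dy);
        const double eps = dist - L0i;
        s_eps(S,q) = eps;
        s_F(S,q) = std::fabs(Nb[q] * ki * eps);
      } else {
        s_eps(S,q) = NA_REAL; s_F(S,q) = 0.0;
      }
    }
    ++S;
  };

  std::vector<double> ev_t; std::vector<int> ev_fa;
  std::vector<double> Pmid(2*n), Cmid(2*nc), Vmid(2*nv);
  double tnow = t0;
  double next_sample = (sample_dt > 0.0) ? t0 + sample_dt : t_end;
  record(tnow);
  bool converged = false;
  double maxF = NA_REAL;
  int steps = 0;

  while (tnow < t_end - 1e-12) {
    eval(P, C, V, f1, tnow);
    maxF = 0.0;
    for (int i = 0; i < n; ++i) if (!pinned[i]) {
      maxF = std::max(maxF, std::max(std::fabs(f1.FP[2*i]), std::fabs(f1.FP[2*i+1])));
    }
    for (int i = 0; i < 2*nv; ++i) maxF = std::max(maxF, std::fabs(f1.FV[i]));
    for (int i = 0; i < 2*nc; ++i) maxF = std::max(maxF, std::fabs(f1.FC[i]));
    if (relax_mode && maxF < tol) { converged = true; break; }

    // adaptive step from the stiffest incident spring
    double dt;
    if (fixed_dt > 0.0) {
      dt = fixed_dt;
    } else {
      double rate = 0.0;   // max k/eta over nodes
      for (int i = 0; i < n; ++i) if (!pinned[i])
        rate = std::max(rate, f1.kP[i] / eta_ecm);
      for (int i = 0; i < nv; ++i) rate = std::max(rate, f1.kV[i] / eta_cell);
      for (int i = 0; i < nc; ++i) rate = std::max(rate, f1.kC[i] / eta_cell);
      dt = (rate > 0.0) ? safety / rate : (t_end - tnow);
    }
    if (tnow + dt > next_sample) dt = next_sample - tnow;
    if (tnow + dt > t_end) dt = t_end - tnow;
    if (dt <= 0.0) dt = 1e-12;

    // Heun predictor
    vel_solve(f1, vP1, vC1, vV1);
    for (int i = 0; i < 2*n; ++i) Pmid[i] = P[i] + dt * vP1[i];
    for (int i = 0; i < 2*nv; ++i) Vmid[i] = V[i] + dt * vV1[i];
    for (int i = 0; i < 2*nc; ++i) Cmid[i] = C[i] + dt * vC1[i];
    eval(Pmid, Cmid, Vmid, f2, tnow);
    vel_solve(f2, vP2, vC2, vV2);
    for (int i = 0; i < 2*n; ++i) P[i] += dt * 0.5 * (vP1[i] + vP2[i]);
    for (int i = 0; i < 2*nv; ++i) V[i] += dt * 0.5 * (vV1[i] + vV2[i]);
    for (int i = 0; i < 2*nc; ++i) C[i] += dt * 0.5 * (vC1[i] + vC2[i]);
    tnow += dt;

    // exact exponential update of the binding ODE (force frozen over dt)
    for (int q = 0; q < nfa; ++q) {
      if (!att[q]) continue;
      const double dx = V[2*fa_vert[q]] - P[2*fa_node[q]];
      const double dy = V[2*fa_vert[q]+1] - P[2*fa_node[q]+1];
      const double eps = std::sqrt(dx*dx + dy*dy) - L0i;
      const double Fi = ki * std::max(eps, 0.0);
      const double kof = koff_c(Fi, kc, Fc, ks, Fs);
      const double lam = Kon + kof;
      const double Nstar = Kon * fa_N[q] / lam;
      Nb[q] = Nstar + (Nb[q] - Nstar) * std::exp(-lam * dt);
      if (Nb[q] < detach_thr) {    // detachment is permanent
        att[q] = 0; Nb[q] = 0.0;
        ev_t.push_back(tnow); ev_fa.push_back(q + 1);
      }
    }

    if (std::fabs(tnow - next_sample) < 1e-12) {
      record(tnow);
      next_sample += sample_dt;
      bool bad = false;
      for (int i = 0; i < 2*n && !bad; ++i) bad = !R_finite(P[i]);
      for (int i = 0; i < 2*nv && !bad; ++i) bad = !R_finite(V[i]);
      if (bad) stop("non-finite state at t = %g (diagnostic snapshot recorded)", tnow);
    }
    if (++steps >= max_steps)
      stop("step budget (%d) exhausted at t = %g (max force %g pN)",
           max_steps, tnow, maxF);
  }
  if (S == 0 || s_times[S-1] < tnow - 1e-12) record(tnow);

  NumericMatrix Pf(n,2), Vf(nv,2), Cf(nc,2), velVf(nv,2), velCf(nc,2);
  for (int i = 0; i < n; ++i) { Pf(i,0)=P[2*i]; Pf(i,1)=P[2*i+1]; }
  for (int i = 0; i < nv; ++i) { Vf(i,0)=V[2*i]; Vf(i,1)=V[2*i+1];
    velVf(i,0)=vV1[2*i]; velVf(i,1)=vV1[2*i+1]; }
  for (int i = 0; i < nc; ++i) { Cf(i,0)=C[2*i]; Cf(i,1)=C[2*i+1];
    velCf(i,0)=vC1[2*i]; velCf(i,1)=vC1[2*i+1]; }

  // trim the sample buffers to the S recorded frames (explicit copy:
  // column ranges break down for zero-column matrices)
  auto trim = [&](const NumericMatrix& mm) {
    NumericMatrix out(S, mm.ncol());
    for (int r = 0; r < S; ++r)
      for (int cidx = 0; cidx < mm.ncol(); ++cidx) out(r, cidx) = mm(r, cidx);
    return out;
  };
  NumericVector t_out(S);
  for (int r = 0; r < S; ++r) t_out[r] = s_times[r];

  return List::create(
    _["times"] = t_out,
    _["P"] = trim(s_P),
    _["V"] = trim(s_V),
    _["C"] = trim(s_C),
    _["Nb"] = trim(s_Nb),
    _["fa_force"] = trim(s_F),
    _["fa_eps"] = trim(s_eps),
    _["fa_attached"] = trim(s_att),
    _["event_times"] = wrap(ev_t), _["event_fa"] = wrap(ev_fa),
    _["pos"] = Pf, _["vertices"] = Vf, _["centres"] = Cf,
    _["vel_vertices"] = velVf, _["vel_centres"] = velCf,
    _["Nb_final"] = wrap(Nb), _["attached_final"] = wrap(att),
    _["time"] = tnow, _["steps"] = steps,
    _["converged"] = converged, _["max_force"] = maxF);
}
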