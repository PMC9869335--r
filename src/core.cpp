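// Numerical core: pair potentials, forces, dU/dlambda, Brownian dynamics.
//
// Units: lengths nm, energies kT (kT = 1), forces kT/nm, time s.
//
// System encoding (built in R, see R/forcefield.R):
//   pos    n x 3 coordinates
//   bonds  m x 5 : (i, j, r0, k, kind)  1-based; kind 1 = ENM, 2 = linker, 3 = anchor
//   pairs  p x 6 : (i, j, sigma_ij, qq, attr, cross)  1-based
//          sigma_ij = sum of radii; qq = q_i * q_j; attr = 1 if the
//          nonspecific LJ attraction applies (protein beads of different
//          proteins); cross = 1 if the pair couples the alchemical group to
//          the rest of the system (lambda-scaled)
//   params (eps_wca, eps_lj, alpha, bjerrum, debye_eff, lj_cutoff_factor)
//
// Soft-core (Beutler form): with t = (r/sigma)^6 and A = alpha*(1-lambda),
//   U_attr = 4 lam eps [ (A+t)^-2 - (A+t)^-1 ],  truncated at r = rc
//   U_wca  = U_attr(eps_wca) + lam*eps_wca,      truncated at t = 2 - A
// Both reduce to the plain truncated potentials at lambda = 1 and vanish at
// lambda = 0; finite at r = 0 for lambda < 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct PairTerms {
  double wca, lj, elec;          // energies (kT)
  double dUdr;                   // radial derivative (kT/nm)
  double dUdlam_lj, dUdlam_el;   // lambda derivatives (cross pairs only)
};

// soft-core sterics + DH electrostatics for one pair; lam in [0,1]
static inline void eval_pair(double r, double sigma, double qq, bool attr,
                             bool cross, double lam_lj, double lam_el,
                             const double* pp, PairTerms& out) {
  const double eps_w = pp[0], eps_a = pp[1], alpha = pp[2];
  const double lB = pp[3], lD = pp[4], cutf = pp[5];
  out.wca = out.lj = out.elec = 0.0;
  out.dUdr = out.dUdlam_lj = out.dUdlam_el = 0.0;

  const double lam = cross ? lam_lj : 1.0;
  if (lam > 0.0) {
    const double A = alpha * (1.0 - lam);
    const double sr = r / sigma;
    const double t = sr * sr * sr * sr * sr * sr;  // (r/sigma)^6
    const double D1 = A + t;
    const double i1 = 1.0 / D1, i2 = i1 * i1, i3 = i2 * i1;
    // WCA component, truncated at its minimum t = 2 - A, shifted by lam*eps
    if (t < 2.0 - A) {
      out.wca = 4.0 * lam * eps_w * (i2 - i1) + lam * eps_w;
      const double dUdt = 4.0 * lam * eps_w * (-2.0 * i3 + i2);
      if (r > 0.0) out.dUdr += dUdt * 6.0 * t / r;
      if (cross)
        out.dUdlam_lj += 4.0 * eps_w * (i2 - i1) + eps_w +
                         4.0 * lam * eps_w * alpha * (2.0 * i3 - i2);
    }
    // nonspecific attraction: full LJ with plain truncation at cutf*sigma
    if (attr && eps_a != 0.0) {
      const double tcut = cutf * cutf * cutf * cutf * cutf * cutf;
      if (t < tcut) {
        out.lj = 4.0 * lam * eps_a * (i2 - i1);
        const double dUdt = 4.0 * lam * eps_a * (-2.0 * i3 + i2);
        if (r > 0.0) out.dUdr += dUdt * 6.0 * t / r;
        if (cross)
          out.dUdlam_lj += 4.0 * eps_a * (i2 - i1) +
                           4.0 * lam * eps_a * alpha * (2.0 * i3 - i2);
      }
    }
  }
  // Debye-Hueckel, linear lambda interpolation; only meaningful for r > 0
  if (qq != 0.0 && r > 0.0) {
    const double u0 = lB * qq * std::exp(-r / lD) / r;  // unscaled DH
    const double le = cross ? lam_el : 1.0;
    out.elec = le * u0;
    out.dUdr += le * u0 * (-1.0 / lD - 1.0 / r);
    if (cross) out.dUdlam_el += u0;
  }
}

// struct-of-arrays copy of the system for the hot loops
struct SysData {
  int n;
  std::vector<int> bi, bj, bkind;
  std::vector<double> br0, bk;
  std::vector<int> pi, pj;
  std::vector<double> sigma, qq;
  std::vector<char> attr, cross;
  std::vector<double> rmax2;  // early-reject radius^2 per pair (Inf if charged)

  SysData(const NumericMatrix& pos, const NumericMatrix& bonds,
          const NumericMatrix& pairs, const double* pp, double lam_lj) {
    n = pos.nrow();
    const int M = bonds.nrow();
    bi.resize(M); bj.resize(M); bkind.resize(M); br0.resize(M); bk.resize(M);
    for (int b = 0; b < M; ++b) {
      bi[b] = (int)bonds(b, 0) - 1;
      bj[b] = (int)bonds(b, 1) - 1;
      br0[b] = bonds(b, 2);
      bk[b] = bonds(b, 3);
      bkind[b] = (int)bonds(b, 4) - 1;
    }
    const int P = pairs.nrow();
    pi.resize(P); pj.resize(P); sigma.resize(P); qq.resize(P);
    attr.resize(P); cross.resize(P); rmax2.resize(P);
    const double eps_a = pp[1], alpha = pp[2], cutf = pp[5];
    for (int p = 0; p < P; ++p) {
      pi[p] = (int)pairs(p, 0) - 1;
      pj[p] = (int)pairs(p, 1) - 1;
      sigma[p] = pairs(p, 2);
      qq[p] = pairs(p, 3);
      attr[p] = pairs(p, 4) != 0.0;
      cross[p] = pairs(p, 5) != 0.0;
      // largest radius with a nonzero sterics contribution at this lambda
      const double A = cross[p] ? alpha * (1.0 - lam_lj) : 0.0;
      double tmax = 2.0 - A;  // WCA truncation
      if (attr[p] && eps_a != 0.0)
        tmax = std::max(tmax, cutf * cutf * cutf * cutf * cutf * cutf);
      double rm2 = sigma[p] * sigma[p] * std::cbrt(tmax);
      if (qq[p] != 0.0) rm2 = std::numeric_limits<double>::infinity();
      rmax2[p] = rm2;
    }
  }
};

// accumulate energy terms and (optionally) forces into caller buffers
static void accumulate(const SysData& sd, const double* pos, double lam_lj,
                       double lam_el, const double* pp, double* terms,
                       double* frc, double* dudl_lj, double* dudl_el) {
  const int n = sd.n;
  for (int k = 0; k < 6; ++k) terms[k] = 0.0;
  *dudl_lj = 0.0;
  *dudl_el = 0.0;
  if (frc) std::fill(frc, frc + 3 * n, 0.0);

  for (size_t b = 0; b < sd.bi.size(); ++b) {
    const int i = sd.bi[b], j = sd.bj[b];
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      d[c] = pos[i + n * c] - pos[j + n * c];
      r2 += d[c] * d[c];
    }
    const double r = std::sqrt(r2);
    const double dr = r - sd.br0[b];
    terms[sd.bkind[b]] += 0.5 * sd.bk[b] * dr * dr;
    if (frc && r > 0.0) {
      const double f = -sd.bk[b] * dr / r;
      for (int c = 0; c < 3; ++c) {
        frc[3 * i + c] += f * d[c];
        frc[3 * j + c] -= f * d[c];
      }
    }
  }

  PairTerms pt;
  for (size_t p = 0; p < sd.pi.size(); ++p) {
    const int i = sd.pi[p], j = sd.pj[p];
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      d[c] = pos[i + n * c] - pos[j + n * c];
      r2 += d[c] * d[c];
    }
    if (r2 >= sd.rmax2[p]) continue;  // no term in range (uncharged pair)
    const double r = std::sqrt(r2);
    eval_pair(r, sd.sigma[p], sd.qq[p], sd.attr[p], sd.cross[p], lam_lj,
              lam_el, pp, pt);
    terms[3] += pt.wca;
    terms[4] += pt.lj;
    terms[5] += pt.elec;
    *dudl_lj += pt.dUdlam_lj;
    *dudl_el += pt.dUdlam_el;
    if (frc && r > 0.0) {
      const double f = -pt.dUdr / r;
      for (int c = 0; c < 3; ++c) {
        frc[3 * i + c] += f * d[c];
        frc[3 * j + c] -= f * d[c];
      }
    }
  }
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix pos, NumericMatrix bonds,
                       NumericMatrix pairs, NumericVector params,
                       double lambda_lj, double lambda_elec,
                       bool want_forces) {
  const int n = pos.nrow();
  const double* pp = &params[0];
  SysData sd(pos, bonds, pairs, pp, lambda_lj);
  double terms[6], dlj, del;
  NumericMatrix frc(want_forces ? n : 0, 3);
  std::vector<double> fbuf(want_forces ? 3 * n : 0);
  accumulate(sd, &pos[0], lambda_lj, lambda_elec, pp, terms,
             want_forces ? fbuf.data() : nullptr, &dlj, &del);
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) frc(i, c) = fbuf[3 * i + c];
  double total = 0.0;
  for (int k = 0; k < 6; ++k) total += terms[k];
  NumericVector by_term = NumericVector::create(
      _["enm"] = terms[0], _["linker_bonds"] = terms[1],
      _["anchors"] = terms[2], _["wca"] = terms[3], _["lj"] = terms[4],
      _["elec"] = terms[5]);
  return List::create(_["total"] = total, _["by_term"] = by_term,
                      _["dudl_lj"] = dlj, _["dudl_elec"] = del,
                      _["forces"] = frc);
}

// Scaled (lambda-dependent) cross-pair energy of each frame at each of K
// states, plus dU/dlambda of each frame at its own state.  frames is an
// (n x 3 x F) array.  Only cross pairs contribute: all other terms are
// identical across states and cancel in every DeltaU_ij.
// [[Rcpp::export]]
List eval_frames_cpp(NumericVector frames, NumericMatrix bonds,
                     NumericMatrix pairs, NumericVector params,
                     NumericVector lam_lj_states, NumericVector lam_el_states,
                     double own_lam_lj, double own_lam_el, int stage) {
  IntegerVector dim = frames.attr("dim");
  const int n = dim[0], F = dim[2];
  const int K = lam_lj_states.size();
  const double* pp = &params[0];
  NumericMatrix scaled(F, K);
  NumericVector dudl(F);

  const int P = pairs.nrow();
  std::vector<int> ci, cj;
  std::vector<double> cs, cq;
  std::vector<char> ca;
  for (int p = 0; p < P; ++p) {
    if (pairs(p, 5) != 0.0) {  // cross pairs only
      ci.push_back((int)pairs(p, 0) - 1);
      cj.push_back((int)pairs(p, 1) - 1);
      cs.push_back(pairs(p, 2));
      cq.push_back(pairs(p, 3));
      ca.push_back(pairs(p, 4) != 0.0);
    }
  }
  PairTerms pt;
  for (int f = 0; f < F; ++f) {
    for (size_t p = 0; p < ci.size(); ++p) {
      const int i = ci[p], j = cj[p];
      double r2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        const double d = frames[i + n * c + 3 * n * f] -
                         frames[j + n * c + 3 * n * f];
        r2 += d * d;
      }
      const double r = std::sqrt(r2);
      for (int k = 0; k < K; ++k) {
        eval_pair(r, cs[p], cq[p], ca[p], true, lam_lj_states[k],
                  lam_el_states[k], pp, pt);
        scaled(f, k) += pt.wca + pt.lj + pt.elec;
      }
      eval_pair(r, cs[p], cq[p], ca[p], true, own_lam_lj, own_lam_el, pp, pt);
      dudl[f] += (stage == 1) ? pt.dUdlam_lj : pt.dUdlam_el;
    }
  }
  return List::create(_["scaled"] = scaled, _["dudl"] = dudl);
}

// Overdamped Langevin integrator:
//   dx = (D/kT) F dt + sqrt(2 D dt) xi,  xi ~ N(0, 1) per coordinate.
// Uses R's RNG so trajectories are reproducible under set.seed().
// Frames (including the initial configuration) recorded every `stride` steps.
// [[Rcpp::export]]
List run_bd_cpp(NumericMatrix pos0, NumericMatrix bonds, NumericMatrix pairs,
                NumericVector params, double lambda_lj, double lambda_elec,
                int n_steps, int stride, double D, double dt, double kT,
                LogicalVector mobile) {
  const int n = pos0.nrow();
  const double* pp = &params[0];
  SysData sd(pos0, bonds, pairs, pp, lambda_lj);
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pos[i + n * c] = pos0(i, c);
  const double c1 = D * dt / kT;
  const double c2 = std::sqrt(2.0 * D * dt);
  const int F = n_steps / stride + 1;
  NumericVector frames(Dimension(n, 3, F));
  double terms[6], dlj, del;
  std::vector<double> frc(3 * n);

  int fidx = 0;
  for (int i = 0; i < 3 * n; ++i) frames[i] = pos[i];
  ++fidx;

  for (int step = 1; step <= n_steps; ++step) {
    accumulate(sd, pos.data(), lambda_lj, lambda_elec, pp, terms, frc.data(),
               &dlj, &del);
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) {
        const double f = frc[3 * i + c];
        if (!std::isfinite(f))
          stop("non-finite force on bead %d at step %d", i + 1, step);
        pos[i + n * c] += c1 * f + c2 * norm_rand();
      }
    }
    if (step % stride == 0) {
      for (int i = 0; i < 3 * n; ++i) frames[i + 3 * n * fidx] = pos[i];
      ++fidx;
    }
  }
  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) fin(i, c) = pos[i + n * c];
  return List::create(_["frames"] = frames, _["final"] = fin);
}

// capped steepest-descent relaxation used by the assembly shake
// [[Rcpp::export]]
NumericMatrix minimize_cpp(NumericMatrix pos0, NumericMatrix bonds,
                           NumericMatrix pairs, NumericVector params,
                           double lambda_lj, double lambda_elec, int n_iter,
                           double gamma, double max_step) {
  const int n = pos0.nrow();
  const double* pp = &params[0];
  SysData sd(pos0, bonds, pairs, pp, lambda_lj);
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pos[i + n * c] = pos0(i, c);
  double terms[6], dlj, del;
  std::vector<double> frc(3 * n);
  for (int it = 0; it < n_iter; ++it) {
    accumulate(sd, pos.data(), lambda_lj, lambda_elec, pp, terms, frc.data(),
               &dlj, &del);
    double fmax = 0.0;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(frc[i]));
    if (fmax < 1e-6) break;
    const double scale = std::min(gamma, max_step / fmax);
    for (int i = 0; i < 3 * n; ++i) pos[i] += scale * frc[i];
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = pos[i + n * c];
  return out;
}
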