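// Hot loops of the rotation-space search: the match score
//   F(q) = -sum_ij w_ij * exp(-theta_ij(q)^2 / delta^2),
// theta_ij the angle between R(q) v_i and w_j, w_ij >= 0 a weight that is
// zero for type-mismatched pairs (and may carry the length-mismatch
// factor), and its steepest-descent minimization over unit quaternions.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void quat_to_rotmat(const double *q, double R[9]) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  double w = q[0]/n, x = q[1]/n, y = q[2]/n, z = q[3]/n;
  R[0] = 1 - 2*(y*y + z*z); R[1] = 2*(x*y - w*z);     R[2] = 2*(x*z + w*y);
  R[3] = 2*(x*y + w*z);     R[4] = 1 - 2*(x*x + z*z); R[5] = 2*(y*z - w*x);
  R[6] = 2*(x*z - w*y);     R[7] = 2*(y*z + w*x);     R[8] = 1 - 2*(x*x + y*y);
}

// F at one quaternion. V: nx x 3, W: ny x 3 (row-major buffers passed as
// R column-major NumericMatrix; we index explicitly).
static double eval_F(const NumericMatrix &V, const NumericMatrix &W,
                     const NumericMatrix &wts, double delta, const double *q) {
  int nx = V.nrow(), ny = W.nrow();
  double R[9];
  quat_to_rotmat(q, R);
  double inv_d2 = 1.0 / (delta * delta);
  double F = 0.0;
  for (int i = 0; i < nx; ++i) {
    double vx = V(i,0), vy = V(i,1), vz = V(i,2);
    double ax = R[0]*vx + R[1]*vy + R[2]*vz;
    double ay = R[3]*vx + R[4]*vy + R[5]*vz;
    double az = R[6]*vx + R[7]*vy + R[8]*vz;
    for (int j = 0; j < ny; ++j) {
      double wgt = wts(i,j);
      if (wgt == 0.0) continue;
      double u = ax*W(j,0) + ay*W(j,1) + az*W(j,2);
      if (u > 1.0) u = 1.0; else if (u < -1.0) u = -1.0;
      double th = std::acos(u);
      F -= wgt * std::exp(-th*th*inv_d2);
    }
  }
  return F;
}

// F and its gradient w.r.t. the 4 quaternion components (raw, i.e. before
// projection onto the tangent space of the unit sphere). q must be unit.
static double eval_F_grad(const NumericMatrix &V, const NumericMatrix &W,
                          const NumericMatrix &wts, double delta,
                          const double *q, double grad[4]) {
  int nx = V.nrow(), ny = W.nrow();
  double R[9];
  quat_to_rotmat(q, R);
  double inv_d2 = 1.0 / (delta * delta);
  double F = 0.0;
  // M3[k][l] = dF/dR_kl accumulated over pairs
  double M3[9] = {0,0,0,0,0,0,0,0,0};
  for (int i = 0; i < nx; ++i) {
    double vx = V(i,0), vy = V(i,1), vz = V(i,2);
    double ax = R[0]*vx + R[1]*vy + R[2]*vz;
    double ay = R[3]*vx + R[4]*vy + R[5]*vz;
    double az = R[6]*vx + R[7]*vy + R[8]*vz;
    for (int j = 0; j < ny; ++j) {
      double wgt = wts(i,j);
      if (wgt == 0.0) continue;
      double u = ax*W(j,0) + ay*W(j,1) + az*W(j,2);
      if (u > 1.0) u = 1.0; else if (u < -1.0) u = -1.0;
      double th = std::acos(u);
      double g = std::exp(-th*th*inv_d2);
      F -= wgt * g;
      // dF/du = -wgt * g * 2 theta / (delta^2 sin theta): as u grows the
      // pair aligns and F decreases. theta/sin(theta) -> 1 at theta -> 0;
      // the exp factor kills the theta -> pi pole for the delta values in
      // use, but clamp sin for safety.
      double s = std::sqrt(1.0 - u*u);
      double ratio = (th < 1e-8) ? 1.0 : th / (s > 1e-12 ? s : 1e-12);
      double c = -wgt * g * 2.0 * ratio * inv_d2; // dF/du_ij
      // u = w_j^T R v_i => dF/dR_kl += c * w_j[k] * v_i[l]
      double wj[3] = { W(j,0), W(j,1), W(j,2) };
      double vi[3] = { vx, vy, vz };
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l)
          M3[3*k + l] += c * wj[k] * vi[l];
    }
  }
  // contract with dR/dq_c at unit q
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double dRw[9] = { 0, -2*z, 2*y,   2*z, 0, -2*x,   -2*y, 2*x, 0 };
  double dRx[9] = { 0, 2*y, 2*z,    2*y, -4*x, -2*w, 2*z, 2*w, -4*x };
  double dRy[9] = { -4*y, 2*x, 2*w, 2*x, 0, 2*z,    -2*w, 2*z, -4*y };
  double dRz[9] = { -4*z, -2*w, 2*x, 2*w, -4*z, 2*y, 2*x, 2*y, 0 };
  const double *dR[4] = { dRw, dRx, dRy, dRz };
  for (int c = 0; c < 4; ++c) {
    double s = 0.0;
    for (int t = 0; t < 9; ++t) s += dR[c][t] * M3[t];
    grad[c] = s;
  }
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_match_scores(NumericMatrix V, NumericMatrix W,
                               NumericMatrix wts, NumericMatrix quats,
                               double delta) {
  int m = quats.nrow();
  NumericVector out(m);
  double q[4];
  for (int r = 0; r < m; ++r) {
    q[0] = quats(r,0); q[1] = quats(r,1); q[2] = quats(r,2); q[3] = quats(r,3);
    out[r] = eval_F(V, W, wts, delta, q);
  }
  return out;
}

// Raw 4-component gradient dF/dq at a unit quaternion (before tangent
// projection). Exposed for finite-difference verification in the tests.
// [[Rcpp::export]]
NumericVector cpp_match_grad(NumericMatrix V, NumericMatrix W,
                             NumericMatrix wts, NumericVector q0,
                             double delta) {
  double q[4] = { q0[0], q0[1], q0[2], q0[3] };
  double g[4];
  eval_F_grad(V, W, wts, delta, q, g);
  return NumericVector::create(g[0], g[1], g[2], g[3]);
}

// [[Rcpp::export]]
List cpp_descend(NumericMatrix V, NumericMatrix W, NumericMatrix wts,
                 NumericVector q0, double delta, double grad_tol, int max_iter) {
  double q[4] = { q0[0], q0[1], q0[2], q0[3] };
  double n0 = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int c = 0; c < 4; ++c) q[c] /= n0;
  double F = eval_F(V, W, wts, delta, q);
  double step = 0.25;
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    double g[4];
    eval_F_grad(V, W, wts, delta, q, g);
    // project onto the tangent space at q
    double gq = g[0]*q[0] + g[1]*q[1] + g[2]*q[2] + g[3]*q[3];
    for (int c = 0; c < 4; ++c) g[c] -= gq * q[c];
    double gn = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2] + g[3]*g[3]);
    if (gn < grad_tol) { converged = true; break; }
    double d[4];
    for (int c = 0; c < 4; ++c) d[c] = -g[c] / gn;
    // backtracking line search with step memory (grow then halve)
    double s = std::min(2.0 * step, 1.0);
    bool accepted = false;
    double qn[4], Fn = F;
    while (s > 1e-14) {
      double cand[4];
      double nn = 0.0;
      for (int c = 0; c < 4; ++c) { cand[c] = q[c] + s * d[c]; nn += cand[c]*cand[c]; }
      nn = std::sqrt(nn);
      for (int c = 0; c < 4; ++c) cand[c] /= nn;
      double Fc = eval_F(V, W, wts, delta, cand);
      if (Fc < F - 1e-4 * s * gn) {
        for (int c = 0; c < 4; ++c) qn[c] = cand[c];
        Fn = Fc; accepted = true; break;
      }
      s *= 0.5;
    }
    if (!accepted) { converged = true; break; } // no descent direction progress
    for (int c = 0; c < 4; ++c) q[c] = qn[c];
    F = Fn;
    step = s;
    if (!std::isfinite(F)) stop("non-finite match score during descent");
  }
  NumericVector qout(4);
  for (int c = 0; c < 4; ++c) qout[c] = q[c];
  return List::create(_["q"] = qout, _["F"] = F,
                      _["iterations"] = it, _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_descend_batch(NumericMatrix V, NumericMatrix W, NumericMatrix wts,
                       NumericMatrix q0s, double delta, double grad_tol,
                       int max_iter) {
  int m = q0s.nrow();
  NumericMatrix qs(m, 4);
  NumericVector Fs(m);
  for (int r = 0; r < m; ++r) {
    NumericVector q0 = q0s(r, _);
    List res = cpp_descend(V, W, wts, q0, delta, grad_tol, max_iter);
    NumericVector q = res["q"];
    for (int c = 0; c < 4; ++c) qs(r, c) = q[c];
    Fs[r] = as<double>(res["F"]);
  }
  return List::create(_["q"] = qs, _["F"] = Fs);
}

// Initial-guess enumeration: ordered vector pairs (i, j), i < j <= i+m in
// X and same-type pairs (k, l), k < l <= k+m in Y; the guess maps v_i onto
// w_k and plane(v_i, v_j) onto plane(w_k, w_l). Near-collinear generator
// pairs are skipped; near-duplicate rotations (within dedup_eps degrees)
// are removed greedily in enumeration order.
static void frame_from_pair(const double *a, const double *b, double E[9]) {
  // columns e1, e2, e3 (stored row-major: E[3*r + c] = e_{c+1}[r])
  double e1[3] = { a[0], a[1], a[2] };
  double d = b[0]*e1[0] + b[1]*e1[1] + b[2]*e1[2];
  double e2[3] = { b[0] - d*e1[0], b[1] - d*e1[1], b[2] - d*e1[2] };
  double n = std::sqrt(e2[0]*e2[0] + e2[1]*e2[1] + e2[2]*e2[2]);
  for (int c = 0; c < 3; ++c) e2[c] /= n;
  double e3[3] = { e1[1]*e2[2] - e1[2]*e2[1],
                   e1[2]*e2[0] - e1[0]*e2[2],
                   e1[0]*e2[1] - e1[1]*e2[0] };
  for (int r = 0; r < 3; ++r) {
    E[3*r + 0] = e1[r]; E[3*r + 1] = e2[r]; E[3*r + 2] = e3[r];
  }
}

static void rotmat_to_quat(const double R[9], double q[4]) {
  double tr = R[0] + R[4] + R[8];
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    q[0] = 0.25*s; q[1] = (R[7]-R[5])/s; q[2] = (R[2]-R[6])/s; q[3] = (R[3]-R[1])/s;
  } else if (R[0] >= R[4] && R[0] >= R[8]) {
    double s = std::sqrt(1.0 + R[0] - R[4] - R[8]) * 2.0;
    q[0] = (R[7]-R[5])/s; q[1] = 0.25*s; q[2] = (R[1]+R[3])/s; q[3] = (R[2]+R[6])/s;
  } else if (R[4] >= R[8]) {
    double s = std::sqrt(1.0 + R[4] - R[0] - R[8]) * 2.0;
    q[0] = (R[2]-R[6])/s; q[1] = (R[1]+R[3])/s; q[2] = 0.25*s; q[3] = (R[5]+R[7])/s;
  } else {
    double s = std::sqrt(1.0 + R[8] - R[0] - R[4]) * 2.0;
    q[0] = (R[3]-R[1])/s; q[1] = (R[2]+R[6])/s; q[2] = (R[5]+R[7])/s; q[3] = 0.25*s;
  }
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int c = 0; c < 4; ++c) q[c] /= n;
}

// [[Rcpp::export]]
NumericMatrix cpp_initial_rotations(NumericMatrix V, IntegerVector tV,
                                    NumericMatrix W, IntegerVector tW,
                                    int m, double collinear_eps_deg,
                                    double dedup_eps_deg) {
  int nx = V.nrow(), ny = W.nrow();
  double cos_coll = std::cos(collinear_eps_deg * M_PI / 180.0);
  double cos_half = std::cos(dedup_eps_deg * M_PI / 360.0);
  std::vector<std::array<int,2> > px, py;
  for (int i = 0; i + 1 < nx; ++i)
    for (int j = i + 1; j < std::min(nx, i + m + 1); ++j) {
      double d = V(i,0)*V(j,0) + V(i,1)*V(j,1) + V(i,2)*V(j,2);
      if (std::fabs(d) < cos_coll) px.push_back({{i, j}});
    }
  for (int k = 0; k + 1 < ny; ++k)
    for (int l = k + 1; l < std::min(ny, k + m + 1); ++l) {
      double d = W(k,0)*W(l,0) + W(k,1)*W(l,1) + W(k,2)*W(l,2);
      if (std::fabs(d) < cos_coll) py.push_back({{k, l}});
    }
  std::vector<double> kept;  // flat quats
  for (size_t a = 0; a < px.size(); ++a) {
    double va[3] = { V(px[a][0],0), V(px[a][0],1), V(px[a][0],2) };
    double vb[3] = { V(px[a][1],0), V(px[a][1],1), V(px[a][1],2) };
    double Ex[9];
    frame_from_pair(va, vb, Ex);
    for (size_t b = 0; b < py.size(); ++b) {
      if (tV[px[a][0]] != tW[py[b][0]] || tV[px[a][1]] != tW[py[b][1]]) continue;
      double wa[3] = { W(py[b][0],0), W(py[b][0],1), W(py[b][0],2) };
      double wb[3] = { W(py[b][1],0), W(py[b][1],1), W(py[b][1],2) };
      double Ey[9];
      frame_from_pair(wa, wb, Ey);
      // R = Ey * Ex^T
      double R[9];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          R[3*r + c] = Ey[3*r+0]*Ex[3*c+0] + Ey[3*r+1]*Ex[3*c+1] + Ey[3*r+2]*Ex[3*c+2];
      double q[4];
      rotmat_to_quat(R, q);
      bool dup = false;
      for (size_t t = 0; t < kept.size(); t += 4) {
        double d = std::fabs(q[0]*kept[t] + q[1]*kept[t+1] + q[2]*kept[t+2] + q[3]*kept[t+3]);
        if (d >= cos_half) { dup = true; break; }
      }
      if (!dup) { kept.push_back(q[0]); kept.push_back(q[1]); kept.push_back(q[2]); kept.push_back(q[3]); }
    }
  }
  int nkept = kept.size() / 4;
  NumericMatrix out(nkept, 4);
  for (int r = 0; r < nkept; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = kept[4*r + c];
  return out;
}

// Order-preserving alignment DP with gap-opening penalty and free
// extension. mode: 0 = global, 1 = semiglobal (free end gaps), 2 = local.
// States: 1 = M (match), 2 = Ix (query SSE unmatched), 3 = Iy (target
// SSE unmatched). Ties break match > Ix > Iy for determinism.
// [[Rcpp::export]]
List cpp_align(NumericMatrix S, double gap_open, int mode) {
  int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  int N1 = n + 1, M1 = m + 1;
  std::vector<double> M(N1*M1, NEG), Ix(N1*M1, NEG), Iy(N1*M1, NEG);
  std::vector<int> pM(N1*M1, 0), pIx(N1*M1, 0), pIy(N1*M1, 0);
  #define AT(i,j) ((i)*M1 + (j))
  M[AT(0,0)] = 0.0;
  if (mode != 2) {
    double edge = (mode == 0) ? gap_open : 0.0;
    for (int i = 1; i <= n; ++i) { Ix[AT(i,0)] = edge; pIx[AT(i,0)] = (i == 1) ? 1 : 2; }
    for (int j = 1; j <= m; ++j) { Iy[AT(0,j)] = edge; pIy[AT(0,j)] = (j == 1) ? 1 : 3; }
  } else {
    for (int i = 0; i <= n; ++i) M[AT(i,0)] = 0.0;
    for (int j = 0; j <= m; ++j) M[AT(0,j)] = 0.0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double c1 = M[AT(i-1,j-1)], c2 = Ix[AT(i-1,j-1)], c3 = Iy[AT(i-1,j-1)];
      double best = c1; int bs = 1;
      if (c2 > best) { best = c2; bs = 2; }
      if (c3 > best) { best = c3; bs = 3; }
      if (mode == 2 && best < 0) { best = 0.0; bs = 0; }
      M[AT(i,j)] = S(i-1, j-1) + best;
      pM[AT(i,j)] = bs;
      double g1 = M[AT(i-1,j)] + gap_open, g2 = Ix[AT(i-1,j)], g3 = Iy[AT(i-1,j)] + gap_open;
      best = g1; bs = 1;
      if (g2 > best) { best = g2; bs = 2; }
      if (g3 > best) { best = g3; bs = 3; }
      Ix[AT(i,j)] = best; pIx[AT(i,j)] = bs;
      double h1 = M[AT(i,j-1)] + gap_open, h2 = Ix[AT(i,j-1)] + gap_open, h3 = Iy[AT(i,j-1)];
      best = h1; bs = 1;
      if (h2 > best) { best = h2; bs = 2; }
      if (h3 > best) { best = h3; bs = 3; }
      Iy[AT(i,j)] = best; pIy[AT(i,j)] = bs;
    }
  }
  double score; int ci, cj, cs;
  if (mode == 0) {
    score = M[AT(n,m)]; ci = n; cj = m; cs = 1;
    if (Ix[AT(n,m)] > score) { score = Ix[AT(n,m)]; cs = 2; }
    if (Iy[AT(n,m)] > score) { score = Iy[AT(n,m)]; cs = 3; }
  } else if (mode == 1) {
    score = NEG; ci = n; cj = m; cs = 1;
    for (int j = 0; j <= m; ++j)
      for (int s = 1; s <= 3; ++s) {
        double v = (s == 1 ? M : (s == 2 ? Ix : Iy))[AT(n,j)];
        if (v > score) { score = v; ci = n; cj = j; cs = s; }
      }
    for (int i = 0; i <= n; ++i)
      for (int s = 1; s <= 3; ++s) {
        double v = (s == 1 ? M : (s == 2 ? Ix : Iy))[AT(i,m)];
        if (v > score) { score = v; ci = i; cj = m; cs = s; }
      }
  } else {
    score = 0.0; ci = 0; cj = 0; cs = 1;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M[AT(i,j)] > score) { score = M[AT(i,j)]; ci = i; cj = j; }
  }
  std::vector<int> pi, pj;
  int gap_count = 0;
  int i = ci, j = cj, s = cs;
  while (i > 0 || j > 0) {
    if (s == 1) {
      if (i == 0 || j == 0) break;  // border M cells hold no pair
      pi.push_back(i); pj.push_back(j);
      int ps = pM[AT(i,j)];
      --i; --j;
      if (mode == 2 && ps == 0) break;
      s = ps;
    } else if (s == 2) {
      int ps = pIx[AT(i,j)];
      if (ps != 2) ++gap_count;
      --i; s = ps;
    } else {
      int ps = pIy[AT(i,j)];
      if (ps != 3) ++gap_count;
      --j; s = ps;
    }
  }
  int k = pi.size();
  IntegerMatrix pairs(k, 2);
  double total = 0.0;
  for (int t = 0; t < k; ++t) {
    pairs(t, 0) = pi[k - 1 - t];
    pairs(t, 1) = pj[k - 1 - t];
    total += S(pairs(t,0) - 1, pairs(t,1) - 1);
  }
  return List::create(_["pairs"] = pairs, _["total_score"] = total,
                      _["dp_score"] = score, _["gap_count"] = gap_count);
  #undef AT
}
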