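#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Voxel geometry helper. `origin` is the physical position of the centre of
// voxel [1,1,1]; `lo` is the lower corner of the grid bounding box.
struct Geom {
  int nx, ny, nz;
  double sx, sy, sz;
  double lox, loy, loz;
  Geom(const IntegerVector& dims, const NumericVector& spacing,
       const NumericVector& origin) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    sx = spacing[0]; sy = spacing[1]; sz = spacing[2];
    lox = origin[0] - 0.5 * sx;
    loy = origin[1] - 0.5 * sy;
    loz = origin[2] - 0.5 * sz;
  }
  double hix() const { return lox + nx * sx; }
  double hiy() const { return loy + ny * sy; }
  double hiz() const { return loz + nz * sz; }
};

// Clip ray p0 + t*dir against the grid box; returns false if it misses.
static bool clip_ray(const Geom& g, const double* p0, const double* dir,
                     double& t0, double& t1) {
  t0 = 0.0; t1 = R_PosInf;
  const double lo[3] = {g.lox, g.loy, g.loz};
  const double hi[3] = {g.hix(), g.hiy(), g.hiz()};
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(dir[k]) < 1e-12) {
      if (p0[k] < lo[k] || p0[k] >= hi[k]) return false;
    } else {
      double ta = (lo[k] - p0[k]) / dir[k];
      double tb = (hi[k] - p0[k]) / dir[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  return t1 > t0;
}

// Amanatides-Woo voxel traversal: record every voxel crossed with its entry
// and exit ray parameters. `dir` must be unit length so t is in mm.
static void traverse(const Geom& g, const double* p0, const double* dir,
                     std::vector<int>& idx, std::vector<double>& tin,
                     std::vector<double>& tout) {
  idx.clear(); tin.clear(); tout.clear();
  double t0, t1;
  if (!clip_ray(g, p0, dir, t0, t1)) return;
  const double eps = 1e-9;
  double q[3] = {p0[0] + (t0 + eps) * dir[0],
                 p0[1] + (t0 + eps) * dir[1],
                 p0[2] + (t0 + eps) * dir[2]};
  int i = (int)std::floor((q[0] - g.lox) / g.sx);
  int j = (int)std::floor((q[1] - g.loy) / g.sy);
  int k = (int)std::floor((q[2] - g.loz) / g.sz);
  i = std::max(0, std::min(g.nx - 1, i));
  j = std::max(0, std::min(g.ny - 1, j));
  k = std::max(0, std::min(g.nz - 1, k));
  int si = dir[0] > 0 ? 1 : -1, sj = dir[1] > 0 ? 1 : -1,
      sk = dir[2] > 0 ? 1 : -1;
  double tmx, tmy, tmz, tdx, tdy, tdz;
  if (std::fabs(dir[0]) < 1e-12) { tmx = R_PosInf; tdx = R_PosInf; }
  else {
    double bx = g.lox + (i + (si > 0 ? 1 : 0)) * g.sx;
    tmx = (bx - p0[0]) / dir[0];
    tdx = g.sx / std::fabs(dir[0]);
  }
  if (std::fabs(dir[1]) < 1e-12) { tmy = R_PosInf; tdy = R_PosInf; }
  else {
    double by = g.loy + (j + (sj > 0 ? 1 : 0)) * g.sy;
    tmy = (by - p0[1]) / dir[1];
    tdy = g.sy / std::fabs(dir[1]);
  }
  if (std::fabs(dir[2]) < 1e-12) { tmz = R_PosInf; tdz = R_PosInf; }
  else {
    double bz = g.loz + (k + (sk > 0 ? 1 : 0)) * g.sz;
    tmz = (bz - p0[2]) / dir[2];
    tdz = g.sz / std::fabs(dir[2]);
  }
  double tcur = t0;
  while (tcur < t1 - 1e-9) {
    double tnext = std::min(std::min(tmx, tmy), std::min(tmz, t1));
    if (tnext <= tcur) tnext = tcur + 1e-9;
    idx.push_back(i + g.nx * (j + g.ny * k));
    tin.push_back(tcur);
    tout.push_back(tnext);
    if (tmx <= tmy && tmx <= tmz) { i += si; tmx += tdx; }
    else if (tmy <= tmz)          { j += sj; tmy += tdy; }
    else                          { k += sk; tmz += tdz; }
    tcur = tnext;
    if (i < 0 || i >= g.nx || j < 0 || j >= g.ny || k < 0 || k >= g.nz) break;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_trace_ray(NumericVector rsp, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericVector p0, NumericVector dir) {
  Geom g(dims, spacing, origin);
  std::vector<int> idx; std::vector<double> tin, tout;
  double P[3] = {p0[0], p0[1], p0[2]};
  double D[3] = {dir[0], dir[1], dir[2]};
  traverse(g, P, D, idx, tin, tout);
  int n = (int)idx.size();
  NumericMatrix out(n, 4);
  double w = 0.0;
  for (int m = 0; m < n; ++m) {
    w += rsp[idx[m]] * (tout[m] - tin[m]);
    out(m, 0) = idx[m] + 1;  // 1-based linear index
    out(m, 1) = tin[m];
    out(m, 2) = tout[m];
    out(m, 3) = w;
  }
  colnames(out) = CharacterVector::create("idx", "t_in", "t_out", "wepl");
  return out;
}

// For each ray (shared unit direction), the cumulative WEPL from grid entry
// to the distal exit of `mask`, plus the geometric chord length inside the
// mask. Rays that never enter the mask get NA.
// [[Rcpp::export]]
NumericMatrix cpp_det_rays(NumericVector rsp, LogicalVector mask,
                           IntegerVector dims, NumericVector spacing,
                           NumericVector origin, NumericMatrix p0s,
                           NumericVector dir) {
  Geom g(dims, spacing, origin);
  double D[3] = {dir[0], dir[1], dir[2]};
  int nray = p0s.nrow();
  NumericMatrix out(nray, 2);
  std::vector<int> idx; std::vector<double> tin, tout;
  for (int r = 0; r < nray; ++r) {
    double P[3] = {p0s(r, 0), p0s(r, 1), p0s(r, 2)};
    traverse(g, P, D, idx, tin, tout);
    double w = 0.0, wexit = NA_REAL, chord = 0.0;
    for (size_t m = 0; m < idx.size(); ++m) {
      w += rsp[idx[m]] * (tout[m] - tin[m]);
      if (mask[idx[m]]) {
        wexit = w;  // keep updating: last masked voxel = distal exit
        chord += tout[m] - tin[m];
      }
    }
    out(r, 0) = chord > 0 ? wexit : NA_REAL;
    out(r, 1) = chord;
  }
  colnames(out) = CharacterVector::create("wepl_exit", "chord");
  return out;
}

// ---- pencil-beam dose deposition ------------------------------------------

// Per-energy integral-depth-dose table unpacked from an R list.
struct Etab {
  double step;                 // depth sampling step (mm)
  const double* vals;          // relative dose vs WEPL depth
  int n;
  double range;                // R(E) in mm water
  double wcut;                 // support cutoff R + 4*sigma_R
  double norm;                 // peak central-axis dose in uniform water
};

static inline double interp_tab(const Etab& e, double w) {
  if (w < 0.0 || w >= e.wcut) return 0.0;
  double x = w / e.step;
  int i = (int)x;
  if (i >= e.n - 1) return e.vals[e.n - 1];
  double f = x - i;
  return e.vals[i] * (1.0 - f) + e.vals[i + 1] * f;
}

// Lateral Gaussian sigma at WEPL depth w for a beam of water range R.
static inline double lat_sigma2(double w, double R, double sig_air,
                                double mcs_frac) {
  double x = w / R;
  double smcs2 = mcs_frac * mcs_frac * R * R * x * x * x;  // (f*R*(w/R)^1.5)^2
  return sig_air * sig_air + smcs2;
}

// Shared spot loop: transforms evaluation points to the beam frame of one
// gantry angle, traces each spot's central axis for WEPL, and calls
// deposit(point, spot, dose_per_unit_weight * weight).
template <typename F>
static void spot_loop(const NumericVector& rsp, const Geom& g,
                      const NumericMatrix& pts, const NumericVector& iso,
                      double angle_deg, const NumericVector& su,
                      const NumericVector& sv, const IntegerVector& eid,
                      const NumericVector& wt, const std::vector<Etab>& et,
                      double sig_air, double mcs_frac, double cutoff_sigma,
                      F&& deposit) {
  const double a = angle_deg * M_PI / 180.0;
  // gantry 0 travels +y; angles increase counter-clockwise in the axial plane
  const double dir[3] = {-std::sin(a), std::cos(a), 0.0};
  const double ux[3] = {std::cos(a), std::sin(a), 0.0};  // BEV u axis
  // BEV v axis is +z
  const int npt = pts.nrow(), nspot = su.size();
  if (npt == 0 || nspot == 0) return;

  // beam-frame coordinates of evaluation points (relative to isocenter)
  std::vector<double> pu(npt), pv(npt), pt_t(npt);
  for (int i = 0; i < npt; ++i) {
    double dx = pts(i, 0) - iso[0], dy = pts(i, 1) - iso[1],
           dz = pts(i, 2) - iso[2];
    pu[i] = dx * ux[0] + dy * ux[1];
    pv[i] = dz;
    pt_t[i] = dx * dir[0] + dy * dir[1];
  }

  // lateral search window per spot and the max over spots (bin cell size)
  std::vector<double> win(nspot);
  double wmax = 0.0;
  for (int jx = 0; jx < nspot; ++jx) {
    const Etab& e = et[eid[jx] - 1];
    win[jx] = cutoff_sigma *
              std::sqrt(lat_sigma2(e.wcut, e.range, sig_air, mcs_frac));
    wmax = std::max(wmax, win[jx]);
  }
  double umin = *std::min_element(pu.begin(), pu.end());
  double umax = *std::max_element(pu.begin(), pu.end());
  double vmin = *std::min_element(pv.begin(), pv.end());
  double vmax = *std::max_element(pv.begin(), pv.end());
  double cell = std::max(wmax, 1.0);
  int ncu = std::max(1, (int)((umax - umin) / cell) + 1);
  int ncv = std::max(1, (int)((vmax - vmin) / cell) + 1);
  // counting-sort points into 2D bins over (pu, pv)
  std::vector<int> cnt(ncu * ncv + 1, 0), order(npt), start(ncu * ncv + 1, 0);
  std::vector<int> cidx(npt);
  for (int i = 0; i < npt; ++i) {
    int cu = std::min(ncu - 1, (int)((pu[i] - umin) / cell));
    int cv = std::min(ncv - 1, (int)((pv[i] - vmin) / cell));
    cidx[i] = cu + ncu * cv;
    cnt[cidx[i] + 1]++;
  }
  for (int c = 0; c < ncu * ncv; ++c) start[c + 1] = start[c] + cnt[c + 1];
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int i = 0; i < npt; ++i) order[fill[cidx[i]]++] = i;

  // distance from isocenter at which spot rays start (outside the grid)
  double rg = 0.0;
  double cx[2] = {g.lox, g.hix()}, cy[2] = {g.loy, g.hiy()},
         cz[2] = {g.loz, g.hiz()};
  for (int ix = 0; ix < 2; ++ix)
    for (int iy = 0; iy < 2; ++iy)
      for (int iz = 0; iz < 2; ++iz) {
        double dx = cx[ix] - iso[0], dy = cy[iy] - iso[1], dz = cz[iz] - iso[2];
        rg = std::max(rg, std::sqrt(dx * dx + dy * dy + dz * dz));
      }
  const double tback = rg + 10.0;

  const double wdt = 0.25;  // WEPL lookup table step along the axis (mm)
  std::vector<int> vidx; std::vector<double> vtin, vtout, wtab;
  const double inv2pi = 1.0 / (2.0 * M_PI);

  for (int jx = 0; jx < nspot; ++jx) {
    if (wt[jx] == 0.0) continue;
    const Etab& e = et[eid[jx] - 1];
    // central-axis ray
    double P[3] = {iso[0] + ux[0] * su[jx] - dir[0] * tback,
                   iso[1] + ux[1] * su[jx] - dir[1] * tback,
                   iso[2] + sv[jx] - dir[2] * tback};
    traverse(g, P, dir, vidx, vtin, vtout);
    if (vidx.empty()) continue;  // beam misses the grid: zero dose
    double tstop = vtout.back();
    int ntab = (int)(tstop / wdt) + 2;
    wtab.assign(ntab, 0.0);
    {
      double wcum = 0.0;
      size_t m = 0;
      double wprev_t = 0.0, wprev = 0.0;
      // cumulative WEPL is piecewise linear in t; sample it on a uniform grid
      for (int q = 1; q < ntab; ++q) {
        double t = q * wdt;
        while (m < vidx.size() && vtout[m] <= t) {
          wcum += rsp[vidx[m]] * (vtout[m] - vtin[m]);
          wprev_t = vtout[m];
          wprev = wcum;
          ++m;
        }
        double w = wprev;
        if (m < vidx.size() && vtin[m] < t)
          w += rsp[vidx[m]] * (t - std::max(vtin[m], wprev_t));
        wtab[q] = w;
      }
    }
    const double wj = win[jx], u0 = su[jx], v0 = sv[jx];
    int cu0 = std::max(0, (int)((u0 - wj - umin) / cell));
    int cu1 = std::min(ncu - 1, (int)((u0 + wj - umin) / cell));
    int cv0 = std::max(0, (int)((v0 - wj - vmin) / cell));
    int cv1 = std::min(ncv - 1, (int)((v0 + wj - vmin) / cell));
    if (u0 + wj < umin || u0 - wj > umax || v0 + wj < vmin || v0 - wj > vmax)
      continue;
    for (int cv = cv0; cv <= cv1; ++cv)
      for (int cu = cu0; cu <= cu1; ++cu) {
        int c = cu + ncu * cv;
        for (int s = start[c]; s < start[c] + cnt[c + 1]; ++s) {
          int i = order[s];
          double du = pu[i] - u0, dv = pv[i] - v0;
          if (std::fabs(du) > wj || std::fabs(dv) > wj) continue;
          double t = pt_t[i] + tback;
          if (t < 0.0 || t >= tstop) continue;
          double x = t / wdt;
          int q = (int)x;
          double f = x - q;
          double w = (q + 1 < ntab) ? wtab[q] * (1.0 - f) + wtab[q + 1] * f
                                    : wtab[ntab - 1];
          double d0 = interp_tab(e, w);
          if (d0 <= 0.0) continue;
          double s2 = lat_sigma2(w, e.range, sig_air, mcs_frac);
          double gsn = std::exp(-(du * du + dv * dv) / (2.0 * s2)) *
                       inv2pi / s2;
          deposit(i, jx, wt[jx] * d0 * gsn / e.norm);
        }
      }
  }
}

static std::vector<Etab> unpack_etab(const List& etab) {
  std::vector<Etab> et(etab.size());
  for (int k = 0; k < etab.size(); ++k) {
    List e = etab[k];
    NumericVector vals = e["vals"];
    et[k].step = as<double>(e["step"]);
    et[k].vals = REAL(vals);
    et[k].n = vals.size();
    et[k].range = as<double>(e["range"]);
    et[k].wcut = as<double>(e["wcut"]);
    et[k].norm = as<double>(e["norm"]);
  }
  return et;
}

// Dose at arbitrary evaluation points from all spots of one gantry angle.
// [[Rcpp::export]]
NumericVector cpp_dose_points_angle(NumericVector rsp, IntegerVector dims,
                                    NumericVector spacing,
                                    NumericVector origin, NumericMatrix pts,
                                    NumericVector iso, double angle_deg,
                                    NumericVector su, NumericVector sv,
                                    IntegerVector eid, NumericVector wt,
                                    List etab, double sigma_air,
                                    double mcs_frac, double cutoff_sigma) {
  Geom g(dims, spacing, origin);
  std::vector<Etab> et = unpack_etab(etab);
  NumericVector dose(pts.nrow());
  double* dp = REAL(dose);
  spot_loop(rsp, g, pts, iso, angle_deg, su, sv, eid, wt, et, sigma_air,
            mcs_frac, cutoff_sigma,
            [dp](int i, int, double val) { dp[i] += val; });
  return dose;
}

// Influence triplets (point, spot-within-call, dose per unit weight) for the
// spots of one gantry angle.
// [[Rcpp::export]]
List cpp_influence_angle(NumericVector rsp, IntegerVector dims,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix pts, NumericVector iso,
                         double angle_deg, NumericVector su, NumericVector sv,
                         IntegerVector eid, List etab, double sigma_air,
                         double mcs_frac, double cutoff_sigma) {
  Geom g(dims, spacing, origin);
  std::vector<Etab> et = unpack_etab(etab);
  NumericVector wt(su.size(), 1.0);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  spot_loop(rsp, g, pts, iso, angle_deg, su, sv, eid, wt, et, sigma_air,
            mcs_frac, cutoff_sigma, [&](int i, int j, double val) {
              ti.push_back(i + 1);
              tj.push_back(j + 1);
              tx.push_back(val);
            });
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
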