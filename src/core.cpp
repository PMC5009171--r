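#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Conventions: world coordinates in mm; voxel (i,j,k) (0-based here) has its
// center at ((i+0.5)vs, (j+0.5)vs, (k+0.5)vs); fiber orientation arrays are
// laid out as R arrays dim = (nx, ny, nz, K, 3); fraction arrays (nx, ny, nz, K).

namespace {

struct Vec3 { double x, y, z; };

inline double dot(const Vec3& a, const Vec3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

struct FiberField {
  const double* ori;  // (nx,ny,nz,K,3)
  const double* fr;   // (nx,ny,nz,K)
  int nx, ny, nz, K;
  double kappa, vs, floor_;
  long voxN() const { return (long)nx * ny * nz; }
  inline long vidx(int i, int j, int k) const { return i + (long)nx * (j + (long)ny * k); }
  inline double frac(long v, int p) const { return fr[v + voxN() * p]; }
  inline Vec3 axis(long v, int p) const {
    long base = v + voxN() * p;
    long stride = voxN() * K;
    return Vec3{ ori[base], ori[base + stride], ori[base + 2 * stride] };
  }
};

// Draw one direction from a Watson distribution (density ~ exp(kappa (mu.x)^2))
// about axis mu by rejection from the uniform sphere; antipodally symmetric.
inline Vec3 watson_draw(const Vec3& mu, double kappa, std::mt19937_64& rng,
                        std::uniform_real_distribution<double>& U) {
  if (kappa > 1e5) return mu;  // dispersion-free limit
  for (int it = 0; it < 100000; ++it) {
    double z = 2.0 * U(rng) - 1.0;
    double phi = 2.0 * M_PI * U(rng);
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    Vec3 x{ r * std::cos(phi), r * std::sin(phi), z };
    double c = dot(x, mu);
    if (U(rng) < std::exp(kappa * (c * c - 1.0))) return x;
  }
  return mu;  // unreachable for kappa < 1e5
}

// Sample a direction at voxel v: pick a population proportional to fraction
// (populations below floor excluded), Watson-scatter about its axis, then
// sign-align with prev. Returns false when no population is available.
inline bool sample_dir(const FiberField& F, long v, const Vec3& prev, Vec3& out,
                       int& pop_out, std::mt19937_64& rng,
                       std::uniform_real_distribution<double>& U) {
  double cum[8];
  int keep[8];
  int m = 0;
  double tot = 0.0;
  for (int p = 0; p < F.K; ++p) {
    double f = F.frac(v, p);
    if (f >= F.floor_ && f > 0.0) { tot += f; cum[m] = tot; keep[m] = p; ++m; }
  }
  if (m == 0) return false;
  double u = U(rng) * tot;
  int p = keep[m - 1];
  for (int q = 0; q < m; ++q) if (u <= cum[q]) { p = keep[q]; break; }
  Vec3 mu = F.axis(v, p);
  Vec3 d = watson_draw(mu, F.kappa, rng, U);
  if (dot(d, prev) < 0) { d.x = -d.x; d.y = -d.y; d.z = -d.z; }
  pop_out = p;
  out = d;
  return true;
}

enum Status { ACCEPTED = 0, REJ_EXCL = 1, REJ_NOTARGET = 2, TERM_CURV = 3 };

} // namespace

// [[Rcpp::export]]
List cpp_sample_dirs(NumericMatrix axes, NumericVector fracs, double kappa,
                     NumericVector prev, double floor_, int n, double seed) {
  int K = axes.nrow();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericMatrix dirs(n, 3);
  IntegerVector pop(n);
  Vec3 pv{ prev[0], prev[1], prev[2] };
  // inline field with a single voxel
  std::vector<double> ori(3 * K), fr(K);
  for (int p = 0; p < K; ++p) {
    fr[p] = fracs[p];
    ori[p] = axes(p, 0); ori[p + K] = axes(p, 1); ori[p + 2 * K] = axes(p, 2);
  }
  FiberField F{ ori.data(), fr.data(), 1, 1, 1, K, kappa, 1.0, floor_ };
  for (int i = 0; i < n; ++i) {
    Vec3 d; int p;
    if (!sample_dir(F, 0, pv, d, p, rng, U))
      stop("no population above the fraction floor");
    dirs(i, 0) = d.x; dirs(i, 1) = d.y; dirs(i, 2) = d.z;
    pop[i] = p + 1;
  }
  return List::create(_["dirs"] = dirs, _["pop"] = pop);
}

// Full tracker. Seeds are given either as explicit points (mm; seed_points
// with nrow > 0) or as 1-based voxel indices with `samples` jittered points
// per voxel. Each accepted streamline increments a voxel's count at most once.
// [[Rcpp::export]]
List cpp_track(NumericVector ori, NumericVector fr, double kappa, double floor_,
               IntegerVector dims, double vs,
               IntegerVector target, IntegerVector excl,
               IntegerMatrix seed_voxels, NumericMatrix seed_points,
               int samples, double step, double curv, int max_steps,
               double seed, int collect) {
  int nx = dims[0], ny = dims[1], nz = dims[2], K = dims[3];
  FiberField F{ REAL(ori), REAL(fr), nx, ny, nz, K, kappa, vs, floor_ };
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  long NV = F.voxN();
  std::vector<int> counts(NV, 0), stamp(NV, -1);
  const int* tg = INTEGER(target);
  const int* ex = INTEGER(excl);
  double ext_x = nx * vs, ext_y = ny * vs, ext_z = nz * vs;

  auto voxel_of = [&](const Vec3& p, long& v) -> bool {
    if (p.x < 0 || p.y < 0 || p.z < 0 || p.x >= ext_x || p.y >= ext_y || p.z >= ext_z)
      return false;
    v = F.vidx((int)(p.x / vs), (int)(p.y / vs), (int)(p.z / vs));
    return true;
  };

  // build the seed point list
  std::vector<Vec3> seeds;
  if (seed_points.nrow() > 0) {
    for (int i = 0; i < seed_points.nrow(); ++i)
      seeds.push_back(Vec3{ seed_points(i, 0), seed_points(i, 1), seed_points(i, 2) });
  } else {
    for (int i = 0; i < seed_voxels.nrow(); ++i) {
      double cx = (seed_voxels(i, 0) - 1) * vs, cy = (seed_voxels(i, 1) - 1) * vs,
             cz = (seed_voxels(i, 2) - 1) * vs;
      for (int s = 0; s < samples; ++s)
        seeds.push_back(Vec3{ cx + U(rng) * vs, cy + U(rng) * vs, cz + U(rng) * vs });
    }
  }

  long n_acc = 0, n_excl = 0, n_curv = 0, n_noreach = 0;
  List coll(collect > 0 ? std::min<long>((long)collect, (long)seeds.size()) : 0);
  int coll_n = 0;
  std::vector<Vec3> pts_f, pts_b;

  for (size_t si = 0; si < seeds.size(); ++si) {
    const Vec3 seedp = seeds[si];
    long v0;
    Status status = REJ_NOTARGET;
    bool any_curv = false;
    bool hit_f = false, hit_b = false;
    pts_f.clear(); pts_b.clear();
    if (voxel_of(seedp, v0)) {
      int p0 = -1; double fbest = -1.0;
      for (int p = 0; p < K; ++p) {
        double f = F.frac(v0, p);
        if (f >= floor_ && f > fbest) { fbest = f; p0 = p; }
      }
      if (p0 >= 0) {
        Vec3 prev0 = F.axis(v0, p0);
        Vec3 d0; int pp;
        sample_dir(F, v0, prev0, d0, pp, rng, U);
        bool excluded = false;
        for (int b = 0; b < 2 && !excluded; ++b) {
          std::vector<Vec3>& pts = (b == 0) ? pts_f : pts_b;
          Vec3 d = (b == 0) ? d0 : Vec3{ -d0.x, -d0.y, -d0.z };
          Vec3 p = seedp;
          for (int s = 0; s < max_steps; ++s) {
            Vec3 pn{ p.x + step * d.x, p.y + step * d.y, p.z + step * d.z };
            long v;
            if (!voxel_of(pn, v)) break;
            pts.push_back(pn);
            if (ex[v]) { excluded = true; break; }
            if (tg[v]) { if (b == 0) hit_f = true; else hit_b = true; break; }
            Vec3 nd; int npop;
            if (!sample_dir(F, v, d, nd, npop, rng, U)) break;
            if (dot(nd, d) < curv) { any_curv = true; break; }
            p = pn; d = nd;
          }
        }
        if (excluded) status = REJ_EXCL;
        else if (hit_f || hit_b) status = ACCEPTED;
        else status = any_curv ? TERM_CURV : REJ_NOTARGET;
      }
    }

    if (status == ACCEPTED) {
      ++n_acc;
      long id = (long)si;
      long v;
      if (voxel_of(seedp, v) && stamp[v] != id) { stamp[v] = id; ++counts[v]; }
      for (const Vec3& q : pts_f) if (voxel_of(q, v) && stamp[v] != (long)id) { stamp[v] = id; ++counts[v]; }
      for (const Vec3& q : pts_b) if (voxel_of(q, v) && stamp[v] != (long)id) { stamp[v] = id; ++counts[v]; }
    } else if (status == REJ_EXCL) ++n_excl;
    else if (status == TERM_CURV) ++n_curv;
    else ++n_noreach;

    if (collect > 0 && coll_n < coll.size()) {
      // merged polyline: reversed backward half, seed, forward half; oriented
      // so that when a target was hit, the target end is last.
      size_t nb = pts_b.size(), nf = pts_f.size();
      NumericMatrix P(nb + 1 + nf, 3);
      size_t r = 0;
      for (size_t q = nb; q > 0; --q, ++r) {
        P(r, 0) = pts_b[q - 1].x; P(r, 1) = pts_b[q - 1].y; P(r, 2) = pts_b[q - 1].z;
      }
      P(r, 0) = seedp.x; P(r, 1) = seedp.y; P(r, 2) = seedp.z; ++r;
      for (size_t q = 0; q < nf; ++q, ++r) {
        P(r, 0) = pts_f[q].x; P(r, 1) = pts_f[q].y; P(r, 2) = pts_f[q].z;
      }
      if (hit_b && !hit_f) {  // flip so the target end is last
        NumericMatrix Q(P.nrow(), 3);
        for (int a = 0; a < P.nrow(); ++a)
          for (int c = 0; c < 3; ++c) Q(P.nrow() - 1 - a, c) = P(a, c);
        P = Q;
      }
      const char* st = status == ACCEPTED ? "accepted"
                     : status == REJ_EXCL ? "rejected_exclusion"
                     : status == TERM_CURV ? "terminated_curvature_then_rejected"
                     : "rejected_no_target";
      coll[coll_n++] = List::create(_["points"] = P, _["status"] = st);
    }
  }

  IntegerVector cnt(NV);
  for (long v = 0; v < NV; ++v) cnt[v] = counts[v];
  cnt.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(
    _["counts"] = cnt, _["n_accepted"] = (double)n_acc,
    _["n_attempted"] = (double)seeds.size(),
    _["n_rejected_exclusion"] = (double)n_excl,
    _["n_terminated_curvature"] = (double)n_curv,
    _["n_rejected_no_target"] = (double)n_noreach,
    _["streamlines"] = coll);
}

// Separable 2D convolution with a symmetric 1D kernel, reflected boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv2(NumericMatrix img, NumericVector kernel) {
  int nx = img.nrow(), ny = img.ncol(), kn = kernel.size(), r = kn / 2;
  NumericMatrix tmp(nx, ny), out(nx, ny);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0;
      for (int q = 0; q < kn; ++q) s += kernel[q] * img(refl(i + q - r, nx), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0;
      for (int q = 0; q < kn; ++q) s += kernel[q] * tmp(i, refl(j + q - r, ny));
      out(i, j) = s;
    }
  return out;
}

// Bilinear sampling of a 2D image at mm coordinates (pixel centers at
// (i+0.5)*sp). Outside the image returns `fill`; a NaN fill means
// clamp-to-edge extension instead.
// [[Rcpp::export]]
NumericVector cpp_bilinear2(NumericMatrix img, NumericVector x, NumericVector y,
                            double sp, double fill) {
  int nx = img.nrow(), ny = img.ncol(), n = x.size();
  bool clamp = std::isnan(fill);
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double gx = x[q] / sp - 0.5, gy = y[q] / sp - 0.5;
    if (clamp) {
      gx = std::min(std::max(gx, 0.0), (double)nx - 1.0);
      gy = std::min(std::max(gy, 0.0), (double)ny - 1.0);
    } else if (gx < -1 || gy < -1 || gx > nx || gy > ny) {
      out[q] = fill; continue;
    }
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
    double fx = gx - i0, fy = gy - j0;
    double acc = 0.0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj) {
        int i = i0 + di, j = j0 + dj;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy);
        if (i >= 0 && i < nx && j >= 0 && j < ny) acc += w * img(i, j);
        else acc += w * (clamp ? img(std::min(std::max(i, 0), nx - 1),
                                     std::min(std::max(j, 0), ny - 1)) : fill);
      }
    out[q] = acc;
  }
  return out;
}

// Trilinear sampling of a 3D volume at mm coordinates; outside returns fill.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims, double vs,
                            NumericMatrix pts, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2], n = pts.nrow();
  const double* V = REAL(vol);
  NumericVector out(n);
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
    return V[i + (long)nx * (j + (long)ny * k)];
  };
  for (int q = 0; q < n; ++q) {
    double gx = pts(q, 0) / vs - 0.5, gy = pts(q, 1) / vs - 0.5, gz = pts(q, 2) / vs - 0.5;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk)
          acc += (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz) *
                 at(i0 + di, j0 + dj, k0 + dk);
    out[q] = acc;
  }
  return out;
}
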