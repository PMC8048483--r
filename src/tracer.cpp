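// Monte-Carlo two-band + PAR radiation transport over rosette canopies.
//
// Geometry: laminas are planar ellipses (center C, unit axis d, unit side s,
// semi-axes a along d and b along s); petioles are opaque finite cylinders.
// All coordinates in meters, soil plane z = 0.
//
// Acceleration: uniform 2D grid over (x, y); rays walk cells with a DDA and
// test only the primitives whose xy bounding box overlaps the current cell.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double EPS_T = 1e-9;      // minimum ray parameter for a hit
static const double EPS_OFF = 1e-7;    // offset applied after a scattering event

// ---------------------------------------------------------------------------
// PCG32 RNG: deterministic across platforms, cheap, seedable per substream.
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double uni() { return (next() >> 8) * (1.0 / 16777216.0); } // [0,1)
};

struct Vec3 { double x, y, z; };
static inline Vec3 v3(double x, double y, double z) { Vec3 v; v.x=x; v.y=y; v.z=z; return v; }
static inline Vec3 add(const Vec3&a, const Vec3&b){ return v3(a.x+b.x,a.y+b.y,a.z+b.z); }
static inline Vec3 sub(const Vec3&a, const Vec3&b){ return v3(a.x-b.x,a.y-b.y,a.z-b.z); }
static inline Vec3 mul(const Vec3&a, double k){ return v3(a.x*k,a.y*k,a.z*k); }
static inline double dot(const Vec3&a, const Vec3&b){ return a.x*b.x+a.y*b.y+a.z*b.z; }
static inline Vec3 cross(const Vec3&a, const Vec3&b){
  return v3(a.y*b.z-a.z*b.y, a.z*b.x-a.x*b.z, a.x*b.y-a.y*b.x);
}
static inline double norm(const Vec3&a){ return std::sqrt(dot(a,a)); }
static inline Vec3 unit(const Vec3&a){ double n=norm(a); return n>0 ? mul(a,1.0/n) : a; }

struct Lamina {
  Vec3 C, d, s, n;   // center, axis, side, normal (d x s)
  double a, b;       // semi-axes (m)
  int plant, leaf;
};
struct Petiole {
  Vec3 p0, axis;     // base point, unit axis
  double len, rad;
  int plant, leaf;
};

// Ray vs ellipse: returns t or INF.
static inline double hitLamina(const Lamina& L, const Vec3& O, const Vec3& D) {
  double dn = dot(D, L.n);
  if (std::fabs(dn) < 1e-14) return INF;
  double t = dot(sub(L.C, O), L.n) / dn;
  if (t <= EPS_T) return INF;
  Vec3 q = sub(add(O, mul(D, t)), L.C);
  double u = dot(q, L.d) / L.a;
  double v = dot(q, L.s) / L.b;
  return (u*u + v*v <= 1.0) ? t : INF;
}

// Ray vs finite cylinder (no caps): returns t or INF.
static inline double hitPetiole(const Petiole& P, const Vec3& O, const Vec3& D) {
  Vec3 oc = sub(O, P.p0);
  double dA = dot(D, P.axis), ocA = dot(oc, P.axis);
  Vec3 Dp = sub(D, mul(P.axis, dA));
  Vec3 Op = sub(oc, mul(P.axis, ocA));
  double A = dot(Dp, Dp);
  if (A < 1e-18) return INF;
  double B = 2.0 * dot(Dp, Op);
  double C = dot(Op, Op) - P.rad * P.rad;
  double disc = B*B - 4*A*C;
  if (disc < 0) return INF;
  double sq = std::sqrt(disc);
  for (int k = 0; k < 2; ++k) {
    double t = (k == 0) ? (-B - sq) / (2*A) : (-B + sq) / (2*A);
    if (t > EPS_T) {
      double h = ocA + t * dA;
      if (h >= 0 && h <= P.len) return t;
    }
  }
  return INF;
}

// ---------------------------------------------------------------------------
// Uniform 2D grid over [x0,x1] x [y0,y1].
struct Grid {
  double x0, x1, y0, y1, cw, ch;
  int nx, ny;
  std::vector<std::vector<int> > lamCells, petCells;
  std::vector<Lamina> lams;
  std::vector<Petiole> pets;
  std::vector<int> lamMail, petMail;
  int stamp;

  void build(const NumericMatrix& lamM, const NumericMatrix& petM,
             double bx0, double bx1, double by0, double by1, double cell) {
    x0 = bx0; x1 = bx1; y0 = by0; y1 = by1;
    nx = std::max(1, (int)std::floor((x1 - x0) / cell));
    ny = std::max(1, (int)std::floor((y1 - y0) / cell));
    if (nx > 256) nx = 256;
    if (ny > 256) ny = 256;
    cw = (x1 - x0) / nx; ch = (y1 - y0) / ny;
    lamCells.assign((size_t)nx * ny, std::vector<int>());
    petCells.assign((size_t)nx * ny, std::vector<int>());
    stamp = 0;
    int nl = lamM.nrow();
    lams.resize(nl);
    for (int i = 0; i < nl; ++i) {
      Lamina L;
      L.C = v3(lamM(i,0), lamM(i,1), lamM(i,2));
      L.d = v3(lamM(i,3), lamM(i,4), lamM(i,5));
      L.s = v3(lamM(i,6), lamM(i,7), lamM(i,8));
      L.a = lamM(i,9); L.b = lamM(i,10);
      L.plant = (int)lamM(i,11); L.leaf = (int)lamM(i,12);
      L.n = unit(cross(L.d, L.s));
      lams[i] = L;
      double rx = std::fabs(L.d.x)*L.a + std::fabs(L.s.x)*L.b;
      double ry = std::fabs(L.d.y)*L.a + std::fabs(L.s.y)*L.b;
      insert(lamCells, i, L.C.x - rx, L.C.x + rx, L.C.y - ry, L.C.y + ry);
    }
    int np = petM.nrow();
    pets.resize(np);
    for (int i = 0; i < np; ++i) {
      Petiole P;
      P.p0 = v3(petM(i,0), petM(i,1), petM(i,2));
      Vec3 p1 = v3(petM(i,3), petM(i,4), petM(i,5));
      Vec3 ax = sub(p1, P.p0);
      P.len = norm(ax);
      P.axis = P.len > 0 ? mul(ax, 1.0/P.len) : v3(0,0,1);
      P.rad = petM(i,6);
      P.plant = (int)petM(i,7); P.leaf = (int)petM(i,8);
      pets[i] = P;
      double lo_x = std::min(P.p0.x, p1.x) - P.rad, hi_x = std::max(P.p0.x, p1.x) + P.rad;
      double lo_y = std::min(P.p0.y, p1.y) - P.rad, hi_y = std::max(P.p0.y, p1.y) + P.rad;
      insert(petCells, i, lo_x, hi_x, lo_y, hi_y);
    }
    lamMail.assign(nl, -1);
    petMail.assign(np, -1);
  }

  void insert(std::vector<std::vector<int> >& cells, int id,
              double lx, double hx, double ly, double hy) {
    int i0 = clampi((int)std::floor((lx - x0)/cw), 0, nx-1);
    int i1 = clampi((int)std::floor((hx - x0)/cw), 0, nx-1);
    int j0 = clampi((int)std::floor((ly - y0)/ch), 0, ny-1);
    int j1 = clampi((int)std::floor((hy - y0)/ch), 0, ny-1);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        cells[(size_t)j*nx + i].push_back(id);
  }
  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

  // Nearest primitive hit with t <= tLimit. Returns type (0 none, 1 lamina,
  // 2 petiole), index and t. excludeLeaf: skip laminas/petioles of that
  // (plant, leaf) pair (used by the tip sensors; -1 disables).
  void nearestHit(const Vec3& O, const Vec3& D, double tLimit,
                  int exPlant, int exLeaf,
                  int& type, int& idx, double& tHit) {
    ++stamp;
    type = 0; idx = -1; tHit = INF;
    // locate entry cell (advance to the grid if starting outside in xy)
    double t0 = 0.0;
    double px = O.x, py = O.y;
    if (px < x0 || px > x1 || py < y0 || py > y1) {
      // clip to grid in xy
      double tEnter = 0.0, tExit = INF;
      if (std::fabs(D.x) > 1e-15) {
        double ta = (x0 - O.x)/D.x, tb = (x1 - O.x)/D.x;
        if (ta > tb) std::swap(ta, tb);
        tEnter = std::max(tEnter, ta); tExit = std::min(tExit, tb);
      } else if (px < x0 || px > x1) return;
      if (std::fabs(D.y) > 1e-15) {
        double ta = (y0 - O.y)/D.y, tb = (y1 - O.y)/D.y;
        if (ta > tb) std::swap(ta, tb);
        tEnter = std::max(tEnter, ta); tExit = std::min(tExit, tb);
      } else if (py < y0 || py > y1) return;
      if (tEnter > tExit || tEnter > tLimit) return;
      t0 = tEnter + 1e-12;
      px = O.x + D.x * t0; py = O.y + D.y * t0;
    }
    int ci = clampi((int)std::floor((px - x0)/cw), 0, nx-1);
    int cj = clampi((int)std::floor((py - y0)/ch), 0, ny-1);
    int stepi = D.x > 0 ? 1 : (D.x < 0 ? -1 : 0);
    int stepj = D.y > 0 ? 1 : (D.y < 0 ? -1 : 0);
    double tMaxX = INF, tMaxY = INF, tDX = INF, tDY = INF;
    if (stepi != 0) {
      double edge = x0 + (ci + (stepi > 0 ? 1 : 0)) * cw;
      tMaxX = (edge - O.x) / D.x;
      tDX = cw / std::fabs(D.x);
    }
    if (stepj != 0) {
      double edge = y0 + (cj + (stepj > 0 ? 1 : 0)) * ch;
      tMaxY = (edge - O.y) / D.y;
      tDY = ch / std::fabs(D.y);
    }
    double best = INF; int bType = 0, bIdx = -1;
    while (true) {
      double tCellExit = std::min(tMaxX, tMaxY);
      const std::vector<int>& lc = lamCells[(size_t)cj*nx + ci];
      for (size_t k = 0; k < lc.size(); ++k) {
        int id = lc[k];
        if (lamMail[id] == stamp) continue;
        lamMail[id] = stamp;
        const Lamina& L = lams[id];
        if (exPlant >= 0 && L.plant == exPlant && L.leaf == exLeaf) continue;
        double t = hitLamina(L, O, D);
        if (t < best) { best = t; bType = 1; bIdx = id; }
      }
      const std::vector<int>& pc = petCells[(size_t)cj*nx + ci];
      for (size_t k = 0; k < pc.size(); ++k) {
        int id = pc[k];
        if (petMail[id] == stamp) continue;
        petMail[id] = stamp;
        const Petiole& P = pets[id];
        if (exPlant >= 0 && P.plant == exPlant && P.leaf == exLeaf) continue;
        double t = hitPetiole(P, O, D);
        if (t < best) { best = t; bType = 2; bIdx = id; }
      }
      if (best <= tCellExit) break;          // cannot be beaten by later cells
      if (tCellExit > tLimit) break;         // ground/top reached first
      if (tMaxX < tMaxY) {
        ci += stepi; tMaxX += tDX;
        if (ci < 0 || ci >= nx) break;
      } else {
        cj += stepj; tMaxY += tDY;
        if (cj < 0 || cj >= ny) break;
      }
      if (stepi == 0 && stepj == 0) break;   // vertical ray: one cell only
    }
    if (best <= tLimit) { type = bType; idx = bIdx; tHit = best; }
  }

  // All lamina/petiole crossings along a ray (for transmission sampling).
  // Appends (type, id) of every crossing with t in (EPS_T, tLimit].
  void allCrossings(const Vec3& O, const Vec3& D, double tLimit,
                    int exPlant, int exLeaf,
                    std::vector<std::pair<int,int> >& out) {
    out.clear();
    Vec3 o = O;
    double tBase = 0.0;
    for (int guard = 0; guard < 4096; ++guard) {
      int type, idx; double t;
      nearestHit(o, D, tLimit - tBase, exPlant, exLeaf, type, idx, t);
      if (type == 0) return;
      out.push_back(std::make_pair(type, idx));
      tBase += t + EPS_OFF;
      if (tBase >= tLimit) return;
      o = add(o, mul(D, t + EPS_OFF));
    }
  }
};

// Cosine-weighted direction in the hemisphere around unit normal n.
static Vec3 cosineHemisphere(const Vec3& n, Pcg32& rng) {
  double u1 = rng.uni(), u2 = rng.uni();
  double r = std::sqrt(u1), phi = 2.0 * M_PI * u2;
  double lx = r * std::cos(phi), ly = r * std::sin(phi);
  double lz = std::sqrt(std::max(0.0, 1.0 - u1));
  // orthonormal basis around n
  Vec3 t1 = std::fabs(n.x) < 0.9 ? v3(1,0,0) : v3(0,1,0);
  Vec3 u = unit(cross(n, t1));
  Vec3 v = cross(n, u);
  return unit(add(add(mul(u, lx), mul(v, ly)), mul(n, lz)));
}

// Uniform direction in the hemisphere around n.
static Vec3 uniformHemisphere(const Vec3& n, Pcg32& rng) {
  double u1 = rng.uni(), u2 = rng.uni();
  double lz = u1;                       // cos(theta) uniform in [0,1)
  double r = std::sqrt(std::max(0.0, 1.0 - lz*lz));
  double phi = 2.0 * M_PI * u2;
  Vec3 t1 = std::fabs(n.x) < 0.9 ? v3(1,0,0) : v3(0,1,0);
  Vec3 u = unit(cross(n, t1));
  Vec3 v = cross(n, u);
  return unit(add(add(mul(u, r*std::cos(phi)), mul(v, r*std::sin(phi))), mul(n, lz)));
}

// ---------------------------------------------------------------------------
// Forward Monte-Carlo transport.
//
// lam: n x 13 (C, d, s, a, b, plant, leaf); pet: m x 9 (p0, p1, radius,
// plant, leaf); optics: 3 x 3 rows = bands (PAR, R, FR), cols = (abs, refl,
// trans); tiles: t x 4 (xmin, xmax, ymin, ymax); bounds: emission rectangle
// (xmin, xmax, ymin, ymax); intensity: per-band source intensity on an
// unobstructed horizontal plane.
// [[Rcpp::export]]
List cpp_trace(NumericMatrix lam, NumericMatrix pet, NumericMatrix optics,
               NumericVector bounds, double z_emit, int angular_model,
               int n_rays, int seed, int max_bounces, double rr_threshold,
               NumericVector intensity, NumericMatrix tiles,
               double cell_size) {
  Grid grid;
  grid.build(lam, pet, bounds[0], bounds[1], bounds[2], bounds[3], cell_size);
  int nl = lam.nrow(), np = pet.nrow(), nt = tiles.nrow();
  double ax0 = bounds[0], ax1 = bounds[1], ay0 = bounds[2], ay1 = bounds[3];
  double area = (ax1 - ax0) * (ay1 - ay0);

  NumericMatrix lamAbs(nl, 3), petAbs(np, 3), tileDep(nt, 3);
  NumericVector emitted(3), absorbedTot(3), soilTileTot(3), soilOtherTot(3),
                escapedTot(3), imb(3), imbVar(3);

  for (int b = 0; b < 3; ++b) {
    double I = intensity[b];
    if (I <= 0) continue;
    double w0 = I * area / n_rays;
    double aAbs = optics(b,0), aRef = optics(b,1), aTra = optics(b,2);
    Pcg32 rng((uint64_t)seed * 2654435761ULL + 11ULL * b, 54u + (uint64_t)b);
    for (int r = 0; r < n_rays; ++r) {
      Vec3 O = v3(ax0 + rng.uni()*(ax1-ax0), ay0 + rng.uni()*(ay1-ay0), z_emit);
      Vec3 D;
      if (angular_model == 0) D = v3(0,0,-1);
      else if (angular_model == 1) D = cosineHemisphere(v3(0,0,-1), rng);
      else D = uniformHemisphere(v3(0,0,-1), rng);
      double w = w0, dep = 0.0;
      emitted[b] += w0;
      int wraps = 0;
      for (int bounce = 0; ; ) {
        double tGround = D.z < -1e-15 ? (0.0 - O.z)/D.z :
                         (std::fabs(O.z) < 1e-12 && D.z <= 0 ? 0.0 : INF);
        double tTop = D.z > 1e-15 ? (z_emit - O.z)/D.z : INF;
        // lateral domain exit: the domain is periodic (the stand repeats),
        // so side exits wrap instead of escaping
        double tSide = INF;
        if (D.x > 1e-15) tSide = std::min(tSide, (ax1 - O.x)/D.x);
        else if (D.x < -1e-15) tSide = std::min(tSide, (ax0 - O.x)/D.x);
        if (D.y > 1e-15) tSide = std::min(tSide, (ay1 - O.y)/D.y);
        else if (D.y < -1e-15) tSide = std::min(tSide, (ay0 - O.y)/D.y);
        double tLimit = std::min(std::min(tGround, tTop), tSide);
        int type, idx; double t;
        grid.nearestHit(O, D, tLimit, -1, -1, type, idx, t);
        if (type == 0) {
          if (tSide < tGround && tSide < tTop) { // wrap laterally
            if (++wraps > 64) { escapedTot[b] += w; dep += w; w = 0; break; }
            O = add(O, mul(D, tSide + 1e-9));
            double W = ax1 - ax0, H = ay1 - ay0;
            if (O.x <= ax0) O.x += W; else if (O.x >= ax1) O.x -= W;
            if (O.y <= ay0) O.y += H; else if (O.y >= ay1) O.y -= H;
            continue;
          }
          if (tGround < INF && tGround <= tTop) {
            double sx = O.x + D.x*tGround, sy = O.y + D.y*tGround;
            bool inTile = false;
            for (int k = 0; k < nt; ++k) {
              if (sx >= tiles(k,0) && sx <= tiles(k,1) &&
                  sy >= tiles(k,2) && sy <= tiles(k,3)) {
                tileDep(k,b) += w; soilTileTot[b] += w; inTile = true; break;
              }
            }
            if (!inTile) soilOtherTot[b] += w;
          } else {
            escapedTot[b] += w;   // through the top
          }
          dep += w; w = 0.0;
          break;
        }
        ++bounce;
        Vec3 H = add(O, mul(D, t));
        if (type == 2) {                     // petiole: opaque black
          petAbs(idx, b) += w; absorbedTot[b] += w; dep += w; w = 0.0;
          break;
        }
        // lamina interaction
        lamAbs(idx, b) += w * aAbs; absorbedTot[b] += w * aAbs; dep += w * aAbs;
        w *= (1.0 - aAbs);
        double scat = aRef + aTra;
        if (w <= 0 || scat <= 0) { // fully absorbing surface
          if (w > 0) { lamAbs(idx,b) += w; absorbedTot[b] += w; dep += w; w = 0; }
          break;
        }
        if (bounce > max_bounces) {          // truncation: book as escaped
          escapedTot[b] += w; dep += w; w = 0.0;
          break;
        }
        // Russian roulette on low weight
        if (w < rr_threshold * w0) {
          if (rng.uni() < 0.5) break;        // terminated, weight unaccounted
          w *= 2.0;
        }
        const Lamina& L = grid.lams[idx];
        Vec3 nIn = dot(D, L.n) < 0 ? L.n : mul(L.n, -1.0); // faces incoming
        bool reflect = rng.uni() < aRef / scat;
        Vec3 nd = reflect ? cosineHemisphere(nIn, rng)
                          : cosineHemisphere(mul(nIn, -1.0), rng);
        O = add(H, mul(nd, EPS_OFF));
        D = nd;
      }
      double d = w0 - dep;
      imb[b] += d; imbVar[b] += d * d;
    }
  }

  NumericVector tileArea(nt);
  NumericMatrix tileFlux(nt, 3);
  for (int k = 0; k < nt; ++k) {
    tileArea[k] = (tiles(k,1)-tiles(k,0)) * (tiles(k,3)-tiles(k,2));
    for (int b = 0; b < 3; ++b) tileFlux(k,b) = tileDep(k,b) / tileArea[k];
  }
  NumericVector imbSe(3);
  for (int b = 0; b < 3; ++b) imbSe[b] = std::sqrt(imbVar[b]);

  return List::create(
    _["lamina_absorbed"] = lamAbs, _["petiole_absorbed"] = petAbs,
    _["tile_flux"] = tileFlux, _["tile_area"] = tileArea,
    _["emitted"] = emitted, _["absorbed"] = absorbedTot,
    _["soil_tiles"] = soilTileTot, _["soil_other"] = soilOtherTot,
    _["escaped"] = escapedTot, _["imbalance"] = imb, _["imbalance_se"] = imbSe);
}

// ---------------------------------------------------------------------------
// Tip sensors: cosine-weighted upward transmission sampling from each lamina
// tip. Per band, fluence relative to open sky = mean over directions of the
// product of lamina transmittances crossed (petiole crossings are opaque).
// The sensing leaf's own lamina and petiole are excluded.
//
// tips: k x 5 (x, y, z, plant, leaf). Returns k x 3 relative fluence.
// [[Rcpp::export]]
NumericMatrix cpp_sense_tips(NumericMatrix lam, NumericMatrix pet,
                             NumericMatrix optics, NumericVector bounds,
                             double z_emit, NumericMatrix tips, int n_dirs,
                             int seed, double cell_size) {
  Grid grid;
  grid.build(lam, pet, bounds[0], bounds[1], bounds[2], bounds[3], cell_size);
  int k = tips.nrow();
  double ax0 = bounds[0], ax1 = bounds[1], ay0 = bounds[2], ay1 = bounds[3];
  NumericMatrix rel(k, 3);
  for (int i = 0; i < k; ++i) {
    Pcg32 rng((uint64_t)seed * 1099087573ULL + 7ULL * i, 91u);
    Vec3 T = v3(tips(i,0), tips(i,1), tips(i,2));
    int pl = (int)tips(i,3), lf = (int)tips(i,4);
    double acc[3] = {0,0,0};
    for (int d = 0; d < n_dirs; ++d) {
      Vec3 dir = cosineHemisphere(v3(0,0,1), rng);
      Vec3 O = T;
      double tau[3] = {1,1,1};
      int wraps = 0, guard = 0;
      while (guard++ < 4096) {
        double tTop = dir.z > 1e-15 ? (z_emit - O.z)/dir.z : INF;
        if (tTop < 0) break;                  // already above the canopy
        double tSide = INF;
        if (dir.x > 1e-15) tSide = std::min(tSide, (ax1 - O.x)/dir.x);
        else if (dir.x < -1e-15) tSide = std::min(tSide, (ax0 - O.x)/dir.x);
        if (dir.y > 1e-15) tSide = std::min(tSide, (ay1 - O.y)/dir.y);
        else if (dir.y < -1e-15) tSide = std::min(tSide, (ay0 - O.y)/dir.y);
        int type, idx; double t;
        grid.nearestHit(O, dir, std::min(tTop, tSide), pl, lf, type, idx, t);
        if (type == 1) {                      // lamina: attenuate, continue
          for (int b = 0; b < 3; ++b) tau[b] *= optics(b,2);
          if (tau[2] <= 0) break;
          O = add(O, mul(dir, t + EPS_OFF));
        } else if (type == 2) {               // petiole: opaque
          tau[0] = tau[1] = tau[2] = 0; break;
        } else if (tSide < tTop) {            // periodic wrap
          if (++wraps > 64) break;
          O = add(O, mul(dir, tSide + 1e-9));
          double W = ax1 - ax0, H = ay1 - ay0;
          if (O.x <= ax0) O.x += W; else if (O.x >= ax1) O.x -= W;
          if (O.y <= ay0) O.y += H; else if (O.y >= ay1) O.y -= H;
        } else break;                         // open sky
      }
      for (int b = 0; b < 3; ++b) acc[b] += tau[b];
    }
    for (int b = 0; b < 3; ++b) rel(i,b) = acc[b] / n_dirs;
  }
  return rel;
}

// ---------------------------------------------------------------------------
// Exhaustive vertical-ray map over a rectangular region: per grid point the
// per-band direct transmittance (product of lamina transmittances; petioles
// opaque) and whether any lamina covers it. Independent oracle for the MC
// tracer under a vertical source with non-scattering optics, and the basis
// of the vertical cover fraction.
// region: (xmin, xmax, ymin, ymax); returns list(trans = res*res x 3,
// covered = res*res logical), points in row-major y-then-x order.
// [[Rcpp::export]]
List cpp_vertical_map(NumericMatrix lam, NumericMatrix pet,
                      NumericMatrix optics, NumericVector region,
                      int res, double z_emit, double cell_size) {
  NumericVector bounds = NumericVector::create(region[0], region[1],
                                               region[2], region[3]);
  Grid grid;
  grid.build(lam, pet, bounds[0], bounds[1], bounds[2], bounds[3], cell_size);
  int n = res * res;
  NumericMatrix trans(n, 3);
  LogicalVector covered(n);
  double dx = (region[1]-region[0]) / res, dy = (region[3]-region[2]) / res;
  std::vector<std::pair<int,int> > crossings;
  Vec3 dir = v3(0,0,-1);
  int i = 0;
  for (int jy = 0; jy < res; ++jy) {
    for (int jx = 0; jx < res; ++jx, ++i) {
      Vec3 O = v3(region[0] + (jx + 0.5)*dx, region[2] + (jy + 0.5)*dy, z_emit);
      grid.allCrossings(O, dir, z_emit + 1.0, -1, -1, crossings);
      double tau[3] = {1,1,1};
      bool cov = false;
      for (size_t c = 0; c < crossings.size(); ++c) {
        if (crossings[c].first == 2) { tau[0]=tau[1]=tau[2]=0; continue; }
        cov = true;
        for (int b = 0; b < 3; ++b) tau[b] *= optics(b,2);
      }
      for (int b = 0; b < 3; ++b) trans(i,b) = tau[b];
      covered[i] = cov;
    }
  }
  return List::create(_["trans"] = trans, _["covered"] = covered);
}

// ---------------------------------------------------------------------------
// Touch detection: for every lamina, is any lamina of another plant (or,
// optionally, of the same plant) within `tol` meters in 3D? Ellipses are
// discretised to nv-gons; the pairwise distance uses edge-edge segment
// distances, vertex-to-face projections and edge-face piercing.
// [[Rcpp::export]]
LogicalVector cpp_touch(NumericMatrix lam, double tol, int nv, bool self) {
  int n = lam.nrow();
  std::vector<Lamina> L(n);
  for (int i = 0; i < n; ++i) {
    L[i].C = v3(lam(i,0), lam(i,1), lam(i,2));
    L[i].d = v3(lam(i,3), lam(i,4), lam(i,5));
    L[i].s = v3(lam(i,6), lam(i,7), lam(i,8));
    L[i].a = lam(i,9); L[i].b = lam(i,10);
    L[i].plant = (int)lam(i,11); L[i].leaf = (int)lam(i,12);
    L[i].n = unit(cross(L[i].d, L[i].s));
  }
  // polygon vertices
  std::vector<std::vector<Vec3> > poly(n);
  for (int i = 0; i < n; ++i) {
    poly[i].resize(nv);
    for (int k = 0; k < nv; ++k) {
      double th = 2.0 * M_PI * k / nv;
      poly[i][k] = add(L[i].C, add(mul(L[i].d, L[i].a*std::cos(th)),
                                   mul(L[i].s, L[i].b*std::sin(th))));
    }
  }
  LogicalVector touched(n);
  for (int i = 0; i < n; ++i) touched[i] = false;

  auto segseg = [](const Vec3& p1, const Vec3& p2, const Vec3& q1, const Vec3& q2) {
    Vec3 u = sub(p2,p1), v = sub(q2,q1), w = sub(p1,q1);
    double a = dot(u,u), b = dot(u,v), c = dot(v,v), d = dot(u,w), e = dot(v,w);
    double den = a*c - b*b, sc, tc;
    if (den < 1e-18) { sc = 0.0; tc = (b > c ? d/b : e/c); }
    else { sc = (b*e - c*d)/den; tc = (a*e - b*d)/den; }
    sc = std::min(1.0, std::max(0.0, sc));
    tc = std::min(1.0, std::max(0.0, tc));
    // refine clamped solution
    tc = c > 1e-18 ? std::min(1.0, std::max(0.0, (b*sc + e)/c)) : 0.0;
    sc = a > 1e-18 ? std::min(1.0, std::max(0.0, (b*tc - d)/a)) : 0.0;
    Vec3 diff = sub(add(p1, mul(u,sc)), add(q1, mul(v,tc)));
    return norm(diff);
  };
  auto inEllipse = [](const Lamina& E, const Vec3& q) {
    Vec3 r = sub(q, E.C);
    double u = dot(r, E.d)/E.a, v = dot(r, E.s)/E.b;
    return u*u + v*v <= 1.0;
  };

  for (int i = 0; i < n; ++i) {
    for (int j = i+1; j < n; ++j) {
      if (!self && L[i].plant == L[j].plant) continue;
      double cd = norm(sub(L[i].C, L[j].C));
      if (cd > L[i].a + L[j].a + tol) continue;
      if (touched[i] && touched[j]) continue;
      double best = INF;
      // vertex -> other plane projection
      for (int pass = 0; pass < 2 && best > tol; ++pass) {
        const Lamina& A = pass == 0 ? L[i] : L[j];
        const std::vector<Vec3>& PB = pass == 0 ? poly[j] : poly[i];
        const Lamina& B = pass == 0 ? L[j] : L[i];
        (void)PB;
        const std::vector<Vec3>& PA = pass == 0 ? poly[i] : poly[j];
        for (int k = 0; k < nv; ++k) {
          double h = dot(sub(PA[k], B.C), B.n);
          Vec3 q = sub(PA[k], mul(B.n, h));
          if (inEllipse(B, q)) best = std::min(best, std::fabs(h));
        }
        // edge-face piercing
        for (int k = 0; k < nv && best > 0; ++k) {
          const Vec3& p1 = PA[k];
          const Vec3& p2 = PA[(k+1)%nv];
          double h1 = dot(sub(p1, B.C), B.n), h2 = dot(sub(p2, B.C), B.n);
          if (h1 * h2 < 0) {
            double tt = h1 / (h1 - h2);
            Vec3 q = add(p1, mul(sub(p2,p1), tt));
            if (inEllipse(B, q)) best = 0.0;
          }
        }
        (void)A;
      }
      // edge-edge
      if (best > tol) {
        for (int k = 0; k < nv && best > tol; ++k)
          for (int m = 0; m < nv; ++m) {
            double dd = segseg(poly[i][k], poly[i][(k+1)%nv],
                               poly[j][m], poly[j][(m+1)%nv]);
            if (dd < best) best = dd;
            if (best <= tol) break;
          }
      }
      if (best <= tol) { touched[i] = true; touched[j] = true; }
    }
  }
  return touched;
}
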