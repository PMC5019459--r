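// Core computational kernels: quadric-region containment, Monte Carlo volume
// integration, source sampling, and analog photon transport with Woodcock
// (delta) tracking.  All randomness is drawn from R's RNG stream so results
// are reproducible with set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int PRIM_NCOL = 15;

// Primitive row layout (all doubles):
//  0 type (1 ellipsoid, 2 elliptic_cylinder, 3 cone_pair, 4 half_space)
//  1-3 shift tx ty tz (world -> local: p' = (p - t) / s)
//  4-6 scale sx sy sz
//  7.. params:
//   ellipsoid:          a b c z_lo z_hi   (7,8,9,10,11)
//   elliptic_cylinder:  a b z_lo z_hi     (7,8,9,10)
//   cone_pair:          A L z_lo z_hi     (7,8,9,10)
//   half_space:         nx ny nz d        (7,8,9,10)
static inline bool prim_contains(const double *r, double x, double y, double z) {
  const double px = (x - r[1]) / r[4];
  const double py = (y - r[2]) / r[5];
  const double pz = (z - r[3]) / r[6];
  switch ((int)r[0]) {
  case 1: {
    if (pz < r[10] || pz > r[11]) return false;
    const double u = px / r[7], v = py / r[8], w = pz / r[9];
    return u * u + v * v + w * w <= 1.0;
  }
  case 2: {
    if (pz < r[9] || pz > r[10]) return false;
    const double u = px / r[7], v = py / r[8];
    return u * u + v * v <= 1.0;
  }
  case 3: {
    if (pz < r[9] || pz > r[10]) return false;
    const double R = r[7] * (1.0 + pz / r[8]);
    if (R <= 0.0) return false;
    return px * px + py * py <= std::fabs(px) * R;
  }
  case 4:
    return r[7] * px + r[8] * py + r[9] * pz <= r[10];
  }
  return false;
}

// Postfix boolean program over primitives.  Tokens: k >= 1 pushes
// containment of primitive k (1-based); -1 AND; -2 OR; -3 DIFF (a && !b).
static inline bool prog_contains(const double *prim, const int *prog, int np,
                                 double x, double y, double z) {
  bool st[64];
  int sp = 0;
  for (int i = 0; i < np; ++i) {
    const int tok = prog[i];
    if (tok > 0) {
      st[sp++] = prim_contains(prim + (size_t)(tok - 1) * PRIM_NCOL, x, y, z);
    } else if (tok == -1) {
      --sp; st[sp - 1] = st[sp - 1] && st[sp];
    } else if (tok == -2) {
      --sp; st[sp - 1] = st[sp - 1] || st[sp];
    } else if (tok == -3) {
      --sp; st[sp - 1] = st[sp - 1] && !st[sp];
    }
  }
  return st[0];
}

static std::vector<double> flatten_prim(const NumericMatrix &prim) {
  const int n = prim.nrow();
  std::vector<double> out((size_t)n * PRIM_NCOL, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < PRIM_NCOL; ++j) out[(size_t)i * PRIM_NCOL + j] = prim(i, j);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_contains(NumericMatrix prim, IntegerVector prog, NumericMatrix pts) {
  std::vector<double> P = flatten_prim(prim);
  const int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = prog_contains(P.data(), &prog[0], prog.size(), pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
int cpp_mc_hits(NumericMatrix prim, IntegerVector prog, NumericVector lo,
                NumericVector hi, int n) {
  std::vector<double> P = flatten_prim(prim);
  RNGScope scope;
  int hits = 0;
  const double dx = hi[0] - lo[0], dy = hi[1] - lo[1], dz = hi[2] - lo[2];
  for (int i = 0; i < n; ++i) {
    const double x = lo[0] + dx * unif_rand();
    const double y = lo[1] + dy * unif_rand();
    const double z = lo[2] + dz * unif_rand();
    if (prog_contains(P.data(), &prog[0], prog.size(), x, y, z)) ++hits;
  }
  return hits;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_region(NumericMatrix prim, IntegerVector prog,
                                NumericVector lo, NumericVector hi, int n,
                                double min_acceptance) {
  std::vector<double> P = flatten_prim(prim);
  RNGScope scope;
  NumericMatrix out(n, 3);
  const double dx = hi[0] - lo[0], dy = hi[1] - lo[1], dz = hi[2] - lo[2];
  long tries = 0, got = 0;
  const long try_floor = 1000;
  while (got < n) {
    const double x = lo[0] + dx * unif_rand();
    const double y = lo[1] + dy * unif_rand();
    const double z = lo[2] + dz * unif_rand();
    ++tries;
    if (prog_contains(P.data(), &prog[0], prog.size(), x, y, z)) {
      out(got, 0) = x; out(got, 1) = y; out(got, 2) = z;
      ++got;
    }
    if (tries > try_floor && (double)got / (double)tries < min_acceptance)
      stop("rejection sampling acceptance rate below %g: degenerate region?",
           min_acceptance);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_iso(int n) {
  RNGScope scope;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const double w = 2.0 * unif_rand() - 1.0;
    const double phi = 2.0 * M_PI * unif_rand();
    const double s = std::sqrt(std::max(0.0, 1.0 - w * w));
    out(i, 0) = s * std::cos(phi);
    out(i, 1) = s * std::sin(phi);
    out(i, 2) = w;
  }
  return out;
}

// Klein-Nishina sampling of the scattered-to-incident energy ratio
// x = E'/E by rejection: pdf(x) ~ x + 1/x - 1 + cos^2(theta),
// cos(theta) = 1 + 1/k - 1/(k x), x in [1/(1+2k), 1], k = E/m_e c^2.
static inline void sample_kn(double k, double &xout, double &mu) {
  const double xmin = 1.0 / (1.0 + 2.0 * k);
  const double bound = xmin + 1.0 / xmin; // >= x + 1/x on [xmin, 1]
  double x = 1.0, ct = 1.0;
  for (int it = 0; it < 10000; ++it) {
    x = xmin + (1.0 - xmin) * unif_rand();
    ct = 1.0 + 1.0 / k - 1.0 / (k * x);
    const double g = x + 1.0 / x - 1.0 + ct * ct;
    if (unif_rand() * bound <= g) break;
  }
  xout = x;
  mu = ct;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E, int n) {
  RNGScope scope;
  NumericMatrix out(n, 2);
  const double k = E / 0.5109989;
  for (int i = 0; i < n; ++i) {
    double x, mu;
    sample_kn(k, x, mu);
    out(i, 0) = E * x;
    out(i, 1) = mu;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Transport
// ---------------------------------------------------------------------------

struct XSTables {
  std::vector<double> logE;       // ng
  int ng, nm, ne;
  std::vector<double> log_tot;    // ng*nm column-major (ng fast)
  std::vector<double> log_pe, log_inc, log_coh, log_pair;
  std::vector<double> log_maj;    // ng
  std::vector<double> elemZ;      // ne
  std::vector<double> mat_elem_w; // nm*ne (nm fast? store ne columns: idx m + nm*e)
  std::vector<double> log_elem_coh; // ng*ne
  std::vector<double> coh_logt;   // nt (log of q^2 grid, in A^-2)
  std::vector<double> coh_cdf;    // nt*ne cumulative integral of F^2 over t
  int nt;
};

struct ECache {
  double E, k, maj;
  int idx;
  double f; // interpolation fraction
};

static inline void xs_update_cache(const XSTables &xs, double E, ECache &c) {
  c.E = E;
  c.k = E / 0.5109989;
  double le = std::log(E);
  if (le <= xs.logE[0]) { c.idx = 0; c.f = 0.0; }
  else if (le >= xs.logE[xs.ng - 1]) { c.idx = xs.ng - 2; c.f = 1.0; }
  else {
    int lo = 0, hi = xs.ng - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (xs.logE[mid] <= le) lo = mid; else hi = mid; }
    c.idx = lo;
    c.f = (le - xs.logE[lo]) / (xs.logE[lo + 1] - xs.logE[lo]);
  }
  c.maj = std::exp((1.0 - c.f) * xs.log_maj[c.idx] + c.f * xs.log_maj[c.idx + 1]);
}

static inline double xs_val(const std::vector<double> &tab, const XSTables &xs,
                            const ECache &c, int col) {
  const double lv = (1.0 - c.f) * tab[c.idx + xs.ng * col] +
                    c.f * tab[c.idx + 1 + xs.ng * col];
  return lv <= -600.0 ? 0.0 : std::exp(lv);
}

// Rotate direction (u,v,w) by polar angle with cosine mu and random azimuth.
static inline void rotate_dir(double &u, double &v, double &w, double mu) {
  const double phi = 2.0 * M_PI * unif_rand();
  const double sth = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  const double cph = std::cos(phi), sph = std::sin(phi);
  const double a = std::sqrt(std::max(1e-20, 1.0 - w * w));
  double nu, nv, nw;
  if (a > 1e-8) {
    nu = u * mu + sth * (u * w * cph - v * sph) / a;
    nv = v * mu + sth * (v * w * cph + u * sph) / a;
    nw = w * mu - a * sth * cph;
  } else { // travelling along +-z
    nu = sth * cph;
    nv = sth * sph;
    nw = (w > 0 ? mu : -mu);
  }
  const double nrm = std::sqrt(nu * nu + nv * nv + nw * nw);
  u = nu / nrm; v = nv / nrm; w = nw / nrm;
}

// Sample a coherent-scattering deflection using the Thomas-Fermi-Moliere
// atomic form factor: draw q^2 from the tabulated cumulative F^2 integral,
// then accept on the Thomson angular factor.
static inline double sample_coherent_mu(const XSTables &xs, const ECache &c,
                                        int elem) {
  // k in A^-1: E[MeV] -> q = 2 k sin(theta/2), k = E/(hbar c), hbar c = 1.97327e-3 MeV*A
  const double kA = c.E / 1.97327e-3;
  const double tmax = 4.0 * kA * kA;
  const double ltmax = std::log(tmax);
  const double *cdf = &xs.coh_cdf[(size_t)elem * xs.nt];
  // cumulative at tmax (clamped to table range)
  double Gmax;
  if (ltmax <= xs.coh_logt[0]) Gmax = cdf[0];
  else if (ltmax >= xs.coh_logt[xs.nt - 1]) Gmax = cdf[xs.nt - 1];
  else {
    int lo = 0, hi = xs.nt - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (xs.coh_logt[mid] <= ltmax) lo = mid; else hi = mid; }
    const double f = (ltmax - xs.coh_logt[lo]) / (xs.coh_logt[lo + 1] - xs.coh_logt[lo]);
    Gmax = (1.0 - f) * cdf[lo] + f * cdf[lo + 1];
  }
  for (int it = 0; it < 500; ++it) {
    const double u = unif_rand() * Gmax;
    int lo = 0, hi = xs.nt - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (cdf[mid] <= u) lo = mid; else hi = mid; }
    const double span = cdf[lo + 1] - cdf[lo];
    const double f = span > 0 ? (u - cdf[lo]) / span : 0.5;
    const double t = std::exp((1.0 - f) * xs.coh_logt[lo] + f * xs.coh_logt[lo + 1]);
    const double mu = 1.0 - t / (2.0 * kA * kA);
    if (mu < -1.0) continue;
    if (unif_rand() * 2.0 <= 1.0 + mu * mu) return mu;
  }
  return 1.0; // extremely forward-peaked: keep direction
}

struct Geometry {
  std::vector<double> prim;
  std::vector<std::vector<int> > progs;
  std::vector<double> bbox; // norg x 6 (row-major xlo xhi ylo yhi zlo zhi)
  std::vector<int> env_prog;
  std::vector<int> mat;     // per organ, 0-based
  int mat_residual;
  int norg;
  double world_r2;
};

static inline int classify(const Geometry &g, double x, double y, double z) {
  // -1 vacuum, 0..norg-1 organ, norg residual
  if (!prog_contains(g.prim.data(), g.env_prog.data(), g.env_prog.size(), x, y, z))
    return -1;
  for (int i = 0; i < g.norg; ++i) {
    const double *bb = &g.bbox[(size_t)i * 6];
    if (x < bb[0] || x > bb[1] || y < bb[2] || y > bb[3] || z < bb[4] || z > bb[5])
      continue;
    if (prog_contains(g.prim.data(), g.progs[i].data(), g.progs[i].size(), x, y, z))
      return i;
  }
  return g.norg;
}

static Geometry build_geometry(List geom) {
  Geometry g;
  g.prim = flatten_prim(as<NumericMatrix>(geom["prim"]));
  List progs = geom["progs"];
  g.norg = progs.size();
  for (int i = 0; i < g.norg; ++i) {
    IntegerVector p = progs[i];
    g.progs.push_back(std::vector<int>(p.begin(), p.end()));
  }
  NumericMatrix bb = geom["bbox"];
  g.bbox.resize((size_t)g.norg * 6);
  for (int i = 0; i < g.norg; ++i)
    for (int j = 0; j < 6; ++j) g.bbox[(size_t)i * 6 + j] = bb(i, j);
  IntegerVector ep = geom["env_prog"];
  g.env_prog.assign(ep.begin(), ep.end());
  IntegerVector mat = geom["mat"];
  for (int i = 0; i < g.norg; ++i) g.mat.push_back(mat[i] - 1);
  g.mat_residual = as<int>(geom["mat_residual"]) - 1;
  const double wr = as<double>(geom["world_r"]);
  g.world_r2 = wr * wr;
  return g;
}

static XSTables build_xs(List xs) {
  XSTables t;
  NumericVector logE = xs["logE"];
  t.logE.assign(logE.begin(), logE.end());
  t.ng = t.logE.size();
  NumericMatrix lt = xs["log_tot"], lp = xs["log_pe"], li = xs["log_inc"],
                lc = xs["log_coh"], lr = xs["log_pair"];
  t.nm = lt.ncol();
  t.log_tot.assign(lt.begin(), lt.end());
  t.log_pe.assign(lp.begin(), lp.end());
  t.log_inc.assign(li.begin(), li.end());
  t.log_coh.assign(lc.begin(), lc.end());
  t.log_pair.assign(lr.begin(), lr.end());
  NumericVector lm = xs["log_maj"];
  t.log_maj.assign(lm.begin(), lm.end());
  NumericVector ez = xs["elemZ"];
  t.elemZ.assign(ez.begin(), ez.end());
  t.ne = t.elemZ.size();
  NumericMatrix mw = xs["mat_elem_w"]; // nm x ne
  t.mat_elem_w.assign(mw.begin(), mw.end());
  NumericMatrix lec = xs["log_elem_coh"]; // ng x ne
  t.log_elem_coh.assign(lec.begin(), lec.end());
  NumericVector clt = xs["coh_logt"];
  t.coh_logt.assign(clt.begin(), clt.end());
  t.nt = t.coh_logt.size();
  NumericMatrix cc = xs["coh_cdf"]; // nt x ne
  t.coh_cdf.assign(cc.begin(), cc.end());
  return t;
}

// [[Rcpp::export]]
List cpp_simulate(List geom, List xs_list, int source, double E0, int n_hist,
                  int n_batch, double cutoff, bool coherent_on) {
  Geometry g = build_geometry(geom);
  XSTables xs = build_xs(xs_list);
  RNGScope scope;

  const int nrow = g.norg + 2; // organs, residual, escape
  NumericMatrix dep(nrow, n_batch);
  const int src = source - 1;
  const double *sbb = &g.bbox[(size_t)src * 6];
  const double sdx = sbb[1] - sbb[0], sdy = sbb[3] - sbb[2], sdz = sbb[5] - sbb[4];
  const std::vector<int> &sprog = g.progs[src];

  int per = n_hist / n_batch, extra = n_hist % n_batch;
  ECache c0;
  xs_update_cache(xs, std::max(E0, cutoff * 1.0000001), c0);

  for (int b = 0; b < n_batch; ++b) {
    const int nb = per + (b < extra ? 1 : 0);
    double *dcol = &dep(0, b);
    for (int h = 0; h < nb; ++h) {
      // source point by rejection in the source organ's bounding box
      double x, y, z;
      long tries = 0;
      do {
        x = sbb[0] + sdx * unif_rand();
        y = sbb[2] + sdy * unif_rand();
        z = sbb[4] + sdz * unif_rand();
        if (++tries > 2000000) stop("source sampling failed: degenerate organ");
      } while (!prog_contains(g.prim.data(), sprog.data(), sprog.size(), x, y, z));

      // photon stack (pair production pushes one extra photon)
      double st_x[4], st_y[4], st_z[4], st_u[4], st_v[4], st_w[4], st_E[4];
      int sp = 0;
      {
        const double w0 = 2.0 * unif_rand() - 1.0;
        const double phi = 2.0 * M_PI * unif_rand();
        const double s0 = std::sqrt(std::max(0.0, 1.0 - w0 * w0));
        st_x[0] = x; st_y[0] = y; st_z[0] = z;
        st_u[0] = s0 * std::cos(phi); st_v[0] = s0 * std::sin(phi); st_w[0] = w0;
        st_E[0] = E0;
        sp = 1;
      }
      while (sp > 0) {
        --sp;
        double px = st_x[sp], py = st_y[sp], pz = st_z[sp];
        double u = st_u[sp], v = st_v[sp], w = st_w[sp];
        double E = st_E[sp];
        ECache c;
        if (E <= cutoff) { // forced local deposition at birth
          int org = classify(g, px, py, pz);
          if (org >= 0) dcol[org] += E; else dcol[g.norg + 1] += E;
          continue;
        }
        xs_update_cache(xs, E, c);
        bool alive = true;
        while (alive) {
          const double s = -std::log(unif_rand()) / c.maj;
          px += s * u; py += s * v; pz += s * w;
          if (px * px + py * py + pz * pz > g.world_r2) {
            dcol[g.norg + 1] += E; // escaped
            break;
          }
          const int org = classify(g, px, py, pz);
          if (org < 0) continue; // vacuum: fictitious collision
          const int m = (org == g.norg) ? g.mat_residual : g.mat[org];
          const double mu_t = xs_val(xs.log_tot, xs, c, m);
          if (unif_rand() * c.maj > mu_t) continue; // fictitious
          // real collision: select channel
          const double mu_pe = xs_val(xs.log_pe, xs, c, m);
          const double mu_in = xs_val(xs.log_inc, xs, c, m);
          const double mu_co = coherent_on ? xs_val(xs.log_coh, xs, c, m) : 0.0;
          const double mu_pr = xs_val(xs.log_pair, xs, c, m);
          const double tot = mu_pe + mu_in + mu_co + mu_pr;
          double xi = unif_rand() * tot;
          if (xi < mu_pe) { // photoelectric: full local absorption
            dcol[org] += E;
            alive = false;
          } else if (xi < mu_pe + mu_in) { // incoherent (Compton)
            double xr, mu;
            sample_kn(c.k, xr, mu);
            const double Ep = E * xr;
            dcol[org] += E - Ep;
            if (Ep <= cutoff) { dcol[org] += Ep; alive = false; }
            else {
              E = Ep;
              xs_update_cache(xs, E, c);
              rotate_dir(u, v, w, mu);
            }
          } else if (xi < mu_pe + mu_in + mu_co) { // coherent: redirect only
            // pick scattering element weighted by its coherent contribution
            double wsum = 0.0, we[16];
            for (int e = 0; e < xs.ne; ++e) {
              const double lv = (1.0 - c.f) * xs.log_elem_coh[c.idx + xs.ng * e] +
                                c.f * xs.log_elem_coh[c.idx + 1 + xs.ng * e];
              const double cv = lv <= -600.0 ? 0.0 : std::exp(lv);
              we[e] = xs.mat_elem_w[m + xs.nm * e] * cv;
              wsum += we[e];
            }
            int elem = 0;
            if (wsum > 0) {
              double r = unif_rand() * wsum;
              for (int e = 0; e < xs.ne; ++e) { r -= we[e]; if (r <= 0) { elem = e; break; } }
            }
            rotate_dir(u, v, w, sample_coherent_mu(xs, c, elem));
          } else { // pair production
            dcol[org] += E - 1.0219978;
            // two annihilation photons, back to back, isotropic
            const double w0 = 2.0 * unif_rand() - 1.0;
            const double phi = 2.0 * M_PI * unif_rand();
            const double s0 = std::sqrt(std::max(0.0, 1.0 - w0 * w0));
            u = s0 * std::cos(phi); v = s0 * std::sin(phi); w = w0;
            if (sp < 3) {
              st_x[sp] = px; st_y[sp] = py; st_z[sp] = pz;
              st_u[sp] = -u; st_v[sp] = -v; st_w[sp] = -w;
              st_E[sp] = 0.5109989;
              ++sp;
            }
            E = 0.5109989;
            xs_update_cache(xs, E, c);
          }
        }
      }
    }
  }
  return List::create(_["dep"] = dep);
}

// Reference surface-to-surface ray tracer for sphere fixtures (independent
// oracle for the Woodcock tracker).  Spheres: matrix (cx cy cz radius),
// per-sphere material index (1-based), same physics as cpp_simulate.
// [[Rcpp::export]]
List cpp_ray_trace_spheres(NumericMatrix spheres, IntegerVector smat,
                           List xs_list, int source, double E0, int n_hist,
                           int n_batch, double cutoff, bool coherent_on,
                           double world_r) {
  XSTables xs = build_xs(xs_list);
  RNGScope scope;
  const int ns = spheres.nrow();
  const int nrow = ns + 1; // spheres + escape
  NumericMatrix dep(nrow, n_batch);
  const int src = source - 1;
  const double wr2 = world_r * world_r;

  int per = n_hist / n_batch, extra = n_hist % n_batch;
  for (int b = 0; b < n_batch; ++b) {
    const int nb = per + (b < extra ? 1 : 0);
    double *dcol = &dep(0, b);
    for (int h = 0; h < nb; ++h) {
      // uniform point in source sphere
      double px, py, pz;
      do {
        px = 2.0 * unif_rand() - 1.0;
        py = 2.0 * unif_rand() - 1.0;
        pz = 2.0 * unif_rand() - 1.0;
      } while (px * px + py * py + pz * pz > 1.0);
      const double R = spheres(src, 3);
      px = spheres(src, 0) + R * px;
      py = spheres(src, 1) + R * py;
      pz = spheres(src, 2) + R * pz;
      double w0 = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double s0 = std::sqrt(std::max(0.0, 1.0 - w0 * w0));
      double u = s0 * std::cos(phi), v = s0 * std::sin(phi), w = w0;
      double E = E0;
      if (E <= cutoff) { dcol[src] += E; continue; }
      ECache c;
      xs_update_cache(xs, E, c);
      bool alive = true;
      while (alive) {
        // which sphere are we in?
        int cur = -1;
        for (int i = 0; i < ns; ++i) {
          const double dx = px - spheres(i, 0), dy = py - spheres(i, 1), dz = pz - spheres(i, 2);
          if (dx * dx + dy * dy + dz * dz <= spheres(i, 3) * spheres(i, 3)) { cur = i; break; }
        }
        // distance to next boundary along (u,v,w)
        double dist_b = 1e30;
        for (int i = 0; i < ns; ++i) {
          const double dx = px - spheres(i, 0), dy = py - spheres(i, 1), dz = pz - spheres(i, 2);
          const double bq = dx * u + dy * v + dz * w;
          const double cq = dx * dx + dy * dy + dz * dz - spheres(i, 3) * spheres(i, 3);
          const double disc = bq * bq - cq;
          if (disc <= 0) continue;
          const double rt = std::sqrt(disc);
          const double t1 = -bq - rt, t2 = -bq + rt;
          if (t1 > 1e-9 && t1 < dist_b) dist_b = t1;
          if (t2 > 1e-9 && t2 < dist_b) dist_b = t2;
        }
        if (cur < 0) { // in vacuum: jump to next sphere or escape
          if (dist_b > 1e29 || px * px + py * py + pz * pz > wr2) {
            dcol[ns] += E;
            break;
          }
          const double step = dist_b + 1e-7;
          px += step * u; py += step * v; pz += step * w;
          continue;
        }
        const int m = smat[cur] - 1;
        const double mu_t = xs_val(xs.log_tot, xs, c, m);
        const double s = -std::log(unif_rand()) / mu_t;
        if (s >= dist_b) { // crosses boundary without interacting
          const double step = dist_b + 1e-7;
          px += step * u; py += step * v; pz += step * w;
          continue;
        }
        px += s * u; py += s * v; pz += s * w;
        const double mu_pe = xs_val(xs.log_pe, xs, c, m);
        const double mu_in = xs_val(xs.log_inc, xs, c, m);
        const double mu_co = coherent_on ? xs_val(xs.log_coh, xs, c, m) : 0.0;
        const double mu_pr = xs_val(xs.log_pair, xs, c, m);
        const double tot = mu_pe + mu_in + mu_co + mu_pr;
        double xi = unif_rand() * tot;
        if (xi < mu_pe) {
          dcol[cur] += E;
          alive = false;
        } else if (xi < mu_pe + mu_in) {
          double xr, mu;
          sample_kn(c.k, xr, mu);
          const double Ep = E * xr;
          dcol[cur] += E - Ep;
          if (Ep <= cutoff) { dcol[cur] += Ep; alive = false; }
          else { E = Ep; xs_update_cache(xs, E, c); rotate_dir(u, v, w, mu); }
        } else if (xi < mu_pe + mu_in + mu_co) {
          double wsum = 0.0, we[16];
          for (int e = 0; e < xs.ne; ++e) {
            const double lv = (1.0 - c.f) * xs.log_elem_coh[c.idx + xs.ng * e] +
                              c.f * xs.log_elem_coh[c.idx + 1 + xs.ng * e];
            const double cv = lv <= -600.0 ? 0.0 : std::exp(lv);
            we[e] = xs.mat_elem_w[m + xs.nm * e] * cv;
            wsum += we[e];
          }
          int elem = 0;
          if (wsum > 0) {
            double r = unif_rand() * wsum;
            for (int e = 0; e < xs.ne; ++e) { r -= we[e]; if (r <= 0) { elem = e; break; } }
          }
          rotate_dir(u, v, w, sample_coherent_mu(xs, c, elem));
        } else {
          dcol[cur] += E - 1.0219978; // rare at these energies; photons dropped
          dcol[ns] += 1.0219978;      // accounted as escaped annihilation quanta
          alive = false;
        }
      }
    }
  }
  return List::create(_["dep"] = dep);
}
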