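#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rates.h"
using namespace Rcpp;

// Exact stochastic simulation of one update window [t0, t1]. Per-agent
// propensities (cycle + migration + death) are frozen at the nutrient
// concentration each agent cached at the last field update; daughters born
// during the window sample the frozen field at their own birth position.
// Event selection is O(log N) via a Fenwick (binary indexed) tree over the
// per-agent propensity totals.

namespace {

struct Fenwick {
  int n;  // capacity; slots beyond the live agents hold zero
  std::vector<double> t;
  void init_from(const std::vector<double>& a, int capacity) {
    n = std::max(capacity, (int) a.size());
    t.assign(n + 1, 0.0);
    for (size_t i = 0; i < a.size(); ++i) t[i + 1] += a[i];
    for (int i = 1; i <= n; ++i) {
      int j = i + (i & -i);
      if (j <= n) t[j] += t[i];
    }
  }
  void add(int i, double delta) {
    for (++i; i <= n; i += i & -i) t[i] += delta;
  }
  double total() const {
    double s = 0.0;
    for (int i = n; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  // smallest 0-based index with prefix sum >= u
  int find(double u) const {
    int pos = 0, pw = 1;
    while ((pw << 1) <= n) pw <<= 1;
    for (; pw; pw >>= 1)
      if (pos + pw <= n && t[pos + pw] < u) {
        pos += pw;
        u -= t[pos];
      }
    return pos;
  }
};

struct Field {
  const double* c;
  int I;
  double L, h, half;
  double sample(double x, double y, double z) const {
    double u = (x + half) / h, v = (y + half) / h, w = (z + half) / h;
    if (u < 0 || v < 0 || w < 0 || u > I - 1 || v > I - 1 || w > I - 1)
      stop("position outside the grid");
    int i0 = std::min((int) std::floor(u), I - 2);
    int j0 = std::min((int) std::floor(v), I - 2);
    int k0 = std::min((int) std::floor(w), I - 2);
    double fx = u - i0, fy = v - j0, fz = w - k0;
    auto at = [&](int i, int j, int k) {
      return c[i + (size_t) I * (j + (size_t) I * k)];
    };
    double c00 = at(i0, j0, k0) * (1 - fx) + at(i0 + 1, j0, k0) * fx;
    double c10 = at(i0, j0 + 1, k0) * (1 - fx) + at(i0 + 1, j0 + 1, k0) * fx;
    double c01 = at(i0, j0, k0 + 1) * (1 - fx) + at(i0 + 1, j0, k0 + 1) * fx;
    double c11 = at(i0, j0 + 1, k0 + 1) * (1 - fx) + at(i0 + 1, j0 + 1, k0 + 1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
};

// uniform direction on the unit sphere: azimuth uniform on [0, 2*pi),
// cosine of the polar angle uniform on [-1, 1]
inline void runit(double& dx, double& dy, double& dz) {
  double cth = 2.0 * unif_rand() - 1.0;
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double phi = 2.0 * M_PI * unif_rand();
  dx = sth * std::cos(phi);
  dy = sth * std::sin(phi);
  dz = cth;
}

inline double cycle_rate(int phase, double c, const RateParams& p) {
  if (phase == 0) return rate_r2y(c, p);
  if (phase == 1) return p.Ry;
  return p.Rg;
}

}  // namespace

// [[Rcpp::export]]
List cpp_gillespie_window(NumericVector x0, NumericVector y0, NumericVector z0,
                          IntegerVector phase0, NumericVector cc0,
                          double t0, double t1, List par,
                          NumericVector cfield, int I) {
  RateParams rp;
  rp.Rr_max = par["Rr_max"]; rp.Ry = par["Ry"]; rp.Rg = par["Rg"];
  rp.d_max = par["d_max"]; rp.d_min = par["d_min"];
  rp.m_max = par["m_max"]; rp.m_min = par["m_min"];
  rp.eta1 = par["eta1"]; rp.eta2 = par["eta2"]; rp.eta3 = par["eta3"];
  rp.c_a = par["c_a"]; rp.c_m = par["c_m"]; rp.c_d = par["c_d"];
  double sigma = par["sigma"], mu = par["mu"], L = par["L"];
  double half = L / 2.0;

  Field fld;
  fld.c = cfield.begin(); fld.I = I; fld.L = L;
  fld.h = L / (I - 1); fld.half = half;

  int n0 = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      z(z0.begin(), z0.end()), cc(cc0.begin(), cc0.end());
  std::vector<int> phase(phase0.begin(), phase0.end());
  std::vector<char> alive(n0, 1);
  std::vector<double> prop(n0);
  for (int i = 0; i < n0; ++i)
    prop[i] = cycle_rate(phase[i], cc[i], rp) + rate_mig(cc[i], rp) +
              rate_dth(cc[i], rp);

  Fenwick fw;
  fw.init_from(prop, std::max(64, n0 + n0 / 4));

  std::vector<double> dx_, dy_, dz_, dt_;  // death records
  long n_r2y = 0, n_y2g = 0, n_mitosis = 0, n_death = 0, n_migration = 0;
  double t = t0;
  double t_first = NA_REAL;
  bool have_first = false;

  auto check_inside = [&](double px, double py, double pz) {
    if (std::fabs(px) >= half || std::fabs(py) >= half || std::fabs(pz) >= half)
      stop("boundary breach: an agent reached the edge of the domain; "
           "increase the domain length L");
  };

  for (;;) {
    double total = fw.total();
    if (total < -1e-9) stop("internal error: negative total propensity");
    if (total <= 0.0) { t = t1; break; }
    double dt = exp_rand() / total;
    if (t + dt > t1) { t = t1; break; }
    t += dt;
    if (!have_first) { t_first = t; have_first = true; }

    int a = fw.find(unif_rand() * total);
    // guard against selecting a zeroed (dead) slot through round-off
    while (a < (int) prop.size() && (!alive[a] || prop[a] <= 0.0)) ++a;
    if (a >= (int) prop.size()) continue;

    double cyc = cycle_rate(phase[a], cc[a], rp);
    double mig = rate_mig(cc[a], rp);
    double dth = rate_dth(cc[a], rp);
    double u = unif_rand() * (cyc + mig + dth);

    if (u < dth) {  // death: remove, record location and time
      alive[a] = 0;
      fw.add(a, -prop[a]);
      prop[a] = 0.0;
      dx_.push_back(x[a]); dy_.push_back(y[a]); dz_.push_back(z[a]);
      dt_.push_back(t);
      ++n_death;
    } else if (u < dth + mig) {  // migration: step of length mu
      double ux, uy, uz;
      runit(ux, uy, uz);
      double nx = x[a] + mu * ux, ny = y[a] + mu * uy, nz = z[a] + mu * uz;
      check_inside(nx, ny, nz);
      x[a] = nx; y[a] = ny; z[a] = nz;  // cached_c stays frozen
      ++n_migration;
    } else {  // cycle progression
      if (phase[a] == 0) {
        phase[a] = 1;
        double np = rp.Ry + mig + dth;
        fw.add(a, np - prop[a]);
        prop[a] = np;
        ++n_r2y;
      } else if (phase[a] == 1) {
        phase[a] = 2;
        double np = rp.Rg + mig + dth;
        fw.add(a, np - prop[a]);
        prop[a] = np;
        ++n_y2g;
      } else {  // mitosis: parent -> two red daughters sigma/2 apart
        double ux, uy, uz;
        runit(ux, uy, uz);
        alive[a] = 0;
        fw.add(a, -prop[a]);
        prop[a] = 0.0;
        for (int s = -1; s <= 1; s += 2) {
          double nx = x[a] + s * 0.5 * sigma * ux;
          double ny = y[a] + s * 0.5 * sigma * uy;
          double nz = z[a] + s * 0.5 * sigma * uz;
          check_inside(nx, ny, nz);
          double cd = fld.sample(nx, ny, nz);
          double np = rate_r2y(cd, rp) + rate_mig(cd, rp) + rate_dth(cd, rp);
          x.push_back(nx); y.push_back(ny); z.push_back(nz);
          phase.push_back(0); cc.push_back(cd);
          alive.push_back(1); prop.push_back(np);
          if ((int) prop.size() > fw.n)  // capacity exhausted: double it
            fw.init_from(prop, 2 * (int) prop.size());
          else
            fw.add((int) prop.size() - 1, np);
        }
        ++n_mitosis;
      }
    }
  }

  int nalive = 0;
  for (size_t i = 0; i < alive.size(); ++i) nalive += alive[i];
  NumericVector xo(nalive), yo(nalive), zo(nalive), co(nalive);
  IntegerVector po(nalive);
  int k = 0;
  for (size_t i = 0; i < alive.size(); ++i)
    if (alive[i]) {
      xo[k] = x[i]; yo[k] = y[i]; zo[k] = z[i];
      co[k] = cc[i]; po[k] = phase[i];
      ++k;
    }

  return List::create(
      _["x"] = xo, _["y"] = yo, _["z"] = zo, _["phase"] = po, _["cached_c"] = co,
      _["death_x"] = NumericVector(dx_.begin(), dx_.end()),
      _["death_y"] = NumericVector(dy_.begin(), dy_.end()),
      _["death_z"] = NumericVector(dz_.begin(), dz_.end()),
      _["death_time"] = NumericVector(dt_.begin(), dt_.end()),
      _["time"] = t,
      _["t_first_event"] = t_first,
      _["n_r2y"] = (double) n_r2y, _["n_y2g"] = (double) n_y2g,
      _["n_mitosis"] = (double) n_mitosis, _["n_death"] = (double) n_death,
      _["n_migration"] = (double) n_migration);
}

// The engine's own rate laws, exposed so the R-level rate functions and the
// compiled event code can be pinned against each other in tests.
// [[Rcpp::export]]
NumericMatrix cpp_rate_laws(NumericVector c, List par) {
  RateParams rp;
  rp.Rr_max = par["Rr_max"]; rp.Ry = par["Ry"]; rp.Rg = par["Rg"];
  rp.d_max = par["d_max"]; rp.d_min = par["d_min"];
  rp.m_max = par["m_max"]; rp.m_min = par["m_min"];
  rp.eta1 = par["eta1"]; rp.eta2 = par["eta2"]; rp.eta3 = par["eta3"];
  rp.c_a = par["c_a"]; rp.c_m = par["c_m"]; rp.c_d = par["c_d"];
  int n = c.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = rate_r2y(c[i], rp);
    out(i, 1) = rate_mig(c[i], rp);
    out(i, 2) = rate_dth(c[i], rp);
  }
  colnames(out) = CharacterVector::create("red_to_yellow", "migration", "death");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_random_unit_directions(int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double ux, uy, uz;
    runit(ux, uy, uz);
    out(i, 0) = ux; out(i, 1) = uy; out(i, 2) = uz;
  }
  return out;
}
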