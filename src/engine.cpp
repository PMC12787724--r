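// Core CG-MD engine: truncated-shifted LJ + harmonic bonds/angles + junction
// tethers, evaluated over a Verlet pair list with minimum-image convention,
// integrated with the Gronbech-Jensen-Farago Langevin scheme (reduces to
// velocity Verlet at zeta = 0).
#include <RcppArmadillo.h>
#include <vector>
#include <unordered_set>
#include <cstdint>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free xoshiro256++ PRNG, seeded via splitmix64.  One stream per run;
// independent of R's RNG so trajectories are bitwise reproducible for a seed.
namespace {

struct Xoshiro {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Box-Muller with cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct PairTables {
  // indexed [ti * ntype + tj]
  std::vector<double> sigma2, rcut2, eshift, listcut2;
  double eps;
  int ntype;
};

struct Topology {
  arma::Mat<int> bonds;            // n_bonds x 2, 0-based
  arma::Mat<int> angles;           // n_angles x 3, 0-based, centre in col 1
  std::vector<double> ka;          // per angle
  std::vector<int> tether_idx;     // 0-based
  arma::mat tether_anchor;         // n_teth x 3
  double kb, r0, theta0, k_tether;
  std::unordered_set<uint64_t> excl;  // 1-2 exclusions, key i*N+j (i<j)
};

struct NeighborList {
  std::vector<int> pi, pj, pk;     // pair members and type-pair table index
  std::vector<double> sx, sy, sz;  // periodic image shift frozen at build
  arma::mat ref_pos;               // positions at last build
  long n_rebuilds = 0;
};

// Pair search over type blocks: each block uses its own (cutoff + skin), so
// the short network-network cutoff is not inflated by the large rod-network
// one.  Distances use wrapped coordinates with a branchy minimum image.
void build_neighbor_list(const arma::mat& pos, const arma::vec& box,
                         const std::vector<int>& type, const PairTables& pt,
                         const Topology& topo, NeighborList& nl) {
  const int n = pos.n_rows;
  nl.pi.clear(); nl.pj.clear(); nl.pk.clear();
  nl.sx.clear(); nl.sy.clear(); nl.sz.clear();
  if (pt.eps != 0.0) {
    const double Lx = box[0], Ly = box[1], Lz = box[2];
    const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
    std::vector<double> wx(n), wy(n), wz(n);
    for (int i = 0; i < n; ++i) {
      wx[i] = pos(i, 0) - Lx * std::floor(pos(i, 0) / Lx);
      wy[i] = pos(i, 1) - Ly * std::floor(pos(i, 1) / Ly);
      wz[i] = pos(i, 2) - Lz * std::floor(pos(i, 2) / Lz);
    }
    std::vector<std::vector<int>> ids(pt.ntype);
    for (int i = 0; i < n; ++i) ids[type[i]].push_back(i);
    for (int ta = 0; ta < pt.ntype; ++ta) {
      if (ids[ta].empty()) continue;
      for (int tb = ta; tb < pt.ntype; ++tb) {
        if (ids[tb].empty()) continue;
        const int k = ta * pt.ntype + tb;
        const double cut2 = pt.listcut2[k];
        const double cut = std::sqrt(cut2);
        const std::vector<int>& A = ids[ta];
        const std::vector<int>& B = ids[tb];
        const size_t na = A.size(), nb = B.size();
        for (size_t a = 0; a < na; ++a) {
          const int i = A[a];
          const double xi = wx[i], yi = wy[i], zi = wz[i];
          const size_t b0 = (ta == tb) ? a + 1 : 0;
          for (size_t b = b0; b < nb; ++b) {
            const int j = B[b];
            double dx = xi - wx[j];
            if (dx > hx) dx -= Lx; else if (dx < -hx) dx += Lx;
            if (dx > cut || dx < -cut) continue;
            double dy = yi - wy[j];
            if (dy > hy) dy -= Ly; else if (dy < -hy) dy += Ly;
            if (dy > cut || dy < -cut) continue;
            double dz = zi - wz[j];
            if (dz > hz) dz -= Lz; else if (dz < -hz) dz += Lz;
            if (dx * dx + dy * dy + dz * dz < cut2) {
              int lo = i < j ? i : j, hi2 = i < j ? j : i;
              if (topo.excl.count((uint64_t)lo * n + hi2)) continue;
              nl.pi.push_back(i); nl.pj.push_back(j);
              nl.pk.push_back(type[i] * pt.ntype + type[j]);
              // shift stays valid between rebuilds (moves bounded by skin)
              nl.sx.push_back(pos(i, 0) - pos(j, 0) - dx);
              nl.sy.push_back(pos(i, 1) - pos(j, 1) - dy);
              nl.sz.push_back(pos(i, 2) - pos(j, 2) - dz);
            }
          }
        }
      }
    }
  }
  nl.ref_pos = pos;
  nl.n_rebuilds++;
}

// Rebuild when the two largest displacements since the last build sum past
// the skin (no pair can then have approached by more than the skin).
bool needs_rebuild(const arma::mat& pos, const NeighborList& nl, double skin) {
  double m1 = 0.0, m2 = 0.0;
  for (arma::uword i = 0; i < pos.n_rows; ++i) {
    double dx = pos(i, 0) - nl.ref_pos(i, 0);
    double dy = pos(i, 1) - nl.ref_pos(i, 1);
    double dz = pos(i, 2) - nl.ref_pos(i, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > m1) { m2 = m1; m1 = d2; }
    else if (d2 > m2) { m2 = d2; }
  }
  return std::sqrt(m1) + std::sqrt(m2) > skin;
}

// Energy + forces for the current configuration.  Positions are unwrapped;
// minimum image is applied per displacement, so unwrapped coordinates are
// valid inputs as long as the box exceeds twice the largest cutoff.
double compute_forces(const arma::mat& pos, const arma::vec& box,
                      const std::vector<int>& type, const PairTables& pt,
                      const Topology& topo, const NeighborList& nl,
                      arma::mat& force) {
  force.zeros();
  double energy = 0.0;

  // LJ pairs (truncated, shifted to zero at rcut; shift affects energy only)
  const size_t npair = nl.pi.size();
  for (size_t p = 0; p < npair; ++p) {
    const int i = nl.pi[p], j = nl.pj[p];
    double dx = pos(i, 0) - pos(j, 0) - nl.sx[p];
    double dy = pos(i, 1) - pos(j, 1) - nl.sy[p];
    double dz = pos(i, 2) - pos(j, 2) - nl.sz[p];
    double r2 = dx * dx + dy * dy + dz * dz;
    const int k = nl.pk[p];
    if (r2 >= pt.rcut2[k]) continue;
    if (r2 < 1e-12)
      stop("overlapping beads (%d, %d): r < 1e-6 sigma", i + 1, j + 1);
    double sr2 = pt.sigma2[k] / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    energy += 4.0 * pt.eps * (sr12 - sr6) - pt.eshift[k];
    double fr = 24.0 * pt.eps * (2.0 * sr12 - sr6) / r2;  // (1/r) dU/dr * (-1/r)
    force(i, 0) += fr * dx; force(i, 1) += fr * dy; force(i, 2) += fr * dz;
    force(j, 0) -= fr * dx; force(j, 1) -= fr * dy; force(j, 2) -= fr * dz;
  }

  // Harmonic bonds U = kb (r - r0)^2  (no 1/2 prefactor)
  for (arma::uword b = 0; b < topo.bonds.n_rows; ++b) {
    const int i = topo.bonds(b, 0), j = topo.bonds(b, 1);
    double dx = min_image(pos(i, 0) - pos(j, 0), box[0]);
    double dy = min_image(pos(i, 1) - pos(j, 1), box[1]);
    double dz = min_image(pos(i, 2) - pos(j, 2), box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - topo.r0;
    energy += topo.kb * dr * dr;
    double fr = -2.0 * topo.kb * dr / r;
    force(i, 0) += fr * dx; force(i, 1) += fr * dy; force(i, 2) += fr * dz;
    force(j, 0) -= fr * dx; force(j, 1) -= fr * dy; force(j, 2) -= fr * dz;
  }

  // Harmonic angles U = ka (theta - theta0)^2, centre bead in column 1
  for (arma::uword a = 0; a < topo.angles.n_rows; ++a) {
    const int i = topo.angles(a, 0), j = topo.angles(a, 1), k = topo.angles(a, 2);
    double d1x = min_image(pos(i, 0) - pos(j, 0), box[0]);
    double d1y = min_image(pos(i, 1) - pos(j, 1), box[1]);
    double d1z = min_image(pos(i, 2) - pos(j, 2), box[2]);
    double d2x = min_image(pos(k, 0) - pos(j, 0), box[0]);
    double d2y = min_image(pos(k, 1) - pos(j, 1), box[1]);
    double d2z = min_image(pos(k, 2) - pos(j, 2), box[2]);
    double r1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
    double r2 = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
    if (r1 < 1e-10 || r2 < 1e-10) stop("degenerate angle geometry at angle %d", (int)a + 1);
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double theta = std::acos(c);
    double dth = theta - topo.theta0;
    energy += topo.ka[a] * dth * dth;
    double aa = -2.0 * topo.ka[a] * dth / s;
    double a11 = aa * c / (r1 * r1);
    double a12 = -aa / (r1 * r2);
    double a22 = aa * c / (r2 * r2);
    double fix = a11 * d1x + a12 * d2x, fiy = a11 * d1y + a12 * d2y, fiz = a11 * d1z + a12 * d2z;
    double fkx = a22 * d2x + a12 * d1x, fky = a22 * d2y + a12 * d1y, fkz = a22 * d2z + a12 * d1z;
    force(i, 0) += fix; force(i, 1) += fiy; force(i, 2) += fiz;
    force(k, 0) += fkx; force(k, 1) += fky; force(k, 2) += fkz;
    force(j, 0) -= fix + fkx; force(j, 1) -= fiy + fky; force(j, 2) -= fiz + fkz;
  }

  // Junction tethers U = k |r - anchor|^2 (anchor in unwrapped frame)
  for (size_t t = 0; t < topo.tether_idx.size(); ++t) {
    const int i = topo.tether_idx[t];
    double dx = pos(i, 0) - topo.tether_anchor(t, 0);
    double dy = pos(i, 1) - topo.tether_anchor(t, 1);
    double dz = pos(i, 2) - topo.tether_anchor(t, 2);
    energy += topo.k_tether * (dx * dx + dy * dy + dz * dz);
    force(i, 0) -= 2.0 * topo.k_tether * dx;
    force(i, 1) -= 2.0 * topo.k_tether * dy;
    force(i, 2) -= 2.0 * topo.k_tether * dz;
  }
  return energy;
}

PairTables make_pair_tables(const NumericMatrix& sigma_table, double eps,
                            double rcut_factor, double skin) {
  PairTables pt;
  pt.ntype = sigma_table.nrow();
  pt.eps = eps;
  pt.sigma2.resize(pt.ntype * pt.ntype);
  pt.rcut2.resize(pt.ntype * pt.ntype);
  pt.eshift.resize(pt.ntype * pt.ntype);
  pt.listcut2.resize(pt.ntype * pt.ntype);
  for (int a = 0; a < pt.ntype; ++a)
    for (int b = 0; b < pt.ntype; ++b) {
      double sig = sigma_table(a, b);
      double rc = rcut_factor * sig;
      int k = a * pt.ntype + b;
      pt.sigma2[k] = sig * sig;
      pt.rcut2[k] = rc * rc;
      double sr6 = std::pow(sig / rc, 6);
      pt.eshift[k] = 4.0 * eps * (sr6 * sr6 - sr6);
      pt.listcut2[k] = (rc + skin) * (rc + skin);
    }
  return pt;
}

Topology make_topology(const IntegerMatrix& bonds, const IntegerMatrix& angles,
                       const NumericVector& ka, const IntegerVector& tether_idx,
                       const NumericMatrix& tether_anchor, double kb, double r0,
                       double theta0, double k_tether, int n) {
  Topology topo;
  topo.bonds.set_size(bonds.nrow(), 2);
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    topo.bonds(b, 0) = i; topo.bonds(b, 1) = j;
    if (i > j) std::swap(i, j);
    topo.excl.insert((uint64_t)i * n + j);
  }
  topo.angles.set_size(angles.nrow(), 3);
  for (int a = 0; a < angles.nrow(); ++a)
    for (int c = 0; c < 3; ++c) topo.angles(a, c) = angles(a, c) - 1;
  topo.ka.assign(ka.begin(), ka.end());
  topo.tether_idx.resize(tether_idx.size());
  for (int t = 0; t < tether_idx.size(); ++t) topo.tether_idx[t] = tether_idx[t] - 1;
  topo.tether_anchor = as<arma::mat>(tether_anchor);
  topo.kb = kb; topo.r0 = r0; topo.theta0 = theta0; topo.k_tether = k_tether;
  return topo;
}

}  // namespace

// ---------------------------------------------------------------------------
// Single-point energy/forces (neighbour-list path, fresh list each call).
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector box, IntegerVector type,
                NumericMatrix sigma_table, double eps, double rcut_factor,
                IntegerMatrix bonds, IntegerMatrix angles, NumericVector ka,
                IntegerVector tether_idx, NumericMatrix tether_anchor,
                double kb, double r0, double theta0, double k_tether) {
  const int n = pos.nrow();
  arma::mat P = as<arma::mat>(pos);
  arma::vec B = as<arma::vec>(box);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) ty[i] = type[i] - 1;
  PairTables pt = make_pair_tables(sigma_table, eps, rcut_factor, 0.0);
  Topology topo = make_topology(bonds, angles, ka, tether_idx, tether_anchor,
                                kb, r0, theta0, k_tether, n);
  NeighborList nl;
  build_neighbor_list(P, B, ty, pt, topo, nl);
  arma::mat F(n, 3);
  double e = compute_forces(P, B, ty, pt, topo, nl, F);
  return List::create(_["energy"] = e, _["forces"] = wrap(F));
}

// ---------------------------------------------------------------------------
// Langevin run.  Positions in/out are unwrapped; `save_idx` (1-based) selects
// the beads stored per frame.  Production frame 0 is the post-equilibration
// state; a frame is stored every `save_stride` steps thereafter.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                      IntegerVector type, NumericMatrix sigma_table, double eps,
                      double rcut_factor, IntegerMatrix bonds,
                      IntegerMatrix angles, NumericVector ka,
                      IntegerVector tether_idx, NumericMatrix tether_anchor,
                      double kb, double r0, double theta0, double k_tether,
                      double dt, double zeta, double temperature, double mass,
                      int n_steps, int save_stride, int equil_steps,
                      double seed, bool thermostat_off, double skin,
                      IntegerVector save_idx) {
  const int n = pos.nrow();
  arma::mat P = as<arma::mat>(pos);
  arma::mat V = as<arma::mat>(vel);
  arma::vec B = as<arma::vec>(box);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) ty[i] = type[i] - 1;

  PairTables pt = make_pair_tables(sigma_table, eps, rcut_factor, skin);
  Topology topo = make_topology(bonds, angles, ka, tether_idx, tether_anchor,
                                kb, r0, theta0, k_tether, n);
  NeighborList nl;
  build_neighbor_list(P, B, ty, pt, topo, nl);
  arma::mat F(n, 3), Fnew(n, 3);
  double pe = compute_forces(P, B, ty, pt, topo, nl, F);

  Xoshiro rng((uint64_t)seed);
  const double gamma = thermostat_off ? 0.0 : zeta;
  const double bfac = 1.0 / (1.0 + gamma * dt / 2.0);
  const double afac = (1.0 - gamma * dt / 2.0) * bfac;
  const double nsd = (gamma > 0.0)
      ? std::sqrt(2.0 * gamma * mass * temperature * dt) : 0.0;

  const int n_save = n_steps / save_stride + 1;
  const int nsv = save_idx.size();
  arma::cube frames(n_save, nsv, 3);
  std::vector<double> save_time(n_save), ke_series(n_save), pe_series(n_save);
  double ke_accum = 0.0;
  long ke_count = 0;
  // kinetic temperature is accumulated from the GJF half-step velocity
  // (x_{n+1} - x_n)/(sqrt(b) dt), which samples kBT/m without the on-site
  // velocity's O((w dt)^2) depression for stiff modes
  const double vh_norm = 1.0 / (std::sqrt(bfac) * dt);
  arma::mat Pprev(n, 3);

  int save_slot = 0;
  const long total = (long)equil_steps + n_steps;
  arma::mat beta(n, 3);

  auto store_frame = [&](int slot, long prod_step) {
    for (int s = 0; s < nsv; ++s) {
      int i = save_idx[s] - 1;
      frames(slot, s, 0) = P(i, 0);
      frames(slot, s, 1) = P(i, 1);
      frames(slot, s, 2) = P(i, 2);
    }
    save_time[slot] = prod_step * dt;
    ke_series[slot] = 0.5 * mass * arma::accu(V % V);
    pe_series[slot] = pe;
  };
  if (equil_steps == 0) store_frame(save_slot++, 0);

  for (long step = 1; step <= total; ++step) {
    if (nsd > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) beta(i, c) = nsd * rng.gauss();
    }
    Pprev = P;
    // GJF position update
    if (nsd > 0.0)
      P += bfac * dt * V + (bfac * dt * dt / (2.0 * mass)) * F +
           (bfac * dt / (2.0 * mass)) * beta;
    else
      P += bfac * dt * V + (bfac * dt * dt / (2.0 * mass)) * F;

    if (needs_rebuild(P, nl, skin)) build_neighbor_list(P, B, ty, pt, topo, nl);
    pe = compute_forces(P, B, ty, pt, topo, nl, Fnew);

    // GJF velocity update
    if (nsd > 0.0)
      V = afac * V + (dt / (2.0 * mass)) * (afac * F + Fnew) + (bfac / mass) * beta;
    else
      V = afac * V + (dt / (2.0 * mass)) * (afac * F + Fnew);
    F = Fnew;

    if (!P.is_finite() || !V.is_finite())
      stop("non-finite coordinate/velocity at step %ld", step);

    if (step >= equil_steps) {
      long prod_step = step - equil_steps;
      if (prod_step > 0) {
        arma::mat vh = (P - Pprev) * vh_norm;
        ke_accum += 0.5 * mass * arma::accu(vh % vh);
        ke_count++;
      }
      if (prod_step % save_stride == 0 && save_slot < n_save)
        store_frame(save_slot++, prod_step);
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["frames"] = wrap(frames), _["times"] = wrap(save_time),
      _["ke_series"] = wrap(ke_series), _["pe_series"] = wrap(pe_series),
      _["ke_mean_per_bead"] = (ke_count > 0 ? ke_accum / (ke_count * (double)n)
                                            : 0.5 * mass * arma::accu(V % V) / n),
      _["final_pos"] = wrap(P), _["final_vel"] = wrap(V),
      _["n_rebuilds"] = (double)nl.n_rebuilds);
}

// ---------------------------------------------------------------------------
// Per-rod reduction: centre of mass, gyration eigenvalues (ascending from
// eig_sym, returned descending), principal axis (largest eigenvalue), squared
// end-to-end distance.  `frames` is n_frames x n_beads x 3 (unwrapped);
// `rod_of` maps saved beads to rod index 1..n_rods (0 = not a rod bead).
// [[Rcpp::export]]
List cpp_rod_series(NumericVector frames, IntegerVector dims,
                    IntegerVector rod_of, int n_rods) {
  const int nf = dims[0], nb = dims[1];
  arma::cube C(frames.begin(), nf, nb, 3, false);
  arma::cube com(nf, n_rods, 3), axis(nf, n_rods, 3), eigs(nf, n_rods, 3);
  arma::mat ree2(nf, n_rods);

  std::vector<std::vector<int>> members(n_rods);
  for (int b = 0; b < nb; ++b)
    if (rod_of[b] > 0) members[rod_of[b] - 1].push_back(b);

  arma::mat33 S, vecs;
  arma::vec3 vals;
  for (int r = 0; r < n_rods; ++r) {
    const std::vector<int>& mb = members[r];
    const int m = mb.size();
    if (m < 2) stop("rod %d has fewer than 2 beads", r + 1);
    for (int f = 0; f < nf; ++f) {
      double cx = 0, cy = 0, cz = 0;
      for (int q = 0; q < m; ++q) {
        cx += C(f, mb[q], 0); cy += C(f, mb[q], 1); cz += C(f, mb[q], 2);
      }
      cx /= m; cy /= m; cz /= m;
      com(f, r, 0) = cx; com(f, r, 1) = cy; com(f, r, 2) = cz;
      S.zeros();
      for (int q = 0; q < m; ++q) {
        double dx = C(f, mb[q], 0) - cx, dy = C(f, mb[q], 1) - cy,
               dz = C(f, mb[q], 2) - cz;
        S(0, 0) += dx * dx; S(0, 1) += dx * dy; S(0, 2) += dx * dz;
        S(1, 1) += dy * dy; S(1, 2) += dy * dz; S(2, 2) += dz * dz;
      }
      S(1, 0) = S(0, 1); S(2, 0) = S(0, 2); S(2, 1) = S(1, 2);
      S /= m;
      if (S(0,0) + S(1,1) + S(2,2) < 1e-20)
        stop("all beads of rod %d coincide at frame %d", r + 1, f + 1);
      arma::eig_sym(vals, vecs, S);
      // descending eigenvalues; axis = eigenvector of the largest
      eigs(f, r, 0) = vals[2]; eigs(f, r, 1) = vals[1]; eigs(f, r, 2) = vals[0];
      axis(f, r, 0) = vecs(0, 2); axis(f, r, 1) = vecs(1, 2); axis(f, r, 2) = vecs(2, 2);
      double ex = C(f, mb[m - 1], 0) - C(f, mb[0], 0);
      double ey = C(f, mb[m - 1], 1) - C(f, mb[0], 1);
      double ez = C(f, mb[m - 1], 2) - C(f, mb[0], 2);
      ree2(f, r) = ex * ex + ey * ey + ez * ez;
      // provisional sign: along the end-to-end vector
      if (axis(f, r, 0) * ex + axis(f, r, 1) * ey + axis(f, r, 2) * ez < 0) {
        axis(f, r, 0) = -axis(f, r, 0);
        axis(f, r, 1) = -axis(f, r, 1);
        axis(f, r, 2) = -axis(f, r, 2);
      }
    }
    // sign continuity in time overrides the end-to-end convention after frame 1
    for (int f = 1; f < nf; ++f) {
      double d = axis(f, r, 0) * axis(f - 1, r, 0) +
                 axis(f, r, 1) * axis(f - 1, r, 1) +
                 axis(f, r, 2) * axis(f - 1, r, 2);
      if (d < 0) {
        axis(f, r, 0) = -axis(f, r, 0);
        axis(f, r, 1) = -axis(f, r, 1);
        axis(f, r, 2) = -axis(f, r, 2);
      }
    }
  }
  return List::create(_["com"] = wrap(com), _["axis"] = wrap(axis),
                      _["gyration_eigs"] = wrap(eigs), _["ree2"] = wrap(ree2));
}
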