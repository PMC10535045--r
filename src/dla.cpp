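#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

// On-lattice DLA emulating the dense radially branched dendrites of drying
// protein self-assembly. Walkers take 4-neighbour steps on the integer
// plane; inside the boundary layer around the cluster (within the launch
// radius) each step is biased toward the lattice centre with probability
// `drift`, emulating the evaporation-driven convective flux of a drying
// droplet (drift = 0 recovers the classical Witten--Sander model). Outside
// that layer the walk is pure diffusion. Walkers attach with probability
// `stickiness` when 8-adjacent to the cluster, are launched on a circle just
// outside the current cluster radius and relaunched (never discarded) past
// the kill radius at three times the launch radius.
//
// When a walker is farther from the cluster than its next L steps can cover,
// the L-step walk is sampled exactly in one move (the x/y split is
// Binomial(L, 1/2) and each axis displacement is a shifted Binomial), which
// preserves the walk distribution while skipping the empty-space steps.
//
// The only randomness is a mt19937 keyed by `rng_seed`; R's RNG stream is
// never touched. Coordinates are 0-based internally; the returned matrix is
// 1-based (row, col), seed sites first, then particles in attachment order.

static inline double dist2(double dr, double dc) { return dr * dr + dc * dc; }

// [[Rcpp::export(name = ".grow_cluster_cpp")]]
IntegerMatrix grow_cluster_cpp(int lattice_size, int n_particles,
                               double stickiness, int rng_seed, int n_nuclei,
                               double drift) {
  const int L = lattice_size;
  std::mt19937 rng(static_cast<uint32_t>(rng_seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> step4(0, 3);

  std::vector<uint8_t> grid(static_cast<size_t>(L) * L, 0);
  auto at = [&](int r, int c) -> uint8_t& {
    return grid[static_cast<size_t>(r) * L + c];
  };

  std::vector<int> occ_r, occ_c;
  occ_r.reserve(n_particles + n_nuclei);
  occ_c.reserve(n_particles + n_nuclei);

  const double ctr = (L - 1) / 2.0;

  if (n_nuclei == 1) {
    int r0 = L / 2, c0 = L / 2;
    at(r0, c0) = 1;
    occ_r.push_back(r0);
    occ_c.push_back(c0);
  } else {
    // keep random nuclei off the outer margin so growth is not aborted
    // by a seed that spawns against the boundary
    const int m = std::max(5, L / 16);
    std::uniform_int_distribution<int> pos(m, L - 1 - m);
    int placed = 0;
    while (placed < n_nuclei) {
      int r0 = pos(rng), c0 = pos(rng);
      if (!at(r0, c0)) {
        at(r0, c0) = 1;
        occ_r.push_back(r0);
        occ_c.push_back(c0);
        ++placed;
      }
    }
  }

  double rmax = 0.0;  // cluster radius about the lattice centre
  for (size_t i = 0; i < occ_r.size(); ++i) {
    double d = std::sqrt(dist2(occ_r[i] - ctr, occ_c[i] - ctr));
    if (d > rmax) rmax = d;
  }

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};

  auto adjacent = [&](int r, int c) -> bool {
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr >= 0 && rr < L && cc >= 0 && cc < L && at(rr, cc)) return true;
    }
    return false;
  };

  std::uniform_real_distribution<double> ang(0.0, 2.0 * M_PI);

  for (int p = 0; p < n_particles; ++p) {
    double launch = rmax + 5.0;
    double kill = 3.0 * launch;
    double kill2 = kill * kill;

    double a = ang(rng);
    int r = static_cast<int>(std::lround(ctr + launch * std::sin(a)));
    int c = static_cast<int>(std::lround(ctr + launch * std::cos(a)));

    bool stuck = false;
    while (!stuck) {
      double d_ctr = std::sqrt(dist2(r - ctr, c - ctr));
      if (d_ctr * d_ctr > kill2) {  // relaunch, never discard
        a = ang(rng);
        r = static_cast<int>(std::lround(ctr + launch * std::sin(a)));
        c = static_cast<int>(std::lround(ctr + launch * std::cos(a)));
        continue;
      }
      int gap = static_cast<int>(std::floor(d_ctr - rmax - 2.0));
      if (gap >= 8) {
        // exact L-step jump through empty space
        std::binomial_distribution<int> split(gap, 0.5);
        int kx = split(rng);
        int ky = gap - kx;
        std::binomial_distribution<int> bx(kx, 0.5), by(ky, 0.5);
        r += 2 * by(rng) - ky;
        c += 2 * bx(rng) - kx;
        continue;
      }
      int rn, cn;
      if (drift > 0 && d_ctr <= rmax + 10.0 && unif(rng) < drift) {
        // convective step toward the lattice centre, axis chosen
        // proportionally to the displacement components
        double adr = std::fabs(ctr - r), adc = std::fabs(ctr - c);
        bool row_step = (adr + adc) > 0 &&
          unif(rng) < adr / (adr + adc);
        rn = r + (row_step ? (ctr > r ? 1 : -1) : 0);
        cn = c + (row_step ? 0 : (ctr > c ? 1 : -1));
      } else {
        int k = step4(rng);
        rn = r + dr4[k];
        cn = c + dc4[k];
      }
      if (rn >= 0 && rn < L && cn >= 0 && cn < L && at(rn, cn))
        continue;  // blocked: cluster sites are never stepped on
      r = rn;
      c = cn;
      if (r >= 0 && r < L && c >= 0 && c < L && adjacent(r, c) &&
          unif(rng) < stickiness) {
        if (r == 0 || r == L - 1 || c == 0 || c == L - 1)
          stop("cluster reached the lattice boundary after %d of %d particles; "
               "increase lattice_size or reduce n_particles", p, n_particles);
        at(r, c) = 1;
        occ_r.push_back(r);
        occ_c.push_back(c);
        double d = std::sqrt(dist2(r - ctr, c - ctr));
        if (d > rmax) rmax = d;
        stuck = true;
      }
    }
    if ((p & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix out(occ_r.size(), 2);
  for (size_t i = 0; i < occ_r.size(); ++i) {
    out(i, 0) = occ_r[i] + 1;
    out(i, 1) = occ_c[i] + 1;
  }
  return out;
}
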