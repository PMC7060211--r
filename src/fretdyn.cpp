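#include <Rcpp.h>
#include <random>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Brownian-dynamics photon-stream simulation
//
// Freely diffusing molecules in a periodic box, 3D-Gaussian detection
// profile, continuous-time state switching resolved exactly within each
// diffusion step, per-state emission rates per detection channel, photon
// micro-times from the state's donor/acceptor decay convolved with a
// Gaussian IRF. Units: time ms, space um, micro-times ns.
// ---------------------------------------------------------------------------

struct PhotonBuf {
  std::vector<double> t;      // absolute time, ms
  std::vector<int> det;       // 0 green, 1 red
  std::vector<double> mic;    // micro-time, ns (pre-discretisation)
};

// [[Rcpp::export]]
List cpp_simulate_photons(
    int n_mol, NumericVector box_half, double w_xy, double w_z,
    double diff_coef, double dt, double duration,
    NumericMatrix K,                 // rate matrix, K(i,j) = rate i->j (1/ms)
    NumericMatrix trans_prob,        // exp(K * dt), row = from state
    NumericMatrix chan_rates,        // n_states x 4: green, red_fret, red_ct, red_dir (kHz)
    NumericVector state_kfret,       // FRET rate per state (1/ns)
    NumericVector donor_amp, NumericVector donor_tau,   // donor spectrum (ns)
    double tau_acceptor,             // ns
    double irf_mean, double irf_sigma,                   // ns
    IntegerVector init_state, NumericMatrix init_pos, bool use_init_pos,
    double intensity_cutoff, double seed) {

  const int n_states = K.nrow();
  const int nd = donor_amp.size();
  std::vector<double> damp_cum(nd);
  double acc = 0.0;
  for (int m = 0; m < nd; ++m) { acc += donor_amp[m]; damp_cum[m] = acc; }
  for (int m = 0; m < nd; ++m) damp_cum[m] /= acc;

  std::vector<double> k_exit(n_states, 0.0);
  for (int s = 0; s < n_states; ++s)
    for (int j = 0; j < n_states; ++j) if (j != s) k_exit[s] += K(s, j);

  const double lx = box_half[0], ly = box_half[1], lz = box_half[2];
  const double sig_step = std::sqrt(2.0 * diff_coef * dt);
  const long n_steps = (long)std::ceil(duration / dt);

  PhotonBuf buf;
  buf.t.reserve(1 << 20);

  for (int mol = 0; mol < n_mol; ++mol) {
    // deterministic per-molecule child seed
    std::mt19937_64 rng((uint64_t)seed * 6364136223846793005ULL +
                        (uint64_t)(mol + 1) * 1442695040888963407ULL);
    std::normal_distribution<double> norm01(0.0, 1.0);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    double x, y, z;
    if (use_init_pos) {
      x = init_pos(mol, 0); y = init_pos(mol, 1); z = init_pos(mol, 2);
    } else {
      x = (2.0 * unif(rng) - 1.0) * lx;
      y = (2.0 * unif(rng) - 1.0) * ly;
      z = (2.0 * unif(rng) - 1.0) * lz;
    }
    int s = init_state[mol % init_state.size()];
    double t_switch = (k_exit[s] > 0.0)
      ? -std::log(unif(rng)) / k_exit[s] : std::numeric_limits<double>::infinity();

    // squared-radius bound outside which emission is negligible
    const double log_cut = -std::log(std::max(intensity_cutoff, 1e-300));

    for (long step = 0; step < n_steps; ++step) {
      const double t0 = step * dt;
      const double t1 = std::min(t0 + dt, duration);
      const double arg = 2.0 * (x * x + y * y) / (w_xy * w_xy)
                       + 2.0 * z * z / (w_z * w_z);
      if (arg > log_cut) {
        // far from the focus no photon can be detected, so the chain only
        // needs its end-of-step state: draw it from the exact transition
        // matrix exp(K dt) and redraw the next switch time (Markov property)
        if (t_switch <= t1 && k_exit[s] > 0.0) {
          const double u = unif(rng);
          double c = 0.0; int nxt = s;
          for (int j = 0; j < n_states; ++j) {
            c += trans_prob(s, j);
            if (u <= c) { nxt = j; break; }
            nxt = j;
          }
          s = nxt;
          t_switch = t1 + ((k_exit[s] > 0.0)
            ? -std::log(unif(rng)) / k_exit[s]
            : std::numeric_limits<double>::infinity());
        }
        if (sig_step > 0.0) {
          x += sig_step * norm01(rng);
          y += sig_step * norm01(rng);
          z += sig_step * norm01(rng);
          if (x > lx) x -= 2.0 * lx; else if (x < -lx) x += 2.0 * lx;
          if (y > ly) y -= 2.0 * ly; else if (y < -ly) y += 2.0 * ly;
          if (z > lz) z -= 2.0 * lz; else if (z < -lz) z += 2.0 * lz;
        }
        continue;
      }
      // the detection intensity is held at the step-start position; the
      // diffusion step is short enough (sqrt(2 D dt) <= w_xy/20) that this
      // quasi-static sampling reproduces the diffusion correlation shape
      const double inten = std::exp(-arg);
      double seg_start = t0;
      while (seg_start < t1) {
        double seg_end = std::min(t1, t_switch);
        {
          const double dur = seg_end - seg_start;
          for (int ch = 0; ch < 4; ++ch) {
            const double rate = chan_rates(s, ch) * inten;
            if (rate <= 0.0) continue;
            // Knuth Poisson sampling: cheap at the small per-step means
            int n_ph = 0;
            {
              const double L = std::exp(-rate * dur);
              double prod = unif(rng);
              while (prod > L) { ++n_ph; prod *= unif(rng); }
            }
            for (int p = 0; p < n_ph; ++p) {
              const double tp = seg_start + dur * unif(rng);
              // micro-time: donor decay component + FRET quench (+ acceptor)
              double mic = irf_mean + irf_sigma * norm01(rng);
              const double u = unif(rng);
              int m = 0; while (m < nd - 1 && u > damp_cum[m]) ++m;
              const double k_d = 1.0 / donor_tau[m];
              const double kf = state_kfret[s];
              if (ch == 0 || ch == 2) {
                // green fluorescence / crosstalk: donor-quenched decay
                mic += -std::log(unif(rng)) / (k_d + kf);
              } else if (ch == 1) {
                // FRET-sensitised acceptor: transfer time + acceptor decay
                mic += -std::log(unif(rng)) / (k_d + kf)
                     - std::log(unif(rng)) * tau_acceptor;
              } else {
                // directly excited acceptor
                mic += -std::log(unif(rng)) * tau_acceptor;
              }
              buf.t.push_back(tp);
              buf.det.push_back(ch == 0 ? 0 : 1);
              buf.mic.push_back(mic);
            }
          }
        }
        if (t_switch <= t1) {
          // exact state switch inside the diffusion step
          double u = unif(rng) * k_exit[s];
          int nxt = 0; double c = 0.0;
          for (int j = 0; j < n_states; ++j) {
            if (j == s) continue;
            c += K(s, j);
            if (u <= c) { nxt = j; break; }
            nxt = j;
          }
          s = nxt;
          t_switch += (k_exit[s] > 0.0)
            ? -std::log(unif(rng)) / k_exit[s]
            : std::numeric_limits<double>::infinity();
        }
        seg_start = seg_end;
      }
      // diffusion step with periodic wrapping
      if (sig_step > 0.0) {
        x += sig_step * norm01(rng);
        y += sig_step * norm01(rng);
        z += sig_step * norm01(rng);
        if (x > lx) x -= 2.0 * lx; else if (x < -lx) x += 2.0 * lx;
        if (y > ly) y -= 2.0 * ly; else if (y < -ly) y += 2.0 * ly;
        if (z > lz) z -= 2.0 * lz; else if (z < -lz) z += 2.0 * lz;
      }
    }
  }
  return List::create(_["time_ms"] = buf.t, _["detector"] = buf.det,
                      _["micro_ns"] = buf.mic);
}

// ---------------------------------------------------------------------------
// Photon-pair correlator on a quasi-logarithmic lag grid.
// For sorted photon times t with per-photon weights w1 (species i) and w2
// (species j), accumulates S_k = sum_i w1_i * sum_{j: t_j - t_i in bin k} w2_j
// via persistent two-pointer sweeps and prefix sums, plus the expected
// independent-pair mass D_k with boundary (finite-duration) correction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pair_correlate(NumericVector t, NumericVector w1, NumericVector w2,
                        NumericVector edges, double T_total) {
  const int n = t.size();
  const int nb = edges.size() - 1;
  std::vector<double> pre(n + 1, 0.0);
  for (int i = 0; i < n; ++i) pre[i + 1] = pre[i] + w2[i];
  const double W2 = pre[n];
  double W1 = 0.0;
  for (int i = 0; i < n; ++i) W1 += w1[i];

  NumericVector S(nb), D(nb);
  for (int k = 0; k < nb; ++k) {
    const double e0 = edges[k], e1 = edges[k + 1];
    int lo = 0, hi = 0;
    double s = 0.0, ovl = 0.0;
    for (int i = 0; i < n; ++i) {
      if (w1[i] == 0.0) continue;
      const double a = t[i] + e0, b = t[i] + e1;
      while (lo < n && t[lo] < a) ++lo;
      if (hi < lo) hi = lo;
      while (hi < n && t[hi] < b) ++hi;
      s += w1[i] * (pre[hi] - pre[lo]);
      const double cover = std::max(0.0, std::min(b, T_total) - std::min(a, T_total));
      ovl += w1[i] * cover;
    }
    S[k] = s;
    D[k] = (W2 / T_total) * ovl;
  }
  return List::create(_["S"] = S, _["D"] = D, _["W1"] = W1, _["W2"] = W2);
}

// ---------------------------------------------------------------------------
// Accessible-volume grid search: Dijkstra geodesic ("linker path") distances
// from the attachment point over voxels with enough clearance for the linker,
// returning all voxels reachable within the linker length that can host at
// least one of the dye-sphere radii.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_acv_grid(NumericMatrix atoms, NumericVector vdw,
                  NumericVector attach, double linker_length,
                  double linker_radius, NumericVector dye_radii,
                  double contact_thickness, double spacing) {
  const int na = atoms.nrow();
  double max_r = 0.0;
  for (double r : dye_radii) max_r = std::max(max_r, r);
  const double ext = linker_length + max_r;
  const int half = (int)std::floor(ext / spacing);
  const int dim = 2 * half + 1;
  const long nv = (long)dim * dim * dim;

  // clearance = min over atoms of (distance to atom centre - vdw radius)
  std::vector<double> clear_(nv, 1e30);
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int ix = 0; ix < dim; ++ix)
    for (int iy = 0; iy < dim; ++iy)
      for (int iz = 0; iz < dim; ++iz) {
        const long v = ((long)ix * dim + iy) * dim + iz;
        vx[v] = attach[0] + (ix - half) * spacing;
        vy[v] = attach[1] + (iy - half) * spacing;
        vz[v] = attach[2] + (iz - half) * spacing;
      }
  for (int a = 0; a < na; ++a) {
    const double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    // only atoms that can influence the box
    if (std::abs(ax - attach[0]) > ext + vdw[a] + max_r + spacing) continue;
    if (std::abs(ay - attach[1]) > ext + vdw[a] + max_r + spacing) continue;
    if (std::abs(az - attach[2]) > ext + vdw[a] + max_r + spacing) continue;
    for (long v = 0; v < nv; ++v) {
      const double dx = vx[v] - ax, dy = vy[v] - ay, dz = vz[v] - az;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[a];
      if (d < clear_[v]) clear_[v] = d;
    }
  }

  // Dijkstra over the 26-neighbourhood; a voxel is traversable if the
  // flexible linker fits (clearance >= linker_radius)
  std::vector<double> dist(nv, 1e30);
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  const long start = ((long)half * dim + half) * dim + half;
  dist[start] = 0.0;
  pq.push(Node(0.0, start));
  const int off[26][3] = {
    {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
    {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
    {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},{1,-1,-1},
    {1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}};
  double wlen[26];
  for (int o = 0; o < 26; ++o)
    wlen[o] = spacing * std::sqrt((double)(off[o][0]*off[o][0] +
                                           off[o][1]*off[o][1] +
                                           off[o][2]*off[o][2]));
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    const double d0 = nd.first; const long v = nd.second;
    if (d0 > dist[v]) continue;
    if (d0 > linker_length) continue;
    const int iz = (int)(v % dim), iy = (int)((v / dim) % dim),
              ix = (int)(v / ((long)dim * dim));
    for (int o = 0; o < 26; ++o) {
      const int jx = ix + off[o][0], jy = iy + off[o][1], jz = iz + off[o][2];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= dim || jy >= dim || jz >= dim)
        continue;
      const long u = ((long)jx * dim + jy) * dim + jz;
      if (clear_[u] < linker_radius) continue;
      const double d1 = d0 + wlen[o];
      if (d1 < dist[u] && d1 <= linker_length) {
        dist[u] = d1;
        pq.push(Node(d1, u));
      }
    }
  }

  std::vector<double> ox, oy, oz, ocl, odist;
  std::vector<int> contact;
  for (long v = 0; v < nv; ++v) {
    if (dist[v] > linker_length) continue;
    bool fits = false;
    for (double r : dye_radii) if (clear_[v] >= r) { fits = true; break; }
    if (!fits) continue;
    ox.push_back(vx[v]); oy.push_back(vy[v]); oz.push_back(vz[v]);
    ocl.push_back(clear_[v]); odist.push_back(dist[v]);
    contact.push_back(clear_[v] <= contact_thickness ? 1 : 0);
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["z"] = oz,
                      _["clearance"] = ocl, _["path_length"] = odist,
                      _["contact"] = contact);
}

// weighted mean pairwise distance and mean FRET efficiency between clouds
// [[Rcpp::export]]
NumericVector cpp_cloud_metrics(NumericMatrix d_xyz, NumericVector d_w,
                                NumericMatrix a_xyz, NumericVector a_w,
                                double R0) {
  const int n = d_xyz.nrow(), m = a_xyz.nrow();
  double sum_r = 0.0, sum_e = 0.0, sum_w = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = d_xyz(i, 0), yi = d_xyz(i, 1), zi = d_xyz(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = xi - a_xyz(j, 0), dy = yi - a_xyz(j, 1),
                   dz = zi - a_xyz(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = d_w[i] * a_w[j];
      sum_r += w * r;
      if (R0 > 0) {
        const double q = std::pow(r / R0, 6.0);
        sum_e += w / (1.0 + q);
      }
      sum_w += w;
    }
  }
  return NumericVector::create(sum_r / sum_w,
                               R0 > 0 ? sum_e / sum_w : NA_REAL);
}
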