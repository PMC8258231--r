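// Simulation engine: bit-packed genomes (uint64), per-channel brightness masks
// (uint32), and the per-iteration loop (energy provisioning, breeding with
// compatibility gating, mutation, dispersal, settlement, age-based death),
// plus species delimitation as connected components of the genetic
// compatibility graph. All randomness flows through one xoshiro256++ stream
// per world so that (seed, settings, environment) fully determine a run.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <map>
#include <algorithm>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ------

// xoshiro256++ with splitmix64 seeding (Blackman & Vigna). Self-contained so
// replays are exact across platforms, independent of R's RNG state.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
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
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // unbiased integer in [0, n)
  uint64_t bounded(uint64_t n) {
    uint64_t x, r;
    do { x = next(); r = x % n; } while (x - r > UINT64_MAX - (n - 1));
    return r;
  }
};

// ----------------------------------------------------- bitstring helpers ---

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static uint64_t parse_bits(const std::string& s, int nbits) {
  if ((int)s.size() != nbits)
    stop("expected a %d-bit binary string, got %d characters", nbits, (int)s.size());
  uint64_t v = 0;
  for (int i = 0; i < nbits; ++i) {
    char c = s[i];
    if (c != '0' && c != '1') stop("bit strings may contain only '0' and '1'");
    v = (v << 1) | (uint64_t)(c - '0');
  }
  return v;
}

static std::string format_bits(uint64_t v, int nbits) {
  std::string s(nbits, '0');
  for (int i = 0; i < nbits; ++i)
    if ((v >> (nbits - 1 - i)) & 1ULL) s[i] = '1';
  return s;
}

// The coding half is the first 32 characters of the 64-bit string (the high
// 32 bits of the packed value); the remaining 32 bits are fitness-neutral
// but count toward breeding compatibility.
static inline uint32_t coding_half(uint64_t g) { return (uint32_t)(g >> 32); }

// [[Rcpp::export]]
IntegerVector cpp_bit_hamming(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("lengths of 'a' and 'b' must match (or one must be length 1)");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    if (sa.size() != sb.size()) stop("bit strings must have equal length");
    uint64_t va = parse_bits(sa, sa.size());
    uint64_t vb = parse_bits(sb, sb.size());
    out[i] = popcount64(va ^ vb);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector g) {
  int n = g.size();
  std::vector<uint64_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = parse_bits(as<std::string>(g[i]), 64);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = popcount64(v[i] ^ v[j]);
      out(i, j) = d; out(j, i) = d;
    }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_random_genomes(int n, double seed) {
  Rng rng((uint64_t)seed);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = format_bits(rng.next(), 64);
  return out;
}

// ------------------------------------------------------------- masks -------

// One 32-bit mask per channel (r,g,b) per brightness 0..255; adjacent
// brightness levels differ by exactly one bit: mask[c][0] is uniform random,
// each subsequent mask flips one uniformly chosen bit of its predecessor.
// [[Rcpp::export]]
CharacterMatrix cpp_generate_masks(double seed) {
  Rng rng((uint64_t)seed);
  CharacterMatrix out(256, 3);
  for (int c = 0; c < 3; ++c) {
    uint32_t m = (uint32_t)(rng.next() & 0xFFFFFFFFULL);
    out(0, c) = format_bits(m, 32);
    for (int v = 1; v < 256; ++v) {
      m ^= (uint32_t)(1U << rng.bounded(32));
      out(v, c) = format_bits(m, 32);
    }
  }
  return out;
}

static void parse_masks(const CharacterMatrix& m, uint32_t masks[3][256]) {
  if (m.nrow() != 256 || m.ncol() != 3)
    stop("mask matrix must be 256 x 3 (brightness x channel)");
  for (int c = 0; c < 3; ++c)
    for (int v = 0; v < 256; ++v)
      masks[c][v] = (uint32_t)parse_bits(as<std::string>(m(v, c)), 32);
}

// [[Rcpp::export]]
IntegerVector cpp_coding_bitcount(CharacterVector genomes, IntegerVector colour,
                                  CharacterMatrix mask_matrix) {
  if (colour.size() != 3) stop("'colour' must have 3 channel values");
  for (int c = 0; c < 3; ++c)
    if (colour[c] < 0 || colour[c] > 255) stop("channel values must lie in 0..255");
  uint32_t masks[3][256];
  parse_masks(mask_matrix, masks);
  IntegerVector out(genomes.size());
  for (R_xlen_t i = 0; i < genomes.size(); ++i) {
    uint32_t cod = coding_half(parse_bits(as<std::string>(genomes[i]), 64));
    int bc = 0;
    for (int c = 0; c < 3; ++c) bc += popcount64(cod ^ masks[c][colour[c]]);
    out[i] = bc;
  }
  return out;
}

// ------------------------------------------------- standalone operations ---

// Offspring genome: each bit drawn fairly from one of the two parents, then
// with probability `mutation_chance` exactly one uniformly chosen bit flips.
// [[Rcpp::export]]
CharacterVector cpp_make_offspring(std::string p1, std::string p2,
                                   double mutation_chance, double seed, int n) {
  uint64_t g1 = parse_bits(p1, 64), g2 = parse_bits(p2, 64);
  Rng rng((uint64_t)seed);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t pick = rng.next();
    uint64_t child = (g1 & pick) | (g2 & ~pick);
    if (rng.unif() < mutation_chance) child ^= (1ULL << rng.bounded(64));
    out[i] = format_bits(child, 64);
  }
  return out;
}

// Dispersal kernel: weight 1/(1+d) for Euclidean centre-to-centre distance
// d <= scale; out-of-grid draws are rejected, which renormalizes the kernel
// over in-grid cells (d = 0 is always in-grid, so sampling terminates).
struct Kernel {
  std::vector<int> dx, dy;
  std::vector<double> cum;
  void build(int scale) {
    dx.clear(); dy.clear(); cum.clear();
    double tot = 0.0;
    for (int a = -scale; a <= scale; ++a)
      for (int b = -scale; b <= scale; ++b) {
        double d = std::sqrt((double)(a * a + b * b));
        if (d > scale + 1e-12) continue;
        dx.push_back(a); dy.push_back(b);
        tot += 1.0 / (1.0 + d);
        cum.push_back(tot);
      }
  }
};

static int draw_kernel(const Kernel& k, Rng& rng, int x, int y, int W, int H) {
  if (k.cum.empty()) return y * W + x;
  for (;;) {
    double u = rng.unif() * k.cum.back();
    size_t j = std::upper_bound(k.cum.begin(), k.cum.end(), u) - k.cum.begin();
    if (j >= k.cum.size()) j = k.cum.size() - 1;
    int tx = x + k.dx[j], ty = y + k.dy[j];
    if (tx >= 0 && tx < W && ty >= 0 && ty < H) return ty * W + tx;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_dispersal_draws(int width, int height, int x, int y,
                                  int scale, int n, double seed) {
  if (x < 0 || x >= width || y < 0 || y >= height) stop("parent position out of grid");
  Kernel k; k.build(scale);
  Rng rng((uint64_t)seed);
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int cell = draw_kernel(k, rng, x, y, width, height);
    out(i, 0) = cell % width;
    out(i, 1) = cell / width;
  }
  return out;
}

// ------------------------------------------------------------- world -------

struct Pending { uint64_t g; int cell; int sp; };

class WorldCpp {
public:
  // settings
  int W, H, S;
  double E;
  int tol, target;
  double breed_thr, breed_cost, mut;
  int maxdiff, lifespan, log_int, disp_scale;
  bool hybrid;
  // masks + environment
  uint32_t masks[3][256];
  std::vector<std::vector<unsigned char>> frames;
  int refresh; bool interp, cyclic;
  std::vector<unsigned char> cur;
  // organisms (index = cell * S + slot)
  std::vector<uint64_t> gen;
  std::vector<double> en;
  std::vector<int> age, sp, fitv;
  std::vector<unsigned char> alive;
  std::vector<int> occ;
  std::vector<Pending> pending;
  long iter; int next_species; bool seeded;
  Rng rng;
  Kernel kernel;
  // species registry
  std::vector<int> reg_id, reg_parent;
  std::vector<long> reg_origin, reg_extinct, reg_last;
  // accumulated logs
  std::vector<double> wl_iter, wl_abund, wl_fit, wl_even;
  std::vector<int> wl_rich;
  std::vector<double> sl_iter, sl_abund, sl_energy;
  std::vector<int> sl_id, sl_parent;

  WorldCpp(List settings, CharacterMatrix mask_matrix, List frame_list,
           int refresh_, bool interp_, bool cyclic_, double seed)
      : iter(0), next_species(1), seeded(false), rng((uint64_t)seed) {
    W = as<int>(settings["grid_width"]);
    H = as<int>(settings["grid_height"]);
    S = as<int>(settings["slots_per_cell"]);
    E = as<double>(settings["energy_per_cell"]);
    tol = as<int>(settings["settle_tolerance"]);
    target = as<int>(settings["fitness_target"]);
    breed_thr = as<double>(settings["breed_threshold"]);
    breed_cost = as<double>(settings["breed_cost"]);
    mut = as<double>(settings["mutation_chance"]);
    maxdiff = as<int>(settings["max_breed_difference"]);
    lifespan = as<int>(settings["max_lifespan"]);
    log_int = as<int>(settings["logging_interval"]);
    disp_scale = as<int>(settings["dispersal_scale"]);
    hybrid = as<bool>(settings["allow_hybridization"]);
    parse_masks(mask_matrix, masks);
    refresh = refresh_; interp = interp_; cyclic = cyclic_;
    int nf = frame_list.size();
    if (nf < 1) stop("environment needs at least one frame");
    for (int f = 0; f < nf; ++f) {
      IntegerVector fr = frame_list[f];  // flattened h x w x 3 (R array order)
      if ((int)fr.size() != W * H * 3) stop("frame dimensions must match the grid");
      std::vector<unsigned char> buf(W * H * 3);
      // R array [y, x, ch] is column-major: index y + H*x + H*W*ch
      for (int yy = 0; yy < H; ++yy)
        for (int xx = 0; xx < W; ++xx)
          for (int ch = 0; ch < 3; ++ch) {
            int v = fr[yy + H * xx + H * W * ch];
            if (v < 0 || v > 255) stop("channel values must lie in 0..255");
            buf[(yy * W + xx) * 3 + ch] = (unsigned char)v;
          }
      frames.push_back(std::move(buf));
    }
    int n = W * H * S;
    gen.assign(n, 0); en.assign(n, 0.0); age.assign(n, 0);
    sp.assign(n, 0); fitv.assign(n, 0); alive.assign(n, 0);
    occ.assign(W * H, 0);
    kernel.build(disp_scale);
    cur.assign(W * H * 3, 0);
    frame_for(0, cur);
  }

  // environment frame for iteration t (linear interpolation between key
  // frames; weighted integer mean floors exactly)
  void frame_for(long t, std::vector<unsigned char>& out) const {
    size_t nf = frames.size();
    if (nf == 1) { out = frames[0]; return; }
    long idx = t / refresh;
    long frac = t % refresh;
    size_t ia, ib;
    if (cyclic) { ia = (size_t)(idx % (long)nf); ib = (ia + 1) % nf; }
    else {
      ia = (size_t)std::min<long>(idx, (long)nf - 1);
      ib = (size_t)std::min<long>(idx + 1, (long)nf - 1);
    }
    const std::vector<unsigned char>& A = frames[ia];
    const std::vector<unsigned char>& B = frames[ib];
    if (!interp || frac == 0) { out = A; return; }
    out.resize(A.size());
    for (size_t i = 0; i < A.size(); ++i)
      out[i] = (unsigned char)(((long)A[i] * (refresh - frac) + (long)B[i] * frac) / refresh);
  }

  int fitness_at(int cell, uint64_t g) const {
    const unsigned char* col = &cur[cell * 3];
    uint32_t cod = coding_half(g);
    int bc = popcount64(cod ^ masks[0][col[0]]) +
             popcount64(cod ^ masks[1][col[1]]) +
             popcount64(cod ^ masks[2][col[2]]);
    int f = tol - std::abs(target - bc);
    return f < 0 ? 0 : f;
  }

  void phase_env() {
    std::vector<unsigned char> nc;
    frame_for(iter, nc);
    if (nc != cur) {
      cur.swap(nc);
      for (int c = 0; c < W * H; ++c) {
        if (occ[c] == 0) continue;
        for (int s = 0; s < S; ++s) {
          int i = c * S + s;
          if (alive[i]) fitv[i] = fitness_at(c, gen[i]);
        }
      }
    }
  }

  void phase_provision() {
    for (int c = 0; c < W * H; ++c) {
      if (occ[c] == 0) continue;
      long sumf = 0;
      int base = c * S;
      for (int s = 0; s < S; ++s)
        if (alive[base + s]) sumf += fitv[base + s];
      if (sumf <= 0) continue;  // zero-total-fitness cells distribute nothing
      double per = E / (double)sumf;
      for (int s = 0; s < S; ++s) {
        int i = base + s;
        if (alive[i] && fitv[i] > 0) en[i] += per * fitv[i];
      }
    }
  }

  void phase_breed() {
    std::vector<int> list;
    for (int c = 0; c < W * H; ++c) {
      if (occ[c] == 0) continue;
      list.clear();
      int base = c * S;
      for (int s = 0; s < S; ++s) {
        int i = base + s;
        if (alive[i] && en[i] > breed_thr) list.push_back(i);
      }
      size_t L = list.size();
      if (L == 0) continue;
      // randomized processing order, drawn from the run's RNG
      for (size_t a = L - 1; a > 0; --a)
        std::swap(list[a], list[rng.bounded(a + 1)]);
      if (L == 1) continue;  // singleton list: costless failure
      for (size_t pos = 0; pos < L; ++pos) {
        int ini = list[pos];
        // partner uniform among the other listed occupants
        size_t j = rng.bounded(L - 1);
        if (j >= pos) ++j;
        int par = list[j];
        if (!hybrid && sp[ini] != sp[par]) continue;        // failure, no cost
        if (popcount64(gen[ini] ^ gen[par]) > maxdiff) continue;  // failure, no cost
        en[ini] -= breed_cost;
        uint64_t pick = rng.next();
        uint64_t child = (gen[ini] & pick) | (gen[par] & ~pick);
        if (rng.unif() < mut) child ^= (1ULL << rng.bounded(64));
        int tc = draw_kernel(kernel, rng, c % W, c / W, W, H);
        pending.push_back({child, tc, sp[ini]});
      }
    }
  }

  void phase_age() {
    for (int c = 0; c < W * H; ++c) {
      if (occ[c] == 0) continue;
      int base = c * S;
      for (int s = 0; s < S; ++s) {
        int i = base + s;
        if (!alive[i]) continue;
        if (++age[i] > lifespan) { alive[i] = 0; --occ[c]; }
      }
    }
  }

  void phase_settle() {
    size_t P = pending.size();
    for (size_t a = P; a > 1; --a)
      std::swap(pending[a - 1], pending[rng.bounded(a)]);
    for (size_t p = 0; p < P; ++p) {
      int c = pending[p].cell;
      if (occ[c] >= S) continue;  // at capacity: offspring dies
      int f = fitness_at(c, pending[p].g);
      if (f <= 0) continue;       // unfit in target cell: offspring dies
      int base = c * S;
      for (int s = 0; s < S; ++s) {
        int i = base + s;
        if (!alive[i]) {
          alive[i] = 1; gen[i] = pending[p].g; en[i] = 0.0; age[i] = 0;
          sp[i] = pending[p].sp; fitv[i] = f; ++occ[c];
          break;
        }
      }
    }
    pending.clear();
  }

  void step() {
    ++iter;
    phase_env();
    phase_provision();
    phase_breed();
    phase_age();
    phase_settle();
  }

  void seed_centre(int max_tries, int min_fitness) {
    if (seeded) stop("world is already seeded");
    int cx = W / 2, cy = H / 2;
    int cell = cy * W + cx;
    uint64_t g = 0; int f = 0;
    int t = 0;
    for (; t < max_tries; ++t) {
      g = rng.next();
      f = fitness_at(cell, g);
      if (f >= min_fitness) break;
    }
    if (f < min_fitness) stop("no viable founder genome found in %d draws", max_tries);
    int base = cell * S;
    for (int s = 0; s < S; ++s) {
      int i = base + s;
      alive[i] = 1; gen[i] = g; en[i] = 0.0; age[i] = 0; sp[i] = 0; fitv[i] = f;
    }
    occ[cell] = S;
    reg_id.push_back(0); reg_parent.push_back(-1);
    reg_origin.push_back(0); reg_extinct.push_back(-1); reg_last.push_back(0);
    seeded = true;
  }

  // --- species delimitation (connected components of the compatibility
  // graph over unique genotypes, via union-find) ---
  struct UF {
    std::vector<int> p;
    explicit UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
    int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
  };

  void detect_and_log(bool record) {
    std::map<int, std::vector<int>> members;
    for (int i = 0; i < (int)alive.size(); ++i)
      if (alive[i]) members[sp[i]].push_back(i);
    // extinctions: registered species with no living members
    for (size_t r = 0; r < reg_id.size(); ++r)
      if (reg_extinct[r] < 0 && members.find(reg_id[r]) == members.end())
        reg_extinct[r] = iter;

    std::map<int, std::pair<long, double>> out_species;  // id -> (abund, mean energy)
    for (std::map<int, std::vector<int>>::iterator kv = members.begin();
         kv != members.end(); ++kv) {
      int anc = kv->first;
      std::vector<int>& mem = kv->second;
      // collapse to unique genotypes
      std::map<uint64_t, int> uidx;
      std::vector<uint64_t> ug;
      std::vector<long> ucount;
      for (size_t m = 0; m < mem.size(); ++m) {
        uint64_t g = gen[mem[m]];
        std::map<uint64_t, int>::iterator it = uidx.find(g);
        if (it == uidx.end()) {
          uidx[g] = (int)ug.size(); ug.push_back(g); ucount.push_back(1);
        } else ++ucount[it->second];
      }
      int u = (int)ug.size();
      UF uf(u);
      for (int a = 0; a < u; ++a)
        for (int b = a + 1; b < u; ++b)
          if (popcount64(ug[a] ^ ug[b]) <= maxdiff) uf.unite(a, b);
      // component summaries
      std::map<int, int> roots;  // root -> comp index
      std::vector<long> cab; std::vector<uint64_t> cmin;
      std::vector<int> comp_of(u);
      for (int a = 0; a < u; ++a) {
        int r = uf.find(a);
        std::map<int, int>::iterator it = roots.find(r);
        int ci;
        if (it == roots.end()) {
          ci = (int)cab.size(); roots[r] = ci;
          cab.push_back(0); cmin.push_back(ug[a]);
        } else ci = it->second;
        comp_of[a] = ci;
        cab[ci] += ucount[a];
        if (ug[a] < cmin[ci]) cmin[ci] = ug[a];
      }
      int nc = (int)cab.size();
      std::vector<int> comp_id(nc, anc);
      if (nc > 1) {
        // keeper: most abundant; tie -> component holding the smallest genome
        int keep = 0;
        for (int ci = 1; ci < nc; ++ci)
          if (cab[ci] > cab[keep] || (cab[ci] == cab[keep] && cmin[ci] < cmin[keep]))
            keep = ci;
        // new IDs in decreasing abundance order (ties by smallest genome)
        std::vector<int> order;
        for (int ci = 0; ci < nc; ++ci) if (ci != keep) order.push_back(ci);
        std::sort(order.begin(), order.end(), [&](int a, int b) {
          if (cab[a] != cab[b]) return cab[a] > cab[b];
          return cmin[a] < cmin[b];
        });
        for (size_t k = 0; k < order.size(); ++k) {
          int id = next_species++;
          comp_id[order[k]] = id;
          reg_id.push_back(id); reg_parent.push_back(anc);
          reg_origin.push_back(iter); reg_extinct.push_back(-1);
          reg_last.push_back(iter);
        }
        for (size_t m = 0; m < mem.size(); ++m)
          sp[mem[m]] = comp_id[comp_of[uidx[gen[mem[m]]]]];
      }
      for (int ci = 0; ci < nc; ++ci) {
        std::pair<long, double>& rec = out_species[comp_id[ci]];
        rec.first += cab[ci];
      }
      for (size_t m = 0; m < mem.size(); ++m)
        out_species[sp[mem[m]]].second += en[mem[m]];
    }
    // update last_seen
    for (size_t r = 0; r < reg_id.size(); ++r)
      if (out_species.count(reg_id[r])) reg_last[r] = iter;

    if (!record) return;
    long tot = 0; double fsum = 0.0; int nalive = 0;
    for (int i = 0; i < (int)alive.size(); ++i)
      if (alive[i]) { ++tot; fsum += fitv[i]; ++nalive; }
    double Hent = 0.0;
    int Srich = (int)out_species.size();
    for (std::map<int, std::pair<long, double>>::iterator it = out_species.begin();
         it != out_species.end(); ++it) {
      long ab = it->second.first;
      if (tot > 0 && ab > 0) {
        double p = (double)ab / (double)tot;
        Hent -= p * std::log(p);
      }
      sl_iter.push_back((double)iter);
      sl_id.push_back(it->first);
      int parent = -1;
      for (size_t r = 0; r < reg_id.size(); ++r)
        if (reg_id[r] == it->first) { parent = reg_parent[r]; break; }
      sl_parent.push_back(parent);
      sl_abund.push_back((double)ab);
      sl_energy.push_back(ab > 0 ? it->second.second / (double)ab : NA_REAL);
    }
    double J = NA_REAL;
    if (Srich == 1) J = 1.0;
    else if (Srich > 1) J = Hent / std::log((double)Srich);
    wl_iter.push_back((double)iter);
    wl_abund.push_back((double)tot);
    wl_rich.push_back(Srich);
    wl_fit.push_back(nalive > 0 ? fsum / nalive : NA_REAL);
    wl_even.push_back(J);
  }

  void run(long n, bool record) {
    for (long k = 0; k < n; ++k) {
      step();
      if (log_int > 0 && iter % log_int == 0) detect_and_log(record);
    }
  }
};

// ------------------------------------------------------- R interface -------

// [[Rcpp::export]]
SEXP world_create(List settings, CharacterMatrix masks, List frames,
                  int refresh, bool interpolate, bool cyclic, double seed) {
  WorldCpp* w = new WorldCpp(settings, masks, frames, refresh, interpolate, cyclic, seed);
  XPtr<WorldCpp> p(w, true);
  return p;
}

static WorldCpp* get_world(SEXP ptr) {
  XPtr<WorldCpp> p(ptr);
  if (!p) stop("invalid world pointer");
  return p.get();
}

// [[Rcpp::export]]
void world_seed(SEXP ptr, int max_tries = 100000, int min_fitness = 1) {
  get_world(ptr)->seed_centre(max_tries, min_fitness);
}

// [[Rcpp::export]]
void world_seed_genome(SEXP ptr, std::string genome) {
  WorldCpp* w = get_world(ptr);
  if (w->seeded) stop("world is already seeded");
  int cell = (w->H / 2) * w->W + w->W / 2;
  uint64_t g = parse_bits(genome, 64);
  int f = w->fitness_at(cell, g);
  if (f <= 0) stop("founder genome has zero fitness in the seed cell");
  int base = cell * w->S;
  for (int s = 0; s < w->S; ++s) {
    int i = base + s;
    w->alive[i] = 1; w->gen[i] = g; w->en[i] = 0.0; w->age[i] = 0;
    w->sp[i] = 0; w->fitv[i] = f;
  }
  w->occ[cell] = w->S;
  w->reg_id.push_back(0); w->reg_parent.push_back(-1);
  w->reg_origin.push_back(0); w->reg_extinct.push_back(-1);
  w->reg_last.push_back(0);
  w->seeded = true;
}

// [[Rcpp::export]]
void world_step(SEXP ptr, int n = 1) {
  WorldCpp* w = get_world(ptr);
  for (int i = 0; i < n; ++i) w->step();
}

// [[Rcpp::export]]
void world_run(SEXP ptr, int n, bool record = true) {
  get_world(ptr)->run(n, record);
}

// [[Rcpp::export]]
void world_phase(SEXP ptr, std::string phase) {
  WorldCpp* w = get_world(ptr);
  if (phase == "env") w->phase_env();
  else if (phase == "provision") w->phase_provision();
  else if (phase == "breed") w->phase_breed();
  else if (phase == "age") w->phase_age();
  else if (phase == "settle") w->phase_settle();
  else if (phase == "detect") w->detect_and_log(true);
  else stop("unknown phase '%s'", phase.c_str());
}

// [[Rcpp::export]]
long world_iteration(SEXP ptr) { return get_world(ptr)->iter; }

// [[Rcpp::export]]
int world_pending_count(SEXP ptr) { return (int)get_world(ptr)->pending.size(); }

// [[Rcpp::export]]
DataFrame world_state(SEXP ptr) {
  WorldCpp* w = get_world(ptr);
  std::vector<int> x, y, slot, age_, sp_, fit_;
  std::vector<double> en_;
  CharacterVector g;
  std::vector<std::string> gs;
  for (int c = 0; c < w->W * w->H; ++c) {
    if (w->occ[c] == 0) continue;
    for (int s = 0; s < w->S; ++s) {
      int i = c * w->S + s;
      if (!w->alive[i]) continue;
      x.push_back(c % w->W); y.push_back(c / w->W); slot.push_back(s);
      gs.push_back(format_bits(w->gen[i], 64));
      en_.push_back(w->en[i]); age_.push_back(w->age[i]);
      sp_.push_back(w->sp[i]); fit_.push_back(w->fitv[i]);
    }
  }
  return DataFrame::create(
      _["x"] = x, _["y"] = y, _["slot"] = slot, _["genome"] = wrap(gs),
      _["energy"] = en_, _["age"] = age_, _["species_id"] = sp_,
      _["fitness"] = fit_, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
void world_insert(SEXP ptr, int x, int y, std::string genome, double energy,
                  int age, int species_id) {
  WorldCpp* w = get_world(ptr);
  if (x < 0 || x >= w->W || y < 0 || y >= w->H) stop("position out of grid");
  int cell = y * w->W + x;
  if (w->occ[cell] >= w->S) stop("cell is at capacity");
  uint64_t g = parse_bits(genome, 64);
  int base = cell * w->S;
  for (int s = 0; s < w->S; ++s) {
    int i = base + s;
    if (!w->alive[i]) {
      w->alive[i] = 1; w->gen[i] = g; w->en[i] = energy; w->age[i] = age;
      w->sp[i] = species_id; w->fitv[i] = w->fitness_at(cell, g);
      ++w->occ[cell];
      break;
    }
  }
  bool known = false;
  for (size_t r = 0; r < w->reg_id.size(); ++r)
    if (w->reg_id[r] == species_id) { known = true; break; }
  if (!known) {
    w->reg_id.push_back(species_id); w->reg_parent.push_back(-1);
    w->reg_origin.push_back(w->iter); w->reg_extinct.push_back(-1);
    w->reg_last.push_back(w->iter);
    if (species_id >= w->next_species) w->next_species = species_id + 1;
  }
  w->seeded = true;
}

// [[Rcpp::export]]
DataFrame world_registry(SEXP ptr) {
  WorldCpp* w = get_world(ptr);
  int n = (int)w->reg_id.size();
  IntegerVector id(n), parent(n);
  NumericVector origin(n), ext(n), last(n);
  for (int i = 0; i < n; ++i) {
    id[i] = w->reg_id[i];
    parent[i] = w->reg_parent[i] < 0 ? NA_INTEGER : w->reg_parent[i];
    origin[i] = (double)w->reg_origin[i];
    ext[i] = w->reg_extinct[i] < 0 ? NA_REAL : (double)w->reg_extinct[i];
    last[i] = (double)w->reg_last[i];
  }
  return DataFrame::create(
      _["species_id"] = id, _["parent_species_id"] = parent,
      _["origin_iteration"] = origin, _["extinction_iteration"] = ext,
      _["last_seen_iteration"] = last);
}

// [[Rcpp::export]]
DataFrame world_log(SEXP ptr) {
  WorldCpp* w = get_world(ptr);
  return DataFrame::create(
      _["iteration"] = w->wl_iter, _["total_abundance"] = w->wl_abund,
      _["species_richness"] = w->wl_rich, _["mean_fitness"] = w->wl_fit,
      _["evenness"] = w->wl_even);
}

// [[Rcpp::export]]
DataFrame world_species_log(SEXP ptr) {
  WorldCpp* w = get_world(ptr);
  return DataFrame::create(
      _["iteration"] = w->sl_iter, _["species_id"] = w->sl_id,
      _["parent_species_id"] = w->sl_parent, _["abundance"] = w->sl_abund,
      _["mean_energy"] = w->sl_energy);
}

// [[Rcpp::export]]
List world_info(SEXP ptr) {
  WorldCpp* w = get_world(ptr);
  long tot = 0; double fsum = 0.0;
  std::map<int, long> ab;
  for (int i = 0; i < (int)w->alive.size(); ++i)
    if (w->alive[i]) { ++tot; fsum += w->fitv[i]; ++ab[w->sp[i]]; }
  IntegerVector ids(ab.size());
  NumericVector abund(ab.size());
  int k = 0;
  for (std::map<int, long>::iterator it = ab.begin(); it != ab.end(); ++it) {
    ids[k] = it->first; abund[k] = (double)it->second; ++k;
  }
  return List::create(
      _["iteration"] = (double)w->iter,
      _["total_abundance"] = (double)tot,
      _["species_richness"] = (int)ab.size(),
      _["mean_fitness"] = tot > 0 ? fsum / tot : NA_REAL,
      _["species_ids"] = ids, _["species_abundance"] = abund);
}
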