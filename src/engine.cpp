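// Optimised engine for the crowded selfish-herd lattice-gas model.
//
// All randomness is drawn from R's global RNG (unif_rand / norm_rand) in a
// fixed documented order, so that a run is bit-reproducible from set.seed()
// and the plain-R reference engine (R/engine-r.R) replays identical
// trajectories.  Draw order per generation:
//   placement: per agent, rejection-sample floor(U * ncells) until vacant
//   per step:  Fisher-Yates permutation (k = N-1..1, j = floor(U*(k+1)))
//   per agent: one U for the noise input node; one U only on argmax ties;
//              one U only if the target cell is occupied and p_transit > 0
//   selection: partial Fisher-Yates over score ties at the cutoff; then per
//              offspring parent a = floor(U*ns), b redrawn until b != a, and
//              per weight one U (crossover) then one N(0,1) (mutation).
//
// The lattice keeps an incrementally maintained field of Moore-neighbourhood
// occupancy counts so a movement decision reads 5 precomputed counts instead
// of rescanning windows; position swaps leave the occupied set (hence the
// whole count field) unchanged.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

inline int uidx(int n) {
  // floor(U * n) clamped; unif_rand() is in (0, 1)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct World {
  int W, H, ncell, r, m, wmax;
  std::vector<int> occ;    // agent id (0-based) or -1 when vacant
  std::vector<int> nbr;    // occupied Moore-r cells around each cell
  std::vector<int> adj;    // ncell x 4, N,S,E,W targets
  std::vector<int> moore;  // ncell x m wrapped Moore window

  void init(int W_, int H_, int r_) {
    W = W_; H = H_; r = r_;
    ncell = W * H;
    m = (2 * r + 1) * (2 * r + 1) - 1;
    wmax = m;
    occ.assign(ncell, -1);
    nbr.assign(ncell, 0);
    adj.resize(4 * (size_t)ncell);
    moore.resize((size_t)m * ncell);
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        int c = y * W + x;
        int yn = (y - 1 + H) % H, ys = (y + 1) % H;
        int xe = (x + 1) % W, xw = (x - 1 + W) % W;
        adj[4 * c + 0] = yn * W + x;   // north
        adj[4 * c + 1] = ys * W + x;   // south
        adj[4 * c + 2] = y * W + xe;   // east
        adj[4 * c + 3] = y * W + xw;   // west
        int k = 0;
        for (int dy = -r; dy <= r; ++dy) {
          for (int dx = -r; dx <= r; ++dx) {
            if (dx == 0 && dy == 0) continue;
            int yy = ((y + dy) % H + H) % H;
            int xx = ((x + dx) % W + W) % W;
            moore[(size_t)m * c + k++] = yy * W + xx;
          }
        }
      }
    }
  }

  void clear() {
    std::fill(occ.begin(), occ.end(), -1);
    std::fill(nbr.begin(), nbr.end(), 0);
  }

  inline void occupy(int c, int id) {
    occ[c] = id;
    const int *mo = &moore[(size_t)m * c];
    for (int k = 0; k < m; ++k) ++nbr[mo[k]];
  }

  inline void vacate(int c) {
    occ[c] = -1;
    const int *mo = &moore[(size_t)m * c];
    for (int k = 0; k < m; ++k) --nbr[mo[k]];
  }
};

// one asynchronous time step: every agent acts once in a fresh random order
void do_step(World &w, std::vector<int> &pos, const double *wt, int N,
             double p_transit, std::vector<int> &perm) {
  for (int i = 0; i < N; ++i) perm[i] = i;
  for (int k = N - 1; k > 0; --k) {
    int j = uidx(k + 1);
    std::swap(perm[k], perm[j]);
  }
  double inp[11];
  inp[10] = 1.0;
  const double inv = 1.0 / w.wmax;
  for (int q = 0; q < N; ++q) {
    const int i = perm[q];
    const int c = pos[i];
    const int *a = &w.adj[4 * (size_t)c];
    for (int d = 0; d < 4; ++d) inp[d] = (w.occ[a[d]] >= 0) ? 1.0 : 0.0;
    for (int d = 0; d < 4; ++d) inp[4 + d] = w.nbr[a[d]] * inv;
    inp[8] = w.nbr[c] * inv;
    inp[9] = unif_rand();
    double out[4];
    for (int O = 0; O < 4; ++O) {
      double s = 0.0;
      const double *col = wt + (size_t)N * 11 * O + i;  // wt(i, I + 11*O)
      for (int I = 0; I < 11; ++I) s += col[(size_t)N * I] * inp[I];
      out[O] = s;
    }
    double best = out[0];
    for (int O = 1; O < 4; ++O) if (out[O] > best) best = out[O];
    int ties[4], nt = 0;
    for (int O = 0; O < 4; ++O) if (out[O] == best) ties[nt++] = O;
    const int dir = (nt > 1) ? ties[uidx(nt)] : ties[0];
    const int tgt = a[dir];
    if (w.occ[tgt] < 0) {
      w.vacate(c);
      w.occupy(tgt, i);
      pos[i] = tgt;
    } else if (p_transit > 0.0 && unif_rand() < p_transit) {
      const int j = w.occ[tgt];  // atomic swap; occupied set unchanged
      w.occ[tgt] = i;
      w.occ[c] = j;
      pos[i] = tgt;
      pos[j] = c;
    }
    // else blocked: stay put
  }
}

struct GenOut {
  std::vector<double> sn, sm;
  std::vector<double> occasions, moves;  // leave-profile counts per bin 0..wmax
};

// run one generation: placement (unless init positions given), T steps,
// accumulators.  When recording, per-step positions / neighbourhood sizes /
// moved flags are written to the supplied matrices.
void run_gen(World &w, int N, int T, double p_transit, const double *wt,
             std::vector<int> &pos, GenOut &out,
             const int *init_cell,  // NULL -> random placement
             int *pos_rec, int *nbr_rec, int *mov_rec) {
  w.clear();
  pos.resize(N);
  if (init_cell) {
    for (int i = 0; i < N; ++i) {
      w.occupy(init_cell[i], i);
      pos[i] = init_cell[i];
    }
  } else {
    for (int i = 0; i < N; ++i) {
      int c;
      do { c = uidx(w.ncell); } while (w.occ[c] >= 0);
      w.occupy(c, i);
      pos[i] = c;
    }
  }
  std::vector<int> perm(N), prevpos(pos), prevn(N, -1);
  std::vector<long> nbrsum(N, 0);
  std::vector<int> movecnt(N, 0);
  out.occasions.assign(w.wmax + 1, 0.0);
  out.moves.assign(w.wmax + 1, 0.0);
  for (int t = 1; t <= T; ++t) {
    do_step(w, pos, wt, N, p_transit, perm);
    for (int i = 0; i < N; ++i) {
      const int moved = (pos[i] != prevpos[i]) ? 1 : 0;
      if (t >= 2) {
        movecnt[i] += moved;
        out.occasions[prevn[i]] += 1.0;
        out.moves[prevn[i]] += moved;
        if (mov_rec) mov_rec[i + (size_t)N * (t - 2)] = moved;
      }
      const int nn = w.nbr[pos[i]];
      nbrsum[i] += nn;
      prevn[i] = nn;
      prevpos[i] = pos[i];
      if (pos_rec) {
        pos_rec[i + (size_t)N * (t - 1)] = pos[i];
        nbr_rec[i + (size_t)N * (t - 1)] = nn;
      }
    }
  }
  out.sn.resize(N);
  out.sm.resize(N);
  for (int i = 0; i < N; ++i) {
    out.sn[i] = (double)nbrsum[i] / T;
    out.sm[i] = (T > 1) ? (double)movecnt[i] / (T - 1) : NA_REAL;
  }
}

// truncation selection + refill; kills round(mu*N) lowest S^N agents (score
// ties at the cutoff broken uniformly at random), replaces each with an
// offspring of two distinct uniformly drawn survivors. Returns killed ids.
std::vector<int> select_reproduce(std::vector<double> &W8, int N,
                                  const std::vector<double> &sn,
                                  double mu, double mut_sd) {
  const int k = (int)R::fround(mu * N, 0.0);
  if (k <= 0) return std::vector<int>();
  std::vector<double> sorted(sn);
  std::sort(sorted.begin(), sorted.end());
  const double thr = sorted[k - 1];
  std::vector<int> definite, border;
  for (int i = 0; i < N; ++i) {
    if (sn[i] < thr) definite.push_back(i);
    else if (sn[i] == thr) border.push_back(i);
  }
  const int need = k - (int)definite.size();
  std::vector<int> killed(definite);
  if (need > 0) {
    std::vector<int> arr(border);
    const int nb = (int)arr.size();
    for (int q = 0; q < need; ++q) {
      int j = q + uidx(nb - q);
      std::swap(arr[q], arr[j]);
    }
    killed.insert(killed.end(), arr.begin(), arr.begin() + need);
  }
  std::sort(killed.begin(), killed.end());
  std::vector<char> dead(N, 0);
  for (int id : killed) dead[id] = 1;
  std::vector<int> surv;
  for (int i = 0; i < N; ++i) if (!dead[i]) surv.push_back(i);
  const int ns = (int)surv.size();
  std::vector<double> offs((size_t)k * 44);
  for (int q = 0; q < k; ++q) {
    int a = uidx(ns), b;
    do { b = uidx(ns); } while (b == a);
    const int sa = surv[a], sb = surv[b];
    for (int wi = 0; wi < 44; ++wi) {
      double v = (unif_rand() < 0.5) ? W8[sa + (size_t)N * wi]
                                     : W8[sb + (size_t)N * wi];
      v += norm_rand() * mut_sd;
      offs[q + (size_t)k * wi] = v;
    }
  }
  for (int q = 0; q < k; ++q)
    for (int wi = 0; wi < 44; ++wi)
      W8[killed[q] + (size_t)N * wi] = offs[q + (size_t)k * wi];
  return killed;
}

void summarise(const std::vector<double> &v, double &mean, double &var) {
  const int n = (int)v.size();
  double s = 0.0;
  for (double x : v) s += x;
  mean = s / n;
  double ss = 0.0;
  for (double x : v) ss += (x - mean) * (x - mean);
  var = (n > 1) ? ss / (n - 1) : NA_REAL;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_generation(int width, int height, int T, int r, double p_transit,
                        NumericMatrix weights, bool record,
                        Nullable<IntegerVector> init_cells) {
  const int N = weights.nrow();
  World w;
  w.init(width, height, r);
  std::vector<int> pos;
  GenOut out;
  IntegerMatrix pos_rec, nbr_rec, mov_rec;
  int *pp = nullptr, *np = nullptr, *mp = nullptr;
  if (record) {
    pos_rec = IntegerMatrix(N, T);
    nbr_rec = IntegerMatrix(N, T);
    mov_rec = IntegerMatrix(N, std::max(T - 1, 0));
    pp = INTEGER(pos_rec); np = INTEGER(nbr_rec); mp = INTEGER(mov_rec);
  }
  std::vector<int> init;
  const int *ic = nullptr;
  if (init_cells.isNotNull()) {
    IntegerVector v(init_cells);
    if (v.size() != N) stop("init_cells must have one cell per agent");
    init.assign(v.begin(), v.end());
    ic = init.data();
  }
  run_gen(w, N, T, p_transit, REAL(weights), pos, out, ic, pp, np, mp);
  List res = List::create(
      _["neighbourhood_score"] = NumericVector(out.sn.begin(), out.sn.end()),
      _["mobility_score"] = NumericVector(out.sm.begin(), out.sm.end()),
      _["occasions"] = NumericVector(out.occasions.begin(), out.occasions.end()),
      _["moves"] = NumericVector(out.moves.begin(), out.moves.end()),
      _["final_cells"] = IntegerVector(pos.begin(), pos.end()));
  if (record) {
    res["positions"] = pos_rec;
    res["neighbour_sizes"] = nbr_rec;
    res["moved"] = mov_rec;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_run_evolution(int width, int height, int T, int G, int r,
                       double mu, double mut_sd, double p_transit,
                       NumericMatrix weights0, IntegerVector archive_gens) {
  const int N = weights0.nrow();
  World w;
  w.init(width, height, r);
  std::vector<double> W8(REAL(weights0), REAL(weights0) + (size_t)N * 44);
  std::set<int> arch(archive_gens.begin(), archive_gens.end());
  NumericMatrix stats(G, 4);
  NumericMatrix occ_cnt(G, w.wmax + 1), mov_cnt(G, w.wmax + 1);
  const int kkill = (int)R::fround(mu * N, 0.0);
  IntegerMatrix killed_rec(G, std::max(kkill, 1));
  if (kkill == 0) std::fill(killed_rec.begin(), killed_rec.end(), NA_INTEGER);
  List archives;
  CharacterVector arch_names;
  std::vector<int> pos;
  GenOut out;
  for (int g = 0; g < G; ++g) {
    if (g % 16 == 0) Rcpp::checkUserInterrupt();
    if (arch.count(g)) {
      NumericMatrix cp(N, 44);
      std::copy(W8.begin(), W8.end(), cp.begin());
      archives.push_back(cp);
      arch_names.push_back(std::to_string(g));
    }
    run_gen(w, N, T, p_transit, W8.data(), pos, out, nullptr,
            nullptr, nullptr, nullptr);
    double me, va;
    summarise(out.sn, me, va);
    stats(g, 0) = me; stats(g, 1) = va;
    summarise(out.sm, me, va);
    stats(g, 2) = me; stats(g, 3) = va;
    for (int b = 0; b <= w.wmax; ++b) {
      occ_cnt(g, b) = out.occasions[b];
      mov_cnt(g, b) = out.moves[b];
    }
    std::vector<int> killed = select_reproduce(W8, N, out.sn, mu, mut_sd);
    for (int q = 0; q < (int)killed.size(); ++q)
      killed_rec(g, q) = killed[q] + 1;  // 1-based ids for R
  }
  NumericMatrix finalW(N, 44);
  std::copy(W8.begin(), W8.end(), finalW.begin());
  archives.attr("names") = arch_names;
  return List::create(_["stats"] = stats,
                      _["occasions"] = occ_cnt,
                      _["moves"] = mov_cnt,
                      _["archives"] = archives,
                      _["final_weights"] = finalW,
                      _["killed"] = killed_rec,
                      _["window_max"] = w.wmax);
}
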