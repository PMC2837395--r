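#include <Rcpp.h>
#include <array>
#include <cstring>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// 3x3x3 cube geometry. Site index s = x + 3*y + 9*z, x,y,z in {0,1,2}.
// A maximally compact conformation is a self-avoiding chain of 27 residues
// visiting every site once (a Hamiltonian path of the cube grid graph).

static inline int site_of(int x, int y, int z) { return x + 3 * y + 9 * z; }

struct CubeTables {
  // adjacency lists of the grid graph
  int adj[27][6];
  int deg[27];
  // the 24 proper rotations of the cube as site permutations; reflections
  // are excluded so mirror-image conformations count as distinct
  int sym[24][27];
  CubeTables() {
    for (int s = 0; s < 27; ++s) {
      int x = s % 3, y = (s / 3) % 3, z = s / 9;
      deg[s] = 0;
      const int dx[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; ++k) {
        int nx = x + dx[k], ny = y + dy[k], nz = z + dz[k];
        if (nx >= 0 && nx < 3 && ny >= 0 && ny < 3 && nz >= 0 && nz < 3)
          adj[s][deg[s]++] = site_of(nx, ny, nz);
      }
    }
    int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                       {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
    int psign[6] = {1, -1, -1, 1, 1, -1};
    int op = 0;
    for (int p = 0; p < 6; ++p)
      for (int fl = 0; fl < 8; ++fl) {
        int nflip = ((fl & 1) != 0) + ((fl & 2) != 0) + ((fl & 4) != 0);
        int det = psign[p] * ((nflip % 2 == 0) ? 1 : -1);
        if (det != 1) continue; // proper rotations only
        for (int s = 0; s < 27; ++s) {
          int c[3] = {s % 3, (s / 3) % 3, s / 9};
          int t[3];
          for (int a = 0; a < 3; ++a) {
            int v = c[perms[p][a]];
            if (fl & (1 << a)) v = 2 - v;
            t[a] = v;
          }
          sym[op][s] = site_of(t[0], t[1], t[2]);
        }
        ++op;
      }
  }
};

static const CubeTables CUBE;

// canonical form of a directed Hamiltonian path: lexicographic minimum over
// the 24 rotation images of the path and of the reversed path
static void canonicalize(const uint8_t *path, uint8_t *best) {
  uint8_t cand[27];
  bool have = false;
  for (int op = 0; op < 24; ++op) {
    const int *pm = CUBE.sym[op];
    for (int dir = 0; dir < 2; ++dir) {
      for (int k = 0; k < 27; ++k)
        cand[k] = (uint8_t)pm[path[dir ? 26 - k : k]];
      if (!have || std::memcmp(cand, best, 27) < 0) {
        std::memcpy(best, cand, 27);
        have = true;
      }
    }
  }
}

struct Enumerator {
  std::unordered_set<std::string> seen;
  uint8_t path[27];
  uint32_t used;

  void dfs(int s, int depth) {
    path[depth] = (uint8_t)s;
    used |= (1u << s);
    if (depth == 26) {
      // keep one direction of each undirected path
      if (path[0] < path[26]) {
        uint8_t best[27];
        canonicalize(path, best);
        seen.emplace(reinterpret_cast<char *>(best), 27);
      }
    } else {
      for (int k = 0; k < CUBE.deg[s]; ++k) {
        int nxt = CUBE.adj[s][k];
        if (!(used & (1u << nxt))) dfs(nxt, depth + 1);
      }
    }
    used &= ~(1u << s);
  }
};

// [[Rcpp::export(name = ".enumerate_conformations_cpp")]]
IntegerMatrix enumerate_conformations_cpp() {
  Enumerator en;
  en.used = 0;
  // one start site per symmetry class of cube vertices:
  // corner (0,0,0), edge (1,0,0), face centre (1,1,0), body centre (1,1,1)
  const int starts[4] = {site_of(0, 0, 0), site_of(1, 0, 0),
                         site_of(1, 1, 0), site_of(1, 1, 1)};
  for (int i = 0; i < 4; ++i) en.dfs(starts[i], 0);

  std::vector<std::string> all(en.seen.begin(), en.seen.end());
  std::sort(all.begin(), all.end());
  int n = (int)all.size();
  IntegerMatrix out(n, 27);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 27; ++k) out(i, k) = (int)(uint8_t)all[i][k];
  return out;
}

// non-bonded nearest-neighbour contacts (chain positions, 0-based, i<j, j>i+1)
// of each conformation; every compact conformation has exactly 28
// [[Rcpp::export(name = ".contact_maps_cpp")]]
IntegerMatrix contact_maps_cpp(IntegerMatrix paths) {
  int n = paths.nrow();
  IntegerMatrix out(n, 56);
  for (int i = 0; i < n; ++i) {
    int pos_of[27];
    for (int k = 0; k < 27; ++k) pos_of[paths(i, k)] = k;
    int c = 0;
    for (int k = 0; k < 27; ++k) {
      int s = paths(i, k);
      for (int a = 0; a < CUBE.deg[s]; ++a) {
        int t = CUBE.adj[s][a];
        int kt = pos_of[t];
        if (kt > k + 1) {
          if (c >= 28) stop("conformation has more than 28 contacts");
          out(i, 2 * c) = k;
          out(i, 2 * c + 1) = kt;
          ++c;
        }
      }
    }
    if (c != 28) stop("conformation does not have 28 contacts");
  }
  return out;
}

// chain positions (0-based) sitting on each of the 6 cube faces, 9 per face,
// in row-major (u fastest) order of the in-plane coordinates. Face order:
// x=0, x=2, y=0, y=2, z=0, z=2; for normal axis a the in-plane axes (u,v)
// are the remaining axes in increasing order.
// [[Rcpp::export(name = ".face_tables_cpp")]]
IntegerMatrix face_tables_cpp(IntegerMatrix paths) {
  int n = paths.nrow();
  IntegerMatrix out(n, 54);
  const int axes[6] = {0, 0, 1, 1, 2, 2};
  const int lvls[6] = {0, 2, 0, 2, 0, 2};
  for (int i = 0; i < n; ++i) {
    int pos_of[27];
    for (int k = 0; k < 27; ++k) pos_of[paths(i, k)] = k;
    for (int f = 0; f < 6; ++f) {
      int a = axes[f], l = lvls[f];
      int ua = (a == 0) ? 1 : 0;
      int va = (a == 2) ? 1 : 2;
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u) {
          int c[3];
          c[a] = l; c[ua] = u; c[va] = v;
          out(i, 9 * f + 3 * v + u) = pos_of[site_of(c[0], c[1], c[2])];
        }
    }
  }
  return out;
}

// conformational energies of one sequence over a conformation set:
// E_c = sum over the 28 contacts of the pairwise contact energy
// [[Rcpp::export(name = ".fold_energies_cpp")]]
NumericVector fold_energies_cpp(IntegerVector aa, IntegerMatrix contacts,
                                NumericMatrix mj) {
  int n = contacts.nrow();
  if (aa.size() != 27) stop("sequence must have 27 residues");
  NumericVector out(n);
  // per-sequence position-pair energies: one lookup per contact
  double eseq[27 * 27];
  for (int p = 0; p < 27; ++p)
    for (int q = 0; q < 27; ++q) eseq[27 * p + q] = mj(aa[p], aa[q]);
  const int *ct = INTEGER(contacts);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int c = 0; c < 56; c += 2)
      e += eseq[27 * ct[(size_t)c * n + i] + ct[(size_t)(c + 1) * n + i]];
    out[i] = e;
  }
  return out;
}

// in-plane maps of the 144 docking modes. The partner of face site (u,v) of
// protein A is face site phi_r(u,v) of protein B where phi_r = R_r o M,
// M(u,v) = (2-u, v) (the facing mirror) and R(u,v) = (v, 2-u) (quarter turn).
// Each phi_r is an involution, so mode (f_i, f_j, r) on the pair (i, j)
// produces the same contact set as mode (f_j, f_i, r) on (j, i).
static void mode_map(int rot, int map_out[9]) {
  for (int v = 0; v < 3; ++v)
    for (int u = 0; u < 3; ++u) {
      int mu = 2 - u, mv = v;
      for (int t = 0; t < rot; ++t) {
        int nu = mv, nv = 2 - mu;
        mu = nu; mv = nv;
      }
      map_out[3 * v + u] = 3 * mv + mu;
    }
}

// binding energies of the 144 rigid docking modes between two native
// conformations, given their 6x9 face tables (as 54-vectors) and sequences
// [[Rcpp::export(name = ".dock_energies_cpp")]]
NumericVector dock_energies_cpp(IntegerVector aa_i, IntegerVector aa_j,
                                IntegerVector faces_i, IntegerVector faces_j,
                                NumericMatrix mj) {
  if (aa_i.size() != 27 || aa_j.size() != 27)
    stop("sequences must have 27 residues");
  if (faces_i.size() != 54 || faces_j.size() != 54)
    stop("face tables must have 54 entries");
  int maps[4][9];
  for (int r = 0; r < 4; ++r) mode_map(r, maps[r]);
  NumericVector out(144);
  int idx = 0;
  for (int fi = 0; fi < 6; ++fi)
    for (int fj = 0; fj < 6; ++fj)
      for (int r = 0; r < 4; ++r) {
        double e = 0.0;
        for (int s = 0; s < 9; ++s) {
          int pi = faces_i[9 * fi + s];
          int pj = faces_j[9 * fj + maps[r][s]];
          e += mj(aa_i[pi], aa_j[pj]);
        }
        out[idx++] = e;
      }
  return out;
}

// site pair lists of the 144 docking modes (cube site indices, 0-based),
// independent of any conformation; used by enumerate_docking_modes()
// [[Rcpp::export(name = ".docking_site_pairs_cpp")]]
IntegerMatrix docking_site_pairs_cpp() {
  const int axes[6] = {0, 0, 1, 1, 2, 2};
  const int lvls[6] = {0, 2, 0, 2, 0, 2};
  int face_sites[6][9];
  for (int f = 0; f < 6; ++f) {
    int a = axes[f], l = lvls[f];
    int ua = (a == 0) ? 1 : 0;
    int va = (a == 2) ? 1 : 2;
    for (int v = 0; v < 3; ++v)
      for (int u = 0; u < 3; ++u) {
        int c[3];
        c[a] = l; c[ua] = u; c[va] = v;
        face_sites[f][3 * v + u] = site_of(c[0], c[1], c[2]);
      }
  }
  int maps[4][9];
  for (int r = 0; r < 4; ++r) mode_map(r, maps[r]);
  IntegerMatrix out(144, 18);
  int idx = 0;
  for (int fi = 0; fi < 6; ++fi)
    for (int fj = 0; fj < 6; ++fj)
      for (int r = 0; r < 4; ++r) {
        for (int s = 0; s < 9; ++s) {
          out(idx, 2 * s) = face_sites[fi][s];
          out(idx, 2 * s + 1) = face_sites[fj][maps[r][s]];
        }
        ++idx;
      }
  return out;
}

// phenotype refresh for a mutated genome: re-fold each changed gene and
// re-dock every pair touching one, in a single call. aa108: 4x27 residues;
// changed: 1-based gene indices; natives: 1-based native conformation
// indices (updated for changed genes); contacts/faces: conformation set
// tables; kform selects the binding-constant convention: 0 = centered on
// the pair's mean mode energy, 1 = minimum-energy, 2 = mode-summed.
// [[Rcpp::export(name = ".mutant_phenotype_cpp")]]
List mutant_phenotype_cpp(IntegerVector aa108, IntegerVector changed,
                          IntegerVector natives, NumericVector pnat,
                          NumericVector K10, NumericVector pint10,
                          IntegerMatrix contacts, IntegerMatrix faces,
                          NumericMatrix mj, double temperature, int kform) {
  static const int PI[10] = {1, 1, 1, 1, 2, 2, 2, 3, 3, 4};
  static const int PJ[10] = {1, 2, 3, 4, 2, 3, 4, 3, 4, 4};
  int nconf = contacts.nrow();
  IntegerVector nat = clone(natives);
  NumericVector pn = clone(pnat);
  NumericVector K = clone(K10);
  NumericVector pint = clone(pint10);
  bool chg[5] = {false, false, false, false, false};
  for (int c = 0; c < changed.size(); ++c) {
    int g = changed[c];
    chg[g] = true;
    const int off = 27 * (g - 1);
    double eseq[27 * 27];
    for (int p = 0; p < 27; ++p)
      for (int q = 0; q < 27; ++q)
        eseq[27 * p + q] = mj(aa108[off + p], aa108[off + q]);
    const int *ct = INTEGER(contacts);
    double e0 = R_PosInf;
    int best = 0;
    std::vector<double> e(nconf);
    for (int i = 0; i < nconf; ++i) {
      double ei = 0.0;
      for (int cc = 0; cc < 56; cc += 2)
        ei += eseq[27 * ct[(size_t)cc * nconf + i] + ct[(size_t)(cc + 1) * nconf + i]];
      e[i] = ei;
      if (ei < e0) { e0 = ei; best = i; }
    }
    double z = 0.0;
    for (int i = 0; i < nconf; ++i) z += std::exp(-(e[i] - e0) / temperature);
    nat[g - 1] = best + 1;
    pn[g - 1] = 1.0 / z;
  }
  int maps[4][9];
  for (int r = 0; r < 4; ++r) mode_map(r, maps[r]);
  for (int p = 0; p < 10; ++p) {
    int gi = PI[p], gj = PJ[p];
    if (!chg[gi] && !chg[gj]) continue;
    const int offi = 27 * (gi - 1), offj = 27 * (gj - 1);
    int ci = nat[gi - 1] - 1, cj = nat[gj - 1] - 1;
    double emin = R_PosInf, esum = 0.0;
    double em[144];
    int idx = 0;
    for (int fi = 0; fi < 6; ++fi)
      for (int fj = 0; fj < 6; ++fj)
        for (int r = 0; r < 4; ++r) {
          double e = 0.0;
          for (int s = 0; s < 9; ++s) {
            int pi_ = faces(ci, 9 * fi + s);
            int pj_ = faces(cj, 9 * fj + maps[r][s]);
            e += mj(aa108[offi + pi_], aa108[offj + pj_]);
          }
          em[idx++] = e;
          esum += e;
          if (e < emin) emin = e;
        }
    double w = 0.0;
    for (int k = 0; k < 144; ++k) w += std::exp(-(em[k] - emin) / temperature);
    pint[p] = 1.0 / w;
    K[p] = kform == 0 ? std::exp((esum / 144.0 - emin) / temperature)
         : kform == 1 ? std::exp(-emin / temperature)
                      : std::exp(-emin / temperature) * w;
  }
  return List::create(_["native"] = nat, _["pnat"] = pn, _["K10"] = K,
                      _["pint10"] = pint);
}

// law-of-mass-action fixed point for N cells at once. Cmat: N x 4 totals;
// K10: N x 10 pair-store binding constants (order 11,12,13,14,22,23,24,33,
// 34,44). 0.5-damped iteration per row with early exit; same fixed point as
// the scalar solver. Returns free monomers and the dimer pair store
// (homodimers carry the 1/2 symmetry factor).
// [[Rcpp::export(name = ".lma_matrix_cpp")]]
List lma_matrix_cpp(NumericMatrix Cmat, NumericMatrix K10, double rel_tol,
                    int max_iter) {
  static const int PI[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
  static const int PJ[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
  int n = Cmat.nrow();
  NumericMatrix F(n, 4), Fpair(n, 10);
  IntegerVector iters(n);
  double tol = rel_tol / 2.0;
  for (int r = 0; r < n; ++r) {
    double C[4], f[4], K[4][4];
    for (int i = 0; i < 4; ++i) { C[i] = Cmat(r, i); f[i] = C[i]; }
    for (int p = 0; p < 10; ++p) {
      K[PI[p]][PJ[p]] = K10(r, p);
      K[PJ[p]][PI[p]] = K10(r, p);
    }
    int it = 0;
    for (; it < max_iter; ++it) {
      double maxd = 0.0;
      double fn[4];
      for (int i = 0; i < 4; ++i) {
        double den = 1.0;
        for (int j = 0; j < 4; ++j) den += K[i][j] * f[j];
        fn[i] = 0.5 * (C[i] / den + f[i]);
      }
      for (int i = 0; i < 4; ++i) {
        double base = fn[i] > 1e-300 ? fn[i] : 1e-300;
        double d = std::fabs(fn[i] - f[i]) / base;
        if (C[i] > 0 && d > maxd) maxd = d;
        f[i] = fn[i];
      }
      if (maxd < tol) break;
    }
    iters[r] = it;
    for (int i = 0; i < 4; ++i) F(r, i) = f[i];
    for (int p = 0; p < 10; ++p) {
      double v = K10(r, p) * f[PI[p]] * f[PJ[p]];
      Fpair(r, p) = (PI[p] == PJ[p]) ? v / 2.0 : v;
    }
  }
  return List::create(_["F"] = F, _["F_pair"] = Fpair, _["iterations"] = iters);
}
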