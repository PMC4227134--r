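#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
using namespace Rcpp;

// Fixed-length approximate string matching matrices and the structured
// merge. Matrices are (n+1) x (m+1), column-major (R layout): rows index
// end positions 0..n in y, columns end positions 0..m in x. Hamming cells
// whose two windows have unequal lengths hold the sentinel k+1 (stands for
// infinity; strictly greater than any attainable window distance).

static inline int idx2(int i, int j, int nrow) { return i + j * nrow; }

// ---------------------------------------------------------------- Hamming

static void hamming_fill(const std::string &x, const std::string &y, int k,
                         std::vector<int> &M) {
  const int m = (int)x.size(), n = (int)y.size();
  const int nrow = n + 1, sent = k + 1;
  M.assign((size_t)nrow * (m + 1), sent);
  M[idx2(0, 0, nrow)] = 0;
  for (int d = -(n - 1); d <= m - 1; ++d) { // diagonal: j = i + d
    int mism = 0;
    int i0 = std::max(1, 1 - d);
    for (int i = i0; i <= n && i + d <= m; ++i) {
      int j = i + d;
      mism += (y[i - 1] != x[j - 1]);
      if (i > k && j > k) mism -= (y[i - 1 - k] != x[j - 1 - k]);
      if ((i >= k && j >= k) || i == j) M[idx2(i, j, nrow)] = mism;
    }
  }
}

static void hamming_fill_bp(const std::string &x, const std::string &y, int k,
                            std::vector<int> &M) {
  if (k > 64) stop("bitparallel engine requires k <= 64");
  const int m = (int)x.size(), n = (int)y.size();
  const int nrow = n + 1, sent = k + 1;
  const uint64_t mask = (k == 64) ? ~0ULL : ((1ULL << k) - 1);
  M.assign((size_t)nrow * (m + 1), sent);
  M[idx2(0, 0, nrow)] = 0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    uint64_t w = 0;
    int i0 = std::max(1, 1 - d);
    for (int i = i0; i <= n && i + d <= m; ++i) {
      int j = i + d;
      w = ((w << 1) | (uint64_t)(y[i - 1] != x[j - 1])) & mask;
      if ((i >= k && j >= k) || i == j)
        M[idx2(i, j, nrow)] = (int)__builtin_popcountll(w);
    }
  }
}

// ------------------------------------------------------------------- Edit

// One column of D: pattern p (window or window prefix) against y with free
// start in y (Sellers: D[i,0] = 0, D[0,l] = l).
static void edit_pattern_column(const std::string &y, const char *p, int L,
                                std::vector<int> &col) {
  const int n = (int)y.size();
  std::vector<int> prev(L + 1), cur(L + 1);
  for (int l = 0; l <= L; ++l) prev[l] = l;
  col[0] = L;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int l = 1; l <= L; ++l) {
      int sub = prev[l - 1] + (y[i - 1] != p[l - 1]);
      int ins = prev[l] + 1;
      int del = cur[l - 1] + 1;
      cur[l] = std::min(sub, std::min(ins, del));
    }
    col[i] = cur[L];
    std::swap(prev, cur);
  }
}

static void edit_fill(const std::string &x, const std::string &y, int k,
                      std::vector<int> &M) {
  const int m = (int)x.size(), n = (int)y.size();
  const int nrow = n + 1;
  M.assign((size_t)nrow * (m + 1), 0);
  std::vector<int> col(n + 1);
  for (int j = 1; j <= m; ++j) {
    int L = std::min(j, k);
    edit_pattern_column(y, x.c_str() + (j - L), L, col);
    for (int i = 0; i <= n; ++i) M[idx2(i, j, nrow)] = col[i];
  }
}

// Myers-style bit-vector column (semi-global: free start in y).
static void myers_column(const std::string &y, const char *p, int L,
                         std::vector<int> &col) {
  const int n = (int)y.size();
  uint64_t Peq[256];
  std::fill(Peq, Peq + 256, 0ULL);
  for (int l = 0; l < L; ++l) Peq[(unsigned char)p[l]] |= (1ULL << l);
  const uint64_t mask = (L == 64) ? ~0ULL : ((1ULL << L) - 1);
  const uint64_t hibit = 1ULL << (L - 1);
  uint64_t VP = mask, VN = 0;
  int score = L;
  col[0] = L;
  for (int i = 1; i <= n; ++i) {
    uint64_t X = Peq[(unsigned char)y[i - 1]] | VN;
    uint64_t D0 = (((X & VP) + VP) ^ VP) | X;
    uint64_t HN = VP & D0;
    uint64_t HP = VN | ~(VP | D0);
    if (HP & hibit) ++score;
    else if (HN & hibit) --score;
    uint64_t HPs = HP << 1; // no +1 carry-in: column 0 of the DP stays 0
    uint64_t HNs = HN << 1;
    VP = (HNs | ~(HPs | D0)) & mask;
    VN = (HPs & D0) & mask;
    col[i] = score;
  }
}

static void edit_fill_bp(const std::string &x, const std::string &y, int k,
                         std::vector<int> &M) {
  if (k > 64) stop("bitparallel engine requires k <= 64");
  const int m = (int)x.size(), n = (int)y.size();
  const int nrow = n + 1;
  M.assign((size_t)nrow * (m + 1), 0);
  std::vector<int> col(n + 1);
  for (int j = 1; j <= m; ++j) {
    int L = std::min(j, k);
    myers_column(y, x.c_str() + (j - L), L, col);
    for (int i = 0; i <= n; ++i) M[idx2(i, j, nrow)] = col[i];
  }
}

// ------------------------------------------------------------ matrix API

static IntegerMatrix wrap_matrix(const std::vector<int> &M, int n, int m) {
  IntegerMatrix out(n + 1, m + 1);
  std::copy(M.begin(), M.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_flasm_matrix(std::string x, std::string y, int k,
                               bool edit, bool bitparallel) {
  std::vector<int> M;
  if (edit) {
    if (bitparallel) edit_fill_bp(x, y, k, M);
    else edit_fill(x, y, k, M);
  } else {
    if (bitparallel) hamming_fill_bp(x, y, k, M);
    else hamming_fill(x, y, k, M);
  }
  return wrap_matrix(M, (int)y.size(), (int)x.size());
}

// ------------------------------------------------------------------ merge

struct MergeParams {
  std::vector<int> k, e, K;     // K[t] = k[2]+...+k[t+1] (1-based boxes)
  const int *Vx, *Vy;           // gamma x C prefix-sum gap offsets
  int gamma, C;
  std::vector<int> pmin, pmax;  // per-interval progression ranges
  bool pruned, edit;
};

struct PairView {
  std::vector<const int *> mats; // one per box (shared across equal k)
  int nrow;                      // rows of the stored matrices
  bool swapped;                  // occurrence space = matrix columns
  int occ_max, src_max;          // sequence lengths
  inline int val(int b, int r, int c) const {
    return swapped ? mats[b][idx2(c, r, nrow)] : mats[b][idx2(r, c, nrow)];
  }
};

struct Recs {
  std::vector<int> xid, yid, i, j, cand;
  void push(int a, int b, int r, int c, int cd) {
    xid.push_back(a); yid.push_back(b);
    i.push_back(r); j.push_back(c); cand.push_back(cd);
  }
};

static inline bool cell_pass(const PairView &pv, const MergeParams &P,
                             int box, int row, int col) {
  int kb = P.k[box], eb = P.e[box];
  if (col < kb || col > pv.src_max) return false;
  if (!P.edit) {
    if (row < kb || row > pv.occ_max) return false;
    return pv.val(box, row, col) <= eb;
  }
  // edit model: end position in y is uncertain by up to e per box; widen
  int lo = std::max(row - eb, kb), hi = std::min(row + eb, pv.occ_max);
  for (int r = lo; r <= hi; ++r)
    if (pv.val(box, r, col) <= eb) return true;
  return false;
}

static void merge_core(const PairView &pv, const MergeParams &P,
                       int xid, int yid, Recs &out,
                       long long &anchors, long long &checks) {
  const int k1 = P.k[0], e1 = P.e[0];
  const int G = P.gamma, C = P.C;
  std::vector<char> grid;
  std::vector<int> goff(G + 1, 0), gw(G);
  if (P.pruned && G > 0) {
    for (int t = 0; t < G; ++t) {
      gw[t] = P.pmax[t] - P.pmin[t] + 1;
      goff[t + 1] = goff[t] + gw[t] * gw[t];
    }
    grid.resize(goff[G]);
  }
  // walk the stored matrix in memory order (contiguous inner index)
  const int *M0 = pv.mats[0];
  const int jmax = pv.swapped ? pv.occ_max : pv.src_max;
  const int imax = pv.swapped ? pv.src_max : pv.occ_max;
  for (int jc = k1; jc <= jmax; ++jc) {
    const int *colp = M0 + (size_t)jc * pv.nrow;
    for (int ir = k1; ir <= imax; ++ir) {
      if (colp[ir] > e1) continue;
      const int r = pv.swapped ? jc : ir;
      const int c = pv.swapped ? ir : jc;
      ++anchors;
      if (G == 0) { out.push(xid, yid, r, c, 1); continue; }
      if (!P.pruned) {
        for (int cd = 0; cd < C; ++cd) {
          bool ok = true;
          for (int t = 0; t < G && ok; ++t) {
            ++checks;
            ok = cell_pass(pv, P, t + 1,
                           r + P.K[t] + P.Vy[t + (size_t)cd * G],
                           c + P.K[t] + P.Vx[t + (size_t)cd * G]);
          }
          if (ok) out.push(xid, yid, r, c, cd + 1);
        }
      } else {
        // evaluate each distinct progression cell once, then look up
        for (int t = 0; t < G; ++t) {
          int w = gw[t], p0 = P.pmin[t];
          for (int vy = 0; vy < w; ++vy)
            for (int vx = 0; vx < w; ++vx) {
              ++checks;
              grid[goff[t] + vy * w + vx] =
                cell_pass(pv, P, t + 1, r + P.K[t] + p0 + vy,
                          c + P.K[t] + p0 + vx);
            }
        }
        for (int cd = 0; cd < C; ++cd) {
          bool ok = true;
          for (int t = 0; t < G && ok; ++t) {
            int w = gw[t], p0 = P.pmin[t];
            ok = grid[goff[t] + (P.Vy[t + (size_t)cd * G] - p0) * w +
                      (P.Vx[t + (size_t)cd * G] - p0)] != 0;
          }
          if (ok) out.push(xid, yid, r, c, cd + 1);
        }
      }
    }
  }
}

static MergeParams make_params(IntegerVector k, IntegerVector e,
                               IntegerVector K, IntegerMatrix Vx,
                               IntegerMatrix Vy, IntegerVector pmin,
                               IntegerVector pmax, bool pruned, bool edit) {
  MergeParams P;
  P.k = as<std::vector<int>>(k);
  P.e = as<std::vector<int>>(e);
  P.K = as<std::vector<int>>(K);
  P.gamma = Vx.nrow();
  P.C = (P.gamma > 0) ? Vx.ncol() : 1;
  P.Vx = Vx.begin();
  P.Vy = Vy.begin();
  P.pmin = as<std::vector<int>>(pmin);
  P.pmax = as<std::vector<int>>(pmax);
  P.pruned = pruned;
  P.edit = edit;
  return P;
}

// Merge one ordered pair from prebuilt matrices (rows = y, cols = x).
// [[Rcpp::export]]
List cpp_merge_pair(List mats, IntegerVector k, IntegerVector e,
                    IntegerVector K, IntegerMatrix Vx, IntegerMatrix Vy,
                    IntegerVector pmin, IntegerVector pmax,
                    bool pruned, bool edit) {
  MergeParams P = make_params(k, e, K, Vx, Vy, pmin, pmax, pruned, edit);
  std::vector<IntegerMatrix> keep;
  PairView pv;
  for (int b = 0; b < (int)P.k.size(); ++b)
    keep.push_back(as<IntegerMatrix>(mats[b]));
  pv.nrow = keep[0].nrow();
  pv.swapped = false;
  pv.occ_max = keep[0].nrow() - 1;
  pv.src_max = keep[0].ncol() - 1;
  for (auto &mm : keep) pv.mats.push_back(mm.begin());
  Recs out;
  long long anchors = 0, checks = 0;
  merge_core(pv, P, 1, 1, out, anchors, checks);
  return List::create(_["i"] = out.i, _["j"] = out.j, _["cand"] = out.cand,
                      _["n_anchors"] = (double)anchors,
                      _["n_cell_checks"] = (double)checks);
}

// Full extraction over all ordered pairs (self-pairs included). Hamming
// matrices are window-symmetric, so each unordered pair is computed once
// and the transposed view serves the opposite orientation.
// [[Rcpp::export]]
List cpp_extract(CharacterVector seqs, IntegerVector k, IntegerVector e,
                 IntegerVector K, IntegerMatrix Vx, IntegerMatrix Vy,
                 IntegerVector pmin, IntegerVector pmax,
                 bool pruned, bool edit, bool bitparallel) {
  MergeParams P = make_params(k, e, K, Vx, Vy, pmin, pmax, pruned, edit);
  const int N = seqs.size();
  std::vector<std::string> ss(N);
  for (int a = 0; a < N; ++a) ss[a] = as<std::string>(seqs[a]);

  // one matrix buffer per distinct window length
  std::vector<int> kd;                 // distinct k values
  std::vector<int> slot(P.k.size());   // box -> buffer slot
  for (size_t b = 0; b < P.k.size(); ++b) {
    int s = -1;
    for (size_t u = 0; u < kd.size(); ++u) if (kd[u] == P.k[b]) s = (int)u;
    if (s < 0) { kd.push_back(P.k[b]); s = (int)kd.size() - 1; }
    slot[b] = s;
  }
  std::vector<std::vector<int>> buf(kd.size());

  Recs out;
  long long anchors = 0, checks = 0;
  for (int a = 0; a < N; ++a) {
    for (int b = edit ? 0 : a; b < N; ++b) {
      // matrices for x = ss[a], y = ss[b]
      for (size_t u = 0; u < kd.size(); ++u) {
        if (edit) {
          if (bitparallel) edit_fill_bp(ss[a], ss[b], kd[u], buf[u]);
          else edit_fill(ss[a], ss[b], kd[u], buf[u]);
        } else {
          if (bitparallel) hamming_fill_bp(ss[a], ss[b], kd[u], buf[u]);
          else hamming_fill(ss[a], ss[b], kd[u], buf[u]);
        }
      }
      PairView pv;
      pv.nrow = (int)ss[b].size() + 1;
      for (size_t bb = 0; bb < P.k.size(); ++bb)
        pv.mats.push_back(buf[slot[bb]].data());
      // orientation: source x = a, occurrences in y = b
      pv.swapped = false;
      pv.occ_max = (int)ss[b].size();
      pv.src_max = (int)ss[a].size();
      merge_core(pv, P, a + 1, b + 1, out, anchors, checks);
      if (!edit && b != a) {
        // transposed view: source x = b, occurrences in y = a
        pv.swapped = true;
        pv.occ_max = (int)ss[a].size();
        pv.src_max = (int)ss[b].size();
        merge_core(pv, P, b + 1, a + 1, out, anchors, checks);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["xid"] = out.xid, _["yid"] = out.yid,
                      _["i"] = out.i, _["j"] = out.j, _["cand"] = out.cand,
                      _["n_anchors"] = (double)anchors,
                      _["n_cell_checks"] = (double)checks);
}

// --------------------------------------------------- direct occurrence scan

// Sliding-window occurrence counter, independent of the matrix machinery.
// Returns, per sequence, the number of distinct per-box end-position tuples
// realising an (e_i)-occurrence of the motif with in-interval gaps.
// [[Rcpp::export]]
NumericVector cpp_occurrence_scan(CharacterVector seqs, CharacterVector boxes,
                                  IntegerVector e, IntegerVector dmin,
                                  IntegerVector dmax, bool edit) {
  const int N = seqs.size(), beta = boxes.size();
  std::vector<std::string> bx(beta);
  for (int b = 0; b < beta; ++b) bx[b] = as<std::string>(boxes[b]);
  NumericVector out(N);
  for (int s = 0; s < N; ++s) {
    std::string y = as<std::string>(seqs[s]);
    int n = (int)y.size();
    // occ[b][i]: box b e-occurs ending at position i (1-based)
    std::vector<std::vector<char>> occ(beta, std::vector<char>(n + 1, 0));
    std::vector<int> col(n + 1);
    for (int b = 0; b < beta; ++b) {
      int kb = (int)bx[b].size();
      if (kb > n) continue;
      if (edit) {
        edit_pattern_column(y, bx[b].c_str(), kb, col);
        for (int i = kb; i <= n; ++i) occ[b][i] = (col[i] <= e[b]);
      } else {
        for (int i = kb; i <= n; ++i) {
          int d = 0;
          for (int l = 0; l < kb && d <= e[b]; ++l)
            d += (y[i - kb + l] != bx[b][l]);
          occ[b][i] = (d <= e[b]);
        }
      }
    }
    // count endpoint tuples chained through the gap intervals
    std::vector<double> f(n + 2, 0.0), g(n + 2, 0.0);
    for (int i = 0; i <= n; ++i) f[i] = occ[beta - 1][i] ? 1.0 : 0.0;
    for (int b = beta - 2; b >= 0; --b) {
      int knext = (int)bx[b + 1].size();
      for (int i = 0; i <= n; ++i) {
        g[i] = 0.0;
        if (!occ[b][i]) continue;
        for (int gp = dmin[b]; gp <= dmax[b]; ++gp) {
          int nx = i + knext + gp;
          if (nx <= n) g[i] += f[nx];
        }
      }
      std::swap(f, g);
    }
    double tot = 0.0;
    for (int i = 0; i <= n; ++i) tot += f[i];
    out[s] = tot;
  }
  return out;
}
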