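#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; anything not ACGT (case-insensitive) -> 4
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int> > map;
};

// Build an exact k-mer index of a (concatenated) reference string.
// [[Rcpp::export]]
SEXP cpp_seed_index(std::string ref, int k) {
  if (k < 1 || k > 31) stop("seed length k must be in [1,31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  SeedIndex* si = new SeedIndex();
  si->k = k;
  si->map.reserve(ref.size());
  uint64_t h = 0; int valid = 0;
  for (size_t i = 0; i < ref.size(); ++i) {
    int c = base_code(ref[i]);
    if (c > 3) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) si->map[h].push_back((int)(i + 1 - k));
  }
  XPtr<SeedIndex> p(si, true);
  return p;
}

// Query the index; k-mers occurring more than max_per times in the
// reference are skipped (cheap repeat masking).  Positions are 0-based.
// [[Rcpp::export]]
List cpp_seed_query(SEXP index, std::string query, int max_per) {
  XPtr<SeedIndex> si(index);
  const int k = si->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<int> rp, qp;
  uint64_t h = 0; int valid = 0;
  for (size_t i = 0; i < query.size(); ++i) {
    int c = base_code(query[i]);
    if (c > 3) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto it = si->map.find(h);
      if (it != si->map.end() && (int)it->second.size() <= max_per) {
        int q0 = (int)(i + 1 - k);
        for (int r0 : it->second) { rp.push_back(r0); qp.push_back(q0); }
      }
    }
  }
  return List::create(_["ref_pos"] = wrap(rp), _["query_pos"] = wrap(qp));
}

// One-shot convenience: index + query.
// [[Rcpp::export]]
List cpp_seed_hits(std::string ref, std::string query, int k, int max_per) {
  SEXP idx = cpp_seed_index(ref, k);
  return cpp_seed_query(idx, query, max_per);
}

struct TraceCell { uint8_t bits; }; // bits0-1: H origin, bit2: E ext, bit3: F ext

// Banded affine-gap alignment over windows of `ref` x `query`.
// mode 0: local (Smith-Waterman); mode 1: overlap (free end gaps on both).
// Band: j - i in [dlo, dhi] where i indexes query (1..n), j ref (1..m).
// subs: 16 integers, genome-base-major 4x4 (subs[4*g + q]).
// Deletion = gap in query consuming ref; insertion = extra query base.
// Returns 0-based half-open coordinates within the given windows, a
// run-length cigar over {=,X,I,D}, and (for local mode) per-query-position
// score increments summing to the score.
// [[Rcpp::export]]
List cpp_band_align(std::string ref, std::string query,
                    IntegerVector subs,
                    int del_open, int del_ext, int ins_open, int ins_ext,
                    int dlo, int dhi, int mode) {
  const int n = (int)query.size(), m = (int)ref.size();
  if (n < 1 || m < 1) stop("empty sequence in alignment window");
  if (dhi < dlo) stop("bad band");
  const int W = dhi - dlo + 1;
  const int NEG = -1000000000; // effectively -inf for integer scores
  std::vector<int> q(n), r(m);
  for (int i = 0; i < n; ++i) q[i] = base_code(query[i]);
  for (int j = 0; j < m; ++j) r[j] = base_code(ref[j]);
  int smin = subs[0];
  for (int t = 1; t < 16; ++t) if (subs[t] < smin) smin = subs[t];
  auto S = [&](int gi, int qi) -> int {
    if (gi > 3 || qi > 3) return smin;
    return subs[4 * gi + qi];
  };
  // rows 0..n, band width W; cell (i, b) -> j = i + dlo + b.
  // Score rows are rolling (cache-resident); only the 1-byte trace matrix
  // is kept in full.  Buffers are reused across calls.
  static std::vector<int> Hprev, Hcur, Ecur, Fprev, Fcur;
  static std::vector<uint8_t> T;
  Hprev.assign(W, NEG); Hcur.assign(W, NEG);
  Ecur.assign(W, NEG); Fprev.assign(W, NEG); Fcur.assign(W, NEG);
  T.assign((size_t)(n + 1) * W, 0);
  auto IDX = [&](int i, int b) { return (size_t)i * W + b; };
  // row 0: H = 0 wherever in range
  for (int b = 0; b < W; ++b) {
    int j = 0 + dlo + b;
    if (j >= 0 && j <= m) Hprev[b] = 0;
  }
  int best = (mode == 0) ? 0 : NEG;
  int bi = -1, bb = -1;
  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    int b0 = -i - dlo; // band index of column j = 0, if any
    if (b0 >= 0 && b0 < W) Hcur[b0] = 0;
    int jlo = std::max(1, i + dlo), jhi = std::min(m, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      int b = j - i - dlo;
      // E: gap consuming ref (deletion from query): from (i, j-1) = (i, b-1)
      int e = NEG; uint8_t ebit = 0;
      if (b - 1 >= 0) {
        int ho = Hcur[b - 1], eo = Ecur[b - 1];
        int v1 = (ho <= NEG / 2) ? NEG : ho - del_open - del_ext;
        int v2 = (eo <= NEG / 2) ? NEG : eo - del_ext;
        if (v2 > v1) { e = v2; ebit = 1; } else { e = v1; ebit = 0; }
      }
      // F: gap consuming query (insertion): from (i-1, j) = (i-1, b+1)
      int f = NEG; uint8_t fbit = 0;
      if (b + 1 < W) {
        int hi_ = Hprev[b + 1], fo = Fprev[b + 1];
        int v1 = (hi_ <= NEG / 2) ? NEG : hi_ - ins_open - ins_ext;
        int v2 = (fo <= NEG / 2) ? NEG : fo - ins_ext;
        if (v2 > v1) { f = v2; fbit = 1; } else { f = v1; fbit = 0; }
      }
      // H
      int d = NEG;
      int hd = Hprev[b]; // (i-1, j-1) same band index
      if (hd > NEG / 2) d = hd + S(r[j - 1], q[i - 1]);
      int h; uint8_t org;
      if (mode == 0) { h = 0; org = 0; } else { h = NEG; org = 0; }
      if (d > h) { h = d; org = 1; }
      if (e > h) { h = e; org = 2; }
      if (f > h) { h = f; org = 3; }
      Hcur[b] = h; Ecur[b] = e; Fcur[b] = f;
      T[IDX(i, b)] = org | (ebit << 2) | (fbit << 3);
      bool record = false;
      if (mode == 0) record = h > best;
      else record = (i == n || j == m) && h > best;
      if (record) { best = h; bi = i; bb = b; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  if (bi < 0) { // overlap mode with nothing: shouldn't happen
    return List::create(_["score"] = 0.0, _["ok"] = false);
  }
  // traceback
  std::string ops;
  int i = bi, b = bb;
  int j = i + dlo + b;
  const int qend = i, rend = j;
  bool edge = false;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if ((b == 0 || b == W - 1) && i > 0 && i < n) edge = true;
    uint8_t t = T[IDX(i, b)];
    if (state == 0) {
      uint8_t org = t & 3;
      if (org == 0) break;
      if (org == 1) {
        ops.push_back((r[j - 1] == q[i - 1] && q[i - 1] <= 3) ? '=' : 'X');
        --i; --j; b = j - i - dlo;
      } else if (org == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E at (i,j): consumed ref j
      uint8_t ext = (T[IDX(i, b)] >> 2) & 1;
      ops.push_back('D');
      --j; b = j - i - dlo;
      state = ext ? 1 : 0;
    } else { // F at (i,j): consumed query i
      uint8_t ext = (T[IDX(i, b)] >> 3) & 1;
      ops.push_back('I');
      --i; b = j - i - dlo;
      state = ext ? 2 : 0;
    }
  }
  const int qstart = i, rstart = j;
  std::reverse(ops.begin(), ops.end());
  // run-length encode + per-query-position profile
  std::string cig;
  {
    size_t p = 0;
    while (p < ops.size()) {
      size_t p2 = p;
      while (p2 < ops.size() && ops[p2] == ops[p]) ++p2;
      cig += std::to_string(p2 - p);
      cig.push_back(ops[p]);
      p = p2;
    }
  }
  // per-query-position score increments; deletion runs are charged to the
  // next query base so that sum(profile) == score
  NumericVector prof(qend - qstart);
  {
    int qi = qstart, rj = rstart;
    double pending = 0.0;
    size_t p = 0;
    while (p < ops.size()) {
      size_t p2 = p;
      while (p2 < ops.size() && ops[p2] == ops[p]) ++p2;
      int len = (int)(p2 - p);
      char op = ops[p];
      if (op == '=' || op == 'X') {
        for (int tt = 0; tt < len; ++tt) {
          prof[qi - qstart] += S(r[rj], q[qi]) + pending; pending = 0.0;
          ++qi; ++rj;
        }
      } else if (op == 'I') {
        for (int tt = 0; tt < len; ++tt) {
          double c = -(double)ins_ext - (tt == 0 ? (double)ins_open : 0.0);
          prof[qi - qstart] += c + pending; pending = 0.0;
          ++qi;
        }
      } else { // D
        pending -= (double)del_open + (double)len * del_ext;
        rj += len;
      }
      p = p2;
    }
    if (pending != 0.0 && prof.size() > 0) prof[prof.size() - 1] += pending;
  }
  return List::create(
      _["score"] = (double)best, _["ok"] = true, _["edge"] = edge,
      _["query_start"] = qstart, _["query_end"] = qend,
      _["ref_start"] = rstart, _["ref_end"] = rend,
      _["cigar"] = cig, _["profile"] = prof);
}

// Optimal division of a read among candidate alignments.
// starts/ends: 0-based half-open read intervals of the candidates (already
// ordered by caller preference rank for deterministic ties); profiles:
// per-read-position score increments for each candidate.  Maximizes
// sum(chosen scores) - jump * (nseg - 1), allowing arbitrary trimming of
// candidates so chosen read intervals are disjoint.  Ties: fewer segments.
// [[Rcpp::export]]
List cpp_split_dp(int read_len, IntegerVector starts, IntegerVector ends,
                  List profiles, double jump) {
  const int C = starts.size();
  std::vector<NumericVector> prof(C);
  for (int c = 0; c < C; ++c) prof[c] = as<NumericVector>(profiles[c]);
  const double NEG = -1e18;
  const int L = read_len;
  // M[c][x], V[x]; nseg counters Mn, Vn
  std::vector<std::vector<double> > M(C);
  std::vector<std::vector<int> > Mn(C), Morg(C); // org: 0 self, 1 fresh, 2 from V (x-1) w/ jump
  for (int c = 0; c < C; ++c) {
    int len = ends[c] - starts[c];
    M[c].assign(len, NEG); Mn[c].assign(len, 0); Morg[c].assign(len, 1);
  }
  std::vector<double> V(L, 0.0);
  std::vector<int> Vn(L, 0), Vc(L, -1); // Vc: candidate achieving V at x (-1: carried)
  auto better = [](double s1, int n1, double s2, int n2) {
    return s1 > s2 + 1e-9 || (s1 > s2 - 1e-9 && n1 < n2);
  };
  for (int x = 0; x < L; ++x) {
    double vprev = (x > 0) ? V[x - 1] : 0.0;
    int vprevn = (x > 0) ? Vn[x - 1] : 0;
    for (int c = 0; c < C; ++c) {
      if (x < starts[c] || x >= ends[c]) continue;
      int k = x - starts[c];
      double p = prof[c][k];
      // options
      double bs = 0.0; int bn = 1; int org = 1; // fresh start (first segment)
      if (x > 0 && vprevn > 0) {
        double s2 = vprev - jump; int n2 = vprevn + 1;
        if (better(s2, n2, bs, bn)) { bs = s2; bn = n2; org = 2; }
      }
      if (k > 0 && M[c][k - 1] > NEG / 2) {
        if (better(M[c][k - 1], Mn[c][k - 1], bs, bn)) {
          bs = M[c][k - 1]; bn = Mn[c][k - 1]; org = 0;
        }
      }
      M[c][k] = bs + p; Mn[c][k] = bn; Morg[c][k] = org;
    }
    // V[x]
    double bs = (x > 0) ? V[x - 1] : 0.0; int bn = (x > 0) ? Vn[x - 1] : 0;
    int bc = -1;
    for (int c = 0; c < C; ++c) {
      if (x < starts[c] || x >= ends[c]) continue;
      int k = x - starts[c];
      if (better(M[c][k], Mn[c][k], bs, bn)) { bs = M[c][k]; bn = Mn[c][k]; bc = c; }
    }
    V[x] = bs; Vn[x] = bn; Vc[x] = bc;
  }
  if (L == 0 || V[L - 1] <= 1e-9) {
    return List::create(_["score"] = 0.0, _["cand"] = IntegerVector(0),
                        _["seg_start"] = IntegerVector(0),
                        _["seg_end"] = IntegerVector(0));
  }
  // traceback
  std::vector<int> cands, sstart, send;
  int x = L - 1;
  while (x >= 0 && Vc[x] == -1) --x; // position where V last improved
  while (x >= 0) {
    int c = Vc[x];
    if (c < 0) break;
    int endx = x + 1;
    int k = x - starts[c];
    while (Morg[c][k] == 0) { --x; --k; }
    cands.push_back(c); sstart.push_back(x); send.push_back(endx);
    if (Morg[c][k] == 1) break; // fresh start: done
    // org == 2: came from V[x-1]
    --x;
    while (x >= 0 && Vc[x] == -1) --x;
  }
  std::reverse(cands.begin(), cands.end());
  std::reverse(sstart.begin(), sstart.end());
  std::reverse(send.begin(), send.end());
  return List::create(_["score"] = V[L - 1],
                      _["cand"] = wrap(cands),
                      _["seg_start"] = wrap(sstart),
                      _["seg_end"] = wrap(send));
}
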