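#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <map>
#include <set>
#include <string>
#include <utility>
#include <vector>

using namespace Rcpp;

// Protein boundaries in the database text are marked by a sentinel that is
// lexicographically smaller than every residue letter; suffix comparison
// treats it as end-of-string so no comparison crosses a protein boundary.
static const char SENT = '$';
static const int NEG = INT_MIN / 4;

static inline int floordiv(int a, int b) {
  int q = a / b;
  if ((a % b != 0) && ((a < 0) != (b < 0))) --q;
  return q;
}

// ---------------------------------------------------------------------------
// suffix array

// [[Rcpp::export]]
IntegerVector sa_build_cpp(std::string text) {
  const char* s = text.c_str();
  const int n = (int)text.size();
  std::vector<int> pos;
  pos.reserve(n);
  for (int i = 0; i < n; ++i)
    if (s[i] != SENT) pos.push_back(i);
  std::sort(pos.begin(), pos.end(), [s](int a, int b) {
    int i = a, j = b;
    for (;;) {
      const char ca = s[i], cb = s[j];
      const bool ea = (ca == SENT), eb = (cb == SENT);
      if (ea || eb) {
        if (ea && eb) return a < b;  // equal suffixes: ascending position
        return ea;                   // shorter suffix sorts first
      }
      if (ca != cb) return ca < cb;
      ++i;
      ++j;
    }
  });
  return IntegerVector(pos.begin(), pos.end());
}

// true iff the (sentinel-truncated) suffix starting at p is lexicographically
// smaller than query[qoff..]
static bool suffix_less(const char* s, int p, const std::string& q, size_t qoff) {
  size_t k = 0;
  for (;;) {
    const char c = s[p + k];
    const bool es = (c == SENT);
    const bool eq = (qoff + k >= q.size());
    if (es || eq) {
      if (es && eq) return false;
      return es;
    }
    const char qc = q[qoff + k];
    if (c != qc) return c < qc;
    ++k;
  }
}

static int lcp_len(const char* s, int p, const std::string& q, size_t qoff) {
  int k = 0;
  while (qoff + k < (int)q.size() && s[p + k] != SENT && s[p + k] == q[qoff + k]) ++k;
  return k;
}

// number of database suffixes strictly smaller than qsuf, i.e. the 0-based
// insertion index of qsuf in the suffix array
// [[Rcpp::export]]
int sa_locate_cpp(std::string text, IntegerVector positions, std::string qsuf) {
  const char* s = text.c_str();
  int lo = 0, hi = positions.size();
  while (lo < hi) {
    const int mid = (lo + hi) / 2;
    if (suffix_less(s, positions[mid], qsuf, 0)) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// ---------------------------------------------------------------------------
// neighborhood voting

// For every query suffix, inspect the 2W suffixes at array indices
// [i - W, i + W) around the insertion index i; each neighbor with a common
// prefix of at least min_match residues casts one vote for its
// (protein, diagonal band). At most one vote per (query position, protein,
// band). Returns one row per (protein, band) with the accumulated count;
// protein indices are 1-based for R.
// [[Rcpp::export]]
DataFrame sa_vote_cpp(std::string text, IntegerVector positions, IntegerVector offsets,
                      std::string query, int W, int min_match, int band_width) {
  const char* s = text.c_str();
  const int n = positions.size();
  const int Lq = (int)query.size();
  std::vector<int> offs(offsets.begin(), offsets.end());
  std::map<std::pair<int, int>, int> counts;

  for (int q = 0; q + min_match <= Lq; ++q) {
    int lo = 0, hi = n;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (suffix_less(s, positions[mid], query, q)) lo = mid + 1; else hi = mid;
    }
    std::set<std::pair<int, int> > seen;
    for (int j = lo - W; j < lo + W; ++j) {
      if (j < 0 || j >= n) continue;
      const int p = positions[j];
      if (lcp_len(s, p, query, q) < min_match) continue;
      const int prot =
          (int)(std::upper_bound(offs.begin(), offs.end(), p) - offs.begin()) - 1;
      const int diag = q - (p - offs[prot]);
      seen.insert(std::make_pair(prot, floordiv(diag, band_width)));
    }
    for (std::set<std::pair<int, int> >::const_iterator it = seen.begin();
         it != seen.end(); ++it)
      counts[*it] += 1;
  }

  const int m = (int)counts.size();
  IntegerVector prot(m), band(m), cnt(m);
  int k = 0;
  for (std::map<std::pair<int, int>, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++k) {
    prot[k] = it->first.first + 1;
    band[k] = it->first.second;
    cnt[k] = it->second;
  }
  return DataFrame::create(_["protein"] = prot, _["band"] = band, _["vote"] = cnt);
}

// ---------------------------------------------------------------------------
// alignment

// residue -> row index of the 21-letter scoring matrix (ARNDCQEGHILKMFPSTWYV X);
// anything unknown scores as X
static void encode(const std::string& x, std::vector<int>& out) {
  static int tab[256];
  static bool init = false;
  if (!init) {
    const std::string order = "ARNDCQEGHILKMFPSTWYVX";
    for (int i = 0; i < 256; ++i) tab[i] = 20;
    for (size_t i = 0; i < order.size(); ++i) tab[(unsigned char)order[i]] = (int)i;
    init = true;
  }
  out.resize(x.size());
  for (size_t i = 0; i < x.size(); ++i) out[i] = tab[(unsigned char)x[i]];
}

// Local (Smith-Waterman) alignment with affine gaps (a gap of length k costs
// gap_open + k * gap_extend), restricted to cells whose residue diagonal
// q - t satisfies |q - t - center| <= half_band. Traceback ties prefer
// diagonal, then up (gap in target), then left (gap in query).
// Coordinates in the result are 0-based half-open.
// [[Rcpp::export]]
List banded_sw_cpp(std::string query, std::string target, int center, int half_band,
                   IntegerMatrix mat, int gap_open, int gap_extend) {
  const int m = (int)query.size(), n = (int)target.size();
  std::vector<int> qi, ti;
  encode(query, qi);
  encode(target, ti);

  const size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<int> H(sz, NEG), E(sz, NEG), F(sz, NEG);
  std::vector<unsigned char> trH(sz, 0), trE(sz, 0), trF(sz, 0);
#define IDX(i, j) ((size_t)(i) * (n + 1) + (j))
  for (int j = 0; j <= n; ++j) H[IDX(0, j)] = 0;
  for (int i = 0; i <= m; ++i) H[IDX(i, 0)] = 0;

  int best = 0, bi = 0, bj = 0;
  const int go = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i - center - half_band);
    const int jhi = std::min(n, i - center + half_band);
    for (int j = jlo; j <= jhi; ++j) {
      const size_t c = IDX(i, j);
      const int hl = H[IDX(i, j - 1)], el = E[IDX(i, j - 1)];
      const int eo = (hl <= NEG / 2) ? NEG : hl - go;
      const int ee = (el <= NEG / 2) ? NEG : el - gap_extend;
      E[c] = std::max(eo, ee);
      trE[c] = (ee > eo) ? 1 : 0;
      const int hu = H[IDX(i - 1, j)], fu = F[IDX(i - 1, j)];
      const int fo = (hu <= NEG / 2) ? NEG : hu - go;
      const int fe = (fu <= NEG / 2) ? NEG : fu - gap_extend;
      F[c] = std::max(fo, fe);
      trF[c] = (fe > fo) ? 1 : 0;
      const int hd = H[IDX(i - 1, j - 1)];
      const int ds = (hd <= NEG / 2) ? NEG : hd + mat(qi[i - 1], ti[j - 1]);
      int h = 0;
      unsigned char tr = 0;
      if (ds > h) { h = ds; tr = 1; }
      if (F[c] > h) { h = F[c]; tr = 2; }
      if (E[c] > h) { h = E[c]; tr = 3; }
      H[c] = h;
      trH[c] = tr;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string qa, ta;
  int i = bi, j = bj;
  if (best > 0) {
    int state = 0;
    for (;;) {
      if (state == 0) {
        const unsigned char t = trH[IDX(i, j)];
        if (t == 0) break;
        if (t == 1) {
          qa += query[i - 1];
          ta += target[j - 1];
          --i;
          --j;
        } else if (t == 2) {
          state = 2;
        } else {
          state = 3;
        }
      } else if (state == 2) {
        const unsigned char t = trF[IDX(i, j)];
        qa += query[i - 1];
        ta += '-';
        --i;
        state = t ? 2 : 0;
      } else {
        const unsigned char t = trE[IDX(i, j)];
        qa += '-';
        ta += target[j - 1];
        --j;
        state = t ? 3 : 0;
      }
    }
  }
#undef IDX
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = best, _["q_aln"] = qa, _["t_aln"] = ta,
                      _["q_start"] = (best > 0) ? i : 0,
                      _["q_end"] = (best > 0) ? bi : 0,
                      _["t_start"] = (best > 0) ? j : 0,
                      _["t_end"] = (best > 0) ? bj : 0);
}

static int sw_score_one(const std::vector<int>& qi, const std::vector<int>& ti,
                        const IntegerMatrix& mat, int gap_open, int gap_extend) {
  const int m = (int)qi.size(), n = (int)ti.size();
  const int go = gap_open + gap_extend;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int e = NEG;
    Hcur[0] = 0;
    const int* srow = &mat[0] + 0;  // column-major access below
    for (int j = 1; j <= n; ++j) {
      const int eo = Hcur[j - 1] - go;
      e = std::max(eo, (e <= NEG / 2) ? NEG : e - gap_extend);
      const int fo = Hprev[j] - go;
      Fcol[j] = std::max(fo, (Fcol[j] <= NEG / 2) ? NEG : Fcol[j] - gap_extend);
      int h = Hprev[j - 1] + mat(qi[i - 1], ti[j - 1]);
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (Fcol[j] > h) h = Fcol[j];
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    (void)srow;
  }
  return best;
}

// unbanded Smith-Waterman score (affine gaps), score only
// [[Rcpp::export]]
int sw_score_cpp(std::string query, std::string target, IntegerMatrix mat,
                 int gap_open, int gap_extend) {
  std::vector<int> qi, ti;
  encode(query, qi);
  encode(target, ti);
  return sw_score_one(qi, ti, mat, gap_open, gap_extend);
}

// one query against many targets
// [[Rcpp::export]]
IntegerVector sw_score_multi_cpp(std::string query, CharacterVector targets,
                                 IntegerMatrix mat, int gap_open, int gap_extend) {
  std::vector<int> qi, ti;
  encode(query, qi);
  const int nt = targets.size();
  IntegerVector out(nt);
  for (int k = 0; k < nt; ++k) {
    encode(std::string(targets[k]), ti);
    out[k] = sw_score_one(qi, ti, mat, gap_open, gap_extend);
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
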