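#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hamming distance with early exit once `limit` is exceeded.
static inline int hamming_limited(const char *a, const char *b, int n, int limit) {
  int d = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) {
      if (++d > limit) return d;
    }
  }
  return d;
}

// [[Rcpp::export]]
IntegerVector hamming_dist_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("vectors must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    int na = LENGTH(STRING_ELT(a, i));
    if (na != LENGTH(STRING_ELT(b, i))) stop("sequences must have equal length");
    out[i] = hamming_limited(sa, sb, na, na);
  }
  return out;
}

// Chunk boundaries: split [0, len) into n_chunks near-equal pieces.
// Pigeonhole: if two strings differ at <= r positions and we cut into r+1
// chunks, at least one chunk is identical -- so exact chunk lookup finds
// every neighbour within radius r.
static void chunk_bounds(int len, int n_chunks, std::vector<int> &start,
                         std::vector<int> &size) {
  start.resize(n_chunks);
  size.resize(n_chunks);
  int base = len / n_chunks, rem = len % n_chunks, pos = 0;
  for (int c = 0; c < n_chunks; ++c) {
    size[c] = base + (c < rem ? 1 : 0);
    start[c] = pos;
    pos += size[c];
  }
}

// Greedy abundance-ranked collapse. `seqs` must be pre-sorted by descending
// abundance (ties broken deterministically by the caller). Returns for each
// candidate the 1-based index of the retained center that absorbs it (its own
// index if it is retained itself).
// [[Rcpp::export]]
IntegerVector greedy_collapse_cpp(CharacterVector seqs, int radius) {
  int n = seqs.size();
  IntegerVector assign(n);
  if (n == 0) return assign;
  int len = LENGTH(STRING_ELT(seqs, 0));
  int n_chunks = radius + 1;
  std::vector<int> cstart, csize;
  chunk_bounds(len, n_chunks, cstart, csize);

  // one hash per chunk: chunk substring -> indices of retained centers
  std::vector<std::unordered_map<std::string, std::vector<int> > > idx(n_chunks);
  std::vector<const char *> ptr(n);
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(seqs, i)) != len) stop("sequences must have equal length");
    ptr[i] = CHAR(STRING_ELT(seqs, i));
  }
  std::vector<int> seen(n, -1);
  for (int i = 0; i < n; ++i) {
    int best = -1;
    if (radius > 0) {
      for (int c = 0; c < n_chunks; ++c) {
        std::string key(ptr[i] + cstart[c], csize[c]);
        auto it = idx[c].find(key);
        if (it == idx[c].end()) continue;
        for (int center : it->second) {
          if (seen[center] == i) continue;  // already tested for this candidate
          seen[center] = i;
          int d = hamming_limited(ptr[i], ptr[center], len, radius);
          // absorb into the most abundant (earliest-retained) center in range
          if (d <= radius && (best == -1 || center < best)) best = center;
        }
      }
    }
    if (best >= 0) {
      assign[i] = best + 1;
    } else {
      assign[i] = i + 1;  // retained as a new center
      for (int c = 0; c < n_chunks; ++c) {
        std::string key(ptr[i] + cstart[c], csize[c]);
        idx[c][key].push_back(i);
      }
    }
  }
  return assign;
}

// Map query barcodes to reference barcodes by Hamming distance.
// Returns 1-based reference index, or NA when no reference lies within
// `max_mismatch` or when two references tie at the minimal distance.
// [[Rcpp::export]]
IntegerVector map_barcodes_cpp(CharacterVector queries, CharacterVector refs,
                               int max_mismatch) {
  int nq = queries.size(), nr = refs.size();
  if (nr == 0) stop("empty reference");
  int len = LENGTH(STRING_ELT(refs, 0));
  int n_chunks = max_mismatch + 1;
  std::vector<int> cstart, csize;
  chunk_bounds(len, n_chunks, cstart, csize);

  std::vector<std::unordered_map<std::string, std::vector<int> > > idx(n_chunks);
  std::vector<const char *> rptr(nr);
  for (int j = 0; j < nr; ++j) {
    if (LENGTH(STRING_ELT(refs, j)) != len) stop("reference sequences must have equal length");
    rptr[j] = CHAR(STRING_ELT(refs, j));
    for (int c = 0; c < n_chunks; ++c) {
      std::string key(rptr[j] + cstart[c], csize[c]);
      idx[c][key].push_back(j);
    }
  }

  IntegerVector out(nq, NA_INTEGER);
  std::vector<int> seen(nr, -1);
  for (int i = 0; i < nq; ++i) {
    SEXP q = STRING_ELT(queries, i);
    if (q == NA_STRING || LENGTH(q) != len) continue;  // unmappable
    const char *qp = CHAR(q);
    int best = -1, best_d = max_mismatch + 1, n_at_best = 0;
    for (int c = 0; c < n_chunks; ++c) {
      std::string key(qp + cstart[c], csize[c]);
      auto it = idx[c].find(key);
      if (it == idx[c].end()) continue;
      for (int j : it->second) {
        if (seen[j] == i) continue;
        seen[j] = i;
        int d = hamming_limited(qp, rptr[j], len, max_mismatch);
        if (d > max_mismatch) continue;
        if (d < best_d) { best_d = d; best = j; n_at_best = 1; }
        else if (d == best_d) ++n_at_best;
      }
    }
    if (best >= 0 && n_at_best == 1) out[i] = best + 1;
  }
  return out;
}

// Inject independent per-base substitution errors at rate `error_rate`,
// using R's RNG (reproducible under set.seed). Gap-skipping: successive
// error positions over the concatenated bases are separated by geometric
// gaps, so runtime scales with the number of errors, not the number of bases.
// [[Rcpp::export]]
CharacterVector add_substitution_errors_cpp(CharacterVector reads, double error_rate) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)");
  int n = reads.size();
  CharacterVector out(n);
  if (error_rate == 0) {
    for (int i = 0; i < n; ++i) SET_STRING_ELT(out, i, STRING_ELT(reads, i));
    return out;
  }
  RNGScope scope;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  double log1me = std::log1p(-error_rate);

  // total length and per-read offsets
  std::vector<R_xlen_t> offset(n + 1, 0);
  for (int i = 0; i < n; ++i)
    offset[i + 1] = offset[i] + LENGTH(STRING_ELT(reads, i));
  R_xlen_t total = offset[n];

  std::vector<std::string> buf(n);
  for (int i = 0; i < n; ++i)
    buf[i].assign(CHAR(STRING_ELT(reads, i)), LENGTH(STRING_ELT(reads, i)));

  R_xlen_t pos = -1;
  int cur = 0;
  while (true) {
    double u = unif_rand();
    pos += 1 + (R_xlen_t)std::floor(std::log(u) / log1me);
    if (pos >= total) break;
    while (offset[cur + 1] <= pos) ++cur;
    R_xlen_t k = pos - offset[cur];
    char old = buf[cur][k];
    int oi = (old == 'A') ? 0 : (old == 'C') ? 1 : (old == 'G') ? 2 : 3;
    int shift = 1 + (int)(unif_rand() * 3.0);
    if (shift > 3) shift = 3;  // guard against unif_rand() == 1.0 edge
    buf[cur][k] = bases[(oi + shift) % 4];
  }
  for (int i = 0; i < n; ++i)
    SET_STRING_ELT(out, i, Rf_mkCharLen(buf[i].c_str(), (int)buf[i].size()));
  return out;
}
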