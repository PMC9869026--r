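// Low-level sequence kernels: MinHash sketching, seed-and-extend fragment
// alignment, minimizer-based read assignment, conserved-anchor scanning and
// per-base HiFi noise simulation.  All hashes are masked to 53 bits so they
// survive the round trip through R doubles.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static const uint64_t MASK53 = (1ULL << 53) - 1ULL;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char bit2base(int b) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  return B[b & 3];
}

// Enumerate canonical k-mer codes (min of forward and reverse-complement
// 2-bit encodings); windows containing non-ACGT bases are skipped.
template <typename F>
static void for_each_canonical_kmer(const std::string& s, int k, F&& fun) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      fun((long)(i + 1 - k), canon, fwd);
    }
  }
}

// ---------------------------------------------------------------------------
// MinHash sketch: bottom-s distinct 53-bit hashes of canonical k-mers.
// [[Rcpp::export]]
NumericVector mh_sketch_cpp(CharacterVector seqs, int k, int s, double seed) {
  const uint64_t seed64 = (uint64_t)seed;
  std::vector<uint64_t> hashes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string sq = as<std::string>(seqs[i]);
    for_each_canonical_kmer(sq, k, [&](long, uint64_t canon, uint64_t) {
      hashes.push_back(splitmix64(canon ^ seed64) & MASK53);
    });
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t n = std::min((size_t)s, hashes.size());
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (double)hashes[i];
  return out;
}

// All distinct canonical k-mer hashes (exact set, used for Jaccard checks
// on small sequences and for seeding diagnostics).
// [[Rcpp::export]]
NumericVector kmer_hash_set_cpp(CharacterVector seqs, int k, double seed) {
  const uint64_t seed64 = (uint64_t)seed;
  std::vector<uint64_t> hashes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string sq = as<std::string>(seqs[i]);
    for_each_canonical_kmer(sq, k, [&](long, uint64_t canon, uint64_t) {
      hashes.push_back(splitmix64(canon ^ seed64) & MASK53);
    });
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  return NumericVector(hashes.begin(), hashes.end());
}

// ---------------------------------------------------------------------------
// Banded semi-global alignment of a fragment against a reference window.
// The fragment is aligned end-to-end (after clipping to the reference);
// leading/trailing gaps in the window are free.  Returns matches and total
// alignment columns on the optimal path.
struct BandAln { int matches; int columns; int score; };

static BandAln banded_align(const std::string& frag, const std::string& wnd,
                            int band2) {
  const int m = (int)frag.size();
  const int n = (int)wnd.size();
  const int C = band2 + 1;                    // offsets j - i in [0, band2]
  const int NEG = -1000000000;
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  std::vector<int> S((size_t)(m + 1) * C, NEG);
  std::vector<signed char> P((size_t)(m + 1) * C, 0); // 1 diag, 2 up, 3 left
  for (int c = 0; c < C; ++c)
    if (c <= n) S[c] = 0;                     // free leading window gaps
  for (int i = 1; i <= m; ++i) {
    for (int c = 0; c < C; ++c) {
      int j = i + c;
      if (j < 1 || j > n) continue;
      int best = NEG, ptr = 0;
      int d = S[(size_t)(i - 1) * C + c];
      if (d > NEG) {
        int sc = d + (frag[i - 1] == wnd[j - 1] ? MATCH : MISMATCH);
        if (sc > best) { best = sc; ptr = 1; }
      }
      if (c + 1 < C) {                        // gap in window (frag consumed)
        int u = S[(size_t)(i - 1) * C + c + 1];
        if (u > NEG && u + GAP > best) { best = u + GAP; ptr = 2; }
      }
      if (c - 1 >= 0) {                       // gap in fragment
        int l = S[(size_t)i * C + c - 1];
        if (l > NEG && l + GAP > best) { best = l + GAP; ptr = 3; }
      }
      S[(size_t)i * C + c] = best;
      P[(size_t)i * C + c] = (signed char)ptr;
    }
  }
  int bestc = -1, bests = NEG;
  for (int c = 0; c < C; ++c) {
    int j = m + c;
    if (j > n) continue;
    int sc = S[(size_t)m * C + c];
    if (sc > bests) { bests = sc; bestc = c; }
  }
  BandAln res; res.matches = 0; res.columns = 0; res.score = bests;
  if (bestc < 0) return res;
  int i = m, c = bestc;
  while (i > 0) {
    signed char ptr = P[(size_t)i * C + c];
    if (ptr == 1) {
      int j = i + c;
      if (frag[i - 1] == wnd[j - 1]) res.matches++;
      res.columns++; i--;
    } else if (ptr == 2) { res.columns++; i--; c++; }
    else if (ptr == 3) { res.columns++; c--; }
    else break;                               // hit the free boundary row
  }
  return res;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[s.size() - 1 - i]);
    r[i] = (b < 0) ? 'N' : bit2base(3 - b);
  }
  return r;
}

// Fragment ANI core: cut `query` into consecutive `frag_bp` fragments,
// anchor each by shared k-mer seeds to its best diagonal in `ref` (both
// strands), extend with a banded alignment (half band = band_frac*frag_bp)
// and report per-fragment identity and fragment coverage.
// [[Rcpp::export]]
DataFrame ani_fragments_cpp(std::string query, std::string ref, int frag_bp,
                            int k, double band_frac, int min_seeds) {
  // forward k-mer index of the reference
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(ref.size());
  {
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    uint64_t fwd = 0; int valid = 0;
    for (size_t i = 0; i < ref.size(); ++i) {
      int b = base2bit(ref[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= k) idx[fwd].push_back((int)(i + 1 - k));
    }
  }
  const int n_frag = (int)(query.size() / (size_t)frag_bp);
  const int B = (int)std::max(8.0, band_frac * frag_bp + 0.5);
  const int rlen = (int)ref.size();
  std::vector<int> f_start(n_frag), f_seeds(n_frag);
  std::vector<int> f_strand(n_frag);
  std::vector<double> f_ident(n_frag), f_cov(n_frag);

  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (int f = 0; f < n_frag; ++f) {
    std::string frag = query.substr((size_t)f * frag_bp, frag_bp);
    int best_seeds = 0, best_diag = 0, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string fr = strand == 0 ? frag : revcomp_str(frag);
      std::unordered_map<int, int> votes;
      uint64_t fwd = 0; int valid = 0;
      for (size_t i = 0; i < fr.size(); ++i) {
        int b = base2bit(fr[i]);
        if (b < 0) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          auto it = idx.find(fwd);
          if (it != idx.end() && it->second.size() <= 50) {
            int p = (int)(i + 1 - k);
            for (int rp : it->second) votes[rp - p]++;
          }
        }
      }
      for (auto& kv : votes) {
        if (kv.second > best_seeds ||
            (kv.second == best_seeds && best_seeds > 0 &&
             strand == best_strand && kv.first < best_diag)) {
          best_seeds = kv.second; best_diag = kv.first; best_strand = strand;
        }
      }
    }
    f_start[f] = f * frag_bp;
    f_seeds[f] = best_seeds;
    f_strand[f] = best_strand;
    if (best_seeds < min_seeds) { f_ident[f] = NA_REAL; f_cov[f] = 0.0; continue; }
    std::string fr = best_strand == 0 ? frag : revcomp_str(frag);
    // clip fragment to the part that lands on the reference
    int d = best_diag;
    int trim_l = d < 0 ? -d : 0;
    int trim_r = (d + (int)fr.size() > rlen) ? d + (int)fr.size() - rlen : 0;
    int m = (int)fr.size() - trim_l - trim_r;
    if (m < k) { f_ident[f] = NA_REAL; f_cov[f] = 0.0; continue; }
    std::string frc = fr.substr(trim_l, m);
    int tstart = d + trim_l;                  // ref pos of trimmed frag start
    int ws = std::max(0, tstart - B);
    int we = std::min(rlen, tstart + m + B);
    std::string wnd = ref.substr(ws, we - ws);
    BandAln a = banded_align(frc, wnd, 2 * B);
    if (a.columns == 0) { f_ident[f] = NA_REAL; f_cov[f] = 0.0; continue; }
    f_ident[f] = 100.0 * a.matches / a.columns;
    f_cov[f] = 100.0 * m / (double)frag_bp;
  }
  return DataFrame::create(_["frag_start"] = f_start,
                           _["n_seeds"] = f_seeds,
                           _["strand"] = f_strand,
                           _["identity"] = f_ident,
                           _["coverage"] = f_cov);
}

// ---------------------------------------------------------------------------
// Minimizer-based read assignment.
// (k, w) minimizers: minimum hashed canonical k-mer in each window of w
// consecutive k-mers, deduplicated between adjacent windows.
static void minimizers_of(const std::string& s, int k, int w, uint64_t seed64,
                          std::vector<std::pair<uint64_t, int> >& out) {
  std::vector<std::pair<uint64_t, int> > ring; // (hash, pos) for all kmers
  ring.reserve(s.size());
  for_each_canonical_kmer(s, k, [&](long pos, uint64_t canon, uint64_t) {
    ring.push_back(std::make_pair(splitmix64(canon ^ seed64) & MASK53, (int)pos));
  });
  const int n = (int)ring.size();
  if (n == 0) return;
  int last_pos = -1;
  for (int i = 0; i + w <= n; ++i) {
    int best = i;
    for (int j = i + 1; j < i + w; ++j)
      if (ring[j].first < ring[best].first) best = j;
    if (ring[best].second != last_pos) {
      out.push_back(ring[best]);
      last_pos = ring[best].second;
    }
  }
  if (n < w) { // short sequence: single window over what exists
    int best = 0;
    for (int j = 1; j < n; ++j)
      if (ring[j].first < ring[best].first) best = j;
    out.push_back(ring[best]);
  }
}

// [[Rcpp::export]]
DataFrame assign_reads_cpp(CharacterVector reads, CharacterVector genomes,
                           int k, int w, int min_hits, double seed) {
  const uint64_t seed64 = (uint64_t)seed;
  const int G = (int)genomes.size();
  std::unordered_map<uint64_t, std::vector<uint64_t> > idx; // gi<<32 | pos
  for (int g = 0; g < G; ++g) {
    std::string sq = as<std::string>(genomes[g]);
    std::vector<std::pair<uint64_t, int> > mins;
    minimizers_of(sq, k, w, seed64, mins);
    for (auto& m : mins) {
      std::vector<uint64_t>& v = idx[m.first];
      if (v.size() < 200) v.push_back(((uint64_t)g << 32) | (uint64_t)m.second);
    }
  }
  const R_xlen_t N = reads.size();
  IntegerVector genome(N), hits(N), rstart(N), rend(N), nmin(N);
  std::vector<int> cnt(G), mn(G), mx(G);
  for (R_xlen_t i = 0; i < N; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<std::pair<uint64_t, int> > mins;
    minimizers_of(rd, k, w, seed64, mins);
    std::fill(cnt.begin(), cnt.end(), 0);
    std::fill(mn.begin(), mn.end(), INT_MAX);
    std::fill(mx.begin(), mx.end(), -1);
    for (auto& m : mins) {
      auto it = idx.find(m.first);
      if (it == idx.end() || it->second.size() >= 200) continue;
      for (uint64_t e : it->second) {
        int g = (int)(e >> 32), p = (int)(e & 0xFFFFFFFFULL);
        cnt[g]++;
        if (p < mn[g]) mn[g] = p;
        if (p > mx[g]) mx[g] = p;
      }
    }
    int best = -1;
    for (int g = 0; g < G; ++g)
      if (best < 0 || cnt[g] > cnt[best]) best = g;
    nmin[i] = (int)mins.size();
    if (best >= 0 && cnt[best] >= min_hits) {
      genome[i] = best + 1;
      hits[i] = cnt[best];
      rstart[i] = mn[best];            // 0-based
      rend[i] = mx[best] + k;          // half-open
    } else {
      genome[i] = NA_INTEGER; hits[i] = best >= 0 ? cnt[best] : 0;
      rstart[i] = NA_INTEGER; rend[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["genome"] = genome, _["hits"] = hits,
                           _["ref_start"] = rstart, _["ref_end"] = rend,
                           _["n_minimizers"] = nmin);
}

// ---------------------------------------------------------------------------
// Conserved-anchor scan: find every position where an anchor (15-mer)
// occurs with at most `max_mismatch` (0 or 1) substitutions, on either
// strand.  Strand "-" means the reverse complement of the anchor matches
// the sequence as written.
// [[Rcpp::export]]
DataFrame scan_anchors_cpp(CharacterVector seqs, CharacterVector anchors,
                           int max_mismatch) {
  const int A = (int)anchors.size();
  int alen = -1;
  std::vector<uint64_t> afwd(A), arev(A);
  for (int a = 0; a < A; ++a) {
    std::string as_ = as<std::string>(anchors[a]);
    if (alen < 0) alen = (int)as_.size();
    if ((int)as_.size() != alen) stop("anchors must share one length");
    uint64_t f = 0;
    for (char c : as_) {
      int b = base2bit(c);
      if (b < 0) stop("anchor contains non-ACGT base");
      f = (f << 2) | (uint64_t)b;
    }
    afwd[a] = f;
    std::string rc = revcomp_str(as_);
    uint64_t r = 0;
    for (char c : rc) r = (r << 2) | (uint64_t)base2bit(c);
    arev[a] = r;
  }
  if (alen > 31) stop("anchors longer than 31 bp are not supported");
  const uint64_t mask = (1ULL << (2 * alen)) - 1ULL;
  const uint64_t odd = 0x5555555555555555ULL & mask;
  std::vector<int> o_seq, o_anchor, o_pos;
  std::vector<int> o_strand;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string sq = as<std::string>(seqs[i]);
    uint64_t fwd = 0; int valid = 0;
    for (size_t p = 0; p < sq.size(); ++p) {
      int b = base2bit(sq[p]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid < alen) continue;
      int start = (int)(p + 1 - alen);
      for (int a = 0; a < A; ++a) {
        uint64_t x = fwd ^ afwd[a];
        uint64_t z = (x | (x >> 1)) & odd;
        if (__builtin_popcountll(z) <= max_mismatch) {
          o_seq.push_back((int)i + 1); o_anchor.push_back(a + 1);
          o_pos.push_back(start + 1); o_strand.push_back(1);
        }
        x = fwd ^ arev[a];
        z = (x | (x >> 1)) & odd;
        if (__builtin_popcountll(z) <= max_mismatch) {
          o_seq.push_back((int)i + 1); o_anchor.push_back(a + 1);
          o_pos.push_back(start + 1); o_strand.push_back(-1);
        }
      }
    }
  }
  return DataFrame::create(_["seq"] = o_seq, _["anchor"] = o_anchor,
                           _["pos"] = o_pos, _["strand"] = o_strand);
}

// ---------------------------------------------------------------------------
// HiFi noise simulation.  For each read: per-base quality = q0 + jitter
// drawn uniformly from {-jit..jit}; each base substituted with probability
// 10^(-Q/10), so Phred-implied accuracy is an unbiased estimate of the
// realized accuracy.  Uses R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
List simulate_noise_cpp(CharacterVector seqs, IntegerVector q0, int jitter) {
  const R_xlen_t N = seqs.size();
  if (q0.size() != N) stop("q0 must match seqs");
  CharacterVector mut(N), qual(N);
  IntegerVector nerr(N);
  List errpos(N);
  double perr[128];
  for (int q = 0; q < 128; ++q) perr[q] = std::pow(10.0, -q / 10.0);
  const int span = 2 * jitter + 1;
  for (R_xlen_t i = 0; i < N; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string qs(s.size(), '!');
    std::vector<int> pos;
    for (size_t p = 0; p < s.size(); ++p) {
      int j = (int)(unif_rand() * span) - jitter;
      int q = q0[i] + j;
      if (q < 2) q = 2;
      if (q > 93) q = 93;
      qs[p] = (char)(q + 33);
      if (unif_rand() < perr[q]) {
        int b = base2bit(s[p]);
        if (b >= 0) {
          int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
          s[p] = bit2base(nb);
          pos.push_back((int)p + 1);
        }
      }
    }
    mut[i] = s;
    qual[i] = qs;
    nerr[i] = (int)pos.size();
    errpos[i] = IntegerVector(pos.begin(), pos.end());
  }
  return List::create(_["seq"] = mut, _["qual"] = qual,
                      _["n_err"] = nerr, _["err_pos"] = errpos);
}

// Mean Phred error probability per quality string (Sanger +33 offset).
// [[Rcpp::export]]
NumericVector qual_mean_error_cpp(CharacterVector quals) {
  NumericVector out(quals.size());
  double perr[128];
  for (int q = 0; q < 128; ++q) perr[q] = std::pow(10.0, -q / 10.0);
  for (R_xlen_t i = 0; i < quals.size(); ++i) {
    std::string qs = as<std::string>(quals[i]);
    if (qs.empty()) { out[i] = NA_REAL; continue; }
    double s = 0;
    for (char c : qs) {
      int q = (int)c - 33;
      if (q < 0) q = 0;
      if (q > 127) q = 127;
      s += perr[q];
    }
    out[i] = s / qs.size();
  }
  return out;
}

// FNV-1a 64-bit hash of a string, masked to 53 bits (for config hashing).
// [[Rcpp::export]]
double fnv1a_cpp(std::string s) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 0x100000001B3ULL;
  }
  return (double)(h & MASK53);
}
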