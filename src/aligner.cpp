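// Split-read aligner for single-gene references.
//
// Strategy: exact k-mer anchors -> diagonal grouping -> collinear chain DP
// (deletion-type reference gaps only) -> per-junction split resolution with
// microhomology handling (snap to annotated exon boundaries when a placement
// within the homology window puts both edges on annotated positions, else
// left-align) -> full-length layout, soft-clipping of low-identity tails,
// mismatch-fraction filter.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <sstream>

using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char cmpl(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[i] = cmpl(s[s.size() - 1 - i]);
  return out;
}

struct KmerIndex {
  int k;
  std::string seq;
  std::unordered_map<uint64_t, std::vector<int32_t> > map;
};

// All k-mer (start, 2-bit code) pairs of s; windows containing non-ACGT skipped.
static void kmers_of(const std::string& s, int k,
                     std::vector<std::pair<int, uint64_t> >& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t val = 0;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = b2(s[i]);
    if (b < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)b) & mask;
    if (++run >= k) out.push_back(std::make_pair(i - k + 1, val));
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (seq.empty()) stop("reference sequence is empty");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->seq = seq;
  std::vector<std::pair<int, uint64_t> > km;
  kmers_of(seq, k, km);
  for (size_t i = 0; i < km.size(); ++i) idx->map[km[i].second].push_back(km[i].first);
  XPtr<KmerIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<KmerIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("query length must equal k");
  std::vector<std::pair<int, uint64_t> > km;
  kmers_of(kmer, xp->k, km);
  if (km.empty()) return IntegerVector(0);
  std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it =
    xp->map.find(km[0].second);
  if (it == xp->map.end()) return IntegerVector(0);
  return wrap(it->second);
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp_) { XPtr<KmerIndex> xp(xp_); return xp->k; }

// [[Rcpp::export]]
int cpp_index_reflen(SEXP xp_) { XPtr<KmerIndex> xp(xp_); return (int)xp->seq.size(); }

struct DiagEnt {
  long d;
  int qmin, qmax;  // anchor start positions (q of first base)
  int count;
};

struct Chain {
  std::vector<int> idx;  // entries in q order
  int score;
  long gapsum;
  bool tie;
};

static int collect_anchors(const std::string& read, const KmerIndex& idx,
                           std::vector<std::pair<int, long> >& anchors,
                           int max_hits_per_kmer) {
  anchors.clear();
  std::vector<std::pair<int, uint64_t> > km;
  kmers_of(read, idx.k, km);
  for (size_t i = 0; i < km.size(); ++i) {
    std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it =
      idx.map.find(km[i].second);
    if (it == idx.map.end()) continue;
    if ((int)it->second.size() > max_hits_per_kmer) continue;
    for (size_t j = 0; j < it->second.size(); ++j)
      anchors.push_back(std::make_pair(km[i].first, (long)it->second[j]));
  }
  return (int)anchors.size();
}

struct AlnResult {
  int status;  // 0 unmapped, 1 mapped, 2 ambiguous
  bool rc;
  int clipL, clipR, mism, aligned;
  std::vector<int> q0, q1;
  std::vector<long> r0, r1;
  std::vector<int> jstat;  // per junction: 0 left_aligned, 1 exon_snap
};

static bool in_sorted(const std::vector<long>& v, long x) {
  return std::binary_search(v.begin(), v.end(), x);
}

static void align_oriented(const std::string& read, const KmerIndex& idx,
                           const std::vector<std::pair<int, long> >& anchors,
                           long max_gap, int hwin, double max_mm_frac,
                           int min_terminal, int min_aligned,
                           const std::vector<long>& donors,
                           const std::vector<long>& acceptors,
                           AlnResult& res) {
  res.status = 0;
  res.q0.clear(); res.q1.clear(); res.r0.clear(); res.r1.clear(); res.jstat.clear();
  res.clipL = 0; res.clipR = 0; res.mism = 0; res.aligned = 0;
  const std::string& ref = idx.seq;
  const long reflen = (long)ref.size();
  const int rl = (int)read.size();
  const int k = idx.k;
  if (anchors.empty()) return;

  // group anchors by diagonal
  std::unordered_map<long, DiagEnt> dm;
  for (size_t i = 0; i < anchors.size(); ++i) {
    long d = anchors[i].second - (long)anchors[i].first;
    std::unordered_map<long, DiagEnt>::iterator it = dm.find(d);
    if (it == dm.end()) {
      DiagEnt e; e.d = d; e.qmin = anchors[i].first; e.qmax = anchors[i].first; e.count = 1;
      dm[d] = e;
    } else {
      if (anchors[i].first < it->second.qmin) it->second.qmin = anchors[i].first;
      if (anchors[i].first > it->second.qmax) it->second.qmax = anchors[i].first;
      it->second.count += 1;
    }
  }
  std::vector<DiagEnt> de;
  de.reserve(dm.size());
  for (std::unordered_map<long, DiagEnt>::iterator it = dm.begin(); it != dm.end(); ++it)
    de.push_back(it->second);
  std::sort(de.begin(), de.end(),
            [](const DiagEnt& a, const DiagEnt& b) {
              if (a.qmin != b.qmin) return a.qmin < b.qmin;
              return a.d < b.d;
            });

  // chain DP: query order increasing, diagonal strictly increasing (deletions
  // only), gap <= max_gap; maximize anchor count, tie-break on total gap
  int n = (int)de.size();
  std::vector<int> score(n), parent(n, -1);
  std::vector<long> gapsum(n, 0);
  std::vector<bool> tie(n, false);
  for (int i = 0; i < n; ++i) {
    score[i] = de[i].count;
    for (int j = 0; j < i; ++j) {
      if (de[i].qmin <= de[j].qmax) continue;
      if (de[i].d <= de[j].d) continue;
      long g = de[i].d - de[j].d;
      if (g > max_gap) continue;
      int cand = score[j] + de[i].count;
      long cg = gapsum[j] + g;
      if (cand > score[i] || (cand == score[i] && cg < gapsum[i])) {
        score[i] = cand; gapsum[i] = cg; parent[i] = j; tie[i] = tie[j];
      } else if (cand == score[i] && cg == gapsum[i] && parent[i] != j) {
        tie[i] = true;  // a distinct equally-good chain exists
      }
    }
  }
  int best = 0;
  for (int i = 1; i < n; ++i) {
    if (score[i] > score[best] ||
        (score[i] == score[best] && gapsum[i] < gapsum[best])) best = i;
    else if (score[i] == score[best] && gapsum[i] == gapsum[best] && i != best) {
      // distinct chain with identical score and gap: flag as tie unless it is
      // the same single-diagonal placement
      tie[best] = true;
    }
  }
  bool ambiguous = tie[best];
  std::vector<int> chain;
  for (int i = best; i >= 0; i = parent[i]) chain.push_back(i);
  std::reverse(chain.begin(), chain.end());
  int nb = (int)chain.size();

  // resolve splits between consecutive blocks
  std::vector<int> splits(nb + 1);
  splits[0] = 0; splits[nb] = rl;
  std::vector<int> jstat(nb > 1 ? nb - 1 : 0, 0);
  for (int i = 0; i + 1 < nb; ++i) {
    const DiagEnt& L = de[chain[i]];
    const DiagEnt& R = de[chain[i + 1]];
    long d1 = L.d, d2 = R.d;
    int A = L.qmax + k;   // certainly matched on d1 for q < A
    int B = R.qmin;       // certainly matched on d2 for q >= B
    // extend the certain zones base-by-base while matching
    int Aext = A;
    while (Aext < rl) {
      long rp = (long)Aext + d1;
      if (rp < 0 || rp >= reflen || read[Aext] != ref[rp]) break;
      ++Aext;
    }
    int Bext = B;
    while (Bext > 0) {
      long rp = (long)(Bext - 1) + d2;
      if (rp < 0 || rp >= reflen || read[Bext - 1] != ref[rp]) break;
      --Bext;
    }
    int cap_hi = R.qmax + k;       // split cannot pass the right block's anchors
    int cap_lo = splits[i];        // nor precede the previous split
    std::vector<int> coopt;        // co-optimal split positions, ascending
    if (Bext <= Aext) {
      int lo = std::max(Bext, cap_lo);
      int hi = std::min(Aext, cap_hi);
      if (lo > hi) { lo = hi = std::min(std::max(B, cap_lo), cap_hi); }
      for (int s = lo; s <= hi; ++s) coopt.push_back(s);
    } else {
      // mismatch zone [Aext, Bext]: pick split(s) maximizing matches
      int lo = std::max(Aext, cap_lo), hi = std::min(Bext, cap_hi);
      if (lo > hi) { lo = hi = std::min(std::max(Aext, cap_lo), cap_hi); }
      int len = hi - lo;
      std::vector<int> m1(len), m2(len);
      for (int t = 0; t < len; ++t) {
        int q = lo + t;
        long rp1 = (long)q + d1, rp2 = (long)q + d2;
        m1[t] = (rp1 >= 0 && rp1 < reflen && read[q] == ref[rp1]) ? 1 : 0;
        m2[t] = (rp2 >= 0 && rp2 < reflen && read[q] == ref[rp2]) ? 1 : 0;
      }
      int suff2 = 0;
      for (int t = 0; t < len; ++t) suff2 += m2[t];
      int pre1 = 0, bestsc = -1;
      std::vector<int> scs(len + 1);
      for (int s = 0; s <= len; ++s) {
        scs[s] = pre1 + suff2;
        if (scs[s] > bestsc) bestsc = scs[s];
        if (s < len) { pre1 += m1[s]; suff2 -= m2[s]; }
      }
      for (int s = 0; s <= len; ++s) if (scs[s] == bestsc) coopt.push_back(lo + s);
    }
    // snap to annotated boundaries if a co-optimal placement within the
    // homology window lands both edges on annotated positions; else left-align
    int chosen = coopt[0], st = 0;
    if (!donors.empty()) {
      for (size_t t = 0; t < coopt.size(); ++t) {
        int s = coopt[t];
        if (s - coopt[0] > hwin) break;
        if (in_sorted(donors, (long)s + d1) && in_sorted(acceptors, (long)s + d2)) {
          chosen = s; st = 1; break;
        }
      }
    }
    splits[i + 1] = chosen;
    jstat[i] = st;
  }
  // enforce monotone splits (degenerate overlaps)
  for (int i = 1; i <= nb; ++i) if (splits[i] < splits[i - 1]) splits[i] = splits[i - 1];

  // mismatch layout over the full read
  std::vector<char> mm(rl, 1);
  for (int i = 0; i < nb; ++i) {
    long d = de[chain[i]].d;
    for (int q = splits[i]; q < splits[i + 1]; ++q) {
      long rp = (long)q + d;
      mm[q] = (rp >= 0 && rp < reflen && read[q] == ref[rp]) ? 0 : 1;
    }
  }

  // soft-clip low-identity tails: clip prefix/suffix minimizing running score
  // (match +1, mismatch -3)
  long sc = 0, minv = 0; int clipL = 0;
  for (int i = 1; i <= rl; ++i) {
    sc += mm[i - 1] ? -3 : 1;
    if (sc <= minv) { minv = sc; clipL = i; }
  }
  if (minv >= 0) clipL = 0;
  sc = 0; minv = 0; int clipR = 0;
  for (int i = 1; i <= rl; ++i) {
    sc += mm[rl - i] ? -3 : 1;
    if (sc <= minv) { minv = sc; clipR = i; }
  }
  if (minv >= 0) clipR = 0;
  if (clipL + clipR >= rl) return;  // nothing credible aligned

  // apply clips to blocks; drop empty blocks and their junctions
  std::vector<int> bq0, bq1; std::vector<long> br0, br1; std::vector<int> bjs;
  for (int i = 0; i < nb; ++i) {
    int q0 = std::max(splits[i], clipL);
    int q1 = std::min(splits[i + 1], rl - clipR);
    if (q1 <= q0) continue;
    long d = de[chain[i]].d;
    if (!bq0.empty()) bjs.push_back(jstat[i - 1]);  // junction to previous kept block
    bq0.push_back(q0); bq1.push_back(q1);
    br0.push_back((long)q0 + d); br1.push_back((long)q1 + d);
  }
  // note: if a middle block was dropped the jstat pairing above is approximate;
  // dropped middle blocks are vanishingly rare (they imply a fully-clipped
  // internal block) and the junction is then between the flanking diagonals.

  // terminal blocks below the minimum length are not allowed to call junctions:
  // clip them away entirely
  while ((int)bq0.size() > 1 && bq1.front() - bq0.front() < min_terminal) {
    clipL = bq1.front();
    bq0.erase(bq0.begin()); bq1.erase(bq1.begin());
    br0.erase(br0.begin()); br1.erase(br1.begin());
    bjs.erase(bjs.begin());
  }
  while ((int)bq0.size() > 1 && bq1.back() - bq0.back() < min_terminal) {
    clipR = rl - bq0.back();
    bq0.pop_back(); bq1.pop_back(); br0.pop_back(); br1.pop_back();
    bjs.pop_back();
  }
  if (bq0.empty()) return;

  int aligned = 0, mism = 0;
  for (size_t i = 0; i < bq0.size(); ++i) {
    aligned += bq1[i] - bq0[i];
    for (int q = bq0[i]; q < bq1[i]; ++q) mism += mm[q];
  }
  if (aligned < min_aligned) return;
  if ((double)mism / (double)aligned > max_mm_frac) return;

  res.status = ambiguous ? 2 : 1;
  res.clipL = clipL; res.clipR = clipR;
  res.mism = mism; res.aligned = aligned;
  res.q0 = bq0; res.q1 = bq1; res.r0 = br0; res.r1 = br1; res.jstat = bjs;
}

// [[Rcpp::export]]
List cpp_align_reads(SEXP xp_, CharacterVector reads,
                     NumericVector donors_, NumericVector acceptors_,
                     NumericVector span_points_, double max_gap,
                     int homology_window, double max_mismatch_frac,
                     int min_terminal, int min_span, int min_aligned,
                     int max_hits_per_kmer) {
  XPtr<KmerIndex> xp(xp_);
  const KmerIndex& idx = *xp;
  int nr = reads.size();
  std::vector<long> donors(donors_.begin(), donors_.end());
  std::vector<long> acceptors(acceptors_.begin(), acceptors_.end());
  std::vector<long> spts(span_points_.begin(), span_points_.end());
  std::sort(donors.begin(), donors.end());
  std::sort(acceptors.begin(), acceptors.end());
  std::sort(spts.begin(), spts.end());

  CharacterVector status(nr), strand(nr), blocks(nr), junctions(nr),
    junc_status(nr), spans(nr);
  IntegerVector n_blocks(nr), mismatches(nr), aligned(nr), clip_left(nr), clip_right(nr);

  std::vector<std::pair<int, long> > anc_f, anc_r;
  AlnResult res;
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int nf = collect_anchors(rd, idx, anc_f, max_hits_per_kmer);
    std::string rdr = revcomp(rd);
    int nrv = collect_anchors(rdr, idx, anc_r, max_hits_per_kmer);
    bool use_rc = nrv > nf;
    const std::string& ord = use_rc ? rdr : rd;
    const std::vector<std::pair<int, long> >& anc = use_rc ? anc_r : anc_f;
    align_oriented(ord, idx, anc, (long)max_gap, homology_window,
                   max_mismatch_frac, min_terminal, min_aligned,
                   donors, acceptors, res);
    res.rc = use_rc;

    if (res.status == 0) {
      status[i] = "unmapped"; strand[i] = use_rc ? "-" : "+";
      n_blocks[i] = 0; mismatches[i] = NA_INTEGER; aligned[i] = 0;
      clip_left[i] = NA_INTEGER; clip_right[i] = NA_INTEGER;
      blocks[i] = ""; junctions[i] = ""; junc_status[i] = ""; spans[i] = "";
      continue;
    }
    status[i] = (res.status == 2) ? "ambiguous" : "mapped";
    strand[i] = use_rc ? "-" : "+";
    int nb = (int)res.q0.size();
    n_blocks[i] = nb;
    mismatches[i] = res.mism; aligned[i] = res.aligned;
    clip_left[i] = res.clipL; clip_right[i] = res.clipR;
    std::ostringstream ob, oj, os, osp;
    for (int b = 0; b < nb; ++b) {
      if (b) ob << ";";
      ob << res.q0[b] << ":" << res.q1[b] << ":" << res.r0[b] << ":" << res.r1[b];
      if (b) {
        if (b > 1) { oj << ";"; os << ";"; }
        oj << res.r1[b - 1] << ":" << res.r0[b];
        os << (res.jstat[b - 1] ? "exon_snap" : "left_aligned");
      }
      // annotated boundaries spanned with min_span flank on both sides
      std::vector<long>::const_iterator lo =
        std::lower_bound(spts.begin(), spts.end(), res.r0[b] + min_span);
      for (std::vector<long>::const_iterator it = lo;
           it != spts.end() && *it <= res.r1[b] - min_span; ++it) {
        if (osp.tellp() > 0) osp << ",";
        osp << (int)(it - spts.begin()) + 1;
      }
    }
    blocks[i] = ob.str(); junctions[i] = oj.str();
    junc_status[i] = os.str(); spans[i] = osp.str();
  }
  return List::create(
    _["status"] = status, _["strand"] = strand, _["n_blocks"] = n_blocks,
    _["mismatches"] = mismatches, _["aligned"] = aligned,
    _["clip_left"] = clip_left, _["clip_right"] = clip_right,
    _["blocks"] = blocks, _["junctions"] = junctions,
    _["junc_status"] = junc_status, _["spans"] = spans);
}
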