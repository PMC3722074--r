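// Seed-and-extend read mapper and pileup engine.
//
// The index is an exact k-mer hash over one genome (k <= 32, 2-bit packed;
// k-mers containing non-ACGT bases are skipped).  Mapping seeds a read on
// both strands with a small number of evenly spaced non-overlapping seeds,
// then scores each candidate locus with a semi-global (read-global,
// window-local) edit-distance DP and reports every locus attaining the
// minimal edit distance <= max_edit.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

struct GenomeIndex {
  int k;
  std::vector<std::string> chrom_names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> table;
};

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 8 || k > 32) stop("seed length k must be in [8, 32]");
  GenomeIndex* idx = new GenomeIndex();
  idx->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ci = 0; ci < seqs.size(); ci++) {
    std::string s = as<std::string>(seqs[ci]);
    idx->chrom_names.push_back(as<std::string>(names[ci]));
    uint64_t kmer = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    for (size_t p = 0; p < s.size(); p++) {
      int b = base2bits(s[p]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      valid++;
      if (valid >= k) {
        idx->table[kmer].push_back({(int32_t)ci, (int32_t)(p - k + 1)});
      }
    }
    idx->seqs.push_back(std::move(s));
  }
  XPtr<GenomeIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP index_ptr, std::string kmer) {
  XPtr<GenomeIndex> idx(index_ptr);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int b = base2bits(c);
    if (b < 0) return IntegerVector(0);  // k-mers with N are never indexed
    key = (key << 2) | (uint64_t)b;
  }
  auto it = idx->table.find(key);
  if (it == idx->table.end()) return IntegerVector(0);
  IntegerVector chrom(it->second.size()), pos(it->second.size());
  for (size_t i = 0; i < it->second.size(); i++) {
    chrom[i] = it->second[i].first + 1;
    pos[i] = it->second[i].second;
  }
  chrom.attr("pos") = pos;
  return chrom;
}

struct Hit {
  int chrom;
  int pos;       // 0-based leftmost on forward genome
  bool rev;
  int edit;
  int ref_len;
  std::string cigar;
};

// Semi-global DP of query against window ws..we (0-based, half-open) of
// chrom sequence.  Free start over the first free_cols+1 columns; query must
// be consumed entirely.  Costs are combined as 256 per mismatch and 257 per
// gap base, so minimal combined cost means minimal edit distance first and,
// among equal-edit alignments, the fewest indels — a final-base substitution
// is reported as a mismatch, never traded for an indel.  Requires the
// maximum edit distance < 256.
static const int SUB_COST = 256;
static const int GAP_COST = 257;

static bool align_window(const std::string& ref, int ws, int we,
                         const std::string& query, int free_cols,
                         Hit& out, std::vector<int32_t>& D) {
  const int L = (int)query.size();
  const int W = we - ws;
  if (W <= 0) return false;
  const int INF = 1 << 28;
  const int cols = W + 1;
  D.assign((size_t)(L + 1) * cols, INF);
  for (int j = 0; j <= std::min(free_cols, W); j++) D[j] = 0;
  for (int i = 1; i <= L; i++) {
    int32_t* cur = &D[(size_t)i * cols];
    int32_t* prev = &D[(size_t)(i - 1) * cols];
    cur[0] = prev[0] + GAP_COST;
    char qc = query[i - 1];
    for (int j = 1; j <= W; j++) {
      int sub = prev[j - 1] + (ref[ws + j - 1] == qc ? 0 : SUB_COST);
      int ins = prev[j] + GAP_COST;   // query base not in ref
      int del = cur[j - 1] + GAP_COST;  // ref base skipped
      int v = sub < ins ? sub : ins;
      if (del < v) v = del;
      cur[j] = v;
    }
  }
  // pick end column: minimal combined cost, smallest j on true ties
  int best = INF, jend = -1;
  const int32_t* last = &D[(size_t)L * cols];
  for (int j = 0; j <= W; j++) {
    if (last[j] < best) { best = last[j]; jend = j; }
  }
  if (jend < 0 || best >= INF) return false;
  // traceback; prefer diagonal, then deletion (left), then insertion (up)
  std::vector<std::pair<char, int>> ops;
  int i = L, j = jend;
  while (i > 0) {
    const int32_t* cur = &D[(size_t)i * cols];
    const int32_t* prev = &D[(size_t)(i - 1) * cols];
    char qc = query[i - 1];
    if (j > 0 && prev[j - 1] + (ref[ws + j - 1] == qc ? 0 : SUB_COST) ==
                     cur[j]) {
      if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
      else ops.push_back({'M', 1});
      i--; j--;
    } else if (j > 0 && cur[j - 1] + GAP_COST == cur[j]) {
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back({'D', 1});
      j--;
    } else {
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back({'I', 1});
      i--;
    }
  }
  out.pos = ws + j;
  out.edit = best / SUB_COST;  // combined = 256*edits + indels, indels < 256
  out.ref_len = jend - j;
  std::string cig;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    cig += std::to_string(it->second);
    cig += it->first;
  }
  out.cigar = cig;
  return true;
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP index_ptr, CharacterVector reads, int max_edit,
                   int n_seeds) {
  XPtr<GenomeIndex> idx(index_ptr);
  if (max_edit < 0 || max_edit >= 256) stop("max_edit must be in [0, 255]");
  const int k = idx->k;
  std::vector<int> o_read, o_chrom, o_pos, o_edit, o_reflen, o_nbest;
  std::vector<bool> o_rev;
  std::vector<std::string> o_cigar;
  std::vector<int32_t> D;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (int r = 0; r < reads.size(); r++) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev = revcomp(fwd);
    std::vector<Hit> hits;
    for (int strand = 0; strand < 2; strand++) {
      const std::string& q = strand == 0 ? fwd : rev;
      // evenly spaced non-overlapping seed offsets
      std::vector<int> offs;
      int ns = std::min(n_seeds, L / k);
      if (ns < 1) ns = 1;
      if (ns == 1) offs.push_back(0);
      else {
        for (int i = 0; i < ns; i++)
          offs.push_back((int)((long long)i * (L - k) / (ns - 1)));
      }
      // collect candidate alignment start positions
      std::vector<std::pair<int, int>> cands;  // (chrom, start)
      for (int off : offs) {
        uint64_t kmer = 0;
        bool ok = true;
        for (int p = 0; p < k; p++) {
          int b = base2bits(q[off + p]);
          if (b < 0) { ok = false; break; }
          kmer = ((kmer << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        auto it = idx->table.find(kmer);
        if (it == idx->table.end()) continue;
        for (auto& cp : it->second)
          cands.push_back({cp.first, cp.second - off});
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      // merge candidates on the same chrom within max_edit of each other
      std::vector<std::pair<int, int>> merged;
      for (auto& c : cands) {
        if (!merged.empty() && merged.back().first == c.first &&
            c.second - merged.back().second <= max_edit) continue;
        merged.push_back(c);
      }
      for (auto& c : merged) {
        const std::string& ref = idx->seqs[c.first];
        int ws = std::max(0, c.second - max_edit);
        int we = std::min((int)ref.size(), c.second + L + 2 * max_edit);
        Hit h;
        h.chrom = c.first;
        h.rev = strand == 1;
        if (align_window(ref, ws, we, q, 3 * max_edit, h, D) &&
            h.edit <= max_edit)
          hits.push_back(h);
      }
    }
    if (hits.empty()) continue;
    // dedup by (chrom, pos, strand), keep min edit
    std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.pos != b.pos) return a.pos < b.pos;
      if (a.rev != b.rev) return a.rev < b.rev;
      return a.edit < b.edit;
    });
    std::vector<Hit> uniq;
    for (auto& h : hits) {
      if (!uniq.empty() && uniq.back().chrom == h.chrom &&
          uniq.back().pos == h.pos && uniq.back().rev == h.rev) continue;
      uniq.push_back(h);
    }
    int best = INT32_MAX;
    for (auto& h : uniq) best = std::min(best, h.edit);
    int nbest = 0;
    for (auto& h : uniq) if (h.edit == best) nbest++;
    for (auto& h : uniq) {
      if (h.edit != best) continue;
      o_read.push_back(r + 1);
      o_chrom.push_back(h.chrom + 1);
      o_pos.push_back(h.pos);
      o_rev.push_back(h.rev);
      o_edit.push_back(h.edit);
      o_reflen.push_back(h.ref_len);
      o_cigar.push_back(h.cigar);
      o_nbest.push_back(nbest);
    }
  }
  return List::create(
      _["read"] = wrap(o_read), _["chrom"] = wrap(o_chrom),
      _["pos"] = wrap(o_pos), _["rev"] = wrap(o_rev),
      _["edit"] = wrap(o_edit), _["ref_len"] = wrap(o_reflen),
      _["cigar"] = wrap(o_cigar), _["n_best"] = wrap(o_nbest));
}

// Pileup of aligned reads over a set of intervals.  Alignments are given by
// (chrom index 1-based, 0-based pos, CIGAR over {M,I,D}, sequence already in
// genome orientation).  Intervals are 0-based half-open on the same chrom
// indexing.  Returns an integer matrix with one row per interval position
// (concatenated in input order) and columns A, C, G, T.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector chrom, IntegerVector pos,
                         CharacterVector cigar, CharacterVector seq,
                         IntegerVector iv_chrom, IntegerVector iv_start,
                         IntegerVector iv_end, IntegerVector chrom_len) {
  int n_chrom = chrom_len.size();
  // per-chromosome 4-row count arrays
  std::vector<std::vector<int32_t>> counts(n_chrom);
  std::vector<bool> needed(n_chrom, false);
  for (int i = 0; i < iv_chrom.size(); i++) needed[iv_chrom[i] - 1] = true;
  for (int c = 0; c < n_chrom; c++)
    if (needed[c]) counts[c].assign((size_t)4 * chrom_len[c], 0);

  for (int a = 0; a < chrom.size(); a++) {
    int c = chrom[a] - 1;
    if (!needed[c]) continue;
    std::vector<int32_t>& cnt = counts[c];
    int clen = chrom_len[c];
    std::string cig = as<std::string>(cigar[a]);
    std::string s = as<std::string>(seq[a]);
    int p = pos[a], q = 0, num = 0;
    for (char ch : cig) {
      if (ch >= '0' && ch <= '9') { num = num * 10 + (ch - '0'); continue; }
      if (ch == 'M') {
        for (int t = 0; t < num; t++) {
          if (p >= 0 && p < clen && q < (int)s.size()) {
            int b = base2bits(s[q]);
            if (b >= 0) cnt[(size_t)4 * p + b]++;
          }
          p++; q++;
        }
      } else if (ch == 'I') {
        q += num;
      } else if (ch == 'D') {
        p += num;
      }
      num = 0;
    }
  }
  int total = 0;
  for (int i = 0; i < iv_chrom.size(); i++) total += iv_end[i] - iv_start[i];
  IntegerMatrix out(total, 4);
  int row = 0;
  for (int i = 0; i < iv_chrom.size(); i++) {
    int c = iv_chrom[i] - 1;
    for (int p = iv_start[i]; p < iv_end[i]; p++, row++) {
      for (int b = 0; b < 4; b++)
        out(row, b) = counts[c][(size_t)4 * p + b];
    }
  }
  colnames(out) = CharacterVector::create("A", "C", "G", "T");
  return out;
}
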