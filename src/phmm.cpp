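// Pair-HMM read mapper core: exhaustive k-mer seed index, forward-algorithm
// likelihood with per-cycle substitution probabilities, Viterbi traceback for
// the reported alignment, and a batch mapping driver.
//
// HMM conventions (shared with the R-level documentation and the test
// oracles):
//   * three states: M (match/mismatch), X (insertion in the read),
//     Y (deletion, i.e. genome base skipped);
//   * emissions: M at read cycle j emits the read base with probability
//     (1 - e_j) on base equality and e_j/3 otherwise (N on either side
//     counts as a mismatch); X emits the read base with probability 1/4;
//     Y emits nothing;
//   * transitions: Begin->M = M->M = 1 - 2*gap_open,
//     Begin->X = M->X = M->Y = gap_open, X->X = Y->Y = gap_extend,
//     X->M = Y->M = 1 - gap_extend; no X<->Y transitions;
//   * alignments start and end in M or X; the genome window is local
//     (free unscored flanks, start offsets not renormalised), the read is
//     global (every cycle consumed).
// Probabilities are accumulated in linear space; reads are <= ~100 nt so the
// smallest products (~(e/3)^L) stay far above double underflow.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <tuple>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> kmers;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector contigs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  CharacterVector nm = contigs.names();
  bool any_long_enough = false;
  for (int c = 0; c < contigs.size(); ++c) {
    idx->names.push_back(nm.size() ? as<std::string>(nm[c]) : "contig" + std::to_string(c + 1));
    idx->seqs.push_back(as<std::string>(contigs[c]));
    const std::string& s = idx->seqs.back();
    int n = (int)s.size();
    if (n >= k) any_long_enough = true;
    uint64_t key = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;  // number of consecutive non-N bases ending here
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b == 4) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      ++valid;
      if (valid >= k) idx->kmers[key].push_back({(int32_t)c, (int32_t)(i - k + 1)});
    }
  }
  if (!any_long_enough) {
    delete idx;
    stop("k exceeds the length of every contig");
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

static bool encode_kmer(const std::string& s, int from, int k, uint64_t* key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[from + i]);
    if (b == 4) return false;
    v = (v << 2) | (uint64_t)b;
  }
  *key = v;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_query_kmer(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  std::vector<int> contig; std::vector<int> pos;
  uint64_t key;
  if (encode_kmer(kmer, 0, idx->k, &key)) {
    auto it = idx->kmers.find(key);
    if (it != idx->kmers.end())
      for (auto& pc : it->second) { contig.push_back(pc.first + 1); pos.push_back(pc.second); }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos);
}

struct Cand {
  int32_t contig;
  int32_t wstart, wend;  // 0-based half-open window on the forward strand
  int strand;            // 0 = '+', 1 = '-'
  int hits;
};

// Collect candidate windows for one read: every exact k-mer hit of the read
// (forward) or of its reverse complement anchors an implied alignment start;
// windows of read span +/- band are merged per (contig, strand) when they
// overlap, then ranked by supporting hit count (ties: lowest contig, start,
// '+' before '-') and capped.
static std::vector<Cand> collect_candidates(const SeedIndex& idx, const std::string& read,
                                            int band, int max_candidates) {
  int k = idx.k;
  int m = (int)read.size();
  std::vector<Cand> out;
  if (m < k) return out;
  // key: (contig, strand, implied_start) -> hits
  std::map<std::tuple<int32_t, int, int32_t>, int> anchors;
  for (int strand = 0; strand < 2; ++strand) {
    std::string s = strand == 0 ? read : revcomp(read);
    for (int o = 0; o + k <= m; ++o) {
      uint64_t key;
      if (!encode_kmer(s, o, k, &key)) continue;
      auto it = idx.kmers.find(key);
      if (it == idx.kmers.end()) continue;
      for (auto& pc : it->second) {
        int32_t implied = pc.second - o;
        anchors[{pc.first, strand, implied}]++;
      }
    }
  }
  // windows, merged per (contig, strand); map iteration order is already
  // sorted by (contig, strand, implied)
  std::vector<Cand> merged;
  for (auto& kv : anchors) {
    int32_t c = std::get<0>(kv.first);
    int strand = std::get<1>(kv.first);
    int32_t implied = std::get<2>(kv.first);
    int32_t clen = (int32_t)idx.seqs[c].size();
    int32_t ws = std::max(0, implied - band);
    int32_t we = std::min(clen, implied + m + band);
    if (we <= ws) continue;
    if (!merged.empty() && merged.back().contig == c && merged.back().strand == strand &&
        ws <= merged.back().wend) {
      merged.back().wend = std::max(merged.back().wend, we);
      merged.back().hits += kv.second;
    } else {
      merged.push_back({c, ws, we, strand, kv.second});
    }
  }
  std::stable_sort(merged.begin(), merged.end(), [](const Cand& a, const Cand& b) {
    if (a.hits != b.hits) return a.hits > b.hits;
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.wstart != b.wstart) return a.wstart < b.wstart;
    return a.strand < b.strand;
  });
  if ((int)merged.size() > max_candidates) merged.resize(max_candidates);
  return merged;
}

// [[Rcpp::export]]
DataFrame cpp_candidates(SEXP xp, std::string read, int band, int max_candidates) {
  XPtr<SeedIndex> idx(xp);
  std::vector<Cand> cands = collect_candidates(*idx, read, band, max_candidates);
  int n = (int)cands.size();
  CharacterVector contig(n), strand(n);
  IntegerVector ws(n), we(n), hits(n);
  for (int i = 0; i < n; ++i) {
    contig[i] = idx->names[cands[i].contig];
    ws[i] = cands[i].wstart;
    we[i] = cands[i].wend;
    strand[i] = cands[i].strand == 0 ? "+" : "-";
    hits[i] = cands[i].hits;
  }
  return DataFrame::create(_["contig"] = contig, _["wstart"] = ws, _["wend"] = we,
                           _["strand"] = strand, _["hits"] = hits,
                           _["stringsAsFactors"] = false);
}

static inline double emit_m(char rb, char wb, double e) {
  int r = base_code(rb), w = base_code(wb);
  if (r == 4 || w == 4 || r != w) return e / 3.0;
  return 1.0 - e;
}

// Forward algorithm: P(read | window) summed over all alignments under the
// conventions in the file header.
static double forward_ll(const std::string& read, const std::string& win,
                         const double* e, double g, double gext) {
  int m = (int)read.size(), n = (int)win.size();
  if (m == 0) return R_NegInf;
  const double tMM = 1.0 - 2.0 * g, tMX = g, tMY = g;
  const double tXX = gext, tYY = gext, tXM = 1.0 - gext, tYM = 1.0 - gext;
  std::vector<double> Mp(n + 1, 0.0), Xp(n + 1, 0.0), Yp(n + 1, 0.0);
  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1);
  for (int i = 1; i <= m; ++i) {
    double ei = e[i - 1];
    Mc[0] = 0.0; Yc[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double from = (i == 1) ? tMM : (tMM * Mp[j - 1] + tXM * Xp[j - 1] + tYM * Yp[j - 1]);
      Mc[j] = emit_m(read[i - 1], win[j - 1], ei) * from;
    }
    for (int j = 0; j <= n; ++j) {
      double from = (i == 1) ? tMX : (tMX * Mp[j] + tXX * Xp[j]);
      Xc[j] = 0.25 * from;
    }
    for (int j = 1; j <= n; ++j) Yc[j] = tMY * Mc[j - 1] + tYY * Yc[j - 1];
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double tot = 0.0;
  for (int j = 0; j <= n; ++j) tot += Mp[j] + Xp[j];
  return tot > 0.0 ? std::log(tot) : R_NegInf;
}

// [[Rcpp::export]]
double cpp_forward(std::string read, std::string window, NumericVector esub,
                   double gap_open, double gap_extend) {
  if ((int)esub.size() < (int)read.size()) stop("error profile shorter than read");
  return forward_ll(read, window, REAL(esub), gap_open, gap_extend);
}

// Viterbi with traceback. Returns the best path's log probability, the
// 0-based alignment start within the window, the number of genome bases
// consumed, a CIGAR over {M,I,D} in read order, and a per-cycle edit string
// over {'=','X','I'} (D does not consume a cycle).
struct VitRes {
  double score;
  int wstart, glen;
  std::string cigar, edit;
  bool ok;
};

static VitRes viterbi_aln(const std::string& read, const std::string& win,
                          const double* e, double g, double gext) {
  int m = (int)read.size(), n = (int)win.size();
  VitRes res; res.ok = false; res.score = R_NegInf;
  if (m == 0) return res;
  const double tMM = 1.0 - 2.0 * g, tMX = g, tMY = g;
  const double tXX = gext, tYY = gext, tXM = 1.0 - gext, tYM = 1.0 - gext;
  const double NEG = -1e300;
  // log-space Viterbi; backpointers: 0 begin, 1 M, 2 X, 3 Y
  std::vector<double> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  std::vector<uint8_t> bM((m + 1) * (n + 1), 0), bX((m + 1) * (n + 1), 0),
      bY((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  double lMM = std::log(tMM), lMX = tMX > 0 ? std::log(tMX) : NEG,
         lMY = tMY > 0 ? std::log(tMY) : NEG, lXX = gext > 0 ? std::log(tXX) : NEG,
         lYY = gext > 0 ? std::log(tYY) : NEG, lXM = std::log(tXM), lYM = std::log(tYM);
  for (int i = 1; i <= m; ++i) {
    double ei = e[i - 1];
    for (int j = 1; j <= n; ++j) {
      double em = emit_m(read[i - 1], win[j - 1], ei);
      double lem = em > 0 ? std::log(em) : NEG;
      double best; uint8_t bp;
      if (i == 1) { best = lMM; bp = 0; }
      else {
        best = lMM + M[at(i - 1, j - 1)]; bp = 1;
        double v = lXM + X[at(i - 1, j - 1)];
        if (v > best) { best = v; bp = 2; }
        v = lYM + Y[at(i - 1, j - 1)];
        if (v > best) { best = v; bp = 3; }
      }
      M[at(i, j)] = lem + best; bM[at(i, j)] = bp;
    }
    for (int j = 0; j <= n; ++j) {
      double best; uint8_t bp;
      if (i == 1) { best = lMX; bp = 0; }
      else {
        best = lMX + M[at(i - 1, j)]; bp = 1;
        double v = lXX + X[at(i - 1, j)];
        if (v > best) { best = v; bp = 2; }
      }
      X[at(i, j)] = std::log(0.25) + best; bX[at(i, j)] = bp;
    }
    for (int j = 1; j <= n; ++j) {
      double best = lMY + M[at(i, j - 1)]; uint8_t bp = 1;
      double v = lYY + Y[at(i, j - 1)];
      if (v > best) { best = v; bp = 3; }
      Y[at(i, j)] = best; bY[at(i, j)] = bp;
    }
  }
  // best end: M or X at row m (prefer M, then lower j, on exact ties)
  double best = NEG; int bj = -1; int bstate = 0;
  for (int j = 0; j <= n; ++j) {
    if (j >= 1 && M[at(m, j)] > best) { best = M[at(m, j)]; bj = j; bstate = 1; }
    if (X[at(m, j)] > best) { best = X[at(m, j)]; bj = j; bstate = 2; }
  }
  if (bj < 0 || best <= NEG / 2) return res;
  // traceback
  std::string moves;  // in reverse; 'M','I','D'
  int i = m, j = bj, st = bstate;
  int wend = j;
  while (i > 0) {
    if (st == 1) {
      moves.push_back('M');
      uint8_t bp = bM[at(i, j)];
      --i; --j;
      st = bp == 0 ? 0 : bp;
      if (bp == 0) break;
    } else if (st == 2) {
      moves.push_back('I');
      uint8_t bp = bX[at(i, j)];
      --i;
      st = bp == 0 ? 0 : bp;
      if (bp == 0) break;
    } else {  // Y
      moves.push_back('D');
      uint8_t bp = bY[at(i, j)];
      --j;
      st = bp;
    }
  }
  int wstart = j;
  std::reverse(moves.begin(), moves.end());
  // CIGAR run-length encode; per-cycle edit string
  std::string cigar, edit;
  int run = 0; char cur = 0;
  int ri = 0, wj = wstart;
  for (char mv : moves) {
    if (mv == cur) ++run;
    else {
      if (run) cigar += std::to_string(run) + cur;
      cur = mv; run = 1;
    }
    if (mv == 'M') {
      int rb = base_code(read[ri]), wb = base_code(win[wj]);
      edit.push_back((rb != 4 && rb == wb) ? '=' : 'X');
      ++ri; ++wj;
    } else if (mv == 'I') {
      edit.push_back('I');
      ++ri;
    } else {
      ++wj;
    }
  }
  if (run) cigar += std::to_string(run) + cur;
  res.score = best;
  res.wstart = wstart;
  res.glen = wend - wstart;
  res.cigar = cigar;
  res.edit = edit;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_viterbi(std::string read, std::string window, NumericVector esub,
                 double gap_open, double gap_extend) {
  if ((int)esub.size() < (int)read.size()) stop("error profile shorter than read");
  VitRes v = viterbi_aln(read, window, REAL(esub), gap_open, gap_extend);
  return List::create(_["score"] = v.score, _["wstart"] = v.wstart, _["glen"] = v.glen,
                      _["cigar"] = v.cigar, _["edit"] = v.edit, _["ok"] = v.ok);
}

static double logsumexp(const std::vector<double>& v) {
  double mx = R_NegInf;
  for (double x : v) if (x > mx) mx = x;
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

// Batch mapper: candidates + forward likelihood per candidate + Viterbi on
// the best candidate. Returns raw log-likelihoods; posterior/MAPQ policy is
// applied at the R level. Ties in likelihood (within 1e-9) resolve to the
// lowest (contig, window start, '+' strand) candidate.
// [[Rcpp::export]]
List cpp_map_batch(SEXP xp, CharacterVector reads, NumericVector esub,
                   double gap_open, double gap_extend, int band, int max_candidates) {
  XPtr<SeedIndex> idx(xp);
  int n = reads.size();
  LogicalVector mapped(n);
  CharacterVector contig(n, NA_STRING), strand(n, NA_STRING), cigar(n, NA_STRING),
      edit(n, NA_STRING);
  IntegerVector start(n, NA_INTEGER), end(n, NA_INTEGER), ncand(n, 0);
  NumericVector ll_best(n, NA_REAL), ll_others(n, NA_REAL);
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    if ((int)esub.size() < (int)read.size()) stop("error profile shorter than read");
    std::vector<Cand> cands = collect_candidates(*idx, read, band, max_candidates);
    if (cands.empty()) { mapped[r] = false; continue; }
    // deterministic scoring order: (contig, wstart, strand)
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.contig != b.contig) return a.contig < b.contig;
      if (a.wstart != b.wstart) return a.wstart < b.wstart;
      return a.strand < b.strand;
    });
    std::vector<double> lls(cands.size());
    std::vector<std::string> wins(cands.size());
    int best = -1; double bll = R_NegInf;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Cand& cd = cands[ci];
      std::string win = idx->seqs[cd.contig].substr(cd.wstart, cd.wend - cd.wstart);
      if (cd.strand == 1) win = revcomp(win);
      wins[ci] = win;
      lls[ci] = forward_ll(read, win, REAL(esub), gap_open, gap_extend);
      if (lls[ci] > bll + 1e-9) { bll = lls[ci]; best = (int)ci; }
    }
    if (best < 0 || !std::isfinite(bll)) { mapped[r] = false; continue; }
    std::vector<double> others;
    for (size_t ci = 0; ci < lls.size(); ++ci)
      if ((int)ci != best && std::isfinite(lls[ci])) others.push_back(lls[ci]);
    const Cand& cd = cands[best];
    VitRes v = viterbi_aln(read, wins[best], REAL(esub), gap_open, gap_extend);
    if (!v.ok) { mapped[r] = false; continue; }
    int astart, aend;
    if (cd.strand == 0) {
      astart = cd.wstart + v.wstart;
      aend = astart + v.glen;
    } else {
      aend = cd.wend - v.wstart;
      astart = aend - v.glen;
    }
    mapped[r] = true;
    contig[r] = idx->names[cd.contig];
    start[r] = astart;
    end[r] = aend;
    strand[r] = cd.strand == 0 ? "+" : "-";
    ll_best[r] = bll;
    ll_others[r] = others.empty() ? R_NegInf : logsumexp(others);
    ncand[r] = (int)cands.size();
    cigar[r] = v.cigar;
    edit[r] = v.edit;
  }
  return List::create(_["mapped"] = mapped, _["contig"] = contig, _["start"] = start,
                      _["end"] = end, _["strand"] = strand, _["ll_best"] = ll_best,
                      _["ll_others"] = ll_others, _["n_candidates"] = ncand,
                      _["cigar"] = cigar, _["edit"] = edit);
}

// Leftmost 3' adaptor occurrence: smallest i such that read[i..] matches a
// prefix of the adaptor with overlap >= min_overlap and mismatch rate
// <= max_rate. Returns the 0-based insert length, or -1 when no match.
// [[Rcpp::export]]
IntegerVector cpp_trim3(CharacterVector seqs, std::string adapter, int min_overlap,
                        double max_rate) {
  int n = seqs.size();
  int alen = (int)adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int len = (int)s.size();
    int found = -1;
    for (int i = 0; i + min_overlap <= len; ++i) {
      int ov = std::min(len - i, alen);
      int allowed = (int)std::floor(max_rate * ov + 1e-9);
      int mm = 0;
      bool okmatch = true;
      for (int j = 0; j < ov; ++j) {
        if (s[i + j] != adapter[j]) {
          if (++mm > allowed) { okmatch = false; break; }
        }
      }
      if (okmatch) { found = i; break; }
    }
    out[r] = found;
  }
  return out;
}
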