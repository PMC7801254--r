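#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; -1 for ambiguous bases
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char bitbase(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

// splitmix64 finalizer: well-mixed 64-bit hash
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Hashes are truncated to 53 bits so they survive the round trip through
// R doubles exactly.
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

// Enumerate canonical k-mers of a sequence, calling f(kmer) for each
// valid (ambiguity-free) window. kmer is the 2-bit packed canonical form
// (lexicographic min of forward and reverse complement).
template <typename F>
static void each_canonical_kmer(const char *s, int n, int k, F f) {
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < n; i++) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) f(std::min(fwd, rev), i - k + 1);
  }
}

// Bottom-s MinHash sketch over canonical k-mers (distinct hashes).
// Returns sorted ascending numeric vector of at most sketch_size hashes.
// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(CharacterVector contigs, int k,
                                int sketch_size, double seed) {
  uint64_t hseed = (uint64_t)seed;
  std::vector<uint64_t> hashes;
  for (R_xlen_t ci = 0; ci < contigs.size(); ci++) {
    const char *s = CHAR(STRING_ELT(contigs, ci));
    int n = (int)LENGTH(STRING_ELT(contigs, ci));
    each_canonical_kmer(s, n, k, [&](uint64_t kmer, int) {
      hashes.push_back(mix64(kmer ^ hseed) & HASH_MASK);
    });
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  if ((int)hashes.size() > sketch_size) hashes.resize(sketch_size);
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); i++) out[i] = (double)hashes[i];
  return out;
}

struct KPos { int contig; int pos; };

// Forward-strand k-mer index of a genome (positions per packed k-mer),
// capped at max_hits positions per k-mer.
static std::unordered_map<uint64_t, std::vector<KPos> >
index_kmers(CharacterVector contigs, int k, size_t max_hits) {
  std::unordered_map<uint64_t, std::vector<KPos> > idx;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (R_xlen_t ci = 0; ci < contigs.size(); ci++) {
    const char *s = CHAR(STRING_ELT(contigs, ci));
    int n = (int)LENGTH(STRING_ELT(contigs, ci));
    uint64_t fwd = 0; int valid = 0;
    for (int i = 0; i < n; i++) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        std::vector<KPos> &v = idx[fwd];
        if (v.size() < max_hits)
          v.push_back(KPos{(int)ci, i - k + 1});
      }
    }
  }
  return idx;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: break;
    }
  }
  return r;
}

// Fragment-based directional mapping of query onto target: the query is
// cut into non-overlapping fragments of fragment_len bp; each fragment is
// anchored to the target by shared k-mers (diagonal voting over both
// orientations) and scored by ungapped column comparison on the winning
// diagonal. Returns per-fragment identities and mapped lengths.
// [[Rcpp::export]]
List ani_fragments_cpp(CharacterVector query, CharacterVector target,
                       int fragment_len, int k, int min_anchors) {
  auto idx = index_kmers(target, k, 8);
  std::vector<std::string> tseq;
  for (R_xlen_t i = 0; i < target.size(); i++)
    tseq.push_back(as<std::string>(target[i]));

  std::vector<double> idents;
  long total_len = 0, mapped_len = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  for (R_xlen_t qi = 0; qi < query.size(); qi++) {
    std::string qc = as<std::string>(query[qi]);
    total_len += (long)qc.size();
    int nfrag = (int)qc.size() / fragment_len;
    for (int f = 0; f < nfrag; f++) {
      std::string frag = qc.substr((size_t)f * fragment_len, fragment_len);
      double best_ident = -1.0;
      int best_cols = 0;
      for (int ori = 0; ori < 2; ori++) {
        std::string fo = ori ? revcomp_str(frag) : frag;
        // vote on (target contig, diagonal)
        std::unordered_map<int64_t, int> votes;
        uint64_t fwd = 0; int valid = 0;
        for (int i = 0; i < (int)fo.size(); i++) {
          int b = base2bit(fo[i]);
          if (b < 0) { valid = 0; fwd = 0; continue; }
          fwd = ((fwd << 2) | (uint64_t)b) & mask;
          if (++valid >= k) {
            auto it = idx.find(fwd);
            if (it == idx.end()) continue;
            int qpos = i - k + 1;
            for (const KPos &kp : it->second) {
              int64_t key = ((int64_t)kp.contig << 32) |
                (uint32_t)(kp.pos - qpos + fragment_len);
              votes[key]++;
            }
          }
        }
        int best_votes = 0; int64_t best_key = 0;
        for (auto &kv : votes)
          if (kv.second > best_votes) { best_votes = kv.second; best_key = kv.first; }
        if (best_votes < min_anchors) continue;
        int tcontig = (int)(best_key >> 32);
        int diag = (int)(uint32_t)(best_key & 0xFFFFFFFF) - fragment_len;
        const std::string &tc = tseq[tcontig];
        // identity over the columns that actually lie on the target
        // contig, so fragments overhanging a contig end are scored on
        // their mapped portion only (minimum overlap 100 bp)
        int matches = 0, cols = 0;
        for (int i = 0; i < fragment_len; i++) {
          int tp = diag + i;
          if (tp < 0 || tp >= (int)tc.size()) continue;
          cols++;
          if (toupper(fo[i]) == toupper(tc[tp])) matches++;
        }
        if (cols < 100) continue;
        double ident = (double)matches / cols;
        if (ident > best_ident) { best_ident = ident; best_cols = cols; }
      }
      if (best_ident >= 0) {
        idents.push_back(best_ident);
        mapped_len += best_cols;
      }
    }
  }
  return List::create(_["identity"] = wrap(idents),
                      _["query_length"] = (double)total_len,
                      _["mapped_length"] = (double)mapped_len);
}

// ---------------------------------------------------------------------------
// Anchor-chain alignment of a member genome against a representative
// ---------------------------------------------------------------------------

struct Anchor { int rcontig; int rpos; int qpos; };  // 0-based starts

struct Sub { int rpos; char ref; char alt; int qpos; };  // 0-based

struct Block {
  int rcontig;
  int rstart, rend;        // 0-based inclusive, on representative
  int qstart, qend;        // 0-based inclusive, oriented member coords
  int strand;              // +1 / -1
  int ncols, nmatch;
  int n_indel1, n_indel_multi;
  std::vector<Sub> subs;
};

// Needleman-Wunsch on short gap sequences; appends substitution columns
// (with 0-based coordinates relative to rgap/qgap starts) and counts
// indel runs by length. match +1, mismatch -1, gap -2.
static void nw_gap(const std::string &rs, const std::string &qs,
                   int rpos0, int qpos0, int qdir, Block &blk) {
  int n = (int)rs.size(), m = (int)qs.size();
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; i++) S[i][0] = -2 * i;
  for (int j = 1; j <= m; j++) S[0][j] = -2 * j;
  for (int i = 1; i <= n; i++)
    for (int j = 1; j <= m; j++) {
      int d = S[i-1][j-1] + (toupper(rs[i-1]) == toupper(qs[j-1]) ? 1 : -1);
      int u = S[i-1][j] - 2, l = S[i][j-1] - 2;
      S[i][j] = std::max(d, std::max(u, l));
    }
  // traceback
  int i = n, j = m;
  std::vector<int> ops; // 0 diag, 1 up (gap in q), 2 left (gap in r)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i][j] == S[i-1][j-1] + (toupper(rs[i-1]) == toupper(qs[j-1]) ? 1 : -1)) {
      ops.push_back(0); i--; j--;
    } else if (i > 0 && S[i][j] == S[i-1][j] - 2) {
      ops.push_back(1); i--;
    } else {
      ops.push_back(2); j--;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int ri = 0, qj = 0, gaprun = 0;
  for (int op : ops) {
    if (op == 0) {
      if (gaprun) { (gaprun == 1 ? blk.n_indel1 : blk.n_indel_multi)++; gaprun = 0; }
      char rc = toupper(rs[ri]), qc = toupper(qs[qj]);
      blk.ncols++;
      if (rc == qc) blk.nmatch++;
      else blk.subs.push_back(Sub{rpos0 + ri, rc, qc, qpos0 + qdir * qj});
      ri++; qj++;
    } else {
      blk.ncols++;
      gaprun++;
      if (op == 1) ri++; else qj++;
    }
  }
  if (gaprun) (gaprun == 1 ? blk.n_indel1 : blk.n_indel_multi)++;
}

// Chain anchors (one rep contig, one member contig and orientation) into
// alignment blocks; close inter-anchor gaps by direct column comparison
// (equal gaps) or NW (unequal, small gaps). Anchors are greedily chained
// in member order; anchors incompatible with the current chain start new
// blocks on a later pass.
static void chain_to_blocks(std::vector<Anchor> &anchors, int k,
                            const std::string &rseq, const std::string &qseq,
                            int strand, int qlen_fwd, int max_gap,
                            std::vector<Block> &out) {
  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor &a, const Anchor &b) {
              return a.qpos != b.qpos ? a.qpos < b.qpos : a.rpos < b.rpos;
            });
  std::vector<bool> used(anchors.size(), false);
  for (size_t i0 = 0; i0 < anchors.size(); i0++) {
    if (used[i0]) continue;
    Block blk; blk.rcontig = anchors[i0].rcontig; blk.strand = strand;
    blk.ncols = blk.nmatch = blk.n_indel1 = blk.n_indel_multi = 0;
    blk.rstart = anchors[i0].rpos; blk.qstart = anchors[i0].qpos;
    // emit the seed anchor
    blk.ncols = k; blk.nmatch = k;
    int rcur = anchors[i0].rpos + k, qcur = anchors[i0].qpos + k;
    used[i0] = true;
    for (size_t i = i0 + 1; i < anchors.size(); i++) {
      if (used[i]) continue;
      const Anchor &a = anchors[i];
      int qgap = a.qpos - qcur, rgap = a.rpos - rcur;
      if (qgap < 0 || rgap < 0) {
        // overlapping the frontier: extend only if on the frontier diagonal
        if (qgap == rgap && a.qpos + k > qcur) {
          int ext = a.qpos + k - qcur;  // new exact columns
          blk.ncols += ext; blk.nmatch += ext;
          qcur += ext; rcur += ext;
          used[i] = true;
        }
        continue;
      }
      if (qgap > max_gap || rgap > max_gap) break;
      if (std::abs(qgap - rgap) > 100) break;
      if (qgap == rgap) {
        for (int g = 0; g < qgap; g++) {
          char rc = toupper(rseq[rcur + g]), qc = toupper(qseq[qcur + g]);
          blk.ncols++;
          if (rc == qc) blk.nmatch++;
          else blk.subs.push_back(Sub{rcur + g, rc, qc, qcur + g});
        }
      } else {
        nw_gap(rseq.substr(rcur, rgap), qseq.substr(qcur, qgap),
               rcur, qcur, 1, blk);
      }
      blk.ncols += k; blk.nmatch += k;  // the anchor itself
      rcur = a.rpos + k; qcur = a.qpos + k;
      used[i] = true;
    }
    blk.rend = rcur - 1; blk.qend = qcur - 1;
    // ungapped X-drop extension into the unanchored tails (match +1,
    // mismatch -2, stop when score drops 12 below the running best)
    {
      const int XDROP = 12;
      int score = 0, best = 0, best_i = 0, last_i = 0;
      bool dropped = false;
      std::vector<Sub> pend;
      std::vector<Sub> add;
      // right end
      for (int i = 1; blk.rend + i < (int)rseq.size() &&
                      blk.qend + i < (int)qseq.size(); i++) {
        char rc2 = toupper(rseq[blk.rend + i]), qc2 = toupper(qseq[blk.qend + i]);
        if (rc2 == qc2) score += 1;
        else { score -= 2; pend.push_back(Sub{blk.rend + i, rc2, qc2,
                                              blk.qend + i}); }
        last_i = i;
        if (score > best) {
          best = score; best_i = i;
          for (Sub &s : pend) add.push_back(s);
          pend.clear();
        }
        if (score < best - XDROP) { dropped = true; break; }
      }
      // reached a sequence boundary without the score collapsing:
      // commit the whole homologous tail, trailing mismatches included
      if (!dropped && last_i > best_i) {
        best_i = last_i;
        for (Sub &s : pend) add.push_back(s);
        pend.clear();
      }
      if (best_i > 0) {
        for (Sub &s : add) blk.subs.push_back(s);
        blk.ncols += best_i; blk.nmatch += best_i - (int)add.size();
        blk.rend += best_i; blk.qend += best_i;
      }
      // left end
      score = 0; best = 0; best_i = 0; last_i = 0; dropped = false;
      pend.clear(); add.clear();
      for (int i = 1; blk.rstart - i >= 0 && blk.qstart - i >= 0; i++) {
        char rc2 = toupper(rseq[blk.rstart - i]), qc2 = toupper(qseq[blk.qstart - i]);
        if (rc2 == qc2) score += 1;
        else { score -= 2; pend.push_back(Sub{blk.rstart - i, rc2, qc2,
                                              blk.qstart - i}); }
        last_i = i;
        if (score > best) {
          best = score; best_i = i;
          for (Sub &s : pend) add.push_back(s);
          pend.clear();
        }
        if (score < best - XDROP) { dropped = true; break; }
      }
      if (!dropped && last_i > best_i) {
        best_i = last_i;
        for (Sub &s : pend) add.push_back(s);
        pend.clear();
      }
      if (best_i > 0) {
        for (Sub &s : add) blk.subs.push_back(s);
        blk.ncols += best_i; blk.nmatch += best_i - (int)add.size();
        blk.rstart -= best_i; blk.qstart -= best_i;
      }
    }
    // convert oriented member coords to forward-strand coords
    if (strand < 0) {
      int qs = qlen_fwd - 1 - blk.qend, qe = qlen_fwd - 1 - blk.qstart;
      blk.qstart = qs; blk.qend = qe;
      for (Sub &s : blk.subs) s.qpos = qlen_fwd - 1 - s.qpos;
    }
    out.push_back(blk);
  }
}

// Align member contigs to representative contigs by unique k-mer anchors
// chained collinearly; returns one list element per alignment block.
// [[Rcpp::export]]
List anchor_align_cpp(CharacterVector member, CharacterVector rep,
                      int k, int max_gap) {
  // index unique rep k-mers (forward strand)
  std::unordered_map<uint64_t, KPos> uniq;
  std::unordered_map<uint64_t, int> counts;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::vector<std::string> rseqs;
  for (R_xlen_t ci = 0; ci < rep.size(); ci++)
    rseqs.push_back(as<std::string>(rep[ci]));
  for (R_xlen_t ci = 0; ci < rep.size(); ci++) {
    const std::string &s = rseqs[ci];
    uint64_t fwd = 0; int valid = 0;
    for (int i = 0; i < (int)s.size(); i++) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        counts[fwd]++;
        if (counts[fwd] == 1) uniq[fwd] = KPos{(int)ci, i - k + 1};
      }
    }
  }
  for (auto it = uniq.begin(); it != uniq.end();)
    it = (counts[it->first] > 1) ? uniq.erase(it) : std::next(it);

  List blocks;
  for (R_xlen_t qi = 0; qi < member.size(); qi++) {
    std::string qfwd = as<std::string>(member[qi]);
    int qlen = (int)qfwd.size();
    for (int strand = +1; strand >= -1; strand -= 2) {
      std::string qseq = strand > 0 ? qfwd : revcomp_str(qfwd);
      // collect anchors per rep contig
      std::unordered_map<int, std::vector<Anchor> > per_rc;
      uint64_t fwd = 0; int valid = 0;
      for (int i = 0; i < (int)qseq.size(); i++) {
        int b = base2bit(qseq[i]);
        if (b < 0) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          auto it = uniq.find(fwd);
          if (it != uniq.end())
            per_rc[it->second.contig].push_back(
              Anchor{it->second.contig, it->second.pos, i - k + 1});
        }
      }
      for (auto &kv : per_rc) {
        std::vector<Block> got;
        chain_to_blocks(kv.second, k, rseqs[kv.first], qseq, strand,
                        qlen, max_gap, got);
        for (Block &b : got) {
          int ns = (int)b.subs.size();
          IntegerVector rpos(ns), qpos(ns);
          CharacterVector ref(ns), alt(ns);
          for (int s = 0; s < ns; s++) {
            rpos[s] = b.subs[s].rpos + 1;  // 1-based
            qpos[s] = b.subs[s].qpos + 1;
            ref[s] = std::string(1, b.subs[s].ref);
            alt[s] = std::string(1, b.subs[s].alt);
          }
          blocks.push_back(List::create(
            _["rep_contig"] = b.rcontig + 1,
            _["member_contig"] = (int)qi + 1,
            _["rep_start"] = b.rstart + 1, _["rep_end"] = b.rend + 1,
            _["member_start"] = b.qstart + 1, _["member_end"] = b.qend + 1,
            _["strand"] = b.strand,
            _["n_cols"] = b.ncols, _["n_match"] = b.nmatch,
            _["n_indel1"] = b.n_indel1, _["n_indel_multi"] = b.n_indel_multi,
            _["sub_rep_pos"] = rpos, _["sub_member_pos"] = qpos,
            _["sub_ref"] = ref, _["sub_alt"] = alt));
        }
      }
    }
  }
  return blocks;
}
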