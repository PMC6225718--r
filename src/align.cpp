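// Seed-and-extend alignment core shared by the read aligner, the
// transcript-to-genome mapper and the RBH scorer, plus the SAM-free
// pileup engine.  Sequences are plain uppercase A/C/G/T/N strings.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else: never indexed, always a mismatch
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = complement(c);
  return r;
}

// k-mer index over a set of sequences: kmer -> (seq id, offset) list.
// k <= 31; k-mers containing non-ACGT are skipped.
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > map;

  void build(const std::vector<std::string> &seqs, int k_, int step = 1) {
    k = k_;
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    for (size_t s = 0; s < seqs.size(); ++s) {
      const std::string &seq = seqs[s];
      if ((int)seq.size() < k) continue;
      uint64_t key = 0;
      int run = 0; // valid bases accumulated
      for (size_t i = 0; i < seq.size(); ++i) {
        int b = base2bit(seq[i]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          int32_t off = (int32_t)(i + 1 - k);
          if (off % step == 0)
            map[key].push_back(std::make_pair((int32_t)s, off));
        }
      }
    }
  }

  const std::vector<std::pair<int32_t, int32_t> > *lookup(const std::string &seq,
                                                          int off) const {
    uint64_t key = 0;
    for (int i = 0; i < k; ++i) {
      int b = base2bit(seq[off + i]);
      if (b < 0) return nullptr;
      key = (key << 2) | (uint64_t)b;
    }
    auto it = map.find(key);
    if (it == map.end()) return nullptr;
    return &it->second;
  }
};

// ---------------------------------------------------------------------------
// Read aligner
// ---------------------------------------------------------------------------

struct Placement {
  bool   valid = false;
  int    sid = -1;       // reference sequence index
  int    pos = -1;       // 0-based leftmost reference position
  int    mm = 0;         // substitution mismatches
  int    indel_len = 0;  // 0 = ungapped; >0 deletion; <0 insertion
  int    split = 0;      // read bases aligned before the indel
  char   strand = '+';
  int    cost = 1 << 30; // mm + penalty if gapped
};

// order for deterministic tie-breaking: ungapped first, then '+' strand,
// then smaller reference id, then smaller position
static inline bool placement_before(const Placement &a, const Placement &b) {
  bool ag = a.indel_len != 0, bg = b.indel_len != 0;
  if (ag != bg) return !ag;
  if (a.strand != b.strand) return a.strand == '+';
  if (a.sid != b.sid) return a.sid < b.sid;
  return a.pos < b.pos;
}

static int count_mm(const std::string &read, const std::string &ref,
                    int diag, int from, int to, int tshift, int abort_at) {
  int mm = 0;
  for (int i = from; i < to; ++i) {
    if (read[i] != ref[diag + tshift + i]) {
      if (++mm > abort_at) return mm;
    }
  }
  return mm;
}

// one-indel alignment: read prefix [0,j) on diagonal d, suffix on d+s
// (s > 0: deletion of s reference bases; s < 0: insertion of -s read bases)
static bool try_one_indel(const std::string &read, const std::string &ref,
                          int d, int s, int best_cost, int penalty,
                          Placement &out) {
  int len = (int)read.size(), tlen = (int)ref.size();
  int ins = s < 0 ? -s : 0;
  if (d < 0 || d + len + (s > 0 ? s : -ins) > tlen || d + s < 0) return false;
  std::vector<int> pm(len + 1), rc(len + 1);
  pm[0] = 0;
  for (int i = 0; i < len; ++i)
    pm[i + 1] = pm[i] + (read[i] != ref[d + i] ? 1 : 0);
  rc[len] = 0;
  for (int i = len - 1; i >= 0; --i) {
    int t = d + s + i;
    rc[i] = rc[i + 1] + ((t < 0 || t >= tlen || read[i] != ref[t]) ? 1 : 0);
  }
  int best_mm = 1 << 30, best_j = -1;
  int jmax = s > 0 ? len - 1 : len - ins - 1;
  for (int j = 1; j <= jmax; ++j) {
    int mm = pm[j] + (s > 0 ? rc[j] : rc[j + ins]);
    if (mm < best_mm) { best_mm = mm; best_j = j; }
  }
  if (best_j < 0) return false;
  int cost = best_mm + penalty;
  if (cost >= best_cost + 2) return false; // hopeless, skip bookkeeping
  out.valid = true;
  out.sid = -1; // caller fills
  out.pos = d;
  out.mm = best_mm;
  out.indel_len = s;
  out.split = best_j;
  out.cost = cost;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector ref_seqs, CharacterVector reads,
                          int k, double max_mm_frac, int max_indel,
                          int indel_penalty, bool try_revcomp) {
  int nref = ref_seqs.size(), nread = reads.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  KmerIndex idx;
  idx.build(refs, k);

  IntegerVector out_ref(nread, NA_INTEGER), out_pos(nread, NA_INTEGER),
      out_nm(nread, NA_INTEGER);
  CharacterVector out_cigar(nread, NA_STRING), out_strand(nread, NA_STRING);
  LogicalVector out_mapped(nread), out_amb(nread);

  for (int r = 0; r < nread; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    Placement best, second;
    if (len < k) { out_mapped[r] = false; continue; }
    int abort_mm = (int)(max_mm_frac * len) + indel_penalty + 2;

    for (int ori = 0; ori < (try_revcomp ? 2 : 1); ++ori) {
      std::string seq = ori == 0 ? fwd : revcomp(fwd);
      char strand = ori == 0 ? '+' : '-';
      // gather candidate (sid, diag) votes from seeds
      std::unordered_map<int64_t, int> votes;
      int step = std::max(1, (len - k) / 8);
      for (int off = 0; off <= len - k; off += step) {
        const auto *hits = idx.lookup(seq, off);
        if (!hits) continue;
        if (hits->size() > 64) continue; // repetitive seed
        for (const auto &h : *hits) {
          int diag = h.second - off;
          votes[((int64_t)h.first << 32) | (uint32_t)(diag + len)]++;
        }
      }
      if (votes.empty()) continue;
      std::vector<std::pair<int, int64_t> > cand;
      cand.reserve(votes.size());
      for (const auto &kv : votes) cand.push_back({kv.second, kv.first});
      std::sort(cand.begin(), cand.end(),
                [](const std::pair<int, int64_t> &a,
                   const std::pair<int, int64_t> &b) {
                  if (a.first != b.first) return a.first > b.first;
                  return a.second < b.second;
                });
      size_t ncand = std::min(cand.size(), (size_t)16);

      auto consider = [&](Placement p) {
        if (!p.valid) return;
        if (p.cost < best.cost ||
            (p.cost == best.cost && best.valid && placement_before(p, best) &&
             !(p.sid == best.sid && p.pos == best.pos &&
               p.indel_len == best.indel_len && p.strand == best.strand))) {
          if (best.valid &&
              !(p.sid == best.sid && p.pos == best.pos &&
                p.indel_len == best.indel_len && p.strand == best.strand))
            second = best;
          best = p;
        } else if (best.valid &&
                   !(p.sid == best.sid && p.pos == best.pos &&
                     p.indel_len == best.indel_len && p.strand == best.strand) &&
                   p.cost < second.cost) {
          second = p;
        }
      };

      for (size_t c = 0; c < ncand; ++c) {
        int sid = (int)(cand[c].second >> 32);
        int diag = (int)(uint32_t)(cand[c].second & 0xffffffff) - len;
        const std::string &ref = refs[sid];
        if (diag >= 0 && diag + len <= (int)ref.size()) {
          int mm = count_mm(seq, ref, diag, 0, len, 0, abort_mm);
          Placement p;
          p.valid = true; p.sid = sid; p.pos = diag; p.mm = mm;
          p.strand = strand; p.cost = mm;
          consider(p);
        }
        // gapped: only worth trying if ungapped best can still be beaten
        if (best.cost > indel_penalty) {
          for (int s = 1; s <= max_indel; ++s) {
            for (int sg = -1; sg <= 1; sg += 2) {
              int ss = s * sg;
              for (int which = 0; which < 2; ++which) {
                int dpre = which == 0 ? diag : diag - ss;
                Placement p;
                if (try_one_indel(seq, refs[sid], dpre, ss, best.cost,
                                  indel_penalty, p)) {
                  p.sid = sid; p.strand = strand;
                  consider(p);
                }
              }
            }
          }
        }
      }
    }

    if (!best.valid || best.mm > max_mm_frac * len) {
      out_mapped[r] = false;
      continue;
    }
    out_mapped[r] = true;
    out_amb[r] = second.valid && second.cost == best.cost;
    out_ref[r] = best.sid + 1;
    out_pos[r] = best.pos + 1;
    out_nm[r] = best.mm + std::abs(best.indel_len);
    out_strand[r] = best.strand == '+' ? "+" : "-";
    std::string cig;
    if (best.indel_len == 0) {
      cig = std::to_string(len) + "M";
    } else if (best.indel_len > 0) {
      cig = std::to_string(best.split) + "M" +
            std::to_string(best.indel_len) + "D" +
            std::to_string(len - best.split) + "M";
    } else {
      int ins = -best.indel_len;
      cig = std::to_string(best.split) + "M" + std::to_string(ins) + "I" +
            std::to_string(len - best.split - ins) + "M";
    }
    out_cigar[r] = cig;
  }

  return DataFrame::create(
      _["ref"] = out_ref, _["pos"] = out_pos, _["strand"] = out_strand,
      _["cigar"] = out_cigar, _["nm"] = out_nm, _["mapped"] = out_mapped,
      _["ambiguous"] = out_amb, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Pileup engine
// ---------------------------------------------------------------------------

static inline int base_row(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

// left-normalize a deletion of ref[t0, t0+dlen) -> smallest equivalent t0
static int normalize_del(const std::string &ref, int t0, int dlen, int lo) {
  while (t0 > lo && ref[t0 - 1] == ref[t0 + dlen - 1]) --t0;
  return t0;
}

// left-normalize an insertion of `ins` before ref position t0
static void normalize_ins(const std::string &ref, int &t0, std::string &ins,
                          int lo) {
  while (t0 > lo && ref[t0 - 1] == ins.back()) {
    ins = ins.back() + ins.substr(0, ins.size() - 1);
    --t0;
  }
}

// [[Rcpp::export]]
List cpp_pileup(CharacterVector ref_seqs, IntegerVector aln_ref,
                IntegerVector aln_pos, CharacterVector aln_cigar,
                CharacterVector aln_seq, CharacterVector aln_strand) {
  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  std::vector<IntegerMatrix> counts;
  counts.reserve(nref);
  for (int i = 0; i < nref; ++i)
    counts.push_back(IntegerMatrix(5, (int)refs[i].size()));
  // (refid, pos, allele-string) -> count; pos is the 0-based anchor base
  std::vector<std::map<std::pair<int, std::string>, int> > insmap(nref),
      delmap(nref);

  int n = aln_ref.size();
  for (int a = 0; a < n; ++a) {
    if (IntegerVector::is_na(aln_ref[a])) continue;
    int sid = aln_ref[a] - 1;
    if (sid < 0 || sid >= nref) stop("alignment references unknown sequence");
    const std::string &ref = refs[sid];
    std::string seq = as<std::string>(aln_seq[a]);
    if (as<std::string>(aln_strand[a]) == "-") seq = revcomp(seq);
    const std::string cigar = as<std::string>(aln_cigar[a]);
    int tpos = aln_pos[a] - 1; // 0-based
    size_t qpos = 0, ci = 0;
    IntegerMatrix &cm = counts[sid];
    while (ci < cigar.size()) {
      size_t j = ci;
      int num = 0;
      while (j < cigar.size() && cigar[j] >= '0' && cigar[j] <= '9') {
        num = num * 10 + (cigar[j] - '0');
        ++j;
      }
      if (j == ci || j == cigar.size())
        stop("malformed CIGAR '%s'", cigar.c_str());
      char op = cigar[j];
      ci = j + 1;
      if (op == 'M' || op == '=' || op == 'X') {
        for (int x = 0; x < num; ++x) {
          if (tpos + x >= (int)ref.size() || qpos + x >= seq.size())
            stop("alignment runs off sequence end (CIGAR '%s')", cigar.c_str());
          cm(base_row(seq[qpos + x]), tpos + x)++;
        }
        tpos += num; qpos += num;
      } else if (op == 'I') {
        std::string ins = seq.substr(qpos, num);
        int t0 = tpos;
        normalize_ins(ref, t0, ins, 1); // anchor at >= base 2 (t0-1 exists)
        insmap[sid][{t0 - 1, ins}]++;
        qpos += num;
      } else if (op == 'D') {
        int t0 = normalize_del(ref, tpos, num, 1);
        delmap[sid][{t0 - 1, ref.substr(t0, num)}]++;
        tpos += num;
      } else if (op == 'S') {
        qpos += num;
      } else if (op == 'H') {
        // consumes nothing
      } else {
        stop("unsupported CIGAR op '%c'", op);
      }
    }
  }

  List out(nref);
  for (int i = 0; i < nref; ++i) {
    int ni = (int)insmap[i].size(), nd = (int)delmap[i].size();
    IntegerVector ipos(ni), icnt(ni), dpos(nd), dcnt(nd);
    CharacterVector iseq(ni), dseq(nd);
    int x = 0;
    for (const auto &kv : insmap[i]) {
      ipos[x] = kv.first.first + 1; // 1-based anchor
      iseq[x] = kv.first.second;
      icnt[x] = kv.second; ++x;
    }
    x = 0;
    for (const auto &kv : delmap[i]) {
      dpos[x] = kv.first.first + 1;
      dseq[x] = kv.first.second;
      dcnt[x] = kv.second; ++x;
    }
    out[i] = List::create(
        _["counts"] = counts[i],
        _["ins"] = DataFrame::create(_["pos"] = ipos, _["seq"] = iseq,
                                     _["count"] = icnt,
                                     _["stringsAsFactors"] = false),
        _["del"] = DataFrame::create(_["pos"] = dpos, _["seq"] = dseq,
                                     _["count"] = dcnt,
                                     _["stringsAsFactors"] = false));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Chained mapper (transcript -> genome, transcript -> transcript)
// ---------------------------------------------------------------------------

struct ChainResult {
  bool valid = false;
  int target = -1;
  char strand = '+';
  std::vector<std::array<int, 4> > blocks; // qstart,qend,tstart,tend (0-based, oriented query)
  int matches = 0, mismatches = 0, gapq = 0, gapt = 0;
  double score = -1e18;
};

static ChainResult chain_one(const std::string &q, const std::string &t,
                             const std::vector<std::pair<int, int> > &hits_in,
                             int k, int max_gap) {
  ChainResult res;
  if (hits_in.empty()) return res;
  // modal diagonal, then keep hits within a window around it
  std::unordered_map<int, int> dcount;
  for (const auto &h : hits_in) dcount[h.second - h.first]++;
  int modal = 0, mc = -1;
  for (const auto &kv : dcount)
    if (kv.second > mc || (kv.second == mc && kv.first < modal)) {
      modal = kv.first; mc = kv.second;
    }
  std::vector<std::pair<int, int> > hits;
  for (const auto &h : hits_in)
    if (std::abs((h.second - h.first) - modal) <= 200) hits.push_back(h);
  std::sort(hits.begin(), hits.end());
  // greedy colinear chain
  std::vector<std::pair<int, int> > chain;
  int lq = -1, lt = -1, ldiag = 0;
  for (const auto &h : hits) {
    int diag = h.second - h.first;
    if (chain.empty()) {
      chain.push_back(h); lq = h.first; lt = h.second; ldiag = diag;
    } else if (h.first > lq && h.second > lt &&
               std::abs(diag - ldiag) <= max_gap) {
      chain.push_back(h); lq = h.first; lt = h.second; ldiag = diag;
    }
  }
  if (chain.empty()) return res;
  // merge chained anchors into blocks (one block per diagonal run)
  struct Blk { int q1, q2, t1, t2; };
  std::vector<Blk> blocks;
  for (const auto &h : chain) {
    int q1 = h.first, t1 = h.second, q2 = q1 + k - 1, t2 = t1 + k - 1;
    if (!blocks.empty() && (t1 - q1) == (blocks.back().t1 - blocks.back().q1) &&
        q1 > blocks.back().q1) {
      blocks.back().q2 = std::max(blocks.back().q2, q2);
      blocks.back().t2 = std::max(blocks.back().t2, t2);
    } else if (!blocks.empty() && q1 <= blocks.back().q2) {
      // diagonal change overlapping the previous block: trim the new one
      int delta = blocks.back().q2 + 1 - q1;
      q1 += delta; t1 += delta;
      if (q1 > q2 || t1 > t2 || t1 <= blocks.back().t2) continue;
      blocks.push_back({q1, q2, t1, t2});
    } else if (!blocks.empty() && t1 <= blocks.back().t2) {
      int delta = blocks.back().t2 + 1 - t1;
      q1 += delta; t1 += delta;
      if (q1 > q2 || t1 > t2 || q1 <= blocks.back().q2) continue;
      blocks.push_back({q1, q2, t1, t2});
    } else {
      blocks.push_back({q1, q2, t1, t2});
    }
  }
  // extend outer ends while bases match
  while (blocks.front().q1 > 0 && blocks.front().t1 > 0 &&
         q[blocks.front().q1 - 1] == t[blocks.front().t1 - 1] &&
         base2bit(q[blocks.front().q1 - 1]) >= 0) {
    blocks.front().q1--; blocks.front().t1--;
  }
  while (blocks.back().q2 + 1 < (int)q.size() &&
         blocks.back().t2 + 1 < (int)t.size() &&
         q[blocks.back().q2 + 1] == t[blocks.back().t2 + 1] &&
         base2bit(q[blocks.back().q2 + 1]) >= 0) {
    blocks.back().q2++; blocks.back().t2++;
  }
  int match = 0, mism = 0, gq = 0, gt = 0;
  for (size_t b = 0; b < blocks.size(); ++b) {
    for (int i = blocks[b].q1, j = blocks[b].t1; i <= blocks[b].q2; ++i, ++j) {
      if (q[i] == t[j] && base2bit(q[i]) >= 0) ++match; else ++mism;
    }
    if (b > 0) {
      gq += blocks[b].q1 - blocks[b - 1].q2 - 1;
      gt += blocks[b].t1 - blocks[b - 1].t2 - 1;
    }
  }
  res.valid = true;
  res.matches = match; res.mismatches = mism; res.gapq = gq; res.gapt = gt;
  res.score = (double)match - (double)mism - 2.0 * (gq + gt);
  res.blocks.reserve(blocks.size());
  for (const auto &b : blocks)
    res.blocks.push_back({b.q1, b.q2, b.t1, b.t2});
  return res;
}

// Best (and second-best-target) chained local alignment of each query
// against a set of targets, both strands.
// [[Rcpp::export]]
List cpp_map_seqs(CharacterVector query_seqs, CharacterVector target_seqs,
                  int k, int max_gap) {
  int nq = query_seqs.size(), nt = target_seqs.size();
  std::vector<std::string> qs(nq), ts(nt);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(query_seqs[i]);
  for (int i = 0; i < nt; ++i) ts[i] = as<std::string>(target_seqs[i]);
  KmerIndex idx;
  idx.build(ts, k);

  List out(nq);
  for (int q = 0; q < nq; ++q) {
    ChainResult best, second; // second restricted to a different target
    int best_target = -1;
    for (int ori = 0; ori < 2; ++ori) {
      std::string seq = ori == 0 ? qs[q] : revcomp(qs[q]);
      if ((int)seq.size() < k) continue;
      std::unordered_map<int, std::vector<std::pair<int, int> > > per_target;
      for (int off = 0; off + k <= (int)seq.size(); ++off) {
        const auto *hits = idx.lookup(seq, off);
        if (!hits) continue;
        if (hits->size() > 256) continue;
        for (const auto &h : *hits)
          per_target[h.first].push_back({off, h.second});
      }
      for (auto &kv : per_target) {
        ChainResult cr = chain_one(seq, ts[kv.first], kv.second, k, max_gap);
        if (!cr.valid) continue;
        cr.target = kv.first;
        cr.strand = ori == 0 ? '+' : '-';
        if (cr.score > best.score ||
            (cr.score == best.score &&
             (cr.target < best.target ||
              (cr.target == best.target && cr.strand == '+')))) {
          if (best.valid && best.target != cr.target &&
              best.score > second.score)
            second = best;
          best = cr;
          best_target = cr.target;
        } else if (cr.target != best_target && cr.score > second.score) {
          second = cr;
        }
      }
    }
    if (!best.valid) {
      out[q] = R_NilValue;
      continue;
    }
    int qlen = (int)qs[q].size();
    int nb = (int)best.blocks.size();
    IntegerMatrix bm(nb, 4);
    for (int b = 0; b < nb; ++b) {
      int q1 = best.blocks[b][0], q2 = best.blocks[b][1];
      if (best.strand == '-') { // convert to original query coordinates
        int nq1 = qlen - 1 - q2, nq2 = qlen - 1 - q1;
        q1 = nq1; q2 = nq2;
      }
      bm(b, 0) = q1 + 1; bm(b, 1) = q2 + 1;
      bm(b, 2) = best.blocks[b][2] + 1; bm(b, 3) = best.blocks[b][3] + 1;
    }
    int aligned = best.matches + best.mismatches;
    out[q] = List::create(
        _["target"] = best.target + 1,
        _["strand"] = std::string(1, best.strand),
        _["blocks"] = bm, _["matches"] = best.matches,
        _["mismatches"] = best.mismatches,
        _["gap_bases"] = best.gapq + best.gapt, _["score"] = best.score,
        _["coverage"] = (double)aligned / qlen,
        _["identity"] =
            aligned > 0 ? (double)best.matches / aligned : 0.0,
        _["second_score"] = second.valid ? second.score : NA_REAL,
        _["second_target"] = second.valid ? second.target + 1 : NA_INTEGER);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small utilities
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  out.names() = seqs.names();
  return out;
}

// Sprinkle substitution errors at a per-base rate; draws come from R's RNG
// so set.seed() upstream fixes the result.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector reads, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    for (auto &c : s) {
      if (unif_rand() < rate) {
        char nb;
        do {
          nb = bases[(int)(unif_rand() * 4) & 3];
        } while (nb == c);
        c = nb;
      }
    }
    out[i] = s;
  }
  return out;
}
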