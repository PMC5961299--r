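// Seed-and-extend local alignment of short, highly conserved queries
// against a genome: k-mer seeding with optional over-occurrence masking,
// diagonal clustering of seed hits, and banded affine-gap Smith-Waterman
// extension (or gapless extension in fast mode).

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N or other IUPAC ambiguity
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

struct SeedIndex {
  int k;
  int step;
  double occ;  // occurrence threshold; R_PosInf disables masking
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // k-mer code -> slice (start, n) of the sid/pos arrays
  std::unordered_map<uint64_t, std::pair<uint32_t, uint32_t>> dir;
  std::vector<int32_t> sid;
  std::vector<int32_t> pos;
};

// [[Rcpp::export]]
SEXP sa_build_index(CharacterVector names, CharacterVector seqs, int k,
                    int step, double occ_threshold) {
  if (k < 4 || k > 16) stop("seed length k must be between 4 and 16");
  if (step < 1) stop("sampling step must be >= 1");
  if (seqs.size() == 0) stop("genome is empty");

  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  idx->step = step;
  idx->occ = occ_threshold;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
  }

  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const bool use_occ = R_finite(occ_threshold);
  std::unordered_map<uint64_t, uint32_t> cnt;  // genome-wide count at step 1
  std::vector<uint64_t> scode;
  std::vector<int32_t> ssid, spos;

  for (size_t s = 0; s < idx->seqs.size(); ++s) {
    const std::string &S = idx->seqs[s];
    uint64_t code = 0;
    int run = 0;  // length of current N-free run
    for (size_t i = 0; i < S.size(); ++i) {
      int b = base_code(S[i]);
      if (b > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        int32_t p = (int32_t)(i + 1 - k);
        if (use_occ) cnt[code]++;
        if (p % step == 0) {
          scode.push_back(code);
          ssid.push_back((int32_t)s);
          spos.push_back(p);
        }
      }
    }
  }

  std::vector<size_t> keep;
  keep.reserve(scode.size());
  for (size_t i = 0; i < scode.size(); ++i) {
    if (!use_occ || cnt[scode[i]] <= (uint32_t)occ_threshold) keep.push_back(i);
  }
  std::sort(keep.begin(), keep.end(), [&](size_t a, size_t b) {
    if (scode[a] != scode[b]) return scode[a] < scode[b];
    if (ssid[a] != ssid[b]) return ssid[a] < ssid[b];
    return spos[a] < spos[b];
  });
  idx->sid.reserve(keep.size());
  idx->pos.reserve(keep.size());
  for (size_t j = 0; j < keep.size(); ++j) {
    uint64_t c = scode[keep[j]];
    auto it = idx->dir.find(c);
    if (it == idx->dir.end()) {
      idx->dir[c] = std::make_pair((uint32_t)idx->sid.size(), 1u);
    } else {
      it->second.second++;
    }
    idx->sid.push_back(ssid[keep[j]]);
    idx->pos.push_back(spos[keep[j]]);
  }

  XPtr<SeedIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
List sa_index_info(SEXP xp_) {
  XPtr<SeedIndex> xp(xp_);
  return List::create(_["k"] = xp->k, _["step"] = xp->step,
                      _["occ_threshold"] = xp->occ,
                      _["n_kmers"] = (double)xp->dir.size(),
                      _["n_positions"] = (double)xp->pos.size(),
                      _["seq_names"] = wrap(xp->names));
}

// [[Rcpp::export]]
List sa_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<SeedIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("k-mer length does not match index k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b > 3) return List::create(_["sid"] = IntegerVector(0),
                                   _["offset"] = IntegerVector(0));
    code = (code << 2) | (uint64_t)b;
  }
  auto it = xp->dir.find(code);
  if (it == xp->dir.end())
    return List::create(_["sid"] = IntegerVector(0),
                        _["offset"] = IntegerVector(0));
  uint32_t a = it->second.first, n = it->second.second;
  IntegerVector sid(n), off(n);
  for (uint32_t i = 0; i < n; ++i) {
    sid[i] = xp->sid[a + i] + 1;  // 1-based sequence index for R
    off[i] = xp->pos[a + i];
  }
  return List::create(_["sid"] = sid, _["offset"] = off);
}

struct Hit {
  int32_t sid, diag, tpos, qpos;
};

struct AlnRec {
  int matches = 0, mism = 0, ncount = 0;
  int qnum = 0, qbase = 0, tnum = 0, tbase = 0;
  char strand = '+';
  int sid = 0;
  int tstart = 0, tend = 0;
  int qstart = 0, qend = 0;  // on the aligned (strand-adjusted) query
  std::vector<int> bsize, bq, bt;
  long score = 0;
};

static inline int pair_score(char qc, char tc, int match, int mismatch) {
  int a = base_code(qc), b = base_code(tc);
  if (a > 3 || b > 3) return 0;  // N pairs are neutral
  return (a == b) ? match : -mismatch;
}

// Best-scoring gapless segment on diagonal d (Kadane).  Returns score;
// fills [q0, q1) query range of the best segment.
static long kadane_diag(const std::string &Q, const std::string &T, int d,
                        int match, int mismatch, int *q0, int *q1) {
  int qlen = (int)Q.size(), tlen = (int)T.size();
  int lo = std::max(0, -d);
  int hi = std::min(qlen, tlen - d);
  long best = LONG_MIN, cur = 0;
  int cur_start = lo, b0 = lo, b1 = lo;
  for (int i = lo; i < hi; ++i) {
    int s = pair_score(Q[i], T[i + d], match, mismatch);
    if (cur <= 0) { cur = s; cur_start = i; }
    else cur += s;
    if (cur > best) { best = cur; b0 = cur_start; b1 = i + 1; }
  }
  *q0 = b0;
  *q1 = b1;
  return best == LONG_MIN ? 0 : best;
}

static void finalize_record(AlnRec &rec, const std::string &Q,
                            const std::string &T,
                            std::vector<std::pair<int, int>> &pairs) {
  // trim non-match ends (a local alignment never benefits from ending on a
  // mismatch; trailing/leading neutral N pairs are trimmed for tidiness)
  size_t a = 0, b = pairs.size();
  while (a < b &&
         pair_score(Q[pairs[a].first], T[pairs[a].second], 1, 1) <= 0) ++a;
  while (b > a &&
         pair_score(Q[pairs[b - 1].first], T[pairs[b - 1].second], 1, 1) <= 0) --b;
  if (a >= b) { rec.bsize.clear(); return; }

  rec.bsize.clear(); rec.bq.clear(); rec.bt.clear();
  int prev_q = -2, prev_t = -2;
  for (size_t i = a; i < b; ++i) {
    int qi = pairs[i].first, ti = pairs[i].second;
    if (qi == prev_q + 1 && ti == prev_t + 1) {
      rec.bsize.back()++;
    } else {
      rec.bsize.push_back(1);
      rec.bq.push_back(qi);
      rec.bt.push_back(ti);
    }
    int qa = base_code(Q[qi]), tb = base_code(T[ti]);
    if (qa > 3 || tb > 3) rec.ncount++;
    else if (qa == tb) rec.matches++;
    else rec.mism++;
    prev_q = qi; prev_t = ti;
  }
  rec.qstart = rec.bq.front();
  rec.qend = rec.bq.back() + rec.bsize.back();
  rec.tstart = rec.bt.front();
  rec.tend = rec.bt.back() + rec.bsize.back();
  for (size_t j = 1; j < rec.bsize.size(); ++j) {
    int dq = rec.bq[j] - (rec.bq[j - 1] + rec.bsize[j - 1]);
    int dt = rec.bt[j] - (rec.bt[j - 1] + rec.bsize[j - 1]);
    if (dq > 0) { rec.qnum++; rec.qbase += dq; }
    if (dt > 0) { rec.tnum++; rec.tbase += dt; }
  }
}

// Banded local alignment with affine gaps over diagonals [dlo, dhi].
// Returns false when no positive-scoring alignment exists.
static bool banded_sw(const std::string &Q, const std::string &T, int dlo,
                      int dhi, int match, int mismatch, int gap_open,
                      int gap_ext, AlnRec &rec) {
  const int qlen = (int)Q.size(), tlen = (int)T.size();
  const int W = dhi - dlo + 1;
  const int NEG = INT_MIN / 4;
  const int open_cost = gap_open + gap_ext;

  std::vector<int> M((size_t)(qlen + 1) * W, NEG);
  std::vector<int> Ix((size_t)(qlen + 1) * W, NEG);
  std::vector<int> Iy((size_t)(qlen + 1) * W, NEG);
  std::vector<uint8_t> tbM((size_t)(qlen + 1) * W, 0);
  std::vector<uint8_t> tbX((size_t)(qlen + 1) * W, 0);
  std::vector<uint8_t> tbY((size_t)(qlen + 1) * W, 0);

  auto at = [W, dlo](int i, int d) { return (size_t)i * W + (d - dlo); };

  // row 0: nothing consumed from the query
  for (int d = dlo; d <= dhi; ++d) {
    M[at(0, d)] = NEG; Ix[at(0, d)] = NEG; Iy[at(0, d)] = NEG;
  }

  long best = 0;
  int bi = -1, bd = 0;

  for (int i = 1; i <= qlen; ++i) {
    for (int d = dlo; d <= dhi; ++d) {
      int t = i + d;
      // M: Q[i-1] aligned with T[t-1]
      if (t >= 1 && t <= tlen) {
        int prev = 0; uint8_t tb = 0;
        size_t pidx = at(i - 1, d);
        if (M[pidx] > prev) { prev = M[pidx]; tb = 1; }
        if (Ix[pidx] > prev) { prev = Ix[pidx]; tb = 2; }
        if (Iy[pidx] > prev) { prev = Iy[pidx]; tb = 3; }
        M[at(i, d)] = prev + pair_score(Q[i - 1], T[t - 1], match, mismatch);
        tbM[at(i, d)] = tb;
        if (M[at(i, d)] > best) { best = M[at(i, d)]; bi = i; bd = d; }
      } else {
        M[at(i, d)] = NEG;
      }
      // Ix: Q[i-1] opposite a gap (target not consumed); from (i-1, d+1)
      if (d + 1 <= dhi) {
        size_t pidx = at(i - 1, d + 1);
        int vM = (M[pidx] <= NEG / 2) ? NEG : M[pidx] - open_cost;
        int vX = (Ix[pidx] <= NEG / 2) ? NEG : Ix[pidx] - gap_ext;
        if (vM >= vX) { Ix[at(i, d)] = vM; tbX[at(i, d)] = 1; }
        else { Ix[at(i, d)] = vX; tbX[at(i, d)] = 2; }
      }
      // Iy: T[t-1] opposite a gap (query not consumed); from (i, d-1)
      if (d - 1 >= dlo && t >= 1 && t <= tlen) {
        size_t pidx = at(i, d - 1);
        int vM = (M[pidx] <= NEG / 2) ? NEG : M[pidx] - open_cost;
        int vY = (Iy[pidx] <= NEG / 2) ? NEG : Iy[pidx] - gap_ext;
        if (vM >= vY) { Iy[at(i, d)] = vM; tbY[at(i, d)] = 1; }
        else { Iy[at(i, d)] = vY; tbY[at(i, d)] = 3; }
      }
    }
  }

  if (bi < 0 || best <= 0) return false;

  std::vector<std::pair<int, int>> pairs;  // (query pos, target pos), 0-based
  int i = bi, d = bd, state = 1;  // 1=M, 2=Ix, 3=Iy
  while (true) {
    if (state == 1) {
      pairs.push_back(std::make_pair(i - 1, i + d - 1));
      uint8_t tb = tbM[at(i, d)];
      if (tb == 0) break;
      state = tb;
      i -= 1;
    } else if (state == 2) {
      state = tbX[at(i, d)] == 1 ? 1 : 2;
      i -= 1; d += 1;
    } else {
      state = tbY[at(i, d)] == 1 ? 1 : 3;
      d -= 1;
    }
  }
  std::reverse(pairs.begin(), pairs.end());
  rec.score = best;
  finalize_record(rec, Q, T, pairs);
  return !rec.bsize.empty();
}

struct Cluster {
  int sid;
  std::vector<int> diags;  // distinct seed diagonals, ascending
  int nhits;
  int dmin, dmax;
};

static std::vector<Cluster> cluster_hits(std::vector<Hit> &hits,
                                         int band_width, int qlen) {
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    if (a.sid != b.sid) return a.sid < b.sid;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.tpos < b.tpos;
  });
  std::vector<Cluster> out;
  for (size_t i = 0; i < hits.size(); ++i) {
    bool fresh = out.empty() || hits[i].sid != out.back().sid ||
                 hits[i].diag - out.back().dmax > band_width ||
                 hits[i].diag - out.back().dmin > 2 * band_width;
    if (!fresh && hits[i].diag == hits[i - 1].diag &&
        hits[i].tpos - hits[i - 1].tpos > qlen + 2 * band_width) {
      fresh = true;  // distant repeat on the same diagonal
    }
    if (fresh) {
      Cluster c;
      c.sid = hits[i].sid;
      c.diags.push_back(hits[i].diag);
      c.nhits = 1;
      c.dmin = c.dmax = hits[i].diag;
      out.push_back(c);
    } else {
      Cluster &c = out.back();
      if (hits[i].diag != c.dmax) c.diags.push_back(hits[i].diag);
      c.dmax = hits[i].diag;
      c.nhits++;
    }
  }
  return out;
}

// [[Rcpp::export]]
List sa_align_query(SEXP xp_, std::string query, double min_identity,
                    bool fast, int match, int mismatch, int gap_open,
                    int gap_ext, int band_width) {
  XPtr<SeedIndex> xp(xp_);
  const int k = xp->k;
  const int qlen = (int)query.size();
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<AlnRec> recs;

  for (int strand_i = 0; strand_i < 2; ++strand_i) {
    char strand = strand_i == 0 ? '+' : '-';
    std::string Q = strand == '+' ? query : revcomp(query);

    // collect seed hits
    std::vector<Hit> hits;
    uint64_t code = 0;
    int run = 0;
    for (int i = 0; i < qlen; ++i) {
      int b = base_code(Q[i]);
      if (b > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = xp->dir.find(code);
        if (it != xp->dir.end()) {
          int qpos = i + 1 - k;
          uint32_t a = it->second.first, n = it->second.second;
          for (uint32_t j = 0; j < n; ++j) {
            Hit h;
            h.sid = xp->sid[a + j];
            h.tpos = xp->pos[a + j];
            h.qpos = qpos;
            h.diag = h.tpos - qpos;
            hits.push_back(h);
          }
        }
      }
    }
    if (hits.empty()) continue;

    std::vector<Cluster> clusters = cluster_hits(hits, band_width, qlen);
    // With few candidate loci every cluster is extended; on large genomes
    // spurious single-seed clusters are screened by a cheap gapless
    // extension first (BLAT analogously requires multi-seed support).
    const bool extend_all = clusters.size() <= 64;

    for (const Cluster &c : clusters) {
      const std::string &T = xp->seqs[c.sid];
      long pre_best = LONG_MIN;
      int pre_q0 = 0, pre_q1 = 0, pre_d = c.dmin;
      for (int d : c.diags) {
        int q0, q1;
        long s = kadane_diag(Q, T, d, match, mismatch, &q0, &q1);
        if (s > pre_best) { pre_best = s; pre_q0 = q0; pre_q1 = q1; pre_d = d; }
      }
      if (!extend_all && c.nhits < 2 && pre_best < k + 5) continue;

      AlnRec rec;
      rec.strand = strand;
      rec.sid = c.sid;
      bool ok = false;
      // a perfect full-length gapless extension cannot be improved upon:
      // emit it directly and skip the banded DP
      bool exact_full = pre_best == (long)qlen * match &&
                        pre_q0 == 0 && pre_q1 == qlen;
      if (fast || exact_full) {
        if (pre_best > 0 && pre_q1 > pre_q0) {
          std::vector<std::pair<int, int>> pairs;
          for (int i = pre_q0; i < pre_q1; ++i)
            pairs.push_back(std::make_pair(i, i + pre_d));
          rec.score = pre_best;
          finalize_record(rec, Q, T, pairs);
          ok = !rec.bsize.empty();
        }
      } else {
        int dlo = c.dmin - band_width;
        int dhi = c.dmax + band_width;
        ok = banded_sw(Q, T, dlo, dhi, match, mismatch, gap_open, gap_ext, rec);
      }
      if (!ok) continue;
      // the sensitivity contract covers loci of >= 2k bases; shorter
      // incidental seed blips are below the aligner's resolution
      if (rec.matches + rec.mism + rec.ncount < 2 * k) continue;
      double denom = rec.matches + rec.mism;
      double ident = denom > 0 ? rec.matches / denom : 1.0;
      if (ident + 1e-12 < min_identity) continue;
      recs.push_back(rec);
    }
  }

  // one record per locus: greedy by score (ties: leftmost target start,
  // then '+' strand), dropping records overlapping a kept one on the target
  std::vector<size_t> ord(recs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (recs[a].score != recs[b].score) return recs[a].score > recs[b].score;
    if (recs[a].sid != recs[b].sid) return recs[a].sid < recs[b].sid;
    if (recs[a].tstart != recs[b].tstart) return recs[a].tstart < recs[b].tstart;
    return recs[a].strand == '+' && recs[b].strand == '-';
  });
  std::vector<size_t> kept;
  for (size_t i : ord) {
    bool clash = false;
    for (size_t j : kept) {
      if (recs[j].sid == recs[i].sid && recs[i].tstart < recs[j].tend &&
          recs[j].tstart < recs[i].tend) {
        clash = true;
        break;
      }
    }
    if (!clash) kept.push_back(i);
  }
  std::sort(kept.begin(), kept.end(), [&](size_t a, size_t b) {
    if (recs[a].sid != recs[b].sid) return recs[a].sid < recs[b].sid;
    if (recs[a].tstart != recs[b].tstart) return recs[a].tstart < recs[b].tstart;
    return recs[a].strand == '+' && recs[b].strand == '-';
  });

  List out(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    const AlnRec &r = recs[kept[i]];
    out[i] = List::create(
        _["matches"] = r.matches, _["misMatches"] = r.mism,
        _["nCount"] = r.ncount, _["qNumInsert"] = r.qnum,
        _["qBaseInsert"] = r.qbase, _["tNumInsert"] = r.tnum,
        _["tBaseInsert"] = r.tbase,
        _["strand"] = std::string(1, r.strand), _["sid"] = r.sid + 1,
        _["tStart"] = r.tstart, _["tEnd"] = r.tend,
        _["qStartAligned"] = r.qstart, _["qEndAligned"] = r.qend,
        _["blockSizes"] = wrap(r.bsize), _["qStarts"] = wrap(r.bq),
        _["tStarts"] = wrap(r.bt), _["score"] = (double)r.score);
  }
  return out;
}
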