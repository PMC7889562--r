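#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit encoding; 4 = N / anything else
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = c < 4 ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

// ---------------------------------------------------------------------------
// Nearest-neighbor Tm.  Tables indexed by 4*first + second (A=0,C=1,G=2,T=3).
// dS salt correction and the Tm formula itself are applied on the R side's
// parameter values; everything is passed in so R owns the thermodynamic table.
// [[Rcpp::export]]
NumericVector cpp_tm(CharacterVector seqs, NumericVector dh, NumericVector ds,
                     double dh_init_gc, double ds_init_gc,
                     double dh_init_at, double ds_init_at,
                     double sodium_molar, double strand_molar) {
  const double Rgas = 1.9872; // cal / (mol K)
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<uint8_t> v = encode(s);
    int L = (int)v.size();
    double H = 0.0, S = 0.0;
    bool bad = false;
    for (int j = 0; j + 1 < L; ++j) {
      if (v[j] > 3 || v[j + 1] > 3) { bad = true; break; }
      int idx = 4 * v[j] + v[j + 1];
      H += dh[idx];
      S += ds[idx];
    }
    if (bad || L < 2 || v[0] > 3 || v[L - 1] > 3) { out[i] = NA_REAL; continue; }
    // initiation terms per terminal pair
    for (int end = 0; end < 2; ++end) {
      uint8_t c = end == 0 ? v[0] : v[L - 1];
      if (c == 1 || c == 2) { H += dh_init_gc; S += ds_init_gc; }
      else { H += dh_init_at; S += ds_init_at; }
    }
    // entropy-based monovalent salt correction (0.368 * (L-1) * ln[Na+])
    S += 0.368 * (L - 1) * std::log(sodium_molar);
    double tm = 1000.0 * H / (S + Rgas * std::log(strand_molar / 4.0)) - 273.15;
    out[i] = tm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed-and-extend ungapped local search with X-drop.
//
// Subjects are concatenated (separated by an N sentinel); an index of all
// word_size-mers maps word -> global positions.  Each query is scanned on both
// strands; seeds are extended without gaps under an X-drop rule; overlapping
// extensions on the same diagonal are merged by skipping seeds that fall in an
// already-reported alignment.

struct Hit {
  int query, subject;
  char strand;
  int qstart, qend, sstart, send; // 0-based half-open; query coords in original orientation
  int matches, mismatches, score;
};

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector queries, CharacterVector subjects,
                     int match, int mismatch, int word_size, int xdrop,
                     int min_score) {
  int nsub = subjects.size();
  std::vector<uint8_t> cat;   // concatenated subject codes with sentinels
  std::vector<size_t> offset(nsub + 1, 0);
  size_t total = 0;
  for (int i = 0; i < nsub; ++i) total += Rf_xlength(STRING_ELT(subjects, i)) + 1;
  cat.reserve(total);
  for (int i = 0; i < nsub; ++i) {
    std::string s = as<std::string>(subjects[i]);
    offset[i] = cat.size();
    for (char c : s) cat.push_back((uint8_t)base_code(c));
    cat.push_back(4); // sentinel between subjects
  }
  offset[nsub] = cat.size();
  size_t N = cat.size();

  // word index (two-pass flat layout)
  const uint32_t nwords = 1u << (2 * word_size);
  const uint32_t wmask = nwords - 1;
  std::vector<uint32_t> cnt(nwords + 1, 0);
  {
    uint32_t w = 0; int run = 0;
    for (size_t i = 0; i < N; ++i) {
      if (cat[i] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | cat[i]) & wmask;
      if (++run >= word_size) cnt[w + 1]++;
    }
  }
  for (uint32_t w = 0; w < nwords; ++w) cnt[w + 1] += cnt[w];
  std::vector<uint32_t> pos(cnt[nwords]);
  {
    std::vector<uint32_t> fill(cnt.begin(), cnt.end() - 1);
    uint32_t w = 0; int run = 0;
    for (size_t i = 0; i < N; ++i) {
      if (cat[i] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | cat[i]) & wmask;
      if (++run >= word_size) pos[fill[w]++] = (uint32_t)(i - word_size + 1);
    }
  }

  std::vector<Hit> hits;
  std::vector<size_t> sub_of(0);

  auto subject_of = [&](size_t gpos) {
    // binary search for the subject containing global position gpos
    int lo = 0, hi = nsub - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (offset[mid] <= gpos) lo = mid; else hi = mid - 1;
    }
    return lo;
  };

  int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    std::vector<uint8_t> qfwd = encode(qs);
    int qlen = (int)qfwd.size();
    if (qlen < word_size) continue;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t> q = strand == 0 ? qfwd : revcomp_codes(qfwd);
      // per-diagonal covered subject intervals
      std::unordered_map<long long, std::vector<std::pair<int,int> > > covered;
      uint32_t w = 0; int run = 0;
      for (int qp = 0; qp < qlen; ++qp) {
        if (q[qp] > 3) { run = 0; w = 0; continue; }
        w = ((w << 2) | q[qp]) & wmask;
        if (++run < word_size) continue;
        int qseed = qp - word_size + 1;
        for (uint32_t pi = cnt[w]; pi < cnt[w + 1]; ++pi) {
          size_t g = pos[pi];
          long long diag = (long long)g - qseed;
          bool skip = false;
          auto it = covered.find(diag);
          if (it != covered.end()) {
            for (auto &iv : it->second)
              if ((long long)g >= iv.first && (long long)g < iv.second) { skip = true; break; }
          }
          if (skip) continue;
          int si = subject_of(g);
          long long slo = (long long)offset[si];
          long long shi = (long long)offset[si + 1] - 1; // exclude sentinel
          // extend right from end of seed
          int sc = word_size * match, best = sc;
          long long qa = qseed, qb = qseed + word_size; // current best [qa,qb) in q coords
          long long ga = g, gb = g + word_size;
          {
            long long qq = qb, gg = gb; int cur = sc;
            long long bq = qb, bg = gb;
            while (qq < qlen && gg < shi) {
              cur += (q[qq] < 4 && q[qq] == cat[gg]) ? match : mismatch;
              ++qq; ++gg;
              if (cur > best) { best = cur; bq = qq; bg = gg; }
              if (best - cur > xdrop) break;
            }
            qb = bq; gb = bg; sc = best;
          }
          {
            long long qq = qa, gg = ga; int cur = sc; int bestl = sc;
            long long bq = qa, bg = ga;
            while (qq > 0 && gg > slo) {
              --qq; --gg;
              cur += (q[qq] < 4 && q[qq] == cat[gg]) ? match : mismatch;
              if (cur > bestl) { bestl = cur; bq = qq; bg = gg; }
              if (bestl - cur > xdrop) break;
            }
            qa = bq; ga = bg; sc = bestl;
          }
          // count matches over final alignment
          int m = 0, mm = 0;
          for (long long t = 0; t < qb - qa; ++t) {
            if (q[qa + t] < 4 && q[qa + t] == cat[ga + t]) ++m; else ++mm;
          }
          covered[diag].push_back(std::make_pair((int)ga, (int)gb));
          if (sc >= min_score) {
            Hit h;
            h.query = qi + 1; h.subject = si + 1;
            h.strand = strand == 0 ? '+' : '-';
            if (strand == 0) { h.qstart = (int)qa; h.qend = (int)qb; }
            else { h.qstart = qlen - (int)qb; h.qend = qlen - (int)qa; }
            h.sstart = (int)(ga - slo); h.send = (int)(gb - slo);
            h.matches = m; h.mismatches = mm; h.score = sc;
            hits.push_back(h);
          }
        }
      }
    }
  }

  int nh = (int)hits.size();
  IntegerVector query(nh), subject(nh), qstart(nh), qend(nh), sstart(nh),
      send(nh), matches(nh), mismatches(nh), score(nh);
  CharacterVector strand(nh);
  for (int i = 0; i < nh; ++i) {
    query[i] = hits[i].query; subject[i] = hits[i].subject;
    strand[i] = std::string(1, hits[i].strand);
    qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
    sstart[i] = hits[i].sstart; send[i] = hits[i].send;
    matches[i] = hits[i].matches; mismatches[i] = hits[i].mismatches;
    score[i] = hits[i].score;
  }
  return DataFrame::create(
      _["query"] = query, _["subject"] = subject, _["strand"] = strand,
      _["qstart"] = qstart, _["qend"] = qend, _["sstart"] = sstart,
      _["send"] = send, _["matches"] = matches, _["mismatches"] = mismatches,
      _["score"] = score, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Canonical k-mer counting.  Codes returned as doubles (exact for k <= 26).
// [[Rcpp::export]]
List cpp_kmer_count(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, double> tab;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    uint64_t w = 0, rc = 0;
    int run = 0;
    for (int j = 0; j < L; ++j) {
      int c = base_code(s[j]);
      if (c > 3) { run = 0; w = 0; rc = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(w, rc);
        tab[canon] += 1.0;
      }
    }
  }
  size_t m = tab.size();
  NumericVector code(m), count(m);
  size_t idx = 0;
  for (auto &kv : tab) { code[idx] = (double)kv.first; count[idx] = kv.second; ++idx; }
  return List::create(_["code"] = code, _["count"] = count);
}

// ---------------------------------------------------------------------------
// Apply point substitutions chosen on the R side (keeps all RNG in R).
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, IntegerVector seq_idx,
                               IntegerVector pos, CharacterVector newbase) {
  CharacterVector out = clone(seqs);
  int n = seq_idx.size();
  std::unordered_map<int, std::string> touched;
  for (int i = 0; i < n; ++i) {
    int si = seq_idx[i] - 1;
    auto it = touched.find(si);
    if (it == touched.end())
      it = touched.emplace(si, as<std::string>(out[si])).first;
    std::string b = as<std::string>(newbase[i]);
    it->second[pos[i] - 1] = b[0];
  }
  for (auto &kv : touched) out[kv.first] = kv.second;
  return out;
}
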