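// Core sequence engines: Gotoh affine-gap Smith-Waterman for peptides,
// k-mer-seeded translated read search, and a seeded ungapped nucleotide
// read mapper. Scoring matrices are supplied from R (BLOSUM62 expanded to
// the 27-letter A..Z,* index space), so the C++ side is matrix-agnostic.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Standard genetic code, codon index = 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3.
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int aa_index(char c) {
  if (c == '*') return 26;
  if (c >= 'A' && c <= 'Z') return c - 'A';
  if (c >= 'a' && c <= 'z') return c - 'a';
  return 23; // 'X'
}

static inline int nt_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char nt_comp(char c) {
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
  for (size_t i = 0; i < r.size(); ++i) r[i] = nt_comp(r[i]);
  return r;
}

// Translate one frame (offset 0..2) of a nucleotide string; codons touching
// an ambiguous base become 'X', stop codons '*'.
static std::string translate_frame(const std::string& dna, int offset) {
  std::string pep;
  size_t n = dna.size();
  if (n < (size_t)(offset + 3)) return pep;
  pep.reserve((n - offset) / 3);
  for (size_t i = offset; i + 2 < n; i += 3) {
    int b1 = nt_index(dna[i]), b2 = nt_index(dna[i + 1]), b3 = nt_index(dna[i + 2]);
    if (b1 > 3 || b2 > 3 || b3 > 3) pep.push_back('X');
    else pep.push_back(CODON_TABLE[16 * b1 + 4 * b2 + b3]);
  }
  return pep;
}

// [[Rcpp::export]]
CharacterVector cpp_six_frame(std::string dna) {
  CharacterVector out(6);
  std::string rc = revcomp(dna);
  for (int f = 0; f < 3; ++f) {
    out[f] = translate_frame(dna, f);
    out[f + 3] = translate_frame(rc, f);
  }
  out.attr("names") = CharacterVector::create("+1", "+2", "+3", "-1", "-2", "-3");
  return out;
}

struct AlnResult {
  int score, qstart, qend, sstart, send, nid, alen;
};

// Score-only Gotoh local alignment with rolling arrays; used to screen the
// (mostly spurious) seeded candidates before the full traceback alignment.
static int sw_score_only(const std::vector<int>& qi, const std::vector<int>& si,
                         const IntegerMatrix& smat, int gapOpen, int gapExt) {
  int m = qi.size(), n = si.size();
  if (m == 0 || n == 0) return 0;
  const int NEG = -1000000000;
  static std::vector<int> H, F;
  H.assign(n + 1, 0);
  F.assign(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = H[0], e = NEG, hj = 0;
    const int* srow = &smat(qi[i - 1], 0);
    for (int j = 1; j <= n; ++j) {
      int fo = H[j] - gapOpen - gapExt, fe = F[j] - gapExt;
      F[j] = fe > fo ? fe : fo;
      int eo = hj - gapOpen - gapExt, ee = e - gapExt;
      e = ee > eo ? ee : eo;
      int h = diag + srow[si[j - 1] * 27];
      if (e > h) h = e;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      diag = H[j]; H[j] = h; hj = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Gotoh local alignment with affine gaps: a gap of length L costs
// gapOpen + L * gapExt. Traceback recovers identity and aligned spans.
static std::vector<int> encode_pep(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = aa_index(s[i]);
  return v;
}

static AlnResult sw_align(const std::vector<int>& qi, const std::vector<int>& si,
                          const IntegerMatrix& smat, int gapOpen, int gapExt) {
  AlnResult res = {0, 0, 0, 0, 0, 0, 0};
  int m = qi.size(), n = si.size();
  if (m == 0 || n == 0) return res;

  // H, E (gap in query / move along subject), F (gap in subject)
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), 0),
      F((m + 1) * (n + 1), 0);
  // trace: 0 stop, 1 diag, 2 from E, 3 from F; traceE/traceF: 1 = extend
  std::vector<uint8_t> tr((m + 1) * (n + 1), 0), trE((m + 1) * (n + 1), 0),
      trF((m + 1) * (n + 1), 0);
  const int NEG = -1000000000;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int row = i * (n + 1), prow = (i - 1) * (n + 1);
    E[row] = NEG; F[row] = NEG;
    for (int j = 1; j <= n; ++j) {
      int eo = H[row + j - 1] - gapOpen - gapExt;
      int ee = E[row + j - 1] - gapExt;
      E[row + j] = (ee > eo) ? ee : eo;
      trE[row + j] = (ee > eo) ? 1 : 0;
      int fo = H[prow + j] - gapOpen - gapExt;
      int fe = F[prow + j] - gapExt;
      F[row + j] = (fe > fo) ? fe : fo;
      trF[row + j] = (fe > fo) ? 1 : 0;
      int diag = H[prow + j - 1] + smat(qi[i - 1], si[j - 1]);
      int h = 0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[row + j] > h) { h = E[row + j]; t = 2; }
      if (F[row + j] > h) { h = F[row + j]; t = 3; }
      H[row + j] = h; tr[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0) return res;
  // traceback
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  res.qend = bi; res.send = bj;
  while (i > 0 && j > 0) {
    int idx = i * (n + 1) + j;
    if (state == 0) {
      uint8_t t = tr[idx];
      if (t == 0) break;
      if (t == 1) {
        res.alen++; if (qi[i - 1] == si[j - 1]) res.nid++;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      res.alen++;
      state = trE[idx] ? 1 : 0;
      --j;
    } else {
      res.alen++;
      state = trF[idx] ? 2 : 0;
      --i;
    }
  }
  res.qstart = i + 1; res.sstart = j + 1;
  return res;
}

// [[Rcpp::export]]
List cpp_sw_pair(std::string query, std::string subject, IntegerMatrix smat,
                 int gapOpen, int gapExt) {
  AlnResult r = sw_align(encode_pep(query), encode_pep(subject), smat,
                         gapOpen, gapExt);
  return List::create(_["score"] = r.score, _["qstart"] = r.qstart,
                      _["qend"] = r.qend, _["sstart"] = r.sstart,
                      _["send"] = r.send, _["n_identical"] = r.nid,
                      _["align_len"] = r.alen);
}

// Exact k-mer index over peptide subjects, 5 bits per residue (k <= 6).
typedef std::unordered_map<uint32_t, std::vector<int> > PepIndex;

static void index_subjects(const std::vector<std::vector<int> >& subs, int k,
                           PepIndex& idx) {
  for (size_t s = 0; s < subs.size(); ++s) {
    const std::vector<int>& seq = subs[s];
    if ((int)seq.size() < k) continue;
    uint32_t key = 0, mask = (1u << (5 * k)) - 1;
    for (size_t p = 0; p < seq.size(); ++p) {
      key = ((key << 5) | (uint32_t)seq[p]) & mask;
      if ((int)p >= k - 1) {
        std::vector<int>& v = idx[key];
        if (v.empty() || v.back() != (int)s) v.push_back((int)s);
      }
    }
  }
}

static void seed_candidates(const std::vector<int>& pep, int k,
                            const PepIndex& idx,
                            std::vector<int>& seen, int tag,
                            std::vector<int>& cand) {
  if ((int)pep.size() < k) return;
  uint32_t key = 0, mask = (1u << (5 * k)) - 1;
  for (size_t p = 0; p < pep.size(); ++p) {
    key = ((key << 5) | (uint32_t)pep[p]) & mask;
    if ((int)p >= k - 1) {
      PepIndex::const_iterator it = idx.find(key);
      if (it == idx.end()) continue;
      for (size_t t = 0; t < it->second.size(); ++t) {
        int s = it->second[t];
        if (seen[s] != tag) { seen[s] = tag; cand.push_back(s); }
      }
    }
  }
}

// Translated search of nucleotide reads against peptide subjects: all six
// frames are seeded with exact k-mers, candidates aligned by Smith-Waterman,
// hits at or above minScore reported (1-based read/subject indices).
// [[Rcpp::export]]
DataFrame cpp_search_reads(CharacterVector reads, CharacterVector subjects,
                           IntegerMatrix smat, int gapOpen, int gapExt,
                           int k, double minScore) {
  int nsub = subjects.size();
  std::vector<std::vector<int> > subs(nsub);
  for (int s = 0; s < nsub; ++s)
    subs[s] = encode_pep(as<std::string>(subjects[s]));
  PepIndex idx;
  index_subjects(subs, k, idx);
  std::vector<int> seen(nsub, -1);

  std::vector<int> out_read, out_sub, out_frame, out_score, out_nid, out_alen,
      out_sstart, out_send;
  static const int FRAMES[6] = {1, 2, 3, -1, -2, -3};
  int tag = 0;
  for (int r = 0; r < reads.size(); ++r) {
    std::string dna = as<std::string>(reads[r]);
    std::string rc = revcomp(dna);
    for (int f = 0; f < 6; ++f) {
      std::vector<int> pep = encode_pep(translate_frame(f < 3 ? dna : rc, f % 3));
      std::vector<int> cand;
      seed_candidates(pep, k, idx, seen, tag++, cand);
      for (size_t c = 0; c < cand.size(); ++c) {
        int s = cand[c];
        if (sw_score_only(pep, subs[s], smat, gapOpen, gapExt) < minScore)
          continue;
        AlnResult a = sw_align(pep, subs[s], smat, gapOpen, gapExt);
        if (a.score >= minScore && a.alen >= 1) {
          out_read.push_back(r + 1);
          out_sub.push_back(s + 1);
          out_frame.push_back(FRAMES[f]);
          out_score.push_back(a.score);
          out_nid.push_back(a.nid);
          out_alen.push_back(a.alen);
          out_sstart.push_back(a.sstart);
          out_send.push_back(a.send);
        }
      }
    }
  }
  return DataFrame::create(
      _["read"] = out_read, _["subject"] = out_sub, _["frame"] = out_frame,
      _["score"] = out_score, _["n_identical"] = out_nid,
      _["align_len"] = out_alen, _["sstart"] = out_sstart,
      _["send"] = out_send);
}

// ---- nucleotide read mapper (seeded, ungapped verification) ----

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > NtIndex;

static void index_contigs(const std::vector<std::string>& contigs, int k,
                          NtIndex& idx) {
  for (size_t c = 0; c < contigs.size(); ++c) {
    const std::string& seq = contigs[c];
    if ((int)seq.size() < k) continue;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (size_t p = 0; p < seq.size(); ++p) {
      int b = nt_index(seq[p]);
      if (b > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        idx[key].push_back(std::make_pair((int)c, (int)p - k + 1));
    }
  }
}

// Map reads onto contigs: exact k-mer seeds define candidate diagonals, each
// verified by full-length ungapped comparison; a read maps if identity >=
// minIdent over an overlap of >= minCov of read length. Best = most matching
// bases; ties broken by contig order as supplied (callers pass contigs sorted
// by id). Returns 0 for unmapped.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs, int k,
                        double minIdent, double minCov) {
  int ncon = contigs.size();
  std::vector<std::string> cons(ncon);
  for (int c = 0; c < ncon; ++c) cons[c] = as<std::string>(contigs[c]);
  NtIndex idx;
  index_contigs(cons, k, idx);

  int nr = reads.size();
  IntegerVector out_contig(nr, 0), out_pos(nr, NA_INTEGER),
      out_strand(nr, NA_INTEGER);
  NumericVector out_ident(nr, NA_REAL), out_cov(nr, NA_REAL);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = fwd.size();
    if (len < k) continue;
    std::string strands[2] = {fwd, revcomp(fwd)};
    int best_matches = -1, best_contig = -1, best_pos = 0, best_strand = 0;
    double best_ident = 0, best_cov = 0;
    for (int st = 0; st < 2; ++st) {
      const std::string& rd = strands[st];
      uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
      int run = 0;
      // collect distinct (contig, offset) diagonals
      std::vector<std::pair<int, int> > diags;
      for (int p = 0; p < len; ++p) {
        int b = nt_index(rd[p]);
        if (b > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        NtIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t t = 0; t < it->second.size(); ++t)
          diags.push_back(std::make_pair(it->second[t].first,
                                         it->second[t].second - (p - k + 1)));
      }
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      for (size_t d = 0; d < diags.size(); ++d) {
        int c = diags[d].first, off = diags[d].second;
        const std::string& cs = cons[c];
        int lo = std::max(0, -off), hi = std::min(len, (int)cs.size() - off);
        int overlap = hi - lo;
        if (overlap < (int)(minCov * len + 0.999999)) continue;
        int matches = 0;
        for (int p = lo; p < hi; ++p)
          if (nt_index(rd[p]) == nt_index(cs[p + off]) && nt_index(rd[p]) <= 3)
            ++matches;
        double ident = (double)matches / overlap;
        if (ident < minIdent) continue;
        bool better = matches > best_matches ||
                      (matches == best_matches && c < best_contig);
        if (better) {
          best_matches = matches; best_contig = c; best_pos = off + lo;
          best_strand = st; best_ident = ident;
          best_cov = (double)overlap / len;
        }
      }
    }
    if (best_contig >= 0) {
      out_contig[r] = best_contig + 1;
      out_pos[r] = best_pos + 1;
      out_strand[r] = best_strand == 0 ? 1 : -1;
      out_ident[r] = best_ident;
      out_cov[r] = best_cov;
    }
  }
  return DataFrame::create(_["contig"] = out_contig, _["pos"] = out_pos,
                           _["strand"] = out_strand, _["identity"] = out_ident,
                           _["coverage"] = out_cov);
}
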