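#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; returns -1 for non-ACGT
static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (auto &c : out) c = comp_base(c);
  return out;
}

// Encode k-mer starting at pos; returns false if it contains non-ACGT.
static inline bool encode_kmer(const std::string &s, size_t pos, int k,
                               uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

static inline int mismatches_capped(const std::string &a, size_t apos,
                                    const std::string &b, size_t bpos,
                                    size_t len, int cap) {
  int mm = 0;
  for (size_t i = 0; i < len; ++i) {
    if (a[apos + i] != b[bpos + i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Seed-and-extend read mapper onto a single reference. Each read is placed
// at its best position on either strand (fewest mismatches over the full
// read; ties broken by leftmost position, then forward strand). Depth is
// incremented over the aligned span of mapped reads.
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, std::string ref, int k,
                   int max_mismatch) {
  const size_t L = ref.size();
  if ((size_t)k > L) stop("seed length exceeds reference length");

  // k-mer index of the reference
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(L);
  {
    uint64_t code;
    for (size_t p = 0; p + (size_t)k <= L; ++p) {
      if (encode_kmer(ref, p, k, code)) index[code].push_back((int)p);
    }
  }

  const int n = reads.size();
  IntegerVector depth(L, 0);
  IntegerVector pos(n, NA_INTEGER);
  IntegerVector mism(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  int n_mapped = 0;

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int m = (int)fwd.size();
    if (m < k || (size_t)m > L) continue;
    std::string rev = revcomp_str(fwd);

    int best_mm = max_mismatch + 1;
    long best_pos = -1;
    int best_strand = 0; // 0 fwd, 1 rev

    for (int st = 0; st < 2; ++st) {
      const std::string &rd = (st == 0) ? fwd : rev;
      // seed offsets: 0, k, 2k, ..., plus the tail k-mer
      std::vector<int> offs;
      for (int o = 0; o + k <= m; o += k) offs.push_back(o);
      if (offs.empty() || offs.back() != m - k) offs.push_back(m - k);
      std::vector<long> cand;
      for (int o : offs) {
        uint64_t code;
        if (!encode_kmer(rd, (size_t)o, k, code)) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (int h : it->second) {
          long p = (long)h - o;
          if (p >= 0 && p + m <= (long)L) cand.push_back(p);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (long p : cand) {
        int mm = mismatches_capped(ref, (size_t)p, rd, 0, (size_t)m,
                                   best_mm);
        if (mm > max_mismatch) continue;
        if (mm < best_mm ||
            (mm == best_mm && (p < best_pos ||
                               (p == best_pos && st < best_strand)))) {
          best_mm = mm;
          best_pos = p;
          best_strand = st;
        }
      }
    }

    if (best_pos >= 0) {
      ++n_mapped;
      pos[r] = (int)best_pos + 1; // 1-based
      mism[r] = best_mm;
      strand[r] = best_strand == 0 ? "+" : "-";
      for (int i = 0; i < m; ++i) depth[best_pos + i]++;
    }
  }

  return List::create(_["depth"] = depth, _["pos"] = pos,
                      _["strand"] = strand, _["mismatches"] = mism,
                      _["n_mapped"] = n_mapped, _["n_reads"] = n);
}

// Greedy consensus read walking off the 3' end of `terminal`. At each step
// the terminal `anchor_k`-mer is located in the reads (either strand); a
// read votes for the next base when it overlaps the current terminus by at
// least `min_overlap` with at most `max_mismatch` mismatches and extends
// past it. The majority base is appended when its support and agreement
// clear the thresholds; otherwise the walk stops with a reason.
// [[Rcpp::export(name = ".extend_walk_cpp")]]
List extend_walk_cpp(std::string terminal, CharacterVector reads,
                     int anchor_k, int min_overlap, int max_mismatch,
                     int min_support, double min_agreement,
                     int max_extension) {
  if ((int)terminal.size() < anchor_k)
    stop("terminal sequence shorter than anchor_k");

  const int n = reads.size();
  std::vector<std::string> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads[i]);
    rev[i] = revcomp_str(fwd[i]);
  }

  std::string cur = terminal;
  std::string added;
  std::vector<int> support;
  std::string stop_reason = "max_length";

  while ((int)added.size() < max_extension) {
    const size_t cl = cur.size();
    std::string anchor = cur.substr(cl - anchor_k);
    int votes[4] = {0, 0, 0, 0};
    int total = 0;

    for (int i = 0; i < n; ++i) {
      for (int st = 0; st < 2; ++st) {
        const std::string &rd = (st == 0) ? fwd[i] : rev[i];
        if ((int)rd.size() < anchor_k) continue;
        // best alignment of this read against the terminus, anchored on an
        // exact match of the terminal anchor_k-mer
        int best_mm = max_mismatch + 1;
        long best_q = -1;
        size_t q = rd.find(anchor);
        while (q != std::string::npos) {
          long ov = (long)q + anchor_k; // overlap with terminus
          if (ov >= min_overlap && ov <= (long)cl &&
              (size_t)ov < rd.size()) {
            int mm = mismatches_capped(cur, cl - ov, rd, 0, (size_t)ov,
                                       best_mm);
            if (mm < best_mm) {
              best_mm = mm;
              best_q = q;
            }
          }
          q = rd.find(anchor, q + 1);
        }
        if (best_q >= 0 && best_mm <= max_mismatch) {
          char nxt = rd[best_q + anchor_k];
          int b = base2bits(nxt);
          if (b >= 0) {
            votes[b]++;
            total++;
          }
          break; // one vote per read
        }
      }
    }

    if (total == 0) {
      stop_reason = "no_overlap";
      break;
    }
    int best_b = 0;
    for (int b = 1; b < 4; ++b)
      if (votes[b] > votes[best_b]) best_b = b;
    int sup = votes[best_b];
    double agree = (double)sup / (double)total;
    if (sup < min_support) {
      stop_reason = "low_support";
      break;
    }
    if (agree < min_agreement) {
      stop_reason = "ambiguous";
      break;
    }
    const char bases[5] = "ACGT";
    cur.push_back(bases[best_b]);
    added.push_back(bases[best_b]);
    support.push_back(sup);
  }

  return List::create(_["added_sequence"] = added,
                      _["per_base_support"] = wrap(support),
                      _["stop_reason"] = stop_reason,
                      _["extended"] = cur);
}
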