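#include <Rcpp.h>
using namespace Rcpp;

// Banded local alignment of an (already strand-oriented) read against a
// reference sequence.  The band constrains reference position j to
// j - i in [diag - band, diag + band] for read position i (both 0-based),
// where diag is the seed-chain diagonal estimate.  Scoring is linear-gap
// (454 indels are short, affine gaps buy nothing here).  The traceback
// reports per-column counts and, for every substitution column, the
// reference position together with the read base -- the substrate for
// pileups downstream.
//
// [[Rcpp::export(".banded_align")]]
List banded_align(const std::string& read, const std::string& ref,
                  const int diag, const int band,
                  const int match = 2, const int mismatch = -1,
                  const int gap = -2) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;

  // S[i][k]: best local score of a path ending at read prefix i,
  // reference prefix j = i + diag + (k - band).
  std::vector<int> S((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> TB((size_t)(n + 1) * W, 0);  // 0 stop, 1 diag, 2 ref-only, 3 read-only
  const size_t Wz = (size_t) W;

  int best = 0, bi = -1, bk = -1;
  for (int k = 0; k < W; ++k) {
    int j = diag + k - band;
    if (j >= 0 && j <= m) S[Wz * 0 + k] = 0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + diag + k - band;
      if (j < 0 || j > m) continue;
      int sc = 0;                // a local alignment may start here
      unsigned char tb = 0;
      if (j >= 1) {
        int p = S[Wz * (i - 1) + k];  // consume read[i-1] and ref[j-1]
        if (p > NEG) {
          int s = p + (read[i - 1] == ref[j - 1] ? match : mismatch);
          if (s > sc) { sc = s; tb = 1; }
        }
        if (k >= 1) {                 // consume ref[j-1] only (gap in read)
          int q = S[Wz * i + (k - 1)];
          if (q > NEG) { int s = q + gap; if (s > sc) { sc = s; tb = 2; } }
        }
      }
      if (k + 1 < W) {                // consume read[i-1] only (gap in ref)
        int r = S[Wz * (i - 1) + (k + 1)];
        if (r > NEG) { int s = r + gap; if (s > sc) { sc = s; tb = 3; } }
      }
      S[Wz * i + k] = sc;
      TB[Wz * i + k] = tb;
      if (sc > best) { best = sc; bi = i; bk = k; }
    }
  }

  if (bi < 0 || best <= 0) {
    return List::create(_["score"] = 0, _["n_match"] = 0, _["n_mismatch"] = 0,
                        _["n_gapcols"] = 0, _["read_start"] = 0,
                        _["read_end"] = 0, _["ref_start"] = 0,
                        _["ref_end"] = 0, _["ref_pos"] = IntegerVector(0),
                        _["base"] = CharacterVector(0));
  }

  int i = bi, k = bk;
  int nm = 0, nx = 0, ng = 0;
  std::vector<int> rp;
  std::string rb;
  const int read_end = bi;
  const int ref_end = bi + diag + bk - band;
  for (;;) {
    unsigned char tb = TB[Wz * i + k];
    if (tb == 0) break;
    int j = i + diag + k - band;
    if (tb == 1) {
      if (read[i - 1] == ref[j - 1]) ++nm; else ++nx;
      rp.push_back(j - 1);
      rb.push_back(read[i - 1]);
      i -= 1;
    } else if (tb == 2) {
      ++ng; k -= 1;
    } else {
      ++ng; i -= 1; k += 1;
    }
  }
  const int read_start = i;
  const int ref_start = i + diag + k - band;

  std::reverse(rp.begin(), rp.end());
  std::reverse(rb.begin(), rb.end());
  CharacterVector bases(rb.size());
  for (size_t t = 0; t < rb.size(); ++t) bases[t] = std::string(1, rb[t]);

  return List::create(_["score"] = best, _["n_match"] = nm,
                      _["n_mismatch"] = nx, _["n_gapcols"] = ng,
                      _["read_start"] = read_start, _["read_end"] = read_end,
                      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
                      _["ref_pos"] = wrap(rp), _["base"] = bases);
}
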