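// Weighted ungapped window scans for 23-mer guide candidates.
//
// A guide pairs antiparallel with a transcript window: guide position p
// (1-based) lies opposite window position 24-p. Equivalently, the penalty of
// a window is a weighted Hamming distance between the window and the reverse
// complement of the guide, with the penalty vector reversed into window
// coordinates. Penalties arrive as integers (scale 1e4) so sums and ties are
// exact.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <numeric>
using namespace Rcpp;

static const int SENTINEL = 1 << 29;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return 4;  // never matches any complement
}

// complement code of a guide base; 4 (unknown) maps to 9 so it mismatches all
static inline int comp_code(int c) { return c < 4 ? 3 - c : 9; }

static std::vector<std::vector<int>> encode_subjects(const CharacterVector& subjects) {
  std::vector<std::vector<int>> enc(subjects.size());
  for (R_xlen_t s = 0; s < subjects.size(); ++s) {
    const char* str = CHAR(STRING_ELT(subjects, s));
    size_t n = strlen(str);
    enc[s].resize(n);
    for (size_t i = 0; i < n; ++i) enc[s][i] = base_code(str[i]);
  }
  return enc;
}

// window-coordinate weights: v[q] = penalty[22 - q]
static std::vector<int> window_weights(const IntegerVector& penalty) {
  std::vector<int> v(23);
  for (int q = 0; q < 23; ++q) v[q] = penalty[22 - q];
  return v;
}

// positions with non-zero weight, heaviest first (stable)
static std::vector<int> weight_order(const std::vector<int>& v, int lo, int hi) {
  std::vector<int> idx;
  for (int q = lo; q <= hi; ++q)
    if (v[q] > 0) idx.push_back(q);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] > v[b]; });
  return idx;
}

// Generic early-exit scan: one pass per guide over every window.
// [[Rcpp::export]]
List cpp_profile_scan(CharacterVector guides, CharacterVector subjects,
                      IntegerVector penalty) {
  if (penalty.size() != 23) stop("penalty must have length 23");
  std::vector<std::vector<int>> enc = encode_subjects(subjects);
  std::vector<int> v = window_weights(penalty);
  std::vector<int> order = weight_order(v, 0, 22);

  R_xlen_t ng = guides.size();
  NumericVector profile(ng);
  IntegerVector n_best(ng);

  for (R_xlen_t gi = 0; gi < ng; ++gi) {
    const char* gstr = CHAR(STRING_ELT(guides, gi));
    if (strlen(gstr) != 23) stop("guide must have length 23");
    int target[23];  // target[q] = complement of guide base opposite window q
    for (int q = 0; q < 23; ++q) target[q] = comp_code(base_code(gstr[22 - q]));

    int best = SENTINEL;
    long long cnt = 0;
    for (size_t s = 0; s < enc.size(); ++s) {
      const std::vector<int>& sub = enc[s];
      if (sub.size() < 23) continue;
      size_t nwin = sub.size() - 22;
      for (size_t i = 0; i < nwin; ++i) {
        int acc = 0;
        bool pruned = false;
        for (size_t k = 0; k < order.size(); ++k) {
          int q = order[k];
          if (target[q] != sub[i + q]) {
            acc += v[q];
            if (acc > best) { pruned = true; break; }
          }
        }
        if (pruned) continue;
        if (acc < best) { best = acc; cnt = 1; }
        else if (acc == best) ++cnt;
      }
    }
    if (best == SENTINEL) {
      profile[gi] = R_PosInf;
      n_best[gi] = 0;
    } else {
      profile[gi] = best / 1e4;
      n_best[gi] = (int)cnt;
    }
    if (gi % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["profile"] = profile, _["n_best"] = n_best);
}

// Prefix-factored scan for candidate batches sharing a 10-mer prefix.
// The prefix occupies window positions 13..22, the 13-mer suffix positions
// 0..12. Per-window prefix penalties p0 are computed once, windows are
// sorted by p0 ascending, and each suffix stops scanning as soon as p0 alone
// exceeds its current best total (suffix penalties are non-negative).
// [[Rcpp::export]]
List cpp_profile_scan_prefix(std::string prefix, CharacterVector suffixes,
                             CharacterVector subjects, IntegerVector penalty) {
  if (penalty.size() != 23) stop("penalty must have length 23");
  if (prefix.size() != 10) stop("prefix must have length 10");
  std::vector<std::vector<int>> enc = encode_subjects(subjects);
  std::vector<int> v = window_weights(penalty);

  int tprefix[23];  // valid for q = 13..22
  for (int q = 13; q < 23; ++q)
    tprefix[q] = comp_code(base_code(prefix[22 - q]));
  std::vector<int> pref_order = weight_order(v, 13, 22);
  std::vector<int> suff_order = weight_order(v, 0, 12);

  // collect windows and prefix penalties
  std::vector<const int*> win;
  std::vector<int> p0;
  for (size_t s = 0; s < enc.size(); ++s) {
    const std::vector<int>& sub = enc[s];
    if (sub.size() < 23) continue;
    size_t nwin = sub.size() - 22;
    for (size_t i = 0; i < nwin; ++i) {
      const int* w = sub.data() + i;
      int acc = 0;
      for (size_t k = 0; k < pref_order.size(); ++k) {
        int q = pref_order[k];
        if (tprefix[q] != w[q]) acc += v[q];
      }
      win.push_back(w);
      p0.push_back(acc);
    }
  }
  size_t nw = win.size();
  std::vector<int> idx(nw);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return p0[a] < p0[b]; });

  R_xlen_t ns = suffixes.size();
  NumericVector profile(ns);
  IntegerVector n_best(ns);

  for (R_xlen_t si = 0; si < ns; ++si) {
    const char* sstr = CHAR(STRING_ELT(suffixes, si));
    if (strlen(sstr) != 13) stop("suffix must have length 13");
    int target[13];  // target[q] = complement of suffix base opposite window q
    for (int q = 0; q < 13; ++q) target[q] = comp_code(base_code(sstr[12 - q]));

    int best = SENTINEL;
    long long cnt = 0;
    for (size_t k = 0; k < nw; ++k) {
      int wi = idx[k];
      int base_pen = p0[wi];
      if (base_pen > best) break;  // sorted: no later window can tie or win
      const int* w = win[wi];
      int tot = base_pen;
      bool pruned = false;
      for (size_t j = 0; j < suff_order.size(); ++j) {
        int q = suff_order[j];
        if (target[q] != w[q]) {
          tot += v[q];
          if (tot > best) { pruned = true; break; }
        }
      }
      if (pruned) continue;
      if (tot < best) { best = tot; cnt = 1; }
      else if (tot == best) ++cnt;
    }
    if (best == SENTINEL) {
      profile[si] = R_PosInf;
      n_best[si] = 0;
    } else {
      profile[si] = best / 1e4;
      n_best[si] = (int)cnt;
    }
    if (si % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["profile"] = profile, _["n_best"] = n_best);
}
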