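#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Canonical Watson-Crick plus G-U wobble pairs on the RNA alphabet.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing secondary structure (Nussinov-style dynamic
// programming). min_loop is the minimum number of unpaired bases enclosed
// by a hairpin-closing pair, so (i, j) may pair only when j - i > min_loop.
// Traceback is deterministic: pairing is preferred over leaving an end
// unpaired, which is preferred over bifurcation at the smallest split.
// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  const int L = (int) seq.size();
  if (L > 5000) stop("sequence too long for the built-in folding backend (max 5000)");
  std::string structure(L, '.');
  if (L < 2) return List::create(_["structure"] = structure, _["n_bp"] = 0);

  // DP table flattened; M[i*L+j] = max pairs on seq[i..j]
  std::vector<int> M((size_t) L * L, 0);
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      int j = i + span;
      int best = M[(size_t)(i + 1) * L + j];            // i unpaired
      int b2 = M[(size_t) i * L + (j - 1)];             // j unpaired
      if (b2 > best) best = b2;
      if (can_pair(seq[i], seq[j])) {
        int b3 = 1 + (i + 1 <= j - 1 ? M[(size_t)(i + 1) * L + (j - 1)] : 0);
        if (b3 > best) best = b3;
      }
      for (int k = i + 1; k < j; ++k) {                 // bifurcation
        int b4 = M[(size_t) i * L + k] + M[(size_t)(k + 1) * L + j];
        if (b4 > best) best = b4;
      }
      M[(size_t) i * L + j] = best;
    }
  }

  // Traceback (iterative, fixed preference order for determinism).
  int n_bp = 0;
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    int m = M[(size_t) i * L + j];
    if (m == 0) continue;
    if (can_pair(seq[i], seq[j]) &&
        m == 1 + (i + 1 <= j - 1 ? M[(size_t)(i + 1) * L + (j - 1)] : 0)) {
      structure[i] = '(';
      structure[j] = ')';
      ++n_bp;
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (m == M[(size_t)(i + 1) * L + j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    if (m == M[(size_t) i * L + (j - 1)]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    bool split = false;
    for (int k = i + 1; k < j; ++k) {
      if (m == M[(size_t) i * L + k] + M[(size_t)(k + 1) * L + j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        split = true;
        break;
      }
    }
    if (!split) stop("internal error: traceback failed");
  }

  return List::create(_["structure"] = structure, _["n_bp"] = n_bp);
}
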