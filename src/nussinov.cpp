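#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

// Base-pair maximization (Nussinov) over Watson-Crick + GU wobble pairs
// with a minimum hairpin-loop size. Sequences arrive as DNA; T is treated
// as U. 'N' never pairs.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
int nussinov_pairs_cpp(std::string seq, int min_loop) {
  int n = (int) seq.size();
  if (n == 0) return 0;
  for (int i = 0; i < n; ++i) {
    if (seq[i] == 'T') seq[i] = 'U';
  }
  std::vector<int> F((size_t) n * n, 0); // F[i*n+j]
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = F[(size_t)(i + 1) * n + j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(seq[i], seq[k])) {
          int left = (k - 1 >= i + 1) ? F[(size_t)(i + 1) * n + (k - 1)] : 0;
          int right = (k + 1 <= j) ? F[(size_t)(k + 1) * n + j] : 0;
          best = std::max(best, 1 + left + right);
        }
      }
      F[(size_t) i * n + j] = best;
    }
  }
  return F[(size_t) 0 * n + (n - 1)];
}
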