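// Maximum base-pairing (Nussinov) dynamic program with a deterministic
// traceback: position i pairs with the smallest admissible j. Allowed
// pairs: AU, GC, GU wobble; hairpin loops span at least min_loop bases.

#include <Rcpp.h>
#include <vector>
#include <string>

static bool can_pair_cpp(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
std::string cpp_nussinov_fold(const std::string& bases, int min_loop) {
  int L = bases.size();
  std::string db(L, '.');
  if (L == 0) return db;
  std::vector<std::vector<int>> dp(L, std::vector<int>(L, 0));
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      int j = i + span;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {  // i pairs with k
        if (can_pair_cpp(bases[i], bases[k])) {
          int left = (i + 1 <= k - 1) ? dp[i + 1][k - 1] : 0;
          int right = (k + 1 <= j) ? dp[k + 1][j] : 0;
          if (left + 1 + right > best) best = left + 1 + right;
        }
      }
      dp[i][j] = best;
    }
  }
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, L - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || dp[i][j] == 0) continue;
    if (dp[i][j] == dp[i + 1][j]) {  // prefer leaving i unpaired only if optimal
      bool paired = false;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair_cpp(bases[i], bases[k])) {
          int left = (i + 1 <= k - 1) ? dp[i + 1][k - 1] : 0;
          int right = (k + 1 <= j) ? dp[k + 1][j] : 0;
          if (left + 1 + right == dp[i][j]) { paired = true; break; }
        }
      }
      if (!paired) { stack.push_back({i + 1, j}); continue; }
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (can_pair_cpp(bases[i], bases[k])) {
        int left = (i + 1 <= k - 1) ? dp[i + 1][k - 1] : 0;
        int right = (k + 1 <= j) ? dp[k + 1][j] : 0;
        if (left + 1 + right == dp[i][j]) {
          db[i] = '('; db[k] = ')';
          if (i + 1 <= k - 1) stack.push_back({i + 1, k - 1});
          if (k + 1 <= j) stack.push_back({k + 1, j});
          break;
        }
      }
    }
  }
  return db;
}
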