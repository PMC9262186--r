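#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <utility>

// Weighted maximum-pairing folding (Nussinov-style dynamic programme).
// Bases are integer-coded A=0, C=1, G=2, U=3. Pair weights reflect relative
// pair stability: G-C 3, A-U 2, G-U (wobble) 1, everything else 0.

static inline int pair_weight(int a, int b) {
  if (a > b) std::swap(a, b);
  if (a == 1 && b == 2) return 3;  // C-G
  if (a == 0 && b == 3) return 2;  // A-U
  if (a == 2 && b == 3) return 1;  // G-U
  return 0;
}

static void nussinov_pairs(const std::vector<int>& s, int min_loop,
                           std::vector<std::pair<int, int>>& pairs) {
  const int L = (int)s.size();
  pairs.clear();
  if (L == 0) return;

  // M[i][j]: best total weight on s[i..j], stored flat, 0 for empty intervals
  std::vector<int> M((size_t)L * L, 0);
  auto m = [&](int i, int j) -> int {
    return (i > j || i < 0 || j >= L) ? 0 : M[(size_t)i * L + j];
  };

  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      int j = i + span;
      int best = m(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(s[i], s[k]);
        if (w == 0) continue;
        int cand = w + m(i + 1, k - 1) + m(k + 1, j);
        if (cand > best) best = cand;
      }
      M[(size_t)i * L + j] = best;
    }
  }

  // deterministic traceback: prefer pairing i (leftmost partner k) over
  // leaving i unpaired whenever the pairing attains the optimum
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    int target = m(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = pair_weight(s[i], s[k]);
      if (w == 0) continue;
      if (w + m(i + 1, k - 1) + m(k + 1, j) == target) {
        pairs.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix nussinov_fold_cpp(Rcpp::IntegerVector codes, int min_loop) {
  std::vector<int> s(codes.begin(), codes.end());
  std::vector<std::pair<int, int>> pairs;
  nussinov_pairs(s, min_loop, pairs);
  Rcpp::IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stochastic inverse-folding local search against the maximum-pairing folder.
// Moves: compensatory resampling of target pairs, defect-directed repairs of
// spurious/missing pairs, single-base mutations. Acceptance: candidate
// base-pair distance to the target must not increase. Restarts from a fresh
// draw after `stall_limit` non-improving iterations, alternating a diverse
// random draw with a tie-poor one (G-C stems over an all-A background).
// Uses R's RNG stream, so results are reproducible under set.seed().

static const int PAIR5[6] = {2, 1, 0, 3, 2, 3};  // G C A U G U
static const int PAIR3[6] = {1, 2, 3, 0, 3, 2};  // C G U A U G

static inline int runif_int(int n) {
  return (int)(unif_rand() * n) % n;
}

static void keys_of(const std::vector<std::pair<int, int>>& pairs, int L,
                    std::vector<int>& keys) {
  keys.clear();
  for (size_t r = 0; r < pairs.size(); ++r)
    keys.push_back(pairs[r].first * L + pairs[r].second);
  std::sort(keys.begin(), keys.end());
}

static int sym_diff(const std::vector<int>& a, const std::vector<int>& b) {
  size_t i = 0, j = 0;
  int d = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++i; ++j; }
    else if (a[i] < b[j]) { ++d; ++i; }
    else { ++d; ++j; }
  }
  return d + (int)(a.size() - i) + (int)(b.size() - j);
}

// [[Rcpp::export]]
Rcpp::List inverse_fold_search_cpp(Rcpp::IntegerMatrix target_pairs, int L,
                                   int min_loop, int max_iter,
                                   int stall_limit) {
  const int np = target_pairs.nrow();
  std::vector<int> ti(np), tj(np);
  std::vector<int> partner(L, -1);
  std::vector<int> target_keys;
  for (int r = 0; r < np; ++r) {
    ti[r] = target_pairs(r, 0);
    tj[r] = target_pairs(r, 1);
    partner[ti[r]] = tj[r];
    partner[tj[r]] = ti[r];
    target_keys.push_back(ti[r] * L + tj[r]);
  }
  std::sort(target_keys.begin(), target_keys.end());

  // per base, which bases it can pair with (canonical + wobble)
  const bool pairable[4][4] = {
    {false, false, false, true},   // A: U
    {false, false, true, false},   // C: G
    {false, true, false, true},    // G: C, U
    {true, false, true, false}};   // U: A, G

  auto draw_init = [&](bool gc_only, std::vector<int>& codes) {
    codes.resize(L);
    for (int p = 0; p < L; ++p)
      codes[p] = gc_only ? 0 : runif_int(4);
    for (int r = 0; r < np; ++r) {
      int type;
      if (gc_only) {
        type = runif_int(2);
      } else {
        double u = unif_rand();
        type = u < 0.3 ? 0 : u < 0.6 ? 1 : u < 0.75 ? 2 : u < 0.9 ? 3 :
               u < 0.95 ? 4 : 5;
      }
      codes[ti[r]] = PAIR5[type];
      codes[tj[r]] = PAIR3[type];
    }
  };

  std::vector<int> cur, cand, best;
  std::vector<std::pair<int, int>> pairs;
  std::vector<int> fold_keys, cand_keys;

  draw_init(false, cur);
  nussinov_pairs(cur, min_loop, pairs);
  keys_of(pairs, L, fold_keys);
  int cur_d = sym_diff(fold_keys, target_keys);
  best = cur;
  int best_d = cur_d;
  int stall = 0, restarts = 0, it = 0;
  std::vector<int> spurious, missing;

  while (cur_d > 0 && it < max_iter) {
    ++it;
    cand = cur;
    spurious.clear();
    missing.clear();
    {
      size_t i = 0, j = 0;
      while (i < fold_keys.size() && j < target_keys.size()) {
        if (fold_keys[i] == target_keys[j]) { ++i; ++j; }
        else if (fold_keys[i] < target_keys[j]) spurious.push_back(fold_keys[i++]);
        else missing.push_back(target_keys[j++]);
      }
      for (; i < fold_keys.size(); ++i) spurious.push_back(fold_keys[i]);
      for (; j < target_keys.size(); ++j) missing.push_back(target_keys[j]);
    }
    int n_def = (int)(spurious.size() + missing.size());
    if (unif_rand() < 0.8 && n_def > 0) {
      int pick = runif_int(n_def);
      bool is_missing = pick >= (int)spurious.size();
      int key = is_missing ? missing[pick - spurious.size()] : spurious[pick];
      int i = key / L, j = key % L;
      if (is_missing) {
        int type = runif_int(6);
        cand[i] = PAIR5[type];
        cand[j] = PAIR3[type];
      } else {
        bool i_free = partner[i] < 0, j_free = partner[j] < 0;
        if (!i_free && !j_free) {
          int side = unif_rand() < 0.5 ? i : j;
          int p5 = std::min(side, partner[side]);
          int p3 = std::max(side, partner[side]);
          int type = runif_int(6);
          cand[p5] = PAIR5[type];
          cand[p3] = PAIR3[type];
        } else {
          int side, other;
          if (i_free && j_free) {
            if (unif_rand() < 0.5) { side = i; other = j; }
            else { side = j; other = i; }
          } else if (i_free) { side = i; other = j; }
          else { side = j; other = i; }
          // bases that cannot pair the opposite side, excluding the current
          // one; prefer A so loop/linker complementarity dies out
          int opts[4], w[4], n_opt = 0, wtot = 0;
          for (int b = 0; b < 4; ++b) {
            if (b == cand[side] || pairable[b][cand[other]]) continue;
            opts[n_opt] = b;
            w[n_opt] = (b == 0) ? 3 : 1;
            wtot += w[n_opt];
            ++n_opt;
          }
          if (n_opt > 0) {
            double u = unif_rand() * wtot;
            int acc = 0, chosen = opts[0];
            for (int t = 0; t < n_opt; ++t) {
              acc += w[t];
              if (u < acc) { chosen = opts[t]; break; }
            }
            cand[side] = chosen;
          }
        }
      }
    } else if (np > 0 && unif_rand() < 0.7) {
      int r = runif_int(np);
      int type = runif_int(6);
      cand[ti[r]] = PAIR5[type];
      cand[tj[r]] = PAIR3[type];
    } else {
      int pos = runif_int(L);
      int b = runif_int(3);
      cand[pos] = (b >= cand[pos]) ? b + 1 : b;
    }
    nussinov_pairs(cand, min_loop, pairs);
    keys_of(pairs, L, cand_keys);
    int d = sym_diff(cand_keys, target_keys);
    if (d <= cur_d) {
      if (d < cur_d) stall = 0;
      cur = cand;
      cur_d = d;
      fold_keys = cand_keys;
    }
    ++stall;
    if (cur_d > 0 && stall >= stall_limit) {
      ++restarts;
      draw_init(restarts % 2 == 1, cur);
      nussinov_pairs(cur, min_loop, pairs);
      keys_of(pairs, L, fold_keys);
      cur_d = sym_diff(fold_keys, target_keys);
      stall = 0;
    }
    if (cur_d < best_d) {
      best = cur;
      best_d = cur_d;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("codes") = Rcpp::IntegerVector(best.begin(), best.end()),
    Rcpp::Named("distance") = best_d,
    Rcpp::Named("iterations") = it);
}
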