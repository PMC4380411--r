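// Minimum-free-energy RNA secondary structure prediction.
//
// Zuker-style dynamic program over a nearest-neighbor model:
//   * Watson-Crick + G:U pairs, stacking free energies from a 6x6 table;
//   * affine hairpin-loop penalty (any size >= minHairpin);
//   * affine interior/bulge penalty with an asymmetry term, each side
//     capped at maxIntlSide unpaired bases (larger interior loops are
//     outside the model);
//   * affine multiloop penalty (closure + per-branch + per-unpaired);
//   * exterior unpaired bases are free; no dangles, no coaxial stacking,
//     no pseudoknots.
//
// Energies are handled internally as integer centi-kcal/mol so that
// minima and tie-breaks are exact. Tie-break: every minimization scans
// candidates in a fixed order and keeps the FIRST optimum, with the
// exterior recursion scanning 5'->3', so among co-optimal structures the
// one pairing the leftmost 5' base is produced. Output is deterministic.

#include <Rcpp.h>
#include <vector>
#include <climits>
#include <cstdlib>

using namespace Rcpp;

static const int INF = INT_MAX / 4;
static const int LIM = INT_MAX / 8;  // validity cutoff for sums with INF

// base encoding: A=0, C=1, G=2, U=3
static inline int encodeBase(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// pair types: AU=0 CG=1 GC=2 UA=3 GU=4 UG=5, -1 if not pairable
static inline int pairType(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 3 && b == 0) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  int stack[6][6];      // centi-kcal
  int hairpinA, hairpinB;
  int intlA, intlB, intlAsym;
  int maxIntlSide;
  int multiA, multiB, multiC;
  int minHairpin;
};

static inline int hairpinE(const Params &p, int size) {
  return p.hairpinA + p.hairpinB * (size - 3);
}

static inline int interiorE(const Params &p, int n1, int n2) {
  return p.intlA + p.intlB * (n1 + n2) + p.intlAsym * std::abs(n1 - n2);
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, List params) {
  const int n = (int) seq.size();

  Params P;
  NumericMatrix st = params["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      P.stack[a][b] = (int) lround(100.0 * st(a, b));
  P.hairpinA  = (int) lround(100.0 * as<double>(params["hairpin_a"]));
  P.hairpinB  = (int) lround(100.0 * as<double>(params["hairpin_b"]));
  P.intlA     = (int) lround(100.0 * as<double>(params["intl_a"]));
  P.intlB     = (int) lround(100.0 * as<double>(params["intl_b"]));
  P.intlAsym  = (int) lround(100.0 * as<double>(params["intl_asym"]));
  P.maxIntlSide = as<int>(params["max_intl_side"]);
  P.multiA    = (int) lround(100.0 * as<double>(params["multi_a"]));
  P.multiB    = (int) lround(100.0 * as<double>(params["multi_b"]));
  P.multiC    = (int) lround(100.0 * as<double>(params["multi_c"]));
  P.minHairpin = as<int>(params["min_hairpin"]);

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = encodeBase(seq[i]);
    if (s[i] < 0) stop("invalid character in sequence: '%c'", seq[i]);
  }

  std::string db(n, '.');
  if (n < P.minHairpin + 2) {
    return List::create(_["structure"] = db, _["mfe"] = 0.0);
  }

  // V[i*n+j]: min energy of [i,j] given i pairs j; WM[i*n+j]: min energy
  // of a multiloop segment on [i,j] containing >= 1 branch. WMT is the
  // transposed copy of WM (column access made contiguous). INF is kept
  // small enough that INF + INF does not overflow, so the hot loops can
  // add first and compare once instead of branching on INF.
  std::vector<int> V((size_t) n * n, INF), WM((size_t) n * n, INF),
                   WMT((size_t) n * n, INF);
  std::vector<int> ptab((size_t) n * n, -1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      ptab[(size_t) i * n + j] = pairType(s[i], s[j]);

  for (int span = P.minHairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int pt = ptab[(size_t) i * n + j];
      if (pt >= 0) {
        int best = hairpinE(P, j - i - 1);
        // stack + interior/bulge loops
        const int kmax = std::min(i + 1 + P.maxIntlSide, j - 1);
        for (int k = i + 1; k <= kmax; ++k) {
          const int *Vk = &V[(size_t) k * n];
          const int lmin = std::max(k + P.minHairpin + 1,
                                    j - 1 - P.maxIntlSide);
          const int n1 = k - i - 1;
          if (n1 == 0) {
            // stack candidate at l = j-1, interior for l < j-1
            int pt2 = ptab[(size_t) k * n + (j - 1)];
            if (pt2 >= 0) {
              int e = P.stack[pt][pt2] + Vk[j - 1];
              if (e < best) best = e;
            }
            for (int l = j - 2; l >= lmin; --l) {
              int e = interiorE(P, 0, j - l - 1) + Vk[l];
              if (e < best) best = e;
            }
          } else {
            for (int l = j - 1; l >= lmin; --l) {
              int e = interiorE(P, n1, j - l - 1) + Vk[l];
              if (e < best) best = e;
            }
          }
        }
        // multiloop closed by (i,j): >= 2 branches inside
        {
          const int *rowA = &WM[(size_t) (i + 1) * n];
          const int *colB = &WMT[(size_t) (j - 1) * n];
          int mbest = INF;
          for (int k = i + 1; k < j - 1; ++k) {
            int e = rowA[k] + colB[k + 1];
            if (e < mbest) mbest = e;
          }
          if (mbest < LIM && P.multiA + P.multiB + mbest < best)
            best = P.multiA + P.multiB + mbest;
        }
        V[(size_t) i * n + j] = best;
      }
      // WM
      int w = INF;
      {
        int v = V[(size_t) i * n + j];
        if (v < INF) w = v + P.multiB;
        int a = WM[(size_t) (i + 1) * n + j];
        if (a < INF && a + P.multiC < w) w = a + P.multiC;
        int bb = WM[(size_t) i * n + (j - 1)];
        if (bb < INF && bb + P.multiC < w) w = bb + P.multiC;
        const int *rowA = &WM[(size_t) i * n];
        const int *colB = &WMT[(size_t) j * n];
        int sbest = INF;
        for (int k = i; k < j; ++k) {
          int e = rowA[k] + colB[k + 1];
          if (e < sbest) sbest = e;
        }
        if (sbest < w) w = sbest;
      }
      // sums involving an INF operand can land below INF; anything this
      // large is not a real energy, clamp back to INF
      if (w >= LIM) w = INF;
      WM[(size_t) i * n + j] = w;
      WMT[(size_t) j * n + i] = w;
    }
  }

  // exterior loop
  std::vector<int> W(n + 1, 0);
  std::vector<int> Wch(n + 1, -1);  // k (1-based pos of paired start) or -1 = j unpaired
  for (int j = 1; j <= n; ++j) {
    int best = W[j - 1];
    int choice = -1;
    for (int k = 1; k <= j; ++k) {
      if (V[(size_t) (k - 1) * n + (j - 1)] >= INF) continue;
      int e = W[k - 1] + V[(size_t) (k - 1) * n + (j - 1)];
      if (e < best) { best = e; choice = k; }
    }
    W[j] = best;
    Wch[j] = choice;
  }

  // --- traceback ---
  struct Seg { int i, j, state; };  // state 0 = V, 1 = WM
  std::vector<Seg> stack_;

  // exterior
  {
    int j = n;
    while (j > 0) {
      if (Wch[j] == -1) { --j; continue; }
      // leftmost-preferring: recompute choosing the SMALLEST k achieving W[j]
      int pick = -1;
      for (int k = 1; k <= j; ++k) {
        if (V[(size_t) (k - 1) * n + (j - 1)] >= INF) continue;
        if (W[k - 1] + V[(size_t) (k - 1) * n + (j - 1)] == W[j]) { pick = k; break; }
      }
      if (pick == -1) { --j; continue; }
      stack_.push_back({pick - 1, j - 1, 0});
      j = pick - 1;
    }
  }

  while (!stack_.empty()) {
    Seg sg = stack_.back(); stack_.pop_back();
    int i = sg.i, j = sg.j;
    if (sg.state == 0) {
      db[i] = '('; db[j] = ')';
      int pt = pairType(s[i], s[j]);
      int target = V[(size_t) (i) * n + (j)];
      if (target == hairpinE(P, j - i - 1)) continue;
      bool found = false;
      int kmax = std::min(i + 1 + P.maxIntlSide, j - 1);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int lmin = std::max(k + P.minHairpin + 1, j - 1 - P.maxIntlSide);
        for (int l = j - 1; l >= lmin; --l) {
          if (V[(size_t) (k) * n + (l)] >= INF) continue;
          int n1 = k - i - 1, n2 = j - l - 1;
          int e;
          if (n1 == 0 && n2 == 0) {
            e = P.stack[pt][pairType(s[k], s[l])] + V[(size_t) (k) * n + (l)];
          } else {
            e = interiorE(P, n1, n2) + V[(size_t) (k) * n + (l)];
          }
          if (e == target) { stack_.push_back({k, l, 0}); found = true; break; }
        }
      }
      if (found) continue;
      for (int k = i + 1; k < j - 1; ++k) {
        if (WM[(size_t) (i + 1) * n + (k)] >= INF || WM[(size_t) (k + 1) * n + (j - 1)] >= INF) continue;
        if (P.multiA + P.multiB + WM[(size_t) (i + 1) * n + (k)] + WM[(size_t) (k + 1) * n + (j - 1)] == target) {
          stack_.push_back({i + 1, k, 1});
          stack_.push_back({k + 1, j - 1, 1});
          found = true; break;
        }
      }
      if (!found) stop("traceback failure in V");
    } else {
      int target = WM[(size_t) (i) * n + (j)];
      if (target >= INF) stop("traceback failure in WM");
      if (V[(size_t) (i) * n + (j)] < INF && V[(size_t) (i) * n + (j)] + P.multiB == target) {
        stack_.push_back({i, j, 0});
        continue;
      }
      if (i + 1 <= j && WM[(size_t) (i + 1) * n + (j)] < INF && WM[(size_t) (i + 1) * n + (j)] + P.multiC == target) {
        stack_.push_back({i + 1, j, 1});
        continue;
      }
      if (j - 1 >= i && WM[(size_t) (i) * n + (j - 1)] < INF && WM[(size_t) (i) * n + (j - 1)] + P.multiC == target) {
        stack_.push_back({i, j - 1, 1});
        continue;
      }
      bool found = false;
      for (int k = i; k < j; ++k) {
        if (WM[(size_t) (i) * n + (k)] >= INF || WM[(size_t) (k + 1) * n + (j)] >= INF) continue;
        if (WM[(size_t) (i) * n + (k)] + WM[(size_t) (k + 1) * n + (j)] == target) {
          stack_.push_back({i, k, 1});
          stack_.push_back({k + 1, j, 1});
          found = true; break;
        }
      }
      if (!found) stop("traceback failure in WM split");
    }
  }

  return List::create(_["structure"] = db,
                      _["mfe"] = W[n] / 100.0);
}
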