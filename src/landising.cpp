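#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// logistic of -dE, computed on the stable branch
static inline double flip_prob(double dE) {
  if (dE > 0.0) {
    double e = std::exp(-dE);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(dE));
}

// Single-flip Glauber dynamics on a d x d torus.
// states: square matrix over {-1, +1}; n_steps attempted flips.
// The acceptance probability depends only on (x, S) with S in {-4,-2,0,2,4},
// so the ten probabilities are precomputed; the noise-suppression constant Q
// enters only for a background cell whose four neighbours are all background.
// Uses R's RNG so trajectories are reproducible via set.seed().
// [[Rcpp::export]]
IntegerMatrix glauber_run_cpp(IntegerMatrix states, double B, double J,
                              double Q, double n_steps) {
  int d = states.nrow();
  if (states.ncol() != d) stop("landscape must be square");
  if (d < 2) stop("landscape side must be at least 2");
  IntegerMatrix s = clone(states);
  int *sp = INTEGER(s);
  const int n = d * d;

  double p[2][5]; // [x==-1 ? 0 : 1][(S+4)/2]
  for (int xi = 0; xi < 2; ++xi) {
    for (int si = 0; si < 5; ++si) {
      double x = (xi == 0) ? -1.0 : 1.0;
      double S = -4.0 + 2.0 * si;
      double dE = 2.0 * x * (J * S + B);
      if (xi == 0 && si == 0) dE += Q; // x = -1 with all-background hood
      p[xi][si] = flip_prob(dE);
    }
  }

  std::vector<int> up(d), dn(d);
  for (int i = 0; i < d; ++i) {
    up[i] = (i + d - 1) % d;
    dn[i] = (i + 1) % d;
  }

  long long N = (long long)n_steps;
  for (long long t = 0; t < N; ++t) {
    int cell = (int)(unif_rand() * n);
    if (cell >= n) cell = n - 1;
    int r = cell % d, c = cell / d;
    int S = sp[up[r] + c * d] + sp[dn[r] + c * d] +
            sp[r + up[c] * d] + sp[r + dn[c] * d];
    int xi = (sp[cell] > 0) ? 1 : 0;
    double u = unif_rand();
    if (u < p[xi][(S + 4) / 2]) sp[cell] = -sp[cell];
  }
  return s;
}

// Connected-components labelling of focus (+1) cells on the plane (no torus
// wrap). Iterative stack-based fill; connectivity 4 (von Neumann) or 8.
// Background gets label 0; patches are numbered in column-major scan order.
// [[Rcpp::export]]
IntegerMatrix label_patches_cpp(IntegerMatrix states, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = states.nrow(), nc = states.ncol();
  IntegerMatrix lab(nr, nc);
  const int *sp = INTEGER(states);
  int *lp = INTEGER(lab);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int idx0 = r0 + c0 * nr;
      if (sp[idx0] != 1 || lp[idx0] != 0) continue;
      ++next;
      lp[idx0] = next;
      stack.push_back(idx0);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int j = rr + cc * nr;
            if (sp[j] == 1 && lp[j] == 0) {
              lp[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return lab;
}
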