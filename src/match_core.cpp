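// Hot core of the pharmacophore matcher: exhaustive enumeration of
// injective, kind-respecting feature correspondences with Kabsch RMSD.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// RMSD after optimal proper rotation, centered inputs. Residuals are
// evaluated through the explicit rotation rather than the trace identity
// (ssP + ssQ - 2*tr), which loses half the significant digits to
// cancellation for near-perfect superpositions.
static double kabsch_rmsd(const arma::mat& Pc, const arma::mat& Qc) {
  arma::mat H = Qc.t() * Pc;          // 3x3
  arma::vec s;
  arma::mat U, V;
  if (!arma::svd(U, s, V, H)) return arma::datum::inf;
  arma::mat R = V * U.t();
  if (arma::det(R) < 0) {             // enforce a proper rotation
    V.col(2) *= -1.0;
    R = V * U.t();
  }
  arma::mat resid = Pc - Qc * R.t();
  return std::sqrt(arma::accu(resid % resid) / Pc.n_rows);
}

// next k-permutation of {0..n-1} in lexicographic order over index vectors;
// perm holds k distinct values; returns false when exhausted
static bool next_kperm(std::vector<int>& perm, int n, int k) {
  // increment positions from the right, skipping used values
  std::vector<bool> used(n, false);
  for (int i = 0; i < k; ++i) used[perm[i]] = true;
  for (int pos = k - 1; pos >= 0; --pos) {
    used[perm[pos]] = false;
    for (int v = perm[pos] + 1; v < n; ++v) {
      if (!used[v]) {
        perm[pos] = v;
        used[v] = true;
        // fill the tail with the smallest unused values
        for (int j = pos + 1; j < k; ++j) {
          for (int w = 0; w < n; ++w) {
            if (!used[w]) { perm[j] = w; used[w] = true; break; }
          }
        }
        return true;
      }
    }
  }
  return false;
}

static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] < b[i]) return true;
    if (a[i] > b[i]) return false;
  }
  return false;
}

// [[Rcpp::export(name = ".match_core")]]
List match_core(const arma::mat& M, const arma::mat& don,
                const arma::mat& acc, int k_d, int k_a,
                const IntegerVector& don_atom,
                const IntegerVector& acc_atom) {
  const int n_d = don.n_rows, n_a = acc.n_rows;
  const int k = k_d + k_a;
  arma::mat Mc = M.each_row() - arma::mean(M, 0);
  arma::vec normM(k);
  for (int i = 0; i < k; ++i) normM(i) = arma::norm(Mc.row(i), 2);

  std::vector<int> pd(k_d), pa(k_a);
  for (int i = 0; i < k_d; ++i) pd[i] = i;
  double best = arma::datum::inf;
  std::vector<int> best_atoms;
  arma::mat Q(k, 3);
  std::vector<int> atoms(k);

  bool more_d = true;
  while (more_d) {
    for (int i = 0; i < k_d; ++i) Q.row(i) = don.row(pd[i]);
    for (int i = 0; i < k_a; ++i) pa[i] = i;
    bool more_a = true;
    while (more_a) {
      for (int i = 0; i < k_a; ++i) Q.row(k_d + i) = acc.row(pa[i]);
      arma::rowvec cq = arma::mean(Q, 0);
      arma::mat Qc = Q.each_row() - cq;
      // norms about the centroid are rotation-invariant: lower bound
      double lb2 = 0;
      for (int i = 0; i < k; ++i) {
        double dnm = normM(i) - arma::norm(Qc.row(i), 2);
        lb2 += dnm * dnm;
      }
      lb2 /= k;
      if (!std::isfinite(best) || lb2 <= best * best + 1e-9) {
        double r = kabsch_rmsd(Mc, Qc);
        for (int i = 0; i < k_d; ++i) atoms[i] = don_atom[pd[i]];
        for (int i = 0; i < k_a; ++i) atoms[k_d + i] = acc_atom[pa[i]];
        if (r < best - 1e-12 ||
            (std::abs(r - best) <= 1e-12 && !best_atoms.empty() &&
             lex_less(atoms, best_atoms))) {
          best = r;
          best_atoms = atoms;
        }
      }
      more_a = (k_a > 0) && next_kperm(pa, n_a, k_a);
    }
    more_d = (k_d > 0) && next_kperm(pd, n_d, k_d);
    if (k_d == 0) break;
  }
  if (!std::isfinite(best))
    return List::create(_["rmsd"] = NA_REAL,
                        _["atoms"] = IntegerVector(0));
  return List::create(_["rmsd"] = best,
                      _["atoms"] = IntegerVector(best_atoms.begin(),
                                                 best_atoms.end()));
}
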