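#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Out-of-fold KNN accuracy and autism probability for every scalar
// feature in X (subjects x features). Each feature gets its own KNN
// classifier on absolute distance; all features share one fold
// assignment. Distance ties are broken by tie_rank (a seeded
// permutation supplied from R) so results are deterministic.
//
// y: 1 = ASD (positive), 0 = TD. prob = fraction of the k nearest
// training subjects labelled ASD; predicted ASD iff prob > 0.5
// (exact 0.5 resolves to TD). With resubstitution = true the
// classifier is trained and evaluated on the full cohort (the subject
// itself is an eligible neighbour).
// [[Rcpp::export]]
List local_knn_grid_cpp(NumericMatrix X, IntegerVector y,
                        IntegerVector fold, IntegerVector tie_rank,
                        int k, bool resubstitution = false) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n || fold.size() != n || tie_rank.size() != n)
    stop("y, fold and tie_rank must have one entry per subject");
  if (k < 1) stop("k must be positive");

  int n_folds = 0;
  for (int i = 0; i < n; ++i) n_folds = std::max(n_folds, fold[i]);

  // index lists per fold
  std::vector<std::vector<int> > test_idx(n_folds);
  for (int i = 0; i < n; ++i) test_idx[fold[i] - 1].push_back(i);
  for (int f = 0; f < n_folds; ++f) {
    int n_train = resubstitution ? n : n - (int)test_idx[f].size();
    if (k > n_train)
      stop("k exceeds the number of training subjects in a fold");
  }

  NumericVector accuracy(p);
  NumericMatrix prob(n, p);

  struct Neigh { double d; int rank; int lab; };
  std::vector<Neigh> cand;
  cand.reserve(n);

  for (int j = 0; j < p; ++j) {
    const double *xj = &X(0, j);
    int correct = 0;
    for (int f = 0; f < n_folds; ++f) {
      const std::vector<int> &test = test_idx[f];
      for (size_t t = 0; t < test.size(); ++t) {
        int i = test[t];
        cand.clear();
        for (int m = 0; m < n; ++m) {
          bool in_train = resubstitution ? true : (fold[m] - 1 != f);
          if (!in_train) continue;
          Neigh nb;
          nb.d = std::fabs(xj[m] - xj[i]);
          nb.rank = tie_rank[m];
          nb.lab = y[m];
          cand.push_back(nb);
        }
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end(),
                          [](const Neigh &a, const Neigh &b) {
                            if (a.d != b.d) return a.d < b.d;
                            return a.rank < b.rank;
                          });
        int pos = 0;
        for (int m = 0; m < k; ++m) pos += cand[m].lab;
        double pr = (double)pos / k;
        prob(i, j) = pr;
        int pred = pr > 0.5 ? 1 : 0;
        if (pred == y[i]) ++correct;
      }
    }
    accuracy[j] = (double)correct / n;
  }
  return List::create(_["accuracy"] = accuracy, _["prob"] = prob);
}
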