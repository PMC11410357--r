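#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double cosdist(const double *u, const double *v, int D) {
  double dot = 0.0, nu = 0.0, nv = 0.0;
  for (int d = 0; d < D; ++d) {
    dot += u[d] * v[d];
    nu += u[d] * u[d];
    nv += v[d] * v[d];
  }
  if (nu == 0.0 || nv == 0.0) return NA_REAL;
  return 1.0 - dot / std::sqrt(nu * nv);
}

// Scores every leave-two-out pair against a (possibly permuted) target
// matrix, reusing per-fold prediction operators computed once from the
// sensor features. folds[[f]] is a numeric array (2, ntr, D): the linear map
// sending the standardized training targets to the standardized predictions
// of the two held-out rows, with the fold's selected per-dimension alphas
// already baked in. Target standardization (training rows only, sd with
// n-1 denominator, constant columns scaled by 1) is recomputed here because
// it depends on the target matrix being scored.
// [[Rcpp::export(name = ".eval_pairs_cached")]]
NumericVector eval_pairs_cached(List folds, List train_idx,
                                IntegerMatrix pairs, NumericMatrix Y) {
  const int npairs = pairs.nrow();
  const int D = Y.ncol();
  NumericVector out(npairs);
  std::vector<double> mu(D), sd(D), p1(D), p2(D);

  for (int f = 0; f < npairs; ++f) {
    NumericVector M = folds[f];
    IntegerVector tr = train_idx[f];
    const int ntr = tr.size();
    for (int j = 0; j < D; ++j) {
      double s = 0.0;
      for (int i = 0; i < ntr; ++i) s += Y(tr[i] - 1, j);
      mu[j] = s / ntr;
      double ss = 0.0;
      for (int i = 0; i < ntr; ++i) {
        double e = Y(tr[i] - 1, j) - mu[j];
        ss += e * e;
      }
      sd[j] = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 1.0;
      if (sd[j] == 0.0) sd[j] = 1.0;
    }
    // M is laid out (k, i, j): k fastest, then training row, then dimension
    const double *m = REAL(M);
    for (int j = 0; j < D; ++j) {
      double a1 = 0.0, a2 = 0.0;
      const double *mj = m + (size_t)2 * ntr * j;
      for (int i = 0; i < ntr; ++i) {
        double ys = (Y(tr[i] - 1, j) - mu[j]) / sd[j];
        a1 += mj[2 * i] * ys;
        a2 += mj[2 * i + 1] * ys;
      }
      p1[j] = a1 * sd[j] + mu[j];
      p2[j] = a2 * sd[j] + mu[j];
    }
    const int i1 = pairs(f, 0) - 1, i2 = pairs(f, 1) - 1;
    std::vector<double> t1(D), t2(D);
    for (int j = 0; j < D; ++j) {
      t1[j] = Y(i1, j);
      t2[j] = Y(i2, j);
    }
    double matched = cosdist(p1.data(), t1.data(), D) +
                     cosdist(p2.data(), t2.data(), D);
    double crossed = cosdist(p1.data(), t2.data(), D) +
                     cosdist(p2.data(), t1.data(), D);
    if (ISNAN(matched) || ISNAN(crossed))
      out[f] = NA_REAL;
    else if (matched < crossed)
      out[f] = 1.0;
    else if (matched > crossed)
      out[f] = 0.0;
    else
      out[f] = 0.5;
  }
  return out;
}
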