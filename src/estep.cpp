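#include <Rcpp.h>
using namespace Rcpp;

// E-step kernels for the bifactor EM. A "block" is the joint quadrature grid
// over the general factor and one connected set of specific factors; these
// loops avoid materialising the chain of n x M temporaries that the pure-R
// formulation would create. Raw pointer arithmetic matters here: these inner
// loops dominate the EM cycle time on full-size models.

// Likelihood of each respondent at every block grid point, and its collapse
// onto the general-factor margin.
// X: n x Jb item codes (1..K_j) for the items of this block;
// P: list of K_j x M category probability matrices;
// ws: specific-dimension weight per grid point (length M);
// gofm: 1-based index of each grid point's general-factor node (length M).
// [[Rcpp::export]]
List block_lik(IntegerMatrix X, List P, NumericVector ws,
               IntegerVector gofm, int ng) {
  const int n = X.nrow(), Jb = X.ncol(), M = ws.size();
  NumericMatrix L(n, M), Lg(n, ng);
  std::fill(L.begin(), L.end(), 1.0);
  double* Lp = L.begin();
  for (int j = 0; j < Jb; ++j) {
    NumericMatrix Pj = P[j];
    const double* Pp = Pj.begin();
    const int K = Pj.nrow();
    const int* xcol = &X(0, j);
    for (int m = 0; m < M; ++m) {
      double* Lcol = Lp + (size_t)m * n;
      const double* pcol = Pp + (size_t)m * K;
      for (int i = 0; i < n; ++i) Lcol[i] *= pcol[xcol[i] - 1];
    }
  }
  double* Lgp = Lg.begin();
  const int* gm = gofm.begin();
  const double* wsp = ws.begin();
  for (int m = 0; m < M; ++m) {
    double* Lgcol = Lgp + (size_t)(gm[m] - 1) * n;
    const double* Lcol = Lp + (size_t)m * n;
    const double w = wsp[m];
    for (int i = 0; i < n; ++i) Lgcol[i] += w * Lcol[i];
  }
  return List::create(_["L"] = L, _["Lg"] = Lg);
}

// Joint posterior over the block grid: post(i,m) =
//   outer(i, g(m)) * ws[m] * L(i, m),
// where outer carries the other blocks' likelihood, the general-factor prior
// weight, and the 1/L_i normalisation.
// [[Rcpp::export]]
NumericMatrix block_post(NumericMatrix L, NumericMatrix outer_g,
                         NumericVector ws, IntegerVector gofm) {
  const int n = L.nrow(), M = L.ncol();
  NumericMatrix post(n, M);
  const double* Lp = L.begin();
  const double* Op = outer_g.begin();
  double* pp = post.begin();
  const int* gm = gofm.begin();
  const double* wsp = ws.begin();
  for (int m = 0; m < M; ++m) {
    const double* ocol = Op + (size_t)(gm[m] - 1) * n;
    const double* Lcol = Lp + (size_t)m * n;
    double* pcol = pp + (size_t)m * n;
    const double w = wsp[m];
    for (int i = 0; i < n; ++i) pcol[i] = ocol[i] * w * Lcol[i];
  }
  return post;
}

// Expected count tables r_j (K_j x M) for every item of a block in one pass.
// [[Rcpp::export]]
List block_counts(IntegerMatrix X, NumericMatrix post, IntegerVector K) {
  const int n = X.nrow(), Jb = X.ncol(), M = post.ncol();
  const double* pp = post.begin();
  List out(Jb);
  for (int j = 0; j < Jb; ++j) {
    const int Kj = K[j];
    NumericMatrix r(Kj, M);
    double* rp = r.begin();
    const int* xcol = &X(0, j);
    for (int m = 0; m < M; ++m) {
      const double* pcol = pp + (size_t)m * n;
      double* rcol = rp + (size_t)m * Kj;
      for (int i = 0; i < n; ++i) rcol[xcol[i] - 1] += pcol[i];
    }
    out[j] = r;
  }
  return out;
}
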