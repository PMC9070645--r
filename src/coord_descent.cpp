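#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent with covariance updates for
//   (1/2n) || y - b0 - X b ||^2 + lambda * P(b),
// P = 0.5 ||b||^2 (ridge) or ||b||_1 (lasso), on column-standardized X.
// Inputs are the sufficient statistics XtX = X'X/n and Xty = X'(y - ybar)/n;
// the intercept is unpenalized and equals ybar, so it never enters here.
// Coefficients are warm-started along the (decreasing) lambda path.
//
// [[Rcpp::export(name = ".cd_path")]]
List cd_path(NumericMatrix XtX, NumericVector Xty, NumericVector lambda,
             bool lasso, double tol, int maxit, double ytyn) {
  int p = Xty.size();
  int nlam = lambda.size();
  NumericMatrix beta(p, nlam);
  std::vector<double> b(p, 0.0);
  std::vector<double> s(p, 0.0);   // s = (X'X/n) b
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);
  std::vector<double> objTrace;

  for (int l = 0; l < nlam; ++l) {
    double lam = lambda[l];
    bool ok = false;
    int it = 0;
    for (it = 0; it < maxit; ++it) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        double d = XtX(j, j);
        if (d <= 0) { b[j] = 0.0; continue; }   // zero-sd column
        double c = Xty[j] - s[j] + d * b[j];
        double bnew;
        if (lasso) {
          double a = fabs(c) - lam;
          bnew = (a > 0) ? ((c > 0 ? a : -a) / d) : 0.0;
        } else {
          bnew = c / (d + lam);
        }
        double del = bnew - b[j];
        if (del != 0.0) {
          b[j] = bnew;
          for (int k = 0; k < p; ++k) s[k] += XtX(k, j) * del;
          if (fabs(del) > maxdel) maxdel = fabs(del);
        }
      }
      if (nlam == 1) {
        double fit = 0.0, pen = 0.0;
        for (int j = 0; j < p; ++j) {
          fit += b[j] * (0.5 * s[j] - Xty[j]);
          pen += lasso ? fabs(b[j]) : 0.5 * b[j] * b[j];
        }
        objTrace.push_back(0.5 * ytyn + fit + lam * pen);
      }
      if (maxdel < tol) { ok = true; break; }
    }
    iters[l] = it + 1;
    conv[l] = ok;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = conv,
                      _["objective"] = wrap(objTrace));
}
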