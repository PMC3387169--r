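#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase (forward-backward) IIR filtering along the ROWS of a V x T
// matrix, with odd-symmetric edge padding of length npad (MATLAB-style
// filtfilt edge handling). Filtering along rows keeps the voxel-major
// memory layout of BOLD matrices and avoids transposes.

// [[Rcpp::export(name = ".filtfilt_rows_cpp")]]
NumericMatrix filtfilt_rows_cpp(NumericVector b, NumericVector a,
                                NumericMatrix X, int npad) {
  const int n = a.size();
  const int V = X.nrow(), tt = X.ncol();
  if (npad > tt - 1) npad = tt - 1;
  const int T2 = tt + 2 * npad;
  NumericMatrix Y(V, tt);
  std::vector<double> x(T2), y(T2), z((size_t)(n - 1));

  for (int v = 0; v < V; ++v) {
    // odd reflection: x[-i] = 2*x[0] - x[i]
    for (int i = 0; i < npad; ++i)
      x[i] = 2.0 * X(v, 0) - X(v, npad - i);
    for (int t = 0; t < tt; ++t) x[npad + t] = X(v, t);
    for (int i = 0; i < npad; ++i)
      x[npad + tt + i] = 2.0 * X(v, tt - 1) - X(v, tt - 2 - i);

    // forward pass
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < T2; ++t) {
      const double xt = x[t];
      const double yt = b[0] * xt + z[0];
      for (int i = 0; i < n - 2; ++i)
        z[i] = z[i + 1] + b[i + 1] * xt - a[i + 1] * yt;
      z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
      y[t] = yt;
    }
    // backward pass
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = T2 - 1; t >= 0; --t) {
      const double xt = y[t];
      const double yt = b[0] * xt + z[0];
      for (int i = 0; i < n - 2; ++i)
        z[i] = z[i + 1] + b[i + 1] * xt - a[i + 1] * yt;
      z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
      x[t] = yt;
    }
    for (int t = 0; t < tt; ++t) Y(v, t) = x[npad + t];
  }
  return Y;
}
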