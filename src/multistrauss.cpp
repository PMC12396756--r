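#include <Rcpp.h>
using namespace Rcpp;

// canonical index of the unordered type pair (a,b), 0-based, pairs ordered
// (0,0),(0,1),...,(0,C-1),(1,1),...,(C-1,C-1)
static inline int pair_index(int a, int b, int C) {
  if (a > b) std::swap(a, b);
  return a * C - a * (a - 1) / 2 + (b - a);
}

// distance bin: -2 below the hardcore, -1 beyond the last breakpoint,
// otherwise 0..m-1 with half-open bins [r_{k-1}, r_k) and the last closed
static inline int bin_of(double d, double rh, const NumericVector& br) {
  if (d < rh) return -2;
  int m = br.size();
  if (d > br[m - 1]) return -1;
  for (int k = 0; k < m; k++) if (d < br[k]) return k;
  return m - 1; // d == br[m-1]
}

// Neighbor counts by type and distance bin for a set of query locations.
// ct is 1-based type codes; exclude[i] is a 1-based cell index to leave out
// of query i's counts (0 = none). Column layout of the result: bin-major,
// type-fastest, i.e. column k*ntypes + j holds counts of type j+1 in bin k+1.
// [[Rcpp::export]]
List cpp_neighbor_counts(NumericVector qx, NumericVector qy,
                         NumericVector cx, NumericVector cy,
                         IntegerVector ct, int ntypes,
                         double rh, NumericVector breaks,
                         IntegerVector exclude) {
  int nq = qx.size(), nc = cx.size(), m = breaks.size();
  double rmax = breaks[m - 1], rmax2 = rmax * rmax, rh2 = rh * rh;
  IntegerMatrix counts(nq, ntypes * m);
  LogicalVector hard(nq);
  for (int i = 0; i < nq; i++) {
    int ex = exclude[i] - 1;
    double xi = qx[i], yi = qy[i];
    for (int j = 0; j < nc; j++) {
      if (j == ex) continue;
      double dx = cx[j] - xi, dy = cy[j] - yi;
      double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) continue;
      if (d2 < rh2) { hard[i] = true; continue; }
      int k = bin_of(std::sqrt(d2), rh, breaks);
      counts(i, k * ntypes + (ct[j] - 1))++;
    }
  }
  return List::create(_["counts"] = counts, _["hardcore"] = hard);
}

// All neighbor pairs within the outermost breakpoint, with their bin.
// Returns 1-based i, j (both directions) and 1-based bin; pairs below the
// hardcore are reported with bin 0.
// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericVector x, NumericVector y,
                        double rh, NumericVector breaks) {
  int n = x.size(), m = breaks.size();
  double rmax = breaks[m - 1];
  std::vector<int> ii, jj, bb;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      int k = bin_of(d, rh, breaks);
      int b = (k == -2) ? 0 : k + 1;
      ii.push_back(i + 1); jj.push_back(j + 1); bb.push_back(b);
      ii.push_back(j + 1); jj.push_back(i + 1); bb.push_back(b);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["bin"] = wrap(bb));
}

// log Papangelou conditional intensity of a marked point (ux,uy,uc) given
// the current state, skipping index `skip` (-1 for none); -Inf on a
// hardcore violation
static double loglam_point(double ux, double uy, int uc,
                           const std::vector<double>& X,
                           const std::vector<double>& Y,
                           const std::vector<int>& T, int skip,
                           const NumericVector& logbeta,
                           const NumericMatrix& logdelta,
                           double rh, const NumericVector& br, int C) {
  double s = logbeta[uc];
  int m = br.size();
  double rmax = br[m - 1], rmax2 = rmax * rmax, rh2 = rh * rh;
  for (int j = 0; j < (int)X.size(); j++) {
    if (j == skip) continue;
    double dx = X[j] - ux, dy = Y[j] - uy;
    double d2 = dx * dx + dy * dy;
    if (d2 > rmax2) continue;
    if (d2 < rh2) return R_NegInf;
    int k = bin_of(std::sqrt(d2), rh, br);
    if (k >= 0) s += logdelta(pair_index(uc, T[j], C), k);
  }
  return s;
}

// Birth-death-shift Metropolis-Hastings sampler for the multirange
// multitype Strauss-hardcore density. Acceptance ratios use conditional
// intensities only, so the normalizing constant never appears. Types in
// t0 and in the result are 1-based. Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
List cpp_gibbs(NumericVector logbeta, NumericMatrix logdelta,
               double rh, NumericVector breaks,
               double xmin, double xmax, double ymin, double ymax,
               NumericVector x0, NumericVector y0, IntegerVector t0,
               int n_prop, double p_birth, double p_death) {
  RNGScope scope;
  int C = logbeta.size();
  double wx = xmax - xmin, wy = ymax - ymin;
  double log_vol = std::log(wx * wy * C);
  std::vector<double> X(x0.begin(), x0.end());
  std::vector<double> Y(y0.begin(), y0.end());
  std::vector<int> T(t0.size());
  for (int i = 0; i < t0.size(); i++) T[i] = t0[i] - 1;

  for (int it = 0; it < n_prop; it++) {
    double u = unif_rand();
    int n = (int)X.size();
    if (u < p_birth) {
      double px = xmin + unif_rand() * wx;
      double py = ymin + unif_rand() * wy;
      int pc = (int)(unif_rand() * C); if (pc == C) pc = C - 1;
      double ll = loglam_point(px, py, pc, X, Y, T, -1,
                               logbeta, logdelta, rh, breaks, C);
      if (ll > R_NegInf) {
        double logA = ll + log_vol - std::log((double)n + 1.0);
        if (std::log(unif_rand()) < logA) {
          X.push_back(px); Y.push_back(py); T.push_back(pc);
        }
      }
    } else if (u < p_birth + p_death) {
      if (n == 0) continue;
      int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
      double ll = loglam_point(X[i], Y[i], T[i], X, Y, T, i,
                               logbeta, logdelta, rh, breaks, C);
      bool acc = (ll == R_NegInf);
      if (!acc) {
        double logA = std::log((double)n) - ll - log_vol;
        acc = std::log(unif_rand()) < logA;
      }
      if (acc) {
        X.erase(X.begin() + i); Y.erase(Y.begin() + i); T.erase(T.begin() + i);
      }
    } else {
      if (n == 0) continue;
      int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
      double px = xmin + unif_rand() * wx;
      double py = ymin + unif_rand() * wy;
      double llnew = loglam_point(px, py, T[i], X, Y, T, i,
                                  logbeta, logdelta, rh, breaks, C);
      if (llnew == R_NegInf) continue;
      double llold = loglam_point(X[i], Y[i], T[i], X, Y, T, i,
                                  logbeta, logdelta, rh, breaks, C);
      if (llold == R_NegInf || std::log(unif_rand()) < llnew - llold) {
        X[i] = px; Y[i] = py;
      }
    }
  }
  IntegerVector tout(T.size());
  for (int i = 0; i < (int)T.size(); i++) tout[i] = T[i] + 1;
  return List::create(_["x"] = wrap(X), _["y"] = wrap(Y), _["type"] = tout);
}
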