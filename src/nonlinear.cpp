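#include <Rcpp.h>
using namespace Rcpp;

// Template match counts for sample entropy. Chebyshev (max-abs) distance,
// self-matches excluded. Both template lengths use the same N - m starting
// points so that SE = -log(A/B) reduces to the ratio of raw counts.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  int M = N - m;
  if (M < 2) stop("series too short for template length m");
  double B = 0.0, A = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Streaming recurrence / determinism scan on a delay embedding, without
// materializing the N x N recurrence matrix. epsilon is eps_frac times the
// phase-space diameter (max pairwise Euclidean distance, eps_mode = 0) or
// the mean pairwise distance (eps_mode = 1) among embedded points. Only
// the upper triangle is scanned; for a symmetric recurrence matrix the DET
// ratio is unchanged. Diagonals with offset < theiler (the line of
// identity for theiler = 1) are excluded from both counts.
// [[Rcpp::export]]
List rqa_det_cpp(NumericVector x, int d, int tau, double eps_frac,
                 int lmin, int theiler, int eps_mode) {
  int n = x.size() - (d - 1) * tau;
  if (n < 2) stop("too few embedded points");
  // pass 1: phase-space scale, in the squared-distance domain (no sqrt
  // needed for the max; the mean-distance mode needs the square roots)
  double eps;
  if (eps_mode == 0) {
    double dmax2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dd = 0.0;
        for (int a = 0; a < d; ++a) {
          double t = x[i + a * tau] - x[j + a * tau];
          dd += t * t;
        }
        if (dd > dmax2) dmax2 = dd;
      }
    }
    eps = eps_frac * std::sqrt(dmax2);
  } else {
    double sum = 0.0, npairs = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dd = 0.0;
        for (int a = 0; a < d; ++a) {
          double t = x[i + a * tau] - x[j + a * tau];
          dd += t * t;
        }
        sum += std::sqrt(dd);
        npairs += 1.0;
      }
    }
    eps = eps_frac * (sum / npairs);
  }
  double eps2 = eps * eps;
  double rec = 0.0, det_pts = 0.0;
  if (theiler < 1) theiler = 1;
  for (int k = theiler; k < n; ++k) {
    int run = 0;
    for (int i = 0; i + k < n; ++i) {
      double dd = 0.0;
      bool hit = true;
      for (int a = 0; a < d; ++a) {
        double t = x[i + a * tau] - x[i + k + a * tau];
        dd += t * t;
        if (dd > eps2) { hit = false; break; }
      }
      if (hit) { ++run; rec += 1.0; }
      if ((!hit || i + k == n - 1) && run > 0) {
        if (run >= lmin) det_pts += run;
        run = 0;
      }
    }
  }
  double det = rec > 0 ? det_pts / rec : 0.0;
  return List::create(_["det"] = det, _["eps"] = eps,
                      _["n_embedded"] = n,
                      _["recurrence_rate"] =
                        rec / (0.5 * (double)n * ((double)n - 1.0)));
}

// Kennel false-nearest-neighbour fraction at dimension d, checked against
// the (d+1)-th delay coordinate. Both classical criteria are applied: a
// neighbour is false when the extra-coordinate distance exceeds rtol times
// the in-space distance (loss of neighbourhood), or when the augmented
// distance exceeds atol times the attractor size ra (the neighbour was
// never close on the attractor's scale). Temporal neighbours within
// `theiler` samples are excluded from the nearest-neighbour search (along
// with the point itself). The ratio denominator is floored at `dmin` so
// near-coincident returns of a noiseless orbit (distance ~ 0, extra
// coordinate ~ 0) are not declared false by a 0/0-type ratio.
// [[Rcpp::export]]
double fnn_fraction_cpp(NumericVector x, int d, int tau, double rtol,
                        int theiler, double dmin, double atol, double ra) {
  int n = x.size() - d * tau;
  if (n < 10) stop("too few points for FNN at this dimension");
  int nfalse = 0, ntot = 0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double dd = 0.0;
      for (int a = 0; a < d; ++a) {
        double t = x[i + a * tau] - x[j + a * tau];
        dd += t * t;
        if (dd >= best) break;
      }
      if (dd < best) { best = dd; bj = j; }
    }
    if (bj < 0) continue;
    double dist = std::sqrt(best);
    double extra = std::fabs(x[i + d * tau] - x[bj + d * tau]);
    double denom = dist < dmin ? dmin : dist;
    ++ntot;
    bool crit1 = extra / denom > rtol;
    bool crit2 = std::sqrt(dist * dist + extra * extra) / ra > atol;
    if (crit1 || crit2) ++nfalse;
  }
  if (ntot == 0) return 1.0;
  return (double)nfalse / (double)ntot;
}
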