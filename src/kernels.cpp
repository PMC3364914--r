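#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise distance binning for the O-ring numerator.
// breaks2: squared ring boundaries, strictly increasing; slot k covers
// [breaks2[k], breaks2[k+1]).  slot_ring maps slot -> ring index (or -1 for a
// gap between non-contiguous rings).  Counts are summed over all type-1 points.
// [[Rcpp::export]]
IntegerVector cpp_count_annuli(NumericVector x1, NumericVector y1,
                               NumericVector x2, NumericVector y2,
                               NumericVector breaks2, IntegerVector slot_ring,
                               int nring) {
  const int n1 = x1.size(), n2 = x2.size(), nb = breaks2.size();
  IntegerVector out(nring);
  const double lo = breaks2[0], hi = breaks2[nb - 1];
  for (int i = 0; i < n1; ++i) {
    const double xi = x1[i], yi = y1[i];
    for (int j = 0; j < n2; ++j) {
      const double dx = x2[j] - xi, dy = y2[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < lo || d2 >= hi) continue;
      // binary search: largest k with breaks2[k] <= d2
      int a = 0, b = nb - 1;
      while (b - a > 1) {
        int m = (a + b) / 2;
        if (breaks2[m] <= d2) a = m; else b = m;
      }
      const int ring = slot_ring[a];
      if (ring >= 0) ++out[ring];
    }
  }
  return out;
}

// Distance from each query point to its nearest reference point.
// [[Rcpp::export]]
NumericVector cpp_nearest_dist(NumericVector px, NumericVector py,
                               NumericVector fx, NumericVector fy) {
  const int n = px.size(), m = fx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i];
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = fx[j] - xi, dy = fy[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Per-focal, per-species nearest-neighbour distances accumulated as counts of
// focals whose nearest species-i individual lies within each radius.
// sp: 0-based species index per community point; radii must be increasing.
// Returns an (nsp x nradii) matrix of cumulative counts; dividing by the
// number of focals gives the empirical nearest-neighbour distribution D_fi(r).
// [[Rcpp::export]]
IntegerMatrix cpp_species_nn_counts(NumericVector fx, NumericVector fy,
                                    NumericVector tx, NumericVector ty,
                                    IntegerVector sp, int nsp,
                                    NumericVector radii) {
  const int nf = fx.size(), nt = tx.size(), nr = radii.size();
  IntegerMatrix out(nsp, nr);
  NumericVector r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  const double rmax2 = r2[nr - 1];
  std::vector<double> best(nsp);
  for (int i = 0; i < nf; ++i) {
    std::fill(best.begin(), best.end(), R_PosInf);
    const double xi = fx[i], yi = fy[i];
    for (int j = 0; j < nt; ++j) {
      const double dx = tx[j] - xi, dy = ty[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best[sp[j]]) best[sp[j]] = d2;
    }
    for (int s = 0; s < nsp; ++s) {
      const double b = best[s];
      if (b > rmax2) continue;
      // first radius with r2 >= b (cumulative: count at that radius and beyond)
      int a = 0, c = nr - 1;
      if (r2[0] >= b) a = 0;
      else {
        while (c - a > 1) {
          int m = (a + c) / 2;
          if (r2[m] >= b) c = m; else a = m;
        }
        a = c;
      }
      for (int k = a; k < nr; ++k) ++out(s, k);
    }
  }
  return out;
}

// ---- exact circle / rectangle geometry ------------------------------------

// antiderivative of sqrt(r^2 - x^2)
static inline double S_half(double x, double r) {
  if (x >= r) x = r;
  if (x <= -r) x = -r;
  return 0.5 * (x * std::sqrt(std::max(0.0, r * r - x * x)) +
                r * r * std::asin(x / r));
}

// area of {x^2 + y^2 <= r^2} intersected with {x <= a, y <= b}
static double disc_corner_cdf(double a, double b, double r) {
  if (a <= -r || b <= -r) return 0.0;
  const double A = std::min(a, r);
  if (b >= r) return 2.0 * (S_half(A, r) - S_half(-r, r));
  const double xb = std::sqrt(std::max(0.0, r * r - b * b));
  double area = 0.0;
  if (b >= 0.0) {
    // x in [-r, -xb]: full chord 2 s(x); x in [-xb, xb]: b + s(x); beyond: 2 s(x)
    double up = std::min(A, -xb);
    area += 2.0 * (S_half(up, r) - S_half(-r, r));
    if (A > -xb) {
      double u2 = std::min(A, xb);
      area += b * (u2 + xb) + S_half(u2, r) - S_half(-xb, r);
      if (A > xb) area += 2.0 * (S_half(A, r) - S_half(xb, r));
    }
  } else {
    // only x in [-xb, xb] contributes, with height b + s(x)
    if (A > -xb) {
      double u2 = std::min(A, xb);
      area += b * (u2 + xb) + S_half(u2, r) - S_half(-xb, r);
    }
  }
  return area;
}

// Area of the disc of radius r centred at (cx, cy) clipped to [0,W] x [0,H],
// by inclusion-exclusion of the bivariate corner CDF. Vectorised over centres.
// [[Rcpp::export]]
NumericVector cpp_disc_rect_area(NumericVector cx, NumericVector cy, double r,
                                 double W, double H) {
  const int n = cx.size();
  NumericVector out(n);
  if (r <= 0) return out;
  for (int i = 0; i < n; ++i) {
    const double x1 = -cx[i], x2 = W - cx[i];
    const double y1 = -cy[i], y2 = H - cy[i];
    out[i] = disc_corner_cdf(x2, y2, r) - disc_corner_cdf(x1, y2, r) -
             disc_corner_cdf(x2, y1, r) + disc_corner_cdf(x1, y1, r);
  }
  return out;
}
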