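#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Bilinear sample of an image matrix (row = y + 1, col = x + 1, 0-based pixel
// coordinates) at a continuous position. Out-of-bounds reads as 0 (background).
static inline double sample_bilinear(const NumericMatrix& img, double x, double y) {
  const int H = img.nrow(), W = img.ncol();
  if (x < 0.0 || y < 0.0 || x > W - 1.0 || y > H - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > W - 2) x0 = W - 2;
  if (y0 > H - 2) y0 = H - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  double v00 = img(y0, x0), v10 = img(y0, x0 + 1);
  double v01 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// Slant angle (degrees from normal view) of the linear part of a 2D affine map,
// from the ratio of its singular values.
static inline double slant_deg(double a, double b, double c, double d) {
  double E = (a + d) / 2.0, F = (a - d) / 2.0;
  double G = (c + b) / 2.0, Hh = (c - b) / 2.0;
  double Q = std::sqrt(E * E + Hh * Hh), R = std::sqrt(F * F + G * G);
  double smax = Q + R, smin = std::fabs(Q - R);
  if (smax <= 0) return 90.0;
  double r = smin / smax;
  if (r > 1.0) r = 1.0;
  return std::acos(r) * 180.0 / M_PI;
}

// Score the three-circle ("Mickey") template against the facet probability map
// for a set of candidate face positions. The affine map sends the template
// anchors (ear1, ear2, face) onto (ear1_img, ear2_img, candidate). For each
// candidate: theta* = sum(p*t)/sum(t^2) and
// delta = sum((p - theta*t)^2) over the non-NaN template pixels.
// [[Rcpp::export]]
List cpp_mickey_scan(const NumericMatrix& prob,
                     const NumericVector& tvals,
                     const NumericVector& tx,
                     const NumericVector& ty,
                     const NumericMatrix& anchors,  // 3 x 2: ear1, ear2, face
                     const NumericVector& ear1,
                     const NumericVector& ear2,
                     const NumericVector& cand_x,
                     const NumericVector& cand_y) {
  const int n_px = tvals.size(), n_cand = cand_x.size();
  // Invert the 3x3 template-anchor matrix [ax ay 1] once.
  double M[3][3] = {{anchors(0, 0), anchors(0, 1), 1.0},
                    {anchors(1, 0), anchors(1, 1), 1.0},
                    {anchors(2, 0), anchors(2, 1), 1.0}};
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) < 1e-12) stop("degenerate template anchors");
  double inv[3][3];
  inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
  inv[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / det;
  inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
  inv[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / det;
  inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
  inv[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / det;
  inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
  inv[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / det;
  inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;

  double sum_t2 = 0.0;
  for (int i = 0; i < n_px; ++i) sum_t2 += tvals[i] * tvals[i];

  NumericVector delta(n_cand), theta(n_cand), slant(n_cand);
  for (int k = 0; k < n_cand; ++k) {
    // coefficients: x_img = cx0*tx + cx1*ty + cx2 (and same for y)
    double vx[3] = {ear1[0], ear2[0], cand_x[k]};
    double vy[3] = {ear1[1], ear2[1], cand_y[k]};
    double cx0 = inv[0][0] * vx[0] + inv[0][1] * vx[1] + inv[0][2] * vx[2];
    double cx1 = inv[1][0] * vx[0] + inv[1][1] * vx[1] + inv[1][2] * vx[2];
    double cx2 = inv[2][0] * vx[0] + inv[2][1] * vx[1] + inv[2][2] * vx[2];
    double cy0 = inv[0][0] * vy[0] + inv[0][1] * vy[1] + inv[0][2] * vy[2];
    double cy1 = inv[1][0] * vy[0] + inv[1][1] * vy[1] + inv[1][2] * vy[2];
    double cy2 = inv[2][0] * vy[0] + inv[2][1] * vy[1] + inv[2][2] * vy[2];
    double sum_pt = 0.0, sum_p2 = 0.0;
    for (int i = 0; i < n_px; ++i) {
      double xi = cx0 * tx[i] + cx1 * ty[i] + cx2;
      double yi = cy0 * tx[i] + cy1 * ty[i] + cy2;
      double p = sample_bilinear(prob, xi, yi);
      sum_pt += p * tvals[i];
      sum_p2 += p * p;
    }
    double th = sum_pt / sum_t2;
    theta[k] = th;
    delta[k] = sum_p2 - 2.0 * th * sum_pt + th * th * sum_t2;
    slant[k] = slant_deg(cx0, cx1, cy0, cy1);
  }
  return List::create(_["delta"] = delta, _["theta"] = theta, _["slant"] = slant);
}

// Sampled (probability, template) value pairs for a single pose; used for
// oracle-style checks of the closed-form brightness parameter.
// [[Rcpp::export]]
List cpp_mickey_sample(const NumericMatrix& prob,
                       const NumericVector& tvals,
                       const NumericVector& tx,
                       const NumericVector& ty,
                       const NumericMatrix& anchors,
                       const NumericVector& ear1,
                       const NumericVector& ear2,
                       const NumericVector& face) {
  NumericVector cx(1), cy(1);
  cx[0] = face[0];
  cy[0] = face[1];
  // reuse the scan machinery for coefficients by replicating its solve
  const int n_px = tvals.size();
  double M[3][3] = {{anchors(0, 0), anchors(0, 1), 1.0},
                    {anchors(1, 0), anchors(1, 1), 1.0},
                    {anchors(2, 0), anchors(2, 1), 1.0}};
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) < 1e-12) stop("degenerate template anchors");
  double inv[3][3];
  inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
  inv[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / det;
  inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
  inv[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / det;
  inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
  inv[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / det;
  inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
  inv[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / det;
  inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
  double vx[3] = {ear1[0], ear2[0], face[0]};
  double vy[3] = {ear1[1], ear2[1], face[1]};
  double cx0 = inv[0][0] * vx[0] + inv[0][1] * vx[1] + inv[0][2] * vx[2];
  double cx1 = inv[1][0] * vx[0] + inv[1][1] * vx[1] + inv[1][2] * vx[2];
  double cx2 = inv[2][0] * vx[0] + inv[2][1] * vx[1] + inv[2][2] * vx[2];
  double cy0 = inv[0][0] * vy[0] + inv[0][1] * vy[1] + inv[0][2] * vy[2];
  double cy1 = inv[1][0] * vy[0] + inv[1][1] * vy[1] + inv[1][2] * vy[2];
  double cy2 = inv[2][0] * vy[0] + inv[2][1] * vy[1] + inv[2][2] * vy[2];
  NumericVector p(n_px), t(n_px);
  for (int i = 0; i < n_px; ++i) {
    double xi = cx0 * tx[i] + cx1 * ty[i] + cx2;
    double yi = cy0 * tx[i] + cy1 * ty[i] + cy2;
    p[i] = sample_bilinear(prob, xi, yi);
    t[i] = tvals[i];
  }
  return List::create(_["p"] = p, _["t"] = t,
                      _["slant"] = slant_deg(cx0, cx1, cy0, cy1));
}

// For every pixel of a H x W image, the index (1-based) of the nearest of a
// set of centers plus the distances to the nearest and second-nearest center.
// Spatial-hash ring search keeps this near O(H*W).
// [[Rcpp::export]]
List cpp_nearest2(const NumericVector& cx, const NumericVector& cy,
                  int width, int height) {
  const int n = cx.size();
  if (n < 1) stop("no centers");
  double xmin = cx[0], xmax = cx[0], ymin = cy[0], ymax = cy[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, cx[i]); xmax = std::max(xmax, cx[i]);
    ymin = std::min(ymin, cy[i]); ymax = std::max(ymax, cy[i]);
  }
  // bucket size ~ typical spacing
  double span = std::max(xmax - xmin, ymax - ymin) + 1.0;
  double g = std::max(2.0, span / std::max(1.0, std::sqrt((double)n)));
  int nbx = (int)std::floor((xmax - xmin) / g) + 1;
  int nby = (int)std::floor((ymax - ymin) / g) + 1;
  std::vector<std::vector<int>> buckets((size_t)nbx * nby);
  for (int i = 0; i < n; ++i) {
    int bx = (int)((cx[i] - xmin) / g), by = (int)((cy[i] - ymin) / g);
    buckets[(size_t)by * nbx + bx].push_back(i);
  }
  IntegerMatrix label(height, width);
  NumericMatrix d1(height, width), d2(height, width);
  const double INF = std::numeric_limits<double>::infinity();
  for (int py = 0; py < height; ++py) {
    for (int px = 0; px < width; ++px) {
      int bx = (int)((px - xmin) / g), by = (int)((py - ymin) / g);
      double best1 = INF, best2 = INF;
      int bi = -1;
      int maxring = std::max(nbx, nby) + std::max(
          std::max(bx, nbx - 1 - bx), std::max(by, nby - 1 - by)) + 2;
      for (int ring = 0; ring <= maxring; ++ring) {
        // stop once ring lower-bound distance exceeds both current bests
        double lb = (ring - 1) * g;
        if (ring > 0 && lb > best2) break;
        for (int dy = -ring; dy <= ring; ++dy) {
          int yy = by + dy;
          if (yy < 0 || yy >= nby) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
            int xx = bx + dx;
            if (xx < 0 || xx >= nbx) continue;
            const std::vector<int>& B = buckets[(size_t)yy * nbx + xx];
            for (size_t q = 0; q < B.size(); ++q) {
              int i = B[q];
              double ddx = px - cx[i], ddy = py - cy[i];
              double d = std::sqrt(ddx * ddx + ddy * ddy);
              if (d < best1) { best2 = best1; best1 = d; bi = i; }
              else if (d < best2) { best2 = d; }
            }
          }
        }
      }
      label(py, px) = bi + 1;
      d1(py, px) = best1;
      d2(py, px) = (best2 == INF) ? best1 : best2;
    }
  }
  return List::create(_["label"] = label, _["d1"] = d1, _["d2"] = d2);
}

// Minimum distance from a query point to a set of points.
// [[Rcpp::export]]
double cpp_min_dist(const NumericVector& px, const NumericVector& py,
                    double qx, double qy) {
  double best = std::numeric_limits<double>::infinity();
  for (int i = 0; i < px.size(); ++i) {
    double dx = px[i] - qx, dy = py[i] - qy;
    double d = dx * dx + dy * dy;
    if (d < best) best = d;
  }
  return std::sqrt(best);
}
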