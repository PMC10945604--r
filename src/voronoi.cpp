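#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Periodic Voronoi / Laguerre cell areas by half-plane clipping.
//
// The cell of point i on the torus is the intersection, over all periodic
// images g of every generator j (including the non-central images of i
// itself), of the half-planes bounded by the (power-)bisector of p_i and g.
// Clipping starts from the centred square of side L, which contains the
// cell by construction (the bisectors to i's own images cut exactly that
// square), and proceeds nearest-image first with an exact stopping rule
// for the unweighted case: an image at distance d cannot cut the current
// polygon once d/2 exceeds the largest vertex distance.

struct Pt { double x, y; };

static double poly_area(const std::vector<Pt>& p) {
  double a = 0.0;
  int n = p.size();
  for (int k = 0; k < n; ++k) {
    const Pt& u = p[k];
    const Pt& v = p[(k + 1) % n];
    a += u.x * v.y - v.x * u.y;
  }
  return 0.5 * std::fabs(a);
}

// Clip polygon (relative to p_i at origin) with half-plane
// { r : dot(r, n) <= c }, n = direction to the image, c = signed offset.
static void clip(std::vector<Pt>& poly, double nx, double ny, double c) {
  std::vector<Pt> out;
  int n = poly.size();
  if (n == 0) return;
  out.reserve(n + 2);
  for (int k = 0; k < n; ++k) {
    const Pt& a = poly[k];
    const Pt& b = poly[(k + 1) % n];
    double da = a.x * nx + a.y * ny - c;
    double db = b.x * nx + b.y * ny - c;
    if (da <= 0.0) out.push_back(a);
    if ((da < 0.0 && db > 0.0) || (da > 0.0 && db < 0.0)) {
      double t = da / (da - db);
      out.push_back({ a.x + t * (b.x - a.x), a.y + t * (b.y - a.y) });
    }
  }
  poly.swap(out);
}

// [[Rcpp::export]]
NumericVector voronoi_areas_cpp(NumericMatrix pos, double L,
                                Nullable<NumericVector> weights = R_NilValue) {
  int N = pos.nrow();
  bool laguerre = weights.isNotNull();
  NumericVector w;
  if (laguerre) w = weights.get();

  struct Img { double dx, dy, d2, dw; };
  NumericVector areas(N);

  for (int i = 0; i < N; ++i) {
    std::vector<Img> imgs;
    imgs.reserve(9 * N + 8);
    double wi = laguerre ? w[i] : 0.0;
    for (int j = 0; j < N; ++j) {
      double wj = laguerre ? w[j] : 0.0;
      for (int gx = -1; gx <= 1; ++gx) for (int gy = -1; gy <= 1; ++gy) {
        if (j == i && gx == 0 && gy == 0) continue;
        double dx = pos(j, 0) + gx * L - pos(i, 0);
        double dy = pos(j, 1) + gy * L - pos(i, 1);
        imgs.push_back({ dx, dy, dx * dx + dy * dy, wi - wj });
      }
    }
    std::sort(imgs.begin(), imgs.end(),
              [](const Img& a, const Img& b) { return a.d2 < b.d2; });

    // start from the centred square of side L
    std::vector<Pt> poly = { {-L / 2, -L / 2}, {L / 2, -L / 2},
                             {L / 2, L / 2}, {-L / 2, L / 2} };
    double maxr2 = L * L / 2.0;  // squared max vertex distance
    for (const Img& im : imgs) {
      if (!laguerre && im.d2 > 4.0 * maxr2) break;
      double d = std::sqrt(im.d2);
      if (d == 0.0) stop("coincident generators in Voronoi construction");
      // power bisector: dot(r, u) = (d^2 + w_i - w_j) / (2 d), u = image dir
      double c = (im.d2 + im.dw) / (2.0 * d);
      clip(poly, im.dx / d, im.dy / d, c);
      if (poly.empty()) break;
      if (!laguerre) {
        maxr2 = 0.0;
        for (const Pt& v : poly)
          maxr2 = std::max(maxr2, v.x * v.x + v.y * v.y);
      }
    }
    areas[i] = poly.empty() ? 0.0 : poly_area(poly);
  }
  return areas;
}
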