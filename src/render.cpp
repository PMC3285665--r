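#include <Rcpp.h>
using namespace Rcpp;

// Pixel-level synthetic image renderer. Places random ellipses ("cells")
// until the target area fraction is covered, then fills foreground and
// background with lognormal pixel noise around their means. Uses R's RNG
// so results are reproducible under set.seed() from the R side.
// [[Rcpp::export(name = ".render_image_cpp")]]
IntegerMatrix render_image_cpp(double fg_mean, int nr, int nc,
                               double area_fraction,
                               double fg_sdlog, double bg_mean,
                               double bg_sdlog, double max_val) {
  const int n = nr * nc;
  std::vector<char> mask(n, 0);
  const int target = (int)std::ceil(area_fraction * n);
  int covered = 0, iter = 0;
  const double rmax = std::max(4.0, std::min(nr, nc) / 8.0);
  const double rmin = std::max(2.0, rmax / 4.0);
  while (covered < target && iter < 10000) {
    ++iter;
    double cx = R::runif(1, nc), cy = R::runif(1, nr);
    double a = R::runif(rmin, rmax), b = R::runif(rmin, rmax);
    double th = R::runif(0, M_PI);
    double r = std::max(a, b), ct = std::cos(th), st = std::sin(th);
    int r0 = std::max(1, (int)std::floor(cy - r));
    int r1 = std::min(nr, (int)std::ceil(cy + r));
    int c0 = std::max(1, (int)std::floor(cx - r));
    int c1 = std::min(nc, (int)std::ceil(cx + r));
    for (int cc = c0; cc <= c1; ++cc) {
      double dx = cc - cx;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = rr - cy;
        double u = (dx * ct + dy * st) / a;
        double v = (-dx * st + dy * ct) / b;
        if (u * u + v * v <= 1.0) {
          int idx = (cc - 1) * nr + (rr - 1);
          if (!mask[idx]) { mask[idx] = 1; ++covered; }
        }
      }
    }
  }
  // lognormal with mean exactly equal to the requested level
  const double fg_mu =
    std::log(std::max(fg_mean, 1e-300)) - fg_sdlog * fg_sdlog / 2.0;
  const double bg_mu =
    std::log(std::max(bg_mean, 1e-300)) - bg_sdlog * bg_sdlog / 2.0;
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) {
    double val;
    if (mask[i]) {
      val = fg_sdlog > 0 ? std::exp(fg_mu + fg_sdlog * norm_rand()) : fg_mean;
    } else {
      val = bg_sdlog > 0 ? std::exp(bg_mu + bg_sdlog * norm_rand()) : bg_mean;
    }
    val = std::nearbyint(val);
    if (val < 0) val = 0;
    if (val > max_val) val = max_val;
    out[i] = (int)val;
  }
  return out;
}
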