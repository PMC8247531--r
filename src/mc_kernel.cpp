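#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo inner loop: for each draw, resample the daily total-PM2.5
// field from per-cell-day lognormals (comonotonic: one N(0,1) deviate per
// draw shared by all cell-days; independent: iid per cell-day), re-run the
// attribution pipeline (background isolation, 2-day averaging, zero clamp)
// and accumulate the health impact function into daily admission totals.
//
// Layouts (all flattened from R [ny, nx, day] arrays): cell index s within
// a day, day-major stride ncell. `ratio` is the precomputed back/fire
// fraction per cell-day (1 where the with-fire field is ~0, so dx = 0).
// Draws consume R's RNG (norm_rand), so set.seed() governs reproducibility.
//
// [[Rcpp::export]]
NumericMatrix mc_daily_totals(const NumericVector& mean_x,
                              const NumericVector& meanlog,
                              const NumericVector& sdlog,
                              const int ny, const int nx, const int nday,
                              const int bg_kind, // 0 = ratio, 1 = baseline
                              const NumericVector& ratio,
                              const NumericVector& baseline,
                              const NumericVector& ynf,
                              const NumericVector& pop,
                              const NumericVector& beta_draws,
                              const bool sample_exposure,
                              const bool comonotonic,
                              const bool clamp_before) {
  const int ncell = ny * nx;
  const int n_draws = beta_draws.size();
  if (mean_x.size() != ncell * nday)
    stop("mean_x length does not match grid dimensions");
  if (bg_kind == 0 && ratio.size() != ncell * nday)
    stop("ratio length does not match grid dimensions");
  if (bg_kind == 1 && baseline.size() != ncell)
    stop("baseline length does not match grid dimensions");

  NumericMatrix daily(n_draws, nday);
  std::vector<double> xs(nday);
  std::vector<double> acc(nday);

  // cells with zero population or zero baseline rate contribute exactly 0
  // to every total and are skipped
  std::vector<int> active;
  active.reserve(ncell);
  for (int s = 0; s < ncell; ++s)
    if (ynf[s] * pop[s] != 0.0) active.push_back(s);

  for (int d = 0; d < n_draws; ++d) {
    const double beta = beta_draws[d];
    double zshare = 0.0;
    if (sample_exposure && comonotonic) zshare = norm_rand();
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t a = 0; a < active.size(); ++a) {
      const int s = active[a];
      const double w = ynf[s] * pop[s];
      // sampled (or mean) daily series for this cell
      for (int t = 0; t < nday; ++t) {
        const int idx = t * ncell + s;
        double x;
        if (!sample_exposure || sdlog[idx] == 0.0) {
          x = mean_x[idx];
        } else {
          const double z = comonotonic ? zshare : norm_rand();
          x = std::exp(meanlog[idx] + sdlog[idx] * z);
        }
        xs[t] = x;
      }
      // isolate fire-originated component + 2-day average + clamp
      double prev_a = 0.0, prev_b = 0.0, prev_d = 0.0;
      for (int t = 0; t < nday; ++t) {
        const int idx = t * ncell + s;
        double dx;
        if (!clamp_before) {
          const double xnf = (bg_kind == 0) ? xs[t] * ratio[idx]
                                            : baseline[s];
          const double a = (t == 0) ? xs[t] : 0.5 * (xs[t] + prev_a);
          const double b = (t == 0) ? xnf : 0.5 * (xnf + prev_b);
          dx = a - b;
          if (dx < 0.0) dx = 0.0;
          prev_a = xs[t];
          prev_b = xnf;
        } else {
          const double xnf = (bg_kind == 0) ? xs[t] * ratio[idx]
                                            : baseline[s];
          double dd = xs[t] - xnf;
          if (dd < 0.0) dd = 0.0;
          dx = (t == 0) ? dd : 0.5 * (dd + prev_d);
          prev_d = dd;
        }
        acc[t] += w * std::expm1(beta * dx);
      }
    }
    for (int t = 0; t < nday; ++t) daily(d, t) = acc[t];
  }
  return daily;
}
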