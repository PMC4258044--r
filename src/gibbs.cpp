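#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the balanced additive two-way random-effects model
//   y_blr = mu + B_b + L_l + e_blr
// under the improper prior flat in (mu, sigma_b, sigma_l, sigma_e), i.e.
// p(sigma2) proportional to sigma2^{-1/2} per component. All full
// conditionals are conjugate: normal for mu and the effect blocks,
// inverse-gamma (shape (m-1)/2, rate S/2 for m effects with sum of
// squares S) for each variance.
//
// Sufficient statistics: the b0 x l0 matrix of cell means plus the pooled
// within-cell sum of squares (zero when r0 = 1), so one iteration costs
// O(b0 * l0) regardless of r0.
//
// [[Rcpp::export]]
NumericMatrix gibbs_vc(NumericMatrix cell_means, double ss_within, int r0,
                       int n_iter, int burnin, int thin,
                       double s2b_init, double s2l_init, double s2e_init) {
  const int b0 = cell_means.nrow(), l0 = cell_means.ncol();
  const double n = static_cast<double>(b0) * l0 * r0;

  std::vector<double> row_sum(b0, 0.0), col_sum(l0, 0.0);
  double tot = 0.0;
  for (int j = 0; j < l0; ++j)
    for (int i = 0; i < b0; ++i) {
      const double m = cell_means(i, j);
      row_sum[i] += m;
      col_sum[j] += m;
      tot += m;
    }

  std::vector<double> B(b0, 0.0), L(l0, 0.0);
  double mu = tot / (b0 * l0);
  double s2b = s2b_init, s2l = s2l_init, s2e = s2e_init;

  const int n_keep = (n_iter - burnin) / thin;
  NumericMatrix out(n_keep, 4);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    double sumB = 0.0, sumL = 0.0;
    for (int i = 0; i < b0; ++i) sumB += B[i];
    for (int j = 0; j < l0; ++j) sumL += L[j];

    // mu | rest
    const double mu_mean = (tot * r0 - l0 * r0 * sumB - b0 * r0 * sumL) / n;
    mu = R::rnorm(mu_mean, std::sqrt(s2e / n));

    // subject effects
    double ssB = 0.0;
    {
      const double prec = l0 * r0 / s2e + 1.0 / s2b;
      const double sd = std::sqrt(1.0 / prec);
      sumB = 0.0;
      for (int i = 0; i < b0; ++i) {
        const double resid = r0 * (row_sum[i] - l0 * mu - sumL);
        B[i] = R::rnorm(resid / s2e / prec, sd);
        sumB += B[i];
        ssB += B[i] * B[i];
      }
    }

    // rater effects
    double ssL = 0.0;
    {
      const double prec = b0 * r0 / s2e + 1.0 / s2l;
      const double sd = std::sqrt(1.0 / prec);
      sumL = 0.0;
      for (int j = 0; j < l0; ++j) {
        const double resid = r0 * (col_sum[j] - b0 * mu - sumB);
        L[j] = R::rnorm(resid / s2e / prec, sd);
        sumL += L[j];
        ssL += L[j] * L[j];
      }
    }

    // variances: inverse-gamma via rate / Gamma(shape, 1)
    s2b = (ssB / 2.0) / R::rgamma((b0 - 1) / 2.0, 1.0);
    s2l = (ssL / 2.0) / R::rgamma((l0 - 1) / 2.0, 1.0);

    double sse = ss_within;
    for (int j = 0; j < l0; ++j)
      for (int i = 0; i < b0; ++i) {
        const double r = cell_means(i, j) - mu - B[i] - L[j];
        sse += r0 * r * r;
      }
    s2e = (sse / 2.0) / R::rgamma((n - 1.0) / 2.0, 1.0);

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      out(kept, 0) = mu;
      out(kept, 1) = s2b;
      out(kept, 2) = s2l;
      out(kept, 3) = s2e;
      ++kept;
    }
  }
  return out;
}
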