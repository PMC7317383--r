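// Per-offset steady-state evaluation of the pulsed-saturation cycle.
// Receives the offset-independent cycle pieces from R and performs the
// per-point matrix exponential / linear solves of the saturation interval
// and the periodic fixed point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::vec cpp_spectrum_raw(const arma::mat& RL, const arma::vec& rlm0,
                           const arma::mat& L1, const arma::mat& R1,
                           const arma::vec& u, const arma::vec& cs,
                           const double tm, const arma::mat& prec,
                           const arma::uvec& xi, const arma::mat& satrate,
                           const arma::uvec& zsemi, const arma::vec& w1,
                           const arma::uword ziw) {
  const arma::uword n = RL.n_rows;
  const arma::uword npts = w1.n_elem;
  const arma::mat I = arma::eye(n, n);
  arma::vec out(npts);
  arma::mat X(n, n), Em(n, n), A(n, n);
  arma::vec mss(n), cm(n), cv(n), m(n);
  for (arma::uword i = 0; i < npts; ++i) {
    X = RL;
    for (arma::uword j = 0; j < xi.n_elem; ++j) {
      const arma::uword ix = xi(j);
      X(ix, ix + 1) += prec(i, j);
      X(ix + 1, ix) -= prec(i, j);
      X(ix + 1, ix + 2) -= w1(i);
      X(ix + 2, ix + 1) += w1(i);
    }
    for (arma::uword s = 0; s < zsemi.n_elem; ++s)
      X(zsemi(s), zsemi(s)) -= satrate(i, s);
    Em = arma::expmat(X * tm);
    if (!arma::solve(mss, X, rlm0, arma::solve_opts::no_approx))
      Rcpp::stop("singular saturation system");
    cm = mss - Em * mss;
    A = L1 * (Em * R1);
    cv = L1 * (Em * u + cm) + cs;
    if (!arma::solve(m, I - A, cv, arma::solve_opts::no_approx))
      Rcpp::stop("singular cycle propagator (non-convergent sequence)");
    out(i) = m(ziw);
  }
  return out;
}

// ---- full model evaluation -------------------------------------------------
// Builds R_L, the interval propagators and the per-offset saturation terms
// from raw pool-parameter vectors, so the optimizer's objective runs without
// touching R. Index layout matches the R containers: (x,y,z) triples for
// mobile pools in system order, then one z row per semisolid pool.

static double ls_lorentz(const double d_hz, const double t2) {
  const double u = 2.0 * M_PI * d_hz * t2;
  return (t2 / M_PI) / (1.0 + u * u);
}
static double ls_gauss(const double d_hz, const double t2) {
  const double u = 2.0 * M_PI * d_hz * t2;
  return t2 / std::sqrt(2.0 * M_PI) * std::exp(-0.5 * u * u);
}
static double sl_raw_cpp(const double d_hz, const double t2,
                         const arma::vec& glx, const arma::vec& glw) {
  const double u = 2.0 * M_PI * d_hz * t2;
  double s = 0.0;
  for (arma::uword i = 0; i < glx.n_elem; ++i) {
    const double c = 3.0 * std::cos(glx(i)) * std::cos(glx(i)) - 1.0;
    const double e = u / c;
    s += glw(i) * std::sin(glx(i)) * std::sqrt(2.0 / M_PI) *
      (t2 / std::fabs(c)) * std::exp(-2.0 * e * e);
  }
  return s;
}

// [[Rcpp::export]]
arma::vec cpp_spectrum_model(const arma::vec& shift_ppm, const arma::vec& r1,
                             const arma::vec& r2, const arma::vec& m0r,
                             const arma::vec& kex, const arma::ivec& mobile,
                             const arma::ivec& lshape, const double f0,
                             const double tm, const double ts, const double tr,
                             const double exc_deg, const arma::vec& off_ppm,
                             const arma::vec& w1, const double b0_ppm,
                             const arma::vec& glx, const arma::vec& glw,
                             const double sl_cutoff) {
  const arma::uword np = shift_ppm.n_elem;
  arma::uword nmob = 0;
  for (arma::uword j = 0; j < np; ++j) if (mobile(j)) ++nmob;
  const arma::uword n = 3 * nmob + (np - nmob);
  // index maps (0-based)
  arma::uvec xi(np, arma::fill::zeros), zi(np, arma::fill::zeros);
  arma::uword mi = 0, si = 0;
  for (arma::uword j = 0; j < np; ++j) {
    if (mobile(j)) { xi(j) = 3 * mi; zi(j) = 3 * mi + 2; ++mi; }
    else { zi(j) = 3 * nmob + si; ++si; }
  }
  // relaxation/exchange matrix and equilibrium
  arma::mat RL(n, n, arma::fill::zeros);
  arma::vec m0(n, arma::fill::zeros);
  arma::vec kf = kex % m0r;  // water -> pool forward rates
  kf(0) = 0.0;
  double kf_mob = 0.0, kf_all = 0.0;
  for (arma::uword j = 1; j < np; ++j) {
    kf_all += kf(j);
    if (mobile(j)) kf_mob += kf(j);
  }
  RL(0, 0) = RL(1, 1) = -r2(0) - kf_mob;
  RL(2, 2) = -r1(0) - kf_all;
  m0(2) = 1.0;
  for (arma::uword j = 1; j < np; ++j) {
    m0(zi(j)) = m0r(j);
    if (mobile(j)) {
      for (arma::uword d = 0; d < 2; ++d) {
        const arma::uword i = xi(j) + d;
        RL(i, i) = -r2(j) - kex(j);
        RL(d, i) = kex(j);
        RL(i, d) = kf(j);
      }
    }
    RL(zi(j), zi(j)) = -r1(j) - kex(j);
    RL(2, zi(j)) = kex(j);
    RL(zi(j), 2) = kf(j);
  }
  // spoil / excitation diagonals
  arma::vec sdg(n, arma::fill::ones), cdg(n);
  const double a = exc_deg * M_PI / 180.0;
  cdg.fill(std::cos(a));
  for (arma::uword j = 0; j < np; ++j) if (mobile(j)) {
    sdg(xi(j)) = sdg(xi(j) + 1) = 0.0;
    cdg(xi(j)) = cdg(xi(j) + 1) = std::sin(a);
  }
  const arma::mat Er = arma::expmat(RL * tr);
  const arma::mat Es = arma::expmat(RL * ts);
  const arma::mat L1 = Es.each_row() % sdg.t();
  arma::mat R1 = Er.each_col() % sdg;
  R1 = R1.each_row() % cdg.t();
  const arma::vec u0 = sdg % (m0 - Er * m0);
  const arma::vec cs = m0 - Es * m0;
  const arma::vec rlm0 = RL * m0;
  const arma::mat I = arma::eye(n, n);
  // super-Lorentzian near-resonance cubic anchors, one set per semisolid pool
  arma::mat slcf(4, np, arma::fill::zeros);
  arma::vec slcap(np, arma::fill::zeros);
  for (arma::uword j = 0; j < np; ++j) {
    if (!mobile(j) && lshape(j) == 3) {
      const double t2 = 1.0 / r2(j);
      arma::vec xa = { sl_cutoff, sl_cutoff * 7.0 / 6.0,
                       sl_cutoff * 8.0 / 6.0, sl_cutoff * 1.5 };
      arma::mat V(4, 4);
      arma::vec ya(4);
      for (int q = 0; q < 4; ++q) {
        ya(q) = sl_raw_cpp(xa(q), t2, glx, glw);
        double pw = 1.0;
        for (int c = 0; c < 4; ++c) { V(q, c) = pw; pw *= xa(q); }
      }
      slcf.col(j) = arma::solve(V, ya);
      slcap(j) = slcf(0, j);
    }
  }
  const arma::uword npts = off_ppm.n_elem;
  arma::vec out(npts);
  arma::mat X(n, n), Em(n, n), A(n, n);
  arma::vec mss(n), cm(n), cv(n), m(n);
  for (arma::uword i = 0; i < npts; ++i) {
    X = RL;
    for (arma::uword j = 0; j < np; ++j) {
      const double d_hz = (off_ppm(i) + b0_ppm - shift_ppm(j)) * f0;
      if (mobile(j)) {
        const double uu = 2.0 * M_PI * d_hz;
        const arma::uword ix = xi(j);
        X(ix, ix + 1) += uu;
        X(ix + 1, ix) -= uu;
        X(ix + 1, ix + 2) -= w1(i);
        X(ix + 2, ix + 1) += w1(i);
      } else {
        const double t2 = 1.0 / r2(j);
        double g;
        if (lshape(j) == 1) g = ls_lorentz(d_hz, t2);
        else if (lshape(j) == 2) g = ls_gauss(d_hz, t2);
        else {
          const double ad = std::fabs(d_hz);
          if (ad >= sl_cutoff) g = sl_raw_cpp(d_hz, t2, glx, glw);
          else {
            g = slcf(0, j) + ad * (slcf(1, j) + ad * (slcf(2, j) +
                  ad * slcf(3, j)));
            if (g < 0.0) g = 0.0;
            if (g > slcap(j)) g = slcap(j);
          }
        }
        X(zi(j), zi(j)) -= M_PI * w1(i) * w1(i) * g;
      }
    }
    Em = arma::expmat(X * tm);
    if (!arma::solve(mss, X, rlm0, arma::solve_opts::no_approx))
      Rcpp::stop("singular saturation system");
    cm = mss - Em * mss;
    A = L1 * (Em * R1);
    cv = L1 * (Em * u0 + cm) + cs;
    if (!arma::solve(m, I - A, cv, arma::solve_opts::no_approx))
      Rcpp::stop("singular cycle propagator (non-convergent sequence)");
    out(i) = m(2);
  }
  return out;
}
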