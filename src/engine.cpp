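// Hot loop of the multi-timescale Euler-Maruyama integrator.
//
// One call integrates the full coupled system (4 species x {M, p},
// 3 J-variants, 5 X-cycle pools) for n_steps biological timesteps.
// The J-cycle increments are scaled by 1/tau_J and the X-cycle
// increments by 1/(tau_J * tau_X) per biological step; stochastic
// increments are sigma_bar * g * sqrt(dt_eff) * N(0,1).
//
// RNG: uses R's stream (unif_rand / norm_rand) so that trajectories are
// reproducible from set.seed() and identical to an R-level stepper that
// draws in the same order: per species A..D the mutation uniforms
// (p-genotype events then q-genotype events), then 4 biomass normals,
// 3 J-variant normals, and 3 X-cycle normals (XA, XB, X). With
// sigma_bar == 0 nothing is drawn and the step is fully deterministic
// (mutation fractions take their expectations).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rha(double x) {  // round half away from zero
  return x >= 0.0 ? std::floor(x + 0.5) : std::ceil(x - 0.5);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline double sigmoid_feedback(double X, double fb0, double Xon,
                                      double Xoff, double a, double b) {
  return fb0 / (1.0 + std::exp(-a * (X - Xon))) /
               (1.0 + std::exp(b * (X - Xoff)));
}

static inline double suppress(double X, double alpha0, double k_alpha,
                              double Xsuppress) {
  if (X < Xsuppress) return 0.0;
  return alpha0 / (1.0 + std::exp(-k_alpha * (X - Xsuppress)));
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector state0, double t0, List par,
                int n_steps, double dt_bio, int record_every) {
  // parameters
  const double Fin0 = par["Fin0"], Fout0 = par["Fout0"];
  const double Rmax = par["Rmax"], K = par["K"], rn_bar = par["rn_bar"];
  const double Km = par["Km"], g0 = par["g0"], W0 = par["W0"];
  const double s = par["s"], Ji0 = par["Ji0"], m0 = par["m0"];
  const double eps_X = par["eps_X"], Xrel0 = par["Xrel0"];
  const double fb0 = par["Xfeedback0"], Xon = par["Xon"],
               Xoff = par["Xoff"], a = par["a"], b = par["b"];
  const double tau_J = par["tau_J"], tau_X = par["tau_X"];
  const double Xsuppress = par["Xsuppress"], alpha0 = par["alpha0"],
               k_alpha = par["k_alpha"];
  const double omega = par["omega"], Xvar0 = par["Xvar0"];
  const double sigma = par["sigma_bar"];
  const double Xin0 = par["Xin0"], Xout0 = par["Xout0"];
  const double Xres_tol = par["Xres_tol"];
  const bool growth_sqdiff = as<int>(par["growth_sqdiff"]) != 0;
  const bool re_count = as<int>(par["re_count"]) != 0;
  const bool gS_product = as<int>(par["gS_product"]) != 0;

  const double m0p = m0, m0q = m0 * m0;
  const bool stochastic = sigma > 0.0;
  const double dtb = dt_bio;
  const double dtJ_eff = dt_bio / tau_J;
  const double dtX_eff = dt_bio / (tau_J * tau_X);
  const double sq_dtb = std::sqrt(dtb);
  const double sq_dtJ = std::sqrt(dtJ_eff);
  const double sq_dtX = std::sqrt(dtX_eff);
  static const int sub[4] = {0, 1, 0, 2};  // substrate index per species

  // state
  double M[4], p[4], J[3];
  for (int i = 0; i < 4; ++i) M[i] = state0[i];
  for (int i = 0; i < 4; ++i) p[i] = state0[4 + i];
  for (int x = 0; x < 3; ++x) J[x] = state0[8 + x];
  double X = state0[11], XA = state0[12], XB = state0[13];
  double Xres = state0[14], Xres2 = state0[15];
  double alpha = suppress(X, alpha0, k_alpha, Xsuppress);

  // recording
  const int ncol = 26;
  int n_rec = 0;
  if (record_every > 0) n_rec = n_steps / record_every + 1;
  NumericMatrix rec(n_rec, ncol);
  int rec_row = 0;
  auto record = [&](double t) {
    double CR[3];
    for (int x = 0; x < 3; ++x) CR[x] = J[x] / Ji0;
    double ab = std::sqrt(CR[0] * p[0] * CR[1] * p[1]);
    double cdb = std::cbrt(CR[0] * p[2] * CR[2] * p[3] * CR[1] * p[1]);
    double tot = ab + cdb;
    double ab_n = tot > 0.0 ? ab / tot : 0.5;
    double cdb_n = tot > 0.0 ? cdb / tot : 0.5;
    int c = 0;
    rec(rec_row, c++) = t;
    for (int i = 0; i < 4; ++i) rec(rec_row, c++) = M[i];
    for (int i = 0; i < 4; ++i) rec(rec_row, c++) = p[i];
    for (int x = 0; x < 3; ++x) rec(rec_row, c++) = J[x];
    rec(rec_row, c++) = X; rec(rec_row, c++) = XA; rec(rec_row, c++) = XB;
    rec(rec_row, c++) = Xres; rec(rec_row, c++) = Xres2;
    rec(rec_row, c++) = alpha;
    for (int x = 0; x < 3; ++x) rec(rec_row, c++) = CR[x];
    rec(rec_row, c++) = ab; rec(rec_row, c++) = cdb;
    rec(rec_row, c++) = ab_n; rec(rec_row, c++) = cdb_n;
    rec(rec_row, c++) = (p[0] + p[1] + p[2] + p[3]) / 4.0;
    ++rec_row;
  };
  if (record_every > 0) record(t0);

  double np[4], dp[4], dM[4], R[4], gS[4], gR[4];

  for (int step = 1; step <= n_steps; ++step) {
    // --- biology: counts, fitnesses, mutation, frequency drift ---
    double Wp[4], Wq[4], REp[4], REq[4];
    for (int i = 0; i < 4; ++i) {
      np[i] = rha(p[i] * M[i]);
      double Js = J[sub[i]];
      Wp[i] = W0 * (1.0 + s * Js);
      Wq[i] = W0;
      double nq = M[i] - np[i];
      double Wm = M[i] > 0.0 ? (Wp[i] * np[i] + Wq[i] * nq) / M[i] : W0;
      if (Wm <= 0.0)
        stop("non-positive mean fitness for species %d at step %d",
             i + 1, step);
      double scale = re_count ? M[i] : 1.0;
      REp[i] = rha(Wp[i] * p[i] * scale);
      REq[i] = rha(Wq[i] * (1.0 - p[i]) * scale);
      double mp, mq;
      if (!stochastic) {
        mp = REp[i] > 0 ? m0p : 0.0;
        mq = REq[i] > 0 ? m0q : 0.0;
      } else {
        int same = 0, re = (int)REp[i];
        for (int k = 0; k < re; ++k)
          if (unif_rand() - m0p > 0.0) ++same;
        mp = re > 0 ? (double)(re - same) / re : 0.0;
        same = 0; re = (int)REq[i];
        for (int k = 0; k < re; ++k)
          if (unif_rand() - m0q > 0.0) ++same;
        mq = re > 0 ? (double)(re - same) / re : 0.0;
      }
      // an extinct genotype can only be regenerated by mutation, so the
      // selection term does not act on p = 0 (q = 0 is covered exactly:
      // n_p = M makes the mean fitness equal W_p)
      double sel = p[i] > 0.0 ? (Wp[i] - Wm) / Wm : 0.0;
      dp[i] = sel - mp + mq;
      double frac = M[i] / K;
      dM[i] = growth_sqdiff ? g0 * M[i] * (1.0 - frac) * (1.0 - frac)
                            : g0 * M[i] * (1.0 - frac * frac);
    }
    dM[2] -= M[2] * alpha;  // suppression kill on species C

    // --- reaction rates ---
    for (int i = 0; i < 4; ++i) {
      double BE = np[i] * rn_bar;
      if (BE > omega) BE = omega;
      double eff = J[sub[i]] * BE;
      R[i] = Rmax * eff / (Km + eff);
    }

    // --- J-cycle drift ---
    double dJ[3];
    dJ[0] = Fin0 - J[0] * Fout0 - R[0] + R[1] * (1.0 - eps_X) - R[2];
    dJ[1] = Fin0 - J[1] * Fout0 + R[0] * (1.0 - eps_X) - R[1] + R[3];
    dJ[2] = Fin0 - J[2] * Fout0 + R[2] - R[3];

    // --- X-cycle drift ---
    double prodAB = XA * XB;
    double Xvar = Xvar0 * Rmax * prodAB / (Km + prodAB);
    double dXA = eps_X * R[0] - Xout0 * XA - Xvar;
    double dXB = eps_X * R[1] - Xout0 * XB - Xvar;
    double dXres = -Xvar * Xres;
    double Xrelease = Xres > 0.0 ? 0.0 : Xrel0 * (Xres2 + Xvar);
    double dXres2 = -dXres - Xrelease;
    double Xfb = sigmoid_feedback(X, fb0, Xon, Xoff, a, b);
    double dX = Xin0 - Xout0 * X + Xrelease + Xfb;

    // --- diffusion coefficients and noise ---
    double gJ[3] = {0, 0, 0}, gXA_ = 0, gXB_ = 0, gXmain = 0;
    double zb[4] = {0, 0, 0, 0}, zJ[3] = {0, 0, 0},
           zXA = 0, zXB = 0, zX = 0;
    if (stochastic) {
      for (int i = 0; i < 4; ++i) {
        double vp = REp[i] > 0 ? m0p * (1.0 - m0p) / REp[i] : 0.0;
        double vq = REq[i] > 0 ? m0q * (1.0 - m0q) / REq[i] : 0.0;
        gS[i] = gS_product ? vp * vq : std::sqrt(vp + vq);
        double VARS = Wp[i] * p[i] * (1.0 - p[i]) +
                      Wq[i] * (1.0 - p[i]) * p[i];
        double VARnp = p[i] * p[i] * VARS + M[i] * M[i] * vp;
        double Js = J[sub[i]];
        double dRdn = (np[i] * rn_bar >= omega) ? 0.0 :
          Km * Rmax * Js * rn_bar /
            std::pow(Km + Js * np[i] * rn_bar, 2);
        gR[i] = dRdn * std::sqrt(VARnp);
      }
      gJ[0] = std::sqrt(gR[0] * gR[0] + gR[1] * gR[1] + gR[2] * gR[2]);
      gJ[1] = std::sqrt(gR[0] * gR[0] + gR[1] * gR[1] + gR[3] * gR[3]);
      gJ[2] = std::sqrt(gR[2] * gR[2] + gR[3] * gR[3]);
      gXA_ = gR[0]; gXB_ = gR[1];
      double den = std::pow(Km + prodAB, 2);
      double dxvA = Xvar0 * Rmax * XB * Km / den;
      double dxvB = Xvar0 * Rmax * XA * Km / den;
      gXmain = std::sqrt(gXA_ * gXA_ + gXB_ * gXB_ +
                         dxvA * dxvA * gXA_ * gXA_ +
                         dxvB * dxvB * gXB_ * gXB_);
      for (int i = 0; i < 4; ++i) zb[i] = norm_rand();
      for (int x = 0; x < 3; ++x) zJ[x] = norm_rand();
      zXA = norm_rand(); zXB = norm_rand(); zX = norm_rand();
    }

    // --- simultaneous update with clamping ---
    for (int i = 0; i < 4; ++i) {
      p[i] = clamp01(p[i] + dp[i] * dtb);
      double Mi = M[i] + dM[i] * dtb;
      if (stochastic) Mi += sigma * gS[i] * sq_dtb * zb[i];
      M[i] = Mi > 0.0 ? Mi : 0.0;
    }
    for (int x = 0; x < 3; ++x) {
      double Jx = J[x] + dJ[x] * dtJ_eff;
      if (stochastic) Jx += sigma * gJ[x] * sq_dtJ * zJ[x];
      J[x] = Jx > 0.0 ? Jx : 0.0;
    }
    XA += dXA * dtX_eff;
    if (stochastic) XA += sigma * gXA_ * sq_dtX * zXA;
    if (XA < 0.0) XA = 0.0;
    XB += dXB * dtX_eff;
    if (stochastic) XB += sigma * gXB_ * sq_dtX * zXB;
    if (XB < 0.0) XB = 0.0;
    Xres += dXres * dtX_eff;
    if (Xres < Xres_tol) Xres = 0.0;
    Xres2 += dXres2 * dtX_eff;
    if (Xres2 < 0.0) Xres2 = 0.0;
    X += dX * dtX_eff;
    if (stochastic) X += sigma * gXmain * sq_dtX * zX;
    if (X < 0.0) X = 0.0;
    alpha = suppress(X, alpha0, k_alpha, Xsuppress);

    // numerical-instability guard
    for (int i = 0; i < 4; ++i)
      if (!R_finite(M[i]) || !R_finite(p[i]))
        stop("non-finite biological state (species %d) at step %d",
             i + 1, step);
    if (!R_finite(J[0]) || !R_finite(J[1]) || !R_finite(J[2]))
      stop("non-finite J-variant level at step %d", step);
    if (!R_finite(X) || !R_finite(XA) || !R_finite(XB) ||
        !R_finite(Xres) || !R_finite(Xres2))
      stop("non-finite X-cycle state at step %d", step);

    if (record_every > 0 && step % record_every == 0)
      record(t0 + step * dt_bio);
  }

  NumericVector fin(16);
  for (int i = 0; i < 4; ++i) fin[i] = M[i];
  for (int i = 0; i < 4; ++i) fin[4 + i] = p[i];
  for (int x = 0; x < 3; ++x) fin[8 + x] = J[x];
  fin[11] = X; fin[12] = XA; fin[13] = XB; fin[14] = Xres;
  fin[15] = Xres2;

  NumericMatrix out_rec = (record_every > 0)
    ? rec(Range(0, rec_row - 1), Range(0, ncol - 1))
    : NumericMatrix(0, ncol);
  return List::create(_["state"] = fin, _["alpha"] = alpha,
                      _["records"] = out_rec);
}
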