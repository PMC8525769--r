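#include <Rcpp.h>
using namespace Rcpp;

static inline double clip01(double x, double eps) {
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// One forward pass of the two-level, dual-stream binary HGF.
//
// Per trial: predict level-1 beliefs from the previous level-2 state
// (social map depends on the perceptual variant), combine the two streams
// by precision weighting in bet-agreement space, then update level 2 of
// each stream with its input via the precision-weighted prediction error.
//
// social_variant: 1 = logistic(eta * omega_s * mu2_s)   (winning map)
//                 2 = logistic(mu2_s + bias)            (additive exponent)
//                 3 = logistic(bias * mu2_s)            (free multiplicative)
// has_social = false runs the non-social stream alone (the bet-free first
// phase); the combined belief then equals the non-social prediction in
// scene space and all social columns are NA.
//
// Note the level-1 precision 1/(p*(1-p)) is identical in scene space and in
// agreement space because p*(1-p) is symmetric under p -> 1-p.
// [[Rcpp::export]]
List hgf_filter_cpp(NumericVector u_s, NumericVector u_ns, NumericVector rb,
                    LogicalVector bet_is_scene,
                    double omega_s, double omega_ns, double eta,
                    double social_bias, int social_variant,
                    double mu2s0, double sigma2s0,
                    double mu2ns0, double sigma2ns0,
                    bool has_social, double eps) {
  int n = u_ns.size();
  NumericVector mu1hat_s(n), mu1hat_ns(n), a_ns(n), b(n),
    mu2_s(n), sigma2_s(n), mu2_ns(n), sigma2_ns(n),
    delta1_s(n), delta1_ns(n), pi1hat_s(n), pi1hat_ns(n),
    pi2hat_s(n), pi2hat_ns(n);
  double m2s = mu2s0, s2s = sigma2s0, m2ns = mu2ns0, s2ns = sigma2ns0;

  for (int t = 0; t < n; ++t) {
    // predictions (from the previous trial's level-2 state)
    double m1ns = clip01(1.0 / (1.0 + std::exp(-(m2ns + rb[t]))), eps);
    double p1ns = 1.0 / (m1ns * (1.0 - m1ns));
    mu1hat_ns[t] = m1ns;
    pi1hat_ns[t] = p1ns;

    if (has_social) {
      double xs;
      if (social_variant == 1)      xs = eta * omega_s * m2s;
      else if (social_variant == 2) xs = m2s + social_bias;
      else                          xs = social_bias * m2s;
      double m1s = clip01(1.0 / (1.0 + std::exp(-xs)), eps);
      double p1s = 1.0 / (m1s * (1.0 - m1s));
      double ans = bet_is_scene[t] ? m1ns : 1.0 - m1ns;
      b[t] = (p1s * m1s + p1ns * ans) / (p1s + p1ns);
      mu1hat_s[t] = m1s;
      pi1hat_s[t] = p1s;
      a_ns[t] = ans;

      // social level-2 update (input: bet correctness)
      double p2h = 1.0 / (s2s + omega_s);
      double d1 = u_s[t] - m1s;
      double p2 = p2h + m1s * (1.0 - m1s);
      m2s += d1 / p2;
      s2s = 1.0 / p2;
      pi2hat_s[t] = p2h;
      delta1_s[t] = d1;
      mu2_s[t] = m2s;
      sigma2_s[t] = s2s;
    } else {
      b[t] = m1ns;  // scene-space belief; no bets exist in this phase
      mu1hat_s[t] = NA_REAL; pi1hat_s[t] = NA_REAL; a_ns[t] = NA_REAL;
      pi2hat_s[t] = NA_REAL; delta1_s[t] = NA_REAL;
      mu2_s[t] = NA_REAL; sigma2_s[t] = NA_REAL;
    }

    // non-social level-2 update (input: scene fraction)
    {
      double p2h = 1.0 / (s2ns + omega_ns);
      double d1 = u_ns[t] - m1ns;
      double p2 = p2h + m1ns * (1.0 - m1ns);
      m2ns += d1 / p2;
      s2ns = 1.0 / p2;
      pi2hat_ns[t] = p2h;
      delta1_ns[t] = d1;
      mu2_ns[t] = m2ns;
      sigma2_ns[t] = s2ns;
    }
  }

  return List::create(
    _["mu1hat_s"] = mu1hat_s, _["mu1hat_ns"] = mu1hat_ns,
    _["a_ns"] = a_ns, _["b"] = b,
    _["pi1hat_s"] = pi1hat_s, _["pi1hat_ns"] = pi1hat_ns,
    _["pi2hat_s"] = pi2hat_s, _["pi2hat_ns"] = pi2hat_ns,
    _["delta1_s"] = delta1_s, _["delta1_ns"] = delta1_ns,
    _["mu2_s"] = mu2_s, _["sigma2_s"] = sigma2_s,
    _["mu2_ns"] = mu2_ns, _["sigma2_ns"] = sigma2_ns);
}

// Rescorla-Wagner baseline: fixed-rate delta-rule tracking of each input
// stream; streams are combined exactly as in the HGF (precision weights
// computed from the associative strengths in agreement space).
// [[Rcpp::export]]
List rw_filter_cpp(NumericVector u_s, NumericVector u_ns,
                   LogicalVector bet_is_scene,
                   double alpha_s, double alpha_ns,
                   double V0_s, double V0_ns,
                   bool has_social, double eps) {
  int n = u_ns.size();
  NumericVector mu1hat_s(n), mu1hat_ns(n), a_ns(n), b(n), V_s(n), V_ns(n);
  double vs = V0_s, vns = V0_ns;

  for (int t = 0; t < n; ++t) {
    double m1ns = clip01(vns, eps);
    double p1ns = 1.0 / (m1ns * (1.0 - m1ns));
    mu1hat_ns[t] = m1ns;

    if (has_social) {
      double m1s = clip01(vs, eps);
      double p1s = 1.0 / (m1s * (1.0 - m1s));
      double ans = bet_is_scene[t] ? m1ns : 1.0 - m1ns;
      b[t] = (p1s * m1s + p1ns * ans) / (p1s + p1ns);
      mu1hat_s[t] = m1s;
      a_ns[t] = ans;
      vs += alpha_s * (u_s[t] - vs);
      V_s[t] = vs;
    } else {
      b[t] = m1ns;
      mu1hat_s[t] = NA_REAL; a_ns[t] = NA_REAL; V_s[t] = NA_REAL;
    }

    vns += alpha_ns * (u_ns[t] - vns);
    V_ns[t] = vns;
  }

  return List::create(
    _["mu1hat_s"] = mu1hat_s, _["mu1hat_ns"] = mu1hat_ns,
    _["a_ns"] = a_ns, _["b"] = b,
    _["V_s"] = V_s, _["V_ns"] = V_ns);
}
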