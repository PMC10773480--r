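// Joint negative log posterior of the mixed-effects location-scale
// beta-binomial model, for Laplace-marginal estimation via TMB.
//
// Location:  logit(p_ij)  = x_ij' beta_p  + u0_i + u1_i * zage_ij
// Scale:     log(theta_ij) = w_ij' beta_theta + v0_i   (clamped at +/-16,
//            beyond which the count is numerically binomial and lgamma
//            differences would lose precision)
// (u0, u1, v0)_i ~ MVN(0, D R D), non-centred: effects = D L z_i with
// z_i ~ N(0, I3) and L the Cholesky factor of the correlation matrix R,
// parametrized by canonical partial correlations z = tanh(cpc_raw).
//
// Priors: normal on fixed effects (per-coefficient scales), half-t on the
// random-effect SDs, LKJ(eta) on R expressed through the CPCs (for eta = 1
// the implied prior is uniform over valid correlation matrices).
#define TMB_LIB_INIT R_init_melsbb
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()()
{
  DATA_MATRIX(Xp);            // n_obs x P design for logit p
  DATA_MATRIX(Xt);            // n_obs x Q design for log theta
  DATA_VECTOR(zage);          // centred age (decades), random-slope variable
  DATA_VECTOR(y);             // scores
  DATA_VECTOR(ntr);           // trials per observation
  DATA_VECTOR(lchoose_ny);    // log C(n, y), parameter-free
  DATA_IVECTOR(person);       // 0-based person index per row
  DATA_VECTOR(prior_sc_p);    // normal prior SDs for beta_p
  DATA_VECTOR(prior_sc_t);    // normal prior SDs for beta_theta
  DATA_SCALAR(sd_df);
  DATA_SCALAR(sd_scale);
  DATA_SCALAR(lkj_eta);
  DATA_INTEGER(include_prior);

  PARAMETER_VECTOR(beta_p);
  PARAMETER_VECTOR(beta_theta);
  PARAMETER_VECTOR(log_sd);   // (sd_u0, sd_u1, sd_v0) on log scale
  PARAMETER_VECTOR(cpc_raw);  // atanh canonical partial correlations
  PARAMETER_MATRIX(z_re);     // n_persons x 3 standardized person effects

  int n_obs = y.size();
  int n_per = z_re.rows();

  Type nll = 0;

  vector<Type> sdv = exp(log_sd);
  vector<Type> z = tanh(cpc_raw);  // (z21, z31, z32)

  // Cholesky factor of the correlation matrix from the CPCs; always PD.
  Type l21 = z(0);
  Type l22 = sqrt(Type(1) - l21 * l21);
  Type l31 = z(1);
  Type l32 = z(2) * sqrt(Type(1) - l31 * l31);
  Type l33sq = Type(1) - l31 * l31 - l32 * l32;
  l33sq = CppAD::CondExpGt(l33sq, Type(1e-12), l33sq, Type(1e-12));
  Type l33 = sqrt(l33sq);

  // Standardized effects ~ N(0, I)
  for (int i = 0; i < n_per; i++)
    for (int k = 0; k < 3; k++)
      nll -= dnorm(z_re(i, k), Type(0), Type(1), true);

  // Actual person effects: u = D L z
  vector<Type> u0(n_per), u1(n_per), v0(n_per);
  for (int i = 0; i < n_per; i++) {
    u0(i) = sdv(0) * z_re(i, 0);
    u1(i) = sdv(1) * (l21 * z_re(i, 0) + l22 * z_re(i, 1));
    v0(i) = sdv(2) * (l31 * z_re(i, 0) + l32 * z_re(i, 1) + l33 * z_re(i, 2));
  }

  vector<Type> eta_p_fix = Xp * beta_p;
  vector<Type> eta_t_fix = Xt * beta_theta;

  for (int j = 0; j < n_obs; j++) {
    int i = person(j);
    Type eta_p = eta_p_fix(j) + u0(i) + u1(i) * zage(j);
    Type eta_t = eta_t_fix(j) + v0(i);
    // clamps keep p off the exact 0/1 boundary and theta where lgamma
    // differences retain precision; inactive at any plausible mode
    eta_p = CppAD::CondExpGt(eta_p, Type(15), Type(15), eta_p);
    eta_p = CppAD::CondExpLt(eta_p, Type(-15), Type(-15), eta_p);
    eta_t = CppAD::CondExpGt(eta_t, Type(16), Type(16), eta_t);
    eta_t = CppAD::CondExpLt(eta_t, Type(-16), Type(-16), eta_t);
    Type p = invlogit(eta_p);
    Type theta = exp(eta_t);
    Type a = p * theta;
    Type b = (Type(1) - p) * theta;
    nll -= lchoose_ny(j) +
      lgamma(y(j) + a) + lgamma(ntr(j) - y(j) + b) -
      lgamma(ntr(j) + a + b) + lgamma(a + b) - lgamma(a) - lgamma(b);
  }

  if (include_prior) {
    for (int j = 0; j < beta_p.size(); j++)
      nll -= dnorm(beta_p(j), Type(0), prior_sc_p(j), true);
    for (int j = 0; j < beta_theta.size(); j++)
      nll -= dnorm(beta_theta(j), Type(0), prior_sc_t(j), true);
    // half-t prior on sd, with log-sd Jacobian
    for (int k = 0; k < 3; k++)
      nll -= dt(sdv(k) / sd_scale, sd_df, true) - log(sd_scale) +
        log(Type(2)) + log_sd(k);
    // LKJ(eta) through independent scaled-Beta CPCs; alpha_j depends on
    // the column of the Cholesky row the CPC lives in; the tanh Jacobian
    // contributes one extra power of (1 - z^2).
    vector<Type> alpha(3);
    alpha(0) = lkj_eta + Type(0.5);
    alpha(1) = lkj_eta + Type(0.5);
    alpha(2) = lkj_eta;
    for (int j = 0; j < 3; j++)
      nll -= alpha(j) * log(Type(1) - z(j) * z(j));
  }

  vector<Type> rho(3);   // (r_u0u1, r_u0v0, r_u1v0)
  rho(0) = l21;
  rho(1) = l31;
  rho(2) = l21 * l31 + l22 * l32;
  ADREPORT(sdv);
  ADREPORT(rho);

  return nll;
}
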