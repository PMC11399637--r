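// Joint negative log-likelihood for one drug's hierarchical PK model:
// 1-compartment (IV bolus / first-order oral) or comparator 2-compartment IV,
// lognormal inter-individual variability on ka, Vd, CL with a full
// correlation matrix, logit-normal bioavailability, body-weight and sex
// covariates on the log scale, proportional residual error, and
// left-censored (BLQ) observations entering as censored probability mass.
// The Laplace approximation over the per-subject random effects `eta`
// (via MakeADFun(random = "eta")) yields the marginal likelihood.
#define TMB_LIB_INIT R_init_sulfatrim
#include <TMB.hpp>

// numerically robust log Phi(x): exact in the bulk, Mills-ratio
// asymptotic expansion in the far left tail (keeps gradients finite and
// smooth where pnorm() underflows)
template <class Type>
Type log_pnorm_robust(Type x) {
  Type bulk = log(pnorm(x) + Type(1e-308));
  Type x2 = x * x;
  Type tail = -Type(0.5) * x2 - log(-x + Type(1e-12)) -
              Type(0.5) * log(Type(2) * M_PI) +
              log(Type(1) - Type(1) / x2 + Type(3) / (x2 * x2));
  return CppAD::CondExpLt(x, Type(-6), tail, bulk);
}

template <class Type>
Type objective_function<Type>::operator()() {
  // observations (one drug)
  DATA_IVECTOR(obs_subj);   // 0-based subject index
  DATA_VECTOR(obs_time);    // h, absolute study time
  DATA_VECTOR(obs_dv);      // ug/mL; ignored when censored
  DATA_IVECTOR(obs_cens);   // 1 = left-censored at obs_loq
  DATA_VECTOR(obs_loq);     // ug/mL

  // dose events (same drug)
  DATA_IVECTOR(ev_subj);
  DATA_VECTOR(ev_time);     // h
  DATA_VECTOR(ev_amt);      // mg, absolute
  DATA_IVECTOR(ev_oral);    // 1 = oral, 0 = IV bolus

  // subjects
  DATA_VECTOR(bw);          // kg
  DATA_VECTOR(logbw_norm);  // log(BW / median BW)
  DATA_IVECTOR(sexM);       // 1 = male

  DATA_INTEGER(ncmt);       // 1 or 2 (2: IV-only comparator)

  PARAMETER(logit_F);
  PARAMETER(log_ka);        // 1/h
  PARAMETER(log_Vd);        // L/kg (V1 for the 2-compartment model)
  PARAMETER(log_CL);        // L/h/kg
  PARAMETER(beta_ka_bw);
  PARAMETER(beta_Vd_bw);
  PARAMETER(beta_CL_bw);
  PARAMETER(beta_ka_sex);
  PARAMETER(beta_Vd_sex);
  PARAMETER(beta_CL_sex);
  PARAMETER_VECTOR(log_omega);   // SDs of eta: (ka, Vd, CL)
  PARAMETER_VECTOR(corr_theta);  // unstructured 3x3 correlation, 3 values
  PARAMETER(log_b);              // proportional error SD
  PARAMETER(log_Q);              // L/h/kg, 2-cmt only
  PARAMETER(log_V2);             // L/kg,   2-cmt only
  PARAMETER_MATRIX(eta);         // n_subj x 3

  int n_subj = bw.size();
  int n_obs = obs_time.size();
  int n_ev = ev_time.size();

  vector<Type> omega = exp(log_omega);
  Type F = invlogit(logit_F);
  Type b = exp(log_b);

  Type nll = Type(0);

  // random-effect density: eta_i ~ N(0, D R D), D = diag(omega)
  density::UNSTRUCTURED_CORR_t<Type> R(corr_theta);
  for (int i = 0; i < n_subj; i++) {
    vector<Type> ei = eta.row(i);
    nll += density::VECSCALE(R, omega)(ei);
  }

  // realized individual parameters (absolute units)
  vector<Type> ka_i(n_subj), V_i(n_subj), CL_i(n_subj), Q_i(n_subj), V2_i(n_subj);
  for (int i = 0; i < n_subj; i++) {
    Type sx = Type(sexM(i));
    Type lbw = logbw_norm(i);
    ka_i(i) = exp(log_ka + beta_ka_bw * lbw + beta_ka_sex * sx + eta(i, 0));
    V_i(i) = exp(log_Vd + beta_Vd_bw * lbw + beta_Vd_sex * sx + eta(i, 1)) * bw(i);
    CL_i(i) = exp(log_CL + beta_CL_bw * lbw + beta_CL_sex * sx + eta(i, 2)) * bw(i);
    Q_i(i) = exp(log_Q) * bw(i);
    V2_i(i) = exp(log_V2) * bw(i);
  }

  // predictions by superposition over dose events
  vector<Type> f(n_obs);
  f.setZero();
  for (int j = 0; j < n_obs; j++) {
    int i = obs_subj(j);
    Type ke = CL_i(i) / V_i(i);
    for (int e = 0; e < n_ev; e++) {
      if (ev_subj(e) != i) continue;
      Type dt = obs_time(j) - ev_time(e);
      if (asDouble(dt) < 0) continue;
      Type amt = ev_amt(e);
      if (ev_oral(e) == 1) {
        // Bateman; analytic ka -> ke limit when |ka - ke| < 1e-6 * ke
        Type d = ka_i(i) - ke;
        Type tol = Type(1e-6) * ke;
        Type d_safe = CppAD::CondExpGt(fabs(d), tol, d, tol);
        Type bateman = F * amt * ka_i(i) / (V_i(i) * d_safe) *
                       (exp(-ke * dt) - exp(-ka_i(i) * dt));
        Type limit = F * amt * ka_i(i) * dt * exp(-ka_i(i) * dt) / V_i(i);
        f(j) += CppAD::CondExpGt(fabs(d), tol, bateman, limit);
      } else if (ncmt == 2) {
        // bi-exponential disposition, central compartment V1
        Type k10 = CL_i(i) / V_i(i);
        Type k12 = Q_i(i) / V_i(i);
        Type k21 = Q_i(i) / V2_i(i);
        Type s = k10 + k12 + k21;
        Type root = sqrt(s * s - Type(4) * k10 * k21);
        Type alpha = (s + root) / Type(2);
        Type beta2 = (s - root) / Type(2);
        Type A = (alpha - k21) / (alpha - beta2);
        Type B = (k21 - beta2) / (alpha - beta2);
        f(j) += amt / V_i(i) * (A * exp(-alpha * dt) + B * exp(-beta2 * dt));
      } else {
        f(j) += amt / V_i(i) * exp(-ke * dt);
      }
    }
  }

  // residual likelihood: proportional error, M3 censoring
  for (int j = 0; j < n_obs; j++) {
    Type fj = f(j) + Type(1e-12);  // guard exact zero predictions
    Type sd = b * fj;
    if (obs_cens(j) == 1) {
      nll -= log_pnorm_robust((obs_loq(j) - fj) / sd);
    } else {
      nll -= dnorm(obs_dv(j), fj, sd, true);
    }
  }

  matrix<Type> corr = R.cov();
  vector<Type> ka_pop(1), Vd_pop(1), CL_pop(1), F_pop(1), b_err(1);
  F_pop(0) = F; ka_pop(0) = exp(log_ka); Vd_pop(0) = exp(log_Vd);
  CL_pop(0) = exp(log_CL); b_err(0) = b;
  ADREPORT(F_pop);
  ADREPORT(ka_pop);
  ADREPORT(Vd_pop);
  ADREPORT(CL_pop);
  ADREPORT(omega);
  ADREPORT(b_err);
  ADREPORT(corr);
  REPORT(f);

  return nll;
}
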