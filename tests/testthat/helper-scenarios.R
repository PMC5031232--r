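# Shared scenario builders used across test files.

# Heatmap/heterogeneity generating state: per-estimate variance 1/3
# (within-study variance 19.94 at effective size 61).
fig_state <- function(theta, tau2 = 0, sigma2 = 1 / 3) {
  true_state(theta, sigma2, tau2 = tau2, sigma2_is_total = TRUE)
}

# The three selection models at theta0 = 0.5 with scale sqrt(sigma2).
selection_models <- function(sigma2 = 1 / 3) {
  list(
    power_law = decision_model("power_law", theta0 = 0.5, t = 3),
    extreme_value = decision_model("extreme_value", theta0 = 0.5, r = 0.8,
                                   sigma = sqrt(sigma2)),
    probit = decision_model("probit", theta0 = 0.5, r = 0.8,
                            sigma = sqrt(sigma2))
  )
}

# Dentifrice decision scenario: true state and window rule.
johnson_state <- function(df = 60) {
  true_state(theta = 0.28, sigma2 = 21.62, n1 = 61, df = df)
}

johnson_window <- function(a = 50, b = 500) {
  decision_model("power_calc_window", a = a, b = b, alpha = 0.05, beta = 0.2)
}

# Design-bias scenario of the d-sweep simulations (theta = 0.2,
# delta = 0.2, variances 19.94 / 24.96, n1 = 61).
sweep_design_state <- function(df = 60) {
  true_state(theta = 0.2, sigma2 = 19.94, n1 = 61, df = df)
}

# Monte-Carlo covariance of p(theta_hat) with theta_hat: independent oracle
# for the quadrature in cov_p_theta / expected_p.
mc_p_moments <- function(state, model, reps = 1e6, seed = 42) {
  set.seed(seed)
  x <- rnorm(reps, state$theta,
             sqrt(if (state$sigma2_is_total) state$sigma2 + state$tau2
                  else state$sigma2 / state$n1 + state$tau2))
  p <- decision_prob(model, x, state = state)
  list(cov = stats::cov(p, x),
       cov_se = stats::sd((p - mean(p)) * (x - mean(x))) / sqrt(reps),
       e_p = mean(p),
       e_p_se = stats::sd(p) / sqrt(reps))
}
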