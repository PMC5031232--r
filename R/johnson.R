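#' The fluoride dentifrice worked example
#'
#' Loads the packaged fixture for the worked example: a nine-study
#' meta-analysis of sodium monofluorophosphate versus sodium fluoride
#' dentifrices (dental decay score, mean difference). The fixture carries
#' the first three trials' effective sample sizes and pooled variances,
#' the first trial's effect estimate (0.86), the nine-study pooled values
#' taken as the true state (\eqn{\theta} = 0.28, \eqn{\sigma^2} = 21.62),
#' the sample-size window for a new trial (200--2000 patients, i.e.
#' effective sizes 50--500), and the design-bias offset
#' \eqn{\delta} = -0.36 that "corrects" the first estimate to 0.50. The
#' second and third trials' effect estimates are not part of the fixture
#' (`NA`); only their weights enter any computation.
#'
#' @return An object of class `"johnson_fixture"`: a list with elements
#'   `trials` (list of [study_summary()]), `theta_hat1`, `theta`,
#'   `sigma2`, `a`, `b`, `alpha`, `beta`, `delta_design`, `n1_sim`,
#'   `sigma2_first`, `sigma2_second`.
#' @export
johnson_fixture <- function() {
  trials <- read_study_table(
    system.file("extdata", "johnson_trials.csv", package = "seqmetabias",
                mustWork = TRUE))
  par_tab <- utils::read.csv(
    system.file("extdata", "johnson_scenario.csv", package = "seqmetabias",
                mustWork = TRUE), stringsAsFactors = FALSE)
  pars <- stats::setNames(as.numeric(par_tab$value), par_tab$key)
  structure(
    list(trials = trials,
         theta_hat1 = pars[["theta_hat1"]],
         theta = pars[["assumed_true_theta"]],
         sigma2 = pars[["assumed_true_sigma2"]],
         a = pars[["window_a"]], b = pars[["window_b"]],
         alpha = pars[["alpha"]], beta = pars[["beta"]],
         delta_design = pars[["delta_design"]],
         n1_sim = pars[["n1_sim"]],
         sigma2_first = pars[["sigma2_first"]],
         sigma2_second = pars[["sigma2_second"]]),
    class = "johnson_fixture"
  )
}

#' @export
print.johnson_fixture <- function(x, ...) {
  cat("fluoride dentifrice worked example\n")
  cat(sprintf("  first-trial estimate %.2f; assumed true theta = %.2f, sigma2 = %.2f\n",
              x$theta_hat1, x$theta, x$sigma2))
  cat(sprintf("  window (%g, %g], alpha = %g, beta = %g, design delta = %g\n",
              x$a, x$b, x$alpha, x$beta, x$delta_design))
  invisible(x)
}

#' Decision-bias report for the worked example
#'
#' Computes, side by side, the analytic (quadrature) and simulated
#' quantities of the worked example's decision scenario: the required
#' second-trial size from the estimate-based formula; the unconditional
#' continuation probability under the (50, 500] window and under the
#' relaxed rule with no lower restriction; and the simulated continuation
#' probability with the three percent biases (unconditional,
#' continue-branch, stop-branch) of the pooled two-trial estimate.
#'
#' @param fixture A [johnson_fixture()].
#' @param reps Monte-Carlo replications (default 10000).
#' @param seed Integer seed.
#' @param df Degrees of freedom for the first trial's sample variance in
#'   the probability model and simulation. Default `round(n1) - 1 = 60`
#'   (matching the simulation's effective-size framing); the per-arm
#'   alternative `N - 2 = 243` can be passed for sensitivity.
#' @return A data frame with columns `quantity` and `value`; the
#'   underlying `"bias_result"` is attached as attribute `"sim"`.
#' @export
run_decision_report <- function(fixture, reps = 10000L, seed = 1L, df = 60L) {
  stopifnot(inherits(fixture, "johnson_fixture"))
  cst <- power_constant(fixture$alpha, fixture$beta)
  tr1 <- fixture$trials[[1]]
  n2_req <- sample_size_estimated_target(
    fixture$theta_hat1, tr1$s2, tr1$n_eff, delta = 0, c = cst)
  state <- true_state(theta = fixture$theta, sigma2 = fixture$sigma2,
                      n1 = fixture$n1_sim, df = df)
  windowed <- decision_model("power_calc_window", a = fixture$a,
                             b = fixture$b, alpha = fixture$alpha,
                             beta = fixture$beta)
  relaxed <- decision_model("power_calc_window", a = -Inf, b = fixture$b,
                            alpha = fixture$alpha, beta = fixture$beta)
  p_window <- continuation_prob_unconditional(state, windowed)
  p_relaxed <- continuation_prob_unconditional(state, relaxed)
  sim <- simulate_decision(sim_config(state, windowed,
                                      weights_policy = "inverse_variance",
                                      reps = reps, seed = seed))
  out <- data.frame(
    quantity = c("c", "c_squared", "n2_required",
                 "p_continue_analytic", "p_continue_analytic_no_lower",
                 "p_continue_simulated", "percent_bias_unconditional",
                 "percent_bias_continue", "percent_bias_stop"),
    value = c(cst$c, cst$c^2, n2_req, p_window, p_relaxed,
              sim$p_continue, sim$percent_unconditional,
              sim$percent_continue, sim$percent_stop))
  attr(out, "sim") <- sim
  out
}

#' Design-bias report for the worked example
#'
#' Sweeps the design-bias simulation over a grid of variance-guess ratios
#' `d` for the worked example's design scenario: the investigators assume
#' the first estimate is too optimistic and apply \eqn{\delta = -0.36} to
#' "correct" the target to 0.50, then size the second trial from it.
#'
#' @param fixture A [johnson_fixture()].
#' @param d_grid Variance-guess ratios (default 0.1 to 10 in steps of
#'   0.1).
#' @param reps Monte-Carlo replications per grid point (default 10000).
#' @param seed Integer seed.
#' @param df Degrees of freedom for the first-trial variance estimate.
#' @return The [simulate_design()] table (`d`, `percent_bias`,
#'   `mc_se_percent`).
#' @export
run_design_report <- function(fixture, d_grid = seq(0.1, 10, by = 0.1),
                              reps = 10000L, seed = 1L, df = 60L) {
  stopifnot(inherits(fixture, "johnson_fixture"))
  state <- true_state(theta = fixture$theta, sigma2 = fixture$sigma2_first,
                      n1 = fixture$n1_sim, df = df)
  scen <- design_scenario(state, sigma2_second = fixture$sigma2_second,
                          d_ratio = 1, delta = fixture$delta_design,
                          alpha = fixture$alpha, beta = fixture$beta,
                          reps = reps, seed = seed)
  simulate_design(scen, d_grid = d_grid)
}
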