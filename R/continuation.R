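#' Conditional probability that the window rule launches the next trial
#'
#' Under the power-calculation window rule the next trial is run iff its
#' required size \eqn{n_2 = c^2 s_1^2/\theta_1^2 - n_1} falls in
#' \eqn{(a, b]}. Given \eqn{\hat\theta_1 = \theta_1}, the only randomness
#' left is the sample variance, with
#' \eqn{d_1 s_1^2/\sigma_1^2 \sim \chi^2_{d_1}}, so
#' \deqn{P(a < n_2 \le b \mid \theta_1) =
#'   F_{\chi^2_{d_1}}\!\big(d_1 (b+n_1)\theta_1^2/(c^2\sigma_1^2)\big) -
#'   F_{\chi^2_{d_1}}\!\big(d_1 (a+n_1)\theta_1^2/(c^2\sigma_1^2)\big).}
#' With `a = -Inf` the lower restriction is dropped entirely (continue
#' whenever \eqn{n_2 \le b}) and only the first term remains.
#'
#' @param theta1 Value(s) of the first-trial effect estimate.
#' @param state A [true_state()] giving \eqn{\sigma_1^2}, \eqn{n_1} and the
#'   degrees of freedom \eqn{d_1}.
#' @param model A `"decision_model"` of variant `"power_calc_window"`.
#' @return Probabilities in `[0, 1]`, vectorised over `theta1`.
#' @export
continuation_prob_conditional <- function(theta1, state, model) {
  stopifnot(inherits(state, "true_state"), inherits(model, "decision_model"))
  if (model$variant != "power_calc_window") {
    stop("model must be of variant power_calc_window", call. = FALSE)
  }
  cc <- power_constant(model$alpha, model$beta)$c
  d1 <- state$df
  scale <- d1 * theta1^2 / (cc^2 * state$sigma2)
  hi <- stats::pchisq((model$b + state$n1) * scale, d1)
  lo <- if (is.finite(model$a)) {
    stats::pchisq((model$a + state$n1) * scale, d1)
  } else 0
  pmax(hi - lo, 0)
}

#' Unconditional probability that the window rule launches the next trial
#'
#' Integrates [continuation_prob_conditional()] against the sampling law
#' of the first-trial estimate,
#' \eqn{\hat\theta_1 \sim N(\theta, \sigma_1^2/n_1)}, by adaptive
#' quadrature over \eqn{\theta \pm 10} standard deviations (the omitted
#' normal tail mass is below 1e-22).
#'
#' @inheritParams continuation_prob_conditional
#' @param abs_tol Absolute quadrature tolerance (default 1e-8).
#' @return A single probability.
#' @export
continuation_prob_unconditional <- function(state, model, abs_tol = 1e-8) {
  stopifnot(inherits(state, "true_state"), inherits(model, "decision_model"))
  sd1 <- sqrt(.marginal_var(state))
  f <- function(x) {
    continuation_prob_conditional(x, state, model) *
      stats::dnorm(x, state$theta, sd1)
  }
  res <- tryCatch(
    stats::integrate(f, state$theta - 10 * sd1, state$theta + 10 * sd1,
                     abs.tol = abs_tol, rel.tol = abs_tol,
                     subdivisions = 500L),
    error = function(e) {
      stop("quadrature failed: ", conditionMessage(e), call. = FALSE)
    })
  min(max(res$value, 0), 1)
}
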