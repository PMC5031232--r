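# Expectation of g(X) for X ~ N(mean, sd^2) by adaptive quadrature over
# mean +/- 10 sd, split at the supplied discontinuity knots of g.
.gauss_expect <- function(g, mean, sd, knots = numeric(0), abs_tol = 1e-8) {
  lo <- mean - 10 * sd
  hi <- mean + 10 * sd
  pts <- sort(unique(c(lo, knots[knots > lo & knots < hi], hi)))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    res <- tryCatch(
      stats::integrate(function(x) g(x) * stats::dnorm(x, mean, sd),
                       pts[i], pts[i + 1L],
                       abs.tol = abs_tol, rel.tol = abs_tol,
                       subdivisions = 500L),
      error = function(e) {
        stop("quadrature failed: ", conditionMessage(e), call. = FALSE)
      })
    total <- total + res$value
  }
  total
}

# Discontinuity points of the decision probability, for quadrature splitting.
.model_knots <- function(model) {
  switch(model$variant,
    power_law = c(0, model$theta0),
    extreme_value = ,
    probit = model$r * model$theta0,
    power_calc_window = numeric(0))
}

# p(theta_hat) as a function of the estimate alone; for the window rule the
# sample variance is already integrated out.
.p_fun <- function(state, model) {
  function(x) decision_prob(model, x, state = state)
}

#' Expected probability of conducting the next trial
#'
#' \eqn{E[p(\hat\theta_1)]} under
#' \eqn{\hat\theta_1 \sim N(\theta, \sigma^2/n_1 + \tau^2)} (or
#' \eqn{\sigma^2 + \tau^2} when the state fixes the per-estimate variance),
#' evaluated by quadrature.
#'
#' @param state A [true_state()].
#' @param model A `"decision_model"`.
#' @return A probability.
#' @export
expected_p <- function(state, model) {
  p <- .gauss_expect(.p_fun(state, model), state$theta,
                     sqrt(.marginal_var(state)), .model_knots(model))
  min(max(p, 0), 1)
}

#' Covariance between the continuation probability and the estimate
#'
#' \eqn{Cov\{p(\hat\theta_1), \hat\theta_1\}} under the marginal normal law
#' of the first-stage estimate. This covariance is the engine of sequential
#' decision bias: the pooled estimate after the decision is biased exactly
#' when it is non-zero.
#'
#' @inheritParams expected_p
#' @return The covariance (a real number).
#' @export
cov_p_theta <- function(state, model) {
  sd1 <- sqrt(.marginal_var(state))
  knots <- .model_knots(model)
  pf <- .p_fun(state, model)
  e_p <- .gauss_expect(pf, state$theta, sd1, knots)
  e_px <- .gauss_expect(function(x) pf(x) * x, state$theta, sd1, knots)
  e_px - e_p * state$theta
}

#' Unconditional bias of the pooled two-stage estimate
#'
#' \eqn{E[\hat\theta_{(2)}] - \theta = (\omega_1 - 1)\,
#' Cov\{p(\hat\theta_1), \hat\theta_1\}}: when the probability of a further
#' trial is positively correlated with the current estimate, the pooled
#' estimator is negatively biased (\eqn{\omega_1 - 1 < 0}).
#'
#' @inheritParams expected_p
#' @param omega1 Normalised weight of the first stage, in (0, 1].
#' @return The bias (effect units).
#' @export
unconditional_bias <- function(state, model, omega1) {
  if (omega1 <= 0 || omega1 > 1) stop("omega1 must be in (0, 1]", call. = FALSE)
  (omega1 - 1) * cov_p_theta(state, model)
}

#' Conditional bias of the pooled estimate given the decision
#'
#' Given that the next trial is conducted (`branch = "continue"`), the bias
#' is \eqn{\omega_1 Cov\{p, \hat\theta_1\}/E[p] +
#' \omega_1 (E\hat\theta_1 - \theta)}; the last term is zero for an
#' unbiased first stage but is carried so the expression composes across
#' sequential steps (see [recurrent_bias()]). Given that it is not
#' (`branch = "stop"`), the bias is
#' \eqn{-Cov\{p, \hat\theta_1\}/(1 - E[p])}. Under a positive covariance
#' the continue-branch bias is positive and the stop-branch bias negative.
#'
#' @inheritParams unconditional_bias
#' @param branch `"continue"` or `"stop"`.
#' @param first_stage_bias \eqn{E[\hat\theta_1] - \theta} (default 0).
#' @return The conditional bias (effect units).
#' @export
conditional_bias <- function(state, model, omega1,
                             branch = c("continue", "stop"),
                             first_stage_bias = 0) {
  branch <- match.arg(branch)
  if (omega1 <= 0 || omega1 > 1) stop("omega1 must be in (0, 1]", call. = FALSE)
  e_p <- expected_p(state, model)
  cv <- cov_p_theta(state, model)
  if (branch == "continue") {
    if (e_p <= .Machine$double.eps) {
      stop("continue branch has probability 0", call. = FALSE)
    }
    omega1 * cv / e_p + omega1 * first_stage_bias
  } else {
    if (1 - e_p <= .Machine$double.eps) {
      stop("stop branch has probability 0", call. = FALSE)
    }
    -cv / (1 - e_p)
  }
}

#' Full analytic bias decomposition for one decision step
#'
#' Evaluates, by quadrature, the unconditional bias, both conditional
#' biases, the continuation probability and the covariance for one
#' decision step, packaged so that the total-expectation identity
#' \eqn{E = p\,E[\cdot|Y{=}1] + (1-p)\,E[\cdot|Y{=}0]} can be checked
#' directly.
#'
#' @inheritParams unconditional_bias
#' @return An object of class `"bias_decomposition"`: a list with
#'   `unconditional`, `conditional_continue`, `conditional_stop`,
#'   `p_continue`, `cov_p_theta`.
#' @export
bias_decomposition <- function(state, model, omega1) {
  e_p <- expected_p(state, model)
  cv <- cov_p_theta(state, model)
  structure(
    list(
      unconditional = (omega1 - 1) * cv,
      conditional_continue = if (e_p > .Machine$double.eps) {
        omega1 * cv / e_p
      } else NA_real_,
      conditional_stop = if (1 - e_p > .Machine$double.eps) {
        -cv / (1 - e_p)
      } else NA_real_,
      p_continue = e_p,
      cov_p_theta = cv,
      omega1 = omega1),
    class = "bias_decomposition"
  )
}

#' @export
print.bias_decomposition <- function(x, ...) {
  cat(sprintf(
    paste0("bias decomposition (omega1 = %g):\n",
           "  unconditional        %+ .6f\n",
           "  conditional continue %+ .6f\n",
           "  conditional stop     %+ .6f\n",
           "  P(continue)           % .4f   Cov(p, est) %+ .6f\n"),
    x$omega1, x$unconditional, x$conditional_continue, x$conditional_stop,
    x$p_continue, x$cov_p_theta))
  invisible(x)
}

#' Sequential decision bias after K trials by recurrence
#'
#' When trials are added one at a time and the decision to run trial
#' \eqn{i+1} depends on the cumulative estimate \eqn{\hat\theta_{(i)}},
#' the conditional bias accumulates as
#' \deqn{E_K[\hat\theta_{(K)}] - \theta = \bar\omega_{K-1}
#'   \big(E_{K-1}[\hat\theta_{(K-1)}] - \theta\big) +
#'   \bar\omega_{K-1}\, Cov\{p_{K-1}, \hat\theta_{(K-1)}\} / E[p_{K-1}],}
#' where \eqn{\bar\omega_i = \sum_1^i w_j / \sum_1^{i+1} w_j} is the
#' normalised weight of the first \eqn{i} trials within the first
#' \eqn{i+1}. The base case \eqn{K = 2} is the continue-branch bias of
#' [conditional_bias()].
#'
#' @param cov_p Vector (length `K - 1`) of per-step covariances
#'   \eqn{Cov\{p_i, \hat\theta_{(i)}\}}.
#' @param e_p Vector (length `K - 1`) of per-step expected continuation
#'   probabilities \eqn{E[p_i]}, each in (0, 1].
#' @param omega_bar Vector (length `K - 1`) of step weights
#'   \eqn{\bar\omega_i}.
#' @param initial_bias Bias of the first-stage estimate (default 0).
#' @return The bias of the cumulative estimate after `K` trials,
#'   conditional on all decisions having been to continue.
#' @export
recurrent_bias <- function(cov_p, e_p, omega_bar, initial_bias = 0) {
  k1 <- length(cov_p)
  if (length(e_p) != k1 || length(omega_bar) != k1 || k1 < 1) {
    stop("cov_p, e_p, omega_bar must have equal length >= 1", call. = FALSE)
  }
  if (any(e_p <= 0)) stop("e_p must be positive", call. = FALSE)
  bias <- initial_bias
  for (i in seq_len(k1)) {
    bias <- omega_bar[i] * (bias + cov_p[i] / e_p[i])
  }
  bias
}
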