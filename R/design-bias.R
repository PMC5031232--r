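#' Specify a sequential design-bias scenario
#'
#' Collects the generating parameters for the setting where the second
#' trial's size is computed from the first trial's estimate: the true
#' state of the first trial, the second trial's population variance
#' \eqn{\sigma_2^2}, the variance guess \eqn{\sigma_g^2} used in the
#' sizing formula (either a fixed value, through the ratio
#' \eqn{d = \sigma_g/\sigma_2}, or the first trial's sample variance when
#' `use_s1_sq`), the offset \eqn{\delta}, and the test operating
#' characteristics.
#'
#' @param state A [true_state()] for the first trial.
#' @param sigma2_second Population variance \eqn{\sigma_2^2} of the second
#'   trial (> 0).
#' @param sigma2_guess Fixed variance guess \eqn{\sigma_g^2}; mutually
#'   exclusive with `d_ratio` and `use_s1_sq`.
#' @param d_ratio Ratio \eqn{d = \sigma_g/\sigma_2} (>= 0).
#' @param use_s1_sq If `TRUE`, the guess is the first trial's sample
#'   variance \eqn{s_1^2}, drawn as \eqn{\sigma_1^2 \chi^2_{d_1}/d_1}.
#' @param delta Offset \eqn{\delta} added to the estimate in the sizing
#'   formula.
#' @param alpha,beta Test size and type-II error.
#' @param reps Monte-Carlo replications (default 10000).
#' @param seed Integer seed.
#' @return An object of class `"design_scenario"`.
#' @export
design_scenario <- function(state, sigma2_second, sigma2_guess = NULL,
                            d_ratio = NULL, use_s1_sq = FALSE, delta = 0,
                            alpha = 0.05, beta = 0.2,
                            reps = 10000L, seed = 1L) {
  stopifnot(inherits(state, "true_state"))
  if (sigma2_second <= 0) stop("sigma2_second must be > 0", call. = FALSE)
  if (!use_s1_sq) {
    if (!is.null(sigma2_guess) && !is.null(d_ratio)) {
      if (abs(d_ratio - sqrt(sigma2_guess / sigma2_second)) > 1e-8) {
        stop("d_ratio inconsistent with sigma2_guess", call. = FALSE)
      }
    } else if (!is.null(sigma2_guess)) {
      d_ratio <- sqrt(sigma2_guess / sigma2_second)
    } else if (!is.null(d_ratio)) {
      if (d_ratio < 0) stop("d_ratio must be >= 0", call. = FALSE)
      sigma2_guess <- d_ratio^2 * sigma2_second
    } else {
      stop("supply sigma2_guess, d_ratio, or use_s1_sq", call. = FALSE)
    }
  }
  structure(
    list(state = state, sigma2_second = sigma2_second,
         sigma2_guess = sigma2_guess, d_ratio = d_ratio,
         use_s1_sq = isTRUE(use_s1_sq), delta = delta,
         alpha = alpha, beta = beta,
         reps = as.integer(reps), seed = as.integer(seed)),
    class = "design_scenario"
  )
}

#' Pooled estimate when the second trial is sized from the first
#'
#' With \eqn{w_2 = (c^2/(\hat\theta_1+\delta)^2 - w_1) d^2} (clamped at 0),
#' the inverse-variance pooled estimate can be written
#' \deqn{\hat\theta_{(2)} = \hat\theta_2 + \frac{w_1 (\hat\theta_1 -
#'   \hat\theta_2)(\hat\theta_1+\delta)^2}{w_1 (\hat\theta_1+\delta)^2
#'   (1-d^2) + d^2 c^2}.}
#' When \eqn{w_2 = 0} (no second trial: large estimate or \eqn{d = 0}) the
#' estimate is just \eqn{\hat\theta_1}.
#'
#' @param theta1,theta2 First- and second-trial effect estimates
#'   (vectorised).
#' @param w1 First-trial unnormalised weight \eqn{n_1/\sigma_1^2} (> 0).
#' @param d_ratio Variance-guess ratio \eqn{d \ge 0}.
#' @param delta Offset \eqn{\delta}.
#' @param c A [power_constant()] or bare numeric `c`.
#' @return The pooled estimate(s).
#' @export
combined_estimator_design <- function(theta1, theta2, w1, d_ratio, delta, c) {
  if (w1 <= 0) stop("w1 must be > 0", call. = FALSE)
  if (d_ratio < 0) stop("d_ratio must be >= 0", call. = FALSE)
  cc <- .c_value(c)
  tgt2 <- (theta1 + delta)^2
  w2 <- pmax((cc^2 / tgt2 - w1) * d_ratio^2, 0)
  denom <- w1 * tgt2 * (1 - d_ratio^2) + d_ratio^2 * cc^2
  if (any(w2 > 0 & denom <= 0)) {
    stop("degenerate pooled weight: non-positive denominator", call. = FALSE)
  }
  ifelse(w2 <= 0, theta1, theta2 + w1 * (theta1 - theta2) * tgt2 / denom)
}

#' Expected first-trial estimate given the sequence stopped
#'
#' If the sizing rule \eqn{n_2 = c^2 \sigma_g^2/(\hat\theta_1+\delta)^2 -
#' w_1 \sigma_g^2} returns a non-positive value, no further trial is run:
#' the observed result already has the desired power for the observed
#' effect. Stopping therefore selects \eqn{|\hat\theta_1 + \delta| \ge
#' c/\sqrt{w_1}}, and the retained estimate is highly biased upwards for
#' positive effects. This function evaluates
#' \eqn{E[\hat\theta_1 \mid n_2 \le 0]} in closed form from two-sided
#' truncated-normal moments, with
#' \eqn{\hat\theta_1 \sim N(\theta, \sigma_1^2/n_1)}.
#'
#' @param state A [true_state()] (uses `theta`, `sigma2`, `n1`).
#' @param delta Offset \eqn{\delta}.
#' @param c A [power_constant()] or bare numeric `c`.
#' @return The conditional expectation (effect units).
#' @export
stopped_expectation <- function(state, delta, c) {
  stopifnot(inherits(state, "true_state"))
  cc <- .c_value(c)
  sdx <- sqrt(.marginal_var(state))
  w1 <- state$n1 / state$sigma2
  cut <- cc / sqrt(w1)
  upper <- cut - delta   # stop when theta_hat1 >= upper ...
  lower <- -cut - delta  # ... or theta_hat1 <= lower
  zu <- (upper - state$theta) / sdx
  zl <- (lower - state$theta) / sdx
  p_stop <- stats::pnorm(zu, lower.tail = FALSE) + stats::pnorm(zl)
  if (p_stop <= .Machine$double.eps) {
    stop("stopping probability is zero", call. = FALSE)
  }
  mass <- state$theta * stats::pnorm(zu, lower.tail = FALSE) +
    sdx * stats::dnorm(zu) +
    state$theta * stats::pnorm(zl) - sdx * stats::dnorm(zl)
  mass / p_stop
}

#' Analytic upper bound on the design bias at d = 1
#'
#' When the second-trial variance is guessed exactly
#' (\eqn{d = \sigma_g/\sigma_2 = 1}), the unconditional bias of the pooled
#' estimate is bounded above by
#' \deqn{\phi(h)\,\sigma_1/\sqrt{n_1} + 2(\theta+\delta)/c^2, \qquad
#'   h = \frac{c/\sqrt{w_1} - \delta - \theta}{\sigma_1/\sqrt{n_1}},}
#' with \eqn{\phi} the standard normal density. The bound is validated
#' through dominance over the simulated bias rather than as a point value.
#'
#' @inheritParams stopped_expectation
#' @return The upper bound on \eqn{E[\hat\theta_{(2)}] - \theta}.
#' @export
design_bias_upper_bound <- function(state, delta, c) {
  stopifnot(inherits(state, "true_state"))
  cc <- .c_value(c)
  sdx <- sqrt(.marginal_var(state))
  w1 <- state$n1 / state$sigma2
  h <- (cc / sqrt(w1) - delta - state$theta) / sdx
  stats::dnorm(h) * sdx + 2 * (state$theta + delta) / cc^2
}

#' Unconditional expectation of the design-sized pooled estimate
#'
#' \eqn{E[\hat\theta_{(2)}]} under the estimate-based sizing rule. With a
#' fixed variance guess the second-trial estimate contributes no bias and
#' the expectation reduces to a one-dimensional integral over
#' \eqn{\hat\theta_1}, evaluated by adaptive quadrature split at the
#' stop/continue boundary \eqn{|\hat\theta_1+\delta| = c/\sqrt{w_1}}. With
#' `use_s1_sq` the variance guess is random and the expectation is
#' estimated by seeded Monte Carlo ([simulate_design()]).
#'
#' @param scenario A [design_scenario()].
#' @return The expectation \eqn{E[\hat\theta_{(2)}]} (effect units).
#' @export
unconditional_design_expectation <- function(scenario) {
  stopifnot(inherits(scenario, "design_scenario"))
  st <- scenario$state
  cc <- power_constant(scenario$alpha, scenario$beta)$c
  if (scenario$use_s1_sq) {
    res <- simulate_design(scenario)
    return(st$theta * (1 + res$percent_bias[1] / 100))
  }
  w1 <- st$n1 / st$sigma2
  sdx <- sqrt(.marginal_var(st))
  d <- scenario$d_ratio
  cut <- cc / sqrt(w1)
  # E[theta_hat_(2)] = theta + E[(X - theta) g(X)], g = shrink factor on the
  # continue region, 1 on the stop region (estimate kept as theta_hat1).
  g <- function(x) {
    tgt2 <- (x + scenario$delta)^2
    cont <- tgt2 < cut^2 & d > 0
    denom <- w1 * tgt2 * (1 - d^2) + d^2 * cc^2
    ifelse(cont, w1 * tgt2 / denom, 1)
  }
  knots <- c(-cut - scenario$delta, cut - scenario$delta)
  st$theta + .gauss_expect(function(x) (x - st$theta) * g(x),
                           st$theta, sdx, knots)
}
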