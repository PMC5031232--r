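#' Power constant for a two-sided test with given size and power
#'
#' The constant \eqn{c = z_{1-\alpha/2} + z_{1-\beta}} entering the classical
#' normal-theory sample-size formula: a trial powered at \eqn{1-\beta} to
#' detect \eqn{\theta_0} with a two-sided level-\eqn{\alpha} Wald test needs
#' total weight \eqn{c^2/\theta_0^2}.
#'
#' @param alpha Two-sided test size, in (0, 1).
#' @param beta Type-II error rate, in (0, 1).
#' @return An object of class `"power_constant"` with fields `c`, `alpha`,
#'   `beta`.
#' @examples
#' power_constant(0.05, 0.2) # c ~ 2.802, c^2 ~ 7.85
#' @export
power_constant <- function(alpha = 0.05, beta = 0.2) {
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("alpha and beta must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(c = stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta),
         alpha = alpha, beta = beta),
    class = "power_constant"
  )
}

#' @export
print.power_constant <- function(x, ...) {
  cat(sprintf("power constant c = %.4f (c^2 = %.4f) for alpha = %g, beta = %g\n",
              x$c, x$c^2, x$alpha, x$beta))
  invisible(x)
}

# Accept either a power_constant object or a bare numeric c.
.c_value <- function(c) {
  if (inherits(c, "power_constant")) c$c else as.numeric(c)
}

#' Specify a probability-of-next-trial model
#'
#' A decision model gives, as a function of the current (cumulative) effect
#' estimate, the probability that the next trial is conducted. Four variants
#' are supported; only the fields relevant to a variant are consulted.
#'
#' * `power_law`: \eqn{p(\hat\theta) = (\hat\theta/\theta_0)^t} on
#'   \eqn{(0, \theta_0)}, 0 elsewhere. A further trial is never run once the
#'   clinically relevant effect \eqn{\theta_0} has been reached.
#' * `extreme_value`, `probit`: selection-style models
#'   \eqn{p = [1 - G(\hat\theta)]/[1 - G(r\theta_0)]} for
#'   \eqn{\hat\theta \ge r\theta_0} and 0 below, with
#'   \eqn{G = \exp(-\exp((\theta_0-\theta)/\sigma))} (extreme value) or
#'   \eqn{G = \Phi(\alpha_{sel} + \beta_{sel}(\theta-\theta_0)/\sigma)}
#'   (probit).
#' * `power_calc_window`: the next trial is run iff its required size
#'   \eqn{n_2 = c^2 s_1^2/\hat\theta_1^2 - n_1} falls in the window
#'   \eqn{(a, b]}; `a = -Inf` removes the lower restriction (continue
#'   whenever \eqn{n_2 \le b}).
#'
#' @param variant One of `"power_law"`, `"extreme_value"`, `"probit"`,
#'   `"power_calc_window"`.
#' @param theta0 Clinically relevant effect (> 0 for the selection models).
#' @param t Power-law exponent (> 0).
#' @param r Truncation fraction in (0, 1): the next trial is possible only
#'   when the estimate exceeds \eqn{r \theta_0}.
#' @param sigma Scale used inside `G` (> 0), typically the standard
#'   deviation of the effect estimate.
#' @param alpha_sel,beta_sel Probit location and slope.
#' @param a,b Window bounds on the required size, `a < b`; `a = -Inf` for
#'   no lower restriction.
#' @param alpha,beta Test size and type-II error defining the power
#'   constant `c` of the window rule.
#' @param delta Offset added to the estimate in the sizing formula.
#' @param next_trial_size_policy `"fixed_b"` (run the next study with size
#'   `b`, the default) or `"computed_n2"` (run it with the computed size).
#' @return An object of class `"decision_model"`.
#' @export
decision_model <- function(variant = c("power_law", "extreme_value", "probit",
                                       "power_calc_window"),
                           theta0 = NULL, t = 3, r = 0.8, sigma = NULL,
                           alpha_sel = 0, beta_sel = 1,
                           a = NULL, b = NULL, alpha = 0.05, beta = 0.2,
                           delta = 0,
                           next_trial_size_policy = c("fixed_b", "computed_n2")) {
  variant <- match.arg(variant)
  next_trial_size_policy <- match.arg(next_trial_size_policy)
  if (variant %in% c("power_law", "extreme_value", "probit")) {
    if (is.null(theta0) || theta0 <= 0) {
      stop("theta0 > 0 required for the selection models", call. = FALSE)
    }
  }
  if (variant == "power_law" && t <= 0) stop("t must be > 0", call. = FALSE)
  if (variant %in% c("extreme_value", "probit")) {
    if (r <= 0 || r >= 1) stop("r must lie in (0, 1)", call. = FALSE)
    if (is.null(sigma) || sigma <= 0) stop("sigma > 0 required", call. = FALSE)
  }
  if (variant == "power_calc_window") {
    if (is.null(a) || is.null(b) || !(a <= b)) {
      stop("window bounds a <= b required", call. = FALSE)
    }
  }
  structure(
    list(variant = variant, theta0 = theta0, t = t, r = r, sigma = sigma,
         alpha_sel = alpha_sel, beta_sel = beta_sel,
         a = a, b = b, alpha = alpha, beta = beta, delta = delta,
         next_trial_size_policy = next_trial_size_policy),
    class = "decision_model"
  )
}

#' @export
print.decision_model <- function(x, ...) {
  cat("decision model:", x$variant, "\n")
  flds <- switch(x$variant,
    power_law = sprintf("theta0 = %g, t = %g", x$theta0, x$t),
    extreme_value = sprintf("theta0 = %g, r = %g, sigma = %g",
                            x$theta0, x$r, x$sigma),
    probit = sprintf("theta0 = %g, r = %g, sigma = %g, alpha = %g, beta = %g",
                     x$theta0, x$r, x$sigma, x$alpha_sel, x$beta_sel),
    power_calc_window = sprintf(
      "window (%g, %g], alpha = %g, beta = %g, policy = %s",
      x$a, x$b, x$alpha, x$beta, x$next_trial_size_policy))
  cat(" ", flds, "\n")
  invisible(x)
}

#' Power-law probability of conducting the next trial
#'
#' \eqn{p(\hat\theta) = (\hat\theta/\theta_0)^t} for
#' \eqn{0 < \hat\theta < \theta_0} and 0 otherwise: promising results raise
#' the probability of a further trial, and no further trial is needed once
#' the effect reaches \eqn{\theta_0}. `t = 1` is the uniform distribution
#' function on \eqn{[0, \theta_0)}.
#'
#' @param theta_hat Current effect estimate (vectorised).
#' @param theta0 Clinically relevant effect (> 0).
#' @param t Exponent (> 0).
#' @return Probabilities in `[0, 1]`.
#' @export
prob_power_law <- function(theta_hat, theta0, t) {
  if (theta0 <= 0 || t <= 0) stop("theta0 and t must be > 0", call. = FALSE)
  ifelse(theta_hat > 0 & theta_hat < theta0, (theta_hat / theta0)^t, 0)
}

#' Truncated selection-model probability of the next trial
#'
#' \eqn{p = [1 - G(\hat\theta)]/[1 - G(r\theta_0)]} for
#' \eqn{\hat\theta \ge r\theta_0}, 0 below the truncation point, with `G`
#' the extreme-value or probit distribution function of the model. The
#' probability is 1 at the truncation point and non-increasing above it.
#'
#' @param theta_hat Current effect estimate (vectorised).
#' @param model A `"decision_model"` of variant `"extreme_value"` or
#'   `"probit"`.
#' @return Probabilities in `[0, 1]`.
#' @export
prob_truncated_selection <- function(theta_hat, model) {
  stopifnot(inherits(model, "decision_model"))
  if (!model$variant %in% c("extreme_value", "probit")) {
    stop("model must be extreme_value or probit", call. = FALSE)
  }
  G <- switch(model$variant,
    extreme_value = function(x) exp(-exp((model$theta0 - x) / model$sigma)),
    probit = function(x) {
      stats::pnorm(model$alpha_sel +
                     model$beta_sel * (x - model$theta0) / model$sigma)
    })
  cut <- model$r * model$theta0
  denom <- 1 - G(cut)
  p <- ifelse(theta_hat >= cut, (1 - G(theta_hat)) / denom, 0)
  pmin(pmax(p, 0), 1)
}

#' Required size of the next trial for a fixed clinical target
#'
#' The next trial's effective size so that the pooled estimate is powered
#' at \eqn{1-\beta} to detect \eqn{\theta_0} at two-sided level
#' \eqn{\alpha}: \eqn{n_{next} = (c^2/\theta_0^2 - W) \sigma^2_{next}},
#' where \eqn{W} is the accumulated weight of the prior studies. A
#' non-positive value means the accumulated evidence already achieves the
#' desired power; callers clamp at zero.
#'
#' @param theta0 Target effect (non-zero).
#' @param prior_weight Accumulated unnormalised weight \eqn{W \ge 0}.
#' @param sigma_next2 Population variance of the next trial (> 0).
#' @param c A [power_constant()] or bare numeric `c`.
#' @return The (possibly non-positive) required effective size.
#' @export
sample_size_fixed_target <- function(theta0, prior_weight, sigma_next2, c) {
  if (theta0 == 0) stop("theta0 must be non-zero", call. = FALSE)
  if (sigma_next2 <= 0) stop("sigma_next2 must be > 0", call. = FALSE)
  if (prior_weight < 0) stop("prior_weight must be >= 0", call. = FALSE)
  cc <- .c_value(c)
  (cc^2 / theta0^2 - prior_weight) * sigma_next2
}

#' Required size of the next trial when the target is the estimate
#'
#' The sizing rule actually used when, lacking clinical knowledge, the
#' estimated effect (possibly offset by `delta`) from the first trial is
#' plugged in as the target:
#' \eqn{n_2 = c^2 s_1^2/(\hat\theta_1+\delta)^2 - n_1}. A negative value
#' means a further trial is not conducted; a zero denominator is returned
#' as `Inf` (exceeds any finite upper window bound).
#'
#' @param theta_hat1 First-trial effect estimate (vectorised).
#' @param s1_sq First-trial variance estimate (> 0, vectorised).
#' @param n1 First-trial effective size (> 0).
#' @param delta Offset added to the estimate (default 0).
#' @param c A [power_constant()] or bare numeric `c`.
#' @return Required effective size (may be negative or infinite).
#' @export
sample_size_estimated_target <- function(theta_hat1, s1_sq, n1, delta = 0, c) {
  if (any(s1_sq <= 0)) stop("s1_sq must be > 0", call. = FALSE)
  if (n1 <= 0) stop("n1 must be > 0", call. = FALSE)
  cc <- .c_value(c)
  target <- theta_hat1 + delta
  ifelse(target == 0, Inf, cc^2 * s1_sq / target^2 - n1)
}

#' Evaluate a decision model's probability of the next trial
#'
#' Vectorised dispatcher over the model variants. For the
#' `power_calc_window` variant the returned value is the conditional
#' continuation probability given the estimate, which requires the
#' generating state (the sample variance is integrated out against its
#' scaled chi-square law); see [continuation_prob_conditional()].
#'
#' @param model A `"decision_model"`.
#' @param theta_hat Effect estimate(s) at which to evaluate.
#' @param state A [true_state()], required for `power_calc_window`.
#' @return Probabilities in `[0, 1]`.
#' @export
decision_prob <- function(model, theta_hat, state = NULL) {
  stopifnot(inherits(model, "decision_model"))
  switch(model$variant,
    power_law = prob_power_law(theta_hat, model$theta0, model$t),
    extreme_value = ,
    probit = prob_truncated_selection(theta_hat, model),
    power_calc_window = {
      if (is.null(state)) {
        stop("power_calc_window needs the generating state", call. = FALSE)
      }
      continuation_prob_conditional(theta_hat, state, model)
    })
}
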