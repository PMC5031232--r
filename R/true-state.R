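#' Generating parameters for simulation and quadrature
#'
#' The "true state" bundles the parameters of the data-generating model:
#' the true effect \eqn{\theta}, the within-study population variance
#' \eqn{\sigma^2}, the between-study (heterogeneity) variance \eqn{\tau^2},
#' the first-trial effective size \eqn{n_1}, and the degrees of freedom of
#' the variance estimate. The effect estimate is
#' \eqn{\hat\theta_1 \sim N(\theta, \sigma^2/n_1 + \tau^2)} and the sample
#' variance \eqn{s_1^2 \sim \sigma^2 \chi^2_{d}/d}, independent of
#' \eqn{\hat\theta_1}.
#'
#' Some scenarios state the variance of the estimate directly rather than
#' per observation (e.g. a total variance of 1/3); set
#' `sigma2_is_total = TRUE` to interpret `sigma2` as the per-estimate
#' variance, in which case the marginal variance is
#' \eqn{\sigma^2 + \tau^2}.
#'
#' @param theta True effect.
#' @param sigma2 Within-study population variance (> 0).
#' @param n1 First-trial effective sample size (> 0).
#' @param tau2 Between-study variance (>= 0, default 0).
#' @param df Degrees of freedom of the variance estimate (default
#'   `round(n1) - 1`).
#' @param sigma2_is_total If `TRUE`, `sigma2` is already the variance of
#'   the effect estimate.
#' @return An object of class `"true_state"`.
#' @export
true_state <- function(theta, sigma2, n1 = 1, tau2 = 0,
                       df = max(1L, round(n1) - 1L),
                       sigma2_is_total = FALSE) {
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  if (n1 <= 0) stop("n1 must be > 0", call. = FALSE)
  df <- as.integer(round(df))
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  structure(
    list(theta = theta, sigma2 = sigma2, tau2 = tau2, n1 = n1, df = df,
         sigma2_is_total = isTRUE(sigma2_is_total)),
    class = "true_state"
  )
}

# Marginal variance of the first-stage effect estimate.
.marginal_var <- function(state) {
  base <- if (state$sigma2_is_total) state$sigma2 else state$sigma2 / state$n1
  base + state$tau2
}

#' @export
print.true_state <- function(x, ...) {
  cat(sprintf(
    "true state: theta = %g, sigma2 = %g%s, tau2 = %g, n1 = %g, df = %d\n",
    x$theta, x$sigma2, if (x$sigma2_is_total) " (per estimate)" else "",
    x$tau2, x$n1, x$df))
  invisible(x)
}
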