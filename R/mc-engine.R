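#' Simulation configuration for decision-bias studies
#'
#' @param state A [true_state()] generating the trials.
#' @param model A `"decision_model"` deciding on each further trial.
#' @param weights_policy `"equal"` (cumulative mean, as in the heatmap and
#'   heterogeneity studies) or `"inverse_variance"`
#'   (\eqn{w_i = n_i/s_i^2} with estimated variances).
#' @param steps Number of trials when every decision is to continue
#'   (2 or 3).
#' @param reps Monte-Carlo replications (default 10000, giving roughly
#'   two-decimal precision for the estimated biases).
#' @param seed Integer seed.
#' @param grid Optional named list of `theta`, `theta0` (and `tau2`)
#'   values for [grid_sweep()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(state, model,
                       weights_policy = c("equal", "inverse_variance"),
                       steps = 2L, reps = 10000L, seed = 1L, grid = NULL) {
  stopifnot(inherits(state, "true_state"), inherits(model, "decision_model"))
  weights_policy <- match.arg(weights_policy)
  steps <- as.integer(steps)
  if (steps < 2L) stop("steps must be >= 2", call. = FALSE)
  if (model$variant == "power_calc_window" && steps != 2L) {
    stop("the window rule simulator supports steps = 2", call. = FALSE)
  }
  structure(
    list(state = state, model = model, weights_policy = weights_policy,
         steps = steps, reps = as.integer(reps), seed = as.integer(seed),
         grid = grid),
    class = "sim_config"
  )
}

#' Draw simulated trial summaries
#'
#' Draws `n` independent pairs \eqn{(\hat\theta, s^2)} from the generating
#' model: \eqn{\hat\theta \sim N(\theta, \sigma^2/n_1 + \tau^2)} (or
#' \eqn{\sigma^2 + \tau^2} for a per-estimate variance state) and
#' \eqn{s^2 \sim \sigma^2 \chi^2_{d}/d}, independent of the estimate. Uses
#' the current RNG state; seed with [set.seed()].
#'
#' @param state A [true_state()].
#' @param n Number of draws.
#' @return A list with numeric vectors `theta_hat` and `s2`.
#' @export
draw_study <- function(state, n = 1L) {
  stopifnot(inherits(state, "true_state"))
  list(
    theta_hat = stats::rnorm(n, state$theta, sqrt(.marginal_var(state))),
    s2 = state$sigma2 * stats::rchisq(n, state$df) / state$df
  )
}

# Assemble a bias_result from final estimates and the continue indicator.
.bias_result <- function(final, cont, theta, reps, seed) {
  n_cont <- sum(cont)
  n_stop <- reps - n_cont
  branch_stats <- function(x) {
    if (!length(x)) return(c(NA_real_, NA_real_))
    c(mean(x) - theta, stats::sd(x) / sqrt(length(x)))
  }
  cs <- branch_stats(final[cont])
  ss <- branch_stats(final[!cont])
  pct <- function(b) if (theta != 0) 100 * b / theta else NA_real_
  structure(
    list(
      p_continue = n_cont / reps,
      unconditional_bias = mean(final) - theta,
      conditional_bias_continue = cs[1],
      conditional_bias_stop = ss[1],
      percent_unconditional = pct(mean(final) - theta),
      percent_continue = pct(cs[1]),
      percent_stop = pct(ss[1]),
      mc_se = list(
        p_continue = sqrt(n_cont / reps * (1 - n_cont / reps) / reps),
        unconditional = stats::sd(final) / sqrt(reps),
        continue = cs[2], stop = ss[2]),
      n_continue = n_cont, n_stop = n_stop,
      reps_used = reps, seed = seed, theta = theta),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  fmt <- function(b, p) {
    if (is.na(b)) "undefined (empty branch)"
    else if (is.na(p)) sprintf("%+.5f", b)
    else sprintf("%+.5f (%+.2f%%)", b, p)
  }
  cat(sprintf("Monte-Carlo bias estimates (%d reps, seed %d):\n",
              x$reps_used, x$seed))
  cat("  P(continue)         ", sprintf("%.4f", x$p_continue), "\n")
  cat("  unconditional bias  ",
      fmt(x$unconditional_bias, x$percent_unconditional), "\n")
  cat("  bias | continue     ",
      fmt(x$conditional_bias_continue, x$percent_continue), "\n")
  cat("  bias | stop         ",
      fmt(x$conditional_bias_stop, x$percent_stop), "\n")
  invisible(x)
}

#' Simulate one decision-bias scenario
#'
#' Per replication: draw the first trial; decide on each further trial
#' (a Bernoulli draw with probability \eqn{p(\hat\theta_{(i)})} for the
#' power-law/extreme-value/probit models, the deterministic window check
#' on the required size for the power-calculation rule); draw and pool any
#' further trials under the configured weights policy. Reports the
#' continuation probability and the unconditional and branch-conditional
#' biases with their Monte-Carlo standard errors. The stop branch collects
#' every replication in which some decision was to stop, with the
#' cumulative estimate frozen at that point; the continue branch requires
#' every decision to continue.
#'
#' For the window rule the second trial runs with size `b`
#' (`next_trial_size_policy = "fixed_b"`) or the computed size, its sample
#' variance is drawn with the balanced-trial degrees of freedom
#' `round(4 n) - 2`, and pooling uses the configured weights policy.
#'
#' @param config A [sim_config()].
#' @return An object of class `"bias_result"`.
#' @export
simulate_decision <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- config$state
  md <- config$model
  R <- config$reps
  if (md$variant == "power_calc_window") {
    cc <- power_constant(md$alpha, md$beta)$c
    d1 <- draw_study(st, R)
    n2 <- sample_size_estimated_target(d1$theta_hat, d1$s2, st$n1,
                                       md$delta, cc)
    cont <- (!is.finite(md$a) | n2 > md$a) & n2 <= md$b
    size2 <- if (md$next_trial_size_policy == "fixed_b") {
      rep(md$b, R)
    } else pmax(n2, 0)
    final <- d1$theta_hat
    idx <- which(cont & size2 > 0)
    if (length(idx)) {
      sz <- size2[idx]
      th2 <- stats::rnorm(length(idx), st$theta, sqrt(st$sigma2 / sz))
      # balanced-trial d.f. for the second trial's variance estimate,
      # capped so an unbounded trial size degenerates gracefully
      df2 <- pmax(1, round(4 * pmin(sz, 1e12)) - 2)
      s22 <- st$sigma2 * stats::rchisq(length(idx), df2) / df2
      if (config$weights_policy == "inverse_variance") {
        w1 <- st$n1 / d1$s2[idx]
        w2 <- sz / s22
      } else {
        w1 <- rep(1, length(idx))
        w2 <- rep(1, length(idx))
      }
      final[idx] <- (w1 * d1$theta_hat[idx] + w2 * th2) / (w1 + w2)
    }
    return(.bias_result(final, cont, st$theta, R, config$seed))
  }
  # selection models, possibly over several sequential steps
  steps <- config$steps
  est <- matrix(NA_real_, R, steps)
  s2m <- matrix(NA_real_, R, steps)
  d <- draw_study(st, R)
  est[, 1] <- d$theta_hat
  s2m[, 1] <- d$s2
  cum <- est[, 1]
  final <- cum
  alive <- rep(TRUE, R)
  for (i in 2:steps) {
    p <- decision_prob(md, cum)
    go <- alive & (stats::runif(R) < p)
    di <- draw_study(st, R)
    est[, i] <- di$theta_hat
    s2m[, i] <- di$s2
    if (config$weights_policy == "equal") {
      newcum <- rowMeans(est[, 1:i, drop = FALSE])
    } else {
      w <- st$n1 / s2m[, 1:i, drop = FALSE]
      newcum <- rowSums(w * est[, 1:i, drop = FALSE]) / rowSums(w)
    }
    cum <- ifelse(go, newcum, cum)
    final <- ifelse(go, newcum, final)
    alive <- go
  }
  .bias_result(final, alive, st$theta, R, config$seed)
}

#' Simulate a design-bias scenario over a grid of variance-guess ratios
#'
#' Per ratio `d` and replication: draw the first trial; compute the second
#' trial's size \eqn{n_2 = (c^2/(\hat\theta_1+\delta)^2 - w_1)\sigma_g^2}
#' with \eqn{\sigma_g^2 = d^2 \sigma_2^2} (or \eqn{s_1^2} when the
#' scenario sets `use_s1_sq`); if \eqn{n_2 > 0} draw the second trial with
#' variance \eqn{\sigma_2^2} and pool with inverse-variance weights,
#' otherwise keep \eqn{\hat\theta_1}. Reports the mean percent bias
#' \eqn{100 (E[\hat\theta_{(2)}] - \theta)/\theta} per `d`.
#'
#' Each grid point uses its own deterministic seed derived from the
#' scenario seed, so points are independently reproducible.
#'
#' @param scenario A [design_scenario()].
#' @param d_grid Ratios \eqn{d} to sweep (default 0.1 to 10 in steps of
#'   0.1); ignored when `use_s1_sq`, which is a single run reported with
#'   `d = NA`.
#' @return A data frame with columns `d`, `percent_bias`, `mc_se_percent`.
#' @export
simulate_design <- function(scenario, d_grid = seq(0.1, 10, by = 0.1)) {
  stopifnot(inherits(scenario, "design_scenario"))
  st <- scenario$state
  cc <- power_constant(scenario$alpha, scenario$beta)$c
  w1 <- st$n1 / st$sigma2
  one_run <- function(d, seed) {
    set.seed(seed)
    R <- scenario$reps
    th1 <- stats::rnorm(R, st$theta, sqrt(.marginal_var(st)))
    sig_g2 <- if (scenario$use_s1_sq) {
      st$sigma2 * stats::rchisq(R, st$df) / st$df
    } else rep(d^2 * scenario$sigma2_second, R)
    n2 <- pmax((cc^2 / (th1 + scenario$delta)^2 - w1) * sig_g2, 0)
    final <- th1
    idx <- which(n2 > 0)
    if (length(idx)) {
      th2 <- stats::rnorm(length(idx), st$theta,
                          sqrt(scenario$sigma2_second / n2[idx]))
      w2 <- n2[idx] / scenario$sigma2_second
      final[idx] <- (w1 * th1[idx] + w2 * th2) / (w1 + w2)
    }
    bias <- final - st$theta
    c(100 * mean(bias) / st$theta,
      100 * stats::sd(bias) / sqrt(R) / abs(st$theta))
  }
  if (scenario$use_s1_sq) {
    r <- one_run(NA_real_, scenario$seed)
    return(data.frame(d = NA_real_, percent_bias = r[1], mc_se_percent = r[2]))
  }
  out <- t(vapply(seq_along(d_grid),
                  function(i) one_run(d_grid[i], scenario$seed + i - 1L),
                  numeric(2)))
  data.frame(d = d_grid, percent_bias = out[, 1], mc_se_percent = out[, 2])
}

#' Sweep a decision-bias simulation over a parameter grid
#'
#' Runs [simulate_decision()] at every combination of the grid's `theta`,
#' `theta0` and `tau2` values (each defaulting to the configured state or
#' model value) and returns a long-format table sufficient to regenerate
#' bias surfaces and heterogeneity profiles. Each grid point gets its own
#' deterministic seed derived from the configuration seed.
#'
#' @param config A [sim_config()] whose `grid` element is a named list
#'   with any of `theta`, `theta0`, `tau2`.
#' @return A long data frame with columns `theta`, `theta0`, `tau2`,
#'   `estimand` (`p_continue`, `bias_unconditional`, `bias_continue`,
#'   `bias_stop`) and `value` (biases in effect units; empty branches are
#'   `NA`).
#' @export
grid_sweep <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  if (is.null(grid)) stop("config has no grid", call. = FALSE)
  thetas <- if (!is.null(grid$theta)) grid$theta else config$state$theta
  theta0s <- if (!is.null(grid$theta0)) grid$theta0 else config$model$theta0
  tau2s <- if (!is.null(grid$tau2)) grid$tau2 else config$state$tau2
  cells <- expand.grid(theta = thetas, theta0 = theta0s, tau2 = tau2s,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    st <- config$state
    st$theta <- cells$theta[i]
    st$tau2 <- cells$tau2[i]
    md <- config$model
    if (!is.null(md$theta0)) md$theta0 <- cells$theta0[i]
    cf <- config
    cf$state <- st
    cf$model <- md
    cf$seed <- config$seed + i - 1L
    res <- simulate_decision(cf)
    rows[[i]] <- data.frame(
      theta = cells$theta[i], theta0 = cells$theta0[i],
      tau2 = cells$tau2[i],
      estimand = c("p_continue", "bias_unconditional",
                   "bias_continue", "bias_stop"),
      value = c(res$p_continue, res$unconditional_bias,
                res$conditional_bias_continue, res$conditional_bias_stop))
  }
  do.call(rbind, rows)
}
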