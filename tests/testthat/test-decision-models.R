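test_that("power constant sums the two standard-normal quantiles", {
  pc <- power_constant(0.05, 0.2)
  expect_equal(round(pc$c^2, 2), 7.85)
  expect_equal(pc$c, 2.802, tolerance = 5e-4)
  # beta = 0.5 contributes a zero quantile
  expect_equal(power_constant(0.05, 0.5)$c, qnorm(0.975))
  expect_error(power_constant(0, 0.2), "alpha")
  expect_error(power_constant(0.05, 1), "alpha")
})

test_that("power-law probability is the (theta_hat/theta0)^t law on (0, theta0)", {
  expect_equal(prob_power_law(0.25, 0.5, 1), 0.5)
  expect_equal(prob_power_law(0.25, 0.5, 3), 0.125)
  expect_equal(prob_power_law(0.6, 0.5, 3), 0)   # effect reached: no new trial
  expect_equal(prob_power_law(-0.1, 0.5, 3), 0)
  grid <- seq(0.01, 0.49, 0.01)
  expect_false(is.unsorted(prob_power_law(grid, 0.5, 3)))
  expect_error(prob_power_law(0.2, -1, 3), "theta0")
})

test_that("truncated selection probabilities match brute-force G evaluation", {
  for (variant in c("extreme_value", "probit")) {
    md <- decision_model(variant, theta0 = 0.5, r = 0.8, sigma = 0.4)
    cut <- 0.8 * 0.5
    expect_equal(prob_truncated_selection(cut, md), 1)
    expect_equal(prob_truncated_selection(cut - 1e-9, md), 0)
    expect_equal(prob_truncated_selection(-1, md), 0)
    expect_lt(prob_truncated_selection(50, md), 1e-6)
    grid <- seq(cut, 3, length.out = 200)
    p <- prob_truncated_selection(grid, md)
    expect_false(is.unsorted(rev(p)))       # non-increasing above the cut
    expect_true(all(p >= 0 & p <= 1))
    # independent evaluation of [1 - G(x)] / [1 - G(r theta0)]
    G <- if (variant == "extreme_value") {
      function(x) exp(-exp((0.5 - x) / 0.4))
    } else {
      function(x) pnorm((x - 0.5) / 0.4)
    }
    expect_equal(p, (1 - G(grid)) / (1 - G(cut)), tolerance = 1e-12)
  }
})

test_that("fixed-target sizing satisfies boundary, linearity and the power curve", {
  cc <- power_constant(0.05, 0.2)
  th0 <- 0.5
  expect_equal(sample_size_fixed_target(th0, cc$c^2 / th0^2, 2, cc), 0)
  n_a <- sample_size_fixed_target(th0, 1.5, 2, cc)
  n_b <- sample_size_fixed_target(th0, 1.5, 4, cc)
  expect_equal(n_b, 2 * n_a)
  # brute-force power of the two-sided Wald test at the returned size
  sig2 <- 2
  n <- sample_size_fixed_target(th0, 0, sig2, cc)
  set.seed(31)
  est <- rnorm(2e5, th0, sqrt(sig2 / n))
  rejected <- abs(est) / sqrt(sig2 / n) > qnorm(0.975)
  se3 <- 3 * sqrt(0.8 * 0.2 / 2e5)
  expect_lt(abs(mean(rejected) - 0.8), se3)
  expect_error(sample_size_fixed_target(0, 1, 2, cc), "theta0")
})

test_that("estimate-based sizing reproduces the worked-example requirement", {
  cc <- power_constant(0.05, 0.2)
  n2 <- sample_size_estimated_target(0.86, 19.94, 61.30, delta = 0, c = cc)
  expect_equal(n2, 150.35, tolerance = 0.05 / 150)
  # dominance of -n1 for large estimates: no further trial
  expect_lt(sample_size_estimated_target(50, 19.94, 61.30, c = cc), 0)
  # homogeneity: scaling s2 and (theta_hat + delta)^2 together only moves -n1
  a <- sample_size_estimated_target(0.4, 10, 5, c = cc)
  b <- sample_size_estimated_target(0.8, 40, 5, c = cc)
  expect_equal(a, b)
  # zero target: unbounded size
  expect_identical(sample_size_estimated_target(0.3, 10, 5, delta = -0.3,
                                                c = cc), Inf)
})

test_that("conditional continuation probability matches a chi-square Monte Carlo", {
  st <- true_state(theta = 0, sigma2 = 20, n1 = 60, df = 59)
  md <- decision_model("power_calc_window", a = 30, b = 80)
  expect_equal(continuation_prob_conditional(0, st, md), 0)
  cc <- power_constant(0.05, 0.2)$c
  set.seed(17)
  s2 <- 20 * rchisq(1e6, 59) / 59
  for (t1 in c(1.0, 1.2, 1.5)) {
    p <- continuation_prob_conditional(t1, st, md)
    n2 <- cc^2 * s2 / t1^2 - 60
    frac <- mean(n2 > 30 & n2 <= 80)
    expect_lt(abs(p - frac),
              3 * sqrt(frac * (1 - frac) / 1e6) + 1e-12)
  }
  # degenerate large-df limit: indicator of a < c^2 sigma^2/theta1^2 - n1 <= b
  st_big <- true_state(theta = 0, sigma2 = 20, n1 = 60, df = 1e5)
  n2_det <- function(t1) cc^2 * 20 / t1^2 - 60
  for (t1 in c(0.2, 0.3, 0.5, 1.5)) {
    ind <- as.numeric(n2_det(t1) > 30 & n2_det(t1) <= 80)
    expect_equal(continuation_prob_conditional(t1, st_big, md), ind,
                 tolerance = 0.05)
  }
})

test_that("unconditional continuation probability agrees with simulation", {
  st <- johnson_state()
  md <- johnson_window()
  p <- continuation_prob_unconditional(st, md)
  set.seed(23)
  d <- draw_study(st, 1e5)
  n2 <- sample_size_estimated_target(d$theta_hat, d$s2, 61,
                                     c = power_constant(0.05, 0.2))
  frac <- mean(n2 > 50 & n2 <= 500)
  expect_lt(abs(p - frac), 3 * sqrt(frac * (1 - frac) / 1e5))
  # zero-width window carries no continuation probability
  expect_equal(continuation_prob_unconditional(st, johnson_window(a = 500)),
               0)
})

test_that("probability outputs always lie in [0, 1]", {
  st <- johnson_state()
  models <- c(selection_models(), list(window = johnson_window()))
  set.seed(5)
  x <- rnorm(500, 0.3, 1)
  for (md in models) {
    p <- decision_prob(md, x, state = st)
    expect_true(all(p >= 0 & p <= 1))
  }
})
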