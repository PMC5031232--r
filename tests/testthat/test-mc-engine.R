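test_that("draw_study reproduces the generating moments", {
  st <- true_state(0.28, 21.62, n1 = 61, tau2 = 0.05, df = 60)
  set.seed(101)
  d <- draw_study(st, 1e6)
  v <- 21.62 / 61 + 0.05
  expect_lt(abs(mean(d$theta_hat) - 0.28), 3 * sqrt(v / 1e6))
  expect_lt(abs(var(d$theta_hat) - v), 3 * sqrt(2 * v^2 / 1e6))
  s2_se <- sd(d$s2) / sqrt(1e6)
  expect_lt(abs(mean(d$s2) - 21.62), 3 * s2_se)
})

test_that("simulation results are bit-identical under the same seed", {
  cfg <- sim_config(johnson_state(), johnson_window(),
                    weights_policy = "inverse_variance",
                    reps = 2000, seed = 77)
  r1 <- simulate_decision(cfg)
  r2 <- simulate_decision(cfg)
  expect_identical(r1, r2)
  cfg$seed <- 78L
  expect_false(identical(simulate_decision(cfg)$unconditional_bias,
                         r1$unconditional_bias))
  scen <- design_scenario(sweep_design_state(), 24.96, d_ratio = 1,
                          delta = 0.2, reps = 2000, seed = 5)
  expect_identical(simulate_design(scen, d_grid = c(0.5, 1)),
                   simulate_design(scen, d_grid = c(0.5, 1)))
})

test_that("branch means decompose the unconditional mean exactly", {
  for (md in c(selection_models()["extreme_value"],
               list(window = johnson_window()))) {
    st <- if (identical(md$variant, "power_calc_window")) {
      johnson_state()
    } else fig_state(0.4)
    res <- simulate_decision(sim_config(st, md, "equal", reps = 5000,
                                        seed = 3))
    recon <- res$p_continue * res$conditional_bias_continue +
      (1 - res$p_continue) * res$conditional_bias_stop
    expect_equal(recon, res$unconditional_bias, tolerance = 1e-10)
  }
})

test_that("a constant continuation probability yields no simulated bias", {
  st <- johnson_state()
  md <- decision_model("power_calc_window", a = -Inf, b = Inf)
  res <- simulate_decision(sim_config(st, md, "equal",
                                      reps = 50000, seed = 11))
  expect_equal(res$p_continue, 1)
  expect_lt(abs(res$unconditional_bias), 3 * res$mc_se$unconditional)
})

test_that("simulated decision biases agree with the quadrature decomposition", {
  for (nm in names(selection_models())) {
    md <- selection_models()[[nm]]
    st <- fig_state(0.35)
    bd <- bias_decomposition(st, md, 0.5)
    res <- simulate_decision(sim_config(st, md, "equal", reps = 2e5,
                                        seed = 41))
    expect_lt(abs(res$unconditional_bias - bd$unconditional),
              3 * res$mc_se$unconditional)
    expect_lt(abs(res$conditional_bias_continue - bd$conditional_continue),
              3 * res$mc_se$continue)
    expect_lt(abs(res$conditional_bias_stop - bd$conditional_stop),
              3 * res$mc_se$stop)
    expect_lt(abs(res$p_continue - bd$p_continue), 3 * res$mc_se$p_continue)
  }
})

test_that("empty branches are reported as missing, not zero", {
  # a true effect far above the target: the power-law never continues
  st <- fig_state(5, sigma2 = 1e-4)
  res <- simulate_decision(sim_config(st, selection_models()$power_law,
                                      "equal", reps = 500, seed = 2))
  expect_equal(res$p_continue, 0)
  expect_true(is.na(res$conditional_bias_continue))
  expect_false(is.na(res$conditional_bias_stop))
})

test_that("design sweep reproduces the headline mean bias and its control", {
  # variance guessed by the first trial's sample variance
  scen <- design_scenario(sweep_design_state(), 24.96, use_s1_sq = TRUE,
                          delta = 0.2, reps = 10000, seed = 1)
  res <- simulate_design(scen)
  expect_equal(nrow(res), 1)
  expect_equal(res$percent_bias, 49.9, tolerance = 0.12)
  # sizing from the true effect and true variance with no offset is unbiased
  cc <- power_constant(0.05, 0.2)
  w1 <- 61 / 19.94
  n2 <- sample_size_fixed_target(0.2, w1, 24.96, cc)
  set.seed(1)
  th1 <- rnorm(10000, 0.2, sqrt(19.94 / 61))
  th2 <- rnorm(10000, 0.2, sqrt(24.96 / n2))
  w2 <- n2 / 24.96
  ctrl <- 100 * (mean((w1 * th1 + w2 * th2) / (w1 + w2)) - 0.2) / 0.2
  expect_lt(abs(ctrl), 1)
})

test_that("grid sweep emits a long table consistent with single runs", {
  cfg <- sim_config(fig_state(0.3), selection_models()$power_law, "equal",
                    reps = 4000, seed = 9,
                    grid = list(theta = c(0.1, 0.3), theta0 = c(0.5, 0.9)))
  tab <- grid_sweep(cfg)
  expect_equal(nrow(tab), 2 * 2 * 4)
  expect_setequal(unique(tab$estimand),
                  c("p_continue", "bias_unconditional", "bias_continue",
                    "bias_stop"))
  # small effect against a high target: strong positive continue-branch bias
  small <- subset(tab, theta == 0.1 & theta0 == 0.9 &
                    estimand == "bias_continue")$value
  expect_gt(small, 0.05)
  # grid cell reproduces a direct run at the derived seed
  cfg1 <- sim_config(fig_state(0.1),
                     decision_model("power_law", theta0 = 0.5, t = 3),
                     "equal", reps = 4000, seed = 9)
  direct <- simulate_decision(cfg1)
  cell <- subset(tab, theta == 0.1 & theta0 == 0.5 &
                   estimand == "bias_unconditional")$value
  expect_equal(cell, direct$unconditional_bias)
})
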