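test_that("guarding_params validates its inputs", {
  expect_s3_class(guarding_params(1, 1, 0), "guarding_params")
  expect_error(guarding_params(0, 1, 1), class = "mateguard_validation_error")
  expect_error(guarding_params(1, -1, 1), class = "mateguard_validation_error")
  expect_error(guarding_params(1, 1, -0.1), class = "mateguard_validation_error")
  expect_error(guarding_params(1, 1, Inf), class = "mateguard_validation_error")
  expect_equal(guarding_params(1, 2, 1)$t_max, 5) # default horizon 10/beta
})

test_that("benefit is zero at t = 0, concave, increasing, and smaller for larger alpha", {
  p <- guarding_params(alpha = 2, beta = 0.8, gamma = 1)
  expect_identical(benefit(0, p), 0)
  t <- seq(0, p$t_max, length.out = 200)
  b <- benefit(t, p)
  expect_true(all(diff(b) >= 0))
  expect_true(all(diff(diff(b)) <= 1e-12)) # diminishing returns
  p_hi <- guarding_params(alpha = 3, beta = 0.8, gamma = 1)
  expect_true(all(benefit(t[-1], p_hi) < benefit(t[-1], p)))
  expect_error(benefit(-1, p), class = "mateguard_domain_error")
})

test_that("benefit slope matches a central-difference oracle", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- guarding_params(runif(1, 0.2, 3), runif(1, 0.2, 3), runif(1, 0, 2))
      t <- runif(1, 0.05, p$t_max * 0.9)
      h <- 1e-6 * max(t, 1)
      fd <- (benefit(t + h, p) - benefit(t - h, p)) / (2 * h)
      analytic <- exp(1) * p$beta / p$alpha * exp(-p$beta * t)
      expect_equal(fd, analytic, tolerance = 1e-6)
    }
  })
})

test_that("cost is zero at t = 0, zero for gamma = 0, and linear in gamma", {
  p0 <- guarding_params(1, 1, 0)
  t <- seq(0, 10, length.out = 50)
  expect_true(all(guarding_cost(t, p0) == 0))
  withr::with_seed(11, {
    for (i in 1:10) {
      g <- runif(1, 0.1, 4)
      tt <- runif(1, 0, 10)
      c1 <- guarding_cost(tt, guarding_params(1, 1, g))
      c2 <- guarding_cost(tt, guarding_params(1, 1, 2 * g))
      expect_equal(c2, 2 * c1, tolerance = 1e-12)
    }
  })
  expect_identical(guarding_cost(0, guarding_params(1, 1, 3)), 0)
})

test_that("net payoff recomposes exactly as benefit minus cost", {
  withr::with_seed(3, {
    p <- guarding_params(1.3, 0.6, 0.9)
    t <- runif(100, 0, p$t_max)
    expect_equal(net_payoff(t, p), benefit(t, p) - guarding_cost(t, p),
      tolerance = 1e-12
    )
  })
  # no cost: payoff non-decreasing over the horizon
  p0 <- guarding_params(1, 1, 0)
  expect_true(all(diff(net_payoff(seq(0, p0$t_max, length.out = 100), p0)) >= 0))
  expect_identical(net_payoff(0, p0), 0)
})

test_that("payoff_curve satisfies its structural invariants", {
  pc <- payoff_curve(guarding_params(1, 1, 1.5), n = 64)
  expect_equal(nrow(pc), 64)
  expect_identical(pc$benefit_values[1], 0)
  expect_identical(pc$cost_values[1], 0)
  expect_true(all(diff(pc$benefit_values) >= 0))
  expect_true(all(diff(pc$cost_values) >= 0))
  expect_equal(pc$net_values, pc$benefit_values - pc$cost_values)
})

test_that("zero cost gives the corner at t_max; huge cost the corner at zero", {
  for (method in c("closed_form", "grid_search")) {
    fit0 <- optimal_guarding_time(guarding_params(1, 1, 0), method)
    expect_identical(fit0$solution_kind, "corner_max")
    expect_equal(fit0$t_star, 10)
    fit_hi <- optimal_guarding_time(guarding_params(1, 1, 50), method)
    expect_identical(fit_hi$solution_kind, "corner_zero")
    expect_equal(fit_hi$t_star, 0)
  }
})

test_that("closed form and grid search agree on random interior parameter sets", {
  withr::with_seed(42, {
    tol <- 1e-8
    for (i in 1:50) {
      alpha <- runif(1, 0.3, 3)
      beta <- runif(1, 0.3, 3)
      lo <- beta / alpha
      gamma <- runif(1, 1.05 * lo, 0.95 * exp(1) * lo) # interior regime
      p <- guarding_params(alpha, beta, gamma)
      cf <- optimal_guarding_time(p, "closed_form", tolerance = tol)
      gs <- optimal_guarding_time(p, "grid_search", tolerance = tol)
      expect_identical(cf$solution_kind, "interior")
      expect_identical(gs$solution_kind, "interior")
      expect_lt(abs(cf$t_star - gs$t_star), 10 * tol)
    }
  })
})

test_that("the optimum changes character at gamma = e*beta/alpha", {
  # with alpha = beta = 1 the interior optimum vanishes exactly at gamma = e
  below <- optimal_guarding_time(guarding_params(1, 1, exp(1) * (1 - 1e-9)))
  above <- optimal_guarding_time(guarding_params(1, 1, exp(1)))
  expect_identical(below$solution_kind, "interior")
  expect_gt(below$t_star, 0)
  expect_identical(above$solution_kind, "corner_zero")
  # the numerical route resolves the same transition at its grid resolution
  g_below <- optimal_guarding_time(guarding_params(1, 1, exp(1) - 0.05),
    "grid_search",
    grid_size = 100000L
  )
  g_above <- optimal_guarding_time(guarding_params(1, 1, exp(1) + 0.05),
    "grid_search",
    grid_size = 100000L
  )
  expect_identical(g_below$solution_kind, "interior")
  expect_identical(g_above$solution_kind, "corner_zero")
})

test_that("regime classification follows the printed windows with lower-regime ties", {
  expect_identical(classify_regime(guarding_params(1, 1, 2)), "scenario_C_window")
  expect_identical(classify_regime(guarding_params(1, 1, 3)), "scenario_D_window")
  expect_identical(classify_regime(guarding_params(1, 1, 0.5)), "below_window")
  # exact boundaries resolve downward
  expect_identical(classify_regime(guarding_params(1, 1, 1)), "below_window")
  expect_identical(classify_regime(guarding_params(1, 1, exp(1))), "scenario_C_window")
  # boundaries scale as beta/alpha
  expect_identical(classify_regime(guarding_params(2, 1, 0.6)), "scenario_C_window")
})

test_that("predict_smd labels scenarios and rejects identical parameter sets", {
  naive <- guarding_params(1, 1, 1.5)
  expect_error(predict_smd(naive, guarding_params(1, 1, 1.5)),
    class = "mateguard_validation_error"
  )
  a <- predict_smd(naive, guarding_params(1.5, 1, 1.5))
  expect_identical(a$scenario, "A_alpha_larger")
  expect_true(a$smd_predicted)
  expect_lt(a$delta_t_star, 0)
  comp <- predict_smd(naive, guarding_params(1.5, 0.7, 1.5))
  expect_identical(comp$scenario, "composite")
})

test_that("gamma increases inside the C window always shorten the optimum", {
  naive <- guarding_params(1, 1, 1.01) # lower end of the window
  gammas <- seq(1.1, exp(1) * 0.99, length.out = 20)
  for (g in gammas) {
    pred <- predict_smd(naive, guarding_params(1, 1, g), method = "grid_search")
    expect_identical(pred$scenario, "C_gamma_larger")
    expect_lt(pred$delta_t_star, 0)
  }
})

test_that("parameter_sweep matches pointwise solves and the regime classifier", {
  base <- guarding_params(1, 1, 1.5)
  one <- parameter_sweep(base, "gamma", 1.5)
  direct <- optimal_guarding_time(base)
  expect_equal(one$t_star, direct$t_star)
  expect_equal(one$payoff, direct$payoff_at_optimum)
  expect_identical(one$solution_kind, direct$solution_kind)

  grid <- seq(0.5, 3.5, length.out = 31)
  sw <- parameter_sweep(base, "gamma", grid)
  expect_equal(sw$param_value, grid)
  for (i in seq_len(nrow(sw))) {
    p <- guarding_params(1, 1, sw$param_value[i])
    expect_identical(sw$regime[i], classify_regime(p))
  }
  # within the C window t* is strictly decreasing in gamma
  cw <- sw[sw$regime == "scenario_C_window", ]
  expect_true(all(diff(cw$t_star) < 0))
  expect_error(parameter_sweep(base, "gamma", numeric(0)),
    class = "mateguard_validation_error"
  )
})

test_that("a custom model definition can be swapped in behind the solver", {
  quad <- guarding_model(
    benefit = function(t, p) (2 / p$alpha) * t - p$beta * t^2 / 2,
    cost = function(t, p) p$gamma * t
  )
  p <- guarding_params(1, 1, 1, t_max = 3)
  expect_error(optimal_guarding_time(p, "closed_form", model = quad),
    class = "mateguard_validation_error"
  )
  fit <- optimal_guarding_time(p, "grid_search", model = quad)
  expect_equal(fit$t_star, 1, tolerance = 1e-6) # argmax of 2t - t^2/2 - t
})
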