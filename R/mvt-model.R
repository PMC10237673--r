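# Marginal-value-theorem model of post-ejaculatory mate guarding.
#
# A guarding male accrues a saturating fertilization benefit and a linear
# guarding cost; the optimal guarding duration maximizes net payoff on
# [0, t_max].  The functional forms live in `guarding_model()` so that an
# alternative parameterization can be substituted without touching the solver.

#' Parameters of the mate-guarding cost-benefit model
#'
#' Bundles the three model parameters and the guarding horizon. `alpha` is an
#' inverse-capacity parameter of the fertilization benefit: the total number of
#' eggs a guarding male can ever fertilize is `e/alpha`, so a larger `alpha`
#' means fewer fertilizable eggs in total. `beta` is the benefit-accrual rate
#' (per unit time): the benefit approaches its ceiling on the timescale
#' `1/beta`. `gamma` is the cost-accrual rate (cost units per unit time), with
#' `gamma = 0` meaning cost-free guarding. The regime of the optimum is
#' governed by comparing `gamma` with `beta/alpha` and `e * beta/alpha` (see
#' [classify_regime()]).
#'
#' @param alpha Positive benefit inverse-capacity parameter.
#' @param beta Positive benefit-accrual rate (1/time).
#' @param gamma Non-negative cost-accrual rate.
#' @param t_max Positive upper bound of admissible guarding durations.
#'   Defaults to `10/beta`, several benefit time constants, which captures
#'   benefit saturation without an unbounded search interval.
#'
#' @return An object of class `"guarding_params"`: a named list with fields
#'   `alpha`, `beta`, `gamma`, `t_max`.
#' @examples
#' guarding_params(alpha = 1, beta = 1, gamma = 2)
#' @export
guarding_params <- function(alpha, beta, gamma, t_max = 10 / beta) {
  for (nm in c("alpha", "beta", "gamma", "t_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(
        sprintf("`%s` must be a single finite number.", nm),
        class = "mateguard_validation_error"
      )
    }
  }
  if (alpha <= 0 || beta <= 0 || t_max <= 0 || gamma < 0) {
    rlang::abort(
      "Require alpha > 0, beta > 0, gamma >= 0, t_max > 0.",
      class = "mateguard_validation_error"
    )
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, t_max = t_max),
    class = "guarding_params"
  )
}

#' @export
print.guarding_params <- function(x, ...) {
  cat(sprintf(
    "<guarding_params> alpha = %g, beta = %g, gamma = %g, t_max = %g\n",
    x$alpha, x$beta, x$gamma, x$t_max
  ))
  cat(sprintf(
    "  regime boundaries: beta/alpha = %g, e*beta/alpha = %g (%s)\n",
    x$beta / x$alpha, exp(1) * x$beta / x$alpha, classify_regime(x)
  ))
  invisible(x)
}

#' Model definition: benefit and cost functional forms
#'
#' The single seam housing the algebra of the guarding model. The default
#' forms are the simplest concave-benefit / linear-cost pair whose optimum
#' reproduces the published regime structure exactly:
#' \deqn{B(t) = (e/\alpha)\,(1 - e^{-\beta t}), \qquad C(t) = \gamma t,}
#' with net payoff \eqn{N(t) = B(t) - C(t)}. The interior optimum is
#' \eqn{t^* = \log(e\beta/(\alpha\gamma))/\beta}, which is positive exactly
#' when \eqn{\gamma < e\beta/\alpha} and exceeds \eqn{1/\beta} exactly when
#' \eqn{\gamma < \beta/\alpha} — the two regime boundaries of the model.
#'
#' @param benefit Function `(t, params) -> numeric`, vectorized in `t`.
#' @param cost Function `(t, params) -> numeric`, vectorized in `t`.
#' @param closed_form Either a function `(params) -> list(t_star, kind)` giving
#'   the analytic argmax of benefit minus cost on `[0, t_max]` (with `kind` one
#'   of `"interior"`, `"corner_zero"`, `"corner_max"`), or `NULL` if no closed
#'   form is available (the solver then refuses `method = "closed_form"`).
#'
#' @return An object of class `"guarding_model"`.
#' @export
guarding_model <- function(benefit = NULL, cost = NULL, closed_form = NULL) {
  if (is.null(benefit)) benefit <- .default_benefit
  if (is.null(cost)) cost <- .default_cost
  if (is.null(closed_form) && identical(benefit, .default_benefit) &&
      identical(cost, .default_cost)) {
    closed_form <- .default_closed_form
  }
  structure(
    list(benefit = benefit, cost = cost, closed_form = closed_form),
    class = "guarding_model"
  )
}

.default_benefit <- function(t, params) {
  (exp(1) / params$alpha) * (1 - exp(-params$beta * t))
}

.default_cost <- function(t, params) {
  params$gamma * t
}

# Analytic argmax of B - C on [0, t_max] for the default forms.
.default_closed_form <- function(params) {
  if (params$gamma == 0) {
    return(list(t_star = params$t_max, kind = "corner_max"))
  }
  u <- (1 + log(params$beta / (params$alpha * params$gamma))) / params$beta
  if (u <= 0) {
    list(t_star = 0, kind = "corner_zero")
  } else if (u >= params$t_max) {
    list(t_star = params$t_max, kind = "corner_max")
  } else {
    list(t_star = u, kind = "interior")
  }
}

.check_t <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    rlang::abort("`t` must be finite numeric.", class = "mateguard_validation_error")
  }
  if (any(t < 0)) {
    rlang::abort("Guarding duration `t` must be >= 0.", class = "mateguard_domain_error")
  }
  invisible(t)
}

.check_params <- function(params) {
  if (!inherits(params, "guarding_params")) {
    rlang::abort("`params` must be created by guarding_params().",
      class = "mateguard_validation_error"
    )
  }
  invisible(params)
}

#' Fertilization benefit of guarding for `t` time units
#'
#' @param t Non-negative guarding duration(s).
#' @param params A [guarding_params()] object.
#' @param model A [guarding_model()]; defaults to the built-in forms.
#' @return Benefit value(s), same length as `t`. `benefit(0, ...) = 0`; the
#'   benefit is non-decreasing and concave in `t` (diminishing returns).
#' @export
benefit <- function(t, params, model = guarding_model()) {
  .check_t(t)
  .check_params(params)
  model$benefit(t, params)
}

#' Accumulated cost of guarding for `t` time units
#'
#' @inheritParams benefit
#' @return Cost value(s); zero at `t = 0`, identically zero when `gamma = 0`,
#'   strictly increasing in `t` when `gamma > 0`, and linear in `gamma`.
#' @export
guarding_cost <- function(t, params, model = guarding_model()) {
  .check_t(t)
  .check_params(params)
  model$cost(t, params)
}

#' Net payoff of guarding: benefit minus cost
#'
#' @inheritParams benefit
#' @return `benefit(t, params) - guarding_cost(t, params)`.
#' @export
net_payoff <- function(t, params, model = guarding_model()) {
  benefit(t, params, model) - guarding_cost(t, params, model)
}

#' Evaluate the benefit, cost and net payoff on a time grid
#'
#' @inheritParams benefit
#' @param n Number of grid points on `[0, t_max]`.
#' @return A tibble of class `"payoff_curve"` with columns `times`,
#'   `benefit_values`, `cost_values`, `net_values`.
#' @export
payoff_curve <- function(params, n = 512, model = guarding_model()) {
  .check_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  times <- seq(0, params$t_max, length.out = n)
  out <- tibble::tibble(
    times = times,
    benefit_values = benefit(times, params, model),
    cost_values = guarding_cost(times, params, model),
    net_values = NA_real_
  )
  out$net_values <- out$benefit_values - out$cost_values
  class(out) <- c("payoff_curve", class(out))
  out
}

# Golden-section refinement of a bracketed maximum of f on [lo, hi].
.golden_section_max <- function(f, lo, hi, tolerance, max_iter = 500L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo
  b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  iter <- 0L
  while ((b - a) > tolerance) {
    iter <- iter + 1L
    if (iter > max_iter) {
      rlang::abort(
        sprintf(
          "Golden-section refinement failed to converge: interval [%g, %g] after %d iterations (tolerance %g).",
          a, b, max_iter, tolerance
        ),
        class = "mateguard_solver_error"
      )
    }
    if (f1 < f2) {
      a <- x1
      x1 <- x2
      f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- f(x2)
    } else {
      b <- x2
      x2 <- x1
      f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Optimal guarding duration
#'
#' Maximizes net payoff over `[0, t_max]`, either analytically
#' (`method = "closed_form"`, available for the default model forms) or by a
#' uniform grid search followed by golden-section refinement of the bracketed
#' argmax (`method = "grid_search"`, works for any model definition).
#'
#' @inheritParams benefit
#' @param method `"closed_form"` or `"grid_search"`.
#' @param grid_size Number of uniform grid points (>= 1000) for the grid search.
#' @param tolerance Absolute tolerance in `t` for the golden-section refinement.
#' @return An object of class `"optimal_guarding"`: a list with `t_star`,
#'   `payoff_at_optimum`, `solution_kind` (`"interior"`, `"corner_zero"` or
#'   `"corner_max"`) and `method`.
#' @examples
#' optimal_guarding_time(guarding_params(1, 1, 2))
#' @export
optimal_guarding_time <- function(params,
                                  method = c("closed_form", "grid_search"),
                                  grid_size = 10000L,
                                  tolerance = 1e-8,
                                  model = guarding_model()) {
  .check_params(params)
  method <- match.arg(method)
  stopifnot(tolerance > 0)
  if (method == "closed_form") {
    if (is.null(model$closed_form)) {
      rlang::abort(
        "This model definition has no closed-form solver; use method = \"grid_search\".",
        class = "mateguard_validation_error"
      )
    }
    sol <- model$closed_form(params)
    t_star <- sol$t_star
    kind <- sol$kind
  } else {
    if (grid_size < 1000L) {
      rlang::abort("`grid_size` must be >= 1000 for grid_search.",
        class = "mateguard_validation_error"
      )
    }
    grid <- seq(0, params$t_max, length.out = grid_size)
    vals <- net_payoff(grid, params, model)
    i <- which.max(vals)
    if (i == 1L) {
      t_star <- 0
      kind <- "corner_zero"
    } else if (i == grid_size) {
      t_star <- params$t_max
      kind <- "corner_max"
    } else {
      f <- function(t) net_payoff(t, params, model)
      t_star <- .golden_section_max(f, grid[i - 1L], grid[i + 1L], tolerance)
      kind <- "interior"
    }
  }
  structure(
    list(
      t_star = t_star,
      payoff_at_optimum = net_payoff(t_star, params, model),
      solution_kind = kind,
      method = method
    ),
    class = "optimal_guarding"
  )
}

#' @export
print.optimal_guarding <- function(x, ...) {
  cat(sprintf(
    "<optimal_guarding> t* = %g (%s, %s), net payoff %g\n",
    x$t_star, x$solution_kind, x$method, x$payoff_at_optimum
  ))
  invisible(x)
}

#' Classify the cost-parameter regime of the model
#'
#' The character of the optimum is governed by where `gamma` sits relative to
#' `beta/alpha` and `e * beta/alpha`:
#' * `below_window` — `gamma <= beta/alpha`: cheap guarding, long optimal
#'   durations (the unclamped optimum exceeds one benefit time constant).
#' * `scenario_C_window` — `beta/alpha < gamma <= e * beta/alpha`: interior
#'   optimum, shrinking as `gamma` grows.
#' * `scenario_D_window` — `gamma > e * beta/alpha`: guarding never pays;
#'   the optimum collapses to zero.
#'
#' Exact boundary values classify into the lower-labelled regime.
#'
#' @inheritParams benefit
#' @return One of `"below_window"`, `"scenario_C_window"`, `"scenario_D_window"`.
#' @examples
#' classify_regime(guarding_params(1, 1, 2)) # "scenario_C_window"
#' @export
classify_regime <- function(params) {
  .check_params(params)
  lower <- params$beta / params$alpha
  upper <- exp(1) * lower
  if (params$gamma <= lower) {
    "below_window"
  } else if (params$gamma <= upper) {
    "scenario_C_window"
  } else {
    "scenario_D_window"
  }
}

# Scenario label from the parameter delta between two conditions.
.scenario_label <- function(naive, experienced) {
  changed <- c("alpha", "beta", "gamma")[vapply(
    c("alpha", "beta", "gamma"),
    function(nm) !isTRUE(all.equal(naive[[nm]], experienced[[nm]])),
    logical(1)
  )]
  if (length(changed) != 1L) {
    return("composite")
  }
  if (changed == "alpha" && experienced$alpha > naive$alpha) {
    "A_alpha_larger"
  } else if (changed == "beta" && experienced$beta < naive$beta) {
    "B_beta_smaller"
  } else if (changed == "gamma" && experienced$gamma > naive$gamma) {
    "C_gamma_larger"
  } else if (changed == "gamma" && experienced$gamma < naive$gamma) {
    "D_gamma_smaller"
  } else {
    "composite"
  }
}

#' Predict whether a parameter shift produces shorter mating duration
#'
#' Computes the optimal guarding time under the naive and the experienced
#' parameter sets and reports their difference. SMD (shorter mating duration in
#' experienced males) is predicted when the experienced optimum is strictly
#' shorter.
#'
#' @param naive,experienced [guarding_params()] for the two conditions; they
#'   must differ in at least one of `alpha`, `beta`, `gamma`.
#' @inheritParams optimal_guarding_time
#' @return An object of class `"scenario_prediction"`: list with `scenario`
#'   (one of `"A_alpha_larger"`, `"B_beta_smaller"`, `"C_gamma_larger"`,
#'   `"D_gamma_smaller"`, `"composite"`), `naive_params`, `experienced_params`,
#'   the two `optimal_guarding` fits, `delta_t_star` (experienced minus naive)
#'   and `smd_predicted` (`delta_t_star < 0`).
#' @export
predict_smd <- function(naive, experienced,
                        method = c("closed_form", "grid_search"),
                        grid_size = 10000L, tolerance = 1e-8,
                        model = guarding_model()) {
  .check_params(naive)
  .check_params(experienced)
  same <- all(vapply(
    c("alpha", "beta", "gamma"),
    function(nm) isTRUE(all.equal(naive[[nm]], experienced[[nm]])),
    logical(1)
  ))
  if (same) {
    rlang::abort(
      "`naive` and `experienced` must differ in at least one of alpha, beta, gamma.",
      class = "mateguard_validation_error"
    )
  }
  method <- match.arg(method)
  fit_n <- optimal_guarding_time(naive, method, grid_size, tolerance, model)
  fit_e <- optimal_guarding_time(experienced, method, grid_size, tolerance, model)
  delta <- fit_e$t_star - fit_n$t_star
  structure(
    list(
      scenario = .scenario_label(naive, experienced),
      naive_params = naive,
      experienced_params = experienced,
      naive_fit = fit_n,
      experienced_fit = fit_e,
      delta_t_star = delta,
      smd_predicted = delta < 0
    ),
    class = "scenario_prediction"
  )
}

#' @export
print.scenario_prediction <- function(x, ...) {
  cat(sprintf(
    "<scenario_prediction> %s: t*(naive) = %g, t*(exp.) = %g, delta = %g -> SMD %spredicted\n",
    x$scenario, x$naive_fit$t_star, x$experienced_fit$t_star,
    x$delta_t_star, if (x$smd_predicted) "" else "not "
  ))
  invisible(x)
}

#' Sweep one model parameter and record the optimum along the grid
#'
#' @param base A [guarding_params()] object supplying the non-swept parameters.
#' @param which One of `"alpha"`, `"beta"`, `"gamma"`.
#' @param grid Ordered numeric vector of values for the swept parameter; every
#'   value must yield valid parameters.
#' @inheritParams optimal_guarding_time
#' @return A tibble with one row per grid value, in grid order: `param_value`,
#'   `t_star`, `payoff`, `solution_kind`, `regime`.
#' @export
parameter_sweep <- function(base, which = c("alpha", "beta", "gamma"), grid,
                            method = c("closed_form", "grid_search"),
                            grid_size = 10000L, tolerance = 1e-8,
                            model = guarding_model()) {
  .check_params(base)
  which <- match.arg(which)
  method <- match.arg(method)
  if (length(grid) < 1L) {
    rlang::abort("`grid` must be non-empty.", class = "mateguard_validation_error")
  }
  rows <- lapply(grid, function(v) {
    p <- base
    p[[which]] <- v
    # beta sweeps with a default horizon keep the horizon tied to the new beta
    p <- tryCatch(
      guarding_params(p$alpha, p$beta, p$gamma, p$t_max),
      error = function(e) {
        rlang::abort(
          sprintf("Invalid swept value %s = %g: %s", which, v, conditionMessage(e)),
          class = "mateguard_validation_error"
        )
      }
    )
    fit <- tryCatch(
      optimal_guarding_time(p, method, grid_size, tolerance, model),
      error = function(e) {
        rlang::abort(
          sprintf("Solver failed at %s = %g: %s", which, v, conditionMessage(e)),
          class = "mateguard_solver_error"
        )
      }
    )
    tibble::tibble(
      param_value = v,
      t_star = fit$t_star,
      payoff = fit$payoff_at_optimum,
      solution_kind = fit$solution_kind,
      regime = classify_regime(p)
    )
  })
  dplyr::bind_rows(rows)
}
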