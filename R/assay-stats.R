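# Two-group statistics and behavioral metrics for assay tables.

.as_numeric_group <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) == 0L || any(!is.finite(x))) {
    rlang::abort(sprintf("`%s` must be non-empty finite numeric.", what),
      class = "mateguard_validation_error"
    )
  }
  x
}

#' Keep only males that mated within the inclusion window
#'
#' Only males that succeed in mating within the window (1 h by default) are
#' included in analyses. The boundary is inclusive: a copulation latency equal
#' to the window is kept. Row order is preserved and the filter is idempotent.
#'
#' @param table Assay table containing a `copulation_latency_s` column (e.g.
#'   from [simulate_md_assay()]).
#' @param window Inclusion window in seconds (default 3600).
#' @return The included rows, with the `included` flag set to `TRUE`.
#' @export
filter_within_window <- function(table, window = 3600) {
  if (!"copulation_latency_s" %in% names(table)) {
    rlang::abort("`table` is missing required column `copulation_latency_s`.",
      class = "mateguard_schema_error"
    )
  }
  table$included <- table$copulation_latency_s <= window
  table[table$included, , drop = FALSE]
}

#' Percent reduction of a comparison group relative to a reference group
#'
#' `(mean(reference) - mean(comparison)) / mean(reference) * 100`. The naive
#' group is the reference denominator when quantifying experience-dependent
#' shortening.
#'
#' @param reference,comparison Numeric vectors of measurements.
#' @return Percent reduction (positive when the comparison mean is smaller).
#' @examples
#' percent_reduction(c(100, 100), c(87, 88.2)) # 12.4
#' @export
percent_reduction <- function(reference, comparison) {
  reference <- .as_numeric_group(reference, "reference")
  comparison <- .as_numeric_group(comparison, "comparison")
  m_ref <- mean(reference)
  if (m_ref <= 0) {
    rlang::abort("Reference mean must be > 0.", class = "mateguard_domain_error")
  }
  (m_ref - mean(comparison)) / m_ref * 100
}

#' Two-sample Student's t test (pooled variance)
#'
#' The classic unpaired pooled-variance test:
#' `t = (mean(a) - mean(b)) / sqrt(s_p^2 (1/n_a + 1/n_b))` with
#' `df = n_a + n_b - 2` and a two-sided p-value. Welch's unequal-variance
#' variant is available via `var_equal = FALSE`. Zero pooled variance with
#' equal means yields `t = 0, p = 1`; zero pooled variance with unequal means
#' is reported as `p = 0` with a degeneracy flag.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance statistic (default `TRUE`).
#' @return List with `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
students_t <- function(a, b, var_equal = TRUE) {
  a <- .as_numeric_group(a, "a")
  b <- .as_numeric_group(b, "b")
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) {
    rlang::abort("Each group needs n >= 2.", class = "mateguard_validation_error")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (d == 0) {
      return(list(t_statistic = 0, df = df, p_value = 1, degenerate = TRUE))
    }
    return(list(
      t_statistic = sign(d) * Inf, df = df, p_value = 0, degenerate = TRUE
    ))
  }
  t <- d / se
  list(
    t_statistic = t, df = df,
    p_value = 2 * stats::pt(-abs(t), df),
    degenerate = FALSE
  )
}

#' Kolmogorov-Smirnov check of normality (or lognormality)
#'
#' One-sample KS test of the data against a normal law with mean and SD
#' estimated from the sample. Because the parameters are estimated, the
#' default applies the Lilliefors correction to the p-value; the naive
#' fully-specified KS test (anticonservative here) is available as an option.
#' `mode = "lognormal"` tests the log-transformed values.
#'
#' @param values Numeric vector, n >= 5, non-constant; strictly positive when
#'   `mode = "lognormal"`.
#' @param mode `"normal"` or `"lognormal"`.
#' @param correction `"lilliefors"` (default) or `"naive"`.
#' @return List with `statistic` (the KS D), `p_value`, `mode`, `correction`.
#' @export
ks_normality <- function(values, mode = c("normal", "lognormal"),
                         correction = c("lilliefors", "naive")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  values <- .as_numeric_group(values, "values")
  if (length(values) < 5) {
    rlang::abort("Need n >= 5 for the normality check.",
      class = "mateguard_validation_error"
    )
  }
  if (mode == "lognormal") {
    if (any(values <= 0)) {
      rlang::abort("Lognormality mode requires strictly positive values.",
        class = "mateguard_domain_error"
      )
    }
    values <- log(values)
  }
  if (stats::sd(values) == 0) {
    rlang::abort("Constant sample: normality is undefined.",
      class = "mateguard_domain_error"
    )
  }
  if (correction == "lilliefors") {
    fit <- nortest::lillie.test(values)
  } else {
    fit <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
    )
  }
  list(
    statistic = unname(fit$statistic), p_value = fit$p.value,
    mode = mode, correction = correction
  )
}

#' Bootstrap estimation statistics for an unpaired mean difference
#'
#' Effect-size-centric companion to the t test: the unpaired mean difference
#' `mean(b) - mean(a)` with a bootstrap confidence interval, obtained by
#' independent with-replacement resampling within each group. The percentile
#' interval is the default; the bias-corrected and accelerated (BCa) interval
#' is available.
#'
#' @param a,b Numeric vectors (reference and comparison), each n >= 2.
#' @param n_resamples Number of bootstrap resamples (>= 100; default 5000).
#' @param ci_level Confidence level (default 0.95).
#' @param method `"percentile"` or `"bca"`.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `"estimation_result"`: list with
#'   `mean_difference`, `ci_low`, `ci_high`, `ci_level`, `n_resamples`,
#'   `method`, `seed` and the `resample_distribution`.
#' @export
bootstrap_mean_difference <- function(a, b, n_resamples = 5000L,
                                      ci_level = 0.95,
                                      method = c("percentile", "bca"),
                                      seed = 1L) {
  method <- match.arg(method)
  a <- .as_numeric_group(a, "a")
  b <- .as_numeric_group(b, "b")
  if (length(a) < 2 || length(b) < 2) {
    rlang::abort("Each group needs n >= 2.", class = "mateguard_validation_error")
  }
  if (n_resamples < 100) {
    rlang::abort("`n_resamples` must be >= 100.", class = "mateguard_validation_error")
  }
  stopifnot(ci_level > 0, ci_level < 1)
  obs <- mean(b) - mean(a)
  boots <- withr::with_seed(seed, {
    ra <- matrix(sample(a, n_resamples * length(a), replace = TRUE), nrow = n_resamples)
    rb <- matrix(sample(b, n_resamples * length(b), replace = TRUE), nrow = n_resamples)
    rowMeans(rb) - rowMeans(ra)
  })
  alpha <- (1 - ci_level) / 2
  if (stats::sd(boots) == 0) {
    ci <- c(boots[1], boots[1])
  } else if (method == "percentile") {
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  } else {
    # BCa: bias correction from the resample distribution, acceleration from
    # the jackknife over both samples.
    z0 <- stats::qnorm((sum(boots < obs) + 0.5 * sum(boots == obs)) / n_resamples)
    jack <- c(
      vapply(seq_along(a), function(i) mean(b) - mean(a[-i]), numeric(1)),
      vapply(seq_along(b), function(i) mean(b[-i]) - mean(a), numeric(1))
    )
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    acc <- if (den == 0) 0 else num / den
    zq <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    ci <- unname(stats::quantile(boots, adj))
  }
  structure(
    list(
      mean_difference = obs, ci_low = ci[1], ci_high = ci[2],
      ci_level = ci_level, n_resamples = as.integer(n_resamples),
      method = method, seed = as.integer(seed),
      resample_distribution = boots
    ),
    class = "estimation_result"
  )
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "<estimation_result> mean difference %g [%g, %g] (%g%% %s CI, %d resamples)\n",
    x$mean_difference, x$ci_low, x$ci_high, 100 * x$ci_level, x$method,
    x$n_resamples
  ))
  invisible(x)
}

#' Star annotation for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05 (all strict
#' inequalities), `"ns"` otherwise.
#'
#' @param p A p-value in `[0, 1]`.
#' @return One of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
significance_annotation <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    rlang::abort("`p` must be a single value in [0, 1].",
      class = "mateguard_domain_error"
    )
  }
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Courtship index
#'
#' Fraction of the observation window a male spends courting; when mating
#' occurs before the window ends, the window is truncated at the time of
#' mating.
#'
#' @param courtship_time_s Seconds spent in courtship-related activity.
#' @param observation_window_s Observation window in seconds (default 600).
#' @param time_to_mate_s Optional time at which mating occurred.
#' @return The courtship index on `[0, 1]`.
#' @examples
#' courtship_index(300) # 0.5
#' courtship_index(150, time_to_mate_s = 200) # 0.75
#' @export
courtship_index <- function(courtship_time_s, observation_window_s = 600,
                            time_to_mate_s = NULL) {
  window <- observation_window_s
  if (!is.null(time_to_mate_s)) window <- pmin(window, time_to_mate_s)
  if (any(window <= 0) || any(courtship_time_s < 0)) {
    rlang::abort("Times must be non-negative and the window positive.",
      class = "mateguard_domain_error"
    )
  }
  if (any(courtship_time_s > window)) {
    rlang::abort("Courtship time exceeds the effective observation window.",
      class = "mateguard_domain_error"
    )
  }
  courtship_time_s / window
}

#' Locomotion velocity
#'
#' Distance walked divided by elapsed time.
#'
#' @param distance_mm Distance walked in mm (>= 0).
#' @param time_s Elapsed time in seconds (> 0).
#' @return Velocity in mm/s.
#' @export
locomotion_velocity <- function(distance_mm, time_s) {
  if (any(time_s <= 0) || any(distance_mm < 0)) {
    rlang::abort("Require distance >= 0 and time > 0.",
      class = "mateguard_domain_error"
    )
  }
  distance_mm / time_s
}

#' Normalize reporter fluorescence to autofluorescence
#'
#' @param gfp Reporter fluorescence intensity.
#' @param autofluorescence Autofluorescence intensity (> 0).
#' @return The normalized ratio `gfp / autofluorescence`.
#' @export
normalize_fluorescence <- function(gfp, autofluorescence) {
  if (any(autofluorescence <= 0)) {
    rlang::abort("Autofluorescence must be > 0.", class = "mateguard_domain_error")
  }
  gfp / autofluorescence
}
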