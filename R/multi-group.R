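# Rank-based multi-group comparisons: Kruskal-Wallis and Dunn's post hoc.
#
# Both procedures share the joint ranking and the tie correction, so they are
# computed from one set of ranks; stats::kruskal.test provides an independent
# cross-check in the test suite.

.prep_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    rlang::abort("`groups` must be a list of >= 2 numeric vectors.",
      class = "mateguard_validation_error"
    )
  }
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) < 1L) ||
      any(!vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    rlang::abort("Every group must be non-empty finite numeric.",
      class = "mateguard_validation_error"
    )
  }
  if (sum(lengths(groups)) < 3L) {
    rlang::abort("Need total n >= 3.", class = "mateguard_validation_error")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

# Joint ranks, per-group rank means, and the tie term sum(t^3 - t).
.joint_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  tab <- table(x)
  list(
    n = lengths(groups),
    N = length(x),
    rank_means = tapply(r, factor(g, levels = names(groups)), mean),
    tie_term = sum(tab^3 - tab)
  )
}

#' Kruskal-Wallis rank test
#'
#' The rank-based H statistic with the standard tie correction and a
#' chi-square approximation on k - 1 degrees of freedom. All-identical data
#' yield `H = 0, p = 1`.
#'
#' @param groups List (optionally named) of >= 2 numeric vectors, total n >= 3.
#' @return List with `H`, `p_value`, `df`, `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  groups <- .prep_groups(groups)
  jr <- .joint_ranks(groups)
  N <- jr$N
  correction <- 1 - jr$tie_term / (N^3 - N)
  if (correction == 0) { # every value identical
    return(list(H = 0, p_value = 1, df = length(groups) - 1L, n = jr$n))
  }
  h <- (12 / (N * (N + 1))) * sum(jr$n * jr$rank_means^2) - 3 * (N + 1)
  h <- h / correction
  list(
    H = h,
    p_value = stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE),
    df = length(groups) - 1L,
    n = jr$n
  )
}

#' Dunn's multiple comparison test
#'
#' Pairwise post-hoc comparisons on the joint ranks following a Kruskal-Wallis
#' test. For groups i and j,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tied values. Two-sided p-values are
#' Bonferroni-adjusted over the comparisons performed (the classical Dunn
#' adjustment); `hash_mark` flags adjusted p < 0.05, the number-sign
#' annotation used alongside stars on multi-group panels.
#'
#' @inheritParams kruskal_wallis
#' @param control Index (or name) of the control group, compared against all
#'   others (the default, `1`), or `"all_pairs"` for every pairwise comparison.
#' @return An object of class `"multi_group_result"`: list with `kw_H`, `kw_p`
#'   and a `comparisons` tibble (`pair`, `rank_mean_diff`, `z`, `p_value`,
#'   `p_adjusted`, `hash_mark`).
#' @export
dunns_multiple_comparison <- function(groups, control = 1L) {
  groups <- .prep_groups(groups)
  kw <- kruskal_wallis(groups)
  jr <- .joint_ranks(groups)
  N <- jr$N
  k <- length(groups)
  if (identical(control, "all_pairs")) {
    pairs <- utils::combn(k, 2, simplify = FALSE)
  } else {
    if (is.character(control)) control <- match(control, names(groups))
    if (is.na(control) || control < 1 || control > k) {
      rlang::abort("`control` must name or index one of the groups.",
        class = "mateguard_validation_error"
      )
    }
    pairs <- lapply(setdiff(seq_len(k), control), function(j) c(control, j))
  }
  m <- length(pairs)
  var_term <- N * (N + 1) / 12 - jr$tie_term / (12 * (N - 1))
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]
    j <- pr[2]
    dif <- unname(jr$rank_means[i] - jr$rank_means[j])
    se <- sqrt(var_term * (1 / jr$n[[i]] + 1 / jr$n[[j]]))
    z <- if (se == 0) 0 else dif / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(
      pair = paste(names(groups)[i], names(groups)[j], sep = " vs "),
      rank_mean_diff = dif,
      z = z,
      p_value = p,
      p_adjusted = min(1, p * m)
    )
  })
  comparisons <- dplyr::bind_rows(rows)
  comparisons$hash_mark <- comparisons$p_adjusted < 0.05
  structure(
    list(kw_H = kw$H, kw_p = kw$p_value, comparisons = comparisons),
    class = "multi_group_result"
  )
}

#' @export
print.multi_group_result <- function(x, ...) {
  cat(sprintf("<multi_group_result> Kruskal-Wallis H = %g, p = %g\n", x$kw_H, x$kw_p))
  print(x$comparisons)
  invisible(x)
}

#' Run the full comparison pipeline for one metric of an assay table
#'
#' Applies the analysis route used for every behavioral panel: filter to males
#' mating within the window, check per-group normality, compare groups
#' (Student's t for two groups; Kruskal-Wallis plus Dunn's post hoc against
#' the reference for more), attach bootstrap estimation statistics of each
#' group against the reference, and annotate significance.
#'
#' @param table Assay table (e.g. from [simulate_md_assay()]).
#' @param metric Name of the metric column (default `"mating_duration_s"`).
#' @param group_col Name of the grouping column (default `"condition"`).
#' @param ref_group Label of the reference (internal control) group; default
#'   `"naive"`.
#' @param window Inclusion window in seconds passed to
#'   [filter_within_window()]; use `Inf` to skip filtering.
#' @param n_resamples,seed Bootstrap settings (see
#'   [bootstrap_mean_difference()]).
#' @return An object of class `"comparison_result"`: list with `group_labels`,
#'   `n`, `means`, `sems`, `normality_p`, `percent_reduction` (reference
#'   versus each other group), and either `t_statistic`/`df`/`p_value` (two
#'   groups) or a `multi_group` [dunns_multiple_comparison()] result, plus
#'   `stars` and a per-comparison `estimation` list.
#' @export
compare_experiment <- function(table, metric = "mating_duration_s",
                               group_col = "condition", ref_group = "naive",
                               window = 3600, n_resamples = 5000L, seed = 1L) {
  missing_cols <- setdiff(c(metric, group_col), names(table))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("`table` is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "mateguard_schema_error"
    )
  }
  if ("copulation_latency_s" %in% names(table) && is.finite(window)) {
    table <- filter_within_window(table, window)
  }
  groups <- split(table[[metric]], table[[group_col]])
  if (!ref_group %in% names(groups)) {
    rlang::abort(
      sprintf(
        "Reference group '%s' not present after filtering (found: %s).",
        ref_group, paste(names(groups), collapse = ", ")
      ),
      class = "mateguard_validation_error"
    )
  }
  # reference first, remaining groups in table order
  groups <- groups[c(ref_group, setdiff(names(groups), ref_group))]
  labels <- names(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), numeric(1))
  normality_p <- vapply(groups, function(g) {
    if (length(g) >= 5 && stats::sd(g) > 0) ks_normality(g)$p_value else NA_real_
  }, numeric(1))
  pr <- vapply(
    labels[-1],
    function(lb) percent_reduction(groups[[ref_group]], groups[[lb]]),
    numeric(1)
  )
  estimation <- lapply(labels[-1], function(lb) {
    bootstrap_mean_difference(groups[[ref_group]], groups[[lb]],
      n_resamples = n_resamples, seed = seed
    )
  })
  names(estimation) <- labels[-1]
  if (length(groups) == 2L) {
    tt <- students_t(groups[[1]], groups[[2]])
    out <- list(
      group_labels = labels, n = n, means = means, sems = sems,
      normality_p = normality_p, percent_reduction = pr,
      t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
      stars = significance_annotation(tt$p_value),
      estimation = estimation, multi_group = NULL
    )
  } else {
    mg <- dunns_multiple_comparison(groups, control = 1L)
    out <- list(
      group_labels = labels, n = n, means = means, sems = sems,
      normality_p = normality_p, percent_reduction = pr,
      t_statistic = NULL, df = NULL, p_value = mg$kw_p,
      stars = significance_annotation(mg$kw_p),
      estimation = estimation, multi_group = mg
    )
  }
  structure(out, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s (n = %s)\n",
    paste(x$group_labels, collapse = " / "),
    paste(x$n, collapse = " / ")
  ))
  cat(sprintf(
    "  means: %s\n",
    paste(sprintf("%.3g", x$means), collapse = " / ")
  ))
  if (length(x$percent_reduction)) {
    cat(sprintf(
      "  percent reduction vs %s: %s\n", x$group_labels[1],
      paste(sprintf("%.3g%%", x$percent_reduction), collapse = " / ")
    ))
  }
  if (!is.null(x$t_statistic)) {
    cat(sprintf(
      "  Student's t = %.4g (df %g), p = %.3g %s\n",
      x$t_statistic, x$df, x$p_value, x$stars
    ))
  } else {
    cat(sprintf(
      "  Kruskal-Wallis p = %.3g %s (%d Dunn comparisons)\n",
      x$p_value, x$stars, nrow(x$multi_group$comparisons)
    ))
  }
  invisible(x)
}
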