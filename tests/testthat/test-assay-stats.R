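toy_table <- function(latencies) {
  tibble::tibble(
    fly_id = sprintf("f%02d", seq_along(latencies)),
    genotype = "CS",
    condition = "naive",
    mating_duration_s = 1200,
    copulation_latency_s = latencies,
    included = TRUE
  )
}

test_that("the 1 h inclusion filter keeps the boundary and is idempotent", {
  tab <- toy_table(c(100, 3599, 3600, 3601, 7200))
  kept <- filter_within_window(tab)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$copulation_latency_s, c(100, 3599, 3600))
  expect_identical(filter_within_window(kept), kept)
  all_in <- toy_table(c(10, 20))
  expect_equal(filter_within_window(all_in), all_in)
  empty <- toy_table(numeric(0))
  expect_equal(nrow(filter_within_window(empty)), 0)
  expect_error(
    filter_within_window(dplyr::select(tab, -copulation_latency_s)),
    class = "mateguard_schema_error"
  )
})

test_that("percent reduction is the reference-denominated mean contrast", {
  expect_equal(percent_reduction(c(100, 100), c(87.6, 87.6)), 12.4)
  expect_equal(percent_reduction(1:10, 1:10), 0)
  expect_error(percent_reduction(c(-1, 1), c(1, 1)), class = "mateguard_domain_error")
  expect_error(percent_reduction(numeric(0), 1), class = "mateguard_validation_error")
})

test_that("Student's t matches the pooled-variance formula and stats::t.test", {
  tt <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$t_statistic, -3.6742, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0213, tolerance = 1e-3)
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- rnorm(sample(3:20, 1))
      b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
      ours <- students_t(a, b)
      ref <- t.test(a, b, var.equal = TRUE)
      expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$df, unname(ref$parameter))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      welch <- students_t(a, b, var_equal = FALSE)
      ref_w <- t.test(a, b)
      expect_equal(welch$t_statistic, unname(ref_w$statistic), tolerance = 1e-12)
      expect_equal(welch$p_value, ref_w$p.value, tolerance = 1e-12)
    }
  })
})

test_that("zero pooled variance follows the stated degenerate conventions", {
  eq <- students_t(c(2, 2, 2), c(2, 2))
  expect_true(eq$degenerate)
  expect_equal(eq$p_value, 1)
  ne <- students_t(c(2, 2, 2), c(3, 3))
  expect_true(ne$degenerate)
  expect_equal(ne$p_value, 0)
})

test_that("normality checks use the Lilliefors correction and detect skew", {
  withr::with_seed(8, {
    x <- rnorm(100, 5, 2)
    ours <- ks_normality(x)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
    y <- rlnorm(100)
    expect_equal(
      ks_normality(y, mode = "lognormal")$p_value,
      nortest::lillie.test(log(y))$p.value
    )
    # a strongly exponential sample is rejected in normality mode
    z <- rexp(500)
    expect_lt(ks_normality(z)$p_value, 0.05)
    naive <- ks_normality(x, correction = "naive")
    ref_naive <- ks.test(x, "pnorm", mean(x), sd(x))
    expect_equal(naive$p_value, ref_naive$p.value)
  })
  expect_error(ks_normality(c(0, 1, 2, 3, 4), mode = "lognormal"),
    class = "mateguard_domain_error"
  )
  expect_error(ks_normality(rep(1, 10)), class = "mateguard_domain_error")
  expect_error(ks_normality(c(1, 2, 3)), class = "mateguard_validation_error")
})

test_that("Kruskal-Wallis matches the no-tie rank formula and stats::kruskal.test", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2) # 12/(9*10) * (3*4 + 3*25 + 3*64) - 3*10
  expect_equal(kw$df, 2)
  two_same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(two_same$H, 0)
  flat <- kruskal_wallis(list(c(1, 1), c(1, 1, 1)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)
  withr::with_seed(13, {
    for (i in 1:20) {
      groups <- lapply(1:3, function(j) sample(1:8, sample(2:8, 1), replace = TRUE))
      ours <- kruskal_wallis(groups)
      ref <- kruskal.test(groups)
      expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
  expect_error(kruskal_wallis(list(1:3)), class = "mateguard_validation_error")
})

test_that("Dunn's z statistics match an independent brute-force ranking oracle", {
  res <- dunns_multiple_comparison(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$comparisons$z, 0)
  expect_equal(res$comparisons$p_adjusted, 1)
  expect_false(res$comparisons$hash_mark)
  withr::with_seed(29, {
    for (i in 1:50) {
      groups <- random_small_groups(sample(2:4, 1))
      ours <- dunns_multiple_comparison(groups)
      expect_equal(ours$comparisons$z, brute_dunn_z(groups), tolerance = 1e-10)
      expect_equal(ours$kw_H, brute_kw_h(groups), tolerance = 1e-10)
      expect_equal(
        ours$comparisons$hash_mark,
        ours$comparisons$p_adjusted < 0.05
      )
    }
  })
})

test_that("Dunn adjustment scales with the number of comparisons performed", {
  groups <- list(ctrl = c(1, 2, 3), g1 = c(7, 8, 9), g2 = c(4, 5, 6), g3 = c(2, 3, 4))
  vs_ctrl <- dunns_multiple_comparison(groups, control = "ctrl")
  all_pairs <- dunns_multiple_comparison(groups, control = "all_pairs")
  expect_equal(nrow(vs_ctrl$comparisons), 3)
  expect_equal(nrow(all_pairs$comparisons), 6)
  shared <- vs_ctrl$comparisons$pair[1]
  i <- match(shared, all_pairs$comparisons$pair)
  expect_equal(
    all_pairs$comparisons$p_value[i],
    vs_ctrl$comparisons$p_value[1]
  )
  expect_equal(
    min(1, vs_ctrl$comparisons$p_value[1] * 3),
    vs_ctrl$comparisons$p_adjusted[1]
  )
})

test_that("bootstrap estimation is seeded, ordered, and degenerate-safe", {
  withr::with_seed(2, {
    a <- rnorm(20)
    b <- rnorm(20, 1)
  })
  r1 <- bootstrap_mean_difference(a, b, n_resamples = 500, seed = 7)
  r2 <- bootstrap_mean_difference(a, b, n_resamples = 500, seed = 7)
  expect_identical(r1[c("ci_low", "ci_high")], r2[c("ci_low", "ci_high")])
  expect_equal(r1$mean_difference, mean(b) - mean(a))
  expect_lte(r1$ci_low, r1$mean_difference)
  expect_gte(r1$ci_high, r1$mean_difference)
  const <- bootstrap_mean_difference(rep(2, 5), rep(2, 5), n_resamples = 200)
  expect_equal(const$mean_difference, 0)
  expect_equal(const$ci_low, 0)
  expect_equal(const$ci_high, 0)
  bca <- bootstrap_mean_difference(a, b, n_resamples = 500, method = "bca", seed = 7)
  expect_lt(bca$ci_low, bca$ci_high)
  expect_error(bootstrap_mean_difference(a, b, n_resamples = 50),
    class = "mateguard_validation_error"
  )
})

test_that("star annotation uses the strict legend thresholds", {
  expect_identical(significance_annotation(0.0005), "***")
  expect_identical(significance_annotation(0.001), "**")
  expect_identical(significance_annotation(0.009), "**")
  expect_identical(significance_annotation(0.01), "*")
  expect_identical(significance_annotation(0.049), "*")
  expect_identical(significance_annotation(0.05), "ns")
  expect_identical(significance_annotation(0.2), "ns")
  expect_error(significance_annotation(1.2), class = "mateguard_domain_error")
})

test_that("behavioral metrics follow their defining ratios", {
  expect_equal(courtship_index(300), 0.5)
  expect_equal(courtship_index(150, time_to_mate_s = 200), 0.75)
  expect_equal(courtship_index(0), 0)
  expect_error(courtship_index(700), class = "mateguard_domain_error")
  expect_equal(locomotion_velocity(80, 10), 8)
  expect_equal(locomotion_velocity(0, 10), 0)
  expect_error(locomotion_velocity(10, 0), class = "mateguard_domain_error")
  expect_equal(normalize_fluorescence(200, 100), 2)
  expect_equal(normalize_fluorescence(150, 150), 1)
  expect_error(normalize_fluorescence(200, 0), class = "mateguard_domain_error")
})

test_that("compare_experiment runs the full two-group route consistently", {
  tab <- simulate_md_assay(assay_design(percent_reduction = 15, seed = 44))
  res <- compare_experiment(tab, n_resamples = 500, seed = 3)
  expect_s3_class(res, "comparison_result")
  expect_identical(res$group_labels[1], "naive")
  expect_equal(unname(res$n), c(sum(tab$condition == "naive" & tab$included),
    sum(tab$condition == "experienced" & tab$included)))
  expect_identical(res$stars, significance_annotation(res$p_value))
  est <- res$estimation$experienced
  expect_lt(est$mean_difference, 0) # experienced shorter
  # identical groups: ns and a CI spanning zero
  null_tab <- simulate_md_assay(assay_design(percent_reduction = 0, seed = 45))
  null_res <- compare_experiment(null_tab, n_resamples = 500, seed = 3)
  expect_identical(null_res$stars, "ns")
  expect_lt(null_res$estimation$experienced$ci_low, 0)
  expect_gt(null_res$estimation$experienced$ci_high, 0)
  expect_error(
    compare_experiment(tab, ref_group = "missing_group"),
    "missing_group"
  )
})

test_that("compare_experiment routes multi-group designs to Kruskal-Wallis/Dunn", {
  groups <- tibble::tibble(
    genotype = "CS",
    condition = c("naive", rep("experienced", 3)),
    n = 36L,
    percent_reduction = c(NA, 0, 15, 15),
    label = c("naive", "2h", "12h", "24h")
  )
  tab <- simulate_md_assay(assay_design(groups = groups, seed = 46))
  res <- compare_experiment(tab, group_col = "label", n_resamples = 200, seed = 3)
  expect_false(is.null(res$multi_group))
  expect_equal(nrow(res$multi_group$comparisons), 3)
  expect_identical(
    res$multi_group$comparisons$hash_mark,
    res$multi_group$comparisons$p_adjusted < 0.05
  )
})
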