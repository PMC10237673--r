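# Independent brute-force oracles used to cross-check the rank-based
# statistics. Ranks are computed by counting comparisons, not by rank(), and
# the statistics are written out directly from their defining formulas.

# Midrank of each observation by explicit counting.
brute_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

# Kruskal-Wallis H (tie-corrected) from first principles.
brute_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- brute_ranks(x)
  n_tot <- length(x)
  h <- 0
  for (k in seq_along(groups)) {
    rk <- mean(r[g == k])
    h <- h + length(groups[[k]]) * rk^2
  }
  h <- (12 / (n_tot * (n_tot + 1))) * h - 3 * (n_tot + 1)
  ties <- 0
  for (v in unique(x)) {
    tv <- sum(x == v)
    ties <- ties + tv^3 - tv
  }
  h / (1 - ties / (n_tot^3 - n_tot))
}

# Dunn z statistics (control group 1 vs the rest) from first principles.
brute_dunn_z <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- brute_ranks(x)
  n_tot <- length(x)
  ties <- 0
  for (v in unique(x)) {
    tv <- sum(x == v)
    ties <- ties + tv^3 - tv
  }
  s2 <- n_tot * (n_tot + 1) / 12 - ties / (12 * (n_tot - 1))
  vapply(seq_along(groups)[-1], function(j) {
    d <- mean(r[g == 1]) - mean(r[g == j])
    d / sqrt(s2 * (1 / sum(g == 1) + 1 / sum(g == j)))
  }, numeric(1))
}

# Random small multi-group instance (total n <= 12), optionally with ties.
random_small_groups <- function(k = 3) {
  sizes <- pmax(1, stats::rmultinom(1, sample(3:12, 1), rep(1, k))[, 1])
  lapply(seq_len(k), function(i) sample(1:6, sizes[i], replace = TRUE))
}
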