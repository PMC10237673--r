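# Egg/progeny ratio analyses and two-sire paternity attribution via the
# recessive sepia eye-color marker.

.check_cross_genotypes <- function(mother_gt, sire1_gt, sire2_gt) {
  gts <- c("se/se", "+/+")
  if (!all(c(mother_gt, sire1_gt, sire2_gt) %in% gts)) {
    rlang::abort("Genotypes must be 'se/se' or '+/+'.",
      class = "mateguard_validation_error"
    )
  }
  if (sire1_gt == sire2_gt) {
    rlang::abort("The two sires are indistinguishable at the sepia locus.",
      class = "mateguard_attribution_error"
    )
  }
  if (mother_gt != "se/se") {
    rlang::abort(
      "Attribution requires a se/se mother: with a +/+ mother every progeny is wild-type eyed.",
      class = "mateguard_attribution_error"
    )
  }
  invisible(TRUE)
}

#' Attribute a progeny's sire from its eye phenotype
#'
#' In a two-sire cross with a se/se mother and sires differing at the sepia
#' locus, sepia is recessive: sepia-eyed progeny carry se from both parents and
#' therefore belong to the se/se sire, while wild-type-eyed progeny are the
#' heterozygous offspring of the +/+ sire.
#'
#' @param eye_phenotype `"sepia"` or `"wildtype"`.
#' @param mother_gt,sire1_gt,sire2_gt Genotypes at the sepia locus (`"se/se"`
#'   or `"+/+"`); the mother must be se/se and the sires must differ.
#' @return `"first"` or `"second"`.
#' @examples
#' assign_sire("sepia", "se/se", "se/se", "+/+") # "first"
#' assign_sire("sepia", "se/se", "+/+", "se/se") # "second"
#' @export
assign_sire <- function(eye_phenotype, mother_gt = "se/se",
                        sire1_gt = "se/se", sire2_gt = "+/+") {
  if (!eye_phenotype %in% c("sepia", "wildtype")) {
    rlang::abort("`eye_phenotype` must be 'sepia' or 'wildtype'.",
      class = "mateguard_validation_error"
    )
  }
  .check_cross_genotypes(mother_gt, sire1_gt, sire2_gt)
  se_sire <- if (sire1_gt == "se/se") "first" else "second"
  other <- setdiff(c("first", "second"), se_sire)
  if (eye_phenotype == "sepia") se_sire else other
}

#' Paternity shares from two-sire cross records
#'
#' Attributes every progeny to its sire via [assign_sire()] and reports the
#' progeny-pooled percentage sired by the first and second male, together with
#' per-female shares. Females with zero progeny are excluded from the
#' per-female statistics but still counted in `n_females`.
#'
#' @param records Data frame of cross records with columns `female_id`,
#'   `mother_gt`, `sire1_gt`, `sire2_gt`, `n_sepia`, `n_wildtype` (e.g. from
#'   [simulate_paternity()]).
#' @return An object of class `"paternity_result"`: list with
#'   `first_sire_share` and `second_sire_share` (pooled percentages),
#'   `n_females`, `total_progeny`, and a `per_female` tibble.
#' @export
paternity_share <- function(records) {
  required <- c("female_id", "mother_gt", "sire1_gt", "sire2_gt", "n_sepia", "n_wildtype")
  if (NROW(records) == 0) {
    rlang::abort("`records` must contain at least one cross.",
      class = "mateguard_validation_error"
    )
  }
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("`records` is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "mateguard_schema_error"
    )
  }
  if (any(records$n_sepia < 0) || any(records$n_wildtype < 0)) {
    rlang::abort("Progeny counts must be non-negative.",
      class = "mateguard_validation_error"
    )
  }
  n_first <- numeric(nrow(records))
  n_second <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    .check_cross_genotypes(r$mother_gt, r$sire1_gt, r$sire2_gt)
    sepia_sire <- assign_sire("sepia", r$mother_gt, r$sire1_gt, r$sire2_gt)
    if (sepia_sire == "first") {
      n_first[i] <- r$n_sepia
      n_second[i] <- r$n_wildtype
    } else {
      n_first[i] <- r$n_wildtype
      n_second[i] <- r$n_sepia
    }
  }
  total <- n_first + n_second
  grand <- sum(total)
  if (grand == 0) {
    rlang::abort("No progeny in any record; shares are undefined.",
      class = "mateguard_validation_error"
    )
  }
  per_female <- tibble::tibble(
    female_id = records$female_id,
    total_progeny = as.integer(total),
    first_sire_share = ifelse(total > 0, 100 * n_first / total, NA_real_)
  )
  structure(
    list(
      first_sire_share = 100 * sum(n_first) / grand,
      second_sire_share = 100 * sum(n_second) / grand,
      n_females = nrow(records),
      total_progeny = as.integer(grand),
      per_female = per_female
    ),
    class = "paternity_result"
  )
}

#' @export
print.paternity_result <- function(x, ...) {
  cat(sprintf(
    "<paternity_result> first sire %.1f%% / second sire %.1f%% (%d progeny, %d females)\n",
    x$first_sire_share, x$second_sire_share, x$total_progeny, x$n_females
  ))
  invisible(x)
}

#' Relative ratio of naive-arm to experienced-arm counts
#'
#' The bar-plot style summary used for egg and progeny comparisons: the naive
#' arm is the control bar fixed at 1, and the experienced bar is
#' `mean(naive counts) / mean(experienced counts)`. A pooled-variance
#' Student's t comparison of the raw counts and a bootstrap CI of the ratio
#' (resampling females) accompany the ratio.
#'
#' @param counts_naive_arm,counts_experienced_arm Per-female counts (eggs or
#'   progeny) for the two arms.
#' @param n_resamples,ci_level,seed Bootstrap settings for the ratio CI.
#' @return List with `control_bar` (always 1), `ratio`, `ratio_ci` (length-2),
#'   `t_statistic`, `df`, `p_value`, `stars`.
#' @export
relative_ratio <- function(counts_naive_arm, counts_experienced_arm,
                           n_resamples = 5000L, ci_level = 0.95, seed = 1L) {
  a <- .as_numeric_group(counts_naive_arm, "counts_naive_arm")
  b <- .as_numeric_group(counts_experienced_arm, "counts_experienced_arm")
  if (mean(b) <= 0) {
    rlang::abort("Experienced-arm mean must be > 0.", class = "mateguard_domain_error")
  }
  ratio <- mean(a) / mean(b)
  boots <- withr::with_seed(seed, {
    ra <- matrix(sample(a, n_resamples * length(a), replace = TRUE), nrow = n_resamples)
    rb <- matrix(sample(b, n_resamples * length(b), replace = TRUE), nrow = n_resamples)
    rowMeans(ra) / pmax(rowMeans(rb), .Machine$double.eps)
  })
  alpha <- (1 - ci_level) / 2
  tt <- students_t(a, b)
  list(
    control_bar = 1,
    ratio = ratio,
    ratio_ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
    t_statistic = tt$t_statistic,
    df = tt$df,
    p_value = tt$p_value,
    stars = significance_annotation(tt$p_value)
  )
}
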