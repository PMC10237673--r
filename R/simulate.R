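# Seeded generators for synthetic behavioral assay data.
#
# The generators emulate the statistical structure the downstream analyses
# assume: per-group normal mating durations recorded to 10 s, a configurable
# percent reduction in the experienced condition, right-skewed positive
# latencies, Poisson eggs with binomial progeny survival, binomial sperm use
# in two-sire crosses with a recessive sepia marker, and lognormal
# fluorescence intensities. Every generator is a pure function of its design
# (which includes the seed).

# Lognormal draws matching a target mean and sd exactly; sd = 0 degenerates to
# the mean itself.
.rlnorm_moments <- function(n, mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) {
    return(rep(mean, n))
  }
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

.check_design <- function(x, class) {
  if (!inherits(x, class)) {
    rlang::abort(sprintf("`design` must be created by %s().", sub("_design$", "_design", class)),
      class = "mateguard_validation_error"
    )
  }
  invisible(x)
}

#' Design of a mating-duration assay cohort
#'
#' Describes the groups and the generating distributions of a synthetic
#' mating-duration (MD) assay. Defaults follow the study conditions of the
#' assays the package targets: 36 males per group (the minimum cohort size
#' used for MD assays), a 1-hour mating inclusion window, durations recorded
#' to 10 s, and a 15% reduction of the experienced-group mean relative to
#' naive (wild-type strains show 15.7~15.8%, w1118 12.4%).
#'
#' @param groups Data frame with columns `genotype`, `condition` (each
#'   `"naive"` or `"experienced"`) and `n` (>= 1 flies). Default: one CS-like
#'   genotype in both conditions, n = 36 each. Optional columns:
#'   `percent_reduction` (per-group override of the design-level effect, e.g.
#'   for exposure-time cohorts; `NA` falls back to the design value) and
#'   `label` (carried through to the output table for multi-arm designs).
#' @param md_mean_naive Mean naive mating duration in seconds (> 0).
#' @param md_sd Common SD of mating duration in seconds (>= 0).
#' @param percent_reduction Percent shortening of the experienced mean relative
#'   to naive, in `[0, 100)`.
#' @param copulation_latency_mean,copulation_latency_sd Moments (s) of the
#'   right-skewed (lognormal) copulation latency.
#' @param mating_window Inclusion window in seconds (default 3600: only males
#'   that mate within 1 h are analyzed).
#' @param courtship_index_mean,courtship_index_sd Moments of the courtship
#'   index, clamped to `[0, 1]`.
#' @param velocity_mean,velocity_sd Moments of locomotion velocity (mm/s).
#' @param seed Integer seed; the generator is deterministic given the design.
#' @return An object of class `"assay_design"`.
#' @export
assay_design <- function(groups = NULL,
                         md_mean_naive = 1500,
                         md_sd = 300,
                         percent_reduction = 15,
                         copulation_latency_mean = 900,
                         copulation_latency_sd = 600,
                         mating_window = 3600,
                         courtship_index_mean = 0.6,
                         courtship_index_sd = 0.15,
                         velocity_mean = 8,
                         velocity_sd = 2,
                         seed = 1L) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      genotype = "CS",
      condition = c("naive", "experienced"),
      n = 36L
    )
  }
  groups <- tibble::as_tibble(groups)
  ok <- all(c("genotype", "condition", "n") %in% names(groups)) &&
    all(groups$condition %in% c("naive", "experienced")) &&
    all(groups$n >= 1)
  if (!ok) {
    rlang::abort(
      "`groups` needs columns genotype, condition in {naive, experienced}, n >= 1.",
      class = "mateguard_validation_error"
    )
  }
  if (md_mean_naive <= 0 || md_sd < 0 ||
      percent_reduction < 0 || percent_reduction >= 100 ||
      copulation_latency_mean <= 0 || copulation_latency_sd < 0 ||
      mating_window <= 0 || courtship_index_sd < 0 ||
      courtship_index_mean < 0 || courtship_index_mean > 1 ||
      velocity_mean <= 0 || velocity_sd < 0) {
    rlang::abort("Invalid assay design parameters.", class = "mateguard_validation_error")
  }
  structure(
    list(
      groups = groups, md_mean_naive = md_mean_naive, md_sd = md_sd,
      percent_reduction = percent_reduction,
      copulation_latency_mean = copulation_latency_mean,
      copulation_latency_sd = copulation_latency_sd,
      mating_window = mating_window,
      courtship_index_mean = courtship_index_mean,
      courtship_index_sd = courtship_index_sd,
      velocity_mean = velocity_mean, velocity_sd = velocity_sd,
      seed = as.integer(seed)
    ),
    class = "assay_design"
  )
}

#' Generate a synthetic mating-duration assay table
#'
#' Mating durations are drawn per group from a normal distribution (the study
#' design reports normally distributed durations), floored at 60 s and rounded
#' to the nearest 10 s (the recording accuracy); the experienced-group mean is
#' `md_mean_naive * (1 - percent_reduction/100)`. Copulation and courtship
#' latencies are lognormal; the courtship index is normal clamped to `[0, 1]`;
#' velocity is normal clamped at zero. `included` flags males whose copulation
#' latency falls within the mating window.
#'
#' @param design An [assay_design()].
#' @return A tibble with columns `fly_id`, `genotype`, `condition`,
#'   `mating_duration_s`, `copulation_latency_s`, `courtship_latency_s`,
#'   `courtship_index`, `velocity_mm_s`, `included`.
#' @export
simulate_md_assay <- function(design) {
  .check_design(design, "assay_design")
  withr::with_seed(design$seed, {
    rows <- lapply(seq_len(nrow(design$groups)), function(i) {
      g <- design$groups[i, ]
      mu <- design$md_mean_naive
      if (g$condition == "experienced") {
        pr <- design$percent_reduction
        if ("percent_reduction" %in% names(g) && !is.na(g$percent_reduction)) {
          pr <- g$percent_reduction
        }
        mu <- mu * (1 - pr / 100)
      }
      n <- g$n
      md <- round(pmax(stats::rnorm(n, mu, design$md_sd), 60) / 10) * 10
      cop_lat <- .rlnorm_moments(
        n, design$copulation_latency_mean, design$copulation_latency_sd
      )
      crt_lat <- cop_lat * stats::runif(n, 0.1, 0.9)
      ci <- pmin(pmax(
        stats::rnorm(n, design$courtship_index_mean, design$courtship_index_sd),
        0
      ), 1)
      vel <- pmax(stats::rnorm(n, design$velocity_mean, design$velocity_sd), 0)
      tibble::tibble(
        genotype = g$genotype,
        condition = g$condition,
        label = if ("label" %in% names(g)) g$label else g$condition,
        mating_duration_s = md,
        copulation_latency_s = cop_lat,
        courtship_latency_s = crt_lat,
        courtship_index = ci,
        velocity_mm_s = vel,
        included = cop_lat <= design$mating_window
      )
    })
    out <- dplyr::bind_rows(rows)
    tibble::add_column(out, fly_id = sprintf("fly_%04d", seq_len(nrow(out))), .before = 1)
  })
}

#' Design of a fecundity (egg and progeny count) experiment
#'
#' Two arms of females, each mated to naive or to experienced males, lay eggs
#' for 24 h; eggs are counted, and progeny are the eggs surviving to eclosion.
#'
#' @param n_females Females per arm (>= 1).
#' @param egg_mean Mean eggs per female per 24 h (>= 0).
#' @param progeny_survival Probability an egg yields an eclosed adult, in `[0, 1]`.
#' @param egg_multiplier,survival_multiplier Named multipliers (arms
#'   `mated_to_naive`, `mated_to_experienced`) applied to the egg mean and the
#'   survival probability; the product of survival and its multiplier is capped
#'   at 1.
#' @param overdispersion Optional positive negative-binomial size parameter;
#'   `NULL` (default) draws Poisson egg counts.
#' @param seed Integer seed.
#' @return An object of class `"fecundity_design"`.
#' @export
fecundity_design <- function(n_females = 20L,
                             egg_mean = 50,
                             progeny_survival = 0.9,
                             egg_multiplier = c(mated_to_naive = 1, mated_to_experienced = 1),
                             survival_multiplier = c(mated_to_naive = 1, mated_to_experienced = 1),
                             overdispersion = NULL,
                             seed = 1L) {
  arms <- c("mated_to_naive", "mated_to_experienced")
  if (n_females < 1 || egg_mean < 0 || progeny_survival < 0 || progeny_survival > 1 ||
      !all(arms %in% names(egg_multiplier)) || !all(arms %in% names(survival_multiplier)) ||
      any(egg_multiplier < 0) || any(survival_multiplier < 0) ||
      (!is.null(overdispersion) && overdispersion <= 0)) {
    rlang::abort("Invalid fecundity design parameters.", class = "mateguard_validation_error")
  }
  structure(
    list(
      n_females = as.integer(n_females), egg_mean = egg_mean,
      progeny_survival = progeny_survival,
      egg_multiplier = egg_multiplier[arms],
      survival_multiplier = survival_multiplier[arms],
      overdispersion = overdispersion, seed = as.integer(seed)
    ),
    class = "fecundity_design"
  )
}

#' Generate synthetic egg and progeny counts
#'
#' @param design A [fecundity_design()].
#' @return Tibble with columns `female_id`, `arm`, `eggs_24h`, `progeny`;
#'   `progeny <= eggs_24h` row-wise.
#' @export
simulate_fecundity <- function(design) {
  .check_design(design, "fecundity_design")
  withr::with_seed(design$seed, {
    rows <- lapply(names(design$egg_multiplier), function(arm) {
      n <- design$n_females
      mu <- design$egg_mean * design$egg_multiplier[[arm]]
      eggs <- if (is.null(design$overdispersion)) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, size = design$overdispersion, mu = mu)
      }
      p <- min(design$progeny_survival * design$survival_multiplier[[arm]], 1)
      tibble::tibble(
        arm = arm,
        eggs_24h = as.integer(eggs),
        progeny = as.integer(stats::rbinom(n, eggs, p))
      )
    })
    out <- dplyr::bind_rows(rows)
    tibble::add_column(out, female_id = sprintf("female_%04d", seq_len(nrow(out))), .before = 1)
  })
}

#' Design of a two-sire sperm-competition cross
#'
#' Each female mates first with one male and then with a second male of a
#' different genotype at the sepia (se) locus; progeny eye color identifies the
#' sire (sepia is recessive: sepia-eyed progeny require a se allele from both
#' parents).
#'
#' @param n_females Number of females (>= 1).
#' @param mother_genotype,first_sire_genotype,second_sire_genotype Genotypes at
#'   the sepia locus, `"se/se"` or `"+/+"`. The two sires must differ.
#' @param first_sire_share Probability a progeny is sired by the first male.
#' @param progeny_mean Mean progeny per female (Poisson).
#' @param seed Integer seed.
#' @return An object of class `"cross_design"`.
#' @export
cross_design <- function(n_females = 20L,
                         mother_genotype = "se/se",
                         first_sire_genotype = "se/se",
                         second_sire_genotype = "+/+",
                         first_sire_share = 0.3,
                         progeny_mean = 40,
                         seed = 1L) {
  gts <- c("se/se", "+/+")
  if (!mother_genotype %in% gts || !first_sire_genotype %in% gts ||
      !second_sire_genotype %in% gts ||
      first_sire_share < 0 || first_sire_share > 1 ||
      n_females < 1 || progeny_mean < 0) {
    rlang::abort("Invalid cross design parameters.", class = "mateguard_validation_error")
  }
  if (first_sire_genotype == second_sire_genotype) {
    rlang::abort(
      "The two sires must differ at the sepia locus for paternity attribution.",
      class = "mateguard_validation_error"
    )
  }
  structure(
    list(
      n_females = as.integer(n_females), mother_genotype = mother_genotype,
      first_sire_genotype = first_sire_genotype,
      second_sire_genotype = second_sire_genotype,
      first_sire_share = first_sire_share, progeny_mean = progeny_mean,
      seed = as.integer(seed)
    ),
    class = "cross_design"
  )
}

# Eye phenotype of progeny from mother x sire at the sepia locus; sepia is
# recessive, so only se/se x se/se crosses give sepia-eyed offspring here.
.progeny_phenotype <- function(mother_gt, sire_gt) {
  if (mother_gt == "se/se" && sire_gt == "se/se") "sepia" else "wildtype"
}

#' Generate synthetic two-sire cross records
#'
#' Per female, total progeny is Poisson; each progeny is sired by the first
#' male with probability `first_sire_share`, and eye color follows from the
#' recessive sepia marker.
#'
#' @param design A [cross_design()].
#' @return Tibble of cross records: `female_id`, `mother_gt`, `sire1_gt`,
#'   `sire2_gt`, `n_sepia`, `n_wildtype`.
#' @export
simulate_paternity <- function(design) {
  .check_design(design, "cross_design")
  withr::with_seed(design$seed, {
    total <- stats::rpois(design$n_females, design$progeny_mean)
    n_first <- stats::rbinom(design$n_females, total, design$first_sire_share)
    n_second <- total - n_first
    ph1 <- .progeny_phenotype(design$mother_genotype, design$first_sire_genotype)
    ph2 <- .progeny_phenotype(design$mother_genotype, design$second_sire_genotype)
    n_sepia <- (ph1 == "sepia") * n_first + (ph2 == "sepia") * n_second
    tibble::tibble(
      female_id = sprintf("female_%04d", seq_len(design$n_females)),
      mother_gt = design$mother_genotype,
      sire1_gt = design$first_sire_genotype,
      sire2_gt = design$second_sire_genotype,
      n_sepia = as.integer(n_sepia),
      n_wildtype = as.integer(total - n_sepia)
    )
  })
}

#' Design of an activity-reporter fluorescence experiment
#'
#' Emulates quantification of an activity-dependent GFP reporter in tarsal
#' segments T4 and T5 of naive and experienced males, with a separate
#' autofluorescence reading used for normalization. Defaults configure an
#' experience-dependent increase in T5 only, mirroring the segment-specific
#' contrast such reporters show.
#'
#' @param n_per_condition Flies per condition (>= 1).
#' @param levels Data frame with columns `condition`, `segment` (`"T4"`,
#'   `"T5"`), `gfp_mean` (> 0) and `gfp_sd` (>= 0), one row per
#'   condition-segment cell.
#' @param autofluorescence_mean,autofluorescence_sd Moments of the (lognormal)
#'   autofluorescence reading (> 0, >= 0).
#' @param seed Integer seed.
#' @return An object of class `"fluorescence_design"`.
#' @export
fluorescence_design <- function(n_per_condition = 10L,
                                levels = NULL,
                                autofluorescence_mean = 400,
                                autofluorescence_sd = 60,
                                seed = 1L) {
  if (is.null(levels)) {
    levels <- tibble::tibble(
      condition = rep(c("naive", "experienced"), each = 2),
      segment = rep(c("T4", "T5"), 2),
      gfp_mean = c(800, 800, 800, 1600),
      gfp_sd = 150
    )
  }
  levels <- tibble::as_tibble(levels)
  ok <- all(c("condition", "segment", "gfp_mean", "gfp_sd") %in% names(levels)) &&
    all(levels$gfp_mean > 0) && all(levels$gfp_sd >= 0)
  if (!ok || n_per_condition < 1 || autofluorescence_mean <= 0 ||
      autofluorescence_sd < 0) {
    rlang::abort("Invalid fluorescence design parameters.", class = "mateguard_validation_error")
  }
  structure(
    list(
      n_per_condition = as.integer(n_per_condition), levels = levels,
      autofluorescence_mean = autofluorescence_mean,
      autofluorescence_sd = autofluorescence_sd, seed = as.integer(seed)
    ),
    class = "fluorescence_design"
  )
}

#' Generate synthetic reporter-fluorescence readings
#'
#' @param design A [fluorescence_design()].
#' @return Tibble with columns `fly_id`, `condition`, `segment`, `gfp`,
#'   `autofluorescence`; all intensities strictly positive.
#' @export
simulate_calexa <- function(design) {
  .check_design(design, "fluorescence_design")
  withr::with_seed(design$seed, {
    rows <- lapply(seq_len(nrow(design$levels)), function(i) {
      lv <- design$levels[i, ]
      n <- design$n_per_condition
      tibble::tibble(
        fly_id = sprintf("%s_fly_%03d", lv$condition, seq_len(n)),
        condition = lv$condition,
        segment = lv$segment,
        gfp = .rlnorm_moments(n, lv$gfp_mean, lv$gfp_sd),
        autofluorescence = .rlnorm_moments(
          n, design$autofluorescence_mean, design$autofluorescence_sd
        )
      )
    })
    dplyr::bind_rows(rows)
  })
}
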