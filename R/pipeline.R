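# Orchestration: configuration, end-to-end runs, report serialization, CSV IO.

#' Map sexual-experience exposure time to the expected effect size
#'
#' Experience-dependent shortening requires a sufficiently long exposure:
#' cohorts exposed for 6 h or less show no shortening, cohorts exposed for
#' 12 h or more show the full effect, and intermediate exposures are
#' interpolated linearly.
#'
#' @param hours Hours of exposure to virgin females (>= 0).
#' @param full_effect Percent reduction at full effect (default 15).
#' @return Percent reduction to configure for the exposed group.
#' @examples
#' exposure_percent_reduction(c(2, 6, 12, 24))
#' @export
exposure_percent_reduction <- function(hours, full_effect = 15) {
  if (any(hours < 0)) {
    rlang::abort("`hours` must be >= 0.", class = "mateguard_domain_error")
  }
  pmin(pmax((hours - 6) / 6, 0), 1) * full_effect
}

#' The four canonical single-parameter scenario predictions
#'
#' Builds the four comparative-statics scenarios under which shorter mating
#' duration can be favored, each as a single-parameter shift from a naive
#' parameter set evaluated in its stated regime: (A) the benefit
#' inverse-capacity `alpha` increases (fewer fertilizable eggs in total);
#' (B) the benefit rate `beta` decreases; (C) the cost rate `gamma` increases
#' within the `beta/alpha < gamma < e*beta/alpha` window; (D) `gamma`
#' decreases while staying above `e*beta/alpha`.
#'
#' @param alpha,beta,gamma Naive parameters for scenarios A-C; `gamma` must
#'   lie inside the C window of the naive parameters.
#' @param gamma_d_naive,gamma_d_experienced Naive and experienced cost rates
#'   for scenario D (both above `e*beta/alpha`).
#' @param ... Passed to [predict_smd()] (solver settings).
#' @return Named list of four [predict_smd()] results (`A`, `B`, `C`, `D`).
#' @export
smd_scenarios <- function(alpha = 1, beta = 1, gamma = 1.5,
                          gamma_d_naive = 3.5, gamma_d_experienced = 3.0,
                          ...) {
  naive <- guarding_params(alpha, beta, gamma)
  list(
    A = predict_smd(naive, guarding_params(alpha * 1.5, beta, gamma), ...),
    B = predict_smd(naive, guarding_params(alpha, beta * 0.7, gamma), ...),
    C = predict_smd(naive, guarding_params(alpha, beta, min(gamma * 1.5, exp(1) * beta / alpha * 0.99)), ...),
    D = predict_smd(
      guarding_params(alpha, beta, gamma_d_naive),
      guarding_params(alpha, beta, gamma_d_experienced), ...
    )
  )
}

.require_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf(
        "%s is missing required column(s): %s.", what,
        paste(missing_cols, collapse = ", ")
      ),
      class = "mateguard_schema_error"
    )
  }
  invisible(df)
}

#' Read an assay table, fecundity table or cross-record CSV
#'
#' Readers for the documented CSV schemas; a malformed header is rejected with
#' a message naming the missing columns.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble.
#' @export
read_assay_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_columns(
    df, c("fly_id", "genotype", "condition", "mating_duration_s", "copulation_latency_s"),
    sprintf("Assay table '%s'", path)
  )
}

#' @rdname read_assay_table
#' @export
read_fecundity_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_columns(
    df, c("female_id", "arm", "eggs_24h", "progeny"),
    sprintf("Fecundity table '%s'", path)
  )
}

#' @rdname read_assay_table
#' @export
read_cross_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_columns(
    df, c("female_id", "mother_gt", "sire1_gt", "sire2_gt", "n_sepia", "n_wildtype"),
    sprintf("Cross records '%s'", path)
  )
}

#' Read a pipeline run configuration from JSON
#'
#' @param path Path to a JSON configuration (see [run_pipeline()] for the
#'   structure).
#' @return The configuration as a list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file '%s' does not exist.", path),
      class = "mateguard_io_error"
    )
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# JSON configs arrive as nested lists: collapse named lists of scalars to
# named vectors (multipliers) and lists of records to tibbles (group tables).
.coerce_design_arg <- function(a) {
  if (!is.list(a) || is.data.frame(a)) {
    return(a)
  }
  if (is.null(names(a)) && length(a) > 0 && is.list(a[[1]]) && !is.null(names(a[[1]]))) {
    return(dplyr::bind_rows(lapply(a, function(row) {
      tibble::as_tibble(lapply(row, function(v) if (is.null(v)) NA else v))
    })))
  }
  if (!is.null(names(a)) && all(vapply(a, function(v) is.atomic(v) && length(v) == 1L, logical(1)))) {
    return(unlist(a))
  }
  a
}

# Build a generator design from a config block.
.design_from_block <- function(block, seed) {
  args <- block$design
  if (is.null(args)) args <- list()
  args <- lapply(args, .coerce_design_arg)
  args$seed <- seed
  switch(block$type,
    md_assay = do.call(assay_design, args),
    fecundity = do.call(fecundity_design, args),
    paternity = do.call(cross_design, args),
    calexa = do.call(fluorescence_design, args),
    rlang::abort(sprintf("Unknown experiment type '%s'.", block$type),
      class = "mateguard_validation_error"
    )
  )
}

.run_block <- function(block, seed) {
  type <- block$type
  analysis <- block$analysis
  if (is.null(analysis)) analysis <- list()
  if (type == "md_assay") {
    tab <- if (!is.null(block$data)) {
      read_assay_table(block$data)
    } else {
      simulate_md_assay(.design_from_block(block, seed))
    }
    args <- c(list(table = tab, seed = seed), analysis)
    result <- do.call(compare_experiment, args)
    list(type = type, n_rows = nrow(tab), result = result)
  } else if (type == "fecundity") {
    tab <- if (!is.null(block$data)) {
      read_fecundity_table(block$data)
    } else {
      simulate_fecundity(.design_from_block(block, seed))
    }
    arms <- split(tab, tab$arm)
    list(
      type = type, n_rows = nrow(tab),
      egg_ratio = relative_ratio(
        arms$mated_to_naive$eggs_24h, arms$mated_to_experienced$eggs_24h,
        seed = seed
      ),
      progeny_ratio = relative_ratio(
        arms$mated_to_naive$progeny, arms$mated_to_experienced$progeny,
        seed = seed
      )
    )
  } else if (type == "paternity") {
    tab <- if (!is.null(block$data)) {
      read_cross_records(block$data)
    } else {
      simulate_paternity(.design_from_block(block, seed))
    }
    list(type = type, n_rows = nrow(tab), result = paternity_share(tab))
  } else if (type == "calexa") {
    tab <- simulate_calexa(.design_from_block(block, seed))
    tab$normalized <- normalize_fluorescence(tab$gfp, tab$autofluorescence)
    per_segment <- lapply(split(tab, tab$segment), function(seg) {
      compare_experiment(seg,
        metric = "normalized", group_col = "condition",
        ref_group = "naive", window = Inf, seed = seed
      )
    })
    list(type = type, n_rows = nrow(tab), result = per_segment)
  } else {
    rlang::abort(sprintf("Unknown experiment type '%s'.", type),
      class = "mateguard_validation_error"
    )
  }
}

.run_mvt_block <- function(block) {
  out <- list()
  if (!is.null(block$naive) && !is.null(block$experienced)) {
    naive <- do.call(guarding_params, block$naive)
    experienced <- do.call(guarding_params, block$experienced)
    out$prediction <- predict_smd(naive, experienced)
  }
  if (!is.null(block$sweep)) {
    sw <- block$sweep
    base_args <- if (!is.null(block$naive)) block$naive else list(alpha = 1, beta = 1, gamma = 1.5)
    base <- do.call(guarding_params, base_args)
    out$sweep <- parameter_sweep(
      base,
      which = sw$which,
      grid = seq(sw$from, sw$to, length.out = sw$steps)
    )
  }
  if (isTRUE(block$scenarios)) {
    out$scenarios <- smd_scenarios()
  }
  out
}

#' Run the full simulate-analyze-model pipeline
#'
#' Executes every experiment block of a configuration (generating synthetic
#' data or loading CSV inputs, then running the matching analysis) plus an
#' optional guarding-model block, with all randomness derived from the global
#' seed. A failing block records a structured error without aborting the
#' others.
#'
#' @param config A list (or the result of [read_run_config()]) with fields:
#'   `seed` (integer), `experiments` (list of blocks, each with `name`,
#'   `type` in `md_assay`/`fecundity`/`paternity`/`calexa`, and either a
#'   `design` list or a `data` CSV path, plus an optional `analysis` list),
#'   and optionally `mvt` (list with `naive`, `experienced`, `sweep`,
#'   `scenarios`).
#' @return An object of class `"report_bundle"`: list with `provenance`
#'   (seed, config hash, package version, timestamp), `experiments` (one
#'   entry or one recorded error per block) and `mvt`.
#' @export
run_pipeline <- function(config) {
  if (!is.list(config)) {
    rlang::abort("`config` must be a list.", class = "mateguard_validation_error")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  blocks <- config$experiments
  if (is.null(blocks)) blocks <- list()
  results <- list()
  for (i in seq_along(blocks)) {
    block <- blocks[[i]]
    nm <- if (!is.null(block$name)) block$name else sprintf("experiment_%d", i)
    results[[nm]] <- tryCatch(
      .run_block(block, seed = seed + i),
      error = function(e) list(error = conditionMessage(e), type = block$type)
    )
  }
  mvt <- if (!is.null(config$mvt)) {
    tryCatch(.run_mvt_block(config$mvt), error = function(e) list(error = conditionMessage(e)))
  } else {
    NULL
  }
  structure(
    list(
      provenance = list(
        seed = seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("mateguard")),
        timestamp = format(Sys.time(), tz = "UTC")
      ),
      experiments = results,
      mvt = mvt
    ),
    class = "report_bundle"
  )
}

#' A bundled demonstration configuration
#'
#' Mirrors the structure of a typical experimental series: an SMD-style
#' two-group mating-duration comparison, a four-arm exposure-time cohort
#' routed to Kruskal-Wallis/Dunn, fecundity and paternity blocks, and the
#' guarding-model scenario panel with a cost-rate sweep.
#'
#' @param seed Global seed for the run.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  exposure <- c(2, 6, 12, 24)
  groups <- tibble::tibble(
    genotype = "CS",
    condition = c("naive", rep("experienced", 4)),
    n = 36L,
    percent_reduction = c(NA, exposure_percent_reduction(exposure)),
    label = c("naive", sprintf("exposed_%dh", exposure))
  )
  list(
    seed = as.integer(seed),
    experiments = list(
      list(
        name = "smd_two_group", type = "md_assay",
        design = list(percent_reduction = 15),
        analysis = list(metric = "mating_duration_s", group_col = "condition")
      ),
      list(
        name = "exposure_time", type = "md_assay",
        design = list(groups = groups),
        analysis = list(metric = "mating_duration_s", group_col = "label", ref_group = "naive")
      ),
      list(
        name = "fecundity", type = "fecundity",
        design = list(
          n_females = 20,
          survival_multiplier = c(mated_to_naive = 1, mated_to_experienced = 0.7)
        )
      ),
      list(name = "paternity", type = "paternity", design = list()),
      list(name = "calexa", type = "calexa", design = list())
    ),
    mvt = list(
      naive = list(alpha = 1, beta = 1, gamma = 1.5),
      experienced = list(alpha = 1, beta = 1, gamma = 2.2),
      sweep = list(which = "gamma", from = 0.5, to = 3.5, steps = 61),
      scenarios = TRUE
    )
  )
}

# Recursively strip classes and drop bulky fields for JSON serialization.
.jsonable <- function(x) {
  if (inherits(x, "estimation_result")) {
    x$resample_distribution <- list(
      quantiles = as.list(stats::quantile(x$resample_distribution, c(.025, .25, .5, .75, .975))),
      sd = stats::sd(x$resample_distribution)
    )
  }
  if (is.data.frame(x)) {
    return(as.data.frame(x))
  }
  if (is.list(x)) {
    return(lapply(unclass(x), .jsonable))
  }
  x
}

#' Write / read a machine-readable pipeline report
#'
#' `write_report()` serializes a report bundle to JSON at full double
#' precision (bootstrap resample distributions are summarized by quantiles);
#' `read_report()` reads it back as a list. The JSON representation
#' round-trips losslessly.
#'
#' @param bundle A `"report_bundle"` from [run_pipeline()].
#' @param path Output (input) JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   report as a list.
#' @export
write_report <- function(bundle, path) {
  jsonlite::write_json(
    .jsonable(bundle), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE,
    force = TRUE
  )
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Report '%s' does not exist.", path),
      class = "mateguard_io_error"
    )
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a generated table as UTF-8 CSV
#'
#' @param table A tibble from one of the generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
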