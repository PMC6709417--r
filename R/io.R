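OBS_COLUMNS <- c("pair_id", "role", "time_days", "enrichment_mg_per_kg",
                 "dose_g", "MWT_kg", "BWT_start_kg", "BWT_end_kg",
                 "country", "assay")

#' Read a long-format observation table
#'
#' Delimited text (comma or tab inferred from the extension) with a
#' required header carrying the standard columns. Parsing is
#' locale-independent (decimal point, UTF-8). If a `baseline_mg_per_kg`
#' column is present it is subtracted from the enrichment on read;
#' otherwise enrichment is assumed already baseline-subtracted.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @return Observation tibble; schema violations raise errors naming the
#'   offending columns or rows.
#' @export
read_observations <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  x <- reader(path, show_col_types = FALSE, locale = readr::locale(decimal_mark = "."))
  missing <- setdiff(OBS_COLUMNS, names(x))
  if (length(missing)) {
    stop("observation table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("baseline_mg_per_kg" %in% names(x)) {
    x$enrichment_mg_per_kg <- x$enrichment_mg_per_kg - x$baseline_mg_per_kg
    x$baseline_mg_per_kg <- NULL
  }
  bad_role <- which(!x$role %in% c("mother", "infant"))
  if (length(bad_role)) {
    stop("invalid role at row(s): ", paste(utils::head(bad_role, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_time <- which(!is.finite(x$time_days) | x$time_days < 0)
  if (length(bad_time)) {
    stop("invalid time_days at row(s): ", paste(utils::head(bad_time, 5), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Write an observation (or any) tibble as delimited text
#'
#' @param x A tibble.
#' @param path Destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(x, path)
  invisible(path)
}

#' Run configuration for the full pipeline
#'
#' Bundles every downstream module's settings plus the global seed. All
#' per-stage randomness derives deterministically from `seed`. Unknown
#' arguments are rejected.
#'
#' @param cohort A [cohort_config()] (for simulation-driven runs).
#' @param prior Prior regime name for per-pair fits.
#' @param residual A [residual_model()].
#' @param classifier A [classifier_config()].
#' @param fraction_holdout Holdout fraction for the design-evaluation split.
#' @param designs Optional `design_set` restriction; `NULL` enumerates
#'   family-A designs of size 2 on the cohort grid.
#' @param n_chains,n_warmup,n_samples Sampler settings.
#' @param method `"population"` (hierarchical fits, default) or
#'   `"independent"` (isolated per-pair fits) for both the reference and
#'   the streamlined refits.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), prior = "mixed",
                       residual = residual_model(sigma1 = c(0.04, 0.08),
                                                 sigma2 = c(1.5, 3),
                                                 group = c("IRMS", "FTIR")),
                       classifier = classifier_config(),
                       fraction_holdout = 1 / 3, designs = NULL,
                       n_chains = 2, n_warmup = 1000, n_samples = 1000,
                       method = c("population", "independent"),
                       seed = 1L) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "run_config")
}

#' Simulate a cohort to files
#'
#' Generates a synthetic cohort and writes the observation table, the truth
#' table, and a manifest (seed, sizes, settings) as delimited text /
#' JSON under `dir`. Byte-identical given identical config and seed.
#'
#' @param config A [run_config()] (its `cohort` and `seed` are used).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written paths.
#' @export
simulate_to_files <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) {
    stop("simulate_to_files: output directory not writable: ", dir, call. = FALSE)
  }
  coh <- generate_cohort(config$cohort, seed = config$seed)
  paths <- list(
    observations = file.path(dir, "observations.csv"),
    truth = file.path(dir, "truth.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_table(coh$observations, paths$observations)
  write_table(coh$truth, paths$truth)
  manifest <- list(
    seed = config$seed,
    n_pairs = nrow(coh$truth),
    n_non_ebf = sum(coh$truth$true_class == "non-EBF"),
    n_observations = nrow(coh$observations),
    day_grid = config$cohort$day_grid,
    prior = config$prior
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Run the full streamlined-design workflow
#'
#' Executes the whole analysis on a cohort: split into model-building and
#' design-evaluation sets, fit the reference (full-design) model per pair,
#' exclude clearance outliers, classify every pair (the reference
#' classification, from un-imputed data), build the imputed balanced data
#' set, enumerate or accept candidate designs, evaluate each design by
#' bootstrap-refit-reclassify on both halves, and assemble the side-by-side
#' validation table.
#'
#' @param cohort A `dtm_cohort` (e.g. from [generate_cohort()]), or a list
#'   with an `observations` tibble and a per-pair `truth`-like tibble
#'   carrying `pair_id` and `country` for the split.
#' @param config A [run_config()].
#' @param progress Print per-stage messages.
#' @return A list of class `dtm_run`: `split`, `reference` (per-half
#'   classification tibbles), `outliers`, `validation`
#'   (design_validation tibble), `performance` (per-half
#'   design_performance), and timing per stage.
#' @export
run_full <- function(cohort, config = run_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  prior <- build_prior(config$prior)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    if (progress) {
      cat(sprintf("[%s] %.1fs\n", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    val
  }
  pairs <- dplyr::distinct(cohort$observations, .data$pair_id, .data$country)
  split <- stage("split", split_cohort(
    pairs, config$fraction_holdout, seed = derive_seed(config$seed, 11),
    calibration_country =
      if (!is.null(config$cohort$calibration_country) &&
          config$cohort$calibration_country %in% pairs$country)
        config$cohort$calibration_country else NULL))

  halves <- list(best = split$model_building$pair_id,
                 evaluation = split$design_evaluation$pair_id)
  grid <- sort(unique(cohort$observations$time_days))
  designs <- config$designs
  if (is.null(designs)) {
    designs <- enumerate_designs("A", grid = grid, size_min = 2, size_max = 2)
  }

  out <- list(split = split)
  perf <- list()
  refs <- list()
  for (ctx in names(halves)) {
    obs <- dplyr::filter(cohort$observations, .data$pair_id %in% halves[[ctx]])
    fit_seed <- derive_seed(config$seed, 20 + match(ctx, names(halves)))
    design_residual <- config$residual
    fits <- stage(paste0("fit-", ctx), if (config$method == "population") {
      popref <- fit_population(
        obs, prior = prior, residual = config$residual,
        n_chains = config$n_chains, n_warmup = config$n_warmup,
        n_samples = config$n_samples, seed = fit_seed)
      design_residual <- estimated_residual(popref)
      as_pair_fits(popref)
    } else {
      fit_pairs(obs, prior = prior, residual = config$residual,
                n_chains = config$n_chains, n_warmup = config$n_warmup,
                n_samples = config$n_samples, seed = fit_seed)
    })
    flt <- filter_outliers(fits)
    fits$fits <- fits$fits[flt$retained]
    reference <- stage(paste0("classify-", ctx), classify_pairs(
      fits, config$classifier, seed = derive_seed(config$seed, 30 + match(ctx, names(halves)))))
    obs_kept <- dplyr::filter(obs, .data$pair_id %in% flt$retained)
    imputed <- stage(paste0("impute-", ctx), impute_full(obs_kept, fits, grid = grid))
    perf[[ctx]] <- stage(paste0("designs-", ctx), evaluate_designs(
      designs, imputed, reference, prior = prior, residual = design_residual,
      config = config$classifier, n_chains = config$n_chains,
      n_warmup = config$n_warmup, n_samples = config$n_samples,
      method = config$method,
      seed = derive_seed(config$seed, 40 + match(ctx, names(halves)))))
    refs[[ctx]] <- reference
    if (ctx == "best") out$outliers <- flt$excluded
  }
  out$reference <- refs
  out$performance <- perf
  out$validation <- rank_and_validate(perf$best, perf$evaluation)
  class(out) <- "dtm_run"
  out
}

#' @export
print.dtm_run <- function(x, ...) {
  cat(sprintf("<dtm_run> %d + %d pairs; %d designs evaluated\n",
              nrow(x$split$model_building), nrow(x$split$design_evaluation),
              nrow(x$validation)))
  print(utils::head(tibble::as_tibble(unclass(x$validation)), 10))
  invisible(x)
}
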