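#' Evaluate one streamlined design against the reference classification
#'
#' The full streamlined-design pipeline for a single candidate schedule:
#' build the bootstrap streamlined data set from the imputed full data set,
#' refit the kinetic model to the streamlined data under the chosen prior
#' regime, classify each pair from its Rs posterior, and score the labels
#' against the reference classification (which is always computed from the
#' un-imputed full-design data). Pairs whose chains fail the Rhat stability
#' gate are excluded from the confusion counts and reported through
#' `stable_fraction`; a design on which every pair is unstable is returned
#' flagged as failed rather than raising an error.
#'
#' By default the refit is the hierarchical population model
#' ([fit_population()]): with one to three samples per pair the individual
#' clearances are only weakly identified on their own, and it is the
#' population model — with the regime's priors on the typical values and
#' between-subject SDs — that keeps the individual Rs posteriors tight
#' enough to classify. `method = "independent"` fits every pair in
#' isolation instead.
#'
#' @param design One row of a `design_set`.
#' @param imputed An [impute_full()] result.
#' @param reference A `dtm_classification` tibble from the reference
#'   (full, un-imputed) design.
#' @param prior Prior regime for the streamlined refits (default mixed).
#' @param residual A [residual_model()].
#' @param config A [classifier_config()].
#' @param n_chains,n_warmup,n_samples Sampler settings for the refits.
#' @param seed Integer seed (bootstrap and fits derive from it).
#' @param resample Passed to [bootstrap_streamlined()].
#' @param method `"population"` (hierarchical refit, default) or
#'   `"independent"` (per-pair refit).
#' @param covariates Covariate structure for the population refit.
#' @param estimate_sigma Re-estimate the residual SDs during the refit;
#'   by default they are held at the values in `residual` (normally the
#'   reference fit's estimates), since a streamlined design carries almost
#'   no information on the error model.
#' @param n_boot Number of bootstrap replicates of the streamlined data
#'   set. The default, 1, scores a single realisation; larger values
#'   report the median sensitivity/specificity (and mean stability) across
#'   replicates, damping bootstrap-composition noise.
#' @return One-row tibble of class `design_performance`: `design`,
#'   `family`, `size`, `sensitivity`, `specificity`, `stable_fraction`,
#'   `n_scored`, `failed`.
#' @export
evaluate_design <- function(design, imputed, reference,
                            prior = build_prior("mixed"),
                            residual = residual_model(),
                            config = classifier_config(),
                            n_chains = 3, n_warmup = 1000, n_samples = 1000,
                            seed = 1L, resample = TRUE,
                            method = c("population", "independent"),
                            covariates = default_covariates(),
                            estimate_sigma = FALSE, n_boot = 1) {
  method <- match.arg(method)
  if (n_boot > 1) {
    reps <- lapply(seq_len(n_boot), function(b) {
      evaluate_design(design, imputed, reference, prior = prior,
                      residual = residual, config = config,
                      n_chains = n_chains, n_warmup = n_warmup,
                      n_samples = n_samples,
                      seed = derive_seed(seed, 7000 + b), resample = resample,
                      method = method, covariates = covariates,
                      estimate_sigma = estimate_sigma, n_boot = 1)
    })
    reps <- dplyr::bind_rows(reps)
    out <- reps[1, ]
    out$sensitivity <- stats::median(reps$sensitivity, na.rm = TRUE)
    out$specificity <- stats::median(reps$specificity, na.rm = TRUE)
    out$stable_fraction <- mean(reps$stable_fraction)
    out$n_scored <- round(mean(reps$n_scored))
    out$failed <- all(reps$failed)
    return(out)
  }
  dsg <- design  # keep out of tibble()'s sequential scope below
  streamlined <- bootstrap_streamlined(imputed, design, seed = seed,
                                       resample = resample)
  fits <- if (method == "population") {
    pop <- fit_population(streamlined, prior = prior,
                          residual = pop_residual(residual),
                          covariates = covariates, n_chains = n_chains,
                          n_warmup = n_warmup, n_samples = n_samples,
                          estimate_sigma = estimate_sigma,
                          seed = derive_seed(seed, 1e6))
    as_pair_fits(pop)
  } else {
    fit_pairs(streamlined, prior = prior, residual = residual,
              n_chains = n_chains, n_warmup = n_warmup,
              n_samples = n_samples, seed = derive_seed(seed, 1e6))
  }
  cls <- classify_pairs(fits, config, seed = derive_seed(seed, 2e6))
  stable_fraction <- mean(cls$stable)
  link <- dplyr::distinct(streamlined, .data$pair_id, .data$source_pair_id)
  cls <- dplyr::left_join(cls, link, by = "pair_id")
  scored <- dplyr::filter(cls, .data$stable)
  out <- tibble::tibble(
    design = dsg$design, family = dsg$family, size = dsg$size,
    sensitivity = NA_real_, specificity = NA_real_,
    stable_fraction = stable_fraction, n_scored = nrow(scored),
    failed = nrow(scored) == 0
  )
  if (nrow(scored) > 0) {
    m <- scored |>
      dplyr::select(working_id = "pair_id", "source_pair_id", "label") |>
      dplyr::left_join(
        dplyr::select(reference, source_pair_id = "pair_id", ref_label = "label"),
        by = "source_pair_id"
      )
    conf <- score_against_reference(
      test = tibble::tibble(pair_id = m$working_id, label = m$label),
      reference = tibble::tibble(pair_id = m$working_id, label = m$ref_label)
    )
    out$sensitivity <- conf$sensitivity
    out$specificity <- conf$specificity
  }
  class(out) <- c("design_performance", class(out))
  out
}

#' Evaluate a list of designs
#'
#' Maps [evaluate_design()] over a `design_set`; results are independent of
#' execution order because every design derives its own seed from the
#' global one.
#'
#' @param designs A `design_set` tibble.
#' @inheritParams evaluate_design
#' @param progress Print one line per design.
#' @return `design_performance` tibble, one row per design.
#' @export
evaluate_designs <- function(designs, imputed, reference,
                             prior = build_prior("mixed"),
                             residual = residual_model(),
                             config = classifier_config(),
                             n_chains = 3, n_warmup = 1000, n_samples = 1000,
                             seed = 1L, resample = TRUE,
                             method = c("population", "independent"),
                             covariates = default_covariates(),
                             estimate_sigma = FALSE, progress = FALSE) {
  method <- match.arg(method)
  rows <- purrr::map_dfr(seq_len(nrow(designs)), function(i) {
    perf <- evaluate_design(designs[i, ], imputed, reference,
                            prior = prior, residual = residual, config = config,
                            n_chains = n_chains, n_warmup = n_warmup,
                            n_samples = n_samples,
                            seed = derive_seed(seed, i), resample = resample,
                            method = method, covariates = covariates,
                            estimate_sigma = estimate_sigma)
    if (progress) {
      cat(sprintf("design %-12s sens %.2f spec %.2f stable %.2f\n",
                  perf$design, perf$sensitivity, perf$specificity,
                  perf$stable_fraction))
    }
    perf
  })
  class(rows) <- c("design_performance", class(rows))
  rows
}

#' Side-by-side validation table with Diff columns
#'
#' Joins the operating characteristics of the candidate designs on the
#' model-building ("best") data with those on the held-out design
#' evaluation data, and reports `diff = evaluation - best` for both rates.
#' Rows are sorted (by default) by descending `min(sensitivity,
#' specificity)` in the model-building context.
#'
#' @param best,evaluation `design_performance` tibbles sharing a design list.
#' @param sort Sort the output by model-building performance.
#' @return Tibble of class `design_validation` with columns `design`,
#'   `family`, `size`, `sens_best`, `sens_eval`, `diff_sensitivity`,
#'   `spec_best`, `spec_eval`, `diff_specificity`, `stable_fraction_best`,
#'   `stable_fraction_eval`.
#' @export
rank_and_validate <- function(best, evaluation, sort = TRUE) {
  if (!setequal(best$design, evaluation$design)) {
    stop("rank_and_validate: the two contexts must share the design list",
         call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(best, "design", "family", "size",
                  sens_best = "sensitivity", spec_best = "specificity",
                  stable_fraction_best = "stable_fraction"),
    dplyr::select(evaluation, "design",
                  sens_eval = "sensitivity", spec_eval = "specificity",
                  stable_fraction_eval = "stable_fraction"),
    by = "design"
  ) |>
    dplyr::mutate(
      diff_sensitivity = .data$sens_eval - .data$sens_best,
      diff_specificity = .data$spec_eval - .data$spec_best
    ) |>
    dplyr::relocate("design", "family", "size", "sens_best", "sens_eval",
                    "diff_sensitivity", "spec_best", "spec_eval",
                    "diff_specificity")
  if (sort) {
    out <- dplyr::arrange(out, dplyr::desc(pmin(.data$sens_best, .data$spec_best)))
  }
  class(out) <- c("design_validation", class(out))
  out
}


## A grouped residual model for the population refit: reuse the grouped
## sigmas if present, else duplicate the global pair across assays.
pop_residual <- function(residual) {
  if (!is.null(residual$group)) return(residual)
  residual_model(residual$kind,
                 sigma1 = rep(residual$sigma1[1], 2),
                 sigma2 = rep(max(residual$sigma2[1], 1e-3), 2),
                 group = c("IRMS", "FTIR"))
}
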