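#' Classifier configuration
#'
#' Settings for the posterior-probability classifier of exclusive
#' breastfeeding: a pair is labelled non-EBF when the posterior probability
#' that its non-milk water intake `Rs` exceeds the cutoff is above the
#' probability threshold,
#' `Pr(Rs > 86.6 g/day) > 0.9 => non-EBF, else EBF`.
#' The comparator at the threshold defaults to strict `>` (so `Pr = 0.9`
#' exactly yields EBF); set `strict = FALSE` for the `>=` reading.
#'
#' @param rs_cutoff Rs cutoff in g/day (default 86.6).
#' @param prob_threshold Posterior-probability threshold in (0, 1)
#'   (default 0.9).
#' @param strict Use strict `>` at the probability threshold.
#' @param ra_fraction,rg_water_fraction,study_duration Ancillary-rate
#'   settings forwarded to the Rs computation.
#' @param ra_cv Coefficient of variation of the sampled atmospheric influx.
#' @param rg_sd Absolute SD (g/day) of the sampled growth retention.
#' @param turnover_per_kg_water Infant water turnover per kg body water
#'   (1/day) used to size the atmospheric influx independently of the
#'   fitted clearances.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(rs_cutoff = 86.6, prob_threshold = 0.9,
                              strict = TRUE,
                              ra_fraction = 0.063, rg_water_fraction = 0.73,
                              study_duration = 14, ra_cv = 0.25, rg_sd = 15,
                              turnover_per_kg_water = 0.25) {
  if (rs_cutoff <= 0) stop("classifier_config: rs_cutoff must be positive", call. = FALSE)
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop("classifier_config: prob_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "classifier_config")
}

#' Posterior draws of the non-milk water intake Rs
#'
#' Applies the Rs mass balance to every joint posterior draw of the kinetic
#' parameters, pairing each with an independently sampled realisation of
#' the design-independent ancillary rates (atmospheric influx `R_a`, growth
#' retention `R_g`). Sampling the ancillaries draw-by-draw propagates their
#' dispersion into the Rs posterior, which sets the lower bound on its
#' spread regardless of the sampling design.
#'
#' `R_a` is drawn log-normally with CV `ra_cv` around
#' `ra_fraction * 1000 * turnover`, where turnover is approximated from the
#' infant's size (`turnover_per_kg_water * V_b`) so that the ancillary draw
#' is independent of the design-dependent parameter draws; `R_g` is drawn
#' normally around the water content of the observed weight change with SD
#' `rg_sd`.
#'
#' @param fit A `dtm_fit` object.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return Numeric vector of Rs draws (g/day), one per parameter draw.
#' @export
rs_draws <- function(fit, config = classifier_config(), seed = 1L) {
  stopifnot(inherits(fit, "dtm_fit"))
  draws <- fit$draws
  n <- nrow(draws)
  set.seed(seed)
  ra_med <- config$ra_fraction * 1000 * config$turnover_per_kg_water * fit$pair$V_b
  sdlog <- sqrt(log(1 + config$ra_cv^2))
  R_a <- ra_med * exp(stats::rnorm(n, 0, sdlog))
  rg_mean <- config$rg_water_fraction *
    (fit$pair$BWT_end_kg - fit$pair$BWT_start_kg) / config$study_duration * 1000
  R_g <- stats::rnorm(n, rg_mean, config$rg_sd)
  1000 * (draws$CL_bo - draws$CL_mb) + R_g - R_a
}

#' Classify one pair from its Rs posterior
#'
#' @param rs Numeric vector of Rs posterior draws (g/day).
#' @param config A [classifier_config()].
#' @param pair_id Optional id carried into the result.
#' @return One-row tibble of class `dtm_classification`: `pair_id`,
#'   `pr_non_ebf` (fraction of draws strictly above the cutoff), `label`,
#'   `rs_mean`, `rs_sd`.
#' @export
#' @examples
#' classify_pair(rnorm(1000, 150, 30))
classify_pair <- function(rs, config = classifier_config(), pair_id = NA_character_) {
  if (length(rs) < 1) stop("classify_pair: no Rs draws supplied", call. = FALSE)
  pr <- mean(rs > config$rs_cutoff)
  non_ebf <- if (config$strict) pr > config$prob_threshold else pr >= config$prob_threshold
  out <- tibble::tibble(
    pair_id = pair_id, pr_non_ebf = pr,
    label = ifelse(non_ebf, "non-EBF", "EBF"),
    rs_mean = mean(rs), rs_sd = stats::sd(rs)
  )
  class(out) <- c("dtm_classification", class(out))
  out
}

#' Classify every fitted pair
#'
#' @param fits A `dtm_fits` object.
#' @param config A [classifier_config()].
#' @param seed Integer seed (per-pair seeds derived deterministically).
#' @param only_stable Drop pairs failing the Rhat stability gate before
#'   classification.
#' @return Tibble of class `dtm_classification` with one row per pair and a
#'   `stable` column.
#' @export
classify_pairs <- function(fits, config = classifier_config(), seed = 1L,
                           only_stable = FALSE) {
  stopifnot(inherits(fits, "dtm_fits"))
  rows <- purrr::imap_dfr(fits$fits, function(f, id) {
    cls <- classify_pair(rs_draws(f, config, seed = derive_seed(seed, match(id, names(fits$fits)))),
                         config, pair_id = f$pair$pair_id)
    dplyr::mutate(cls, stable = f$stable)
  })
  if (only_stable) rows <- dplyr::filter(rows, .data$stable)
  class(rows) <- c("dtm_classification", class(rows))
  rows
}

#' Score a test classification against a reference
#'
#' Confusion counts and operating characteristics with non-EBF as the
#' positive class: sensitivity = TP / all reference positives,
#' specificity = TN / all reference negatives. When a denominator is empty
#' the corresponding rate is returned as `NaN` with a warning.
#'
#' @param test,reference Tibbles with `pair_id` and `label`
#'   (`"EBF"`/`"non-EBF"`); the pair sets must match.
#' @return One-row tibble of class `confusion_summary`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `n`.
#' @export
score_against_reference <- function(test, reference) {
  missing_in_test <- setdiff(reference$pair_id, test$pair_id)
  missing_in_ref <- setdiff(test$pair_id, reference$pair_id)
  if (length(missing_in_test) || length(missing_in_ref)) {
    stop("score_against_reference: pair sets differ; missing in test: [",
         paste(utils::head(missing_in_test, 5), collapse = ", "),
         "]; missing in reference: [",
         paste(utils::head(missing_in_ref, 5), collapse = ", "), "]",
         call. = FALSE)
  }
  m <- dplyr::inner_join(
    dplyr::select(test, "pair_id", test_label = "label"),
    dplyr::select(reference, "pair_id", ref_label = "label"),
    by = "pair_id"
  )
  tp <- sum(m$test_label == "non-EBF" & m$ref_label == "non-EBF")
  fp <- sum(m$test_label == "non-EBF" & m$ref_label == "EBF")
  tn <- sum(m$test_label == "EBF" & m$ref_label == "EBF")
  fn <- sum(m$test_label == "EBF" & m$ref_label == "non-EBF")
  if (tp + fn == 0) warning("no reference non-EBF pairs; sensitivity undefined", call. = FALSE)
  if (tn + fp == 0) warning("no reference EBF pairs; specificity undefined", call. = FALSE)
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
    n = nrow(m)
  )
  class(out) <- c("confusion_summary", class(out))
  out
}
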