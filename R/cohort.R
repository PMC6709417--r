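DEFAULT_GRID <- c(1:9, 13, 14)
RS_CUTOFF <- 86.6

#' Configuration of a synthetic DTM cohort
#'
#' Describes a simulated multi-country dose-to-mother study: covariate
#' distributions matched to typical field demographics (median mother
#' weight 57 kg, infant ~6.3 kg and ~3.4 months at enrolment, doses 6–60 g
#' depending on assay), population kinetic parameters with covariate
#' effects and log-normal between-subject variability (BSV), assay-specific
#' combined residual noise, a known fraction of non-EBF pairs, and the
#' post-dose sampling grid.
#'
#' Covariate models follow the allometric log-linear form
#' `ln(theta_i) = ln(theta1) + theta2 * ln(cov_i / cov_median)`:
#' mother weight scales her volume of distribution
#' (`ln V_m = 3.54 + 0.46 ln(MWT/70)`) and infant weight scales the
#' infant's water clearance (`ln CL_bo = -0.16 + 0.55 ln(BWT/5)`).
#'
#' Non-EBF pairs are simulated by a breastmilk-clearance deficit: the
#' supplemented infant draws less water through milk, and the pair's true
#' non-milk intake `Rs` lands a configurable margin above the 86.6 g/day
#' cutoff (margin drawn log-normally). The alternative mechanism
#' `"clbo_inflate"` instead raises the infant's total clearance.
#'
#' @param n_pairs Number of mother-infant pairs.
#' @param fraction_non_ebf Expected fraction of truly non-EBF pairs.
#' @param mwt_median,mwt_sdlog Mother-weight log-normal (median kg, sdlog).
#' @param bwt_median,bwt_sdlog Infant start-weight log-normal.
#' @param weight_gain_mean,weight_gain_sd Infant weight gain over the study
#'   (kg), normal.
#' @param age_median,age_sdlog Infant age (months), log-normal.
#' @param p_irms Probability a pair is assayed by IRMS (rest FTIR).
#' @param dose_irms,dose_ftir Candidate doses (g) per assay; one is sampled
#'   uniformly per pair. IRMS studies use < 30 g, FTIR >= 30 g.
#' @param theta Named list of population covariate models; see defaults.
#' @param bsv Named numeric BSV SDs on the log scale for `k_mm`, `V_m`,
#'   `CL_bo` (the milk clearance inherits its dispersion from the Rs target
#'   and `CL_bo`).
#' @param sigma1,sigma2 Named numeric residual SDs per assay
#'   (`IRMS`, `FTIR`): proportional and additive components.
#' @param rs_ebf_mean,rs_ebf_sd True-Rs distribution for EBF pairs (g/day,
#'   normal, clamped below the cutoff).
#' @param rs_margin_meanlog,rs_margin_sdlog Log-normal margin (g/day) by
#'   which non-EBF true Rs exceeds the cutoff.
#' @param non_ebf_mechanism `"clmb_deficit"` (default) or `"clbo_inflate"`.
#' @param day_grid Post-dose sampling days.
#' @param p_missing Per-day probability a scheduled record is missing
#'   (missing completely at random); scalar or one per grid day.
#' @param countries,country_probs Country labels and sampling weights.
#' @param calibration_country Label whose pairs always stay in the
#'   model-building half when splitting (the closely controlled
#'   calibration study); see [split_cohort()].
#' @param study_duration Days between the infant weighings.
#' @param water_fraction,ra_fraction,rg_water_fraction Forwarded to
#'   [infant_water_volume()] and [default_ancillary()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 100,
                          fraction_non_ebf = 0.33,
                          mwt_median = 57, mwt_sdlog = 0.18,
                          bwt_median = 6.3, bwt_sdlog = 0.21,
                          weight_gain_mean = 0.2, weight_gain_sd = 0.08,
                          age_median = 3.4, age_sdlog = 0.45,
                          p_irms = 0.33,
                          dose_irms = c(6, 10, 15, 20, 25),
                          dose_ftir = c(30, 30, 30, 40, 50, 60),
                          theta = list(
                            ln_k_mm = list(intercept = -2.18),
                            ln_V_m = list(intercept = 3.54, slope = 0.46,
                                          covariate = "MWT_kg", median = 70),
                            ln_CL_bo = list(intercept = -0.16, slope = 0.55,
                                            covariate = "BWT_kg", median = 5)
                          ),
                          bsv = c(k_mm = 0.18, V_m = 0.15, CL_bo = 0.15),
                          sigma1 = c(IRMS = 0.04, FTIR = 0.08),
                          sigma2 = c(IRMS = 1.5, FTIR = 3),
                          rs_ebf_mean = 15, rs_ebf_sd = 20,
                          rs_margin_meanlog = log(150), rs_margin_sdlog = 0.5,
                          non_ebf_mechanism = c("clmb_deficit", "clbo_inflate"),
                          day_grid = DEFAULT_GRID,
                          p_missing = 0,
                          countries = c("South Africa", "Thailand", "Kenya",
                                        "Indonesia", "Other"),
                          country_probs = c(0.16, 0.22, 0.24, 0.15, 0.23),
                          calibration_country = "Indonesia",
                          study_duration = 14,
                          water_fraction = 0.60,
                          ra_fraction = 0.063,
                          rg_water_fraction = 0.73) {
  non_ebf_mechanism <- match.arg(non_ebf_mechanism)
  cfg <- as.list(environment())
  if (cfg$n_pairs < 1) stop("cohort_config: n_pairs must be >= 1", call. = FALSE)
  if (cfg$fraction_non_ebf < 0 || cfg$fraction_non_ebf > 1) {
    stop("cohort_config: fraction_non_ebf must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$p_missing < 0) || any(cfg$p_missing > 1)) {
    stop("cohort_config: p_missing must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(cfg$day_grid) <= 0) || any(cfg$day_grid <= 0)) {
    stop("cohort_config: day_grid must be strictly increasing positive days",
         call. = FALSE)
  }
  if (cfg$fraction_non_ebf > 0 && cfg$n_pairs == 0) {
    stop("cohort_config: cannot place non-EBF pairs in an empty cohort", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

eval_covariate_model <- function(model, covariates) {
  mu <- rep(model$intercept, nrow(covariates))
  if (!is.null(model$covariate)) {
    mu <- mu + model$slope * log(covariates[[model$covariate]] / model$median)
  }
  mu
}

#' Generate a synthetic mother-infant cohort
#'
#' Draws covariates, individual kinetic parameters, true EBF status, and
#' noisy enrichment observations on the configured sampling grid. The
#' result carries full simulation truth so downstream classification can be
#' validated against known labels.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the draw is reproducible given (config, seed).
#' @return A list of class `dtm_cohort` with elements
#'   `observations` (long tibble: `pair_id`, `role`, `time_days`,
#'   `enrichment_mg_per_kg`, `dose_g`, `MWT_kg`, `BWT_start_kg`,
#'   `BWT_end_kg`, `country`, `assay`) and
#'   `truth` (one row per pair with covariates, true kinetic parameters,
#'   `R_a`, `R_g`, `true_rs`, `true_class`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_pairs = 4), seed = 1)
#' dplyr::count(coh$observations, pair_id)
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_pairs

  mwt <- config$mwt_median * exp(stats::rnorm(n, 0, config$mwt_sdlog))
  bwt_start <- config$bwt_median * exp(stats::rnorm(n, 0, config$bwt_sdlog))
  gain <- stats::rnorm(n, config$weight_gain_mean, config$weight_gain_sd)
  bwt_end <- pmax(bwt_start + gain, 0.5 * bwt_start)
  age <- config$age_median * exp(stats::rnorm(n, 0, config$age_sdlog))
  assay <- ifelse(stats::runif(n) < config$p_irms, "IRMS", "FTIR")
  dose <- ifelse(assay == "IRMS",
                 sample(config$dose_irms, n, replace = TRUE),
                 sample(config$dose_ftir, n, replace = TRUE))
  country <- sample(config$countries, n, replace = TRUE, prob = config$country_probs)
  bwt_ref <- (bwt_start + bwt_end) / 2

  covariates <- tibble::tibble(MWT_kg = mwt, BWT_kg = bwt_ref)
  ln_k_mm <- eval_covariate_model(config$theta$ln_k_mm, covariates) +
    stats::rnorm(n, 0, config$bsv[["k_mm"]])
  ln_V_m <- eval_covariate_model(config$theta$ln_V_m, covariates) +
    stats::rnorm(n, 0, config$bsv[["V_m"]])
  ln_CL_bo <- eval_covariate_model(config$theta$ln_CL_bo, covariates) +
    stats::rnorm(n, 0, config$bsv[["CL_bo"]])
  k_mm <- exp(ln_k_mm)
  V_m <- exp(ln_V_m)
  CL_bo <- exp(ln_CL_bo)
  V_b <- infant_water_volume(bwt_start, bwt_end, config$water_fraction)

  ## ancillary rates (deterministic components used as simulation truth)
  R_a <- config$ra_fraction * 1000 * CL_bo
  R_g <- config$rg_water_fraction * (bwt_end - bwt_start) / config$study_duration * 1000

  ## true class and target Rs
  non_ebf <- stats::runif(n) < config$fraction_non_ebf
  rs_target <- stats::rnorm(n, config$rs_ebf_mean, config$rs_ebf_sd)
  rs_target <- pmin(rs_target, RS_CUTOFF - 20)  # EBF truth stays clear of the cutoff
  margin <- stats::rlnorm(n, config$rs_margin_meanlog, config$rs_margin_sdlog)
  rs_target[non_ebf] <- RS_CUTOFF + margin[non_ebf]

  ## solve the water balance for the milk clearance (or inflate CL_bo)
  if (config$non_ebf_mechanism == "clmb_deficit") {
    CL_mb <- CL_bo + (R_g - R_a - rs_target) / 1000
  } else {
    ## EBF-level milk flow first, then extra turnover for supplemented infants
    CL_mb <- CL_bo + (R_g - R_a - pmin(rs_target, RS_CUTOFF - 20)) / 1000
    extra <- pmax(rs_target - pmin(rs_target, RS_CUTOFF - 20), 0) / 1000
    CL_bo <- CL_bo + extra
  }
  ## heavily supplemented infants keep a token milk flow; the recomputed
  ## true_rs below keeps truth and class label consistent
  CL_mb <- pmax(CL_mb, 0.05 * CL_bo)
  true_rs <- 1000 * (CL_bo - CL_mb) + R_g - R_a

  truth <- tibble::tibble(
    pair_id = sprintf("P%04d", seq_len(n)),
    dose_g = dose, MWT_kg = mwt,
    BWT_start_kg = bwt_start, BWT_end_kg = bwt_end,
    infant_age_mo = age, country = country, assay = assay,
    k_mm = k_mm, V_m = V_m, CL_mb = CL_mb, CL_bo = CL_bo, V_b = V_b,
    R_a = R_a, R_g = R_g, true_rs = true_rs,
    true_class = ifelse(true_rs > RS_CUTOFF, "non-EBF", "EBF")
  )

  grid <- config$day_grid
  obs <- tidyr::expand_grid(
    pair_id = truth$pair_id,
    role = c("mother", "infant"),
    time_days = grid
  )
  obs <- dplyr::left_join(obs, truth, by = "pair_id")
  block <- 2L * length(grid)  # rows per pair (both roles x grid)
  f <- numeric(nrow(obs))
  for (i in seq_len(n)) {
    idx <- ((i - 1L) * block + 1L):(i * block)
    p <- kinetic_params(k_mm[i], V_m[i], CL_mb[i], CL_bo[i], V_b[i])
    f[idx] <- predict_enrichment(dose[i], p, obs$time_days[idx], obs$role[idx])
  }
  s1 <- config$sigma1[obs$assay]
  s2 <- config$sigma2[obs$assay]
  noise_sd <- sqrt(f^2 * s1^2 + s2^2)
  y <- f + stats::rnorm(nrow(obs), 0, noise_sd)

  observations <- tibble::tibble(
    pair_id = obs$pair_id, role = obs$role, time_days = obs$time_days,
    enrichment_mg_per_kg = y,
    dose_g = obs$dose_g, MWT_kg = obs$MWT_kg,
    BWT_start_kg = obs$BWT_start_kg, BWT_end_kg = obs$BWT_end_kg,
    country = obs$country, assay = obs$assay
  )

  structure(list(observations = observations, truth = truth, config = config,
                 seed = seed),
            class = "dtm_cohort")
}

#' @export
print.dtm_cohort <- function(x, ...) {
  n_non <- sum(x$truth$true_class == "non-EBF")
  cat(sprintf("<dtm_cohort> %d pairs (%d non-EBF), %d observations, grid {%s}\n",
              nrow(x$truth), n_non, nrow(x$observations),
              paste(x$config$day_grid, collapse = ",")))
  invisible(x)
}

#' Drop records missing completely at random
#'
#' Each post-dose record is dropped independently with its day's
#' probability, emulating field-study non-attendance. Pre-dose baseline
#' handling is untouched (synthetic observations are already
#' baseline-subtracted and carry no day-0 rows).
#'
#' @param observations Long observation tibble (see [generate_cohort()]).
#' @param p_missing Scalar, or named/numeric vector giving a probability per
#'   distinct day in the data (recycled in day order).
#' @param seed Integer seed.
#' @return The observation tibble with rows removed.
#' @export
apply_missingness <- function(observations, p_missing, seed = 1L) {
  days <- sort(unique(observations$time_days))
  if (length(p_missing) == 1L) p_missing <- rep(p_missing, length(days))
  if (length(p_missing) != length(days)) {
    stop("apply_missingness: p_missing must be scalar or one per distinct day",
         call. = FALSE)
  }
  if (any(p_missing < 0 | p_missing > 1)) {
    stop("apply_missingness: probabilities must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  p <- p_missing[match(observations$time_days, days)]
  keep <- stats::runif(nrow(observations)) >= p
  observations[keep, , drop = FALSE]
}

#' Split a cohort into model-building and design-evaluation sets
#'
#' Pair-level, country-stratified random split. Pairs from the calibration
#' country (a closely controlled study, if `calibration_country` is set)
#' always remain in the model-building set; the holdout fraction applies to
#' the field pairs within each country.
#'
#' @param truth Truth tibble (or any per-pair tibble with `pair_id` and
#'   `country`).
#' @param fraction_holdout Fraction of eligible pairs held out for design
#'   evaluation, in (0, 1).
#' @param seed Integer seed.
#' @param calibration_country Country label exempt from holdout (`NULL` for
#'   none).
#' @return List with tibbles `model_building` and `design_evaluation`;
#'   disjoint and exhaustive over input pairs.
#' @export
split_cohort <- function(truth, fraction_holdout = 1 / 3, seed = 1L,
                         calibration_country = "Indonesia") {
  if (nrow(truth) < 2) stop("split_cohort: need at least 2 pairs", call. = FALSE)
  if (fraction_holdout <= 0 || fraction_holdout >= 1) {
    stop("split_cohort: fraction_holdout must lie strictly in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  eligible <- truth
  if (!is.null(calibration_country)) {
    eligible <- dplyr::filter(truth, .data$country != calibration_country)
  }
  holdout_ids <- eligible |>
    dplyr::group_by(.data$country) |>
    dplyr::group_map(function(df, key) {
      k <- floor(nrow(df) * fraction_holdout + 0.5)  # round half up
      if (k == 0) return(character(0))
      sample(df$pair_id, k)
    }) |>
    unlist()
  list(
    model_building = dplyr::filter(truth, !(.data$pair_id %in% holdout_ids)),
    design_evaluation = dplyr::filter(truth, .data$pair_id %in% holdout_ids)
  )
}
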