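RHAT_GATE <- 1.05

#' Potential scale reduction factor (Rhat)
#'
#' Classic multi-chain Gelman-Rubin diagnostic: the square root of the
#' ratio of the pooled-variance estimate to the mean within-chain variance.
#' Values near 1 indicate the chains agree; the package's stability gate is
#' `Rhat < 1.05` on every parameter. Chains that are numerically constant
#' return exactly 1.
#'
#' @param x Numeric matrix, iterations x chains.
#' @return A single Rhat value.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x)
  n <- nrow(x)
  if (m < 2) stop("rhat needs at least 2 chains", call. = FALSE)
  chain_means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(chain_means)
  if (!is.finite(W) || W <= .Machine$double.eps * max(1, mean(abs(x)))^2) {
    return(1)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

## Heuristic, chain-jittered starting values on the log scale.
pair_inits <- function(obs, prior, dose, Vb, mwt, n_chains, jitter = 0.4,
                       bounds = param_bounds()) {
  pm <- individual_prior(prior)
  init <- pm$mean
  names(init) <- LOG_PARAM_NAMES
  diffuse <- pm$sd > 10
  mother <- obs[obs$role == "mother", , drop = FALSE]
  if (diffuse[2]) {  # ln V_m from the earliest mother sample, else from MWT
    if (nrow(mother) > 0) {
      i <- which.min(mother$time_days)
      y0 <- max(mother$enrichment_mg_per_kg[i], 1)
      init[2] <- log(dose * 1000 / y0)
    } else {
      init[2] <- log(0.58 * mwt)
    }
  }
  if (diffuse[1]) {  # ln k_mm from the mother washout slope, else 6-day half-life
    if (nrow(mother) >= 2) {
      fit <- stats::coef(stats::lm(log(pmax(mother$enrichment_mg_per_kg, 1)) ~
                                     mother$time_days))
      sl <- -fit[2]
      init[1] <- log(ifelse(is.finite(sl) && sl > 0.01, sl, 0.113))
    } else {
      init[1] <- log(0.113)
    }
  }
  if (diffuse[4]) init[4] <- log(0.25 * Vb)
  if (diffuse[3]) init[3] <- log(0.9 * exp(init[4]))
  init <- pmin(pmax(init, bounds$lower + 0.2), bounds$upper - 0.2)
  t(vapply(seq_len(n_chains), function(c) {
    pmin(pmax(init + stats::rnorm(4, 0, jitter), bounds$lower + 0.05),
         bounds$upper - 0.05)
  }, numeric(4)))
}

#' Fit the kinetic model to one mother-infant pair
#'
#' Samples the joint posterior of the four individual log-scale kinetic
#' parameters given the pair's enrichment series, using adaptive-covariance
#' random-walk Metropolis with multiple chains. The residual SDs are held
#' fixed at the values in `residual` (typically population estimates);
#' per-pair data are far too sparse to inform them.
#'
#' @param pair_obs Long observation tibble for a single pair (both roles),
#'   with the standard columns (see [generate_cohort()]).
#' @param prior A [build_prior()] regime (default mixed).
#' @param residual A [residual_model()]; assay-grouped sigmas are resolved
#'   via the pair's `assay` column.
#' @param n_chains Number of chains (>= 2; default 3).
#' @param n_warmup,n_samples Warmup and kept iterations per chain.
#' @param seed Integer seed.
#' @param water_fraction Infant body-water fraction used to derive `V_b`.
#' @param bounds Physiological truncation of the parameter support, see
#'   [param_bounds()].
#' @return An object of class `dtm_fit`: a list with `draws` (tibble:
#'   `chain`, `draw`, `k_mm`, `V_m`, `CL_mb`, `CL_bo` on the natural
#'   scale), `diagnostics` (tibble: `parameter`, `rhat`), `stable` (all
#'   Rhat below the 1.05 gate), `pair` (metadata row), and sampler info.
#' @export
fit_pair <- function(pair_obs, prior = build_prior("mixed"),
                     residual = residual_model(),
                     n_chains = 3, n_warmup = 1000, n_samples = 1000,
                     seed = 1L, water_fraction = 0.60,
                     bounds = param_bounds()) {
  if (nrow(pair_obs) == 0) {
    stop("fit_pair: pair has zero post-dose observations", call. = FALSE)
  }
  if (length(unique(pair_obs$pair_id)) != 1L) {
    stop("fit_pair: expected observations from exactly one pair", call. = FALSE)
  }
  if (n_chains < 2) {
    stop("fit_pair: stability assessment requires at least 2 chains", call. = FALSE)
  }
  meta <- pair_obs[1, c("pair_id", "dose_g", "MWT_kg", "BWT_start_kg",
                        "BWT_end_kg", "assay")]
  Vb <- infant_water_volume(meta$BWT_start_kg, meta$BWT_end_kg, water_fraction)
  sig <- residual_sigmas(residual, meta$assay)
  pm <- individual_prior(prior)

  set.seed(seed)
  init <- pair_inits(pair_obs, prior, meta$dose_g, Vb, meta$MWT_kg, n_chains,
                     bounds = bounds)
  res <- cpp_fit_pair(
    t = pair_obs$time_days, y = pair_obs$enrichment_mg_per_kg,
    role = as.integer(pair_obs$role == "infant"),
    dose = meta$dose_g, Vb = Vb,
    prior_mean = pm$mean, prior_sd = pm$sd,
    sigma1 = sig[1], sigma2 = sig[2],
    combined = residual$kind == "combined",
    init = init, n_warmup = as.integer(n_warmup), n_keep = as.integer(n_samples),
    lower = bounds$lower, upper = bounds$upper
  )
  draws_log <- res$draws
  colnames(draws_log) <- LOG_PARAM_NAMES
  rhats <- vapply(seq_len(4), function(j) {
    rhat(matrix(draws_log[, j], nrow = n_samples, ncol = n_chains))
  }, numeric(1))
  diagnostics <- tibble::tibble(parameter = PARAM_NAMES, rhat = rhats)
  draws <- tibble::tibble(
    chain = res$chain,
    draw = rep(seq_len(n_samples), times = n_chains),
    k_mm = exp(draws_log[, 1]), V_m = exp(draws_log[, 2]),
    CL_mb = exp(draws_log[, 3]), CL_bo = exp(draws_log[, 4])
  )
  structure(
    list(draws = draws, diagnostics = diagnostics,
         stable = all(is.finite(rhats)) && all(rhats < RHAT_GATE),
         pair = tibble::tibble(meta, V_b = Vb),
         accept_rate = as.numeric(res$accept_rate),
         prior = attr(prior, "name"), residual = residual,
         n_chains = n_chains, n_warmup = n_warmup, n_samples = n_samples,
         seed = seed),
    class = "dtm_fit"
  )
}

#' @export
print.dtm_fit <- function(x, ...) {
  cat(sprintf("<dtm_fit> pair %s: %d chains x %d draws, prior '%s', %s\n",
              x$pair$pair_id, x$n_chains, x$n_samples, x$prior,
              if (x$stable) "stable" else
                sprintf("UNSTABLE (max Rhat %.3f)", max(x$diagnostics$rhat))))
  print(summarise_draws(x$draws))
  invisible(x)
}

summarise_draws <- function(draws) {
  draws |>
    tidyr::pivot_longer(dplyr::all_of(PARAM_NAMES),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     q2.5 = stats::quantile(.data$value, 0.025),
                     q97.5 = stats::quantile(.data$value, 0.975),
                     .groups = "drop")
}

#' Fit every pair in an observation table independently
#'
#' Convenience wrapper mapping [fit_pair()] over pairs, with per-pair seeds
#' derived from the global seed. Sampler failures surface as unstable fits,
#' never silently.
#'
#' @param observations Long observation tibble for many pairs.
#' @inheritParams fit_pair
#' @param progress Print a dot per fitted pair.
#' @return A list of class `dtm_fits`: `fits` (named list of `dtm_fit`),
#'   `diagnostics` (one tibble with `pair_id`, `parameter`, `rhat`,
#'   `stable`).
#' @export
fit_pairs <- function(observations, prior = build_prior("mixed"),
                      residual = residual_model(),
                      n_chains = 3, n_warmup = 1000, n_samples = 1000,
                      seed = 1L, water_fraction = 0.60,
                      bounds = param_bounds(), progress = FALSE) {
  ids <- unique(observations$pair_id)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  for (i in seq_along(ids)) {
    po <- observations[observations$pair_id == ids[i], , drop = FALSE]
    fits[[i]] <- fit_pair(po, prior, residual, n_chains, n_warmup, n_samples,
                          seed = derive_seed(seed, i),
                          water_fraction = water_fraction, bounds = bounds)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  diagnostics <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(pair_id = f$pair$pair_id, f$diagnostics, stable = f$stable)
  })
  structure(list(fits = fits, diagnostics = diagnostics),
            class = "dtm_fits")
}

#' @export
print.dtm_fits <- function(x, ...) {
  n <- length(x$fits)
  n_stable <- sum(vapply(x$fits, `[[`, logical(1), "stable"))
  cat(sprintf("<dtm_fits> %d pairs, %d stable (Rhat gate %.2f)\n",
              n, n_stable, RHAT_GATE))
  invisible(x)
}

#' Posterior means of the kinetic parameters per pair
#'
#' @param fits A `dtm_fits` object.
#' @return Tibble with `pair_id`, posterior-mean `k_mm`, `V_m`, `CL_mb`,
#'   `CL_bo`, derived `V_b`, and the stability flag.
#' @export
posterior_means <- function(fits) {
  purrr::map_dfr(fits$fits, function(f) {
    tibble::tibble(
      pair_id = f$pair$pair_id,
      k_mm = mean(f$draws$k_mm), V_m = mean(f$draws$V_m),
      CL_mb = mean(f$draws$CL_mb), CL_bo = mean(f$draws$CL_bo),
      V_b = f$pair$V_b, stable = f$stable
    )
  })
}

## Deterministic per-stage / per-item seed derivation from a global seed,
## kept within the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
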