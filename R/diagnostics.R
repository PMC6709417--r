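#' Exclude subject outliers on infant water clearance
#'
#' A pair is physiologically implausible when the posterior mean of the
#' infant's total water clearance exceeds 40% of the child's body weight
#' per day; such pairs are excluded before any downstream analysis. The
#' rule is a strict inequality: a pair sitting exactly on the boundary is
#' retained.
#'
#' @param fits A `dtm_fits` object (or a tibble from [posterior_means()]
#'   with `pair_id`, `CL_bo` and reference weight columns).
#' @param weights Optional tibble with `pair_id`, `BWT_start_kg`,
#'   `BWT_end_kg`; defaults to the weights stored in the fits.
#' @param threshold Fraction of child body weight (default 0.40).
#' @return List with `retained` (character pair ids) and `excluded`
#'   (tibble: `pair_id`, `CL_bo_mean`, `reference_weight_kg`, `ratio`).
#' @export
filter_outliers <- function(fits, weights = NULL, threshold = 0.40) {
  pm <- if (inherits(fits, "dtm_fits")) posterior_means(fits) else fits
  if (is.null(weights)) {
    weights <- purrr::map_dfr(fits$fits, function(f) {
      tibble::tibble(pair_id = f$pair$pair_id,
                     BWT_start_kg = f$pair$BWT_start_kg,
                     BWT_end_kg = f$pair$BWT_end_kg)
    })
  }
  tab <- dplyr::left_join(pm, weights, by = "pair_id") |>
    dplyr::mutate(
      reference_weight_kg = (.data$BWT_start_kg + .data$BWT_end_kg) / 2,
      ratio = .data$CL_bo / .data$reference_weight_kg
    )
  excluded <- tab |>
    dplyr::filter(.data$ratio > threshold * (1 + 1e-12) + 1e-12) |>
    dplyr::transmute(.data$pair_id, CL_bo_mean = .data$CL_bo,
                     .data$reference_weight_kg, .data$ratio)
  list(retained = setdiff(tab$pair_id, excluded$pair_id), excluded = excluded)
}

#' Individual visual predictive check (iVPC)
#'
#' Simulates observations from a pair's posterior draws plus residual
#' noise and summarises them as the predictive median and 2.5/97.5%
#' quantile curves per role, the standard per-subject adequacy check for
#' sparse kinetic fits.
#'
#' @param fit A `dtm_fit` object.
#' @param residual A [residual_model()]; defaults to the one used in the fit.
#' @param time_grid Times (days) at which to evaluate the bands.
#' @param n_sim Simulated observations per time point (a warning is logged
#'   below 100, but the bands are still computed).
#' @param seed Integer seed.
#' @return A tibble of class `dtm_ivpc`: `role`, `time_days`, `q2.5`,
#'   `median`, `q97.5`.
#' @export
ivpc <- function(fit, residual = NULL, time_grid = seq(0, 15, by = 0.25),
                 n_sim = 1000, seed = 1L) {
  stopifnot(inherits(fit, "dtm_fit"))
  if (is.null(residual)) residual <- fit$residual
  if (n_sim < 100) {
    warning("ivpc: n_sim < 100 gives ragged quantile bands", call. = FALSE)
  }
  set.seed(seed)
  draws <- fit$draws
  idx <- sample.int(nrow(draws), n_sim, replace = TRUE)
  sig <- residual_sigmas(residual, fit$pair$assay)
  out <- purrr::map_dfr(c("mother", "infant"), function(role) {
    f <- vapply(idx, function(i) {
      p <- kinetic_params(draws$k_mm[i], draws$V_m[i], draws$CL_mb[i],
                          draws$CL_bo[i], fit$pair$V_b)
      predict_enrichment(fit$pair$dose_g, p, time_grid, rep(role, length(time_grid)))
    }, numeric(length(time_grid)))
    f <- matrix(f, nrow = length(time_grid))
    sd <- if (residual$kind == "additive") sig[1] else sqrt(f^2 * sig[1]^2 + sig[2]^2)
    y <- f + matrix(stats::rnorm(length(f), 0, sd), nrow = nrow(f))
    qs <- apply(y, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
    tibble::tibble(role = role, time_days = time_grid,
                   q2.5 = qs[1, ], median = qs[2, ], q97.5 = qs[3, ])
  })
  class(out) <- c("dtm_ivpc", class(out))
  out
}
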