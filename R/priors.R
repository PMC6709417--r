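PARAM_NAMES <- c("k_mm", "V_m", "CL_mb", "CL_bo")
LOG_PARAM_NAMES <- paste0("ln_", PARAM_NAMES)

#' Prior regimes for the four kinetic parameters
#'
#' Three named regimes are supported for fitting streamlined (sparse)
#' designs, all expressed on the natural-log scale of
#' `k_mm`, `V_m`, `CL_mb`, `CL_bo`:
#'
#' * `"low_information"`: diffuse normals on every typical value and
#'   between-subject variability (BSV), so the data alone drive the fit.
#' * `"informative"`: tight priors on all four parameters (typical values
#'   and BSVs), as obtained from a previously fitted base model.
#' * `"mixed"`: informative on `ln V_m` and `ln k_mm` — the parameters that
#'   do not enter Rs — and diffuse on `ln CL_mb` and `ln CL_bo`, so the
#'   pair's own data "speak" to the clearances that determine Rs. Typical
#'   values: `ln(V_m)` mean 3.45 (SD 0.01) with BSV 0.15 (SD 0.01);
#'   `ln(k_mm)` mean −2.18 (SD 0.01) with BSV 0.18 (SD 0.01); both
#'   clearances mean 0 with SD 1000.
#'
#' BSV entries are interpreted as a normal prior on the BSV standard
#' deviation truncated at zero.
#'
#' @param name One of `"low_information"`, `"informative"`, `"mixed"`.
#' @return A tibble of class `prior_spec` with one row per log-parameter and
#'   columns `parameter`, `tv_mean`, `tv_sd`, `bsv_mean`, `bsv_sd`, plus a
#'   `name` attribute.
#' @export
#' @examples
#' build_prior("mixed")
build_prior <- function(name = c("mixed", "low_information", "informative")) {
  valid <- c("mixed", "low_information", "informative")
  if (!is.character(name) || length(name) < 1L || !(name[1] %in% valid)) {
    stop("unknown prior regime '", paste(name[1]), "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  name <- name[1]
  spec <- switch(
    name,
    mixed = tibble::tibble(
      parameter = LOG_PARAM_NAMES,
      tv_mean = c(-2.18, 3.45, 0, 0),
      tv_sd   = c(0.01, 0.01, 1000, 1000),
      bsv_mean = c(0.18, 0.15, 0, 0),
      bsv_sd   = c(0.01, 0.01, 1000, 1000)
    ),
    low_information = tibble::tibble(
      parameter = LOG_PARAM_NAMES,
      tv_mean = c(0, 0, 0, 0),
      tv_sd   = rep(1000, 4),
      bsv_mean = rep(0, 4),
      bsv_sd   = rep(1000, 4)
    ),
    informative = tibble::tibble(
      parameter = LOG_PARAM_NAMES,
      tv_mean = c(-2.18, 3.45, -0.08, -0.02),
      tv_sd   = c(0.01, 0.01, 0.05, 0.05),
      bsv_mean = c(0.18, 0.15, 0.20, 0.20),
      bsv_sd   = c(0.01, 0.01, 0.02, 0.02)
    )
  )
  structure(spec, class = c("prior_spec", class(spec)), name = name)
}

#' Individual-level prior moments implied by a prior regime
#'
#' For a single pair fitted on its own, the prior on each individual
#' log-parameter is the typical-value prior widened by the between-subject
#' variability: mean `tv_mean`, SD `sqrt(tv_sd^2 + bsv_mean^2)`.
#'
#' @param prior A [build_prior()] object.
#' @return List with numeric vectors `mean` and `sd` (length 4, ordered
#'   `ln_k_mm`, `ln_V_m`, `ln_CL_mb`, `ln_CL_bo`).
#' @export
individual_prior <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  list(
    mean = prior$tv_mean,
    sd = sqrt(prior$tv_sd^2 + prior$bsv_mean^2)
  )
}

#' Residual (observation-noise) model
#'
#' Two residual-error structures for the enrichment observations `y` about
#' the model prediction `f`:
#' * additive: `var(y | f) = sigma1^2`;
#' * combined: `var(y | f) = f^2 sigma1^2 + sigma2^2`, i.e. a proportional
#'   component plus an additive floor.
#'
#' Residual SDs may differ between assay groups (isotope-ratio mass
#' spectrometry is more precise than Fourier-transform infrared
#' spectrometry); supply one row per group.
#'
#' @param kind `"combined"` (default) or `"additive"`.
#' @param sigma1 Proportional-component SD (unitless fraction of `f`) for
#'   the combined model, or the additive SD (mg/kg) for the additive model.
#' @param sigma2 Additive-component SD (mg/kg); ignored for `"additive"`.
#' @param group Optional character vector of group labels (e.g. assay
#'   methods) parallel to `sigma1`/`sigma2`; `NULL` means one global pair.
#' @return A list of class `residual_model`.
#' @export
#' @examples
#' residual_model("combined", sigma1 = c(0.04, 0.08), sigma2 = c(1.5, 3),
#'                group = c("IRMS", "FTIR"))
residual_model <- function(kind = c("combined", "additive"),
                           sigma1 = 0.05, sigma2 = 2, group = NULL) {
  kind <- match.arg(kind)
  if (any(sigma1 < 0) || any(sigma2 < 0)) {
    stop("residual_model: sigmas must be non-negative", call. = FALSE)
  }
  if (kind == "additive") sigma2 <- rep(0, length(sigma1))
  if (!is.null(group)) {
    stopifnot(length(group) == length(sigma1), length(sigma2) == length(sigma1))
  }
  structure(list(kind = kind, sigma1 = sigma1, sigma2 = sigma2, group = group),
            class = "residual_model")
}

#' Residual SDs applicable to one observation group
#'
#' @param residual A [residual_model()].
#' @param group A single group label (e.g. `"IRMS"`); ignored when the model
#'   is ungrouped.
#' @return Numeric `c(sigma1, sigma2)`.
#' @export
residual_sigmas <- function(residual, group = NULL) {
  stopifnot(inherits(residual, "residual_model"))
  if (is.null(residual$group) || is.null(group)) {
    return(c(residual$sigma1[1], residual$sigma2[1]))
  }
  i <- match(group, residual$group)
  if (is.na(i)) {
    stop("residual_model has no sigmas for group '", group, "'", call. = FALSE)
  }
  c(residual$sigma1[i], residual$sigma2[i])
}

#' Residual standard deviation at a prediction
#'
#' Evaluates the residual model's SD at prediction `f`:
#' `sqrt(f^2 sigma1^2 + sigma2^2)` for the combined model, constant
#' `sigma1` for the additive model.
#'
#' @inheritParams residual_sigmas
#' @param f Model predictions (mg/kg).
#' @return SD per prediction (mg/kg).
#' @export
residual_sd <- function(residual, f, group = NULL) {
  s <- residual_sigmas(residual, group)
  if (residual$kind == "additive") {
    rep(s[1], length(f))
  } else {
    sqrt(f^2 * s[1]^2 + s[2]^2)
  }
}

#' Physiological support for the kinetic parameters
#'
#' Truncation bounds, on the natural scale, applied to the posterior
#' sampler. Diffuse priors (SD 1000 on the log scale) are only proper in
#' practice when restricted to a plausible support; these bounds encode
#' coarse physiology — a mother's body water lies between 10 and 100 kg,
#' her D2O elimination half-life between a day and a month, and no infant
#' can clear or receive more than 5 kg of water per day — while remaining
#' far wider than any observed value.
#'
#' @param k_mm,V_m,CL_mb,CL_bo Length-2 numeric `c(lower, upper)` on the
#'   natural scale.
#' @return List with log-scale `lower` and `upper` vectors (ordered
#'   `ln_k_mm`, `ln_V_m`, `ln_CL_mb`, `ln_CL_bo`).
#' @export
param_bounds <- function(k_mm = c(0.02, 0.7), V_m = c(10, 100),
                         CL_mb = c(0.005, 5), CL_bo = c(0.01, 5)) {
  b <- rbind(k_mm, V_m, CL_mb, CL_bo)
  if (any(b[, 1] <= 0) || any(b[, 2] <= b[, 1])) {
    stop("param_bounds: need 0 < lower < upper for every parameter", call. = FALSE)
  }
  list(lower = log(b[, 1]), upper = log(b[, 2]))
}
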