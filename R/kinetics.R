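#' Kinetic parameters of a mother-infant water-turnover model
#'
#' Bundles the four fitted parameters of the linked one-compartment
#' deuterium dose-to-mother (DTM) model together with the derived infant
#' body-water volume.
#'
#' @param k_mm First-order elimination rate of D2O from the mother (1/day).
#' @param V_m Mother's D2O distribution volume, i.e. her total body water (kg).
#' @param CL_mb Water clearance from mother to infant via breastmilk (kg/day).
#' @param CL_bo Total water clearance out of the infant (kg/day).
#' @param V_b Infant body-water volume (kg). Usually derived from the infant's
#'   weight via [infant_water_volume()] rather than supplied directly.
#'
#' @details The infant elimination rate constant is `k_bb = CL_bo / V_b`.
#'   All fields must be strictly positive and finite.
#'
#' @return A list of class `kinetic_params`.
#' @seealso [infant_water_volume()], [mother_enrichment()], [infant_enrichment()]
#' @export
#' @examples
#' kinetic_params(k_mm = 0.113, V_m = 31.5, CL_mb = 0.9, CL_bo = 0.95, V_b = 3.8)
kinetic_params <- function(k_mm, V_m, CL_mb, CL_bo, V_b) {
  p <- list(k_mm = k_mm, V_m = V_m, CL_mb = CL_mb, CL_bo = CL_bo, V_b = V_b)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("kinetic_params: field '", nm, "' must be a single finite positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "kinetic_params")
}

#' @export
format.kinetic_params <- function(x, ...) {
  sprintf(
    "<kinetic_params> k_mm=%.4g/d V_m=%.4g kg CL_mb=%.4g kg/d CL_bo=%.4g kg/d V_b=%.4g kg",
    x$k_mm, x$V_m, x$CL_mb, x$CL_bo, x$V_b
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Infant body-water volume from weight
#'
#' Infant total body water is taken as a fixed fraction of body weight;
#' about 60% of an infant's mass is water. The reference weight defaults to
#' the mean of the study start and end weights.
#'
#' @param bwt_start,bwt_end Infant weight at study start and end (kg).
#' @param water_fraction Body-water fraction of weight (default 0.60).
#' @return Body-water volume in kg.
#' @export
infant_water_volume <- function(bwt_start, bwt_end = bwt_start, water_fraction = 0.60) {
  ref <- (bwt_start + bwt_end) / 2
  if (any(ref <= 0)) stop("infant_water_volume: reference weight must be positive", call. = FALSE)
  water_fraction * ref
}

check_dose_time <- function(dose, t) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0) {
    stop("dose must be a single positive number (g)", call. = FALSE)
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative (days post-dose)", call. = FALSE)
  }
}

#' Maternal D2O enrichment curve
#'
#' Closed-form prediction of the mother's saliva D2O enrichment above
#' pre-dose baseline after a single oral dose: monoexponential washout from
#' her body-water pool,
#' \deqn{C_m(t) = \frac{1000\,\mathrm{dose}}{V_m} e^{-k_{mm} t}.}
#'
#' @param dose D2O dose given to the mother (g).
#' @param params A [kinetic_params()] object.
#' @param t Time(s) post-dose (days); vectorised.
#' @return Enrichment in mg D2O per kg body water, same length as `t`.
#' @export
#' @examples
#' p <- kinetic_params(0.113, 31.5, 0.9, 0.95, 3.8)
#' mother_enrichment(30, p, t = c(0, 1, 7, 14))
mother_enrichment <- function(dose, params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  check_dose_time(dose, t)
  dose * 1000 / params$V_m * exp(-params$k_mm * t)
}

#' Infant D2O enrichment curve
#'
#' Closed-form prediction of the infant's saliva enrichment. D2O reaches the
#' infant only through breastmilk (clearance `CL_mb` acting on the maternal
#' concentration) and is eliminated with rate constant `k_bb = CL_bo / V_b`,
#' giving the classic flip-flop two-exponential profile
#' \deqn{C_b(t) = \frac{1000\,\mathrm{dose}\, CL_{mb}}{V_m V_b}
#'   \frac{e^{-k_{mm} t} - e^{-k_{bb} t}}{k_{bb} - k_{mm}}.}
#' When `k_bb` and `k_mm` coincide (within `tol`) the removable singularity
#' is handled by the analytic limit `t exp(-k_mm t)`.
#'
#' @inheritParams mother_enrichment
#' @param tol Rate-difference tolerance (1/day) below which the equal-rates
#'   limit branch is used.
#' @return Enrichment in mg/kg, same length as `t`; zero at `t = 0`.
#' @export
infant_enrichment <- function(dose, params, t, tol = 1e-8) {
  stopifnot(inherits(params, "kinetic_params"))
  check_dose_time(dose, t)
  k_mm <- params$k_mm
  k_bb <- params$CL_bo / params$V_b
  scale <- dose * 1000 * params$CL_mb / (params$V_m * params$V_b)
  if (abs(k_bb - k_mm) < tol) {
    scale * t * exp(-k_mm * t)
  } else {
    scale * (exp(-k_mm * t) - exp(-k_bb * t)) / (k_bb - k_mm)
  }
}

#' Predicted enrichment for either role
#'
#' Convenience dispatcher used throughout the fitting and imputation code.
#'
#' @inheritParams mother_enrichment
#' @param role `"mother"` or `"infant"`, recycled against `t`.
#' @return Enrichment (mg/kg).
#' @export
predict_enrichment <- function(dose, params, t, role) {
  role <- rep_len(as.character(role), length(t))
  out <- numeric(length(t))
  m <- role == "mother"
  if (any(m)) out[m] <- mother_enrichment(dose, params, t[m])
  if (any(!m)) out[!m] <- infant_enrichment(dose, params, t[!m])
  out
}

#' Ancillary water-balance rates
#'
#' The two design-independent inputs to the infant's water budget:
#' atmospheric water absorbed through lungs and skin (`R_a`) and water
#' retained for growth (`R_g`), both in g/day. `R_g` may be negative only
#' when the infant lost weight over the study.
#'
#' @param R_a Atmospheric (insensible) water influx (g/day), `>= 0`.
#' @param R_g Growth water retention (g/day).
#' @return A list of class `ancillary_rates`.
#' @export
ancillary_rates <- function(R_a, R_g) {
  if (!is.numeric(R_a) || length(R_a) != 1L || !is.finite(R_a) || R_a < 0) {
    stop("ancillary_rates: R_a must be a single non-negative number (g/day)", call. = FALSE)
  }
  if (!is.numeric(R_g) || length(R_g) != 1L || !is.finite(R_g)) {
    stop("ancillary_rates: R_g must be a single finite number (g/day)", call. = FALSE)
  }
  structure(list(R_a = R_a, R_g = R_g), class = "ancillary_rates")
}

#' Default ancillary rates for a pair
#'
#' `R_a` is modelled as a small fixed fraction of the infant's water
#' turnover (default 6.3% of `CL_bo`); `R_g` as the water fraction (default
#' 0.73) of the infant's weight change over the study.
#'
#' @param CL_bo Infant water clearance (kg/day).
#' @param bwt_start,bwt_end Infant start/end weight (kg).
#' @param duration Study duration (days).
#' @param ra_fraction Fraction of turnover absorbed from the atmosphere.
#' @param rg_water_fraction Water fraction of tissue gained.
#' @return An [ancillary_rates()] object.
#' @export
default_ancillary <- function(CL_bo, bwt_start, bwt_end, duration = 14,
                              ra_fraction = 0.063, rg_water_fraction = 0.73) {
  ancillary_rates(
    R_a = ra_fraction * 1000 * CL_bo,
    R_g = rg_water_fraction * (bwt_end - bwt_start) / duration * 1000
  )
}

#' Non-milk water intake rate Rs
#'
#' Mass balance over the infant's water pool at steady state: inflows
#' (breastmilk `CL_mb`, atmospheric `R_a`, and other sources `Rs`) balance
#' the outflow `CL_bo` plus water retained for growth `R_g`, so
#' \deqn{R_s = 1000\,(CL_{bo} - CL_{mb}) + R_g - R_a \quad \text{(g/day)}.}
#' `Rs` is the quantity on which the exclusive-breastfeeding classifier
#' operates; negative values are interpreted as effectively zero intake
#' from other sources.
#'
#' @param params A [kinetic_params()] object, or a list/data frame with
#'   numeric `CL_mb` and `CL_bo` columns (kg/day); vectorised in the latter
#'   case.
#' @param anc An [ancillary_rates()] object (or list with `R_a`, `R_g`).
#' @return Rs in g/day.
#' @export
#' @examples
#' compute_rs(kinetic_params(0.113, 31.5, 0.80, 0.85, 3.8),
#'            ancillary_rates(R_a = 25, R_g = 20))
compute_rs <- function(params, anc) {
  if (is.null(params$CL_mb) || is.null(params$CL_bo)) {
    stop("compute_rs: params must carry CL_mb and CL_bo", call. = FALSE)
  }
  1000 * (params$CL_bo - params$CL_mb) + anc$R_g - anc$R_a
}
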