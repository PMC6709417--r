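#' Enumerate streamlined sampling designs
#'
#' Exhaustively lists reduced post-dose sampling schedules on a day grid.
#' Two families are supported:
#' * family A — limited sampling intensity: any subset of the grid with
#'   between `size_min` and `size_max` paired samples (default at most 3),
#'   on any study day;
#' * family B — limited study duration: subsets whose last day is no later
#'   than `last_day` (default 9) and whose span (`last - first + 1`) is at
#'   most `max_span` consecutive days (default 7).
#'
#' Designs are returned in deterministic lexicographic order and labelled
#' with the conventional "+"-joined notation, e.g. `"7+13"`.
#'
#' @param family `"A"` or `"B"`.
#' @param grid Candidate post-dose days (default days 1-9, 13, 14).
#' @param size_min,size_max Range of the number of paired samples.
#' @param max_span Family-B maximum window span in days.
#' @param last_day Family-B latest permitted sampling day.
#' @return Tibble of class `design_set` with columns `design` (label),
#'   `family`, `size`, and `days` (list column of integer day vectors).
#' @export
#' @examples
#' nrow(enumerate_designs("A", size_min = 1, size_max = 1))  # 11
enumerate_designs <- function(family = c("A", "B"), grid = DEFAULT_GRID,
                              size_min = 1, size_max = 3,
                              max_span = 7, last_day = 9) {
  family <- match.arg(family)
  if (length(grid) == 0) stop("enumerate_designs: empty day grid", call. = FALSE)
  grid <- sort(unique(grid))
  sizes <- seq(max(1, size_min), min(size_max, length(grid)))
  subsets <- purrr::map(sizes, function(k) {
    m <- utils::combn(grid, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  })
  subsets <- purrr::flatten(subsets)
  if (family == "B") {
    keep <- vapply(subsets, function(d) {
      max(d) <= last_day && (max(d) - min(d) + 1) <= max_span
    }, logical(1))
    subsets <- subsets[keep]
  }
  if (length(subsets) == 0) {
    stop("enumerate_designs: no design satisfies the constraints (family ",
         family, ", sizes ", size_min, "-", size_max,
         if (family == "B") paste0(", span <= ", max_span, ", last day <= ", last_day),
         ")", call. = FALSE)
  }
  ## lexicographic order on the padded day vectors
  key <- vapply(subsets, function(d) paste(sprintf("%02d", d), collapse = "+"),
                character(1))
  ord <- order(lengths(subsets), key)
  subsets <- subsets[ord]
  out <- tibble::tibble(
    design = vapply(subsets, function(d) paste(d, collapse = "+"), character(1)),
    family = family,
    size = lengths(subsets),
    days = subsets
  )
  class(out) <- c("design_set", class(out))
  out
}

#' Impute a fully balanced observation table
#'
#' Extends an (unbalanced) observation table so that every pair contributes
#' exactly one record per grid day per role. Missing cells are filled by
#' single imputation at the pair's posterior-mean model prediction for that
#' dose, covariates and sample time — no residual noise is added — while
#' measured records pass through untouched. An `imputed` mask records
#' provenance.
#'
#' @param observations Long observation tibble.
#' @param fits A `dtm_fits` object covering every pair in `observations`.
#' @param grid Target day grid (default days 1-9, 13, 14).
#' @return A list of class `imputed_dataset`: `data` (balanced observation
#'   tibble with logical `imputed` column) and `grid`.
#' @export
impute_full <- function(observations, fits, grid = DEFAULT_GRID) {
  ids <- unique(observations$pair_id)
  missing_fits <- setdiff(ids, names(fits$fits))
  if (length(missing_fits)) {
    stop("impute_full: no posterior available for pair(s) ",
         paste(utils::head(missing_fits, 5), collapse = ", "), call. = FALSE)
  }
  meta_cols <- c("dose_g", "MWT_kg", "BWT_start_kg", "BWT_end_kg", "country", "assay")
  meta <- observations |>
    dplyr::distinct(.data$pair_id, dplyr::across(dplyr::all_of(meta_cols)))
  skeleton <- tidyr::expand_grid(
    pair_id = ids, role = c("mother", "infant"), time_days = as.numeric(grid)
  ) |>
    dplyr::left_join(meta, by = "pair_id")
  measured <- dplyr::mutate(observations, imputed = FALSE)
  out <- dplyr::left_join(
    skeleton,
    dplyr::select(measured, "pair_id", "role", "time_days",
                  "enrichment_mg_per_kg", "imputed"),
    by = c("pair_id", "role", "time_days")
  )
  need <- which(is.na(out$enrichment_mg_per_kg))
  if (length(need)) {
    pred <- vapply(need, function(i) {
      f <- fits$fits[[out$pair_id[i]]]
      d <- f$draws
      mean(predict_enrichment_draws(out$dose_g[i], d, f$pair$V_b,
                                    out$time_days[i], out$role[i]))
    }, numeric(1))
    out$enrichment_mg_per_kg[need] <- pred
    out$imputed[need] <- TRUE
  }
  out <- dplyr::relocate(out, "pair_id", "role", "time_days",
                         "enrichment_mg_per_kg")
  structure(list(data = out, grid = as.numeric(grid)), class = "imputed_dataset")
}

## Model predictions at one (time, role) across all posterior draws.
predict_enrichment_draws <- function(dose, draws, Vb, t, role) {
  if (role == "mother") {
    dose * 1000 / draws$V_m * exp(-draws$k_mm * t)
  } else {
    k_bb <- draws$CL_bo / Vb
    scale <- dose * 1000 * draws$CL_mb / (draws$V_m * Vb)
    d <- k_bb - draws$k_mm
    near <- abs(d) < 1e-8
    out <- scale * (exp(-draws$k_mm * t) - exp(-k_bb * t)) / d
    out[near] <- (scale * t * exp(-draws$k_mm * t))[near]
    out
  }
}

#' @export
print.imputed_dataset <- function(x, ...) {
  cat(sprintf("<imputed_dataset> %d pairs x %d days x 2 roles; %d of %d records imputed\n",
              length(unique(x$data$pair_id)), length(x$grid),
              sum(x$data$imputed), nrow(x$data)))
  invisible(x)
}

#' Build a bootstrap streamlined data set
#'
#' Draws pairs with replacement from the imputed full data set (to the
#' original pair count) and keeps only the design's sampling days,
#' emulating the data a future field study run under the streamlined
#' schedule would collect. Resampled duplicates receive distinct working
#' ids; the `source_pair_id` column retains the truth/reference linkage.
#'
#' @param imputed An [impute_full()] result.
#' @param design One row of a `design_set` (or a list with `days`).
#' @param seed Integer seed.
#' @param resample Set `FALSE` to keep the original pairs (identity
#'   "bootstrap"), e.g. to round-trip the full design.
#' @return Observation tibble with columns as the input plus
#'   `source_pair_id`; `pair_id` holds the working id.
#' @export
bootstrap_streamlined <- function(imputed, design, seed = 1L, resample = TRUE) {
  stopifnot(inherits(imputed, "imputed_dataset"))
  days <- if (is.list(design$days)) design$days[[1]] else design$days
  if (!all(days %in% imputed$grid)) {
    stop("bootstrap_streamlined: design days outside the imputed grid", call. = FALSE)
  }
  ids <- unique(imputed$data$pair_id)
  set.seed(seed)
  chosen <- if (resample) sample(ids, length(ids), replace = TRUE) else ids
  working <- tibble::tibble(
    pair_id = sprintf("B%04d", seq_along(chosen)),
    source_pair_id = chosen
  )
  base <- dplyr::filter(imputed$data, .data$time_days %in% days)
  out <- working |>
    dplyr::inner_join(base, by = c(source_pair_id = "pair_id"),
                      relationship = "many-to-many")
  dplyr::relocate(out, "pair_id", "source_pair_id")
}
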