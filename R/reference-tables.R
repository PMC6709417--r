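#' Reference classification counts from the original field study
#'
#' Per-country EBF / non-EBF counts reported for the 565-pair
#' model-building data set of the original nine-country DTM field study,
#' shipped as plain CSV. These are fixed published summaries used for
#' cross-checks (e.g. that per-country counts reproduce the all-countries
#' total); they are not re-estimated by this package.
#'
#' @return Tibble with `country`, `non_ebf`, `ebf`, `total`; the last row
#'   is the `"All countries"` margin.
#' @export
field_classification_table <- function() {
  readr::read_csv(
    system.file("extdata", "field_classification_by_country.csv",
                package = "ebfdtm"),
    show_col_types = FALSE
  )
}

#' Reference streamlined-design operating characteristics
#'
#' The published side-by-side validation of the 30 short-listed streamlined
#' designs from the original field study: sensitivity and specificity on
#' the model-building ("best") and held-out ("evaluation") data, with
#' `diff = evaluation - best`, in the same layout [rank_and_validate()]
#' produces for synthetic cohorts.
#'
#' @return Tibble with `no`, `design`, `family`, `sens_best`, `sens_eval`,
#'   `diff_sensitivity`, `spec_best`, `spec_eval`, `diff_specificity`.
#' @export
field_design_table <- function() {
  readr::read_csv(
    system.file("extdata", "field_design_validation.csv", package = "ebfdtm"),
    show_col_types = FALSE
  )
}

#' Arithmetic consistency of the reference tables
#'
#' Recomputes the derivable entries of the shipped field-study tables:
#' the all-countries classification totals as the sum of the per-country
#' rows, and the design-validation `diff` columns as evaluation minus best.
#'
#' @return List with `classification` (tibble: quantity, reported,
#'   recomputed) and `design_diffs` (tibble per design with reported and
#'   recomputed diffs and their agreement at the printed 2-decimal
#'   precision).
#' @export
check_field_tables <- function() {
  cls <- field_classification_table()
  per_country <- dplyr::filter(cls, .data$country != "All countries")
  all_row <- dplyr::filter(cls, .data$country == "All countries")
  classification <- tibble::tibble(
    quantity = c("non_ebf_total", "ebf_total", "grand_total"),
    reported = c(all_row$non_ebf, all_row$ebf, all_row$total),
    recomputed = c(sum(per_country$non_ebf), sum(per_country$ebf),
                   sum(per_country$total))
  )
  des <- field_design_table()
  design_diffs <- des |>
    dplyr::transmute(
      .data$design,
      reported_diff_sens = .data$diff_sensitivity,
      recomputed_diff_sens = round(.data$sens_eval - .data$sens_best, 2),
      reported_diff_spec = .data$diff_specificity,
      recomputed_diff_spec = round(.data$spec_eval - .data$spec_best, 2)
    ) |>
    dplyr::mutate(
      agree = .data$reported_diff_sens == .data$recomputed_diff_sens &
        .data$reported_diff_spec == .data$recomputed_diff_spec
    )
  list(classification = classification, design_diffs = design_diffs)
}
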