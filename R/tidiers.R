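#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-pair kinetic fit
#'
#' @param x A `dtm_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per kinetic parameter: posterior `mean`,
#'   `sd`, central 95% interval, and `rhat`.
#' @method tidy dtm_fit
#' @export
tidy.dtm_fit <- function(x, ...) {
  dplyr::left_join(
    dplyr::rename(summarise_draws(x$draws), estimate = "mean", std.error = "sd",
                  conf.low = "q2.5", conf.high = "q97.5"),
    x$diagnostics, by = "parameter"
  )
}

#' @param x A `dtm_fit` object.
#' @param ... Unused.
#' @rdname tidy.dtm_fit
#' @return For `glance`: a one-row tibble with the pair id, draw counts,
#'   maximum Rhat and the stability flag.
#' @method glance dtm_fit
#' @export
glance.dtm_fit <- function(x, ...) {
  tibble::tibble(
    pair_id = x$pair$pair_id, n_chains = x$n_chains, n_samples = x$n_samples,
    prior = x$prior, max_rhat = max(x$diagnostics$rhat), stable = x$stable
  )
}

#' Tidy a population fit
#'
#' @param x A `dtm_popfit` object.
#' @param ... Unused.
#' @return Tibble with one row per population-level parameter: posterior
#'   `estimate` (mean), `std.error`, central 95% interval and `rhat`.
#' @method tidy dtm_popfit
#' @export
tidy.dtm_popfit <- function(x, ...) {
  pars <- setdiff(names(x$population), c("chain", "draw"))
  purrr::map_dfr(pars, function(nm) {
    v <- x$population[[nm]]
    tibble::tibble(
      parameter = nm, estimate = mean(v), std.error = stats::sd(v),
      conf.low = stats::quantile(v, 0.025), conf.high = stats::quantile(v, 0.975)
    )
  }) |>
    dplyr::left_join(x$diagnostics, by = "parameter")
}

#' @param x A `dtm_popfit` object.
#' @param ... Unused.
#' @rdname tidy.dtm_popfit
#' @method glance dtm_popfit
#' @export
glance.dtm_popfit <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$meta), n_chains = x$n_chains, n_samples = x$n_samples,
    prior = x$prior, max_rhat = max(x$diagnostics$rhat, na.rm = TRUE)
  )
}

#' Tidy a design validation table
#'
#' @param x A `design_validation` object.
#' @param ... Unused.
#' @return The underlying tibble (already tidy: one row per design).
#' @method tidy design_validation
#' @export
tidy.design_validation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
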