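#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an individual visual predictive check
#'
#' Predictive median and 2.5/97.5% bands per role; overlay the pair's
#' observations with `observations`.
#'
#' @param object A `dtm_ivpc` tibble from [ivpc()].
#' @param observations Optional observation tibble for the same pair.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtm_ivpc
#' @export
autoplot.dtm_ivpc <- function(object, observations = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_days)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~role, scales = "free_y") +
    ggplot2::labs(x = "Days post-dose", y = "D2O enrichment (mg/kg)",
                  title = "Individual visual predictive check")
  if (!is.null(observations)) {
    p <- p + ggplot2::geom_point(
      data = observations,
      ggplot2::aes(y = .data$enrichment_mg_per_kg), shape = 1)
  }
  p
}

#' Plot design operating characteristics
#'
#' Sensitivity vs specificity of the evaluated streamlined designs,
#' labelled with the "+"-joined day notation.
#'
#' @param object A `design_performance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot design_performance
#' @export
autoplot.design_performance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$specificity, y = .data$sensitivity,
                               shape = .data$family)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$design),
                       vjust = -0.6, size = 2.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Specificity", y = "Sensitivity",
                  title = "Streamlined-design operating characteristics")
}

#' Plot the clearance information profile
#'
#' @param object An [information_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot information_profile
#' @export
autoplot.information_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$time_days, y = abs(.data$normalized),
                               linetype = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$argmax,
                        ggplot2::aes(xintercept = .data$time_days),
                        colour = "grey60") +
    ggplot2::labs(x = "Days post-dose", y = "|normalised sensitivity|",
                  title = "Sampling-time information profile of the clearances")
}

#' Plot a synthetic cohort's enrichment series
#'
#' Spaghetti plot of observed enrichment per role, coloured by true class.
#'
#' @param object A `dtm_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtm_cohort
#' @export
autoplot.dtm_cohort <- function(object, ...) {
  dat <- dplyr::left_join(
    object$observations,
    dplyr::select(object$truth, "pair_id", "true_class"), by = "pair_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_days,
                                    y = .data$enrichment_mg_per_kg,
                                    group = .data$pair_id,
                                    colour = .data$true_class)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~role, scales = "free_y") +
    ggplot2::labs(x = "Days post-dose", y = "D2O enrichment (mg/kg)",
                  colour = "Truth")
}
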