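#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_hline geom_boxplot labs theme_minimal facet_wrap
NULL

#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none reference
#' strategies (and the comparator when present) over the threshold grid.
#'
#' @param object A `carpe_decision_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carpe_decision_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            dplyr::any_of(c("nb_model", "nb_all", "nb_none",
                                            "nb_reference")),
                            names_to = "strategy", values_to = "nb")
  ggplot(df, aes(x = .data$pt, y = .data$nb, colour = .data$strategy)) +
    geom_line() +
    labs(x = "threshold probability", y = "net benefit",
         colour = NULL) +
    theme_minimal()
}

#' Plot a reliability diagram
#'
#' @param object A `carpe_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carpe_calibration <- function(object, ...) {
  ggplot(object$bins[object$bins$n > 0, ],
         aes(x = .data$mean_pred, y = .data$obs_freq)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(aes(size = .data$n)) + geom_line() +
    labs(x = "mean predicted probability", y = "observed frequency",
         title = sprintf("Brier score %.3f", object$brier)) +
    theme_minimal()
}

#' Plot bootstrap metric distributions per method
#'
#' @param object A `carpe_bootstrap`.
#' @param metric One of `"auroc"`, `"auprc"`, `"brier"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carpe_bootstrap <- function(object, metric = "auroc", ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$method, y = .data[[metric]])) +
    geom_boxplot() +
    labs(x = NULL, y = toupper(metric)) +
    theme_minimal()
}
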