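#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline geom_density labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the feature-selection curve
#'
#' Cross-validated MCC against the number of top-ranked probabilistic
#' features, with the chosen size highlighted.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$m, y = .data$mcc)) +
    geom_line(colour = "grey40") +
    geom_point(aes(colour = .data$chosen), size = 2, show.legend = FALSE) +
    labs(x = "top-ranked probabilistic features (m)",
         y = "cross-validated MCC") +
    theme_minimal()
}

#' ROC curve from pooled out-of-fold predictions
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  oof <- object$oof[order(-object$oof$score), ]
  n_pos <- sum(oof$truth == 1); n_neg <- sum(oof$truth == 0)
  d <- tibble(
    fpr = cumsum(oof$truth == 0) / max(1, n_neg),
    tpr = cumsum(oof$truth == 1) / max(1, n_pos)
  )
  ggplot(d, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(linetype = "dashed", colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate") +
    theme_minimal()
}

#' Class-wise physicochemical property densities
#'
#' Density view of the six chemical-space properties by activity class,
#' the numeric counterpart of which is in
#' [chem_space_report()]`$properties`.
#'
#' @param object A `chemspace_report`.
#' @param ... Unused.
#' @return A ggplot faceted by property.
#' @export
autoplot.chemspace_report <- function(object, ...) {
  d <- object$physchem |>
    tidyr::pivot_longer(c("mw", "alogp", "hba", "hbd", "tpsa", "nrotb"),
                        names_to = "property", values_to = "value")
  ggplot(d, aes(x = .data$value, fill = .data$label)) +
    geom_density(alpha = 0.5) +
    facet_wrap(~property, scales = "free") +
    labs(x = NULL, y = "density", fill = NULL) +
    theme_minimal()
}
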