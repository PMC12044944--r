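#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a metrics report into long form
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble (`metric`, `value`) covering ACC, BACC, SN, SP, MCC and
#'   AUC (when present).
#' @export
tidy.metrics_report <- function(x, ...) {
  metrics <- intersect(c("acc", "bacc", "sn", "sp", "mcc", "auc"), names(x))
  tibble(metric = toupper(metrics),
         value = as.numeric(x[1, metrics]))
}

#' @export
glance.metrics_report <- function(x, ...) {
  as_tibble(x)[, intersect(c("acc", "bacc", "sn", "sp", "mcc", "auc", "n"),
                           names(x))]
}

#' @export
tidy.cv_result <- function(x, ...) {
  x$per_fold |>
    tidyr::pivot_longer(c("tp", "tn", "fp", "fn"),
                        names_to = "count", values_to = "value")
}

#' @export
glance.cv_result <- function(x, ...) glance(x$pooled)

#' Tidy a feature-selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble (`m`, `mcc`, `chosen`).
#' @export
tidy.selection_result <- function(x, ...) {
  x$cv_mcc |> mutate(chosen = .data$m == x$chosen_m)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(chosen_m = x$chosen_m, best_cv_mcc = max(x$cv_mcc$mcc),
         n_candidates = length(x$grid))
}

#' Tidy a stacked model: one row per base model
#'
#' @param x A `stack_model`.
#' @param ... Unused.
#' @return Tibble (`algorithm`, `family`, `subset`, `cv_mcc`, `selected_n`:
#'   how many of the model's PFV columns the meta-classifier uses).
#' @export
tidy.stack_model <- function(x, ...) {
  purrr::map_dfr(x$base, function(b) {
    tibble(algorithm = b$algorithm, family = b$family,
           subset = b$subset_index, cv_mcc = b$model$cv_mcc,
           selected = base_key(b$algorithm, b$family, b$subset_index) %in%
             x$meta$columns)
  })
}

#' @export
glance.stack_model <- function(x, ...) {
  tibble(n_base_models = length(x$base),
         n_algorithms = length(x$algorithms),
         n_families = length(x$families),
         n_subsets = length(x$subsets),
         pfv_width = ncol(x$train_pfv),
         chosen_m = if (!is.null(x$selection)) x$selection$chosen_m else
           ncol(x$train_pfv),
         threshold = x$meta$threshold)
}
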