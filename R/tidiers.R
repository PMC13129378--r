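#' @importFrom ggplot2 ggplot aes geom_boxplot geom_line geom_point labs
#'   theme_minimal autoplot
#' @importFrom rlang .data
NULL

#' Broom-style tidiers for fitted/evaluated objects
#'
#' `tidy()` returns one row per logged quantity; `glance()` a one-row
#' summary.
#'
#' @param x object to tidy.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.mr4dct_trained <- function(x, ...) {
  x$log
}

#' @rdname tidiers
#' @export
glance.mr4dct_trained <- function(x, ...) {
  tibble::tibble(model_kind = x$cfg$model_kind,
                 iterations = x$cfg$iterations,
                 lambda = x$cfg$weights$lambda,
                 gamma = x$cfg$weights$gamma,
                 best_iteration = x$best_iteration,
                 best_val_loss = min(x$val_log$val_loss),
                 final_train_loss = x$log$loss[nrow(x$log)])
}

#' @rdname tidiers
#' @export
tidy.mr4dct_jacobian <- function(x, ...) {
  tibble::tibble(foldings_pct = 100 * x$foldings_fraction,
                 stdlj = x$std_log_jacobian,
                 foldings_mask_pct = 100 * (x$foldings_fraction_mask %||%
                                              NA_real_),
                 stdlj_mask = x$std_log_jacobian_mask %||% NA_real_)
}

#' @rdname tidiers
#' @export
glance.mr4dct_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 phases = length(x$fields),
                 runtime_s = x$runtime_s,
                 mean_phase_s = mean(x$per_phase_s))
}

#' @rdname tidiers
#' @export
tidy.mr4dct_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

# generics re-exported so tidy()/glance() work without loading broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Box plots of an endpoint by method
#'
#' Per-organ records (aggregates excluded) are drawn as one box per method,
#' optionally faceted by organ — the standard at-a-glance comparison of
#' contour-mapping quality across methods.
#'
#' @param records metric tibble from [evaluate_result()].
#' @param endpoint column to plot.
#' @param by_organ facet by organ?
#' @return A ggplot object.
#' @export
plot_method_boxplots <- function(records, endpoint = "dsc",
                                 by_organ = FALSE) {
  df <- dplyr::filter(records, !.data$organ %in% c("seen", "unseen", "all"))
  p <- ggplot(df, aes(x = .data$method, y = .data[[endpoint]],
                      fill = .data$method)) +
    geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    labs(x = NULL, y = endpoint) +
    theme_minimal()
  if (by_organ) p <- p + ggplot2::facet_wrap(~organ)
  p
}

#' @rdname tidiers
#' @param object a `mr4dct_binned` table.
#' @export
autoplot.mr4dct_binned <- function(object, ...) {
  ggplot(object, aes(x = .data$bin + 0.05, y = .data$mean_dsc,
                     colour = .data$method)) +
    geom_line() +
    geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    labs(x = "Dice after rigid pre-registration (bin)",
         y = "Dice after deformable registration") +
    theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.mr4dct_trained <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log,
                            c("similarity", "regularization", "dice",
                              "loss"),
                            names_to = "term", values_to = "value")
  ggplot(df, aes(x = .data$iteration, y = .data$value,
                 colour = .data$term)) +
    geom_line(alpha = 0.7) +
    labs(x = "iteration", y = "loss term") +
    theme_minimal()
}
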