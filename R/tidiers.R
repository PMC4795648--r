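# broom-style accessors and ggplot2 autoplot methods for experiment
# results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-condition estimates of an experiment result
#'
#' @param x A `cfe_result`, `fie_result` or `wpe_result`.
#' @param ... Unused.
#' @return The per-condition summary tibble (size class, condition, point
#'   estimate, SEM).
#' @export
tidy.holo_result <- function(x, ...) x$summary

#' One-row-per-size-class effect summary of an experiment result
#'
#' @param x A `cfe_result`, `fie_result` or `wpe_result`.
#' @param ... Unused.
#' @return Tibble with one row per tuning size: effect size, SEM and
#'   p-value(s).
#' @export
glance.holo_result <- function(x, ...) x$effects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of an experiment's condition estimates
#'
#' Per-condition point estimates with SEM error bars, one panel per
#' tuning size — the standard presentation of the three holism markers.
#'
#' @param object A `cfe_result`, `fie_result` or `wpe_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.holo_result <- function(object, ...) {
  s <- object$summary
  value_col <- setdiff(names(s), c("size_class", "condition", "sem"))[1]
  s$estimate <- s[[value_col]]
  s$size_class <- factor(s$size_class, levels = unique(s$size_class))
  s$condition <- factor(s$condition, levels = unique(s$condition))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$estimate,
                                  fill = .data$condition)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$sem,
                                        ymax = .data$estimate + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~size_class) +
    ggplot2::labs(y = gsub("_", " ", value_col), x = NULL,
                  title = object$meta$label) +
    ggplot2::theme_minimal()
}

#' Bar plot of effect sizes across tuning sizes
#'
#' @param object A `holo_result`.
#' @return A ggplot object showing the effect size (condition difference)
#'   per tuning size with SEM error bars.
#' @export
plot_effect_sizes <- function(object) {
  e <- object$effects
  e$size_class <- factor(e$size_class, levels = unique(e$size_class))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$size_class, y = .data$effect)) +
    ggplot2::geom_col(width = 0.6, fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$effect - .data$sem,
                                        ymax = .data$effect + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = "tuning size", y = "effect size",
                  title = object$meta$label) +
    ggplot2::theme_minimal()
}
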