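#' Tidy the aggregated results of a static experiment
#'
#' @param x A `static_gsa` object.
#' @param ... Unused.
#' @return The aggregated tibble (`gene`, `condition`, `method`,
#'   `order`, `size`, `mean`, `band_low`, `band_high`, `n_boot`).
#' @method tidy static_gsa
#' @export
tidy.static_gsa <- function(x, ...) x$results

#' @rdname tidy.static_gsa
#' @method tidy timecourse_gsa
#' @export
tidy.timecourse_gsa <- function(x, ...) x$results

#' One-row summary of a sensitivity experiment
#'
#' @param x A `static_gsa` or `timecourse_gsa` object.
#' @param ... Unused.
#' @return A one-row tibble with counts of genes, methods, analysis
#'   units and failed cells.
#' @method glance static_gsa
#' @export
glance.static_gsa <- function(x, ...) {
  tibble(
    n_genes = length(x$a),
    n_methods = length(x$methods),
    n_sizes = length(x$config$sizes),
    n_boot = x$config$n_boot,
    n_failures = length(x$log$failures)
  )
}

#' @rdname glance.static_gsa
#' @method glance timecourse_gsa
#' @export
glance.timecourse_gsa <- function(x, ...) {
  tibble(
    n_genes = length(x$a),
    n_methods = length(x$methods),
    n_units = dplyr::n_distinct(x$results[[x$unit]]),
    n_samples = x$log$n_samples,
    scaled = x$log$scaled,
    n_failures = length(x$log$failures)
  )
}

#' @export
print.static_gsa <- function(x, ...) {
  cat("<static_gsa> ", length(x$a), " genes, methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  cat("  sizes ", paste(x$config$sizes, collapse = "/"),
      ", ", x$config$n_boot, " bootstraps per size\n", sep = "")
  print(x$results, n = 6)
  invisible(x)
}

#' @export
print.timecourse_gsa <- function(x, ...) {
  cat("<timecourse_gsa> ", length(x$a), " genes per ", x$unit,
      ", methods: ", paste(x$methods, collapse = ", "), "\n", sep = "")
  print(x$results, n = 6)
  invisible(x)
}

#' Bar-chart visualisation of sensitivity indices
#'
#' Per-gene index bars with the bootstrap confidence band (static
#' experiment) or one bar per analysis unit (time course), faceted by
#' method. Monte Carlo estimates slightly below zero are shown as
#' drawn; clip beforehand if a non-negative display is wanted.
#'
#' @param object A `static_gsa` or `timecourse_gsa` object.
#' @param methods Optional subset of method tags to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot static_gsa
#' @export
autoplot.static_gsa <- function(object, methods = NULL, ...) {
  df <- object$results
  if (!is.null(methods)) df <- dplyr::filter(df, .data$method %in% methods)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$gene, y = .data$mean, fill = .data$condition)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$band_low, ymax = .data$band_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::facet_grid(ggplot2::vars(.data$size),
                        ggplot2::vars(.data$method, .data$order)) +
    ggplot2::labs(x = NULL, y = "sensitivity index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname autoplot.static_gsa
#' @method autoplot timecourse_gsa
#' @export
autoplot.timecourse_gsa <- function(object, methods = NULL, ...) {
  df <- object$results
  if (!is.null(methods)) df <- dplyr::filter(df, .data$method %in% methods)
  unit <- object$unit
  df$unit_label <- factor(as.character(df[[unit]]),
                          levels = unique(as.character(df[[unit]])))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$gene, y = .data$value, fill = .data$unit_label)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$method, .data$order),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = "sensitivity index", fill = unit) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
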