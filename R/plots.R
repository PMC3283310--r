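#' Plot mean missing-branch rates by method
#'
#' Bar chart of the mean FN rate per method with standard-error bars, from a
#' [run_experiment()] results table.
#'
#' @param table Results tibble with `method_label` and `fn_rate` columns.
#' @return A ggplot object.
#' @export
plot_fn_rates <- function(table) {
  dat <- table[!is.na(table$fn_rate), , drop = FALSE]
  summ <- dplyr::summarise(
    dplyr::group_by(dat, .data$method_label),
    mean_fn = mean(.data$fn_rate),
    se = stats::sd(.data$fn_rate) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(
    x = stats::reorder(.data$method_label, .data$mean_fn),
    y = .data$mean_fn
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean_fn - .data$se, 0),
        ymax = .data$mean_fn + .data$se
      ),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "mean missing-branch (FN) rate") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot FN rate against number of genes
#'
#' Line plot of mean FN rate per method across gene counts, for results
#' tables pooled over configurations differing in `n_genes`.
#'
#' @param table Results tibble with `method_label`, `n_genes`, `fn_rate`.
#' @return A ggplot object.
#' @export
plot_fn_by_genes <- function(table) {
  dat <- table[!is.na(table$fn_rate), , drop = FALSE]
  summ <- dplyr::summarise(
    dplyr::group_by(dat, .data$method_label, .data$n_genes),
    mean_fn = mean(.data$fn_rate),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$n_genes, y = .data$mean_fn,
    colour = .data$method_label, group = .data$method_label
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of genes", y = "mean missing-branch (FN) rate",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
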