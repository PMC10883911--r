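# ggplot2 views of the main result types.

#' Bar plot of lncRNA positional classes
#'
#' The classic classification bar plot: candidate counts per positional
#' subtype, filled by top level (genic / intergenic).
#'
#' @param classes output of [classify_position()].
#' @return a ggplot object.
#' @export
plot_lnc_classes <- function(classes) {
  df <- classes |> count(.data$top_level, .data$subtype)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$n,
                                   fill = .data$top_level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "lncRNA candidates", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Volcano plot of a differential-expression result
#'
#' Convenience wrapper around `autoplot()` for [wald_test()] output.
#'
#' @param de a `cerna_de` table.
#' @param ... forwarded to the autoplot method.
#' @return a ggplot object.
#' @export
plot_volcano <- function(de, ...) autoplot(de, ...)

#' @export
autoplot.cerna_network <- function(object, ...) {
  s <- summarize_network(object) |>
    tidyr::pivot_longer(c("n_lnc", "n_mir", "n_mrna"),
                        names_to = "class", values_to = "n") |>
    mutate(class = dplyr::recode(.data$class, n_lnc = "lncRNA",
                                 n_mir = "miRNA", n_mrna = "mRNA"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mode, y = .data$n,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "ceRNA network mode", y = "distinct nodes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
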