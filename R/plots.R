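#' Plot a mining result
#'
#' Copy numbers per characterised lineage (total vs clean independent),
#' coloured by lineage status.
#'
#' @param object A `te_mining` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_mining <- function(object, ...) {
  ln <- object$lineages
  if (nrow(ln) == 0) stop("no characterised lineages to plot", call. = FALSE)
  df <- ln |>
    dplyr::select("lineage", "status", total = "total_copies",
                  clean = "clean_independent") |>
    tidyr::pivot_longer(c("total", "clean"), names_to = "count_type",
                        values_to = "copies")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$lineage, -.data$copies),
                                   y = .data$copies, fill = .data$status,
                                   alpha = .data$count_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(total = 0.45, clean = 1)) +
    ggplot2::labs(x = NULL, y = "copies", alpha = NULL, fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a mask report
#'
#' Genome fraction masked per superfamily.
#'
#' @param object A `mask_report` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mask_report <- function(object, ...) {
  df <- object$by_superfamily
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$superfamily,
                                                      -.data$fraction),
                                   y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of genome masked",
                  subtitle = sprintf("total: %.2f%%",
                                     100 * object$total_fraction)) +
    ggplot2::theme_minimal()
}
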