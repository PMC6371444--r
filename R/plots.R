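# ggplot2 quick-look plots for the result objects. Figures are a thin
# presentation layer; every number they show comes from the tidiers.

#' @export
autoplot.chromstrat_enrichment <- function(object, ...) {
  d <- tidy(object) |>
    mutate(signif = dplyr::case_when(
      .data$q_bh < 0.001 ~ "q < 0.001",
      .data$q_bh < 0.05 ~ "q < 0.05",
      TRUE ~ "ns"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$segments_name, y = .data$fold,
                                  fill = .data$signif)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~feature_name, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c("q < 0.001" = "#b2182b",
                                          "q < 0.05" = "#ef8a62",
                                          "ns" = "grey70")) +
    ggplot2::labs(x = NULL, y = "fold enrichment (obs/exp)", fill = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.chromstrat_score_matrix <- function(object, ...) {
  ggplot2::ggplot(average_profile(object),
                  ggplot2::aes(x = .data$rel_pos, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from centre (bp)", y = "mean signal") +
    ggplot2::theme_bw()
}

#' @export
autoplot.chromstrat_cormat <- function(object, ...) {
  d <- tidy(object) |>
    mutate(a = factor(.data$a, levels = object$labels),
           b = factor(.data$b, levels = object$labels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.chromstrat_expression_link <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(x = .data$dominant_group, y = .data$log_tpm,
                               fill = .data$dominant_group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "dominant remodeller group at promoter",
                  y = "log TPM") +
    ggplot2::theme_bw()
}

#' @export
autoplot.chromstrat_partition <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$class, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of genome") +
    ggplot2::theme_bw()
}
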