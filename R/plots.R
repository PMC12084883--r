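# ggplot2 views of result objects; U is the display label for internal T

relabel_u <- function(x) ifelse(x == "T", "U", x)

#' Plot isomiR class fractions across samples
#'
#' Stacked per-sample bars of the four 3'-end classes.
#'
#' @param fractions output of [class_fractions()] (rows from several samples
#'   may be bound together).
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$iso_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of reads", fill = "3' class") +
    ggplot2::theme_minimal()
}

#' Plot NT-tail nucleotide frequencies
#'
#' @param freqs output of [nt_nucleotide_freq()] (possibly several samples).
#' @return A ggplot object.
#' @export
plot_nt_freq <- function(freqs) {
  freqs |>
    mutate(base = relabel_u(.data$base)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$base, y = .data$freq,
                                 fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "non-templated tail nucleotide", y = "frequency",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tail_composition <- function(object, ...) {
  tidy(object) |>
    mutate(category = relabel_u(sub("mono\\(T\\)", "mono(U)", .data$category))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$tail_len, y = .data$count,
                                 fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "NT tail length (nt)", y = "reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tailscope_de <- function(object, padj_max = 0.05, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$p)) |>
    mutate(status = dplyr::case_when(
      !is.na(.data$padj) & .data$padj < padj_max & .data$log2fc > 0 ~ "up",
      !is.na(.data$padj) & .data$padj < padj_max & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue", ns = "grey70")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ "adjusted" ~ italic(P))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.polya_comparison <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-5, 5), linetype = "dashed") +
    ggplot2::labs(x = "median poly(A) length difference, KO - WT (nt)",
                  y = expression(-log[10] ~ "adjusted" ~ italic(P)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.monoa_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$lfc_monoA, y = .data$lfc_canonical)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression("mono(A) isomiR" ~ log[2] ~ "fold change"),
      y = expression("canonical isomiR" ~ log[2] ~ "fold change"),
      subtitle = sprintf("Pearson r = %s (n = %d)",
                         format(object$r, digits = 3), object$n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.interaction_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lfc_mirna, y = .data$lfc_gene,
                               colour = .data$sign_class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(negative = "darkorchid4",
                                            positive = "sienna4",
                                            undefined = "grey60")) +
    ggplot2::labs(x = expression("miRNA" ~ log[2] ~ "fold change"),
                  y = expression("target mRNA" ~ log[2] ~ "fold change"),
                  colour = "correlation sign") +
    ggplot2::theme_minimal()
}
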