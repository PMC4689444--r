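# ggplot2 views of the main result types.

#' Plot canonical motif-class frequencies
#'
#' Bar chart of the per-period canonical-class frequency table, one facet
#' per motif period.
#'
#' @param stats An `ssr_stats` object from [ssr_statistics()].
#' @return A ggplot object.
#' @export
plot_motif_frequency <- function(stats) {
  stopifnot(inherits(stats, "ssr_stats"))
  df <- tidy(stats) %>%
    mutate(period = paste0(.data$period, "-base motif"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$percent),
    y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~period, scales = "free_x") +
    ggplot2::labs(x = "canonical motif class", y = "% of loci") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 45, hjust = 1))
}

#' @export
autoplot.ssr_stats <- function(object, ...) plot_motif_frequency(object)

#' Plot PAL yield by motif period
#'
#' @param pals PAL tibble from [design_pals()].
#' @return A ggplot object.
#' @export
plot_pal_yield <- function(pals) {
  df <- count(pals, period = factor(.data$period))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "motif period (bases)", y = "PALs") +
    ggplot2::theme_minimal()
}

#' Plot repeat and gene content of a profiled run
#'
#' Fractions of reconstructed fragments assigned to each repeat class,
#' plus the gene-like fraction when available.
#'
#' @param run A `gssr_run` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_content_profile <- function(run) {
  stopifnot(inherits(run, "gssr_run"))
  df <- tibble(category = character(), percent = double())
  if (!is.null(run$profile$repeats)) {
    fr <- filter(run$profile$repeats$fractions, .data$class != "total")
    df <- bind_rows(df, tibble(category = fr$class,
                               percent = fr$percent))
  }
  if (!is.null(run$profile$gene_fraction)) {
    df <- bind_rows(df, tibble(category = "gene-like",
                               percent = run$profile$gene_fraction))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "% of reconstructed fragments") +
    ggplot2::theme_minimal()
}
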