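#' Plot scan results
#'
#' Significance profile of the scanned pairs: -log10 interaction p-value by
#' significance rank, coloured by whether the pair is intra- or
#' inter-chromosomal, with the scan threshold drawn as a dashed line.
#'
#' @param object An `epi_scan` tibble from [scan_all_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_scan <- function(object, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    rank = dplyr::row_number(.data$p),
    pair_type = ifelse(.data$chr1 == .data$chr2, "same chromosome", "different chromosomes")
  )
  thr <- attr(object, "p_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pair_type), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::labs(
      x = "pair rank", y = expression(-log[10](p)),
      colour = NULL,
      title = "SNP-SNP interaction scan",
      subtitle = sprintf(
        "%d significant of %s tested pairs",
        nrow(df), format(attr(object, "n_tests"), big.mark = ",")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a variance partition
#'
#' Stacked single-bar view of the three hierarchical R-squared components
#' of one pair fit.
#'
#' @param object An `epi_vpart` from [hierarchical_r2()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_vpart <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = rev(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = "pair", y = .data$r_squared, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = expression(R^2),
      title = "Hierarchical variance partition"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the top-pair variance partitions
#'
#' Stacked bars of covariate, main-effect and interaction R-squared for
#' each pair in a [partition_top_pairs()] table, ordered by interaction
#' delta R-squared.
#'
#' @param partition Tibble from [partition_top_pairs()].
#' @return A ggplot object.
#' @export
plot_partition_top <- function(partition) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(partition, pair = paste(.data$snp1, .data$snp2, sep = " x ")),
    cols = c("r2_cov", "delta_r2_main", "delta_r2_int"),
    names_to = "component", values_to = "r_squared"
  )
  df$component <- factor(
    df$component,
    levels = c("delta_r2_int", "delta_r2_main", "r2_cov"),
    labels = c("interaction", "main effects", "covariates")
  )
  df$pair <- stats::reorder(df$pair, df$r_squared, sum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$r_squared, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = expression(R^2), fill = NULL,
      title = "Variance explained by top interaction pairs"
    ) +
    ggplot2::theme_minimal()
}
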