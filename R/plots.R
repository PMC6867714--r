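#' Fragment-length ladder plot
#'
#' Overlaid 1 bp length histograms of the histone-strain and
#' empty-vector libraries, with the oligomer model lengths marked.
#'
#' @param strain_lengths,ev_lengths Fragment lengths (bp).
#' @param range Length range shown.
#' @return A ggplot object.
#' @export
plot_fragment_ladder <- function(strain_lengths, ev_lengths = NULL,
                                 range = c(20, 160)) {
  tb <- tibble::tibble(length = strain_lengths, library = "histone strain")
  if (!is.null(ev_lengths)) {
    tb <- dplyr::bind_rows(tb, tibble::tibble(length = ev_lengths,
                                              library = "empty vector"))
  }
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$length, colour = .data$library)) +
    ggplot2::geom_freqpoly(binwidth = 1) +
    ggplot2::geom_vline(xintercept = oligomer_length(1:4), linetype = 3) +
    ggplot2::coord_cartesian(xlim = range) +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  title = "Protected-fragment length distribution") +
    ggplot2::theme_minimal()
}

#' Heatmap of coverage around TSSs by fragment size
#' @param object A `tss_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tss_profile
#' @export
autoplot.tss_profile <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$distance, y = .data$size_bin,
                                 fill = .data$mean_coverage)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mean coverage") +
    ggplot2::labs(x = "distance from TSS (bp)", y = "fragment size (bp)") +
    ggplot2::theme_minimal()
}

#' Read-internal nucleotide enrichment plot
#' @param object A `nuc_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nuc_profile
#' @export
autoplot.nuc_profile <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$position, y = .data$enrichment,
                                 colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "position in fragment (bp)",
                  y = "enrichment over genome background") +
    ggplot2::theme_minimal()
}

#' Top and bottom univariately informative k-mers
#' @param eval A `model_eval` from [evaluate_model()].
#' @param n K-mers per direction.
#' @return A ggplot object.
#' @export
plot_kmer_ranking <- function(eval, n = 20) {
  tb <- dplyr::bind_rows(
    dplyr::mutate(utils::head(eval$univariate, n), direction = "top"),
    dplyr::mutate(utils::tail(eval$univariate, n), direction = "bottom"))
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$term, .data$rho),
                                   y = .data$rho, fill = .data$rho > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho with occupancy") +
    ggplot2::theme_minimal()
}

#' Group occupancy distributions per window type
#' @param assoc An `occupancy_association` from [window_occupancy()].
#' @param size_class Which track to show (default `"pooled"`).
#' @return A ggplot object.
#' @export
plot_occupancy_association <- function(assoc, size_class = "pooled") {
  assoc$per_gene |>
    dplyr::filter(.data$size_class == !!size_class, !.data$excluded,
                  !is.na(.data$group)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$mean_occ)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$window), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean normalized occupancy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
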