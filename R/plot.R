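#' Plot a copy-number profile
#'
#' Per-bin log2 ratios along the genome, optionally overlaid with
#' segment means and coloured by hard call when calls are supplied.
#'
#' @param profile A `cnv_profile`.
#' @param segments Optional `cnv_segments` to overlay.
#' @param calls Optional `cnv_calls` to colour bins by state.
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(profile, segments = NULL, calls = NULL) {
  stopifnot(inherits(profile, "cnv_profile"))
  df <- as_tibble(profile)
  df$call <- NA_integer_
  if (!is.null(calls)) {
    df$call <- calls$call[match(df$bin, calls$bin)]
  }
  df <- df[!is.na(df$log2), ]
  df$state <- factor(
    dplyr::case_when(
      is.na(df$call) ~ "uncalled",
      df$call <= -1 ~ "loss",
      df$call == 0 ~ "neutral",
      df$call == 1 ~ "gain",
      TRUE ~ "amplification"
    ),
    levels = c("loss", "neutral", "gain", "amplification", "uncalled")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$log2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state),
                        size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      loss = "#c0392b", neutral = "grey50", gain = "#27ae60",
      amplification = "#145a32", uncalled = "grey80"
    ), drop = FALSE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "bin", y = "log2 ratio",
                  title = attr(profile, "sample_id")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(segments)) {
    segdf <- segments$segments
    p <- p + ggplot2::geom_segment(
      data = segdf,
      ggplot2::aes(x = .data$first_bin, xend = .data$last_bin,
                   y = .data$mean_log2, yend = .data$mean_log2),
      inherit.aes = FALSE, colour = "black", linewidth = 0.8
    )
  }
  p
}

#' Heatmap of condensed-region calls across a cohort
#'
#' Regions on the x axis (widths proportional to region bin counts is
#' deliberately *not* attempted: one tile per region, so chromosome
#' sizes reflect informative breakpoint structure, not physical scale),
#' samples on the y axis in dendrogram leaf order, tiles coloured by
#' hard call.
#'
#' @param clustering A `cnv_clustering` from [cluster_samples()].
#' @return A ggplot object.
#' @export
plot_call_heatmap <- function(clustering) {
  stopifnot(inherits(clustering, "cnv_clustering"))
  heat <- clustering$heatmap
  heat$sample_id <- factor(heat$sample_id, levels = clustering$order)
  heat$state <- factor(
    dplyr::case_when(
      heat$call <= -1 ~ "loss",
      heat$call == 0 ~ "neutral",
      heat$call == 1 ~ "gain",
      TRUE ~ "amplification"
    ),
    levels = c("loss", "neutral", "gain", "amplification")
  )
  ggplot2::ggplot(heat, ggplot2::aes(x = .data$region, y = .data$sample_id,
                                     fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      loss = "#c0392b", neutral = "white", gain = "#27ae60",
      amplification = "#145a32"
    ), drop = FALSE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "condensed region", y = NULL, fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @rdname plot_cnv_profile
#' @param object,... Autoplot interface: a `cnv_profile`.
#' @method autoplot cnv_profile
#' @export
autoplot.cnv_profile <- function(object, ...) plot_cnv_profile(object, ...)

#' @rdname plot_call_heatmap
#' @param object,... Autoplot interface: a `cnv_clustering`.
#' @method autoplot cnv_clustering
#' @export
autoplot.cnv_clustering <- function(object, ...) plot_call_heatmap(object)
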