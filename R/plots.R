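#' Plot the delta-mass distribution with detected peaks
#'
#' @param psms PSM tibble (recalibrated).
#' @param peaks Optional peak tibble; apexes are marked.
#' @param binwidth Histogram bin width (Da).
#' @return A ggplot object.
#' @export
plot_delta_mass <- function(psms, peaks = NULL, binwidth = 0.01) {
  g <- ggplot2::ggplot(psms, ggplot2::aes(x = delta_mass)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = expression(Delta * "M (Da)"), y = "PSMs") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0)
    g <- g + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = apex),
                                 colour = "firebrick", linetype = 3,
                                 linewidth = 0.3)
  g
}

#' Heatmap of residue/quintile specificity profiles
#'
#' Mirrors the specificity landscape view: one row per delta-mass peak,
#' residue columns shaded by background-corrected frequency and quintile
#' columns by raw frequency.
#'
#' @param profiles A `ptm_specificity` object.
#' @param what `"residues"` or `"quintiles"`.
#' @return A ggplot object.
#' @export
plot_specificity <- function(profiles, what = c("residues", "quintiles")) {
  what <- match.arg(what)
  if (what == "residues") {
    d <- profiles$residues
    ggplot2::ggplot(d, ggplot2::aes(x = residue, y = peak_id,
                                    fill = corrected)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "white", high = "steelblue4",
                                    name = "corrected %") +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "residue", y = NULL)
  } else {
    d <- profiles$quintiles
    ggplot2::ggplot(d, ggplot2::aes(x = factor(quintile), y = peak_id,
                                    fill = freq)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "white", high = "sienna4",
                                   name = "% of PSMs") +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "sequence quintile", y = NULL)
  }
}

#' Heatmap of group contrasts for selected sites
#'
#' @param contrasts Output of [group_average()].
#' @param elements Optional subset of elements to show.
#' @return A ggplot object.
#' @export
plot_group_heatmap <- function(contrasts, elements = NULL) {
  d <- contrasts
  if (!is.null(elements)) d <- d[d$element %in% elements, ]
  ggplot2::ggplot(d, ggplot2::aes(x = group, y = element, fill = contrast)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "vs control")
}

#' Plot a clustering result on its correlation network
#'
#' @param object A `ptm_clusters` object.
#' @param ... Unused.
#' @return A ggplot object (nodes laid out with igraph's
#'   Fruchterman-Reingold, coloured by cluster).
#' @export
autoplot.ptm_clusters <- function(object, ...) {
  edges <- object$edges
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(element = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  memb <- tidy(object)[, c("element", "cluster")]
  nodes <- dplyr::left_join(nodes, memb, by = "element")
  seg <- dplyr::left_join(edges, nodes, by = c("from" = "element")) |>
    dplyr::left_join(nodes, by = c("to" = "element"),
                     suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = x, y = y, xend = x_to,
                                       yend = y_to),
                          colour = "grey80", linewidth = 0.2) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = x, y = y,
                                     colour = factor(cluster)), size = 1.5) +
    ggplot2::scale_colour_discrete(na.value = "grey60", name = "cluster") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
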