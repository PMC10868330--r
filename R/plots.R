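#' Plot a label similarity map
#'
#' Heatmap of the integrated Jaccard matrix in the clustering order (when
#' [cluster_labels()] has been run), or the MDS embedding when
#' `type = "mds"`.
#'
#' @param object A `similarity_map`.
#' @param type `"heatmap"` or `"mds"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_map <- function(object, type = c("heatmap", "mds"), ...) {
  type <- match.arg(type)
  if (type == "mds") {
    if (is.null(object$M)) object <- embed_mds(object)
    m <- object$M
    return(
      ggplot(m, aes(.data$dim1, .data$dim2, color = .data$reference)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::geom_text(aes(label = .data$subtype), vjust = -0.8, size = 3,
                           show.legend = FALSE) +
        ggplot2::labs(x = "MDS 1", y = "MDS 2",
                      title = "Label similarity map (classical MDS of 1 - Jaccard)")
    )
  }
  ord <- if (!is.null(object$H)) object$H$order else seq_len(nrow(object$J))
  keys <- rownames(object$J)[ord]
  df <- tidy.similarity_map(object)
  df$label_a <- factor(df$label_a, levels = keys)
  df$label_b <- factor(df$label_b, levels = keys)
  ggplot(df, aes(.data$label_a, .data$label_b, fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot spots colored by cluster, score or structure membership
#'
#' @param grid A `spot_grid`.
#' @param fill Optional vector (length = spots) or a `signature_scores` /
#'   `structure_call` table; defaults to the cluster labels.
#' @param label Legend title.
#' @return A ggplot object.
#' @export
plot_spots <- function(grid, fill = NULL, label = "value") {
  df <- grid$spots
  if (is.null(fill)) {
    df$value <- as.character(df$cluster)
    label <- "cluster"
  } else if (inherits(fill, "structure_call")) {
    df$value <- fill$in_structure[match(df$spot_id, fill$spot_id)]
    label <- "in structure"
  } else if (is.data.frame(fill)) {
    df$value <- fill$score[match(df$spot_id, fill$spot_id)]
    label <- "score"
  } else {
    df$value <- fill
  }
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_point(shape = 21, size = 2.4, stroke = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = label)
}

#' @rdname plot_spots
#' @param object A `structure_call`.
#' @param ... Unused.
#' @export
autoplot.structure_call <- function(object, ...) {
  df <- tibble(spot_id = object$spot_id, in_structure = object$in_structure)
  ggplot(df, aes(seq_along(.data$spot_id), as.integer(.data$in_structure))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "spot", y = "called",
                  title = sprintf("GMI = %.3f (%s strategy)",
                                  attr(object, "gmi"), attr(object, "strategy")))
}

#' Dot plot of ligand-receptor test results
#'
#' @param results Tibble from [lr_permutation_test()].
#' @return A ggplot object: pairs against strength, sized by -log10(p),
#'   significant pairs highlighted.
#' @export
plot_lr_results <- function(results) {
  df <- dplyr::mutate(results,
                      pair = paste(.data$ligand, .data$receptor, sep = " - "),
                      neglogp = -log10(pmax(.data$p, 1 / max(1, lengths(.data$null)[1]))))
  ggplot(df, aes(.data$strength, .data$pair, size = .data$neglogp,
                 color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "interaction strength", y = NULL,
                  size = "-log10 p", color = "significant")
}
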