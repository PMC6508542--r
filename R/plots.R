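#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' Overlay per-node mean shapes
#'
#' The node-1 mean (juvenile) is drawn in every panel under each node's
#' mean, the standard way of showing where along the series shape diverges
#' from the juvenile form.
#'
#' @param means a [node_mean_shapes()] tibble.
#' @param boundary landmark indices to connect, in margin order.
#' @return a ggplot.
#' @export
plot_node_means <- function(means, boundary = leaf_boundary_order()) {
  ring <- function(row) {
    m <- landmark_matrix(row)[boundary, ]
    tibble::tibble(x = c(m[, 1], m[1, 1]), y = c(m[, 2], m[1, 2]))
  }
  shapes <- means %>%
    dplyr::rowwise() %>%
    dplyr::group_split() %>%
    purrr::map_dfr(function(r) dplyr::mutate(ring(r), node = r$node))
  juvenile <- dplyr::mutate(shapes[shapes$node == min(shapes$node), ], node = NULL)
  ggplot(shapes, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = juvenile, colour = "darkgreen", linewidth = 0.4) +
    ggplot2::geom_path(colour = "magenta4") +
    ggplot2::facet_wrap(~node, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Allometric scatter of sqrt subareas against sqrt total area
#'
#' @param subareas a [subarea_table()] tibble.
#' @param fits an optional [fit_allometry()] result whose lines and 95%
#'   confidence bands are superimposed.
#' @param colour_by identity column mapped to point colour (e.g. `"node"`).
#' @return a ggplot.
#' @export
plot_allometry <- function(subareas, fits = NULL, colour_by = NULL) {
  regions <- sub("^area_", "", grep("^area_(?!total)", names(subareas), value = TRUE, perl = TRUE))
  long <- subareas %>%
    tidyr::pivot_longer(dplyr::all_of(paste0("area_", regions)),
                        names_to = "subregion", values_to = "area") %>%
    dplyr::mutate(subregion = sub("^area_", "", .data$subregion))
  p <- ggplot(long, aes(x = sqrt(.data$area_total), y = sqrt(.data$area))) +
    ggplot2::facet_wrap(~subregion, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = expression(sqrt("total area")), y = expression(sqrt("subarea")))
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_point(alpha = 0.4, size = 0.8)
  } else {
    p + ggplot2::geom_point(aes(colour = .data[[colour_by]]), alpha = 0.6, size = 0.8)
  }
  if (!is.null(fits)) {
    xr <- range(sqrt(subareas$area_total))
    bands <- fits %>%
      dplyr::rowwise() %>%
      dplyr::group_split() %>%
      purrr::map_dfr(function(f) {
        dplyr::mutate(allometry_band(f, seq(xr[1], xr[2], length.out = 50)),
                      subregion = f$subregion, group = f$group)
      })
    p <- p +
      ggplot2::geom_ribbon(data = bands,
                           aes(x = .data$x, ymin = .data$lower, ymax = .data$upper,
                               group = .data$group),
                           inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(data = bands,
                         aes(x = .data$x, y = .data$fit, group = .data$group),
                         inherit.aes = FALSE, linewidth = 0.3)
  }
  p
}

#' Effect heatmap (species, heteroblasty or interaction terms)
#'
#' Colour encodes effect direction (positive magenta, negative green),
#' opacity its magnitude; traits are ordered by hierarchical clustering.
#'
#' @param effects an [effect_matrices()] tibble.
#' @param term which term to draw.
#' @return a ggplot.
#' @export
plot_effect_heatmap <- function(effects, term = c("species", "interaction", "heteroblasty")) {
  term <- match.arg(term)
  sub <- effects[effects$term == term & !effects$constant, ]
  wide <- tidyr::pivot_wider(sub[, c("trait", "species", "estimate")],
                             names_from = "trait", values_from = "estimate")
  ord <- cluster_traits(t(as.matrix(wide[, -1])))$labels
  sub$trait <- factor(sub$trait, levels = ord)
  sub$row <- if (term == "heteroblasty") "heteroblasty" else sub$species
  ggplot(sub, aes(x = .data$trait, y = .data$row,
                  fill = sign(.data$estimate), alpha = abs(.data$estimate))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "grey90", high = "magenta3",
                                  guide = "none") +
    ggplot2::scale_alpha_continuous(range = c(0.05, 1), name = "|effect|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "trait (clustered)", y = NULL,
                  title = sprintf("%s effects", term))
}

#' Heatmap of per-node correct species assignment
#'
#' @param table a [node_discrimination_table()] result.
#' @return a ggplot with a per-node average row at the bottom.
#' @export
plot_discrimination <- function(table) {
  avg <- node_accuracy(table) %>%
    dplyr::mutate(species = "average", prop_correct = .data$average)
  df <- dplyr::bind_rows(table[, c("node", "species", "prop_correct")],
                         avg[, c("node", "species", "prop_correct")])
  df$species <- factor(df$species, levels = c(sort(unique(table$species)), "average"))
  ggplot(df, aes(x = .data$node, y = .data$species, fill = .data$prop_correct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("black", "orange", "yellow"),
                                  limits = c(0, 1), name = "correct") +
    ggplot2::scale_x_continuous(breaks = unique(df$node)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "heteroblastic node", y = NULL)
}

#' Heatmap of per-node trait standard deviations
#'
#' @param sds a [trait_sd_by_node()] tibble.
#' @return a ggplot with traits clustered on their node profiles.
#' @export
plot_trait_sd <- function(sds) {
  wide <- tidyr::pivot_wider(sds[, c("trait", "node", "sd")],
                             names_from = "node", values_from = "sd")
  ord <- cluster_traits(wide)$labels
  sds$trait <- factor(sds$trait, levels = ord)
  ggplot(sds, aes(x = .data$node, y = .data$trait, fill = .data$sd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("black", "orange", "yellow"), name = "SD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "heteroblastic node", y = "trait (clustered)")
}

#' Trajectory vectors in embedding space
#'
#' @param vectors a [vine_vectors()] tibble (optionally [center_vectors()]ed).
#' @param colour_by identity column mapped to arrow colour.
#' @return a ggplot of one arrow per vine, base marked with a hollow circle.
#' @export
plot_trajectories <- function(vectors, colour_by = "class_label") {
  mapping <- if (colour_by %in% names(vectors)) aes(colour = .data[[colour_by]]) else aes()
  ggplot(vectors) +
    ggplot2::geom_segment(aes(x = .data$base_dim1, y = .data$base_dim2,
                              xend = .data$tip_dim1, yend = .data$tip_dim2,
                              !!!mapping),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(aes(x = .data$base_dim1, y = .data$base_dim2),
                        shape = 21, fill = "white", colour = "black", size = 1.5) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2")
}

#' @export
autoplot.leaf_gpa <- function(object, ...) {
  cloud <- purrr::map_dfr(seq_along(object$aligned), function(i) {
    m <- object$aligned[[i]]
    tibble::tibble(leaf = i, landmark = seq_len(nrow(m)), x = m[, 1], y = m[, 2])
  })
  mean_df <- tibble::tibble(x = object$mean_shape[, 1], y = object$mean_shape[, 2])
  ggplot(cloud, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5, colour = "steelblue") +
    ggplot2::geom_point(data = mean_df, colour = "black", size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Procrustes-aligned landmarks and mean shape")
}

#' @export
autoplot.leaf_embedding <- function(object, colour_by = "class_label", ...) {
  mapping <- if (colour_by %in% names(object)) aes(colour = .data[[colour_by]]) else aes()
  ggplot(object, aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(mapping, size = 0.8, alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2")
}

#' @export
autoplot.allometric_fit <- function(object, ...) {
  ggplot(object, aes(x = .data$subregion, y = .data$slope, colour = .data$group)) +
    ggplot2::geom_pointrange(aes(ymin = .data$slope - 1.96 * .data$slope_se,
                                 ymax = .data$slope + 1.96 * .data$slope_se),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "sqrt-area slope", x = NULL)
}
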