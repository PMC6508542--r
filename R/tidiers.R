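#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a generalized Procrustes fit into one row per landmark per leaf
#'
#' @param x a `leaf_gpa` object.
#' @param ... unused.
#' @return a tibble `leaf`, `landmark`, `x`, `y`, `centroid_size`.
#' @export
tidy.leaf_gpa <- function(x, ...) {
  sizes <- x$centroid_sizes
  purrr::map_dfr(seq_along(x$aligned), function(i) {
    m <- x$aligned[[i]]
    tibble::tibble(leaf = i, landmark = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2],
                   centroid_size = sizes[i])
  })
}

#' One-row summary of a generalized Procrustes fit
#'
#' @param x a `leaf_gpa` object.
#' @param ... unused.
#' @return a tibble with `n`, `landmarks`, `iterations`, `converged`,
#'   `mean_residual` (root mean squared Procrustes residual to the mean).
#' @export
glance.leaf_gpa <- function(x, ...) {
  resid <- vapply(x$aligned, function(m) sqrt(sum((m - x$mean_shape)^2)), 0)
  tibble::tibble(
    n = length(x$aligned), landmarks = nrow(x$mean_shape),
    iterations = x$iterations, converged = x$converged,
    mean_residual = mean(resid)
  )
}

#' Tidy an allometric fit table (already one row per line; returned as-is
#' with a stable column order)
#'
#' @param x an `allometric_fit` tibble.
#' @param ... unused.
#' @export
tidy.allometric_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("group", "subregion", "slope", "slope_se",
                           "intercept", "intercept_se", "r_squared", "n")]
}

#' One-row-per-group summary of allometric fits
#'
#' @param x an `allometric_fit` tibble.
#' @param ... unused.
#' @return per group: `n`, mean blade and vein slopes and their difference.
#' @export
glance.allometric_fit <- function(x, ...) {
  x %>%
    dplyr::mutate(kind = ifelse(grepl("blade", .data$subregion), "blade", "vein")) %>%
    dplyr::group_by(group = .data$group) %>%
    dplyr::summarise(
      n = dplyr::first(.data$n),
      blade_slope = mean(.data$slope[.data$kind == "blade"]),
      vein_slope = mean(.data$slope[.data$kind == "vein"]),
      slope_gap = .data$blade_slope - .data$vein_slope,
      .groups = "drop"
    )
}

#' Tidy a leave-one-out discrimination result
#'
#' @param x a `node_discrimination` object.
#' @param ... unused.
#' @return the per-species proportions tibble.
#' @export
tidy.node_discrimination <- function(x, ...) x$proportions

#' One-row summary of a leave-one-out discrimination result
#'
#' @param x a `node_discrimination` object.
#' @param ... unused.
#' @export
glance.node_discrimination <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$proportions),
    n_leaves = sum(x$proportions$n),
    average = x$average,
    n_excluded = length(x$excluded)
  )
}

#' Tidy an effect table (stable column order)
#'
#' @param x an `effect_table` tibble.
#' @param ... unused.
#' @export
tidy.effect_table <- function(x, ...) {
  tibble::as_tibble(x)[, c("trait", "term", "species", "estimate", "se",
                           "estimable", "constant")]
}

#' Per-term magnitude summary of an effect table
#'
#' @param x an `effect_table` tibble.
#' @param ... unused.
#' @return per term: number of estimates and mean |effect| over
#'   non-constant, estimable traits.
#' @export
glance.effect_table <- function(x, ...) {
  x %>%
    dplyr::filter(!.data$constant, .data$estimable) %>%
    dplyr::group_by(term = .data$term) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_effect = mean(abs(.data$estimate)),
                     .groups = "drop")
}
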