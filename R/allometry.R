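#' Area of a simple polygon
#'
#' Absolute shoelace area of the polygon through the given vertices.
#'
#' @param points an n x 2 matrix of vertices (n >= 3, closed implicitly).
#' @return a nonnegative scalar.
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop_validation("a polygon needs at least 3 vertices")
  abs(signed_area(points))
}

#' Default subdivision of the 15-landmark leaf into subarea polygons
#'
#' Splits the whole-leaf polygon (through the margin landmarks) into four
#' named subregions — distal blade, proximal blade, midvein and proximal
#' vein — given as lists of landmark-index rings. A subregion may consist
#' of more than one simple part (the midvein strip splits each blade into a
#' left and a right part); parts share their internal chords exactly, so
#' the subareas sum to the total area identically on any configuration on
#' which every part keeps its orientation. The index lists are
#' configuration, not code: alternative subdivisions can be supplied to
#' [leaf_subareas()] in the same format.
#'
#' @return a `polygon_spec` list: `subregions` (named list of lists of index
#'   rings, counter-clockwise on the template) and `total` (margin ring).
#' @export
default_polygon_spec <- function() {
  structure(list(
    subregions = list(
      distal_blade = list(c(3L, 13L, 9L, 7L), c(2L, 7L, 8L, 12L)),
      proximal_blade = list(c(1L, 5L, 11L, 15L, 13L, 3L), c(1L, 2L, 12L, 14L, 10L, 4L)),
      midvein = list(c(1L, 3L, 7L, 2L)),
      proximal_vein = list(c(1L, 15L, 11L, 5L), c(14L, 1L, 4L, 10L))
    ),
    total = leaf_boundary_order()
  ), class = "polygon_spec")
}

#' Subareas of one aligned leaf configuration
#'
#' Shoelace area of each subregion polygon plus the whole-leaf polygon.
#' If any subregion part loses its counter-clockwise orientation on this
#' configuration (a folded or self-intersecting polygon, e.g. from
#' coincident landmarks under noise), the record is flagged: its areas are
#' still reported (absolute values) but closure is not guaranteed.
#'
#' @param config a 15 x 2 landmark matrix (typically Procrustes-aligned).
#' @param spec a [default_polygon_spec()]-style subdivision.
#' @return a one-row tibble `area_distal_blade, area_proximal_blade,
#'   area_midvein, area_proximal_vein, area_total, flagged`.
#' @export
leaf_subareas <- function(config, spec = default_polygon_spec()) {
  config <- as.matrix(config)
  signed <- lapply(spec$subregions, function(parts) {
    vapply(parts, function(ring) signed_area(config[ring, , drop = FALSE]), 0)
  })
  flagged <- any(unlist(signed) < -1e-12)
  areas <- vapply(signed, function(a) sum(abs(a)), 0)
  out <- tibble::as_tibble(as.list(stats::setNames(areas, paste0("area_", names(areas)))))
  out$area_total <- abs(signed_area(config[spec$total, , drop = FALSE]))
  out$flagged <- flagged
  out
}

#' Subarea table for every leaf in an aligned collection
#'
#' @param collection an aligned leaf collection ([align_leaves()]).
#' @param spec a [default_polygon_spec()]-style subdivision.
#' @return a tibble: leaf identity columns, the four subareas, `area_total`
#'   and `flagged` (orientation-degenerate records); a quality warning is
#'   raised if any record is flagged.
#' @export
subarea_table <- function(collection, spec = default_polygon_spec()) {
  areas <- dplyr::bind_rows(lapply(seq_len(nrow(collection)), function(i) {
    leaf_subareas(landmark_matrix(collection[i, ]), spec)
  }))
  out <- dplyr::bind_cols(
    collection[, intersect(c("species", "class_label", "vine", "node"), names(collection))],
    areas
  )
  if (any(out$flagged)) {
    warn_quality(sprintf(
      "%d of %d leaves have degenerate subregion polygons; closure not guaranteed for them",
      sum(out$flagged), nrow(out)
    ))
  }
  out
}

#' Square-root allometric regressions of subareas on total area
#'
#' For each subregion (and each group, if grouping), ordinary least squares
#' of `sqrt(subarea)` on `sqrt(total area)`. The square-root transform puts
#' both axes on a length scale, where area growth of leaf parts is linear
#' in overall size. Zero-area subregions contribute `sqrt(0) = 0` and are
#' not excluded.
#'
#' @param subareas a [subarea_table()] (or [simulate_subareas()]) tibble.
#' @param group_by `"overall"` for one pooled fit per subregion, or the
#'   name of a grouping column (e.g. `"species"`).
#' @param drop_flagged exclude records flagged as degenerate.
#' @return an `allometric_fit` tibble: `group`, `subregion`, `slope`,
#'   `intercept`, their standard errors, `slope_intercept_cov`, `sigma`,
#'   `r_squared`, `n`, and the mean and spread of the regressor needed to
#'   draw pointwise 95% confidence bands. Groups with fewer than 3 records
#'   or no size variation are skipped with a warning.
#' @export
fit_allometry <- function(subareas, group_by = "overall", drop_flagged = TRUE) {
  df <- subareas
  if (drop_flagged && "flagged" %in% names(df)) df <- df[!df$flagged, ]
  regions <- sub("^area_", "", grep("^area_(?!total)", names(df), value = TRUE, perl = TRUE))
  df$.group <- if (identical(group_by, "overall")) "overall" else {
    if (!group_by %in% names(df)) stop_validation(sprintf("no grouping column '%s'", group_by))
    as.character(df[[group_by]])
  }
  out <- list()
  for (g in unique(df$.group)) {
    sub <- df[df$.group == g, ]
    if (nrow(sub) < 3L) {
      warn_quality(sprintf("group '%s' has %d records (< 3); skipped", g, nrow(sub)))
      next
    }
    x <- sqrt(sub$area_total)
    if (stats::sd(x) < 1e-12) {
      warn_quality(sprintf("group '%s': total area is constant; slope undefined, skipped", g))
      next
    }
    for (r in regions) {
      y <- sqrt(sub[[paste0("area_", r)]])
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)
      cf <- stats::coef(sm)
      vc <- stats::vcov(fit)
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, subregion = r,
        slope = cf["x", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
        slope_se = cf["x", "Std. Error"], intercept_se = cf["(Intercept)", "Std. Error"],
        slope_intercept_cov = vc["(Intercept)", "x"],
        sigma = sm$sigma, r_squared = sm$r.squared,
        n = nrow(sub), x_mean = mean(x), x_ssq = sum((x - mean(x))^2)
      )
    }
  }
  if (length(out) == 0L) stop_validation("no group with enough records to fit")
  res <- dplyr::bind_rows(out)
  class(res) <- c("allometric_fit", class(res))
  res
}

#' Pointwise 95% confidence band of an allometric fit
#'
#' @param fit one row of an `allometric_fit` tibble.
#' @param x sqrt-total-area values at which to evaluate the band.
#' @return a tibble `x, fit, lower, upper`.
#' @export
allometry_band <- function(fit, x) {
  stopifnot(nrow(fit) == 1L)
  pred <- fit$intercept + fit$slope * x
  se <- fit$sigma * sqrt(1 / fit$n + (x - fit$x_mean)^2 / fit$x_ssq)
  tcrit <- stats::qt(0.975, df = fit$n - 2L)
  tibble::tibble(x = x, fit = pred, lower = pred - tcrit * se, upper = pred + tcrit * se)
}
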