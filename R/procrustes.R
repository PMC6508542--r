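#' Center a landmark configuration and scale it to unit centroid size
#'
#' Centroid size is the root summed squared distance of the landmarks to
#' their centroid; it is the size measure removed by Procrustes scaling.
#'
#' @param config a landmarks x 2 numeric matrix.
#' @return a list with `config` (centered, unit-size matrix) and `size`
#'   (the input's centroid size).
#' @export
center_scale <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop_degenerate("need at least 2 landmarks")
  ctr <- colMeans(config)
  centered <- sweep(config, 2L, ctr)
  size <- sqrt(sum(centered^2))
  if (size < 1e-12) stop_degenerate("all landmarks coincide: centroid size is zero")
  list(config = centered / size, size = size)
}

#' Optimal orthogonal superimposition of one configuration onto another
#'
#' Finds the orthogonal map `R` (rotation, or rotation-plus-reflection if
#' allowed) minimizing the summed squared distance between `A` and `B %*% R`.
#' Both configurations are expected centered and of unit centroid size.
#'
#' @param A,B landmarks x 2 matrices with equal row counts.
#' @param allow_reflection if `FALSE`, `R` is constrained to determinant +1.
#' @return list with `rotation` (2 x 2 orthogonal matrix, applied on the
#'   right of `B`) and `residual` (root summed squared distance after the
#'   optimal superimposition).
#' @export
superimpose <- function(A, B, allow_reflection = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) {
    stop_validation(sprintf("landmark counts differ: %d vs %d", nrow(A), nrow(B)))
  }
  M <- crossprod(B, A)  # maximize tr(R' M)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    # flip the direction with the smallest singular value
    flip <- diag(c(1, -1))
    R <- sv$u %*% flip %*% t(sv$v)
  }
  resid <- sqrt(max(0, sum((A - B %*% R)^2)))
  list(rotation = R, residual = resid)
}

#' Generalized Procrustes analysis of landmark configurations
#'
#' Iteratively superimposes all configurations (translation removed,
#' centroid size fixed to 1, optimal rotation and optionally reflection)
#' onto their evolving mean shape until the mean moves less than `tol`
#' between iterations. The global orientation, which generalized Procrustes
#' analysis leaves free, is anchored by rotating the whole solution so the
#' final mean shape is optimally superimposed on the first input
#' configuration.
#'
#' @param configs a list of landmarks x 2 matrices with equal row counts.
#' @param allow_reflection allow improper rotations (mirroring) during
#'   superimposition; the default matches reflection-tolerant alignment of
#'   leaf scans.
#' @param tol convergence tolerance on the root-summed-squares movement of
#'   the mean shape.
#' @param max_iter iteration cap.
#' @return an object of class `leaf_gpa`: list with `aligned` (list of
#'   aligned configurations, input order), `mean_shape`, `centroid_sizes`,
#'   `iterations`, `converged`.
#' @export
gpa <- function(configs, allow_reflection = TRUE, tol = 1e-8, max_iter = 100L) {
  if (length(configs) < 2L) stop_validation("need at least 2 configurations")
  k <- nrow(as.matrix(configs[[1]]))
  cs <- lapply(configs, center_scale)
  X <- lapply(cs, `[[`, "config")
  if (any(vapply(X, nrow, 0L) != k)) stop_validation("landmark counts differ across configurations")
  sizes <- vapply(cs, `[[`, 0, "size")

  mean_shape <- X[[1]]
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    X <- lapply(X, function(cfg) {
      cfg %*% superimpose(mean_shape, cfg, allow_reflection)$rotation
    })
    new_mean <- Reduce(`+`, X) / length(X)
    # re-normalize the reference so convergence is measured in shape space
    ref <- center_scale(new_mean)$config
    delta <- sqrt(sum((ref - center_scale(mean_shape)$config)^2))
    mean_shape <- ref
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  mean_raw <- Reduce(`+`, X) / length(X)
  # deterministic global orientation: anchor the mean to the first input
  anchor <- superimpose(X[[1]], center_scale(mean_raw)$config, allow_reflection)$rotation
  X <- lapply(X, function(cfg) cfg %*% anchor)
  mean_raw <- Reduce(`+`, X) / length(X)
  structure(
    list(aligned = X, mean_shape = mean_raw, centroid_sizes = sizes,
         iterations = iterations, converged = converged),
    class = "leaf_gpa"
  )
}

#' @export
print.leaf_gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes analysis: %d configurations x %d landmarks, %d iterations (%s)\n",
    length(x$aligned), nrow(x$mean_shape), x$iterations,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Procrustes distance between two landmark configurations
#'
#' Root summed squared distance after centering, unit-size scaling and
#' optimal superimposition. Symmetric, zero for configurations related by a
#' similarity transform (including reflection when allowed).
#'
#' @inheritParams superimpose
#' @return a nonnegative scalar.
#' @export
procrustes_distance <- function(A, B, allow_reflection = TRUE) {
  a <- center_scale(A)$config
  b <- center_scale(B)$config
  superimpose(a, b, allow_reflection)$residual
}

#' Align every leaf in a collection by generalized Procrustes analysis
#'
#' @param collection a leaf collection with raw landmark coordinates.
#' @param allow_reflection passed to [gpa()].
#' @return the collection with coordinates replaced by their aligned values
#'   (centered, unit centroid size, common orientation), a `centroid_size`
#'   column holding each leaf's original size, and the fitted `leaf_gpa`
#'   object in attribute `"gpa"`.
#' @export
align_leaves <- function(collection, allow_reflection = TRUE) {
  configs <- lapply(seq_len(nrow(collection)), function(i) landmark_matrix(collection[i, ]))
  fit <- gpa(configs, allow_reflection = allow_reflection)
  coords <- t(vapply(fit$aligned, landmark_vector, numeric(2L * N_LANDMARKS)))
  out <- collection
  out[, coord_names()] <- tibble::as_tibble(coords)
  out$centroid_size <- fit$centroid_sizes
  out <- restore_collection(out, collection, aligned = TRUE)
  attr(out, "gpa") <- fit
  out
}

#' Per-node mean shapes of an aligned collection
#'
#' For each heteroblastic node (base-first numbering), the coordinate-wise
#' mean of the aligned configurations at that node. Superimposing these
#' means is how node-to-node shape change is visualized.
#'
#' @param collection an aligned leaf collection ([align_leaves()]).
#' @return a tibble with `node`, `n` (leaves averaged) and the mean
#'   coordinate columns; one row per node present in the collection.
#' @export
node_mean_shapes <- function(collection) {
  if (!isTRUE(attr(collection, "aligned"))) {
    warn_quality("collection does not look Procrustes-aligned; node means mix raw coordinates")
  }
  collection %>%
    dplyr::group_by(node = .data$node) %>%
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(coord_names()), mean),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$node)
}
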