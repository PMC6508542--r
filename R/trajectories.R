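#' Two-dimensional embedding of all leaves
#'
#' Reduces the joint trait space (aligned landmarks plus normalized EFD
#' coefficients) to two dimensions. The default is t-distributed stochastic
#' neighbor embedding at perplexity 40, computed exactly (no tree
#' approximation) and deterministically for a given seed; principal
#' components are available as a fast deterministic alternative.
#'
#' @param traits a tibble with identity columns and numeric trait columns.
#' @param method `"tsne"` or `"pca"`.
#' @param perplexity t-SNE perplexity; auto-reduced to `floor((n - 1) / 3)`
#'   with a warning when the collection is too small.
#' @param seed integer seed controlling the embedding initialization.
#' @param n_iter t-SNE gradient iterations.
#' @return a `leaf_embedding` tibble: the identity columns of `traits`
#'   plus `dim1`, `dim2`; attributes `method`, `perplexity`, `seed`.
#' @export
embed_2d <- function(traits, method = c("tsne", "pca"), perplexity = 40,
                     seed = 1L, n_iter = 600L) {
  method <- match.arg(method)
  tcols <- trait_columns(traits)
  X <- as.matrix(traits[, tcols])
  if (!all(is.finite(X))) stop_validation("trait columns contain non-finite values")
  n <- nrow(X)
  if (n < 10L) stop_validation("need at least 10 leaves to embed")
  eff_perp <- perplexity
  if (method == "tsne" && n < 3 * perplexity + 1) {
    eff_perp <- floor((n - 1) / 3)
    warn_quality(sprintf("perplexity reduced from %g to %g for n = %d",
                         perplexity, eff_perp, n))
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  # identical trait rows are one point in shape space: embed unique rows and
  # give duplicates identical coordinates
  key <- apply(X, 1L, paste, collapse = "\r")
  first <- match(key, key)
  uniq <- which(first == seq_along(key))
  Xu <- X[uniq, , drop = FALSE]
  Y <- if (method == "tsne") {
    Yu <- tsne_exact(Xu, perplexity = min(eff_perp, floor((nrow(Xu) - 1) / 3)),
                     seed = derive_seed(seed, "tsne"), n_iter = n_iter)
    Yu[match(first, uniq), , drop = FALSE]
  } else {
    p <- stats::prcomp(X, rank. = 2L)
    s <- sign(colSums(p$rotation^3))  # deterministic axis signs
    sweep(p$x[, 1:2, drop = FALSE], 2L, ifelse(s == 0, 1, s), `*`)
  }
  out <- dplyr::bind_cols(
    traits[, setdiff(names(traits), tcols)],
    tibble::tibble(dim1 = Y[, 1], dim2 = Y[, 2])
  )
  attr(out, "method") <- method
  attr(out, "perplexity") <- if (method == "tsne") eff_perp else NA_real_
  attr(out, "seed") <- seed
  class(out) <- c("leaf_embedding", class(out))
  out
}

#' Heteroblastic trajectory vector of each vine
#'
#' One vector per vine in embedding space: the base is the embedded
#' position of the vine's first sampled node (lowest node number,
#' base-first), the tip that of its furthest sampled node. Each vector is
#' the shape space the vine traverses across its heteroblastic series.
#'
#' @param embedding a [embed_2d()] result carrying `vine`, `node`, `dim1`,
#'   `dim2` (and `species` / `class_label` if available).
#' @return a `vine_vectors` tibble: `vine`, `species`, `class_label`,
#'   `base_node`, `tip_node`, `base_dim1`, `base_dim2`, `tip_dim1`,
#'   `tip_dim2`. Vines with a single leaf are skipped with a warning.
#' @export
vine_vectors <- function(embedding) {
  needed <- c("vine", "node", "dim1", "dim2")
  if (!all(needed %in% names(embedding))) {
    stop_validation("embedding must carry vine, node, dim1, dim2")
  }
  singles <- embedding %>%
    dplyr::count(.data$vine) %>%
    dplyr::filter(.data$n < 2L)
  if (nrow(singles) > 0L) {
    warn_quality(sprintf("skipping %d vine(s) with a single leaf", nrow(singles)))
  }
  out <- embedding %>%
    dplyr::filter(!.data$vine %in% singles$vine) %>%
    dplyr::group_by(.data$vine) %>%
    dplyr::arrange(.data$node, .by_group = TRUE) %>%
    dplyr::summarise(
      species = if ("species" %in% names(embedding)) dplyr::first(.data$species) else NA_character_,
      class_label = if ("class_label" %in% names(embedding)) dplyr::first(.data$class_label) else NA_character_,
      base_node = dplyr::first(.data$node), tip_node = dplyr::last(.data$node),
      base_dim1 = dplyr::first(.data$dim1), base_dim2 = dplyr::first(.data$dim2),
      tip_dim1 = dplyr::last(.data$dim1), tip_dim2 = dplyr::last(.data$dim2),
      .groups = "drop"
    )
  class(out) <- c("vine_vectors", class(out))
  out
}

#' Translate every trajectory vector's base to the origin
#'
#' Centering exposes the direction and magnitude of each vine's
#' heteroblastic shape change, independent of where in shape space it
#' started; vector lengths are preserved exactly.
#'
#' @param vectors a [vine_vectors()] tibble.
#' @return the tibble with `base_dim1 = base_dim2 = 0` and tips replaced by
#'   tip - base (idempotent).
#' @export
center_vectors <- function(vectors) {
  if (nrow(vectors) == 0L) stop_validation("no vectors to center")
  out <- vectors %>%
    dplyr::mutate(
      tip_dim1 = .data$tip_dim1 - .data$base_dim1,
      tip_dim2 = .data$tip_dim2 - .data$base_dim2,
      base_dim1 = 0, base_dim2 = 0
    )
  class(out) <- class(vectors)
  out
}

#' Juvenile-convergence statistic of trajectory vectors
#'
#' Dispersion (mean pairwise Euclidean distance) among vector bases and
#' among vector tips, and their ratio. A ratio below 1 quantifies juvenile
#' convergence: vines start from a tight shared region of shape space and
#' fan out toward divergent adult shapes.
#'
#' @param vectors a [vine_vectors()] tibble (>= 3 vectors).
#' @return a tibble `base_dispersion`, `tip_dispersion`, `ratio`.
#' @export
convergence_stat <- function(vectors) {
  if (nrow(vectors) < 3L) stop_validation("need at least 3 vectors")
  disp <- function(x, y) mean(stats::dist(cbind(x, y)))
  base <- disp(vectors$base_dim1, vectors$base_dim2)
  tip <- disp(vectors$tip_dim1, vectors$tip_dim2)
  tibble::tibble(
    base_dispersion = base,
    tip_dispersion = tip,
    ratio = if (tip > 0) base / tip else NA_real_
  )
}
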