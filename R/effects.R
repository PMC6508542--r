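#' Decompose one trait into species, heteroblasty and interaction effects
#'
#' Ordinary least squares of `trait ~ species * node` with treatment coding:
#' the reference species is absorbed into the intercept, node enters as a
#' numeric covariate (one heteroblasty slope), and each non-reference
#' species gets an offset (species effect) and a node-slope offset
#' (species-by-heteroblasty interaction effect).
#'
#' @param trait numeric response vector.
#' @param species character/factor vector of species labels.
#' @param node integer vector of node positions (base-first).
#' @param reference reference species; defaults to the alphabetically first
#'   label.
#' @return a tibble with one row per model term: `term` (`"species"`,
#'   `"heteroblasty"` or `"interaction"`), `species` (`NA` for the
#'   heteroblasty row), `estimate`, `se`, `estimable`.
#' @export
fit_trait_model <- function(trait, species, node, reference = NULL) {
  et <- effect_matrices(
    tibble::tibble(species = as.character(species), node = as.integer(node), trait = trait),
    reference = reference
  )
  et[, c("term", "species", "estimate", "se", "estimable")]
}

#' Species / heteroblasty / interaction effect table for many traits
#'
#' Fits `trait ~ species * node` to every trait column at once (one shared
#' design matrix, treatment coding, node numeric) and returns the
#' coefficient table the effect heatmaps are drawn from. Traits that are
#' constant get zero effects and `constant = TRUE`; coefficients that are
#' not estimable (rank-deficient design, e.g. a species observed at a
#' single node) are flagged.
#'
#' @param traits a tibble with `species`, `node` and numeric trait columns
#'   (all other numeric columns are treated as traits).
#' @param reference reference species (intercept); default alphabetically
#'   first.
#' @param include_reference also emit the reference species' rows, which
#'   are exactly zero by coding.
#' @return an `effect_table` tibble: `trait`, `term`, `species`,
#'   `estimate`, `se`, `estimable`, `constant`; attributes `reference` and
#'   `intercepts` (per-trait intercept and node slope of the reference).
#' @export
effect_matrices <- function(traits, reference = NULL, include_reference = FALSE) {
  if (!all(c("species", "node") %in% names(traits))) {
    stop_validation("traits must carry 'species' and 'node' columns")
  }
  sp <- as.character(traits$species)
  levels <- sort(unique(sp))
  if (length(levels) < 2L) stop_validation("need at least 2 species")
  if (length(unique(traits$node)) < 2L) stop_validation("need at least 2 distinct nodes")
  if (is.null(reference)) reference <- levels[1]
  if (!reference %in% levels) {
    stop_validation(sprintf("reference species '%s' not present", reference))
  }
  fsp <- stats::relevel(factor(sp, levels = levels), ref = reference)
  node <- as.numeric(traits$node)
  trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)], c("node"))
  if (length(trait_cols) == 0L) stop_validation("no numeric trait columns")
  Y <- as.matrix(traits[, trait_cols])
  if (!all(is.finite(Y))) stop_validation("trait columns contain non-finite values")
  constant <- apply(Y, 2L, function(v) stats::sd(v) < 1e-12)

  fit <- stats::lm(Y ~ fsp * node)
  cf <- stats::coef(fit)  # p x traits (or vector if one trait)
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1L, dimnames = list(names(cf), trait_cols))
  aliased <- is.na(cf[, 1])
  # standard errors from the shared design: se_jt = sqrt(diag((X'X)^-1) * sigma2_t)
  qr_ <- fit$qr
  rank <- qr_$rank
  R <- qr.R(qr_)[seq_len(rank), seq_len(rank), drop = FALSE]
  XtXinv_d <- rowSums(backsolve(R, diag(rank))^2)
  res <- as.matrix(stats::residuals(fit))
  dfres <- nrow(Y) - rank
  sigma2 <- colSums(res^2) / dfres
  se <- matrix(NA_real_, nrow(cf), ncol(cf), dimnames = dimnames(cf))
  se[qr_$pivot[seq_len(rank)], ] <- sqrt(outer(XtXinv_d, sigma2))

  rn <- rownames(cf)
  others <- setdiff(levels, reference)
  term_info <- dplyr::bind_rows(
    tibble::tibble(term = "species", species = others,
                   coef = paste0("fsp", others)),
    tibble::tibble(term = "heteroblasty", species = NA_character_, coef = "node"),
    tibble::tibble(term = "interaction", species = others,
                   coef = paste0("fsp", others, ":node"))
  )
  stopifnot(all(term_info$coef %in% rn))
  rows <- lapply(seq_along(trait_cols), function(t) {
    est <- cf[term_info$coef, t]
    if (constant[t]) est[] <- 0
    tibble::tibble(
      trait = trait_cols[t], term = term_info$term, species = term_info$species,
      estimate = est,
      se = se[term_info$coef, t],
      estimable = !aliased[term_info$coef] | constant[t],
      constant = constant[t]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (include_reference) {
    ref_rows <- tidyr::expand_grid(trait = trait_cols, term = c("species", "interaction")) %>%
      dplyr::mutate(species = reference, estimate = 0, se = NA_real_,
                    estimable = TRUE, constant = FALSE)
    out <- dplyr::bind_rows(out, ref_rows) %>%
      dplyr::arrange(.data$trait, .data$term, .data$species)
  }
  attr(out, "reference") <- reference
  attr(out, "intercepts") <- tibble::tibble(
    trait = trait_cols,
    intercept = cf["(Intercept)", ],
    node_slope = cf["node", ]
  )
  class(out) <- c("effect_table", class(out))
  out
}

#' Hierarchically cluster traits for heatmap ordering
#'
#' Agglomerative clustering (complete linkage by default) on Euclidean
#' distances between trait profiles — rows are traits, columns are effect
#' sizes or per-node standard deviations. The returned leaf order is the
#' deterministic dendrogram order (ties resolved by row index, as
#' agglomeration visits pairs in index order).
#'
#' @param mat a numeric matrix (traits x profile values) with rownames, or
#'   a tibble with a `trait` column and numeric columns.
#' @param method linkage passed to [stats::hclust()].
#' @return a list: `order` (integer leaf order), `labels` (trait names in
#'   dendrogram order), `hclust` (the tree).
#' @export
cluster_traits <- function(mat, method = "complete") {
  if (is.data.frame(mat)) {
    labs <- if ("trait" %in% names(mat)) mat$trait else rownames(mat)
    mat <- as.matrix(mat[, vapply(mat, is.numeric, TRUE)])
    rownames(mat) <- labs
  }
  if (nrow(mat) < 2L) stop_validation("need at least 2 traits to cluster")
  if (!all(is.finite(mat))) stop_validation("trait profiles contain non-finite values")
  hc <- stats::hclust(stats::dist(mat), method = method)
  list(order = hc$order, labels = rownames(mat)[hc$order], hclust = hc)
}
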