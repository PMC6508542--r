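#' Leave-one-out species assignment by linear discriminant analysis
#'
#' For each leaf, a linear discriminant rule (pooled within-class
#' covariance, class priors proportional to training counts) is estimated
#' on all other leaves of the node and the held-out leaf is assigned to the
#' class with the highest discriminant score — the "leave-one-out"
#' cross-validation that keeps reassignment honest. Species with fewer
#' than 2 leaves are excluded with a warning; a singular pooled covariance
#' is ridge-regularized with `epsilon = 1e-8 * trace / p` (warned once).
#'
#' @param X numeric feature matrix (leaves x traits) for one node.
#' @param y species labels (length `nrow(X)`).
#' @param priors `"proportional"` (to training counts) or `"uniform"`.
#' @return a `node_discrimination` list: `confusion` (true species x
#'   assigned species counts), `proportions` (tibble `species`, `n`,
#'   `prop_correct`), `average` (mean per-species proportion correct),
#'   `excluded` (species dropped for insufficient leaves).
#' @export
loo_species_assignment <- function(X, y, priors = c("proportional", "uniform")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_validation("features must be finite")
  y <- as.character(y)
  counts <- table(y)
  excluded <- names(counts)[counts < 2L]
  if (length(excluded) > 0L) {
    warn_quality(sprintf(
      "excluding %d species with a single leaf: %s",
      length(excluded), paste(excluded, collapse = ", ")
    ))
    keep <- !(y %in% excluded)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop_validation("need at least 2 species with >= 2 leaves")
  # near-constant features carry no discriminant information and break the
  # covariance scale
  v <- apply(X, 2L, stats::var)
  X <- X[, v >= 1e-12, drop = FALSE]
  if (ncol(X) == 0L) stop_validation("no non-constant features")
  n <- nrow(X); p <- ncol(X)
  assigned <- character(n)
  warned_ridge <- FALSE
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    cls <- sort(unique(yt))
    mu <- t(vapply(cls, function(cl) colMeans(Xt[yt == cl, , drop = FALSE]), numeric(p)))
    Sw <- matrix(0, p, p)
    for (cl in cls) {
      Z <- sweep(Xt[yt == cl, , drop = FALSE], 2L, mu[cl == cls, ])
      Sw <- Sw + crossprod(Z)
    }
    Sw <- Sw / (nrow(Xt) - length(cls))
    ok <- FALSE
    ch <- tryCatch(chol(Sw), error = function(e) NULL)
    if (is.null(ch) || nrow(Xt) - length(cls) < p) {
      if (!warned_ridge) {
        warn_quality("singular pooled covariance; ridge-regularizing (1e-8 * trace / p)")
        warned_ridge <- TRUE
      }
      Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / p, p)
      ch <- chol(Sw)
    }
    prior <- if (priors == "proportional") {
      as.numeric(table(factor(yt, levels = cls))) / length(yt)
    } else rep(1 / length(cls), length(cls))
    # discriminant score: log prior - Mahalanobis/2, via one triangular solve
    diff <- sweep(mu, 2L, X[i, ], `-`)
    z <- backsolve(ch, t(diff), transpose = TRUE)
    score <- log(prior) - colSums(z^2) / 2
    assigned[i] <- cls[which.max(score)]
  }
  confusion <- table(factor(y, levels = classes), factor(assigned, levels = classes))
  props <- tibble::tibble(
    species = classes,
    n = as.integer(rowSums(confusion)),
    prop_correct = diag(confusion) / rowSums(confusion)
  )
  structure(list(
    confusion = unclass(confusion),
    proportions = props,
    average = mean(props$prop_correct),
    excluded = excluded
  ), class = "node_discrimination")
}

#' @export
print.node_discrimination <- function(x, ...) {
  cat(sprintf("Leave-one-out LDA: %d species, average proportion correct %.3f\n",
              nrow(x$proportions), x$average))
  invisible(x)
}

#' Per-node species discrimination table
#'
#' Runs [loo_species_assignment()] independently at every heteroblastic
#' node using all trait columns jointly (aligned landmark coordinates plus
#' normalized EFD coefficients, when both are present in `traits`).
#'
#' @param traits a tibble with `species`, `node` and numeric trait columns
#'   (e.g. from [leaf_traits()]).
#' @param priors passed to [loo_species_assignment()].
#' @return a tibble `node`, `species`, `n`, `prop_correct` plus per-node
#'   average rows retrievable with [node_accuracy()]; attribute
#'   `confusions` holds the per-node confusion matrices. Nodes with fewer
#'   than 2 usable species are skipped with a warning.
#' @export
node_discrimination_table <- function(traits, priors = "proportional") {
  tcols <- trait_columns(traits)
  nodes <- sort(unique(traits$node))
  rows <- list(); confusions <- list()
  for (k in nodes) {
    sub <- traits[traits$node == k, ]
    res <- tryCatch(
      loo_species_assignment(as.matrix(sub[, tcols]), sub$species, priors = priors),
      leafmorph_validation_error = function(e) NULL
    )
    if (is.null(res)) {
      warn_quality(sprintf("node %d skipped: fewer than 2 usable species", k))
      next
    }
    rows[[length(rows) + 1L]] <- dplyr::mutate(res$proportions, node = k, .before = 1L)
    confusions[[as.character(k)]] <- res$confusion
  }
  if (length(rows) == 0L) stop_validation("no node with enough species to discriminate")
  out <- dplyr::bind_rows(rows)
  attr(out, "confusions") <- confusions
  class(out) <- c("discrimination_table", class(out))
  out
}

#' Per-node average correct-assignment rate
#'
#' @param table a [node_discrimination_table()] result.
#' @return a tibble `node`, `average` (mean of per-species proportions).
#' @export
node_accuracy <- function(table) {
  table %>%
    dplyr::group_by(node = .data$node) %>%
    dplyr::summarise(average = mean(.data$prop_correct), .groups = "drop")
}

#' Standard deviation of each trait at each heteroblastic node
#'
#' Sample standard deviation (n - 1 denominator) of every trait over all
#' leaves at each node, pooled across species — the per-node variability
#' profile whose rise along the series marks divergence from the shared
#' juvenile shape.
#'
#' @param traits a tibble with `node` and numeric trait columns.
#' @return a long tibble `node`, `trait`, `sd`, `n`; nodes with a single
#'   leaf yield `NA` standard deviations and a quality warning.
#' @export
trait_sd_by_node <- function(traits) {
  tcols <- trait_columns(traits)
  out <- traits %>%
    dplyr::group_by(node = .data$node) %>%
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(tcols), stats::sd),
      .groups = "drop"
    ) %>%
    tidyr::pivot_longer(dplyr::all_of(tcols), names_to = "trait", values_to = "sd") %>%
    dplyr::arrange(.data$node, .data$trait)
  if (any(out$n < 2L)) {
    warn_quality(sprintf(
      "node(s) %s have a single leaf: standard deviations undefined",
      paste(unique(out$node[out$n < 2L]), collapse = ", ")
    ))
  }
  out[, c("node", "trait", "sd", "n")]
}

#' Trait columns of a trait tibble
#'
#' The numeric columns that are shape traits, i.e. everything numeric
#' except identifiers (`node`, `centroid_size`, embedding dimensions).
#'
#' @param traits a trait tibble.
#' @return a character vector of column names.
#' @export
trait_columns <- function(traits) {
  num <- names(traits)[vapply(traits, is.numeric, TRUE)]
  setdiff(num, c("node", "centroid_size", "dim1", "dim2"))
}
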