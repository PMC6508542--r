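#' Joint trait matrix: aligned landmarks plus normalized EFD coefficients
#'
#' Binds the two shape representations used throughout the analysis into
#' one tibble, one row per leaf: the 30 Procrustes-aligned landmark
#' coordinates and the 4H normalized elliptical Fourier coefficients.
#' Coefficients fixed by the normalization (a1 = 1, b1 = c1 = 0) are
#' constant columns; they are kept here and flagged or dropped downstream.
#'
#' @param aligned an aligned leaf collection ([align_leaves()]).
#' @param efd an [efd_traits()] tibble for the same leaves (computed from
#'   `aligned`'s outlines when omitted).
#' @return a tibble: `species`, `class_label`, `vine`, `node`, `x1..y15`,
#'   `a1..dH`.
#' @export
leaf_traits <- function(aligned, efd = NULL) {
  if (is.null(efd)) efd <- efd_traits(aligned)
  key <- c("species", "vine", "node")
  if (!all(vapply(key, function(k) identical(aligned[[k]], efd[[k]]), TRUE))) {
    efd <- dplyr::left_join(aligned[, key], efd, by = key)
  }
  cn <- grep("^[abcd][0-9]+$", names(efd), value = TRUE)
  out <- dplyr::bind_cols(
    aligned[, c(intersect(c("species", "class_label", "vine", "node"), names(aligned)),
                coord_names())],
    efd[, cn]
  )
  tibble::as_tibble(out)
}

#' Drop trait columns with (near-)zero variance
#'
#' @param traits a trait tibble.
#' @param tol variance threshold.
#' @return the tibble without the near-constant trait columns.
#' @export
drop_constant_traits <- function(traits, tol = 1e-12) {
  tcols <- trait_columns(traits)
  v <- vapply(traits[tcols], stats::var, 0)
  traits[, !names(traits) %in% tcols[v < tol]]
}
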