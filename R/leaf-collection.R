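#' Build a leaf collection from a data frame
#'
#' A leaf collection is a tibble with one row per leaf carrying the leaf's
#' identity (`species`, `vine`, `node`, optionally `class_label`) and its
#' 15-landmark configuration in columns `x1..x15, y1..y15`. The node
#' numbering convention travels with the collection as an attribute:
#' `"base_first"` means node 1 is the oldest leaf at the shoot base (the
#' convention of the heteroblastic series), `"tip_first"` means node 1 is the
#' youngest leaf at the growing tip (the convention of raw scan sheets).
#'
#' @param df a data frame with columns `species`, `vine`, `node` and the 30
#'   coordinate columns; a `class_label` column and an `outline` list column
#'   (closed polygon matrices) are kept if present.
#' @param numbering `"base_first"` or `"tip_first"`.
#' @return a `leaf_collection` tibble.
#' @export
leaf_collection <- function(df, numbering = c("base_first", "tip_first")) {
  numbering <- match.arg(numbering)
  df <- tibble::as_tibble(df)
  required <- c("species", "vine", "node", coord_names())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_validation(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"class_label" %in% names(df)) df$class_label <- NA_character_
  df$node <- as.integer(df$node)
  if (any(!is.finite(df$node)) || any(df$node < 1L)) {
    stop_validation("node indices must be positive integers")
  }
  coords <- as.matrix(df[, coord_names()])
  if (!all(is.finite(coords))) {
    bad <- which(!stats::complete.cases(coords))[1]
    stop_format(sprintf("non-finite landmark coordinate in row %d", bad))
  }
  dup <- duplicated(df[, c("vine", "node")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_validation(sprintf(
      "duplicate (vine, node) = (%s, %d)", df$vine[i], df$node[i]
    ))
  }
  keep <- c("species", "class_label", "vine", "node", coord_names(),
            intersect("outline", names(df)))
  out <- df[, keep]
  attr(out, "numbering") <- numbering
  attr(out, "aligned") <- isTRUE(attr(df, "aligned"))
  class(out) <- c("leaf_collection", class(tibble::tibble()))
  out
}

#' Node numbering convention of a collection
#' @param collection a leaf collection.
#' @return `"base_first"` or `"tip_first"`.
#' @export
leaf_numbering <- function(collection) {
  attr(collection, "numbering") %||% "base_first"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Renumber nodes between tip-first and base-first conventions
#'
#' Raw scan sheets number leaves from the growing tip ("1" is the youngest
#' leaf); the heteroblastic series numbers them from the shoot base ("1" is
#' the oldest leaf). Converting flips each vine's numbering around its own
#' maximum: node `k` becomes `max(node) - k + 1` within the vine, so gaps in
#' a vine's sampled nodes are preserved. Converting to the current convention
#' is the identity, and the map is an involution.
#'
#' @param collection a leaf collection.
#' @param target `"base_first"` or `"tip_first"`.
#' @return the collection with renumbered nodes and updated convention.
#' @export
renumber_nodes <- function(collection, target = c("base_first", "tip_first")) {
  target <- match.arg(target)
  current <- leaf_numbering(collection)
  if (!current %in% c("base_first", "tip_first")) {
    stop_validation(sprintf("unknown node numbering convention '%s'", current))
  }
  if (current == target) {
    return(collection)
  }
  att <- attributes(collection)
  out <- collection %>%
    dplyr::group_by(.data$vine) %>%
    dplyr::mutate(node = max(.data$node) - .data$node + 1L) %>%
    dplyr::ungroup()
  attr(out, "numbering") <- target
  attr(out, "aligned") <- att$aligned
  class(out) <- att$class
  out
}

#' @export
print.leaf_collection <- function(x, ...) {
  cat(sprintf(
    "# Leaf collection: %d leaves, %d species, %d vines (%s numbering%s)\n",
    nrow(x), dplyr::n_distinct(x$species), dplyr::n_distinct(x$vine),
    leaf_numbering(x), if (isTRUE(attr(x, "aligned"))) ", aligned" else ""
  ))
  NextMethod()
}

# Restore collection attributes after a dplyr verb stripped them.
restore_collection <- function(df, template, aligned = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "numbering") <- leaf_numbering(template)
  attr(out, "aligned") <- if (is.null(aligned)) isTRUE(attr(template, "aligned")) else aligned
  class(out) <- c("leaf_collection", class(tibble::tibble()))
  out
}
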