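#' Describe the on-disk layout of a landmark table
#'
#' Landmark tables are delimited text with a header, one leaf per row:
#' identity columns followed by 30 coordinate values (x1, y1, ..., x15, y15
#' interleaved, or all x then all y). Deposited tables differ in column
#' naming, so the mapping is configuration rather than convention.
#'
#' @param sep field separator (`"\t"`, `","`, or `""` for any whitespace).
#' @param species,vine,node,class_label names of the identity columns
#'   (`class_label = NULL` if the table has none).
#' @param coords `"interleaved"` (`x1,y1,x2,y2,...`) or `"blocked"`
#'   (`x1..x15` then `y1..y15`). Coordinate columns are taken by position:
#'   every column that is not an identity column, in file order.
#' @param numbering node numbering convention declared for the file.
#' @return a dialect description used by [read_landmark_table()].
#' @export
landmark_dialect <- function(sep = "\t", species = "species", vine = "vine",
                             node = "node", class_label = NULL,
                             coords = c("interleaved", "blocked"),
                             numbering = c("base_first", "tip_first")) {
  list(sep = sep, species = species, vine = vine, node = node,
       class_label = class_label, coords = match.arg(coords),
       numbering = match.arg(numbering))
}

#' Read a delimited landmark table
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [landmark_dialect()] describing the layout.
#' @return a [leaf_collection()] with one record per row.
#' @export
read_landmark_table <- function(path, dialect = landmark_dialect()) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  df <- if (identical(dialect$sep, "")) {
    tibble::as_tibble(utils::read.table(path, header = TRUE,
                                        stringsAsFactors = FALSE,
                                        colClasses = "character"))
  } else {
    readr::read_delim(path, delim = dialect$sep, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE, show_col_types = FALSE)
  }
  id_cols <- c(dialect$species, dialect$vine, dialect$node, dialect$class_label)
  missing <- setdiff(id_cols, names(df))
  if (length(missing) > 0L) {
    stop_format(paste0("missing identity columns: ", paste(missing, collapse = ", ")))
  }
  coord_cols <- setdiff(names(df), id_cols)
  if (length(coord_cols) != 2L * N_LANDMARKS) {
    stop_format(sprintf(
      "expected %d coordinate columns, found %d", 2L * N_LANDMARKS, length(coord_cols)
    ))
  }
  coords <- matrix(NA_real_, nrow(df), 2L * N_LANDMARKS)
  for (j in seq_along(coord_cols)) {
    v <- suppressWarnings(as.numeric(df[[coord_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[coord_cols[j]]]))
    if (length(bad) > 0L || anyNA(df[[coord_cols[j]]])) {
      row <- if (length(bad) > 0L) bad[1] else which(is.na(df[[coord_cols[j]]]))[1]
      stop_format(sprintf(
        "non-numeric or missing coordinate in row %d, column '%s'", row, coord_cols[j]
      ))
    }
    coords[, j] <- v
  }
  target <- if (dialect$coords == "interleaved") coord_names_interleaved() else coord_names()
  colnames(coords) <- target
  out <- tibble::tibble(
    species = as.character(df[[dialect$species]]),
    vine = as.character(df[[dialect$vine]]),
    node = parse_numeric(df[[dialect$node]], "node column")
  )
  if (!is.null(dialect$class_label)) out$class_label <- as.character(df[[dialect$class_label]])
  out <- dplyr::bind_cols(out, tibble::as_tibble(coords)[, coord_names()])
  leaf_collection(out, numbering = dialect$numbering)
}

#' Write a leaf collection as a delimited landmark table
#'
#' Coordinates are written at full double precision so that a write/read
#' round trip reproduces them to better than 1e-12.
#'
#' @param collection a leaf collection.
#' @param path output file path.
#' @param dialect a [landmark_dialect()]; its `numbering` field is ignored in
#'   favour of the collection's own convention.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(collection, path, dialect = landmark_dialect()) {
  cols <- if (dialect$coords == "interleaved") coord_names_interleaved() else coord_names()
  df <- collection[, c("species", "vine", "node", cols)]
  names(df)[1:3] <- c(dialect$species, dialect$vine, dialect$node)
  if (!is.null(dialect$class_label)) {
    df[[dialect$class_label]] <- collection$class_label
    df <- df[, c(dialect$species, dialect$vine, dialect$node, dialect$class_label, cols)]
  }
  for (cc in cols) df[[cc]] <- sprintf("%.17g", df[[cc]])
  sep <- if (identical(dialect$sep, "")) " " else dialect$sep
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SHAPE-dialect NEF file of normalized elliptical Fourier descriptors
#'
#' The NEF layout is per record: a name line, a line with the harmonic count
#' H, then H lines of four numbers (a, b, c, d). Windows line endings,
#' repeated whitespace and comment lines starting with `#` are tolerated.
#' All records must share the same H.
#'
#' @param path path to a NEF file.
#' @return a tibble with one row per leaf: `leaf` plus wide coefficient
#'   columns `a1, b1, c1, d1, ..., aH, bH, cH, dH`; attributes `harmonics`
#'   and `normalized = TRUE`.
#' @export
read_nef <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  names_out <- character(0)
  coef_rows <- list()
  H_all <- integer(0)
  i <- 1L
  while (i <= length(lines)) {
    name <- lines[i]
    if (i + 1L > length(lines)) stop_format(sprintf("truncated record '%s': missing harmonic count", name))
    H <- suppressWarnings(as.integer(lines[i + 1L]))
    if (is.na(H) || H < 1L) {
      stop_format(sprintf("record '%s': invalid harmonic count '%s'", name, lines[i + 1L]))
    }
    if (i + 1L + H > length(lines)) {
      stop_format(sprintf("truncated record '%s': expected %d harmonic lines", name, H))
    }
    block <- lines[(i + 2L):(i + 1L + H)]
    vals <- lapply(block, function(l) {
      tok <- strsplit(l, "[[:space:],]+")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) != 4L) {
        stop_format(sprintf("record '%s': expected 4 coefficients per line, got %d", name, length(tok)))
      }
      parse_numeric(tok, sprintf("record '%s'", name))
    })
    coef_rows[[length(coef_rows) + 1L]] <- do.call(rbind, vals)
    names_out <- c(names_out, name)
    H_all <- c(H_all, H)
    i <- i + 2L + H
  }
  if (length(names_out) == 0L) stop_format("empty NEF file")
  if (length(unique(H_all)) != 1L) {
    stop_format(sprintf(
      "inconsistent harmonic counts across records: %s", paste(unique(H_all), collapse = ", ")
    ))
  }
  H <- H_all[1]
  wide <- t(vapply(coef_rows, function(m) as.vector(t(m)), numeric(4L * H)))
  colnames(wide) <- efd_col_names(H)
  out <- dplyr::bind_cols(tibble::tibble(leaf = names_out), tibble::as_tibble(wide))
  attr(out, "harmonics") <- H
  attr(out, "normalized") <- TRUE
  out
}

efd_col_names <- function(H) {
  as.vector(vapply(seq_len(H), function(n) paste0(c("a", "b", "c", "d"), n), character(4)))
}

#' Write elliptical Fourier descriptors as a SHAPE-dialect NEF file
#'
#' @param efd a tibble as returned by [read_nef()] or [efd_traits()]: a
#'   `leaf` (or `species`/`vine`/`node`) identity plus `a1..dH` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nef <- function(efd, path) {
  cn <- grep("^[abcd][0-9]+$", names(efd), value = TRUE)
  H <- length(cn) / 4L
  stopifnot(H == floor(H), all(efd_col_names(H) %in% cn))
  leaf <- if ("leaf" %in% names(efd)) {
    efd$leaf
  } else {
    paste(efd$species, efd$vine, efd$node, sep = "_")
  }
  con <- file(path, "w")
  on.exit(close(con))
  m <- as.matrix(efd[, efd_col_names(H)])
  for (i in seq_len(nrow(efd))) {
    writeLines(leaf[i], con)
    writeLines(as.character(H), con)
    block <- matrix(m[i, ], ncol = 4L, byrow = TRUE)
    writeLines(apply(block, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}
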