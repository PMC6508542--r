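#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Internal error helpers: every user-facing failure carries a class so tests
# can assert on the failure mode, not on message wording.
stop_format <- function(msg, ...) abort(msg, class = "leafmorph_format_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "leafmorph_validation_error", ...)
stop_degenerate <- function(msg, ...) abort(msg, class = "leafmorph_degenerate_error", ...)

warn_quality <- function(msg) warn(msg, class = "leafmorph_quality_warning")

#' Number of landmarks per leaf
#'
#' All landmark configurations in this package are ordered sets of 15
#' planar points: the petiolar junction and bases of the major veins
#' (landmarks 1-6) plus lobe tips, sinuses and vein tips (7-15).
#' @export
N_LANDMARKS <- 15L

coord_names <- function(n = N_LANDMARKS) {
  c(paste0("x", seq_len(n)), paste0("y", seq_len(n)))
}

# Interleaved coordinate column order used on disk: x1,y1,...,x15,y15
coord_names_interleaved <- function(n = N_LANDMARKS) {
  as.vector(rbind(paste0("x", seq_len(n)), paste0("y", seq_len(n))))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' Convert one leaf row (or coordinate vector) to a landmark matrix
#'
#' @param x a one-row data frame carrying `x1..x15, y1..y15`, or a numeric
#'   vector of length 30 in that column order.
#' @return a 15 x 2 numeric matrix with columns `x`, `y`.
#' @export
landmark_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.numeric(x[1, coord_names(), drop = TRUE])
  }
  stopifnot(length(x) == 2L * N_LANDMARKS)
  m <- matrix(as.numeric(x), ncol = 2L, dimnames = list(NULL, c("x", "y")))
  m
}

# Inverse of landmark_matrix(): 15x2 matrix -> named coordinate vector
landmark_vector <- function(m) {
  stats::setNames(c(m[, 1], m[, 2]), coord_names(nrow(m)))
}

# Signed polygon area (shoelace / 2); positive for counter-clockwise rings.
signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# A tolerant numeric parse that reports the offending token.
parse_numeric <- function(tokens, context) {
  out <- suppressWarnings(as.numeric(tokens))
  bad <- which(is.na(out) & !is.na(tokens))
  if (length(bad) > 0L) {
    stop_format(sprintf("non-numeric value '%s' in %s", tokens[bad[1]], context))
  }
  out
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stage label,
# so adding a stage never perturbs the random stream of another.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
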