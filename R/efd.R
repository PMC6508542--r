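#' Elliptical Fourier coefficients of a closed polyline
#'
#' Decomposes the x(t), y(t) parameterization of a closed contour
#' (piecewise-linear, chord-length parameter) into a harmonic series. Each
#' harmonic n contributes four coefficients (a_n, b_n, c_n, d_n); the
#' zeroth-order terms (the contour centroid of the parameterization) are
#' kept in the attribute `center`.
#'
#' @param points an n x 2 matrix of contour vertices (closed implicitly;
#'   counter-clockwise recommended, clockwise input is reversed).
#' @param harmonics number of harmonics H.
#' @return an `efd_coefficients` object: an H x 4 matrix with columns
#'   `a, b, c, d`, attributes `normalized = FALSE` and `center`.
#' @export
outline_efd <- function(points, harmonics = 20L) {
  pts <- as.matrix(points)
  if (harmonics < 1L) stop_validation("harmonics must be >= 1")
  if (signed_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  dx <- pts[nxt, 1] - pts[, 1]
  dy <- pts[nxt, 2] - pts[, 2]
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 1e-15
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (length(dt) < 3L) stop_degenerate("contour has fewer than 3 distinct vertices")
  tt <- cumsum(dt)
  total <- tt[length(tt)]
  phi1 <- 2 * pi * tt / total
  phi0 <- c(0, phi1[-length(phi1)])
  ns <- seq_len(harmonics)
  # H x segments trigonometric increments
  dcos <- cos(outer(ns, phi1)) - cos(outer(ns, phi0))
  dsin <- sin(outer(ns, phi1)) - sin(outer(ns, phi0))
  fac <- total / (2 * ns^2 * pi^2)
  vx <- dx / dt
  vy <- dy / dt
  a <- fac * as.vector(dcos %*% vx)
  b <- fac * as.vector(dsin %*% vx)
  cc <- fac * as.vector(dcos %*% vy)
  d <- fac * as.vector(dsin %*% vy)
  # trapezoid rule is exact for the piecewise-linear x(t), y(t)
  x1 <- pts[keep, 1]; y1 <- pts[keep, 2]
  x2 <- x1 + dx; y2 <- y1 + dy
  center <- c(sum(dt * (x1 + x2) / 2), sum(dt * (y1 + y2) / 2)) / total
  coeffs <- cbind(a = a, b = b, c = cc, d = d)
  structure(coeffs, class = c("efd_coefficients", "matrix", "array"),
            normalized = FALSE, center = center)
}

#' Elliptical Fourier coefficients from a Freeman chain code
#'
#' The chain code is treated as a closed piecewise-linear contour (unit
#' steps for even codes, sqrt(2) for diagonal codes) and decomposed with
#' [outline_efd()].
#'
#' @param chain a `chain_code` from [trace_contour()].
#' @param harmonics number of harmonics H.
#' @return an `efd_coefficients` object (raw, un-normalized).
#' @export
chain_to_efd <- function(chain, harmonics = 20L) {
  if (!isTRUE(chain$closed)) stop_validation("chain code must be closed")
  outline_efd(chain_to_polyline(chain), harmonics = harmonics)
}

efd_attrs <- function(coeffs, normalized, center = c(0, 0)) {
  structure(coeffs, class = c("efd_coefficients", "matrix", "array"),
            normalized = normalized, center = center)
}

#' First-harmonic normalization of elliptical Fourier coefficients
#'
#' Removes size, rotation and starting point using the first-harmonic
#' ellipse: the parameter origin is shifted to the semi-major axis, the
#' shape is rotated so that axis lies along x, and all coefficients are
#' divided by the semi-major axis length. After normalization a_1 = 1,
#' b_1 = c_1 = 0 and |d_1| <= 1 (the first-harmonic aspect ratio, signed by
#' contour chirality). The half-period ambiguity of the axis direction is
#' resolved deterministically by choosing the candidate whose reconstructed
#' point at parameter 0 has the larger x coordinate.
#'
#' @param coeffs an `efd_coefficients` object.
#' @return a normalized `efd_coefficients` object (idempotent).
#' @export
normalize_efd <- function(coeffs) {
  m <- unclass(coeffs)
  a1 <- m[1, 1]; b1 <- m[1, 2]; c1 <- m[1, 3]; d1 <- m[1, 4]
  if (abs(a1 * d1 - b1 * c1) < 1e-18 && (a1^2 + b1^2 + c1^2 + d1^2) < 1e-18) {
    stop_degenerate("degenerate first harmonic: cannot normalize")
  }
  theta0 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  H <- nrow(m)
  ns <- seq_len(H)
  apply_theta_psi <- function(theta) {
    ct <- cos(ns * theta); st <- sin(ns * theta)
    A <- m[, 1] * ct + m[, 2] * st
    B <- -m[, 1] * st + m[, 2] * ct
    C <- m[, 3] * ct + m[, 4] * st
    D <- -m[, 3] * st + m[, 4] * ct
    psi <- atan2(C[1], A[1])
    cp <- cos(psi); sp <- sin(psi)
    A2 <- cp * A + sp * C
    B2 <- cp * B + sp * D
    C2 <- -sp * A + cp * C
    D2 <- -sp * B + cp * D
    E <- A2[1]
    list(coeffs = cbind(a = A2, b = B2, c = C2, d = D2) / E, E = E)
  }
  cands <- lapply(theta0 + c(0, 0.5, 1, 1.5) * pi, apply_theta_psi)
  Es <- vapply(cands, `[[`, 0, "E")
  if (max(Es) < 1e-15) stop_degenerate("degenerate first harmonic: cannot normalize")
  major <- which(Es > max(Es) * (1 - 1e-9))
  if (length(major) > 1L) {
    # tie between the half-period-shifted candidates: larger x at parameter 0
    x0 <- vapply(major, function(i) sum(cands[[i]]$coeffs[, 1]), 0)
    major <- major[which.max(x0)]
  }
  efd_attrs(cands[[major]]$coeffs, normalized = TRUE)
}

#' Reconstruct a closed outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated Fourier series at equally spaced parameter
#' values. The coefficient `center` attribute, if present, is added back.
#'
#' @param coeffs an `efd_coefficients` object (raw or normalized).
#' @param n_points number of outline vertices (>= 16).
#' @return an n_points x 2 matrix tracing the closed outline.
#' @export
reconstruct_outline <- function(coeffs, n_points = 200L) {
  if (n_points < 16L) stop_validation("n_points must be >= 16")
  m <- unclass(coeffs)
  H <- nrow(m)
  tt <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  ns <- seq_len(H)
  cosmat <- cos(outer(tt, ns))
  sinmat <- sin(outer(tt, ns))
  center <- attr(coeffs, "center") %||% c(0, 0)
  x <- center[1] + cosmat %*% m[, 1] + sinmat %*% m[, 2]
  y <- center[2] + cosmat %*% m[, 3] + sinmat %*% m[, 4]
  cbind(x = as.vector(x), y = as.vector(y))
}

#' Coefficient-wise mean of normalized elliptical Fourier descriptors
#'
#' @param efds a list of normalized `efd_coefficients` with equal harmonic
#'   count, or a tibble of wide `a1..dH` columns (e.g. a node's subset of
#'   [efd_traits()] rows).
#' @return a normalized-flagged `efd_coefficients` object of the means.
#' @export
mean_efd <- function(efds) {
  if (is.data.frame(efds)) {
    cn <- grep("^[abcd][0-9]+$", names(efds), value = TRUE)
    H <- length(cn) / 4L
    if (H < 1L || H != floor(H)) stop_validation("no coefficient columns found")
    mm <- colMeans(as.matrix(efds[, efd_col_names(H)]))
    out <- matrix(mm, ncol = 4L, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c", "d")))
    return(efd_attrs(out, normalized = TRUE))
  }
  Hs <- vapply(efds, nrow, 0L)
  if (length(unique(Hs)) != 1L) {
    stop_validation(sprintf("mixed harmonic counts: %s", paste(unique(Hs), collapse = ", ")))
  }
  out <- Reduce(`+`, lapply(efds, unclass)) / length(efds)
  efd_attrs(out, normalized = all(vapply(efds, function(e) isTRUE(attr(e, "normalized")), TRUE)))
}

#' Harmonic-contribution grid
#'
#' For each (harmonic rank, amplification factor) pair, reconstructs the
#' outline with that rank's quadruple multiplied by the factor and all
#' other harmonics untouched — the standard visualization of what each
#' harmonic contributes to a shape.
#'
#' @param coeffs a (typically mean, normalized) `efd_coefficients` object.
#' @param ranks harmonic indices to perturb.
#' @param factors amplification factors (0 removes the harmonic, 1 is the
#'   identity).
#' @param n_points outline resolution per cell.
#' @return a tibble with columns `rank`, `factor` and an `outline` list
#'   column of reconstructed outlines.
#' @export
harmonic_contribution <- function(coeffs, ranks = 1:5, factors = c(0, 0.5, 1, 2),
                                  n_points = 200L) {
  H <- nrow(coeffs)
  if (any(ranks < 1L) || any(ranks > H)) {
    stop_validation(sprintf("ranks must lie in 1..%d", H))
  }
  grid <- tidyr::expand_grid(rank = as.integer(ranks), factor = as.numeric(factors))
  grid$outline <- purrr::map2(grid$rank, grid$factor, function(r, f) {
    m <- unclass(coeffs)
    m[r, ] <- m[r, ] * f
    reconstruct_outline(efd_attrs(m, normalized = attr(coeffs, "normalized") %||% FALSE,
                                  center = attr(coeffs, "center") %||% c(0, 0)),
                        n_points = n_points)
  })
  grid
}

#' Normalized elliptical Fourier descriptors for every leaf in a collection
#'
#' Each leaf's outline (the `outline` list column if present, otherwise a
#' periodic spline through the boundary landmarks) is decomposed into H
#' harmonics and first-harmonic normalized.
#'
#' @param collection a leaf collection.
#' @param harmonics number of harmonics H.
#' @param n_points outline resolution used when outlines are interpolated
#'   from landmarks.
#' @return a tibble with `species`, `vine`, `node` and wide columns
#'   `a1..dH`; attributes `harmonics` and `normalized = TRUE`.
#' @export
efd_traits <- function(collection, harmonics = 20L, n_points = 120L) {
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    ol <- if ("outline" %in% names(collection) && !is.null(collection$outline[[i]])) {
      collection$outline[[i]]
    } else {
      landmarks_to_outline(landmark_matrix(collection[i, c(coord_names())]),
                           n_points = n_points)
    }
    nef <- normalize_efd(outline_efd(ol, harmonics = harmonics))
    as.vector(t(unclass(nef)))
  })
  wide <- do.call(rbind, rows)
  colnames(wide) <- efd_col_names(harmonics)
  out <- dplyr::bind_cols(
    collection[, c("species", "vine", "node")],
    tibble::as_tibble(wide)
  )
  attr(out, "harmonics") <- as.integer(harmonics)
  attr(out, "normalized") <- TRUE
  out
}
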