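#' Construct a closed leaf outline
#'
#' An outline is an ordered closed polyline (the first point implicitly
#' follows the last), stored counter-clockwise so its signed area is
#' positive. Clockwise input is reversed; degenerate rings are rejected.
#'
#' @param points an n x 2 numeric matrix of vertices (n >= 8).
#' @return an `outline` matrix (counter-clockwise, no consecutive
#'   duplicates).
#' @export
outline <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop_degenerate("empty outline")
  if (!all(is.finite(points))) stop_validation("outline has non-finite coordinates")
  # drop consecutive duplicates (including a repeated closing vertex)
  d <- rowSums((points - points[c(nrow(points), seq_len(nrow(points) - 1L)), , drop = FALSE])^2)
  points <- points[d > 1e-24 | seq_len(nrow(points)) == 1L, , drop = FALSE]
  if (nrow(points) < 8L) stop_degenerate("outline needs at least 8 distinct points")
  a <- signed_area(points)
  if (abs(a) < 1e-15) stop_degenerate("outline encloses no area")
  if (a < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  colnames(points) <- c("x", "y")
  structure(points, class = c("leaf_outline", "matrix", "array"))
}

#' Default boundary ordering of the 15-landmark leaf
#'
#' The landmarks lying on the leaf margin, in counter-clockwise order:
#' petiolar junction (1), right proximal lobe tip (15), right distal sinus
#' (13), right distal lobe tip (9), apex (7), left distal lobe tip (8),
#' left distal sinus (12), left proximal lobe tip (14). The interior
#' landmarks (vein bases and vein tips) do not lie on the margin.
#' @return an integer vector of landmark indices.
#' @export
leaf_boundary_order <- function() c(1L, 15L, 13L, 9L, 7L, 8L, 12L, 14L)

#' Interpolate a smooth closed outline through boundary landmarks
#'
#' Fits a periodic cubic spline (chord-length parameterized) through the
#' configuration's boundary landmarks, optionally low-pass smoothed with a
#' circular Gaussian kernel, and resamples it at `n_points` vertices.
#'
#' @param config a landmarks x 2 matrix.
#' @param smoothing circular Gaussian bandwidth as a fraction of the outline
#'   perimeter (0 = interpolating spline).
#' @param n_points number of outline vertices to emit.
#' @param boundary landmark indices on the margin, in boundary order.
#' @return an [outline()] with `n_points` vertices.
#' @export
landmarks_to_outline <- function(config, smoothing = 0, n_points = 120L,
                                 boundary = leaf_boundary_order()) {
  config <- as.matrix(config)
  pts <- config[boundary, , drop = FALSE]
  if (max(stats::dist(pts)) < 1e-12) stop_degenerate("all boundary landmarks coincide")
  ring <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(ring)^2))
  if (any(seg < 1e-12)) {
    keep <- c(TRUE, seg[-length(seg)] >= 1e-12)
    pts <- pts[keep, , drop = FALSE]
    ring <- rbind(pts, pts[1, ])
    seg <- sqrt(rowSums(diff(ring)^2))
  }
  tt <- c(0, cumsum(seg))
  total <- tt[length(tt)]
  tout <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  xs <- stats::spline(tt, ring[, 1], method = "periodic", xout = tout)$y
  ys <- stats::spline(tt, ring[, 2], method = "periodic", xout = tout)$y
  if (smoothing > 0) {
    sd_pts <- smoothing * n_points
    half <- min(n_points %/% 2L, ceiling(4 * sd_pts))
    w <- stats::dnorm(seq(-half, half), sd = sd_pts)
    w <- w / sum(w)
    circ <- function(v) {
      ext <- c(utils::tail(v, half), v, utils::head(v, half))
      stats::filter(ext, w, sides = 2)[half + seq_along(v)]
    }
    xs <- circ(xs); ys <- circ(ys)
  }
  outline(cbind(xs, ys))
}

#' Rasterize a closed outline to a binary mask
#'
#' Scanline (even-odd) polygon fill on a pixel grid of `resolution` pixels
#' per coordinate unit. The mask is a logical matrix indexed `[x, y]` with y
#' increasing upward; attributes `origin` and `resolution` map pixel `[i, j]`
#' to the coordinate of its center.
#'
#' @param outline an [outline()] (or n x 2 matrix) that is closed and simple.
#' @param resolution pixels per coordinate unit.
#' @param check reject self-intersecting outlines (quadratic in edge count).
#' @return a logical mask matrix with attributes `origin`, `resolution`.
#' @export
rasterize_outline <- function(outline, resolution = 100, check = TRUE) {
  pts <- as.matrix(outline)
  if (nrow(pts) < 3L) stop_degenerate("outline has fewer than 3 vertices")
  if (check && outline_self_intersects(pts)) {
    stop_validation("outline is self-intersecting")
  }
  x0 <- floor(min(pts[, 1]) * resolution) / resolution - 1 / resolution
  y0 <- floor(min(pts[, 2]) * resolution) / resolution - 1 / resolution
  nx <- ceiling((max(pts[, 1]) - x0) * resolution) + 2L
  ny <- ceiling((max(pts[, 2]) - y0) * resolution) + 2L
  xc <- x0 + (seq_len(nx) - 0.5) / resolution
  yc <- y0 + (seq_len(ny) - 0.5) / resolution
  p1 <- pts
  p2 <- pts[c(2:nrow(pts), 1L), , drop = FALSE]
  mask <- matrix(FALSE, nx, ny)
  for (j in seq_len(ny)) {
    y <- yc[j]
    cross <- (p1[, 2] <= y & p2[, 2] > y) | (p2[, 2] <= y & p1[, 2] > y)
    if (!any(cross)) next
    xint <- p1[cross, 1] + (y - p1[cross, 2]) / (p2[cross, 2] - p1[cross, 2]) *
      (p2[cross, 1] - p1[cross, 1])
    xint <- sort(xint)
    for (k in seq(1L, length(xint) - 1L, by = 2L)) {
      mask[xc >= xint[k] & xc < xint[k + 1L], j] <- TRUE
    }
  }
  if (!any(mask)) stop_degenerate("rasterized outline contains no foreground pixels")
  attr(mask, "origin") <- c(x0, y0)
  attr(mask, "resolution") <- resolution
  mask
}

# Quadratic-time proper-crossing test between non-adjacent edges.
outline_self_intersects <- function(pts) {
  n <- nrow(pts)
  a1 <- pts
  a2 <- pts[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    j <- j[!(i == 1L & j == n)]  # skip edges adjacent through the closure
    if (length(j) == 0L) next
    d1 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a1[j, 1], a1[j, 2])
    d2 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a2[j, 1], a2[j, 2])
    d3 <- cross2(a1[j, 1], a1[j, 2], a2[j, 1], a2[j, 2], rep(a1[i, 1], length(j)), rep(a1[i, 2], length(j)))
    d4 <- cross2(a1[j, 1], a1[j, 2], a2[j, 1], a2[j, 2], rep(a2[i, 1], length(j)), rep(a2[i, 2], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# 8-connectivity move table: code 0 = east, increasing counter-clockwise.
CHAIN_DX <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
CHAIN_DY <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Trace the boundary of a binary mask as a Freeman chain code
#'
#' Moore boundary following on the 8-connected foreground, starting from the
#' left-most pixel of the top-most foreground row and proceeding
#' counter-clockwise (positive signed area in the `[x, y]`, y-up convention
#' of [rasterize_outline()]). Codes 0..7 denote the eight pixel moves, code
#' 0 = +x, increasing counter-clockwise.
#'
#' @param mask a logical or 0/1 matrix indexed `[x, y]`.
#' @return a `chain_code` object: list with `start` (pixel indices), `codes`
#'   (integer vector), `closed = TRUE`.
#' @export
trace_contour <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop_degenerate("empty mask")
  ncomp <- count_components(m)
  if (ncomp > 1L) {
    stop_validation(sprintf("mask has %d foreground components; expected exactly 1", ncomp))
  }
  nx <- nrow(m); ny <- ncol(m)
  top <- max(which(apply(m, 2L, any)))
  sx <- min(which(m[, top]))
  sy <- top
  codes <- integer(0)
  cx <- sx; cy <- sy
  dprev <- 0L  # pretend we arrived moving east: first search starts at south-west
  first_dir <- NA_integer_
  max_steps <- 4L * (nx * ny)
  repeat {
    d <- next_direction(m, cx, cy, dprev)
    if (is.na(d)) stop_degenerate("isolated pixel: boundary chain shorter than 8 moves")
    if (is.na(first_dir)) {
      first_dir <- d
    } else if (cx == sx && cy == sy && d == first_dir) {
      break  # back at the start, about to repeat the first move (Jacob's criterion)
    }
    codes <- c(codes, d)
    cx <- cx + CHAIN_DX[d + 1L]; cy <- cy + CHAIN_DY[d + 1L]
    dprev <- d
    if (length(codes) > max_steps) stop_validation("contour tracing failed to close")
  }
  if (length(codes) < 8L) {
    stop_degenerate("boundary chain shorter than 8 moves")
  }
  structure(list(start = c(x = sx, y = sy), codes = codes, closed = TRUE),
            class = "chain_code")
}

# Resume the Moore neighborhood scan just past the backtrack pixel
# (the pixel we came from sits at dprev + 4): first candidate is dprev + 5.
next_direction <- function(m, cx, cy, dprev) {
  nx <- nrow(m); ny <- ncol(m)
  s <- (dprev + 5L) %% 8L
  for (k in 0:7) {
    d <- (s + k) %% 8L
    xp <- cx + CHAIN_DX[d + 1L]; yp <- cy + CHAIN_DY[d + 1L]
    if (xp >= 1L && xp <= nx && yp >= 1L && yp <= ny && m[xp, yp]) return(d)
  }
  NA_integer_
}

# Count 8-connected foreground components by iterative frontier expansion.
count_components <- function(m) {
  remaining <- m
  count <- 0L
  while (any(remaining)) {
    count <- count + 1L
    seed <- which(remaining)[1]
    comp <- matrix(FALSE, nrow(m), ncol(m))
    comp[seed] <- TRUE
    repeat {
      grown <- dilate8(comp) & remaining
      if (all(grown == comp)) break
      comp <- grown
    }
    remaining <- remaining & !comp
    if (count > 64L) break  # enough to report "many"
  }
  count
}

dilate8 <- function(b) {
  nx <- nrow(b); ny <- ncol(b)
  out <- b
  sh <- function(mat, dx, dy) {
    res <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
    okx <- xs >= 1L & xs <= nx; oky <- ys >= 1L & ys <= ny
    res[okx, oky] <- mat[xs[okx], ys[oky]]
    res
  }
  for (d in 1:8) out <- out | sh(b, CHAIN_DX[d], CHAIN_DY[d])
  out
}

#' Convert a chain code to its polyline in pixel coordinates
#'
#' @param chain a `chain_code` from [trace_contour()].
#' @return an n x 2 matrix of pixel-center vertices (the start point first;
#'   the closing vertex is implicit).
#' @export
chain_to_polyline <- function(chain) {
  dx <- CHAIN_DX[chain$codes + 1L]
  dy <- CHAIN_DY[chain$codes + 1L]
  x <- chain$start[["x"]] + cumsum(c(0L, dx))
  y <- chain$start[["y"]] + cumsum(c(0L, dy))
  n <- length(x)
  if (x[n] != x[1] || y[n] != y[1]) stop_validation("chain code is not closed")
  cbind(x = x[-n], y = y[-n])
}
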