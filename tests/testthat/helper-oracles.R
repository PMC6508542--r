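# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Brute-force optimal superimposition over a fine rotation grid, both
# determinant signs.
grid_superimpose <- function(A, B, step = 0.001) {
  best <- Inf
  for (th in seq(0, 2 * pi, by = step)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    for (s in c(1, -1)) {
      r <- sqrt(sum((A - B %*% (R %*% diag(c(1, s))))^2))
      if (r < best) best <- r
    }
  }
  best
}

# Alternating-minimization generalized Procrustes oracle built on
# vegan::procrustes for the pairwise rotation step.
gpa_oracle <- function(configs, tol = 1e-12, max_iter = 2000L) {
  X <- lapply(configs, function(m) {
    m <- as.matrix(m)
    ctr <- colMeans(m)
    c0 <- sweep(m, 2L, ctr)
    c0 / sqrt(sum(c0^2))
  })
  mean_shape <- X[[1]]
  for (it in seq_len(max_iter)) {
    X <- lapply(X, function(cfg) {
      cfg %*% vegan::procrustes(mean_shape, cfg, symmetric = FALSE, scale = FALSE)$rotation
    })
    nm <- Reduce(`+`, X) / length(X)
    nm <- nm / sqrt(sum(sweep(nm, 2L, colMeans(nm))^2))
    if (sqrt(sum((nm - mean_shape)^2)) < tol) break
    mean_shape <- nm
  }
  list(aligned = X, mean = Reduce(`+`, X) / length(X))
}

# Dense numerical integration of the elliptical Fourier integrals over a
# piecewise-linear contour (midpoint rule on finely subdivided segments).
efd_quadrature <- function(points, harmonics, subdiv = 400L) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  xs <- c(); ys <- c(); ds <- c()
  for (i in seq_len(n)) {
    p <- pts[i, ]; q <- pts[nxt[i], ]
    L <- sqrt(sum((q - p)^2))
    if (L < 1e-15) next
    tt <- (seq_len(subdiv) - 0.5) / subdiv
    xs <- c(xs, p[1] + tt * (q[1] - p[1]))
    ys <- c(ys, p[2] + tt * (q[2] - p[2]))
    ds <- c(ds, rep(L / subdiv, subdiv))
  }
  s <- cumsum(ds) - ds / 2
  Tt <- sum(ds)
  phi <- 2 * pi * s / Tt
  out <- matrix(0, harmonics, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(harmonics)) {
    out[h, 1] <- 2 / Tt * sum(xs * cos(h * phi) * ds)
    out[h, 2] <- 2 / Tt * sum(xs * sin(h * phi) * ds)
    out[h, 3] <- 2 / Tt * sum(ys * cos(h * phi) * ds)
    out[h, 4] <- 2 / Tt * sum(ys * sin(h * phi) * ds)
  }
  out
}

# First-harmonic axis ratio of an ellipse under arc-length parameterization,
# by dense quadrature of the exact contour.
ellipse_arclength_d1 <- function(a = 2, b = 1, n = 20000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  x <- a * cos(th); y <- b * sin(th)
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(ds)); Tt <- s[length(s)]
  xm <- (x[-1] + x[-length(x)]) / 2; ym <- (y[-1] + y[-length(y)]) / 2
  pm <- 2 * pi * (s[-1] - ds / 2) / Tt
  a1 <- 2 / Tt * sum(xm * cos(pm) * ds)
  d1 <- 2 / Tt * sum(ym * sin(pm) * ds)
  d1 / a1
}

# Mean distance from each point of `poly` to the nearest vertex-sampled
# point of `ref` (both n x 2).
mean_nearest_dist <- function(poly, ref) {
  d2 <- outer(rowSums(poly^2), rowSums(ref^2), `+`) - 2 * poly %*% t(ref)
  mean(sqrt(pmax(apply(d2, 1L, min), 0)))
}

# Silhouette of a 2-group labelling in a 2-D embedding.
silhouette2 <- function(Y, labels) {
  D <- as.matrix(dist(Y))
  sil <- vapply(seq_len(nrow(Y)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(Y)) != i])
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, 0)
  mean(sil)
}

# Brute-force complete-linkage agglomeration: merge heights by exhaustive
# pairwise search.
complete_linkage_heights <- function(mat) {
  groups <- lapply(seq_len(nrow(mat)), identity)
  D <- as.matrix(dist(mat))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq.int(i + 1L, length(groups))) {
        h <- max(D[groups[[i]], groups[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  heights
}

# Small random landmark configuration.
random_config <- function(k = 15L, sd = 1) matrix(rnorm(2L * k, sd = sd), k)

# A tiny leaf collection built by hand (no generator) for I/O tests.
tiny_collection <- function(n = 3L, numbering = "base_first") {
  set.seed(11)
  coords <- matrix(rnorm(n * 30L), n, 30L,
                   dimnames = list(NULL, c(paste0("x", 1:15), paste0("y", 1:15))))
  df <- tibble::tibble(
    species = rep("spA", n), vine = rep("v1", n), node = seq_len(n),
    class_label = rep("A", n)
  )
  leaf_collection(dplyr::bind_cols(df, tibble::as_tibble(coords)), numbering = numbering)
}
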