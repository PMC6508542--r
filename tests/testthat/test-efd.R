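digitize <- function(points, resolution = 1) {
  trace_contour(rasterize_outline(outline(points), resolution, check = FALSE))
}

circle_pts <- function(r = 50, cx = 60, cy = 60, n = 512) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

square_pts <- function(lo = 10, hi = 40, per_edge = 4) {
  s <- seq(lo, hi, length.out = per_edge + 1)[-(per_edge + 1)]
  r <- seq(hi, lo, length.out = per_edge + 1)[-(per_edge + 1)]
  rbind(cbind(s, lo), cbind(hi, s), cbind(r, hi), cbind(lo, r))
}

test_that("contour tracing yields closed counter-clockwise chains with a deterministic start", {
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  ch <- trace_contour(m)
  expect_length(ch$codes, 36L)
  expect_setequal(unique(ch$codes), c(0L, 2L, 4L, 6L))
  expect_identical(unname(ch$start), c(3L, 12L))  # left-most pixel of top-most row
  # closure: net displacement zero for this and for digitized curved shapes
  for (chain in list(ch, digitize(circle_pts()))) {
    dx <- leafmorph:::CHAIN_DX[chain$codes + 1L]
    dy <- leafmorph:::CHAIN_DY[chain$codes + 1L]
    expect_identical(c(sum(dx), sum(dy)), c(0L, 0L))
    expect_gt(leafmorph:::signed_area(chain_to_polyline(chain)), 0)
  }
  expect_error(trace_contour(matrix(FALSE, 5, 5)), class = "leafmorph_degenerate_error")
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(trace_contour(single), class = "leafmorph_degenerate_error")
  two <- matrix(FALSE, 9, 9); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  expect_error(trace_contour(two), "2", class = "leafmorph_validation_error")
})

test_that("chain-code EFDs reproduce analytic shapes and a quadrature oracle", {
  # circle: first harmonic (1, 0, 0, 1), higher harmonics tiny
  ne <- normalize_efd(chain_to_efd(digitize(circle_pts()), 10))
  expect_equal(unname(unclass(ne)[1, ]), c(1, 0, 0, 1), tolerance = 0.01)
  expect_lt(max(abs(unclass(ne)[2:5, ])), 0.02)

  # 2:1 ellipse: d1 equals the arc-length first-harmonic ratio (dense
  # quadrature of the exact contour; uniform-angle parameterization would
  # give 0.5, but chain codes advance by arc length)
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  ell <- cbind(100 + 80 * cos(th), 100 + 40 * sin(th))
  ne2 <- normalize_efd(chain_to_efd(digitize(ell), 10))
  expect_equal(unname(unclass(ne2)[1, 4]), ellipse_arclength_d1(2, 1), tolerance = 0.02)

  # square: closed-form coefficients match dense numerical integration of the
  # same polyline
  sq_chain <- digitize(square_pts())
  poly <- chain_to_polyline(sq_chain)
  got <- chain_to_efd(sq_chain, 12)
  oracle <- efd_quadrature(poly, 12)
  expect_equal(unclass(got), oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("first-harmonic normalization is idempotent and similarity/start invariant", {
  sim <- simulate_leaves(sim_params(n_species = 2, vines_per_species = 1,
                                    nodes_per_vine = 3, seed = 13))
  leafy <- sim$leaves$outline[[3]]
  base <- normalize_efd(outline_efd(leafy, 15))
  expect_equal(unname(unclass(base)[1, 1:3]), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(unclass(normalize_efd(base)), unclass(base), tolerance = 1e-12)

  # rotation by 37 degrees and 3x scaling
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- 3 * as.matrix(leafy) %*% R
  expect_equal(unclass(normalize_efd(outline_efd(moved, 15))), unclass(base),
               tolerance = 1e-6, ignore_attr = TRUE)

  # starting-point shift of the source contour
  n <- nrow(leafy)
  shifted <- as.matrix(leafy)[c(40:n, 1:39), ]
  expect_equal(unclass(normalize_efd(outline_efd(shifted, 15))), unclass(base),
               tolerance = 1e-6, ignore_attr = TRUE)

  degen <- matrix(0, 5, 4)
  class(degen) <- c("efd_coefficients", "matrix", "array")
  expect_error(normalize_efd(degen), class = "leafmorph_degenerate_error")
})

test_that("Parseval energy is invariant under starting-point shift", {
  poly <- chain_to_polyline(digitize(circle_pts(30, 40, 40, 256)))
  e1 <- sum(unclass(outline_efd(poly, 20))^2)
  e2 <- sum(unclass(outline_efd(poly[c(100:nrow(poly), 1:99), ], 20))^2)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("reconstruction refines monotonically and reproduces sources", {
  one <- matrix(c(1, 0, 0, 1), 1)
  class(one) <- c("efd_coefficients", "matrix", "array")
  circ <- reconstruct_outline(one, 64)
  expect_equal(sqrt(rowSums(circ^2)), rep(1, 64), tolerance = 1e-9)
  expect_error(reconstruct_outline(one, 8), class = "leafmorph_validation_error")

  sq_chain <- digitize(square_pts())
  poly <- chain_to_polyline(sq_chain)
  errs <- vapply(c(2L, 5L, 10L, 20L, 40L), function(H) {
    mean_nearest_dist(reconstruct_outline(chain_to_efd(sq_chain, H), 400), poly)
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3] , errs[1])

  # digitized leaf-like fixture at H = 20: sub-pixel mean deviation
  sim <- simulate_leaves(sim_params(n_species = 2, vines_per_species = 1,
                                    nodes_per_vine = 3, seed = 13))
  chain <- trace_contour(rasterize_outline(sim$leaves$outline[[5]], resolution = 200,
                                           check = FALSE))
  ref <- chain_to_polyline(chain)
  rec <- reconstruct_outline(chain_to_efd(chain, 20), 600)
  expect_lt(mean_nearest_dist(rec, ref), 1)
})

test_that("mean EFDs and harmonic contributions behave coefficient-wise", {
  base <- normalize_efd(outline_efd(circle_pts(1, 0, 0, 64), 6))
  same <- mean_efd(list(base, base, base))
  expect_equal(unclass(same), unclass(base), tolerance = 1e-12)

  delta <- unclass(base); delta[3, ] <- delta[3, ] + 0.1
  minus <- unclass(base); minus[3, ] <- minus[3, ] - 0.1
  cls <- c("efd_coefficients", "matrix", "array")
  class(delta) <- cls; class(minus) <- cls
  expect_equal(unclass(mean_efd(list(delta, minus))), unclass(base), tolerance = 1e-12)

  short <- unclass(base)[1:3, ]; class(short) <- cls
  expect_error(mean_efd(list(base, short)), class = "leafmorph_validation_error")

  grid <- harmonic_contribution(base, ranks = 1:3, factors = c(0, 1, 2, 3))
  expect_identical(nrow(grid), 12L)
  ident <- grid$outline[[which(grid$rank == 2 & grid$factor == 1)]]
  expect_equal(ident, reconstruct_outline(base, 200), tolerance = 1e-12)
  removed <- grid$outline[[which(grid$rank == 2 & grid$factor == 0)]]
  dropped <- unclass(base); dropped[2, ] <- 0; class(dropped) <- cls
  expect_equal(removed, reconstruct_outline(dropped, 200), tolerance = 1e-12)
  expect_error(harmonic_contribution(base, ranks = 0), class = "leafmorph_validation_error")
  expect_error(harmonic_contribution(base, ranks = 7), class = "leafmorph_validation_error")
})

test_that("per-leaf EFD traits are normalized and keyed to the collection", {
  sim <- simulate_leaves(sim_params(n_species = 2, vines_per_species = 1,
                                    nodes_per_vine = 4, seed = 19))
  ef <- efd_traits(sim$leaves, harmonics = 8)
  expect_identical(nrow(ef), nrow(sim$leaves))
  expect_true(all(abs(ef$a1 - 1) < 1e-9))
  expect_true(all(abs(ef$b1) < 1e-9) && all(abs(ef$c1) < 1e-9))
  expect_identical(attr(ef, "harmonics"), 8L)
})
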