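rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)

test_that("centering and unit-size scaling behave as the size measure requires", {
  sq <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4)
  cs <- center_scale(sq)
  expect_equal(colMeans(cs$config), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(cs$config^2)), 1, tolerance = 1e-12)
  # centroid size of the unit square: 4 corners at distance sqrt(0.5)
  expect_equal(cs$size, sqrt(4 * 0.5), tolerance = 1e-12)
  # idempotent on an already-normalized configuration
  again <- center_scale(cs$config)
  expect_equal(again$config, cs$config, tolerance = 1e-12)
  expect_equal(again$size, 1, tolerance = 1e-12)
  expect_error(center_scale(matrix(1, 5, 2)), class = "leafmorph_degenerate_error")
})

test_that("pairwise superimposition recovers exact transforms and matches a grid oracle", {
  set.seed(21)
  A <- center_scale(random_config())$config
  B <- A %*% rot2(pi / 2)
  fit <- superimpose(A, B)
  expect_lt(fit$residual, 1e-12)
  expect_equal(B %*% fit$rotation, A, tolerance = 1e-12)

  M <- A %*% diag(c(-1, 1))  # mirrored copy
  expect_lt(superimpose(A, M, allow_reflection = TRUE)$residual, 1e-12)
  expect_gt(superimpose(A, M, allow_reflection = FALSE)$residual, 0.01)
  det_c <- det(superimpose(A, M, allow_reflection = FALSE)$rotation)
  expect_equal(det_c, 1, tolerance = 1e-12)

  B2 <- center_scale(random_config())$config
  fit2 <- superimpose(A, B2)
  grid <- grid_superimpose(A, B2)
  expect_lte(fit2$residual, grid + 1e-12)
  expect_lt(grid - fit2$residual, 1e-5)
  expect_error(superimpose(A, B2[1:10, ]), class = "leafmorph_validation_error")
})

test_that("procrustes distance is a similarity-invariant symmetric premetric", {
  set.seed(22)
  A <- random_config()
  expect_equal(procrustes_distance(A, A), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(A, 2 * A), 0, tolerance = 1e-12)
  moved <- 0.5 * A %*% rot2(1.1) + matrix(rep(c(3, -2), each = 15), 15)
  expect_lt(procrustes_distance(A, moved), 1e-12)
  B <- random_config()
  expect_equal(procrustes_distance(A, B), procrustes_distance(B, A), tolerance = 1e-12)
  # square vs 2:1 rectangle, against the grid-search oracle
  sq <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4)
  rect <- matrix(c(0, 2, 2, 0, 0, 0, 1, 1), 4)
  d <- procrustes_distance(sq, rect)
  oracle <- grid_superimpose(center_scale(sq)$config, center_scale(rect)$config)
  expect_equal(d, oracle, tolerance = 1e-5)
})

test_that("generalized Procrustes alignment matches an independent alternating oracle", {
  set.seed(23)
  configs <- lapply(1:10, function(i) random_config())
  fit <- gpa(configs)
  expect_true(fit$converged)
  # invariants: centered, unit size, mean is the coordinate-wise average
  for (m in fit$aligned) {
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_lt(abs(sqrt(sum(m^2)) - 1), 1e-9)
  }
  expect_equal(fit$mean_shape, Reduce(`+`, fit$aligned) / 10, tolerance = 1e-12)

  orc <- gpa_oracle(configs)
  expect_lt(procrustes_distance(fit$mean_shape, orc$mean), 1e-6)
  for (i in c(1, 4, 9)) {
    expect_equal(procrustes_distance(fit$aligned[[i]], fit$aligned[[i + 1]]),
                 procrustes_distance(orc$aligned[[i]], orc$aligned[[i + 1]]),
                 tolerance = 1e-9)
  }
  expect_error(gpa(configs[1]), class = "leafmorph_validation_error")
})

test_that("alignment is invariant to arbitrary similarity transforms of the inputs", {
  set.seed(24)
  configs <- lapply(1:6, function(i) random_config())
  fit0 <- gpa(configs)
  mangled <- lapply(seq_along(configs), function(i) {
    s <- runif(1, 0.3, 3)
    R <- rot2(runif(1, 0, 2 * pi)) %*% diag(c(sample(c(-1, 1), 1), 1))
    s * configs[[i]] %*% R + matrix(rep(runif(2, -5, 5), each = 15), 15)
  })
  fit1 <- gpa(mangled)
  pd0 <- sapply(1:5, function(i) procrustes_distance(fit0$aligned[[i]], fit0$aligned[[i + 1]]))
  pd1 <- sapply(1:5, function(i) procrustes_distance(fit1$aligned[[i]], fit1$aligned[[i + 1]]))
  expect_equal(pd0, pd1, tolerance = 1e-9)
  # two configurations related by a similarity transform align exactly
  pair <- gpa(list(configs[[1]], 2.5 * configs[[1]] %*% rot2(0.7) + 3))
  expect_lt(procrustes_distance(pair$aligned[[1]], pair$aligned[[2]]), 1e-9)
})

test_that("a mirrored dataset yields identical pairwise distances when reflection is allowed", {
  set.seed(25)
  configs <- lapply(1:5, function(i) random_config())
  mirrored <- lapply(configs, function(m) m %*% diag(c(-1, 1)))
  f1 <- gpa(configs, allow_reflection = TRUE)
  f2 <- gpa(mirrored, allow_reflection = TRUE)
  d1 <- sapply(1:4, function(i) procrustes_distance(f1$aligned[[i]], f1$aligned[[i + 1]]))
  d2 <- sapply(1:4, function(i) procrustes_distance(f2$aligned[[i]], f2$aligned[[i + 1]]))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("per-node mean shapes average aligned configurations node-wise", {
  col <- tiny_collection(4)
  attr(col, "aligned") <- TRUE
  col$node <- c(1L, 1L, 2L, 3L)
  means <- node_mean_shapes(col)
  expect_identical(means$node, c(1L, 2L, 3L))
  expect_identical(means$n, c(2L, 1L, 1L))
  expect_equal(landmark_matrix(means[means$node == 2, ]),
               landmark_matrix(col[3, ]), tolerance = 1e-12)
  expect_equal(landmark_matrix(means[means$node == 1, ]),
               (landmark_matrix(col[1, ]) + landmark_matrix(col[2, ])) / 2,
               tolerance = 1e-12)
  # a collection that is not aligned draws a quality warning
  expect_warning(node_mean_shapes(tiny_collection(3)), class = "leafmorph_quality_warning")
})

test_that("aligning a collection preserves row order and records sizes", {
  sim <- simulate_leaves(sim_params(n_species = 2, vines_per_species = 2,
                                    nodes_per_vine = 4, seed = 8, shape_noise_sd = 0))
  al <- align_leaves(sim$leaves)
  expect_identical(al$species, sim$leaves$species)
  p <- sim$truth$params
  expect_equal(al$centroid_size, p$size_base + p$size_gain * sim$leaves$node,
               tolerance = 1e-9)
  # re-aligning aligned data changes nothing beyond tolerance
  al2 <- align_leaves(al)
  expect_equal(as.matrix(al2[, leafmorph:::coord_names()]),
               as.matrix(al[, leafmorph:::coord_names()]), tolerance = 1e-6)
})
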