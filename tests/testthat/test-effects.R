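test_that("the trait model recovers noise-free coefficients exactly", {
  nodes <- rep(1:10, 2)
  species <- rep(c("A", "B"), each = 10)
  y <- 2 + 3 * (species == "B") + 0 * nodes + 1 * (species == "B") * nodes
  row <- fit_trait_model(y, species, nodes, reference = "A")
  expect_equal(unname(row$estimate[row$term == "species"]), 3, tolerance = 1e-10)
  expect_equal(unname(row$estimate[row$term == "heteroblasty"]), 0, tolerance = 1e-10)
  expect_equal(unname(row$estimate[row$term == "interaction"]), 1, tolerance = 1e-10)

  tr <- tibble::tibble(species = species, node = nodes, t1 = y)
  full <- effect_matrices(tr, include_reference = TRUE)
  ref_rows <- full[full$species == "A" & full$term %in% c("species", "interaction"), ]
  expect_true(all(ref_rows$estimate == 0))
  expect_error(effect_matrices(tr, reference = "Z"), class = "leafmorph_validation_error")
})

test_that("changing the reference species changes coefficients but not fitted values", {
  set.seed(51)
  tr <- tibble::tibble(
    species = rep(c("A", "B", "C"), each = 12),
    node = rep(1:12, 3),
    t1 = rnorm(36), t2 = rnorm(36)
  )
  predict_from <- function(et, data, trait) {
    ints <- attr(et, "intercepts")
    b0 <- ints$intercept[ints$trait == trait]
    b1 <- ints$node_slope[ints$trait == trait]
    ref <- attr(et, "reference")
    sub <- et[et$trait == trait, ]
    off <- function(sp, term) {
      if (sp == ref) return(0)
      sub$estimate[sub$term == term & !is.na(sub$species) & sub$species == sp]
    }
    vapply(seq_len(nrow(data)), function(i) {
      sp <- data$species[i]
      b0 + off(sp, "species") + (b1 + off(sp, "interaction")) * data$node[i]
    }, 0)
  }
  eA <- effect_matrices(tr, reference = "A")
  eC <- effect_matrices(tr, reference = "C")
  expect_false(isTRUE(all.equal(eA$estimate, eC$estimate)))
  expect_equal(predict_from(eA, tr, "t1"), predict_from(eC, tr, "t1"), tolerance = 1e-9)
  expect_equal(predict_from(eA, tr, "t2"), predict_from(eC, tr, "t2"), tolerance = 1e-9)
})

test_that("constant traits and rank-deficient species are flagged, not fatal", {
  tr <- tibble::tibble(
    species = rep(c("A", "B"), each = 6),
    node = c(1:6, rep(2L, 6)),  # species B observed at a single node
    flat = rep(1, 12),
    ok = rnorm(12)
  )
  et <- effect_matrices(tr)
  expect_true(all(et$estimate[et$trait == "flat"] == 0))
  expect_true(all(et$constant[et$trait == "flat"]))
  bint <- et[et$trait == "ok" & et$term == "interaction", ]
  expect_false(any(bint$estimable))
})

test_that("generating interaction slopes are recovered within 3 standard errors", {
  p <- sim_params(seed = 29, shape_noise_sd = 0.01)
  sim <- simulate_leaves(p, scale_size = FALSE)
  cn <- leafmorph:::coord_names()
  tr <- dplyr::bind_cols(sim$leaves[, c("species", "node")], sim$leaves[, cn])
  et <- effect_matrices(tr)
  truth <- sim$truth
  ref <- attr(et, "reference")
  # generating slope of each species: least-squares projection of w_s(k) on k
  proj <- function(s) {
    w <- truth$weights$w[truth$weights$species == s]
    k <- truth$weights$node[truth$weights$species == s]
    stats::coef(stats::lm(w ~ k))[["k"]]
  }
  D <- truth$deformation
  b_ref <- proj(ref)
  checks <- 0L; within <- 0L
  for (s in setdiff(names(D), ref)) {
    b_s <- proj(s)
    true_slope <- b_s * c(D[[s]][, 1], D[[s]][, 2]) - b_ref * c(D[[ref]][, 1], D[[ref]][, 2])
    sub <- et[et$term == "interaction" & et$species == s, ]
    sub <- sub[match(cn, sub$trait), ]
    dev <- abs(sub$estimate - true_slope) / sub$se
    checks <- checks + length(dev)
    within <- within + sum(dev <= 3)
  }
  expect_gte(within / checks, 0.95)

  # zero noise: exact recovery of the projected slopes
  sim0 <- simulate_leaves(sim_params(seed = 29, shape_noise_sd = 0), scale_size = FALSE)
  tr0 <- dplyr::bind_cols(sim0$leaves[, c("species", "node")], sim0$leaves[, cn])
  et0 <- effect_matrices(tr0)
  s2 <- setdiff(names(sim0$truth$deformation), ref)[1]
  w <- sim0$truth$weights$w[sim0$truth$weights$species == s2]
  k <- sim0$truth$weights$node[sim0$truth$weights$species == s2]
  b_s2 <- stats::coef(stats::lm(w ~ k))[["k"]]
  wr <- sim0$truth$weights$w[sim0$truth$weights$species == ref]
  b_r2 <- stats::coef(stats::lm(wr ~ k))[["k"]]
  D0 <- sim0$truth$deformation
  expected <- b_s2 * c(D0[[s2]][, 1], D0[[s2]][, 2]) - b_r2 * c(D0[[ref]][, 1], D0[[ref]][, 2])
  sub0 <- et0[et0$term == "interaction" & et0$species == s2, ]
  sub0 <- sub0[match(cn, sub0$trait), ]
  expect_equal(unname(sub0$estimate), unname(expected), tolerance = 1e-8)
})

test_that("species effects dominate interactions, which dominate the heteroblasty term", {
  sim <- simulate_leaves(sim_params(seed = 7))
  al <- suppressWarnings(align_leaves(sim$leaves))
  traits <- suppressWarnings(leaf_traits(al))
  tr <- drop_constant_traits(traits[, c("species", "node", trait_columns(traits))])
  gl <- glance(effect_matrices(tr))
  o <- stats::setNames(gl$mean_abs_effect, gl$term)
  expect_gt(o[["species"]], o[["interaction"]])
  expect_gt(o[["interaction"]], o[["heteroblasty"]])
  # species effects are several-fold stronger than everything node-linked
  expect_gt(o[["species"]] / o[["interaction"]], 2)
})

test_that("trait clustering is deterministic and matches a brute-force oracle", {
  m <- rbind(a = c(0, 0), b = c(0, 0.01), c = c(5, 5), d = c(5.2, 5), e = c(-4, 2), f = c(20, -20))
  cl <- cluster_traits(m)
  # identical-ish profiles merge first, the outlier joins last
  expect_equal(cl$hclust$height[1], dist(m[c("a", "b"), ])[1], tolerance = 1e-12)
  expect_identical(cl$labels[which.max(cl$labels == "f")], "f")
  merged_last <- cl$hclust$merge[nrow(cl$hclust$merge), ]
  expect_true(-6L %in% merged_last)  # row 6 = the outlier profile
  oracle <- complete_linkage_heights(m)
  expect_equal(sort(cl$hclust$height), sort(oracle), tolerance = 1e-9)

  expect_error(cluster_traits(m[1, , drop = FALSE]), class = "leafmorph_validation_error")
  m2 <- m; m2[2, 1] <- NA
  expect_error(cluster_traits(m2), class = "leafmorph_validation_error")
})
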