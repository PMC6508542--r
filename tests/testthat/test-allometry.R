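test_that("shoelace areas match closed forms and a Monte-Carlo oracle", {
  expect_equal(polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  expect_equal(polygon_area(cbind(c(0, 2, 0), c(0, 0, 2))), 2)
  expect_error(polygon_area(cbind(0:1, 0:1)), class = "leafmorph_validation_error")

  set.seed(31)
  # star-shaped random 7-gon (vertices sorted by angle => simple)
  th <- sort(runif(7, 0, 2 * pi))
  r <- runif(7, 0.5, 1.5)
  poly <- cbind(r * cos(th), r * sin(th))
  a <- polygon_area(poly)
  pts <- cbind(runif(1e6, -1.5, 1.5), runif(1e6, -1.5, 1.5))
  # crossing-number point-in-polygon, vectorized over test points
  inside <- rep(FALSE, nrow(pts))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    cond <- (poly[i, 2] > pts[, 2]) != (poly[j, 2] > pts[, 2])
    xi <- poly[i, 1] + (pts[, 2] - poly[i, 2]) / (poly[j, 2] - poly[i, 2]) *
      (poly[j, 1] - poly[i, 1])
    inside <- xor(inside, cond & pts[, 1] < xi)
  }
  mc <- mean(inside) * 9
  expect_equal(a, mc, tolerance = 0.005)
})

test_that("subareas tile custom polygon specs and flag degenerate configurations", {
  cfg <- matrix(0, 15, 2)
  cfg[1:4, ] <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  spec <- structure(list(
    subregions = list(lower = list(c(1L, 2L, 3L)), upper = list(c(1L, 3L, 4L))),
    total = c(1L, 2L, 3L, 4L)
  ), class = "polygon_spec")
  rec <- leaf_subareas(cfg, spec)
  expect_equal(rec$area_lower, 0.5)
  expect_equal(rec$area_upper, 0.5)
  expect_equal(rec$area_total, 1)
  expect_false(rec$flagged)

  # coincident vein landmarks collapse the vein strip to zero area
  sim <- simulate_leaves(sim_params(n_species = 2, vines_per_species = 1,
                                    nodes_per_vine = 3, seed = 41, shape_noise_sd = 0))
  cfg2 <- landmark_matrix(sim$leaves[1, ])
  cfg2[2, ] <- cfg2[3, ] <- cfg2[1, ]
  rec2 <- leaf_subareas(cfg2)
  expect_equal(rec2$area_midvein, 0, tolerance = 1e-12)

  # a folded subregion polygon is flagged
  cfg3 <- landmark_matrix(sim$leaves[1, ])
  cfg3[3, 1] <- cfg3[2, 1] - 0.05  # swap midvein base pair: quad flips
  expect_true(leaf_subareas(cfg3)$flagged)
})

test_that("subareas close exactly on generated leaves, raw and aligned", {
  sim <- simulate_leaves(sim_params(seed = 17))
  for (col in list(sim$leaves, align_leaves(sim$leaves))) {
    sa <- suppressWarnings(subarea_table(col))
    ok <- !sa$flagged
    expect_gt(mean(ok), 0.95)
    total <- sa$area_distal_blade + sa$area_proximal_blade +
      sa$area_midvein + sa$area_proximal_vein
    expect_lt(max(abs(total - sa$area_total)[ok]), 1e-9)
  }
})

test_that("areas are scale-equivariant and allometric slopes scale-invariant", {
  sim <- simulate_leaves(sim_params(n_species = 2, vines_per_species = 2,
                                    nodes_per_vine = 5, seed = 43))
  sa1 <- suppressWarnings(subarea_table(sim$leaves))
  scaled <- sim$leaves
  cn <- leafmorph:::coord_names()
  scaled[, cn] <- scaled[, cn] * 3
  sa3 <- suppressWarnings(subarea_table(scaled))
  expect_equal(sa3$area_total, 9 * sa1$area_total, tolerance = 1e-9)
  expect_equal(sa3$area_midvein, 9 * sa1$area_midvein, tolerance = 1e-9)
  f1 <- suppressWarnings(fit_allometry(sa1))
  f3 <- suppressWarnings(fit_allometry(sa3))
  expect_equal(f1$slope, f3$slope, tolerance = 1e-9)
})

test_that("sqrt-allometric regression recovers exact structure and guards degenerate groups", {
  # base-R lm warns about the (intended) numerically perfect fits
  quiet_fit <- function(...) {
    withCallingHandlers(fit_allometry(...),
                        simpleWarning = function(w) invokeRestart("muffleWarning"))
  }
  # exact linearity: sqrt(subarea) = 0.5 sqrt(total)
  tot <- seq(1, 4, length.out = 20)
  sa <- tibble::tibble(area_half = 0.25 * tot, area_rest = 0.75 * tot, area_total = tot)
  fit <- quiet_fit(sa)
  half <- fit[fit$subregion == "half", ]
  expect_equal(half$slope, 0.5, tolerance = 1e-12)
  expect_equal(half$intercept, 0, tolerance = 1e-12)
  expect_equal(half$r_squared, 1, tolerance = 1e-12)

  # constant total area: slope undefined, group skipped with a warning
  const <- tibble::tibble(area_a = rep(0.3, 5), area_total = rep(1, 5))
  expect_warning(expect_error(fit_allometry(const), class = "leafmorph_validation_error"),
                 class = "leafmorph_quality_warning")
  # group with < 3 records skipped
  sa$grp <- c("big", rep("ok", 19))
  expect_warning(quiet_fit(sa, group_by = "grp"), class = "leafmorph_quality_warning")

  # noise-free recovery of the generating slopes from the subarea model
  p <- sim_params(seed = 5)
  series <- simulate_subareas(p, n = 300)
  fit2 <- quiet_fit(series)
  slopes <- attr(series, "slopes")
  for (r in names(slopes)) {
    got <- fit2$slope[fit2$subregion == r]
    expect_lt(abs(got - slopes[[r]]) / slopes[[r]], 0.01)
  }
})

test_that("blade subareas expand faster than vein subareas on generated leaf series", {
  sim <- simulate_leaves(sim_params(seed = 17))
  sa <- suppressWarnings(subarea_table(align_leaves(sim$leaves)))
  overall <- suppressWarnings(fit_allometry(sa))
  blades <- overall$slope[grepl("blade", overall$subregion)]
  veins <- overall$slope[grepl("vein|midvein", overall$subregion)]
  expect_gt(mean(blades), max(veins))
  per_species <- glance(suppressWarnings(fit_allometry(sa, group_by = "species")))
  expect_gt(mean(per_species$slope_gap > 0), 0.6)
})
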