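#' Parameters of the synthetic heteroblastic leaf-series generator
#'
#' The generator emulates the structure of a multi-species heteroblastic
#' leaf collection: every species starts from one shared juvenile shape and
#' follows its own saturating (logistic-in-node) trajectory toward a
#' species-specific adult shape, with most of the change completed in the
#' first few nodes. Trajectory directions are centered across species so
#' that the node main effect (averaged over species) is negligible by
#' construction, while species-specific trajectories produce strong
#' species and species-by-node interaction effects.
#'
#' @param n_species number of species (>= 2).
#' @param vines_per_species vines grown per species.
#' @param nodes_per_vine nodes sampled per vine (>= 2), numbered base-first.
#' @param w0 trajectory weight at node 1 (0 = pure juvenile shape; 1 makes
#'   every node fully adult, i.e. no heteroblasty).
#' @param rate_range range of the per-species logistic rate of the
#'   juvenile-to-adult transition (drawn uniformly per species).
#' @param inflection shared node at which the logistic transition is
#'   steepest; below node 2 most change happens within the first two nodes.
#' @param shape_noise_sd per-landmark isotropic Gaussian noise, in
#'   mean-shape units (the leaf template is ~1 unit tall).
#' @param size_base,size_gain centroid size of a node-k leaf is
#'   `size_base + size_gain * k` (allometric growth along the shoot).
#' @param blade_slope,vein_slope generating square-root allometric slopes of
#'   blade vs vein subareas (`blade_slope > vein_slope` enforced): vein
#'   subarea fractions of the juvenile and adult template are set to
#'   `vein_slope^2` (midvein) and `(0.8 * vein_slope)^2` (proximal veins),
#'   and [simulate_subareas()] draws directly from the implied exact
#'   sqrt-linear model.
#' @param seed integer seed; identical parameters give byte-identical data.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_species = 8L, vines_per_species = 5L, nodes_per_vine = 10L,
                       w0 = 0.05, rate_range = c(1.0, 1.7), inflection = 1.5,
                       shape_noise_sd = 0.005, size_base = 1, size_gain = 0.25,
                       blade_slope = 0.67, vein_slope = 0.20, seed = 1L) {
  if (n_species < 2L) stop_validation("n_species must be >= 2")
  if (vines_per_species < 1L) stop_validation("vines_per_species must be >= 1")
  if (nodes_per_vine < 2L) stop_validation("nodes_per_vine must be >= 2")
  if (w0 < 0 || w0 > 1) stop_validation("w0 must lie in [0, 1]")
  if (shape_noise_sd < 0) stop_validation("shape_noise_sd must be >= 0")
  if (size_base <= 0 || size_gain < 0) stop_validation("size_base must be > 0 and size_gain >= 0")
  if (!(blade_slope > vein_slope) || vein_slope <= 0) {
    stop_validation("blade_slope must exceed vein_slope and both must be positive")
  }
  structure(list(
    n_species = as.integer(n_species), vines_per_species = as.integer(vines_per_species),
    nodes_per_vine = as.integer(nodes_per_vine), w0 = w0, rate_range = rate_range,
    inflection = inflection, shape_noise_sd = shape_noise_sd,
    size_base = size_base, size_gain = size_gain,
    blade_slope = blade_slope, vein_slope = vein_slope, seed = as.integer(seed)
  ), class = "sim_params")
}

# Juvenile boundary template: a round, shallowly lobed leaf about 1 unit
# tall with the petiolar junction at the origin. Only the 8 margin
# landmarks are set here; vein landmarks are placed by fill_vein_landmarks().
juvenile_boundary <- function() {
  m <- matrix(NA_real_, N_LANDMARKS, 2L, dimnames = list(NULL, c("x", "y")))
  m[1, ] <- c(0, 0)          # petiolar junction
  m[7, ] <- c(0, 1.00)       # apex (midvein tip)
  m[8, ] <- c(-0.48, 0.62)   # left distal lobe tip
  m[9, ] <- c(0.48, 0.62)    # right distal lobe tip
  m[12, ] <- c(-0.32, 0.50)  # left distal sinus (shallow in the juvenile)
  m[13, ] <- c(0.32, 0.50)   # right distal sinus
  m[14, ] <- c(-0.40, 0.05)  # left proximal lobe tip
  m[15, ] <- c(0.40, 0.05)   # right proximal lobe tip
  m
}

# Place the vein landmarks (2-6, 10, 11) for a given margin geometry so the
# vein polygons of default_polygon_spec() take exact area fractions f_mv
# (midvein) and f_pv (both proximal vein strips together) of the total
# leaf polygon. Both vein areas are linear in the placement parameters, so
# the solution is closed-form.
fill_vein_landmarks <- function(m, f_mv, f_pv) {
  total <- abs(signed_area(m[leaf_boundary_order(), ]))
  p1 <- m[1, ]; p7 <- m[7, ]; p14 <- m[14, ]; p15 <- m[15, ]
  # midvein quad (1, 3, 7, 2) with 2, 3 at (x1 -/+ u, y1 + 0.1 dy):
  # its area is u * (y7 - y1) exactly.
  dy <- p7[2] - p1[2]
  u <- f_mv * total / dy
  h <- p1[2] + 0.1 * dy
  m[2, ] <- c(p1[1] - u, h)
  m[3, ] <- c(p1[1] + u, h)
  m[6, ] <- p1 + 0.05 * (p7 - p1)  # midvein base marker
  # proximal vein strips: trapezoids of height d over the basal margin
  # edges 1-15 (right) and 14-1 (left); area = d * L * (1 + beta - alpha)/2.
  alpha <- 0.15; beta <- 0.9
  Lr <- sqrt(sum((p15 - p1)^2)); Ll <- sqrt(sum((p14 - p1)^2))
  d <- 2 * f_pv * total / ((Lr + Ll) * (1 + beta - alpha))
  inward <- function(from, to) {  # unit normal to the left of from->to (leaf interior)
    v <- (to - from) / sqrt(sum((to - from)^2))
    c(-v[2], v[1])
  }
  nr <- inward(p1, p15)
  m[5, ] <- p1 + alpha * (p15 - p1) + d * nr
  m[11, ] <- p1 + beta * (p15 - p1) + d * nr
  nl <- inward(p14, p1)
  m[4, ] <- p1 + alpha * (p14 - p1) + d * nl
  m[10, ] <- p1 + beta * (p14 - p1) + d * nl
  m
}

vein_fractions <- function(params) {
  c(midvein = params$vein_slope^2, proximal_vein = (0.8 * params$vein_slope)^2)
}

# Species-specific adult margin deformation: deeper sinuses, extended lobes,
# apex elongation and proximal "wing" spread, plus small landmark jitter.
adult_deformation <- function(lobing, elongation, wing, breadth, jitter) {
  d <- matrix(0, N_LANDMARKS, 2L)
  # breadth: proportional width change of the whole margin. A pure x-scaling
  # multiplies every subregion area equally, so it drives total leaf area
  # (per unit centroid size) without disturbing subarea fractions — the
  # dominant, allometrically clean axis of shape change along a series.
  margin <- leaf_boundary_order()
  jb <- juvenile_boundary()
  d[margin, 1] <- d[margin, 1] + breadth * jb[margin, 1]
  # dissection: sinuses cut toward the midvein while lobe tips extend
  d[13, ] <- d[13, ] + c(-0.28, -0.12) * lobing; d[12, ] <- d[12, ] + c(0.28, -0.12) * lobing
  d[9, ] <- d[9, ] + c(0.25, 0.10) * lobing;     d[8, ] <- d[8, ] + c(-0.25, 0.10) * lobing
  d[7, ] <- c(0, 0.35) * elongation
  d[15, ] <- d[15, ] + c(0.30, -0.08) * wing;    d[14, ] <- d[14, ] + c(-0.30, -0.08) * wing
  d[margin, ] <- d[margin, ] + jitter
  d
}

# Logistic trajectory weight: w(1) = w0, nondecreasing, saturating at 1.
trajectory_weight <- function(k, w0, rate, inflection) {
  L <- stats::plogis(rate * (k - inflection))
  L1 <- stats::plogis(rate * (1 - inflection))
  w0 + (1 - w0) * (L - L1) / (1 - L1)
}

#' Generate a synthetic heteroblastic leaf-series dataset
#'
#' Every leaf's landmark configuration is a noisy point on its species'
#' trajectory, `J + w_s(node) * (M_s - J) + noise`, rescaled to centroid
#' size `size_base + size_gain * node`; `J` is the shared juvenile shape and
#' `M_s` the species' adult shape. Each record also carries a smooth closed
#' outline interpolated through its margin landmarks, so the elliptical
#' Fourier chain is exercised end to end. Identical parameters (including
#' the seed) reproduce the dataset exactly.
#'
#' @param params a [sim_params()] object.
#' @param scale_size rescale each configuration to its allometric centroid
#'   size (the default). `FALSE` leaves configurations in shape space
#'   (`J + w * (M_s - J) + noise` exactly), which is convenient when
#'   validating recovery of the generating linear model.
#' @return a list of class `leaf_sim`: `leaves` (a [leaf_collection()] with
#'   an `outline` list column, base-first numbering) and `truth` (ground
#'   truth: juvenile shape, per-species adult shapes and deformations,
#'   trajectory weights per node, vein-area fractions, generating subarea
#'   slopes, and the drawn per-species parameters).
#' @export
simulate_leaves <- function(params = sim_params(), scale_size = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  S <- params$n_species
  fr <- vein_fractions(params)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(params$seed, "species"))
  species <- sprintf("sp%02d", seq_len(S))
  rate <- stats::runif(S, params$rate_range[1], params$rate_range[2])
  # wide spreads: real congeners range from entire to deeply dissected and
  # from lance-shaped to broad
  lobing <- stats::runif(S, 0.1, 1.3)
  elongation <- stats::runif(S, -0.3, 0.6)
  wing <- stats::runif(S, -0.2, 0.5)
  # adults are distinctly broader or narrower than the shared juvenile
  # (balanced signs keep the mean trajectory near zero; bounded magnitude
  # guarantees every species a resolvable within-series area trend)
  breadth <- sample(rep(c(-1, 1), length.out = S)) * stats::runif(S, 0.25, 0.55)
  # the first species (the default model reference) changes little along the
  # series, like the lance-leaved species of the genus: its raw trajectory is
  # the across-species mean, so after centering it is nearly null
  lobing[1] <- mean(lobing[-1]); elongation[1] <- mean(elongation[-1])
  wing[1] <- mean(wing[-1]); breadth[1] <- mean(breadth[-1])
  class_label <- c("G", LETTERS[(seq_len(S - 1L) - 1L) %% 7L + 1L])
  jitter <- lapply(seq_len(S), function(i) {
    matrix(stats::rnorm(2L * length(leaf_boundary_order()), sd = 0.03),
           ncol = 2L)
  })

  Jb <- juvenile_boundary()
  D_margin <- lapply(seq_len(S), function(i) {
    adult_deformation(lobing[i], elongation[i], wing[i], breadth[i], jitter[[i]])
  })
  # center trajectory directions: the mean trajectory across species is zero,
  # so the node main effect is negligible by construction
  Dbar <- Reduce(`+`, D_margin) / S
  D_margin <- lapply(D_margin, function(d) d - Dbar)

  J <- fill_vein_landmarks(Jb, fr[1], fr[2])
  adults <- lapply(D_margin, function(d) fill_vein_landmarks(Jb + d, fr[1], fr[2]))
  D_full <- lapply(adults, function(M) M - J)

  K <- params$nodes_per_vine
  weights <- tidyr::expand_grid(species = species, node = seq_len(K))
  weights$w <- trajectory_weight(weights$node, params$w0,
                                 rate[match(weights$species, species)],
                                 params$inflection)

  set.seed(derive_seed(params$seed, "leaves"))
  n_leaves <- S * params$vines_per_species * K
  coords <- matrix(NA_real_, n_leaves, 2L * N_LANDMARKS,
                   dimnames = list(NULL, coord_names()))
  id_species <- character(n_leaves); id_class <- character(n_leaves)
  id_vine <- character(n_leaves); id_node <- integer(n_leaves)
  outlines <- vector("list", n_leaves)
  idx <- 0L
  for (s in seq_len(S)) {
    for (v in seq_len(params$vines_per_species)) {
      vine_id <- sprintf("%s_v%d", species[s], v)
      for (k in seq_len(K)) {
        w <- trajectory_weight(k, params$w0, rate[s], params$inflection)
        shape <- J + w * D_full[[s]]
        if (params$shape_noise_sd > 0) {
          shape <- shape + matrix(stats::rnorm(2L * N_LANDMARKS, sd = params$shape_noise_sd),
                                  ncol = 2L)
        }
        config <- if (scale_size) {
          target_size <- params$size_base + params$size_gain * k
          ctr <- colMeans(shape)
          centered <- sweep(shape, 2L, ctr)
          sweep(centered / sqrt(sum(centered^2)) * target_size, 2L, ctr, `+`)
        } else shape
        idx <- idx + 1L
        coords[idx, ] <- landmark_vector(config)
        id_species[idx] <- species[s]; id_class[idx] <- class_label[s]
        id_vine[idx] <- vine_id; id_node[idx] <- k
        outlines[[idx]] <- landmarks_to_outline(config)
      }
    }
  }
  leaves <- dplyr::bind_cols(
    tibble::tibble(species = id_species, class_label = id_class,
                   vine = id_vine, node = id_node),
    tibble::as_tibble(coords)
  )
  leaves$outline <- outlines
  leaves <- leaf_collection(leaves, numbering = "base_first")
  truth <- list(
    params = params,
    species = tibble::tibble(species = species, class_label = class_label,
                             rate = rate, lobing = lobing,
                             elongation = elongation, wing = wing,
                             breadth = breadth),
    juvenile = J,
    adult = stats::setNames(adults, species),
    deformation = stats::setNames(D_full, species),
    weights = weights,
    vein_fractions = fr,
    subarea_slopes = sqrt(subarea_fractions(params))
  )
  structure(list(leaves = leaves, truth = truth), class = "leaf_sim")
}

#' @export
print.leaf_sim <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "Synthetic heteroblastic leaf series: %d species x %d vines x %d nodes (seed %d)\n",
    p$n_species, p$vines_per_species, p$nodes_per_vine, p$seed
  ))
  invisible(x)
}

# Exact subarea fractions implied by the generating sqrt-slopes: squared
# region weights, normalized to sum to one so closure holds by construction.
subarea_fractions <- function(params) {
  w <- c(distal_blade = params$blade_slope,
         proximal_blade = 0.85 * params$blade_slope,
         midvein = params$vein_slope,
         proximal_vein = 0.8 * params$vein_slope)
  w^2 / sum(w^2)
}

#' Draw subarea records from the generating sqrt-linear allometric model
#'
#' Emits records in which each subregion takes an exact, constant fraction
#' of total area (fractions are the squared generating slopes, normalized),
#' so `sqrt(subarea) = slope * sqrt(total)` holds exactly: regression
#' recovers the generating slopes to machine precision at zero noise, and
#' closure (sum of subareas = total) is exact.
#'
#' @param params a [sim_params()] object (`blade_slope`, `vein_slope`, `seed`).
#' @param n number of records.
#' @param noise_sd Gaussian noise added to each sqrt-subarea (0 = exact).
#' @return a tibble of subarea records with attribute `slopes`, the
#'   generating slope of each subregion.
#' @export
simulate_subareas <- function(params = sim_params(), n = 200L, noise_sd = 0) {
  fr <- subarea_fractions(params)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(params$seed, "subareas"))
  sqrt_total <- stats::runif(n, 0.6, 1.6)
  sq <- outer(sqrt_total, sqrt(fr))
  if (noise_sd > 0) sq <- pmax(sq + matrix(stats::rnorm(length(sq), sd = noise_sd), n), 0)
  areas <- sq^2
  colnames(areas) <- paste0("area_", names(fr))
  out <- dplyr::bind_cols(
    tibble::tibble(leaf = sprintf("leaf%04d", seq_len(n))),
    tibble::as_tibble(areas)
  )
  out$area_total <- rowSums(areas)
  attr(out, "slopes") <- sqrt(fr)
  out
}

# Save/restore the global RNG state so simulation is reproducible without
# clobbering the caller's stream.
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
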