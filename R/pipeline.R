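#' Run the full heteroblasty analysis pipeline
#'
#' Orchestrates every stage from input (a landmark table and optional NEF
#' file, or the synthetic generator) through Procrustes alignment,
#' elliptical Fourier decomposition, subarea allometry, effect
#' decomposition, per-node discrimination and variability, and trajectory
#' vectors, writing each stage's table plus a reproducibility manifest to
#' the output directory. One master seed governs every stochastic stage
#' through stage-named substreams, so a rerun with the same configuration
#' reproduces all outputs exactly.
#'
#' @param config a named list or path to a YAML file with fields:
#'   either `landmarks` (path, with optional `nef` and `numbering`) or
#'   `sim` (a list of [sim_params()] arguments) — exactly one of the two;
#'   optional `harmonics` (default 20), `reference` species, `perplexity`
#'   (default 40), `embedding` (`"tsne"`/`"pca"`), `seed` (default 1),
#'   `out` (output directory, default `"leafmorph_run"`).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_input <- !is.null(config$landmarks)
  has_sim <- !is.null(config$sim)
  if (has_input == has_sim) {
    stop_validation("config must provide exactly one of 'landmarks' (input paths) or 'sim'")
  }
  seed <- as.integer(config$seed %||% 1L)
  harmonics <- as.integer(config$harmonics %||% 20L)
  out_dir <- config$out %||% "leafmorph_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("leafmorph")),
                   seed = seed, stages = list())
  warnings_log <- list()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  catch_warn <- function(stage, expr) {
    withCallingHandlers(expr, leafmorph_quality_warning = function(w) {
      warnings_log[[stage]] <<- c(warnings_log[[stage]], conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # ingest / simulate
  if (has_input) {
    dialect <- landmark_dialect(numbering = config$numbering %||% "base_first")
    collection <- read_landmark_table(config$landmarks, dialect)
    collection <- renumber_nodes(collection, "base_first")
    efd_in <- if (!is.null(config$nef)) read_nef(config$nef) else NULL
    note("ingest", landmarks = config$landmarks,
         digest = unname(tools::md5sum(config$landmarks)), n = nrow(collection))
    truth <- NULL
  } else {
    params <- do.call(sim_params, c(config$sim, list(seed = derive_seed(seed, "simulate"))))
    sim <- simulate_leaves(params)
    collection <- sim$leaves
    truth <- sim$truth
    efd_in <- NULL
    note("simulate", params = unclass(params)[setdiff(names(unclass(params)), "rate_range")],
         n = nrow(collection))
  }

  aligned <- catch_warn("gpa", align_leaves(collection))
  write_landmark_table(aligned, file.path(out_dir, "aligned_landmarks.tsv"))
  note("gpa", iterations = attr(aligned, "gpa")$iterations,
       converged = attr(aligned, "gpa")$converged)

  efd <- if (is.null(efd_in)) efd_traits(aligned, harmonics = harmonics) else efd_in
  write_nef(efd, file.path(out_dir, "shapes.nef"))
  note("efd", harmonics = attr(efd, "harmonics") %||% harmonics)

  traits <- leaf_traits(aligned, efd)
  readr::write_csv(traits, file.path(out_dir, "traits.csv"))

  subareas <- catch_warn("allometry", subarea_table(aligned))
  fits <- catch_warn("allometry", fit_allometry(subareas, group_by = "species"))
  readr::write_csv(subareas, file.path(out_dir, "subareas.csv"))
  readr::write_csv(fits, file.path(out_dir, "allometry_fits.csv"))
  note("allometry", groups = length(unique(fits$group)))

  effects <- catch_warn("effects", effect_matrices(
    drop_constant_traits(traits[, c("species", "node", trait_columns(traits))]),
    reference = config$reference
  ))
  readr::write_csv(effects, file.path(out_dir, "effects.csv"))
  note("effects", reference = attr(effects, "reference"),
       n_traits = length(unique(effects$trait)))

  disc <- catch_warn("discrimination", node_discrimination_table(traits))
  sds <- catch_warn("discrimination", trait_sd_by_node(traits))
  readr::write_csv(disc, file.path(out_dir, "node_discrimination.csv"))
  readr::write_csv(sds, file.path(out_dir, "trait_sd_by_node.csv"))
  note("discrimination", nodes = length(unique(disc$node)))

  emb <- catch_warn("trajectories", embed_2d(
    traits, method = config$embedding %||% "tsne",
    perplexity = config$perplexity %||% 40,
    seed = derive_seed(seed, "embedding")
  ))
  vectors <- catch_warn("trajectories", vine_vectors(emb))
  conv <- convergence_stat(vectors)
  readr::write_csv(tibble::as_tibble(emb), file.path(out_dir, "embedding.csv"))
  readr::write_csv(vectors, file.path(out_dir, "vine_vectors.csv"))
  readr::write_csv(conv, file.path(out_dir, "convergence.csv"))
  note("trajectories", method = attr(emb, "method"),
       perplexity = attr(emb, "perplexity"),
       convergence_ratio = conv$ratio)

  manifest$warnings <- warnings_log
  manifest$files <- as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                                     pattern = "\\.(csv|tsv|nef)$")))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
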