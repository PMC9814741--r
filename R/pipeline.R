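#' Read a pipeline configuration
#'
#' YAML configuration driving [run_pipeline()]. Top-level keys:
#' `systems` (list of entries with `id` and either `trajectory` — a file
#' path, optionally with `format`/`unit`/`selection` bead groups — or
#' `synthetic` — arguments for [synthetic_spec()]), `soap`
#' (arguments for [soap_params()]),
#' `pooling` (`n_per_system`, `seed`), `reduction` (`n_components`),
#' `clustering` (`n_grid`, `K`, `n_boot`, `seed`, `lambda_qs`,
#' `n_localization`), `dynamics` (`lag`), `compare` (`reference`),
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return The validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list built in code.
#' @export
as_pipeline_config <- function(cfg) {
  if (is.null(cfg$systems) || length(cfg$systems) < 1) {
    rlang::abort("config needs at least one system.",
                 class = "defectometer_config_error")
  }
  for (s in cfg$systems) {
    if (is.null(s$id) || (is.null(s$trajectory) && is.null(s$synthetic))) {
      rlang::abort("each system needs an id and a trajectory or synthetic block.",
                   class = "defectometer_config_error")
    }
  }
  ids <- vapply(cfg$systems, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    rlang::abort("system ids must be unique.",
                 class = "defectometer_config_error")
  }
  cfg$soap <- cfg$soap %||% list()
  cfg$pooling <- utils::modifyList(list(n_per_system = 2000, seed = 0),
                                   cfg$pooling %||% list())
  cfg$reduction <- utils::modifyList(list(n_components = 3),
                                     cfg$reduction %||% list())
  cfg$clustering <- utils::modifyList(
    list(n_grid = NULL, K = NULL, n_boot = 73, seed = 0, lambda_qs = 3,
         n_localization = NULL), cfg$clustering %||% list())
  cfg$dynamics <- utils::modifyList(list(lag = 1), cfg$dynamics %||% list())
  cfg$compare <- cfg$compare %||% list()
  cfg$output_dir <- cfg$output_dir %||% "defectometer_out"
  structure(cfg, class = "pipeline_config")
}

load_system <- function(s) {
  if (!is.null(s$synthetic)) {
    args <- s$synthetic
    spec <- do.call(synthetic_spec, args)
    asm <- generate_assembly(spec)
    asm$trajectory$system_id <- s$id
    return(list(trajectory = asm$trajectory, assembly = asm))
  }
  traj <- read_trajectory(s$trajectory, format = s$format %||% "auto",
                          unit = s$unit, system_id = s$id)
  if (!is.null(s$selection)) {
    sel <- lapply(s$selection, as.integer)
    Tn <- n_frames(traj)
    centers <- array(NA_real_, dim = c(length(sel), 3, Tn))
    for (t in seq_len(Tn)) {
      centers[, , t] <- compute_centers(frame_coords(traj, t), traj$box, sel)
    }
    traj <- cg_trajectory(centers, traj$box, times = traj$times,
                          system_id = s$id,
                          sampling_interval = traj$sampling_interval)
  }
  list(trajectory = traj, assembly = NULL)
}

#' Run the full motif-detection and classification pipeline
#'
#' End to end from one configuration: load or generate every system,
#' compute per-center SOAP spectra and the global fingerprints, pool a
#' balanced training set, fit the principal-component projection, run the
#' density-based clustering with bootstrap stability, derive per-system
#' state populations and transition matrices, and classify the systems by
#' the averaged-SOAP distance matrix with a single-linkage tree. All
#' artifacts are plain text (CSV, JSON, DOT, Newick) under `output_dir`,
#' and a manifest records every parameter and seed.
#'
#' @param config a `pipeline_config` (from [read_pipeline_config()] or
#'   [as_pipeline_config()]), or a path to a YAML config.
#' @param output_dir overrides the config's output directory.
#' @return Invisibly, a list with the in-memory results (`soap`,
#'   `projection`, `fit`, `dynamics`, `distance`, `tree`, `manifest`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- output_dir %||% config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "defectometer_pipeline_error")
    })
  }
  params <- stage("soap-params", do.call(soap_params, config$soap))
  systems <- stage("load", lapply(config$systems, load_system))
  ids <- vapply(config$systems, function(s) s$id, character(1))

  results <- stage("soap", lapply(systems, function(sy) {
    soap_trajectory(sy$trajectory, params)
  }))
  names(results) <- ids
  for (i in seq_along(results)) {
    write_spectra_csv(results[[i]]$dataset,
                      file.path(out, sprintf("%s_spectra.csv", ids[i])))
  }

  pooled <- stage("pool", pool_balanced(
    lapply(results, function(r) r$dataset),
    n_per_system = config$pooling$n_per_system,
    seed = config$pooling$seed))
  proj <- stage("reduce", fit_projection(pooled,
                                         config$reduction$n_components))
  write_projection(proj, file.path(out, "projection_model.txt"))

  cl <- config$clustering
  fit <- stage("cluster", pamm(proj$scores, n_grid = cl$n_grid, K = cl$K,
                               n_boot = cl$n_boot, seed = cl$seed,
                               n_localization = cl$n_localization,
                               lambda_qs = cl$lambda_qs))
  if (!is.null(fit$stability)) {
    utils::write.csv(fit$stability, file.path(out, "stability_matrix.csv"))
    write_micro_newick(fit, file.path(out, "microclusters.nwk"))
  }

  dyn <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    sc <- project(proj, r$dataset)
    micro <- assign_microstates(sc, fit$grid, fit$grid_labels)
    macro <- fit$micro_to_macro[micro]
    M <- max(r$dataset$meta$center); Tn <- max(r$dataset$meta$frame)
    scores_df <- dplyr::bind_cols(r$dataset$meta, tibble::as_tibble(sc),
                                  tibble::tibble(micro = micro,
                                                 macro = macro))
    utils::write.csv(scores_df,
                     file.path(out, sprintf("%s_scores_labels.csv", ids[i])),
                     row.names = FALSE)
    st <- state_trajectories(macro, M = M, T = Tn,
                             sampling_interval =
                               systems[[i]]$trajectory$sampling_interval)
    tm <- if (Tn > config$dynamics$lag) {
      transition_matrix(st, lag = config$dynamics$lag, K = fit$K)
    } else NULL
    if (!is.null(tm)) {
      write_transitions_json(tm, file.path(out,
                                           sprintf("%s_dynamics.json",
                                                   ids[i])))
      write_interconversion_dot(tm, file.path(out,
                                              sprintf("%s_interconversion.dot",
                                                      ids[i])))
    }
    dyn[[ids[i]]] <- list(states = st, transitions = tm)
  }

  dm <- NULL; tree <- NULL
  if (length(results) >= 2) {
    dm <- stage("compare", soap_distance_matrix(
      lapply(results, function(r) r$simulation_average)))
    utils::write.csv(unclass(dm), file.path(out, "d_soap_matrix.csv"))
    tree <- single_linkage(dm)
    write_system_newick(tree, file.path(out, "systems.nwk"))
    utils::write.csv(reorder_by_tree(dm, tree),
                     file.path(out, "d_soap_matrix_reordered.csv"))
    ref <- config$compare$reference %||% ids[1]
    utils::write.csv(rank_by_distance(dm, ref),
                     file.path(out, sprintf("ranking_from_%s.csv", ref)),
                     row.names = FALSE)
  }

  manifest <- list(systems = ids,
                   soap = unclass(params),
                   pooling = config$pooling,
                   reduction = config$reduction,
                   clustering = config$clustering[
                     !vapply(config$clustering, is.null, logical(1))],
                   dynamics = config$dynamics,
                   n_micro = fit$n_micro, K = fit$K)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(soap = results, projection = proj, fit = fit,
                 dynamics = dyn, distance = dm, tree = tree,
                 manifest = manifest, output_dir = out))
}

#' Serialize a projection model to a flat text block
#'
#' @param proj a `soap_projection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  lines <- c(sprintf("n_components: %d", nrow(proj$components)),
             sprintf("explained_ratio: %s",
                     paste(format(proj$explained_ratio, digits = 10),
                           collapse = " ")),
             sprintf("mean: %s",
                     paste(format(proj$mean, digits = 10), collapse = " ")),
             vapply(seq_len(nrow(proj$components)), function(j) {
               sprintf("component_%d: %s", j,
                       paste(format(proj$components[j, ], digits = 10),
                             collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
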