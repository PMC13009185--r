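# End-to-end orchestration: validated YAML/list configuration, staged
# execution (simulate -> terrain -> classify -> hsm -> isotope), declared
# outputs, and a reproducible run manifest with checksums and seeds.

#' Default pipeline configuration
#'
#' All stage settings mirror the study defaults: 5 m fishnet, BPI at
#' 10 m / 100 m, 25 m VRM window, 5,000 background points, 50 m blocks,
#' 5 folds, 99 importance replicates, +5 per-mil enrichment threshold.
#'
#' @param master_seed integer seed fanned out to all stages.
#' @return nested configuration list.
#' @export
default_config <- function(master_seed = 1) {
  list(
    master_seed = as.integer(master_seed),
    scene = list(extent_cells = c(256, 256), cell_size = 1, mound_height = 20,
                 noise_amplitude = 0.4, noise_correlation_length = 8,
                 n_carbonate_patches = 8, patch_radius_range = c(3, 8),
                 seep_fraction = 0.6, n_occurrences = 155),
    terrain = list(bpi_scales = c(10, 100), vrm_window = 25),
    classify = list(fishnet_cell = 5),
    hsm = list(algorithms = c("rf", "gbm"), n_background = 5000,
               block_size = 50, n_folds = 5, n_importance_reps = 99,
               importance = TRUE, surface = FALSE),
    isotope = list(n_active = 19, n_transition = 3, uptake_probability = 1 / 3,
                   enrichment_threshold = 5))
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge <- function(b, u) {
    if (!is.list(b) || !is.list(u)) return(u)
    for (n in names(u)) b[[n]] <- if (n %in% names(b)) merge(b[[n]], u[[n]]) else u[[n]]
    b
  }
  merge(base, user)
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns all violations rather than
#' stopping at the first.
#'
#' @param config configuration list (see [default_config()]).
#' @return data.frame with columns `field`, `problem`; zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  flag <- function(field, problem)
    v[[length(v) + 1]] <<- data.frame(field = field, problem = problem,
                                      stringsAsFactors = FALSE)
  sc <- config$scene
  if (is.null(sc)) flag("scene", "missing") else {
    if (length(sc$extent_cells) != 2 || any(sc$extent_cells < 64))
      flag("scene.extent_cells", "must be a pair of integers >= 64")
    if (!is.null(sc$cell_size) && sc$cell_size <= 0)
      flag("scene.cell_size", "must be > 0")
    if (!is.null(sc$seep_fraction) &&
        (sc$seep_fraction < 0 || sc$seep_fraction > 1))
      flag("scene.seep_fraction", "must be in [0, 1]")
    if (!is.null(sc$n_carbonate_patches) && sc$n_carbonate_patches == 0 &&
        isTRUE(sc$seep_fraction > 0))
      flag("scene.n_carbonate_patches", "zero patches cannot host indicators")
  }
  tr <- config$terrain
  if (!is.null(tr)) {
    cs <- if (!is.null(sc$cell_size)) sc$cell_size else 1
    if (!is.null(tr$vrm_window) && tr$vrm_window < 3 * cs)
      flag("terrain.vrm_window", "must span at least 3 cells")
    if (!is.null(tr$bpi_scales) && any(tr$bpi_scales <= cs))
      flag("terrain.bpi_scales", "outer radius must exceed one cell")
  }
  cl <- config$classify
  if (!is.null(cl) && !is.null(cl$fishnet_cell) && cl$fishnet_cell <= 0)
    flag("classify.fishnet_cell", "must be > 0")
  h <- config$hsm
  if (!is.null(h)) {
    if (!is.null(h$n_folds) && h$n_folds < 2) flag("hsm.n_folds", "must be >= 2")
    if (!is.null(h$block_size)) {
      if (h$block_size <= 0) flag("hsm.block_size", "must be > 0")
      else if (!is.null(cl$fishnet_cell) && h$block_size < cl$fishnet_cell)
        flag("hsm.block_size", "must be >= the fishnet cell size")
    }
    if (!is.null(h$n_importance_reps) && h$n_importance_reps < 1)
      flag("hsm.n_importance_reps", "must be >= 1")
  }
  iso <- config$isotope
  if (!is.null(iso)) {
    if (!is.null(iso$uptake_probability) &&
        (iso$uptake_probability < 0 || iso$uptake_probability > 1))
      flag("isotope.uptake_probability", "must be in [0, 1]")
    if (any(c(iso$n_active, iso$n_transition) < 0))
      flag("isotope.n", "group sizes must be >= 0")
  }
  if (length(v) == 0)
    data.frame(field = character(0), problem = character(0))
  else do.call(rbind, v)
}

#' Run the pipeline end to end
#'
#' Validates the configuration, then executes simulate -> terrain ->
#' classify -> hsm -> isotope, writing every declared output (ESRI ASCII
#' rasters, CSV tables, JSON summaries) plus a run manifest with per-stage
#' wall-clock, seeds and MD5 checksums of all outputs. A stage failure
#' aborts downstream stages.
#'
#' @param config configuration list ([default_config()] / [read_config()]).
#' @param output_dir directory for all outputs (created if needed).
#' @param stages contiguous subset of
#'   `c("simulate", "terrain", "classify", "hsm", "isotope")` to run.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `output_dir`.
#' @export
run_pipeline <- function(config = default_config(), output_dir,
                         stages = c("simulate", "terrain", "classify",
                                    "hsm", "isotope")) {
  stages <- match.arg(stages, c("simulate", "terrain", "classify", "hsm",
                                "isotope"), several.ok = TRUE)
  bad <- validate_config(config)
  if (nrow(bad) > 0)
    stop("invalid configuration:\n",
         paste(sprintf("  %s: %s", bad$field, bad$problem), collapse = "\n"),
         call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  manifest <- list(config = config, package_version =
                     as.character(utils::packageVersion("seepscape")),
                   seeds = list(master = seed), stages = list())
  outputs <- character(0)
  state <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  if ("simulate" %in% stages) {
    state$scene <- timed("simulate", {
      sc <- config$scene
      cfg <- scene_config(extent_cells = sc$extent_cells, cell_size = sc$cell_size,
                          mound_height = sc$mound_height,
                          noise_amplitude = sc$noise_amplitude,
                          noise_correlation_length = sc$noise_correlation_length,
                          n_carbonate_patches = sc$n_carbonate_patches,
                          patch_radius_range = sc$patch_radius_range,
                          seep_fraction = sc$seep_fraction, rng_seed = seed)
      scene <- simulate_scene(cfg, n_occurrences = sc$n_occurrences)
      write_asc(scene$bathymetry, file.path(output_dir, "bathymetry.asc"))
      for (f in names(scene$features))
        write_asc(scene$features[[f]], file.path(output_dir, paste0(f, ".asc")))
      write_asc(scene$suitability$surface,
                file.path(output_dir, "true_suitability.asc"))
      utils::write.csv(scene$occurrences,
                       file.path(output_dir, "occurrences.csv"), row.names = FALSE)
      jsonlite::write_json(
        c(unclass(cfg),
          list(suitability_link =
                 "exp(-d_carbonate/2) * (0.5 + 0.5*exp(-d_indicator/10))",
               decay_carbonate = scene$suitability$decay_carbonate,
               decay_indicator = scene$suitability$decay_indicator)),
        file.path(output_dir, "scene_config.json"), auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, file.path(output_dir,
        c("bathymetry.asc", paste0(names(scene$features), ".asc"),
          "true_suitability.asc", "occurrences.csv", "scene_config.json")))
      scene
    })
  }

  if ("terrain" %in% stages) {
    if (is.null(state$scene)) stop("terrain stage needs the simulate stage")
    state$preds <- timed("terrain", {
      stack <- terrain_stack(state$scene$bathymetry,
                             bpi_scales = config$terrain$bpi_scales,
                             vrm_window = config$terrain$vrm_window)
      dists <- distance_layers(state$scene$features)
      preds <- assemble_predictors(stack, dists)
      outputs <<- c(outputs, write_predictors(preds,
                                              file.path(output_dir, "predictors")))
      preds
    })
  }

  if ("classify" %in% stages) {
    if (is.null(state$scene)) stop("classify stage needs the simulate stage")
    state$classified <- timed("classify", {
      net <- build_fishnet(state$scene$bathymetry,
                           cell = config$classify$fishnet_cell)
      cells <- classify_cells(net, state$scene$features)
      occ <- classify_occurrences(state$scene$occurrences, cells)
      nid <- nearest_indicator_distance(occ, state$scene$features)
      occ$nearest_indicator_m <- nid$distances
      utils::write.csv(occ, file.path(output_dir, "occurrences_labelled.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(cells),
                       file.path(output_dir, "cell_labels.csv"), row.names = FALSE)
      jsonlite::write_json(nid$summary,
                           file.path(output_dir, "classification_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, file.path(output_dir,
        c("occurrences_labelled.csv", "cell_labels.csv",
          "classification_summary.json")))
      list(cells = cells, occ = occ, summary = nid$summary)
    })
  }

  if ("hsm" %in% stages) {
    if (is.null(state$preds)) stop("hsm stage needs the terrain stage")
    state$hsm <- timed("hsm", {
      h <- config$hsm
      spec <- hsm_spec(algorithms = h$algorithms, n_background = h$n_background,
                       block_size = h$block_size, n_folds = h$n_folds,
                       n_importance_reps = h$n_importance_reps,
                       rng_seed = seed + 1L)
      fit <- run_hsm(state$scene$occurrences, state$preds, spec,
                     importance = isTRUE(h$importance),
                     surface = isTRUE(h$surface))
      utils::write.csv(fit$eval, file.path(output_dir, "hsm_eval.csv"),
                       row.names = FALSE)
      outputs <<- c(outputs, file.path(output_dir, "hsm_eval.csv"))
      if (!is.null(fit$importance)) {
        utils::write.csv(fit$importance,
                         file.path(output_dir, "hsm_importance.csv"),
                         row.names = FALSE)
        outputs <<- c(outputs, file.path(output_dir, "hsm_importance.csv"))
      }
      if (!is.null(fit$ensemble)) {
        write_asc(fit$ensemble$hsi, file.path(output_dir, "hsi.asc"))
        outputs <<- c(outputs, file.path(output_dir, "hsi.asc"))
      }
      fit
    })
    manifest$seeds$hsm <- seed + 1L
  }

  if ("isotope" %in% stages) {
    state$isotope <- timed("isotope", {
      iso <- config$isotope
      cfg <- isotope_sim_config(n_active = iso$n_active,
                                n_transition = iso$n_transition,
                                uptake_probability = iso$uptake_probability,
                                rng_seed = seed + 2L)
      rec <- generate_isotopes(cfg)
      rep <- isotope_report(rec, threshold = iso$enrichment_threshold)
      utils::write.csv(rec, file.path(output_dir, "isotopes.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(summaries = rep$summaries, welch = rep$welch,
             n_enriched = if (!is.null(rep$enrichment))
               rep$enrichment$n_enriched else NULL),
        file.path(output_dir, "isotope_summary.json"),
        auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, file.path(output_dir,
                                       c("isotopes.csv", "isotope_summary.json")))
      rep
    })
    manifest$seeds$isotope <- seed + 2L
  }

  manifest$outputs <- data.frame(
    path = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
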