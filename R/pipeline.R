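#' Validate a pipeline configuration
#'
#' Fills defaults (soil threshold 0.10, 300 m cells, 1 ha area criterion and
#' minimum mapping unit, 5% reporting level, base/update segmentation
#' parameter sets) and checks ranges and date ordering. All problems are
#' reported at once, with field paths.
#'
#' @param config named list; recognised fields: `scenes` (list of
#'   `list(path=, date=)`), `endmembers` (matrix or CSV path),
#'   `normalize` (logical), `reference` (index of the normalization
#'   reference scene), `soil_threshold`, `cell_size_m`, `min_area_ha`,
#'   `mmu_ha`, `level`, `base_segmentation` / `update_segmentation`
#'   (lists passed to [segmentation_params()]), `rules`, `external_masks`,
#'   `out_dir`, `seed`.
#' @return the validated config (class `lg_config`).
#' @export
validate_config <- function(config) {
  defaults <- list(normalize = TRUE, reference = 1L, soil_threshold = 0.10,
                   cell_size_m = 300, min_area_ha = 1, mmu_ha = 1,
                   level = 0.05, seed = 1L, out_dir = NULL,
                   external_masks = NULL,
                   base_segmentation = list(scale = 10, shape_weight = 0.2,
                                            compactness_weight = 0.5),
                   update_segmentation = list(scale = 50, shape_weight = 0.1,
                                              compactness_weight = 0.5))
  known <- c(names(defaults), "scenes", "endmembers", "rules")
  problems <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    problems <- c(problems, paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  if (is.null(config$rules)) config$rules <- rule_set()
  if (is.null(config$scenes) || length(config$scenes) < 1) {
    problems <- c(problems, "scenes: at least one dated scene required")
  } else {
    dates <- try(as.Date(vapply(config$scenes,
                                function(s) as.character(s$date),
                                character(1))), silent = TRUE)
    if (inherits(dates, "try-error") || anyNA(dates)) {
      problems <- c(problems, "scenes: unparseable date(s)")
    } else {
      if (anyDuplicated(dates))
        problems <- c(problems, "scenes: duplicate dates")
      if (is.unsorted(dates, strictly = TRUE))
        problems <- c(problems, "scenes: dates must be strictly increasing")
    }
  }
  if (config$soil_threshold <= 0 || config$soil_threshold >= 1)
    problems <- c(problems, "soil_threshold: must lie in (0, 1)")
  if (config$cell_size_m <= 0)
    problems <- c(problems, "cell_size_m: must be positive")
  if (config$min_area_ha < 0)
    problems <- c(problems, "min_area_ha: must be >= 0")
  if (config$level < 0 || config$level > 1)
    problems <- c(problems, "level: must lie in [0, 1]")
  if (length(problems))
    stop("validation error:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  class(config) <- "lg_config"
  config
}

#' Read and validate a JSON pipeline configuration
#' @param path JSON file.
#' @return validated `lg_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(cfg$endmembers) && is.character(cfg$endmembers))
    cfg$endmembers <- read_endmembers(cfg$endmembers)
  validate_config(cfg)
}

#' Run the full annual monitoring pipeline
#'
#' Per date: radiometric normalization to the reference scene over
#' pseudo-invariant features, spectral unmixing, forest-mask construction
#' (base year) or update (later years), soil-fraction disturbance masking,
#' and grid-cell accounting. Across dates: annual rates, change matrices,
#' recurrence counts and area summaries. A manifest records inputs,
#' parameters and seeds; when `out_dir` is set, tables are written as CSV
#' and the manifest as JSON.
#'
#' Supplying `external_masks` (one [classmap()] per date) replaces the
#' masking stage entirely, so existing forest masks can drive the grid
#' assessment.
#'
#' @param config validated [validate_config()] list.
#' @param scenes optional list of in-memory [scene()]s overriding
#'   `config$scenes` paths.
#' @return list bundle: `masks`, `fractions`, `disturbance`, `assessments`,
#'   `rates`, `change_matrices`, `recurrence`, `area_summaries`, `grid`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, scenes = NULL) {
  if (!inherits(config, "lg_config")) config <- validate_config(config)
  if (is.null(scenes))
    scenes <- lapply(config$scenes, function(s) read_scene(s$path))
  n <- length(scenes)
  em <- config$endmembers
  if (is.character(em)) em <- read_endmembers(em)
  if (is.matrix(em)) em <- endmembers(em)
  if (is.null(em)) em <- endmembers(default_endmembers())
  rules <- if (inherits(config$rules, "lg_rules")) config$rules
           else rule_set(config$rules)
  base_par <- do.call(segmentation_params, config$base_segmentation)
  upd_par <- do.call(segmentation_params, config$update_segmentation)
  years <- vapply(seq_len(n), function(i) {
    d <- config$scenes[[i]]$date %||% scenes[[i]]$date
    format(as.Date(d), "%Y")
  }, character(1))

  stage <- function(what, i, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline failed at stage '%s', date %s: %s",
                   what, years[i], conditionMessage(e)), call. = FALSE))
  }

  ref <- scenes[[config$reference]]
  fractions <- vector("list", n)
  masks <- vector("list", n)
  disturbance <- vector("list", n)
  assessments <- vector("list", n)
  grid <- build_grid(dim(ref$bands)[1:2], config$cell_size_m,
                     ref$pixel_size)
  norm_models <- vector("list", n)

  for (i in seq_len(n)) {
    sc <- scenes[[i]]
    if (isTRUE(config$normalize) && i != config$reference) {
      stage("normalize", i, {
        pif <- select_pif(ref, sc, min_pif = min(100, floor(
          sum(scene_valid(sc)) / 4)))
        nm <- normalize_to_reference(sc, ref, pif)
        sc <- nm$scene
        norm_models[[i]] <- nm$model
      })
    }
    fractions[[i]] <- stage("unmix", i, unmix(sc, em))
    if (!is.null(config$external_masks)) {
      masks[[i]] <- config$external_masks[[i]]
    } else if (i == 1L) {
      masks[[i]] <- stage("mask", i, base_forest_mask(
        sc, fractions[[i]], params = base_par, rules = rules,
        min_area_ha = config$min_area_ha, year = years[i]))
    } else {
      masks[[i]] <- stage("mask", i, update_forest_mask(
        masks[[i - 1]], sc, fractions[[i]], params = upd_par,
        rules = rules, mmu_ha = config$mmu_ha, year = years[i]))
    }
    disturbance[[i]] <- stage("disturbance", i, soil_disturbance_mask(
      fractions[[i]], masks[[i]], config$soil_threshold))
    assessments[[i]] <- stage("assess", i, assess_cells(
      grid, masks[[i]], disturbance[[i]], year = years[i]))
  }
  names(assessments) <- years
  names(masks) <- years

  rates <- if (n >= 2) annual_rates(assessments, masks, disturbance,
                                    level = config$level) else NULL
  cmats <- if (n >= 2) {
    out <- vector("list", n - 1)
    for (t in 2:n)
      out[[t - 1]] <- change_matrix(
        combined_map(masks[[t - 1]], disturbance[[t - 1]]),
        combined_map(masks[[t]], disturbance[[t]]),
        pixel_area_ha = ref$pixel_size^2 / 1e4)
    names(out) <- paste(years[-n], years[-1], sep = "-")
    out
  } else NULL
  recur <- recurrence(assessments, level = config$level)
  summaries <- lapply(assessments, area_summary)

  manifest <- list(
    package_version = as.character(utils::packageVersion("loggrid")),
    dates = years, n_scenes = n, grid = grid_hash(grid),
    soil_threshold = config$soil_threshold,
    cell_size_m = config$cell_size_m, min_area_ha = config$min_area_ha,
    mmu_ha = config$mmu_ha, level = config$level, seed = config$seed,
    normalize = config$normalize, reference = config$reference,
    rules = lapply(unclass(rules), as.list),
    base_segmentation = config$base_segmentation,
    update_segmentation = config$update_segmentation,
    external_masks = !is.null(config$external_masks))

  bundle <- list(masks = masks, fractions = fractions,
                 disturbance = disturbance, assessments = assessments,
                 rates = rates, change_matrices = cmats,
                 recurrence = recur, area_summaries = summaries,
                 grid = grid, norm_models = norm_models,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (y in names(bundle$assessments))
    utils::write.csv(bundle$assessments[[y]],
                     file.path(out_dir, paste0("cells_", y, ".csv")),
                     row.names = FALSE)
  if (!is.null(bundle$rates))
    utils::write.csv(bundle$rates, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)
  for (nm in names(bundle$change_matrices)) {
    utils::write.csv(as.data.frame(unclass(bundle$change_matrices[[nm]])),
                     file.path(out_dir, paste0("change_", nm, ".csv")))
  }
  utils::write.csv(bundle$recurrence,
                   file.path(out_dir, "recurrence.csv"), row.names = FALSE)
  for (y in names(bundle$area_summaries))
    utils::write.csv(bundle$area_summaries[[y]],
                     file.path(out_dir, paste0("area_summary_", y, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic multi-year bundle), `validate`
#' (check a JSON config), `run` (execute the pipeline from a JSON config).
#' Installed as `exec/loggrid`; call via
#' `Rscript -e 'loggrid::loggrid_cli()' <verb> ...`.
#'
#' @param args character vector of CLI arguments.
#' @return exit status, invisibly.
#' @export
loggrid_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: loggrid <verb> [options]",
    "  simulate --out <dir> [--years n] [--size px] [--seed s] [--noise sd]",
    "  validate --config <file.json>",
    "  run --config <file.json>", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  verb <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  if (verb == "simulate") {
    out <- opt("out") %||% stop("simulate: --out required", call. = FALSE)
    cfg <- simulation_config(
      extent = rep(as.integer(opt("size", 100)), 2),
      n_years = as.integer(opt("years", 5)),
      noise_sd = as.numeric(opt("noise", 0.01)),
      seed = as.integer(opt("seed", 42)))
    truth <- simulate_landscape(cfg)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (y in seq_len(cfg$n_years))
      write_simulated_year(truth, y, file.path(out, sprintf("year%02d", y)))
    message(sprintf("wrote %d years to %s", cfg$n_years, out))
    return(invisible(0L))
  }
  if (verb %in% c("validate", "run")) {
    cfgp <- opt("config") %||% stop(verb, ": --config required",
                                    call. = FALSE)
    cfg <- read_config(cfgp)
    if (verb == "validate") {
      message("config OK: ", length(cfg$scenes), " scene(s)")
      return(invisible(0L))
    }
    bundle <- run_pipeline(cfg)
    message("pipeline complete: ", length(bundle$assessments), " date(s)")
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
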