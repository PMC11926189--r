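.pkgVersion <- function() {
  as.character(utils::packageVersion("PolysomeTracer"))
}

.validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$markers))
    stop("config validation: 'markers' block (entry_offset, exit_offset) is required")
  if (is.null(config$simulate) && is.null(config$star))
    stop("config validation: either 'star' (+ 'pixel_size') or a 'simulate' block is required")
  if (!is.null(config$star) && is.null(config$pixel_size))
    stop("config validation: 'pixel_size' is required with 'star' input")
  config
}

.markerFromConfig <- function(m) {
  markerConfig(entryOffset = unlist(m$entry_offset),
               exitOffset = unlist(m$exit_offset),
               traceCutoff = m$trace_cutoff %||% 250,
               distanceCutoff = m$distance_cutoff %||% 500,
               mapDirection = m$map_direction %||% "inverse")
}

#' Run the full tracing and statistics pipeline
#'
#' Validates a run configuration, loads (or simulates) the particles,
#' traces polysomes, and writes a reproducible run directory: the
#' annotated particle STAR file, the surviving link table (CSV), a JSON
#' statistics report, the resolved configuration (YAML, with package
#' version and config hash) and a JSON-lines log recording particle and
#' link counts at every rule.
#'
#' Config keys: \code{star} + \code{pixel_size} (+ optional
#' \code{label_columns}) or a \code{simulate} block (fields of
#' [sceneParams()], snake_case); \code{markers} (entry_offset,
#' exit_offset, trace_cutoff, distance_cutoff, map_direction);
#' \code{seed}; \code{labels} (occupancy_label, occupancy_value,
#' state_label, group_label) controlling which statistics run.
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory.
#' @param force overwrite an existing non-empty run directory.
#' @return invisibly, a list with the computed objects (particles,
#'   chains, graph, stats, files).
#' @export
runPipeline <- function(config, outDir, force = FALSE) {
  config <- .validateRunConfig(config)
  if (dir.exists(outDir) && length(dir(outDir)) && !force)
    stop("output directory not empty (use force = TRUE): ", outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run_log.jsonl")
  cat(NULL, file = logFile)
  logEvent <- function(stage, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logFile, append = TRUE)
  }
  markers <- .markerFromConfig(config$markers)
  seed <- as.integer(config$seed %||% 1L)
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pset <- withStage("input", {
    if (!is.null(config$star)) {
      readParticles(config$star, pixelSize = config$pixel_size,
                    labelColumns = unlist(config$label_columns %||%
                                            character()))
    } else {
      sim <- config$simulate
      par <- sceneParams(
        nCells = sim$n_cells %||% 28,
        cellBox = unlist(sim$cell_box %||% c(5000, 5000, 1500)),
        nPolysomesPerCell = sim$n_polysomes_per_cell %||% 6,
        polysomeLength = sim$polysome_length,
        lengthLambda = sim$length_lambda %||% 3,
        stepDistanceMean = sim$step_distance_mean %||% 70,
        stepDistanceSD = sim$step_distance_sd %||% 15,
        monosomeCount = sim$monosome_count %||% 30,
        monosomeMinClearance = sim$monosome_min_clearance %||% 600,
        occupancyP = sim$occupancy_p %||% 0.67,
        tfBoundP = sim$tf_bound_p %||% 0.88,
        positionNoiseSD = sim$position_noise_sd %||% 0,
        markers = markers, seed = seed)
      simulateScene(par, seed = seed)$particles
    }
  })
  logEvent("input", particlesRead = nParticles(pset),
           tomograms = length(unique(particles(pset)$tomoID)))
  tr <- withStage("trace", tracePolysomes(pset, markers))
  logEvent("trace", candidateLinks = unname(tr$counts["candidateLinks"]),
           removedShared = unname(tr$counts["removedShared"]),
           removedCycles = unname(tr$counts["removedCycles"]),
           chains = unname(tr$counts["chains"]))
  tracedStar <- file.path(outDir, "traced.star")
  writeParticles(pset, tracedStar, chains = tr$chains)
  linksCsv <- file.path(outDir, "links.csv")
  lk <- links(tr$graph)
  utils::write.csv(
    data.frame(from_id = lk$from, to_id = lk$to,
               distance_A = lk$distance, tomo_id = lk$tomoID),
    linksCsv, row.names = FALSE)

  labels <- config$labels %||% list()
  occLabel <- labels$occupancy_label %||% "occupancy"
  occValue <- labels$occupancy_value %||% "2xbS20"
  stats <- withStage("stats", {
    out <- list(nParticles = nParticles(pset),
                nChains = length(chainMembers(tr$chains)),
                chainLengths = as.integer(chainLengths(tr$chains)))
    hasOcc <- occLabel %in% labelColumns(pset)
    if (hasOcc) {
      comp <- compositionFractions(tr$chains, pset, occLabel, occValue)
      occ <- occupancyByCell(pset, occLabel, occValue)
      nd <- neighbourDistances(pset, markers, occLabel)
      cs <- compareStrata(nd)
      out$composition <- comp[c("mean", "sd", "weightedMean", "nChains")]
      out$occupancy <- occ[c("mean", "sd", "pooled")]
      out$distanceStrata <- cs$strata
      out$strataTests <- cs$tests
      out$testMethod <- cs$method
      utils::write.csv(nd, file.path(outDir, "neighbour_distances.csv"),
                       row.names = FALSE)
    }
    if (!is.null(labels$state_label) && !is.null(labels$group_label)) {
      sd <- stateDistribution(pset, labels$state_label, labels$group_label)
      out$stateDistribution <- list(
        counts = as.data.frame(sd$counts),
        proportions = as.data.frame(sd$proportions),
        chisq = if (!is.null(sd$test))
          list(statistic = unname(sd$test$statistic),
               df = unname(sd$test$parameter), p = sd$test$p.value),
        note = sd$note)
    }
    out
  })
  reportJson <- file.path(outDir, "report.json")
  jsonlite::write_json(stats, reportJson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  resolved <- file.path(outDir, "resolved_config.yaml")
  yaml::write_yaml(config, resolved)
  cfg <- c(readLines(resolved),
           paste0("package_version: ", .pkgVersion()),
           paste0("config_hash: ", unname(tools::md5sum(resolved))))
  writeLines(cfg, resolved)
  logEvent("done", report = basename(reportJson))
  invisible(list(particles = pset, chains = tr$chains, graph = tr$graph,
                 stats = stats,
                 files = c(traced = tracedStar, links = linksCsv,
                           report = reportJson, config = resolved,
                           log = logFile)))
}
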