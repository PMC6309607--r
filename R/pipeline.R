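## End-to-end pipeline driver: simulate -> modules -> adjust -> map -> impact
## -> traits -> enrich, with a provenance manifest.

.configDefaults <- function() list(
  seed = 1L,
  nSubjects = 200L, nFeatures = 400L,
  moduleSpec = data.frame(module_id = 1:4, n_features = 50,
                          within_correlation = 0.6),
  gridShape = c(24L, 24L, 24L), voxelSize = 1, maskType = "ellipsoid",
  baseline = 20, couplingSpec = NULL, pathologySpec = list(),
  noise = list(smoothSigma = 2, sd = 1),
  traitSpec = list(r2_module = 0.17, r2_increment = 0, pathology_weight = 0),
  nStreamlines = 2000L,
  regionLabels = c("SFG", "MFG", "IFG", "ACC", "PUT", "THA"),
  minModuleSize = 20L, clusterRuns = 50L, consensusThreshold = 0.5,
  edgeThreshold = 0.2,
  q = 0.05, minClusterVoxels = 100L, connectivity = 6L,
  family = "per_module",
  adjustPathology = FALSE,
  stages = c("simulate", "modules", "adjust", "map", "impact", "traits",
             "enrich"))

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (the synthetic study conditions: 200
#' subjects, four 50-feature modules at within-correlation 0.6 among 400
#' features, 24^3 grid, FDR 5%, 100-voxel cluster extent, face connectivity)
#' and overrides the named entries. Unknown keys are rejected.
#'
#' @param ... named overrides of the default configuration.
#' @return a validated configuration list (class `voxelOmicsConfig`).
#' @export
pipelineConfig <- function(...) {
  cfg <- .configDefaults()
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (!all(cfg$stages %in% .configDefaults()$stages))
    stop("unknown stage name(s)")
  structure(cfg, class = "voxelOmicsConfig")
}

.stamp <- function(manifest, stage, params, files) {
  manifest$stages[[stage]] <- list(
    stage = stage, parameters = params,
    outputs = as.list(tools::md5sum(files)))
  manifest
}

#' Run the full imaging-omics pipeline on a synthetic cohort
#'
#' Executes the enabled stages in order — simulate, modules, adjust, map,
#' impact, traits, enrich — writing every intermediate product (TSV, NIfTI,
#' JSON) plus a provenance manifest (`manifest.json`: per-stage parameters
#' and MD5 checksums of outputs, and the serialized configuration) into
#' `outDir`. A failing stage aborts with its name; earlier outputs are
#' retained.
#'
#' @param config a configuration from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage products and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (!inherits(config, "voxelOmicsConfig")) stop("config must come from pipelineConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "voxelOmics", seed = config$seed, stages = list())
  state <- list()
  out <- function(...) file.path(outDir, ...)
  run <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible())
    ok <- try(fn(), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("pipeline stage '", stage, "' failed: ", attr(ok, "condition")$message)
  }

  run("simulate", function() {
    sc <- simConfig(nSubjects = config$nSubjects, nFeatures = config$nFeatures,
                    moduleSpec = config$moduleSpec,
                    gridShape = config$gridShape, voxelSize = config$voxelSize,
                    maskType = config$maskType, baseline = config$baseline,
                    couplingSpec = config$couplingSpec %||%
                      list(list(module = 1,
                                roi = roiCuboid(c(5, 5, 5), c(6, 6, 6),
                                                config$gridShape),
                                beta = 1)),
                    pathologySpec = config$pathologySpec,
                    noise = config$noise, traitSpec = config$traitSpec,
                    seed = config$seed)
    path <- generatePathology(sc)
    om <- generateOmics(sc, pathology = path)
    stack <- generateR2Stack(sc, om$latents, path)
    stream <- generateStreamlines(sc, config$nStreamlines,
                                  config$regionLabels)
    traits <- generateTraits(sc, om$latents[1, ], pathology = path)
    part <- unlist(om$truth$truePartition)
    sets <- split(names(part)[part > 0], part[part > 0])
    names(sets) <- paste0("planted_set_", names(sets))
    writeOmicsTsv(om$omics, out("omics.tsv"))
    writeTableTsv(path, out("pathology.tsv"))
    writeTableTsv(traits, out("traits.tsv"))
    writeStreamlinesTsv(stream, out("streamlines.tsv"))
    writeVolumeStack(stack, out("volumes"))
    writeGroundTruth(om$truth, out("ground_truth.json"))
    writeGmt(sets, out("sets.gmt"))
    state$sim <<- list(cfg = sc, omics = om$omics, latents = om$latents,
                       truth = om$truth, stack = stack, stream = stream,
                       traits = traits, pathology = path)
    manifest <<- .stamp(manifest, "simulate", list(seed = config$seed),
                        out(c("omics.tsv", "pathology.tsv", "traits.tsv",
                              "streamlines.tsv", "ground_truth.json",
                              "sets.gmt")))
  })

  run("modules", function() {
    om <- filterFeatures(state$sim$omics)
    cc <- correlationMatrix(om)
    part <- consensusCluster(cc, nRuns = config$clusterRuns,
                             minModuleSize = config$minModuleSize,
                             consensusThreshold = config$consensusThreshold,
                             edgeThreshold = config$edgeThreshold,
                             seed = config$seed)
    lv <- moduleAverages(om, part)
    writePartitionTsv(part, out("partition.tsv"))
    writeModuleLevelsTsv(lv, out("module_levels.tsv"))
    state$partition <<- part
    state$levels <<- lv
    manifest <<- .stamp(manifest, "modules",
                        list(nRuns = config$clusterRuns,
                             minModuleSize = config$minModuleSize),
                        out(c("partition.tsv", "module_levels.tsv")))
  })

  run("adjust", function() {
    cov <- state$sim$traits[, c("subject_id", "age_at_death", "sex",
                                "education")]
    X <- makeDesign(cov, if (config$adjustPathology) state$sim$pathology)
    state$stackAdj <<- residualizeVolumes(state$sim$stack, X)
    state$levelsAdj <<- residualizeLevels(state$levels, X)
    writeModuleLevelsTsv(state$levelsAdj, out("module_levels_adjusted.tsv"))
    manifest <<- .stamp(manifest, "adjust",
                        list(pathology = config$adjustPathology,
                             columns = colnames(X)),
                        out("module_levels_adjusted.tsv"))
  })

  run("map", function() {
    mp <- mapAllModules(state$levelsAdj, state$stackAdj, q = config$q,
                        minClusterVoxels = config$minClusterVoxels,
                        connectivity = config$connectivity,
                        family = config$family)
    writeTableTsv(mp$summary, out("mapping_summary.tsv"))
    for (m in names(mp$results))
      writeVolume(sigMask(mp$results[[m]]), out(sprintf("sig_%s.nii", m)),
                  config$voxelSize)
    state$mapping <<- mp
    manifest <<- .stamp(manifest, "map",
                        list(q = config$q,
                             minClusterVoxels = config$minClusterVoxels,
                             connectivity = config$connectivity,
                             family = config$family),
                        out("mapping_summary.tsv"))
  })

  run("impact", function() {
    counts <- vapply(state$mapping$results,
                     function(r) sum(sigMask(r)), numeric(1))
    files <- character(0)
    if (any(counts > 0)) {
      top <- names(counts)[which.max(counts)]
      roi <- which(sigMask(state$mapping$results[[top]]))
      imp <- impactScores(state$sim$stream, roi)
      writeTableTsv(pairPercentages(imp), out("impact_pairs.tsv"))
      writeTableTsv(regionScores(imp), out("impact_regions.tsv"))
      state$impact <<- imp
      files <- out(c("impact_pairs.tsv", "impact_regions.tsv"))
    }
    manifest <<- .stamp(manifest, "impact", list(), files)
  })

  run("traits", function() {
    grid <- moduleTraitGrid(state$levelsAdj, state$sim$traits, fdr = config$q)
    writeTableTsv(grid, out("module_trait_grid.tsv"))
    state$traitGrid <<- grid
    manifest <<- .stamp(manifest, "traits", list(fdr = config$q),
                        out("module_trait_grid.tsv"))
  })

  run("enrich", function() {
    sets <- readGmt(out("sets.gmt"))
    enr <- hypergeomEnrich(state$partition, sets)
    writeTableTsv(enr, out("enrichment.tsv"))
    state$enrichment <<- enr
    manifest <<- .stamp(manifest, "enrich", list(fdr = config$q),
                        out("enrichment.tsv"))
  })

  cfgSerial <- config
  cfgSerial$moduleSpec <- as.list(config$moduleSpec)
  jsonlite::write_json(list(config = unclass(cfgSerial)),
                       out("config.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(state, list(manifest = manifest)))
}
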