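#' @import methods
#' @importFrom stats cor sd rnorm rbinom runif qt pt phyper dhyper p.adjust
#'   complete.cases lm rpois quantile setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata `metadata<-` DataFrame
NULL

#' OmicsMatrix: a features-by-subjects omics assay
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding one
#' assay (`"omics"`) of numeric feature levels (genes for expression, CpGs for
#' methylation) across subjects, plus the omic kind in `metadata()`.
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#' @seealso [OmicsMatrix()] for construction, [correlationMatrix()],
#'   [consensusCluster()], [moduleAverages()]
#' @export
setClass("OmicsMatrix", contains = "SummarizedExperiment")

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (!"omics" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'omics' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "subject identifiers must be present and unique")
  kind <- metadata(object)$omicKind
  if (is.null(kind) || !kind %in% c("expression", "methylation"))
    msg <- c(msg, "metadata()$omicKind must be 'expression' or 'methylation'")
  if (length(msg)) msg else TRUE
})

#' ModuleLevels: per-subject average module levels
#'
#' A modules-by-subjects `SummarizedExperiment` whose single assay `"levels"`
#' holds, for each module, the per-subject arithmetic mean of the z-scored
#' member features. Rows are modules, columns subjects in the order of the
#' source [OmicsMatrix].
#'
#' @export
setClass("ModuleLevels", contains = "SummarizedExperiment")

setValidity("ModuleLevels", function(object) {
  msg <- character()
  if (!"levels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'levels' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "module identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "subject identifiers must be present and unique")
  if (length(msg)) msg else TRUE
})

#' ModulePartition: feature-to-module assignment from consensus clustering
#'
#' @slot assignment named integer vector mapping each feature to a module id;
#'   module id 0 means unassigned (background).
#' @slot moduleSizes named integer vector of member counts per named module
#'   (unassigned excluded).
#' @slot consensusSummary named numeric vector, per-module mean off-diagonal
#'   co-assignment frequency across base clustering runs.
#' @slot parameters list of the clustering parameters used.
#' @export
setClass("ModulePartition",
  slots = c(assignment = "integer", moduleSizes = "integer",
            consensusSummary = "numeric", parameters = "list"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  a <- object@assignment
  if (is.null(names(a)) || anyDuplicated(names(a)))
    msg <- c(msg, "assignment must be named with unique feature ids")
  if (any(a < 0L)) msg <- c(msg, "module ids must be >= 0")
  sz <- table(a[a > 0L])
  if (length(object@moduleSizes) != length(sz) ||
      (length(sz) && !identical(unname(object@moduleSizes[as.character(names(sz))]),
                                as.integer(sz))))
    msg <- c(msg, "moduleSizes inconsistent with assignment")
  if (length(msg)) msg else TRUE
})

#' R2Stack: subject-aligned voxelwise R2 volumes with a brain mask
#'
#' Transverse relaxation rate (R2 = 1/T2) volumes for a cohort, stored as a
#' subjects-by-voxels matrix over the full grid in R array (column-major)
#' order, together with a logical 3D mask of analyzed voxels, the grid
#' dimensions, and the isotropic voxel size in mm. Out-of-mask voxels are NA.
#'
#' @slot values numeric matrix, subjects x prod(gridDim); rownames are subject
#'   ids. Voxel v of subject s is `values[s, v]` with v a 1-based linear index
#'   into the grid.
#' @slot mask logical 3D array, TRUE for in-mask voxels.
#' @slot gridDim integer(3) grid shape.
#' @slot voxelSize numeric(1), isotropic voxel edge length in mm.
#' @export
setClass("R2Stack",
  slots = c(values = "matrix", mask = "array", gridDim = "integer",
            voxelSize = "numeric"))

setValidity("R2Stack", function(object) {
  msg <- character()
  d <- object@gridDim
  if (length(d) != 3L || any(d < 1L)) msg <- c(msg, "gridDim must be 3 positive integers")
  if (!identical(dim(object@mask), d)) msg <- c(msg, "mask dimensions must equal gridDim")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (ncol(object@values) != prod(d)) msg <- c(msg, "values must have prod(gridDim) columns")
  if (is.null(rownames(object@values)) || anyDuplicated(rownames(object@values)))
    msg <- c(msg, "subject ids (rownames of values) must be present and unique")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a positive scalar")
  inmask <- which(as.vector(object@mask))
  if (length(inmask) == 0L) msg <- c(msg, "mask must contain at least one voxel")
  else if (!all(is.finite(object@values[, inmask])))
    msg <- c(msg, "in-mask values must be finite")
  if (length(msg)) msg else TRUE
})

#' MappingResult: one module's voxelwise correlation map with FDR and
#' cluster-extent control
#'
#' @slot moduleId character(1)
#' @slot rMap,pMap numeric 3D arrays (NA outside mask); `pMap` holds two-sided
#'   p-values from the t transform of the Pearson correlation.
#' @slot qThreshold numeric(1): the Benjamini-Hochberg critical p-value for
#'   the family this module was corrected in (0 if nothing was rejected).
#' @slot sigMaskPrefilter logical 3D array: BH rejections before the
#'   cluster-extent filter.
#' @slot sigMaskFinal logical 3D array: voxels in surviving clusters.
#' @slot clusters data.frame with columns cluster_id, size, peak_abs_r and a
#'   list-column `voxels` of 1-based linear voxel indices, sorted by
#'   decreasing size (ties: smallest linear index first).
#' @export
setClass("MappingResult",
  slots = c(moduleId = "character", rMap = "array", pMap = "array",
            qThreshold = "numeric", sigMaskPrefilter = "array",
            sigMaskFinal = "array", clusters = "data.frame"))

setValidity("MappingResult", function(object) {
  msg <- character()
  d <- dim(object@rMap)
  for (s in c("pMap", "sigMaskPrefilter", "sigMaskFinal"))
    if (!identical(dim(slot(object, s)), d)) msg <- c(msg, paste(s, "dim mismatch"))
  if (any(slot(object, "sigMaskFinal") & !slot(object, "sigMaskPrefilter")))
    msg <- c(msg, "sigMaskFinal must be a subset of sigMaskPrefilter")
  r <- object@rMap
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) msg <- c(msg, "rMap must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' StreamlineTable: tractography streamline endpoint and traversal records
#'
#' Each record is one streamline: two gray-matter endpoint region labels and
#' the set of (1-based linear) voxel indices it traverses.
#'
#' @slot records data.frame with columns streamline_id, region_a, region_b and
#'   a list-column `traversed` of integer vectors.
#' @slot regionLabels character vector: the gray-region vocabulary.
#' @slot gridDim integer(3): the voxel grid the traversal indices refer to.
#' @export
setClass("StreamlineTable",
  slots = c(records = "data.frame", regionLabels = "character",
            gridDim = "integer"))

setValidity("StreamlineTable", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("streamline_id", "region_a", "region_b", "traversed")
  if (!all(need %in% names(rec))) {
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(rec)) {
    if (!all(rec$region_a %in% object@regionLabels) ||
        !all(rec$region_b %in% object@regionLabels))
      msg <- c(msg, "endpoint regions must be drawn from regionLabels")
    if (any(lengths(rec$traversed) == 0L))
      msg <- c(msg, "traversed voxel sets must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' ImpactTable: gray-matter impact scores of a white-matter ROI
#'
#' For a white-matter region of interest, `pairs` gives the percentage of
#' ROI-traversing streamlines connecting each gray-region pair, and `regions`
#' the per-region impact score: the summed percentages of ROI-traversing
#' streamlines terminating in that region. Pair percentages sum to 100; region
#' scores sum to 200 when no streamline self-connects a region (each
#' streamline has two endpoints).
#'
#' @slot pairs data.frame: region_a, region_b, n, pct (regions in each pair
#'   sorted lexicographically; rows sorted by decreasing pct).
#' @slot regions data.frame: region, score, sorted by decreasing score, ties
#'   by label.
#' @slot nTraversing integer(1): streamlines intersecting the ROI.
#' @export
setClass("ImpactTable",
  slots = c(pairs = "data.frame", regions = "data.frame",
            nTraversing = "integer"))

setValidity("ImpactTable", function(object) {
  msg <- character()
  if (object@nTraversing > 0L) {
    if (abs(sum(object@pairs$pct) - 100) > 1e-9)
      msg <- c(msg, "pair percentages must sum to 100")
  }
  if (length(msg)) msg else TRUE
})
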