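#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features x subjects.
#' @param omicKind `"expression"` or `"methylation"`.
#' @param featureIds,subjectIds identifiers; default to the dimnames of
#'   `values`.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' om <- OmicsMatrix(m, "expression")
#' omicKind(om)
#' @export
OmicsMatrix <- function(values, omicKind = c("expression", "methylation"),
                        featureIds = rownames(values),
                        subjectIds = colnames(values)) {
  omicKind <- match.arg(omicKind)
  values <- as.matrix(values)
  if (is.null(featureIds) || is.null(subjectIds))
    stop("feature and subject identifiers are required")
  dimnames(values) <- list(featureIds, subjectIds)
  se <- SummarizedExperiment(assays = list(omics = values))
  metadata(se)$omicKind <- omicKind
  new("OmicsMatrix", se)
}

#' Construct a ModuleLevels object
#'
#' @param values numeric matrix, modules x subjects, with module ids as
#'   rownames and subject ids as colnames.
#' @return A [ModuleLevels-class] object.
#' @export
ModuleLevels <- function(values) {
  se <- SummarizedExperiment(assays = list(levels = as.matrix(values)))
  new("ModuleLevels", se)
}

#' Construct an R2Stack
#'
#' @param values numeric matrix, subjects x voxels (full grid, column-major
#'   linear order), subject ids as rownames.
#' @param mask logical 3D array.
#' @param voxelSize isotropic voxel edge length in mm.
#' @return An [R2Stack-class] object; out-of-mask entries are set to NA.
#' @export
R2Stack <- function(values, mask, voxelSize = 1) {
  mask <- array(as.logical(mask), dim = dim(mask))
  values <- as.matrix(values)
  values[, !as.vector(mask)] <- NA_real_
  new("R2Stack", values = values, mask = mask,
      gridDim = as.integer(dim(mask)), voxelSize = as.numeric(voxelSize))
}

#' @rdname OmicsMatrix
#' @export
setMethod("omicKind", "OmicsMatrix", function(object) metadata(object)$omicKind)

#' @rdname ModulePartition
#' @export
setMethod("moduleAssignment", "ModulePartition", function(object) object@assignment)

#' @rdname ModulePartition
#' @export
setMethod("moduleSizes", "ModulePartition", function(object) object@moduleSizes)

#' @rdname R2Stack
#' @export
setMethod("brainMask", "R2Stack", function(object) object@mask)

#' @rdname R2Stack
#' @export
setMethod("voxelValues", "R2Stack", function(object) object@values)

#' @rdname R2Stack
#' @export
setMethod("gridDim", "R2Stack", function(object) object@gridDim)

#' @rdname R2Stack
#' @export
setMethod("voxelSize", "R2Stack", function(object) object@voxelSize)

#' @rdname R2Stack
#' @export
setMethod("subjectIds", "R2Stack", function(object) rownames(object@values))

#' @rdname MappingResult
#' @param final if TRUE (default) the post-cluster-filter mask, else the BH
#'   prefilter mask.
#' @param ... unused
#' @export
setMethod("sigMask", "MappingResult", function(object, final = TRUE, ...)
  if (final) object@sigMaskFinal else object@sigMaskPrefilter)

#' @rdname MappingResult
#' @export
setMethod("clusterTable", "MappingResult", function(object) object@clusters)

#' @rdname StreamlineTable
#' @export
setMethod("streamlineRecords", "StreamlineTable", function(object) object@records)

#' @rdname StreamlineTable
#' @export
setMethod("gridDim", "StreamlineTable", function(object) object@gridDim)

#' @rdname ImpactTable
#' @export
setMethod("regionScores", "ImpactTable", function(object) object@regions)

#' @rdname ImpactTable
#' @export
setMethod("pairPercentages", "ImpactTable", function(object) object@pairs)

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix (%s): %d features x %d subjects\n",
              omicKind(object), nrow(object), ncol(object)))
})

setMethod("show", "ModulePartition", function(object) {
  a <- object@assignment
  cat(sprintf("ModulePartition: %d features, %d modules, %d unassigned\n",
              length(a), length(object@moduleSizes), sum(a == 0L)))
  if (length(object@moduleSizes)) {
    sz <- sort(object@moduleSizes, decreasing = TRUE)
    cat("  sizes:", paste(sprintf("m%s=%d", names(sz), sz), collapse = " "), "\n")
  }
})

setMethod("show", "R2Stack", function(object) {
  cat(sprintf("R2Stack: %d subjects, grid %s, %d in-mask voxels (%.3g mm)\n",
              nrow(object@values), paste(object@gridDim, collapse = "x"),
              sum(object@mask), object@voxelSize))
})

setMethod("show", "MappingResult", function(object) {
  cat(sprintf(
    "MappingResult [%s]: %d BH rejections (critical p = %.3g), %d clusters, %d final voxels\n",
    object@moduleId, sum(object@sigMaskPrefilter, na.rm = TRUE),
    object@qThreshold, nrow(object@clusters),
    sum(object@sigMaskFinal, na.rm = TRUE)))
})

setMethod("show", "StreamlineTable", function(object) {
  cat(sprintf("StreamlineTable: %d streamlines, %d gray regions, grid %s\n",
              nrow(object@records), length(object@regionLabels),
              paste(object@gridDim, collapse = "x")))
})

setMethod("show", "ImpactTable", function(object) {
  cat(sprintf("ImpactTable: %d traversing streamlines, %d region pairs\n",
              object@nTraversing, nrow(object@pairs)))
  if (nrow(object@regions))
    print(head(object@regions, 5))
})
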