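#' @rdname OmicsMatrix
#' @param object an object
#' @export
setGeneric("omicKind", function(object) standardGeneric("omicKind"))

#' @rdname ModulePartition
#' @param object an object
#' @export
setGeneric("moduleAssignment", function(object) standardGeneric("moduleAssignment"))

#' @rdname ModulePartition
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname R2Stack
#' @param object an object
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))

#' @rdname R2Stack
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))

#' @rdname R2Stack
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' @rdname R2Stack
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname R2Stack
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname MappingResult
#' @param object an object
#' @export
setGeneric("sigMask", function(object, ...) standardGeneric("sigMask"))

#' @rdname MappingResult
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))

#' @rdname StreamlineTable
#' @param object an object
#' @export
setGeneric("streamlineRecords", function(object) standardGeneric("streamlineRecords"))

#' @rdname ImpactTable
#' @param object an object
#' @export
setGeneric("regionScores", function(object) standardGeneric("regionScores"))

#' @rdname ImpactTable
#' @export
setGeneric("pairPercentages", function(object) standardGeneric("pairPercentages"))
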