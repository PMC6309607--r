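## Shared readers/writers. TSV dialect: tab-separated, header row, UTF-8,
## "NA" for missing. Volumes are NIfTI-1 via RNifti. Voxel indices in all
## tables are 1-based linear indices in R array (column-major) order.

#' @importFrom RNifti readNifti writeNifti asNifti pixdim "pixdim<-"
NULL

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read / write tabular pipeline inputs as TSV
#'
#' Plain readers/writers for covariate, pathology and trait tables
#' (tab-separated, header row, `NA` for missing).
#'
#' @param df data.frame.
#' @param path file path.
#' @return `readTableTsv` returns a data.frame.
#' @export
writeTableTsv <- function(df, path) .writeTsv(df, path)

#' @rdname writeTableTsv
#' @export
readTableTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write an omics matrix as TSV
#'
#' Layout: first column `feature_id`, remaining columns one per subject.
#'
#' @param omics an [OmicsMatrix-class].
#' @param path file path.
#' @param omicKind used on read; `"expression"` or `"methylation"`.
#' @export
writeOmicsTsv <- function(omics, path) {
  v <- assay(omics, "omics")
  .writeTsv(data.frame(feature_id = rownames(v), v, check.names = FALSE), path)
}

#' @rdname writeOmicsTsv
#' @export
readOmicsTsv <- function(path, omicKind = "expression") {
  df <- readTableTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  OmicsMatrix(m, omicKind)
}

#' Read / write module levels as TSV
#'
#' @param levels a [ModuleLevels-class].
#' @param path file path.
#' @export
writeModuleLevelsTsv <- function(levels, path) {
  v <- assay(levels, "levels")
  .writeTsv(data.frame(module_id = rownames(v), v, check.names = FALSE), path)
}

#' @rdname writeModuleLevelsTsv
#' @export
readModuleLevelsTsv <- function(path) {
  df <- readTableTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$module_id)
  ModuleLevels(m)
}

#' Read / write a module partition as two-column TSV
#'
#' Columns `feature_id`, `module_id` (0 = unassigned).
#'
#' @param partition a [ModulePartition-class].
#' @param path file path.
#' @export
writePartitionTsv <- function(partition, path) {
  a <- moduleAssignment(partition)
  .writeTsv(data.frame(feature_id = names(a), module_id = unname(a)), path)
}

#' @rdname writePartitionTsv
#' @export
readPartitionTsv <- function(path) {
  df <- readTableTsv(path)
  a <- setNames(as.integer(df$module_id), df$feature_id)
  named <- sort(unique(a[a > 0L]))
  msizes <- vapply(named, function(j) sum(a == j), integer(1))
  new("ModulePartition", assignment = a,
      moduleSizes = setNames(msizes, as.character(named)),
      consensusSummary = setNames(rep(NA_real_, length(named)),
                                  as.character(named)),
      parameters = list())
}

#' Read / write a streamline table as TSV
#'
#' Columns `streamline_id`, `region_a`, `region_b`, `traversed` (traversed
#' 1-based linear voxel indices joined with commas).
#'
#' @param table a [StreamlineTable-class].
#' @param path file path.
#' @param gridDim integer(3), required on read.
#' @param regionLabels optional region vocabulary on read; defaults to the
#'   labels observed in the file.
#' @export
writeStreamlinesTsv <- function(table, path) {
  rec <- table@records
  .writeTsv(data.frame(
    streamline_id = rec$streamline_id, region_a = rec$region_a,
    region_b = rec$region_b,
    traversed = vapply(rec$traversed, paste, character(1), collapse = ",")),
    path)
}

#' @rdname writeStreamlinesTsv
#' @export
readStreamlinesTsv <- function(path, gridDim, regionLabels = NULL) {
  df <- readTableTsv(path)
  rec <- data.frame(streamline_id = df$streamline_id,
                    region_a = as.character(df$region_a),
                    region_b = as.character(df$region_b))
  rec$traversed <- lapply(strsplit(as.character(df$traversed), ","),
                          as.integer)
  if (is.null(regionLabels))
    regionLabels <- sort(unique(c(rec$region_a, rec$region_b)))
  new("StreamlineTable", records = rec, regionLabels = regionLabels,
      gridDim = as.integer(gridDim))
}

#' Write a 3D map as NIfTI-1
#'
#' @param map 3D numeric or logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize isotropic voxel edge in mm.
#' @export
writeVolume <- function(map, path, voxelSize = 1) {
  img <- asNifti(array(as.numeric(map), dim(map)))
  pixdim(img) <- rep(voxelSize, 3)
  writeNifti(img, path)
  invisible(path)
}

#' Read / write an R2 volume stack as per-subject NIfTI files
#'
#' The stack directory holds one volume per subject, a `mask.nii` file, and a
#' `manifest.tsv` (columns `subject_id`, `file`) fixing the subject order.
#'
#' @param stack an [R2Stack-class].
#' @param dir directory (created if needed).
#' @return `readVolumeStack` returns an [R2Stack-class]; subject order follows
#'   the manifest.
#' @export
writeVolumeStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- stack@gridDim
  subj <- subjectIds(stack)
  files <- sprintf("r2_%s.nii", subj)
  vals <- stack@values
  vals[is.na(vals)] <- 0
  for (i in seq_along(subj))
    writeVolume(array(vals[i, ], d), file.path(dir, files[i]),
                stack@voxelSize)
  writeVolume(stack@mask, file.path(dir, "mask.nii"), stack@voxelSize)
  .writeTsv(data.frame(subject_id = subj, file = files),
            file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname writeVolumeStack
#' @export
readVolumeStack <- function(dir) {
  man <- readTableTsv(file.path(dir, "manifest.tsv"))
  mask <- readNifti(file.path(dir, "mask.nii"))
  vs <- pixdim(mask)[1]
  d <- dim(mask)
  maskArr <- array(as.vector(mask) != 0, d)
  if (!any(maskArr)) stop("mask contains no in-mask voxels")
  vals <- matrix(NA_real_, nrow(man), prod(d),
                 dimnames = list(man$subject_id, NULL))
  for (i in seq_len(nrow(man))) {
    img <- readNifti(file.path(dir, man$file[i]))
    if (!identical(dim(img), d))
      stop("volume shape mismatch: ", man$file[i], " vs mask.nii")
    if (max(abs(pixdim(img)[1:3] - pixdim(mask)[1:3])) > 1e-6)
      stop("voxel size mismatch: ", man$file[i], " vs mask.nii")
    vals[i, ] <- as.vector(img)
  }
  R2Stack(vals, maskArr, vs)
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of member identifier vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(s)
    paste(c(s, "na", sets[[s]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
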