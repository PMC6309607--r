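## Covariate / neuropathology adjustment: ordinary-least-squares
## residualization of R2 volumes (per voxel) and module levels (per module).

#' Build a design matrix from covariate and optional pathology tables
#'
#' Columns: intercept, age_at_death, sex, education, plus — when `pathology`
#' is supplied — global_ad_pathology, gross_infarcts, microinfarcts,
#' lewy_bodies (the second, optional adjustment block). Subjects with any
#' missing entry are dropped listwise with a message.
#'
#' @param covariates data.frame with subject_id, age_at_death, sex, education.
#' @param pathology optional data.frame with subject_id and pathology columns.
#' @return numeric design matrix with subject ids as rownames (intercept
#'   included).
#' @export
makeDesign <- function(covariates, pathology = NULL) {
  d <- covariates[, c("subject_id", "age_at_death", "sex", "education")]
  if (!is.null(pathology)) {
    pcols <- intersect(c("global_ad_pathology", "gross_infarcts",
                         "microinfarcts", "lewy_bodies"), names(pathology))
    d <- merge(d, pathology[, c("subject_id", pcols)], by = "subject_id",
               sort = FALSE)
  }
  ok <- complete.cases(d)
  if (any(!ok))
    message(sum(!ok), " subject(s) dropped for missing design entries")
  d <- d[ok, , drop = FALSE]
  X <- cbind(intercept = 1, as.matrix(d[, -1, drop = FALSE]))
  rownames(X) <- d$subject_id
  X
}

.checkDesign <- function(X) {
  if (is.null(rownames(X))) stop("design matrix must carry subject ids as rownames")
  if (!"intercept" %in% colnames(X) && !all(X[, 1] == 1))
    X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  list(X = X, qr = qrX)
}

#' Residualize R2 volumes against a design matrix
#'
#' Replaces every in-mask voxel's across-subject series by its OLS residuals
#' against the design (intercept included). Subjects absent from the design
#' are dropped from the returned stack; out-of-mask voxels stay NA.
#'
#' @param stack an [R2Stack-class].
#' @param design subjects x p numeric matrix with subject-id rownames, e.g.
#'   from [makeDesign()].
#' @return An [R2Stack-class] of residuals for the common subjects.
#' @export
residualizeVolumes <- function(stack, design) {
  chk <- .checkDesign(design)
  subj <- intersect(subjectIds(stack), rownames(chk$X))
  if (length(subj) < ncol(chk$X) + 1)
    stop("too few common subjects for the design")
  if (length(subj) < nrow(stack@values))
    message(nrow(stack@values) - length(subj),
            " subject(s) dropped (not in design)")
  X <- chk$X[subj, , drop = FALSE]
  qrX <- qr(X)
  vals <- stack@values[subj, , drop = FALSE]
  inmask <- which(as.vector(stack@mask))
  vals[, inmask] <- qr.resid(qrX, vals[, inmask, drop = FALSE])
  R2Stack(vals, stack@mask, stack@voxelSize)
}

#' Residualize module levels against a design matrix
#'
#' As [residualizeVolumes()], applied to each module row of a
#' [ModuleLevels-class].
#'
#' @param levels a [ModuleLevels-class].
#' @param design subjects x p numeric matrix with subject-id rownames.
#' @return A [ModuleLevels-class] of residuals for the common subjects.
#' @export
residualizeLevels <- function(levels, design) {
  chk <- .checkDesign(design)
  subj <- intersect(colnames(levels), rownames(chk$X))
  if (length(subj) < ncol(chk$X) + 1)
    stop("too few common subjects for the design")
  X <- chk$X[subj, , drop = FALSE]
  qrX <- qr(X)
  lv <- assay(levels, "levels")[, subj, drop = FALSE]
  res <- t(qr.resid(qrX, t(lv)))
  ModuleLevels(res)
}
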