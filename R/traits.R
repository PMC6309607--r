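## Module-trait association grid and incremental variance explained.

#' Module-trait association grid
#'
#' Pearson correlation of every module level with every trait (binary traits
#' are coerced to 0/1, making the statistic the point-biserial correlation),
#' with the two-sided t-based p-value, Benjamini-Hochberg q-values over all
#' defined cells of the grid, and a significance flag at `q <= fdr`. Cells
#' with a constant trait or fewer than 4 complete pairs are left NA and
#' excluded from the BH family.
#'
#' @param levels a [ModuleLevels-class].
#' @param traits data.frame with `subject_id` and trait columns (numeric or
#'   0/1 coded).
#' @param fdr FDR level for the flag (default 0.05).
#' @param traitCols trait columns to use; defaults to all non-id numeric
#'   columns.
#' @return data.frame: module_id, trait, n, r, p, q, significant.
#' @export
moduleTraitGrid <- function(levels, traits, fdr = 0.05, traitCols = NULL) {
  lv <- assay(levels, "levels")
  common <- intersect(colnames(lv), traits$subject_id)
  if (length(common) < 4) stop("fewer than 4 aligned subjects")
  tr <- traits[match(common, traits$subject_id), , drop = FALSE]
  lv <- lv[, common, drop = FALSE]
  if (is.null(traitCols))
    traitCols <- setdiff(names(tr)[vapply(tr, is.numeric, logical(1))],
                         "subject_id")
  grid <- expand.grid(module_id = rownames(lv), trait = traitCols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- lv[grid$module_id[i], ]
    y <- tr[[grid$trait[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4 || sd(y[ok]) == 0 || sd(x[ok]) == 0)
      return(c(n = n, r = NA_real_, p = NA_real_))
    r <- cor(x[ok], y[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(n = n, r = r, p = 2 * pt(-abs(tt), n - 2))
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$q <- NA_real_
  def <- !is.na(out$p)
  if (any(def)) out$q[def] <- p.adjust(out$p[def], "BH")
  out$significant <- !is.na(out$q) & out$q <= fdr
  out
}

#' Incremental variance in a trait explained by a module beyond mean R2
#'
#' Compares the variance in a trait (e.g. the cognitive-decline slope)
#' explained by a module level against, and on top of, the mean R2 over the
#' trait-associated voxels: `r2_module` is the R-squared of trait ~ module,
#' `r2_base` of trait ~ mean in-mask R2 over `traitSigMask`, and `delta_r2`
#' the gain of the full model trait ~ base + module over the base model.
#' Computed on listwise-complete subjects.
#'
#' @param trait numeric per-subject trait, named by subject id (or aligned to
#'   the stack).
#' @param moduleLevel numeric per-subject module level, named by subject id
#'   (or aligned to the stack).
#' @param stack an [R2Stack-class].
#' @param traitSigMask logical 3D array of trait-correlated voxels (e.g. from
#'   mapping the trait itself with [mapAllModules()]); must be nonempty.
#' @return list with `r2_module`, `r2_base`, `delta_r2`.
#' @export
incrementalVariance <- function(trait, moduleLevel, stack, traitSigMask) {
  vox <- which(as.vector(traitSigMask & stack@mask))
  if (!length(vox))
    stop("empty trait significance mask; relax the FDR or cluster thresholds")
  subj <- subjectIds(stack)
  if (!is.null(names(trait))) trait <- trait[subj]
  if (!is.null(names(moduleLevel))) moduleLevel <- moduleLevel[subj]
  base <- rowMeans(stack@values[, vox, drop = FALSE])
  ok <- is.finite(trait) & is.finite(moduleLevel) & is.finite(base)
  y <- trait[ok]; m <- moduleLevel[ok]; b <- base[ok]
  if (length(y) < 4) stop("fewer than 4 complete subjects")
  r2 <- function(fit) summary(fit)$r.squared
  r2m <- r2(lm(y ~ m))
  r2b <- r2(lm(y ~ b))
  r2f <- r2(lm(y ~ b + m))
  list(r2_module = r2m, r2_base = r2b, delta_r2 = r2f - r2b)
}
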