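## The core mapping stage: voxelwise Pearson correlation of a module level
## with R2, Benjamini-Hochberg FDR control, and contiguous cluster-extent
## filtering.

#' Voxelwise Pearson correlation map of a module level
#'
#' For every in-mask voxel, the sample Pearson correlation between the
#' per-subject module level and the voxel's R2 series, with the two-sided
#' p-value from the exact-null t transform t = r * sqrt((n-2)/(1-r^2)) on
#' n - 2 degrees of freedom. Zero-variance voxels get r = NA, p = 1.
#'
#' @param level numeric per-subject module level, aligned to the stack's
#'   subjects (or named by subject id).
#' @param stack an [R2Stack-class] with >= 4 subjects.
#' @return list with 3D arrays `rMap` and `pMap` (NA outside the mask).
#' @export
pearsonMap <- function(level, stack) {
  n <- nrow(stack@values)
  if (n < 4) stop("at least 4 subjects are required")
  if (!is.null(names(level))) level <- level[subjectIds(stack)]
  if (length(level) != n) stop("module level / stack subject mismatch")
  if (sd(level) == 0) stop("module level is constant across subjects")
  d <- stack@gridDim
  inmask <- which(as.vector(stack@mask))
  V <- stack@values[, inmask, drop = FALSE]
  z <- (level - mean(level)) / sd(level)
  mu <- colMeans(V)
  Vc <- sweep(V, 2, mu)
  sdv <- sqrt(colSums(Vc^2) / (n - 1))
  r <- as.vector(crossprod(Vc, z)) / ((n - 1) * sdv)
  r[sdv == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- Inf * sign(r[abs(r) >= 1])
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[is.na(r)] <- 1
  rMap <- array(NA_real_, d); pMap <- array(NA_real_, d)
  rMap[inmask] <- r
  pMap[inmask] <- p
  list(rMap = rMap, pMap = pMap)
}

## Benjamini-Hochberg step-up on a p-value vector: the critical p is p_(k)
## for the largest k with p_(k) <= (k/m) q, 0 when no such k exists.
bhCritical <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= (seq_len(m) / m) * q)
  if (!length(ok)) 0 else ps[max(ok)]
}

#' Benjamini-Hochberg FDR threshold of a voxelwise p-map
#'
#' Applies the BH step-up procedure over the in-mask p-values and returns the
#' BH critical p-value together with the binary rejection mask (p <= critical
#' p).
#'
#' @param pMap 3D array of p-values (NA outside the mask) or numeric vector.
#' @param mask logical 3D array delimiting the family; defaults to the
#'   non-NA entries of `pMap`.
#' @param q FDR level in (0, 1).
#' @return list with `qThreshold` (the BH critical p, 0 if nothing rejected)
#'   and `sigMask` (logical, same shape as `pMap`).
#' @export
fdrThreshold <- function(pMap, mask = NULL, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (is.null(mask)) mask <- !is.na(pMap)
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("empty p-value family")
  p <- as.vector(pMap)[idx]
  if (anyNA(p)) stop("NA p-values inside the family")
  crit <- bhCritical(p, q)
  sig <- array(FALSE, dim = if (is.null(dim(pMap))) length(pMap) else dim(pMap))
  sig[idx] <- p <= crit & crit > 0
  list(qThreshold = crit, sigMask = sig)
}

## 3D connected components by level-synchronous flood fill.
## connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' Label connected components of a 3D binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array of component labels (0 = background), labelled in
#'   order of first (smallest linear index) voxel.
#' @export
labelComponents <- function(mask, connectivity = 6) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  d <- dim(mask)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(off != 0)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  labels <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  coords <- arrayInd(fg, d)
  inFg <- array(FALSE, d); inFg[fg] <- TRUE
  cur <- 0L
  for (s in fg) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    frontier <- matrix(arrayInd(s, d), 1)
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                       drop = FALSE] +
        off[rep(seq_len(nrow(off)), nrow(frontier)), , drop = FALSE]
      keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
              cand[, 2] >= 1 & cand[, 2] <= d[2] &
              cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
      new <- unique(lin[inFg[lin] & labels[lin] == 0L])
      if (!length(new)) break
      labels[new] <- cur
      frontier <- arrayInd(new, d)
    }
  }
  labels
}

#' Cluster-extent filter of a significance mask
#'
#' Labels connected components of the BH rejection mask at the chosen voxel
#' connectivity and discards components smaller than `minClusterVoxels`
#' (default 100 voxels = 100 mm^3 at 1 mm isotropic voxels; for other voxel
#' sizes express the threshold via `minClusterMm3`, converted by rounding
#' up).
#'
#' @param sigMask logical 3D array (BH rejections).
#' @param minClusterVoxels smallest retained component, in voxels.
#' @param connectivity 6 (default, face adjacency), 18 or 26.
#' @param rMap optional correlation map used to report each cluster's peak
#'   absolute correlation.
#' @param minClusterMm3,voxelSize alternative threshold in mm^3 with the
#'   voxel edge length in mm; overrides `minClusterVoxels` when given.
#' @return list with `clusters` (data.frame: cluster_id, size, peak_abs_r,
#'   list-column `voxels` of linear indices; sorted by decreasing size, ties
#'   by smallest linear index) and `sigMaskFinal` (logical array).
#' @export
clusterFilter <- function(sigMask, minClusterVoxels = 100, connectivity = 6,
                          rMap = NULL, minClusterMm3 = NULL, voxelSize = 1) {
  if (!is.null(minClusterMm3))
    minClusterVoxels <- ceiling(minClusterMm3 / voxelSize^3)
  labels <- labelComponents(sigMask, connectivity)
  final <- array(FALSE, dim(sigMask))
  comp <- split(which(labels > 0L), labels[labels > 0L])
  sizes <- lengths(comp)
  keep <- comp[sizes >= minClusterVoxels]
  if (length(keep)) {
    ord <- order(-lengths(keep), vapply(keep, min, numeric(1)))
    keep <- keep[ord]
    final[unlist(keep, use.names = FALSE)] <- TRUE
    peaks <- vapply(keep, function(vx)
      if (is.null(rMap)) NA_real_ else max(abs(rMap[vx]), na.rm = TRUE),
      numeric(1))
    clusters <- data.frame(cluster_id = seq_along(keep),
                           size = unname(lengths(keep)),
                           peak_abs_r = unname(peaks))
    clusters$voxels <- lapply(unname(keep), as.integer)
  } else {
    clusters <- data.frame(cluster_id = integer(0), size = integer(0),
                           peak_abs_r = numeric(0))
    clusters$voxels <- list()
  }
  list(clusters = clusters, sigMaskFinal = final)
}

#' Map every module onto the R2 stack
#'
#' Runs [pearsonMap()], [fdrThreshold()] and [clusterFilter()] for each module
#' row. The BH family is per module by default (`family = "per_module"`: one
#' correction over in-mask voxels for each module) or pooled across all
#' module-voxel tests (`family = "pooled"`). A per-module summary also counts
#' voxels significant at the uncorrected p < 0.01 threshold for
#' solid-vs-hollow-bar style comparisons of uncorrected versus FDR maps.
#'
#' @param levels a [ModuleLevels-class].
#' @param stack an [R2Stack-class] with the same subjects.
#' @param q FDR level (default 0.05).
#' @param minClusterVoxels cluster-extent threshold (default 100).
#' @param connectivity 6, 18 or 26 (default 6).
#' @param family `"per_module"` or `"pooled"`.
#' @param uncorrectedP threshold for the uncorrected comparison count
#'   (default 0.01).
#' @return list with `results` (named list of [MappingResult-class]) and
#'   `summary` (data.frame: module_id, n_sig_uncorrected, n_sig_fdr,
#'   n_clusters, largest_cluster, n_sig_final).
#' @export
mapAllModules <- function(levels, stack, q = 0.05, minClusterVoxels = 100,
                          connectivity = 6,
                          family = c("per_module", "pooled"),
                          uncorrectedP = 0.01) {
  family <- match.arg(family)
  common <- intersect(colnames(levels), subjectIds(stack))
  if (length(common) < 4) stop("fewer than 4 aligned subjects")
  lv <- assay(levels, "levels")[, common, drop = FALSE]
  sub <- stack@values[common, , drop = FALSE]
  stk <- R2Stack(sub, stack@mask, stack@voxelSize)
  mods <- rownames(lv)
  maps <- lapply(mods, function(m) pearsonMap(lv[m, ], stk))
  names(maps) <- mods
  if (family == "pooled") {
    inmask <- which(as.vector(stk@mask))
    allp <- unlist(lapply(maps, function(x) x$pMap[inmask]))
    crit <- bhCritical(allp, q)
  }
  results <- list()
  summ <- data.frame()
  for (m in mods) {
    pm <- maps[[m]]
    if (family == "per_module") {
      fd <- fdrThreshold(pm$pMap, stk@mask, q)
    } else {
      sig <- array(FALSE, stk@gridDim)
      sig[stk@mask & !is.na(pm$pMap) & pm$pMap <= crit & crit > 0] <- TRUE
      fd <- list(qThreshold = crit, sigMask = sig)
    }
    cf <- clusterFilter(fd$sigMask, minClusterVoxels, connectivity,
                        rMap = pm$rMap)
    results[[m]] <- new("MappingResult", moduleId = m, rMap = pm$rMap,
                        pMap = pm$pMap, qThreshold = fd$qThreshold,
                        sigMaskPrefilter = fd$sigMask,
                        sigMaskFinal = cf$sigMaskFinal, clusters = cf$clusters)
    summ <- rbind(summ, data.frame(
      module_id = m,
      n_sig_uncorrected = sum(pm$pMap < uncorrectedP, na.rm = TRUE),
      n_sig_fdr = sum(fd$sigMask),
      n_clusters = nrow(cf$clusters),
      largest_cluster = if (nrow(cf$clusters)) max(cf$clusters$size) else 0L,
      n_sig_final = sum(cf$sigMaskFinal)))
  }
  list(results = results, summary = summ)
}
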