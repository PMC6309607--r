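## Module detection: consensus clustering of the feature-feature Pearson
## correlation matrix, and per-subject module average levels.

#' Drop zero-variance features
#'
#' Features constant across subjects carry no correlation information and are
#' removed before clustering; the number dropped is reported via `message()`.
#'
#' @param omics an [OmicsMatrix-class].
#' @return An [OmicsMatrix-class] containing only features with nonzero
#'   variance.
#' @export
filterFeatures <- function(omics) {
  v <- assay(omics, "omics")
  sds <- apply(v, 1, sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop))
    message(sum(drop), " zero-variance feature(s) removed before clustering")
  OmicsMatrix(v[!drop, , drop = FALSE], omicKind(omics))
}

#' Feature-feature Pearson correlation matrix
#'
#' @param omics an [OmicsMatrix-class] with >= 3 subjects and no
#'   zero-variance features (see [filterFeatures()]).
#' @return Symmetric features x features correlation matrix with unit
#'   diagonal.
#' @export
correlationMatrix <- function(omics) {
  v <- assay(omics, "omics")
  if (ncol(v) < 3) stop("at least 3 subjects are required")
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(rownames(v)[sds == 0], collapse = ", "),
         " (run filterFeatures() first)")
  cc <- cor(t(v))
  diag(cc) <- 1
  cc
}

#' Consensus clustering of a correlation matrix into modules
#'
#' Runs a stochastic base community detection (weighted label propagation on
#' the graph of feature pairs with correlation >= `edgeThreshold`; negative
#' and weak edges are discarded since module averages are unsigned means)
#' `nRuns` times, accumulates the co-assignment frequency of every feature
#' pair into a consensus matrix, then cuts the consensus matrix once by
#' average-linkage hierarchical clustering at dissimilarity
#' `1 - consensusThreshold`. Clusters smaller than `minModuleSize` are merged
#' into the unassigned pool (module id 0). Surviving modules are renumbered
#' 1, 2, ... by decreasing size.
#'
#' After the cut, low-membership features are pruned: a member whose
#' module-membership correlation (its correlation with the module's average
#' profile, computed from the correlation matrix as
#' mean_j r_ij / sqrt(mean_jl r_jl) over members j, l) falls below
#' `minMembership` is returned to the unassigned pool, iterating until
#' stable. This removes features attached to a module by one or two spurious
#' edges, which label propagation alone cannot reject.
#'
#' @param corr symmetric correlation matrix from [correlationMatrix()].
#' @param nRuns number of base clustering runs (default 50).
#' @param minModuleSize smallest reportable module (default 20).
#' @param consensusThreshold co-assignment frequency at which two features are
#'   considered to belong together in the final cut (default 0.5).
#' @param edgeThreshold minimum correlation for a graph edge (default 0.2).
#' @param minMembership module-membership pruning threshold (default 0.4).
#' @param seed integer seed; the run is deterministic given it.
#' @return A [ModulePartition-class].
#' @export
consensusCluster <- function(corr, nRuns = 50, minModuleSize = 20,
                             consensusThreshold = 0.5, edgeThreshold = 0.2,
                             minMembership = 0.4, seed = 1) {
  if (is.null(dim(corr)) || nrow(corr) == 0) stop("empty correlation matrix")
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (nRuns < 1) stop("nRuns must be >= 1")
  p <- nrow(corr)
  ids <- rownames(corr) %||% sprintf("f%05d", seq_len(p))
  adj <- corr
  diag(adj) <- 0
  adj[adj < edgeThreshold] <- 0
  if (all(adj == 0)) {
    return(new("ModulePartition",
               assignment = setNames(integer(p), ids),
               moduleSizes = setNames(integer(0), character(0)),
               consensusSummary = setNames(numeric(0), character(0)),
               parameters = list(nRuns = nRuns, minModuleSize = minModuleSize,
                                 consensusThreshold = consensusThreshold,
                                 edgeThreshold = edgeThreshold,
                                 minMembership = minMembership, seed = seed)))
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  consensus <- matrix(0, p, p)
  for (run in seq_len(nRuns)) {
    set.seed(substreamSeed(seed + run, "clustering"))
    memb <- igraph::membership(
      igraph::cluster_label_prop(g, weights = igraph::E(g)$weight))
    for (cl in split(seq_len(p), memb))
      consensus[cl, cl] <- consensus[cl, cl] + 1
  }
  consensus <- consensus / nRuns
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  cut <- stats::cutree(hc, h = 1 - consensusThreshold)
  ## membership pruning: drop weakly attached members (correlation with the
  ## module average profile below minMembership), iterating until stable
  repeat {
    changed <- FALSE
    for (cl in unique(cut[cut > 0L])) {
      member <- which(cut == cl)
      if (length(member) < 2) next
      cm <- corr[member, member, drop = FALSE]
      kme <- rowMeans(corr[member, member, drop = FALSE]) / sqrt(mean(cm))
      weak <- member[kme < minMembership]
      if (length(weak)) {
        cut[weak] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(cut[cut > 0L])
  keep <- names(sizes)[sizes >= minModuleSize]
  assignment <- setNames(integer(p), ids)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (j in seq_along(ord))
      assignment[cut == as.integer(ord[j])] <- j
  }
  named <- sort(unique(assignment[assignment > 0L]))
  msizes <- vapply(named, function(j) sum(assignment == j), integer(1))
  csum <- vapply(named, function(j) {
    idx <- which(assignment == j)
    if (length(idx) < 2) return(1)
    cm <- consensus[idx, idx]
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  new("ModulePartition",
      assignment = assignment,
      moduleSizes = setNames(msizes, as.character(named)),
      consensusSummary = setNames(csum, as.character(named)),
      parameters = list(nRuns = nRuns, minModuleSize = minModuleSize,
                        consensusThreshold = consensusThreshold,
                        edgeThreshold = edgeThreshold,
                        minMembership = minMembership, seed = seed))
}

#' Per-subject module average levels
#'
#' Each module's level in a subject is the arithmetic mean, over member
#' features, of the feature's z-score (feature minus its across-subject mean,
#' divided by its SD). Unassigned features (module 0) are excluded.
#'
#' @param omics an [OmicsMatrix-class].
#' @param partition a [ModulePartition-class] whose features are a subset of
#'   the omics features.
#' @return A [ModuleLevels-class], modules x subjects.
#' @export
moduleAverages <- function(omics, partition) {
  v <- assay(omics, "omics")
  a <- moduleAssignment(partition)
  if (!all(names(a) %in% rownames(v)))
    stop("partition contains features absent from the omics matrix")
  mods <- sort(unique(a[a > 0L]))
  if (!length(mods)) stop("partition has no named modules")
  z <- t(scale(t(v)))
  lv <- matrix(NA_real_, length(mods), ncol(v),
               dimnames = list(as.character(mods), colnames(v)))
  for (j in seq_along(mods)) {
    member <- names(a)[a == mods[j]]
    zm <- z[member, , drop = FALSE]
    if (any(!is.finite(zm)))
      stop("module ", mods[j], " has zero-variance member feature(s)")
    lv[j, ] <- colMeans(zm)
  }
  ModuleLevels(lv)
}
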