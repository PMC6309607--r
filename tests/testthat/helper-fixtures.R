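## Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages(library(SummarizedExperiment))

## tiny omics matrix with fixed values for hand-checkable arithmetic
tinyOmics <- function(values = NULL) {
  if (is.null(values))
    values <- matrix(c(1, 2, 3, 4,
                       2, 4, 6, 8,
                       4, 3, 2, 1), nrow = 3, byrow = TRUE)
  dimnames(values) <- list(sprintf("g%d", seq_len(nrow(values))),
                           sprintf("s%d", seq_len(ncol(values))))
  OmicsMatrix(values, "expression")
}

## small all-in-mask stack from a subjects x voxels matrix
tinyStack <- function(values, dm = NULL, voxelSize = 1) {
  if (is.null(dm)) dm <- c(ncol(values), 1L, 1L)
  rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  R2Stack(values, array(TRUE, dm), voxelSize)
}

## independent connected-component oracle: iterate "take the minimum label
## among my neighbours" to a fixpoint, then renumber by first voxel
oracleLabelComponents <- function(mask, connectivity = 6) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(off != 0)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0, d)
  lab[mask] <- which(mask)   # provisional label = own linear index
  repeat {
    old <- lab
    for (v in which(mask)) {
      co <- arrayInd(v, d)
      for (o in seq_len(nrow(off))) {
        nb <- co + off[o, , drop = FALSE]
        if (any(nb < 1) || any(nb > d)) next
        ln <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (mask[ln] && lab[ln] < lab[v]) lab[v] <- lab[ln]
      }
    }
    if (identical(old, lab)) break
  }
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

## brute-force upper-tail hypergeometric P(X >= k) by pmf summation
oracleHyperTail <- function(k, setSize, universe, draws) {
  xs <- k:min(setSize, draws)
  sum(dhyper(xs, setSize, universe - setSize, draws))
}

## streamline table built by hand from explicit records
handStreamlines <- function(regionA, regionB, traversed,
                            gridDim = c(10L, 10L, 10L)) {
  rec <- data.frame(streamline_id = seq_along(regionA),
                    region_a = regionA, region_b = regionB)
  rec$traversed <- traversed
  new("StreamlineTable", records = rec,
      regionLabels = sort(unique(c(regionA, regionB))),
      gridDim = as.integer(gridDim))
}
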