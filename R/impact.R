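## Gray-matter impact scoring: which gray regions terminate the streamlines
## that traverse a significant white-matter ROI.

#' Streamlines traversing a white-matter ROI
#'
#' A streamline traverses the ROI when at least one of its traversed voxels
#' lies inside it.
#'
#' @param table a [StreamlineTable-class].
#' @param roi integer vector of 1-based linear voxel indices (e.g.
#'   `which(sigMask(result))`), nonempty.
#' @return A [StreamlineTable-class] restricted to the traversing records.
#' @export
traversingStreamlines <- function(table, roi) {
  if (!length(roi)) stop("empty ROI")
  nvox <- prod(table@gridDim)
  if (any(roi < 1L) || any(roi > nvox)) stop("ROI indices outside the grid")
  inroi <- logical(nvox)
  inroi[roi] <- TRUE
  hit <- vapply(table@records$traversed, function(v) any(inroi[v]), logical(1))
  new("StreamlineTable", records = table@records[hit, , drop = FALSE],
      regionLabels = table@regionLabels, gridDim = table@gridDim)
}

#' Gray-matter impact scores of a white-matter ROI
#'
#' Restricts the streamline table to ROI-traversing records, computes the
#' percentage of those streamlines connecting each (unordered) gray-region
#' endpoint pair, and scores each gray region by summing the percentages of
#' all pairs it participates in — the summed percentages of ROI-traversing
#' streamlines terminating in that region. A self-connecting pair (both
#' endpoints in one region) contributes its percentage once.
#'
#' @param table a [StreamlineTable-class].
#' @param roi integer vector of 1-based linear voxel indices, nonempty.
#' @return An [ImpactTable-class]. With no traversing streamlines the tables
#'   are empty and a warning is raised.
#' @export
impactScores <- function(table, roi) {
  trav <- traversingStreamlines(table, roi)
  rec <- trav@records
  n <- nrow(rec)
  if (n == 0L) {
    warning("no streamlines traverse the ROI")
    pairs <- data.frame(region_a = character(0), region_b = character(0),
                        n = integer(0), pct = numeric(0))
    regions <- data.frame(region = character(0), score = numeric(0))
    return(new("ImpactTable", pairs = pairs, regions = regions,
               nTraversing = 0L))
  }
  a <- pmin(rec$region_a, rec$region_b)
  b <- pmax(rec$region_a, rec$region_b)
  key <- paste(a, b, sep = "\r")
  cnt <- table(key)
  ab <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  pairs <- data.frame(region_a = ab[, 1], region_b = ab[, 2],
                      n = as.integer(cnt), pct = 100 * as.integer(cnt) / n)
  pairs <- pairs[order(-pairs$pct, pairs$region_a, pairs$region_b), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  score <- setNames(numeric(0), character(0))
  addTo <- function(g, x) {
    score[g] <<- (if (g %in% names(score)) score[[g]] else 0) + x
  }
  for (i in seq_len(nrow(pairs))) {
    addTo(pairs$region_a[i], pairs$pct[i])
    if (pairs$region_b[i] != pairs$region_a[i])
      addTo(pairs$region_b[i], pairs$pct[i])
  }
  regions <- data.frame(region = names(score), score = unname(score))
  regions <- regions[order(-regions$score, regions$region), , drop = FALSE]
  rownames(regions) <- NULL
  new("ImpactTable", pairs = pairs, regions = regions, nTraversing = n)
}
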