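## Module annotation by exact hypergeometric over-representation against
## gene-set collections (ontology categories, cell-type signatures).

#' Read a GMT gene-set collection
#'
#' @param path path to a GMT file (one set per line: id, description,
#'   members).
#' @return named list of member character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation of modules in gene sets
#'
#' For every named module and gene set, the upper-tail exact hypergeometric
#' p-value P(X >= overlap) of drawing the observed overlap when
#' |module & universe| features are drawn without replacement from a universe
#' containing |set & universe| set members. The tail includes the observed
#' overlap. Benjamini-Hochberg q-values are computed across all module-set
#' tests. Modules with no features in the universe are skipped with a
#' warning. The universe defaults to the features of the partition — the
#' analyzable background — rather than the genome.
#'
#' @param partition a [ModulePartition-class].
#' @param sets named list of member identifier vectors (see [readGmt()]).
#' @param universe character vector of annotatable features; default all
#'   features in the partition.
#' @param fdr FDR level for the significance flag (default 0.05).
#' @return data.frame: module_id, set_id, module_size, set_size, overlap, p,
#'   q, significant; sorted by p.
#' @export
hypergeomEnrich <- function(partition, sets, universe = NULL, fdr = 0.05) {
  a <- moduleAssignment(partition)
  if (is.null(universe)) universe <- names(a)
  universe <- unique(universe)
  N <- length(universe)
  if (!N) stop("empty universe")
  sets <- lapply(sets, function(s) intersect(s, universe))
  mods <- sort(unique(a[a > 0L]))
  rows <- list()
  for (m in mods) {
    member <- intersect(names(a)[a == m], universe)
    if (!length(member)) {
      warning("module ", m, " has no features in the universe; skipped")
      next
    }
    k <- length(member)
    for (s in names(sets)) {
      K <- length(sets[[s]])
      ov <- length(intersect(member, sets[[s]]))
      p <- phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m, set_id = s, module_size = k, set_size = K,
        overlap = ov, p = p)
    }
  }
  if (!length(rows))
    return(data.frame(module_id = integer(0), set_id = character(0),
                      module_size = integer(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$q <= fdr
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
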