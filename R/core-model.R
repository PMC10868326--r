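## Elementary wMEC cost operations shared by the solver, haplotagging and
## the metrics. All costs are exact integer arithmetic.

#' Row cost of reads against one haplotype
#'
#' The cost of editing a read's observed allele chain to match the given
#' haplotype: the sum of the weights of concrete observations whose allele
#' differs from the haplotype at that column. Sentinel observations
#' (ambiguous or unknown) contribute nothing.
#'
#' @param reads a \linkS4class{CondensedReadSet}.
#' @param haplotype integer vector of allele indices, one per column of
#'   \code{reads}.
#' @return integer vector of per-read costs, length \code{length(reads)}.
#' @examples
#' crs <- CondensedReadSet("r1",
#'   data.frame(read = 1, col = 1:3, allele = c(0, 0, 1), weight = 5))
#' rowCost(crs, c(0L, 0L, 1L))  # 0
#' rowCost(crs, c(1L, 1L, 0L))  # 15
#' @export
rowCost <- function(reads, haplotype) {
  stopifnot(is(reads, "CondensedReadSet"))
  ob <- reads@obs
  haplotype <- as.integer(haplotype)
  if (nrow(ob) && max(ob$col) > length(haplotype))
    stop("observation column exceeds haplotype length")
  cost <- integer(length(reads))
  if (nrow(ob)) {
    mism <- ob$allele >= 0L & ob$allele != haplotype[ob$col]
    if (any(mism)) {
      agg <- rowsum(ob$weight[mism], ob$read[mism])
      cost[as.integer(rownames(agg))] <- as.integer(agg[, 1L])
    }
  }
  cost
}

#' Total wMEC cost of a diplotype
#'
#' Each read is charged the cheaper of its two row costs (against h1 and
#' h2); the diplotype cost is the sum over reads. This is the objective
#' the solver minimizes.
#'
#' @param reads a \linkS4class{CondensedReadSet}.
#' @param d a \linkS4class{Diplotype} addressing the same columns.
#' @return non-negative integer.
#' @export
diplotypeCost <- function(reads, d) {
  stopifnot(is(d, "Diplotype"))
  as.integer(sum(pmin(rowCost(reads, d@h1), rowCost(reads, d@h2))))
}

#' Canonical orientation of a diplotype
#'
#' Swaps h1/h2 if needed so that \code{h1[1] <= h2[1]}. The cost is
#' orientation-invariant. Canonical orientation makes solver output
#' deterministic and comparable across runs.
#'
#' @param d a \linkS4class{Diplotype}.
#' @return the canonicalized \linkS4class{Diplotype}.
#' @export
canonicalizeDiplotype <- function(d) {
  stopifnot(is(d, "Diplotype"))
  if (nSites(d) && d@h1[1L] > d@h2[1L]) {
    tmp <- d@h1
    d@h1 <- d@h2
    d@h2 <- tmp
  }
  d
}
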