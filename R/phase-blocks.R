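## Phase block generation: the sweep that partitions each chromosome's
## heterozygous sites into putative blocks by read-mapping connectivity.

#' Does a mapping span a new site and the current block?
#'
#' TRUE iff the mapping's reference span fully contains the new site's
#' half-open span \code{[pos, pos + nchar(ref))} and at least one block
#' site's span. Full containment (rather than partial overlap) avoids
#' phantom connectivity from reads abutting a site.
#'
#' @param mapping numeric length-2 vector \code{c(start, end)} (0-based
#'   half-open) or a list with \code{start}/\code{end}.
#' @param blockSpans two-column matrix (start, end) of block site spans.
#' @param newSpan numeric length-2 vector, the new site's span.
#' @return logical.
#' @examples
#' spansBlock(c(100, 5000), cbind(200, 201), c(4800, 4801))  # TRUE
#' spansBlock(c(100, 300), cbind(200, 201), c(4800, 4801))   # FALSE
#' @export
spansBlock <- function(mapping, blockSpans, newSpan) {
  if (is.list(mapping)) mapping <- c(mapping$start, mapping$end)
  covers <- function(s, e) mapping[1L] <= s & e <= mapping[2L]
  covers(newSpan[1L], newSpan[2L]) &&
    any(covers(blockSpans[, 1L], blockSpans[, 2L]))
}

#' Generate putative phase blocks from read connectivity
#'
#' Sweeps each chromosome's heterozygous sites in order. A single-variant
#' block is started from the first site; each next site extends the
#' current block if (a) at least one mapping with sufficient mapping
#' quality fully covers both the new site and some site already in the
#' block, or failing that (b) some read has one mapping covering the new
#' site and a different same-name mapping (a primary/supplementary pair)
#' covering a block site -- the bridge that lets blocks span homozygous
#' deletions and reference gaps. Otherwise the block is closed and a new
#' one starts. The resulting blocks are contiguous, disjoint, consume
#' every heterozygous site, and are a lower bound on the final number of
#' phase blocks (solving may split, never merge).
#'
#' @param sites a \linkS4class{VariantSet}.
#' @param alignments data.frame of alignment records with at least
#'   \code{readName}, \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{mapq}, \code{supplementary}.
#' @param minMapq minimum mapping quality for connectivity (default 5).
#' @return list of unsolved \linkS4class{PhaseBlock}s in genomic order.
#' @export
generateBlocks <- function(sites, alignments, minMapq = 5L) {
  blocks <- list()
  blockId <- 0L
  aln <- alignments[alignments$mapq >= minMapq, , drop = FALSE]
  for (ch in unique(siteChrom(sites))) {
    hetRows <- which(siteChrom(sites) == ch & isHet(sites))
    if (!length(hetRows)) next
    hetRows <- hetRows[order(siteIndex(sites)[hetRows])]
    pos <- sitePos(sites)[hetRows]
    if (is.unsorted(pos)) stop("sites must be position-sorted")
    spanEnd <- pos + nchar(siteRef(sites)[hetRows])
    ca <- aln[aln$chrom == ch, , drop = FALSE]
    if (nrow(ca) && is.unsorted(ca$start)) stop("alignments must be sorted by start")
    ## alignments fully covering each site
    cov <- if (nrow(ca)) {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = pos + 1L, end = pmax(spanEnd, pos + 1L)),
        IRanges::IRanges(start = ca$start + 1L, end = ca$end),
        type = "within")
      split(S4Vectors::subjectHits(hits),
            factor(S4Vectors::queryHits(hits), seq_along(hetRows)))
    } else rep(list(integer(0)), length(hetRows))

    inBlockAln <- logical(nrow(ca))
    inBlockName <- new.env(parent = emptyenv())
    cur <- 1L   # local index of first site of current block
    flush <- function(from, to) {
      blockId <<- blockId + 1L
      idx <- siteIndex(sites)[hetRows[from:to]]
      blocks[[length(blocks) + 1L]] <<- PhaseBlock(
        blockId, ch, idx, phaseSet = pos[from] + 1L)
    }
    enter <- function(i) {
      ids <- cov[[i]]
      inBlockAln[ids] <<- TRUE
      for (nm in unique(ca$readName[ids])) assign(nm, TRUE, envir = inBlockName)
    }
    enter(1L)
    i <- 2L
    while (i <= length(hetRows)) {
      ids <- cov[[i]]
      direct <- any(inBlockAln[ids])
      bridged <- !direct && length(ids) &&
        any(vapply(unique(ca$readName[ids]), function(nm)
          isTRUE(get0(nm, envir = inBlockName)), TRUE))
      if (direct || bridged) {
        enter(i)
      } else {
        flush(cur, i - 1L)
        inBlockAln[] <- FALSE
        inBlockName <- new.env(parent = emptyenv())
        cur <- i
        enter(i)
      }
      i <- i + 1L
    }
    flush(cur, length(hetRows))
  }
  blocks
}
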