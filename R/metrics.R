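## Phasing evaluation: switch/flip errors against a truth, block NG50,
## phased-variant counts by class, and the fully-phased-gene fraction.

## greedy switch/flip decomposition of one block's agreement sequence.
## a: 0/1 agreement (predicted h1 matches truth h1 vs truth h2); NA sites
## (unphased in truth) are dropped first. Two adjacent transitions
## bounding a single site are one flip; every other transition is a
## switch, so switches + 2*flips equals the raw transition count.
switchFlipBlock <- function(a) {
  a <- a[!is.na(a)]
  if (length(a) < 2L) return(c(switches = 0L, flips = 0L))
  trans <- which(diff(a) != 0L)
  sw <- 0L; fl <- 0L
  k <- 1L
  while (k <= length(trans)) {
    if (k < length(trans) && trans[k + 1L] == trans[k] + 1L) {
      fl <- fl + 1L
      k <- k + 2L
    } else {
      sw <- sw + 1L
      k <- k + 1L
    }
  }
  c(switches = sw, flips = fl)
}

#' Switch and flip errors against a truth phasing
#'
#' For each solved block, forms the agreement sequence over sites phased
#' in both truth and prediction (1 where the predicted h1 allele equals
#' the truth h1 allele) and counts its transitions: a single flipped site
#' bounded by two transitions is one flip; every remaining transition is
#' one switch. Per-block orientation is immaterial: complementing the
#' agreement sequence leaves its transitions unchanged, so the counts are
#' already the orientation minimum, and the result is symmetric under
#' globally swapping the truth haplotypes.
#'
#' @param truthH1 integer vector of truth h1 alleles indexed by
#'   heterozygous site index (single chromosome), or a named list of such
#'   vectors keyed by chromosome. NA marks sites unphased in the truth.
#' @param blocks list of \linkS4class{PhaseBlock}s (unsolved blocks are
#'   skipped).
#' @return named integer vector \code{c(switches, flips)}.
#' @export
switchFlip <- function(truthH1, blocks) {
  tot <- c(switches = 0L, flips = 0L)
  for (b in blocks) {
    if (!isSolved(b) || nSites(b) < 2L) next
    tv <- if (is.list(truthH1)) truthH1[[b@chrom]] else truthH1
    if (is.null(tv)) stop("no truth for chromosome ", b@chrom)
    if (max(b@siteIndices) > length(tv))
      stop("truth does not cover block sites")
    a <- ifelse(is.na(tv[b@siteIndices]), NA_integer_,
                as.integer(b@diplotype@h1 == tv[b@siteIndices]))
    tot <- tot + switchFlipBlock(a)
  }
  tot
}

#' Phase block NG50
#'
#' The largest length L such that blocks of length >= L cover at least
#' half of the reference length; 0 when the blocks never reach half.
#' Invariant under block order and monotone in block growth.
#'
#' @param blockLengths numeric vector of block span lengths in bases.
#' @param referenceLength total reference length in bases (> 0); the
#'   denominator is the reference, not the covered genome.
#' @return NG50 in bases.
#' @examples
#' ng50(c(30, 30, 30), 100)  # 30
#' ng50(10, 100)             # 0
#' @export
ng50 <- function(blockLengths, referenceLength) {
  stopifnot(referenceLength > 0)
  s <- sort(as.numeric(blockLengths), decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= referenceLength / 2)
  if (!length(i)) 0 else s[i[1L]]
}

#' Block spans
#'
#' Reference span of each block: from its first site's start to its last
#' site's end.
#'
#' @param blocks list of \linkS4class{PhaseBlock}s.
#' @param sites the \linkS4class{VariantSet}.
#' @param solvedOnly restrict to solved multi-site blocks (default TRUE).
#' @return data.frame: chrom, start, end (0-based half-open), length.
#' @export
blockSpans <- function(blocks, sites, solvedOnly = TRUE) {
  rows <- lapply(blocks, function(b) {
    if (solvedOnly && (!isSolved(b) || nSites(b) < 2L)) return(NULL)
    sel <- which(siteChrom(sites) == b@chrom & isHet(sites) &
                 siteIndex(sites) %in% b@siteIndices)
    data.frame(chrom = b@chrom, start = min(sitePos(sites)[sel]),
               end = max(sitePos(sites)[sel] + nchar(siteRef(sites)[sel])))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out$length <- out$end - out$start
  out
}

#' Phased-variant counts by class
#'
#' Counts heterozygous sites inside solved multi-site blocks, partitioned
#' by source class.
#'
#' @param blocks list of \linkS4class{PhaseBlock}s.
#' @param sites the \linkS4class{VariantSet}.
#' @return named integer vector: small, sv, tandem_repeat, total.
#' @export
phasedCounts <- function(blocks, sites) {
  counts <- setNames(integer(3L), VARIANT_SOURCES)
  for (b in blocks) {
    if (!isSolved(b) || nSites(b) < 2L) next
    sel <- which(siteChrom(sites) == b@chrom & isHet(sites) &
                 siteIndex(sites) %in% b@siteIndices)
    tab <- table(factor(siteSource(sites)[sel], VARIANT_SOURCES))
    counts <- counts + as.integer(tab)
  }
  c(counts, total = sum(counts))
}

#' Fraction of fully phased genes
#'
#' A gene is fully phased iff all heterozygous sites starting within its
#' interval belong to one single solved block; genes with no heterozygous
#' site count as (vacuously) fully phased. With \code{requireSpan = TRUE}
#' the block must additionally span the whole gene interval.
#'
#' @param genes gene intervals: a \code{GRanges}, a BED path (imported
#'   via rtracklayer), or a data.frame with chrom/start/end (0-based
#'   half-open).
#' @param blocks list of \linkS4class{PhaseBlock}s.
#' @param sites the \linkS4class{VariantSet}.
#' @param requireSpan stricter block-spans-gene definition.
#' @return fraction in [0, 1] (NaN for an empty gene set).
#' @export
genePhasing <- function(genes, blocks, sites, requireSpan = FALSE) {
  if (is.character(genes)) genes <- rtracklayer::import(genes)
  if (is(genes, "GRanges"))
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes) - 1L,
                        end = GenomicRanges::end(genes))
  ## block of each het site, plus solved-block spans
  siteBlock <- list()
  span <- list()
  for (b in blocks) {
    if (!isSolved(b) || nSites(b) < 2L) next
    key <- paste(b@chrom, b@siteIndices)
    for (kk in key) siteBlock[[kk]] <- b@blockId
    sel <- which(siteChrom(sites) == b@chrom & isHet(sites) &
                 siteIndex(sites) %in% b@siteIndices)
    span[[as.character(b@blockId)]] <-
      c(min(sitePos(sites)[sel]),
        max(sitePos(sites)[sel] + nchar(siteRef(sites)[sel])))
  }
  phased <- logical(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    sel <- which(siteChrom(sites) == genes$chrom[g] & isHet(sites) &
                 sitePos(sites) >= genes$start[g] &
                 sitePos(sites) < genes$end[g])
    if (!length(sel)) {
      phased[g] <- TRUE
      next
    }
    ids <- unlist(siteBlock[paste(genes$chrom[g], siteIndex(sites)[sel])])
    if (length(ids) == length(sel) && length(unique(ids)) == 1L) {
      if (requireSpan) {
        sp <- span[[as.character(ids[1L])]]
        phased[g] <- sp[1L] <= genes$start[g] && sp[2L] >= genes$end[g]
      } else phased[g] <- TRUE
    }
  }
  sum(phased) / nrow(genes)
}
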