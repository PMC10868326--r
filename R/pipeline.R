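## End-to-end orchestration: per-chromosome, per-block work units with a
## deterministic parallel-execution contract (the parallel unit is the
## putative phase block; results are collected in genomic order, so output
## bytes are identical for any worker count).

#' PhasingResult: everything a phasing run produced
#'
#' @slot sites the merged \linkS4class{VariantSet}.
#' @slot blocks list of final (post-split) \linkS4class{PhaseBlock}s in
#'   genomic order.
#' @slot reads list of per-block \linkS4class{CondensedReadSet}s, parallel
#'   to \code{blocks} where solved (NULL for single-site blocks).
#' @slot tagMap data.frame (readName, hap, ps) of haplotag assignments.
#' @slot summary list of summary statistics.
#' @slot files character vector of written output paths.
#' @export
setClass("PhasingResult",
  representation(sites = "VariantSet", blocks = "list", reads = "list",
                 tagMap = "data.frame", summary = "list",
                 files = "character")
)

setMethod("show", "PhasingResult", function(object) {
  s <- object@summary
  cat("PhasingResult:", length(object@blocks), "blocks (",
      s$n_solved, "solved,", s$n_fallback, "fallback )\n")
  cat(sprintf("  phased variants: %d small, %d sv, %d tandem_repeat (total %d)\n",
              s$phased["small"], s$phased["sv"], s$phased["tandem_repeat"],
              s$phased["total"]))
  cat(sprintf("  block NG50: %s bp\n", format(s$ng50, big.mark = ",")))
})

#' PhasingResult accessors
#' @param x a \linkS4class{PhasingResult}
#' @name phasingResultAccessors
#' @export
resultBlocks <- function(x) x@blocks

#' @rdname phasingResultAccessors
#' @export
resultSites <- function(x) x@sites

#' @rdname phasingResultAccessors
#' @export
resultReads <- function(x) x@reads

#' @rdname phasingResultAccessors
#' @export
resultSummary <- function(x) x@summary

#' @rdname phasingResultAccessors
#' @export
resultTagMap <- function(x) x@tagMap

#' Assign reads to haplotypes
#'
#' Each condensed read is assigned to the haplotype with strictly smaller
#' row cost against its block's solved diplotype; ties (including reads
#' whose observations are all ambiguous) are left untagged. A read
#' condensed into several blocks is tagged from the block where it has the
#' most concrete observations (earliest block on ties).
#'
#' @param blocks list of solved \linkS4class{PhaseBlock}s.
#' @param readSets list of \linkS4class{CondensedReadSet}s parallel to
#'   \code{blocks}.
#' @return data.frame: readName, hap (1/2), ps.
#' @export
haplotagAssign <- function(blocks, readSets) {
  rows <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    crs <- readSets[[i]]
    if (is.null(crs) || !isSolved(b) || nSites(b) < 2L) next
    d <- b@diplotype
    c1 <- rowCost(crs, d@h1)
    c2 <- rowCost(crs, d@h2)
    ob <- crs@obs
    nConc <- integer(length(crs))
    if (nrow(ob)) {
      agg <- rowsum((ob$allele >= 0L) + 0L, ob$read)
      nConc[as.integer(rownames(agg))] <- as.integer(agg[, 1L])
    }
    sel <- which(c1 != c2)
    if (length(sel))
      rows[[length(rows) + 1L]] <- data.frame(
        readName = crs@readName[sel],
        hap = ifelse(c1[sel] < c2[sel], 1L, 2L),
        ps = b@phaseSet, nConc = nConc[sel])
  }
  all <- do.call(rbind, rows)
  if (is.null(all))
    return(data.frame(readName = character(0), hap = integer(0),
                      ps = integer(0)))
  all <- all[order(all$readName, -all$nConc, all$ps), , drop = FALSE]
  all <- all[!duplicated(all$readName), , drop = FALSE]
  all <- all[order(all$readName), c("readName", "hap", "ps")]
  rownames(all) <- NULL
  all
}

## solve one putative multi-site block: assignment -> collapse -> A* ->
## post-split. Pure function of its inputs (the deterministic parallel
## unit).
solveBlockUnit <- function(block, sites, alignments, reference, mode,
                           budget, minMapq, windowPad, chunkSize) {
  hetSel <- which(siteChrom(sites) == block@chrom & isHet(sites) &
                  siteIndex(sites) %in% block@siteIndices)
  spanA <- min(sitePos(sites)[hetSel])
  spanB <- max(sitePos(sites)[hetSel] + nchar(siteRef(sites)[hetSel]))
  ca <- alignments[alignments$chrom == block@chrom &
                   alignments$mapq >= minMapq &
                   alignments$start < spanB &
                   alignments$end > spanA, , drop = FALSE]
  asg <- assignBlock(ca, sites, reference, block@chrom, mode = mode,
                     budget = budget, windowPad = windowPad)
  crs <- collapseMappings(asg$observations, ca$readName, block@siteIndices)
  gt <- blockGenotypes(sites, block@chrom, block@siteIndices)
  d <- solveAStar(crs, gt, chunkSize = chunkSize)
  stats <- list(mode = asg$mode, fallback = asg$fallback,
                expansions = attr(d, "expansions"), cost = d@cost)
  solved <- PhaseBlock(block@blockId, block@chrom, block@siteIndices,
                       block@phaseSet, diplotype = d, stats = stats)
  parts <- postSplit(solved, crs, sites)
  readsOf <- lapply(parts, function(p)
    restrictColumns(crs, match(p@siteIndices, block@siteIndices)))
  list(blocks = parts, reads = readsOf)
}

#' Run the full phasing pipeline
#'
#' Reads variants and alignments, generates putative phase blocks per
#' chromosome, assigns alleles (dual mode by default), collapses
#' same-name mappings, solves each block's diplotype to optimality,
#' splits blocks at junctions without phase evidence, and (optionally)
#' writes phased VCFs, haplotagged alignments and statistics. Blocks are
#' independent sub-problems; with \code{threads > 1} they are solved in
#' parallel and the output is byte-identical to a single-threaded run.
#'
#' @param vcf character vector of VCF paths, named by source class
#'   (\code{small}, \code{sv}, \code{tandem_repeat}); unnamed = small.
#' @param alignments SAM/BAM path.
#' @param reference FASTA path (or a named character vector of
#'   chromosome sequences).
#' @param sample sample name in the VCFs.
#' @param outPrefix if non-NULL, write \code{<prefix>.<source>.phased.vcf}
#'   per input VCF, \code{<prefix>.haplotagged.sam} (when
#'   \code{haplotag}), \code{<prefix>.blocks.tsv} and
#'   \code{<prefix>.summary.tsv}.
#' @param mode allele assignment mode: \code{"dual"} (default),
#'   \code{"global"}, \code{"local"}.
#' @param budget dual-mode DP-cell budget per block (default 1e9).
#' @param minMapq connectivity/assignment mapping-quality floor
#'   (default 5).
#' @param windowPad local re-alignment window pad (default 25).
#' @param chunkSize A* heuristic chunk width (default 8).
#' @param haplotag also assign reads to haplotypes.
#' @param threads worker count for per-block solving.
#' @param referenceLength NG50 denominator; defaults to the total length
#'   of the supplied reference.
#' @return a \linkS4class{PhasingResult}.
#' @export
runPhasing <- function(vcf, alignments, reference, sample,
                       outPrefix = NULL, mode = c("dual", "global", "local"),
                       budget = 1e9, minMapq = 5L, windowPad = 25L,
                       chunkSize = 8L, haplotag = FALSE, threads = 1L,
                       referenceLength = NULL) {
  mode <- match.arg(mode)
  refSeqs <- if (is.character(reference) && length(reference) == 1L &&
                 file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    names(x) <- sub("\\s.*", "", names(x))
    setNames(as.character(x), names(x))
  } else reference
  referenceLength <- referenceLength %||% sum(nchar(refSeqs))

  sites <- readVariantFiles(vcf, sample)
  alnPath <- alignments
  aln <- readAlignments(alnPath)
  blocks <- generateBlocks(sites, aln, minMapq = minMapq)

  multi <- which(vapply(blocks, nSites, 0L) >= 2L)
  applyFun <- if (threads > 1L)
    function(xx, f) parallel::mclapply(xx, f, mc.cores = threads)
  else lapply
  solvedUnits <- applyFun(blocks[multi], function(b) {
    if (!b@chrom %in% names(refSeqs))
      stop("chromosome ", b@chrom, " absent from reference")
    solveBlockUnit(b, sites, aln, refSeqs[[b@chrom]], mode, budget,
                   minMapq, windowPad, chunkSize)
  })
  for (u in solvedUnits)
    if (inherits(u, "try-error") || !is.list(u)) stop(u)

  ## splice solved (possibly split) blocks back in genomic order and
  ## renumber ids deterministically
  outBlocks <- list(); outReads <- list()
  ui <- 1L
  for (i in seq_along(blocks)) {
    if (i %in% multi) {
      u <- solvedUnits[[ui]]; ui <- ui + 1L
      for (j in seq_along(u$blocks)) {
        outBlocks[[length(outBlocks) + 1L]] <- u$blocks[[j]]
        outReads[[length(outReads) + 1L]] <- u$reads[[j]]
      }
    } else {
      outBlocks[[length(outBlocks) + 1L]] <- blocks[[i]]
      outReads[length(outReads) + 1L] <- list(NULL)
    }
  }
  for (i in seq_along(outBlocks)) outBlocks[[i]]@blockId <- i

  tagMap <- if (haplotag) haplotagAssign(outBlocks, outReads)
            else data.frame(readName = character(0), hap = integer(0),
                            ps = integer(0))

  counts <- phasedCounts(outBlocks, sites)
  spans <- blockSpans(outBlocks, sites)
  summary <- list(
    n_blocks = length(outBlocks),
    n_solved = sum(vapply(outBlocks, isSolved, TRUE)),
    n_fallback = sum(vapply(outBlocks, function(b)
      isTRUE(b@stats$fallback), TRUE)),
    phased = counts,
    ng50 = ng50(spans$length, referenceLength),
    total_cost = sum(vapply(outBlocks, function(b)
      if (isSolved(b)) b@diplotype@cost else 0L, 0L)))

  files <- character(0)
  if (!is.null(outPrefix)) {
    srcs <- names(vcf) %||% rep("small", length(vcf))
    srcs[!nzchar(srcs)] <- "small"
    for (i in seq_along(vcf)) {
      out <- sprintf("%s.%s.phased.vcf", outPrefix, srcs[i])
      writePhasedVcf(vcf[i], sites, outBlocks, out, sample)
      files <- c(files, out)
    }
    if (haplotag && grepl("\\.sam$", alnPath, ignore.case = TRUE)) {
      out <- paste0(outPrefix, ".haplotagged.sam")
      writeHaplotaggedSam(alnPath, tagMap, out)
      files <- c(files, out)
    }
    bs <- paste0(outPrefix, ".blocks.tsv")
    writeBlockStats(outBlocks, sites, bs)
    sm <- paste0(outPrefix, ".summary.tsv")
    sdf <- data.frame(metric = c("n_blocks", "n_solved", "n_fallback",
                                 "phased_small", "phased_sv",
                                 "phased_tandem_repeat", "phased_total",
                                 "ng50", "total_cost"),
                      value = c(summary$n_blocks, summary$n_solved,
                                summary$n_fallback, counts, summary$ng50,
                                summary$total_cost))
    utils::write.table(sdf, sm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, bs, sm)
  }

  new("PhasingResult", sites = sites, blocks = outBlocks, reads = outReads,
      tagMap = tagMap, summary = summary, files = files)
}
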