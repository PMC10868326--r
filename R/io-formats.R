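## File-format boundary. Reading goes through VariantAnnotation and
## Rsamtools; the phased-VCF and haplotagged-SAM writers are surgical
## line-level edits of the input text so that non-target records pass
## through byte-identical.

#' Read variant calls from one or more VCFs
#'
#' Merges the small/SV/tandem-repeat caller triad into one position-sorted
#' site list tagged by source. Duplicate (chrom, pos, ref, alt) records
#' across files are dropped preferring the small-variant file. Only
#' diploid genotypes are admitted, and by default only records with FILTER
#' PASS or '.'.
#'
#' @param paths character vector of VCF paths; names give the source class
#'   (\code{small}, \code{sv}, \code{tandem_repeat}); unnamed paths are
#'   \code{small}.
#' @param sample sample name (must be present in every file).
#' @param chrom optional chromosome filter.
#' @param passOnly drop non-PASS records (default TRUE).
#' @return a \linkS4class{VariantSet}.
#' @export
readVariantFiles <- function(paths, sample, chrom = NULL, passOnly = TRUE) {
  srcs <- names(paths) %||% rep("small", length(paths))
  srcs[!nzchar(srcs)] <- "small"
  stopifnot(all(srcs %in% VARIANT_SOURCES))
  ## small first so dedup prefers it
  ord <- order(match(srcs, VARIANT_SOURCES))
  parts <- lapply(ord, function(i) {
    v <- VariantAnnotation::readVcf(paths[i])
    if (!sample %in% colnames(v))
      stop("sample '", sample, "' not found in ", paths[i])
    rr <- SummarizedExperiment::rowRanges(v)
    gt <- VariantAnnotation::geno(v)$GT[, sample]
    filt <- as.character(rr$FILTER)
    keep <- if (passOnly) filt %in% c("PASS", ".") else rep(TRUE, length(v))
    m <- regmatches(gt, regexec("^([0-9]+)[/|]([0-9]+)$", gt))
    dip <- lengths(m) == 3L
    keep <- keep & dip
    if (!is.null(chrom)) keep <- keep & as.character(seqnames(rr)) %in% chrom
    keep <- which(keep)
    data.frame(
      chrom = as.character(seqnames(rr))[keep],
      pos = start(rr)[keep] - 1L,
      ref = as.character(rr$REF)[keep],
      alt = I(lapply(keep, function(j)
        as.character(rr$ALT[[j]]))),
      gt1 = vapply(m[keep], function(x) as.integer(x[2L]), 0L),
      gt2 = vapply(m[keep], function(x) as.integer(x[3L]), 0L),
      source = srcs[i])
  })
  all <- do.call(rbind, parts)
  key <- paste(all$chrom, all$pos, all$ref,
               vapply(all$alt, paste, "", collapse = ","), sep = "\r")
  all <- all[!duplicated(key), , drop = FALSE]
  VariantSet(chrom = all$chrom, pos = all$pos, ref = all$ref,
             alt = unclass(all$alt), gt1 = all$gt1, gt2 = all$gt2,
             source = all$source)
}

#' Read alignment records from SAM or BAM
#'
#' SAM input is converted with \code{Rsamtools::asBam} behind the scenes.
#' Unmapped and secondary records are dropped; supplementary records are
#' kept and flagged.
#'
#' @param path SAM or BAM path.
#' @param chrom optional chromosome filter.
#' @return data.frame: readName, chrom, start, end (0-based half-open),
#'   mapq, supplementary, cigar, seq, qual, sorted by start.
#' @export
readAlignments <- function(path, chrom = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    flag = flags)
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  df <- data.frame(
    readName = x$qname,
    chrom = as.character(x$rname),
    start = x$pos - 1L,
    end = x$pos - 1L +
      GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar),
    mapq = x$mapq,
    supplementary = bitwAnd(x$flag, 2048L) > 0L,
    cigar = x$cigar,
    seq = as.character(x$seq),
    qual = as.character(x$qual))
  if (!is.null(chrom)) df <- df[df$chrom %in% chrom, , drop = FALSE]
  df <- df[order(df$start, df$readName), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## map from (chrom,pos0,ref,alt-joined) to (h1, h2, ps) over solved
## multi-site blocks
phasedSiteMap <- function(sites, blocks) {
  keys <- character(0); h1 <- integer(0); h2 <- integer(0); ps <- integer(0)
  hetRowByIdx <- function(ch) {
    sel <- which(siteChrom(sites) == ch & isHet(sites))
    sel[order(siteIndex(sites)[sel])]
  }
  for (b in blocks) {
    if (!isSolved(b) || nSites(b) < 2L) next
    rows <- hetRowByIdx(b@chrom)[b@siteIndices]
    d <- b@diplotype
    keys <- c(keys, paste(siteChrom(sites)[rows], sitePos(sites)[rows],
                          siteRef(sites)[rows],
                          vapply(siteAlt(sites)[rows], paste, "",
                                 collapse = ","), sep = "\r"))
    h1 <- c(h1, d@h1)
    h2 <- c(h2, d@h2)
    ps <- c(ps, rep(b@phaseSet, nSites(b)))
  }
  data.frame(key = keys, h1 = h1, h2 = h2, ps = ps)
}

#' Write a phased VCF
#'
#' Rewrites the input VCF so that every heterozygous site inside a solved
#' multi-site block carries the phased genotype \code{h1|h2} and a PS
#' (phase set) FORMAT field equal to the block's phase set (the 1-based
#' position of its first site). Every other record -- homozygous sites,
#' sites in single-variant blocks, records that were never loaded --
#' passes through byte-identical; the record counts in and out are equal.
#' A \code{##FORMAT} PS header line is inserted if absent.
#'
#' @param inPath input VCF path (plain text).
#' @param sites the \linkS4class{VariantSet} read from the inputs.
#' @param blocks list of solved \linkS4class{PhaseBlock}s.
#' @param outPath output path.
#' @param sample sample whose genotypes are rewritten.
#' @return \code{outPath}, invisibly.
#' @export
writePhasedVcf <- function(inPath, sites, blocks, outPath, sample) {
  lines <- readLines(inPath)
  isHdr <- startsWith(lines, "#")
  cn <- lines[isHdr][sum(isHdr)]
  cols <- strsplit(cn, "\t", fixed = TRUE)[[1L]]
  sCol <- which(cols == sample)
  if (!length(sCol)) stop("sample '", sample, "' not found in ", inPath)
  hdr <- lines[isHdr]
  if (!any(grepl("^##FORMAT=<ID=PS[,>]", hdr))) {
    psLine <- "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">"
    hdr <- c(hdr[-length(hdr)], psLine, hdr[length(hdr)])
  }
  map <- phasedSiteMap(sites, blocks)
  body <- lines[!isHdr]
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    keys <- vapply(f, function(x)
      paste(x[1L], as.integer(x[2L]) - 1L, x[4L], x[5L], sep = "\r"), "")
    hit <- match(keys, map$key)
    for (i in which(!is.na(hit))) {
      x <- f[[i]]
      fmt <- strsplit(x[9L], ":", fixed = TRUE)[[1L]]
      smp <- strsplit(x[sCol], ":", fixed = TRUE)[[1L]]
      gtIx <- which(fmt == "GT")
      if (!length(gtIx)) next
      j <- hit[i]
      smp[gtIx] <- sprintf("%d|%d", map$h1[j], map$h2[j])
      psIx <- which(fmt == "PS")
      if (length(psIx)) {
        smp[psIx] <- as.character(map$ps[j])
      } else {
        fmt <- c(fmt, "PS")
        smp <- c(smp, as.character(map$ps[j]))
        x[9L] <- paste(fmt, collapse = ":")
      }
      x[sCol] <- paste(smp, collapse = ":")
      body[i] <- paste(x, collapse = "\t")
    }
  }
  writeLines(c(hdr, body), outPath)
  invisible(outPath)
}

#' Write haplotagged alignments
#'
#' Appends \code{HP:i:<1|2>} and \code{PC:i:<phase set>} tags to every
#' alignment record whose read name is in the tag map; all other records
#' (and all header lines) pass through unchanged, in order.
#'
#' @param inPath input SAM path (BAM is converted via
#'   \code{Rsamtools::asSam}).
#' @param tagMap data.frame with \code{readName}, \code{hap} (1 or 2) and
#'   \code{ps}, e.g. from \code{\link{haplotagAssign}}.
#' @param outPath output SAM path.
#' @return \code{outPath}, invisibly.
#' @export
writeHaplotaggedSam <- function(inPath, tagMap, outPath) {
  if (grepl("\\.bam$", inPath, ignore.case = TRUE))
    inPath <- Rsamtools::asSam(inPath, tempfile())
  lines <- readLines(inPath)
  rec <- !startsWith(lines, "@")
  if (any(rec) && nrow(tagMap)) {
    qn <- sub("\t.*", "", lines[rec])
    hit <- match(qn, tagMap$readName)
    sel <- !is.na(hit)
    lines[rec][sel] <- paste0(lines[rec][sel],
                              sprintf("\tHP:i:%d\tPC:i:%d",
                                      tagMap$hap[hit[sel]],
                                      tagMap$ps[hit[sel]]))
  }
  writeLines(lines, outPath)
  invisible(outPath)
}

#' Per-block statistics table
#'
#' One row per block: span, site counts by source, solving state and
#' cost. \code{writeBlockStats} renders it as TSV.
#'
#' @param blocks list of \linkS4class{PhaseBlock}s.
#' @param sites the \linkS4class{VariantSet}.
#' @return data.frame.
#' @export
blockStats <- function(blocks, sites) {
  rows <- lapply(blocks, function(b) {
    sel <- which(siteChrom(sites) == b@chrom & isHet(sites) &
                 siteIndex(sites) %in% b@siteIndices)
    srcs <- table(factor(siteSource(sites)[sel], VARIANT_SOURCES))
    data.frame(
      block_id = b@blockId, chrom = b@chrom,
      start = min(sitePos(sites)[sel]) + 1L,
      end = max(sitePos(sites)[sel] + nchar(siteRef(sites)[sel])),
      phase_set = b@phaseSet, n_sites = nSites(b),
      n_small = as.integer(srcs[["small"]]),
      n_sv = as.integer(srcs[["sv"]]),
      n_tandem_repeat = as.integer(srcs[["tandem_repeat"]]),
      solved = isSolved(b),
      cost = if (isSolved(b)) b@diplotype@cost else NA_integer_,
      mode = b@stats$mode %||% NA_character_,
      fallback = isTRUE(b@stats$fallback),
      expansions = b@stats$expansions %||% NA_integer_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(block_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      phase_set = integer(0), n_sites = integer(0),
                      n_small = integer(0), n_sv = integer(0),
                      n_tandem_repeat = integer(0), solved = logical(0),
                      cost = integer(0), mode = character(0),
                      fallback = logical(0), expansions = integer(0))
  out
}

#' @rdname blockStats
#' @param path output TSV path.
#' @return \code{writeBlockStats}: the path, invisibly.
#' @export
writeBlockStats <- function(blocks, sites, path) {
  utils::write.table(blockStats(blocks, sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Extracts phased heterozygous genotypes (GT with the \code{|}
#' separator) and their phase sets, e.g. to use a phased VCF as an
#' evaluation truth.
#'
#' @param path VCF path.
#' @param sample sample name.
#' @return data.frame: chrom, pos (0-based), ref, alt (comma-joined), h1,
#'   h2, ps (NA when no PS field).
#' @export
readPhasedHaplotypes <- function(path, sample) {
  v <- VariantAnnotation::readVcf(path)
  if (!sample %in% colnames(v)) stop("sample '", sample, "' not found")
  rr <- SummarizedExperiment::rowRanges(v)
  gt <- VariantAnnotation::geno(v)$GT[, sample]
  ps <- if ("PS" %in% names(VariantAnnotation::geno(v)))
    VariantAnnotation::geno(v)$PS[, sample] else rep(NA_integer_, length(gt))
  m <- regmatches(gt, regexec("^([0-9]+)\\|([0-9]+)$", gt))
  phased <- lengths(m) == 3L
  h1 <- vapply(m, function(x) if (length(x)) as.integer(x[2L]) else NA_integer_, 0L)
  h2 <- vapply(m, function(x) if (length(x)) as.integer(x[3L]) else NA_integer_, 0L)
  keep <- which(phased & h1 != h2)
  data.frame(
    chrom = as.character(seqnames(rr))[keep],
    pos = start(rr)[keep] - 1L,
    ref = as.character(rr$REF)[keep],
    alt = vapply(keep, function(j)
      paste(as.character(rr$ALT[[j]]), collapse = ","), ""),
    h1 = h1[keep], h2 = h2[keep],
    ps = as.integer(unlist(ps)[keep]))
}
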