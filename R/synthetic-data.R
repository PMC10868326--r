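## Seeded diploid simulator: a reference segment, variants of all three
## classes with truth haplotypes, and allele-level simulated reads that
## can be rendered to sequences, SAM and VCF. Everything downstream is
## testable against the known truth without external data.

#' TruthSet: a simulated diploid ground truth
#'
#' @slot chrom chromosome name.
#' @slot reference the reference sequence.
#' @slot sites a \linkS4class{VariantSet} (het and hom).
#' @slot truthH1,truthH2 integer allele per heterozygous site (indexed by
#'   \code{siteIndex}); they differ at every position.
#' @slot delIntervals two-column matrix (start, end; 0-based half-open) of
#'   homozygous-deletion spans across which read mappings split.
#' @export
setClass("TruthSet",
  representation(chrom = "character", reference = "character",
                 sites = "VariantSet", truthH1 = "integer",
                 truthH2 = "integer", delIntervals = "matrix")
)

setValidity("TruthSet", function(object) {
  nh <- sum(isHet(object@sites))
  if (length(object@truthH1) != nh || length(object@truthH2) != nh)
    return("truth haplotypes must cover every heterozygous site")
  if (any(object@truthH1 == object@truthH2))
    return("truth haplotypes must differ at every heterozygous site")
  TRUE
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet %s (%d bp): %d sites (%d het), %d hom-deletion gap(s)\n",
              object@chrom, nchar(object@reference), length(object@sites),
              sum(isHet(object@sites)), nrow(object@delIntervals)))
})

#' TruthSet accessors
#' @param x a \linkS4class{TruthSet}
#' @name truthAccessors
#' @export
truthVariants <- function(x) x@sites

#' @rdname truthAccessors
#' @export
truthReference <- function(x) x@reference

#' @rdname truthAccessors
#' @export
truthChrom <- function(x) x@chrom

#' @rdname truthAccessors
#' @export
truthHaplotypes <- function(x) cbind(h1 = x@truthH1, h2 = x@truthH2)

#' @rdname truthAccessors
#' @export
deletionIntervals <- function(x) x@delIntervals

#' SimulatedReadSet: allele-level simulated alignments
#'
#' One row of \code{records} per mapping record; split reads (crossing a
#' homozygous deletion) contribute a primary plus supplementary record
#' sharing \code{readName}. \code{observations} holds, per record, the
#' observed allele at each fully-overlapped site (after error injection),
#' keyed by row of the truth's \linkS4class{VariantSet}.
#'
#' @slot records data.frame: readName, chrom, start, end, mapq,
#'   supplementary, hap.
#' @slot observations list of data.frames (siteRow, allele).
#' @export
setClass("SimulatedReadSet",
  representation(records = "data.frame", observations = "list")
)

setMethod("show", "SimulatedReadSet", function(object) {
  cat(sprintf("SimulatedReadSet: %d records (%d supplementary) from %d reads\n",
              nrow(object@records), sum(object@records$supplementary),
              length(unique(object@records$readName))))
})

#' @describeIn SimulatedReadSet the alignment record table
#' @param x a SimulatedReadSet
#' @export
simRecords <- function(x) x@records

#' @rdname simRecords
#' @export
simObservations <- function(x) x@observations

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

otherBase <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Simulate a diploid truth set
#'
#' Generates a random reference of \code{refLength} bases carrying:
#' SNVs at per-base rate \code{snvRate} and short indels (1-6 bp) at rate
#' \code{indelRate} (two thirds heterozygous, one third homozygous-alt,
#' with a small fraction of multi-allelic 1/2 heterozygotes); exactly
#' \code{svCount} heterozygous structural variants (insertions or
#' deletions of 50-300 bp); exactly \code{trCount} heterozygous tandem
#' repeat sites (a planted motif whose two haplotypes carry different copy
#' numbers, sometimes both differing from the reference, i.e. 1/2
#' genotypes); and optionally homozygous deletions (\code{homDelSpans},
#' list of \code{c(start, length)}) whose crossing reads later split into
#' primary/supplementary pairs. Sites never overlap. Heterozygous alleles
#' are assigned to the two truth haplotypes at random. Fully deterministic
#' for a fixed seed.
#'
#' @param refLength reference length in bases (>= 10 kb when
#'   \code{svCount > 0}).
#' @param snvRate,indelRate per-base rates in \code{[0, 1]}.
#' @param svCount,trCount exact site counts.
#' @param seed RNG seed.
#' @param homDelSpans optional list of \code{c(start0, length)} homozygous
#'   deletions.
#' @param chrom chromosome name.
#' @return a \linkS4class{TruthSet}.
#' @examples
#' tr <- simulateTruth(20000, snvRate = 1e-3, indelRate = 0, svCount = 0,
#'                     trCount = 0, seed = 7)
#' tr
#' @export
simulateTruth <- function(refLength, snvRate = 1e-3, indelRate = 2e-4,
                          svCount = 2L, trCount = 5L, seed = 1L,
                          homDelSpans = NULL, chrom = "simA") {
  stopifnot(snvRate >= 0, snvRate <= 1, indelRate >= 0, indelRate <= 1,
            refLength > 200L)
  if (svCount > 0L && refLength < 10000L)
    stop("refLength must be >= 10 kb when svCount > 0")
  set.seed(seed)
  reference <- randSeq(refLength)

  occupied <- IRanges::IRanges()
  claim <- function(s, w, pad = 25L) {
    r <- IRanges::IRanges(start = max(1L, s + 1L - pad), width = w + 2L * pad)
    if (length(occupied) &&
        length(IRanges::findOverlaps(r, occupied)) > 0L) return(FALSE)
    occupied <<- c(occupied, r)
    TRUE
  }
  pick <- function(w) {
    for (try in 1:2000) {
      s <- sample.int(refLength - w - 600L, 1L) + 300L
      if (claim(s, w)) return(s)
    }
    stop("infeasible variant density: could not place a site")
  }

  pos <- integer(0); ref <- character(0); alt <- list()
  g1 <- integer(0); g2 <- integer(0); src <- character(0)
  th <- list()  # per emitted site: c(a1, a2) truth alleles (het) or NULL
  emit <- function(p, r, a, gt, source, truth = NULL) {
    pos[length(pos) + 1L] <<- p
    ref[length(ref) + 1L] <<- r
    alt[[length(alt) + 1L]] <<- a
    g1[length(g1) + 1L] <<- gt[1L]
    g2[length(g2) + 1L] <<- gt[2L]
    src[length(src) + 1L] <<- source
    th[[length(pos)]] <<- truth
  }
  hetTruth <- function(gt) sample(gt, 2L)  # random phase orientation

  ## homozygous deletions (explicit spans; alignment-splitting gaps)
  delIntervals <- matrix(integer(0), 0L, 2L,
                         dimnames = list(NULL, c("start", "end")))
  for (hd in homDelSpans %||% list()) {
    p <- as.integer(hd[1L]); L <- as.integer(hd[2L])
    if (!claim(p, L + 1L)) stop("homozygous deletion overlaps another site")
    r <- substr(reference, p + 1L, p + L + 1L)
    emit(p, r, substr(r, 1L, 1L), c(1L, 1L), "sv")
    delIntervals <- rbind(delIntervals, c(p + 1L, p + 1L + L))
  }

  ## heterozygous structural variants (|len(alt) - len(ref)| >= 50)
  for (i in seq_len(svCount)) {
    L <- sample(50:300, 1L)
    if (runif(1) < 0.5) {            # deletion
      p <- pick(L + 1L)
      r <- substr(reference, p + 1L, p + L + 1L)
      emit(p, r, substr(r, 1L, 1L), c(0L, 1L), "sv", hetTruth(0:1))
    } else {                          # insertion
      p <- pick(1L)
      r <- substr(reference, p + 1L, p + 1L)
      emit(p, r, paste0(r, randSeq(L)), c(0L, 1L), "sv", hetTruth(0:1))
    }
  }

  ## tandem repeats: plant motif^r in the reference, haplotypes carry
  ## different copy numbers
  for (i in seq_len(trCount)) {
    mlen <- sample(2:4, 1L)
    motif <- randSeq(mlen)
    rcop <- sample(8:14, 1L)
    w <- mlen * rcop
    p <- pick(w)
    substr(reference, p + 1L, p + w) <- strrep(motif, rcop)
    cops <- rcop + sample(c(-3:-1, 1:3), 2L)
    r <- strrep(motif, rcop)
    altCops <- setdiff(unique(cops), rcop)
    a <- vapply(altCops, function(cc) strrep(motif, cc), "")
    gt <- match(cops, altCops, nomatch = 0L)  # 0 where cop == rcop
    emit(p, r, a, sort(gt), "tandem_repeat", hetTruth(gt))
  }

  ## SNVs and short indels
  scatter <- function(rate, maker) {
    if (rate <= 0) return(invisible())
    hits <- which(runif(refLength - 600L) < rate) + 300L
    for (p in hits) maker(p)
  }
  genoDraw <- function(k) {
    if (runif(1) < 2 / 3) {
      if (k >= 2L && runif(1) < 0.05) c(1L, 2L) else c(0L, 1L)
    } else c(1L, 1L)
  }
  scatter(snvRate, function(p) {
    multi <- runif(1) < 0.02
    rb <- substr(reference, p + 1L, p + 1L)
    a <- if (multi) sample(setdiff(c("A", "C", "G", "T"), rb), 2L)
         else otherBase(rb)
    gt <- genoDraw(length(a))
    if (multi) gt <- c(1L, 2L)
    if (!claim(p, 1L, pad = 3L)) return(invisible())
    emit(p, rb, a, gt, "small",
         if (gt[1L] != gt[2L]) hetTruth(gt) else NULL)
  })
  scatter(indelRate, function(p) {
    L <- sample(1:6, 1L)
    del <- runif(1) < 0.5
    if (del) {
      if (!claim(p, L + 1L)) return(invisible())
      r <- substr(reference, p + 1L, p + L + 1L)
      a <- substr(r, 1L, 1L)
    } else {
      if (!claim(p, 1L)) return(invisible())
      r <- substr(reference, p + 1L, p + 1L)
      a <- paste0(r, randSeq(L))
    }
    gt <- genoDraw(1L)
    gt[gt > 1L] <- 1L
    emit(p, r, a, gt, "small",
         if (gt[1L] != gt[2L]) hetTruth(gt) else NULL)
  })

  vs <- VariantSet(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   gt1 = g1, gt2 = g2, source = src)
  ## map truth alleles onto the sorted het ordering
  nh <- sum(isHet(vs))
  th1 <- integer(nh); th2 <- integer(nh)
  hetSel <- which(isHet(vs))
  orig <- match(sitePos(vs)[hetSel], pos)
  for (i in seq_along(hetSel)) {
    tt <- th[[orig[i]]]
    th1[siteIndex(vs)[hetSel[i]]] <- tt[1L]
    th2[siteIndex(vs)[hetSel[i]]] <- tt[2L]
  }
  new("TruthSet", chrom = chrom, reference = reference, sites = vs,
      truthH1 = th1, truthH2 = th2, delIntervals = delIntervals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate reads from a diploid truth
#'
#' Draws a Poisson number of reads (expectation
#' \code{coverage * refLength / readLength}), each from one truth
#' haplotype with a uniform start and fixed reference-span length. The
#' observed allele at every fully-overlapped site is the source
#' haplotype's allele, corrupted to a different allele with probability
#' \code{alleleErrorRate}. Reads crossing a homozygous deletion are
#' emitted as a primary plus supplementary record pair sharing the read
#' name, split at the deletion -- emulating the alignment breaks that the
#' supplementary-bridge logic in block generation repairs. Read ends are
#' nudged off partially-overlapped multi-base sites so every rendered
#' base is well-defined.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param coverage mean depth (> 0).
#' @param readLength reference span per read (>= 1 kb).
#' @param alleleErrorRate per-observation corruption probability.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulatedReadSet}.
#' @export
simulateReads <- function(truth, coverage = 30, readLength = 3000L,
                          alleleErrorRate = 0, seed = 1L) {
  stopifnot(coverage > 0, readLength >= 1000L)
  refLen <- nchar(truth@reference)
  stopifnot(refLen > readLength)
  set.seed(seed + 1000003L)
  n <- rpois(1L, coverage * refLen / readLength)
  vs <- truth@sites
  pos <- sitePos(vs)
  spanEnd <- pos + nchar(siteRef(vs))
  wide <- which(nchar(siteRef(vs)) > 1L)
  k <- lengths(siteAlt(vs))
  dels <- truth@delIntervals
  if (nrow(dels) > 1L) dels <- dels[order(dels[, 1L]), , drop = FALSE]

  recs <- list(); obs <- list()
  for (i in seq_len(n)) {
    hap <- sample(1:2, 1L)
    s <- sample.int(refLen - readLength, 1L) - 1L
    ## a start inside a deletion gap has no sample sequence there
    for (d in seq_len(nrow(dels)))
      if (s >= dels[d, 1L] && s < dels[d, 2L]) s <- dels[d, 2L]
    ## the read holds readLength bases of sample sequence: its reference
    ## span grows by every homozygous-deletion gap it crosses
    e <- s + readLength
    for (d in seq_len(nrow(dels))) {   # dels are position-sorted
      if (dels[d, 1L] >= s && dels[d, 1L] < e)
        e <- min(e + (dels[d, 2L] - dels[d, 1L]), refLen)
    }
    ## an end inside a gap truncates to the gap start
    for (d in seq_len(nrow(dels)))
      if (e > dels[d, 1L] && e <= dels[d, 2L]) e <- dels[d, 1L]
    ## move ends off partially-overlapped multi-base sites
    for (r in wide) {
      if (pos[r] < s && s < spanEnd[r]) s <- spanEnd[r]
      if (pos[r] < e && e < spanEnd[r]) e <- pos[r]
    }
    if (e - s < 200L) next
    ## split at contained homozygous deletions
    segs <- matrix(c(s, e), 1L)
    for (d in seq_len(nrow(dels))) {
      d0 <- dels[d, 1L]; d1 <- dels[d, 2L]
      out <- matrix(integer(0), 0L, 2L)
      for (g in seq_len(nrow(segs))) {
        a <- segs[g, 1L]; b <- segs[g, 2L]
        if (a < d0 && d1 < b) out <- rbind(out, c(a, d0), c(d1, b))
        else out <- rbind(out, c(a, b))
      }
      segs <- out
    }
    nm <- sprintf("read%06d", i)
    for (g in seq_len(nrow(segs))) {
      a <- segs[g, 1L]; b <- segs[g, 2L]
      inside <- which(pos >= a & spanEnd <= b)
      allele <- integer(length(inside))
      for (jj in seq_along(inside)) {
        r <- inside[jj]
        aTrue <- if (isHet(vs)[r]) {
          if (hap == 1L) truth@truthH1[siteIndex(vs)[r]]
          else truth@truthH2[siteIndex(vs)[r]]
        } else vs@gt1[r]
        if (alleleErrorRate > 0 && runif(1) < alleleErrorRate) {
          cands <- setdiff(0:k[r], aTrue)
          aTrue <- cands[sample.int(length(cands), 1L)]
        }
        allele[jj] <- aTrue
      }
      recs[[length(recs) + 1L]] <- data.frame(
        readName = nm, chrom = truth@chrom, start = a, end = b,
        mapq = 60L, supplementary = (g > 1L), hap = hap)
      obs[[length(obs) + 1L]] <- data.frame(siteRow = inside, allele = allele)
    }
  }
  if (!length(recs)) stop("no reads simulated; increase coverage")
  records <- do.call(rbind, recs)
  o <- order(records$start, records$readName, records$supplementary)
  new("SimulatedReadSet", records = records[o, , drop = FALSE],
      observations = obs[o])
}

## render one record's sequence and CIGAR from its observed alleles
renderRecord <- function(truth, rec, ob) {
  vs <- truth@sites
  pos <- sitePos(vs); refA <- siteRef(vs)
  segStart <- rec$start
  pieces <- character(0)
  ops <- character(0); lens <- integer(0)
  addOp <- function(op, L) {
    if (L <= 0L) return(invisible())
    nn <- length(ops)
    if (nn && ops[nn] == op) lens[nn] <<- lens[nn] + L
    else { ops[nn + 1L] <<- op; lens[nn + 1L] <<- L }
  }
  cursor <- rec$start
  if (nrow(ob)) ob <- ob[order(pos[ob$siteRow]), , drop = FALSE]
  for (j in seq_len(nrow(ob))) {
    r <- ob$siteRow[j]
    if (pos[r] > cursor) {
      pieces <- c(pieces, substr(truth@reference, cursor + 1L, pos[r]))
      addOp("M", pos[r] - cursor)
    }
    aseq <- alleleSeq(vs, r, ob$allele[j])
    lr <- nchar(refA[r]); la <- nchar(aseq)
    pieces <- c(pieces, aseq)
    p <- min(lr, la)
    addOp("M", p)
    if (la > lr) addOp("I", la - lr) else if (lr > la) addOp("D", lr - la)
    cursor <- pos[r] + lr
  }
  if (cursor < rec$end) {
    pieces <- c(pieces, substr(truth@reference, cursor + 1L, rec$end))
    addOp("M", rec$end - cursor)
  }
  list(seq = paste(pieces, collapse = ""),
       cigar = paste0(lens, ops, collapse = ""))
}

#' Render simulated records to sequences
#'
#' Turns allele-level simulated records into sequence-level alignment
#' records (seq, cigar, qual) against the truth reference. Split reads
#' get soft-clipped primary/supplementary CIGARs over the full read
#' sequence. Base qualities are a constant Q30.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param sim a \linkS4class{SimulatedReadSet}.
#' @return data.frame: the record table plus \code{seq}, \code{cigar},
#'   \code{qual}.
#' @export
renderReads <- function(truth, sim) {
  recs <- sim@records
  rendered <- lapply(seq_len(nrow(recs)), function(i)
    renderRecord(truth, as.list(recs[i, ]), sim@observations[[i]]))
  seqs <- vapply(rendered, `[[`, "", "seq")
  cigs <- vapply(rendered, `[[`, "", "cigar")
  ## assemble split reads: full sequence with soft clips on each record
  out <- recs
  out$seq <- seqs; out$cigar <- cigs
  for (nm in unique(recs$readName[recs$supplementary])) {
    ix <- which(recs$readName == nm)
    ix <- ix[order(recs$start[ix])]
    lens <- nchar(seqs[ix])
    full <- paste(seqs[ix], collapse = "")
    for (jj in seq_along(ix)) {
      before <- sum(lens[seq_len(jj - 1L)])
      after <- sum(lens) - before - lens[jj]
      out$seq[ix[jj]] <- full
      out$cigar[ix[jj]] <- paste0(
        if (before) paste0(before, "S") else "",
        cigs[ix[jj]],
        if (after) paste0(after, "S") else "")
    }
  }
  out$qual <- strrep("?", nchar(out$seq))
  out
}

#' Write simulated alignments as SAM
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param sim a \linkS4class{SimulatedReadSet}.
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
writeSimulatedSam <- function(truth, sim, path) {
  r <- renderReads(truth, sim)
  r <- r[order(r$start, r$readName, r$supplementary), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", truth@chrom, nchar(truth@reference)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  r$readName, ifelse(r$supplementary, 2048L, 0L), r$chrom,
                  r$start + 1L, r$mapq, r$cigar, r$seq, r$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the truth reference as FASTA
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param path output FASTA path (an .fai index is written alongside).
#' @return the path, invisibly.
#' @export
writeSimulatedReference <- function(truth, path) {
  x <- Biostrings::DNAStringSet(setNames(truth@reference, truth@chrom))
  Biostrings::writeXStringSet(x, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Write truth variants as VCF
#'
#' One file per variant class mirrors the usual small/SV/tandem-repeat
#' caller triad; \code{phased = TRUE} writes truth-phased genotypes
#' (\code{h1|h2} with a per-chromosome PS) for use as an evaluation
#' truth.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param path output VCF path.
#' @param source variant classes to include.
#' @param phased write truth-phased genotypes.
#' @param sample sample name.
#' @return the path, invisibly.
#' @export
writeTruthVcf <- function(truth, path,
                          source = c("small", "sv", "tandem_repeat"),
                          phased = FALSE, sample = "SAMPLE") {
  vs <- truth@sites
  sel <- which(siteSource(vs) %in% source)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", truth@chrom,
                   nchar(truth@reference)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (phased)
             "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  lines <- character(length(sel))
  hetSel <- isHet(vs)[sel]
  ps <- if (any(hetSel)) min(sitePos(vs)[sel][hetSel]) + 1L else NA_integer_
  for (i in seq_along(sel)) {
    r <- sel[i]
    altStr <- paste(siteAlt(vs)[[r]], collapse = ",")
    if (phased && isHet(vs)[r]) {
      gt <- sprintf("%d|%d", truth@truthH1[siteIndex(vs)[r]],
                    truth@truthH2[siteIndex(vs)[r]])
      fmt <- "GT:PS"
      smp <- sprintf("%s:%d", gt, ps)
    } else {
      sep <- if (phased) "|" else "/"
      fmt <- "GT"
      smp <- sprintf("%d%s%d", vs@gt1[r], sep, vs@gt2[r])
    }
    lines[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
                        truth@chrom, sitePos(vs)[r] + 1L, siteRef(vs)[r],
                        altStr, fmt, smp)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @describeIn writeTruthVcf write the small/SV/tandem-repeat VCF triad
#'   plus reference and return the paths.
#' @param prefix output path prefix.
#' @export
writeTruthInputs <- function(truth, prefix, sample = "SAMPLE") {
  paths <- c(small = paste0(prefix, ".small.vcf"),
             sv = paste0(prefix, ".sv.vcf"),
             tandem_repeat = paste0(prefix, ".tr.vcf"),
             reference = paste0(prefix, ".fa"))
  writeTruthVcf(truth, paths[["small"]], source = "small", sample = sample)
  writeTruthVcf(truth, paths[["sv"]], source = "sv", sample = sample)
  writeTruthVcf(truth, paths[["tandem_repeat"]], source = "tandem_repeat",
                sample = sample)
  writeSimulatedReference(truth, paths[["reference"]])
  paths
}
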