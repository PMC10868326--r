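## Allele assignment: converting read mappings into condensed per-site
## allele observations, by windowed local re-alignment or by exact global
## re-alignment against an alt-aware variant graph.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

dnaCodes <- function(s) {
  v <- BASE_CODES[strsplit(toupper(s), "", fixed = TRUE)[[1L]]]
  v[is.na(v)] <- 5L
  unname(v)
}

#' VariantGraph: an alt-aware reference graph over a locus
#'
#' A DAG over a reference segment with, at each variant site (or merged
#' cluster of overlapping sites), one branch per allele (including the
#' reference allele). Every source-to-sink path spells one consistent
#' local haplotype; the all-reference path spells the reference segment.
#' Overlapping site definitions are merged into a single branch set that
#' enumerates the joint allele combinations whose replacements do not
#' physically collide.
#'
#' Nodes are single characters (plus epsilon junction nodes) held in
#' flattened topological order for the compiled alignment kernel.
#'
#' @slot chrom chromosome of the locus.
#' @slot refStart 0-based start of the spanned reference segment.
#' @slot refSeq the reference segment.
#' @slot sites the \linkS4class{VariantSet} rows inside the segment
#'   (heterozygous and homozygous; homozygous sites are context).
#' @slot hetIndex the original (chromosome-wide) heterozygous site index
#'   of each included row, NA for homozygous rows. Subsetting a
#'   VariantSet renumbers its indices, so the graph keeps the originals.
#' @slot nodeChar,predPtr,predIdx flattened DAG (0-based ids for the
#'   kernel).
#' @slot clusters per-cluster branch tables: \code{branchEnd} (0-based end
#'   node per branch), \code{choice} (branch x site allele matrix),
#'   \code{siteRow} (rows of \code{sites} in the cluster).
#' @export
setClass("VariantGraph",
  representation(chrom = "character", refStart = "integer", refSeq = "character",
                 sites = "VariantSet", hetIndex = "integer",
                 nodeChar = "integer",
                 predPtr = "integer", predIdx = "integer", clusters = "list")
)

setMethod("show", "VariantGraph", function(object) {
  cat(sprintf("VariantGraph %s:[%d,%d): %d sites in %d branch set(s), %d nodes\n",
              object@chrom, object@refStart,
              object@refStart + nchar(object@refSeq),
              length(object@sites), length(object@clusters),
              length(object@nodeChar)))
})

#' Number of DP nodes in a variant graph
#' @param graph a \linkS4class{VariantGraph}
#' @export
graphNodes <- function(graph) length(graph@nodeChar)

## apply replacements (0-based starts rel. to seg) right-to-left
applyAlleles <- function(seg, starts, widths, repls) {
  o <- order(starts, decreasing = TRUE)
  for (i in o) {
    seg <- paste0(substr(seg, 1L, starts[i]),
                  repls[i],
                  substr(seg, starts[i] + widths[i] + 1L, nchar(seg)))
  }
  seg
}

#' Build an alt-aware variant graph
#'
#' @param reference the full chromosome sequence (character or
#'   \code{DNAString}).
#' @param sites a \linkS4class{VariantSet}; rows whose span lies inside
#'   \code{[segStart, segEnd)} are included (het and hom alike).
#' @param chrom chromosome of the locus.
#' @param segStart,segEnd 0-based half-open segment to span.
#' @param maxCombos cap on joint allele combinations per merged cluster;
#'   above it, enumeration is restricted to the alleles of the called
#'   genotypes (plus reference).
#' @return a \linkS4class{VariantGraph}.
#' @export
buildVariantGraph <- function(reference, sites, chrom, segStart, segEnd,
                              maxCombos = 256L) {
  reference <- as.character(reference)
  segStart <- max(0L, as.integer(segStart))
  segEnd <- min(nchar(reference), as.integer(segEnd))
  stopifnot(segEnd > segStart)
  refSeq <- substr(reference, segStart + 1L, segEnd)

  inSeg <- which(siteChrom(sites) == chrom &
                 sitePos(sites) >= segStart &
                 sitePos(sites) + nchar(siteRef(sites)) <= segEnd)
  hetIndex <- siteIndex(sites)[inSeg]
  sub <- sites[inSeg]
  ## ref alleles must spell the reference at their position
  if (length(sub)) {
    spelled <- substring(refSeq, sitePos(sub) - segStart + 1L,
                         sitePos(sub) - segStart + nchar(siteRef(sub)))
    if (any(spelled != siteRef(sub)))
      stop("reference allele inconsistent with reference sequence")
  }

  ## merge overlapping site spans into clusters
  relStart <- sitePos(sub) - segStart
  relWidth <- nchar(siteRef(sub))
  clusters <- list()
  if (length(sub)) {
    rng <- IRanges::IRanges(start = relStart + 1L, width = pmax(relWidth, 1L))
    red <- IRanges::reduce(rng)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(rng, red))
    clusters <- lapply(seq_along(red), function(g) which(grp == g))
  }

  ## chunk-appended node store (per-segment, not per-character)
  chunkChar <- list(); chunkPredLen <- list(); chunkPredVal <- list()
  nNodes <- 0L
  nChunks <- 0L
  addChain <- function(s, predv) {
    codes <- if (is.character(s)) {
      if (nchar(s)) dnaCodes(s) else 0L     # empty branch -> epsilon
    } else s                                 # 0L = explicit epsilon node
    k <- length(codes)
    ids <- nNodes + seq_len(k)
    nChunks <<- nChunks + 1L
    chunkChar[[nChunks]] <<- codes
    chunkPredLen[[nChunks]] <<- c(length(predv), rep(1L, k - 1L))
    chunkPredVal[[nChunks]] <<- c(as.integer(predv), ids[-k])
    nNodes <<- nNodes + k
    ids[k]
  }
  addNode <- function(ch, predv) addChain(ch, predv)

  src <- addNode(0L, integer(0))
  frontier <- src
  cursor <- 0L   # position in refSeq (0-based)
  clusterInfo <- list()

  for (ci in seq_along(clusters)) {
    rows <- clusters[[ci]]
    cs <- min(relStart[rows])
    ce <- max(relStart[rows] + relWidth[rows])
    if (cs > cursor)
      frontier <- addChain(substr(refSeq, cursor + 1L, cs), frontier)
    entry <- addNode(0L, frontier)
    ## enumerate joint combinations
    kk <- lengths(siteAlt(sub))[rows]
    alleleLists <- lapply(seq_along(rows), function(i) 0:kk[i])
    combos <- as.matrix(rev(expand.grid(rev(alleleLists))))
    if (nrow(combos) > maxCombos) {
      gtm <- siteGenotype(sub)[rows, , drop = FALSE]
      alleleLists <- lapply(seq_along(rows), function(i)
        sort(unique(c(0L, gtm[i, ]))))
      combos <- as.matrix(rev(expand.grid(rev(alleleLists))))
    }
    colnames(combos) <- NULL
    ## drop combinations whose non-reference replacements collide
    keep <- apply(combos, 1L, function(a) {
      nz <- which(a > 0L)
      if (length(nz) < 2L) return(TRUE)
      st <- relStart[rows][nz]
      en <- st + relWidth[rows][nz]
      o <- order(st)
      all(st[o][-1L] >= en[o][-length(o)])
    })
    combos <- combos[keep, , drop = FALSE]
    clSeg <- substr(refSeq, cs + 1L, ce)
    ends <- integer(nrow(combos))
    for (b in seq_len(nrow(combos))) {
      a <- combos[b, ]
      nz <- which(a > 0L)
      bseq <- applyAlleles(clSeg, relStart[rows][nz] - cs,
                           relWidth[rows][nz],
                           vapply(nz, function(i)
                             siteAlt(sub)[[rows[i]]][a[i]], ""))
      ends[b] <- addChain(bseq, entry)
    }
    frontier <- addNode(0L, ends)
    clusterInfo[[ci]] <- list(branchEnd = ends - 1L, choice = combos,
                              siteRow = rows)
    cursor <- ce
  }
  if (cursor < nchar(refSeq))
    frontier <- addChain(substr(refSeq, cursor + 1L, nchar(refSeq)), frontier)

  predPtr <- c(0L, cumsum(unlist(chunkPredLen, use.names = FALSE)))
  new("VariantGraph", chrom = chrom, refStart = segStart, refSeq = refSeq,
      sites = sub, hetIndex = hetIndex,
      nodeChar = unlist(chunkChar, use.names = FALSE),
      predPtr = as.integer(predPtr),
      predIdx = as.integer(unlist(chunkPredVal, use.names = FALSE) - 1L),
      clusters = clusterInfo)
}

#' Enumerate all haplotype paths of a variant graph
#'
#' Spells every source-to-sink path together with its per-site allele
#' choices. Intended for oracle tests on small graphs; refuses more than
#' \code{maxPaths} paths.
#'
#' @param graph a \linkS4class{VariantGraph}.
#' @param maxPaths enumeration guard.
#' @return data.frame with columns \code{seq} and one \code{site<i>}
#'   allele column per site (NA where a joint combination omits a site --
#'   never the case after construction).
#' @export
enumerateGraphPaths <- function(graph, maxPaths = 4096L) {
  cl <- graph@clusters
  nPaths <- prod(vapply(cl, function(c) nrow(c$choice), 0))
  if (length(cl) && nPaths > maxPaths) stop("too many paths to enumerate")
  sub <- graph@sites
  relStart <- sitePos(sub) - graph@refStart
  relWidth <- nchar(siteRef(sub))
  idx <- if (length(cl)) expand.grid(lapply(cl, function(c) seq_len(nrow(c$choice))))
         else data.frame(row.names = 1L)
  out <- vector("list", max(1L, nrow(idx)))
  alleles <- matrix(NA_integer_, max(1L, nrow(idx)), length(sub))
  for (p in seq_len(max(1L, nrow(idx)))) {
    seq <- graph@refSeq
    starts <- integer(0); widths <- integer(0); repls <- character(0)
    for (ci in seq_along(cl)) {
      a <- cl[[ci]]$choice[idx[p, ci], ]
      rows <- cl[[ci]]$siteRow
      alleles[p, rows] <- a
      nz <- which(a > 0L)
      for (i in nz) {
        starts <- c(starts, relStart[rows[i]])
        widths <- c(widths, relWidth[rows[i]])
        repls <- c(repls, siteAlt(sub)[[rows[i]]][a[i]])
      }
    }
    out[[p]] <- applyAlleles(seq, starts, widths, repls)
  }
  res <- data.frame(seq = unlist(out), stringsAsFactors = FALSE)
  if (length(sub))
    for (i in seq_along(sub)) res[[paste0("site", i)]] <- alleles[, i]
  res
}

#' Optimal edit cost of a read against a variant graph
#'
#' The minimum fitting-alignment edit cost (read aligned end-to-end,
#' leading/trailing graph characters free) over all haplotype paths.
#'
#' @param read query sequence (character).
#' @param graph a \linkS4class{VariantGraph}.
#' @return non-negative integer edit cost.
#' @export
graphAlignCost <- function(read, graph) {
  res <- graph_align_cpp(graph@nodeChar, graph@predPtr, graph@predIdx,
                         dnaCodes(read), integer(0))
  as.integer(res$cost)
}

#' Globally re-align a mapping against a variant graph
#'
#' Computes the exact minimum-edit-cost fitting alignment of the read
#' sequence against the graph. The optimal path's branch choices give the
#' allele at each site; the observation weight is the margin
#' \code{cost(best path forced through the other allele) - cost(best
#' path)}, capped. A zero margin is reported as ambiguous. Sites whose
#' span is not fully contained in the mapping's reference span are
#' unknown. If the best alignment cost exceeds
#' \code{maxCostPerBase * read length} the mapping is likely mismapped and
#' every site is reported unknown.
#'
#' @param mapping a list/row with \code{start}, \code{end} (0-based
#'   half-open reference span) and \code{seq} (query sequence).
#' @param graph a \linkS4class{VariantGraph} covering the mapping.
#' @param cap weight cap (default 60).
#' @param maxCostPerBase mismap ceiling (default 0.3).
#' @return data.frame with one row per heterozygous graph site:
#'   \code{site} (global heterozygous site index), \code{allele},
#'   \code{weight}.
#' @export
assignGlobal <- function(mapping, graph, cap = WEIGHT_CAP,
                         maxCostPerBase = 0.3) {
  sub <- graph@sites
  hetRows <- which(isHet(sub))
  empty <- data.frame(site = integer(0), allele = integer(0),
                      weight = integer(0))
  if (!length(hetRows)) return(empty)
  siteIdxs <- graph@hetIndex[hetRows]
  unknown <- data.frame(site = siteIdxs, allele = UNKNOWN_ALLELE,
                        weight = 0L)
  if (is.null(mapping$seq) || is.na(mapping$seq) || !nzchar(mapping$seq))
    return(unknown)

  branchEnds <- unlist(lapply(graph@clusters, `[[`, "branchEnd"))
  res <- graph_align_cpp(graph@nodeChar, graph@predPtr, graph@predIdx,
                         dnaCodes(mapping$seq), as.integer(branchEnds))
  if (res$cost > maxCostPerBase * nchar(mapping$seq)) return(unknown)

  ## forced cost per (cluster, branch) -> per (site, allele)
  offs <- c(0L, cumsum(vapply(graph@clusters, function(c) length(c$branchEnd), 0L)))
  pos <- sitePos(sub)
  wid <- nchar(siteRef(sub))
  out <- unknown
  for (ci in seq_along(graph@clusters)) {
    cl <- graph@clusters[[ci]]
    forced <- res$forced[(offs[ci] + 1L):offs[ci + 1L]]
    for (i in seq_along(cl$siteRow)) {
      r <- cl$siteRow[i]
      if (!(r %in% hetRows)) next
      if (pos[r] < mapping$start || pos[r] + wid[r] > mapping$end) next
      k <- length(siteAlt(sub)[[r]])
      fc <- vapply(0:k, function(a) {
        sel <- cl$choice[, i] == a
        if (!any(sel)) return(NA_integer_)
        min(forced[sel])
      }, 0L)
      ok <- which(!is.na(fc))
      if (!length(ok)) next
      o <- ok[order(fc[ok])]
      row <- which(out$site == graph@hetIndex[r])
      if (length(o) == 1L || fc[o[2L]] > fc[o[1L]]) {
        margin <- if (length(o) == 1L) cap else fc[o[2L]] - fc[o[1L]]
        if (margin == 0L) {
          out$allele[row] <- AMBIGUOUS_ALLELE
        } else {
          out$allele[row] <- o[1L] - 1L
          out$weight[row] <- min(as.integer(cap), as.integer(margin))
        }
      } else {
        out$allele[row] <- AMBIGUOUS_ALLELE
      }
    }
  }
  out
}

## ref window [refA, refB) -> query window [qa, qb), 0-based, via CIGAR
projectWindow <- function(cigar, mapStart, refA, refB) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  refPos <- mapStart
  qPos <- 0L
  qa <- NA_integer_
  qb <- NA_integer_
  for (i in seq_along(ops)) {
    op <- ops[i]; L <- lens[i]
    consumesQ <- op %in% c("M", "=", "X", "I", "S")
    consumesR <- op %in% c("M", "=", "X", "D", "N")
    if (consumesR) {
      if (is.na(qa) && refPos + L > refA)
        qa <- if (consumesQ) qPos + max(0L, refA - refPos) else qPos
      if (refPos + L >= refB) {
        qb <- if (consumesQ) qPos + (refB - refPos) else qPos
        return(c(qa, qb))
      }
      refPos <- refPos + L
    }
    if (consumesQ) qPos <- qPos + L
  }
  c(qa, if (is.na(qb)) qPos else qb)
}

#' Locally re-align a mapping around each variant site
#'
#' For each heterozygous site fully contained in the mapping span, the
#' query subsequence projected onto a window of \code{windowPad} bases
#' around the site is scored by edit distance against each allele's
#' windowed sequence. The closest allele wins; an exact tie is ambiguous.
#' The weight is the minimum base quality over the query window (a
#' constant 30 when qualities are absent), capped.
#'
#' @param mapping list/row with \code{start}, \code{end}, \code{cigar},
#'   \code{seq} and optionally \code{qual}.
#' @param sites a \linkS4class{VariantSet} (the block's sites; homozygous
#'   rows are ignored).
#' @param reference full chromosome sequence (character or
#'   \code{DNAString}).
#' @param chrom chromosome of the mapping.
#' @param windowPad bases of context on each side (default 25).
#' @param cap weight cap (default 60).
#' @return data.frame (\code{site}, \code{allele}, \code{weight}) as in
#'   \code{\link{assignGlobal}}.
#' @export
assignLocal <- function(mapping, sites, reference, chrom,
                        windowPad = 25L, cap = WEIGHT_CAP) {
  reference <- as.character(reference)
  hetRows <- which(siteChrom(sites) == chrom & isHet(sites) &
                   sitePos(sites) >= mapping$start &
                   sitePos(sites) + nchar(siteRef(sites)) <= mapping$end)
  out <- data.frame(site = siteIndex(sites)[hetRows],
                    allele = rep(UNKNOWN_ALLELE, length(hetRows)),
                    weight = rep(0L, length(hetRows)))
  if (!length(hetRows)) return(out)
  badInput <- is.null(mapping$seq) || is.na(mapping$seq) ||
    !nzchar(mapping$seq) || is.null(mapping$cigar) || is.na(mapping$cigar)
  if (badInput) return(out)
  quals <- if (!is.null(mapping$qual) && !is.na(mapping$qual) &&
               nzchar(mapping$qual) && mapping$qual != "*")
    utf8ToInt(mapping$qual) - 33L else NULL
  for (i in seq_along(hetRows)) {
    r <- hetRows[i]
    pos <- sitePos(sites)[r]
    refAll <- siteRef(sites)[r]
    wA <- max(mapping$start, pos - windowPad)
    wB <- min(mapping$end, pos + nchar(refAll) + windowPad, nchar(reference))
    q <- projectWindow(mapping$cigar, mapping$start, wA, wB)
    if (anyNA(q) || q[2L] <= q[1L]) next
    querySub <- substr(mapping$seq, q[1L] + 1L, q[2L])
    alleles <- c(refAll, siteAlt(sites)[[r]])
    cands <- vapply(alleles, function(a)
      paste0(substr(reference, wA + 1L, pos),
             a,
             substr(reference, pos + nchar(refAll) + 1L, wB)), "")
    d <- as.integer(adist(querySub, cands))
    best <- which(d == min(d))
    if (length(best) > 1L) {
      out$allele[i] <- AMBIGUOUS_ALLELE
    } else {
      out$allele[i] <- best - 1L
      w <- if (is.null(quals)) 30L
           else min(quals[(q[1L] + 1L):q[2L]])
      out$weight[i] <- max(1L, min(as.integer(cap), as.integer(w)))
    }
  }
  out
}

#' Assign alleles for every mapping of a block
#'
#' Runs allele assignment in one of three modes. \code{global} builds a
#' per-mapping variant graph and re-aligns exactly; \code{local} uses the
#' windowed method; \code{dual} runs global unless the block's cumulative
#' alignment work (graph nodes x read length, summed in DP cells -- a
#' deterministic, machine-independent proxy for run time) exceeds
#' \code{budget}, in which case the whole block falls back to local and is
#' flagged. The fallback decision is always per-block, never per-read.
#'
#' @param mappings data.frame of alignment records (see
#'   \code{\link{readAlignments}}) overlapping the block.
#' @param sites the chromosome's \linkS4class{VariantSet}.
#' @param reference full chromosome sequence.
#' @param chrom chromosome name.
#' @param mode one of \code{"dual"}, \code{"global"}, \code{"local"}.
#' @param budget DP-cell budget for dual mode (default 1e9).
#' @param windowPad local window pad / graph pad (default 25).
#' @param cap weight cap.
#' @return list with \code{observations} (one data.frame per mapping, as
#'   \code{\link{assignGlobal}}), \code{mode} (mode actually used) and
#'   \code{fallback} (flag).
#' @export
assignBlock <- function(mappings, sites, reference, chrom,
                        mode = c("dual", "global", "local"),
                        budget = 1e9, windowPad = 25L, cap = WEIGHT_CAP) {
  mode <- match.arg(mode)
  reference <- as.character(reference)
  runLocal <- function() lapply(seq_len(nrow(mappings)), function(i)
    assignLocal(as.list(mappings[i, ]), sites, reference, chrom,
                windowPad = windowPad, cap = cap))
  if (mode == "local")
    return(list(observations = runLocal(), mode = "local", fallback = FALSE))

  graphs <- vector("list", nrow(mappings))
  cells <- 0
  for (i in seq_len(nrow(mappings))) {
    m <- as.list(mappings[i, ])
    graphs[[i]] <- buildVariantGraph(reference, sites, chrom,
                                     m$start - windowPad, m$end + windowPad)
    readLen <- if (!is.null(m$seq) && !is.na(m$seq)) nchar(m$seq) else 0L
    cells <- cells + as.numeric(graphNodes(graphs[[i]])) * readLen
    if (mode == "dual" && cells > budget)
      return(list(observations = runLocal(), mode = "local", fallback = TRUE))
  }
  obs <- lapply(seq_len(nrow(mappings)), function(i)
    assignGlobal(as.list(mappings[i, ]), graphs[[i]], cap = cap))
  list(observations = obs, mode = "global", fallback = FALSE)
}

#' Collapse same-name mappings into condensed reads
#'
#' Unions the per-mapping observation lists of each read name into a
#' single condensed read: the bridge that lets primary/supplementary
#' pairs span homozygous deletions and reference gaps. At a site observed
#' by several mappings of one read, two conflicting concrete alleles
#' collapse to ambiguous (weight 0); agreeing concrete alleles keep the
#' maximum weight; a concrete allele outranks a sentinel, and ambiguous
#' outranks unknown. The result has at most one observation per site and
#' each read name appears exactly once; output is independent of the
#' order mappings are presented.
#'
#' @param observations list of data.frames (\code{site}, \code{allele},
#'   \code{weight}), one per mapping.
#' @param readName character vector, the read name of each mapping.
#' @param blockSites global heterozygous site indices of the block
#'   (become the columns); observations outside are dropped.
#' @return a \linkS4class{CondensedReadSet} with reads sorted by name.
#' @export
collapseMappings <- function(observations, readName, blockSites) {
  stopifnot(length(observations) == length(readName))
  blockSites <- as.integer(blockSites)
  if (!length(observations))
    return(CondensedReadSet(character(0),
                            data.frame(read = integer(0), col = integer(0),
                                       allele = integer(0), weight = integer(0)),
                            sites = blockSites))
  all <- do.call(rbind, lapply(seq_along(observations), function(i) {
    ob <- observations[[i]]
    if (is.null(ob) || !nrow(ob)) return(NULL)
    cbind(ob, name = readName[i])
  }))
  names <- sort(unique(readName))
  if (is.null(all) || !nrow(all))
    return(CondensedReadSet(names,
                            data.frame(read = integer(0), col = integer(0),
                                       allele = integer(0), weight = integer(0)),
                            sites = blockSites))
  all <- all[all$site %in% blockSites, , drop = FALSE]
  key <- paste(all$name, all$site, sep = "\r")
  resolved <- lapply(split(seq_len(nrow(all)), key), function(ix) {
    a <- all$allele[ix]
    w <- all$weight[ix]
    conc <- a >= 0L
    if (any(conc)) {
      ua <- unique(a[conc])
      if (length(ua) > 1L)
        return(c(AMBIGUOUS_ALLELE, 0L))
      return(c(ua, max(w[conc])))
    }
    if (any(a == AMBIGUOUS_ALLELE)) return(c(AMBIGUOUS_ALLELE, 0L))
    c(UNKNOWN_ALLELE, 0L)
  })
  first <- !duplicated(key)
  ord <- order(key)
  keys <- key[first]
  m <- do.call(rbind, resolved[keys])   # resolved is named by key
  obs <- data.frame(
    read = match(all$name[first], names),
    col = match(all$site[first], blockSites),
    allele = m[, 1L], weight = m[, 2L])
  CondensedReadSet(names, obs, sites = blockSites)
}
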