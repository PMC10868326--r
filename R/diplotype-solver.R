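## wMEC diplotype solving. Each phase block is an independent weighted
## minimum error correction instance: find haplotypes (h1, h2) minimizing
## the summed cost of editing every read to match one of them. The solver
## is an A* best-first search over per-site allele-to-haplotype choices;
## its admissible heuristic chains exhaustively solved chunk sub-problems.

#' Genotype matrix of a block
#'
#' Extracts the called genotype pairs (smaller allele first) for a run of
#' heterozygous site indices on one chromosome, as the solver expects.
#'
#' @param sites a \linkS4class{VariantSet}.
#' @param chrom chromosome name.
#' @param siteIdx heterozygous site indices (defaults to all on chrom).
#' @return integer matrix with columns \code{lo}, \code{hi}, one row per
#'   site.
#' @export
blockGenotypes <- function(sites, chrom, siteIdx = NULL) {
  sel <- which(siteChrom(sites) == chrom & isHet(sites))
  sel <- sel[order(siteIndex(sites)[sel])]
  if (!is.null(siteIdx)) sel <- sel[match(siteIdx, siteIndex(sites)[sel])]
  cbind(lo = sites@gt1[sel], hi = sites@gt2[sel])
}

## strip sentinel observations and reads left empty; solver-facing view
concreteObs <- function(reads) {
  ob <- reads@obs
  ob[ob$allele >= 0L, , drop = FALSE]
}

#' Restrict a read set to a subset of columns
#'
#' Keeps only observations on the given columns and renumbers columns to
#' 1..length(cols); reads without any remaining concrete observation are
#' kept (they simply contribute zero cost).
#'
#' @param reads a \linkS4class{CondensedReadSet}.
#' @param cols columns to keep (1-based, increasing).
#' @return a \linkS4class{CondensedReadSet} over the restricted columns.
#' @export
restrictColumns <- function(reads, cols) {
  cols <- as.integer(cols)
  ob <- reads@obs
  keep <- ob$col %in% cols
  ob <- ob[keep, , drop = FALSE]
  ob$col <- match(ob$col, cols)
  CondensedReadSet(reads@readName, ob, sites = reads@sites[cols])
}

## Enumerate all canonical choice vectors for n sites in lexicographic
## order of h1 (site 1 fixed to choice 0 by the h1/h2 symmetry).
choiceMatrix <- function(n) {
  if (n == 1L) return(matrix(0L, 1L, 1L))
  counts <- 0:(2^(n - 1L) - 1L)
  m <- matrix(0L, length(counts), n)
  for (j in 2:n)
    m[, j] <- (counts %/% 2L^(n - j)) %% 2L
  m
}

## cost vector over all enumerated assignments; genotypes: lo/hi matrix
enumCosts <- function(reads, genotypes, choices) {
  lo <- genotypes[, 1L]
  hi <- genotypes[, 2L]
  H1 <- matrix(ifelse(choices == 0L, rep(lo, each = nrow(choices)),
                      rep(hi, each = nrow(choices))), nrow(choices))
  H2 <- matrix(ifelse(choices == 0L, rep(hi, each = nrow(choices)),
                      rep(lo, each = nrow(choices))), nrow(choices))
  ob <- concreteObs(reads)
  total <- numeric(nrow(choices))
  if (!nrow(ob)) return(list(total = total, H1 = H1, H2 = H2))
  for (r in unique(ob$read)) {
    sel <- ob$read == r
    cc <- ob$col[sel]
    aa <- ob$allele[sel]
    ww <- ob$weight[sel]
    m1 <- H1[, cc, drop = FALSE] != rep(aa, each = nrow(H1))
    m2 <- H2[, cc, drop = FALSE] != rep(aa, each = nrow(H1))
    total <- total + pmin(as.numeric(m1 %*% ww), as.numeric(m2 %*% ww))
  }
  list(total = total, H1 = H1, H2 = H2)
}

#' Exhaustive wMEC solver (oracle)
#'
#' Enumerates every allele-to-haplotype assignment (2^(n-1) after fixing
#' the first site's orientation) and returns the minimum-cost canonical
#' diplotype. Intended as the independent oracle for the A* solver and for
#' chunk sub-problems; refuses more than 16 sites.
#'
#' @param reads a \linkS4class{CondensedReadSet}.
#' @param genotypes integer matrix (columns lo, hi) of called genotype
#'   pairs, e.g. from \code{\link{blockGenotypes}}.
#' @return a canonical \linkS4class{Diplotype}; ties are broken toward the
#'   lexicographically smallest h1.
#' @export
bruteForceDiplotype <- function(reads, genotypes) {
  n <- nrow(genotypes)
  if (n < 1L) stop("at least one site required")
  if (n > 16L) stop("brute force refused beyond 16 sites")
  stopifnot(all(genotypes[, 1L] < genotypes[, 2L]))
  choices <- choiceMatrix(n)
  e <- enumCosts(reads, genotypes, choices)
  i <- which.min(e$total)
  Diplotype(e$H1[i, ], e$H2[i, ], as.integer(e$total[i]))
}

## minimum cost only (used by the heuristic's chunk solves)
bruteForceCost <- function(reads, genotypes) {
  n <- nrow(genotypes)
  e <- enumCosts(reads, genotypes, choiceMatrix(n))
  as.integer(min(e$total))
}

#' Chained-chunk heuristic for the A* solver
#'
#' The heuristic value at depth \code{j} (sites 1..j already assigned)
#' partitions the remaining sites j+1..n into consecutive chunks of at
#' most \code{chunkSize} sites, solves each chunk's wMEC instance exactly
#' on the reads restricted to that chunk's columns, and sums the chunk
#' optima. Because each read's minimum cost over column subsets sums to at
#' most its minimum over all remaining columns, and chunk optima ignore
#' cross-chunk consistency, the chained value never exceeds the true
#' optimal completion cost: the heuristic is admissible.
#'
#' @param reads a \linkS4class{CondensedReadSet}.
#' @param genotypes lo/hi genotype matrix (see
#'   \code{\link{blockGenotypes}}).
#' @param chunkSize maximum chunk width (default 8; chunk solves enumerate
#'   at most 2^7 assignments).
#' @param j depth: number of leading sites already assigned (0..n).
#' @return non-negative integer lower bound on the completion cost.
#' @export
heuristicChain <- function(reads, genotypes, chunkSize = 8L, j) {
  stopifnot(j >= 0L, j <= nrow(genotypes))
  chainHeuristicTable(reads, genotypes, chunkSize)[j + 1L]
}

## H[j + 1] = heuristic at depth j, via the suffix recurrence
## H[j] = chunkOpt(j+1 .. e) + H[e],  e = min(j + chunkSize, n)
chainHeuristicTable <- function(reads, genotypes, chunkSize = 8L) {
  n <- nrow(genotypes)
  chunkSize <- max(1L, as.integer(chunkSize))
  H <- integer(n + 1L)
  if (n == 0L) return(H)
  for (j in (n - 1L):0) {
    e <- min(j + chunkSize, n)
    cols <- (j + 1L):e
    sub <- restrictColumns(reads, cols)
    H[j + 1L] <- bruteForceCost(sub, genotypes[cols, , drop = FALSE]) +
      H[e + 1L]
  }
  H
}

## ---- binary heap keyed by (f, depth desc, lexicographic h1 choices) ----
newHeap <- function() {
  env <- new.env(parent = emptyenv())
  env$f <- numeric(0)
  env$depth <- integer(0)
  env$key <- character(0)
  env$payload <- list()
  env
}

heapLess <- function(h, a, b) {
  if (h$f[a] != h$f[b]) return(h$f[a] < h$f[b])
  if (h$depth[a] != h$depth[b]) return(h$depth[a] > h$depth[b])
  h$key[a] < h$key[b]
}

heapSwap <- function(h, a, b) {
  h$f[c(a, b)] <- h$f[c(b, a)]
  h$depth[c(a, b)] <- h$depth[c(b, a)]
  h$key[c(a, b)] <- h$key[c(b, a)]
  tmp <- h$payload[[a]]
  h$payload[[a]] <- h$payload[[b]]
  h$payload[[b]] <- tmp
}

heapPush <- function(h, f, depth, key, payload) {
  i <- length(h$f) + 1L
  h$f[i] <- f
  h$depth[i] <- depth
  h$key[i] <- key
  h$payload[[i]] <- payload
  while (i > 1L) {
    p <- i %/% 2L
    if (heapLess(h, i, p)) {
      heapSwap(h, i, p)
      i <- p
    } else break
  }
}

heapPop <- function(h) {
  n <- length(h$f)
  if (n == 0L) return(NULL)
  top <- h$payload[[1L]]
  if (n > 1L) heapSwap(h, 1L, n)
  h$f <- h$f[-n]
  h$depth <- h$depth[-n]
  h$key <- h$key[-n]
  h$payload[[n]] <- NULL
  i <- 1L
  n <- n - 1L
  repeat {
    l <- 2L * i
    r <- l + 1L
    s <- i
    if (l <= n && heapLess(h, l, s)) s <- l
    if (r <= n && heapLess(h, r, s)) s <- r
    if (s == i) break
    heapSwap(h, i, s)
    i <- s
  }
  top
}

#' A* wMEC diplotype solver
#'
#' Searches the tree of per-site allele-to-haplotype choices best-first.
#' A node at depth j carries the partial haplotypes over sites 1..j, its
#' observed cost g (each read charged the cheaper of its two partial row
#' costs) and f = g + heuristic(j) from the chained-chunk heuristic
#' (\code{\link{heuristicChain}}). The first site's orientation is fixed
#' (canonical h1), halving the space. Frontier states identical on the
#' "active" sites (assigned sites still overlapped by a read reaching past
#' the frontier) have identical completion costs, so duplicates are pruned
#' keeping the smallest g. Ties in f are popped deepest-first, then by
#' lexicographically smallest partial h1, making the returned optimum
#' deterministic. Every read is used; there is no down-sampling.
#'
#' @param reads a \linkS4class{CondensedReadSet}; reads whose observations
#'   are all ambiguous/unknown are dropped (zero-weight rows cannot affect
#'   the optimum).
#' @param genotypes lo/hi genotype matrix, one row per block site.
#' @param chunkSize chunk width for the heuristic (default 8).
#' @return a canonical \linkS4class{Diplotype} with the globally optimal
#'   cost; the number of expanded nodes is attached as attribute
#'   \code{"expansions"}.
#' @examples
#' crs <- CondensedReadSet(c("a", "b"),
#'   data.frame(read = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
#'              allele = c(0, 0, 1, 1), weight = 30))
#' gt <- cbind(lo = c(0L, 0L), hi = c(1L, 1L))
#' solveAStar(crs, gt)
#' @export
solveAStar <- function(reads, genotypes, chunkSize = 8L) {
  n <- nrow(genotypes)
  if (is.null(n) || n < 1L) stop("empty site list")
  stopifnot(all(genotypes[, 1L] < genotypes[, 2L]))
  lo <- as.integer(genotypes[, 1L])
  hi <- as.integer(genotypes[, 2L])

  ob <- concreteObs(reads)
  nReads <- length(reads@readName)
  H <- chainHeuristicTable(reads, genotypes, chunkSize)

  ## per-column observation lists and active-site bookkeeping
  colObs <- split(ob[, c("read", "allele", "weight")], factor(ob$col, 1:n))
  maxColOfRead <- integer(nReads)
  if (nrow(ob)) {
    agg <- tapply(ob$col, ob$read, max)
    maxColOfRead[as.integer(names(agg))] <- as.integer(agg)
  }
  maxReach <- integer(n)
  if (nrow(ob)) {
    agg <- tapply(maxColOfRead[ob$read], ob$col, max)
    maxReach[as.integer(names(agg))] <- as.integer(agg)
  }
  activeAt <- lapply(1:n, function(j) which(maxReach[1:j] > j))

  heap <- newHeap()
  bestG <- new.env(parent = emptyenv())
  root <- list(depth = 0L, choices = integer(0),
               c1 = integer(nReads), c2 = integer(nReads), g = 0L)
  heapPush(heap, H[1L], 0L, "", root)
  expansions <- 0L

  repeat {
    node <- heapPop(heap)
    if (is.null(node)) stop("search space exhausted without a goal")
    j <- node$depth
    if (j > 0L) {
      akey <- paste0(j, ":", paste(node$choices[activeAt[[j]]], collapse = ""))
      g0 <- get0(akey, envir = bestG, ifnotfound = NA_integer_)
      if (!is.na(g0) && g0 < node$g) next  # dominated duplicate
    }
    if (j == n) {
      h1 <- ifelse(node$choices == 0L, lo, hi)
      h2 <- ifelse(node$choices == 0L, hi, lo)
      d <- Diplotype(h1, h2, node$g)
      attr(d, "expansions") <- expansions
      return(d)
    }
    expansions <- expansions + 1L
    co <- colObs[[j + 1L]]
    for (cc in if (j == 0L) 0L else c(0L, 1L)) {
      h1a <- if (cc == 0L) lo[j + 1L] else hi[j + 1L]
      h2a <- if (cc == 0L) hi[j + 1L] else lo[j + 1L]
      c1 <- node$c1
      c2 <- node$c2
      if (!is.null(co) && nrow(co)) {
        m1 <- co$allele != h1a
        m2 <- co$allele != h2a
        if (any(m1)) {
          add <- rowsum(co$weight[m1], co$read[m1])
          c1[as.integer(rownames(add))] <-
            c1[as.integer(rownames(add))] + as.integer(add[, 1L])
        }
        if (any(m2)) {
          add <- rowsum(co$weight[m2], co$read[m2])
          c2[as.integer(rownames(add))] <-
            c2[as.integer(rownames(add))] + as.integer(add[, 1L])
        }
      }
      g <- as.integer(sum(pmin(c1, c2)))
      choices <- c(node$choices, cc)
      jj <- j + 1L
      akey <- paste0(jj, ":", paste(choices[activeAt[[jj]]], collapse = ""))
      g0 <- get0(akey, envir = bestG, ifnotfound = NA_integer_)
      if (!is.na(g0) && g0 <= g) next
      assign(akey, g, envir = bestG)
      heapPush(heap, g + H[jj + 1L], jj, paste(choices, collapse = ""),
               list(depth = jj, choices = choices, c1 = c1, c2 = c2, g = g))
    }
  }
}

#' Split a solved block at unsupported junctions
#'
#' A junction between consecutive block sites is supported when at least
#' one collapsed read carries concrete (non-ambiguous) alleles on both
#' sides and those alleles agree with the read's best-matching solved
#' haplotype on each side. Junctions without such a read carry no phase
#' evidence for the chosen relative phase (typically because every
#' spanning read collapsed to ambiguity) and the block is split there into
#' separate phase sets. Splitting never alters any site's within-block
#' phase; the putative blocks are thus a lower bound on the final block
#' count.
#'
#' @param block a solved \linkS4class{PhaseBlock}.
#' @param reads the block's \linkS4class{CondensedReadSet}.
#' @param sites the \linkS4class{VariantSet} (for phase-set positions of
#'   new sub-blocks).
#' @param nextId first block id to assign to sub-blocks beyond the first.
#' @return list of solved \linkS4class{PhaseBlock}s (length 1 if no split).
#' @export
postSplit <- function(block, reads, sites, nextId = block@blockId + 1L) {
  stopifnot(isSolved(block))
  d <- block@diplotype
  n <- nSites(d)
  if (n < 2L) return(list(block))
  ob <- concreteObs(reads)
  c1 <- rowCost(reads, d@h1)
  c2 <- rowCost(reads, d@h2)
  supported <- logical(n - 1L)
  if (nrow(ob)) {
    agree1 <- ob$allele == d@h1[ob$col]
    agree2 <- ob$allele == d@h2[ob$col]
    for (r in unique(ob$read)) {
      hb <- if (c1[r] < c2[r]) 1L else if (c2[r] < c1[r]) 2L else next
      sel <- ob$read == r
      okCols <- ob$col[sel][if (hb == 1L) agree1[sel] else agree2[sel]]
      if (length(okCols) < 2L) next
      lohi <- range(okCols)
      if (lohi[2L] > lohi[1L])
        supported[lohi[1L]:(lohi[2L] - 1L)] <- TRUE
    }
  }
  if (all(supported)) return(list(block))
  cuts <- which(!supported)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  posByIdx <- hetPositions(sites, block@chrom)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    cols <- starts[k]:ends[k]
    si <- block@siteIndices[cols]
    sub <- restrictColumns(reads, cols)
    dk <- canonicalizeDiplotype(
      Diplotype(d@h1[cols], d@h2[cols], 0L))
    dk@cost <- diplotypeCost(sub, dk)
    id <- if (k == 1L) block@blockId else nextId + k - 2L
    st <- block@stats
    st$cost <- dk@cost
    st$split <- TRUE
    out[[k]] <- PhaseBlock(id, block@chrom, si,
                           phaseSet = posByIdx[si[1L]] + 1L,
                           diplotype = dk, stats = st)
  }
  out
}

## positions (0-based) of het sites on a chromosome, indexed by siteIndex
hetPositions <- function(sites, chrom) {
  sel <- which(siteChrom(sites) == chrom & isHet(sites))
  pos <- integer(length(sel))
  pos[siteIndex(sites)[sel]] <- sitePos(sites)[sel]
  pos
}
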