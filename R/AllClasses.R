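## Central S4 containers. Coordinates are 0-based half-open internally;
## VCF/SAM I/O converts to and from 1-based at the boundary.

#' Sentinel allele codes
#'
#' Concrete alleles are non-negative integers (0 = reference, 1..k = the
#' k alternate alleles). Two sentinels complete the coding:
#' \code{AMBIGUOUS_ALLELE} (-1) marks conflicting evidence at a site,
#' \code{UNKNOWN_ALLELE} (-2) marks absence of evidence. Both always carry
#' weight 0, but statistics report them separately.
#'
#' @format Integer constants.
#' @export
AMBIGUOUS_ALLELE <- -1L

#' @rdname AMBIGUOUS_ALLELE
#' @export
UNKNOWN_ALLELE <- -2L

## Maximum phred-like observation weight. Integer weights keep A* costs
## exact and comparisons with the exhaustive oracle bit-stable.
WEIGHT_CAP <- 60L

VARIANT_SOURCES <- c("small", "sv", "tandem_repeat")

#' VariantSet: ordered variant calls for one sample
#'
#' Holds one chromosome-sorted collection of diploid variant calls. Each
#' site has a 0-based reference start, a reference allele, one or more
#' alternate alleles, a diploid genotype as a pair of allele indices
#' (0 = ref), and a source class (\code{small}, \code{sv} or
#' \code{tandem_repeat}). Heterozygous sites additionally carry a dense
#' per-chromosome \code{siteIndex} (1-based) giving their rank in the
#' chromosome's heterozygous ordering; homozygous sites have
#' \code{NA} there and are kept only as re-alignment context.
#'
#' @slot chrom character, chromosome per site.
#' @slot pos integer, 0-based reference start per site.
#' @slot ref character, reference allele sequence.
#' @slot alt list of character vectors, ordered alternate alleles.
#' @slot gt1,gt2 integer allele indices of the called genotype
#'   (\code{gt1 <= gt2}).
#' @slot source character, one of \code{small}, \code{sv},
#'   \code{tandem_repeat}.
#' @slot siteIndex integer, dense heterozygous rank within the chromosome
#'   (NA for homozygous sites).
#' @export
setClass("VariantSet",
  representation(
    chrom = "character", pos = "integer", ref = "character",
    alt = "list", gt1 = "integer", gt2 = "integer",
    source = "character", siteIndex = "integer"
  )
)

setValidity("VariantSet", function(object) {
  n <- length(object@pos)
  lens <- c(length(object@chrom), length(object@ref), length(object@alt),
            length(object@gt1), length(object@gt2), length(object@source),
            length(object@siteIndex))
  if (any(lens != n)) return("slot lengths differ")
  if (n == 0L) return(TRUE)
  if (any(lengths(object@alt) < 1L)) return("alt_alleles must be non-empty")
  k <- lengths(object@alt)
  if (any(object@gt1 < 0L | object@gt2 < 0L | object@gt1 > k | object@gt2 > k))
    return("genotype allele index exceeds allele count")
  if (any(object@gt1 > object@gt2)) return("genotype must be stored gt1 <= gt2")
  if (!all(object@source %in% VARIANT_SOURCES))
    return("unknown source class")
  ## strict (pos, ref, alt1) ordering within chromosome
  alt1 <- vapply(object@alt, `[`, "", 1L)
  o <- order(object@chrom, object@pos, object@ref, alt1, method = "radix")
  if (!identical(o, seq_len(n)))
    return("sites must be sorted by (chrom, pos, ref, first alt)")
  key <- paste(object@chrom, object@pos, object@ref, alt1, sep = "\r")
  if (anyDuplicated(key)) return("duplicate site definition")
  het <- object@gt1 != object@gt2
  if (any(is.na(object@siteIndex[het])))
    return("heterozygous sites must carry a siteIndex")
  for (ch in unique(object@chrom)) {
    si <- object@siteIndex[het & object@chrom == ch]
    if (length(si) && !identical(as.integer(si), seq_along(si)))
      return("siteIndex must be dense 1..n_het within each chromosome")
  }
  TRUE
})

#' Construct a VariantSet
#'
#' @param chrom,pos,ref,alt,gt1,gt2,source per-site vectors; see the class
#'   documentation. \code{alt} may be a character vector (one alt each) or
#'   a list of character vectors. Input need not be sorted; sites are
#'   sorted by (chrom, pos, ref, first alt) and heterozygous site indices
#'   are (re)assigned.
#' @return A \linkS4class{VariantSet}.
#' @examples
#' vs <- VariantSet(chrom = "chr1", pos = c(100L, 300L), ref = c("A", "T"),
#'                  alt = c("G", "C"), gt1 = c(0L, 0L), gt2 = c(1L, 1L))
#' isHet(vs)
#' @export
VariantSet <- function(chrom = character(), pos = integer(),
                       ref = character(), alt = list(),
                       gt1 = integer(), gt2 = integer(),
                       source = "small") {
  n <- length(pos)
  if (!is.list(alt)) alt <- as.list(alt)
  alt <- unname(lapply(alt, unname))
  pos <- unname(pos)
  ref <- unname(ref)
  gt1 <- unname(gt1)
  gt2 <- unname(gt2)
  chrom <- rep_len(as.character(chrom), n)
  source <- rep_len(as.character(source), n)
  ref <- rep_len(as.character(ref), n)
  if (length(alt) == 1L && n > 1L) alt <- rep(alt, n)
  pos <- as.integer(pos)
  gg1 <- pmin(rep_len(as.integer(gt1), n), rep_len(as.integer(gt2), n))
  gg2 <- pmax(rep_len(as.integer(gt1), n), rep_len(as.integer(gt2), n))
  alt1 <- if (n) vapply(alt, `[`, "", 1L) else character()
  o <- order(chrom, pos, as.character(ref), alt1, method = "radix")
  new("VariantSet", chrom = chrom[o], pos = pos[o],
      ref = as.character(ref)[o], alt = alt[o],
      gt1 = gg1[o], gt2 = gg2[o], source = source[o],
      siteIndex = denseHetIndex(chrom[o], gg1[o], gg2[o]))
}

## dense het site indices per chromosome (sites already sorted)
denseHetIndex <- function(chrom, gt1, gt2) {
  het <- gt1 != gt2
  si <- rep(NA_integer_, length(het))
  for (ch in unique(chrom)) {
    sel <- het & chrom == ch
    si[sel] <- seq_len(sum(sel))
  }
  si
}

#' @describeIn VariantSet number of sites (het + hom)
#' @param x a VariantSet
#' @export
setMethod("length", "VariantSet", function(x) length(x@pos))

#' Heterozygosity indicator
#'
#' @param x a \linkS4class{VariantSet}
#' @return logical vector, TRUE where the two genotype alleles differ.
#' @export
isHet <- function(x) x@gt1 != x@gt2

#' @describeIn VariantSet subset sites (reassigns het site indices)
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  new("VariantSet", chrom = x@chrom[i], pos = x@pos[i],
      ref = x@ref[i], alt = x@alt[i], gt1 = x@gt1[i], gt2 = x@gt2[i],
      source = x@source[i],
      siteIndex = denseHetIndex(x@chrom[i], x@gt1[i], x@gt2[i]))
})

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet with", length(object), "sites (",
      sum(isHet(object)), "het ) on",
      length(unique(object@chrom)), "chromosome(s)\n")
  tab <- table(factor(object@source, VARIANT_SOURCES))
  cat("  by source:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

#' Per-site accessors for VariantSet
#'
#' \code{siteChrom}, \code{sitePos} (0-based), \code{siteRef},
#' \code{siteAlt}, \code{siteGenotype} (two-column integer matrix),
#' \code{siteSource} and \code{siteSpan} (half-open reference span
#' \code{[pos, pos + nchar(ref))} as an \code{IRanges}).
#'
#' @param x a \linkS4class{VariantSet}
#' @name variantAccessors
#' @export
siteChrom <- function(x) x@chrom

#' @rdname variantAccessors
#' @export
sitePos <- function(x) x@pos

#' @rdname variantAccessors
#' @export
siteRef <- function(x) x@ref

#' @rdname variantAccessors
#' @export
siteAlt <- function(x) x@alt

#' @rdname variantAccessors
#' @export
siteGenotype <- function(x) cbind(gt1 = x@gt1, gt2 = x@gt2)

#' @rdname variantAccessors
#' @export
siteSource <- function(x) x@source

#' @rdname variantAccessors
#' @export
siteIndex <- function(x) x@siteIndex

#' @rdname variantAccessors
#' @export
siteSpan <- function(x)
  IRanges::IRanges(start = x@pos, width = nchar(x@ref))

## allele sequence for index a (0 = ref) at site i
alleleSeq <- function(vs, i, a) {
  if (a == 0L) vs@ref[i] else vs@alt[[i]][a]
}

#' CondensedReadSet: the wMEC matrix of a phase block
#'
#' Each read name appears exactly once; its row is the chain of per-site
#' allele observations (one per overlapped site, sorted by column) with
#' integer weights giving the cost to alter or ignore the observation.
#' Columns 1..n correspond to the block's heterozygous sites, whose global
#' site indices are kept in \code{sites}.
#'
#' @slot readName character, one entry per read (unique).
#' @slot sites integer, global heterozygous site indices of the columns.
#' @slot obs data.frame with columns \code{read} (row index into
#'   \code{readName}), \code{col} (1..n), \code{allele} (>= 0 concrete,
#'   \code{AMBIGUOUS_ALLELE}, \code{UNKNOWN_ALLELE}) and \code{weight}
#'   (0..60; 0 whenever the allele is a sentinel).
#' @export
setClass("CondensedReadSet",
  representation(readName = "character", sites = "integer", obs = "data.frame")
)

setValidity("CondensedReadSet", function(object) {
  ob <- object@obs
  need <- c("read", "col", "allele", "weight")
  if (!all(need %in% names(ob))) return("obs must have read/col/allele/weight")
  if (anyDuplicated(object@readName)) return("read names must be unique")
  if (nrow(ob)) {
    if (any(ob$read < 1L | ob$read > length(object@readName)))
      return("obs$read out of range")
    if (any(ob$col < 1L | ob$col > length(object@sites)))
      return("obs$col out of range")
    if (anyDuplicated(ob[, c("read", "col")]))
      return("at most one observation per read and site")
    if (any(ob$weight < 0L)) return("weights must be non-negative")
    if (any(ob$weight > WEIGHT_CAP)) return("weight exceeds cap")
    sentinel <- ob$allele < 0L
    if (any(ob$weight[sentinel] != 0L))
      return("sentinel alleles must have weight 0")
    if (any(!ob$allele %in% c(AMBIGUOUS_ALLELE, UNKNOWN_ALLELE) & ob$allele < 0L))
      return("invalid allele code")
    o <- order(ob$read, ob$col)
    if (is.unsorted(ob$read) || !identical(o, seq_len(nrow(ob))))
      return("obs must be sorted by (read, col)")
  }
  TRUE
})

#' Construct a CondensedReadSet
#'
#' @param readName character vector of unique read names.
#' @param obs data.frame with columns \code{read}, \code{col},
#'   \code{allele}, \code{weight} (rows in any order; sorted internally).
#' @param sites global site indices of the columns; defaults to
#'   \code{seq_len(max(obs$col))} for abstract instances.
#' @return A \linkS4class{CondensedReadSet}.
#' @export
CondensedReadSet <- function(readName, obs, sites = NULL) {
  obs$read <- as.integer(obs$read)
  obs$col <- as.integer(obs$col)
  obs$allele <- as.integer(obs$allele)
  obs$weight <- as.integer(obs$weight)
  if (is.null(sites))
    sites <- seq_len(if (nrow(obs)) max(obs$col) else 0L)
  obs <- obs[order(obs$read, obs$col), , drop = FALSE]
  rownames(obs) <- NULL
  new("CondensedReadSet", readName = as.character(readName),
      sites = as.integer(sites), obs = obs)
}

#' @describeIn CondensedReadSet number of reads (wMEC rows)
#' @param x a CondensedReadSet
#' @export
setMethod("length", "CondensedReadSet", function(x) length(x@readName))

#' Number of sites (columns) addressed by an object
#'
#' @param x a \linkS4class{CondensedReadSet}, \linkS4class{Diplotype} or
#'   \linkS4class{PhaseBlock}
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname nSites
#' @export
setMethod("nSites", "CondensedReadSet", function(x) length(x@sites))

setMethod("show", "CondensedReadSet", function(object) {
  cat("CondensedReadSet:", length(object), "reads x", nSites(object),
      "sites,", nrow(object@obs), "observations\n")
})

#' Observations of a CondensedReadSet
#'
#' @param x a \linkS4class{CondensedReadSet}
#' @return the observation data.frame (read, col, allele, weight).
#' @export
readObservations <- function(x) x@obs

#' Read names of a CondensedReadSet
#' @param x a \linkS4class{CondensedReadSet}
#' @export
readNames <- function(x) x@readName

#' Diplotype: the two haplotypes solved for a phase block
#'
#' @slot h1,h2 integer vectors of allele indices, one per block site.
#' @slot cost total wMEC cost of the solution (non-negative integer).
#' @export
setClass("Diplotype",
  representation(h1 = "integer", h2 = "integer", cost = "integer")
)

setValidity("Diplotype", function(object) {
  if (length(object@h1) != length(object@h2))
    return("h1 and h2 must have equal length")
  if (length(object@cost) != 1L || is.na(object@cost) || object@cost < 0L)
    return("cost must be one non-negative integer")
  if (any(object@h1 < 0L) || any(object@h2 < 0L))
    return("haplotype alleles must be concrete (>= 0)")
  TRUE
})

#' Construct a Diplotype
#'
#' @param h1,h2 integer allele vectors of equal length.
#' @param cost total wMEC cost.
#' @return A \linkS4class{Diplotype} (not canonicalized; see
#'   \code{\link{canonicalizeDiplotype}}).
#' @export
Diplotype <- function(h1, h2, cost = 0L) {
  new("Diplotype", h1 = as.integer(h1), h2 = as.integer(h2),
      cost = as.integer(cost))
}

#' @rdname nSites
#' @export
setMethod("nSites", "Diplotype", function(x) length(x@h1))

#' Haplotype and cost accessors
#'
#' @param x a \linkS4class{Diplotype} (or, for \code{wmecCost}, anything
#'   carrying a solved diplotype)
#' @name diplotypeAccessors
#' @export
haplotype1 <- function(x) x@h1

#' @rdname diplotypeAccessors
#' @export
haplotype2 <- function(x) x@h2

#' @rdname diplotypeAccessors
#' @export
setGeneric("wmecCost", function(x) standardGeneric("wmecCost"))

#' @rdname diplotypeAccessors
#' @export
setMethod("wmecCost", "Diplotype", function(x) x@cost)

setMethod("show", "Diplotype", function(object) {
  cat("Diplotype over", nSites(object), "sites, cost", object@cost, "\n")
  if (nSites(object) <= 40L) {
    cat("  h1:", paste(object@h1, collapse = ""), "\n")
    cat("  h2:", paste(object@h2, collapse = ""), "\n")
  }
})

#' PhaseBlock: a run of connected heterozygous sites
#'
#' A maximal run of consecutive heterozygous sites connected by read
#' mappings, with its solving state. \code{phaseSet} is the 1-based
#' position of the block's first site (the VCF PS convention).
#' Single-site putative blocks are reported in statistics but left
#' unphased.
#'
#' @slot blockId integer id.
#' @slot chrom chromosome.
#' @slot siteIndices contiguous global het site indices of the block.
#' @slot phaseSet 1-based position of the first site.
#' @slot diplotype the solved \linkS4class{Diplotype}, or NULL while
#'   unsolved.
#' @slot stats list of solving statistics (mode, fallback flag, cost,
#'   expansions, per-source site counts, span).
#' @export
setClass("PhaseBlock",
  representation(blockId = "integer", chrom = "character",
                 siteIndices = "integer", phaseSet = "integer",
                 diplotype = "ANY", stats = "list")
)

setValidity("PhaseBlock", function(object) {
  si <- object@siteIndices
  if (!length(si)) return("siteIndices must be non-empty")
  if (!identical(si, si[1L] + seq_along(si) - 1L))
    return("siteIndices must be contiguous")
  if (!is.null(object@diplotype)) {
    if (!is(object@diplotype, "Diplotype")) return("diplotype must be a Diplotype or NULL")
    if (nSites(object@diplotype) != length(si))
      return("diplotype length must match block size")
  }
  TRUE
})

#' Construct a PhaseBlock
#'
#' @param blockId integer id.
#' @param chrom chromosome name.
#' @param siteIndices contiguous heterozygous site indices.
#' @param phaseSet 1-based position of the first site.
#' @param diplotype solved \linkS4class{Diplotype} or NULL.
#' @param stats list of statistics.
#' @return A \linkS4class{PhaseBlock}.
#' @export
PhaseBlock <- function(blockId, chrom, siteIndices, phaseSet,
                       diplotype = NULL, stats = list()) {
  new("PhaseBlock", blockId = as.integer(blockId), chrom = as.character(chrom),
      siteIndices = as.integer(siteIndices), phaseSet = as.integer(phaseSet),
      diplotype = diplotype, stats = stats)
}

#' @rdname nSites
#' @export
setMethod("nSites", "PhaseBlock", function(x) length(x@siteIndices))

#' PhaseBlock accessors
#'
#' @param x a \linkS4class{PhaseBlock}
#' @name phaseBlockAccessors
#' @export
blockSites <- function(x) x@siteIndices

#' @rdname phaseBlockAccessors
#' @export
phaseSet <- function(x) x@phaseSet

#' @rdname phaseBlockAccessors
#' @export
blockDiplotype <- function(x) x@diplotype

#' @rdname phaseBlockAccessors
#' @export
blockChrom <- function(x) x@chrom

#' @rdname phaseBlockAccessors
#' @export
isSolved <- function(x) !is.null(x@diplotype)

setMethod("show", "PhaseBlock", function(object) {
  cat(sprintf("PhaseBlock %d on %s: %d sites (PS=%d), %s\n",
              object@blockId, object@chrom, nSites(object), object@phaseSet,
              if (isSolved(object)) sprintf("solved cost=%d", object@diplotype@cost)
              else "unsolved"))
})
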