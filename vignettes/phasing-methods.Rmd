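---
title: "Joint read-backed phasing with DiploPhase: model, algorithms and design choices"
author: "DiploPhase maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint read-backed phasing with DiploPhase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiploPhase)
```

# The problem

In a diploid sample, variant callers report genotypes but not which
alleles co-occur on the same chromosome copy. Read-backed phasing
resolves this by exploiting that a single long read carries the alleles
of one haplotype at every heterozygous site it covers. Long accurate
reads (10 kb and beyond, ~Q30 per base) routinely span several
heterozygous sites, and also support calling of structural variants
(insertions/deletions of 50 bp and more) and tandem repeat copy-number
variants. DiploPhase phases all of these classes jointly: SNVs, short
indels, structural variants and tandem repeat variants, including
multi-allelic sites (genotype 1/2), from one aligned read set.

The method decomposes into three stages, each of which is an exported,
separately testable surface.

# Phase block generation

Heterozygous sites are swept in genomic order per chromosome. A block is
seeded from the first site; the next site joins the current block when
at least one mapping (with mapping quality at or above `minMapq`,
default 5) fully covers both the new site's reference span and the span
of some site already in the block. When no single mapping spans both,
the sweep checks for a *split-read bridge*: one read whose primary
mapping covers a block site and whose supplementary mapping covers the
new site (or vice versa). This is what lets blocks continue across
homozygous deletions and reference gaps, where no single mapping
segment can span the junction but the read itself does. Blocks closed
by the sweep are independent sub-problems — no read connects two blocks,
so they can be assigned and solved in parallel, and the putative block
count is a lower bound on the final count (solving can split blocks,
never merge them).

Two conventions here were genuinely open and are package decisions: a
variant's span for overlap testing is the half-open interval
`[pos, pos + nchar(ref))` (a 1-base anchor for insertions), and a
mapping must contain the span entirely — partial overlap at a site edge
is not evidence. One spanning read suffices to extend a block; this
threshold is deliberately permissive and configurable upstream of the
solver, which is robust to occasional spurious connections because weak
junctions are re-split after solving (below).

# Allele assignment

Every mapping in a block is reduced to a *condensed read*: a chain of
per-site allele observations, each with an integer weight — the cost of
altering or ignoring that observation during solving. Weights are
phred-like and capped at 60 so that all downstream arithmetic is exact
integer arithmetic; ambiguous (conflicting evidence) and unknown (no
evidence) observations are distinguished for statistics but both carry
weight 0.

**Local mode** scores, for each site covered by the mapping, the query
subsequence projected (via the CIGAR) onto a window of `windowPad`
(default 25) bases around the site against each allele's windowed
sequence, by edit distance. The nearest allele wins; an exact tie is
ambiguous. The weight is the minimum base quality over the query window
(constant 30 for the simulator's Q30 reads). The 25 bp default exceeds
typical homopolymer indel context; it is the right scale for SNVs and
isolated short indels, and the wrong tool for structural alleles that
do not fit any window — which is why a second mode exists.

**Global mode** re-aligns the whole mapping against an *alt-aware
variant graph*: a DAG over the mapping's reference span carrying one
branch per allele (reference included) at every site, with overlapping
site definitions merged into joint branch sets that enumerate only
physically consistent local haplotypes. The alignment is an exact
fitting alignment (the read end-to-end, graph ends free) under unit
edit costs, computed by dynamic programming over the character-level
DAG in compiled code. The allele at a site is the one on the optimal
path; its weight is the margin `cost(best path forced through the other
allele) − cost(best path)`, capped at 60, with a zero margin reported
as ambiguous. A mapping whose best cost exceeds 0.3 per base is treated
as mismapped and yields only unknowns. Wavefront-style acceleration
would change none of these outputs — the contract is optimality of the
edit cost, and the forward/backward DP already provides every forced
cost from two passes.

**Dual mode** (the default) runs global assignment unless the block's
cumulative alignment work exceeds a budget, in which case the whole
block is redone locally and flagged as a fallback. The trigger is
deliberately not wall-clock time but DP cells (graph nodes × read
length, summed over mappings; default 10^9 per block), a deterministic,
machine-independent proxy — the same inputs always fall back in the same
way on any machine. The fallback is per block, never per read, so a
mixed run is always reproducible as one of the two pure modes per
block.

Finally, mappings sharing a read name are collapsed into one condensed
read — the bridge that joins primary/supplementary pairs across
deletion gaps. Conflicting concrete alleles at a site collapse to
ambiguous; agreeing ones keep the larger weight; a concrete observation
outranks a sentinel. The result is independent of mapping order.

# Diplotype solving

Each block is a weighted minimum error correction (wMEC) instance:
given the read × site allele matrix with weights, find haplotypes
(h1, h2) — at every site carrying exactly the two called genotype
alleles — minimizing the summed cost of editing each read to match its
cheaper haplotype. DiploPhase solves this exactly with A* search over
partial diplotypes: a node at depth j fixes the allele-to-haplotype
choice for the first j sites; its observed cost g charges each read the
cheaper of its two partial row costs; its priority is f = g + h(j).

The heuristic h(j) *chains sub-problem solutions*: the remaining sites
are partitioned into consecutive chunks of at most `chunkSize`
(default 8) sites, each chunk's wMEC optimum is solved exhaustively on
the reads restricted to that chunk's columns, and the chunk optima are
summed. Admissibility follows from two relaxations: per read, minima
over column subsets sum to at most the minimum over their union, and
chunk optima ignore cross-chunk consistency. With `chunkSize` at least
the block size the heuristic *is* the optimum and A* walks straight to
the goal; the default keeps every chunk solve at 2^7 enumerations.
These sub-problem optima are computed once per block by a suffix
recurrence (h(j) reuses h(j + chunkSize)).

Three further design choices make the search fast and deterministic:
the first site's orientation is fixed (halving the space and fixing the
canonical h1); equal-f nodes pop deepest-first, then by smallest partial
h1; and frontier states identical on the *active* sites (assigned sites
still covered by a read reaching past the frontier) are pruned keeping
the smallest g — inactive prefixes cannot influence any remaining read,
so the dominance is exact. Reads whose observations are all sentinel are
dropped; every other read is used, with no down-sampling at any
coverage. The exhaustive enumerator is retained as `bruteForceDiplotype`
and serves as the solver's independent oracle in the test suite; it is
never called on the solving path for blocks beyond 16 sites.

After solving, junctions between consecutive sites that no collapsed
read supports with concrete alleles on both sides (agreeing with the
read's best haplotype) are cut, and the block separates into distinct
phase sets. This is boundary-only: no site's within-block phase
changes.

# Outputs

Phased genotypes are written back into the input VCFs: heterozygous
sites inside solved multi-site blocks get an ordered `h1|h2` genotype
and a `PS` FORMAT field equal to the 1-based position of the block's
first site (the prevailing read-backed phasing convention). Everything
else passes through byte-identical — single-site blocks carry no phase
information and are left unphased (they still appear in the statistics
table). Haplotagging assigns each read to the haplotype with strictly
smaller row cost and writes `HP:i:1|2` and `PC:i:<phase set>` tags;
ties stay untagged. Writing is a surgical line-level edit of the input
text, which is what makes the byte-level pass-through guarantee (and
byte-level determinism checks across worker counts) possible. The
parallel unit is the phase block; results are buffered and written in
genomic order, so output is identical for any thread count.

# Evaluation metrics

Against a truth phasing, errors are counted per block on the agreement
sequence (1 where predicted h1 matches truth h1): an isolated
disagreement bounded by two transitions is a *flip*; every remaining
transition is a *switch*; hence switches + 2·flips equals the raw
transition count, and the counts are invariant under either global or
per-block haplotype swaps. Block length is summarized as NG50 with the
reference length (not the covered length) as denominator. Phased
variant counts are partitioned by class (small / structural / tandem
repeat). A gene is *fully phased* when all heterozygous sites starting
in its interval lie in one solved block; genes without heterozygous
sites count as vacuously phased, and a stricter block-spans-gene
reading is available via `requireSpan` — the variant-containment
reading is the default because it matches what downstream consumers of
`PS` actually need.

# The simulator, and what passing tests mean

`simulateTruth` plants, on a uniform random reference: SNVs (per-base
rate, default 10^-3, two thirds heterozygous with a small multi-allelic
fraction), short indels of 1–6 bp (rate 2×10^-4), an exact number of
heterozygous structural variants (insertions/deletions of 50–300 bp),
an exact number of tandem repeat sites (a planted motif of 2–4 bp at
8–14 reference copies whose two haplotypes carry different copy
numbers — sometimes both non-reference, giving genuine 1/2 genotypes),
and optional homozygous deletions that later split crossing reads into
primary/supplementary pairs. Heterozygous alleles are assigned to the
two truth haplotypes uniformly. `simulateReads` draws a Poisson number
of reads at the requested coverage with uniform starts and fixed
reference-span length, observes each fully-covered site's source-
haplotype allele, and corrupts observations independently at
`alleleErrorRate`. Rendering to sequences/SAM is exact (clean CIGARs,
constant Q30 qualities, soft-clipped split reads).

The defaults mirror the desk-scale study conditions used throughout the
tests and the acceptance script: a 200 kb diploid with SNVs + 2 SVs +
5 TR sites at 30× with 3 kb reads, error-free and with 2% allele
corruption. These sizes keep the full pipeline runs to tens of seconds;
they are stated here as the package's chosen study conditions.

What the simulator does *not* emulate: realistic sequencing-error
profiles (errors are clean allele swaps, not context-dependent
homopolymer noise), mapping reference bias, mapping-quality variation,
chimeric reads, or variant-calling errors (genotypes are correct by
construction). Passing the recovery tests therefore demonstrates the
correctness of the machinery — connectivity, assignment, exact solving,
output plumbing — not the error robustness one would measure on real
data. The solver-optimality and admissibility properties, in contrast,
are exercised on adversarial random matrices with 10–20% corruption and
arbitrary weights, and hold regardless of the error model.

# Numerical and degenerate-input choices

Integer weights capped at 60 make every cost comparison exact.
Alignment uses unit edit costs; all coordinates are 0-based half-open
internally, converting to 1-based only in VCF/SAM text. Degenerate
inputs are handled explicitly: an empty site list is an error for the
solver but yields an empty graph path set upstream; a mapping without
sequence or CIGAR degrades to all-unknown observations rather than
failing; merged clusters whose joint allele enumeration would explode
(beyond 256 combinations) restrict to the called genotype alleles plus
reference; reads aligning above the per-base cost ceiling yield
unknowns. Single-variant blocks are never "solved" and never phased.
Ties are resolved deterministically everywhere: allele ties are
ambiguous rather than arbitrary, solver ties prefer the
lexicographically smallest h1, haplotag ties stay untagged.

# Known limitations

Local-mode candidate windows are built on the pure reference, so a
nearby homozygous variant inside the window inflates both candidates'
distances equally; with clean reads the argmin is unaffected, but in
repetitive context this can produce avoidable ambiguity (global mode
includes homozygous sites in the graph and does not have this issue).
Phasing is per-sample and diploid only; polyploid genotypes, inversion
and copy-number phasing, and population- or pedigree-informed block
joining are out of scope. NG50 requires the caller to supply the
reference length when the FASTA is not the full genome. The A* solver
has no node budget: pathological blocks (extreme coverage plus extreme
corruption) are solved exactly however long it takes, which is the
intended trade — at realistic long-read coverage the chained heuristic
keeps expansions near-linear in block size.
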