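# Shared fixture builders. Everything is generated in code at test time;
# all randomness is locally seeded so tests are reproducible.

# Random wMEC instance: n biallelic (occasionally multi-allelic) het
# sites, m reads with contiguous-ish spans, random weights 1..60 and a
# corruption fraction of wrong alleles.
mkWmecInstance <- function(n, m, corrupt = 0.15, multiFrac = 0.15) {
  multi <- runif(n) < multiFrac
  lo <- ifelse(multi, 1L, 0L)
  hi <- ifelse(multi, 2L, 1L)
  gt <- cbind(lo = lo, hi = hi)
  pickTruth <- t(vapply(seq_len(n), function(j) sample(c(lo[j], hi[j])),
                        integer(2)))
  obs <- do.call(rbind, lapply(seq_len(m), function(r) {
    a <- sample.int(n, 1L)
    b <- min(n, a + sample.int(max(1L, n - a + 1L), 1L) - 1L)
    span <- a:b
    hap <- sample(1:2, 1L)
    al <- pickTruth[span, hap]
    err <- runif(length(span)) < corrupt
    kmax <- ifelse(multi[span], 2L, 1L)
    al[err] <- vapply(which(err), function(i) {
      cands <- setdiff(0:kmax[i], al[i])
      cands[sample.int(length(cands), 1L)]
    }, 0L)
    data.frame(read = r, col = span, allele = al,
               weight = sample(1:60, length(span), TRUE))
  }))
  list(reads = CondensedReadSet(sprintf("r%03d", seq_len(m)), obs),
       genotypes = gt, truth = pickTruth)
}

# Small end-to-end dataset written to a temp dir; returns paths + truth.
mkDataset <- function(dir, refLength = 30000, snvRate = 1e-3,
                      indelRate = 2e-4, svCount = 1L, trCount = 2L,
                      coverage = 20, readLength = 3000L,
                      alleleErrorRate = 0, seed = 7L, homDelSpans = NULL) {
  tr <- simulateTruth(refLength, snvRate = snvRate, indelRate = indelRate,
                      svCount = svCount, trCount = trCount, seed = seed,
                      homDelSpans = homDelSpans)
  sim <- simulateReads(tr, coverage = coverage, readLength = readLength,
                       alleleErrorRate = alleleErrorRate, seed = seed)
  paths <- writeTruthInputs(tr, file.path(dir, "t"))
  sam <- writeSimulatedSam(tr, sim, file.path(dir, "t.sam"))
  list(truth = tr, sim = sim, vcf = paths[c("small", "sv", "tandem_repeat")],
       reference = paths[["reference"]], sam = sam)
}

# Independent fitting-alignment oracle: minimum edit distance of `read`
# to any substring of `text` (read global, text ends free), via TRE's
# approximate matching.
fitDistance <- function(read, text) {
  as.integer(utils::adist(read, text, partial = TRUE))
}

# Did a solved block recover the truth phase (up to h1/h2 swap)?
recoversTruth <- function(block, truthMat) {
  d <- blockDiplotype(block)
  t1 <- truthMat[blockSites(block), 1L]
  t2 <- truthMat[blockSites(block), 2L]
  identical(haplotype1(d), t1) || identical(haplotype1(d), t2)
}
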