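test_that("truth simulation is seed-deterministic and honors exact counts", {
  a <- simulateTruth(50000, snvRate = 1e-3, indelRate = 2e-4, svCount = 2,
                     trCount = 3, seed = 7)
  b <- simulateTruth(50000, snvRate = 1e-3, indelRate = 2e-4, svCount = 2,
                     trCount = 3, seed = 7)
  expect_identical(truthReference(a), truthReference(b))
  expect_identical(sitePos(truthVariants(a)), sitePos(truthVariants(b)))
  expect_identical(truthHaplotypes(a), truthHaplotypes(b))
  vs <- truthVariants(a)
  ## exactly svCount sites with length change >= 50
  lenDiff <- vapply(seq_along(vs), function(i)
    max(abs(nchar(siteAlt(vs)[[i]]) - nchar(siteRef(vs)[i]))), 0)
  expect_identical(sum(lenDiff >= 50), 2L)
  expect_identical(sum(siteSource(vs) == "tandem_repeat"), 3L)
  ## tandem repeats are heterozygous by construction
  expect_true(all(isHet(vs)[siteSource(vs) == "tandem_repeat"]))
})

test_that("all-zero rates produce zero variants", {
  tr <- simulateTruth(20000, snvRate = 0, indelRate = 0, svCount = 0,
                      trCount = 0, seed = 1)
  expect_length(truthVariants(tr), 0L)
})

test_that("read count follows the coverage expectation within 3 sigma", {
  tr <- simulateTruth(50000, snvRate = 1e-3, indelRate = 0, svCount = 0,
                      trCount = 0, seed = 3)
  sim <- simulateReads(tr, coverage = 20, readLength = 2500, seed = 3)
  lambda <- 20 * 50000 / 2500
  n <- length(unique(simRecords(sim)$readName))
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
})

test_that("error-free reads observe exactly their source haplotype", {
  tr <- simulateTruth(30000, snvRate = 2e-3, indelRate = 5e-4, svCount = 1,
                      trCount = 1, seed = 13)
  sim <- simulateReads(tr, coverage = 10, readLength = 2000,
                       alleleErrorRate = 0, seed = 13)
  vs <- truthVariants(tr)
  th <- truthHaplotypes(tr)
  recs <- simRecords(sim)
  for (i in seq_len(nrow(recs))) {
    ob <- simObservations(sim)[[i]]
    for (j in seq_len(nrow(ob))) {
      r <- ob$siteRow[j]
      want <- if (isHet(vs)[r]) th[siteIndex(vs)[r], recs$hap[i]]
              else siteGenotype(vs)[r, 1L]
      expect_identical(ob$allele[j], unname(want))
    }
  }
})

test_that("reads crossing a homozygous deletion split into same-name record pairs", {
  tr <- simulateTruth(40000, snvRate = 1e-3, indelRate = 0, svCount = 0,
                      trCount = 0, seed = 19,
                      homDelSpans = list(c(15000L, 10000L)))
  expect_identical(nrow(deletionIntervals(tr)), 1L)
  sim <- simulateReads(tr, coverage = 20, readLength = 4000, seed = 19)
  recs <- simRecords(sim)
  expect_gt(sum(recs$supplementary), 0L)
  spl <- unique(recs$readName[recs$supplementary])
  counts <- table(recs$readName[recs$readName %in% spl])
  expect_true(all(counts >= 2))
  ## record spans never enter the deleted interval
  di <- deletionIntervals(tr)
  expect_true(all(recs$end <= di[1] | recs$start >= di[2]))
})

test_that("rendered sequences re-spell the reference on all-reference reads", {
  tr <- simulateTruth(20000, snvRate = 0, indelRate = 0, svCount = 0,
                      trCount = 0, seed = 2)
  sim <- simulateReads(tr, coverage = 3, readLength = 1500, seed = 2)
  rr <- renderReads(tr, sim)
  for (i in seq_len(min(5, nrow(rr))))
    expect_identical(rr$seq[i], substr(truthReference(tr),
                                       rr$start[i] + 1L, rr$end[i]))
  expect_true(all(grepl("^[0-9]+M$", rr$cigar[1:5])))
})
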