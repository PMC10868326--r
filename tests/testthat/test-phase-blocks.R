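mkAln <- function(readName, start, end, mapq = 60L, supplementary = FALSE) {
  data.frame(readName = readName, chrom = "c", start = start, end = end,
             mapq = mapq, supplementary = supplementary)
}

test_that("spansBlock uses half-open full containment", {
  expect_true(spansBlock(c(100, 5000), cbind(200, 201), c(4800, 4801)))
  expect_false(spansBlock(c(100, 300), cbind(200, 201), c(4800, 4801)))
  ## site exactly at the mapping end is outside the half-open span
  expect_false(spansBlock(c(100, 300), cbind(200, 201), c(300, 301)))
  expect_true(spansBlock(c(100, 301), cbind(200, 201), c(300, 301)))
})

test_that("full connectivity yields one block, none yields singletons", {
  sites <- VariantSet(chrom = "c", pos = c(100L, 200L, 300L), ref = "A",
                      alt = "G", gt1 = 0L, gt2 = 1L)
  one <- generateBlocks(sites, mkAln("r1", 50L, 400L))
  expect_length(one, 1L)
  expect_identical(blockSites(one[[1]]), 1:3)
  expect_identical(phaseSet(one[[1]]), 101L)

  two <- VariantSet(chrom = "c", pos = c(100L, 5000L), ref = "A", alt = "G",
                    gt1 = 0L, gt2 = 1L)
  far <- rbind(mkAln("r1", 50L, 400L), mkAln("r2", 4900L, 5400L))
  blocks <- generateBlocks(two, far)
  expect_length(blocks, 2L)
  expect_true(all(vapply(blocks, nSites, 0L) == 1L))
})

test_that("low-quality mappings do not connect sites", {
  sites <- VariantSet(chrom = "c", pos = c(100L, 200L), ref = "A", alt = "G",
                      gt1 = 0L, gt2 = 1L)
  expect_length(generateBlocks(sites, mkAln("r1", 50L, 300L, mapq = 2L)), 2L)
  expect_length(generateBlocks(sites, mkAln("r1", 50L, 300L, mapq = 5L)), 1L)
})

test_that("same-name primary/supplementary pairs bridge coverage gaps", {
  sites <- VariantSet(chrom = "c", pos = c(100L, 200L, 12000L, 12100L),
                      ref = "A", alt = "G", gt1 = 0L, gt2 = 1L)
  local <- rbind(mkAln("a", 50L, 400L), mkAln("b", 11900L, 12400L))
  expect_length(generateBlocks(sites, local), 2L)
  bridged <- rbind(local,
                   mkAln("split", 150L, 1500L),
                   mkAln("split", 11800L, 12300L, supplementary = TRUE))
  bridged <- bridged[order(bridged$start), ]
  blocks <- generateBlocks(sites, bridged)
  expect_length(blocks, 1L)
  expect_identical(blockSites(blocks[[1]]), 1:4)
})

test_that("a simulated homozygous deletion is bridged only via supplementary records", {
  dir <- withr::local_tempdir()
  ds <- mkDataset(dir, refLength = 50000, snvRate = 2e-3, indelRate = 0,
                  svCount = 0, trCount = 0, coverage = 25,
                  readLength = 5000L, seed = 11,
                  homDelSpans = list(c(20000L, 10000L)))
  aln <- readAlignments(ds$sam)
  sites <- readVariantFiles(ds$vcf[c("small", "sv")], "SAMPLE")
  expect_length(generateBlocks(sites, aln), 1L)
  expect_length(generateBlocks(sites, aln[!aln$supplementary, ]), 2L)
})

test_that("blocks partition the het sites and deleting reads never merges blocks", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    pos <- sort(sample.int(20000L, n))
    sites <- VariantSet(chrom = "c", pos = pos, ref = "A", alt = "G",
                        gt1 = 0L, gt2 = 1L)
    m <- sample(5:15, 1)
    st <- sample.int(19000L, m)
    aln <- mkAln(sprintf("r%d", 1:m), st, st + sample(500:4000, m, TRUE))
    aln <- aln[order(aln$start), ]
    blocks <- generateBlocks(sites, aln)
    got <- sort(unlist(lapply(blocks, blockSites)))
    expect_identical(got, 1:n)                       # union = all het sites
    expect_identical(anyDuplicated(got), 0L)         # disjoint
    fewer <- generateBlocks(sites, aln[-sample.int(m, 1), , drop = FALSE])
    expect_gte(length(fewer), length(blocks))
  }
})
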