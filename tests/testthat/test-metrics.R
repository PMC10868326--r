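mkSolvedBlock <- function(h1, siteIdx = seq_along(h1), id = 1L, ps = 1L) {
  PhaseBlock(id, "c", siteIdx, ps,
             diplotype = Diplotype(h1, 1L - h1, 0L))
}

test_that("switchFlip classifies perfect, flipped and switched blocks", {
  truth <- c(0L, 1L, 0L, 1L, 0L, 1L)
  expect_identical(switchFlip(truth, list(mkSolvedBlock(truth))),
                   c(switches = 0L, flips = 0L))
  ## one interior site inverted in a 5-site block -> one flip
  flip <- truth[1:5]; flip[3] <- 1L - flip[3]
  expect_identical(switchFlip(truth[1:5], list(mkSolvedBlock(flip))),
                   c(switches = 0L, flips = 1L))
  ## agreement on sites 1-3, inversion on 4-6 -> one switch
  sw <- truth; sw[4:6] <- 1L - sw[4:6]
  expect_identical(switchFlip(truth, list(mkSolvedBlock(sw))),
                   c(switches = 1L, flips = 0L))
  ## global h1/h2 swap of the prediction changes nothing
  expect_identical(switchFlip(truth, list(mkSolvedBlock(1L - sw))),
                   c(switches = 1L, flips = 0L))
})

test_that("switches + 2*flips equals the transition count of the agreement", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    truth <- sample(0:1, n, TRUE)
    pred <- truth
    ix <- sample.int(n, sample(0:n, 1))
    pred[ix] <- 1L - pred[ix]
    sf <- switchFlip(truth, list(mkSolvedBlock(pred)))
    a <- as.integer(pred == truth)
    expect_identical(unname(sf["switches"] + 2L * sf["flips"]),
                     sum(diff(a) != 0L))
  }
})

test_that("ng50 follows the cumulative half-reference rule", {
  expect_identical(ng50(60, 100), 60)
  expect_identical(ng50(c(30, 30, 30), 100), 30)
  expect_identical(ng50(10, 100), 0)
  set.seed(4)
  lens <- sample(100:1000, 10)
  expect_identical(ng50(lens, 3000), ng50(sample(lens), 3000))
  expect_gte(ng50(lens + 10, 3000), ng50(lens, 3000))
})

test_that("phasedCounts partitions solved multi-site block sites by class", {
  sites <- VariantSet(chrom = "c", pos = c(100L, 200L, 300L, 400L, 600L),
                      ref = "A", alt = "G", gt1 = 0L, gt2 = 1L,
                      source = c("small", "small", "small", "sv", "small"))
  blocks <- list(mkSolvedBlock(c(0L, 1L, 0L, 1L), 1:4),
                 PhaseBlock(2L, "c", 5L, 601L))    # single-site, unphased
  counts <- phasedCounts(blocks, sites)
  expect_identical(counts, c(small = 3L, sv = 1L, tandem_repeat = 0L,
                             total = 4L))
  expect_identical(phasedCounts(list(), sites),
                   c(small = 0L, sv = 0L, tandem_repeat = 0L, total = 0L))
})

test_that("gene phasing counts single-block genes and vacuous genes", {
  sites <- VariantSet(chrom = "c", pos = c(100L, 200L, 5000L, 5100L),
                      ref = "A", alt = "G", gt1 = 0L, gt2 = 1L)
  blocks <- list(mkSolvedBlock(c(0L, 1L), 1:2, id = 1L),
                 mkSolvedBlock(c(1L, 0L), 3:4, id = 2L, ps = 5001L))
  genes <- data.frame(chrom = "c",
                      start = c(50L, 150L, 8000L),
                      end = c(250L, 5200L, 9000L))
  ## gene 1: both sites in block 1 -> phased; gene 2 straddles blocks;
  ## gene 3 has no het sites -> vacuously phased
  expect_equal(genePhasing(genes, blocks, sites), 2 / 3)
  ## the stricter span rule also passes gene 1 (block spans 100-201)
  expect_equal(genePhasing(genes[1, ], blocks, sites, requireSpan = FALSE), 1)
})
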