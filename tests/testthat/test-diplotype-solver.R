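test_that("brute force handles single-site and multi-allelic genotype constraints", {
  ## one 0/1 site: each read charged its minority-orientation weight
  crs <- CondensedReadSet(c("a", "b", "c"),
    data.frame(read = 1:3, col = 1, allele = c(0, 1, 1), weight = c(4, 9, 2)))
  d <- bruteForceDiplotype(crs, cbind(lo = 0L, hi = 1L))
  expect_identical(wmecCost(d), 0L)  # both alleles present in the diplotype
  expect_identical(sort(c(haplotype1(d), haplotype2(d))), c(0L, 1L))
  ## 1/2 site: haplotypes carry the called alleles, never 0
  m <- CondensedReadSet(c("a", "b"),
    data.frame(read = 1:2, col = 1, allele = c(1, 2), weight = 5))
  dm <- bruteForceDiplotype(m, cbind(lo = 1L, hi = 2L))
  expect_setequal(c(haplotype1(dm), haplotype2(dm)), c(1L, 2L))
  expect_error(bruteForceDiplotype(crs, cbind(lo = integer(0), hi = integer(0))),
               "at least one")
  big <- cbind(lo = rep(0L, 17), hi = rep(1L, 17))
  expect_error(bruteForceDiplotype(crs, big), "refused")
})

test_that("A* returns the exhaustive optimum on randomized instances", {
  set.seed(2024)
  for (rep in 1:120) {
    inst <- mkWmecInstance(sample(2:10, 1), sample(3:15, 1))
    bf <- bruteForceDiplotype(inst$reads, inst$genotypes)
    as <- solveAStar(inst$reads, inst$genotypes,
                     chunkSize = sample(c(2L, 4L, 8L), 1))
    expect_identical(wmecCost(as), wmecCost(bf))
    ## the reported cost is the true cost of the reported diplotype
    expect_identical(diplotypeCost(inst$reads, as), wmecCost(as))
    ## canonical orientation
    expect_lte(haplotype1(as)[1], haplotype2(as)[1])
  }
})

test_that("consistent error-free reads are solved at cost zero with truth recovery", {
  set.seed(55)
  inst <- mkWmecInstance(5, 20, corrupt = 0)
  d <- solveAStar(inst$reads, inst$genotypes)
  expect_identical(wmecCost(d), 0L)
  expect_true(identical(haplotype1(d), inst$truth[, 1]) ||
              identical(haplotype1(d), inst$truth[, 2]))
})

test_that("two equal-weight cohorts at a junction cost the minority weight", {
  ## 3 reads support 00/11 phase, 3 support 01/10, all weight 7
  obs <- rbind(
    do.call(rbind, lapply(1:3, function(r)
      data.frame(read = r, col = 1:2, allele = c(0, 0), weight = 7))),
    do.call(rbind, lapply(4:6, function(r)
      data.frame(read = r, col = 1:2, allele = c(0, 1), weight = 7))))
  crs <- CondensedReadSet(sprintf("r%d", 1:6), obs)
  gt <- cbind(lo = c(0L, 0L), hi = c(1L, 1L))
  d <- solveAStar(crs, gt)
  ## whichever phase wins, the 3 losing reads each pay one weight-7
  ## mismatch on their cheaper haplotype... but only at one of two sites
  expect_identical(wmecCost(d), wmecCost(bruteForceDiplotype(crs, gt)))
  expect_identical(wmecCost(d), 21L)
})

test_that("chained-chunk heuristic is admissible at every depth", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(3:9, 1)
    inst <- mkWmecInstance(n, sample(4:12, 1))
    cs <- sample(2:4, 1)
    for (j in 0:n) {
      h <- heuristicChain(inst$reads, inst$genotypes, cs, j)
      compl <- if (j == n) 0L else
        wmecCost(bruteForceDiplotype(
          restrictColumns(inst$reads, (j + 1):n),
          inst$genotypes[(j + 1):n, , drop = FALSE]))
      expect_lte(h, compl)
    }
    ## single full-width chunk at the root is the exact optimum
    expect_identical(
      heuristicChain(inst$reads, inst$genotypes, n, 0L),
      wmecCost(bruteForceDiplotype(inst$reads, inst$genotypes)))
    expect_identical(heuristicChain(inst$reads, inst$genotypes, 3L, n), 0L)
  }
})

test_that("postSplit cuts junctions without concrete spanning support", {
  sites <- VariantSet(chrom = "c", pos = c(100L, 200L, 300L, 400L),
                      ref = "A", alt = "G", gt1 = 0L, gt2 = 1L)
  gt <- blockGenotypes(sites, "c")
  ## fully supported: every junction crossed by a concrete consistent read
  obs <- do.call(rbind, lapply(1:6, function(r) {
    span <- if (r %% 2) 1:3 else 2:4
    data.frame(read = r, col = span, allele = if (r <= 3) 0 else 1,
               weight = 30)
  }))
  crs <- CondensedReadSet(sprintf("r%d", 1:6), obs, sites = 1:4)
  d <- solveAStar(crs, gt)
  blk <- PhaseBlock(1L, "c", 1:4, 101L, diplotype = d)
  expect_length(postSplit(blk, crs, sites), 1L)

  ## junction 2-3 crossed only by reads that collapsed to ambiguity there
  obs2 <- rbind(
    do.call(rbind, lapply(1:4, function(r)
      data.frame(read = r, col = 1:2, allele = if (r <= 2) 0 else 1,
                 weight = 30))),
    do.call(rbind, lapply(5:8, function(r)
      data.frame(read = r, col = 3:4, allele = if (r <= 6) 0 else 1,
                 weight = 30))),
    data.frame(read = 9, col = 2:3, allele = AMBIGUOUS_ALLELE, weight = 0))
  crs2 <- CondensedReadSet(sprintf("r%d", 1:9), obs2, sites = 1:4)
  d2 <- solveAStar(crs2, gt)
  blk2 <- PhaseBlock(1L, "c", 1:4, 101L, diplotype = d2)
  parts <- postSplit(blk2, crs2, sites)
  expect_length(parts, 2L)
  expect_identical(blockSites(parts[[1]]), 1:2)
  expect_identical(blockSites(parts[[2]]), 3:4)
  ## splitting is boundary-only: each part equals the original diplotype
  ## restricted to its sites, up to an orientation swap
  orig <- haplotype1(d2)
  for (k in 1:2) {
    cols <- if (k == 1) 1:2 else 3:4
    hk <- haplotype1(blockDiplotype(parts[[k]]))
    expect_true(identical(hk, orig[cols]) || identical(hk, 1L - orig[cols]))
  }
  ## each sub-block keeps its own phase set position
  expect_identical(phaseSet(parts[[2]]), 301L)
})
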