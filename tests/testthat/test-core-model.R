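test_that("rowCost charges only concrete mismatching observations", {
  crs <- CondensedReadSet("r1",
    data.frame(read = 1, col = 1:3, allele = c(0, 0, 1), weight = 5))
  expect_identical(rowCost(crs, c(0L, 0L, 1L)), 0L)
  expect_identical(rowCost(crs, c(1L, 1L, 0L)), 15L)
  amb <- CondensedReadSet("r1",
    data.frame(read = 1, col = 1:3, allele = c(0, AMBIGUOUS_ALLELE, 1),
               weight = c(5, 0, 7)))
  expect_identical(rowCost(amb, c(1L, 0L, 1L)), 5L)
  expect_error(rowCost(crs, c(0L, 1L)), "exceeds")
})

test_that("diplotypeCost charges each read its cheaper haplotype", {
  crs <- CondensedReadSet(c("a", "b"),
    data.frame(read = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
               allele = c(0, 0, 1, 1), weight = 10))
  d <- Diplotype(c(0L, 0L), c(1L, 1L))
  expect_identical(diplotypeCost(crs, d), 0L)
  one <- CondensedReadSet("a",
    data.frame(read = 1, col = 1:2, allele = c(0, 1), weight = c(7, 3)))
  expect_identical(diplotypeCost(one, d), 3L)
})

test_that("canonicalizeDiplotype orients h1[1] <= h2[1] without cost change", {
  d <- Diplotype(c(1L, 0L), c(0L, 1L), 4L)
  cd <- canonicalizeDiplotype(d)
  expect_identical(haplotype1(cd), c(0L, 1L))
  expect_identical(haplotype2(cd), c(1L, 0L))
  expect_identical(wmecCost(cd), 4L)
  already <- Diplotype(c(0L, 1L), c(1L, 0L), 2L)
  expect_identical(canonicalizeDiplotype(already), already)
})

test_that("cost invariants: swap symmetry, weight monotonicity, read removal", {
  set.seed(101)
  for (rep in 1:20) {
    inst <- mkWmecInstance(sample(2:6, 1), sample(3:8, 1))
    d <- bruteForceDiplotype(inst$reads, inst$genotypes)
    swapped <- Diplotype(haplotype2(d), haplotype1(d))
    expect_identical(diplotypeCost(inst$reads, d),
                     diplotypeCost(inst$reads, swapped))
    ## bumping one observation weight never decreases the cost
    ob <- readObservations(inst$reads)
    i <- sample.int(nrow(ob), 1)
    ob$weight[i] <- min(60L, ob$weight[i] + 10L)
    bumped <- CondensedReadSet(readNames(inst$reads), ob)
    expect_gte(diplotypeCost(bumped, d), diplotypeCost(inst$reads, d))
    ## dropping a read never increases the cost
    r <- sample.int(length(inst$reads), 1)
    ob2 <- readObservations(inst$reads)
    ob2 <- ob2[ob2$read != r, , drop = FALSE]
    ob2$read <- match(ob2$read, sort(unique(c(ob2$read, r))))  # keep ids valid
    ob2$read <- as.integer(ob2$read)
    dropped <- CondensedReadSet(readNames(inst$reads), ob2)
    expect_lte(diplotypeCost(dropped, d), diplotypeCost(inst$reads, d))
  }
})

test_that("class validity catches malformed objects", {
  expect_error(CondensedReadSet("r",
    data.frame(read = 1, col = c(1, 1), allele = 0:1, weight = 1)),
    "one observation")
  expect_error(CondensedReadSet("r",
    data.frame(read = 1, col = 1, allele = AMBIGUOUS_ALLELE, weight = 5)),
    "sentinel")
  expect_error(VariantSet(chrom = "c", pos = 1L, ref = "A", alt = "G",
                          gt1 = 0L, gt2 = 3L), "exceeds")
  expect_error(Diplotype(c(0L, 1L), 0L), "equal length")
})
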