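set.seed(5150)
REF400 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")

snvAt <- function(p, ref = REF400) {
  b <- substr(ref, p + 1, p + 1)
  list(ref = b, alt = setdiff(c("A", "C", "G", "T"), b)[1])
}

test_that("variant graph with no sites is the linear reference", {
  vs <- VariantSet()
  g <- buildVariantGraph(REF400, vs, "c", 0, 400)
  paths <- enumerateGraphPaths(g)
  expect_identical(nrow(paths), 1L)
  expect_identical(paths$seq, REF400)
})

test_that("a biallelic SNV contributes two one-base branches", {
  s <- snvAt(150)
  vs <- VariantSet(chrom = "c", pos = 150L, ref = s$ref, alt = s$alt,
                   gt1 = 0L, gt2 = 1L)
  g <- buildVariantGraph(REF400, vs, "c", 0, 400)
  paths <- enumerateGraphPaths(g)
  expect_identical(nrow(paths), 2L)
  expect_true(REF400 %in% paths$seq)
  want <- paste0(substr(REF400, 1, 150), s$alt, substr(REF400, 152, 400))
  expect_true(want %in% paths$seq)
})

test_that("overlapping deletions merge into one branch set of consistent joint haplotypes", {
  ## two deletions sharing ground: [100,111) and [105,116)
  d1 <- substr(REF400, 101, 111)
  d2 <- substr(REF400, 106, 116)
  vs <- VariantSet(chrom = "c", pos = c(100L, 105L), ref = c(d1, d2),
                   alt = c(substr(d1, 1, 1), substr(d2, 1, 1)),
                   gt1 = 0L, gt2 = 1L)
  g <- buildVariantGraph(REF400, vs, "c", 0, 400)
  paths <- enumerateGraphPaths(g)
  ## (0,0), (1,0), (0,1) are consistent; (1,1) physically collides
  expect_identical(nrow(paths), 3L)
  apply1 <- paste0(substr(REF400, 1, 100), substr(d1, 1, 1),
                   substr(REF400, 112, 400))
  apply2 <- paste0(substr(REF400, 1, 105), substr(d2, 1, 1),
                   substr(REF400, 117, 400))
  expect_setequal(paths$seq, c(REF400, apply1, apply2))
})

test_that("local re-alignment calls ref, alt and window ties", {
  s <- snvAt(200)
  vs <- VariantSet(chrom = "c", pos = 200L, ref = s$ref, alt = s$alt,
                   gt1 = 0L, gt2 = 1L)
  mkMap <- function(seq) list(start = 0L, end = 400L, seq = seq,
                              cigar = paste0(nchar(seq), "M"),
                              qual = strrep("?", nchar(seq)))
  refRead <- mkMap(REF400)
  obR <- assignLocal(refRead, vs, REF400, "c")
  expect_identical(obR$allele, 0L)
  expect_identical(obR$weight, 30L)
  altSeq <- paste0(substr(REF400, 1, 200), s$alt, substr(REF400, 202, 400))
  obA <- assignLocal(mkMap(altSeq), vs, REF400, "c")
  expect_identical(obA$allele, 1L)
  ## a read equidistant from both alleles: N at the site base
  nSeq <- paste0(substr(REF400, 1, 200), "N", substr(REF400, 202, 400))
  obN <- assignLocal(mkMap(nSeq), vs, REF400, "c")
  expect_identical(obN$allele, AMBIGUOUS_ALLELE)
  expect_identical(obN$weight, 0L)
  ## missing sequence degrades to all-unknown, not an error
  broken <- list(start = 0L, end = 400L, seq = NA_character_,
                 cigar = NA_character_, qual = NA_character_)
  obU <- assignLocal(broken, vs, REF400, "c")
  expect_identical(obU$allele, UNKNOWN_ALLELE)
})

test_that("global re-alignment assigns a 100 bp insertion with a capped margin", {
  set.seed(61)
  ins <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  anchor <- substr(REF400, 201, 201)
  vs <- VariantSet(chrom = "c", pos = 200L, ref = anchor,
                   alt = paste0(anchor, ins), gt1 = 0L, gt2 = 1L)
  g <- buildVariantGraph(REF400, vs, "c", 0, 400)
  altSeq <- paste0(substr(REF400, 1, 201), ins, substr(REF400, 202, 400))
  ob <- assignGlobal(list(start = 0L, end = 400L, seq = altSeq), g)
  expect_identical(ob$allele, 1L)
  expect_identical(ob$weight, 60L)   # forced-path margin, cap-bounded
  obr <- assignGlobal(list(start = 0L, end = 400L, seq = REF400), g)
  expect_identical(obr$allele, 0L)
  ## read ending before the site: unknown
  obu <- assignGlobal(list(start = 0L, end = 150L,
                           seq = substr(REF400, 1, 150)), g)
  expect_identical(obu$allele, UNKNOWN_ALLELE)
})

test_that("graph alignment cost matches the enumerated-path fitting oracle", {
  set.seed(99)
  for (rep in 1:100) {
    ref <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    nSite <- sample(1:4, 1)
    pos <- sort(sample(seq(10L, 100L, by = 12L), nSite))
    vslist <- lapply(pos, function(p) {
      kind <- sample(c("snv", "ins", "del"), 1)
      b <- substr(ref, p + 1, p + 1)
      if (kind == "snv") list(pos = p, ref = b,
                              alt = setdiff(c("A", "C", "G", "T"), b)[1])
      else if (kind == "ins") list(pos = p, ref = b,
        alt = paste0(b, paste(sample(c("A", "C", "G", "T"),
                                     sample(1:6, 1), TRUE), collapse = "")))
      else list(pos = p, ref = substr(ref, p + 1, p + 1 + sample(1:5, 1)),
                alt = b)
    })
    vs <- VariantSet(chrom = "c",
                     pos = vapply(vslist, `[[`, 0L, "pos"),
                     ref = vapply(vslist, `[[`, "", "ref"),
                     alt = vapply(vslist, `[[`, "", "alt"),
                     gt1 = 0L, gt2 = 1L)
    g <- buildVariantGraph(ref, vs, "c", 0, 120)
    paths <- enumerateGraphPaths(g)
    ## a mutated random read drawn from a random haplotype path
    src <- paths$seq[sample.int(nrow(paths), 1)]
    a <- sample.int(max(1, nchar(src) - 60), 1)
    read <- substr(src, a, a + 59)
    nmut <- sample(0:4, 1)
    if (nmut > 0) {
      ix <- sample.int(nchar(read), nmut)
      for (i in ix) substr(read, i, i) <- sample(c("A", "C", "G", "T"), 1)
    }
    got <- graphAlignCost(read, g)
    oracle <- min(vapply(paths$seq, function(p) fitDistance(read, p), 0L))
    expect_identical(got, oracle)
  }
})

test_that("global alleles and margin weights match the forced-path oracle", {
  set.seed(431)
  for (rep in 1:30) {
    ref <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    pos <- sort(sample(seq(20L, 120L, by = 25L), sample(1:3, 1)))
    b <- vapply(pos, function(p) substr(ref, p + 1, p + 1), "")
    vs <- VariantSet(chrom = "c", pos = pos, ref = b,
                     alt = vapply(b, function(x)
                       setdiff(c("A", "C", "G", "T"), x)[1], ""),
                     gt1 = 0L, gt2 = 1L)
    g <- buildVariantGraph(ref, vs, "c", 0, 150)
    paths <- enumerateGraphPaths(g)
    src <- paths$seq[sample.int(nrow(paths), 1)]
    read <- src
    for (i in sample.int(nchar(read), sample(0:3, 1)))
      substr(read, i, i) <- sample(c("A", "C", "G", "T"), 1)
    ob <- assignGlobal(list(start = 0L, end = 150L, seq = read), g)
    for (s in seq_along(pos)) {
      forced <- vapply(0:1, function(a)
        min(vapply(which(paths[[paste0("site", s)]] == a), function(p)
          fitDistance(read, paths$seq[p]), 0L)), 0L)
      if (forced[1] == forced[2]) {
        expect_identical(ob$allele[s], AMBIGUOUS_ALLELE)
        expect_identical(ob$weight[s], 0L)
      } else {
        expect_identical(ob$allele[s], which.min(forced) - 1L)
        expect_identical(ob$weight[s],
                         min(60L, as.integer(abs(diff(forced)))))
      }
    }
  }
})

test_that("collapsing unions disjoint mappings and resolves conflicts", {
  obs <- list(
    data.frame(site = 1:3, allele = c(0L, 1L, 0L), weight = c(10L, 20L, 30L)),
    data.frame(site = 9:10, allele = c(1L, 1L), weight = c(15L, 25L)),
    data.frame(site = 3L, allele = 1L, weight = 20L),
    data.frame(site = 10L, allele = 1L, weight = 40L))
  names <- c("splitread", "splitread", "splitread", "splitread")
  crs <- collapseMappings(obs, names, blockSites = 1:10)
  expect_length(crs, 1L)
  ob <- readObservations(crs)
  ## disjoint sites union; site 3 conflicts 0 vs 1 -> ambiguous, weight 0;
  ## site 10 agrees 1/1 -> max weight
  expect_identical(ob$allele[ob$col == 1], 0L)
  expect_identical(ob$allele[ob$col == 3], AMBIGUOUS_ALLELE)
  expect_identical(ob$weight[ob$col == 3], 0L)
  expect_identical(ob$allele[ob$col == 10], 1L)
  expect_identical(ob$weight[ob$col == 10], 40L)
  ## order independence
  perm <- c(4, 2, 3, 1)
  crs2 <- collapseMappings(obs[perm], names[perm], blockSites = 1:10)
  expect_identical(readObservations(crs2), ob)
})

test_that("dual mode is per-block: budget 0 forces local, ample budget equals global", {
  dir <- withr::local_tempdir()
  ds <- mkDataset(dir, refLength = 15000, snvRate = 2e-3, svCount = 1,
                  trCount = 1, coverage = 8, readLength = 1500L, seed = 23)
  aln <- readAlignments(ds$sam)
  sites <- readVariantFiles(ds$vcf, "SAMPLE")
  ref <- truthReference(ds$truth)
  sub <- aln[1:10, ]
  g <- assignBlock(sub, sites, ref, "simA", mode = "global")
  l <- assignBlock(sub, sites, ref, "simA", mode = "local")
  d0 <- assignBlock(sub, sites, ref, "simA", mode = "dual", budget = 0)
  dA <- assignBlock(sub, sites, ref, "simA", mode = "dual", budget = 1e12)
  expect_true(d0$fallback)
  expect_identical(d0$observations, l$observations)
  expect_false(dA$fallback)
  expect_identical(dA$observations, g$observations)
})

test_that("error-free global assignment reproduces each read's source alleles", {
  dir <- withr::local_tempdir()
  ds <- mkDataset(dir, refLength = 15000, snvRate = 2e-3, indelRate = 5e-4,
                  svCount = 1, trCount = 1, coverage = 6,
                  readLength = 1500L, seed = 29)
  aln <- readAlignments(ds$sam)
  sites <- readVariantFiles(ds$vcf, "SAMPLE")
  vs <- truthVariants(ds$truth)
  th <- truthHaplotypes(ds$truth)
  recs <- simRecords(ds$sim)
  ref <- truthReference(ds$truth)
  asg <- assignBlock(aln, sites, ref, "simA", mode = "global")
  for (i in seq_len(nrow(aln))) {
    ob <- asg$observations[[i]]
    ob <- ob[ob$allele != UNKNOWN_ALLELE, , drop = FALSE]
    ri <- which(recs$readName == aln$readName[i] &
                recs$supplementary == aln$supplementary[i])[1]
    hap <- recs$hap[ri]
    for (j in seq_len(nrow(ob)))
      expect_identical(ob$allele[j], unname(th[ob$site[j], hap]))
  }
})
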