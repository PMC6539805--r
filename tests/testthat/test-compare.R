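test_that("anchor chain structure reflects planted differences", {
  trio <- sharedTrio()
  a <- trio$genomes$A[[1]]
  ## identical genomes: one anchor covering everything
  ch <- buildAnchorChain(a, a)
  expect_equal(nrow(ch@segments), 1L)
  expect_equal(ch@segments$length, genomeLength(a))
  ## one planted SNP: two anchors flanking the position
  s <- genomeSeq(a)
  p <- 15000L
  alt <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  b <- annotatedGenome("mut", paste0(substr(s, 1, p - 1), alt,
                                     substr(s, p + 1, nchar(s))))
  ch2 <- buildAnchorChain(a, b)
  expect_equal(nrow(ch2@segments), 2L)
  expect_equal(ch2@segments$endA[1], p - 1L)
  expect_equal(ch2@segments$startA[2], p + 1L)
  v <- callVariants(ch2, a, b)
  expect_equal(nrow(v), 1L)
  expect_equal(v$posA, p)
  expect_equal(v$alt, alt)
})

test_that("identical sequences yield zero variants and no inversions", {
  trio <- sharedTrio()
  a <- trio$genomes$A[[1]]
  ch <- buildAnchorChain(a, a)
  expect_equal(nrow(callVariants(ch, a, a)), 0L)
  expect_equal(nrow(detectInversions(ch, a, a)), 0L)
})

test_that("intraspecies calls equal the planted truth exactly", {
  trio <- sharedTrio()
  for (sp in c("A", "C")) {
    a <- trio$genomes[[sp]][[1]]
    b <- trio$genomes[[sp]][[2]]
    v <- callVariants(buildAnchorChain(a, b), a, b)
    tv <- trio$truth$intraspecies[[sp]]
    expect_equal(v[, c("kind", "posA", "ref", "alt")],
                 tv[, c("kind", "posA", "ref", "alt")],
                 ignore_attr = TRUE)
  }
  b <- trio$genomes$B
  expect_equal(nrow(callVariants(buildAnchorChain(b[[1]], b[[2]]),
                                 b[[1]], b[[2]])), 0L)
})

test_that("variant calling is symmetric up to allele polarity", {
  trio <- sharedTrio()
  a <- trio$genomes$A[[1]]
  b <- trio$genomes$A[[2]]
  vab <- callVariants(buildAnchorChain(a, b), a, b)
  vba <- callVariants(buildAnchorChain(b, a), b, a)
  expect_equal(nrow(vab), nrow(vba))
  expect_equal(vab$posA, vba$posB)
  expect_equal(vab$ref, vba$alt)
  expect_equal(vab$alt, vba$ref)
})

test_that("a planted inversion is recovered with exact breakpoints", {
  trio <- sharedTrio()
  a <- trio$genomes$A[[1]]
  bB <- trio$genomes$B[[1]]
  ch <- buildAnchorChain(a, bB)
  inv <- detectInversions(ch, a, bB)
  expect_equal(nrow(inv), 1L)
  tru <- trio$truth$inversion
  expect_equal(c(inv$startA, inv$endA), tru$intervalA)
  expect_equal(c(inv$startB, inv$endB), tru$intervalB)
  expect_equal(inv$length, tru$length)
  expect_false(inv$unresolved)
  expect_setequal(strsplit(inv$genes, ",")[[1]], tru$genes)
  ## a freshly planted small inversion in a random leaf
  set.seed(77)
  s <- genomeSeq(a)
  x <- 5000L; y <- 5299L
  b2 <- annotatedGenome("inv300", paste0(substr(s, 1, x - 1),
                                         rcOracle(substr(s, x, y)),
                                         substr(s, y + 1, nchar(s))))
  inv2 <- detectInversions(buildAnchorChain(a, b2), a, b2)
  expect_equal(c(inv2$startA, inv2$endA, inv2$length), c(x, y, 300L))
})

test_that("applying called variants and inversions reconstructs the target", {
  trio <- sharedTrio()
  a <- trio$genomes$A[[1]]
  for (other in list(trio$genomes$A[[2]], trio$genomes$B[[1]],
                     trio$genomes$C[[1]])) {
    ch <- buildAnchorChain(a, other)
    v <- callVariants(ch, a, other)
    inv <- detectInversions(ch, a, other)
    expect_identical(applyVariants(a, v, inv), genomeSeq(other))
  }
})

test_that("interspecies calls recover the planted branch events", {
  trio <- sharedTrio()
  key <- function(d) paste(d$kind, d$posA, d$ref, d$alt)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    x <- trio$genomes[[pr[1]]][[1]]
    y <- trio$genomes[[pr[2]]][[1]]
    v <- callVariants(buildAnchorChain(x, y), x, y)
    tv <- trio$truth$pairVariants[[paste(pr, collapse = "_")]]
    expect_gte(mean(key(tv) %in% key(v)), 0.95)
  }
})

test_that("oversized gaps are refused as structural events", {
  set.seed(9)
  s <- randomDna(3000)
  a <- annotatedGenome("a", s)
  b <- annotatedGenome("b", paste0(substr(s, 1, 1500), randomDna(900),
                                   substr(s, 1501, 3000)))
  ch <- buildAnchorChain(a, b)
  expect_error(callVariants(ch, a, b, maxGapLength = 500L), "maxGapLength")
  expect_equal(nrow(callVariants(ch, a, b, maxGapLength = 2000L)), 1L)
})

test_that("variants are classified genic or intergenic against the annotation", {
  trio <- sharedTrio()
  a <- trio$genomes$A[[1]]
  f <- genomeFeatures(a)
  gene1 <- S4Vectors::mcols(f)$gene[1]
  pIn <- IRanges::start(f)[1] + 5L
  pOut <- IRanges::end(f)[1] + 5L      # inside the following spacer
  s <- genomeSeq(a)
  mut <- function(p) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    annotatedGenome("m", paste0(substr(s, 1, p - 1), alt,
                                substr(s, p + 1, nchar(s))),
                    features = NULL)
  }
  v1 <- callVariants(buildAnchorChain(a, mut(pIn)), a, mut(pIn))
  expect_match(v1$class, paste0("^genic:", gene1, "$"))
  v2 <- callVariants(buildAnchorChain(a, mut(pOut)), a, mut(pOut))
  expect_match(v2$class, "^intergenic:")
  expect_match(v2$class, gene1, fixed = TRUE)
})

test_that("45S region tallies match planted counts and flag heterogeneous sites", {
  c45 <- shared45()
  tl <- tallyRegionVariants(c45$units)
  expect_equal(unname(tl$counts), unname(c45$truth$regionCounts))
  expect_equal(tl$total, c45$truth$total)
  expect_equal(tl$heterogeneousSites, c45$truth$heterogeneousSite)
  ## identical units: all-zero tally
  u <- c45$units$A
  threes <- list(u, cistronUnit("c2", cistronSeq(u)),
                 cistronUnit("c3", cistronSeq(u)))
  t0 <- tallyRegionVariants(threes)
  expect_equal(sum(t0$counts), 0L)
})
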