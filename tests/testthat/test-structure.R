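test_that("a planted toy IR is found exactly, matching the exhaustive oracle", {
  set.seed(101)
  n <- 600L
  s <- randomDna(n)
  arm <- substr(s, 51, 110)
  s <- paste0(substr(s, 1, 300), rcOracle(arm), substr(s, 361, n))
  g <- annotatedGenome("toy", s)
  ir <- detectInvertedRepeats(g, minIrLength = 30L, seedK = 15L)
  bf <- bruteForceIr(s, 30L)
  expect_equal(irLength(ir), bf$len)
  armStarts <- sort(c(PlastomeAuth::junctions(partitionQuadripartite(g, ir))[
    c("J_LSC_IRb", "J_SSC_IRa")]))
  expect_equal(unname(armStarts), sort(c(bf$arm1, bf$arm2)))
  ## arms are exact reverse complements with zero mismatches
  expect_equal(ir@mismatches, 0L)
})

test_that("random sequence without a planted IR yields the absence signal", {
  set.seed(7)
  g <- annotatedGenome("r", randomDna(2000))
  expect_null(detectInvertedRepeats(g, minIrLength = 100L))
})

test_that("quadripartite partition tiles the circle and labels LSC correctly", {
  ## toy circle, arms [11,20] and [61,70] (1-based), equal gaps: tie rule
  set.seed(5)
  base <- randomDna(100)
  arm <- substr(base, 11, 20)
  s <- paste0(substr(base, 1, 60), rcOracle(arm), substr(base, 71, 100))
  g <- annotatedGenome("tie", s)
  ir <- detectInvertedRepeats(g, minIrLength = 8L, seedK = 8L)
  p <- partitionQuadripartite(g, ir)
  expect_equal(sum(regionLengths(p)), 100L)
  ## tie: the gap following IRa is the LSC, so IRb gets the smallest start
  expect_equal(IRanges::start(p@irb), min(IRanges::start(ir@ira),
                                          IRanges::start(ir@irb)))
})

test_that("partition intervals sum to the genome length on the trio", {
  trio <- sharedTrio()
  for (sp in c("A", "B", "C")) {
    g <- trio$genomes[[sp]][[1]]
    ir <- detectInvertedRepeats(g)
    p <- partitionQuadripartite(g, ir)
    expect_equal(sum(regionLengths(p)), genomeLength(g))
    expect_true(regionLengths(p)["LSC"] >= regionLengths(p)["SSC"])
    ## arms are exact reverse complements
    s <- genomeSeq(g)
    a1 <- circSubstr(s, IRanges::start(p@irb), IRanges::end(p@irb))
    a2 <- circSubstr(s, IRanges::start(p@ira), IRanges::end(p@ira))
    expect_identical(a2, rcOracle(a1))
  }
})

test_that("detected junctions equal the planted junctions on the trio", {
  trio <- sharedTrio()
  for (sp in c("A", "B", "C")) {
    g <- trio$genomes[[sp]][[1]]
    ir <- detectInvertedRepeats(g)
    expect_equal(irLength(ir), trio$truth$irLength[[sp]])
    p <- partitionQuadripartite(g, ir)
    expect_equal(junctions(p), trio$truth$junctions[[sp]],
                 ignore_attr = FALSE)
  }
})

test_that("IR gene-content diff reports the genes captured by the expansion", {
  trio <- sharedTrio()
  gs <- lapply(trio$genomes, `[[`, 1)
  irs <- lapply(gs, detectInvertedRepeats)
  ps <- Map(partitionQuadripartite, gs, irs)
  d <- irGeneContentDiff(gs$B, ps$B, gs$A, ps$A)
  expect_setequal(d$gainedInA, trio$truth$irGainedGenes)
  expect_length(d$gainedInB, 0L)
  ## identity comparison is empty
  d2 <- irGeneContentDiff(gs$A, ps$A, gs$A, ps$A)
  expect_length(d2$gainedInA, 0L)
  expect_length(d2$gainedInB, 0L)
})

test_that("structureTable reports lengths and junctions per accession", {
  trio <- sharedTrio()
  gs <- lapply(trio$genomes, `[[`, 1)
  irs <- lapply(gs, detectInvertedRepeats)
  ps <- Map(partitionQuadripartite, gs, irs)
  tab <- structureTable(gs, ps)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$LSC + tab$IRb + tab$SSC + tab$IRa, tab$length)
})
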