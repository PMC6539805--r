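test_that("identical seeds give byte-identical trios", {
  t1 <- generateGenomeTrio(trioSpec(seed = 5))
  t2 <- generateGenomeTrio(trioSpec(seed = 5))
  for (sp in c("A", "B", "C")) for (acc in 1:2)
    expect_identical(genomeSeq(t1$genomes[[sp]][[acc]]),
                     genomeSeq(t2$genomes[[sp]][[acc]]))
  expect_identical(t1$truth$pairVariants, t2$truth$pairVariants)
  c1 <- generate45STrio(seed = 5)
  c2 <- generate45STrio(seed = 5)
  expect_identical(cistronSeq(c1$units$C), cistronSeq(c2$units$C))
})

test_that("different seeds give different genomes", {
  t1 <- sharedTrio()
  t2 <- generateGenomeTrio(trioSpec(seed = 5))
  expect_false(identical(genomeSeq(t1$genomes$A[[1]]),
                         genomeSeq(t2$genomes$A[[1]])))
})

test_that("the truth table is consistent with the emitted sequences", {
  trio <- sharedTrio()
  tru <- trio$truth
  ## TR loci: the recorded interval holds exactly `copies` unit copies
  for (sp in c("A", "B", "C")) {
    s <- genomeSeq(trio$genomes[[sp]][[1]])
    for (i in seq_len(nrow(tru$trLoci))) {
      cp <- tru$trLoci[[paste0("copies_", sp)]][i]
      if (cp == 0L) next
      st <- tru$trLoci[[paste0("start_", sp)]][i]
      en <- tru$trLoci[[paste0("end_", sp)]][i]
      expect_identical(substr(s, st, en), strrep(tru$trLoci$unit[i], cp),
                       info = paste(tru$trLoci$id[i], sp))
    }
  }
  ## the inversion interval in B is the reverse complement of A's interval
  sA <- genomeSeq(trio$genomes$A[[1]])
  sB <- genomeSeq(trio$genomes$B[[1]])
  ia <- tru$inversion$intervalA; ib <- tru$inversion$intervalB
  expect_identical(substr(sB, ib[1], ib[2]),
                   rcOracle(substr(sA, ia[1], ia[2])))
  ## intraspecies truth reproduces accession 2 from accession 1
  for (sp in c("A", "C")) {
    g1 <- trio$genomes[[sp]][[1]]; g2 <- trio$genomes[[sp]][[2]]
    expect_identical(applyVariants(g1, tru$intraspecies[[sp]]), genomeSeq(g2))
  }
})

test_that("accession pairs differ only by the planted intraspecies variants", {
  trio <- sharedTrio()
  expect_identical(genomeSeq(trio$genomes$B[[1]]),
                   genomeSeq(trio$genomes$B[[2]]))
  expect_false(identical(genomeSeq(trio$genomes$A[[1]]),
                         genomeSeq(trio$genomes$A[[2]])))
})

test_that("rate limits and degenerate specs are rejected", {
  expect_error(trioSpec(substRate = c(A = 0.2, B = 0.001, C = 0.004,
                                      internal = 0.0015)))
  expect_error(trioSpec(nGenes = 10L))
  expect_error(trioSpec(ancestorLength = 10000L))
})

test_that("a zero-rate multiplier-1 45S trio is three identical units", {
  c0 <- generate45STrio(seed = 9,
                        baseRates = c(A = 0, B = 0, C = 0, internal = 0),
                        itsMultiplier = 1, heterogeneousSite = FALSE)
  expect_identical(cistronSeq(c0$units$A), cistronSeq(c0$units$B))
  expect_identical(cistronSeq(c0$units$A), cistronSeq(c0$units$C))
  expect_equal(sum(c0$truth$regionCounts), 0L)
  tl <- tallyRegionVariants(c0$units)
  expect_equal(sum(tl$counts), 0L)
})

test_that("ITS substitution density exceeds rRNA-gene density over seeds", {
  itsD <- rRnaD <- numeric(0)
  for (seed in 1:20) {
    tr <- generate45STrio(seed = seed)$truth
    cnt <- tr$regionCounts
    itsD <- c(itsD, sum(cnt[c("ITS1", "ITS2")]) / (250 + 230))
    rRnaD <- c(rRnaD, sum(cnt[c("18S", "5.8S", "26S")]) / (1800 + 160 + 3380))
  }
  expect_gt(mean(itsD), mean(rRnaD))
})
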