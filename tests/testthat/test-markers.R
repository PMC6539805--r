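test_that("in-silico PCR returns exact planted distances, linear and circular", {
  set.seed(41)
  fwd <- "GACCTGAACGTCTAGGCTCA"
  rev_ <- "CAGGTCCATGAACTTCAGGT"        # primer; its revcomp sits on the template
  mid <- randomDna(200)
  s <- paste0(randomDna(150), fwd, mid, rcOracle(rev_), randomDna(150))
  g <- annotatedGenome("lin", s, circular = FALSE)
  amp <- inSilicoPcr(g, c(F = fwd, R = rev_))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, nchar(fwd) + 200L + nchar(rev_))
  expect_equal(amp$start, 151L)
  ## same template circularised and rotated so the product spans the origin
  gc <- annotatedGenome("circ", paste0(substr(s, 301, nchar(s)),
                                       substr(s, 1, 300)))
  amp2 <- inSilicoPcr(gc, c(F = fwd, R = rev_))
  expect_equal(amp2$size, nchar(fwd) + 200L + nchar(rev_))
  expect_gt(amp2$end, genomeLength(gc))   # origin-spanning
  ## a primer absent from the template: no amplicon
  expect_equal(nrow(inSilicoPcr(g, c(F = fwd, R = "ACGTACGTACGTACGTACGT"))), 0L)
  ## primers containing N are rejected
  expect_error(inSilicoPcr(g, c(F = "ACGTNACGTACGTACGTACG", R = rev_)), "N")
})

test_that("product size is inclusive of both primer footprints", {
  set.seed(42)
  for (i in 1:10) {
    d <- sample(80:400, 1)
    fwd <- randomDna(20); rev_ <- randomDna(20)
    s <- paste0(randomDna(100), fwd, randomDna(d - 40), rcOracle(rev_),
                randomDna(100))
    g <- annotatedGenome("t", s, circular = FALSE)
    amp <- inSilicoPcr(g, c(F = fwd, R = rev_))
    if (nrow(amp) == 1L) expect_equal(amp$size, d)
  }
})

test_that("the three-primer junction assay amplifies the junction band only in the expanded leaf", {
  trio <- sharedTrio()
  refs <- lapply(trio$genomes, `[[`, 1)
  irs <- lapply(refs, detectInvertedRepeats)
  parts <- Map(partitionQuadripartite, refs, irs)
  asy <- designAssay(list(expanded = "B", partitions = parts), refs,
                     kind = "three_primer", id = "IR01")
  expect_s4_class(asy, "MarkerAssay")
  ex <- expectedProducts(asy)
  ctrl <- intersect(intersect(ex$A, ex$B), ex$C)
  expect_length(ctrl, 1L)                       # control band in all leaves
  expect_length(ex$A, 1L)
  expect_length(ex$C, 1L)
  expect_length(ex$B, 2L)                       # junction band only in B
  junctionBand <- setdiff(ex$B, ctrl)
  expect_length(junctionBand, 1L)
})

test_that("marker loci respect the size threshold and intraspecies exclusion", {
  set.seed(43)
  ## three "species": a 3-bp deletion locus (below minDelta) and an 8-bp
  ## locus; species A additionally carries an intraspecies SNP near a third
  ## 10-bp locus, which must be excluded
  core <- randomDna(6000)
  cut <- function(s, at, len) paste0(substr(s, 1, at - 1),
                                     substr(s, at + len, nchar(s)))
  gA <- core
  gB <- cut(cut(core, 4000, 10), 2000, 8)
  gC <- cut(core, 1000, 3)
  genomes <- list(A = annotatedGenome("A", gA),
                  B = annotatedGenome("B", gB),
                  C = annotatedGenome("C", gC))
  mkVar <- function(pos) data.frame(kind = "SNP", posA = pos, posB = pos,
                                    ref = "A", alt = "G", length = 1L,
                                    class = "intergenic:NA")
  inter <- rbind(
    data.frame(kind = "indel", posA = 1000, posB = 1000, ref = substr(core, 1000, 1002),
               alt = "-", length = 3L, class = "intergenic:NA"),
    data.frame(kind = "indel", posA = 2000, posB = 1997, ref = substr(core, 2000, 2007),
               alt = "-", length = 8L, class = "intergenic:NA"),
    data.frame(kind = "indel", posA = 4000, posB = 3989, ref = substr(core, 4000, 4009),
               alt = "-", length = 10L, class = "intergenic:NA"))
  ## without intraspecies variants: the 3-bp locus is below minDelta
  loci <- selectMarkerLoci(genomes, interVariants = inter, minDelta = 4L)
  expect_setequal(loci$maxDelta, c(8L, 10L))
  ## an intraspecies SNP within the flank kills the 10-bp locus
  loci2 <- selectMarkerLoci(genomes, interVariants = inter,
                            intraVariants = list(A = mkVar(4080)),
                            minDelta = 4L)
  expect_equal(loci2$maxDelta, 8L)
})

test_that("designed pair assays separate species by the planted size difference", {
  trio <- sharedTrio()
  refs <- lapply(trio$genomes, `[[`, 1)
  trs <- lapply(refs, findTandemRepeats)
  cnv <- buildCnvCatalog(trs, refs)
  loci <- selectMarkerLoci(refs, cnvCatalog = cnv,
                           intraVariants = trio$truth$intraspecies)
  expect_gt(nrow(loci), 0L)
  cnvLoci <- loci[loci$type == "cnv", ]
  asy <- designAssay(cnvLoci[1, ], refs, kind = "pair", id = cnvLoci$id[1])
  expect_s4_class(asy, "MarkerAssay")
  ex <- expectedProducts(asy)
  sizes <- vapply(ex, `[`, numeric(1), 1)
  want <- unlist(cnvLoci[1, paste0("size_", c("A", "B", "C"))])
  ## product size differences equal the locus size differences
  expect_equal(unname(sizes - sizes[["A"]]), unname(want - want[["size_A"]]))
  ## assay expectation matches a fresh in-silico PCR recomputation
  for (sp in names(refs))
    expect_equal(ex[[sp]],
                 sort(unique(inSilicoPcr(refs[[sp]], assayPrimers(asy))$size)))
})

test_that("the allele-specific cistron assay amplifies only its target", {
  c45 <- shared45()
  asy <- PlastomeAuth:::.designCistronAssay(c45$units)
  expect_s4_class(asy, "MarkerAssay")
  ex <- expectedProducts(asy)
  nBands <- vapply(ex, length, integer(1))
  target <- names(which.max(nBands))
  expect_equal(unname(sort(nBands)), c(1L, 1L, 2L))
  ## the control band is shared by everyone
  ctrl <- Reduce(intersect, ex)
  expect_length(ctrl, 1L)
})

test_that("an uninformative panel is reported unresolved", {
  trio <- sharedTrio()
  refs <- lapply(trio$genomes, `[[`, 1)
  ## a control-style assay in a conserved region amplifies equally everywhere
  s <- genomeSeq(refs$A)
  win <- substr(s, 200, 420)     # inside the conserved LSC head
  pp <- PlastomeAuth:::.pickPrimerPair(substr(win, 1, 110),
                                       substr(win, 112, 221))
  asy <- new("MarkerAssay", id = "CTRL", kind = "pair",
             primers = c(F = pp$F, R = pp$R), targetLocus = "conserved",
             expected = list())
  disc <- discriminationMatrix(list(asy), refs)
  expect_false(disc$resolved)
  expect_length(disc$unresolvedPairs, 3L)
})
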