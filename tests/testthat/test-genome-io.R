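test_that("FASTA + feature table and GenBank round-trip an annotated genome", {
  trio <- sharedTrio()
  g <- trio$genomes$B[[1]]
  td <- withr::local_tempdir()

  gb <- file.path(td, "b.gb")
  writeGenome(g, gb, format = "genbank")
  g2 <- readGenome(gb)
  expect_identical(genomeSeq(g2), genomeSeq(g))
  expect_identical(genomeId(g2), genomeId(g))
  expect_true(isCircular(g2))
  fd <- function(x) {
    d <- as.data.frame(genomeFeatures(x))[, c("start", "end", "strand")]
    d$gene <- S4Vectors::mcols(genomeFeatures(x))$gene
    d[order(d$start, d$gene), ]
  }
  expect_equal(fd(g2), fd(g), ignore_attr = TRUE)

  fa <- file.path(td, "b.fa")
  writeGenome(g, fa, format = "fasta")
  g3 <- readGenome(fa, featureTable = paste0(fa, ".features.tsv"))
  expect_identical(genomeSeq(g3), genomeSeq(g))
  expect_equal(fd(g3), fd(g), ignore_attr = TRUE)
})

test_that("minimal FASTA input yields a featureless genome", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "x.fa")
  writeLines(c(">x", "ACGT"), fa)
  g <- readGenome(fa, circular = FALSE)
  expect_equal(genomeLength(g), 4L)
  expect_length(genomeFeatures(g), 0L)
})

test_that("malformed input is rejected with informative errors", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "bad.fa")
  writeLines(c(">x", "ACGQT"), fa)
  expect_error(readGenome(fa), "non-ACGTN residue 'Q' at position 4")
  gb <- file.path(td, "bad.gb")
  writeLines(c("not a genbank file", "at all"), gb)
  expect_error(readGenome(gb, format = "genbank"), "LOCUS")
  expect_error(readGenome(file.path(td, "missing.gb")), "not found")
})

test_that("GenBank locations support complement, join and origin spanning", {
  td <- withr::local_tempdir()
  gb <- file.path(td, "j.gb")
  n <- 60L
  sq <- strrep("ACGTTGCAAC", 6L)
  writeLines(c(
    "LOCUS       toy 60 bp DNA circular PLN",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(11..22)",
    '                     /gene="g1"',
    "     tRNA            join(55..60,1..6)",
    '                     /gene="g2"',
    "ORIGIN",
    paste("        1", tolower(sq)),
    "//"), gb)
  g <- readGenome(gb)
  f <- genomeFeatures(g)
  expect_equal(S4Vectors::mcols(f)$gene, c("g1", "g2"))
  g2row <- f[S4Vectors::mcols(f)$gene == "g2"]
  expect_equal(IRanges::start(g2row), 55L)
  expect_equal(IRanges::end(g2row), 66L)      # unwrapped over the origin
  expect_identical(extractFeatureSequence(g, "g2"),
                   paste0(substr(sq, 55, 60), substr(sq, 1, 6)))
  g1row <- f[S4Vectors::mcols(f)$gene == "g1"]
  expect_identical(extractFeatureSequence(g, g1row),
                   rcOracle(substr(sq, 11, 22)))
})

test_that("feature extraction handles strand and the circular origin", {
  g <- annotatedGenome("t", "ATGCCC")
  gr <- function(s, e, st) GenomicRanges::GRanges("t", IRanges::IRanges(s, e),
                                                  strand = st)
  expect_identical(extractFeatureSequence(g, gr(1, 3, "+")), "ATG")
  expect_identical(extractFeatureSequence(g, gr(5, 8, "+")), "CCAT")
  expect_identical(extractFeatureSequence(g, gr(1, 3, "-")), "CAT")
  ## double reverse complement is the identity; width matches the interval
  for (i in 1:20) {
    s <- sample(1:6, 1); e <- s + sample(0:5, 1)
    sq <- extractFeatureSequence(g, gr(s, e, "+"))
    expect_identical(rcOracle(rcOracle(sq)), sq)
    expect_equal(nchar(sq), e - s + 1L)
  }
  expect_error(extractFeatureSequence(g, gr(2, 10, "+")), "outside circular")
})

test_that("orientation normalisation recovers rotation and reverse complement", {
  trio <- sharedTrio()
  ref <- trio$genomes$A[[1]]
  rot <- rotateGenome(ref, 1001L)
  expect_identical(genomeSeq(normalizeOrientation(rot, ref)), genomeSeq(ref))
  rc <- revcompGenome(rot)
  back <- normalizeOrientation(rc, ref)
  expect_identical(genomeSeq(back), genomeSeq(ref))
  ## idempotent, and identity on an already-normalised genome
  expect_identical(genomeSeq(normalizeOrientation(back, ref)), genomeSeq(ref))
  ## features remap consistently: same strand-corrected gene sequences
  expect_identical(extractFeatureSequence(back, "rbcL"),
                   extractFeatureSequence(ref, "rbcL"))
  set.seed(4242)   # a fresh stream, uncorrelated with the trio generator
  expect_error(normalizeOrientation(annotatedGenome("r", randomDna(500)), ref),
               "unrelated genomes")
})

test_that("rotation and reverse complement remap features consistently", {
  trio <- sharedTrio()
  g <- trio$genomes$C[[1]]
  for (gg in list(rotateGenome(g, 7777L), revcompGenome(g))) {
    for (gene in c("psbA", "ycf1", "rpl32"))
      expect_identical(extractFeatureSequence(gg, gene),
                       extractFeatureSequence(g, gene))
  }
})
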