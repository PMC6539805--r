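test_that("a textbook tandem array is reported with primitive unit and phase", {
  set.seed(21)
  ## 10-bp unit, 3 copies, unique flanks; guard the edges so the array
  ## cannot extend by chance
  unit <- "AATGAGCCGT"
  left <- "CCCTTTGGGACCACTGTCAC"
  right <- "TGAGTTCAAGCTTGACTGCA"
  g <- annotatedGenome("t", paste0(left, strrep(unit, 3), right),
                       circular = FALSE)
  tr <- findTandemRepeats(g, minUnit = 10, maxUnit = 39, minCopies = 2)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, unit)
  expect_equal(tr$copies, 3L)
  expect_equal(tr$start, nchar(left) + 1L)
})

test_that("no reported unit is a repetition of a shorter unit", {
  set.seed(22)
  for (rep_ in 1:5) {
    g <- annotatedGenome("r", randomDna(5000), circular = FALSE)
    tr <- findTandemRepeats(g, minUnit = 2, maxUnit = 20, minCopies = 2,
                            minSpan = 4)
    for (u in tr$unit) {
      L <- nchar(u)
      for (d in seq_len(L %/% 2)) {
        if (L %% d == 0)
          expect_false(identical(u, strrep(substr(u, 1, d), L / d)))
      }
    }
  }
})

test_that("planted arrays are recovered with exact copy numbers", {
  set.seed(23)
  units <- c("TAGTGACGATATTGATGC", "TTCTATTTCTTTTCTATATATG",
             "AAATATTAATCTACTTCT", "ACCGAAAGGAAAAGCGTGAA",
             "TATATTGTTATAAT", "TTATACAAGGTACTTAAATGTAAA",
             "AAACTCTCTTCAAGAGTTATTAACACCAACCCGGTGTTC")
  copies <- c(4L, 3L, 2L, 2L, 5L, 2L, 2L)
  flank <- function(n) randomDna(n)
  parts <- character(0)
  for (i in seq_along(units)) {
    repeat {
      fl <- flank(700)
      ## edge guard: flanking bases must not extend the array
      if (substr(fl, 700, 700) != substr(units[i], nchar(units[i]),
                                         nchar(units[i]))) break
    }
    parts <- c(parts, fl, strrep(units[i], copies[i]))
  }
  parts <- c(parts, flank(700))
  g <- annotatedGenome("p", paste(parts, collapse = ""), circular = FALSE)
  tr <- findTandemRepeats(g)
  found <- tr[tr$unit %in% units, ]
  expect_equal(nrow(found), length(units))
  expect_equal(found$copies[match(units, found$unit)], copies)
})

test_that("the CNV catalog matches loci by flanks and drops non-CNVs", {
  trio <- sharedTrio()
  refs <- lapply(trio$genomes, `[[`, 1)
  trs <- lapply(refs, findTandemRepeats)
  cnv <- buildCnvCatalog(trs, refs)
  tru <- trio$truth$trLoci
  for (i in seq_len(nrow(tru))) {
    hit <- cnv[cnv$unit == tru$unit[i], ]
    expect_equal(nrow(hit), 1L, info = tru$id[i])
    for (sp in c("A", "B", "C")) {
      want <- tru[[paste0("copies_", sp)]][i]
      want <- if (want == 0L) "nf" else as.character(want)
      expect_identical(hit[[paste0("copies_", sp)]], want,
                       info = paste(tru$id[i], sp))
    }
  }
  ## equal copy vectors are not CNVs
  expect_true(all(apply(cnv[, paste0("copies_", c("A", "B", "C"))], 1,
                        function(v) length(unique(v)) > 1) | cnv$ambiguous))
})

test_that("every CNV locus has a matching indel in the interspecies calls", {
  trio <- sharedTrio()
  refs <- lapply(trio$genomes, `[[`, 1)
  tru <- trio$truth$trLoci
  varies <- tru[tru$copies_A != tru$copies_B, ]
  v <- callVariants(buildAnchorChain(refs$A, refs$B), refs$A, refs$B)
  ind <- v[v$kind == "indel", ]
  for (i in seq_len(nrow(varies))) {
    near <- abs(ind$posA - varies$start_A[i]) <=
      (abs(varies$copies_A[i] - varies$copies_B[i]) * varies$unitLength[i] +
         varies$unitLength[i] + 5L)
    expect_true(any(near), info = varies$id[i])
  }
})
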