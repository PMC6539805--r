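test_that("identical CDS give Ka = Ks = 0 and class 'identical'", {
  set.seed(31)
  cds <- PlastomeAuth:::.randomCds(300L)
  r <- kaksNG86(codonAlign(cds, cds, gene = "g"))
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_identical(r$class, "identical")
})

test_that("single synonymous change matches first-principles counting", {
  ## TTT -> TTC (Phe -> Phe): Sd = 1, Nd = 0; per-codon synonymous sites
  ## are 1/3 for both codons, so S = 1/3 and pS = 3 (JC-undefined)
  aln <- list(gene = "toy", codonsA = "TTT", codonsB = "TTC",
              excludedCodons = 0L)
  r <- kaksNG86(aln)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 1 / 3)
  expect_equal(ng86Oracle$synSites("TTT"), 1 / 3)
  expect_equal(ng86Oracle$synSites("TTC"), 1 / 3)
  expect_true(is.na(r$Ks))            # pS = 3 >= 3/4 saturates the correction
  expect_equal(r$Ka, 0)
})

test_that("pathway counting agrees with the recursive oracle on sampled pairs", {
  set.seed(32)
  pc <- PlastomeAuth:::.pairCounts()
  sense <- ng86Oracle$sense
  pairs <- cbind(sample(sense, 120, replace = TRUE),
                 sample(sense, 120, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (a == b) next
    o <- ng86Oracle$pathCounts(a, b)
    expect_equal(pc$Sd[a, b], unname(o["Sd"]), info = paste(a, b))
    expect_equal(pc$Nd[a, b], unname(o["Nd"]), info = paste(a, b))
  }
  ## site counts agree too
  syn <- PlastomeAuth:::.synSites()
  for (cod in sample(sense, 20))
    expect_equal(unname(syn[cod]), ng86Oracle$synSites(cod), info = cod)
})

test_that("Ka and Ks are symmetric in argument order", {
  set.seed(33)
  a <- PlastomeAuth:::.randomCds(240L)
  ## ~8 random substitutions avoiding stops
  sv <- strsplit(a, "")[[1]]
  ct <- PlastomeAuth:::.codonTable()
  for (i in 1:12) {
    p <- sample(4:(length(sv) - 3), 1)
    old <- sv[p]
    sv[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    c0 <- ((p - 1) %/% 3) * 3 + 1
    if (ct$aa[[paste(sv[c0:(c0 + 2)], collapse = "")]] == "*") sv[p] <- old
  }
  b <- paste(sv, collapse = "")
  r1 <- kaksNG86(codonAlign(a, b, gene = "f"))
  r2 <- kaksNG86(codonAlign(b, a, gene = "r"))
  expect_equal(r1$Ka, r2$Ka)
  expect_equal(r1$Ks, r2$Ks)
})

test_that("codon alignment excludes gap codons and rejects internal stops", {
  a <- codonAlign("ATGAAA", "ATGAAAGAT", gene = "g")
  expect_equal(a$excludedCodons, 1L)
  expect_length(a$codonsA, 2L)
  expect_error(codonAlign("ATGTAAAAA", "ATGAAAAAA", gene = "g"),
               "internal stop codon at codon 2")
  expect_error(codonAlign("ATGAA", "ATGAAA", gene = "g"), "multiple of 3")
})

test_that("the trio screen finds identical genes and elevated divergence to C", {
  trio <- sharedTrio()
  refs <- lapply(trio$genomes, `[[`, 1)
  kAB <- kaksScreen(refs$A, refs$B)
  kAC <- kaksScreen(refs$A, refs$C)
  expect_gt(nrow(kAB), 20L)
  ## close pair: median Ka of 0
  expect_equal(median(kAB$Ka, na.rm = TRUE), 0)
  ## the outgroup pair diverges more
  expect_gt(mean(kAC$Ka + kAC$Ks, na.rm = TRUE),
            mean(kAB$Ka + kAB$Ks, na.rm = TRUE))
  sm <- selectionSummary(list(A_B = kAB, A_C = kAC))
  expect_equal(sm$table$identical[sm$table$pair == "A_B"],
               sum(kAB$Nd + kAB$Sd == 0))
  expect_true(all(sm$mutuallyIdentical %in% kAB$gene))
  ## an all-identical comparison: every gene identical, none selected
  kAA <- kaksScreen(refs$A, refs$A)
  smAA <- selectionSummary(list(A_A = kAA))
  expect_equal(smAA$table$identical, nrow(kAA))
  expect_equal(smAA$table$positively_selected, 0L)
})

test_that("genes with planted nonsynonymous excess are flagged as selected", {
  set.seed(34)
  ct <- PlastomeAuth:::.codonTable()
  makeGene <- function(nCodons) PlastomeAuth:::.randomCds(3L * nCodons)
  ## plant nonsynonymous-only changes in 3 of 6 genes, synonymous-only in
  ## the rest (third-position changes within 4-fold degenerate codons)
  genesA <- replicate(6, makeGene(200L))
  ## single-nucleotide codon changes, so each event is purely synonymous
  ## or purely nonsynonymous
  oneStep <- function(cod) {
    out <- character(0)
    v <- strsplit(cod, "")[[1]]
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), v[p])) {
      w <- v; w[p] <- b
      out <- c(out, paste(w, collapse = ""))
    }
    out[out %in% ct$sense]
  }
  mutate1 <- function(cds, nmut, syn) {
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    done <- 0
    for (i in sample(2:(length(cod) - 1))) {
      cand <- oneStep(cod[i])
      cand <- cand[(ct$aa[cand] == ct$aa[[cod[i]]]) == syn]
      if (length(cand)) { cod[i] <- sample(cand, 1); done <- done + 1 }
      if (done >= nmut) break
    }
    paste(cod, collapse = "")
  }
  mutateNonsyn <- function(cds, nmut) mutate1(cds, nmut, syn = FALSE)
  mutateSyn <- function(cds, nmut) mutate1(cds, nmut, syn = TRUE)
  flagged <- logical(6)
  for (gi in 1:6) {
    ## selected genes carry a nonsynonymous excess over a small synonymous
    ## background; the rest are synonymous-only
    b <- if (gi <= 3) mutateSyn(mutateNonsyn(genesA[gi], 10L), 2L)
         else mutateSyn(genesA[gi], 8L)
    r <- kaksNG86(codonAlign(genesA[gi], b, gene = paste0("g", gi)))
    flagged[gi] <- !is.na(r$ratio) && r$ratio >= 1 && r$Ka > 0
  }
  expect_identical(flagged, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})
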