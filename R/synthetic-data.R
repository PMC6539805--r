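## Seeded simulator of a three-taxon chloroplast-genome trio (two accessions
## per species) and a 45S cistron trio, carrying every event class the
## pipeline detects: branch-specific SNPs and indels under a Jukes-Cantor /
## geometric-length model, tandem-repeat arrays with per-species copy
## numbers, one segmental inversion (species B), one IR boundary expansion
## (species B), intraspecies variants between accession pairs, and elevated
## ITS substitution rates in the 45S trio. Every planted event is recorded
## in a machine-readable truth table consistent with the emitted sequences.
##
## Fixed topology ((A,B),C): A and B share an internal branch; C is the
## outgroup. Species B is the structurally rearranged lineage.

#' Specification for a synthetic genome trio
#'
#' Defaults define the simulated study conditions: a 30-kb circular
#' ancestor with a quadripartite skeleton (4-kb IR arms, SSC about 23% of
#' the genome), 40 genes, per-branch substitution rates giving roughly
#' 0.2% within the (A,B) clade and 0.5-0.7% divergence to the outgroup C
#' (the magnitude seen between closely related Apiaceae plastomes), sparse
#' intergenic indels with geometric lengths, six tandem-repeat loci with
#' distinct per-species copy numbers (one absent from C), a 625-bp
#' inversion spanning three tRNA genes on branch B, a 1.2-kb IR expansion
#' on branch B, and intraspecies variants for species A (3 SNPs + 6
#' indels) and C (1 SNP + 5 indels) but none for B.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical trios.
#' @param ancestorLength ancestral genome length in bp (default 30000).
#' @param irLength ancestral IR arm length in bp (default 4000, >= 3200).
#' @param nGenes number of distinct genes (default 40, >= 20).
#' @param substRate named per-branch substitution probabilities per site
#'   (`A`, `B`, `C`, `internal`), each in [0, 0.05].
#' @param indelRate per-site indel initiation probability per branch
#'   (intergenic sites only).
#' @param indelGeomP geometric length parameter for indels (default 0.3).
#' @param indelMaxLen indel length cap in bp (default 50).
#' @param irCapture LSC tail captured by the IR expansion on branch B
#'   (default 1200 bp, containing three genes).
#' @param inversionLength inversion length on branch B (default 625 bp).
#' @param intraspecies list per species: `c(snps =, indels =)` counts
#'   separating the two accessions.
#' @param trLoci data.frame of planted tandem-repeat loci (`region`
#'   `"LSC"`/`"SSC"`, `unitLength`, `copies_A`, `copies_B`, `copies_C`), or
#'   `NULL` for the default six-locus table.
#' @return a validated specification list for [generateGenomeTrio()].
#' @export
trioSpec <- function(seed = 1L, ancestorLength = 30000L, irLength = 4000L,
                     nGenes = 40L,
                     substRate = c(A = 0.001, B = 0.001, C = 0.004,
                                   internal = 0.0015),
                     indelRate = 1e-4, indelGeomP = 0.3, indelMaxLen = 50L,
                     irCapture = 1200L, inversionLength = 625L,
                     intraspecies = list(A = c(snps = 3L, indels = 6L),
                                         B = c(snps = 0L, indels = 0L),
                                         C = c(snps = 1L, indels = 5L)),
                     trLoci = NULL) {
  if (is.null(trLoci))
    trLoci <- data.frame(
      region = c("LSC", "LSC", "LSC", "LSC", "SSC", "SSC"),
      unitLength = c(13L, 17L, 22L, 20L, 18L, 14L),
      copies_A = c(2L, 2L, 1L, 2L, 2L, 3L),
      copies_B = c(1L, 2L, 4L, 2L, 1L, 2L),
      copies_C = c(1L, 1L, 1L, 0L, 1L, 2L),
      stringsAsFactors = FALSE)
  stopifnot(all(substRate >= 0), all(substRate <= 0.05),
            indelRate >= 0, indelRate <= 0.05,
            irLength >= 3200L, nGenes >= 20L,
            ancestorLength >= 2L * irLength + 10000L,
            inversionLength >= 500L, irCapture >= 1100L)
  list(seed = as.integer(seed), ancestorLength = as.integer(ancestorLength),
       irLength = as.integer(irLength), nGenes = as.integer(nGenes),
       substRate = substRate, indelRate = indelRate,
       indelGeomP = indelGeomP, indelMaxLen = as.integer(indelMaxLen),
       irCapture = as.integer(irCapture),
       inversionLength = as.integer(inversionLength),
       intraspecies = intraspecies, trLoci = trLoci)
}

.SPECIES <- c("A", "B", "C")
.BRANCH_PATH <- list(A = c("internal", "A"), B = c("internal", "B"), C = "C")

.LSC_CDS_POOL <- c("psbA", "matK", "rps16", "atpA", "atpF", "atpH", "atpI",
                   "rps2", "rpoC2", "rpoC1", "rpoB", "psbD", "psbC", "psaB",
                   "psaA", "ycf3", "rps4", "ndhC", "atpE", "atpB", "rbcL",
                   "accD", "ycf4", "petA", "psbE", "rps18", "rpl20", "clpP",
                   "psbB", "psbH", "petB", "petD", "rpoA", "rps11", "rpl36",
                   "rps8", "rpl14", "rpl16", "rps3", "rpl22")
.CAPTURE_GENES <- c("rps19", "rpl2", "rpl23")
.INV_TRNAS <- c("trnD-GUC", "trnY-GUA", "trnE-UUC")

## random in-frame CDS: ATG + sense codons + TAA
.randomCds <- function(len) {
  ct <- .codonTable()
  sense <- setdiff(ct$sense, "ATG")
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", paste(sample(sense, len %/% 3L - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

## ---------------------------------------------------------------------------
## ancestor composition
## ---------------------------------------------------------------------------

## Builds the ancestral genome piece by piece; returns the sequence, the
## feature table, region boundaries, TR insertion points, the inversion
## window and the IR-capture segment start.
.composeAncestor <- function(spec) {
  irLen <- spec$irLength
  sscLen <- round(0.23 * spec$ancestorLength)
  lscLen <- spec$ancestorLength - 2L * irLen - sscLen
  nLscCds <- spec$nGenes - 13L          # 3 tRNA + 2 IR + 8 SSC genes
  if (nLscCds < 6L) .stopf("nGenes too small for the genome skeleton")
  bodyCds <- .LSC_CDS_POOL[seq_len(nLscCds - 3L)]

  seqParts <- character(0)
  feats <- list()
  trRows <- list()
  pos <- 0L                              # last filled position
  emit <- function(s) {
    seqParts[[length(seqParts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  emitGene <- function(name, kind, len, strand = "+") {
    s <- switch(kind, CDS = .randomCds(len), randomDna(len))
    if (strand == "-") s <- revcompChr(s)
    feats[[length(feats) + 1L]] <<- data.frame(
      gene = name, kind = kind, start = pos + 1L, end = pos + len,
      strand = strand, stringsAsFactors = FALSE)
    emit(s)
  }
  emitTrGap <- function(trIdx, gapLen = 320L) {
    point <- pos + gapLen %/% 2L
    trRows[[length(trRows) + 1L]] <<- data.frame(
      id = sprintf("TR%02d", trIdx), point = point, stringsAsFactors = FALSE)
    emit(randomDna(gapLen))
  }

  ## --- LSC body ---------------------------------------------------------
  lscTrIdx <- which(spec$trLoci$region == "LSC")
  cdsLens <- 3L * sample(100:160, length(bodyCds), replace = TRUE)
  trnaLens <- c(75L, 80L, 72L)
  captureCdsLen <- 330L
  ## capture block: 4 gaps + 3 genes, total = irCapture
  capGap <- (spec$irCapture - 3L * captureCdsLen) %/% 4L
  capResid <- spec$irCapture - 3L * captureCdsLen - 4L * capGap
  if (capGap < 50L) .stopf("irCapture too small for its three genes")
  ## fixed lengths inside the LSC body
  nTrGapsLsc <- length(lscTrIdx)
  trioBlock <- 170L + trnaLens[1L] + 90L + trnaLens[2L] + 85L +
    trnaLens[3L] + 170L
  nFiller <- length(bodyCds) + 1L        # leading gap + one gap after each CDS
  fixed <- sum(cdsLens) + 320L * nTrGapsLsc + trioBlock + spec$irCapture
  fillerTotal <- lscLen - fixed
  filler <- fillerTotal %/% nFiller
  fillResid <- fillerTotal - filler * nFiller
  if (filler < 60L)
    .stopf("events unplaceable: LSC too small for %d genes", length(bodyCds))

  ## interleave: spread TR gaps over the first ~60% of the CDS genes and
  ## the tRNA trio at ~75%
  nBody <- length(bodyCds)
  if (nBody < 10L) .stopf("nGenes too small to place the planted events")
  trAfter <- unique(pmax(1L, floor(seq(0.1, 0.6, length.out = nTrGapsLsc) *
                                     nBody)))
  if (length(trAfter) < nTrGapsLsc)
    .stopf("nGenes too small for %d LSC tandem-repeat loci", nTrGapsLsc)
  trioAfter <- min(nBody - 1L, floor(0.75 * nBody))
  emit(randomDna(filler + fillResid))    # leading gap absorbs the residue
  trUsed <- 0L
  inv <- NULL
  for (ci in seq_along(bodyCds)) {
    emitGene(bodyCds[ci], "CDS", cdsLens[ci])
    emit(randomDna(filler))
    if (trUsed < nTrGapsLsc && ci == trAfter[trUsed + 1L]) {
      trUsed <- trUsed + 1L
      emitTrGap(lscTrIdx[trUsed])
    }
    if (ci == trioAfter) {
      emit(randomDna(170L))
      invAnchor <- pos + 1L              # first base after the pre-margin
      emitGene(.INV_TRNAS[1L], "tRNA", trnaLens[1L], "-")
      emit(randomDna(90L))
      emitGene(.INV_TRNAS[2L], "tRNA", trnaLens[2L], "-")
      emit(randomDna(85L))
      emitGene(.INV_TRNAS[3L], "tRNA", trnaLens[3L], "-")
      emit(randomDna(170L))
      inv <- c(invAnchor - 60L, invAnchor - 60L + spec$inversionLength - 1L)
    }
  }
  ## capture block at the LSC tail
  segStart <- pos + 1L
  emit(randomDna(capGap + capResid))
  for (gn in .CAPTURE_GENES) {
    emitGene(gn, "CDS", captureCdsLen)
    emit(randomDna(capGap))
  }
  if (pos != lscLen) .stopf("internal error: LSC layout is %d bp, want %d",
                            pos, lscLen)
  if (is.null(inv)) .stopf("inversion window not placed")

  ## --- IRb --------------------------------------------------------------
  irbStart <- pos + 1L
  emit(randomDna(150L))
  emitGene("rrn16", "rRNA", 1450L)
  emit(randomDna(200L))
  emitGene("ycf2", "CDS", 1197L)
  emit(randomDna(irLen - (pos - irbStart + 1L)))
  irbSeq <- paste(seqParts[(length(seqParts) - 4L):length(seqParts)],
                  collapse = "")
  irbFeats <- feats[(length(feats) - 1L):length(feats)]

  ## --- SSC --------------------------------------------------------------
  sscStart <- pos + 1L
  sscTrIdx <- which(spec$trLoci$region == "SSC")
  sscGenes <- data.frame(
    gene = c("ndhF", "rpl32", "ccsA", "ndhD", "psaC", "ndhE", "ndhA", "ycf1"),
    len = c(570L, 300L, 420L, 450L, 246L, 306L, 540L, 900L),
    strand = c("+", "-", "+", "+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  sscFixed <- sum(sscGenes$len) + 320L * length(sscTrIdx)
  sscFillN <- nrow(sscGenes)             # gap after ndhF handled by TR gap
  sscFill <- (sscLen - sscFixed) %/% sscFillN
  sscFillResid <- sscLen - sscFixed - sscFill * sscFillN
  if (sscFill < 60L) .stopf("SSC too small for its gene set")
  emit(randomDna(sscFill + sscFillResid))
  for (gi in seq_len(nrow(sscGenes))) {
    emitGene(sscGenes$gene[gi], "CDS", sscGenes$len[gi], sscGenes$strand[gi])
    if (sscGenes$gene[gi] == "ndhF" && length(sscTrIdx) >= 1L)
      emitTrGap(sscTrIdx[1L])
    else if (sscGenes$gene[gi] == "psaC" && length(sscTrIdx) >= 2L)
      emitTrGap(sscTrIdx[2L])
    else if (gi < nrow(sscGenes)) emit(randomDna(sscFill))
  }
  ## trailing SSC gap
  emit(randomDna(sscStart + sscLen - 1L - pos))
  if (pos != lscLen + irLen + sscLen)
    .stopf("internal error: SSC layout ends at %d", pos)

  ## --- IRa = revcomp(IRb) ----------------------------------------------
  iraStart <- pos + 1L
  emit(revcompChr(irbSeq))
  for (f in irbFeats) {
    os <- f$start - irbStart; oe <- f$end - irbStart
    feats[[length(feats) + 1L]] <- data.frame(
      gene = f$gene, kind = f$kind,
      start = iraStart + (irLen - 1L - oe), end = iraStart + (irLen - 1L - os),
      strand = if (f$strand == "+") "-" else "+", stringsAsFactors = FALSE)
  }
  total <- pos
  stopifnot(total == spec$ancestorLength)

  sq <- paste(seqParts, collapse = "")
  ## make the planted IR junctions non-extendable: the single-copy base at
  ## each arm edge must not complement-pair with its mirror, otherwise the
  ## maximal exact IR pair would exceed the planted arms by chance
  svFix <- .charvec(sq)
  fixBase <- function(i, forbidden) {
    ## deterministic replacement, so the fixups never shift the seeded
    ## random stream
    if (svFix[i] %in% forbidden)
      svFix[i] <<- setdiff(.BASES, forbidden)[1L]
  }
  ## arm-edge pairings: IRb's left edge pairs (via the anti-diagonal) with
  ## the base following IRa, which is the LSC first base across the origin
  fixBase(lscLen, .COMP[[svFix[1L]]])                     # LSC/IRb vs origin
  fixBase(sscStart, .COMP[[svFix[iraStart - 1L]]])        # IRb/SSC vs SSC/IRa
  fixBase(segStart - 1L, .COMP[[svFix[1L]]])              # expanded junction (B)
  ## inversion edges: keep the planted breakpoints unambiguous (an edge
  ## base complement-pairing with its flank would let the detected block
  ## shift while still describing the same sequence)
  fixBase(inv[1L] - 1L, .COMP[[svFix[inv[2L] + 1L]]])
  fixBase(inv[1L], .COMP[[svFix[inv[2L]]]])
  sq <- paste(svFix, collapse = "")
  featDf <- do.call(rbind, feats)
  ## trRows are in emission order: LSC loci first, then SSC loci
  emOrder <- c(lscTrIdx, sscTrIdx)
  trDf <- cbind(do.call(rbind, trRows), spec$trLoci[emOrder, , drop = FALSE])
  ## planted TR units with non-extension guards at the insertion point
  sv <- .charvec(sq)
  trDf$unit <- vapply(seq_len(nrow(trDf)), function(i) {
    u <- trDf$unitLength[i]
    repeat {
      unit <- randomDna(u)
      if (!.isPrimitive(unit)) next
      if (substr(unit, u, u) == sv[trDf$point[i]]) next
      if (substr(unit, 1L, 1L) == sv[trDf$point[i] + 1L]) next
      break
    }
    unit
  }, character(1))

  list(seq = sq, features = featDf, lscLen = lscLen, irLen = irLen,
       sscLen = sscLen, irbStart = irbStart, sscStart = sscStart,
       iraStart = iraStart, total = total, tr = trDf, inv = inv,
       segStart = segStart)
}

## ---------------------------------------------------------------------------
## branch event sampling
## ---------------------------------------------------------------------------

## masks, then indels (intergenic, >=100 bp apart), then substitutions
## (outside IRs / planted footprints / indel footprints, at most one per
## codon, never creating a stop in any leaf)
.sampleBranchEvents <- function(spec, anc) {
  n <- anc$total
  sv <- .charvec(anc$seq)
  allowed <- rep(TRUE, n)
  allowed[anc$irbStart:(anc$irbStart + anc$irLen - 1L)] <- FALSE
  allowed[anc$iraStart:n] <- FALSE
  allowed[max(1L, anc$inv[1L] - 100L):min(n, anc$inv[2L] + 100L)] <- FALSE
  for (p in anc$tr$point)
    allowed[max(1L, p - 100L):min(n, p + 101L)] <- FALSE
  ## the LSC head (junction-primer window) and the IR-captured LSC tail
  ## (control-primer window) stay conserved across the trio, as the marker
  ## stage requires conserved primer footprints at these sites
  allowed[1:450] <- FALSE
  allowed[max(1L, anc$segStart - 100L):anc$lscLen] <- FALSE
  allowed[(n - 60L):n] <- FALSE
  ## junction-edge bases fixed by .composeAncestor stay fixed
  allowed[c(anc$lscLen, anc$sscStart, anc$iraStart - 1L,
            anc$segStart - 1L, anc$segStart)] <- FALSE

  intergenic <- rep(TRUE, n)
  for (i in seq_len(nrow(anc$features)))
    intergenic[anc$features$start[i]:anc$features$end[i]] <- FALSE

  branches <- c("internal", "A", "B", "C")
  ## --- indels -----------------------------------------------------------
  segAllowed <- allowed & intergenic
  segAllowed[max(1L, anc$segStart - 100L):anc$lscLen] <- FALSE  # IR-capture segment
  indelRows <- list()
  taken <- integer(0)
  for (br in branches) {
    nEv <- stats::rbinom(1L, sum(segAllowed), spec$indelRate)
    placed <- 0L; tries <- 0L
    while (placed < nEv && tries < 500L) {
      tries <- tries + 1L
      pool <- which(segAllowed)
      if (!length(pool)) break
      p <- pool[sample.int(length(pool), 1L)]
      len <- min(1L + stats::rgeom(1L, spec$indelGeomP), spec$indelMaxLen)
      if (p + len + 100L > n || p < 101L) next
      if (length(taken) && any(abs(taken - p) < 150L)) next
      ## the event footprint itself must be intergenic and allowed
      if (!all(segAllowed[p:(p + len)])) next
      type <- sample(c("ins", "del"), 1L)
      indelRows[[length(indelRows) + 1L]] <- data.frame(
        branch = br, ancAfter = p, type = type, len = len,
        seq = if (type == "ins") randomDna(len)
              else paste(sv[(p + 1L):(p + len)], collapse = ""),
        stringsAsFactors = FALSE)
      taken <- c(taken, p)
      placed <- placed + 1L
    }
  }
  indels <- if (length(indelRows)) do.call(rbind, indelRows) else
    data.frame(branch = character(0), ancAfter = integer(0),
               type = character(0), len = integer(0), seq = character(0),
               stringsAsFactors = FALSE)

  ## --- substitutions ----------------------------------------------------
  subAllowed <- allowed
  for (i in seq_len(nrow(indels))) {
    lo <- max(1L, indels$ancAfter[i] - 35L)
    hi <- min(n, indels$ancAfter[i] + indels$len[i] + 35L)
    subAllowed[lo:hi] <- FALSE
  }
  cds <- anc$features[anc$features$kind == "CDS", , drop = FALSE]
  codonKey <- function(p) {
    hitRow <- which(cds$start <= p & p <= cds$end)
    if (!length(hitRow)) return(NA_character_)
    f <- cds[hitRow[1L], ]
    off <- if (f$strand == "+") p - f$start else f$end - p
    sprintf("%s:%d", f$gene, off %/% 3L)
  }
  usedCodons <- character(0)
  subRows <- list()
  ct <- .codonTable()
  for (br in branches) {
    nEv <- stats::rbinom(1L, sum(subAllowed), spec$substRate[[br]])
    placed <- 0L; tries <- 0L
    while (placed < nEv && tries < 2000L) {
      tries <- tries + 1L
      pool <- which(subAllowed)
      if (!length(pool)) break
      p <- pool[sample.int(length(pool), 1L)]
      key <- codonKey(p)
      if (!is.na(key) && key %in% usedCodons) next
      newBase <- .pickSafeBase(sv, p, cds, ct)
      if (is.na(newBase)) next
      subRows[[length(subRows) + 1L]] <- data.frame(
        branch = br, pos = p, ref = sv[p], base = newBase,
        stringsAsFactors = FALSE)
      subAllowed[p] <- FALSE
      if (!is.na(key)) usedCodons <- c(usedCodons, key)
      placed <- placed + 1L
    }
  }
  subs <- if (length(subRows)) do.call(rbind, subRows) else
    data.frame(branch = character(0), pos = integer(0), ref = character(0),
               base = character(0), stringsAsFactors = FALSE)
  list(subs = subs, indels = indels)
}

## a substitution base for position p that never creates a stop codon
.pickSafeBase <- function(sv, p, cds, ct) {
  hitRow <- which(cds$start <= p & p <= cds$end)
  cand <- sample(setdiff(.BASES, sv[p]))
  if (!length(hitRow)) return(cand[1L])
  f <- cds[hitRow[1L], ]
  for (b in cand) {
    if (f$strand == "+") {
      off <- p - f$start
      c0 <- f$start + (off %/% 3L) * 3L
      cod <- sv[c0:(c0 + 2L)]
      cod[p - c0 + 1L] <- b
      codon <- paste(cod, collapse = "")
    } else {
      off <- f$end - p
      c0 <- f$end - (off %/% 3L) * 3L
      cod <- sv[c0:(c0 - 2L)]
      cod[c0 - p + 1L] <- b
      codon <- paste(.COMP[cod], collapse = "")
    }
    if (ct$aa[[codon]] != "*") return(b)
  }
  NA_character_
}

## ---------------------------------------------------------------------------
## leaf materialisation
## ---------------------------------------------------------------------------

## Applies branch substitutions and length-changing edits to the ancestor
## and returns the leaf sequence plus an ancestor->leaf coordinate map.
.buildLeaf <- function(anc, ev, spec, sp) {
  path <- .BRANCH_PATH[[sp]]
  sv <- .charvec(anc$seq)
  mySubs <- ev$subs[ev$subs$branch %in% path, , drop = FALSE]
  if (nrow(mySubs)) sv[mySubs$pos] <- mySubs$base

  edits <- list()
  addEdit <- function(ancAfter, delLen, insSeq, tag = "")
    edits[[length(edits) + 1L]] <<- list(ancAfter = ancAfter, delLen = delLen,
                                         insSeq = insSeq, tag = tag)
  myIndels <- ev$indels[ev$indels$branch %in% path, , drop = FALSE]
  for (i in seq_len(nrow(myIndels))) {
    r <- myIndels[i, ]
    if (r$type == "ins") addEdit(r$ancAfter, 0L, r$seq, "ins")
    else addEdit(r$ancAfter, r$len, "", "del")
  }
  for (i in seq_len(nrow(anc$tr))) {
    cp <- anc$tr[[paste0("copies_", sp)]][i]
    addEdit(anc$tr$point[i], 0L, strrep(anc$tr$unit[i], cp), "tr")
  }
  if (sp == "B") {
    seg <- paste(sv[anc$inv[1L]:anc$inv[2L]], collapse = "")
    addEdit(anc$inv[1L] - 1L, anc$inv[2L] - anc$inv[1L] + 1L,
            revcompChr(seg), "inv")
  }
  ord <- order(vapply(edits, `[[`, numeric(1), "ancAfter"))
  edits <- edits[ord]

  chunks <- character(0)
  blocks <- list()                       # identity blocks anc -> leaf
  insAt <- list()                        # leaf start of each edit insertion
  cur <- 1L; leafPos <- 0L
  for (e in edits) {
    if (e$ancAfter >= cur) {
      chunks[[length(chunks) + 1L]] <-
        paste(sv[cur:e$ancAfter], collapse = "")
      blocks[[length(blocks) + 1L]] <-
        c(cur, e$ancAfter, leafPos + 1L)
      leafPos <- leafPos + (e$ancAfter - cur + 1L)
    }
    if (nzchar(e$insSeq)) {
      chunks[[length(chunks) + 1L]] <- e$insSeq
      insAt[[length(insAt) + 1L]] <- c(leafPos + 1L, nchar(e$insSeq))
      names(insAt)[length(insAt)] <- e$tag
      leafPos <- leafPos + nchar(e$insSeq)
    } else {
      insAt[[length(insAt) + 1L]] <- c(leafPos, 0L)
      names(insAt)[length(insAt)] <- e$tag
    }
    cur <- e$ancAfter + e$delLen + 1L
  }
  if (cur <= anc$total) {
    chunks[[length(chunks) + 1L]] <- paste(sv[cur:anc$total], collapse = "")
    blocks[[length(blocks) + 1L]] <- c(cur, anc$total, leafPos + 1L)
    leafPos <- leafPos + (anc$total - cur + 1L)
  }
  bm <- do.call(rbind, blocks)
  mapPos <- function(p) {
    i <- findInterval(p, bm[, 1L])
    if (i < 1L || p > bm[i, 2L]) return(NA_integer_)
    bm[i, 3L] + (p - bm[i, 1L])
  }
  edits2 <- Map(function(e, at) c(e, list(leafStart = at[1L], leafLen = at[2L])),
                edits, insAt)
  list(seq = paste(chunks, collapse = ""), sv = sv, mapPos = mapPos,
       edits = edits2, length = leafPos)
}

## leaf feature table: identity-block mapping, with reflection inside the
## inversion (species B) and duplication into the appended IR copy
.leafFeatures <- function(anc, leaf, sp, spec) {
  f <- anc$features
  inv <- anc$inv
  invEdit <- if (sp == "B")
    Filter(function(e) e$tag == "inv", leaf$edits)[[1L]] else NULL
  rows <- list()
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- f$end[i]
    if (!is.null(invEdit) && s >= inv[1L] && e <= inv[2L]) {
      ls <- invEdit$leafStart + (inv[2L] - e)
      le <- invEdit$leafStart + (inv[2L] - s)
      strand <- if (f$strand[i] == "+") "-" else "+"
    } else {
      ls <- leaf$mapPos(s); le <- leaf$mapPos(e)
      strand <- f$strand[i]
    }
    if (is.na(ls) || is.na(le)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = f$gene[i], kind = f$kind[i], start = ls, end = le,
      strand = strand, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic three-species genome trio with truth tables
#'
#' See [trioSpec()] for the simulated conditions. Species B carries the
#' planted inversion and the IR expansion (the captured LSC tail is
#' re-annotated as IR and its reverse complement, with duplicated gene
#' copies, is inserted at the IRa/LSC junction). Each species is emitted as
#' two accessions differing only by the planted intraspecies variants.
#'
#' @param spec a specification from [trioSpec()].
#' @return list with `genomes` (species -> list of two
#'   [AnnotatedGenome-class] accessions), and `truth`: `junctions` and
#'   `irLength` per species, `irGainedGenes`, `inversion` (interval per
#'   relevant species and contained genes), `trLoci` (per-species copies
#'   and leaf coordinates), `intraspecies` (per-species variant tables in
#'   accession-1 coordinates, left-normalised), and `pairVariants`
#'   (per-species-pair SNP/indel tables in first-species coordinates).
#' @export
generateGenomeTrio <- function(spec = trioSpec()) {
  set.seed(spec$seed)
  anc <- .composeAncestor(spec)
  ev <- .sampleBranchEvents(spec, anc)
  leaves <- lapply(stats::setNames(.SPECIES, .SPECIES), function(sp)
    .buildLeaf(anc, ev, spec, sp))

  feats <- lapply(stats::setNames(.SPECIES, .SPECIES), function(sp)
    .leafFeatures(anc, leaves[[sp]], sp, spec))

  ## --- species B: IR expansion -----------------------------------------
  segStartLeaf <- leaves$B$mapPos(anc$segStart)
  lscEndLeaf <- leaves$B$mapPos(anc$lscLen)
  capture <- lscEndLeaf - segStartLeaf + 1L
  appendBase <- leaves$B$length
  segSeq <- substr(leaves$B$seq, segStartLeaf, lscEndLeaf)
  leaves$B$seq <- paste0(leaves$B$seq, revcompChr(segSeq))
  inSeg <- feats$B$start >= segStartLeaf & feats$B$end <= lscEndLeaf
  dup <- feats$B[inSeg, , drop = FALSE]
  if (nrow(dup)) {
    newStart <- appendBase + (lscEndLeaf - dup$end) + 1L
    newEnd <- appendBase + (lscEndLeaf - dup$start) + 1L
    dup$start <- newStart; dup$end <- newEnd
    dup$strand <- ifelse(dup$strand == "+", "-", "+")
    feats$B <- rbind(feats$B, dup)
  }
  leaves$B$length <- nchar(leaves$B$seq)

  ## --- truth: junctions and IR lengths ---------------------------------
  junctions <- list()
  irLengths <- integer(0)
  for (sp in .SPECIES) {
    mp <- leaves[[sp]]$mapPos
    if (sp == "B") {
      junctions[[sp]] <- c(J_LSC_IRb = segStartLeaf,
                           J_IRb_SSC = mp(anc$sscStart),
                           J_SSC_IRa = mp(anc$iraStart),
                           J_IRa_LSC = 1L)
      irLengths[[sp]] <- capture + anc$irLen
    } else {
      junctions[[sp]] <- c(J_LSC_IRb = mp(anc$irbStart),
                           J_IRb_SSC = mp(anc$sscStart),
                           J_SSC_IRa = mp(anc$iraStart),
                           J_IRa_LSC = 1L)
      irLengths[[sp]] <- anc$irLen
    }
  }

  ## --- truth: TR loci in leaf coordinates ------------------------------
  trTruth <- anc$tr
  for (sp in .SPECIES) {
    trEdits <- Filter(function(e) e$tag == "tr", leaves[[sp]]$edits)
    starts <- vapply(trEdits, `[[`, numeric(1), "leafStart")
    lens <- vapply(trEdits, `[[`, numeric(1), "leafLen")
    ## tr edits appear in ancestor point order within the sorted edit list
    o <- order(vapply(trEdits, `[[`, numeric(1), "ancAfter"))
    ptOrder <- order(anc$tr$point)
    trTruth[[paste0("start_", sp)]][ptOrder] <- as.integer(starts[o])
    trTruth[[paste0("end_", sp)]][ptOrder] <-
      as.integer(starts[o] + pmax(lens[o] - 1L, 0L))
  }

  ## --- truth: inversion -------------------------------------------------
  invEdit <- Filter(function(e) e$tag == "inv", leaves$B$edits)[[1L]]
  invLen <- anc$inv[2L] - anc$inv[1L] + 1L
  invTruth <- list(
    species = "B",
    intervalB = c(invEdit$leafStart, invEdit$leafStart + invLen - 1L),
    intervalA = c(leaves$A$mapPos(anc$inv[1L]), leaves$A$mapPos(anc$inv[2L])),
    intervalC = c(leaves$C$mapPos(anc$inv[1L]), leaves$C$mapPos(anc$inv[2L])),
    length = invLen, genes = .INV_TRNAS)

  ## --- accessions and intraspecies truth --------------------------------
  genomes <- list(); intra <- list()
  for (sp in .SPECIES) {
    g1 <- annotatedGenome(paste0(sp, "-01"), leaves[[sp]]$seq,
                          circular = TRUE, features = feats[[sp]])
    iv <- .plantIntraspecies(g1, spec$intraspecies[[sp]],
                             trTruth, invTruth, junctions[[sp]],
                             irLengths[[sp]], sp, spec)
    g2 <- annotatedGenome(paste0(sp, "-02"),
                          applyVariants(g1, iv),
                          circular = TRUE,
                          features = .shiftFeatures(feats[[sp]], iv))
    genomes[[sp]] <- list(g1, g2)
    intra[[sp]] <- iv
  }

  ## --- interspecies pair truth ------------------------------------------
  pairTruth <- list()
  combs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  for (pr in combs) {
    x <- pr[1L]; y <- pr[2L]
    onPath <- setdiff(union(.BRANCH_PATH[[x]], .BRANCH_PATH[[y]]),
                      intersect(.BRANCH_PATH[[x]], .BRANCH_PATH[[y]]))
    svx <- leaves[[x]]$sv; svy <- leaves[[y]]$sv
    rows <- list()
    ss <- ev$subs[ev$subs$branch %in% onPath, , drop = FALSE]
    for (i in seq_len(nrow(ss))) {
      p <- ss$pos[i]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "SNP", posA = leaves[[x]]$mapPos(p),
        ref = svx[p], alt = svy[p], length = 1L, stringsAsFactors = FALSE)
    }
    ii <- ev$indels[ev$indels$branch %in% onPath, , drop = FALSE]
    sx <- leaves[[x]]$seq
    for (i in seq_len(nrow(ii))) {
      r <- ii[i, ]
      onX <- r$branch %in% .BRANCH_PATH[[x]]
      ## an insertion on the x side (or deletion on the y side) leaves x
      ## with extra sequence: a deletion record in x polarity
      xHasExtra <- (r$type == "ins" && onX) || (r$type == "del" && !onX)
      if (xHasExtra) {
        pos <- leaves[[x]]$mapPos(r$ancAfter) + 1L
        sh <- .leftShiftIndel(sx, pos - 1L, r$seq)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "indel", posA = sh$pos + 1L, ref = sh$seq, alt = "-",
          length = r$len, stringsAsFactors = FALSE)
      } else {
        pos <- leaves[[x]]$mapPos(r$ancAfter)
        sh <- .leftShiftIndel(sx, pos, r$seq)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "indel", posA = sh$pos, ref = "-", alt = sh$seq,
          length = r$len, stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(kind = character(0), posA = integer(0), ref = character(0),
                 alt = character(0), length = integer(0),
                 stringsAsFactors = FALSE)
    df <- df[order(df$posA), , drop = FALSE]
    rownames(df) <- NULL
    pairTruth[[paste(pr, collapse = "_")]] <- df
  }

  list(genomes = genomes,
       truth = list(junctions = junctions, irLength = irLengths,
                    irGainedGenes = .CAPTURE_GENES,
                    inversion = invTruth, trLoci = trTruth,
                    intraspecies = intra, pairVariants = pairTruth,
                    branchSubs = ev$subs, branchIndels = ev$indels))
}

## intraspecies variants for the second accession: intergenic single-copy
## positions away from every planted event
.plantIntraspecies <- function(g1, counts, trTruth, invTruth, junc, irLen,
                               sp, spec) {
  empty <- data.frame(kind = character(0), posA = integer(0),
                      ref = character(0), alt = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  nSnp <- counts[["snps"]]; nInd <- counts[["indels"]]
  if (nSnp + nInd == 0L) return(empty)
  s <- genomeSeq(g1)
  n <- nchar(s)
  ok <- rep(TRUE, n)
  f <- genomeFeatures(g1)
  for (i in seq_along(f))
    ok[IRanges::start(f)[i]:min(IRanges::end(f)[i], n)] <- FALSE
  ## exclude both IR arms (keeps the arms of accession 2 exactly mirrored)
  irbS <- junc[["J_LSC_IRb"]]; sscS <- junc[["J_IRb_SSC"]]
  iraS <- junc[["J_SSC_IRa"]]
  ok[irbS:(sscS - 1L)] <- FALSE
  ok[iraS:n] <- FALSE
  ## stay clear of planted TR loci and the inversion
  for (i in seq_len(nrow(trTruth))) {
    st <- trTruth[[paste0("start_", sp)]][i]
    en <- trTruth[[paste0("end_", sp)]][i]
    ok[max(1L, st - 150L):min(n, en + 150L)] <- FALSE
  }
  if (sp == "B") {
    iv <- invTruth$intervalB
    ok[max(1L, iv[1L] - 150L):min(n, iv[2L] + 150L)] <- FALSE
  }
  ok[1:100] <- FALSE
  sv <- .charvec(s)
  rows <- list(); taken <- integer(0)
  plant <- function(kind) {
    tries <- 0L
    while (tries < 500L) {
      tries <- tries + 1L
      pool <- which(ok)
      if (!length(pool)) break
      p <- pool[sample.int(length(pool), 1L)]
      if (length(taken) && any(abs(taken - p) < 120L)) next
      if (kind == "SNP") {
        alt <- sample(setdiff(.BASES, sv[p]), 1L)
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "SNP", posA = p, ref = sv[p], alt = alt, length = 1L,
          stringsAsFactors = FALSE)
      } else {
        len <- min(1L + stats::rgeom(1L, spec$indelGeomP), spec$indelMaxLen)
        if (p + len + 1L > n || !all(ok[p:(p + len + 1L)])) next
        if (sample(c(TRUE, FALSE), 1L)) {      # deletion from accession 2
          sh <- .leftShiftIndel(s, p, substr(s, p + 1L, p + len))
          rows[[length(rows) + 1L]] <<- data.frame(
            kind = "indel", posA = sh$pos + 1L, ref = sh$seq, alt = "-",
            length = len, stringsAsFactors = FALSE)
        } else {                               # insertion in accession 2
          sh <- .leftShiftIndel(s, p, randomDna(len))
          rows[[length(rows) + 1L]] <<- data.frame(
            kind = "indel", posA = sh$pos, ref = "-", alt = sh$seq,
            length = len, stringsAsFactors = FALSE)
        }
      }
      taken <<- c(taken, p)
      return(invisible(TRUE))
    }
    .stopf("could not place intraspecies variant for species %s", sp)
  }
  for (i in seq_len(nSnp)) plant("SNP")
  for (i in seq_len(nInd)) plant("indel")
  df <- do.call(rbind, rows)
  df <- df[order(df$posA), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## shift a feature table by the net offsets of intraspecies indels
.shiftFeatures <- function(feats, variants) {
  if (is.null(variants) || !nrow(variants)) return(feats)
  ind <- variants[variants$kind == "indel", , drop = FALSE]
  if (!nrow(ind)) return(feats)
  delta <- ifelse(ind$ref == "-", nchar(ind$alt), -nchar(ind$ref))
  shift <- function(p) p + sum(delta[ind$posA < p])
  out <- feats
  out$start <- vapply(feats$start, shift, numeric(1))
  out$end <- vapply(feats$end, shift, numeric(1))
  out
}

#' Generate a synthetic 45S cistron trio with truth counts
#'
#' Per-region substitution counts are drawn binomially per branch of the
#' fixed ((A,B),C) topology, with ITS1/ITS2 rates elevated by
#' `itsMultiplier`; substitution positions are sampled without replacement
#' so the per-region truth counts equal the number of polymorphic columns.
#' Optionally one heterogeneous site (IUPAC code in unit A, emulating a
#' within-species polymorphism) is planted in 26S; it is excluded from SNP
#' truth counts.
#'
#' @param seed integer RNG seed.
#' @param regionLengths named region lengths in bp (defaults 18S 1800,
#'   ITS1 250, 5.8S 160, ITS2 230, 26S 3380, giving a 5820-bp unit).
#' @param baseRates named per-branch substitution probabilities per site
#'   for the rRNA genes.
#' @param itsMultiplier rate multiplier for ITS1/ITS2 (default 10, >= 1).
#' @param heterogeneousSite plant the IUPAC heterogeneous site (default
#'   TRUE).
#' @return list with `units` (A/B/C [CistronUnit-class]s; only unit A
#'   carries region annotation) and `truth` (`regionCounts`, `total`,
#'   `events` data.frame, `heterogeneousSite` position or NA).
#' @export
generate45STrio <- function(seed = 1L,
                            regionLengths = c(`18S` = 1800L, ITS1 = 250L,
                                              `5.8S` = 160L, ITS2 = 230L,
                                              `26S` = 3380L),
                            baseRates = c(A = 0.001, B = 0.001, C = 0.003,
                                          internal = 0.0015),
                            itsMultiplier = 10, heterogeneousSite = TRUE) {
  stopifnot(itsMultiplier >= 1,
            identical(names(regionLengths), .CISTRON_REGIONS))
  set.seed(seed)
  total <- sum(regionLengths)
  ancestor <- .charvec(randomDna(total))
  regEnd <- cumsum(regionLengths)
  regStart <- c(1L, utils::head(regEnd, -1L) + 1L)
  leafSv <- list(A = ancestor, B = ancestor, C = ancestor)
  events <- list()
  used <- integer(0)
  for (r in seq_along(regionLengths)) {
    mult <- if (names(regionLengths)[r] %in% c("ITS1", "ITS2"))
      itsMultiplier else 1
    posPool <- regStart[r]:regEnd[r]
    for (br in c("internal", "A", "B", "C")) {
      k <- stats::rbinom(1L, regionLengths[[r]], baseRates[[br]] * mult)
      k <- min(k, length(setdiff(posPool, used)))
      if (k == 0L) next
      pos <- sample(setdiff(posPool, used), k)
      used <- c(used, pos)
      for (p in pos) {
        alt <- sample(setdiff(.BASES, ancestor[p]), 1L)
        tgt <- if (br == "internal") c("A", "B") else br
        for (sp in tgt) leafSv[[sp]][p] <- alt
        events[[length(events) + 1L]] <- data.frame(
          region = names(regionLengths)[r], branch = br, pos = p,
          ref = ancestor[p], alt = alt, stringsAsFactors = FALSE)
      }
    }
  }
  evDf <- if (length(events)) do.call(rbind, events) else
    data.frame(region = character(0), branch = character(0), pos = integer(0),
               ref = character(0), alt = character(0), stringsAsFactors = FALSE)
  hetero <- NA_integer_
  if (heterogeneousSite) {
    pool <- setdiff(regStart[5L]:regEnd[5L], used)
    hetero <- sample(pool, 1L)
    base <- leafSv$A[hetero]
    iupac <- c(A = "R", G = "R", C = "Y", T = "Y")   # transition partner
    leafSv$A[hetero] <- iupac[[base]]
  }
  counts <- stats::setNames(integer(length(regionLengths)),
                            names(regionLengths))
  if (nrow(evDf)) {
    tb <- table(factor(evDf$region, levels = names(regionLengths)))
    counts[names(tb)] <- as.integer(tb)
  }
  units <- list(
    A = cistronUnit("45S-A", paste(leafSv$A, collapse = ""),
                    as.list(regionLengths)),
    B = cistronUnit("45S-B", paste(leafSv$B, collapse = "")),
    C = cistronUnit("45S-C", paste(leafSv$C, collapse = "")))
  list(units = units,
       truth = list(regionCounts = counts, total = sum(counts),
                    events = evDf, heterogeneousSite = hetero))
}
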