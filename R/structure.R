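## Quadripartite structure detection: the inverted-repeat (IR) pair, the
## LSC/IRb/SSC/IRa partition with junction coordinates, and IR gene-content
## comparison across genomes (the signature of IR boundary expansion).

#' Detect the inverted-repeat pair of a circular genome
#'
#' Seeds exact reverse-complement `seedK`-mer matches and extends them
#' without mismatches along the anti-diagonal; the maximal-length pair of
#' disjoint segments `(IRb, IRa)` with `seq(IRa) == revcomp(seq(IRb))` wins.
#' Ties are broken towards the smallest IRa start. Positions containing `N`
#' never seed. A mismatch-tolerant extension mode (`maxMismatches > 0`)
#' exists but is off by default so junction coordinates stay exactly
#' reproducible.
#'
#' Arms are labelled so that the single-copy gap following IRa (clockwise)
#' is the LSC (the longer gap; on a tie, IRa is the arm with the larger
#' start, leaving IRb with the smallest start).
#'
#' @param g a circular [AnnotatedGenome-class], `length > 2 * minIrLength`.
#' @param minIrLength minimum arm length in bp (default 1000; chloroplast IR
#'   arms are 18-36 kb, and this floor avoids tRNA-scale hits).
#' @param seedK seed k-mer size (default 25).
#' @param maxMismatches mismatches tolerated when bridging interrupted
#'   extensions (default 0 = exact).
#' @return an [IRPair-class], or `NULL` when no arm pair reaches
#'   `minIrLength` (valid for IR-lacking plastomes).
#' @export
detectInvertedRepeats <- function(g, minIrLength = 1000L, seedK = 25L,
                                  maxMismatches = 0L) {
  s <- genomeSeq(g)
  n <- nchar(s)
  if (!isCircular(g)) .stopf("IR detection requires a circular genome")
  if (n <= 2L * minIrLength)
    .stopf("genome length %d must exceed 2*minIrLength = %d", n, 2L * minIrLength)
  km <- circKmers(s, seedK)
  rckm <- circKmersRC(s, seedK)
  hasN <- grepl("N", km, fixed = TRUE)
  km[hasN] <- NA; rckm[hasN] <- NA
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  kmu <- km; kmu[dup] <- NA
  idx <- match(rckm, kmu, incomparables = NA)
  j <- which(!is.na(idx))
  if (!length(j)) return(NULL)
  i <- idx[j]
  classes <- unique((i + j + seedK - 2L) %% n)

  sv <- .charvec(s)
  compv <- unname(.COMP[sv])
  compv[is.na(compv)] <- "N"
  best <- NULL
  cand <- list()
  for (cc in classes) {
    qv <- ((cc - seq_len(n)) %% n) + 1L          # partner position per p
    m <- sv == compv[qv] & sv != "N"
    runs <- .circularRuns(m, maxMismatches)
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      r1 <- runs$start[r]; r2 <- runs$end[r]     # r2 may be unwrapped (> n)
      L <- r2 - r1 + 1L
      if (L > n) { r2 <- r1 + n - 1L; L <- n }
      q1 <- modpos(cc - modpos(r2, n) + 1L, n)   # mirror of r2
      mirrorIsSelf <- ((q1 - r1) %% n) < L
      if (mirrorIsSelf) {
        arm <- L %/% 2L
        if (arm < minIrLength) next
        a1 <- modpos(r1, n); b1 <- modpos(r2 - arm + 1L, n)
        cand[[length(cand) + 1L]] <- c(a1, b1, arm, runs$mismatches[r])
      } else {
        if (L < minIrLength) next
        a1 <- modpos(r1, n); b1 <- q1
        if (((b1 - a1) %% n) == 0L) next
        key1 <- min(a1, b1)
        if (a1 != key1) next                     # mirror run reported once
        cand[[length(cand) + 1L]] <- c(a1, b1, L, runs$mismatches[r])
      }
    }
  }
  if (!length(cand)) return(NULL)
  cm <- do.call(rbind, cand)
  cm <- cm[order(-cm[, 3L], pmin(cm[, 1L], cm[, 2L])), , drop = FALSE]
  topLen <- cm[1L, 3L]
  if (topLen < minIrLength) return(NULL)
  a1 <- cm[1L, 1L]; b1 <- cm[1L, 2L]; L <- as.integer(cm[1L, 3L])
  mm <- as.integer(cm[1L, 4L])
  .labelArms(a1, b1, L, mm, n)
}

## Label the two arms so that the gap following IRa is the LSC.
.labelArms <- function(a1, b1, L, mm, n) {
  e1 <- a1 + L - 1L; e2 <- b1 + L - 1L
  gapAfter1 <- (b1 - modpos(e1, n) - 1L) %% n    # gap between arm1-end, arm2-start
  gapAfter2 <- (a1 - modpos(e2, n) - 1L) %% n
  if (gapAfter1 == 0L || gapAfter2 == 0L)
    .stopf("degenerate partition: IR arms are adjacent on the circle")
  if (gapAfter1 > gapAfter2) {                   # LSC follows arm1 -> arm1 = IRa
    ira <- c(a1, e1); irb <- c(b1, e2)
  } else if (gapAfter2 > gapAfter1) {
    ira <- c(b1, e2); irb <- c(a1, e1)
  } else {                                       # tie: IRa = larger start
    if (a1 > b1) { ira <- c(a1, e1); irb <- c(b1, e2) }
    else { ira <- c(b1, e2); irb <- c(a1, e1) }
  }
  new("IRPair",
      ira = IRanges::IRanges(ira[1L], ira[2L]),
      irb = IRanges::IRanges(irb[1L], irb[2L]),
      irLength = as.integer(L), mismatches = mm, genomeLength = as.integer(n))
}

## Maximal circular runs of TRUE in a logical vector; optionally bridge
## FALSE gaps while the total bridged length stays <= maxMismatches.
## Returns data.frame(start, end, mismatches); end may exceed n (wrap).
.circularRuns <- function(m, maxMismatches = 0L) {
  n <- length(m)
  if (!any(m)) return(data.frame(start = integer(0), end = integer(0),
                                 mismatches = integer(0)))
  if (all(m)) return(data.frame(start = 1L, end = n, mismatches = 0L))
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(start = starts[r$values], end = ends[r$values])
  # wrap: join last TRUE run to first when both touch the boundary
  if (m[1L] && m[n] && nrow(df) > 1L) {
    df$end[nrow(df)] <- df$end[nrow(df)] + df$end[1L]
    df <- df[-1L, , drop = FALSE]
  }
  df$mismatches <- 0L
  if (maxMismatches > 0L && nrow(df) > 1L) {
    merged <- df[1L, , drop = FALSE]
    for (i in 2L:nrow(df)) {
      gap <- df$start[i] - merged$end[nrow(merged)] - 1L
      if (gap > 0L && merged$mismatches[nrow(merged)] + gap <= maxMismatches) {
        merged$end[nrow(merged)] <- df$end[i]
        merged$mismatches[nrow(merged)] <-
          merged$mismatches[nrow(merged)] + gap
      } else {
        merged <- rbind(merged, df[i, , drop = FALSE])
      }
    }
    df <- merged
  }
  df
}

#' Partition a genome into LSC / IRb / SSC / IRa
#'
#' The two single-copy gaps between the IR arms are labelled LSC (longer)
#' and SSC (shorter); on a tie, the gap following IRa is declared the LSC.
#' The four junction coordinates are reported 1-based as the first base of
#' the downstream region.
#'
#' @param g the [AnnotatedGenome-class] the arms were detected on.
#' @param ir its [IRPair-class].
#' @return a [QuadripartitePartition-class].
#' @export
partitionQuadripartite <- function(g, ir) {
  n <- genomeLength(g)
  stopifnot(ir@genomeLength == n)
  iraS <- IRanges::start(ir@ira); iraE <- IRanges::end(ir@ira)
  irbS <- IRanges::start(ir@irb); irbE <- IRanges::end(ir@irb)
  lscS <- modpos(iraE + 1L, n)
  lscW <- (irbS - lscS) %% n
  sscS <- modpos(irbE + 1L, n)
  sscW <- (iraS - sscS) %% n
  if (lscW == 0L || sscW == 0L)
    .stopf("degenerate partition: zero-length single-copy region")
  part <- new("QuadripartitePartition",
              lsc = IRanges::IRanges(lscS, lscS + lscW - 1L),
              irb = IRanges::IRanges(irbS, irbE),
              ssc = IRanges::IRanges(sscS, sscS + sscW - 1L),
              ira = IRanges::IRanges(iraS, iraE),
              junctions = c(J_LSC_IRb = modpos(irbS, n),
                            J_IRb_SSC = sscS,
                            J_SSC_IRa = modpos(iraS, n),
                            J_IRa_LSC = lscS),
              genomeLength = n)
  part
}

#' Genes gained or lost from the inverted repeat between two genomes
#'
#' A gene counts as IR-resident when its full span lies inside either IR
#' arm (circular containment). The difference in IR gene content between
#' two annotated genomes is the signature of an IR boundary expansion or
#' contraction.
#'
#' @param gA,gB annotated [AnnotatedGenome-class] objects.
#' @param pA,pB their [QuadripartitePartition-class]s.
#' @return list with `gainedInA`, `gainedInB` (gene symbols whose IR
#'   residency is specific to one genome) and `sharedIR`.
#' @export
irGeneContentDiff <- function(gA, pA, gB, pB) {
  irGenes <- function(g, p) {
    f <- genomeFeatures(g)
    if (!length(f)) .stopf("genome %s carries no annotation", genomeId(g))
    n <- genomeLength(g)
    inArm <- function(arm) {
      circContains(IRanges::start(arm), IRanges::end(arm),
                   IRanges::start(f), IRanges::end(f), n)
    }
    sort(unique(S4Vectors::mcols(f)$gene[inArm(p@irb) | inArm(p@ira)]))
  }
  a <- irGenes(gA, pA)
  b <- irGenes(gB, pB)
  list(gainedInA = setdiff(a, b), gainedInB = setdiff(b, a),
       sharedIR = intersect(a, b))
}

#' Tabulate quadripartite structure across genomes
#'
#' @param genomes list of [AnnotatedGenome-class]s.
#' @param partitions matching list of [QuadripartitePartition-class]s.
#' @return data.frame with one row per genome: accession, total and
#'   per-region lengths, and the four junction coordinates (1-based).
#' @export
structureTable <- function(genomes, partitions) {
  do.call(rbind, Map(function(g, p) {
    w <- regionLengths(p); j <- junctions(p)
    data.frame(accession = genomeId(g), length = genomeLength(g),
               LSC = unname(w["LSC"]), IRb = unname(w["IRb"]),
               SSC = unname(w["SSC"]), IRa = unname(w["IRa"]),
               J_LSC_IRb = unname(j["J_LSC_IRb"]),
               J_IRb_SSC = unname(j["J_IRb_SSC"]),
               J_SSC_IRa = unname(j["J_SSC_IRa"]),
               J_IRa_LSC = unname(j["J_IRa_LSC"]),
               stringsAsFactors = FALSE)
  }, genomes, partitions))
}
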