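## Collinear whole-genome comparison: unique-k-mer anchor chaining, SNP and
## indel calling in the inter-anchor gaps, inversion detection from
## reverse-orientation blocks, and genic/intergenic classification.
##
## Both genomes are expected to be orientation-normalised (see
## normalizeOrientation()) so they can be compared as linear strings with a
## common origin.

#' Build a collinear anchor chain between two genomes
#'
#' Matches `k`-mers that are unique within each genome, collapses adjacent
#' matches into maximal exact shared segments, and selects the collinear
#' chain maximising total anchored length (weighted longest-increasing-
#' subsequence). Segments matching in reverse-complement orientation are
#' retained as candidate inversion blocks when they fit inside a gap of the
#' forward chain. `k`-mers containing `N` never anchor.
#'
#' @param a,b orientation-normalised [AnnotatedGenome-class] objects.
#' @param k anchor k-mer size (default 31).
#' @return an [AnchorChain-class]. Warns (but still returns the chain) when
#'   less than half of genome `a` is anchored.
#' @export
buildAnchorChain <- function(a, b, k = 31L) {
  sa <- genomeSeq(a); sb <- genomeSeq(b)
  na <- nchar(sa); nb <- nchar(sb)
  kma <- linKmers(sa, k)
  kmb <- linKmers(sb, k)
  kma[grepl("N", kma, fixed = TRUE)] <- NA
  kmb[grepl("N", kmb, fixed = TRUE)] <- NA
  ua <- !(duplicated(kma) | duplicated(kma, fromLast = TRUE)) & !is.na(kma)
  ub <- !(duplicated(kmb) | duplicated(kmb, fromLast = TRUE)) & !is.na(kmb)
  kmbU <- ifelse(ub, kmb, NA)

  ## forward matches
  idx <- match(ifelse(ua, kma, NA), kmbU, incomparables = NA)
  hit <- which(!is.na(idx))
  fwd <- .collapseDiagonal(hit, idx[hit], k, reverse = FALSE)

  ## reverse-complement matches: revcomp of the k-mer starting at j in b
  ## is the k-mer starting at (nb - j - k + 2) of revcomp(b)
  rcb <- revcompChr(sb)
  kmrcb <- linKmers(rcb, k)
  kmrcb[grepl("N", kmrcb, fixed = TRUE)] <- NA
  rckmb <- rev(kmrcb)                      # indexed by j in b
  urc <- !(duplicated(rckmb) | duplicated(rckmb, fromLast = TRUE)) & !is.na(rckmb)
  idxR <- match(ifelse(ua, kma, NA), ifelse(urc, rckmb, NA), incomparables = NA)
  hitR <- which(!is.na(idxR))
  rev_ <- .collapseDiagonal(hitR, idxR[hitR], k, reverse = TRUE)

  chain <- .chainSegments(fwd)
  revKept <- .reverseBlocksInGaps(rev_, chain, na, nb)

  anchored <- if (nrow(chain)) sum(chain$length) else 0L
  if (anchored < 0.5 * na)
    .warnf("divergent genomes: only %.1f%% of %s anchored against %s",
           100 * anchored / na, genomeId(a), genomeId(b))
  new("AnchorChain", idA = genomeId(a), idB = genomeId(b),
      segments = chain, reverseBlocks = revKept,
      k = as.integer(k), lengthA = as.integer(na), lengthB = as.integer(nb))
}

## Collapse per-position k-mer matches (i in a, j in b) into maximal exact
## segments. Forward: consecutive (i+1, j+1); reverse: consecutive (i+1, j-1)
## (j is the start of the k-mer in b whose revcomp matches at i).
.collapseDiagonal <- function(i, j, k, reverse = FALSE) {
  empty <- data.frame(startA = integer(0), endA = integer(0),
                      startB = integer(0), endB = integer(0),
                      length = integer(0))
  if (!length(i)) return(empty)
  o <- order(i)
  i <- i[o]; j <- j[o]
  step <- if (reverse) -1L else 1L
  brk <- c(TRUE, diff(i) != 1L | diff(j) != step)
  grp <- cumsum(brk)
  out <- lapply(split(seq_along(i), grp), function(ix) {
    i0 <- i[ix[1L]]; i1 <- i[ix[length(ix)]]
    if (!reverse) {
      data.frame(startA = i0, endA = i1 + k - 1L,
                 startB = j[ix[1L]], endB = j[ix[length(ix)]] + k - 1L,
                 length = i1 - i0 + k)
    } else {
      data.frame(startA = i0, endA = i1 + k - 1L,
                 startB = j[ix[length(ix)]], endB = j[ix[1L]] + k - 1L,
                 length = i1 - i0 + k)
    }
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

## Weighted LIS over forward segments, maximising summed anchored length.
## Segments on different diagonals can overlap by up to k-1 at their
## boundaries (a k-mer window straddling a variant can match by chance),
## so chaining permits overlap and trims the downstream segment's start;
## trimming an exact diagonal match keeps it exact.
.chainSegments <- function(seg) {
  if (!nrow(seg)) return(seg)
  seg <- seg[order(seg$startA, seg$startB), , drop = FALSE]
  m <- nrow(seg)
  best <- as.numeric(seg$length)
  prev <- rep(NA_integer_, m)
  for (t in seq_len(m)) {
    if (t == 1L) next
    pr <- seq_len(t - 1L)
    trim <- pmax(seg$endA[pr] - seg$startA[t] + 1L,
                 seg$endB[pr] - seg$startB[t] + 1L, 0L)
    cand <- which(trim < seg$length[t])
    if (length(cand)) {
      w <- best[cand] + seg$length[t] - trim[cand]
      pick <- which.max(w)
      if (w[pick] > best[t]) { best[t] <- w[pick]; prev[t] <- cand[pick] }
    }
  }
  t <- which.max(best)
  path <- integer(0)
  while (!is.na(t)) { path <- c(t, path); t <- prev[t] }
  out <- seg[path, , drop = FALSE]
  if (nrow(out) > 1L) {
    for (i in 2L:nrow(out)) {
      trim <- max(out$endA[i - 1L] - out$startA[i] + 1L,
                  out$endB[i - 1L] - out$startB[i] + 1L, 0L)
      if (trim > 0L) {
        out$startA[i] <- out$startA[i] + trim
        out$startB[i] <- out$startB[i] + trim
        out$length[i] <- out$length[i] - trim
      }
    }
  }
  rownames(out) <- NULL
  out
}

## Keep reverse segments that fall inside one inter-anchor gap of the
## forward chain (in both genomes). A reverse segment can extend a few
## bases past the gap edge when flanking bases complement-pair by chance;
## such segments are trimmed to the gap, anti-diagonally (trimming the
## left edge in A trims the right edge in B and vice versa).
.reverseBlocksInGaps <- function(rev_, chain, na, nb, minKeep = 31L) {
  if (!nrow(rev_)) return(rev_)
  gaps <- .chainGaps(chain, na, nb)
  out <- rev_[0L, , drop = FALSE]
  for (r in seq_len(nrow(rev_))) {
    a1 <- rev_$startA[r]; a2 <- rev_$endA[r]
    b1 <- rev_$startB[r]; b2 <- rev_$endB[r]
    gi <- which(gaps$startA <= a2 & a1 <= gaps$endA &
                gaps$startB <= b2 & b1 <= gaps$endB)
    if (!length(gi)) next
    g <- gaps[gi[1L], ]
    tL <- max(0L, g$startA - a1); a1 <- a1 + tL; b2 <- b2 - tL
    tR <- max(0L, a2 - g$endA);   a2 <- a2 - tR; b1 <- b1 + tR
    tBl <- max(0L, g$startB - b1); b1 <- b1 + tBl; a2 <- a2 - tBl
    tBr <- max(0L, b2 - g$endB);  b2 <- b2 - tBr; a1 <- a1 + tBr
    len <- a2 - a1 + 1L
    if (len < minKeep || (b2 - b1 + 1L) != len) next
    out <- rbind(out, data.frame(startA = a1, endA = a2, startB = b1,
                                 endB = b2, length = len))
  }
  rownames(out) <- NULL
  out
}

## Inter-anchor gaps of a chain, including the leading and trailing gap.
## Zero-width gaps are dropped; coordinates are the first/last unanchored
## base in each genome.
.chainGaps <- function(chain, na, nb) {
  bndA <- c(0L, chain$endA, na + 1L)
  bndB <- c(0L, chain$endB, nb + 1L)
  stA <- c(0L, chain$startA, na + 1L)
  stB <- c(0L, chain$startB, nb + 1L)
  m <- nrow(chain)
  out <- data.frame(startA = integer(0), endA = integer(0),
                    startB = integer(0), endB = integer(0))
  for (t in seq_len(m + 1L)) {
    gA <- c(bndA[t] + 1L, stA[t + 1L] - 1L)
    gB <- c(bndB[t] + 1L, stB[t + 1L] - 1L)
    if (gA[2L] < gA[1L] && gB[2L] < gB[1L]) next
    out <- rbind(out, data.frame(startA = gA[1L], endA = gA[2L],
                                 startB = gB[1L], endB = gB[2L]))
  }
  out
}

#' Detect segmental inversions from an anchor chain
#'
#' Each forward-chain gap whose retained reverse-orientation blocks form one
#' consistent anti-collinear block becomes an inversion record: the segment
#' of genome `a` aligns to the reverse complement of the matched segment of
#' genome `b`, and removing the block restores collinearity. Gaps with
#' overlapping (mutually inconsistent) reverse blocks are reported with
#' `unresolved = TRUE` rather than merged.
#'
#' @param chain an [AnchorChain-class] built with reverse blocks retained.
#' @param a,b the two genomes the chain was built from.
#' @param minIdentity minimum alignment identity between segment A and the
#'   reverse complement of segment B (default 0.9).
#' @return data.frame with columns `startA, endA, startB, endB, length,
#'   identity, unresolved, genes` (comma-separated symbols of features of
#'   `a` fully inside the inverted segment). Zero rows for collinear pairs.
#' @export
detectInversions <- function(chain, a, b, minIdentity = 0.9) {
  empty <- data.frame(startA = integer(0), endA = integer(0),
                      startB = integer(0), endB = integer(0),
                      length = integer(0), identity = numeric(0),
                      unresolved = logical(0), genes = character(0),
                      stringsAsFactors = FALSE)
  rb <- chain@reverseBlocks
  if (!nrow(rb)) return(empty)
  gaps <- .chainGaps(chain@segments, chain@lengthA, chain@lengthB)
  sa <- genomeSeq(a); sb <- genomeSeq(b)
  out <- empty
  for (gi in seq_len(nrow(gaps))) {
    inGap <- rb[gaps$startA[gi] <= rb$startA & rb$endA <= gaps$endA[gi] &
                gaps$startB[gi] <= rb$startB & rb$endB <= gaps$endB[gi], ,
                drop = FALSE]
    if (!nrow(inGap)) next
    inGap <- inGap[order(inGap$startA), , drop = FALSE]
    overl <- FALSE
    if (nrow(inGap) > 1L) {
      m_ <- nrow(inGap)
      overlapA <- any(inGap$startA[-1L] <= inGap$endA[-m_])
      bOrd <- inGap[order(inGap$startB), , drop = FALSE]
      overlapB <- any(bOrd$startB[-1L] <= bOrd$endB[-m_])
      # anti-collinear consistency: B descends as A ascends
      antiOk <- all(diff(inGap$startB) < 0)
      overl <- overlapA || overlapB || !antiOk
    }
    blkA <- c(min(inGap$startA), max(inGap$endA))
    blkB <- c(min(inGap$startB), max(inGap$endB))
    segA <- substr(sa, blkA[1L], blkA[2L])
    segB <- revcompChr(substr(sb, blkB[1L], blkB[2L]))
    ident <- if (identical(segA, segB)) 1.0 else {
      pa <- .nucAlign(segA, segB)
      Biostrings::pid(pa) / 100
    }
    if (!overl && ident < minIdentity) next
    f <- genomeFeatures(a)
    genes <- character(0)
    if (length(f)) {
      inside <- IRanges::start(f) >= blkA[1L] & IRanges::end(f) <= blkA[2L]
      genes <- S4Vectors::mcols(f)$gene[inside]
    }
    out <- rbind(out, data.frame(
      startA = blkA[1L], endA = blkA[2L], startB = blkB[1L], endB = blkB[2L],
      length = blkA[2L] - blkA[1L] + 1L, identity = ident,
      unresolved = overl, genes = paste(genes, collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Call SNPs and indels between two chained genomes
#'
#' Aligns every inter-anchor gap globally (match +1, mismatch -1, gap open
#' -4, gap extend -1), emits one SNP per mismatch column and merges each
#' maximal run of gap columns into a single indel event. Indels are
#' left-normalised (shifted left while the flanking context allows).
#' Gaps occupied by an inversion block are excised from small-variant
#' calling (the flanking remainders are still aligned); inversions are
#' reported separately by [detectInversions()].
#'
#' Events are polarised against genome `a`: a deletion (`alt == "-"`) is
#' sequence present in `a` and absent from `b`; an insertion (`ref == "-"`)
#' is sequence present in `b`, recorded after position `posA`.
#'
#' @param chain an [AnchorChain-class].
#' @param a,b the two genomes the chain was built from.
#' @param maxGapLength refuse gaps longer than this (default 20000 bp;
#'   such a gap is a structural event, not a small variant).
#' @return data.frame with columns `kind` (`SNP`/`indel`), `posA`, `posB`
#'   (1-based; for insertions `posA` is the base after which the insertion
#'   sits), `ref`, `alt`, `length`, `class` (`genic:<gene>` or
#'   `intergenic:<geneL ~ geneR>`).
#' @export
callVariants <- function(chain, a, b, maxGapLength = 20000L) {
  sa <- genomeSeq(a); sb <- genomeSeq(b)
  gaps <- .chainGaps(chain@segments, chain@lengthA, chain@lengthB)
  inv <- detectInversions(chain, a, b)
  recs <- list()
  for (gi in seq_len(nrow(gaps))) {
    gA <- c(gaps$startA[gi], gaps$endA[gi])
    gB <- c(gaps$startB[gi], gaps$endB[gi])
    ## excise any inversion block inside this gap
    pieces <- list(list(gA = gA, gB = gB))
    hit <- inv[gA[1L] <= inv$startA & inv$endA <= gA[2L] &
               gB[1L] <= inv$startB & inv$endB <= gB[2L], , drop = FALSE]
    if (nrow(hit)) {
      pieces <- list()
      curA <- gA[1L]; curB <- gB[1L]
      hit <- hit[order(hit$startA), , drop = FALSE]
      for (hv in seq_len(nrow(hit))) {
        pieces[[length(pieces) + 1L]] <-
          list(gA = c(curA, hit$startA[hv] - 1L),
               gB = c(curB, hit$startB[hv] - 1L))
        curA <- hit$endA[hv] + 1L
        curB <- hit$endB[hv] + 1L
      }
      pieces[[length(pieces) + 1L]] <- list(gA = c(curA, gA[2L]),
                                            gB = c(curB, gB[2L]))
    }
    for (p in pieces) {
      la <- p$gA[2L] - p$gA[1L] + 1L
      lb <- p$gB[2L] - p$gB[1L] + 1L
      if (la <= 0L && lb <= 0L) next
      if (max(la, lb) > maxGapLength)
        .stopf("gap of %d bp at %s:%d exceeds maxGapLength (structural event?)",
               max(la, lb), chain@idA, p$gA[1L])
      gv <- .gapVariants(sa, sb, p$gA, p$gB)
      if (!is.null(gv)) recs[[length(recs) + 1L]] <- gv
    }
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(kind = character(0), posA = integer(0), posB = integer(0),
               ref = character(0), alt = character(0), length = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$posA, df$posB), , drop = FALSE]
    df$class <- vapply(df$posA, function(p) .classifyPos(a, p), character(1))
  } else df$class <- character(0)
  rownames(df) <- NULL
  df
}

## Variants within one gap: gapA = sa[gA1..gA2] vs gapB = sb[gB1..gB2].
.gapVariants <- function(sa, sb, gA, gB) {
  la <- gA[2L] - gA[1L] + 1L
  lb <- gB[2L] - gB[1L] + 1L
  rec <- function(kind, posA, posB, ref, alt)
    data.frame(kind = kind, posA = posA, posB = posB, ref = ref, alt = alt,
               length = ifelse(kind == "SNP", 1L, nchar(ifelse(ref == "-", alt, ref))),
               stringsAsFactors = FALSE)
  if (la <= 0L) {             # pure insertion (b has extra sequence)
    ins <- substr(sb, gB[1L], gB[2L])
    sh <- .leftShiftIndel(sa, gA[1L] - 1L, ins)
    return(rec("indel", sh$pos, gB[1L] - (gA[1L] - 1L - sh$pos), "-", sh$seq))
  }
  if (lb <= 0L) {             # pure deletion (a has extra sequence)
    del <- substr(sa, gA[1L], gA[2L])
    sh <- .leftShiftIndel(sa, gA[1L] - 1L, del)   # same left-context rule
    return(rec("indel", sh$pos + 1L, gB[1L] - (gA[1L] - 1L - sh$pos) - 1L,
               sh$seq, "-"))
  }
  aln <- .nucAlign(substr(sa, gA[1L], gA[2L]), substr(sb, gB[1L], gB[2L]))
  ap <- .charvec(as.character(Biostrings::alignedPattern(aln)))
  as_ <- .charvec(as.character(Biostrings::alignedSubject(aln)))
  posA <- gA[1L] - 1L; posB <- gB[1L] - 1L
  out <- list()
  i <- 1L
  ncol_ <- length(ap)
  while (i <= ncol_) {
    if (ap[i] != "-" && as_[i] != "-") {
      posA <- posA + 1L; posB <- posB + 1L
      if (ap[i] != as_[i])
        out[[length(out) + 1L]] <- rec("SNP", posA, posB, ap[i], as_[i])
      i <- i + 1L
    } else if (ap[i] == "-") {         # insertion run (b only)
      j <- i
      while (j <= ncol_ && ap[j] == "-") j <- j + 1L
      ins <- paste(as_[i:(j - 1L)], collapse = "")
      sh <- .leftShiftIndel(sa, posA, ins)
      out[[length(out) + 1L]] <-
        rec("indel", sh$pos, posB + 1L - (posA - sh$pos), "-", sh$seq)
      posB <- posB + (j - i)
      i <- j
    } else {                           # deletion run (a only)
      j <- i
      while (j <= ncol_ && as_[j] == "-") j <- j + 1L
      del <- paste(ap[i:(j - 1L)], collapse = "")
      sh <- .leftShiftIndel(sa, posA, del)
      out[[length(out) + 1L]] <-
        rec("indel", sh$pos + 1L, posB - (posA - sh$pos), sh$seq, "-")
      posA <- posA + (j - i)
      i <- j
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## Left-normalise an indel: sequence `seq` inserted after position `pos` of
## `s` (or deleted from pos+1). While the base at `pos` equals the last base
## of `seq`, the event can shift one base left. Returns the shifted pos/seq.
.leftShiftIndel <- function(s, pos, seq) {
  L <- nchar(seq)
  while (pos >= 1L && substr(s, pos, pos) == substr(seq, L, L)) {
    seq <- paste0(substr(s, pos, pos), substr(seq, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

## genic/intergenic classification of a 1-based position in genome g
.classifyPos <- function(g, pos) {
  f <- genomeFeatures(g)
  if (!length(f)) return("intergenic:NA")
  n <- genomeLength(g)
  s <- IRanges::start(f); e <- IRanges::end(f)
  inside <- circContains(s, e, pos, pos, n)
  if (any(inside))
    return(paste0("genic:", S4Vectors::mcols(f)$gene[which(inside)[1L]]))
  gene <- S4Vectors::mcols(f)$gene
  distL <- (pos - modpos(e, n)) %% n      # distance from feature end to pos
  distR <- (s - pos) %% n                 # distance from pos to feature start
  paste0("intergenic:", gene[which.min(distL)], " ~ ", gene[which.min(distR)])
}

#' Reconstruct genome B by applying called variants to genome A
#'
#' The reconstruction oracle: applying all variant records (polarised as by
#' [callVariants()]) and inversion records to `a` must reproduce `b`
#' byte-exactly when the call set is complete.
#'
#' @param a the source [AnnotatedGenome-class] (or a character sequence).
#' @param variants data.frame as returned by [callVariants()].
#' @param inversions data.frame as returned by [detectInversions()]
#'   (optional).
#' @return the reconstructed sequence (character scalar).
#' @export
applyVariants <- function(a, variants, inversions = NULL) {
  s <- if (is.character(a)) a else genomeSeq(a)
  ev <- list()
  if (!is.null(variants) && nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      ev[[length(ev) + 1L]] <-
        if (v$kind == "SNP") list(pos = v$posA, type = "snp", alt = v$alt)
        else if (v$ref == "-") list(pos = v$posA, type = "ins", seq = v$alt)
        else list(pos = v$posA, type = "del", len = nchar(v$ref))
    }
  }
  if (!is.null(inversions) && nrow(inversions)) {
    for (i in seq_len(nrow(inversions)))
      ev[[length(ev) + 1L]] <- list(pos = inversions$startA[i], type = "inv",
                                    end = inversions$endA[i])
  }
  if (!length(ev)) return(s)
  ord <- order(vapply(ev, `[[`, numeric(1), "pos"), decreasing = TRUE)
  for (e in ev[ord]) {
    s <- switch(e$type,
      snp = paste0(substr(s, 1L, e$pos - 1L), e$alt,
                   substr(s, e$pos + 1L, nchar(s))),
      ins = paste0(substr(s, 1L, e$pos), e$seq,
                   substr(s, e$pos + 1L, nchar(s))),
      del = paste0(substr(s, 1L, e$pos - 1L),
                   substr(s, e$pos + e$len, nchar(s))),
      inv = paste0(substr(s, 1L, e$pos - 1L),
                   revcompChr(substr(s, e$pos, e$end)),
                   substr(s, e$end + 1L, nchar(s))))
  }
  s
}
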