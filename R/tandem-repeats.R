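## Exact tandem-repeat arrays and the cross-species copy-number-variation
## catalog. Only exact full-copy repetitions are counted (copy numbers are
## integers; no partial terminal copy), units are reported primitive (not
## themselves a repetition of a shorter unit) at the leftmost phase, and
## loci are matched across species by exact flanking-sequence anchors, not
## by coordinate.

#' Find exact tandem-repeat arrays in a genome
#'
#' Scans every unit length and phase for maximal exact full-copy arrays.
#' An array at unit length `u` is reported only with a primitive unit
#' (arrays whose unit is a k-fold repetition of a shorter unit surface at
#' that shorter length instead). Circular genomes are scanned across the
#' origin.
#'
#' @param g an [AnnotatedGenome-class].
#' @param minUnit,maxUnit unit-length bounds in bp (defaults 10-39, the
#'   range observed for chloroplast tandem repeats; sub-10-bp microsatellite
#'   units are out of scope).
#' @param minCopies minimum exact full copies (default 2).
#' @param minSpan minimum total array span in bp (default 20).
#' @return data.frame with columns `unit`, `unitLength`, `copies`, `start`
#'   (1-based leftmost phase), `end` (last base of the last full copy; may
#'   exceed the genome length for origin-spanning arrays), `locus` (flanking
#'   feature pair or containing gene, `NA` without annotation).
#' @export
findTandemRepeats <- function(g, minUnit = 10L, maxUnit = 39L,
                              minCopies = 2L, minSpan = 20L) {
  s <- genomeSeq(g)
  n <- nchar(s)
  circ <- isCircular(g)
  ## scan a doubled sequence so origin-spanning arrays appear contiguous
  ss <- if (circ) paste0(s, s) else s
  sv <- .charvec(ss)
  N <- length(sv)
  out <- list()
  for (u in minUnit:min(maxUnit, n %/% 2L)) {
    if (N <= u) next
    m <- sv[seq_len(N - u)] == sv[(u + 1L):N]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= u * (minCopies - 1L)
    for (ix in which(ok)) {
      i <- starts[ix]
      span <- r$lengths[ix] + u
      copies <- span %/% u
      if (copies < minCopies || copies * u < minSpan) next
      if (circ && i > n) next                    # duplicate in second copy
      if (copies * u > n) next                   # array cannot exceed genome
      unit <- substr(ss, i, i + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      if (!.isPrimitive(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        unit = unit, unitLength = u, copies = copies,
        start = i, end = i + copies * u - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(unit = character(0), unitLength = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), locus = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$unitLength), , drop = FALSE]
  df$locus <- vapply(seq_len(nrow(df)), function(i)
    .locusLabel(g, df$start[i], df$end[i]), character(1))
  rownames(df) <- NULL
  df
}

## primitive <=> the unit is not a whole-number repetition of a shorter unit
.isPrimitive <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u %/% 2L)) {
    if (u %% d != 0L) next
    if (identical(unit, strrep(substr(unit, 1L, d), u %/% d))) return(FALSE)
  }
  TRUE
}

## "geneA ~ geneB" flanking label (or the containing gene) for an interval
.locusLabel <- function(g, start, end) {
  f <- genomeFeatures(g)
  if (!length(f)) return(NA_character_)
  n <- genomeLength(g)
  fs <- IRanges::start(f); fe <- IRanges::end(f)
  gene <- S4Vectors::mcols(f)$gene
  inside <- circContains(fs, fe, start, end, n)
  if (any(inside)) return(gene[which(inside)[1L]])
  distL <- (start - modpos(fe, n)) %% n
  distR <- (fs - modpos(end, n)) %% n
  paste0(gene[which.min(distL)], " ~ ", gene[which.min(distR)])
}

#' Build the cross-species tandem-repeat CNV catalog
#'
#' Loci are matched across species by exact identity of the `flank`-bp
#' sequences immediately flanking each array (never by coordinate). For a
#' species without a detected array at a locus, the inter-flank segment is
#' inspected directly: one full unit copy is recorded as `1`, no copy as
#' `"nf"` (not found). Loci with identical copy vectors across all species
#' are dropped (they are not CNVs); loci whose flanks match ambiguously are
#' kept but flagged rather than guessed.
#'
#' @param trsBySpecies named list (species -> data.frame from
#'   [findTandemRepeats()]).
#' @param genomes named list (species -> [AnnotatedGenome-class]), same
#'   names; the first-listed species provides the locus labels.
#' @param flank flanking-anchor length in bp (default 60).
#' @param maxLocusSpan widest inter-flank segment considered one locus
#'   (default 2000 bp).
#' @return data.frame with `unit`, `unitLength`, one `copies_<species>`
#'   column per species (integer as character, or `"nf"`), `locus`, and
#'   `ambiguous`.
#' @export
buildCnvCatalog <- function(trsBySpecies, genomes, flank = 60L,
                            maxLocusSpan = 2000L) {
  species <- names(trsBySpecies)
  stopifnot(length(species) >= 2L, all(species %in% names(genomes)))
  seqs <- lapply(genomes[species], function(g)
    if (isCircular(g)) paste0(genomeSeq(g), substr(genomeSeq(g), 1L,
                                                   flank + maxLocusSpan))
    else genomeSeq(g))
  lens <- vapply(genomes[species], genomeLength, integer(1))

  claimed <- lapply(stats::setNames(species, species), function(x) integer(0))
  rows <- list()
  for (sp in species) {
    trs <- trsBySpecies[[sp]]
    if (is.null(trs) || !nrow(trs)) next
    for (i in seq_len(nrow(trs))) {
      arr <- trs[i, ]
      if (.overlapsClaimed(arr$start, arr$end, claimed[[sp]])) next
      lf <- .flankSeq(seqs[[sp]], lens[[sp]], arr$start - flank, arr$start - 1L)
      rf <- .flankSeq(seqs[[sp]], lens[[sp]], arr$end + 1L, arr$end + flank)
      if (is.null(lf) || is.null(rf)) next
      res <- lapply(species, function(sp2)
        .locusInSpecies(seqs[[sp2]], lens[[sp2]], lf, rf, arr$unit,
                        flank, maxLocusSpan))
      names(res) <- species
      if (any(vapply(res, is.null, logical(1)))) next   # flank absent somewhere
      ambig <- any(vapply(res, function(x) x$ambiguous, logical(1)))
      copies <- vapply(res, function(x) x$copies, character(1))
      for (sp2 in species) {
        iv <- res[[sp2]]$interval
        if (!is.null(iv)) claimed[[sp2]] <- c(claimed[[sp2]], iv)
      }
      rows[[length(rows) + 1L]] <- c(
        list(unit = arr$unit, unitLength = arr$unitLength),
        stats::setNames(as.list(copies), paste0("copies_", species)),
        stats::setNames(lapply(res, function(x) x$interval[1L]),
                        paste0("start_", species)),
        stats::setNames(lapply(res, function(x) x$interval[2L]),
                        paste0("end_", species)),
        list(locus = .locusLabel(genomes[[species[1L]]],
                                 res[[species[1L]]]$interval[1L],
                                 res[[species[1L]]]$interval[2L]),
             ambiguous = ambig))
    }
  }
  if (!length(rows)) {
    cols <- c("unit", "unitLength", paste0("copies_", species),
              paste0("start_", species), paste0("end_", species), "locus",
              "ambiguous")
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  ## drop non-CNVs: identical, unambiguous copy vectors
  cc <- df[, paste0("copies_", species), drop = FALSE]
  isCnv <- apply(cc, 1L, function(v) length(unique(v)) > 1L) | df$ambiguous
  df <- df[isCnv, , drop = FALSE]
  rownames(df) <- NULL
  df
}

.overlapsClaimed <- function(start, end, claimed) {
  if (!length(claimed)) return(FALSE)
  iv <- matrix(claimed, ncol = 2L, byrow = TRUE)
  any(start <= iv[, 2L] & end >= iv[, 1L])
}

## flank sequence on the (possibly extended-circular) string; NULL if the
## interval falls off a linear sequence
.flankSeq <- function(ss, n, start, end) {
  if (start < 1L) {
    if (nchar(ss) > n) { start <- start + n; end <- end + n }  # circular
    else return(NULL)
  }
  if (end > nchar(ss)) return(NULL)
  substr(ss, start, end)
}

## Locate a locus by its flank pair in one species and count exact full
## tandem copies of `unit` in the inter-flank segment.
.locusInSpecies <- function(ss, n, lf, rf, unit, flank, maxLocusSpan) {
  lhits <- .allOccurrences(ss, lf, n)
  if (!length(lhits)) return(NULL)
  found <- NULL
  ambiguous <- FALSE
  for (lh in lhits) {
    segStart <- lh + flank
    windowEnd <- min(segStart + maxLocusSpan + flank, nchar(ss))
    win <- substr(ss, segStart, windowEnd)
    rrel <- .allOccurrences(win, rf, nchar(win))
    if (!length(rrel)) next
    segEnd <- segStart + rrel[1L] - 2L          # base before right flank
    cand <- c(segStart, segEnd)
    if (is.null(found)) found <- cand else ambiguous <- TRUE
    if (length(rrel) > 1L) ambiguous <- TRUE
  }
  if (is.null(found)) return(NULL)
  segment <- if (found[2L] >= found[1L])
    substr(ss, found[1L], found[2L]) else ""
  list(copies = as.character(.maxTandemCopies(segment, unit)),
       ambiguous = ambiguous,
       interval = c(modpos(found[1L], n),
                    modpos(found[1L], n) + max(found[2L] - found[1L], 0L)))
}

## all start positions of exact pattern occurrences with start <= n
.allOccurrences <- function(ss, pat, n) {
  hits <- gregexpr(pat, ss, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  hits <- as.integer(hits)
  hits[hits <= n]
}

## maximal exact full-copy tandem run of `unit` within `segment`
## (0 when the unit is absent, 1 when present but not repeated)
.maxTandemCopies <- function(segment, unit) {
  if (!nzchar(segment)) return("nf")
  u <- nchar(unit)
  hits <- .allOccurrences(segment, unit, nchar(segment))
  if (!length(hits)) return("nf")
  best <- 1L
  for (h in hits) {
    c_ <- 1L
    while (substr(segment, h + c_ * u, h + (c_ + 1L) * u - 1L) == unit &&
           h + (c_ + 1L) * u - 1L <= nchar(segment)) c_ <- c_ + 1L
    best <- max(best, c_)
  }
  best
}
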