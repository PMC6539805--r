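## Region-wise SNP tallies across 45S rDNA cistron units. One unit carries
## the 18S/ITS1/5.8S/ITS2/26S annotation; the others are projected onto it
## by reference-pivot progressive pairwise alignment (three near-identical
## units make a full multiple alignment unnecessary and this keeps the
## output deterministic).

#' Tally SNPs per cistron region across 45S units
#'
#' Aligns every unit pairwise against the annotated reference unit and
#' stacks the alignments on reference coordinates. A SNP is a column with at
#' least two distinct bases among the units and no gap; columns containing
#' an IUPAC ambiguity code (a heterogeneous site within one species) are
#' flagged and excluded from the per-region counts. Insertions relative to
#' the reference are indel events, not SNP columns.
#'
#' @param units list of [CistronUnit-class]s (>= 2).
#' @param refId id of the region-annotated reference unit; defaults to the
#'   first unit carrying regions.
#' @return list with `counts` (named integer per region, in cistron order),
#'   `total`, `heterogeneousSites` (reference positions excluded), and
#'   `regionStatus` (named character: `"ok"` or `"NA"` when a region could
#'   not be projected).
#' @export
tallyRegionVariants <- function(units, refId = NULL) {
  if (length(units) < 2L) .stopf("need at least two cistron units")
  ids <- vapply(units, cistronId, character(1))
  if (is.null(refId)) {
    hasReg <- which(vapply(units, function(u) length(u@regions) > 0L, logical(1)))
    if (!length(hasReg)) .stopf("no unit carries region annotation")
    refId <- ids[hasReg[1L]]
  }
  ref <- units[[match(refId, ids)]]
  if (!length(ref@regions)) .stopf("reference unit %s carries no regions", refId)
  mat <- .cistronBaseMatrix(units, refId)

  isBase <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  isGap <- mat == "-"
  hasAmbig <- apply(!isBase & !isGap, 2L, any)
  noGap <- !apply(isGap, 2L, any)
  distinct <- apply(mat, 2L, function(col) length(unique(col)))
  snpCol <- noGap & !hasAmbig & distinct >= 2L
  heteroCol <- which(noGap & hasAmbig)

  reg <- ref@regions
  counts <- stats::setNames(integer(length(reg)), names(reg))
  status <- stats::setNames(rep("ok", length(reg)), names(reg))
  for (r in seq_along(reg)) {
    cols <- IRanges::start(reg)[r]:IRanges::end(reg)[r]
    gapFrac <- vapply(seq_len(nrow(mat)), function(i) mean(isGap[i, cols]),
                      numeric(1))
    if (any(gapFrac > 0.5)) {      # region unalignable in some unit
      counts[r] <- NA_integer_
      status[r] <- "NA"
    } else {
      counts[r] <- sum(snpCol[cols])
    }
  }
  list(counts = counts, total = sum(counts, na.rm = TRUE),
       heterogeneousSites = heteroCol, regionStatus = status)
}

## Stack all units on reference coordinates by pairwise global alignment:
## a character matrix (unit id x reference position) of aligned bases,
## "-" where a unit has a gap. Insertions relative to the reference are
## not represented (they are indel events, not columns).
.cistronBaseMatrix <- function(units, refId = NULL) {
  ids <- vapply(units, cistronId, character(1))
  if (is.null(refId)) {
    hasReg <- which(vapply(units, function(u) length(u@regions) > 0L,
                           logical(1)))
    refId <- ids[if (length(hasReg)) hasReg[1L] else 1L]
  }
  refSeq <- cistronSeq(units[[match(refId, ids)]])
  n <- nchar(refSeq)
  mat <- matrix("-", nrow = length(units), ncol = n,
                dimnames = list(ids, NULL))
  mat[refId, ] <- .charvec(refSeq)
  for (u in units[ids != refId]) {
    aln <- .nucAlign(refSeq, cistronSeq(u))
    ap <- .charvec(as.character(Biostrings::alignedPattern(aln)))
    as_ <- .charvec(as.character(Biostrings::alignedSubject(aln)))
    mat[cistronId(u), ] <- as_[ap != "-"]
  }
  mat
}

## map a reference column to the corresponding position in another unit
## (NA when the unit has a gap there)
.mapRefColToUnit <- function(ref, unit, col) {
  if (identical(cistronId(ref), cistronId(unit))) return(col)
  aln <- .nucAlign(cistronSeq(ref), cistronSeq(unit))
  ap <- .charvec(as.character(Biostrings::alignedPattern(aln)))
  as_ <- .charvec(as.character(Biostrings::alignedSubject(aln)))
  refPos <- cumsum(ap != "-")
  uPos <- cumsum(as_ != "-")
  hit <- which(refPos == col & ap != "-")
  if (!length(hit) || as_[hit[1L]] == "-") return(NA_integer_)
  uPos[hit[1L]]
}
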