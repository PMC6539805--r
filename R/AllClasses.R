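#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges start end width
#' @importFrom GenomicRanges GRanges seqnames strand
NULL

## ---------------------------------------------------------------------------
## AnnotatedGenome
## ---------------------------------------------------------------------------

#' AnnotatedGenome: a circular annotated plastid genome
#'
#' Holds an uppercase DNA sequence (alphabet `A,C,G,T,N`), a circularity flag
#' and strand-aware gene features. Feature coordinates are 1-based inclusive;
#' a feature spanning the circular origin is encoded with `end > length`
#' (with `end <= start + length - 1`).
#'
#' @slot id accession-style identifier.
#' @slot seq a [Biostrings::DNAString] (uppercase).
#' @slot circular logical scalar; `TRUE` for plastomes.
#' @slot features a [GenomicRanges::GRanges] with metadata columns `gene`
#'   (symbol, e.g. `ycf2`, `trnL-CAA`), `kind` (one of `CDS`, `tRNA`, `rRNA`,
#'   `misc`) and `codon_start` (1-3, CDS reading-frame offset).
#'
#' @seealso [readGenome()], [annotatedGenome()], [extractFeatureSequence()]
#' @export
setClass("AnnotatedGenome",
         representation(id = "character", seq = "ANY",
                        circular = "logical", features = "GRanges"))

.FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "misc")

setValidity("AnnotatedGenome", function(object) {
  msg <- character(0)
  n <- length(object@seq)
  if (n == 0L) msg <- c(msg, "sequence must be non-empty")
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty string")
  bad <- setdiff(Biostrings::uniqueLetters(object@seq), c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains non-ACGTN letters: ",
                         paste(bad, collapse = ",")))
  f <- object@features
  if (length(f)) {
    mc <- S4Vectors::mcols(f)
    if (!all(c("gene", "kind") %in% colnames(mc))) {
      msg <- c(msg, "features need 'gene' and 'kind' metadata columns")
    } else {
      if (any(!nzchar(mc$gene))) msg <- c(msg, "feature names must be non-empty")
      if (any(!mc$kind %in% .FEATURE_KINDS))
        msg <- c(msg, "feature kind must be CDS/tRNA/rRNA/misc")
      if (any(IRanges::start(f) < 1L) || any(IRanges::start(f) > n))
        msg <- c(msg, "feature starts must lie in [1, length]")
      if (any(IRanges::end(f) > IRanges::start(f) + n - 1L))
        msg <- c(msg, "feature end may exceed length only to span the origin")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param id accession-style identifier.
#' @param seq DNA sequence as a character scalar or `DNAString`; uppercased.
#' @param circular logical; defaults to `TRUE`.
#' @param features a `GRanges` with `gene`/`kind` metadata columns, or a
#'   data.frame with columns `gene`, `kind`, `start`, `end`, `strand`
#'   (1-based inclusive) and optionally `codon_start`.
#' @return an [AnnotatedGenome-class] object.
#' @examples
#' g <- annotatedGenome("toy", "ATGAAATAA",
#'                      features = data.frame(gene = "orf1", kind = "CDS",
#'                                            start = 1, end = 9, strand = "+"))
#' genomeLength(g)
#' @export
annotatedGenome <- function(id, seq, circular = TRUE, features = NULL) {
  sq <- Biostrings::DNAString(toupper(as.character(seq)))
  if (is.null(features)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene <- character(0)
    S4Vectors::mcols(gr)$kind <- character(0)
    S4Vectors::mcols(gr)$codon_start <- integer(0)
  } else if (is.data.frame(features)) {
    if (nrow(features) == 0L) return(annotatedGenome(id, sq, circular, NULL))
    cs <- if ("codon_start" %in% names(features)) as.integer(features$codon_start)
          else rep(1L, nrow(features))
    gr <- GenomicRanges::GRanges(
      seqnames = id,
      ranges = IRanges::IRanges(start = as.integer(features$start),
                                end = as.integer(features$end)),
      strand = features$strand)
    S4Vectors::mcols(gr)$gene <- as.character(features$gene)
    S4Vectors::mcols(gr)$kind <- as.character(features$kind)
    S4Vectors::mcols(gr)$codon_start <- cs
  } else {
    gr <- features
    if (is.null(S4Vectors::mcols(gr)$codon_start))
      S4Vectors::mcols(gr)$codon_start <- rep(1L, length(gr))
  }
  gr <- gr[order(IRanges::start(gr))]
  new("AnnotatedGenome", id = id, seq = sq, circular = circular, features = gr)
}

#' @describeIn annotatedGenome accession identifier
#' @param x,object an `AnnotatedGenome`
#' @export
genomeId <- function(x) x@id

#' @describeIn annotatedGenome genome sequence as an uppercase character scalar
#' @export
genomeSeq <- function(x) as.character(x@seq)

#' @describeIn annotatedGenome genome length in bp
#' @export
genomeLength <- function(x) length(x@seq)

#' @describeIn annotatedGenome circularity flag
#' @export
isCircular <- function(x) x@circular

#' @describeIn annotatedGenome gene features as a `GRanges`
#' @export
genomeFeatures <- function(x) x@features

setMethod("show", "AnnotatedGenome", function(object) {
  cat(sprintf("AnnotatedGenome %s: %s bp, %s, %d features\n",
              object@id, format(length(object@seq), big.mark = ","),
              if (object@circular) "circular" else "linear",
              length(object@features)))
})

## ---------------------------------------------------------------------------
## CistronUnit
## ---------------------------------------------------------------------------

#' CistronUnit: a 45S ribosomal DNA cistron unit
#'
#' A linear nuclear rDNA repeat unit with the five canonical regions
#' `18S < ITS1 < 5.8S < ITS2 < 26S`, stored as contiguous, ordered,
#' non-overlapping 1-based intervals tiling a sub-interval of the sequence.
#' IUPAC ambiguity codes are allowed in the sequence (they encode
#' heterogeneous sites observed between accessions of one species).
#'
#' @slot id accession-style identifier.
#' @slot seq a [Biostrings::DNAString].
#' @slot regions a named [IRanges::IRanges] over the five region names, or
#'   empty when the unit carries no annotation.
#' @export
setClass("CistronUnit",
         representation(id = "character", seq = "ANY", regions = "IRanges"))

.CISTRON_REGIONS <- c("18S", "ITS1", "5.8S", "ITS2", "26S")

setValidity("CistronUnit", function(object) {
  msg <- character(0)
  r <- object@regions
  if (length(r)) {
    if (!identical(names(r), .CISTRON_REGIONS))
      msg <- c(msg, "regions must be named 18S, ITS1, 5.8S, ITS2, 26S in order")
    else {
      if (any(IRanges::start(r)[-1L] != IRanges::end(r)[-length(r)] + 1L))
        msg <- c(msg, "regions must be contiguous and ordered")
      if (IRanges::end(r)[length(r)] > length(object@seq))
        msg <- c(msg, "regions exceed the sequence")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CistronUnit
#'
#' @param id accession identifier.
#' @param seq DNA sequence (character or `DNAString`).
#' @param regions `NULL`, a named `IRanges`, or a named list/vector of region
#'   lengths in order `18S, ITS1, 5.8S, ITS2, 26S` (regions then tile the
#'   sequence from position 1).
#' @return a [CistronUnit-class] object.
#' @export
cistronUnit <- function(id, seq, regions = NULL) {
  sq <- Biostrings::DNAString(toupper(as.character(seq)))
  if (is.null(regions)) {
    r <- IRanges::IRanges()
  } else if (methods::is(regions, "IRanges")) {
    r <- regions
  } else {
    len <- as.integer(unlist(regions))
    stopifnot(identical(names(regions), .CISTRON_REGIONS))
    e <- cumsum(len)
    r <- IRanges::IRanges(start = c(1L, head(e, -1L) + 1L), end = e,
                          names = .CISTRON_REGIONS)
  }
  new("CistronUnit", id = id, seq = sq, regions = r)
}

#' @describeIn cistronUnit region intervals (named `IRanges`)
#' @param x an object of class `CistronUnit`
#' @export
cistronRegions <- function(x) x@regions

#' @describeIn cistronUnit unit sequence as a character scalar
#' @export
cistronSeq <- function(x) as.character(x@seq)

#' @describeIn cistronUnit accession identifier
#' @export
cistronId <- function(x) x@id

setMethod("show", "CistronUnit", function(object) {
  cat(sprintf("CistronUnit %s: %d bp%s\n", object@id, length(object@seq),
              if (length(object@regions))
                paste0(" (", paste(sprintf("%s:%d", names(object@regions),
                                           IRanges::width(object@regions)),
                                   collapse = ", "), ")")
              else " (unannotated)"))
})

## ---------------------------------------------------------------------------
## IRPair and QuadripartitePartition
## ---------------------------------------------------------------------------

#' IRPair: the two inverted-repeat arms of a plastome
#'
#' Arm intervals are 1-based inclusive on the circle; an arm spanning the
#' origin is encoded with `end > genomeLength`. The sequence at `ira` equals
#' the reverse complement of the sequence at `irb` up to `mismatches`
#' positions (0 under the default exact-extension mode).
#'
#' @slot ira,irb single-range [IRanges::IRanges] for the two arms; `irb` is
#'   the arm followed (clockwise) by the SSC, `ira` the arm followed by the
#'   LSC, matching the conventional LSC-IRb-SSC-IRa order.
#' @slot irLength arm length in bp.
#' @slot mismatches number of tolerated mismatches between the arms.
#' @slot genomeLength length of the genome the arms were detected on.
#' @seealso [detectInvertedRepeats()], [partitionQuadripartite()]
#' @export
setClass("IRPair",
         representation(ira = "IRanges", irb = "IRanges",
                        irLength = "integer", mismatches = "integer",
                        genomeLength = "integer"))

setMethod("show", "IRPair", function(object) {
  fmt <- function(r) sprintf("[%s..%s]", IRanges::start(r), IRanges::end(r))
  cat(sprintf("IRPair: %s bp arms, IRb %s / IRa %s (%d mismatches)\n",
              format(object@irLength, big.mark = ","), fmt(object@irb),
              fmt(object@ira), object@mismatches))
})

#' @describeIn detectInvertedRepeats arm length in bp
#' @param x an `IRPair`
#' @export
irLength <- function(x) x@irLength

#' QuadripartitePartition: LSC / IRb / SSC / IRa tiling of a plastome
#'
#' The four intervals tile the circle exactly once in the order
#' LSC, IRb, SSC, IRa; `|LSC| >= |SSC|`. Junctions are reported 1-based as
#' the first base of the downstream region.
#'
#' @slot lsc,irb,ssc,ira single-range [IRanges::IRanges] (1-based inclusive;
#'   `end > genomeLength` encodes an origin-spanning region).
#' @slot junctions named numeric of length 4: `J_LSC_IRb`, `J_IRb_SSC`,
#'   `J_SSC_IRa`, `J_IRa_LSC`, each the 1-based start of the downstream
#'   region.
#' @slot genomeLength genome length in bp.
#' @export
setClass("QuadripartitePartition",
         representation(lsc = "IRanges", irb = "IRanges", ssc = "IRanges",
                        ira = "IRanges", junctions = "numeric",
                        genomeLength = "integer"))

setValidity("QuadripartitePartition", function(object) {
  n <- object@genomeLength
  tot <- sum(vapply(list(object@lsc, object@irb, object@ssc, object@ira),
                    IRanges::width, integer(1)))
  if (tot != n) return(sprintf("intervals sum to %d, expected %d", tot, n))
  if (IRanges::width(object@lsc) < IRanges::width(object@ssc))
    return("|LSC| must be >= |SSC|")
  TRUE
})

#' @describeIn partitionQuadripartite region widths as a named vector
#' @param x a `QuadripartitePartition`
#' @export
regionLengths <- function(x) {
  c(LSC = IRanges::width(x@lsc), IRb = IRanges::width(x@irb),
    SSC = IRanges::width(x@ssc), IRa = IRanges::width(x@ira))
}

#' @describeIn partitionQuadripartite the four junction coordinates (1-based
#'   first base of the downstream region)
#' @export
junctions <- function(x) x@junctions

setMethod("show", "QuadripartitePartition", function(object) {
  w <- regionLengths(object)
  cat(sprintf("QuadripartitePartition: LSC %s / IRb %s / SSC %s / IRa %s bp\n",
              format(w["LSC"], big.mark = ","), format(w["IRb"], big.mark = ","),
              format(w["SSC"], big.mark = ","), format(w["IRa"], big.mark = ",")))
  cat("  junctions:", paste(sprintf("%s=%d", names(object@junctions),
                                    object@junctions), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## AnchorChain
## ---------------------------------------------------------------------------

#' AnchorChain: collinear exact-match decomposition of two genomes
#'
#' Maximal unique exact shared segments between two (orientation-normalised)
#' genomes, chained collinearly; reverse-orientation blocks that fit in a
#' forward gap are retained as candidate inversions.
#'
#' @slot idA,idB identifiers of the two genomes.
#' @slot segments data.frame of chained forward segments with columns
#'   `startA, endA, startB, endB, length` (1-based inclusive), monotone in
#'   both genomes.
#' @slot reverseBlocks data.frame of retained reverse-orientation blocks with
#'   the same columns; segment A matches the reverse complement of segment B.
#' @slot k anchor k-mer size.
#' @slot lengthA,lengthB genome lengths.
#' @seealso [buildAnchorChain()], [callVariants()], [detectInversions()]
#' @export
setClass("AnchorChain",
         representation(idA = "character", idB = "character",
                        segments = "data.frame", reverseBlocks = "data.frame",
                        k = "integer", lengthA = "integer", lengthB = "integer"))

setMethod("show", "AnchorChain", function(object) {
  cat(sprintf("AnchorChain %s vs %s: %d forward segments (%s bp anchored), %d reverse blocks\n",
              object@idA, object@idB, nrow(object@segments),
              format(sum(object@segments$length), big.mark = ","),
              nrow(object@reverseBlocks)))
})

## ---------------------------------------------------------------------------
## MarkerAssay
## ---------------------------------------------------------------------------

#' MarkerAssay: a species-authentication PCR assay
#'
#' @slot id assay identifier (e.g. `CNV01`).
#' @slot kind one of `pair` (two primers spanning a length polymorphism),
#'   `three_primer` (control pair plus an IR-junction primer) or
#'   `allele_specific` (SNP-terminal primer plus shared reverse, with a
#'   control pair).
#' @slot primers named character vector of primer sequences, 5'→3'.
#' @slot targetLocus human-readable locus label (e.g. `"psaC ~ ndhE"`).
#' @slot expected named list: species -> sorted numeric vector of predicted
#'   product sizes in bp (length 0 means no amplification, printed `na`).
#' @seealso [designAssay()], [inSilicoPcr()], [discriminationMatrix()]
#' @export
setClass("MarkerAssay",
         representation(id = "character", kind = "character",
                        primers = "character", targetLocus = "character",
                        expected = "list"))

setValidity("MarkerAssay", function(object) {
  if (!object@kind %in% c("pair", "three_primer", "allele_specific"))
    return("kind must be pair/three_primer/allele_specific")
  np <- length(object@primers)
  if (object@kind == "pair" && np != 2L) return("pair assays need 2 primers")
  if (object@kind != "pair" && np != 3L)
    return("three_primer/allele_specific assays need 3 primers")
  TRUE
})

#' @describeIn designAssay expected product-size map (species -> bp vector)
#' @param x a `MarkerAssay`
#' @export
expectedProducts <- function(x) x@expected

#' @describeIn designAssay primer sequences (named, 5'→3')
#' @export
assayPrimers <- function(x) x@primers

setMethod("show", "MarkerAssay", function(object) {
  cat(sprintf("MarkerAssay %s (%s) at %s\n", object@id, object@kind,
              object@targetLocus))
  for (nm in names(object@primers))
    cat(sprintf("  %-10s 5'-%s-3'\n", nm, object@primers[[nm]]))
  sizes <- vapply(object@expected, function(v)
    if (length(v)) paste(sort(v), collapse = "+") else "na", character(1))
  cat("  products:", paste(sprintf("%s=%s", names(sizes), sizes),
                           collapse = " / "), "\n")
})
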