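## Reading and writing annotated circular genomes and 45S cistron units,
## plus the coordinate/orientation normalisation shared by all later stages.
##
## Supported formats: GenBank flat file (reader; minimal writer), FASTA
## (reader/writer) with a tab-separated feature table (gene, kind, start,
## end, strand[, codon_start]; 1-based inclusive) as annotation fallback.
## join() locations are supported; contiguous-over-the-origin joins are
## merged into one origin-spanning feature, any other join (e.g. the
## trans-spliced rps12) is split into independent parts.

#' Read an annotated genome from GenBank or FASTA
#'
#' @param path path to a GenBank flat file or a FASTA file.
#' @param format `"auto"` (sniffed from the first line), `"genbank"` or
#'   `"fasta"`.
#' @param featureTable for FASTA input, optional path to a tab-separated
#'   feature table with columns `gene`, `kind`, `start`, `end`, `strand`
#'   (1-based inclusive) and optionally `codon_start`.
#' @param circular circularity flag for FASTA input (GenBank input takes the
#'   topology from the LOCUS line).
#' @param id identifier override; defaults to the record name.
#' @return an [AnnotatedGenome-class].
#' @export
readGenome <- function(path, format = c("auto", "genbank", "fasta"),
                       featureTable = NULL, circular = TRUE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  if (format == "genbank") .readGenbank(path, id = id)
  else .readFastaGenome(path, featureTable, circular, id = id)
}

.readFastaGenome <- function(path, featureTable, circular, id = NULL) {
  ## read as raw strings first so a bad residue yields a position-specific
  ## error instead of a DNAString coercion failure
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 1L)
    .stopf("expected exactly one FASTA record in %s, found %d", path, length(ss))
  if (is.null(id)) id <- strsplit(names(ss)[1L], "\\s+")[[1L]][1L]
  feats <- NULL
  if (!is.null(featureTable)) {
    feats <- utils::read.delim(featureTable, stringsAsFactors = FALSE)
    if (nrow(feats) == 0L) feats <- NULL
    else {
      need <- c("gene", "kind", "start", "end", "strand")
      if (!all(need %in% names(feats)))
        .stopf("feature table %s lacks columns: %s", featureTable,
               paste(setdiff(need, names(feats)), collapse = ","))
    }
  }
  .checkAcgtn(as.character(ss[[1L]]), path)
  annotatedGenome(id, ss[[1L]], circular = circular, features = feats)
}

.checkAcgtn <- function(s, label) {
  bad <- regexpr("[^ACGTN]", toupper(s))
  if (bad > 0L)
    .stopf("non-ACGTN residue '%s' at position %d in %s",
           substr(toupper(s), bad, bad), bad, label)
}

## Minimal GenBank flat-file parser: LOCUS topology, FEATURES with
## gene/CDS/tRNA/rRNA keys, location operators complement() and join(),
## /gene= and /codon_start= qualifiers, ORIGIN sequence block.
.readGenbank <- function(path, id = NULL) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines)
  if (!length(locus)) .stopf("%s: no LOCUS line (line 1)", path)
  lf <- strsplit(trimws(lines[locus[1L]]), "\\s+")[[1L]]
  recName <- if (length(lf) >= 2L) lf[2L] else "genome"
  circ <- any(grepl("circular", lines[locus[1L]], ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) .stopf("%s: no ORIGIN block (line %d expected after features)",
                           path, length(lines))
  endRec <- grep("^//", lines)
  endRec <- if (length(endRec)) endRec[endRec > ori[1L]][1L] else length(lines) + 1L
  seqLines <- lines[(ori[1L] + 1L):(endRec - 1L)]
  sq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(sq)) .stopf("%s: empty sequence after ORIGIN (line %d)", path, ori[1L])
  .checkAcgtn(sq, path)
  n <- nchar(sq)

  featStart <- grep("^FEATURES", lines)
  feats <- NULL
  if (length(featStart)) {
    block <- lines[(featStart[1L] + 1L):(ori[1L] - 1L)]
    feats <- .parseGbFeatures(block, n, path, offset = featStart[1L])
  }
  if (is.null(id)) id <- recName
  annotatedGenome(id, sq, circular = circ, features = feats)
}

.parseGbFeatures <- function(block, n, path, offset = 0L) {
  keyIdx <- grep("^ {5}\\S", block)
  out <- list()
  for (ii in seq_along(keyIdx)) {
    i <- keyIdx[ii]
    j <- if (ii < length(keyIdx)) keyIdx[ii + 1L] - 1L else length(block)
    key <- sub("^ {5}(\\S+).*$", "\\1", block[i])
    kind <- switch(key, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   gene = NA_character_, misc_feature = "misc", NULL)
    if (is.null(kind) || is.na(kind)) next   # 'gene' keys duplicate CDS/tRNA/rRNA
    body <- paste(trimws(block[i:j]), collapse = " ")
    loc <- sub(paste0("^", key, "\\s+"), "", trimws(block[i]))
    # location may continue on following lines until the first qualifier
    kk <- i + 1L
    while (kk <= j && !grepl("^\\s+/", block[kk])) {
      loc <- paste0(loc, trimws(block[kk])); kk <- kk + 1L
    }
    gene <- if (grepl('/gene="', body, fixed = TRUE))
      sub('.*?/gene="([^"]+)".*', "\\1", body) else key
    cs <- if (grepl("/codon_start=", body, fixed = TRUE))
      as.integer(sub(".*?/codon_start=(\\d+).*", "\\1", body)) else 1L
    parsed <- tryCatch(.parseGbLocation(loc, n),
                       error = function(e)
                         .stopf("%s: malformed location '%s' (line %d)",
                                path, loc, offset + i))
    for (p in seq_len(nrow(parsed$spans))) {
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, kind = kind,
        start = parsed$spans$start[p], end = parsed$spans$end[p],
        strand = if (parsed$complement) "-" else "+",
        codon_start = cs, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## Returns list(spans = data.frame(start,end), complement = flag).
## Contiguous join parts crossing the origin are merged into one
## origin-spanning interval (end > n); other join parts stay separate.
.parseGbLocation <- function(loc, n) {
  comp <- FALSE
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  spans <- lapply(seq_along(parts), function(i) {
    if (length(m[[i]]) == 3L)
      c(as.integer(m[[i]][2L]), as.integer(m[[i]][3L]))
    else if (length(single[[i]]) == 2L)
      rep(as.integer(single[[i]][2L]), 2L)
    else stop("bad span")
  })
  df <- data.frame(start = vapply(spans, `[`, integer(1), 1L),
                   end = vapply(spans, `[`, integer(1), 2L))
  # merge a two-part join that is contiguous across the origin
  if (nrow(df) == 2L && df$end[1L] == n && df$start[2L] == 1L)
    df <- data.frame(start = df$start[1L], end = n + df$end[2L])
  list(spans = df, complement = comp)
}

#' Write an annotated genome
#'
#' @param g an [AnnotatedGenome-class].
#' @param path output path. For `format = "fasta"` the features are written
#'   alongside as `<path>.features.tsv` (unless `featureTable` is given).
#' @param format `"fasta"` or `"genbank"` (minimal flat file).
#' @param featureTable path for the feature table when `format = "fasta"`.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(g, path, format = c("fasta", "genbank"),
                        featureTable = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(genomeSeq(g))
    names(ss) <- genomeId(g)
    Biostrings::writeXStringSet(ss, path)
    if (is.null(featureTable)) featureTable <- paste0(path, ".features.tsv")
    utils::write.table(.featureDf(g), featureTable, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    .writeGenbank(g, path)
  }
  invisible(path)
}

.featureDf <- function(g) {
  f <- genomeFeatures(g)
  data.frame(gene = S4Vectors::mcols(f)$gene, kind = S4Vectors::mcols(f)$kind,
             start = IRanges::start(f), end = IRanges::end(f),
             strand = as.character(GenomicRanges::strand(f)),
             codon_start = S4Vectors::mcols(f)$codon_start,
             stringsAsFactors = FALSE)
}

.writeGenbank <- function(g, path) {
  n <- genomeLength(g)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   PLN",
                     genomeId(g), n,
                     if (isCircular(g)) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s.", genomeId(g)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  df <- .featureDf(g)
  if (nrow(df)) for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    loc <- if (e > n) sprintf("join(%d..%d,1..%d)", s, n, e - n)
           else sprintf("%d..%d", s, e)
    if (df$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (df$kind[i] == "misc") "misc_feature" else df$kind[i]
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', df$gene[i]), con)
    if (df$kind[i] == "CDS" && df$codon_start[i] != 1L)
      writeLines(sprintf("                     /codon_start=%d",
                         df$codon_start[i]), con)
  }
  writeLines("ORIGIN", con)
  sq <- genomeSeq(g)
  for (s0 in seq(1L, n, by = 60L)) {
    chunk <- substr(sq, s0, min(s0 + 59L, n))
    parts <- substring(chunk, seq(1L, nchar(chunk), 10L),
                       pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s0, tolower(paste(parts, collapse = " "))), con)
  }
  writeLines("//", con)
}

#' Read a 45S cistron unit from FASTA
#'
#' @param path FASTA file with one record.
#' @param regions `NULL` (unannotated unit), a named vector/list of region
#'   lengths in order `18S, ITS1, 5.8S, ITS2, 26S`, or a path to a two-column
#'   TSV (`region`, `length`) in that order.
#' @param id identifier override.
#' @return a [CistronUnit-class].
#' @export
readCistron <- function(path, regions = NULL, id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) .stopf("expected one FASTA record in %s", path)
  if (is.null(id)) id <- strsplit(names(ss)[1L], "\\s+")[[1L]][1L]
  if (is.character(regions) && length(regions) == 1L && file.exists(regions)) {
    df <- utils::read.delim(regions, stringsAsFactors = FALSE)
    regions <- stats::setNames(as.list(df$length), df$region)
  }
  cistronUnit(id, ss[[1L]], regions)
}

## ---------------------------------------------------------------------------
## Feature sequence extraction and orientation normalisation
## ---------------------------------------------------------------------------

#' Extract the strand-corrected sequence of a feature
#'
#' Origin-spanning features (encoded with `end > length`) concatenate the
#' tail and head of the circular sequence; minus-strand features return the
#' reverse complement. The `codon_start` offset is *not* applied here.
#'
#' @param g an [AnnotatedGenome-class].
#' @param f a feature: a single-row `GRanges`, an index into
#'   `genomeFeatures(g)`, or a gene symbol (first match).
#' @return the feature sequence as a character scalar.
#' @examples
#' g <- annotatedGenome("toy", "ATGCCC")
#' extractFeatureSequence(g, GenomicRanges::GRanges("toy", IRanges::IRanges(1, 3)))
#' @export
extractFeatureSequence <- function(g, f) {
  if (is.character(f)) {
    i <- which(S4Vectors::mcols(genomeFeatures(g))$gene == f)
    if (!length(i)) .stopf("no feature named '%s' in %s", f, genomeId(g))
    f <- genomeFeatures(g)[i[1L]]
  } else if (is.numeric(f)) {
    f <- genomeFeatures(g)[f]
  }
  n <- genomeLength(g)
  s <- IRanges::start(f); e <- IRanges::end(f)
  if (s < 1L || e > s + n - 1L)
    .stopf("feature interval [%d,%d] outside circular bounds of %s (len %d)",
           s, e, genomeId(g), n)
  if (e > n && !isCircular(g))
    .stopf("origin-spanning feature on a linear genome")
  sq <- circSubstr(genomeSeq(g), s, e)
  if (as.character(GenomicRanges::strand(f)) == "-") sq <- revcompChr(sq)
  sq
}

#' Rotate a circular genome to a new origin
#'
#' @param g an [AnnotatedGenome-class] (circular).
#' @param newOrigin 1-based position that becomes position 1.
#' @return the rotated genome with features remapped.
#' @export
rotateGenome <- function(g, newOrigin) {
  n <- genomeLength(g)
  newOrigin <- modpos(newOrigin, n)
  if (newOrigin == 1L) return(g)
  sq <- paste0(substr(genomeSeq(g), newOrigin, n),
               substr(genomeSeq(g), 1L, newOrigin - 1L))
  f <- .featureDf(g)
  if (nrow(f)) {
    w <- f$end - f$start
    f$start <- modpos(f$start - newOrigin + 1L, n)
    f$end <- f$start + w
  }
  annotatedGenome(genomeId(g), sq, isCircular(g), f)
}

#' Reverse-complement a genome, remapping features
#'
#' @param g an [AnnotatedGenome-class].
#' @return the reverse-complemented genome.
#' @export
revcompGenome <- function(g) {
  n <- genomeLength(g)
  sq <- revcompChr(genomeSeq(g))
  f <- .featureDf(g)
  if (nrow(f)) {
    w <- f$end - f$start
    newStart <- modpos(n - modpos(f$end, n) + 1L, n)
    f$start <- newStart
    f$end <- newStart + w
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  annotatedGenome(genomeId(g), sq, isCircular(g), f)
}

#' Normalise the orientation and rotation of a genome against a reference
#'
#' Chooses the orientation (forward or reverse complement) of `g` that
#' shares more unique `k`-mers with `ref`, then rotates `g` so that its
#' origin matches the reference origin (the modal circular offset of the
#' shared-k-mer chain). Positions containing `N` never anchor.
#'
#' @param g,ref circular [AnnotatedGenome-class] objects.
#' @param k anchor k-mer size (default 31).
#' @return `g`, possibly reverse-complemented and rotated.
#' @export
normalizeOrientation <- function(g, ref, k = 31L) {
  if (!isCircular(g) || !isCircular(ref))
    .stopf("normalizeOrientation requires circular genomes")
  score <- function(gg) {
    kg <- circKmers(genomeSeq(gg), k)
    kr <- circKmers(genomeSeq(ref), k)
    kg[grepl("N", kg, fixed = TRUE)] <- NA
    kr[grepl("N", kr, fixed = TRUE)] <- NA
    ug <- !duplicated(kg) & !duplicated(kg, fromLast = TRUE) & !is.na(kg)
    ur <- !duplicated(kr) & !duplicated(kr, fromLast = TRUE) & !is.na(kr)
    idx <- match(kg, ifelse(ur, kr, NA))
    hit <- which(ug & !is.na(idx))
    if (!length(hit)) return(list(n = 0L))
    off <- (hit - idx[hit]) %% genomeLength(gg)
    tab <- sort(table(off), decreasing = TRUE)
    ## the rotation must align the *origins*: indels shift the offsets of
    ## all downstream anchors, so use the offset of the first anchor (the
    ## unique shared k-mer with the smallest reference position)
    offO <- off[which.min(idx[hit])]
    list(n = as.integer(tab[1L]), offset = as.integer(offO),
         total = length(hit))
  }
  fw <- score(g)
  rc <- score(revcompGenome(g))
  if (fw$n == 0L && rc$n == 0L)
    .stopf("unrelated genomes: no shared %d-mers between %s and %s",
           k, genomeId(g), genomeId(ref))
  gg <- if (rc$n > fw$n) revcompGenome(g) else g
  best <- if (rc$n > fw$n) rc else fw
  rotateGenome(gg, modpos(best$offset + 1L, genomeLength(gg)))
}
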