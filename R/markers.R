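## Species-authentication assays: primer scoring (Wallace-rule Tm),
## in-silico PCR on circular templates, polymorphic-locus selection, assay
## design (size-polymorphic pairs, three-primer IR-junction assays,
## allele-specific SNP primers) and the species x assay discrimination
## matrix.

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` degrees C; a closed-form rule adequate for the
#' 18-26-mers designed here.
#'
#' @param seq primer sequence(s), 5'->3'.
#' @return numeric Tm in degrees C.
#' @export
wallaceTm <- function(seq) {
  vapply(toupper(seq), function(s) {
    v <- .charvec(s)
    2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

.gcFraction <- function(s) {
  v <- .charvec(toupper(s))
  sum(v %in% c("G", "C")) / length(v)
}

.maxHomopolymer <- function(s) {
  max(rle(.charvec(s))$lengths)
}

## longest self-reverse-complementary stretch (hairpin stem length)
.maxSelfRevcomp <- function(s) {
  n <- nchar(s)
  hi <- min(n %/% 2L, 12L)
  if (hi < 3L) return(0L)
  for (k in hi:3L) {
    km <- linKmers(s, k)
    if (any(vapply(km, revcompChr, character(1)) %in% km)) return(k)
  }
  0L
}

## Score all primer candidates inside a window (given 5'->3' on the
## intended synthesis strand). Hard filters: GC in [minGc,maxGc], Tm in
## [minTm,maxTm], homopolymer <= 4, no N, hairpin stem < 6. Soft score:
## 3'-terminal G/C clamp and Tm centring.
.primerCandidates <- function(window, minLen = 18L, maxLen = 26L,
                              minGc = 0.4, maxGc = 0.6,
                              minTm = 50, maxTm = 62) {
  out <- list()
  nw <- nchar(window)
  for (L in minLen:maxLen) {
    if (nw < L) next
    for (off in 1L:(nw - L + 1L)) {
      p <- substr(window, off, off + L - 1L)
      if (grepl("N", p, fixed = TRUE)) next
      gc <- .gcFraction(p)
      if (gc < minGc || gc > maxGc) next
      tm <- wallaceTm(p)
      if (tm < minTm || tm > maxTm) next
      if (.maxHomopolymer(p) > 4L) next
      if (.maxSelfRevcomp(p) >= 6L) next
      clamp <- substr(p, L, L) %in% c("G", "C")
      score <- (if (clamp) 1 else 0) - abs(tm - 56) / 10
      out[[length(out) + 1L]] <- data.frame(seq = p, offset = off, tm = tm,
                                            gc = gc, score = score,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(-df$score, df$offset), , drop = FALSE]
}

## Best forward/reverse primer combination from two windows, preferring
## pair Tm difference <= maxTmDiff. Reverse primers are the reverse
## complement of the right window (they synthesise the minus strand).
.pickPrimerPair <- function(leftWindow, rightWindow, maxTmDiff = 4) {
  fw <- .primerCandidates(leftWindow)
  rv <- .primerCandidates(revcompChr(rightWindow))
  if (is.null(fw) || is.null(rv)) return(NULL)
  fw <- utils::head(fw, 10L); rv <- utils::head(rv, 10L)
  grid <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
  grid$dtm <- abs(fw$tm[grid$f] - rv$tm[grid$r])
  grid$score <- fw$score[grid$f] + rv$score[grid$r] -
    ifelse(grid$dtm > maxTmDiff, 100, 0)
  bestI <- which.max(grid$score)
  if (grid$dtm[bestI] > maxTmDiff) return(NULL)
  list(F = fw$seq[grid$f[bestI]], R = rv$seq[grid$r[bestI]])
}

## PCR-template view of a CistronUnit: linear, with IUPAC ambiguity codes
## (heterogeneous sites) masked to N so they never support primer binding
.asTemplate <- function(g) {
  if (!methods::is(g, "CistronUnit")) return(g)
  annotatedGenome(cistronId(g), gsub("[^ACGTN]", "N", cistronSeq(g)),
                  circular = FALSE)
}

#' Predict PCR products on a genome (in-silico PCR)
#'
#' Finds every binding site of every primer on both strands, allowing up to
#' `maxMismatch` substitutions with the 3'-terminal `threePrimeExact` bases
#' exact, then reports one amplicon per convergent site pair within
#' `maxProduct` (circular arithmetic on circular templates). All productive
#' primer pairings are enumerated, including a primer pairing with a second
#' binding site of itself or of another primer - the behaviour that lets a
#' control reverse primer duplicated into the IR pair with an LSC primer
#' only in an IR-expanded genome. Product size is inclusive of both primer
#' footprints.
#'
#' @param g an [AnnotatedGenome-class] (or [CistronUnit-class], treated as a
#'   linear template).
#' @param primers named character vector of primer sequences 5'->3'.
#' @param maxProduct maximum product size in bp (default 5000).
#' @param maxMismatch substitutions tolerated per site (default 0; the
#'   stringent setting that makes absent products reproducible).
#' @param threePrimeExact 3'-terminal bases that must match exactly
#'   (default 3).
#' @return data.frame with `fwdPrimer`, `revPrimer`, `start`, `end`
#'   (1-based template coordinates of the product, `end` unwrapped for
#'   origin-spanning products) and `size`. Zero rows when nothing
#'   amplifies.
#' @export
inSilicoPcr <- function(g, primers, maxProduct = 5000L, maxMismatch = 0L,
                        threePrimeExact = 3L) {
  g <- .asTemplate(g)
  if (length(primers) < 2L) .stopf("need at least two primers")
  if (is.null(names(primers)) || any(!nzchar(names(primers))))
    names(primers) <- paste0("P", seq_along(primers))
  primers <- toupper(primers)
  if (any(grepl("N", primers, fixed = TRUE)))
    .stopf("primer contains N: %s",
           paste(names(primers)[grepl("N", primers, fixed = TRUE)], collapse = ","))
  s <- genomeSeq(g)
  n <- nchar(s)
  circ <- isCircular(g)
  ss <- if (circ) paste0(s, substr(s, 1L, max(nchar(primers)) + 1L)) else s

  plus <- list(); minus <- list()
  for (nm in names(primers)) {
    p <- primers[[nm]]
    ph <- .primerSites(ss, n, p, maxMismatch, threePrimeExact, minus = FALSE)
    mh <- .primerSites(ss, n, revcompChr(p), maxMismatch, threePrimeExact,
                       minus = TRUE)
    if (length(ph)) plus[[nm]] <- ph
    if (length(mh)) minus[[nm]] <- mh
  }
  out <- list()
  for (fp in names(plus)) for (rp in names(minus)) {
    Lf <- nchar(primers[[fp]]); Lr <- nchar(primers[[rp]])
    for (p in plus[[fp]]) for (q in minus[[rp]]) {
      e <- q + Lr - 1L                      # product right edge
      size <- if (circ) ((e - p) %% n) + 1L else e - p + 1L
      if (is.na(size) || size > maxProduct) next
      if (size < Lf + Lr) next              # primers may not overlap
      out[[length(out) + 1L]] <- data.frame(
        fwdPrimer = fp, revPrimer = rp, start = p,
        end = p + size - 1L, size = size, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(fwdPrimer = character(0), revPrimer = character(0),
                      start = integer(0), end = integer(0), size = integer(0),
                      stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$size, df$start), , drop = FALSE]
  ## the same physical product found from a wrapped duplicate start
  df <- df[!duplicated(data.frame(modpos(df$start, n), df$size)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Binding-site starts (on the plus strand string) of `pat`; for minus
## sites `pat` is already the reverse complement of the primer and its
## 3'-exact bases are the *first* threePrimeExact of the occurrence.
.primerSites <- function(ss, n, pat, maxMismatch, threePrimeExact, minus) {
  if (maxMismatch == 0L) {
    hits <- .allOccurrences(ss, pat, n)
    return(hits)
  }
  mp <- Biostrings::matchPattern(pat, Biostrings::DNAString(ss),
                                 max.mismatch = maxMismatch)
  st <- IRanges::start(mp)
  st <- st[st <= n]
  L <- nchar(pat)
  keep <- vapply(st, function(p) {
    win <- substr(ss, p, p + L - 1L)
    if (minus) substr(win, 1L, threePrimeExact) ==
      substr(pat, 1L, threePrimeExact)
    else substr(win, L - threePrimeExact + 1L, L) ==
      substr(pat, L - threePrimeExact + 1L, L)
  }, logical(1))
  st[keep]
}

## expected-product map: species -> sorted unique sizes
.expectedMap <- function(assayPrimers, genomes, maxProduct = 5000L,
                         maxMismatch = 0L, threePrimeExact = 3L) {
  lapply(genomes, function(g) {
    amp <- inSilicoPcr(g, assayPrimers, maxProduct = maxProduct,
                       maxMismatch = maxMismatch,
                       threePrimeExact = threePrimeExact)
    sort(unique(amp$size))
  })
}

#' Select candidate marker loci from variation catalogs
#'
#' Keeps loci where species differ in segment length by at least `minDelta`
#' bp (or by presence/absence), with no intraspecies variant within
#' `flank` bp in any species and the `anchorLen`-bp primer-footprint flanks
#' exactly conserved across all species. Candidates come from the
#' tandem-repeat CNV catalog and (optionally) from interspecies indel
#' records.
#'
#' @param genomes named list (species -> [AnnotatedGenome-class]); the
#'   first species anchors coordinates and labels.
#' @param cnvCatalog data.frame from [buildCnvCatalog()] (may be `NULL`).
#' @param interVariants data.frame from [callVariants()] comparing the
#'   first species against another (indel records become candidates; may
#'   be `NULL`).
#' @param intraVariants named list (species -> data.frame from
#'   [callVariants()] between that species' two accessions), or `NULL`.
#' @param minDelta minimum inter-species size difference in bp (default 4;
#'   smaller differences do not separate on agarose gels).
#' @param flank intraspecies-variant exclusion window in bp (default 150).
#' @param anchorLen conserved-flank length used to locate loci (default 60).
#' @return data.frame with one row per retained locus: `id`, `type`
#'   (`cnv` or `indel`), `locus`, `unit` (CNV only), per-species
#'   `size_<sp>`, `start_<sp>`, `end_<sp>`, and `maxDelta`.
#' @export
selectMarkerLoci <- function(genomes, cnvCatalog = NULL, interVariants = NULL,
                             intraVariants = NULL, minDelta = 4L,
                             flank = 150L, anchorLen = 60L) {
  species <- names(genomes)
  ref <- genomes[[1L]]
  sref <- genomeSeq(ref)
  rows <- list()

  addCandidate <- function(type, startRef, endRef, unit = NA_character_) {
    ## locate by conserved flanks in every species
    lf <- .flankSeq(paste0(sref, sref), genomeLength(ref),
                    startRef - anchorLen, startRef - 1L)
    rf <- .flankSeq(paste0(sref, sref), genomeLength(ref),
                    endRef + 1L, endRef + anchorLen)
    if (is.null(lf) || is.null(rf)) return()
    pos <- lapply(species, function(sp) {
      g <- genomes[[sp]]
      ssp <- if (isCircular(g)) paste0(genomeSeq(g),
                                       substr(genomeSeq(g), 1L, 3000L))
             else genomeSeq(g)
      .locusByFlanks(ssp, genomeLength(g), lf, rf, anchorLen)
    })
    names(pos) <- species
    if (any(vapply(pos, is.null, logical(1)))) return()     # flank not conserved
    if (any(vapply(pos, function(x) x$ambiguous, logical(1)))) return()
    sizes <- vapply(pos, function(x) x$size, integer(1))
    delta <- max(sizes) - min(sizes)
    if (delta < minDelta && !any(sizes == 0L)) return()
    ## intraspecies-variant exclusion window
    if (!is.null(intraVariants)) {
      for (sp in species) {
        iv <- intraVariants[[sp]]
        if (is.null(iv) || !nrow(iv)) next
        lo <- pos[[sp]]$start - flank; hi <- pos[[sp]]$end + flank
        if (any(iv$posA >= lo & iv$posA <= hi)) return()
      }
    }
    row <- c(list(type = type,
                  locus = .locusLabel(ref, startRef, endRef), unit = unit,
                  maxDelta = delta),
             stats::setNames(as.list(sizes), paste0("size_", species)),
             stats::setNames(lapply(pos, function(x) x$start),
                             paste0("start_", species)),
             stats::setNames(lapply(pos, function(x) x$end),
                             paste0("end_", species)))
    rows[[length(rows) + 1L]] <<- row
  }

  if (!is.null(cnvCatalog) && nrow(cnvCatalog)) {
    stCol <- paste0("start_", species[1L])
    for (i in seq_len(nrow(cnvCatalog))) {
      r <- cnvCatalog[i, ]
      if (isTRUE(r$ambiguous)) next
      if (stCol %in% names(cnvCatalog)) {
        addCandidate("cnv", r[[stCol]], r[[paste0("end_", species[1L])]],
                     unit = r$unit)
      }
    }
  }
  if (!is.null(interVariants) && nrow(interVariants)) {
    ind <- interVariants[interVariants$kind == "indel" &
                         interVariants$length >= minDelta, , drop = FALSE]
    for (i in seq_len(nrow(ind))) {
      v <- ind[i, ]
      if (v$ref == "-") {            # insertion relative to the reference
        addCandidate("indel", v$posA + 1L, v$posA)
      } else {
        addCandidate("indel", v$posA, v$posA + nchar(v$ref) - 1L)
      }
    }
  }
  if (!length(rows)) {
    cols <- c("type", "locus", "unit", "maxDelta",
              paste0("size_", species), paste0("start_", species),
              paste0("end_", species))
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols)))
  }
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  df <- unique(df)
  ## the same physical locus can surface both as a CNV and as an indel;
  ## keep the first representation (CNV candidates are added first)
  s1 <- df[[paste0("start_", species[1L])]]
  e1 <- df[[paste0("end_", species[1L])]]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (i == 1L) next
    prior <- which(keep[seq_len(i - 1L)])
    if (any(s1[i] <= e1[prior] + 10L & e1[i] >= s1[prior] - 10L))
      keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df$id <- sprintf("%s%02d", toupper(substr(df$type, 1L, 3L)),
                   stats::ave(seq_len(nrow(df)), df$type, FUN = seq_along))
  rownames(df) <- NULL
  df[, c("id", setdiff(names(df), "id"))]
}

## locate the segment between an exact flank pair; NULL when either flank
## is absent; ambiguous when several placements exist
.locusByFlanks <- function(ss, n, lf, rf, anchorLen, maxSpan = 3000L) {
  lhits <- .allOccurrences(ss, lf, n)
  if (!length(lhits)) return(NULL)
  found <- NULL; ambiguous <- length(lhits) > 1L
  for (lh in lhits) {
    segStart <- lh + anchorLen
    win <- substr(ss, segStart, min(segStart + maxSpan, nchar(ss)))
    rrel <- .allOccurrences(win, rf, nchar(win))
    if (!length(rrel)) next
    if (length(rrel) > 1L) ambiguous <- TRUE
    if (!is.null(found)) ambiguous <- TRUE
    found <- c(segStart, segStart + rrel[1L] - 2L)
  }
  if (is.null(found)) return(NULL)
  list(start = found[1L], end = found[2L],
       size = max(found[2L] - found[1L] + 1L, 0L), ambiguous = ambiguous)
}

#' Design a species-authentication assay
#'
#' * `kind = "pair"`: two primers in the conserved flanks of a
#'   length-polymorphic locus (a row of [selectMarkerLoci()]); species are
#'   told apart by product size.
#' * `kind = "three_primer"`: a control primer pair inside the region
#'   captured by an IR expansion (amplifying in every species) plus an LSC
#'   primer immediately downstream of the expanded IRa/LSC junction; the
#'   control reverse primer's site, duplicated into IRa of the expanded
#'   genome, pairs with the LSC primer there and yields a junction product
#'   only in the expanded species. `locus` must be
#'   `list(expanded = <species>, partitions = <named list of
#'   QuadripartitePartition>)`.
#' * `kind = "allele_specific"`: a primer whose 3'-terminal base sits on a
#'   species-specific SNP (amplifying only in the target species under the
#'   exact-match PCR model) plus a shared reverse primer and a conserved
#'   control pair. `locus` must be `list(target = <species>,
#'   pos = <SNP position in the target template>, controlRegion =
#'   c(start, end))`.
#'
#' Every designed assay's expected product map is computed (and can be
#' recomputed) with [inSilicoPcr()] on all templates.
#'
#' @param locus locus descriptor, see above.
#' @param genomes named list of templates ([AnnotatedGenome-class] or
#'   [CistronUnit-class]), one per species.
#' @param kind assay kind.
#' @param id assay identifier.
#' @param maxProduct,maxMismatch,threePrimeExact PCR model settings, see
#'   [inSilicoPcr()].
#' @return a [MarkerAssay-class], or `NULL` when no acceptable primer set
#'   exists ("undesignable locus").
#' @export
designAssay <- function(locus, genomes, kind = c("pair", "three_primer",
                                                 "allele_specific"),
                        id = "assay", maxProduct = 5000L, maxMismatch = 0L,
                        threePrimeExact = 3L) {
  kind <- match.arg(kind)
  genomes <- lapply(genomes, .asTemplate)
  asy <- switch(kind,
    pair = .designPairAssay(locus, genomes, id),
    three_primer = .designThreePrimerAssay(locus, genomes, id),
    allele_specific = .designAlleleSpecificAssay(locus, genomes, id))
  if (is.null(asy)) return(NULL)
  asy@expected <- .expectedMap(asy@primers, genomes, maxProduct = maxProduct,
                               maxMismatch = maxMismatch,
                               threePrimeExact = threePrimeExact)
  methods::validObject(asy)
  asy
}

.designPairAssay <- function(locus, genomes, id) {
  sp1 <- names(genomes)[1L]
  s <- genomeSeq(genomes[[sp1]])
  n <- nchar(s)
  startCol <- paste0("start_", sp1); endCol <- paste0("end_", sp1)
  leftWin <- .flankSeq(paste0(s, s), n, locus[[startCol]] - 60L,
                       locus[[startCol]] - 1L)
  rightWin <- .flankSeq(paste0(s, s), n, locus[[endCol]] + 1L,
                        locus[[endCol]] + 60L)
  if (is.null(leftWin) || is.null(rightWin)) return(NULL)
  pp <- .pickPrimerPair(leftWin, rightWin)
  if (is.null(pp)) return(NULL)
  new("MarkerAssay", id = id, kind = "pair",
      primers = c(F = pp$F, R = pp$R),
      targetLocus = as.character(locus$locus), expected = list())
}

## Control pair inside the IR-captured segment; LSC primer (minus strand)
## just downstream of the expanded IRa/LSC junction.
.designThreePrimerAssay <- function(locus, genomes, id,
                                    controlWindow = 400L, lscWindow = 360L) {
  expanded <- locus$expanded
  parts <- locus$partitions
  others <- setdiff(names(genomes), expanded)
  ge <- genomes[[expanded]]
  pe <- parts[[expanded]]
  capture <- IRanges::width(pe@irb) -
    min(vapply(others, function(sp) IRanges::width(parts[[sp]]@irb), integer(1)))
  if (capture < 120L) return(NULL)            # nothing usefully captured
  se <- genomeSeq(ge); ne <- nchar(se)
  irbStart <- modpos(IRanges::start(pe@irb), ne)
  ctrlLen <- min(controlWindow, capture)
  ctrl <- circSubstr(se, irbStart, irbStart + ctrlLen - 1L)
  ## control windows must be single-locus-conserved in the other species
  for (sp in others) {
    so <- genomeSeq(genomes[[sp]])
    hits <- .allOccurrences(paste0(so, so), ctrl, nchar(so))
    if (length(hits) != 1L) return(NULL)
  }
  pp <- .pickPrimerPair(substr(ctrl, 1L, ctrlLen %/% 2L),
                        substr(ctrl, ctrlLen %/% 2L + 1L, ctrlLen))
  if (is.null(pp)) return(NULL)
  ## LSC primer: minus-strand primer within lscWindow bp after the IRa/LSC
  ## junction of the expanded genome, conserved (single copy) everywhere
  lscStart <- modpos(IRanges::start(pe@lsc), ne)
  lsc <- circSubstr(se, lscStart + 20L, lscStart + 20L + lscWindow - 1L)
  for (sp in others) {
    so <- genomeSeq(genomes[[sp]])
    if (length(.allOccurrences(paste0(so, so), lsc, nchar(so))) != 1L)
      return(NULL)
  }
  lp <- .primerCandidates(revcompChr(lsc))
  if (is.null(lp)) return(NULL)
  new("MarkerAssay", id = id, kind = "three_primer",
      primers = c(LSC_P = lp$seq[1L], Control_F = pp$F, Control_R = pp$R),
      targetLocus = "IR/LSC junction", expected = list())
}

## Allele-specific forward primer with its 3' base on the target-specific
## SNP, plus a conserved control pair downstream of the SNP. The control
## reverse primer does double duty: Specific_F + Control_R is the
## target-only product, Control_F + Control_R amplifies in every species.
.designAlleleSpecificAssay <- function(locus, genomes, id) {
  target <- locus$target
  pos <- locus$pos
  st <- genomeSeq(genomes[[target]])
  others <- setdiff(names(genomes), target)
  occurs <- function(sp, pat) {
    g <- genomes[[sp]]
    so <- genomeSeq(g)
    ss <- if (isCircular(g)) paste0(so, so) else so
    length(.allOccurrences(ss, pat, nchar(so)))
  }
  spec <- NULL
  for (L in 26L:18L) {
    if (pos - L + 1L < 1L) next
    cand <- substr(st, pos - L + 1L, pos)
    if (grepl("N", cand, fixed = TRUE)) next
    if (.maxHomopolymer(cand) > 4L) next
    tm <- wallaceTm(cand)
    if (tm < 50 || tm > 62) next
    ## exact-match PCR model: the SNP-terminal primer must have a site in
    ## the target template and none elsewhere
    if (occurs(target, cand) >= 1L &&
        !any(vapply(others, occurs, integer(1), pat = cand) > 0L)) {
      spec <- cand
      break
    }
  }
  if (is.null(spec)) return(NULL)
  cr <- locus$controlRegion
  if (is.null(cr) || cr[1L] <= pos)
    .stopf("allele_specific locus needs a controlRegion downstream of the SNP")
  ctrlWin <- substr(st, cr[1L], cr[2L])
  if (!all(vapply(c(target, others), occurs, integer(1), pat = ctrlWin) == 1L))
    return(NULL)                               # control region not conserved
  pp <- .pickPrimerPair(substr(ctrlWin, 1L, nchar(ctrlWin) %/% 2L),
                        substr(ctrlWin, nchar(ctrlWin) %/% 2L + 1L,
                               nchar(ctrlWin)))
  if (is.null(pp)) return(NULL)
  new("MarkerAssay", id = id, kind = "allele_specific",
      primers = c(Specific_F = spec, Control_F = pp$F, Control_R = pp$R),
      targetLocus = sprintf("%s-specific SNP at %d", target, pos),
      expected = list())
}

#' Species x assay discrimination matrix
#'
#' Recomputes every assay's banding pattern on every template with
#' [inSilicoPcr()] and judges resolvability: the panel resolves the species
#' iff every species pair differs in at least one assay by presence/absence
#' or by at least `minDelta` bp in some product. Size differences below
#' `minDelta` are reported but flagged gel-indistinguishable.
#'
#' @param assays list of [MarkerAssay-class] objects.
#' @param genomes named list of templates (one per species).
#' @param minDelta minimum gel-resolvable size difference (default 4 bp).
#' @param maxProduct,maxMismatch,threePrimeExact PCR model settings.
#' @return list with `matrix` (character matrix species x assay, products
#'   as `+`-joined sizes or `"na"`), `resolved` (logical), and
#'   `unresolvedPairs` (character vector of species pairs not separated).
#' @export
discriminationMatrix <- function(assays, genomes, minDelta = 4L,
                                 maxProduct = 5000L, maxMismatch = 0L,
                                 threePrimeExact = 3L) {
  stopifnot(length(assays) >= 1L)
  genomes <- lapply(genomes, .asTemplate)
  species <- names(genomes)
  ids <- vapply(assays, function(a) a@id, character(1))
  maps <- lapply(assays, function(a)
    .expectedMap(a@primers, genomes, maxProduct = maxProduct,
                 maxMismatch = maxMismatch, threePrimeExact = threePrimeExact))
  mat <- matrix("na", nrow = length(species), ncol = length(assays),
                dimnames = list(species, ids))
  for (j in seq_along(assays)) for (sp in species) {
    v <- maps[[j]][[sp]]
    if (length(v)) mat[sp, j] <- paste(v, collapse = "+")
  }
  pairsep <- function(s1, s2) {
    for (j in seq_along(assays)) {
      v1 <- maps[[j]][[s1]]; v2 <- maps[[j]][[s2]]
      if (length(v1) != length(v2)) return(TRUE)       # presence/absence
      if (!length(v1)) next
      if (any(abs(sort(v1) - sort(v2)) >= minDelta)) return(TRUE)
    }
    FALSE
  }
  unresolved <- character(0)
  if (length(species) > 1L) {
    cmb <- utils::combn(species, 2L)
    for (cix in seq_len(ncol(cmb))) {
      if (!pairsep(cmb[1L, cix], cmb[2L, cix]))
        unresolved <- c(unresolved, paste(cmb[, cix], collapse = "/"))
    }
  }
  list(matrix = mat, resolved = length(unresolved) == 0L,
       unresolvedPairs = unresolved)
}
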