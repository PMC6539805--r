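## End-to-end orchestration: structure -> intraspecies variants ->
## interspecies variants/inversions -> tandem-repeat CNVs -> Ka/Ks ->
## marker design, with per-stage TSV outputs, a JSON summary and a
## Markdown report.

#' Write variant records as a VCF-like TSV
#'
#' Columns: `CHROM`, `POS` (1-based), `REF`, `ALT`, `TYPE`, `CLASS`.
#'
#' @param variants data.frame from [callVariants()].
#' @param chrom reference name for the CHROM column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantsTsv <- function(variants, chrom, path) {
  cls <- if (is.null(variants$class)) rep(".", nrow(variants))
         else variants$class
  df <- data.frame(CHROM = chrom, POS = variants$posA, REF = variants$ref,
                   ALT = variants$alt, TYPE = variants$kind,
                   CLASS = cls, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SNPs and indels as VCF 4.2
#'
#' Indels are emitted with the conventional anchor base (the base before
#' the event), so `REF`/`ALT` are never empty.
#'
#' @param variants data.frame from [callVariants()] (positions refer to
#'   `genome`).
#' @param genome the [AnnotatedGenome-class] the positions refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantsVcf <- function(variants, genome, path) {
  s <- genomeSeq(genome)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genomeId(genome),
                       genomeLength(genome)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (is.null(variants$class)) variants$class <- "."
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "SNP") {
      pos <- v$posA; ref <- v$ref; alt <- v$alt
    } else if (v$ref == "-") {              # insertion after posA
      pos <- max(v$posA, 1L)
      anchor <- substr(s, pos, pos)
      ref <- anchor; alt <- paste0(anchor, v$alt)
    } else {                                # deletion starting at posA
      pos <- max(v$posA - 1L, 1L)
      anchor <- substr(s, pos, pos)
      ref <- paste0(anchor, v$ref); alt <- anchor
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s;CLASS=%s",
                       genomeId(genome), pos, ref, alt, v$kind, v$class), con)
  }
  invisible(path)
}

#' Write inversion records as BEDPE
#'
#' @param inversions data.frame from [detectInversions()].
#' @param chromA,chromB names of the two genomes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInversionsBedpe <- function(inversions, chromA, chromB, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(inversions))) {
    v <- inversions[i, ]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tinversion_%d\t%d\t+\t-",
                       chromA, v$startA - 1L, v$endA, chromB, v$startB - 1L,
                       v$endB, i, round(100 * v$identity)), con)
  }
  invisible(path)
}

#' Run the full comparative pipeline
#'
#' Stage order: orientation normalisation -> quadripartite structure ->
#' intraspecies variants (accession pairs) -> interspecies variants and
#' inversions -> tandem-repeat CNV catalog -> Ka/Ks selection screen ->
#' marker-locus selection and assay design (-> 45S region tally when
#' cistron units are supplied). Each stage writes a TSV under `outDir`,
#' plus `summary.json` and `report.md`. With a single species only the
#' structure stage runs; comparison stages are skipped with a notice.
#'
#' @param genomes named list: species -> list of 1-2
#'   [AnnotatedGenome-class] accessions (first accession is the species
#'   reference).
#' @param cistrons optional named list: species -> [CistronUnit-class]
#'   (the first must carry region annotation).
#' @param outDir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed RNG seed recorded in the summary (the analysis itself is
#'   deterministic).
#' @param minIrLength,k,minUnit,maxUnit,kaHi,ksHi,minDelta,maxProduct
#'   stage thresholds, passed through to the stage functions.
#' @return list with per-stage results: `structure`, `intraspecies`,
#'   `interspecies`, `inversions`, `cnv`, `kaks`, `selection`, `markers`,
#'   `cistron`, and `summary`.
#' @export
runPipeline <- function(genomes, cistrons = NULL, outDir = NULL, seed = 1L,
                        minIrLength = 1000L, k = 31L, minUnit = 10L,
                        maxUnit = 39L, kaHi = 0.01, ksHi = 0.02,
                        minDelta = 4L, maxProduct = 5000L) {
  if (!length(genomes)) .stopf("no genomes supplied")
  species <- names(genomes)
  if (is.null(species) || any(!nzchar(species)))
    .stopf("genomes must be a named list (species names)")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  put <- function(df, name) {
    if (!is.null(outDir) && !is.null(df))
      utils::write.table(df, file.path(outDir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  notices <- character(0)
  refs <- lapply(genomes, `[[`, 1L)

  ## --- orientation normalisation against the first species -------------
  anchorSp <- species[1L]
  for (sp in setdiff(species, anchorSp))
    refs[[sp]] <- normalizeOrientation(refs[[sp]], refs[[anchorSp]], k = k)

  ## --- structure --------------------------------------------------------
  irs <- lapply(refs, detectInvertedRepeats, minIrLength = minIrLength)
  parts <- Map(function(g, ir) if (is.null(ir)) NULL
               else partitionQuadripartite(g, ir), refs, irs)
  withIr <- !vapply(parts, is.null, logical(1))
  structTab <- if (any(withIr))
    structureTable(refs[withIr], parts[withIr]) else NULL
  put(structTab, "structure.tsv")

  ## --- intraspecies variants --------------------------------------------
  intra <- list()
  for (sp in species) {
    if (length(genomes[[sp]]) < 2L) next
    a <- genomes[[sp]][[1L]]
    b <- normalizeOrientation(genomes[[sp]][[2L]], a, k = k)
    ch <- buildAnchorChain(a, b, k = k)
    intra[[sp]] <- callVariants(ch, a, b)
    put(intra[[sp]], sprintf("intraspecies_%s.tsv", sp))
  }

  single <- length(species) < 2L
  inter <- list(); invs <- list(); cnv <- NULL; kaksRes <- list()
  sel <- NULL; markers <- list(); disc <- NULL; cisTally <- NULL
  if (single) {
    notices <- c(notices, "single species: comparison stages skipped")
  } else {
    ## --- interspecies variants and inversions ---------------------------
    prs <- utils::combn(species, 2L)
    for (ci in seq_len(ncol(prs))) {
      x <- prs[1L, ci]; y <- prs[2L, ci]
      key <- paste(x, y, sep = "_")
      ch <- buildAnchorChain(refs[[x]], refs[[y]], k = k)
      inter[[key]] <- callVariants(ch, refs[[x]], refs[[y]])
      invs[[key]] <- detectInversions(ch, refs[[x]], refs[[y]])
      put(inter[[key]], sprintf("interspecies_%s.tsv", key))
      if (!is.null(outDir)) {
        writeVariantsVcf(inter[[key]], refs[[x]],
                         file.path(outDir, sprintf("interspecies_%s.vcf", key)))
        if (nrow(invs[[key]]))
          writeInversionsBedpe(invs[[key]], genomeId(refs[[x]]),
                               genomeId(refs[[y]]),
                               file.path(outDir, sprintf("inversions_%s.bedpe",
                                                         key)))
      }
    }

    ## --- tandem repeats and CNVs ----------------------------------------
    trs <- lapply(refs, findTandemRepeats, minUnit = minUnit,
                  maxUnit = maxUnit)
    cnv <- buildCnvCatalog(trs, refs)
    put(cnv, "cnv_catalog.tsv")

    ## --- Ka/Ks ----------------------------------------------------------
    for (ci in seq_len(ncol(prs))) {
      key <- paste(prs[1L, ci], prs[2L, ci], sep = "_")
      kk <- tryCatch(kaksScreen(refs[[prs[1L, ci]]], refs[[prs[2L, ci]]],
                                kaHi = kaHi, ksHi = ksHi),
                     error = function(e) NULL)
      if (!is.null(kk)) kaksRes[[key]] <- kk
      put(kk, sprintf("kaks_%s.tsv", key))
    }
    if (length(kaksRes)) sel <- selectionSummary(kaksRes, kaHi = kaHi,
                                                 ksHi = ksHi)
    if (!is.null(sel)) put(sel$table, "selection_summary.tsv")

    ## --- markers --------------------------------------------------------
    firstPair <- paste(species[1L], species[2L], sep = "_")
    loci <- selectMarkerLoci(refs, cnvCatalog = cnv,
                             interVariants = inter[[firstPair]],
                             intraVariants = intra, minDelta = minDelta)
    put(loci, "marker_loci.tsv")
    nPair <- 0L
    for (i in seq_len(nrow(loci))) {
      asy <- designAssay(loci[i, ], refs, kind = "pair",
                         id = loci$id[i], maxProduct = maxProduct)
      if (!is.null(asy)) {
        markers[[asy@id]] <- asy
        nPair <- nPair + 1L
      }
      if (nPair >= 6L) break
    }
    irl <- vapply(irs, function(x) if (is.null(x)) NA_integer_ else
      irLength(x), integer(1))
    if (all(!is.na(irl)) && diff(range(irl)) >= 500L) {
      expanded <- species[which.max(irl)]
      asy <- designAssay(list(expanded = expanded, partitions = parts),
                         refs, kind = "three_primer", id = "IR01",
                         maxProduct = maxProduct)
      if (!is.null(asy)) markers[["IR01"]] <- asy
    }

    ## --- 45S cistrons ---------------------------------------------------
    if (!is.null(cistrons) && length(cistrons) >= 2L) {
      cisTally <- tallyRegionVariants(cistrons)
      if (!is.null(outDir))
        put(data.frame(region = names(cisTally$counts),
                       snps = unname(cisTally$counts)), "cistron_tally.tsv")
      asy <- .designCistronAssay(cistrons)
      if (!is.null(asy)) markers[["nrDNA01"]] <- asy
    }

    if (length(markers)) {
      put(.assayTable(markers), "marker_assays.tsv")
      disc <- discriminationMatrix(markers, refs, minDelta = minDelta,
                                   maxProduct = maxProduct)
      if (!is.null(outDir))
        utils::write.table(cbind(species = rownames(disc$matrix),
                                 as.data.frame(disc$matrix)),
                           file.path(outDir, "discrimination_matrix.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary <- list(
    seed = seed,
    thresholds = list(minIrLength = minIrLength, k = k, minUnit = minUnit,
                      maxUnit = maxUnit, kaHi = kaHi, ksHi = ksHi,
                      minDelta = minDelta, maxProduct = maxProduct),
    species = species,
    genomeLengths = vapply(refs, genomeLength, integer(1)),
    irLengths = vapply(irs, function(x)
      if (is.null(x)) NA_integer_ else irLength(x), integer(1)),
    intraspeciesVariants = vapply(intra, nrow, integer(1)),
    interspeciesVariants = vapply(inter, nrow, integer(1)),
    inversions = vapply(invs, nrow, integer(1)),
    cnvRecords = if (is.null(cnv)) 0L else nrow(cnv),
    markerAssays = length(markers),
    resolved = if (is.null(disc)) NA else disc$resolved,
    cistronSnps = if (is.null(cisTally)) NA else cisTally$total,
    notices = notices)
  if (!is.null(outDir)) {
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .writeReportMd(file.path(outDir, "report.md"), structTab, intra, inter,
                   invs, cnv, sel, markers, disc, cisTally, summary)
  }
  invisible(list(structure = structTab, partitions = parts, irs = irs,
                 intraspecies = intra, interspecies = inter,
                 inversions = invs, cnv = cnv, kaks = kaksRes,
                 selection = sel, markers = markers,
                 discrimination = disc, cistron = cisTally,
                 summary = summary))
}

## one row per primer, with the assay's per-species product sizes
.assayTable <- function(markers) {
  rows <- list()
  for (m in markers) {
    sizes <- vapply(m@expected, function(v)
      if (length(v)) paste(sort(v), collapse = "+") else "na", character(1))
    sizeStr <- paste(sizes, collapse = "/")
    for (pn in names(m@primers)) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = m@id, kind = m@kind, primer = pn,
        sequence_5to3 = unname(m@primers[[pn]]),
        product_sizes = sizeStr, location = m@targetLocus,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## allele-specific 45S assay: first unit with a private SNP vs the others
.designCistronAssay <- function(cistrons) {
  ids <- vapply(cistrons, cistronId, character(1))
  units <- cistrons
  names(units) <- names(cistrons)
  refSp <- names(units)[1L]
  ref <- units[[refSp]]
  if (!length(ref@regions)) return(NULL)
  mat <- .cistronBaseMatrix(units)
  nsp <- nrow(mat)
  for (target in names(units)) {
    ti <- match(cistronId(units[[target]]), rownames(mat))
    for (col in seq_len(ncol(mat))) {
      colv <- mat[, col]
      if (any(!colv %in% c("A", "C", "G", "T"))) next
      if (length(unique(colv[-ti])) != 1L || colv[ti] == colv[-ti][1L]) next
      ## private SNP of `target` at reference column `col`; map to target
      pos <- .mapRefColToUnit(ref, units[[target]], col)
      if (is.na(pos) || pos < 30L) next
      cr <- c(pos + 80L, pos + 260L)
      if (cr[2L] > nchar(cistronSeq(units[[target]]))) next
      asy <- designAssay(list(target = target, pos = pos,
                              controlRegion = cr),
                         units, kind = "allele_specific", id = "nrDNA01")
      if (!is.null(asy)) return(asy)
    }
  }
  NULL
}

.writeReportMd <- function(path, structTab, intra, inter, invs, cnv, sel,
                           markers, disc, cisTally, summary) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Comparative plastome report")
  w("")
  w("Species: %s", paste(summary$species, collapse = ", "))
  if (!is.null(structTab)) {
    w("\n## Quadripartite structure\n")
    w("%s", paste(utils::capture.output(print(structTab, row.names = FALSE)),
                  collapse = "\n"))
  }
  w("\n## Variants\n")
  for (sp in names(intra))
    w("- intraspecies %s: %d records (%d SNPs, %d indels)", sp,
      nrow(intra[[sp]]), sum(intra[[sp]]$kind == "SNP"),
      sum(intra[[sp]]$kind == "indel"))
  for (key in names(inter))
    w("- interspecies %s: %d records, %d inversion(s)", key,
      nrow(inter[[key]]), nrow(invs[[key]]))
  if (!is.null(cnv)) {
    w("\n## Tandem-repeat CNV catalog\n")
    w("%d CNV records", nrow(cnv))
  }
  if (!is.null(sel)) {
    w("\n## Selection screen\n")
    w("%s", paste(utils::capture.output(print(sel$table, row.names = FALSE)),
                  collapse = "\n"))
    w("\nMutually identical genes: %s",
      paste(sel$mutuallyIdentical, collapse = ", "))
  }
  if (!is.null(cisTally)) {
    w("\n## 45S region tally\n")
    w("%s", paste(sprintf("%s: %s", names(cisTally$counts),
                          cisTally$counts), collapse = ", "))
  }
  if (length(markers)) {
    w("\n## Marker assays\n")
    for (m in markers) {
      sizes <- vapply(m@expected, function(v)
        if (length(v)) paste(v, collapse = "+") else "na", character(1))
      w("- %s (%s) at %s: %s", m@id, m@kind, m@targetLocus,
        paste(sprintf("%s=%s", names(sizes), sizes), collapse = " / "))
    }
    if (!is.null(disc))
      w("\nPanel verdict: %s",
        if (disc$resolved) "all species resolved"
        else paste("unresolved pairs:", paste(disc$unresolvedPairs,
                                              collapse = ", ")))
  }
  invisible(path)
}
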