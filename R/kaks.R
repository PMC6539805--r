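## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, on codon
## alignments obtained by back-translating a global protein alignment.
## This pathway-counting implementation is the package's analysis core:
## per-codon synonymous site fractions (changes to stop codons count as
## nonsynonymous), substitution counts averaged over all equal-weight
## mutation pathways that avoid stop codons, and d = -3/4 ln(1 - 4p/3).
## Translation uses genetic code table 11 (bacterial/plastid).

.pkgCache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

.codonTable <- function() {
  if (!is.null(.pkgCache$codons)) return(.pkgCache$codons)
  gc11 <- Biostrings::getGeneticCode("11")
  codons <- names(gc11)
  aa <- unname(gc11)
  .pkgCache$codons <- list(codon = codons, aa = stats::setNames(aa, codons),
                           stops = codons[aa == "*"],
                           sense = codons[aa != "*"])
  .pkgCache$codons
}

## synonymous site count of one codon: sum over the three positions of the
## fraction of the three possible point changes that are synonymous
## (changes creating a stop codon are nonsynonymous); n = 3 - s
.synSites <- function() {
  ct <- .codonTable()
  if (!is.null(.pkgCache$synSites)) return(.pkgCache$synSites)
  s <- stats::setNames(numeric(length(ct$codon)), ct$codon)
  for (cd in ct$codon) {
    cv <- .charvec(cd)
    syn <- 0
    for (p in 1:3) for (b in setdiff(.BASES, cv[p])) {
      alt <- cv; alt[p] <- b
      altc <- paste(alt, collapse = "")
      if (ct$aa[[altc]] == ct$aa[[cd]]) syn <- syn + 1
    }
    s[cd] <- syn / 3
  }
  .pkgCache$synSites <- s
  s
}

## 64x64 matrices of synonymous (Sd) and nonsynonymous (Nd) substitution
## counts per codon pair, averaged over equal-weight mutation pathways that
## avoid stop codons (all pathways if none avoids one)
.pairCounts <- function() {
  if (!is.null(.pkgCache$pairSd)) return(list(Sd = .pkgCache$pairSd,
                                              Nd = .pkgCache$pairNd))
  ct <- .codonTable()
  K <- length(ct$codon)
  Sd <- matrix(0, K, K, dimnames = list(ct$codon, ct$codon))
  Nd <- Sd
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(K)) {
    ci <- .charvec(ct$codon[i])
    for (j in seq_len(K)) {
      if (i == j) next
      cj <- .charvec(ct$codon[j])
      diffPos <- which(ci != cj)
      d <- length(diffPos)
      if (d == 0L) next
      tot <- c(s = 0, n = 0); nPath <- 0L
      totAll <- c(s = 0, n = 0)
      for (pm in perms[[as.character(d)]]) {
        cur <- ci
        path <- c(s = 0, n = 0)
        valid <- TRUE
        for (step in seq_len(d)) {
          nxt <- cur
          nxt[diffPos[pm[step]]] <- cj[diffPos[pm[step]]]
          curC <- paste(cur, collapse = ""); nxtC <- paste(nxt, collapse = "")
          if (ct$aa[[nxtC]] == "*" && step < d) valid <- FALSE
          if (ct$aa[[curC]] == ct$aa[[nxtC]]) path["s"] <- path["s"] + 1
          else path["n"] <- path["n"] + 1
          cur <- nxt
        }
        totAll <- totAll + path
        if (valid) { tot <- tot + path; nPath <- nPath + 1L }
      }
      if (nPath == 0L) { tot <- totAll; nPath <- length(perms[[as.character(d)]]) }
      Sd[i, j] <- tot[["s"]] / nPath
      Nd[i, j] <- tot[["n"]] / nPath
    }
  }
  .pkgCache$pairSd <- Sd
  .pkgCache$pairNd <- Nd
  list(Sd = Sd, Nd = Nd)
}

#' Codon-align two coding sequences
#'
#' Translates both CDS (genetic code table 11; terminal stop codons are
#' stripped first), aligns the proteins globally (BLOSUM62, gap open -10,
#' gap extend -1) and back-translates to codons. Gap columns and codons
#' containing ambiguous bases are excluded from comparison, which also
#' trims unaligned terminal overhangs (relevant for genes whose IR copies
#' truncate, such as ycf1).
#'
#' @param cdsA,cdsB in-frame coding sequences (character), lengths multiples
#'   of 3.
#' @param gene gene symbol carried through to results.
#' @return list with `gene`, `codonsA`/`codonsB` (equal-length character
#'   vectors of compared codons), and `excludedCodons` (gap or ambiguous
#'   columns dropped).
#' @export
codonAlign <- function(cdsA, cdsB, gene = "") {
  ct <- .codonTable()
  split3 <- function(s, label) {
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L)
      .stopf("%s: CDS length %d is not a multiple of 3 (%s)", gene, nchar(s), label)
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(cod) && ct$aa[cod[length(cod)]] %in% "*")
      cod <- cod[-length(cod)]                   # strip terminal stop
    aa <- ifelse(cod %in% ct$codon, unname(ct$aa[cod]), "X")
    stopAt <- which(aa == "*")
    if (length(stopAt))
      .stopf("%s: internal stop codon at codon %d (%s)", gene, stopAt[1L], label)
    list(cod = cod, aa = aa)
  }
  a <- split3(cdsA, "first sequence")
  b <- split3(cdsB, "second sequence")
  if (!length(a$cod) || !length(b$cod))
    .stopf("%s: empty CDS after stop stripping", gene)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(a$aa, collapse = "")),
    Biostrings::AAString(paste(b$aa, collapse = "")),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "global")
  ap <- .charvec(as.character(Biostrings::alignedPattern(pa)))
  as_ <- .charvec(as.character(Biostrings::alignedSubject(pa)))
  ia <- 0L; ib <- 0L
  codA <- character(0); codB <- character(0); excluded <- 0L
  for (col in seq_along(ap)) {
    ga <- ap[col] == "-"; gb <- as_[col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) { excluded <- excluded + 1L; next }
    ca <- a$cod[ia]; cb <- b$cod[ib]
    if (!(ca %in% ct$codon) || !(cb %in% ct$codon)) {
      excluded <- excluded + 1L; next           # ambiguous codon
    }
    codA <- c(codA, ca); codB <- c(codB, cb)
  }
  list(gene = gene, codonsA = codA, codonsB = codB,
       excludedCodons = excluded)
}

#' Nei-Gojobori (1986) Ka/Ks for one codon alignment
#'
#' Synonymous/nonsynonymous site counts are averaged over the two
#' sequences; substitution counts are averaged over equal-weight mutation
#' pathways avoiding stop codons; proportions are Jukes-Cantor corrected
#' (`d = -3/4 ln(1 - 4p/3)`, undefined for `p >= 3/4`). The ratio is
#' undefined (NA) when `Ks == 0`.
#'
#' @param aln a codon alignment from [codonAlign()].
#' @param kaHi,ksHi thresholds flagging elevated Ka (default 0.01) and Ks
#'   (default 0.02) in the `class` field.
#' @return one-row data.frame: `gene`, `codons` (compared), `Nd`, `Sd`,
#'   `N`, `S`, `Ka`, `Ks`, `ratio`, `class` (one of `identical`,
#'   `neutral-ish`, `positively_selected`, `high_Ka`, `high_Ks`).
#' @export
kaksNG86 <- function(aln, kaHi = 0.01, ksHi = 0.02) {
  if (!length(aln$codonsA)) .stopf("%s: empty codon alignment", aln$gene)
  syn <- .synSites()
  pc <- .pairCounts()
  S <- sum((syn[aln$codonsA] + syn[aln$codonsB]) / 2)
  N <- 3 * length(aln$codonsA) - S
  idx <- cbind(match(aln$codonsA, colnames(pc$Sd)),
               match(aln$codonsB, colnames(pc$Sd)))
  Sd <- sum(pc$Sd[idx])
  Nd <- sum(pc$Nd[idx])
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  identical_ <- (Nd + Sd) == 0
  cls <- if (identical_) "identical"
    else if (!is.na(ratio) && ratio >= 1 && Ka > 0) "positively_selected"
    else if (!is.na(Ka) && Ka > kaHi) "high_Ka"
    else if (!is.na(Ks) && Ks > ksHi) "high_Ks"
    else "neutral-ish"
  data.frame(gene = aln$gene, codons = length(aln$codonsA),
             Nd = Nd, Sd = Sd, N = N, S = S, Ka = Ka, Ks = Ks,
             ratio = ratio, class = cls, stringsAsFactors = FALSE)
}

#' Ka/Ks screen across the shared protein-coding genes of two genomes
#'
#' Takes the CDS gene symbols shared by both annotations (one copy per
#' symbol, so IR-duplicated genes enter once), codon-aligns each orthologue
#' pair and computes NG86 Ka/Ks. Genes whose CDS fails (length not a
#' multiple of 3, internal stop) are skipped with a warning rather than
#' failing the screen.
#'
#' @param a,b annotated [AnnotatedGenome-class] objects.
#' @param genes optional gene-symbol subset.
#' @param kaHi,ksHi classification thresholds, see [kaksNG86()].
#' @return data.frame with one row per analysed gene (columns as
#'   [kaksNG86()]).
#' @export
kaksScreen <- function(a, b, genes = NULL, kaHi = 0.01, ksHi = 0.02) {
  cdsNames <- function(g) {
    f <- genomeFeatures(g)
    unique(S4Vectors::mcols(f)$gene[S4Vectors::mcols(f)$kind == "CDS"])
  }
  shared <- intersect(cdsNames(a), cdsNames(b))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (!length(shared)) .stopf("no shared CDS between %s and %s",
                              genomeId(a), genomeId(b))
  out <- list()
  for (gene in shared) {
    res <- tryCatch({
      aln <- codonAlign(extractFeatureSequence(a, gene),
                        extractFeatureSequence(b, gene), gene = gene)
      kaksNG86(aln, kaHi = kaHi, ksHi = ksHi)
    }, error = function(e) {
      .warnf("skipping %s: %s", gene, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Summarise a selection screen across species pairs
#'
#' @param results named list: species-pair label -> data.frame from
#'   [kaksScreen()].
#' @param kaHi,ksHi thresholds for the high-Ka / high-Ks gene lists.
#' @return list with `table` (per-pair medians and category counts),
#'   `genes` (per-pair character vectors: `identical`,
#'   `positively_selected`, `high_Ka`, `high_Ks`) and `mutuallyIdentical`
#'   (genes identical in every pair).
#' @export
selectionSummary <- function(results, kaHi = 0.01, ksHi = 0.02) {
  stopifnot(length(results) >= 1L)
  rows <- list(); genes <- list()
  for (pair in names(results)) {
    df <- results[[pair]]
    ident <- df$gene[df$Nd + df$Sd == 0]
    pos <- df$gene[!is.na(df$ratio) & df$ratio >= 1 & df$Ka > 0]
    hika <- df$gene[!is.na(df$Ka) & df$Ka > kaHi]
    hiks <- df$gene[!is.na(df$Ks) & df$Ks > ksHi]
    genes[[pair]] <- list(identical = ident, positively_selected = pos,
                          high_Ka = hika, high_Ks = hiks)
    rows[[pair]] <- data.frame(
      pair = pair, genes = nrow(df),
      medianKa = stats::median(df$Ka, na.rm = TRUE),
      medianKs = stats::median(df$Ks, na.rm = TRUE),
      identical = length(ident), positively_selected = length(pos),
      high_Ka = length(hika), high_Ks = length(hiks),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  mut <- Reduce(intersect, lapply(genes, `[[`, "identical"))
  list(table = tab, genes = genes, mutuallyIdentical = sort(mut))
}
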