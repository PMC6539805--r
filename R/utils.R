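# Low-level sequence and circular-coordinate helpers shared by all stages.
# Sequences are handled as uppercase character scalars over {A,C,G,T,N}
# (IUPAC ambiguity codes tolerated where noted); Biostrings does the heavy
# lifting for alignment, matching and translation.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
           B = "V", V = "B", D = "H", H = "D")

## reverse complement of a character scalar
revcompChr <- function(s) {
  if (nchar(s) == 0L) return(s)
  paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

## complement without reversal
compChr <- function(s) {
  chartr("ACGTNRYSWKMBVDH", "TGCANYRSWMKVBHD", s)
}

.charvec <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

## 1-based circular position
modpos <- function(p, n) ((p - 1L) %% n) + 1L

## circular substring, 1-based inclusive; end may exceed n (wraps around)
circSubstr <- function(s, start, end) {
  n <- nchar(s)
  start <- modpos(start, n)
  end2 <- start + ((end - start) %% n)   # unwrapped end >= start
  if (end2 <= n) {
    substr(s, start, end2)
  } else {
    paste0(substr(s, start, n), substr(s, 1L, end2 - n))
  }
}

## all k-mers of a circular sequence, one per start position 1..n
circKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  ss <- paste0(s, substr(s, 1L, k - 1L))
  substring(ss, seq_len(n), seq_len(n) + k - 1L)
}

## k-mers of a linear sequence, start positions 1..(n-k+1)
linKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## reverse complements of all circular k-mers (vectorised)
circKmersRC <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  rs <- revcompChr(paste0(s, substr(s, 1L, k - 1L)))
  m <- n + k - 1L
  # k-mer starting at i spans doubled[i .. i+k-1]; its revcomp spans
  # rs[m - (i+k-1) + 1 .. m - i + 1]
  substring(rs, m - seq_len(n) - k + 2L, m - seq_len(n) + 1L)
}

## circular interval length, 1-based inclusive ends (end may be unwrapped)
circWidth <- function(start, end, n) ((end - start) %% n) + 1L

## does circular interval [s1,e1] contain [s2,e2]? (1-based, ends unwrapped ok)
circContains <- function(s1, e1, s2, e2, n) {
  w1 <- (e1 - s1) %% n
  off <- (s2 - s1) %% n
  w2 <- (e2 - s2) %% n
  off + w2 <= w1
}

## random DNA of length n
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## global nucleotide alignment used for inter-anchor gaps and cistron
## projection: match +1 / mismatch -1 / gap open 4 / gap extend 1
.nucAlign <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 1,
                                type = "global")
}
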