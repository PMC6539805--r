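# Independent oracles and shared fixtures. The oracles deliberately use
# different mechanics from the package internals (Biostrings reverse
# complement, their own run detection, recursive pathway enumeration) so
# they can arbitrate.

.fixtureCache <- new.env(parent = emptyenv())

sharedTrio <- function(seed = 11L) {
  key <- paste0("trio", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateGenomeTrio(trioSpec(seed = seed))
  .fixtureCache[[key]]
}

shared45 <- function(seed = 12L) {
  key <- paste0("c45-", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generate45STrio(seed = seed)
  .fixtureCache[[key]]
}

rcOracle <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## Exhaustive inverted-segment search on a circular sequence: scans every
## anti-diagonal (all pairs of positions p, q with p + q constant mod n,
## i.e. all candidate segment pairs), finds maximal complementary runs and
## returns the longest disjoint arm pair, verified by direct reverse-
## complement string comparison. O(n^2).
bruteForceIr <- function(s, minLen) {
  n <- nchar(s)
  sv <- strsplit(s, "")[[1]]
  cv <- strsplit(rcOracle(s), "")[[1]][n:1]      # complement, via Biostrings
  best <- NULL
  for (d in 0:(n - 1)) {
    q <- ((d - seq_len(n)) %% n) + 1L
    m <- sv == cv[q]
    if (!any(m)) next
    if (all(m)) {
      runs <- data.frame(start = 1L, len = n)
    } else {
      ## rotate so the vector starts on a FALSE, then plain rle
      off <- which(!m)[1L]
      mr <- m[c(off:n, seq_len(off - 1L))]
      r <- rle(mr)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- data.frame(
        start = ((starts[r$values] + off - 2L) %% n) + 1L,
        len = r$lengths[r$values])
    }
    for (r in seq_len(nrow(runs))) {
      st <- runs$start[r]; L <- min(runs$len[r], n)
      en <- st + L - 1L
      q1 <- ((d - (((en - 1L) %% n) + 1L)) %% n) + 1L
      selfMirror <- ((q1 - st) %% n) < L
      if (selfMirror) {
        arm <- L %/% 2L
        if (arm < minLen) next
        cand <- c(((st - 1L) %% n) + 1L, ((en - arm) %% n) + 1L, arm)
      } else {
        if (L < minLen) next
        a1 <- ((st - 1L) %% n) + 1L
        if (a1 > q1) next
        cand <- c(a1, q1, L)
      }
      if (is.null(best) || cand[3L] > best[3L] ||
          (cand[3L] == best[3L] && min(cand[1:2]) < min(best[1:2])))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  ## verify by direct string comparison
  seg <- function(a, L) {
    idx <- (((a - 1L) + 0:(L - 1L)) %% n) + 1L
    paste(sv[idx], collapse = "")
  }
  stopifnot(identical(seg(best[2L], best[3L]), rcOracle(seg(best[1L], best[3L]))))
  list(arm1 = best[1L], arm2 = best[2L], len = best[3L])
}

## Independent NG86 per-codon-pair oracle: recursive enumeration of all
## mutation orderings, discarding those that pass through a stop codon
## (falling back to all orderings if none avoids one); synonymous site
## fraction per codon from first principles.
ng86Oracle <- local({
  gc11 <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  aaOf <- function(cod) gc11[[cod]]
  synSitesOracle <- function(cod) {
    v <- strsplit(cod, "")[[1]]
    syn <- 0
    for (i in 1:3) for (b in setdiff(bases, v[i])) {
      w <- v; w[i] <- b
      if (aaOf(paste(w, collapse = "")) == aaOf(cod)) syn <- syn + 1
    }
    syn / 3
  }
  pathCounts <- function(from, to) {
    vf <- strsplit(from, "")[[1]]; vt <- strsplit(to, "")[[1]]
    dpos <- which(vf != vt)
    paths <- list()
    recurse <- function(cur, remaining, s, nn, hitStop) {
      if (!length(remaining)) {
        paths[[length(paths) + 1L]] <<- list(s = s, n = nn, stop = hitStop)
        return(invisible())
      }
      for (i in seq_along(remaining)) {
        p <- remaining[i]
        nxt <- cur; nxt[p] <- vt[p]
        codN <- paste(nxt, collapse = "")
        isSyn <- aaOf(paste(cur, collapse = "")) == aaOf(codN)
        recurse(nxt, remaining[-i], s + isSyn, nn + !isSyn,
                hitStop || (aaOf(codN) == "*" && length(remaining) > 1L))
      }
    }
    recurse(vf, dpos, 0, 0, FALSE)
    ok <- Filter(function(p) !p$stop, paths)
    if (!length(ok)) ok <- paths
    c(Sd = mean(vapply(ok, `[[`, numeric(1), "s")),
      Nd = mean(vapply(ok, `[[`, numeric(1), "n")))
  }
  list(synSites = synSitesOracle, pathCounts = pathCounts,
       sense = names(gc11)[gc11 != "*"])
})
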