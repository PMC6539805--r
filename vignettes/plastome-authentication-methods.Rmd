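---
title: "Methods: comparative plastome analysis and species-authentication markers"
author: "PlastomeAuth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis and species-authentication markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PlastomeAuth)
```

This vignette is the package's own account of its models and numerical
choices: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the known limitations lie.

## Data model

An `AnnotatedGenome` is an uppercase DNA sequence over `{A,C,G,T,N}` with
a circularity flag and strand-aware gene features (`CDS`, `tRNA`, `rRNA`,
`misc`). Coordinates are 1-based inclusive throughout (the
IRanges/GenomicRanges convention); a feature crossing the circular origin
is encoded with `end > length`. GenBank flat files are parsed directly
(LOCUS topology, `complement()`/`join()` locations, `/gene=` and
`/codon_start=` qualifiers); a two-part `join()` that is contiguous across
the origin becomes one origin-spanning feature, while any other join —
notably the trans-spliced *rps12* — is split into independent parts, a
deliberate simplification. A `CistronUnit` is a linear 45S rDNA repeat
with the five canonical regions `18S < ITS1 < 5.8S < ITS2 < 26S` stored as
contiguous intervals; IUPAC ambiguity codes are allowed there because a
heterogeneous site between two accessions of one species is genuinely
ambiguous in the assembled unit.

Before any cross-genome comparison, `normalizeOrientation()` puts a
genome into the reference's frame: the orientation (forward or reverse
complement) sharing more unique 31-mers wins, and the rotation is taken
from the offset of the *first* collinear anchor — the unique shared k-mer
with the smallest reference position. A genome-wide modal offset would be
wrong here: every indel shifts the offsets of all downstream anchors, so
the mode can rotate the genome by the net indel sum and cut one event in
half at the origin.

## Inverted repeats and the quadripartite partition

`detectInvertedRepeats()` seeds exact reverse-complement 25-mer matches
and extends each seed along its anti-diagonal (if positions $p$ and $q$
pair, then $p+q$ is constant), taking the maximal pair of disjoint
segments with `seq(IRa) == revcomp(seq(IRb))`. Defaults:

* `seedK = 25` — long enough that spurious seeds are rare even at 150 kb,
  short enough to seed every real arm.
* `minIrLength = 1000` bp — plastid IR arms in this clade run 18–36 kb; a
  1 kb floor ignores tRNA-scale hairpins while still reporting strongly
  contracted IRs. Genomes that genuinely lack an IR return `NULL` rather
  than an error.
* Extension is exact (`maxMismatches = 0`). Chloroplast IR arms are
  copy-corrected and near-identical in vivo, and exactness makes junction
  coordinates exactly reproducible; a mismatch-bridging mode exists for
  degraded assemblies but is off by default.

The two single-copy gaps become LSC (longer) and SSC (shorter); on a tie
the gap following IRa is declared the LSC, so the conventional
LSC–IRb–SSC–IRa order always holds. Junctions are reported as the first
base of the downstream region. `irGeneContentDiff()` calls a gene
IR-resident when its full span lies inside an arm; the set difference
between two genomes is the gene-level signature of a boundary expansion.

## Anchor chaining and variant calling

`buildAnchorChain()` matches 31-mers that are unique within each genome
(k = 31 makes a random collision essentially impossible at plastome
scale while tolerating ~3% divergence between anchors), collapses
adjacent matches into maximal exact segments, and selects the collinear
chain maximising anchored length with a weighted
longest-increasing-subsequence dynamic programme. Two numerical details
matter:

* Segments on different diagonals can *overlap* by up to k−1 bases when a
  k-mer window straddling a variant matches by chance; the chainer
  therefore permits overlap and trims the downstream segment, which keeps
  an exact match exact.
* Reverse-orientation segments are retained as candidate inversions only
  where they fall inside a forward-chain gap; a reverse segment may
  likewise extend a few bases past the gap edge by chance
  complement-pairing and is trimmed anti-diagonally (left in A is right
  in B).

`callVariants()` aligns each inter-anchor gap globally with match +1,
mismatch −1, gap open −4, gap extend −1 — a scoring that prefers one
contiguous gap run over scattered single-base gaps, so **one gap run is
one indel event**, matching how biologists count indel polymorphisms
between accessions. Indels are left-normalised (shifted left while the
flanking base equals the event's last base), which makes positions unique
and comparable. Gaps longer than 20 kb are refused as structural events.
A tandem-repeat copy-number difference surfaces here as a single indel;
the CNV catalog cross-references these loci rather than double-counting
them. Classification is genic/intergenic against the first genome's
features, intergenic loci labelled by their flanking gene pair
(`"psaC ~ ndhE"` style).

`detectInversions()` reports each gap whose reverse blocks form one
anti-collinear run, with alignment identity of segment A against
revcomp(segment B) ≥ 0.9; overlapping, mutually inconsistent blocks are
flagged `unresolved`, never merged. `applyVariants()` is the
reconstruction oracle: the call set is complete if and only if applying
it to A yields B byte-exactly — asserted over many seeded pairs in the
test suite.

For the 45S trio, `tallyRegionVariants()` uses reference-pivot
progressive pairwise alignment instead of a full multiple alignment:
three near-identical units gain nothing from an MSA and the pivot makes
the output deterministic. A SNP is a gap-free column with at least two
distinct bases; columns containing an IUPAC code are flagged and excluded
from the interspecies totals, since they encode within-species
heterogeneity, not a fixed interspecies difference.

## Tandem repeats and copy-number variation

`findTandemRepeats()` compares the sequence against itself shifted by
each candidate unit length `u` (10–39 bp, the range in which plastome
repeat CNVs are informative; shorter units are microsatellite territory
and out of scope), so a maximal run of agreement of length `L` means a
periodic region spanning `L + u` bases. Only exact full copies are
counted (`copies = floor(span/u)`, minimum 2 copies and 20 bp span) —
copy numbers are integers by construction, which keeps the catalog
deterministic; degenerate Tandem-Repeats-Finder-style scoring is a
non-goal. Units are reported primitive (a divisor scan rejects any unit
that is itself a repetition) at the leftmost phase, which collapses the
multiple representations of one array.

`buildCnvCatalog()` matches loci across species by exact identity of the
60-bp flanks — never by coordinate, which rearrangements would break. In
a species without a detected array the inter-flank segment is inspected
directly: one unit copy records `1`, absence records `"nf"`. Ambiguous
flank placements are flagged, not guessed, and loci with identical copy
vectors are dropped (they are not CNVs).

## The Ka/Ks screen

Each shared CDS symbol enters once (so IR-duplicated genes are not
counted twice), is translated with genetic code table 11
(bacterial/plastid), stripped of its terminal stop, globally aligned at
the protein level (BLOSUM62, gap open −10, extend −1) and back-translated.
Gap columns and ambiguous codons are excluded, which also trims unaligned
terminal overhangs such as the truncated IR copy of *ycf1*. An internal
stop rejects the gene with a named position; in `kaksScreen()` such genes
are skipped with a warning so one broken annotation cannot sink the
screen.

The estimator is Nei–Gojobori (1986): per-codon synonymous site fractions
(each position contributes the fraction of its three possible changes
that are synonymous; changes creating a stop count as nonsynonymous),
substitution counts averaged over all equal-weight mutation pathways that
avoid stop codons (falling back to all pathways in the rare case none
does), and the Jukes–Cantor correction $d = -\tfrac34\ln(1-\tfrac{4p}3)$,
undefined at $p \ge 3/4$. The ratio is undefined when Ks = 0. NG86 was
chosen over a maximum-likelihood codon model deliberately: it is fully
specified, dependency-free and deterministic, and at the near-zero
divergences relevant here (median Ks below 0.01) counting and ML
estimators agree closely, while a median Ka of exactly 0 is
method-invariant. The implementation is checked codon-by-codon against an
independent exhaustive pathway enumerator over all 61 × 61 sense-codon
pairs, and calibrated: under rate-equal simulation the mean Ka/Ks sits
within 0.1 of 1.

Thresholds: *identical* means zero nucleotide differences over the
compared codons; Ka > 0.01 and Ks > 0.02 mark the elevated tails (both
configurable — the 0.02 value follows the convention of flagging the
synonymous tail an order of magnitude above the typical congeneric
median, and corresponds to the threshold used in this assay class;
positive selection is Ka/Ks ≥ 1 with Ka > 0).

## Marker design and the in-silico PCR model

The PCR model is intentionally strict: exact binding
(`maxMismatch = 0`) with the 3′-terminal 3 bases always exact, every
binding site on both strands found, and every convergent site pair within
`maxProduct = 5000` bp (circular arithmetic) reported as a product, sizes
inclusive of both primer footprints. Strictness is what makes "no
amplification" a reproducible, meaningful prediction — the basis of
presence/absence markers and allele-specific primers. A mismatch-tolerant
mode exists for robustness exploration only.

Primer candidates are 18–26-mers with GC between 40% and 60%, Wallace
Tm ($2(A{+}T) + 4(G{+}C)$, adequate closed form at these lengths) between
50 and 62 °C, no homopolymer over 4, no self-reverse-complement stem of
6+, scored for a 3′ G/C clamp and Tm centring, with pair Tm difference
≤ 4 °C. Locus selection requires an inter-species length difference of at
least 4 bp — smaller differences do not separate on agarose gels and are
flagged gel-indistinguishable rather than trusted — plus exactly
conserved flanks and no intraspecies variant within ±150 bp, because a
marker that varies within a species mis-authenticates.

The three-primer junction assay exploits IR-expansion geometry: the
control pair sits inside the captured segment (present in every species,
single-copy in the unexpanded ones), so it amplifies everywhere; in the
expanded genome that segment also exists reverse-complemented at the far
IR arm next to the IRa/LSC junction, where the control *reverse* primer
gains a second, forward-oriented site within reach of a primer placed
just after the junction — an extra band only in the expanded species.
The allele-specific assay places the discriminating SNP at the primer's
3′ terminus and reuses the control reverse primer for the specific
product, mirroring how such nrDNA assays are built in practice.

## The synthetic trio: what it emulates, and what it does not

`trioSpec()` encodes the simulated study conditions: a 30-kb circular
ancestor with a quadripartite skeleton (4-kb arms, SSC ≈ 23% of the
genome — the proportions of a plastome scaled down by a factor of ~5 to
keep the full pipeline fast enough to run hundreds of times in tests),
40 genes with ≥ 50 bp intergenic spacers so locus labels are unambiguous,
fixed topology ((A,B),C). Per-branch substitution rates (A and B 0.001,
internal 0.0015, C 0.004) give ~0.2% divergence within the close pair and
~0.5–0.7% to the outgroup — the magnitude seen between congeneric
plastomes, where the interesting boundary effects (median Ka of 0,
identical genes) live. Indels initiate at 10⁻⁴ per intergenic site with
geometric(0.3) lengths capped at 50 bp — the simplest models that
exercise the detectors. Six tandem-repeat loci carry distinct per-species
copy vectors (one absent from C, so `"nf"` is exercised); lineage B gets
a 625-bp inversion spanning three tRNA genes and a 1.2-kb IR expansion
(the captured LSC tail holds three genes, and its reverse complement is
inserted at the IRa/LSC junction with duplicated annotations); accession
pairs differ by 3 SNPs + 6 indels (A), nothing (B), and 1 SNP + 5 indels
(C). The 45S generator uses the canonical region lengths (1800/250/160/
230/3380 bp) with ITS rates elevated tenfold and rRNA-gene rates chosen
so the expected total lands near the ~66 SNPs a three-species comparison
of this kind yields; one IUPAC heterogeneous site is planted in 26S.

Deliberate idealisations, which bound what a passing test shows about
real data:

* Mutations never hit the IR arms, the planted-event footprints and their
  flanks, the LSC head or the captured segment. Real IRs do mutate (in
  near-mirrored fashion), real flanks drift, and real primer windows are
  not guaranteed conserved — on real data the CNV catalog and marker
  stages degrade gracefully (flagged/absent loci) rather than exactly.
* Junction and inversion edge bases are fixed so the planted coordinates
  are the unique maximal description. In real genomes a junction or
  breakpoint whose edge base complement-pairs with its flank is genuinely
  ambiguous by ±1–2 bp; the generator removes the ambiguity so "exact"
  recovery is well-defined.
* No rate heterogeneity beyond the ITS multiplier, no realistic codon
  usage or GC skew, substitutions at most one per codon, and no
  sequencing error or assembly gaps.
* Both generators draw from R's global stream: calling them with the
  *same* seed yields correlated sequences, so distinct seeds should be
  used for the genome trio and the 45S trio (the acceptance script
  offsets the 45S seed by a large constant).

Validation problem sizes: the test suite runs the full pipeline on
30-kb trios, 30 planted-IR circles of 2 kb against an exhaustive
anti-diagonal oracle, 21 reconstruction pairs over seven seeds, the
complete 61 × 61 codon-pair check, and a 200-replicate Ka/Ks calibration
— sizes chosen so the whole suite completes in a few minutes on one CPU
while still covering every event class.

## Known limitations

* Inexact (degenerate) tandem repeats and units under 10 bp are out of
  scope; a locus whose copies differ by internal SNPs is reported at its
  exact sub-arrays only.
* The GenBank reader covers the flat-file subset plastome records use;
  rich location operators beyond `complement`/`join` are not parsed, and
  trans-spliced genes are treated as independent parts.
* NG86 without codon-frequency correction slightly underestimates rates
  at high divergence; beyond congeneric distances an ML model should be
  preferred.
* `discriminationMatrix()` judges resolvability from predicted sizes
  alone; it does not model amplification efficiency, multiplex
  interactions or heteroduplexes.
* Genomes sharing no 31-mers cannot be compared (`normalizeOrientation()`
  refuses); the pipeline targets congeneric material.
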