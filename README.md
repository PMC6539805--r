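# PlastomeAuth

Comparative analysis of annotated circular chloroplast (plastid) genomes
and 45S ribosomal DNA cistron units from closely related plant species,
aimed at one practical question: **which sequence differences cleanly
authenticate a species, and how do you turn them into PCR assays?**

The package grew out of the comparative-plastome workflow used for
medicinal-herb authentication, where two or three confusable species must
be told apart from dried material. It covers the full chain of that
analysis:

* **Quadripartite structure.** A plastome is a circle of
  LSC + IRb + SSC + IRa (large/small single-copy regions separated by a
  pair of inverted repeats, one arm the reverse complement of the other).
  `detectInvertedRepeats()` finds the maximal exact IR pair by seeding
  reverse-complement 25-mer matches, `partitionQuadripartite()` derives
  the four regions and junction coordinates, and `irGeneContentDiff()`
  reports the genes a boundary ("IR expansion") has duplicated.
* **Collinear comparison and variant calling.**
  `buildAnchorChain()` decomposes two genomes into maximal unique exact
  shared segments (31-mer anchors, weighted longest-increasing-subsequence
  chaining); `callVariants()` aligns the inter-anchor gaps globally (match
  +1, mismatch −1, gap open −4, extend −1), emitting one SNP per mismatch
  column and one left-normalised indel per gap run; `detectInversions()`
  turns reverse-orientation anchor blocks into inversion records.
  `applyVariants()` reconstructs genome B from genome A and the call set —
  the internal correctness oracle.
* **Tandem-repeat copy-number variation.** `findTandemRepeats()` scans all
  phases and unit lengths (10–39 bp) for maximal *exact full-copy* arrays
  with primitive units; `buildCnvCatalog()` matches loci across species by
  60-bp flanking-sequence anchors and keeps loci whose copy vectors
  differ.
* **Selection screen.** `kaksScreen()` codon-aligns each shared
  protein-coding gene (protein-level global alignment, BLOSUM62,
  back-translated) and computes Nei–Gojobori (1986) estimates: per-codon
  synonymous site fractions, substitution counts averaged over equal-weight
  mutation pathways avoiding stop codons, Jukes–Cantor correction
  *d* = −3/4 ln(1 − 4*p*/3). Ka/Ks ≥ 1 flags positive selection;
  Ka > 0.01 and Ks > 0.02 flag elevated rates.
* **Marker design and in-silico PCR.** `selectMarkerLoci()` keeps loci with
  ≥ 4 bp inter-species size difference (or presence/absence), conserved
  primer flanks, and no intraspecies variant within 150 bp;
  `designAssay()` builds size-polymorphic primer pairs, three-primer
  IR-junction assays, and allele-specific (SNP-3′-terminal) assays;
  `inSilicoPcr()` predicts products on circular templates (exact matching,
  3′-exact bases, all productive primer pairings);
  `discriminationMatrix()` delivers the final "does this panel resolve the
  species?" verdict.
* **Synthetic trios with ground truth.** `generateGenomeTrio()` and
  `generate45STrio()` simulate a three-taxon ((A,B),C) study — two
  accessions per species, branch-specific SNPs/indels, tandem-repeat
  arrays with per-species copy numbers, a 625-bp inversion and a 1.2-kb IR
  expansion on one lineage, and an ITS-elevated 45S trio — together with
  machine-readable truth tables used throughout the test suite.

`runPipeline()` chains everything and writes per-stage TSVs, VCF/BEDPE,
a JSON summary and a Markdown report. GenBank flat files and
FASTA + feature tables are read with `readGenome()`; deposited accessions
(e.g. from NCBI) can therefore be analysed directly once downloaded.

## A worked example

```r
library(PlastomeAuth)

trio <- generateGenomeTrio(trioSpec(seed = 1))
g <- trio$genomes$B[[1]]          # the structurally rearranged lineage
g
#> AnnotatedGenome B-01: 31,432 bp, circular, 45 features

ir <- detectInvertedRepeats(g)
ir
#> IRPair: 5,200 bp arms, IRb [14079..19278] / IRa [26233..31432] (0 mismatches)
partitionQuadripartite(g, ir)
#> QuadripartitePartition: LSC 14,078 / IRb 5,200 / SSC 6,954 / IRa 5,200 bp
#>   junctions: J_LSC_IRb=14079, J_IRb_SSC=19279, J_SSC_IRa=26233, J_IRa_LSC=1
```

Species B's IR arms are 5,200 bp — 1,200 bp longer than the 4,000 bp arms
of its relatives, because the boundary migrated into the LSC and
duplicated three genes. Comparing B against species A finds the planted
inversion:

```r
a <- trio$genomes$A[[1]]
ch <- buildAnchorChain(a, g)
detectInversions(ch, a, g)[, c("startA", "endA", "length", "genes")]
#>   startA  endA length                      genes
#> 1  10694 11318    625 trnD-GUC,trnY-GUA,trnE-UUC
```

and a three-primer junction assay separates the expanded lineage — the
control pair amplifies everywhere, while the control reverse primer's
second binding site (inside the expanded IRa) reacts with the LSC primer
only in B:

```r
irs   <- lapply(lapply(trio$genomes, `[[`, 1), detectInvertedRepeats)
parts <- Map(partitionQuadripartite, lapply(trio$genomes, `[[`, 1), irs)
designAssay(list(expanded = "B", partitions = parts),
            lapply(trio$genomes, `[[`, 1), kind = "three_primer", id = "IR01")
#> MarkerAssay IR01 (three_primer) at IR/LSC junction
#>   LSC_P      5'-TATTGGCCTCGGGCATAC-3'
#>   Control_F  5'-GGCTGTGCTGGATTGATC-3'
#>   Control_R  5'-GAGTCCCAATAGTAGTTATG-3'
#>   products: A=392 / B=392+765 / C=392
```

So every species shows the 392-bp control band, and only the IR-expanded
species adds the 765-bp junction band — a one-lane species diagnosis.

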