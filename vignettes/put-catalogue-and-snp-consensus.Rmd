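---
title: "Methods: PUT catalogues and conservative SNP consensus from pooled 454 cDNA libraries"
author: "putsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PUT catalogues and conservative SNP consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(putsnp)
```

## The problem and the study design

Conifer genomes are tens of gigabases, so transcriptome sequencing is the
practical route to gene catalogues and genetic markers. The design this
package targets pools RNA from many seedlings of two varieties (coastal
and interior provenances), two tissues (needle, wood) and three drought
treatments (control, mild, severe) into **twelve normalized cDNA
libraries**, sequenced with 454 chemistry and assembled de novo into
*contigs* (exon-like blocks), *isotigs* (transcript variants chained from
contigs) and *isogroups* (genes). Two consequences of this design drive
everything downstream:

* libraries are *normalized*, so read counts do not measure expression —
  only presence/absence patterns are interpretable; and
* there is *no genome reference*, so for a biallelic SNP neither allele
  can be labelled "reference". Statistics must be invariant under
  swapping the allele labels.

## Pipeline model

**Cleaning.** A read is discarded if it contains an `N`, is shorter than
`min_len` (50 bp), or starts/ends with a polyA/T homopolymer of at least
`polyAT_min_run` (8 bp). "polyA/T" is a homopolymer of A *or* of T — a
poly(A) tail or its reverse complement; mixed A/T runs do not count.
Internal tracts split the read; the longest fragment is kept, ties
resolving to the 5' fragment. The rules run in the fixed order
N → terminal → internal → length so that each removal count is well
defined. Whether terminal-tailed reads should be discarded or merely
trimmed is a genuine reading ambiguity; we default to the literal
`discard` and expose `terminal_policy = "trim"`.

**Catalogue.** Assemblers mark some reads as singletons even when they
match an existing isotig nearly perfectly. We re-align all singletons of
at least 100 bp to the isotigs; any read reaching `min_identity` (0.98,
counted over alignment columns: matches / (matches + mismatches + gap
columns)) and `min_aln_frac` (0.9 of the read aligned) is a
*false-positive singleton* and is rescued. Unmapped reads are real
singletons, checked for exact duplicates (byte-identical sequence only —
near-duplicate clustering belongs to the read sets fed to external
callers, not to catalogue construction). The catalogue is isotigs plus
retained singletons, each singleton founding its own isogroup; the
length filter (≥ 100 bp) is applied once, before rescue, which fixes an
order the original description leaves open.

**Mapping engine.** A k-mer seed index (`k = 11`) finds candidate
references; candidates are ranked by seed count and extended with a
banded local alignment (band ± 10 around the modal seed diagonal;
match +2, mismatch −1, linear gap −2 — 454 indels are short, affine gaps
buy nothing). Both strands are searched. Ties between equally good hits
break deterministically: more alignment columns, then lexicographically
smaller reference id, then forward strand. `min_aln_frac` exists because
a seed hit alone can otherwise "rescue" a singleton on a short spurious
overlap; 0.9 requires most of the read to align.

**SNP consensus.** Pileup columns collect the aligned read base per
reference position (gap columns carry no support). A site is called iff
the two most-supported alleles each have at least `min_allele_support`
(3) reads — so the minimum callable depth is 6, and an exhaustive
enumeration of depth-5 sites shows none is callable. Sites where a third
allele also reaches 3 reads are reduced to the top two (count, then
lexicographic) and flagged. To emulate the original multi-tool
conservatism without re-implementing external callers, the same bespoke
caller is run under three mapping stringencies
(identity 0.98/0.95/0.90 with aligned fraction 0.9/0.8/0.5), and
externally produced VCFs can join via `read_external_callset()`. A
consensus SNP must match in reference, position *and unordered allele
pair* in every callset — position-only agreement would conflate distinct
substitutions; supports merge by read-id union.

**Provenance.** Each allele's origin is the set of varieties among its
supporting reads' library codes (second code letter): `c`, `i`, or `ci`.
The nine ordered origin pairs pool into six categories (`ci/ci`, `ci/c`,
`ci/i`, `c/i`, `c/c`, `i/i`), which is exactly the algebraic consequence
of having no reference allele: the pooling map is the quotient of the
ordered pairs under label swap.

**Coding effect.** Only the top protein hit (smallest e-value) of a PUT
is consulted; all its HSPs are. A SNP outside every HSP is `noncoding`;
with no hit at all, `unannotated`. Inside an HSP, the reading frame
(±1..3, sign = query strand) determines the codon; both alleles are
translated with the standard nuclear code. Among overlapping HSPs the
best bit score wins. Frame/coordinate inconsistencies (phase mismatch,
HSP length not a codon multiple, codon truncated at an HSP edge) are
annotation errors and yield `unannotated` rather than a guess.

**Screens and diversity.** Isotigs partition into seven treatment groups
by the sorted set of treatments among their member reads (tissue and
variety deliberately pooled). Length bins default to < 501, 501–1000,
1001–1999, ≥ 2000 bp; the 2,000 boundary is assigned to the top bin (the
conventional bin labels leave it ambiguous). Keyword screening is
case-insensitive substring matching over hit descriptions — any hit
qualifies an isotig for a term, while candidate reporting lists the best
(smallest e-value) hit; the shipped catalogue holds the 21 standard
drought/stress terms and is user-extensible. The length–reads
correlation is Pearson on log10–log10 pairs (a linear-scale option
exists). The polymorphism level divides the SNP count by the *distinct*
nucleotide total — each contig counted once however many isotigs include
it — so `percent · per_bp = 100` holds exactly before rounding.

## The synthetic-data generator

`generate_transcriptome()` builds genes from ≥ 100 bp contigs; the first
isoform carries every contig and further isoforms drop subsets, so
isoforms of a gene always share contigs and a shared contig id denotes an
identical subsequence. Each isoform gets a treatment profile drawn from
the seven non-empty subsets of {c, m, s}. `plant_variants()` places
biallelic variants (within multi-isoform genes, only in contigs private
to one isoform, so each planted site maps to a single reference) with
per-variety alternate-allele frequencies that realize the six provenance
categories; shared-polymorphism frequencies are drawn from [0.2, 0.8] so
that three reads per allele are likely at moderate depth. The
variety-private categories `c/c` and `i/i` require zero coverage from one
variety; frequencies alone cannot encode that, so the uncovered variety's
frequency is `NA` and that variety's libraries skip the host transcript
entirely.

`simulate_library_reads()` draws reads per library plan: transcripts are
sampled uniformly (normalization is emulated as flat molecule abundance —
a deliberate simplification, with the side effect that the length–reads
correlation in simulated assemblies is near zero, unlike fragmentation-
driven real data; the correlation operation is therefore exercised on
length-weighted draws in its own tests). Read lengths are truncated
normal (default mean 338, s.d. 100, floor 50 bp, the study's read-length
scale); strands are random; each read draws its allele independently per
overlapped variant at the variety's frequency (pooled libraries justify
independence). Error processes apply after allele assignment:
substitutions (default 10^-3 per base), homopolymer indels only inside
runs ≥ 3 nt (454-style; default rate 0), one `N` per affected read
(default 2 % of reads), and terminal polyA/T artifacts of 8–20 bp
(default 5 %). No flowgram/SFF emulation, no duplicate-read (emPCR)
modelling, no MID demultiplexing.

`emit_assembly_fixture()` stands in for the assembler: isotig sequences
are the transcript sequences and member lists come from the simulation
truth, with a labelled mixture withheld as singletons — *false positives*
(members withheld at `fp_singleton_rate`, never emptying an isotig) and
*true singletons* (all reads of whole dropped genes; dropping single
isoforms would leave a contig-sharing sibling that rescues their reads at
full identity). Reads under 100 bp land in a too-short bin, so members +
singletons + too-short always equals the read total.

What passing tests on this generator do **not** show about real data:
assembly is emulated, so chimeras, collapsed paralogs and mosaic isotigs
never occur; coverage is far below study scale; and BLAST hits are
simulated (`simulate_blast_hits()` gives longer transcripts a
logistically higher hit chance and embeds keywords at a set rate) rather
than computed against a protein database.

## Numerical choices and degenerate inputs

* Identity's denominator is alignment *columns* (matches + mismatches +
  gap columns) — "98 % of the alignment length" read literally.
* Pileup and SNP coordinates are 0-based internally, 1-based in VCF and
  TSV exports.
* `call_snps` with an empty pileup, `plant_variants` with `n = 0`, and
  rescue with an empty singleton set all return empty, well-typed
  objects; intersection with fewer than two callsets refuses.
* Every stochastic step takes an explicit seed; per-library and per-stage
  seeds derive from one master seed, and reruns are byte-identical
  (manifests record md5 digests of every artifact).
* Default problem sizes (the shipped `pipeline_config()`: 12 genes, 30
  variants, 250 reads per library; the test suite uses 6–20 genes and
  40–250 reads per library) are chosen so the full pipeline and suite run
  comfortably on a single desktop core while keeping per-variety depth
  high enough that planted-variant recovery is essentially
  deterministic.

## Known limitations

* No genotype likelihoods, quality recalibration, indel calling, or
  allele-frequency estimators: pooled normalized libraries make read
  counts unreliable estimates of allele frequencies, so
  population-genetic summaries (e.g. Tajima-style estimators) are out of
  scope.
* Treatment groups are presence/absence only; no statistical test of
  group differences is offered (with most treatment-specific isotigs
  built from two or three reads, such tests would be underpowered).
* Gene-ontology annotation and live database searches are outside the
  package; hit tables are consumed, not produced.
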