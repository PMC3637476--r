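# putsnp

Post-processing of multi-library 454 cDNA assemblies into a catalogue of
**putative unique transcripts (PUTs)** and a conservative **multi-caller
SNP consensus**, for conifer-scale transcriptome projects that have no
genome reference.

The package is aimed at the classic EST/454 study design: pooled,
normalized cDNA libraries from two varieties (here: coastal and interior
Douglas-fir provenances), two tissues and three drought treatments, twelve
libraries in all, assembled de novo into contigs, isotigs (transcript
variants) and isogroups (genes). From the assembler's output it builds the
reference transcript catalogue, calls SNPs against it, and screens
transcripts for treatment specificity and stress-related annotation. A
synthetic-data generator emulates the whole twelve-library design with
planted truth, so every stage is testable without any external data.

## What it computes

* **Read cleaning** — reads containing `N` are removed; reads shorter
  than 50 bp or carrying a terminal polyA/T homopolymer of ≥ 8 bp are
  discarded; internal polyA/T tracts split the read and the longest
  fragment is kept.
* **PUT catalogue** — singleton reads that align to an isotig at ≥ 98 %
  identity over the alignment are *false-positive singletons* and are
  rescued; the remainder are de-duplicated and join the isotigs in the
  catalogue; sequences under 100 bp are excluded. The bookkeeping
  identity is
  `n_puts = n_isotigs + (n_singletons − n_rescued − n_duplicate)`.
* **SNP calling** — at each pileup column the two most-supported alleles
  must each be confirmed by ≥ 3 reads (minimum callable depth 6). Several
  caller configurations (differing in mapping stringency) are intersected;
  only SNPs identical in position and allele pair across *all* callsets
  enter the consensus. Because no genome fixes a reference allele, alleles
  are stored in canonical order and all statistics are invariant under
  swapping them.
* **Provenance classification** — each allele's origin is the set of
  varieties among its supporting reads (`c`, `i`, or `ci`); the nine
  ordered pairs pool into six categories
  `ci/ci, ci/c, ci/i, c/i, c/c, i/i`.
* **Coding effect** — from BLASTX-style HSPs of a PUT's top protein hit,
  the codon containing the SNP is translated under the HSP frame with each
  allele: synonymous / nonsynonymous / noncoding / unannotated.
* **Screens** — isotigs partition into seven treatment groups
  (`c, m, s, cm, cs, ms, cms`) from their member reads' library codes;
  group and length-bin summaries; keyword screening of hit descriptions
  (21 drought/stress terms by default); length–reads correlation.
* **Polymorphism level** — SNP count divided by the *distinct* nucleotide
  total of the catalogue (a contig shared by several isotigs counts
  once): `percent = 100 · n_snps / distinct_nt`, equivalently one SNP per
  `distinct_nt / n_snps` bases.

## Worked example

```r
library(putsnp)
res <- run_pipeline("demo_run", pipeline_config(
  n_genes = 20, n_variants = 24,
  plans = default_library_plans(n_reads = 150)), seed = 42)
```

```
[putsnp] simulate: 20 genes, 12 libraries
[putsnp] preprocess: 1800 -> 1685 reads
[putsnp] build-puts: 94 PUTs (23 isotigs + 71 singletons; 77 rescued)
[putsnp] call (config 1: identity >= 0.98): 24 SNPs from 1543 mapped reads
[putsnp] call (config 2: identity >= 0.95): 24 SNPs from 1543 mapped reads
[putsnp] call (config 3: identity >= 0.90): 24 SNPs from 1543 mapped reads
[putsnp] consensus: 24 SNPs in all 3 callsets
```

The run simulates 1,800 reads (150 per library), removes 115 in cleaning
(planted `N`s, polyA artifacts and short reads), withholds a labelled
mixture of singletons, rescues the 77 false positives among them, and
collapses 58 duplicate reads, leaving a catalogue of 94 PUTs
(23 isotigs + 71 real singletons). All 24 planted variants are recovered
by each of the three caller configurations, so the consensus holds 24
SNPs; their provenance categories:

```r
res$report$provenance
#>   category n_snps
#> 1    ci/ci     14
#> 2     ci/c      6
#> 3     ci/i      2
#> 4      c/i      1
#> 5      c/c      1
#> 6      i/i      0

res$diversity
#> polymorphism level: 0.07% (1 SNP per 1,438 bp; 24 SNPs over 34,521 bp)
```

`ci/ci` means both alleles segregate in both varieties (shared
polymorphism); `ci/c` means one allele is seen in both varieties and the
other only in coastal reads; `c/c` sites have coastal read support only.
The diversity estimate divides the 24 consensus SNPs by the 34,521
distinct nucleotides of the catalogue (shared contigs counted once).

Every stage is also available as a plain function
(`clean_read`, `rescue_singletons`, `call_snps`, `intersect_callsets`,
`classify_provenance`, `classify_coding_effect`,
`partition_by_treatment`, `keyword_screen`, `polymorphism_level`, ...);
`inst/scripts/run_pipeline.R` wraps the pipeline for shell use. External
callers can join the consensus through `read_external_callset()` (VCF).

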