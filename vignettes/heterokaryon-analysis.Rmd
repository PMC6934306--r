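---
title: "Detecting within-isolate nuclear variation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-isolate nuclear variation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetkaryo)
```

## The scientific problem

Arbuscular mycorrhizal fungi (AMF) such as *Rhizophagus irregularis* are
coenocytic: a single "individual" is a network of hyphae containing thousands
of nuclei. Some isolates are *homokaryons* (all nuclei genetically identical);
others are *heterokaryons* carrying two genetically different nucleus
genotypes mixed at some ratio `p`. A heterokaryon leaves a characteristic
signature in sequencing data: at genomic positions where the two nucleus
genotypes differ, reads show two alleles whose frequencies reflect `p`
(a peak at 0.5 when the genotypes are balanced), and the same bi-allelic
positions recur across replicate libraries and across independent study
designs (whole-genome and ddRAD sequencing). Sequencing error, collapsed
repeats and assembly gaps also create two-allele signals, but those do not
replicate consistently, do not concentrate at a common frequency, and do not
reappear independently in the transcriptome.

`hetkaryo` implements this whole line of evidence as a reusable, testable
pipeline: in silico ddRAD fragment prediction, repeat labeling, per-sample
poly-allelic site classification, allele-frequency distributions with
coverage-threshold sweeps, replicate concordance with hypergeometric overlap
tests, reference-free discovery of bi-allelic transcript positions from a De
Bruijn graph, and RNA-to-genome allele-composition consistency. A seeded
synthetic data generator provides ground truth so that every stage can be
validated without external downloads.

## The synthetic heterokaryon generator

`sim_config()` fixes the study conditions. The defaults describe a desk-scale
study with the statistical structure of real AMF data:

* **Genome**: 200 kb single contig at GC 0.30 (AMF genomes are AT-rich),
  with 60 non-overlapping 1.2-kb single-exon gene models (36% coding),
  20 exact copies of a 500-bp interspersed element, and 2 exact segmental
  duplications of 2 kb (both copies recorded as truth repeats).
* **SNPs**: 300 planted differences between the two nucleus genotypes
  (1.5 per kb, inside the 1–2.8 per kb range reported for real isolates).
  Positions keep a minimum spacing of 100 bp so each SNP forms an isolated
  substitution, and avoid a ±6 bp window around every EcoRI/MseI motif (and
  any substitution that would create one), so both haplotypes share a single
  digest map. This isolates the variant-calling question from
  fragment-presence effects.
* **Reads**: single-end 100 bp; whole-genome and ddRAD at 30× (real samples
  ranged over roughly 13–47× and 22–33×), RNA at 50× transcript coverage.
  Every read is drawn from haplotype 1 with probability `p` (default 0.5),
  otherwise haplotype 2. Substitution errors are uniform at
  `error_rate = 0.005` per base; qualities are constant Q37 because the
  site classifier models error through its own error-rate parameter rather
  than through per-base qualities.
* **Truth**: reads carry their generating coordinates as SAM records, so the
  pipeline needs no read mapper; real-data users supply externally mapped
  BAMs or called VCFs instead.
* **Expression**: per-gene relative abundances are log-normal
  (`sdlog = 0.5`). The real transcriptome-wide distribution is unknown at
  this resolution; log-normal is the standard first-order model for bulk
  RNA abundances and is configurable. Genes can be flagged
  single-allele-expressed as negative controls.

What the generator deliberately does **not** emulate: indels and multi-base
variants, position- and quality-dependent error profiles, PCR duplicates,
library-size selection, intron structure, and read mis-mapping. Passing tests
therefore demonstrate correctness of the algorithms under ideal mapping, not
robustness to alignment artifacts — the problematic-region flagger
(`flag_problematic_regions()`) exists precisely because real assemblies add
artifacts this generator excludes.

## In silico ddRAD digestion

`predict_fragments()` performs the double digest: EcoRI cuts `G^AATTC`,
MseI cuts `T^TAA` (both palindromic, so one strand is scanned; the cut offset
of 1 is the standard chemistry — any consistent convention shifts all
boundaries uniformly). A fragment spans two *consecutive* cuts of different
enzymes — a fragment containing an internal cut would be cleaved, matching
double-digest size-selection practice — and is kept when longer than 49 bp.
No upper size bound is applied by default (`max_length` exists for users who
want one). `anchor_fragments()` re-anchors fragments by searching their
sequence against the genome: fragments matching exactly one locus become
*predicted ddRAD regions*; anything multi-copy is removed. At desk scale the
search is exact matching; for real, divergent data a seeded-identity search
(`min_identity < 1`) is available. A region overlapping a gene model by at
least one base is flagged coding — with no published overlap rule, one base
is the least arbitrary choice and regions are short relative to genes.

## Repeat labeling

Three complementary labelings of repeated elements, mirroring common
practice of testing repeat-detection sensitivity:

* **M03** — all-vs-all *global* alignment of fragments (match +1, mismatch
  −1, gap −2); a pair at ≥ 80% identity labels both members.
* **M07** — each fragment searched against the *whole genome*; hits need
  ≥ 80% identity over ≥ 90% of the fragment. The fragment's own locus is the
  first match, so any additional locus labels it.
* **M12** — seeded mapping reporting all hits within a 30-score band of the
  best (capped at 100 hits); more than one reported hit labels the fragment.

The 0.80 identity thresholds are the package defaults (the alignment tools
historically used for this step apply comparable defaults); they are
configurable, and on exact duplicates every method agrees, so downstream
results are robust to the choice. On exact duplicates M03 labels are a
subset of M07 labels: a fragment globally similar to another fragment
necessarily matches at least two genome loci. `kmer_interspersed_mask()`
provides the interspersed-repeat mask: positions covered by any k-mer
(k = 15) occurring ≥ 4 times genome-wide are masked. This is a stand-in for
a dedicated repeat annotator and an externally supplied BED mask takes
precedence when given.

## Site classification

`pileup_allele_counts()` tallies A/C/G/T from aligned bases with base
quality ≥ 13 (a common pileup floor). `classify_sites()` then applies the
study's rules in order:

1. depth < 10 → `NA` (no call);
2. alleles with frequency ≥ 0.1 are *recorded* (raw fractions, never
   renormalised);
3. one recorded allele → mono-allelic; two or more → bi/tri/tetra-allelic
   **if** the site quality passes 30, else the variant record is filtered
   and the site stays mono.

Site quality replaces a caller's phred-scaled QUAL with an explicit binomial
error model: `q = −10·log10 P(X ≥ minor count)` with
`X ~ Binomial(depth, error_rate/3)` (a *specific* substitution occurs at a
third of the per-base error rate), capped at 999. The default
`error_rate = 0.01` is deliberately conservative (twice the generator's
0.005). No allelic-ratio filter beyond the 0.1 recording rule is applied —
the point of the analysis is to keep all within-isolate polymorphism. Ties
between allele counts order alleles by count then alphabetically; this only
affects reporting, never classification. Whether the frequency rule applies
before or after the quality rule is ambiguous in the original workflow; here
frequency is applied first, quality second, which is the order that mirrors
how a variant caller emits then filters records. Tetra-allelic sites use the
same frequency rule as every other class.

`ingest_vcf()` accepts pre-called variants instead (SNP records only; QUAL
≥ 30, depth ≥ 10, allele fraction ≥ 0.1), so real datasets can enter the
pipeline downstream of any caller.

Density is reported per kb: bi-allelic positions in non-masked coding
predicted regions divided by the positions there with depth ≥ 10 (an
undefined density is `NA`, never 0). `frequency_distribution()` picks one of
the two allele frequencies per bi-allelic site uniformly at random (seeded,
default seed 1) — plotting both would duplicate every site symmetrically —
and returns a kernel density estimate plus a 0.01-bin histogram with
left-closed bins, so a frequency of exactly 0.50 falls in [0.50, 0.51).
Because of the random choice, the distribution is symmetric around 0.5 and a
ratio `p` appears as peaks at `p` and `1−p`; the mode is therefore read up
to that folding. Raising the depth threshold can only drop sites, and on
mixtures of unique ~30× regions with collapsed ~90× repeats a high threshold
(60×) leaves mostly repeat-derived sites — mechanically reproducing the
U-shaped frequency distributions that coverage thresholds induce.

## Replicate concordance

`intersect_sets()` partitions bi-allelic positions by replicate-membership
pattern (the counting behind an UpSet plot; the print method shows the top
15 patterns and buckets the rest). `hypergeometric_overlap()` computes the
upper-tail (inclusive) cumulative hypergeometric probability of an overlap
at least as large as observed. The universe `N` is a deliberate choice the
original analysis leaves open: here it is the conservative *eligible-site*
universe — positions with depth ≥ 10 in both compared samples inside the
analysis regions — and it is configurable; reported p-values are only
meaningful together with the universe definition. Positions are compared on
the shared reference coordinate system; no liftover is attempted.

## Reference-free RNA bi-allele discovery

Reads are QC-filtered (drop reads containing N, trim 3′ bases below Q20,
keep reads ≥ 50 bp), then assembled into a stranded De Bruijn graph
(`k = 41` by default, the standard choice for this application; k must be
odd to avoid palindromic k-mers) with k-mers below a solidity of 2 removed.
A SNP appears as a *Type0a bubble*: two vertex-disjoint simple paths of
exactly k nodes between a shared source and sink, spelling two sequences of
length 2k−1 that differ only at the centre. Only this bubble type is
enumerated; indel and splicing bubbles are out of scope.

Path support is the **maximum** node count along a path. The natural
quantity is "reads sharing at least one path k-mer"; the maximum node count
is its tight observable proxy. The minimum was considered and rejected: it
equals the count of reads spanning the whole 2k−1 window, which collapses
near transcript ends, deflating totals there — true SNPs then fail the
coverage filter and duplicate sequencing errors inflate past the
minor-fraction rule.

`filter_bubbles()` applies, in order: total support ≥ 6; each allele
observed ≥ 2 times; minor-allele fraction ≥ 0.1 (the same recording rule
that defines a bi-allelic position in genome data — without it, two reads
sharing one sequencing error on a well-covered transcript would qualify);
minor-allele site quality ≥ 30 under the binomial error model (the RNA
counterpart of the genome-side quality floor; it is ratio-aware, so a 2-read
minor allele is rejected at 20× support but kept at 6×, where two identical
errors would be genuinely surprising);
and a single unambiguous placement on the curated reference transcriptome
(identity ≥ 0.80 over ≥ 90% of the path; ambiguous means more than one
qualifying hit or a best-hit identity margin under 2%, the package's
quantification of "mapping ambiguity"). Bubbles with no reference hit are
removed — in the synthetic setting the emitted transcriptome *is* the
curated reference, standing in for an assembled, protein-supported
transcript set.

Codon effects use the longest ATG-to-stop ORF on the transcript strand
(stranded library; ties resolve 5′-most): the centre base's codon is
translated with the standard genetic code for both alleles. The centre base
alone decides coding status for bubbles straddling an ORF boundary — the
variant, not its flanks, is what is being classified. Genomic placement
(`bubble_genome_positions()`) maps paths at identity ≥ 0.90, records the
strand-resolved genome coordinate of the centre base for uniquely mapped
bubbles, and flags multi-hit/unmapped bubbles out of the consistency
analysis (they are reported separately).

A position is *consistent* when the whole-genome call at the same
coordinate is bi-allelic with the identical unordered allele pair; anything
else — mono, a different pair, tri-allelic, missing — is *inconsistent*.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 is 1-based closed on
  export, VCF 1-based on ingest, BED 0-based half-open.
* All randomness flows from explicit integer seeds; each simulation stage
  derives a fixed offset from the config seed so stages are independently
  reproducible, and replicate read sets use a caller-supplied `seed_offset`.
  RNG state of the caller is always restored.
* Zero-denominator density and empty frequency distributions return `NA`
  sentinels rather than zeros.
* The seeded mapper is ungapped (seed-and-extend on exact 11-mer seeds,
  both strands, overlapping hits collapsed to the best score). This is
  exact for the generator's indel-free data and a documented approximation
  for real data, where gapped aligner output can be ingested instead.
* `place_intervals()` samples interval starts from the exact set of
  still-feasible positions, so placement fails only when the genome
  genuinely lacks room, with an error naming the constraint.

## Problem sizes used in the test-suite and demonstrations

The packaged tests validate the pipeline at sizes a laptop handles in
minutes, chosen to keep binomial sampling noise well inside the asserted
margins: 200-kb genomes with 300 SNPs at 30× for site-classification and
concordance properties, 100-gene transcriptomes at 50× (with `k = 21`,
recorded in the tests; k is a free parameter and smaller k only shortens
the bubble context) for bubble recall, and 80-kb demonstration studies in
`make_demo()`. The acceptance script rebuilds the demonstration studies
from scratch at each run from the supplied seed.

## Known limitations

* The generator's clean mapping means collapsed-repeat and mis-mapping
  artifacts are only exercised synthetically via the threshold-sweep
  property, not end to end.
* The ungapped internal mapper cannot place reads or bubbles across indels;
  real datasets with indel variation should come in as externally mapped
  BAM/VCF.
* Residual false bi-alleles from coincident duplicate sequencing errors on
  lowly-expressed transcripts survive all published filters at a rate of
  roughly one per few hundred transcripts at 0.5% error; they are the same
  artifact class the consistency analysis is designed to expose, and the
  homokaryon control quantifies them.
* `find_type0a_bubbles()` enumerates bubbles exhaustively; on graphs far
  denser than transcriptome graphs (e.g. unfiltered genomic k-mers) the
  `max_bubbles` cap should be lowered.

## A worked example

```{r demo, eval = FALSE}
library(hetkaryo)
demo <- make_demo(seed = 1)
demo$summary
```

The heterokaryon study shows a bi-allelic density near the planted 1.5/kb,
a modal allele frequency at 0.5, and RNA-detected bi-alleles overwhelmingly
consistent with the genome; the homokaryon control shows near-zero density
and essentially no consistent positions — the qualitative contrast that
separates a true heterokaryon from sequencing artifacts.
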