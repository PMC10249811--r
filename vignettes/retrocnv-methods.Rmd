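---
title: "Detecting and characterizing retrocopy copy-number variants"
author: "retroscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing retrocopy copy-number variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscout)
```

## The problem

A retrocopy is the product of LINE-1 machinery acting on a spliced
mRNA: an intron-less, poly(A)-tailed copy of a gene inserted somewhere
else in the genome, flanked by a target-site duplication (TSD) of the few
bases at the integration site. When the insertion is recent it
segregates — some individuals carry it, others do not — and, critically,
it is absent from the reference assembly. Standard variant callers then
see nothing at the insertion site; what they do see is a halo of oddities
around the *parent gene*: reads containing exon–exon junction sequence
that exists nowhere in the reference, read pairs with one mate in an exon
and the other at the (unrepresented) insertion locus, and non-reference
alleles piling up on the parent's exons because reads from the diverged
retrocopy have nowhere else to go. `retroscout` turns each of those
signals into a pipeline stage.

## Detection model

**mRNA-specific k-mers.** For each annotated transcript we take all
k-mers of the spliced sequence, canonicalize each to the lexicographic
minimum of itself and its reverse complement (sequencing is unstranded),
and discard any k-mer that occurs in the reference genome exactly *or*
within Hamming distance 2 on either strand. The Hamming margin exists
because a single sequencing error in a read overlapping an almost-unique
genomic locus would otherwise mint a spurious "mRNA-specific" k-mer.
Distance is substitution-only by design: short-read errors in this
setting are overwhelmingly substitutions, and the genome-wide filter the
method descends from maps candidates with a substitution-only aligner.
Surviving k-mers necessarily straddle splice junctions. The genome-wide
absence check is exact-matched with an Aho–Corasick dictionary and the
Hamming-2 check uses pigeonhole seeding (split the k-mer into three
segments; any match within two substitutions contains one exact segment)
followed by positional verification. On genomes up to ~100 kb the test
suite verifies the whole construction against an exhaustive
window-by-window Hamming scan.

A sample is called a carrier of a putative retroCNV parent gene when its
reads contain **more than `t_min = 5` distinct** inventory k-mers of the
gene covering **at least `f_min = 10%`** of the inventory. Both
thresholds are exposed. The 10% denominator is the *specific*-k-mer
inventory, not all transcript k-mers — with intron-less or
reference-identical transcripts the inventory is empty and the gene is
excluded (with a warning) rather than trivially called.

The default k = 30 matches the gigabase-scale regime the thresholds come
from. On desk-scale toy genomes the Hamming-2 filter at k = 30 is
essentially never triggered by chance, and at k = 12 it fires so often
that inventories empty out; the test suite therefore runs k = 14–16 on
40–300 kb genomes, chosen so that the expected number of chance
Hamming-2 neighbours per k-mer stays well below one.

**Insertion resolution.** Discordant candidates are records overlapping
a parent exon whose mate maps to another chromosome or beyond
`d_max = 10 kb`; intron-only anchors are discarded because a retrocopy
contains no intron sequence. Mate positions are clustered by
single-linkage with a `cluster_window = 500 bp` gap and a
`min_support = 4` floor — values chosen to be comfortably recoverable at
20x coverage and exposed as configuration. At each cluster, soft-clipped
alignments vote for two breakpoints: the modal right edge of
right-clipped (left-flank-anchored) reads and the modal left edge of
left-clipped reads. Because two independent insertions can land within a
kilobase of one another, the two votes are taken *jointly*: among all
candidate edge pairs whose separation lies in the plausible TSD band
(−10 to +50 bp), the pair with the highest combined clip support wins,
ties broken toward the leftmost coordinate. When the left breakpoint
exceeds the right one, the intervening reference bases are the TSD —
duplicated on both sides of the insert — and the call reports exactly
those bases, so the reported `tsd_seq` always equals the reference
substring of the reported interval. With no clipped support the call
degrades gracefully to the cluster interval with a null TSD.

Parents with k-mer evidence but no resolvable cluster remain reportable
through two weaker evidence classes: counts of reads containing an
exon–exon junction window (last 20 bp of one exon + first 20 bp of the
next, either strand), and a male-only pattern of evidence across a sexed
cohort (≥ 2 males, 0 females), which flags likely Y-linked insertion
sites that cannot be resolved against a reference without a Y.

**Reference retrocopies.** For retrocopies already present in the
reference, absence in a sample is the mirror-image signal: depth over the
interval below 15% of genome-wide depth means homozygously absent;
15–75% with read pairs straddling the interval at a spacing consistent
with its deletion means heterozygously absent.

## Attribution, copy number, expression

SNVs at the parent locus (exact pileup of M-aligned bases, presence =
≥ `r_min = 3` alt reads) are attributed by carrier status: alt in ≥ 1
carrier and 0 non-carriers → retrocopy; alt in any non-carrier →
parental; cohorts lacking either class make every call ambiguous rather
than silently guessing. Coding consequences come from codon arithmetic
against the CDS (indels by length mod 3), cross-checked in the tests
against full translate-and-compare.

"Fixed across all copies" needs a numeric criterion at an amplified
locus. If a sample carries CN retrocopies whose reads all mismap onto
the two parental alleles, a variant present in every copy has expected
alt fraction CN/(CN+2). We call a variant fixed when its alt fraction
reaches `tau_fixed = 0.5` of that expectation in *every* carrier —
lenient enough to survive depth noise, strict enough that a variant on a
minority of copies (e.g. 5 of 25: expected fraction ≈ 0.19 of reads
versus threshold 0.46) fails. Fixed SNVs are N-masked in the transcript
for unbiased RNA-seq alignment; indel diagnostics are recorded but not
masked because masking is positional. Per read pair, observed alleles at
covered diagnostic sites assign parent / retrocopy; bases matching
neither allele (sequencing errors) do not vote; any conflict, within or
between mates, leaves the pair unassigned, and the reported
`retro_fraction` excludes unassigned pairs from its denominator.

Copy number is the mean M-base depth over the duplicated region divided
by genome-wide mean depth, the latter supplied (typically from a
per-chromosome summary, excluding the amplified locus itself — at toy
genome sizes the locus would otherwise dominate the average, which a
gigabase genome dilutes for free). TPM is the standard
length-normalized rate scaled to one million.

## Dating and clustering

Divergence between a retrocopy and its parent transcript is the raw
p-distance: mismatching ungapped columns over ungapped columns, gaps
contributing to neither count. Pairs are aligned globally
(Needleman–Wunsch; match 1, mismatch −1, gap −2 per base) — adequate for
the near-identical pairs being dated — or supplied pre-aligned. The age
is `t = d / (k_lin × mu) × g` with `mu = 7.24e-9`
substitutions/site/generation and `g = 8` years as defaults (the rate
and generation time estimated for horses). `k_lin` defaults to 1,
attributing all divergence to the retrocopy lineage: a retrocopy is
dead-on-arrival sequence accumulating substitutions against a conserved
parent, and this convention matches the arithmetic such estimates are
usually reported with; `k_lin = 2` (both lineages drifting) halves the
age and is one switch away. Cohort ages aggregate as mean, Student-t 95%
interval — n here is a handful of haplotypes, so a t interval is the
defensible choice — and range.

Variant-profile matrices (rows = sequences, columns = binary allele
presence) are clustered with Euclidean distance and average linkage;
node support is the fraction of bootstrap replicates (columns resampled
with replacement) whose tree contains the same leaf set. This is the
ordinary bootstrap, not multiscale/approximately-unbiased resampling:
for deciding whether, say, one species' retrocopies form a clade, clade
frequencies under column resampling answer the question directly and
reproducibly under a fixed seed.

## The synthetic-data generator

Every stage is exercised against simulations with complete ground truth.
The generator emulates the features the pipeline keys on:

* multi-exon genes (2–6 exons, 150–300 bp, introns ≥ 200 bp so splices
  are genuinely discontiguous) on a random-background genome;
* retrocopies with optional internal-exon skipping and 5' truncation, a
  poly(A) tail (default 30 bp; real tails vary and nothing downstream
  depends on the value), and a TSD drawn from the empirically observed
  10–31 bp range (overridable only explicitly);
* tandem amplification of a segment containing a retrocopy, with shared
  (pre-duplication) variants written into every copy and private
  (post-duplication) variants drawn per copy — private variants are
  placed within the retro transcript, where they are observable as
  mismapped alleles at the parent locus, which is the only place the
  pipeline can see them;
* paired-end reads with i.i.d. substitution errors, and RNA-seq read
  pairs drawn from a transcript pool at set proportions.

Rather than running an aligner, the generator emits *truth-guided*
alignments: a segment map ties every base of the sample genome back to
the reference, and each read is placed the way an aligner would place it
on a reference lacking the insertion — the portion in its anchor segment
aligned as M, overhangs into inserted sequence soft-clipped, mates inside
a retrocopy mapped to the parent's exons, poly(A)-only reads unmapped,
and tandem copies all collapsed onto the single original locus.
Externally produced SAM is accepted through the same reader. What this
does *not* model: alignment ambiguity and mapping-quality artifacts,
indel or quality-structured sequencing errors, PCR duplicates, GC bias,
and repeat-induced mismapping. Passing tests therefore demonstrate the
logic of each stage under clean mapping semantics, not robustness to
aligner pathology on real genomes.

Determinism is a contract: a config plus seed reproduces every genome,
read, and truth table byte for byte, and the pipeline manifest records
the seed with each artifact so re-runs skip completed stages.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
closed) and SAM (1-based) are converted exactly once, at I/O. CIGARs are
restricted to M/S/I/D — the vocabulary the simulator emits and the
pipeline consumes — with anything else rejected loudly. k-mers containing
N are skipped; k < 8 is refused as degenerately unspecific. Breakpoint
ties go to higher clip support, then the leftmost coordinate; junction
consensus is per-column majority. A blunt insertion (equal breakpoints)
yields TSD length 0 and a null TSD. Divergence simulation refuses
expected substitution counts above L/2 (saturation), and zero-length or
gap-only alignments are errors rather than NaN ages. Empty read streams,
empty cohorts, and empty inventories all return well-formed empty
results or warnings as the contract specifies.

## Test problem sizes

The acceptance-style tests run parent calling on 1 Mb genomes with five
implanted retrocopies at 20x over 20 seeds (k = 30); insertion/TSD
accuracy on 300 kb genomes (100 events); attribution on 8-sample cohorts
over 20 seeds; copy-number recovery at N ∈ {1, 5, 15, 25, 35} over 10
seeds each; expression recovery at fractions {0.1, 0.5, 0.9} with 10,000
pairs; and the 18 MY clock round trip over 200 replicates. These sizes
make the whole suite run in minutes on one CPU while keeping every
threshold at its full-scale default.

## Known limitations

Only substitution errors and SNV diagnostics are modelled end to end;
indels are classified but neither masked nor simulated as sequencing
error. Multi-copy loci are resolved as a single insertion site by
construction, which matches tandem duplications but would under-report
genuinely dispersed copies. The depth-ratio copy-number estimator
assumes duplicate-free, evenly covered alignments. Dating uses raw
p-distance with no multiple-hit correction, which is adequate below a
few percent divergence but biased downward beyond that. Chimeric
transcripts spanning a retrocopy and its neighbouring gene are out of
scope.
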