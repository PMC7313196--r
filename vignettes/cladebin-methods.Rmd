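---
title: "Methods: binning, screening, relatedness and abundance in cladebin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binning, screening, relatedness and abundance in cladebin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind `cladebin`:
what each stage computes, why its defaults are what they are, and what the
synthetic-community tests do and do not demonstrate about real data.

## The scaffold feature space

Low-diversity holobiont metagenomes separate into genome clusters on a small
number of per-scaffold features, and the whole pipeline is organized around
that feature space.

**Percent GC** is `100 * (G + C) / (A + C + G + T)` with ambiguity
characters excluded from numerator and denominator.

**Nucleotide composition** is realized as canonical tetranucleotide
frequencies: counts over all overlapping 4-mers that contain no ambiguity
character, with each 4-mer pooled with its reverse complement. For k = 4
this yields 136 classes (16 self-complementary plus 120 pooled pairs),
normalized to sum to 1, so the profile of a scaffold equals the profile of
its reverse complement — assembly strand is arbitrary, and the statistic
must not depend on it. k is configurable; 4 is the standard choice in
composition-based binning, balancing resolution against the sampling noise
of the 136-dimensional estimate on 10 kb scaffolds.

**Fold-coverage** is total aligned bases over scaffold length, not read
count over length: aligned-base depth is read-length independent and equals
the mean of the per-base depth array for ungapped end-to-end placements
(this identity is enforced by an exact test against a brute-force per-base
oracle).

**Paired fraction** is the fraction of mapped records on a scaffold whose
mate also mapped in the same mapping run. By default "paired" is evaluated
run-wide (a mate on a different scaffold still counts as paired, matching
how bins of multiple scaffolds behave); a per-scaffold mode is available.
The screen below is stated per scaffold, so per-scaffold fractions are what
it consumes.

## The internal read mapper

Reads are mapped end-to-end (no clipping, no gaps) on both strands with
identity = matches / read length and a configurable identity floor. The
implementation is seed-and-verify: for a floor admitting `m` mismatches the
read is cut into `m + 1` segments, each matched exactly against the
scaffolds (pigeonhole: any valid placement has at least one exact segment),
and every candidate placement is then verified by direct mismatch counting.
At a 100 % floor this reduces to exact full-length substring matching and is
bit-reproducible, which is what the abundance stage uses. Ties are broken to
the lexicographically lowest `(scaffold, position)` and flagged ambiguous;
ambiguous reads are excluded from abundance estimates rather than split
fractionally. Keeping the mapper internal (rather than shelling out to an
aligner) keeps the pipeline dependency-free and its exact-identity mode
deterministic; SAM-derived alignment tables can be supplied instead through
the same tabular alignment interface.

The default profiling floor is 97 % (3 mismatches on a 100 bp read), a
tolerance comparable to a standard end-to-end short-read mapping; the
abundance recruitment floor is 100 %.

## Binning

Scaffolds are first partitioned by their taxonomy label (phylum/class
level, supplied as a pluggable table — any classifier's output fits).
Within a label group, scaffolds are density-clustered (DBSCAN-style,
hand-implemented since no density-clustering package is assumed; at
hundreds of scaffolds the O(n²) scan is trivial) on five axes: GC, log10
coverage, and the top three principal components of the TNF matrix.

Two numerical choices matter here:

* **Fixed axis scales, not z-scores.** Each axis is divided by a fixed
  physical scale — 5 GC points, 0.5 log10-coverage units, 0.05 TNF
  Euclidean units per unit distance. Standardizing by observed standard
  deviations would inflate uninformative axes: in a community whose genomes
  share one GC value, the GC axis is pure measurement noise, and z-scoring
  would blow that noise up to unit variance and drown the coverage
  separation that actually distinguishes the genomes. With fixed scales,
  `eps` (default 1.0) means "one tolerance" in the same units as the
  screening thresholds.
* **Labels are strong evidence.** Labeled scaffolds that fall out of
  density clustering as noise are attached to the nearest cluster sharing
  their label; unlabeled scaffolds (host DNA is typically unclassified)
  join a cluster only if within `eps` of its centroid, and are otherwise
  left unbinned. This is why host contaminant scaffolds — similar coverage
  but distinct dinucleotide structure — stay out of bacterial bins.

The published analyses this automates were done by manual inspection of
GC-coverage plots; an algorithm is fixed here because reproducibility
requires one, and the feature space is exactly the manual one.
`plot_scaffold_profiles()` draws it.

## Screening and refinement

Each bin is re-screened per scaffold, with rejection reasons recorded:

* paired fraction must be **strictly greater than 0.90** ("more than 90 %
  paired"); an undefined fraction (no mapped reads) rejects;
* |GC − bin median| ≤ 5 points;
* |log10 coverage − bin median| ≤ 0.5;
* TNF distance from the bin centroid ≤ 2 × the median within-bin distance;
* taxonomy label must not conflict with the bin majority.

The composition cutoff is a robust median multiple rather than an upper
quantile of the observed distances, for two reasons verified in the test
suite: on a small clean bin the empirical 99th percentile sits below the
in-bin maximum by construction, so a quantile rule rejects one scaffold
from every healthy bin; and when several contaminant scaffolds are present
they inflate the upper quantile and mask each other, while the median is
unaffected by a minority of outliers. In 136 dimensions the within-genome
distance distribution is tightly concentrated, so clean scaffolds sit well
below twice the median.

`refine_bins()` alternates screening with bin-statistic recomputation until
no scaffold is rejected or `max_rounds` is reached; the accepted set never
grows. Re-assembly between rounds is the user's step (any external
assembler), with `recruit_pairs()` preparing its input: every pair with at
least one mate mapped to the bin is emitted complete, the missing mate
rescued from the input files.

## Marker-based quality

Completeness is the percentage of expected single-copy families present at
least once in the bin; contamination is the percentage of extra copies
(`sum(max(0, copies - 1))` over families). This is deliberately a
*simplified* tally: lineage-specific marker sets and collocated-set
corrections are out of scope, and reports should be read accordingly. The
generator's default marker set is synthetic (100 families of 900 bp,
designated spans of each genome); any family list and annotation table can
be substituted.

## Relatedness and rank calls

AAI is the unweighted mean identity over reciprocal best hits: every
protein of each proteome is globally aligned (BLOSUM62, affine gaps open
11 / extend 1) against every protein of the other; a pair is kept when
mutually best by score and above 30 % identity and 70 % coverage of the
shorter protein (conventional floors — the service used in the original
analyses does not publish its criteria, so ours are recorded in output
metadata). Identity is matches over alignment columns excluding terminal
gaps. Fewer than 20 RBH pairs yields an undefined AAI with a warning:
orthologs that sparse do not support a stable mean. The implementation is
checked against an independent affine-gap dynamic-programming oracle with
traceback, and for monotone decrease along a planted 5→20→40 % divergence
ladder.

16S identity uses overlap alignment (terminal gaps free, internal gap
columns counted in the denominator) and is undefined below a 360 nt aligned
span — mirroring both the search cutoff used for environmental matching and
MAGs whose 16S is absent or too partial.

Rank calls take the highest rank whose AAI threshold is met (95 / 65 / 45 %
for species / genus / family, inclusive at the boundary); below the family
threshold a 16S identity at or above 86.5 % supports same-order, otherwise
the pair is novel above order level. With AAI undefined the 16S tiers
(97 / 94.5 / 86.5 %) are the sole evidence; with both undefined the call is
indeterminate. Because AAI and 16S evidence can genuinely disagree,
`identity_matrix()` reports the 16S-only call alongside the primary call
rather than resolving the conflict.

## Abundance estimation and reconciliation

Read recruitment assigns each unambiguously mapped read (at the exact
floor) to its bin's taxon group, normalizing either over classified reads
or over all reads (with an explicit unclassified fraction). Amplicon
estimation assigns each ASV to its best-identity reference 16S at ≥ 97 %
over the full ASV length, then normalizes per sample by total reads. The
two estimators are biased in opposite, known ways: amplicons over-report
taxa in proportion to 16S copy number (the generator plants multi-copy 16S
precisely to reproduce this ~copy-fold inflation), and read recruitment
under-represents small genomes in proportion to length. `compare_metrics()`
reports per-taxon differences and the Spearman rank correlation, with
optional flags for expected discordance sources.

Environmental 16S searching applies local alignment with +1/−2 scoring and
filters on alignment length (≥ 360 nt), e-value (≤ 1e−7, Karlin–Altschul
`E = K·m·n·e^(−λS)` with ungapped nucleotide constants λ = 1.28, K = 0.46,
recorded in output metadata) and an identity tier (97 / 95 / 90 % for
species / genus / distant relative). The filter semantics, not the exact
e-value constants, are the contract.

## The synthetic community

The generator emulates a low-diversity holobiont: one dominant
high-coverage genome, several lower-abundance genomes spanning a wide GC
range and roughly a 100-fold coverage range, host-like contaminant
scaffolds, planted multi-copy 16S genes, and paired-end reads with
substitution errors and a controllable singleton fraction.

Defaults define the reference conditions used throughout the tests: six
200 kb genomes at GC 0.30 / 0.40 / 0.47 / 0.52 / 0.58 / 0.62 and abundances
0.600 / 0.200 / 0.100 / 0.060 / 0.035 / 0.005; 20-fold summed coverage
(`depth_total` is the sum of per-genome expected coverages, so genome *i*
gets `depth_total × abundance_i` — coverage tracks relative abundance, the
premise of coverage-based binning); 2 × 100 bp reads with 300 ± 50 bp
inserts (typical short-insert library values; the original samples' insert
sizes are not published); substitution rate 0.002 and singleton fraction
0.02 (ordinary Illumina-scale values); two 16S copies per genome; 10 %
host-like scaffolds. `singleton_rate` is defined as the expected singleton
fraction among emitted reads (a pair loses one mate with probability
`2r/(1+r)`), which is the quantity the paired-fraction statistic estimates.

Genomes are i.i.d. nucleotides at their target GC, mutually non-homologous
outside planted loci; the host contaminant is a first-order Markov chain
with strong same-base runs, giving it the distinct dinucleotide structure
that real host DNA shows against bacterial scaffolds. 16S templates are
drawn per genome, copies within a genome at ≥ 99 % identity; marker loci
are designated spans (their annotation, not their sequence, is what the
tally consumes). Fragmentation is stick-breaking with a guaranteed minimum
scaffold length. All generators are seed-deterministic, and the pipeline
derives each stage's seed from the community seed by a fixed offset, so any
stage can be reproduced in isolation.

**What passing tests do not show.** The generator has no indels, no quality
decay, no strain microdiversity, no repeats (a toggle exists but defaults
off), no plasmids or viruses, and genome-free 16S divergence (random
templates rather than a conserved gene with variable regions). Binning
accuracy and abundance recovery on these communities demonstrate the
correctness of the statistics and the soundness of the thresholds — not
performance on real assemblies, where repeats, chimeric scaffolds and
conserved regions blur every axis of the feature space.

## Problem sizes and degenerate inputs

The shipped configurations run the full pipeline on ~1.3 Mb of community
sequence and ~40,000 reads in well under a minute per stage on one CPU, and
the abundance-recovery analyses use 100,000 reads; these desk-scale sizes
were chosen so that the entire analysis, including a byte-identical
replicate run, reproduces quickly anywhere. Degenerate inputs are handled
explicitly: zero mapped reads give coverage 0 and an undefined paired
fraction (which the screen rejects); an all-unlabeled community falls back
to pure density clustering with a warning; empty proteomes, empty bins,
reads longer than scaffolds, amplicon regions outside the 16S template, and
malformed FASTQ records all raise informative errors; bins emptied by
screening are dropped with a warning rather than silently vanishing.
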