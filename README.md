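# cladebin

Composition- and coverage-guided genome binning for low-diversity holobiont
metagenomes.

## The problem

Host-associated microbial communities of low diversity — a sponge, say, with
one dominant cyanobacterial symbiont and a handful of heterotrophic
companions — can be resolved into near-complete metagenome-assembled genomes
(MAGs) without reference databases, because each genome occupies a distinct
region of a simple feature space. `cladebin` implements that workflow as a
tested, reusable pipeline for R users working on microbiome and
metagenome-assembled-genome analysis:

1. **Scaffold profiling.** Every scaffold above a length floor (default
   10 kb) is summarized by percent GC, a reverse-complement-canonicalized
   tetranucleotide frequency vector (TNF, 136 components), fold-coverage
   (aligned bases / scaffold length) and the paired-read fraction — of the
   reads mapped to the scaffold, the fraction whose mate also mapped.
2. **Binning.** Scaffolds are grouped by a pluggable phylum/class taxonomy
   label, then density-clustered on (GC, log10 coverage, top-3 TNF principal
   components); unlabeled scaffolds (e.g. host DNA) join a cluster only if
   they sit within the clustering radius of its centroid.
3. **Screening.** Each bin is re-screened scaffold by scaffold: a scaffold
   must have **more than 90 %** paired reads and must not be a GC, coverage,
   composition or taxonomy outlier against its bin. Screening and
   recomputation alternate until stable.
4. **Read recruitment.** A bin recruits every read pair with at least one
   mate mapped to its scaffolds, rescuing the unmapped mate from the input
   files, so external re-assembly sees complete pairs.
5. **Quality tallies.** Completeness = % of single-copy marker families
   present; contamination = % of extra copies (a simplified tally — no
   lineage-specific sets, no collocation correction).
6. **Taxonomic rank calls.** Average amino acid identity (AAI: mean identity
   over reciprocal-best-hit protein pairs) and 16S rRNA identity are
   compared against threshold bands — AAI ≥ 95 / 65 / 45 % for
   species / genus / family, 16S ≥ 97 / 94.5 / 86.5 % for species / genus /
   order floor, inclusive at the boundary.
7. **Abundance reconciliation.** Community composition is estimated two
   ways — metagenomic read recruitment at an exact-identity floor, and 16S
   amplicon (ASV) matching at 97 % identity with per-sample normalization —
   and the two metrics are compared per taxon (multi-copy 16S inflates
   amplicon shares; genome size biases read shares).

A seeded **synthetic community generator** with complete ground truth
(genome of origin for every scaffold and read, true abundances, planted
marker and 16S loci) makes all of this testable without downloading
anything.

## Worked example

```r
library(cladebin)

cfg <- pipeline_config(community = community_config(seed = 1))
run <- run_pipeline(cfg, "cladebin_out")

tidy(run$state$bins_screened, qc = run$state$qc)
```

The default community holds six 200 kb genomes (GC 30–62 %, relative
abundances 0.5–60 %, 20-fold summed coverage, 2 × 100 bp paired reads)
plus ~10 % host-like contaminant scaffolds. The screened bin table printed
by the code above:

```
  bin_id total_length pct_gc n_scaffolds coverage_median            taxonomy completeness contamination
1  bin01       200000  47.04          10        11.72220       Cyanobacteria          100             0
2  bin02       200000  40.01          10         4.01932       Bacteroidetes          100             0
3  bin03       200000  58.20          10         1.93499 Alphaproteobacteria          100             0
4  bin04       200000  52.00          10         1.18918 Alphaproteobacteria          100             0
5  bin05       200000  61.96          10         0.67745 Gammaproteobacteria          100             0
6  bin06       186080  29.97           9         0.09738         Oligoflexia           92             0
```

All six genomes are recovered as uncontaminated bins at their true GC and
coverage; the host scaffolds stay unbinned. The rarest member (0.5 %
abundance, ~0.1× coverage) loses one scaffold — and the 8 marker families
on it — to the paired-fraction screen, which is exactly the conservative
behavior the screen is for at negligible read support.

```r
run$state$concordance
#   sample_id taxon_group         read_recruitment_classified amplicon difference
# 1 S1        Alphaproteobacteria                     0.161     0.155   -0.0056
# 2 S1        Bacteroidetes                           0.201     0.198   -0.0032
# 3 S1        Cyanobacteria                           0.599     0.604    0.0049
# 4 S1        Gammaproteobacteria                     0.0348    0.0383   0.0035
# 5 S1        Oligoflexia                             0.0050    0.0054   0.0004
attr(run$state$concordance, "rank_correlation")   # Spearman rho = 1
```

The two abundance estimators agree to within half a percentage point on
this copy-balanced community and rank the taxa identically.

Per-result plotting and tidying: `plot_scaffold_profiles()` draws the
GC-versus-coverage feature space; `autoplot()` works on bin sets,
abundance tables and relatedness matrices; `tidy()`/`glance()` work on bin
sets, recruitment results and relatedness matrices.

A thin CLI wraps the same functions:

```sh
exec/cladebin run --config config.yaml --outdir out/
```

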