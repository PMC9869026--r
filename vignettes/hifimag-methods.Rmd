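---
title: "Methods: genome recovery and community profiling from HiFi metagenomes"
author: "hifimag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome recovery and community profiling from HiFi metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifimag)
```

## Scope and model

`hifimag` re-creates, as a tested and reusable pipeline, the analysis path
by which complete microbial genomes are recovered from highly accurate
(HiFi) long-read metagenome assemblies and by which the underlying
community is profiled — both from genome coverage depth and directly from
full-length 16S rRNA genes carried by the reads.

The pipeline makes three structural assumptions, each of which mirrors how
HiFi metagenome assemblies behave in practice:

1. **Assembly graphs resolve into three topologies.**  A single segment
   whose two ends are joined by a same-orientation self-link is a complete
   circular replicon; a multi-segment connected component (typically a
   mixture of strains of one species) is a *tangled circle* that needs
   re-assembly; an isolated segment is an ordinary linear contig that goes
   to binning.  Classification operates purely on graph structure, never
   on sequence.
2. **Single-copy markers measure genome quality.**  Completeness is the
   fraction of a marker set present at least once
   (`Cp = 100 |present| / M`), contamination the per-marker surplus
   (`Ct = 100 Σ max(0, c_m − 1) / M`).  Ranks: near-complete
   (`Cp ≥ 90, Ct < 5`), high (`Cp ≥ 70, Ct < 10`), medium
   (`Cp ≥ 50, Ct < 10`), otherwise fail.  Redundant genomes are compared
   by the composite score `Cp − 5 Ct`.  Marker weighting is uniform: we
   deliberately do not model collocated lineage-specific marker sets, so
   absolute `Cp`/`Ct` values are a surrogate for (not a re-implementation
   of) lineage-workflow estimates.
3. **Species are an ANI decision.**  Two genomes belong to one species
   when their fragment-based average nucleotide identity is at least 95%
   with at least 50% aligned coverage *of both genomes*.  Genome-level
   novelty against a catalog uses the same 95% ANI rule; 16S-level novelty
   uses the classical 95% / 97% genus / species identity thresholds.

## The dereplication machinery

Candidate genomes are first grouped by MinHash: bottom-1000 sketches of
canonical 21-mers, hashed with a fixed-seed 64-bit mixer and masked to 53
bits (so hashes survive the round trip through R doubles), compared with
the Mash distance `d = −ln(2j/(1+j))/k` on the merged bottom sketch, and
single-linkage clustered at the permissive `d ≤ 0.05`.  Inside each
cluster, ANI is computed the JSpecies way: the query is cut into
consecutive 1020 bp fragments, each fragment is anchored to its best
seed diagonal in the reference (shared 21-mers, leftmost diagonal on
ties, both strands) and extended with a banded alignment (half-band
0.1 × fragment length, match +1 / mismatch −1 / gap −2).  Fragments with
at least 70% alignment coverage and 30% identity are retained; ANI is
their mean identity, coverage the retained fraction, and the pair's ANI
the mean of the two directions.  Representative selection is greedy by
descending score within each cluster: the best unassigned genome absorbs
everything it is same-species with, which makes the procedure
deterministic and idempotent (ties broken by higher `Cp`, then id).
Iterative compare-and-discard dereplication does not have a canonical
visit order; greedy-by-score is this package's declared choice and may
split borderline chains differently from other orderings.

## Read-level 16S profiling

Full-length 16S genes are detected on reads by conserved-region anchors:
eight 15-mers taken from the conserved blocks of the packaged 16S
template, matched with ≤1 mismatch on either strand.  A candidate needs
at least three anchors on one strand, in template order, with read
spacing within ±20% of template spacing; boundaries extend the outermost
anchors to the template ends.  This anchor detector is a declared
surrogate for covariance-model search: it is exercised only on synthetic
data where the anchors are guaranteed present, and nothing in the package
should be read as a claim that it matches covariance-model sensitivity on
real reads.

Detected genes pass the standard full-length filters — length within 1200–1700 bp and
Phred-implied mean accuracy ≥ 99% (Q20), where the mean error is computed
on the probability scale (`mean of 10^(−Q/10)`), not as a mean Q.  Genes
are classified by a naive-Bayes 8-mer classifier with per-genus word
priors `(n_w + 0.5)/(n + 1)` and 100 bootstrap trials, each scoring a
random 1/8 subsample of the gene's words; the reported confidence is the
trial agreement with the full-word maximum-likelihood genus, and calls
roll up to the deepest rank reaching confidence 0.8.  Bootstrap
subsamples that score all genera equally are counted as unclassifiable
trials rather than silently resolving to the first genus — without this,
random sequences would inherit spurious confidence from tie-breaking.
Profiles divide per-taxon gene counts by 16S copy numbers (genus-rank
table, default 2.0 for unlisted taxa), so abundances reflect cells rather
than gene copies.

## Depth-based composition

Reads are assigned to genomes by shared (17, 11) minimizers with an
absolute floor of 10 shared minimizers; the floor plays the role of the
mapped-identity filter of alignment-based depth scripts and is, again, a
declared surrogate for full alignment.  Mean depth is assigned interval
length over genome length; relative abundance at a rank is the depth
share of the rank's genomes.  Depth (not depth × length) is the abundance
weight; the base-fraction column is emitted alongside for readers who
prefer the other convention.

## The synthetic community and what it does (not) show

All tests run against a simulator whose defaults encode the intended
study conditions rather than being tuning knobs:

* 12 bacterial/archaeal taxa with log-normal abundance skew (σ = 1.5) and
  the dominant taxon pinned at 70% — the *Defluviitoga*-dominated profile
  of a mesophilic food-waste digester.  The dominant taxon carries a small
  plasmid and two 1%-diverged strain variants which the default graph
  renders as a tangled component; one archaeon carries a 0.5% variant that
  dereplication must absorb; a 35 kb virus-class circle exercises the
  small-replicon path.
* Chromosomes are 1.0–2.05 Mb.  These sizes are at the small end of the
  realistic range; they keep the default evaluation (depth multiplier 150,
  five seeds, roughly 0.3 Gb of reads per seed) comfortably desk-sized
  while leaving every per-genome statistic (markers, operons, tRNAs,
  depth) at realistic density.
* Reads follow a truncated-normal length model whose mean is calibrated
  numerically so the expected N50 is 14,254 bp (bounds 1–30 kb), and a
  two-point integer Phred distribution calibrated so the expected
  per-base error equals 1 − 0.9994, jittered ±2 per base.  Errors are
  substitution-only and drawn per base at the exact Phred-implied rate,
  which makes quality strings unbiased accuracy estimates *by
  construction* — deliberately so, because several filters (Q20, read QC)
  are Phred-arithmetic statements.  An indel-free error model is the one
  place the simulator is consciously cleaner than reality; HiFi indel
  rates are low but not zero, and none of the alignment components assume
  zero indels (the ANI aligner is banded, the anchors tolerate
  mismatches).
* rRNA operons are planted as ordered 16S–23S–5S cassettes within ≤ 10 kb
  on one strand, with per-genus 16S variants derived from a packaged
  synthetic template: eight conserved 20 bp blocks are held fixed while
  the variable remainder mutates at 10% per genus (≈ 15% pairwise
  inter-genus divergence).  All 16S genes in a genus are identical
  (1512 bp), so within-genus gene variation on reads comes only from
  sequencing error.  The packaged template, marker set and copy table are
  synthetic and labelled as such; no real database content ships with the
  package.

Passing tests therefore demonstrate internal correctness — truth
recovery under the stated noise model — not performance on real HiFi
data, where detection sensitivity, chimeras, inter-operon heterogeneity
and conserved-region divergence all matter.

## Numerical choices and degenerate inputs

* Circular coordinates are 0-based half-open and wrap at the replicon
  length; emitted files linearize at position 0.  Origin-spanning reads
  are simulated from a doubled sequence.
* Overlap trimming of circular contigs accepts only exact match-length
  CIGARs (`100M`); anything else raises rather than guessing.
* Palindromic self-links (`s + s −`) are *not* circularity; such
  components are classified tangled.
* Sketches shorter than the sketch size are legal (`|hashes| = `
  distinct k-mers); Mash distance is 0 at Jaccard 1 and capped at 1 when
  no hash is shared.
* A fragment pair with no retained fragments yields an ANI of `NA` with
  coverage 0 and can never satisfy the species rule.
* The operon colocation window (10 kb) is a default reflecting typical
  operon architecture, not a measured value, and is exposed as a
  parameter.
* Classifier word size 8, bootstrap fraction 1/8 and confidence floor
  0.8 follow the canonical naive-Bayes 16S classifier description; the
  identity denominator of `ssu_identity` is alignment columns over the
  shorter sequence with free end gaps, and gap penalties (open 4,
  extend 2) exceed the mismatch penalty so substitution-only divergence
  is never re-explained as gaps.

## Problem sizes used by the packaged evaluation

The test-suite and `scripts/acceptance.R` evaluate: triage on 55–60
labelled components; MinHash calibration on 50 pairs of 10 kb sequences
across divergences 0.2–10%; ANI recovery on 1 Mb pairs at 0.5/2/4%
substitution; dereplication of a 10-species × 3-variant panel (200 kb
genomes); and the full pipeline on the default community at depth
multiplier 150 (roughly 20,000 reads, ~400 filtered 16S genes per seed),
five seeds for the recovery criteria.  These sizes are the package's
evaluation design: large enough that binomial noise sits well inside the
stated tolerances (±3 percentage points per taxon on profiles, ±0.5 ANI
points), small enough to run on one CPU in minutes.

## Known limitations

* Re-assembly of tangled components is out of scope; the pipeline emits
  tangle members for an external assembler and otherwise drops them.
* Binning is represented by the pre-binning filter plus
  one-contig-per-candidate handling; no coverage/composition binning
  algorithm is included.
* The marker, anchor and copy-number reference sets are synthetic; on
  real data the user must supply real marker hits (the quality stage
  accepts precomputed hit tables), a real 16S reference set for the
  classifier, and a real copy-number table.
* `ssu_identity` is semi-global; published identity values computed with
  local (BLAST-style) alignment can differ near the thresholds.
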