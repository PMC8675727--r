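---
title: "Identifying miRNA target sites from AGO-qCLASH chimeric reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying miRNA target sites from AGO-qCLASH chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qclashr)
```

## The problem

In CLASH-family experiments (crosslinking, ligation and sequencing of
hybrids; qCLASH is the gel-free variant), an RNA ligase joins a miRNA to
the mRNA fragment it is base-paired with inside Argonaute, so a single
sequencing read — a *chimeric* or *hybrid* read — records both the miRNA
and the exact transcript coordinates it was bound to. Turning raw
paired-end reads into a table of replicate-supported miRNA target sites
requires a chain of standard but error-prone steps: adapter trimming,
read-pair merging, PCR-duplicate collapsing on UMI-bearing sequences, UMI
removal, resolution of each insert into a miRNA arm and a target arm,
folding of the intermolecular duplex, seed-binding classification,
assignment of target intervals to 5'UTR/CDS/3'UTR, interval clustering
across biological replicates, and statistical validation against
mimic/antagomir fold-change data. `qclashr` implements this chain as
composable functions plus a one-call `run_pipeline()`, together with a
synthetic-library generator that provides full ground truth for
benchmarking every stage.

## Library model and preprocessing

A sequenced molecule is `[UMI, 4 nt][insert][UMI, 4 nt][3' adapter]`,
where the insert is either a chimera (full miRNA ligated directly to a
20–50 nt target fragment, in either order) or a lone miRNA / mRNA
fragment. Preprocessing applies a fixed stage order:

1. **Adapter trimming** (`trim_adapter`): the best-scoring full or
   3'-terminal-prefix adapter occurrence (≥ 5 nt, mismatch fraction ≤ 0.1)
   and everything 3' of it is removed. Mate 2 is trimmed in
   reverse-complement space, where its adapter contamination is again a 3'
   occurrence.
2. **Merging** (`merge_pairs`): mate 2 is reverse-complemented and the
   longest suffix/prefix overlap (≥ 10 nt, mismatch fraction ≤ 0.1) is
   taken; disagreements resolve to the higher-quality base. Merge
   failures are dropped — the analysis uses merged reads only.
3. **Collapsing** (`collapse_duplicates`): exact-sequence deduplication
   *before* UMI removal, so two molecules with identical inserts but
   different UMIs stay distinct, while PCR duplicates (identical including
   UMIs) collapse into one record with a copy count.
4. **UMI trimming** (`trim_umi`): the first and last 4 nt are removed;
   reads whose remaining insert would be shorter than 16 nt are discarded
   and counted. Quality filtering is deliberately reduced to this
   minimum-length rule.

## Hybrid calling

`build_index()` stores every k-mer (default k = 12) of the miRNA and
transcript references; `detect_hybrid()` seeds candidate ungapped
alignments from k-mer hits and extends along each diagonal, keeping the
best segment with at most 2 mismatches (match +1, mismatch −2). A hybrid
call requires one miRNA-class arm and one transcript-class arm, each
≥ 16 nt, non-overlapping on the read with an inter-arm gap ≤ 4 nt
(tolerating short non-templated additions at the ligation junction).
Because a target arm can extend by chance a base or two across the
ligation junction, overlapping candidate arms are reconciled by trimming
the junction-facing end of whichever arm loses less score. Among feasible
pairs the summed score is maximized, with deterministic tie-breaking
(fewer mismatches, then lexicographic reference ids, then leftmost
coordinates). Arm extension is ungapped: the simulator emits substitution
errors only, and this is a documented simplification relative to
aligner-based callers. Reads matching only one reference class become
single-arm calls; miRNA-class single-arm calls feed `count_mirnas()`
(counts per million of the miRNA-class total).

## Duplex folding and seed classification

`fold_duplex()` aligns the miRNA (5'→3') against the reversed target
fragment by dynamic programming with additive pair scores: Watson–Crick
+2, G:U wobble +1, opposed-but-unpaired −1, internal gap −2. Dangling
ends are free, as in dedicated duplex-folding tools: bases outside the
aligned block are not penalized. This choice matters — if end gaps are
charged, the optimal alignment of a short miRNA against a longer random
fragment tends to weave across the fragment collecting isolated chance
pairs, and a genuine contiguous seed helix frequently loses to such
weaves. With free ends the best single block wins, which is the behavior
a thermodynamic folder approximates. Among score-optimal alignments the
one with more base pairs is reported (encoded in the DP value), with
traceback preferring pairings toward the miRNA 5' end. The simplified
additive model replaces nearest-neighbor thermodynamics deliberately:
seed classification depends only on pairing topology, which it preserves.

`classify_seed()` applies the canonical definition: `seed_m2_8` when
miRNA nucleotides 2–8 are all Watson–Crick paired to consecutive target
positions, `seed_m2_7` when 2–7 are, otherwise `non_seed` (wobbles and
bulged seeds are non-canonical).

## Region assignment and clustering

`assign_region()` labels a target interval by the region containing its
midpoint (`floor((start + end)/2)`), with midpoints exactly on a CDS
boundary assigned downstream (cds at `cds_start`, utr3 at `cds_end`).
The midpoint rule was chosen over start-position or overlap-majority
labeling because it gives a single deterministic label per site and
agrees with per-nucleotide majority voting whenever a strict majority
exists. Sites on transcripts absent from the annotation are
`unannotated` and excluded from proportions.

`merge_sites()` performs single-linkage merging of target intervals per
(miRNA, transcript) group across replicates: intervals overlapping by
≥ 1 nt merge transitively into their union span; replicate support is
the union of replicate ids and peak reads the sum of copy counts.
Single-linkage with 1-nt overlap is the simplest transitive rule; the
overlap threshold is exposed. `select_high_confidence()` filters by
replicate support (e.g. ≥ 2 of 5), and `sites_to_genes()` collapses to
gene level by maximum replicate support, the accounting used for
gene-level target tables. Both site- and gene-level outputs are kept,
since "recurrence across replicates" can reasonably mean either
coordinate overlap or same-gene identity.

## Validation statistics

`ks_two_sample()` computes the two-sample Kolmogorov–Smirnov statistic
exactly and its p-value by exhaustive enumeration of all
`choose(n1+n2, n1)` group assignments when `n1 + n2 <= 12`, otherwise
from the asymptotic Kolmogorov series with the standard two-term
small-sample correction of the effective size `n1*n2/(n1+n2)`.

`cdf_compare()` builds the empirical CDF of log2 fold changes for each
named target set and tests it against the background. By default the
background *excludes* the tested set: testing a subset against a pool
that contains it shrinks the statistic by a factor `(1 − n_set/n_pool)`
and makes the test conservative, so the disjoint comparison is the
calibrated one (type-I error at the nominal level, verified by
simulation in the test suite). Comparison against the full table is
available by flag for strict reproduction of figure-style curves. Fold
changes are compared on the log2 scale, chosen for symmetry of up- and
down-regulation; correlations of count data are computed on
`log10(x + 1)`, the pseudocount being needed for zero counts on
logarithmic axes. `ddct_fold_change()` implements comparative-Ct
(2^−ΔΔCt) quantification for qPCR validation, and `rank_shift()`
reports rank changes of the top miRNAs between two conditions.

## The synthetic-data generator

`sim_params()` fixes the study conditions; the defaults describe the
experiment the pipeline is designed for and are not tuned per run:

* 200 transcripts of 600–2000 nt, each with an interior CDS (5'UTR
  ≥ 60 nt, 3'UTR ≥ 100 nt), and 60 miRNAs of 18–23 nt;
* log-normal miRNA abundance (sdlog 1.5), heavy-tailed so that a single
  miRNA can dominate a library the way a TSS-miRNA dominates a
  Drosha-knockout line;
* 10,000 molecules per library, half of them chimeras
  (`hybrid_fraction = 0.5`), 90% in miRNA-first ligation order;
* target-fragment midpoints drawn over (5'UTR, CDS, 3'UTR) with weights
  (0.05, 0.45, 0.50), matching the observed concentration of sites in
  CDS and 3'UTR; fragment length uniform 20–50 nt (RNase footprints are
  short; the true insert-length distribution is not published, so this
  is a stand-in);
* 35% of chimeras drawn from implanted canonical sites
  (`seed_site_fraction = 0.35`, below one half — non-canonical binding
  should dominate). Implanted sites complement miRNA nucleotides 2–13,
  a canonical seed plus 3'-supplementary pairing, implanted into the
  transcript sequence itself (one per miRNA per region) so implanted
  chimeras are also mappable; under the additive duplex scores a bare
  7-mer helix is not reliably optimal against a random 20–50 nt
  fragment, whereas the extended helix is;
* 4-nt degenerate UMIs per end, the standard small-RNA 3' adapter
  (configurable — the study-specific adapter belongs in the run
  configuration), geometric PCR copy number with mean 1.8, per-base
  substitution rate 0.005 applied once per molecule (so PCR duplicates
  remain byte-identical; indels and per-cycle quality models are out of
  scope), and 110-nt mates that read through the short insert into the
  adapter on both sides, as real paired-end runs on small-RNA-sized
  inserts do.

Ground truth records every molecule's identity, coordinates, ligation
order, PCR copy number, implantation flag and final insert sequence,
which lets the test suite measure recall, precision, order recovery,
region proportions and seed recovery exactly.

What the generator does *not* emulate: realistic (non-uniform) base
composition and repeat structure of real transcriptomes, isomiR
trimming/tailing, crosslink-induced deletions, ligation sequence biases
and per-cycle error profiles. Passing tests therefore demonstrate the
correctness of the algorithms under the stated generative model, not
performance on real libraries.

## Numerical and design choices

* Determinism: every stochastic component takes an explicit seed;
  identical parameters give byte-identical outputs, and all ordering
  rules (collapse order, tie-breaks in arm pairing, site sort order) are
  total.
* Coordinates are 0-based half-open internally; files are written
  1-based inclusive, converted only at the I/O boundary.
* U and T are equivalent everywhere; miRNAs are written as RNA, internal
  comparisons use the DNA alphabet.
* Degenerate inputs fail loudly (empty adapter, zero-variance
  correlation, empty annotated set) or produce explicit signals
  (merge-failure, discard counts, `unannotated`), never silent zeros;
  a percentage over a zero denominator is reported as undefined.
* Problem sizes in the test suite (libraries of 1,200–10,000 molecules,
  1,000-seed calibration loops, oracle enumerations at n ≤ 12 or
  lengths ≤ 8) were chosen so the whole suite completes in a few
  minutes on one CPU while keeping every statistical check at usable
  power.

## Known limitations

Ungapped arm alignment cannot recover hybrids with indels; antisense,
miRNA–miRNA and mRNA–mRNA chimeras are counted but not analyzed;
genomic (spliced) mapping and isoform-aware annotation are out of scope
(one annotated transcript per id); the duplex model is topological, not
thermodynamic, so its scores are not energies; and KS p-values for
moderately small samples use the corrected asymptotic series rather
than the exact distribution.
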