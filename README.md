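# qclashr

Identification of miRNA target sites from AGO-qCLASH chimeric sequencing
reads.

In CLASH-family experiments, an RNA ligase joins a miRNA to the mRNA
fragment it is base-paired with inside Argonaute (AGO), so that a single
sequencing read — a chimeric "hybrid" read — records both the miRNA and
the exact transcript interval it was bound to. `qclashr` turns raw
paired-end FASTQ libraries into replicate-supported target-site tables
and validates them against mimic/antagomir fold-change data:

* **preprocess** — 3' adapter trimming, read-pair merging,
  PCR-duplicate collapsing on UMI-bearing sequences, UMI removal;
* **hybcall** — k-mer-seeded ungapped resolution of each insert into a
  miRNA arm and a target arm, intermolecular duplex folding by dynamic
  programming (Watson–Crick +2, G:U +1, mismatch −1, gap −2, free
  dangling ends) and canonical seed classification (`seed_m2_8` when
  miRNA nucleotides 2–8 pair Watson–Crick to consecutive target
  positions, `seed_m2_7` for 2–7, else `non_seed`);
* **annotate** — 5'UTR / CDS / 3'UTR assignment of target intervals by
  the midpoint rule;
* **cluster** — single-linkage merging of target intervals within and
  across biological replicates; high-confidence filtering by replicate
  support; per-library summary tables;
* **stats** — per-miRNA normalized counts (CPM), log-scale Pearson
  correlations, empirical CDFs with two-sample Kolmogorov–Smirnov tests
  of target-set repression (exact enumeration for n1+n2 ≤ 12, corrected
  asymptotic series otherwise), comparative-Ct (2^−ΔΔCt) fold changes;
* **synthref** — a synthetic-library generator (references with
  implanted target sites, chimeric reads with UMIs, PCR duplicates and
  substitution errors, fold-change tables) with complete ground truth.

## Worked example

```r
library(qclashr)

run <- run_pipeline(qclash_config(
  output_dir = "demo_run",
  sim = sim_params(n_transcripts = 50, n_mirnas = 20, n_reads = 2000,
                   error_rate = 0, rng_seed = 320),
  n_replicates = 3, min_replicates = 2
))
print(run)
#> qCLASH run: 3 replicates, 3010 hybrid calls, 1678 merged sites (195 high-confidence)
#> focus miRNA: mir-015; outputs in demo_run

summary(run)
#> Library summary (focus miRNA: mir-015 )
#>  replicate group total_hybrids focus_hybrids percent
#>        BR1   all          1810           442   24.42
#>        BR2   all          1727           425   24.61
#>        BR3   all          1822           462   25.36
#>      total   all          5359          1329   24.80
#>
#> Target-site regions:
#>  region proportion
#>    utr5 0.04478447
#>     cds 0.44728494
#>    utr3 0.50793058
#>
#> Seed-binding classes:
#>  seed_class  proportion
#>    non_seed 0.645456242
#>   seed_m2_7 0.002612428
#>   seed_m2_8 0.351931330
```

One highly abundant miRNA (heavy-tailed abundance emulating a
TSS-miRNA-dominated line) carries ~25% of all hybrids; target sites
concentrate in the CDS and 3'UTR; roughly a third of duplexes show
canonical seed binding, the rest are non-canonical — the structure the
pipeline is designed to quantify. Per-stage TSVs (hyb-style call tables,
viennad-style duplex folds, site/gene target tables, summary tables) and
a JSON run manifest with per-stage read accounting are written to
`demo_run/`.

Individual stages are ordinary functions (`trim_adapter()`,
`merge_pairs()`, `collapse_duplicates()`, `trim_umi()`,
`build_index()`, `detect_hybrid()`, `fold_duplex()`, `classify_seed()`,
`assign_region()`, `merge_sites()`, `select_high_confidence()`,
`summarize_hybrids()`, `ks_two_sample()`, `cdf_compare()`, ...) and a
command-line driver with per-stage subcommands is installed at
`inst/scripts/qclash.R`.

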