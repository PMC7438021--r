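# hgcscan

Genome-resolved screening for putative mercury-methylating
microorganisms.

Methylmercury, the bioaccumulative neurotoxin behind most fish-consumption
advisories, is produced by anaerobic bacteria and archaea carrying the
*hgcAB* gene pair: *hgcA* (a corrinoid-dependent putative
methyltransferase) and *hgcB* (a 2[4Fe-4S] ferredoxin). Because
methylation capability is a strain-level trait that neither 16S rRNA
profiles nor broad-range PCR primers predict reliably, the field screens
genome collections — isolates and metagenome-assembled genomes (MAGs) —
directly for the locus. hgcscan is that screen as an R package, for
microbial ecologists working from Prokka/Prodigal annotations and
hmmer-style profile-search hit tables.

## What it computes

A genome is called a **putative methylator** when an ORF passes the hgcA
profile-search thresholds (full-sequence E ≤ 1e−50 **and** bit score
≥ 300) and its protein contains the conserved cap-helix domain
`G(I/V)NVWCAAGK`. The call is **hgcB-confident** when a second ORF with
bit score > 70 and the ferredoxin-binding motif `CXXCXXXC` lies on the
same contig within five ORF ranks downstream of hgcA
(strand-relative; intervening genes allowed). An ArsR-like regulator is
reported when a hit at E ≤ 1e−10 sits one to three ORF ranks upstream.

Around the core caller:

- **In-silico PCR** — mismatch-tolerant scanning of IUPAC-degenerate
  primer pairs over both template orientations, with per-phylum
  amplification crosstabs and on-target flags against called hgcA loci.
- **Guild profiling** — genome × metabolic-marker presence/absence from
  threshold-filtered hits, summarized as group percentages (quality
  cutoffs > 90% completeness / < 10% redundancy, groups of > 5 genomes,
  multi-subunit complexes averaged across subunits).
- **Supermatrix preparation** — the 12-of-16 ribosomal-marker
  completeness rule, per-marker alignment concatenation with gap fill,
  gap-fraction/block column masking, and partition-file export.
- **Expression** — TPM normalization of ORF-level metatranscriptome
  counts (per sample: TPM_i = 1e6 · (c_i/ℓ_i) / Σ_j (c_j/ℓ_j)), per-phylum
  marker totals with per-sample grand totals, per-phylum genome-average
  expression, and hgcA-vs-rpoB housekeeping pairs.
- **Synthetic data** — a seeded generator of genome collections with
  planted hgcA/hgcB/regulator loci, decoy classes that each violate
  exactly one rule, primer constructs with controlled mismatches, and
  phylum/depth-structured negative-binomial counts, so the entire
  pipeline is testable against exact ground truth.

## A worked example

```r
library(hgcscan)
dir <- file.path(tempdir(), "demo")
cfg <- pipeline_config(dir, seed = 7, min_completeness = 0)
sim <- run_simulate(cfg)   # 50 genomes: 10 true methylators + 40 decoys
res <- run_identify(cfg)
#> 30 methylator call(s) across 5 group(s); 20 hgcA candidate(s) removed by filters

head(res$calls[, c("genome_id", "hgcA_orf", "hgcB_orf", "hgcB_distance",
                   "regulator_orf")])
#>   genome_id    hgcA_orf    hgcB_orf hgcB_distance regulator_orf
#> 1      G001 G001_c1_o08 G001_c1_o04             4   G001_c1_o10
#> 2      G002 G002_c1_o09 G002_c1_o04             5   G002_c1_o11
#> 3      G003 G003_c1_o05 G003_c1_o06             1   G003_c1_o02
#> 4      G004 G004_c1_o08 G004_c1_o07             1   G004_c1_o11
#> 5      G005 G005_c1_o09 G005_c1_o04             5   G005_c1_o11
#> 6      G006 G006_c1_o05 G006_c1_o06             1   G006_c1_o02
```

Thirty genomes carry a validated hgcA: the 10 planted true methylators
plus the 20 synteny decoys whose hgcA is genuine but whose hgcB sits on
the wrong contig or six ORFs away — those calls correctly carry
`hgcB_orf = NA`. The 20 removed candidates (broken cap-helix,
sub-threshold scores) are listed in `filter_log.tsv` with the rule that
removed each. Downstream, expression aggregation recovers the planted
10-fold phylum structure:

```r
ex <- run_express(cfg)
round(ex$hgcA_by_group$group_tpm[, c("bog_deep", "fen_deep")], 1)
#>                 bog_deep fen_deep
#> Acidobacteria        2.2      4.0
#> Chloroflexi         17.3     14.8
#> Firmicutes         103.8    159.2
#> Nitrospirae       1470.5   1512.6
#> Verrucomicrobia  13415.3  11647.7
```

Rows are phylum-level sums of TPM over called hgcA ORFs; the planted
multipliers (1×, 10×, … 10,000×) are visible directly. Palsa samples are
all-zero by construction, mirroring sites where no methylator
transcripts are detectable.

Real data enters through the same interfaces: `read_collection()` for
FASTA + GFF3 + a metadata table, `parse_hit_table()` for hmmer
`--tblout` files, `read_counts()` for ORF-level count matrices, and a
YAML `pipeline_config()` for the `run_*` stages (also exposed as a thin
CLI in `inst/scripts/hgcscan.R`).

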