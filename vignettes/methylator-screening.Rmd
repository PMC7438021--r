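---
title: "Genome-resolved screening for putative mercury methylators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved screening for putative mercury methylators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgcscan)
```

## The screening problem

Methylmercury is produced by anaerobic microorganisms carrying the
*hgcAB* gene pair: *hgcA* encodes a corrinoid-dependent putative
methyltransferase and *hgcB* a small 2[4Fe-4S] ferredoxin thought to act
as its electron donor. Neither 16S rRNA phylogeny nor broad-range PCR
primers predict methylation capability reliably, so surveys of
methylation potential increasingly screen genome collections — isolate
genomes and metagenome-assembled genomes (MAGs) — directly for the locus.
hgcscan implements that screen as a reusable, testable pipeline. Gene
calling, profile-HMM search, sequence alignment and tree inference remain
external (Prodigal/Prokka, hmmer, MAFFT/MUSCLE, RAxML/FastTree); the
package owns everything between their outputs: hit filtering, motif and
synteny validation, in-silico PCR, guild profiling, supermatrix
bookkeeping and expression aggregation.

## The calling model

A genome is called a putative methylator when it carries an ORF that

1. passes the hgcA profile-search thresholds — full-sequence E-value
   $\le 10^{-50}$ **and** bit score $\ge 300$ (both inclusive), and
2. contains the conserved cap-helix domain `G(I/V)NVWCAAGK` in its
   protein sequence.

The two-step design reflects how profile searches behave in practice:
score thresholds alone admit corrinoid-protein relatives, and the
cap-helix motif is the discriminating feature of genuine HgcA. Each
validated hgcA ORF yields one call; a genome with several validated ORFs
yields several calls, since multiplicity is biologically possible and
collapsing it would hide evidence.

A call is *hgcB-confident* when a second ORF passes the hgcB screen:
bit score strictly greater than 70 (the threshold is exclusive by
design), the ferredoxin-binding motif `CXXCXXXC`, located on the **same
contig** within **five ORF ranks downstream** of hgcA in hgcA's
transcriptional direction. Intervening genes are allowed — experimentally
verified methylators such as *Desulfovibrio africanus* carry genes
between *hgcA* and *hgcB* — which is why the rule is a rank window rather
than strict adjacency. Downstream-ness is strand-relative: for a
minus-strand hgcA, downstream means decreasing ORF rank. We do not
require hgcB to lie on the same strand as hgcA (the evidence for
cotranscription is suggestive but not universal); `require_same_strand`
exposes the stricter rule.

An ArsR-like transcriptional regulator is additionally reported when a
hit at E-value $\le 10^{-10}$ lies one to three ORF ranks upstream of
hgcA. "One to three" is our reading of "immediately upstream or 1 to 2
genes upstream": rank 1 is adjacency, ranks 2–3 allow one or two
intervening genes. The narrower window is available via
`regulator_max_distance = 2`.

Two deliberate limitations: fused hgcAB-like ORFs are not specially
detected (the same-contig/downstream criteria will simply leave such
genomes without separate hgcB evidence), and hgcB on a different contig
is never accepted even though it may reflect assembly fragmentation
rather than true absence. Both choices prefer false negatives over false
positives, which is the right asymmetry for a screen whose calls seed
downstream phylogenetic and ecological claims.

## Distances, ties, and degenerate inputs

ORF rank on a contig is the rank of the start coordinate (1-based GFF3
coordinates), ties broken by end coordinate then ORF id, so ordering is
deterministic even for pathological annotations. Annotation order is
ignored: coordinate rank is reproducible across re-sorted GFF files.
When several hgcB or regulator candidates qualify, the nearest wins;
equal distances break by higher bit score, then lexicographic ORF id.
Ambiguity characters other than N in contig sequences are squashed to N
with a warning. Missing protein translations are derived from the contig
with the bacterial/archaeal genetic code (translation table 11), the
Prodigal/Prokka default, trimming the terminal stop.

## In-silico PCR

Primer pairs are IUPAC-degenerate strings scanned over both template
orientations. A hit is any forward-primer placement paired with a
downstream placement of the reverse primer's reverse complement on the
same strand, with **per-primer** mismatch counts at or below the setting
(0 and 2 being the conventional settings) and product span at most
`max_product` (default 10,000 bp — qPCR amplicons are far shorter, but
no cap is inherent to the method). Reported coordinates are always on
the plus strand. Design choices worth knowing:

- Template N matches only primer N. An assembly gap should not amplify.
- All overlapping/nested products are reported; no "shortest product"
  collapsing.
- No 3'-anchoring by default: the mismatch allowance is a global count.
  `anchor_3prime = TRUE` requires an exact 3'-terminal match, as many
  PCR simulators do.
- Mismatch semantics are per primer, not summed over the pair.

The amplification crosstab joins hits to genome taxonomy and to called
hgcA ORFs: a genome is *on-target* at a setting when some amplicon
overlaps a called hgcA ORF by coordinates, which is how primer
specificity claims ("Deltaproteobacteria-specific primers also picked up
Actinobacteria sequences") become checkable numbers.

## Guild profiling

Metabolic-marker hits are reduced to a genome × marker presence matrix
(a cell is true iff at least one hit passes that marker's threshold —
a curated bit-score cutoff when the marker config provides one, else
E-value $\le 10^{-10}$). Group summaries retain high-quality genomes
(completeness > 90%, redundancy < 10%, both strict) in groups of
strictly more than 5 genomes. Groups are phyla, except that
Deltaproteobacteria is conventionally treated as a group at class rank
(`class_groups` generalizes this). Multi-subunit complexes
(*nif*, *nar*, *nir*, *nor*, *nos*) are summarized by computing each
subunit's group percentage and averaging those percentages — the
legend-stated order of operations; since group membership is fixed
within a summary, averaging per-genome booleans first would give the
same number, but the per-subunit-percentage form is what is implemented.

## Supermatrix preparation

Genomes enter the concatenated ribosomal-protein tree only with at least
12 of the 16 markers. The shipped rp16 list (L2, L3, L4, L5, L6, L14,
L15, L16, L18, L22, L24, S3, S8, S10, S17, S19) is a conventional
choice, configurable everywhere, and should not be treated as canonical.
Concatenation gap-fills genomes missing a marker and records a partition
table. Column masking is a deliberately simple, documented stand-in for
entropy-based trimmers such as BMGE: drop columns whose gap fraction
exceeds 0.5, then drop surviving blocks shorter than 5 columns —
mirroring the conventional 0.5 gap-rate / block-size-5 settings. It does
not reproduce BMGE's BLOSUM-based entropy scores; externally trimmed
alignments can be supplied wherever a supermatrix is accepted, which is
the route to reproducing a published matrix exactly.

## Expression aggregation

ORF-level metatranscriptome counts are normalized to transcripts per
million per sample: $\mathrm{TPM}_i = 10^6 (c_i/\ell_i) / \sum_j
(c_j/\ell_j)$ with annotated ORF length $\ell_i$ in bp (no effective
length correction — quantification upstream is pseudo-alignment on full
ORFs). One normalization runs per sample across the union of all
genomes' ORFs, the natural reading when all genomes are indexed
together. Samples in which nothing was detected (the palsa situation)
yield all-zero columns rather than errors. Aggregations: per-group
summed marker TPM with a per-sample grand total; per-group
genome-average expression (group total divided by group genome count,
so unexpressed member genomes dilute the average, as they should); and
per-genome hgcA-vs-rpoB pairs using each genome's best-scoring rpoB,
with genomes lacking rpoB flagged and excluded from pairs. Zero hgcA
with nonzero rpoB is a retained, meaningful pair: transcriptionally
active but not detectably methylating.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the standing test bed: 50 genomes over 5
phyla — 10 true methylators plus 10 of each decoy class the rules must
reject for a distinct reason (cap-helix broken; hgcB on another contig;
hgcB six ranks away; sub-threshold scores) — with 2 contigs × 12 ORFs
per genome, completeness 80–100% and redundancy 0–9%, planted regulator
offsets 1–3, hgcB offsets 1–5, primer constructs with 0–2 planted
mismatches per primer, and expression with 10-fold multipliers between
consecutive phyla under negative-binomial noise (dispersion 0.5, the
overdispersion regime typical of metatranscriptome counts) across a
palsa/bog/fen × shallow/deep grid with palsa forced to zero. Background
proteins are uniform-random residues with both conserved motifs rejected
at generation, so planted truth is exact; ORF nucleotide sequences are
random synonymous back-translations, so translation round-trips hold.
All randomness flows from one integer seed and regeneration is
byte-identical.

What it does **not** emulate: real amino-acid composition and
phylogenetic correlation (a profile search on real data faces much
harder negatives than uniform-random background), codon bias, assembly
chimerism, shared-contig multi-genome artifacts, or read-level noise in
quantification. Passing tests therefore demonstrate that the *rules* are
implemented exactly as specified and recover planted truth perfectly
under clean conditions — they say nothing about the sensitivity of the
upstream profile HMMs on real genomes, which is where the hard
biological error modes live.

## Problem sizes and numerical tolerances

The shipped tests run the end-to-end screen at 50 genomes × 20 seeds,
compare the amplicon scanner against an independent exhaustive oracle on
500 random contigs up to 5 kb at mismatch settings 0–2, check motif
matching against two independent oracles on 10,000 random proteins, and
verify TPM mass conservation (column sums within $10^{-6}$ relative,
group totals within $10^{-9}$ relative) on 100 random matrices — sizes
chosen so the whole suite runs in a couple of minutes on one CPU while
still exercising every boundary. Exact-boundary hits (E $= 10^{-50}$,
score $= 300$, score $= 70$, E $= 10^{-10}$) are asserted explicitly
since the inclusive/exclusive decisions are exactly where
implementations drift.

## A worked example

```{r example}
dir <- file.path(tempdir(), "demo")
cfg <- pipeline_config(dir, seed = 7, min_completeness = 0)
sim <- run_simulate(cfg)
res <- run_identify(cfg)
head(res$calls[, c("genome_id", "hgcA_orf", "hgcB_orf", "hgcB_distance",
                   "regulator_orf")])
table(confident_hgcB = !is.na(res$calls$hgcB_orf))
```

Thirty genomes carry a validated hgcA (true methylators plus the two
synteny-decoy classes, whose hgcA is genuine); only the ten planted true
methylators acquire hgcB evidence, and their offsets match the truth
table exactly:

```{r check}
truth <- sim$truth
merged <- merge(res$calls, truth, by = "genome_id")
all(merged$hgcB_distance == merged$hgcB_offset, na.rm = TRUE)
```

## Known limitations

- The screen's sensitivity is bounded by the external profile HMMs; the
  package validates and localizes hits, it cannot rescue a marker the
  search never reported.
- Same-contig and downstream-window rules are conservative on fragmented
  MAGs; genomes with *hgcB* on a short separate contig lose hgcB
  confidence by design.
- The column mask is not BMGE; matrices intended for publication-grade
  trees should be trimmed externally and re-imported.
- Quality metrics (completeness/redundancy) are inputs; the package does
  not recompute them.
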