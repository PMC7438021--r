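Package: hgcscan
Title: Genome-Resolved Screening for Putative Mercury-Methylating Microorganisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative mercury-methylating bacteria and archaea in
    genome collections (isolate genomes and metagenome-assembled genomes) by
    filtering profile-HMM search hits for the hgcA marker, validating the
    conserved cap-helix domain, and applying synteny rules for a paired hgcB
    ferredoxin and an upstream ArsR-like regulator. Also provides in-silico
    PCR with IUPAC-degenerate primers, guild-level metabolic-marker
    presence/absence profiling, concatenated ribosomal-protein supermatrix
    preparation with column masking, TPM normalization and phylum-level
    aggregation of metatranscriptome counts, and a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
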