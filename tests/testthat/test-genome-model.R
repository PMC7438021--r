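test_that("read_fasta handles wrapped records, uppercasing and errors", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">c1", "ac", "GT", ">c2", "NNN"), f)
  seqs <- read_fasta(f)
  expect_equal(seqs, c(c1 = "ACGT", c2 = "NNN"))

  writeLines(c(">c1", "ACGT", ">c1", "AAAA"), f)
  expect_error(read_fasta(f), "duplicate.*c1")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "no records")
})

test_that("read_genome orders ORFs by start and ranks per contig", {
  d <- withr::local_tempdir()
  orfs <- data.frame(
    orf_id = c("b", "a", "c", "e", "d"),
    contig_id = c("c1", "c1", "c1", "c2", "c2"),
    start = c(400L, 1L, 700L, 60L, 10L),
    end = c(900L, 300L, 780L, 90L, 40L),
    strand = c("-", "+", "+", "+", "-"),
    protein = c("MKL", "MVV", "MAA", "MCC", "MDD"))
  g <- genome_record("G1", c(c1 = rand_dna(1000), c2 = rand_dna(100)), orfs,
                     "d__Bacteria;p__Testia", 80, 3)
  write_genome(g, d)
  g2 <- read_genome(file.path(d, "G1.fna"), file.path(d, "G1.gff"),
                    list(genome_id = "G1", taxonomy = "d__Bacteria;p__Testia",
                         completeness = 80, redundancy = 3))
  expect_equal(g2$orfs$orf_id, c("a", "b", "c", "d", "e"))
  expect_equal(g2$orfs$index_on_contig, c(1L, 2L, 3L, 1L, 2L))
  expect_equal(g2$orfs$nt_length, g2$orfs$end - g2$orfs$start + 1L)
})

test_that("CDS outside contig bounds or on unknown contigs error", {
  contig <- c(c1 = rand_dna(1000))
  bad_bounds <- data.frame(orf_id = "x", contig_id = "c1", start = 900L,
                           end = 1200L, strand = "+", protein = "M")
  expect_error(genome_record("G1", contig, bad_bounds), "outside contig bounds")
  bad_contig <- data.frame(orf_id = "x", contig_id = "c9", start = 1L,
                           end = 30L, strand = "+", protein = "M")
  expect_error(genome_record("G1", contig, bad_contig), "unknown contig")
})

test_that("missing translations fall back to genetic code 11 from the contig", {
  # MKW on the minus strand: revcomp(ATGAAATGGTAA)
  nt <- "ATGAAATGGTAA"
  contig <- c(c1 = paste0("GGGG", oracle_revcomp(nt), "GGGG"))
  d <- withr::local_tempdir()
  writeLines(c(">c1", contig), file.path(d, "g.fna"))
  writeLines(c("##gff-version 3",
               paste("c1", "test", "CDS", "5", "16", ".", "-", "0", "ID=o1",
                     sep = "\t")),
             file.path(d, "g.gff"))
  g <- read_genome(file.path(d, "g.fna"), file.path(d, "g.gff"),
                   list(genome_id = "G1", taxonomy = NA,
                        completeness = 90, redundancy = 1))
  expect_equal(g$orfs$protein, "MKW")
})

test_that("FASTA+GFF round trip preserves coordinates, strands and ranks", {
  set.seed(42)
  d <- withr::local_tempdir()
  sim <- generate_collection(sim_config(n_true = 2, n_decoy_no_motif = 0,
                                        n_decoy_off_contig = 0,
                                        n_decoy_distance6 = 0,
                                        n_decoy_low_score = 0),
                             seed = 11, dir = d)
  back <- read_collection(d)
  for (id in names(sim$collection)) {
    a <- sim$collection[[id]]$orfs
    b <- back[[id]]$orfs
    expect_equal(b[c("orf_id", "contig_id", "start", "end", "strand",
                     "index_on_contig", "protein")],
                 a[c("orf_id", "contig_id", "start", "end", "strand",
                     "index_on_contig", "protein")])
    expect_equal(back[[id]]$contigs, sim$collection[[id]]$contigs)
  }
})

test_that("quality filtering is strict on both thresholds and monotone", {
  mk <- function(id, comp, red) {
    toy_genome(id, n = 2, completeness = comp, redundancy = red)
  }
  coll <- genome_collection(list(mk("A", 50, 5), mk("B", 91, 9),
                                 mk("C", 50.1, 10), mk("D", 70, 9.9)))
  expect_equal(names(filter_by_quality(coll, 50, 10)), c("B", "D"))
  expect_equal(names(filter_by_quality(coll, 90, 10)), "B")
  # monotone: raising min_completeness never increases retention
  counts <- vapply(c(0, 30, 50, 70, 90, 100), function(mc) {
    length(filter_by_quality(coll, mc, 10))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # empty collection passes through
  expect_length(filter_by_quality(genome_collection(list()), 50, 10), 0)
})

test_that("ambiguity codes other than N are squashed to N with a warning", {
  orfs <- data.frame(orf_id = "o", contig_id = "c1", start = 1L, end = 3L,
                     strand = "+", protein = "M")
  expect_warning(g <- genome_record("G1", c(c1 = "ARGTW"), orfs), "mapped to N")
  expect_equal(unname(g$contigs), "ANGTN")
})

test_that("taxonomy strings parse by rank with gaps tolerated", {
  tax <- parse_taxonomy("d__Bacteria;p__Nitrospirae;c__;o__;f__;g__;s__")
  expect_equal(unname(tax[c("domain", "phylum")]), c("Bacteria", "Nitrospirae"))
  expect_true(is.na(tax[["class"]]))
  g <- toy_genome("G1", n = 2,
                  taxonomy = "d__Bacteria;p__Proteobacteria;c__Deltaproteobacteria")
  expect_equal(genome_group(g), "Deltaproteobacteria")
  expect_equal(genome_group(g, class_groups = character(0)), "Proteobacteria")
})
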