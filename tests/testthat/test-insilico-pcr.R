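test_that("IUPAC matching semantics, including template N", {
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("N", "T"))
  expect_false(iupac_match("A", "N"))
  expect_true(iupac_match("N", "N"))
  expect_error(iupac_match("Z", "A"), "invalid IUPAC")
  expect_error(iupac_match("A", "Q"), "invalid template")
})

test_that("mismatch counting is position-wise", {
  expect_equal(count_mismatches("ATG", "ATG"), 0)
  expect_equal(count_mismatches("ATG", "ATC"), 1)
  expect_equal(count_mismatches("GGNGG", "GGAGC"), 1)
  expect_error(count_mismatches("ATG", "ATGC"), "length")
  # position-wise oracle on random primer/window pairs
  set.seed(9)
  for (rep in 1:30) {
    m <- sample(5:20, 1)
    p <- paste(sample(names(hgcscan:::IUPAC_DNA), m, replace = TRUE),
               collapse = "")
    w <- rand_dna(m)
    brute <- sum(vapply(seq_len(m), function(k) {
      !iupac_match(substr(p, k, k), substr(w, k, k))
    }, logical(1)))
    expect_equal(count_mismatches(p, w), brute)
  }
})

test_that("a planted construct yields exactly one amplicon of the right span", {
  set.seed(4)
  fwd <- primer("F", "GGTGYAAYGTNTGG")
  rev <- primer("R", "CCRTARTCNGG")
  construct <- paste0("GGTGCAACGTATGG", rand_dna(200), oracle_revcomp("CCGTAATCAGG"))
  contig <- paste0(rand_dna(100), construct, rand_dna(100))
  hits <- scan_amplicons(contig, fwd, rev, max_mismatches = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_length, 14 + 200 + 11)
  expect_equal(hits$orientation, "plus")
  expect_equal(hits$fwd_start, 101L)

  # three substitutions in the forward site exceed the 2-mismatch setting
  broken <- contig
  substr(broken, 101, 103) <- "CCA"  # GGT -> CCA: 3 mismatches
  expect_equal(nrow(scan_amplicons(broken, fwd, rev, max_mismatches = 2)), 0L)
})

test_that("scan equals the independent oracle on small random contigs", {
  set.seed(14)
  fwd <- primer("F", "GGTGYAAYGTNTGGGAYGC")
  rev <- primer("R", "CCRTARTCNGGRTTYTGCA")
  for (rep in 1:8) {
    contig <- paste0(rand_dna(80),
                     "GGTGCAATGTATGGGATGC", rand_dna(60),
                     oracle_revcomp("CCGTAATCAGGATTTTGCA"), rand_dna(80))
    for (mm in 0:2) {
      got <- scan_amplicons(contig, fwd, rev, max_mismatches = mm,
                            max_product = 400)
      exp <- oracle_scan_amplicons(contig, fwd$sequence, rev$sequence,
                                   mm, 400)
      if (is.null(exp)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(sort_amplicons(got), sort_amplicons(exp))
      }
    }
  }
})

test_that("hits nest monotonically in the mismatch setting and mirror under revcomp", {
  set.seed(15)
  fwd <- primer("F", "ACGTRYACGTWS")
  rev <- primer("R", "TGCAKMTGCABD")
  contig <- paste0(rand_dna(150), "ACGTATACGTAC", rand_dna(50),
                   oracle_revcomp("TGCATATGCAAT"), rand_dna(150))
  prev <- 0L
  for (mm in 0:3) {
    n <- nrow(scan_amplicons(contig, fwd, rev, max_mismatches = mm,
                             max_product = 500))
    expect_gte(n, prev)
    prev <- n
  }
  a <- scan_amplicons(contig, fwd, rev, 2, 500)
  b <- scan_amplicons(oracle_revcomp(contig), fwd, rev, 2, 500)
  L <- nchar(contig)
  expect_equal(nrow(a), nrow(b))
  mirrored <- data.frame(fwd_start = L - b$fwd_end + 1L,
                         rev_end = L - b$rev_start + 1L,
                         product_length = b$product_length)
  expect_equal(
    mirrored[order(mirrored$fwd_start), ],
    data.frame(fwd_start = a$fwd_start, rev_end = a$rev_end,
               product_length = a$product_length)[order(a$fwd_start), ],
    ignore_attr = TRUE)
})

test_that("crosstab counts amplified genomes per group with on-target flags", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_true = 4, n_decoy_no_motif = 4, n_decoy_off_contig = 0,
                    n_decoy_distance6 = 0, n_decoy_low_score = 0,
                    primer_mismatches = 0)
  sim <- generate_collection(cfg, seed = 31, dir = d)
  hits <- generate_hit_tables(sim, seed = 32)
  calls <- call_methylators(sim$collection, hits)
  amp <- scan_collection(sim$collection,
                         primer("F", cfg$fwd_primer),
                         primer("R", cfg$rev_primer), max_mismatches = 2)
  ct <- crosstab_amplification(amp, sim$collection, calls,
                               mismatch_settings = c(0, 2))
  truth <- sim$truth
  for (grp in ct$group) {
    gt <- truth[truth$phylum == grp, ]
    expect_equal(ct$amplified_mm0[ct$group == grp],
                 sum(!is.na(gt$primer_contig)))
    # on-target only where the construct sits inside the called hgcA ORF
    expect_equal(ct$on_target_mm0[ct$group == grp],
                 sum(gt$primer_on_target %in% TRUE &
                       gt$genome_id %in% calls$genome_id))
  }
  # empty hit table gives a zero table with one row per group
  ct0 <- crosstab_amplification(amp[0, ], sim$collection, calls)
  expect_true(all(ct0$amplified_mm0 == 0) && all(ct0$amplified_mm2 == 0))
  expect_setequal(ct0$group, unique(truth$phylum))
})
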