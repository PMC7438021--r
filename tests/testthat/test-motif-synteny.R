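test_that("motif matching honours alternation and X semantics", {
  expect_equal(match_motif("MGGINVWCAAGKA", "G(I/V)NVWCAAGK"), 3L)
  expect_equal(match_motif("CAACAAAC", "CXXCXXXC"), 1L)
  expect_equal(match_motif("GLNVWCAAGK", "G(I/V)NVWCAAGK"), integer(0))
  expect_true(validate_hgcA(paste0(rand_protein(20), "GVNVWCAAGK")))
  expect_false(validate_hgcA("GINVWCAAG"))
  expect_error(parse_motif("G(I/V"), "malformed")
  expect_error(parse_motif("AB2"), "malformed")
})

test_that("motif matching equals the naive window oracle, overlaps included", {
  set.seed(11)
  pats <- c("G(I/V)NVWCAAGK", "CXXCXXXC", replicate(10, rand_motif()))
  for (pat in pats) {
    for (rep in 1:20) {
      p <- rand_protein(sample(20:120, 1))
      expect_identical(match_motif(p, pat), oracle_match_motif(p, pat))
    }
  }
  # overlapping matches all reported
  expect_equal(match_motif("CCACCAACCAAC", "CXXCXXXC"),
               oracle_match_motif("CCACCAACCAAC", "CXXCXXXC"))
})

test_that("downstream distance is strand-relative and contig-bounded", {
  g <- toy_genome("G1", n = 10, strands = c("+", "-", rep("+", 8)))
  expect_equal(downstream_distance(g, "G1_o05", "G1_o06"), 1L)
  expect_equal(downstream_distance(g, "G1_o02", "G1_o06"), -4L)  # minus strand
  g2 <- genome_record(
    "G2", c(c1 = rand_dna(100), c2 = rand_dna(100)),
    data.frame(orf_id = c("a", "b"), contig_id = c("c1", "c2"),
               start = c(1L, 1L), end = c(30L, 30L), strand = "+",
               protein = "MKL"))
  expect_true(is.na(downstream_distance(g2, "a", "b")))
  expect_error(downstream_distance(g, "G1_o05", "nope"), "not found")
})

test_that("hgcB pairing and regulator search agree with exhaustive placement", {
  # 17-ORF contig, hgcA at rank 9; candidate planted at every offset -8..8
  for (a_strand in c("+", "-")) {
    for (off in -8:8) {
      if (off == 0) next
      g <- toy_genome("G1", n = 17, strands = rep(a_strand, 17))
      cand_rank <- 9 + off
      cand <- sprintf("G1_o%02d", cand_rank)
      hitB <- data.frame(genome_id = "G1", orf_id = cand, marker = "hgcB",
                         evalue = 1e-20, score = 100)
      got <- pair_hgcB(g, "G1_o09", hitB)
      down <- if (a_strand == "+") off else -off
      if (down >= 1 && down <= 5) {
        expect_equal(got$orf, cand)
        expect_equal(got$distance, down)
      } else {
        expect_true(is.na(got$orf))
      }
      gotr <- find_regulator(g, "G1_o09", hitB)
      up <- -down
      if (up >= 1 && up <= 3) {
        expect_equal(gotr$orf, cand)
        expect_equal(gotr$distance, up)
      } else {
        expect_true(is.na(gotr$orf))
      }
    }
  }
})

test_that("nearest candidate wins; ties break by score then orf id", {
  g <- toy_genome("G1", n = 17)
  hits <- data.frame(genome_id = "G1",
                     orf_id = c("G1_o11", "G1_o13"), marker = "hgcB",
                     evalue = 1e-20, score = c(80, 120))
  expect_equal(pair_hgcB(g, "G1_o09", hits)$distance, 2L)
})

test_that("strand-relative distances survive contig mirroring", {
  set.seed(5)
  strands <- sample(c("+", "-"), 12, replace = TRUE)
  g <- toy_genome("G1", n = 12, strands = strands)
  # mirrored genome: reverse coordinates and flip strands
  L <- nchar(g$contigs[[1]])
  o <- g$orfs
  mirrored <- data.frame(
    orf_id = o$orf_id, contig_id = o$contig_id,
    start = L - o$end + 1L, end = L - o$start + 1L,
    strand = ifelse(o$strand == "+", "-", "+"), protein = o$protein)
  g2 <- genome_record("G1m", setNames(oracle_revcomp(g$contigs[[1]]),
                                      names(g$contigs)), mirrored)
  for (rep in 1:10) {
    ab <- sample(o$orf_id, 2)
    expect_equal(downstream_distance(g, ab[1], ab[2]),
                 downstream_distance(g2, ab[1], ab[2]))
  }
})

test_that("call_methylators recovers planted truth and rejects every decoy class", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_true = 4, n_decoy_no_motif = 4, n_decoy_off_contig = 4,
                    n_decoy_distance6 = 4, n_decoy_low_score = 4)
  sim <- generate_collection(cfg, seed = 21, dir = d)
  hits <- generate_hit_tables(sim, seed = 22)
  calls <- call_methylators(sim$collection, hits)
  truth <- sim$truth
  expected <- expected_calls_from_truth(truth)
  expect_setequal(calls$genome_id, expected$genome_id)
  m <- match(expected$genome_id, calls$genome_id)
  # true genomes: full evidence matches the planted offsets
  tr <- truth$class == "true"
  mt <- match(truth$genome_id[tr], calls$genome_id)
  expect_equal(calls$hgcB_orf[mt], truth$hgcB_orf[tr])
  expect_equal(calls$hgcB_distance[mt], truth$hgcB_offset[tr])
  expect_equal(calls$regulator_orf[mt], truth$regulator_orf[tr])
  expect_equal(calls$regulator_distance[mt], truth$regulator_offset[tr])
  # synteny decoys are called on hgcA but carry no hgcB evidence
  for (cls in c("off_contig", "distance6")) {
    mc <- match(truth$genome_id[truth$class == cls], calls$genome_id)
    expect_true(all(is.na(calls$hgcB_orf[mc])))
    expect_false(any(calls$hgcB_same_contig[mc]))
  }
  # removed candidates are logged with the rule that removed them
  log <- attr(calls, "filter_log")
  expect_setequal(log$genome_id[log$rule == "cap_helix_missing"],
                  truth$genome_id[truth$class == "no_motif"])
  expect_setequal(log$genome_id[log$rule == "hgcA_threshold"],
                  truth$genome_id[truth$class == "low_score"])
})

test_that("neighborhood extraction windows and truncates correctly", {
  g <- toy_genome("G1", n = 10)
  expect_equal(extract_neighborhood(g, "G1_o04", 0)$orf_id, "G1_o04")
  nb <- extract_neighborhood(g, "G1_o04", 2)
  expect_equal(nb$index_on_contig, 2:6)
  edge <- extract_neighborhood(g, "G1_o01", 5)
  expect_equal(edge$index_on_contig, 1:6)
  labs <- c(G1_o04 = "hgcA")
  expect_equal(extract_neighborhood(g, "G1_o04", 1, labels = labs)$product,
               c("hypothetical protein", "hgcA", "hypothetical protein"))
})
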