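simple_counts <- function(counts, lengths, genomes = NULL) {
  n <- nrow(counts)
  count_matrix(counts, data.frame(
    orf_id = sprintf("o%02d", seq_len(n)),
    genome_id = if (is.null(genomes)) rep("G1", n) else genomes,
    length_bp = lengths))
}

test_that("TPM follows the length-normalized formula", {
  cm <- simple_counts(matrix(c(10, 10), ncol = 1,
                             dimnames = list(NULL, "s1")), c(100, 200))
  tpm <- tpm_normalize(cm)
  expect_equal(unname(tpm$counts[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # single expressed ORF takes the whole million
  cm1 <- simple_counts(matrix(5, ncol = 1, dimnames = list(NULL, "s1")), 300)
  expect_equal(unname(tpm_normalize(cm1)$counts[1, 1]), 1e6)
  # all-zero sample maps to zeros without dividing by zero
  cm0 <- simple_counts(matrix(0, nrow = 3, ncol = 2,
                              dimnames = list(NULL, c("a", "b"))),
                       c(100, 200, 300))
  expect_true(all(tpm_normalize(cm0)$counts == 0))
  expect_error(simple_counts(matrix(-1), 100), "negative")
})

test_that("TPM columns sum to one million and are length-unit invariant", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:40, 1); s <- sample(2:5, 1)
    counts <- matrix(rnbinom(n * s, mu = 20, size = 2), nrow = n,
                     dimnames = list(NULL, paste0("s", 1:s)))
    counts[, 1] <- 0
    lens <- sample(100:2000, n)
    tpm <- tpm_normalize(simple_counts(counts, lens))
    sums <- colSums(tpm$counts)
    nz <- colSums(counts) > 0
    expect_equal(unname(sums[nz]), rep(1e6, sum(nz)), tolerance = 1e-6)
    expect_true(all(sums[!nz] == 0))
    tpm_kb <- tpm_normalize(simple_counts(counts, lens / 1000))
    expect_equal(tpm_kb$counts, tpm$counts, tolerance = 1e-12)
  }
})

make_expression_fixture <- function() {
  coll <- genome_collection(list(
    toy_genome("G1", n = 3, taxonomy = "d__Bacteria;p__Pa"),
    toy_genome("G2", n = 3, taxonomy = "d__Bacteria;p__Pa"),
    toy_genome("G3", n = 3, taxonomy = "d__Bacteria;p__Pb")))
  counts <- matrix(c(10, 5, 1, 2, 4, 8, 3, 6, 9,
                     0, 0, 0, 0, 0, 0, 0, 0, 0), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  cm <- count_matrix(counts, data.frame(
    orf_id = c("G1_o01", "G1_o02", "G1_o03", "G2_o01", "G2_o02", "G2_o03",
               "G3_o01", "G3_o02", "G3_o03"),
    genome_id = rep(c("G1", "G2", "G3"), each = 3),
    length_bp = rep(300, 9)))
  calls <- data.frame(
    genome_id = c("G1", "G2", "G3"),
    hgcA_orf = c("G1_o02", "G2_o01", "G3_o03"), hgcA_motif_ok = TRUE,
    hgcB_orf = c("G1_o03", NA, NA), hgcB_distance = c(1L, NA, NA),
    hgcB_same_contig = c(TRUE, FALSE, FALSE),
    regulator_orf = NA_character_, regulator_distance = NA_integer_)
  list(coll = coll, tpm = tpm_normalize(cm), calls = calls)
}

test_that("per-group marker totals add up and conserve the grand total", {
  fx <- make_expression_fixture()
  res <- marker_expression_by_group(fx$tpm, fx$calls, "hgcA", fx$coll)
  # equal lengths: TPM proportional to counts; total counts s1 = 48
  expect_equal(unname(res$group_tpm["Pa", "s1"]), (5 + 2) / 48 * 1e6)
  expect_equal(unname(res$group_tpm["Pb", "s1"]), 9 / 48 * 1e6)
  expect_equal(unname(colSums(res$group_tpm)), unname(res$total),
               tolerance = 1e-9)
  expect_true(all(res$group_tpm[, "s2"] == 0))
  # a called ORF absent from the matrix errors by name
  bad <- fx$calls; bad$hgcA_orf[1] <- "missing_orf"
  expect_error(marker_expression_by_group(fx$tpm, bad, "hgcA", fx$coll),
               "missing_orf")
  # hgcB totals only cover genomes with hgcB evidence
  resB <- marker_expression_by_group(fx$tpm, fx$calls, "hgcB", fx$coll)
  expect_equal(unname(resB$group_tpm["Pa", "s1"]), 1 / 48 * 1e6)
})

test_that("genome averages divide group totals by genome counts", {
  fx <- make_expression_fixture()
  avg <- genome_average_by_group(fx$tpm, fx$coll)
  expect_equal(unname(avg["Pa", "s1"]), ((16 + 14) / 48 * 1e6) / 2)
  expect_equal(unname(avg["Pb", "s1"]), (18 / 48 * 1e6) / 1)
  expect_true(all(avg[, "s2"] == 0))
})

test_that("housekeeping comparison pairs hgcA with best rpoB and flags gaps", {
  fx <- make_expression_fixture()
  rpoB <- data.frame(genome_id = c("G1", "G1", "G2"),
                     orf_id = c("G1_o01", "G1_o03", "G2_o02"),
                     marker = "rpoB", evalue = 1e-100, score = c(700, 650, 800))
  pairs <- compare_to_housekeeping(fx$tpm, fx$calls, rpoB)
  expect_setequal(unique(pairs$genome_id), c("G1", "G2"))
  expect_equal(attr(pairs, "missing_rpoB"), "G3")
  g1s1 <- pairs[pairs$genome_id == "G1" & pairs$sample == "s1", ]
  expect_equal(g1s1$hgcA_tpm, 5 / 48 * 1e6)
  expect_equal(g1s1$rpoB_tpm, 10 / 48 * 1e6)  # best-scoring rpoB ORF
  # zero expression is retained as an explicit (0, x) pair
  g1s2 <- pairs[pairs$genome_id == "G1" & pairs$sample == "s2", ]
  expect_equal(g1s2$hgcA_tpm, 0)
})

test_that("count matrix round trips through its file dialect", {
  fx <- make_expression_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(fx$tpm, f)
  back <- read_counts(f)
  expect_equal(back$counts, fx$tpm$counts, tolerance = 1e-9)
  expect_equal(back$orf_info$genome_id, fx$tpm$orf_info$genome_id)
})
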