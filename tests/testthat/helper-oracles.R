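# Independent oracles and small in-code fixtures shared across tests.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# --- motif oracles -------------------------------------------------------

# parse the motif pattern language independently of the package
oracle_motif_sets <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list(); i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      j <- i + which(chars[(i + 1):length(chars)] == ")")[1]
      sets[[length(sets) + 1]] <- setdiff(chars[(i + 1):(j - 1)], "/")
      i <- j + 1
    } else {
      sets[[length(sets) + 1]] <- if (chars[i] == "X") AA else chars[i]
      i <- i + 1
    }
  }
  sets
}

# naive position-wise scan: logical AND of per-position set membership
oracle_match_motif <- function(protein, pattern) {
  sets <- oracle_motif_sets(pattern)
  s <- strsplit(protein, "")[[1]]
  m <- length(sets); nwin <- length(s) - m + 1
  if (nwin < 1) return(integer(0))
  ok <- rep(TRUE, nwin)
  for (k in seq_len(m)) ok <- ok & s[k:(k + nwin - 1)] %in% sets[[k]]
  which(ok)
}

# full expansion to the word set (finite-alternation motifs only)
oracle_motif_words <- function(pattern) {
  sets <- oracle_motif_sets(pattern)
  stopifnot(prod(lengths(sets)) <= 64)
  words <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(words, 1, paste, collapse = "")
}

oracle_match_by_expansion <- function(protein, pattern) {
  hits <- unlist(lapply(oracle_motif_words(pattern), function(w) {
    out <- integer(0); from <- 1
    repeat {
      p <- regexpr(w, substring(protein, from), fixed = TRUE)
      if (p == -1) break
      out <- c(out, from + p - 1); from <- from + p
    }
    out
  }))
  as.integer(sort(unique(hits)))
}

# random motif with at most 64 expansions (letters + a few alternations)
rand_motif <- function() {
  n <- sample(4:8, 1)
  n_alt <- sample(0:3, 1)
  alt_pos <- sample(n, n_alt)
  parts <- vapply(seq_len(n), function(i) {
    if (i %in% alt_pos) {
      paste0("(", paste(sample(AA, 2), collapse = "/"), ")")
    } else sample(AA, 1)
  }, character(1))
  paste(parts, collapse = "")
}

# --- PCR oracles ---------------------------------------------------------

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# IUPAC expansions, restated independently of the package
ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_count_mm <- function(primer_seq, window) {
  p <- strsplit(primer_seq, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(p), function(k) !(w[k] %in% ORACLE_IUPAC[[p[k]]]),
             logical(1)))
}

# primer site finding via Biostrings (independent C implementation);
# subject restricted to A/C/G/T
oracle_sites <- function(seq, primer_seq, max_mm) {
  m <- Biostrings::matchPattern(primer_seq, Biostrings::DNAString(seq),
                                max.mismatch = max_mm,
                                fixed = c(pattern = FALSE, subject = TRUE))
  st <- Biostrings::start(m)
  mm <- vapply(st, function(s) {
    oracle_count_mm(primer_seq, substr(seq, s, s + nchar(primer_seq) - 1))
  }, numeric(1))
  data.frame(start = st, end = st + nchar(primer_seq) - 1, mismatches = mm)
}

# exhaustive pairing over both strands, mirrored to plus coordinates
oracle_scan_amplicons <- function(seq, fwd_seq, rev_seq, max_mm, max_product) {
  L <- nchar(seq)
  one <- function(template, orientation) {
    f <- oracle_sites(template, fwd_seq, max_mm)
    r <- oracle_sites(template, oracle_revcomp(rev_seq), max_mm)
    if (nrow(f) == 0 || nrow(r) == 0) return(NULL)
    out <- NULL
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (r$start[j] > f$end[i] && r$end[j] - f$start[i] + 1 <= max_product) {
        row <- data.frame(fwd_start = f$start[i], fwd_end = f$end[i],
                          rev_start = r$start[j], rev_end = r$end[j],
                          product_length = r$end[j] - f$start[i] + 1,
                          fwd_mismatches = f$mismatches[i],
                          rev_mismatches = r$mismatches[j],
                          orientation = orientation)
        if (orientation == "minus") {
          row[, c("fwd_start", "fwd_end", "rev_start", "rev_end")] <-
            c(L - row$fwd_end + 1, L - row$fwd_start + 1,
              L - row$rev_end + 1, L - row$rev_start + 1)
        }
        out <- rbind(out, row)
      }
    }
    out
  }
  res <- rbind(one(seq, "plus"), one(oracle_revcomp(seq), "minus"))
  if (is.null(res)) return(res)
  res[order(res$orientation, res$fwd_start, res$rev_start), ]
}

sort_amplicons <- function(h) {
  h <- h[order(h$orientation, h$fwd_start, h$rev_start),
         c("fwd_start", "fwd_end", "rev_start", "rev_end", "product_length",
           "fwd_mismatches", "rev_mismatches", "orientation")]
  rownames(h) <- NULL
  h
}

# --- alignment fixtures --------------------------------------------------

rand_aln_row <- function(w, gap_p = 0.2) {
  paste(ifelse(runif(w) < gap_p, "-", sample(AA, w, replace = TRUE)),
        collapse = "")
}

rand_alignment_set <- function(n_markers = 4, genomes = paste0("G", 1:6)) {
  lapply(seq_len(n_markers), function(k) {
    w <- sample(5:20, 1)
    members <- sample(genomes, sample(2:length(genomes), 1))
    marker_alignment(paste0("m", k),
                     setNames(vapply(members, function(g) rand_aln_row(w),
                                     character(1)), members))
  })
}

# --- toy genome builders -------------------------------------------------

# contig of n equally spaced 30 bp ORFs with given strands and proteins
toy_genome <- function(id = "G1", n = 10, strands = rep("+", n),
                       proteins = NULL, taxonomy = "d__Bacteria;p__Testia",
                       completeness = 95, redundancy = 2) {
  if (is.null(proteins)) {
    proteins <- vapply(seq_len(n), function(i) rand_protein(9), character(1))
  }
  starts <- (seq_len(n) - 1) * 50 + 11
  orfs <- data.frame(
    orf_id = sprintf("%s_o%02d", id, seq_len(n)),
    contig_id = paste0(id, "_c1"),
    start = starts, end = starts + 29, strand = strands,
    protein = proteins, stringsAsFactors = FALSE)
  contig <- setNames(rand_dna(50 * n + 20), paste0(id, "_c1"))
  genome_record(id, contig, orfs, taxonomy, completeness, redundancy)
}

expected_calls_from_truth <- function(truth) {
  truth[truth$class %in% c("true", "off_contig", "distance6"), , drop = FALSE]
}
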