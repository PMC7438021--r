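# Seeded synthetic-data generator: genome collections with planted hgcA/hgcB
# loci (and decoy classes the calling rules must reject), matching hit
# tables, primer constructs, and overdispersed count matrices with planted
# phylum- and depth-structured expression. Every random draw flows from the
# single seed; fixed (config, seed) reproduces files byte-identically.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon table for back-translation (code 11 agrees with the standard code
# on codon->aa assignments; differences concern initiation only)
codon_map <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})
codon_mat <- local({
  aas <- setdiff(names(codon_map), "*")
  m <- matrix(NA_character_, nrow = length(aas), ncol = 6L,
              dimnames = list(aas, NULL))
  for (a in aas) m[a, seq_along(codon_map[[a]])] <- codon_map[[a]]
  m
})
codon_n <- setNames(lengths(codon_map[rownames(codon_mat)]), rownames(codon_mat))

#' Settings for the synthetic-collection generator
#'
#' Defaults describe the standing test bed: 50 genomes over 5 phyla —
#' 10 true methylators and 10 of each decoy class (cap-helix broken,
#' hgcB on another contig, hgcB six ORFs away, sub-threshold scores) —
#' with 2 contigs of 12 ORFs per genome, planted primer constructs, and
#' 10-fold phylum expression multipliers under negative-binomial noise
#' (dispersion 0.5) across a palsa/bog/fen x depth sample grid where the
#' palsa site is assigned multiplier zero (nothing detected there).
#'
#' @param n_true,n_decoy_no_motif,n_decoy_off_contig,n_decoy_distance6,n_decoy_low_score
#'   Genome counts per class.
#' @param n_background Extra genomes with no planted locus.
#' @param phyla Phylum labels cycled over the genomes.
#' @param contigs_per_genome,orfs_per_contig Genome shape.
#' @param orf_len_range Background ORF lengths (aa, inclusive range).
#' @param hgc_orf_len Planted hgcA ORF length (aa; long enough to carry the
#'   primer construct).
#' @param intergenic_range Intergenic spacer lengths (bp).
#' @param completeness_range,redundancy_range Quality metadata ranges (%).
#' @param hgcB_offsets,regulator_offsets Planted offsets (ORF ranks).
#' @param plant_regulator Plant an upstream regulator in true genomes.
#' @param fwd_primer,rev_primer IUPAC primer pair planted in hgcA ORFs of
#'   true genomes (on-target) and in intergenic tails of cap-helix-broken
#'   genomes (off-target).
#' @param primer_mismatches Pool of per-primer mismatch counts planted.
#' @param sites,depths,zero_sites Sample grid; sites in `zero_sites` get
#'   expression multiplier 0.
#' @param depth_effects Multiplier per depth (recycled over `depths`).
#' @param base_meanlog,base_sdlog Log-normal baseline ORF expression.
#' @param phylum_fold Fold change between consecutive phyla in the planted
#'   expression ranking (default 10).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts.
#' @param metabolic_markers Marker ids receiving random presence/absence
#'   hits for guild profiling.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_true = 10, n_decoy_no_motif = 10,
                       n_decoy_off_contig = 10, n_decoy_distance6 = 10,
                       n_decoy_low_score = 10, n_background = 0,
                       phyla = c("Acidobacteria", "Chloroflexi", "Firmicutes",
                                 "Nitrospirae", "Verrucomicrobia"),
                       contigs_per_genome = 2, orfs_per_contig = 12,
                       orf_len_range = c(40, 80), hgc_orf_len = 90,
                       intergenic_range = c(10, 60),
                       completeness_range = c(80, 100),
                       redundancy_range = c(0, 9),
                       hgcB_offsets = 1:5, regulator_offsets = 1:3,
                       plant_regulator = TRUE,
                       fwd_primer = "GGTGYAAYGTNTGGGAYGC",
                       rev_primer = "CCRTARTCNGGRTTYTGCA",
                       primer_mismatches = 0:2,
                       sites = c("palsa", "bog", "fen"),
                       depths = c("shallow", "deep"),
                       zero_sites = "palsa",
                       depth_effects = c(1, 2),
                       base_meanlog = log(5), base_sdlog = 0.5,
                       phylum_fold = 10, dispersion = 0.5,
                       metabolic_markers = c("nifD", "nifH", "nifK",
                                             "dsrA", "dsrB", "sat")) {
  cfg <- as.list(environment())
  n_planted_per_contig <- 1L + max(regulator_offsets) + max(6L, max(hgcB_offsets))
  if (orfs_per_contig < n_planted_per_contig) {
    stop("infeasible config: orfs_per_contig too small for planted offsets")
  }
  structure(cfg, class = "sim_config")
}

random_proteins <- function(n, lens) {
  res <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
  # reject background proteins containing either conserved motif
  bad <- grepl(motif_regex(cap_helix_motif()), res, perl = TRUE) |
    grepl(motif_regex(ferredoxin_motif()), res, perl = TRUE)
  while (any(bad)) {
    res[bad] <- vapply(lens[bad], function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
    bad <- grepl(motif_regex(cap_helix_motif()), res, perl = TRUE) |
      grepl(motif_regex(ferredoxin_motif()), res, perl = TRUE)
  }
  res
}

# insert word into protein at a random interior position
embed_word <- function(protein, word) {
  L <- nchar(protein); w <- nchar(word)
  pos <- sample.int(L - w + 1L, 1L)
  paste0(substr(protein, 1L, pos - 1L), word,
         substr(protein, pos + w, L))
}

cap_helix_word <- function() {
  paste0("G", sample(c("I", "V"), 1L), "NVWCAAGK")
}
broken_cap_helix_word <- function() {
  # L is not in the (I/V) alternation, so the motif cannot match
  "GLNVWCAAGK"
}
ferredoxin_word <- function() {
  x <- sample(setdiff(AA20, "C"), 5L, replace = TRUE)
  paste0("C", x[1], x[2], "C", x[3], x[4], x[5], "C")
}

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  pick <- floor(runif(length(aa)) * codon_n[aa]) + 1L
  paste0(paste(codon_mat[cbind(match(aa, rownames(codon_mat)), pick)],
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# realize a concrete ACGT copy of an IUPAC primer with exactly `mm`
# mismatching positions (never at N positions, which cannot mismatch)
realize_primer_site <- function(primer_seq, mm) {
  p <- strsplit(primer_seq, "")[[1]]
  base <- vapply(p, function(ch) {
    sample(strsplit(IUPAC_DNA[[ch]], "")[[1]], 1L)
  }, character(1))
  mutable <- which(p != "N")
  if (mm > length(mutable)) stop("more mismatches than mutable positions")
  for (k in sample(mutable, mm)) {
    base[k] <- sample(setdiff(c("A", "C", "G", "T"),
                              strsplit(IUPAC_DNA[[p[k]]], "")[[1]]), 1L)
  }
  paste(base, collapse = "")
}

#' Generate a synthetic genome collection with planted ground truth
#'
#' Builds genomes from random-codon background ORFs; planted hgcA proteins
#' embed the cap-helix domain (or a broken variant in the decoy class),
#' planted hgcB proteins embed CXXCXXXC, and primer constructs
#' (`fwd .. spacer .. revcomp(rev)`) are written into true genomes'
#' hgcA ORFs (on-target) and into intergenic tails of cap-helix-broken
#' genomes (off-target), with controlled per-primer mismatch counts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the sole entropy source.
#' @param dir Optional directory; when given, FASTA + GFF3 + metadata and
#'   the truth table are written there.
#' @return List with `collection` (a `GenomeCollection`), `truth` (the
#'   truth table data.frame), `multipliers` (planted per-phylum expression
#'   multipliers) and `dir`.
#' @export
generate_collection <- function(config = sim_config(), seed = 1, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, generate_collection_impl(config, dir))
}

generate_collection_impl <- function(cfg, dir) {
  classes <- rep(c("true", "no_motif", "off_contig", "distance6",
                   "low_score", "background"),
                 c(cfg$n_true, cfg$n_decoy_no_motif, cfg$n_decoy_off_contig,
                   cfg$n_decoy_distance6, cfg$n_decoy_low_score,
                   cfg$n_background))
  n <- length(classes)
  if (n == 0L) stop("infeasible config: no genomes requested")
  phyla <- rep_len(cfg$phyla, n)
  truth <- data.frame(
    genome_id = sprintf("G%03d", seq_len(n)), class = classes,
    phylum = phyla, hgcA_orf = NA_character_, hgcA_contig = NA_character_,
    hgcA_strand = NA_character_, hgcA_motif_ok = NA,
    hgcB_orf = NA_character_, hgcB_offset = NA_integer_,
    hgcB_contig = NA_character_, regulator_orf = NA_character_,
    regulator_offset = NA_integer_, rpoB_orf = NA_character_,
    fwd_mm = NA_integer_, rev_mm = NA_integer_,
    primer_contig = NA_character_, primer_start = NA_integer_,
    primer_on_target = NA, stringsAsFactors = FALSE)

  genomes <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    gid <- truth$genome_id[i]
    nc <- cfg$contigs_per_genome
    npc <- cfg$orfs_per_contig
    lens <- matrix(sample(seq(cfg$orf_len_range[1], cfg$orf_len_range[2]),
                          nc * npc, replace = TRUE), nrow = npc)
    prots <- matrix(random_proteins(nc * npc, as.vector(lens)), nrow = npc)
    strands <- matrix(sample(c("+", "-"), nc * npc, replace = TRUE),
                      nrow = npc)

    plant <- cls %in% c("true", "no_motif", "off_contig", "distance6",
                        "low_score")
    if (plant) {
      a_strand <- sample(c("+", "-"), 1L)
      reg_off <- if (cfg$plant_regulator) {
        sample(cfg$regulator_offsets, 1L)
      } else NA_integer_
      b_off <- switch(cls,
        distance6 = 6L,
        off_contig = NA_integer_,
        sample(cfg$hgcB_offsets, 1L))
      up <- max(cfg$regulator_offsets)
      down <- max(6L, max(cfg$hgcB_offsets))
      a_idx <- if (a_strand == "+") sample((up + 1L):(npc - down), 1L)
               else sample((down + 1L):(npc - up), 1L)
      dir_sign <- if (a_strand == "+") 1L else -1L
      lens[a_idx, 1L] <- cfg$hgc_orf_len
      a_word <- if (cls == "no_motif") broken_cap_helix_word()
                else cap_helix_word()
      prots[a_idx, 1L] <- embed_word(
        random_proteins(1L, cfg$hgc_orf_len), a_word)
      strands[a_idx, 1L] <- a_strand
      truth$hgcA_contig[i] <- paste0(gid, "_c1")
      truth$hgcA_strand[i] <- a_strand
      truth$hgcA_motif_ok[i] <- cls != "no_motif"

      if (cls == "off_contig") {
        b_pos <- c(sample(npc, 1L), 2L)  # (index, contig)
      } else {
        b_pos <- c(a_idx + dir_sign * b_off, 1L)
      }
      prots[b_pos[1L], b_pos[2L]] <- embed_word(
        prots[b_pos[1L], b_pos[2L]], ferredoxin_word())
      truth$hgcB_offset[i] <- b_off
      truth$hgcB_contig[i] <- paste0(gid, "_c", b_pos[2L])

      r_idx <- NA_integer_
      if (!is.na(reg_off) && cls == "true") {
        r_idx <- a_idx - dir_sign * reg_off
        truth$regulator_offset[i] <- reg_off
      }
    }

    # assemble contigs: spacer + ORF nt (+ strand aware) per slot
    contigs <- character(nc)
    orf_rows <- list()
    for (cix in seq_len(nc)) {
      pos <- 0L
      segs <- character(0)
      for (oix in seq_len(npc)) {
        spacer <- sample(seq(cfg$intergenic_range[1], cfg$intergenic_range[2]), 1L)
        segs <- c(segs, paste(sample(c("A", "C", "G", "T"), spacer,
                                     replace = TRUE), collapse = ""))
        pos <- pos + spacer
        nt <- back_translate(prots[oix, cix])
        if (strands[oix, cix] == "-") nt <- revcomp(nt)
        segs <- c(segs, nt)
        orf_rows[[length(orf_rows) + 1L]] <- data.frame(
          orf_id = sprintf("%s_c%d_o%02d", gid, cix, oix),
          contig_id = paste0(gid, "_c", cix),
          start = pos + 1L, end = pos + nchar(nt),
          strand = strands[oix, cix], protein = prots[oix, cix],
          stringsAsFactors = FALSE)
        pos <- pos + nchar(nt)
      }
      tail_pad <- paste(sample(c("A", "C", "G", "T"), 150L, replace = TRUE),
                        collapse = "")
      contigs[cix] <- paste0(paste(segs, collapse = ""), tail_pad)
    }
    names(contigs) <- paste0(gid, "_c", seq_len(nc))
    orfs <- do.call(rbind, orf_rows)

    if (plant) {
      truth$hgcA_orf[i] <- sprintf("%s_c1_o%02d", gid, a_idx)
      truth$hgcB_orf[i] <- sprintf("%s_c%d_o%02d", gid, b_pos[2L], b_pos[1L])
      if (!is.na(r_idx)) {
        truth$regulator_orf[i] <- sprintf("%s_c1_o%02d", gid, r_idx)
      }
      # plant the primer construct
      f_mm <- sample(cfg$primer_mismatches, 1L)
      r_mm <- sample(cfg$primer_mismatches, 1L)
      construct <- paste0(
        realize_primer_site(cfg$fwd_primer, f_mm),
        paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE),
              collapse = ""),
        revcomp(realize_primer_site(cfg$rev_primer, r_mm)))
      if (cls == "true") {
        a_row <- orfs[orfs$orf_id == truth$hgcA_orf[i], ]
        p_contig <- a_row$contig_id
        p_start <- a_row$start + 6L
        on_target <- TRUE
      } else if (cls == "no_motif") {
        p_contig <- paste0(gid, "_c", nc)
        p_start <- nchar(contigs[[p_contig]]) - nchar(construct) - 10L
        on_target <- FALSE
      } else {
        p_contig <- NA_character_
      }
      if (!is.na(p_contig)) {
        substr(contigs[[p_contig]], p_start,
               p_start + nchar(construct) - 1L) <- construct
        truth$fwd_mm[i] <- f_mm
        truth$rev_mm[i] <- r_mm
        truth$primer_contig[i] <- p_contig
        truth$primer_start[i] <- p_start
        truth$primer_on_target[i] <- on_target
      }
    }
    # a designated rpoB-like housekeeping ORF (first slot of contig 1,
    # never overlapping a planted locus by construction of index ranges)
    truth$rpoB_orf[i] <- sprintf("%s_c1_o01", gid)

    genomes[[i]] <- genome_record(
      id = gid, contigs = contigs, orfs = orfs,
      taxonomy = sprintf("d__Bacteria;p__%s;c__;o__;f__;g__;s__", phyla[i]),
      completeness = round(runif(1, cfg$completeness_range[1],
                                 cfg$completeness_range[2]), 1),
      redundancy = round(runif(1, cfg$redundancy_range[1],
                               cfg$redundancy_range[2]), 1))
  }
  collection <- genome_collection(genomes)
  multipliers <- setNames(cfg$phylum_fold ^ (seq_along(cfg$phyla) - 1L),
                          cfg$phyla)
  out <- list(collection = collection, truth = truth,
              multipliers = multipliers, config = cfg, dir = dir)
  if (!is.null(dir)) {
    write_collection(collection, dir)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate profile-search hit tables matching a synthetic collection
#'
#' True loci receive scores and E-values comfortably past their thresholds;
#' the sub-threshold decoy class straddles the hgcA 300 / 1e-50 boundary on
#' the rejecting side. hgcB, regulator, rpoB and metabolic-marker hits are
#' generated against their own thresholds.
#'
#' @param sim Output of [generate_collection()].
#' @param seed Integer seed.
#' @param path Optional file to write the hit table to (package dialect).
#' @return Hit data.frame across all markers.
#' @export
generate_hit_tables <- function(sim, seed = 1, path = NULL) {
  hits <- withr::with_seed(seed, generate_hits_impl(sim))
  if (!is.null(path)) write_hits(hits, path)
  hits
}

generate_hits_impl <- function(sim) {
  truth <- sim$truth
  rows <- list()
  add <- function(gid, orf, marker, evalue, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_id = gid, orf_id = orf, marker = marker,
      evalue = evalue, score = score, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    if (!is.na(t$hgcA_orf)) {
      if (t$class == "low_score") {
        # rejecting side of the 300 / 1e-50 boundary
        if (runif(1) < 0.5) {
          add(t$genome_id, t$hgcA_orf, "hgcA",
              10^-runif(1, 51, 80), runif(1, 150, 295))
        } else {
          add(t$genome_id, t$hgcA_orf, "hgcA",
              10^-runif(1, 20, 49), runif(1, 310, 400))
        }
      } else {
        add(t$genome_id, t$hgcA_orf, "hgcA",
            10^-runif(1, 55, 120), runif(1, 310, 400))
      }
    }
    if (!is.na(t$hgcB_orf)) {
      add(t$genome_id, t$hgcB_orf, "hgcB",
          10^-runif(1, 20, 60), runif(1, 75, 150))
    }
    if (!is.na(t$regulator_orf)) {
      add(t$genome_id, t$regulator_orf, "regulator",
          10^-runif(1, 11, 30), runif(1, 50, 200))
    }
    add(t$genome_id, t$rpoB_orf, "rpoB",
        10^-runif(1, 100, 200), runif(1, 600, 900))
  }
  # random metabolic-marker presence over background ORFs
  markers <- if (is.null(sim$config)) {
    c("nifD", "nifH", "nifK", "dsrA", "dsrB", "sat")
  } else sim$config$metabolic_markers
  for (g in sim$collection) {
    pool <- setdiff(g$orfs$orf_id,
                    unlist(truth[truth$genome_id == g$id,
                                 c("hgcA_orf", "hgcB_orf", "regulator_orf",
                                   "rpoB_orf")]))
    for (mk in markers) {
      if (runif(1) < 0.5) {
        add(g$id, sample(pool, 1L), mk, 10^-runif(1, 12, 40),
            runif(1, 100, 300))
      }
    }
  }
  dedup_hits(do.call(rbind, rows))
}

#' Generate a planted-effect count matrix for a synthetic collection
#'
#' Per-ORF baselines are log-normal; expected counts scale by the planted
#' phylum multiplier and a depth effect, sites listed in `zero_sites` get
#' multiplier zero, and counts are drawn negative-binomially at the
#' configured dispersion (Poisson at dispersion 0).
#'
#' @param sim Output of [generate_collection()].
#' @param config The [sim_config()] used (for the sample grid and noise).
#' @param seed Integer seed.
#' @param path Optional file to write the matrix to.
#' @return A [count_matrix()] with sample ids `<site>_<depth>`.
#' @export
generate_counts <- function(sim, config = sim$config, seed = 1,
                            path = NULL) {
  if (is.null(config)) config <- sim_config()
  cm <- withr::with_seed(seed, generate_counts_impl(sim, config))
  if (!is.null(path)) write_counts(cm, path)
  cm
}

generate_counts_impl <- function(sim, cfg) {
  grid <- expand.grid(depth = cfg$depths, site = cfg$sites,
                      stringsAsFactors = FALSE)
  sample_ids <- paste(grid$site, grid$depth, sep = "_")
  site_mult <- ifelse(grid$site %in% cfg$zero_sites, 0, 1)
  depth_mult <- rep_len(cfg$depth_effects, length(cfg$depths))[
    match(grid$depth, cfg$depths)]
  orf_info <- do.call(rbind, lapply(sim$collection, function(g) {
    data.frame(orf_id = g$orfs$orf_id, genome_id = g$id,
               length_bp = g$orfs$nt_length, stringsAsFactors = FALSE)
  }))
  rownames(orf_info) <- NULL
  phylum <- sim$truth$phylum[match(orf_info$genome_id, sim$truth$genome_id)]
  pmult <- sim$multipliers[phylum]
  base <- rlnorm(nrow(orf_info), cfg$base_meanlog, cfg$base_sdlog)
  counts <- matrix(0, nrow = nrow(orf_info), ncol = length(sample_ids),
                   dimnames = list(orf_info$orf_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- base * pmult * site_mult[j] * depth_mult[j]
    counts[, j] <- if (cfg$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  count_matrix(counts, orf_info)
}

#' Generate a complete synthetic dataset on disk
#'
#' Genomes (FASTA + GFF3 + metadata), truth table, hit table and count
#' matrix, all under one directory — the exact dialects the pipeline
#' consumes.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, the `generate_collection()` result with `hits` and
#'   `counts` attached.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1, dir) {
  sim <- generate_collection(config, seed, dir = file.path(dir, "genomes"))
  sim$hits <- generate_hit_tables(sim, seed = seed + 1L,
                                  path = file.path(dir, "hits.tsv"))
  sim$counts <- generate_counts(sim, config, seed = seed + 2L,
                                path = file.path(dir, "counts.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}
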