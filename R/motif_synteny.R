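# Conserved-motif validation and gene-neighborhood (synteny) rules that turn
# filtered profile hits into per-genome methylator calls.
#
# HgcA must carry the cap-helix domain G(I/V)NVWCAAGK; a confident HgcB must
# score > 70, carry the ferredoxin-binding motif CXXCXXXC, and sit within
# five ORFs downstream of hgcA on the same contig. The ArsR-like regulator
# is accepted 1-3 genes upstream at E <= 1e-10.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a degenerate protein motif
#'
#' Pattern language: uppercase residues match themselves, `X` matches any of
#' the 20 standard residues, and a parenthesized alternation like `(I/V)`
#' matches any listed residue. All expansions have the same fixed length.
#'
#' @param pattern Motif string, e.g. `"G(I/V)NVWCAAGK"` or `"CXXCXXXC"`.
#' @return Object of class `Motif`: a list of per-position residue sets.
#' @export
parse_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "")[[1]]
  sets <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1L]
      if (is.na(j)) stop("malformed motif: unclosed '(' in ", pattern)
      alt <- setdiff(chars[(i + 1L):(j - 1L)], "/")
      if (length(alt) == 0L || !all(alt %in% AA20)) {
        stop("malformed motif: bad alternation in ", pattern)
      }
      sets[[length(sets) + 1L]] <- alt
      i <- j + 1L
    } else if (ch == "X") {
      sets[[length(sets) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch %in% AA20) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("malformed motif: unexpected character '", ch, "' in ", pattern)
    }
  }
  structure(sets, class = "Motif", pattern = pattern)
}

#' @rdname parse_motif
#' @export
cap_helix_motif <- function() parse_motif("G(I/V)NVWCAAGK")

#' @rdname parse_motif
#' @export
ferredoxin_motif <- function() parse_motif("CXXCXXXC")

motif_regex <- function(motif) {
  paste0("(?=", paste(vapply(motif, function(s) {
    if (length(s) == 20L) "[A-Z]"
    else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = ""), ")")
}

#' Find all occurrences of a degenerate motif in a protein
#'
#' Overlapping occurrences are all reported.
#'
#' @param protein Amino-acid string (or character vector of them).
#' @param motif A [parse_motif()] object or pattern string.
#' @return Integer vector of 1-based start positions (a list of such vectors
#'   when `protein` has length > 1).
#' @export
match_motif <- function(protein, motif) {
  if (!inherits(motif, "Motif")) motif <- parse_motif(motif)
  stopifnot(all(nzchar(protein)))
  rx <- motif_regex(motif)
  res <- gregexpr(rx, protein, perl = TRUE)
  out <- lapply(res, function(m) {
    p <- as.integer(m)
    if (length(p) == 1L && p[1L] == -1L) integer(0) else p
  })
  if (length(protein) == 1L) out[[1L]] else out
}

#' Validate an hgcA candidate by the cap-helix domain
#'
#' @param protein Candidate HgcA amino-acid sequence.
#' @return TRUE iff G(I/V)NVWCAAGK occurs at least once.
#' @export
validate_hgcA <- function(protein) {
  length(match_motif(protein, cap_helix_motif())) > 0L
}

#' Strand-relative downstream ORF-rank distance
#'
#' Distance from `a` to `b` in `a`'s transcriptional downstream direction:
#' positive when `b` is downstream of `a`, `NA` when the ORFs lie on
#' different contigs. Intervening genes are counted by ORF rank regardless
#' of their strand.
#'
#' @param genome A `GenomeRecord`.
#' @param a,b ORF ids.
#' @return Integer distance, or `NA` for different contigs.
#' @export
downstream_distance <- function(genome, a, b) {
  oa <- get_orf(genome, a); ob <- get_orf(genome, b)
  if (oa$contig_id != ob$contig_id) return(NA_integer_)
  d <- ob$index_on_contig - oa$index_on_contig
  if (identical(oa$strand, "-")) d <- -d
  as.integer(d)
}

# Pick the nearest candidate among (orf_id, distance, score) rows;
# ties by highest score, then lexicographic orf id.
pick_nearest <- function(cand) {
  if (nrow(cand) == 0L) return(list(orf = NA_character_, distance = NA_integer_))
  cand <- cand[order(cand$distance, -cand$score, cand$orf_id), , drop = FALSE]
  list(orf = cand$orf_id[1L], distance = cand$distance[1L])
}

#' Pair a validated hgcA with a confident downstream hgcB
#'
#' Among motif- and score-validated hgcB candidates on the same contig at
#' downstream rank distance 1..`max_distance` (directly downstream or with
#' intervening genes, as in Desulfovibrio africanus), the nearest wins;
#' ties go to the highest score, then lexicographic ORF id.
#'
#' @param genome A `GenomeRecord`.
#' @param hgcA_orf ORF id of the validated hgcA.
#' @param hgcB_hits Hit data.frame already threshold- and motif-filtered.
#' @param max_distance Maximum downstream ORF-rank distance (default 5).
#' @param require_same_strand Also require hgcB on hgcA's strand
#'   (default FALSE; the stricter rule is exposed for sensitivity checks).
#' @return List `(orf, distance)`, both `NA` when no candidate qualifies.
#' @export
pair_hgcB <- function(genome, hgcA_orf, hgcB_hits, max_distance = 5,
                      require_same_strand = FALSE) {
  hits <- hgcB_hits[hgcB_hits$genome_id %in% c(genome$id, NA), , drop = FALSE]
  hits <- hits[hits$orf_id %in% genome$orfs$orf_id & hits$orf_id != hgcA_orf, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(list(orf = NA_character_, distance = NA_integer_))
  a <- get_orf(genome, hgcA_orf)
  d <- vapply(hits$orf_id, function(b) {
    dd <- downstream_distance(genome, hgcA_orf, b)
    if (is.na(dd)) NA_integer_ else dd
  }, integer(1))
  ok <- !is.na(d) & d >= 1L & d <= max_distance
  if (require_same_strand) {
    ok <- ok & vapply(hits$orf_id, function(b) {
      identical(get_orf(genome, b)$strand, a$strand)
    }, logical(1))
  }
  pick_nearest(data.frame(orf_id = hits$orf_id[ok], distance = d[ok],
                          score = hits$score[ok], stringsAsFactors = FALSE))
}

#' Locate the ArsR-like regulator upstream of hgcA
#'
#' Accepts candidates at strand-relative upstream rank distance
#' 1..`max_distance` (immediately upstream, or one/two genes upstream at the
#' default of 3) on the same contig; nearest wins, ties as in [pair_hgcB()].
#'
#' @param genome A `GenomeRecord`.
#' @param hgcA_orf ORF id of the validated hgcA.
#' @param reg_hits Hit data.frame already filtered at the regulator E-value
#'   cutoff.
#' @param max_distance Maximum upstream rank distance (default 3; set 2 for
#'   the narrower reading of "1 to 2 genes upstream").
#' @return List `(orf, distance)`, both `NA` when no candidate qualifies.
#' @export
find_regulator <- function(genome, hgcA_orf, reg_hits, max_distance = 3) {
  hits <- reg_hits[reg_hits$genome_id %in% c(genome$id, NA), , drop = FALSE]
  hits <- hits[hits$orf_id %in% genome$orfs$orf_id & hits$orf_id != hgcA_orf, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(list(orf = NA_character_, distance = NA_integer_))
  u <- vapply(hits$orf_id, function(b) {
    dd <- downstream_distance(genome, hgcA_orf, b)
    if (is.na(dd)) NA_integer_ else -dd
  }, integer(1))
  ok <- !is.na(u) & u >= 1L & u <= max_distance
  pick_nearest(data.frame(orf_id = hits$orf_id[ok], distance = u[ok],
                          score = hits$score[ok], stringsAsFactors = FALSE))
}

#' Configuration of the methylator-calling rules
#'
#' @param rules Named list of [threshold_rule()]s for hgcA/hgcB/regulator.
#' @param hgcB_max_distance Downstream window for hgcB (ORF ranks, default 5).
#' @param regulator_max_distance Upstream window for the regulator (default 3).
#' @param require_same_strand Require hgcB on hgcA's strand (default FALSE).
#' @return List of class `methylator_config`.
#' @export
methylator_config <- function(rules = default_rules(),
                              hgcB_max_distance = 5,
                              regulator_max_distance = 3,
                              require_same_strand = FALSE) {
  structure(list(rules = rules, hgcB_max_distance = hgcB_max_distance,
                 regulator_max_distance = regulator_max_distance,
                 require_same_strand = require_same_strand),
            class = "methylator_config")
}

empty_calls <- function() {
  data.frame(genome_id = character(0), hgcA_orf = character(0),
             hgcA_motif_ok = logical(0), hgcB_orf = character(0),
             hgcB_distance = integer(0), hgcB_same_contig = logical(0),
             regulator_orf = character(0), regulator_distance = integer(0),
             stringsAsFactors = FALSE)
}

#' Call putative methylators across a genome collection
#'
#' A genome yields one call per hgcA ORF that passes the hgcA threshold rule
#' AND carries the cap-helix domain. For each call, a confident hgcB
#' (score-, motif-, contig- and distance-validated) and an upstream
#' regulator are attached when present. Genomes with no validated hgcA are
#' absent from the output.
#'
#' @param collection A `GenomeCollection`.
#' @param hits Hit data.frame covering markers hgcA/hgcB/regulator (extra
#'   markers ignored), with `genome_id` filled.
#' @param config A [methylator_config()].
#' @return data.frame of calls with per-rule evidence columns, plus a
#'   `"filter_log"` attribute recording every hgcA candidate removed and the
#'   rule that removed it.
#' @export
call_methylators <- function(collection, hits, config = methylator_config()) {
  stopifnot(inherits(config, "methylator_config"))
  unknown <- setdiff(unique(hits$genome_id),
                     c(vapply(collection, `[[`, character(1), "id"), NA))
  if (length(unknown) > 0L) {
    stop("hits reference unknown genome(s): ", paste(unknown, collapse = ", "))
  }
  hgcA_all <- hits[hits$marker == "hgcA", , drop = FALSE]
  hgcA_pass <- filter_hits(hgcA_all, config$rules$hgcA)
  log <- data.frame(genome_id = character(0), orf_id = character(0),
                    rule = character(0), stringsAsFactors = FALSE)
  dropped <- hgcA_all[!paste(hgcA_all$genome_id, hgcA_all$orf_id) %in%
                        paste(hgcA_pass$genome_id, hgcA_pass$orf_id), ,
                      drop = FALSE]
  if (nrow(dropped) > 0L) {
    log <- rbind(log, data.frame(genome_id = dropped$genome_id,
                                 orf_id = dropped$orf_id,
                                 rule = "hgcA_threshold",
                                 stringsAsFactors = FALSE))
  }
  hgcB_pass <- filter_hits(hits, config$rules$hgcB)
  reg_pass <- filter_hits(hits, config$rules$regulator)

  calls <- empty_calls()
  for (g in collection) {
    gh <- hgcA_pass[hgcA_pass$genome_id == g$id, , drop = FALSE]
    if (nrow(gh) == 0L) next
    # hgcB candidates in this genome must also carry the ferredoxin motif
    gb <- hgcB_pass[hgcB_pass$genome_id == g$id, , drop = FALSE]
    if (nrow(gb) > 0L) {
      motif_ok <- vapply(gb$orf_id, function(o) {
        length(match_motif(get_orf(g, o)$protein, ferredoxin_motif())) > 0L
      }, logical(1))
      gb <- gb[motif_ok, , drop = FALSE]
    }
    gr <- reg_pass[reg_pass$genome_id == g$id, , drop = FALSE]
    for (i in seq_len(nrow(gh))) {
      orf <- gh$orf_id[i]
      prot <- get_orf(g, orf)$protein
      if (!validate_hgcA(prot)) {
        log <- rbind(log, data.frame(genome_id = g$id, orf_id = orf,
                                     rule = "cap_helix_missing",
                                     stringsAsFactors = FALSE))
        next
      }
      b <- pair_hgcB(g, orf, gb, config$hgcB_max_distance,
                     config$require_same_strand)
      r <- find_regulator(g, orf, gr, config$regulator_max_distance)
      calls <- rbind(calls, data.frame(
        genome_id = g$id, hgcA_orf = orf, hgcA_motif_ok = TRUE,
        hgcB_orf = b$orf, hgcB_distance = b$distance,
        hgcB_same_contig = !is.na(b$orf),
        regulator_orf = r$orf, regulator_distance = r$distance,
        stringsAsFactors = FALSE))
    }
  }
  rownames(calls) <- NULL
  attr(calls, "filter_log") <- log
  calls
}

#' Extract the gene neighborhood around an ORF
#'
#' All ORFs within `window` rank positions of the center on its contig, in
#' coordinate order — the flat table behind gene-neighborhood plots.
#'
#' @param genome A `GenomeRecord`.
#' @param center ORF id at the center.
#' @param window Rank window on each side (>= 0); truncated at contig edges.
#' @param labels Optional named character vector of product labels per ORF id.
#' @return data.frame `orf_id, contig_id, start, end, strand, index_on_contig,
#'   offset, product`.
#' @export
extract_neighborhood <- function(genome, center, window, labels = NULL) {
  stopifnot(window >= 0)
  c_orf <- get_orf(genome, center)
  o <- genome$orfs
  o <- o[o$contig_id == c_orf$contig_id &
           abs(o$index_on_contig - c_orf$index_on_contig) <= window, ,
         drop = FALSE]
  o <- o[order(o$start), , drop = FALSE]
  out <- o[, c("orf_id", "contig_id", "start", "end", "strand",
               "index_on_contig")]
  out$offset <- o$index_on_contig - c_orf$index_on_contig
  out$product <- if (is.null(labels)) "hypothetical protein" else {
    ifelse(is.na(labels[out$orf_id]), "hypothetical protein",
           labels[out$orf_id])
  }
  rownames(out) <- NULL
  out
}

#' Write a neighborhood as a BED-like table (0-based half-open)
#'
#' @param nbh Output of [extract_neighborhood()].
#' @param path File path.
#' @export
write_neighborhood_bed <- function(nbh, path) {
  bed <- data.frame(nbh$contig_id, nbh$start - 1L, nbh$end, nbh$orf_id,
                    0L, nbh$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
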