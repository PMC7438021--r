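# In-silico PCR: mismatch-tolerant scanning of IUPAC-degenerate primer pairs
# over genome contigs, amplicon calling in both orientations, and taxonomic
# cross-tabulation of amplification against called hgcA loci.

IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# Lookup matrix: rows = primer IUPAC code, cols = template base (A,C,G,T,N).
# Template N matches nothing except primer N (conservative: assembly gaps
# do not amplify).
iupac_lookup <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_DNA), ncol = 5L,
              dimnames = list(names(IUPAC_DNA), c("A", "C", "G", "T", "N")))
  for (code in names(IUPAC_DNA)) {
    m[code, strsplit(IUPAC_DNA[[code]], "")[[1]]] <- TRUE
  }
  m[, "N"] <- FALSE
  m["N", "N"] <- TRUE
  m
})

#' Does a template base satisfy an IUPAC primer code?
#'
#' Template `N` matches only primer `N` (assembly gaps never amplify).
#'
#' @param primer_char Single IUPAC nucleotide code.
#' @param base Template base in `{A,C,G,T,N}`.
#' @return Logical (vectorized over both arguments).
#' @export
iupac_match <- function(primer_char, base) {
  if (any(!primer_char %in% rownames(iupac_lookup))) {
    stop("invalid IUPAC code: ",
         paste(unique(primer_char[!primer_char %in% rownames(iupac_lookup)]),
               collapse = ", "))
  }
  if (any(!base %in% colnames(iupac_lookup))) {
    stop("invalid template base: ",
         paste(unique(base[!base %in% colnames(iupac_lookup)]), collapse = ", "))
  }
  iupac_lookup[cbind(primer_char, base)]
}

#' Construct a Primer
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string (5'->3').
#' @return Object of class `Primer`.
#' @export
primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) ||
      any(!strsplit(sequence, "")[[1]] %in% names(IUPAC_DNA))) {
    stop("primer ", name, ": invalid IUPAC sequence '", sequence, "'")
  }
  structure(list(name = name, sequence = sequence), class = "Primer")
}

#' Count primer/template mismatches over a window
#'
#' @param primer A [primer()] (or IUPAC string).
#' @param window Template string of the same length.
#' @return Number of positions failing [iupac_match()].
#' @export
count_mismatches <- function(primer, window) {
  seq <- if (inherits(primer, "Primer")) primer$sequence else toupper(primer)
  if (nchar(seq) != nchar(window)) {
    stop("window length ", nchar(window), " != primer length ", nchar(seq))
  }
  sum(!iupac_match(strsplit(seq, "")[[1]],
                   strsplit(toupper(window), "")[[1]]))
}

# Reverse complement preserving IUPAC codes (plain-string fast path).
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", s),
                       "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All placements of a primer on the given strand of `seq_chars` with
# mismatches <= max_mm. Returns data.frame(start, end, mismatches).
# Vectorized: one pass per primer position over all windows.
find_primer_sites <- function(seq_chars, primer_seq, max_mm,
                              anchor_3prime = FALSE) {
  p <- strsplit(primer_seq, "")[[1]]
  m <- length(p); L <- length(seq_chars)
  nwin <- L - m + 1L
  if (nwin < 1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  mm <- integer(nwin)
  for (k in seq_len(m)) {
    mm <- mm + !iupac_lookup[p[k], seq_chars[k:(k + nwin - 1L)]]
  }
  keep <- mm <= max_mm
  if (anchor_3prime) {
    keep <- keep & iupac_lookup[p[m], seq_chars[m:(m + nwin - 1L)]]
  }
  data.frame(start = which(keep), end = which(keep) + m - 1L,
             mismatches = mm[keep])
}

empty_amplicons <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
             fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             product_length = integer(0), fwd_mismatches = integer(0),
             rev_mismatches = integer(0), orientation = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a contig for primer-pair amplicons
#'
#' Reports every pairing of a forward-primer match with a downstream match
#' of the reverse primer's reverse complement on the same strand, in both
#' template orientations, with per-primer mismatch counts at or below
#' `max_mismatches` and product length at most `max_product`. Coordinates
#' are always reported on the plus strand; overlapping/nested products are
#' all reported.
#'
#' @param sequence Contig nucleotide string (A/C/G/T/N).
#' @param fwd,rev Forward and reverse [primer()]s (5'->3', as ordered).
#' @param max_mismatches Per-primer mismatch tolerance (0 and 2 being the
#'   conventional settings).
#' @param max_product Maximum product span in bp (default 10000).
#' @param anchor_3prime Require the 3'-terminal primer base to match exactly
#'   (default FALSE: the mismatch allowance is a global count).
#' @param contig_id,genome_id Identifiers copied into the output.
#' @return data.frame of amplicon hits (see fields of the empty value).
#' @export
scan_amplicons <- function(sequence, fwd, rev, max_mismatches = 2,
                           max_product = 10000, anchor_3prime = FALSE,
                           contig_id = NA_character_,
                           genome_id = NA_character_) {
  stopifnot(max_mismatches >= 0, inherits(fwd, "Primer"),
            inherits(rev, "Primer"))
  lf <- nchar(fwd$sequence); lr <- nchar(rev$sequence)
  if (max_product <= lf + lr) stop("max_product must exceed |fwd| + |rev|")
  sequence <- toupper(sequence)
  L <- nchar(sequence)

  scan_strand <- function(chars) {
    f <- find_primer_sites(chars, fwd$sequence, max_mismatches, anchor_3prime)
    r <- find_primer_sites(chars, revcomp(rev$sequence), max_mismatches,
                           anchor_3prime)
    if (nrow(f) == 0L || nrow(r) == 0L) return(NULL)
    pairs <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
    fs <- f$start[pairs$fi]; fe <- f$end[pairs$fi]
    rs <- r$start[pairs$ri]; re <- r$end[pairs$ri]
    ok <- rs > fe & (re - fs + 1L) <= max_product
    if (!any(ok)) return(NULL)
    data.frame(fwd_start = fs[ok], fwd_end = fe[ok],
               rev_start = rs[ok], rev_end = re[ok],
               product_length = re[ok] - fs[ok] + 1L,
               fwd_mismatches = f$mismatches[pairs$fi][ok],
               rev_mismatches = r$mismatches[pairs$ri][ok])
  }

  plus_chars <- strsplit(sequence, "")[[1]]
  plus <- scan_strand(plus_chars)
  minus <- scan_strand(rev(chartr("ACGT", "TGCA", plus_chars)))
  out <- empty_amplicons()
  if (!is.null(plus)) {
    plus$orientation <- "plus"
    out <- rbind(out, cbind(genome_id = genome_id, contig_id = contig_id,
                            plus, stringsAsFactors = FALSE))
  }
  if (!is.null(minus)) {
    # mirror coordinates back to the plus strand
    mirrored <- data.frame(
      fwd_start = L - minus$fwd_end + 1L, fwd_end = L - minus$fwd_start + 1L,
      rev_start = L - minus$rev_end + 1L, rev_end = L - minus$rev_start + 1L,
      product_length = minus$product_length,
      fwd_mismatches = minus$fwd_mismatches,
      rev_mismatches = minus$rev_mismatches,
      orientation = "minus", stringsAsFactors = FALSE)
    out <- rbind(out, cbind(genome_id = genome_id, contig_id = contig_id,
                            mirrored, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Scan every contig of a collection for amplicons
#'
#' @param collection A `GenomeCollection`.
#' @inheritParams scan_amplicons
#' @return Row-bound amplicon hits across all contigs.
#' @export
scan_collection <- function(collection, fwd, rev, max_mismatches = 2,
                            max_product = 10000, anchor_3prime = FALSE) {
  out <- lapply(collection, function(g) {
    per <- lapply(names(g$contigs), function(cid) {
      scan_amplicons(g$contigs[[cid]], fwd, rev, max_mismatches, max_product,
                     anchor_3prime, contig_id = cid, genome_id = g$id)
    })
    do.call(rbind, per)
  })
  res <- do.call(rbind, c(list(empty_amplicons()), out))
  rownames(res) <- NULL
  res
}

#' Cross-tabulate amplification against called hgcA loci, by group
#'
#' For each phylum-level group: how many genomes carry a called hgcA, how
#' many amplified at each mismatch setting, and how many amplicons overlap
#' the called hgcA ORF (on-target by coordinate overlap).
#'
#' @param hits Amplicon hits (from [scan_collection()] at the loosest
#'   setting of interest; per-setting counts reuse the per-primer mismatch
#'   columns).
#' @param collection A `GenomeCollection` with taxonomy.
#' @param calls Methylator calls from [call_methylators()].
#' @param mismatch_settings Integer settings to tabulate (default `c(0, 2)`).
#' @param class_groups Classes promoted to group rank (see [genome_group()]).
#' @return data.frame, one row per group present in the collection, columns
#'   `group, n_genomes, n_hgcA, amplified_mm<k>..., on_target_mm<k>...`.
#' @export
crosstab_amplification <- function(hits, collection, calls,
                                   mismatch_settings = c(0, 2),
                                   class_groups = "Deltaproteobacteria") {
  groups <- vapply(collection, genome_group, character(1),
                   class_groups = class_groups)
  if (anyNA(groups)) stop("taxonomy (phylum) missing for some genomes")
  gids <- vapply(collection, `[[`, character(1), "id")
  ug <- sort(unique(groups))
  out <- data.frame(group = ug,
                    n_genomes = as.integer(table(groups)[ug]),
                    n_hgcA = vapply(ug, function(p) {
                      length(unique(calls$genome_id[
                        calls$genome_id %in% gids[groups == p]]))
                    }, integer(1)),
                    stringsAsFactors = FALSE)
  # coordinates of called hgcA ORFs for the on-target flag
  on_target_hit <- function(h) {
    sub <- calls[calls$genome_id == h$genome_id, , drop = FALSE]
    if (nrow(sub) == 0L) return(FALSE)
    g <- collection[[h$genome_id]]
    span_start <- min(h$fwd_start, h$rev_start)
    span_end <- max(h$fwd_end, h$rev_end)
    any(vapply(sub$hgcA_orf, function(o) {
      orf <- get_orf(g, o)
      orf$contig_id == h$contig_id &&
        span_start <= orf$end && span_end >= orf$start
    }, logical(1)))
  }
  for (mset in mismatch_settings) {
    sel <- hits[hits$fwd_mismatches <= mset & hits$rev_mismatches <= mset, ,
                drop = FALSE]
    amp <- vapply(ug, function(p) {
      length(unique(sel$genome_id[sel$genome_id %in% gids[groups == p]]))
    }, integer(1))
    ont <- vapply(ug, function(p) {
      sub <- sel[sel$genome_id %in% gids[groups == p], , drop = FALSE]
      if (nrow(sub) == 0L) return(0L)
      hit_ok <- vapply(seq_len(nrow(sub)), function(i) {
        on_target_hit(sub[i, , drop = FALSE])
      }, logical(1))
      length(unique(sub$genome_id[hit_ok]))
    }, integer(1))
    out[[paste0("amplified_mm", mset)]] <- amp
    out[[paste0("on_target_mm", mset)]] <- ont
  }
  rownames(out) <- NULL
  out
}

#' Read a primer-pair configuration table
#'
#' Tab-separated with header `name, fwd_seq, rev_seq, target_group`.
#'
#' @param path File path.
#' @return data.frame with one row per primer pair.
#' @export
read_primer_config <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "fwd_seq", "rev_seq") %in% names(p)))
  p
}

#' Export amplicon spans as BED (0-based half-open)
#'
#' @param hits Amplicon hits.
#' @param path File path.
#' @export
write_amplicon_bed <- function(hits, path) {
  bed <- data.frame(hits$contig_id, hits$fwd_start - 1L, hits$rev_end,
                    paste0(hits$genome_id, "_amp", seq_len(nrow(hits))),
                    hits$fwd_mismatches + hits$rev_mismatches,
                    ifelse(hits$orientation == "plus", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
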