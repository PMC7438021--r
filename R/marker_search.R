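# Profile-search hit handling: parse hmmer-style tabular output, apply the
# score/E-value threshold rules, and a naive position-specific scorer used as
# a no-dependency stand-in for external profile search in offline tests.

#' Threshold rule for one marker
#'
#' The shipped defaults encode the screening cutoffs: hgcA hits are retained
#' at E-value <= 1e-50 AND bit score >= 300; hgcB at score strictly > 70;
#' the upstream regulator at E-value <= 1e-10.
#'
#' @param marker Marker id the rule applies to.
#' @param max_evalue Retain hits with `evalue <= max_evalue` (NULL = no bound).
#' @param min_score Retain hits with `score >= min_score` (or `>` when
#'   `min_score_exclusive`); NULL = no bound.
#' @param min_score_exclusive Use a strict `>` comparison on the score.
#' @return Object of class `ThresholdRule`.
#' @export
threshold_rule <- function(marker, max_evalue = NULL, min_score = NULL,
                           min_score_exclusive = FALSE) {
  if (is.null(max_evalue) && is.null(min_score)) {
    stop("at least one of max_evalue / min_score must be set")
  }
  structure(list(marker = marker, max_evalue = max_evalue,
                 min_score = min_score,
                 min_score_exclusive = isTRUE(min_score_exclusive)),
            class = "ThresholdRule")
}

#' Default threshold rules for the methylator screen
#' @return Named list of [threshold_rule()] objects for hgcA, hgcB and the
#'   upstream regulator.
#' @export
default_rules <- function() {
  list(
    hgcA = threshold_rule("hgcA", max_evalue = 1e-50, min_score = 300),
    hgcB = threshold_rule("hgcB", min_score = 70, min_score_exclusive = TRUE),
    regulator = threshold_rule("regulator", max_evalue = 1e-10))
}

empty_hits <- function() {
  data.frame(genome_id = character(0), orf_id = character(0),
             marker = character(0), evalue = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Collapse duplicate (genome, orf, marker) rows keeping the best score.
dedup_hits <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  key <- paste(hits$genome_id, hits$orf_id, hits$marker, sep = "\r")
  ord <- order(key, -hits$score)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Parse a profile-HMM search hit table (tblout dialect)
#'
#' Reads the whitespace-delimited per-sequence table written by standard
#' profile-HMM search tools (`--tblout`): comment lines start with `#`;
#' column 1 is the target (ORF) id, column 3 the query (marker) id, columns
#' 5 and 6 the full-sequence E-value and bit score. Duplicate (ORF, marker)
#' rows are collapsed keeping the best score. The tabular output carries no
#' genome id; see [assign_genomes()].
#'
#' @param path Path to the hit table.
#' @return data.frame with columns `genome_id` (NA), `orf_id`, `marker`,
#'   `evalue`, `score`.
#' @export
parse_hit_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("line ", lineno[which(nf < 6L)[1L]], ": fewer than 6 fields")
  }
  get_num <- function(k) {
    raw <- vapply(fields, `[[`, character(1), k)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      stop("line ", lineno[which(is.na(val))[1L]],
           ": malformed numeric field '", raw[which(is.na(val))[1L]], "'")
    }
    val
  }
  hits <- data.frame(
    genome_id = NA_character_,
    orf_id = vapply(fields, `[[`, character(1), 1L),
    marker = vapply(fields, `[[`, character(1), 3L),
    evalue = get_num(5L),
    score = get_num(6L),
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) stop("negative E-value in ", path)
  dedup_hits(hits)
}

#' Fill in genome ids for hits by ORF lookup
#'
#' @param hits Hit data.frame (as from [parse_hit_table()]).
#' @param collection A `GenomeCollection` whose ORF ids resolve the hits.
#' @return `hits` with `genome_id` filled; unknown ORFs raise an error.
#' @export
assign_genomes <- function(hits, collection) {
  map <- unlist(lapply(collection, function(g) {
    setNames(rep(g$id, nrow(g$orfs)), g$orfs$orf_id)
  }), use.names = TRUE)
  gid <- map[hits$orf_id]
  if (anyNA(gid) && nrow(hits) > 0L) {
    stop("hit ORF(s) not found in collection: ",
         paste(head(hits$orf_id[is.na(gid)], 3L), collapse = ", "))
  }
  hits$genome_id <- unname(gid)
  hits
}

#' Read / write the package's delimited hit-table dialect
#'
#' Tab-separated with header `genome_id, orf_id, marker, evalue, score`.
#'
#' @param path File path.
#' @return `read_hits()`: deduplicated hit data.frame.
#' @export
read_hits <- function(path) {
  h <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "orf_id", "marker", "evalue", "score")
                %in% names(h)))
  dedup_hits(h[, c("genome_id", "orf_id", "marker", "evalue", "score")])
}

#' @param hits Hit data.frame.
#' @rdname read_hits
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter hits by a threshold rule
#'
#' Retains hits with `evalue <= max_evalue` (when set) AND `score >=
#' min_score` (strict `>` when the rule is exclusive, as for hgcB's
#' "greater than 70"). Order is preserved; filtering is monotone in both
#' thresholds and idempotent.
#'
#' @param hits Hit data.frame.
#' @param rule A [threshold_rule()]; its marker must match the hits filtered.
#' @return The retained subset.
#' @export
filter_hits <- function(hits, rule) {
  stopifnot(inherits(rule, "ThresholdRule"))
  h <- hits[hits$marker == rule$marker, , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  if (!is.null(rule$max_evalue)) keep <- keep & h$evalue <= rule$max_evalue
  if (!is.null(rule$min_score)) {
    keep <- keep & if (rule$min_score_exclusive) h$score > rule$min_score
                   else h$score >= rule$min_score
  }
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive position-specific profile scorer
#'
#' Scores a protein against a per-column residue log-odds table by the best
#' ungapped placement of the profile along the sequence: the maximum over
#' placements of the sum of per-column log-odds. A deliberately simple,
#' deterministic stand-in for external profile search in offline tests.
#'
#' @param protein Amino-acid string.
#' @param profile Numeric matrix, rows named by the 20 residues, one column
#'   per profile position.
#' @return Best placement score (numeric scalar).
#' @export
naive_profile_score <- function(protein, profile) {
  stopifnot(is.matrix(profile), !is.null(rownames(profile)),
            all(is.finite(profile)))
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa); m <- ncol(profile)
  if (n < m) stop("sequence shorter than profile (", n, " < ", m, ")")
  if (!all(aa %in% rownames(profile))) {
    stop("residue(s) absent from profile rows: ",
         paste(unique(aa[!aa %in% rownames(profile)]), collapse = ""))
  }
  ridx <- match(aa, rownames(profile))
  scores <- vapply(seq_len(n - m + 1L), function(s) {
    sum(profile[cbind(ridx[s:(s + m - 1L)], seq_len(m))])
  }, numeric(1))
  max(scores)
}
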