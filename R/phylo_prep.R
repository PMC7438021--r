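# Supermatrix preparation for concatenated-marker phylogenies: the
# 12-of-16 ribosomal-marker completeness rule, per-marker alignment
# concatenation with gap fill, and a gap-fraction + minimum-block-size
# column mask. Alignment and tree inference are external.

#' The default rp16 ribosomal-protein marker set
#'
#' A conventional set of 16 syntenic single-copy ribosomal proteins used for
#' concatenated species trees. The membership is configurable everywhere it
#' is consumed and should not be treated as canonical.
#'
#' @return Character vector of 16 marker names.
#' @export
rp16_markers <- function() {
  c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15", "rpL16",
    "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS10", "rpS17", "rpS19")
}

#' Construct a per-marker alignment
#'
#' @param marker Marker name.
#' @param rows Named character vector genome_id -> aligned amino-acid string
#'   (gaps as `-`); all rows must share one width.
#' @return Object of class `MarkerAlignment`.
#' @export
marker_alignment <- function(marker, rows) {
  stopifnot(is.character(rows), length(rows) > 0L, !is.null(names(rows)))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("marker ", marker, ": rows of unequal width")
  if (anyDuplicated(names(rows))) stop("marker ", marker, ": duplicate genome id")
  structure(list(marker = marker, rows = rows, width = w),
            class = "MarkerAlignment")
}

#' Read / write an aligned FASTA as a MarkerAlignment
#'
#' @param path Aligned protein FASTA.
#' @param marker Marker name to attach.
#' @return `read_alignment()`: a [marker_alignment()].
#' @export
read_alignment <- function(path, marker = sub("\\.[^.]*$", "", basename(path))) {
  aa <- Biostrings::readAAStringSet(path)
  marker_alignment(marker, setNames(as.character(aa), sub("\\s.*$", "", names(aa))))
}

#' @param aln A `MarkerAlignment`.
#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(aln$rows), path, width = 80L)
  invisible(path)
}

#' Apply the marker-completeness rule
#'
#' Genomes are included in the concatenated tree only when they contain at
#' least `min_markers` of the marker set (12 of 16 at the defaults).
#'
#' @param per_genome_markers Named list: genome id -> character vector of
#'   markers found in that genome.
#' @param min_markers Minimum marker count (inclusive; default 12).
#' @param markers Universe of valid markers (default [rp16_markers()]).
#' @return Character vector of retained genome ids.
#' @export
filter_marker_completeness <- function(per_genome_markers, min_markers = 12,
                                       markers = rp16_markers()) {
  stopifnot(min_markers <= length(markers))
  counts <- vapply(per_genome_markers, function(x) {
    length(intersect(unique(x), markers))
  }, integer(1))
  names(counts)[counts >= min_markers]
}

#' Concatenate per-marker alignments into a supermatrix
#'
#' Genomes missing a marker receive an all-gap block of that marker's width;
#' the partition table records each marker's column span.
#'
#' @param alignments List of [marker_alignment()]s.
#' @param genomes Genome ids to include (default: union over alignments).
#'   A requested genome present in no alignment is an error.
#' @return Object of class `Supermatrix`: list with `rows` (named character)
#'   and `partitions` (data.frame `marker, start, end`).
#' @export
concatenate <- function(alignments, genomes = NULL) {
  stopifnot(length(alignments) > 0L,
            all(vapply(alignments, inherits, logical(1), "MarkerAlignment")))
  seen <- unique(unlist(lapply(alignments, function(a) names(a$rows))))
  if (is.null(genomes)) genomes <- sort(seen)
  absent <- setdiff(genomes, seen)
  if (length(absent) > 0L) {
    stop("genome(s) present in no alignment: ", paste(absent, collapse = ", "))
  }
  widths <- vapply(alignments, `[[`, integer(1), "width")
  ends <- cumsum(widths)
  partitions <- data.frame(
    marker = vapply(alignments, `[[`, character(1), "marker"),
    start = c(1L, head(ends, -1L) + 1L),
    end = ends, stringsAsFactors = FALSE)
  rows <- vapply(genomes, function(g) {
    paste(vapply(alignments, function(a) {
      if (g %in% names(a$rows)) a$rows[[g]]
      else strrep("-", a$width)
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(rows = rows, partitions = partitions), class = "Supermatrix")
}

#' @export
print.Supermatrix <- function(x, ...) {
  cat("<Supermatrix> ", length(x$rows), " genome(s) x ",
      nchar(x$rows[[1L]]), " column(s), ", nrow(x$partitions),
      " partition(s)\n", sep = "")
  invisible(x)
}

#' Mask gappy columns and short blocks
#'
#' A simplified alignment-trimming mask: drops columns whose gap fraction
#' strictly exceeds `max_gap_fraction`, then drops surviving runs of kept
#' columns shorter than `min_block`. Defaults (0.5, 5) mirror conventional
#' block-filtering settings. Partitions are remapped to the kept columns;
#' externally trimmed alignments can be supplied instead wherever a
#' `Supermatrix` is accepted.
#'
#' @param matrix A `Supermatrix`.
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (in \[0,1\], default 0.5).
#' @param min_block Minimum run length of kept columns (default 5).
#' @return Masked `Supermatrix`; error if no column survives.
#' @export
mask_columns <- function(matrix, max_gap_fraction = 0.5, min_block = 5) {
  stopifnot(inherits(matrix, "Supermatrix"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  chars <- do.call(rbind, strsplit(unname(matrix$rows), ""))
  gap_frac <- colMeans(chars == "-")
  keep <- gap_frac <= max_gap_fraction
  # drop kept runs shorter than min_block
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) stop("empty matrix after masking")
  kept_idx <- which(keep)
  rows <- vapply(seq_along(matrix$rows), function(i) {
    paste(chars[i, kept_idx], collapse = "")
  }, character(1))
  names(rows) <- names(matrix$rows)
  # remap partitions: marker of each kept column, runs stay contiguous
  old_marker <- rep(matrix$partitions$marker,
                    matrix$partitions$end - matrix$partitions$start + 1L)
  km <- old_marker[kept_idx]
  rr <- rle(km)
  ends <- cumsum(rr$lengths)
  partitions <- data.frame(marker = rr$values,
                           start = c(1L, head(ends, -1L) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  structure(list(rows = rows, partitions = partitions), class = "Supermatrix")
}

#' Write a supermatrix as aligned FASTA plus a partition file
#'
#' The partition file uses `marker = start-end` lines, the dialect common
#' tree-inference tools accept.
#'
#' @param matrix A `Supermatrix`.
#' @param fasta,partitions Output paths (`partitions = NULL` to skip).
#' @export
write_supermatrix <- function(matrix, fasta, partitions = NULL) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(matrix$rows), fasta, width = 80L)
  if (!is.null(partitions)) {
    writeLines(sprintf("%s = %d-%d", matrix$partitions$marker,
                       matrix$partitions$start, matrix$partitions$end),
               partitions)
  }
  invisible(fasta)
}
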