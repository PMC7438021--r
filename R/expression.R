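# Metatranscriptome expression: TPM normalization of ORF-level counts and
# phylum-level marker aggregations (per-phylum hgcA totals, per-phylum
# genome-average expression, rpoB comparison).

#' Construct an ORF-level count matrix
#'
#' @param counts Numeric matrix, rows = ORFs, cols = samples; non-negative.
#' @param orf_info data.frame `orf_id, genome_id, length_bp` aligned to the
#'   rows of `counts`.
#' @return Object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, orf_info) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(orf_info),
            all(c("orf_id", "genome_id", "length_bp") %in% names(orf_info)))
  if (any(counts < 0)) stop("negative count")
  if (any(orf_info$length_bp <= 0)) stop("non-positive ORF length")
  if (anyDuplicated(orf_info$orf_id)) stop("duplicate ORF id")
  rownames(counts) <- orf_info$orf_id
  structure(list(counts = counts, orf_info = as.data.frame(orf_info),
                 samples = colnames(counts)),
            class = "CountMatrix")
}

#' Read / write the delimited count-matrix dialect
#'
#' Tab-separated with columns `orf_id, genome_id, length_bp, <sample ids>`.
#'
#' @param path File path.
#' @return `read_counts()`: a [count_matrix()].
#' @export
read_counts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("orf_id", "genome_id", "length_bp") %in% names(d)))
  samples <- setdiff(names(d), c("orf_id", "genome_id", "length_bp"))
  count_matrix(as.matrix(d[, samples, drop = FALSE]),
               d[, c("orf_id", "genome_id", "length_bp")])
}

#' @param x A `CountMatrix` (or TPM matrix of the same shape).
#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  out <- cbind(x$orf_info[, c("orf_id", "genome_id", "length_bp")],
               as.data.frame(x$counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TPM-normalize an ORF-level count matrix
#'
#' Per sample: `rate_i = count_i / length_i`; `TPM_i = 1e6 * rate_i /
#' sum_j rate_j`. Every nonzero sample column of the result sums to one
#' million; all-zero columns (samples where nothing was detected, as in
#' palsa sites) stay all-zero rather than erroring. The result is invariant
#' under a uniform rescaling of lengths (bp vs kb).
#'
#' @param x A [count_matrix()].
#' @return A `CountMatrix`-shaped object of class `c("TpmMatrix",
#'   "CountMatrix")` whose `counts` slot holds TPM values.
#' @export
tpm_normalize <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  rate <- x$counts / x$orf_info$length_bp
  denom <- colSums(rate)
  tpm <- sweep(rate, 2L, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  structure(list(counts = tpm, orf_info = x$orf_info, samples = x$samples),
            class = c("TpmMatrix", "CountMatrix"))
}

marker_orf_column <- c(hgcA = "hgcA_orf", hgcB = "hgcB_orf",
                       regulator = "regulator_orf")

#' Per-group marker expression totals (TPM)
#'
#' For each phylum-level group and sample, the sum of TPM over that group's
#' called marker ORFs, plus the per-sample grand total over all called
#' marker ORFs.
#'
#' @param tpm A [tpm_normalize()]d matrix.
#' @param calls Methylator calls from [call_methylators()].
#' @param marker One of `"hgcA"`, `"hgcB"`, `"regulator"`.
#' @param collection The `GenomeCollection` supplying taxonomy.
#' @param class_groups Classes promoted to group rank.
#' @return List: `group_tpm` (numeric matrix groups x samples) and `total`
#'   (named numeric per-sample totals, computed directly over all marker
#'   ORFs).
#' @export
marker_expression_by_group <- function(tpm, calls,
                                       marker = c("hgcA", "hgcB", "regulator"),
                                       collection,
                                       class_groups = "Deltaproteobacteria") {
  marker <- match.arg(marker)
  stopifnot(inherits(tpm, "TpmMatrix"))
  col <- marker_orf_column[[marker]]
  sub <- calls[!is.na(calls[[col]]), , drop = FALSE]
  orfs <- sub[[col]]
  missing <- setdiff(orfs, rownames(tpm$counts))
  if (length(missing) > 0L) {
    stop("called ", marker, " ORF(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  }
  groups <- vapply(unclass(collection)[unique(calls$genome_id)],
                   genome_group, character(1), class_groups = class_groups)
  ug <- sort(unique(unname(groups)))
  out <- matrix(0, nrow = length(ug), ncol = length(tpm$samples),
                dimnames = list(ug, tpm$samples))
  for (i in seq_len(nrow(sub))) {
    grp <- groups[[sub$genome_id[i]]]
    out[grp, ] <- out[grp, ] + tpm$counts[orfs[i], ]
  }
  total <- colSums(tpm$counts[orfs, , drop = FALSE])
  list(group_tpm = out, total = total)
}

#' Per-group genome-average expression (TPM)
#'
#' Per group and sample: the sum of TPM over all ORFs of all genomes in the
#' group, divided by the number of genomes in the group — the average
#' overall activity of the group's genomes.
#'
#' @param tpm A [tpm_normalize()]d matrix.
#' @param collection The `GenomeCollection` supplying membership/taxonomy.
#' @param class_groups Classes promoted to group rank.
#' @return Numeric matrix, groups x samples.
#' @export
genome_average_by_group <- function(tpm, collection,
                                    class_groups = "Deltaproteobacteria") {
  stopifnot(inherits(tpm, "TpmMatrix"))
  groups <- vapply(collection, genome_group, character(1),
                   class_groups = class_groups)
  ug <- sort(unique(unname(groups[!is.na(groups)])))
  out <- matrix(0, nrow = length(ug), ncol = length(tpm$samples),
                dimnames = list(ug, tpm$samples))
  orf_group <- groups[tpm$orf_info$genome_id]
  for (grp in ug) {
    sel <- !is.na(orf_group) & orf_group == grp
    n_genomes <- sum(groups == grp, na.rm = TRUE)
    out[grp, ] <- colSums(tpm$counts[sel, , drop = FALSE]) / n_genomes
  }
  out
}

#' Pair hgcA expression with rpoB housekeeping expression
#'
#' For every called genome and sample: total TPM of its called hgcA ORF(s)
#' against the TPM of its best-scoring rpoB ORF. Genomes without a
#' confident rpoB are excluded from the pairs and reported in the
#' `"missing_rpoB"` attribute.
#'
#' @param tpm A [tpm_normalize()]d matrix.
#' @param calls Methylator calls.
#' @param rpoB_hits Hit data.frame for the rpoB marker (best score per
#'   genome is used).
#' @return data.frame `genome_id, sample, hgcA_tpm, rpoB_tpm` with attribute
#'   `"missing_rpoB"`.
#' @export
compare_to_housekeeping <- function(tpm, calls, rpoB_hits) {
  stopifnot(inherits(tpm, "TpmMatrix"))
  rpoB_hits <- rpoB_hits[rpoB_hits$marker == "rpoB" &
                           rpoB_hits$orf_id %in% rownames(tpm$counts), ,
                         drop = FALSE]
  best <- rpoB_hits[order(rpoB_hits$genome_id, -rpoB_hits$score), , drop = FALSE]
  best <- best[!duplicated(best$genome_id), , drop = FALSE]
  genomes <- unique(calls$genome_id)
  missing <- setdiff(genomes, best$genome_id)
  paired <- setdiff(genomes, missing)
  rows <- lapply(paired, function(gid) {
    horfs <- calls$hgcA_orf[calls$genome_id == gid]
    horfs <- horfs[horfs %in% rownames(tpm$counts)]
    h <- if (length(horfs) > 0L) {
      colSums(tpm$counts[horfs, , drop = FALSE])
    } else setNames(rep(0, length(tpm$samples)), tpm$samples)
    r <- tpm$counts[best$orf_id[best$genome_id == gid], ]
    data.frame(genome_id = gid, sample = tpm$samples,
               hgcA_tpm = unname(h), rpoB_tpm = unname(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(genome_id = character(0),
                                          sample = character(0),
                                          hgcA_tpm = numeric(0),
                                          rpoB_tpm = numeric(0))), rows))
  rownames(out) <- NULL
  attr(out, "missing_rpoB") <- missing
  out
}
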