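# Guild-level metabolic profiling: genome x marker presence/absence from
# threshold-filtered hits, summarized as group percentages with
# multi-subunit complexes (nif/nar/nir/nor/nos) averaged across subunits.

#' Define a marker set (single marker or multi-subunit complex)
#'
#' @param name Set name shown in summaries (e.g. `"nifDHK"`).
#' @param members Marker ids belonging to the set (e.g. nifD, nifH, nifK).
#' @param averaged Average per-subunit group percentages across members
#'   (the convention for nif/nar/nir/nor/nos complexes); when FALSE the set
#'   must have a single member.
#' @return Object of class `MarkerSet`.
#' @export
marker_set <- function(name, members, averaged = length(members) > 1L) {
  stopifnot(length(members) >= 1L)
  if (!averaged && length(members) > 1L) {
    stop("non-averaged marker set must have exactly one member")
  }
  structure(list(name = name, members = members, averaged = averaged),
            class = "MarkerSet")
}

#' Build a genome x marker presence/absence matrix
#'
#' A cell is TRUE iff at least one hit for that marker in that genome passes
#' the marker's threshold rule.
#'
#' @param collection A `GenomeCollection` (defines the rows).
#' @param hits Hit data.frame with `genome_id` filled.
#' @param rules Named list of [threshold_rule()]s; names define the columns.
#' @return Logical matrix, rows = genome ids, cols = marker ids.
#' @export
build_presence_matrix <- function(collection, hits, rules) {
  gids <- vapply(collection, `[[`, character(1), "id")
  unknown <- setdiff(unique(hits$genome_id), c(gids, NA))
  if (length(unknown) > 0L) {
    stop("hits reference unknown genome(s): ", paste(unknown, collapse = ", "))
  }
  m <- matrix(FALSE, nrow = length(gids), ncol = length(rules),
              dimnames = list(gids, names(rules)))
  for (marker in names(rules)) {
    passed <- filter_hits(hits, rules[[marker]])
    m[unique(passed$genome_id), marker] <- TRUE
  }
  m
}

#' Summarize marker presence as group-level percentages
#'
#' Genomes are first filtered by quality (defaults mirroring the
#' high-quality screen: completeness > 90, redundancy < 10); groups
#' (phyla, with configurable class-rank promotions) with strictly more than
#' `min_group_size` genomes are retained. Unaveraged sets report
#' `100 * present / group size`; averaged complexes compute per-subunit
#' percentages and then take their arithmetic mean.
#'
#' @param matrix Presence matrix from [build_presence_matrix()].
#' @param collection The `GenomeCollection` the matrix rows came from.
#' @param sets List of [marker_set()]s.
#' @param min_group_size Retain groups with more than this many genomes
#'   (strict; default 5).
#' @param min_completeness,max_redundancy Quality cutoffs (strict, percent).
#' @param class_groups Classes promoted to group rank.
#' @return Long data.frame `group, marker_set, percent`.
#' @export
summarize_groups <- function(matrix, collection, sets, min_group_size = 5,
                             min_completeness = 90, max_redundancy = 10,
                             class_groups = "Deltaproteobacteria") {
  hq <- filter_by_quality(collection, min_completeness, max_redundancy)
  hq_ids <- intersect(rownames(matrix),
                      vapply(hq, `[[`, character(1), "id"))
  groups <- vapply(unclass(hq)[hq_ids], genome_group, character(1),
                   class_groups = class_groups)
  tab <- table(groups[!is.na(groups)])
  keep_groups <- names(tab)[tab > min_group_size]
  out <- data.frame(group = character(0), marker_set = character(0),
                    percent = numeric(0), stringsAsFactors = FALSE)
  for (grp in keep_groups) {
    ids <- hq_ids[!is.na(groups) & groups == grp]
    n <- length(ids)
    for (s in sets) {
      missing <- setdiff(s$members, colnames(matrix))
      if (length(missing) > 0L) {
        stop("marker(s) absent from presence matrix: ",
             paste(missing, collapse = ", "))
      }
      per_subunit <- vapply(s$members, function(mk) {
        100 * sum(matrix[ids, mk]) / n
      }, numeric(1))
      pct <- if (s$averaged) mean(per_subunit) else per_subunit[[1L]]
      out <- rbind(out, data.frame(group = grp, marker_set = s$name,
                                   percent = pct, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a metabolic-marker configuration table
#'
#' Tab-separated with header `marker_id, set_name, averaged,
#' min_score_or_evalue`: values > 1 are treated as curated minimum bit
#' scores, values <= 1 as maximum E-values (falling back to E <= 1e-10 when
#' empty).
#'
#' @param path File path.
#' @return List with `rules` (per marker) and `sets` (list of [marker_set()]).
#' @export
read_marker_config <- function(path) {
  cfg <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "set_name", "averaged") %in% names(cfg)))
  rules <- lapply(seq_len(nrow(cfg)), function(i) {
    cut <- if ("min_score_or_evalue" %in% names(cfg)) {
      suppressWarnings(as.numeric(cfg$min_score_or_evalue[i]))
    } else NA_real_
    if (is.na(cut)) threshold_rule(cfg$marker_id[i], max_evalue = 1e-10)
    else if (cut > 1) threshold_rule(cfg$marker_id[i], min_score = cut)
    else threshold_rule(cfg$marker_id[i], max_evalue = cut)
  })
  names(rules) <- cfg$marker_id
  sets <- lapply(split(seq_len(nrow(cfg)), cfg$set_name), function(idx) {
    marker_set(cfg$set_name[idx[1L]], cfg$marker_id[idx],
               averaged = any(as.logical(cfg$averaged[idx])))
  })
  list(rules = rules, sets = unname(sets))
}
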