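# Pipeline orchestration: each run_* stage reads its inputs from a single
# declarative config, writes delimited outputs plus a manifest (config
# snapshot, seed, input checksums, package version) sufficient to reproduce
# results byte-identically.

#' Build a pipeline configuration
#'
#' Defaults encode the screening constants: hgcA at E <= 1e-50 and score
#' >= 300, hgcB at score > 70 within 5 ORFs downstream on the same contig,
#' regulator at E <= 1e-10 within 3 genes upstream, genome quality > 50% /
#' < 10%, high-quality guild screen at > 90% / < 10% with groups of more
#' than 5 genomes, primer settings of 0 and 2 mismatches, 12 of 16
#' ribosomal markers, and a 0.5 gap-fraction / 5-column block mask. Every
#' value is overridable.
#'
#' @param dir Dataset directory (as laid out by [simulate_dataset()]:
#'   `genomes/`, `hits.tsv`, `counts.tsv`).
#' @param out_dir Output directory for stage results.
#' @param seed Seed recorded in the manifest and used by `run_simulate`.
#' @param ... Overrides of any default listed above (see source).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, out_dir = file.path(dir, "results"),
                            seed = 1, ...) {
  cfg <- list(
    dir = dir, out_dir = out_dir, seed = seed,
    genomes_dir = file.path(dir, "genomes"),
    hits_file = file.path(dir, "hits.tsv"),
    counts_file = file.path(dir, "counts.tsv"),
    primer_file = NULL, marker_file = NULL,
    hgcA_max_evalue = 1e-50, hgcA_min_score = 300,
    hgcB_min_score = 70, regulator_max_evalue = 1e-10,
    hgcB_max_distance = 5, regulator_max_distance = 3,
    require_same_strand = FALSE,
    min_completeness = 50, max_redundancy = 10,
    hq_min_completeness = 90, hq_max_redundancy = 10,
    min_group_size = 5, mismatch_settings = c(0, 2), max_product = 10000,
    min_markers = 12, max_gap_fraction = 0.5, min_block = 5,
    class_groups = "Deltaproteobacteria", sim = sim_config())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments
#'   (`dir` required).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$dir))
  do.call(pipeline_config, y)
}

config_rules <- function(config) {
  list(
    hgcA = threshold_rule("hgcA", max_evalue = config$hgcA_max_evalue,
                          min_score = config$hgcA_min_score),
    hgcB = threshold_rule("hgcB", min_score = config$hgcB_min_score,
                          min_score_exclusive = TRUE),
    regulator = threshold_rule("regulator",
                               max_evalue = config$regulator_max_evalue))
}

write_manifest <- function(config, stage, inputs) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("hgcscan")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1)) &
                               !names(unclass(config)) %in% "sim"],
    input_md5 = as.list(tools::md5sum(sort(inputs))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

load_inputs <- function(config, need_counts = FALSE) {
  if (!dir.exists(config$genomes_dir)) {
    stop("no genomes: directory not found: ", config$genomes_dir)
  }
  if (!file.exists(config$hits_file)) {
    stop("missing hit table: ", config$hits_file)
  }
  collection <- read_collection(config$genomes_dir)
  hits <- read_hits(config$hits_file)
  counts <- NULL
  if (need_counts) {
    if (!file.exists(config$counts_file)) {
      stop("missing count matrix: ", config$counts_file)
    }
    counts <- read_counts(config$counts_file)
  }
  list(collection = collection, hits = hits, counts = counts)
}

#' Identify putative methylators (pipeline stage)
#'
#' Quality-filters the collection, applies the hgcA/hgcB/regulator rules,
#' and writes the calls table, per-group counts, and a log of every
#' filtered-out hgcA candidate with the rule that removed it.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly: list with `calls`, `per_group` and `filter_log`.
#' @export
run_identify <- function(config) {
  inp <- load_inputs(config)
  collection <- filter_by_quality(inp$collection, config$min_completeness,
                                  config$max_redundancy)
  mc <- methylator_config(
    rules = config_rules(config),
    hgcB_max_distance = config$hgcB_max_distance,
    regulator_max_distance = config$regulator_max_distance,
    require_same_strand = config$require_same_strand)
  hits <- inp$hits[inp$hits$genome_id %in%
                     vapply(collection, `[[`, character(1), "id"), ,
                   drop = FALSE]
  calls <- call_methylators(collection, hits, mc)
  groups <- vapply(unclass(collection)[unique(calls$genome_id)],
                   genome_group, character(1),
                   class_groups = config$class_groups)
  per_group <- as.data.frame(table(group = unname(groups)),
                             stringsAsFactors = FALSE)
  names(per_group) <- c("group", "n_genomes")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(calls, file.path(config$out_dir, "methylator_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(per_group, file.path(config$out_dir, "methylators_per_group.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(attr(calls, "filter_log"),
              file.path(config$out_dir, "filter_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "identify", c(config$hits_file,
                                       file.path(config$genomes_dir,
                                                 "metadata.tsv")))
  message(nrow(calls), " methylator call(s) across ", nrow(per_group),
          " group(s); ", nrow(attr(calls, "filter_log")),
          " hgcA candidate(s) removed by filters")
  invisible(list(calls = calls, per_group = per_group,
                 filter_log = attr(calls, "filter_log")))
}

#' In-silico PCR stage: amplification crosstab by group
#'
#' @param config A [pipeline_config()] with `primer_file` set (table
#'   `name, fwd_seq, rev_seq, target_group`), or `fwd`/`rev` from the
#'   simulation config as fallback.
#' @return Invisibly: list with `hits` and `crosstab` per primer pair.
#' @export
run_pcr <- function(config) {
  inp <- load_inputs(config)
  calls <- run_identify(config)$calls
  pairs <- if (!is.null(config$primer_file)) {
    read_primer_config(config$primer_file)
  } else {
    data.frame(name = "planted", fwd_seq = config$sim$fwd_primer,
               rev_seq = config$sim$rev_primer, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    hits <- scan_collection(inp$collection,
                            primer(paste0(pairs$name[i], "_F"), pairs$fwd_seq[i]),
                            primer(paste0(pairs$name[i], "_R"), pairs$rev_seq[i]),
                            max_mismatches = max(config$mismatch_settings),
                            max_product = config$max_product)
    ct <- crosstab_amplification(hits, inp$collection, calls,
                                 mismatch_settings = config$mismatch_settings,
                                 class_groups = config$class_groups)
    write.table(ct, file.path(config$out_dir,
                              paste0("pcr_crosstab_", pairs$name[i], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out[[pairs$name[i]]] <- list(hits = hits, crosstab = ct)
  }
  write_manifest(config, "pcr", c(config$hits_file, config$primer_file))
  invisible(out)
}

#' Guild-profiling stage: group-level marker percentages
#'
#' @param config A [pipeline_config()]; `marker_file` (see
#'   [read_marker_config()]) defines rules and sets, else every non-core
#'   marker present in the hit table becomes a singleton set at E <= 1e-10.
#' @return Invisibly: list with `matrix` and `summary`.
#' @export
run_profile <- function(config) {
  inp <- load_inputs(config)
  if (!is.null(config$marker_file)) {
    mcfg <- read_marker_config(config$marker_file)
    rules <- mcfg$rules; sets <- mcfg$sets
  } else {
    markers <- setdiff(unique(inp$hits$marker), c("rpoB"))
    rules <- c(config_rules(config)[intersect(c("hgcA", "hgcB"), markers)],
               lapply(setdiff(markers, c("hgcA", "hgcB")), function(m) {
                 threshold_rule(m, max_evalue = 1e-10)
               }))
    names(rules) <- c(intersect(c("hgcA", "hgcB"), markers),
                      setdiff(markers, c("hgcA", "hgcB")))
    sets <- lapply(names(rules), function(m) marker_set(m, m, averaged = FALSE))
  }
  pm <- build_presence_matrix(inp$collection, inp$hits, rules)
  summary <- summarize_groups(pm, inp$collection, sets,
                              min_group_size = config$min_group_size,
                              min_completeness = config$hq_min_completeness,
                              max_redundancy = config$hq_max_redundancy,
                              class_groups = config$class_groups)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(summary, file.path(config$out_dir, "guild_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "profile", c(config$hits_file, config$marker_file))
  invisible(list(matrix = pm, summary = summary))
}

#' Expression stage: TPM normalization and group aggregations
#'
#' @param config A [pipeline_config()].
#' @return Invisibly: list with `tpm`, `hgcA_by_group` (+ total),
#'   `genome_average` and `rpoB_pairs`.
#' @export
run_express <- function(config) {
  inp <- load_inputs(config, need_counts = TRUE)
  calls <- run_identify(config)$calls
  tpm <- tpm_normalize(inp$counts)
  by_group <- marker_expression_by_group(tpm, calls, "hgcA", inp$collection,
                                         class_groups = config$class_groups)
  avg <- genome_average_by_group(tpm, inp$collection,
                                 class_groups = config$class_groups)
  pairs <- compare_to_housekeeping(tpm, calls,
                                   inp$hits[inp$hits$marker == "rpoB", ,
                                            drop = FALSE])
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cbind(group = rownames(by_group$group_tpm),
                    as.data.frame(by_group$group_tpm, check.names = FALSE)),
              file.path(config$out_dir, "hgcA_tpm_by_group.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(by_group$total),
                         total_hgcA_tpm = unname(by_group$total)),
              file.path(config$out_dir, "hgcA_tpm_total.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(group = rownames(avg),
                    as.data.frame(avg, check.names = FALSE)),
              file.path(config$out_dir, "genome_average_tpm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pairs, file.path(config$out_dir, "hgcA_vs_rpoB.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "express", c(config$hits_file, config$counts_file))
  invisible(list(tpm = tpm, hgcA_by_group = by_group, genome_average = avg,
                 rpoB_pairs = pairs))
}

#' Simulation stage: write a synthetic dataset + truth under the config dir
#'
#' @param config A [pipeline_config()]; uses `config$sim` and `config$seed`.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
run_simulate <- function(config) {
  sim <- simulate_dataset(config$sim, seed = config$seed, dir = config$dir)
  write_manifest(config, "simulate",
                 c(config$hits_file, config$counts_file,
                   file.path(config$genomes_dir, "metadata.tsv")))
  invisible(sim)
}

#' Supermatrix-preparation stage
#'
#' Applies the marker-completeness rule to per-genome marker hits,
#' concatenates the given alignments, masks columns, and writes the
#' supermatrix FASTA and partition file.
#'
#' @param alignments List of [marker_alignment()]s.
#' @param config A [pipeline_config()].
#' @param markers Marker universe (default [rp16_markers()]).
#' @return Invisibly, the masked `Supermatrix`.
#' @export
run_phylo_prep <- function(alignments, config, markers = rp16_markers()) {
  per_genome <- list()
  for (a in alignments) {
    for (g in names(a$rows)) per_genome[[g]] <- c(per_genome[[g]], a$marker)
  }
  keep <- filter_marker_completeness(per_genome, config$min_markers, markers)
  if (length(keep) == 0L) stop("no genome passes the marker-completeness rule")
  sm <- concatenate(alignments, genomes = keep)
  sm <- mask_columns(sm, config$max_gap_fraction, config$min_block)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_supermatrix(sm, file.path(config$out_dir, "supermatrix.faa"),
                    file.path(config$out_dir, "supermatrix.partitions"))
  invisible(sm)
}
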