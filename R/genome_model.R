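# Genome data model: contigs + ordered ORFs + taxonomy/quality metadata.
# Coordinates follow the GFF3 convention (1-based, inclusive); ORF order on a
# contig is the rank of the start coordinate, ties broken by end then id.

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Read a nucleotide FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a plain
#' named character vector of uppercased sequences with line wrapping removed.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (names = record ids, first whitespace token
#'   of each header).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Parse a GTDB-style taxonomy string
#'
#' @param x Taxonomy string `d__...;p__...;c__...;o__...;f__...;g__...;s__...`.
#'   Missing ranks may be empty (`p__`) or absent.
#' @return Named character vector over ranks domain..species; unassigned ranks
#'   are `NA`.
#' @export
parse_taxonomy <- function(x) {
  out <- setNames(rep(NA_character_, 7L), RANK_NAMES)
  if (is.na(x) || !nzchar(x)) return(out)
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  for (p in parts) {
    hit <- which(startsWith(p, RANK_PREFIXES))
    if (length(hit) == 1L) {
      val <- substring(p, 4L)
      if (nzchar(val)) out[[RANK_NAMES[hit]]] <- val
    }
  }
  out
}

#' Construct a GenomeRecord
#'
#' @param id Genome id.
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param orfs data.frame with columns `orf_id, contig_id, start, end, strand,
#'   protein`. `index_on_contig` and `nt_length` are (re)computed.
#' @param taxonomy Taxonomy string (see [parse_taxonomy()]).
#' @param completeness,redundancy Quality estimates in percent.
#' @return Object of class `GenomeRecord`.
#' @export
genome_record <- function(id, contigs, orfs, taxonomy = NA_character_,
                          completeness = NA_real_, redundancy = NA_real_) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig id in genome ", id)
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    warning("genome ", id, ": ambiguity characters other than N mapped to N in ",
            sum(bad), " contig(s)")
    contigs[bad] <- gsub("[^ACGTN]", "N", contigs[bad])
  }
  orfs <- as.data.frame(orfs, stringsAsFactors = FALSE)
  req <- c("orf_id", "contig_id", "start", "end", "strand", "protein")
  stopifnot(all(req %in% names(orfs)))
  if (nrow(orfs) > 0L) {
    unknown <- setdiff(orfs$contig_id, names(contigs))
    if (length(unknown) > 0L) {
      stop("genome ", id, ": ORF(s) on unknown contig(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(orfs$start > orfs$end)) stop("genome ", id, ": ORF with start > end")
    clen <- nchar(contigs)[orfs$contig_id]
    if (any(orfs$start < 1L | orfs$end > clen)) {
      bad_orf <- orfs$orf_id[orfs$start < 1L | orfs$end > clen][1L]
      stop("genome ", id, ": ORF ", bad_orf, " outside contig bounds")
    }
    if (any(!nzchar(orfs$protein))) stop("genome ", id, ": empty protein translation")
    if (anyDuplicated(orfs$orf_id)) stop("genome ", id, ": duplicate ORF id")
    ord <- order(orfs$contig_id, orfs$start, orfs$end, orfs$orf_id)
    orfs <- orfs[ord, , drop = FALSE]
    orfs$index_on_contig <- stats::ave(
      orfs$start, orfs$contig_id, FUN = seq_along)
    orfs$nt_length <- orfs$end - orfs$start + 1L
    rownames(orfs) <- NULL
  } else {
    orfs$index_on_contig <- integer(0)
    orfs$nt_length <- integer(0)
  }
  if (!is.na(completeness) && (completeness < 0 || completeness > 100)) {
    stop("completeness out of [0,100]")
  }
  if (!is.na(redundancy) && (redundancy < 0 || redundancy > 100)) {
    stop("redundancy out of [0,100]")
  }
  structure(
    list(id = id, contigs = contigs, orfs = orfs,
         taxonomy = taxonomy, completeness = as.numeric(completeness),
         redundancy = as.numeric(redundancy)),
    class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat("<GenomeRecord> ", x$id, ": ", length(x$contigs), " contig(s), ",
      nrow(x$orfs), " ORF(s)", sep = "")
  if (!is.na(x$completeness)) {
    cat(sprintf(", %.1f%% complete / %.1f%% redundant",
                x$completeness, x$redundancy))
  }
  cat("\n")
  invisible(x)
}

#' Construct a GenomeCollection
#'
#' @param genomes List of [genome_record()] objects.
#' @return Object of class `GenomeCollection` (a named list of records).
#' @export
genome_collection <- function(genomes) {
  stopifnot(all(vapply(genomes, inherits, logical(1), "GenomeRecord")))
  ids <- vapply(genomes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(setNames(genomes, ids), class = "GenomeCollection")
}

#' @export
print.GenomeCollection <- function(x, ...) {
  cat("<GenomeCollection> of", length(x), "genome(s)\n")
  invisible(x)
}

#' @export
`[.GenomeCollection` <- function(x, i) {
  genome_collection(unclass(x)[i])
}

#' Phylum-level (or overridden-rank) group label of a genome
#'
#' Most groups are phyla; some classes (classically Deltaproteobacteria) are
#' treated as groups in their own right.
#'
#' @param genome A `GenomeRecord`.
#' @param class_groups Character vector of class names promoted to group rank.
#' @return Group label (character), `NA` if no phylum assigned.
#' @export
genome_group <- function(genome, class_groups = "Deltaproteobacteria") {
  tax <- parse_taxonomy(genome$taxonomy)
  if (!is.na(tax[["class"]]) && tax[["class"]] %in% class_groups) {
    return(tax[["class"]])
  }
  tax[["phylum"]]
}

#' Read one genome from FASTA + GFF3 + a metadata row
#'
#' CDS features are taken from the GFF3; protein translations come from a
#' `translation` attribute when present, from a companion protein FASTA
#' (matched by ORF id), or failing both are translated from the contig
#' sequence with the bacterial/archaeal genetic code (table 11), trimming a
#' terminal stop.
#'
#' @param fasta Path to the nucleotide FASTA.
#' @param gff Path to the GFF3 annotation (CDS rows used).
#' @param meta Named list / one-row data.frame with `genome_id, taxonomy,
#'   completeness, redundancy`.
#' @param proteins Optional path to a protein FASTA keyed by ORF id.
#' @return A `GenomeRecord` with ORFs sorted by (contig, start) and
#'   `index_on_contig` assigned per contig.
#' @export
read_genome <- function(fasta, gff, meta, proteins = NULL) {
  contigs <- read_fasta(fasta)
  g <- as.data.frame(rtracklayer::readGFF(gff))
  g <- g[g$type == "CDS", , drop = FALSE]
  orf_id <- if ("ID" %in% names(g)) as.character(g$ID) else NA_character_
  if (anyNA(orf_id)) stop("CDS feature(s) without an ID attribute in ", gff)
  prot <- rep(NA_character_, nrow(g))
  if ("translation" %in% names(g)) prot <- as.character(g$translation)
  if (!is.null(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    names(aa) <- sub("\\s.*$", "", names(aa))
    hit <- match(orf_id, names(aa))
    prot[is.na(prot) & !is.na(hit)] <-
      as.character(aa)[hit[is.na(prot) & !is.na(hit)]]
  }
  need <- which(is.na(prot) | !nzchar(prot))
  if (length(need) > 0L) {
    prot[need] <- translate_cds(contigs, as.character(g$seqid)[need],
                                g$start[need], g$end[need],
                                as.character(g$strand)[need])
  }
  orfs <- data.frame(
    orf_id = orf_id,
    contig_id = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    protein = prot,
    stringsAsFactors = FALSE)
  genome_record(
    id = as.character(meta$genome_id),
    contigs = contigs, orfs = orfs,
    taxonomy = as.character(meta$taxonomy),
    completeness = as.numeric(meta$completeness),
    redundancy = as.numeric(meta$redundancy))
}

# Translate CDS spans with genetic code table 11, trimming the terminal stop.
translate_cds <- function(contigs, contig_id, start, end, strand) {
  code <- Biostrings::getGeneticCode("11")
  vapply(seq_along(contig_id), function(i) {
    nt <- substr(contigs[[contig_id[i]]], start[i], end[i])
    if (identical(strand[i], "-")) {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), genetic.code = code, if.fuzzy.codon = "X"))
    sub("\\*$", "", aa)
  }, character(1))
}

#' Write a genome back to FASTA + GFF3
#'
#' The GFF3 carries each ORF as a CDS row with `ID` and `translation`
#' attributes, so that [read_genome()] round-trips coordinates, strands and
#' `index_on_contig` exactly.
#'
#' @param genome A `GenomeRecord`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the two file paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(genome$id, ".fna"))
  gff <- file.path(dir, paste0(genome$id, ".gff"))
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)
  o <- genome$orfs
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                     nchar(genome$contigs)))
  if (nrow(o) > 0L) {
    lines <- c(lines, sprintf(
      "%s\thgcscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;translation=%s",
      o$contig_id, o$start, o$end, o$strand, o$orf_id, o$protein))
  }
  writeLines(lines, gff)
  invisible(list(fasta = fasta, gff = gff))
}

#' Read a genome collection from a directory
#'
#' Expects `<dir>/<genome_id>.fna` and `<dir>/<genome_id>.gff` for every row
#' of the metadata table.
#'
#' @param dir Directory holding per-genome FASTA/GFF3 files.
#' @param metadata Path to (or data.frame of) the metadata table with header
#'   `genome_id, taxonomy, completeness, redundancy`.
#' @return A `GenomeCollection`.
#' @export
read_collection <- function(dir, metadata = file.path(dir, "metadata.tsv")) {
  meta <- if (is.data.frame(metadata)) metadata else {
    read.delim(metadata, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("genome_id", "taxonomy", "completeness", "redundancy")
                %in% names(meta)))
  if (nrow(meta) == 0L) stop("no genomes listed in metadata")
  genomes <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$genome_id[i]
    read_genome(file.path(dir, paste0(id, ".fna")),
                file.path(dir, paste0(id, ".gff")), meta[i, , drop = FALSE])
  })
  genome_collection(genomes)
}

#' Write a genome collection (FASTA + GFF3 + metadata table)
#'
#' @param collection A `GenomeCollection`.
#' @param dir Output directory.
#' @return Invisibly, the metadata file path.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in collection) write_genome(g, dir)
  meta <- data.frame(
    genome_id = vapply(collection, `[[`, character(1), "id"),
    taxonomy = vapply(collection, `[[`, character(1), "taxonomy"),
    completeness = vapply(collection, `[[`, numeric(1), "completeness"),
    redundancy = vapply(collection, `[[`, numeric(1), "redundancy"),
    stringsAsFactors = FALSE)
  path <- file.path(dir, "metadata.tsv")
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a collection by MIMAG-style quality cutoffs
#'
#' Retains genomes with completeness strictly greater than `min_completeness`
#' and redundancy strictly less than `max_redundancy` (medium quality per
#' MIMAG at the 50/10 defaults).
#'
#' @param collection A `GenomeCollection`.
#' @param min_completeness,max_redundancy Percent thresholds in \[0,100\].
#' @return A filtered `GenomeCollection` (possibly empty).
#' @export
filter_by_quality <- function(collection, min_completeness = 50,
                              max_redundancy = 10) {
  stopifnot(min_completeness >= 0, min_completeness <= 100,
            max_redundancy >= 0, max_redundancy <= 100)
  keep <- vapply(collection, function(g) {
    !is.na(g$completeness) && !is.na(g$redundancy) &&
      g$completeness > min_completeness && g$redundancy < max_redundancy
  }, logical(1))
  genome_collection(unclass(collection)[keep])
}

# Fetch one ORF row by id; errors if absent.
get_orf <- function(genome, orf_id) {
  i <- match(orf_id, genome$orfs$orf_id)
  if (is.na(i)) stop("ORF ", orf_id, " not found in genome ", genome$id)
  genome$orfs[i, , drop = FALSE]
}
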