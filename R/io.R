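#' Read and write sequence FASTA
#'
#' Sequences are stored internally as uppercase DNA strings (U is
#' converted to T on input).
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- chartr("Uu", "Tt", toupper(as.character(x)))
  # keep only the first word of each FASTA header as the id
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write per-library read sets as FASTA
#'
#' One file per library (`<stage>.fa`). Multi-locus annotation is kept
#' in the header (`loci=N`) so that round-tripping preserves the
#' information the read filter needs.
#'
#' @param reads_by_library Named list of read data frames
#'   ([emit_reads()] format).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_reads_fasta <- function(reads_by_library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(names(reads_by_library), function(lib) {
    r <- reads_by_library[[lib]]
    ids <- sprintf("%s_r%06d loci=%d", lib, seq_len(nrow(r)), r$n_loci)
    path <- file.path(dir, paste0(lib, ".fa"))
    writeLines(paste0(">", ids, "\n", r$sequence), path)
    path
  }, character(1))
}

#' Read a per-library read FASTA written by [write_reads_fasta()]
#'
#' @param path FASTA file.
#' @return Read data frame with `sequence`, `n_loci`, `mismatches`.
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  loci <- ifelse(grepl("loci=\\d+", names(x)),
                 as.integer(sub(".*loci=(\\d+).*", "\\1", names(x))), 1L)
  data.frame(sequence = chartr("Uu", "Tt", toupper(as.character(x))),
             n_loci = loci, mismatches = 0L, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write mature-arm annotation as miRBase-dialect GFF3
#'
#' One `miRNA_primary_transcript` feature per hairpin (coordinates are
#' hairpin-relative, 1-based inclusive) with nested `miRNA` features
#' for the mature arms (`Derives_from` pointing at the hairpin).
#'
#' @param hairpins Named character vector of hairpin sequences (names
#'   are locus ids; lengths set the primary-transcript spans).
#' @param regions A [region_annotation()] shared by all hairpins, or a
#'   named list of annotations per locus id.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mature_gff3 <- function(hairpins, regions, path) {
  ids <- names(hairpins)
  per_locus <- if (inherits(regions, "region_annotation"))
    setNames(rep(list(regions), length(ids)), ids) else regions
  rows <- list()
  for (id in ids) {
    reg <- per_locus[[id]]
    rows[[length(rows) + 1L]] <- data.frame(
      seq = id, type = "miRNA_primary_transcript", start = 1L,
      end = nchar(hairpins[[id]]),
      attr = sprintf("ID=%s;Name=%s", id, id))
    a <- reg$arms
    for (k in seq_len(nrow(a)))
      rows[[length(rows) + 1L]] <- data.frame(
        seq = id, type = "miRNA", start = a$start[k], end = a$end[k],
        attr = sprintf("ID=%s-%s;Name=%s-%s;Derives_from=%s",
                       id, a$arm[k], id, a$arm[k], id))
  }
  tab <- do.call(rbind, rows)
  lines <- sprintf("%s\t.\t%s\t%d\t%d\t.\t+\t.\t%s",
                   tab$seq, tab$type, tab$start, tab$end, tab$attr)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read miRBase-dialect GFF3 mature-arm annotation
#'
#' @param path GFF3 file as written by [write_mature_gff3()] or
#'   exported from miRBase (hairpin-relative coordinates).
#' @return Named list of [region_annotation()] objects, one per
#'   hairpin.
#' @export
read_mature_gff3 <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr$type <- as.character(gr$type)
  gr$Derives_from <- vapply(gr$Derives_from, function(v)
    if (length(v)) as.character(v)[1] else NA_character_, character(1))
  prim <- gr[gr$type == "miRNA_primary_transcript", ]
  out <- list()
  for (i in seq_len(nrow(prim))) {
    id <- prim$ID[i]
    kids <- gr[gr$type == "miRNA" & !is.na(gr$Derives_from) &
                 gr$Derives_from == id, ]
    out[[id]] <- region_annotation(
      prim$end[i],
      data.frame(arm = sub(paste0("^", id, "-"), "", kids$ID),
                 start = kids$start, end = kids$end))
  }
  out
}

#' Read and write presence/absence tables
#'
#' Rows are families, columns species, values 0/1.
#'
#' @param presence 0/1 matrix.
#' @param path TSV path.
#' @return `read_presence_tsv()` returns an integer matrix.
#' @export
write_presence_tsv <- function(presence, path) {
  df <- data.frame(family = rownames(presence), presence,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read and write count tables
#'
#' Counts TSV with a leading `mirna` column; the per-library
#' microRNA-mapped and genome-mapped totals are carried in `#`-prefixed
#' header lines so a [mir_counts()] object round-trips.
#'
#' @param x A [mir_counts()] object.
#' @param path TSV path.
#' @return `read_counts_tsv()` returns a [mir_counts()] object.
#' @export
write_counts_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#mirna_mapped\t",
                    paste(x$mirna_mapped, collapse = "\t")), con)
  if (!is.null(x$genome_mapped))
    writeLines(paste0("#genome_mapped\t",
                      paste(x$genome_mapped, collapse = "\t")), con)
  df <- data.frame(mirna = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  hdr <- hdr[startsWith(hdr, "#")]
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  parse_tot <- function(tag) {
    line <- hdr[startsWith(hdr, paste0("#", tag))]
    if (!length(line)) return(NULL)
    as.numeric(strsplit(line, "\t")[[1]][-1])
  }
  mm <- parse_tot("mirna_mapped")
  mir_counts(m, stages = colnames(m),
             mirna_mapped = if (!is.null(mm)) mm else colSums(m),
             genome_mapped = parse_tot("genome_mapped"))
}

#' Serialize and restore a simulation configuration as YAML
#'
#' The species tree is embedded as a Newick string; everything else
#' maps one-to-one onto [simulation_config()] arguments.
#'
#' @param config A [simulation_config()].
#' @param path YAML file.
#' @return `read_config_yaml()` returns a validated
#'   [simulation_config()].
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$tree <- ape::write.tree(config$tree)
  yaml::write_yaml(lapply(lst, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$tree <- ape::read.tree(text = lst$tree)
  for (f in c("birth_rates", "region_rates"))
    lst[[f]] <- unlist(lst[[f]])
  lst$arm5p <- as.integer(unlist(lst$arm5p))
  lst$arm3p <- as.integer(unlist(lst$arm3p))
  lst$stages <- as.character(unlist(lst$stages))
  do.call(simulation_config, lst)
}

#' Write all inputs of a synthetic study to disk
#'
#' Materializes a [simulate_mirna_study()] result in the on-disk
#' formats a real study would be distributed in: hairpin FASTA for both
#' species, mature-arm GFF3, Newick tree with rank labels,
#' presence/absence TSV, counts TSV, family truth TSV, and the YAML
#' configuration.
#'
#' @param study A `"mirna_study"` object.
#' @param dir Output directory.
#' @param reads Also emit per-library read FASTA files (default FALSE).
#' @return Named character vector of files written.
#' @export
write_study <- function(study, dir, reads = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c(
    hairpins_ref = write_fasta(study$hairpins_ref, p("hairpins_ref.fa")),
    hairpins_orth = write_fasta(study$hairpins_orth,
                                p("hairpins_orth.fa")),
    gff3 = write_mature_gff3(study$hairpins_orth, study$regions,
                             p("mature.gff3")),
    tree = write_species_tree(study$tree, p("species.nwk")),
    presence = write_presence_tsv(study$presence, p("presence.tsv")),
    counts = write_counts_tsv(study$expression, p("counts.tsv")),
    config = write_config_yaml(study$config, p("config.yaml")))
  fam <- study$families
  write.table(fam, p("families_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, families = p("families_truth.tsv"))
  if (reads) {
    rd <- emit_reads(study$expression, study$mature_orth)
    files <- c(files, write_reads_fasta(rd, file.path(dir, "reads")))
  }
  files
}
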