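#' MicroRNA expression matrix with per-library totals
#'
#' Container for a microRNA x library count matrix together with the
#' two per-library normalization denominators used in small RNA-seq:
#' reads mapping to microRNAs and reads mapping to the genome. Library
#' order is the developmental sequence and is fixed at construction.
#'
#' @param counts Non-negative numeric matrix, microRNAs in rows,
#'   libraries in columns.
#' @param stages Ordered library labels (defaults to column names).
#' @param mirna_mapped Per-library microRNA-mapped totals (defaults to
#'   the column sums of `counts`).
#' @param genome_mapped Optional per-library genome-mapped totals
#'   (must be >= `mirna_mapped` where given).
#' @return List of class `"mir_counts"` with elements `counts`,
#'   `stages`, `mirna_mapped`, `genome_mapped`, and (after
#'   [normalize_rpm()]) `rpm` and `denominator`.
#' @export
mir_counts <- function(counts, stages = colnames(counts),
                       mirna_mapped = colSums(counts),
                       genome_mapped = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("raw counts must be non-negative")
  if (is.null(stages)) stop("library order must be supplied")
  colnames(counts) <- stages
  structure(list(counts = counts, stages = stages,
                 mirna_mapped = setNames(as.numeric(mirna_mapped), stages),
                 genome_mapped = if (!is.null(genome_mapped))
                   setNames(as.numeric(genome_mapped), stages),
                 rpm = NULL, denominator = NA_character_),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts:", nrow(x$counts), "microRNAs x", length(x$stages),
      "libraries (", paste(head(x$stages, 3), collapse = ", "), "...)\n")
  cat("  microRNA-mapped totals:", paste(head(round(x$mirna_mapped), 3),
                                         collapse = ", "), "...\n")
  if (!is.na(x$denominator))
    cat("  normalized: RPM,", x$denominator, "denominator\n")
  invisible(x)
}

#' Filter small-RNA reads by length, multimapping and mismatches
#'
#' Keeps a read iff its length is between `min_len` and `max_len`
#' (19-24 nt by default), it maps to at most `max_loci` genomic loci
#' (fewer than five by default), it was mapped with at most
#' `max_mismatches` mismatches (one by default), and its sequence is
#' not on the optional blocklist (representing rRNA/tRNA/other ncRNA
#' pre-filtering). The number of reads removed by each rule is attached
#' as the `"dropped"` attribute. Filtering is idempotent.
#'
#' @param reads Data frame with columns `sequence`, `n_loci`,
#'   `mismatches`.
#' @param min_len,max_len Read length bounds (inclusive).
#' @param max_loci Maximum mapped-loci count (inclusive).
#' @param max_mismatches Maximum mismatches used in mapping.
#' @param blocklist Optional character vector of sequences to remove.
#' @return The surviving rows of `reads`, with attribute `"dropped"`:
#'   a named integer vector of removal counts per rule (a read failing
#'   several rules is tallied under each).
#' @export
filter_reads <- function(reads, min_len = 19L, max_len = 24L,
                         max_loci = 4L, max_mismatches = 1L,
                         blocklist = NULL) {
  len <- nchar(reads$sequence)
  ok_len <- len >= min_len & len <= max_len
  ok_loci <- reads$n_loci <= max_loci
  ok_mm <- reads$mismatches <= max_mismatches
  ok_block <- if (is.null(blocklist)) rep(TRUE, nrow(reads))
              else !(reads$sequence %in% blocklist)
  keep <- ok_len & ok_loci & ok_mm & ok_block
  out <- reads[keep, , drop = FALSE]
  attr(out, "dropped") <- c(length = sum(!ok_len),
                            multimapping = sum(!ok_loci),
                            mismatches = sum(!ok_mm),
                            blocklist = sum(!ok_block))
  out
}

#' Count reads against microRNA hairpins
#'
#' Assigns each read to the hairpin loci it matches with at most
#' `max_mismatch` mismatches (no indels), the count serving as the
#' expression estimate of the hairpin. A read matching several loci --
#' paralogs sharing an identical or near-identical mature sequence --
#' is divided equally among them (`multi = "split"`), so read totals
#' are conserved; reads matching no locus are tallied as unassigned.
#' Per-arm counts are retained for arm-usage summaries, assigning each
#' matched read to the arm its match position overlaps most.
#'
#' @param reads_by_library Named list of read data frames (one per
#'   library, in developmental order), as from [emit_reads()] or
#'   [filter_reads()].
#' @param hairpins Named character vector of hairpin sequences.
#' @param regions A [region_annotation()] shared by all hairpins (used
#'   for arm assignment); `NULL` skips arm-level counting.
#' @param max_mismatch Mismatch tolerance of read-to-hairpin matching.
#' @param multi `"split"` divides multi-locus reads equally among
#'   matched loci; `"all"` credits each matched locus with the full
#'   count.
#' @return List with `counts` (a [mir_counts()]), `arm_counts`
#'   (hairpin/arm x library matrix, split rows named `id|5p` etc.),
#'   and `unassigned` (reads per library matching no hairpin).
#' @export
count_to_hairpins <- function(reads_by_library, hairpins, regions = NULL,
                              max_mismatch = 1L,
                              multi = c("split", "all")) {
  multi <- match.arg(multi)
  subj <- Biostrings::DNAStringSet(hairpins)
  libs <- names(reads_by_library)
  ids <- names(hairpins)
  counts <- matrix(0, length(ids), length(libs),
                   dimnames = list(ids, libs))
  arm_ids <- if (!is.null(regions))
    as.vector(outer(ids, regions$arms$arm, paste, sep = "|"))
  arm_counts <- if (!is.null(regions))
    matrix(0, length(arm_ids), length(libs),
           dimnames = list(arm_ids, libs))
  unassigned <- setNames(numeric(length(libs)), libs)

  for (lib in libs) {
    seqs <- reads_by_library[[lib]]$sequence
    if (length(seqs) == 0L) next
    tab <- table(seqs)
    for (u in names(tab)) {
      hits <- which(Biostrings::vcountPattern(u, subj,
                                              max.mismatch = max_mismatch,
                                              with.indels = FALSE) > 0L)
      nread <- as.numeric(tab[[u]])
      if (length(hits) == 0L) {
        unassigned[lib] <- unassigned[lib] + nread
        next
      }
      share <- if (multi == "split") nread / length(hits) else nread
      counts[hits, lib] <- counts[hits, lib] + share
      if (!is.null(regions)) {
        for (h in hits) {
          m <- Biostrings::matchPattern(u, subj[[h]],
                                        max.mismatch = max_mismatch,
                                        with.indels = FALSE)
          if (length(m) == 0L) next
          pos <- seq(Biostrings::start(m)[1], Biostrings::end(m)[1])
          ov <- vapply(seq_len(nrow(regions$arms)), function(k)
            sum(pos >= regions$arms$start[k] & pos <= regions$arms$end[k]),
            numeric(1))
          arm <- regions$arms$arm[which.max(ov)]
          key <- paste(ids[h], arm, sep = "|")
          arm_counts[key, lib] <- arm_counts[key, lib] + share
        }
      }
    }
  }
  list(counts = mir_counts(counts), arm_counts = arm_counts,
       unassigned = unassigned)
}

#' Divide reads of identical paralogous mature sequences
#'
#' Paralogous loci sharing an identical mature sequence cannot be
#' distinguished by sequencing; the group's pooled reads are divided
#' equally among its loci. Grand totals are conserved exactly.
#'
#' @param x A [mir_counts()] object or count matrix.
#' @param groups List of character vectors of locus ids sharing an
#'   identical mature sequence (groups of one are unchanged).
#' @return Object of the same type with adjusted counts.
#' @export
split_paralog_reads <- function(x, groups) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  for (g in groups) {
    missing <- setdiff(g, rownames(m))
    if (length(missing))
      stop("identity group references unknown locus: ", missing[1])
    if (length(g) > 1L)
      m[g, ] <- matrix(colSums(m[g, , drop = FALSE]) / length(g),
                       length(g), ncol(m), byrow = TRUE)
  }
  if (inherits(x, "mir_counts")) { x$counts <- m; x } else m
}

#' Normalize counts to reads per million (RPM)
#'
#' Scales each library by `10^6 /` its total, using either the
#' microRNA-mapped total (so normalized columns sum to 10^6 over the
#' counted microRNAs) or the genome-mapped total. The denominator
#' choice is recorded on the object.
#'
#' @param x A [mir_counts()] object.
#' @param denominator `"mirna_mapped"` or `"genome_mapped"`.
#' @return `x` with `rpm` and `denominator` filled in.
#' @export
normalize_rpm <- function(x, denominator = c("mirna_mapped",
                                             "genome_mapped")) {
  denominator <- match.arg(denominator)
  denom <- x[[denominator]]
  if (is.null(denom)) stop(denominator, " totals not available")
  if (any(denom == 0))
    stop("zero ", denominator, " denominator for library ",
         names(denom)[denom == 0][1])
  x$rpm <- sweep(x$counts, 2L, denom, "/") * 1e6
  x$denominator <- denominator
  x
}

#' Expression breadth across developmental libraries
#'
#' A microRNA is detected in a library when its raw count reaches the
#' detection threshold; its breadth is the number of detecting
#' libraries (1..11 for the standard 11-stage series; microRNAs
#' detected nowhere have breadth 0).
#'
#' @param x A [mir_counts()] object.
#' @param threshold Minimum raw count for detection (default 1).
#' @return Named integer vector of per-microRNA breadths, with the
#'   detection indicator matrix as attribute `"detected"`.
#' @export
detect_breadth <- function(x, threshold = 1) {
  det <- x$counts >= threshold
  out <- rowSums(det)
  attr(out, "detected") <- det
  out
}

#' Flag dominance outliers
#'
#' Flags microRNAs whose read count in any library reaches `fold`
#' times the next most highly expressed microRNA in that library --
#' sequences so dominant they would distort composition and
#' correlation summaries. Flagged entries are meant to be excluded
#' from downstream analyses while staying in the raw table.
#'
#' @param x A [mir_counts()] object.
#' @param fold Dominance factor (default 10; comparison is `>=`).
#' @return Character vector of flagged microRNA ids.
#' @export
flag_outliers <- function(x, fold = 10) {
  m <- x$counts
  if (nrow(m) < 2L) stop("need at least two microRNAs per library")
  flagged <- logical(nrow(m))
  for (j in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m))) {
      nxt <- max(m[-i, j])
      if (m[i, j] > 0 && m[i, j] >= fold * nxt) flagged[i] <- TRUE
    }
  }
  rownames(m)[flagged]
}

#' Partition microRNAs by summed expression level
#'
#' Splits microRNAs into highly expressed (summed RPM across all
#' libraries at or above `threshold`, default 1000 RPM, i.e. 1/1000 of
#' the reads mapping to microRNAs) and lowly expressed.
#'
#' @param x A [mir_counts()] normalized with the microRNA-mapped
#'   denominator.
#' @param threshold Summed-RPM cutoff (inclusive for "high").
#' @return Data frame with columns `mirna`, `total_rpm`, `high`.
#' @export
high_expression_filter <- function(x, threshold = 1000) {
  if (is.null(x$rpm)) stop("normalize first (mirna_mapped denominator)")
  if (!identical(x$denominator, "mirna_mapped"))
    stop("high-expression filter is defined on the microRNA-mapped scale")
  tot <- rowSums(x$rpm)
  data.frame(mirna = rownames(x$rpm), total_rpm = unname(tot),
             high = unname(tot >= threshold), stringsAsFactors = FALSE)
}
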