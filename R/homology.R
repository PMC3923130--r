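#' Alignment scoring scheme
#'
#' Scoring used for global alignment of hairpin sequences. The match and
#' mismatch scores mirror classical short-nucleotide BLASTN rewards and
#' penalties (+2 / -3); gaps are affine (a gap of length L costs
#' `gap_open + L * gap_extend`) with defaults chosen to discourage
#' spurious gapped hits on short hairpins.
#'
#' @param match Match score (default `2`).
#' @param mismatch Mismatch score (default `-3`).
#' @param gap_open Gap opening penalty (default `-5`).
#' @param gap_extend Per-position gap extension penalty (default `-2`).
#' @return A list of class `"align_scoring"`.
#' @export
align_scoring <- function(match = 2, mismatch = -3,
                          gap_open = -5, gap_extend = -2) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.prep_seq <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string")
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside {A,C,G,U/T,N}")
  x
}

#' Global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs and
#' deterministic tie-breaking: where several alignments are optimal, an
#' aligned pair is preferred over a gap, and a gap in the first sequence
#' over a gap in the second. U and T are interchangeable.
#'
#' @param a,b Sequences (single strings over A,C,G,U/T,N).
#' @param scoring An [align_scoring()] scheme.
#' @return A list of class `"pair_alignment"` with `score`, `alignedA`,
#'   `alignedB` (equal-length gapped strings).
#' @examples
#' align_orthologs("ACGU", "ACU")
#' @export
align_orthologs <- function(a, b, scoring = align_scoring()) {
  a <- .prep_seq(a, "sequence A")
  b <- .prep_seq(b, "sequence B")
  res <- .nw_align_cpp(a, b, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  structure(res, class = "pair_alignment")
}

#' Optimal global alignment score between two sequences
#'
#' Deterministic replacement for a heuristic local-similarity search:
#' the score of the optimal global alignment under [align_scoring()].
#'
#' @inheritParams align_orthologs
#' @return Numeric alignment score.
#' @export
score_similarity <- function(a, b, scoring = align_scoring()) {
  align_orthologs(a, b, scoring)$score
}

#' Reciprocal-best-hit ortholog pairing
#'
#' Pairs loci between two species by mutual best global-alignment score.
#' A pair (a, b) is accepted iff b is a's unique best hit and a is b's
#' unique best hit; a query whose top score is shared by two or more
#' targets yields no pair, so accepted pairs are unambiguous and
#' one-to-one. The result is symmetric in the species order.
#'
#' @param lociA,lociB Named character vectors of sequences (names are
#'   locus ids); each species must contribute at least one locus.
#' @param scoring An [align_scoring()] scheme.
#' @return Data frame with columns `locusA`, `locusB`, `score`; zero
#'   rows if no reciprocal pair exists.
#' @export
reciprocal_best_hits <- function(lociA, lociB, scoring = align_scoring()) {
  if (length(lociA) < 1L || length(lociB) < 1L)
    stop("each species needs at least one locus")
  if (is.null(names(lociA))) names(lociA) <- paste0("A", seq_along(lociA))
  if (is.null(names(lociB))) names(lociB) <- paste0("B", seq_along(lociB))
  S <- matrix(NA_real_, length(lociA), length(lociB),
              dimnames = list(names(lociA), names(lociB)))
  for (i in seq_along(lociA))
    for (j in seq_along(lociB))
      S[i, j] <- score_similarity(lociA[[i]], lociB[[j]], scoring)

  best_unique <- function(scores) {
    top <- max(scores)
    hits <- which(scores == top)
    if (length(hits) == 1L) hits else NA_integer_
  }
  bestA <- apply(S, 1L, best_unique)  # best target in B per query in A
  bestB <- apply(S, 2L, best_unique)  # best target in A per query in B

  keep <- which(!is.na(bestA) & vapply(seq_along(bestA), function(i) {
    j <- bestA[i]
    !is.na(bestB[j]) && bestB[j] == i
  }, logical(1)))
  data.frame(locusA = names(lociA)[keep],
             locusB = names(lociB)[bestA[keep]],
             score = S[cbind(keep, bestA[keep])],
             stringsAsFactors = FALSE)
}

#' Synteny support for an ortholog pair
#'
#' An ortholog pair is synteny-supported when a shared flanking gene id
#' occurs on each side (upstream and downstream) of the two loci. Flank
#' lists are given in chromosomal order; if the second locus lies on the
#' minus strand its upstream/downstream sides are swapped before
#' comparison, so support is orientation-aware. Missing flank data gives
#' `NA` ("unknown"), never `FALSE`.
#'
#' @param upA,downA Character vectors of gene ids flanking locus A
#'   upstream / downstream.
#' @param upB,downB Flanking gene ids for locus B.
#' @param strandB Strand of locus B relative to A's frame (`"+"` or
#'   `"-"`).
#' @return `TRUE`, `FALSE`, or `NA` when either side lacks flank data.
#' @export
synteny_support <- function(upA, downA, upB, downB, strandB = "+") {
  if (identical(strandB, "-")) {
    tmp <- upB; upB <- downB; downB <- tmp
  }
  if (length(upA) == 0L || length(downA) == 0L ||
      length(upB) == 0L || length(downB) == 0L)
    return(NA)
  length(intersect(upA, upB)) > 0L && length(intersect(downA, downB)) > 0L
}
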