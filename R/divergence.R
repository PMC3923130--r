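#' Hairpin region annotation
#'
#' Describes where the mature arms sit on a microRNA hairpin, in 1-based
#' inclusive hairpin coordinates. The 6-mer seed of each arm occupies
#' mature positions 2-7; everything not covered by a mature arm is the
#' loop/stem-extension ("outside-mature") region.
#'
#' @param hairpin_length Hairpin length in nt.
#' @param arms Data frame with columns `arm` (`"5p"`/`"3p"`), `start`,
#'   `end` (1-based inclusive, non-overlapping, within the hairpin).
#' @return A list of class `"region_annotation"`. Arms of atypical
#'   mature length (outside 19-24 nt) are flagged in an `atypical`
#'   column, not rejected.
#' @export
region_annotation <- function(hairpin_length, arms) {
  stopifnot(all(c("arm", "start", "end") %in% names(arms)))
  if (any(arms$start < 1L | arms$end > hairpin_length | arms$start > arms$end))
    stop("arm annotation outside hairpin bounds")
  pos <- unlist(mapply(seq, arms$start, arms$end, SIMPLIFY = FALSE))
  if (anyDuplicated(pos)) stop("mature arms overlap")
  arms$atypical <- (arms$end - arms$start + 1L) < 19L |
    (arms$end - arms$start + 1L) > 24L
  structure(list(hairpin_length = as.integer(hairpin_length), arms = arms),
            class = "region_annotation")
}

#' Hairpin positions covered by a region
#'
#' @param regions A [region_annotation()].
#' @param which One of `"hairpin"`, `"mature"`, `"seed"`,
#'   `"outside_mature"`. The masks partition the hairpin: mature and
#'   outside-mature are complementary, and the seed (arm positions 2-7)
#'   is contained in the mature region.
#' @return Sorted integer vector of 1-based hairpin positions. Arms
#'   shorter than 7 nt have no defined seed and are skipped with a
#'   warning.
#' @export
region_slice <- function(regions,
                         which = c("hairpin", "mature", "seed",
                                   "outside_mature")) {
  which <- match.arg(which)
  L <- regions$hairpin_length
  arms <- regions$arms
  mature <- sort(unlist(mapply(seq, arms$start, arms$end, SIMPLIFY = FALSE)))
  switch(which,
    hairpin = seq_len(L),
    mature = mature,
    outside_mature = setdiff(seq_len(L), mature),
    seed = {
      keep <- (arms$end - arms$start + 1L) >= 7L
      if (any(!keep))
        warning("arm(s) shorter than 7 nt: seed undefined, skipped")
      if (!any(keep)) return(integer(0))
      sort(unlist(mapply(function(s, e) seq(s + 1L, s + 6L),
                         arms$start[keep], arms$end[keep],
                         SIMPLIFY = FALSE)))
    })
}

# Map ungapped positions of sequence A to alignment columns.
.cols_for_positions <- function(alignedA, positions) {
  chars <- strsplit(alignedA, "")[[1]]
  ungapped <- cumsum(chars != "-")
  ungapped[chars == "-"] <- NA_integer_
  match(positions, ungapped)
}

# Shared column bookkeeping: which columns are countable (no gap, no N
# in either sequence), and the paired characters.
.aln_columns <- function(alignment, region = NULL) {
  a <- strsplit(alignment$alignedA, "")[[1]]
  b <- strsplit(alignment$alignedB, "")[[1]]
  if (length(a) != length(b)) stop("ragged alignment")
  if (!is.null(region)) {
    cols <- .cols_for_positions(alignment$alignedA, region)
    cols <- cols[!is.na(cols)]
    a <- a[cols]; b <- b[cols]
  }
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  list(a = a[keep], b = b[keep])
}

#' Substitutions per site over an alignment region
#'
#' Counts mismatching columns among the countable columns of a pairwise
#' alignment. Gap columns and columns containing the ambiguity code N
#' are excluded from both the numerator and the denominator. Region
#' positions refer to the ungapped coordinates of the first sequence.
#'
#' @param alignment A [align_orthologs()] result (or any list with
#'   `alignedA`/`alignedB` strings).
#' @param region Optional integer vector of 1-based positions on the
#'   ungapped first sequence (e.g. from [region_slice()]); `NULL` uses
#'   the whole alignment.
#' @return List with `substitutions`, `sites`, and `rate`
#'   (substitutions/site; `NA` with a warning when the region has no
#'   countable column).
#' @examples
#' p_distance(list(alignedA = "ACGT", alignedB = "ACGA"))$rate # 0.25
#' @export
p_distance <- function(alignment, region = NULL) {
  cols <- .aln_columns(alignment, region)
  sites <- length(cols$a)
  subs <- sum(cols$a != cols$b)
  if (sites == 0L) {
    warning("region has no countable alignment column; rate undefined")
    return(list(substitutions = 0L, sites = 0L, rate = NA_real_))
  }
  list(substitutions = subs, sites = sites, rate = subs / sites)
}

#' Kimura two-parameter distance from transition/transversion fractions
#'
#' Closed form `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, where P and
#' Q are the observed proportions of transitions and transversions.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return The corrected distance `d`.
#' @export
k2p_closed_form <- function(P, Q) {
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("K2P saturation: distance undefined for P=", P, ", Q=", Q)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Kimura two-parameter distance over an alignment region
#'
#' Classifies mismatching columns into transitions (purine-purine or
#' pyrimidine-pyrimidine: A/G, C/T) and transversions, and corrects the
#' observed proportions for multiple hits with the two-parameter closed
#' form. Gap and N columns are excluded as in [p_distance()].
#'
#' @inheritParams p_distance
#' @return List with `d`, `P`, `Q`, and `sites`. Saturated alignments
#'   (log argument non-positive) raise an error.
#' @export
kimura2p <- function(alignment, region = NULL) {
  cols <- .aln_columns(alignment, region)
  sites <- length(cols$a)
  if (sites == 0L) {
    warning("region has no countable alignment column; distance undefined")
    return(list(d = NA_real_, P = NA_real_, Q = NA_real_, sites = 0L))
  }
  purine <- c("A", "G")
  diff <- cols$a != cols$b
  ts <- diff & ((cols$a %in% purine) == (cols$b %in% purine))
  P <- sum(ts) / sites
  Q <- sum(diff & !ts) / sites
  list(d = k2p_closed_form(P, Q), P = P, Q = Q, sites = sites)
}

#' Integer substitution counts in mature sequences
#'
#' Mature sequences are of approximately equal length (~22 nt), so their
#' divergence is summarized as integer substitution counts rather than
#' rates, in three classes: perfectly conserved ("0"), one or two
#' substitutions ("1-2"), and three or more (">=3"). Each arm of a
#' hairpin is reported separately.
#'
#' @inheritParams p_distance
#' @param regions A [region_annotation()] on the ungapped first
#'   sequence.
#' @return Data frame with one row per arm: `arm`, `substitutions`,
#'   `class`.
#' @export
mature_substitutions <- function(alignment, regions) {
  arms <- regions$arms
  out <- lapply(seq_len(nrow(arms)), function(i) {
    pd <- p_distance(alignment, seq(arms$start[i], arms$end[i]))
    data.frame(arm = arms$arm[i], substitutions = pd$substitutions,
               class = substitution_class(pd$substitutions),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname mature_substitutions
#' @param n Integer substitution count(s).
#' @export
substitution_class <- function(n) {
  cut(n, breaks = c(-0.5, 0.5, 2.5, Inf), labels = c("0", "1-2", ">=3"))
}

#' Region-partitioned divergence for one ortholog pair
#'
#' Convenience wrapper computing substitutions/site and the K2P distance
#' for every region of a hairpin (whole hairpin, mature, seed,
#' outside-mature), plus the per-arm mature substitution counts.
#' Saturated K2P distances are reported as `NA` rather than failing the
#' whole record.
#'
#' @inheritParams mature_substitutions
#' @param pair_id Identifier copied into the output.
#' @return List with `regions` (data frame: region, sites,
#'   substitutions, rate, K2P, P, Q) and `mature` (per-arm counts and
#'   classes), of class `"divergence_record"`.
#' @export
divergence_record <- function(alignment, regions, pair_id = NA_character_) {
  reg_names <- c("hairpin", "mature", "seed", "outside_mature")
  rows <- lapply(reg_names, function(rn) {
    mask <- region_slice(regions, rn)
    pd <- p_distance(alignment, mask)
    k2p <- tryCatch(suppressWarnings(kimura2p(alignment, mask)),
                    error = function(e) list(d = NA_real_, P = NA_real_,
                                             Q = NA_real_))
    data.frame(pair = pair_id, region = rn, sites = pd$sites,
               substitutions = pd$substitutions, rate = pd$rate,
               K2P = k2p$d, P = k2p$P, Q = k2p$Q, stringsAsFactors = FALSE)
  })
  structure(list(regions = do.call(rbind, rows),
                 mature = cbind(pair = pair_id,
                                mature_substitutions(alignment, regions))),
            class = "divergence_record")
}
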