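# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Brute-force global alignment: enumerate all gapped alignments of two
# short strings and return the best score under affine gap costs
# (gap of length L costs open + L * extend). Exponential; keep inputs
# at length <= 6.
brute_force_align_score <- function(a, b, match = 2, mismatch = -3,
                                    open = -5, extend = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  # state: last move (0 none, 1 diag, 2 gapA, 3 gapB) for affine costs
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 1L))
    }
    if (j <= length(b)) {  # gap in A consumes b[j]
      cost <- extend + if (last == 2L) 0 else open
      best <- max(best, cost + rec(i, j + 1, 2L))
    }
    if (i <= length(a)) {  # gap in B consumes a[i]
      cost <- extend + if (last == 3L) 0 else open
      best <- max(best, cost + rec(i + 1, j, 3L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Independent per-column scan of a gapped alignment restricted to
# positions (ungapped coords of A).
column_scan_counts <- function(alignedA, alignedB, positions = NULL) {
  a <- strsplit(alignedA, "")[[1]]
  b <- strsplit(alignedB, "")[[1]]
  upos <- cumsum(a != "-")
  keep <- rep(TRUE, length(a))
  if (!is.null(positions)) keep <- a != "-" & upos %in% positions
  keep <- keep & a != "-" & b != "-" & a != "N" & b != "N"
  list(sites = sum(keep), substitutions = sum(a[keep] != b[keep]))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# A small ready-made study shared by the heavier tests.
tiny_study <- function(n_families = 40, depth = 20000, seed = 42,
                       ...) {
  simulate_mirna_study(simulation_config(n_families = n_families,
                                         library_depth = depth,
                                         seed = seed, ...))
}
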