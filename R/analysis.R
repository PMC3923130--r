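#' Equally sized divergence bins
#'
#' Sorts microRNAs by sequence divergence (stable tie-break on the
#' identifier) and splits them into `n_bins` groups of near-equal size:
#' low, medium and high divergence for the default three bins. When the
#' group sizes cannot be exactly equal, the lower-divergence bins take
#' the remainder.
#'
#' @param divergence Named numeric vector (substitutions/site or any
#'   divergence measure), at least `n_bins` defined values.
#' @param n_bins Number of bins (default 3).
#' @return List of class `"divergence_bins"`: `membership` (list of id
#'   vectors per bin, low to high), `bin` (named factor per microRNA),
#'   `ranges` (divergence range per bin).
#' @export
tertile_bins <- function(divergence, n_bins = 3L) {
  divergence <- divergence[!is.na(divergence)]
  n <- length(divergence)
  if (n < n_bins) stop("need at least ", n_bins, " divergence values")
  if (length(unique(divergence)) == 1L)
    warning("all divergence values identical; bins follow input order")
  ids <- names(divergence)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(divergence, ids)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of <- rep(seq_len(n_bins), sizes)
  labels <- if (n_bins == 3L) c("low", "medium", "high")
            else paste0("bin", seq_len(n_bins))
  membership <- split(ids[ord], labels[bin_of])[labels]
  bin <- setNames(factor(labels[bin_of], levels = labels), ids[ord])
  ranges <- lapply(membership, function(m) range(divergence[m]))
  structure(list(membership = membership, bin = bin[ids],
                 ranges = ranges),
            class = "divergence_bins")
}

#' Per-stage expression share of each divergence bin
#'
#' For every developmental library, the fraction of total (normalized)
#' microRNA expression contributed by each divergence bin. Fractions
#' sum to 1 at every stage with non-zero total; a stage whose binned
#' microRNAs have zero total is flagged with `NA` fractions.
#'
#' @param x A [mir_counts()] normalized with [normalize_rpm()] (either
#'   denominator; shares are denominator-invariant), or a plain
#'   non-negative matrix.
#' @param bins A [tertile_bins()] result covering (a subset of) the
#'   rows.
#' @return Matrix of fractions, bins x stages.
#' @export
stage_composition <- function(x, bins) {
  m <- if (inherits(x, "mir_counts")) {
    if (is.null(x$rpm)) stop("normalize first") else x$rpm
  } else as.matrix(x)
  missing <- setdiff(unlist(bins$membership), rownames(m))
  if (length(missing)) stop("bin member not in matrix: ", missing[1])
  included <- unlist(bins$membership)
  tot <- colSums(m[included, , drop = FALSE])
  out <- vapply(bins$membership, function(ids)
    colSums(m[ids, , drop = FALSE]) / tot, numeric(ncol(m)))
  out <- t(out)
  if (any(tot == 0)) {
    warning("stage(s) with zero total expression: fractions undefined")
    out[, tot == 0] <- NA_real_
  }
  out
}

#' Divergence-expression correlation at one developmental stage
#'
#' Rank (or product-moment) correlation between sequence divergence and
#' expression level over the microRNAs detected at the given stage.
#' Spearman's rank correlation is independent of the normalization
#' denominator, since within-library ranks are unchanged by a positive
#' per-library scale factor.
#'
#' @param x A [mir_counts()] object.
#' @param divergence Named numeric vector of divergences.
#' @param stage Library label.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param threshold Raw-count detection threshold defining the stage's
#'   microRNA set.
#' @return List with `rho` (estimate), `p` (two-sided), `m` (number of
#'   microRNAs used). Zero variance in either variable gives `NA` with
#'   a warning.
#' @export
stage_correlation <- function(x, divergence, stage,
                              method = c("spearman", "pearson"),
                              threshold = 1) {
  method <- match.arg(method)
  vals <- if (!is.null(x$rpm)) x$rpm else x$counts
  det <- x$counts[, stage] >= threshold
  ids <- intersect(rownames(x$counts)[det],
                   names(divergence)[!is.na(divergence)])
  if (length(ids) < 3L)
    stop("fewer than 3 microRNAs detected at stage ", stage)
  e <- vals[ids, stage]
  d <- divergence[ids]
  if (stats::var(e) == 0 || stats::var(d) == 0) {
    warning("zero variance at stage ", stage, "; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, m = length(ids)))
  }
  ct <- suppressWarnings(stats::cor.test(d, e, method = method,
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, m = length(ids))
}

#' Breadth/divergence contrast
#'
#' Compares sequence divergence between microRNAs expressed at all
#' stages (maximal breadth) and those absent from one or more
#' libraries: two-sample t statistic on the group means (Welch by
#' default) plus the rank correlation of breadth and divergence.
#'
#' @param divergence Named numeric vector.
#' @param breadth Named integer vector as from [detect_breadth()].
#' @param max_breadth Breadth defining the "all stages" group
#'   (default: the maximum observed).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return List with group means, `t`, `p`, `rho` (Spearman breadth vs
#'   divergence) and `rho_p`. Degenerate zero-variance groups with
#'   different means give `t = Inf` (flagged via `degenerate = TRUE`).
#' @export
breadth_contrast <- function(divergence, breadth,
                             max_breadth = max(breadth), pooled = FALSE) {
  ids <- intersect(names(divergence)[!is.na(divergence)], names(breadth))
  d <- divergence[ids]
  g_all <- d[breadth[ids] >= max_breadth]
  g_few <- d[breadth[ids] < max_breadth]
  if (length(g_all) < 2L || length(g_few) < 2L)
    stop("each breadth group needs at least 2 members")
  degenerate <- stats::var(g_all) == 0 && stats::var(g_few) == 0
  if (degenerate) {
    tt <- list(statistic = c(t = if (mean(g_all) == mean(g_few)) 0
                                 else Inf * sign(mean(g_all) - mean(g_few))),
               p.value = NA_real_)
  } else {
    tt <- stats::t.test(g_all, g_few, var.equal = pooled)
  }
  ct <- suppressWarnings(stats::cor.test(breadth[ids], d,
                                         method = "spearman", exact = FALSE))
  list(mean_all_stages = mean(g_all), mean_fewer = mean(g_few),
       t = unname(tt$statistic), p = tt$p.value,
       rho = unname(ct$estimate), rho_p = ct$p.value,
       degenerate = degenerate)
}

#' Correlation of summarized expression with divergence
#'
#' Summarizes each microRNA's expression across all libraries (sum,
#' mean over libraries where it is detected, or maximum) and correlates
#' the summary with hairpin divergence. For the product-moment
#' correlation the summary is log10(x + 1)-transformed, matching the
#' log-scaled axes customarily used for read counts; Spearman is
#' transform-invariant.
#'
#' @param x A normalized [mir_counts()].
#' @param divergence Named numeric vector.
#' @param summary `"sum"`, `"mean_expressed"`, or `"max"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param threshold Detection threshold for `"mean_expressed"`.
#' @return List with `r`, `p`, `m`, and the summary used. Zero
#'   variance gives `NA` with a warning.
#' @export
expression_divergence_cor <- function(x, divergence,
                                      summary = c("sum", "mean_expressed",
                                                  "max"),
                                      method = c("pearson", "spearman"),
                                      threshold = 1) {
  summary <- match.arg(summary)
  method <- match.arg(method)
  vals <- if (!is.null(x$rpm)) x$rpm else x$counts
  ids <- intersect(rownames(vals), names(divergence)[!is.na(divergence)])
  if (length(ids) < 3L) stop("need at least 3 microRNAs")
  e <- switch(summary,
    sum = rowSums(vals[ids, , drop = FALSE]),
    max = apply(vals[ids, , drop = FALSE], 1L, max),
    mean_expressed = vapply(ids, function(i) {
      det <- x$counts[i, ] >= threshold
      if (!any(det)) 0 else mean(vals[i, det])
    }, numeric(1)))
  d <- divergence[ids]
  if (method == "pearson") e <- log10(e + 1)
  if (stats::var(e) == 0 || stats::var(d) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, m = length(ids),
                summary = summary))
  }
  ct <- suppressWarnings(stats::cor.test(e, d, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, m = length(ids),
       summary = summary)
}

#' Expression-weighted mean of a per-microRNA weight at one stage
#'
#' The common core of the transcriptome age index (TAI, weights = age
#' ranks) and transcriptome divergence index (TDI, weights =
#' substitutions per site): `sum(w_i * e_is) / sum(e_is)` over the
#' microRNAs expressed at stage s. The index is invariant to positive
#' rescaling of the expression vector and bounded by the extreme
#' weights.
#'
#' @param expression Non-negative expression values at one stage.
#' @param weights Weights aligned with `expression`.
#' @return The weighted mean.
#' @export
weighted_stage_index <- function(expression, weights) {
  if (length(expression) != length(weights))
    stop("expression and weights must align")
  tot <- sum(expression)
  if (tot <= 0) stop("stage total expression is zero")
  sum(weights * expression) / tot
}

#' Bootstrap standard deviation of a weighted stage index
#'
#' Resamples microRNAs (the rows, not reads) with replacement and
#' recomputes the weighted index for each replicate.
#'
#' @inheritParams weighted_stage_index
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @return Standard deviation of the index over `B` replicates.
#' @export
bootstrap_index_sd <- function(expression, weights, B = 1000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(expression)
  if (n < 2L) stop("need at least 2 microRNAs to bootstrap")
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    weighted_stage_index(expression[idx], weights[idx])
  }, numeric(1))
  stats::sd(reps)
}

#' TAI and TDI at one developmental stage
#'
#' @param x A normalized [mir_counts()].
#' @param ages Named integer vector of age ranks (1 = youngest).
#' @param divergence Named numeric vector of substitutions/site.
#' @param stage Library label.
#' @param threshold Raw-count detection threshold.
#' @return List with `TAI`, `TDI`, and `m` (microRNAs included:
#'   detected at the stage with both weights defined). High TAI means
#'   an older expressed microRNA complement; high TDI means a
#'   faster-evolving one.
#' @export
tai_tdi <- function(x, ages, divergence, stage, threshold = 1) {
  vals <- if (!is.null(x$rpm)) x$rpm else x$counts
  det <- x$counts[, stage] >= threshold
  ids <- Reduce(intersect, list(rownames(vals)[det],
                                names(ages)[!is.na(ages)],
                                names(divergence)[!is.na(divergence)]))
  e <- vals[ids, stage]
  list(TAI = weighted_stage_index(e, ages[ids]),
       TDI = weighted_stage_index(e, divergence[ids]),
       m = length(ids))
}

#' Per-stage TAI/TDI profile with bootstrap uncertainty
#'
#' Computes, for every developmental library: the transcriptome age and
#' divergence indices with their bootstrap standard deviations, and the
#' per-stage Spearman correlation of divergence and expression.
#'
#' @inheritParams tai_tdi
#' @param B Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame (one row per stage, in library order): `stage`,
#'   `m`, `TAI`, `TAI_sd`, `TDI`, `TDI_sd`, `rho`, `rho_p`.
#' @export
stage_indices <- function(x, ages, divergence, threshold = 1,
                          B = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- if (!is.null(x$rpm)) x$rpm else x$counts
  out <- lapply(x$stages, function(s) {
    idx <- tai_tdi(x, ages, divergence, s, threshold)
    det <- x$counts[, s] >= threshold
    ids <- Reduce(intersect, list(rownames(vals)[det],
                                  names(ages)[!is.na(ages)],
                                  names(divergence)[!is.na(divergence)]))
    e <- vals[ids, s]
    ct <- stage_correlation(x, divergence, s, "spearman", threshold)
    data.frame(stage = s, m = idx$m, TAI = idx$TAI,
               TAI_sd = bootstrap_index_sd(e, ages[ids], B),
               TDI = idx$TDI,
               TDI_sd = bootstrap_index_sd(e, divergence[ids], B),
               rho = ct$rho, rho_p = ct$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$stage <- factor(res$stage, levels = x$stages)
  res
}
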