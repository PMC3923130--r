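test_that("divergence bins are equally sized with remainders low", {
  d9 <- setNames(seq(0.1, 0.9, by = 0.1), paste0("m", 1:9))
  b9 <- tertile_bins(d9)
  expect_equal(lengths(b9$membership), c(low = 3L, medium = 3L, high = 3L))
  expect_equal(b9$membership$low, c("m1", "m2", "m3"))

  d10 <- setNames(seq_len(10) / 10, paste0("m", 1:10))
  b10 <- tertile_bins(d10)
  expect_equal(unname(lengths(b10$membership)), c(4L, 3L, 3L))

  expect_error(tertile_bins(c(a = 1, b = 2)), "at least 3")
  expect_warning(tertile_bins(setNames(rep(1, 6), letters[1:6])),
                 "identical")
})

test_that("stage composition fractions sum to one per stage", {
  m <- matrix(c(10, 0, 0, 0, 0,  0, 5, 0, 0, 0,  2, 2, 2, 2, 2), 5, 3,
              dimnames = list(paste0("m", 1:5), c("e0", "e2", "e4")))
  bins <- tertile_bins(setNames(c(0.1, 0.2, 0.3, 0.4, 0.5),
                                paste0("m", 1:5)))
  comp <- stage_composition(m, bins)
  expect_equal(unname(colSums(comp)), rep(1, 3))
  # all expression in the low bin at e0 (m1, m2 are the low bin)
  expect_equal(unname(comp["low", "e0"]), 1)
  # equal expression everywhere: fractions proportional to bin sizes
  eq <- matrix(1, 6, 2, dimnames = list(paste0("m", 1:6), c("a", "b")))
  bins6 <- tertile_bins(setNames(seq_len(6) / 10, paste0("m", 1:6)))
  expect_equal(unname(stage_composition(eq, bins6)[, 1]), rep(1 / 3, 3))
})

test_that("per-stage correlation handles toy and degenerate data", {
  m <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(paste0("m", 1:4), "e0"))
  x <- mir_counts(m)
  d <- setNames(1:4 / 10, paste0("m", 1:4))
  res <- stage_correlation(x, d, "e0")
  expect_equal(res$rho, -1)
  expect_error(stage_correlation(mir_counts(m[1:2, , drop = FALSE]),
                                 d, "e0"), "fewer than 3")
  const <- mir_counts(matrix(5, 4, 1,
                             dimnames = list(paste0("m", 1:4), "e0")))
  expect_warning(r0 <- stage_correlation(const, d, "e0"), "zero variance")
  expect_true(is.na(r0$rho))
})

test_that("Spearman per stage is invariant to the denominator", {
  st <- tiny_study(n_families = 60, depth = 3e4, seed = 12)
  div <- setNames(st$families$true_divergence, st$families$family)
  xm <- normalize_rpm(st$expression, "mirna_mapped")
  xg <- normalize_rpm(st$expression, "genome_mapped")
  for (s in c("e0", "e8", "adult")) {
    expect_equal(stage_correlation(xm, div, s)$rho,
                 stage_correlation(xg, div, s)$rho)
  }
})

test_that("breadth contrast computes t and rank correlation", {
  div <- setNames(c(0.1, 0.12, 0.11, 0.4, 0.45, 0.38), paste0("m", 1:6))
  breadth <- setNames(c(11, 11, 11, 3, 5, 2), paste0("m", 1:6))
  bc <- breadth_contrast(div, breadth)
  expect_lt(bc$mean_all_stages, bc$mean_fewer)
  expect_lt(bc$t, 0)
  expect_lt(bc$rho, 0)
  # identical groups: t = 0
  same <- breadth_contrast(setNames(c(1, 2, 1, 2), paste0("m", 1:4)),
                           setNames(c(11, 11, 5, 5), paste0("m", 1:4)))
  expect_equal(same$t, 0)
  # degenerate zero-variance groups with different means
  degen <- breadth_contrast(setNames(c(1, 1, 2, 2), paste0("m", 1:4)),
                            setNames(c(11, 11, 5, 5), paste0("m", 1:4)))
  expect_true(degen$degenerate)
  expect_equal(degen$t, -Inf)
  expect_error(breadth_contrast(setNames(1:3 / 10, paste0("m", 1:3)),
                                setNames(c(11, 5, 5), paste0("m", 1:3))),
               "at least 2")
})

test_that("summary-level expression-divergence correlations agree in sign", {
  st <- tiny_study(n_families = 80, depth = 5e4, seed = 14)
  x <- normalize_rpm(st$expression, "mirna_mapped")
  div <- setNames(st$families$true_divergence, st$families$family)
  r_sum <- expression_divergence_cor(x, div, "sum")
  r_max <- expression_divergence_cor(x, div, "max")
  r_mean <- expression_divergence_cor(x, div, "mean_expressed")
  expect_lt(r_sum$r, 0)  # conserved microRNAs more highly expressed
  expect_equal(sign(r_sum$r), sign(r_max$r))
  expect_equal(sign(r_sum$r), sign(r_mean$r))
  expect_warning(rc <- expression_divergence_cor(
    x, setNames(rep(0.2, 80), names(div)), "sum"), "zero variance")
  expect_true(is.na(rc$r))
})

test_that("TAI/TDI are expression-weighted means with their identities", {
  m <- matrix(c(100, 300), 2, 1, dimnames = list(c("m1", "m2"), "e0"))
  x <- mir_counts(m)
  ages <- setNames(c(2, 6), c("m1", "m2"))
  div <- setNames(c(0.1, 0.3), c("m1", "m2"))
  res <- tai_tdi(x, ages, div, "e0")
  expect_equal(res$TAI, 5)    # (2*100 + 6*300) / 400
  expect_equal(res$TDI, 0.25) # (0.1*100 + 0.3*300) / 400
  # constant ages give TAI equal to the constant for any expression
  const <- tai_tdi(x, setNames(c(4, 4), c("m1", "m2")), div, "e0")
  expect_equal(const$TAI, 4)
  # invariance under positive rescaling of the stage's counts
  x10 <- mir_counts(m * 13.7)
  expect_equal(tai_tdi(x10, ages, div, "e0")$TAI, res$TAI)
  # bounded by the extreme weights
  expect_gte(res$TAI, min(ages))
  expect_lte(res$TAI, max(ages))
  expect_error(weighted_stage_index(c(0, 0), c(1, 2)), "zero")
})

test_that("bootstrap SD is zero for constant weights and shrinks with m", {
  e <- runif(30, 1, 100)
  expect_equal(bootstrap_index_sd(e, rep(3, 30), B = 1000, seed = 1), 0)
  set.seed(77)
  e_small <- rlnorm(25); w_small <- runif(25, 1, 7)
  e_big <- rlnorm(400); w_big <- runif(400, 1, 7)
  sd_small <- bootstrap_index_sd(e_small, w_small, B = 400, seed = 2)
  sd_big <- bootstrap_index_sd(e_big, w_big, B = 400, seed = 2)
  expect_lt(sd_big, sd_small)
  # doubling B leaves the estimate stable within Monte-Carlo error
  s1 <- bootstrap_index_sd(e_big, w_big, B = 500, seed = 3)
  s2 <- bootstrap_index_sd(e_big, w_big, B = 1000, seed = 3)
  expect_lt(abs(s1 - s2) / s1, 0.25)
})

test_that("stage index profile assembles per-stage results", {
  st <- tiny_study(n_families = 50, depth = 2e4, seed = 6)
  x <- normalize_rpm(st$expression, "mirna_mapped")
  div <- setNames(st$families$true_divergence, st$families$family)
  ages <- setNames(st$families$age_rank, st$families$family)
  idx <- stage_indices(x, ages, div, B = 50, seed = 9)
  expect_equal(nrow(idx), 11L)
  expect_true(all(idx$TAI >= 1 & idx$TAI <= 7))
  expect_true(all(idx$TDI >= 0))
  expect_true(all(idx$TAI_sd >= 0 & idx$TDI_sd >= 0))
  expect_true(all(abs(idx$rho) <= 1))
})
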