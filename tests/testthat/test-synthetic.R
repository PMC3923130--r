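test_that("configuration invariants are enforced", {
  expect_error(simulation_config(birth_rates = c("rank=1" = 0)),
               "birth rate")
  expect_error(simulation_config(nb_dispersion = -0.1), "dispersion")
  expect_error(simulation_config(stages = "e0"), "stages")
  expect_error(simulation_config(region_rates = c(seed = -1, mature = 0.1,
                                                  outside = 0.2)),
               "non-negative")
  expect_error(simulation_config(library_depth = 0), "positive")
  expect_error(simulation_config(birth_rates = c(nowhere = 1)),
               "node labels")
})

test_that("degenerate birth configurations behave as forced", {
  cfg1 <- simulation_config(n_families = 30,
                            birth_rates = c("rank=1" = 1), seed = 3)
  f1 <- simulate_families(cfg1)
  expect_true(all(f1$families$age_rank == 1L))
  expect_true(all(f1$presence[, c("Dmel", "Dvir")] == 1L))
  expect_true(all(f1$presence[, "Bflo"] == 0L))

  cfg7 <- simulation_config(n_families = 30,
                            birth_rates = c("rank=7" = 1), seed = 3)
  f7 <- simulate_families(cfg7)
  expect_true(all(f7$presence == 1L))
})

test_that("branch counts follow the multinomial expectation", {
  probs <- c("rank=1" = 0.4, "rank=3" = 0.3, "rank=5" = 0.2,
             "rank=7" = 0.1)
  cfg <- simulation_config(n_families = 1000, birth_rates = probs,
                           seed = 5)
  fam <- simulate_families(cfg)$families
  counts <- table(factor(fam$origin_label, levels = names(probs)))
  n <- 1000
  for (b in names(probs)) {
    expected <- n * probs[[b]]
    sigma <- sqrt(n * probs[[b]] * (1 - probs[[b]]))
    expect_lt(abs(counts[[b]] - expected), 3 * sigma)
  }
})

test_that("ortholog evolution respects configured rates", {
  reg <- region_annotation(88, data.frame(arm = c("5p", "3p"),
                                          start = c(10, 58),
                                          end = c(31, 79)))
  # zero rate: identical ortholog
  cfg0 <- simulation_config(region_rates = c(seed = 0, mature = 0,
                                             outside = 0))
  h <- random_hairpin(88, seed = 9)
  p0 <- evolve_ortholog_pair(h, reg, cfg0)
  expect_identical(p0$alignedA, p0$alignedB)

  # enormous rate: observed identity saturates near 1/4 (p-dist ~ 0.75)
  cfg10 <- simulation_config(region_rates = c(seed = 10, mature = 10,
                                              outside = 10))
  set.seed(9)
  psat <- mean(replicate(20, p_distance(
    evolve_ortholog_pair(random_hairpin(88), reg, cfg10))$rate))
  expect_lt(abs(psat - 0.75), 0.05)

  # length mismatch between hairpin and annotation is an error
  expect_error(evolve_ortholog_pair(random_hairpin(50), reg, cfg0),
               "does not match")
})

test_that("slower seed than loop yields less seed divergence", {
  reg <- region_annotation(88, data.frame(arm = c("5p", "3p"),
                                          start = c(10, 58),
                                          end = c(31, 79)))
  cfg <- simulation_config(region_rates = c(seed = 0.05, mature = 0.1,
                                            outside = 0.5))
  set.seed(13)
  res <- replicate(500, {
    p <- evolve_ortholog_pair(random_hairpin(88), reg, cfg)
    c(seed = p_distance(p, region_slice(reg, "seed"))$rate,
      loop = p_distance(p, region_slice(reg, "outside_mature"))$rate)
  })
  expect_lt(mean(res["seed", ]), mean(res["loop", ]))
})

test_that("null association gives near-zero per-stage correlations", {
  cfg <- simulation_config(n_families = 200, assoc_strength = 0,
                           expr_div_coupling = 0, seed = 19,
                           library_depth = 5e4)
  set.seed(19)
  div <- setNames(runif(200, 0.01, 0.5), paste0("m", 1:200))
  ex <- simulate_expression(div, cfg, seed = NULL)
  x <- normalize_rpm(ex$counts, "mirna_mapped")
  rhos <- vapply(cfg$stages, function(s)
    stage_correlation(x, div, s)$rho, numeric(1))
  expect_true(all(abs(rhos) < 0.2))
})

test_that("positive association biases fast evolvers to early stages", {
  st <- tiny_study(n_families = 150, depth = 1e5, seed = 8)
  x <- normalize_rpm(st$expression, "mirna_mapped")
  div <- setNames(st$families$true_divergence, st$families$family)
  rhos <- vapply(st$config$stages, function(s)
    stage_correlation(x, div, s)$rho, numeric(1))
  expect_equal(unname(which.max(rhos)), 1L)
})

test_that("a zero-mean microRNA is absent from every library", {
  cfg <- simulation_config(n_families = 5, seed = 2, library_depth = 1e4)
  div <- setNames(rep(0.1, 5), paste0("m", 1:5))
  base <- c(1, 1, 1, 1, 0)
  ex <- simulate_expression(div, cfg, base_abundance = base, seed = 2)
  expect_true(all(ex$counts$counts["m5", ] == 0))
})

test_that("reads round-trip through emit and count exactly", {
  st <- tiny_study(n_families = 25, depth = 4000, seed = 33)
  reads <- emit_reads(st$expression, st$mature_orth, seed = 1)
  expect_equal(nrow(reads[[1]]), sum(st$expression$counts[, 1]))
  counted <- count_to_hairpins(reads, st$hairpins_orth, st$regions)
  expect_equal(counted$counts$counts, st$expression$counts + 0,
               ignore_attr = FALSE)
  expect_true(all(counted$unassigned == 0))
  # per-arm counts sum to the hairpin count
  arm_tot <- rowsum(counted$arm_counts,
                    sub("\\|.*$", "", rownames(counted$arm_counts)))
  expect_equal(arm_tot[rownames(counted$counts$counts), ],
               counted$counts$counts)
})

test_that("a single count emits that many identical reads", {
  m <- matrix(7L, 1, 1, dimnames = list("mirX", "e0"))
  reads <- emit_reads(m, c(mirX = strrep("ACGT", 5)), seed = 1)
  expect_equal(nrow(reads$e0), 7L)
  expect_equal(unique(reads$e0$sequence), strrep("ACGT", 5))
  expect_error(emit_reads(m, c(mirX = strrep("A", 30))), "19-24")
})

test_that("injected contaminants are removed by the read filter", {
  st <- tiny_study(n_families = 10, depth = 1000, seed = 21)
  reads <- emit_reads(st$expression, st$mature_orth,
                      contaminant_fraction = 0.1,
                      multimapper_fraction = 0.05, seed = 4)
  lib <- reads[[1]]
  filtered <- filter_reads(lib)
  expect_true(all(nchar(filtered$sequence) >= 19 &
                    nchar(filtered$sequence) <= 24))
  expect_true(all(filtered$n_loci <= 4))
  # survivors are exactly the clean reads
  expect_equal(nrow(filtered), sum(st$expression$counts[, 1]))
})
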