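test_that("region masks partition the hairpin", {
  reg <- region_annotation(80, data.frame(arm = c("5p", "3p"),
                                          start = c(10, 50),
                                          end = c(31, 71)))
  mature <- region_slice(reg, "mature")
  outside <- region_slice(reg, "outside_mature")
  seeds <- region_slice(reg, "seed")
  expect_equal(sort(c(mature, outside)), 1:80)
  expect_equal(length(outside), 80 - 44)
  expect_true(all(seeds %in% mature))
  # seed = mature positions 2-7 of each arm
  expect_equal(seeds, c(11:16, 51:56))
  expect_error(region_annotation(80, data.frame(arm = "5p", start = 70,
                                                end = 95)),
               "outside hairpin")
  expect_error(region_annotation(80, data.frame(arm = c("5p", "3p"),
                                                start = c(10, 20),
                                                end = c(31, 41))),
               "overlap")
  short <- region_annotation(80, data.frame(arm = "5p", start = 10,
                                            end = 14))
  expect_warning(region_slice(short, "seed"), "seed undefined")
})

test_that("p-distance counts mismatching non-gap columns", {
  expect_equal(p_distance(list(alignedA = "ACGT",
                               alignedB = "ACGA"))$rate, 0.25)
  # gap column excluded from sites and substitutions
  gapped <- p_distance(list(alignedA = "AC-GT", alignedB = "ACCGT"))
  expect_equal(gapped$sites, 4L)
  expect_equal(gapped$rate, 0)
  # N columns dropped
  expect_equal(p_distance(list(alignedA = "ANGT",
                               alignedB = "AAGT"))$sites, 3L)
  expect_warning(
    res <- p_distance(list(alignedA = "--", alignedB = "AA")),
    "undefined")
  expect_true(is.na(res$rate))
})

test_that("p-distance equals an independent column scan on random alignments", {
  set.seed(23)
  for (rep in 1:20) {
    a <- strsplit(random_seq(100), "")[[1]]
    b <- strsplit(random_seq(100), "")[[1]]
    # inject gaps into random columns
    a[sample(100, 5)] <- "-"
    b[sample(100, 5)] <- "-"
    aln <- list(alignedA = paste(a, collapse = ""),
                alignedB = paste(b, collapse = ""))
    got <- p_distance(aln)
    want <- column_scan_counts(aln$alignedA, aln$alignedB)
    expect_equal(got$sites, want$sites)
    expect_equal(got$substitutions, want$substitutions)
  }
})

test_that("K2P closed form is exact and flags saturation", {
  expect_equal(k2p_closed_form(0, 0), 0)
  # frozen from an independent 30-digit evaluation of the closed form
  expect_equal(k2p_closed_form(0.10, 0.05), 0.170181165140347039,
               tolerance = 1e-12)
  expect_error(k2p_closed_form(0.5, 0), "saturation")
  expect_error(k2p_closed_form(0.2, 0.6), "saturation")
})

test_that("alignment-based K2P matches ape's K80 estimator", {
  set.seed(31)
  cfg <- simulation_config(region_rates = c(seed = 0.2, mature = 0.2,
                                            outside = 0.2))
  reg <- config_regions(cfg)
  for (rep in 1:10) {
    h <- random_hairpin(88)
    pair <- evolve_ortholog_pair(h, reg, cfg)
    ours <- kimura2p(pair)
    bin <- ape::as.DNAbin(rbind(A = strsplit(tolower(pair$alignedA), "")[[1]],
                                B = strsplit(tolower(pair$alignedB), "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(ours$d, ref, tolerance = 1e-10)
    # multiple-hit correction never shrinks the observed distance
    expect_gte(ours$d, p_distance(pair)$rate)
  }
})

test_that("mature substitution counts classify per arm", {
  reg <- region_annotation(60, data.frame(arm = c("5p", "3p"),
                                          start = c(5, 35),
                                          end = c(26, 56)))
  a <- random_seq(60)
  # two substitutions in the 5p arm, three in the 3p arm
  bb <- strsplit(a, "")[[1]]
  flip <- function(x) chartr("ACGT", "GTAC", x)
  bb[c(6, 7)] <- flip(bb[c(6, 7)])
  bb[c(36, 40, 44)] <- flip(bb[c(36, 40, 44)])
  ms <- mature_substitutions(list(alignedA = a,
                                  alignedB = paste(bb, collapse = "")),
                             reg)
  expect_equal(ms$substitutions[ms$arm == "5p"], 2L)
  expect_equal(as.character(ms$class), c("1-2", ">=3"))
  none <- mature_substitutions(list(alignedA = a, alignedB = a), reg)
  expect_equal(as.character(none$class), c("0", "0"))
  expect_equal(as.character(substitution_class(c(0, 1, 2, 3, 9))),
               c("0", "1-2", "1-2", ">=3", ">=3"))
})

test_that("substitutions partition exactly across regions", {
  reg <- region_annotation(88, data.frame(arm = c("5p", "3p"),
                                          start = c(10, 58),
                                          end = c(31, 79)))
  cfg <- simulation_config(region_rates = c(seed = 0.05, mature = 0.1,
                                            outside = 0.4))
  set.seed(17)
  for (rep in 1:25) {
    pair <- evolve_ortholog_pair(random_hairpin(88), reg, cfg)
    hp <- p_distance(pair, region_slice(reg, "hairpin"))
    mat <- p_distance(pair, region_slice(reg, "mature"))
    out <- p_distance(pair, region_slice(reg, "outside_mature"))
    expect_identical(hp$substitutions, mat$substitutions + out$substitutions)
    expect_identical(hp$sites, mat$sites + out$sites)
  }
})

test_that("divergence records assemble all regions for a pair", {
  st <- tiny_study(n_families = 5)
  aln <- align_orthologs(st$hairpins_ref[[1]], st$hairpins_orth[[1]])
  rec <- divergence_record(aln, st$regions, pair_id = "p1")
  expect_setequal(rec$regions$region,
                  c("hairpin", "mature", "seed", "outside_mature"))
  expect_true(all(rec$regions$substitutions <= rec$regions$sites))
  expect_true(all(rec$regions$P + rec$regions$Q <= 1, na.rm = TRUE))
  expect_equal(nrow(rec$mature), 2L)
})
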