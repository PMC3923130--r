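#' Configuration for the synthetic microRNA study generator
#'
#' Bundles every tunable of the generator: the ranked species tree,
#' family birth probabilities per branch, region-specific substitution
#' rates on the focal-species path, the transition:transversion ratio,
#' the ordered developmental libraries, the strength of the coupling
#' between sequence divergence and early-stage expression bias, and the
#' negative-binomial count model.
#'
#' Divergence rates are expressed in expected substitutions per site on
#' the path between the two focal species. Older families evolve more
#' slowly: each family's region rates are scaled by
#' `exp(-age_rate_decay * (age_rank - 1))` times lognormal noise.
#' Stage earliness is a linear score from 1 (earliest library) to 0
#' (adult); the log-scale expression model for microRNA i at stage s is
#' `log b_i + expr_div_coupling * d_i + assoc_strength * d_i *
#' earliness_s`, so a positive `assoc_strength` biases fast-evolving
#' microRNAs toward early stages while `expr_div_coupling < 0` keeps the
#' overall conservation-expression correlation negative.
#'
#' @param tree Ranked species tree ([default_species_tree()]).
#' @param reference Reference species tip (homology queries).
#' @param ortholog_species Second focal species (divergence, reads).
#' @param n_families Number of microRNA families to simulate.
#' @param birth_rates Named numeric vector of birth probabilities per
#'   origin node label (`"rank=1"`..`"rank=7"`, optionally tip labels
#'   for species-specific families). Must not sum to zero.
#' @param region_rates Named vector `c(seed=, mature=, outside=)` of
#'   substitutions/site for the seed, mature-nonseed, and
#'   loop/stem-extension regions.
#' @param age_rate_decay Per-rank decay of the family rate factor.
#' @param rate_lognorm_sd Lognormal sd of the family rate factor.
#' @param ts_tv_ratio Transition:transversion event ratio (kappa).
#' @param stages Ordered library labels (>= 2).
#' @param assoc_strength Coefficient coupling divergence to early-stage
#'   expression bias (log scale per unit divergence).
#' @param expr_div_coupling Stage-independent log-scale coefficient of
#'   divergence on expression (negative = conserved microRNAs more
#'   highly expressed).
#' @param abundance_sdlog Lognormal sd of the baseline per-microRNA
#'   abundance (sets the dynamic range of expression).
#' @param nb_dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); must be non-negative.
#' @param library_depth Expected microRNA-mapped reads per library.
#' @param background_fraction Extra genome-mapped (non-microRNA) reads
#'   as a fraction of microRNA-mapped reads.
#' @param hairpin_length,arm5p,arm3p Hairpin geometry: length and the
#'   1-based inclusive coordinates of the two mature arms.
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @return List of class `"sim_config"`.
#' @export
simulation_config <- function(tree = default_species_tree(),
                              reference = "Dmel",
                              ortholog_species = "Dvir",
                              n_families = 300L,
                              birth_rates = c("rank=1" = 0.30,
                                              "rank=2" = 0.10,
                                              "rank=3" = 0.12,
                                              "rank=4" = 0.12,
                                              "rank=5" = 0.08,
                                              "rank=6" = 0.08,
                                              "rank=7" = 0.20),
                              region_rates = c(seed = 0.04, mature = 0.08,
                                               outside = 0.35),
                              age_rate_decay = 0.25,
                              rate_lognorm_sd = 0.4,
                              ts_tv_ratio = 2,
                              stages = c("e0", "e2", "e4", "e6", "e8",
                                         "e10", "e12", "e14", "e16",
                                         "larva", "adult"),
                              assoc_strength = 12,
                              expr_div_coupling = -8,
                              abundance_sdlog = 1.2,
                              nb_dispersion = 0.3,
                              library_depth = 2e5,
                              background_fraction = 0.6,
                              hairpin_length = 88L,
                              arm5p = c(10L, 31L),
                              arm3p = c(58L, 79L),
                              seed = 1L) {
  validate_species_tree(tree)
  if (any(region_rates < 0)) stop("region_rates must be non-negative")
  if (length(stages) < 2L) stop("need at least 2 stages")
  if (library_depth <= 0) stop("library_depth must be positive")
  if (nb_dispersion < 0) stop("negative dispersion")
  if (sum(birth_rates) <= 0) stop("total birth rate is zero")
  if (!all(c("seed", "mature", "outside") %in% names(region_rates)))
    stop("region_rates needs seed, mature, outside entries")
  known <- c(tree$node.label, tree$tip.label)
  if (!all(names(birth_rates) %in% known))
    stop("birth_rates names must be node labels or tips of the tree")
  structure(list(tree = tree, reference = reference,
                 ortholog_species = ortholog_species,
                 n_families = as.integer(n_families),
                 birth_rates = birth_rates, region_rates = region_rates,
                 age_rate_decay = age_rate_decay,
                 rate_lognorm_sd = rate_lognorm_sd,
                 ts_tv_ratio = ts_tv_ratio, stages = stages,
                 assoc_strength = assoc_strength,
                 expr_div_coupling = expr_div_coupling,
                 abundance_sdlog = abundance_sdlog,
                 nb_dispersion = nb_dispersion,
                 library_depth = library_depth,
                 background_fraction = background_fraction,
                 hairpin_length = as.integer(hairpin_length),
                 arm5p = as.integer(arm5p), arm3p = as.integer(arm3p),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default hairpin region annotation for a configuration
#'
#' @param config A [simulation_config()].
#' @return A [region_annotation()] with the configured 5p/3p arms.
#' @export
config_regions <- function(config) {
  region_annotation(config$hairpin_length,
                    data.frame(arm = c("5p", "3p"),
                               start = c(config$arm5p[1], config$arm3p[1]),
                               end = c(config$arm5p[2], config$arm3p[2])))
}

#' Simulate microRNA family births on a species tree
#'
#' Draws an origin branch for each family from the configured birth
#' probabilities and derives the noise-free presence/absence table: a
#' species carries a homolog iff it descends from the origin node. The
#' family's true age rank is the rank of the origin node (0 for births
#' on the reference terminal branch).
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed; defaults to the config seed. Use `NULL` to
#'   draw from the current RNG state.
#' @return List with `families` (data frame: family, origin_label,
#'   age_rank, rate_factor), `presence` (0/1 matrix, families x
#'   species), and `tree`.
#' @export
simulate_families <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  phy <- config$tree
  ntip <- length(phy$tip.label)
  origins <- sample(names(config$birth_rates), config$n_families,
                    replace = TRUE, prob = config$birth_rates)
  fam_ids <- sprintf("mir-s%03d", seq_len(config$n_families))
  ranks <- integer(config$n_families)
  presence <- matrix(0L, config$n_families, ntip,
                     dimnames = list(fam_ids, phy$tip.label))
  for (i in seq_len(config$n_families)) {
    lab <- origins[i]
    if (lab %in% phy$tip.label) {
      ranks[i] <- 0L
      presence[i, lab] <- 1L
    } else {
      node <- ntip + match(lab, phy$node.label)
      ranks[i] <- node_age_ranks(phy)[node - ntip]
      presence[i, node_species(phy, node)] <- 1L
    }
  }
  # older families evolve slower, with lognormal family-to-family noise
  factor <- exp(-config$age_rate_decay * pmax(ranks - 1L, 0L)) *
    stats::rlnorm(config$n_families,
                  meanlog = -config$rate_lognorm_sd^2 / 2,
                  sdlog = config$rate_lognorm_sd)
  fams <- data.frame(family = fam_ids, origin_label = origins,
                     age_rank = ranks, rate_factor = factor,
                     stringsAsFactors = FALSE)
  list(families = fams, presence = presence, tree = phy)
}

#' Random hairpin sequence
#'
#' @param length Sequence length.
#' @param seed Optional RNG seed.
#' @return A DNA string (A/C/G/T, uniform).
#' @export
random_hairpin <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Evolve a diverged ortholog of a hairpin
#'
#' Places substitutions on the hairpin under a two-parameter
#' (transition/transversion) process: each site receives a Poisson
#' number of substitution events at its region's rate (optionally scaled
#' by a per-family rate factor), and each event is a transition with
#' probability `kappa / (kappa + 1)`. Multiple hits at a site are
#' applied sequentially, so observed divergence saturates exactly as in
#' real sequences. Indels are not modelled; the returned pair is a
#' gap-free alignment.
#'
#' @param hairpin Ancestral hairpin sequence (A/C/G/U/T).
#' @param regions A [region_annotation()] partitioning the hairpin.
#' @param config A [simulation_config()] supplying `region_rates` and
#'   `ts_tv_ratio`.
#' @param rate_factor Per-family scaling of all region rates.
#' @param seed Optional RNG seed (`NULL`: current RNG state).
#' @return List with `alignedA` (input), `alignedB` (ortholog),
#'   `true_rates` (expected substitutions/site per region, including the
#'   position-weighted `hairpin` average), and `events` (realized event
#'   counts per region).
#' @export
evolve_ortholog_pair <- function(hairpin, regions, config,
                                 rate_factor = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hairpin <- .prep_seq(hairpin, "hairpin")
  L <- nchar(hairpin)
  if (L != regions$hairpin_length)
    stop("region annotation does not match hairpin length")
  seedpos <- region_slice(regions, "seed")
  mature <- region_slice(regions, "mature")
  outside <- region_slice(regions, "outside_mature")
  rate_by_pos <- numeric(L)
  rate_by_pos[outside] <- config$region_rates[["outside"]]
  rate_by_pos[mature] <- config$region_rates[["mature"]]
  rate_by_pos[seedpos] <- config$region_rates[["seed"]]
  rate_by_pos <- rate_by_pos * rate_factor

  chars <- strsplit(hairpin, "")[[1]]
  kappa <- config$ts_tv_ratio
  n_events <- stats::rpois(L, rate_by_pos)
  region_of <- rep("mature_nonseed", L)
  region_of[outside] <- "outside"
  region_of[seedpos] <- "seed"
  events <- c(seed = 0L, mature_nonseed = 0L, outside = 0L)
  for (i in which(n_events > 0L)) {
    for (k in seq_len(n_events[i])) {
      if (stats::runif(1) < kappa / (kappa + 1)) {
        chars[i] <- .TRANSITION[[chars[i]]]
      } else {
        chars[i] <- sample(.TRANSVERSIONS[[chars[i]]], 1L)
      }
    }
    events[region_of[i]] <- events[region_of[i]] + n_events[i]
  }
  true_rates <- c(config$region_rates, hairpin = unname(
    sum(rate_by_pos) / L / rate_factor)) * rate_factor
  list(alignedA = hairpin, alignedB = paste(chars, collapse = ""),
       true_rates = true_rates, events = events)
}

#' Simulate stage-structured microRNA expression counts
#'
#' Generates negative-binomial counts for each microRNA across the
#' ordered developmental libraries. Expected per-library totals equal
#' the configured library depth; the log-mean of each microRNA carries
#' the configured divergence coupling and the divergence-by-earliness
#' interaction (see [simulation_config()]).
#'
#' @param divergence Named numeric vector of true hairpin divergences
#'   (substitutions/site), one per microRNA.
#' @param config A [simulation_config()].
#' @param base_abundance Optional named vector of baseline relative
#'   abundances; drawn lognormal(0, `abundance_sdlog`) when `NULL`.
#' @param seed Optional RNG seed (`NULL`: current RNG state).
#' @return List with `counts` (a [mir_counts()] object), `true_mean`
#'   (expected count matrix), and `earliness` (per-stage score).
#' @export
simulate_expression <- function(divergence, config, base_abundance = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$nb_dispersion < 0) stop("negative dispersion")
  n <- length(divergence)
  ids <- names(divergence)
  if (is.null(ids)) ids <- paste0("mir", seq_len(n))
  stages <- config$stages
  earliness <- seq(1, 0, length.out = length(stages))
  if (is.null(base_abundance))
    base_abundance <- stats::rlnorm(n, meanlog = 0,
                                    sdlog = config$abundance_sdlog)
  logw <- outer(config$expr_div_coupling * divergence +
                  log(base_abundance),
                rep(1, length(stages))) +
    outer(config$assoc_strength * divergence, earliness)
  w <- exp(logw)
  mu <- sweep(w, 2L, colSums(w), "/") * config$library_depth
  size <- if (config$nb_dispersion == 0) Inf else 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(n * length(stages), mu = mu, size = size),
                   n, length(stages), dimnames = list(ids, stages))
  cnt <- mir_counts(counts, stages = stages,
                    genome_mapped = round(colSums(counts) *
                                            (1 + config$background_fraction)))
  list(counts = cnt, true_mean = mu, earliness = earliness)
}

#' Emit per-library read sets from a count matrix
#'
#' Materializes each count as that many copies of the microRNA's mature
#' sequence, so that the downstream filter/count stage can be exercised
#' end-to-end: with no contaminants, counting the emitted reads
#' reproduces the matrix exactly. Optional contaminants are injected for
#' filter testing: reads of length 18 or 30 nt, and multi-locus reads
#' annotated as mapping to 5 genomic loci.
#'
#' @param counts Raw count matrix (microRNA x library) or a
#'   [mir_counts()] object.
#' @param mature_seqs Named character vector of mature sequences
#'   (19-24 nt) per microRNA.
#' @param contaminant_fraction Fraction of extra off-length reads per
#'   library.
#' @param multimapper_fraction Fraction of extra reads annotated as
#'   mapping to 5 loci.
#' @param seed Optional RNG seed (`NULL`: current RNG state).
#' @return Named list (one per library) of read data frames with
#'   columns `sequence`, `n_loci`, `mismatches`.
#' @export
emit_reads <- function(counts, mature_seqs, contaminant_fraction = 0,
                       multimapper_fraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(counts, "mir_counts")) counts <- counts$counts
  len <- nchar(mature_seqs)
  if (any(len < 19L | len > 24L))
    stop("mature sequences must be 19-24 nt")
  missing <- setdiff(rownames(counts), names(mature_seqs))
  if (length(missing)) stop("no mature sequence for: ", missing[1])
  lapply(setNames(colnames(counts), colnames(counts)), function(lib) {
    n <- counts[, lib]
    seqs <- rep(mature_seqs[rownames(counts)], n)
    reads <- data.frame(sequence = unname(seqs), n_loci = 1L,
                        mismatches = 0L, stringsAsFactors = FALSE)
    n_clean <- nrow(reads)
    if (contaminant_fraction > 0 && n_clean > 0) {
      k <- round(contaminant_fraction * n_clean)
      if (k > 0) {
        lens <- sample(c(18L, 30L), k, replace = TRUE)
        reads <- rbind(reads, data.frame(
          sequence = vapply(lens, random_hairpin, character(1)),
          n_loci = 1L, mismatches = 0L, stringsAsFactors = FALSE))
      }
    }
    if (multimapper_fraction > 0 && n_clean > 0) {
      k <- round(multimapper_fraction * n_clean)
      if (k > 0)
        reads <- rbind(reads, data.frame(
          sequence = vapply(rep(22L, k), random_hairpin, character(1)),
          n_loci = 5L, mismatches = 0L, stringsAsFactors = FALSE))
    }
    reads
  })
}

#' Simulate a complete synthetic microRNA study
#'
#' Runs the full generator: family births on the species tree, random
#' reference hairpins, diverged orthologs in the second focal species,
#' and stage-structured expression counts, with every ground-truth
#' quantity recorded for parameter-recovery testing.
#'
#' @param config A [simulation_config()].
#' @return List of class `"mirna_study"`: `config`, `tree`, `families`
#'   (with true age, rate factor, and true hairpin divergence),
#'   `presence`, `regions`, `hairpins_ref` / `hairpins_orth` (named
#'   character vectors), `mature_orth` (mature 5p sequences of the
#'   ortholog species, the read source), `expression`
#'   (a [mir_counts()]), and `truth` (true mean matrix, per-stage
#'   earliness and association sign, per-pair true region rates and
#'   realized event counts).
#' @export
simulate_mirna_study <- function(config = simulation_config()) {
  set.seed(config$seed)
  fams <- simulate_families(config, seed = NULL)
  regions <- config_regions(config)
  n <- config$n_families
  ids <- fams$families$family
  hairpins_ref <- setNames(vapply(seq_len(n), function(i)
    random_hairpin(config$hairpin_length), character(1)), ids)
  pairs <- lapply(seq_len(n), function(i)
    evolve_ortholog_pair(hairpins_ref[[i]], regions, config,
                         rate_factor = fams$families$rate_factor[i]))
  hairpins_orth <- setNames(vapply(pairs, `[[`, character(1), "alignedB"),
                            ids)
  true_div <- setNames(vapply(pairs, function(p)
    p$true_rates[["hairpin"]], numeric(1)), ids)
  fams$families$true_divergence <- unname(true_div)
  mature_orth <- setNames(substr(hairpins_orth, config$arm5p[1],
                                 config$arm5p[2]), ids)
  expr <- simulate_expression(true_div, config, seed = NULL)
  earliness <- expr$earliness
  structure(list(
    config = config, tree = fams$tree, families = fams$families,
    presence = fams$presence, regions = regions,
    hairpins_ref = hairpins_ref, hairpins_orth = hairpins_orth,
    mature_orth = mature_orth, expression = expr$counts,
    truth = list(
      true_mean = expr$true_mean, earliness = earliness,
      assoc_sign = sign(config$expr_div_coupling +
                          config$assoc_strength * earliness),
      region_rates = lapply(pairs, `[[`, "true_rates"),
      events = lapply(pairs, `[[`, "events"))),
    class = "mirna_study")
}
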