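---
title: "Methods: microRNA age, divergence and developmental expression"
author: "mirage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microRNA age, divergence and developmental expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirage)
```

## The scientific question

Animal microRNAs differ enormously in evolutionary age: some families
predate the bilaterian radiation, others arose within a single genus.
Older microRNAs tend to evolve slowly and to be broadly and highly
expressed, yet conservation of the transcriptome is not uniform across
development. `mirage` packages the analysis chain needed to ask, for a
set of microRNAs in a focal fly species: *how old is each family, how
fast has each hairpin evolved since the split of two focal species, and
how does the expressed microRNA complement shift between fast- and
slow-evolving genes across a developmental time course?*

The chain has five computational parts, each exposed as ordinary R
functions and orchestrated by `run_pipeline()`:

1. **Homology and age** — ortholog pairing by reciprocal best hits,
   with optional synteny support, and parsimony dating of family
   origins on a ranked species tree.
2. **Divergence** — region-partitioned substitution rates
   (substitutions per site and Kimura two-parameter distances) over the
   hairpin, the mature arms, the 6-mer seed, and the loop/stem
   extension.
3. **Expression** — small-RNA read filtering, counting against
   hairpins, paralog read splitting, and RPM normalization under two
   denominators.
4. **Stage-wise statistics** — divergence-tertile composition,
   per-stage rank correlations, breadth contrasts, and the
   transcriptome age and divergence indices (TAI/TDI) with bootstrap
   standard deviations.
5. **A synthetic-study generator** that emulates every input a real
   study would supply, with full ground truth, so the whole chain is
   testable end-to-end.

## Parsimony age dating

The species tree is a rooted `phylo` object whose internal nodes carry
integer **age ranks** in their labels (`rank=1` … `rank=7` on the
default eight-taxon ladder). Rank 1 is the most recent common ancestor
of the two focal Drosophilids; rank 7 is the bilaterian root. Ranks
must be non-decreasing from the tips toward the root, so the rank of
any origin node is a well-defined age.

`assign_age()` places a family's origin at the most recent common
ancestor of the species in which a homolog was found (together with
the reference species) and reports that node's rank. The operation is
monotone: adding a species to the presence set can only move the
origin rootward, never tipward. A family found only in the reference
species originates on the reference's terminal branch; because the
internal rank classes start at 1, this terminal class is encoded as
rank 0 — deliberately *below* every internal rank, mirroring the
convention that species-specific microRNAs are excluded from the 1–7
age weighting of the TAI (they are given `NA` weights downstream).
Within a family, every paralog inherits the age of the oldest member
(`propagate_family_age()`); members whose own presence-based age is
younger are flagged `duplication_inflated`, since their apparent youth
reflects a later duplication, not a later family origin.

## Ortholog pairing

`reciprocal_best_hits()` scores all cross-species hairpin pairs by
optimal global alignment and accepts a pair only when each member is
the *unique* top-scoring hit of the other. Ties reject the pair: the
goal is unambiguous 1-to-1 orthologs, and an arbitrary tie-break would
manufacture certainty that the sequences do not support. The scoring
scheme (match +2, mismatch −3, gap open −5, extend −2) mirrors the
classical short-nucleotide BLASTN reward/penalty ratio; the gap
penalties are deliberately stiff because spurious gapped alignments of
~90-nt hairpins are a bigger risk than missed gapped homology at the
divergence scales involved. Alignment is exact Needleman–Wunsch with
affine gaps (Gotoh's three-state recursion, implemented in C++), with
a deterministic tie-break: an aligned pair beats a gap, and a gap in
the first sequence beats a gap in the second. Determinism matters
because downstream substitution counts must be reproducible to the
digit across platforms.

`synteny_support()` optionally corroborates a pair: support requires a
shared flanking gene on *each* side (upstream and downstream),
swapping sides for a minus-strand partner. Missing flank data returns
`NA` ("unknown"), never `FALSE` — absence of evidence is not evidence
of rearrangement.

## Region-partitioned divergence

Hairpin regions are defined on the ungapped coordinates of one
anchoring sequence (in the pipeline, the ortholog species whose
expression is profiled): the two mature arms from the annotation, the
seed as mature positions 2–7 of each arm, and the loop/stem extension
as everything else. The masks partition the hairpin exactly, which
gives the package one of its strongest internal checks: on any
gap-free alignment, hairpin substitutions must equal mature plus
outside-mature substitutions *exactly*, not approximately.

Two divergence measures are always computed:

* **substitutions per site** (`p_distance()`): mismatching columns
  over countable columns. Gap columns and columns containing `N` are
  excluded from numerator *and* denominator — the standard
  substitution-rate convention, and the one that keeps the partition
  identity exact.
* **Kimura two-parameter distance** (`kimura2p()`):
  $d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ with $P$ and
  $Q$ the observed transition and transversion fractions. Saturated
  alignments (non-positive log argument) raise an error rather than
  returning a fabricated distance; the batch wrapper
  (`divergence_record()`) records them as `NA`.

Mature-arm divergence is additionally summarized as an **integer
substitution count** in three classes (0, 1–2, ≥3), because mature
sequences are of nearly equal length (~22 nt) and integer counts are
easier to interpret at that scale. Each arm of a hairpin is classified
separately.

Downstream analyses default to plain substitutions per site as the
divergence weight; the K2P distance is carried alongside. On the
default synthetic study the two differ by well under 10% (hairpin
rates are ≤ ~0.5 substitutions per site), so the choice is largely
cosmetic; it is switchable where it matters.

## Expression processing

`filter_reads()` keeps a read iff its length is 19–24 nt, it maps to
at most 4 genomic loci, and at most one mismatch was used in mapping;
an optional sequence blocklist stands in for rRNA/tRNA/ncRNA
pre-filtering. Removal counts per rule are attached to the result and
logged by the pipeline. `count_to_hairpins()` assigns reads to hairpin
loci by exact/1-mismatch string matching (no indels); a read matching
several loci — paralogs sharing a mature sequence — is divided equally
among them at counting time, so read totals are conserved.
`split_paralog_reads()` applies the same equal-division rule to
precomputed count tables (bypass mode). Per-arm counts are retained
for arm-usage summaries.

Normalization is reads-per-million under either the microRNA-mapped
denominator (columns then sum to $10^6$) or the genome-mapped
denominator; the choice is recorded on the object. Rank-based
statistics are provably invariant to the choice — the per-stage
Spearman correlations are recomputed under both denominators in the
test suite and must agree identically.

Two screening rules from small-RNA practice are implemented as
explicit, configurable operations rather than manual curation:
`flag_outliers()` flags microRNAs whose count in any library reaches
10× the next most highly expressed microRNA of that library (such
dominance outliers would otherwise control every composition
fraction); `high_expression_filter()` partitions microRNAs at 1000
summed RPM, i.e. 1/1000 of the microRNA-mapped reads.

The detection rule behind expression breadth is a raw count ≥ 1 in a
library by default. This is the weakest defensible rule; it is a
configuration knob (`threshold`) everywhere it is used, because no
principled floor can be chosen without knowing the library depths and
error profile of a particular data set.

## Stage-wise statistics

`tertile_bins()` splits microRNAs into three equally sized divergence
groups (stable tie-break on the identifier; remainders go to the
lower-divergence bins). `stage_composition()` reports each bin's share
of total normalized expression per stage; shares sum to one by
construction. `stage_correlation()` gives the per-stage Spearman ρ of
divergence versus expression over the microRNAs detected at that
stage.

The **transcriptome age index** and **transcriptome divergence index**
at stage $s$ are expression-weighted means over the $m$ microRNAs
expressed at that stage:

$$\mathrm{TAI}_s = \frac{\sum_i a_i e_{is}}{\sum_i e_{is}}, \qquad
  \mathrm{TDI}_s = \frac{\sum_i n_i e_{is}}{\sum_i e_{is}},$$

with $a_i$ the age rank (1 = youngest, 7 = oldest) and $n_i$ the
hairpin substitutions per site. High TAI means an older expressed
complement; high TDI a faster-evolving one. Both indices are invariant
to positive rescaling of a stage's counts (so RPM vs raw is
irrelevant) and bounded by the extreme weights. Their uncertainty is
estimated by bootstrapping the microRNA set — resampling rows, not
reads — 1000 times by default and reporting the standard deviation of
the replicate indices. Species-specific microRNAs (age rank 0, no
ortholog, hence no divergence) are excluded from both indices by
default: the indices require defined weights, and the 1–7 age scale
does not cover them.

## The synthetic-study generator

`simulate_mirna_study()` emulates everything a real study would
download or sequence, with ground truth recorded for every quantity
the pipeline later estimates:

* **Family births** are drawn per family from configurable per-branch
  probabilities on the ranked tree; the presence/absence table marks
  exactly the descendants of the origin (noise-free by default), so
  parsimony dating is exactly recoverable and any failure is a bug,
  not noise. The default branch probabilities put weight both on the
  youngest class (recent Drosophilid expansions) and the root class
  (ancient bilaterian families), the age structure typical of insect
  microRNA complements.
* **Ortholog evolution** places a Poisson number of substitution
  events per site at region-specific rates (defaults, in expected
  substitutions per site on the focal-species path: seed 0.04, mature
  0.08, loop/stem extension 0.35 — conserved functional regions, fast
  loops), each event a transition with probability
  $\kappa/(\kappa+1)$, $\kappa = 2$ by default. Multiple hits accrue
  naturally, so the K2P estimator is tested against genuine
  saturation, not a linearized toy. Older families evolve more slowly:
  rates scale by $e^{-0.25\,(a_i - 1)}$ times lognormal
  family-to-family noise (sd 0.4). Indels are not simulated: the
  divergence measures are substitution-based and the alignment step is
  exercised separately.
* **Expression** is negative-binomial (dispersion 0.3) around
  log-scale means
  $\log b_i + c\,d_i + \alpha\,d_i\,\mathrm{earliness}_s$, where
  $b_i$ is a lognormal baseline abundance (sd 1.2 on the log scale,
  ~3 orders of magnitude of dynamic range), $d_i$ the true hairpin
  divergence, and earliness falls linearly from 1 at the first library
  to 0 in the adult. Expected library totals equal the configured
  depth ($2 \times 10^5$ reads by default — a desk-scale stand-in for
  deeply sequenced libraries). Genome-mapped totals are the microRNA
  totals plus a configurable background fraction (default 0.6).
* **Reads** (`emit_reads()`) materialize each count as copies of the
  mature sequence, with optional off-length (18/30-nt) and multi-locus
  contaminants for filter testing. With no contaminants,
  emit-then-count reproduces the count matrix exactly.

**Calibration of the association defaults.** The generator's
early-bias configuration is the package's standing test bed, so its
effect sizes are chosen to make the qualitative pattern structural
rather than marginal: with coupling $c = -8$ and association
$\alpha = 12$, the adult-stage divergence-expression correlation sits
near ρ ≈ −0.35 (the magnitude reported for real fly data), the
early-embryo correlation near zero (the early correlation is
characteristically weaker), and the divergence-by-earliness term spans
several natural-log units across the divergence range between the
first and last stages, comfortably above the negative-binomial
sampling noise at ~300 microRNAs. A convex, maternal-decay-like
earliness profile was evaluated during design and rejected: it
concentrates all contrast in the first two stages and flattens the
late-stage gradient, destabilizing the adult-end ordering that the
linear profile reproduces robustly.

**What the generator does not emulate.** Real read data carry adapter
remnants, sequencing errors, genomic background, arm-switching, cluster
rearrangements, and presence/absence error from failed homology
searches; libraries differ in depth; mature products vary ±2 nt around
annotated ends. Passing the packaged end-to-end checks therefore
demonstrates the *correctness of the computations* under a faithful
null model of the study design — not robustness to every artifact of
a real sequencing experiment. The module boundaries accept real data
(FASTA/GFF3/Newick/TSV) wherever those artifacts have been handled by
the usual upstream tools (Cutadapt, Bowtie, curated alignments).

## Numerical and degenerate-input choices

* Alignment tie-breaks are fixed (pair > gap-in-A > gap-in-B); RBH
  score ties reject the pair.
* Gap and `N` columns drop out of both numerator and denominator of
  every rate; a region with zero countable columns yields `NA` with a
  warning, never a silent 0.
* K2P saturation is an error at the single-pair level and `NA` at the
  batch level.
* Tertile remainders go to the lower-divergence bins; all-equal
  divergence values warn and split in stable input order.
* The dominance-outlier rule uses `>=` at exactly the fold threshold.
* Welch's t-test is the default for the breadth contrast (pooled
  variance by flag); two zero-variance groups with different means
  report `t = ±Inf` with a `degenerate` flag.
* Product-moment correlations with expression are computed on
  `log10(x + 1)`; Spearman statistics are transform-free.
* All randomness flows from one integer seed per run; bootstrap and
  pipeline results are reproducible byte-for-byte for tabular output.

## Problem sizes

The packaged test suite and acceptance checks run the generator at its
default study scale (300 families, 11 libraries, $2\times10^5$ reads
per library), the K2P estimator-recovery check at 200 replicate pairs
of length 1000, parsimony recovery at 500 families, and bootstrap
identities at $B = 1000$. These sizes were chosen so that every
stochastic check has comfortable statistical resolution while the full
suite completes in well under a minute on a single core.

## Known limitations

* Alignment is global and structure-blind; hairpins with large indels
  or arm shifts should be curated upstream.
* The read counter is a string matcher, not a genome aligner: reads
  from loci absent from the supplied hairpin set are "unassigned",
  and multimapping statistics must be provided by the caller (or the
  generator).
* Parsimony dating inherits the presence/absence table's quality; no
  allowance is made for secondary loss, which biases ages young.
* TDI compares only microRNAs with defined divergence; studies differ
  in how they treat species-specific genes, and the package's
  exclusion default is one convention among several.
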