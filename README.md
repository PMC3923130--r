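# mirage

MicroRNA evolutionary **age**, sequence **divergence**, and
developmental **expression** — an R package for relating how old and
how fast-evolving each microRNA family is to when it is expressed
across a developmental time course.

The package is aimed at small-RNA and molecular-evolution researchers
working with a pair of focal species (the motivating system is two
Drosophilids): it takes hairpin sequences with mature-arm annotation,
per-library small-RNA reads or count tables, a ranked species tree
with a homolog presence/absence table, and produces ortholog pairs,
family ages, region-partitioned divergence estimates, normalized
expression, and the stage-wise statistics that summarize how the
expressed microRNA complement shifts between conserved and
fast-evolving genes over development. A phylogeny-aware synthetic-data
generator with recorded ground truth makes the whole chain testable
end-to-end.

## The statistics at the core

* **Parsimony age**: a family's origin is the most recent common
  ancestor of all species carrying a homolog; its age rank
  *a<sub>i</sub>* ∈ 1..7 is the rank of that node (1 = youngest,
  conserved only within the Drosophilids; 7 = conserved across
  Bilateria). Paralogs inherit the oldest member's age.
* **Region-partitioned divergence**: substitutions per site
  *n<sub>i</sub>* and the Kimura two-parameter distance
  *d* = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)
  over the whole hairpin, the mature arms, the seed (mature positions
  2–7), and the loop/stem extension; mature arms also get integer
  substitution counts in classes 0 / 1–2 / ≥3.
* **Transcriptome age and divergence indices** at stage *s*:

  TAI<sub>s</sub> = Σᵢ aᵢ·eᵢₛ / Σᵢ eᵢₛ,  TDI<sub>s</sub> = Σᵢ nᵢ·eᵢₛ / Σᵢ eᵢₛ

  (expression-weighted means over the *m* microRNAs expressed at the
  stage; high TAI = older complement, high TDI = faster-evolving),
  with standard deviations from 1000× bootstrap over the microRNA set,
  plus per-stage Spearman correlations of divergence vs expression,
  divergence-tertile composition shares, and breadth contrasts.

Expression processing follows standard small-RNA practice: reads of
19–24 nt mapping to at most 4 loci with at most 1 mismatch are
counted against hairpins; reads of paralogs sharing a mature sequence
are divided equally among loci; normalization is reads-per-million
under a microRNA-mapped or genome-mapped denominator; dominance
outliers (≥10× the next-highest count in a library) are flagged.

## Worked example

Simulate a 120-family study, pair orthologs, estimate divergence for
one pair, and compute the per-stage index profile:

```r
library(mirage)

cfg   <- simulation_config(n_families = 120, library_depth = 5e4, seed = 7)
study <- simulate_mirna_study(cfg)

pairs <- reciprocal_best_hits(study$hairpins_ref, study$hairpins_orth)
nrow(pairs)
#> [1] 120          # all 120 true ortholog pairs recovered

aln <- align_orthologs(study$hairpins_ref[["mir-s001"]],
                       study$hairpins_orth[["mir-s001"]])
divergence_record(aln, study$regions, "mir-s001")$regions
#>       pair         region sites substitutions       rate        K2P
#> 1 mir-s001        hairpin    88             7 0.07954545 0.08567173
#> 2 mir-s001         mature    44             0 0.00000000 0.00000000
#> 3 mir-s001           seed    12             0 0.00000000 0.00000000
#> 4 mir-s001 outside_mature    44             7 0.15909091 0.18673122
```

Seven of this hairpin's substitutions fall outside the mature arms and
none inside — the typical pattern for a conserved microRNA, and the
K2P distance slightly exceeds the raw rate because it corrects for
multiple hits. The stage profile:

```r
x    <- normalize_rpm(study$expression, "mirna_mapped")
div  <- setNames(study$families$true_divergence, study$families$family)
ages <- setNames(study$families$age_rank,        study$families$family)
stage_indices(x, ages, div, B = 1000, seed = 7)
#>    stage   m  TAI TAI_sd    TDI  TDI_sd      rho    rho_p
#> 1     e0 120 3.11  0.324 0.1588 0.01158  0.45609 1.65e-07
#> ...
#> 11 adult 120 5.07  0.416 0.0873 0.00728 -0.30032 8.60e-04
```

Read across the rows: the earliest embryonic library has the youngest
(TAI 3.1) and fastest-evolving (TDI 0.159) microRNA complement, and by
the adult the complement is older (TAI 5.1), slower (TDI 0.087), and
the divergence-expression correlation has turned clearly negative
(ρ = −0.30) — fast-evolving microRNAs are an early-embryo phenomenon
in this simulated study, which is exactly the association its
generator encodes.

The full chain, with cached stages, file outputs and a digest
manifest, is one call:

```r
run_pipeline(simulation_config(seed = 1), "run1")
```

or from the shell, `Rscript inst/scripts/run_pipeline.R --out run1
--seed 1`.

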