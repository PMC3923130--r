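#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates simulate -> homology/age -> divergence -> expression ->
#' analysis as one reproducible run. Every stage writes its outputs
#' under `outdir/<stage>/`; a stage whose outputs already exist is
#' skipped unless `force = TRUE`, so deleting one stage's directory
#' reruns only that stage and its dependents. A manifest recording the
#' configuration, seeds, file digests and stage timings is written at
#' the end; identical configuration and seed give byte-identical
#' tabular outputs.
#'
#' @param config A [simulation_config()] or the path to a YAML file
#'   written by [write_config_yaml()].
#' @param outdir Output directory.
#' @param bootstrap_B Bootstrap replicates for the index standard
#'   deviations.
#' @param detection_threshold Raw-count detection threshold.
#' @param force Rerun stages whose outputs already exist.
#' @return The run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         bootstrap_B = 1000L, detection_threshold = 1,
                         force = FALSE) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage_dir <- function(s) {
    d <- file.path(outdir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  run_stage <- function(name, outputs, fn) {
    paths <- file.path(outdir, outputs)
    if (!force && all(file.exists(paths))) {
      message("[", name, "] cached, skipping")
      return(invisible(NULL))
    }
    message("[", name, "] running")
    t0 <- Sys.time()
    fn()
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0,
                                            units = "secs"))
    if (!all(file.exists(paths)))
      stop("stage '", name, "' did not produce: ",
           paths[!file.exists(paths)][1])
    invisible(NULL)
  }

  # -- simulate -------------------------------------------------------
  sim_files <- file.path("simulate",
                         c("hairpins_ref.fa", "hairpins_orth.fa",
                           "mature.gff3", "species.nwk", "presence.tsv",
                           "counts.tsv", "config.yaml",
                           "families_truth.tsv"))
  run_stage("simulate", sim_files, function() {
    study <- simulate_mirna_study(config)
    write_study(study, stage_dir("simulate"))
  })

  hairpins_ref <- read_fasta(file.path(outdir, "simulate/hairpins_ref.fa"))
  hairpins_orth <- read_fasta(file.path(outdir,
                                        "simulate/hairpins_orth.fa"))
  regions_by_locus <- read_mature_gff3(file.path(outdir,
                                                 "simulate/mature.gff3"))
  tree <- read_species_tree(file.path(outdir, "simulate/species.nwk"))
  presence <- read_presence_tsv(file.path(outdir, "simulate/presence.tsv"))

  # -- homology & age -------------------------------------------------
  run_stage("homology", c("homology/ortholog_pairs.tsv",
                          "homology/ages.tsv"), function() {
    d <- stage_dir("homology")
    pairs <- reciprocal_best_hits(hairpins_ref, hairpins_orth)
    write.table(pairs, file.path(d, "ortholog_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ages <- assign_ages(presence, tree, config$reference)
    write.table(ages, file.path(d, "ages.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  pairs <- read.delim(file.path(outdir, "homology/ortholog_pairs.tsv"))
  ages_tab <- read.delim(file.path(outdir, "homology/ages.tsv"))

  # -- divergence -----------------------------------------------------
  run_stage("divergence", c("divergence/divergence.tsv",
                            "divergence/mature_classes.tsv"), function() {
    d <- stage_dir("divergence")
    recs <- lapply(seq_len(nrow(pairs)), function(i) {
      aln <- align_orthologs(hairpins_ref[[pairs$locusA[i]]],
                             hairpins_orth[[pairs$locusB[i]]])
      divergence_record(aln, regions_by_locus[[pairs$locusB[i]]],
                        pair_id = pairs$locusA[i])
    })
    div <- do.call(rbind, lapply(recs, `[[`, "regions"))
    mat <- do.call(rbind, lapply(recs, `[[`, "mature"))
    write.table(div, file.path(d, "divergence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(mat, file.path(d, "mature_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  div <- read.delim(file.path(outdir, "divergence/divergence.tsv"))

  # -- expression -----------------------------------------------------
  run_stage("expression", c("expression/rpm_mirna.tsv",
                            "expression/breadth.tsv",
                            "expression/flags.tsv"), function() {
    d <- stage_dir("expression")
    x <- read_counts_tsv(file.path(outdir, "simulate/counts.tsv"))
    xm <- normalize_rpm(x, "mirna_mapped")
    write_counts_tsv(xm, file.path(d, "rpm_mirna.tsv"))
    breadth <- detect_breadth(x, detection_threshold)
    write.table(data.frame(mirna = names(breadth),
                           breadth = as.integer(breadth)),
                file.path(d, "breadth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    flags <- flag_outliers(x)
    write.table(data.frame(mirna = flags), file.path(d, "flags.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("  flagged ", length(flags), " dominance outlier(s)")
  })

  # -- analysis -------------------------------------------------------
  run_stage("analyze", c("analyze/stage_indices.tsv",
                         "analyze/composition.tsv",
                         "analyze/results.json"), function() {
    d <- stage_dir("analyze")
    x <- read_counts_tsv(file.path(outdir, "simulate/counts.tsv"))
    x <- normalize_rpm(x, "mirna_mapped")
    flagged <- read.delim(file.path(outdir, "expression/flags.tsv"))$mirna
    hp <- div[div$region == "hairpin", ]
    divergence <- setNames(hp$rate, hp$pair)
    ages <- setNames(ages_tab$age_rank, ages_tab$family)
    ages[ages == 0] <- NA  # species-specific: no 1..7 rank
    divergence[names(divergence) %in% flagged] <- NA
    breadth <- with(read.delim(file.path(outdir,
                                         "expression/breadth.tsv")),
                    setNames(breadth, mirna))

    idx <- stage_indices(x, ages, divergence,
                         threshold = detection_threshold,
                         B = bootstrap_B, seed = config$seed)
    write.table(idx, file.path(d, "stage_indices.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bins <- tertile_bins(divergence)
    comp <- stage_composition(x, bins)
    write.table(data.frame(bin = rownames(comp), comp,
                           check.names = FALSE),
                file.path(d, "composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bc <- tryCatch(breadth_contrast(divergence, breadth),
                   error = function(e) {
                     message("  breadth contrast skipped: ",
                             conditionMessage(e))
                     NULL
                   })
    res <- list(schema_version = "1.0",
                stage_indices = idx,
                composition = as.data.frame(comp),
                bin_ranges = bins$ranges,
                breadth_contrast = if (!is.null(bc))
                  bc[c("mean_all_stages", "mean_fewer", "t", "p",
                       "rho", "rho_p")])
    jsonlite::write_json(res, file.path(d, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  })

  # -- manifest -------------------------------------------------------
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    tool = paste0("mirage ", as.character(utils::packageVersion("mirage"))),
    seed = config$seed,
    generated = format(Sys.time(), tz = "UTC"),
    stage_timings_s = timings,
    files = lapply(setNames(files, sub(paste0("^", outdir, "/?"), "",
                                       files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Validate pipeline input files
#'
#' Checks that the input files parse, that coordinates are in bounds,
#' and that species names are consistent between the tree and the
#' presence table. Failures are reported, not raised.
#'
#' @param paths Named list with any of `hairpins` (FASTA), `gff3`
#'   (mature-arm annotation), `tree` (Newick), `presence` (TSV),
#'   `counts` (TSV).
#' @return Data frame with columns `check`, `ok`, `detail`; zero rows
#'   of `ok = FALSE` means a clean report.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(check, ok, detail = "") {
    report[[length(report) + 1L]] <<- data.frame(
      check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  }
  hairpins <- NULL
  if (!is.null(paths$hairpins)) {
    hairpins <- tryCatch(read_fasta(paths$hairpins), error = identity)
    if (inherits(hairpins, "error")) {
      note("hairpins parse", FALSE, conditionMessage(hairpins))
      hairpins <- NULL
    } else note("hairpins parse", TRUE)
  }
  if (!is.null(paths$gff3)) {
    regs <- tryCatch(read_mature_gff3(paths$gff3), error = identity)
    if (inherits(regs, "error")) {
      note("gff3 parse", FALSE, conditionMessage(regs))
    } else {
      note("gff3 parse", TRUE)
      if (!is.null(hairpins)) {
        for (id in names(regs)) {
          if (!id %in% names(hairpins)) {
            note("gff3/hairpin ids", FALSE, paste(id, "not in FASTA"))
          } else if (regs[[id]]$hairpin_length != nchar(hairpins[[id]]) ||
                     max(regs[[id]]$arms$end) > nchar(hairpins[[id]])) {
            note("gff3 bounds", FALSE,
                 paste(id, "mature arm outside hairpin"))
          }
        }
        note("gff3 bounds checked", TRUE)
      }
    }
  }
  tree <- NULL
  if (!is.null(paths$tree)) {
    tree <- tryCatch(read_species_tree(paths$tree), error = identity)
    if (inherits(tree, "error")) {
      note("tree parse", FALSE, conditionMessage(tree))
      tree <- NULL
    } else note("tree parse", TRUE)
  }
  if (!is.null(paths$presence)) {
    pres <- tryCatch(read_presence_tsv(paths$presence), error = identity)
    if (inherits(pres, "error")) {
      note("presence parse", FALSE, conditionMessage(pres))
    } else {
      note("presence parse", TRUE)
      if (!is.null(tree)) {
        extra <- setdiff(colnames(pres), tree$tip.label)
        note("presence species on tree", length(extra) == 0L,
             if (length(extra)) paste("unknown species:",
                                      paste(extra, collapse = ", "))
             else "")
      }
    }
  }
  if (!is.null(paths$counts)) {
    cnt <- tryCatch(read_counts_tsv(paths$counts), error = identity)
    note("counts parse", !inherits(cnt, "error"),
         if (inherits(cnt, "error")) conditionMessage(cnt) else "")
  }
  do.call(rbind, report)
}
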