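# End-to-end orchestration: configuration, the synthesize and run-all entry
# points, per-stage outputs and the run manifest.

#' Pipeline configuration
#'
#' @param genome Path to the genome FASTA.
#' @param mods_a,mods_b Paths to the per-condition modification GFF3 files.
#' @param annotation Path to the gene-annotation GFF3.
#' @param counts_a,counts_b Paths to the per-condition count TSVs.
#' @param islands Optional path to an islands BED.
#' @param out_dir Output directory.
#' @param k Expression categories for the standing profiles (default 3).
#' @param metric Expression metric for categorisation.
#' @param motifs Motif definitions (strings with lowercase methylation
#'   marks, or [motif_spec()] objects).
#' @param sweep A [sweep_config()] or preset name.
#' @param score_min Ingest-time score filter for landscape statistics
#'   (default 21: calls counted as methylated).
#' @param seed Integer seed (bootstrap CIs).
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, mods_a, mods_b, annotation,
                            counts_a, counts_b, islands = NULL,
                            out_dir = "methylink_out", k = 3L,
                            metric = "rpkm",
                            motifs = c("AgGCcT", "GaTNNNNNGtGG"),
                            sweep = "main", score_min = 21,
                            seed = 1L, overwrite = FALSE) {
  paths <- c(genome = genome, mods_a = mods_a, mods_b = mods_b,
             annotation = annotation, counts_a = counts_a,
             counts_b = counts_b)
  if (!is.null(islands)) paths <- c(paths, islands = islands)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) do not exist: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
  if (is.character(sweep)) sweep <- sweep_preset(sweep)
  if (is.character(motifs)) motifs <- lapply(motifs, motif_spec)
  structure(list(paths = as.list(paths), islands = islands,
                 out_dir = out_dir, k = as.integer(k), metric = metric,
                 motifs = motifs, sweep = sweep, score_min = score_min,
                 seed = as.integer(seed), overwrite = isTRUE(overwrite)),
            class = "pipeline_config")
}

#' Write a synthetic input bundle to disk
#'
#' Emits the exact formats the pipeline reads: `genome.fasta`,
#' `mods_A.gff3` / `mods_B.gff3`, `annotation.gff3`, `counts_A.tsv` /
#' `counts_B.tsv` and `truth.json`.
#'
#' @param scenario A [synthetic_scenario()] (or a dataset already built by
#'   [generate_linked_dataset()]).
#' @param out_dir Output directory (created if needed).
#' @return The output directory path, invisibly; the dataset as attribute
#'   `"dataset"`.
#' @export
run_synthesize <- function(scenario, out_dir) {
  ds <- if (inherits(scenario, "synthetic_scenario"))
    generate_linked_dataset(scenario) else scenario
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(ds$genome, file.path(out_dir, "genome.fasta"))
  write_modifications_gff(ds$mods_a, file.path(out_dir, "mods_A.gff3"))
  write_modifications_gff(ds$mods_b, file.path(out_dir, "mods_B.gff3"))
  write_annotation_gff(ds$genes, file.path(out_dir, "annotation.gff3"))
  write_counts_tsv(ds$counts_a, file.path(out_dir, "counts_A.tsv"))
  write_counts_tsv(ds$counts_b, file.path(out_dir, "counts_B.tsv"))
  jsonlite::write_json(
    list(gene_id = ds$truth$gene_id, shift_dir = ds$truth$shift_dir,
         coupled = ds$truth$coupled,
         coupling_offsets = ds$truth$coupling_offsets),
    file.path(out_dir, "truth.json"), auto_unbox = FALSE)
  message("synthetic bundle written to ", out_dir)
  invisible(structure(out_dir, dataset = ds))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest, expression metrics, motif catalog, chromosome
#' landscape, TSC-relative association sweep (run separately for adenine
#' and cytosine calls). Each stage writes a TSV under `out_dir`; a JSON
#' manifest with the configuration echo, record counts and input checksums
#' closes the run.
#'
#' @param config A [pipeline_config()].
#' @param dry_run Validate inputs and print the plan without writing.
#' @param stages Stages to execute after ingest; any subset of
#'   `"expression"`, `"motifs"`, `"landscape"`, `"associate"` (the
#'   association sweep needs no other stage to have run).
#' @return Invisibly, a list with every executed stage's in-memory result
#'   and the manifest.
#' @export
run_pipeline <- function(config, dry_run = FALSE,
                         stages = c("expression", "motifs", "landscape",
                                    "associate")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (dry_run) {
    message("plan: ingest -> ", paste(stages, collapse = " -> "))
    for (nm in names(config$paths))
      message(sprintf("  input %-10s %s", nm, config$paths[[nm]]))
    message("  output dir ", config$out_dir)
    return(invisible(NULL))
  }
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) > 0 && !config$overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  on.exit(if (!file.exists(file.path(out, "manifest.json")))
    writeLines("pipeline did not complete", failed_marker))

  # ingest
  genomes <- read_genome_fasta(config$paths$genome)
  genome <- genomes[[1L]]
  genes <- read_annotation_gff(config$paths$annotation)
  mods_a <- read_modifications_gff(config$paths$mods_a, min_score = 0,
                                   genome = genome)
  mods_b <- read_modifications_gff(config$paths$mods_b, min_score = 0,
                                   genome = genome)
  counts_a <- read_counts_tsv(config$paths$counts_a)
  counts_b <- read_counts_tsv(config$paths$counts_b)
  islands <- if (!is.null(config$islands)) read_islands_bed(config$islands)

  prof_a <- prof_b <- shifts <- NULL
  if ("expression" %in% stages) {
    prof_a <- expression_profile(counts_a, genes, k = config$k,
                                 metric = config$metric)
    prof_b <- expression_profile(counts_b, genes, k = config$k,
                                 metric = config$metric)
    shifts <- category_shifts(prof_a, prof_b)
    write_table(prof_a, file.path(out, "expression_A.tsv"))
    write_table(prof_b, file.path(out, "expression_B.tsv"))
    write_table(shifts, file.path(out, "category_shifts.tsv"))
  }

  pooled <- rbind(mods_a, mods_b)
  sites <- cls <- status <- NULL
  if ("motifs" %in% stages) {
    sites <- lapply(config$motifs, function(m) scan_motif(genome, m))
    names(sites) <- vapply(config$motifs, `[[`, "", "name")
    all_sites <- do.call(rbind, lapply(sites, `[[`, "sites"))
    write_table(all_sites, file.path(out, "motif_sites.tsv"))
    cls <- classify_modifications(pooled, sites)
    status <- lapply(sites, motif_status, mods = pooled,
                     score_cutoff = config$score_min)
    status_tab <- do.call(rbind, lapply(names(status), function(nm)
      cbind(motif = nm, status[[nm]]$status)))
    write_table(status_tab, file.path(out, "motif_status.tsv"))
  }

  prof <- corr_gc <- corr_skew <- bias <- NULL
  if ("landscape" %in% stages) {
    # score-filtered calls, both conditions pooled
    strong <- pooled[pooled$nucmod_score >= config$score_min, , drop = FALSE]
    prof <- window_profile(genome, strong)
    write_table(prof, file.path(out, "window_profile.tsv"))
    corr_gc <- spearman_bootstrap(prof$mod_count, prof$gc_content,
                                  seed = config$seed)
    corr_skew <- spearman_bootstrap(prof$mod_count, prof$gc_skew,
                                    seed = config$seed + 1L)
    regions <- build_region_sets(genes, genome, islands)
    bias <- region_bias(strong, regions, genome)
    write_table(bias, file.path(out, "region_bias.tsv"))
  }

  sweeps <- NULL
  if ("associate" %in% stages) {
    # adenine and cytosine calls analysed separately, never averaged
    sweeps <- lapply(c(A = "A", C = "C"), function(base) {
      sa <- mods_a[mods_a$base == base, , drop = FALSE]
      sb <- mods_b[mods_b$base == base, , drop = FALSE]
      association_sweep(genes, sa, sb, counts_a, counts_b,
                        config = config$sweep, genome = genome,
                        metric = config$metric)
    })
    for (base in names(sweeps)) {
      write_table(sweeps[[base]]$profile,
                  file.path(out, sprintf("sweep_profile_%s.tsv", base)))
      write_table(sweeps[[base]]$runs,
                  file.path(out, sprintf("sweep_runs_%s.tsv", base)))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("methylink")),
    stages = stages,
    inputs = lapply(config$paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    seed = config$seed,
    k = config$k, metric = config$metric, score_min = config$score_min,
    sweep = unclass(config$sweep),
    counts = list(genes = nrow(genes), mods_a = nrow(mods_a),
                  mods_b = nrow(mods_b),
                  canonical = if (!is.null(cls)) nrow(cls$canonical),
                  noncanonical = if (!is.null(cls)) nrow(cls$noncanonical)))
  if (!is.null(corr_gc))
    manifest$landscape <- list(
      spearman_gc = unclass(corr_gc)[c("rho", "ci_low", "ci_high",
                                       "significant")],
      spearman_skew = unclass(corr_skew)[c("rho", "ci_low", "ci_high",
                                           "significant")])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("pipeline complete: ", out)
  invisible(list(genome = genome, genes = genes,
                 profiles = list(A = prof_a, B = prof_b), shifts = shifts,
                 sites = sites, classified = cls, motif_status = status,
                 window_profile = prof,
                 correlations = list(gc = corr_gc, skew = corr_skew),
                 region_bias = bias, sweeps = sweeps, manifest = manifest))
}
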