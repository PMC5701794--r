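#' Pipeline stage runners
#'
#' Thin, file-oriented wrappers tying the package's stages into the
#' standard workflow `simulate -> annotate -> build -> compare`.  Each
#' stage reads/writes standard formats (FASTA, TSV, YAML, Newick) and
#' leaves a JSON run manifest (config hash, seed, package version) so
#' reruns are auditable; all randomness flows from one top-level seed via
#' named substreams, making the whole pipeline deterministic.
#'
#' @name pipeline
NULL

write_manifest <- function(dir, stage, params) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("tcrarep")),
    params_hash = fnv1a32(paste(utils::capture.output(utils::str(params)),
                                collapse = "\n")),
    params = params
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a cohort to disk
#'
#' @param config A `simulation_config` (or a YAML file holding its
#'   arguments).
#' @param out_dir Output directory.
#' @return Invisibly, the `tcra_cohort_sim`.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(simulation_config, args)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config, emit_reads = TRUE, dir = out_dir)
  write_manifest(out_dir, "simulate",
                 list(seed = config$seed, depth = config$depth,
                      richness = config$richness,
                      error_rate = config$error_rate))
  invisible(sim)
}

#' Annotate per-sample read files against a germline reference
#'
#' @param sample_files Named character vector: sample id -> FASTA/FASTQ
#'   path.
#' @param reference_fasta,reference_metadata Germline reference paths.
#' @param out_dir Output directory for per-sample rearrangement TSVs and
#'   the per-stage filtering ledger.
#' @param correct,min_count,key_scheme Stage options (germline correction,
#'   singleton-filter threshold and clonotype key used for it).
#' @return Invisibly, a tibble of per-sample filtering statistics (reads
#'   in, unassignable, non-productive, singletons removed, clonotypes
#'   out).
#' @export
run_annotate <- function(sample_files, reference_fasta, reference_metadata,
                         out_dir, correct = TRUE, min_count = 2L,
                         key_scheme = "full_tcra") {
  if (!file.exists(reference_fasta) || !file.exists(reference_metadata)) {
    abort("reference files not found")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- load_reference(reference_fasta, reference_metadata)
  groups <- collapse_indistinguishable(reference)
  stats_rows <- list()
  for (sid in names(sample_files)) {
    reads <- read_reads(sample_files[[sid]], sid)
    ann <- annotate_reads(reads, groups = groups, correct = correct)
    productive <- ann[ann$productive, , drop = FALSE]
    kept <- filter_singletons(productive, key_scheme, min_count)
    write_rearrangements(kept, file.path(out_dir,
                                         paste0(sid, ".rearrangements.tsv")))
    stats_rows[[sid]] <- tibble(
      sample_id = sid,
      reads_in = nrow(reads),
      unassignable = sum(!is.na(ann$flag) &
                           ann$flag %in% c("unassignable_v",
                                           "unassignable_j")),
      non_productive = sum(!ann$productive),
      singletons_removed = nrow(productive) - nrow(kept),
      reads_out = nrow(kept),
      clonotypes_out = length(unique(clonotype_key(kept, key_scheme)))
    )
  }
  stats <- bind_rows(stats_rows)
  utils::write.table(stats, file.path(out_dir, "annotation_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "annotate",
                 list(samples = names(sample_files), correct = correct,
                      min_count = min_count, key_scheme = key_scheme))
  invisible(stats)
}

#' Build repertoires from rearrangement tables
#'
#' @param rearrangement_files Named vector sample id -> rearrangement TSV.
#' @param design_yaml Cohort design YAML (sample -> metadata map).
#' @param out_dir Output directory for repertoire TSVs.
#' @param key_scheme Clonotype definition.
#' @return Invisibly, the named list of repertoires.
#' @export
run_build <- function(rearrangement_files, design_yaml, out_dir,
                      key_scheme = "full_tcra") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- yaml::read_yaml(design_yaml)$samples
  reps <- lapply(names(rearrangement_files), function(sid) {
    ann <- read_rearrangements(rearrangement_files[[sid]])
    meta <- design[[sid]]
    rep <- build_repertoire(ann, key_scheme,
                            metadata = meta[setdiff(names(meta),
                                                    "sample_id")],
                            sample_id = sid)
    write_repertoire(rep, file.path(out_dir, paste0(sid, ".repertoire.tsv")))
    rep
  })
  names(reps) <- names(rearrangement_files)
  write_manifest(out_dir, "build", list(samples = names(reps),
                                        key_scheme = key_scheme))
  invisible(reps)
}

#' Cohort comparison stage
#'
#' Computes overlap matrices (Jaccard and Chao-Jaccard), genotype-class
#' summaries, segment-usage tables, log2-usage distance matrices with
#' hierarchical leaf orderings (Newick trees), accumulation curves and
#' Chao1 richness, writing everything as TSV/Newick.
#'
#' @param repertoire_files Named vector sample id -> repertoire TSV.
#' @param out_dir Output directory.
#' @param seed Seed for the accumulation-curve subsampling.
#' @param permutations Accumulation permutations per depth.
#' @param pseudocount Pseudocount for the log2-usage transform.
#' @param min_unique Distinct-CDR3a filter for the per-V/J-pair N-region
#'   comparison.
#' @return Invisibly, a list with the computed objects.
#' @export
run_compare <- function(repertoire_files, out_dir, seed,
                        permutations = 100L, pseudocount = 1,
                        min_unique = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reps <- lapply(repertoire_files, read_repertoire)
  names(reps) <- names(repertoire_files)
  design <- cohort_design(reps)

  out <- list()
  for (metric in c("jaccard", "chao_jaccard")) {
    m <- pairwise_matrix(design, metric)
    utils::write.table(m, file.path(out_dir, paste0(metric, "_matrix.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    out[[paste0(metric, "_matrix")]] <- m
    out[[paste0(metric, "_summary")]] <- summarize_by_class(m, design)
  }
  summaries <- bind_rows(
    mutate(out$jaccard_summary, metric = "jaccard", .before = 1),
    mutate(out$chao_jaccard_summary, metric = "chao_jaccard", .before = 1)
  )
  utils::write.table(summaries, file.path(out_dir, "group_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  for (axis in c("TRAV_group", "TRAJ")) {
    usage <- lapply(reps, function(r) usage_table(r, axis))
    utab <- bind_rows(lapply(names(usage), function(sid) {
      mutate(usage[[sid]], sample_id = sid, .before = 1)
    }))
    utils::write.table(utab, file.path(out_dir, paste0("usage_", axis,
                                                       ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d <- usage_distance_matrix(reps, axis, pseudocount = pseudocount)
    ho <- hierarchical_order(d)
    utils::write.table(d[ho$order, ho$order],
                       file.path(out_dir, paste0("distance_", axis, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    writeLines(ho$newick, file.path(out_dir, paste0("tree_", axis, ".nwk")))
    out[[paste0("order_", axis)]] <- ho
  }

  acc <- bind_rows(lapply(names(reps), function(sid) {
    curve <- accumulation_curve(reps[[sid]], permutations = permutations,
                                seed = derive_seed(seed,
                                                   paste0("accum:", sid)))
    mutate(as_tibble(curve), sample_id = sid, .before = 1)
  }))
  utils::write.table(acc, file.path(out_dir, "accumulation_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  richness <- tibble(
    sample_id = names(reps),
    observed = vapply(reps, function(r) nrow(r$clonotypes), numeric(1)),
    chao1 = vapply(reps, estimate_richness, numeric(1))
  )
  utils::write.table(richness, file.path(out_dir, "richness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nreg <- nregion_comparison(design, min_unique = min_unique)
  utils::write.table(nreg, file.path(out_dir, "nregion_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shared <- shared_sequence_report(design)
  utils::write.table(shared, file.path(out_dir, "shared_sequences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$summaries <- summaries
  out$richness <- richness
  out$nregion <- nreg
  out$shared <- shared
  write_manifest(out_dir, "compare",
                 list(samples = names(reps), seed = seed,
                      permutations = permutations,
                      pseudocount = pseudocount, min_unique = min_unique))
  invisible(out)
}

#' Run the full pipeline: simulate, annotate, build, compare
#'
#' Deterministic end to end: two runs with the same config produce
#' byte-identical outputs.
#'
#' @param config A `simulation_config`.
#' @param out_dir Root output directory (stage subdirectories are created
#'   inside).
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  sim_dir <- file.path(out_dir, "simulate")
  ann_dir <- file.path(out_dir, "annotate")
  rep_dir <- file.path(out_dir, "build")
  cmp_dir <- file.path(out_dir, "compare")
  sim <- run_simulate(config, sim_dir)

  sids <- sim$design$sample_id
  sample_files <- stats::setNames(
    file.path(sim_dir, paste0(sids, ".fasta")), sids
  )
  stats <- run_annotate(sample_files,
                        file.path(sim_dir, "reference.fasta"),
                        file.path(sim_dir, "reference.tsv"),
                        ann_dir)
  rear_files <- stats::setNames(
    file.path(ann_dir, paste0(sids, ".rearrangements.tsv")), sids
  )
  reps <- run_build(rear_files, file.path(sim_dir, "design.yaml"), rep_dir)
  rep_files <- stats::setNames(
    file.path(rep_dir, paste0(sids, ".repertoire.tsv")), sids
  )
  cmp <- run_compare(rep_files, cmp_dir,
                     seed = derive_seed(config$seed, "compare"))
  invisible(list(sim = sim, annotate_stats = stats, repertoires = reps,
                 compare = cmp))
}
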