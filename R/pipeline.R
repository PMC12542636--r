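#' End-to-end pipeline stages with fixed artifact contracts
#'
#' Four stage functions tie the package into a reproducible pipeline with
#' stable artifact filenames: `run_simulate()` writes a self-contained
#' fixture directory (`annotations.tsv`, `metadata.tsv`, `truth.json`,
#' `manifest.json`); `run_call()` writes `trait_matrix.tsv`,
#' `evidence.json` and `run.log`; `run_summarize()` writes
#' `subgroup_summary.tsv`, `cooccurrence.tsv`, `ordering.json` and
#' optionally `heatmap.png`; `run_evaluate()` writes `recovery.tsv` and
#' `recovery.json`. Each stage stops with a stage-named error on bad
#' input; the thin command-line wrapper in `inst/scripts/mag-traits` maps
#' those to nonzero exits. TSV artifacts never carry comment lines.
#'
#' @name pipeline
NULL

ensure_outdir <- function(out_dir, stage) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    abort_input("[%s] output directory not writable: %s", stage, out_dir)
  invisible(out_dir)
}

stage_log <- function(lines, path = NULL) {
  for (l in lines) message(l)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname pipeline
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @param rb Rulebook whose traits are planted.
#' @param allow_overlap Passed to [generate_profiles()].
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(out_dir, config = simulation_config(),
                         rb = builtin_rulebook(), allow_overlap = FALSE) {
  ensure_outdir(out_dir, "simulate")
  profiles <- generate_profiles(rb, config$n_subgroups,
                                config$traits_per_subgroup,
                                seed = config$seed,
                                allow_overlap = allow_overlap)
  sim <- simulate_genomes(profiles, config, rb = rb)
  write_tsv(sim$annotations$records, file.path(out_dir, "annotations.tsv"))
  meta <- sim$genomes
  meta$quality_tier <- NULL
  write_tsv(meta, file.path(out_dir, "metadata.tsv"))
  write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
  jsonlite::write_json(
    list(stage = "simulate", rulebook_version = rb$version,
         parameters = unclass(config)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname pipeline
#' @param annotations,metadata Paths to the input TSVs.
#' @param rulebook_path Optional rulebook file; `NULL` uses
#'   [builtin_rulebook()].
#' @param min_completeness,max_contamination Quality-filter thresholds.
#' @param include_excluded Call traits for excluded-tier genomes too.
#' @export
run_call <- function(annotations, metadata, out_dir, rulebook_path = NULL,
                     min_completeness = 50, max_contamination = 10,
                     include_excluded = FALSE) {
  if (!is.null(rulebook_path) && !file.exists(rulebook_path))
    abort_input("[call] rulebook file not found: %s", rulebook_path)
  if (!file.exists(annotations))
    abort_input("[call] annotations file not found: %s", annotations)
  if (!file.exists(metadata))
    abort_input("[call] metadata file not found: %s", metadata)
  ensure_outdir(out_dir, "call")
  rb <- if (is.null(rulebook_path)) builtin_rulebook() else load_rulebook(rulebook_path)
  ann <- read_annotations(annotations)
  gs <- read_genome_metadata(metadata)
  gs <- filter_quality(gs, min_completeness = min_completeness,
                       max_contamination = max_contamination)
  tm <- call_traits(gs, ann, rb, include_excluded = include_excluded)
  write_trait_matrix(tm, file.path(out_dir, "trait_matrix.tsv"))
  write_evidence_json(tm, file.path(out_dir, "evidence.json"))
  tiers <- table(factor(gs$quality_tier, levels = c("high", "medium", "excluded")))
  stage_log(c(
    sprintf("[call] rulebook version: %s", rb$version),
    sprintf("[call] thresholds: completeness >= %s, contamination < %s",
            min_completeness, max_contamination),
    sprintf("[call] genomes: %d high, %d medium, %d excluded",
            tiers[["high"]], tiers[["medium"]], tiers[["excluded"]]),
    sprintf("[call] matrix: %d genomes x %d traits",
            length(tm$genome_ids), length(tm$trait_ids))
  ), file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @rdname pipeline
#' @param matrix Path to a `trait_matrix.tsv`.
#' @param distance,linkage Passed to [cluster_profiles()].
#' @param heatmap Also render `heatmap.png` (needs \pkg{pheatmap}).
#' @export
run_summarize <- function(matrix, metadata, out_dir,
                          distance = "euclidean", linkage = "complete",
                          heatmap = FALSE) {
  if (!file.exists(matrix))
    abort_input("[summarize] trait matrix not found: %s", matrix)
  ensure_outdir(out_dir, "summarize")
  tm <- read_trait_matrix(matrix)
  gs <- read_genome_metadata(metadata)
  if (!length(tm$genome_ids))
    abort_input("[summarize] empty trait matrix: %s", matrix)
  unknown <- setdiff(tm$genome_ids, gs$genome_id)
  if (length(unknown))
    abort_input("[summarize] matrix genome(s) missing from metadata: %s",
                paste(utils::head(unknown, 3), collapse = ", "))
  summ <- summarize_subgroups(tm, gs, default_unassigned = TRUE)
  write_tsv(summ, file.path(out_dir, "subgroup_summary.tsv"))
  write_tsv(cooccurrence_all(tm), file.path(out_dir, "cooccurrence.tsv"))
  ord_traits <- cluster_profiles(tm, "traits", distance, linkage)
  ord_genomes <- cluster_profiles(tm, "genomes", distance, linkage)
  jsonlite::write_json(
    lapply(list(traits = ord_traits, genomes = ord_genomes), function(o)
      list(axis = o$axis, labels = o$labels, order = o$order,
           merges = o$merges, heights = o$heights,
           distance = o$distance, linkage = o$linkage)),
    file.path(out_dir, "ordering.json"), auto_unbox = TRUE, digits = NA)
  if (heatmap)
    plot_trait_heatmap(tm, gs, file = file.path(out_dir, "heatmap.png"),
                       distance = distance, linkage = linkage)
  invisible(out_dir)
}

#' @rdname pipeline
#' @param truth Path to a `truth.json`.
#' @export
run_evaluate <- function(matrix, truth, out_dir) {
  if (!file.exists(matrix))
    abort_input("[evaluate] trait matrix not found: %s", matrix)
  if (!file.exists(truth))
    abort_input("[evaluate] truth file not found: %s", truth)
  ensure_outdir(out_dir, "evaluate")
  tm <- read_trait_matrix(matrix)
  tr <- read_truth_json(truth)
  rec <- score_recovery(tm, tr)
  write_tsv(rec$per_trait, file.path(out_dir, "recovery.tsv"))
  jsonlite::write_json(
    list(overall_accuracy = rec$overall_accuracy, n_genomes = rec$n_genomes,
         per_trait = rec$per_trait),
    file.path(out_dir, "recovery.json"), auto_unbox = TRUE, digits = NA)
  stage_log(sprintf("[evaluate] %d genomes, overall accuracy %.4f",
                    rec$n_genomes, rec$overall_accuracy))
  invisible(rec)
}
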