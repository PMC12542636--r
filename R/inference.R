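#' Trait inference: evaluating the rulebook against genome annotations
#'
#' The evaluator matches each diagnostic gene against a genome's annotation
#' records by KO identifier (case-insensitive) or gene symbol
#' (case-insensitive), requiring at least `min_copies` copies. Complexes
#' pass when strictly more than `min_fraction` of their core subunits match
#' (equality only when `min_fraction = 1`). Every call carries an evidence
#' tree recording the outcome at each requirement node.
#'
#' @name inference
NULL

# Build a copies-by-identity lookup for one genome. Each record contributes
# its copy number under both its KO key (uppercased) and symbol key
# (lowercased); copies from distinct records sharing a key accumulate.
gene_index <- function(records) {
  keys <- c(ifelse(nzchar(records$ko_id), toupper(records$ko_id), NA),
            ifelse(nzchar(records$symbol), tolower(records$symbol), NA))
  copies <- rep(records$copy_number, 2L)
  keep <- !is.na(keys)
  if (!any(keep)) return(numeric(0))
  tapply(copies[keep], keys[keep], sum)
}

# Accept a bare character vector of gene identities (symbols and/or KO ids)
# anywhere an index is expected; handy for interactive use and tests.
as_gene_index <- function(genes) {
  if (is.numeric(genes) && (length(genes) == 0L || !is.null(names(genes))))
    return(genes)
  if (is.character(genes)) {
    if (!length(genes)) return(numeric(0))
    keys <- ifelse(is_ko_id(genes), toupper(genes), tolower(genes))
    return(tapply(rep(1, length(keys)), keys, sum))
  }
  abort_input("genome genes must be a character vector or a named copy-count vector")
}

gene_copies <- function(idx, gene, ko_only = FALSE) {
  keys <- toupper(gene$ko_ids)
  if (!ko_only && nzchar(gene$symbol)) keys <- c(keys, tolower(gene$symbol))
  if (!length(keys) || !length(idx)) return(0)
  hits <- idx[keys]
  max(c(hits[!is.na(hits)], 0))
}

gene_matched <- function(idx, gene, ko_only = FALSE) {
  gene_copies(idx, gene, ko_only) >= gene$min_copies
}

#' Evaluate a multi-subunit complex against a genome
#'
#' @param spec A [complex_spec()].
#' @param genome_genes Character vector of gene identities (symbols/KO ids)
#'   present in the genome, or a named copy-count vector.
#' @param ko_only Match on KO identifiers only.
#' @return A `mag_complex_evidence` list with fields `complex_name`,
#'   `subunits_found`, `fraction`, `satisfied`.
#' @export
#' @examples
#' eval_complex(complex_spec("narGHI", c("narG", "narH", "narI")),
#'              c("narG", "narH"))$satisfied  # 2/3 > 1/2
eval_complex <- function(spec, genome_genes, ko_only = FALSE) {
  idx <- as_gene_index(genome_genes)
  found <- vapply(spec$subunits, gene_matched, logical(1),
                  idx = idx, ko_only = ko_only)
  fraction <- sum(found) / length(spec$subunits)
  satisfied <- if (spec$min_fraction >= 1) fraction == 1 else fraction > spec$min_fraction
  structure(
    list(complex_name = spec$name,
         subunits_found = vapply(spec$subunits[found], function(s) s$symbol,
                                 character(1)),
         fraction = fraction,
         satisfied = satisfied),
    class = "mag_complex_evidence"
  )
}

eval_node <- function(node, idx, ko_only) {
  switch(node$kind,
    gene = {
      ok <- gene_matched(idx, node$gene, ko_only)
      list(kind = "gene", symbol = node$gene$symbol, satisfied = ok)
    },
    complex = {
      ev <- eval_complex(node$complex, idx, ko_only)
      list(kind = "complex", complex_name = ev$complex_name,
           fraction = ev$fraction, subunits_found = ev$subunits_found,
           satisfied = ev$satisfied)
    },
    all_of = {
      kids <- lapply(node$children, eval_node, idx = idx, ko_only = ko_only)
      list(kind = "all_of", children = kids,
           satisfied = all(vapply(kids, `[[`, logical(1), "satisfied")))
    },
    any_of = {
      kids <- lapply(node$children, eval_node, idx = idx, ko_only = ko_only)
      list(kind = "any_of", children = kids,
           satisfied = any(vapply(kids, `[[`, logical(1), "satisfied")))
    }
  )
}

#' Evaluate one trait rule against a genome
#'
#' @param rule A [trait_rule()].
#' @param genome_genes Gene identities present (character vector or named
#'   copy-count vector).
#' @param genome_id Optional genome label stored in the call.
#' @return A `mag_call` list: `genome_id`, `trait_id`, `present`, `evidence`.
#' @export
#' @examples
#' rb <- builtin_rulebook()
#' eval_rule(rb$rules$asr, c("sat", "cysC", "cysH"))$present  # TRUE
eval_rule <- function(rule, genome_genes, genome_id = NA_character_) {
  idx <- as_gene_index(genome_genes)
  ev <- eval_node(rule$requirement, idx, rule$ko_only)
  structure(
    list(genome_id = genome_id, trait_id = rule$trait_id,
         present = ev$satisfied, evidence = ev),
    class = "mag_call"
  )
}

#' Recompute a call's presence from its stored evidence tree
#'
#' Used to assert evidence consistency: the boolean must reproduce the
#' stored `present`.
#'
#' @param evidence The `evidence` element of a `mag_call`.
#' @return Logical.
#' @export
evidence_present <- function(evidence) {
  switch(evidence$kind,
    gene = isTRUE(evidence$satisfied),
    complex = isTRUE(evidence$satisfied),
    all_of = all(vapply(evidence$children, evidence_present, logical(1))),
    any_of = any(vapply(evidence$children, evidence_present, logical(1)))
  )
}

#' Call traits for every genome: the binary trait matrix
#'
#' Evaluates each rulebook rule against each non-excluded genome, producing
#' a binary genomes-by-traits matrix together with per-call evidence. A
#' genome with no annotation records yields an all-absent row (its record
#' count is retained so "no data" can be distinguished from true absence
#' downstream). Row and column order follow the input order; the result is
#' deterministic.
#'
#' @param gs A `mag_genomes` table with quality tiers assigned
#'   ([filter_quality()]).
#' @param ann A `mag_annotations` object.
#' @param rb A `mag_rulebook`.
#' @param include_excluded Also call traits for `excluded`-tier genomes.
#' @return A `mag_trait_matrix`: `genome_ids`, `trait_ids`, `values`
#'   (0/1 integer matrix), `calls` (nested list by genome then trait), and
#'   `annotation_counts`.
#' @export
call_traits <- function(gs, ann, rb, include_excluded = FALSE) {
  if (anyNA(gs$quality_tier))
    abort_input("genome set has unassigned quality tiers; run filter_quality() first")
  genomes <- if (include_excluded) gs$genome_id else
    gs$genome_id[gs$quality_tier != "excluded"]
  if (!length(intersect(ann$genome_ids, gs$genome_id)))
    abort_input("annotation genome ids are disjoint from the genome set: nothing to call")
  ids <- trait_ids(rb)
  split_rec <- split(ann$records, factor(ann$records$genome_id, levels = genomes))
  values <- matrix(0L, nrow = length(genomes), ncol = length(ids),
                   dimnames = list(genomes, ids))
  calls <- vector("list", length(genomes))
  names(calls) <- genomes
  counts <- integer(length(genomes))
  names(counts) <- genomes
  for (gid in genomes) {
    recs <- split_rec[[gid]]
    counts[[gid]] <- if (is.null(recs)) 0L else nrow(recs)
    idx <- if (is.null(recs) || !nrow(recs)) numeric(0) else gene_index(recs)
    gcalls <- lapply(rb$rules, eval_rule, genome_genes = idx, genome_id = gid)
    calls[[gid]] <- gcalls
    values[gid, ] <- vapply(gcalls, function(cl) as.integer(cl$present), integer(1))
  }
  structure(
    list(genome_ids = genomes, trait_ids = ids, values = values,
         calls = calls, annotation_counts = counts,
         rulebook_version = rb$version),
    class = "mag_trait_matrix"
  )
}

#' @export
print.mag_trait_matrix <- function(x, ...) {
  cat(sprintf("<mag_trait_matrix: %d genomes x %d traits, %d presences>\n",
              length(x$genome_ids), length(x$trait_ids), sum(x$values)))
  invisible(x)
}

#' Write / read a trait matrix as TSV
#'
#' The TSV has one `genome_id` column followed by one 0/1 column per trait.
#' Evidence is not round-tripped; use [write_evidence_json()] for that.
#'
#' @param tm A `mag_trait_matrix`.
#' @param path Output/input TSV path.
#' @return `path` invisibly / a `mag_trait_matrix` without evidence.
#' @export
write_trait_matrix <- function(tm, path) {
  df <- data.frame(genome_id = tm$genome_ids, tm$values,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- read_tsv(path)
  if (!"genome_id" %in% names(df) || ncol(df) < 2L)
    abort_format("'%s' is not a trait matrix TSV", path)
  vals <- as.matrix(df[-1])
  if (!all(vals %in% c(0L, 1L)))
    abort_format("'%s': trait matrix cells must be 0/1", path)
  storage.mode(vals) <- "integer"
  rownames(vals) <- df$genome_id
  structure(
    list(genome_ids = as.character(df$genome_id),
         trait_ids = colnames(vals), values = vals,
         calls = NULL, annotation_counts = NULL, rulebook_version = NA_character_),
    class = "mag_trait_matrix"
  )
}

#' Write the per-call evidence trees as JSON
#'
#' JSON object keyed by genome id, then trait id; each leaf records node
#' outcomes including complex subunit fractions.
#'
#' @param tm A `mag_trait_matrix` produced by [call_traits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_json <- function(tm, path) {
  if (is.null(tm$calls))
    abort_input("trait matrix carries no evidence (was it read from TSV?)")
  doc <- lapply(tm$calls, function(gcalls)
    lapply(gcalls, function(cl)
      list(present = cl$present, evidence = cl$evidence)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
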