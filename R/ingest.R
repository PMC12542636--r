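#' Read a per-genome gene annotation table
#'
#' Expects a UTF-8 TSV with header columns `genome_id`, `gene_id`, `ko_id`,
#' `symbol` and optionally `copy_number` (default 1), as typically exported
#' from KO/eggNOG-style annotators. Gzip-compressed files are read
#' transparently. Rows whose KO id and symbol are both blank are dropped
#' with a warning. Duplicate rows for the same gene identity within a
#' genome (KO id when present, else case-insensitive symbol) are merged by
#' summing copy numbers.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return A `mag_annotations` object wrapping the merged records.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path)
  required <- c("genome_id", "gene_id", "ko_id", "symbol")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_format("annotation table '%s' lacks mandatory column(s): %s",
                 path, paste(missing, collapse = ", "))
  if (!"copy_number" %in% names(df)) df$copy_number <- 1L
  df$ko_id <- ifelse(is.na(df$ko_id), "", as.character(df$ko_id))
  df$symbol <- ifelse(is.na(df$symbol), "", as.character(df$symbol))
  df$genome_id <- as.character(df$genome_id)
  df$gene_id <- as.character(df$gene_id)
  cn <- suppressWarnings(as.numeric(df$copy_number))
  if (anyNA(cn) || any(cn != as.integer(cn)) || any(cn < 1))
    abort_format("annotation table '%s': copy_number must be a positive integer", path)
  df$copy_number <- as.integer(cn)
  annotation_table(df[c(required, "copy_number")], source = path)
}

# Internal constructor shared with the simulator; merges duplicates and
# applies the blank-identity rejection rule.
annotation_table <- function(df, source = "<in-memory>") {
  blank <- !nzchar(df$ko_id) & !nzchar(df$symbol)
  if (any(blank)) {
    warning(sprintf("%d annotation row(s) with blank KO id and symbol dropped (%s)",
                    sum(blank), source), call. = FALSE)
    df <- df[!blank, , drop = FALSE]
  }
  key <- ifelse(nzchar(df$ko_id), toupper(df$ko_id), tolower(df$symbol))
  mkey <- paste(df$genome_id, key, sep = "\r")
  if (anyDuplicated(mkey)) {
    first <- !duplicated(mkey)
    copies <- tapply(df$copy_number, mkey, sum)
    out <- df[first, , drop = FALSE]
    out$copy_number <- as.integer(copies[paste(out$genome_id,
      ifelse(nzchar(out$ko_id), toupper(out$ko_id), tolower(out$symbol)),
      sep = "\r")])
    df <- out
  }
  rownames(df) <- NULL
  structure(list(records = df, genome_ids = unique(df$genome_id)),
            class = "mag_annotations")
}

#' @export
print.mag_annotations <- function(x, ...) {
  cat(sprintf("<mag_annotations: %d records, %d genomes>\n",
              nrow(x$records), length(x$genome_ids)))
  invisible(x)
}

#' Read genome quality/subgroup metadata
#'
#' Expects TSV columns `genome_id`, `completeness`, `contamination`
#' (CheckM-style percentages) and optionally `subgroup` and `habitat`.
#' Quality tiers are left unassigned; call [filter_quality()] next.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return A `mag_genomes` data frame.
#' @export
read_genome_metadata <- function(path) {
  df <- read_tsv(path)
  required <- c("genome_id", "completeness", "contamination")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_format("genome metadata '%s' lacks mandatory column(s): %s",
                 path, paste(missing, collapse = ", "))
  df$genome_id <- as.character(df$genome_id)
  if (anyDuplicated(df$genome_id))
    abort_format("genome metadata '%s': duplicate genome_id values", path)
  df$completeness <- as.numeric(df$completeness)
  df$contamination <- as.numeric(df$contamination)
  if (anyNA(df$completeness) || any(df$completeness < 0 | df$completeness > 100))
    abort_format("genome metadata '%s': completeness must lie in [0, 100]", path)
  if (anyNA(df$contamination) || any(df$contamination < 0))
    abort_format("genome metadata '%s': contamination must be >= 0", path)
  if (!"subgroup" %in% names(df)) df$subgroup <- NA_character_
  if (!"habitat" %in% names(df)) df$habitat <- NA_character_
  df$subgroup <- as.character(df$subgroup)
  df$habitat <- as.character(df$habitat)
  df$quality_tier <- NA_character_
  out <- df[c("genome_id", "completeness", "contamination",
              "subgroup", "habitat", "quality_tier")]
  class(out) <- c("mag_genomes", "data.frame")
  out
}

#' Assign MAG quality tiers
#'
#' Tiers follow the usual CheckM conventions: a genome is `excluded` when
#' completeness < `min_completeness` or contamination >= `max_contamination`
#' (both bounds strict in the retained direction: completeness of exactly
#' 50 is kept, contamination of exactly 10 is not); `high` when
#' completeness > `high_completeness` and contamination <
#' `high_contamination`; otherwise `medium`. Tiering annotates, it does not
#' delete, unless `drop = TRUE`.
#'
#' @param gs A `mag_genomes` table from [read_genome_metadata()].
#' @param min_completeness,max_contamination Retention bounds (default 50, 10).
#' @param high_completeness,high_contamination High-quality bounds (default 90, 5).
#' @param drop If `TRUE`, rows tiered `excluded` are removed.
#' @return `gs` with `quality_tier` filled in.
#' @export
#' @examples
#' gs <- data.frame(genome_id = "m1", completeness = 95, contamination = 2,
#'                  subgroup = NA, habitat = NA, quality_tier = NA)
#' class(gs) <- c("mag_genomes", "data.frame")
#' filter_quality(gs)$quality_tier  # "high"
filter_quality <- function(gs, min_completeness = 50, max_contamination = 10,
                           high_completeness = 90, high_contamination = 5,
                           drop = FALSE) {
  if (min_completeness <= 0 || max_contamination <= 0)
    abort_input("quality thresholds must be positive")
  if (high_completeness <= min_completeness)
    abort_input("high_completeness must exceed min_completeness")
  tier <- ifelse(gs$completeness < min_completeness |
                   gs$contamination >= max_contamination, "excluded",
          ifelse(gs$completeness > high_completeness &
                   gs$contamination < high_contamination, "high", "medium"))
  gs$quality_tier <- tier
  if (drop) gs <- gs[gs$quality_tier != "excluded", , drop = FALSE]
  rownames(gs) <- NULL
  gs
}
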