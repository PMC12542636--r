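# Independent brute-force evaluator for requirement trees, used as an
# oracle against eval_rule(). It takes a totally different route: the tree
# is expanded into its minimal satisfying symbol sets (a DNF over gene
# symbols), and a genome satisfies the rule iff some minimal set is a
# subset of its genes. Complex nodes expand to all subunit subsets of the
# smallest size clearing the threshold.

min_complex_count <- function(k, f) {
  # smallest m with m/k > f (or m = k when f = 1)
  if (f >= 1) return(k)
  m <- floor(f * k) + 1
  if (m / k <= f) m <- m + 1
  as.integer(m)
}

dnf_sets <- function(node) {
  switch(node$kind,
    gene = list(node$gene$symbol),
    complex = {
      syms <- vapply(node$complex$subunits, function(s) s$symbol, character(1))
      m <- min_complex_count(length(syms), node$complex$min_fraction)
      combn(syms, m, simplify = FALSE)
    },
    any_of = do.call(c, lapply(node$children, dnf_sets)),
    all_of = {
      sets <- list(character(0))
      for (ch in node$children) {
        child_sets <- dnf_sets(ch)
        sets <- do.call(c, lapply(sets, function(a)
          lapply(child_sets, function(b) union(a, b))))
      }
      sets
    }
  )
}

oracle_present <- function(rule, genes) {
  any(vapply(dnf_sets(rule$requirement), function(s) all(s %in% genes),
             logical(1)))
}

# Tiny in-memory table builders shared across test files.
make_annotations <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_annotations(path)
}

make_genomes <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_genome_metadata(path)
}

ann_df <- function(genome_id, symbols, kos = "", copies = 1L) {
  data.frame(genome_id = genome_id,
             gene_id = paste0(genome_id, "_g", seq_along(symbols)),
             ko_id = kos, symbol = symbols, copy_number = copies,
             stringsAsFactors = FALSE)
}

meta_df <- function(ids, completeness = 95, contamination = 1, subgroup = "subgroup 1") {
  data.frame(genome_id = ids, completeness = completeness,
             contamination = contamination, subgroup = subgroup,
             habitat = "hot spring", stringsAsFactors = FALSE)
}
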