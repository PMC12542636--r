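#' Three-state classification of a trait within a subgroup
#'
#' `MAJOR` when the trait is present in at least half of the subgroup's
#' genomes (exactly 50% counts as MAJOR), `MINOR` when present in some but
#' fewer than half, `ABSENT` when missing from all.
#'
#' @param n_present,n_total Presence count and subgroup size (`n_total >= 1`).
#' @return `"MAJOR"`, `"MINOR"` or `"ABSENT"`.
#' @export
trait_state <- function(n_present, n_total) {
  if (n_total < 1 || n_present < 0 || n_present > n_total)
    abort_input("need 0 <= n_present <= n_total with n_total >= 1")
  if (n_present == 0) "ABSENT"
  else if (n_present / n_total >= 0.5) "MAJOR"
  else "MINOR"
}

genome_subgroups <- function(tm, gs, default_unassigned) {
  sg <- gs$subgroup[match(tm$genome_ids, gs$genome_id)]
  missing <- is.na(sg) | !nzchar(sg)
  if (any(missing)) {
    if (!default_unassigned)
      abort_input("genome(s) without subgroup label: %s (set default_unassigned = TRUE to pool them)",
                  paste(utils::head(tm$genome_ids[missing], 3), collapse = ", "))
    sg[missing] <- "unassigned"
  }
  sg
}

#' Subgroup-level three-state trait summary
#'
#' One row per (subgroup, trait) with presence counts and the
#' MAJOR/MINOR/ABSENT state, mirroring the usual metabolic-network figure
#' semantics.
#'
#' @param tm A `mag_trait_matrix`.
#' @param gs A `mag_genomes` table supplying subgroup labels.
#' @param default_unassigned Pool unlabeled genomes into an `"unassigned"`
#'   subgroup instead of erroring.
#' @return Data frame: `subgroup`, `trait_id`, `n_present`, `n_total`, `state`.
#' @export
summarize_subgroups <- function(tm, gs, default_unassigned = FALSE) {
  sg <- genome_subgroups(tm, gs, default_unassigned)
  groups <- unique(sg)
  out <- do.call(rbind, lapply(groups, function(s) {
    rows <- tm$values[sg == s, , drop = FALSE]
    data.frame(subgroup = s, trait_id = tm$trait_ids,
               n_present = as.integer(colSums(rows)),
               n_total = nrow(rows), row.names = NULL)
  }))
  out$state <- mapply(trait_state, out$n_present, out$n_total)
  out
}

#' Per-subgroup presence counts for one trait
#'
#' @param tm A `mag_trait_matrix`.
#' @param gs A `mag_genomes` table supplying subgroup labels.
#' @param trait_id Trait to count.
#' @param default_unassigned See [summarize_subgroups()].
#' @return Named integer vector, subgroup -> number of genomes carrying the
#'   trait; sums to the matrix column sum.
#' @export
count_by_subgroup <- function(tm, gs, trait_id, default_unassigned = FALSE) {
  if (!trait_id %in% tm$trait_ids)
    abort_input("unknown trait_id '%s'", trait_id)
  sg <- genome_subgroups(tm, gs, default_unassigned)
  counts <- tapply(tm$values[, trait_id], sg, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Pairwise co-occurrence and mutual-exclusivity screen
#'
#' Builds the 2x2 contingency table of two trait columns over genomes.
#' Mutual exclusivity is a descriptive flag: no genome carries both traits
#' while each trait is observed in at least one genome (an all-zero column
#' never counts as exclusive). A hypergeometric lower-tail probability of
#' observing at most `n11` joint presences under independence is reported
#' alongside but never gates the flag.
#'
#' @param tm A `mag_trait_matrix`.
#' @param trait_a,trait_b Trait ids.
#' @return A `mag_cooccurrence` list: `trait_a`, `trait_b`, `n11`, `n10`,
#'   `n01`, `n00`, `jaccard`, `mutually_exclusive`, `p_depletion`.
#' @export
cooccurrence <- function(tm, trait_a, trait_b) {
  for (tr in c(trait_a, trait_b))
    if (!tr %in% tm$trait_ids) abort_input("unknown trait_id '%s'", tr)
  a <- tm$values[, trait_a] == 1L
  b <- tm$values[, trait_b] == 1L
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  denom <- n11 + n10 + n01
  structure(
    list(trait_a = trait_a, trait_b = trait_b,
         n11 = n11, n10 = n10, n01 = n01, n00 = n00,
         jaccard = if (denom == 0) 0 else n11 / denom,
         mutually_exclusive = n11 == 0 && n10 > 0 && n01 > 0,
         p_depletion = stats::phyper(n11, sum(a), length(a) - sum(a), sum(b))),
    class = "mag_cooccurrence"
  )
}

#' All-pairs co-occurrence table
#'
#' @param tm A `mag_trait_matrix`.
#' @return Data frame with one row per unordered trait pair.
#' @export
cooccurrence_all <- function(tm) {
  ids <- tm$trait_ids
  pairs <- utils::combn(ids, 2)
  do.call(rbind, apply(pairs, 2, function(p) {
    co <- cooccurrence(tm, p[1], p[2])
    data.frame(trait_a = co$trait_a, trait_b = co$trait_b,
               n11 = co$n11, n10 = co$n10, n01 = co$n01, n00 = co$n00,
               jaccard = co$jaccard,
               mutually_exclusive = co$mutually_exclusive,
               p_depletion = co$p_depletion, row.names = NULL)
  }))
}

#' Hierarchical clustering of presence/absence profiles
#'
#' Agglomerative clustering of genomes or traits on their binary profiles,
#' as used to order heatmap axes. Distances: Euclidean on the 0/1 vectors,
#' or Jaccard (1 minus the ratio of shared to any presences; two all-zero
#' profiles are at distance 0). Linkage: complete (default) or average.
#' Given identical inputs the ordering is deterministic; distance ties are
#' resolved toward lower original indices by the agglomeration order.
#'
#' @param tm A `mag_trait_matrix`.
#' @param axis `"genomes"` (matrix rows) or `"traits"` (columns).
#' @param distance `"euclidean"` or `"jaccard"`.
#' @param linkage `"complete"` or `"average"`.
#' @return A `mag_ordering` list: `axis`, `labels`, `order` (permutation of
#'   1..n), `merges` (hclust-style merge matrix), `heights`.
#' @export
cluster_profiles <- function(tm, axis = c("genomes", "traits"),
                             distance = c("euclidean", "jaccard"),
                             linkage = c("complete", "average")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  mat <- if (axis == "genomes") tm$values else t(tm$values)
  n <- nrow(mat)
  if (n < 1L) abort_input("nothing to cluster on axis '%s'", axis)
  if (n == 1L) {
    return(structure(list(axis = axis, labels = rownames(mat), order = 1L,
                          merges = matrix(integer(0), 0, 2), heights = numeric(0),
                          distance = distance, linkage = linkage),
                     class = "mag_ordering"))
  }
  d <- if (distance == "euclidean") stats::dist(mat) else stats::dist(mat, method = "binary")
  d[is.na(d)] <- 0  # binary distance between two all-zero profiles
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(axis = axis, labels = rownames(mat), order = hc$order,
         merges = hc$merge, heights = hc$height,
         distance = distance, linkage = linkage),
    class = "mag_ordering"
  )
}

#' Render the binary trait heatmap
#'
#' Draws the genomes-by-traits 0/1 matrix with trait rows ordered by
#' clustering and genome columns grouped by subgroup (with a subgroup
#' annotation bar), in the style of a pheatmap presence/absence figure.
#' Requires the optional \pkg{pheatmap} package.
#'
#' @param tm A `mag_trait_matrix`.
#' @param gs A `mag_genomes` table with subgroup labels.
#' @param file Optional PNG path; when `NULL`, draws to the active device.
#' @param distance,linkage Passed to [cluster_profiles()] for the trait axis.
#' @return The pheatmap object, invisibly.
#' @export
plot_trait_heatmap <- function(tm, gs, file = NULL,
                               distance = "euclidean", linkage = "complete") {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    abort_input("plot_trait_heatmap() needs the 'pheatmap' package")
  sg <- genome_subgroups(tm, gs, default_unassigned = TRUE)
  col_order <- order(sg, match(tm$genome_ids, tm$genome_ids))
  row_order <- cluster_profiles(tm, "traits", distance, linkage)$order
  mat <- t(tm$values)[row_order, col_order, drop = FALSE]
  ann <- data.frame(subgroup = sg[col_order], row.names = colnames(mat))
  args <- list(mat = mat, cluster_rows = FALSE, cluster_cols = FALSE,
               annotation_col = ann, legend_breaks = c(0, 1),
               color = c("#27408B", "#CD2626"), show_colnames = FALSE,
               silent = !is.null(file))
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off())
  }
  p <- do.call(pheatmap::pheatmap, args)
  invisible(p)
}
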