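#' Synthetic MAG annotation data with planted trait profiles
#'
#' The generator emulates a MAG collection partitioned into subgroups with
#' distinct metabolic profiles: each subgroup is assigned a set of planted
#' traits; each simulated genome starts from the subgroup's full gene
#' complement, loses each gene independently with probability
#' `1 - completeness/100` (genome incompleteness as uniform gene dropout),
#' and gains foreign genes from other subgroups' complements with a small
#' injection probability (cross-bin contamination). Trait recovery can
#' then be scored against the planted truth.
#'
#' @name synthetic_data
NULL

#' Construct a subgroup trait profile
#'
#' @param subgroup Subgroup label.
#' @param planted_traits Character vector of trait ids from `rb`.
#' @param rb A `mag_rulebook`.
#' @param check_closure Error when the gene complement additionally
#'   satisfies a non-planted rule.
#' @return A `mag_profile`: `subgroup`, `trait_ids`, `gene_complement`
#'   (all diagnostic genes and complex subunits of the planted traits).
#' @export
subgroup_profile <- function(subgroup, planted_traits, rb, check_closure = TRUE) {
  unknown <- setdiff(planted_traits, trait_ids(rb))
  if (length(unknown))
    abort_input("unknown trait id(s): %s", paste(unknown, collapse = ", "))
  complement <- sort(unique(unlist(lapply(rb$rules[planted_traits], rule_genes))))
  satisfied <- satisfied_traits(complement, rb)
  if (!all(planted_traits %in% satisfied))
    abort_input("subgroup '%s': complement fails planted trait(s) %s", subgroup,
                paste(setdiff(planted_traits, satisfied), collapse = ", "))
  if (check_closure) {
    extra <- setdiff(satisfied, planted_traits)
    if (length(extra))
      abort_input("subgroup '%s': complement also satisfies non-planted trait(s) %s",
                  subgroup, paste(extra, collapse = ", "))
  }
  structure(
    list(subgroup = subgroup, trait_ids = sort(unname(planted_traits)),
         gene_complement = complement),
    class = "mag_profile"
  )
}

satisfied_traits <- function(genes, rb) {
  idx <- as_gene_index(genes)
  ids <- trait_ids(rb)
  ids[vapply(rb$rules, function(r) eval_rule(r, idx)$present, logical(1))]
}

#' Draw planted trait profiles for a set of subgroups
#'
#' Samples `traits_per_subgroup` distinct rulebook traits for each
#' subgroup (no trait planted twice across subgroups), requiring each
#' subgroup's gene complement to satisfy exactly its planted traits
#' (closure) and, unless `allow_overlap = TRUE`, to be disjoint from every
#' other subgroup's complement so contamination is guaranteed foreign.
#' Deterministic for a fixed seed.
#'
#' @param rb A `mag_rulebook`.
#' @param n_subgroups Number of subgroups.
#' @param traits_per_subgroup Planted traits per subgroup.
#' @param seed Integer seed.
#' @param allow_overlap Permit overlapping complements between subgroups.
#' @param max_tries Resampling attempts before giving up.
#' @return List of `mag_profile` objects.
#' @export
generate_profiles <- function(rb, n_subgroups = 4, traits_per_subgroup = 3,
                              seed = 1, allow_overlap = FALSE, max_tries = 200) {
  ids <- trait_ids(rb)
  need <- n_subgroups * traits_per_subgroup
  if (traits_per_subgroup > length(ids) || need > length(ids))
    abort_input("requested %d traits across %d subgroups but the rulebook has only %d rules",
                need, n_subgroups, length(ids))
  set.seed(derive_seed(seed, 0))
  for (try in seq_len(max_tries)) {
    drawn <- sample(ids, need)
    profiles <- vector("list", n_subgroups)
    ok <- TRUE
    for (s in seq_len(n_subgroups)) {
      planted <- drawn[((s - 1) * traits_per_subgroup + 1):(s * traits_per_subgroup)]
      pr <- tryCatch(subgroup_profile(sprintf("subgroup %d", s), planted, rb),
                     magtraits_input_error = function(e) NULL)
      if (is.null(pr)) { ok <- FALSE; break }
      profiles[[s]] <- pr
    }
    if (ok && !allow_overlap) {
      comps <- lapply(profiles, `[[`, "gene_complement")
      for (i in seq_along(comps)) for (j in seq_len(i - 1L))
        if (length(intersect(comps[[i]], comps[[j]]))) { ok <- FALSE }
    }
    if (ok) return(profiles)
  }
  abort_input(paste("could not draw %d non-overlapping, closed subgroup profiles",
                    "in %d tries; consider allow_overlap = TRUE or fewer",
                    "traits per subgroup"), n_subgroups, max_tries)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions the generator stands in for:
#' four subgroups of a MAG collection, per-genome completeness drawn
#' uniformly over 50-98%, CheckM-style contamination estimates below
#' ~7.3%, and a 5% per-gene foreign injection probability.
#'
#' @param n_subgroups Number of subgroups (default 4).
#' @param genomes_per_subgroup Genomes per subgroup (default 45, giving a
#'   collection of 180).
#' @param traits_per_subgroup Planted traits per subgroup (default 3).
#' @param completeness_range Percent range `[lo, hi]` for the per-genome
#'   completeness draw (default `c(50, 98)`).
#' @param contamination_rate Per-foreign-gene injection probability in
#'   `[0, 1]` (default 0.05).
#' @param contamination_pct_range Percent range for the reported (CheckM-style)
#'   contamination estimate (default `c(0, 7.3)`); this metadata figure is
#'   drawn independently of the gene injections, as marker-based estimates
#'   are not derivable from a diagnostic-gene list.
#' @param seed Integer root seed; per-genome streams are derived from it so
#'   changing the genome count never reshuffles earlier genomes.
#' @return A `mag_simconfig` list.
#' @export
simulation_config <- function(n_subgroups = 4, genomes_per_subgroup = 45,
                              traits_per_subgroup = 3,
                              completeness_range = c(50, 98),
                              contamination_rate = 0.05,
                              contamination_pct_range = c(0, 7.3),
                              seed = 1) {
  if (!is_count(n_subgroups) || !is_count(genomes_per_subgroup))
    abort_input("n_subgroups and genomes_per_subgroup must be positive integers")
  lo <- completeness_range[1]; hi <- completeness_range[2]
  if (lo < 0 || hi > 100 || lo > hi)
    abort_input("completeness_range must satisfy 0 <= lo <= hi <= 100")
  if (contamination_rate < 0 || contamination_rate > 1)
    abort_input("contamination_rate must lie in [0, 1]")
  structure(
    list(n_subgroups = as.integer(n_subgroups),
         genomes_per_subgroup = as.integer(genomes_per_subgroup),
         traits_per_subgroup = as.integer(traits_per_subgroup),
         completeness_range = as.numeric(completeness_range),
         contamination_rate = as.numeric(contamination_rate),
         contamination_pct_range = as.numeric(contamination_pct_range),
         seed = as.integer(seed)),
    class = "mag_simconfig"
  )
}

sim_habitats <- c("hot spring", "hydrothermal vent", "marine", "freshwater")

#' Simulate annotation and metadata tables from planted profiles
#'
#' @param profiles List of `mag_profile` objects (see [generate_profiles()]).
#' @param cfg A [simulation_config()]. `cfg$n_subgroups` must match
#'   `length(profiles)`.
#' @param rb Rulebook used to attach KO ids to the emitted annotation rows
#'   (symbol lookup; rows fall back to symbol-only when a gene has no KO).
#' @return List with `annotations` (`mag_annotations`), `genomes`
#'   (`mag_genomes`, tiers unassigned) and `truth` (`mag_truth`: per-genome
#'   planted subgroup/traits, drawn completeness, retained/dropped/injected
#'   genes, plus the config).
#' @export
simulate_genomes <- function(profiles, cfg, rb = builtin_rulebook()) {
  if (length(profiles) != cfg$n_subgroups)
    abort_input("cfg$n_subgroups (%d) does not match profiles (%d)",
                cfg$n_subgroups, length(profiles))
  ko_of <- symbol_ko_map(rb)
  comps <- lapply(profiles, `[[`, "gene_complement")
  lo <- cfg$completeness_range[1]; hi <- cfg$completeness_range[2]
  clo <- cfg$contamination_pct_range[1]; chi <- cfg$contamination_pct_range[2]

  ann_rows <- list()
  meta_rows <- list()
  truth_genomes <- list()
  i <- 0L
  for (s in seq_along(profiles)) {
    pr <- profiles[[s]]
    foreign_pool <- sort(setdiff(unique(unlist(comps[-s])), pr$gene_complement))
    for (j in seq_len(cfg$genomes_per_subgroup)) {
      i <- i + 1L
      gid <- sprintf("sg%d_mag%03d", s, j)
      set.seed(derive_seed(cfg$seed, i))
      completeness <- stats::runif(1, lo, hi)
      keep <- stats::runif(length(pr$gene_complement)) < completeness / 100
      retained <- pr$gene_complement[keep]
      contamination <- stats::runif(1, clo, chi)
      inj <- if (length(foreign_pool))
        foreign_pool[stats::runif(length(foreign_pool)) < cfg$contamination_rate]
      else character(0)
      genes <- c(retained, inj)
      if (length(genes)) {
        ann_rows[[gid]] <- data.frame(
          genome_id = gid,
          gene_id = sprintf("%s_g%04d", gid, seq_along(genes)),
          ko_id = unname(ko_of[genes]),
          symbol = genes,
          copy_number = 1L,
          row.names = NULL
        )
      }
      meta_rows[[gid]] <- data.frame(
        genome_id = gid, completeness = completeness,
        contamination = contamination, subgroup = pr$subgroup,
        habitat = sim_habitats[1L + (i %% length(sim_habitats))],
        quality_tier = NA_character_, row.names = NULL
      )
      truth_genomes[[gid]] <- list(
        subgroup = pr$subgroup, planted_traits = pr$trait_ids,
        completeness = completeness,
        retained = retained, dropped = pr$gene_complement[!keep],
        injected = inj
      )
    }
  }
  ann_df <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(genome_id = character(), gene_id = character(),
               ko_id = character(), symbol = character(),
               copy_number = integer())
  rownames(ann_df) <- NULL
  ann_df$ko_id[is.na(ann_df$ko_id)] <- ""
  genomes <- do.call(rbind, meta_rows)
  rownames(genomes) <- NULL
  class(genomes) <- c("mag_genomes", "data.frame")
  truth <- structure(
    list(genomes = truth_genomes, config = cfg,
         profiles = lapply(profiles, unclass)),
    class = "mag_truth"
  )
  list(annotations = annotation_table(ann_df, source = "<simulated>"),
       genomes = genomes, truth = truth)
}

# First KO id for each symbol in the rulebook (NA when none).
symbol_ko_map <- function(rb) {
  specs <- do.call(c, lapply(rb$rules, function(r) req_gene_specs(r$requirement)))
  out <- character(0)
  for (g in specs) {
    if (!g$symbol %in% names(out))
      out[g$symbol] <- if (length(g$ko_ids)) g$ko_ids[[1]] else NA_character_
  }
  out
}

#' Score trait recovery against the planted truth
#'
#' Compares a called trait matrix to the planted truth, per trait: a
#' genome is a true positive when the trait was planted for its subgroup
#' and called present, a false negative when planted but missed (gene
#' dropout), a false positive when called without having been planted
#' (contamination), and a true negative otherwise.
#'
#' @param tm A `mag_trait_matrix` whose genomes are all in `truth`.
#' @param truth A `mag_truth` from [simulate_genomes()].
#' @return A `mag_recovery` list: `per_trait` data frame (`trait_id`, `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`; rates are `NA` when
#'   undefined) and `overall_accuracy`.
#' @export
score_recovery <- function(tm, truth) {
  missing <- setdiff(tm$genome_ids, names(truth$genomes))
  if (length(missing))
    abort_input("genome(s) in matrix but not in truth: %s",
                paste(utils::head(missing, 3), collapse = ", "))
  planted <- vapply(tm$genome_ids, function(gid)
    tm$trait_ids %in% truth$genomes[[gid]]$planted_traits,
    logical(length(tm$trait_ids)))
  planted <- t(matrix(planted, nrow = length(tm$trait_ids),
                      dimnames = list(tm$trait_ids, tm$genome_ids)))
  called <- tm$values == 1L
  per_trait <- do.call(rbind, lapply(tm$trait_ids, function(tr) {
    p <- planted[, tr]; cl <- called[, tr]
    tp <- sum(p & cl); fn <- sum(p & !cl)
    fp <- sum(!p & cl); tn <- sum(!p & !cl)
    data.frame(trait_id = tr, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
               specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
               row.names = NULL)
  }))
  structure(
    list(per_trait = per_trait,
         overall_accuracy = mean(planted == called),
         n_genomes = length(tm$genome_ids)),
    class = "mag_recovery"
  )
}

#' @export
print.mag_recovery <- function(x, ...) {
  cat(sprintf("<mag_recovery: %d genomes, overall accuracy %.3f>\n",
              x$n_genomes, x$overall_accuracy))
  print(x$per_trait)
  invisible(x)
}

#' Write / read the planted truth as JSON
#'
#' @param truth A `mag_truth`.
#' @param path JSON path.
#' @return `path` invisibly / a `mag_truth`.
#' @export
write_truth_json <- function(truth, path) {
  doc <- list(
    config = unclass(truth$config),
    profiles = truth$profiles,
    genomes = truth$genomes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) abort_input("truth file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  genomes <- lapply(doc$genomes, function(g) list(
    subgroup = g$subgroup,
    planted_traits = as.character(unlist(g$planted_traits %||% list())),
    completeness = as.numeric(g$completeness),
    retained = as.character(unlist(g$retained %||% list())),
    dropped = as.character(unlist(g$dropped %||% list())),
    injected = as.character(unlist(g$injected %||% list()))
  ))
  cfg <- doc$config
  structure(
    list(genomes = genomes,
         config = simulation_config(
           n_subgroups = cfg$n_subgroups,
           genomes_per_subgroup = cfg$genomes_per_subgroup,
           traits_per_subgroup = cfg$traits_per_subgroup,
           completeness_range = as.numeric(unlist(cfg$completeness_range)),
           contamination_rate = cfg$contamination_rate,
           contamination_pct_range = as.numeric(unlist(cfg$contamination_pct_range)),
           seed = cfg$seed),
         profiles = doc$profiles),
    class = "mag_truth"
  )
}
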