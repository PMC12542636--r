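#' Trait rulebook: declarative definitions of metabolic traits
#'
#' A rulebook is an ordered collection of trait rules. Each rule names a
#' metabolic capability (a "trait") and states the gene-level evidence
#' required to call it present in a genome: single diagnostic genes,
#' multi-subunit complexes with a completeness threshold, and arbitrary
#' AND/OR combinations of both.
#'
#' @name rulebook
NULL

trait_categories <- c(
  "carbon metabolism", "carbon fixation", "sulfur metabolism",
  "nitrogen metabolism", "electron transport and hydrogen metabolism",
  "fatty acid metabolism", "transporters", "stress adaptation",
  "energy conservation"
)

#' Define a diagnostic gene
#'
#' @param symbol Gene symbol, e.g. `"pfk"`. Matching against annotation
#'   tables is case-insensitive on the symbol.
#' @param ko_ids Character vector of KEGG Orthology identifiers that also
#'   identify this gene (may be empty). KO lists are configuration data:
#'   the shipped defaults are best-effort and editable.
#' @param min_copies Minimum copy number required for a match (default 1).
#' @return A `mag_gene` object.
#' @export
#' @examples
#' gene_spec("pfk", ko_ids = "K00850")
gene_spec <- function(symbol, ko_ids = character(), min_copies = 1L) {
  if (!is.character(symbol) || length(symbol) != 1L || !nzchar(symbol))
    abort_validation("gene symbol must be a single non-empty string")
  if (!is_count(min_copies))
    abort_validation("min_copies must be a positive integer (gene '%s')", symbol)
  structure(
    list(symbol = symbol,
         ko_ids = as.character(ko_ids %||% character()),
         min_copies = as.integer(min_copies)),
    class = "mag_gene"
  )
}

#' Define a multi-subunit complex with a completeness threshold
#'
#' A complex is called satisfied when the fraction of its core subunits
#' found in a genome strictly exceeds `min_fraction`; when
#' `min_fraction = 1` every subunit is required (equality suffices).
#' With the default 0.5, exactly half of the subunits is not enough.
#'
#' @param name Complex name, e.g. `"narGHI"`.
#' @param subunits List of [gene_spec()] objects (or a character vector of
#'   symbols), at least two, distinct by symbol.
#' @param min_fraction Threshold in (0, 1]; default 0.5.
#' @return A `mag_complex` object.
#' @export
#' @examples
#' complex_spec("narGHI", c("narG", "narH", "narI"))
complex_spec <- function(name, subunits, min_fraction = 0.5) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_validation("complex name must be a single non-empty string")
  if (is.character(subunits)) subunits <- lapply(subunits, gene_spec)
  if (!is.list(subunits) || length(subunits) < 2L)
    abort_validation("complex '%s' must have at least 2 core subunits", name)
  syms <- vapply(subunits, function(s) s$symbol, character(1))
  if (anyDuplicated(syms))
    abort_validation("complex '%s' has duplicate subunit symbols", name)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    abort_validation("complex '%s': min_fraction must lie in (0, 1]", name)
  structure(
    list(name = name, subunits = subunits, min_fraction = min_fraction),
    class = "mag_complex"
  )
}

as_requirement <- function(x) {
  if (inherits(x, "mag_req")) return(x)
  if (inherits(x, "mag_gene"))
    return(structure(list(kind = "gene", gene = x), class = "mag_req"))
  if (inherits(x, "mag_complex"))
    return(structure(list(kind = "complex", complex = x), class = "mag_req"))
  if (is.character(x) && length(x) == 1L)
    return(as_requirement(gene_spec(x)))
  abort_validation("cannot interpret object of class '%s' as a requirement",
                   paste(class(x), collapse = "/"))
}

#' Combine requirements
#'
#' `all_of()` is satisfied when every child is; `any_of()` when at least one
#' child is. Children may be [gene_spec()], [complex_spec()], bare symbol
#' strings, or nested combinations.
#'
#' @param ... One or more child requirements.
#' @return A `mag_req` expression node.
#' @export
all_of <- function(...) {
  children <- lapply(list(...), as_requirement)
  if (length(children) < 1L) abort_validation("all_of() needs at least one child")
  structure(list(kind = "all_of", children = children), class = "mag_req")
}

#' @rdname all_of
#' @export
any_of <- function(...) {
  children <- lapply(list(...), as_requirement)
  if (length(children) < 1L) abort_validation("any_of() needs at least one child")
  structure(list(kind = "any_of", children = children), class = "mag_req")
}

#' Define a trait rule
#'
#' @param trait_id Unique identifier, e.g. `"asr"`.
#' @param display_name Human-readable name.
#' @param category One of the nine functional categories
#'   (see `magtraits:::trait_categories`).
#' @param requirement A requirement expression ([all_of()], [any_of()],
#'   [gene_spec()], [complex_spec()]).
#' @param notes Free-text provenance/comment.
#' @param ko_only If `TRUE`, gene matching for this rule uses KO identifiers
#'   only and ignores symbols.
#' @return A `mag_rule` object.
#' @export
trait_rule <- function(trait_id, display_name = trait_id, category,
                       requirement, notes = "", ko_only = FALSE) {
  if (!is.character(trait_id) || length(trait_id) != 1L || !nzchar(trait_id))
    abort_validation("trait_id must be a single non-empty string")
  if (!category %in% trait_categories)
    abort_validation("trait '%s': unknown category '%s'", trait_id, category)
  requirement <- as_requirement(requirement)
  structure(
    list(trait_id = trait_id, display_name = display_name,
         category = category, requirement = requirement,
         notes = notes, ko_only = isTRUE(ko_only)),
    class = "mag_rule"
  )
}

#' Assemble a rulebook
#'
#' @param rules List of [trait_rule()] objects with unique `trait_id`s.
#' @param version Version string recorded in outputs.
#' @return A `mag_rulebook` object.
#' @export
rulebook <- function(rules, version = "1.0") {
  rb <- structure(list(rules = rules, version = as.character(version)),
                  class = "mag_rulebook")
  viol <- validate_rulebook(rb)
  if (length(viol)) abort_validation("invalid rulebook: %s", viol[[1]])
  names(rb$rules) <- vapply(rb$rules, function(r) r$trait_id, character(1))
  rb
}

#' @export
print.mag_rulebook <- function(x, ...) {
  cat(sprintf("<mag_rulebook v%s: %d trait rules>\n", x$version, length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  %-28s [%s]\n", r$trait_id, r$category))
  invisible(x)
}

trait_ids <- function(rb) unname(vapply(rb$rules, function(r) r$trait_id, character(1)))

validate_requirement <- function(node, where) {
  viol <- character()
  if (!is.list(node) || is.null(node$kind))
    return(sprintf("%s: malformed requirement node", where))
  if (node$kind %in% c("all_of", "any_of")) {
    if (length(node$children %||% list()) < 1L)
      viol <- c(viol, sprintf("%s: %s with no children", where, node$kind))
    for (ch in node$children)
      viol <- c(viol, validate_requirement(ch, where))
  } else if (node$kind == "gene") {
    g <- node$gene
    if (is.null(g$symbol) || !nzchar(g$symbol))
      viol <- c(viol, sprintf("%s: gene with empty symbol", where))
    if (!is_count(g$min_copies %||% 1L))
      viol <- c(viol, sprintf("%s: gene '%s' min_copies < 1", where, g$symbol %||% "?"))
  } else if (node$kind == "complex") {
    cx <- node$complex
    syms <- vapply(cx$subunits %||% list(), function(s) s$symbol %||% "", character(1))
    if (length(syms) < 2L)
      viol <- c(viol, sprintf("%s: complex '%s' has fewer than 2 subunits",
                              where, cx$name %||% "?"))
    if (anyDuplicated(syms))
      viol <- c(viol, sprintf("%s: complex '%s' has duplicate subunits",
                              where, cx$name %||% "?"))
    mf <- cx$min_fraction %||% NA_real_
    if (!is.numeric(mf) || is.na(mf) || mf <= 0 || mf > 1)
      viol <- c(viol, sprintf("%s: complex '%s' min_fraction outside (0, 1]",
                              where, cx$name %||% "?"))
  } else {
    viol <- c(viol, sprintf("%s: unknown node kind '%s'", where, node$kind))
  }
  viol
}

#' Validate a rulebook
#'
#' Checks every structural invariant (unique trait ids, known categories,
#' well-formed requirement trees, complex thresholds in range). Violations
#' are returned as data, not raised.
#'
#' @param rb A `mag_rulebook` (possibly hand-built or freshly parsed).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_rulebook <- function(rb) {
  viol <- character()
  if (!is.list(rb) || !is.list(rb$rules))
    return("rulebook has no rules list")
  ids <- vapply(rb$rules, function(r) as.character(r$trait_id %||% ""), character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    viol <- c(viol, sprintf("duplicate trait_id '%s'", dup))
  for (r in rb$rules) {
    id <- r$trait_id %||% "?"
    if (!nzchar(id %||% ""))
      viol <- c(viol, "rule with empty trait_id")
    if (!(r$category %||% "") %in% trait_categories)
      viol <- c(viol, sprintf("rule '%s': unknown category '%s'", id, r$category %||% ""))
    viol <- c(viol, validate_requirement(r$requirement, sprintf("rule '%s'", id)))
  }
  viol
}

## ---- serialization ---------------------------------------------------------

serialize_requirement <- function(node) {
  switch(node$kind,
    all_of = list(all_of = lapply(node$children, serialize_requirement)),
    any_of = list(any_of = lapply(node$children, serialize_requirement)),
    gene = list(gene = list(symbol = node$gene$symbol,
                            ko_ids = as.list(node$gene$ko_ids),
                            min_copies = node$gene$min_copies)),
    complex = list(complex = list(
      name = node$complex$complex_name %||% node$complex$name,
      min_fraction = node$complex$min_fraction,
      subunits = lapply(node$complex$subunits, function(s)
        list(symbol = s$symbol, ko_ids = as.list(s$ko_ids),
             min_copies = s$min_copies))))
  )
}

deserialize_gene <- function(x, where) {
  if (is.null(x$symbol))
    abort_validation("%s: gene entry lacks a symbol", where)
  structure(
    list(symbol = as.character(x$symbol),
         ko_ids = as.character(unlist(x$ko_ids %||% list())),
         min_copies = as.integer(x$min_copies %||% 1L)),
    class = "mag_gene"
  )
}

deserialize_requirement <- function(x, where) {
  if (!is.list(x) || length(x) != 1L)
    abort_validation("%s: requirement node must have exactly one key", where)
  key <- names(x)
  body <- x[[1]]
  node <- switch(key,
    all_of = list(kind = "all_of",
                  children = lapply(body, deserialize_requirement, where = where)),
    any_of = list(kind = "any_of",
                  children = lapply(body, deserialize_requirement, where = where)),
    gene = list(kind = "gene", gene = deserialize_gene(body, where)),
    complex = list(kind = "complex", complex = structure(
      list(name = as.character(body$name %||% "?"),
           subunits = lapply(body$subunits %||% list(),
                             deserialize_gene, where = where),
           min_fraction = as.numeric(body$min_fraction %||% 0.5)),
      class = "mag_complex")),
    abort_validation("%s: unknown requirement key '%s'", where, key)
  )
  structure(node, class = "mag_req")
}

#' Write a rulebook to YAML or JSON
#'
#' Format is chosen from the file extension (`.yaml`/`.yml` canonical,
#' `.json` accepted). Round-trips with [load_rulebook()].
#'
#' @param rb A `mag_rulebook`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_rulebook <- function(rb, path) {
  doc <- list(
    version = rb$version,
    rules = lapply(rb$rules, function(r) list(
      trait_id = r$trait_id,
      display_name = r$display_name,
      category = r$category,
      notes = r$notes,
      ko_only = r$ko_only,
      requirement = serialize_requirement(r$requirement)
    ))
  )
  names(doc$rules) <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Load and validate a rulebook file
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON (`.json`) rulebook.
#' @return A validated `mag_rulebook`.
#' @export
load_rulebook <- function(path) {
  if (!file.exists(path)) abort_input("rulebook file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(doc) || is.null(doc$rules))
    abort_format("rulebook file '%s' lacks a 'rules' list", path)
  rules <- lapply(doc$rules, function(r) {
    id <- as.character(r$trait_id %||% "")
    if (!nzchar(id)) abort_validation("rulebook entry without trait_id in %s", path)
    structure(
      list(trait_id = id,
           display_name = as.character(r$display_name %||% id),
           category = as.character(r$category %||% ""),
           requirement = deserialize_requirement(r$requirement,
                                                 sprintf("rule '%s'", id)),
           notes = as.character(r$notes %||% ""),
           ko_only = isTRUE(r$ko_only)),
      class = "mag_rule"
    )
  })
  rb <- structure(list(rules = rules,
                       version = as.character(doc$version %||% "1.0")),
                  class = "mag_rulebook")
  viol <- validate_rulebook(rb)
  if (length(viol))
    abort_validation("rulebook '%s' failed validation: %s",
                     path, paste(viol, collapse = "; "))
  names(rb$rules) <- trait_ids(rb)
  rb
}

## ---- gene vocabulary helpers ----------------------------------------------

req_gene_specs <- function(node) {
  switch(node$kind,
    gene = list(node$gene),
    complex = node$complex$subunits,
    do.call(c, lapply(node$children, req_gene_specs))
  )
}

#' Gene symbols referenced by a rule or rulebook
#'
#' For a rule, returns every diagnostic gene and complex subunit symbol in
#' its requirement tree (all branches of `any_of` included).
#'
#' @param x A `mag_rule`, `mag_req`, or `mag_rulebook`.
#' @return Character vector of unique symbols, in first-appearance order.
#' @export
rule_genes <- function(x) {
  node <- if (inherits(x, "mag_rulebook")) {
    return(unique(unlist(lapply(x$rules, rule_genes))))
  } else if (inherits(x, "mag_rule")) x$requirement else as_requirement(x)
  unique(vapply(req_gene_specs(node), function(g) g$symbol, character(1)))
}
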