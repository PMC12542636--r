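# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "magtraits_error", "error")))
}

abort_format <- function(msg, ...) abort("magtraits_format_error", msg, ...)
abort_validation <- function(msg, ...) abort("magtraits_validation_error", msg, ...)
abort_input <- function(msg, ...) abort("magtraits_input_error", msg, ...)

# Derived per-item seed stream: adding genomes must not reshuffle draws for
# earlier genomes, so each genome gets its own deterministic seed below 2^31.
derive_seed <- function(root, i) {
  as.integer((as.numeric(root) %% 2147483646 + 7919 * as.numeric(i)) %% 2147483646) + 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

# KO identifiers look like K00845; used to decide how to normalise a bare
# gene identity string when indexing.
is_ko_id <- function(x) grepl("^K\\d{5}$", x, ignore.case = TRUE)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
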