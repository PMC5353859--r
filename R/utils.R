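# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Split a ";"-separated multi-value cell into a trimmed character vector.
#' @keywords internal
split_multi <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' @keywords internal
join_multi <- function(x) paste(x, collapse = ";")

# Case-insensitive id canonicalisation (gene-symbol case drifts between
# sources); original case is preserved for display.
#' @keywords internal
canon_id <- function(x) tolower(trimws(x))

#' @keywords internal
stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed, so independent
# stages of a pipeline do not share RNG streams.
#' @keywords internal
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 7919L) %% 2147483647L
}
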