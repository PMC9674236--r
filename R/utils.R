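# Internal helpers shared across modules.

#' @keywords internal
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Gap symbol used in terminus windows
#'
#' Positions of a cleavage window that fall outside the precursor sequence are
#' filled with this symbol.
#' @export
GAP_SYMBOL <- "."

BASIC_RESIDUES <- c("K", "R")

is_basic <- function(x) x %in% BASIC_RESIDUES

# character vector of single residues for a sequence string
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# canonical row key for a peptide species
species_key <- function(accession, sequence, start, end, amidated) {
  paste(accession, sequence, start, end, as.logical(amidated), sep = "|")
}

assert_aa <- function(sequence, what = "sequence") {
  bad <- setdiff(unique(seq_chars(sequence)), AA_ALPHABET)
  if (length(bad))
    stopf("%s contains non-amino-acid characters: %s", what,
          paste(bad, collapse = ", "))
  invisible(TRUE)
}
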