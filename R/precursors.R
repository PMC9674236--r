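# Prohormone precursor registry: sequences, annotated peptide features, and the
# coordinate / amidation logic shared by the simulator and the specificity
# analyses. Coordinates are 1-based inclusive (UniProt convention); cleavage
# boundaries are between-residue indices 0..L, boundary b separating residues
# b and b+1.

#' Load prohormone precursor sequences from FASTA
#'
#' Headers must follow the dialect \code{>ACCESSION|GENE free text}; the first
#' two pipe-separated fields of the first whitespace-delimited word give the
#' accession and gene symbol. Sequences are uppercased and must use the
#' canonical 20-letter amino-acid alphabet.
#'
#' @param paths One or more FASTA file paths.
#' @return A \code{precursor_registry}: a named list of records, each with
#'   \code{accession}, \code{gene_symbol}, \code{sequence} and a
#'   \code{features} data frame (empty until \code{\link{read_features}}).
#' @seealso [read_features()], [example_registry()]
#' @export
read_precursors <- function(paths) {
  records <- list()
  for (path in paths) {
    if (!file.exists(path)) stopf("FASTA file not found: %s", path)
    set <- Biostrings::readBStringSet(path)   # alphabet validated below
    if (length(set) == 0) {
      warning(sprintf("empty FASTA file: %s", path))
      next
    }
    headers <- names(set)
    for (i in seq_along(set)) {
      word <- strsplit(headers[i], "\\s+")[[1]][1]
      fields <- strsplit(word, "|", fixed = TRUE)[[1]]
      if (length(fields) < 2 || !nzchar(fields[1]))
        stopf("malformed FASTA header (expected '>ACCESSION|GENE'): '%s'",
              headers[i])
      acc <- fields[1]
      sequence <- toupper(as.character(set[[i]]))
      if (!nzchar(sequence)) stopf("empty sequence for record '%s'", acc)
      assert_aa(sequence, sprintf("sequence of '%s'", acc))
      if (acc %in% names(records)) stopf("duplicate accession: '%s'", acc)
      records[[acc]] <- list(accession = acc, gene_symbol = fields[2],
                             sequence = sequence,
                             features = empty_features())
    }
  }
  structure(records, class = "precursor_registry")
}

empty_features <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             kind = character(), amidated = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.precursor_registry <- function(x, ...) {
  cat(sprintf("precursor_registry with %d precursors\n", length(x)))
  for (r in x)
    cat(sprintf("  %s (%s): %d aa, %d features\n", r$accession, r$gene_symbol,
                nchar(r$sequence), nrow(r$features)))
  invisible(x)
}

#' Attach annotated peptide features to a registry
#'
#' Reads a tab-delimited feature table (columns \code{accession, name, start,
#' end, kind, amidated}) and attaches each row to the matching precursor.
#' \code{kind} must be one of signal, propeptide, chain, peptide. Rows whose
#' accession is absent from the registry are skipped and counted in the
#' \code{"skipped"} attribute of the result.
#'
#' @param path Feature TSV path.
#' @param registry A \code{precursor_registry}.
#' @return The registry with features attached.
#' @export
read_features <- function(path, registry) {
  stopifnot(inherits(registry, "precursor_registry"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("accession", "name", "start", "end", "kind", "amidated")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stopf("feature table lacks required column(s): %s",
          paste(missing, collapse = ", "))
  if (!all(tab$kind %in% c("signal", "propeptide", "chain", "peptide")))
    stopf("feature 'kind' must be one of signal/propeptide/chain/peptide")
  tab$amidated <- as.logical(tab$amidated)
  skipped <- 0L
  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    if (!acc %in% names(registry)) {
      skipped <- skipped + 1L
      next
    }
    L <- nchar(registry[[acc]]$sequence)
    if (is.na(tab$start[i]) || is.na(tab$end[i]) ||
        tab$start[i] < 1 || tab$end[i] > L || tab$start[i] > tab$end[i])
      stopf("feature '%s' of %s has invalid coordinates [%s, %s] (length %d)",
            tab$name[i], acc, tab$start[i], tab$end[i], L)
    registry[[acc]]$features <- rbind(
      registry[[acc]]$features,
      data.frame(name = tab$name[i], start = as.integer(tab$start[i]),
                 end = as.integer(tab$end[i]), kind = tab$kind[i],
                 amidated = tab$amidated[i], stringsAsFactors = FALSE))
  }
  if (skipped > 0)
    message(sprintf("read_features: %d row(s) referenced unknown accessions and were skipped",
                    skipped))
  attr(registry, "skipped") <- skipped
  registry
}

#' Bundled example registry of prohormone precursors
#'
#' Loads the precursor fixtures shipped with the package: the human
#' proglucagon sequence (P01275) plus seven synthetic prohormone constructs
#' whose architecture (signal peptide, bioactive blocks flanked by dibasic
#' linkers, amide-donor glycines, X-P/A amino termini) mirrors real
#' neuropeptide precursors without reproducing their sequences.
#'
#' @return A \code{precursor_registry} with features attached.
#' @export
example_registry <- function() {
  ext <- system.file("extdata", package = "cleavekit")
  reg <- read_precursors(c(file.path(ext, "proglucagon_P01275.fasta"),
                           file.path(ext, "prohormones_synthetic.fasta")))
  read_features(file.path(ext, "prohormone_features.tsv"), reg)
}

#' Precursor sequence lookup
#' @param registry A \code{precursor_registry}.
#' @param accession Precursor accession.
#' @return Amino-acid string.
#' @export
precursor_sequence <- function(registry, accession) {
  if (!accession %in% names(registry)) stopf("unknown accession: '%s'", accession)
  registry[[accession]]$sequence
}

#' Extract the sequence of an annotated feature
#' @inheritParams precursor_sequence
#' @param name Feature name.
#' @param amidated Match the amidated (\code{TRUE}) or plain form.
#' @return Amino-acid substring spanned by the feature.
#' @export
feature_sequence <- function(registry, accession, name, amidated = FALSE) {
  f <- registry[[accession]]$features
  hit <- which(f$name == name & f$amidated == amidated)
  if (length(hit) != 1) stopf("feature '%s' (amidated=%s) not found once in %s",
                              name, amidated, accession)
  substr(registry[[accession]]$sequence, f$start[hit], f$end[hit])
}

#' Is a C-terminal amidation site chemically possible?
#'
#' A peptide C-terminal amide is derived from a precursor glycine: the residue
#' immediately following the peptide's last residue in the precursor must be
#' glycine. Returns \code{FALSE} at the precursor C terminus (no donor
#' residue exists).
#'
#' @inheritParams precursor_sequence
#' @param last_residue_pos 1-based position of the peptide's C-terminal
#'   residue within the precursor.
#' @return Logical.
#' @export
amidation_valid <- function(registry, accession, last_residue_pos) {
  s <- precursor_sequence(registry, accession)
  L <- nchar(s)
  if (last_residue_pos < 1 || last_residue_pos > L)
    stopf("position %s outside [1, %d] for %s", last_residue_pos, L, accession)
  last_residue_pos < L && substr(s, last_residue_pos + 1, last_residue_pos + 1) == "G"
}

#' Cleavage-window context around a boundary
#'
#' Returns the residues at positions -flank..-1 (upstream of the boundary,
#' Schechter-Berger P\emph{flank}..P1) and +1..+flank (downstream,
#' P1'..P\emph{flank}'). Positions beyond the sequence ends are filled with
#' \code{\link{GAP_SYMBOL}}.
#'
#' @inheritParams precursor_sequence
#' @param boundary Between-residue index in 0..L: boundary \code{b} lies
#'   between residues \code{b} and \code{b + 1}.
#' @param flank Number of positions on each side (default 4).
#' @return Named character vector of length \code{2 * flank}
#'   (names "-4".."-1", "+1".."+4" for the default flank).
#' @export
terminus_window <- function(registry, accession, boundary, flank = 4L) {
  if (flank < 1) stopf("flank must be >= 1")
  s <- precursor_sequence(registry, accession)
  L <- nchar(s)
  if (boundary < 0 || boundary > L)
    stopf("boundary %s outside [0, %d] for %s", boundary, L, accession)
  pos <- c(seq(boundary - flank + 1, boundary),           # -flank..-1
           seq(boundary + 1, boundary + flank))           # +1..+flank
  res <- ifelse(pos >= 1 & pos <= L, substring(s, pos, pos), GAP_SYMBOL)
  names(res) <- c(paste0("-", rev(seq_len(flank))), paste0("+", seq_len(flank)))
  res
}
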