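# Peptide quantification tables: construction, TSV round-trip, total-intensity
# normalization, replicate-completeness filtering, precursor mapping and
# roll-up, and bioactive-feature matching.

#' Construct a peptide quantification table
#'
#' @param abundance Numeric matrix, peptides x samples; \code{NA} encodes a
#'   missing (not detected) value; all present values must be nonnegative.
#' @param peptides Data frame with columns \code{sequence} and
#'   \code{modifications} (semicolon-separated subset of
#'   \code{amidated_C_term}, \code{oxidation}, \code{acetyl_N_term});
#'   optional \code{accession}, \code{start}, \code{end}.
#' @param samples Data frame with columns \code{sample_id, clone_id, genotype,
#'   bmp, replicate}; \code{(clone_id, bmp, replicate)} must be unique.
#' @return An object of class \code{quant_table}.
#' @export
quant_table <- function(abundance, peptides, samples) {
  abundance <- as.matrix(abundance)
  required <- c("sample_id", "clone_id", "genotype", "bmp", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stopf("sample metadata lacks required column(s): %s",
          paste(missing, collapse = ", "))
  if (!"sequence" %in% names(peptides)) stopf("peptides need a 'sequence' column")
  if (!"modifications" %in% names(peptides)) peptides$modifications <- ""
  for (col in c("accession", "start", "end"))
    if (!col %in% names(peptides)) peptides[[col]] <- NA
  if (nrow(peptides) != nrow(abundance) || nrow(samples) != ncol(abundance))
    stopf("abundance matrix (%d x %d) does not match %d peptides x %d samples",
          nrow(abundance), ncol(abundance), nrow(peptides), nrow(samples))
  if (any(abundance < 0, na.rm = TRUE)) stopf("abundance values must be nonnegative")
  if (anyDuplicated(samples[, c("clone_id", "bmp", "replicate")]))
    stopf("(clone_id, bmp, replicate) must be unique across samples")
  colnames(abundance) <- samples$sample_id
  rownames(peptides) <- NULL
  structure(list(abundance = abundance, peptides = peptides,
                 samples = samples), class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d peptides x %d samples (%.1f%% missing)\n",
              nrow(x$abundance), ncol(x$abundance),
              100 * mean(is.na(x$abundance))))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$abundance)

is_amidated <- function(qt_or_peps) {
  peps <- if (inherits(qt_or_peps, "quant_table")) qt_or_peps$peptides else qt_or_peps
  grepl("amidated_C_term", peps$modifications, fixed = TRUE)
}

#' Write / read a quantification table as TSV
#'
#' The peptide table (annotation columns followed by one column per sample,
#' missing values as empty cells) and the sample metadata are written as two
#' tab-delimited files. \code{read_quant_table(write_quant_table(x))} is the
#' identity.
#'
#' @param qt A \code{quant_table}.
#' @param path Peptide-table TSV path.
#' @param meta_path Sample-metadata TSV path (default: \code{path} with a
#'   \code{.samples.tsv} suffix).
#' @return \code{write_quant_table}: invisibly, the two paths.
#' @export
write_quant_table <- function(qt, path, meta_path = paste0(path, ".samples.tsv")) {
  stopifnot(inherits(qt, "quant_table"))
  ann <- qt$peptides[, c("sequence", "modifications", "accession", "start", "end")]
  tab <- cbind(ann, as.data.frame(qt$abundance, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(qt$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(path, meta_path))
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path, meta_path = paste0(path, ".samples.tsv")) {
  if (!file.exists(meta_path))
    stopf(paste0("sample metadata file not found: %s (required columns: ",
                 "sample_id, clone_id, genotype, bmp, replicate)"), meta_path)
  samples <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                           check.names = FALSE)
  ann_cols <- c("sequence", "modifications", "accession", "start", "end")
  missing <- setdiff(ann_cols, names(tab))
  if (length(missing))
    stopf("quant table lacks column(s): %s", paste(missing, collapse = ", "))
  sample_cols <- setdiff(names(tab), ann_cols)
  if (!setequal(sample_cols, samples$sample_id))
    stopf("sample columns of %s do not match sample_id in %s", path, meta_path)
  mat <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(mat < 0, na.rm = TRUE)) stopf("abundance values must be nonnegative")
  peps <- tab[, ann_cols]
  peps$modifications[is.na(peps$modifications)] <- ""
  quant_table(mat, peps, samples)
}

#' Total-intensity normalization
#'
#' Scales each sample so that its total (over non-missing values) equals the
#' median of the pre-normalization per-sample totals. Missing values stay
#' missing.
#'
#' @param qt A \code{quant_table}.
#' @return The normalized \code{quant_table}; scale factors in attribute
#'   \code{"scale_factors"}.
#' @export
normalize_total <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  totals <- colSums(qt$abundance, na.rm = TRUE)
  empty <- colSums(!is.na(qt$abundance)) == 0
  if (any(empty))
    stopf("sample(s) with no observed values: %s",
          paste(qt$samples$sample_id[empty], collapse = ", "))
  target <- stats::median(totals)
  factors <- target / totals
  qt$abundance <- sweep(qt$abundance, 2, factors, `*`)
  attr(qt, "scale_factors") <- factors
  qt
}

#' Replicate-completeness filter
#'
#' Keeps a peptide iff there exists a (clone, bmp) group in which it is
#' observed in every replicate.
#'
#' @param qt A \code{quant_table}.
#' @return Filtered \code{quant_table}; the number of removed peptides is
#'   recorded in attribute \code{"n_filtered"}.
#' @export
filter_replicate_complete <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  groups <- interaction(qt$samples$clone_id, qt$samples$bmp, drop = TRUE)
  keep <- rep(FALSE, nrow(qt$abundance))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    keep <- keep | rowSums(is.na(qt$abundance[, cols, drop = FALSE])) == 0
  }
  out <- quant_table(qt$abundance[keep, , drop = FALSE],
                     qt$peptides[keep, , drop = FALSE], qt$samples)
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Map peptides to precursor coordinates by exact substring search
#'
#' Each peptide sequence is searched in every precursor. For amidated peptides
#' a hit additionally requires the residue following the match to be glycine
#' (the amide-donor rule); matches failing it are discarded. A single
#' surviving hit fills \code{accession/start/end} and sets
#' \code{map_status = "unique"}; zero or multiple hits are flagged
#' \code{"unmapped"} / \code{"ambiguous"} and excluded from specificity
#' analyses downstream.
#'
#' @param qt A \code{quant_table}.
#' @param registry A \code{precursor_registry}.
#' @return The \code{quant_table} with mapping columns filled.
#' @export
map_peptides <- function(qt, registry) {
  stopifnot(inherits(qt, "quant_table"), inherits(registry, "precursor_registry"))
  peps <- qt$peptides
  amid <- is_amidated(peps)
  peps$accession <- NA_character_
  peps$start <- NA_integer_
  peps$end <- NA_integer_
  peps$map_status <- "unmapped"
  for (i in seq_len(nrow(peps))) {
    hits <- list()
    for (acc in names(registry)) {
      s <- registry[[acc]]$sequence
      m <- gregexpr(peps$sequence[i], s, fixed = TRUE)[[1]]
      starts <- m[m > 0]
      for (st in starts) {
        en <- st + nchar(peps$sequence[i]) - 1L
        if (amid[i] && !amidation_valid(registry, acc, en)) next
        hits[[length(hits) + 1]] <- list(acc = acc, start = st, end = en)
      }
    }
    if (length(hits) == 1) {
      peps$accession[i] <- hits[[1]]$acc
      peps$start[i] <- hits[[1]]$start
      peps$end[i] <- hits[[1]]$end
      peps$map_status[i] <- "unique"
    } else if (length(hits) > 1) {
      peps$map_status[i] <- "ambiguous"
    }
  }
  qt$peptides <- peps
  qt
}

#' Aggregate mapped peptides to precursor level
#'
#' Per precursor and sample, the sum of non-missing mapped peptide
#' abundances; samples where every peptide of a precursor is missing stay
#' missing (the "n.d." state).
#'
#' @param qt A mapped \code{quant_table}.
#' @return Matrix precursors x samples.
#' @export
aggregate_precursor <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  ok <- !is.na(qt$peptides$accession)
  if (!any(ok)) stopf("no mapped peptides to aggregate")
  mat <- qt$abundance[ok, , drop = FALSE]
  acc <- qt$peptides$accession[ok]
  out <- do.call(rbind, lapply(split(seq_along(acc), acc), function(idx) {
    sub <- mat[idx, , drop = FALSE]
    res <- colSums(sub, na.rm = TRUE)
    res[colSums(!is.na(sub)) == 0] <- NA_real_
    res
  }))
  out
}

#' Label observations matching annotated bioactive peptides
#'
#' An observation is labeled with a feature iff its mapped coordinates equal
#' the feature's exactly and its C-terminal amidation state matches the
#' feature's flag; amidated matches carry an "a" suffix.
#'
#' @param qt A mapped \code{quant_table}.
#' @param registry A \code{precursor_registry} with features attached.
#' @return The \code{quant_table} with a \code{bioactive} peptide column
#'   (\code{NA} where no feature matches).
#' @export
match_bioactive <- function(qt, registry) {
  stopifnot(inherits(qt, "quant_table"))
  peps <- qt$peptides
  amid <- is_amidated(peps)
  peps$bioactive <- NA_character_
  for (i in seq_len(nrow(peps))) {
    acc <- peps$accession[i]
    if (is.na(acc) || !acc %in% names(registry)) next
    f <- registry[[acc]]$features
    hit <- which(f$start == peps$start[i] & f$end == peps$end[i] &
                 f$amidated == amid[i] & f$kind != "signal")
    if (length(hit))
      peps$bioactive[i] <- if (amid[i]) paste0(f$name[hit[1]], "a") else f$name[hit[1]]
  }
  qt$peptides <- peps
  qt
}
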