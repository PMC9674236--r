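# Cleavage-specificity evidence from enriched peptide sets: terminus windows,
# deduplicated sequence logos, residue-enrichment fractions, X-P/A dipeptide
# pair detection, and substrate repertoires.

#' Extract cleavage-window contexts for peptide termini
#'
#' For the N terminus of a peptide the boundary is \code{start - 1}; for the
#' C terminus it is \code{end}. Windows are taken from the precursor with
#' \code{\link{terminus_window}} (flank 4 by default, positions -4..-1 and
#' +1..+4). Peptides without a unique mapping are skipped and counted in the
#' \code{"n_skipped"} attribute.
#'
#' @param peptides Data frame with \code{accession, start, end} (e.g. a
#'   \code{differential_result} or the peptide table of a mapped
#'   \code{quant_table}).
#' @param registry A \code{precursor_registry}.
#' @param terminus \code{"N"} or \code{"C"}.
#' @param flank Window half-width.
#' @return Data frame of contexts: \code{accession, boundary, terminus,
#'   context} (the 2*flank-character window string, gap-padded).
#' @export
extract_contexts <- function(peptides, registry, terminus = c("N", "C"),
                             flank = 4L) {
  terminus <- match.arg(terminus)
  if ("map_status" %in% names(peptides)) {
    skip <- peptides$map_status != "unique"
  } else {
    skip <- is.na(peptides$accession) | is.na(peptides$start) |
      is.na(peptides$end)
  }
  kept <- peptides[!skip, , drop = FALSE]
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    boundary <- if (terminus == "N") kept$start[i] - 1L else kept$end[i]
    w <- terminus_window(registry, kept$accession[i], boundary, flank)
    data.frame(accession = kept$accession[i], boundary = boundary,
               terminus = terminus, context = paste(w, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), boundary = integer(),
               terminus = character(), context = character())
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Collapse duplicate window contexts
#'
#' Contexts with an identical window string are collapsed to one, matching
#' the convention that duplicate P-4..P4 sequences are excluded before logo
#' construction.
#'
#' @param contexts Output of \code{\link{extract_contexts}}.
#' @return The unique-context data frame.
#' @export
dedupe_contexts <- function(contexts) {
  contexts[!duplicated(contexts$context), , drop = FALSE]
}

#' Build a position-frequency logo matrix from contexts
#'
#' Residues are counted once per context at each window position; gap symbols
#' are ignored. Frequencies at each position are taken over non-gap
#' observations, and the information content in bits is computed against the
#' uniform 20-residue background (log2 20 minus the positional entropy).
#'
#' @param contexts Data frame with a \code{context} column (equal-length
#'   window strings); at least one row.
#' @return A \code{logo_matrix}: list with \code{counts} and \code{freq}
#'   (positions x 20 residues), \code{bits} (per position), \code{positions}
#'   and \code{n_contexts}.
#' @export
build_logo <- function(contexts) {
  ctx <- contexts$context
  if (length(ctx) < 1) stopf("at least one context is required")
  width <- unique(nchar(ctx))
  if (length(width) != 1) stopf("contexts must have equal width")
  flank <- width %/% 2
  positions <- c(paste0("-", rev(seq_len(flank))), paste0("+", seq_len(flank)))
  counts <- matrix(0L, width, length(AA_ALPHABET),
                   dimnames = list(positions, AA_ALPHABET))
  chars <- do.call(rbind, strsplit(ctx, ""))
  for (p in seq_len(width)) {
    tab <- table(factor(chars[, p], levels = AA_ALPHABET))
    counts[p, ] <- as.integer(tab)
  }
  totals <- rowSums(counts)
  freq <- counts / ifelse(totals == 0, 1, totals)
  ent <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  bits <- ifelse(totals == 0, 0, log2(length(AA_ALPHABET)) - ent)
  structure(list(counts = counts, freq = freq, bits = bits,
                 positions = positions, n_contexts = length(ctx)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("logo_matrix over %d contexts\n", x$n_contexts))
  top <- apply(x$freq, 1, function(f) names(which.max(f)))
  cat("consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Residue frequency at a logo position
#'
#' Fraction of contexts whose residue at \code{position} belongs to
#' \code{residues} (gap-padded contexts at that position are excluded from
#' the denominator).
#'
#' @param contexts Context data frame.
#' @param position Signed position label, e.g. \code{"-1"} or \code{"+2"}.
#' @param residues Residue set, e.g. \code{c("K", "R")}.
#' @return Numeric fraction (NaN when no context covers the position).
#' @export
residue_fraction <- function(contexts, position, residues) {
  width <- unique(nchar(contexts$context))
  flank <- width %/% 2
  labels <- c(paste0("-", rev(seq_len(flank))), paste0("+", seq_len(flank)))
  idx <- match(position, labels)
  if (is.na(idx)) stopf("position '%s' not in window (%s)", position,
                        paste(labels, collapse = ", "))
  ch <- substr(contexts$context, idx, idx)
  ch <- ch[ch != GAP_SYMBOL]
  mean(ch %in% residues)
}

#' Compare residue enrichment between two context sets
#'
#' Computes the fraction of contexts carrying one of \code{residues} at the
#' given position in each set and a 2x2 Fisher exact comparison.
#'
#' @param contexts_a,contexts_b Context data frames (both non-empty).
#' @param position Signed position label.
#' @param residues Residue set.
#' @return List: \code{fraction_a}, \code{fraction_b}, \code{odds_ratio},
#'   \code{p_value}, \code{table}.
#' @export
residue_enrichment <- function(contexts_a, contexts_b, position, residues) {
  if (nrow(contexts_a) == 0 || nrow(contexts_b) == 0)
    stopf("both context sets must be non-empty")
  count_in <- function(ctx) {
    width <- unique(nchar(ctx$context))
    flank <- width %/% 2
    labels <- c(paste0("-", rev(seq_len(flank))), paste0("+", seq_len(flank)))
    idx <- match(position, labels)
    ch <- substr(ctx$context, idx, idx)
    ch <- ch[ch != GAP_SYMBOL]
    c(hit = sum(ch %in% residues), miss = sum(!ch %in% residues))
  }
  ca <- count_in(contexts_a); cb <- count_in(contexts_b)
  tab <- rbind(A = ca, B = cb)
  ft <- stats::fisher.test(tab)
  list(fraction_a = ca["hit"] / sum(ca), fraction_b = cb["hit"] / sum(cb),
       odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Detect peptide pairs differing by an N-terminal X-P/A dipeptide
#'
#' Finds all ordered pairs (long, short) in a table where the short sequence
#' equals the long sequence minus its first two residues, the long peptide's
#' second residue is in \code{residues_at_2}, both map to the same precursor,
#' and the modifications agree apart from the N-terminal state. Per-pair
#' z-scaled abundances of both members are attached for heatmap display.
#'
#' @param qt A mapped \code{quant_table} (or a peptides data frame; then no
#'   abundances are attached).
#' @param residues_at_2 Residues at position 2 of the long peptide.
#' @return Data frame of pairs: \code{accession, long_sequence,
#'   short_sequence, dipeptide, long_row, short_row}; z-scaled abundance
#'   matrix of the involved rows in attribute \code{"zmatrix"} when
#'   abundances are available.
#' @export
find_dipeptide_pairs <- function(qt, residues_at_2 = c("P", "A")) {
  peps <- if (inherits(qt, "quant_table")) qt$peptides else qt
  strip_nterm <- function(mods) {
    m <- strsplit(mods, ";", fixed = TRUE)
    vapply(m, function(x) paste(sort(setdiff(x, "acetyl_N_term")), collapse = ";"), "")
  }
  mods_cmp <- strip_nterm(peps$modifications %||% rep("", nrow(peps)))
  key <- paste(peps$accession, peps$sequence, mods_cmp, sep = "|")
  lookup <- split(seq_len(nrow(peps)), key)
  out <- list()
  for (i in seq_len(nrow(peps))) {
    sq <- peps$sequence[i]
    if (is.na(peps$accession[i]) || nchar(sq) < 3) next
    if (!(substr(sq, 2, 2) %in% residues_at_2)) next
    short <- substr(sq, 3, nchar(sq))
    hits <- lookup[[paste(peps$accession[i], short, mods_cmp[i], sep = "|")]]
    for (j in hits) {
      # the short form must sit two residues downstream when coordinates exist
      if (!is.na(peps$start[i]) && !is.na(peps$start[j]) &&
          peps$start[j] != peps$start[i] + 2L) next
      out[[length(out) + 1]] <- data.frame(
        accession = peps$accession[i], long_sequence = sq,
        short_sequence = short, dipeptide = substr(sq, 1, 2),
        long_row = i, short_row = j, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(accession = character(), long_sequence = character(),
               short_sequence = character(), dipeptide = character(),
               long_row = integer(), short_row = integer())
  if (inherits(qt, "quant_table") && nrow(pairs)) {
    rows <- unique(c(pairs$long_row, pairs$short_row))
    mat <- log2(qt$abundance[rows, , drop = FALSE])
    mat[is.na(mat)] <- min(mat, na.rm = TRUE)   # display-only floor
    z <- zscale(mat)
    rownames(z) <- qt$peptides$sequence[rows]
    attr(pairs, "zmatrix") <- z
  }
  pairs
}

#' Substrate repertoire of an enriched peptide set
#'
#' @param peptides Data frame with an \code{accession} column (mapped).
#' @return Named integer vector: enriched-peptide count per precursor; the
#'   counts sum to the number of mapped peptides in the set.
#' @export
substrate_repertoire <- function(peptides) {
  acc <- peptides$accession[!is.na(peptides$accession)]
  if (!length(acc)) return(stats::setNames(integer(), character()))
  tab <- table(acc)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a logo matrix as a position-frequency TSV
#'
#' @param logo A \code{logo_matrix}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = logo$positions, logo$freq, bits = logo$bits,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
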