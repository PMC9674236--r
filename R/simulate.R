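# In-silico prohormone processing simulator. Generates ground-truthed peptide
# species under wild-type and protease-knockout genotypes by composing four
# mechanisms:
#   * endoproteolysis C-terminal to dibasic residues (PCSK1/PCSK2-like; both
#     must be disabled to abolish it, emulating their redundancy),
#   * carboxypeptidase trimming of C-terminal K/R (CPE or CPB1, assigned
#     per precursor),
#   * C-terminal amidation from an exposed glycine,
#   * DPP4-like removal of the N-terminal dipeptide when residue 2 is P or A.
# Abundance tables with replicate structure, log-normal noise and left-censored
# missingness are layered on top by generate_quant_table().

#' Enzyme efficiency rules for the processing simulator
#'
#' Each efficiency is the probability, per eligible event, that the reaction
#' fires. At the default of 1 processing is deterministic and complete.
#'
#' @param endo Dibasic endoprotease cleavage probability per eligible boundary.
#' @param carboxy Probability per C-terminal basic residue removal step.
#' @param dpp4 Probability that an eligible N-terminal dipeptide is removed.
#' @param amidation Probability that an exposed C-terminal glycine is converted
#'   to an amide.
#' @param dpp4_iterative If \code{TRUE} DPP4 keeps removing dipeptides while
#'   residue 2 of the remaining peptide is P/A; default is a single removal.
#' @return A named list of class \code{enzyme_rules}.
#' @export
enzyme_rules <- function(endo = 1, carboxy = 1, dpp4 = 1, amidation = 1,
                         dpp4_iterative = FALSE) {
  for (e in c(endo, carboxy, dpp4, amidation))
    if (e < 0 || e > 1) stopf("efficiencies must lie in [0, 1]")
  structure(list(endo = endo, carboxy = carboxy, dpp4 = dpp4,
                 amidation = amidation, dpp4_iterative = dpp4_iterative),
            class = "enzyme_rules")
}

#' Cleave a sequence C-terminally to dibasic residues
#'
#' Eligible boundaries lie immediately after the second residue of a dibasic
#' pair (KK, KR, RK, RR); each fires independently with probability
#' \code{efficiency}. At efficiency 1 the fragments concatenate to the input
#' and every internal boundary follows a dibasic pair.
#'
#' @param sequence Amino-acid string.
#' @param efficiency Cleavage probability per eligible boundary.
#' @param start_pos 1-based coordinate of the first residue of \code{sequence}
#'   within its precursor (used to report fragment coordinates).
#' @return Data frame with columns \code{sequence, start, end}.
#' @export
digest_endo <- function(sequence, efficiency = 1, start_pos = 1L) {
  if (!nzchar(sequence)) stopf("sequence must be non-empty")
  ch <- seq_chars(sequence)
  L <- length(ch)
  eligible <- which(seq_len(L) < L &
                    is_basic(ch) & c(FALSE, is_basic(ch[-L])))
  if (efficiency >= 1) {
    fired <- eligible
  } else if (efficiency <= 0 || length(eligible) == 0) {
    fired <- integer()
  } else {
    fired <- eligible[stats::runif(length(eligible)) < efficiency]
  }
  cuts <- c(0L, fired, L)
  data.frame(
    sequence = substring(sequence, head(cuts, -1) + 1L, cuts[-1]),
    start = as.integer(start_pos + head(cuts, -1)),
    end = as.integer(start_pos + cuts[-1] - 1L),
    stringsAsFactors = FALSE)
}

#' Carboxypeptidase trimming chain
#'
#' With the enzyme active, C-terminal K/R residues are removed one at a time
#' until the C terminus is non-basic (or the peptide is exhausted to one
#' residue's worth of removals). All species along the chain are returned,
#' input first; with the enzyme inactive the input is returned unchanged.
#'
#' @param peptide Amino-acid string.
#' @param active Logical; \code{FALSE} models the knockout.
#' @return Character vector: the trimming chain (input, intermediates, final).
#' @export
trim_carboxy <- function(peptide, active = TRUE) {
  if (!nzchar(peptide)) stopf("peptide must be non-empty")
  if (!active) return(peptide)
  chain <- peptide
  cur <- peptide
  while (nchar(cur) > 1 && is_basic(substr(cur, nchar(cur), nchar(cur)))) {
    cur <- substr(cur, 1, nchar(cur) - 1)
    chain <- c(chain, cur)
  }
  chain
}

#' DPP4-style N-terminal dipeptide removal chain
#'
#' With the enzyme active and residue 2 of the peptide in
#' \code{residues_at_2}, the N-terminal dipeptide is removed; with
#' \code{iterative = TRUE} removal repeats while the condition holds and at
#' least 3 residues remain. All species are returned, input first.
#'
#' @param peptide Amino-acid string of length >= 3.
#' @param active Logical; \code{FALSE} models the knockout.
#' @param iterative Repeat while eligible.
#' @param residues_at_2 Residues at position 2 licensing cleavage.
#' @return Character vector: the chain of species.
#' @export
trim_amino_dpp4 <- function(peptide, active = TRUE, iterative = FALSE,
                            residues_at_2 = c("P", "A")) {
  if (nchar(peptide) < 3) stopf("peptide must have length >= 3")
  if (!active) return(peptide)
  chain <- peptide
  cur <- peptide
  repeat {
    if (nchar(cur) < 3 || !(substr(cur, 2, 2) %in% residues_at_2)) break
    cur <- substr(cur, 3, nchar(cur))
    chain <- c(chain, cur)
    if (!iterative) break
  }
  chain
}

#' Derive the amidated species from a glycine-extended fragment
#'
#' C-terminal amides arise from an exposed precursor glycine: the glycine is
#' removed and the new C terminus is flagged amidated. Returns \code{NULL}
#' when the fragment does not end in glycine or the product would be empty.
#'
#' @param sequence Fragment amino-acid string.
#' @return \code{list(sequence =, amidated = TRUE)} or \code{NULL}.
#' @export
amidate <- function(sequence) {
  n <- nchar(sequence)
  if (n < 2 || substr(sequence, n, n) != "G") return(NULL)
  list(sequence = substr(sequence, 1, n - 1), amidated = TRUE)
}

# default per-precursor carboxypeptidase responsibility: CPB1 for the
# SST/NPW/PPY-like precursors, CPE elsewhere (mirrors the narrower reported
# CPB1 repertoire).
default_carboxy_map <- function(registry) {
  genes <- vapply(registry, `[[`, "", "gene_symbol")
  stats::setNames(ifelse(genes %in% c("SST", "NPW", "PPY"), "CPB1", "CPE"),
                  names(registry))
}

signal_end <- function(record) {
  f <- record$features
  sig <- f$end[f$kind == "signal"]
  if (length(sig)) max(sig) else 0L
}

#' Simulate the peptidome of one genotype
#'
#' Runs the four processing mechanisms over every precursor in the registry.
#' \code{genotype} names the disabled enzymes (subset of PCSK1, PCSK2, CPE,
#' CPB1, DPP4); the wild type is \code{character(0)}. Endoproteolysis stops
#' only when both PCSK1 and PCSK2 are disabled. Trimming chains contribute
#' their terminal species only (intermediates are transient in vivo); at
#' partial carboxy efficiency the chain stops stochastically mid-way. With
#' DPP4 active an eligible species is replaced by its cleavage product.
#'
#' @param registry A \code{precursor_registry} with features attached.
#' @param genotype Character vector of disabled enzymes.
#' @param rules An \code{\link{enzyme_rules}} object.
#' @param seed Integer seed (only consulted when some efficiency < 1).
#' @param carboxy_map Named character vector accession -> "CPE"/"CPB1";
#'   defaults to the package assignment.
#' @param min_length Minimum species length retained (LC-MS detectability
#'   floor).
#' @return Data frame of species: \code{accession, sequence, start, end,
#'   amidated}.
#' @export
simulate_peptidome <- function(registry, genotype = character(),
                               rules = enzyme_rules(), seed = 1L,
                               carboxy_map = NULL, min_length = 5L) {
  stopifnot(inherits(registry, "precursor_registry"))
  known <- c("PCSK1", "PCSK2", "CPE", "CPB1", "DPP4")
  if (length(setdiff(genotype, known)))
    stopf("unknown enzyme(s) in genotype: %s",
          paste(setdiff(genotype, known), collapse = ", "))
  carboxy_map <- carboxy_map %||% default_carboxy_map(registry)
  stochastic <- any(c(rules$endo, rules$carboxy, rules$dpp4, rules$amidation) < 1)
  run <- function() {
    out <- list()
    emit <- function(acc, sequence, start, end, amidated)
      out[[length(out) + 1]] <<- data.frame(accession = acc, sequence = sequence,
                                            start = start, end = end,
                                            amidated = amidated,
                                            stringsAsFactors = FALSE)
    endo_active <- !all(c("PCSK1", "PCSK2") %in% genotype)
    dpp4_active <- !("DPP4" %in% genotype)
    for (acc in names(registry)) {
      rec <- registry[[acc]]
      sig <- signal_end(rec)
      region <- substr(rec$sequence, sig + 1L, nchar(rec$sequence))
      frags <- digest_endo(region, if (endo_active) rules$endo else 0,
                           start_pos = sig + 1L)
      carb_active <- !(carboxy_map[[acc]] %in% genotype)
      for (i in seq_len(nrow(frags))) {
        sp <- frags$sequence[i]; s <- frags$start[i]; e <- frags$end[i]
        if (carb_active) {
          while (nchar(sp) > 1 && is_basic(substr(sp, nchar(sp), nchar(sp))) &&
                 (rules$carboxy >= 1 || stats::runif(1) < rules$carboxy)) {
            sp <- substr(sp, 1, nchar(sp) - 1); e <- e - 1L
          }
        }
        species <- list(list(sequence = sp, start = s, end = e, amidated = FALSE))
        am <- amidate(sp)
        if (!is.null(am) &&
            (rules$amidation >= 1 || stats::runif(1) < rules$amidation))
          species <- c(species, list(list(sequence = am$sequence, start = s,
                                          end = e - 1L, amidated = TRUE)))
        for (spc in species) {
          cur <- spc
          if (dpp4_active && nchar(cur$sequence) >= 3 &&
              substr(cur$sequence, 2, 2) %in% c("P", "A") &&
              (rules$dpp4 >= 1 || stats::runif(1) < rules$dpp4)) {
            chain <- trim_amino_dpp4(cur$sequence, active = TRUE,
                                     iterative = rules$dpp4_iterative)
            prod <- chain[length(chain)]
            cur <- list(sequence = prod,
                        start = cur$start + (nchar(cur$sequence) - nchar(prod)),
                        end = cur$end, amidated = cur$amidated)
          }
          if (nchar(cur$sequence) >= min_length)
            emit(acc, cur$sequence, cur$start, cur$end, cur$amidated)
        }
      }
    }
    res <- do.call(rbind, out)
    res[!duplicated(species_key(res$accession, res$sequence, res$start,
                                res$end, res$amidated)), , drop = FALSE]
  }
  res <- if (stochastic) withr::with_seed(seed, run()) else run()
  rownames(res) <- NULL
  res
}

#' Ground-truth species table for a knockout scenario
#'
#' Simulates the wild-type and knockout peptidomes at efficiency 1 and labels
#' the union: species present only in the knockout are \code{ko_accumulating}
#' (they carry the disabled enzyme's uncut signature), species present only in
#' the wild type are \code{mature} (their production requires the enzyme), and
#' shared species are \code{constitutive}.
#'
#' @inheritParams simulate_peptidome
#' @param ko_genotype Disabled enzymes of the knockout line.
#' @return Data frame of species with columns \code{accession, sequence,
#'   start, end, amidated, label, enzyme}.
#' @export
species_truth <- function(registry, ko_genotype, rules = enzyme_rules(),
                          carboxy_map = NULL, min_length = 5L) {
  wt <- simulate_peptidome(registry, character(), rules,
                           carboxy_map = carboxy_map, min_length = min_length)
  ko <- simulate_peptidome(registry, ko_genotype, rules,
                           carboxy_map = carboxy_map, min_length = min_length)
  kw <- species_key(wt$accession, wt$sequence, wt$start, wt$end, wt$amidated)
  kk <- species_key(ko$accession, ko$sequence, ko$start, ko$end, ko$amidated)
  all <- rbind(wt, ko)
  keys <- c(kw, kk)
  keep <- !duplicated(keys)
  out <- all[keep, , drop = FALSE]
  okeys <- keys[keep]
  out$label <- ifelse(okeys %in% kw & okeys %in% kk, "constitutive",
                      ifelse(okeys %in% kk, "ko_accumulating", "mature"))
  out$enzyme <- paste(ko_genotype, collapse = "+")
  rownames(out) <- NULL
  out
}

#' Study design for the simulator
#'
#' Defaults mirror the knockout peptidomics design: one bulk and one clonal
#' wild-type line, two knockout clones, three technical replicates each,
#' a single BMP state.
#'
#' @param ko_label Genotype label for the knockout samples (e.g. "CPE").
#' @param wt_clones,ko_clones Clone identifiers per genotype.
#' @param replicates Technical replicates per clone (>= 1).
#' @param bmp_states Subset of \code{c("minus", "plus")}.
#' @return A list of class \code{sim_design}.
#' @export
sim_design <- function(ko_label = "CPE",
                       wt_clones = c("bulk", "wt1"),
                       ko_clones = c("ko1", "ko2"),
                       replicates = 3L,
                       bmp_states = "minus") {
  if (replicates < 1) stopf("replicates must be >= 1")
  if (!all(bmp_states %in% c("minus", "plus")))
    stopf("bmp_states must be a subset of c('minus', 'plus')")
  structure(list(ko_label = ko_label, wt_clones = wt_clones,
                 ko_clones = ko_clones, replicates = as.integer(replicates),
                 bmp_states = bmp_states),
            class = "sim_design")
}

#' Measurement-noise model for simulated abundance tables
#'
#' Abundances are generated on the log2 scale as species base level + clone
#' effect + knockout effect + technical noise, then exponentiated; the lowest
#' \code{censor_quantile} fraction of intensities is set missing
#' (left-censoring, the regime the down-shifted imputation assumes).
#'
#' @param log2_sd_technical Per-measurement noise sd (log2).
#' @param log2_sd_biological Clone-effect sd (log2).
#' @param ko_log2_shift Knockout effect size: an affected species sits at its
#'   base level in the genotype where the chemistry produces it and at
#'   base - shift in the genotype where it is depleted (ko_accumulating
#'   species are depleted in the wild type, mature species in the knockout),
#'   giving a KO-vs-WT log2 fold change of +shift / -shift respectively.
#' @param censor_quantile Fraction of lowest intensities set missing, in [0,1).
#' @param log2_base_mean,log2_base_sd Distribution of species base levels.
#' @return A list of class \code{noise_model}.
#' @export
noise_model <- function(log2_sd_technical = 0.5, log2_sd_biological = 0,
                        ko_log2_shift = 4, censor_quantile = 0.1,
                        log2_base_mean = 20, log2_base_sd = 2) {
  if (log2_sd_technical < 0 || log2_sd_biological < 0)
    stopf("noise sds must be nonnegative")
  if (censor_quantile < 0 || censor_quantile >= 1)
    stopf("censor_quantile must lie in [0, 1)")
  structure(list(log2_sd_technical = log2_sd_technical,
                 log2_sd_biological = log2_sd_biological,
                 ko_log2_shift = ko_log2_shift,
                 censor_quantile = censor_quantile,
                 log2_base_mean = log2_base_mean,
                 log2_base_sd = log2_base_sd),
            class = "noise_model")
}

#' Generate a replicate-structured quantification table from species truth
#'
#' In addition to the hormone-derived species of \code{truth}, a constitutive
#' background peptidome of \code{n_background} random peptides (unmapped to
#' any precursor, no knockout response) is generated, emulating the large
#' unchanged fraction of a real label-free peptidome over which
#' total-intensity normalization and the permutation null are computed.
#'
#' @param truth Output of \code{\link{species_truth}}.
#' @param design A \code{\link{sim_design}}.
#' @param noise A \code{\link{noise_model}}.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param n_background Number of constitutive background peptides appended.
#' @return List with elements \code{quant} (a \code{\link{quant_table}}),
#'   \code{truth} (the species table row-aligned with the quant table,
#'   background rows carrying \code{NA} accession) and
#'   \code{censor_threshold}.
#' @export
generate_quant_table <- function(truth, design = sim_design(),
                                 noise = noise_model(), seed = 1L,
                                 n_background = 300L) {
  stopifnot(inherits(design, "sim_design"), inherits(noise, "noise_model"))
  if (n_background > 0) {
    bg <- withr::with_seed(seed + 7L, {
      lens <- sample(9:25, n_background, replace = TRUE)
      vapply(lens, function(l)
        paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""), "")
    })
    truth <- rbind(truth,
                   data.frame(accession = NA_character_, sequence = bg,
                              start = NA_integer_, end = NA_integer_,
                              amidated = FALSE, label = "constitutive",
                              enzyme = truth$enzyme[1] %||% "",
                              stringsAsFactors = FALSE))
  }
  clones <- data.frame(
    clone_id = c(paste0("WT-", design$wt_clones),
                 paste0(design$ko_label, "-", design$ko_clones)),
    genotype = rep(c("WT", design$ko_label),
                   c(length(design$wt_clones), length(design$ko_clones))),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(clones)), function(i) {
    expand.grid(clone_id = clones$clone_id[i], bmp = design$bmp_states,
                replicate = seq_len(design$replicates),
                stringsAsFactors = FALSE)
  }))
  samples$genotype <- clones$genotype[match(samples$clone_id, clones$clone_id)]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$clone_id, samples$bmp,
                               samples$replicate)
  samples <- samples[, c("sample_id", "clone_id", "genotype", "bmp", "replicate")]

  m <- nrow(truth); n <- nrow(samples)
  mat <- withr::with_seed(seed, {
    base <- stats::rnorm(m, noise$log2_base_mean, noise$log2_base_sd)
    clone_eff <- matrix(stats::rnorm(m * nrow(clones), 0,
                                     noise$log2_sd_biological),
                        nrow = m, dimnames = list(NULL, clones$clone_id))
    vals <- matrix(0, m, n)
    for (j in seq_len(n)) {
      is_ko <- samples$genotype[j] != "WT"
      depleted <- if (is_ko) truth$label == "mature" else
        truth$label == "ko_accumulating"
      vals[, j] <- base - depleted * noise$ko_log2_shift +
        clone_eff[, samples$clone_id[j]] +
        stats::rnorm(m, 0, noise$log2_sd_technical)
    }
    vals
  })
  intensity <- 2^mat
  thr <- stats::quantile(intensity, noise$censor_quantile, names = FALSE)
  intensity[intensity < thr] <- NA_real_
  # species below the detection floor in every sample would never be
  # identified; drop them rather than shipping empty rows
  detected <- rowSums(!is.na(intensity)) > 0
  intensity <- intensity[detected, , drop = FALSE]
  truth <- truth[detected, , drop = FALSE]
  rownames(truth) <- NULL
  colnames(intensity) <- samples$sample_id
  peptides <- data.frame(
    sequence = truth$sequence,
    modifications = ifelse(truth$amidated, "amidated_C_term", ""),
    accession = truth$accession, start = truth$start, end = truth$end,
    stringsAsFactors = FALSE)
  list(quant = quant_table(intensity, peptides, samples),
       truth = truth, censor_threshold = thr)
}
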