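# Targeted MS1 verification: theoretical isotope envelopes by convolution of
# natural isotope abundances, the isotope dot product (idotp), isotope-summed
# abundance, and detection calling with the idotp / retention-time rules.

# Residue elemental formulas (residue = amino acid minus water), CHNOS.
AA_FORMULAS <- {
  f <- rbind(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  colnames(f) <- c("C", "H", "N", "O", "S")
  f
}

# Pinned natural isotope abundances; rows are nominal mass offsets 0..4.
ISOTOPE_ABUNDANCES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))

#' Elemental composition of a peptide ion
#'
#' Sums residue formulas plus one water, then applies modification deltas:
#' C-terminal amidation replaces the acid -OH with -NH2 (net -O +N +H),
#' oxidation adds O, N-terminal acetylation adds C2H2O. With \code{charge}
#' > 0 the protons of the charge state are included.
#'
#' @param sequence Amino-acid string (canonical 20-letter alphabet).
#' @param modifications Character vector over \code{amidated_C_term},
#'   \code{oxidation} (repeatable), \code{acetyl_N_term}.
#' @param charge Number of added protons (default 0 = neutral molecule).
#' @return Named integer vector of C, H, N, O, S counts.
#' @export
elemental_composition <- function(sequence, modifications = character(),
                                  charge = 0L) {
  if (!nzchar(sequence)) stopf("sequence must be non-empty")
  ch <- seq_chars(sequence)
  bad <- setdiff(unique(ch), rownames(AA_FORMULAS))
  if (length(bad)) stopf("unknown residue(s): %s", paste(bad, collapse = ", "))
  comp <- colSums(AA_FORMULAS[ch, , drop = FALSE])
  comp["H"] <- comp["H"] + 2; comp["O"] <- comp["O"] + 1   # + water
  for (mod in modifications) {
    if (mod == "amidated_C_term") {
      comp["O"] <- comp["O"] - 1; comp["N"] <- comp["N"] + 1
      comp["H"] <- comp["H"] + 1
    } else if (mod == "oxidation") {
      comp["O"] <- comp["O"] + 1
    } else if (mod == "acetyl_N_term") {
      comp["C"] <- comp["C"] + 2; comp["H"] <- comp["H"] + 2
      comp["O"] <- comp["O"] + 1
    } else if (nzchar(mod)) stopf("unknown modification: '%s'", mod)
  }
  comp["H"] <- comp["H"] + as.integer(charge)
  storage.mode(comp) <- "integer"
  comp
}

# truncated polynomial product of two isotope distributions
conv_trunc <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1)
    if (jmax < 1) next
    idx <- i + seq_len(jmax) - 1
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# distribution of `count` atoms of one element, truncated to n offsets
element_power <- function(dist, count, n) {
  result <- c(1, numeric(n - 1))
  base <- c(dist, numeric(max(0, n - length(dist))))[seq_len(n)]
  while (count > 0) {
    if (count %% 2 == 1) result <- conv_trunc(result, base, n)
    base <- conv_trunc(base, base, n)
    count <- count %/% 2
  }
  result
}

#' Theoretical isotope envelope of an elemental composition
#'
#' Convolves the natural-abundance isotope distributions of C, H, N, O and S
#' (pinned in the package constants), truncates to the first
#' \code{n_isotopes} isotopologues (M, M+1, ...) and renormalizes to sum 1.
#' Truncation is exact for the retained terms: heavier isotopologues never
#' contribute to lighter ones.
#'
#' @param composition Named counts as from \code{\link{elemental_composition}}.
#' @param n_isotopes Number of isotopologues retained (default 5, M..M+4).
#' @return An \code{isotope_envelope}: numeric vector of intensities summing
#'   to 1, class-tagged.
#' @export
theoretical_envelope <- function(composition, n_isotopes = 5L) {
  if (any(composition < 0)) stopf("element counts must be nonnegative")
  env <- c(1, numeric(n_isotopes - 1))
  for (el in names(ISOTOPE_ABUNDANCES)) {
    cnt <- composition[el]
    if (is.na(cnt) || cnt == 0) next
    env <- conv_trunc(env, element_power(ISOTOPE_ABUNDANCES[[el]], cnt,
                                         n_isotopes), n_isotopes)
  }
  structure(env / sum(env), class = "isotope_envelope")
}

#' Isotope dot product between observed and theoretical envelopes
#'
#' The normalized dot product \eqn{\langle o, t\rangle / (\|o\| \|t\|)},
#' a scale-invariant similarity in [0, 1]; an all-zero observation scores 0.
#'
#' @param observed,theoretical Numeric vectors of equal length (theoretical
#'   must be non-zero).
#' @return Numeric scalar in [0, 1].
#' @export
idotp <- function(observed, theoretical) {
  o <- as.numeric(observed); t <- as.numeric(theoretical)
  if (length(o) != length(t))
    stopf("envelope lengths differ (%d vs %d)", length(o), length(t))
  if (all(t == 0)) stopf("theoretical envelope is all zero")
  if (all(o == 0)) return(0)
  sum(o * t) / sqrt(sum(o^2) * sum(t^2))
}

#' Isotope-summed total abundance
#'
#' Sum of the individual isotopologue intensities (M..M+4); the log2 value is
#' attached for display parity with log2-space abundance plots.
#'
#' @param observed Numeric vector of 5 isotopologue intensities.
#' @return Numeric total; \code{attr(, "log2")} holds log2 of the total
#'   (\code{NA} for a zero total).
#' @export
total_abundance <- function(observed) {
  o <- as.numeric(observed)
  if (length(o) != 5) stopf("expected 5 isotopologue intensities (M..M+4)")
  tot <- sum(o)
  attr(tot, "log2") <- if (tot > 0) log2(tot) else NA_real_
  tot
}

#' Detection call for a targeted MS1 ion
#'
#' Detected iff idotp(observed, theoretical) >= \code{idotp_threshold} and,
#' when a retention time is supplied, it falls inside \code{rt_window}
#' (inclusive). Non-detections report abundance 0 (the "n.d." rule).
#'
#' @param observed,theoretical Isotope envelopes (length 5).
#' @param idotp_threshold Similarity threshold (default 0.88).
#' @param rt_observed Observed retention time in minutes, or \code{NULL} to
#'   skip the window check.
#' @param rt_window Expected elution window, minutes (default c(89, 91)).
#' @return List: \code{detected}, \code{idotp}, \code{abundance},
#'   \code{log2_abundance}.
#' @export
call_detection <- function(observed, theoretical, idotp_threshold = 0.88,
                           rt_observed = NULL, rt_window = c(89, 91)) {
  score <- idotp(observed, theoretical)
  in_rt <- is.null(rt_observed) ||
    (rt_observed >= rt_window[1] && rt_observed <= rt_window[2])
  detected <- score >= idotp_threshold && in_rt
  ab <- if (detected) sum(as.numeric(observed)) else 0
  list(detected = detected, idotp = score, abundance = ab,
       log2_abundance = if (ab > 0) log2(ab) else NA_real_)
}

#' Targeted MS1 verification over a table of observed envelopes
#'
#' For every row of \code{envelopes} (one target ion in one sample) the
#' theoretical envelope is computed from the target's sequence,
#' modifications and charge, and \code{\link{call_detection}} is applied.
#'
#' @param targets Data frame: \code{target, sequence, modifications, charge}.
#' @param envelopes Data frame: \code{target, sample_id, i0..i4}, optional
#'   \code{rt}.
#' @param idotp_threshold,rt_window Detection parameters.
#' @return Data frame: target, sample_id, idotp, detected, abundance,
#'   log2_abundance.
#' @export
ms1_verify <- function(targets, envelopes, idotp_threshold = 0.88,
                       rt_window = c(89, 91)) {
  need <- c("target", "sample_id", paste0("i", 0:4))
  missing <- setdiff(need, names(envelopes))
  if (length(missing))
    stopf("envelope table lacks column(s): %s", paste(missing, collapse = ", "))
  theo <- lapply(seq_len(nrow(targets)), function(i) {
    mods <- strsplit(targets$modifications[i] %||% "", ";")[[1]]
    theoretical_envelope(elemental_composition(targets$sequence[i], mods,
                                               targets$charge[i] %||% 0L))
  })
  names(theo) <- targets$target
  out <- lapply(seq_len(nrow(envelopes)), function(i) {
    tg <- envelopes$target[i]
    if (!tg %in% names(theo)) stopf("no target definition for '%s'", tg)
    obs <- as.numeric(envelopes[i, paste0("i", 0:4)])
    rt <- if ("rt" %in% names(envelopes)) envelopes$rt[i] else NULL
    cd <- call_detection(obs, theo[[tg]], idotp_threshold, rt, rt_window)
    data.frame(target = tg, sample_id = envelopes$sample_id[i],
               idotp = cd$idotp, detected = cd$detected,
               abundance = cd$abundance, log2_abundance = cd$log2_abundance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
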